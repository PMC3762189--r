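## Single-molecule TIRF pipeline: frame preprocessing, spot detection,
## nearest-neighbor track linking, the four-rule track filter, dwell-time
## off rates, the filament binding-site census and fraction-bound
## affinities.
##
## Images are plain numeric matrices; the first index is x, the second y
## (the EBImage convention), and detection coordinates are 1-based pixel
## centers.

#' Preprocess a raw TIRF frame
#'
#' Rolling-ball background subtraction (grayscale opening with a disc
#' structuring element of the given radius) followed by a Gaussian blur.
#' Not idempotent: a second pass erodes real spots, so apply once to raw
#' frames only.
#'
#' @param img 2-D numeric matrix.
#' @param ball_radius rolling-ball radius (px).
#' @param sigma Gaussian blur sigma (px).
#' @return Preprocessed matrix of the same size.
#' @export
preprocess_frame <- function(img, ball_radius = 10, sigma = 0.5) {
  if (length(dim(img)) != 2L) stop("img must be a 2-D matrix")
  bg <- .gray_dilate(.gray_erode(img, ball_radius), ball_radius)
  out <- img - bg
  if (sigma > 0)
    out <- EBImage::imageData(EBImage::gblur(EBImage::Image(out),
                                             sigma = sigma))
  out
}

## grayscale flat-disc morphology (compiled); pixels beyond the image
## border are ignored, so a constant image is its own background
.gray_morph <- function(img, radius, do_max) {
  stopifnot(radius >= 1, radius <= 63)
  storage.mode(img) <- "double"
  matrix(.C("arpkin_gray_morph", img = img, nx = as.integer(nrow(img)),
            ny = as.integer(ncol(img)), radius = as.integer(radius),
            do_max = as.integer(do_max),
            out = numeric(length(img)), NAOK = FALSE,
            PACKAGE = "arpkin")$out, nrow(img), ncol(img))
}
.gray_erode <- function(img, radius) .gray_morph(img, radius, 0L)
.gray_dilate <- function(img, radius) .gray_morph(img, radius, 1L)

#' Detect single molecules in a frame
#'
#' Band-pass filtering (difference of Gaussians) to suppress pixel noise
#' and slowly varying background, followed by a global threshold; each
#' connected component above threshold yields one detection at its
#' intensity-weighted centroid.
#'
#' @param frame 2-D numeric matrix (preprocessed).
#' @param low_sigma,high_sigma band-pass cutoffs: spot-scale and
#'   background-scale Gaussian sigmas (px).
#' @param threshold absolute threshold on the band-passed image; if
#'   \code{NULL}, \code{median + nsigma * mad} of the band-passed image.
#' @param nsigma threshold in robust standard deviations.
#' @param min_px minimum component size (px); a genuine PSF-sized spot
#'   covers several pixels above threshold, so tiny suprathreshold noise
#'   islands are discarded.
#' @return data.frame with columns \code{x}, \code{y}, \code{intensity}
#'   (summed band-passed signal) and \code{n_px}.  A largely saturated
#'   frame (many pixels at the maximum value) triggers a warning.
#' @export
detect_molecules <- function(frame, low_sigma = 1, high_sigma = 3,
                             threshold = NULL, nsigma = 5, min_px = 3L) {
  if (length(dim(frame)) != 2L) stop("frame must be a 2-D matrix")
  mx <- max(frame)
  if (mx > 0 && mean(frame == mx) > 0.001)
    warning("frame looks saturated: >0.1% of pixels at the maximum value")
  im <- EBImage::Image(frame)
  bp <- EBImage::gblur(im, sigma = low_sigma) -
    EBImage::gblur(im, sigma = high_sigma)
  bp <- EBImage::imageData(bp)
  if (is.null(threshold))
    threshold <- median(bp) + nsigma * mad(bp)
  mask <- bp > threshold
  if (!any(mask))
    return(data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0), n_px = integer(0)))
  ## watershed on the band-passed intensity splits touching spots; the
  ## tolerance (threshold scale) keeps noise bumps from splitting one spot
  lab <- EBImage::imageData(EBImage::watershed(
    EBImage::Image((bp - threshold) * mask), tolerance = abs(threshold)))
  keep <- which(lab > 0)
  ids <- lab[keep]
  w <- pmax(bp[keep] - threshold, 0)
  xs <- ((keep - 1L) %% nrow(frame)) + 1L
  ys <- ((keep - 1L) %/% nrow(frame)) + 1L
  sw <- tapply(w, ids, sum)
  sx <- tapply(w * xs, ids, sum) / sw
  sy <- tapply(w * ys, ids, sum) / sw
  si <- tapply(bp[keep], ids, sum)
  np <- tapply(rep(1L, length(ids)), ids, sum)
  out <- data.frame(x = as.numeric(sx), y = as.numeric(sy),
                    intensity = as.numeric(si), n_px = as.integer(np))
  out[out$n_px >= min_px, , drop = FALSE]
}

#' Link per-frame detections into molecule tracks
#'
#' Greedy mutual-nearest-neighbor linking between consecutive frames:
#' candidate pairs within \code{max_displacement} are linked in order of
#' increasing distance, each detection at most once.  There is no gap
#' closing -- a molecule absent for one frame ends its track and a new
#' track begins on reappearance.
#'
#' @param detections data.frame with columns \code{frame}, \code{x},
#'   \code{y} and optionally \code{intensity}.
#' @param max_displacement maximum frame-to-frame movement (px).
#' @return The detections with a \code{track_id} column, class
#'   \code{arp_tracks}.
#' @export
link_tracks <- function(detections, max_displacement = 3) {
  if (max_displacement <= 0) stop("max_displacement must be positive")
  need <- c("frame", "x", "y")
  if (nrow(detections) == 0L) {
    detections$track_id <- integer(0)
    return(structure(detections, class = c("arp_tracks", "data.frame")))
  }
  if (!all(need %in% names(detections)))
    stop("detections need columns frame, x, y")
  detections <- detections[order(detections$frame), , drop = FALSE]
  det <- detections
  det$track_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(det$frame))
  prev_idx <- which(det$frame == frames[1])
  det$track_id[prev_idx] <- seq_len(length(prev_idx))
  next_id <- length(prev_idx) + 1L
  for (fi in seq_along(frames)[-1]) {
    cur_idx <- which(det$frame == frames[fi])
    linked <- rep(FALSE, length(cur_idx))
    if (frames[fi] == frames[fi - 1L] + 1L && length(prev_idx)) {
      dx <- outer(det$x[prev_idx], det$x[cur_idx], "-")
      dy <- outer(det$y[prev_idx], det$y[cur_idx], "-")
      dd <- sqrt(dx^2 + dy^2)
      dd[dd > max_displacement] <- NA
      while (any(is.finite(dd))) {
        best <- arrayInd(which.min(dd), dim(dd))
        i <- best[1]; j <- best[2]
        det$track_id[cur_idx[j]] <- det$track_id[prev_idx[i]]
        linked[j] <- TRUE
        dd[i, ] <- NA; dd[, j] <- NA
      }
    }
    if (any(!linked)) {
      det$track_id[cur_idx[!linked]] <-
        next_id + seq_len(sum(!linked)) - 1L
      next_id <- next_id + sum(!linked)
    }
    prev_idx <- cur_idx
  }
  structure(det, class = c("arp_tracks", "data.frame"))
}

#' Summarize tracks to one row per molecule
#'
#' @param tracks an \code{arp_tracks} data.frame.
#' @param frame_interval seconds per frame (used when \code{frame_times}
#'   is not given).
#' @param frame_times optional per-frame timestamps (s); lifetimes then use
#'   the measured frame rate, timestamp of last minus first frame plus one
#'   frame interval.
#' @return data.frame with \code{track_id}, \code{first_frame},
#'   \code{last_frame}, \code{lifetime_frames}, \code{lifetime_s},
#'   \code{x}, \code{y} (mean position) and \code{mean_intensity}.
#' @export
track_stats <- function(tracks, frame_interval = 1, frame_times = NULL) {
  if (nrow(tracks) == 0L)
    return(data.frame(track_id = integer(0), first_frame = integer(0),
                      last_frame = integer(0), lifetime_frames = integer(0),
                      lifetime_s = numeric(0), x = numeric(0),
                      y = numeric(0), mean_intensity = numeric(0)))
  sp <- split(seq_len(nrow(tracks)), tracks$track_id)
  rows <- lapply(sp, function(ii) {
    fr <- tracks$frame[ii]
    lf <- length(ii)
    if (!is.null(frame_times)) {
      dt <- if (length(frame_times) > 1)
        mean(diff(frame_times)) else frame_interval
      ls <- frame_times[max(fr)] - frame_times[min(fr)] + dt
    } else ls <- lf * frame_interval
    data.frame(track_id = tracks$track_id[ii[1]],
               first_frame = min(fr), last_frame = max(fr),
               lifetime_frames = lf, lifetime_s = ls,
               x = mean(tracks$x[ii]), y = mean(tracks$y[ii]),
               mean_intensity = if ("intensity" %in% names(tracks))
                 mean(tracks$intensity[ii]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter molecule tracks by the four standard criteria
#'
#' In order: (1) the molecule must not be present in the first or last
#' frame of the acquisition; (2) its lifetime must exceed one frame; (3)
#' its average intensity must lie within one standard deviation of the
#' mean of all track-average intensities; (4) it must be associated with
#' an actin filament (its mean position on, or within
#' \code{assoc_radius} of, the filament mask).  Each criterion can be
#' toggled; per-criterion rejection counts are recorded in the
#' \code{rejections} attribute.
#'
#' @param stats track summary from \code{\link{track_stats}}.
#' @param first_frame,last_frame frame indices bounding the acquisition.
#' @param filament_mask logical/numeric matrix marking filament pixels
#'   (required when criterion 4 is enabled).
#' @param assoc_radius tolerance (px) for filament association.
#' @param criteria logical vector of length 4 toggling the rules.
#' @return Filtered stats with a \code{rejections} attribute (named counts).
#' @export
filter_tracks <- function(stats, first_frame, last_frame,
                          filament_mask = NULL, assoc_radius = 2,
                          criteria = rep(TRUE, 4)) {
  stopifnot(length(criteria) == 4L)
  rej <- c(boundary = 0L, single_frame = 0L, intensity = 0L,
           off_filament = 0L)
  keep <- rep(TRUE, nrow(stats))
  if (criteria[1]) {
    bad <- stats$first_frame <= first_frame | stats$last_frame >= last_frame
    rej["boundary"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (criteria[2]) {
    bad <- stats$lifetime_frames <= 1L
    rej["single_frame"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (criteria[3]) {
    mi <- stats$mean_intensity[keep]
    mu <- mean(mi); s <- sd(mi)
    bad <- abs(stats$mean_intensity - mu) > s
    bad[is.na(bad)] <- FALSE
    rej["intensity"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (criteria[4]) {
    if (is.null(filament_mask))
      stop("filament_mask required when the filament-association ",
           "criterion is enabled")
    mask <- filament_mask > 0
    if (assoc_radius > 0)
      mask <- EBImage::imageData(EBImage::dilate(
        EBImage::Image(mask * 1),
        EBImage::makeBrush(2L * ceiling(assoc_radius) + 1L,
                           shape = "disc"))) > 0
    xi <- pmin(pmax(round(stats$x), 1L), nrow(mask))
    yi <- pmin(pmax(round(stats$y), 1L), ncol(mask))
    bad <- !mask[cbind(xi, yi)]
    rej["off_filament"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  structure(stats[keep, , drop = FALSE], rejections = rej)
}

#' Classify tracks by binding location
#'
#' A track is \code{branch_junction} when its mean position lies within
#' \code{radius} of a junction present throughout its lifetime,
#' \code{nascent_branch} when a junction appears at its location during
#' its lifetime, and \code{filament_side} otherwise.
#'
#' @param stats track summary (\code{\link{track_stats}} output).
#' @param junctions data.frame with junction \code{x}, \code{y} and
#'   optionally \code{appear_frame} (default: present from the start).
#' @param radius association radius (px).
#' @return \code{stats} with a \code{binding_class} column.
#' @export
classify_tracks <- function(stats, junctions, radius = 3) {
  cls <- rep("filament_side", nrow(stats))
  if (!is.null(junctions) && nrow(junctions) > 0) {
    af <- junctions$appear_frame %||% rep(-Inf, nrow(junctions))
    for (i in seq_len(nrow(stats))) {
      d2 <- (junctions$x - stats$x[i])^2 + (junctions$y - stats$y[i])^2
      near <- which(d2 <= radius^2)
      if (length(near) == 0L) next
      j <- near[which.min(d2[near])]
      cls[i] <- if (af[j] > stats$first_frame[i] &&
                    af[j] <= stats$last_frame[i])
        "nascent_branch" else if (af[j] <= stats$first_frame[i])
          "branch_junction" else "filament_side"
    }
  }
  stats$binding_class <- cls
  stats
}

#' Off rate from a dwell-time sample
#'
#' Lifetimes are binned (default 5 s), the empirical survival function
#' 1 - cumulative frequency is evaluated at the bin upper edges, and a
#' single-exponential decay \code{A exp(-k t)} is fit by unweighted least
#' squares.  The mean bound lifetime is the reciprocal of the fitted off
#' rate.
#'
#' @param lifetimes_s dwell times (s), at least 20.
#' @param bin_width histogram bin width (s).
#' @return Object of class \code{arp_offrate}: list with \code{k_off}
#'   (1/s), \code{tau} (s), \code{amplitude}, \code{n}, and the binned
#'   survival table in \code{survival}.
#' @export
#' @examples
#' lt <- gen_dwell_times(0.05, n = 500, frame_interval = 0.2,
#'                       movie_span = 1e4, seed = 7)
#' off_rate_from_lifetimes(lt$lifetime_s)
off_rate_from_lifetimes <- function(lifetimes_s, bin_width = 5) {
  if (bin_width <= 0) stop("bin_width must be positive")
  lifetimes_s <- lifetimes_s[is.finite(lifetimes_s)]
  n <- length(lifetimes_s)
  if (n < 20L) stop("need at least 20 dwell times (got ", n, ")")
  edges <- seq(0, (max(lifetimes_s) %/% bin_width + 1) * bin_width,
               by = bin_width)
  counts <- tabulate(findInterval(lifetimes_s, edges, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  if (sum(counts > 0) < 2L)
    stop("all dwell times fall in a single bin; decrease bin_width")
  tt <- edges[-1]
  surv <- 1 - cumsum(counts) / n
  start_k <- 1 / mean(lifetimes_s)
  fit <- minpack.lm::nlsLM(surv ~ A * exp(-k * tt),
                           start = list(A = 1, k = start_k),
                           lower = c(0, 1e-12),
                           control = stats::nls.control(maxiter = 200))
  k <- coef(fit)[["k"]]
  structure(list(k_off = k, tau = 1 / k, amplitude = coef(fit)[["A"]],
                 n = n, bin_width = bin_width,
                 survival = data.frame(t = tt, survival = surv)),
            class = "arp_offrate")
}

#' @export
print.arp_offrate <- function(x, ...) {
  cat(sprintf(paste0("Dwell-time exponential fit (n = %d, %g s bins): ",
                     "k_off = %.4g /s, tau = %.3g s\n"),
              x$n, x$bin_width, x$k_off, x$tau))
  invisible(x)
}

#' Census of cortactin binding sites on segmented filaments
#'
#' Converts a binary filament mask to a count of cortactin side-binding
#' sites: junction pixels (5 per junction) are subtracted from the mask
#' area, the remainder is divided by the average filament width (3 px) to
#' give filament length in pixels, converted to micrometers (106.7 nm/px)
#' and to subunits (370 subunits/um), and divided by the
#' cortactin:F-actin stoichiometry (1:6).  The result is rounded down.
#'
#' @param filament_mask binary matrix of filament pixels, or a plain pixel
#'   count.
#' @param n_junctions number of branch junctions in the field.
#' @param pixel_size_nm physical pixel size (nm).
#' @param filament_width_px average filament width in the mask (px).
#' @param junction_px pixels occupied by one junction.
#' @param subunits_per_um actin subunits per micrometer of filament.
#' @param stoichiometry F-actin subunits per cortactin site.
#' @return Object of class \code{arp_census}: list with
#'   \code{filament_pixels}, \code{n_junctions}, \code{filament_um},
#'   \code{subunits}, \code{side_sites} and \code{junction_site_share}
#'   (junctions as a fraction of all binding sites).
#' @export
#' @examples
#' count_side_sites(10000, 10)$side_sites   # 21823
count_side_sites <- function(filament_mask, n_junctions,
                             pixel_size_nm = 106.7, filament_width_px = 3,
                             junction_px = 5, subunits_per_um = 370,
                             stoichiometry = 6) {
  px <- if (is.matrix(filament_mask)) sum(filament_mask > 0)
        else as.numeric(filament_mask)
  if (n_junctions < 0) stop("n_junctions must be >= 0")
  if (junction_px * n_junctions > px)
    stop("junction pixels exceed the filament mask")
  len_px <- (px - junction_px * n_junctions) / filament_width_px
  len_um <- len_px * pixel_size_nm / 1000
  subunits <- len_um * subunits_per_um
  sites <- floor(subunits / stoichiometry)
  structure(list(filament_pixels = px, n_junctions = n_junctions,
                 pixel_size_nm = pixel_size_nm,
                 filament_width_px = filament_width_px,
                 junction_px = junction_px,
                 subunits_per_um = subunits_per_um,
                 stoichiometry = stoichiometry,
                 filament_um = len_um, subunits = subunits,
                 side_sites = sites,
                 junction_site_share = if (sites + n_junctions > 0)
                   n_junctions / (sites + n_junctions) else 0),
            class = "arp_census")
}

#' @export
print.arp_census <- function(x, ...) {
  cat(sprintf(paste0("Binding-site census: %d filament px (%.1f um, ",
                     "%.0f subunits)\n  %d side sites, %d junctions ",
                     "(%.3g%% of all sites)\n"),
              x$filament_pixels, x$filament_um, x$subunits, x$side_sites,
              x$n_junctions, 100 * x$junction_site_share))
  invisible(x)
}

#' Dissociation constant from an equilibrium fraction bound
#'
#' Under excess-ligand conditions (free ligand ~ total ligand), site
#' occupancy \code{fb = c / (K_D + c)} inverts to
#' \code{K_D = c / fb - c}.
#'
#' @param fraction_bound average fraction of sites occupied, in (0, 1).
#' @param ligand_conc free ligand concentration (any concentration unit;
#'   K_D is returned in the same unit).
#' @export
#' @examples
#' kd_from_fraction_bound(0.5, 1)          # half occupancy: K_D = ligand
kd_from_fraction_bound <- function(fraction_bound, ligand_conc) {
  if (any(fraction_bound <= 0) || any(fraction_bound >= 1))
    stop("fraction_bound must be strictly between 0 and 1")
  if (any(ligand_conc <= 0)) stop("ligand_conc must be positive")
  ligand_conc / fraction_bound - ligand_conc
}

#' Excess-ligand sanity check for single-molecule affinity measurements
#'
#' Extrapolates the per-image count of bound molecules to the whole
#' reaction chamber and compares it with the total number of ligand
#' molecules, verifying that binding depletes a negligible fraction so the
#' free concentration equals the total.
#'
#' @param avg_bound_per_frame mean bound molecules per image frame.
#' @param chamber_area_mm2 reaction chamber area (mm^2).
#' @param image_px image dimensions in pixels.
#' @param pixel_size_nm pixel size (nm).
#' @param volume_ul chamber volume (ul).
#' @param conc_nM ligand concentration (nM).
#' @return list with \code{image_area_mm2}, \code{image_fraction_pct},
#'   \code{bound_per_chamber}, \code{total_molecules} and
#'   \code{percent_bound}.
#' @export
excess_ligand_check <- function(avg_bound_per_frame,
                                chamber_area_mm2 = 120,
                                image_px = c(512, 512),
                                pixel_size_nm = 106.7,
                                volume_ul = 12, conc_nM = 1.5) {
  if (chamber_area_mm2 <= 0) stop("chamber area must be positive")
  stopifnot(all(c(pixel_size_nm, volume_ul, conc_nM) > 0),
            avg_bound_per_frame >= 0)
  img_mm2 <- prod(image_px) * (pixel_size_nm * 1e-6)^2
  frac <- img_mm2 / chamber_area_mm2
  bound_chamber <- avg_bound_per_frame / frac
  total <- volume_ul * 1e-6 * conc_nM * 1e-9 * 6.02214076e23
  list(image_area_mm2 = img_mm2,
       image_fraction_pct = 100 * frac,
       bound_per_chamber = bound_chamber,
       total_molecules = total,
       percent_bound = 100 * bound_chamber / total)
}
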