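## Seeded synthetic-data generators: noisy pyrene-trace ensembles from any
## network variant, censored exponential dwell-time samples, and
## two-channel TIRF-like movies with filaments, junctions and
## binding/unbinding molecules.  Every generator is a pure function of its
## arguments plus the seed and emits its ground truth.

#' Generate a noisy pyrene-trace ensemble from a network variant
#'
#' Simulates each reaction condition with the chosen variant and rate
#' constants and adds i.i.d. Gaussian noise with standard deviation
#' \code{noise_sd} times the trace amplitude (its maximum), emulating the
#' roughly constant detector noise of a plate-reader pyrene assay.
#' Optionally maps the traces back to raw-fluorescence units by the
#' inverse of the standard pyrene calibration.
#'
#' @param variant network variant.
#' @param conditions list of \code{\link{arp_conditions}}.
#' @param noise_sd relative noise level (fraction of trace amplitude).
#' @param seed RNG seed.
#' @param overrides rate-constant substitutions passed to
#'   \code{\link{build_network}}.
#' @param fluorescence_mode emit fluorescence-mode traces using
#'   \code{fluor_offset + fluor_gain * concentration}.
#' @param fluor_offset,fluor_gain affine fluorescence calibration used
#'   when \code{fluorescence_mode = TRUE}.
#' @return list with \code{traces} (list of \code{\link{arp_trace}}) and
#'   \code{truth} (variant, overrides, full parameter vector, noise and
#'   seed).
#' @export
gen_pyrene_ensemble <- function(variant, conditions, noise_sd = 0.01,
                                seed = 1, overrides = list(),
                                fluorescence_mode = FALSE,
                                fluor_offset = 0.05, fluor_gain = 0.31) {
  if (length(conditions) == 0L) stop("conditions must be non-empty")
  if (inherits(conditions, "arp_conditions")) conditions <- list(conditions)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  net <- build_network(variant, overrides)
  traces <- with_seed(seed, lapply(conditions, function(cond) {
    sim <- simulate_network(net, cond)
    y <- sim$F
    if (noise_sd > 0) y <- y + rnorm(length(y), sd = noise_sd * max(y))
    if (fluorescence_mode) {
      y <- fluor_offset + fluor_gain * y
      arp_trace(sim$time, y, total_actin = cond$actin, conditions = cond,
                mode = "fluorescence")
    } else {
      arp_trace(sim$time, y, total_actin = cond$actin, conditions = cond,
                mode = "concentration")
    }
  }))
  list(traces = traces,
       truth = list(variant = variant, overrides = overrides,
                    params = net$params, noise_sd = noise_sd, seed = seed,
                    fluorescence_mode = fluorescence_mode,
                    fluor_offset = fluor_offset, fluor_gain = fluor_gain))
}

#' Generate frame-quantized exponential dwell times
#'
#' Draws exponential dwell times at the given off rate, places each event
#' uniformly within the acquisition span, and quantizes to camera frames:
#' the frame-based lifetime counts every frame whose interval overlaps the
#' bound period.  Events overlapping the first or last frame are flagged
#' as censored (they would be removed by the boundary rule of
#' \code{\link{filter_tracks}}).
#'
#' @param k_off true off rate (1/s).
#' @param n number of events.
#' @param frame_interval seconds per frame.
#' @param movie_span acquisition length (s), longer than one frame.
#' @param seed RNG seed.
#' @return data.frame with \code{t_on}, \code{lifetime_true} (continuous,
#'   uncensored), \code{first_frame}, \code{last_frame},
#'   \code{lifetime_frames}, \code{lifetime_s} (frame-quantized, clipped
#'   to the movie) and \code{censored} flags.
#' @export
gen_dwell_times <- function(k_off, n, frame_interval, movie_span, seed = 1) {
  stopifnot(k_off > 0, n > 0, frame_interval > 0)
  if (movie_span <= frame_interval)
    stop("movie_span must exceed one frame interval")
  with_seed(seed, {
    lt <- rexp(n, rate = k_off)
    t_on <- runif(n, 0, movie_span)
    n_frames <- floor(movie_span / frame_interval)
    first <- pmin(floor(t_on / frame_interval) + 1L, n_frames)
    last <- pmin(floor((t_on + lt) / frame_interval) + 1L, n_frames)
    frames <- last - first + 1L
    data.frame(t_on = t_on, lifetime_true = lt,
               first_frame = first, last_frame = last,
               lifetime_frames = frames,
               lifetime_s = frames * frame_interval,
               censored = first <= 1L | last >= n_frames)
  })
}

#' Specification for a synthetic two-channel TIRF movie
#'
#' Defaults describe a field of branched actin filaments probed by a low
#' concentration of a fluorescent side- and junction-binding ligand with
#' the kinetics typical of cortactin: side binding is very slow
#' (1.21e4 /(M s)) and weak (K_D = k_off/k_on = 5.2 uM), junction binding
#' is ~160-fold faster on (2e6 /(M s)) and ~2-fold slower off
#' (K_D = 17 nM).
#'
#' @param field_px image dimensions (px).
#' @param pixel_size_nm pixel size (nm).
#' @param n_filaments number of filaments.
#' @param filament_length_px centerline length per filament (px).
#' @param branch_density_per_um junctions per micrometer of filament.
#' @param ligand_nM labeled ligand concentration (nM).
#' @param k_on_side,k_off_side,k_on_junction,k_off_junction binding
#'   kinetics per class (1/(M s) and 1/s).
#' @param frame_interval seconds per frame.
#' @param n_frames number of frames.
#' @param psf_sigma Gaussian PSF sigma (px).
#' @param amp_mean,amp_cv molecule brightness: mean peak amplitude
#'   (counts) and lognormal coefficient of variation.
#' @param bg_offset camera baseline (counts) entering the Poisson shot
#'   noise.
#' @param read_noise_sd Gaussian read noise (counts).
#' @param stoichiometry F-actin subunits per side-binding site.
#' @param seed RNG seed.
#' @return list of class \code{arp_movie_spec}.
#' @export
tirf_movie_spec <- function(field_px = c(256, 256), pixel_size_nm = 106.7,
                            n_filaments = 12, filament_length_px = 300,
                            branch_density_per_um = 0.2, ligand_nM = 1.5,
                            k_on_side = 1.21e4, k_off_side = 0.063,
                            k_on_junction = 2.0e6, k_off_junction = 0.034,
                            frame_interval = 0.5, n_frames = 2400,
                            psf_sigma = 1.1, amp_mean = 600, amp_cv = 0.1,
                            bg_offset = 100, read_noise_sd = 5,
                            stoichiometry = 6, seed = 1) {
  rates <- c(k_on_side, k_off_side, k_on_junction, k_off_junction,
             ligand_nM, frame_interval)
  if (any(rates <= 0)) stop("rates, concentration and frame interval must ",
                            "be positive")
  structure(as.list(environment()), class = "arp_movie_spec")
}

## random filament centerlines: gently curving random walks clipped to the
## field; returns an n x 2 matrix of ~1-px-spaced points per filament
.gen_polylines <- function(spec) {
  lapply(seq_len(spec$n_filaments), function(i) {
    margin <- 10
    p <- c(runif(1, margin, spec$field_px[1] - margin),
           runif(1, margin, spec$field_px[2] - margin))
    ang <- runif(1, 0, 2 * pi)
    pts <- matrix(NA_real_, spec$filament_length_px, 2)
    dir <- c(cos(ang), sin(ang))
    for (s in seq_len(spec$filament_length_px)) {
      pts[s, ] <- p
      rot <- rnorm(1, 0, 0.03)
      dir <- c(cos(rot) * dir[1] - sin(rot) * dir[2],
               sin(rot) * dir[1] + cos(rot) * dir[2])
      p2 <- p + dir
      ## reflect at the field margins so filaments keep their full length
      if (p2[1] < 3 || p2[1] > spec$field_px[1] - 2) dir[1] <- -dir[1]
      if (p2[2] < 3 || p2[2] > spec$field_px[2] - 2) dir[2] <- -dir[2]
      p <- p + dir
    }
    pts
  })
}

#' Generate a synthetic two-channel TIRF movie with ground truth
#'
#' Renders static filaments (random polylines about 3 px wide), branch
#' junctions placed along them, and single molecules that bind and unbind
#' filament-side sites and junctions with per-class exponential kinetics.
#' Molecules are drawn as Gaussian spots on a Poisson shot-noise plus
#' Gaussian read-noise background.  Side-binding sites are laid out along
#' the filament centerlines (excluding the junction footprints) at the
#' density implied by the census arithmetic of
#' \code{\link{count_side_sites}}, so the pipeline census and the
#' generator agree by construction.  Junction occupancy is simulated
#' per-site as a two-state telegraph process started from equilibrium;
#' side-site arrivals are a Poisson process (occupancy is far below
#' saturation).
#'
#' Frames are rendered on demand (\code{$frame(i)}) so long movies do not
#' need to be held in memory; rendering is deterministic per frame.
#'
#' @param spec an \code{\link{tirf_movie_spec}}.
#' @return list of class \code{arp_movie}: \code{frame(i)} renders the
#'   561-channel frame; \code{filament_image} is the static 488-channel
#'   reference; \code{filament_mask}, \code{junctions} (x, y),
#'   \code{n_side_sites}, \code{events} (ground-truth binding events with
#'   class, position, on/off times) and \code{spec}.
#' @export
gen_tirf_movie <- function(spec = tirf_movie_spec()) {
  stopifnot(inherits(spec, "arp_movie_spec"))
  with_seed(spec$seed, {
    polys <- .gen_polylines(spec)
    centerline <- do.call(rbind, polys)
    mask <- matrix(0L, spec$field_px[1], spec$field_px[2])
    cpx <- unique(round(centerline))
    mask[cpx] <- 1L
    mask <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(mask), EBImage::makeBrush(3, "disc"))) > 0

    len_um <- nrow(centerline) * spec$pixel_size_nm / 1000
    n_j <- max(1L, round(spec$branch_density_per_um * len_um))
    jcand <- centerline[sample.int(nrow(centerline)), , drop = FALSE]
    jxy <- matrix(NA_real_, 0, 2)
    for (i in seq_len(nrow(jcand))) {
      if (nrow(jxy) >= n_j) break
      if (nrow(jxy) == 0 ||
          min((jxy[, 1] - jcand[i, 1])^2 + (jxy[, 2] - jcand[i, 2])^2) > 64)
        jxy <- rbind(jxy, jcand[i, ])
    }
    n_j <- nrow(jxy)
    junctions <- data.frame(x = jxy[, 1], y = jxy[, 2])

    ## side sites on the centerline, excluding junction footprints, at the
    ## census density
    d2min <- rep(Inf, nrow(centerline))
    for (j in seq_len(n_j))
      d2min <- pmin(d2min, (centerline[, 1] - junctions$x[j])^2 +
                      (centerline[, 2] - junctions$y[j])^2)
    free_pts <- centerline[d2min > 9, , drop = FALSE]
    census <- count_side_sites(mask, n_j,
                               pixel_size_nm = spec$pixel_size_nm,
                               stoichiometry = spec$stoichiometry)
    n_sites <- census$side_sites
    site_idx <- rep(seq_len(nrow(free_pts)),
                    length.out = n_sites)
    site_xy <- free_pts[site_idx, , drop = FALSE] +
      matrix(runif(2 * n_sites, -0.5, 0.5), ncol = 2)

    span <- spec$n_frames * spec$frame_interval
    cM <- spec$ligand_nM * 1e-9

    ## side events: Poisson arrivals over all sites + equilibrium initial
    ## occupancy
    fb_side <- cM / (spec$k_off_side / spec$k_on_side + cM)
    n0 <- rbinom(1, n_sites, fb_side)
    ev <- list()
    if (n0 > 0) {
      s0 <- sample.int(n_sites, n0)
      ev[[1]] <- data.frame(class = "filament_side",
                            x = site_xy[s0, 1], y = site_xy[s0, 2],
                            t_on = 0, t_off = rexp(n0, spec$k_off_side))
    }
    lam <- n_sites * spec$k_on_side * cM
    n_arr <- rpois(1, lam * span)
    if (n_arr > 0) {
      sa <- sample.int(n_sites, n_arr, replace = TRUE)
      ton <- runif(n_arr, 0, span)
      ev[[length(ev) + 1]] <- data.frame(class = "filament_side",
                                         x = site_xy[sa, 1],
                                         y = site_xy[sa, 2], t_on = ton,
                                         t_off = ton +
                                           rexp(n_arr, spec$k_off_side))
    }
    ## junction events: exact per-site telegraph from equilibrium
    fb_j <- cM / (spec$k_off_junction / spec$k_on_junction + cM)
    kon_j <- spec$k_on_junction * cM
    for (j in seq_len(n_j)) {
      t <- 0
      bound <- runif(1) < fb_j
      while (t < span) {
        if (bound) {
          dwell <- rexp(1, spec$k_off_junction)
          ev[[length(ev) + 1]] <- data.frame(class = "branch_junction",
                                             x = junctions$x[j],
                                             y = junctions$y[j],
                                             t_on = t, t_off = t + dwell)
          t <- t + dwell
          bound <- FALSE
        } else {
          t <- t + rexp(1, kon_j)
          bound <- TRUE
        }
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(class = character(0), x = numeric(0), y = numeric(0),
                 t_on = numeric(0), t_off = numeric(0))
    events <- events[events$t_on < span & events$t_off > 0, , drop = FALSE]
    events$t_off <- pmin(events$t_off, span + spec$frame_interval)
    events$amp <- spec$amp_mean *
      rlnorm(nrow(events), -0.5 * log(1 + spec$amp_cv^2),
             sqrt(log(1 + spec$amp_cv^2)))
    rownames(events) <- NULL
    frame_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_frames)

    filament_image <- spec$bg_offset + 50 * mask

    frame_fun <- local({
      nx <- spec$field_px[1]; ny <- spec$field_px[2]
      psf <- spec$psf_sigma; half <- ceiling(4 * psf)
      function(i) {
        stopifnot(i >= 1, i <= spec$n_frames)
        tmid <- (i - 0.5) * spec$frame_interval
        act <- which(events$t_on <= tmid & events$t_off > tmid)
        signal <- matrix(0, nx, ny)
        for (e in act) {
          cx <- events$x[e]; cy <- events$y[e]
          x0 <- max(1L, floor(cx - half)); x1 <- min(nx, ceiling(cx + half))
          y0 <- max(1L, floor(cy - half)); y1 <- min(ny, ceiling(cy + half))
          gx <- exp(-((x0:x1) - cx)^2 / (2 * psf^2))
          gy <- exp(-((y0:y1) - cy)^2 / (2 * psf^2))
          signal[x0:x1, y0:y1] <- signal[x0:x1, y0:y1] +
            events$amp[e] * outer(gx, gy)
        }
        with_seed(frame_seeds[i], {
          lambda <- signal + spec$bg_offset
          matrix(rpois(nx * ny, lambda) +
                   rnorm(nx * ny, 0, spec$read_noise_sd), nx, ny)
        })
      }
    })

    structure(list(frame = frame_fun, n_frames = spec$n_frames,
                   field_px = spec$field_px,
                   frame_interval = spec$frame_interval,
                   filament_image = filament_image,
                   filament_mask = mask, junctions = junctions,
                   n_side_sites = n_sites, census = census,
                   events = events, spec = spec),
              class = "arp_movie")
  })
}

#' @export
print.arp_movie <- function(x, ...) {
  cat(sprintf(paste0("Synthetic TIRF movie: %d frames of %dx%d px ",
                     "(%.3g s/frame)\n"),
              x$n_frames, x$field_px[1], x$field_px[2], x$frame_interval))
  cat(sprintf("  %d junctions, %d side sites, %d ground-truth events\n",
              nrow(x$junctions), x$n_side_sites, nrow(x$events)))
  invisible(x)
}

#' Write a synthetic movie to a multi-page TIFF
#'
#' @param movie an \code{arp_movie}.
#' @param path output TIFF path.
#' @param frames frame indices to write (default all).
#' @export
write_tirf_movie <- function(movie, path, frames = seq_len(movie$n_frames)) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks")
  stack <- lapply(frames, function(i) {
    f <- movie$frame(i)
    f / max(f)
  })
  tiff::writeTIFF(stack, path)
  invisible(path)
}

#' Run the full single-molecule pipeline on a movie
#'
#' Chains frame preprocessing, spot detection, nearest-neighbor linking,
#' the four-rule filter, binding-class assignment, per-class dwell-time
#' off rates, the binding-site census, and fraction-bound dissociation
#' constants.
#'
#' @param movie an \code{\link{gen_tirf_movie}} result (or any object with
#'   the same fields).
#' @param preprocess apply \code{\link{preprocess_frame}} to each frame
#'   first.
#' @param max_displacement linking radius (px).
#' @param class_radius junction-association radius (px).
#' @param bin_width dwell-time histogram bin (s).
#' @param min_events minimum per-class events for an off-rate fit.
#' @param detect_args list of extra arguments to
#'   \code{\link{detect_molecules}}.
#' @return Object of class \code{arp_smfit}: list with the detection table,
#'   filtered classified track stats, per-class off-rate fits
#'   (\code{off_rates}), per-frame bound counts, the census, and per-class
#'   \code{kd_uM} plus derived on rates.
#' @export
sm_pipeline <- function(movie, preprocess = TRUE, max_displacement = 3,
                        class_radius = 3, bin_width = 5, min_events = 20,
                        detect_args = list()) {
  dets <- vector("list", movie$n_frames)
  for (i in seq_len(movie$n_frames)) {
    f <- movie$frame(i)
    if (preprocess) f <- preprocess_frame(f)
    d <- do.call(detect_molecules, c(list(f), detect_args))
    if (nrow(d)) d$frame <- i
    dets[[i]] <- d
  }
  dets <- do.call(rbind, dets[vapply(dets, nrow, 0L) > 0])
  if (is.null(dets) || nrow(dets) == 0L)
    stop("no molecules detected in the movie")
  tracks <- link_tracks(dets, max_displacement = max_displacement)
  stats <- track_stats(tracks, frame_interval = movie$frame_interval)
  filt <- filter_tracks(stats, first_frame = 1,
                        last_frame = movie$n_frames,
                        filament_mask = movie$filament_mask)
  filt <- classify_tracks(filt, movie$junctions, radius = class_radius)

  off <- lapply(split(filt$lifetime_s, filt$binding_class), function(lt) {
    if (length(lt) < min_events) return(NULL)
    off_rate_from_lifetimes(lt, bin_width = bin_width)
  })
  off <- off[!vapply(off, is.null, TRUE)]

  ## occupancy from per-frame classified detections
  jx <- movie$junctions$x; jy <- movie$junctions$y
  near_j <- rep(FALSE, nrow(dets))
  for (j in seq_along(jx))
    near_j <- near_j | ((dets$x - jx[j])^2 + (dets$y - jy[j])^2 <=
                          class_radius^2)
  cnt_j <- tabulate(dets$frame[near_j], nbins = movie$n_frames)
  cnt_s <- tabulate(dets$frame[!near_j], nbins = movie$n_frames)
  census <- count_side_sites(movie$filament_mask, nrow(movie$junctions),
                             pixel_size_nm = movie$spec$pixel_size_nm,
                             stoichiometry = movie$spec$stoichiometry)
  conc_uM <- movie$spec$ligand_nM / 1000
  fb_j <- mean(cnt_j) / nrow(movie$junctions)
  fb_s <- mean(cnt_s) / census$side_sites
  kd <- c(branch_junction = if (fb_j > 0 && fb_j < 1)
    kd_from_fraction_bound(fb_j, conc_uM) else NA_real_,
    filament_side = if (fb_s > 0 && fb_s < 1)
      kd_from_fraction_bound(fb_s, conc_uM) else NA_real_)
  kon <- lapply(names(off), function(cl) {
    if (!cl %in% names(kd) || !is.finite(kd[[cl]])) return(NULL)
    k_on_from_kd(off[[cl]]$k_off, kd[[cl]])
  })
  names(kon) <- names(off)

  structure(list(detections = dets, tracks = tracks, track_stats = filt,
                 rejections = attr(filt, "rejections"),
                 off_rates = off, kd_uM = kd, k_on = kon,
                 fraction_bound = c(branch_junction = fb_j,
                                    filament_side = fb_s),
                 bound_per_frame = list(junction = cnt_j, side = cnt_s),
                 census = census),
            class = "arp_smfit")
}

#' @export
print.arp_smfit <- function(x, ...) {
  cat("Single-molecule pipeline result\n")
  cat(sprintf("  %d detections, %d tracks kept (rejected: %s)\n",
              nrow(x$detections), nrow(x$track_stats),
              paste(names(x$rejections), x$rejections, collapse = ", ")))
  for (cl in names(x$off_rates))
    cat(sprintf("  %s: k_off = %.3g /s (tau %.3g s, n = %d)\n", cl,
                x$off_rates[[cl]]$k_off, x$off_rates[[cl]]$tau,
                x$off_rates[[cl]]$n))
  for (cl in names(x$kd_uM))
    if (is.finite(x$kd_uM[[cl]]))
      cat(sprintf("  %s: K_D = %.3g uM (fraction bound %.3g)\n", cl,
                  x$kd_uM[[cl]], x$fraction_bound[[cl]]))
  invisible(x)
}
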