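## Polymerization-trace container and summary statistics for pyrene-actin
## style time courses.

#' Polymerization trace
#'
#' A two-column time series of a bulk polymerization reaction, either raw
#' fluorescence (arbitrary units) or polymerized-actin concentration (uM),
#' with the reaction conditions carried as metadata.
#'
#' @param time time points (s), strictly increasing.
#' @param value signal values.
#' @param total_actin total actin in the reaction (uM).
#' @param conditions optional \code{\link{arp_conditions}} (or any list)
#'   describing the reaction.
#' @param mode \code{"concentration"} or \code{"fluorescence"}.
#' @return data.frame of class \code{arp_trace} with columns \code{time}
#'   and \code{value}.
#' @export
arp_trace <- function(time, value, total_actin = NA_real_,
                      conditions = NULL,
                      mode = c("concentration", "fluorescence")) {
  mode <- match.arg(mode)
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(value))) stop("signal must be finite")
  structure(data.frame(time = as.numeric(time), value = as.numeric(value)),
            total_actin = total_actin, conditions = conditions,
            mode = mode, class = c("arp_trace", "data.frame"))
}

#' @export
print.arp_trace <- function(x, ...) {
  cat(sprintf("Polymerization trace (%s mode): %d points, %g-%g s",
              attr(x, "mode"), nrow(x), min(x$time), max(x$time)))
  if (is.finite(attr(x, "total_actin")))
    cat(sprintf(", total actin %g uM", attr(x, "total_actin")))
  cat("\n")
  invisible(x)
}

.trace_mode <- function(trace) attr(trace, "mode")

## plateau of a trace: mean of the trailing fraction, checked for flatness
.plateau <- function(x, frac = 0.05, tol = 0.01, baseline = NULL) {
  n <- length(x)
  k <- max(3L, round(frac * n))
  tailx <- x[(n - k + 1L):n]
  m <- mean(tailx)
  amp <- m - (if (is.null(baseline)) min(x) else baseline)
  if (amp <= 0 || max(abs(tailx - m)) > tol * abs(amp))
    return(NA_real_)
  m
}

#' Convert a fluorescence trace to polymerized-actin concentration
#'
#' Affine rescaling under the standard pyrene calibration: the initial
#' baseline maps to zero polymer and the equilibrium plateau maps to
#' \code{total_actin - unpolymerized_eq}, i.e. all but a fixed small amount
#' of actin (default 0.1 uM, the critical concentration scale of barbed-end
#' elongation) is polymerized at equilibrium.  Idempotent on traces already
#' in concentration mode.
#'
#' @param trace an \code{\link{arp_trace}} in fluorescence mode with a
#'   discernible plateau.
#' @param unpolymerized_eq actin assumed unpolymerized at equilibrium (uM).
#' @param plateau_frac,plateau_tol plateau detection: the trailing
#'   \code{plateau_frac} of samples must lie within \code{plateau_tol}
#'   (relative to the plateau amplitude) of their mean.
#' @param n_baseline number of leading samples averaged for the baseline.
#' @return The trace in concentration mode.
#' @export
fluorescence_to_concentration <- function(trace, unpolymerized_eq = 0.1,
                                          plateau_frac = 0.05,
                                          plateau_tol = 0.01,
                                          n_baseline = 1L) {
  stopifnot(inherits(trace, "arp_trace"))
  if (.trace_mode(trace) == "concentration") return(trace)
  ta <- attr(trace, "total_actin")
  if (!is.finite(ta) || ta <= unpolymerized_eq)
    stop("total_actin must exceed the unpolymerized equilibrium amount")
  base <- mean(trace$value[seq_len(min(n_baseline, nrow(trace)))])
  pl <- .plateau(trace$value, plateau_frac, plateau_tol, baseline = base)
  if (!is.finite(pl))
    stop("no fluorescence plateau detected; trace may not have reached ",
         "equilibrium")
  conc <- (trace$value - base) / (pl - base) * (ta - unpolymerized_eq)
  arp_trace(trace$time, conc, total_actin = ta,
            conditions = attr(trace, "conditions"), mode = "concentration")
}

#' Maximum polymerization rate of a trace
#'
#' The maximum of the smoothed first derivative, computed as the slope of a
#' centered local quadratic (Savitzky-Golay) fit over a sliding window --
#' the standard robust estimator for pyrene curves.
#'
#' @param trace an \code{\link{arp_trace}} in concentration mode.
#' @param window window width in points (odd; default 11).
#' @return Maximum rate (uM/s).
#' @export
max_polymerization_rate <- function(trace, window = 11L) {
  stopifnot(inherits(trace, "arp_trace"))
  if (.trace_mode(trace) != "concentration")
    stop("trace must be in concentration mode; see ",
         "fluorescence_to_concentration()")
  n <- nrow(trace)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > n) stop("window (", window, ") larger than trace (", n, ")")
  tt <- trace$time; y <- trace$value
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-8 * mean(dt)) {
    ## resample onto a uniform grid of the same length
    ug <- seq(tt[1], tt[n], length.out = n)
    y <- approx(tt, y, xout = ug)$y
    dt <- diff(ug)
  }
  deriv <- signal::sgolayfilt(y, p = 2, n = window, m = 1, ts = dt[1])
  max(deriv)
}

#' Half time to polymerization equilibrium
#'
#' Earliest time at which the trace crosses half of its equilibrium plateau
#' value, linearly interpolated between samples.
#'
#' @param trace an \code{\link{arp_trace}} in concentration mode that
#'   reaches a plateau.
#' @param plateau_frac,plateau_tol plateau criterion, as in
#'   \code{\link{fluorescence_to_concentration}}.
#' @return t_1/2 (s).
#' @export
half_time_to_equilibrium <- function(trace, plateau_frac = 0.05,
                                     plateau_tol = 0.01) {
  stopifnot(inherits(trace, "arp_trace"))
  if (.trace_mode(trace) != "concentration")
    stop("trace must be in concentration mode")
  y <- trace$value
  pl <- .plateau(y, plateau_frac, plateau_tol, baseline = 0)
  if (!is.finite(pl))
    stop("plateau not reached within the trace")
  half <- pl / 2
  if (y[1] >= half) return(0)
  i <- which(y >= half)[1]
  if (is.na(i)) stop("trace never crosses half of its plateau")
  approx(y[(i - 1L):i], trace$time[(i - 1L):i], xout = half, ties = "ordered")$y
}

#' Fold activation relative to a reference reaction
#'
#' The ratio of the maximum polymerization rate of a reaction to that of
#' the matched reference reaction (conventionally the one without the
#' synergizing NPF).
#'
#' @param rate,reference_rate maximum polymerization rates (uM/s).
#' @export
fold_activation <- function(rate, reference_rate) {
  if (any(!is.finite(reference_rate)) || any(reference_rate <= 0))
    stop("reference_rate must be positive")
  rate / reference_rate
}

#' Fit a saturating hyperbola to fold-activation data
#'
#' Fits \code{fold(c) = background + amplitude * c / (half_max + c)} by
#' least squares, with the background fixed to the measured activity at
#' zero concentration.  The amplitude enters linearly, so the fit profiles
#' it out analytically and optimizes only \code{half_max}, which makes the
#' noiseless inverse problem exact to solver precision.
#'
#' @param concs concentrations (uM), including at least one zero.
#' @param folds fold-activation values.
#' @return Object of class \code{arp_hyperbola}: list with
#'   \code{half_max_conc} (uM), \code{amplitude}, \code{max_fold}
#'   (background + amplitude), \code{background}, \code{fitted},
#'   \code{residuals} and \code{identifiable}.
#' @export
fit_synergy_hyperbola <- function(concs, folds) {
  if (length(concs) != length(folds)) stop("length mismatch")
  if (length(concs) < 4L) stop("need at least 4 points")
  if (!any(concs == 0)) stop("a zero-concentration point is required")
  background <- mean(folds[concs == 0])
  y <- folds - background
  amp_for <- function(h) {
    g <- concs / (h + concs)
    s2 <- sum(g * g)
    if (s2 == 0) 0 else sum(g * y) / s2
  }
  ssr_for <- function(lh) {
    h <- exp(lh)
    a <- amp_for(h)
    sum((y - a * concs / (h + concs))^2)
  }
  if (max(abs(y)) < 1e-12 * max(1, abs(background))) {
    fit <- list(half_max_conc = NA_real_, amplitude = 0,
                max_fold = background, background = background,
                fitted = rep(background, length(concs)),
                residuals = folds - background, identifiable = FALSE)
    return(structure(fit, class = "arp_hyperbola"))
  }
  cpos <- concs[concs > 0]
  opt <- optimize(ssr_for, c(log(min(cpos)) - log(1e4),
                             log(max(cpos)) + log(1e4)), tol = 1e-13)
  h <- exp(opt$minimum)
  a <- amp_for(h)
  fitted <- background + a * concs / (h + concs)
  structure(list(half_max_conc = h, amplitude = a,
                 max_fold = background + a, background = background,
                 fitted = fitted, residuals = folds - fitted,
                 identifiable = TRUE),
            class = "arp_hyperbola")
}

#' @export
print.arp_hyperbola <- function(x, ...) {
  cat("Saturating-hyperbola synergy fit\n")
  if (x$identifiable) {
    cat(sprintf("  half-maximal concentration: %.4g uM (%.3g nM)\n",
                x$half_max_conc, 1e3 * x$half_max_conc))
    cat(sprintf("  fold activation at saturation: %.3f (background %.3f)\n",
                x$max_fold, x$background))
  } else {
    cat("  flat response: amplitude 0, half-max not identifiable\n")
  }
  invisible(x)
}

#' Read / write polymerization traces as CSV with a metadata header
#'
#' The file format is a block of \code{# key: value} comment lines followed
#' by a two-column \code{time,value} table.
#'
#' @param trace an \code{\link{arp_trace}}.
#' @param path file path.
#' @rdname trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "arp_trace"))
  cond <- attr(trace, "conditions")
  hdr <- c(paste("# mode:", attr(trace, "mode")),
           paste("# total_actin:", attr(trace, "total_actin")))
  if (inherits(cond, "arp_conditions"))
    hdr <- c(hdr, paste0("# ", c("actin", "arp23", "gst_vca", "cortactin",
                                 "side_sites"), ": ",
                         unlist(cond[c("actin", "arp23", "gst_vca",
                                       "cortactin", "side_sites")])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "time,value"), con)
  utils::write.table(data.frame(trace$time, trace$value), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  cond <- NULL
  if (!is.null(meta$actin))
    cond <- arp_conditions(actin = as.numeric(meta$actin),
                           arp23 = as.numeric(meta$arp23),
                           gst_vca = as.numeric(meta$gst_vca),
                           cortactin = as.numeric(meta$cortactin),
                           side_sites = as.numeric(meta$side_sites))
  arp_trace(tab[[1]], tab[[2]],
            total_actin = as.numeric(meta$total_actin %||% NA),
            conditions = cond,
            mode = meta$mode %||% "concentration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a batch of traces from a manifest CSV
#'
#' The manifest has one row per trace file with columns \code{file} (path,
#' relative to the manifest location unless absolute), \code{actin},
#' \code{arp23}, \code{gst_vca} and \code{cortactin} (uM).  Each trace file
#' is a plain two-column time,value CSV (a metadata header block, if
#' present, is overridden by the manifest conditions).
#'
#' @param path manifest CSV file.
#' @return list of \code{\link{arp_trace}} objects carrying their
#'   conditions.
#' @export
read_trace_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "actin", "arp23", "gst_vca", "cortactin")
  if (!all(need %in% names(man)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(dirname(path), man$file[i])
    if (!file.exists(f)) stop("trace file not found: ", man$file[i])
    tr <- read_trace_csv(f)
    cond <- arp_conditions(actin = man$actin[i], arp23 = man$arp23[i],
                           gst_vca = man$gst_vca[i],
                           cortactin = man$cortactin[i])
    arp_trace(tr$time, tr$value, total_actin = man$actin[i],
              conditions = cond, mode = attr(tr, "mode"))
  })
}
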