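## Global fitting of the reaction network to trace ensembles, the
## quality-of-fit statistic, and mechanism-comparison scans.

#' Mean-weighted residual sum of squares between trace sets
#'
#' For each matched pair of traces the simulated values are interpolated
#' onto the observed time grid and the residual sum of squares is divided
#' by the squared mean of the observed trace; the per-trace statistics are
#' then averaged:
#' \deqn{qof = \frac{1}{N}\sum_{t=1}^{N} \frac{\sum_i (s_{ti}-o_{ti})^2}
#'   {\bar{o}_t^2}.}
#' The mean weighting makes the statistic invariant to a common rescaling
#' of all traces, so fluorescence-unit and concentration-unit fits are
#' comparable.
#'
#' @param simulated,observed lists of \code{\link{arp_trace}} objects (or a
#'   single trace each), matched by position.
#' @return Dimensionless quality of fit (0 for a perfect fit).
#' @export
quality_of_fit <- function(simulated, observed) {
  if (inherits(simulated, "arp_trace")) simulated <- list(simulated)
  if (inherits(observed, "arp_trace")) observed <- list(observed)
  if (length(simulated) != length(observed) || length(observed) == 0L)
    stop("simulated and observed must be matched, non-empty trace sets")
  per <- mapply(function(s, o) {
    si <- approx(s$time, s$value, xout = o$time, rule = 2)$y
    m <- mean(o$value)
    if (m == 0) stop("observed trace has zero mean; cannot mean-weight")
    sum((si - o$value)^2) / m^2
  }, simulated, observed)
  mean(per)
}

#' Globally fit a reaction-network variant to a trace ensemble
#'
#' Fits one shared parameter vector across all traces simultaneously, in
#' the manner of kinetic-simulation parameter estimation: each trace is
#' simulated at its own reaction conditions, residuals are weighted by the
#' trace mean, and the Levenberg-Marquardt algorithm minimizes the combined
#' sum of squares.  Parameters are optimized on a log scale, which
#' enforces positivity.  Fitting is deterministic: the same data and
#' starting values give identical results.
#'
#' @param data list of \code{\link{arp_trace}} objects in concentration
#'   mode, each carrying its \code{\link{arp_conditions}} as the
#'   \code{conditions} attribute.
#' @param variant network variant to fit (see \code{\link{build_network}}).
#' @param float character vector of parameters to optimize; defaults to the
#'   variant's conventional floating set.  Must be a subset of it unless
#'   \code{allow_any_float = TRUE}.
#' @param overrides fixed rate-constant substitutions applied before
#'   fitting (units of \code{\link{arp_rate_table}}).
#' @param start optional named starting values for the floated parameters
#'   (same units); defaults to the table values.
#' @param lower,upper optional named bounds (same units).
#' @param allow_any_float allow floating parameters outside the variant's
#'   conventional set.
#' @param tie_kd_fil when \code{k_fil_on} is floated, constrain the
#'   filament-side off rate by the measured equilibrium constant:
#'   \code{k_fil_off = k_fil_on * tie_kd_fil} (uM).  Set \code{NULL} to
#'   float the on rate with the off rate fixed instead.
#' @param control a \code{\link[minpack.lm]{nls.lm.control}} list.
#' @return An object of class \code{arp_fit} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{residuals},
#'   \code{plot}, \code{deviance} and \code{simulate}.
#' @export
#' @examples
#' \donttest{
#' synth <- gen_pyrene_ensemble(variant = "branching",
#'   conditions = lapply(c(0.05, 0.25, 1), function(v)
#'     arp_conditions(actin = 3, arp23 = 0.05, gst_vca = v,
#'                    t_end = 1500, n_out = 150)),
#'   noise_sd = 0.01, seed = 1)
#' fit <- arp_fit(synth$traces, "branching", float = "k25")
#' coef(fit)
#' }
arp_fit <- function(data, variant, float = NULL, overrides = list(),
                    start = NULL, lower = NULL, upper = NULL,
                    allow_any_float = FALSE, tie_kd_fil = 0.9,
                    control = minpack.lm::nls.lm.control(maxiter = 100)) {
  if (inherits(data, "arp_trace")) data <- list(data)
  stopifnot(length(data) > 0L)
  for (tr in data) {
    if (!inherits(tr, "arp_trace")) stop("data must be arp_trace objects")
    if (!inherits(attr(tr, "conditions"), "arp_conditions"))
      stop("every trace must carry arp_conditions in its 'conditions' ",
           "attribute")
    if (.trace_mode(tr) != "concentration")
      stop("traces must be in concentration mode")
  }
  net0 <- build_network(variant, overrides)
  if (is.null(float)) float <- net0$floating
  float <- vapply(float, .resolve_param, "")
  bad <- setdiff(float, c(net0$floating,
                          if (allow_any_float) names(net0$params),
                          if (allow_any_float) "k_fil_on"))
  if (length(bad))
    stop("parameter(s) ", paste(bad, collapse = ", "),
         " are not in the conventional floating set for variant '",
         variant, "'; set allow_any_float = TRUE to override")

  p0 <- vapply(float, function(nm) {
    if (!is.null(start) && nm %in% names(start)) return(as.numeric(start[[nm]]))
    if (nm == "k_fil_on") return(net0$params[["k13"]])
    if (nm == "k_fil_off") return(net0$params[["km13"]])
    net0$params[[nm]]
  }, 0)
  names(p0) <- float
  wts <- 1 / (vapply(data, function(tr) mean(tr$value), 0) *
                sqrt(length(data)))

  simulate_set <- function(pvec) {
    pl <- as.list(setNames(pvec, float))
    if (!is.null(tie_kd_fil) && "k_fil_on" %in% float)
      pl$k_fil_off <- pl$k_fil_on * tie_kd_fil * 1e-6
    net <- set_network_params(net0, pl)
    lapply(data, function(tr) {
      cond <- attr(tr, "conditions")
      sim <- simulate_network(net, cond, times = tr$time)
      sim$F[match(tr$time, sim$time)]
    })
  }
  resid_fn <- function(logp) {
    sims <- simulate_set(10^logp)
    unlist(mapply(function(sv, tr, w) (sv - tr$value) * w,
                  sims, data, wts, SIMPLIFY = FALSE))
  }
  lw <- if (is.null(lower)) rep(-Inf, length(p0)) else
    log10(vapply(float, function(nm) lower[[nm]] %||% 0, 0))
  up <- if (is.null(upper)) rep(Inf, length(p0)) else
    log10(vapply(float, function(nm) upper[[nm]] %||% Inf, 0))

  lm <- minpack.lm::nls.lm(par = log10(p0), fn = resid_fn,
                           lower = lw, upper = up, control = control)
  est <- setNames(10^lm$par, float)
  est_list <- as.list(est)
  if (!is.null(tie_kd_fil) && "k_fil_on" %in% float)
    est_list$k_fil_off <- est_list$k_fil_on * tie_kd_fil * 1e-6
  net_fit <- set_network_params(net0, est_list)
  sims <- simulate_set(est)
  res <- mapply(function(sv, tr) sv - tr$value, sims, data,
                SIMPLIFY = FALSE)
  qof <- mean(mapply(function(r, tr) sum(r^2) / mean(tr$value)^2,
                     res, data))
  at_bound <- (is.finite(lw) & abs(lm$par - lw) < 1e-8) |
    (is.finite(up) & abs(lm$par - up) < 1e-8)
  structure(list(coefficients = est, quality_of_fit = qof,
                 per_trace_residuals = res, fitted = sims,
                 converged = lm$info %in% 1:4, info = lm$info,
                 message = lm$message, n_iterations = lm$niter,
                 at_bound = setNames(at_bound, float),
                 variant = variant, float = float,
                 network = net_fit, data = data,
                 call = match.call()),
            class = "arp_fit")
}

#' @export
print.arp_fit <- function(x, digits = 4, ...) {
  cat("Global kinetic fit (", x$variant, " network, Levenberg-Marquardt)\n",
      sep = "")
  cat("  traces: ", length(x$data), "; floated: ",
      paste(x$float, collapse = ", "), "\n", sep = "")
  print(signif(x$coefficients, digits))
  cat(sprintf("  quality of fit (mean-weighted RSS): %.4g\n",
              x$quality_of_fit))
  if (!x$converged)
    cat("  WARNING: optimizer did not converge (info ", x$info, ")\n")
  if (any(x$at_bound))
    cat("  note: parameter(s) at bound:",
        paste(x$float[x$at_bound], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.arp_fit <- function(object, ...) {
  rt <- arp_rate_table()
  ids <- vapply(object$float, function(nm)
    .param_reaction_id(.resolve_param(nm))[1], 0L)
  desc <- rt$description[match(ids, rt$id)]
  out <- data.frame(parameter = object$float, estimate = object$coefficients,
                    reaction = desc, at_bound = object$at_bound,
                    row.names = NULL)
  structure(list(table = out, qof = object$quality_of_fit,
                 converged = object$converged,
                 n_iterations = object$n_iterations,
                 n_traces = length(object$data), variant = object$variant),
            class = "summary.arp_fit")
}

#' @export
print.summary.arp_fit <- function(x, ...) {
  cat("Global kinetic fit,", x$variant, "variant:", x$n_traces,
      "traces fit jointly\n")
  print(x$table)
  cat(sprintf("Quality of fit %.4g after %d iterations (%s)\n", x$qof,
              x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.arp_fit <- function(object, ...) object$coefficients

#' @export
deviance.arp_fit <- function(object, ...) object$quality_of_fit

#' @export
residuals.arp_fit <- function(object, ...) object$per_trace_residuals

#' Predict polymerization traces from a fitted network
#'
#' @param object an \code{\link{arp_fit}}.
#' @param conditions list of \code{\link{arp_conditions}}; default: the
#'   conditions of the fitted traces.
#' @param ... unused.
#' @return list of \code{\link{arp_trace}} objects simulated at the fitted
#'   parameter values.
#' @export
predict.arp_fit <- function(object, conditions = NULL, ...) {
  if (is.null(conditions))
    conditions <- lapply(object$data, attr, "conditions")
  if (inherits(conditions, "arp_conditions")) conditions <- list(conditions)
  lapply(conditions, function(cond)
    polymerized_actin(simulate_network(object$network, cond)))
}

#' @export
plot.arp_fit <- function(x, ...) {
  n <- length(x$data)
  cols <- grDevices::hcl.colors(max(n, 2), "viridis")
  xr <- range(unlist(lapply(x$data, function(tr) range(tr$time))))
  yr <- range(unlist(lapply(x$data, function(tr) range(tr$value))))
  plot(NA, xlim = xr, ylim = yr, xlab = "time (s)",
       ylab = "polymerized actin (uM)",
       main = paste("Global fit,", x$variant, "variant"), ...)
  for (i in seq_len(n)) {
    points(x$data[[i]]$time, x$data[[i]]$value, col = cols[i], pch = 16,
           cex = 0.3)
    lines(x$data[[i]]$time, x$fitted[[i]], col = cols[i], lwd = 2)
  }
  invisible(x)
}

#' Simulate noisy replicates from a fitted model
#'
#' @param object an \code{\link{arp_fit}}.
#' @param nsim number of replicate ensembles.
#' @param seed RNG seed.
#' @param noise_sd relative Gaussian noise level.
#' @param ... unused.
#' @return list of \code{nsim} trace ensembles.
#' @export
simulate.arp_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 0.01, ...) {
  conds <- lapply(object$data, attr, "conditions")
  ov <- as.list(coef(object))
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    seed_i <- sample.int(.Machine$integer.max - 1L, 1L)
    gen_pyrene_ensemble(variant = object$variant, conditions = conds,
                        noise_sd = noise_sd, seed = seed_i,
                        overrides = ov)$traces
  }))
}

#' Threshold scan over the filament-binding on rate
#'
#' Fixes the global filament-side association rate k_fil_on (reactions 13,
#' 19, 21 and 22) at each grid value, co-optimizes the remaining floated
#' parameter(s), and reports the quality of fit per grid point and the
#' minimum k_fil_on reaching a quality-of-fit cutoff.  The scan is the
#' standard way of asking how slow filament binding can be while still
#' explaining a trace ensemble.
#'
#' @param data trace ensemble (as for \code{\link{arp_fit}}).
#' @param variant network variant.
#' @param grid k_fil_on values, 1/(M s), increasing.
#' @param float parameters co-optimized at each grid point; defaults to the
#'   variant's floating set minus \code{k_fil_on}.
#' @param qof_cutoff quality-of-fit threshold; if reached, the least grid
#'   value attaining it is reported.
#' @param tie_kd_fil constrain the filament off rate by the measured
#'   equilibrium constant at each grid point, \code{k_fil_off = k_fil_on *
#'   tie_kd_fil} (uM); \code{NULL} keeps the tabulated off rate fixed.
#' @param ... passed to \code{\link{arp_fit}}.
#' @return data.frame of class \code{arp_scan} with one row per grid point
#'   (columns \code{k_fil_on}, \code{qof}, one per co-optimized parameter)
#'   and attribute \code{threshold}.
#' @export
scan_k_fil_on <- function(data, variant, grid, float = NULL,
                          qof_cutoff = NULL, tie_kd_fil = 0.9, ...) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  vdef <- ARP_VARIANTS[[variant]]
  if (is.null(float)) float <- setdiff(vdef$floating, "k_fil_on")
  if (length(float) == 0L)
    stop("no co-optimized parameters left for variant '", variant, "'")
  rows <- lapply(grid, function(kf) {
    ov <- list(k_fil_on = kf)
    if (!is.null(tie_kd_fil)) ov$k_fil_off <- kf * tie_kd_fil * 1e-6
    fit <- arp_fit(data, variant, float = float, overrides = ov,
                   allow_any_float = TRUE, ...)
    c(k_fil_on = kf, qof = fit$quality_of_fit, coef(fit))
  })
  out <- as.data.frame(do.call(rbind, rows))
  thr <- NA_real_
  if (!is.null(qof_cutoff)) {
    ok <- which(out$qof <= qof_cutoff)
    if (length(ok) == 0L)
      warning("quality-of-fit cutoff never reached on the grid")
    else thr <- out$k_fil_on[min(ok)]
  }
  structure(out, threshold = thr, qof_cutoff = qof_cutoff,
            class = c("arp_scan", "data.frame"))
}

#' @export
print.arp_scan <- function(x, ...) {
  cat("k_fil_on threshold scan over", nrow(x), "grid points\n")
  print(as.data.frame(x))
  if (is.finite(attr(x, "threshold")))
    cat(sprintf("minimum k_fil_on with qof <= %.3g: %.3g /(M s)\n",
                attr(x, "qof_cutoff"), attr(x, "threshold")))
  invisible(x)
}

#' Filament-recruitment test: half time versus added side sites
#'
#' Simulates the branching (no cortactin) network with increasing amounts
#' of preformed filament-side binding sites and returns the half time to
#' polymerization equilibrium for each, mimicking pure recruitment of
#' Arp2/3 complex to filament sides.  Comparing the saturated half time
#' against cortactin-driven half times asks whether recruitment alone can
#' account for synergy.
#'
#' @param side_site_grid added side sites (uM).
#' @param conditions base reaction conditions.
#' @param k_fil_on filament-side association rate, 1/(M s).
#' @param overrides further rate substitutions.
#' @return data.frame with \code{side_sites} and \code{t_half} (s).
#' @export
recruitment_test <- function(side_site_grid,
                             conditions = arp_conditions(t_end = 2500,
                                                         n_out = 800),
                             k_fil_on = 1.4e6, overrides = list()) {
  if (any(side_site_grid < 0)) stop("side sites must be >= 0")
  net <- build_network("branching",
                       modifyList(list(k_fil_on = k_fil_on), overrides))
  th <- vapply(side_site_grid, function(s0) {
    sim <- simulate_network(net, add_side_sites(conditions, s0))
    half_time_to_equilibrium(polymerized_actin(sim))
  }, 0)
  data.frame(side_sites = side_site_grid, t_half = th)
}

#' Association rate from an off rate and an equilibrium constant
#'
#' @param k_off dissociation rate (1/s).
#' @param kd_um equilibrium dissociation constant (uM).
#' @return list with \code{k_on_uM} (1/(uM s)) and \code{k_on_M}
#'   (1/(M s)).
#' @export
#' @examples
#' k_on_from_kd(0.034, 0.017)$k_on_M   # 2e6 /(M s)
k_on_from_kd <- function(k_off, kd_um) {
  if (any(k_off <= 0) || any(kd_um <= 0))
    stop("k_off and kd_um must be positive")
  k_on_uM <- k_off / kd_um
  list(k_on_uM = k_on_uM, k_on_M = 1e6 * k_on_uM)
}
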