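## Deterministic integration of a reaction network and derived observables.

#' Reaction conditions for a polymerization simulation
#'
#' Concentrations are micromolar.  \code{gst_vca} is the GST-VCA
#' concentration expressed per monomer, the convention used when tabulating
#' reaction conditions; the network species is the GST-linked dimer and is
#' initialized at \code{gst_vca / 2} (set \code{vca_dimer = FALSE} to treat
#' the printed value as the dimer concentration directly).
#' \code{side_sites} is an extra pool of preformed filament-side binding
#' sites, used to probe recruitment mechanisms: it adds Arp2/3 binding sites
#' without adding barbed ends.
#'
#' @param actin actin monomer concentration (uM).
#' @param arp23 Arp2/3 complex concentration (uM).
#' @param gst_vca GST-VCA concentration, monomeric convention (uM).
#' @param cortactin cortactin concentration (uM).
#' @param side_sites preformed filament-side binding sites (uM).
#' @param t_end simulated time span (s).
#' @param n_out number of output time points (>= 600 recommended).
#' @param rtol,atol relative / absolute solver tolerances (atol in uM).
#' @param vca_dimer logical; interpret \code{gst_vca} as monomeric (halved
#'   into the dimeric species) or as the species concentration itself.
#' @return An object of class \code{arp_conditions}.
#' @export
arp_conditions <- function(actin = 3, arp23 = 0.02, gst_vca = 0.1,
                           cortactin = 0, side_sites = 0,
                           t_end = 2000, n_out = 600,
                           rtol = 1e-8, atol = 1e-12, vca_dimer = TRUE) {
  conc <- c(actin = actin, arp23 = arp23, gst_vca = gst_vca,
            cortactin = cortactin, side_sites = side_sites)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("all concentrations must be finite and non-negative")
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive")
  if (n_out < 2) stop("n_out must be at least 2")
  structure(list(actin = actin, arp23 = arp23, gst_vca = gst_vca,
                 cortactin = cortactin, side_sites = side_sites,
                 t_end = t_end, n_out = n_out, rtol = rtol, atol = atol,
                 vca_dimer = vca_dimer),
            class = "arp_conditions")
}

#' @export
print.arp_conditions <- function(x, ...) {
  cat(sprintf(paste0("Reaction conditions: %.3g uM actin, %.3g nM Arp2/3, ",
                     "%.3g nM GST-VCA (monomeric), %.3g nM cortactin"),
              x$actin, 1e3 * x$arp23, 1e3 * x$gst_vca, 1e3 * x$cortactin))
  if (x$side_sites > 0)
    cat(sprintf(", %.3g uM preformed side sites", x$side_sites))
  cat(sprintf("; t_end %g s\n", x$t_end))
  invisible(x)
}

#' Add preformed filament-side binding sites to reaction conditions
#'
#' Increments the pool of filament-side binding sites without changing
#' barbed ends, emulating recruitment of Arp2/3 complex to pre-existing
#' filament sides.
#'
#' @param conditions an \code{\link{arp_conditions}} object.
#' @param amount side sites to add (uM, >= 0).
#' @export
add_side_sites <- function(conditions, amount) {
  stopifnot(inherits(conditions, "arp_conditions"))
  if (!is.finite(amount) || amount < 0) stop("amount must be >= 0")
  conditions$side_sites <- conditions$side_sites + amount
  conditions
}

#' Integrate a reaction network
#'
#' Solves the mass-action ODE system on a stiff-capable integrator (lsoda,
#' compiled right-hand side) on a fixed output grid and reports the derived
#' polymerized-actin trace and the worst-case drift of total actin, a
#' solver-quality diagnostic.
#'
#' @param network an \code{\link{build_network}} result.
#' @param conditions an \code{\link{arp_conditions}} object.
#' @param times optional explicit output time grid (s), overriding
#'   \code{t_end}/\code{n_out}.
#' @return An object of class \code{arp_sim}: a data.frame with \code{time}
#'   and one column per species (uM), with attributes
#'   \code{mass_balance_drift}, \code{conditions} and \code{network}.
#' @export
#' @examples
#' net <- build_network("branching")
#' sim <- simulate_network(net, arp_conditions(t_end = 500, n_out = 120))
#' sim
simulate_network <- function(network, conditions = arp_conditions(),
                             times = NULL) {
  stopifnot(inherits(network, "arp_network"))
  stopifnot(inherits(conditions, "arp_conditions"))
  y0 <- setNames(numeric(length(ARP_SPECIES)), ARP_SPECIES)
  y0["A"] <- conditions$actin
  y0["R"] <- conditions$arp23
  y0["V"] <- if (conditions$vca_dimer) conditions$gst_vca / 2 else
    conditions$gst_vca
  y0["C"] <- conditions$cortactin
  y0["S"] <- conditions$side_sites
  if (is.null(times))
    times <- seq(0, conditions$t_end, length.out = conditions$n_out)
  if (times[1] > 0) times <- c(0, times)

  parms <- .pack_parms(network)
  out <- deSolve::ode(y = y0, times = times, func = "arpkin_derivs",
                      parms = parms, initfunc = "arpkin_initmod",
                      dllname = "arpkin", method = "lsoda",
                      rtol = conditions$rtol, atol = conditions$atol,
                      maxsteps = 200000)
  att <- attributes(out)
  if (!is.null(att$istate) && att$istate[1] < 0)
    stop("integration failed at t = ", max(out[, "time"]),
         " s (istate ", att$istate[1], ")")
  df <- as.data.frame(unclass(out))
  neg <- min(as.matrix(df[, ARP_SPECIES]))
  neg_tol <- max(1e-9, 100 * conditions$atol)
  if (neg < -neg_tol)
    stop("negative concentration excursion beyond tolerance: ", neg)

  tot <- .total_actin(df)
  tot0 <- tot[1]
  drift <- if (tot0 > 0) max(abs(tot - tot0)) / tot0 else max(abs(tot))
  structure(df, mass_balance_drift = drift, conditions = conditions,
            network = network, class = c("arp_sim", "data.frame"))
}

.total_actin <- function(df) {
  tot <- 0
  for (spn in names(ARP_ACTIN_MULT))
    tot <- tot + ARP_ACTIN_MULT[[spn]] * df[[spn]]
  tot
}

#' @export
print.arp_sim <- function(x, ...) {
  cond <- attr(x, "conditions")
  net <- attr(x, "network")
  cat(sprintf("Simulated %s network: %d time points to %g s\n",
              net$variant, nrow(x), max(x$time)))
  cat(sprintf("  polymerized actin at end: %.4g uM (of %.4g uM total)\n",
              x$F[nrow(x)], cond$actin))
  cat(sprintf("  total-actin mass-balance drift: %.3g (relative)\n",
              attr(x, "mass_balance_drift")))
  invisible(x)
}

#' Extract the polymerized-actin trace of a simulation
#'
#' @param sim an \code{arp_sim}.
#' @return An \code{\link{arp_trace}} in concentration mode.
#' @export
polymerized_actin <- function(sim) {
  stopifnot(inherits(sim, "arp_sim"))
  cond <- attr(sim, "conditions")
  arp_trace(sim$time, sim$F, total_actin = cond$actin,
            conditions = cond, mode = "concentration")
}

#' Fraction of GST-VCA sequestered at branch junctions
#'
#' Computes 100 x (GST-VCA held in nascent- or mature-branch-junction
#' species) / (total GST-VCA).  Nascent-junction species are the
#' filament-side assemblies of Arp2/3 complex, GST-VCA and at least one
#' recruited actin monomer (including their cortactin-bound forms); the
#' mature-junction species is the GST-VCA retained after nucleation in the
#' recycling mechanism.
#'
#' @param sim an \code{arp_sim} from a branching, displacement or recycling
#'   run.
#' @param time evaluation time (s); default the final time point.
#' @return Percentage of total GST-VCA (scalar; vectorized over
#'   \code{time}).
#' @export
sequestered_vca_fraction <- function(sim, time = NULL) {
  stopifnot(inherits(sim, "arp_sim"))
  net <- attr(sim, "network")
  if (!all(ARP_SEQUESTERED_SPECIES %in% names(sim)) ||
      !net$variant %in% c("branching", "displacement", "recycling"))
    stop("simulation lacks branch-junction species; run a branching, ",
         "displacement or recycling variant")
  cond <- attr(sim, "conditions")
  vtot <- if (cond$vca_dimer) cond$gst_vca / 2 else cond$gst_vca
  if (vtot <= 0) return(if (is.null(time)) 0 else rep(0, length(time)))
  seqv <- rowSums(as.matrix(sim[, ARP_SEQUESTERED_SPECIES, drop = FALSE]))
  if (is.null(time)) return(unname(100 * seqv[length(seqv)] / vtot))
  100 * approx(sim$time, seqv, xout = time, rule = 2)$y / vtot
}

#' Write species trajectories as tidy CSV
#'
#' One row per (time, species) pair with the concentration in uM.
#'
#' @param sim an \code{arp_sim}.
#' @param path output file.
#' @export
write_sim_csv <- function(sim, path) {
  stopifnot(inherits(sim, "arp_sim"))
  long <- do.call(rbind, lapply(ARP_SPECIES, function(spn)
    data.frame(time = sim$time, species = spn,
               concentration = sim[[spn]])))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
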