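## Reaction network construction: species bookkeeping, default rate
## constants, mechanism variants, and the packed parameter encoding used by
## the compiled mass-action right-hand side.

## Species of the full network.  Naming: A/D/T free actin monomer/dimer/
## trimer; BE barbed ends (filament number concentration); F polymerized
## subunits; S free filament-side binding sites; V the GST-VCA dimer and
## VA1..VA5 its actin-loaded forms; R Arp2/3 complex, RF its filament-bound
## form; VR/VRA1/VRA2 VCA:Arp2/3 (+0..2 actins) in solution; VRF/VRAF/VRA2F
## the same assemblies on a filament side (VRA2F is the nascent branch
## junction); J a mature branch junction; C cortactin, CF cortactin on a
## filament side, CN cortactin on a nascent junction, CJ cortactin on a
## mature junction; Jv a mature junction retaining its GST-VCA (recycling
## mechanism only).
ARP_SPECIES <- c("A", "D", "T", "BE", "F", "S",
                 "V", "VA1", "VA2", "VA3", "VA4", "VA5",
                 "R", "RF", "VR", "VRA1", "VRA2",
                 "VRF", "VRAF", "VRA2F",
                 "J", "C", "CF", "CN", "CJ", "Jv")

## unpolymerized actin monomers carried by each species (polymerized
## subunits are counted through F)
ARP_ACTIN_MULT <- c(A = 1, D = 2, T = 3, F = 1,
                    VA1 = 1, VA2 = 2, VA3 = 3, VA4 = 4, VA5 = 5,
                    VRA1 = 1, VRA2 = 2, VRAF = 1, VRA2F = 2, CN = 2)

## species holding one GST-VCA dimer
ARP_VCA_SPECIES <- c("V", "VA1", "VA2", "VA3", "VA4", "VA5",
                     "VR", "VRA1", "VRA2", "VRF", "VRAF", "VRA2F",
                     "CN", "Jv")

## GST-VCA counted as sequestered: junction assemblies on the mother
## filament that contain at least one recruited actin monomer (nascent
## branch junctions) plus anything retained at mature junctions.  The
## rapidly exchanging filament-bound VCA:Arp2/3 pool (VRF) is equilibrium
## binding, not sequestration; see the methods vignette.
ARP_SEQUESTERED_SPECIES <- c("VRAF", "VRA2F", "CN", "Jv")

ARP_VARIANTS <- list(
  spontaneous  = list(reactions = 1:4,
                      floating = c("k1", "km1", "k2", "km2", "k3")),
  vca_only     = list(reactions = 1:12,
                      floating = c("k9", "km9", "k10", "km10", "k11", "km11", "k12")),
  branching    = list(reactions = 1:25,
                      floating = "k25"),
  displacement = list(reactions = 1:28,
                      floating = c("k_fil_on", "k25", "k28")),
  recycling    = list(reactions = c(1:25, 29),
                      floating = c("k29", "km29"))
)

ARP_IRREVERSIBLE <- c(3L, 12L, 25L, 28L)
ARP_KFILON_REACTIONS <- c(13L, 19L, 21L, 22L)

#' Default rate-constant table for the branching-nucleation network
#'
#' Reads the packaged rate table (one row per reaction 1-29) giving the
#' association rate constant \code{k_on} (1/(M s) for bimolecular reactions,
#' 1/s for unimolecular ones), the dissociation rate \code{k_off} (1/s,
#' \code{NA} for the irreversible steps 3, 12, 25 and 28), the tabulated
#' equilibrium constant \code{kd_um} (uM) and its literature source.
#' Condition-adjusted constants (reactions 3 and 25) are listed with their
#' range and the package default.
#'
#' @return A data.frame with columns \code{id}, \code{description},
#'   \code{k_on}, \code{k_on_lo}, \code{k_on_hi}, \code{k_off},
#'   \code{kd_um}, \code{bimolecular}, \code{kd_inconsistent},
#'   \code{source}.
#' @export
#' @examples
#' rt <- arp_rate_table()
#' subset(rt, id == 13)      # Arp2/3 binding to filament sides
arp_rate_table <- function() {
  path <- system.file("extdata", "rate_table.yaml", package = "arpkin",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)$reactions
  rows <- lapply(raw, function(r) {
    if (length(r$k_on) == 2L) {
      lo <- r$k_on[[1]]; hi <- r$k_on[[2]]; kon <- r$default
    } else {
      lo <- hi <- NA_real_; kon <- r$k_on
    }
    data.frame(id = as.integer(r$id), description = r$description,
               k_on = as.numeric(kon), k_on_lo = as.numeric(lo),
               k_on_hi = as.numeric(hi),
               k_off = if (is.null(r$k_off)) NA_real_ else as.numeric(r$k_off),
               kd_um = if (is.null(r$kd_um)) NA_real_ else as.numeric(r$kd_um),
               bimolecular = isTRUE(r$bimolecular),
               kd_inconsistent = isTRUE(r$kd_inconsistent),
               source = r$source, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## resolve a user parameter name ("k7", "km7", "k_nuc", "k_dis",
## "k_fil_on", "k_fil_off") to canonical names
.resolve_param <- function(name) {
  switch(name,
         k_nuc = "k25", k_dis = "k28",
         k_fil_on = "k_fil_on", k_fil_off = "k_fil_off",
         name)
}

.param_reaction_id <- function(canonical) {
  if (canonical %in% c("k_fil_on", "k_fil_off")) return(ARP_KFILON_REACTIONS)
  as.integer(sub("^km?", "", canonical))
}

#' Build a branching-nucleation reaction network
#'
#' Constructs the mass-action network for one mechanism variant, with the
#' packaged default rate constants and optional substitutions.  The five
#' variants include the reaction subsets: \code{spontaneous} (actin assembly
#' only, reactions 1-4), \code{vca_only} (plus GST-VCA monomer binding and
#' weak nucleation, 1-12), \code{branching} (plus Arp2/3 activation by
#' GST-VCA on filament sides, 1-25), \code{displacement} (plus cortactin
#' binding to sides and nascent junctions and the cortactin-driven
#' activation step k_dis, 1-28), and \code{recycling} (1-25 with GST-VCA
#' retained at the junction after nucleation, plus reaction 29 by which
#' cortactin returns sequestered GST-VCA to solution).
#'
#' @param variant one of \code{"spontaneous"}, \code{"vca_only"},
#'   \code{"branching"}, \code{"displacement"}, \code{"recycling"}.
#' @param overrides named list of rate-constant substitutions in the units
#'   of \code{\link{arp_rate_table}} (1/(M s) for bimolecular association
#'   constants, 1/s otherwise).  Names are \code{"k<i>"} (forward) and
#'   \code{"km<i>"} (reverse) for reaction \code{i}, or the aliases
#'   \code{"k_nuc"} (k25), \code{"k_dis"} (k28) and \code{"k_fil_on"} /
#'   \code{"k_fil_off"}, which set reactions 13, 19, 21 and 22 as a single
#'   global variable.
#' @return An object of class \code{arp_network}.
#' @export
#' @examples
#' net <- build_network("branching", overrides = list(k_fil_on = 1.4e6))
#' net
build_network <- function(variant = c("spontaneous", "vca_only", "branching",
                                      "displacement", "recycling"),
                          overrides = list()) {
  variant <- match.arg(variant)
  vdef <- ARP_VARIANTS[[variant]]
  rt <- arp_rate_table()
  rt <- rt[rt$id %in% vdef$reactions, , drop = FALSE]

  ## user-unit parameter vector: forward k<i> for every reaction,
  ## reverse km<i> where a dissociation rate exists
  par <- setNames(rt$k_on, paste0("k", rt$id))
  rev <- rt[!is.na(rt$k_off), , drop = FALSE]
  par <- c(par, setNames(rev$k_off, paste0("km", rev$id)))

  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named list")
    for (nm in names(overrides)) {
      canon <- .resolve_param(nm)
      ids <- .param_reaction_id(canon)
      if (!all(ids %in% vdef$reactions))
        stop("override '", nm, "' refers to reaction(s) ",
             paste(setdiff(ids, vdef$reactions), collapse = ", "),
             " not part of variant '", variant, "'")
      val <- as.numeric(overrides[[nm]])
      if (!is.finite(val) || val < 0)
        stop("override '", nm, "' must be a non-negative number")
      keys <- if (canon == "k_fil_on") paste0("k", ids)
              else if (canon == "k_fil_off") paste0("km", ids)
              else canon
      if (!all(keys %in% names(par)))
        stop("unknown parameter '", nm, "'")
      par[keys] <- val
    }
  }

  net <- structure(list(variant = variant,
                        reactions = vdef$reactions,
                        floating = vdef$floating,
                        params = par,
                        bimolecular = setNames(rt$bimolecular,
                                               paste0("k", rt$id))),
                   class = "arp_network")
  net$elementary <- .elementary_reactions(net)
  net
}

## internal-unit (uM, s) forward/reverse constants
.internal_rates <- function(net) {
  par <- net$params
  conv <- rep(1, length(par))
  names(conv) <- names(par)
  bim <- names(net$bimolecular)[net$bimolecular]
  conv[intersect(bim, names(conv))] <- 1e-6
  par * conv
}

## Elementary reaction list.  Each entry: rate constant (uM, s units),
## one or two reactant species, and the stoichiometry change it causes.
## Polymerization (every +1 on F) exposes one new side-binding site (+1 on
## S); reactions in which a complex occupies or vacates a site move S
## explicitly.
.elementary_reactions <- function(net) {
  k <- .internal_rates(net)
  ids <- net$reactions
  E <- list()
  add <- function(kval, re, st) {
    if (kval > 0)
      E[[length(E) + 1L]] <<- list(k = unname(kval), re = re, st = st)
  }
  fwd <- function(i) k[[paste0("k", i)]]
  bwd <- function(i) k[[paste0("km", i)]]

  if (1 %in% ids) {
    add(fwd(1), c("A", "A"), c(A = -2, D = 1))
    add(bwd(1), "D", c(D = -1, A = 2))
  }
  if (2 %in% ids) {
    add(fwd(2), c("D", "A"), c(D = -1, A = -1, T = 1))
    add(bwd(2), "T", c(T = -1, D = 1, A = 1))
  }
  if (3 %in% ids)
    add(fwd(3), "T", c(T = -1, BE = 1, F = 3, S = 3))
  if (4 %in% ids) {
    add(fwd(4), c("BE", "A"), c(A = -1, F = 1, S = 1))
    add(bwd(4), "BE", c(A = 1, F = -1, S = -1))
  }
  ## elongation from GST-VCA-carried actin; the added subunit loses its
  ## identity in the filament, so depolymerization is carried by reaction 4
  if (5 %in% ids)
    add(fwd(5), c("BE", "VA1"), c(VA1 = -1, V = 1, F = 1, S = 1))
  if (6 %in% ids)
    add(fwd(6), c("BE", "VA2"), c(VA2 = -1, VA1 = 1, F = 1, S = 1))
  vchain <- list(c("V", "VA1"), c("VA1", "VA2"), c("VA2", "VA3"),
                 c("VA3", "VA4"), c("VA4", "VA5"))
  for (j in seq_along(vchain)) {
    i <- 6 + j
    if (!(i %in% ids)) next
    from <- vchain[[j]][1]; to <- vchain[[j]][2]
    st <- setNames(c(-1, -1, 1), c(from, "A", to))
    add(fwd(i), c(from, "A"), st)
    add(bwd(i), to, setNames(c(-1, 1, 1), c(to, from, "A")))
  }
  if (12 %in% ids)
    add(fwd(12), "VA5", c(VA5 = -1, V = 1, BE = 1, F = 5, S = 5))
  if (13 %in% ids) {
    add(fwd(13), c("R", "S"), c(R = -1, S = -1, RF = 1))
    add(bwd(13), "RF", c(RF = -1, R = 1, S = 1))
  }
  arpbind <- list(`14` = c("V", "VR"), `15` = c("VA1", "VRA1"),
                  `16` = c("VA2", "VRA2"))
  for (i in c(14, 15, 16)) {
    if (!(i %in% ids)) next
    from <- arpbind[[as.character(i)]][1]; to <- arpbind[[as.character(i)]][2]
    add(fwd(i), c(from, "R"), setNames(c(-1, -1, 1), c(from, "R", to)))
    add(bwd(i), to, setNames(c(-1, 1, 1), c(to, from, "R")))
  }
  if (17 %in% ids) {
    add(fwd(17), c("VR", "A"), c(VR = -1, A = -1, VRA1 = 1))
    add(bwd(17), "VRA1", c(VRA1 = -1, VR = 1, A = 1))
  }
  if (18 %in% ids) {
    add(fwd(18), c("VRA1", "A"), c(VRA1 = -1, A = -1, VRA2 = 1))
    add(bwd(18), "VRA2", c(VRA2 = -1, VRA1 = 1, A = 1))
  }
  if (19 %in% ids) {
    add(fwd(19), c("VRA2", "S"), c(VRA2 = -1, S = -1, VRA2F = 1))
    add(bwd(19), "VRA2F", c(VRA2F = -1, VRA2 = 1, S = 1))
  }
  if (20 %in% ids) {
    add(fwd(20), c("V", "RF"), c(V = -1, RF = -1, VRF = 1))
    add(bwd(20), "VRF", c(VRF = -1, V = 1, RF = 1))
  }
  if (21 %in% ids) {
    add(fwd(21), c("VR", "S"), c(VR = -1, S = -1, VRF = 1))
    add(bwd(21), "VRF", c(VRF = -1, VR = 1, S = 1))
  }
  if (22 %in% ids) {
    add(fwd(22), c("VRA1", "S"), c(VRA1 = -1, S = -1, VRAF = 1))
    add(bwd(22), "VRAF", c(VRAF = -1, VRA1 = 1, S = 1))
  }
  if (23 %in% ids) {
    add(fwd(23), c("VRF", "A"), c(VRF = -1, A = -1, VRAF = 1))
    add(bwd(23), "VRAF", c(VRAF = -1, VRF = 1, A = 1))
  }
  if (24 %in% ids) {
    add(fwd(24), c("VRAF", "A"), c(VRAF = -1, A = -1, VRA2F = 1))
    add(bwd(24), "VRA2F", c(VRA2F = -1, VRAF = 1, A = 1))
  }
  if (25 %in% ids) {
    ## nucleation converts the nascent junction into a mature junction plus
    ## one new barbed end; the two recruited monomers polymerize.  In the
    ## recycling mechanism GST-VCA stays at the junction (Jv); otherwise it
    ## is released during nucleation.
    if (net$variant == "recycling")
      add(fwd(25), "VRA2F", c(VRA2F = -1, Jv = 1, BE = 1, F = 2, S = 2))
    else
      add(fwd(25), "VRA2F", c(VRA2F = -1, J = 1, V = 1, BE = 1, F = 2, S = 2))
  }
  if (26 %in% ids) {
    add(fwd(26), c("C", "S"), c(C = -1, S = -1, CF = 1))
    add(bwd(26), "CF", c(CF = -1, C = 1, S = 1))
  }
  if (27 %in% ids) {
    add(fwd(27), c("C", "VRA2F"), c(C = -1, VRA2F = -1, CN = 1))
    add(bwd(27), "CN", c(CN = -1, C = 1, VRA2F = 1))
  }
  if (28 %in% ids) {
    add(fwd(28), "CN", c(CN = -1, CJ = 1, V = 1, BE = 1, F = 2, S = 2))
    ## cortactin then exchanges at the mature junction with the
    ## nascent-junction binding kinetics (reaction 27)
    add(fwd(27), c("C", "J"), c(C = -1, J = -1, CJ = 1))
    add(bwd(27), "CJ", c(CJ = -1, C = 1, J = 1))
  }
  if (29 %in% ids) {
    ## cortactin binds the GST-VCA-holding junction and releases the VCA;
    ## it subsequently unbinds leaving a bare mature junction
    add(fwd(29), c("C", "Jv"), c(C = -1, Jv = -1, CJ = 1, V = 1))
    add(bwd(29), "CJ", c(CJ = -1, C = 1, J = 1))
  }
  E
}

## pack the elementary reactions into the fixed-length parameter vector
## consumed by the compiled right-hand side
.pack_parms <- function(net, len = 4096L) {
  ix <- setNames(seq_along(ARP_SPECIES), ARP_SPECIES)
  E <- net$elementary
  out <- c(length(ARP_SPECIES), length(E))
  for (e in E) {
    r1 <- ix[[e$re[1]]]
    r2 <- if (length(e$re) > 1L) ix[[e$re[2]]] else 0L
    st <- e$st
    out <- c(out, e$k, r1, r2, length(st),
             rbind(ix[names(st)], unname(st)))
  }
  if (length(out) > len)
    stop("packed network exceeds the compiled parameter buffer")
  c(out, numeric(len - length(out)))
}

#' @export
print.arp_network <- function(x, ...) {
  cat("Branching-nucleation reaction network\n")
  cat("  variant:   ", x$variant, "\n")
  cat("  reactions: ", .format_ids(x$reactions), "\n")
  cat("  elementary mass-action steps:", length(x$elementary), "\n")
  cat("  floating parameters:", paste(x$floating, collapse = ", "), "\n")
  invisible(x)
}

.format_ids <- function(ids) {
  r <- rle(diff(ids) == 1)
  if (all(diff(ids) == 1)) return(paste0(min(ids), "-", max(ids)))
  paste(tapply(ids, cumsum(c(1, diff(ids) != 1)), function(g)
    if (length(g) > 1) paste0(min(g), "-", max(g)) else g), collapse = ", ")
}

#' Update rate constants of an existing network
#'
#' @param network an \code{arp_network}.
#' @param params named numeric vector or list in the same units and naming
#'   convention as the \code{overrides} of \code{\link{build_network}}.
#' @return The network with parameters replaced and elementary reactions
#'   rebuilt.
#' @export
set_network_params <- function(network, params) {
  stopifnot(inherits(network, "arp_network"))
  for (nm in names(params)) {
    canon <- .resolve_param(nm)
    keys <- if (canon == "k_fil_on") paste0("k", ARP_KFILON_REACTIONS)
            else if (canon == "k_fil_off") paste0("km", ARP_KFILON_REACTIONS)
            else canon
    if (!all(keys %in% names(network$params)))
      stop("unknown parameter '", nm, "' for variant '", network$variant, "'")
    network$params[keys] <- as.numeric(params[[nm]])
  }
  network$elementary <- .elementary_reactions(network)
  network
}

#' Consistency of tabulated equilibrium constants with kinetic constants
#'
#' For every reversible reaction with a tabulated K_D, computes the relative
#' deviation of \code{k_off / k_on} from it.
#'
#' @return data.frame with \code{id}, \code{kd_um}, \code{kd_kinetic}
#'   (k_off/k_on, uM), \code{rel_dev} and the \code{kd_inconsistent} flag
#'   carried by the rate table.
#' @export
kd_consistency <- function() {
  rt <- arp_rate_table()
  rt <- rt[!is.na(rt$k_off) & !is.na(rt$kd_um), , drop = FALSE]
  kd_kin <- rt$k_off / rt$k_on * 1e6    # M -> uM
  data.frame(id = rt$id, kd_um = rt$kd_um, kd_kinetic = kd_kin,
             rel_dev = abs(kd_kin - rt$kd_um) / rt$kd_um,
             kd_inconsistent = rt$kd_inconsistent)
}
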