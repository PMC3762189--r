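---
title: "Modeling synergistic Arp2/3 complex activation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling synergistic Arp2/3 complex activation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(arpkin)
```

# The biological problem

Arp2/3 complex nucleates new (daughter) actin filaments from the sides of
existing (mother) filaments, producing the branched networks that drive
lamellipodial protrusion, endocytosis and vesicle motility.  On its own the
complex is essentially inactive: it must bind a filament side and be engaged
by a nucleation promoting factor (NPF).  Type I NPFs such as WASP/N-WASP
carry a VCA region that delivers actin monomers to the complex; type II
NPFs such as cortactin bind filaments and the complex.  Cells deploy both
classes in the same networks, and dimerized N-WASP VCA (modeled here as the
GST-linked dimer, GST-VCA) synergizes strongly with cortactin -- the
combination polymerizes actin several-fold faster than GST-VCA alone.

`arpkin` implements the quantitative machinery needed to dissect that
synergy: a mass-action reaction network with variants corresponding to the
three candidate mechanisms, trace analytics for bulk pyrene-actin assays,
global parameter estimation, and a single-molecule TIRF pipeline with
synthetic-data generators for end-to-end validation.

# The reaction network

The full network has 29 reactions over 26 species.  Its backbone is
standard actin assembly: activation-limited dimer and trimer formation
(reactions 1--2, with very unfavorable equilibria), spontaneous nucleation
from the trimer (3), and reversible barbed-end elongation (4) at
11.6 uM^-1 s^-1 with a 1.4 s^-1 off rate, giving the familiar ~0.12 uM
critical concentration.  Pointed ends are not tracked: monomer
concentrations are low and branching creates no free pointed ends.

On top of that sit GST-VCA monomer loading (7--11), weak VCA-mediated
nucleation (12), Arp2/3 binding to VCA-actin species in solution (14--18),
filament-side binding of the complex and its VCA-loaded forms (13, 19,
21--22, all governed by a single global `k_fil_on`), monomer recruitment on
the filament (23--24), and the final activation step (25, `k_nuc`), which
fires once the filament-bound complex holds two recruited monomers.
Activation converts the nascent branch junction into a mature junction plus
one new barbed end; the two recruited monomers polymerize.

Three mechanism variants differ in what cortactin does:

* **displacement** (reactions 1--28): cortactin binds filament sides (26)
  and nascent branch junctions (27), and a cortactin-bound nascent junction
  activates at `k_dis` (28), ~10-fold faster than `k_nuc` -- cortactin
  accelerates the obligatory release of GST-VCA.
* **recycling** (1--25 plus 29): GST-VCA stays bound to the junction after
  nucleation and is only returned to solution when cortactin binds the
  junction (29).  Cortactin here can only relieve sequestration.
* **branching** (1--25) is the cortactin-free reference, and
  `spontaneous`/`vca_only` are the calibration subsets used to pin down
  the actin-only and VCA-only constants.

## Bookkeeping conventions

Several bookkeeping choices are not dictated by the reaction list and are
worth stating explicitly:

* **GST-VCA is a dimer.**  Reaction conditions quote monomeric
  concentrations, so the species is initialized at half the quoted value
  (`vca_dimer = FALSE` disables this).  The loading chain 7--11 is taken
  literally as five sequential monomer-binding steps; the structural
  meaning of the highest-occupancy species is deliberately left open, and
  with a nucleation rate of 6.1e-8 s^-1 from the terminal species the
  choice is numerically irrelevant.
* **Filament sides are a species.**  Every polymerized subunit exposes one
  side-binding site; `side_sites` in `arp_conditions()` adds preformed
  sites without adding barbed ends, which is what a pure recruitment
  mechanism would do.  Binding (Arp2/3, its VCA forms, cortactin) occupies
  one site; nucleation permanently converts the occupied site into a
  junction.  Whether side binding should occupy a multi-subunit footprint
  is unknown; the one-site convention is used throughout.
* **Elongation from VCA-carried monomers** (5--6) transfers the subunit to
  the filament and frees the carrier.  A subunit loses its identity upon
  polymerization, so depolymerization is applied once, through reaction 4;
  the tabulated 1.4 s^-1 reverse of 5--6 would be a termolecular step at
  this coarse-graining and is not instantiated.
* **Cortactin after activation** stays bound to the mature junction and
  exchanges with the nascent-junction kinetics (reaction 27), matching
  single-molecule observations that cortactin remains at junctions through
  daughter-filament elongation.
* **Ranged constants.**  The spontaneous nucleation rate is tabulated as a
  condition-adjusted range (1110--1220 s^-1); the package default is the
  midpoint, 1165 s^-1.  `k_nuc` is tabulated as 0.004--0.006 s^-1 with a
  globally optimized value of 0.0038 s^-1; the optimized value is the
  default.  Both are plain overrides when a scenario needs them.
* **Three tabulated K_D values are inconsistent with their rates**: for
  reaction 16 the kinetic ratio k_off/k_on is 0.036 uM against a tabulated
  0.028 uM, and for reactions 14/20 it is 0.09 uM against a tabulated
  0.009 uM (the measured dimeric-VCA affinity; the adjusted off rate does
  not reproduce it at the monomeric on rate).  All other rows agree within
  5%.  The kinetic constants are authoritative -- the simulator never
  reads K_D -- and `kd_consistency()` reports the deviations, with the
  three rows flagged in the shipped rate table.

## Numerics

The system is stiff (the dimerization reverse rate is ~5e7 s^-1 against
nucleation at ~4e-3 s^-1), so integration uses `lsoda` with a compiled
mass-action right-hand side, relative tolerance 1e-8 and absolute tolerance
1e-12 uM, on a fixed output grid (600+ points per trace).  Every simulation
reports the worst-case relative drift of total actin; across all variants
and conditions used in the tests it stays below 1e-12, far inside the 1e-6
acceptance bound.  Tiny negative excursions within 100x the absolute
tolerance are tolerated; anything larger aborts the run.

```{r sim}
net <- build_network("displacement")
sim <- simulate_network(net, arp_conditions(cortactin = 1, t_end = 800))
sim
half_time_to_equilibrium(polymerized_actin(sim))
```

# Sequestered GST-VCA

The recycling mechanism turns on how much GST-VCA is trapped at branch
junctions.  `sequestered_vca_fraction()` counts GST-VCA in junction
assemblies on the mother filament that contain at least one recruited
actin monomer -- the nascent branch junction proper -- plus anything
retained at mature junctions.  The filament-bound VCA:Arp2/3 pool without
recruited monomers is deliberately excluded: it exchanges with solution on
the ~1 s timescale of filament release, so it is equilibrium binding, not
sequestration, and including it would make the reported fraction dominated
by a pool that cortactin cannot and need not liberate.  "End of the
reaction" is likewise underdetermined; the function defaults to the final
time of a run taken to its polymerization plateau, which is flat in time
(the junction pool changes slowly after the monomer supply is exhausted).
Under the no-cortactin recycling conditions this yields ~2.6% of total
GST-VCA sequestered -- a few percent, i.e. free GST-VCA never becomes
limiting, which is why the recycling mechanism cannot produce synergy:

```{r seq}
rsim <- simulate_network(build_network("recycling"),
                         arp_conditions(t_end = 2000, n_out = 800))
sequestered_vca_fraction(rsim)
max_polymerization_rate(polymerized_actin(rsim))
```

# Trace analytics

`max_polymerization_rate()` is the maximum of a centered local-quadratic
(Savitzky-Golay) derivative, default window 11 points -- the method behind
the published rate plots is not restated anywhere, so the window is a
package decision, chosen because it is standard for pyrene curves and
stable under 2x grid refinement (<0.5% movement, enforced by tests).
`half_time_to_equilibrium()` interpolates the first crossing of half the
plateau; the plateau is the mean of the trailing 5% of samples and must be
flat to 1% of its amplitude (both configurable), otherwise the trace is
rejected as unequilibrated.  `fluorescence_to_concentration()` applies the
standard pyrene calibration: baseline to zero, plateau to total actin minus
0.1 uM unpolymerized at equilibrium.

Synergy curves are summarized as fold activation (rate over the matched
cortactin-free rate) and fit with a saturating hyperbola whose background
is *fixed* at the zero-cortactin activity, not floated.  The amplitude
enters linearly, so the fit profiles it out and optimizes only the
half-maximal concentration; this makes the noiseless inverse exact to
solver precision and the fit scale-equivariant by construction.

# Global fitting

`arp_fit()` fits one parameter vector jointly across all traces of an
ensemble by Levenberg-Marquardt on log-transformed parameters (positivity
for free).  Residuals are weighted by the observed trace mean, and the
reported quality of fit is the mean-weighted residual sum of squares

$$qof = \frac{1}{N}\sum_t \frac{\sum_i (s_{ti} - o_{ti})^2}{\bar o_t^2},$$

which is invariant to a common rescaling of the data -- the published
definition names the statistic but not the formula, so this per-trace-mean
normalization averaged over traces is a documented package decision,
pinned by a regression test.  Traces of different lengths are not
length-normalized (a longer trace legitimately carries more information).
Each variant carries its conventional floating set (the calibration
constants for the actin-only and VCA-only subsets, `k_nuc` for branching,
`k_fil_on`/`k_nuc`/`k_dis` for displacement, the recycling exchange rates
for 4b); floating anything else requires an explicit override flag.

When `k_fil_on` floats, or is scanned with `scan_k_fil_on()`, the filament
off rate is tied to it through the measured 0.9 uM equilibrium constant
(`tie_kd_fil`).  This matters: with the off rate tied, raising `k_fil_on`
beyond a threshold leaves the fit quality on a plateau (binding
equilibrium unchanged, kinetics no longer rate-limiting) while the
co-optimized `k_nuc` falls -- the published scan behavior -- whereas with a
fixed off rate the scan has a spurious optimum.  On synthetic ensembles
generated at `k_fil_on` = 1.37e6 the no-cortactin ladder itself constrains
the threshold near 1e6 /(M s); the published contrast between a very low
threshold without cortactin and a ~500-fold higher one with cortactin
reflects the information content of the experimental noise and is not a
property the generator reproduces.

```{r fitdemo, eval = FALSE}
conds <- lapply(c(0, 0.05, 0.25, 1), function(v)
  arp_conditions(actin = 3, arp23 = 0.05, gst_vca = v, t_end = 1500))
ens <- gen_pyrene_ensemble("branching", conds, noise_sd = 0.01, seed = 11)
fit <- arp_fit(ens$traces, "branching", float = "k25")
summary(fit)
plot(fit)
```

# The single-molecule pipeline

Frames are background-subtracted with a rolling-ball (grayscale opening
with a disc of radius 10 px) and smoothed with a 0.5 px Gaussian.
Detection is difference-of-Gaussians band-pass (1 and 3 px defaults; the
published analysis does not state its cutoffs) followed by a global
threshold at median + 5 robust SD of the filtered image, and
intensity-weighted centroids of connected components.  Linking is greedy
mutual-nearest-neighbor between consecutive frames with no gap closing: a
one-frame disappearance ends a track, by design.

Tracks then pass the four filters, in order: not present in the first or
last acquisition frame; more than one frame long; average intensity within
one standard deviation of the mean of all track-average intensities (the
population of track means, one of two readings of the published rule, is
used); and filament-associated.  Binding-class assignment, manual in the
original analysis, is automated here from the junction annotations: within
3 px of a pre-existing junction is a junction binder, a junction appearing
at the track's position during its lifetime marks a nascent branch, and
everything else is a side binder.

Off rates come from the published recipe exactly: lifetimes binned at 5 s,
the survival curve (1 - cumulative frequency) evaluated at bin upper
edges, and an unweighted least-squares single-exponential fit with
floating amplitude; the mean lifetime is 1/k.  Evaluating the survival at
bin edges makes the estimator unbiased for exponential data
(E[survival(t)] = exp(-kt) exactly), which the consistency tests confirm
at n = 10^2..10^4.  The affinity side is arithmetic: the binding-site
census converts mask pixels to sites (subtract 5 px per junction, divide
by the 3 px filament width, 106.7 nm/px, 370 subunits/um, one cortactin
site per 6 subunits, rounded down), occupancy gives K_D = c/fb - c under
excess-ligand conditions, and `excess_ligand_check()` verifies the excess
assumption by extrapolating bound counts to the whole chamber.

# Synthetic data: what it does and does not emulate

The generators exist so every stage is testable without external data, and
their defaults are the study conditions: trace ensembles use the tabulated
reaction conditions (e.g. the 0--1 uM cortactin ladder at 3 uM actin,
20 nM Arp2/3, 100 nM GST-VCA) with 1% Gaussian noise relative to trace
amplitude (a realistic plate-reader figure; the level is a package choice,
as no noise model is published).  Movie generation uses the measured
per-class kinetics (side: 1.21e4 /(M s) on, 0.063 /s off; junction:
2e6 /(M s) on, 0.034 /s off) at 1.5 nM ligand.  Geometry is synthetic:
static filaments as gently curving random polylines ~3 px wide (reflecting
at the field edges so filaments keep their nominal length), junctions
dropped along them at 0.2/um, and side sites laid out on the centerlines
at the density implied by the census arithmetic, excluding the junction
footprints (a cortactin cannot side-bind where a junction sits).  The
default field (256 px, 2400 frames at 0.5 s) is sized to give a few
hundred events per class -- the scale of the published event counts -- while
keeping the full pipeline run to ~2 minutes on one core.  Junction sites
are simulated as exact two-state telegraph processes started from
equilibrium; side arrivals are Poisson (occupancy ~3e-4, so saturation is
negligible).  Brightness varies ~10% between molecules so the intensity
filter removes the expected ~32% of tracks without biasing lifetimes.

Not emulated: photobleaching (the original control shows it is negligible
at the imaging intensity), filament growth during acquisition, diffusing
background molecules, and camera fixed-pattern noise.  Passing the
end-to-end recovery tests therefore demonstrates that the analysis chain
is unbiased on data obeying its assumptions, not that those assumptions
hold for any particular microscope.

# Known limitations

* The model-fit quality values attached to the original experimental
  ensembles depend on the raw traces, which were never deposited; fits
  and scans here run on synthetic ensembles, and parameter *recovery* is
  the criterion.
* The recruitment-test half-time curve is monotone-saturating over added
  side sites up to ~1 uM; beyond that the model predicts a mild reversal
  (extra sides also sequester VCA-loaded complexes), so the monotonicity
  property is stated on the 0--1 uM range.
* Binding-class assignment is geometric; overlapping filaments that would
  be resolved by eye can in principle misclassify a side binder as a
  junction binder.  The generator keeps junctions >= 8 px apart, which
  bounds this effect in the validation data.
* The fluorescence-anisotropy competition analysis of the original study
  is out of scope (its fitting equation is given only by citation).
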