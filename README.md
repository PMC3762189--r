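# arpkin

Kinetic modeling and single-molecule analysis of synergistic Arp2/3
complex activation by nucleation promoting factors (NPFs).

Arp2/3 complex nucleates daughter actin filaments from the sides of mother
filaments, but only when activated by NPFs: type I NPFs (WASP/N-WASP,
via their VCA region) deliver actin monomers to the complex, type II NPFs
(cortactin) bind filaments and the complex.  Dimerized N-WASP VCA
(GST-VCA) and cortactin together activate far more strongly than either
alone.  `arpkin` provides the quantitative toolkit for dissecting that
synergy:

* a 29-reaction mass-action network of branching nucleation with five
  mechanism variants — `spontaneous`, `vca_only`, `branching` (filament
  recruitment), `displacement` (cortactin displaces GST-VCA from nascent
  branch junctions at rate k_dis) and `recycling` (GST-VCA stays
  sequestered at junctions until cortactin frees it) — integrated with a
  stiff solver and full conservation-law diagnostics;
* pyrene-trace analytics: fluorescence-to-concentration calibration,
  maximum polymerization rate, half time to equilibrium, fold activation,
  and saturating-hyperbola synergy fits;
* global Levenberg–Marquardt fitting of a variant to a trace ensemble
  (`arp_fit()`, a classed model object with `print`/`summary`/`coef`/
  `predict`/`plot`/`residuals`/`simulate` methods), the mean-weighted
  residual-sum-of-squares quality of fit, and k_fil_on threshold scans;
* a single-molecule TIRF pipeline: rolling-ball preprocessing, band-pass
  spot detection, nearest-neighbor tracking, the standard four-rule track
  filter, dwell-time → off-rate estimation from binned survival curves,
  a filament binding-site census, and fraction-bound K_D estimation;
* seeded synthetic-data generators for all of the above, including a
  two-channel TIRF movie generator with ground truth, so the entire
  analysis chain is testable end to end.

The central quantities, in the field's standard notation: the activation
step converts a nascent branch junction (filament-side–bound
Arp2/3:GST-VCA carrying two recruited actin monomers) into a mature
junction plus a new barbed end at rate k_nuc = 0.0038 s⁻¹; with cortactin
bound at the junction the step runs at k_dis = 0.036 s⁻¹ (~10-fold
faster).  Cortactin targets junctions over filament sides with a ~300-fold
affinity advantage (K_D 17 nM vs 5.2 µM) built mostly from a ~160-fold
faster on rate (k_on = k_off/K_D: 2.0 × 10⁶ vs 1.2 × 10⁴ M⁻¹s⁻¹).

## Worked example

Simulate the obligatory-displacement mechanism at saturating cortactin and
compare against the cortactin-free reaction:

```r
library(arpkin)

net  <- build_network("displacement")
with_cttn <- simulate_network(net, arp_conditions(actin = 3, arp23 = 0.02,
                                                  gst_vca = 0.1,
                                                  cortactin = 1,
                                                  t_end = 800))
no_cttn   <- simulate_network(net, arp_conditions(actin = 3, arp23 = 0.02,
                                                  gst_vca = 0.1,
                                                  cortactin = 0,
                                                  t_end = 2500))
half_time_to_equilibrium(polymerized_actin(with_cttn))
#> [1] 77.89134
half_time_to_equilibrium(polymerized_actin(no_cttn))
#> [1] 456.016
fold_activation(
  max_polymerization_rate(polymerized_actin(with_cttn)),
  max_polymerization_rate(polymerized_actin(no_cttn)))
#> [1] 11.22767
```

Saturating cortactin drops the half time to equilibrium from ~456 s to
~78 s — the measured saturating half time is about 80 s — and raises the
modeled maximum polymerization rate ~11-fold.  That is the synergy the
displacement mechanism is built to explain.  The recycling mechanism
cannot produce it: GST-VCA sequestration at junctions stays in the low
percent range, so free GST-VCA never limits the reaction:

```r
rsim <- simulate_network(build_network("recycling"),
                         arp_conditions(t_end = 2000, n_out = 800))
sequestered_vca_fraction(rsim)
#> [1] 2.582291
```

Fit a synthetic GST-VCA titration globally and recover the nucleation
rate:

```r
conds <- lapply(c(0, 0.05, 0.25, 1), function(v)
  arp_conditions(actin = 3, arp23 = 0.05, gst_vca = v, t_end = 1500))
ens <- gen_pyrene_ensemble("branching", conds, noise_sd = 0.01, seed = 11)
fit <- arp_fit(ens$traces, "branching", float = "k25")
coef(fit)
#>         k25
#> 0.003796986
```

The methods vignette (`vignettes/branching-kinetics.Rmd`) documents the
model assumptions, bookkeeping conventions, fitting and detection
parameter choices, and the limits of what the synthetic data emulate.

A command-line front end for the four workflow arms (simulate / fit /
smtrack / synth) is installed at `inst/cli/arpkin.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","arpkin.R",package="arpkin"))')" \
    simulate --config config.yaml --out results/
```

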