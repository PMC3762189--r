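test_that("quality of fit implements the documented mean-weighted formula", {
  tt <- seq(0, 100, 5)
  a <- arp_trace(tt, 1 + tt / 50, total_actin = 3)
  b <- arp_trace(tt, sqrt(tt + 1), total_actin = 3)
  ## perfect agreement
  expect_equal(quality_of_fit(list(a, b), list(a, b)), 0)
  ## constant offset on one trace: contribution delta^2 * n / mean^2 / N
  delta <- 0.37
  a_off <- arp_trace(tt, a$value + delta, total_actin = 3)
  expected <- (delta^2 * length(tt) / mean(a_off$value)^2) / 2
  expect_equal(quality_of_fit(list(a, b), list(a_off, b)), expected)
  ## invariance under a common rescaling of observed and simulated
  a2 <- arp_trace(tt, 2 * a$value, total_actin = 3)
  ao2 <- arp_trace(tt, 2 * a_off$value, total_actin = 3)
  expect_equal(quality_of_fit(list(a2), list(ao2)),
               quality_of_fit(list(a), list(a_off)))
  expect_error(quality_of_fit(list(a), list(a, b)), "matched")
})

test_that("noiseless self-fit is a fixed point with essentially zero qof", {
  conds <- lapply(c(0.05, 1), function(v)
    arp_conditions(actin = 3, arp23 = 0.05, gst_vca = v, t_end = 1200,
                   n_out = 150))
  ens <- gen_pyrene_ensemble("branching", conds, noise_sd = 0, seed = 1)
  fit <- arp_fit(ens$traces, "branching", float = "k25")
  expect_lt(fit$quality_of_fit, 1e-12)
  expect_equal(unname(coef(fit)["k25"]), 0.0038, tolerance = 1e-4)
})

test_that("global fitting is deterministic", {
  ens <- branching_ensemble()
  sub <- ens$traces[c(3, 6, 9)]
  f1 <- arp_fit(sub, "branching", float = "k25", start = list(k25 = 0.006))
  f2 <- arp_fit(sub, "branching", float = "k25", start = list(k25 = 0.006))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$quality_of_fit, f2$quality_of_fit)
})

test_that("floating-set discipline is enforced", {
  ens <- branching_ensemble()
  expect_error(arp_fit(ens$traces[1:2], "branching", float = "k28"),
               "floating set")
  expect_error(arp_fit(ens$traces[1:2], "branching", float = "k_dis"),
               "floating set")
})

test_that("the nucleation rate is recovered from a noisy GST-VCA titration", {
  ens <- branching_ensemble()
  fit <- arp_fit(ens$traces, "branching", float = "k25",
                 start = list(k25 = 0.006))
  expect_equal(unname(coef(fit)["k25"]), 0.0038, tolerance = 0.10)
  expect_true(fit$converged)
})

test_that("the displacement rate is recovered from a cortactin titration", {
  ens <- displacement_ensemble()
  fit <- arp_fit(ens$traces, "displacement", float = "k28",
                 start = list(k28 = 0.02))
  expect_equal(unname(coef(fit)["k28"]), 0.036, tolerance = 0.15)
  expect_true(fit$converged)
})

test_that("fit object methods are coherent", {
  ens <- branching_ensemble()
  fit <- arp_fit(ens$traces[c(3, 9)], "branching", float = "k25")
  expect_s3_class(fit, "arp_fit")
  expect_named(coef(fit), "k25")
  expect_equal(deviance(fit), fit$quality_of_fit)
  expect_length(residuals(fit), 2)
  s <- summary(fit)
  expect_s3_class(s, "summary.arp_fit")
  expect_match(s$table$reaction[1], "nucleation")
  pr <- predict(fit)
  expect_length(pr, 2)
  expect_s3_class(pr[[1]], "arp_trace")
  ## predictions track the data closely (1% noise)
  expect_equal(pr[[1]]$value, ens$traces[[3]]$value, tolerance = 0.05)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_length(sims[[1]], 2)
  ## printing does not error
  expect_output(print(fit), "Global kinetic fit")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("k_fil_on scan declines to a plateau with decreasing co-optimized k_nuc", {
  ens <- memo("scan_ens", {
    conds <- lapply(c(0.05, 0.25, 1), function(v)
      arp_conditions(actin = 3, arp23 = 0.05, gst_vca = v, t_end = 1200,
                     n_out = 200))
    gen_pyrene_ensemble("branching", conds, noise_sd = 0.01, seed = 3)
  })
  sc <- scan_k_fil_on(ens$traces, "branching",
                      grid = c(1e3, 1e4, 1e5, 1e6, 1e7), qof_cutoff = 0.05)
  ## qof is non-increasing up to the plateau ...
  expect_true(all(diff(sc$qof[1:4]) < 0))
  ## ... and flat (within 5%) across the plateau
  expect_lt(abs(sc$qof[5] - sc$qof[4]) / sc$qof[4], 0.05)
  ## co-optimized nucleation rate decreases with k_fil_on
  expect_true(all(diff(sc$k25) < 0))
  ## data were generated at 1.37e6: the threshold lands on the 1e6 point
  expect_equal(attr(sc, "threshold"), 1e6)
  ## a one-point grid degenerates to a single global fit
  one <- scan_k_fil_on(ens$traces, "branching", grid = 1.37e6)
  ref <- arp_fit(ens$traces, "branching", float = "k25",
                 overrides = list(k_fil_on = 1.37e6,
                                  k_fil_off = 1.37e6 * 0.9e-6),
                 allow_any_float = TRUE)
  expect_equal(one$k25, unname(coef(ref)["k25"]), tolerance = 1e-8)
  expect_warning(scan_k_fil_on(ens$traces, "branching",
                               grid = c(1e2, 1e3), qof_cutoff = 1e-30),
                 "never reached")
})

test_that("recruitment test: identity at zero sites, saturating decline", {
  grid <- c(0, 0.1, 0.25, 0.5, 1)
  rec <- recruitment_test(grid, k_fil_on = 1.4e6)
  ## baseline equals the plain branching half time
  base <- half_time_to_equilibrium(polymerized_actin(
    simulate_network(build_network("branching",
                                   overrides = list(k_fil_on = 1.4e6)),
                     arp_conditions(t_end = 2500, n_out = 800))))
  expect_equal(rec$t_half[1], base)
  ## monotone decreasing and saturating over the probed range
  expect_true(all(diff(rec$t_half) < 0))
  drops <- -diff(rec$t_half) / diff(rec$side_sites)
  expect_lt(drops[length(drops)], drops[1])
})

test_that("on rates follow from off rates and equilibrium constants", {
  ## junction binding: k_off 0.034 /s at K_D 17 nM -> 2e6 /(M s)
  expect_equal(k_on_from_kd(0.034, 0.017)$k_on_M, 2.0e6)
  ## side binding: k_off 0.063 /s at K_D 5.2 uM -> ~1.2e4 /(M s)
  expect_equal(k_on_from_kd(0.063, 5.2)$k_on_M, 1.2e4, tolerance = 0.01)
  ## unit identity: k_off numerically equal to K_D gives 1 /(uM s)
  expect_equal(k_on_from_kd(0.73, 0.73)$k_on_uM, 1)
  expect_error(k_on_from_kd(-1, 1))
  expect_error(k_on_from_kd(1, 0))
})
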