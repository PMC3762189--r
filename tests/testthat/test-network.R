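test_that("variants contain exactly their reaction subsets", {
  expect_equal(build_network("spontaneous")$reactions, 1:4)
  expect_equal(build_network("vca_only")$reactions, 1:12)
  expect_equal(build_network("branching")$reactions, 1:25)
  expect_equal(build_network("displacement")$reactions, 1:28)
  expect_equal(build_network("recycling")$reactions, c(1:25, 29))
  expect_error(build_network("frobnicate"))
})

test_that("rate table is internally consistent (k_off/k_on vs tabulated K_D)", {
  cons <- kd_consistency()
  ## one tabulated K_D is known to disagree with its kinetic constants and
  ## is flagged in the table; all others agree to 5%
  expect_true(all(cons$rel_dev[!cons$kd_inconsistent] <= 0.05))
  expect_true(all(cons$kd_inconsistent == (cons$id %in% c(14, 16, 20))))
  ## spot check: filament binding, k_off/k_on = 1.23/1.37e6 M ~ 0.9 uM
  r13 <- cons[cons$id == 13, ]
  expect_equal(r13$kd_kinetic, 0.898, tolerance = 1e-3)
  ## irreversible steps carry no reverse rate
  rt <- arp_rate_table()
  expect_true(all(is.na(rt$k_off[rt$id %in% c(3, 12, 25, 28)])))
  expect_true(all(!is.na(rt$k_off[!rt$id %in% c(3, 12, 25, 28)])))
})

test_that("overrides substitute constants and reject foreign reactions", {
  net <- build_network("branching", overrides = list(k_nuc = 0.005,
                                                     k_fil_on = 1.4e6))
  expect_equal(unname(net$params["k25"]), 0.005)
  expect_equal(unname(net$params[c("k13", "k19", "k21", "k22")]),
               rep(1.4e6, 4))
  ## cortactin reactions are absent from the branching variant
  expect_error(build_network("branching", overrides = list(k28 = 0.1)),
               "not part of variant")
  expect_error(build_network("spontaneous", overrides = list(k_nuc = 0.01)),
               "not part of variant")
  expect_error(build_network("branching", overrides = list(k25 = -1)))
})

test_that("empty initial conditions give identically zero trajectories", {
  cond <- arp_conditions(actin = 0, arp23 = 0, gst_vca = 0, cortactin = 0,
                         t_end = 100, n_out = 50)
  sim <- simulate_network(build_network("displacement"), cond)
  expect_true(all(as.matrix(sim[, setdiff(names(sim), "time")]) == 0))
})

test_that("an isolated reversible reaction reaches its closed-form equilibrium", {
  ## only cortactin and side sites present: of the displacement network,
  ## just the side-binding reaction (k_on 1.21e4 /(M s), k_off 0.063 /s)
  ## can fire.  Equilibrium bound = quadratic solution of
  ## b*s/(Kd + ...) for A + B <-> AB.
  cond <- arp_conditions(actin = 0, arp23 = 0, gst_vca = 0,
                         cortactin = 1.5e-3, side_sites = 5.21,
                         t_end = 5000, n_out = 100)
  sim <- simulate_network(build_network("displacement"), cond)
  Kd <- 0.063 / (1.21e4 * 1e-6)
  b <- 1.5e-3; s <- 5.21
  bound <- ((b + s + Kd) - sqrt((b + s + Kd)^2 - 4 * b * s)) / 2
  expect_equal(sim$CF[nrow(sim)], bound, tolerance = 1e-6)
  ## all other species untouched (to solver roundoff)
  expect_lt(max(abs(c(sim$F, sim$RF))), 1e-10)
})

test_that("total actin is conserved to 1e-6 in every variant", {
  for (v in c("spontaneous", "vca_only", "branching", "displacement",
              "recycling")) {
    sim <- simulate_network(build_network(v),
                            arp_conditions(actin = 3, arp23 = 0.02,
                                           gst_vca = 0.1, cortactin = 0.25,
                                           t_end = 1000, n_out = 200))
    expect_lt(attr(sim, "mass_balance_drift"), 1e-6)
  }
})

test_that("Arp2/3, GST-VCA and cortactin totals are conserved too", {
  sim <- simulate_network(build_network("displacement"),
                          arp_conditions(actin = 3, arp23 = 0.02,
                                         gst_vca = 0.1, cortactin = 0.1,
                                         t_end = 1500, n_out = 300))
  arp <- rowSums(sim[, c("R", "RF", "VR", "VRA1", "VRA2", "VRF", "VRAF",
                         "VRA2F", "CN", "J", "CJ", "Jv")])
  vca <- rowSums(sim[, c("V", "VA1", "VA2", "VA3", "VA4", "VA5", "VR",
                         "VRA1", "VRA2", "VRF", "VRAF", "VRA2F", "CN",
                         "Jv")])
  ctt <- rowSums(sim[, c("C", "CF", "CN", "CJ")])
  expect_equal(max(abs(arp - 0.02)) / 0.02, 0, tolerance = 1e-6)
  expect_equal(max(abs(vca - 0.05)) / 0.05, 0, tolerance = 1e-6)
  expect_equal(max(abs(ctt - 0.1)) / 0.1, 0, tolerance = 1e-6)
})

test_that("add_side_sites is the identity at zero and speeds polymerization", {
  cond <- arp_conditions(t_end = 2500, n_out = 400)
  expect_identical(add_side_sites(cond, 0), cond)
  expect_error(add_side_sites(cond, -1))
  net <- build_network("branching", overrides = list(k_fil_on = 1.4e6))
  t_half <- vapply(c(0, 0.5), function(s0) {
    sim <- simulate_network(net, add_side_sites(cond, s0))
    half_time_to_equilibrium(polymerized_actin(sim))
  }, 0)
  expect_lt(t_half[2], t_half[1])
})

test_that("sequestered GST-VCA fraction behaves at its edge cases", {
  ## no Arp2/3: no junctions can assemble, fraction is zero at all times
  sim0 <- simulate_network(build_network("recycling"),
                           arp_conditions(arp23 = 0, t_end = 500,
                                          n_out = 100))
  expect_equal(sequestered_vca_fraction(sim0, time = c(0, 100, 500)),
               rep(0, 3))
  ## variants without junction species are rejected
  simv <- simulate_network(build_network("vca_only"),
                           arp_conditions(t_end = 100, n_out = 50))
  expect_error(sequestered_vca_fraction(simv), "junction")
  ## cortactin strictly reduces the sequestered pool in the recycling model
  seqs <- vapply(c(0, 0.075, 1), function(cc) {
    sim <- simulate_network(build_network("recycling"),
                            arp_conditions(cortactin = cc, t_end = 2000,
                                           n_out = 300))
    sequestered_vca_fraction(sim)
  }, 0)
  expect_true(all(diff(seqs) < 0))
})

test_that("trajectory CSV export is tidy and faithful", {
  sim <- simulate_network(build_network("spontaneous"),
                          arp_conditions(t_end = 50, n_out = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sim_csv(sim, path)
  tab <- read.csv(path)
  expect_named(tab, c("time", "species", "concentration"))
  back <- tab[tab$species == "F", "concentration"]
  expect_equal(back, sim$F)
})
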