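## Shared fixtures, memoized so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

## small GST-VCA titration ensemble from the branching variant (truth:
## k_nuc = 0.0038), 1% noise
branching_ensemble <- function() memo("branching_ens", {
  conds <- lapply(c(0, 0.01, 0.025, 0.05, 0.1, 0.15, 0.25, 0.5, 1),
                  function(v) arp_conditions(actin = 3, arp23 = 0.05,
                                             gst_vca = v, t_end = 1500,
                                             n_out = 250))
  gen_pyrene_ensemble("branching", conds, noise_sd = 0.01, seed = 11)
})

## cortactin titration ensemble from the displacement variant (truth:
## k_dis = 0.036), 1% noise
displacement_ensemble <- function() memo("displacement_ens", {
  conds <- lapply(c(0, 0.005, 0.025, 0.075, 0.1, 0.25, 1),
                  function(cc) arp_conditions(actin = 3, arp23 = 0.02,
                                              gst_vca = 0.1,
                                              cortactin = cc,
                                              t_end = 1500, n_out = 250))
  gen_pyrene_ensemble("displacement", conds, noise_sd = 0.01, seed = 12)
})

recycling_sim <- function() memo("recycling_sim", {
  simulate_network(build_network("recycling"),
                   arp_conditions(actin = 3, arp23 = 0.02, gst_vca = 0.1,
                                  cortactin = 0, t_end = 2000,
                                  n_out = 800))
})

displacement_sim_sat <- function() memo("displacement_sim_sat", {
  simulate_network(build_network("displacement"),
                   arp_conditions(actin = 3, arp23 = 0.02, gst_vca = 0.1,
                                  cortactin = 1, t_end = 800,
                                  n_out = 600))
})

## synthetic frame with one Gaussian spot on a noisy background
psf_frame <- function(nx = 64, ny = 64, cx = 30.3, cy = 41.7, amp = 500,
                      sigma = 1.1, bg = 100, noise = 5, seed = 1,
                      slope = 0) {
  set.seed(seed)
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  amp * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * sigma^2)) +
    bg + slope * xg + matrix(rnorm(nx * ny, 0, noise), nx, ny)
}
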