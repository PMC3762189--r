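test_that("preprocessing removes background and preserves spots", {
  ## constant image: rolling-ball background subtraction leaves zero
  flat <- matrix(7, 48, 48)
  expect_equal(max(abs(preprocess_frame(flat))), 0)
  expect_error(preprocess_frame(array(0, c(4, 4, 4))), "2-D")
  ## spot on a sloping background survives well above the residual
  img <- psf_frame(slope = 2, noise = 0, seed = 2)
  pp <- preprocess_frame(img)
  spot_val <- pp[30, 42]
  off_val <- max(abs(pp[seq(5, 15), seq(5, 15)]))
  expect_gt(spot_val, 10 * max(off_val, 1))
  ## a second pass shrinks the spot: preprocessing is not idempotent
  pp2 <- preprocess_frame(pp)
  expect_lt(pp2[30, 42], 0.97 * pp[30, 42])
})

test_that("detection finds spots at sub-pixel accuracy with few false positives", {
  d <- detect_molecules(preprocess_frame(psf_frame()))
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$x - 30.3)^2 + (d$y - 41.7)^2), 0.5)
  ## two spots > 4 px apart resolve into two detections
  img2 <- psf_frame() + psf_frame(cx = 30.3, cy = 47.0, bg = 0, noise = 0)
  d2 <- detect_molecules(preprocess_frame(img2))
  expect_equal(nrow(d2), 2)
  ## pure-noise frames: false-positive rate below 1 per 100 frames
  set.seed(31)
  fp <- 0
  for (i in 1:300) {
    f <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
    fp <- fp + nrow(detect_molecules(preprocess_frame(f)))
  }
  expect_lt(fp / 300, 1 / 100)
  ## saturated frames are flagged
  sat <- matrix(100, 32, 32); sat[1:10, 1:10] <- 4095
  expect_warning(detect_molecules(sat), "saturated")
})

test_that("nearest-neighbor linking builds gapless tracks", {
  ## one static spot over ten frames: a single ten-frame track
  det <- data.frame(frame = 1:10, x = 20 + rnorm(10, 0, 0.1),
                    y = 30 + rnorm(10, 0, 0.1), intensity = 100)
  tr <- link_tracks(det, max_displacement = 2)
  st <- track_stats(tr, frame_interval = 0.5)
  expect_equal(nrow(st), 1)
  expect_equal(st$lifetime_frames, 10)
  expect_equal(st$lifetime_s, 5)
  ## a one-frame disappearance splits the track (no gap closing)
  det2 <- det[-5, ]
  st2 <- track_stats(link_tracks(det2, max_displacement = 2))
  expect_equal(nrow(st2), 2)
  expect_equal(sort(st2$lifetime_frames), c(4, 5))
  ## empty input
  empty <- link_tracks(data.frame(frame = integer(0), x = numeric(0),
                                  y = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("20 simultaneous molecules are tracked without identity switches", {
  set.seed(77)
  n <- 20; nf <- 40
  pts <- matrix(runif(2, 5, 120), 1)
  while (nrow(pts) < n) {
    p <- runif(2, 5, 120)
    if (min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) > 16)
      pts <- rbind(pts, p)
  }
  truth <- data.frame(x = pts[, 1], y = pts[, 2])
  det <- do.call(rbind, lapply(1:nf, function(f)
    data.frame(frame = f, x = truth$x + rnorm(n, 0, 0.2),
               y = truth$y + rnorm(n, 0, 0.2), molecule = 1:n)))
  tr <- link_tracks(det, max_displacement = 2)
  ## each ground-truth molecule maps to exactly one recovered track
  purity <- tapply(tr$track_id, tr$molecule, function(id)
    length(unique(id)) == 1)
  expect_gte(mean(purity), 0.95)
  expect_equal(length(unique(tr$track_id)), n)
})

test_that("the four filtering criteria reject exactly the offending tracks", {
  mask <- matrix(0, 64, 64); mask[, 30:33] <- 1
  mk <- function(id, first, last, inten, y) data.frame(
    track_id = id, first_frame = first, last_frame = last,
    lifetime_frames = last - first + 1L,
    lifetime_s = (last - first + 1) * 0.5, x = 32, y = y,
    mean_intensity = inten)
  stats <- rbind(
    mk(1, 1, 8, 100, 31),     # present in first frame  -> criterion 1
    mk(2, 95, 100, 100, 31),  # present in last frame   -> criterion 1
    mk(3, 10, 10, 100, 31),   # single frame            -> criterion 2
    mk(4, 12, 20, 1e4, 31),   # intensity outlier       -> criterion 3
    mk(5, 30, 40, 100, 5),    # off the filament        -> criterion 4
    mk(6, 12, 22, 101, 31), mk(7, 40, 52, 99, 31),
    mk(8, 60, 70, 100, 32), mk(9, 20, 29, 102, 31),
    mk(10, 75, 85, 98, 33))
  filt <- filter_tracks(stats, first_frame = 1, last_frame = 100,
                        filament_mask = mask)
  expect_equal(sort(filt$track_id), c(6, 7, 8, 9, 10))
  rej <- attr(filt, "rejections")
  expect_equal(unname(rej["boundary"]), 2L)
  expect_equal(unname(rej["single_frame"]), 1L)
  expect_equal(unname(rej["intensity"]), 1L)
  expect_equal(unname(rej["off_filament"]), 1L)
  ## criteria are individually toggleable
  keep_all <- filter_tracks(stats, 1, 100, criteria = c(F, F, F, F))
  expect_equal(nrow(keep_all), 10)
  expect_error(filter_tracks(stats, 1, 100,
                             criteria = c(TRUE, TRUE, TRUE, TRUE)),
               "filament_mask")
})

test_that("binding classes are assigned from junction geometry", {
  st <- data.frame(track_id = 1:3, first_frame = c(5, 5, 5),
                   last_frame = c(20, 20, 20), x = c(10, 40, 60),
                   y = c(10, 40, 60))
  j <- data.frame(x = c(10.5, 60), y = c(10.5, 60),
                  appear_frame = c(1, 12))
  cl <- classify_tracks(st, j, radius = 3)
  expect_equal(cl$binding_class,
               c("branch_junction", "filament_side", "nascent_branch"))
})

test_that("dwell-time off rates are recovered and scale correctly", {
  lt <- gen_dwell_times(0.05, 10000, 0.2, 1e6, seed = 5)
  fit <- off_rate_from_lifetimes(lt$lifetime_true)
  expect_equal(fit$k_off, 0.05, tolerance = 0.05)
  expect_equal(fit$tau, 1 / fit$k_off)
  ## doubling all lifetimes exactly halves the fitted rate (scale property)
  fit2 <- off_rate_from_lifetimes(2 * lt$lifetime_true, bin_width = 10)
  expect_equal(fit2$k_off, fit$k_off / 2, tolerance = 1e-9)
  expect_error(off_rate_from_lifetimes(rexp(5, 1)), "at least 20")
  expect_error(off_rate_from_lifetimes(rep(1, 100), bin_width = 5),
               "single bin")
})

test_that("off-rate estimator bias shrinks with sample size", {
  err <- vapply(c(100, 1000, 10000), function(n) {
    e <- vapply(1:10, function(s) {
      lt <- gen_dwell_times(0.05, n, 0.1, 1e7, seed = 1000 + s)
      abs(off_rate_from_lifetimes(lt$lifetime_true)$k_off - 0.05) / 0.05
    }, 0)
    mean(e)
  }, 0)
  expect_true(err[3] < err[1])
  expect_lt(err[3], 0.02)
})

test_that("binding-site census follows the published arithmetic", {
  ## empty mask
  expect_equal(count_side_sites(matrix(0, 10, 10), 0)$side_sites, 0)
  ## worked example: 10,000 filament pixels, 10 junctions
  cen <- count_side_sites(10000, 10)
  expect_equal(cen$side_sites, floor((10000 - 50) / 3 * 0.1067 * 370 / 6))
  expect_equal(cen$side_sites, 21823)
  ## junction share of all binding sites: 68 junctions vs ~53,000 sites
  share <- 68 / (68 + 53000)
  expect_equal(share * 100, 0.128, tolerance = 0.01)
  ## linear in filament pixels at fixed junction count
  s1 <- count_side_sites(20000, 10)$side_sites
  s2 <- count_side_sites(40000, 10)$side_sites
  s3 <- count_side_sites(60000, 10)$side_sites
  expect_equal(s3 - s2, s2 - s1, tolerance = 1e-3)
  expect_error(count_side_sites(40, 10), "exceed")
})

test_that("fraction-bound K_D inversion is exact", {
  expect_equal(kd_from_fraction_bound(0.5, 0.3), 0.3)
  ## round trip with the forward occupancy formula
  kd <- 0.017; c0 <- 0.0015
  fb <- c0 / (kd + c0)
  expect_equal(kd_from_fraction_bound(fb, c0), kd)
  ## published worked value: 1.5 nM at fraction bound 1.5/18.5 -> 17 nM
  expect_equal(kd_from_fraction_bound(1.5 / 18.5, 1.5), 17)
  expect_error(kd_from_fraction_bound(0, 1))
  expect_error(kd_from_fraction_bound(1.2, 1))
  ## closure with the on-rate arithmetic reproduces the off rate
  k_off <- 0.034
  kon <- k_on_from_kd(k_off, kd_from_fraction_bound(fb, c0))
  expect_equal(kon$k_on_uM * kd, k_off)
})

test_that("excess-ligand bookkeeping reproduces the worked chain", {
  e <- excess_ligand_check(avg_bound_per_frame = 20)
  expect_equal(e$image_area_mm2, 2.98e-3, tolerance = 0.005)
  expect_equal(e$image_fraction_pct, 0.00248, tolerance = 0.01)
  expect_equal(e$bound_per_chamber, 8.06e5, tolerance = 0.01)
  expect_equal(e$total_molecules, 1.08e10, tolerance = 0.005)
  expect_equal(e$percent_bound, 0.0075, tolerance = 0.02)
  ## nothing bound, nothing to worry about
  expect_equal(excess_ligand_check(0)$percent_bound, 0)
  ## doubling the concentration halves the bound percentage
  e2 <- excess_ligand_check(20, conc_nM = 3)
  expect_equal(e2$percent_bound, e$percent_bound / 2)
  expect_error(excess_ligand_check(20, chamber_area_mm2 = 0))
})
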