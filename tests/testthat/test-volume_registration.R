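tc <- function(a, d) nmlineage:::translate_circular(a, d)

test_that("block-mean downsampling conserves structure and intensity", {
  # constant 2x2x2 blocks collapse to the same constants
  a <- array(0, c(4, 4, 4))
  a[1:2, , ] <- 1; a[3:4, , ] <- 5
  v <- volume_stack(a, voxel_size = c(0.5, 0.5, 0.5))
  dv <- downsample_iso(v, 1)
  expect_equal(dim(dv$data), c(2, 2, 2))
  expect_true(all(dv$data[1, , ] == 1) && all(dv$data[2, , ] == 5))
  expect_equal(dv$voxel_size, c(1, 1, 1))

  # already isotropic at the target: identity
  vi <- volume_stack(array(rnorm(27), c(3, 3, 3)))
  expect_equal(downsample_iso(vi, 1)$data, vi$data)

  # no upsampling
  expect_error(downsample_iso(vi, 0.5), "upsample")

  # mean conservation on random volumes with exact factors
  set.seed(1)
  for (i in 1:5) {
    a <- array(runif(8 * 8 * 8), c(8, 8, 8))
    v <- volume_stack(a, voxel_size = c(0.5, 0.5, 0.25))
    dv <- downsample_iso(v, 1)
    expect_equal(mean(dv$data), mean(a), tolerance = 0.01)
  }
})

test_that("phase correlation recovers circular shifts exactly", {
  set.seed(2)
  a <- array(rnorm(24^3), c(24, 24, 24))
  expect_equal(phase_corr_shift(a, a)$shift, c(0L, 0L, 0L))
  for (i in 1:10) {
    d <- sample(-6:6, 3, replace = TRUE)
    expect_equal(phase_corr_shift(a, tc(a, d), max_shift = 6)$shift, d)
  }
  # antisymmetry
  d <- c(3, -4, 2)
  b <- tc(a, d)
  expect_equal(phase_corr_shift(b, a, max_shift = 6)$shift, -d)
  # contract errors
  expect_error(phase_corr_shift(a, array(0, c(8, 8, 8))), "shape")
  expect_error(phase_corr_shift(array(1, c(8, 8, 8)), array(1, c(8, 8, 8))),
               "no signal")
})

test_that("phase correlation matches brute-force lag search on random volumes", {
  brute <- function(a, b, mx) {
    best <- NULL; bv <- -Inf
    for (dz in -mx:mx) for (dy in -mx:mx) for (dx in -mx:mx) {
      v <- sum(a * tc(b, -c(dz, dy, dx)))
      if (v > bv) { bv <- v; best <- c(dz, dy, dx) }
    }
    best
  }
  set.seed(3)
  for (i in 1:5) {
    a <- array(rnorm(16^3), c(16, 16, 16))
    d <- sample(-3:3, 3, replace = TRUE)
    b <- tc(a, d)
    expect_equal(phase_corr_shift(a, b, max_shift = 4)$shift, brute(a, b, 4))
  }
})

test_that("phase correlation stays within one voxel at SNR 3", {
  base <- simulate_drifting_volume(shape = c(32, 32, 32), n_timepoints = 1,
                                   drift = c(0, 0, 0), seed = 4)$stacks[[1]]$data
  sig <- stats::sd(base)
  set.seed(5)
  for (i in 1:10) {
    d <- sample(-5:5, 3, replace = TRUE)
    a <- base + rnorm(length(base), 0, sig / 3)
    b <- tc(base, d) + rnorm(length(base), 0, sig / 3)
    got <- phase_corr_shift(a, b, max_shift = 8)$shift
    expect_true(all(abs(got - d) <= 1))
  }
})

test_that("the online loop emits -interval*drift corrections and recenters", {
  ser0 <- simulate_drifting_volume(shape = c(24, 24, 24), n_timepoints = 11,
                                   drift = c(0, 0, 0), seed = 6)
  ot0 <- online_tracking(ser0, interval = 5)
  expect_true(all(ot0$log[, c("corr_z", "corr_y", "corr_x")] == 0))

  d <- c(0, 1, 2)
  ser <- simulate_drifting_volume(shape = c(32, 32, 32), n_timepoints = 16,
                                  drift = d, seed = 7)
  ot <- online_tracking(ser, interval = 5, max_shift = 12)
  expect_true(all(ot$log$dz == 5 * d[1] & ot$log$dy == 5 * d[2] &
                    ot$log$dx == 5 * d[3]))
  # telescoping: accumulated correction equals total drift up to one event lag
  total_drift <- ser$cumulative_drift[16, ]
  expect_equal(-ot$cumulative_correction, total_drift)

  ctr <- dim(ser$stacks[[1]]$data) / 2
  dist_to_ctr <- function(stacks) {
    cen <- series_centroids(stacks)
    max(sqrt(rowSums(sweep(cen, 2, ctr)^2)))
  }
  expect_lt(dist_to_ctr(ot$corrected), dist_to_ctr(ser$stacks))
})

test_that("low-confidence events withhold the stage correction", {
  ser <- simulate_drifting_volume(shape = c(24, 24, 24), n_timepoints = 11,
                                  drift = c(0, 1, 1), seed = 8)
  ot <- online_tracking(ser, interval = 5, max_shift = 10, confidence_floor = 1.1)
  expect_true(all(!ot$log$applied))
  expect_true(all(ot$log[, c("corr_z", "corr_y", "corr_x")] == 0))
  expect_equal(ot$cumulative_correction, c(0L, 0L, 0L))
})

test_that("offline registration leaves zero residual shifts", {
  # a sudden step displacement at t = 5, as a stage move would cause
  drift_mat <- matrix(0, 10, 3)
  drift_mat[6, ] <- c(0, 4, -3)
  ser <- simulate_drifting_volume(shape = c(24, 24, 24), n_timepoints = 10,
                                  drift = drift_mat, seed = 9)
  off <- offline_register(ser, max_shift = 8)
  expect_equal(off$pairwise[5, ], c(0L, 4L, -3L))
  for (t in 2:10) {
    resid <- phase_corr_shift(off$registered[[t - 1]], off$registered[[t]],
                              max_shift = 8)$shift
    expect_equal(resid, c(0L, 0L, 0L))
  }
  # cumulative shifts are prefix sums of the pairwise shifts
  expect_equal(off$cumulative, rbind(0L, apply(off$pairwise, 2, cumsum)))
  # single frame: identity
  one <- offline_register(ser$stacks[1])
  expect_equal(one$registered[[1]]$data, ser$stacks[[1]]$data)
})

test_that("the drifting-volume simulator honours its contracts", {
  # zero drift, zero noise: identical frames
  ser <- simulate_drifting_volume(shape = c(16, 16, 16), n_timepoints = 4,
                                  drift = c(0, 0, 0), noise_sd = 0, seed = 10)
  for (t in 2:4) expect_equal(ser$stacks[[t]]$data, ser$stacks[[1]]$data)

  # closed loop: integer constant drift recovered exactly at each event
  d <- c(1, -1, 2)
  ser2 <- simulate_drifting_volume(shape = c(32, 32, 32), n_timepoints = 11,
                                   drift = d, seed = 11)
  for (t in c(6, 11)) {
    got <- phase_corr_shift(ser2$stacks[[t - 5]], ser2$stacks[[t]],
                            max_shift = 12)$shift
    expect_equal(got, 5L * d)
  }
})

test_that("TIFF series round-trips through disk", {
  skip_if_not_installed("tiff")
  ser <- simulate_drifting_volume(shape = c(8, 8, 8), n_timepoints = 3,
                                  drift = c(0, 1, 0), seed = 12)
  dir <- withr::local_tempdir()
  write_volume_series(ser, dir)
  back <- read_volume_series(dir)
  expect_length(back, 3)
  for (t in 1:3) {
    expect_equal(back[[t]]$data, ser$stacks[[t]]$data, tolerance = 1e-6)
  }
})
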