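kB <- 0.0019872041

test_that("zero-bias WHAM reduces exactly to -kT log(histogram)", {
  cv <- cv_coordinate(1, 1)
  set.seed(3)
  v <- rnorm(20000, 5, 1.5)
  w <- umbrella_window(5, 0, cv, data.frame(time = seq_along(v), value = v))
  prof <- solve_wham(list(w), bins = 40, range = c(0, 10), periodic = FALSE,
                     temperature = 300, reference = "min_zero")
  h <- prof$counts
  ref <- -kB * 300 * log(h / sum(h))
  ref[h == 0] <- NA
  ref <- ref - min(ref, na.rm = TRUE)
  expect_equal(prof$pmf, ref, tolerance = 1e-10)
})

test_that("a single harmonic window on a flat landscape unbiases to a flat profile", {
  # samples drawn from the bias Boltzmann distribution itself
  cv <- cv_coordinate(1, 1)
  k2 <- 2; kT <- kB * 300
  set.seed(11)
  v <- rnorm(50000, 3, sqrt(kT / k2))
  w <- umbrella_window(3, k2, cv, data.frame(time = seq_along(v), value = v))
  prof <- solve_wham(list(w), bins = 30, range = c(1.8, 4.2),
                     periodic = FALSE, temperature = 300)
  ok <- is.finite(prof$pmf) & prof$counts > 200
  # binomial noise per bin, 3 sigma
  p <- prof$counts[ok] / sum(prof$counts)
  noise <- kT * sqrt((1 - p) / prof$counts[ok])
  dev <- abs(prof$pmf[ok] - mean(prof$pmf[ok]))
  expect_true(all(dev <= pmax(3 * noise, 0.02)))
})

test_that("WHAM output is invariant under window reordering", {
  toy <- build_toy_1d()
  centers <- seq(-180, 160, by = 20)
  wins <- lapply(seq_along(centers), function(i) {
    w <- umbrella_window(centers[i], 33, toy$cv,
                         data.frame(time = 0, value = 0), index = i)
    w$init_coords <- matrix(c(centers[i], 0, 0), 1, 3)
    run_window(toy$system, w, md_params(n_steps = 3e4, cv_stride = 50,
                                        record_interval = 1e5, seed = 40 + i))
  })
  p1 <- solve_wham(wins, bins = 90, periodic = TRUE, temperature = 300)
  set.seed(2)
  p2 <- solve_wham(sample(wins), bins = 90, periodic = TRUE, temperature = 300)
  expect_lt(max(abs(p1$pmf - p2$pmf), na.rm = TRUE), 1e-10)
})

test_that("WHAM error handling: non-convergence and disconnected windows", {
  cv <- cv_coordinate(1, 1)
  set.seed(5)
  mk <- function(c0, sd = 0.8) umbrella_window(c0, 10, cv,
                                     data.frame(time = 1:500,
                                                value = rnorm(500, c0, sd)))
  err <- tryCatch(solve_wham(list(mk(0), mk(2)), bins = 40, range = c(-1, 3),
                             periodic = FALSE, max_iter = 1),
                  error = function(e) e)
  expect_match(conditionMessage(err), "converge")
  expect_true(is.numeric(err$F_i))

  expect_error(solve_wham(list(mk(0, sd = 0.3), mk(50, sd = 0.3)), bins = 100,
                          range = c(-1, 51), periodic = FALSE), "overlap")
})

test_that("stationary-point extraction finds extrema of known curves", {
  x <- seq(-179, 179, by = 2)
  # strictly monotone profile: no interior extrema
  mono <- pmf_profile(seq(0, 1, length.out = 50), seq(0, 5, length.out = 50),
                      unit = "A")
  sp <- profile_stationary_points(mono, smoothing = 1)
  expect_equal(nrow(sp$extrema), 0)
  expect_equal(nrow(sp$endpoints), 2)

  # cos(3x) on a periodic axis: maxima at 0, +-120; minima at +-60, 180
  prof <- pmf_profile(x, cos(3 * x * pi / 180), periodic = TRUE)
  sp2 <- profile_stationary_points(prof, smoothing = 1)$extrema
  expect_lt(max(abs(sort(sp2$position[sp2$kind == "max"]) - c(-120, 0, 120))), 1.5)
  expect_lt(max(abs(sort(sp2$position[sp2$kind == "min"]) - c(-60, 60, 180))), 1.5)

  # light noise: extrema recovered within ~2 bins after smoothing
  set.seed(8)
  noisy <- pmf_profile(x, cos(3 * x * pi / 180) + rnorm(length(x), 0, 0.03),
                       periodic = TRUE)
  sp3 <- profile_stationary_points(noisy, smoothing = 5)$extrema
  maxima <- sort(sp3$position[sp3$kind == "max"])
  expect_length(maxima, 3)
  expect_lt(max(abs(maxima - c(-120, 0, 120))), 5)
})

test_that("calibration inverts a clean rigid rotation exactly", {
  phis <- seq(-180, 0, by = 2)
  coords <- lapply(phis, butane_geometry)
  bt <- build_butane()
  tr <- synthetic_trajectory(coords, system = bt$system)
  target <- md_frame(butane_geometry(0))
  rmsd_cv <- cv_rmsd(1:4, target, weights = bt$system$atoms$mass)
  cal <- build_calibration(tr, rmsd_cv, cv_dihedral(1:4), n_bins = 91)
  # start of the arc maps near -180, the end near 0
  s0 <- cv_value(rmsd_cv, md_frame(butane_geometry(-180)))
  expect_equal(calibrate_dihedral(cal, s0), -180, tolerance = 2.5)
  expect_equal(calibrate_dihedral(cal, 0.01), 0, tolerance = 2.5)
  # a stored knot returns its stored dihedral
  expect_equal(calibrate_dihedral(cal, cal$rmsd[10]),
               ((cal$dihedral[10] + 180) %% 360) - 180, tolerance = 1e-9)
  # clamping outside the calibrated range warns
  expect_warning(calibrate_dihedral(cal, s0 + 1), "clamped")
})

test_that("calibration rejects a folded (non-monotone) coordinate relation", {
  # drive the dihedral through the target: the RMSD reaches 0 and rises
  # again, so two dihedral branches share each RMSD value
  phis <- seq(-60, 170, by = 2)
  coords <- lapply(phis, butane_geometry)
  bt <- build_butane()
  tr <- synthetic_trajectory(coords, system = bt$system)
  rmsd_cv <- cv_rmsd(1:4, md_frame(butane_geometry(90)),
                     weights = bt$system$atoms$mass)
  expect_error(build_calibration(tr, rmsd_cv, cv_dihedral(1:4), n_bins = 60,
                                 margin = 360),
               "monotone")
})

test_that("stitching aligns offsets and reproduces overlapping truth", {
  x <- seq(-179, 180, by = 2)
  truth <- 2 * (1 + cos(3 * x * pi / 180))
  seg <- function(lo, hi, offset = 0) {
    y <- ifelse(x >= lo & x <= hi, truth + offset, NA_real_)
    pmf_profile(x, y)
  }
  # identical overlapping segments: output equals either segment (min-zero)
  s1 <- seg(-179, 20); s2 <- seg(-60, 120)
  out <- stitch_profiles(list(s1, s2), span = 1)
  ok <- is.finite(out$pmf)
  expect_equal(out$pmf[ok], (truth - min(truth[ok]))[ok], tolerance = 1e-10)

  # constant offsets are removed by the least-squares alignment
  out2 <- stitch_profiles(list(seg(-179, 20), seg(-60, 120, offset = 3),
                               seg(80, 180, offset = -1)), span = 1)
  ok2 <- is.finite(out2$pmf)
  expect_equal(out2$pmf[ok2], truth[ok2] - min(truth[ok2]), tolerance = 1e-10)

  # zero overlap is an error
  expect_error(stitch_profiles(list(seg(-179, -100), seg(0, 100)), span = 1),
               "overlap")
})
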