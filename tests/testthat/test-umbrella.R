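test_that("window-center grids have the documented counts", {
  expect_length(make_centers(10.2, 26.4, 0.2), 82)
  expect_length(make_centers(-180, 0, 20, periodic = TRUE), 10)
  expect_equal(make_centers(0, 1, 0.5), c(0, 0.5, 1))
  expect_error(make_centers(0, 1, 0.3), "multiple")
  # dropping the duplicate endpoint only acts on a full-period grid
  expect_length(make_centers(-180, 180, 20, periodic = TRUE,
                             drop_duplicate_endpoint = TRUE), 18)
  expect_length(make_centers(-180, 0, 20, periodic = TRUE,
                             drop_duplicate_endpoint = TRUE), 10)

  cs <- butane_dihedral_centers()
  expect_equal(lengths(cs), c(10L, 4L, 5L))
  expect_equal(sum(lengths(cs)), 19)
  for (s in cs) expect_true(all(diff(s) > 0))
})

test_that("window selection picks the nearest-valued frame, earliest on ties", {
  toy <- build_toy_1d()
  # monotone synthetic coordinate trace 0 -> 1 over 101 frames
  coords <- lapply(seq(0, 1, length.out = 101),
                   function(v) matrix(c(v, 0, 0), 1, 3))
  tr <- synthetic_trajectory(coords, system = toy$system)
  cv <- cv_coordinate(1, 1)
  wins <- select_windows(tr, cv, centers = c(0.25, 0.75), k2 = 10,
                         spacing = 0.5)
  expect_equal(vapply(wins, function(w) w$init_coords[1, 1], 0), c(0.25, 0.75))
  expect_equal(vapply(wins, `[[`, 0, "snapshot_time"), c(25, 75))

  # a frame exactly at the center is selected
  w2 <- select_windows(tr, cv, centers = 0.5, k2 = 10)[[1]]
  expect_equal(w2$init_coords[1, 1], 0.5)

  # coverage warning when no frame is close to a center
  expect_warning(select_windows(tr, cv, centers = 5, k2 = 10, spacing = 0.1),
                 "away")
})

test_that("umbrella bias applies the minimum-image convention and radian units", {
  cv <- cv_dihedral(1:4)
  # value = center: zero energy and force
  b <- umbrella_bias(cv, center = -180, k2 = 33)
  bt <- build_butane()
  r0 <- bias_energy(b, bt$frame)
  expect_lt(r0$energy, 1e-10)
  expect_lt(max(abs(r0$forces)), 1e-6)

  # window at 170, value -170: wraps to 20 degrees, not 340
  b2 <- umbrella_bias(cv, center = 170, k2 = 33)
  f <- md_frame(butane_geometry(-170))
  expect_equal(bias_energy(b2, f)$energy,
               0.5 * 33 * (20 * pi / 180)^2, tolerance = 1e-6)

  # k2 = 33 kcal/(mol rad^2) at 0.1 rad: 0.165 kcal/mol
  b3 <- umbrella_bias(cv, center = 0, k2 = 33)
  f3 <- md_frame(butane_geometry(0.1 * 180 / pi))
  expect_equal(bias_energy(b3, f3)$energy, 0.165, tolerance = 1e-6)

  expect_error(umbrella_bias(cv, 0, k2 = 0), "k2")
})

test_that("umbrella bias energy is continuous across the periodic boundary", {
  cv <- cv_dihedral(1:4)
  b <- umbrella_bias(cv, center = 175, k2 = 33)
  e1 <- bias_energy(b, md_frame(butane_geometry(179.999)))$energy
  e2 <- bias_energy(b, md_frame(butane_geometry(-179.999)))$energy
  expect_lt(abs(e1 - e2), 1e-3)
})

test_that("a stiff restraint pins the sampled series", {
  toy <- build_toy_1d()
  w <- umbrella_window(40, 1e4, toy$cv, data.frame(time = 0, value = 0))
  w$init_coords <- matrix(c(40, 0, 0), 1, 3)
  w <- run_window(toy$system, w, md_params(n_steps = 5e4, cv_stride = 50,
                                           record_interval = 1e5, seed = 3))
  expect_lt(sd(w$series$value), 1)
  expect_lt(abs(mean(w$series$value) - 40), 1)
})

test_that("a harmonic system under a harmonic bias has the closed-form variance", {
  # toy U = k x^2 (spring 2k); bias 1/2 k2 (x - c)^2 on a linear coordinate
  toy <- build_toy_1d(potential = list(kind = "harmonic", k = 1, x0 = 0),
                      mass = 1)
  w <- umbrella_window(0.5, 4, toy$cv, data.frame(time = 0, value = 0))
  w$init_coords <- matrix(c(0.5, 0, 0), 1, 3)
  w <- run_window(toy$system, w,
                  md_params(n_steps = 2e6, cv_stride = 50,
                            record_interval = 1e7, seed = 8))
  ktot <- 2 * 1 + 4
  expect_equal(var(w$series$value), 0.0019872041 * 300 / ktot, tolerance = 0.1)
})

test_that("force-constant selection rejects restraints too weak to center", {
  # a steep cosine landscape: a weak bias at an off-minimum center drifts
  toy <- build_toy_1d(potential = list(kind = "cosine", A = 3, n = 3))
  p <- md_params(n_steps = 1e5, cv_stride = 50, record_interval = 1e6, seed = 21)
  res <- choose_k2(toy$system, toy$cv, test_centers = c(30, 90),
                   candidate_k2s = c(1, 500), md_params = p,
                   init_frames = list(md_frame(matrix(c(30, 0, 0), 1, 3)),
                                      md_frame(matrix(c(90, 0, 0), 1, 3))),
                   mean_tol = 10)
  expect_equal(res$k2, 500)
  rep1 <- res$report[res$report$k2 == 1 & res$report$center == 30, ]
  expect_gt(abs(rep1$mean_shift), 10)

  # flat landscape: any positive restraint passes, the smallest is returned
  flat <- build_toy_1d(potential = list(kind = "cosine", A = 0, n = 3))
  res2 <- choose_k2(flat$system, flat$cv, test_centers = 50,
                    candidate_k2s = c(10, 100), md_params = p,
                    init_frames = md_frame(matrix(c(50, 0, 0), 1, 3)),
                    mean_tol = 10)
  expect_equal(res2$k2, 10)
})

test_that("histogram diagnostics flag shifts and gaps but pass healthy designs", {
  cv <- cv_coordinate(1, 1)
  centers <- seq(0, 10, by = 1)
  set.seed(14)
  mkwin <- function(c0, shift = 0, sd = 0.45) {
    umbrella_window(c0, 5, cv,
                    data.frame(time = 1:4000,
                               value = rnorm(4000, c0 + shift, sd)))
  }
  healthy <- lapply(centers, mkwin)
  d <- diagnose_histograms(healthy, bin_width = 0.25)
  expect_false(any(d$rough))
  expect_false(any(d$shifted))
  expect_false(d$gap)
  expect_true(all(d$neighbor_overlap > 0.1))

  # remove an interior window from a tight design: bare patch
  tight <- lapply(centers, mkwin, sd = 0.2)
  expect_false(diagnose_histograms(tight, bin_width = 0.25)$gap)
  d2 <- diagnose_histograms(tight[-6], bin_width = 0.25)
  expect_true(d2$gap)

  # shift one series by a full window spacing
  shifted <- healthy; shifted[[3]] <- mkwin(centers[3], shift = 1)
  d3 <- diagnose_histograms(shifted, bin_width = 0.25)
  expect_true(d3$shifted[3])

  expect_error(diagnose_histograms(list(umbrella_window(0, 1, cv,
    data.frame(time = numeric(0), value = numeric(0))))), "series")
})
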