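test_that("cross-correlation resolves parallel and anti-phase motion", {
  # atoms 1 and 2 translate identically, atom 3 moves in exact anti-phase,
  # atom 4 wanders independently
  set.seed(10)
  nt <- 400
  s <- sin(seq(0, 12 * pi, length.out = nt))
  w4 <- matrix(rnorm(nt * 3, sd = 0.3), nt, 3)
  coords <- lapply(seq_len(nt), function(t) {
    rbind(c(0, 0, 0) + c(s[t], 0, 0),
          c(4, 0, 0) + c(s[t], 0, 0),
          c(0, 4, 0) + c(-s[t], 0, 0),
          c(4, 4, 0) + w4[t, ])
  })
  tr <- synthetic_trajectory(coords)
  cm <- cross_correlation(tr, 1:4, fit = FALSE)
  C <- cm$matrix
  expect_equal(C[1, 2], 1, tolerance = 1e-10)
  expect_equal(C[1, 3], -1, tolerance = 1e-10)
  # invariants: symmetry, unit diagonal, bounds
  expect_equal(C, t(C))
  expect_equal(diag(C), rep(1, 4))
  expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
})

test_that("a zero-variance atom is flagged, not NaN-propagated", {
  nt <- 50
  set.seed(3)
  coords <- lapply(seq_len(nt), function(t)
    rbind(c(0, 0, 0),                              # frozen atom
          c(4, 0, 0) + rnorm(3, sd = 0.2),
          c(0, 4, 0) + rnorm(3, sd = 0.2)))
  cm <- cross_correlation(synthetic_trajectory(coords), 1:3, fit = FALSE)
  expect_true(cm$undefined[1])
  expect_true(all(is.na(cm$matrix[1, ])))
  expect_false(anyNA(cm$matrix[2:3, 2:3]))
})

test_that("independently fluctuating atoms decorrelate", {
  # 10,000 frames of independent stationary jitter around fixed sites: the
  # off-diagonal correlations shrink like 1/sqrt(n)
  set.seed(21)
  nt <- 10000
  pos0 <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 0))
  coords <- lapply(seq_len(nt), function(t)
    pos0 + matrix(rnorm(12, sd = 0.4), 4, 3))
  cm <- cross_correlation(synthetic_trajectory(coords), 1:4, fit = FALSE)
  off <- cm$matrix[upper.tri(cm$matrix)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("hydrogen-bond occupancy counts geometric criteria per frame", {
  # donor N(1) - H(2) ... acceptor O(3); bond formed iff O is close & aligned
  near <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))   # d(N-O)=2.9, angle 180
  far <- rbind(c(0, 0, 0), c(1, 0, 0), c(6, 0, 0))      # too far
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2.8, 0))   # angle 90 < 120
  triples <- data.frame(donor = 1, hydrogen = 2, acceptor = 3)

  t100 <- synthetic_trajectory(rep(list(near), 8))
  expect_equal(hbond_occupancy(t100, triples)$occupancy, 100)
  t0 <- synthetic_trajectory(rep(list(far), 8))
  expect_equal(hbond_occupancy(t0, triples)$occupancy, 0)
  tbent <- synthetic_trajectory(rep(list(bent), 8))
  expect_equal(hbond_occupancy(tbent, triples)$occupancy, 0)
  t50 <- synthetic_trajectory(c(rep(list(near), 4), rep(list(far), 4)))
  expect_equal(hbond_occupancy(t50, triples)$occupancy, 50)

  # occupancy is invariant under frame reordering
  t50b <- synthetic_trajectory(c(rep(list(far), 2), rep(list(near), 4),
                                 rep(list(far), 2)))
  expect_equal(hbond_occupancy(t50b, triples)$occupancy, 50)
})

test_that("relative helix occupancies are shares of the summed occupancies", {
  tab <- data.frame(occupancy = c(10, 10, 15, 15, 25, 25),
                    helix = c("a1", "a1", "a2", "a2", "a3", "a3"))
  out <- relative_helix_occupancy(tab)
  expect_equal(unname(out[c("a1", "a2", "a3")]), c(20, 30, 50))
  expect_equal(sum(out), 100)
  one <- relative_helix_occupancy(data.frame(occupancy = c(50, 30),
                                             helix = c("a1", "a1")))
  expect_equal(unname(one), 100)
  expect_error(relative_helix_occupancy(data.frame(occupancy = c(0, 0),
                                                   helix = c("a", "b"))),
               "zero")
  expect_error(relative_helix_occupancy(tab, helix = c("a", NA, "a", "a", "a", "a")),
               "exactly one")
})

test_that("interhelical angles recover constructed geometries", {
  hA <- helix_points(axis = c(0, 0, 1))
  hB0 <- helix_points(axis = c(0, 0, 1), origin = c(12, 0, 0))
  hB90 <- helix_points(axis = c(1, 0, 0), origin = c(12, 0, 6))
  frame0 <- md_frame(rbind(hA, hB0))
  frame90 <- md_frame(rbind(hA, hB90))
  n <- nrow(hA)
  expect_lt(interhelical_angle(frame0, 1:n, n + (1:n)), 2)
  expect_equal(interhelical_angle(frame90, 1:n, n + (1:n)), 90, tolerance = 2)

  # antiparallel axes give 180 minus, i.e. a directed angle
  hBrev <- hB0[n:1, ]
  expect_gt(interhelical_angle(md_frame(rbind(hA, hBrev)), 1:n, n + (1:n)), 178)

  # collinear points: the principal axis is the line direction exactly
  lineA <- cbind(seq(0, 5, length.out = 6), 0, 0)
  u <- c(1, 2, 2) / 3
  lineB <- sweep(outer(seq(0, 5, length.out = 6), u), 2, c(0, 8, 0), `+`)
  ang <- interhelical_angle(md_frame(rbind(lineA, lineB)), 1:6, 7:12)
  expect_equal(ang, acos(u[1]) * 180 / pi, tolerance = 1e-6)

  # rigid rotation of the whole frame leaves the angle unchanged
  R <- rotation_matrix(0.4, 1.2, -0.8)
  rot <- md_frame(frame90$coords %*% t(R))
  expect_equal(interhelical_angle(rot, 1:n, n + (1:n)),
               interhelical_angle(frame90, 1:n, n + (1:n)), tolerance = 1e-6)

  # isotropic cloud: no dominant axis
  set.seed(2)
  cloud <- matrix(rnorm(300), 100, 3)
  expect_error(interhelical_angle(md_frame(rbind(cloud, hB0)),
                                  1:100, 100 + (1:n)), "degenerate")
})

test_that("rg and mass-center series match brute-force recomputation", {
  bt <- build_butane()
  set.seed(6)
  coords <- lapply(1:10, function(i) butane_geometry(-180 + 10 * i) +
                                      matrix(rnorm(12, sd = 0.02), 4, 3))
  tr <- synthetic_trajectory(coords, system = bt$system)
  m <- bt$system$atoms$mass

  rg <- rg_series(tr, 1:4)
  brute_rg <- vapply(coords, function(x) {
    xc <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(x, 2, xc)^2)) / sum(m))
  }, 0)
  expect_equal(rg$value, brute_rg, tolerance = 1e-12)

  cd <- com_distance_series(tr, 1:2, 3:4)
  brute_cd <- vapply(coords, function(x) {
    a <- colSums(x[1:2, ] * m[1:2]) / sum(m[1:2])
    b <- colSums(x[3:4, ] * m[3:4]) / sum(m[3:4])
    sqrt(sum((a - b)^2))
  }, 0)
  expect_equal(cd$value, brute_cd, tolerance = 1e-12)
  

  # rigid trajectory: constant series; linear separation: linear series
  rigid <- synthetic_trajectory(rep(list(butane_geometry(-60)), 5),
                                system = bt$system)
  expect_equal(diff(range(rg_series(rigid, 1:4)$value)), 0)
  sep <- lapply(0:5, function(i) rbind(c(0, 0, 0), c(0, 0, 1),
                                       c(3 + i, 0, 0), c(3 + i, 0, 1)))
  trs <- synthetic_trajectory(sep, system = bt$system)
  d <- com_distance_series(trs, 1:2, 3:4, masses = rep(1, 4))$value
  expect_equal(diff(d), rep(1, 5), tolerance = 1e-12)
})
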