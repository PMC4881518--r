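test_that("forces are the negative gradient of the energy for every term type", {
  # butane exercises bonds, angles and torsions; a charged LJ variant
  # exercises the nonbonded terms; the toy exercises external terms
  db <- distorted_butane()
  cases <- list(list(sys = db$system, x = db$frame$coords))

  charged <- build_butane(-100)$system
  charged$atoms$charge <- c(0.1, -0.1, 0.1, -0.1)
  charged$atoms$eps <- 0.1
  cases <- c(cases, list(list(sys = charged, x = db$frame$coords)))

  toy <- build_toy_1d()
  cases <- c(cases, list(list(sys = toy$system,
                              x = matrix(c(47.3, 0.4, -0.2), 1, 3))))

  for (cs in cases) {
    ef <- compute_energy_forces(cs$sys, md_frame(cs$x))
    fd <- fd_gradient(function(x) compute_energy_forces(cs$sys, md_frame(x))$energy,
                      cs$x)
    expect_lt(max(abs(-fd - ef$forces)), 1e-4)
  }
})

test_that("energy is invariant under global rotation and translation", {
  db <- distorted_butane()
  e0 <- compute_energy_forces(db$system, db$frame)$energy
  R <- rotation_matrix(0.3, -1.1, 2.2)
  x2 <- sweep(db$frame$coords %*% t(R), 2, c(5, -3, 11), `+`)
  e1 <- compute_energy_forces(db$system, md_frame(x2))$energy
  expect_lt(abs(e1 - e0), 1e-8)
})

test_that("harmonic terms vanish at their minima and the anti torsion term is zero", {
  # single bond exactly at r0
  sys <- molecular_system(
    data.frame(element = "C", mass = c(12, 12), charge = 0, eps = 0, sigma = 3)[c(1, 1), ],
    bonds = data.frame(i = 1, j = 2, kb = 310, r0 = 1.526))
  ef <- compute_energy_forces(sys, md_frame(rbind(c(0, 0, 0), c(1.526, 0, 0))))
  expect_equal(ef$energy, 0)
  expect_equal(max(abs(ef$forces)), 0)

  # V/2 [1 + cos(3 phi)] at phi = 180: cos(540 deg) = -1
  bt <- build_butane(-180, torsion_v2 = c(0, 0, 1.5))
  terms <- compute_energy_forces(bt$system, bt$frame)$terms
  expect_equal(unname(terms["torsion"]), 0, tolerance = 1e-12)
})

test_that("exclusions remove 1-2/1-3 pairs and scale 1-4 pairs exactly once", {
  sys <- build_butane()$system
  sys$atoms$charge <- c(0.2, -0.2, -0.2, 0.2)
  sys$atoms$eps <- 0.15
  x <- build_butane()$frame$coords
  enb <- compute_energy_forces(sys, md_frame(x))$terms[["nonbonded"]]
  # only the single 1-4 pair (atoms 1-4) survives, once, with scaling
  r14 <- sqrt(sum((x[1, ] - x[4, ])^2))
  eps14 <- 0.5 * 0.15            # lj scale 1/2, equal eps
  sig14 <- 3.9
  elj <- 4 * eps14 * ((sig14 / r14)^12 - (sig14 / r14)^6)
  ecoul <- (1 / 1.2) * 332.0637 * 0.2 * 0.2 / r14
  expect_equal(enb, elj + ecoul, tolerance = 1e-10)
})

test_that("butane fixture has the documented topology and anti start geometry", {
  bt <- build_butane()
  expect_equal(nrow(bt$system$bonds), 3)
  expect_equal(nrow(bt$system$angles), 2)
  expect_gte(nrow(bt$system$torsions), 1)
  phi <- cv_value(cv_dihedral(1:4), bt$frame)
  expect_lt(min(abs(phi - 180), abs(phi + 180)), 1)
  # energy minimization from the fixture start converges
  m <- minimize(bt$system, bt$frame, tol = 1e-3)
  expect_lt(attr(m, "max_force"), 1e-3)
})

test_that("butane torsional profile has the designed stationary values", {
  # the fixture's defining property: gauche ~0.9, syn 5.5, tops ~3.78 rel anti
  bt <- build_butane()
  tors <- function(phi) {
    f <- md_frame(butane_geometry(phi))
    compute_energy_forces(bt$system, f)$terms[["torsion"]]
  }
  rel <- function(phi) tors(phi) - tors(180)
  expect_equal(rel(0), 5.5, tolerance = 1e-3)
  g <- seq(30, 110, by = 0.25)
  vals <- vapply(g, rel, 0)
  expect_equal(min(vals), 0.9, tolerance = 1e-3)
  expect_equal(g[which.min(vals)], 64.25, tolerance = 1)
  g2 <- seq(90, 170, by = 0.25)
  vals2 <- vapply(g2, rel, 0)
  expect_equal(max(vals2), 3.78, tolerance = 1e-3)
})

test_that("toy system matches its analytic potential", {
  # A = 0: flat, zero force everywhere
  toy0 <- build_toy_1d(potential = list(kind = "cosine", A = 0, n = 3))
  ef <- compute_energy_forces(toy0$system, md_frame(matrix(c(33, 0, 0), 1, 3)))
  expect_equal(ef$forces[1, 1], 0)

  # A = 2, n = 3: minima at 60, 180, -60 (modulo 360); force vanishes there
  toy <- build_toy_1d()
  for (x0 in c(60, 180, -60)) {
    ef <- compute_energy_forces(toy$system, md_frame(matrix(c(x0, 0, 0), 1, 3)))
    expect_lt(abs(ef$forces[1, 1]), 1e-10)
    ef2 <- compute_energy_forces(toy$system, md_frame(matrix(c(x0 + 5, 0, 0), 1, 3)))
    expect_gt(ef2$terms[["external"]], ef$terms[["external"]])
  }
  expect_error(build_toy_1d(potential = list(kind = "cosine", A = NaN, n = 3)),
               "finite")
})

test_that("long unbiased Langevin sampling reproduces the Boltzmann distribution", {
  # a 1 kcal/mol barrier keeps well exchange fast (~ps), so the three-well
  # populations converge within the run; samples thinned to ~2 ps spacing
  toy <- build_toy_1d(potential = list(kind = "cosine", A = 0.5, n = 3))
  p <- md_params(n_steps = 5e6, record_interval = 5e6, cv_stride = 2000,
                 seed = 77)
  tr <- run_md(toy$system, toy$frame, p, report_cvs = toy$cv)
  v <- tr$cv_series[[1]]$value
  v <- ((v + 180) %% 360) - 180
  breaks <- seq(-180, 180, by = 15)
  obs <- as.numeric(table(cut(v, breaks)))
  mids <- head(breaks, -1) + 7.5
  U <- 0.5 * (1 + cos(3 * mids * pi / 180))
  pexp <- exp(-U / (0.0019872041 * 300)); pexp <- pexp / sum(pexp)
  ct <- suppressWarnings(chisq.test(obs, p = pexp))
  expect_gt(ct$p.value, 0.01)
})

test_that("structural validation rejects malformed systems and frames", {
  bt <- build_butane()
  expect_error(compute_energy_forces(bt$system, md_frame(matrix(0, 3, 3))),
               "3 atoms")
  bad <- bt$frame$coords; bad[2, ] <- bad[1, ]
  expect_error(compute_energy_forces(bt$system, md_frame(bad)), "zero-length")
  atoms <- bt$system$atoms
  expect_error(molecular_system(atoms, torsions = data.frame(
    i = 1, j = 2, k = 3, l = 4, v2 = 1, n = 0.5, gamma = 0)), "periodicities")
  expect_error(molecular_system(atoms, bonds = data.frame(i = 1, j = 9,
                                                          kb = 1, r0 = 1)),
               "out of range")
})
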