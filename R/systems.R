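# Molecular topologies, the minimal force field, and the built-in fixtures
# (united-atom butane and the analytic 1-D toy system).

#' Construct a molecular system
#'
#' A `molecular_system` bundles the per-atom properties and the bonded /
#' nonbonded interaction terms of a minimal class-I molecular-mechanics force
#' field:
#' \deqn{E = \sum_b k_b (r-r_0)^2 + \sum_a k_a(\theta-\theta_0)^2 +
#'       \sum_t \tfrac{V_n}{2}[1+\cos(n\phi-\gamma)] + E_{LJ} + E_{coul} + E_{ext}}
#' Nonbonded interactions exclude 1-2 and 1-3 pairs; 1-4 pairs are scaled by
#' `scale14`. External one-body terms carry the analytic toy potentials.
#'
#' @param atoms data.frame with columns `element`, `mass` (amu), `charge` (e),
#'   `eps` (kcal/mol), `sigma` (Angstrom).
#' @param bonds data.frame `i, j, kb, r0` with `E = kb (r - r0)^2`,
#'   `kb` in kcal/(mol A^2), `r0` in Angstrom. Indices are 1-based.
#' @param angles data.frame `i, j, k, ka, theta0` with `E = ka (theta - theta0)^2`,
#'   `ka` in kcal/(mol rad^2), `theta0` in degrees.
#' @param torsions data.frame `i, j, k, l, v2, n, gamma`: each row one Fourier
#'   term `(V_n/2)[1 + cos(n phi - gamma)]` with `v2 = V_n/2` in kcal/mol,
#'   integer periodicity `n`, phase `gamma` in degrees. Multiple rows per
#'   quadruple are allowed.
#' @param scale14 length-2 numeric `c(lj, elec)` scale factors applied once to
#'   1-4 nonbonded pairs (AMBER-style defaults `1/2` and `1/1.2`).
#' @param external optional data.frame `atom, axis, kind, p1, p2, p3, p4` of
#'   one-body terms: `kind = "cosine"` gives `p1 * (1 + cos(p2 * w q - p3))`
#'   with `w = 2 pi / p4` (`p3` in degrees), `kind = "harmonic"` gives
#'   `p1 * (q - p2)^2`, acting on coordinate `axis` (1 = x, 2 = y, 3 = z).
#' @param name optional system name.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, bonds = NULL, angles = NULL, torsions = NULL,
                             scale14 = c(lj = 0.5, elec = 1 / 1.2),
                             external = NULL, name = "system") {
  stopifnot(is.data.frame(atoms), all(c("mass", "charge", "eps", "sigma") %in% names(atoms)))
  n <- nrow(atoms)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive and finite")
  empty <- function(cols) as.data.frame(matrix(numeric(0), 0, length(cols),
                                               dimnames = list(NULL, cols)))
  bonds <- bonds %||% empty(c("i", "j", "kb", "r0"))
  angles <- angles %||% empty(c("i", "j", "k", "ka", "theta0"))
  torsions <- torsions %||% empty(c("i", "j", "k", "l", "v2", "n", "gamma"))
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
           torsions$i, torsions$j, torsions$k, torsions$l)
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    stop("bonded-term atom index out of range")
  if (nrow(torsions) && any(torsions$n < 1 | torsions$n != round(torsions$n)))
    stop("torsion periodicities must be positive integers")
  if (!is.null(external)) {
    stopifnot(all(external$atom >= 1 & external$atom <= n),
              all(external$axis %in% 1:3),
              all(external$kind %in% c("cosine", "harmonic")))
    if (any(!is.finite(as.matrix(external[paste0("p", 1:4)]))))
      stop("non-finite external potential parameters")
  }
  sys <- structure(list(atoms = atoms, bonds = bonds, angles = angles,
                        torsions = torsions, scale14 = scale14,
                        external = external, name = name),
                   class = "molecular_system")
  sys$exclusions <- .build_exclusions(sys)
  sys
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system '%s'>: %d atoms, %d bonds, %d angles, %d torsion terms\n",
              x$name, nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$torsions)))
  invisible(x)
}

# symmetric exclusion structure: 1-2/1-3 excluded, 1-4 scaled
.build_exclusions <- function(sys) {
  n <- nrow(sys$atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds$i[r]; j <- sys$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  # graph distances up to 3 bonds
  pairs12 <- pairs13 <- pairs14 <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) {
    d1 <- unique(adj[[i]])
    d2 <- setdiff(unique(unlist(adj[d1])), c(i, d1))
    d3 <- setdiff(unique(unlist(adj[d2])), c(i, d1, d2))
    add <- function(js) cbind(rep(i, sum(js > i)), js[js > i])
    pairs12 <- rbind(pairs12, add(d1))
    pairs13 <- rbind(pairs13, add(d2))
    pairs14 <- rbind(pairs14, add(d3))
  }
  list(excluded = rbind(pairs12, pairs13), scaled = pairs14)
}

# flatten a molecular_system into the list layout the compiled engine parses
.sys_clist <- function(sys) {
  n <- nrow(sys$atoms)
  emptyi <- matrix(numeric(0), 0, 2)
  b <- if (nrow(sys$bonds)) list(idx = cbind(sys$bonds$i, sys$bonds$j),
                                 par = cbind(sys$bonds$kb, sys$bonds$r0))
       else list(idx = emptyi, par = emptyi)
  a <- if (nrow(sys$angles)) list(idx = cbind(sys$angles$i, sys$angles$j, sys$angles$k),
                                  par = cbind(sys$angles$ka, sys$angles$theta0 * pi / 180))
       else list(idx = matrix(numeric(0), 0, 3), par = emptyi)
  t <- if (nrow(sys$torsions)) list(idx = as.matrix(sys$torsions[c("i", "j", "k", "l")]),
                                    par = cbind(sys$torsions$v2, sys$torsions$n,
                                                sys$torsions$gamma * pi / 180))
       else list(idx = matrix(numeric(0), 0, 4), par = matrix(numeric(0), 0, 3))
  # nonbonded pair list with exclusions applied and 1-4 scaling folded in
  keyof <- function(m) if (nrow(m)) m[, 1] * (n + 1) + m[, 2] else numeric(0)
  excl <- keyof(sys$exclusions$excluded)
  scal <- keyof(sys$exclusions$scaled)
  all_pairs <- if (n >= 2) t(utils::combn(n, 2)) else matrix(numeric(0), 0, 2)
  keys <- keyof(all_pairs)
  keep <- !(keys %in% excl)
  pairs <- all_pairs[keep, , drop = FALSE]
  slj <- sel <- rep(1, nrow(pairs))
  is14 <- keyof(pairs) %in% scal
  slj[is14] <- sys$scale14[[1]]; sel[is14] <- sys$scale14[[2]]
  at <- sys$atoms
  nbpar <- if (nrow(pairs))
    cbind(slj * sqrt(at$eps[pairs[, 1]] * at$eps[pairs[, 2]]),
          (at$sigma[pairs[, 1]] + at$sigma[pairs[, 2]]) / 2,
          sel * at$charge[pairs[, 1]] * at$charge[pairs[, 2]])
  else matrix(numeric(0), 0, 3)
  # drop pairs with neither LJ nor charge
  if (nrow(pairs)) {
    live <- nbpar[, 1] > 0 | nbpar[, 3] != 0
    pairs <- pairs[live, , drop = FALSE]; nbpar <- nbpar[live, , drop = FALSE]
  }
  ex <- sys$external
  exl <- if (!is.null(ex) && nrow(ex))
    list(idx = cbind(ex$atom, ex$axis, match(ex$kind, c("cosine", "harmonic"))),
         par = cbind(ex$p1, ex$p2, ifelse(ex$kind == "cosine", ex$p3 * pi / 180, ex$p3), ex$p4))
  else list(idx = matrix(numeric(0), 0, 3), par = matrix(numeric(0), 0, 4))
  list(mass = at$mass, charge = at$charge,
       bonds = b, angles = a, torsions = t,
       nb = list(idx = pairs, par = nbpar), external = exl)
}

#' Create a coordinate frame
#'
#' @param coords n x 3 numeric matrix of Cartesian coordinates in Angstrom.
#' @param time time stamp in ps.
#' @param velocities optional n x 3 matrix in Angstrom/ps.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(coords, time = 0, velocities = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  structure(list(coords = coords, time = time, velocities = velocities),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame>: %d atoms at t = %g ps\n", nrow(x$coords), x$time))
  invisible(x)
}

.check_frame <- function(sys, frame) {
  if (nrow(frame$coords) != nrow(sys$atoms))
    stop(sprintf("frame has %d atoms but system has %d",
                 nrow(frame$coords), nrow(sys$atoms)))
  invisible(TRUE)
}

#' Potential energy and forces of a frame
#'
#' Evaluates the force-field energy and its negative gradient.
#'
#' @param system a [molecular_system()].
#' @param frame an [md_frame()] matching the system.
#' @return list with `energy` (kcal/mol), `forces` (n x 3, kcal/(mol A)) and a
#'   named `terms` breakdown (bond, angle, torsion, nonbonded, external).
#' @export
compute_energy_forces <- function(system, frame) {
  .check_frame(system, frame)
  .ff_energy_forces(.sys_clist(system), frame$coords)
}

# ---------------------------------------------------------------------------
# Fixtures
# ---------------------------------------------------------------------------

# Torsion Fourier coefficients V_n/2 (n = 1, 2, 3) chosen so the vacuum
# united-atom torsional profile has the syn barrier at 5.50 kcal/mol, the
# gauche minima at 0.90 kcal/mol and the intermediate tops at 3.78 kcal/mol
# relative to anti (minima fall near +-64 deg, tops near +-119 deg).
.butane_torsion_v2 <- c(0.889150, 0.259672, 1.860850)

#' Ideal united-atom butane coordinates at a given torsion angle
#'
#' Places the four carbon sites with bond length 1.526 A and bond angle
#' 112.4 deg; the C-C-C-C torsion equals `phi` (IUPAC sign convention).
#'
#' @param phi torsion angle in degrees.
#' @param r C-C bond length (Angstrom).
#' @param theta C-C-C angle (degrees).
#' @return 4 x 3 coordinate matrix.
#' @export
butane_geometry <- function(phi, r = 1.526, theta = 112.4) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  C2 <- c(0, 0, 0)
  C3 <- c(r, 0, 0)
  C1 <- c(r * cos(th), r * sin(th), 0)
  C4 <- C3 + r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  m <- rbind(C1, C2, C3, C4)
  dimnames(m) <- NULL
  m
}

#' Built-in united-atom butane fixture
#'
#' Four united-atom carbon sites (CH3-CH2-CH2-CH3) with harmonic bonds
#' (`kb` = 310 kcal/(mol A^2), `r0` = 1.526 A), harmonic angles (`ka` = 63
#' kcal/(mol rad^2), `theta0` = 112.4 deg) and a three-term torsion Fourier
#' series on the C-C-C-C dihedral whose vacuum profile has gauche minima at
#' 0.90 and the syn barrier at 5.50 kcal/mol relative to anti. The sites are
#' net-neutral with no Lennard-Jones interactions, so the torsional potential
#' of mean force is carried entirely by the torsion series.
#'
#' @param phi initial torsion angle in degrees (default anti, -180).
#' @param kb,r0,ka,theta0,torsion_v2 force-field overrides.
#' @return list with elements `system` ([molecular_system()]) and `frame`
#'   ([md_frame()]) in the requested conformation.
#' @export
build_butane <- function(phi = -180, kb = 310, r0 = 1.526, ka = 63,
                         theta0 = 112.4, torsion_v2 = .butane_torsion_v2) {
  atoms <- data.frame(element = c("C", "C", "C", "C"),
                      mass = c(15.035, 14.027, 14.027, 15.035),
                      charge = 0, eps = 0, sigma = 3.9)
  bonds <- data.frame(i = 1:3, j = 2:4, kb = kb, r0 = r0)
  angles <- data.frame(i = 1:2, j = 2:3, k = 3:4, ka = ka, theta0 = theta0)
  torsions <- data.frame(i = 1, j = 2, k = 3, l = 4,
                         v2 = torsion_v2, n = seq_along(torsion_v2), gamma = 0)
  sys <- molecular_system(atoms, bonds, angles, torsions, name = "butane")
  list(system = sys, frame = md_frame(butane_geometry(phi, r0, theta0)))
}

#' Analytic one-dimensional toy system
#'
#' A single particle whose x coordinate is the reaction coordinate; the only
#' energy terms are the requested 1-D potential on x plus a stiff harmonic
#' confinement of y and z. With `kind = "cosine"` the potential is
#' `U(x) = A [1 + cos(n w x - phase)]` with `w = 2 pi / period`, so for the
#' default `period = 360` the coordinate is read directly in degrees; with
#' `kind = "harmonic"` it is `U(x) = k (x - x0)^2`.
#'
#' @param potential list: for cosine, `list(kind = "cosine", A, n, phase = 0,
#'   period = 360)`; for harmonic, `list(kind = "harmonic", k, x0 = 0)`.
#' @param mass particle mass (amu). The default is light so the coordinate
#'   decorrelates within ~0.2 ps under the default friction, making sub-ns
#'   umbrella windows statistically well converged (the toy exists as a
#'   numerical oracle, not as a physical model).
#' @param confine harmonic constant restraining y and z (kcal/(mol A^2)).
#' @param x0 initial coordinate; defaults to a minimum of the potential.
#' @return list with `system`, `frame`, and `cv` (the coordinate collective
#'   variable, periodic for the cosine potential).
#' @export
build_toy_1d <- function(potential = list(kind = "cosine", A = 2.0, n = 3),
                         mass = 0.05, confine = 1, x0 = NULL) {
  stopifnot(potential$kind %in% c("cosine", "harmonic"))
  atoms <- data.frame(element = "X", mass = mass, charge = 0, eps = 0, sigma = 1)
  if (potential$kind == "cosine") {
    A <- potential$A; nfold <- potential$n
    phase <- potential$phase %||% 0
    period <- potential$period %||% 360
    if (!all(is.finite(c(A, nfold, phase, period))))
      stop("non-finite toy potential parameters")
    ext <- data.frame(atom = 1, axis = 1, kind = "cosine",
                      p1 = A, p2 = nfold, p3 = phase, p4 = period)
    # a minimum of A(1+cos(n w x - phase)): n w x - phase_rad = pi
    x0 <- x0 %||% ((180 + phase) / nfold * (period / 360))
    cv <- cv_coordinate(atom = 1, axis = 1, periodic = TRUE, period = period)
  } else {
    k <- potential$k; xc <- potential$x0 %||% 0
    if (!all(is.finite(c(k, xc)))) stop("non-finite toy potential parameters")
    ext <- data.frame(atom = 1, axis = 1, kind = "harmonic",
                      p1 = k, p2 = xc, p3 = 0, p4 = 0)
    x0 <- x0 %||% xc
    cv <- cv_coordinate(atom = 1, axis = 1, periodic = FALSE)
  }
  ext <- rbind(ext,
               data.frame(atom = 1, axis = 2:3, kind = "harmonic",
                          p1 = confine, p2 = 0, p3 = 0, p4 = 0))
  sys <- molecular_system(atoms, external = ext, name = "toy1d")
  list(system = sys, frame = md_frame(matrix(c(x0, 0, 0), 1, 3)), cv = cv)
}
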