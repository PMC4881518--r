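# shared helpers: finite-difference checks and synthetic trajectory builders

fd_gradient <- function(f, x, h = 1e-5) {
  g <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (d in seq_len(ncol(x))) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    g[i, d] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# a distorted butane frame with a fixed deterministic perturbation
distorted_butane <- function(phi = -100, scale = 0.05) {
  bt <- build_butane(phi)
  set.seed(42)
  list(system = bt$system,
       frame = md_frame(bt$frame$coords + matrix(rnorm(12, sd = scale), 4, 3)))
}

# assemble an md_trajectory directly from a list of coordinate matrices
synthetic_trajectory <- function(coord_list, system = NULL, dt = 1) {
  n <- nrow(coord_list[[1]])
  arr <- array(unlist(coord_list), dim = c(n, 3, length(coord_list)))
  structure(list(system = system, times = (seq_along(coord_list) - 1) * dt,
                 coords = arr, energies = rep(NA_real_, length(coord_list)),
                 cv_series = NULL,
                 final = md_frame(coord_list[[length(coord_list)]]),
                 params = NULL, bias = "none", seed = NA),
            class = "md_trajectory")
}

# ideal helical point set: radius r, rise per point, n points along +axis
helix_points <- function(n = 12, radius = 2.3, rise = 1.5, axis = c(0, 0, 1),
                         origin = c(0, 0, 0)) {
  t <- seq(0, by = 100 * pi / 180, length.out = n)
  local <- cbind(radius * cos(t), radius * sin(t), rise * seq(0, n - 1))
  axis <- axis / sqrt(sum(axis^2))
  # rotation taking +z onto axis
  z <- c(0, 0, 1)
  v <- pracma_cross(z, axis)
  if (sqrt(sum(v^2)) < 1e-12) R <- diag(3) * sign(sum(z * axis))
  else {
    s <- sqrt(sum(v^2)); c0 <- sum(z * axis)
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
  }
  sweep(local %*% t(R), 2, origin, `+`)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

rotation_matrix <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
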