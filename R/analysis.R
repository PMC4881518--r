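# Trajectory-analysis operators: dynamical cross-correlation maps,
# hydrogen-bond occupancies, interhelical angles, and CV time series.

# weighted Kabsch superposition of X onto ref (returns transformed X)
.superpose <- function(X, ref, w = NULL) {
  w <- w %||% rep(1, nrow(X))
  W <- sum(w)
  xc <- colSums(X * w) / W; rc <- colSums(ref * w) / W
  Xc <- sweep(X, 2, xc); Rc <- sweep(ref, 2, rc)
  C <- t(Xc * w) %*% Rc       # maps X-frame onto ref-frame
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(Xc %*% t(R), 2, rc, `+`)
}

#' Dynamical cross-correlation map
#'
#' Normalized covariances of atomic displacement vectors,
#' \deqn{C(i,j) = \langle \Delta r_i \cdot \Delta r_j \rangle /
#'   (\langle \Delta r_i^2 \rangle \langle \Delta r_j^2 \rangle)^{1/2}}
#' where the displacement is the deviation of each selected atom from its
#' time-mean position. By default every frame is first least-squares
#' superposed onto the mean structure to remove rigid-body motion
#' (`fit = FALSE` skips that step).
#'
#' @param trajectory an `md_trajectory` with at least 2 frames.
#' @param selection atom indices (e.g. the C-alpha atoms).
#' @param fit superpose frames onto the mean structure first.
#' @param weights superposition weights (masses; default equal).
#' @return object of class `correlation_map`: `matrix` (values in `[-1, 1]`,
#'   unit diagonal, symmetric), `selection`, and `undefined` flags for atoms
#'   with zero displacement variance (their rows/columns are `NA`).
#' @export
cross_correlation <- function(trajectory, selection, fit = TRUE, weights = NULL) {
  nt <- length(trajectory$times)
  if (nt < 2) stop("need at least 2 frames")
  if (!length(selection)) stop("empty selection")
  X <- lapply(seq_len(nt), function(t)
    matrix(trajectory$coords[selection, , t], ncol = 3))
  if (fit) {
    ref <- X[[1]]
    for (pass in 1:2) {
      Xs <- lapply(X, .superpose, ref = ref, w = weights)
      ref <- Reduce(`+`, Xs) / nt
    }
    X <- Xs
  }
  mean_pos <- Reduce(`+`, X) / nt
  D <- lapply(X, function(x) x - mean_pos)   # displacement vectors
  n <- length(selection)
  cov <- matrix(0, n, n)
  for (t in seq_len(nt)) cov <- cov + D[[t]] %*% t(D[[t]])
  cov <- cov / nt
  v <- diag(cov)
  undef <- v <= .Machine$double.eps * max(v, 1)
  denom <- sqrt(outer(v, v))
  C <- cov / denom
  C[undef, ] <- NA_real_; C[, undef] <- NA_real_
  diag(C)[!undef] <- 1
  C[!undef, !undef] <- pmin(pmax(C[!undef, !undef], -1), 1)
  structure(list(matrix = C, selection = selection, undefined = undef,
                 fitted = fit),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map>: %d atoms%s, range [%.3f, %.3f]\n",
              length(x$selection),
              if (any(x$undefined)) sprintf(" (%d undefined)", sum(x$undefined)) else "",
              min(x$matrix, na.rm = TRUE), max(x$matrix, na.rm = TRUE)))
  invisible(x)
}

#' Hydrogen-bond occupancies over a trajectory
#'
#' A bond counts as formed in a frame when the donor-acceptor heavy-atom
#' distance is at most `dist_cutoff` and the donor-H...acceptor angle is at
#' least `angle_cutoff` (the long-standing PTRAJ-era convention).
#'
#' @param trajectory an `md_trajectory`.
#' @param triples data.frame (or matrix) with columns `donor`, `hydrogen`,
#'   `acceptor` (atom indices); optional `label`, `helix` columns are carried
#'   through.
#' @param dist_cutoff donor-acceptor distance cutoff, Angstrom.
#' @param angle_cutoff D-H...A angle cutoff, degrees.
#' @return object of class `hbond_table`: data.frame with the triples and an
#'   `occupancy` column in percent; the criteria used are attached as
#'   attributes.
#' @export
hbond_occupancy <- function(trajectory, triples, dist_cutoff = 3.5,
                            angle_cutoff = 120) {
  stopifnot(dist_cutoff > 0, angle_cutoff > 0)
  nt <- length(trajectory$times)
  if (nt < 1) stop("empty trajectory")
  triples <- as.data.frame(triples)
  occ <- vapply(seq_len(nrow(triples)), function(r) {
    d <- triples$donor[r]; h <- triples$hydrogen[r]; a <- triples$acceptor[r]
    hits <- 0
    for (t in seq_len(nt)) {
      X <- matrix(trajectory$coords[, , t], ncol = 3)
      da <- sqrt(sum((X[d, ] - X[a, ])^2))
      if (da > dist_cutoff) next
      v1 <- X[d, ] - X[h, ]; v2 <- X[a, ] - X[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= angle_cutoff) hits <- hits + 1
    }
    100 * hits / nt
  }, 0)
  out <- cbind(triples, occupancy = occ)
  attr(out, "criteria") <- c(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff)
  class(out) <- c("hbond_table", "data.frame")
  out
}

#' Relative per-helix hydrogen-bond occupancy
#'
#' Shares of the summed bond occupancies attributed to each helix:
#' `100 * sum(occupancies in helix) / sum(all listed occupancies)`.
#'
#' @param table an [hbond_occupancy()] result (or data.frame with columns
#'   `occupancy` and `helix`).
#' @param helix optional helix assignment vector overriding the table's
#'   `helix` column; every bond must belong to exactly one helix.
#' @return named numeric vector of percentages (sums to 100).
#' @export
relative_helix_occupancy <- function(table, helix = NULL) {
  helix <- helix %||% table$helix
  if (is.null(helix) || length(helix) != nrow(table) || anyNA(helix))
    stop("every bond must be assigned to exactly one helix")
  tot <- sum(table$occupancy)
  if (tot <= 0) stop("all occupancies are zero")
  s <- tapply(table$occupancy, helix, sum)
  out <- 100 * as.numeric(s) / tot
  names(out) <- names(s)
  out
}

#' Interhelical angle from principal axes
#'
#' Angle between the dominant mass-weighted principal axes of two atom sets,
#' with each axis oriented from the first toward the last atom of its set
#' (N- to C-terminal for a helix), so the result is a directed angle in
#' `[0, 180]` degrees.
#'
#' @param frame an [md_frame()].
#' @param helixA,helixB atom index vectors (>= 4 atoms each).
#' @param masses optional per-atom masses for the whole frame.
#' @return angle in degrees.
#' @export
interhelical_angle <- function(frame, helixA, helixB, masses = NULL) {
  x <- if (inherits(frame, "md_frame")) frame$coords else as.matrix(frame)
  masses <- masses %||% rep(1, nrow(x))
  axis_of <- function(sel) {
    if (length(sel) < 4) stop("need at least 4 atoms per helix")
    X <- x[sel, , drop = FALSE]; w <- masses[sel]
    Xc <- sweep(X, 2, colSums(X * w) / sum(w))
    S <- t(Xc * w) %*% Xc
    e <- eigen(S, symmetric = TRUE)
    # require a clearly dominant axis (elongated, helix-like cloud)
    if (e$values[1] < 1e-8 || e$values[1] / max(e$values[2], 1e-300) < 2)
      stop("degenerate atom cloud: principal axis undefined")
    a <- e$vectors[, 1]
    ends <- X[length(sel), ] - X[1, ]
    if (sum(a * ends) < 0) a <- -a
    a
  }
  a <- axis_of(helixA); b <- axis_of(helixB)
  acos(max(-1, min(1, sum(a * b)))) * 180 / pi
}

#' Radius-of-gyration time series
#'
#' @param trajectory an `md_trajectory`.
#' @param selection atom indices.
#' @param masses weights (default: system masses of the selection).
#' @return data.frame `time`, `value` (Angstrom).
#' @export
rg_series <- function(trajectory, selection, masses = NULL) {
  masses <- masses %||% trajectory$system$atoms$mass[selection]
  cv_trace(trajectory, cv_rg(selection, weights = masses))
}

#' Mass-center distance time series
#'
#' @param trajectory an `md_trajectory`.
#' @param groupA,groupB disjoint atom index vectors.
#' @param masses per-atom masses (default: system masses).
#' @return data.frame `time`, `value` (Angstrom).
#' @export
com_distance_series <- function(trajectory, groupA, groupB, masses = NULL) {
  masses <- masses %||% trajectory$system$atoms$mass
  cv_trace(trajectory,
           cv_com_distance(groupA, groupB, masses[groupA], masses[groupB]))
}
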