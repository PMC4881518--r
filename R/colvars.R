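# Collective variables: scalar functions of a frame with analytic per-atom
# gradients, used both as reaction coordinates and as bias targets.

.cv_new <- function(kind_code, kind, sel, unit, periodic, period = NA_real_,
                    ref = NULL, weights = NULL, sel2 = NULL, axis = 1L,
                    label = kind) {
  structure(list(kind = kind_code, kind_name = kind, sel = as.numeric(sel),
                 sel2 = if (is.null(sel2)) NULL else as.numeric(sel2),
                 ref = ref, weights = weights, axis = as.integer(axis),
                 unit = unit, periodic = periodic, period = period,
                 label = label),
            class = "colvar")
}

#' @export
print.colvar <- function(x, ...) {
  cat(sprintf("<colvar %s> %d atom(s), unit %s%s\n", x$kind_name,
              length(x$sel) + length(x$sel2), x$unit,
              if (isTRUE(x$periodic)) sprintf(", periodic (%g)", x$period) else ""))
  invisible(x)
}

#' Dihedral (torsion) angle collective variable
#'
#' Value in degrees, wrapped to `[-180, 180)` with the IUPAC sign convention;
#' periodic with period 360.
#'
#' @param atoms integer vector of the four atom indices (1-based), in chain
#'   order i-j-k-l.
#' @param label optional name.
#' @return A `colvar` object.
#' @export
cv_dihedral <- function(atoms, label = "dihedral") {
  stopifnot(length(atoms) == 4)
  .cv_new(1L, "dihedral", atoms, "deg", TRUE, 360, label = label)
}

#' Mass-weighted RMSD collective variable
#'
#' Root-mean-square deviation of the selected atoms from a reference
#' structure after optimal weighted rigid-body superposition (Kabsch rotation
#' with reflection guard). Weights default to unity; pass atomic masses for a
#' mass-weighted RMSD.
#'
#' @param atoms selection (1-based indices into the frame).
#' @param ref reference coordinates for the selection: an [md_frame()] (from
#'   which `atoms` rows are taken) or a `length(atoms) x 3` matrix.
#' @param weights per-atom weights (e.g. masses); recycled scalar allowed.
#' @param label optional name.
#' @return A `colvar` object (unit Angstrom).
#' @export
cv_rmsd <- function(atoms, ref, weights = 1, label = "rmsd") {
  stopifnot(length(atoms) >= 1)
  refm <- if (inherits(ref, "md_frame")) ref$coords[atoms, , drop = FALSE] else as.matrix(ref)
  if (nrow(refm) != length(atoms))
    stop("rmsd reference must have one row per selected atom")
  w <- rep_len(weights, length(atoms))
  if (sum(w) <= 0) stop("rmsd weights must have positive total")
  .cv_new(2L, "rmsd", atoms, "A", FALSE, ref = refm, weights = w, label = label)
}

#' Radius-of-gyration collective variable
#'
#' Weighted RMS distance of the selected atoms from their weighted centroid.
#'
#' @inheritParams cv_rmsd
#' @return A `colvar` object (unit Angstrom).
#' @export
cv_rg <- function(atoms, weights = 1, label = "rg") {
  stopifnot(length(atoms) >= 1)
  w <- rep_len(weights, length(atoms))
  if (sum(w) <= 0) stop("total weight must be positive")
  .cv_new(3L, "rg", atoms, "A", FALSE, weights = w, label = label)
}

#' Single-coordinate collective variable (toy systems)
#'
#' The raw Cartesian coordinate of one atom along one axis; used as the
#' reaction coordinate of [build_toy_1d()]. For a periodic toy potential the
#' coordinate is treated as an angle in degrees.
#'
#' @param atom atom index.
#' @param axis 1 = x, 2 = y, 3 = z.
#' @param periodic logical; `period` the period when periodic.
#' @param label optional name.
#' @return A `colvar` object.
#' @export
cv_coordinate <- function(atom, axis = 1, periodic = FALSE, period = 360,
                          label = "coord") {
  .cv_new(4L, "coordinate", atom, if (periodic) "deg" else "A",
          periodic, if (periodic) period else NA_real_, axis = axis, label = label)
}

#' Center-of-mass distance collective variable
#'
#' @param groupA,groupB disjoint non-empty index vectors.
#' @param weightsA,weightsB per-atom weights (masses).
#' @param label optional name.
#' @return A `colvar` object (unit Angstrom).
#' @export
cv_com_distance <- function(groupA, groupB, weightsA = 1, weightsB = 1,
                            label = "com_distance") {
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  w <- c(rep_len(weightsA, length(groupA)), rep_len(weightsB, length(groupB)))
  .cv_new(5L, "com_distance", groupA, "A", FALSE, weights = w,
          sel2 = groupB, label = label)
}

# list layout the compiled engine parses
.cv_clist <- function(cv) {
  list(kind = cv$kind, sel = cv$sel, sel2 = cv$sel2, ref = cv$ref,
       weights = cv$weights, axis = cv$axis)
}

#' Evaluate a collective variable
#'
#' @param cv a `colvar`.
#' @param frame an [md_frame()] (or bare coordinate matrix).
#' @return scalar value in the variable's unit (degrees or Angstrom).
#' @export
cv_value <- function(cv, frame) {
  x <- if (inherits(frame, "md_frame")) frame$coords else as.matrix(frame)
  .cv_value(.cv_clist(cv), x)
}

#' Analytic gradient of a collective variable
#'
#' Per-atom derivatives of [cv_value()] with respect to Cartesian coordinates
#' (unit of the variable per Angstrom). The RMSD gradient is evaluated at the
#' optimal superposition; exactly at RMSD = 0 it is undefined and a zero
#' matrix is returned with attribute `degenerate = TRUE` (any harmonic bias
#' force vanishes there anyway).
#'
#' @inheritParams cv_value
#' @return n x 3 matrix.
#' @export
cv_gradient <- function(cv, frame) {
  x <- if (inherits(frame, "md_frame")) frame$coords else as.matrix(frame)
  g <- .cv_gradient(.cv_clist(cv), x)
  if (cv$kind == 2L && all(g == 0))
    attr(g, "degenerate") <- TRUE
  g
}

#' Distance between the mass centers of two atom groups
#'
#' @param frame an [md_frame()].
#' @param groupA,groupB disjoint non-empty 1-based index vectors.
#' @param masses per-atom masses for the whole frame (defaults to equal
#'   weights).
#' @return distance in Angstrom.
#' @export
com_distance <- function(frame, groupA, groupB, masses = NULL) {
  x <- if (inherits(frame, "md_frame")) frame$coords else as.matrix(frame)
  masses <- masses %||% rep(1, nrow(x))
  cv <- cv_com_distance(groupA, groupB, masses[groupA], masses[groupB])
  .cv_value(.cv_clist(cv), x)
}

#' Minimum-image difference between two collective-variable values
#'
#' @param cv a `colvar`.
#' @param a,b values in the variable's unit.
#' @return wrapped difference `a - b` (in `[-period/2, period/2)` when
#'   periodic).
#' @export
cv_wrap_diff <- function(cv, a, b) {
  d <- a - b
  if (isTRUE(cv$periodic)) d <- d - cv$period * round(d / cv$period)
  d
}
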