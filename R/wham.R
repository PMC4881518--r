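# Weighted histogram analysis method (1-D, periodic or linear), PMF profile
# utilities, RMSD-to-dihedral calibration and segment stitching.

#' Construct a PMF profile object
#'
#' @param centers bin centers (deg or Angstrom).
#' @param pmf free energies (kcal/mol); `NA` for unvisited bins.
#' @param periodic logical.
#' @param counts per-bin total sample counts.
#' @param reference `"min_zero"` or `"endpoint_zero"`.
#' @param temperature K.
#' @param iterations,max_dF convergence metadata.
#' @param unit coordinate unit label.
#' @return object of class `pmf_profile`.
#' @export
pmf_profile <- function(centers, pmf, periodic = FALSE, counts = NULL,
                        reference = "min_zero", temperature = NA_real_,
                        iterations = NA_integer_, max_dF = NA_real_,
                        unit = "deg") {
  stopifnot(length(centers) == length(pmf))
  structure(list(centers = centers, pmf = pmf, periodic = periodic,
                 counts = counts %||% rep(NA_real_, length(pmf)),
                 reference = reference, temperature = temperature,
                 iterations = iterations, max_dF = max_dF, unit = unit),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$pmf)
  cat(sprintf("<pmf_profile>: %d/%d defined bins on [%g, %g] %s%s\n",
              sum(ok), length(x$pmf), min(x$centers), max(x$centers), x$unit,
              if (x$periodic) " (periodic)" else ""))
  if (sum(ok))
    cat(sprintf("  range %.3f .. %.3f kcal/mol; reference %s; %s iterations\n",
                min(x$pmf[ok]), max(x$pmf[ok]), x$reference,
                format(x$iterations)))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$centers, x$pmf, type = "l",
                 xlab = sprintf("coordinate (%s)", x$unit),
                 ylab = "PMF (kcal/mol)", ...)
  invisible(x)
}

# re-reference a pmf vector
.reref <- function(pmf, reference, centers = NULL) {
  ok <- is.finite(pmf)
  if (!any(ok)) return(pmf)
  off <- if (reference == "endpoint_zero") pmf[which(ok)[1]] else min(pmf[ok])
  pmf - off
}

#' Evaluate a PMF profile at arbitrary coordinates
#'
#' Linear interpolation between defined bins (with periodic wrap when the
#' profile is periodic).
#'
#' @param profile a [pmf_profile()].
#' @param at coordinates.
#' @return interpolated free energies (kcal/mol).
#' @export
pmf_at <- function(profile, at) {
  ok <- is.finite(profile$pmf)
  xs <- profile$centers[ok]; ys <- profile$pmf[ok]
  if (profile$periodic) {
    per <- 360
    xs <- c(xs[length(xs)] - per, xs, xs[1] + per)
    ys <- c(ys[length(ys)], ys, ys[1])
    lo <- min(profile$centers); hi <- lo + per
    at <- lo + (at - lo) %% per
  }
  stats::approx(xs, ys, xout = at, rule = 2)$y
}

#' Solve the weighted histogram analysis method equations
#'
#' Combines the biased histograms of a set of umbrella windows into one
#' unbiased probability (and free-energy) profile by the standard
#' self-consistent two-equation iteration:
#' \deqn{P(x_b) = \frac{\sum_i n_i(x_b)}{\sum_i N_i \exp[(F_i - V_i(x_b))/kT]},
#'  \qquad F_i = -kT \ln \sum_b P(x_b) \exp[-V_i(x_b)/kT]}
#' iterated until the window free-energy constants change by less than `tol`;
#' the PMF is `-kT ln P` under the chosen reference convention. `V_i` is the
#' window's harmonic bias evaluated at the bin center with minimum-image
#' wrapping for periodic coordinates (and degree-to-radian conversion for
#' angular coordinates, whose `k2` is per rad^2).
#'
#' @param windows list of sampled `umbrella_window`s on a common CV.
#' @param bins number of bins (over `range`) or a vector of bin breaks.
#' @param range coordinate range; defaults to `c(-180, 180)` for periodic
#'   angular CVs, otherwise the sampled data range.
#' @param periodic logical; defaults to the CV's periodicity.
#' @param temperature K.
#' @param tol convergence threshold on `max |dF_i|` (kcal/mol).
#' @param max_iter maximum iterations.
#' @param reference `"min_zero"` (default) or `"endpoint_zero"`.
#' @return a [pmf_profile()]; unvisited bins are `NA`.
#' @export
solve_wham <- function(windows, bins = 180, range = NULL, periodic = NULL,
                       temperature = 300, tol = 1e-6, max_iter = 100000,
                       reference = "min_zero") {
  stopifnot(length(windows) >= 1)
  if (any(vapply(windows, function(w) is.null(w$series) || !nrow(w$series), TRUE)))
    stop("every window needs a non-empty sampled series")
  cv <- windows[[1]]$cv
  periodic <- periodic %||% isTRUE(cv$periodic)
  angular <- identical(cv$unit, "deg")
  period <- if (periodic) (cv$period %||% 360) else NA_real_
  # monotone window ordering by center
  ord <- order(vapply(windows, `[[`, 0, "center"))
  windows <- windows[ord]

  vals <- lapply(windows, function(w) w$series$value)
  if (is.null(range))
    range <- if (periodic && angular) c(-180, 180)
             else range(unlist(vals))
  breaks <- if (length(bins) > 1) bins else seq(range[1], range[2], length.out = bins + 1)
  nb <- length(breaks) - 1
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2

  nw <- length(windows)
  n_ib <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    v <- vals[[i]]
    if (periodic) v <- range[1] + (v - range[1]) %% period
    bi <- findInterval(v, breaks, rightmost.closed = TRUE)
    keep <- bi >= 1 & bi <= nb
    n_ib[i, ] <- tabulate(bi[keep], nbins = nb)
  }
  N_i <- rowSums(n_ib)
  total <- colSums(n_ib)
  if (all(total == 0)) stop("no samples fall inside the binning range")
  # disconnected support check: all visited bins must form one overlap graph
  .check_connected(n_ib)

  kT <- .kB * temperature
  scale <- if (angular) pi / 180 else 1
  V <- matrix(0, nw, nb)  # bias energy of window i at bin b
  for (i in seq_len(nw)) {
    d <- mids - windows[[i]]$center
    if (periodic) d <- d - period * round(d / period)
    V[i, ] <- 0.5 * windows[[i]]$k2 * (d * scale)^2
  }
  expmV <- exp(-V / kT)

  F_i <- rep(0, nw)
  iter <- 0; max_dF <- Inf
  visited <- total > 0
  while (iter < max_iter) {
    iter <- iter + 1
    denom <- colSums((N_i * exp(F_i / kT)) * expmV)
    P <- ifelse(denom > 0, total / denom, 0)
    Fnew <- -kT * log(pmax(expmV %*% P, 1e-300))
    Fnew <- Fnew - Fnew[1]
    max_dF <- max(abs(Fnew - F_i))
    F_i <- as.numeric(Fnew)
    if (max_dF < tol) break
  }
  if (max_dF >= tol) {
    cond <- simpleError(sprintf(
      "WHAM did not converge in %d iterations (max |dF| = %.3g)", max_iter, max_dF))
    cond$F_i <- F_i
    stop(cond)
  }
  denom <- colSums((N_i * exp(F_i / kT)) * expmV)
  P <- ifelse(denom > 0 & visited, total / denom, NA_real_)
  pmf <- -kT * log(P)
  pmf <- .reref(pmf, reference)
  pmf_profile(mids, pmf, periodic = periodic, counts = total,
              reference = reference, temperature = temperature,
              iterations = iter, max_dF = max_dF,
              unit = cv$unit)
}

.check_connected <- function(n_ib) {
  nw <- nrow(n_ib)
  if (nw == 1) return(invisible(TRUE))
  # windows are connected when they share a visited bin
  seen <- rep(FALSE, nw); seen[1] <- TRUE
  repeat {
    grew <- FALSE
    cover <- colSums(n_ib[seen, , drop = FALSE]) > 0
    for (i in which(!seen))
      if (any(n_ib[i, ] > 0 & cover)) { seen[i] <- TRUE; grew <- TRUE }
    if (!grew) break
  }
  if (!all(seen))
    stop("windows with zero histogram overlap: disconnected support")
  invisible(TRUE)
}

#' Stationary points of a PMF profile
#'
#' Locates interior minima and maxima of the (lightly smoothed) profile;
#' endpoints are reported separately. For periodic profiles the smoothing and
#' the extremum search wrap around the boundary.
#'
#' @param profile a [pmf_profile()] with at least 3 defined bins.
#' @param smoothing centered moving-average span in bins (odd; 1 = none).
#' @return list with `extrema` (data.frame `position`, `value`, `kind`) and
#'   `endpoints` (data.frame for the two support endpoints; empty for
#'   periodic profiles).
#' @export
profile_stationary_points <- function(profile, smoothing = 3) {
  ok <- is.finite(profile$pmf)
  if (sum(ok) < 3) stop("need at least 3 defined bins")
  x <- profile$centers[ok]; y <- profile$pmf[ok]
  n <- length(y)
  if (smoothing > 1) {
    k <- rep(1 / smoothing, smoothing)
    y <- as.numeric(stats::filter(y, k, sides = 2, circular = profile$periodic))
    if (!profile$periodic) { # shrink to the valid core, keep raw ends
      raw <- profile$pmf[ok]
      bad <- !is.finite(y)
      y[bad] <- raw[bad]
    }
  }
  kind <- character(0); pos <- val <- numeric(0)
  idx <- if (profile$periodic) seq_len(n) else 2:(n - 1)
  for (i in idx) {
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    if (!profile$periodic && (i == 1 || i == n)) next
    if (y[i] > y[im] && y[i] >= y[ip]) {
      kind <- c(kind, "max"); pos <- c(pos, x[i]); val <- c(val, profile$pmf[ok][i])
    } else if (y[i] < y[im] && y[i] <= y[ip]) {
      kind <- c(kind, "min"); pos <- c(pos, x[i]); val <- c(val, profile$pmf[ok][i])
    }
  }
  extrema <- data.frame(position = pos, value = val, kind = kind)
  endpoints <- if (profile$periodic) data.frame(position = numeric(0),
                                                value = numeric(0), kind = character(0))
  else data.frame(position = x[c(1, n)], value = profile$pmf[ok][c(1, n)],
                  kind = "endpoint")
  list(extrema = extrema, endpoints = endpoints)
}

#' Calibration curve mapping RMSD to dihedral angle
#'
#' Along one TMD section the RMSD to the target and the driven dihedral vary
#' together monotonically, so each RMSD value corresponds to one dihedral
#' value. The calibration bins the per-frame (RMSD, dihedral) pairs of the
#' trajectory, verifies monotonicity, and interpolates piecewise linearly.
#'
#' Because both coordinates are driven nearly linearly in time by the TMD
#' ramp, the pairs are formed from per-time-bin medians, which suppresses the
#' thermal vibration noise of the instantaneous RMSD. Frames whose dihedral
#' lies outside the driven arc (plus `margin`) are excluded first: an RMSD
#' restraint cannot distinguish the two mirror branches of the rotation, so
#' brief excursions onto the wrong branch would otherwise contaminate the
#' map.
#'
#' @param trajectory an `md_trajectory` (a TMD section run).
#' @param rmsd_cv the RMSD `colvar` (to the section target).
#' @param dihedral_cv the dihedral `colvar`.
#' @param n_bins number of time bins averaged into calibration knots.
#' @param tolerance maximum tolerated non-monotone excursion of the binned
#'   dihedral medians (degrees).
#' @param margin branch-filter margin around the driven dihedral arc
#'   (degrees).
#' @return object of class `calibration_curve` with fields `rmsd`, `dihedral`
#'   (ordered pairs) usable via [calibrate_dihedral()].
#' @export
build_calibration <- function(trajectory, rmsd_cv, dihedral_cv, n_bins = 50,
                              tolerance = 30, margin = 15) {
  r <- cv_trace(trajectory, rmsd_cv)$value
  d_raw <- cv_trace(trajectory, dihedral_cv)$value
  # unwrap around the midpoint of the driven path so neither end sits on the
  # wrap seam
  mid <- d_raw[1] + cv_wrap_diff(dihedral_cv, d_raw[length(d_raw)], d_raw[1]) / 2
  d <- mid + cv_wrap_diff(dihedral_cv, d_raw, mid)
  arc <- range(mid + cv_wrap_diff(dihedral_cv, d_raw[1], mid), d[length(d)])
  keep <- d >= arc[1] - margin & d <= arc[2] + margin
  r <- r[keep]; d <- d[keep]
  grp <- ceiling(seq_along(r) / (length(r) / n_bins))
  rm <- tapply(r, grp, stats::median)
  dm <- tapply(d, grp, stats::median)
  ord <- order(rm)
  rm <- as.numeric(rm[ord]); dm <- as.numeric(dm[ord])
  dup <- duplicated(rm)
  rm <- rm[!dup]; dm <- dm[!dup]
  # monotone check on the binned dihedral means
  dir <- sign(dm[length(dm)] - dm[1])
  exc <- max(0, max(dir * (cummax(dir * dm) - dir * dm)))
  if (exc > tolerance)
    stop(sprintf("RMSD-dihedral relation not monotone (excursion %.1f deg)", exc))
  # enforce strict monotonicity for interpolation
  dm <- dir * cummax(dir * dm)
  structure(list(rmsd = rm, dihedral = dm, direction = dir,
                 range_rmsd = range(rm), range_dihedral = range(dm)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve>: RMSD [%.3f, %.3f] A -> dihedral [%.1f, %.1f] deg (%d knots)\n",
              x$range_rmsd[1], x$range_rmsd[2], x$range_dihedral[1],
              x$range_dihedral[2], length(x$rmsd)))
  invisible(x)
}

#' Map RMSD values to dihedral angles through a calibration curve
#'
#' Piecewise-linear interpolation; queries outside the calibrated RMSD range
#' clamp to the nearest end with a warning.
#'
#' @param calibration a [build_calibration()] result.
#' @param rmsd RMSD values (Angstrom).
#' @return dihedral angles in degrees (wrapped to `[-180, 180)`).
#' @export
calibrate_dihedral <- function(calibration, rmsd) {
  out_of_range <- rmsd < calibration$range_rmsd[1] - 1e-9 |
                  rmsd > calibration$range_rmsd[2] + 1e-9
  if (any(out_of_range))
    warning(sprintf("%d RMSD value(s) outside the calibrated range; clamped",
                    sum(out_of_range)))
  d <- stats::approx(calibration$rmsd, calibration$dihedral, xout = rmsd,
                     rule = 2)$y
  ((d + 180) %% 360) - 180
}

#' Map a PMF profile from the RMSD axis onto the dihedral axis
#'
#' Relabels each defined RMSD bin with its calibrated dihedral angle and
#' interpolates onto a regular dihedral grid (pure axis relabeling; no
#' Jacobian correction, matching how segment profiles are merged). The
#' interpolation runs on the calibration's continuous (unwrapped) dihedral
#' arc, so a segment whose arc crosses +-180 never bridges the rest of the
#' circle; bins outside the calibrated RMSD range are dropped, as are bins
#' with fewer than `min_count` samples (their free energies carry large
#' histogram noise).
#'
#' @param profile a [pmf_profile()] on an RMSD axis.
#' @param calibration the section's [build_calibration()] curve.
#' @param grid target dihedral grid (degrees).
#' @param min_count minimum per-bin sample count.
#' @return a [pmf_profile()] on `grid` (NA outside the segment's arc).
#' @export
map_profile_to_dihedral <- function(profile, calibration, grid, min_count = 10) {
  ok <- is.finite(profile$pmf) & !is.na(profile$counts) &
        profile$counts >= min_count &
        profile$centers >= calibration$range_rmsd[1] &
        profile$centers <= calibration$range_rmsd[2]
  if (sum(ok) < 3) stop("fewer than 3 usable bins after trimming")
  # unwrapped dihedral positions along the section's arc
  phi <- stats::approx(calibration$rmsd, calibration$dihedral,
                       xout = profile$centers[ok], rule = 2)$y
  y <- profile$pmf[ok]
  ordp <- order(phi)
  phi <- phi[ordp]; y <- y[ordp]
  y <- tapply(y, round(phi, 6), mean)
  phi <- as.numeric(names(y)); y <- as.numeric(y)
  # evaluate the arc at grid points modulo 360
  out <- rep(NA_real_, length(grid))
  for (off in c(-360, 0, 360)) {
    v <- stats::approx(phi, y, xout = grid + off, rule = 1)$y
    out[is.na(out)] <- v[is.na(out)]
  }
  pmf_profile(grid, out, periodic = FALSE, reference = profile$reference,
              temperature = profile$temperature, unit = "deg")
}

#' Stitch overlapping segment PMF profiles into one profile
#'
#' Segments defined on a common axis are merged pairwise: a constant offset
#' is fitted by least squares over each overlap (the mean difference), the
#' shifted segments are averaged where they overlap, and a centered moving
#' average (default 3 points) smooths the bins around each seam. The result
#' is referenced to `min_zero`.
#'
#' @param segment_profiles list of >= 2 [pmf_profile()]s on the same bin
#'   centers (NA outside each segment's support).
#' @param span moving-average span for seam smoothing (odd).
#' @param periodic treat the common axis as periodic.
#' @return a [pmf_profile()].
#' @export
stitch_profiles <- function(segment_profiles, span = 3, periodic = FALSE) {
  stopifnot(length(segment_profiles) >= 2)
  centers <- segment_profiles[[1]]$centers
  for (p in segment_profiles)
    if (!isTRUE(all.equal(p$centers, centers)))
      stop("segments must share a common axis")
  aligned <- list(segment_profiles[[1]]$pmf)
  merged <- aligned[[1]]
  seams <- integer(0)
  for (s in 2:length(segment_profiles)) {
    seg <- segment_profiles[[s]]$pmf
    both <- is.finite(merged) & is.finite(seg)
    if (!any(both)) stop(sprintf("segment %d has no overlap with the merged profile", s))
    seg <- seg + mean(merged[both] - seg[both])  # least-squares constant offset
    seams <- c(seams, range(which(both)))
    aligned[[s]] <- seg
    M <- do.call(rbind, aligned)
    cnt <- colSums(is.finite(M))
    merged <- ifelse(cnt > 0, colMeans(M, na.rm = TRUE), NA_real_)
  }
  # seam smoothing: centered moving average across overlap boundaries
  if (span > 1) {
    half <- span %/% 2
    sm <- merged
    n <- length(merged)
    for (i in seq_len(n)) {
      if (!is.finite(merged[i])) next
      near_seam <- any(abs(i - seams) <= half)
      if (!near_seam) next
      idx <- (i - half):(i + half)
      if (periodic) idx <- ((idx - 1) %% n) + 1 else idx <- idx[idx >= 1 & idx <= n]
      v <- merged[idx]
      sm[i] <- mean(v[is.finite(v)])
    }
    merged <- sm
  }
  pmf_profile(centers, .reref(merged, "min_zero"), periodic = periodic,
              reference = "min_zero",
              temperature = segment_profiles[[1]]$temperature, unit = "deg")
}
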