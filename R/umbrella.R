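# Umbrella sampling: window layout, initial-structure selection from TMD
# trajectories, harmonic biases, sampling runs and histogram diagnostics.

#' Evenly spaced umbrella window centers
#'
#' @param lo,hi inclusive range; `hi - lo` must be an integer multiple of
#'   `spacing` (to 1e-9).
#' @param spacing center spacing (> 0).
#' @param periodic whether the coordinate is periodic.
#' @param period coordinate period (used with `drop_duplicate_endpoint`).
#' @param drop_duplicate_endpoint when the grid spans exactly one full period
#'   of a periodic coordinate, drop the lower endpoint (it duplicates the
#'   upper one); a no-op otherwise.
#' @return numeric vector of centers.
#' @export
make_centers <- function(lo, hi, spacing, periodic = FALSE, period = 360,
                         drop_duplicate_endpoint = FALSE) {
  stopifnot(hi > lo, spacing > 0)
  k <- (hi - lo) / spacing
  if (abs(k - round(k)) > 1e-9)
    stop("range (hi - lo) is not an integer multiple of spacing")
  centers <- lo + spacing * (0:round(k))
  if (drop_duplicate_endpoint && periodic && abs((hi - lo) - period) < 1e-9)
    centers <- centers[-1]
  centers
}

#' Dihedral-route window centers for the butane rotation
#'
#' Three sections at 20-degree spacing: -180..0 (10 centers), 20..80 (4) and
#' 100..180 (5), 19 in total. The -180 and +180 centers are both kept: they
#' belong to different TMD sections and are physically equivalent restraints
#' (minimum-image bias), contributing two independent windows at the anti
#' conformation.
#'
#' @return list of three numeric vectors (one per section).
#' @export
butane_dihedral_centers <- function() {
  list(make_centers(-180, 0, 20, periodic = TRUE),
       make_centers(20, 80, 20, periodic = TRUE),
       make_centers(100, 180, 20, periodic = TRUE))
}

.umbrella_window <- function(index, center, k2, cv, init_coords = NULL,
                             snapshot_time = NA_real_, series = NULL) {
  structure(list(index = index, center = center, k2 = k2, cv = cv,
                 init_coords = init_coords, snapshot_time = snapshot_time,
                 series = series),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window %d> center %g %s, k2 = %g, %s\n", x$index,
              x$center, x$cv$unit, x$k2,
              if (is.null(x$series)) "no series" else
                sprintf("%d samples", nrow(x$series))))
  invisible(x)
}

#' Construct an umbrella window directly from a sampled series
#'
#' Mainly for feeding externally produced time series to [solve_wham()] and
#' [diagnose_histograms()].
#'
#' @param center window center (CV units).
#' @param k2 force constant (kcal/(mol rad^2) for angular CVs, kcal/(mol A^2)
#'   otherwise).
#' @param cv the `colvar` sampled.
#' @param series data.frame with columns `time`, `value`.
#' @param index window index.
#' @return an `umbrella_window`.
#' @export
umbrella_window <- function(center, k2, cv, series, index = 1L) {
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)))
  .umbrella_window(index, center, k2, cv, series = series)
}

#' Select umbrella-window initial structures from a trajectory
#'
#' For each center, picks the trajectory frame whose CV value is nearest the
#' center (ties resolved to the earlier frame) and records its snapshot time.
#'
#' @param trajectory an `md_trajectory` (typically a TMD run).
#' @param cv the reaction-coordinate `colvar`.
#' @param centers window centers.
#' @param k2 force constant(s), recycled across windows.
#' @param spacing coverage tolerance: a window whose nearest frame is farther
#'   than this from the center is flagged with a warning (default: the center
#'   spacing).
#' @return list of `umbrella_window`s with initial frames (series unfilled).
#' @export
select_windows <- function(trajectory, cv, centers, k2, spacing = NULL) {
  stopifnot(length(trajectory$times) >= 1)
  trace <- cv_trace(trajectory, cv)
  spacing <- spacing %||% if (length(centers) > 1) min(abs(diff(centers))) else Inf
  k2 <- rep_len(k2, length(centers))
  lapply(seq_along(centers), function(w) {
    d <- abs(cv_wrap_diff(cv, trace$value, centers[w]))
    i <- which.min(d)  # which.min returns the first (earliest) minimum
    if (d[i] > spacing)
      warning(sprintf("window %d (center %g): nearest sampled value is %.3g away",
                      w, centers[w], d[i]))
    .umbrella_window(w, centers[w], k2[w], cv,
                     init_coords = matrix(trajectory$coords[, , i], ncol = 3),
                     snapshot_time = trace$time[i])
  })
}

#' Harmonic umbrella bias potential
#'
#' Restraint `V(r) = 1/2 k2 (r - r0)^2` on a collective variable, with the
#' minimum-image deviation for periodic variables. For angular variables the
#' deviation is converted to radians internally, so `k2` is in
#' kcal/(mol rad^2) while centers and CV values stay in degrees.
#'
#' @param cv a `colvar`.
#' @param center window center `r0` (CV units).
#' @param k2 force constant (> 0).
#' @return a `bias_potential` usable with [run_md()].
#' @export
umbrella_bias <- function(cv, center, k2) {
  stopifnot(k2 > 0)
  clist <- list(kind = "umbrella", cv = .cv_clist(cv), k2 = k2, center = center,
                angular = identical(cv$unit, "deg"),
                periodic = isTRUE(cv$periodic),
                period = if (isTRUE(cv$periodic)) cv$period else 360)
  structure(list(kind = "umbrella", clist = clist, cv = cv, center = center,
                 k2 = k2),
            class = "bias_potential")
}

#' Umbrella bias energy and forces at a frame
#'
#' @param bias a `bias_potential` from [umbrella_bias()].
#' @param frame an [md_frame()] (or coordinate matrix).
#' @return list with `energy` and `forces`.
#' @export
bias_energy <- function(bias, frame) {
  x <- if (inherits(frame, "md_frame")) frame$coords else as.matrix(frame)
  .bias_energy_forces(bias$clist, x, 0)
}

#' Run one umbrella-sampling window
#'
#' Langevin sampling with the window's harmonic restraint; the restrained CV
#' is recorded every `cv_stride` steps into the window's series.
#'
#' @param system a [molecular_system()].
#' @param window an `umbrella_window` with an initial frame.
#' @param md_params an [md_params()].
#' @return the window with `$series` filled (data.frame `time`, `value`).
#' @export
run_window <- function(system, window, md_params) {
  if (is.null(window$init_coords)) stop("window has no initial frame")
  traj <- run_md(system, md_frame(window$init_coords), md_params,
                 bias = umbrella_bias(window$cv, window$center, window$k2),
                 report_cvs = list(window$cv))
  window$series <- traj$cv_series[[1]]
  window$seed <- md_params$seed
  window
}

#' Choose an umbrella force constant by distribution shape
#'
#' Runs a test window at each test center for every candidate `k2` and
#' returns the smallest candidate whose sampled distribution is unimodal
#' (after histogram smoothing) with mean within `mean_tol` of the center at
#' every test center.
#'
#' @param system a [molecular_system()].
#' @param cv the restrained `colvar`.
#' @param test_centers centers to probe.
#' @param candidate_k2s ascending candidate force constants.
#' @param md_params an [md_params()] for the test runs.
#' @param init_frames optional list of start [md_frame()]s per test center
#'   (defaults to the same frame for all, which then must be supplied).
#' @param mean_tol acceptable |mean - center| (CV units); default half the
#'   spacing between test centers (or 1 unit for a single center).
#' @param bins histogram bin width for the unimodality check.
#' @return list with `k2` (recommended, or `NA` if none pass) and `report`
#'   (per candidate x center: mean shift, sd, number of modes, pass).
#' @export
choose_k2 <- function(system, cv, test_centers, candidate_k2s, md_params,
                      init_frames, mean_tol = NULL, bins = NULL) {
  stopifnot(!is.unsorted(candidate_k2s), length(test_centers) >= 1)
  if (inherits(init_frames, "md_frame"))
    init_frames <- rep(list(init_frames), length(test_centers))
  mean_tol <- mean_tol %||% if (length(test_centers) > 1)
    min(abs(diff(test_centers))) / 2 else 1
  rows <- list()
  for (k2 in candidate_k2s) {
    for (ci in seq_along(test_centers)) {
      w <- .umbrella_window(ci, test_centers[ci], k2, cv,
                            init_coords = init_frames[[ci]]$coords)
      p <- md_params; p$seed <- md_params$seed + ci * 131 + match(k2, candidate_k2s)
      w <- run_window(system, w, p)
      v <- w$series$value
      if (isTRUE(cv$periodic))
        v <- test_centers[ci] + cv_wrap_diff(cv, v, test_centers[ci])
      # bins sized from the sampled spread so a clean peak spans a few bins
      bw <- bins %||% max(stats::sd(v) / 1.5, 1e-6)
      h <- .smooth3(hist_counts(v, bw)$counts)
      modes <- .count_modes(h)
      rows[[length(rows) + 1]] <-
        data.frame(k2 = k2, center = test_centers[ci],
                   mean_shift = mean(v) - test_centers[ci], sd = stats::sd(v),
                   modes = modes,
                   pass = modes == 1 && abs(mean(v) - test_centers[ci]) <= mean_tol)
    }
  }
  report <- do.call(rbind, rows)
  ok <- vapply(candidate_k2s, function(k) all(report$pass[report$k2 == k]), TRUE)
  list(k2 = if (any(ok)) candidate_k2s[which(ok)[1]] else NA_real_,
       report = report)
}

hist_counts <- function(v, bin_width, lo = NULL, hi = NULL) {
  lo <- lo %||% (floor(min(v) / bin_width) * bin_width)
  hi <- hi %||% (ceiling(max(v) / bin_width) * bin_width)
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (tail(breaks, 1) < hi) breaks <- c(breaks, tail(breaks, 1) + bin_width)
  counts <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1),
                          length(breaks) - 1),
                     nbins = length(breaks) - 1)
  list(breaks = breaks, mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
       counts = counts)
}

.smooth3 <- function(x) {
  if (length(x) < 3) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  s[1] <- mean(x[1:2]); s[length(x)] <- mean(x[(length(x) - 1):length(x)])
  s
}

# count local maxima above a relative floor in a (smoothed) histogram
.count_modes <- function(h, rel_floor = 0.2) {
  h <- as.numeric(h)
  if (length(h) < 3) return(1L)
  d <- diff(h)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  if (h[1] > h[2]) peaks <- c(1, peaks)
  if (h[length(h)] > h[length(h) - 1]) peaks <- c(peaks, length(h))
  peaks <- peaks[h[peaks] > rel_floor * max(h)]
  max(1L, length(peaks))
}

#' Histogram diagnostics for a set of umbrella windows
#'
#' Mirrors the visual sufficiency checks applied to per-window histograms:
#' each histogram should be smooth, centered near its window, and the union
#' of all histograms should leave no bare patch along the coordinate.
#'
#' @param windows list of sampled `umbrella_window`s on the same CV.
#' @param bin_width histogram bin width (defaults: 2 deg for angular CVs,
#'   0.02 A otherwise).
#' @param rough_threshold jaggedness bound: maximum allowed residual between
#'   a histogram and its 3-point moving average, relative to the histogram
#'   peak, over bins above 20 percent of the peak.
#' @param shift_threshold maximum allowed |mean - center|; defaults to 3/4 of
#'   the window spacing (windows on steep slopes shift by an appreciable
#'   fraction of the spacing even when healthy).
#' @return object of class `histogram_report`: per-window histograms, mean
#'   shifts, neighbor-overlap fractions, and logical flags `rough`,
#'   `shifted`, `gap`.
#' @export
diagnose_histograms <- function(windows, bin_width = NULL,
                                rough_threshold = 0.25, shift_threshold = NULL) {
  stopifnot(length(windows) >= 1)
  if (any(vapply(windows, function(w) is.null(w$series) || !nrow(w$series), TRUE)))
    stop("all windows must carry a sampled series")
  cv <- windows[[1]]$cv
  centers <- vapply(windows, `[[`, 0, "center")
  ord <- order(centers)
  windows <- windows[ord]; centers <- centers[ord]
  bin_width <- bin_width %||% if (identical(cv$unit, "deg")) 2 else 0.02
  spacing <- if (length(centers) > 1) min(abs(diff(centers))) else Inf
  shift_threshold <- shift_threshold %||% (0.75 * spacing)

  vals <- lapply(windows, function(w) {
    v <- w$series$value
    if (isTRUE(cv$periodic)) w$center + cv_wrap_diff(cv, v, w$center) else v
  })
  lo <- floor(min(unlist(vals)) / bin_width) * bin_width
  hi <- ceiling(max(unlist(vals)) / bin_width) * bin_width
  hists <- lapply(vals, hist_counts, bin_width = bin_width, lo = lo, hi = hi)

  mean_shift <- vapply(seq_along(windows), function(i)
    mean(vals[[i]]) - centers[i], 0)
  rough <- vapply(hists, function(h) {
    s <- .smooth3(h$counts)
    core <- s > 0.2 * max(s)
    if (sum(core) < 3) return(FALSE)
    any(abs(h$counts[core] - s[core]) / max(s) > rough_threshold)
  }, TRUE)
  shifted <- abs(mean_shift) > shift_threshold
  # overlap fraction between neighboring windows (shared histogram mass)
  overlap <- if (length(windows) > 1)
    vapply(seq_len(length(windows) - 1), function(i) {
      a <- hists[[i]]$counts / max(1, sum(hists[[i]]$counts))
      b <- hists[[i + 1]]$counts / max(1, sum(hists[[i + 1]]$counts))
      sum(pmin(a, b))
    }, 0)
  else numeric(0)
  # bare patch: an empty bin strictly between the extreme window means
  total <- Reduce(`+`, lapply(hists, `[[`, "counts"))
  mids <- hists[[1]]$mids
  m_lo <- min(vapply(vals, mean, 0)); m_hi <- max(vapply(vals, mean, 0))
  inner <- mids > m_lo & mids < m_hi
  gap <- any(inner) && any(total[inner] == 0)
  structure(list(centers = centers, breaks = hists[[1]]$breaks, mids = mids,
                 counts = do.call(rbind, lapply(hists, `[[`, "counts")),
                 mean_shift = mean_shift, neighbor_overlap = overlap,
                 rough = rough, shifted = shifted, gap = gap,
                 flags = list(rough = any(rough), shifted = any(shifted),
                              gap = gap)),
            class = "histogram_report")
}

#' @export
print.histogram_report <- function(x, ...) {
  cat(sprintf("<histogram_report>: %d windows, flags: rough=%s shifted=%s gap=%s\n",
              length(x$centers), any(x$rough), any(x$shifted), x$gap))
  invisible(x)
}
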