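# End-to-end pipeline drivers: TMD sections -> window selection -> umbrella
# sampling -> WHAM (and, for the RMSD route, calibration + stitching).

.config_hash <- function(cfg) {
  cfg$outdir <- NULL   # where results land does not change what they are
  s <- paste(deparse(cfg), collapse = "")
  # small stable polynomial hash over the deparsed config
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 268435456
  sprintf("%07x", h)
}

#' Default pipeline configuration for the butane fixture
#'
#' @param seed base seed; stage seeds derive from it (section index for TMD
#'   runs, window index for umbrella runs).
#' @param tmd_ps TMD ramp duration per section (ps).
#' @param window_ps umbrella sampling time per window (ps).
#' @param temperature K.
#' @param k2_dihedral umbrella force constant for the dihedral route,
#'   kcal/(mol rad^2).
#' @param bins_dihedral number of dihedral bins over 360 degrees.
#' @param rmsd_spacing window spacing of the RMSD route (Angstrom).
#' @param rmsd_nwin windows per section on the RMSD route.
#' @param k2_rmsd per-section force-constant ranges (kcal/(mol A^2)); each
#'   section's windows ramp linearly across its range, stiffer toward small
#'   RMSD.
#' @param outdir optional directory for persisted intermediates.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, tmd_ps = 1000, window_ps = 500,
                            temperature = 300, k2_dihedral = 33,
                            bins_dihedral = 180, rmsd_spacing = 0.1,
                            rmsd_nwin = c(8, 5, 7),
                            k2_rmsd = list(c(50, 90), c(80, 160), c(50, 90)),
                            outdir = NULL) {
  structure(list(seed = seed, tmd_ps = tmd_ps, window_ps = window_ps,
                 temperature = temperature, k2_dihedral = k2_dihedral,
                 bins_dihedral = bins_dihedral, rmsd_spacing = rmsd_spacing,
                 rmsd_nwin = rmsd_nwin, k2_rmsd = k2_rmsd, outdir = outdir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; unknown keys
#' are an error. Referenced paths must exist.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

.stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[pmfpath] ", fmt), ...))
}

.run_tmd_sections <- function(cfg, verbose) {
  lapply(1:3, function(s) {
    sec <- butane_tmd_section(s)
    p <- md_params(n_steps = round(cfg$tmd_ps / 0.001),
                   temperature = cfg$temperature,
                   record_interval = 100, cv_stride = 100,
                   seed = cfg$seed + s)
    .stage_msg(verbose, "TMD section %d: phi %g -> %g deg, k1 = %g", s,
               sec$start_phi, sec$target_phi, sec$k1)
    traj <- tryCatch(
      run_tmd(sec$system, sec$start, sec$target, cfg$tmd_ps, sec$k1, p,
              report_cvs = list(sec$cv)),
      error = function(e) stop(sprintf("stage tmd (section %d): %s", s,
                                       conditionMessage(e))))
    list(section = sec, traj = traj)
  })
}

.persist <- function(cfg, hash, name, writer) {
  if (is.null(cfg$outdir)) return(invisible(NULL))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  writer(file.path(cfg$outdir, name))
}

#' Dihedral-route PMF pipeline for the butane fixture
#'
#' Runs the three TMD sections, selects the 19 dihedral umbrella windows
#' (20-degree spacing) from their trajectories, samples each window with the
#' harmonic restraint, and solves periodic WHAM over the full rotation.
#'
#' @param config a [pipeline_config()] (or arguments forwarded to it).
#' @param verbose print per-stage progress.
#' @param ... overrides forwarded to [pipeline_config()] when `config` is
#'   missing.
#' @return list of class `pmf_pipeline`: `profile` (periodic
#'   [pmf_profile()]), `windows`, `tmd` (per-section TMD info incl. final
#'   RMSD), `diagnostics` (histogram report), `stationary`
#'   (stationary-point table), `config`.
#' @export
run_pipeline_dihedral <- function(config = NULL, verbose = FALSE, ...) {
  cfg <- config %||% pipeline_config(...)
  hash <- .config_hash(unclass(cfg))
  secs <- .run_tmd_sections(cfg, verbose)
  centers <- butane_dihedral_centers()
  windows <- list(); wi <- 0
  for (s in 1:3) {
    sel <- select_windows(secs[[s]]$traj, secs[[s]]$section$cv, centers[[s]],
                          k2 = cfg$k2_dihedral)
    for (w in sel) {
      wi <- wi + 1
      w$index <- wi
      p <- md_params(n_steps = round(cfg$window_ps / 0.001),
                     temperature = cfg$temperature,
                     record_interval = 10000, cv_stride = 50,
                     seed = cfg$seed + 100 + wi)
      windows[[wi]] <- tryCatch(run_window(secs[[s]]$traj$system, w, p),
                                error = function(e)
                                  stop(sprintf("stage umbrella (window %d): %s",
                                               wi, conditionMessage(e))))
      .stage_msg(verbose, "window %d/19 center %g deg done", wi, w$center)
    }
  }
  diag <- diagnose_histograms(windows)
  profile <- tryCatch(
    solve_wham(windows, bins = cfg$bins_dihedral, periodic = TRUE,
               temperature = cfg$temperature),
    error = function(e) stop("stage wham: ", conditionMessage(e)))
  .persist(cfg, hash, "pmf_dihedral.tsv",
           function(p) write_pmf_table(profile, p, cfg$seed, hash))
  if (!is.null(cfg$outdir))
    write_windows(windows, cfg$outdir, "dihedral", cfg$seed, hash)
  structure(list(profile = profile, windows = windows,
                 tmd = lapply(secs, function(x)
                   list(k1 = x$section$k1, final_rmsd = attr(x$traj, "final_rmsd"),
                        start_phi = x$section$start_phi,
                        target_phi = x$section$target_phi)),
                 diagnostics = diag,
                 stationary = profile_stationary_points(profile)$extrema,
                 config = cfg, config_hash = hash),
            class = "pmf_pipeline")
}

#' RMSD-route PMF pipeline for the butane fixture
#'
#' Runs the three TMD sections; for each section lays umbrella windows along
#' the RMSD-to-target coordinate (spacing `rmsd_spacing`, counts
#' `rmsd_nwin`, force constants ramped across the section's `k2_rmsd`
#' range), samples them, and solves non-periodic WHAM per segment. Each
#' segment profile is then mapped onto the dihedral axis through the
#' section's RMSD-dihedral calibration and the three segments are stitched
#' by constant-offset alignment plus adjacent averaging.
#'
#' @inheritParams run_pipeline_dihedral
#' @return list of class `pmf_pipeline`: `profile` (stitched, on the
#'   dihedral axis), `segment_profiles` (per-section RMSD-axis profiles),
#'   `segment_profiles_dihedral`, `calibrations`, `windows`, `tmd`,
#'   `config`.
#' @export
run_pipeline_rmsd <- function(config = NULL, verbose = FALSE, ...) {
  cfg <- config %||% pipeline_config(...)
  hash <- .config_hash(unclass(cfg))
  secs <- .run_tmd_sections(cfg, verbose)
  grid <- seq(-179, 180, by = 2)
  seg_prof <- seg_prof_phi <- cals <- vector("list", 3)
  all_windows <- list()
  for (s in 1:3) {
    sec <- secs[[s]]$section; traj <- secs[[s]]$traj
    rmsd_cv <- sec$rmsd_cv
    s0 <- attr(traj, "schedule")$rmsd0_start
    nwin <- cfg$rmsd_nwin[s]
    centers <- s0 - cfg$rmsd_spacing * (0:(nwin - 1))
    if (min(centers) <= 0) stop("RMSD window centers must stay positive")
    k2r <- cfg$k2_rmsd[[s]]
    # stiffer restraints toward RMSD -> 0, ramped linearly across the range
    k2 <- k2r[1] + (k2r[2] - k2r[1]) * (s0 - centers) /
      (cfg$rmsd_spacing * max(nwin - 1, 1))
    wins <- select_windows(traj, rmsd_cv, centers, k2 = k2)
    sampled <- lapply(seq_along(wins), function(i) {
      p <- md_params(n_steps = round(cfg$window_ps / 0.001),
                     temperature = cfg$temperature,
                     record_interval = 10000, cv_stride = 50,
                     seed = cfg$seed + 500 + 100 * s + i)
      tryCatch(run_window(sec$system, wins[[i]], p),
               error = function(e)
                 stop(sprintf("stage umbrella (section %d window %d): %s",
                              s, i, conditionMessage(e))))
    })
    all_windows <- c(all_windows, sampled)
    .stage_msg(verbose, "section %d: %d RMSD windows sampled", s, nwin)
    seg_prof[[s]] <- tryCatch(
      solve_wham(sampled, bins = 60, periodic = FALSE,
                 temperature = cfg$temperature),
      error = function(e) stop(sprintf("stage wham (section %d): %s", s,
                                       conditionMessage(e))))
    cals[[s]] <- tryCatch(
      build_calibration(traj, rmsd_cv, sec$cv),
      error = function(e) stop(sprintf("stage calibration (section %d): %s", s,
                                       conditionMessage(e))))
    seg_prof_phi[[s]] <- map_profile_to_dihedral(seg_prof[[s]], cals[[s]], grid,
                                                 min_count = 25)
  }
  stitched <- tryCatch(stitch_profiles(seg_prof_phi, periodic = TRUE),
                       error = function(e) stop("stage stitch: ",
                                                conditionMessage(e)))
  .persist(cfg, hash, "pmf_rmsd_stitched.tsv",
           function(p) write_pmf_table(stitched, p, cfg$seed, hash))
  structure(list(profile = stitched, segment_profiles = seg_prof,
                 segment_profiles_dihedral = seg_prof_phi,
                 calibrations = cals, windows = all_windows,
                 tmd = lapply(secs, function(x)
                   list(k1 = x$section$k1, final_rmsd = attr(x$traj, "final_rmsd"),
                        start_phi = x$section$start_phi,
                        target_phi = x$section$target_phi)),
                 config = cfg, config_hash = hash),
            class = "pmf_pipeline")
}

#' @export
print.pmf_pipeline <- function(x, ...) {
  cat("<pmf_pipeline>\n")
  print(x$profile)
  invisible(x)
}
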