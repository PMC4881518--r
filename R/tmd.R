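# Targeted molecular dynamics: harmonic restraint on the mass-weighted RMSD
# to a target structure, with a setpoint RMSD0(t) ramped linearly to zero.

#' TMD restraint schedule
#'
#' Defines the targeted-MD restraint
#' \deqn{E_{TMD}(t) = \tfrac12 k_1 N \, [RMSD(t) - RMSD_0(t)]^2}
#' where `k1` is the per-atom harmonic force constant (the total restraint
#' stiffness scales with the restrained-atom count `N`), `RMSD(t)` is the
#' mass-weighted RMSD of the restrained atoms to the target structure, and
#' the setpoint `RMSD0(t)` decreases linearly from the start-vs-target RMSD
#' to exactly zero over `duration`.
#'
#' @param system a [molecular_system()].
#' @param start,target [md_frame()]s sharing the system's topology.
#' @param k1 per-atom harmonic force constant, kcal/(mol A^2).
#' @param duration ramp duration in ps.
#' @param atoms restrained-atom selection; defaults to all atoms.
#' @param weights RMSD weights; defaults to the atomic masses of the
#'   selection (mass-weighted RMSD).
#' @return object of class `tmd_schedule`.
#' @export
tmd_schedule <- function(system, start, target, k1, duration, atoms = NULL,
                         weights = NULL) {
  .check_frame(system, start); .check_frame(system, target)
  stopifnot(k1 > 0, duration > 0)
  atoms <- atoms %||% seq_len(nrow(system$atoms))
  weights <- weights %||% system$atoms$mass[atoms]
  cv <- cv_rmsd(atoms, target, weights = weights, label = "rmsd_to_target")
  rmsd0 <- cv_value(cv, start)
  structure(list(k1 = k1, N = length(atoms), cv = cv, duration = duration,
                 rmsd0_start = rmsd0, atoms = atoms),
            class = "tmd_schedule")
}

#' Setpoint RMSD0(t) of a TMD schedule
#' @param schedule a [tmd_schedule()].
#' @param t time in ps (vectorized).
#' @return setpoint values; linear in `t`, exactly 0 at `t >= duration`.
#' @export
tmd_rmsd0 <- function(schedule, t) {
  if (any(t < 0 | t > schedule$duration))
    stop("time outside the TMD schedule [0, duration]")
  schedule$rmsd0_start * pmax(0, 1 - t / schedule$duration)
}

.tmd_bias_clist <- function(schedule) {
  list(kind = "tmd", cv = .cv_clist(schedule$cv), k1 = schedule$k1,
       rmsd0_start = schedule$rmsd0_start, duration = schedule$duration)
}

#' TMD bias as a reusable bias potential
#'
#' @param schedule a [tmd_schedule()].
#' @return a `bias_potential` usable with [run_md()].
#' @export
tmd_bias_potential <- function(schedule) {
  structure(list(kind = "tmd", clist = .tmd_bias_clist(schedule),
                 schedule = schedule),
            class = "bias_potential")
}

#' TMD restraint energy and forces at a time point
#'
#' @param frame an [md_frame()].
#' @param t time in ps, within `[0, duration]`.
#' @param schedule a [tmd_schedule()].
#' @return list with `energy` (kcal/mol, always >= 0) and `forces`.
#' @export
tmd_bias <- function(frame, t, schedule) {
  if (t < 0 || t > schedule$duration)
    stop("time outside the TMD schedule [0, duration]")
  .bias_energy_forces(.tmd_bias_clist(schedule), frame$coords, t)
}

#' Run a targeted molecular dynamics simulation
#'
#' Langevin dynamics with the TMD restraint active; the setpoint ramps from
#' the initial RMSD to zero over the full run.
#'
#' @param system a [molecular_system()].
#' @param start,target start and target [md_frame()]s.
#' @param duration run length in ps (also the ramp duration).
#' @param k1 per-atom force constant, kcal/(mol A^2).
#' @param md_params an [md_params()]; its `n_steps` is derived from
#'   `duration` if missing (`duration / timestep`).
#' @param atoms restrained selection (default all atoms).
#' @param report_cvs extra `colvar`s to record; the restraint RMSD is always
#'   recorded as series `rmsd_to_target`.
#' @return an `md_trajectory`; attribute `final_rmsd` carries the last-frame
#'   restrained RMSD, attribute `schedule` the schedule used.
#' @export
run_tmd <- function(system, start, target, duration, k1, md_params = NULL,
                    atoms = NULL, report_cvs = list()) {
  if (is.null(md_params))
    md_params <- md_params(n_steps = round(duration / 0.001))
  md_params$n_steps <- round(duration / md_params$timestep)
  sched <- tmd_schedule(system, start, target, k1, duration, atoms = atoms)
  if (inherits(report_cvs, "colvar")) report_cvs <- list(report_cvs)
  traj <- run_md(system, start, md_params, bias = tmd_bias_potential(sched),
                 report_cvs = c(list(sched$cv), report_cvs))
  attr(traj, "final_rmsd") <- cv_value(sched$cv, traj$final)
  attr(traj, "schedule") <- sched
  traj
}

#' Screen TMD force constants
#'
#' Runs one TMD simulation per candidate force constant and accepts the
#' smallest one whose final restrained RMSD falls below `threshold`.
#'
#' @inheritParams run_tmd
#' @param candidates ascending vector of `k1` values.
#' @param threshold acceptance threshold on the final RMSD (Angstrom).
#' @param primary_cv optional `colvar` (e.g. the driven dihedral) whose final
#'   value is reported per candidate.
#' @return list with `k1` (accepted value) and `report` (data.frame with one
#'   row per candidate: `k1`, `final_rmsd`, `accepted`, and `final_cv` when a
#'   primary CV is given). Errors if no candidate passes, with the report
#'   attached to the condition.
#' @export
screen_force_constants <- function(system, start, target, duration, candidates,
                                   md_params = NULL, threshold = 0.15,
                                   atoms = NULL, primary_cv = NULL) {
  stopifnot(length(candidates) >= 1, !is.unsorted(candidates))
  rows <- lapply(candidates, function(k1) {
    traj <- run_tmd(system, start, target, duration, k1, md_params, atoms = atoms)
    data.frame(k1 = k1, final_rmsd = attr(traj, "final_rmsd"),
               final_cv = if (is.null(primary_cv)) NA_real_
                          else cv_value(primary_cv, traj$final))
  })
  report <- do.call(rbind, rows)
  report$accepted <- report$final_rmsd < threshold
  if (!any(report$accepted)) {
    cond <- simpleError("no TMD force constant reached the RMSD threshold")
    cond$report <- report
    stop(cond)
  }
  list(k1 = report$k1[which(report$accepted)[1]], report = report)
}

# per-section presets mirroring the three-way decomposition of the butane
# rotation (RMSD cannot distinguish a full 360 deg turn, so the circle is
# covered by three overlapping arcs)
.butane_sections <- list(
  list(start_phi = -180, target_phi = 0,   k1 = 90),
  list(start_phi = -60,  target_phi = 90,  k1 = 110),
  list(start_phi = 60,   target_phi = 180, k1 = 65)
)

#' Butane TMD section preset
#'
#' The butane rotation is driven in three overlapping dihedral arcs
#' (-180 to 0, -60 to 90, 60 to 180 degrees), because an RMSD restraint cannot
#' tell apart conformations related by a full 360-degree turn. Each preset
#' carries start and target frames at ideal geometry and a screened per-atom
#' force constant (90, 110 and 65 kcal/(mol A^2) for sections 1-3).
#'
#' @param section 1, 2 or 3.
#' @return list with `system`, `start`, `target`, `start_phi`, `target_phi`,
#'   `k1`, the driven dihedral `cv`, and the restrained RMSD `rmsd_cv`
#'   (4-carbon, mass-weighted, referenced to the target).
#' @export
butane_tmd_section <- function(section) {
  stopifnot(section %in% 1:3)
  p <- .butane_sections[[section]]
  bt <- build_butane(phi = p$start_phi)
  target <- md_frame(butane_geometry(p$target_phi))
  list(system = bt$system, start = bt$frame, target = target,
       start_phi = p$start_phi, target_phi = p$target_phi, k1 = p$k1,
       cv = cv_dihedral(1:4),
       rmsd_cv = cv_rmsd(1:4, target, weights = bt$system$atoms$mass))
}
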