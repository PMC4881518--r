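# Langevin dynamics (BAOAB splitting) with pluggable bias potentials, and a
# gradient-based energy minimizer.

#' Molecular-dynamics parameters
#'
#' @param n_steps number of integration steps.
#' @param timestep integration step in ps (default 1 fs).
#' @param temperature thermostat temperature in K.
#' @param friction Langevin friction in 1/ps; `friction = 0` with
#'   `temperature = 0` noise gives plain velocity-Verlet (NVE) integration.
#' @param record_interval frame-recording stride in steps.
#' @param cv_stride stride (steps) for recording reported collective
#'   variables; 0 disables the series.
#' @param seed integer PRNG seed; identical seed and inputs give a bitwise
#'   identical trajectory.
#' @param energy_ceiling abort threshold on |potential energy| (kcal/mol).
#' @return list of class `md_params`.
#' @export
md_params <- function(n_steps, timestep = 0.001, temperature = 300,
                      friction = 1, record_interval = 1000, cv_stride = 50,
                      seed = 1, energy_ceiling = 1e8) {
  stopifnot(timestep > 0, temperature >= 0, friction >= 0,
            n_steps >= 0, record_interval >= 1, cv_stride >= 0)
  structure(list(n_steps = n_steps, timestep = timestep,
                 temperature = temperature, friction = friction,
                 record_interval = record_interval, cv_stride = cv_stride,
                 seed = as.numeric(seed), energy_ceiling = energy_ceiling),
            class = "md_params")
}

.traj_new <- function(system, res, params, bias_kind = "none", report_cvs = list()) {
  cv <- NULL
  if (!is.null(res$cv_times)) {
    vals <- res$cv_values
    cv <- lapply(seq_len(nrow(vals)), function(i)
      data.frame(time = as.numeric(res$cv_times), value = as.numeric(vals[i, ])))
    names(cv) <- vapply(report_cvs, function(x) x$label, "")
  }
  structure(list(system = system, times = as.numeric(res$frame_times),
                 coords = res$frames, energies = as.numeric(res$energies),
                 cv_series = cv, final = md_frame(res$final_coords,
                                                  time = tail(res$frame_times, 1),
                                                  velocities = res$final_velocities),
                 params = params, bias = bias_kind,
                 seed = params$seed),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory>: %d frames, %g ps, %d atoms (bias: %s, seed %s)\n",
              length(x$times), diff(range(x$times)), dim(x$coords)[1],
              x$bias, format(x$seed)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame from a trajectory
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return an [md_frame()].
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= length(traj$times))
  md_frame(matrix(traj$coords[, , i], ncol = 3), time = traj$times[i])
}

#' Evaluate a collective variable over all frames of a trajectory
#' @param traj an `md_trajectory`.
#' @param cv a `colvar`.
#' @return data.frame with columns `time`, `value`.
#' @export
cv_trace <- function(traj, cv) {
  cl <- .cv_clist(cv)
  v <- vapply(seq_len(length(traj$times)),
              function(i) .cv_value(cl, matrix(traj$coords[, , i], ncol = 3)), 0)
  data.frame(time = traj$times, value = v)
}

# assemble the C++ bias list from a bias_potential object (or NULL)
.bias_clist <- function(bias) {
  if (is.null(bias)) return(list(kind = "none"))
  stopifnot(inherits(bias, "bias_potential"))
  bias$clist
}

#' Run Langevin dynamics
#'
#' Integrates the system with the BAOAB splitting of Langevin dynamics; an
#' optional time-dependent bias potential (umbrella restraint or TMD ramp) is
#' added to the force field. Initial velocities are drawn from the
#' Maxwell-Boltzmann distribution at the thermostat temperature unless the
#' start frame carries velocities.
#'
#' @param system a [molecular_system()].
#' @param start an [md_frame()].
#' @param params an [md_params()].
#' @param bias optional `bias_potential` (see [umbrella_bias()],
#'   [tmd_bias_potential()]).
#' @param report_cvs list of `colvar`s whose values are recorded every
#'   `cv_stride` steps.
#' @param t0 simulation time of the start frame (ps); bias schedules are
#'   evaluated at absolute time.
#' @return an `md_trajectory` with recorded frames, total energies, optional
#'   CV series (`$cv_series`), and the final frame with velocities.
#' @export
run_md <- function(system, start, params, bias = NULL, report_cvs = list(), t0 = 0) {
  .check_frame(system, start)
  if (inherits(report_cvs, "colvar")) report_cvs <- list(report_cvs)
  p <- unclass(params); p$t0 <- t0
  res <- .run_langevin(.sys_clist(system), start$coords, start$velocities, p,
                       .bias_clist(bias), lapply(report_cvs, .cv_clist))
  .traj_new(system, res, params,
            bias_kind = if (is.null(bias)) "none" else bias$kind,
            report_cvs = report_cvs)
}

#' Minimize the potential energy of a frame
#'
#' L-BFGS-B minimization with analytic forces, followed by a check on the
#' largest force component.
#'
#' @param system a [molecular_system()].
#' @param start an [md_frame()].
#' @param tol convergence threshold on the maximum absolute force component,
#'   kcal/(mol A).
#' @param max_iter maximum optimizer iterations.
#' @return the minimized [md_frame()]; attribute `max_force` holds the final
#'   largest force component.
#' @export
minimize <- function(system, start, tol = 1e-3, max_iter = 2000) {
  .check_frame(system, start)
  cl <- .sys_clist(system)
  n <- nrow(start$coords)
  fn <- function(x) .ff_energy_forces(cl, matrix(x, n, 3))$energy
  gr <- function(x) -as.vector(.ff_energy_forces(cl, matrix(x, n, 3))$forces)
  x <- as.vector(start$coords)
  for (round in 1:3) {
    opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 1, pgtol = tol / 10))
    x <- opt$par
    if (max(abs(gr(x))) <= tol) break
  }
  mf <- max(abs(gr(x)))
  if (mf > tol)
    stop(sprintf("minimization did not converge: max |force| = %.3g > %.3g", mf, tol))
  out <- md_frame(matrix(x, n, 3), time = start$time)
  attr(out, "max_force") <- mf
  out
}
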