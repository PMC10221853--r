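# NVT/NVE molecular dynamics driver over the compiled kernel.

#' Integrator configuration
#'
#' @param dt time step (LJ time).
#' @param steps number of integration steps.
#' @param thermostat `"nose-hoover"` (deterministic given initial
#'   velocities), `"langevin"` (BAOAB splitting, seeded), or `"none"` (NVE).
#' @param T target temperature.
#' @param damping thermostat time constant (both thermostats).
#' @param seed RNG seed for the Langevin noise.
#' @param sample_every trajectory/thermodynamic sampling stride (steps).
#' @param skin neighbor-list skin distance.
#' @param vmax velocity component beyond which the run aborts as blown up.
#' @return An `integrator_config` object.
#' @export
integrator_config <- function(dt = 0.005, steps = 1000L,
                              thermostat = c("nose-hoover", "langevin", "none"),
                              T = 1, damping = 1, seed = 1L,
                              sample_every = 100L, skin = 0.3, vmax = 100) {
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0, steps >= 1, damping > 0, sample_every >= 1, skin >= 0)
  if (thermostat != "none" && T <= 0)
    stop("thermostatted runs require a positive target temperature")
  structure(list(dt = dt, steps = as.integer(steps), thermostat = thermostat,
                 T = T, damping = damping, seed = as.integer(seed),
                 sample_every = as.integer(sample_every), skin = skin,
                 vmax = vmax),
            class = "integrator_config")
}

itable_matrices <- function(sys) {
  it <- sys$itable
  list(eps = unname(it$eps), rc = unname(it$rc),
       lo = unname(it$wall_lower), hi = unname(it$wall_upper),
       kfene = it$bond$kfene, rfene = it$bond$rfene)
}

#' Single-point forces and potential energy
#'
#' Evaluates all interactions of the system at its current coordinates:
#' pair (truncated-shifted LJ), FENE bonds, 9-3 walls and, optionally, a
#' harmonic bias on the z center of mass of a bead group. Forces are
#' reported for every bead including immobile ones (which the integrator
#' never moves).
#'
#' @param sys a `particle_system`.
#' @param bias optional `list(k, l, group)` center-of-mass spring.
#' @return list: `forces` (n x 3), `energy` and components `epair`, `ebond`,
#'   `ewall`, `ebias`, plus `bias_z` (group COM altitude).
#' @export
compute_forces <- function(sys, bias = NULL) {
  tm <- itable_matrices(sys)
  bk <- 0; bl <- 1; bg <- integer(0)
  if (!is.null(bias)) {
    bk <- bias$k
    bl <- bias$l
    bg <- as.integer(bias$group)
  }
  forces_cpp(sys$pos, sys$vel, sys$type, sys$mobile, sys$bonds,
             box_vec(sys$box),
             tm$eps, tm$rc, tm$lo, tm$hi, tm$kfene, tm$rfene, bk, bl, bg)
}

#' Run molecular dynamics
#'
#' Velocity-Verlet integration of all mobile beads, periodic in x and y,
#' confined in z by the implicit walls. Thermostats: single Nose-Hoover
#' (quarter-step splitting, thermostat mass from the mobile degrees of
#' freedom and the damping time) or Langevin via the BAOAB splitting.
#' A FENE overstretch, a wall escape, or a velocity blow-up aborts with a
#' bead diagnostic.
#'
#' @param sys a `particle_system` with initialized velocities.
#' @param config an [integrator_config()].
#' @param record bead indices recorded per frame (default: all beads).
#' @param bias optional `list(k, l, group)` harmonic spring on the z center
#'   of mass of `group` (steered-MD umbrella bias).
#' @param xi0 initial Nose-Hoover friction variable (for restarts).
#' @return An `md_trajectory`: `frames` (`length(record)` x 3 x n_frames
#'   array), `times`, `thermo` (data.frame: time, temp, ke, pe, etot,
#'   bias_z, xi), recorded subset metadata, and `final` (the evolved
#'   `particle_system`).
#' @export
run_md <- function(sys, config = integrator_config(), record = NULL,
                   bias = NULL, xi0 = 0) {
  stopifnot(inherits(sys, "particle_system"),
            inherits(config, "integrator_config"))
  if (is.null(record)) record <- seq_len(nrow(sys$pos))
  record <- as.integer(record)
  tm <- itable_matrices(sys)
  bk <- 0; bl <- 1; bg <- integer(0)
  if (!is.null(bias)) {
    bk <- bias$k
    bl <- if (is.null(bias$l)) 1 else bias$l
    bg <- as.integer(bias$group)
  }
  tcode <- match(config$thermostat, c("none", "nose-hoover", "langevin")) - 1L
  out <- md_run_cpp(sys$pos, sys$vel, sys$type, sys$mobile, sys$bonds,
                    box_vec(sys$box),
                    tm$eps, tm$rc, tm$lo, tm$hi, tm$kfene, tm$rfene,
                    config$steps, config$dt, tcode, config$T, config$damping,
                    config$skin, config$sample_every, record,
                    bk, bl, bg, config$seed, xi0, config$vmax)
  final <- sys
  final$pos <- out$pos
  final$vel <- out$vel
  structure(list(frames = out$frames, times = out$times,
                 thermo = as.data.frame(out$thermo),
                 record = record,
                 type = sys$type[record], mol = sys$mol[record],
                 role = sys$role[record],
                 box = sys$box, config = config, xi = out$xi, final = final),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md trajectory: %d frames x %d beads, t = %g .. %g (%s)\n",
              length(x$times), dim(x$frames)[1], min(x$times), max(x$times),
              x$config$thermostat))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame of a trajectory
#' @param traj an `md_trajectory`.
#' @param i frame index.
#' @return matrix of coordinates (recorded beads x 3).
#' @export
frame_coords <- function(traj, i) {
  traj$frames[, , i, drop = TRUE]
}
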