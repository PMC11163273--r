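# Canonical-ensemble propagation: velocity-Verlet core with a BAOAB-split
# Langevin thermostat (gamma = 1/friction_time; gamma = 0 recovers NVE),
# and the direct-coexistence equilibrate-then-produce protocol.

#' Integrator settings
#'
#' Defaults follow the standard direct-coexistence protocol for this model
#' family: 10 fs time step, Langevin relaxation time 10 ps, 250 K.
#'
#' @param dt Time step, ps (default 0.01 = 10 fs).
#' @param friction_time Langevin relaxation time tau, ps; the friction is
#'   gamma = 1/tau.
#' @param temperature Kelvin.
#' @param seed Integer seed for the thermostat noise.
#' @param com_motion_removal Remove net momentum each step.
#' @param save_interval Frame save interval, ps (default 100).
#' @param save_velocities Keep velocities of saved frames.
#' @return An `integrator_settings` list.
#' @export
integrator_settings <- function(dt = 0.01, friction_time = 10,
                                temperature = 250, seed = 1L,
                                com_motion_removal = TRUE,
                                save_interval = 100,
                                save_velocities = FALSE) {
  stopifnot(dt > 0, friction_time > 0)
  structure(list(dt = dt, friction_time = friction_time,
                 temperature = temperature, seed = seed,
                 com_motion_removal = com_motion_removal,
                 save_interval = save_interval,
                 save_velocities = save_velocities),
            class = "integrator_settings")
}

run_md_internal <- function(state, topology, ff, settings, n_steps, gamma) {
  ka <- ff_kernel_args(topology, ff)
  save_every <- max(1L, as.integer(round(settings$save_interval / settings$dt)))
  res <- cpp_run_md(state$pos, state$vel, state$box, topology$type,
                    topology$charge, topology$mass, topology$bonds - 1L,
                    topology$bond_ref, topology$bond_k, ka$tabs$eps_alpha,
                    ka$tabs$sigma, ka$tabs$mu, ka$tabs$nu, ka$tabs$R,
                    ka$kq, ka$kappa, ka$rcoul, ka$rlist, 0.3,
                    settings$dt, as.integer(n_steps), gamma,
                    .kB * settings$temperature, as.double(settings$seed),
                    save_every, settings$com_motion_removal,
                    settings$save_velocities)
  final <- structure(list(pos = res$pos, vel = res$vel, box = state$box,
                          time = state$time + n_steps * settings$dt),
                     class = "configuration")
  structure(list(frames = res$frames, vel_frames = res$vel_frames,
                 times = state$time + res$times, box = state$box,
                 pe = res$pe, ke_trace = res$ke_trace,
                 n_rebuilds = res$n_rebuilds, dt = settings$dt,
                 save_interval = save_every * settings$dt,
                 final = final), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$frames), " frames, dt = ", x$dt,
      " ps, save interval = ", x$save_interval, " ps\n", sep = "")
  invisible(x)
}

#' Microcanonical (NVE) velocity-Verlet run
#'
#' Thermostat disabled; symplectic and time-reversible.
#'
#' @param state A `configuration`.
#' @param topology,ff As elsewhere.
#' @param settings [integrator_settings()]; `friction_time` is ignored.
#' @param n_steps Number of steps.
#' @return A `trajectory` (with `$final` state, per-save potential energies
#'   `$pe` and per-step kinetic energies `$ke_trace`).
#' @export
run_nve <- function(state, topology, ff, settings, n_steps) {
  run_md_internal(state, topology, ff, settings, n_steps, gamma = 0)
}

#' Langevin (NVT) run
#'
#' BAOAB discretization of Langevin dynamics with friction
#' `1/friction_time`; the stationary distribution approximates the
#' canonical ensemble at `settings$temperature`. Seeded runs are bitwise
#' reproducible.
#'
#' @inheritParams run_nve
#' @return A `trajectory`.
#' @export
run_langevin <- function(state, topology, ff, settings, n_steps) {
  run_md_internal(state, topology, ff, settings, n_steps,
                  gamma = 1 / settings$friction_time)
}

#' Instantaneous kinetic temperature trace of a trajectory
#'
#' @param traj A `trajectory`.
#' @param topology The matching `topology`.
#' @param com_removed Whether net momentum was constrained (3 fewer
#'   degrees of freedom).
#' @return Numeric vector of per-step temperatures (K).
#' @export
kinetic_temperature <- function(traj, topology, com_removed = TRUE) {
  dof <- 3 * topology$n - if (com_removed) 3 else 0
  2 * traj$ke_trace / (dof * .kB)
}

#' Direct-coexistence protocol: equilibrate, then produce
#'
#' Builds the system (unless given one), runs `equil_time` of Langevin
#' dynamics that is discarded, then `prod_time` whose frames are returned
#' for density analysis. The production frames start with the state at the
#' end of equilibration (time zero of production), so with
#' `equil_time = 0` the first production frame is the initial state.
#'
#' @param spec A [system_spec].
#' @param ff A [forcefield].
#' @param settings [integrator_settings()].
#' @param equil_time Equilibration, ps (default 40000 = 40 ns).
#' @param prod_time Production, ps (default 20000 = 20 ns).
#' @param system Optional prebuilt `list(topology, configuration)`;
#'   otherwise built from `spec` with `settings$seed`.
#' @return List with `trajectory` (production), `topology` and the
#'   equilibration-end `state`.
#' @export
coexistence_protocol <- function(spec, ff, settings = integrator_settings(),
                                 equil_time = 40000, prod_time = 20000,
                                 system = NULL) {
  if (is.null(system)) {
    system <- build_system(spec, ff, seed = settings$seed)
  }
  topo <- system$topology
  state <- system$configuration
  if (equil_time > 0) {
    eq <- run_md_internal(state, topo, ff, settings,
                          as.integer(round(equil_time / settings$dt)),
                          gamma = 1 / settings$friction_time)
    state <- eq$final
  }
  prod_settings <- settings
  prod_settings$seed <- settings$seed + 1L
  traj <- run_langevin(state, topo, ff, prod_settings,
                       as.integer(round(prod_time / settings$dt)))
  # production frames at 0, s, ..., prod_time - s  (count = prod/s)
  wrap <- function(p, box) {
    for (k in 1:3) p[, k] <- p[, k] - box[k] * floor(p[, k] / box[k])
    p
  }
  traj$frames <- c(list(wrap(state$pos, state$box)), head(traj$frames, -1))
  traj$times <- c(state$time, head(traj$times, -1))
  list(trajectory = traj, topology = topo, state = traj$final)
}
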