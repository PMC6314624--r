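#' Reflex controller parameters
#'
#' Gains and sensory delay of the segmental (spinal) posture controller. The
#' desired muscle lengths `lmd` default to the muscle lengths at the initial
#' posture, so the control law restores the starting configuration.
#'
#' @param kp proportional (stretch) reflex gain, 1/s^2.
#' @param kd derivative (velocity) reflex gain, 1/s.
#' @param tau_so sensory conduction delay in seconds (muscle spindle loop).
#' @param lmd desired muscle lengths (meters); `NULL` means "capture at
#'   t = 0".
#' @return an object of class `reflex_params`.
#' @export
reflex_params <- function(kp = 10, kd = 10, tau_so = 0.02, lmd = NULL) {
  stopifnot(kp >= 0, kd >= 0, tau_so >= 0)
  structure(list(kp = kp, kd = kd, tau_so = tau_so, lmd = lmd),
            class = "reflex_params")
}

#' Reflex muscle-length acceleration goal
#'
#' The segmental control law
#' `lmddot_goal = kp (lmd - lm(t - tau_so)) - kd lmdot(t - tau_so)`,
#' operating on delayed muscle length and velocity signals.
#'
#' @param lm_delayed perceived (delayed) muscle lengths, meters.
#' @param lmdot_delayed perceived (delayed) muscle velocities, m/s.
#' @param params a [reflex_params()] with `lmd` set.
#' @return muscle-length acceleration goal (length m, m/s^2).
#' @export
reflex_muscle_goal <- function(lm_delayed, lmdot_delayed, params) {
  stopifnot(inherits(params, "reflex_params"), !is.null(params$lmd))
  params$kp * (params$lmd - lm_delayed) - params$kd * lmdot_delayed
}

#' Gaussian force disturbance
#'
#' Smooth task-space force impulse
#' `f(t) = a exp(-(t - t0)^2 / sigma^2) * direction`.
#'
#' @param t time (s), vectorized.
#' @param spec a [disturbance_spec()].
#' @return for scalar `t`, the force vector (length d, N); for vector `t`, a
#'   length(t) x d matrix.
#' @export
gaussian_disturbance <- function(t, spec) {
  stopifnot(inherits(spec, "disturbance_spec"))
  mag <- spec$a * exp(-((t - spec$t0)^2) / spec$sigma^2)
  if (length(t) == 1L) return(mag * spec$direction)
  outer(mag, spec$direction)
}

#' Disturbance specification
#'
#' Defaults reproduce the posture-experiment impulse: 15 N, applied at
#' t = 0.1 s with width 0.01 s, acting along -x.
#'
#' @param a magnitude (N).
#' @param t0 application time (s).
#' @param sigma impulse width (s), > 0.
#' @param direction unit direction vector in task space.
#' @return an object of class `disturbance_spec`.
#' @export
disturbance_spec <- function(a = 15, t0 = 0.1, sigma = 0.01,
                             direction = c(-1, 0)) {
  stopifnot(sigma > 0)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-12) direction <- direction / nrm
  structure(list(a = a, t0 = t0, sigma = sigma, direction = direction),
            class = "disturbance_spec")
}

#' Smooth sigmoid task trajectory
#'
#' Desired end-point trajectory with a bell-shaped velocity profile: the
#' displacement along the movement direction is `a/2 (tanh(b (t - t0)) + 1)`,
#' with analytic first and second time derivatives; the movement direction is
#' obtained by rotating +x by `gamma` about the out-of-plane axis, around the
#' starting position `xt0`. Peak speed is `a b / 2`, reached at `t0`.
#'
#' @param t time (s), scalar.
#' @param xt0 starting task position (length 2, m).
#' @param spec a [trajectory_spec()].
#' @return list with `xd`, `xddot`, `xdddot` (desired position, velocity,
#'   acceleration; length-2 vectors).
#' @export
sigmoid_task_trajectory <- function(t, xt0, spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  u <- spec$b * (t - spec$t0)
  th <- tanh(u); sech2 <- 1 - th^2
  s <- spec$a / 2 * (th + 1)
  sd <- spec$a * spec$b / 2 * sech2
  sdd <- -spec$a * spec$b^2 * sech2 * th
  dir <- c(cos(spec$gamma), sin(spec$gamma))
  list(xd = xt0 + s * dir, xddot = sd * dir, xdddot = sdd * dir)
}

#' Trajectory specification
#'
#' Defaults reproduce the reaching experiment: displacement a = 0.3 m,
#' steepness b = 4 1/s, midpoint t0 = 1 s.
#'
#' @param a displacement magnitude (m).
#' @param b steepness (1/s).
#' @param t0 midpoint time (s).
#' @param gamma movement direction angle (radians, rotation about z).
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(a = 0.3, b = 4, t0 = 1, gamma = 0) {
  structure(list(a = a, b = b, t0 = t0, gamma = gamma),
            class = "trajectory_spec")
}

#' Muscle-space inverse-dynamics force computation
#'
#' Computes the muscle forces realizing a muscle-length acceleration goal
#' while respecting the muscle-model force bounds:
#' (1) solve the muscle-space equations of motion for the particular solution
#' `fm_par = -Lambda_m (lmddot_goal + b_m) - R+' f`, ignoring the null-space
#' term; (2) find the null-space correction of minimum norm, `min ||fm0||^2`
#' subject to the bound inequalities (a quadratic program in the reduced
#' null-space coordinates); (3) return `fm = fm_par + N_TR fm0`. The
#' correction leaves the delivered torque unchanged.
#'
#' @inheritParams task_projection
#' @param lmddot_goal muscle-length acceleration goal (length m, m/s^2).
#' @param lmdot0 free null-space muscle velocity (length m, m/s).
#' @param muscle_model a [linear_muscle_model()] or [hill_muscle_model()].
#' @return muscle-force vector (length m, N) within the model bounds.
#' @export
muscle_space_controller <- function(model, state, lmddot_goal, lmdot0 = NULL,
                                    muscle_model = linear_muscle_model(model$fmax),
                                    rtol = 1e-10) {
  proj <- muscle_projection(model, state, lmdot0, rtol)
  lmddot_goal <- as_real_vector(lmddot_goal, "lmddot_goal", model$n_muscles)
  fm_par <- drop(-proj$Lambda_m %*% (lmddot_goal + proj$b_m) -
                   proj$RplusT %*% proj$f)
  H <- build_force_inequalities(fm_par, muscle_model, proj$N_TR,
                                lm = proj$lm, lmdot = proj$lmdot, rtol = rtol)
  y <- minnorm_in_polytope(H$Z, H$beta)
  if (is.null(y)) {
    stop("goal exceeds muscle capacity: bound inequalities are infeasible",
         call. = FALSE)
  }
  drop(fm_par + H$basis %*% y)
}

#' Task-space inverse-dynamics tracking controller
#'
#' PD tracking in task space with model-based feedforward: the commanded task
#' acceleration is `xddot_cmd = xddot_d + kp (xd - xt) + kd (xdot_d - xtdot)`;
#' the task force follows from the task-space equations of motion
#' `ft = Lambda_t (xddot_cmd + b_t) + Jbar_t' f` (no secondary joint-space
#' objective, `tau0 = 0`), and the joint torque is `tau = Jt' ft`.
#'
#' @inheritParams task_projection
#' @param xd,xdot_d,xddot_d desired task position / velocity / acceleration.
#' @param kp,kd tracking gains (defaults 50 and 5).
#' @return list with `ft` (task force, N) and `tau` (joint torque, N·m).
#' @export
task_space_controller <- function(model, state, xd, xdot_d, xddot_d,
                                  kp = 50, kd = 5, rtol = 1e-10) {
  proj <- task_projection(model, state, rtol)
  xd <- as_real_vector(xd, "xd", 2)
  xdot_d <- as_real_vector(xdot_d, "xdot_d", 2)
  xddot_d <- as_real_vector(xddot_d, "xddot_d", 2)
  cmd <- xddot_d + kp * (xd - proj$xt) + kd * (xdot_d - proj$xtdot)
  ft <- drop(proj$Lambda_t %*% (cmd + proj$b_t) + proj$JbarT %*% proj$f)
  list(ft = ft, tau = drop(t(proj$Jt) %*% ft))
}

#' Mixed-dynamics forward simulation
#'
#' Integrates the plant `M(q) qdd = tau - f(q, qd)` with a fixed-step
#' explicit Runge-Kutta 4 scheme (default dt = 1 ms), driven by an
#' inverse-dynamics controller evaluated once per step (mixed-dynamics
#' scheme: ID controller, FD plant). The controller receives the current
#' state and a delayed-signal lookup backed by a dense state history at dt
#' resolution with linear interpolation; history before t = 0 equals the
#' initial state. Runs are fully deterministic.
#'
#' The controller is a function `function(t, state, history, model)` returning
#' a list with either `fm` (muscle forces; the plant torque is `-R' fm`) or
#' `tau` (direct joint torques), and optionally `ft` for logging. `history`
#' is a function of time returning `list(q, qdot, lm, lmdot)`.
#'
#' @param model a `planar_arm` model.
#' @param controller controller closure (see Details), or `NULL` for an
#'   unactuated plant.
#' @param duration simulated time span (s).
#' @param dt fixed integrator step (s).
#' @param state0 initial [arm_state()]; defaults to the model reference
#'   posture at rest.
#' @param disturbance optional [disturbance_spec()]: task-space force applied
#'   at the end effector (entering the plant only, not the controller model).
#' @return an object of class `msk_simulation`: list of aligned per-step
#'   series `time`, `q`, `qdot`, `qddot`, `lm`, `lmdot`, `fm`, `tau`, `xt`,
#'   `ft` plus the integration parameters.
#' @export
simulate_arm <- function(model, controller = NULL, duration = 1, dt = 1e-3,
                         state0 = NULL, disturbance = NULL) {
  stopifnot(duration > 0, dt > 0)
  n <- model$n_joints; m <- model$n_muscles
  state0 <- if (is.null(state0)) arm_state(model$q_ref, rep(0, n)) else
    check_state(model, state0)
  n_steps <- as.integer(round(duration / dt))
  times <- seq(0, by = dt, length.out = n_steps + 1L)

  Q <- matrix(0, n_steps + 1L, n); Qd <- matrix(0, n_steps + 1L, n)
  Qdd <- matrix(0, n_steps + 1L, n)
  LM <- matrix(0, n_steps + 1L, m); LMd <- matrix(0, n_steps + 1L, m)
  FM <- matrix(NA_real_, n_steps + 1L, m)
  TAU <- matrix(0, n_steps + 1L, n)
  XT <- matrix(0, n_steps + 1L, 2)
  FT <- matrix(NA_real_, n_steps + 1L, 2)
  Q[1, ] <- state0$q; Qd[1, ] <- state0$qdot

  mk0 <- evaluate_muscle_kinematics(model, state0)
  LM[1, ] <- mk0$lm; LMd[1, ] <- mk0$lmdot

  history <- function(t_query) {
    if (t_query <= 0) {
      return(list(q = Q[1, ], qdot = Qd[1, ], lm = LM[1, ], lmdot = LMd[1, ]))
    }
    idx <- t_query / dt
    i0 <- min(floor(idx), n_steps) + 1L
    i1 <- min(i0 + 1L, n_steps + 1L)
    w <- idx - (i0 - 1L)
    w <- min(max(w, 0), 1)
    list(
      q = (1 - w) * Q[i0, ] + w * Q[i1, ],
      qdot = (1 - w) * Qd[i0, ] + w * Qd[i1, ],
      lm = (1 - w) * LM[i0, ] + w * LM[i1, ],
      lmdot = (1 - w) * LMd[i0, ] + w * LMd[i1, ]
    )
  }

  # The generalized force computed by the controller (tau = -R' fm for muscle
  # actuation) is held constant over each integration step: sampling the
  # torque, rather than the muscle forces, at the plant rate keeps the
  # null-space force component exactly movement-invisible in discrete time
  # (re-evaluating -R(q)' fm at intermediate stage states would leak a
  # torque of order ||fm0|| * dR as the posture moves within the step).
  plant_qdd <- function(t_, q, qd, tau) {
    st <- arm_state(q, qd, t_)
    ext <- NULL
    if (!is.null(disturbance)) {
      tk <- evaluate_task_kinematics(model, st)
      ext <- drop(t(tk$Jt) %*% gaussian_disturbance(t_, disturbance))
    }
    dyn <- evaluate_dynamics(model, st, ext)
    drop(solve(dyn$M, tau - dyn$f))
  }

  for (k in seq_len(n_steps + 1L)) {
    t_k <- times[k]
    q <- Q[k, ]; qd <- Qd[k, ]
    st <- arm_state(q, qd, t_k)
    ctl <- if (is.null(controller)) list() else controller(t_k, st, history, model)
    # a controller may return the generalized force directly (preferred when
    # it already assembled tau from its own projection quantities) and/or
    # muscle forces; with only fm given, tau = -R' fm
    tau <- if (!is.null(ctl$tau)) ctl$tau
      else if (!is.null(ctl$fm)) {
        mk <- evaluate_muscle_kinematics(model, st)
        drop(-t(mk$R) %*% ctl$fm)
      } else rep(0, n)
    Qdd[k, ] <- plant_qdd(t_k, q, qd, tau)
    TAU[k, ] <- tau
    if (!is.null(ctl$fm)) FM[k, ] <- ctl$fm
    if (!is.null(ctl$ft)) FT[k, ] <- ctl$ft
    tk <- evaluate_task_kinematics(model, st)
    XT[k, ] <- tk$xt
    if (k > n_steps) break
    # RK4 step with the controller torque held over the step
    k1q <- qd;               k1v <- Qdd[k, ]
    k2q <- qd + dt / 2 * k1v; k2v <- plant_qdd(t_k + dt / 2, q + dt / 2 * k1q, k2q, tau)
    k3q <- qd + dt / 2 * k2v; k3v <- plant_qdd(t_k + dt / 2, q + dt / 2 * k2q, k3q, tau)
    k4q <- qd + dt * k3v;     k4v <- plant_qdd(t_k + dt, q + dt * k3q, k4q, tau)
    Q[k + 1L, ] <- q + dt / 6 * (k1q + 2 * k2q + 2 * k3q + k4q)
    Qd[k + 1L, ] <- qd + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    if (any(!is.finite(Qd[k + 1L, ])) || sqrt(sum(Qd[k + 1L, ]^2)) > 1e3) {
      stop(sprintf("integrator divergence at t = %.4f s (||qdot|| explodes)",
                   t_k + dt), call. = FALSE)
    }
    mk <- evaluate_muscle_kinematics(model, arm_state(Q[k + 1L, ], Qd[k + 1L, ]))
    LM[k + 1L, ] <- mk$lm; LMd[k + 1L, ] <- mk$lmdot
  }

  structure(
    list(time = times, q = Q, qdot = Qd, qddot = Qdd, lm = LM, lmdot = LMd,
         fm = FM, tau = TAU, xt = XT, ft = FT, dt = dt, duration = duration,
         muscle_names = model$muscle_names),
    class = "msk_simulation"
  )
}

#' @export
print.msk_simulation <- function(x, ...) {
  cat(sprintf("<msk_simulation> %.3f s at dt = %g s (%d steps), %d joints, %d muscles\n",
              x$duration, x$dt, length(x$time) - 1L, ncol(x$q), ncol(x$lm)))
  invisible(x)
}

#' Reflex posture-control experiment
#'
#' Simulates the muscle-space reflex controller under a task-space force
#' impulse: the controller turns delayed muscle length/velocity errors into a
#' muscle-length acceleration goal ([reflex_muscle_goal()]), realizes it with
#' bounded muscle forces ([muscle_space_controller()]), and the plant
#' integrates forward. With both loops active (kp, kd > 0) the arm returns to
#' its initial posture; with the length loop disabled (kp = 0) it settles at
#' a new equilibrium.
#'
#' @param model a `planar_arm` model.
#' @param params a [reflex_params()].
#' @param disturbance a [disturbance_spec()].
#' @param duration,dt simulation span and step (s).
#' @param state0 initial state (defaults to the reference posture at rest).
#' @param muscle_model muscle model bounding the forces.
#' @param lmdot0 free null-space muscle velocity passed to the projection.
#' @param fm0_strategy `"min-norm"` (default) picks the smallest feasible
#'   null-space correction each step; `"max-vertex"` picks the polytope
#'   vertex of largest norm instead (maximal co-contraction) — the movement
#'   is unchanged either way.
#' @return an `msk_simulation`.
#' @export
run_reflex_experiment <- function(model,
                                  params = reflex_params(),
                                  disturbance = disturbance_spec(),
                                  duration = 3, dt = 1e-3,
                                  state0 = NULL,
                                  muscle_model = linear_muscle_model(model$fmax),
                                  lmdot0 = NULL,
                                  fm0_strategy = c("min-norm", "max-vertex")) {
  fm0_strategy <- match.arg(fm0_strategy)
  state0 <- if (is.null(state0)) arm_state(model$q_ref) else check_state(model, state0)
  if (is.null(params$lmd)) {
    params$lmd <- evaluate_muscle_kinematics(model, state0)$lm
  }
  # The plant torque is assembled from the particular solution before the
  # null-space strategy branch: R' N_TR fm0 = 0 holds identically, so the
  # null component's torque is evaluated as the exact zero it is rather than
  # re-accumulated through a catastrophically cancelling R' fm product whose
  # rounding noise would differ between fm0 strategies. The full muscle
  # force (particular + null correction) is what the bound check and the
  # logs see.
  controller <- function(t_, state, history, model) {
    h <- history(t_ - params$tau_so)
    goal <- reflex_muscle_goal(h$lm, h$lmdot, params)
    proj <- muscle_projection(model, state, lmdot0)
    fm_par <- drop(-proj$Lambda_m %*% (goal + proj$b_m) -
                     proj$RplusT %*% proj$f)
    tau <- drop(-t(proj$R) %*% fm_par)
    H <- build_force_inequalities(fm_par, muscle_model, proj$N_TR,
                                  lm = proj$lm, lmdot = proj$lmdot)
    fm <- if (fm0_strategy == "min-norm") {
      y <- minnorm_in_polytope(H$Z, H$beta)
      if (is.null(y)) {
        stop("goal exceeds muscle capacity: bound inequalities are infeasible",
             call. = FALSE)
      }
      drop(fm_par + H$basis %*% y)
    } else {
      vs <- enumerate_vertices(H)
      nrm <- rowSums(vs$vertices^2)
      drop(fm_par + H$basis %*% vs$vertices[which.max(nrm), ])
    }
    list(tau = tau, fm = fm)
  }
  simulate_arm(model, controller, duration, dt, state0, disturbance)
}

#' Task-space reaching experiment
#'
#' Simulates the task-space tracking controller along a smooth sigmoid
#' reaching trajectory in direction `gamma`, using the mixed-dynamics scheme
#' (ID task controller, FD plant, torque actuation).
#'
#' @inheritParams run_reflex_experiment
#' @param spec a [trajectory_spec()] (direction angle included).
#' @param kp,kd task tracking gains.
#' @return an `msk_simulation` (with the task force log `ft` filled in).
#' @export
run_reaching_experiment <- function(model,
                                    spec = trajectory_spec(gamma = pi),
                                    kp = 50, kd = 5,
                                    duration = 2, dt = 1e-3,
                                    state0 = NULL) {
  state0 <- if (is.null(state0)) arm_state(model$q_ref) else check_state(model, state0)
  xt0 <- evaluate_task_kinematics(model, state0)$xt
  controller <- function(t_, state, history, model) {
    des <- sigmoid_task_trajectory(t_, xt0, spec)
    out <- task_space_controller(model, state, des$xd, des$xddot, des$xdddot,
                                 kp = kp, kd = kd)
    list(tau = out$tau, ft = out$ft)
  }
  simulate_arm(model, controller, duration, dt, state0)
}

#' Extract a decimated trajectory from a simulation
#'
#' Picks `n_points` evenly spaced time steps and returns them in the format
#' expected by [joint_reaction_bounds()] (q, qdot, qddot, time per point).
#'
#' @param sim an `msk_simulation`.
#' @param n_points number of time points to keep.
#' @return list of trajectory points.
#' @export
trajectory_from_simulation <- function(sim, n_points = 10L) {
  stopifnot(inherits(sim, "msk_simulation"))
  idx <- unique(round(seq(1, length(sim$time), length.out = n_points)))
  lapply(idx, function(i) {
    list(q = sim$q[i, ], qdot = sim$qdot[i, ], qddot = sim$qddot[i, ],
         time = sim$time[i], tau = sim$tau[i, ])
  })
}
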