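#' Task-space projection of the equations of motion
#'
#' Projects the joint-space dynamics onto the task (operational) space:
#' task-space inertia `Lambda_t = (Jt M^-1 Jt')^-1`, bias `b_t = -Jtd qd`,
#' the dynamically consistent generalized inverse transpose
#' `Jbar_t' = Lambda_t Jt M^-1` (the unique inverse for which null-space
#' generalized forces produce zero task acceleration), and the
#' pseudoinverse-based task null-space projector `N_FJt = I - Jt+ Jt`.
#' Also returns the coupled task-muscle map `Theta = Jt R+`.
#'
#' @param model a `planar_arm` model.
#' @param state an [arm_state()].
#' @param rtol relative singular-value cutoff for pseudoinverses.
#' @return an object of class `task_projection`: list with `Lambda_t`, `b_t`,
#'   `JbarT` (d x n), `N_FJt` (n x n), `Theta` (d x m), plus the underlying
#'   `Jt`, `Jtdot`, `M`, `f`, `xt`, `xtdot`.
#' @export
task_projection <- function(model, state, rtol = 1e-10) {
  state <- check_state(model, state)
  dyn <- evaluate_dynamics(model, state)
  tk <- evaluate_task_kinematics(model, state)
  mk <- evaluate_muscle_kinematics(model, state)
  Minv <- solve(dyn$M)
  JMJ <- tk$Jt %*% Minv %*% t(tk$Jt)
  if (rcond(JMJ) < 1e-12) {
    stop("kinematic singularity: Jt M^-1 Jt' is numerically singular",
         call. = FALSE)
  }
  Lambda_t <- solve(JMJ)
  Lambda_t <- (Lambda_t + t(Lambda_t)) / 2
  Jt_pinv <- pinv(tk$Jt, rtol)
  structure(
    list(
      Lambda_t = Lambda_t,
      b_t = -drop(tk$Jtdot %*% state$qdot),
      JbarT = Lambda_t %*% tk$Jt %*% Minv,
      N_FJt = diag(model$n_joints) - Jt_pinv %*% tk$Jt,
      Theta = tk$Jt %*% pinv(mk$R, rtol),
      Jt = tk$Jt, Jtdot = tk$Jtdot, Jt_pinv = Jt_pinv,
      M = dyn$M, f = dyn$f, xt = tk$xt, xtdot = tk$xtdot
    ),
    class = "task_projection"
  )
}

#' Muscle-space projection of the equations of motion
#'
#' Projects the joint-space dynamics onto muscle space: muscle-space inertia
#' `Lambda_m = (R M^-1 R')+` (pseudoinverse — the matrix has rank n < m by
#' construction), bias `b_m = -Rd qd - Nd_TR lmdot0`, the moment-arm
#' null-space projector `N_TR = I - R R+` and the joint-to-muscle force map
#' `R+'`. `Nd_TR` (the time derivative of the null-space projector) is
#' obtained by central finite differences of `N_TR` along the current
#' velocity, since `N_TR` depends on the configuration only.
#'
#' The free null-space muscle velocity `lmdot0` defaults to zero (the
#' "unbiased" strategy); it only enters the bias term.
#'
#' @inheritParams task_projection
#' @param lmdot0 free null-space muscle velocity (length m, m/s).
#' @param fd_step time step (s) for the finite-difference `Nd_TR`.
#' @return an object of class `muscle_projection`: list with `Lambda_m`
#'   (m x m), `b_m` (length m), `N_TR` (m x m), `RplusT` (m x n), `Ndot_TR`,
#'   `lmdot0`, plus the underlying `R`, `Rdot`, `lm`, `lmdot`, `M`, `f`.
#' @export
muscle_projection <- function(model, state, lmdot0 = NULL, rtol = 1e-10,
                              fd_step = 1e-5) {
  state <- check_state(model, state)
  m <- model$n_muscles; n <- model$n_joints
  lmdot0 <- if (is.null(lmdot0)) rep(0, m) else as_real_vector(lmdot0, "lmdot0", m)
  dyn <- evaluate_dynamics(model, state)
  mk <- evaluate_muscle_kinematics(model, state)
  r_found <- qr(mk$R, tol = rtol)$rank
  if (r_found < n) {
    stop(sprintf("moment-arm matrix is rank deficient (rank %d < %d)",
                 r_found, n), call. = FALSE)
  }
  Minv <- solve(dyn$M)
  Lambda_m <- pinv(mk$R %*% Minv %*% t(mk$R), rtol)
  Lambda_m <- (Lambda_m + t(Lambda_m)) / 2
  R_pinv <- pinv(mk$R, rtol)
  N_TR <- diag(m) - mk$R %*% R_pinv
  Ndot_TR <- nullspace_projector_dot(model, state, fd_step, rtol)
  structure(
    list(
      Lambda_m = Lambda_m,
      b_m = -drop(mk$Rdot %*% state$qdot) - drop(Ndot_TR %*% lmdot0),
      N_TR = N_TR,
      RplusT = t(R_pinv),
      Ndot_TR = Ndot_TR,
      lmdot0 = lmdot0,
      R = mk$R, Rdot = mk$Rdot, R_pinv = R_pinv,
      lm = mk$lm, lmdot = mk$lmdot, M = dyn$M, f = dyn$f
    ),
    class = "muscle_projection"
  )
}

# d N_TR / d t by central differences along the instantaneous velocity;
# exact at fixed moment-arm rank because N_TR depends only on q.
nullspace_projector_dot <- function(model, state, h = 1e-5, rtol = 1e-10) {
  m <- model$n_muscles
  ntr_at <- function(q) {
    R <- evaluate_muscle_kinematics(model, arm_state(q, state$qdot))$R
    diag(m) - R %*% pinv(R, rtol)
  }
  (ntr_at(state$q + h * state$qdot) - ntr_at(state$q - h * state$qdot)) / (2 * h)
}

#' Map task forces to joint generalized forces
#'
#' `tau = Jt' ft + N_FJt tau0`: the task force contribution plus an arbitrary
#' joint-space force projected onto the task null space (movement-invisible
#' at the task level). The inverse map `ft = Jt+' tau` recovers `ft` when
#' `tau0 = 0`.
#'
#' @param ft task force vector (length d, N).
#' @param tau0 arbitrary joint-space generalized force (length n, N·m).
#' @param proj a [task_projection()].
#' @return joint generalized force vector (length n, N·m).
#' @export
task_force_map <- function(ft, tau0, proj) {
  stopifnot(inherits(proj, "task_projection"))
  ft <- as_real_vector(ft, "ft", nrow(proj$Jt))
  tau0 <- as_real_vector(tau0, "tau0", ncol(proj$Jt))
  drop(t(proj$Jt) %*% ft + proj$N_FJt %*% tau0)
}

#' Recover task forces from joint generalized forces
#'
#' The pseudoinverse-transpose map `ft = Jt+' tau`; null-space components of
#' `tau` are annihilated.
#'
#' @param tau joint generalized force (length n, N·m).
#' @param proj a [task_projection()].
#' @return task force vector (length d, N).
#' @export
task_force_inverse_map <- function(tau, proj) {
  stopifnot(inherits(proj, "task_projection"))
  tau <- as_real_vector(tau, "tau", ncol(proj$Jt))
  drop(t(proj$Jt_pinv) %*% tau)
}

#' Map joint torques to muscle forces
#'
#' `fm = -R+' tau + N_TR fm0`: the minimum-norm muscle-force realization of
#' the torque (negative sign convention — muscles do positive work while
#' shortening) plus an arbitrary co-contraction component projected onto the
#' null space of the moment-arm transpose, which leaves the delivered torque
#' `-R' fm = tau` unchanged.
#'
#' @param tau joint torque vector (length n, N·m).
#' @param fm0 arbitrary muscle-force vector (length m, N).
#' @param proj a [muscle_projection()].
#' @return muscle force vector (length m, N).
#' @export
muscle_force_map <- function(tau, fm0, proj) {
  stopifnot(inherits(proj, "muscle_projection"))
  tau <- as_real_vector(tau, "tau", ncol(proj$R))
  fm0 <- as_real_vector(fm0, "fm0", nrow(proj$R))
  drop(-proj$RplusT %*% tau + proj$N_TR %*% fm0)
}

#' Particular muscle-force solution for a commanded motion
#'
#' Computes the particular (null-space-free) muscle-force solution realizing
#' a commanded motion, expressed in any of the three operational spaces:
#'
#' * `route = "task"`: `fm = -Theta' (Lambda_t (xddot + b_t) + Jbar_t' f)`
#'   with `Theta = Jt R+`, from a commanded task acceleration `xddot`;
#' * `route = "joint"`: `fm = -R+' (M qddot + f)` from a commanded joint
#'   acceleration `qddot`;
#' * `route = "muscle"`: `fm = -Lambda_m (lmddot + b_m) - R+' f` from a
#'   commanded muscle-length acceleration `lmddot`.
#'
#' The joint and muscle routes agree identically; the task route agrees with
#' them whenever the realizing torque has no task-null-space component.
#'
#' @inheritParams task_projection
#' @param route one of `"task"`, `"joint"`, `"muscle"`.
#' @param motion the commanded acceleration matching the route: `xddot`
#'   (length d), `qddot` (length n) or `lmddot` (length m).
#' @param lmdot0 free null-space muscle velocity for the muscle route.
#' @param external_torque externally applied generalized force entering `f`.
#' @return particular muscle-force vector (length m, N).
#' @export
particular_muscle_forces <- function(model, state,
                                     route = c("joint", "task", "muscle"),
                                     motion, lmdot0 = NULL,
                                     external_torque = NULL, rtol = 1e-10) {
  route <- match.arg(route)
  state <- check_state(model, state)
  n <- model$n_joints; m <- model$n_muscles
  if (route == "task") {
    proj <- task_projection(model, state, rtol)
    if (!is.null(external_torque)) {
      proj$f <- evaluate_dynamics(model, state, external_torque)$f
    }
    xddot <- as_real_vector(motion, "motion (xddot)", nrow(proj$Jt))
    ft <- drop(proj$Lambda_t %*% (xddot + proj$b_t) + proj$JbarT %*% proj$f)
    drop(-t(proj$Theta) %*% ft)
  } else if (route == "joint") {
    dyn <- evaluate_dynamics(model, state, external_torque)
    qddot <- as_real_vector(motion, "motion (qddot)", n)
    mk <- evaluate_muscle_kinematics(model, state)
    drop(-t(pinv(mk$R, rtol)) %*% (dyn$M %*% qddot + dyn$f))
  } else {
    proj <- muscle_projection(model, state, lmdot0, rtol)
    if (!is.null(external_torque)) {
      proj$f <- evaluate_dynamics(model, state, external_torque)$f
    }
    lmddot <- as_real_vector(motion, "motion (lmddot)", m)
    drop(-proj$Lambda_m %*% (lmddot + proj$b_m) - proj$RplusT %*% proj$f)
  }
}
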