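test_that("reflex control law evaluates the delayed PD formula", {
  params <- reflex_params(kp = 10, kd = 10, lmd = rep(0.2, 3))
  expect_equal(reflex_muscle_goal(rep(0.2, 3), rep(0, 3), params), rep(0, 3))
  # pure damping when the length loop is off
  params0 <- reflex_params(kp = 0, kd = 10, lmd = rep(0.2, 3))
  expect_equal(reflex_muscle_goal(rep(0.25, 3), c(0.1, 0, -0.1), params0),
               c(-1, 0, 1))
  # unit length error, zero velocity: goal = kp per unit error
  expect_equal(reflex_muscle_goal(rep(0.2, 3) - 1, rep(0, 3), params),
               rep(10, 3))
})

test_that("gaussian disturbance has the analytic magnitude and integral", {
  spec <- disturbance_spec(a = 15, t0 = 0.1, sigma = 0.01, direction = c(-1, 0))
  expect_equal(gaussian_disturbance(0.1, spec), c(-15, 0))
  expect_equal(sqrt(sum(gaussian_disturbance(0.11, spec)^2)), 15 * exp(-1))
  # integral over the real line: a sigma sqrt(pi)
  num <- stats::integrate(function(t)
    sapply(t, function(ti) -gaussian_disturbance(ti, spec)[1]),
    -Inf, Inf)$value
  expect_equal(num, 15 * 0.01 * sqrt(pi), tolerance = 1e-6)
  expect_error(disturbance_spec(sigma = 0), "sigma")
})

test_that("sigmoid trajectory has the documented landmarks", {
  spec <- trajectory_spec(a = 0.3, b = 4, t0 = 1, gamma = 0)
  xt0 <- c(0.3, 0.3)
  at_t0 <- sigmoid_task_trajectory(1, xt0, spec)
  expect_equal(at_t0$xd, xt0 + c(0.15, 0))          # half displacement
  expect_equal(at_t0$xddot, c(0.3 * 4 / 2, 0))      # peak speed a b / 2
  expect_equal(at_t0$xdddot, c(0, 0))
  far <- sigmoid_task_trajectory(100, xt0, spec)
  expect_equal(far$xd, xt0 + c(0.3, 0), tolerance = 1e-12)
  # peak speed is attained at t0
  speeds <- vapply(seq(0.5, 1.5, by = 0.01), function(t)
    sigmoid_task_trajectory(t, xt0, spec)$xddot[1], numeric(1))
  expect_equal(which.max(speeds), 51L)
  # rotation moves the displacement, not the start point
  rot <- sigmoid_task_trajectory(1, xt0, trajectory_spec(gamma = pi / 2))
  expect_equal(rot$xd, xt0 + c(0, 0.15), tolerance = 1e-12)
})

test_that("muscle-space controller realizes goals within bounds", {
  model <- default_model
  st <- arm_state(model$q_ref)
  mm <- linear_muscle_model(model$fmax)
  # at rest with zero goal the minimum-norm solution is zero force
  fm <- muscle_space_controller(model, st, rep(0, 9), muscle_model = mm)
  expect_lt(max(abs(fm)), 1e-9)
  # a finite goal: forces within bounds, torque matches the particular solution
  goal <- c(1, -0.5, 0.3, 0.2, -0.4, 0.1, 0.5, -0.2, 0.3)
  fm <- muscle_space_controller(model, st, goal, muscle_model = mm)
  expect_true(all(fm >= -1e-8) && all(fm <= model$fmax + 1e-8))
  mp <- muscle_projection(model, st)
  fm_par <- drop(-mp$Lambda_m %*% (goal + mp$b_m) - mp$RplusT %*% mp$f)
  expect_lt(max(abs(t(mp$R) %*% (fm - fm_par))), 1e-8)
  # infeasible goal errors out
  expect_error(
    muscle_space_controller(model, st, rep(1e5, 9), muscle_model = mm),
    "capacity"
  )
})

test_that("bound clamping preserves torque on the toy interval", {
  # fm_par = (-0.2, 0.8) with bounds [0, 1]: the minimum-norm null correction
  # shifts along (1, -1)/2; hand QP: fm = (0, 0.6) + ... solves to
  # fm = fm_par + 0.2 * (1, -1)
  proj <- toy_muscle_projection()
  fm_par <- c(-0.2, 0.8)
  H <- build_force_inequalities(fm_par, linear_muscle_model(c(1, 1)), proj$N_TR)
  y <- msknull:::minnorm_in_polytope(H$Z, H$beta)
  fm <- fm_par + drop(H$basis %*% y)
  expect_equal(fm, c(0, 0.6), tolerance = 1e-9)
  expect_equal(drop(-t(proj$R) %*% fm), drop(-t(proj$R) %*% fm_par),
               tolerance = 1e-12)
})

test_that("task-space controller output follows the operational-space law", {
  model <- default_model
  st <- arm_state(model$q_ref, c(0.1, -0.2, 0.3))
  tp <- task_projection(model, st)
  xd <- tp$xt; xdot_d <- tp$xtdot     # perfect tracking
  xddot_d <- c(0.4, -0.6)
  out <- task_space_controller(model, st, xd, xdot_d, xddot_d, kp = 50, kd = 5)
  ft_expect <- drop(tp$Lambda_t %*% (xddot_d + tp$b_t) + tp$JbarT %*% tp$f)
  expect_equal(out$ft, ft_expect, tolerance = 1e-12)
  expect_equal(out$tau, drop(t(tp$Jt) %*% out$ft))
  # zero gains: pure feedforward regardless of tracking error
  out0 <- task_space_controller(model, st, xd + 1, xdot_d + 1, xddot_d,
                                kp = 0, kd = 0)
  expect_equal(out0$ft, ft_expect, tolerance = 1e-12)
})

test_that("the simulator is deterministic and respects trivial invariants", {
  model <- default_model
  # no controller, no gravity, zero initial velocity: state frozen
  sim <- simulate_arm(model, NULL, duration = 0.05, dt = 1e-3)
  expect_equal(max(abs(sweep(sim$q, 2, model$q_ref))), 0)
  expect_equal(nrow(sim$q), 51L)      # duration/dt + 1 rows
  # bit-identical reruns
  ctl <- function(t_, state, history, model) list(tau = c(0.1, 0, -0.05))
  a <- simulate_arm(model, ctl, duration = 0.1, dt = 1e-3)
  b <- simulate_arm(model, ctl, duration = 0.1, dt = 1e-3)
  expect_identical(a$q, b$q)
  expect_identical(a$qdot, b$qdot)
  # divergence aborts with a diagnostic
  bad <- function(t_, state, history, model) list(tau = 1e6 * state$qdot + 1)
  expect_error(simulate_arm(model, bad, duration = 1, dt = 1e-3),
               "divergence")
})

test_that("delayed feedback with zero delay equals instantaneous feedback", {
  model <- default_model
  seen <- new.env()
  probe <- function(t_, state, history, model) {
    h <- history(t_ - 0)
    mk <- evaluate_muscle_kinematics(model, state)
    seen$worst <- max(seen$worst %||% 0,
                      max(abs(h$lm - mk$lm)), max(abs(h$q - state$q)))
    list(tau = c(0.05, -0.02, 0.01))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  simulate_arm(model, probe, duration = 0.1, dt = 1e-3,
               state0 = arm_state(model$q_ref, c(0.2, -0.1, 0.1)))
  expect_lt(seen$worst, 1e-12)
})

test_that("reflex and reaching experiments run and settle (short horizon)", {
  model <- default_model
  sim <- run_reflex_experiment(model, duration = 0.3, dt = 1e-3)
  expect_s3_class(sim, "msk_simulation")
  # muscle forces stay within the linear-model bounds at every step
  expect_true(all(sim$fm >= -1e-8))
  expect_true(all(sweep(sim$fm, 2, model$fmax) <= 1e-8))
  # the perturbation actually moved the arm
  expect_gt(max(abs(sweep(sim$q, 2, model$q_ref))), 0.05)

  sim2 <- run_reaching_experiment(model, trajectory_spec(gamma = pi),
                                  duration = 0.5, dt = 1e-3)
  # tracking follows the sigmoid: by 0.5 s the hand has barely moved
  # (midpoint is at t0 = 1 s) but tracking error stays small
  des <- sigmoid_task_trajectory(0.5, sim2$xt[1, ], trajectory_spec(gamma = pi))
  expect_lt(sqrt(sum((sim2$xt[501, ] - des$xd)^2)), 5e-3)
})
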