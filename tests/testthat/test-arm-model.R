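test_that("the bundled model has the documented topology and valid geometry", {
  model <- default_model
  expect_s3_class(model, "planar_arm")
  expect_equal(model$n_joints, 3L)
  expect_equal(model$n_muscles, 9L)
  mk <- evaluate_muscle_kinematics(model, arm_state(model$q_ref))
  expect_equal(dim(mk$R), c(9L, 3L))
  expect_equal(qr(mk$R, tol = 1e-10)$rank, 3L)
  expect_true(all(mk$lm > 0))
})

test_that("parameter invariants are enforced", {
  p <- pendulum_parameters()
  p$mass <- -1
  expect_error(build_planar_arm(p), "mass")
  p <- pendulum_parameters()
  p$com_distance <- 0.5       # > segment length
  expect_error(build_planar_arm(p), "Lc")
  p <- pendulum_parameters()
  p$muscles[[1]]$path$seg <- c(1L, 1L, 1L, 1L)   # spans no joint
  expect_error(build_planar_arm(p), "spans no joint")
  p <- pendulum_parameters()
  p$muscles[[2]]$fmax <- 0
  expect_error(build_planar_arm(p), "fmax")
})

test_that("single pendulum matches the textbook closed form", {
  model <- build_planar_arm(pendulum_parameters())
  dyn <- evaluate_dynamics(model, arm_state(0.3, 0.7))
  expect_equal(dyn$M[1, 1], 0.0075 + 1.0 * 0.15^2, tolerance = 1e-12)
  expect_equal(dyn$f, 0)  # no gravity; 1-DoF has no Coriolis force
})

test_that("inertia matrix is symmetric positive definite and f vanishes at rest", {
  model <- default_model
  dyn0 <- evaluate_dynamics(model, arm_state(model$q_ref))
  expect_equal(dyn0$f, rep(0, 3))
  set.seed(21)
  for (i in 1:25) {
    dyn <- evaluate_dynamics(model, random_state(model))
    expect_lt(max(abs(dyn$M - t(dyn$M))), 1e-12)
    expect_gt(min(eigen(dyn$M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("external torque enters the force term with negative sign", {
  model <- default_model
  tau_ext <- c(0.5, -0.2, 0.1)
  dyn <- evaluate_dynamics(model, arm_state(model$q_ref), tau_ext)
  expect_equal(dyn$f, -tau_ext)
})

test_that("unforced motion with gravity conserves energy", {
  p <- default_arm_parameters()
  p$gravity <- c(0, -9.81)
  model <- build_planar_arm(p)
  st0 <- arm_state(model$q_ref, c(0.5, -0.3, 0.2))
  sim <- simulate_arm(model, NULL, duration = 0.5, dt = 1e-3, state0 = st0)
  E <- vapply(seq_along(sim$time), function(i)
    arm_energy(model, arm_state(sim$q[i, ], sim$qdot[i, ])), numeric(1))
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-5)
})

test_that("closed-form muscle kinematics match finite differences", {
  model <- default_model
  set.seed(22)
  for (i in 1:50) {
    st <- random_state(model)
    mk <- evaluate_muscle_kinematics(model, st)
    # R = d lm / d q
    num_R <- fd_jacobian(function(q)
      evaluate_muscle_kinematics(model, arm_state(q))$lm, st$q)
    expect_lt(max(abs(mk$R - num_R)), 1e-6)
  }
  # Rdot along the motion direction
  st <- arm_state(model$q_ref, c(0.4, -0.6, 0.8))
  h <- 1e-6
  Rp <- evaluate_muscle_kinematics(model, arm_state(st$q + h * st$qdot, st$qdot))$R
  Rm <- evaluate_muscle_kinematics(model, arm_state(st$q - h * st$qdot, st$qdot))$R
  mk <- evaluate_muscle_kinematics(model, st)
  expect_lt(max(abs(mk$Rdot - (Rp - Rm) / (2 * h))), 1e-6)
  expect_equal(mk$lmdot, drop(mk$R %*% st$qdot))
})

test_that("moment arms respect the muscle topology", {
  # mono-articular muscles have zero moment arm at unspanned joints
  mk <- evaluate_muscle_kinematics(default_model, arm_state(default_model$q_ref))
  expect_equal(mk$R["shoulder_flex", 2:3], c(0, 0), ignore_attr = TRUE)
  expect_equal(mk$R["wrist_ext", 1:2], c(0, 0), ignore_attr = TRUE)
  expect_equal(mk$R["biart_sh_el_flex", 3], 0, ignore_attr = TRUE)

  # a mirror-symmetric antagonist pair has equal and opposite moment arms
  model <- build_planar_arm(square_task_parameters())
  p <- square_task_parameters()
  p$muscles[[2]]$path <- p$muscles[[1]]$path
  p$muscles[[2]]$path$y <- -p$muscles[[2]]$path$y
  model <- build_planar_arm(p)
  mk <- evaluate_muscle_kinematics(model, arm_state(c(0, 0.001)))
  expect_equal(mk$R[1, ], -mk$R[2, ], tolerance = 1e-10, ignore_attr = TRUE)

  # degenerate geometry (coincident path points) errors
  p <- pendulum_parameters()
  p$muscles[[1]]$path <- data.frame(seg = c(0L, 1L), x = c(0.05, 0.05),
                                    y = c(0, 0))
  # insertion at (0.05, 0) on segment 1 coincides with the ground point at
  # the zero posture
  model <- build_planar_arm2 <- tryCatch(build_planar_arm(p), error = identity)
  expect_true(inherits(model, "error"))
  expect_match(conditionMessage(model), "degenerate|rank")
})

test_that("task kinematics are exact", {
  model <- default_model
  # fully extended chain points along +x
  tk0 <- evaluate_task_kinematics(model, arm_state(c(0, 0, 0)))
  expect_equal(tk0$xt, c(sum(model$segment_length), 0), tolerance = 1e-12)

  set.seed(23)
  for (i in 1:20) {
    st <- random_state(model)
    tk <- evaluate_task_kinematics(model, st)
    num_J <- fd_jacobian(function(q)
      evaluate_task_kinematics(model, arm_state(q))$xt, st$q)
    expect_lt(max(abs(tk$Jt - num_J)), 1e-6)
    expect_equal(tk$xtdot, drop(tk$Jt %*% st$qdot))
  }

  # xtddot = Jtdot qdot + Jt qddot along an unforced trajectory
  sim <- simulate_arm(model, NULL, duration = 0.2, dt = 1e-3,
                      state0 = arm_state(model$q_ref, c(0.5, -0.4, 0.3)))
  i <- 100
  st <- arm_state(sim$q[i, ], sim$qdot[i, ])
  tk <- evaluate_task_kinematics(model, st)
  xddot_pred <- drop(tk$Jtdot %*% st$qdot + tk$Jt %*% sim$qddot[i, ])
  h <- 1e-3  # one grid step: second central difference of xt
  xddot_num <- (sim$xt[i + 1, ] - 2 * sim$xt[i, ] + sim$xt[i - 1, ]) / h^2
  expect_lt(max(abs(xddot_pred - xddot_num)), 1e-4)
})

test_that("rank pattern holds over the admissible workspace grid", {
  model <- default_model
  gr <- expand.grid(
    q1 = seq(model$q_range[1, 1], model$q_range[1, 2], length.out = 5),
    q2 = seq(model$q_range[2, 1], model$q_range[2, 2], length.out = 5),
    q3 = seq(model$q_range[3, 1], model$q_range[3, 2], length.out = 5)
  )
  for (i in seq_len(nrow(gr))) {
    st <- arm_state(as.numeric(gr[i, ]))
    expect_equal(qr(evaluate_muscle_kinematics(model, st)$R, tol = 1e-10)$rank, 3L)
    expect_equal(qr(evaluate_task_kinematics(model, st)$Jt, tol = 1e-8)$rank, 2L)
  }
})
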