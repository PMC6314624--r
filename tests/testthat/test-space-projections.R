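test_that("task projection decouples null-space forces; the plain MPP does not", {
  model <- default_model
  set.seed(31)
  for (i in 1:10) {
    st <- random_state(model)
    tp <- task_projection(model, st)
    Minv <- solve(tp$M)
    # dynamically consistent inverse: zero task acceleration from null forces
    expect_lt(max(abs(tp$Jt %*% Minv %*% (diag(3) - t(tp$Jt) %*% tp$JbarT))),
              1e-8)
    # the pseudoinverse-based projector leaves a generic residual
    expect_gt(max(abs(tp$Jt %*% Minv %*% (diag(3) - t(tp$Jt) %*% t(tp$Jt_pinv)))),
              1e-4)
    # Lambda_t symmetric positive definite
    expect_lt(max(abs(tp$Lambda_t - t(tp$Lambda_t))), 1e-10)
    expect_gt(min(eigen(tp$Lambda_t, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(tp$b_t, -drop(tp$Jtdot %*% st$qdot))
  }
})

test_that("square task (d = n) has no kinematic redundancy", {
  model <- build_planar_arm(square_task_parameters())
  st <- arm_state(model$q_ref)
  tp <- task_projection(model, st)
  expect_lt(max(abs(tp$N_FJt)), 1e-10)
  # Jbar equals the plain inverse transpose and tau = Jt' ft inverts exactly
  expect_lt(max(abs(tp$JbarT - t(solve(tp$Jt)))), 1e-8)
  ft <- c(3, -2)
  tau <- task_force_map(ft, c(0.5, -0.5), tp)   # tau0 is annihilated
  expect_equal(task_force_inverse_map(tau, tp), ft, tolerance = 1e-10)
})

test_that("task force map and its inverse are consistent", {
  model <- default_model
  st <- arm_state(model$q_ref, c(0.2, -0.1, 0.3))
  tp <- task_projection(model, st)
  ft <- c(5, -2)
  # round trip with no null component
  expect_equal(task_force_inverse_map(task_force_map(ft, rep(0, 3), tp), tp),
               ft, tolerance = 1e-10)
  # pure null input produces no task force
  set.seed(32)
  for (i in 1:10) {
    tau0 <- rnorm(3)
    tau_null <- task_force_map(c(0, 0), tau0, tp)
    expect_lt(max(abs(task_force_inverse_map(tau_null, tp))),
              1e-10 * (1 + max(abs(tau0))))
  }
})

test_that("muscle projection satisfies the inertia-matrix identities", {
  model <- default_model
  set.seed(33)
  for (i in 1:10) {
    st <- random_state(model)
    mp <- muscle_projection(model, st)
    TR <- mp$R %*% mp$R_pinv
    expect_lt(max(abs(mp$Lambda_m - t(mp$Lambda_m))), 1e-8)
    expect_lt(max(abs(mp$Lambda_m %*% TR - mp$Lambda_m)), 1e-8)
    expect_lt(max(abs(mp$Lambda_m %*% pinv(mp$Lambda_m) - TR)), 1e-8)
    expect_lt(max(abs(mp$Lambda_m %*% mp$N_TR)), 1e-8)
    # with lmdot0 = 0 the bias is exactly -Rdot qdot
    expect_equal(mp$b_m, -drop(mp$Rdot %*% st$qdot))
  }
})

test_that("projectors from R and R+' span the same subspaces", {
  model <- default_model
  set.seed(34)
  for (i in 1:10) {
    st <- random_state(model)
    mk <- evaluate_muscle_kinematics(model, st)
    expect_lt(max(abs(projectors(mk$R)$range_proj -
                        projectors(t(pinv(mk$R)))$range_proj)), 1e-10)
  }
})

test_that("null-space projector time derivative matches the analytic formula", {
  # oracle: at full column rank, d(R+)/dt = -R+ Rd R+ + (R'R)^-1 Rd' N_TR,
  # hence Nd_TR = -Rd R+ - R d(R+)/dt
  model <- default_model
  st <- arm_state(model$q_ref, c(0.4, -0.7, 0.5))
  mp <- muscle_projection(model, st)
  Rp <- mp$R_pinv; Rd <- mp$Rdot
  dRp <- -Rp %*% Rd %*% Rp +
    solve(crossprod(mp$R)) %*% t(Rd) %*% mp$N_TR
  Nd_oracle <- -Rd %*% Rp - mp$R %*% dRp
  expect_lt(max(abs(mp$Ndot_TR - Nd_oracle)), 1e-5)
})

test_that("nonzero lmdot0 shifts the muscle bias through Nd_TR", {
  model <- default_model
  st <- arm_state(model$q_ref, c(0.3, -0.2, 0.4))
  lmdot0 <- rnorm(9)
  mp0 <- muscle_projection(model, st)
  mp1 <- muscle_projection(model, st, lmdot0 = lmdot0)
  expect_equal(mp1$b_m, mp0$b_m - drop(mp0$Ndot_TR %*% lmdot0))
})

test_that("muscle force map delivers the torque and hides the null component", {
  proj <- toy_muscle_projection()
  expect_equal(muscle_force_map(-1, c(0, 0), proj), c(0.5, 0.5))
  # null input shifts the force distribution but not the torque
  expect_equal(proj$N_TR, matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  fm <- muscle_force_map(-1, c(1, 0), proj)
  expect_equal(fm, c(1, 0))
  expect_equal(drop(-t(proj$R) %*% fm), -1)
  expect_equal(muscle_force_map(0, c(0, 0), proj), c(0, 0))

  # torque invariance of the null term at scale, on the full model
  model <- default_model
  set.seed(35)
  st <- random_state(model)
  mp <- muscle_projection(model, st)
  for (i in 1:200) {
    v <- rnorm(9)
    expect_lt(max(abs(t(mp$R) %*% (mp$N_TR %*% v))), 1e-8 * sqrt(sum(v^2)))
  }
})

test_that("the three particular-force routes agree where they must", {
  model <- default_model
  set.seed(36)
  for (i in 1:10) {
    st <- random_state(model)
    dyn <- evaluate_dynamics(model, st)
    mp <- muscle_projection(model, st)
    qdd <- rnorm(3)
    fm_joint <- particular_muscle_forces(model, st, "joint", qdd)
    # muscle route with the consistent lmddot = Rd qd + R qdd
    lmdd <- drop(mp$Rdot %*% st$qdot + mp$R %*% qdd)
    fm_muscle <- particular_muscle_forces(model, st, "muscle", lmdd)
    expect_lt(max(abs(fm_joint - fm_muscle)), 1e-8)
    # task route agrees when tau = Jt' ft exactly
    tp <- task_projection(model, st)
    ft <- rnorm(2)
    tau <- drop(t(tp$Jt) %*% ft)
    qdd2 <- drop(solve(dyn$M, tau - dyn$f))
    xdd <- drop(tp$Jt %*% qdd2 + tp$Jtdot %*% st$qdot)
    fm_task <- particular_muscle_forces(model, st, "task", xdd)
    fm_joint2 <- particular_muscle_forces(model, st, "joint", qdd2)
    expect_lt(max(abs(fm_task - fm_joint2)), 1e-8)
  }
  # static, force-free posture needs no muscle force
  expect_equal(particular_muscle_forces(model, arm_state(model$q_ref),
                                        "joint", rep(0, 3)),
               rep(0, 9))
})
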