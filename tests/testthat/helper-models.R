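# Shared fixtures and oracles, all built in code.

default_model <- build_planar_arm()

# axis-aligned cube |y_j| <= 0.5 in R^3, as printed halfspace rows
cube_halfspaces <- function() {
  A <- rbind(c(0, 0, -1), c(0, -1, 0), c(1, 0, 0),
             c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  halfspaces(A, rep(0.5, 6))
}

# single revolute joint with an antagonist muscle pair
pendulum_parameters <- function(gravity = c(0, 0)) {
  list(
    n_joints = 1L,
    segment_length = 0.3, com_distance = 0.15,
    mass = 1.0, inertia = 0.0075,
    gravity = gravity,
    q_ref = 0, q_range = rbind(c(-1, 1.5)),
    task = list(segment = 1L, point = c(0.3, 0)),
    muscles = list(
      list(name = "flex", fmax = 200, path = data.frame(
        seg = c(0L, 0L, 1L, 1L), x = c(-0.10, -0.05, 0.05, 0.10),
        y = c(0.035, 0.03, 0.03, 0.025))),
      list(name = "ext", fmax = 200, path = data.frame(
        seg = c(0L, 0L, 1L, 1L), x = c(-0.07, -0.02, 0.02, 0.07),
        y = -c(0.035, 0.03, 0.03, 0.025)))
    )
  )
}

# two joints, planar position task: square (d = n = 2) Jacobian, no
# kinematic redundancy
square_task_parameters <- function() {
  list(
    n_joints = 2L,
    segment_length = c(0.3, 0.25), com_distance = c(0.13, 0.11),
    mass = c(1.8, 1.1), inertia = c(0.013, 0.006),
    gravity = c(0, 0),
    q_ref = c(0.4, 1.2), q_range = rbind(c(-1, 1.5), c(0.2, 2.2)),
    task = list(segment = 2L, point = c(0.25, 0)),
    muscles = list(
      list(name = "m1f", fmax = 400, path = data.frame(
        seg = c(0L, 1L), x = c(-0.05, 0.05), y = c(0.03, 0.03))),
      list(name = "m1e", fmax = 400, path = data.frame(
        seg = c(0L, 1L), x = c(-0.02, 0.02), y = -c(0.03, 0.03))),
      list(name = "m2f", fmax = 300, path = data.frame(
        seg = c(1L, 2L), x = c(0.25, 0.05), y = c(0.025, 0.025))),
      list(name = "m2e", fmax = 300, path = data.frame(
        seg = c(1L, 2L), x = c(0.28, 0.02), y = -c(0.025, 0.025)))
    )
  )
}

# algebraic 1-DoF / 2-muscle worked example: R = [[1], [1]], built as a bare
# muscle_projection object for the force-map algebra (no linkage behind it)
toy_muscle_projection <- function() {
  R <- matrix(c(1, 1), 2, 1)
  Rp <- pinv(R)
  structure(list(R = R, R_pinv = Rp, RplusT = t(Rp),
                 N_TR = diag(2) - R %*% Rp),
            class = "muscle_projection")
}

random_state <- function(model, scale_qdot = 1) {
  q <- stats::runif(model$n_joints, model$q_range[, 1], model$q_range[, 2])
  arm_state(q, scale_qdot * stats::rnorm(model$n_joints, 0, 0.5))
}

# vertex-set equality up to row order
expect_same_point_set <- function(A, B, tol = 1e-8) {
  expect_equal(nrow(A), nrow(B))
  if (nrow(A) == 0) return(invisible(TRUE))
  ok <- apply(A, 1, function(v) min(apply(abs(sweep(B, 2, v)), 1, max)) < tol)
  expect_true(all(ok))
}

# central finite differences of a vector/matrix-valued function of q
fd_jacobian <- function(f, q, h = 1e-6) {
  cols <- lapply(seq_along(q), function(i) {
    e <- replace(rep(0, length(q)), i, h)
    (f(q + e) - f(q - e)) / (2 * h)
  })
  do.call(cbind, lapply(cols, as.vector))
}
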