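#' @name planar_arm_model
#' @title Analytic planar linkage musculoskeletal model
#'
#' @description
#' An open planar chain of revolute joints actuated by point-to-point muscles.
#' All model quantities — joint-space inertia `M(q)`, bias forces `f(q, qd)`
#' (Coriolis/centrifugal + gravity - external), musculotendon lengths `lm(q)`,
#' moment-arm matrix `R(q) = d lm / d q` and its time derivative, task
#' (end-point) position, Jacobian and Jacobian derivative — are exact closed
#' forms, derived from the Lagrangian of the chain and from Euclidean polyline
#' muscle path lengths. Closed-form derivatives make higher-order terms (`Rd`,
#' `Jtd`, Christoffel symbols) available without numerical differentiation;
#' the test-suite cross-checks every derivative against finite differences.
#'
#' Conventions: joint angles are relative (anatomical) revolute angles,
#' counter-clockwise positive; the zero posture is the chain fully extended
#' along +x; the base joint sits at the origin. Muscle paths are straight
#' polylines through attachment (and optional via) points fixed in segment
#' frames; segment index 0 denotes ground.
NULL

#' Default parameters of the bundled arm model
#'
#' A three-degree-of-freedom, nine-muscle planar arm: three segments
#' (upper arm, forearm, hand) with 50th-percentile anthropometric lengths,
#' masses and rod inertias; three mono-articular antagonist muscle pairs (one
#' per joint) plus three bi-articular muscles (two flexor-side, one
#' extensor-side). The numeric values are a documented stand-in chosen so that
#' the moment-arm matrix keeps full column rank over the admissible joint
#' range; every value can be overridden (see [load_model_config()]).
#'
#' Gravity defaults to zero (posture/reaching experiments in a horizontal
#' plane); set `gravity = c(0, -9.81)` for vertical-plane studies.
#'
#' @return a named list of model parameters accepted by [build_planar_arm()].
#' @export
default_arm_parameters <- function() {
  L <- c(0.31, 0.27, 0.15)
  # Muscle paths are polylines whose only moving parts are the chords that
  # cross a joint between two via points placed symmetrically about it, at
  # along-segment offset d and perpendicular offset h (flexors on +y,
  # extensors on -y). A chord with via points at equal radii keeps the sign
  # of its moment arm over a 180-degree window of joint angle whose position
  # is set by atan(h/d): flexor chords shorten with flexion for angles in
  # (-2 atan(h/d), pi - 2 atan(h/d)), extensor chords lengthen with flexion
  # on the mirrored window. Flexors therefore use d > h (a chord spanning
  # the front of the joint) while extensors use d < h (a chord hugging the
  # back of the joint, pulley-like) — emulating anatomical wrapping without
  # curved-surface geometry. Offsets below are sized so each window covers
  # the joint range with margin. Path segments between points fixed in the
  # same body add (constant) length but no moment arm.
  prox_x <- function(seg) if (seg == 0L) 0 else L[seg]
  mono <- function(name, fmax, joint, s, d, h) {
    a <- joint - 1L
    list(name = name, fmax = fmax, path = data.frame(
      seg = c(a, a, joint, joint),
      x = c(prox_x(a) - d - 0.05, prox_x(a) - d, d, d + 0.05),
      y = s * c(h + 0.005, h, h, h - 0.005)
    ))
  }
  bi <- function(name, fmax, j1, s, d1, h1, d2, h2) {
    a <- j1 - 1L
    list(name = name, fmax = fmax, path = data.frame(
      seg = c(a, j1, j1, j1 + 1L),
      x = c(prox_x(a) - d1, d1, L[j1] - d2, d2),
      y = s * c(h1, h1, h2, h2)
    ))
  }
  list(
    n_joints = 3L,
    segment_length = L,
    com_distance = c(0.135, 0.120, 0.060),
    mass = c(1.96, 1.18, 0.45),
    inertia = c(0.0157, 0.0072, 0.0009),
    gravity = c(0, 0),
    q_ref = c(-0.397, 1.935, 0),
    q_range = rbind(c(-1.0, 1.6), c(0.2, 2.4), c(-1.0, 1.0)),
    task = list(segment = 3L, point = c(0.15, 0)),
    muscles = list(
      mono("shoulder_flex", 800, 1L, +1, 0.050, 0.036),
      mono("shoulder_ext",  800, 1L, -1, 0.028, 0.037),
      mono("elbow_flex",    600, 2L, +1, 0.065, 0.017),
      mono("elbow_ext",     600, 2L, -1, 0.008, 0.038),
      mono("wrist_flex",    300, 3L, +1, 0.030, 0.0121),
      mono("wrist_ext",     300, 3L, -1, 0.010, 0.0248),
      bi("biart_sh_el_flex", 700, 1L, +1, 0.055, 0.040, 0.070, 0.019),
      bi("biart_el_wr_flex", 400, 2L, +1, 0.060, 0.016, 0.028, 0.0113),
      bi("biart_sh_el_ext",  700, 1L, -1, 0.030, 0.040, 0.009, 0.042)
    )
  )
}

#' Build a planar arm model
#'
#' Validates a parameter set (see [default_arm_parameters()] for the schema)
#' and returns a model object used by [evaluate_dynamics()],
#' [evaluate_muscle_kinematics()] and [evaluate_task_kinematics()]. Rejects
#' parameter sets whose moment-arm matrix loses column rank at the reference
#' posture, naming the offending muscles.
#'
#' @param params named parameter list; defaults to the bundled
#'   three-joint, nine-muscle arm.
#' @return an object of class `planar_arm`.
#' @export
build_planar_arm <- function(params = default_arm_parameters()) {
  n <- as.integer(params$n_joints)
  stopifnot(length(n) == 1L, n >= 1L)
  L <- as_real_vector(params$segment_length, "segment_length", n)
  Lc <- as_real_vector(params$com_distance, "com_distance", n)
  mass <- as_real_vector(params$mass, "mass", n)
  inertia <- as_real_vector(params$inertia, "inertia", n)
  gravity <- as_real_vector(params$gravity, "gravity", 2)
  if (any(L <= 0)) stop("segment_length must be strictly positive", call. = FALSE)
  if (any(Lc <= 0) || any(Lc > L)) {
    stop("com_distance must satisfy 0 < Lc <= L", call. = FALSE)
  }
  if (any(mass <= 0)) stop("mass must be strictly positive", call. = FALSE)
  if (any(inertia <= 0)) stop("inertia must be strictly positive", call. = FALSE)

  muscles <- params$muscles
  if (length(muscles) < 1L) stop("at least one muscle is required", call. = FALSE)
  for (mu in muscles) {
    p <- mu$path
    if (!is.data.frame(p) || nrow(p) < 2L ||
        !all(c("seg", "x", "y") %in% names(p))) {
      stop(sprintf("muscle '%s': path must be a data.frame with columns seg, x, y and >= 2 points",
                   mu$name), call. = FALSE)
    }
    if (any(p$seg < 0L) || any(p$seg > n)) {
      stop(sprintf("muscle '%s': host segment out of range", mu$name), call. = FALSE)
    }
    if (max(p$seg) - min(p$seg) < 1L) {
      stop(sprintf("muscle '%s' spans no joint", mu$name), call. = FALSE)
    }
    if (is.null(mu$fmax) || mu$fmax <= 0) {
      stop(sprintf("muscle '%s': fmax must be strictly positive", mu$name),
           call. = FALSE)
    }
  }
  q_ref <- as_real_vector(params$q_ref %||% rep(0, n), "q_ref", n)
  q_range <- params$q_range %||% cbind(rep(-pi, n), rep(pi, n))
  task <- params$task %||% list(segment = n, point = c(L[n], 0))

  model <- structure(
    list(
      n_joints = n,
      n_muscles = length(muscles),
      segment_length = L, com_distance = Lc,
      mass = mass, inertia = inertia, gravity = gravity,
      muscles = muscles,
      muscle_names = vapply(muscles, `[[`, character(1), "name"),
      fmax = vapply(muscles, `[[`, numeric(1), "fmax"),
      q_ref = q_ref, q_range = q_range, task = task
    ),
    class = "planar_arm"
  )

  # geometric sanity at the reference posture
  mk <- evaluate_muscle_kinematics(model, arm_state(q_ref, rep(0, n)))
  r_found <- qr(mk$R, tol = 1e-10)$rank
  if (r_found < n) {
    row_norm <- sqrt(rowSums(mk$R^2))
    weak <- model$muscle_names[row_norm < 1e-8]
    stop(sprintf(
      "moment-arm matrix is rank %d < %d at the reference posture%s",
      r_found, n,
      if (length(weak)) paste0(" (zero moment arms: ", paste(weak, collapse = ", "), ")") else ""
    ), call. = FALSE)
  }
  model
}

#' @export
print.planar_arm <- function(x, ...) {
  cat(sprintf("<planar_arm> %d joints, %d muscles\n", x$n_joints, x$n_muscles))
  cat("  segments [m]:", paste(format(x$segment_length), collapse = ", "), "\n")
  cat("  muscles:", paste(x$muscle_names, collapse = ", "), "\n")
  invisible(x)
}

#' Joint-space state of a model
#'
#' @param q joint angles (radians).
#' @param qdot joint angular velocities (rad/s); defaults to zero.
#' @param time simulation time in seconds.
#' @return an object of class `arm_state`.
#' @export
arm_state <- function(q, qdot = NULL, time = 0) {
  q <- as_real_vector(q, "q")
  qdot <- if (is.null(qdot)) rep(0, length(q)) else as_real_vector(qdot, "qdot", length(q))
  structure(list(q = q, qdot = qdot, time = as.double(time)), class = "arm_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_state <- function(model, state) {
  if (!inherits(state, "arm_state")) state <- arm_state(state$q, state$qdot, state$time %||% 0)
  if (length(state$q) != model$n_joints) {
    stop(sprintf("state dimension %d does not match model (%d joints)",
                 length(state$q), model$n_joints), call. = FALSE)
  }
  state
}

# ---- chain kinematics (closed forms) -------------------------------------
#
# theta_k = sum_{i<=k} q_i; joint k position j_k (j_1 at the origin); the
# Jacobian of any point p carried by segment s has columns
#   dp/dq_i = zhat x (p - j_i)   for i <= s,  0 otherwise,
# and the columns' time derivatives are zhat x (pdot - jdot_i). Both facts
# follow from p = j_s + Rot(theta_s) r with all rotations about +z.

zrot <- function(v) c(-v[2], v[1])  # zhat x v in the plane

chain_kinematics <- function(model, q) {
  n <- model$n_joints
  theta <- cumsum(q)
  ct <- cos(theta); st <- sin(theta)
  joints <- matrix(0, n + 1, 2)
  for (k in seq_len(n)) {
    joints[k + 1, ] <- joints[k, ] + model$segment_length[k] * c(ct[k], st[k])
  }
  # Jacobian of each joint position: joint_jac[[i]] is 2 x n (zero cols l >= i)
  joint_jac <- vector("list", n + 1)
  for (i in seq_len(n + 1)) {
    Ji <- matrix(0, 2, n)
    if (i > 1) for (l in seq_len(i - 1)) Ji[, l] <- zrot(joints[i, ] - joints[l, ])
    joint_jac[[i]] <- Ji
  }
  list(theta = theta, ct = ct, st = st, joints = joints, joint_jac = joint_jac)
}

# world position of a point fixed on segment seg (0 = ground) at local (x, y)
point_position <- function(ck, seg, x, y) {
  if (seg == 0L) return(c(x, y))
  ck$joints[seg, ] + c(x * ck$ct[seg] - y * ck$st[seg],
                       x * ck$st[seg] + y * ck$ct[seg])
}

point_jacobian <- function(ck, seg, p, n) {
  J <- matrix(0, 2, n)
  if (seg >= 1L) for (i in seq_len(seg)) J[, i] <- zrot(p - ck$joints[i, ])
  J
}

# time derivative of a point Jacobian given qdot
point_jacobian_dot <- function(ck, seg, p, J, qdot, n) {
  Jd <- matrix(0, 2, n)
  if (seg >= 1L) {
    pdot <- drop(J %*% qdot)
    for (i in seq_len(seg)) {
      jdot_i <- drop(ck$joint_jac[[i]] %*% qdot)
      Jd[, i] <- zrot(pdot - jdot_i)
    }
  }
  Jd
}

# partial derivative of a point Jacobian with respect to q_l
point_jacobian_partial <- function(ck, seg, p, J, l, n) {
  dJ <- matrix(0, 2, n)
  if (seg >= 1L && l <= seg) {
    dp_dl <- J[, l]
    for (i in seq_len(seg)) {
      dj_dl <- if (l < i) zrot(ck$joints[i, ] - ck$joints[l, ]) else c(0, 0)
      dJ[, i] <- zrot(dp_dl - dj_dl)
    }
  }
  dJ
}

# COM Jacobians and their q-partials, used for M, dM/dq and gravity
com_jacobians <- function(model, ck) {
  n <- model$n_joints
  lapply(seq_len(n), function(k) {
    p <- point_position(ck, k, model$com_distance[k], 0)
    J <- point_jacobian(ck, k, p, n)
    list(p = p, J = J)
  })
}

#' Evaluate joint-space dynamics
#'
#' Returns the joint-space inertia matrix `M(q)` and the aggregate force term
#' `f(q, qd)` of the equations of motion `M qdd + f = tau`. `f` collects
#' Coriolis/centrifugal forces (from the closed-form Christoffel symbols of
#' `M`), the gravity gradient, and minus any externally applied generalized
#' torque, so that `M qdd = tau - f`.
#'
#' @param model a `planar_arm` model.
#' @param state an [arm_state()].
#' @param external_torque externally applied generalized force (N·m, length
#'   n), entering `f` with negative sign.
#' @return list with `M` (n x n, symmetric positive definite) and `f`
#'   (length n).
#' @export
evaluate_dynamics <- function(model, state, external_torque = NULL) {
  state <- check_state(model, state)
  n <- model$n_joints
  tau_ext <- if (is.null(external_torque)) rep(0, n) else
    as_real_vector(external_torque, "external_torque", n)
  ck <- chain_kinematics(model, state$q)
  coms <- com_jacobians(model, ck)

  M <- matrix(0, n, n)
  for (k in seq_len(n)) {
    Jk <- coms[[k]]$J
    M <- M + model$mass[k] * crossprod(Jk)
    M[seq_len(k), seq_len(k)] <- M[seq_len(k), seq_len(k)] + model$inertia[k]
  }
  M <- (M + t(M)) / 2

  # dM/dq_l via the COM Jacobian partials (rotational term is q-independent)
  dM <- array(0, c(n, n, n))
  for (l in seq_len(n)) {
    acc <- matrix(0, n, n)
    for (k in seq_len(n)) {
      if (l > k) next
      Jk <- coms[[k]]$J
      dJk <- point_jacobian_partial(ck, k, coms[[k]]$p, Jk, l, n)
      acc <- acc + model$mass[k] * (crossprod(dJk, Jk) + crossprod(Jk, dJk))
    }
    dM[, , l] <- acc
  }
  qd <- state$qdot
  # Coriolis/centrifugal: h = (sum_l dM/dq_l qd_l) qd - 1/2 d(qd' M qd)/dq
  h <- rep(0, n)
  Mdot <- matrix(0, n, n)
  for (l in seq_len(n)) Mdot <- Mdot + dM[, , l] * qd[l]
  h <- drop(Mdot %*% qd)
  for (i in seq_len(n)) h[i] <- h[i] - 0.5 * drop(t(qd) %*% dM[, , i] %*% qd)

  grav <- rep(0, n)
  if (any(model$gravity != 0)) {
    for (k in seq_len(n)) {
      grav <- grav - model$mass[k] * drop(model$gravity %*% coms[[k]]$J)
    }
  }
  list(M = M, f = h + grav - tau_ext)
}

#' Evaluate muscle kinematics
#'
#' Musculotendon lengths `lm(q)` (polyline lengths of the muscle paths), the
#' moment-arm matrix `R = d lm / d q` (m x n, tall) and its time derivative
#' `Rd`, all as closed forms.
#'
#' @inheritParams evaluate_dynamics
#' @return list with `lm` (length m), `lmdot` (= `R qd`), `R` (m x n) and
#'   `Rdot` (m x n). Row names carry the muscle names.
#' @export
evaluate_muscle_kinematics <- function(model, state) {
  state <- check_state(model, state)
  n <- model$n_joints; m <- model$n_muscles
  ck <- chain_kinematics(model, state$q)
  qd <- state$qdot
  lm <- numeric(m)
  R <- matrix(0, m, n)
  Rd <- matrix(0, m, n)
  for (j in seq_len(m)) {
    path <- model$muscles[[j]]$path
    K <- nrow(path)
    P <- vector("list", K); J <- vector("list", K); Jd <- vector("list", K)
    for (i in seq_len(K)) {
      P[[i]] <- point_position(ck, path$seg[i], path$x[i], path$y[i])
      J[[i]] <- point_jacobian(ck, path$seg[i], P[[i]], n)
      Jd[[i]] <- point_jacobian_dot(ck, path$seg[i], P[[i]], J[[i]], qd, n)
    }
    for (i in seq_len(K - 1)) {
      d <- P[[i + 1]] - P[[i]]
      len <- sqrt(sum(d^2))
      if (len < 1e-9) {
        stop(sprintf("muscle '%s': degenerate path segment (coincident points)",
                     model$muscles[[j]]$name), call. = FALSE)
      }
      dJ <- J[[i + 1]] - J[[i]]
      row <- drop(d %*% dJ) / len
      lm[j] <- lm[j] + len
      R[j, ] <- R[j, ] + row
      ddot <- drop(dJ %*% qd)
      dJd <- Jd[[i + 1]] - Jd[[i]]
      Rd[j, ] <- Rd[j, ] +
        (drop(ddot %*% dJ) + drop(d %*% dJd)) / len -
        row * sum(d * ddot) / len^2
    }
  }
  rownames(R) <- rownames(Rd) <- names(lm) <- model$muscle_names
  list(lm = lm, lmdot = drop(R %*% qd), R = R, Rdot = Rd)
}

#' Evaluate task kinematics
#'
#' Planar position of the task point (by default the tip of the last
#' segment), the task Jacobian `Jt = d g / d q` (d x n with d = 2) and its
#' time derivative — all closed forms.
#'
#' @inheritParams evaluate_dynamics
#' @return list with `xt` (length 2), `xtdot`, `Jt` (2 x n), `Jtdot` (2 x n).
#' @export
evaluate_task_kinematics <- function(model, state) {
  state <- check_state(model, state)
  n <- model$n_joints
  ck <- chain_kinematics(model, state$q)
  seg <- model$task$segment
  pt <- model$task$point
  p <- point_position(ck, seg, pt[1], pt[2])
  J <- point_jacobian(ck, seg, p, n)
  Jd <- point_jacobian_dot(ck, seg, p, J, state$qdot, n)
  list(xt = p, xtdot = drop(J %*% state$qdot), Jt = J, Jtdot = Jd)
}

#' Total mechanical energy of the arm
#'
#' Kinetic plus gravitational potential energy; conserved by unforced,
#' undamped motion (used as an integration-accuracy oracle).
#'
#' @inheritParams evaluate_dynamics
#' @return scalar energy in joules.
#' @export
arm_energy <- function(model, state) {
  state <- check_state(model, state)
  dyn <- evaluate_dynamics(model, state)
  ck <- chain_kinematics(model, state$q)
  V <- 0
  if (any(model$gravity != 0)) {
    for (k in seq_len(model$n_joints)) {
      p <- point_position(ck, k, model$com_distance[k], 0)
      V <- V - model$mass[k] * sum(model$gravity * p)
    }
  }
  0.5 * drop(t(state$qdot) %*% dyn$M %*% state$qdot) + V
}
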