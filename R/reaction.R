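#' Joint reaction forces for a given muscle-force realization
#'
#' Computes the constraint (reaction) forces transmitted across each revolute
#' joint by a recursive Newton-Euler pass over the chain, with every muscle
#' applied as equal-and-opposite tension forces along its path at the
#' attachment (and via) points of its host segments. Pin joints transmit no
#' constraint moment in the plane, so the reaction at joint k follows from
#' the force balance of the distal subchain:
#' `F_k = m_k a_k - m_k g - (muscle forces on segment k) + F_{k+1}`.
#'
#' Reactions depend on the full muscle-force distribution, not only on the
#' net joint torque: null-space (co-contraction) components change them while
#' leaving the movement untouched.
#'
#' @inheritParams evaluate_dynamics
#' @param qddot joint accelerations (length n, rad/s^2).
#' @param fm muscle tensions (length m, N).
#' @return an n x 2 matrix; row k is the planar force exerted by the parent
#'   body on segment k across joint k (N).
#' @export
joint_reaction_forces <- function(model, state, qddot, fm) {
  state <- check_state(model, state)
  n <- model$n_joints
  qddot <- as_real_vector(qddot, "qddot", n)
  fm <- as_real_vector(fm, "fm", model$n_muscles)
  ck <- chain_kinematics(model, state$q)

  # COM accelerations: a = Jc qdd + Jcd qd
  acc <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    p <- point_position(ck, k, model$com_distance[k], 0)
    J <- point_jacobian(ck, k, p, n)
    Jd <- point_jacobian_dot(ck, k, p, J, state$qdot, n)
    acc[k, ] <- drop(J %*% qddot + Jd %*% state$qdot)
  }

  # muscle path forces per segment
  seg_force <- matrix(0, n, 2)
  for (j in seq_len(model$n_muscles)) {
    path <- model$muscles[[j]]$path
    K <- nrow(path)
    P <- lapply(seq_len(K), function(i)
      point_position(ck, path$seg[i], path$x[i], path$y[i]))
    for (i in seq_len(K)) {
      s <- path$seg[i]
      if (s == 0L) next
      Fi <- c(0, 0)
      if (i > 1L) {
        d <- P[[i - 1]] - P[[i]]
        Fi <- Fi + fm[j] * d / sqrt(sum(d^2))
      }
      if (i < K) {
        d <- P[[i + 1]] - P[[i]]
        Fi <- Fi + fm[j] * d / sqrt(sum(d^2))
      }
      seg_force[s, ] <- seg_force[s, ] + Fi
    }
  }

  reactions <- matrix(0, n, 2,
                      dimnames = list(paste0("joint", seq_len(n)), c("fx", "fy")))
  F_next <- c(0, 0)
  for (k in rev(seq_len(n))) {
    Fk <- model$mass[k] * acc[k, ] - model$mass[k] * model$gravity -
      seg_force[k, ] + F_next
    reactions[k, ] <- Fk
    F_next <- Fk
  }
  reactions
}

#' Joint reaction envelopes over the feasible muscle-force set
#'
#' For each time step of a trajectory and every feasible muscle-force sample,
#' computes the joint reaction forces and returns the component-wise
#' per-joint min/max envelope, together with the reactions of the
#' minimum-norm muscle-force solution (the feasible force vector of smallest
#' Euclidean norm). By convexity of the feasible set and linearity of the
#' reaction map in the muscle forces, the vertex-sample envelope brackets the
#' reaction of every feasible realization, the minimum-norm one included.
#'
#' @param model a `planar_arm` model.
#' @param trajectory a list of time points, each a list with `q`, `qdot`,
#'   `qddot` and optionally `time` — e.g. from [trajectory_from_simulation()].
#' @param fsets list of [feasible_force_set()] objects, one per time point.
#' @return an object of class `reaction_envelope`: list with `time`, arrays
#'   `lo`, `hi`, `minnorm` (T x n x 2), and magnitude summaries `mag_lo`,
#'   `mag_hi`, `mag_minnorm` (T x n).
#' @export
joint_reaction_bounds <- function(model, trajectory, fsets) {
  stopifnot(length(trajectory) == length(fsets), length(trajectory) >= 1L)
  Tn <- length(trajectory); n <- model$n_joints
  lo <- hi <- mn <- array(NA_real_, c(Tn, n, 2))
  mag_lo <- mag_hi <- mag_mn <- matrix(NA_real_, Tn, n)
  times <- numeric(Tn)
  for (ti in seq_len(Tn)) {
    tp <- trajectory[[ti]]
    if (is.null(tp$qddot)) {
      stop("trajectory point lacks qddot (joint accelerations are required)",
           call. = FALSE)
    }
    st <- arm_state(tp$q, tp$qdot, tp$time %||% (ti - 1))
    times[ti] <- st$time
    fs <- fsets[[ti]]
    samples <- fs$samples
    reac <- array(0, c(nrow(samples), n, 2))
    for (si in seq_len(nrow(samples))) {
      reac[si, , ] <- joint_reaction_forces(model, st, tp$qddot, samples[si, ])
    }
    lo[ti, , ] <- apply(reac, c(2, 3), min)
    hi[ti, , ] <- apply(reac, c(2, 3), max)
    fm_min <- minnorm_feasible_force(fs)
    mn[ti, , ] <- joint_reaction_forces(model, st, tp$qddot, fm_min)
    mags <- sqrt(reac[, , 1]^2 + reac[, , 2]^2)
    if (is.null(dim(mags))) mags <- matrix(mags, nrow(samples), n)
    mag_lo[ti, ] <- apply(mags, 2, min)
    mag_hi[ti, ] <- apply(mags, 2, max)
    mag_mn[ti, ] <- sqrt(mn[ti, , 1]^2 + mn[ti, , 2]^2)
  }
  structure(
    list(time = times, lo = lo, hi = hi, minnorm = mn,
         mag_lo = mag_lo, mag_hi = mag_hi, mag_minnorm = mag_mn),
    class = "reaction_envelope"
  )
}

#' Minimum-norm feasible muscle-force vector of a feasible force set
#'
#' Solves `min ||fm||^2` over the set's polytope (quadratic program in the
#' reduced null-space coordinates).
#'
#' @param fset a [feasible_force_set()].
#' @return muscle-force vector (length m, N).
#' @export
minnorm_feasible_force <- function(fset) {
  stopifnot(inherits(fset, "feasible_force_set"))
  H <- fset$halfspaces
  r <- H$r
  d <- drop(t(H$basis) %*% fset$fm_par)
  y <- solve_qp_ineq(d, H$Z, H$beta)
  if (is.null(y)) {
    stop("minimum-norm QP failed on a feasible set", call. = FALSE)
  }
  drop(fset$fm_par + H$basis %*% y)
}
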