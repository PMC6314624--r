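#' Halfspace (H-) representation of a convex polytope
#'
#' The system `Z y <= beta` in `r` reduced coordinates. When constructed by
#' [build_force_inequalities()] the object also carries `basis` (m x r,
#' orthonormal) and `origin` (the particular solution `fm_par`), mapping a
#' reduced point `y` back to muscle space as `fm = origin + basis %*% y`.
#'
#' @param Z constraint matrix (rows = halfspaces).
#' @param beta right-hand-side vector.
#' @param basis optional map from reduced coordinates back to the embedding
#'   space.
#' @param origin optional offset in the embedding space.
#' @return an object of class `halfspaces`.
#' @export
halfspaces <- function(Z, beta, basis = NULL, origin = NULL) {
  Z <- as_real_matrix(Z, "Z")
  beta <- as_real_vector(beta, "beta", nrow(Z))
  structure(list(Z = Z, beta = beta, r = ncol(Z),
                 basis = basis, origin = origin),
            class = "halfspaces")
}

#' @export
print.halfspaces <- function(x, ...) {
  cat(sprintf("<halfspaces> %d halfspaces in %d reduced dimension(s)\n",
              nrow(x$Z), x$r))
  invisible(x)
}

#' Build the feasible null-space force inequalities
#'
#' Encodes the physiological force bounds `lo <= fm_par + N_TR fm0 <= hi`
#' (with `(lo, hi) = (0, fmax)` for the linear muscle model) as a bounded
#' halfspace system `Z y <= beta`. The null-space projector is first reduced
#' to a full-column-rank orthonormal basis `B` of its range (dimension
#' `r = m - n` for a full-rank moment-arm matrix) — without this reduction
#' the system is unbounded along the removed directions. Then
#' `Z = rbind(B, -B)` (2m rows) and `beta = c(hi - fm_par, fm_par - lo)`.
#' Any feasible reduced point `y` maps to the muscle-space force
#' `fm = fm_par + B y`.
#'
#' @param fm_par particular muscle-force solution (length m, N).
#' @param muscle_model a [linear_muscle_model()] or [hill_muscle_model()].
#' @param N_TR moment-arm null-space projector (m x m).
#' @param lm,lmdot state-dependent muscle kinematics (Hill hook only).
#' @param rtol relative cutoff for the rank reduction of `N_TR`.
#' @return a [halfspaces()] object with `basis` and `origin` set.
#' @export
build_force_inequalities <- function(fm_par, muscle_model, N_TR,
                                     lm = NULL, lmdot = NULL, rtol = 1e-10) {
  N_TR <- as_real_matrix(N_TR, "N_TR")
  m <- nrow(N_TR)
  fm_par <- as_real_vector(fm_par, "fm_par", m)
  bounds <- force_bounds(muscle_model, lm, lmdot)
  sv <- svd(N_TR)
  keep <- sv$d > rtol * max(sv$d, 1e-300)
  B <- sv$u[, keep, drop = FALSE]
  halfspaces(
    Z = rbind(B, -B),
    beta = c(bounds$hi - fm_par, fm_par - bounds$lo),
    basis = B,
    origin = fm_par
  )
}

# ---- vertex enumeration ---------------------------------------------------

#' Enumerate the vertices of a bounded polytope
#'
#' Converts an H-representation `Z y <= beta` to its V-representation (the
#' set of extreme points). Two independent backends implement the same
#' contract and are pinned against each other in the test-suite:
#'
#' * `"dd"` (default): incremental halfspace insertion (double-description
#'   style) starting from a bounding box obtained by linear programming;
#'   candidate points that are not true vertices (rank of the active
#'   constraint set below `r`) are filtered out, which makes the method
#'   robust to degeneracy.
#' * `"exhaustive"`: the combinatorial reference oracle — intersect every
#'   r-subset of the hyperplanes and keep the feasible intersection points.
#'   Cost grows as `choose(nrow(Z), r)`.
#'
#' @param H a [halfspaces()] object.
#' @param method `"dd"` or `"exhaustive"`.
#' @param tol feasibility tolerance for accepting candidate points.
#' @param dedup_tol absolute tolerance below which two vertices are
#'   considered identical.
#' @return an object of class `vertex_set`: list with `vertices` (k x r
#'   matrix), `dedup_tol`, and `feasible` (FALSE when the system has no
#'   solution, in which case `vertices` has zero rows).
#' @export
enumerate_vertices <- function(H, method = c("dd", "exhaustive"),
                               tol = 1e-8, dedup_tol = 1e-9) {
  stopifnot(inherits(H, "halfspaces"))
  method <- match.arg(method)
  if (!polytope_feasible(H, tol)) {
    return(structure(list(vertices = matrix(0, 0, H$r), dedup_tol = dedup_tol,
                          feasible = FALSE), class = "vertex_set"))
  }
  V <- if (method == "exhaustive") vertices_exhaustive(H, tol)
       else vertices_dd(H, tol)
  V <- dedup_points(V, dedup_tol)
  structure(list(vertices = V, dedup_tol = dedup_tol, feasible = TRUE),
            class = "vertex_set")
}

#' @export
print.vertex_set <- function(x, ...) {
  cat(sprintf("<vertex_set> %d vertices in %d dimension(s)%s\n",
              nrow(x$vertices), ncol(x$vertices),
              if (!x$feasible) " (infeasible system)" else ""))
  invisible(x)
}

# feasibility via the always-well-posed QP min ||y||^2 s.t. Z y <= beta
polytope_feasible <- function(H, tol = 1e-8) {
  y <- minnorm_in_polytope(H$Z, H$beta)
  if (is.null(y)) return(FALSE)
  all(H$Z %*% y <= H$beta + tol * (1 + abs(H$beta)))
}

# min (1/2) y'y + d0'y s.t. Z y <= beta via Goldfarb-Idnani; NULL if infeasible
solve_qp_ineq <- function(d0, Z, beta) {
  r <- ncol(Z)
  ans <- tryCatch(
    quadprog::solve.QP(diag(r), -d0, -t(Z), -beta),
    error = function(e) NULL
  )
  if (is.null(ans) || any(!is.finite(ans$solution))) return(NULL)
  ans$solution
}

# minimum-norm point of {y : Z y <= beta}, or NULL when infeasible
minnorm_in_polytope <- function(Z, beta) {
  r <- ncol(Z)
  if (all(beta >= 0)) return(rep(0, r))  # origin already feasible
  y <- solve_qp_ineq(rep(0, r), Z, beta)
  if (is.null(y)) return(NULL)
  viol <- max(Z %*% y - beta)
  if (viol > 1e-6 * (1 + max(abs(beta)))) return(NULL)
  y
}

# Containing box of the polytope via Lagrange duality: any lambda >= 0 with
# Z' lambda = c certifies max{c'y : Z y <= beta} <= beta' lambda. The least
# squares multiplier is found by a (slightly ridge-regularized) nonnegative QP;
# a direction that cannot be represented (residual stays large) certifies an
# unbounded recession direction, i.e. the system violates the full-column-rank
# boundedness condition.
polytope_box <- function(H, tol = 1e-6) {
  Z <- H$Z; beta <- H$beta; r <- ncol(Z); nh <- nrow(Z)
  # fast path for the paired form Z = [B; -B] with orthonormal B: the exact
  # dual multiplier along c is the split of B c into positive/negative parts
  if (nh %% 2L == 0L) {
    m2 <- nh %/% 2L
    B <- Z[seq_len(m2), , drop = FALSE]
    if (max(abs(Z[m2 + seq_len(m2), , drop = FALSE] + B)) < 1e-12 &&
        max(abs(crossprod(B) - diag(r))) < 1e-10) {
      lo <- hi <- numeric(r)
      for (j in seq_len(r)) {
        mu <- B[, j]
        hi[j] <- sum(beta[seq_len(m2)] * pmax(mu, 0)) +
          sum(beta[m2 + seq_len(m2)] * pmax(-mu, 0))
        lo[j] <- -(sum(beta[seq_len(m2)] * pmax(-mu, 0)) +
                     sum(beta[m2 + seq_len(m2)] * pmax(mu, 0)))
      }
      return(list(lo = lo, hi = hi))
    }
  }
  scale_z <- max(abs(Z), 1)
  C <- Z %*% t(Z) + 1e-9 * scale_z^2 * diag(nh)
  bound_along <- function(cc) {
    ans <- tryCatch(
      quadprog::solve.QP(C, drop(Z %*% cc), diag(nh), rep(0, nh)),
      error = function(e) NULL
    )
    if (is.null(ans) || any(!is.finite(ans$solution))) return(NULL)
    lam <- pmax(ans$solution, 0)
    if (sqrt(sum((drop(crossprod(Z, lam)) - cc)^2)) > tol) return(NULL)
    sum(beta * lam)
  }
  lo <- hi <- numeric(r)
  for (j in seq_len(r)) {
    e <- rep(0, r); e[j] <- 1
    up <- bound_along(e); dn <- bound_along(-e)
    if (is.null(up) || is.null(dn)) {
      stop("polytope is unbounded: a bounded feasible system requires Z of full column rank",
           call. = FALSE)
    }
    hi[j] <- up; lo[j] <- -dn
  }
  list(lo = lo, hi = hi)
}

# reference oracle: intersect every r-subset of hyperplanes, keep feasible
vertices_exhaustive <- function(H, tol = 1e-8) {
  Z <- H$Z; beta <- H$beta; r <- ncol(Z); nh <- nrow(Z)
  scale <- 1 + abs(beta)
  if (r == 0L) return(matrix(0, 1, 0))
  if (nh < r) return(matrix(0, 0, r))
  combs <- utils::combn(nh, r)
  out <- vector("list", ncol(combs))
  k <- 0L
  for (ci in seq_len(ncol(combs))) {
    idx <- combs[, ci]
    Zi <- Z[idx, , drop = FALSE]
    v <- tryCatch(solve(Zi, beta[idx]), error = function(e) NULL)
    if (is.null(v) || any(!is.finite(v))) next
    if (all(Z %*% v <= beta + tol * scale)) {
      k <- k + 1L
      out[[k]] <- v
    }
  }
  if (k == 0L) return(matrix(0, 0, r))
  do.call(rbind, out[seq_len(k)])
}

# production backend: incremental halfspace insertion into a bounding box.
# Vertices kept as rows of V; constraint activity as a logical matrix; pairs
# of kept/cut vertices are adjacency-tested by the size (and, in degenerate
# cases, rank) of their shared active set; candidate points that end up
# supported by fewer than r independent true constraints (box facets
# excluded) are filtered at the end, making the method robust to degeneracy.
vertices_dd <- function(H, tol = 1e-8) {
  Z <- H$Z; beta <- H$beta; r <- ncol(Z)
  if (r == 0L) return(matrix(0, 1, 0))
  if (r == 1L) {  # interval: closed form
    z <- Z[, 1]; up <- beta[z > 0] / z[z > 0]; dn <- beta[z < 0] / z[z < 0]
    return(matrix(c(max(dn), min(up)), 2, 1))
  }
  box <- polytope_box(H, tol)
  pad <- 0.5 * (box$hi - box$lo) + 1
  lo <- box$lo - pad; hi <- box$hi + pad
  corners <- as.matrix(expand.grid(lapply(seq_len(r), function(j) c(lo[j], hi[j]))))
  dimnames(corners) <- NULL
  Zall <- rbind(diag(r), -diag(r), Z)
  ball <- c(hi, -lo, beta)
  nbox <- 2L * r
  scale <- 1 + abs(ball)
  V <- corners
  for (ci in seq_len(nrow(Z))) {
    gidx <- nbox + ci
    g <- drop(V %*% Zall[gidx, ]) - ball[gidx]
    keep <- g <= tol * scale[gidx]
    if (all(keep)) next
    if (!any(keep)) return(matrix(0, 0, r))
    # activity of current vertices against the constraints inserted so far
    act <- abs(Zall[seq_len(gidx - 1L), , drop = FALSE] %*% t(V) -
                 ball[seq_len(gidx - 1L)]) <= tol * scale[seq_len(gidx - 1L)]
    ik <- which(keep); jc <- which(!keep)
    shared_n <- crossprod(act[, ik, drop = FALSE] + 0, act[, jc, drop = FALSE] + 0)
    cand <- which(shared_n >= r - 1L, arr.ind = TRUE)
    newV <- NULL
    if (nrow(cand)) {
      adj <- logical(nrow(cand))
      for (ii in seq_len(nrow(cand))) {
        i <- ik[cand[ii, 1]]; j <- jc[cand[ii, 2]]
        if (shared_n[cand[ii, 1], cand[ii, 2]] == r - 1L) { adj[ii] <- TRUE; next }
        shared <- which(act[, i] & act[, j])
        adj[ii] <- qr(Zall[shared, , drop = FALSE], tol = 1e-12)$rank >= r - 1L
      }
      cand <- cand[adj, , drop = FALSE]
      if (nrow(cand)) {
        gi <- g[ik[cand[, 1]]]; gj <- g[jc[cand[, 2]]]
        t_ <- gi / (gi - gj)
        newV <- V[ik[cand[, 1]], , drop = FALSE] +
          t_ * (V[jc[cand[, 2]], , drop = FALSE] - V[ik[cand[, 1]], , drop = FALSE])
      }
    }
    V <- rbind(V[keep, , drop = FALSE], newV)
    # key-based dedup to bound growth (final output deduped robustly later)
    key <- apply(round(V / 1e-10), 1, paste, collapse = ",")
    V <- V[!duplicated(key), , drop = FALSE]
  }
  # keep only points supported by >= r independent true (non-box) constraints
  act <- abs(Z %*% t(V) - beta) <= tol * scale[-seq_len(nbox)]
  ok <- vapply(seq_len(nrow(V)), function(i) {
    a <- which(act[, i])
    length(a) >= r && qr(Z[a, , drop = FALSE], tol = 1e-12)$rank == r
  }, logical(1))
  V[ok, , drop = FALSE]
}

dedup_index <- function(P, tol) {
  if (nrow(P) <= 1L) return(seq_len(nrow(P)))
  keep <- rep(TRUE, nrow(P))
  # pairwise max-abs distance; quadratic but point counts stay small here
  for (i in seq_len(nrow(P) - 1L)) {
    if (!keep[i]) next
    d <- abs(sweep(P[(i + 1):nrow(P), , drop = FALSE], 2, P[i, ]))
    close <- which(apply(d, 1, max) <= tol) + i
    keep[close] <- FALSE
  }
  which(keep)
}

dedup_points <- function(P, tol) {
  P[dedup_index(P, tol), , drop = FALSE]
}

#' Iterative interior sampling of a bounded polytope
#'
#' Depth 0 returns the vertex set; each further iteration adds the midpoints
#' (`lambda = 0.5`) of all distinct point pairs and removes duplicates. By
#' convexity every returned point satisfies the inequalities. For the
#' axis-aligned cube `|y_j| <= c` this yields 8 vertices at depth 0 and 27
#' distinct points at depth 1 (vertices, edge midpoints, face centers, body
#' center).
#'
#' @inheritParams enumerate_vertices
#' @param depth number of midpoint-refinement iterations (>= 0).
#' @return a k x r matrix of sample points in reduced coordinates.
#' @export
sample_polytope <- function(H, depth = 0L, method = c("dd", "exhaustive"),
                            tol = 1e-8, dedup_tol = 1e-9) {
  vs <- enumerate_vertices(H, method, tol, dedup_tol)
  if (!vs$feasible) {
    stop("cannot sample: the halfspace system is infeasible", call. = FALSE)
  }
  P <- vs$vertices
  depth <- as.integer(depth)
  for (it in seq_len(max(depth, 0L))) {
    k <- nrow(P)
    if (k < 2L) break
    pairs <- utils::combn(k, 2L)
    mids <- (P[pairs[1, ], , drop = FALSE] + P[pairs[2, ], , drop = FALSE]) / 2
    P <- dedup_points(rbind(P, mids), dedup_tol)
  }
  P
}

#' Feasible muscle-force set for a commanded torque
#'
#' Computes the particular muscle-force solution `fm_par = -R+' tau`, builds
#' the bounded null-space inequality system, samples it (vertices plus
#' optional midpoint refinement), and maps every sample back to muscle space:
#' `fm_i = fm_par + N_TR fm0_i`. Every sample respects the muscle-model force
#' bounds and delivers the same joint torque `-R' fm = tau`.
#'
#' @inheritParams task_projection
#' @param tau commanded joint torque (length n, N·m).
#' @param muscle_model a [linear_muscle_model()] or [hill_muscle_model()].
#' @param depth midpoint-refinement depth passed to [sample_polytope()].
#' @param method vertex-enumeration backend.
#' @return an object of class `feasible_force_set`: list with `fm_par`,
#'   `samples` (k x m matrix, one feasible muscle-force vector per row),
#'   `halfspaces`, `muscle_model`, `state_tag` (the state time), `tau`.
#' @export
feasible_force_set <- function(model, state, tau, muscle_model,
                               depth = 0L, method = c("dd", "exhaustive"),
                               rtol = 1e-10) {
  state <- check_state(model, state)
  method <- match.arg(method)
  tau <- as_real_vector(tau, "tau", model$n_joints)
  mk <- evaluate_muscle_kinematics(model, state)
  R_pinv <- pinv(mk$R, rtol)
  fm_par <- drop(-t(R_pinv) %*% tau)
  N_TR <- diag(model$n_muscles) - mk$R %*% R_pinv
  H <- build_force_inequalities(fm_par, muscle_model, N_TR,
                                lm = mk$lm, lmdot = mk$lmdot, rtol = rtol)
  if (!polytope_feasible(H)) {
    stop("task infeasible under muscle bounds: no feasible null-space correction exists",
         call. = FALSE)
  }
  Y <- sample_polytope(H, depth, method)
  samples <- matrix(rep(fm_par, each = nrow(Y)), nrow(Y), model$n_muscles) +
    Y %*% t(H$basis)
  colnames(samples) <- model$muscle_names
  structure(
    list(fm_par = fm_par, samples = samples, halfspaces = H,
         muscle_model = muscle_model, state_tag = state$time, tau = tau),
    class = "feasible_force_set"
  )
}

#' @export
print.feasible_force_set <- function(x, ...) {
  cat(sprintf("<feasible_force_set> %d samples, %d muscles (t = %g s)\n",
              nrow(x$samples), ncol(x$samples), x$state_tag))
  invisible(x)
}

#' Summary statistics of a feasible force set
#'
#' Box-plot statistics (min, lower quartile, median, upper quartile, max) per
#' muscle and the m x m Pearson correlation matrix across samples.
#' Zero-variance muscles yield undefined correlation entries: these are
#' returned as `NA` with the companion logical matrix `defined` set to
#' `FALSE` (self-correlations of degenerate muscles included), rather than
#' propagating `NaN`.
#'
#' @param fset a [feasible_force_set()] (or any k x m sample matrix).
#' @return list with `stats` (data.frame: muscle, min, q25, median, q75,
#'   max), `correlation` (m x m), `defined` (logical m x m).
#' @export
force_space_summary <- function(fset) {
  S <- if (inherits(fset, "feasible_force_set")) fset$samples else as.matrix(fset)
  if (nrow(S) < 2L) {
    stop("at least two samples are required for a force-space summary",
         call. = FALSE)
  }
  qs <- apply(S, 2, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  stats_df <- data.frame(
    muscle = colnames(S) %||% paste0("m", seq_len(ncol(S))),
    min = qs[1, ], q25 = qs[2, ], median = qs[3, ], q75 = qs[4, ], max = qs[5, ],
    row.names = NULL
  )
  sds <- apply(S, 2, stats::sd)
  ok <- sds > 1e-12 * (1 + apply(abs(S), 2, max))
  m <- ncol(S)
  corr <- matrix(NA_real_, m, m, dimnames = list(stats_df$muscle, stats_df$muscle))
  if (any(ok)) {
    corr[ok, ok] <- stats::cor(S[, ok, drop = FALSE])
  }
  defined <- outer(ok, ok, `&`)
  list(stats = stats_df, correlation = corr, defined = defined)
}

# ---- H-representation text format ----------------------------------------

#' Read / write the plain-text H-representation format
#'
#' Line 1: `<number of halfspaces> <dimension>`; each further line holds one
#' row `z_1 ... z_r beta`, whitespace-separated, full decimal precision
#' (exact round-trip).
#'
#' @param path file path.
#' @return `read_hrep` returns a [halfspaces()] object.
#' @export
read_hrep <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("H-representation file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1], quiet = TRUE)
  nh <- as.integer(hdr[1]); r <- as.integer(hdr[2])
  body <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  if (length(body) != nh * (r + 1)) {
    stop(sprintf("malformed H-representation: expected %d values, got %d",
                 nh * (r + 1), length(body)), call. = FALSE)
  }
  Mx <- matrix(body, nh, r + 1, byrow = TRUE)
  halfspaces(Mx[, seq_len(r), drop = FALSE], Mx[, r + 1])
}

#' @rdname read_hrep
#' @param H a [halfspaces()] object.
#' @export
write_hrep <- function(H, path) {
  stopifnot(inherits(H, "halfspaces"))
  rows <- apply(cbind(H$Z, H$beta), 1, function(v)
    paste(format(v, digits = 17, scientific = TRUE, trim = TRUE), collapse = " "))
  writeLines(c(sprintf("%d %d", nrow(H$Z), H$r), rows), path)
  invisible(path)
}
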