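#' Linear muscle model
#'
#' The simplest activation-to-force model `fm = fmax * am` with activations
#' `0 <= am <= 1`, giving force bounds `0 <= fm <= fmax`.
#'
#' @param fmax maximum isometric muscle forces (length m, N).
#' @return an object of class `muscle_model` with `kind = "linear"`.
#' @export
linear_muscle_model <- function(fmax) {
  fmax <- as_real_vector(fmax, "fmax")
  if (any(fmax <= 0)) stop("fmax must be strictly positive", call. = FALSE)
  structure(list(kind = "linear", fmax = fmax), class = "muscle_model")
}

#' Hill-type muscle model hook
#'
#' Affine-in-activation force bounds for a Hill-type muscle:
#' `c0 <= fm <= c1 + c0` with active gain
#' `c1 = fmax * fl(lm / l0) * fv(lmdot / v0)` and passive offset
#' `c0 = fmax * fpe(lm / l0)`. The force-length, force-velocity and passive
#' curves are user-supplied vectorized functions of normalized length /
#' velocity; the bundled defaults (Gaussian bell, logistic sigmoid,
#' exponential passive) are generic stand-in shapes, not fits to any specific
#' muscle.
#'
#' @inheritParams linear_muscle_model
#' @param l0 optimal musculotendon lengths (length m, meters).
#' @param v0 maximum shortening speeds (length m, m/s).
#' @param fl active force-length curve, function of `lm / l0`.
#' @param fv force-velocity curve, function of `lmdot / v0`.
#' @param fpe passive force-length curve, function of `lm / l0`.
#' @return an object of class `muscle_model` with `kind = "hill"`.
#' @export
hill_muscle_model <- function(fmax, l0, v0 = NULL,
                              fl = function(l) exp(-((l - 1) / 0.45)^2),
                              fv = function(v) 1.6 / (1 + exp(4 * v)) ,
                              fpe = function(l) 0.05 * exp(5 * (l - 1.1)) * (l > 1.1)) {
  fmax <- as_real_vector(fmax, "fmax")
  if (any(fmax <= 0)) stop("fmax must be strictly positive", call. = FALSE)
  l0 <- as_real_vector(l0, "l0", length(fmax))
  v0 <- if (is.null(v0)) 10 * l0 else as_real_vector(v0, "v0", length(fmax))
  structure(list(kind = "hill", fmax = fmax, l0 = l0, v0 = v0,
                 fl = fl, fv = fv, fpe = fpe),
            class = "muscle_model")
}

#' Force bounds of a muscle model at a state
#'
#' Lower/upper feasible force per muscle: `(0, fmax)` for the linear model,
#' `(c0, c1 + c0)` for the Hill-type hook.
#'
#' @param muscle_model a [linear_muscle_model()] or [hill_muscle_model()].
#' @param lm musculotendon lengths (needed for the Hill hook).
#' @param lmdot musculotendon velocities (needed for the Hill hook).
#' @return list with numeric vectors `lo` and `hi`.
#' @export
force_bounds <- function(muscle_model, lm = NULL, lmdot = NULL) {
  stopifnot(inherits(muscle_model, "muscle_model"))
  if (muscle_model$kind == "linear") {
    return(list(lo = rep(0, length(muscle_model$fmax)), hi = muscle_model$fmax))
  }
  if (is.null(lm) || is.null(lmdot)) {
    stop("hill-type bounds require lm and lmdot", call. = FALSE)
  }
  ln <- lm / muscle_model$l0
  vn <- lmdot / muscle_model$v0
  c0 <- muscle_model$fmax * muscle_model$fpe(ln)
  c1 <- pmax(muscle_model$fmax * muscle_model$fl(ln) * muscle_model$fv(vn), 0)
  list(lo = c0, hi = c1 + c0)
}

#' @export
print.muscle_model <- function(x, ...) {
  cat(sprintf("<muscle_model> kind '%s', %d muscles\n", x$kind, length(x$fmax)))
  invisible(x)
}
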