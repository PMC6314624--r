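#' Load a model / experiment configuration file
#'
#' Reads a structured YAML configuration whose keys mirror the model
#' parameter names (SI units throughout; see [default_arm_parameters()] for
#' the schema) and validates every invariant by building the model. Unknown
#' keys and invariant violations are rejected with the offending key named.
#'
#' @param path path to a YAML configuration file.
#' @return list with `params` (validated parameter list), `model` (the built
#'   `planar_arm`) and `experiment` (optional experiment parameter list from
#'   the config, if present).
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("n_joints", "segment_length", "com_distance", "mass", "inertia",
             "gravity", "q_ref", "q_range", "task", "muscles", "experiment")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  params <- raw[setdiff(names(raw), "experiment")]
  params$n_joints <- as.integer(params$n_joints)
  for (key in c("segment_length", "com_distance", "mass", "inertia",
                "gravity", "q_ref")) {
    if (!is.null(params[[key]])) params[[key]] <- as.numeric(unlist(params[[key]]))
  }
  if (!is.null(params$q_range)) {
    params$q_range <- do.call(rbind, lapply(params$q_range, as.numeric))
  }
  if (!is.null(params$task)) {
    params$task <- list(segment = as.integer(params$task$segment),
                        point = as.numeric(unlist(params$task$point)))
  }
  params$muscles <- lapply(params$muscles, function(mu) {
    list(name = mu$name, fmax = as.numeric(mu$fmax),
         path = data.frame(seg = as.integer(unlist(mu$path$seg)),
                           x = as.numeric(unlist(mu$path$x)),
                           y = as.numeric(unlist(mu$path$y))))
  })
  model <- tryCatch(build_planar_arm(params), error = function(e) {
    stop(sprintf("invalid configuration '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  list(params = params, model = model, experiment = raw$experiment)
}

#' Save a model parameter set as a YAML configuration
#'
#' Inverse of [load_model_config()]; `load(save(params))` reproduces the
#' parameters exactly (numeric values are written with full precision).
#'
#' @param params parameter list (see [default_arm_parameters()]).
#' @param path output file path.
#' @export
save_model_config <- function(params, path) {
  out <- params
  out$q_range <- lapply(seq_len(nrow(params$q_range)), function(i)
    as.numeric(params$q_range[i, ]))
  out$muscles <- lapply(params$muscles, function(mu) {
    list(name = mu$name, fmax = mu$fmax,
         path = list(seg = as.integer(mu$path$seg),
                     x = as.numeric(mu$path$x),
                     y = as.numeric(mu$path$y)))
  })
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Write simulation time series to CSV
#'
#' One CSV per signal group (joint state, muscle state, task state), each
#' with unit-annotated headers and full double precision, plus a
#' `manifest.json` capturing the resolved run parameters, file digests and a
#' version tag. Written values round-trip exactly through [read_timeseries()].
#'
#' @param result an `msk_simulation`.
#' @param dir output directory (created if missing).
#' @param params optional named list of resolved run parameters recorded in
#'   the manifest.
#' @return invisibly, the manifest path.
#' @export
write_timeseries <- function(result, dir, params = list()) {
  stopifnot(inherits(result, "msk_simulation"))
  if (length(result$time) < 1L) stop("empty simulation result", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory %s", dir), call. = FALSE)
  fmt <- function(M, prefix, unit) {
    M <- as.matrix(M)
    colnames(M) <- sprintf("%s%d_%s", prefix, seq_len(ncol(M)), unit)
    M
  }
  joints <- data.frame(time_s = result$time,
                       fmt(result$q, "q", "rad"),
                       fmt(result$qdot, "qdot", "rad_per_s"),
                       fmt(result$qddot, "qddot", "rad_per_s2"),
                       fmt(result$tau, "tau", "Nm"),
                       check.names = FALSE)
  muscles <- data.frame(time_s = result$time,
                        fmt(result$lm, "lm", "m"),
                        fmt(result$lmdot, "lmdot", "m_per_s"),
                        fmt(result$fm, "fm", "N"),
                        check.names = FALSE)
  task <- data.frame(time_s = result$time,
                     fmt(result$xt, "xt", "m"),
                     fmt(result$ft, "ft", "N"),
                     check.names = FALSE)
  files <- c(joints = "joints.csv", muscles = "muscles.csv", task = "task.csv")
  for (nm in names(files)) {
    df <- get(nm)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
    utils::write.csv(df, file.path(dir, files[[nm]]), row.names = FALSE,
                     quote = FALSE)
  }
  manifest <- list(
    artifact = paste0("msknull ", as.character(utils::packageVersion("msknull"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = c(list(dt_s = result$dt, duration_s = result$duration), params),
    files = as.list(tools::md5sum(file.path(dir, unname(files))))
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest_path)
}

#' Read back time series written by [write_timeseries()]
#'
#' @param dir directory containing the CSV files.
#' @return list of data frames `joints`, `muscles`, `task` and the parsed
#'   `manifest`.
#' @export
read_timeseries <- function(dir) {
  res <- lapply(c(joints = "joints.csv", muscles = "muscles.csv",
                  task = "task.csv"),
                function(f) utils::read.csv(file.path(dir, f), check.names = FALSE))
  res$manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  res
}

#' Deterministic test fixtures
#'
#' Seeded generators for the objects the test-suite exercises:
#'
#' * `"random_model"`: a valid random 3-joint / 9-muscle parameter set
#'   (segment lengths, masses, inertias and attachment offsets jittered
#'   around the defaults), guaranteed to pass [build_planar_arm()]
#'   validation with a full-rank moment-arm matrix at the reference posture;
#' * `"random_polytope"`: a feasible bounded halfspace system in `r`
#'   dimensions (an axis box, which bounds the set, plus random oblique
#'   cuts through the interior);
#' * `"toy_1dof"`: the single-joint, two-muscle worked-example system with
#'   moment-arm matrix `R = [[1], [1]]` and unit maximum forces.
#'
#' All randomness flows from the single `seed`; the global RNG state is
#' restored on exit.
#'
#' @param kind one of `"random_model"`, `"random_polytope"`, `"toy_1dof"`.
#' @param seed integer seed.
#' @param r dimension of the random polytope.
#' @param n_cuts number of random oblique cuts of the random polytope.
#' @return see Details; a parameter list, a [halfspaces()] object, or a list
#'   with `R`, `fmax`, `N_TR`.
#' @export
generate_fixture <- function(kind = c("random_model", "random_polytope", "toy_1dof"),
                             seed, r = 3L, n_cuts = 4L) {
  kind <- match.arg(kind)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  switch(kind,
    toy_1dof = list(
      R = matrix(c(1, 1), 2, 1),
      fmax = c(1, 1),
      N_TR = matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2)
    ),
    random_polytope = {
      box_hw <- stats::runif(r, 0.5, 2)
      cuts <- matrix(stats::rnorm(n_cuts * r), n_cuts, r)
      cuts <- cuts / sqrt(rowSums(cuts^2))
      halfspaces(
        Z = rbind(diag(r), -diag(r), cuts),
        beta = c(box_hw, box_hw, stats::runif(n_cuts, 0.2, 1.5))
      )
    },
    random_model = {
      for (attempt in 1:20) {
        p <- default_arm_parameters()
        jit <- function(x, rel) x * stats::runif(length(x), 1 - rel, 1 + rel)
        p$segment_length <- jit(p$segment_length, 0.2)
        p$com_distance <- pmin(jit(p$com_distance, 0.2), 0.95 * p$segment_length)
        p$mass <- jit(p$mass, 0.3)
        p$inertia <- jit(p$inertia, 0.3)
        p$muscles <- lapply(p$muscles, function(mu) {
          mu$fmax <- jit(mu$fmax, 0.3)
          mu$path$x <- jit(mu$path$x, 0.25)
          mu$path$y <- jit(mu$path$y, 0.25)
          mu
        })
        ok <- tryCatch({ build_planar_arm(p); TRUE }, error = function(e) FALSE)
        if (ok) return(p)
      }
      stop("failed to generate a valid random model in 20 attempts", call. = FALSE)
    }
  )
}
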