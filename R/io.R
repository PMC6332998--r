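#' Load a run configuration from a YAML file
#'
#' An empty or absent-keys file yields the all-defaults configuration
#' (reference parameter table, default cost weights, noise variances and PID
#' gains).  Unknown top-level keys are rejected so typos fail loudly.
#'
#' @param path Path to a YAML configuration file.
#' @return A list of class `run_config` with elements `params`
#'   ([patient_params()]), `weights` ([cost_weights()]), `noise`
#'   ([noise_spec()]), `uncertainty` ([uncertainty_spec()]), `scenario`
#'   (a `scenario`), `controller` (name), `pretrain` (list of pretraining
#'   settings), and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("params", "weights", "noise", "uncertainty", "scenario",
             "controller", "pretrain", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("load_config: unknown keys in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  params <- do.call(patient_params, as.list(raw$params))
  weights <- do.call(cost_weights, modifyList(
    list(), raw$weights %||% list()))
  noise <- do.call(noise_spec, as.list(raw$noise))
  unc <- do.call(uncertainty_spec, as.list(raw$uncertainty))
  scen <- if (is.null(raw$scenario)) default_day("fast") else {
    sc <- raw$scenario
    if (!is.null(sc$tau_class)) {
      do.call(default_day, sc[intersect(names(sc), c("tau_class", "horizon", "dt"))])
    } else {
      meals <- as.data.frame(sc$meals %||% list(t_start = numeric(0),
                                                carbs = numeric(0),
                                                tau_D = numeric(0)))
      make_scenario(meals, horizon = sc$horizon %||% 1440,
                    dt = sc$dt %||% 1, pulse_min = sc$pulse_min %||% 15)
    }
  }
  structure(list(params = params, weights = weights, noise = noise,
                 uncertainty = unc, scenario = scen,
                 controller = raw$controller %||% "rlff",
                 pretrain = raw$pretrain %||% list(),
                 seed = raw$seed %||% 1L),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trajectory as a delimited text table
#'
#' Tab-separated, full float precision, fixed column order; the round trip
#' is lossless.
#'
#' @param traj A `glucose_trajectory` data frame.
#' @param path Output (input) file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the trajectory data frame.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time_min", "D1", "D2", "g", "chi", "g_hat", "chi_hat",
            "u_basal", "u_bolus", "i_total", "cost")
  stopifnot(all(cols %in% names(traj)))
  ok <- tryCatch({
    utils::write.table(format(traj[cols], digits = 17, trim = TRUE,
                              scientific = NA),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e)
    stop("write_trajectory: cannot write ", path, ": ",
         conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path))
    stop("read_trajectory: no such file: ", path, call. = FALSE)
  tr <- utils::read.table(path, header = TRUE, sep = "\t")
  class(tr) <- c("glucose_trajectory", "data.frame")
  tr
}

#' Serialise a pretrained kernel (and its metadata) to JSON
#'
#' @param result A `pretrain_result` from [pretrain()] (or a list with
#'   `kernel` and `policy`).
#' @param path Output JSON path.
#' @param meta Optional named list of extra metadata (seed, episodes, ...).
#' @return `write_kernel` returns `path` invisibly; `read_kernel` returns a
#'   list with `kernel`, `policy` and `meta`.
#' @export
write_kernel <- function(result, path, meta = list()) {
  obj <- list(w = result$kernel$w,
              P = result$kernel$P,
              K = result$policy$K,
              i_be = result$policy$i_be,
              meta = meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(kernel = qkernel(matrix(obj$w, 3, 3)),
       policy = rl_policy(K = obj$K, i_be = obj$i_be),
       meta = obj$meta)
}

# Provenance block written alongside CLI outputs.
provenance <- function(config_path, seed) {
  list(package = "rlglucose",
       version = as.character(utils::packageVersion("rlglucose")),
       config = config_path,
       config_sha = if (!is.null(config_path) && file.exists(config_path))
         unname(tools::md5sum(config_path)) else NA,
       seed = seed,
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}
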