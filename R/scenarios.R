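#' Construct a meal scenario
#'
#' A scenario couples a meal table to a simulation horizon and sampling
#' interval.  Each meal has a true start time, carbohydrate mass and
#' absorption constant, plus announced counterparts (what the controller is
#' told); by default announcements equal the truth.
#'
#' @param meals Data frame with columns `t_start` (min), `carbs` (g),
#'   `tau_D` (min).  Announced columns are added if absent.
#' @param horizon Simulation horizon (min).
#' @param dt Sampling interval (min).
#' @param pulse_min Duration of the rectangular meal pulse (min).
#' @return A list of class `scenario`.
#' @export
make_scenario <- function(meals, horizon = 1440, dt = 1, pulse_min = 15) {
  if (is.null(meals$announced_t_start)) meals$announced_t_start <- meals$t_start
  if (is.null(meals$announced_carbs)) meals$announced_carbs <- meals$carbs
  if (is.null(meals$announced_tau_D)) meals$announced_tau_D <- meals$tau_D
  if (nrow(meals) > 0) {
    stopifnot(all(meals$t_start >= 0), all(meals$carbs >= 0),
              all(meals$tau_D > 0))
    if (horizon < max(meals$t_start) + 300)
      stop("make_scenario: horizon should extend at least 300 min past the last meal",
           call. = FALSE)
  }
  structure(list(meals = meals, horizon = horizon, dt = dt,
                 pulse_min = pulse_min),
            class = "scenario")
}

#' Default daily meal scenario
#'
#' Three meals over a 24 h day: 50 g carbohydrate at 08:00, 70 g at 13:00 and
#' 60 g at 19:00 (t = 480, 780, 1140 min), with the absorption class setting
#' every meal's time constant: `"fast"` uses tau_D = 10 min, `"slow"` uses
#' tau_D = 50 min.  These amounts are this package's declared reference day
#' for all comparative experiments; they are ordinary mixed-meal sizes, not
#' taken from any particular dataset.
#'
#' @param tau_class `"fast"` or `"slow"` glucose absorption.
#' @param horizon Simulation horizon (min, default 24 h).
#' @param dt Sampling interval (min).
#' @return A `scenario` object.
#' @examples
#' default_day("fast")$meals
#' @export
default_day <- function(tau_class = c("fast", "slow"), horizon = 1440, dt = 1) {
  tau_class <- match.arg(tau_class)
  tau <- if (tau_class == "fast") 10 else 50
  meals <- data.frame(t_start = c(480, 780, 1140),
                      carbs = c(50, 70, 60),
                      tau_D = tau)
  sc <- make_scenario(meals, horizon = horizon, dt = dt)
  sc$tau_class <- tau_class
  sc
}

#' Perturb announced meal information
#'
#' Draws the announced carbohydrate mass from a Gaussian centred on the true
#' mass with relative standard deviation `spec$cho_sd_frac` (truncated at 0),
#' and the announced start time from a Gaussian centred on the true time with
#' standard deviation `spec$time_sd_min` minutes (truncated at 0).  True
#' meals are untouched: the plant digests the truth while the controller
#' sees the announcement.
#'
#' @param scenario A `scenario` object.
#' @param spec An [uncertainty_spec()].
#' @param seed Optional integer seed.
#' @return The scenario with perturbed announced columns.
#' @export
perturb_scenario <- function(scenario, spec, seed = NULL) {
  with_local_seed(seed, {
    m <- scenario$meals
    if (nrow(m) > 0) {
      m$announced_carbs <- pmax(0, rnorm(nrow(m), m$carbs,
                                         spec$cho_sd_frac * m$carbs))
      m$announced_t_start <- pmax(0, rnorm(nrow(m), m$t_start, spec$time_sd_min))
    }
    scenario$meals <- m
    scenario
  })
}

# Build the named controller over a shared pretrained policy/filter and the
# scenario's announced meals.
build_controller <- function(name, scenario, policy, filter, params,
                             g_d = params$g_b) {
  ann_rate <- meal_rate_fn(scenario$meals, params,
                           pulse_min = scenario$pulse_min, announced = TRUE)
  switch(name,
    rlff = {
      prof <- bolus_profile(scenario$meals, scenario$horizon, scenario$dt,
                            params, g_d = g_d, pulse_min = scenario$pulse_min)
      controller_rlff(policy, filter, prof, announced_meal_rate = ann_rate)
    },
    orl = controller_orl(policy, filter, announced_meal_rate = ann_rate),
    pid = controller_pid(i_be = params$i_be, g_d = g_d),
    constant = controller_constant(i_be = params$i_be),
    stop("unknown controller: ", name, call. = FALSE))
}

#' Compare controllers on a common scenario
#'
#' Runs each requested controller on the identical scenario (same meals,
#' same seed, shared pretrained policy for RLFF and ORL) and tabulates the
#' trajectory metrics plus the relative peak reduction of the first
#' controller against each other one.
#'
#' @param scenario A `scenario` object.
#' @param policy Pretrained [rl_policy()] shared by RLFF and ORL.
#' @param params A [patient_params()] object.
#' @param controllers Character vector from `c("rlff", "orl", "pid")`.
#' @param filter Optional `kalman_filter`; designed from defaults if `NULL`.
#' @param g_d Glucose target (mg/dL).
#' @param keep_trajectories Return the full trajectories as well.
#' @return A list with `metrics` (one row per controller, including
#'   `peak_reduction_vs_<other>` columns in percent for the first
#'   controller) and optionally `trajectories`.
#' @export
run_comparison <- function(scenario, policy, params = patient_params(),
                           controllers = c("rlff", "orl", "pid"),
                           filter = NULL, g_d = params$g_b,
                           keep_trajectories = FALSE) {
  if (is.null(filter)) filter <- design_kalman(params, g_d, dt = scenario$dt)
  trajs <- list()
  mets <- list()
  for (nm in controllers) {
    ctl <- build_controller(nm, scenario, policy, filter, params, g_d)
    tr <- tryCatch(simulate_closed_loop(scenario, ctl, params, g_d = g_d),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      warning("controller '", nm, "' diverged: ", conditionMessage(tr))
      mets[[nm]] <- data.frame(peak_excursion = NA_real_, undershoot = NA_real_,
                               fluctuation_range = NA_real_,
                               settling_min = NA_real_, total_cost = NA_real_)
      next
    }
    trajs[[nm]] <- tr
    mets[[nm]] <- trajectory_metrics(tr, g_d)
  }
  metrics <- do.call(rbind, mets)
  metrics <- cbind(controller = names(mets), metrics)
  rownames(metrics) <- NULL
  ref <- controllers[1]
  for (other in setdiff(controllers, ref)) {
    pk_ref <- metrics$peak_excursion[metrics$controller == ref]
    pk_oth <- metrics$peak_excursion[metrics$controller == other]
    metrics[[paste0("peak_reduction_vs_", other)]] <-
      ifelse(metrics$controller == ref, 100 * (pk_oth - pk_ref) / pk_oth, NA)
  }
  out <- list(metrics = metrics)
  if (keep_trajectories) out$trajectories <- trajs
  out
}

#' Monte-Carlo uncertainty study of meal-information errors
#'
#' Repeats the closed-loop day `spec$n_reps` times, each time perturbing the
#' announced meal information ([perturb_scenario()]) while the plant receives
#' the true meals, and computes the per-time mean and standard deviation of
#' glucose across repetitions.
#'
#' @param scenario A `scenario` object (nominal announcements).
#' @param spec An [uncertainty_spec()] (needs `n_reps >= 2`).
#' @param policy Pretrained [rl_policy()].
#' @param params A [patient_params()] object.
#' @param controller Controller name (default `"rlff"`).
#' @param filter Optional `kalman_filter`.
#' @param g_d Glucose target (mg/dL).
#' @param seed Integer seed; repetition r uses sub-seed `seed + r`.
#' @return A list with `bands` (data frame `time_min, mean_g, sd_g, upper,
#'   lower` where upper/lower are mean +/- one SD) and `extremes`
#'   (`upper_above_target` = max of `upper - g_d`, `lower_below_target` =
#'   max of `g_d - lower`).
#' @export
run_uncertainty <- function(scenario, spec, policy, params = patient_params(),
                            controller = "rlff", filter = NULL,
                            g_d = params$g_b, seed = 1) {
  if (spec$n_reps < 2)
    stop("run_uncertainty: need n_reps >= 2 to form standard deviation bands",
         call. = FALSE)
  if (is.null(filter)) filter <- design_kalman(params, g_d, dt = scenario$dt)
  G <- NULL
  for (r in seq_len(spec$n_reps)) {
    sc_r <- perturb_scenario(scenario, spec, seed = seed + r)
    ctl <- build_controller(controller, sc_r, policy, filter, params, g_d)
    tr <- simulate_closed_loop(sc_r, ctl, params, g_d = g_d)
    if (is.null(G)) G <- matrix(NA_real_, length(tr$g), spec$n_reps)
    G[, r] <- tr$g
  }
  mean_g <- rowMeans(G)
  sd_g <- apply(G, 1, stats::sd)
  bands <- data.frame(time_min = seq(0, scenario$horizon, by = scenario$dt),
                      mean_g = mean_g, sd_g = sd_g,
                      upper = mean_g + sd_g, lower = mean_g - sd_g)
  list(bands = bands,
       extremes = data.frame(
         upper_above_target = max(bands$upper - g_d),
         lower_below_target = max(g_d - bands$lower)))
}
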