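#' Closed-loop simulation of a meal scenario
#'
#' Integrates the nonlinear plant under a feedback controller sampled every
#' `dt` minutes.  At each sample the controller sees the measured glucose
#' deviation (optionally noisy), commands a total insulin concentration
#' (basal adjustment + equilibrium basal + feedforward bolus, clamped at
#' zero), and the plant is advanced with inputs held over the interval.
#'
#' @param scenario A scenario from [default_day()] or [make_scenario()].
#' @param controller A controller object (see [controller_rlff()],
#'   [controller_pid()], ...).
#' @param params A [patient_params()] object.
#' @param weights Cost weights used for the recorded per-step cost.
#' @param g_d Glucose target (mg/dL).
#' @param state0 Initial plant state; defaults to the basal equilibrium.
#' @param measurement_sd Standard deviation of additive Gaussian glucose
#'   measurement noise (mg/dL); 0 (default) gives noiseless measurements.
#' @param seed Optional seed for the measurement noise.
#' @return A data frame of class `glucose_trajectory` with one row per
#'   sample and columns `time_min, D1, D2, g, chi, g_hat, chi_hat, u_basal,
#'   u_bolus, i_total, cost`.  The number of insulin-clamping events is
#'   attached as attribute `"n_clamped"`.
#' @examples
#' sc <- default_day("fast", horizon = 120)
#' sc$meals <- sc$meals[0, ]  # fasting
#' tr <- simulate_closed_loop(sc, controller_constant(), patient_params())
#' range(tr$g)  # stays at basal
#' @export
simulate_closed_loop <- function(scenario, controller, params,
                                 weights = cost_weights(), g_d = params$g_b,
                                 state0 = c(0, 0, params$g_b, 0),
                                 measurement_sd = 0, seed = NULL) {
  dt <- scenario$dt
  n_steps <- round(scenario$horizon / dt)
  times <- seq(0, scenario$horizon, by = dt)
  true_rate <- meal_rate_fn(scenario$meals, params,
                            pulse_min = scenario$pulse_min)
  tau_sim <- if (!is.null(scenario$meals) && nrow(scenario$meals) > 0)
    scenario$meals$tau_D[1] else params$tau_D

  with_local_seed(seed, {
    noise <- if (measurement_sd > 0)
      rnorm(n_steps + 1, 0, measurement_sd) else numeric(n_steps + 1)

    out <- matrix(NA_real_, n_steps + 1, 11)
    colnames(out) <- c("time_min", "D1", "D2", "g", "chi", "g_hat", "chi_hat",
                       "u_basal", "u_bolus", "i_total", "cost")
    s <- state0
    ctx <- controller$init(s[3] - g_d + noise[1])
    n_clamped <- 0L
    for (k in seq_len(n_steps + 1)) {
      t <- times[k]
      y <- s[3] - g_d + noise[k]
      x_hat_pre <- if (!is.null(ctx$x_hat)) ctx$x_hat else c(0, 0, y, 0)
      a <- tryCatch(controller$act(ctx, y, k, t), error = function(e)
        stop(sprintf("controller '%s' failed at t = %g min (g = %.2f): %s",
                     controller$name, t, s[3], conditionMessage(e)),
             call. = FALSE))
      ctx <- a$ctx
      i_raw <- params$i_be + a$u_basal_dev + a$u_bolus
      i_total <- max(0, i_raw)
      if (i_raw < 0) n_clamped <- n_clamped + 1L
      out[k, ] <- c(t, s[1], s[2], s[3], s[4],
                    x_hat_pre[3] + g_d, x_hat_pre[4],
                    params$i_be + a$u_basal_dev, a$u_bolus, i_total,
                    rl_cost(a$x_ctrl, a$u_basal_dev, weights))
      if (k <= n_steps) {
        s <- plant_step(s, i_total, true_rate(t), dt, params, tau_D = tau_sim)
        if (!all(is.finite(s)))
          stop(sprintf("plant state became non-finite at t = %g min under controller '%s'",
                       t + dt, controller$name), call. = FALSE)
      }
    }
    tr <- as.data.frame(out)
    class(tr) <- c("glucose_trajectory", "data.frame")
    attr(tr, "controller") <- controller$name
    attr(tr, "n_clamped") <- n_clamped
    tr
  })
}

#' Summary metrics of a glucose trajectory
#'
#' @param traj A `glucose_trajectory` from [simulate_closed_loop()].
#' @param g_d Glucose target (mg/dL).
#' @param settle_band Half-width (mg/dL) of the band used for the settling
#'   time.
#' @return A one-row data frame: `peak_excursion` (max of `g - g_d`, floored
#'   at 0), `undershoot` (max of `g_d - g`, floored at 0),
#'   `fluctuation_range` (max absolute deviation), `settling_min` (first
#'   time after which `|g - g_d|` stays inside the band; `NA` if never), and
#'   `total_cost`.
#' @export
trajectory_metrics <- function(traj, g_d = 80, settle_band = 2) {
  dev <- traj$g - g_d
  inside <- abs(dev) <= settle_band
  settled_from <- if (all(!inside)) NA_real_ else {
    idx <- which(rev(cumprod(rev(inside))) == 1)
    traj$time_min[idx[1]]
  }
  data.frame(peak_excursion = max(c(dev, 0)),
             undershoot = max(c(-dev, 0)),
             fluctuation_range = max(abs(dev)),
             settling_min = settled_from,
             total_cost = sum(traj$cost))
}
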