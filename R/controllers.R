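# Controllers share a small functional interface: a list with
#   $init(y0)            -> ctx     (internal state, e.g. filter estimate)
#   $act(ctx, y, k, t)   -> list(u_basal_dev, u_bolus, x_ctrl, ctx)
# where y is the measured glucose deviation, k the sample index (1-based),
# t the clock time.  u_basal_dev is the basal adjustment relative to i_be,
# u_bolus the feedforward increment; simulate_closed_loop() forms the total
# insulin and clamps it at zero.

new_controller <- function(name, init, act) {
  structure(list(name = name, init = init, act = act), class = "glucose_controller")
}

#' Reinforcement-learning basal controller with feedforward bolus (RLFF)
#'
#' Combines the pretrained basal policy acting on `(measured g - g_d,
#' estimated chi)` with the precomputed feedforward bolus profile for the
#' announced meals.  The interstitial activity estimate comes from the
#' steady-state Kalman filter, which is also fed the announced meal rate so
#' that estimation quality degrades gracefully when announcements are wrong.
#'
#' @param policy An [rl_policy()] (typically from [pretrain()]).
#' @param filter A `kalman_filter` from [design_kalman()].
#' @param profile A [bolus_profile()] sampled on the simulation grid, or
#'   `NULL` for no bolus (then the controller is the ORL controller).
#' @param announced_meal_rate Function of time giving the announced meal rate
#'   (mmol/min) supplied to the filter.
#' @return A controller object for [simulate_closed_loop()].
#' @export
controller_rlff <- function(policy, filter, profile,
                            announced_meal_rate = function(t) 0) {
  ub <- if (is.null(profile)) NULL else profile$u_bolus
  new_controller(
    name = if (is.null(profile)) "orl" else "rlff",
    init = function(y0) list(x_hat = c(0, 0, y0, 0)),
    act = function(ctx, y, k, t) {
      x_ctrl <- c(y, ctx$x_hat[4])
      u_basal_dev <- sum(policy$K * x_ctrl)
      u_bolus <- if (is.null(ub) || k > length(ub)) 0 else ub[k]
      i_total <- max(0, policy$i_be + u_basal_dev + u_bolus)
      ctx$x_hat <- estimate_update(ctx$x_hat,
                                   u = c(announced_meal_rate(t),
                                         i_total - policy$i_be),
                                   y = y, filter = filter)
      list(u_basal_dev = u_basal_dev, u_bolus = u_bolus, x_ctrl = x_ctrl,
           ctx = ctx)
    })
}

#' Optimal-RL comparison controller (basal updates only, no bolus)
#'
#' Identical policy, filter and parameters as the RLFF controller but without
#' the feedforward bolus, isolating the contribution of meal compensation.
#'
#' @inheritParams controller_rlff
#' @return A controller object.
#' @export
controller_orl <- function(policy, filter,
                           announced_meal_rate = function(t) 0) {
  controller_rlff(policy, filter, profile = NULL,
                  announced_meal_rate = announced_meal_rate)
}

#' PID comparison controller
#'
#' Textbook proportional-integral-derivative law on the measured glucose:
#' `u_k = Kp e_k + Ki sum(e) + Kd (g_k - g_{k-1})`, with the derivative
#' acting on the raw measurement.  No anti-windup by default (matching the
#' reference tuning); `anti_windup = TRUE` freezes the integral while the
#' total insulin command is clamped at zero.
#'
#' @param Kp,Ki,Kd PID gains (defaults 1, 0.001, 0.01).
#' @param i_be Basal insulin the adjustment is added to (uIU/ml).
#' @param g_d Glucose target (mg/dL).
#' @param anti_windup Conditional integration flag (default off).
#' @return A controller object for [simulate_closed_loop()].
#' @export
controller_pid <- function(Kp = 1, Ki = 0.001, Kd = 0.01,
                           i_be = patient_params()$i_be,
                           g_d = patient_params()$g_b,
                           anti_windup = FALSE) {
  new_controller(
    name = "pid",
    init = function(y0) list(esum = 0, g_prev = NA_real_),
    act = function(ctx, y, k, t) {
      g <- y + g_d
      dterm <- if (is.na(ctx$g_prev)) 0 else g - ctx$g_prev
      u <- Kp * y + Ki * (ctx$esum + y) + Kd * dterm
      clamped <- (i_be + u) < 0
      if (!anti_windup || !clamped) ctx$esum <- ctx$esum + y
      ctx$g_prev <- g
      list(u_basal_dev = u, u_bolus = 0, x_ctrl = c(y, 0), ctx = ctx)
    })
}

#' Constant basal controller
#'
#' Holds insulin at the equilibrium basal concentration; useful as an
#' open-loop reference and for equilibrium tests.
#'
#' @param i_be Basal insulin concentration (uIU/ml).
#' @return A controller object.
#' @export
controller_constant <- function(i_be = patient_params()$i_be) {
  new_controller(
    name = "constant",
    init = function(y0) list(),
    act = function(ctx, y, k, t)
      list(u_basal_dev = 0, u_bolus = 0, x_ctrl = c(y, 0), ctx = ctx))
}
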