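#' Transfer functions of the meal, insulin and feedforward submodels
#'
#' `meal_tf` is the two-compartment carbohydrate absorption chain from intake
#' rate to glucose appearance, `A_G / (tau_D s + 1)^2`; `insulin_tf` is the
#' first-order interstitial activity response to plasma insulin,
#' `p3 / (s + p2)`; and `ff_frequency_response` is the inverse-model
#' feedforward `-meal_tf / insulin_tf = -A_G (s + p2) / (p3 (tau_D s + 1)^2)`,
#' designed so that `meal_tf(s) + ff(s) * insulin_tf(s) = 0` identically.
#'
#' @param s Complex (or real) Laplace variable; vectorised.
#' @param params A [patient_params()] object.
#' @param tau_D Absorption constant (min); defaults to `params$tau_D`.
#' @return Complex frequency response value(s).
#' @examples
#' ff_frequency_response(0, patient_params())  # DC gain -A_G p2 / p3
#' @export
ff_frequency_response <- function(s, params, tau_D = params$tau_D) {
  pole <- abs(tau_D * s + 1)
  if (any(pole < 1e-12))
    stop("ff_frequency_response: evaluation at the double pole s = -1/tau_D",
         call. = FALSE)
  -params$A_G * (s + params$p2) / (params$p3 * (tau_D * s + 1)^2)
}

#' @rdname ff_frequency_response
#' @export
meal_tf <- function(s, params, tau_D = params$tau_D) {
  params$A_G / (tau_D * s + 1)^2
}

#' @rdname ff_frequency_response
#' @export
insulin_tf <- function(s, params) {
  params$p3 / (s + params$p2)
}

# Companion-form realisation of the bolus generator.  The inverse model is
# realised in state space so the (s + p2) numerator never differentiates the
# meal signal numerically:
#   den(s) q = D(s),  u = b1 q' + b0 q,
# with den = a2 s^2 + a1 s + a0.  `scale = "insulin"` divides the raw inverse
# model output by -g_d, turning it into the insulin concentration increment
# that cancels the meal on the linearised plant (the chi -> glucose coupling
# has gain -g_d); `scale = "raw"` returns the unscaled inverse-model output.
ff_realization <- function(params, g_d, tau_D, scale = c("insulin", "raw")) {
  scale <- match.arg(scale)
  sgn <- if (scale == "insulin") -1 / g_d else 1
  list(a2 = params$p3 * tau_D^2, a1 = 2 * params$p3 * tau_D, a0 = params$p3,
       b1 = sgn * -params$A_G, b0 = sgn * -params$A_G * params$p2)
}

#' One Runge-Kutta step of the bolus generator dynamics
#'
#' Advances the companion-form state `(q, q')` of the second-order inverse
#' model `p3 tau_D^2 u'' + 2 p3 tau_D u' + p3 u = forcing(D)` by one step,
#' with the meal rate held constant over the step.
#'
#' @param q State 2-vector `(q, dq/dt)` of the companion realisation.
#' @param D Meal intake rate over the step (mmol/min).
#' @param dt Step (min), positive.
#' @param params A [patient_params()] object.
#' @param tau_D Absorption constant of the meal being compensated (min).
#' @return Updated state 2-vector.
#' @export
bolus_ode_step <- function(q, D, dt, params, tau_D = params$tau_D) {
  if (dt <= 0) stop("bolus_ode_step: dt must be positive", call. = FALSE)
  rz <- ff_realization(params, g_d = 1, tau_D, scale = "raw")
  f <- function(q) c(q[2], (D - rz$a0 * q[1] - rz$a1 * q[2]) / rz$a2)
  k1 <- f(q); k2 <- f(q + dt / 2 * k1); k3 <- f(q + dt / 2 * k2); k4 <- f(q + dt * k3)
  q + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# output map of the companion state for a given realisation
ff_output <- function(q, rz) rz$b0 * q[1] + rz$b1 * q[2]

#' Feedforward bolus insulin profile for announced meals
#'
#' Integrates the inverse-model dynamics driven by the announced meal signal
#' (rectangular pulses of `pulse_min` minutes) and returns the bolus insulin
#' increment at every sample.  Each meal uses its own announced absorption
#' constant; overlapping responses superpose.  The profile is the signed
#' canceling increment: its trailing part is negative (insulin should fall
#' below basal after absorption ends) and is clamped only when the total
#' commanded insulin is formed, not here.
#'
#' @param meals Meal table (see [default_day()]); announced columns are used.
#' @param horizon Simulation horizon (min).
#' @param dt Sample interval (min).
#' @param params A [patient_params()] object.
#' @param g_d Glucose target used for the insulin scaling (mg/dL).
#' @param pulse_min Duration of the rectangular meal pulse (min).
#' @param scale `"insulin"` (canceling insulin increment, default) or
#'   `"raw"` (unscaled inverse-model output).
#' @param substeps Integration substeps per sample; the stored value for each
#'   interval is the substep average of the continuous output, i.e. the best
#'   piecewise-constant (zero-order-hold) representation of the canceling
#'   signal.
#' @return A data frame of class `bolus_profile` with columns `time_min` and
#'   `u_bolus` (`horizon/dt + 1` rows); `u_bolus[k]` is the increment applied
#'   over the interval starting at `time_min[k]`.
#' @export
bolus_profile <- function(meals, horizon, dt, params, g_d = params$g_b,
                          pulse_min = 15, scale = "insulin", substeps = 4) {
  times <- seq(0, horizon, by = dt)
  u <- numeric(length(times))
  h <- dt / substeps
  if (!is.null(meals) && nrow(meals) > 0) {
    for (m in seq_len(nrow(meals))) {
      t0 <- meals$announced_t_start[m]
      carbs <- meals$announced_carbs[m]
      tau <- meals$announced_tau_D[m]
      if (t0 > horizon || carbs <= 0) next
      rz <- ff_realization(params, g_d, tau, scale)
      rate <- carbs * params$cho_to_mmol / pulse_min
      q <- c(0, 0)
      k0 <- floor(t0 / dt) + 1
      for (k in k0:length(times)) {
        t <- times[k]
        # trapezoid average of the output over [t, t + dt)
        acc <- ff_output(q, rz) / 2
        for (j in seq_len(substeps)) {
          ts <- t + (j - 1) * h
          D <- if (ts >= t0 && ts < t0 + pulse_min) rate else 0
          q <- bolus_ode_step(q, D, h, params, tau)
          acc <- acc + ff_output(q, rz) * (if (j < substeps) 1 else 0.5)
        }
        u[k] <- u[k] + acc / substeps
      }
    }
  }
  structure(data.frame(time_min = times, u_bolus = u),
            class = c("bolus_profile", "data.frame"))
}
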