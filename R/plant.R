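#' Time derivatives of the nonlinear glucose-insulin plant
#'
#' The plant couples a two-compartment carbohydrate absorption chain
#' (D1, D2, in mmol) to minimal-model glucose kinetics:
#' \deqn{\dot D_1 = A_G D - D_1/\tau_D}
#' \deqn{\dot D_2 = (D_1 - D_2)/\tau_D}
#' \deqn{\dot g = -p_1 (g - g_b) - \chi g + D_2/\tau_D}
#' \deqn{\dot \chi = -p_2 \chi + p_3 (i - i_{be})}
#' The bilinear term \eqn{-\chi g} is insulin-dependent glucose uptake; its
#' Jacobian at the basal equilibrium supplies the \eqn{-g_d} coupling of the
#' linearised model.
#'
#' @param state Numeric 4-vector `(D1, D2, g, chi)`.
#' @param insulin Plasma insulin concentration (uIU/ml), nonnegative.
#' @param meal_rate Carbohydrate intake rate (mmol/min), nonnegative.
#' @param params A [patient_params()] object.
#' @param tau_D Optional absorption constant override (min); defaults to
#'   `params$tau_D`.
#' @return Numeric 4-vector of time derivatives.
#' @examples
#' pp <- patient_params()
#' plant_derivatives(c(0, 0, pp$g_b, 0), pp$i_be, 0, pp)  # equilibrium: all zero
#' @export
plant_derivatives <- function(state, insulin, meal_rate, params,
                              tau_D = params$tau_D) {
  if (!all(is.finite(state)) || !is.finite(insulin) || !is.finite(meal_rate))
    stop("plant_derivatives: non-finite state or inputs", call. = FALSE)
  if (insulin < 0 || meal_rate < 0)
    stop("plant_derivatives: insulin and meal_rate must be nonnegative",
         call. = FALSE)
  D1 <- state[1]; D2 <- state[2]; g <- state[3]; chi <- state[4]
  c(params$A_G * meal_rate - D1 / tau_D,
    (D1 - D2) / tau_D,
    -params$p1 * (g - params$g_b) - chi * g + D2 / tau_D,
    -params$p2 * chi + params$p3 * (insulin - params$i_be))
}

#' Advance the plant by one fixed step (classical Runge-Kutta)
#'
#' Inputs (insulin concentration and meal rate) are held constant over the
#' step, consistent with the zero-order-hold convention used for the
#' discrete-time controller and estimator.
#'
#' @inheritParams plant_derivatives
#' @param dt Step length (min), positive.
#' @return The state after `dt` minutes.
#' @export
plant_step <- function(state, insulin, meal_rate, dt, params,
                       tau_D = params$tau_D) {
  if (dt <= 0) stop("plant_step: dt must be positive", call. = FALSE)
  k1 <- plant_derivatives(state, insulin, meal_rate, params, tau_D)
  k2 <- plant_derivatives(state + dt / 2 * k1, insulin, meal_rate, params, tau_D)
  k3 <- plant_derivatives(state + dt / 2 * k2, insulin, meal_rate, params, tau_D)
  k4 <- plant_derivatives(state + dt * k3, insulin, meal_rate, params, tau_D)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Linearised state-space model at the basal equilibrium
#'
#' Jacobian of the plant at `(0, 0, g_d, 0)` with `i = i_be`, in deviation
#' coordinates `x = (D1, D2, g - g_d, chi)` with inputs `(D, i - i_be)` and
#' measured output `g - g_d`.
#'
#' Two conventions exist for the insulin input gain of the chi equation.  The
#' `"volume"` convention divides the clearance gain by the plasma volume
#' (`p3 / V`) and is the one used for estimator design; the `"plant"`
#' convention uses `p3`, matching [plant_derivatives()] and the transfer-
#' function factorisation behind the feedforward inverse.  Both forms appear
#' in the model family this plant belongs to; see the methods vignette for
#' the consequences.
#'
#' @param params A [patient_params()] object.
#' @param g_d Target (desired) glucose (mg/dL); defaults to `params$g_b`.
#' @param insulin_gain `"volume"` (`p3 / V`) or `"plant"` (`p3`).
#' @param tau_D Optional absorption constant override (min).
#' @return A `linear_system` list with fields `A` (4x4), `B` (4x2, inputs
#'   `(D, i - i_be)`), `C` (1x4), `H` (4x1 noise input column), and `dt`
#'   (`NA` for continuous time).
#' @examples
#' sys <- linearize(patient_params())
#' sys$A[3, 4]  # -g_d
#' @export
linearize <- function(params, g_d = params$g_b,
                      insulin_gain = c("volume", "plant"),
                      tau_D = params$tau_D) {
  validate_patient_params(params)
  insulin_gain <- match.arg(insulin_gain)
  b_ins <- if (insulin_gain == "volume") params$p3 / params$V else params$p3
  A <- matrix(c(-1 / tau_D, 0,          0,          0,
                1 / tau_D, -1 / tau_D,  0,          0,
                0,          1 / tau_D, -params$p1, -g_d,
                0,          0,          0,         -params$p2),
              4, 4, byrow = TRUE)
  B <- matrix(c(params$A_G, 0,
                0,          0,
                0,          0,
                0,          b_ins), 4, 2, byrow = TRUE)
  C <- matrix(c(0, 0, 1, 0), 1, 4)
  H <- matrix(c(0, 0, 0, b_ins), 4, 1)
  structure(list(A = A, B = B, C = C, H = H, dt = NA_real_,
                 insulin_gain = insulin_gain),
            class = "linear_system")
}

#' Zero-order-hold discretisation of a continuous linear system
#'
#' Exact discretisation via the augmented matrix exponential:
#' `A_d = expm(A dt)`, `B_d = integral_0^dt expm(A s) ds B`, and likewise for
#' the noise input column.
#'
#' @param sys A continuous-time `linear_system` (from [linearize()]).
#' @param dt Sampling interval (min), positive.
#' @return A discrete-time `linear_system` with the same fields and `dt` set.
#' @export
discretize <- function(sys, dt) {
  if (!is.na(sys$dt)) stop("discretize: system is already discrete", call. = FALSE)
  if (dt <= 0) stop("discretize: dt must be positive", call. = FALSE)
  n <- nrow(sys$A)
  Baug <- cbind(sys$B, sys$H)
  m <- ncol(Baug)
  M <- rbind(cbind(sys$A, Baug), matrix(0, m, n + m))
  E <- as.matrix(Matrix::expm(M * dt))
  if (!all(is.finite(E)))
    stop("discretize: matrix exponential did not evaluate finitely", call. = FALSE)
  out <- sys
  out$A <- E[seq_len(n), seq_len(n), drop = FALSE]
  out$B <- E[seq_len(n), n + seq_len(ncol(sys$B)), drop = FALSE]
  out$H <- E[seq_len(n), n + ncol(sys$B) + 1, drop = FALSE]
  out$dt <- dt
  out
}

# Piecewise-constant carbohydrate intake rate (mmol/min) for a meal table.
# Each meal of `carbs` grams is delivered as a rectangular pulse of
# `pulse_min` minutes starting at `t_start`; `announced = TRUE` reads the
# announced columns instead of the true ones.
meal_rate_fn <- function(meals, params, pulse_min = 15, announced = FALSE) {
  if (is.null(meals) || nrow(meals) == 0) return(function(t) 0)
  t0 <- if (announced) meals$announced_t_start else meals$t_start
  cg <- if (announced) meals$announced_carbs else meals$carbs
  rate <- cg * params$cho_to_mmol / pulse_min
  function(t) {
    sum(rate[t >= t0 & t < t0 + pulse_min])
  }
}
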