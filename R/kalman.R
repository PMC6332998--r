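#' Steady-state solution of the estimation Riccati equation
#'
#' Solves the discrete algebraic Riccati equation of the one-step predictor,
#' \deqn{M = A M A' + H R_w H' - A M C' (C M C' + R_v)^{-1} C M A',}
#' by the structure-preserving doubling algorithm, and verifies the fixed
#' point residual.  Process noise enters through the noise input column `H`
#' of the system (insulin input noise), measurement noise through `R_v`.
#'
#' @param sys A discrete-time `linear_system` (see [discretize()]).
#' @param noise A [noise_spec()] object.
#' @param tol Convergence tolerance for the doubling iteration.
#' @return The symmetric positive semidefinite solution `M`, with the fixed
#'   point residual attached as attribute `"residual"`.
#' @export
solve_riccati <- function(sys, noise, tol = 1e-14) {
  if (is.na(sys$dt)) stop("solve_riccati: discretize the system first", call. = FALSE)
  A <- sys$A; C <- sys$C; H <- sys$H
  n <- nrow(A)
  # Duality: the estimation DARE is the control DARE for (A', C', H Rw H', Rv).
  Ak <- t(A)
  Gk <- crossprod(C) / noise$R_v          # C' Rv^-1 C
  Xk <- tcrossprod(H) * noise$R_w         # H Rw H'
  I <- diag(n)
  for (it in seq_len(200)) {
    W <- tryCatch(solve(I + Gk %*% Xk), error = function(e)
      stop("solve_riccati: singular iterate in doubling algorithm: ",
           conditionMessage(e), call. = FALSE))
    AW <- Ak %*% W
    Xn <- Xk + t(Ak) %*% Xk %*% W %*% Ak
    Gn <- Gk + AW %*% Gk %*% t(Ak)
    An <- AW %*% Ak
    delta <- max(abs(Xn - Xk))
    Ak <- An; Gk <- Gn; Xk <- Xn
    if (delta < tol * max(1, max(abs(Xk)))) break
  }
  M <- (Xk + t(Xk)) / 2
  S <- drop(C %*% M %*% t(C)) + noise$R_v
  resid <- max(abs(A %*% M %*% t(A) + tcrossprod(H) * noise$R_w -
                   (A %*% M %*% t(C)) %*% t(A %*% M %*% t(C)) / S - M))
  if (!is.finite(resid) || resid > 1e-9 * max(1, max(abs(M))))
    stop(sprintf("solve_riccati: doubling iteration did not converge (residual %.3g)",
                 resid), call. = FALSE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(abs(ev), 1))
    stop("solve_riccati: solution is not positive semidefinite", call. = FALSE)
  attr(M, "residual") <- resid
  M
}

#' Steady-state Kalman gain from a Riccati solution
#'
#' @param M Riccati solution (from [solve_riccati()]).
#' @param C Output row matrix (1 x n).
#' @param R_v Measurement noise variance, positive.
#' @return The n x 1 gain column `L = M C' (C M C' + R_v)^{-1}`.
#' @export
kalman_gain <- function(M, C, R_v) {
  S <- drop(C %*% M %*% t(C)) + R_v
  if (S <= 0) stop("kalman_gain: innovation covariance is not positive", call. = FALSE)
  M %*% t(C) / S
}

#' Design the steady-state Kalman filter for the glucose system
#'
#' Bundles linearisation at the target, zero-order-hold discretisation,
#' Riccati solution and gain computation into a filter object used by the
#' closed-loop controllers.  The filter is designed once, offline, at the
#' glucose target; it is not relinearised during a simulated day.
#'
#' @param params A [patient_params()] object.
#' @param g_d Glucose target (mg/dL).
#' @param dt Sampling interval (min).
#' @param noise A [noise_spec()] object.
#' @param insulin_gain Convention for the insulin input gain of the linear
#'   model; see [linearize()].
#' @return A `kalman_filter` list: `sys` (discrete system), `L` (4x1 gain),
#'   `M` (Riccati solution), `noise`, `dt`.
#' @examples
#' kf <- design_kalman(patient_params(), dt = 1)
#' kf$L
#' @export
design_kalman <- function(params, g_d = params$g_b, dt = 1,
                          noise = noise_spec(),
                          insulin_gain = c("volume", "plant")) {
  insulin_gain <- match.arg(insulin_gain)
  sys <- discretize(linearize(params, g_d, insulin_gain), dt)
  M <- solve_riccati(sys, noise)
  L <- kalman_gain(M, sys$C, noise$R_v)
  # estimator stability: spectral radius of (A - L C A) must be < 1
  Acl <- sys$A - L %*% sys$C %*% sys$A
  rho <- max(Mod(eigen(Acl, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("design_kalman: estimator is unstable (spectral radius %.6f)", rho),
         call. = FALSE)
  structure(list(sys = sys, L = L, M = M, noise = noise, dt = dt,
                 spectral_radius = rho),
            class = "kalman_filter")
}

#' One predictor-form Kalman update
#'
#' Computes \eqn{\hat x_{k+1|k} = A \hat x_{k|k-1} + B u_k + L (y_k - C \hat
#' x_{k|k-1})}.  The input is what the controller knows: the announced meal
#' rate and the commanded insulin deviation from equilibrium.
#'
#' @param x_hat Current predicted state estimate (4-vector, deviation
#'   coordinates `(D1, D2, g - g_d, chi)`).
#' @param u Known input 2-vector `(meal rate mmol/min, i - i_be)`.
#' @param y Measured glucose deviation `g - g_d` (mg/dL).
#' @param filter A `kalman_filter` from [design_kalman()], or any list with
#'   `sys` and `L`.
#' @return The predicted estimate for the next sample (4-vector).
#' @export
estimate_update <- function(x_hat, u, y, filter) {
  sys <- filter$sys
  drop(sys$A %*% x_hat + sys$B %*% u + filter$L * (y - drop(sys$C %*% x_hat)))
}
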