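#' Physiological parameters of the glucose-insulin minimal model
#'
#' Constructs the parameter set of the simulated patient: minimal-model
#' glucose kinetics, a first-order interstitial insulin activity compartment,
#' and a two-compartment carbohydrate absorption chain.
#'
#' @param p1 Glucose effectiveness (1/min): first-order return of plasma
#'   glucose towards its basal value independent of insulin action.
#' @param p2 Insulin sensitivity (1/min): decay rate of the interstitial
#'   insulin activity.
#' @param p3 Insulin rate of clearance (1/min): gain from plasma insulin
#'   deviation to the interstitial activity.
#' @param A_G Carbohydrate bioavailability, the fraction of ingested
#'   carbohydrate that appears in plasma (dimensionless, in (0, 1]).
#' @param tau_D Glucose absorption time constant (min) of the two-compartment
#'   meal chain.  Meals may override this per event.
#' @param V Plasma volume scaling constant (g).
#' @param i_be Equilibrium basal plasma insulin concentration (uIU/ml).
#' @param g_b Basal plasma glucose (mg/dL); equals the control target.
#' @param cho_to_mmol Conversion from grams of carbohydrate to mmol glucose
#'   (default 1000/180, the molar mass of glucose).
#'
#' @return An object of class `patient_params` (a validated named list).
#' @examples
#' pp <- patient_params()
#' pp$p1
#' @export
patient_params <- function(p1 = 0.2, p2 = 0.028, p3 = 1e-4, A_G = 0.8,
                           tau_D = 10, V = 2730, i_be = 7.326, g_b = 80,
                           cho_to_mmol = 1000 / 180) {
  p <- list(p1 = p1, p2 = p2, p3 = p3, A_G = A_G, tau_D = tau_D, V = V,
            i_be = i_be, g_b = g_b, cho_to_mmol = cho_to_mmol)
  validate_patient_params(p)
  class(p) <- "patient_params"
  p
}

validate_patient_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("patient_params: non-numeric or non-finite fields: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  pos <- unlist(p) > 0
  if (!all(pos)) {
    stop("patient_params: all parameters must be strictly positive; offenders: ",
         paste(names(p)[!pos], collapse = ", "), call. = FALSE)
  }
  if (p$A_G > 1) stop("patient_params: A_G must be in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Quadratic cost weights of the control objective
#'
#' The per-step cost is \eqn{r_{k+1} = x_k' Q x_k + R u_k^2} where
#' \eqn{x = (g - g_d, \chi)} is the controller state and \eqn{u} the basal
#' insulin adjustment.  The glucose-error weight dominates by design: keeping
#' glucose at target is the primary objective, insulin activity and action
#' effort are regularisers.
#'
#' @param Q 2x2 symmetric positive semidefinite state weight matrix.
#' @param R Positive scalar action weight.
#' @param gamma Discount factor in (0, 1].
#' @return An object of class `cost_weights`.
#' @export
cost_weights <- function(Q = diag(c(100, 0.1)), R = 0.01, gamma = 0.9) {
  Q <- as.matrix(Q)
  if (!all(dim(Q) == c(2L, 2L)) || max(abs(Q - t(Q))) > 1e-12)
    stop("cost_weights: Q must be a symmetric 2x2 matrix", call. = FALSE)
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12)
    stop("cost_weights: Q must be positive semidefinite", call. = FALSE)
  if (!is.numeric(R) || length(R) != 1 || R <= 0)
    stop("cost_weights: R must be a positive scalar", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("cost_weights: gamma must be in (0, 1]", call. = FALSE)
  structure(list(Q = Q, R = R, gamma = gamma), class = "cost_weights")
}

#' Process and measurement noise variances for the state estimator
#'
#' @param R_w Variance of the insulin input noise.
#' @param R_v Variance of the glucose measurement noise.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(R_w = 0.01, R_v = 0.01) {
  if (!is.numeric(R_w) || R_w <= 0 || !is.numeric(R_v) || R_v <= 0)
    stop("noise_spec: R_w and R_v must be positive", call. = FALSE)
  structure(list(R_w = R_w, R_v = R_v), class = "noise_spec")
}

#' Meal-information uncertainty specification
#'
#' Describes how the announced meal information supplied to the controller
#' deviates from the true meal: carbohydrate content is perturbed with a
#' relative Gaussian error (reported carbohydrate-counting accuracy of adult
#' patients), and the announced start time with an absolute Gaussian error.
#'
#' @param cho_sd_frac Relative standard deviation of announced carbohydrate
#'   mass (default 0.46, i.e. 46 percent of the true value).
#' @param time_sd_min Standard deviation of the announced meal start time
#'   (min, default 2).
#' @param n_reps Number of Monte-Carlo repetitions for band studies.
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(cho_sd_frac = 0.46, time_sd_min = 2, n_reps = 100) {
  if (cho_sd_frac < 0 || time_sd_min < 0)
    stop("uncertainty_spec: standard deviations must be nonnegative", call. = FALSE)
  if (n_reps < 1) stop("uncertainty_spec: n_reps must be >= 1", call. = FALSE)
  structure(list(cho_sd_frac = cho_sd_frac, time_sd_min = time_sd_min,
                 n_reps = as.integer(n_reps)),
            class = "uncertainty_spec")
}

# Run the RNG-dependent expression under a local seed, restoring the caller's
# RNG state afterwards so package functions never clobber the session RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}
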