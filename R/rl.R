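#' Per-step quadratic control cost
#'
#' \eqn{r = x' Q x + R u^2} for controller state `x = (g - g_d, chi)` and
#' basal insulin adjustment `u`.
#'
#' @param x Numeric 2-vector.
#' @param u Scalar action.
#' @param weights A [cost_weights()] object.
#' @return Nonnegative scalar cost.
#' @export
rl_cost <- function(x, u, weights = cost_weights()) {
  if (!all(is.finite(x)) || !is.finite(u))
    stop("rl_cost: non-finite inputs", call. = FALSE)
  drop(t(x) %*% weights$Q %*% x) + weights$R * u^2
}

#' Kronecker feature vector of the joint state-action
#'
#' Maps `z = (x1, x2, u)` to the 9-element basis `z %x% z`, so that any
#' quadratic form `z' P z` is linear in the features:
#' `vec(P)' (z %x% z) = z' P z`.
#'
#' @param z Numeric 3-vector.
#' @return Numeric 9-vector.
#' @export
featurize <- function(z) {
  if (!all(is.finite(z))) stop("featurize: non-finite input", call. = FALSE)
  as.vector(z %x% z)
}

#' Quadratic action-value kernel
#'
#' Wraps a symmetric 3x3 kernel matrix `P` together with its flattened
#' 9-element weight vector.  The partition blocks follow the joint vector
#' `z = (x, u)`: `P_xx` (2x2), `P_xu` (2x1), `P_ux` (1x2), `P_uu` (scalar).
#'
#' @param P Symmetric 3x3 matrix (symmetrised if slightly asymmetric).
#' @return An object of class `qkernel` with fields `P` and `w`.
#' @export
qkernel <- function(P) {
  P <- as.matrix(P)
  if (!all(dim(P) == c(3L, 3L)))
    stop("qkernel: P must be 3x3", call. = FALSE)
  P <- (P + t(P)) / 2
  structure(list(P = P, w = as.vector(P)), class = "qkernel")
}

#' @export
print.qkernel <- function(x, ...) {
  cat("Quadratic action-value kernel (z = (g - g_d, chi, u)):\n")
  print(x$P)
  cat(sprintf("P_uu = %.6g\n", x$P[3, 3]))
  invisible(x)
}

#' Evaluate the approximate action-value function
#'
#' @param kernel A [qkernel()].
#' @param x Controller state 2-vector.
#' @param u Scalar action.
#' @return The quadratic form `z' P z` with `z = (x, u)`.
#' @export
q_value <- function(kernel, x, u) {
  z <- c(x, u)
  drop(t(z) %*% kernel$P %*% z)
}

#' Least-squares policy evaluation of the quadratic action-value function
#'
#' Fits the Bellman fixed point `Q(x, u) = r + gamma Q(x', u')` in the
#' Kronecker basis by linear least squares over a batch of transitions:
#' the weight vector solves
#' `min_w || (Phi(z_k) - gamma Phi(z_{k+1}))' w - r_{k+1} ||^2`.
#'
#' If a `policy` is supplied, the next action is recomputed as the policy's
#' greedy action at `x'` (least-squares temporal-difference Q evaluation);
#' otherwise the recorded exploratory next action `u_next` is used.
#'
#' The Kronecker basis is over-parameterised (9 features for 6 distinct
#' monomials), so the regressor is never full column rank; the solve is the
#' minimum-norm least-squares solution via SVD.  Directions whose singular
#' values fall below `tol` times the largest are truncated; when that removes
#' more than the intrinsic redundancy the fit is flagged as deficient (state
#' directions that the data does not excite).  With `strict = TRUE` a
#' deficient fit is an error; with `strict = FALSE` it is reported in the
#' `"deficient"`/`"rank"` attributes so a training loop can react.
#'
#' @param transitions Data frame with columns `x1, x2, u, r, x1n, x2n`
#'   (state, action, realised cost, next state) and optionally `un` (next
#'   action).
#' @param weights A [cost_weights()] (supplies the discount factor).
#' @param policy Optional [rl_policy()] used to recompute next actions.
#' @param tol Relative singular value truncation tolerance.
#' @param strict Error on deficient excitation (default) or report it.
#' @return A [qkernel()] with attributes `rank` and `deficient`.
#' @export
policy_evaluation <- function(transitions, weights = cost_weights(),
                              policy = NULL, tol = 1e-6, strict = TRUE) {
  n <- nrow(transitions)
  if (is.null(n) || n < 9)
    stop("policy_evaluation: need at least 9 transitions, got ",
         if (is.null(n)) 0 else n, call. = FALSE)
  gamma <- weights$gamma
  un <- if (!is.null(policy)) {
    policy$K[1] * transitions$x1n + policy$K[2] * transitions$x2n
  } else {
    if (is.null(transitions$un))
      stop("policy_evaluation: supply either a policy or recorded next actions",
           call. = FALSE)
    transitions$un
  }
  X <- matrix(0, n, 9)
  for (k in seq_len(n)) {
    z  <- c(transitions$x1[k], transitions$x2[k], transitions$u[k])
    zn <- c(transitions$x1n[k], transitions$x2n[k], un[k])
    X[k, ] <- featurize(z) - gamma * featurize(zn)
  }
  r <- transitions$r
  if (!all(is.finite(X)) || !all(is.finite(r)))
    stop("policy_evaluation: non-finite transition data", call. = FALSE)
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1]
  rank <- sum(keep)
  # 6 = dimension of symmetric quadratics in 3 variables
  deficient <- rank < 6L
  if (deficient && strict)
    stop(sprintf(paste0("policy_evaluation: regressor is rank deficient ",
                        "(numerical rank %d of 6 identifiable directions); ",
                        "the data does not excite the full state-action space"),
                 rank), call. = FALSE)
  w <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% r) / sv$d[keep])
  kern <- qkernel(matrix(w, 3, 3))
  attr(kern, "rank") <- rank
  attr(kern, "deficient") <- deficient
  kern
}

#' Linear basal policy
#'
#' @param K Gain row `(k_g, k_chi)`: the basal adjustment is `u = K x` with
#'   `x = (g - g_d, chi)`.
#' @param i_be Equilibrium basal insulin concentration added to the
#'   adjustment (uIU/ml).
#' @return An object of class `rl_policy`.
#' @export
rl_policy <- function(K = c(0, 0), i_be = patient_params()$i_be) {
  K <- as.numeric(K)
  if (length(K) != 2 || !all(is.finite(K)))
    stop("rl_policy: K must be a finite 2-vector", call. = FALSE)
  structure(list(K = K, i_be = i_be), class = "rl_policy")
}

#' Greedy policy improvement from a quadratic kernel
#'
#' The minimiser of `z' P z` over `u` at fixed `x` is
#' `u = -P_uu^{-1} P_ux x`, which requires positive action curvature.
#'
#' @param kernel A [qkernel()].
#' @param i_be Basal insulin passed through to the policy.
#' @return An [rl_policy()].
#' @export
policy_improvement <- function(kernel, i_be = patient_params()$i_be) {
  Puu <- kernel$P[3, 3]
  if (!is.finite(Puu) || Puu <= 0)
    stop(sprintf(paste0("policy_improvement: kernel is not improvable ",
                        "(P_uu = %.3g <= 0); policy evaluation failed to ",
                        "identify positive action curvature"), Puu),
         call. = FALSE)
  rl_policy(K = -kernel$P[3, 1:2] / Puu, i_be = i_be)
}

#' Basal insulin command of a policy
#'
#' `u_basal = K x + i_be`, clamped at zero from below (insulin delivery
#' cannot be negative).
#'
#' @param policy An [rl_policy()].
#' @param x Controller state 2-vector `(g - g_d, chi)`.
#' @return Nonnegative insulin concentration (uIU/ml).
#' @export
basal_action <- function(policy, x) {
  if (!all(is.finite(x))) stop("basal_action: non-finite state", call. = FALSE)
  max(0, sum(policy$K * x) + policy$i_be)
}

#' Pretrain the basal controller in the fasting scenario
#'
#' Episodic least-squares policy iteration without meals: each episode starts
#' at 90 mg/dL (initial interstitial activity drawn uniformly from
#' `[0, chi0_max]`) and lasts `episode_min` minutes; the agent explores with
#' additive Gaussian action noise, the latest `window` transitions are kept,
#' and after every episode the kernel is re-estimated
#' ([policy_evaluation()] with the current policy's greedy next actions) and
#' the policy improved when the estimated action curvature is positive.
#'
#' The default training environment is the fasting deviation model linearised
#' at the target (`env = "linear"`), where the sampled transitions are exactly
#' consistent with a quadratic value function and the iteration converges to
#' the discounted LQR solution; `env = "nonlinear"` trains against the full
#' plant, which is noisier (see the methods vignette for why the action
#' curvature is then hard to identify).  Episodes whose glucose leaves
#' [20, 600] mg/dL are aborted and the policy gains halved (divergence guard).
#'
#' @param params A [patient_params()] object.
#' @param weights A [cost_weights()] object.
#' @param g_d Glucose target (mg/dL).
#' @param episodes Number of training episodes.
#' @param episode_min Episode length (min).
#' @param dt Control interval (min).
#' @param g0 Initial glucose of each episode (mg/dL).
#' @param chi0_max Upper bound of the uniform initial interstitial activity.
#' @param sigma_explore Standard deviation of the Gaussian exploration noise
#'   added to the action (uIU/ml).
#' @param window Rolling window of retained transitions.
#' @param env `"linear"` (default) or `"nonlinear"` training plant.
#' @param tol Singular-value truncation tolerance passed to
#'   [policy_evaluation()].  The default is tight (`1e-12`) for the linear
#'   environment, whose transitions are exactly consistent with a quadratic
#'   value function, and loose (`1e-6`) for the nonlinear one, where weakly
#'   excited directions carry mostly Bellman-residual noise and are better
#'   truncated.
#' @param seed Integer seed; the RNG state of the caller is preserved.
#' @return A list of class `pretrain_result`: `kernel` ([qkernel()]),
#'   `policy` ([rl_policy()]), and `log` (per-episode data frame with
#'   cumulative cost, acceptance and divergence flags).
#' @export
pretrain <- function(params = patient_params(), weights = cost_weights(),
                     g_d = params$g_b, episodes = 50, episode_min = 30,
                     dt = 1, g0 = 90, chi0_max = 0.05, sigma_explore = 1,
                     window = 300, env = c("linear", "nonlinear"),
                     tol = NULL, seed = NULL) {
  env <- match.arg(env)
  if (is.null(tol)) tol <- if (env == "linear") 1e-12 else 1e-6
  if (episodes < 0) stop("pretrain: episodes must be >= 0", call. = FALSE)
  steps <- round(episode_min / dt)
  dsys <- discretize(linearize(params, g_d, insulin_gain = "plant"), dt)
  Ad <- dsys$A[3:4, 3:4]; Bd <- dsys$B[3:4, 2]
  kernel <- qkernel(diag(c(0, 0, weights$R)))  # myopic initial curvature
  policy <- rl_policy(K = c(0, 0), i_be = params$i_be)
  if (episodes == 0)
    return(structure(list(kernel = kernel, policy = policy,
                          log = data.frame()), class = "pretrain_result"))
  with_local_seed(seed, {
    buf <- vector("list", 0)
    log <- data.frame(episode = seq_len(episodes), cost = NA_real_,
                      accepted = FALSE, diverged = FALSE,
                      K1 = NA_real_, K2 = NA_real_)
    for (ep in seq_len(episodes)) {
      if (env == "nonlinear") s <- c(0, 0, g0, runif(1, 0, chi0_max))
      x <- if (env == "nonlinear") c(s[3] - g_d, s[4])
           else c(g0 - g_d, runif(1, 0, chi0_max))
      ep_cost <- 0
      diverged <- FALSE
      for (k in seq_len(steps)) {
        u <- sum(policy$K * x) + rnorm(1, 0, sigma_explore)
        u <- max(u, -params$i_be)          # total insulin stays nonnegative
        if (env == "nonlinear") {
          s2 <- plant_step(s, params$i_be + u, 0, dt, params)
          ok <- all(is.finite(s2)) && s2[3] > 20 && s2[3] < 600
          xn <- if (ok) c(s2[3] - g_d, s2[4]) else NULL
        } else {
          xn <- drop(Ad %*% x + Bd * u)
          ok <- all(is.finite(xn)) && abs(xn[1]) < 520
        }
        if (!ok) { diverged <- TRUE; break }
        r <- rl_cost(x, u, weights)
        ep_cost <- ep_cost + r
        buf[[length(buf) + 1]] <- c(x, u, r, xn)
        if (length(buf) > window) buf <- buf[-1]
        x <- xn
        if (env == "nonlinear") s <- s2
      }
      log$cost[ep] <- ep_cost
      if (diverged) {
        policy <- rl_policy(policy$K / 2, i_be = params$i_be)
        log$diverged[ep] <- TRUE
      } else {
        tr <- as.data.frame(do.call(rbind, buf))
        names(tr) <- c("x1", "x2", "u", "r", "x1n", "x2n")
        cand <- tryCatch(
          policy_evaluation(tr, weights, policy = policy, tol = tol,
                            strict = FALSE),
          error = function(e) NULL)
        if (!is.null(cand) && cand$P[3, 3] > 0) {
          kernel <- cand
          policy <- policy_improvement(kernel, i_be = params$i_be)
          log$accepted[ep] <- TRUE
        }
      }
      log$K1[ep] <- policy$K[1]; log$K2[ep] <- policy$K[2]
    }
    structure(list(kernel = kernel, policy = policy, log = log),
              class = "pretrain_result")
  })
}
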