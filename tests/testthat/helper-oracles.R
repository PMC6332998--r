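# Independent oracles used across tests.  These deliberately use plain
# fixed-point iteration (not the package's solvers) so that agreement is a
# genuine cross-check.

# Discounted discrete-time LQR by value iteration; returns list(P, K) with
# policy u = K x (note sign: u = -inv(R + B'PB) B'PA x).
oracle_lqr <- function(A, B, Q, R, gamma = 1, tol = 1e-13, max_iter = 1e6) {
  A <- sqrt(gamma) * A; B <- sqrt(gamma) * as.matrix(B)
  P <- Q
  for (i in seq_len(max_iter)) {
    S <- drop(R + t(B) %*% P %*% B)
    Kt <- (t(B) %*% P %*% A) / S
    Pn <- Q + t(A) %*% P %*% A - t(A) %*% P %*% B %*% Kt
    if (max(abs(Pn - P)) < tol * max(1, max(abs(Pn)))) { P <- Pn; break }
    P <- Pn
  }
  S <- drop(R + t(B) %*% P %*% B)
  list(P = P, K = -drop((t(B) %*% P %*% A) / S))
}

# Steady-state estimation error covariance by brute-force iteration of the
# time-varying covariance recursion (predictor form).
oracle_riccati_iter <- function(A, C, Hq, Rv, tol = 1e-15, max_iter = 1e6) {
  n <- nrow(A)
  M <- matrix(0, n, n)
  for (i in seq_len(max_iter)) {
    S <- drop(C %*% M %*% t(C)) + Rv
    K <- (A %*% M %*% t(C)) / S
    Mn <- A %*% M %*% t(A) + Hq - K %*% t(A %*% M %*% t(C))
    if (max(abs(Mn - M)) < tol * max(1, max(abs(Mn)))) return(Mn)
    M <- Mn
  }
  Mn
}

# Simulate the discretised linear plant (deviation coordinates) in closed
# loop with an insulin increment signal; returns the glucose deviation trace.
linear_meal_response <- function(params, g_d, dt, horizon, meal_rate_fun,
                                 insulin_increment = function(t) 0) {
  dsys <- discretize(linearize(params, g_d, insulin_gain = "plant"), dt)
  n <- round(horizon / dt)
  x <- rep(0, 4)
  y <- numeric(n + 1)
  for (k in seq_len(n)) {
    t <- (k - 1) * dt
    x <- drop(dsys$A %*% x + dsys$B %*% c(meal_rate_fun(t), insulin_increment(t)))
    y[k + 1] <- x[3]
  }
  y
}

# default pretrained policy shared by the heavier closed-loop tests
shared_policy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pretrain(seed = 1)$policy
    cache
  }
})

# fixed reference kernel with realistic magnitudes (regression fixture)
reference_kernel <- function() {
  qkernel(matrix(c(4.454e2, -8.870e4, -0.084,
                   -8.870e4, 3.538e7, 33.630,
                   -0.084,   33.630,  0.010), 3, 3, byrow = TRUE))
}
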