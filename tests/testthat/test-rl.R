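pp <- patient_params()
wt <- cost_weights()

test_that("quadratic cost matches its closed form", {
  expect_equal(rl_cost(c(0, 0), 0, wt), 0)
  expect_equal(rl_cost(c(1, 0), 0, wt), 100)
  expect_equal(rl_cost(c(0, 1), 1, wt), 0.1 + 0.01)
  expect_error(rl_cost(c(Inf, 0), 0, wt), "non-finite")
})

test_that("Kronecker features represent every quadratic form exactly", {
  expect_equal(featurize(c(1, 0, 0)), c(1, rep(0, 8)))
  expect_equal(featurize(c(1, 1, 1)), rep(1, 9))
  set.seed(11)
  for (i in 1:50) {
    z <- rnorm(3)
    S <- matrix(rnorm(9), 3, 3); S <- (S + t(S)) / 2
    expect_equal(drop(t(z) %*% S %*% z), sum(as.vector(S) * featurize(z)),
                 tolerance = 1e-12)
  }
})

test_that("q_value agrees between matrix and weight representations", {
  expect_equal(q_value(qkernel(diag(3)), c(3, 4), 0), 25)
  kern <- reference_kernel()
  expect_equal(q_value(kern, c(10, 0), 0), 4.454e4)
  set.seed(12)
  for (i in 1:20) {
    z <- rnorm(3)
    expect_equal(q_value(kern, z[1:2], z[3]),
                 sum(kern$w * featurize(z)),
                 tolerance = 1e-12)
  }
})

test_that("policy evaluation recovers a known quadratic fixed point", {
  # toy deterministic linear system; costs constructed from the Bellman
  # identity so the chosen kernel is the exact solution
  A <- matrix(c(0.9, 0.1, 0, 0.8), 2, 2, byrow = TRUE)
  B <- c(0.05, 0.2)
  Pstar <- matrix(c(4, 1, 0.5, 1, 3, 0.2, 0.5, 0.2, 2), 3, 3)
  Pstar <- (Pstar + t(Pstar)) / 2
  pol <- rl_policy(K = c(0.3, -0.4), i_be = 0)
  set.seed(21)
  n <- 60
  x <- matrix(rnorm(2 * n), n, 2)
  u <- rnorm(n)
  tr <- data.frame(x1 = x[, 1], x2 = x[, 2], u = u,
                   r = NA, x1n = NA, x2n = NA)
  for (k in seq_len(n)) {
    xn <- drop(A %*% x[k, ] + B * u[k])
    un <- sum(pol$K * xn)
    tr$x1n[k] <- xn[1]; tr$x2n[k] <- xn[2]
    tr$r[k] <- q_value(qkernel(Pstar), x[k, ], u[k]) -
      wt$gamma * q_value(qkernel(Pstar), xn, un)
  }
  kern <- policy_evaluation(tr, wt, policy = pol, tol = 1e-10)
  expect_equal(kern$P, Pstar, tolerance = 1e-6)
  # consistent duplication leaves the least-squares solution unchanged
  kern2 <- policy_evaluation(rbind(tr, tr), wt, policy = pol, tol = 1e-10)
  expect_equal(kern2$P, kern$P, tolerance = 1e-9)
})

test_that("policy evaluation rejects uninformative data", {
  expect_error(policy_evaluation(data.frame()), "at least 9")
  tr <- data.frame(x1 = rep(1, 20), x2 = 0, u = 0, r = 1, x1n = 1, x2n = 0,
                   un = 0)
  expect_error(policy_evaluation(tr, wt), "rank deficient")
  kern <- policy_evaluation(tr, wt, strict = FALSE)
  expect_true(attr(kern, "deficient"))
})

test_that("policy improvement is the exact argmin of the q-function", {
  expect_equal(policy_improvement(qkernel(diag(3)))$K, c(0, 0))
  pol <- policy_improvement(reference_kernel())
  expect_equal(pol$K, c(8.4, -3363), tolerance = 1e-12)
  expect_error(policy_improvement(qkernel(diag(c(1, 1, -1)))), "not improvable")
  # closed form vs numeric minimisation, and argmin dominance
  set.seed(31)
  for (i in 1:20) {
    S <- matrix(rnorm(9), 3, 3); S <- S %*% t(S) + diag(3) * 0.5  # SPD
    kern <- qkernel(S)
    pol <- policy_improvement(kern)
    x <- rnorm(2, sd = 5)
    ustar <- sum(pol$K * x)
    unum <- stats::optimize(function(u) q_value(kern, x, u),
                            interval = ustar + c(-50, 50), tol = 1e-12)$minimum
    expect_equal(ustar, unum, tolerance = 1e-6)
    for (u in rnorm(20, sd = 10))
      expect_lte(q_value(kern, x, ustar), q_value(kern, x, u) + 1e-9)
  }
})

test_that("basal action adds the equilibrium insulin and clamps at zero", {
  pol <- rl_policy(c(8.86, -3534.11), i_be = pp$i_be)
  expect_equal(basal_action(pol, c(0, 0)), 7.326)
  expect_equal(basal_action(pol, c(10, 0)), 7.326 + 88.6)
  expect_equal(basal_action(pol, c(-10, 0)), 0)
})

test_that("pretraining is reproducible and stabilises fasting glucose", {
  pt0 <- pretrain(episodes = 0)
  expect_equal(pt0$policy$K, c(0, 0))
  pa <- pretrain(episodes = 10, seed = 5)
  pb <- pretrain(episodes = 10, seed = 5)
  expect_identical(pa$kernel$w, pb$kernel$w)
  expect_identical(pa$policy$K, pb$policy$K)

  pol <- shared_policy()
  kf <- design_kalman(pp, dt = 1)
  sc <- make_scenario(data.frame(t_start = numeric(0), carbs = numeric(0),
                                 tau_D = numeric(0)), horizon = 360)
  ctl <- controller_orl(pol, kf)
  tr <- simulate_closed_loop(sc, ctl, pp, state0 = c(0, 0, 90, 0))
  expect_lt(max(abs(tr$g[tr$time_min >= 300] - 80)), 2)
})

test_that("policy iteration matches the LQR solution on the linear plant", {
  # gamma = 1, exploration-rich synthetic transitions on the discretised
  # two-state deviation model; oracle is plain Riccati value iteration
  dsys <- discretize(linearize(pp, insulin_gain = "plant"), 1)
  A <- dsys$A[3:4, 3:4]; B <- dsys$B[3:4, 2]
  wt1 <- cost_weights(gamma = 1)
  orc <- oracle_lqr(A, B, wt1$Q, wt1$R, gamma = 1)
  set.seed(41)
  n <- 400
  x <- cbind(rnorm(n, sd = 10), rnorm(n, sd = 0.05))
  u <- rnorm(n, sd = 20)
  xn <- t(apply(cbind(x, u), 1, function(z) A %*% z[1:2] + B * z[3]))
  tr <- data.frame(x1 = x[, 1], x2 = x[, 2], u = u,
                   r = wt1$Q[1, 1] * x[, 1]^2 + wt1$Q[2, 2] * x[, 2]^2 +
                     wt1$R * u^2,
                   x1n = xn[, 1], x2n = xn[, 2])
  pol <- rl_policy(c(0, 0), i_be = 0)
  for (it in 1:30) {
    kern <- policy_evaluation(tr, wt1, policy = pol, tol = 1e-12)
    pol <- policy_improvement(kern, i_be = 0)
  }
  expect_equal(pol$K, orc$K, tolerance = 1e-3)
})

test_that("converged kernels have small Bellman residuals on held-out data", {
  pt <- pretrain(seed = 3)
  dsys <- discretize(linearize(pp, insulin_gain = "plant"), 1)
  A <- dsys$A[3:4, 3:4]; B <- dsys$B[3:4, 2]
  bellman_residual <- function(kern, pol) {
    set.seed(99)  # held-out transitions, common across kernels
    res <- numeric(200)
    for (k in 1:200) {
      x <- c(rnorm(1, sd = 5), runif(1, 0, 0.05))
      u <- sum(pol$K * x) + rnorm(1)
      xn <- drop(A %*% x + B * u)
      un <- sum(pol$K * xn)
      r <- rl_cost(x, u, wt)
      res[k] <- abs(q_value(kern, x, u) - r - wt$gamma * q_value(kern, xn, un))
    }
    mean(res)
  }
  r_trained <- bellman_residual(pt$kernel, pt$policy)
  r_initial <- bellman_residual(pretrain(episodes = 0)$kernel, pt$policy)
  expect_lt(r_trained * 10, r_initial)
})
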