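pp <- patient_params()

test_that("basal equilibrium is a fixed point of the dynamics", {
  d <- plant_derivatives(c(0, 0, pp$g_b, 0), pp$i_be, 0, pp)
  expect_equal(d, rep(0, 4))
  s <- c(0, 0, pp$g_b, 0)
  expect_equal(plant_step(s, pp$i_be, 0, 5, pp), s, tolerance = 1e-12)
})

test_that("carbohydrate input enters compartment 1 with bioavailability A_G", {
  d <- plant_derivatives(c(0, 0, pp$g_b, 0), pp$i_be, 1, pp)
  expect_equal(d[1], pp$A_G)
  expect_error(plant_derivatives(c(0, 0, NaN, 0), pp$i_be, 0, pp), "non-finite")
  expect_error(plant_derivatives(c(0, 0, 80, 0), -1, 0, pp), "nonnegative")
})

test_that("glucose rises monotonically during absorption onset of a meal", {
  s <- c(0, 0, pp$g_b, 0)
  rate <- 50 * pp$cho_to_mmol / 15
  gs <- numeric(16)
  gs[1] <- s[3]
  for (k in 1:15) {
    s <- plant_step(s, pp$i_be, rate, 1, pp)
    gs[k + 1] <- s[3]
  }
  expect_true(all(diff(gs) > 0))
})

test_that("meal mass is conserved through the absorption chain", {
  # time-integral of the glucose appearance rate D2/tau_D equals the
  # bioavailable fraction of the ingested mass
  for (tau in c(10, 50)) {
    M_g <- 50
    rate <- M_g * pp$cho_to_mmol / 15
    s <- c(0, 0, pp$g_b, 0)
    horizon <- 15 + 40 * tau
    appear <- numeric(horizon + 1)
    for (k in seq_len(horizon)) {
      t <- k - 1
      appear[k] <- s[2] / tau
      s <- plant_step(s, pp$i_be, if (t < 15) rate else 0, 1, pp, tau_D = tau)
    }
    appear[horizon + 1] <- s[2] / tau
    got <- sum((appear[-1] + appear[-length(appear)]) / 2)  # trapezoid, dt = 1
    expect_equal(got, pp$A_G * M_g * pp$cho_to_mmol, tolerance = 1e-3)
  }
})

test_that("fixed-step integration shows fourth-order convergence", {
  s0 <- c(5, 10, 95, 0.01)
  f <- function(dt) {
    s <- s0
    for (k in seq_len(round(30 / dt))) s <- plant_step(s, 20, 2, dt, pp)
    s[3]
  }
  e1 <- abs(f(2) - f(1))
  e2 <- abs(f(1) - f(0.5))
  order <- log2(e1 / e2)
  expect_gt(order, 3.8)
})

test_that("linearisation matches the closed-form coefficient matrices", {
  sys <- linearize(pp, g_d = 80)
  expect_equal(sys$A[1, 1], -1 / pp$tau_D)
  expect_equal(sys$A[3, 4], -80)
  expect_equal(sys$A, matrix(c(-0.1, 0, 0, 0,
                               0.1, -0.1, 0, 0,
                               0, 0.1, -0.2, -80,
                               0, 0, 0, -0.028), 4, 4, byrow = TRUE))
  expect_equal(sys$B[1, 1], pp$A_G)
  expect_equal(sys$B[4, 2], pp$p3 / pp$V)
  expect_equal(as.vector(sys$H), c(0, 0, 0, pp$p3 / pp$V))
  expect_equal(as.vector(sys$C), c(0, 0, 1, 0))
  expect_equal(linearize(pp, insulin_gain = "plant")$B[4, 2], pp$p3)
})

test_that("finite-difference Jacobian agrees with the linearisation", {
  sys <- linearize(pp, g_d = pp$g_b, insulin_gain = "plant")
  x0 <- c(0, 0, pp$g_b, 0)
  h <- 1e-6
  A_fd <- matrix(0, 4, 4)
  for (j in 1:4) {
    e <- rep(0, 4); e[j] <- h
    A_fd[, j] <- (plant_derivatives(x0 + e, pp$i_be, 0, pp) -
                  plant_derivatives(x0 - e, pp$i_be, 0, pp)) / (2 * h)
  }
  expect_equal(A_fd, sys$A, tolerance = 1e-6)
  b_ins <- (plant_derivatives(x0, pp$i_be + h, 0, pp) -
            plant_derivatives(x0, pp$i_be - h, 0, pp)) / (2 * h)
  expect_equal(b_ins, sys$B[, 2], tolerance = 1e-6)
  b_meal <- (plant_derivatives(x0, pp$i_be, h, pp) -
             plant_derivatives(x0, pp$i_be, 0, pp)) / h
  expect_equal(b_meal, sys$B[, 1], tolerance = 1e-6)
})

test_that("zero-order-hold discretisation reproduces scalar closed forms", {
  mk <- function(a) structure(list(A = matrix(a, 1, 1), B = matrix(2, 1, 1),
                                   C = matrix(1, 1, 1), H = matrix(1, 1, 1),
                                   dt = NA_real_), class = "linear_system")
  d0 <- discretize(mk(0), 0.7)
  expect_equal(d0$A[1, 1], 1)
  expect_equal(d0$B[1, 1], 2 * 0.7)
  da <- discretize(mk(-0.3), 2)
  expect_equal(da$A[1, 1], exp(-0.6))
  expect_equal(da$B[1, 1], 2 * (1 - exp(-0.6)) / 0.3)
  expect_error(discretize(da, 1), "already discrete")
})

test_that("the discretised default system is strictly stable", {
  dsys <- discretize(linearize(pp), 1)
  expect_lt(max(Mod(eigen(dsys$A, only.values = TRUE)$values)), 1)
})
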