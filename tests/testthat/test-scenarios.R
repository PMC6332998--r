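pp <- patient_params()

test_that("the default day has the declared meals and absorption classes", {
  sc <- default_day("fast")
  expect_equal(sc$meals$t_start, c(480, 780, 1140))
  expect_equal(sum(sc$meals$carbs), 180)
  expect_true(all(sc$meals$tau_D == 10))
  expect_true(all(default_day("slow")$meals$tau_D == 50))
  expect_equal(sc$meals$announced_carbs, sc$meals$carbs)
  expect_equal(sc$meals$announced_t_start, sc$meals$t_start)
})

test_that("perturbation draws announced meals with the specified spread", {
  sc <- default_day("fast")
  id <- perturb_scenario(sc, uncertainty_spec(0, 0), seed = 4)
  expect_equal(id$meals, sc$meals)
  p1 <- perturb_scenario(sc, uncertainty_spec(), seed = 4)
  p2 <- perturb_scenario(sc, uncertainty_spec(), seed = 4)
  expect_identical(p1$meals, p2$meals)
  expect_equal(p1$meals$carbs, sc$meals$carbs)   # the truth is untouched
  # law of large numbers on the announced/true carb ratio
  set.seed(71)
  ratios <- replicate(4000, {
    p <- perturb_scenario(sc, uncertainty_spec(), seed = sample.int(1e8, 1))
    p$meals$announced_carbs / p$meals$carbs
  })
  expect_equal(stats::sd(as.vector(ratios)), 0.46, tolerance = 0.02)
})

test_that("closed-loop runs are reproducible and correctly sampled", {
  sc <- make_scenario(data.frame(t_start = 480, carbs = 50, tau_D = 10),
                      horizon = 780)
  ctl <- controller_constant(pp$i_be)
  tr <- simulate_closed_loop(sc, ctl, pp, measurement_sd = 1, seed = 9)
  tr2 <- simulate_closed_loop(sc, ctl, pp, measurement_sd = 1, seed = 9)
  expect_identical(tr, tr2)
  expect_equal(nrow(tr), 781)
  full <- default_day("fast")
  tr3 <- simulate_closed_loop(full, ctl, pp)
  expect_equal(nrow(tr3), 1441)
})

test_that("all controllers hold the fasting equilibrium", {
  pol <- shared_policy()
  kf <- design_kalman(pp, dt = 1)
  sc <- make_scenario(data.frame(t_start = numeric(0), carbs = numeric(0),
                                 tau_D = numeric(0)), horizon = 360)
  for (nm in c("rlff", "orl", "pid")) {
    ctl <- rlglucose:::build_controller(nm, sc, pol, kf, pp)
    tr <- simulate_closed_loop(sc, ctl, pp)
    expect_lt(max(abs(tr$g[tr$time_min >= 60] - 80)), 2)
  }
})

test_that("uncertainty bands need replication and collapse without noise", {
  pol <- shared_policy()
  sc <- make_scenario(data.frame(t_start = 480, carbs = 50, tau_D = 10),
                      horizon = 840)
  expect_error(run_uncertainty(sc, uncertainty_spec(n_reps = 1), pol, pp),
               "n_reps >= 2")
  un0 <- run_uncertainty(sc, uncertainty_spec(0, 0, n_reps = 3), pol, pp,
                         seed = 2)
  expect_lt(max(un0$bands$sd_g), 1e-12)
  ctl <- rlglucose:::build_controller("rlff", sc, pol,
                                      design_kalman(pp, dt = 1), pp)
  nominal <- simulate_closed_loop(sc, ctl, pp)
  expect_equal(un0$bands$mean_g, nominal$g, tolerance = 1e-12)
})

test_that("wider carbohydrate uncertainty weakly widens the glucose bands", {
  pol <- shared_policy()
  sc <- make_scenario(data.frame(t_start = 480, carbs = 50, tau_D = 10),
                      horizon = 840)
  width <- vapply(c(0, 0.46, 0.9), function(f) {
    un <- run_uncertainty(sc, uncertainty_spec(f, 0, n_reps = 30), pol, pp,
                          seed = 5)  # common random numbers across levels
    max(un$bands$upper - un$bands$lower)
  }, numeric(1))
  expect_true(all(diff(width) >= 0))
})

test_that("carbohydrate-counting errors dominate meal-time errors for slow meals", {
  pol <- shared_policy()
  sc <- make_scenario(data.frame(t_start = 480, carbs = 50, tau_D = 50),
                      horizon = 840)
  un_cho <- run_uncertainty(sc, uncertainty_spec(0.46, 0, n_reps = 40), pol,
                            pp, seed = 6)
  un_time <- run_uncertainty(sc, uncertainty_spec(0, 2, n_reps = 40), pol,
                             pp, seed = 6)
  expect_gt(max(un_cho$bands$upper - un_cho$bands$lower),
            max(un_time$bands$upper - un_time$bands$lower))
})
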