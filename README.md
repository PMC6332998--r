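# rlglucose

Closed-loop basal-bolus insulin dosing for a simulated type-1 diabetes
patient: a reinforcement-learning basal controller, an inverse-model
feedforward bolus generator, and a steady-state Kalman filter, together
with the nonlinear glucose–insulin plant they act on and the comparison
and robustness experiments that evaluate them.

## The problem and the approach

People with type-1 diabetes produce no insulin; glucose control means
choosing a continuous **basal** insulin level plus **bolus** doses that
pre-empt meals.  This package simulates that loop end to end on a
minimal-model virtual patient,

    dD1/dt = A_G·D − D1/τ_D            (gut compartments, mmol)
    dD2/dt = (D1 − D2)/τ_D
    dg/dt  = −p1·(g − g_b) − χ·g + D2/τ_D     (plasma glucose, mg/dL)
    dχ/dt  = −p2·χ + p3·(i − i_be)            (insulin activity, 1/min)

with three cooperating controllers:

* **Basal (RL).**  A quadratic action-value function
  `Q(x, u) ≈ z'Pz`, `z = (g − g_d, χ, u)`, is fitted by least-squares
  policy iteration in the Kronecker basis `z ⊗ z`; the greedy policy is
  the closed form `u = −P_uu⁻¹ P_ux x`, applied on top of the equilibrium
  basal `i_be`.  Pretraining runs the fasting protocol (episodes from
  90 mg/dL towards the 80 mg/dL target) and converges to the discounted
  LQR solution of the linearised problem.
* **Bolus (feedforward).**  The meal path `G_meal = A_G/(τ_D s + 1)²` is
  cancelled through the insulin path `G_ins = p3/(s + p2)` by the inverse
  model `G_ff = −A_G(s + p2)/(p3(τ_D s + 1)²)`, realised in state space and
  driven by the announced meals; `G_meal + G_ff·G_ins ≡ 0` exactly.
* **Estimator (Kalman).**  Unmeasured states are reconstructed by the
  steady-state predictor-form filter whose gain solves the discrete
  algebraic Riccati equation of the linearised, zero-order-hold-discretised
  model (`R_w = R_v = 0.01`).

Comparison controllers: the RL basal law alone ("ORL") and a PID on
measured glucose (`Kp = 1, Ki = 0.001, Kd = 0.01`).  A scenario engine
runs daily meal profiles (fast and slow carbohydrate absorption) and
Monte-Carlo studies of carbohydrate-counting (46 % relative SD) and
meal-time (2 min SD) announcement errors.

See `vignettes/methods.Rmd` for the full model description, parameter
meanings and the numerical design choices.

## Worked example

```r
library(rlglucose)

params <- patient_params()          # virtual patient (Bergman-type model)
pt     <- pretrain(seed = 42)       # fasting-protocol policy iteration
round(pt$policy$K, 2)
#> [1]    36.68 -7510.83

filt <- design_kalman(params, dt = 1)
cmp  <- run_comparison(default_day("fast"), pt$policy, params, filter = filt)
print(cmp$metrics[, c("controller", "peak_excursion", "undershoot",
                      "fluctuation_range")], digits = 3)
#>   controller peak_excursion undershoot fluctuation_range
#> 1       rlff          0.396       6.30              6.30
#> 2        orl          3.716       7.19              7.19
#> 3        pid         35.364       5.21             35.36

un <- run_uncertainty(default_day("fast"), uncertainty_spec(), pt$policy,
                      params, seed = 42)
print(un$extremes, digits = 3)
#>   upper_above_target lower_below_target
#> 1               2.02               7.32
```

Reading the numbers: on the fast-absorption reference day (50/70/60 g
meals) the feedforward-augmented controller (rlff) keeps the postprandial
peak to 0.4 mg/dL above the 80 mg/dL target, versus 3.7 for the same basal
policy without boluses (orl) and 35.4 for the PID; its worst deviation over
the day (6.3 mg/dL) is the post-meal undershoot created by clamping insulin
at zero while the bolus tail asks for withdrawal.  Under meal-announcement
uncertainty the mean+SD band stays within about 2 mg/dL above target and
the mean−SD band within about 7 mg/dL below it.

A thin command-line wrapper ships in `inst/cli/rlglucose`
(`simulate`, `pretrain`, `bolus`, `design-filter`, `compare`,
`uncertainty`), each writing its output next to a JSON provenance block.

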