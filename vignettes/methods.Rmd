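---
title: "Closed-loop basal-bolus insulin dosing: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop basal-bolus insulin dosing: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlglucose)
```

## The control problem

In type-1 diabetes the pancreas produces no insulin, so plasma glucose must
be regulated by exogenous dosing: a slowly varying *basal* insulin level
that holds fasting glucose at a healthy target, and *bolus* doses that
absorb the glucose rise caused by meals.  This package simulates a full
closed loop around a minimal-model virtual patient: a reinforcement-learning
agent adapts the basal level from measured glucose, an inverse-model
feedforward generator shapes the bolus from announced meal information, and
a steady-state Kalman filter reconstructs the insulin activity state that no
sensor measures.

## The virtual patient

The plant couples a two-compartment carbohydrate absorption chain to
Bergman-type glucose-insulin kinetics:

$$
\begin{aligned}
\dot D_1 &= A_G\,D(t) - D_1/\tau_D, &
\dot D_2 &= (D_1 - D_2)/\tau_D,\\
\dot g   &= -p_1\,(g - g_b) - \chi\, g + D_2/\tau_D, &
\dot\chi &= -p_2\,\chi + p_3\,(i - i_{be}),
\end{aligned}
$$

where $D(t)$ is the carbohydrate intake rate (mmol/min), $D_1, D_2$ the
gut compartments (mmol), $g$ plasma glucose (mg/dL), $\chi$ the
interstitial insulin activity (1/min) and $i$ the commanded plasma insulin
concentration ($\mu$IU/ml).  Defaults (`patient_params()`): $p_1 = 0.2$,
$p_2 = 0.028$, $p_3 = 10^{-4}$ (all 1/min), $A_G = 0.8$, $\tau_D = 10$ min
(50 min for slowly absorbed meals), $V = 2730$ g, $i_{be} = 7.326$
$\mu$IU/ml, and basal glucose $g_b$ equal to the control target
$g_d = 80$ mg/dL.  A meal of $M$ grams is applied as a rectangular pulse of
15 min at rate $M \cdot (1000/180)/15$ mmol/min; both the pulse length and
the grams-to-mmol conversion are configurable.

The bilinear uptake term $-\chi g$ is the single nonlinearity; its Jacobian
at the basal equilibrium contributes the $-g_d$ entry of the linearised
model returned by `linearize()`.  Two conventions exist for the insulin
input gain of the $\chi$ equation, differing by the plasma volume: the
transfer-function factorisation behind the feedforward uses $p_3$, while
the linear model used for estimator design divides by $V$.  Both are
exposed through `linearize(..., insulin_gain = )`; the plant itself uses
$p_3$, the filter design the $p_3/V$ form.  The consequence — discussed
below — is that the filter's $\hat\chi$ tracks a state roughly $V$-fold
smaller than the plant's $\chi$, so the deployed policy's $\hat\chi$ term
is essentially inert and glucose feedback dominates.

Integration is fixed-step classical Runge-Kutta with inputs held over each
step (`plant_step()`), matching the zero-order-hold convention of the
discrete-time controller; the observed convergence order ($\ge 3.8$ on meal
responses) is asserted in the test suite.  Adaptive integrators were
deliberately avoided: fixed-step RK4 keeps runs bit-reproducible and makes
the discretisation error analysable.

## Basal control by least-squares policy iteration

The controller state is $x = (g - g_d,\ \chi)$ and the action $u$ is the
basal adjustment around $i_{be}$.  The per-step cost is
$r = x^\top Q x + R u^2$ with $Q = \mathrm{diag}(100, 0.1)$, $R = 0.01$:
glucose error dominates, insulin activity and action effort regularise.
The action-value function is approximated as a quadratic form
$Q^\pi(x, u) \approx z^\top P z$, $z = (x, u)$, expressed linearly in the
Kronecker basis $\Phi(z) = z \otimes z$ so that policy evaluation is a
linear least-squares problem over sampled transitions:

$$
\min_w \big\Vert (\Phi(z_k) - \gamma\,\Phi(z_{k+1}))^\top w - r_{k+1}
\big\Vert^2 .
$$

`policy_evaluation()` recomputes the next action as the current policy's
greedy action (LSTDQ); the greedy improvement is the closed form
$u = -P_{uu}^{-1} P_{ux} x$ and requires the identified action curvature
$P_{uu}$ to be positive.  The discount factor defaults to $\gamma = 0.9$
(about a 10-minute effective horizon at 1-min sampling); $\gamma = 1$ is
used in the test that checks the iteration against the discrete-Riccati
LQR solution on the linearised plant.

### Numerical design of the evaluation step

The Kronecker basis has 9 coordinates but only 6 distinct monomials, so the
regressor is structurally rank deficient; the solver therefore returns the
minimum-norm SVD solution and truncates singular values below a relative
tolerance.  The tolerance is a real modelling choice, not a formality:

* on the linearised fasting model the transitions are *exactly* consistent
  with a quadratic value function, and once the policy tightens, the
  exploration noise is small relative to the policy term, compressing the
  informative directions to $\sim 10^{-11}$ of the leading singular value.
  A tight tolerance ($10^{-12}$) keeps them and the iteration converges to
  the LQR fixed point;
* on the nonlinear plant, the weakly excited directions carry mostly
  Bellman-residual noise from the bilinear term, and a loose tolerance
  ($10^{-6}$) that truncates them is the safer default.

### Why pretraining uses the linearised fasting model

Pretraining follows the fasting protocol: episodes of 30 one-minute steps
from 90 mg/dL towards the 80 mg/dL target, additive Gaussian exploration
($\sigma = 1\ \mu$IU/ml), a rolling window of 300 transitions, one
evaluation/improvement per episode, and a divergence guard that aborts an
episode and halves the gains if glucose leaves [20, 600] mg/dL.  The
initial interstitial activity of each episode is drawn uniformly from
$[0, 0.05]$ so that the $\chi$ direction of the kernel is excited at all.

The default training environment is the fasting deviation model linearised
at the target (`pretrain(env = "linear")`).  The reason is identifiability,
not convenience.  With the default cost weights the true action curvature
is $P_{uu} = R + \gamma B^\top P B \approx 0.01$–$0.03$, because a single
1-minute insulin step moves the state only $O(p_3\,\mathrm{d}t)$.  On the
nonlinear plant the quadratic model is misspecified by the bilinear term,
leaving Bellman residuals several orders of magnitude larger than that
curvature; the estimated sign of $P_{uu}$ is then essentially random and
policy iteration wanders between inert and destabilising gains from seed to
seed.  On the
linear environment the same algorithm, data sizes and exploration converge
to the discounted LQR gain for every seed, which is also the behaviour a
correctly identified model-free learner should approach.  The nonlinear
environment remains available (`env = "nonlinear"`) for studying exactly
this failure mode.

At deployment the policy acts on the *measured* glucose deviation and the
Kalman $\hat\chi$.  Because the filter follows the $p_3/V$ convention, its
$\hat\chi$ is far smaller than the plant's $\chi$ and the learned
$\hat\chi$ gain contributes negligibly; in practice the basal loop behaves
like a well-tuned proportional controller on glucose error.  This is a
faithful consequence of combining the two stated gain conventions, and it
is what keeps the basal loop from fighting the feedforward bolus (a large
bolus raises the plant's $\chi$, and a $\chi$-proportional basal cut would
otherwise cancel the bolus through the nonnegativity clamp).

## Feedforward meal compensation

The meal and insulin submodels are linear time-invariant with transfer
functions

$$
G_{meal}(s) = \frac{A_G}{(\tau_D s + 1)^2}, \qquad
G_{ins}(s) = \frac{p_3}{s + p_2},
$$

and the inverse-model feedforward is chosen to null the meal path:

$$
G_{ff}(s) = -\,G_{meal}(s)\,G_{ins}^{-1}(s)
          = \frac{-A_G\,(s + p_2)}{p_3\,(\tau_D s + 1)^2},
$$

so that $G_{meal} + G_{ff}\,G_{ins} \equiv 0$ exactly
(`ff_frequency_response()`; verified to $10^{-12}$ at random complex
frequencies).  The glucose equation couples the canceled pair through the
$-g_d$ gain of the uptake term, so the insulin *increment* that cancels a
meal on the linearised plant is the inverse-model output divided by
$-g_d$; `bolus_profile()` returns this signed increment directly (the raw
unscaled output is available with `scale = "raw"`).

The $(s + p_2)$ numerator is realised in companion state-space form driven
by the announced rectangular meal signal, so the meal rate is never
differentiated numerically and pulse edges are handled exactly
(`bolus_ode_step()`).  Because the applied insulin is held constant over
each 1-minute sample, the stored profile value is the substep *average* of
the continuous output over the hold interval — the best piecewise-constant
representation — which keeps the residual glucose deviation of a
compensated meal on the linearised plant below 1 % of the uncompensated
peak at 1-min sampling.

Two practical caveats follow from inverting a stable but
non-minimum-effort model.  First, after the absorption peak the exact
canceling increment is strongly negative (insulin should be withdrawn
faster than clearance allows); the total command clamps at zero and the
excess insulin activity produces a moderate post-meal undershoot — the
price of exact peak cancellation.  Second, the compensation degrades
gracefully with wrong announcements: the residual is the response to the
*difference* between true and announced meal signals.

## State estimation

The filter is the steady-state one-step predictor on the zero-order-hold
discretisation of the volume-scaled linear model:
$\hat x_{k+1|k} = A\hat x + B u_K + L(y - C\hat x)$, with
$u_K$ = (announced meal rate, commanded insulin deviation) and
$y = g - g_d$ measured.  The gain comes from the estimation-form discrete
algebraic Riccati equation with process noise entering through the insulin
noise column $H$ and variances $R_w = R_v = 0.01$; `solve_riccati()` uses
the structure-preserving doubling algorithm (quadratically convergent,
residual checked against $10^{-9}$), and the tests cross-check it against
brute-force covariance iteration.  The filter is designed once at the
target and not relinearised during the day.  Innovation whiteness under
the design noise model and geometric error decay on the noiseless plant
are asserted in the suite.

## Scenarios, baselines and uncertainty studies

`default_day()` defines the reference day: 50 g at 08:00, 70 g at 13:00,
60 g at 19:00, 24 h horizon, 1-min sampling, with fast ($\tau_D = 10$) and
slow ($\tau_D = 50$) absorption classes.  The comparison controllers are
the RL basal policy alone (ORL) and a PID on measured glucose with the
reference gains $K_p = 1$, $K_i = 0.001$, $K_d = 0.01$, derivative on the
raw measurement, no anti-windup by default (an optional conditional
integration flag exists for exploration, off by default, because the
reference tuning has none).

`perturb_scenario()` models announcement errors: announced carbohydrates
$\sim \mathcal N(\text{true}, (0.46\cdot\text{true})^2)$ truncated at zero
(reported adult carbohydrate-counting accuracy) and announced start times
$\sim \mathcal N(\text{true}, 2^2)$ min.  `run_uncertainty()` repeats the
day (default 100 repetitions) with freshly drawn announcements while the
plant digests the truth, and reports per-minute mean $\pm$ SD bands and
their extreme excursions.  Common random numbers (shared sub-seed
sequences) are used across uncertainty levels and controllers so paired
comparisons are not washed out by Monte-Carlo noise.

What the generator emulates: meal timing/size structure of an ordinary
day, announcement errors with the stated spreads, sensor sampling at
1-minute intervals.  What it does not emulate: CGM sensor error models
(drift, autocorrelated noise), insulin pump quantisation and infusion
kinetics, circadian variation of insulin sensitivity, exercise and stress.
Passing the included checks therefore demonstrates correctness of the
control and estimation machinery on the stated model class, not clinical
performance.

## Numerical choices and degenerate inputs

* Sampling `dt = 1` min throughout (sensor-like sampling); all
  discretisations are exact zero-order-hold via the augmented matrix
  exponential.
* Insulin nonnegativity: the total command is clamped at zero; clamping
  events are counted on every trajectory (`attr(traj, "n_clamped")`).
* Divergent controllers abort with time-and-state context; in
  `run_comparison()` one controller's failure does not stop the others.
* Empty meal tables, zero-episode pretraining and zero-uncertainty
  specifications are all valid degenerate inputs with the obvious
  behaviour (flat basal trace, untouched initial kernel, collapsed bands).
* Problem sizes used by the shipped experiments: 50 pretraining episodes
  of 30 steps, 24 h days at 1-min sampling (1441 samples), 100
  Monte-Carlo repetitions per uncertainty study.

## Known limitations

* The two insulin-gain conventions ($p_3$ vs $p_3/V$) cannot be
  made mutually consistent; this package keeps each subsystem faithful to
  its own stated form and documents the interaction.  A single coherent
  convention would change both the learned gains and the estimator scale.
* Exact feedforward inversion minimises the postprandial peak but trades
  it for a clamp-induced undershoot; a detuned (partial) inversion would
  trade the other way.  The package implements the exact inverse because
  the design condition defining the feedforward is exact cancellation.
* Model-free pretraining directly on the nonlinear plant with the default
  cost weights is statistically unidentifiable at realistic data sizes
  (see above); the package makes the failure reproducible rather than
  hiding it behind an unstable default.
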