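Package: rlglucose
Title: Closed-Loop Blood Glucose Control by Reinforcement Learning with
    Feedforward Meal Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for closed-loop basal-bolus insulin dosing
    in type-1 diabetes.  Provides a nonlinear minimal-model glucose-insulin
    plant with a two-compartment carbohydrate absorption chain, a
    reinforcement-learning basal controller based on least-squares policy
    iteration with a quadratic (Kronecker-basis) action-value function, a
    feedforward bolus generator obtained by inverting the meal and insulin
    transfer functions, a steady-state Kalman filter designed from the
    discrete algebraic Riccati equation, and PID and optimal-RL comparison
    controllers.  Includes a scenario engine for daily meal simulations and
    Monte-Carlo robustness studies under carbohydrate-counting and meal-time
    uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
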