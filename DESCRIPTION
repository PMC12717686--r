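Package: roisim
Title: Simulation-Based Return-on-Investment Evaluation of Adherence-Enhancing Chronic Disease Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time health-economic simulator for chronic disease
    management policies. Couples logistic disease progression with
    time-varying medication adherence and policy expenditure in a discounted
    cumulative cost model, and evaluates policy designs by return on
    investment (ROI), payback time, and break-even policy cost. Includes a
    six-scenario policy registry (early, delayed, regressive, adaptive-nudge
    and low-impact interventions against a no-intervention baseline),
    Monte Carlo propagation of behavioral uncertainty in the adherence gain,
    (delta, gamma) design-space scans with iso-ROI contours and a
    cost-effectiveness frontier, robustness stress tests (cost inflation,
    accelerated progression), two-anchor dollar calibration, and a
    command-line interface over JSON/YAML configuration files.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
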