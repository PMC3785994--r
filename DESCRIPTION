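Package: adaptrand
Title: Covariate-Adaptive Minimization Randomization for Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequential covariate-adaptive treatment allocation for
    randomized clinical trials, with three minimization engines: the
    Pocock-Simon marginal-total method, a symmetric Kullback-Leibler
    divergence (Jeffreys) balance index supporting continuous and
    categorical prognostic factors, and two-way minimization that trades
    off arm-size against covariate-distribution imbalance with a dynamic
    biased coin. Includes double-blind masked-number pools with automatic
    replenishment, an append-only auditable allocation ledger with
    deterministic replay and traceable corrections, CSV batch input,
    balance reporting, a synthetic-cohort generator, and a paired
    simulation harness comparing minimization against simple
    randomization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
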