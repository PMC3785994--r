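# adaptrand

Covariate-adaptive minimization randomization for clinical trials.

Simple randomization leaves chance imbalance in prognostic factors and arm
sizes — enough, in small and moderate trials, to cost real precision.
`adaptrand` is for trial statisticians and data managers who need
sequential, auditable treatment allocation that actively minimizes that
imbalance while keeping assignments unpredictable. It implements three
minimization engines behind one allocation interface:

* **Pocock–Simon marginal totals** (any number of arms, categorical
  factors): the score for arm *i* is the weighted marginal treatment total
  at the incoming subject's factor levels,
  *G<sub>i</sub>* = Σ<sub>j</sub> *w<sub>j</sub>* *n*<sub>*i*, *j*, *r<sub>j</sub>*</sub>;
  the smallest *G<sub>i</sub>* marks the under-represented arm, which
  receives the biased probability *P<sub>i</sub>* (remaining arms split
  1 − *P<sub>i</sub>* equally; tied scores pool and split their ranks'
  probabilities).
* **Symmetric Kullback–Leibler (Jeffreys) divergence** (2 arms,
  continuous and categorical factors): *d<sub>i</sub>* is the Jeffreys
  divergence between the two arms' covariate distributions — multivariate
  normal summaries for continuous factors, smoothed level proportions for
  categorical ones — assuming the new subject joins arm *i*; the lower
  *d<sub>i</sub>* gets *P<sub>i</sub>*. The first 4 subjects form a
  permuted block of 2 per arm.
* **Two-way minimization** (2 arms, categorical factors): balances arm
  sizes (δ = |*n<sub>T</sub>* − *n<sub>C</sub>*|) and factor
  distributions (*D<sub>i</sub>* = Σ<sub>j</sub> *w<sub>j</sub>*
  |*n*<sub>*T*, *j*, *r<sub>j</sub>*</sub> − *n*<sub>*C*, *j*,
  *r<sub>j</sub>*</sub>|) alternately, minimizing δ with dynamic
  probability *P* = 1 − 0.95<sup>δ</sup> and *D* otherwise.

Around the engines: validated subject intake (one at a time or CSV
batches, duplicate IDs refused), an append-only allocation ledger with
reasoned corrections and deterministic replay, masked-number pools for
double-blind trials (projected enrollment + 10%, automatic replenishment
at 90% assigned, per site and arm), balance summary tables, a
synthetic-cohort generator, and a paired simulation harness against
simple randomization. Everything is reproducible: all randomness derives
from the trial seed and the ledger position, never the wall clock.

## Worked example

```r
library(adaptrand)

cfg <- trial_config(
  trial_id = "demo", method = "pocock_simon", n_arms = 2,
  factors = list(
    factor_spec("gender",  "categorical", levels = c("Female", "Male")),
    factor_spec("smoking", "categorical", levels = c("never", "current"))),
  biased_probability = 0.8, seed = 20260930)

ledger <- new_ledger("demo")
set.seed(1)
for (i in 1:40) {
  s <- subject_record(sprintf("P%02d", i), "site1",
                      list(gender  = sample(c("Female", "Male"), 1),
                           smoking = sample(c("never", "current"), 1)))
  ledger <- randomize_subject(ledger, cfg, s)$ledger
}
balance_table(ledger, cfg)
#>  factor   level arm 1 arm 2 total max diff
#>  gender  Female      9    10    19        1
#>  gender  Male       12     9    21        3
#>  smoking never      10     9    19        1
#>  smoking current    11    10    21        1
#>  Total              21    19    40        2
replay_ledger(ledger, cfg)$message
#> [1] "verified, 40 records"
```

After 40 subjects no factor level differs by more than 3 between arms, and
the total split is 21/19. Each ledger record stores the score vector, the
probability vector actually used, and the uniform draw — the 40th record,
for instance, holds scores (20, 18), so arm 2 was favored with
probabilities (0.2, 0.8), and the stored draw 0.4757 selected arm 2.
`replay_ledger()` recomputes all of this from the ledger prefix and
confirms every recorded arm; flip any arm code by hand and it reports the
divergent sequence number.

A command-line interface over the same functions lives at
`system.file("cli", "adaptrand.R", package = "adaptrand")`, with
subcommands `init`, `randomize`, `import`, `report`, `export`,
`masked-table`, `replay`, and `simulate` operating on a portable trial
directory (YAML config + NDJSON ledger + masked-number state).

See `vignettes/minimization-methods.Rmd` for the statistical background,
the numerical safeguards (covariance regularization, proportion
smoothing, tie tolerances), and known limitations.

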