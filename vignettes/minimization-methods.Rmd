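---
title: "Covariate-adaptive minimization: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adaptive minimization: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrand)
```

## The problem

Simple randomization guarantees unbiased allocation in expectation, but in
small and moderate trials it routinely leaves chance imbalance in important
prognostic factors (accidental bias) and in arm sizes, costing precision.
Covariate-adaptive *minimization* addresses this by scoring, for each new
subject, how imbalanced the trial would become under each hypothetical
assignment, and then assigning the subject to the least-imbalancing arm with
a high — but deliberately not certain — probability. The residual randomness
(Efron's biased-coin idea) is what protects against selection bias: a fully
deterministic rule would let staff predict upcoming assignments.

`adaptrand` implements three minimization engines behind one sequential
allocation interface, plus the operational machinery a real trial needs:
validated subject intake (single records or CSV batches), an append-only
allocation ledger that supports corrections and deterministic replay,
masked-number pools for double-blind trials, balance reporting, and a
simulation harness for comparing schemes before a protocol is finalized.

## The three imbalance scores

### Pocock–Simon marginal totals

For arms $i = 1, \dots, I$, categorical factors $j = 1, \dots, J$ with
levels $m = 1, \dots, M_j$, let $n_{ijm}$ be the number of subjects at
level $m$ of factor $j$ already assigned to arm $i$. A new subject presents
levels $r_1, \dots, r_J$. The score for arm $i$ is the weighted marginal
treatment total at the subject's own levels:

$$G_i = \sum_{j=1}^{J} w_j \, n_{i, j, r_j}.$$

A small $G_i$ means arm $i$ is under-represented among subjects *like this
one*, margin by margin (joint strata are deliberately not balanced — with
several factors they are too sparse to balance at realistic trial sizes).
Adding the conventional "+1" for the incoming subject would shift every
$G_i$ by the same constant $\sum_j w_j$ and cannot change the ranking, so
it is omitted. Other members of the Pocock–Simon family (range or variance
functionals per margin) are intentionally not implemented; the marginal
total is the score this package is built around, and for two arms it
favors the same arm as the range functional on each margin.

The scores are ranked and converted to assignment probabilities: the arm
with the smallest score receives the biased probability $P_i$, every other
arm receives $(1 - P_i)/(I - 1)$, and arms with tied scores (relative
tolerance $10^{-9}$ — scores are sums of weighted counts, and with
non-integer weights exact equality would be representation-dependent) pool
the probability mass of the ranks they occupy and split it equally. One
uniform draw then selects the arm by inverse CDF. Keeping ties inside the
probability vector, rather than re-flipping a separate coin, means each
allocation consumes exactly one uniform, which keeps replay trivial.

### Symmetric Kullback–Leibler (Jeffreys) divergence

The second engine supports *continuous* prognostic factors directly,
without categorization, for two-arm trials. Each arm's continuous factors
are summarized as a multivariate normal (mean vector $\mu_i$, maximum-
likelihood covariance $S_i$), and each categorical factor as a vector of
level proportions. The imbalance left by hypothetically assigning the new
subject to arm $i$ is the Jeffreys divergence (the symmetrized KL sum)
between the two arms' distributions after that assignment:

$$d_i = \underbrace{\tfrac12\!\left[\operatorname{tr}(S_{i'}^{-1}S_i) +
\operatorname{tr}(S_i^{-1}S_{i'}) - 2j' +
(\mu_i - \mu_{i'})^\top (S_i^{-1} + S_{i'}^{-1})(\mu_i -
\mu_{i'})\right]}_{\text{continuous factors, MVN closed form}}
\; + \; \sum_{\text{categorical } j} w_j \sum_m (p_{ijm} - p_{i'jm})
\ln\frac{p_{ijm}}{p_{i'jm}}.$$

The log-determinant terms of the two directed KLs cancel in the symmetric
sum. The arm with the lower $d_i$ receives $P_i$ through the same biased
coin as above. The first four subjects are allocated as a permuted block
of two per arm, realized sequentially: at each position the draw
probability is proportional to each arm's remaining slots in the
$(1,1,2,2)$ block, which is distributionally identical to drawing the
permutation up front but needs only the standard one-uniform-per-subject
draw discipline.

Numerical choices, all of which matter only while arms are small:

* **Covariance regularization.** While an arm holds $n_i \le j' + 1$
  subjects the ML covariance is rank-deficient, so it is restricted to its
  diagonal; a relative ridge $10^{-6}\cdot\overline{\operatorname{diag}(S)}$
  (absolute floor $10^{-6}$ when the diagonal is zero, e.g. a single
  subject) keeps it invertible. From the fifth subject onward $d_i$ is
  therefore always finite.
* **Proportion smoothing.** Early in a trial a categorical level often has
  mass in one arm only, which makes the discrete Jeffreys sum infinite.
  Half a pseudo-count per level (Haldane–Anscombe) is added before forming
  proportions.
* **Scale.** Continuous factors enter on their recorded scale; no
  automatic transformation is attempted. Configurations with continuous
  factors trigger a one-time advisory about the multivariate-normality
  assumption and the value of consulting a biostatistician about
  transformations.
* The continuous block and each categorical factor are summed with weight
  1 by default; categorical weights are configurable per factor.

### Two-way minimization

The third engine (two arms, categorical factors) balances two quantities
*alternately* rather than combining them into one score: the arm-size
imbalance $\delta = |n_T - n_C|$ and the factor-distribution imbalance

$$D_i = \sum_j w_j \, \big|\,n_{T, j, r_j} - n_{C, j, r_j}\big|$$

evaluated after hypothetically adding the subject to arm $i$. With
probability $P = 1 - 0.95^{\delta}$ the subject is assigned to the smaller
arm (minimizing $\delta$); otherwise to the arm minimizing $D$. When the
arms are equal in size, $P = 0$ and covariate balance alone drives the
assignment; as $\delta$ grows, size correction takes over with probability
approaching 1. Ties on the active criterion fall back to a fair coin. No
user-set biased probability exists for this method — the coin is the
$\delta$-driven function itself, and the base 0.95 is a named constant,
not a tuning knob. Whether $D$ is evaluated before or after the
hypothetical addition is not observable from the ranking when evaluated
"before" (both arms shift identically at a shared level); "after" is
implemented, mirroring the KLD engine's hypothetical-assignment logic.

## The biased probability

$P_i$ trades balance against predictability and is accepted on
$[1/I,\, 1)$: at $1/I$ minimization degenerates to simple randomization,
and values of 1 are refused unless the config sets an explicit
`deterministic` flag, because pure minimization makes every assignment
predictable to anyone tracking the ledger (the flag exists chiefly for
oracle testing, where argmin behavior must be exact). The simulation
harness quantifies the trade: the correct-guess rate of a greedy adversary
rises monotonically with $P_i$. A typical two-arm choice is $2/3$; the
package default in examples is $0.8$.

For the Pocock–Simon engine the first `n_initial_simple` subjects (default
1) are allocated by unrestricted uniform draws, and configurations below
10 trigger a non-blocking recommendation to use simple randomization for
the first 10–15 subjects, which removes any information an observer could
extract from the earliest assignments. The initial simple phase is fully
unrestricted (not blocked): blocking would partially defeat its
unpredictability purpose, and the minimization phase corrects any size
drift it leaves.

## The ledger, determinism and corrections

Every allocation appends one immutable record: subject fields, arm, phase,
the score vector, the probability vector actually used, and the uniform
draw(s). All randomness derives from the trial seed and the current ledger
length — each allocation's draws come from a generator state derived from
`(seed, ledger position)`, consumed in a fixed order (two-way: criterion
uniform first, selection uniform second). Consequences, each of which the
test suite asserts:

* identical seed + subject stream ⇒ identical ledgers, bitwise in the
  stored draws (timestamps are recorded for audit but excluded from
  determinism comparisons);
* `replay_ledger()` re-derives every score and probability vector from the
  ledger prefix and re-applies the stored draws, flagging the first
  divergence — a tampered arm code is caught, an honest ledger verifies;
* corrections (wrong factor value, misspelled site) are append-only
  entries with a mandatory reason; they never touch a recorded outcome and
  consume no randomness, so allocations made before a correction are
  unchanged while later allocations count the corrected values. Replay
  applies each correction at the ledger position where it was recorded.

## Masked numbers for double-blind trials

For double-blind trials each site receives a pool of
$\lceil 1.10 \times \text{projected max}\rceil$ masked numbers ("M" + 6
random digits, globally unique, issuance order pre-shuffled within
site/arm so neither code value nor issue order carries arm information),
split evenly across arms with randomized remainders. When a site/arm pool
reaches 90% assigned, a batch of $\lceil 10\%$ of the initial pool$\rceil$
(minimum 5) is appended for that site/arm only, so exhaustion is
unreachable in normal operation. The pool-size arithmetic is done in exact
rational form ($\lceil 11x/10 \rceil$, $\lceil 9x/10 \rceil$) — the naive
floating-point `ceiling(1.10 * 100)` is 111 on IEEE doubles. The
site/number/arm key is exported only through an explicitly acknowledged
"unblinded" path; blinded ledger exports carry masked numbers and never
arm codes or score vectors.

## The synthetic-cohort generator and what the simulations show

`cohort_spec()`/`generate_cohort()` produce enrollment streams with
independent subjects: categorical factors from fixed level frequencies,
continuous factors from (optionally correlated) normals, sites from fixed
probabilities. Defaults used throughout the package's own experiments:
trials of $n = 200$ subjects, balanced binary factors at 50/50, continuous
factors standard normal, 500 replicates (200 for the KLD comparisons,
whose per-allocation covariance work is heavier) — sizes chosen as typical
of the small-to-moderate trials where minimization matters most, and
small enough that a full paired comparison runs in minutes on one CPU.

`run_comparison()` allocates each replicate cohort under every scheme plus
a simple-randomization baseline with shared, replicate-derived seeds, so
contrasts are paired. Its allocation loop maintains counts incrementally
but composes exactly the exported scoring kernels and the engine's seed
derivation; a suite test asserts the loop is draw-for-draw identical to
`randomize_subject()` for all three methods. With the default conditions
the package's acceptance checks find, as expected: Pocock–Simon at
$P_i = 0.8$ cuts mean terminal max marginal imbalance to roughly a sixth
of simple randomization's; the KLD engine cuts the mean absolute
between-arm mean difference of a standard-normal factor by roughly a
factor of eight; two-way minimization holds terminal $|n_T - n_C|$ near
zero where simple randomization averages about $\sqrt{2n/\pi} \approx 11$
at $n = 200$.

What these cohorts do *not* emulate: time trends in enrollment, site-level
heterogeneity in factor distributions, missing or erroneous factor values,
and informative enrollment order. Passing simulations therefore show the
engines balance what they score under clean sequential enrollment; they do
not certify behavior under covariate drift, nor do they address inference
after minimization (re-randomization or permutation analyses are out of
scope).

## Known limitations

* **KLD arm-size drift.** The Jeffreys index compares distributions only;
  no term rewards equal arm sizes, and the larger arm's summary is
  perturbed less by a new subject, so the index mildly favors it. Over
  $n = 200$ the terminal arm-size gap under the KLD engine averages
  noticeably *above* simple randomization (order 20 vs 14 in the package's
  own simulations) even as covariate balance improves dramatically. Trials
  for which near-equal arm sizes matter should prefer Pocock–Simon (which
  self-corrects sizes through every margin) or two-way minimization, or
  should monitor $\delta$ alongside the balance report.
* Two arms only for the KLD and two-way engines; Pocock–Simon supports
  $I \ge 2$.
* For $I > 2$ the probability schedule gives the best-ranked arm $P_i$ and
  splits the remainder equally — a simple choice; schedules graded in rank
  are not implemented.
* The ledger contract is strictly sequential; concurrent multi-user
  randomization is explicitly out of scope (the CLI's atomic
  write-then-rename protects against torn files, not against two
  simultaneous writers).
* First-order interactions can be balanced by encoding a product factor
  (e.g. gender × smoking as a 4-level factor); no automatic interaction
  support exists.

## A worked example

```{r example}
cfg <- trial_config(
  trial_id = "demo", method = "pocock_simon", n_arms = 2,
  factors = list(
    factor_spec("gender", "categorical", levels = c("Female", "Male")),
    factor_spec("smoking", "categorical", levels = c("never", "current"))),
  biased_probability = 0.8, seed = 20260930)

ledger <- new_ledger("demo")
set.seed(1)
for (i in 1:40) {
  s <- subject_record(sprintf("P%02d", i), "site1",
                      list(gender = sample(c("Female", "Male"), 1),
                           smoking = sample(c("never", "current"), 1)))
  ledger <- randomize_subject(ledger, cfg, s)$ledger
}
balance_table(ledger, cfg)
replay_ledger(ledger, cfg)$message
```
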