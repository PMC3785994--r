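# Two-way minimization for 2-arm trials: balance either the arm sizes
# (delta) or the prognostic-factor distributions (D), choosing which to
# minimize by a dynamic coin P = 1 - 0.95^delta.

#' Arm-size imbalance delta
#'
#' @param ledger An `allocation_ledger` of a 2-arm trial.
#' @return \eqn{\delta = |n_T - n_C|}, the absolute difference between the
#'   two arm totals.
#' @export
size_imbalance <- function(ledger) {
  tot <- arm_totals(ledger, 2L)
  abs(tot[[1]] - tot[[2]])
}

#' Prognostic-factor distribution imbalance D
#'
#' For each candidate arm `i`, hypothetically adds the incoming subject to
#' arm `i` and returns the weighted sum over factors of the absolute
#' marginal count gap at the subject's own levels:
#' \deqn{D_i = \sum_j w_j \, |n_{T, j, r_j} - n_{C, j, r_j}|}
#' evaluated after the hypothetical addition. The smaller `D_i` marks the
#' assignment that leaves the factor margins more balanced.
#'
#' @param ledger An `allocation_ledger` of a 2-arm trial.
#' @param cfg A validated `trial_config` (all factors categorical).
#' @param subject A validated `subject_record`.
#' @param upto,as_of Prefix controls as in [marginal_counts()].
#' @return Numeric vector `c(D_1, D_2)`.
#' @export
distribution_imbalance <- function(ledger, cfg, subject,
                                   upto = ledger_size(ledger), as_of = Inf) {
  counts <- marginal_counts(ledger, cfg, upto = upto, as_of = as_of)
  w <- factor_weights(cfg)
  vals <- subject$categorical_values
  if (!length(vals) && !is.null(subject$values)) vals <- subject$values
  vapply(1:2, function(i) {
    D <- 0
    for (j in names(counts)) {
      r_j <- as.character(vals[[j]])
      n_at_level <- counts[[j]][, r_j]
      n_at_level[i] <- n_at_level[i] + 1L   # hypothetical addition
      D <- D + w[[j]] * abs(n_at_level[1] - n_at_level[2])
    }
    D
  }, 0)
}

#' Dynamic coin for two-way minimization
#'
#' The probability of minimizing the arm-size imbalance rather than the
#' factor-distribution imbalance: \eqn{P = 1 - 0.95^\delta}. Zero when the
#' arms are balanced (size never drives the choice), strictly increasing
#' in \eqn{\delta}, approaching 1 as the size gap grows.
#'
#' @param delta Nonnegative integer arm-size imbalance.
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' p_minimize_delta(0)  # 0
#' p_minimize_delta(1)  # 0.05
p_minimize_delta <- function(delta) {
  if (any(delta < 0)) stop("delta must be nonnegative")
  1 - TWO_WAY_BASE^delta
}

# Named constant, not user-configurable.
TWO_WAY_BASE <- 0.95

#' Two-way minimization assignment
#'
#' Draws a criterion uniform `u`; with probability \eqn{P = 1 - 0.95^\delta}
#' (i.e. `u < P`) the subject goes to the smaller arm, otherwise to the arm
#' minimizing the distribution imbalance `D`. A tie on the active criterion
#' falls back to a fair coin, expressed as a (possibly degenerate) two-point
#' probability vector over the arms from which one further uniform selects
#' by inverse CDF. Draw order is fixed — criterion first, selection second —
#' so ledgers replay deterministically; both draws are recorded.
#'
#' @param ledger An `allocation_ledger` with each arm already occupied
#'   (the simple initial phase owns allocation before that).
#' @param cfg A validated `trial_config` with `method = "two_way"`.
#' @param subject A validated `subject_record`.
#' @param criterion_draw,uniform_draw Supply stored draws to replay a past
#'   allocation instead of consuming fresh randomness.
#' @param upto,as_of Prefix controls as in [marginal_counts()].
#' @return List: `arm_code`, `criterion_used` (`"delta"` or `"D"`),
#'   `score_vector` (the per-arm `D` values), `probability_vector`
#'   (conditional on the active criterion), `criterion_draw`,
#'   `uniform_draw`.
#' @export
two_way_assign <- function(ledger, cfg, subject,
                           criterion_draw = NULL, uniform_draw = NULL,
                           upto = ledger_size(ledger), as_of = Inf) {
  tot <- arm_totals(ledger, 2L)
  delta <- abs(tot[[1]] - tot[[2]])
  if (any(tot == 0L)) stop("two-way minimization starts once each arm is occupied")
  P <- p_minimize_delta(delta)
  if (is.null(criterion_draw)) criterion_draw <- stats::runif(1)
  D <- distribution_imbalance(ledger, cfg, subject, upto = upto, as_of = as_of)

  if (criterion_draw < P) {
    criterion <- "delta"
    target <- which(tot == min(tot))     # unique: P > 0 implies delta > 0
  } else {
    criterion <- "D"
    tol <- 1e-9 * max(1, abs(D))
    target <- which(D <= min(D) + tol)
  }
  probs <- numeric(2)
  probs[target] <- 1 / length(target)
  if (is.null(uniform_draw)) uniform_draw <- stats::runif(1)
  arm <- select_arm(uniform_draw, probs)
  list(arm_code = arm, criterion_used = criterion, score_vector = D,
       probability_vector = probs, criterion_draw = criterion_draw,
       uniform_draw = uniform_draw)
}
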