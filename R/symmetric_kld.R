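# Symmetric Kullback-Leibler (Jeffreys) divergence balance index for
# 2-arm trials with continuous and/or categorical prognostic factors.
# Continuous factors are summarized per arm as a multivariate normal
# (mean vector + ML covariance); categorical factors as level proportions.

#' Summarize one arm's covariate distribution
#'
#' Builds the per-arm summary the divergence index compares: subject count,
#' mean vector and maximum-likelihood (divide-by-n) covariance over the
#' continuous factors, and smoothed level proportions per categorical
#' factor. An optional extra subject is included to form the hypothetical
#' "what if the incoming subject joined this arm" summary, leaving the
#' other arm unchanged.
#'
#' Numerical safeguards: while an arm holds `n_i <= j' + 1` subjects the
#' covariance is restricted to its diagonal, and a relative ridge
#' `1e-6 * mean(diag(S))` (floor 1e-6 when the diagonal is all zero) is
#' added so the matrix stays invertible from the fifth subject onward.
#' Categorical proportions receive a half pseudo-count per level
#' (Haldane-Anscombe) so no level ever has mass in one arm only, which
#' would make the divergence infinite early in a trial.
#'
#' @param ledger An `allocation_ledger`.
#' @param cfg A validated `trial_config` (`method = "symmetric_kld"`, 2 arms).
#' @param arm Arm code, 1 or 2.
#' @param extra_subject Optional validated `subject_record` to include.
#' @param upto,as_of Prefix controls as in [marginal_counts()].
#' @return An object of class `"arm_summary"`: `n_i`, `mean_vector`,
#'   `covariance` (regularized), `covariance_ml` (raw ML estimate),
#'   `categorical_counts` and `categorical_proportions` (smoothed).
#' @export
arm_summary <- function(ledger, cfg, arm, extra_subject = NULL,
                        upto = ledger_size(ledger), as_of = Inf) {
  if (!arm %in% c(1L, 2L)) stop("arm must be 1 or 2")
  subj <- effective_subjects(ledger, cfg, upto = upto, as_of = as_of)
  subj <- subj[subj$arm_code == arm, , drop = FALSE]
  con_names <- vapply(Filter(function(f) f$kind == "continuous", cfg$factors),
                      `[[`, "", "name")
  cat_specs <- Filter(function(f) f$kind == "categorical", cfg$factors)

  jp <- length(con_names)
  n_i <- nrow(subj) + !is.null(extra_subject)
  X <- as.matrix(subj[, con_names, drop = FALSE])
  if (jp > 0L && !is.null(extra_subject))
    X <- rbind(X, vapply(con_names, function(nm)
      as.numeric(extra_subject$continuous_values[[nm]]), 0))

  gauss <- gaussian_summary(X, jp)
  cat_counts <- list(); cat_props <- list()
  for (f in cat_specs) {
    obs <- subj[[f$name]]
    if (!is.null(extra_subject)) {
      ev <- extra_subject$categorical_values[[f$name]]
      if (!is.null(ev)) obs <- c(obs, ev)
    }
    cnt <- stats::setNames(
      as.integer(table(factor(obs, levels = f$levels))), f$levels)
    cat_counts[[f$name]] <- cnt
    cat_props[[f$name]] <- smoothed_proportions(cnt)
  }

  structure(list(n_i = n_i,
                 mean_vector = stats::setNames(gauss$mu, con_names),
                 covariance = gauss$S, covariance_ml = gauss$S_ml,
                 categorical_counts = cat_counts,
                 categorical_proportions = cat_props),
            class = "arm_summary")
}

# ML mean/covariance of the rows of X with the small-sample safeguards:
# diagonal restriction while n <= jp + 1, then a relative ridge.
gaussian_summary <- function(X, jp = ncol(X)) {
  n <- nrow(X)
  if (jp > 0L && n > 0L) {
    mu <- colMeans(X)
    centered <- sweep(X, 2, mu)
    S_ml <- crossprod(centered) / n
    S <- S_ml
    if (n <= jp + 1L) S <- diag(diag(S), nrow = jp)
    scale <- mean(diag(S))
    if (!is.finite(scale) || scale <= 0) scale <- 1
    S <- S + 1e-6 * scale * diag(jp)
  } else {
    mu <- numeric(jp)
    S_ml <- S <- diag(1e-6, nrow = jp)
  }
  list(mu = mu, S = S, S_ml = S_ml)
}

# Haldane-Anscombe smoothing: half a pseudo-count per level.
smoothed_proportions <- function(counts) {
  p <- (as.numeric(counts) + 0.5) / (sum(counts) + 0.5 * length(counts))
  names(p) <- names(counts)
  p
}

#' Jeffreys divergence between two multivariate-normal summaries
#'
#' The symmetric sum \eqn{KL(a\|b) + KL(b\|a)} for multivariate normals,
#' in which the log-determinant terms cancel:
#' \deqn{J = \tfrac12\left[\mathrm{tr}(S_b^{-1}S_a) + \mathrm{tr}(S_a^{-1}S_b)
#'  - 2j' + (\mu_a-\mu_b)^\top (S_a^{-1} + S_b^{-1})(\mu_a-\mu_b)\right]}
#' Zero when the summaries coincide; symmetric in its arguments.
#'
#' @param summary_a,summary_b `"arm_summary"` objects (or lists with
#'   `mean_vector` and `covariance`).
#' @return Nonnegative scalar (0 when there are no continuous factors).
#' @export
skld_continuous <- function(summary_a, summary_b) {
  mu_a <- summary_a$mean_vector; mu_b <- summary_b$mean_vector
  jp <- length(mu_a)
  if (jp == 0L) return(0)
  if (length(mu_b) != jp) stop("summaries cover different continuous factors")
  Sa <- summary_a$covariance; Sb <- summary_b$covariance
  Sa_inv <- tryCatch(solve(Sa), error = function(e) stop("singular covariance (arm a)"))
  Sb_inv <- tryCatch(solve(Sb), error = function(e) stop("singular covariance (arm b)"))
  d <- as.numeric(mu_a - mu_b)
  val <- 0.5 * (sum(diag(Sb_inv %*% Sa)) + sum(diag(Sa_inv %*% Sb)) - 2 * jp +
                  as.numeric(t(d) %*% (Sa_inv + Sb_inv) %*% d))
  max(val, 0)
}

#' Jeffreys divergence between two discrete distributions
#'
#' \deqn{J(p, q) = \sum_m (p_m - q_m) \ln(p_m / q_m)}
#' Symmetric, nonnegative, and zero iff `p == q`. Callers smooth
#' zero-proportion levels upstream (see [arm_summary()]); a level with
#' mass in exactly one of the two vectors yields `Inf`.
#'
#' @param p,q Probability vectors of equal length.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' skld_categorical(c(0.5, 0.5), c(0.25, 0.75))  # 0.25*log(2) + 0.25*log(3/2)
skld_categorical <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  terms <- (p - q) * log(p / q)
  terms[p == q] <- 0
  sum(terms)
}

#' Symmetric-KLD imbalance scores d_i
#'
#' For each candidate arm `i`, `d_i` is the total Jeffreys divergence
#' between the two arms' covariate distributions assuming the incoming
#' subject is allocated to arm `i` (so `n_i` becomes `n_i + 1` while the
#' other arm is unchanged): the multivariate-normal kernel over the
#' continuous factors plus the weighted discrete kernel per categorical
#' factor. `d_i` measures the imbalance that assignment to arm `i` would
#' leave behind; the engine hands `(d_1, d_2)` to
#' [probability_vector_from_scores()] so the arm with the *lower* `d_i`
#' receives the higher probability.
#'
#' @param ledger An `allocation_ledger` with at least 4 records (the
#'   permuted-block phase owns allocation before that).
#' @param cfg A validated `trial_config` with `method = "symmetric_kld"`.
#' @param subject A validated `subject_record`.
#' @param upto,as_of Prefix controls as in [marginal_counts()].
#' @return Numeric vector `c(d_1, d_2)`.
#' @export
d_scores <- function(ledger, cfg, subject, upto = ledger_size(ledger), as_of = Inf) {
  if (upto < 4L)
    stop("symmetric-KLD scoring starts after the permuted block of 4 subjects")
  w <- factor_weights(cfg)
  vapply(1:2, function(i) {
    other <- 3L - i
    sa <- arm_summary(ledger, cfg, i, extra_subject = subject, upto = upto, as_of = as_of)
    sb <- arm_summary(ledger, cfg, other, extra_subject = NULL, upto = upto, as_of = as_of)
    d <- skld_continuous(sa, sb)
    for (nm in names(sa$categorical_proportions))
      d <- d + w[[nm]] * skld_categorical(sa$categorical_proportions[[nm]],
                                          sb$categorical_proportions[[nm]])
    d
  }, 0)
}

#' Multivariate-normality advisory for the symmetric-KLD method
#'
#' The continuous kernel models each arm's continuous factors as
#' multivariate normal. For configurations using continuous factors this
#' returns a one-time, non-blocking reminder of that assumption and of the
#' value of consulting a biostatistician about transformations when serious
#' violations are expected; `NULL` otherwise.
#'
#' @param cfg A validated `trial_config`.
#' @return Advisory string, or `NULL`.
#' @export
normality_advisory <- function(cfg) {
  if (!identical(cfg$method, "symmetric_kld")) return(NULL)
  kinds <- vapply(cfg$factors, `[[`, "", "kind")
  if (!any(kinds == "continuous")) return(NULL)
  paste0(
    "Advisory: the symmetric-KLD index assumes a multivariate normal ",
    "distribution for continuous prognostic factors (the method is robust ",
    "to moderate departures). Consult a biostatistician on the need for ",
    "data transformation if serious violations are expected.")
}
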