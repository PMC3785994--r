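# Pocock-Simon marginal-balance scoring: the candidate arm's marginal
# treatment totals at the incoming subject's factor levels.

#' Marginal counts n_ijm from the ledger
#'
#' Cross-tabulates the ledger's subjects (corrections applied) by arm,
#' factor and level: `counts[[j]][i, m]` is the number of subjects at level
#' `m` of factor `j` previously assigned to arm `i`.
#'
#' @param ledger An `allocation_ledger`.
#' @param cfg A validated `trial_config`; all factors must be categorical.
#' @param upto Use only the first `upto` records (default: all).
#' @param as_of Apply only corrections recorded while the ledger held at
#'   most this many records (default: all).
#' @return An object of class `"marginal_counts"`: a named list, one
#'   `I x M_j` integer matrix per factor, rows = arms, columns = levels.
#' @export
marginal_counts <- function(ledger, cfg, upto = ledger_size(ledger), as_of = Inf) {
  kinds <- vapply(cfg$factors, `[[`, "", "kind")
  if (any(kinds == "continuous"))
    stop("marginal counts require categorical factors only")
  subj <- effective_subjects(ledger, cfg, upto = upto, as_of = as_of)
  I <- cfg$n_arms
  counts <- lapply(cfg$factors, function(f) {
    m <- matrix(0L, nrow = I, ncol = length(f$levels),
                dimnames = list(as.character(seq_len(I)), f$levels))
    if (nrow(subj)) {
      tab <- table(factor(subj$arm_code, levels = seq_len(I)),
                   factor(subj[[f$name]], levels = f$levels))
      m[] <- as.integer(tab)
    }
    m
  })
  names(counts) <- vapply(cfg$factors, `[[`, "", "name")
  structure(counts, class = "marginal_counts")
}

#' Pocock-Simon G scores
#'
#' For each candidate arm `i`, the marginal treatment total
#' \deqn{G_i = \sum_j w_j \, n_{i, j, r_j}}
#' i.e. the weighted sum over factors of arm `i`'s current count at the
#' incoming subject's level \eqn{r_j} of each factor. The hypothetical "+1"
#' for the incoming subject shifts every arm's total by the same constant
#' \eqn{\sum_j w_j} and is omitted; the ranking is unchanged. The smallest
#' `G_i` marks the least-represented — favored — arm.
#'
#' @param counts A `"marginal_counts"` object.
#' @param subject A validated `subject_record` supplying a level for every
#'   factor.
#' @param weights Named per-factor weights (default: 1 each).
#' @return Numeric vector of length `I`.
#' @export
g_scores <- function(counts, subject,
                     weights = stats::setNames(rep(1, length(counts)), names(counts))) {
  I <- nrow(counts[[1]])
  g <- numeric(I)
  vals <- subject$categorical_values
  if (!length(vals) && !is.null(subject$values)) vals <- subject$values
  for (j in names(counts)) {
    r_j <- as.character(vals[[j]])
    if (is.null(vals[[j]]) || !r_j %in% colnames(counts[[j]]))
      stop(sprintf("subject level for factor '%s' absent from counts table", j))
    w <- if (j %in% names(weights)) weights[[j]] else 1
    g <- g + w * counts[[j]][, r_j]
  }
  unname(g)
}
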