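# Synthetic cohorts and replicated virtual trials: verify that
# minimization delivers tighter covariate and arm-size balance than simple
# randomization, and quantify the predictability cost of a larger biased
# probability.

#' Specify a synthetic cohort
#'
#' Describes an enrollment stream: categorical factors with level
#' frequencies, continuous factors with normal means/SDs and an optional
#' correlation matrix, site assignment probabilities, and a seed.
#'
#' @param n_subjects Number of subjects to generate.
#' @param categorical Named list: one named probability vector per
#'   categorical factor (names are the level labels).
#' @param continuous Named list: one `c(mean, sd)` (or
#'   `list(mean =, sd =)`) per continuous factor.
#' @param correlation Optional correlation matrix across the continuous
#'   factors (default: independent).
#' @param site_probabilities Named probability vector over sites (default:
#'   one site, `"site1"`).
#' @param seed Integer seed; the cohort is deterministic given the spec.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects, categorical = list(), continuous = list(),
                        correlation = NULL,
                        site_probabilities = c(site1 = 1), seed = 1L) {
  for (nm in names(categorical)) {
    p <- categorical[[nm]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("categorical factor '%s': named probabilities must lie on the simplex", nm))
  }
  if (any(site_probabilities < 0) || abs(sum(site_probabilities) - 1) > 1e-8)
    stop("site_probabilities must lie on the simplex")
  if (!is.null(correlation)) {
    k <- length(continuous)
    if (!is.matrix(correlation) || any(dim(correlation) != k) ||
        !isTRUE(all.equal(correlation, t(correlation))) ||
        any(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
      stop("correlation must be a symmetric positive-semidefinite matrix over the continuous factors")
  }
  structure(list(n_subjects = as.integer(n_subjects), categorical = categorical,
                 continuous = continuous, correlation = correlation,
                 site_probabilities = site_probabilities, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Independent draws per the spec's generators; deterministic given the
#' spec's seed.
#'
#' @param spec A `cohort_spec`.
#' @return Data frame with `subject_id`, `site`, and one column per factor.
#' @export
generate_cohort <- function(spec) {
  n <- spec$n_subjects
  with_seed(spec$seed, {
    out <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      site = if (n) sample(names(spec$site_probabilities), n, replace = TRUE,
                           prob = spec$site_probabilities) else character(0),
      stringsAsFactors = FALSE)
    for (nm in names(spec$categorical)) {
      p <- spec$categorical[[nm]]
      out[[nm]] <- if (n) sample(names(p), n, replace = TRUE, prob = p) else character(0)
    }
    k <- length(spec$continuous)
    if (k) {
      mus <- vapply(spec$continuous, function(x) as.numeric(x[[1]]), 0)
      sds <- vapply(spec$continuous, function(x) as.numeric(x[[2]]), 0)
      Z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k)
      if (!is.null(spec$correlation))
        Z <- Z %*% chol(spec$correlation)
      X <- sweep(sweep(Z, 2, sds, `*`), 2, mus, `+`)
      for (j in seq_len(k)) out[[names(spec$continuous)[j]]] <- X[, j]
    }
    out
  })
}

#' Allocate a whole cohort under one scheme
#'
#' Runs the sequential allocation of every cohort subject under the
#' config's method (or under unrestricted simple randomization when
#' `scheme = "simple"`), using the same scoring kernels, initial-phase
#' rules, biased-coin construction and per-allocation seed derivation as
#' [randomize_subject()], with incrementally maintained counts so large
#' replicated simulations stay fast. The two paths are draw-for-draw
#' identical (a property the test suite asserts).
#'
#' @param cohort Data frame from [generate_cohort()] (column order is the
#'   enrollment order).
#' @param cfg A validated `trial_config`.
#' @param scheme `"method"` (the config's method) or `"simple"`.
#' @return List: `arms` (integer allocation per subject),
#'   `correct_guesses` (logical per subject: did a greedy adversary
#'   knowing ledger and method guess the assignment?), `counts` (final
#'   marginal counts, categorical factors), `totals` (final arm totals).
#' @export
allocate_cohort <- function(cohort, cfg, scheme = c("method", "simple")) {
  scheme <- match.arg(scheme)
  n <- nrow(cohort)
  I <- cfg$n_arms
  method <- if (scheme == "simple") "simple" else cfg$method
  cat_specs <- Filter(function(f) f$kind == "categorical", cfg$factors)
  con_names <- vapply(Filter(function(f) f$kind == "continuous", cfg$factors),
                      `[[`, "", "name")
  w <- factor_weights(cfg)
  counts <- lapply(cat_specs, function(f)
    matrix(0L, nrow = I, ncol = length(f$levels),
           dimnames = list(as.character(seq_len(I)), f$levels)))
  names(counts) <- vapply(cat_specs, `[[`, "", "name")
  X <- if (length(con_names)) as.matrix(cohort[, con_names, drop = FALSE]) else NULL
  totals <- integer(I)
  arms <- integer(n)
  guesses <- logical(n)

  for (s in seq_len(n)) {
    lev <- stats::setNames(
      lapply(names(counts), function(j) as.character(cohort[[j]][s])), names(counts))

    res <- with_alloc_rng(cfg$seed, s - 1L, {
      init_probs <- NULL
      if (method == "simple") {
        init_probs <- rep(1 / I, I)
      } else if (method == "pocock_simon" && s - 1L < (cfg$n_initial_simple %||% 1L)) {
        init_probs <- rep(1 / I, I)
      } else if (method == "symmetric_kld" && s <= 4L) {
        remaining <- pmax(2L - totals, 0L)
        init_probs <- remaining / sum(remaining)
      } else if (method == "two_way" && any(totals == 0L)) {
        init_probs <- rep(1 / I, I)
      }

      if (!is.null(init_probs)) {
        u <- stats::runif(1)
        list(arm = select_arm(u, init_probs), guess = which.min(totals))
      } else if (method == "two_way") {
        delta <- abs(totals[1] - totals[2])
        P <- p_minimize_delta(delta)
        crit_u <- stats::runif(1)
        D <- vapply(1:2, function(i) {
          d <- 0
          for (j in names(counts)) {
            at <- counts[[j]][, lev[[j]]]
            at[i] <- at[i] + 1L
            d <- d + w[[j]] * abs(at[1] - at[2])
          }
          d
        }, 0)
        if (crit_u < P) {
          target <- which(totals == min(totals))
        } else {
          tol <- 1e-9 * max(1, abs(D))
          target <- which(D <= min(D) + tol)
        }
        probs <- numeric(2); probs[target] <- 1 / length(target)
        # greedy adversary: guess the arm with the larger induced probability
        ind <- function(set) { v <- numeric(2); v[set] <- 1 / length(set); v }
        tolD <- 1e-9 * max(1, abs(D))
        induced <- P * ind(which(totals == min(totals))) +
          (1 - P) * ind(which(D <= min(D) + tolD))
        u <- stats::runif(1)
        list(arm = select_arm(u, probs), guess = which.max(induced))
      } else {
        scores <- if (method == "pocock_simon") {
          g_scores(structure(counts, class = "marginal_counts"),
                   list(categorical_values = lev), w)
        } else {
          vapply(1:2, function(i) {
            other <- 3L - i
            d <- 0
            if (length(con_names)) {
              idx_i <- which(arms[seq_len(s - 1L)] == i)
              idx_o <- which(arms[seq_len(s - 1L)] == other)
              gi <- gaussian_summary(rbind(X[idx_i, , drop = FALSE],
                                           X[s, , drop = FALSE]))
              go <- gaussian_summary(X[idx_o, , drop = FALSE])
              d <- d + skld_continuous(list(mean_vector = gi$mu, covariance = gi$S),
                                       list(mean_vector = go$mu, covariance = go$S))
            }
            for (j in names(counts)) {
              ci <- counts[[j]][i, ]; ci[lev[[j]]] <- ci[lev[[j]]] + 1L
              d <- d + w[[j]] * skld_categorical(smoothed_proportions(ci),
                                                 smoothed_proportions(counts[[j]][other, ]))
            }
            d
          }, 0)
        }
        probs <- probability_vector_from_scores(scores, cfg$biased_probability, I)
        u <- stats::runif(1)
        list(arm = select_arm(u, probs), guess = which.min(scores))
      }
    })

    arms[s] <- res$arm
    guesses[s] <- res$arm == res$guess
    totals[res$arm] <- totals[res$arm] + 1L
    for (j in names(counts))
      counts[[j]][res$arm, lev[[j]]] <- counts[[j]][res$arm, lev[[j]]] + 1L
  }
  list(arms = arms, correct_guesses = guesses, counts = counts, totals = totals)
}

cohort_metrics <- function(alloc, cohort, con_names) {
  m <- list(
    max_marginal_imbalance = if (length(alloc$counts))
      max(vapply(alloc$counts, function(cm)
        max(apply(cm, 2, function(col) max(col) - min(col))), 0)) else NA_real_,
    arm_size_gap = max(alloc$totals) - min(alloc$totals),
    correct_guess_rate = mean(alloc$correct_guesses))
  for (nm in con_names) {
    x1 <- cohort[[nm]][alloc$arms == 1L]
    x2 <- cohort[[nm]][alloc$arms == 2L]
    absdiff <- abs(mean(x1) - mean(x2))
    sp <- sqrt(((length(x1) - 1) * stats::var(x1) +
                  (length(x2) - 1) * stats::var(x2)) /
                 (length(x1) + length(x2) - 2))
    m[[paste0("abs_mean_diff_", nm)]] <- absdiff
    m[[paste0("asmd_", nm)]] <- if (sp > 0) absdiff / sp else 0
  }
  m
}

#' Run a paired comparison of allocation schemes
#'
#' For each replicate one cohort is drawn and allocated under every scheme
#' — the same subjects in the same enrollment order, with the same
#' replicate-derived seed, so scheme contrasts are paired. A simple-
#' randomization baseline is always included. Per replicate and scheme the
#' result records the terminal maximum marginal imbalance over all factor
#' levels, the terminal arm-size gap, the absolute (and standardized)
#' between-arm mean difference per continuous factor, and the correct-
#' guess rate of a greedy adversary.
#'
#' @param spec A `cohort_spec` (its `n_subjects` sets the trial size; its
#'   seed is overridden per replicate).
#' @param configs Named list of validated `trial_config`s; all must share
#'   the spec's factor structure. Their seeds are overridden per replicate
#'   to keep schemes paired.
#' @param n_replicates Number of replicate cohorts (default 500).
#' @param seed Root seed for the whole comparison.
#' @return A tidy data frame of class `"simulation_result"`: one row per
#'   replicate x scheme x metric (`replicate`, `scheme`, `metric`,
#'   `value`).
#' @export
run_comparison <- function(spec, configs, n_replicates = 500L, seed = 1L) {
  if (is.null(names(configs)) || !all(nzchar(names(configs))))
    stop("configs must be a named list of trial_config objects")
  base_cfg <- configs[[1]]
  con_names <- vapply(Filter(function(f) f$kind == "continuous", base_cfg$factors),
                      `[[`, "", "name")
  for (cfg in configs) {
    fn <- vapply(cfg$factors, `[[`, "", "name")
    missing <- setdiff(fn, c(names(spec$categorical), names(spec$continuous)))
    if (length(missing))
      stop(sprintf("cohort spec lacks generator(s) for factor(s): %s",
                   paste(missing, collapse = ", ")))
  }
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, r)
    spec$seed <- rep_seed
    cohort <- generate_cohort(spec)
    rep_rows <- list()
    for (nm in names(configs)) {
      cfg <- configs[[nm]]
      cfg$seed <- rep_seed
      met <- cohort_metrics(allocate_cohort(cohort, cfg, "method"), cohort, con_names)
      rep_rows[[nm]] <- data.frame(replicate = r, scheme = nm,
                                   metric = names(met),
                                   value = unlist(met, use.names = FALSE),
                                   stringsAsFactors = FALSE)
    }
    cfg <- base_cfg
    cfg$seed <- rep_seed
    met <- cohort_metrics(allocate_cohort(cohort, cfg, "simple"), cohort, con_names)
    rep_rows[["simple"]] <- data.frame(replicate = r, scheme = "simple",
                                       metric = names(met),
                                       value = unlist(met, use.names = FALSE),
                                       stringsAsFactors = FALSE)
    rows[[r]] <- do.call(rbind, rep_rows)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("simulation_result", "data.frame")
  out
}

#' Summarize a simulation result
#'
#' Mean of every metric by scheme, wide by scheme.
#'
#' @param object A `"simulation_result"`.
#' @param ... Unused.
#' @return Data frame: metric x scheme means.
#' @export
summary.simulation_result <- function(object, ...) {
  agg <- stats::aggregate(value ~ metric + scheme, data = object, FUN = mean)
  stats::reshape(agg, idvar = "metric", timevar = "scheme", direction = "wide")
}
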