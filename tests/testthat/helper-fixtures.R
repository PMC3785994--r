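# Shared fixtures and independent brute-force oracles for the test suite.

cat2 <- function(name, levels = c("A", "B"), weight = 1)
  factor_spec(name, "categorical", levels = levels, weight = weight)

ps_config <- function(n_arms = 2, p = 0.8, seed = 1, n_initial = 1,
                      factors = list(cat2("gender", c("Female", "Male"))),
                      deterministic = FALSE, ...) {
  trial_config("ps-test", "pocock_simon", n_arms, factors = factors,
               biased_probability = p, seed = seed,
               n_initial_simple = n_initial, deterministic = deterministic, ...)
}

kld_config <- function(p = 0.8, seed = 1,
                       factors = list(factor_spec("x", "continuous")), ...) {
  trial_config("kld-test", "symmetric_kld", 2, factors = factors,
               biased_probability = p, seed = seed, ...)
}

tw_config <- function(seed = 1, factors = list(cat2("gender", c("F", "M"))), ...) {
  trial_config("tw-test", "two_way", 2, factors = factors, seed = seed, ...)
}

# Build a ledger directly from raw assignments, bypassing the engine --
# used when testing counting/scoring code against brute force.
ledger_from_raw <- function(trial_id, subjects, arms) {
  led <- new_ledger(trial_id)
  for (i in seq_along(arms)) {
    s <- subjects[[i]]
    led$records[[i]] <- list(
      sequence_number = i, subject_id = s$subject_id %||% paste0("S", i),
      site = s$site %||% "site1",
      categorical_values = s$categorical_values %||% list(),
      continuous_values = s$continuous_values %||% list(),
      arm_code = as.integer(arms[i]), masked_number = NA_character_,
      phase = "minimization", probability_vector = numeric(0),
      uniform_draw = 0, criterion_draw = NA_real_,
      criterion_used = NA_character_, score_vector = numeric(0),
      timestamp = "1970-01-01T00:00:00.000+0000")
  }
  led
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_categorical_ledger <- function(cfg, n) {
  subjects <- lapply(seq_len(n), function(i) {
    vals <- lapply(cfg$factors, function(f) sample(f$levels, 1))
    names(vals) <- vapply(cfg$factors, `[[`, "", "name")
    list(subject_id = paste0("S", i), site = cfg$sites[1],
         categorical_values = vals, continuous_values = list())
  })
  arms <- sample.int(cfg$n_arms, n, replace = TRUE)
  list(ledger = ledger_from_raw(cfg$trial_id, subjects, arms),
       subjects = subjects, arms = arms)
}

# Oracle: recount n_ijm by looping over raw records.
oracle_marginal_counts <- function(subjects, arms, cfg) {
  out <- lapply(cfg$factors, function(f) {
    m <- matrix(0L, cfg$n_arms, length(f$levels),
                dimnames = list(as.character(seq_len(cfg$n_arms)), f$levels))
    for (i in seq_along(arms)) {
      lev <- subjects[[i]]$categorical_values[[f$name]]
      m[arms[i], lev] <- m[arms[i], lev] + 1L
    }
    m
  })
  names(out) <- vapply(cfg$factors, `[[`, "", "name")
  out
}

# Oracle: G_i by direct summation over factors of the candidate arm's count
# at the new subject's level.
oracle_g_scores <- function(subjects, arms, cfg, new_subject) {
  cnt <- oracle_marginal_counts(subjects, arms, cfg)
  vapply(seq_len(cfg$n_arms), function(i) {
    g <- 0
    for (f in cfg$factors)
      g <- g + f$weight * cnt[[f$name]][i, new_subject$categorical_values[[f$name]]]
    g
  }, 0)
}

# Oracle: two-way D_i by direct counting after the hypothetical addition.
oracle_distribution_imbalance <- function(subjects, arms, cfg, new_subject) {
  vapply(1:2, function(i) {
    D <- 0
    for (f in cfg$factors) {
      lev <- new_subject$categorical_values[[f$name]]
      n1 <- sum(vapply(seq_along(arms), function(k)
        arms[k] == 1 && subjects[[k]]$categorical_values[[f$name]] == lev, TRUE)) +
        (i == 1)
      n2 <- sum(vapply(seq_along(arms), function(k)
        arms[k] == 2 && subjects[[k]]$categorical_values[[f$name]] == lev, TRUE)) +
        (i == 2)
      D <- D + f$weight * abs(n1 - n2)
    }
    D
  }, 0)
}

# Oracle: d_i for a univariate continuous trial by rebuilding both
# hypothetical summaries from the raw values and evaluating the closed
# form directly (independent of arm_summary / skld_continuous).
oracle_d_scores_univariate <- function(values_by_arm, new_value) {
  ml_var <- function(v) mean((v - mean(v))^2)
  reg <- function(s2, n) {
    s2d <- s2                               # univariate: diagonal == itself
    sc <- if (is.finite(s2d) && s2d > 0) s2d else 1
    s2d + 1e-6 * sc
  }
  jeffreys <- function(m1, v1, m2, v2)
    0.5 * (v1 / v2 + v2 / v1 - 2 + (m1 - m2)^2 * (1 / v1 + 1 / v2))
  vapply(1:2, function(i) {
    a <- c(values_by_arm[[i]], new_value)
    b <- values_by_arm[[3 - i]]
    va <- reg(ml_var(a), length(a)); vb <- reg(ml_var(b), length(b))
    jeffreys(mean(a), va, mean(b), vb)
  }, 0)
}

# per-factor weights of a config, for oracle comparisons
factor_weights_of <- function(cfg)
  stats::setNames(vapply(cfg$factors, function(f) f$weight, 0),
                  vapply(cfg$factors, `[[`, "", "name"))

random_subject_for <- function(cfg, id = "new") {
  vals <- lapply(cfg$factors, function(f)
    if (f$kind == "categorical") sample(f$levels, 1) else stats::rnorm(1))
  names(vals) <- vapply(cfg$factors, `[[`, "", "name")
  validate_subject(subject_record(id, cfg$sites[1], vals), cfg, new_ledger(cfg$trial_id))
}

# Drive the real engine over a cohort data frame; returns the ledger.
run_engine <- function(cfg, cohort, masked_table = NULL) {
  led <- new_ledger(cfg$trial_id)
  fnames <- vapply(cfg$factors, `[[`, "", "name")
  for (i in seq_len(nrow(cohort))) {
    s <- subject_record(cohort$subject_id[i],
                        if ("site" %in% names(cohort)) cohort$site[i] else cfg$sites[1],
                        as.list(cohort[i, fnames, drop = FALSE]))
    res <- randomize_subject(led, cfg, s, masked_table)
    led <- res$ledger
    masked_table <- res$masked_table
  }
  list(ledger = led, masked_table = masked_table)
}
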