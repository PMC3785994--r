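test_that("subject validation reports duplicates, unknown sites/levels, ranges", {
  cfg <- kld_config(factors = list(factor_spec("bmi", "continuous",
                                               validation_rule = c(15, 60)),
                                   cat2("gender", c("Female", "Male"))))
  led <- new_ledger(cfg$trial_id)
  ok <- validate_subject(subject_record("S1", "site1",
                                        list(bmi = 30, gender = "Female")),
                         cfg, led)
  expect_identical(ok$categorical_values$gender, "Female")
  expect_identical(ok$continuous_values$bmi, 30)
  led$records[[1]] <- list(subject_id = "S1", arm_code = 1L)

  err <- tryCatch(
    validate_subject(subject_record("S1", "siteX", list(bmi = 99, gender = "Femle")),
                     cfg, led),
    error = conditionMessage)
  expect_match(err, "duplicate subject_id 'S1'")
  expect_match(err, "unknown site 'siteX'")
  expect_match(err, "factor 'gender'.*'Femle'")
  expect_match(err, "factor 'bmi'.*outside")

  err2 <- tryCatch(
    validate_subject(subject_record("S2", "site1", list(bmi = 30)), cfg, led),
    error = conditionMessage)
  expect_match(err2, "missing value for factor 'gender'")
})

test_that("probability vector implements pooled-rank ties and the biased coin", {
  expect_equal(probability_vector_from_scores(c(2, 3), 2 / 3), c(2 / 3, 1 / 3))
  expect_equal(probability_vector_from_scores(c(5, 5), 0.9), c(0.5, 0.5))
  expect_equal(probability_vector_from_scores(c(1, 4, 4), 0.6), c(0.6, 0.2, 0.2))
  expect_error(probability_vector_from_scores(c(NaN, 1), 0.8), "non-finite")

  # properties on random score vectors: simplex output, permutation
  # equivariance, favored arm gets the largest mass
  set.seed(7)
  for (rep in 1:200) {
    I <- sample(2:5, 1)
    scores <- round(stats::rnorm(I), sample(0:2, 1))
    p <- stats::runif(1, 1 / I, 1)
    probs <- probability_vector_from_scores(scores, p, I)
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    perm <- sample.int(I)
    expect_equal(probability_vector_from_scores(scores[perm], p, I), probs[perm])
    expect_equal(which(probs == max(probs)), which(scores == min(scores)))
  }
})

test_that("initial phases fire first and hand over on schedule", {
  # pocock_simon: uniform 1/I while ledger < n_initial_simple
  cfg <- ps_config(n_arms = 3, n_initial = 2)
  led <- new_ledger(cfg$trial_id)
  init <- initial_phase_assignment(cfg, led)
  expect_identical(init$phase, "simple")
  expect_equal(init$probability_vector, rep(1 / 3, 3))
  res <- run_engine(cfg, data.frame(subject_id = c("a", "b", "c"),
                                    gender = c("Female", "Male", "Female")))
  phases <- vapply(res$ledger$records, `[[`, "", "phase")
  expect_identical(phases, c("simple", "simple", "minimization"))

  # two_way: simple until both arms occupied, then none
  cfgt <- tw_config()
  ledt <- new_ledger(cfgt$trial_id)
  ledt$records <- ledger_from_raw(cfgt$trial_id, list(
    list(categorical_values = list(gender = "F")),
    list(categorical_values = list(gender = "M"))), c(1, 2))$records
  expect_null(initial_phase_assignment(cfgt, ledt))
  ledt$records <- ledt$records[1]
  expect_identical(initial_phase_assignment(cfgt, ledt)$phase, "simple")
})

test_that("the KLD permuted block always lands 2 subjects per arm", {
  cohort <- data.frame(subject_id = paste0("S", 1:4), x = c(0.1, -0.2, 0.3, 0))
  orders <- character(0)
  for (seed in 1:60) {
    cfg <- kld_config(seed = seed)
    led <- run_engine(cfg, cohort)$ledger
    arms <- vapply(led$records, `[[`, 0L, "arm_code")
    expect_equal(sort(arms), c(1L, 1L, 2L, 2L))
    expect_true(all(vapply(led$records, `[[`, "", "phase") == "permuted_block"))
    orders <- c(orders, paste(arms, collapse = ""))
  }
  expect_gt(length(unique(orders)), 2)  # order varies with the seed
})

test_that("identical seed and subject stream give identical ledgers", {
  cfg <- ps_config(n_arms = 3, seed = 123,
                   factors = list(cat2("g", c("A", "B")), cat2("h", c("C", "D"))))
  set.seed(42)
  cohort <- data.frame(subject_id = paste0("S", 1:40),
                       g = sample(c("A", "B"), 40, TRUE),
                       h = sample(c("C", "D"), 40, TRUE))
  l1 <- run_engine(cfg, cohort)$ledger
  l2 <- run_engine(cfg, cohort)$ledger
  expect_identical(serialize_ledger(l1), serialize_ledger(l2))
  # conservation: arm totals partition N
  expect_identical(sum(arm_totals(l1, 3)), 40L)
  # a different seed changes the draws
  cfg2 <- ps_config(n_arms = 3, seed = 124, factors = cfg$factors)
  l3 <- run_engine(cfg2, cohort)$ledger
  expect_false(identical(serialize_ledger(l1), serialize_ledger(l3)))
})

test_that("deterministic override always selects the argmin arm", {
  cfg <- ps_config(p = 1, deterministic = TRUE, n_initial = 1,
                   factors = list(cat2("g", c("A", "B"))))
  set.seed(9)
  cohort <- data.frame(subject_id = paste0("S", 1:50),
                       g = sample(c("A", "B"), 50, TRUE))
  led <- run_engine(cfg, cohort)$ledger
  for (k in 2:50) {
    rec <- led$records[[k]]
    if (rec$phase != "minimization") next
    sc <- rec$score_vector
    if (abs(diff(sc)) < 1e-9) next   # tie: either arm is legitimate
    expect_identical(rec$arm_code, which.min(sc))
  }
})

test_that("corrections are append-only, reasoned, and leave outcomes intact", {
  cfg <- ps_config(factors = list(cat2("gender", c("Female", "Male"))))
  set.seed(5)
  cohort <- data.frame(subject_id = paste0("S", 1:17),
                       gender = sample(c("Female", "Male"), 17, TRUE))
  led <- run_engine(cfg, cohort)$ledger
  before <- serialize_ledger(led)

  expect_error(correct_record(led, 17, "categorical_values.gender", "Male", ""),
               "nonempty reason")
  expect_error(correct_record(led, 17, "arm_code", 2, "tamper"),
               "allocation outcome")
  expect_error(correct_record(led, 17, "uniform_draw", 0.5, "tamper"),
               "allocation outcome")

  led2 <- correct_record(led, 17, "categorical_values.gender", "Male",
                         "data-entry error")
  expect_length(led2$corrections, 1)
  # no field of any allocation record changed
  expect_identical(vapply(led2$records, function(r)
    as.character(jsonlite::toJSON(r[names(r) != "timestamp"], auto_unbox = TRUE,
                                  digits = NA)), ""),
    vapply(led$records, function(r)
      as.character(jsonlite::toJSON(r[names(r) != "timestamp"], auto_unbox = TRUE,
                                    digits = NA)), ""))
  expect_identical(led2$records[[17]]$arm_code, led$records[[17]]$arm_code)
  expect_identical(before, serialize_ledger(led))

  # the next randomization sees the corrected counts
  cnt <- marginal_counts(led2, cfg)
  oracle <- oracle_marginal_counts(
    lapply(seq_len(17), function(k) effective_record(led2, k)),
    vapply(led2$records, `[[`, 0L, "arm_code"), cfg)
  expect_equal(unclass(cnt), oracle)
  s <- validate_subject(subject_record("S18", "site1", list(gender = "Male")),
                        cfg, led2)
  g_corrected <- g_scores(cnt, s)
  g_uncorrected <- g_scores(marginal_counts(led, cfg), s)
  expect_false(isTRUE(all.equal(g_corrected, g_uncorrected)))
})

test_that("replay verifies honest ledgers and flags tampering", {
  for (cfg in list(ps_config(n_arms = 3, seed = 2,
                             factors = list(cat2("g", c("A", "B")))),
                   kld_config(seed = 3,
                              factors = list(factor_spec("x", "continuous"),
                                             cat2("g", c("A", "B")))),
                   tw_config(seed = 4, factors = list(cat2("g", c("A", "B")))))) {
    set.seed(cfg$seed)
    cohort <- data.frame(subject_id = paste0("S", 1:25),
                         g = sample(c("A", "B"), 25, TRUE),
                         x = stats::rnorm(25))
    fnames <- vapply(cfg$factors, `[[`, "", "name")
    led <- run_engine(cfg, cohort[, c("subject_id", fnames), drop = FALSE])$ledger

    rep <- replay_ledger(led, cfg)
    expect_true(rep$verified)
    expect_identical(rep$message, "verified, 25 records")

    tampered <- led
    tampered$records[[11]]$arm_code <-
      (tampered$records[[11]]$arm_code %% cfg$n_arms) + 1L
    repT <- replay_ledger(tampered, cfg)
    expect_false(repT$verified)
    expect_identical(repT$divergence$sequence_number, 11L)

    # corrections replay at the positions they were recorded
    led2 <- correct_record(led, 6, "categorical_values.g",
                           setdiff(c("A", "B"), effective_record(led, 6)$categorical_values$g),
                           "transcription fix")
    extra <- subject_record("S26", "site1", list(g = "A", x = 0.2)[fnames])
    led2 <- randomize_subject(led2, cfg, extra)$ledger
    expect_true(replay_ledger(led2, cfg)$verified)
  }
})

test_that("ledgers survive an NDJSON round-trip and still replay", {
  cfg <- kld_config(seed = 11, factors = list(factor_spec("x", "continuous")))
  set.seed(1)
  cohort <- data.frame(subject_id = paste0("S", 1:12), x = stats::rnorm(12))
  led <- run_engine(cfg, cohort)$ledger
  led <- correct_record(led, 2, "continuous_values.x", 0.5, "re-measured")
  path <- withr::local_tempfile(fileext = ".ndjson")
  write_ledger(led, path)
  back <- read_ledger(path, cfg$trial_id)
  expect_equal(serialize_ledger(back, include_timestamps = TRUE),
               serialize_ledger(led, include_timestamps = TRUE))
  expect_true(replay_ledger(back, cfg)$verified)
})
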