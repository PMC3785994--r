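test_that("arm summaries reproduce direct mean/covariance formulas", {
  cfg <- kld_config(factors = list(factor_spec("x", "continuous"),
                                   factor_spec("y", "continuous"),
                                   cat2("g", c("A", "B", "C"))))
  set.seed(23)
  vals <- lapply(1:6, function(i)
    list(subject_id = paste0("S", i),
         categorical_values = list(g = sample(c("A", "B", "C"), 1)),
         continuous_values = list(x = rnorm(1), y = rnorm(1))))
  led <- ledger_from_raw(cfg$trial_id, vals, c(1, 1, 1, 1, 1, 1))
  sm <- arm_summary(led, cfg, 1)
  X <- t(vapply(vals, function(v) c(v$continuous_values$x, v$continuous_values$y), c(0, 0)))
  expect_equal(unname(sm$mean_vector), colMeans(X))
  ml_cov <- crossprod(sweep(X, 2, colMeans(X))) / 6   # divide-by-n estimator
  expect_equal(unname(sm$covariance_ml), unname(ml_cov))
  expect_equal(unname(sm$covariance), unname(ml_cov), tolerance = 1e-4)
  expect_equal(sm$covariance, t(sm$covariance))
  expect_equal(sum(sm$categorical_proportions$g), 1)

  # single hypothetical subject in an empty arm: mean = values, floor cov
  s <- validate_subject(subject_record("new", "site1",
                                       list(x = 1.5, y = -2, g = "B")), cfg,
                        new_ledger(cfg$trial_id))
  sm2 <- arm_summary(led, cfg, 2, extra_subject = s)
  expect_identical(sm2$n_i, 1L)
  expect_equal(unname(sm2$mean_vector), c(1.5, -2))
  expect_equal(unname(diag(sm2$covariance)), rep(1e-6, 2))
})

test_that("continuous Jeffreys kernel matches hand evaluations and properties", {
  uni <- function(m, v) list(mean_vector = m, covariance = matrix(v))
  expect_identical(skld_continuous(uni(0, 1), uni(0, 1)), 0)
  # unit mean shift at unit variance: each directed KL is 1/2, sum is 1
  expect_equal(skld_continuous(uni(0, 1), uni(1, 1)), 1.0, tolerance = 1e-12)

  set.seed(4)
  for (rep in 1:200) {
    k <- sample(1:3, 1)
    A <- crossprod(matrix(rnorm(k * (k + 2)), k + 2, k)) / (k + 2)
    B <- crossprod(matrix(rnorm(k * (k + 2)), k + 2, k)) / (k + 2)
    sa <- list(mean_vector = rnorm(k), covariance = A)
    sb <- list(mean_vector = rnorm(k), covariance = B)
    j1 <- skld_continuous(sa, sb)
    expect_gte(j1, 0)
    expect_equal(j1, skld_continuous(sb, sa), tolerance = 1e-9)
  }
})

test_that("categorical Jeffreys kernel matches hand evaluations and properties", {
  expect_identical(skld_categorical(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(skld_categorical(c(0.5, 0.5), c(0.25, 0.75)),
               0.25 * log(2) + 0.25 * log(3 / 2), tolerance = 1e-12)
  expect_error(skld_categorical(c(0.5, 0.5), c(1, 0, 0)), "equal length")

  set.seed(8)
  for (rep in 1:200) {
    M <- sample(2:5, 1)
    p <- stats::runif(M) + 0.01; p <- p / sum(p)
    q <- stats::runif(M) + 0.01; q <- q / sum(q)
    expect_gte(skld_categorical(p, q), 0)
    expect_equal(skld_categorical(p, q), skld_categorical(q, p), tolerance = 1e-12)
  }
})

test_that("d scores match a from-scratch univariate oracle and are label-symmetric", {
  cfg <- kld_config(factors = list(factor_spec("x", "continuous")))
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    arms <- c(1, 1, 2, 2, sample(1:2, n - 4, TRUE))
    xs <- rnorm(n)
    vals <- lapply(seq_len(n), function(i)
      list(subject_id = paste0("S", i), continuous_values = list(x = xs[i]),
           categorical_values = list()))
    led <- ledger_from_raw(cfg$trial_id, vals, arms)
    s <- validate_subject(subject_record("new", "site1", list(x = rnorm(1))),
                          cfg, led)
    d <- d_scores(led, cfg, s)
    oracle <- oracle_d_scores_univariate(split(xs, arms), s$continuous_values$x)
    expect_equal(d, oracle, tolerance = 1e-9)
    # relabeling arms swaps d_1 and d_2
    led_swapped <- ledger_from_raw(cfg$trial_id, vals, 3 - arms)
    expect_equal(d_scores(led_swapped, cfg, s), rev(d), tolerance = 1e-12)
  }
})

test_that("identical arm compositions give equal d scores; categorical-only reduces", {
  cfg <- kld_config(factors = list(factor_spec("x", "continuous"),
                                   cat2("g", c("A", "B"))))
  vals <- list(
    list(continuous_values = list(x = 1.0), categorical_values = list(g = "A")),
    list(continuous_values = list(x = -1.0), categorical_values = list(g = "B")),
    list(continuous_values = list(x = 1.0), categorical_values = list(g = "A")),
    list(continuous_values = list(x = -1.0), categorical_values = list(g = "B")))
  led <- ledger_from_raw(cfg$trial_id, vals, c(1, 1, 2, 2))
  s <- validate_subject(subject_record("new", "site1", list(x = 0.3, g = "A")),
                        cfg, led)
  d <- d_scores(led, cfg, s)
  expect_equal(d[1], d[2], tolerance = 1e-12)

  cfg_cat <- kld_config(factors = list(cat2("g", c("A", "B"))))
  led_cat <- ledger_from_raw(cfg_cat$trial_id, lapply(vals, function(v)
    list(categorical_values = v["categorical_values"][[1]])), c(1, 1, 2, 2))
  s_cat <- validate_subject(subject_record("n2", "site1", list(g = "A")),
                            cfg_cat, led_cat)
  d_cat <- d_scores(led_cat, cfg_cat, s_cat)
  # no continuous factors: d is exactly the smoothed categorical Jeffreys sum
  p1 <- c(2.5, 1.5) / 4   # arm 1 + new A subject, smoothed
  q1 <- c(1.5, 1.5) / 3
  expect_equal(d_cat[1], skld_categorical(p1, q1), tolerance = 1e-12)
  expect_error(d_scores(led_cat, cfg_cat, s_cat, upto = 3), "permuted block")
})

test_that("d favors the arm whose mean moves toward the other's", {
  # equal n, equal spread: adding x = 2 to the low-mean arm closes the gap
  cfg <- kld_config(factors = list(factor_spec("x", "continuous")))
  base <- rep(c(-0.5, 0.5), each = 20)
  xs <- c(base - 1, base + 1)   # arm 1 centered at -1, arm 2 at +1
  vals <- lapply(xs, function(x) list(continuous_values = list(x = x),
                                      categorical_values = list()))
  led <- ledger_from_raw(cfg$trial_id, vals, rep(1:2, each = 40))
  s <- validate_subject(subject_record("new", "site1", list(x = 2)), cfg, led)
  d <- d_scores(led, cfg, s)
  expect_lt(d[1], d[2])
  s2 <- validate_subject(subject_record("n2", "site1", list(x = -2)), cfg, led)
  d2 <- d_scores(led, cfg, s2)
  expect_lt(d2[2], d2[1])
})

test_that("normality advisory fires only for KLD configs with continuous factors", {
  expect_match(normality_advisory(
    kld_config(factors = list(factor_spec("bmi", "continuous")))),
    "multivariate normal")
  expect_null(normality_advisory(kld_config(factors = list(cat2("g")))))
  expect_null(normality_advisory(ps_config()))
})
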