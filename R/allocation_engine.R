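# Allocation engine: append-only ledger, initial-phase rules, biased-coin
# draw over method scores, corrections, deterministic replay.

#' Create an empty allocation ledger
#'
#' The ledger is the single source of truth for a trial: an append-only
#' sequence of allocation records plus a parallel list of correction
#' entries. Appending never mutates existing records; every count, score
#' and report is derived from it.
#'
#' @param trial_id Trial identifier (must match the config at randomize time).
#' @return An object of class `"allocation_ledger"`.
#' @export
new_ledger <- function(trial_id) {
  structure(list(trial_id = trial_id, records = list(), corrections = list()),
            class = "allocation_ledger")
}

#' @export
print.allocation_ledger <- function(x, ...) {
  cat(sprintf("<allocation_ledger '%s'> %d record(s), %d correction(s)\n",
              x$trial_id, length(x$records), length(x$corrections)))
  if (length(x$records)) {
    tot <- arm_totals(x)
    cat("  arm totals:", paste(sprintf("%s=%d", names(tot), tot), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname new_ledger
#' @param ledger An `allocation_ledger`.
#' @export
ledger_size <- function(ledger) length(ledger$records)

#' Arm totals from the ledger
#'
#' @param ledger An `allocation_ledger`.
#' @param n_arms Number of arms; inferred from the ledger when omitted.
#' @return Integer vector of per-arm subject counts, named "1".."I".
#' @export
arm_totals <- function(ledger, n_arms = NULL) {
  arms <- vapply(ledger$records, `[[`, 0L, "arm_code")
  I <- n_arms %||% max(c(2L, arms))
  tab <- tabulate(arms, nbins = I)
  names(tab) <- as.character(seq_len(I))
  tab
}

#' Construct a subject record
#'
#' @param subject_id Unique identifier within the trial.
#' @param site Site short-name (must match a configured site).
#' @param values Named list/vector of factor values (both categorical level
#'   labels and continuous numbers), keyed by factor name.
#' @return An object of class `"subject_record"`. Factor values are split
#'   into categorical and continuous slots when validated against a config.
#' @export
subject_record <- function(subject_id, site, values = list()) {
  structure(list(subject_id = as.character(subject_id), site = as.character(site),
                 categorical_values = list(), continuous_values = list(),
                 values = as.list(values)),
            class = "subject_record")
}

#' Validate a subject record against the trial configuration and ledger
#'
#' Checks subject-ID uniqueness (duplicate randomization of the same ID is
#' refused), site membership, presence of every configured factor, level
#' membership for categorical factors, and the validation range for
#' continuous factors. All violations are reported together.
#'
#' @param record A `subject_record`.
#' @param cfg A validated `trial_config`.
#' @param ledger The current `allocation_ledger`.
#' @return The record with `categorical_values` / `continuous_values`
#'   normalized per the config; errors otherwise.
#' @export
validate_subject <- function(record, cfg, ledger) {
  errs <- character()
  push <- function(msg) errs[[length(errs) + 1L]] <<- msg

  ids <- vapply(ledger$records, function(r) r$subject_id, "")
  if (record$subject_id %in% ids)
    push(sprintf("duplicate subject_id '%s': already randomized in this trial",
                 record$subject_id))
  if (!record$site %in% cfg$sites)
    push(sprintf("unknown site '%s' (configured: %s)", record$site,
                 paste(cfg$sites, collapse = ", ")))

  vals <- record$values
  if (!length(vals)) vals <- c(record$categorical_values, record$continuous_values)
  cat_vals <- list(); con_vals <- list()
  for (f in cfg$factors) {
    v <- vals[[f$name]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      push(sprintf("missing value for factor '%s'", f$name))
      next
    }
    if (identical(f$kind, "categorical")) {
      allowed <- f$validation_rule %||% f$levels
      if (!as.character(v) %in% allowed) {
        push(sprintf("factor '%s': value '%s' not in {%s}", f$name, v,
                     paste(f$levels, collapse = ", ")))
      } else cat_vals[[f$name]] <- as.character(v)
    } else {
      vn <- suppressWarnings(as.numeric(v))
      if (is.na(vn)) {
        push(sprintf("factor '%s': unparseable continuous value '%s'", f$name, v))
      } else if (!is.null(f$validation_rule) &&
                 (vn < f$validation_rule[1] || vn > f$validation_rule[2])) {
        push(sprintf("factor '%s': value %g outside [%g, %g]", f$name, vn,
                     f$validation_rule[1], f$validation_rule[2]))
      } else con_vals[[f$name]] <- vn
    }
  }
  extra <- setdiff(names(vals), vapply(cfg$factors, `[[`, "", "name"))
  if (length(extra))
    push(sprintf("unknown factor(s): %s", paste(extra, collapse = ", ")))

  if (length(errs))
    stop("invalid subject record:\n", paste0("  - ", errs, collapse = "\n"),
         call. = FALSE)
  record$categorical_values <- cat_vals
  record$continuous_values <- con_vals
  record$values <- NULL
  record
}

# Deterministic per-allocation RNG: the trial seed and the ledger position
# jointly derive the generator state, so replay after a restart, and
# corrections (which consume no randomness), cannot shift later draws.
derive_seed <- function(seed, n) {
  as.integer((abs(as.numeric(seed)) * 69069 + (n + 1) * 104729) %% 2147483647)
}

with_alloc_rng <- function(seed, n, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, n), kind = "Mersenne-Twister")
  force(expr)
}

#' Initial-phase allocation rule
#'
#' Each method owns a distinct start-up rule before minimization takes over:
#' Pocock-Simon draws uniformly while fewer than `n_initial_simple` subjects
#' are on the ledger; the symmetric-KLD method allocates the first four
#' subjects as a permuted block of two per arm; two-way minimization draws
#' uniformly until both arms hold at least one subject.
#'
#' @param cfg A validated `trial_config`.
#' @param ledger The current `allocation_ledger`.
#' @return `NULL` once the initial condition is exhausted, else a list with
#'   `phase` (`"simple"` or `"permuted_block"`) and the `probability_vector`
#'   governing the draw.
#' @export
initial_phase_assignment <- function(cfg, ledger) {
  n <- ledger_size(ledger)
  I <- cfg$n_arms
  if (identical(cfg$method, "pocock_simon")) {
    if (n < (cfg$n_initial_simple %||% 1L))
      return(list(phase = "simple", probability_vector = rep(1 / I, I)))
    return(NULL)
  }
  if (identical(cfg$method, "symmetric_kld")) {
    if (n < 4L) {
      # sequential realization of a random permutation of (1,1,2,2):
      # the draw probability is proportional to each arm's remaining slots
      assigned <- tabulate(vapply(ledger$records, `[[`, 0L, "arm_code"), nbins = 2L)
      remaining <- pmax(2L - assigned, 0L)
      return(list(phase = "permuted_block",
                  probability_vector = remaining / sum(remaining)))
    }
    return(NULL)
  }
  # two_way: simple phase until each arm is occupied
  if (n == 0L || any(arm_totals(ledger, I) == 0L))
    return(list(phase = "simple", probability_vector = rep(1 / I, I)))
  NULL
}

#' Convert imbalance scores into a biased-coin probability vector
#'
#' The arm with the smallest score receives the biased probability
#' \eqn{P_i}; every other arm receives \eqn{(1 - P_i)/(I - 1)}. Arms whose
#' scores tie (relative tolerance 1e-9) pool the probabilities of the ranks
#' they occupy and split them equally, so the output is a permutation-
#' equivariant function of the scores and always sums to 1.
#'
#' @param scores Length-`I` numeric vector of imbalance scores (smaller =
#'   more favored).
#' @param p_assign Biased probability \eqn{P_i \in [1/I, 1]}.
#' @param n_arms Number of arms `I` (defaults to `length(scores)`).
#' @return Length-`I` probability vector on the simplex.
#' @export
#' @examples
#' probability_vector_from_scores(c(2, 3), 2 / 3)        # c(2/3, 1/3)
#' probability_vector_from_scores(c(5, 5), 0.8)          # full tie: c(0.5, 0.5)
#' probability_vector_from_scores(c(1, 4, 4), 0.6)       # c(0.6, 0.2, 0.2)
probability_vector_from_scores <- function(scores, p_assign, n_arms = length(scores)) {
  I <- as.integer(n_arms)
  if (I < 2L || length(scores) != I) stop("need I >= 2 scores")
  if (any(!is.finite(scores))) stop("non-finite imbalance scores")
  if (p_assign < 1 / I - 1e-12 || p_assign > 1 + 1e-12)
    stop(sprintf("p_assign %.4g outside [1/%d, 1]", p_assign, I))
  base <- c(p_assign, rep((1 - p_assign) / (I - 1L), I - 1L))
  ord <- order(scores)
  sorted <- scores[ord]
  tol <- 1e-9 * max(1, abs(scores))
  grp <- cumsum(c(1, diff(sorted) > tol))
  pooled <- stats::ave(base, grp, FUN = mean)
  probs <- numeric(I)
  probs[ord] <- pooled
  probs
}

# inverse-CDF selection of an arm from one uniform draw
select_arm <- function(u, probs) {
  cum <- cumsum(probs)
  arm <- sum(cum <= u) + 1L
  min(arm, length(probs))
}

#' Randomize one subject
#'
#' Validates the subject, applies the method's initial-phase rule or its
#' minimization score, converts scores to a biased-coin probability vector,
#' draws one uniform, selects the arm by inverse CDF, and appends a complete
#' allocation record (draws, probabilities and scores included, so the
#' allocation can be replayed and audited). For double-blind trials the next
#' masked number for the chosen site/arm is attached.
#'
#' All randomness derives from `cfg$seed` and the current ledger length;
#' identical seeds and subject streams yield identical ledgers.
#'
#' @param ledger The current `allocation_ledger`.
#' @param cfg A validated `trial_config`.
#' @param subject A `subject_record`.
#' @param masked_table Masked-number table (required iff
#'   `cfg$blinding == "double"`); see [generate_masked_table()].
#' @return A list with the grown `ledger`, the appended `record`, and the
#'   (possibly replenished) `masked_table`.
#' @export
randomize_subject <- function(ledger, cfg, subject, masked_table = NULL) {
  if (!identical(ledger$trial_id, cfg$trial_id))
    stop("ledger and config belong to different trials")
  if (identical(cfg$blinding, "double") && is.null(masked_table))
    stop("double-blind trial: masked_table is required")
  subject <- validate_subject(subject, cfg, ledger)
  n <- ledger_size(ledger)
  I <- cfg$n_arms

  res <- with_alloc_rng(cfg$seed, n, {
    init <- initial_phase_assignment(cfg, ledger)
    if (!is.null(init)) {
      u <- stats::runif(1)
      list(phase = init$phase, probs = init$probability_vector, u = u,
           scores = numeric(0), criterion_draw = NA_real_,
           criterion_used = NA_character_,
           arm = select_arm(u, init$probability_vector))
    } else if (identical(cfg$method, "two_way")) {
      tw <- two_way_assign(ledger, cfg, subject)
      list(phase = "minimization", probs = tw$probability_vector,
           u = tw$uniform_draw, scores = tw$score_vector,
           criterion_draw = tw$criterion_draw, criterion_used = tw$criterion_used,
           arm = tw$arm_code)
    } else {
      scores <- if (identical(cfg$method, "pocock_simon")) {
        counts <- marginal_counts(ledger, cfg)
        g_scores(counts, subject, factor_weights(cfg))
      } else {
        d_scores(ledger, cfg, subject)
      }
      probs <- probability_vector_from_scores(scores, cfg$biased_probability, I)
      u <- stats::runif(1)
      list(phase = "minimization", probs = probs, u = u, scores = scores,
           criterion_draw = NA_real_, criterion_used = NA_character_,
           arm = select_arm(u, probs))
    }
  })

  masked <- NA_character_
  if (identical(cfg$blinding, "double")) {
    nm <- next_masked_number(masked_table, subject$site, res$arm,
                             seed = derive_seed(cfg$seed, n) + 1L)
    masked <- nm$masked_number
    masked_table <- nm$table
  }

  record <- list(
    sequence_number = n + 1L,
    subject_id = subject$subject_id,
    site = subject$site,
    categorical_values = subject$categorical_values,
    continuous_values = subject$continuous_values,
    arm_code = res$arm,
    masked_number = masked,
    phase = res$phase,
    probability_vector = res$probs,
    uniform_draw = res$u,
    criterion_draw = res$criterion_draw,
    criterion_used = res$criterion_used,
    score_vector = res$scores,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"))
  ledger$records[[n + 1L]] <- record
  list(ledger = ledger, record = record, masked_table = masked_table)
}

#' Correct a factor value or subject metadata on a past record
#'
#' The allocation outcome of the target record (arm, probabilities, draws)
#' is immutable: only factor values and subject metadata may be corrected,
#' a nonempty reason is mandatory, and the correction is recorded as a
#' traceable entry rather than an in-place edit. Randomizations that
#' happened before the correction remain unchanged; subsequent ones compute
#' their counts from the corrected values.
#'
#' @param ledger An `allocation_ledger`.
#' @param seq Sequence number of the record to correct.
#' @param field_path One of `"site"`, `"subject_id"`,
#'   `"categorical_values.<factor>"` or `"continuous_values.<factor>"`.
#' @param new_value Replacement value.
#' @param reason Nonempty free-text justification.
#' @return The ledger with one appended `CorrectionEntry`.
#' @export
correct_record <- function(ledger, seq, field_path, new_value, reason) {
  if (!is.character(reason) || length(reason) != 1L || !nzchar(trimws(reason)))
    stop("a nonempty reason is required for every correction")
  if (seq < 1L || seq > ledger_size(ledger))
    stop(sprintf("no record with sequence number %s", seq))
  parts <- strsplit(field_path, ".", fixed = TRUE)[[1]]
  root <- parts[1]
  locked <- c("arm_code", "probability_vector", "uniform_draw", "criterion_draw",
              "criterion_used", "score_vector", "phase", "masked_number",
              "sequence_number", "timestamp")
  if (root %in% locked)
    stop(sprintf("field '%s' is an allocation outcome and cannot be corrected", root))
  if (!root %in% c("site", "subject_id", "categorical_values", "continuous_values"))
    stop(sprintf("unknown field_path '%s'", field_path))
  if (root %in% c("categorical_values", "continuous_values") && length(parts) != 2L)
    stop("field_path must name the factor, e.g. 'categorical_values.gender'")

  eff <- effective_record(ledger, seq)
  old_value <- if (length(parts) == 2L) eff[[root]][[parts[2]]] else eff[[root]]
  entry <- list(
    target_sequence_number = as.integer(seq),
    field_path = field_path,
    old_value = old_value,
    new_value = new_value,
    reason = reason,
    as_of_sequence = ledger_size(ledger),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"))
  ledger$corrections[[length(ledger$corrections) + 1L]] <- entry
  ledger
}

#' Effective view of a record after corrections
#'
#' @param ledger An `allocation_ledger`.
#' @param seq Sequence number.
#' @param as_of Apply only corrections recorded while the ledger held at
#'   most `as_of` records (used by [replay_ledger()] to reconstruct the
#'   state each allocation actually saw). Default: all corrections.
#' @return The record with corrections applied to its subject fields.
#' @export
effective_record <- function(ledger, seq, as_of = Inf) {
  rec <- ledger$records[[seq]]
  for (corr in ledger$corrections) {
    if (corr$target_sequence_number != seq) next
    if ((corr$as_of_sequence %||% 0L) > as_of) next
    parts <- strsplit(corr$field_path, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      v <- corr$new_value
      rec[[parts[1]]][[parts[2]]] <- if (parts[1] == "continuous_values") as.numeric(v) else v
    } else rec[[parts[1]]] <- corr$new_value
  }
  rec
}

# Data frame of effective subject fields for records 1..upto, with
# corrections recorded up to ledger size `as_of` applied.
effective_subjects <- function(ledger, cfg, upto = ledger_size(ledger),
                               as_of = Inf) {
  if (upto == 0L) {
    cols <- c(list(sequence = integer(0), subject_id = character(0),
                   site = character(0), arm_code = integer(0)),
              stats::setNames(lapply(cfg$factors, function(f)
                if (f$kind == "categorical") character(0) else numeric(0)),
                vapply(cfg$factors, `[[`, "", "name")))
    return(as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE))
  }
  recs <- lapply(seq_len(upto), function(k) effective_record(ledger, k, as_of))
  out <- data.frame(
    sequence = vapply(recs, `[[`, 0L, "sequence_number"),
    subject_id = vapply(recs, `[[`, "", "subject_id"),
    site = vapply(recs, `[[`, "", "site"),
    arm_code = vapply(recs, `[[`, 0L, "arm_code"),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (f in cfg$factors) {
    out[[f$name]] <- if (f$kind == "categorical")
      vapply(recs, function(r) r$categorical_values[[f$name]] %||% NA_character_, "")
    else
      vapply(recs, function(r) r$continuous_values[[f$name]] %||% NA_real_, 0)
  }
  out
}

factor_weights <- function(cfg) {
  stats::setNames(vapply(cfg$factors, function(f) f$weight, 0),
                  vapply(cfg$factors, `[[`, "", "name"))
}

#' Replay a ledger and verify every allocation
#'
#' Re-derives each record's phase, score vector and probability vector from
#' the ledger prefix (with corrections applied at the sequence positions at
#' which they were recorded), re-applies the stored uniform draw, and
#' confirms the stored arm code. Supports quality control and replication:
#' an untampered ledger verifies end to end; any divergence is reported
#' with its sequence number rather than raised.
#'
#' @param ledger An `allocation_ledger`.
#' @param cfg The trial's validated `trial_config`.
#' @return A list with `verified` (logical), `n_records`, `divergence`
#'   (`NULL`, or the first mismatch: sequence number, field, expected,
#'   stored), and a human-readable `message`.
#' @export
replay_ledger <- function(ledger, cfg) {
  N <- ledger_size(ledger)
  # prefix records are materialized with corrections already applied at the
  # positions they were recorded, so the prefix carries no correction list
  # of its own (otherwise they would be applied twice)
  prefix <- new_ledger(ledger$trial_id)
  for (k in seq_len(N)) {
    stored <- ledger$records[[k]]
    subj <- effective_record(ledger, k, as_of = k - 1L)
    subject <- structure(
      list(subject_id = subj$subject_id, site = subj$site,
           categorical_values = subj$categorical_values,
           continuous_values = subj$continuous_values),
      class = "subject_record")
    # reconstruct the prefix view as of allocation k
    prefix$records <- lapply(seq_len(k - 1L), function(i)
      effective_record(ledger, i, as_of = k - 1L))

    init <- initial_phase_assignment(cfg, prefix)
    if (!is.null(init)) {
      probs <- init$probability_vector
      arm <- select_arm(stored$uniform_draw, probs)
      phase <- init$phase
    } else if (identical(cfg$method, "two_way")) {
      tw <- two_way_assign(prefix, cfg, subject,
                           criterion_draw = stored$criterion_draw,
                           uniform_draw = stored$uniform_draw)
      probs <- tw$probability_vector
      arm <- tw$arm_code
      phase <- "minimization"
    } else {
      scores <- if (identical(cfg$method, "pocock_simon")) {
        g_scores(marginal_counts(prefix, cfg), subject, factor_weights(cfg))
      } else d_scores(prefix, cfg, subject)
      probs <- probability_vector_from_scores(scores, cfg$biased_probability, cfg$n_arms)
      arm <- select_arm(stored$uniform_draw, probs)
      phase <- "minimization"
    }

    diverged <- if (arm != stored$arm_code) {
      list(field = "arm_code", expected = arm, stored = stored$arm_code)
    } else if (!isTRUE(all.equal(probs, as.numeric(stored$probability_vector),
                                 tolerance = 1e-9))) {
      list(field = "probability_vector", expected = probs,
           stored = stored$probability_vector)
    } else if (!identical(phase, stored$phase)) {
      list(field = "phase", expected = phase, stored = stored$phase)
    } else NULL
    if (!is.null(diverged)) {
      return(list(verified = FALSE, n_records = N,
                  divergence = c(list(sequence_number = k), diverged),
                  message = sprintf("divergence at sequence %d: %s (expected %s, stored %s)",
                                    k, diverged$field,
                                    paste(format(diverged$expected), collapse = ","),
                                    paste(format(diverged$stored), collapse = ","))))
    }
  }
  list(verified = TRUE, n_records = N, divergence = NULL,
       message = sprintf("verified, %d records", N))
}

#' Serialize / persist an allocation ledger
#'
#' Records are written as newline-delimited JSON (one object per line), with
#' a sidecar NDJSON file for correction entries. `serialize_ledger()`
#' returns the JSON lines; by default it drops timestamps, which are
#' recorded for audit but excluded from determinism comparisons.
#'
#' @param ledger An `allocation_ledger`.
#' @param include_timestamps Keep timestamp fields in the serialization.
#' @return Character vector of JSON lines.
#' @export
serialize_ledger <- function(ledger, include_timestamps = FALSE) {
  ser <- function(x) {
    if (!include_timestamps) x$timestamp <- NULL
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  c(vapply(ledger$records, ser, ""), vapply(ledger$corrections, ser, ""))
}

#' @rdname serialize_ledger
#' @param path Path for the records NDJSON file; corrections go to
#'   `<path>.corrections`.
#' @export
write_ledger <- function(ledger, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(vapply(ledger$records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null")), ""), tmp)
  file.rename(tmp, path)
  cpath <- paste0(path, ".corrections")
  tmp <- paste0(cpath, ".tmp")
  writeLines(vapply(ledger$corrections, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null")), ""), tmp)
  file.rename(tmp, cpath)
  invisible(path)
}

#' @rdname serialize_ledger
#' @param trial_id Trial identifier for the loaded ledger.
#' @export
read_ledger <- function(path, trial_id) {
  led <- new_ledger(trial_id)
  fix_rec <- function(r) {
    r$sequence_number <- as.integer(r$sequence_number)
    r$arm_code <- as.integer(r$arm_code)
    r$categorical_values <- as.list(r$categorical_values)
    r$continuous_values <- lapply(as.list(r$continuous_values), as.numeric)
    r$probability_vector <- as.numeric(r$probability_vector)
    r$score_vector <- as.numeric(r$score_vector)
    r$masked_number <- as.character(r$masked_number %||% NA_character_)
    r$criterion_draw <- as.numeric(r$criterion_draw %||% NA_real_)
    r$criterion_used <- as.character(r$criterion_used %||% NA_character_)
    r
  }
  if (file.exists(path)) {
    lines <- readLines(path)
    led$records <- lapply(lines[nzchar(lines)], function(l)
      fix_rec(jsonlite::fromJSON(l, simplifyVector = TRUE)))
  }
  cpath <- paste0(path, ".corrections")
  if (file.exists(cpath)) {
    lines <- readLines(cpath)
    led$corrections <- lapply(lines[nzchar(lines)], function(l) {
      e <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      e$target_sequence_number <- as.integer(e$target_sequence_number)
      e$as_of_sequence <- as.integer(e$as_of_sequence)
      e
    })
  }
  led
}
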