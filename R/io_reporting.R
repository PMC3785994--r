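# Batch CSV input, allocation export (blinded / unblinded views), and the
# per-factor-level balance summary table.

#' Read a batch of subjects from CSV
#'
#' Parses an RFC-4180 CSV with a header row containing `subject_id`,
#' `site`, and one column per configured factor (matched by name, any
#' order). Every record must validate — including uniqueness of subject
#' IDs within the file and against the ledger — or the whole batch is
#' rejected with a line-numbered list of all violations.
#'
#' @param path CSV file path.
#' @param cfg A validated `trial_config`.
#' @param ledger Optional current `allocation_ledger`, so IDs already
#'   randomized are rejected at parse time.
#' @return List of validated `subject_record` objects.
#' @export
read_subjects_csv <- function(path, cfg, ledger = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  fnames <- vapply(cfg$factors, `[[`, "", "name")
  need <- c("subject_id", "site", fnames)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("CSV is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (is.null(ledger)) ledger <- new_ledger(cfg$trial_id)

  errs <- character()
  seen <- ledger   # grows as rows validate, so in-file duplicates are caught
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L   # header is line 1
    rec <- subject_record(df$subject_id[i], df$site[i],
                          as.list(df[i, fnames, drop = FALSE]))
    v <- tryCatch(validate_subject(rec, cfg, seen), error = function(e) e)
    if (inherits(v, "error")) {
      msg <- sub("^invalid subject record:\n", "", conditionMessage(v))
      errs <- c(errs, sprintf("line %d: %s", line, gsub("\n\\s*- ", "; ", msg)))
    } else {
      records[[i]] <- v
      seen$records[[length(seen$records) + 1L]] <-
        list(subject_id = v$subject_id, arm_code = 1L)
    }
  }
  if (length(errs))
    stop("batch rejected:\n", paste0("  ", errs, collapse = "\n"), call. = FALSE)
  records
}

#' Export allocation records as CSV
#'
#' The unblinded view carries the full audit columns: sequence, subject,
#' site, factor values, arm, phase, the uniform draw, the probability
#' vector actually used, and the method's score vector — enough to replay
#' every allocation. The blinded view carries the same minus arm and
#' scores, plus the masked number, and never contains arm identity.
#'
#' @param ledger An `allocation_ledger`.
#' @param cfg A validated `trial_config`.
#' @param view `"blinded"` or `"unblinded"`.
#' @param path Optional output path; when omitted the data frame is
#'   returned.
#' @param acknowledge_unblinded Must be `TRUE` to export the unblinded
#'   view of a double-blind trial (it reveals arm assignments).
#' @return The exported data frame (invisibly when `path` is given).
#' @export
write_allocations_csv <- function(ledger, cfg, view = c("unblinded", "blinded"),
                                  path = NULL, acknowledge_unblinded = FALSE) {
  view <- match.arg(view)
  if (view == "unblinded" && identical(cfg$blinding, "double") &&
      !isTRUE(acknowledge_unblinded))
    stop("unblinded export of a double-blind trial requires acknowledge_unblinded = TRUE")
  subj <- effective_subjects(ledger, cfg)
  join <- function(x) paste(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                            collapse = ";")
  out <- subj
  out$phase <- vapply(ledger$records, `[[`, "", "phase")[seq_len(nrow(subj))]
  out$uniform_draw <- vapply(ledger$records, `[[`, 0, "uniform_draw")
  out$probability_vector <- vapply(ledger$records, function(r)
    join(r$probability_vector), "")
  if (view == "unblinded") {
    out$score_vector <- vapply(ledger$records, function(r)
      if (length(r$score_vector)) join(r$score_vector) else "", "")
  } else {
    out$arm_code <- NULL
    out$masked_number <- vapply(ledger$records, function(r)
      r$masked_number %||% NA_character_, "")
  }
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Maximum between-group difference
#'
#' @param arm_counts Integer vector of per-arm counts (length `I >= 2`).
#' @return `max(arm_counts) - min(arm_counts)`.
#' @export
#' @examples
#' max_group_difference(c(52, 46, 48))  # 6
max_group_difference <- function(arm_counts) {
  if (length(arm_counts) < 2L) stop("need counts for at least 2 arms")
  as.integer(max(arm_counts) - min(arm_counts))
}

#' Balance summary table
#'
#' The per-factor-level cross-tabulation of arm counts, with a row total
#' and the maximum between-group difference per level, closed by a
#' grand-total row over arms. Continuous factors appear only if display
#' cut points are supplied; binning is report-only and never feeds any
#' scoring path.
#'
#' @param ledger An `allocation_ledger`.
#' @param cfg A validated `trial_config`.
#' @param bins Named list of numeric cut points per continuous factor
#'   (passed to [cut()] with `right = FALSE`, `include.lowest = TRUE`).
#' @return A data frame of class `"balance_table"` with columns `factor`,
#'   `level`, one `arm_<i>` column per arm, `total`,
#'   `max_group_difference`.
#' @export
balance_table <- function(ledger, cfg, bins = NULL) {
  subj <- effective_subjects(ledger, cfg)
  I <- cfg$n_arms
  arm_cols <- paste0("arm_", seq_len(I))
  rows <- list()
  for (f in cfg$factors) {
    if (f$kind == "categorical") {
      vals <- factor(subj[[f$name]], levels = f$levels)
      lvls <- f$levels
    } else {
      if (is.null(bins[[f$name]])) next   # continuous factors need display bins
      br <- bins[[f$name]]
      vals <- cut(subj[[f$name]], breaks = br, right = FALSE, include.lowest = TRUE)
      if (nrow(subj) && anyNA(vals))
        stop(sprintf("bins for '%s' do not cover all observed values", f$name))
      lvls <- levels(vals)
    }
    tab <- table(vals, factor(subj$arm_code, levels = seq_len(I)))
    for (lv in lvls) {
      cnt <- as.integer(tab[lv, ])
      row <- c(list(factor = f$name, level = lv),
               stats::setNames(as.list(cnt), arm_cols),
               list(total = sum(cnt), max_group_difference = max_group_difference(cnt)))
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  tot <- as.integer(arm_totals(ledger, I))
  rows[[length(rows) + 1L]] <- as.data.frame(
    c(list(factor = "Total", level = ""),
      stats::setNames(as.list(tot), arm_cols),
      list(total = sum(tot), max_group_difference = max_group_difference(tot))),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("balance_table", "data.frame")
  out
}

#' @export
print.balance_table <- function(x, ...) {
  df <- as.data.frame(x)
  names(df) <- sub("^arm_", "arm ", names(df))
  names(df)[names(df) == "max_group_difference"] <- "max diff"
  print(format(df, justify = "left"), row.names = FALSE)
  invisible(x)
}
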