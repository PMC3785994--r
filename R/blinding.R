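# Masked-number pools for double-blind trials: random codes ("M" + 6
# digits) stand in for arm identity on labels; the code-to-arm key is the
# unblinding artifact and is exported only on explicit request.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister")
  force(expr)
}

MASKED_WIDTH <- 6L

new_masked_numbers <- function(n, exclude = character()) {
  used <- as.integer(sub("^M", "", exclude))
  pool <- setdiff(0:(10^MASKED_WIDTH - 1L), used)
  sprintf("M%0*d", MASKED_WIDTH, sample(pool, n))
}

#' Generate the masked-number table for a double-blind trial
#'
#' For every site, the pool holds `ceiling(1.10 * projected_max)` masked
#' numbers (the projected maximum enrollment plus 10%), split across arms
#' as evenly as possible with any remainder assigned by random draw. Each
#' masked number is a globally unique random fixed-width code prefixed
#' "M", and issuance order is pre-shuffled so neither lexical nor temporal
#' order carries arm information.
#'
#' @param cfg A validated `trial_config` with `blinding = "double"`.
#' @param seed Optional seed for the pool draw; defaults to a value derived
#'   from `cfg$seed`, so the table is reproducible per trial.
#' @return A data frame of class `"masked_number_table"` with columns
#'   `site`, `masked_number`, `arm_code`, `assigned`, `batch`, carrying a
#'   per-site/arm `initial_pool` attribute used by the replenishment rule.
#' @export
generate_masked_table <- function(cfg, seed = NULL) {
  if (!identical(cfg$blinding, "double"))
    stop("masked-number tables exist only for double-blind trials")
  if (is.null(seed)) seed <- derive_seed(cfg$seed, 1000003L)
  I <- cfg$n_arms
  pm <- unlist(cfg$projected_max_per_site)
  if (is.null(names(pm)) || !all(nzchar(names(pm)))) names(pm) <- cfg$sites

  with_seed(seed, {
    rows <- list()
    init <- list()
    for (site in cfg$sites) {
      # exact rational form: ceiling(1.10 * x) without binary-fraction error
      pool <- as.integer(ceiling(11 * pm[[site]] / 10))
      base <- pool %/% I
      per_arm <- rep(base, I)
      rem <- pool - base * I
      if (rem > 0L) {
        lucky <- sample.int(I, rem)
        per_arm[lucky] <- per_arm[lucky] + 1L
      }
      arms <- sample(rep(seq_len(I), times = per_arm))   # shuffled issuance order
      nums <- new_masked_numbers(pool,
                                 exclude = unlist(lapply(rows, `[[`, "masked_number")))
      rows[[site]] <- data.frame(site = site, masked_number = nums,
                                 arm_code = arms, assigned = FALSE, batch = 1L,
                                 stringsAsFactors = FALSE)
      init[[site]] <- stats::setNames(per_arm, as.character(seq_len(I)))
    }
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    attr(tab, "initial_pool") <- init
    class(tab) <- c("masked_number_table", "data.frame")
    tab
  })
}

pool_status <- function(table, site, arm) {
  sel <- table$site == site & table$arm_code == arm
  list(total = sum(sel), assigned = sum(sel & table$assigned),
       initial = attr(table, "initial_pool")[[site]][[as.character(arm)]])
}

#' Issue the next masked number for a site and arm
#'
#' Returns the next unassigned entry for the site/arm in the pre-shuffled
#' issuance order and marks it assigned; no number is ever issued twice.
#' When the assignment brings the site/arm pool to its 90%-assigned
#' threshold, the pool is replenished immediately afterwards, so exhaustion
#' is unreachable in normal operation (hitting it signals an internal
#' fault).
#'
#' @param table A `"masked_number_table"`.
#' @param site Site short-name.
#' @param arm_code Arm code.
#' @param seed Optional seed for any replenishment draw.
#' @return List with `masked_number` (string) and the updated `table`.
#' @export
next_masked_number <- function(table, site, arm_code, seed = NULL) {
  idx <- which(table$site == site & table$arm_code == arm_code & !table$assigned)
  if (!length(idx))
    stop(sprintf("masked-number pool exhausted for site '%s', arm %d (internal fault)",
                 site, arm_code))
  i <- idx[1]
  table$assigned[i] <- TRUE
  st <- pool_status(table, site, arm_code)
  if (st$assigned >= ceiling(9 * st$total / 10))
    table <- replenish_masked_table(table, site, seed = seed)
  list(masked_number = table$masked_number[i], table = table)
}

#' Replenish depleted masked-number pools at a site
#'
#' Appends a fresh batch of masked numbers for every arm at the site whose
#' pool is at least 90% assigned. The batch size is `ceiling(10%` of that
#' arm's initial pool`)`, with a minimum of 5. Other sites and arms are
#' untouched; global uniqueness is preserved.
#'
#' @param table A `"masked_number_table"`.
#' @param site Site short-name.
#' @param seed Optional seed for the draw of new numbers.
#' @return The (possibly grown) table.
#' @export
replenish_masked_table <- function(table, site, seed = NULL) {
  arms <- sort(unique(table$arm_code[table$site == site]))
  with_seed(seed, {
    for (arm in arms) {
      st <- pool_status(table, site, arm)
      if (st$assigned < ceiling(9 * st$total / 10)) next
      n_new <- max(5L, as.integer(ceiling(st$initial / 10)))
      add <- data.frame(site = site,
                        masked_number = new_masked_numbers(n_new, table$masked_number),
                        arm_code = arm, assigned = FALSE,
                        batch = max(table$batch[table$site == site & table$arm_code == arm]) + 1L,
                        stringsAsFactors = FALSE)
      init <- attr(table, "initial_pool")
      table <- rbind(as.data.frame(table), add, make.row.names = FALSE)
      attr(table, "initial_pool") <- init
      class(table) <- c("masked_number_table", "data.frame")
    }
    table
  })
}

#' Export the masked-number table (the unblinding key)
#'
#' Writes the site / masked-number / arm mapping as RFC-4180 CSV. This file
#' is the unblinding key: in a double-blind trial it should be held by a
#' third party only (e.g. for encoding treatments on drug bottle labels)
#' and kept from everyone performing or monitoring randomization until the
#' blind is broken.
#'
#' @param table A `"masked_number_table"`.
#' @param path Optional file path; when omitted the CSV content is
#'   returned as a character vector of lines.
#' @param arm_labels Optional arm labels replacing numeric codes.
#' @return `path` (invisibly) when writing, else the CSV lines.
#' @export
export_masked_table <- function(table, path = NULL, arm_labels = NULL) {
  if (!inherits(table, "masked_number_table"))
    stop("no masked-number table exists (single-blind trials have none)")
  out <- data.frame(site = table$site, masked_number = table$masked_number,
                    arm = if (is.null(arm_labels)) table$arm_code
                          else arm_labels[table$arm_code],
                    stringsAsFactors = FALSE)
  if (is.null(path)) {
    con <- textConnection("csv_lines", "w", local = TRUE)
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
    close(con)
    return(csv_lines)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a masked-number table back from CSV
#'
#' Round-trips the export of [export_masked_table()] (assignment state and
#' batch structure are not part of the unblinding key and default to
#' unassigned, batch 1).
#'
#' @param path CSV path.
#' @return A `"masked_number_table"`.
#' @export
read_masked_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- data.frame(site = as.character(df$site),
                    masked_number = as.character(df$masked_number),
                    arm_code = as.integer(df$arm), assigned = FALSE, batch = 1L,
                    stringsAsFactors = FALSE)
  init <- lapply(split(tab$arm_code, tab$site), function(a) {
    tt <- table(a); stats::setNames(as.integer(tt), names(tt))
  })
  attr(tab, "initial_pool") <- init
  class(tab) <- c("masked_number_table", "data.frame")
  tab
}
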