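#' Define a prognostic factor
#'
#' A prognostic factor is a baseline covariate used for balancing treatment
#' arms. Categorical factors carry an ordered set of level labels; continuous
#' factors carry an optional closed numeric validation range.
#'
#' @param name Identifier string; must be unique within a trial.
#' @param kind `"categorical"` or `"continuous"`.
#' @param levels Character vector of level labels (categorical only,
#'   at least two, pairwise distinct).
#' @param weight Nonnegative weight multiplying this factor's contribution
#'   to the imbalance score. Defaults to 1 (equal weighting).
#' @param validation_rule Optional validation: for categorical factors a
#'   character vector of allowed values (defaults to `levels`); for
#'   continuous factors a numeric `c(lower, upper)` closed range.
#'
#' @return A list of class `"factor_spec"`.
#' @export
#' @examples
#' factor_spec("gender", "categorical", levels = c("Female", "Male"))
#' factor_spec("bmi", "continuous", validation_rule = c(15, 60))
factor_spec <- function(name, kind = c("categorical", "continuous"),
                        levels = NULL, weight = 1, validation_rule = NULL) {
  kind <- match.arg(kind)
  spec <- structure(
    list(name = name, kind = kind, levels = levels, weight = weight,
         validation_rule = validation_rule),
    class = "factor_spec")
  errs <- .factor_spec_errors(spec)
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  spec
}

.factor_spec_errors <- function(spec) {
  errs <- character()
  push <- function(msg) errs[[length(errs) + 1L]] <<- msg
  if (!is.character(spec$name) || length(spec$name) != 1L || !nzchar(spec$name))
    push("factor name must be a nonempty string")
  nm <- if (is.character(spec$name) && length(spec$name) == 1L) spec$name else "<factor>"
  if (!spec$kind %in% c("categorical", "continuous"))
    push(sprintf("factor '%s': unknown kind '%s'", nm, spec$kind))
  if (identical(spec$kind, "categorical")) {
    if (is.null(spec$levels) || length(spec$levels) < 2L)
      push(sprintf("factor '%s': categorical factors need >= 2 levels", nm))
    else if (anyDuplicated(spec$levels))
      push(sprintf("factor '%s': duplicate level names", nm))
  } else {
    if (!is.null(spec$levels))
      push(sprintf("factor '%s': continuous factors must not declare levels", nm))
    if (!is.null(spec$validation_rule) &&
        (!is.numeric(spec$validation_rule) || length(spec$validation_rule) != 2L ||
         spec$validation_rule[1] > spec$validation_rule[2]))
      push(sprintf("factor '%s': continuous validation_rule must be c(lower, upper)", nm))
  }
  if (!is.numeric(spec$weight) || length(spec$weight) != 1L ||
      is.na(spec$weight) || spec$weight < 0)
    push(sprintf("factor '%s': weight must be a nonnegative number", nm))
  errs
}

#' Define a trial configuration
#'
#' The trial configuration governs every downstream operation: arm count,
#' sites, blinding mode, allocation method, prognostic factors, the biased
#' assignment probability, and the root seed for all randomness.
#'
#' @param trial_id Identifier string for the trial.
#' @param method `"pocock_simon"`, `"symmetric_kld"`, or `"two_way"`.
#' @param n_arms Number of treatment arms `I >= 2`. The symmetric-KLD and
#'   two-way methods are limited to 2 arms.
#' @param factors List of [factor_spec()] objects. Continuous factors are
#'   permitted only under `symmetric_kld`.
#' @param seed Integer seed; the sole source of randomness for the trial.
#' @param arm_labels Optional character vector of arm names, length `n_arms`.
#' @param sites Character vector of site short-names (default one site).
#' @param blinding `"single"` or `"double"`.
#' @param projected_max_per_site Named (or positional) integer vector of the
#'   projected maximum enrollment per site; required iff `blinding = "double"`
#'   (it sizes the masked-number pools).
#' @param biased_probability Biased-coin probability \eqn{P_i \in [1/I, 1)}
#'   assigned to the arm with the smallest imbalance score. Required for
#'   `pocock_simon` and `symmetric_kld`; forbidden for `two_way`, which
#'   derives its coin dynamically as \eqn{P = 1 - 0.95^\delta}.
#' @param n_initial_simple Number of initial subjects allocated by simple
#'   randomization before minimization takes over (`pocock_simon` only;
#'   default 1).
#' @param deterministic Allow `biased_probability = 1` (pure minimization).
#'   Maximally predictable, so off by default; useful for oracle testing.
#'
#' @return A validated list of class `"trial_config"`.
#' @seealso [validate_config()], [advise_initial_phase()]
#' @export
#' @examples
#' cfg <- trial_config(
#'   trial_id = "demo", method = "pocock_simon", n_arms = 2,
#'   factors = list(factor_spec("gender", "categorical",
#'                              levels = c("Female", "Male"))),
#'   biased_probability = 2 / 3, seed = 42)
trial_config <- function(trial_id, method, n_arms, factors, seed,
                         arm_labels = NULL, sites = "site1",
                         blinding = c("single", "double"),
                         projected_max_per_site = NULL,
                         biased_probability = NULL,
                         n_initial_simple = if (identical(method, "pocock_simon")) 1L else NULL,
                         deterministic = FALSE) {
  blinding <- match.arg(blinding)
  cfg <- structure(
    list(trial_id = trial_id, blinding = blinding, n_arms = as.integer(n_arms),
         arm_labels = arm_labels, sites = sites,
         projected_max_per_site = projected_max_per_site, method = method,
         biased_probability = biased_probability,
         n_initial_simple = if (is.null(n_initial_simple)) NULL else as.integer(n_initial_simple),
         factors = factors, seed = as.integer(seed),
         deterministic = isTRUE(deterministic)),
    class = "trial_config")
  validate_config(cfg)
}

#' Validate a trial configuration
#'
#' Checks every structural invariant of a trial configuration and reports
#' *all* violations at once rather than stopping at the first. Validating an
#' already-valid configuration returns it unchanged (idempotence).
#'
#' @param cfg A `trial_config` object, a plain list with the same fields
#'   (e.g. parsed from YAML), or a path to a YAML config file.
#' @return The validated `trial_config`, invisibly identical to its input
#'   when that input was already valid.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- read_trial_config(cfg)
  if (!is.list(cfg)) stop("config must be a list or a path to a YAML file")
  errs <- character()
  push <- function(msg) errs[[length(errs) + 1L]] <<- msg

  if (is.null(cfg$trial_id) || !nzchar(cfg$trial_id %||% ""))
    push("trial_id must be a nonempty string")
  if (is.null(cfg$method) || !cfg$method %in% c("pocock_simon", "symmetric_kld", "two_way"))
    push(sprintf("unknown method '%s' (use pocock_simon, symmetric_kld or two_way)",
                 cfg$method %||% "<missing>"))
  I <- suppressWarnings(as.integer(cfg$n_arms %||% NA))
  if (is.na(I) || I < 2L) push("n_arms must be an integer >= 2")
  if (!is.na(I) && !is.null(cfg$arm_labels) && length(cfg$arm_labels) != I)
    push("arm_labels must have length n_arms")
  if (isTRUE(cfg$method %in% c("symmetric_kld", "two_way")) && !is.na(I) && I != 2L)
    push(sprintf("method '%s' is limited to 2 arms", cfg$method))
  if (is.null(cfg$sites) || length(cfg$sites) < 1L || anyDuplicated(cfg$sites))
    push("sites must be a nonempty list of distinct short-names")
  if (is.null(cfg$blinding) || !cfg$blinding %in% c("single", "double"))
    push("blinding must be 'single' or 'double'")

  if (identical(cfg$blinding, "double")) {
    pm <- cfg$projected_max_per_site
    if (is.null(pm)) {
      push("double blinding requires projected_max_per_site for every site")
    } else {
      pm <- unlist(pm)
      if (!is.null(names(pm)) && any(nzchar(names(pm)))) {
        missing_sites <- setdiff(cfg$sites, names(pm))
        if (length(missing_sites))
          push(sprintf("projected_max_per_site missing for site(s): %s",
                       paste(missing_sites, collapse = ", ")))
      } else if (length(pm) != length(cfg$sites)) {
        push("projected_max_per_site must cover every site")
      }
      if (any(!is.finite(pm)) || any(pm < 1))
        push("projected_max_per_site entries must be positive integers")
    }
  } else if (!is.null(cfg$projected_max_per_site) &&
             !identical(cfg$blinding, "double")) {
    # tolerated but inert for single-blind trials
  }

  # biased probability: required for score-ranking methods, forbidden for two-way
  if (isTRUE(cfg$method %in% c("pocock_simon", "symmetric_kld"))) {
    p <- cfg$biased_probability
    if (is.null(p)) {
      push(sprintf("method '%s' requires biased_probability", cfg$method))
    } else if (!is.numeric(p) || length(p) != 1L || !is.finite(p)) {
      push("biased_probability must be a single finite number")
    } else if (!is.na(I)) {
      hi_ok <- if (isTRUE(cfg$deterministic)) p <= 1 else p < 1
      if (p < 1 / I || !hi_ok)
        push(sprintf(
          "biased_probability %.4g outside [1/%d, 1)%s", p, I,
          if (isTRUE(cfg$deterministic)) "" else " (set deterministic = TRUE for P = 1)"))
    }
  } else if (identical(cfg$method, "two_way") && !is.null(cfg$biased_probability)) {
    push("two_way derives its coin dynamically; biased_probability is forbidden")
  }

  if (!is.null(cfg$n_initial_simple)) {
    if (!identical(cfg$method, "pocock_simon"))
      push("n_initial_simple applies to pocock_simon only")
    else if (is.na(suppressWarnings(as.integer(cfg$n_initial_simple))) ||
             cfg$n_initial_simple < 0)
      push("n_initial_simple must be a nonnegative integer")
  }

  if (is.null(cfg$factors) || !length(cfg$factors)) {
    push("at least one prognostic factor is required")
  } else {
    for (f in cfg$factors) {
      fe <- .factor_spec_errors(structure(f, class = "factor_spec"))
      for (e in fe) push(e)
    }
    fnames <- vapply(cfg$factors, function(f) f$name %||% "", "")
    if (anyDuplicated(fnames)) push("duplicate factor names")
    kinds <- vapply(cfg$factors, function(f) f$kind %||% "", "")
    if (isTRUE(cfg$method %in% c("pocock_simon", "two_way")) && any(kinds == "continuous"))
      push(sprintf("continuous factors are not supported by '%s' (categorize them or use symmetric_kld)",
                   cfg$method))
    wts <- vapply(cfg$factors, function(f) as.numeric(f$weight %||% 1), 0)
    if (all(is.finite(wts)) && !any(wts > 0))
      push("at least one factor must have weight > 0")
  }

  seed <- suppressWarnings(as.integer(cfg$seed %||% NA))
  if (is.na(seed)) push("seed must be an integer")

  if (length(errs))
    stop("invalid trial configuration:\n", paste0("  - ", errs, collapse = "\n"),
         call. = FALSE)
  class(cfg) <- "trial_config"
  cfg$n_arms <- I
  cfg$seed <- seed
  cfg$factors <- lapply(cfg$factors, function(f) {
    f$weight <- as.numeric(f$weight %||% 1)
    structure(f, class = "factor_spec")
  })
  cfg
}

#' Advise on the initial simple-randomization phase
#'
#' For Pocock-Simon trials configured with fewer initial simple-randomization
#' subjects than recommended, returns a non-blocking advisory suggesting
#' simple randomization for the first 10 to 15 subjects, which guards against
#' assignment guessing while arm counts are small. Returns `NULL` otherwise.
#'
#' @param cfg A validated `trial_config`.
#' @return Advisory string, or `NULL`.
#' @export
advise_initial_phase <- function(cfg) {
  if (!identical(cfg$method, "pocock_simon")) return(NULL)
  n0 <- cfg$n_initial_simple %||% 1L
  if (n0 >= 10L) return(NULL)
  paste0(
    "Advisory: consider simple randomization for the first 10 to 15 subjects ",
    "(currently n_initial_simple = ", n0, ") to prevent guessing of ",
    "assignments while arm counts are small.")
}

#' Read / write a trial configuration file
#'
#' Configurations are stored as a single human-editable YAML document per
#' trial and round-trip losslessly.
#'
#' @param path Path to the YAML file.
#' @return `read_trial_config()` returns a validated `trial_config`;
#'   `write_trial_config()` returns `path` invisibly.
#' @export
read_trial_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$factors))
    raw$factors <- lapply(raw$factors, function(f) {
      if (!is.null(f$levels)) f$levels <- as.character(f$levels)
      if (!is.null(f$validation_rule) && identical(f$kind, "continuous"))
        f$validation_rule <- as.numeric(f$validation_rule)
      f
    })
  if (!is.null(raw$projected_max_per_site))
    raw$projected_max_per_site <- unlist(raw$projected_max_per_site)
  validate_config(raw)
}

#' @rdname read_trial_config
#' @param cfg A validated `trial_config`.
#' @export
write_trial_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$factors <- lapply(out$factors, unclass)
  if (!is.null(out$projected_max_per_site))
    out$projected_max_per_site <- as.list(out$projected_max_per_site)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf("<trial_config '%s'> %s, %d arms, %d site(s), %s-blind\n",
              x$trial_id, x$method, x$n_arms, length(x$sites), x$blinding))
  if (!is.null(x$biased_probability))
    cat(sprintf("  biased probability P = %.4g\n", x$biased_probability))
  for (f in x$factors)
    cat(sprintf("  factor %-12s %s%s (weight %g)\n", f$name, f$kind,
                if (identical(f$kind, "categorical"))
                  paste0(" {", paste(f$levels, collapse = ", "), "}") else "",
                f$weight))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Arm labels with positional fallback "1", "2", ...
arm_label <- function(cfg, arm) {
  if (!is.null(cfg$arm_labels)) cfg$arm_labels[arm] else as.character(arm)
}
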