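#' Label vocabularies
#'
#' Closed vocabularies used throughout the package. Marital status covers the
#' seven statuses retained for analysis plus the abstention value `NOT_GIVEN`.
#' `DATING` is a derived category: base annotators never emit it; it is produced
#' by [derive_dating()] from a `PARTNERED` call without partner cohabitation.
#' The `ENGAGED` status is deliberately absent (too rare to analyse).
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
MARITAL_LEVELS <- c(
  "MARRIED", "SINGLE", "PARTNERED", "DATING",
  "SEPARATED", "DIVORCED", "WIDOWED", "NOT_GIVEN"
)

#' @rdname vocabularies
#' @export
LIVING_LEVELS <- c("ALONE", "WITH_FAMILY", "WITH_OTHERS", "NOT_GIVEN")

#' @rdname vocabularies
#' @export
COHAB_LEVELS <- c("WITH_PARTNER", "NOT_WITH_PARTNER", "UNKNOWN")

#' Conditions tracked per admission
#' @export
CONDITIONS <- c("depression", "alcohol_abuse", "drug_abuse")

#' Marital-status change classes
#' @export
CHANGE_LEVELS <- c("SAME", "GOT_MARRIED", "OTHER_CHANGE")

assert_marital <- function(x, what = "label") {
  bad <- setdiff(unique(x), MARITAL_LEVELS)
  if (length(bad) > 0) {
    stop(sprintf("invalid marital %s: %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

assert_living <- function(x, what = "label") {
  bad <- setdiff(unique(x), LIVING_LEVELS)
  if (length(bad) > 0) {
    stop(sprintf("invalid living %s: %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

assert_cohab <- function(x, what = "label") {
  bad <- setdiff(unique(x), COHAB_LEVELS)
  if (length(bad) > 0) {
    stop(sprintf("invalid cohabitation %s: %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_mix <- function(mix, levels, name) {
  if (is.null(names(mix)) || !all(names(mix) %in% levels)) {
    stop(sprintf("%s must be named with values among: %s",
                 name, paste(levels, collapse = ", ")), call. = FALSE)
  }
  assert_prob(unname(mix), name)
  if (abs(sum(mix) - 1) > 1e-9) {
    stop(sprintf("%s must sum to 1 (got %.12f)", name, sum(mix)), call. = FALSE)
  }
  full <- stats::setNames(rep(0, length(levels)), levels)
  full[names(mix)] <- mix
  full
}

#' Derive a module seed from a master seed
#'
#' Deterministically maps `(master_seed, module_name)` to a 31-bit seed so each
#' pipeline stage can be rerun in isolation with the same stream it saw inside
#' [run_experiment()].
#'
#' @param master_seed Integer master seed.
#' @param module Character module name.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
module_seed <- function(master_seed, module) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  h <- sum(utf8ToInt(module) * seq_along(utf8ToInt(module)))
  as.integer((abs(master_seed) * 7919 + h * 104729) %% 2147483646 + 1)
}
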