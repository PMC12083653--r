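#' Pattern-based weak annotator
#'
#' A deterministic cue-lexicon extractor standing in for off-the-shelf
#' marital-status models. Marital rules are applied in a fixed precedence
#' order (widow > divorce > separation > marriage > partner > single; first
#' match wins) so rare, specific statuses are not shadowed by more common
#' cues. Separate lexicons detect the living arrangement and whether the
#' patient lives with a partner. No match yields `NOT_GIVEN` / `UNKNOWN`;
#' the function is total (an empty string is fine).
#'
#' @param text Character vector of note texts.
#' @return A data.frame with columns `marital`, `living`, `cohab`.
#' @examples
#' pattern_annotate("Pt is married, lives with wife.")
#' pattern_annotate("Has a girlfriend, lives alone.")
#' @export
pattern_annotate <- function(text) {
  stopifnot(!anyNA(text))
  mar_lex <- marital_cue_lexicon()
  liv_lex <- living_cue_lexicon()
  with_partner <- cohab_partner_pattern()
  alone <- cohab_alone_pattern()
  marital <- vapply(text, first_cue_match, character(1),
                    lexicon = mar_lex, fallback = "NOT_GIVEN",
                    USE.NAMES = FALSE)
  living <- vapply(text, first_cue_match, character(1),
                   lexicon = liv_lex, fallback = "NOT_GIVEN",
                   USE.NAMES = FALSE)
  low <- tolower(text)
  cohab <- ifelse(
    grepl(with_partner, low, perl = TRUE), "WITH_PARTNER",
    ifelse(grepl(alone, low, perl = TRUE), "NOT_WITH_PARTNER", "UNKNOWN")
  )
  data.frame(marital = marital, living = living, cohab = cohab,
             stringsAsFactors = FALSE)
}

#' Default structured-field vocabulary mapping
#'
#' Maps raw demographics tokens to marital labels; mirrors a typical ICU
#' demographics dictionary. Editable: pass any named character vector to
#' [structured_annotate()].
#'
#' @return Named character vector (token -> marital label).
#' @export
default_structured_mapping <- function() {
  c(
    "MARRIED" = "MARRIED",
    "SINGLE" = "SINGLE",
    "WIDOWED" = "WIDOWED",
    "DIVORCED" = "DIVORCED",
    "SEPARATED" = "SEPARATED",
    "LIFE PARTNER" = "PARTNERED",
    "UNKNOWN (DEFAULT)" = "NOT_GIVEN"
  )
}

#' Annotate from the structured demographics field
#'
#' Maps the raw structured token to a marital label. Empty or unmapped tokens
#' give `NOT_GIVEN`. The structured field carries no living-arrangement
#' information, so `living` is always `NOT_GIVEN` and `cohab` is `UNKNOWN`.
#'
#' @param structured_status Character vector of raw tokens (may be `""`).
#' @param mapping Named character vector (token -> marital label).
#' @return A data.frame with columns `marital`, `living`, `cohab`.
#' @export
structured_annotate <- function(structured_status,
                                mapping = default_structured_mapping()) {
  assert_marital(unname(mapping), "mapping target")
  marital <- unname(mapping[structured_status])
  marital[is.na(marital) | structured_status == ""] <- "NOT_GIVEN"
  data.frame(
    marital = marital,
    living = rep("NOT_GIVEN", length(marital)),
    cohab = rep("UNKNOWN", length(marital)),
    stringsAsFactors = FALSE
  )
}

#' Confusion specification for a simulated annotator
#'
#' @param matrix Row-stochastic matrix: rows indexed by true marital label,
#'   columns by emitted label (both subsets of [MARITAL_LEVELS]).
#' @param seed Integer seed used by [simulate_annotator()].
#' @return An object of class `confusion_spec`.
#' @export
confusion_spec <- function(matrix, seed = 1L) {
  stopifnot(is.matrix(matrix))
  assert_marital(rownames(matrix), "confusion row")
  assert_marital(colnames(matrix), "confusion column")
  assert_prob(as.vector(matrix), "confusion probabilities")
  bad <- which(abs(rowSums(matrix) - 1) > 1e-9)
  if (length(bad) > 0) {
    stop(sprintf("confusion rows must sum to 1 (rows: %s)",
                 paste(rownames(matrix)[bad], collapse = ", ")), call. = FALSE)
  }
  structure(list(matrix = matrix, seed = as.integer(seed)),
            class = "confusion_spec")
}

#' Build a diagonal-plus-uniform confusion spec
#'
#' Convenience constructor: each true label is emitted correctly with
#' probability `accuracy`, and the remaining mass is spread uniformly over the
#' other labels.
#'
#' @param accuracy Per-class probability of the correct label.
#' @param labels Labels covered (default: all but `DATING`, which base
#'   annotators never emit).
#' @param seed Integer seed.
#' @export
uniform_confusion_spec <- function(accuracy,
                                   labels = setdiff(MARITAL_LEVELS, "DATING"),
                                   seed = 1L) {
  k <- length(labels)
  m <- matrix((1 - accuracy) / (k - 1), k, k, dimnames = list(labels, labels))
  diag(m) <- accuracy
  confusion_spec(m, seed = seed)
}

#' Simulate a noisy annotator from a confusion specification
#'
#' Emits, for each gold label, a label drawn from that label's confusion row.
#' Deterministic given the spec seed and the order of the gold vector.
#'
#' @param gold Character vector of true marital labels.
#' @param conf A [confusion_spec()].
#' @return Character vector of emitted labels, same length as `gold`.
#' @export
simulate_annotator <- function(gold, conf) {
  stopifnot(inherits(conf, "confusion_spec"))
  assert_marital(gold)
  missing_rows <- setdiff(unique(gold), rownames(conf$matrix))
  if (length(missing_rows) > 0) {
    stop(sprintf("confusion spec has no row for: %s",
                 paste(missing_rows, collapse = ", ")), call. = FALSE)
  }
  old <- .Random.seed_exists()
  set.seed(conf$seed)
  on.exit(.restore_seed(old), add = TRUE)
  labels <- colnames(conf$matrix)
  cum <- t(apply(conf$matrix, 1, cumsum))
  u <- stats::runif(length(gold))
  idx <- vapply(seq_along(gold), function(i) {
    sum(u[i] > cum[gold[i], ]) + 1L
  }, integer(1))
  labels[pmin(idx, length(labels))]
}

#' Harmonize a partnered call against cohabitation (stage 1)
#'
#' Keeps `PARTNERED` only when the annotator also found the patient living
#' with the partner; a `PARTNERED` call without cohabitation evidence is
#' demoted to `SINGLE` (at this stage dating individuals are treated as
#' single). All other labels pass through unchanged. Idempotent.
#'
#' @param marital Character vector of marital labels.
#' @param cohab Character vector of cohabitation labels.
#' @return Recoded marital labels.
#' @export
recode_partnered <- function(marital, cohab) {
  assert_marital(marital)
  assert_cohab(cohab)
  ifelse(marital == "PARTNERED" & cohab != "WITH_PARTNER", "SINGLE", marital)
}

#' Derive the dating category (stage 2)
#'
#' Patients labelled `PARTNERED` who do not live with their partner are coded
#' into the separate `DATING` category; everything else passes through
#' unchanged. Idempotent.
#'
#' @inheritParams recode_partnered
#' @return Recoded marital labels.
#' @export
derive_dating <- function(marital, cohab) {
  assert_marital(marital)
  assert_cohab(cohab)
  ifelse(marital == "PARTNERED" & cohab != "WITH_PARTNER", "DATING", marital)
}
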