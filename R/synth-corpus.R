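#' Specification for a synthetic social-history corpus
#'
#' Describes a corpus of templated social-history snippets of the kind found in
#' discharge notes: each note may carry a marital-status cue sentence, a
#' living-arrangement sentence and filler sentences about tobacco/alcohol
#' history, plus a structured demographics token with configurable missingness
#' and staleness (a stale field stores the token of a different, randomly
#' chosen status, emulating outdated demographics).
#'
#' The default `class_mix` follows the composition of a manually annotated
#' tuning set of 322 social-history sections (single 53, partnered 49, married
#' 117, separated 6, divorced 34, widowed 42, not given 21); `DATING` defaults
#' to 0 because structured fields and off-the-shelf extractors do not support
#' it as a primary category.
#'
#' @param n_notes Number of notes to generate.
#' @param class_mix Named probabilities over [MARITAL_LEVELS] (must sum to 1).
#' @param living_mix Named probabilities over [LIVING_LEVELS] (must sum to 1).
#'   Notes with gold status `PARTNERED` are always rendered as living with the
#'   partner and notes with `DATING` as living alone, whatever the mix, since
#'   those statuses are defined by cohabitation.
#' @param structured_missing_rate Probability the structured field is empty.
#' @param structured_stale_rate Probability the structured field holds the
#'   token of a uniformly chosen *other* status.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_notes = 1000,
                        class_mix = c(
                          MARRIED = 117 / 322, SINGLE = 53 / 322,
                          PARTNERED = 49 / 322, DATING = 0,
                          SEPARATED = 6 / 322, DIVORCED = 34 / 322,
                          WIDOWED = 42 / 322, NOT_GIVEN = 21 / 322
                        ),
                        living_mix = c(
                          ALONE = 0.25, WITH_FAMILY = 0.45,
                          WITH_OTHERS = 0.10, NOT_GIVEN = 0.20
                        ),
                        structured_missing_rate = 0.10,
                        structured_stale_rate = 0.05,
                        seed = 1L) {
  if (!is.numeric(n_notes) || length(n_notes) != 1 || n_notes < 0 ||
      n_notes != floor(n_notes)) {
    stop("n_notes must be a nonnegative integer", call. = FALSE)
  }
  class_mix <- assert_mix(class_mix, MARITAL_LEVELS, "class_mix")
  living_mix <- assert_mix(living_mix, LIVING_LEVELS, "living_mix")
  assert_prob(structured_missing_rate, "structured_missing_rate")
  assert_prob(structured_stale_rate, "structured_stale_rate")
  if (structured_missing_rate + structured_stale_rate > 1 + 1e-9) {
    stop("structured_missing_rate + structured_stale_rate must be <= 1",
         call. = FALSE)
  }
  structure(
    list(
      n_notes = as.integer(n_notes),
      class_mix = class_mix,
      living_mix = living_mix,
      structured_missing_rate = structured_missing_rate,
      structured_stale_rate = structured_stale_rate,
      seed = as.integer(seed)
    ),
    class = "corpus_spec"
  )
}

# Template bank. Each marital class has >= 3 cue sentences using only its own
# cue lexicon; fillers carry no marital or living cues.
marital_templates <- function() {
  list(
    MARRIED = c("Pt is married.", "Patient has been married for many years.",
                "Married, two grown children."),
    SINGLE = c("Pt is single.", "Patient reports being single.",
               "Currently unmarried."),
    PARTNERED = c("Has a girlfriend.", "Has a boyfriend.",
                  "Patient has a long-term partner."),
    DATING = c("Has a girlfriend.", "Has a boyfriend.",
               "Patient has a long-term partner."),
    SEPARATED = c("Pt is separated.", "Patient is currently separated.",
                  "Recently separated."),
    DIVORCED = c("Pt is divorced.", "Divorced several years ago.",
                 "Recently divorced."),
    WIDOWED = c("Pt is widowed.", "Patient is a widow.", "Widower, retired."),
    NOT_GIVEN = character(0)
  )
}

living_templates <- function(status) {
  partner_terms <- c("wife", "husband", "partner", "girlfriend", "boyfriend")
  list(
    ALONE = c("Lives alone.", "Patient lives alone in an apartment.",
              "Currently living alone."),
    WITH_FAMILY = if (status == "MARRIED") {
      c("Lives with his wife.", "Lives with her husband.",
        "Lives at home with spouse.")
    } else if (status %in% c("PARTNERED")) {
      paste0("Lives with ", c("her partner", "his girlfriend", "her boyfriend"), ".")
    } else {
      c("Lives with family.", "Lives with her daughter.",
        "Lives at home with his son.")
    },
    WITH_OTHERS = c("Lives with a roommate.", "Lives with friends.",
                    "Lives in a group home.")
  )
}

filler_templates <- function() {
  c("Tobacco: denies.", "Former smoker, quit 10 years ago.",
    "Occasional alcohol use.", "Denies illicit drug use.",
    "Works as a teacher.", "Retired.", "No history of IV drug use.")
}

#' Map a marital status to its structured-field token
#'
#' Mirrors a typical ICU demographics dictionary. `DATING` maps to `"SINGLE"`
#' (structured fields record dating patients as single) and `NOT_GIVEN` maps to
#' the dictionary's explicit unknown token.
#'
#' @param status Character vector of marital labels.
#' @return Character vector of raw structured tokens.
#' @export
structured_token_for <- function(status) {
  assert_marital(status)
  map <- c(
    MARRIED = "MARRIED", SINGLE = "SINGLE", PARTNERED = "LIFE PARTNER",
    DATING = "SINGLE", SEPARATED = "SEPARATED", DIVORCED = "DIVORCED",
    WIDOWED = "WIDOWED", NOT_GIVEN = "UNKNOWN (DEFAULT)"
  )
  unname(map[status])
}

#' Generate a synthetic social-history corpus
#'
#' Renders one templated note per record: a marital cue sentence matching the
#' gold status (none for `NOT_GIVEN`), a living-arrangement sentence matching
#' the gold living label (none for `NOT_GIVEN`), and 1-2 filler sentences, in
#' a shuffled-but-seeded order with the marital sentence first. The structured
#' field holds the token for the gold status except when missing or stale.
#'
#' @param spec A [corpus_spec()].
#' @return A data.frame with one row per note: `note_id`, `patient_id`,
#'   `admission_id`, `text`, `structured_status`, `gold_status`, `gold_living`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_notes
  out <- data.frame(
    note_id = sprintf("note-%05d", seq_len(n)),
    patient_id = sprintf("pt-%05d", seq_len(n)),
    admission_id = sprintf("adm-%05d", seq_len(n)),
    text = character(n),
    structured_status = character(n),
    gold_status = character(n),
    gold_living = character(n),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(out)

  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(.restore_seed(old), add = TRUE)

  gold <- sample(MARITAL_LEVELS, n, replace = TRUE, prob = spec$class_mix)
  living <- sample(LIVING_LEVELS, n, replace = TRUE, prob = spec$living_mix)
  # Cohabitation defines these two statuses, so their living label is forced.
  living[gold == "PARTNERED"] <- "WITH_FAMILY"
  living[gold == "DATING"] <- "ALONE"

  fillers <- filler_templates()
  mar_bank <- marital_templates()
  texts <- character(n)
  for (i in seq_len(n)) {
    sents <- character(0)
    if (gold[i] != "NOT_GIVEN") {
      bank <- mar_bank[[gold[i]]]
      sents <- c(sents, bank[sample.int(length(bank), 1)])
    }
    if (living[i] != "NOT_GIVEN") {
      bank <- living_templates(gold[i])[[living[i]]]
      sents <- c(sents, bank[sample.int(length(bank), 1)])
    }
    nf <- sample.int(2, 1)
    sents <- c(sents, fillers[sample.int(length(fillers), nf)])
    texts[i] <- paste(sents, collapse = " ")
  }

  token <- structured_token_for(gold)
  u <- stats::runif(n)
  missing <- u < spec$structured_missing_rate
  stale <- !missing &
    u < spec$structured_missing_rate + spec$structured_stale_rate
  token[missing] <- ""
  if (any(stale)) {
    for (i in which(stale)) {
      others <- setdiff(MARITAL_LEVELS, gold[i])
      token[i] <- structured_token_for(others[sample.int(length(others), 1)])
    }
  }

  out$text <- texts
  out$structured_status <- token
  out$gold_status <- gold
  out$gold_living <- living
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write / read a corpus as JSONL
#'
#' One JSON object per line, UTF-8. Optional gold fields are preserved.
#'
#' @param corpus Data.frame as returned by [generate_corpus()].
#' @param path File path.
#' @return `write_corpus_jsonl` returns `path` invisibly; `read_corpus_jsonl`
#'   returns the corpus data.frame.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(as.list(corpus[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
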