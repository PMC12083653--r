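definite_statuses <- function() setdiff(MARITAL_LEVELS, "NOT_GIVEN")

#' Default cohort-generator parameters
#'
#' `default_transition_matrix()` is a sticky chain over the seven definite
#' statuses (`stay` self-transition, remainder uniform).
#' `default_prevalence()` holds the per-status first-admission prevalence of
#' each condition; `default_event_probs()` the per-group (`SAME`/`CHANGE`)
#' patient-level new-diagnosis and recovery probabilities. Cells that published
#' ICU-population figures do not pin down are declared package defaults.
#'
#' @param stay Self-transition probability per admission step.
#' @return A matrix (`default_transition_matrix`, `default_prevalence`) or a
#'   list of two matrices (`default_event_probs`).
#' @export
default_transition_matrix <- function(stay = 0.97) {
  s <- definite_statuses()
  m <- matrix((1 - stay) / (length(s) - 1), length(s), length(s),
              dimnames = list(s, s))
  diag(m) <- stay
  m
}

#' @rdname default_transition_matrix
#' @export
default_prevalence <- function() {
  # Rows: status at first admission; columns: condition prevalence.
  # Married/partnered/dating/widowed rates follow published ICU-population
  # figures; the remaining cells are declared package defaults.
  rbind(
    MARRIED   = c(depression = 0.0932, alcohol_abuse = 0.0655, drug_abuse = 0.0255),
    SINGLE    = c(depression = 0.1500, alcohol_abuse = 0.1200, drug_abuse = 0.0800),
    PARTNERED = c(depression = 0.1500, alcohol_abuse = 0.2180, drug_abuse = 0.1650),
    DATING    = c(depression = 0.1930, alcohol_abuse = 0.1830, drug_abuse = 0.1000),
    SEPARATED = c(depression = 0.1600, alcohol_abuse = 0.1200, drug_abuse = 0.0700),
    DIVORCED  = c(depression = 0.1600, alcohol_abuse = 0.1500, drug_abuse = 0.0700),
    WIDOWED   = c(depression = 0.1240, alcohol_abuse = 0.0236, drug_abuse = 0.0196)
  )
}

#' @rdname default_transition_matrix
#' @export
default_event_probs <- function() {
  list(
    new_diagnosis = rbind(
      SAME   = c(depression = 0.062, alcohol_abuse = 0.014, drug_abuse = 0.016),
      CHANGE = c(depression = 0.072, alcohol_abuse = 0.043, drug_abuse = 0.072)
    ),
    recovery = rbind(
      SAME   = c(depression = 0.042, alcohol_abuse = 0.018, drug_abuse = 0.016),
      CHANGE = c(depression = 0.108, alcohol_abuse = 0.050, drug_abuse = 0.058)
    )
  )
}

#' Specification for a synthetic longitudinal ICU cohort
#'
#' Describes patient timelines: ordered admissions with ISO dates, a marital
#' status per admission evolving by a first-order transition matrix, condition
#' flags (depression, alcohol abuse, drug abuse), an age centred near 57 years
#' and a nonnegative integer comorbidity score (Elixhauser-van Walraven style)
#' drawn per status.
#'
#' The per-patient flag trajectory for each condition is drawn by first
#' assigning the patient to an event case by the change/same group he or she
#' belongs to: a new-diagnosis case (flag off at the first admission, switching
#' on at a later one) with probability `new_diagnosis_prob`, a recovery case
#' (on at first, off by the last) with probability `recovery_prob`, otherwise a
#' stable flag drawn at an adjusted prevalence so the first-admission
#' prevalence matches `prevalence` for the patient's status. This makes the
#' patient-level new-diagnosis and recovery rates equal the configured
#' probabilities exactly in expectation, with group size as denominator.
#'
#' @param n_patients Number of patients.
#' @param mean_age,sd_age Age-at-first-admission distribution (normal,
#'   truncated to 18-95 years).
#' @param min_admissions Minimum admissions per patient.
#' @param mean_extra_admissions Poisson mean of admissions beyond the minimum.
#' @param gap_years_range Range of the uniform inter-admission gap, in years.
#'   The default upper end of 6 years guarantees the 5-year eligibility filter
#'   has something to remove.
#' @param initial_mix Named probabilities of the first-admission status over
#'   the seven definite statuses; the default follows the relative sizes of a
#'   published static ICU cohort (single 262, dating 159, partnered 486,
#'   married 3774, widowed 62, divorced 592).
#' @param transition_matrix Row-stochastic matrix over the definite statuses.
#' @param prevalence Status x condition matrix of first-admission prevalences.
#' @param new_diagnosis_prob,recovery_prob Group (`SAME`/`CHANGE`) x condition
#'   matrices of patient-level event probabilities.
#' @param evw_lambda Named per-status Poisson mean of the comorbidity score.
#' @param abstain_rate Probability that an admission's recorded status label is
#'   `NOT_GIVEN`, emulating extraction abstention on that note.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1000,
                        mean_age = 57, sd_age = 15,
                        min_admissions = 2, mean_extra_admissions = 1,
                        gap_years_range = c(0.5, 6),
                        initial_mix = c(
                          MARRIED = 3774, SINGLE = 262, PARTNERED = 486,
                          DATING = 159, SEPARATED = 0, DIVORCED = 592,
                          WIDOWED = 62
                        ) / 5335,
                        transition_matrix = default_transition_matrix(),
                        prevalence = default_prevalence(),
                        new_diagnosis_prob = default_event_probs()$new_diagnosis,
                        recovery_prob = default_event_probs()$recovery,
                        evw_lambda = c(
                          MARRIED = 5, SINGLE = 6, PARTNERED = 6, DATING = 6,
                          SEPARATED = 6, DIVORCED = 7, WIDOWED = 6
                        ),
                        abstain_rate = 0.05,
                        seed = 1L) {
  s <- definite_statuses()
  if (!is.numeric(n_patients) || n_patients < 0) {
    stop("n_patients must be a nonnegative count", call. = FALSE)
  }
  if (mean_age <= 0) stop("mean_age must be positive", call. = FALSE)
  initial_mix <- assert_mix(initial_mix, s, "initial_mix")[s]
  if (!is.matrix(transition_matrix) ||
      !identical(sort(rownames(transition_matrix)), sort(s))) {
    stop("transition_matrix must be a matrix over the definite statuses",
         call. = FALSE)
  }
  transition_matrix <- transition_matrix[s, s]
  assert_prob(as.vector(transition_matrix), "transition_matrix")
  bad <- which(abs(rowSums(transition_matrix) - 1) > 1e-9)
  if (length(bad) > 0) {
    stop(sprintf("transition_matrix rows must sum to 1 (rows: %s)",
                 paste(s[bad], collapse = ", ")), call. = FALSE)
  }
  prevalence <- prevalence[s, CONDITIONS, drop = FALSE]
  assert_prob(as.vector(prevalence), "prevalence")
  for (m in list(new_diagnosis_prob, recovery_prob)) {
    stopifnot(identical(rownames(m), c("SAME", "CHANGE")),
              identical(colnames(m), CONDITIONS))
    assert_prob(as.vector(m), "event probabilities")
  }
  if (any(new_diagnosis_prob + recovery_prob > 1 + 1e-9)) {
    stop("new_diagnosis_prob + recovery_prob must be <= 1 per cell",
         call. = FALSE)
  }
  assert_prob(abstain_rate, "abstain_rate")
  structure(
    list(
      n_patients = as.integer(n_patients), mean_age = mean_age, sd_age = sd_age,
      min_admissions = as.integer(min_admissions),
      mean_extra_admissions = mean_extra_admissions,
      gap_years_range = gap_years_range, initial_mix = initial_mix,
      transition_matrix = transition_matrix, prevalence = prevalence,
      new_diagnosis_prob = new_diagnosis_prob, recovery_prob = recovery_prob,
      evw_lambda = evw_lambda[s], abstain_rate = abstain_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' @param spec A [cohort_spec()].
#' @return A long data.frame with one row per admission: `patient_id`,
#'   `admission_index`, `date` (class `Date`), `status` (recorded label, may be
#'   `NOT_GIVEN` when `abstain_rate > 0`), `true_status`, one 0/1 column per
#'   condition, `age_at_first`, `evw_score`. Admissions are strictly
#'   date-ordered within patient. Deterministic given the spec.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  s <- definite_statuses()
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(.restore_seed(old), add = TRUE)

  ages <- pmin(95, pmax(18, stats::rnorm(n, spec$mean_age, spec$sd_age)))
  n_adm <- spec$min_admissions + stats::rpois(n, spec$mean_extra_admissions)
  n_adm <- pmax(1L, n_adm)
  origin <- as.Date("2001-01-01")

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_adm[i]
    status <- character(k)
    status[1] <- sample(s, 1, prob = spec$initial_mix)
    if (k > 1) {
      for (j in 2:k) {
        status[j] <- sample(s, 1, prob = spec$transition_matrix[status[j - 1], ])
      }
    }
    gaps <- stats::runif(max(k - 1, 0), spec$gap_years_range[1],
                         spec$gap_years_range[2])
    dates <- origin + sample.int(2922, 1) +
      round(cumsum(c(0, gaps)) * 365.25)
    group <- if (status[1] == status[k]) "SAME" else "CHANGE"

    flags <- matrix(0L, k, length(CONDITIONS),
                    dimnames = list(NULL, CONDITIONS))
    for (cond in CONDITIONS) {
      p_new <- spec$new_diagnosis_prob[group, cond]
      p_rec <- spec$recovery_prob[group, cond]
      prev <- spec$prevalence[status[1], cond]
      u <- stats::runif(1)
      if (k >= 2 && u < p_new) {
        onset <- 1L + sample.int(k - 1, 1)
        flags[onset:k, cond] <- 1L
      } else if (k >= 2 && u < p_new + p_rec) {
        offset <- 1L + sample.int(k - 1, 1)
        flags[seq_len(offset - 1), cond] <- 1L
      } else {
        prev_adj <- (prev - p_rec) / max(1 - p_new - p_rec, 1e-12)
        prev_adj <- min(1, max(0, prev_adj))
        flags[, cond] <- as.integer(stats::runif(1) < prev_adj)
      }
    }

    recorded <- status
    abst <- stats::runif(k) < spec$abstain_rate
    recorded[abst] <- "NOT_GIVEN"

    rows[[i]] <- data.frame(
      patient_id = sprintf("pt-%06d", i),
      admission_index = seq_len(k),
      date = dates,
      status = recorded,
      true_status = status,
      depression = flags[, "depression"],
      alcohol_abuse = flags[, "alcohol_abuse"],
      drug_abuse = flags[, "drug_abuse"],
      age_at_first = ages[i],
      evw_score = stats::rpois(1, spec$evw_lambda[status[1]]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort table as CSV
#'
#' Dates are written ISO-8601. Round-trips the data.frame produced by
#' [generate_cohort()].
#'
#' @param cohort Long admission-level data.frame.
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- cohort
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}
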