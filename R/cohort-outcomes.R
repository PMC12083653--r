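#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Bounds from Beta-distribution quantiles: with `a = (1 - level) / 2`,
#' `lower = qbeta(a, x, n - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - a, x + 1, n - x)` (1 when `x = n`). Conservative:
#' coverage is at least the nominal level.
#'
#' @param x Event count.
#' @param n Denominator (at least 1).
#' @param level Confidence level in (0, 1).
#' @return An object of class `proportion_ci`: list with `x`, `n`, `p_hat`,
#'   `level`, `lower`, `upper`.
#' @export
exact_binomial_ci <- function(x, n, level = 0.95) {
  if (length(x) != 1 || length(n) != 1 || !is.finite(x) || !is.finite(n) ||
      n < 1 || x < 0 || x > n || x != floor(x) || n != floor(n)) {
    stop("need integer counts with 0 <= x <= n and n >= 1", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  structure(list(x = as.integer(x), n = as.integer(n), p_hat = x / n,
                 level = level, lower = lower, upper = upper),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI %.1f%%-%.1f%%)\n",
              x$x, x$n, 100 * x$p_hat, round(100 * x$level),
              100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Select patients eligible for longitudinal analysis
#'
#' Keeps patients with at least `min_admissions` admissions whose admissions
#' fall within the allowed span: by default the full first-to-last span must be
#' at most `max_span_years` (measured in days, `round(365.25 * years)`,
#' inclusive); `mode = "consecutive"` instead requires every consecutive gap to
#' satisfy the limit.
#'
#' @param cohort Long admission-level data.frame ([generate_cohort()] layout),
#'   date-sorted within patient.
#' @param min_admissions Minimum number of admissions (>= 2).
#' @param max_span_years Time window in years.
#' @param mode `"span"` (default) or `"consecutive"`.
#' @return The eligible subset of `cohort`.
#' @export
select_eligible <- function(cohort, min_admissions = 2, max_span_years = 5,
                            mode = c("span", "consecutive")) {
  mode <- match.arg(mode)
  stopifnot(min_admissions >= 2, max_span_years > 0)
  limit_days <- round(365.25 * max_span_years)
  by_pt <- split(cohort, cohort$patient_id)
  keep <- vapply(by_pt, function(df) {
    if (nrow(df) < min_admissions) return(FALSE)
    d <- sort(as.numeric(df$date))
    if (mode == "span") {
      (d[length(d)] - d[1]) <= limit_days
    } else {
      all(diff(d) <= limit_days)
    }
  }, logical(1))
  eligible <- names(by_pt)[keep]
  out <- cohort[cohort$patient_id %in% eligible, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify each patient's marital-status change
#'
#' Compares the first and last *definite* (non-`NOT_GIVEN`) admission labels:
#' equal gives `SAME`; a change ending in `MARRIED` gives `GOT_MARRIED`; any
#' other difference gives `OTHER_CHANGE`. Intervening admissions, including
#' `NOT_GIVEN` ones, are ignored. Patients with fewer than two definite labels
#' are excluded (`change_class = NA`) with the reason recorded.
#'
#' @param cohort Long admission-level data.frame with a `status` column.
#' @param status_col Column holding the per-admission label.
#' @return Patient-level data.frame: `patient_id`, `change_class`,
#'   `n_definite`, `first_status`, `last_status`, `exclusion_reason`.
#' @export
classify_change <- function(cohort, status_col = "status") {
  by_pt <- split(cohort, cohort$patient_id)
  rows <- lapply(by_pt, function(df) {
    df <- df[order(df$date), , drop = FALSE]
    lab <- df[[status_col]]
    def <- lab[lab != "NOT_GIVEN"]
    if (length(def) < 2) {
      return(data.frame(patient_id = df$patient_id[1], change_class = NA_character_,
                        n_definite = length(def),
                        first_status = if (length(def)) def[1] else NA_character_,
                        last_status = NA_character_,
                        exclusion_reason = "fewer than two definite labels",
                        stringsAsFactors = FALSE))
    }
    first <- def[1]; last <- def[length(def)]
    cls <- if (first == last) "SAME"
      else if (last == "MARRIED") "GOT_MARRIED"
      else "OTHER_CHANGE"
    data.frame(patient_id = df$patient_id[1], change_class = cls,
               n_definite = length(def), first_status = first,
               last_status = last, exclusion_reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age-matched downsampling of cohort groups
#'
#' Randomly subsamples groups whose mean age differs from the reference
#' group's by more than `tolerance_years`, stratified by `bin_width`-year age
#' bins toward the reference group's bin distribution. Groups already within
#' tolerance are returned unchanged. Deterministic given `seed`.
#'
#' @param patients Patient-level data.frame with columns `patient_id`,
#'   `group`, `age`.
#' @param reference_group Name of the group whose mean age is the target.
#' @param tolerance_years Allowed absolute difference of group means.
#' @param seed Integer seed.
#' @param bin_width Age-bin width in years.
#' @return The downsampled patient-level data.frame.
#' @export
downsample_age_match <- function(patients, reference_group,
                                 tolerance_years = 1, seed = 1L,
                                 bin_width = 5) {
  stopifnot(all(c("patient_id", "group", "age") %in% names(patients)),
            tolerance_years > 0)
  groups <- split(patients, patients$group)
  if (!reference_group %in% names(groups)) {
    stop(sprintf("reference group '%s' not present", reference_group),
         call. = FALSE)
  }
  if (any(vapply(groups, nrow, integer(1)) == 0)) {
    stop("empty group", call. = FALSE)
  }
  breaks <- seq(0, 120, by = bin_width)
  ref <- groups[[reference_group]]
  ref_mean <- mean(ref$age)
  ref_bins <- table(cut(ref$age, breaks, right = FALSE))
  ref_prop <- ref_bins / sum(ref_bins)

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)

  out <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    if (g == reference_group || abs(mean(df$age) - ref_mean) <= tolerance_years) {
      return(df)
    }
    bins <- cut(df$age, breaks, right = FALSE)
    avail <- table(bins)
    usable <- names(ref_prop)[ref_prop > 0 & avail[names(ref_prop)] > 0]
    if (length(usable) == 0) {
      stop(sprintf(
        "cannot age-match group '%s' to '%s': no overlapping age bins (group range %.0f-%.0f, reference range %.0f-%.0f)",
        g, reference_group, min(df$age), max(df$age),
        min(ref$age), max(ref$age)), call. = FALSE)
    }
    prop <- ref_prop[usable] / sum(ref_prop[usable])
    n_target <- floor(min(avail[usable] / prop))
    take <- pmin(round(prop * n_target), avail[usable])
    picked <- do.call(rbind, lapply(usable, function(b) {
      rows <- df[bins == b, , drop = FALSE]
      rows[sample.int(nrow(rows), take[b]), , drop = FALSE]
    }))
    if (nrow(picked) == 0 ||
        abs(mean(picked$age) - ref_mean) > tolerance_years) {
      stop(sprintf(
        "cannot age-match group '%s' to '%s' within %.1f years (achieved mean %.1f vs reference %.1f)",
        g, reference_group, tolerance_years,
        if (nrow(picked)) mean(picked$age) else NA_real_, ref_mean),
        call. = FALSE)
    }
    picked
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

first_admission <- function(cohort) {
  by_pt <- split(cohort, cohort$patient_id)
  do.call(rbind, lapply(by_pt, function(df) df[which.min(df$date), , drop = FALSE]))
}

#' Condition prevalence at first admission
#'
#' @param group Long admission-level data.frame for one patient group.
#' @param condition One of [CONDITIONS].
#' @param level Confidence level.
#' @return A [exact_binomial_ci()] `proportion_ci`.
#' @export
prevalence <- function(group, condition, level = 0.95) {
  stopifnot(condition %in% names(group), nrow(group) > 0)
  fa <- first_admission(group)
  exact_binomial_ci(sum(fa[[condition]] > 0), nrow(fa), level)
}

#' New-diagnosis and recovery rates for a condition
#'
#' New diagnosis: the flag is off at the first admission and on at any later
#' one. Recovery: on at the first admission and off at the last. Both use the
#' group size as denominator, and the two event sets are disjoint by
#' construction.
#'
#' @inheritParams prevalence
#' @return List with `new_diagnosis` and `recovery` (`proportion_ci` each).
#' @export
transition_rates <- function(group, condition, level = 0.95) {
  stopifnot(condition %in% names(group))
  by_pt <- split(group, group$patient_id)
  stopifnot(all(vapply(by_pt, nrow, integer(1)) >= 2))
  status <- vapply(by_pt, function(df) {
    df <- df[order(df$date), , drop = FALSE]
    f <- df[[condition]] > 0
    if (!f[1] && any(f[-1])) "new" else if (f[1] && !f[length(f)]) "recovery"
    else "none"
  }, character(1))
  n <- length(by_pt)
  list(
    new_diagnosis = exact_binomial_ci(sum(status == "new"), n, level),
    recovery = exact_binomial_ci(sum(status == "recovery"), n, level)
  )
}

#' Rank-sum (Mann-Whitney) comparison of two score samples
#'
#' Exact enumeration when both samples have at most 8 observations and no
#' ties; otherwise the tie-corrected normal approximation (no continuity
#' correction).
#'
#' @param scores_a,scores_b Numeric samples (e.g. comorbidity scores).
#' @return List with `statistic` (Mann-Whitney U of the first sample) and
#'   `p_value` (two-sided).
#' @export
rank_sum_compare <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) > 0, length(scores_b) > 0)
  ties <- any(duplicated(c(scores_a, scores_b)))
  use_exact <- length(scores_a) <= 8 && length(scores_b) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    scores_a, scores_b, exact = use_exact, correct = FALSE
  ))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Holm step-down adjustment of p-values
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}
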