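mk_timeline <- function(patient_id, dates, statuses,
                        depression = rep(0L, length(dates))) {
  data.frame(patient_id = patient_id,
             admission_index = seq_along(dates),
             date = as.Date(dates), status = statuses,
             depression = depression,
             alcohol_abuse = 0L, drug_abuse = 0L,
             age_at_first = 60, evw_score = 5L,
             stringsAsFactors = FALSE)
}

test_that("eligibility applies the admission-count and 5-year span rules", {
  cohort <- rbind(
    mk_timeline("p1", c("2001-06-01", "2003-06-01"), rep("MARRIED", 2)),
    mk_timeline("p2", c("2001-06-01", "2007-06-01"), rep("MARRIED", 2)),
    mk_timeline("p3", "2001-06-01", "MARRIED")
  )
  kept <- unique(select_eligible(cohort)$patient_id)
  expect_identical(kept, "p1")

  # exactly 5 years (1826 days) is inclusive
  d0 <- as.Date("2001-01-01")
  edge <- mk_timeline("p4", c(d0, d0 + 1826), rep("SINGLE", 2))
  expect_equal(unique(select_eligible(edge)$patient_id), "p4")
  over <- mk_timeline("p5", c(d0, d0 + 1827), rep("SINGLE", 2))
  expect_equal(nrow(select_eligible(over)), 0)

  # consecutive-gap mode accepts a long span with short gaps
  tri <- mk_timeline("p6", c("2001-01-01", "2005-01-01", "2009-01-01"),
                     rep("MARRIED", 3))
  expect_equal(nrow(select_eligible(tri)), 0)
  expect_equal(unique(select_eligible(tri, mode = "consecutive")$patient_id),
               "p6")
})

test_that("change classification compares first and last definite labels", {
  same <- classify_change(mk_timeline("p1", c("2001-01-01", "2002-01-01"),
                                      c("MARRIED", "MARRIED")))
  expect_equal(same$change_class, "SAME")

  gm <- classify_change(mk_timeline("p2", c("2001-01-01", "2002-01-01"),
                                    c("SINGLE", "MARRIED")))
  expect_equal(gm$change_class, "GOT_MARRIED")

  oc <- classify_change(mk_timeline("p3", c("2001-01-01", "2002-01-01"),
                                    c("MARRIED", "DIVORCED")))
  expect_equal(oc$change_class, "OTHER_CHANGE")

  # NOT_GIVEN admissions between the endpoints are ignored
  ng <- classify_change(mk_timeline(
    "p4", c("2001-01-01", "2001-06-01", "2002-01-01", "2002-06-01"),
    c("NOT_GIVEN", "SINGLE", "NOT_GIVEN", "MARRIED")))
  expect_equal(ng$change_class, "GOT_MARRIED")

  # fewer than two definite labels: excluded with a reason
  excl <- classify_change(mk_timeline("p5", c("2001-01-01", "2002-01-01"),
                                      c("NOT_GIVEN", "MARRIED")))
  expect_true(is.na(excl$change_class))
  expect_match(excl$exclusion_reason, "definite")

  # a dating/partnered swap is an OTHER_CHANGE
  dp <- classify_change(mk_timeline("p6", c("2001-01-01", "2002-01-01"),
                                    c("DATING", "PARTNERED")))
  expect_equal(dp$change_class, "OTHER_CHANGE")
})

test_that("age matching downsamples toward the reference mean deterministically", {
  set.seed(15)
  patients <- rbind(
    data.frame(patient_id = sprintf("r%03d", 1:150), group = "ref",
               age = rnorm(150, 60, 4)),
    data.frame(patient_id = sprintf("y%03d", 1:400), group = "young",
               age = rnorm(400, 50, 8))
  )
  out <- downsample_age_match(patients, "ref", tolerance_years = 1, seed = 3)
  ref_mean <- mean(patients$age[patients$group == "ref"])
  young <- out[out$group == "young", ]
  expect_lt(abs(mean(young$age) - ref_mean), 1)
  expect_lt(nrow(young), 400)
  # reference group untouched, rerun identical
  expect_equal(sum(out$group == "ref"), 150)
  out2 <- downsample_age_match(patients, "ref", tolerance_years = 1, seed = 3)
  expect_identical(out, out2)

  # groups already within tolerance are unchanged
  near <- patients
  near$age[near$group == "young"] <- rnorm(400, ref_mean, 2)
  out3 <- downsample_age_match(near, "ref", tolerance_years = 5, seed = 3)
  expect_equal(nrow(out3), nrow(near))

  # impossible matches raise diagnostics
  disjoint <- rbind(
    data.frame(patient_id = "a1", group = "ref", age = 80),
    data.frame(patient_id = sprintf("b%d", 1:30), group = "kids", age = 10)
  )
  expect_error(downsample_age_match(disjoint, "ref", seed = 1),
               "no overlapping age bins")
  expect_error(
    downsample_age_match(patients[patients$group == "ref", ][0, ], "ref"),
    "reference group|empty"
  )
})

test_that("exact binomial CI reproduces Beta-quantile bounds and edge cases", {
  expect_ci_close(exact_binomial_ci(10, 139), 3.5, 12.8)
  expect_ci_close(exact_binomial_ci(6, 139), 1.6, 9.2)

  z <- exact_binomial_ci(0, 50)
  expect_equal(z$lower, 0)
  f <- exact_binomial_ci(50, 50)
  expect_equal(f$upper, 1)

  expect_error(exact_binomial_ci(5, 0), "n >= 1")
  expect_error(exact_binomial_ci(6, 5), "x <= n")
  expect_error(exact_binomial_ci(3, 10, level = 1.2), "level")

  # cross-check against the independent exact implementation in binom.test
  for (x in c(0, 1, 7, 70, 139)) {
    ours <- exact_binomial_ci(x, 139)
    ref <- stats::binom.test(x, 139)$conf.int
    expect_equal(c(ours$lower, ours$upper), as.numeric(ref), tolerance = 1e-12)
  }

  # both bounds nondecreasing in x; interval always contains x/n
  prev <- exact_binomial_ci(0, 60)
  for (x in 1:60) {
    cur <- exact_binomial_ci(x, 60)
    expect_gte(cur$lower, prev$lower)
    expect_gte(cur$upper, prev$upper)
    expect_true(cur$lower <= cur$p_hat && cur$p_hat <= cur$upper)
    prev <- cur
  }
})

test_that("transition rates count disjoint new-diagnosis and recovery events", {
  # hand-built 5-patient toy: 2 new diagnoses, 1 recovery
  toy <- rbind(
    mk_timeline("p1", c("2001-01-01", "2002-01-01"), rep("MARRIED", 2),
                depression = c(0L, 1L)),   # new
    mk_timeline("p2", c("2001-01-01", "2002-01-01"), rep("MARRIED", 2),
                depression = c(0L, 1L)),   # new
    mk_timeline("p3", c("2001-01-01", "2002-01-01"), rep("MARRIED", 2),
                depression = c(1L, 0L)),   # recovery
    mk_timeline("p4", c("2001-01-01", "2002-01-01"), rep("MARRIED", 2),
                depression = c(1L, 1L)),
    mk_timeline("p5", c("2001-01-01", "2002-01-01"), rep("MARRIED", 2),
                depression = c(0L, 0L))
  )
  tr <- transition_rates(toy, "depression")
  expect_equal(tr$new_diagnosis$p_hat, 2 / 5)
  expect_equal(tr$recovery$p_hat, 1 / 5)
  expect_equal(tr$new_diagnosis$n, 5L)

  # constant flags: both rates zero
  flat <- rbind(
    mk_timeline("q1", c("2001-01-01", "2002-01-01"), rep("SINGLE", 2),
                depression = c(1L, 1L)),
    mk_timeline("q2", c("2001-01-01", "2002-01-01"), rep("SINGLE", 2))
  )
  tr0 <- transition_rates(flat, "depression")
  expect_equal(tr0$new_diagnosis$x, 0L)
  expect_equal(tr0$recovery$x, 0L)

  # 10 events among 139 patients prints as 7.2% with the published CI
  pts <- lapply(seq_len(139), function(i) {
    mk_timeline(sprintf("w%03d", i), c("2001-01-01", "2002-01-01"),
                rep("MARRIED", 2),
                depression = if (i <= 10) c(0L, 1L) else c(0L, 0L))
  })
  tr139 <- transition_rates(do.call(rbind, pts), "depression")
  expect_equal(round(100 * tr139$new_diagnosis$p_hat, 1), 7.2)
  expect_ci_close(tr139$new_diagnosis, 3.5, 12.8)
})

test_that("rank-sum comparison handles exact, tied and shifted samples", {
  ident <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_gt(ident$p_value, 0.9)

  small <- rank_sum_compare(c(1, 2), c(3, 4))
  expect_equal(small$p_value, 1 / 3, tolerance = 1e-12)

  set.seed(90)
  hits <- vapply(1:10, function(i) {
    a <- rpois(200, 7); b <- rpois(200, 5)
    rank_sum_compare(a, b)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Holm adjustment matches hand-computed step-down values", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.6), 0.6)
  expect_equal(holm_adjust(c(0.01, 0.01, 0.01)), c(0.03, 0.03, 0.03))
  # original order preserved
  expect_equal(holm_adjust(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("CP intervals cover the generating prevalence across replicates", {
  s <- maritalens:::definite_statuses()
  ident <- diag(length(s)); dimnames(ident) <- list(s, s)
  mix <- stats::setNames(rep(0, length(s)), s); mix["MARRIED"] <- 1
  covered <- vapply(1:20, function(i) {
    spec <- cohort_spec(n_patients = 400, transition_matrix = ident,
                        initial_mix = mix, abstain_rate = 0, seed = 100 + i)
    ci <- prevalence(generate_cohort(spec), "depression")
    ci$lower <= 0.0932 && 0.0932 <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
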