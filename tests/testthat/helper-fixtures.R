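# Shared fixtures built in code.

make_votes <- function(s, a, b,
                       la = rep("NOT_GIVEN", length(s)),
                       lb = rep("NOT_GIVEN", length(s))) {
  vote_records(note_id = sprintf("n%03d", seq_along(s)),
               structured = s, model_a = a, model_b = b,
               living_a = la, living_b = lb)
}

# Simulated three-annotator vote table over a random gold vector: each
# annotator is conditionally independent with diagonal accuracy `acc` and
# uniform errors. Returns list(votes, gold).
simulate_vote_table <- function(n, acc = c(0.75, 0.75, 0.75), seed = 1,
                                labels = setdiff(MARITAL_LEVELS, "DATING")) {
  set.seed(seed)
  gold <- sample(labels, n, replace = TRUE)
  draws <- lapply(seq_along(acc), function(k) {
    simulate_annotator(gold, uniform_confusion_spec(acc[k], labels = labels,
                                                    seed = seed + 100 * k))
  })
  list(
    votes = make_votes(draws[[1]], draws[[2]], draws[[3]]),
    gold = gold
  )
}

# Corpus + noisy annotators arranged so the majority-vote teacher abstains on
# roughly 30% of notes: the structured field is often missing/stale and the
# two text models carry independent confusion noise.
noisy_teacher_setting <- function(n_notes, seed) {
  spec <- corpus_spec(n_notes = n_notes,
                      structured_missing_rate = 0.30,
                      structured_stale_rate = 0.15,
                      seed = seed)
  corpus <- generate_corpus(spec)
  base <- pattern_annotate(corpus$text)
  lv <- setdiff(MARITAL_LEVELS, "DATING")
  ma <- derive_dating(
    simulate_annotator(base$marital,
                       uniform_confusion_spec(0.70, labels = lv, seed = seed + 1)),
    base$cohab)
  mb <- derive_dating(
    simulate_annotator(base$marital,
                       uniform_confusion_spec(0.70, labels = lv, seed = seed + 2)),
    base$cohab)
  votes <- vote_records(note_id = corpus$note_id,
                        structured = structured_annotate(corpus$structured_status)$marital,
                        model_a = ma, model_b = mb,
                        living_a = base$living, living_b = base$living)
  list(corpus = corpus, votes = votes, gold = corpus$gold_status)
}

# compare CI bounds to printed values at one-decimal-percent precision
expect_ci_close <- function(ci, lower_pct, upper_pct) {
  expect_equal(round(100 * ci$lower, 1), lower_pct)
  expect_equal(round(100 * ci$upper, 1), upper_pct)
}
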