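test_that("featurization counts unigrams and bigrams over a fixed vocabulary", {
  vocab <- c("a", "a b", "b", "b c", "c", "married")
  x <- featurize_text(c("", "married married", "a b c"), vocab)
  expect_equal(dim(x), c(3L, 6L))
  expect_equal(sum(x[1, ]), 0)
  expect_equal(as.numeric(x[2, "married"]), 2)
  # "a b c": unigrams a, b, c and bigrams "a b", "b c" -> L1 norm 5
  expect_equal(sum(x[3, ]), 5)
  expect_equal(as.numeric(x[3, c("a", "a b", "b", "b c", "c")]),
               rep(1, 5))
  # out-of-vocabulary tokens are ignored
  expect_equal(sum(featurize_text("zzz qqq", vocab)), 0)
})

test_that("pseudo-labeling keeps decisions and drops abstentions", {
  corpus <- data.frame(note_id = sprintf("n%03d", 1:6),
                       text = sprintf("text %d", 1:6),
                       stringsAsFactors = FALSE)
  agree <- make_votes(rep("MARRIED", 6), rep("MARRIED", 6), rep("MARRIED", 6))
  agree$note_id <- corpus$note_id
  pool <- pseudo_label(corpus, agree, "unanimous")
  expect_equal(nrow(pool), 6)
  expect_equal(attr(pool, "n_dropped"), 0L)

  disagree <- make_votes(
    c("MARRIED", "SINGLE", "WIDOWED", "DIVORCED", "MARRIED", "SINGLE"),
    c("SINGLE", "WIDOWED", "DIVORCED", "MARRIED", "WIDOWED", "MARRIED"),
    c("WIDOWED", "DIVORCED", "MARRIED", "SINGLE", "DIVORCED", "WIDOWED")
  )
  disagree$note_id <- corpus$note_id
  pool2 <- pseudo_label(corpus, disagree, "majority")
  expect_equal(nrow(pool2), 0)
  expect_equal(attr(pool2, "n_dropped"), 6L)

  # precision/forest NOT_GIVEN outputs are genuine predictions, kept
  tab <- compute_precision_table(
    list(structured = rep("NOT_GIVEN", 4), model_a = rep("NOT_GIVEN", 4),
         model_b = rep("NOT_GIVEN", 4)),
    rep("NOT_GIVEN", 4))
  pool3 <- pseudo_label(corpus, disagree, "precision", table = tab)
  expect_equal(nrow(pool3), 6)
})

test_that("pool size tracks the vote agreement rate", {
  set.seed(31)
  n <- 1000
  p_agree <- 0.7
  gold <- sample(setdiff(MARITAL_LEVELS, "DATING"), n, replace = TRUE)
  agree <- runif(n) < p_agree
  a <- gold; b <- gold; s <- gold
  # on disagreeing notes force a three-way split so majority abstains
  for (i in which(!agree)) {
    others <- setdiff(MARITAL_LEVELS, gold[i])
    s[i] <- others[1]; a[i] <- others[2]; b[i] <- others[3]
  }
  votes <- make_votes(s, a, b)
  corpus <- data.frame(note_id = votes$note_id, text = "t",
                       stringsAsFactors = FALSE)
  pool <- pseudo_label(corpus, votes, "majority")
  se <- sqrt(p_agree * (1 - p_agree) / n)
  expect_lt(abs(nrow(pool) / n - p_agree), 4 * se)
})

test_that("student learns a separable fixture and handles degenerate pools", {
  co <- generate_corpus(corpus_spec(n_notes = 800, seed = 17))
  pool <- data.frame(note_id = co$note_id, text = co$text,
                     pseudo_label = co$gold_status, source_ensemble = "gold",
                     stringsAsFactors = FALSE)
  train <- pool[1:600, ]; held <- pool[601:800, ]
  st <- train_student(train, seed = 1)
  expect_equal(mean(student_predict(st, held$text) == held$pseudo_label), 1)

  # duplication invariance: the multinomial objective scales, argmax unchanged
  st2 <- train_student(rbind(train, train), seed = 1)
  expect_identical(student_predict(st2, held$text),
                   student_predict(st, held$text))

  # deterministic predictions
  expect_identical(student_predict(st, held$text),
                   student_predict(st, held$text))

  # single-class pool warns and returns a constant predictor
  single <- train[train$pseudo_label == "MARRIED", ]
  expect_warning(stc <- train_student(single), "single-class")
  expect_identical(student_predict(stc, c("a", "b")), rep("MARRIED", 2))

  expect_error(train_student(train[0, ]), "empty")
})

test_that("empty text falls back to the bias argmax and never abstains", {
  co <- generate_corpus(corpus_spec(n_notes = 500, seed = 19))
  pool <- data.frame(note_id = co$note_id, text = co$text,
                     pseudo_label = co$gold_status, source_ensemble = "gold",
                     stringsAsFactors = FALSE)
  st <- train_student(pool, seed = 1)
  expect_equal(student_predict(st, ""), st$classes[which.max(st$bias)])
  preds <- student_predict(st, c("", "zzz unseen words", co$text[1]))
  expect_true(all(preds %in% st$classes))
})

test_that("student model serialization round-trips exactly", {
  co <- generate_corpus(corpus_spec(n_notes = 300, seed = 23))
  pool <- data.frame(note_id = co$note_id, text = co$text,
                     pseudo_label = co$gold_status, source_ensemble = "gold",
                     stringsAsFactors = FALSE)
  st <- train_student(pool, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  student_to_json(st, path)
  back <- student_from_json(path)
  expect_identical(back$classes, st$classes)
  expect_identical(back$vocab, st$vocab)
  expect_identical(unname(back$weights), unname(st$weights))
  expect_identical(unname(back$bias), unname(as.numeric(st$bias)))
  expect_identical(student_predict(back, co$text), student_predict(st, co$text))
})

test_that("student raises macro recall over an abstaining majority teacher", {
  setting <- noisy_teacher_setting(n_notes = 2500, seed = 29)
  n <- nrow(setting$corpus)
  test_idx <- 1:500
  pool_idx <- 501:n

  teacher <- majority_vote(setting$votes)
  abstain_rate <- mean(teacher[pool_idx] == "NOT_GIVEN")
  expect_gt(abstain_rate, 0.15)  # the teacher abstains substantially

  pool <- pseudo_label(setting$corpus[pool_idx, ],
                       setting$votes[pool_idx, ], "majority")
  st <- train_student(pool, seed = 1)
  student_labels <- student_predict(st, setting$corpus$text[test_idx])

  classes <- MARITAL_LEVELS[MARITAL_LEVELS %in%
                              unique(c(setting$gold[test_idx], teacher[test_idx],
                                       student_labels))]
  ev_teacher <- evaluate_labels(setting$gold[test_idx], teacher[test_idx],
                                classes = classes)
  ev_student <- evaluate_labels(setting$gold[test_idx], student_labels,
                                classes = classes)
  expect_gt(ev_student$macro_recall, ev_teacher$macro_recall)

  # the student assigns a definite label to every note the teacher abstained on
  abstained <- test_idx[teacher[test_idx] == "NOT_GIVEN"]
  expect_true(all(student_predict(st, setting$corpus$text[abstained]) %in%
                    setdiff(MARITAL_LEVELS, "NOT_GIVEN") |
                    "NOT_GIVEN" %in% st$classes))
})
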