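tokenize_text <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

ngram_terms <- function(tokens) {
  if (length(tokens) == 0) return(character(0))
  bi <- if (length(tokens) >= 2) {
    paste(tokens[-length(tokens)], tokens[-1])
  } else {
    character(0)
  }
  c(tokens, bi)
}

#' Build a term vocabulary from training texts
#'
#' Lowercase alphanumeric tokenization; unigrams plus adjacent bigrams. Terms
#' occurring fewer than `min_count` times in the whole collection are dropped.
#'
#' @param texts Character vector.
#' @param min_count Minimum total term frequency.
#' @return Sorted character vector of terms.
#' @export
build_vocabulary <- function(texts, min_count = 2) {
  terms <- unlist(lapply(tokenize_text(texts), ngram_terms))
  tab <- table(terms)
  sort(names(tab[tab >= min_count]))
}

#' Term-frequency featurization
#'
#' Maps texts to a sparse document-by-term count matrix over a fixed
#' vocabulary. Out-of-vocabulary terms are ignored, so unseen words at
#' inference time contribute nothing.
#'
#' @param texts Character vector.
#' @param vocab Character vector of terms (fixed at training time).
#' @return A `dgCMatrix` of dimension `length(texts)` x `length(vocab)`.
#' @export
featurize_text <- function(texts, vocab) {
  term_lists <- lapply(tokenize_text(texts), ngram_terms)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_along(term_lists)) {
    idx <- match(term_lists[[i]], vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) > 0) {
      tab <- table(idx)
      ii <- c(ii, rep.int(i, length(tab)))
      jj <- c(jj, as.integer(names(tab)))
      xx <- c(xx, as.numeric(tab))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(texts), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Apply an ensemble strategy to a vote table
#'
#' Thin dispatcher over the four aggregation rules so pipelines can be driven
#' by a strategy name.
#'
#' @param votes A [vote_records()] data.frame.
#' @param strategy One of `"unanimous"`, `"majority"`, `"precision"`, `"forest"`.
#' @param table [compute_precision_table()] result (for `"precision"`).
#' @param forest [train_forest()] model (for `"forest"`).
#' @return Character vector of labels.
#' @export
ensemble_label <- function(votes,
                           strategy = c("unanimous", "majority",
                                        "precision", "forest"),
                           table = NULL, forest = NULL) {
  strategy <- match.arg(strategy)
  switch(strategy,
    unanimous = unanimous_vote(votes),
    majority = majority_vote(votes),
    precision = {
      if (is.null(table)) stop("precision strategy needs a precision table",
                               call. = FALSE)
      precision_select(votes, table)
    },
    forest = {
      if (is.null(forest)) stop("forest strategy needs a trained forest",
                                call. = FALSE)
      forest_predict(forest, votes)
    }
  )
}

#' Pseudo-label a corpus with an ensemble teacher
#'
#' Produces one pseudo-label per note from the given strategy. For the
#' abstaining strategies (`unanimous`, `majority`) a `NOT_GIVEN` output is a
#' "no decision", not a prediction, so those records are dropped from the
#' training pool; for `precision` and `forest` a `NOT_GIVEN` output is a
#' genuine prediction and is kept as a class. Set `include_abstained = TRUE`
#' to keep abstentions regardless.
#'
#' @inheritParams ensemble_label
#' @param corpus Corpus data.frame with `note_id` and `text`, aligned with
#'   `votes` by `note_id`.
#' @param include_abstained Keep abstention-derived `NOT_GIVEN` records.
#' @return A data.frame with `note_id`, `text`, `pseudo_label`,
#'   `source_ensemble`; attributes `n_kept` and `n_dropped`.
#' @export
pseudo_label <- function(corpus, votes, strategy, table = NULL, forest = NULL,
                         include_abstained = FALSE) {
  stopifnot(all(votes$note_id %in% corpus$note_id))
  labels <- ensemble_label(votes, strategy, table = table, forest = forest)
  texts <- corpus$text[match(votes$note_id, corpus$note_id)]
  pool <- data.frame(note_id = votes$note_id, text = texts,
                     pseudo_label = labels,
                     source_ensemble = strategy, stringsAsFactors = FALSE)
  abstaining <- strategy %in% c("unanimous", "majority")
  if (abstaining && !include_abstained) {
    keep <- pool$pseudo_label != "NOT_GIVEN"
    dropped <- sum(!keep)
    pool <- pool[keep, , drop = FALSE]
  } else {
    dropped <- 0L
  }
  rownames(pool) <- NULL
  attr(pool, "n_kept") <- nrow(pool)
  attr(pool, "n_dropped") <- dropped
  pool
}

#' Train a student text classifier on pseudo-labels
#'
#' Fits an L2-penalized multinomial logistic model on bag-of-ngrams term
#' frequencies (ridge, single fixed penalty, deterministic fit). This is the
#' recall-raising step: the student never abstains, so it assigns definite
#' labels to the notes on which the teacher abstained.
#'
#' @param pool A [pseudo_label()] pool (columns `text`, `pseudo_label`).
#' @param l2 Ridge penalty (glmnet `lambda`).
#' @param min_count Vocabulary frequency cutoff.
#' @param seed Integer seed (recorded; the fit itself is deterministic).
#' @return An object of class `student_model`.
#' @export
train_student <- function(pool, l2 = 1e-3, min_count = 2, seed = 1L) {
  if (nrow(pool) == 0) stop("empty pseudo-label pool", call. = FALSE)
  # a class needs at least 2 examples to estimate its weights; rarer
  # pseudo-labels are set aside
  tab <- table(pool$pseudo_label)
  rare <- names(tab)[tab < 2]
  if (length(rare) > 0) {
    pool <- pool[!pool$pseudo_label %in% rare, , drop = FALSE]
  }
  if (nrow(pool) == 0) stop("empty pseudo-label pool", call. = FALSE)
  classes <- MARITAL_LEVELS[MARITAL_LEVELS %in% unique(pool$pseudo_label)]
  vocab <- build_vocabulary(pool$text, min_count = min_count)
  if (length(classes) < 2) {
    warning("single-class pool: returning a constant predictor", call. = FALSE)
    return(structure(
      list(constant = classes, classes = classes, vocab = vocab,
           weights = NULL, bias = NULL,
           hyperparams = list(l2 = l2, min_count = min_count, seed = seed)),
      class = "student_model"
    ))
  }
  x <- featurize_text(pool$text, vocab)
  y <- factor(pool$pseudo_label, levels = classes)
  # warm-started path down to the target penalty; fitting the single small
  # lambda directly is numerically unstable in coordinate descent
  lambda_path <- l2 * 10^seq(3, 0, length.out = 30)
  # glmnet warns about classes with < 8 examples; small pseudo-label classes
  # are inherent to weak supervision, so that note is muffled
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                   lambda = lambda_path, standardize = FALSE,
                   thresh = 1e-8, maxit = 1e6),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- glmnet::coef.glmnet(fit, s = l2)
  weights <- do.call(cbind, lapply(classes, function(cl) {
    as.numeric(co[[cl]])[-1]
  }))
  colnames(weights) <- classes
  bias <- vapply(classes, function(cl) as.numeric(co[[cl]])[1], numeric(1))
  structure(
    list(constant = NULL, classes = classes, vocab = vocab,
         weights = weights, bias = bias,
         hyperparams = list(l2 = l2, min_count = min_count, seed = seed)),
    class = "student_model"
  )
}

#' Predict marital labels with a student model
#'
#' Argmax of the linear class scores; ties broken by the fixed class order of
#' [MARITAL_LEVELS]. An empty or fully out-of-vocabulary text falls back to
#' the class with the largest bias (the training prior). Never abstains unless
#' `NOT_GIVEN` was a trained class.
#'
#' @param model A [train_student()] model.
#' @param texts Character vector.
#' @return Character vector of labels.
#' @export
student_predict <- function(model, texts) {
  stopifnot(inherits(model, "student_model"))
  if (!is.null(model$constant)) return(rep(model$constant, length(texts)))
  x <- featurize_text(texts, model$vocab)
  scores <- as.matrix(x %*% model$weights)
  scores <- sweep(scores, 2, model$bias, "+")
  model$classes[apply(scores, 1, which.max)]
}

#' Serialize / deserialize a student model as JSON
#'
#' Numbers are written at full precision so the model round-trips exactly.
#'
#' @param model A `student_model`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @export
student_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "student_model"))
  payload <- list(
    constant = model$constant, classes = model$classes, vocab = model$vocab,
    weights = if (is.null(model$weights)) NULL else unname(model$weights),
    bias = if (is.null(model$bias)) NULL else unname(as.numeric(model$bias)),
    hyperparams = model$hyperparams
  )
  js <- jsonlite::toJSON(payload, digits = I(17), null = "null",
                         auto_unbox = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname student_to_json
#' @param json JSON string or file path produced by [student_to_json()].
#' @export
student_from_json <- function(json) {
  src <- if (file.exists(json)) paste(readLines(json, warn = FALSE),
                                      collapse = "") else json
  p <- jsonlite::fromJSON(src)
  weights <- if (is.null(p$weights)) NULL else {
    m <- as.matrix(p$weights)
    colnames(m) <- p$classes
    m
  }
  bias <- if (is.null(p$bias)) NULL else stats::setNames(as.numeric(p$bias),
                                                         p$classes)
  structure(
    list(constant = if (length(p$constant) == 0) NULL else p$constant,
         classes = as.character(p$classes), vocab = as.character(p$vocab),
         weights = weights, bias = bias,
         hyperparams = as.list(p$hyperparams)),
    class = "student_model"
  )
}
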