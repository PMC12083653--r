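#' Assemble a vote table from three annotators
#'
#' A vote record holds the 5 labels the aggregation rules consume: 3 marital
#' votes (structured field, model A, model B) and the 2 living-arrangement
#' votes of the text models.
#'
#' @param note_id Identifiers.
#' @param structured,model_a,model_b Marital labels per annotator.
#' @param living_a,living_b Living labels of the two text models.
#' @return A data.frame of class `vote_record`.
#' @export
vote_records <- function(note_id, structured, model_a, model_b,
                         living_a, living_b) {
  assert_marital(structured); assert_marital(model_a); assert_marital(model_b)
  assert_living(living_a); assert_living(living_b)
  n <- length(note_id)
  stopifnot(length(structured) == n, length(model_a) == n,
            length(model_b) == n, length(living_a) == n, length(living_b) == n)
  out <- data.frame(note_id = note_id, structured = structured,
                    model_a = model_a, model_b = model_b,
                    living_a = living_a, living_b = living_b,
                    stringsAsFactors = FALSE)
  class(out) <- c("vote_record", "data.frame")
  out
}

vote_columns <- c("structured", "model_a", "model_b")

#' Unanimous-vote ensemble
#'
#' Returns the common label when all three marital votes agree; otherwise the
#' abstention label `NOT_GIVEN`.
#'
#' @param votes A [vote_records()] data.frame.
#' @return Character vector of labels.
#' @export
unanimous_vote <- function(votes) {
  ifelse(votes$structured == votes$model_a & votes$model_a == votes$model_b,
         votes$structured, "NOT_GIVEN")
}

#' Majority-vote ensemble
#'
#' Returns any label held by at least two of the three marital votes;
#' `NOT_GIVEN` when all three differ. `NOT_GIVEN` counts as an ordinary vote
#' value, so two `NOT_GIVEN` votes yield a `NOT_GIVEN` majority.
#'
#' @inheritParams unanimous_vote
#' @return Character vector of labels.
#' @export
majority_vote <- function(votes) {
  a <- votes$model_a; b <- votes$model_b; s <- votes$structured
  ifelse(a == b, a, ifelse(s == a, a, ifelse(s == b, b, "NOT_GIVEN")))
}

#' Per-annotator, per-class precision on a tuning split
#'
#' Precision(annotator, class) = correct predictions of the class / all
#' predictions of the class. Cells in which the annotator never predicts the
#' class are undefined; they are stored as 0 with `defined = FALSE` so they can
#' never win the precision-based selection.
#'
#' @param predictions Named list of per-annotator label vectors, aligned with
#'   `gold`.
#' @param gold Gold marital labels.
#' @return A data.frame of class `precision_table` with columns `annotator`,
#'   `class`, `precision`, `n_predicted`, `defined`.
#' @export
compute_precision_table <- function(predictions, gold) {
  stopifnot(is.list(predictions), length(predictions) > 0, length(gold) > 0)
  for (p in predictions) {
    if (length(p) != length(gold)) {
      stop("predictions and gold must be aligned", call. = FALSE)
    }
  }
  rows <- lapply(names(predictions), function(a) {
    pred <- predictions[[a]]
    vapply(MARITAL_LEVELS, function(cl) {
      n_pred <- sum(pred == cl)
      prec <- if (n_pred == 0) 0 else sum(pred == cl & gold == cl) / n_pred
      c(precision = prec, n_predicted = n_pred)
    }, numeric(2))
  })
  out <- data.frame(
    annotator = rep(names(predictions), each = length(MARITAL_LEVELS)),
    class = rep(MARITAL_LEVELS, length(predictions)),
    precision = unlist(lapply(rows, function(m) m["precision", ])),
    n_predicted = unlist(lapply(rows, function(m) m["n_predicted", ])),
    stringsAsFactors = FALSE
  )
  out$defined <- out$n_predicted > 0
  rownames(out) <- NULL
  class(out) <- c("precision_table", "data.frame")
  out
}

#' Precision-based ensemble
#'
#' For each note, each annotator's predicted label is scored by that
#' annotator's tuning-set precision *for that label* and the label of the
#' highest-precision (annotator, label) pair wins. Undefined precision cells
#' score 0. Exact ties are broken by a fixed annotator priority.
#'
#' @param votes A [vote_records()] data.frame.
#' @param table A [compute_precision_table()] result computed on a disjoint
#'   tuning split, with annotators named `structured`, `model_a`, `model_b`.
#' @param priority Annotator priority for ties, best first.
#' @param mode `"per_class"` (default): the champion is chosen per (annotator,
#'   predicted label) cell. `"per_model"`: the single annotator with the
#'   highest overall (prediction-weighted) tuning precision supplies every
#'   label, which reduces the ensemble to one base model.
#' @return Character vector of labels.
#' @export
precision_select <- function(votes, table,
                             priority = c("model_a", "model_b", "structured"),
                             mode = c("per_class", "per_model")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "precision_table"),
            all(vote_columns %in% table$annotator),
            setequal(priority, vote_columns))
  if (mode == "per_model") {
    overall <- vapply(priority, function(a) {
      rows <- table[table$annotator == a, ]
      if (sum(rows$n_predicted) == 0) return(0)
      sum(rows$precision * rows$n_predicted) / sum(rows$n_predicted)
    }, numeric(1))
    return(votes[[priority[which.max(overall)]]])
  }
  lookup <- matrix(0, nrow = length(vote_columns), ncol = length(MARITAL_LEVELS),
                   dimnames = list(vote_columns, MARITAL_LEVELS))
  for (i in seq_len(nrow(table))) {
    if (table$annotator[i] %in% vote_columns) {
      lookup[table$annotator[i], table$class[i]] <- table$precision[i]
    }
  }
  # priority order: scan candidates best-priority-first, keep strict improvements
  vapply(seq_len(nrow(votes)), function(i) {
    best_lab <- "NOT_GIVEN"; best_p <- -Inf
    for (a in priority) {
      lab <- votes[[a]][i]
      p <- lookup[a, lab]
      if (p > best_p) { best_p <- p; best_lab <- lab }
    }
    best_lab
  }, character(1))
}

one_hot_votes <- function(votes) {
  blocks <- list()
  for (col in vote_columns) {
    f <- factor(votes[[col]], levels = MARITAL_LEVELS)
    m <- matrix(0L, length(f), length(MARITAL_LEVELS),
                dimnames = list(NULL, paste0(col, ".", MARITAL_LEVELS)))
    m[cbind(seq_along(f), as.integer(f))] <- 1L
    blocks[[col]] <- m
  }
  for (col in c("living_a", "living_b")) {
    f <- factor(votes[[col]], levels = LIVING_LEVELS)
    m <- matrix(0L, length(f), length(LIVING_LEVELS),
                dimnames = list(NULL, paste0(col, ".", LIVING_LEVELS)))
    m[cbind(seq_along(f), as.integer(f))] <- 1L
    blocks[[col]] <- m
  }
  do.call(cbind, blocks)
}

#' Random-forest meta-classifier over vote features
#'
#' Trains a bagged ensemble of randomized decision trees on one-of-K encodings
#' of the 5 categorical vote features (3 marital + 2 living votes), learning
#' which annotator to trust in which voting configuration. Training and
#' prediction are deterministic given the seed.
#'
#' @param votes Training [vote_records()].
#' @param gold Gold marital labels aligned with `votes`.
#' @param num_trees Number of trees.
#' @param max_depth Depth limit per tree.
#' @param seed Integer seed.
#' @return An object of class `forest_model`.
#' @export
train_forest <- function(votes, gold, num_trees = 200, max_depth = 8,
                         seed = 1L) {
  if (nrow(votes) == 0) stop("empty training set", call. = FALSE)
  assert_marital(gold)
  stopifnot(length(gold) == nrow(votes))
  classes <- MARITAL_LEVELS[MARITAL_LEVELS %in% unique(gold)]
  if (length(classes) == 1) {
    return(structure(list(constant = classes, classes = classes, fit = NULL),
                     class = "forest_model"))
  }
  x <- one_hot_votes(votes)
  y <- factor(gold, levels = classes)
  fit <- ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = num_trees, max.depth = max_depth,
    seed = seed, num.threads = 1
  )
  structure(list(constant = NULL, classes = classes, fit = fit,
                 feature_names = colnames(x)),
            class = "forest_model")
}

#' Predict with the forest meta-classifier
#'
#' Deterministic plurality over trees; ties are broken by the fixed class
#' order of [MARITAL_LEVELS]. Vote levels never seen in training are encoded
#' as all-zero blocks, not an error.
#'
#' @param model A [train_forest()] model.
#' @param votes New [vote_records()].
#' @return Character vector of labels.
#' @export
forest_predict <- function(model, votes) {
  stopifnot(inherits(model, "forest_model"))
  if (!is.null(model$constant)) {
    return(rep(model$constant, nrow(votes)))
  }
  x <- as.data.frame(one_hot_votes(votes))
  per_tree <- stats::predict(model$fit, data = x, predict.all = TRUE,
                             num.threads = 1)$predictions
  apply(per_tree, 1, function(r) {
    counts <- tabulate(r, nbins = length(model$classes))
    model$classes[which.max(counts)]
  })
}
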