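#' Experiment configuration
#'
#' Bundles every tunable the end-to-end pipeline needs. All per-stage seeds
#' are derived deterministically from the master seed via [module_seed()], so
#' a stage can be rerun in isolation with the stream it saw in the full run.
#'
#' @param master_seed Integer master seed.
#' @param n_notes Corpus size.
#' @param n_patients Cohort size.
#' @param tune_frac,test_frac Fractions of the corpus used as the annotated
#'   tuning and test splits; the remainder is the unlabeled pool that the
#'   ensembles pseudo-label.
#' @param model_a_accuracy,model_b_accuracy Per-class accuracy of the two
#'   simulated text extractors (noise applied on top of the pattern
#'   annotator's output).
#' @param dating_category If `TRUE` (stage 2) partnered calls without
#'   cohabitation are recoded to `DATING`; if `FALSE` (stage 1) they are
#'   treated as `SINGLE`.
#' @param strategies Ensemble strategies to run.
#' @param student_l2,student_min_count Student hyperparameters.
#' @param corpus Optional [corpus_spec()] override.
#' @param cohort Optional [cohort_spec()] override.
#' @param reference_group Static group whose mean age anchors the age
#'   matching.
#' @param age_tolerance_years Age-matching tolerance.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(master_seed = 1L,
                              n_notes = 5000,
                              n_patients = 5000,
                              tune_frac = 0.1,
                              test_frac = 0.1,
                              model_a_accuracy = 0.85,
                              model_b_accuracy = 0.75,
                              dating_category = TRUE,
                              strategies = c("unanimous", "majority",
                                             "precision", "forest"),
                              student_l2 = 1e-3,
                              student_min_count = 2,
                              corpus = NULL,
                              cohort = NULL,
                              reference_group = "MARRIED",
                              age_tolerance_years = 1) {
  stopifnot(tune_frac > 0, test_frac > 0, tune_frac + test_frac < 1)
  cfg <- list(
    master_seed = as.integer(master_seed), n_notes = n_notes,
    n_patients = n_patients, tune_frac = tune_frac, test_frac = test_frac,
    model_a_accuracy = model_a_accuracy, model_b_accuracy = model_b_accuracy,
    dating_category = dating_category, strategies = strategies,
    student_l2 = student_l2, student_min_count = student_min_count,
    corpus = corpus, cohort = cohort,
    reference_group = reference_group,
    age_tolerance_years = age_tolerance_years
  )
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [experiment_config()] defaults.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(experiment_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0) {
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  do.call(experiment_config, raw)
}

#' Annotate a corpus with the three weak label sources
#'
#' Runs the structured-field annotator and two noisy text extractors (the
#' pattern annotator degraded by per-model confusion noise), then applies the
#' partnered harmonization: stage 1 demotes non-cohabiting partnered calls to
#' `SINGLE`, stage 2 recodes them to `DATING`. Harmonization applies to the
#' text models only; the structured field never emits a bare partnered call
#' that needs demoting.
#'
#' @param corpus Corpus data.frame.
#' @param config An [experiment_config()].
#' @return A [vote_records()] data.frame plus a `gold` attribute holding the
#'   harmonized gold labels on the same stage-1/stage-2 convention.
#' @export
annotate_corpus <- function(corpus, config) {
  structured <- structured_annotate(corpus$structured_status)
  base <- pattern_annotate(corpus$text)
  conf_a <- uniform_confusion_spec(config$model_a_accuracy,
                                   seed = module_seed(config$master_seed,
                                                      "model_a"))
  conf_b <- uniform_confusion_spec(config$model_b_accuracy,
                                   seed = module_seed(config$master_seed,
                                                      "model_b"))
  recode <- if (config$dating_category) derive_dating else recode_partnered
  model_a <- recode(simulate_annotator(base$marital, conf_a), base$cohab)
  model_b <- recode(simulate_annotator(base$marital, conf_b), base$cohab)
  votes <- vote_records(
    note_id = corpus$note_id,
    structured = structured$marital,
    model_a = model_a, model_b = model_b,
    living_a = base$living, living_b = base$living
  )
  gold <- corpus$gold_status
  if (!config$dating_category) gold[gold == "DATING"] <- "SINGLE"
  attr(votes, "gold") <- gold
  votes
}

split_corpus <- function(n, tune_frac, test_frac, seed) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  idx <- sample.int(n)
  n_tune <- max(1, round(tune_frac * n))
  n_test <- max(1, round(test_frac * n))
  list(
    tune = sort(idx[seq_len(n_tune)]),
    test = sort(idx[n_tune + seq_len(n_test)]),
    pool = sort(idx[-(seq_len(n_tune + n_test))])
  )
}

hash_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full experiment pipeline
#'
#' Executes: synthetic corpus generation, annotation by the three weak label
#' sources, the four ensemble strategies (precision table and forest fitted on
#' the tuning split), pseudo-labeling of the unannotated pool and student
#' training per strategy, evaluation of all label sources on the held-out test
#' split, synthetic cohort generation, eligibility filtering, change
#' classification, age-matched downsampling, and the outcome statistics
#' (prevalence, new-diagnosis and recovery rates with exact binomial CIs, and
#' comorbidity rank-sum comparisons with Holm adjustment). Writes every
#' artifact plus a manifest to `out_dir`; rerunning with an identical config
#' produces byte-identical artifacts and manifest.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results: `corpus`, `votes`,
#'   `splits`, `labels` (per label source, on the test split), `report`
#'   (evaluation rows), `outcomes`, `manifest`.
#' @export
run_experiment <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  counts <- list()

  # --- corpus + annotation -------------------------------------------------
  cspec <- config$corpus
  if (is.null(cspec)) {
    cspec <- corpus_spec(n_notes = config$n_notes,
                         seed = module_seed(config$master_seed, "synthgen"))
  }
  corpus <- generate_corpus(cspec)
  counts$notes <- nrow(corpus)
  say("stage synthgen: %d notes", nrow(corpus))

  votes <- annotate_corpus(corpus, config)
  gold <- attr(votes, "gold")
  splits <- split_corpus(nrow(corpus), config$tune_frac, config$test_frac,
                         module_seed(config$master_seed, "split"))
  counts$tune <- length(splits$tune)
  counts$test <- length(splits$test)
  counts$pool <- length(splits$pool)
  say("stage annotate: tune %d / test %d / pool %d",
      counts$tune, counts$test, counts$pool)

  # --- ensembles -----------------------------------------------------------
  tune_votes <- votes[splits$tune, , drop = FALSE]
  ptable <- compute_precision_table(
    list(structured = tune_votes$structured, model_a = tune_votes$model_a,
         model_b = tune_votes$model_b),
    gold[splits$tune]
  )
  forest <- train_forest(tune_votes, gold[splits$tune],
                         seed = module_seed(config$master_seed, "forest"))

  test_votes <- votes[splits$test, , drop = FALSE]
  test_gold <- gold[splits$test]
  labels <- list(
    structured = test_votes$structured,
    model_a = test_votes$model_a,
    model_b = test_votes$model_b
  )
  for (s in config$strategies) {
    labels[[paste0("ensemble_", s)]] <-
      ensemble_label(test_votes, s, table = ptable, forest = forest)
  }

  # --- weak supervision ----------------------------------------------------
  pool_votes <- votes[splits$pool, , drop = FALSE]
  students <- list()
  for (s in config$strategies) {
    pool <- pseudo_label(corpus, pool_votes, s, table = ptable,
                         forest = forest)
    counts[[paste0("pool_", s)]] <- nrow(pool)
    if (nrow(pool) == 0 || length(unique(pool$pseudo_label)) < 2) {
      say("stage weaklabel[%s]: pool too small or degenerate, skipping student", s)
      next
    }
    student <- train_student(pool, l2 = config$student_l2,
                             min_count = config$student_min_count,
                             seed = module_seed(config$master_seed,
                                                paste0("student_", s)))
    students[[s]] <- student
    labels[[paste0("student_", s)]] <-
      student_predict(student, corpus$text[splits$test])
    say("stage weaklabel[%s]: %d pseudo-labels kept", s, nrow(pool))
  }

  # --- evaluation ----------------------------------------------------------
  classes <- MARITAL_LEVELS[MARITAL_LEVELS %in%
                              unique(c(test_gold, unlist(labels)))]
  report <- do.call(rbind, lapply(names(labels), function(src) {
    ev <- evaluate_labels(test_gold, labels[[src]], classes = classes)
    data.frame(source = src,
               macro_precision = ev$macro_precision,
               macro_recall = ev$macro_recall, macro_f1 = ev$macro_f1,
               weighted_precision = ev$weighted_precision,
               weighted_recall = ev$weighted_recall,
               weighted_f1 = ev$weighted_f1,
               accuracy = ev$accuracy, stringsAsFactors = FALSE)
  }))
  counts$report_rows <- nrow(report)
  say("stage evaluate: %d label sources", nrow(report))

  # --- cohort outcomes -----------------------------------------------------
  kspec <- config$cohort
  if (is.null(kspec)) {
    kspec <- cohort_spec(n_patients = config$n_patients,
                         seed = module_seed(config$master_seed, "cohort"))
  }
  cohort <- generate_cohort(kspec)
  eligible <- select_eligible(cohort)
  changes <- classify_change(eligible)
  counts$patients <- length(unique(cohort$patient_id))
  counts$eligible <- length(unique(eligible$patient_id))
  counts$excluded_no_definite <- sum(is.na(changes$change_class))
  say("stage cohort: %d patients, %d eligible, %d excluded (no definite labels)",
      counts$patients, counts$eligible, counts$excluded_no_definite)

  changes_ok <- changes[!is.na(changes$change_class), , drop = FALSE]
  fa <- first_admission(eligible)
  patients <- data.frame(
    patient_id = changes_ok$patient_id,
    group = changes_ok$first_status,
    change_class = changes_ok$change_class,
    age = fa$age_at_first[match(changes_ok$patient_id, fa$patient_id)],
    evw_score = fa$evw_score[match(changes_ok$patient_id, fa$patient_id)],
    stringsAsFactors = FALSE
  )

  static_groups <- tryCatch(
    downsample_age_match(patients, config$reference_group,
                         tolerance_years = config$age_tolerance_years,
                         seed = module_seed(config$master_seed, "agematch")),
    error = function(e) {
      say("stage agematch: %s (using unmatched groups)", conditionMessage(e))
      patients
    }
  )

  static_tbl <- list()
  for (g in sort(unique(static_groups$group))) {
    ids <- static_groups$patient_id[static_groups$group == g]
    sub <- eligible[eligible$patient_id %in% ids, , drop = FALSE]
    static_tbl[[g]] <- c(
      list(n = length(ids),
           mean_age = mean(static_groups$age[static_groups$group == g])),
      stats::setNames(lapply(CONDITIONS, function(cond) {
        unclass(prevalence(sub, cond))
      }), CONDITIONS)
    )
  }

  dynamic_tbl <- list()
  for (g in c(CHANGE_LEVELS, "CHANGE")) {
    ids <- if (g == "CHANGE") {
      patients$patient_id[patients$change_class != "SAME"]
    } else {
      patients$patient_id[patients$change_class == g]
    }
    if (length(ids) == 0) next
    sub <- eligible[eligible$patient_id %in% ids, , drop = FALSE]
    dynamic_tbl[[g]] <- c(
      list(n = length(ids)),
      stats::setNames(lapply(CONDITIONS, function(cond) {
        tr <- transition_rates(sub, cond)
        list(new_diagnosis = unclass(tr$new_diagnosis),
             recovery = unclass(tr$recovery))
      }), CONDITIONS)
    )
  }

  ref_scores <- patients$evw_score[patients$group == config$reference_group]
  other_groups <- setdiff(sort(unique(patients$group)), config$reference_group)
  evw_raw <- vapply(other_groups, function(g) {
    rank_sum_compare(patients$evw_score[patients$group == g], ref_scores)$p_value
  }, numeric(1))
  evw <- list(
    reference = config$reference_group,
    comparisons = other_groups,
    median_reference = stats::median(ref_scores),
    medians = vapply(other_groups, function(g) {
      stats::median(patients$evw_score[patients$group == g])
    }, numeric(1)),
    p_raw = evw_raw,
    p_holm = holm_adjust(evw_raw)
  )
  outcomes <- list(static = static_tbl, dynamic = dynamic_tbl,
                   evw_rank_tests = evw)

  # --- artifacts + manifest ------------------------------------------------
  paths <- list(
    corpus = file.path(out_dir, "corpus.jsonl"),
    votes = file.path(out_dir, "votes.csv"),
    cohort = file.path(out_dir, "cohort.csv"),
    report = file.path(out_dir, "report.json"),
    outcomes = file.path(out_dir, "outcomes.json")
  )
  write_corpus_jsonl(corpus, paths$corpus)
  utils::write.csv(as.data.frame(votes), paths$votes, row.names = FALSE)
  write_cohort_csv(cohort, paths$cohort)
  jsonlite::write_json(report, paths$report, dataframe = "rows", digits = NA)
  jsonlite::write_json(outcomes, paths$outcomes, auto_unbox = TRUE,
                       digits = NA)
  for (s in names(labels)) {
    p <- file.path(out_dir, sprintf("labels_%s.csv", s))
    utils::write.csv(
      data.frame(note_id = test_votes$note_id, label = labels[[s]],
                 stringsAsFactors = FALSE),
      p, row.names = FALSE)
    paths[[paste0("labels_", s)]] <- p
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("maritalens")),
    config_hash = hash_object(unclass(config)),
    master_seed = config$master_seed,
    counts = counts,
    artifacts = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(corpus = corpus, votes = votes, splits = splits,
                 precision_table = ptable, forest = forest,
                 students = students, labels = labels, report = report,
                 outcomes = outcomes, manifest = manifest))
}
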