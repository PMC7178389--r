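# Task protocols: multi-label gene-ontology-style prediction with a
# term-frequency filter, and per-dataset binary homology detection with
# cluster-based validation splits and validation-AUC model selection.

#' Filter a multi-label term space by training-set frequency
#'
#' Keeps only terms annotated at least `min_term_count` times in the
#' training partition (counts from the training partition only).
#'
#' @param labels 0/1 (or logical) matrix, records x terms, with term
#'   column names.
#' @param train_idx row indices of the training partition.
#' @param min_term_count minimum number of training occurrences (50 in
#'   the canonical protocol).
#' @return character vector of surviving term names; attribute `counts`
#'   holds the full training-count table.
#' @export
filter_terms <- function(labels, train_idx, min_term_count = 50) {
  counts <- colSums(labels[train_idx, , drop = FALSE] != 0)
  keep <- names(counts)[counts >= min_term_count]
  if (length(keep) == 0) {
    msg <- paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")
    stop("no terms survive the frequency filter (training counts: ", msg, ")")
  }
  structure(keep, counts = counts)
}

#' Combine model scores with external alignment-based scores
#'
#' Score-level ensembling with a fixed relative weight on the external
#' side: `(1 - weight) * model + weight * external`. The external scores
#' (e.g. from an alignment-based k-nearest-neighbour method) are consumed
#' as given, never computed here.
#'
#' @param model_scores,external_scores numeric matrices of identical
#'   shape.
#' @param weight relative weight of the external scores in [0, 1].
#' @export
combine_scores <- function(model_scores, external_scores, weight) {
  stopifnot(identical(dim(model_scores), dim(external_scores)),
            weight >= 0, weight <= 1)
  (1 - weight) * model_scores + weight * external_scores
}

#' Run the multi-label (gene-ontology-style) task
#'
#' Filters the term space on training counts, fine-tunes a multi-label
#' classifier (binary cross-entropy, flat output layer), optionally
#' combines its scores with externally supplied alignment scores, and
#' reports Fmax, Smin and AUPR on the test partition.
#'
#' @param task list with `records` (data.frame: `id`, `sequence`) and
#'   `labels` (0/1 matrix with term column names), e.g. from
#'   [generate_multilabel_task()].
#' @param lm pre-trained `aa_lm` (or an untrained one for from-scratch).
#' @param split list with integer row indices `train`, `valid`, `test`.
#' @param min_term_count term-frequency threshold (default 50).
#' @param config optional [classifier_config()]; defaults to
#'   [go_classifier_config()] for the filtered term count.
#' @param schedule optional [unfreeze_schedule()].
#' @param external_scores optional matrix (test records x terms).
#' @param external_weight relative weight of the external scores.
#' @param seed integer seed.
#' @return list with `terms`, `clf`, `scores` (test-set term scores),
#'   `report` (fmax, smin, aupr).
#' @export
run_go_task <- function(task, lm, split, min_term_count = 50,
                        config = NULL, schedule = NULL,
                        external_scores = NULL, external_weight = 0.5,
                        seed = 1L) {
  labels <- task$labels * 1
  terms <- filter_terms(labels, split$train, min_term_count)
  Y <- labels[, terms, drop = FALSE]
  if (is.null(config))
    config <- go_classifier_config(n_outputs = length(terms), seed = seed)
  if (config$loss != "binary") stop("the multi-label task requires binary loss")
  clf <- build_classifier(lm, config)
  tr <- list(sequences = task$records$sequence[split$train],
             y = Y[split$train, , drop = FALSE])
  va <- list(sequences = task$records$sequence[split$valid],
             y = Y[split$valid, , drop = FALSE])
  finetune(clf, tr, va, schedule = schedule, selection_metric = "loss",
           seed = seed)
  scores <- predict_proba(clf, task$records$sequence[split$test])
  attr(scores, "errors") <- NULL
  colnames(scores) <- as.character(terms)
  if (!is.null(external_scores))
    scores <- combine_scores(scores, external_scores[, terms, drop = FALSE],
                             external_weight)
  truth_sets <- apply(Y[split$test, , drop = FALSE], 1,
                      function(r) terms[r != 0], simplify = FALSE)
  score_table <- apply(scores, 1, function(r) r, simplify = FALSE)
  ic <- information_content(Y[split$train, , drop = FALSE])
  report <- list(
    fmax = fmax_score(truth_sets, score_table)$fmax,
    smin = smin_score(truth_sets, score_table, ic)$smin,
    aupr = aupr_score(as.vector(Y[split$test, , drop = FALSE] != 0),
                      as.vector(scores)))
  list(terms = terms, clf = clf, scores = scores, report = report)
}

#' Run the per-dataset binary detection task
#'
#' Applies one shared hyperparameter set to every dataset: each dataset's
#' training sequences are split into training and validation partitions by
#' cluster, a binary classifier is fine-tuned with per-epoch model
#' selection on validation AUC (ties resolved toward the earliest epoch),
#' and the test AUC and AUC50 are reported per dataset together with
#' their means. Datasets whose training labels contain a single class are
#' skipped with a warning and excluded from the means.
#'
#' @param datasets list as produced by [generate_detection_benchmark()]:
#'   each element has `train`, `test` (data.frames: `id`, `sequence`,
#'   `label`) and `clusters`.
#' @param lm pre-trained `aa_lm`.
#' @param config a [classifier_config()] shared by all datasets
#'   (binary loss, 1 output).
#' @param schedule optional shared [unfreeze_schedule()].
#' @param valid_ratio fraction of training clusters held out for
#'   validation.
#' @param seed integer seed.
#' @return list with `per_dataset` (data.frame: dataset, auc, auc50),
#'   `mean_auc`, `mean_auc50`, `models`.
#' @export
run_detection_task <- function(datasets, lm, config = NULL, schedule = NULL,
                               valid_ratio = 0.25, seed = 1L) {
  if (is.null(config))
    config <- classifier_config(n_outputs = 1, loss = "binary", seed = seed)
  rows <- list(); models <- list()
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    if (length(unique(ds$train$label)) < 2) {
      warning(sprintf("dataset %d skipped: single-class training labels", d))
      next
    }
    sp <- make_split(ds$clusters, c(1 - valid_ratio, valid_ratio, 0),
                     mode = "cluster", seed = derive_seed(seed, paste0("ds", d)))
    tr_ids <- c(sp$train); va_ids <- c(sp$valid)
    # guard: validation must contain both classes for AUC selection
    lab_of <- stats::setNames(ds$train$label, ds$train$id)
    if (length(unique(lab_of[va_ids])) < 2) {
      move <- names(lab_of)[lab_of != lab_of[va_ids][1]][1]
      va_ids <- c(va_ids, move); tr_ids <- setdiff(tr_ids, move)
    }
    seq_of <- stats::setNames(ds$train$sequence, ds$train$id)
    clf <- build_classifier(lm, config)
    finetune(clf,
             list(sequences = unname(seq_of[tr_ids]),
                  y = matrix(lab_of[tr_ids], ncol = 1)),
             list(sequences = unname(seq_of[va_ids]),
                  y = matrix(lab_of[va_ids], ncol = 1)),
             schedule = schedule, selection_metric = "auc",
             seed = derive_seed(seed, paste0("ft", d)))
    sc <- predict_proba(clf, ds$test$sequence)[, 1]
    rows[[length(rows) + 1]] <-
      data.frame(dataset = d, auc = auc_score(ds$test$label, sc),
                 auc50 = auc50_score(ds$test$label, sc))
    models[[length(models) + 1]] <- clf
  }
  if (!length(rows)) stop("no dataset had both classes in training")
  per <- do.call(rbind, rows)
  list(per_dataset = per, mean_auc = mean(per$auc),
       mean_auc50 = mean(per$auc50), models = models)
}
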