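# Evaluation metrics: accuracy, macro-averaged F1, protein-centric Fmax,
# Smin with information-content weighting, AUPR, AUC and AUC50.

#' Classification accuracy
#' @param truth,pred equal-length vectors of class labels.
#' @return fraction of positions where `pred == truth`.
#' @export
accuracy_score <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) == 0) stop("empty input")
  mean(truth == pred)
}

#' Unweighted mean of per-class F1 scores
#'
#' One-vs-rest F1 per class over the classes present in the ground truth,
#' averaged without weighting. A class with no predictions and no true
#' positives scores 0.
#'
#' @inheritParams accuracy_score
#' @export
mean_f1 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) == 0) stop("empty input")
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Information content of annotation terms
#'
#' `ic(term) = -log2(n_term / N)` estimated from the training-partition
#' annotations only. Terms never seen in training are assigned the maximum
#' observed information content when queried (documented fallback).
#'
#' @param annotations logical/0-1 matrix, proteins x terms, of
#'   training-set annotations (with term column names).
#' @param base logarithm base (2 for bits, the default).
#' @return named numeric vector of class `ic_table` (attribute
#'   `max_ic` carries the fallback value).
#' @export
information_content <- function(annotations, base = 2) {
  if (is.null(dim(annotations)) || nrow(annotations) == 0)
    stop("empty annotation table")
  n <- colSums(annotations != 0)
  N <- nrow(annotations)
  ic <- ifelse(n > 0, -log(n / N, base = base), NA_real_)
  max_ic <- if (all(is.na(ic))) 0 else max(ic, na.rm = TRUE)
  ic[is.na(ic)] <- max_ic
  structure(stats::setNames(ic, colnames(annotations)),
            max_ic = max_ic, class = "ic_table")
}

ic_lookup <- function(ic, terms) {
  v <- unclass(ic)[terms]
  v[is.na(v)] <- attr(ic, "max_ic")
  v
}

#' Protein-centric maximum F-measure (Fmax)
#'
#' For each threshold `t` on a grid over [0, 1], a protein's predicted term
#' set is every term scored `>= t`. Precision at `t` is averaged over
#' proteins with at least one predicted term; recall is averaged over all
#' proteins with at least one ground-truth term. Fmax is the maximum over
#' the grid of the harmonic mean of the two.
#'
#' @param truth_sets list of character vectors: true terms per protein.
#' @param score_table list of named numeric vectors: term scores in [0, 1]
#'   per protein (may omit unscored terms, treated as score 0).
#' @param grid_step threshold grid resolution (default 0.01).
#' @return list with `fmax`, `threshold` (argmax) and `curve` (data.frame:
#'   threshold, precision, recall).
#' @export
fmax_score <- function(truth_sets, score_table, grid_step = 0.01) {
  stopifnot(length(truth_sets) == length(score_table))
  has_truth <- lengths(truth_sets) > 0
  if (!any(has_truth)) stop("no protein has any ground-truth term")
  n_steps <- max(1L, round(1 / grid_step))
  thresholds <- (0:n_steps) / n_steps   # correctly rounded grid points
  n_prot <- length(truth_sets)
  pr <- rc <- numeric(length(thresholds))
  for (ti in seq_along(thresholds)) {
    t <- thresholds[ti]
    precs <- c(); recs <- c()
    for (i in seq_len(n_prot)) {
      pred <- names(score_table[[i]])[score_table[[i]] >= t]
      if (length(pred) > 0)
        precs <- c(precs, length(intersect(pred, truth_sets[[i]])) / length(pred))
      if (has_truth[i])
        recs <- c(recs, length(intersect(pred, truth_sets[[i]])) /
                    length(truth_sets[[i]]))
    }
    pr[ti] <- if (length(precs)) mean(precs) else NA_real_
    rc[ti] <- mean(recs)
  }
  f <- ifelse(!is.na(pr) & (pr + rc) > 0, 2 * pr * rc / (pr + rc), 0)
  f[is.na(f)] <- 0
  best <- which.max(f)
  list(fmax = f[best], threshold = thresholds[best],
       curve = data.frame(threshold = thresholds, precision = pr, recall = rc))
}

#' Minimum semantic distance (Smin)
#'
#' At each threshold, remaining uncertainty `ru` is the mean (over proteins
#' with ground-truth terms) of the summed information content of false
#' negatives, and misinformation `mi` the mean summed information content
#' of false positives. `Smin = min_t sqrt(ru(t)^2 + mi(t)^2)`.
#'
#' @inheritParams fmax_score
#' @param ic an [information_content()] table covering all true terms.
#' @return list with `smin`, `threshold` and `curve` (threshold, ru, mi).
#' @export
smin_score <- function(truth_sets, score_table, ic, grid_step = 0.01) {
  stopifnot(length(truth_sets) == length(score_table))
  has_truth <- lengths(truth_sets) > 0
  if (!any(has_truth)) stop("no protein has any ground-truth term")
  missing_ic <- setdiff(unique(unlist(truth_sets)), names(unclass(ic)))
  if (length(missing_ic) && is.null(attr(ic, "max_ic")))
    stop("information content missing for term ", missing_ic[1])
  n_steps <- max(1L, round(1 / grid_step))
  thresholds <- (0:n_steps) / n_steps
  idx <- which(has_truth)
  ru <- mi <- numeric(length(thresholds))
  for (ti in seq_along(thresholds)) {
    t <- thresholds[ti]
    ru_i <- mi_i <- numeric(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      pred <- names(score_table[[i]])[score_table[[i]] >= t]
      fn <- setdiff(truth_sets[[i]], pred)
      fp <- setdiff(pred, truth_sets[[i]])
      ru_i[k] <- sum(ic_lookup(ic, fn))
      mi_i[k] <- sum(ic_lookup(ic, fp))
    }
    ru[ti] <- mean(ru_i); mi[ti] <- mean(mi_i)
  }
  s <- sqrt(ru^2 + mi^2)
  best <- which.min(s)
  list(smin = s[best], threshold = thresholds[best],
       curve = data.frame(threshold = thresholds, ru = ru, mi = mi))
}

#' Area under the ROC curve
#'
#' Probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, with ties counted one half (the rank-statistic
#' definition).
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores numeric scores, higher = more positive.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration of precision over recall at every distinct
#' score threshold (descending), starting from recall 0.
#'
#' @inheritParams auc_score
#' @export
aupr_score <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("AUPR requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  keep <- c(diff(sc) != 0, TRUE)         # last index of each tie group
  tp <- cumsum(lab)[keep]
  fp <- cumsum(1 - lab)[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  prec <- c(1, prec); rec <- c(0, rec)   # anchor at recall 0
  sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
}

#' Truncated ROC area up to the first 50 false positives (AUC50)
#'
#' Instances are ranked by score (descending, stable). With `K =
#' min(fp_cap, N_neg)`, `AUC50 = (1 / (K * N_pos)) * sum over the first K
#' negatives of the number of positives ranked above that negative`;
#' positives tied with a negative count one half. Equals the standard AUC
#' whenever `N_neg <= fp_cap`.
#'
#' @inheritParams auc_score
#' @param fp_cap false-positive cap (default 50).
#' @export
auc50_score <- function(labels, scores, fp_cap = 50) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC50 requires both classes to be present")
  K <- min(fp_cap, n_neg)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  neg_idx <- which(lab == 0)[seq_len(K)]
  total <- 0
  for (j in neg_idx) {
    s <- sc[j]
    above <- sum(lab == 1 & sc > s)
    tied <- sum(lab == 1 & sc == s)
    total <- total + above + tied / 2
  }
  total / (K * n_pos)
}
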