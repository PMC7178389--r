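# Each ranking/threshold metric is checked against an independent
# brute-force oracle on randomly generated small instances.

# --- oracles -----------------------------------------------------------

oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

oracle_fmax <- function(truth_sets, score_table) {
  cand <- sort(unique(c(0, 1, unlist(score_table))))
  best <- 0
  for (t in cand) {
    precs <- c(); recs <- c()
    for (i in seq_along(truth_sets)) {
      pred <- names(score_table[[i]])[score_table[[i]] >= t]
      if (length(pred)) precs <- c(precs, length(intersect(pred, truth_sets[[i]])) / length(pred))
      if (length(truth_sets[[i]]))
        recs <- c(recs, length(intersect(pred, truth_sets[[i]])) / length(truth_sets[[i]]))
    }
    p <- if (length(precs)) mean(precs) else 0
    r <- if (length(recs)) mean(recs) else 0
    if (p + r > 0) best <- max(best, 2 * p * r / (p + r))
  }
  best
}

oracle_smin <- function(truth_sets, score_table, ic_vec) {
  cand <- sort(unique(c(0, 1, unlist(score_table))))
  idx <- which(lengths(truth_sets) > 0)
  best <- Inf
  for (t in cand) {
    ru <- 0; mi <- 0
    for (i in idx) {
      pred <- names(score_table[[i]])[score_table[[i]] >= t]
      ru <- ru + sum(ic_vec[setdiff(truth_sets[[i]], pred)])
      mi <- mi + sum(ic_vec[setdiff(pred, truth_sets[[i]])])
    }
    best <- min(best, sqrt((ru / length(idx))^2 + (mi / length(idx))^2))
  }
  best
}

oracle_auc50 <- function(labels, scores, cap = 50) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  negs <- which(lab == 0)[seq_len(min(cap, sum(lab == 0)))]
  total <- 0
  for (j in negs)
    total <- total + sum(lab == 1 & sc > sc[j]) + 0.5 * sum(lab == 1 & sc == sc[j])
  total / (length(negs) * sum(lab == 1))
}

oracle_aupr <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  keep <- c(diff(sc) != 0, TRUE)
  tp <- cumsum(lab)[keep]; fp <- cumsum(1 - lab)[keep]
  prec <- c(1, tp / (tp + fp)); rec <- c(0, tp / sum(lab))
  sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
}

random_go_instance <- function() {
  n_prot <- sample(2:8, 1); n_terms <- sample(2:8, 1)
  terms <- paste0("t", seq_len(n_terms))
  truth <- lapply(seq_len(n_prot), function(i)
    sample(terms, sample(0:n_terms, 1)))
  if (!any(lengths(truth) > 0)) truth[[1]] <- terms[1]
  scores <- lapply(seq_len(n_prot), function(i)
    stats::setNames(round(stats::runif(n_terms), 2), terms))
  list(truth = truth, scores = scores, terms = terms)
}

# --- examples ----------------------------------------------------------

test_that("accuracy and mean F1 match counting on worked examples", {
  expect_equal(accuracy_score(c(1, 0, 1, 0), c(1, 1, 1, 0)), 0.75)
  expect_equal(accuracy_score(1:4, 1:4), 1.0)
  expect_equal(mean_f1(1:4, 1:4), 1.0)
  expect_error(accuracy_score(integer(0), integer(0)), "empty")
  # brute-force confusion-matrix cross-check
  set.seed(2)
  for (i in 1:25) {
    k <- sample(2:5, 1); n <- sample(5:40, 1)
    truth <- sample(k, n, replace = TRUE); pred <- sample(k, n, replace = TRUE)
    f1s <- vapply(sort(unique(truth)), function(cl) {
      tp <- sum(truth == cl & pred == cl)
      prec <- if (sum(pred == cl)) tp / sum(pred == cl) else 0
      rec <- tp / sum(truth == cl)
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }, numeric(1))
    expect_equal(mean_f1(truth, pred), mean(f1s))
  }
})

test_that("information content follows -log2(frequency) with max-IC fallback", {
  ann <- matrix(0, 8, 3, dimnames = list(NULL, c("all", "one", "none")))
  ann[, "all"] <- 1
  ann[1, "one"] <- 1
  ic <- information_content(ann)
  expect_equal(unname(unclass(ic)[["all"]]), 0)
  expect_equal(unname(unclass(ic)[["one"]]), 3)   # -log2(1/8)
  expect_equal(unname(unclass(ic)[["none"]]), 3)  # fallback to max observed
  # monotonicity: IC non-increasing in frequency
  set.seed(3)
  ann2 <- matrix(stats::runif(200) < 0.4, 20, 10,
                 dimnames = list(NULL, paste0("t", 1:10)))
  ann2[1, ] <- TRUE
  ic2 <- unclass(information_content(ann2))
  o <- order(colSums(ann2))
  expect_true(all(diff(ic2[o]) <= 1e-12))
})

test_that("Fmax handles the single-protein worked example exactly", {
  res <- fmax_score(list(c("A")), list(c(A = 0.9, B = 0.4)))
  expect_equal(res$fmax, 1.0)
  expect_true(res$threshold > 0.4 && res$threshold <= 0.9)
  perfect <- fmax_score(list(c("A", "B"), "A"),
                        list(c(A = 1, B = 1), c(A = 1, B = 0)))
  expect_equal(perfect$fmax, 1.0)
  expect_error(fmax_score(list(character(0)), list(c(A = 1))), "ground-truth")
})

test_that("Smin is zero for perfect predictions and hits the empty-prediction limit", {
  ann <- matrix(c(1, 1, 0, 1), 2, 2, dimnames = list(NULL, c("A", "B")))
  ic <- information_content(ann)
  perfect <- smin_score(list(c("A", "B"), "B"),
                        list(c(A = 1, B = 1), c(A = 0, B = 1)), ic)
  expect_equal(perfect$smin, 0)
  # nothing predicted at any threshold above all scores: ru = mean total IC
  res <- smin_score(list(c("A", "B"), "B"),
                    list(c(A = 0, B = 0), c(A = 0, B = 0)), ic)
  top <- res$curve[nrow(res$curve), ]
  icv <- unclass(ic)
  expect_equal(top$ru, mean(c(icv["A"] + icv["B"], icv["B"])))
  expect_equal(top$mi, 0)
})

test_that("AUC handles ties and perfect separation", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auc_score(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(auc_score(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("AUC50 equals AUC when negatives are within the cap", {
  set.seed(5)
  for (i in 1:30) {
    n_pos <- sample(2:10, 1); n_neg <- sample(2:40, 1)
    labels <- c(rep(1, n_pos), rep(0, n_neg))
    scores <- round(stats::runif(n_pos + n_neg), 1)
    expect_equal(auc50_score(labels, scores, fp_cap = 50),
                 auc_score(labels, scores), tolerance = 1e-12)
  }
  expect_equal(auc50_score(c(1, 1, 0, 0), c(4, 3, 2, 1), fp_cap = 1), 1.0)
})

test_that("ranking metrics agree with brute-force oracles on random instances", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(stats::runif(n), sample(1:3, 1))  # force ties sometimes
    expect_equal(auc_score(labels, scores), oracle_auc(labels, scores),
                 tolerance = 1e-9)
    expect_equal(auc50_score(labels, scores, fp_cap = 7),
                 oracle_auc50(labels, scores, cap = 7), tolerance = 1e-9)
    expect_equal(aupr_score(labels, scores), oracle_aupr(labels, scores),
                 tolerance = 1e-9)
  }
})

test_that("Fmax and Smin agree with exhaustive-threshold oracles on random instances", {
  set.seed(13)
  for (i in 1:100) {
    inst <- random_go_instance()
    ann <- matrix(0, length(inst$truth), length(inst$terms),
                  dimnames = list(NULL, inst$terms))
    for (k in seq_along(inst$truth)) ann[k, inst$truth[[k]]] <- 1
    ic <- information_content(ann)
    expect_equal(fmax_score(inst$truth, inst$scores, grid_step = 0.01)$fmax,
                 oracle_fmax(inst$truth, inst$scores), tolerance = 1e-9)
    expect_equal(smin_score(inst$truth, inst$scores, ic, grid_step = 0.01)$smin,
                 oracle_smin(inst$truth, inst$scores, unclass(ic)),
                 tolerance = 1e-9)
  }
})

test_that("metrics are permutation invariant", {
  set.seed(17)
  labels <- sample(c(0, 1), 30, replace = TRUE); labels[1:2] <- c(0, 1)
  scores <- round(stats::runif(30), 2)
  perm <- sample(30)
  expect_equal(auc_score(labels, scores), auc_score(labels[perm], scores[perm]))
  expect_equal(aupr_score(labels, scores), aupr_score(labels[perm], scores[perm]))
  expect_equal(auc50_score(labels, scores, 5),
               auc50_score(labels[perm], scores[perm], 5))
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:10) {
    labels <- sample(c(0, 1), 50, replace = TRUE); labels[1:2] <- c(0, 1)
    scores <- stats::rnorm(50)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(labels, scores), ref, tolerance = 1e-9)
  }
})
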