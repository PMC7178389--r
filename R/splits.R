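# Cluster-aware dataset splitting, redundancy control and subsampling.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomized operations in the package go through this.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stage label, deterministically,
# staying within the 32-bit integer range.
derive_seed <- function(seed, stage) {
  s <- utf8ToInt(as.character(stage))
  h <- sum(s * seq_along(s))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Split a corpus into train/validation/test partitions
#'
#' Two modes: `"cluster"` assigns whole sequence clusters to partitions, so
#' that no cluster ever spans two partitions (the split used with
#' UniRef50-style cluster assignments); `"random"` assigns individual
#' sequences irrespective of clusters. Ratios apply to cluster counts in
#' cluster mode and to sequence counts in random mode. The default ratios
#' are 90:5:5.
#'
#' @param clusters a `cluster_table` (see [cluster_table()]).
#' @param ratios numeric length-3 vector of non-negative shares summing to 1
#'   (train, validation, test).
#' @param mode `"cluster"` or `"random"`.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return object of class `dataset_split`: list with `train`, `valid`,
#'   `test` (character vectors of sequence ids), `train_clusters`,
#'   `valid_clusters`, `test_clusters` (cluster ids; cluster mode only),
#'   `mode`, `ratios`, `seed`.
#' @export
make_split <- function(clusters, ratios = c(0.9, 0.05, 0.05),
                       mode = c("cluster", "random"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(ratios) == 3, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-8)
    stop("split ratios must sum to 1 (got ", sum(ratios), ")")
  if (mode == "cluster" && length(clusters$clusters) < 3)
    stop("cluster-mode split needs at least 3 clusters")

  if (mode == "cluster") {
    cl <- sort(clusters$clusters)
    K <- length(cl)
    n_train <- round(ratios[1] * K)
    n_valid <- round(ratios[2] * K)
    n_valid <- min(n_valid, K - n_train)
    perm <- with_seed(seed, sample(cl))
    train_cl <- perm[seq_len(n_train)]
    valid_cl <- perm[n_train + seq_len(n_valid)]
    test_cl <- perm[-seq_len(n_train + n_valid)]
    ids_in <- function(cls) names(clusters$member_of)[clusters$member_of %in% cls]
    out <- list(train = ids_in(train_cl), valid = ids_in(valid_cl),
                test = ids_in(test_cl),
                train_clusters = train_cl, valid_clusters = valid_cl,
                test_clusters = test_cl)
  } else {
    ids <- sort(names(clusters$member_of))
    N <- length(ids)
    n_train <- round(ratios[1] * N)
    n_valid <- min(round(ratios[2] * N), N - n_train)
    perm <- with_seed(seed, sample(ids))
    out <- list(train = perm[seq_len(n_train)],
                valid = perm[n_train + seq_len(n_valid)],
                test = perm[-seq_len(n_train + n_valid)],
                train_clusters = NULL, valid_clusters = NULL,
                test_clusters = NULL)
  }
  structure(c(out, list(mode = mode, ratios = ratios, seed = seed)),
            class = "dataset_split")
}

#' Expand a split into sequence-id lists with redundancy control
#'
#' Validation and test partitions always contain only cluster
#' representatives (non-redundant sequences). The training partition
#' contains either the full cluster membership, including redundant
#' sequences (`"all_members"`), or representatives only
#' (`"representatives_only"`).
#'
#' @param split a `dataset_split` from [make_split()] (cluster mode).
#' @param clusters the `cluster_table` the split was made from.
#' @param train_mode `"all_members"` or `"representatives_only"`.
#' @return list with character vectors `train`, `valid`, `test`.
#' @export
expand_members <- function(split, clusters,
                           train_mode = c("all_members", "representatives_only")) {
  train_mode <- match.arg(train_mode)
  if (split$mode != "cluster")
    stop("expand_members requires a cluster-mode split")
  all_cl <- c(split$train_clusters, split$valid_clusters, split$test_clusters)
  no_rep <- setdiff(all_cl, names(clusters$representative))
  if (length(no_rep))
    stop(sprintf("cluster '%s' has no designated representative", no_rep[1]))
  reps_of <- function(cls) unname(clusters$representative[as.character(cls)])
  train <- if (train_mode == "all_members") {
    names(clusters$member_of)[clusters$member_of %in% split$train_clusters]
  } else reps_of(split$train_clusters)
  list(train = train, valid = reps_of(split$valid_clusters),
       test = reps_of(split$test_clusters))
}

#' Subsample the training partition by cluster, keeping test/valid fixed
#'
#' Retains `ceiling(fraction * K)` of the `K` training clusters, chosen
#' uniformly at random; the validation and test partitions are unchanged.
#' Subsets are nested: under the same seed, the clusters kept at a smaller
#' fraction are a subset of those kept at a larger one.
#'
#' @param split a cluster-mode `dataset_split`.
#' @param clusters the `cluster_table` the split was made from.
#' @param fraction fraction of training clusters to keep, in (0, 1].
#' @param seed integer seed for the subsampling order.
#' @return a new `dataset_split` with the reduced training partition.
#' @export
subsample_training <- function(split, clusters, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (split$mode != "cluster")
    stop("subsample_training requires a cluster-mode split")
  K <- length(split$train_clusters)
  keep_n <- ceiling(fraction * K)
  perm <- with_seed(seed, sample(sort(split$train_clusters)))
  keep <- perm[seq_len(keep_n)]
  out <- split
  out$train_clusters <- split$train_clusters[split$train_clusters %in% keep]
  out$train <- names(clusters$member_of)[clusters$member_of %in% keep]
  out
}
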