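# Synthetic motif-family corpora.
#
# Families are defined by short residue motifs implanted in background
# sequences; clusters arise by point-mutating a common ancestor, which gives
# direct control over within-cluster identity (1 - mutation_rate in
# expectation at non-motif positions, since substitutions always change the
# residue). This emulates the structure real tasks have: class signal
# carried by local motifs, redundancy carried by cluster membership.

#' Configuration for the synthetic motif-family generator
#'
#' @param n_families number of protein families (classes).
#' @param motifs character vector of one residue motif per family; pairwise
#'   distinct, built from the 20 standard amino acids. Default: randomly
#'   drawn motifs of length 5.
#' @param length_range integer length-2 vector, min/max sequence length.
#' @param clusters_per_family clusters (ancestors) per family.
#' @param members_per_cluster sequences per cluster (the ancestor itself
#'   plus mutated copies).
#' @param mutation_rate per-residue substitution probability in [0, 1) for
#'   non-motif positions; substitutions are uniform over the other 19
#'   standard residues, so expected identity to the ancestor at non-motif
#'   positions is exactly `1 - mutation_rate`.
#' @param background probability vector over the 20 standard amino acids
#'   used to draw ancestor sequences (default uniform; used by the iid
#'   background model).
#' @param background_model `"iid"` draws residues independently from
#'   `background`; `"markov"` draws them from a first-order Markov chain
#'   whose sparse transition matrix is sampled per config seed (rows are
#'   normalized Gamma(`markov_concentration`) draws). The Markov model
#'   emulates the local compositional regularities of real protein
#'   sequences and makes next-token prediction learnable.
#' @param markov_concentration Dirichlet concentration of the transition
#'   rows (smaller = sparser = more predictable chains).
#' @param motif_len motif length when motifs are drawn automatically.
#' @param seed mandatory integer seed.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_families = 6, motifs = NULL,
                         length_range = c(40, 60), clusters_per_family = 10,
                         members_per_cluster = 3, mutation_rate = 0.1,
                         background = NULL,
                         background_model = c("iid", "markov"),
                         markov_concentration = 0.15, motif_len = 5, seed) {
  if (missing(seed)) stop("synth_config requires an explicit seed")
  background_model <- match.arg(background_model)
  standard <- aa_vocabulary()$standard
  if (is.null(background)) background <- rep(1 / 20, 20)
  stopifnot(length(background) == 20, all(background >= 0),
            abs(sum(background) - 1) < 1e-8)
  transition <- NULL
  if (background_model == "markov") {
    transition <- with_seed(derive_seed(seed, "markov"), {
      Tm <- matrix(stats::rgamma(400, shape = markov_concentration), 20, 20)
      Tm / rowSums(Tm)
    })
    dimnames(transition) <- list(standard, standard)
  }
  if (is.null(motifs)) {
    motifs <- with_seed(derive_seed(seed, "motifs"), {
      m <- character(0)
      while (length(unique(m)) < n_families)
        m <- unique(c(m, paste(sample(standard, motif_len, replace = TRUE),
                               collapse = "")))
      m[seq_len(n_families)]
    })
  }
  stopifnot(length(motifs) == n_families, !anyDuplicated(motifs))
  if (max(nchar(motifs)) >= length_range[1])
    stop("motif length must be smaller than the minimum sequence length")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must be in [0, 1)")
  structure(list(n_families = n_families, motifs = motifs,
                 length_range = as.integer(length_range),
                 clusters_per_family = clusters_per_family,
                 members_per_cluster = members_per_cluster,
                 mutation_rate = mutation_rate, background = background,
                 background_model = background_model,
                 transition = transition,
                 seed = as.integer(seed)),
            class = "synth_config")
}

sample_background <- function(n, config, standard) {
  if (identical(config$background_model, "markov")) {
    Tm <- config$transition
    out <- integer(n)
    out[1] <- sample.int(20, 1, prob = config$background)
    if (n > 1)
      for (i in 2:n) out[i] <- sample.int(20, 1, prob = Tm[out[i - 1], ])
    paste(standard[out], collapse = "")
  } else {
    paste(sample(standard, n, replace = TRUE, prob = config$background),
          collapse = "")
  }
}

mutate_sequence <- function(chars, protect, rate, standard) {
  hit <- stats::runif(length(chars)) < rate & !protect
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(standard, a), 1), character(1))
  }
  chars
}

#' Generate a synthetic motif-family corpus
#'
#' For each family, `clusters_per_family` ancestor sequences are drawn from
#' the background distribution with the family motif implanted at a random
#' position; each cluster consists of the ancestor (its representative) and
#' `members_per_cluster - 1` mutated copies. Motif positions are never
#' mutated, so every sequence carries its family motif intact.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_corpus` with `records` (data.frame: `id`,
#'   `sequence`, `family` (integer class label), `cluster_id`), `clusters`
#'   (a `cluster_table`), `truth` (data.frame: `id`, `motif_start`,
#'   `motif_end`) and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  standard <- aa_vocabulary()$standard
  with_seed(derive_seed(config$seed, "corpus"), {
    rows <- list(); truth <- list(); member_of <- c(); representative <- c()
    k <- 0L
    for (fam in seq_len(config$n_families)) {
      motif <- strsplit(config$motifs[fam], "")[[1]]
      for (cl in seq_len(config$clusters_per_family)) {
        k <- k + 1L
        cl_id <- sprintf("c%04d", k)
        L <- sample(seq(config$length_range[1], config$length_range[2]), 1)
        anc <- strsplit(sample_background(L, config, standard),
                        "")[[1]]
        pos <- sample(seq_len(L - length(motif) + 1), 1)
        anc[pos:(pos + length(motif) - 1)] <- motif
        protect <- rep(FALSE, L)
        protect[pos:(pos + length(motif) - 1)] <- TRUE
        for (m in seq_len(config$members_per_cluster)) {
          id <- sprintf("f%02d_%s_m%02d", fam, cl_id, m)
          chars <- if (m == 1) anc else
            mutate_sequence(anc, protect, config$mutation_rate, standard)
          rows[[length(rows) + 1L]] <-
            data.frame(id = id, sequence = paste(chars, collapse = ""),
                       family = fam, cluster_id = cl_id,
                       stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <-
            data.frame(id = id, motif_start = pos,
                       motif_end = pos + length(motif) - 1L)
          member_of[id] <- cl_id
          if (m == 1) representative[cl_id] <- id
        }
      }
    }
    records <- do.call(rbind, rows)
    structure(list(records = records,
                   clusters = cluster_table(member_of, representative),
                   truth = do.call(rbind, truth), config = config),
              class = "synth_corpus")
  })
}

#' Generate a multi-label task over motif-defined terms
#'
#' Each of `n_terms` terms is tied to one motif; a sequence is annotated
#' with every term whose motif it carries. Motifs are implanted with
#' per-term frequencies spanning rare to common so that downstream
#' term-frequency filters (e.g. a minimum of 50 training occurrences) are
#' exercised. With `term_noise = 0` labels are exactly recoverable by a
#' motif scan.
#'
#' @param config a [synth_config()]; `n_families` is reused as the number
#'   of base families whose sequences receive term motifs.
#' @param n_terms number of terms (>= 2).
#' @param term_noise probability of flipping each label bit after
#'   construction (default 0).
#' @param n_records number of sequences to generate.
#' @return list of class `synth_multilabel` with `records` (data.frame:
#'   `id`, `sequence`), `labels` (logical matrix, records x terms),
#'   `term_motifs` (character vector) and `term_prob` (implant
#'   probabilities).
#' @export
generate_multilabel_task <- function(config, n_terms = 8, term_noise = 0,
                                     n_records = 200) {
  stopifnot(n_terms >= 2)
  standard <- aa_vocabulary()$standard
  with_seed(derive_seed(config$seed, "multilabel"), {
    term_motifs <- character(0)
    while (length(term_motifs) < n_terms)
      term_motifs <- unique(c(term_motifs,
                              paste(sample(standard, 5, replace = TRUE),
                                    collapse = "")))
    term_motifs <- term_motifs[seq_len(n_terms)]
    # implant probabilities spanning rare to common (geometric ladder)
    term_prob <- 0.9 * 0.65^(seq_len(n_terms) - 1) + 0.02
    L_min <- config$length_range[1]; L_max <- config$length_range[2]
    seqs <- character(n_records)
    labels <- matrix(FALSE, n_records, n_terms,
                     dimnames = list(NULL, sprintf("term%02d", seq_len(n_terms))))
    for (i in seq_len(n_records)) {
      L <- sample(seq(L_min, L_max), 1)
      chars <- strsplit(sample_background(L, config, standard),
                        "")[[1]]
      carry <- stats::runif(n_terms) < term_prob
      free_from <- 1L
      for (tm in which(carry)) {
        mot <- strsplit(term_motifs[tm], "")[[1]]
        if (free_from + length(mot) - 1L > L) { carry[tm] <- FALSE; next }
        chars[free_from:(free_from + length(mot) - 1L)] <- mot
        free_from <- free_from + length(mot)
      }
      seqs[i] <- paste(chars, collapse = "")
      labels[i, ] <- carry
    }
    if (term_noise > 0) {
      flip <- matrix(stats::runif(length(labels)) < term_noise, nrow(labels))
      labels <- xor(labels, flip)
    }
    structure(list(records = data.frame(id = sprintf("s%04d", seq_len(n_records)),
                                        sequence = seqs,
                                        stringsAsFactors = FALSE),
                   labels = labels, term_motifs = term_motifs,
                   term_prob = term_prob),
              class = "synth_multilabel")
  })
}

#' Generate per-dataset binary detection benchmarks
#'
#' Emulates remote-homology benchmarks composed of many separate binary
#' datasets: each dataset takes its positives from one family and its
#' negatives from the remaining families, with train/test splits by
#' cluster.
#'
#' @param config a [synth_config()]; needs at least `n_datasets + 1`
#'   families.
#' @param n_datasets number of binary datasets (>= 1).
#' @return list of `n_datasets` elements, each with `train`, `test`
#'   (data.frames: `id`, `sequence`, `label` in 0/1) and `clusters` (a
#'   `cluster_table` covering the training sequences).
#' @export
generate_detection_benchmark <- function(config, n_datasets = 5) {
  stopifnot(n_datasets >= 1, config$n_families >= n_datasets + 1)
  corpus <- generate_corpus(config)
  rec <- corpus$records
  with_seed(derive_seed(config$seed, "detection"), {
    lapply(seq_len(n_datasets), function(d) {
      pos <- rec[rec$family == d, ]
      neg <- rec[rec$family != d, ]
      neg <- neg[sample(nrow(neg), min(nrow(neg), 3 * nrow(pos))), ]
      dat <- rbind(cbind(pos, label = 1L), cbind(neg, label = 0L))
      # cluster-held-out test set: one quarter of clusters per class,
      # stratified so both classes are present in the test set
      pos_cl <- unique(dat$cluster_id[dat$label == 1])
      neg_cl <- unique(dat$cluster_id[dat$label == 0])
      test_cl <- c(sample(pos_cl, max(1, round(0.25 * length(pos_cl)))),
                   sample(neg_cl, max(1, round(0.25 * length(neg_cl)))))
      test <- dat[dat$cluster_id %in% test_cl, ]
      train <- dat[!dat$cluster_id %in% test_cl, ]
      mo <- stats::setNames(train$cluster_id, train$id)
      reps <- tapply(train$id, train$cluster_id, function(x) x[1])
      list(train = train[, c("id", "sequence", "label")],
           test = test[, c("id", "sequence", "label")],
           clusters = cluster_table(mo, stats::setNames(as.character(reps),
                                                        names(reps))))
    })
  })
}

#' Brute-force motif scan: recover term labels from sequences
#'
#' Independent oracle for synthetic labels: a sequence is labelled with a
#' term iff it contains the term's motif as a substring.
#'
#' @param sequences character vector.
#' @param motifs character vector of motifs.
#' @return logical matrix `length(sequences) x length(motifs)`.
#' @export
motif_scan <- function(sequences, motifs) {
  out <- vapply(motifs, function(m) grepl(m, sequences, fixed = TRUE),
                logical(length(sequences)))
  matrix(out, nrow = length(sequences),
         dimnames = list(NULL, names(motifs)))
}

#' Write a synthetic corpus in the formats read_corpus() reads
#'
#' @param corpus a `synth_corpus`.
#' @param dir output directory (created if needed).
#' @return named list of the three file paths (fasta, clusters, labels).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "sequences.fasta")
  clusters <- file.path(dir, "clusters.tsv")
  labels <- file.path(dir, "labels.tsv")
  write_fasta(corpus$records, fasta)
  write_cluster_table(corpus$clusters, clusters)
  utils::write.table(data.frame(seq_id = corpus$records$id,
                                label = corpus$records$family),
                     labels, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, clusters = clusters, labels = labels)
}
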