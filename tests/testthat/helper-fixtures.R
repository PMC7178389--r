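# Shared fixtures, built in code and memoized for the whole test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# 100 singleton clusters (c001..c100), each with its own sequence id
singleton_clusters <- function(n = 100) {
  ids <- sprintf("s%03d", seq_len(n))
  cl <- sprintf("c%03d", seq_len(n))
  cluster_table(stats::setNames(cl, ids), stats::setNames(ids, cl))
}

# small multi-member cluster table: k clusters of given sizes
sized_clusters <- function(sizes) {
  member_of <- c(); representative <- c()
  for (k in seq_along(sizes)) {
    cl <- sprintf("c%02d", k)
    ids <- sprintf("%s_m%02d", cl, seq_len(sizes[k]))
    member_of[ids] <- cl
    representative[cl] <- ids[1]
  }
  cluster_table(member_of, representative)
}

# tiny two-family motif corpus with a pretrained LM and a fine-tuned
# classifier that demonstrably uses the motifs (shared by attribution and
# benchmark-direction tests)
get_motif_fixture <- function() {
  memo("motif_fixture", function() {
    cc <- synth_config(n_families = 2, motifs = c("WWHKW", "DEDCY"),
                       length_range = c(30, 40), clusters_per_family = 40,
                       members_per_cluster = 2, mutation_rate = 0.05,
                       background_model = "markov", seed = 77)
    corpus <- generate_corpus(cc)
    rec <- corpus$records
    split <- make_split(corpus$clusters, c(0.7, 0.1, 0.2), "cluster", seed = 7)
    parts <- expand_members(split, corpus$clusters, "all_members")
    seq_of <- stats::setNames(rec$sequence, rec$id)
    fam_of <- stats::setNames(rec$family, rec$id)
    # architecture donor only; the motif classifier is trained from scratch
    # (the transfer benefit itself is covered by run_transfer_benchmark)
    lm <- build_lm(lm_config(seed = 7), aa_vocabulary())
    cfg <- classifier_config(n_outputs = 2, head_hidden = 32,
                             epochs_final = 15, base_lr = 2e-2,
                             batch_size = 16, head_dropout = 0.3, seed = 7)
    clf <- build_classifier(lm, cfg, from_scratch = TRUE)
    finetune(clf, list(sequences = unname(seq_of[parts$train]),
                       y = unname(fam_of[parts$train])),
             list(sequences = unname(seq_of[parts$valid]),
                  y = unname(fam_of[parts$valid])),
             schedule = unfreeze_schedule(cfg$base_lr, stage_epochs = 1,
                                          epochs_final = 15),
             seed = 7)
    list(config = cc, corpus = corpus, split = split, parts = parts,
         lm = lm, clf = clf, seq_of = seq_of, fam_of = fam_of)
  })
}

# random-weight tiny classifier over the full vocabulary (fast; for
# structural and attribution-completeness checks that need no training)
get_random_clf <- function() {
  memo("random_clf", function() {
    lm <- build_lm(lm_config(embedding_dim = 8, hidden_dim = 12, seed = 11),
                   aa_vocabulary())
    build_classifier(lm, classifier_config(n_outputs = 3, head_hidden = 10,
                                           seed = 11))
  })
}
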