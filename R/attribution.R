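# Per-residue attribution maps: integrated gradients and occlusion by
# substitution with the unknown amino acid X.
#
# Maps are computed in the classifier's own reading direction and reported
# in original sequence coordinates (backward-direction maps are
# re-reversed), so forward and backward maps can be averaged position by
# position.

new_attribution <- function(values, sequence, target_class, method, meta) {
  structure(data.frame(position = seq_len(nchar(sequence)),
                       residue = strsplit(sequence, "")[[1]],
                       attribution = values),
            target_class = target_class, method = method, meta = meta,
            class = c("attribution_map", "data.frame"))
}

#' Integrated-gradients attribution
#'
#' Per-position attribution along the straight path in embedding space
#' from a baseline (all-`<PAD>` embedding by default) to the input
#' embedding, using a midpoint Riemann sum with `steps` segments and
#' summing over embedding dimensions. The attributed output is the
#' post-softmax probability of `target_class` (set `on_logit = TRUE` for
#' the pre-softmax score). Satisfies completeness approximately: the
#' attributions sum to `F(input) - F(baseline)`.
#'
#' @param clf an `aa_classifier`.
#' @param sequence residue string.
#' @param target_class output index to attribute.
#' @param steps number of path segments (>= 2; default 64).
#' @param baseline `"pad"` (embedding of the padding token, the default)
#'   or `"zero"`.
#' @param on_logit attribute the pre-softmax logit instead of the
#'   probability.
#' @return an `attribution_map` data.frame (position, residue,
#'   attribution) with attributes `target_class`, `method`, `meta`.
#' @export
integrated_gradients <- function(clf, sequence, target_class, steps = 64,
                                 baseline = c("pad", "zero"),
                                 on_logit = FALSE) {
  baseline <- match.arg(baseline)
  if (steps < 2) stop("integrated gradients needs steps >= 2")
  cfg <- clf$config
  ids <- as.integer(tokenize(sequence, clf$vocab, cfg$direction))
  L1 <- length(ids)                        # L + 1 (with <BOS>)
  de <- clf$lm_config$embedding_dim
  Xin <- clf$params$E[ids, , drop = FALSE]               # L1 x de
  Bm <- if (baseline == "pad")
    matrix(clf$params$E[clf$vocab$pad_id, ], L1, de, byrow = TRUE)
  else matrix(0, L1, de)
  Bm[1, ] <- Xin[1, ]                      # <BOS> shared by input and baseline
  diffm <- Xin - Bm

  alphas <- (seq_len(steps) - 0.5) / steps # midpoint rule
  # batch the interpolation points along the batch dimension
  X_over <- lapply(seq_len(L1), function(t) {
    outer(alphas, diffm[t, ]) + matrix(Bm[t, ], steps, de, byrow = TRUE)
  })
  res <- clf_batch_pass(clf, lengths = rep(L1, steps), X_override = X_over,
                        input_grads = TRUE, target_class = target_class,
                        target_on = if (on_logit) "logit" else "prob",
                        compute_grads = FALSE)
  avg_grad <- t(vapply(res$dX, colMeans, numeric(de)))    # L1 x de
  attr_tok <- rowSums(avg_grad * diffm)
  values <- attr_tok[-1]                   # drop <BOS> (zero by construction)
  if (cfg$direction == "backward") values <- rev(values)
  f_of <- function(X) {
    r <- clf_batch_pass(clf, lengths = L1,
                        X_override = lapply(seq_len(L1), function(t)
                          matrix(X[t, ], 1, de)))
    if (on_logit) r$logits[1, target_class] else r$probs[1, target_class]
  }
  new_attribution(values, sequence, target_class, "integrated_gradients",
                  meta = list(steps = steps, baseline = baseline,
                              f_input = f_of(Xin), f_baseline = f_of(Bm)))
}

#' Occlusion attribution (substitution with X)
#'
#' Attribution at position `i` is the change in the target-class score
#' when residue `i` is replaced by the unknown amino acid X:
#' `score(original) - score(occluded)`. Positions already holding X get
#' attribution 0 (the substitution is a no-op).
#'
#' @inheritParams integrated_gradients
#' @return an `attribution_map` data.frame.
#' @export
occlusion <- function(clf, sequence, target_class) {
  if (!"X" %in% clf$vocab$residues)
    stop("vocabulary must contain the unknown amino acid X")
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  variants <- vapply(seq_len(L), function(i) {
    v <- chars; v[i] <- "X"; paste(v, collapse = "")
  }, character(1))
  p <- predict_proba(clf, c(sequence, variants))
  base <- p[1, target_class]
  values <- base - p[-1, target_class]
  values[chars == "X"] <- 0
  new_attribution(values, sequence, target_class, "occlusion",
                  meta = list(score_original = base))
}

#' Average forward and backward attribution maps
#'
#' Maps are already reported in original sequence coordinates, so the
#' ensemble map is the positionwise mean.
#'
#' @param map_fwd,map_bwd `attribution_map`s for the same sequence.
#' @return an `attribution_map`.
#' @export
ensemble_attribution <- function(map_fwd, map_bwd) {
  stopifnot(nrow(map_fwd) == nrow(map_bwd),
            all(map_fwd$residue == map_bwd$residue))
  out <- map_fwd
  out$attribution <- (map_fwd$attribution + map_bwd$attribution) / 2
  attr(out, "method") <- "ensemble"
  out
}
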