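#' Amino-acid vocabulary
#'
#' The model vocabulary covers the 20 standard amino acids plus the six
#' non-standard symbols found in curated protein databases (B, J, O, U, X, Z),
#' together with two special tokens: `<PAD>` for padding and `<BOS>` marking
#' the beginning of a sequence.
#'
#' Token-id convention (fixed here, used everywhere else in the package):
#' ids are 1-based; `<PAD>` = 1, `<BOS>` = 2, then the 20 standard residues
#' in alphabetical order (A, C, D, ..., Y) at ids 3..22, then the 6
#' non-standard residues (B, J, O, U, X, Z) at ids 23..28.
#'
#' @param include_nonstandard keep the six non-standard symbols in the
#'   residue alphabet (default `TRUE`; the language model always uses the
#'   full 26-symbol alphabet, PSSM code paths use only the standard 20).
#' @return An object of class `aa_vocab` with elements `residues` (character
#'   vector of residue symbols), `tokens` (all tokens including specials, in
#'   id order), `pad_id`, `bos_id`, `index` (named integer vector mapping
#'   symbol to id) and `size`.
#' @examples
#' v <- aa_vocabulary()
#' v$size          # 28 = 26 residues + <PAD> + <BOS>
#' v$index[["M"]]
#' @export
aa_vocabulary <- function(include_nonstandard = TRUE) {
  standard <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  nonstandard <- c("B", "J", "O", "U", "X", "Z")
  residues <- if (include_nonstandard) c(standard, nonstandard) else standard
  tokens <- c("<PAD>", "<BOS>", residues)
  index <- stats::setNames(seq_along(tokens), tokens)
  structure(
    list(
      residues = residues,
      standard = standard,
      nonstandard = if (include_nonstandard) nonstandard else character(0),
      tokens = tokens,
      pad_id = 1L,
      bos_id = 2L,
      index = index,
      size = length(tokens)
    ),
    class = "aa_vocab"
  )
}

#' @export
print.aa_vocab <- function(x, ...) {
  cat("Amino-acid vocabulary:", length(x$residues), "residues +",
      x$size - length(x$residues), "special tokens (<PAD>=1, <BOS>=2)\n")
  invisible(x)
}

#' Tokenize a protein sequence
#'
#' Encodes a residue string as integer token ids with a leading `<BOS>`
#' token. In the backward direction the residue order is reversed but the
#' `<BOS>` token stays first, so a backward language model reads the
#' sequence C-terminus to N-terminus.
#'
#' @param sequence a single residue string (e.g. `"MSLR"`).
#' @param vocab an [aa_vocabulary()].
#' @param direction `"forward"` or `"backward"`.
#' @return integer vector of length `nchar(sequence) + 1`, class
#'   `aa_tokens`, with attributes `direction`.
#' @examples
#' v <- aa_vocabulary()
#' tokenize("MSLR", v)               # <BOS> M S L R
#' tokenize("MSLR", v, "backward")   # <BOS> R L S M
#' @export
tokenize <- function(sequence, vocab, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L)
    stop("cannot tokenize an empty sequence (length must be >= 1)")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ids <- vocab$index[chars]
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    stop(sprintf("unknown residue symbol '%s' at position %d", chars[bad], bad))
  }
  if (direction == "backward") ids <- rev(ids)
  structure(c(vocab$bos_id, unname(ids)), direction = direction,
            class = "aa_tokens")
}

#' Decode token ids back to a residue string
#'
#' Inverse of [tokenize()]: strips the leading `<BOS>` and, for backward
#' token sequences, re-reverses the residues so the original sequence is
#' recovered.
#'
#' @param ids integer token ids (typically an `aa_tokens` object).
#' @param vocab an [aa_vocabulary()].
#' @param direction direction the ids were produced with; defaults to the
#'   `direction` attribute when present.
#' @return the residue string.
#' @export
detokenize <- function(ids, vocab, direction = NULL) {
  if (is.null(direction))
    direction <- attr(ids, "direction") %||% "forward"
  ids <- as.integer(ids)
  if (length(ids) < 1L || ids[1] != vocab$bos_id)
    stop("token sequence must start with <BOS>")
  body <- ids[-1]
  if (any(body <= 2L | body > vocab$size))
    stop("token ids outside the residue range")
  if (direction == "backward") body <- rev(body)
  paste(vocab$tokens[body], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-hot encode a sequence over the 26-letter residue alphabet
#'
#' Produces the L x 26 indicator matrix used by the convolutional baseline:
#' one row per residue position, columns ordered as the vocabulary's residue
#' alphabet (20 standard alphabetically, then B, J, O, U, X, Z).
#'
#' @inheritParams tokenize
#' @return numeric matrix of dimension `L x 26`, with residue symbols as
#'   column names.
#' @export
one_hot <- function(sequence, vocab = aa_vocabulary()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  col <- match(chars, vocab$residues)
  if (anyNA(col)) {
    bad <- which(is.na(col))[1]
    stop(sprintf("unknown residue symbol '%s' at position %d", chars[bad], bad))
  }
  m <- matrix(0, nrow = length(chars), ncol = length(vocab$residues),
              dimnames = list(NULL, vocab$residues))
  m[cbind(seq_along(chars), col)] <- 1
  m
}
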