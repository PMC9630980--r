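# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
# When seed is NULL the expression uses the current stream as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; keeps results < 2^31.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483629)
}

# Hamming distance between one query string and a character matrix of
# reference sequences (rows = sequences, columns = positions).
hamming_to_refs <- function(query_chars, ref_mat) {
  rowSums(ref_mat != matrix(query_chars, nrow = nrow(ref_mat),
                            ncol = length(query_chars), byrow = TRUE))
}

# Split barcode strings into a character matrix (n x len).
seq_char_matrix <- function(seqs) {
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("sequences must all have the same length")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = len, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop(sprintf("%s must be a probability strictly inside (0, 1)", name))
  invisible(x)
}
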