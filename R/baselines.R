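# Comparison encoders: n-gram (an alias of k-mer, kept so experiment configs
# mirror the benchmark naming) and the 400-D skip-gram dipeptide model.

#' n-gram composition (alias of k-mer)
#'
#' Identical contract to [kmer()]; kept under the benchmark's name so
#' experiment configurations read the same as the published comparisons.
#'
#' @param seq protein sequence.
#' @param n word size, 1..3.
#' @export
ngram <- function(seq, n = 1L) {
  out <- kmer(seq, k = n)
  attr(out, "encoder_id") <- paste0("ngram", n)
  out
}

#' 400-D skip-gram dipeptide features
#'
#' For each ordered residue pair (a, b), counts occurrences of a followed by
#' b at gaps 0..`max_skip` (gap 0 = adjacent), pooled uniformly over gaps and
#' normalized by the total number of counted position pairs; 20 x 20 = 400
#' dimensions summing to 1. With `max_skip = 0` this equals [kmer()] with
#' k = 2. Uniform gap weighting is a documented choice: the "adaptive"
#' weighting of the published variant is unspecified.
#'
#' @param seq protein sequence of length >= 2.
#' @param max_skip largest gap counted (default 3).
#' @return Named numeric vector of length 400.
#' @export
skipgram_400 <- function(seq, max_skip = 3L) {
  stopifnot(max_skip >= 0L)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < 2L) stop("skipgram_400: sequence must have length >= 2")
  pair_names <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET,
                                  function(a, b) paste0(a, b))))
  counts <- setNames(numeric(400L), pair_names)
  total <- 0L
  for (gap in 0:max_skip) {
    d <- gap + 1L
    if (d >= L + 1L || L - d < 1L) break
    a <- chars[seq_len(L - d)]
    b <- chars[seq_len(L - d) + d]
    tab <- table(factor(paste0(a, b), levels = pair_names))
    counts <- counts + as.numeric(tab)
    total <- total + (L - d)
  }
  structure(counts / total, names = pair_names, encoder_id = "skipgram400")
}
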