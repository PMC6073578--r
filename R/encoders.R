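# Encoder registry: maps names used in experiment configs and the CLI to
# per-sequence feature functions, and builds feature matrices for datasets.

#' Resolve an encoder name to a per-sequence feature function
#'
#' Registered encoders:
#' \describe{
#'   \item{`"188d"`}{[extract_188d()], 188-D CTD descriptor;}
#'   \item{`"pse"`}{[extract_pse_combined()] with [default_pse_config()], 434-D;}
#'   \item{`"188d+pse"`}{concatenation of the two above (622-D), the
#'     recommended predictor encoding;}
#'   \item{`"kmer2"` / `"ngram1"`}{word-count baselines;}
#'   \item{`"skipgram400"`}{the 400-D gapped dipeptide baseline.}
#' }
#'
#' @param encoder an encoder name above, or a function `(sequence) -> named
#'   numeric vector` for custom encodings.
#' @return Function mapping one sequence to a named numeric vector.
#' @export
make_encoder <- function(encoder = "188d+pse") {
  if (is.function(encoder)) return(encoder)
  switch(encoder,
    "188d" = extract_188d,
    "pse" = function(s) extract_pse_combined(s),
    "188d+pse" = function(s) {
      out <- c(extract_188d(s), extract_pse_combined(s))
      attr(out, "encoder_id") <- "188d+pse"
      out
    },
    "kmer2" = function(s) kmer(s, 2L),
    "ngram1" = function(s) ngram(s, 1L),
    "skipgram400" = function(s) skipgram_400(s),
    stop("make_encoder: unknown encoder '", encoder, "'"))
}

#' Encode a dataset into a feature matrix
#'
#' @param dataset a [labeled_dataset()], or a named character vector of
#'   sequences.
#' @param encoder encoder name or function (see [make_encoder()]).
#' @return Numeric matrix, one row per sequence (rownames = ids, colnames =
#'   dimension names).
#' @export
encode_dataset <- function(dataset, encoder = "188d+pse") {
  seqs <- if (inherits(dataset, "labeled_dataset")) dataset$sequences else dataset
  if (is.matrix(encoder)) {  # precomputed feature matrix passthrough
    stopifnot(nrow(encoder) == length(seqs))
    return(encoder)
  }
  f <- make_encoder(encoder)
  rows <- lapply(seqs, function(s) as.numeric(f(s)))
  first <- f(seqs[[1]])
  X <- do.call(rbind, rows)
  colnames(X) <- names(first)
  rownames(X) <- names(seqs)
  stopifnot(all(is.finite(X)))
  X
}

#' Write a feature matrix to CSV/TSV
#'
#' Rows = sequences (id column first), header = dimension names.
#'
#' @param X feature matrix from [encode_dataset()].
#' @param path output path; extension `.csv` selects comma separation,
#'   anything else tab.
#' @export
write_feature_matrix <- function(X, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
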