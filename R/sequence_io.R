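#' @useDynLib amyforest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict rbinom runif sd setNames
#' @importFrom utils head write.table
NULL

#' The 20-letter amino-acid alphabet, alphabetically ordered
#'
#' Single-letter codes of the 20 standard amino acids. All feature encoders
#' order their composition dimensions by this vector.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Characters that can legally appear in raw input but are not one of the 20
# standard residues: ambiguity codes, rare residues, and the stop symbol.
NONSTANDARD_CHARS <- c("B", "J", "O", "U", "X", "Z", "*")

#' Construct a validated protein sequence
#'
#' A `protein_sequence` is a length-1 character string over the 20-letter
#' amino-acid alphabet, carrying an identifier. Construction fails on empty
#' or non-standard residues; use [sanitize_sequence()] first for raw input.
#'
#' @param id character identifier.
#' @param residues character string of amino acids (case-insensitive).
#' @return An object of class `protein_sequence`: a character scalar with an
#'   `id` attribute.
#' @examples
#' protein_sequence("p1", "MKVLLE")
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) {
    stop("protein_sequence: residues must be non-empty (id: ", id, ")")
  }
  bad <- setdiff(unique(strsplit(residues, "", fixed = TRUE)[[1]]), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("protein_sequence: non-standard residue(s) ",
         paste(bad, collapse = ", "), " in '", id,
         "'; run sanitize_sequence() first")
  }
  structure(residues, id = id, class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n%s\n",
              attr(x, "id"), nchar(x),
              if (nchar(x) > 60) paste0(substr(x, 1, 57), "...") else x))
  invisible(x)
}

#' Sanitize a raw sequence string
#'
#' Applies one of three policies for characters outside the 20-letter
#' alphabet (`B J O U X Z *`):
#' \describe{
#'   \item{`"reject"`}{fail, citing the first offending character and its
#'     position;}
#'   \item{`"strip"`}{drop the offending characters (default policy of the
#'     dataset assembly functions);}
#'   \item{`"map-to-ALA"`}{substitute by chemical similarity:
#'     U (selenocysteine) -> C, B (Asx) -> N, Z (Glx) -> Q, and X/J/O/`*` -> A.}
#' }
#' Any character that is neither a standard residue nor one of the known
#' non-standard codes (digits, gaps, whitespace) is always an error.
#'
#' @param raw raw sequence string (case-insensitive).
#' @param id identifier to attach to the result.
#' @param policy one of `"reject"`, `"strip"`, `"map-to-ALA"`.
#' @return A [protein_sequence()].
#' @examples
#' sanitize_sequence("MKXV", "p1", policy = "strip")   # "MKV"
#' sanitize_sequence("MKUV", "p1", policy = "map-to-ALA") # "MKCV"
#' @export
sanitize_sequence <- function(raw, id = "seq", policy = c("strip", "reject", "map-to-ALA")) {
  policy <- match.arg(policy)
  stopifnot(is.character(raw), length(raw) == 1L)
  chars <- strsplit(toupper(raw), "", fixed = TRUE)[[1]]
  unknown <- which(!(chars %in% c(AA_ALPHABET, NONSTANDARD_CHARS)))
  if (length(unknown) > 0L) {
    stop("sanitize_sequence: unrecognized character '", chars[unknown[1]],
         "' at position ", unknown[1], " in '", id, "'")
  }
  ns <- which(chars %in% NONSTANDARD_CHARS)
  if (policy == "reject" && length(ns) > 0L) {
    stop("sanitize_sequence: non-standard residue '", chars[ns[1]],
         "' at position ", ns[1], " in '", id, "' (policy: reject)")
  }
  if (policy == "strip" && length(ns) > 0L) {
    chars <- chars[-ns]
  }
  if (policy == "map-to-ALA" && length(ns) > 0L) {
    map <- c(U = "C", B = "N", Z = "Q", X = "A", J = "A", O = "A", "*" = "A")
    chars[ns] <- map[chars[ns]]
  }
  if (length(chars) == 0L) {
    stop("sanitize_sequence: sequence '", id, "' empty after stripping")
  }
  protein_sequence(id, paste(chars, collapse = ""))
}

#' Read a FASTA file of protein sequences
#'
#' Multi-record FASTA with wrapped or unwrapped sequence lines; lowercase is
#' accepted and uppercased. Headers are parsed to ids (first whitespace-
#' delimited token after `>`). Sequence content before the first header is a
#' parse error naming the line. Sequences are returned raw (not sanitized);
#' pass them through [sanitize_sequence()] or use [read_labeled_dataset()].
#'
#' @param path path to a FASTA file.
#' @return A named character vector of sequences (names = ids), in file order.
#'   An empty file yields an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "" & !startsWith(trimws(lines), ";"))
  if (length(nonblank) == 0L) {
    warning("read_fasta: '", path, "' contains no records")
    return(setNames(character(0), character(0)))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("read_fasta: sequence data before first header at line ", first,
         " of '", path, "'")
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences (names used as headers).
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Drop sequences shorter than a minimum length
#'
#' The dataset-construction filter: sequences with fewer than `min_len`
#' residues (default 50) are removed; order is preserved and the number
#' removed is reported via `message()`.
#'
#' @param seqs named character vector of sequences.
#' @param min_len minimum length kept (default 50).
#' @return The surviving subset of `seqs`, in input order.
#' @export
filter_min_length <- function(seqs, min_len = 50L) {
  stopifnot(min_len >= 1L)
  keep <- nchar(seqs) >= min_len
  if (any(!keep)) {
    message("filter_min_length: removed ", sum(!keep), " sequence(s) shorter than ",
            min_len, " aa")
  }
  seqs[keep]
}

# k-mer set of a sequence, used by the identity proxy below
kmer_set <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  unique(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
}

# Pairwise identity proxy: exact global identity for equal-length pairs,
# shared k-mer Jaccard otherwise. Alignment-free; NOT CD-HIT-equivalent.
sequence_identity <- function(a, b, k = 5L) {
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    return(mean(ca == cb))
  }
  ka <- kmer_set(a, k)
  kb <- kmer_set(b, k)
  u <- length(union(ka, kb))
  if (u == 0L) return(0)
  length(intersect(ka, kb)) / u
}

#' Greedy identity clustering (redundancy-removal fallback)
#'
#' A stand-in for CD-HIT when the external tool is unavailable: sequences are
#' sorted longest-first and greedily assigned to the first representative with
#' pairwise identity at or above the threshold; unassigned sequences become new
#' representatives. Identity is exact column identity for equal-length pairs
#' and a shared 5-mer Jaccard proxy otherwise, so results are NOT equivalent
#' to CD-HIT clustering.
#'
#' @param seqs named character vector of sequences.
#' @param identity_threshold fraction in (0, 1]; default 0.9 (the external
#'   tool's threshold for this dataset is not published -- this is a config
#'   default, not a claim).
#' @param k k-mer size for the unequal-length identity proxy.
#' @return The representatives, ordered longest-first.
#' @export
greedy_identity_cluster <- function(seqs, identity_threshold = 0.9, k = 5L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (length(seqs) == 0L) return(seqs)
  ord <- order(-nchar(seqs))
  seqs <- seqs[ord]
  reps <- integer(0)
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    for (r in reps) {
      if (sequence_identity(seqs[[i]], seqs[[r]], k = k) >= identity_threshold) {
        assigned <- TRUE
        break
      }
    }
    if (!assigned) reps <- c(reps, i)
  }
  seqs[reps]
}

#' Assemble a labeled two-class sequence dataset
#'
#' Labels come from file (or vector) of origin: positives are amyloid (label
#' 1), negatives non-amyloid (label 0). Ids must be unique across the dataset.
#'
#' @param positive named character vector of positive-class sequences.
#' @param negative named character vector of negative-class sequences.
#' @param name dataset name.
#' @return A `labeled_dataset`: list with `sequences` (named character vector),
#'   `labels` (integer 0/1), `name`.
#' @export
labeled_dataset <- function(positive, negative, name = "dataset") {
  seqs <- c(positive, negative)
  labels <- c(rep(1L, length(positive)), rep(0L, length(negative)))
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    stop("labeled_dataset: duplicate id '", dup, "'")
  }
  structure(list(sequences = seqs, labels = labels, name = name),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %s: %d sequences (%d positive / %d negative)\n",
              x$name, length(x$sequences), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Read, sanitize and filter a labeled dataset from paired FASTA files
#'
#' Convenience wrapper reproducing the dataset-construction pipeline:
#' read positives and negatives, sanitize each sequence under `policy`
#' (sequences rejected under `"reject"`, or emptied by `"strip"`, are dropped
#' with a warning), then apply the minimum-length filter.
#'
#' @param positive_path FASTA of positive (amyloid) sequences.
#' @param negative_path FASTA of negative sequences.
#' @param min_len minimum sequence length kept (default 50).
#' @param policy sanitization policy, see [sanitize_sequence()].
#' @param name dataset name.
#' @return A [labeled_dataset()].
#' @export
read_labeled_dataset <- function(positive_path, negative_path, min_len = 50L,
                                 policy = "strip", name = "dataset") {
  load_one <- function(path) {
    raw <- read_fasta(path)
    out <- character(0)
    for (i in seq_along(raw)) {
      s <- tryCatch(
        as.character(sanitize_sequence(raw[[i]], id = names(raw)[i], policy = policy)),
        error = function(e) {
          warning("dropping '", names(raw)[i], "': ", conditionMessage(e))
          NA_character_
        })
      if (!is.na(s)) out[names(raw)[i]] <- s
    }
    filter_min_length(out, min_len = min_len)
  }
  labeled_dataset(load_one(positive_path), load_one(negative_path), name = name)
}
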