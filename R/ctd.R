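# Composition/transition/distribution (CTD) descriptors: 20 amino-acid
# composition features plus, for each of 8 three-class physicochemical
# partitions, 3 class-composition + 3 transition + 15 distribution features
# (21 per property), 188 dimensions in total.

#' Default three-class physicochemical partitions
#'
#' The canonical CTD residue-to-class assignments for the 8 properties of the
#' 188-D descriptor. Each partition splits the 20-letter alphabet into three
#' disjoint classes; class order is fixed (it determines feature ordering).
#' The partitions are a documented default and can be overridden by passing a
#' list of the same shape to the CTD functions.
#'
#' @return Named list of 8 partitions; each a list of three character vectors
#'   (`class1`, `class2`, `class3`).
#' @examples
#' names(default_partitions())
#' @export
default_partitions <- function() {
  split3 <- function(a, b, c) {
    list(class1 = strsplit(a, "", fixed = TRUE)[[1]],
         class2 = strsplit(b, "", fixed = TRUE)[[1]],
         class3 = strsplit(c, "", fixed = TRUE)[[1]])
  }
  list(
    hydrophobicity        = split3("RKEDQN",   "GASTPHY",          "CLVIMFW"),
    vdw_volume            = split3("GASTPDC",  "NVEQIL",           "MHKFRYW"),
    polarity              = split3("LIFWCMVY", "PATGS",            "HQRKNED"),
    polarizability        = split3("GASDT",    "CPNVEQIL",         "KMHFRYW"),
    charge                = split3("KR",       "ANCQGHILMFPSTWYV", "DE"),
    surface_tension       = split3("GQDNAHR",  "KTSEC",            "ILMFPWYV"),
    secondary_structure   = split3("EALMQKRH", "VIYCWFT",          "GNPSD"),
    solvent_accessibility = split3("ALFCGIVW", "RKQEND",           "MSPTHY")
  )
}

validate_partition <- function(part, name = "partition") {
  stopifnot(is.list(part), length(part) == 3L)
  all_res <- sort(unlist(part, use.names = FALSE))
  if (!identical(all_res, sort(AA_ALPHABET))) {
    stop(name, ": classes must be disjoint and cover the 20-letter alphabet exactly")
  }
  invisible(part)
}

# residues -> integer class labels 1/2/3 under a partition
partition_classes <- function(chars, part) {
  cls <- integer(length(chars))
  cls[chars %in% part[[1]]] <- 1L
  cls[chars %in% part[[2]]] <- 2L
  cls[chars %in% part[[3]]] <- 3L
  cls
}

seq_chars <- function(seq) {
  s <- toupper(as.character(seq))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("non-standard residue(s): ", paste(bad, collapse = ", "),
         "; sanitize first")
  }
  chars
}

#' Amino-acid composition (20-D)
#'
#' Per-residue frequencies `count(a) / L`, alphabetically ordered; sums to 1.
#'
#' @param seq protein sequence (string or [protein_sequence()]).
#' @return Named numeric vector of length 20.
#' @examples
#' aa_composition("ACAC")  # A = 0.5, C = 0.5
#' @export
aa_composition <- function(seq) {
  chars <- seq_chars(seq)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  structure(as.numeric(counts) / length(chars), names = AA_ALPHABET,
            encoder_id = "aa_composition")
}

#' CTD class composition (3-D per property)
#'
#' Fraction of residues falling in each of the three property classes,
#' in class order; sums to 1.
#'
#' @param seq protein sequence.
#' @param part a three-class partition (one entry of [default_partitions()]).
#' @return Numeric vector of length 3, names `c1`, `c2`, `c3`.
#' @export
ctd_composition <- function(seq, part) {
  validate_partition(part)
  cls <- partition_classes(seq_chars(seq), part)
  setNames(tabulate(cls, nbins = 3L) / length(cls), c("c1", "c2", "c3"))
}

#' CTD transition (3-D per property)
#'
#' For the unordered class pairs (1,2), (1,3), (2,3): the number of adjacent
#' positions whose classes form that pair in either order, divided by L - 1.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of length 3, names `t12`, `t13`, `t23`.
#' @export
ctd_transition <- function(seq, part) {
  validate_partition(part)
  cls <- partition_classes(seq_chars(seq), part)
  L <- length(cls)
  if (L < 2L) stop("ctd_transition: undefined for length-1 sequences")
  a <- cls[-L]
  b <- cls[-1]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- c(t12 = sum(lo == 1L & hi == 2L),
           t13 = sum(lo == 1L & hi == 3L),
           t23 = sum(lo == 2L & hi == 3L)) / (L - 1)
  out
}

#' CTD distribution (15-D per property)
#'
#' For each class with n occurrences, the 1-based positions of the 1st,
#' `ceiling(0.25 n)`-th, `ceiling(0.50 n)`-th, `ceiling(0.75 n)`-th and n-th
#' occurrence, each divided by the sequence length L. A class absent from the
#' sequence contributes five zeros.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of length 15 (5 quantile positions x 3 classes).
#' @export
ctd_distribution <- function(seq, part) {
  validate_partition(part)
  cls <- partition_classes(seq_chars(seq), part)
  L <- length(cls)
  qs <- c(0, 0.25, 0.50, 0.75, 1)  # 0 stands for "first occurrence"
  out <- numeric(0)
  for (k in 1:3) {
    pos <- which(cls == k)
    n <- length(pos)
    block <- if (n == 0L) {
      rep(0, 5L)
    } else {
      idx <- pmax(1L, ceiling(qs * n))
      pos[idx] / L
    }
    out <- c(out, setNames(block, paste0("c", k, ".d", c("first", "25", "50", "75", "last"))))
  }
  out
}

#' 188-D composition + physicochemical CTD feature vector
#'
#' Concatenation of the 20-D amino-acid composition with, for each of the 8
#' properties in fixed order (hydrophobicity, normalized van der Waals volume,
#' polarity, polarizability, charge, surface tension, secondary structure,
#' solvent accessibility), the 3 class-composition + 3 transition + 15
#' distribution features. Dimension names encode the property and sub-block;
#' the ordering is frozen so serialized models remain stable.
#'
#' @param seq protein sequence of length >= 2.
#' @param partitions list of 8 partitions (default [default_partitions()]).
#' @return Named numeric vector of length 188 with attribute
#'   `encoder_id = "188d"`.
#' @examples
#' length(extract_188d(strrep("ACDEFGHIKLMNPQRSTVWY", 3)))
#' @export
extract_188d <- function(seq, partitions = default_partitions()) {
  stopifnot(length(partitions) == 8L)
  out <- aa_composition(seq)
  names(out) <- paste0("comp.", names(out))
  for (p in names(partitions)) {
    part <- partitions[[p]]
    block <- c(ctd_composition(seq, part),
               ctd_transition(seq, part),
               ctd_distribution(seq, part))
    names(block) <- paste0(p, ".", names(block))
    out <- c(out, block)
  }
  attr(out, "encoder_id") <- "188d"
  out
}
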