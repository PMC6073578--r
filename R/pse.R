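# Sequence-derivable Pse-in-One encoders: composition (k-mer, DR, distance
# pair), autocorrelation (AC, CC, ACC, PDT) and pseudo amino-acid composition
# (PC/SC-PseAAC and their General variants). Profile-based and predicted-
# structure methods need PSSMs / structure predictors and are catalogued as
# unsupported.

#' Default physicochemical index table
#'
#' The classical pseudo-AAC triple: hydrophobicity, hydrophilicity and
#' side-chain mass, as raw (unstandardized) values per residue. Used as the
#' default substrate of the autocorrelation and pseudo-AAC encoders;
#' overridable by any matrix of the same shape (rows = indices, 20 columns
#' named by residue).
#'
#' @return Numeric matrix, 3 rows x 20 columns (alphabetical residue order).
#' @export
default_indices <- function() {
  hydrophobicity <- c(A =  0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
                      G =  0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
                      M =  0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
                      S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)
  hydrophilicity <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
                      G =  0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
                      M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
                      S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  side_chain_mass <- c(A = 15, C = 47, D = 59, E = 73, F = 91,
                       G = 1, H = 82, I = 57, K = 73, L = 57,
                       M = 75, N = 58, P = 42, Q = 72, R = 101,
                       S = 31, T = 45, V = 43, W = 130, Y = 107)
  m <- rbind(hydrophobicity = hydrophobicity[AA_ALPHABET],
             hydrophilicity = hydrophilicity[AA_ALPHABET],
             side_chain_mass = side_chain_mass[AA_ALPHABET])
  colnames(m) <- AA_ALPHABET
  m
}

#' Standardize physicochemical indices over the 20 residues
#'
#' Each row is centered and scaled to mean 0 and (population, n = 20)
#' standard deviation 1 -- the classical pseudo-AAC normalization.
#'
#' @param indices numeric matrix, rows = indices, 20 named columns.
#' @return Matrix of the same shape with attribute `standardized = TRUE`.
#' @export
standardize_indices <- function(indices) {
  stopifnot(is.matrix(indices), ncol(indices) == 20L)
  if (isTRUE(attr(indices, "standardized"))) return(indices)
  indices <- indices[, AA_ALPHABET, drop = FALSE]
  out <- t(apply(indices, 1L, function(v) {
    mu <- mean(v)
    sdev <- sqrt(mean((v - mu)^2))
    if (sdev == 0) stop("standardize_indices: constant index row")
    (v - mu) / sdev
  }))
  colnames(out) <- AA_ALPHABET
  attr(out, "standardized") <- TRUE
  out
}

# per-position standardized property values, one row per index
index_profile <- function(chars, indices) {
  indices <- standardize_indices(indices)
  indices[, chars, drop = FALSE]
}

all_kmers <- function(k) {
  if (k == 1L) return(AA_ALPHABET)
  grids <- do.call(expand.grid,
                   c(rep(list(AA_ALPHABET), k), stringsAsFactors = FALSE))
  # expand.grid varies the FIRST column fastest; reorder for alphabetical kmers
  apply(grids[, k:1, drop = FALSE], 1L, paste, collapse = "")
}

#' k-mer composition
#'
#' Frequency of each of the `20^k` alphabetically ordered k-mers, normalized
#' by the number of windows `L - k + 1`; sums to 1. `k = 1` equals
#' [aa_composition()].
#'
#' @param seq protein sequence.
#' @param k word size, 1..3.
#' @return Named numeric vector of length `20^k`.
#' @export
kmer <- function(seq, k = 2L) {
  stopifnot(k >= 1L, k <= 3L)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < k) stop("kmer: sequence shorter than k")
  words <- vapply(seq_len(L - k + 1L),
                  function(i) paste(chars[i:(i + k - 1L)], collapse = ""),
                  character(1))
  lv <- all_kmers(k)
  counts <- table(factor(words, levels = lv))
  structure(as.numeric(counts) / (L - k + 1L), names = lv, encoder_id = paste0("kmer", k))
}

#' Distance-based residue (DR) features
#'
#' Co-occurrence counts of residues at sequence separations `d = 0..d_max`.
#' The layout implemented here: the `d = 0` block is the 20 single-residue
#' frequencies; each block `d >= 1` holds the 400 ordered residue pairs
#' `(a, b)` = (residue at i, residue at i + d), normalized by the number of
#' position pairs at that distance (`L - d`). Total length `20 + 400 d_max`.
#'
#' @param seq protein sequence.
#' @param d_max maximum separation (default 3); must be `< L`.
#' @return Named numeric vector of length `20 + 400 * d_max`.
#' @export
distance_residue <- function(seq, d_max = 3L) {
  stopifnot(d_max >= 0L)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L <= d_max) stop("distance_residue: sequence length must exceed d_max")
  out <- aa_composition(paste(chars, collapse = ""))
  names(out) <- paste0("d0.", names(out))
  if (d_max >= 1L) {
    pair_names <- as.vector(outer(AA_ALPHABET, AA_ALPHABET,
                                  function(a, b) paste0(a, b)))
    # outer varies rows fastest -> "AA","CA",... ; want "AA","AC",...:
    pair_names <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET,
                                    function(a, b) paste0(a, b))))
    for (d in seq_len(d_max)) {
      first <- chars[seq_len(L - d)]
      second <- chars[seq_len(L - d) + d]
      pairs <- paste0(first, second)
      counts <- table(factor(pairs, levels = pair_names))
      block <- as.numeric(counts) / (L - d)
      names(block) <- paste0("d", d, ".", pair_names)
      out <- c(out, block)
    }
  }
  attr(out, "encoder_id") <- paste0("dr", d_max)
  out
}

#' Distance-pair features (unordered variant)
#'
#' As [distance_residue()] but with unordered residue pairs: the `d = 0` block
#' is the 20 single-residue frequencies; each block `d >= 1` holds the 210
#' unordered pairs `{a, b}`, normalized by `L - d`. Total length
#' `20 + 210 d_max`.
#'
#' @inheritParams distance_residue
#' @return Named numeric vector of length `20 + 210 * d_max`.
#' @export
distance_pair <- function(seq, d_max = 3L) {
  stopifnot(d_max >= 0L)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L <= d_max) stop("distance_pair: sequence length must exceed d_max")
  out <- aa_composition(paste(chars, collapse = ""))
  names(out) <- paste0("d0.", names(out))
  if (d_max >= 1L) {
    combos <- outer(AA_ALPHABET, AA_ALPHABET, function(a, b)
      ifelse(a <= b, paste0(a, b), paste0(b, a)))
    pair_names <- sort(unique(as.vector(combos)))  # 210 unordered pairs
    for (d in seq_len(d_max)) {
      a <- chars[seq_len(L - d)]
      b <- chars[seq_len(L - d) + d]
      pairs <- ifelse(a <= b, paste0(a, b), paste0(b, a))
      counts <- table(factor(pairs, levels = pair_names))
      block <- as.numeric(counts) / (L - d)
      names(block) <- paste0("d", d, ".", pair_names)
      out <- c(out, block)
    }
  }
  attr(out, "encoder_id") <- paste0("dp", d_max)
  out
}

#' Auto covariance (AC) of physicochemical profiles
#'
#' For each index u and lag g in `1..lag_max`:
#' `AC(u, g) = mean over i of (P_u(i) - mean_u) (P_u(i+g) - mean_u)` with the
#' mean taken over the `L - g` position pairs and `mean_u` the sequence mean
#' of the standardized property profile `P_u`.
#'
#' @param seq protein sequence.
#' @param indices physicochemical index matrix (default [default_indices()]).
#' @param lag_max maximum lag (default 2); must be `< L`.
#' @return Named numeric vector of length `nrow(indices) * lag_max`.
#' @export
autocorrelation_AC <- function(seq, indices = default_indices(), lag_max = 2L) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (lag_max >= L) stop("autocorrelation_AC: lag_max must be < sequence length")
  P <- index_profile(chars, indices)
  out <- numeric(0)
  for (u in rownames(P)) {
    pu <- P[u, ]
    mu <- mean(pu)
    for (g in seq_len(lag_max)) {
      v <- mean((pu[seq_len(L - g)] - mu) * (pu[seq_len(L - g) + g] - mu))
      out[paste0("AC.", u, ".lag", g)] <- v
    }
  }
  attr(out, "encoder_id") <- "AC"
  out
}

#' Cross covariance (CC) of physicochemical profiles
#'
#' For each ordered pair of distinct indices (u1, u2) and lag g:
#' `CC(u1, u2, g) = mean over i of (P_u1(i) - mean_u1) (P_u2(i+g) - mean_u2)`.
#'
#' @inheritParams autocorrelation_AC
#' @return Named numeric vector of length
#'   `nrow(indices) * (nrow(indices) - 1) * lag_max`.
#' @export
autocorrelation_CC <- function(seq, indices = default_indices(), lag_max = 2L) {
  if (nrow(indices) < 2L) stop("autocorrelation_CC: needs at least 2 indices")
  chars <- seq_chars(seq)
  L <- length(chars)
  if (lag_max >= L) stop("autocorrelation_CC: lag_max must be < sequence length")
  P <- index_profile(chars, indices)
  out <- numeric(0)
  for (u1 in rownames(P)) for (u2 in rownames(P)) {
    if (u1 == u2) next
    p1 <- P[u1, ]; p2 <- P[u2, ]
    m1 <- mean(p1); m2 <- mean(p2)
    for (g in seq_len(lag_max)) {
      v <- mean((p1[seq_len(L - g)] - m1) * (p2[seq_len(L - g) + g] - m2))
      out[paste0("CC.", u1, ".", u2, ".lag", g)] <- v
    }
  }
  attr(out, "encoder_id") <- "CC"
  out
}

#' Auto-cross covariance (ACC)
#'
#' Concatenation of the AC block then the CC block; length
#' `nrow(indices)^2 * lag_max`.
#'
#' @inheritParams autocorrelation_AC
#' @export
autocorrelation_ACC <- function(seq, indices = default_indices(), lag_max = 2L) {
  out <- c(autocorrelation_AC(seq, indices, lag_max),
           autocorrelation_CC(seq, indices, lag_max))
  attr(out, "encoder_id") <- "ACC"
  out
}

#' Physicochemical distance transformation (PDT)
#'
#' For each index u and lag g: the mean over the `L - g` position pairs of
#' `(P_u(i) - P_u(i+g))^2 / 2` (squared-difference form); nonnegative, zero
#' on homopolymers.
#'
#' @inheritParams autocorrelation_AC
#' @export
pdt <- function(seq, indices = default_indices(), lag_max = 2L) {
  chars <- seq_chars(seq)
  L <- length(chars)
  if (lag_max >= L) stop("pdt: lag_max must be < sequence length")
  P <- index_profile(chars, indices)
  out <- numeric(0)
  for (u in rownames(P)) {
    pu <- P[u, ]
    for (g in seq_len(lag_max)) {
      v <- mean((pu[seq_len(L - g)] - pu[seq_len(L - g) + g])^2) / 2
      out[paste0("PDT.", u, ".lag", g)] <- v
    }
  }
  attr(out, "encoder_id") <- "PDT"
  out
}

# sequence-order correlation factors: theta_j pooled over indices (type I)
# or per index (type II); squared-difference correlation function.
pse_thetas <- function(chars, indices, lam, per_index = FALSE) {
  L <- length(chars)
  P <- index_profile(chars, indices)
  m <- nrow(P)
  if (per_index) {
    out <- numeric(0)
    for (j in seq_len(lam)) {
      for (u in rownames(P)) {
        pu <- P[u, ]
        out[paste0("lam", j, ".", u)] <-
          mean((pu[seq_len(L - j)] - pu[seq_len(L - j) + j])^2)
      }
    }
    out
  } else {
    vapply(seq_len(lam), function(j) {
      d2 <- (P[, seq_len(L - j), drop = FALSE] -
             P[, seq_len(L - j) + j, drop = FALSE])^2
      mean(colMeans(d2))
    }, numeric(1))
  }
}

#' Parallel-correlation pseudo amino-acid composition (PC-PseAAC, type I)
#'
#' Classic type-I pseudo-AAC: the first 20 entries are
#' `f_a / (sum f + w sum theta_j)` and the last `lam` entries
#' `w theta_j / (same denominator)`, where `f_a` are residue frequencies and
#' `theta_j = mean over i of Theta(R_i, R_{i+j})` with `Theta` the mean
#' squared difference of the standardized index values over the supplied
#' indices. The vector sums to 1. The "General" variant is this function with
#' a user-supplied index matrix.
#'
#' @param seq protein sequence.
#' @param indices physicochemical index matrix (default [default_indices()]).
#' @param lam number of sequence-order correlation factors; must be `< L`.
#' @param w weight of the correlation factors (default 0.05).
#' @return Named numeric vector of length `20 + lam`.
#' @export
pc_pseaac <- function(seq, indices = default_indices(), lam = 2L, w = 0.05) {
  stopifnot(w > 0, lam >= 0L)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (lam >= L) stop("pc_pseaac: lam must be < sequence length")
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET))) / L
  theta <- if (lam > 0L) pse_thetas(chars, indices, lam) else numeric(0)
  denom <- sum(f) + w * sum(theta)
  out <- c(setNames(f / denom, paste0("f.", AA_ALPHABET)),
           if (lam > 0L) setNames(w * theta / denom, paste0("theta.", seq_len(lam))))
  attr(out, "encoder_id") <- paste0("pc_pseaac", lam)
  out
}

#' Series-correlation pseudo amino-acid composition (SC-PseAAC, type II)
#'
#' Type-II pseudo-AAC: correlation factors kept separate per index, giving
#' `nrow(indices) * lam` tail entries ordered lag-major (all indices at lag 1,
#' then lag 2, ...). Per-index correlation is the squared difference of the
#' standardized values, so with a single index this reduces exactly to
#' [pc_pseaac()]. Normalization as in [pc_pseaac()]; sums to 1.
#'
#' @inheritParams pc_pseaac
#' @return Named numeric vector of length `20 + nrow(indices) * lam`.
#' @export
sc_pseaac <- function(seq, indices = default_indices(), lam = 2L, w = 0.05) {
  stopifnot(w > 0, lam >= 0L)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (lam >= L) stop("sc_pseaac: lam must be < sequence length")
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET))) / L
  tau <- if (lam > 0L) pse_thetas(chars, indices, lam, per_index = TRUE) else numeric(0)
  denom <- sum(f) + w * sum(tau)
  out <- c(setNames(f / denom, paste0("f.", AA_ALPHABET)),
           if (lam > 0L) setNames(w * tau / denom, paste0("tau.", names(tau))))
  attr(out, "encoder_id") <- paste0("sc_pseaac", lam)
  out
}

#' Catalog of the 22 named sequence-encoding methods
#'
#' The five-group catalog of the Pse-in-One encoder family. Groups 1-3
#' (amino-acid composition, autocorrelation, pseudo amino-acid composition)
#' are computable from sequence alone and are implemented here; the
#' profile-based group needs PSSMs from a PSI-BLAST database search and the
#' predicted-structure group needs secondary-structure / accessibility
#' predictors, so those entries are listed with `supported = FALSE`.
#'
#' @return data.frame with columns `name`, `group`, `supported` (22 rows,
#'   5 groups).
#' @export
method_catalog <- function() {
  g <- function(names, group, supported) {
    data.frame(name = names, group = group, supported = supported,
               stringsAsFactors = FALSE)
  }
  rbind(
    g(c("Kmer", "DR", "DistancePair"),
      "amino acid composition", TRUE),
    g(c("AC", "CC", "ACC", "PDT"),
      "autocorrelation", TRUE),
    g(c("PC-PseAAC", "SC-PseAAC", "PC-PseAAC-General", "SC-PseAAC-General"),
      "pseudo amino acid composition", TRUE),
    g(c("Top-n-gram", "PDT-Profile", "DT", "AC-PSSM", "CC-PSSM", "ACC-PSSM",
        "PSSM-DT", "PSSM-RT", "CS"),
      "profile-based", FALSE),
    g(c("SS", "SASA"),
      "predicted structure", FALSE)
  )
}

# dispatcher from catalog method names to encoder calls
pse_method_fun <- function(name) {
  switch(name,
    "Kmer"              = function(seq, p) kmer(seq, k = p$k %||% 2L),
    "DR"                = function(seq, p) distance_residue(seq, d_max = p$d_max %||% 3L),
    "DistancePair"      = function(seq, p) distance_pair(seq, d_max = p$d_max %||% 3L),
    "AC"                = function(seq, p) autocorrelation_AC(seq, p$indices %||% default_indices(), p$lag_max %||% 2L),
    "CC"                = function(seq, p) autocorrelation_CC(seq, p$indices %||% default_indices(), p$lag_max %||% 2L),
    "ACC"               = function(seq, p) autocorrelation_ACC(seq, p$indices %||% default_indices(), p$lag_max %||% 2L),
    "PDT"               = function(seq, p) pdt(seq, p$indices %||% default_indices(), p$lag_max %||% 2L),
    "PC-PseAAC"         = function(seq, p) pc_pseaac(seq, p$indices %||% default_indices(), p$lam %||% 2L, p$w %||% 0.05),
    "SC-PseAAC"         = function(seq, p) sc_pseaac(seq, p$indices %||% default_indices(), p$lam %||% 2L, p$w %||% 0.05),
    "PC-PseAAC-General" = function(seq, p) pc_pseaac(seq, p$indices %||% stop("PC-PseAAC-General requires user indices"), p$lam %||% 2L, p$w %||% 0.05),
    "SC-PseAAC-General" = function(seq, p) sc_pseaac(seq, p$indices %||% stop("SC-PseAAC-General requires user indices"), p$lam %||% 2L, p$w %||% 0.05),
    NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combined Pse-in-One feature vector
#'
#' Concatenates the outputs of the selected supported methods, in config
#' order, with dimension names prefixed by method. Selecting a profile-based
#' or predicted-structure method is an error naming the method and why it is
#' unsupported.
#'
#' @param seq protein sequence.
#' @param config list of method configs, each `list(method = <name>, ...)`
#'   with method-specific parameters (`k`, `d_max`, `lag_max`, `lam`, `w`,
#'   `indices`). Default: Kmer(k=2) + AC(lag 2) + PDT(lag 2) + PC-PseAAC(lam 2).
#' @return Named numeric vector.
#' @export
extract_pse_combined <- function(seq, config = default_pse_config()) {
  cat_tbl <- method_catalog()
  out <- numeric(0)
  for (entry in config) {
    m <- entry$method
    row <- cat_tbl[cat_tbl$name == m, ]
    if (nrow(row) == 0L) stop("extract_pse_combined: unknown method '", m, "'")
    if (!row$supported) {
      stop("extract_pse_combined: method '", m, "' is unsupported (group '",
           row$group, "' requires ",
           if (row$group == "profile-based") "PSSM profiles from PSI-BLAST"
           else "structure prediction", ")")
    }
    block <- pse_method_fun(m)(seq, entry)
    names(block) <- paste0(m, ".", names(block))
    out <- c(out, block)
  }
  attr(out, "encoder_id") <- "pse_combined"
  out
}

#' Default combined Pse-in-One configuration
#'
#' Kmer (k = 2, 400-D), AC (3 default indices, lag 2, 6-D), PDT (6-D) and
#' PC-PseAAC (lam = 2, w = 0.05, 22-D): 434 dimensions. The original
#' publication names the encoder family but not the members or parameters of
#' its combined vector; this profile is a documented default, not a
#' reproduction claim.
#'
#' @return List of method configs for [extract_pse_combined()].
#' @export
default_pse_config <- function() {
  list(list(method = "Kmer", k = 2L),
       list(method = "AC", lag_max = 2L),
       list(method = "PDT", lag_max = 2L),
       list(method = "PC-PseAAC", lam = 2L, w = 0.05))
}
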