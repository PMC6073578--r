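# Independent naive-loop oracles. Everything here is written with explicit
# per-character loops and no shared code with the package implementations,
# so agreement is a genuine cross-check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(L, freqs = NULL) {
  paste(sample(AA, L, replace = TRUE, prob = freqs), collapse = "")
}

oracle_aa_comp <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- setNames(numeric(20), AA)
  for (c in ch) out[c] <- out[c] + 1
  out / length(ch)
}

oracle_class_of <- function(c, part) {
  for (k in 1:3) if (c %in% part[[k]]) return(k)
  stop("unclassified residue ", c)
}

oracle_ctd_comp <- function(s, part) {
  ch <- strsplit(s, "")[[1]]
  out <- numeric(3)
  for (c in ch) out[oracle_class_of(c, part)] <- out[oracle_class_of(c, part)] + 1
  out / length(ch)
}

oracle_ctd_trans <- function(s, part) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  out <- numeric(3)  # pairs (1,2), (1,3), (2,3)
  for (i in 1:(L - 1)) {
    a <- oracle_class_of(ch[i], part)
    b <- oracle_class_of(ch[i + 1], part)
    p <- sort(c(a, b))
    if (p[1] == 1 && p[2] == 2) out[1] <- out[1] + 1
    if (p[1] == 1 && p[2] == 3) out[2] <- out[2] + 1
    if (p[1] == 2 && p[2] == 3) out[3] <- out[3] + 1
  }
  out / (L - 1)
}

oracle_ctd_dist <- function(s, part) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (k in 1:3) {
    pos <- c()
    for (i in seq_len(L)) if (oracle_class_of(ch[i], part) == k) pos <- c(pos, i)
    n <- length(pos)
    if (n == 0) {
      out <- c(out, rep(0, 5))
    } else {
      for (q in c(0, 0.25, 0.5, 0.75, 1)) {
        idx <- max(1, ceiling(q * n))
        out <- c(out, pos[idx] / L)
      }
    }
  }
  out
}

oracle_188d <- function(s, parts) {
  out <- oracle_aa_comp(s)
  for (p in parts) {
    out <- c(out, oracle_ctd_comp(s, p), oracle_ctd_trans(s, p),
             oracle_ctd_dist(s, p))
  }
  unname(out)
}

oracle_kmer <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  counts <- list()
  for (i in 1:(L - k + 1)) {
    w <- paste(ch[i:(i + k - 1)], collapse = "")
    counts[[w]] <- (counts[[w]] %||% 0) + 1
  }
  lv <- AA
  if (k >= 2) for (j in 2:k) lv <- as.vector(t(outer(lv, AA, paste0)))
  out <- setNames(numeric(length(lv)), lv)
  for (w in names(counts)) out[w] <- counts[[w]]
  out / (L - k + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_std_indices <- function(idx) {
  out <- idx
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    mu <- sum(v) / 20
    sdev <- sqrt(sum((v - mu)^2) / 20)
    out[r, ] <- (v - mu) / sdev
  }
  out
}

oracle_ac <- function(s, idx, lag_max) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  P <- oracle_std_indices(idx)
  out <- c()
  for (u in seq_len(nrow(P))) {
    pu <- sapply(ch, function(c) P[u, c])
    mu <- mean(pu)
    for (g in 1:lag_max) {
      acc <- 0
      for (i in 1:(L - g)) acc <- acc + (pu[i] - mu) * (pu[i + g] - mu)
      out <- c(out, acc / (L - g))
    }
  }
  unname(out)
}

oracle_cc <- function(s, idx, lag_max) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  P <- oracle_std_indices(idx)
  out <- c()
  for (u1 in seq_len(nrow(P))) for (u2 in seq_len(nrow(P))) {
    if (u1 == u2) next
    p1 <- sapply(ch, function(c) P[u1, c])
    p2 <- sapply(ch, function(c) P[u2, c])
    m1 <- mean(p1); m2 <- mean(p2)
    for (g in 1:lag_max) {
      acc <- 0
      for (i in 1:(L - g)) acc <- acc + (p1[i] - m1) * (p2[i + g] - m2)
      out <- c(out, acc / (L - g))
    }
  }
  unname(out)
}

oracle_pdt <- function(s, idx, lag_max) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  P <- oracle_std_indices(idx)
  out <- c()
  for (u in seq_len(nrow(P))) {
    pu <- sapply(ch, function(c) P[u, c])
    for (g in 1:lag_max) {
      acc <- 0
      for (i in 1:(L - g)) acc <- acc + (pu[i] - pu[i + g])^2
      out <- c(out, acc / (L - g) / 2)
    }
  }
  unname(out)
}

oracle_pc_pseaac <- function(s, idx, lam, w) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  P <- oracle_std_indices(idx)
  f <- setNames(numeric(20), AA)
  for (c in ch) f[c] <- f[c] + 1
  f <- f / L
  theta <- numeric(lam)
  for (j in seq_len(lam)) {
    acc <- 0
    for (i in 1:(L - j)) {
      corr <- 0
      for (u in seq_len(nrow(P))) corr <- corr + (P[u, ch[i]] - P[u, ch[i + j]])^2
      acc <- acc + corr / nrow(P)
    }
    theta[j] <- acc / (L - j)
  }
  denom <- sum(f) + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

oracle_sc_pseaac <- function(s, idx, lam, w) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  P <- oracle_std_indices(idx)
  f <- setNames(numeric(20), AA)
  for (c in ch) f[c] <- f[c] + 1
  f <- f / L
  tau <- c()
  for (j in seq_len(lam)) {
    for (u in seq_len(nrow(P))) {
      acc <- 0
      for (i in 1:(L - j)) acc <- acc + (P[u, ch[i]] - P[u, ch[i + j]])^2
      tau <- c(tau, acc / (L - j))
    }
  }
  denom <- sum(f) + w * sum(tau)
  unname(c(f / denom, w * tau / denom))
}

oracle_dr <- function(s, d_max) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  out <- unname(oracle_aa_comp(s))
  if (d_max >= 1) {
    pairs <- as.vector(t(outer(AA, AA, paste0)))
    for (d in 1:d_max) {
      counts <- setNames(numeric(400), pairs)
      for (i in 1:(L - d)) {
        w <- paste0(ch[i], ch[i + d])
        counts[w] <- counts[w] + 1
      }
      out <- c(out, unname(counts) / (L - d))
    }
  }
  out
}

oracle_skipgram <- function(s, max_skip) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  pairs <- as.vector(t(outer(AA, AA, paste0)))
  counts <- setNames(numeric(400), pairs)
  total <- 0
  for (gap in 0:max_skip) {
    d <- gap + 1
    if (L - d < 1) break
    for (i in 1:(L - d)) {
      w <- paste0(ch[i], ch[i + d])
      counts[w] <- counts[w] + 1
      total <- total + 1
    }
  }
  unname(counts) / total
}

# metrics from integer counts in exact rational terms: returns both a value
# and (num, den) pairs computed purely with integer arithmetic
oracle_metrics <- function(TP, FP, TN, FN) {
  frac <- function(num, den) if (den == 0) 0 else num / den
  SE <- frac(TP, TP + FN)
  SP <- frac(TN, TN + FP)
  ACC <- frac(TP + TN, TP + TN + FP + FN)
  mcc_den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)  # squared denom
  MCC <- if (mcc_den2 == 0) 0 else (TP * TN - FP * FN) / sqrt(mcc_den2)
  P <- frac(TP, TP + FP)
  R <- SE
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(SE = SE, SP = SP, ACC = ACC, MCC = MCC, Precision = P, Recall = R,
    F_measure = F1)
}

# AUC as the normalized Mann-Whitney U: fraction of (pos, neg) pairs with
# the positive scored higher, ties counting one half
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# brute-force all-pairs identity check used against greedy clustering
oracle_pairwise_identity <- function(a, b, k = 5) {
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    return(sum(ca == cb) / length(ca))
  }
  km <- function(s) {
    n <- nchar(s) - k + 1
    if (n < 1) return(character(0))
    unique(sapply(1:n, function(i) substr(s, i, i + k - 1)))
  }
  ka <- km(a); kb <- km(b)
  u <- length(union(ka, kb))
  if (u == 0) return(0)
  length(intersect(ka, kb)) / u
}
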