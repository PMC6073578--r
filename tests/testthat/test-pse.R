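idx <- default_indices()

test_that("index standardization gives mean 0 / population sd 1 per row", {
  S <- standardize_indices(idx)
  for (r in seq_len(nrow(S))) {
    expect_equal(mean(S[r, ]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((S[r, ] - mean(S[r, ]))^2)), 1, tolerance = 1e-9)
  }
  expect_identical(standardize_indices(S), S)  # idempotent via flag
})

test_that("kmer: k = 1 equals aa_composition, normalization, errors", {
  withr::with_seed(3, s <- rand_seq(40))
  expect_equal(as.numeric(kmer(s, 1L)), as.numeric(aa_composition(s)))
  v <- kmer("AAA", 2L)
  expect_equal(v[["AA"]], 1)
  expect_equal(sum(v), 1)
  expect_length(v, 400)
  expect_error(kmer("ACD", 4L))
  expect_error(kmer("AC", 3L), "shorter than k")
})

test_that("kmer agrees with the dictionary-count oracle", {
  withr::with_seed(4, seqs <- replicate(50, rand_seq(sample(10:60, 1))))
  for (s in seqs) {
    expect_equal(as.numeric(kmer(s, 2L)), as.numeric(oracle_kmer(s, 2)), tolerance = 1e-12)
  }
  expect_equal(as.numeric(kmer(seqs[[1]], 3L)), as.numeric(oracle_kmer(seqs[[1]], 3)),
               tolerance = 1e-12)
})

test_that("distance_residue: layout, d_max = 0 reduction, homopolymer mass", {
  withr::with_seed(6, s <- rand_seq(25))
  expect_equal(as.numeric(distance_residue(s, 0L)), as.numeric(aa_composition(s)))
  expect_length(distance_residue(s, 3L), 20 + 400 * 3)
  v <- distance_residue("AAAA", 2L)
  expect_equal(sum(v[grepl("^d0\\.A$|\\.AA$", names(v))]), sum(v))
  expect_error(distance_residue("ACD", 3L), "exceed d_max")
})

test_that("distance_residue and skipgram agree with pair-enumeration oracles", {
  withr::with_seed(10, seqs <- replicate(50, rand_seq(sample(10:40, 1))))
  for (s in seqs[1:10]) {
    expect_equal(as.numeric(distance_residue(s, 3L)), oracle_dr(s, 3), tolerance = 1e-12)
  }
  for (s in seqs) {
    expect_equal(as.numeric(skipgram_400(s, 2L)), oracle_skipgram(s, 2), tolerance = 1e-12)
  }
})

test_that("distance_pair is the unordered variant with 210 pairs per distance", {
  withr::with_seed(11, s <- rand_seq(30))
  v <- distance_pair(s, 2L)
  expect_length(v, 20 + 210 * 2)
  # folding the ordered variant onto unordered pairs must reproduce it
  dr <- distance_residue(s, 2L)
  for (d in 1:2) {
    for (a in c("A", "L")) for (b in c("C", "W")) {
      unord <- paste0("d", d, ".", min(a, b), max(a, b))
      ord1 <- paste0("d", d, ".", a, b)
      ord2 <- paste0("d", d, ".", b, a)
      expect_equal(v[[unord]], dr[[ord1]] + dr[[ord2]])
    }
  }
})

test_that("AC: homopolymer zeroes, period-2 sign pattern, oracle agreement", {
  expect_equal(max(abs(autocorrelation_AC(strrep("A", 30), idx, 4L))), 0)
  # alternating sequence of two residues separated by hydrophobicity:
  # lag-1 covariance negative, lag-2 positive
  s2 <- strrep("RI", 15)
  h <- idx["hydrophobicity", , drop = FALSE]
  v <- autocorrelation_AC(s2, h, 2L)
  expect_lt(v[[1]], 0)
  expect_gt(v[[2]], 0)
  withr::with_seed(12, seqs <- replicate(50, rand_seq(30)))
  for (s in seqs[1:15]) {
    expect_equal(as.numeric(autocorrelation_AC(s, h, 4L)), oracle_ac(s, h, 4),
                 tolerance = 1e-12)
  }
  expect_error(autocorrelation_AC("ACD", idx, 3L), "lag_max")
})

test_that("CC excludes self-pairs; ACC concatenates AC then CC; oracle agreement", {
  withr::with_seed(14, s <- rand_seq(30))
  two <- idx[1:2, , drop = FALSE]
  cc <- autocorrelation_CC(s, two, 3L)
  expect_length(cc, 2 * 1 * 3)
  expect_false(any(grepl("hydrophobicity\\.hydrophobicity", names(cc))))
  acc <- autocorrelation_ACC(s, two, 3L)
  expect_length(acc, 4 * 3)
  expect_equal(as.numeric(acc),
               c(as.numeric(autocorrelation_AC(s, two, 3L)), as.numeric(cc)))
  expect_equal(as.numeric(cc), oracle_cc(s, two, 3), tolerance = 1e-12)
  expect_error(autocorrelation_CC(s, idx[1, , drop = FALSE], 2L), "2 indices")
})

test_that("PDT: nonnegative, homopolymer zero, oracle agreement", {
  expect_equal(max(abs(pdt(strrep("C", 20), idx, 3L))), 0)
  withr::with_seed(15, seqs <- replicate(50, rand_seq(30)))
  for (s in seqs[1:15]) {
    expect_equal(as.numeric(pdt(s, idx, 3L)), oracle_pdt(s, idx, 3), tolerance = 1e-12)
  }
  for (s in seqs) expect_true(all(pdt(s, idx, 2L) >= 0))
})

test_that("pc_pseaac: length, normalization, homopolymer reduction, oracle", {
  withr::with_seed(16, s <- rand_seq(30))
  v <- pc_pseaac(s, idx, lam = 3L, w = 0.05)
  expect_length(v, 23)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  hp <- pc_pseaac(strrep("G", 25), idx, lam = 3L, w = 0.05)
  expect_equal(hp[["f.G"]], 1)
  expect_equal(as.numeric(hp[21:23]), c(0, 0, 0))
  expect_equal(as.numeric(v), oracle_pc_pseaac(s, idx, 3, 0.05), tolerance = 1e-12)
  expect_error(pc_pseaac("ACD", idx, lam = 5L), "lam")
})

test_that("sc_pseaac: length, one-index reduction to pc_pseaac, oracle", {
  withr::with_seed(17, s <- rand_seq(30))
  v <- sc_pseaac(s, idx, lam = 2L, w = 0.05)
  expect_length(v, 20 + 3 * 2)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  one <- idx[2, , drop = FALSE]
  expect_equal(as.numeric(sc_pseaac(s, one, lam = 3L, w = 0.1)),
               as.numeric(pc_pseaac(s, one, lam = 3L, w = 0.1)), tolerance = 1e-12)
  expect_equal(as.numeric(v), oracle_sc_pseaac(s, idx, 2, 0.05), tolerance = 1e-12)
})

test_that("pse oracle agreement holds across 50 random sequences per encoder", {
  withr::with_seed(18, seqs <- replicate(50, rand_seq(sample(15:50, 1))))
  h <- idx[1, , drop = FALSE]
  for (s in seqs) {
    expect_equal(as.numeric(autocorrelation_AC(s, h, 2L)), oracle_ac(s, h, 2),
                 tolerance = 1e-12)
    expect_equal(as.numeric(pdt(s, h, 2L)), oracle_pdt(s, h, 2), tolerance = 1e-12)
    expect_equal(as.numeric(pc_pseaac(s, idx, 2L, 0.05)),
                 oracle_pc_pseaac(s, idx, 2, 0.05), tolerance = 1e-12)
  }
})

test_that("method catalog lists 22 methods in 5 groups with support flags", {
  cat_tbl <- method_catalog()
  expect_identical(nrow(cat_tbl), 22L)
  expect_identical(length(unique(cat_tbl$group)), 5L)
  expect_false(any(cat_tbl$supported[cat_tbl$group %in%
                                     c("profile-based", "predicted structure")]))
  expect_true(all(cat_tbl$supported[!cat_tbl$group %in%
                                    c("profile-based", "predicted structure")]))
  expect_false(cat_tbl$supported[cat_tbl$name == "SS"])
  expect_false(cat_tbl$supported[cat_tbl$name == "SASA"])
})

test_that("extract_pse_combined concatenates in config order and rejects unsupported", {
  withr::with_seed(19, s <- rand_seq(40))
  v1 <- extract_pse_combined(s, list(list(method = "Kmer", k = 1L)))
  expect_length(v1, 20)
  v2 <- extract_pse_combined(s, list(list(method = "Kmer", k = 2L),
                                     list(method = "PC-PseAAC", lam = 2L)))
  expect_length(v2, 422)
  expect_equal(as.numeric(v2), c(as.numeric(kmer(s, 2L)), as.numeric(pc_pseaac(s, lam = 2L))))
  expect_true(all(startsWith(names(v2)[1:400], "Kmer.")))
  expect_error(extract_pse_combined(s, list(list(method = "AC-PSSM"))),
               "PSSM")
  expect_error(extract_pse_combined(s, list(list(method = "SS"))),
               "unsupported")
  expect_error(extract_pse_combined(s, list(list(method = "nope"))), "unknown")
})

test_that("encoders are deterministic and length-stable across input lengths", {
  withr::with_seed(20, {
    s1 <- rand_seq(35)
    s2 <- rand_seq(80)
  })
  for (f in list(function(s) kmer(s, 2L),
                 function(s) distance_residue(s, 3L),
                 function(s) autocorrelation_ACC(s, idx, 2L),
                 function(s) pc_pseaac(s, idx, 2L),
                 function(s) sc_pseaac(s, idx, 2L),
                 function(s) extract_pse_combined(s))) {
    expect_identical(length(f(s1)), length(f(s2)))
    expect_identical(f(s1), f(s1))
  }
})
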