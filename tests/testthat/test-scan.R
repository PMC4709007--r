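P_k1 <- build_profile(build_count_matrix(c("A", "A", "C", "G"), 1), 4)

test_that("best_kmer returns the leftmost maximum-likelihood window", {
  b <- best_kmer(P_k1, "WCA")
  expect_equal(b$kmer, "A")
  expect_equal(b$start, 3L)
  expect_equal(b$phi, 0.75)
  tie <- best_kmer(P_k1, "CWC")
  expect_equal(tie$kmer, "C")
  expect_equal(tie$start, 1L)
  expect_null(best_kmer(P_k1, "X"))
})

test_that("best_kmer equals the brute-force argmax on random instances", {
  set.seed(31)
  for (rep in 1:300) {
    k <- sample(1:8, 1); M <- sample(2:30, 1)
    P <- rand_profile(k, M)
    res <- rand_residues(sample(k:40, 1), p_noncanonical = 0.05)
    got <- best_kmer(P, res)
    want <- best_kmer_oracle(P, res)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$start, want$start)
      expect_identical(got$kmer, want$kmer)
      expect_equal(got$phi, want$phi, tolerance = 1e-9)
    }
  }
})

test_that("scan ranks by descending phi with id ties and reports skips", {
  prot <- seq_records(id = c("p_g", "p_a", "p_c", "p_x"),
                      residues = c("WGW", "DAD", "KCK", "XXX"))
  hits <- scan_proteome(P_k1, prot)
  # phi: A = 0.75, then the C/G tie at 0.5 ordered by protein id
  expect_equal(hits$protein_id, c("p_a", "p_c", "p_g"))
  expect_equal(hits$rank, 1:3)
  expect_equal(hits$phi, c(0.75, 0.5, 0.5))
  expect_equal(attr(hits, "skipped_ids"), "p_x")

  # identical sequences tie; ordering falls back to protein id
  same <- seq_records(id = c("z9", "a1", "m5"), residues = rep("WAW", 3))
  h2 <- scan_proteome(P_k1, same)
  expect_equal(h2$protein_id, c("a1", "m5", "z9"))

  # ranking is invariant to input order
  set.seed(32)
  prot2 <- generate_background(50, c(20, 30))
  h_fwd <- scan_proteome(P_k1, prot2)
  h_rev <- scan_proteome(P_k1, prot2[rev(seq_len(nrow(prot2))), ])
  expect_identical(h_fwd$protein_id, h_rev$protein_id)
  expect_identical(h_fwd$phi, h_rev$phi)

  expect_error(scan_proteome(P_k1, seq_records("only", "XXXX")), "no scannable")
})

test_that("3IQR threshold uses interpolated quartiles and strict exceedance", {
  t0 <- threshold_3iqr(rep(-5, 10))
  expect_equal(t0$cutoff_log10, -5)
  expect_equal(t0$iqr, 0)

  t1 <- threshold_3iqr(c(rep(-10, 9), -1))
  expect_equal(t1$q1, -10)
  expect_equal(t1$q3, -10)
  expect_equal(t1$cutoff_log10, -10)

  vals <- c(-4, -3, -2, -1)
  t2 <- threshold_3iqr(vals)
  # independent interpolated-quartile oracle (order statistics, type-7 rule)
  q <- function(p) { h <- (4 - 1) * p + 1
    sort(vals)[floor(h)] + (h - floor(h)) * (sort(vals)[ceiling(h)] - sort(vals)[floor(h)]) }
  expect_equal(t2$q1, q(0.25))
  expect_equal(t2$q3, q(0.75))
  expect_equal(t2$cutoff_log10, q(0.75) + 3 * (q(0.75) - q(0.25)))

  expect_error(threshold_3iqr(c(-1, -2, -3)), "too small")
})

test_that("reference 5% threshold interpolates best scores on the log scale", {
  # k = 1 profile: each single-letter reference sequence has a known score
  P <- build_profile(build_count_matrix(c(rep("A", 15), rep("C", 4), "G"), 1), 20)

  # all-equal reference scores: the cutoff is that value
  ref_same <- seq_records(id = sprintf("r%02d", 1:20), residues = rep("A", 20))
  t_same <- threshold_ref5(P, ref_same)
  expect_equal(t_same$cutoff_log10, log10(16 / 20))
  expect_equal(t_same$reference_size, 20)
  expect_warning(threshold_ref5(P, ref_same[1:5, ]), "unstable")

  # twenty distinct single-letter sequences: hand-interpolate the 5th percentile
  ref_all <- seq_records(id = sprintf("q%02d", 1:20), residues = AA_ALPHABET)
  t_all <- threshold_ref5(P, ref_all)
  vals <- sort(log10((build_count_matrix(c(rep("A", 15), rep("C", 4), "G"), 1)$counts[, 1] + 1) / 20))
  h <- (20 - 1) * 0.05 + 1
  want <- unname(vals[floor(h)] + (h - floor(h)) * (vals[ceiling(h)] - vals[floor(h)]))
  expect_equal(t_all$cutoff_log10, want, tolerance = 1e-12)
})

test_that("the 5th percentile on -1..-20 is -19.05", {
  # oracle for the interpolation rule used by threshold_ref5: index (n-1)*0.05
  vals <- seq(-1, -20)
  s <- sort(vals)
  h <- (20 - 1) * 0.05 + 1
  expect_equal(s[1] + (h - 1) * (s[2] - s[1]), -19.05)
  expect_equal(unname(quantile(vals, 0.05, type = 7)), -19.05)
})

test_that("outlier calls are strict and deduplication annotates duplicates", {
  hits <- data.frame(rank = 1:4,
                     protein_id = c("b", "a", "c", "d"),
                     kmer = c("AA", "AA", "CC", "DD"),
                     phi = c(1e-3, 1e-3, 1e-6, 1e-9),
                     log10_phi = c(-3, -3, -6, -9),
                     stringsAsFactors = FALSE)
  th <- structure(list(method = "iqr3", q1 = -9, q2 = -6, q3 = -6, iqr = 3,
                       cutoff_log10 = -4), class = "threshold_result")
  rep1 <- call_outliers(hits, th, dedup = TRUE)
  expect_equal(sum(rep1$hits$outlier_iqr3), 1)
  expect_equal(rep1$hits$protein_id[rep1$hits$outlier_iqr3], "a")
  expect_equal(rep1$hits$duplicate_of[rep1$hits$protein_id == "b"], "a")
  expect_true(all(is.na(rep1$hits$duplicate_of[rep1$hits$protein_id %in% c("a", "c", "d")])))

  # a hit exactly at the cutoff is not an outlier ("exceeding" is strict)
  th2 <- structure(list(method = "iqr3", cutoff_log10 = -3),
                   class = "threshold_result")
  rep2 <- call_outliers(hits, th2, dedup = FALSE)
  expect_equal(sum(rep2$hits$outlier_iqr3), 0)

  # decisions on log10 phi match decisions on phi (log is monotone)
  cut_lin <- 10^th$cutoff_log10
  expect_identical(rep1$hits$log10_phi > th$cutoff_log10,
                   rep1$hits$phi > cut_lin)
})

test_that("column scrambling permutes columns and preserves their contents", {
  set.seed(33)
  P <- rand_profile(3, 10)
  expect_equal(scramble_columns(P, perm = 1:3)$probs, P$probs)
  Ps <- scramble_columns(P, perm = c(3, 1, 2))
  expect_equal(Ps$probs[, 1], P$probs[, 3])
  expect_equal(Ps$probs[, 2], P$probs[, 1])
  expect_equal(Ps$probs[, 3], P$probs[, 2])
  expect_equal(Ps$M, P$M)
  # random permutation: column multiset preserved; consensus letters permuted
  P20 <- rand_profile(8, 15)
  Pr <- scramble_columns(P20)
  cols <- function(m) sort(apply(m, 2, paste, collapse = ","))
  expect_identical(cols(Pr$probs), cols(P20$probs))
  expect_identical(sort(strsplit(consensus(Pr), "")[[1]]),
                   sort(strsplit(consensus(P20), "")[[1]]))
})

test_that("scrambled control with a forced identity permutation reproduces the plain scan", {
  set.seed(34)
  bm <- make_benchmark(synthetic_spec(n_background = 200, n_planted = 3,
                                      length_range = c(40L, 80L),
                                      planted_consensus = "WHQKGDERACDE",
                                      subs_per_instance = 1L, seed = 35),
                       n_training = 40, training_length = 50)
  motif <- multi_restart(bm$training, discovery_config(k = 12, N = 500,
                                                       restarts = 5, seed = 36))
  hits <- scan_proteome(motif$profile, bm$proteome)
  n_plain <- sum(call_outliers(hits, threshold_3iqr(hits$log10_phi))$hits$outlier_iqr3)
  # identity "scramble": same outlier count
  with_identity <- local({
    Ps <- scramble_columns(motif$profile, perm = 1:12)
    h <- scan_proteome(Ps, bm$proteome)
    sum(call_outliers(h, threshold_3iqr(h$log10_phi))$hits$outlier_iqr3)
  })
  expect_equal(with_identity, n_plain)
  expect_gte(n_plain, 3)  # the carriers are found before scrambling
  # genuine scrambles on the decoys only: rate near zero
  set.seed(37)
  ctrl <- scrambled_control(motif$profile, bm$proteome[1:200, ], n_scrambles = 20)
  expect_lt(ctrl$fpr_percent, 0.5)
  expect_equal(ctrl$n_proteins, 200)
  expect_length(ctrl$per_scramble, 20)
})

test_that("N-terminal restriction keeps residues 2..k+1 and drops short sequences", {
  prot <- seq_records(id = c("long", "short"),
                      residues = c("MABCDEFGHIKLMNPQRSTVWY", "MACDEFGHIK"))
  expect_warning(out <- restrict_n_terminal(prot, 20), "dropping")
  expect_equal(nrow(out), 1)
  expect_identical(out$residues, substr("MABCDEFGHIKLMNPQRSTVWY", 2, 21))
  prot2 <- seq_records("x", "MABCDEFGH")
  expect_identical(restrict_n_terminal(prot2, 5)$residues, "ABCDE")
})
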