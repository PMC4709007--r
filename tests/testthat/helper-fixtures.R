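# Shared fixtures: everything is generated in code; no stored data.

# random residue string over the canonical alphabet, optionally salted with
# non-canonical letters
rand_residues <- function(n, p_noncanonical = 0) {
  letters <- sample(AA_ALPHABET, n, replace = TRUE)
  if (p_noncanonical > 0) {
    bad <- runif(n) < p_noncanonical
    letters[bad] <- sample(c("X", "B", "Z", "U"), sum(bad), replace = TRUE)
  }
  paste(letters, collapse = "")
}

# random profile built from a random training selection (valid by construction)
rand_profile <- function(k, M, mode = "paper") {
  kmers <- vapply(seq_len(M), function(i) rand_residues(k), character(1))
  build_profile(build_count_matrix(kmers, k), M, mode = mode)
}

# independent likelihood oracle: direct product of linear-space matrix entries,
# no log arithmetic, no shared indexing code
phi_oracle <- function(P, kmer) {
  letters <- strsplit(kmer, "", fixed = TRUE)[[1]]
  prod(vapply(seq_along(letters),
              function(i) P$probs[letters[i], i], numeric(1)))
}

# independent best-window oracle: enumerate substrings by hand and score each
# fully canonical one on the log10 scale (the scale the scan is defined on),
# keeping the leftmost maximum
best_kmer_oracle <- function(P, residues) {
  k <- P$k
  n <- nchar(residues)
  if (n < k) return(NULL)
  best <- NULL
  for (s in seq_len(n - k + 1L)) {
    txt <- substr(residues, s, s + k - 1L)
    if (grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), txt)) next
    letters <- strsplit(txt, "", fixed = TRUE)[[1]]
    lp <- sum(vapply(seq_len(k),
                     function(i) log10(P$probs[letters[i], i]), numeric(1)))
    if (is.null(best) || lp > best$log10_phi)
      best <- list(start = s, kmer = txt, log10_phi = lp, phi = 10^lp)
  }
  best
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# small planted training set used by several discovery tests
small_planted_set <- function(n = 30, len = 60, consensus = "HQLKGSSSSIG",
                              s = 1, seed = 99) {
  set.seed(seed)
  seqs <- generate_background(n, c(len, len), prefix = "tr")
  plant_motif(seqs, consensus, s)
}
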