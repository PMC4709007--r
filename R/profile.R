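#' Build an occurrence-count matrix from aligned k-mers
#'
#' Tabulates, for residue j and motif position i, the number of k-mers
#' carrying residue j at position i. Each training sequence contributes at
#' most one k-mer, so every column sums to the number of k-mers.
#'
#' @param kmers character vector of k-mer texts, all of length `k`, containing
#'   only canonical residues (pre-filter with [enumerate_valid_kmers()]).
#' @param k motif length (columns).
#' @return an object of class `count_matrix`: list with `k`, `n_kmers`, and
#'   `counts`, a 20 x k integer matrix with rows named by [AA_ALPHABET].
#' @export
build_count_matrix <- function(kmers, k) {
  stopifnot(is.numeric(k), k >= 1)
  k <- as.integer(k)
  counts <- matrix(0L, nrow = 20L, ncol = k,
                   dimnames = list(AA_ALPHABET, NULL))
  if (length(kmers)) {
    if (any(nchar(kmers) != k)) stop("all k-mers must have length k = ", k)
    idx <- aa_index(unlist(strsplit(kmers, "", fixed = TRUE), use.names = FALSE))
    if (anyNA(idx)) {
      bad <- unique(unlist(strsplit(kmers, "", fixed = TRUE))[is.na(idx)])
      stop("k-mer(s) contain non-canonical letter(s): ",
           paste(bad, collapse = ", "), " (pre-filter with enumerate_valid_kmers)")
    }
    pos <- rep(seq_len(k), times = length(kmers))
    tab <- table(factor(idx, levels = 1:20), factor(pos, levels = seq_len(k)))
    counts[] <- as.integer(tab)
  }
  structure(list(k = k, n_kmers = length(kmers), counts = counts),
            class = "count_matrix")
}

#' Build a pseudocount probability matrix from counts
#'
#' The occurrence model adds a +1 pseudocount to every cell so that no residue
#' has zero probability anywhere. Two denominators are offered:
#' \describe{
#'   \item{`paper`}{`P[j,i] = (m_ji + 1) / M`, where `M` is the training-set
#'     size. Columns sum to `(M + 20) / M` (slightly above 1); this is the
#'     default because it keeps likelihood values on the scale the occurrence
#'     model defines.}
#'   \item{`normalized`}{`P[j,i] = (m_ji + 1) / (M + 20)`; columns sum to 1.
#'     For any k-mer, the paper-mode likelihood equals the normalized-mode
#'     likelihood times `((M + 20) / M)^k`, so rankings are identical.}
#' }
#'
#' @param counts a `count_matrix`.
#' @param M training-set size used as the pseudocount denominator (>= 1).
#' @param mode `"paper"` (default) or `"normalized"`.
#' @param provenance optional named list of training metadata (algorithm,
#'   seed, iterations, source file) carried along for serialization.
#' @return an object of class `profile_matrix`: list with `k`, `M`, `mode`,
#'   `probs` (20 x k double matrix), `log10_probs`, and `provenance`.
#' @export
build_profile <- function(counts, M, mode = c("paper", "normalized"),
                          provenance = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "count_matrix"), is.numeric(M))
  if (M < 1) stop("empty training set (M = 0)")
  M <- as.integer(M)
  if (any(colSums(counts$counts) > M))
    stop("count column sums exceed M; each training sequence contributes at most one k-mer")
  denom <- if (mode == "paper") M else M + 20L
  probs <- (counts$counts + 1) / denom
  structure(list(k = counts$k, M = M, mode = mode, probs = probs,
                 log10_probs = log10(probs), provenance = provenance),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: k = %d, M = %d, mode = %s\n", x$k, x$M, x$mode))
  cat(sprintf("consensus: %s\n", consensus(x)))
  if (length(x$provenance))
    cat("provenance:", paste(names(x$provenance),
                             vapply(x$provenance, function(v) paste(format(v), collapse = ","), ""),
                             sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' k-mer likelihood under a profile matrix
#'
#' The likelihood of k-mer `X = (x_1, ..., x_k)` is the product of its
#' per-position matrix entries, `phi(X) = prod_i P[x_i, i]`. All arithmetic is
#' done in log10 space (proteome-scale values reach 1e-50 territory);
#' [log10_likelihood()] returns the sum of log10 entries and [likelihood()]
#' exponentiates it.
#'
#' In paper mode the value lies in `[(1/M)^k, ((M+1)/M)^k]`; pseudocounts
#' guarantee the log10 value is finite.
#'
#' @param P a `profile_matrix`.
#' @param kmer_text a string of length `P$k` over the canonical alphabet.
#' @return a positive real (`likelihood`) or a finite real (`log10_likelihood`).
#' @export
likelihood <- function(P, kmer_text) 10^log10_likelihood(P, kmer_text)

#' @rdname likelihood
#' @export
log10_likelihood <- function(P, kmer_text) {
  stopifnot(inherits(P, "profile_matrix"), is.character(kmer_text),
            length(kmer_text) == 1L)
  if (nchar(kmer_text) != P$k)
    stop(sprintf("k-mer length %d does not match profile k = %d",
                 nchar(kmer_text), P$k))
  idx <- aa_index(kmer_text, split = TRUE)
  if (anyNA(idx)) stop("k-mer contains non-canonical letter(s): ", kmer_text)
  sum(P$log10_probs[cbind(idx, seq_len(P$k))])
}

#' Consensus sequence of a motif
#'
#' Per column, the residue most likely to occur (argmax of the column); ties
#' are broken by the earliest letter in [AA_ALPHABET] order, which makes the
#' consensus deterministic.
#'
#' @param x a `profile_matrix` or `count_matrix`.
#' @return a string of length `k`.
#' @export
consensus <- function(x) {
  m <- if (inherits(x, "profile_matrix")) x$probs
       else if (inherits(x, "count_matrix")) x$counts
       else stop("need a profile_matrix or count_matrix")
  # max.col(ties.method = "first") on the transpose = per-column first argmax
  paste(AA_ALPHABET[max.col(t(m), ties.method = "first")], collapse = "")
}

#' Total mismatch score of a k-mer selection against a consensus
#'
#' The sum over all selected k-mers of the Hamming distance to the consensus
#' sequence. Multi-restart motif discovery ranks restarts by this score
#' (smaller is better: the selected k-mers agree more with each other).
#'
#' @param consensus a string of length k.
#' @param kmers character vector of k-mer texts, all of length k.
#' @return a non-negative integer.
#' @export
mismatch_score <- function(consensus, kmers) {
  k <- nchar(consensus)
  if (length(kmers) == 0L) return(0L)
  if (any(nchar(kmers) != k)) stop("k-mer length does not match consensus length ", k)
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  sum(vapply(strsplit(kmers, "", fixed = TRUE),
             function(x) sum(x != cons), integer(1)))
}

#' Per-column information content (bits)
#'
#' For sequence-logo style summaries: column i carries
#' `log2(20) + sum_j f_ji * log2(f_ji)` bits, where `f = (m + 1) / (M + 20)`
#' are the normalized pseudocount frequencies. Values range from 0 (uniform
#' column) to `log2(20) ~ 4.32` (fully conserved in the no-pseudocount limit).
#' Normalized frequencies are used regardless of the profile mode: entropy of
#' an unnormalized column is undefined.
#'
#' @param counts a `count_matrix`.
#' @param M training-set size (>= 1).
#' @return numeric vector of length k, in bits.
#' @export
column_information <- function(counts, M) {
  stopifnot(inherits(counts, "count_matrix"), M >= 1)
  f <- (counts$counts + 1) / (M + 20)
  f <- sweep(f, 2, colSums(f), "/")  # guard partially filled columns
  log2(20) + colSums(f * log2(f))
}

#' Recover counts from a paper-mode profile
#'
#' Inverts `P = (m + 1)/M` as `m = round(P * M - 1)`; exact for matrices the
#' package built itself.
#'
#' @param P a paper-mode `profile_matrix`.
#' @return a `count_matrix`.
#' @keywords internal
profile_to_counts <- function(P) {
  stopifnot(inherits(P, "profile_matrix"), P$mode == "paper")
  counts <- matrix(as.integer(round(P$probs * P$M - 1)), nrow = 20L, ncol = P$k,
                   dimnames = list(AA_ALPHABET, NULL))
  n <- unique(colSums(counts))
  structure(list(k = P$k, n_kmers = if (length(n) == 1L) n else NA_integer_,
                 counts = counts),
            class = "count_matrix")
}
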