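#' Enumerate the valid k-mers of a sequence
#'
#' All substrings of length k consisting only of canonical residues, in
#' left-to-right order. Windows touching a non-canonical letter (X, B, Z, J,
#' U, O, ...) are excluded because no matrix row exists for those letters.
#'
#' @param residues a sanitized residue string (see [sanitize_residues()]).
#' @param k motif length.
#' @return data.frame with columns `start` (1-based) and `text`; zero rows if
#'   the sequence is shorter than k or has no fully canonical window.
#' @export
enumerate_valid_kmers <- function(residues, k) {
  w <- .seq_windows(residues, k)
  if (is.null(w)) return(data.frame(start = integer(), text = character(),
                                    stringsAsFactors = FALSE))
  data.frame(start = w$starts,
             text = substring(residues, w$starts, w$starts + k - 1L),
             stringsAsFactors = FALSE)
}

# Precompute the scoring scaffold of one sequence: residue indices, the valid
# window starts, and an m x k matrix of linear indices into a flattened 20 x k
# score matrix. This is the hot path shared by discovery and scanning; a
# window's score is then .rowSums(Lvec[lin], m, k).
.seq_windows <- function(residues, k) {
  n <- nchar(residues)
  if (n < k) return(NULL)
  idx <- aa_index(residues, split = TRUE)
  m <- n - k + 1L
  # a window starting at s is valid iff no NA among idx[s..s+k-1]
  bad <- is.na(idx)
  if (any(bad)) {
    run <- cumsum(bad)
    valid <- (run[seq_len(m) + k - 1L] - c(0L, run)[seq_len(m)]) == 0L
  } else {
    valid <- rep(TRUE, m)
  }
  starts <- which(valid)
  if (length(starts) == 0L) return(NULL)
  offs <- matrix(rep(starts, times = k) + rep(0L:(k - 1L), each = length(starts)),
                 nrow = length(starts), ncol = k)
  lin <- matrix(idx[offs], nrow = length(starts), ncol = k) +
    rep((0L:(k - 1L)) * 20L, each = length(starts))
  list(starts = starts, lin = lin, m = length(starts))
}

# Score every valid window of a precomputed scaffold against a flattened
# 20 x k log10 matrix.
.window_scores <- function(w, log10_vec) {
  .rowSums(log10_vec[w$lin], w$m, ncol(w$lin))
}

# Build per-sequence scaffolds for a sequence table; returns NULL entries for
# ineligible sequences (shorter than k, or no fully canonical window).
.build_scaffolds <- function(seqs, k) {
  lapply(seqs$residues, .seq_windows, k = k)
}
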