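#' Specification of a synthetic planted-motif data set
#'
#' Describes an i.i.d. background proteome with a degenerate planted motif:
#' background residues are drawn independently from `background_freqs`
#' (uniform 1/20 by default, the implicit null of the occurrence model), and
#' each planted instance is the consensus with exactly `subs_per_instance`
#' positions substituted by a uniformly chosen different residue, overwritten
#' at a uniformly chosen window of a carrier sequence.
#'
#' @param n_background number of background sequences.
#' @param length_range integer pair (min, max) of sequence lengths; min must
#'   be at least the consensus length when motifs are planted.
#' @param background_freqs 20-vector of residue frequencies summing to 1
#'   (order [AA_ALPHABET]).
#' @param planted_consensus motif consensus string (length k).
#' @param n_planted number of sequences carrying one instance each.
#' @param subs_per_instance substitutions per planted instance (0..k).
#' @param seed RNG seed; generation is byte-deterministic given it.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_background = 2000L,
                           length_range = c(80L, 300L),
                           background_freqs = rep(1 / 20, 20),
                           planted_consensus = "DFKKVDPHVHQLKGSSSSIG",
                           n_planted = 5L,
                           subs_per_instance = 2L,
                           seed = 1L) {
  stopifnot(length(background_freqs) == 20,
            abs(sum(background_freqs) - 1) < 1e-9,
            all(background_freqs >= 0),
            length(length_range) == 2, length_range[1] <= length_range[2])
  k <- nchar(planted_consensus)
  if (subs_per_instance > k) stop("subs_per_instance exceeds motif length")
  if (n_planted > 0 && length_range[1] < k)
    stop("minimum length must be >= motif length for planted sequences")
  if (is.na(aa_index(planted_consensus, split = TRUE)[1]) ||
      anyNA(aa_index(planted_consensus, split = TRUE)))
    stop("planted_consensus must use canonical residues only")
  structure(list(n_background = as.integer(n_background),
                 length_range = as.integer(length_range),
                 background_freqs = background_freqs,
                 planted_consensus = planted_consensus,
                 n_planted = as.integer(n_planted),
                 subs_per_instance = as.integer(subs_per_instance),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate i.i.d. background sequences
#'
#' @param n number of sequences.
#' @param length_range integer pair (min, max); lengths are uniform in it.
#' @param background_freqs 20-vector of residue frequencies.
#' @param prefix id prefix; ids are `<prefix>_0001`, ...
#' @return a sequence table with `source = "synthetic"`.
#' @export
generate_background <- function(n, length_range = c(80L, 300L),
                                background_freqs = rep(1 / 20, 20),
                                prefix = "bg") {
  stopifnot(n >= 1, length(background_freqs) == 20,
            abs(sum(background_freqs) - 1) < 1e-9)
  lens <- if (length_range[1] == length_range[2]) rep(length_range[1], n)
          else sample(length_range[1]:length_range[2], n, replace = TRUE)
  letters20 <- AA_ALPHABET
  res <- vapply(lens, function(L)
    paste(sample(letters20, L, replace = TRUE, prob = background_freqs),
          collapse = ""), character(1))
  width <- max(4L, nchar(as.character(n)))
  seq_records(id = sprintf(paste0(prefix, "_%0", width, "d"), seq_len(n)),
              residues = res, description = "synthetic background",
              source = "synthetic")
}

#' Plant one degenerate motif instance into each sequence
#'
#' Each instance is the consensus with exactly `s` distinct positions
#' (uniformly chosen) substituted by a uniformly chosen different residue,
#' written over a uniformly chosen window of the sequence. The Hamming
#' distance of every instance to the consensus is exactly `s` by
#' construction.
#'
#' @param seqs a sequence table; every sequence must be at least as long as
#'   the consensus.
#' @param consensus the motif consensus string.
#' @param s substitutions per instance (0..k).
#' @return `seqs` with motifs planted; attribute `ground_truth` is a
#'   data.frame with `id`, `start` (1-based) and `planted_text`.
#' @export
plant_motif <- function(seqs, consensus, s = 2L) {
  k <- nchar(consensus)
  if (s > k) stop("s exceeds motif length")
  if (any(nchar(seqs$residues) < k))
    stop("all target sequences must be at least as long as the consensus")
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  gt <- data.frame(id = seqs$id, start = NA_integer_,
                   planted_text = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(seqs))) {
    inst <- cons
    if (s > 0) {
      pos <- sample.int(k, s)
      for (p in pos) inst[p] <- sample(setdiff(AA_ALPHABET, cons[p]), 1L)
    }
    text <- paste(inst, collapse = "")
    L <- nchar(seqs$residues[i])
    start <- if (L == k) 1L else sample.int(L - k + 1L, 1L)
    substr(seqs$residues[i], start, start + k - 1L) <- text
    gt$start[i] <- start
    gt$planted_text[i] <- text
  }
  attr(seqs, "ground_truth") <- gt
  seqs
}

#' Build a planted-motif benchmark with known ground truth
#'
#' Bundles background generation and motif planting into (a) a training set
#' of `n_training` sequences each carrying one instance, and (b) a decoy
#' proteome of `spec$n_background` clean sequences plus `spec$n_planted`
#' carriers. The ground truth of every planted window is returned, so
#' discovery and scanning can be validated end to end without any external
#' data.
#'
#' @param spec a `synthetic_spec`.
#' @param n_training number of planted training sequences (default 100).
#' @param training_length length of each training sequence (default 120).
#' @return a list of class `motif_benchmark`: `training` (sequence table with
#'   ground truth attribute), `proteome`, `training_truth`, `proteome_truth`,
#'   `spec`.
#' @export
make_benchmark <- function(spec = synthetic_spec(), n_training = 100L,
                           training_length = 120L) {
  stopifnot(inherits(spec, "synthetic_spec"), training_length >= nchar(spec$planted_consensus))
  set.seed(spec$seed)
  training <- generate_background(n_training,
                                  length_range = c(training_length, training_length),
                                  background_freqs = spec$background_freqs,
                                  prefix = "train")
  training <- plant_motif(training, spec$planted_consensus, spec$subs_per_instance)
  proteome <- if (spec$n_background > 0)
    generate_background(spec$n_background,
                        length_range = spec$length_range,
                        background_freqs = spec$background_freqs,
                        prefix = "bg")
  proteome_truth <- NULL
  if (spec$n_planted > 0) {
    carriers <- generate_background(spec$n_planted,
                                    length_range = spec$length_range,
                                    background_freqs = spec$background_freqs,
                                    prefix = "carrier")
    carriers <- plant_motif(carriers, spec$planted_consensus, spec$subs_per_instance)
    proteome_truth <- attr(carriers, "ground_truth")
    attr(carriers, "ground_truth") <- NULL
    proteome <- rbind(proteome, carriers)
    row.names(proteome) <- NULL
  }
  if (is.null(proteome))
    stop("benchmark needs n_background > 0 or n_planted > 0 for a proteome")
  structure(list(training = training,
                 training_truth = attr(training, "ground_truth"),
                 proteome = proteome,
                 proteome_truth = proteome_truth,
                 spec = spec),
            class = "motif_benchmark")
}
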