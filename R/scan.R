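#' Profile-most-probable k-mer of one protein
#'
#' The valid k-mer of the sequence with maximal likelihood under `P`
#' (leftmost on ties). This single k-mer represents the protein in a proteome
#' scan.
#'
#' @param P a `profile_matrix`.
#' @param residues a sanitized residue string.
#' @return a one-row data.frame with `start` (1-based), `kmer`, `phi`,
#'   `log10_phi`; or `NULL` if the sequence has no valid k-mer.
#' @export
best_kmer <- function(P, residues) {
  w <- .seq_windows(residues, P$k)
  if (is.null(w)) return(NULL)
  scores <- .window_scores(w, as.vector(P$log10_probs))
  i <- which.max(scores)
  data.frame(start = w$starts[i],
             kmer = substring(residues, w$starts[i], w$starts[i] + P$k - 1L),
             phi = 10^scores[i], log10_phi = scores[i],
             stringsAsFactors = FALSE)
}

#' Scan a proteome against a motif profile
#'
#' Scores every protein by its profile-most-probable k-mer and ranks proteins
#' by descending likelihood; equal likelihoods are ordered by protein id so
#' the ranking is deterministic and invariant to input order. Proteins with
#' no valid k-mer (shorter than k, or every window touching a non-canonical
#' letter) are skipped and reported via the `skipped_ids` attribute.
#'
#' @param P a `profile_matrix`.
#' @param proteome a sequence table (see [seq_records()] / [read_fasta()]).
#' @return a data.frame of hits with columns `rank`, `protein_id`,
#'   `description`, `kmer`, `start` (1-based), `phi`, `log10_phi`, sorted by
#'   rank; attribute `skipped_ids` lists unscannable proteins.
#' @export
scan_proteome <- function(P, proteome) {
  stopifnot(inherits(P, "profile_matrix"), nrow(proteome) > 0L)
  hits <- lapply(proteome$residues, best_kmer, P = P)
  ok <- !vapply(hits, is.null, logical(1))
  if (!any(ok)) stop("no scannable protein in the proteome (k = ", P$k, ")")
  df <- do.call(rbind, hits[ok])
  df <- data.frame(protein_id = proteome$id[ok],
                   description = proteome$description[ok],
                   df, stringsAsFactors = FALSE)
  ord <- order(-df$log10_phi, df$protein_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- data.frame(rank = seq_len(nrow(df)), df, row.names = NULL,
                   stringsAsFactors = FALSE)
  attr(df, "skipped_ids") <- proteome$id[!ok]
  df
}

#' 3*IQR outlier threshold on the log10 likelihood scale
#'
#' Computes Q1 and Q3 of the log10 likelihood distribution by linear
#' interpolation of order statistics (`stats::quantile` type 7) and sets the
#' cutoff at `Q3 + 3 * (Q3 - Q1)`. A hit is an outlier only if its log10
#' likelihood strictly exceeds the cutoff.
#'
#' @param log10_phis numeric vector of log10 likelihoods (>= 4 values).
#' @return a list of class `threshold_result` with `method = "iqr3"`, `q1`,
#'   `q2`, `q3`, `iqr`, and `cutoff_log10`.
#' @export
threshold_3iqr <- function(log10_phis) {
  if (length(log10_phis) < 4L) stop("distribution too small (need >= 4 values)")
  q <- stats::quantile(log10_phis, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(method = "iqr3", q1 = q[1], q2 = q[2], q3 = q[3],
                 iqr = q[3] - q[1],
                 cutoff_log10 = q[3] + 3 * (q[3] - q[1])),
            class = "threshold_result")
}

#' Reference 5th-percentile threshold
#'
#' Applies the profile back to its own reference family: every reference
#' sequence is scored by its profile-most-probable k-mer, and the cutoff is
#' the 5th percentile of those log10 likelihoods (linear interpolation on the
#' log scale). Unlike the 3*IQR rule, this threshold does not depend on the
#' queried proteome, so it can also score single sequences.
#'
#' @param P a `profile_matrix`.
#' @param reference the reference sequence table the profile was trained on.
#' @return a `threshold_result` with `method = "ref5"`, `cutoff_log10`, and
#'   `reference_size`.
#' @export
threshold_ref5 <- function(P, reference) {
  stopifnot(nrow(reference) > 0L)
  hits <- lapply(reference$residues, best_kmer, P = P)
  vals <- vapply(hits[!vapply(hits, is.null, logical(1))],
                 function(h) h$log10_phi, numeric(1))
  if (length(vals) == 0L) stop("no scorable sequence in the reference set")
  if (length(vals) < 20L)
    warning("fewer than 20 reference sequences; 5th percentile is unstable")
  structure(list(method = "ref5",
                 cutoff_log10 = stats::quantile(vals, 0.05, names = FALSE, type = 7),
                 reference_size = length(vals)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$method == "iqr3")
    cat(sprintf("threshold iqr3: Q1 = %.4f, Q3 = %.4f, IQR = %.4f, cutoff log10(phi) = %.4f\n",
                x$q1, x$q3, x$iqr, x$cutoff_log10))
  else
    cat(sprintf("threshold ref5: cutoff log10(phi) = %.4f (reference n = %d)\n",
                x$cutoff_log10, x$reference_size))
  invisible(x)
}

#' Call outlier proteins from a ranked scan
#'
#' Flags every hit whose log10 likelihood strictly exceeds each threshold's
#' cutoff. With `dedup = TRUE`, hits that share an identical motif k-mer and
#' likelihood (relative difference below 1e-12) are collapsed: only the first
#' by protein id is flagged, the rest carry its id in `duplicate_of`. Such
#' duplicates typically represent splicing variants or redundant proteome
#' entries; gene-level annotation, which plain FASTA lacks, is not consulted.
#'
#' @param hits a scan table from [scan_proteome()].
#' @param thresholds a `threshold_result` or list of them (one per method).
#' @param dedup collapse duplicate hits before flagging (default `TRUE`).
#' @return an object of class `outlier_report`: list with `hits` (the scan
#'   table plus one logical `outlier_<method>` column per threshold and a
#'   `duplicate_of` column), `thresholds`, and `dedup_applied`.
#' @export
call_outliers <- function(hits, thresholds, dedup = TRUE) {
  if (inherits(thresholds, "threshold_result")) thresholds <- list(thresholds)
  dup_of <- rep(NA_character_, nrow(hits))
  if (dedup && nrow(hits) > 1L) {
    ord <- order(hits$kmer, hits$protein_id, method = "radix")
    h <- hits[ord, ]
    same <- h$kmer[-1] == h$kmer[-nrow(h)] &
      abs(h$log10_phi[-1] - h$log10_phi[-nrow(h)]) <=
        1e-12 * pmax(abs(h$log10_phi[-1]), abs(h$log10_phi[-nrow(h)]), 1e-300)
    grp <- cumsum(c(TRUE, !same))
    first <- h$protein_id[!duplicated(grp)][grp]
    dup_of[ord] <- ifelse(first == h$protein_id, NA_character_, first)
  }
  eligible <- is.na(dup_of)
  out <- hits
  for (th in thresholds) {
    out[[paste0("outlier_", th$method)]] <-
      eligible & (hits$log10_phi > th$cutoff_log10)
  }
  out$duplicate_of <- dup_of
  structure(list(hits = out, thresholds = thresholds, dedup_applied = dedup),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  for (th in x$thresholds) {
    col <- paste0("outlier_", th$method)
    n <- sum(x$hits[[col]])
    cat(sprintf("%s: %d outlier(s) above log10(phi) = %.4f\n",
                th$method, n, th$cutoff_log10))
    if (n > 0) {
      top <- x$hits[x$hits[[col]], c("rank", "protein_id", "kmer", "phi")]
      print(utils::head(top, 10), row.names = FALSE)
    }
  }
  if (x$dedup_applied)
    cat(sprintf("duplicates annotated: %d\n", sum(!is.na(x$hits$duplicate_of))))
  invisible(x)
}

#' Scramble the columns of a profile matrix
#'
#' Applies a uniformly random permutation to the column order of `P`, leaving
#' each column's 20 values intact. Positional structure is destroyed while
#' the per-position residue composition is preserved, giving a matched
#' negative-control matrix.
#'
#' @param P a `profile_matrix`.
#' @param perm optional explicit permutation of `1:k` (e.g. `1:k` for the
#'   identity); drawn uniformly at random if missing.
#' @return a `profile_matrix` with permuted columns; `M`, `k` and mode are
#'   preserved and the permutation is recorded in the provenance.
#' @export
scramble_columns <- function(P, perm = NULL) {
  stopifnot(inherits(P, "profile_matrix"))
  if (is.null(perm)) perm <- sample.int(P$k)
  stopifnot(length(perm) == P$k, all(sort(perm) == seq_len(P$k)))
  out <- P
  out$probs <- P$probs[, perm, drop = FALSE]
  out$log10_probs <- P$log10_probs[, perm, drop = FALSE]
  out$provenance <- c(P$provenance, list(scramble_perm = perm))
  out
}

#' Column-scrambling false-positive control
#'
#' Repeatedly scrambles the profile's columns, rescans the proteome with each
#' scrambled matrix, and counts outlier calls. The false-positive rate is the
#' total number of calls divided by (number of scrambles x number of scanned
#' proteins), reported as a percentage. A specific signature should lose its
#' detection power when its positional structure is destroyed, so this rate
#' should be near zero.
#'
#' @param P a `profile_matrix`.
#' @param proteome a sequence table.
#' @param n_scrambles number of scrambled matrices (default 100).
#' @param threshold_method `"iqr3"` (cutoff recomputed per scramble) or
#'   `"ref5"` (fixed cutoff from `reference`).
#' @param reference reference sequence table, required for `"ref5"`.
#' @param dedup passed to [call_outliers()].
#' @return a list of class `scramble_control`: `fpr_percent`, `total_calls`,
#'   `n_scrambles`, `n_proteins`, and `per_scramble` counts.
#' @export
scrambled_control <- function(P, proteome, n_scrambles = 100L,
                              threshold_method = c("iqr3", "ref5"),
                              reference = NULL, dedup = TRUE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(n_scrambles >= 1)
  if (threshold_method == "ref5" && is.null(reference))
    stop("threshold_method = 'ref5' needs a reference set")
  # precompute per-protein window scaffolds once; each scramble reuses them
  scafs <- .build_scaffolds(proteome, P$k)
  ok <- !vapply(scafs, is.null, logical(1))
  if (!any(ok)) stop("no scannable protein in the proteome")
  scafs <- scafs[ok]
  ids <- proteome$id[ok]
  kmer_of <- function(res, s, i) substring(res, s$starts[i], s$starts[i] + P$k - 1L)
  residues <- proteome$residues[ok]
  per <- integer(n_scrambles)
  for (r in seq_len(n_scrambles)) {
    Ps <- scramble_columns(P)
    Lv <- as.vector(Ps$log10_probs)
    top <- vapply(scafs, function(s) {
      sc <- .window_scores(s, Lv)
      i <- which.max(sc)
      c(sc[i], s$starts[i])
    }, numeric(2))
    hits <- data.frame(protein_id = ids,
                       kmer = mapply(kmer_of, residues, scafs, top[2, ]),
                       log10_phi = top[1, ], phi = 10^top[1, ],
                       stringsAsFactors = FALSE)
    th <- if (threshold_method == "iqr3") threshold_3iqr(hits$log10_phi)
          else threshold_ref5(Ps, reference)
    rep_r <- call_outliers(hits, th, dedup = dedup)
    per[r] <- sum(rep_r$hits[[paste0("outlier_", threshold_method)]])
  }
  structure(list(fpr_percent = 100 * sum(per) / (n_scrambles * length(ids)),
                 total_calls = sum(per), n_scrambles = n_scrambles,
                 n_proteins = length(ids), per_scramble = per,
                 threshold_method = threshold_method),
            class = "scramble_control")
}

#' @export
print.scramble_control <- function(x, ...) {
  cat(sprintf("scrambled-matrix control (%s): %d call(s) in %d scrambles x %d proteins\n",
              x$threshold_method, x$total_calls, x$n_scrambles, x$n_proteins))
  cat(sprintf("false-positive rate: %.4g%%\n", x$fpr_percent))
  invisible(x)
}

#' Restrict a proteome to its N-terminal window
#'
#' Replaces every sequence by residues 2..k+1 (the k residues immediately
#' following the initiating methionine). Sequences shorter than k+1 are
#' dropped with a warning. Scanning such an artificially restricted proteome
#' is a negative control: a mid-protein domain signature should no longer be
#' found.
#'
#' @param proteome a sequence table.
#' @param k window length.
#' @return the restricted sequence table.
#' @export
restrict_n_terminal <- function(proteome, k) {
  keep <- nchar(proteome$residues) >= k + 1L
  if (!all(keep))
    warning(sprintf("dropping %d sequence(s) shorter than %d residues",
                    sum(!keep), k + 1L))
  out <- proteome[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no sequence long enough for the 2..k+1 window")
  out$residues <- substring(out$residues, 2L, k + 1L)
  row.names(out) <- NULL
  out
}
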