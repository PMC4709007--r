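#' Motif discovery configuration
#'
#' Bundles the tunables of motif discovery. Defaults are the operating point
#' used for histidine phosphotransfer (HPt) domains: motif length `k = 20`
#' (the best-conserved helical stretch around the reactive histidine),
#' `N = 2000` Gibbs iterations (sufficient for training sets of roughly 300
#' sequences), and 20 restarts ranked by mismatch score. A core-histone
#' style signature is obtained by setting `k = 15`.
#'
#' @param k motif length (>= 2).
#' @param N Gibbs iterations per restart (>= 1).
#' @param restarts number of independent restarts; restart r uses sub-seed
#'   `seed + r` (r = 0..restarts-1).
#' @param algorithm `"gibbs"`, `"randomized"` or `"greedy"`.
#' @param seed master RNG seed; every run is bit-reproducible given it.
#' @param gibbs_holdout if `TRUE`, the resampled sequence's own k-mer is
#'   removed from the profile before resampling (the classic leave-one-out
#'   Gibbs move). Default `FALSE`: resample against the full current profile.
#' @param bias_profile optional `profile_matrix` used as the initial profile
#'   (e.g. one with an absolutely conserved histidine at a chosen position);
#'   the initial k-mer selection is still random, but the first resampling
#'   draw is weighted by this matrix.
#' @param max_randomized_iters iteration cap for the randomized search.
#' @return a list of class `discovery_config`.
#' @export
discovery_config <- function(k = 20L, N = 2000L, restarts = 20L,
                             algorithm = c("gibbs", "randomized", "greedy"),
                             seed = 1L, gibbs_holdout = FALSE,
                             bias_profile = NULL,
                             max_randomized_iters = 1000L) {
  algorithm <- match.arg(algorithm)
  stopifnot(k >= 2, N >= 1, restarts >= 1, max_randomized_iters >= 1)
  if (!is.null(bias_profile)) {
    stopifnot(inherits(bias_profile, "profile_matrix"))
    if (bias_profile$k != k) stop("bias_profile k does not match config k")
  }
  structure(list(k = as.integer(k), N = as.integer(N),
                 restarts = as.integer(restarts), algorithm = algorithm,
                 seed = as.integer(seed), gibbs_holdout = isTRUE(gibbs_holdout),
                 bias_profile = bias_profile,
                 max_randomized_iters = as.integer(max_randomized_iters)),
            class = "discovery_config")
}

#' Build a biased initial profile with one absolutely conserved position
#'
#' A uniform profile except that one column puts all of its occurrence mass on
#' a single residue (by default histidine). Supplying it as
#' `discovery_config(bias_profile = ...)` steers the first Gibbs resampling
#' draws towards windows carrying that residue at the chosen position.
#'
#' @param k motif length.
#' @param M pseudocount denominator (nominal training-set size).
#' @param position column (1..k) to conserve.
#' @param letter the conserved residue, default `"H"`.
#' @return a paper-mode `profile_matrix`.
#' @export
conserved_position_profile <- function(k, M, position, letter = "H") {
  stopifnot(position >= 1, position <= k, letter %in% AA_ALPHABET)
  counts <- build_count_matrix(character(), k)
  counts$counts[letter, position] <- as.integer(M)
  counts$n_kmers <- NA_integer_
  build_profile(counts, M, mode = "paper",
                provenance = list(kind = "bias",
                                  conserved = sprintf("%s@%d", letter, position)))
}

# --- internal engine -------------------------------------------------------

# residue row indices of scaffold window w (recovered from the linear indices)
.window_rows <- function(scaf, w) {
  scaf$lin[w, ] - (0L:(ncol(scaf$lin) - 1L)) * 20L
}

.counts_from_rows <- function(rows_mat, k) {
  # rows_mat: n_sel x k matrix of residue indices
  counts <- matrix(0L, 20L, k, dimnames = list(AA_ALPHABET, NULL))
  tab <- table(factor(as.vector(rows_mat), levels = 1:20),
               factor(rep(seq_len(k), each = nrow(rows_mat)), levels = seq_len(k)))
  counts[] <- as.integer(tab)
  counts
}

# one weighted draw over window scores, consuming exactly one uniform variate
.weighted_pick <- function(scores) {
  w <- 10^(scores - max(scores))
  cs <- cumsum(w)
  u <- stats::runif(1) * cs[length(cs)]
  min(1L + findInterval(u, cs), length(cs))
}

.eligibility <- function(seqs, k) {
  scaf <- .build_scaffolds(seqs, k)
  elig <- which(!vapply(scaf, is.null, logical(1)))
  list(scaf = scaf[elig], elig = elig,
       skipped_ids = seqs$id[setdiff(seq_len(nrow(seqs)), elig)])
}

.finish_result <- function(seqs, el, sel_w, k, config, algorithm,
                           restart_index, seed) {
  starts <- mapply(function(s, w) s$starts[w], el$scaf, sel_w)
  ids <- seqs$id[el$elig]
  texts <- substring(seqs$residues[el$elig], starts, starts + k - 1L)
  counts <- build_count_matrix(texts, k)
  prof <- build_profile(counts, M = length(texts), mode = "paper",
                        provenance = list(algorithm = algorithm, seed = seed,
                                          N = config$N, k = k,
                                          restart_index = restart_index))
  cons <- consensus(prof)
  structure(list(selected = data.frame(id = ids, start = starts, text = texts,
                                       stringsAsFactors = FALSE),
                 profile = prof, consensus = cons,
                 mismatch_score = mismatch_score(cons, texts),
                 config = config, algorithm = algorithm,
                 restart_index = restart_index,
                 skipped_ids = el$skipped_ids),
            class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("motif_result (%s): %d k-mers of length %d\n",
              x$algorithm, nrow(x$selected), x$profile$k))
  cat(sprintf("consensus: %s  (mismatch score %d, restart %d)\n",
              x$consensus, x$mismatch_score, x$restart_index))
  if (length(x$skipped_ids))
    cat(sprintf("skipped %d ineligible sequence(s)\n", length(x$skipped_ids)))
  invisible(x)
}

#' Sample one k-mer of a sequence weighted by its likelihood
#'
#' Draws a valid k-mer of `residues` with probability proportional to its
#' likelihood under `P` (phi normalized over all valid windows of the
#' sequence). This is the Gibbs resampling move; a draw consumes exactly one
#' uniform variate, so runs are reproducible under a fixed seed.
#'
#' @param P a `profile_matrix`.
#' @param residues a sanitized residue string with at least one valid k-mer.
#' @return a one-row data.frame with `start` (1-based), `text`, and
#'   `log10_phi`.
#' @export
weighted_kmer_choice <- function(P, residues) {
  w <- .seq_windows(residues, P$k)
  if (is.null(w)) stop("sequence has no valid k-mer of length ", P$k)
  scores <- .window_scores(w, as.vector(P$log10_probs))
  i <- .weighted_pick(scores)
  data.frame(start = w$starts[i],
             text = substring(residues, w$starts[i], w$starts[i] + P$k - 1L),
             log10_phi = scores[i], stringsAsFactors = FALSE)
}

#' Gibbs-sampling motif search
#'
#' Starts from one uniformly random valid k-mer per eligible sequence, then
#' iterates `N` times: pick one sequence uniformly at random, resample its
#' k-mer with probability proportional to likelihood under the current
#' profile, and rebuild the profile from the updated selection. There is no
#' early stopping; convergence is observed, not enforced. With
#' `config$bias_profile` set, the first resampling draw is weighted by the
#' supplied matrix instead of the profile of the random initial selection.
#'
#' @param seqs a sequence table (see [seq_records()]). Sequences shorter than
#'   k or without a fully canonical window are excluded up front and listed in
#'   the result's `skipped_ids`.
#' @param config a `discovery_config`; `config$seed` makes the run
#'   deterministic.
#' @param restart_index label recorded in the result (set by
#'   [multi_restart()]).
#' @param seed RNG seed for this run; defaults to `config$seed`.
#' @return a `motif_result`.
#' @export
gibbs_search <- function(seqs, config = discovery_config(),
                         restart_index = 0L, seed = config$seed) {
  k <- config$k
  el <- .eligibility(seqs, k)
  if (length(el$elig) < 2L)
    stop("need at least 2 sequences with a valid k-mer of length ", k)
  if (length(el$skipped_ids))
    message(sprintf("gibbs_search: skipping %d sequence(s) without a valid %d-mer",
                    length(el$skipped_ids), k))
  set.seed(seed)
  M <- length(el$elig)
  sel_w <- vapply(el$scaf, function(s) sample.int(s$m, 1L), integer(1))
  rows <- t(mapply(.window_rows, el$scaf, sel_w))
  counts <- .counts_from_rows(rows, k)
  use_bias <- !is.null(config$bias_profile)
  Lvec <- if (use_bias) as.vector(config$bias_profile$log10_probs)
          else as.vector(log10((counts + 1) / M))
  col_off <- (0L:(k - 1L)) * 20L
  for (t in seq_len(config$N)) {
    s <- sample.int(M, 1L)
    scaf <- el$scaf[[s]]
    if (config$gibbs_holdout && !use_bias) {
      held <- counts
      held[cbind(rows[s, ], seq_len(k))] <- held[cbind(rows[s, ], seq_len(k))] - 1L
      Ls <- as.vector(log10((held + 1) / (M - 1L)))
    } else {
      Ls <- Lvec
    }
    pick <- .weighted_pick(.window_scores(scaf, Ls))
    changed <- pick != sel_w[s]
    if (changed) {
      old <- cbind(rows[s, ], seq_len(k))
      counts[old] <- counts[old] - 1L
      rows[s, ] <- scaf$lin[pick, ] - col_off
      new <- cbind(rows[s, ], seq_len(k))
      counts[new] <- counts[new] + 1L
      sel_w[s] <- pick
    }
    if (changed || use_bias) {
      # rebuild the profile after every update; cheap (20 x k)
      Lvec <- as.vector(log10((counts + 1) / M))
      use_bias <- FALSE
    }
  }
  .finish_result(seqs, el, sel_w, k, config, "gibbs", restart_index, seed)
}

#' Randomized motif search
#'
#' Starts from a random selection, then repeatedly replaces every sequence's
#' k-mer with its profile-most-probable k-mer under the profile of the current
#' selection, rebuilding the profile after each full sweep, until the
#' selection reaches a fixed point or `max_randomized_iters` sweeps.
#'
#' @inheritParams gibbs_search
#' @return a `motif_result`.
#' @export
randomized_search <- function(seqs, config = discovery_config(algorithm = "randomized"),
                              restart_index = 0L, seed = config$seed) {
  k <- config$k
  el <- .eligibility(seqs, k)
  if (length(el$elig) < 2L)
    stop("need at least 2 sequences with a valid k-mer of length ", k)
  set.seed(seed)
  M <- length(el$elig)
  sel_w <- vapply(el$scaf, function(s) sample.int(s$m, 1L), integer(1))
  col_off <- (0L:(k - 1L)) * 20L
  for (iter in seq_len(config$max_randomized_iters)) {
    rows <- t(mapply(.window_rows, el$scaf, sel_w))
    Lvec <- as.vector(log10((.counts_from_rows(rows, k) + 1) / M))
    new_w <- vapply(el$scaf, function(s) which.max(.window_scores(s, Lvec)),
                    integer(1))
    if (identical(new_w, sel_w)) break
    sel_w <- new_w
  }
  .finish_result(seqs, el, sel_w, k, config, "randomized", restart_index, seed)
}

#' Greedy motif search
#'
#' For every k-mer of the first eligible sequence: seed a selection with it,
#' then walk the remaining sequences in order, each time adding the
#' profile-most-probable k-mer under the pseudocount profile of the selection
#' built so far. The seed whose completed selection has the smallest mismatch
#' score wins (ties: the leftmost seed window). Fully deterministic; the seed
#' argument is accepted for interface symmetry and ignored.
#'
#' @inheritParams gibbs_search
#' @return a `motif_result`.
#' @export
greedy_search <- function(seqs, config = discovery_config(algorithm = "greedy"),
                          restart_index = 0L, seed = config$seed) {
  k <- config$k
  el <- .eligibility(seqs, k)
  M <- length(el$elig)
  if (M < 2L)
    stop("need at least 2 sequences with a valid k-mer of length ", k)
  best_sel <- NULL
  best_score <- Inf
  for (w0 in seq_len(el$scaf[[1]]$m)) {
    sel_w <- integer(M)
    sel_w[1] <- w0
    counts <- .counts_from_rows(matrix(.window_rows(el$scaf[[1]], w0), 1L), k)
    for (s in 2L:M) {
      Lvec <- as.vector(log10((counts + 1) / (s - 1L)))
      pick <- which.max(.window_scores(el$scaf[[s]], Lvec))
      sel_w[s] <- pick
      new <- cbind(.window_rows(el$scaf[[s]], pick), seq_len(k))
      counts[new] <- counts[new] + 1L
    }
    cons <- consensus(structure(list(k = k, n_kmers = M, counts = counts),
                                class = "count_matrix"))
    starts <- mapply(function(sc, w) sc$starts[w], el$scaf, sel_w)
    texts <- substring(seqs$residues[el$elig], starts, starts + k - 1L)
    score <- mismatch_score(cons, texts)
    if (score < best_score) {
      best_score <- score
      best_sel <- sel_w
    }
  }
  .finish_result(seqs, el, best_sel, k, config, "greedy", restart_index, seed)
}

#' Multi-restart motif discovery
#'
#' Runs the configured search `config$restarts` times with sub-seeds
#' `config$seed + r` (r = 0, 1, ...) and returns the restart whose selected
#' k-mers have the minimum total mismatch score against their own consensus;
#' ties go to the lowest restart index. The greedy search is deterministic, so
#' it is run once regardless of `restarts`.
#'
#' @inheritParams gibbs_search
#' @return the best `motif_result`, with `restart_index` recording which
#'   restart produced it.
#' @export
multi_restart <- function(seqs, config = discovery_config()) {
  runner <- switch(config$algorithm,
                   gibbs = gibbs_search,
                   randomized = randomized_search,
                   greedy = greedy_search)
  R <- if (config$algorithm == "greedy") 1L else config$restarts
  best <- NULL
  for (r in seq_len(R) - 1L) {
    res <- runner(seqs, config, restart_index = r, seed = config$seed + r)
    if (is.null(best) || res$mismatch_score < best$mismatch_score) best <- res
  }
  best
}

#' @rdname multi_restart
#' @export
find_motif <- multi_restart
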