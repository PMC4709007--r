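---
title: "An indel-free occurrence model for short protein-domain signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An indel-free occurrence model for short protein-domain signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probmotif)
```

## The problem

Some protein domains are too short and too weakly conserved for alignment-based
search to find them reliably. The motivating case is the histidine
phosphotransfer (HPt) domain of multistep His–Asp phosphorelays: a small
four-helix bundle whose only absolutely conserved residue is the phosphorylated
histidine, so BLAST-style homology search struggles and even profile HMMs gain
little from their insertion/deletion states over such a short span.
`probmotif` takes the opposite bet: it models a *fixed-length, gapless* window
(default `k = 20`, spanning the best-conserved helix around the reactive
histidine) as a position-specific occurrence matrix, and scores every protein
in a proteome by its single best window.

## The model

Given a reference family of `M` domain sequences, the motif is a 20 × k matrix

    P[j, i] = (m_ji + 1) / M

where `m_ji` counts, among the currently selected k-mers (one per reference
sequence), those carrying residue `j` at motif position `i`, and the `+1`
pseudocount guarantees that no residue has probability zero anywhere —
essential when `M` is only a few hundred. The likelihood of a k-mer
`X = (x_1, ..., x_k)` is the product of its matrix entries,

    phi(X) = prod_i P[x_i, i],

and every computation in the package accumulates `log10 phi` (proteome-level
scores reach 1e-50 and below; log space avoids underflow and makes ranking
robust). Two conventions for the denominator are offered:

* `mode = "paper"` (default): `(m + 1)/M`. Columns sum to `(M + 20)/M`,
  slightly above 1, so `phi` is an *occurrence score*, not a normalized
  probability over k-mers. This is the scale on which the package's cutoff
  constants live, so it is the default.
* `mode = "normalized"`: `(m + 1)/(M + 20)`; columns sum to 1. For any k-mer
  the two modes differ by the constant factor `((M + 20)/M)^k`, so rankings,
  quartiles on the log scale and outlier decisions are identical.

The residue order `ACDEFGHIKLMNPQRSTVWY` is fixed package-wide: matrix rows,
consensus tie-breaks (argmax ties go to the earlier letter) and the TSV
serialization all depend on it. K-mers containing non-canonical letters
(X, B, Z, J, U, O) are excluded from training and scanning — no matrix row
exists for them — and each exclusion is reported rather than silently dropped.

## Learning the motif

Three searches share the same machinery and return the same `motif_result`
structure:

* **Gibbs sampling** (`gibbs_search`): start from a uniformly random valid
  k-mer per sequence; per iteration, pick one sequence uniformly at random and
  resample its k-mer with probability proportional to `phi` under the current
  matrix, then rebuild the matrix. `N = 2000` iterations is the default
  operating point for `k = 20` and reference sets of a few hundred sequences;
  there is no early stopping — convergence is observed, not enforced. The
  resampling draw deliberately uses the *full* current matrix (the sequence's
  own previous k-mer included), which is the described method;
  `gibbs_holdout = TRUE` switches to the statistically classic leave-one-out
  move.
* **Randomized search** (`randomized_search`): replace *every* sequence's
  k-mer by its profile-most-probable k-mer, rebuild, repeat to a fixed point
  (capped at `max_randomized_iters = 1000`; the fixed-point stop rule is this
  package's choice). It converges fast but reaches shifted local optima more
  often than the sampler, so it benefits most from restarts.
* **Greedy search** (`greedy_search`): for each seed k-mer of the first
  sequence, grow the selection sequence-by-sequence via profile-most-probable
  picks; fully deterministic.

Because all three optimize a non-convex objective, `multi_restart` runs the
configured search `restarts = 20` times and keeps the restart whose selected
k-mers have the *minimum total mismatch score* — the summed Hamming distance
to their own consensus — with ties going to the lowest restart index. Restart
`r` uses sub-seed `seed + r`; re-randomizing both the initial selection and
the iteration order per restart is a deliberate choice (the alternative,
re-randomizing only the initial selection, explores less). Identical inputs
and seed give bit-identical results for all three algorithms; a weighted draw
consumes exactly one uniform variate (a single `runif` inverted through the
cumulative weights) to keep replay stable.

An optional biased initial matrix (`conserved_position_profile`) places all
occurrence mass of one column on a chosen residue — e.g. an absolutely
conserved histidine at a chosen offset — and is used for the *first* resampling
draw only; after the first update the matrix is rebuilt from the actual
selection.

## Scanning a proteome

Each protein is represented by its *profile-most-probable k-mer* — the valid
window maximizing `phi`, leftmost on exact ties — and proteins are ranked by
descending `phi`, with equal scores ordered by protein id so the ranking is
invariant to input order. Candidate domain carriers are then called two ways:

* **3·IQR rule** (`threshold_3iqr`): flag proteins whose `log10 phi` strictly
  exceeds `Q3 + 3·(Q3 − Q1)` of the proteome's distribution. Quartiles use
  linear interpolation of order statistics (`stats::quantile` type 7, the
  common spreadsheet/statistical default); the choice is recorded in the
  threshold object. This cutoff adapts to each proteome.
* **Reference 5% rule** (`threshold_ref5`): apply the matrix back to its own
  reference family and take the 5th percentile of the resulting `log10 phi`
  values (interpolated on the log scale, where the distribution is examined
  and filtered). This cutoff is proteome-independent, so it can score single
  sequences; it is usually the more restrictive of the two. Note that the
  reference scores are mildly optimistic — the matrix was fitted to those very
  sequences — so genuine but degenerate family members can fall just below it.

"Exceeding" is strict in both rules: a hit exactly at the cutoff is not an
outlier. Optional deduplication collapses hits with identical k-mer and
likelihood (relative difference < 1e-12) — typically splicing variants or
redundant proteome entries — keeping the first protein id and annotating the
rest with `duplicate_of`. Gene-level identity, the natural third criterion,
needs annotation that plain FASTA lacks and is deliberately not guessed at.
Internally all coordinates are 0-based half-open; every report is 1-based
inclusive, the UniProt convention.

Two negative controls accompany a scan. `scramble_columns` permutes the matrix
columns uniformly at random (the identity permutation is not excluded; at
`k = 20` it has probability `1/20!`), preserving each column's composition
while destroying positional structure; `scrambled_control` repeats
scramble-and-rescan (default 100 times) and reports the false-positive rate as
total calls over scrambles × proteins, in percent. `restrict_n_terminal`
rebuilds the proteome from residues 2..k+1 only — a signature that lives
mid-protein should disappear from such a scan.

## The synthetic benchmark

`make_benchmark` generates the package's ground-truth test bed: background
proteins with i.i.d. residues (uniform 1/20 by default — the implicit null of
the occurrence model; a frequency vector estimated from any real FASTA may be
substituted), plus planted instances of a known consensus, each with exactly
`s` uniformly placed substitutions to a uniformly chosen different residue
(`s = 2` by default — degenerate enough that no instance equals the
consensus). The default conditions are a training set of 100 sequences of
length 120 each carrying one instance, and a decoy proteome of 2000 background
sequences (lengths uniform on 80–300, ordinary small-protein territory) plus 5
carriers. The default planted 20-mer is an HPt-like helix segment
(`DFKKVDPHVHQLKGSSSSIG`). These sizes keep a full train–scan–control cycle in
the tens of seconds while leaving the planted signal many orders of magnitude
above the decoy background.

What the benchmark does *not* emulate: compositional bias, low-complexity
runs, repeats, paralog families, or real domain-flanking context. Passing it
shows the machinery recovers and detects a planted gapless signal under the
model's own null — not that any particular biological family will separate as
cleanly.

One behavior of the 3·IQR rule is worth understanding before reading
benchmark output. Each protein's score is the maximum over dozens to hundreds
of windows, so the proteome-wide `log10 phi` distribution has an
extreme-value-type right tail, and the `Q3 + 3·IQR` fence is grazed by on the
order of 0.05–0.25% of pure-background proteins — one to a few per 2000, the
same magnitude the scrambled-matrix control reports. On a 2000-decoy
benchmark the planted carriers therefore occupy the top ranks by a
wide margin, but a handful of background proteins near the fence may be
flagged alongside them at some seeds. The adaptive fence buys
proteome-portability at the price of this small, quantifiable false-positive
floor; the reference-5% rule does not share it.

## Numerical and edge-case choices

* Likelihood arithmetic: sums of `log10` entries end to end; linear `phi` is
  exponentiated only for reporting.
* Column information content (`column_information`, for logo-style summaries)
  always uses normalized frequencies `(m + 1)/(M + 20)`, renormalized per
  column, regardless of matrix mode — entropy of an unnormalized column is
  undefined. Values run 0 to `log2 20 ≈ 4.32` bits.
* Sequences shorter than `k`, or with no fully canonical window, are excluded
  before a run and listed in `skipped_ids`.
* `M` (the pseudocount denominator) is the number of *contributing* sequences,
  so count-matrix columns always sum to `M`.
* Matrix TSV serialization writes 17 significant digits so a write–read round
  trip is bit-exact.
* The 3·IQR rule refuses distributions of fewer than 4 values; the reference
  5% rule warns below 20 reference sequences.

## Problem sizes used in the test suite

The package's own checks run the full operating point (k = 20, N = 2000, 20
restarts, 100 training sequences) for consensus-recovery and detection, a
20-master-seed recovery sweep, and a 100-scramble control on the 2000-decoy
proteome; unit tests use smaller instances (two-sequence greedy oracles,
k ≤ 10 sweeps) chosen to be exhaustively checkable. Reproducing the published
HPt proteome results additionally needs the Pfam PF01627 eukaryotic member
sequences and UniProt reference proteomes supplied locally (see
`tests/testthat/test-acceptance.R`); those files are not bundled.

## Known limitations

* No insertion/deletion states, by design: a domain whose conservation is
  interrupted by variable-length loops within the window will score poorly.
* The fixed `k` is a user decision; nothing optimizes motif width.
* The i.i.d. background understates the tail of real proteomes (low-complexity
  and repeat regions), so real-data false-positive rates can exceed the
  benchmark's.
* Duplicate collapsing cannot see gene mappings, only sequence-level identity
  of k-mer and score.
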