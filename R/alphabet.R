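#' The canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in the fixed order
#' \code{ACDEFGHIKLMNPQRSTVWY}. Matrix row indices throughout the package
#' depend on this order, and consensus ties are broken by it, so it is
#' immutable across a run.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# letter -> row index lookup over the raw byte value; non-canonical letters map to NA
.aa_lookup <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt(paste(AA_ALPHABET, collapse = "")) + 1L] <- seq_len(20L)
  lut
})

#' Map residue letters to alphabet row indices
#'
#' @param letters character vector of single uppercase letters, or a single
#'   string when `split = TRUE`.
#' @param split if `TRUE`, `letters` is one string that is split into single
#'   characters first.
#' @return integer vector of row indices in [1, 20]; `NA` for letters outside
#'   the canonical alphabet (X, B, Z, U, ...).
#' @keywords internal
aa_index <- function(letters, split = FALSE) {
  if (split) {
    stopifnot(length(letters) == 1L)
    return(.aa_lookup[utf8ToInt(letters) + 1L])
  }
  .aa_lookup[vapply(letters, utf8ToInt, integer(1), USE.NAMES = FALSE) + 1L]
}

#' Sanitize a raw residue string
#'
#' Uppercases the input and strips alignment gap characters (`-`, `.`), stop
#' codons (`*`) and whitespace. All other characters are preserved:
#' non-canonical letters such as X, B, Z or U are kept here and excluded later
#' at the k-mer level, where no matrix row exists for them.
#'
#' @param raw arbitrary text from a sequence record body (possibly a gapped
#'   alignment export).
#' @return the sanitized residue string; may be empty, which callers should
#'   treat as a record to skip.
#' @examples
#' sanitize_residues("mk-De")   # "MKDE"
#' sanitize_residues("AC..gx*") # "ACGX"
#' @export
sanitize_residues <- function(raw) {
  stopifnot(is.character(raw))
  gsub("[-.*[:space:]]", "", toupper(raw))
}

#' Assemble a sequence-record table
#'
#' The package represents a collection of protein (or reference-domain)
#' sequences as a plain data frame with columns `id`, `description`,
#' `residues` and `source`. Residues are sanitized, empty records are dropped
#' with a warning, and duplicate ids are disambiguated with a logged suffix so
#' that ids are unique within the collection.
#'
#' @param id character vector of accessions.
#' @param residues character vector of residue strings (sanitized here).
#' @param description free-text descriptions (recycled if length 1).
#' @param source provenance label, e.g. a file path or `"synthetic"`.
#' @return a `data.frame` with one row per non-empty sequence.
#' @export
seq_records <- function(id, residues, description = "", source = "synthetic") {
  stopifnot(length(id) == length(residues))
  description <- rep_len(as.character(description), length(id))
  source <- rep_len(as.character(source), length(id))
  res <- sanitize_residues(residues)
  keep <- nzchar(res)
  if (!all(keep)) {
    warning(sprintf("dropping %d record(s) empty after sanitization: %s",
                    sum(!keep), paste(utils::head(id[!keep], 5L), collapse = ", ")))
  }
  id <- as.character(id)[keep]
  res <- res[keep]
  description <- description[keep]
  source <- source[keep]
  if (anyDuplicated(id)) {
    dup <- duplicated(id)
    id[dup] <- make.unique(id, sep = "_dup")[dup]
    message(sprintf("%d duplicate id(s) disambiguated with a suffix", sum(dup)))
  }
  if (length(id) == 0L) stop("no usable sequence records (all empty after sanitization)")
  data.frame(id = id,
             description = description,
             residues = res,
             source = source,
             stringsAsFactors = FALSE)
}
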