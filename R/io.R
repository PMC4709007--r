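#' Read protein sequences from a FASTA file
#'
#' Reads (possibly gapped) FASTA through Biostrings and returns a sanitized
#' sequence table. UniProt-style headers `db|ACC|NAME description` are parsed
#' so that the id is the accession; for any other header the id is the first
#' whitespace-delimited token. Duplicate ids are disambiguated with a logged
#' suffix and records empty after sanitization are dropped with a warning.
#'
#' @param path path to a FASTA file.
#' @return a sequence table (see [seq_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0L) stop("no FASTA records in ", path)
  headers <- names(xs)
  first_tok <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  # UniProt convention: >db|ACCESSION|ENTRY_NAME description
  uni <- grepl("^[^|[:space:]]+\\|[^|[:space:]]+\\|", first_tok)
  ids <- ifelse(uni, vapply(strsplit(first_tok, "|", fixed = TRUE), `[`, "", 2L),
                first_tok)
  seq_records(id = ids, residues = as.character(xs), description = desc,
              source = path)
}

#' Write a sequence table to FASTA
#'
#' @param seqs a sequence table.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  xs <- Biostrings::BStringSet(seqs$residues)
  names(xs) <- ifelse(nzchar(seqs$description),
                      paste(seqs$id, seqs$description), seqs$id)
  Biostrings::writeXStringSet(xs, path, width = 60L)
  invisible(path)
}

#' Read a reference alignment (Stockholm or gapped FASTA)
#'
#' Domain-family exports are usually alignments. A file starting with
#' `# STOCKHOLM` is parsed as Stockholm: markup lines (`#=GF`, `#=GC`,
#' `#=GS`, `#=GR`), the terminator `//` and blank lines are ignored, and
#' sequence lines (`name  aligned-residues`) are accumulated across blocks.
#' Anything else is handed to the FASTA reader. Gap characters are stripped
#' in either case, so the per-sequence residue order is exactly that of the
#' ungapped sequences.
#'
#' @param path path to an alignment file.
#' @return a sequence table.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^#\\s*STOCKHOLM", first)) {
    lines <- readLines(path, warn = FALSE)
    seqlines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                        nzchar(trimws(lines))]
    if (length(seqlines) == 0L)
      stop("unrecognized alignment: Stockholm header but no sequence lines in ", path)
    parts <- regmatches(seqlines, regexec("^(\\S+)\\s+(\\S+)\\s*$", seqlines))
    bad <- vapply(parts, length, integer(1)) != 3L
    if (any(bad))
      stop("malformed Stockholm sequence line(s), e.g.: ",
           seqlines[which(bad)[1]])
    nm <- vapply(parts, `[`, "", 2L)
    sq <- vapply(parts, `[`, "", 3L)
    res <- vapply(split(sq, factor(nm, levels = unique(nm))),
                  paste, "", collapse = "")
    return(seq_records(id = names(res), residues = unname(res), source = path))
  }
  if (grepl("^>", first)) return(read_fasta(path))
  stop("unrecognized format for ", path,
       ": neither Stockholm ('# STOCKHOLM' header) nor FASTA ('>' header)")
}

#' Serialize a profile matrix to TSV
#'
#' Writes comment header lines (`#k=`, `#M=`, `#mode=`, `#seed=`,
#' `#source=`), a `pos` header row numbering the motif columns, and 20 data
#' rows labeled by residue. Probabilities are written with 17 significant
#' digits so that [read_matrix()] round-trips bit-exactly.
#'
#' @param P a `profile_matrix`.
#' @param path output path.
#' @export
write_matrix <- function(P, path) {
  stopifnot(inherits(P, "profile_matrix"))
  prov <- P$provenance
  hdr <- c(sprintf("#k=%d", P$k),
           sprintf("#M=%d", P$M),
           sprintf("#mode=%s", P$mode),
           sprintf("#seed=%s", if (is.null(prov$seed)) "NA" else format(prov$seed)),
           sprintf("#source=%s", if (is.null(prov$source)) "NA" else prov$source))
  rows <- vapply(seq_len(20L), function(j)
    paste(c(AA_ALPHABET[j], sprintf("%.17g", P$probs[j, ])), collapse = "\t"),
    character(1))
  writeLines(c(hdr, paste(c("pos", seq_len(P$k)), collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a profile matrix written by [write_matrix()]
#'
#' @param path path to a matrix TSV.
#' @return a `profile_matrix`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^#", lines)
  meta <- lines[is_hdr]
  get_meta <- function(key) {
    m <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(m) == 0L) stop("matrix file missing header '#", key, "=' in ", path)
    sub(paste0("^#", key, "="), "", m[1])
  }
  k <- as.integer(get_meta("k"))
  M <- as.integer(get_meta("M"))
  mode <- get_meta("mode")
  body_idx <- which(!is_hdr & nzchar(lines))
  body <- lines[body_idx]
  if (length(body) != 21L)
    stop(sprintf("matrix file %s: expected 'pos' header + 20 residue rows, found %d body line(s)",
                 path, length(body)))
  probs <- matrix(NA_real_, 20L, k, dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(20L)) {
    fields <- strsplit(body[j + 1L], "\t", fixed = TRUE)[[1]]
    lineno <- body_idx[j + 1L]
    if (length(fields) != k + 1L)
      stop(sprintf("matrix file %s line %d: expected %d columns, found %d",
                   path, lineno, k + 1L, length(fields) - 1L))
    if (fields[1] != AA_ALPHABET[j])
      stop(sprintf("matrix file %s line %d: expected residue row '%s', found '%s'",
                   path, lineno, AA_ALPHABET[j], fields[1]))
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals))
      stop(sprintf("matrix file %s line %d: non-numeric entry", path, lineno))
    probs[j, ] <- vals
  }
  seed <- suppressWarnings(as.integer(get_meta("seed")))
  structure(list(k = k, M = M, mode = mode, probs = probs,
                 log10_probs = log10(probs),
                 provenance = list(seed = seed, source = get_meta("source"))),
            class = "profile_matrix")
}

#' Write / read a scan hit table (TSV)
#'
#' `write_hits()` writes the ranked hits of an [outlier_report][call_outliers]
#' or plain scan table; likelihoods use scientific notation with 6+
#' significant digits. `read_hits()` restores the table with correct column
#' types.
#'
#' @param hits an `outlier_report` or a scan data.frame.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  df <- if (inherits(hits, "outlier_report")) hits$hits else hits
  df <- df[order(df$rank), , drop = FALSE]
  fmt <- df
  fmt$phi <- sprintf("%.6e", df$phi)
  fmt$log10_phi <- sprintf("%.10g", df$log10_phi)
  names(fmt)[names(fmt) == "start"] <- "start_1based"
  lead <- intersect(c("rank", "protein_id", "description", "kmer",
                      "start_1based", "phi", "log10_phi"), names(fmt))
  fmt <- fmt[, c(lead, setdiff(names(fmt), lead)), drop = FALSE]
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Record how an output was produced
#'
#' A small provenance manifest: command, configuration, seed, md5 digests of
#' the input files, package version and a timestamp. Written as JSON next to
#' the outputs so every result file can be traced to the run that made it.
#'
#' @param command name of the command or function run.
#' @param config named list of configuration values.
#' @param seed the RNG seed used.
#' @param inputs character vector of input file paths (digested if they
#'   exist).
#' @param path optional path; if given the manifest is written there as JSON.
#' @return the manifest as a named list, invisibly if written.
#' @export
run_manifest <- function(command, config = list(), seed = NA_integer_,
                         inputs = character(), path = NULL) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  man <- list(command = command,
              config = config,
              seed = seed,
              input_md5 = digests,
              package = "probmotif",
              version = as.character(utils::packageVersion("probmotif")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(man))
  }
  man
}
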