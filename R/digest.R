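#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (multi-)FASTA file of amino-acid sequences.
#' @param strip_invalid Drop residues outside the 20-letter alphabet instead
#'   of erroring? Default `FALSE` (digestion rejects ambiguity codes).
#' @return `data.frame` with columns `name` (first token of the description
#'   line), `description` (full line) and `sequence`.
#' @export
read_protein_fasta <- function(path, strip_invalid = FALSE) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  if (strip_invalid) {
    seqs <- vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1]]
      paste(chars[chars %in% names(.AA_MONO)], collapse = "")
    }, character(1))
  }
  data.frame(
    name = vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L),
    description = unname(names(aa)),
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
}

#' Path to the packaged synthetic library-protein FASTA
#'
#' Synthetic stand-in sequences for the five proteins of the tryptic
#' library (BSA, bovine thyroglobulin, bovine alpha-lactalbumin, human
#' alpha- and beta-hemoglobin). They are constructed so that tryptic
#' digestion with up to two missed cleavages yields the documented
#' reference peptides of each precursor; they are not the curated database
#' sequences (see the package vignette).
#'
#' @return File path (character).
#' @export
library_proteins_fasta <- function() {
  system.file("extdata", "library_proteins_synthetic.fasta",
              package = "cpdquant", mustWork = TRUE)
}

# 0-missed tryptic boundaries: cleave after K/R, optionally suppressed
# before Pro (Keil rule).
.tryptic_sites <- function(res, no_cleave_before_proline) {
  n <- length(res)
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n]
  if (no_cleave_before_proline) {
    sites <- sites[res[sites + 1L] != "P"]
  }
  sites
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to every Lys or Arg (optionally suppressed when the
#' next residue is Pro) and returns all fragments with 0 to `max_missed`
#' internal missed cleavage sites, with 1-based coordinates in the
#' precursor.
#'
#' @param sequence Protein sequence (character scalar).
#' @param name Precursor name recorded with each peptide.
#' @param max_missed Maximum number of missed cleavages (>= 0). Default 2.
#' @param no_cleave_before_proline Apply the Keil rule (no cleavage before
#'   Pro)? Default `TRUE`.
#' @return `data.frame` with columns `sequence`, `precursor`, `start`,
#'   `end`, `missed`.
#' @export
#' @examples
#' trypsin_digest("AAKGGRPP", name = "toy", max_missed = 0)
trypsin_digest <- function(sequence, name = "protein", max_missed = 2L,
                           no_cleave_before_proline = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("protein sequence must be non-empty")
  if (max_missed < 0L) stop("'max_missed' must be >= 0")
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!res %in% names(.AA_MONO))
  if (length(bad)) {
    stop(sprintf("non-standard residue '%s' at position %d in %s",
                 res[bad[1L]], bad[1L], name))
  }
  sites <- .tryptic_sites(res, no_cleave_before_proline)
  bounds <- c(0L, sites, length(res))          # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (m in 0:min(max_missed, nfrag - 1L)) {
    from <- seq_len(nfrag - m)
    starts <- bounds[from] + 1L
    ends <- bounds[from + m + 1L]
    out[[length(out) + 1L]] <- data.frame(
      sequence = substring(sequence, starts, ends),
      precursor = name, start = starts, end = ends, missed = m,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Build a pooled tryptic peptide library
#'
#' Digests each protein separately and pools the results, de-duplicated by
#' (sequence, precursor, coordinates) and ordered deterministically by
#' precursor then position.
#'
#' @param proteins `data.frame` with columns `name` and `sequence`
#'   (e.g. from [read_protein_fasta()]).
#' @param max_missed Maximum missed cleavages per peptide. Default 2.
#' @param no_cleave_before_proline Apply the Keil rule? Default `TRUE`.
#' @return `data.frame` of library peptides (`sequence`, `precursor`,
#'   `start`, `end`, `missed`).
#' @export
build_library <- function(proteins, max_missed = 2L,
                          no_cleave_before_proline = TRUE) {
  if (!is.data.frame(proteins) || nrow(proteins) == 0L) {
    stop("'proteins' must be a non-empty data.frame with name and sequence")
  }
  digs <- lapply(seq_len(nrow(proteins)), function(i) {
    trypsin_digest(proteins$sequence[i], name = proteins$name[i],
                   max_missed = max_missed,
                   no_cleave_before_proline = no_cleave_before_proline)
  })
  lib <- do.call(rbind, digs)
  lib <- lib[!duplicated(lib[, c("sequence", "precursor", "start", "end")]), ]
  lib <- lib[order(lib$precursor, lib$start, lib$end), , drop = FALSE]
  rownames(lib) <- NULL
  lib
}

#' Annotate a peptide library with mass, tag and charge columns
#'
#' Adds `theor_mass`, `tags` (free amines) and `charge` (expected charge)
#' to a library table, the layout used when exporting the library as TSV.
#'
#' @param library A library `data.frame` with a `sequence` column.
#' @return The input with three additional columns.
#' @export
annotate_library <- function(library) {
  stopifnot(is.data.frame(library), "sequence" %in% names(library))
  library$theor_mass <- vapply(library$sequence, monoisotopic_mass, numeric(1))
  library$tags <- vapply(library$sequence, count_free_amines, integer(1))
  library$charge <- vapply(library$sequence, expected_charge, integer(1))
  rownames(library) <- NULL
  library
}
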