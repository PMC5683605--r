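#' Construct a peptide
#'
#' A `peptide` is the unit of all mass, charge and specificity computation:
#' an ordered vector of one-letter residue codes with an N-terminal state
#' (free amine or acetylated) and optional methionine-oxidation marks.
#' The C-terminus is always a free acid.
#'
#' @param sequence Character scalar (e.g. `"QQAAALAK"`) or character vector
#'   of one-letter residue codes.
#' @param n_term `"free"` (default) or `"acetyl"`.
#' @param oxidized Integer positions carrying a Met-oxidation; each must be
#'   an `M`.
#' @param precursor Optional precursor protein name.
#' @return Object of class `peptide`.
#' @export
#' @examples
#' p <- peptide("SAMTEEAAVAIKAMAK", oxidized = 3)
#' monoisotopic_mass(p)
peptide <- function(sequence, n_term = c("free", "acetyl"),
                    oxidized = integer(), precursor = NA_character_) {
  n_term <- match.arg(n_term)
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (length(sequence) == 0L) stop("peptide sequence must be non-empty")
  bad <- which(!sequence %in% names(.AA_MONO))
  if (length(bad)) {
    stop(sprintf("unknown residue code '%s' at position %d",
                 sequence[bad[1L]], bad[1L]))
  }
  oxidized <- as.integer(oxidized)
  if (any(oxidized < 1L | oxidized > length(sequence))) {
    stop("oxidation position outside sequence bounds")
  }
  if (any(sequence[oxidized] != "M")) {
    stop("oxidation is only allowed on Met residues")
  }
  structure(
    list(residues = sequence, n_term = n_term,
         oxidized = sort(unique(oxidized)), precursor = precursor),
    class = "peptide"
  )
}

#' Parse text notation for a peptide
#'
#' Accepts plain sequences, an `"Ac-"` prefix for N-terminal acetylation,
#' and `"Mox"` or `"M(ox)"` inline markers for oxidized methionine, the
#' notation used in published substrate tables (e.g.
#' `"Ac-ADEIAKAQVAR"`, `"SAMoxTEEAAVAIKAMAK"`).
#'
#' @param text Character scalar.
#' @param precursor Optional precursor protein name.
#' @return A [peptide()].
#' @export
parse_peptide <- function(text, precursor = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  n_term <- "free"
  if (grepl("^Ac-", txt)) {
    n_term <- "acetyl"
    txt <- sub("^Ac-", "", txt)
  }
  txt <- gsub("M\\(ox\\)", "Mox", txt)
  chars <- strsplit(txt, "")[[1]]
  residues <- character()
  oxidized <- integer()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "M" && i + 2L <= length(chars) &&
        chars[i + 1L] == "o" && chars[i + 2L] == "x") {
      residues <- c(residues, "M")
      oxidized <- c(oxidized, length(residues))
      i <- i + 3L
    } else {
      residues <- c(residues, ch)
      i <- i + 1L
    }
  }
  peptide(residues, n_term = n_term, oxidized = oxidized,
          precursor = precursor)
}

#' Coerce to peptide
#'
#' Character input is run through [parse_peptide()]; `peptide` objects pass
#' through unchanged. Most package functions accept either.
#'
#' @param x A `peptide` or a character scalar in table notation.
#' @return A [peptide()].
#' @export
as_peptide <- function(x) {
  if (inherits(x, "peptide")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_peptide(x))
  stop("cannot coerce to peptide: expected a peptide object or a single string")
}

#' @export
format.peptide <- function(x, ...) {
  res <- x$residues
  if (length(x$oxidized)) {
    res[x$oxidized] <- "Mox"
  }
  paste0(if (x$n_term == "acetyl") "Ac-" else "", paste(res, collapse = ""))
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s (%d residues, M = %.5f Da)\n",
              format(x), length(x$residues), monoisotopic_mass(x)))
  invisible(x)
}

# Per-residue masses including positional modification deltas.
.residue_masses <- function(p) {
  m <- unname(.AA_MONO[p$residues])
  if (length(p$oxidized)) m[p$oxidized] <- m[p$oxidized] + .MOD_OXIDATION
  m
}

#' Theoretical monoisotopic mass
#'
#' Sum of monoisotopic residue masses plus water, plus modification deltas
#' (N-terminal acetyl +42.01057 Da, Met oxidation +15.99491 Da). This is the
#' neutral mass convention used for "Theor M" columns in substrate tables.
#'
#' @param p A [peptide()] or character sequence.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("QQAAALAK")           # 799.455
#' monoisotopic_mass("Ac-ADEIAKAQVAR")     # 1212.646
monoisotopic_mass <- function(p) {
  p <- as_peptide(p)
  m <- sum(.residue_masses(p)) + .MASS_WATER
  if (p$n_term == "acetyl") m <- m + .MOD_ACETYL
  m
}

#' Count free amines (isotopic tag sites)
#'
#' Amine-reactive isotopic tags label the free N-terminal amine and every
#' Lys side chain, so the expected tag count T equals the Lys count plus one
#' for an unmodified N-terminus (acetylation removes the N-terminal site).
#'
#' @param p A [peptide()] or character sequence.
#' @return Integer tag count.
#' @export
#' @examples
#' count_free_amines("KFEKLPESK")     # 4
#' count_free_amines("Ac-ADEIAKAQVAR") # 1
count_free_amines <- function(p) {
  p <- as_peptide(p)
  sum(p$residues == "K") + as.integer(p$n_term == "free")
}

#' Expected charge of a peptide
#'
#' Basic residues plus one for a free N-terminus. By default only Lys and
#' Arg count as basic: His-containing peptides are normally excluded from
#' TMAB analyses, and His protonation at the relevant pH is partial; set
#' `include_his = TRUE` to count His as basic.
#'
#' @param p A [peptide()] or character sequence.
#' @param include_his Count His as a basic residue? Default `FALSE`.
#' @return Integer expected charge (>= 1 for a free N-terminus).
#' @export
#' @examples
#' expected_charge("LRVDPVNFK") # 3
#' expected_charge("VVLQDR")    # 2
expected_charge <- function(p, include_his = FALSE) {
  p <- as_peptide(p)
  basic <- c("K", "R", if (include_his) "H")
  sum(p$residues %in% basic) + as.integer(p$n_term == "free")
}

#' b/y fragment ion series
#'
#' Singly-protonated b and y fragment masses, b1..b(n-1) and y1..y(n-1):
#' \eqn{b_i = \sum_{1..i} res + 1.00728} (plus the N-terminal modification
#' delta), \eqn{y_i = \sum_{n-i+1..n} res + H_2O + 1.00728}. Modification
#' deltas are applied positionally.
#'
#' @param p A [peptide()] or character sequence of length >= 2.
#' @return `data.frame` with columns `ion`, `series`, `index`, `mz`.
#' @export
#' @examples
#' by_fragment_series("GQKR")
by_fragment_series <- function(p) {
  p <- as_peptide(p)
  n <- length(p$residues)
  if (n < 2L) stop("fragment series require a peptide of length >= 2")
  m <- .residue_masses(p)
  nterm_delta <- if (p$n_term == "acetyl") .MOD_ACETYL else 0
  b <- cumsum(m)[seq_len(n - 1L)] + .MASS_PROTON + nterm_delta
  # cumsum(rev(m)) sums from the C-terminus; index i of y spans the last i residues
  y <- cumsum(rev(m))[seq_len(n - 1L)] + .MASS_WATER + .MASS_PROTON
  data.frame(
    ion = c(paste0("b", seq_len(n - 1L)), paste0("y", seq_len(n - 1L))),
    series = rep(c("b", "y"), each = n - 1L),
    index = c(seq_len(n - 1L), seq_len(n - 1L)),
    mz = c(b, y),
    stringsAsFactors = FALSE
  )
}
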