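#' Classify a peptide from its dose-dependent intensity ratios
#'
#' Applies the published thresholds to control-normalized ratios observed
#' over increasing enzyme amounts: a decrease of at least 60% at the
#' highest enzyme amount (ratio <= `good_threshold`) makes a good
#' substrate; a decrease of at least 20% but less than 60% (ratio in
#' (`good_threshold`, `weak_threshold`]) a weak substrate; smaller
#' decreases a non-substrate. Peptides whose intensity instead rises with
#' enzyme (ratio at the highest amount >= `product_threshold` and
#' non-decreasing across amounts) are products of cleavage.
#'
#' @param ratios Named numeric vector of enzyme/control ratios (censored
#'   values at their reported floor/cap).
#' @param enzyme_order Character vector of condition names ordered by
#'   increasing enzyme amount (control excluded). Defaults to `names(ratios)`.
#' @param good_threshold Good-substrate ratio ceiling. Default 0.40.
#' @param weak_threshold Weak-substrate ratio ceiling. Default 0.80.
#' @param product_threshold Minimum top-dose ratio for a product call.
#'   Default 1.5.
#' @param monotone_tol Relative slack allowed when testing monotonicity
#'   across amounts: multiplicative measurement noise makes strict
#'   monotonicity too brittle (with ~5% channel CV a dose-to-dose ratio
#'   step has a log-scale SD near 0.07, so a slack of several SD is
#'   needed). Default 0.25, i.e. a step may fall by up to 25% of the
#'   previous ratio and still count as non-decreasing; profiles that
#'   genuinely decrease are additionally excluded by the
#'   `product_threshold` gate.
#' @param quantifiable Set `FALSE` to propagate an unquantifiable profile.
#' @return List with `category` (one of `"good"`, `"weak"`, `"non"`,
#'   `"product"`, `"unquantifiable"`), `dose_consistent` (monotone
#'   non-increase for substrates / non-decrease for products across the
#'   ordered amounts) and `evidence` (the ratios used, in dose order).
#' @export
#' @examples
#' classify_substrate(c(`0.1nM` = 1.08, `1nM` = 1.05, `10nM` = 0.84,
#'                      `100nM` = 0.40))
classify_substrate <- function(ratios, enzyme_order = names(ratios),
                               good_threshold = 0.40, weak_threshold = 0.80,
                               product_threshold = 1.5, monotone_tol = 0.25,
                               quantifiable = TRUE) {
  if (!isTRUE(quantifiable)) {
    return(list(category = "unquantifiable", dose_consistent = NA,
                evidence = ratios))
  }
  stopifnot(!is.null(names(ratios)), all(enzyme_order %in% names(ratios)))
  if (length(enzyme_order) < 1L) stop("need >= 1 enzyme condition")
  r <- ratios[enzyme_order]
  if (any(!is.finite(r)) || any(r <= 0)) stop("ratios must be positive")
  r_top <- r[[length(r)]]
  prev <- r[-length(r)]
  nxt <- r[-1L]
  non_decreasing <- all(nxt >= prev * (1 - monotone_tol))
  non_increasing <- all(nxt <= prev * (1 + monotone_tol))
  if (r_top >= product_threshold && non_decreasing) {
    category <- "product"
    dose_consistent <- non_decreasing
  } else if (r_top <= good_threshold) {
    category <- "good"
    dose_consistent <- non_increasing
  } else if (r_top <= weak_threshold) {
    category <- "weak"
    dose_consistent <- non_increasing
  } else {
    category <- "non"
    dose_consistent <- NA
  }
  list(category = category, dose_consistent = dose_consistent, evidence = r)
}

#' Call the domain preference of a substrate
#'
#' For a peptide that is a substrate of the two-domain enzyme, compares the
#' residual intensities after incubation with the single-domain-active
#' mutants. The dI/dII ratio is intensity(domain I active) over
#' intensity(domain II active), censored to `[floor, cap]`; a censored
#' domain-I numerator (below background) forces the floor and a censored
#' domain-II denominator forces the cap. A low ratio means domain I removed
#' the peptide, i.e. a domain-I-preferential substrate.
#'
#' @param ratios Named numeric vector with elements `rhCPD`, `domain_I` and
#'   `domain_II`: enzyme/control ratios for the full enzyme and the two
#'   single-domain-active forms (control = double mutant).
#' @param censored Named logical vector (same names) marking
#'   below-background censored ratios. Default all `FALSE`.
#' @param cutoffs Length-2 numeric `(lower, upper)`: ratio <= lower calls
#'   domain I, >= upper calls domain II. Default `c(0.50, 2.00)`.
#' @param floor,cap Censoring limits of the dI/dII ratio. Defaults 0.10 and
#'   5.00.
#' @param weak_threshold Substrate gate on the `rhCPD` ratio. Default 0.80.
#' @return List with `call` (one of `"domain_I_preferential"`,
#'   `"domain_II_preferential"`, `"shared"`, `"neither"`), `dI_dII_ratio`
#'   and `ratio_censored`.
#' @export
#' @examples
#' call_domain_preference(c(rhCPD = 0.27, domain_I = 0.65, domain_II = 0.10),
#'                        censored = c(rhCPD = FALSE, domain_I = FALSE,
#'                                     domain_II = TRUE))
call_domain_preference <- function(ratios, censored = NULL,
                                   cutoffs = c(0.50, 2.00), floor = 0.10,
                                   cap = 5.00, weak_threshold = 0.80) {
  need <- c("rhCPD", "domain_I", "domain_II")
  missing <- setdiff(need, names(ratios))
  if (length(missing)) {
    stop(sprintf("missing condition(s): %s", paste(missing, collapse = ", ")))
  }
  if (is.null(censored)) censored <- setNames(rep(FALSE, 3L), need)
  if (ratios[["rhCPD"]] > weak_threshold && !censored[["rhCPD"]]) {
    return(list(call = "neither", dI_dII_ratio = NA_real_,
                ratio_censored = NA))
  }
  dI <- ratios[["domain_I"]]; dII <- ratios[["domain_II"]]
  cI <- isTRUE(censored[["domain_I"]]); cII <- isTRUE(censored[["domain_II"]])
  if (cI && cII) {
    # both channels below background: completely cleaved by both domains
    ratio <- 1; rc <- TRUE
  } else if (cI) {
    ratio <- floor; rc <- TRUE
  } else if (cII) {
    ratio <- cap; rc <- TRUE
  } else {
    ratio <- dI / dII
    rc <- FALSE
    if (ratio < floor) { ratio <- floor; rc <- TRUE }
    if (ratio > cap) { ratio <- cap; rc <- TRUE }
  }
  call <- if (ratio <= cutoffs[1L]) "domain_I_preferential"
    else if (ratio >= cutoffs[2L]) "domain_II_preferential"
    else "shared"
  list(call = call, dI_dII_ratio = ratio, ratio_censored = rc)
}

#' P1'/P1 residue preference profile
#'
#' Tallies, per substrate category, how often each residue occupies the
#' C-terminal (P1') or penultimate (P1) position. Following the published
#' convention, the P1 profile counts only peptides whose P1' residue is
#' permissive (Lys or Arg).
#'
#' @param sequences Character vector of peptide sequences (table notation
#'   allowed).
#' @param categories Character vector of categories, same length.
#' @param position `"P1prime"` (default) or `"P1"`.
#' @param permissive Permissive P1' residues for the P1 profile.
#'   Default `c("K", "R")`.
#' @return Integer matrix residues x categories (only residues/categories
#'   observed).
#' @export
build_profile <- function(sequences, categories,
                          position = c("P1prime", "P1"),
                          permissive = c("K", "R")) {
  position <- match.arg(position)
  stopifnot(length(sequences) == length(categories))
  if (!length(sequences)) {
    return(matrix(integer(), 0L, 0L))
  }
  res <- character(0); cat_kept <- character(0)
  for (i in seq_along(sequences)) {
    p <- as_peptide(sequences[i])
    n <- length(p$residues)
    if (position == "P1prime") {
      res <- c(res, p$residues[n]); cat_kept <- c(cat_kept, categories[i])
    } else {
      if (n < 2L) stop("P1 profile requires peptides of length >= 2")
      if (p$residues[n] %in% permissive) {
        res <- c(res, p$residues[n - 1L])
        cat_kept <- c(cat_kept, categories[i])
      }
    }
  }
  if (!length(res)) return(matrix(integer(), 0L, 0L))
  table(factor(res), factor(cat_kept))
}

#' Deduce the cleaved residue behind a product peptide
#'
#' Locates a product peptide inside precursor sequences; the residue
#' immediately downstream of the product's C-terminus is the residue the
#' carboxypeptidase removed. All occurrences (across and within precursors)
#' are reported; multiple occurrences are flagged ambiguous.
#'
#' @param product Product peptide sequence (character) or [peptide()].
#' @param precursors Named character vector of precursor sequences.
#' @return `data.frame` with columns `precursor`, `start`, `end`, `site`
#'   (position of the cleaved residue), `cleaved_residue`, `ambiguous`.
#' @export
#' @examples
#' deduce_cleavage("LRVDPVNF", c(aHb = "HAHKLRVDPVNFKLLS"))
deduce_cleavage <- function(product, precursors) {
  p <- as_peptide(product)
  seqtxt <- paste(p$residues, collapse = "")
  if (is.null(names(precursors))) {
    names(precursors) <- paste0("precursor", seq_along(precursors))
  }
  hits <- vector("list", 0L)
  at_terminus_only <- FALSE
  for (nm in names(precursors)) {
    prec <- precursors[[nm]]
    m <- gregexpr(seqtxt, prec, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (s in as.integer(m)) {
      e <- s + nchar(seqtxt) - 1L
      if (e >= nchar(prec)) {
        at_terminus_only <- TRUE
        next  # no downstream residue at the precursor C-terminus
      }
      hits[[length(hits) + 1L]] <- data.frame(
        precursor = nm, start = s, end = e, site = e + 1L,
        cleaved_residue = substr(prec, e + 1L, e + 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    if (at_terminus_only) {
      stop(sprintf("product '%s' only matches at a precursor C-terminus: no downstream residue to deduce",
                   seqtxt))
    }
    stop(sprintf("product '%s' not found in any precursor", seqtxt))
  }
  out <- do.call(rbind, hits)
  out$ambiguous <- nrow(out) > 1L
  rownames(out) <- NULL
  out
}

#' Drop peptides carrying excluded residues
#'
#' Peptides containing Cys, Tyr or His show label side reactions and
#' intensity artifacts; they are removed before classification.
#'
#' @param sequences Character vector of sequences.
#' @param excluded Residues to exclude. Default `c("C", "Y", "H")`.
#' @return Logical vector: `TRUE` where the peptide is kept.
#' @export
keep_analyzable <- function(sequences, excluded = c("C", "Y", "H")) {
  vapply(sequences, function(s) {
    !any(as_peptide(s)$residues %in% excluded)
  }, logical(1), USE.NAMES = FALSE)
}
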