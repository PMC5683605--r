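#' Parse a possibly-censored printed ratio
#'
#' Substrate tables print below-background ratios as `"<0.10"` and capped
#' domain-preference ratios as `">5.00"`. This parses such strings into a
#' numeric value (at the censoring limit) plus a censoring flag.
#'
#' @param x Character (or numeric) vector of printed ratios.
#' @return `data.frame` with columns `value` and `censored`.
#' @export
#' @examples
#' parse_ratio(c("<0.10", "0.68", ">5.00"))
parse_ratio <- function(x) {
  x <- as.character(x)
  censored <- grepl("^\\s*[<>]", x)
  value <- as.numeric(gsub("[<> ]", "", x))
  data.frame(value = value, censored = censored)
}

#' Curated reference substrate and kinetics tables
#'
#' Packaged reference tables of recombinant human CPD experiments:
#' \describe{
#'   \item{`"tryptic_good"`}{good substrates of the full enzyme identified
#'     with the tryptic peptide library across the 0.1-100 nM dose series.}
#'   \item{`"domains"`}{good and weak substrates compared across the full
#'     enzyme and the single-domain-active mutants (E762Q = domain I
#'     active, E350Q = domain II active), with the dI/dII intensity ratio.}
#'   \item{`"hek_good"`}{good substrates identified in a HEK293T-derived
#'     peptidome across the same dose series.}
#'   \item{`"kinetics"`}{Michaelis-Menten constants for hydrolysis of
#'     dansyl-Phe-Ala-Arg by each enzyme form (NA = not detectable).}
#' }
#' Ratio columns keep the printed censored notation (`"<0.10"`, `">5.00"`);
#' use [parse_ratio()].
#'
#' @param which One of `"tryptic_good"`, `"domains"`, `"hek_good"`,
#'   `"kinetics"`.
#' @return `data.frame`.
#' @export
#' @examples
#' head(cpd_reference("tryptic_good"))
cpd_reference <- function(which = c("tryptic_good", "domains", "hek_good",
                                    "kinetics")) {
  which <- match.arg(which)
  file <- switch(which,
    tryptic_good = "ref_good_substrates_tryptic.tsv",
    domains = "ref_substrates_domains.tsv",
    hek_good = "ref_good_substrates_hek.tsv",
    kinetics = "ref_kinetics_dansyl_FAR.tsv"
  )
  path <- system.file("extdata", file, package = "cpdquant", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, colClasses = NA,
                    stringsAsFactors = FALSE)
}
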