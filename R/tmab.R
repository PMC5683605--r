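# TMAB (4-trimethylammoniumbutyrate) 5-plex label constants.
#
# Per-tag mass steps between isotopologue channels are frozen constants
# derived from standard atomic masses:
#   3 x (D - H)    = 3 x 1.006277 = 3.01883 Da  (D3, D6, D9 increments)
#   3 x (13C - 12C) = 3 x 1.003355 = 3.01007 Da  (D12 - D9 increment)
# The D0 tag addition (128.10753 Da) is the neutral-equivalent mass of the
# trimethylammonium-butyryl group per labeled amine: the tag's permanent
# quaternary cation contributes one charge, which is bookkept as if it were
# a proton at the m/z stage, so observable peak-set spacings are exact and
# absolute m/z carries a fixed, channel-independent convention.
.TMAB_TAG_MASS <- 128.10753
.TMAB_DELTAS <- c(D0 = 0, D3 = 3.01883, D6 = 6.03766, D9 = 9.05649,
                  D12 = 12.06656)

#' TMAB channel names
#'
#' The five isotopologue channels in increasing-mass order.
#'
#' @return Character vector `c("D0","D3","D6","D9","D12")`.
#' @export
tmab_channels <- function() names(.TMAB_DELTAS)

#' Per-tag channel mass deltas
#'
#' Mass addition per tag of each channel relative to D0 (Da).
#'
#' @return Named numeric vector over [tmab_channels()].
#' @export
tmab_channel_deltas <- function() .TMAB_DELTAS

#' Neutral-equivalent mass of a TMAB-labeled peptide
#'
#' Monoisotopic mass plus one tag per free amine:
#' `mass + T * (128.10753 + delta[channel])`. Errors for unlabelable
#' peptides (acetylated N-terminus and no Lys).
#'
#' @param p A [peptide()] or character sequence.
#' @param channel One of [tmab_channels()].
#' @return Neutral-equivalent labeled mass (Da).
#' @export
#' @examples
#' labeled_mass("QQAAALAK", "D0")   # 2 tags
labeled_mass <- function(p, channel = "D0") {
  p <- as_peptide(p)
  channel <- match.arg(channel, tmab_channels())
  tags <- count_free_amines(p)
  if (tags < 1L) {
    stop(sprintf("unlabelable peptide '%s': no free amines", format(p)))
  }
  monoisotopic_mass(p) + tags * (.TMAB_TAG_MASS + .TMAB_DELTAS[[channel]])
}

#' Predicted 5-channel peak-set pattern
#'
#' m/z of the five TMAB isotopologue peaks of a labeled peptide at a given
#' charge: `(labeled_mass + z * 1.00728) / z`. Adjacent-channel spacing is
#' `tags * step / z` (step 3.01883 Da for D0..D9, 3.01007 Da for D9->D12),
#' the geometric signature used for peak-set detection.
#'
#' @param p A [peptide()] or character sequence.
#' @param charge Positive integer charge state.
#' @return Object of class `labeled_pattern`: list with `peptide`
#'   (formatted sequence), `tag_count`, `charge` and `mz` (named vector over
#'   channels).
#' @export
#' @examples
#' peakset_pattern("QQAAALAK", charge = 2)
peakset_pattern <- function(p, charge) {
  p <- as_peptide(p)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("'charge' must be >= 1")
  tags <- count_free_amines(p)
  mz <- vapply(tmab_channels(), function(ch) {
    (labeled_mass(p, ch) + charge * .MASS_PROTON) / charge
  }, numeric(1))
  structure(
    list(peptide = format(p), tag_count = tags, charge = charge, mz = mz),
    class = "labeled_pattern"
  )
}

#' @export
print.labeled_pattern <- function(x, ...) {
  cat(sprintf("<labeled_pattern> %s  T=%d z=%d\n", x$peptide, x$tag_count,
              x$charge))
  print(round(x$mz, 4))
  invisible(x)
}

#' Recover tag count and charge from an ideal peak-set pattern
#'
#' Inverts the pattern geometry. The channel spacings fix the ratio
#' `tag_count / charge` (spacing = `tags * step / z`); supplying the
#' unlabeled monoisotopic mass of the peptide resolves the integer pair
#' uniquely via the absolute D0 position
#' `(mass + t*128.10753 + z*1.00728)/z`.
#'
#' @param mz Named numeric vector of channel m/z values (all five channels).
#' @param base_mass Unlabeled monoisotopic mass of the peptide (Da).
#' @param max_tags,max_charge Search bounds. Defaults 8 and 6.
#' @param tol Absolute m/z tolerance. Default 1e-6.
#' @return list with `tag_count` and `charge`, or error when no integer
#'   pair reproduces the pattern.
#' @export
infer_pattern_geometry <- function(mz, base_mass, max_tags = 8L,
                                   max_charge = 6L, tol = 1e-6) {
  stopifnot(all(tmab_channels() %in% names(mz)))
  d03 <- mz[["D3"]] - mz[["D0"]]
  d912 <- mz[["D12"]] - mz[["D9"]]
  for (z in seq_len(max_charge)) {
    for (t in seq_len(max_tags)) {
      d0 <- (base_mass + t * .TMAB_TAG_MASS + z * .MASS_PROTON) / z
      if (abs(d03 - t * 3.01883 / z) < tol &&
          abs(d912 - t * 3.01007 / z) < tol &&
          abs(d0 - mz[["D0"]]) < tol) {
        return(list(tag_count = t, charge = z))
      }
    }
  }
  stop("no (tag_count, charge) pair reproduces the observed pattern")
}
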