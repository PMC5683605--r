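#' Read a centroided peak list
#'
#' Tab-separated file with columns `mz` and `intensity` (header required;
#' lines starting with `#` ignored). Peaks are sorted by m/z on read.
#'
#' @param path File path.
#' @param run_id Run identifier; defaults to the file name.
#' @return `data.frame` with columns `mz`, `intensity` and attribute
#'   `run_id`.
#' @export
read_peak_list <- function(path, run_id = basename(path)) {
  df <- utils::read.delim(path, comment.char = "#")
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("peak list must have 'mz' and 'intensity' columns")
  }
  df <- df[order(df$mz), c("mz", "intensity")]
  rownames(df) <- NULL
  attr(df, "run_id") <- run_id
  df
}

#' Write a peak list as TSV
#'
#' @param peaks `data.frame` with `mz` and `intensity`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.table(peaks[, c("mz", "intensity")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Index of the peak nearest to `target`; exact ties broken toward lower m/z.
.nearest_peak <- function(mz, target) {
  i <- findInterval(target, mz)
  cand <- c(i, i + 1L)
  cand <- cand[cand >= 1L & cand <= length(mz)]
  if (!length(cand)) return(NA_integer_)
  d <- abs(mz[cand] - target)
  cand[order(d, mz[cand])][1L]
}

#' Detect 5-channel labeled peak sets
#'
#' For each library peptide and admissible charge (1 up to its expected
#' charge, or the charges supplied), searches the peak list for the
#' predicted TMAB channel pattern. A peak set is reported when at least
#' `min_channels` channels match within `tol_ppm`; intensities come from
#' the nearest matching centroid and unmatched channels get intensity 0.
#'
#' @param peaks Peak list `data.frame` (`mz`, `intensity`), sorted by m/z.
#' @param library Library `data.frame` with a `sequence` column (and
#'   optionally `precursor`). Sequences may use table notation.
#' @param charges `NULL` (all charges 1..expected), `"expected"` (the
#'   expected charge only), or an integer vector of charges to try.
#' @param tol_ppm Matching tolerance in ppm. Default 50.
#' @param min_channels Minimum matched channels to report a set. Default 2.
#' @return `data.frame` with one row per detected peak set: `sequence`,
#'   `precursor`, `charge`, `tag_count`, `n_matched`, and per-channel
#'   `intensity_*` and `ppm_*` columns.
#' @export
detect_peaksets <- function(peaks, library, charges = NULL, tol_ppm = 50,
                            min_channels = 2L) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (is.unsorted(peaks$mz)) stop("peak list must be sorted by m/z")
  if (!is.data.frame(library) || nrow(library) == 0L) {
    stop("'library' must be a non-empty data.frame with a sequence column")
  }
  if (any(peaks$intensity < 0)) stop("peak intensities must be >= 0")
  chs <- tmab_channels()
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(library))) {
    p <- as_peptide(library$sequence[i])
    if (count_free_amines(p) < 1L) next
    zmax <- expected_charge(p)
    zs <- if (is.null(charges)) {
      seq_len(zmax)
    } else if (identical(charges, "expected")) {
      zmax
    } else {
      intersect(as.integer(charges), seq_len(zmax))
    }
    for (z in zs) {
      pat <- peakset_pattern(p, z)
      idx <- vapply(pat$mz, .nearest_peak, integer(1), mz = peaks$mz)
      ppm <- ifelse(is.na(idx), NA_real_,
                    (peaks$mz[idx] - pat$mz) / pat$mz * 1e6)
      hit <- !is.na(ppm) & abs(ppm) <= tol_ppm
      if (sum(hit) < min_channels) next
      inten <- ifelse(hit, peaks$intensity[idx], 0)
      row <- data.frame(
        sequence = format(p),
        precursor = if ("precursor" %in% names(library))
          library$precursor[i] else NA_character_,
        charge = z, tag_count = pat$tag_count, n_matched = sum(hit),
        stringsAsFactors = FALSE
      )
      row[paste0("intensity_", chs)] <- as.list(unname(inten))
      row[paste0("ppm_", chs)] <- as.list(unname(ifelse(hit, ppm, NA_real_)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    out <- data.frame(sequence = character(), precursor = character(),
                      charge = integer(), tag_count = integer(),
                      n_matched = integer(), stringsAsFactors = FALSE)
    out[paste0("intensity_", chs)] <- list(numeric())
    out[paste0("ppm_", chs)] <- list(numeric())
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate a peptide identification
#'
#' Applies the acceptance criteria for an identification: parent mass
#' within `tol_ppm` of theoretical, tag count equal to the number of free
#' amines, observed charge admissible (at most the expected charge, or
#' exactly equal with `strict_charge = TRUE`), and — when MS2 fragments are
#' supplied — at least 80% of them matching predicted b/y ions with a
#' minimum of five matches. Peptides containing Cys, Tyr or His are flagged
#' (such peptides suffer label side reactions and are normally excluded).
#'
#' @param peptide A [peptide()] or character sequence.
#' @param observed_mass Observed neutral monoisotopic mass (Da).
#' @param observed_charge Observed charge state.
#' @param observed_tags Observed number of incorporated tags.
#' @param ms2_fragments Numeric vector of observed fragment m/z (the major
#'   fragments), or `NULL` when no MS2 was acquired.
#' @param frag_tol Absolute fragment matching tolerance (m/z units).
#'   Default 0.01.
#' @param tol_ppm Parent-mass tolerance (ppm). Default 50.
#' @param strict_charge Require observed charge == expected charge?
#'   Default `FALSE` (observed lower charge states are admissible).
#' @return List with flags `mass_ok`, `tag_ok`, `charge_ok`, `fragment_ok`
#'   (`NA` when MS2 not evaluated), `fragment_match_fraction`,
#'   `fragment_match_count`, `excluded_residue_flag`, `ppm` and `accepted`
#'   (all evaluated gates passed and not excluded).
#' @export
validate_identification <- function(peptide, observed_mass, observed_charge,
                                    observed_tags, ms2_fragments = NULL,
                                    frag_tol = 0.01, tol_ppm = 50,
                                    strict_charge = FALSE) {
  p <- as_peptide(peptide)
  if (!is.finite(observed_mass) || observed_mass <= 0) {
    stop("'observed_mass' must be positive")
  }
  ppm <- ppm_difference(observed_mass, monoisotopic_mass(p))
  mass_ok <- abs(ppm) <= tol_ppm
  tag_ok <- observed_tags == count_free_amines(p)
  zexp <- expected_charge(p)
  charge_ok <- if (strict_charge) observed_charge == zexp else
    observed_charge >= 1 && observed_charge <= zexp
  if (is.null(ms2_fragments)) {
    frac <- NA_real_; nmatch <- NA_integer_; fragment_ok <- NA
  } else if (length(ms2_fragments) == 0L) {
    frac <- 0; nmatch <- 0L; fragment_ok <- FALSE
  } else {
    pred <- by_fragment_series(p)$mz
    matched <- vapply(ms2_fragments, function(f) {
      any(abs(pred - f) <= frag_tol)
    }, logical(1))
    nmatch <- sum(matched)
    frac <- nmatch / length(ms2_fragments)
    fragment_ok <- frac >= 0.80 && nmatch >= 5L
  }
  excluded <- any(p$residues %in% c("C", "Y", "H"))
  accepted <- mass_ok && tag_ok && charge_ok && !excluded &&
    (is.na(fragment_ok) || fragment_ok)
  list(mass_ok = mass_ok, tag_ok = tag_ok, charge_ok = charge_ok,
       fragment_ok = fragment_ok, fragment_match_fraction = frac,
       fragment_match_count = nmatch, excluded_residue_flag = excluded,
       ppm = ppm, accepted = accepted)
}

#' Censored enzyme/control intensity ratios
#'
#' Converts one peak set's per-channel intensities into condition-wise
#' ratios against the control condition. Ratios below `floor` — or whose
#' numerator is at or below the background estimate — are reported at the
#' floor and flagged censored (printed `"<0.10"` in substrate tables);
#' ratios above `cap` are reported at the cap (printed `">5.00"`). A
#' control intensity at or below background makes the profile
#' unquantifiable.
#'
#' @param intensities Named numeric vector of channel intensities.
#' @param channel_config Named character vector mapping channel -> condition
#'   (e.g. `c(D0 = "100nM", ..., D12 = "0nM")`).
#' @param control Name of the control condition.
#' @param floor Lower censoring limit. Default 0.10.
#' @param cap Upper censoring limit. Default 5.00.
#' @param background Background intensity estimate. Default 0.
#' @return `data.frame` with columns `condition`, `ratio`, `censored`,
#'   plus attributes `control` and `quantifiable`.
#' @export
#' @examples
#' compute_ratios(c(D0 = 80, D12 = 1000),
#'                channel_config = c(D0 = "100nM", D12 = "0nM"),
#'                control = "0nM")
compute_ratios <- function(intensities, channel_config, control,
                           floor = 0.10, cap = 5.00, background = 0) {
  stopifnot(!is.null(names(intensities)), !is.null(names(channel_config)))
  if (!control %in% channel_config) {
    stop(sprintf("control condition '%s' not present in channel_config",
                 control))
  }
  ctrl_channel <- names(channel_config)[channel_config == control][1L]
  if (!ctrl_channel %in% names(intensities)) {
    stop(sprintf("control channel '%s' has no intensity", ctrl_channel))
  }
  ctrl <- intensities[[ctrl_channel]]
  conds <- unname(channel_config)
  out <- data.frame(condition = conds, ratio = NA_real_, censored = FALSE,
                    stringsAsFactors = FALSE)
  quantifiable <- is.finite(ctrl) && ctrl > background && ctrl > 0
  if (quantifiable) {
    for (i in seq_len(nrow(out))) {
      ch <- names(channel_config)[i]
      if (conds[i] == control) {
        out$ratio[i] <- 1
        next
      }
      num <- if (ch %in% names(intensities)) intensities[[ch]] else 0
      if (!is.finite(num) || num <= background) {
        out$ratio[i] <- floor; out$censored[i] <- TRUE
      } else {
        r <- num / ctrl
        if (r < floor) {
          out$ratio[i] <- floor; out$censored[i] <- TRUE
        } else if (r > cap) {
          out$ratio[i] <- cap; out$censored[i] <- TRUE
        } else {
          out$ratio[i] <- r
        }
      }
    }
  }
  attr(out, "control") <- control
  attr(out, "quantifiable") <- quantifiable
  out
}
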