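chs <- tmab_channels()
full5 <- function(v) setNames(as.list(rep(v, 5)), chs)

test_that("injected ideal patterns are recovered exactly once with 0 ppm", {
  seqs <- c("QQAAALAK", "LVTDLTK")
  peaks <- inject_peaklist(seqs, list(full5(1000), full5(500)))
  lib <- data.frame(sequence = c(seqs, "VVLQDR"))
  ps <- detect_peaksets(peaks, lib, charges = "expected")
  expect_identical(sort(ps$sequence), sort(seqs))      # absent peptide absent
  expect_identical(anyDuplicated(ps$sequence), 0L)
  for (i in seq_len(nrow(ps))) {
    expect_identical(ps$n_matched[i], 5L)
    expect_equal(as.numeric(ps[i, paste0("ppm_", chs)]), rep(0, 5),
                 tolerance = 1e-9)
  }
})

test_that("a missing channel yields a 4-channel set with zero intensity", {
  ints <- full5(1000)
  ints$D0 <- NULL
  peaks <- inject_peaklist("QQAAALAK", list(ints))
  ps <- detect_peaksets(peaks, data.frame(sequence = "QQAAALAK"),
                        charges = "expected")
  expect_identical(nrow(ps), 1L)
  expect_identical(ps$n_matched, 4L)
  expect_identical(ps$intensity_D0, 0)
  expect_true(is.na(ps$ppm_D0))
})

test_that("detection validates its inputs", {
  peaks <- data.frame(mz = c(500, 400), intensity = c(1, 1))
  expect_error(detect_peaksets(peaks, data.frame(sequence = "GAK")),
               "sorted")
  expect_error(detect_peaksets(data.frame(mz = 1, intensity = 1),
                               data.frame()), "non-empty")
})

test_that("identification gates follow the published criteria", {
  v <- validate_identification("VDPVNFK", observed_mass = 817.42,
                               observed_charge = 2, observed_tags = 2)
  expect_true(v$mass_ok)    # about -16 ppm, within 50
  expect_true(v$tag_ok)
  expect_true(v$charge_ok)  # observed 2 <= expected 2
  expect_true(is.na(v$fragment_ok))
  expect_true(v$accepted)
  # +51 ppm parent mass fails the gate
  m <- monoisotopic_mass("VDPVNFK")
  v2 <- validate_identification("VDPVNFK", m * (1 + 51e-6), 2, 2)
  expect_false(v2$mass_ok)
  # 80% matched but only 4 matches: below the minimum of five
  pred <- by_fragment_series("VDPVNFK")$mz
  frags <- c(pred[1:4], 9999)
  v3 <- validate_identification("VDPVNFK", m, 2, 2, ms2_fragments = frags)
  expect_equal(v3$fragment_match_fraction, 0.8)
  expect_identical(v3$fragment_match_count, 4L)
  expect_false(v3$fragment_ok)
  # 5 of 6 fragments is >= 80% with >= 5 matches
  v4 <- validate_identification("VDPVNFK", m, 2, 2,
                                ms2_fragments = c(pred[1:5], 9999))
  expect_true(v4$fragment_ok)
  # charge above the rule is rejected; lower charge only in strict mode
  v5 <- validate_identification("LRVDPVNFK", monoisotopic_mass("LRVDPVNFK"),
                                4, 2)
  expect_false(v5$charge_ok)
  v6 <- validate_identification("LRVDPVNFK", monoisotopic_mass("LRVDPVNFK"),
                                2, 2, strict_charge = TRUE)
  expect_false(v6$charge_ok)
  # Cys/Tyr/His peptides are flagged for exclusion
  v7 <- validate_identification("GACK", monoisotopic_mass("GACK"), 2, 2)
  expect_true(v7$excluded_residue_flag)
  expect_false(v7$accepted)
})

test_that("ratio computation censors at the floor and cap", {
  cfg <- c(D0 = "enzyme", D12 = "control")
  r <- compute_ratios(c(D0 = 80, D12 = 1000), cfg, control = "control")
  expect_equal(r$ratio[r$condition == "enzyme"], 0.10)
  expect_true(r$censored[r$condition == "enzyme"])
  r2 <- compute_ratios(c(D0 = 1000, D12 = 1000), cfg, control = "control")
  expect_equal(r2$ratio, c(1, 1))
  expect_false(any(r2$censored))
  r3 <- compute_ratios(c(D0 = 6000, D12 = 1000), cfg, control = "control")
  expect_equal(r3$ratio[r3$condition == "enzyme"], 5.00)
  expect_true(r3$censored[r3$condition == "enzyme"])
  # control below background: unquantifiable
  r4 <- compute_ratios(c(D0 = 500, D12 = 0), cfg, control = "control")
  expect_false(attr(r4, "quantifiable"))
  # numerator below background censors at the floor
  r5 <- compute_ratios(c(D0 = 40, D12 = 1000), cfg, control = "control",
                       background = 50)
  expect_equal(r5$ratio[r5$condition == "enzyme"], 0.10)
  expect_true(r5$censored[r5$condition == "enzyme"])
})

test_that("ratios are scale invariant and censoring is monotone", {
  cfg <- default_channel_config()
  ints <- c(D0 = 120, D3 = 600, D6 = 900, D9 = 980, D12 = 1000)
  r1 <- compute_ratios(ints, cfg, control = "0nM")
  r2 <- compute_ratios(ints * 37.5, cfg, control = "0nM")
  expect_equal(r1$ratio, r2$ratio)
  expect_identical(r1$censored, r2$censored)
  # decreasing an enzyme-channel intensity never increases its ratio
  prev <- Inf
  for (i in seq(1200, 0, by = -100)) {
    ints["D0"] <- i
    rr <- compute_ratios(ints, cfg, control = "0nM")
    val <- rr$ratio[rr$condition == "100nM"]
    expect_lte(val, prev + 1e-12)
    prev <- val
  }
})

test_that("peak lists round-trip through TSV", {
  peaks <- inject_peaklist("VVLQDR", list(full5(100)))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_peak_list(peaks, path)
  back <- read_peak_list(path)
  expect_equal(back$mz, peaks$mz)
  expect_equal(back$intensity, peaks$intensity)
})
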