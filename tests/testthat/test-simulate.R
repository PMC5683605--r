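test_that("generators are deterministic under a fixed seed", {
  t1 <- simulate_cleavage(c("AAGTLK", "VVSDQR"), seed = 61)
  t2 <- simulate_cleavage(c("AAGTLK", "VVSDQR"), seed = 61)
  expect_identical(t1, t2)
  p1 <- render_spectra(t1, noise_cv = 0.05, seed = 62)
  p2 <- render_spectra(t2, noise_cv = 0.05, seed = 62)
  expect_identical(p1, p2)
  d1 <- generate_rates(150, 10, 2.5, noise_cv = 0.05, seed = 63)
  d2 <- generate_rates(150, 10, 2.5, noise_cv = 0.05, seed = 63)
  expect_identical(d1, d2)
  expect_identical(generate_hek_peptidome(20, seed = 64),
                   generate_hek_peptidome(20, seed = 64))
})

test_that("the cleavage model enforces the P1'/P1 rules", {
  truth <- simulate_cleavage(c("AAGTLK", "AAGTPR", "AAGTLG"), seed = 65)
  sub <- truth[!truth$is_product, ]
  # ...L-K is cleavable and its product lacks the terminal Lys
  expect_gt(sub$efficiency[sub$sequence == "AAGTLK"], 0)
  expect_true("AAGTL" %in% truth$sequence[truth$is_product])
  expect_identical(
    truth$cleaved_residue[truth$is_product & truth$parent == "AAGTLK"], "K")
  # Pro in P1 blocks cleavage even with a basic C-terminus
  expect_identical(sub$efficiency[sub$sequence == "AAGTPR"], 0)
  expect_identical(sub$category[sub$sequence == "AAGTPR"], "non")
  # non-basic C-terminus is never a substrate
  expect_identical(sub$efficiency[sub$sequence == "AAGTLG"], 0)
  # zero-enzyme condition always has ratio 1
  expect_true(all(truth$ratio_0nM == 1))
})

test_that("peptidome composition matches the requested basic fraction", {
  none <- generate_hek_peptidome(50, basic_cterm_fraction = 0, seed = 66)
  last <- substr(none, nchar(none), nchar(none))
  expect_false(any(last %in% c("K", "R")))
  all_b <- generate_hek_peptidome(50, basic_cterm_fraction = 1, seed = 66)
  last <- substr(all_b, nchar(all_b), nchar(all_b))
  expect_true(all(last %in% c("K", "R")))
  big <- generate_hek_peptidome(1000, basic_cterm_fraction = 0.3, seed = 67)
  frac <- mean(substr(big, nchar(big), nchar(big)) %in% c("K", "R"))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  lens <- nchar(big)
  expect_true(all(lens >= 5 & lens <= 20))
})

test_that("domain-biased models skew the substrate P1' composition", {
  lib <- generate_substrate_library(150, seed = 68)
  count_subs <- function(model) {
    truth <- simulate_cleavage(lib, model = model, seed = 69)
    sub <- truth[!truth$is_product &
                   truth$category %in% c("good", "weak"), ]
    last <- substr(sub$sequence, nchar(sub$sequence), nchar(sub$sequence))
    c(K = sum(last == "K"), R = sum(last == "R"))
  }
  dI <- count_subs(enzyme_model("I"))
  dII <- count_subs(enzyme_model("II"))
  expect_gt(dI[["R"]], 2 * dI[["K"]])      # Arg-dominated under domain I
  expect_gt(dII[["K"]], 0.5 * dII[["R"]])  # comparable under domain II
})

test_that("noiseless spectra quantify back to the exact generated ratios", {
  lib <- generate_substrate_library(20, seed = 70)
  truth <- simulate_cleavage(lib, seed = 71)
  peaks <- render_spectra(truth, noise_cv = 0, seed = 72)
  ps <- detect_peaksets(peaks, data.frame(sequence = truth$sequence),
                        charges = "expected")
  cfg <- default_channel_config()
  for (i in seq_len(nrow(truth))) {
    row <- ps[ps$sequence == truth$sequence[i], ]
    expect_identical(nrow(row), 1L)
    ints <- setNames(as.numeric(row[paste0("intensity_", tmab_channels())]),
                     tmab_channels())
    rp <- compute_ratios(ints, cfg, control = "0nM")
    for (cond in rp$condition) {
      true_r <- truth[[paste0("ratio_", cond)]][i]
      got <- rp$ratio[rp$condition == cond]
      if (rp$censored[rp$condition == cond]) {
        expect_lt(true_r, 0.10)
      } else {
        expect_equal(got, true_r, tolerance = 1e-9)
      }
    }
  }
})
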