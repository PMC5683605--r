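dose <- c("0.1nM", "1nM", "10nM", "100nM")
ratios_at <- function(r100, r10 = 1, r1 = 1, r01 = 1) {
  setNames(c(r01, r1, r10, r100), dose)
}

test_that("threshold boundaries are closed/open as published", {
  expect_identical(classify_substrate(ratios_at(0.40))$category, "good")
  expect_identical(classify_substrate(ratios_at(0.401))$category, "weak")
  expect_identical(classify_substrate(ratios_at(0.80))$category, "weak")
  expect_identical(classify_substrate(ratios_at(0.801))$category, "non")
  expect_identical(classify_substrate(ratios_at(0.10))$category, "good")
})

test_that("dose-response profiles classify as in the reference rows", {
  # good substrate despite non-monotone intermediate doses
  lvtdltk <- ratios_at(0.40, 0.84, 1.05, 1.08)
  expect_identical(classify_substrate(lvtdltk)$category, "good")
  expect_identical(classify_substrate(ratios_at(0.54, 0.9, 1, 1))$category,
                   "weak")
  expect_identical(classify_substrate(ratios_at(1, 1, 1, 1))$category, "non")
  # rising profile correlated with enzyme amount is a product
  prod <- setNames(c(1.02, 1.2, 1.9, 2.6), dose)
  cl <- classify_substrate(prod)
  expect_identical(cl$category, "product")
  expect_true(cl$dose_consistent)
  # a rise below the product threshold is not called
  expect_identical(classify_substrate(ratios_at(1.4, 1.3, 1.1, 1))$category,
                   "non")
  # unquantifiable propagates
  expect_identical(
    classify_substrate(ratios_at(0.2), quantifiable = FALSE)$category,
    "unquantifiable")
  expect_error(classify_substrate(setNames(-1, "100nM")), "positive")
})

test_that("domain preference calls reproduce the censor conventions", {
  # residual intensity under domain I only, cleaved by domain II
  v <- call_domain_preference(
    c(rhCPD = 0.10, domain_I = 1.05, domain_II = 0.10),
    censored = c(rhCPD = TRUE, domain_I = FALSE, domain_II = TRUE))
  expect_identical(v$call, "domain_II_preferential")
  expect_equal(v$dI_dII_ratio, 5.00)
  expect_true(v$ratio_censored)
  # cleaved by domain I, residual under domain II
  f <- call_domain_preference(
    c(rhCPD = 0.12, domain_I = 0.10, domain_II = 0.24),
    censored = c(rhCPD = FALSE, domain_I = TRUE, domain_II = FALSE))
  expect_identical(f$call, "domain_I_preferential")
  expect_equal(f$dI_dII_ratio, 0.10)
  # equal residual: shared
  s <- call_domain_preference(
    c(rhCPD = 0.64, domain_I = 0.79, domain_II = 0.79))
  expect_identical(s$call, "shared")
  expect_equal(s$dI_dII_ratio, 1.00)
  # not a substrate of the full enzyme
  n <- call_domain_preference(
    c(rhCPD = 0.95, domain_I = 0.9, domain_II = 0.9))
  expect_identical(n$call, "neither")
  expect_error(call_domain_preference(c(rhCPD = 0.3, domain_I = 0.5)),
               "domain_II")
})

test_that("P1'/P1 profiles tally positions with the permissive restriction", {
  seqs <- c("QQAAALAK", "FAATSFR", "LVTDLTF", "GAK")
  cats <- c("good", "good", "weak", "weak")
  p1p <- build_profile(seqs, cats, position = "P1prime")
  expect_identical(sum(p1p), 4L)
  expect_identical(unname(p1p["F", "weak"]), 1L)
  # P1 profile drops the Phe-terminated peptide
  p1 <- build_profile(seqs, cats, position = "P1")
  expect_identical(sum(p1), 3L)
  expect_false("F" %in% colnames(p1))
  expect_identical(unname(p1["A", "good"]), 1L)  # QQAAAL[A]K
  # P1 totals never exceed the number of K/R-terminated peptides
  set.seed(41)
  rs <- random_sequences(30, c(3, 8))
  cs <- sample(c("good", "weak", "non"), 30, replace = TRUE)
  nkr <- sum(substr(rs, nchar(rs), nchar(rs)) %in% c("K", "R"))
  expect_lte(sum(build_profile(rs, cs, position = "P1")), nkr)
  expect_identical(dim(build_profile(character(), character())), c(0L, 0L))
})

test_that("cleavage deduction locates products and names the removed residue", {
  ded <- deduce_cleavage("LRVDPVNF", c(aHb = "HAHKLRVDPVNFKLLS"))
  expect_identical(nrow(ded), 1L)
  expect_identical(ded$cleaved_residue, "K")
  expect_identical(ded$site, 13L)
  expect_false(ded$ambiguous)
  # product at the precursor C-terminus has no downstream residue
  expect_error(deduce_cleavage("GAK", c(p = "GAK")), "C-terminus")
  expect_error(deduce_cleavage("WWW", c(p = "GAK")), "not found")
  # repeated occurrence is reported twice and flagged
  ded2 <- deduce_cleavage("AGA", c(p = "AGAKAGAR"))
  expect_identical(nrow(ded2), 2L)
  expect_true(all(ded2$ambiguous))
  expect_identical(ded2$cleaved_residue, c("K", "R"))
})

test_that("peptides with Cys/Tyr/His are screened out", {
  expect_identical(keep_analyzable(c("GAK", "GACK", "GAYK", "GAHK")),
                   c(TRUE, FALSE, FALSE, FALSE))
})
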