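test_that("center of mass is the mass-weighted mean of heavy atoms", {
  two <- data.frame(element = c("C", "C"), x = c(0, 2), y = 0, z = 0)
  expect_equal(center_of_mass(two), c(x = 1, y = 0, z = 0))
  one <- data.frame(element = "N", x = 3, y = -1, z = 2)
  expect_equal(unname(center_of_mass(one)), c(3, -1, 2))
  # mass-weighted: (15.999 * 1.33) / (12.011 + 15.999)
  co <- data.frame(element = c("C", "O"), x = c(0, 1.33), y = 0, z = 0)
  expect_equal(center_of_mass(co)[["x"]], 0.759681, tolerance = 1e-6)
  # hydrogens excluded unless requested
  ch <- data.frame(element = c("C", "H"), x = c(0, 1), y = 0, z = 0)
  expect_equal(center_of_mass(ch)[["x"]], 0)
  expect_gt(center_of_mass(ch, include_h = TRUE)[["x"]], 0)
  expect_error(center_of_mass(ch[0, ]), "no atoms")
  # COM stays inside the atoms' bounding box
  set.seed(51)
  for (i in 1:10) {
    atoms <- data.frame(element = sample(c("C", "N", "O", "S"), 8, TRUE),
                        x = runif(8, -5, 5), y = runif(8, -5, 5),
                        z = runif(8, -5, 5))
    com <- center_of_mass(atoms)
    expect_true(all(com >= c(min(atoms$x), min(atoms$y), min(atoms$z))))
    expect_true(all(com <= c(max(atoms$x), max(atoms$y), max(atoms$z))))
  }
})

test_that("pose correctness applies the dual 10 A criterion", {
  rec <- toy_receptor()
  pocket <- toy_pocket()
  expect_true(pose_is_correct(toy_pose_at(9.9, 9.9), rec, pocket))
  expect_false(pose_is_correct(toy_pose_at(10.1, 9.9), rec, pocket))
  expect_false(pose_is_correct(toy_pose_at(9.9, 10.1), rec, pocket))
  expect_true(pose_is_correct(toy_pose_at(0, 0), rec, pocket))
  bad <- pocket_definition(s1prime = list(chain = "A", resno = 99L),
                           s1 = list(chain = "A", resno = 2L))
  expect_error(pose_is_correct(toy_pose_at(1, 1), rec, bad), "resno 99")
})

test_that("correctness flags are invariant under rigid motion", {
  g <- generate_poses(4, n_inside = 10, n_outside = 10, seed = 52)
  before <- score_poses(g$poses, g$receptor, g$pocket)$per_pose_correct
  theta <- 0.83
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  shift <- c(12, -7, 4)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + shift[1]
    df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  after <- score_poses(lapply(g$poses, move), move(g$receptor),
                       g$pocket)$per_pose_correct
  expect_identical(after, before)
})

test_that("percent correct matches construction and grows with the cutoff", {
  g <- generate_poses(4, n_inside = 101, n_outside = 0, seed = 53)
  expect_equal(score_poses(g$poses, g$receptor, g$pocket)$percent_correct, 100)
  g0 <- generate_poses(4, n_inside = 0, n_outside = 20, seed = 54)
  expect_equal(score_poses(g0$poses, g0$receptor, g0$pocket)$percent_correct, 0)
  gm <- generate_poses(4, n_inside = 30, n_outside = 30, seed = 55)
  pcts <- vapply(c(2, 5, 10, 20, 40), function(cut) {
    score_poses(gm$poses, gm$receptor, toy_pocket(cutoff = cut))$percent_correct
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("rank correlation matches the closed-form Spearman statistic", {
  # anti-monotone scores and ratios give rho = +1 under the sign convention
  scores <- c(a = 90, b = 60, c = 30, d = 10)
  ratios <- c(a = 0.1, b = 0.4, c = 0.7, d = 0.95)
  expect_equal(rank_correlation(scores, ratios), 1)
  expect_warning(rho <- rank_correlation(c(a = 1, b = 1, c = 1), ratios[1:3]),
                 "constant")
  expect_true(is.na(rho))
  expect_error(rank_correlation(scores[1:2], ratios[1:2]), ">= 3")
  # seeded random pairs against the 1 - 6*sum(d^2)/(n(n^2-1)) formula
  set.seed(56)
  s <- setNames(sample(1:100, 6), letters[1:6])
  r <- setNames(runif(6), letters[1:6])
  d <- rank(s) - rank(1 - r)
  expect_equal(rank_correlation(s, r), 1 - 6 * sum(d^2) / (6 * (36 - 1)))
})

test_that("toy pose sets round-trip through PDB files", {
  g <- generate_poses(3, n_inside = 2, n_outside = 1, seed = 57)
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  # write a minimal multi-model PDB by hand and read it back with bio3d
  lines <- character(0)
  for (m in seq_along(g$poses)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    pose <- g$poses[[m]]
    for (i in seq_len(nrow(pose))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        i, pose$resid[i], pose$chain[i], pose$resno[i],
        pose$x[i], pose$y[i], pose$z[i], pose$element[i]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  models <- read_structure_pdb(path, multi = TRUE)
  expect_length(models, 3)
  flags <- vapply(models, pose_is_correct, logical(1),
                  receptor = g$receptor, pocket = g$pocket)
  expect_identical(unname(flags), g$truth)
})
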