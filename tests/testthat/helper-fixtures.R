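# Shared in-code fixtures for the test suite.

# Peak list holding the ideal 5-channel pattern of each peptide, with the
# given per-channel intensities (named by channel, missing channels dropped).
inject_peaklist <- function(sequences, intensities, charges = NULL) {
  mzs <- numeric(0); ints <- numeric(0)
  for (i in seq_along(sequences)) {
    z <- if (is.null(charges)) expected_charge(sequences[i]) else charges[i]
    pat <- peakset_pattern(sequences[i], z)
    for (ch in names(intensities[[i]])) {
      mzs <- c(mzs, pat$mz[[ch]])
      ints <- c(ints, intensities[[i]][[ch]])
    }
  }
  ord <- order(mzs)
  data.frame(mz = mzs[ord], intensity = ints[ord])
}

# Minimal structure: one single-atom residue per element of `coords`
# (a named list resno -> xyz), so each residue COM is its coordinate.
toy_structure <- function(coords, chain = "A", element = "C") {
  rows <- lapply(seq_along(coords), function(i) {
    data.frame(chain = chain, resno = as.integer(names(coords)[i]),
               resid = "GLY", elety = element, element = element,
               x = coords[[i]][1], y = coords[[i]][2], z = coords[[i]][3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Toy two-residue pocket receptor: S1' residue 1 at origin, S1 residue 2 at
# (6, 0, 0), matching generate_poses().
toy_receptor <- function() {
  toy_structure(list(`1` = c(0, 0, 0), `2` = c(6, 0, 0)), element = "O")
}

toy_pocket <- function(cutoff = 10) {
  pocket_definition(s1prime = list(chain = "A", resno = 1L),
                    s1 = list(chain = "A", resno = 2L), cutoff = cutoff)
}

# Pose whose P1 (resno 3) and P1' (resno 4) single-atom residues sit at the
# requested distances from the two pocket centers, along +y.
toy_pose_at <- function(d_p1prime, d_p1) {
  toy_structure(list(`1` = c(-3, 3, 0), `2` = c(-1, 3, 0),
                     `3` = c(6, d_p1, 0), `4` = c(0, d_p1prime, 0)),
                chain = "B")
}

# Random valid peptide sequences for property tests.
random_sequences <- function(n, len_range = c(3L, 12L)) {
  alphabet <- names(amino_acid_masses())
  vapply(seq_len(n), function(i) {
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}
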