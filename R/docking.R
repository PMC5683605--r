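# Standard atomic masses for the heavy atoms commonly present in protein
# structures (H retained for the include_h option).
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, SE = 78.971, ZN = 65.38)

#' Mass-weighted center of mass of a set of atoms
#'
#' Hydrogens are excluded by default (pose files often lack them); masses
#' come from the standard atomic-mass table.
#'
#' @param atoms `data.frame` with columns `element`, `x`, `y`, `z`.
#' @param include_h Include hydrogens? Default `FALSE`.
#' @return Numeric length-3 vector `(x, y, z)` in Angstrom.
#' @export
#' @examples
#' center_of_mass(data.frame(element = c("C", "O"),
#'                           x = c(0, 1.33), y = 0, z = 0))
center_of_mass <- function(atoms, include_h = FALSE) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!include_h) atoms <- atoms[toupper(atoms$element) != "H", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no atoms to average")
  el <- toupper(atoms$element)
  unknown <- setdiff(unique(el), names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop(sprintf("unknown element(s): %s", paste(unknown, collapse = ", ")))
  }
  w <- .ATOMIC_MASS[el]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  colSums(xyz * w) / sum(w)
}

#' Read a protein/peptide structure from PDB
#'
#' Thin wrapper over [bio3d::read.pdb()] returning the atom table in the
#' column layout the pose filter uses. Multi-model files (MODEL/ENDMDL
#' records, e.g. docking pose ensembles) return a list of per-model tables.
#'
#' @param path PDB file path.
#' @param multi Read all models? Default `FALSE` (first model only).
#' @return A `data.frame` (`chain`, `resno`, `resid`, `elety`, `element`,
#'   `x`, `y`, `z`) or a list of them when `multi = TRUE`.
#' @export
read_structure_pdb <- function(path, multi = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = multi)
  atom <- pdb$atom
  element <- atom$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- substr(trimws(atom$elety), 1L, 1L)
  }
  base <- data.frame(
    chain = atom$chain, resno = atom$resno, resid = atom$resid,
    elety = atom$elety, element = toupper(trimws(element)),
    x = atom$x, y = atom$y, z = atom$z, stringsAsFactors = FALSE
  )
  nmodels <- nrow(pdb$xyz)
  if (!multi || is.null(nmodels) || nmodels <= 1L) return(base)
  lapply(seq_len(nmodels), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    out <- base
    out$x <- xyz[, 1L]; out$y <- xyz[, 2L]; out$z <- xyz[, 3L]
    out
  })
}

#' Define the S1'/S1 pocket criterion
#'
#' @param s1prime List/vector with `chain` and `resno` of the S1' pocket
#'   residue (e.g. the conserved Asp that binds the P1' basic side chain).
#' @param s1 Same for the S1 pocket residue (e.g. the Glu contacting P1).
#' @param cutoff Distance cutoff in Angstrom (> 0). Default 10.
#' @return Object of class `pocket_definition`.
#' @export
pocket_definition <- function(s1prime, s1, cutoff = 10) {
  if (cutoff <= 0) stop("'cutoff' must be positive")
  structure(list(s1prime = s1prime, s1 = s1, cutoff = cutoff),
            class = "pocket_definition")
}

# Heavy-atom COM of one receptor residue, error naming it when absent.
.residue_com <- function(structure, chain, resno, label) {
  sel <- structure$resno == resno &
    (is.na(chain) | is.na(structure$chain) | structure$chain == chain)
  atoms <- structure[sel, , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop(sprintf("pocket residue %s (chain %s, resno %s) not found in receptor",
                 label, chain, resno))
  }
  center_of_mass(atoms)
}

# Residue-wise split of a pose, ordered N->C by residue number.
.pose_residues <- function(pose) {
  ord <- unique(pose$resno[order(pose$resno)])
  lapply(ord, function(r) pose[pose$resno == r, , drop = FALSE])
}

#' Is a docking pose geometrically correct?
#'
#' A pose is correct when the centers of mass of its P1' (C-terminal) and
#' P1 (penultimate) residues lie within `pocket$cutoff` Angstrom of the
#' centers of mass of the receptor's S1' and S1 pocket residues,
#' respectively.
#'
#' @param pose Pose atom table (see [read_structure_pdb()]), >= 2 residues.
#' @param receptor Receptor atom table.
#' @param pocket A [pocket_definition()].
#' @return Logical flag.
#' @export
pose_is_correct <- function(pose, receptor, pocket) {
  stopifnot(inherits(pocket, "pocket_definition"))
  res <- .pose_residues(pose)
  if (length(res) < 2L) stop("pose must contain >= 2 residues")
  p1prime <- center_of_mass(res[[length(res)]])
  p1 <- center_of_mass(res[[length(res) - 1L]])
  s1p <- .residue_com(receptor, pocket$s1prime$chain, pocket$s1prime$resno,
                      "S1'")
  s1 <- .residue_com(receptor, pocket$s1$chain, pocket$s1$resno, "S1")
  d1p <- sqrt(sum((p1prime - s1p)^2))
  d1 <- sqrt(sum((p1 - s1)^2))
  d1p <= pocket$cutoff && d1 <= pocket$cutoff
}

#' Percent of correct poses in a docking ensemble
#'
#' Applies [pose_is_correct()] to every pose and reports the percentage of
#' correct solutions over all supplied poses (the published protocol scores
#' 101 minimized poses per peptide/domain).
#'
#' @param poses List of pose atom tables.
#' @param receptor Receptor atom table.
#' @param pocket A [pocket_definition()].
#' @return List with `per_pose_correct` (logical vector), `percent_correct`
#'   and `n`.
#' @export
score_poses <- function(poses, receptor, pocket) {
  if (!length(poses)) stop("need >= 1 pose")
  flags <- vapply(poses, pose_is_correct, logical(1),
                  receptor = receptor, pocket = pocket)
  list(per_pose_correct = flags,
       percent_correct = 100 * sum(flags) / length(flags),
       n = length(flags))
}

#' Rank correlation between pose scores and experimental cleavage
#'
#' Spearman correlation between percent-correct pose scores and the
#' experimental cleavage extent `1 - ratio` (enzyme/control intensity
#' ratio), so that a positive coefficient means more correct poses go with
#' stronger cleavage.
#'
#' @param scores Named numeric vector: peptide -> percent correct.
#' @param ratios Named numeric vector: peptide -> enzyme/control ratio.
#' @return Spearman rho (`NA` with a warning when either input is
#'   constant).
#' @export
rank_correlation <- function(scores, ratios) {
  common <- intersect(names(scores), names(ratios))
  if (length(common) < 3L) stop("need >= 3 paired peptides")
  s <- scores[common]; r <- 1 - ratios[common]
  if (stats::sd(s) == 0 || stats::sd(r) == 0) {
    warning("constant scores or ratios: rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(s, r, method = "spearman")
}
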