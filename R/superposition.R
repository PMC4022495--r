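# Rigid-body superposition (Kabsch), RMSD between conformers, and the
# two-stage fixed/moving-domain fit used to measure Venus fly-trap closure
# angles between open and closed conformers.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum | A_i - (R B_i + t) |^2` over paired coordinates, i.e. the rigid
#' transform mapping `coordsB` onto `coordsA`.  Reflections are corrected via
#' the sign of the smallest singular value, so `det(R) = +1` always.
#'
#' @param coordsA,coordsB n x 3 matrices of paired coordinates (n >= 3).
#' @return list of class `superposition_result` with elements `rotation`
#'   (3 x 3), `translation` (3-vector), `rmsd` (Angstrom, residual after the
#'   fit) and `n_atoms`.
#' @export
kabsch <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (!all(dim(coordsA) == dim(coordsB)))
    stop("coordinate sets differ in size")
  n <- nrow(coordsA)
  if (n < 3) stop("need at least 3 paired atoms for superposition")
  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  Ac <- sweep(coordsA, 2, ca); Bc <- sweep(coordsB, 2, cb)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (rank < 2) point set: superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ca - as.vector(R %*% cb)
  fitted <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ac - fitted)^2)))
  structure(list(rotation = R, translation = t_vec,
                 rmsd = rmsd, n_atoms = n),
            class = "superposition_result")
}

#' Apply a rigid transform to coordinates or to a structure
#'
#' @param x n x 3 coordinate matrix or a [protein_structure].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector (Angstrom).
#' @return transformed object of the same type.
#' @export
apply_transform <- function(x, rotation, translation = c(0, 0, 0)) {
  if (inherits(x, "protein_structure")) {
    xyz <- atom_xyz(x) %*% t(rotation)
    xyz <- sweep(xyz, 2, translation, "+")
    return(set_atom_xyz(x, xyz))
  }
  sweep(as.matrix(x) %*% t(rotation), 2, translation, "+")
}

pair_selections <- function(selA, selB) {
  keyA <- paste(selA$index$resno, selA$index$insert, selA$index$elety)
  keyB <- paste(selB$index$resno, selB$index$insert, selB$index$elety)
  common <- intersect(keyA, keyB)
  list(A = selA$xyz[match(common, keyA), , drop = FALSE],
       B = selB$xyz[match(common, keyB), , drop = FALSE],
       n_dropped = (length(keyA) - length(common)) +
                   (length(keyB) - length(common)))
}

#' RMSD between two structures over a selection
#'
#' Atoms are paired by author residue number (and atom name) so that residues
#' missing from one structure are dropped rather than misaligned.
#'
#' @param structA,structB [protein_structure] objects (single chains or a
#'   chain selected via `chainA`/`chainB`).
#' @param selection a [domain_def], range string, or NULL for all residues.
#' @param atom_names atoms used (default CA).
#' @param fit if TRUE (default) superpose by [kabsch] first; if FALSE report
#'   RMSD in the current frames.
#' @param chainA,chainB chain ids to compare (default: first chain of each).
#' @return RMSD in Angstrom, with attributes `n_atoms` and `n_dropped`.
#' @export
rmsd_structures <- function(structA, structB, selection = NULL,
                            atom_names = "CA", fit = TRUE,
                            chainA = chain_ids(structA)[1],
                            chainB = chain_ids(structB)[1]) {
  selection <- chain_agnostic(selection)
  selA <- select_atoms(get_chain(structA, chainA, include_het = FALSE),
                       selection, atom_names)
  selB <- select_atoms(get_chain(structB, chainB, include_het = FALSE),
                       selection, atom_names)
  pr <- pair_selections(selA, selB)
  if (nrow(pr$A) < 3) stop("pairing produced fewer than 3 atoms")
  val <- if (fit) {
    kabsch(pr$A, pr$B)$rmsd
  } else {
    sqrt(mean(rowSums((pr$A - pr$B)^2)))
  }
  attr(val, "n_atoms") <- nrow(pr$A)
  attr(val, "n_dropped") <- pr$n_dropped
  val
}

#' Domain closure/rotation between two conformers
#'
#' Two-stage fit in the spirit of hinge-bending (DynDom-style) analysis with
#' explicitly supplied domains: (1) superpose conformer B onto conformer A
#' using the `fixed_domain` atoms; (2) superpose the transformed B's
#' `moving_domain` onto A's `moving_domain`.  The stage-2 rotation is the
#' closure: its angle (degrees, in [0, 180]) and right-handed unit axis are
#' reported, together with the fixed-domain residual RMSD and the
#' moving-domain RMSD after the stage-1 fit only (diagnostics).
#'
#' @param structA,structB conformers (same chain numbering).
#' @param fixed_domain,moving_domain [domain_def]s or range strings.
#' @param atom_names atoms used for both fits (default CA).
#' @param chainA,chainB chains compared.
#' @return list of class `domain_motion_result` with `angle`, `axis`,
#'   `fixed_rmsd`, `moving_rmsd`, `rotation`.
#' @export
closure_analysis <- function(structA, structB, fixed_domain, moving_domain,
                             atom_names = "CA",
                             chainA = chain_ids(structA)[1],
                             chainB = chain_ids(structB)[1]) {
  if (is.character(fixed_domain)) fixed_domain <- domain_def("fixed", fixed_domain)
  if (is.character(moving_domain)) moving_domain <- domain_def("moving", moving_domain)
  # single-chain comparison: residue ranges apply to whichever chain is used
  fixed_domain <- chain_agnostic(fixed_domain)
  moving_domain <- chain_agnostic(moving_domain)
  A <- get_chain(structA, chainA, include_het = FALSE)
  B <- get_chain(structB, chainB, include_het = FALSE)
  fA <- select_atoms(A, fixed_domain, atom_names)
  fB <- select_atoms(B, fixed_domain, atom_names)
  pf <- pair_selections(fA, fB)
  if (nrow(pf$A) < 3) stop("fixed-domain fit failed: fewer than 3 paired atoms")
  fit1 <- kabsch(pf$A, pf$B)
  mA <- select_atoms(A, moving_domain, atom_names)
  mB <- select_atoms(B, moving_domain, atom_names)
  pm <- pair_selections(mA, mB)
  if (nrow(pm$A) < 3) stop("moving-domain fit failed: fewer than 3 paired atoms")
  mB1 <- apply_transform(pm$B, fit1$rotation, fit1$translation)
  moving_rmsd <- sqrt(mean(rowSums((pm$A - mB1)^2)))
  fit2 <- kabsch(pm$A, mB1)
  aa <- rotation_angle_axis(fit2$rotation)
  structure(list(angle = aa$angle, axis = aa$axis,
                 fixed_rmsd = fit1$rmsd, moving_rmsd = moving_rmsd,
                 moving_fit_rmsd = fit2$rmsd,
                 rotation = fit2$rotation),
            class = "domain_motion_result")
}

#' @export
print.domain_motion_result <- function(x, ...) {
  cat(sprintf(
    "domain closure: %.3f deg about axis (%.3f, %.3f, %.3f)\n  fixed-domain rmsd %.3f A; moving-domain rmsd after fixed fit %.3f A\n",
    x$angle, x$axis[1], x$axis[2], x$axis[3], x$fixed_rmsd, x$moving_rmsd))
  invisible(x)
}
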