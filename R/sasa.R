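# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral point set, and SASA-based buried interface area for a dimer.

#' Default van der Waals radii (Angstrom) by element
#' @export
DEFAULT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Deterministic quasi-uniform points on the unit sphere (golden spiral)
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

atom_radii <- function(atoms, radii, default_radius) {
  r <- unname(radii[atoms$elesy])
  if (any(is.na(r))) {
    if (is.null(default_radius))
      stop("no radius for element(s): ",
           paste(unique(atoms$elesy[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- default_radius
  }
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each heavy atom is expanded by the probe radius and sampled with a
#' deterministic golden-spiral point set; a point is exposed iff it lies
#' outside every neighbouring expanded sphere.  The atom's area is the
#' exposed fraction times `4*pi*(r+w)^2`.  Waters are always excluded;
#' hetero residues are excluded unless `include_het = TRUE`.
#'
#' @param s a [protein_structure].
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 960, minimum 92).
#' @param radii named vector element -> radius (Angstrom).
#' @param default_radius radius for elements missing from `radii`; set to
#'   NULL to make unknown elements an error.
#' @param include_het include hetero (ligand) atoms.
#' @return list of class `sasa_result`: `per_atom` (Angstrom^2), `total`,
#'   `probe_radius`, `n_points`, and `atoms` (the atom table scored, same
#'   order as `per_atom`).
#' @export
sasa <- function(s, probe = 1.4, n_points = 960, radii = DEFAULT_RADII,
                 default_radius = 1.70, include_het = FALSE) {
  stopifnot(inherits(s, "protein_structure"), probe > 0, n_points >= 92)
  a <- census_atoms(s, include_het)
  if (nrow(a) == 0) stop("no heavy atoms to score")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- atom_radii(a, radii, default_radius) + probe
  n <- nrow(a)
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)
  # neighbour lists from the full distance matrix (fine at analysis sizes)
  D2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  for (i in seq_len(n)) {
    lim <- (R[i] + R)^2
    nb <- which(D2[i, ] < lim & seq_len(n) != i)
    P <- sweep(pts * R[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
            (P[, 3] - xyz[j, 3])^2
      exposed <- exposed & dd > R[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe_radius = probe, n_points = n_points, atoms = a),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe_radius, x$n_points))
  invisible(x)
}

#' Buried interface area between two sides of a complex
#'
#' Computes the SASA of each side in isolation and of the complex.  The
#' total buried area is `SASA(side1) + SASA(side2) - SASA(complex)` (the
#' "total buried area" convention, NOT halved); the halved value is also
#' reported as `interface_area` for comparison with tools that report
#' per-interface area.  Waters and hetero ligands are excluded by default.
#'
#' @param s a [protein_structure] with at least two chains.
#' @param chains_side1,chains_side2 chain id vectors for the two sides
#'   (disjoint, non-empty).
#' @param probe,n_points,radii,default_radius see [sasa].
#' @param include_het include hetero atoms in the area computation.
#' @param residue_threshold per-residue buried area (Angstrom^2) above which
#'   a residue is listed as interfacial (default 1).
#' @return list of class `interface_report`: `buried_total`,
#'   `buried_per_side` (named), `interface_area` (= buried_total / 2),
#'   `interface_residues` (data.frame chain, resno, resid, buried).
#' @export
buried_area <- function(s, chains_side1, chains_side2, probe = 1.4,
                        n_points = 960, radii = DEFAULT_RADII,
                        default_radius = 1.70, include_het = FALSE,
                        residue_threshold = 1) {
  if (length(chains_side1) == 0 || length(chains_side2) == 0)
    stop("both sides must contain at least one chain")
  if (length(intersect(chains_side1, chains_side2)))
    stop("overlapping side definitions: ",
         paste(intersect(chains_side1, chains_side2), collapse = ","))
  a <- census_atoms(s, include_het)
  a1 <- a[a$chain %in% chains_side1, , drop = FALSE]
  a2 <- a[a$chain %in% chains_side2, , drop = FALSE]
  if (nrow(a1) == 0 || nrow(a2) == 0) stop("a side selects no atoms")
  sub <- function(at, id) protein_structure(at, id = id)
  s1 <- sasa(sub(a1, "side1"), probe, n_points, radii, default_radius,
             include_het = TRUE)
  s2 <- sasa(sub(a2, "side2"), probe, n_points, radii, default_radius,
             include_het = TRUE)
  sc <- sasa(sub(rbind(a1, a2), "complex"), probe, n_points, radii,
             default_radius, include_het = TRUE)
  iso <- c(s1$per_atom, s2$per_atom)
  loss <- iso - sc$per_atom      # per atom, complex order = rbind(a1, a2)
  side <- rep(c("side1", "side2"), c(nrow(a1), nrow(a2)))
  buried_per_side <- c(side1 = sum(loss[side == "side1"]),
                       side2 = sum(loss[side == "side2"]))
  at <- sc$atoms
  res_key <- paste(at$chain, at$resno, at$insert)
  res_loss <- tapply(loss, res_key, sum)
  res_first <- !duplicated(res_key)
  res_tab <- data.frame(chain = at$chain[res_first],
                        resno = at$resno[res_first],
                        resid = at$resid[res_first],
                        buried = as.numeric(res_loss[res_key[res_first]]),
                        stringsAsFactors = FALSE)
  res_tab <- res_tab[res_tab$buried > residue_threshold, , drop = FALSE]
  res_tab <- res_tab[order(res_tab$chain, res_tab$resno), , drop = FALSE]
  rownames(res_tab) <- NULL
  structure(list(buried_total = s1$total + s2$total - sc$total,
                 buried_per_side = buried_per_side,
                 interface_area = (s1$total + s2$total - sc$total) / 2,
                 interface_residues = res_tab,
                 probe_radius = probe, n_points = n_points),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(
    "buried interface: total %.1f A^2 (per side %.1f / %.1f; halved %.1f); %d interface residues\n",
    x$buried_total, x$buried_per_side[1], x$buried_per_side[2],
    x$interface_area, nrow(x$interface_residues)))
  invisible(x)
}
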