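# Deterministic synthetic-structure generators.  Backbones are built from
# internal coordinates (NeRF chain extension) with idealized bond lengths
# (N-CA 1.458, CA-C 1.525, C-N 1.329 A), so fixtures can prescribe
# phi/psi/omega, the N-CA-C angle, and the carbonyl out-of-plane angle
# exactly.  Residues are poly-Ala (backbone + CB); no rotamers, no packing
# realism, no energies - these are geometric test articles, not models of
# real folds.

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_CA_CB <- 1.521
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_O_C_N  <- 122.7
ANGLE_CA_C_O <- 120.8

HELIX_PHI <- -57; HELIX_PSI <- -47
STRAND_PHI <- -139; STRAND_PSI <- 135

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a poly-Ala backbone from internal coordinates
#'
#' Residue i carries atoms N, CA, C, O (and CB unless `with_cb = FALSE`).
#' `psi[i]`, `omega[i]` and `theta_c[i]` describe the peptide between
#' residues i and i+1 (the last entries are ignored); `phi[i]` is ignored for
#' the first residue; `ncac[i]` is the N-CA-C bond angle of residue i.
#' `theta_c` is the carbonyl pyramidalization: the deviation from 180 degrees
#' of the improper torsion O(i)-C(i)-N(i+1)-CA(i), so 0 gives an exactly
#' planar peptide unit.
#'
#' @param n number of residues.
#' @param phi,psi,omega,ncac,theta_c scalars or length-n vectors, degrees.
#' @param resid 3-letter residue name(s).
#' @param chain chain id.
#' @param first_resno author number of the first residue.
#' @param with_cb add CB atoms (default TRUE).
#' @param id structure label.
#' @return a [protein_structure].
#' @export
build_backbone <- function(n, phi = HELIX_PHI, psi = HELIX_PSI, omega = 180,
                           ncac = 111.0, theta_c = 0, resid = "ALA",
                           chain = "A", first_resno = 1L, with_cb = TRUE,
                           id = "synthetic") {
  stopifnot(n >= 2)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  ncac <- rep_len(ncac, n); theta_c <- rep_len(theta_c, n)
  resid <- rep_len(resid, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th1 <- deg2rad(ncac[1])
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(th1), sin(th1), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_N,
                             ANGLE_CA_C_N, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], BOND_N_CA,
                              ANGLE_C_N_CA, omega[i])
    O[i, ] <- place_atom(CA[i, ], N[i + 1, ], C[i, ], BOND_C_O,
                         ANGLE_O_C_N, 180 + theta_c[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], BOND_CA_C,
                             ncac[i + 1], phi[i + 1])
  }
  O[n, ] <- place_atom(N[n, ], CA[n, ], C[n, ], BOND_C_O, ANGLE_CA_C_O, 180)
  rows <- list()
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    pos <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (with_cb && resid[i] != "GLY") {
      cb <- place_atom(C[i, ], N[i, ], CA[i, ], BOND_CA_CB, 110.5, -122.5)
      nm <- c(nm, "CB"); pos <- rbind(pos, cb)
    }
    rows[[i]] <- data.frame(chain = chain, resno = first_resno + i - 1L,
                            insert = "", resid = resid[i], elety = nm,
                            elesy = substr(nm, 1, 1),
                            x = pos[, 1], y = pos[, 2], z = pos[, 3],
                            o = 1, b = 0, alt = "", het = FALSE,
                            stringsAsFactors = FALSE)
  }
  protein_structure(do.call(rbind, rows), id = id)
}

#' Ideal peptide fixtures for stereochemistry checks
#'
#' @param n_helix,n_strand residues in the helix and in each sheet strand.
#' @param delta_omega peptide-planarity offset (degrees) applied to the
#'   `dipeptide_offset` fixture, so its omega is `180 + delta_omega`.
#' @param theta_c_offset carbonyl pyramidalization (degrees) applied to the
#'   `dipeptide_offset` fixture.
#' @param helix_ncac,strand_ncac N-CA-C angles used for the helix and sheet
#'   fixtures (defaults are the literature-typical helix/sheet values).
#' @return named list of [protein_structure]s: `helix`, `sheet` (two chains,
#'   antiparallel), `dipeptide` (exact trans planar), `dipeptide_offset`,
#'   `strand` (single extended strand).
#' @export
make_ideal_peptide_fixtures <- function(n_helix = 16, n_strand = 8,
                                        delta_omega = -5, theta_c_offset = 3,
                                        helix_ncac = 111.2,
                                        strand_ncac = 108.9) {
  helix <- build_backbone(n_helix, HELIX_PHI, HELIX_PSI, 180,
                          ncac = helix_ncac, id = "ideal_helix")
  sheet <- make_antiparallel_sheet(n_strand, ncac = strand_ncac)
  dipep <- build_backbone(2, phi = -120, psi = 130, omega = 180,
                          id = "trans_dipeptide")
  dipep_off <- build_backbone(2, phi = -120, psi = 130,
                              omega = 180 + delta_omega,
                              theta_c = theta_c_offset,
                              id = "offset_dipeptide")
  strand <- build_backbone(n_strand, STRAND_PHI, STRAND_PSI, 180,
                           ncac = strand_ncac, id = "isolated_strand")
  list(helix = helix, sheet = sheet, dipeptide = dipep,
       dipeptide_offset = dipep_off, strand = strand)
}

#' Ideal two-stranded antiparallel beta sheet
#'
#' Builds one extended strand, duplicates it as chain B rotated 180 degrees
#' about the strand axis, and refines the rigid placement of B so that the
#' cross-strand backbone N...O ladder reaches hydrogen-bonding distance.
#' Deterministic (fixed optimizer start).
#'
#' @param n residues per strand.
#' @param ncac N-CA-C angle used for both strands.
#' @return a two-chain [protein_structure].
#' @export
make_antiparallel_sheet <- function(n = 8, ncac = 108.9) {
  A <- build_backbone(n, STRAND_PHI, STRAND_PSI, 180, ncac = ncac,
                      chain = "A", id = "sheet")
  axyz <- atom_xyz(A)
  ca <- select_atoms(A, NULL, "CA")$xyz
  dirv <- unitv(ca[n, ] - ca[1, ])        # strand direction
  ctr <- colMeans(ca)
  perp <- unitv(cross3(dirv, c(0, 0, 1))) # in the pleat plane
  zax <- unitv(cross3(dirv, perp))        # sheet normal
  selN_A <- select_atoms(A, NULL, "N")$xyz
  selO_A <- select_atoms(A, NULL, "O")$xyz
  place_b <- function(p, flip_axis) {
    R0 <- rotation_matrix(flip_axis, 180)   # reverses the strand direction
    Rp <- rotation_matrix(c(0, 0, 1), p[4]) %*%
          rotation_matrix(c(0, 1, 0), p[5]) %*%
          rotation_matrix(c(1, 0, 0), p[6])
    xyz <- sweep(axyz, 2, ctr) %*% t(R0) %*% t(Rp)
    xyz <- sweep(xyz, 2, ctr + p[1:3], "+")
    B <- set_atom_xyz(A, xyz)
    B$atoms$chain <- "B"
    B
  }
  obj <- function(p, flip_axis) {
    B <- place_b(p, flip_axis)
    selN_B <- select_atoms(B, NULL, "N")$xyz
    selO_B <- select_atoms(B, NULL, "O")$xyz
    d <- 0
    for (i in seq(2, n - 1, by = 2)) {   # narrow-pair registry i <-> n+1-i
      j <- n + 1 - i
      d <- d + (vnorm(selN_A[i, ] - selO_B[j, ]) - 2.9)^2
      d <- d + (vnorm(selO_A[i, ] - selN_B[j, ]) - 2.9)^2
    }
    caB <- select_atoms(B, NULL, "CA")$xyz
    d2 <- outer(rowSums(ca^2), rowSums(caB^2), "+") - 2 * ca %*% t(caB)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin < 4.2) d <- d + 100 * (4.2 - dmin)^2
    d
  }
  best <- NULL
  for (flip_axis in list(zax, perp)) {
    for (sgn in c(-1, 1)) {
      for (shift in c(0, 1.7, -1.7)) {
        start <- c(sgn * 4.9 * perp + shift * dirv, 0, 0, 0)
        fit <- stats::optim(start, obj, flip_axis = flip_axis,
                            method = "Nelder-Mead",
                            control = list(maxit = 5000, reltol = 1e-14))
        fit <- stats::optim(fit$par, obj, flip_axis = flip_axis,
                            method = "Nelder-Mead",
                            control = list(maxit = 5000, reltol = 1e-14))
        if (is.null(best) || fit$value < best$value)
          best <- list(value = fit$value, par = fit$par, axis = flip_axis)
      }
    }
  }
  B <- place_b(best$par, best$axis)
  out <- protein_structure(rbind(A$atoms, B$atoms), id = "ideal_sheet")
  attr(out, "placement_objective") <- best$value
  out
}

#' Two-lobe (bilobed) poly-Ala monomer with a swapping tail
#'
#' Emulates the architecture of a bilobed substrate-binding protein monomer:
#' two compact helical-hairpin lobes joined by an extended linker, followed
#' by a short extended hinge and a C-terminal helical tail (the segment that
#' is exchanged in the swapped dimer).  Pure function of `spec` (the seed
#' controls a small deterministic coordinate jitter that breaks exact
#' internal symmetries).
#'
#' @param spec list with `n_res_per_lobe`, `linker_length`,
#'   `helix_tail_length`, `seed` (all counts >= 1).
#' @param jitter_sd per-coordinate Gaussian jitter in Angstrom (default 0.05).
#' @return list with `structure` (a [protein_structure]), `domains` (named
#'   list of [domain_def]: lobe1, lobe2, linker, hinge, tail) and
#'   `annotation` (a [swap_annotation] for the dimer builder).
#' @export
make_two_lobe_monomer <- function(spec, jitter_sd = 0.05) {
  stopifnot(all(c("n_res_per_lobe", "linker_length", "helix_tail_length",
                  "seed") %in% names(spec)))
  nl <- spec$n_res_per_lobe; ll <- spec$linker_length
  tl <- spec$helix_tail_length
  stopifnot(nl >= 1, ll >= 1, tl >= 1)
  n_hinge <- max(1L, min(3L, tl - 1L))
  n_tailhelix <- tl - n_hinge
  lobe_tors <- function(n) {
    # helical hairpin: two helical halves joined by a short non-helical turn
    half <- (n - 3) %/% 2
    turn <- n - 2 * half
    list(phi = c(rep(HELIX_PHI, half), rep(-95, turn), rep(HELIX_PHI, n - half - turn)),
         psi = c(rep(HELIX_PSI, half), rep(60, turn), rep(HELIX_PSI, n - half - turn)))
  }
  l1 <- lobe_tors(nl); l2 <- lobe_tors(nl)
  phi <- c(l1$phi, rep(STRAND_PHI, ll), l2$phi,
           rep(STRAND_PHI, n_hinge), rep(HELIX_PHI, n_tailhelix))
  psi <- c(l1$psi, rep(STRAND_PSI, ll), l2$psi,
           rep(STRAND_PSI, n_hinge), rep(HELIX_PSI, n_tailhelix))
  n <- length(phi)
  s <- build_backbone(n, phi, psi, 180, ncac = 111.0, chain = "A",
                      id = sprintf("two_lobe_monomer_seed%d", spec$seed))
  if (jitter_sd > 0) {
    xyz <- atom_xyz(s)
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(length(xyz), 0, jitter_sd),
                              ncol = 3))
    s <- set_atom_xyz(s, xyz + noise)
  }
  b1 <- nl; b2 <- nl + ll; b3 <- 2 * nl + ll
  b4 <- b3 + n_hinge
  rng <- function(a, b) data.frame(chain = "A", start = a, end = b)
  domains <- list(
    lobe1 = domain_def("lobe I", rng(1, b1)),
    linker = domain_def("linker", rng(b1 + 1, b2)),
    lobe2 = domain_def("lobe II", rng(b2 + 1, b3)),
    hinge = domain_def("hinge", rng(b3 + 1, b4)),
    tail = domain_def("swapped tail", rng(b4 + 1, n)))
  annotation <- swap_annotation(swapped = c(b4 + 1, n),
                                hinge = c(b3 + 1, b4),
                                main_body = c(1, b3))
  list(structure = s, domains = domains, annotation = annotation)
}

#' Rigidly rotate one domain of a structure
#'
#' @param s a [protein_structure].
#' @param domain [domain_def] or range string selecting the atoms to move.
#' @param axis rotation axis (3-vector, normalized internally).
#' @param angle_deg rotation angle in degrees (right-handed about `axis`).
#' @param pivot point on the axis (default: centroid of the domain atoms).
#' @return the structure with only the domain atoms moved.
#' @export
apply_domain_rotation <- function(s, domain, axis, angle_deg, pivot = NULL) {
  if (vnorm(axis) < 1e-12) stop("zero-length rotation axis")
  if (is.character(domain)) domain <- domain_def("moving", domain)
  mask <- domain_mask(s, domain)
  if (!any(mask)) stop("domain selects no atoms")
  xyz <- atom_xyz(s)
  if (is.null(pivot)) pivot <- colMeans(xyz[mask, , drop = FALSE])
  R <- rotation_matrix(axis, angle_deg)
  moved <- sweep(sweep(xyz[mask, , drop = FALSE], 2, pivot) %*% t(R),
                 2, pivot, "+")
  xyz[mask, ] <- moved
  set_atom_xyz(s, xyz)
}

#' Build a two-fold symmetric C-terminal-swapped dimer
#'
#' Duplicates a monomer and places the copy by an exact 180-degree rotation
#' about a two-fold axis, positioned so that each chain's tail (the swapped
#' segment of `annotation`) packs against the main body of the other chain
#' while the two main bodies stay apart.  The axis offset is found by a
#' deterministic scan: the smallest offset at which the closest tail/body
#' approach is at least `separation` and the body/body gap exceeds
#' `body_gap_min`.
#'
#' @param monomer a [protein_structure] (single chain) or the list returned
#'   by [make_two_lobe_monomer].
#' @param annotation a [swap_annotation]; taken from the monomer list if
#'   omitted.
#' @param separation target closest heavy-atom approach between a tail and
#'   the opposite main body, Angstrom (default 3.8).
#' @param body_gap_min minimum allowed body/body (and tail/tail) heavy-atom
#'   distance (default 6).
#' @param hinge_clear minimum allowed distance between hinge (or any residue
#'   outside the annotated segments) and the partner chain (default 5.0), so
#'   every inter-chain contact at census cutoffs is tail-to-body.
#' @return a two-chain [protein_structure] (chains A and B).
#' @export
make_swapped_dimer <- function(monomer, annotation = NULL, separation = 3.8,
                               body_gap_min = 6, hinge_clear = 5.0) {
  if (is.list(monomer) && !inherits(monomer, "protein_structure")) {
    if (is.null(annotation)) annotation <- monomer$annotation
    monomer <- monomer$structure
  }
  if (is.null(annotation)) stop("swap annotation required")
  stopifnot(inherits(monomer, "protein_structure"))
  a <- monomer$atoms
  tail_mask <- a$resno >= annotation$swapped[1] & a$resno <= annotation$swapped[2]
  body_mask <- a$resno >= annotation$main_body[1] & a$resno <= annotation$main_body[2]
  if (length(unique(a$resno[tail_mask])) < 3)
    stop("tail too short to span the two-fold axis")
  xyz <- atom_xyz(monomer)
  cb <- colMeans(xyz[body_mask, , drop = FALSE])
  ct <- colMeans(xyz[tail_mask, , drop = FALSE])
  L <- vnorm(ct - cb)
  if (L < 6) stop("tail too short to span: tail centroid inside the body")
  # canonical frame: body centroid at origin, tail centroid on +x
  xyz0 <- sweep(xyz, 2, cb)
  u <- unitv(ct - cb)
  # rotation taking u -> +x
  v <- cross3(u, c(1, 0, 0)); sv <- vnorm(v)
  if (sv < 1e-9) Ru <- diag(3) else
    Ru <- rotation_matrix(v, rad2deg(atan2(sv, sum(u * c(1, 0, 0)))))
  xyz0 <- xyz0 %*% t(Ru)
  A <- set_atom_xyz(monomer, xyz0)
  A$atoms$chain <- "A"
  two_fold <- function(xy, a_off) {
    out <- xy
    out[, 1] <- 2 * a_off - xy[, 1]
    out[, 2] <- -xy[, 2]
    out
  }
  min_cross <- function(P, Q) {
    if (nrow(P) == 0 || nrow(Q) == 0) return(Inf)
    d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
    sqrt(max(0, min(d2)))
  }
  # deterministic search: orientation about the body->tail axis (gamma), then
  # smallest two-fold offset with a tail/body contact at ~separation and all
  # other cross-chain classes clear of the census cutoffs
  a_grid <- seq(L / 2, L / 2 + 30, by = 0.25)
  chosen <- NULL
  for (relax in c(0, 1)) {
  if (relax) {
    # second pass: just above the census cutoffs still keeps contacts pure
    hinge_clear <- max(4.6, hinge_clear - 0.4)
    body_gap_min <- max(4.8, body_gap_min - 1.2)
  }
  for (gam in seq(0, 350, by = 10)) {
    xg <- xyz0 %*% t(rotation_matrix(c(1, 0, 0), gam))
    tailA <- xg[tail_mask, , drop = FALSE]
    bodyA <- xg[body_mask, , drop = FALSE]
    otherA <- xg[!tail_mask & !body_mask, , drop = FALSE]  # hinge + leftovers
    for (a_off in a_grid) {
      allB <- two_fold(xg, a_off)
      tb <- min(min_cross(tailA, allB[body_mask, , drop = FALSE]),
                min_cross(allB[tail_mask, , drop = FALSE], bodyA))
      if (tb < separation - 0.3 || tb > separation + 0.6) next
      bb <- min_cross(bodyA, allB[body_mask, , drop = FALSE])
      tt <- min_cross(tailA, allB[tail_mask, , drop = FALSE])
      hc <- min(min_cross(otherA, allB),
                min_cross(allB[!tail_mask & !body_mask, , drop = FALSE], xg))
      if (bb >= body_gap_min && tt >= body_gap_min && hc >= hinge_clear) {
        chosen <- list(gamma = gam, a_off = a_off, xg = xg)
        break
      }
    }
    if (!is.null(chosen)) break
  }
  if (!is.null(chosen)) break
  }
  if (is.null(chosen))
    stop("could not place two-fold axis without clashes")
  A <- set_atom_xyz(A, chosen$xg)
  B <- A
  B$atoms$chain <- "B"
  B <- set_atom_xyz(B, two_fold(chosen$xg, chosen$a_off))
  out <- protein_structure(rbind(A$atoms, B$atoms),
                           id = paste0(monomer$id, "_swapped_dimer"))
  attr(out, "two_fold_offset") <- chosen$a_off
  attr(out, "orientation_gamma") <- chosen$gamma
  out
}

#' Add isotropic Gaussian coordinate noise
#'
#' @param s a [protein_structure].
#' @param sigma per-coordinate standard deviation, Angstrom (>= 0).
#' @param seed integer seed; the perturbation is deterministic per seed.
#' @return perturbed structure.
#' @export
perturb_structure <- function(s, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(s)
  xyz <- atom_xyz(s)
  noise <- with_seed(seed, matrix(stats::rnorm(length(xyz), 0, sigma), ncol = 3))
  set_atom_xyz(s, xyz + noise)
}
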