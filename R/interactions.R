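# Census of residue-residue interactions (salt bridges, hydrogen bonds,
# hydrophobic contacts) and their classification into the closed (C-) and
# open (O-) interfaces of a 3D domain-swapped dimer, following Eisenberg's
# nomenclature: the C-interface is formed by the swapped segment of one
# chain with the main body of the other; everything else that crosses the
# chain boundary (body-body, hinge-mediated) belongs to the O-interface.

BASIC_N <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                HIS = c("ND1", "NE2"))
ACID_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# donor heavy atoms -> antecedent atom used for the angle check
HBOND_DONORS <- list(
  "*:N"      = "CA",
  "ARG:NE"   = "CZ", "ARG:NH1" = "CZ", "ARG:NH2" = "CZ",
  "LYS:NZ"   = "CE",
  "HIS:ND1"  = "CE1", "HIS:NE2" = "CE1",
  "SER:OG"   = "CB", "THR:OG1" = "CB", "TYR:OH" = "CZ",
  "ASN:ND2"  = "CG", "GLN:NE2" = "CD", "TRP:NE1" = "CD1")

HBOND_ACCEPTORS <- list(
  "*:O" = TRUE, "*:OXT" = TRUE,
  "ASP:OD1" = TRUE, "ASP:OD2" = TRUE, "GLU:OE1" = TRUE, "GLU:OE2" = TRUE,
  "ASN:OD1" = TRUE, "GLN:OE1" = TRUE,
  "SER:OG" = TRUE, "THR:OG1" = TRUE, "TYR:OH" = TRUE,
  "HIS:ND1" = TRUE, "HIS:NE2" = TRUE)

APOLAR_RESIDS <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO",
                   "TYR")

empty_contacts <- function() {
  data.frame(kind = character(), chain1 = character(), resno1 = integer(),
             resid1 = character(), atom1 = character(), chain2 = character(),
             resno2 = integer(), resid2 = character(), atom2 = character(),
             distance = numeric(), flag = character(),
             stringsAsFactors = FALSE)
}

atom_subset <- function(a, spec_list) {
  key <- paste(a$resid, trimws(a$elety), sep = ":")
  wild <- paste("*", trimws(a$elety), sep = ":")
  a[key %in% names(spec_list) | wild %in% names(spec_list), , drop = FALSE]
}

scope_ok <- function(c1, c2, scope) {
  switch(scope,
         intra = c1 == c2,
         inter = c1 != c2,
         all = TRUE,
         stop("scope must be 'intra', 'inter' or 'all'"))
}

# pairwise census core: candidate atom tables d (donor-like) and acc
# (acceptor-like); returns min-distance contact per residue pair
pair_census <- function(d, acc, cutoff, scope, kind,
                        exclude_adjacent = FALSE) {
  if (nrow(d) == 0 || nrow(acc) == 0) return(empty_contacts())
  P <- as.matrix(d[, c("x", "y", "z")])
  Q <- as.matrix(acc[, c("x", "y", "z")])
  D2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  D2[D2 < 0] <- 0
  hits <- which(D2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_contacts())
  out <- data.frame(
    kind = kind,
    chain1 = d$chain[hits[, 1]], resno1 = d$resno[hits[, 1]],
    resid1 = d$resid[hits[, 1]], atom1 = trimws(d$elety[hits[, 1]]),
    chain2 = acc$chain[hits[, 2]], resno2 = acc$resno[hits[, 2]],
    resid2 = acc$resid[hits[, 2]], atom2 = trimws(acc$elety[hits[, 2]]),
    distance = sqrt(D2[hits]), flag = "", stringsAsFactors = FALSE)
  same_res <- out$chain1 == out$chain2 & out$resno1 == out$resno2
  out <- out[!same_res, , drop = FALSE]
  if (exclude_adjacent && nrow(out)) {
    adj <- out$chain1 == out$chain2 & abs(out$resno1 - out$resno2) <= 1
    out <- out[!adj, , drop = FALSE]
  }
  if (nrow(out) == 0) return(empty_contacts())
  out <- out[scope_ok(out$chain1, out$chain2, scope), , drop = FALSE]
  if (nrow(out) == 0) return(empty_contacts())
  canonicalize_contacts(out)
}

# store each residue pair once (canonical order), keep the closest atom pair
canonicalize_contacts <- function(out) {
  swap <- paste(out$chain1, sprintf("%06d", out$resno1)) >
          paste(out$chain2, sprintf("%06d", out$resno2))
  if (any(swap)) {
    tmp <- out[swap, c("chain2", "resno2", "resid2", "atom2")]
    out[swap, c("chain2", "resno2", "resid2", "atom2")] <-
      out[swap, c("chain1", "resno1", "resid1", "atom1")]
    out[swap, c("chain1", "resno1", "resid1", "atom1")] <- tmp
  }
  key <- paste(out$kind, out$chain1, out$resno1, out$chain2, out$resno2)
  out <- out[order(key, out$distance), , drop = FALSE]
  out <- out[!duplicated(paste(out$kind, out$chain1, out$resno1,
                               out$chain2, out$resno2)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Salt-bridge census
#'
#' Pairs in which a basic side-chain nitrogen (Arg NE/NH1/NH2, Lys NZ, His
#' ND1/NE2) lies within `cutoff` of an acidic side-chain oxygen (Asp
#' OD1/OD2, Glu OE1/OE2).  One contact per residue pair (minimum distance
#' kept).  His partners are flagged "his_protonation_unknown".
#'
#' @param s a [protein_structure].
#' @param cutoff N...O distance cutoff, Angstrom (default 4.0).
#' @param scope "intra", "inter" (between chains) or "all".
#' @param include_het include hetero residues (default FALSE).
#' @return contact data.frame (kind, chain/resno/resid/atom for both
#'   partners, distance, flag).
#' @export
salt_bridges <- function(s, cutoff = 4.0, scope = "all",
                         include_het = FALSE) {
  a <- census_atoms(s, include_het)
  bn <- atom_subset(a, stats::setNames(as.list(unlist(BASIC_N)),
    unlist(mapply(function(r, at) paste(r, at, sep = ":"),
                  rep(names(BASIC_N), lengths(BASIC_N)), unlist(BASIC_N)))))
  ao <- atom_subset(a, stats::setNames(as.list(unlist(ACID_O)),
    unlist(mapply(function(r, at) paste(r, at, sep = ":"),
                  rep(names(ACID_O), lengths(ACID_O)), unlist(ACID_O)))))
  out <- pair_census(bn, ao, cutoff, scope, "salt_bridge")
  if (nrow(out))
    out$flag[out$resid1 == "HIS" | out$resid2 == "HIS"] <-
      "his_protonation_unknown"
  out
}

census_atoms <- function(s, include_het = FALSE) {
  a <- s$atoms[!(s$atoms$resid %in% WATER_RESIDS), , drop = FALSE]
  if (!include_het) a <- a[!a$het, , drop = FALSE]
  a
}

#' Hydrogen-bond census (heavy-atom criteria)
#'
#' Donor-acceptor pairs of N/O heavy atoms with distance <= `d_max` and
#' antecedent-donor-acceptor angle >= `angle_min` where the donor's
#' antecedent heavy atom is present; pairs whose angle cannot be computed
#' are kept on distance alone and flagged "angle_unavailable".  Covalently
#' adjacent backbone pairs (same chain, |residue difference| <= 1) are
#' excluded.
#'
#' @param s a [protein_structure].
#' @param d_max donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_min minimum antecedent-donor-acceptor angle, degrees
#'   (default 120).
#' @param scope "intra", "inter" or "all".
#' @param include_het include hetero residues.
#' @return contact data.frame as in [salt_bridges].
#' @export
hydrogen_bonds <- function(s, d_max = 3.5, angle_min = 120, scope = "all",
                           include_het = FALSE) {
  a <- census_atoms(s, include_het)
  don <- atom_subset(a, HBOND_DONORS)
  acc <- atom_subset(a, HBOND_ACCEPTORS)
  raw <- pair_census_directional(don, acc, d_max, scope)
  if (nrow(raw) == 0) return(empty_contacts())
  # angle filter on the *directional* contacts, then canonicalize
  keep <- logical(nrow(raw))
  flag <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    dr <- raw[i, ]
    key <- paste(dr$resid1, dr$atom1, sep = ":")
    ante_name <- HBOND_DONORS[[key]]
    if (is.null(ante_name)) ante_name <- HBOND_DONORS[[paste0("*:", dr$atom1)]]
    ante <- a[a$chain == dr$chain1 & a$resno == dr$resno1 &
                trimws(a$elety) == ante_name, , drop = FALSE]
    if (nrow(ante) == 0) {
      keep[i] <- TRUE; flag[i] <- "angle_unavailable"
    } else {
      dpos <- a[a$chain == dr$chain1 & a$resno == dr$resno1 &
                  trimws(a$elety) == dr$atom1, c("x", "y", "z")]
      apos <- a[a$chain == dr$chain2 & a$resno == dr$resno2 &
                  trimws(a$elety) == dr$atom2, c("x", "y", "z")]
      ang <- bond_angle(as.numeric(ante[1, c("x", "y", "z")]),
                        as.numeric(dpos[1, ]), as.numeric(apos[1, ]))
      keep[i] <- ang >= angle_min
    }
  }
  out <- raw[keep, , drop = FALSE]
  if (nrow(out) == 0) return(empty_contacts())
  out$flag <- flag[keep]
  out$kind <- "hbond"
  canonicalize_contacts(out)
}

# directional census (donor kept as partner 1) without canonical swap
pair_census_directional <- function(d, acc, cutoff, scope) {
  if (nrow(d) == 0 || nrow(acc) == 0) return(empty_contacts())
  P <- as.matrix(d[, c("x", "y", "z")])
  Q <- as.matrix(acc[, c("x", "y", "z")])
  D2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  D2[D2 < 0] <- 0
  hits <- which(D2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_contacts())
  out <- data.frame(
    kind = "hbond",
    chain1 = d$chain[hits[, 1]], resno1 = d$resno[hits[, 1]],
    resid1 = d$resid[hits[, 1]], atom1 = trimws(d$elety[hits[, 1]]),
    chain2 = acc$chain[hits[, 2]], resno2 = acc$resno[hits[, 2]],
    resid2 = acc$resid[hits[, 2]], atom2 = trimws(acc$elety[hits[, 2]]),
    distance = sqrt(D2[hits]), flag = "", stringsAsFactors = FALSE)
  same_res <- out$chain1 == out$chain2 & out$resno1 == out$resno2
  adj <- out$chain1 == out$chain2 & abs(out$resno1 - out$resno2) <= 1
  out <- out[!(same_res | adj), , drop = FALSE]
  out <- out[scope_ok(out$chain1, out$chain2, scope), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hydrophobic-contact census
#'
#' Residue pairs of apolar residues (Ala, Val, Leu, Ile, Met, Phe, Trp, Pro,
#' Tyr) with any side-chain carbon-carbon distance <= `cutoff`; one contact
#' per pair (minimum distance).
#'
#' @param s a [protein_structure].
#' @param cutoff C...C cutoff, Angstrom (default 4.5).
#' @param scope "intra", "inter" or "all".
#' @param include_het include hetero residues.
#' @return contact data.frame as in [salt_bridges].
#' @export
hydrophobic_contacts <- function(s, cutoff = 4.5, scope = "all",
                                 include_het = FALSE) {
  a <- census_atoms(s, include_het)
  sc <- a[a$resid %in% APOLAR_RESIDS & a$elesy == "C" &
            !(trimws(a$elety) %in% c("C", "CA")), , drop = FALSE]
  pair_census(sc, sc, cutoff, scope, "hydrophobic")
}

#' Annotation of a swapped dimer's segments
#'
#' Residue ranges (author numbering, applied to both chains) of the swapped
#' segment, the hinge connecting it to the main body, and the main body
#' itself.  Defaults follow the TmArgBP layout: swapped C-terminal helix
#' 237-246, hinge 232-236 (KKSPY), main body 20-233.
#'
#' @param swapped,hinge,main_body length-2 integer vectors (start, end).
#' @return object of class `swap_annotation`.
#' @export
swap_annotation <- function(swapped = c(237L, 246L), hinge = c(232L, 236L),
                            main_body = c(20L, 233L)) {
  stopifnot(length(swapped) == 2, length(hinge) == 2, length(main_body) == 2,
            swapped[1] <= swapped[2], hinge[1] <= hinge[2],
            main_body[1] <= main_body[2])
  structure(list(swapped = as.integer(swapped), hinge = as.integer(hinge),
                 main_body = as.integer(main_body)),
            class = "swap_annotation")
}

swap_region <- function(resno, ann) {
  ifelse(resno >= ann$swapped[1] & resno <= ann$swapped[2], "swapped",
  ifelse(resno >= ann$hinge[1] & resno <= ann$hinge[2], "hinge",
  ifelse(resno >= ann$main_body[1] & resno <= ann$main_body[2], "body",
         "other")))
}

#' Classify inter-chain contacts of a swapped dimer
#'
#' Each inter-chain contact is assigned to exactly one interface:
#' C-interface iff one partner lies in the swapped segment and the other in
#' the main body of the opposite chain; all remaining inter-chain contacts
#' (body-body, hinge-body, hinge-hinge, swapped-hinge, swapped-swapped) go
#' to the O-interface.  Intra-chain contacts are excluded.
#'
#' @param dimer a two-protein-chain [protein_structure].
#' @param annotation a [swap_annotation].
#' @param contacts contact data.frame (e.g. rbind of the three censuses run
#'   with `scope = "inter"`); computed with default cutoffs if omitted.
#' @return list of class `swap_interface_report` with `c_interface`,
#'   `o_interface` (contact data.frames), `counts` (table by kind and
#'   interface) and `per_chain_c_counts`.
#' @export
classify_swap_interfaces <- function(dimer, annotation, contacts = NULL) {
  ch <- chain_ids(protein_structure(census_atoms(dimer), id = dimer$id))
  if (length(ch) == 1) {
    # isolated monomer: no inter-chain contacts by definition
    return(structure(list(c_interface = empty_contacts(),
                          o_interface = empty_contacts(),
                          counts = table(factor(character(),
                                                c("salt_bridge", "hbond",
                                                  "hydrophobic"))),
                          per_chain_c_counts = stats::setNames(0, ch)),
                     class = "swap_interface_report"))
  }
  if (length(ch) != 2)
    stop("swapped-dimer classification requires exactly 2 protein chains, got ",
         length(ch))
  if (is.null(contacts)) {
    contacts <- rbind(salt_bridges(dimer, scope = "inter"),
                      hydrogen_bonds(dimer, scope = "inter"),
                      hydrophobic_contacts(dimer, scope = "inter"))
  }
  inter <- contacts[contacts$chain1 != contacts$chain2, , drop = FALSE]
  if (nrow(inter) == 0) {
    return(structure(list(c_interface = empty_contacts(),
                          o_interface = empty_contacts(),
                          counts = table(factor(character(),
                                                c("salt_bridge", "hbond",
                                                  "hydrophobic"))),
                          per_chain_c_counts = stats::setNames(c(0, 0), ch)),
                     class = "swap_interface_report"))
  }
  r1 <- swap_region(inter$resno1, annotation)
  r2 <- swap_region(inter$resno2, annotation)
  is_c <- (r1 == "swapped" & r2 == "body") | (r1 == "body" & r2 == "swapped")
  cint <- inter[is_c, , drop = FALSE]
  oint <- inter[!is_c, , drop = FALSE]
  # which chain donated the swapped segment of each C-interface contact
  swapped_chain <- ifelse(swap_region(cint$resno1, annotation) == "swapped",
                          cint$chain1, cint$chain2)
  per_chain <- stats::setNames(
    c(sum(swapped_chain == ch[1]), sum(swapped_chain == ch[2])), ch)
  counts <- table(factor(c(cint$kind, oint$kind),
                         c("salt_bridge", "hbond", "hydrophobic")),
                  rep(c("C", "O"), c(nrow(cint), nrow(oint))))
  structure(list(c_interface = cint, o_interface = oint, counts = counts,
                 per_chain_c_counts = per_chain),
            class = "swap_interface_report")
}

#' @export
print.swap_interface_report <- function(x, ...) {
  cat(sprintf("swap interfaces: %d C-interface, %d O-interface contacts\n",
              nrow(x$c_interface), nrow(x$o_interface)))
  print(x$counts)
  invisible(x)
}

#' Contacts anchoring a bound ligand
#'
#' Salt bridges, hydrogen bonds and hydrophobic contacts between a ligand
#' residue and the protein, with the same criteria as the global censuses,
#' plus the ligand's solvent-accessible area in the complex (a solvent
#' inaccessibility check).  For an amino-acid ligand the alpha-amino/
#' guanidinium nitrogens act as basic/donor atoms and the carboxylate
#' oxygens as acidic/acceptor atoms.
#'
#' @param s a [protein_structure] containing the ligand.
#' @param ligand_resid residue name of the ligand (e.g. "ARG").
#' @param ligand_resno residue number; if NULL the first hetero residue with
#'   `ligand_resid` is used.
#' @param chain ligand chain (optional).
#' @param sb_cutoff,hb_dmax,hb_angle_min,phob_cutoff census criteria.
#' @param probe,n_points SASA parameters for the inaccessibility check.
#' @return list with `contacts` (data.frame), `ligand_sasa` (Angstrom^2 in
#'   the complex) and `ligand_sasa_free` (ligand alone).
#' @export
ligand_pocket_contacts <- function(s, ligand_resid = "ARG",
                                   ligand_resno = NULL, chain = NULL,
                                   sb_cutoff = 4.0, hb_dmax = 3.5,
                                   hb_angle_min = 120, phob_cutoff = 4.5,
                                   probe = 1.4, n_points = 960) {
  a <- s$atoms[!(s$atoms$resid %in% WATER_RESIDS), , drop = FALSE]
  lig <- a[a$het & a$resid == ligand_resid, , drop = FALSE]
  if (!is.null(ligand_resno)) lig <- lig[lig$resno == ligand_resno, , drop = FALSE]
  if (!is.null(chain)) lig <- lig[lig$chain == chain, , drop = FALSE]
  if (nrow(lig) == 0) stop("ligand ", ligand_resid, " not found")
  lig <- lig[lig$resno == lig$resno[1] & lig$chain == lig$chain[1], , drop = FALSE]
  prot <- a[!a$het, , drop = FALSE]
  if (nrow(prot) == 0) {
    contacts <- empty_contacts()
  } else {
    lig_n <- lig[lig$elesy == "N", , drop = FALSE]
    lig_o <- lig[lig$elesy == "O", , drop = FALSE]
    lig_c <- lig[lig$elesy == "C" & !(trimws(lig$elety) %in% c("C", "CA")), ,
                 drop = FALSE]
    prot_acid <- atom_subset(prot, stats::setNames(as.list(unlist(ACID_O)),
      unlist(mapply(function(r, at) paste(r, at, sep = ":"),
                    rep(names(ACID_O), lengths(ACID_O)), unlist(ACID_O)))))
    prot_basic <- atom_subset(prot, stats::setNames(as.list(unlist(BASIC_N)),
      unlist(mapply(function(r, at) paste(r, at, sep = ":"),
                    rep(names(BASIC_N), lengths(BASIC_N)), unlist(BASIC_N)))))
    sb <- rbind(pair_census(lig_n, prot_acid, sb_cutoff, "all", "salt_bridge"),
                pair_census(lig_o, prot_basic, sb_cutoff, "all", "salt_bridge"))
    prot_don <- atom_subset(prot, HBOND_DONORS)
    prot_acc <- atom_subset(prot, HBOND_ACCEPTORS)
    hb <- rbind(pair_census(lig_n, prot_acc, hb_dmax, "all", "hbond"),
                pair_census(lig_o, prot_don, hb_dmax, "all", "hbond"))
    if (nrow(hb)) hb$flag <- "angle_unavailable"
    prot_c <- prot[prot$resid %in% APOLAR_RESIDS & prot$elesy == "C" &
                     !(trimws(prot$elety) %in% c("C", "CA")), , drop = FALSE]
    ph <- pair_census(lig_c, prot_c, phob_cutoff, "all", "hydrophobic")
    contacts <- rbind(sb, hb, ph)
    # drop hbonds duplicating a salt bridge on the same atom pair
    if (nrow(contacts)) {
      key <- paste(contacts$chain1, contacts$resno1, contacts$atom1,
                   contacts$chain2, contacts$resno2, contacts$atom2)
      dup <- duplicated(key) & contacts$kind == "hbond"
      contacts <- contacts[!dup, , drop = FALSE]
    }
  }
  lig_struct <- protein_structure(lig, id = "ligand")
  lig_key <- paste(lig$chain, lig$resno)
  complex_sasa <- sasa(protein_structure(rbind(prot, lig), id = "complex"),
                       probe = probe, n_points = n_points,
                       include_het = TRUE)
  in_complex <- paste(complex_sasa$atoms$chain, complex_sasa$atoms$resno) %in%
    lig_key & complex_sasa$atoms$het
  list(contacts = contacts,
       ligand_sasa = sum(complex_sasa$per_atom[in_complex]),
       ligand_sasa_free = sasa(lig_struct, probe = probe,
                               n_points = n_points,
                               include_het = TRUE)$total)
}
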