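# Backbone stereochemistry: phi/psi/omega dihedrals, the N-CA-C bond angle,
# peptide planarity (delta-omega = omega - 180), carbonyl pyramidalization
# (theta_c, an improper-torsion deviation from planarity at the carbonyl
# carbon), a lightweight hydrogen-bond-pattern secondary-structure
# assignment, and psi-window statistics of these quantities.

#' Per-residue backbone geometry
#'
#' For residue i (chain breaks, CA-CA > 4.5 A, split the chain logically):
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1);
#' omega(i) = CA(i)-C(i)-N(i+1)-CA(i+1), assigned to the peptide following
#' residue i; `delta_omega = wrap(omega - 180)`; `ncac` is the N-CA-C bond
#' angle; `theta_c = wrap(tau(O(i), C(i), N(i+1), CA(i)) - 180)` (improper
#' torsion convention; flip the sign with `theta_c_sign = -1` if your
#' comparison tool uses the opposite handedness).  Values that need a
#' missing neighbour or atom are NA.
#'
#' @param s a [protein_structure].
#' @param theta_c_sign +1 (default) or -1; sign convention for theta_c.
#' @param break_cutoff CA-CA distance (Angstrom) above which consecutive
#'   residues are treated as a chain break (default 4.5).
#' @return data.frame with one row per protein residue: chain, resno, resid,
#'   phi, psi, omega, delta_omega, ncac, theta_c, ss.
#' @export
backbone_geometry <- function(s, theta_c_sign = 1, break_cutoff = 4.5) {
  a <- census_atoms(s, include_het = FALSE)
  out <- list()
  for (ch in unique(a$chain)) {
    ac <- a[a$chain == ch, , drop = FALSE]
    res <- unique(ac[, c("resno", "insert", "resid")])
    res <- res[order(res$resno, res$insert), , drop = FALSE]
    n <- nrow(res)
    get_atom <- function(i, name) {
      hit <- ac[ac$resno == res$resno[i] & ac$insert == res$insert[i] &
                  trimws(ac$elety) == name, c("x", "y", "z")]
      if (nrow(hit) == 0) return(NULL)
      as.numeric(hit[1, ])
    }
    N <- lapply(seq_len(n), get_atom, "N")
    CA <- lapply(seq_len(n), get_atom, "CA")
    C <- lapply(seq_len(n), get_atom, "C")
    O <- lapply(seq_len(n), get_atom, "O")
    linked <- rep(FALSE, n)   # residue i linked to i+1
    if (n > 1) for (i in seq_len(n - 1)) {
      linked[i] <- !is.null(CA[[i]]) && !is.null(CA[[i + 1]]) &&
        vnorm(CA[[i + 1]] - CA[[i]]) <= break_cutoff
    }
    g <- data.frame(chain = ch, resno = res$resno, resid = res$resid,
                    phi = NA_real_, psi = NA_real_, omega = NA_real_,
                    delta_omega = NA_real_, ncac = NA_real_,
                    theta_c = NA_real_, ss = "C", stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      if (!is.null(N[[i]]) && !is.null(CA[[i]]) && !is.null(C[[i]]))
        g$ncac[i] <- bond_angle(N[[i]], CA[[i]], C[[i]])
      if (i > 1 && linked[i - 1] && !is.null(C[[i - 1]]) && !is.null(N[[i]]) &&
          !is.null(CA[[i]]) && !is.null(C[[i]]))
        g$phi[i] <- torsion_angle(C[[i - 1]], N[[i]], CA[[i]], C[[i]])
      if (i < n && linked[i]) {
        if (!is.null(N[[i]]) && !is.null(CA[[i]]) && !is.null(C[[i]]) &&
            !is.null(N[[i + 1]]))
          g$psi[i] <- torsion_angle(N[[i]], CA[[i]], C[[i]], N[[i + 1]])
        if (!is.null(CA[[i]]) && !is.null(C[[i]]) && !is.null(N[[i + 1]]) &&
            !is.null(CA[[i + 1]])) {
          g$omega[i] <- torsion_angle(CA[[i]], C[[i]], N[[i + 1]], CA[[i + 1]])
          g$delta_omega[i] <- wrap_angle(g$omega[i] - 180)
        }
        if (!is.null(O[[i]]) && !is.null(C[[i]]) && !is.null(N[[i + 1]]) &&
            !is.null(CA[[i]]))
          g$theta_c[i] <- theta_c_sign *
            wrap_angle(torsion_angle(O[[i]], C[[i]], N[[i + 1]], CA[[i]]) - 180)
      }
    }
    out[[ch]] <- g
  }
  g <- do.call(rbind, out)
  rownames(g) <- NULL
  ss <- assign_ss(s, break_cutoff = break_cutoff)
  key <- paste(g$chain, g$resno)
  g$ss <- ss$ss[match(key, paste(ss$chain, ss$resno))]
  g$ss[is.na(g$ss)] <- "C"
  g
}

backbone_hbonds <- function(a, d_max = 3.5) {
  don <- a[trimws(a$elety) == "N", , drop = FALSE]
  acc <- a[trimws(a$elety) == "O", , drop = FALSE]
  if (nrow(don) == 0 || nrow(acc) == 0)
    return(data.frame(chain_d = character(), res_d = integer(),
                      chain_a = character(), res_a = integer()))
  P <- as.matrix(don[, c("x", "y", "z")])
  Q <- as.matrix(acc[, c("x", "y", "z")])
  D2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  hits <- which(D2 <= d_max^2, arr.ind = TRUE)
  if (nrow(hits) == 0)
    return(data.frame(chain_d = character(), res_d = integer(),
                      chain_a = character(), res_a = integer()))
  hb <- data.frame(chain_d = don$chain[hits[, 1]], res_d = don$resno[hits[, 1]],
                   chain_a = acc$chain[hits[, 2]], res_a = acc$resno[hits[, 2]],
                   stringsAsFactors = FALSE)
  # drop the trivially close covalent neighbours
  hb[!(hb$chain_d == hb$chain_a & abs(hb$res_d - hb$res_a) <= 1), ,
     drop = FALSE]
}

#' Lightweight secondary-structure assignment (H/E/C)
#'
#' H: the helical backbone hydrogen-bond pattern O(i)...N(i+4) (N-O distance
#' <= `d_max`) in smoothed runs of at least 4 residues.  E: participation in
#' an inter-strand ladder, i.e. two nearby cross-strand backbone N...O
#' hydrogen bonds (sequence separation > 2 or different chains).  Everything
#' else: C.  This is a hydrogen-bond-pattern assignment for aggregating
#' geometry statistics, not a DSSP energy model.
#'
#' @param s a [protein_structure].
#' @param d_max backbone N...O hydrogen-bond distance cutoff (default 3.5).
#' @param break_cutoff chain-break CA-CA cutoff (unused in the H-bond logic
#'   but kept for interface symmetry with [backbone_geometry]).
#' @return data.frame chain, resno, ss in {"H", "E", "C"}.
#' @export
assign_ss <- function(s, d_max = 3.5, break_cutoff = 4.5) {
  a <- census_atoms(s, include_het = FALSE)
  res <- unique(a[, c("chain", "resno")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  ss <- rep("C", nrow(res))
  hb <- backbone_hbonds(a, d_max)
  key <- paste(res$chain, res$resno)
  # helix: O(i) -> N(i+4) within a chain
  hel <- hb[hb$chain_d == hb$chain_a & (hb$res_d - hb$res_a) == 4, ,
            drop = FALSE]
  cand <- rep(FALSE, nrow(res))
  if (nrow(hel)) {
    for (k in seq_len(nrow(hel))) {
      covered <- paste(hel$chain_a[k], hel$res_a[k]:hel$res_d[k])
      cand[key %in% covered] <- TRUE
    }
  }
  # smoothed runs >= 4
  for (ch in unique(res$chain)) {
    sel <- which(res$chain == ch)
    r <- rle(cand[sel])
    pos <- cumsum(r$lengths)
    for (j in seq_along(r$lengths)) {
      if (r$values[j] && r$lengths[j] >= 4) {
        i2 <- pos[j]; i1 <- i2 - r$lengths[j] + 1
        ss[sel[i1:i2]] <- "H"
      }
    }
  }
  # sheet ladder: two nearby cross-strand hydrogen bonds
  cross <- hb[hb$chain_d != hb$chain_a |
                abs(hb$res_d - hb$res_a) > 2, , drop = FALSE]
  if (nrow(cross) > 1) {
    part <- rep(FALSE, nrow(res))
    for (k in seq_len(nrow(cross))) {
      for (l in seq_len(nrow(cross))) {
        if (k == l) next
        near_d <- cross$chain_d[k] == cross$chain_d[l] &&
          abs(cross$res_d[k] - cross$res_d[l]) <= 2
        near_a <- cross$chain_a[k] == cross$chain_a[l] &&
          abs(cross$res_a[k] - cross$res_a[l]) <= 2
        alt_d <- cross$chain_d[k] == cross$chain_a[l] &&
          abs(cross$res_d[k] - cross$res_a[l]) <= 2
        alt_a <- cross$chain_a[k] == cross$chain_d[l] &&
          abs(cross$res_a[k] - cross$res_d[l]) <= 2
        if ((near_d && near_a) || (alt_d && alt_a)) {
          part[key == paste(cross$chain_d[k], cross$res_d[k])] <- TRUE
          part[key == paste(cross$chain_a[k], cross$res_a[k])] <- TRUE
        }
      }
    }
    ss[part & ss != "H"] <- "E"
    # smooth single non-E residues between two ladder residues of a strand
    for (ch in unique(res$chain)) {
      sel <- which(res$chain == ch)
      if (length(sel) > 2) {
        for (m in sel[-c(1, length(sel))]) {
          if (ss[m] == "C" && ss[m - 1] == "E" && ss[m + 1] == "E")
            ss[m] <- "E"
        }
      }
    }
  }
  data.frame(chain = res$chain, resno = res$resno, ss = ss,
             stringsAsFactors = FALSE)
}

#' Statistics of a geometry quantity in psi windows
#'
#' @param geom data.frame from [backbone_geometry].
#' @param quantity one of "ncac", "delta_omega", "theta_c".
#' @param windows list of length-2 numeric vectors (psi_lo, psi_hi), degrees;
#'   defaults to the two windows used for planarity statistics, 75-105 and
#'   135-165.
#' @return data.frame psi_lo, psi_hi, n, mean, sd (mean/sd NA when n = 0);
#'   residues whose psi lies strictly inside a window contribute.
#' @export
psi_window_stats <- function(geom, quantity = c("ncac", "delta_omega",
                                                "theta_c"),
                             windows = list(c(75, 105), c(135, 165))) {
  quantity <- match.arg(quantity)
  stopifnot(nrow(geom) > 0)
  q <- geom[[quantity]]
  out <- lapply(windows, function(w) {
    inw <- !is.na(geom$psi) & !is.na(q) & geom$psi > w[1] & geom$psi < w[2]
    n <- sum(inw)
    data.frame(psi_lo = w[1], psi_hi = w[2], n = n,
               mean = if (n >= 1) mean(q[inw]) else NA_real_,
               sd = if (n >= 2) stats::sd(q[inw]) else
                 if (n == 1) 0 else NA_real_)
  })
  do.call(rbind, out)
}

#' Mean N-CA-C angle by secondary-structure class
#'
#' @param geom data.frame from [backbone_geometry].
#' @return data.frame ss, n, mean_ncac, sd_ncac for classes H, E, C.
#' @export
ncac_by_ss <- function(geom) {
  do.call(rbind, lapply(c("H", "E", "C"), function(cl) {
    v <- geom$ncac[geom$ss == cl & !is.na(geom$ncac)]
    data.frame(ss = cl, n = length(v),
               mean_ncac = if (length(v)) mean(v) else NA_real_,
               sd_ncac = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
}
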