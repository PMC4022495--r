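test_that("an exactly planar trans peptide has zero planarity deviations", {
  g <- backbone_geometry(fx_peptides()$dipeptide)
  expect_equal(g$omega[1], 180, tolerance = 1e-9)
  expect_equal(g$delta_omega[1], 0, tolerance = 1e-9)
  expect_equal(g$theta_c[1], 0, tolerance = 1e-9)
})

test_that("prescribed internal coordinates are recovered exactly", {
  g <- backbone_geometry(fx_peptides()$dipeptide_offset)
  expect_equal(g$delta_omega[1], -5, tolerance = 1e-9)
  expect_equal(g$theta_c[1], 3, tolerance = 1e-9)
  for (ang in c(105, 110, 111.2, 114)) {
    s <- build_backbone(4, ncac = ang)
    expect_equal(backbone_geometry(s)$ncac,
                 rep(ang, 4), tolerance = 1e-9)
  }
  s <- build_backbone(3, phi = -63, psi = -41, omega = 178.5)
  g3 <- backbone_geometry(s)
  expect_equal(g3$phi[2], -63, tolerance = 1e-9)
  expect_equal(g3$psi[1], -41, tolerance = 1e-9)
  expect_equal(g3$delta_omega[1], -1.5, tolerance = 1e-9)
})

test_that("wrap convention maps 181 to -179 and gives delta-omega +1 at -179", {
  expect_equal(wrap_angle(181), -179)
  expect_equal(wrap_angle(-180), 180)
  s <- build_backbone(3, omega = 181)   # stored as -179
  g <- backbone_geometry(s)
  expect_equal(g$omega[1], -179, tolerance = 1e-9)
  expect_equal(g$delta_omega[1], 1, tolerance = 1e-9)
})

test_that("dihedrals are invariant under rigid transforms", {
  h <- fx_peptides()$helix
  g0 <- backbone_geometry(h)
  set.seed(21)
  moved <- apply_transform(h, random_rotation(), rnorm(3, sd = 30))
  g1 <- backbone_geometry(moved)
  for (q in c("phi", "psi", "omega", "ncac", "theta_c")) {
    i <- !is.na(g0[[q]])
    # compare on the circle: +180 and -180 are the same dihedral
    expect_lt(max(abs(wrap_angle(g1[[q]][i] - g0[[q]][i]))), 1e-9)
  }
})

test_that("torsions agree with an independent implementation", {
  f <- tempfile(fileext = ".pdb")
  write_pdb(fx_monomer()$structure, f)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(f, verbose = FALSE))
  g <- backbone_geometry(fx_monomer()$structure)
  i <- 2:(nrow(g) - 1)
  # 0.2 deg tolerance: the PDB file truncates coordinates to 3 decimals
  expect_lt(max(abs(tor$phi[i] - g$phi[i])), 0.2)
  expect_lt(max(abs(tor$psi[i] - g$psi[i])), 0.2)
  unlink(f)
})

test_that("the ideal helix is assigned H throughout its core", {
  g <- backbone_geometry(fx_peptides()$helix)
  expect_true(all(g$ss == "H"))
})

test_that("the antiparallel sheet is assigned E in the strand cores", {
  g <- backbone_geometry(fx_peptides()$sheet)
  core <- g$resno %in% 2:7
  expect_true(all(g$ss[core] == "E"))
  expect_false(any(g$ss == "H"))
})

test_that("an isolated extended strand has no ladder and stays coil", {
  g <- backbone_geometry(fx_peptides()$strand)
  expect_true(all(g$ss == "C"))
})

test_that("helix N-CA-C angles exceed sheet angles when built with literature values", {
  gh <- backbone_geometry(fx_peptides()$helix)
  gs <- backbone_geometry(fx_peptides()$sheet)
  tab <- ncac_by_ss(rbind(gh, gs))
  mh <- tab$mean_ncac[tab$ss == "H"]
  me <- tab$mean_ncac[tab$ss == "E"]
  expect_equal(mh, 111.2, tolerance = 1e-6)
  expect_equal(me, 108.9, tolerance = 1e-6)
  expect_gt(mh, me)
})

test_that("psi-window statistics aggregate the right residues", {
  s <- build_backbone(20, phi = -120, psi = 150, omega = 182)
  g <- backbone_geometry(s)
  st <- psi_window_stats(g, "delta_omega")
  w2 <- st[st$psi_lo == 135, ]
  expect_equal(w2$n, 19)            # last residue has no following peptide
  expect_equal(w2$mean, 2, tolerance = 1e-9)
  w1 <- st[st$psi_lo == 75, ]
  expect_equal(w1$n, 0)
  expect_true(is.na(w1$mean))
})

test_that("chain breaks suppress cross-gap dihedrals", {
  s <- build_backbone(6)
  a <- s$atoms
  shift <- a$resno >= 4
  a$x[shift] <- a$x[shift] + 50
  broken <- protein_structure(a)
  g <- backbone_geometry(broken)
  expect_true(is.na(g$psi[3]))
  expect_true(is.na(g$omega[3]))
  expect_true(is.na(g$phi[4]))
  expect_false(is.na(g$psi[2]))
})

test_that("missing backbone atoms yield missing dependent values only", {
  s <- build_backbone(5)
  a <- s$atoms
  a <- a[!(a$resno == 3 & trimws(a$elety) == "O"), , drop = FALSE]
  g <- backbone_geometry(protein_structure(a))
  expect_true(is.na(g$theta_c[3]))
  expect_false(is.na(g$omega[3]))
  expect_false(is.na(g$ncac[3]))
})
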