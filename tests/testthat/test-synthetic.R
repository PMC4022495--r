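test_that("the two-lobe monomer has the specified layout and full backbone", {
  m <- fx_monomer()
  s <- m$structure
  expect_equal(length(unique(s$atoms$resno)), 75)   # 30 + 5 + 30 + 10
  per_res <- table(s$atoms$resno)
  expect_true(all(per_res == 5))                    # N, CA, C, O, CB
  for (nm in c("lobe1", "linker", "lobe2", "hinge", "tail"))
    expect_s3_class(m$domains[[nm]], "domain_def")
  expect_equal(m$domains$tail$ranges$end, 75)
})

test_that("generators are pure functions of spec and seed", {
  spec <- list(n_res_per_lobe = 12, linker_length = 3,
               helix_tail_length = 6, seed = 99)
  a <- make_two_lobe_monomer(spec)
  b <- make_two_lobe_monomer(spec)
  expect_identical(a$structure$atoms, b$structure$atoms)
  c2 <- make_two_lobe_monomer(modifyList(spec, list(seed = 100)))
  expect_false(identical(a$structure$atoms, c2$structure$atoms))
})

test_that("the lobes are spatially separated", {
  m <- fx_monomer()
  c1 <- colMeans(select_atoms(m$structure, m$domains$lobe1, "CA")$xyz)
  c2 <- colMeans(select_atoms(m$structure, m$domains$lobe2, "CA")$xyz)
  expect_gt(sqrt(sum((c1 - c2)^2)), 10)
})

test_that("domain rotation is exact and validates its inputs", {
  m <- fx_monomer()
  s0 <- apply_domain_rotation(m$structure, m$domains$lobe2, c(0, 0, 1), 0)
  expect_equal(atom_xyz_of(s0), atom_xyz_of(m$structure), tolerance = 1e-12)
  expect_error(apply_domain_rotation(m$structure, m$domains$lobe2,
                                     c(0, 0, 0), 30), "zero-length")
  # round trip through closure analysis at a large, fly-trap-scale angle
  rot <- apply_domain_rotation(m$structure, m$domains$lobe2,
                               c(0.6, 0.64, 0.48), 84)
  cl <- closure_analysis(m$structure, rot, m$domains$lobe1, m$domains$lobe2)
  expect_equal(cl$angle, 84, tolerance = 1e-6)
})

test_that("the swapped dimer is exactly two-fold symmetric", {
  d <- fx_dimer()
  expect_equal(chain_ids(d), c("A", "B"))
  r <- rmsd_structures(d, d, chainA = "A", chainB = "B")
  expect_lt(as.numeric(r), 0.01)
})

test_that("swapped-dimer contacts are confined to tail/partner-body", {
  d <- fx_dimer()
  rep <- classify_swap_interfaces(d, fx_monomer()$annotation)
  expect_gt(nrow(rep$c_interface), 0)
  expect_equal(nrow(rep$o_interface), 0)
  expect_gt(buried_area(d, "A", "B")$buried_total, 0)
})

test_that("a too-short tail is rejected", {
  m <- fx_monomer()
  bad_ann <- swap_annotation(swapped = c(75, 75), hinge = c(73, 74),
                             main_body = c(1, 72))
  expect_error(make_swapped_dimer(m$structure, bad_ann), "too short")
})

test_that("coordinate perturbation matches the chi-distribution scale", {
  s <- build_backbone(150)     # 750 atoms
  expect_identical(perturb_structure(s, 0, 1)$atoms, s$atoms)
  p1 <- perturb_structure(s, 0.2, 7)
  p2 <- perturb_structure(s, 0.2, 7)
  expect_identical(p1$atoms, p2$atoms)
  disp <- as.matrix(p1$atoms[, c("x", "y", "z")]) -
    as.matrix(s$atoms[, c("x", "y", "z")])
  rmsd <- sqrt(mean(rowSums(disp^2)))
  expect_lt(abs(rmsd - 0.2 * sqrt(3)) / (0.2 * sqrt(3)), 0.1)
})

test_that("generated structures survive a PDB round trip", {
  d <- fx_dimer()
  f <- tempfile(fileext = ".pdb")
  write_pdb(d, f)
  back <- read_pdb(f)
  expect_equal(nrow(back$atoms), nrow(d$atoms))
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                    as.matrix(d$atoms[, c("x", "y", "z")]))), 5e-4)
  unlink(f)
})

test_that("ideal fixtures carry their prescribed offsets", {
  fx <- make_ideal_peptide_fixtures(delta_omega = -7, theta_c_offset = 2.5)
  g <- backbone_geometry(fx$dipeptide_offset)
  expect_equal(g$delta_omega[1], -7, tolerance = 1e-9)
  expect_equal(g$theta_c[1], 2.5, tolerance = 1e-9)
})
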