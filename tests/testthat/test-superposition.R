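test_that("kabsch recovers exact transforms and rejects degenerate input", {
  set.seed(11)
  A <- matrix(rnorm(30), ncol = 3)
  res <- kabsch(A, A)
  expect_equal(res$rmsd, 0, tolerance = 1e-12)
  expect_equal(res$rotation, diag(3), tolerance = 1e-12)

  R90 <- rotation_matrix(c(0, 0, 1), 90)
  B <- apply_transform(A, t(R90), c(0, 0, 0))  # A = R90 B + t with t = ...
  B <- sweep(B, 2, c(5, 0, 0), "+")
  fit <- kabsch(A, B)
  expect_lt(fit$rmsd, 1e-10)
  aa <- rotation_angle_axis(fit$rotation)
  expect_equal(aa$angle, 90, tolerance = 1e-9)

  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "degenerate")
  expect_error(kabsch(A[1:2, ], A[1:2, ]), "at least 3")
})

test_that("kabsch rmsd is invariant under a common rigid transform", {
  set.seed(12)
  for (k in 1:20) {
    A <- matrix(rnorm(45), ncol = 3)
    B <- A + 0.3 * matrix(rnorm(45), ncol = 3)
    r0 <- kabsch(A, B)$rmsd
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    A2 <- apply_transform(A, R, t); B2 <- apply_transform(B, R, t)
    expect_equal(kabsch(A2, B2)$rmsd, r0, tolerance = 1e-9)
  }
})

test_that("rmsd of a structure against itself is zero, fitted or not", {
  m <- fx_monomer()$structure
  expect_equal(as.numeric(rmsd_structures(m, m)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(rmsd_structures(m, m, fit = FALSE)), 0,
               tolerance = 1e-12)
})

test_that("closure of a structure with itself is zero with zero residuals", {
  m <- fx_monomer()
  cl <- closure_analysis(m$structure, m$structure, m$domains$lobe1,
                         m$domains$lobe2)
  expect_equal(cl$angle, 0, tolerance = 1e-9)
  expect_equal(cl$fixed_rmsd, 0, tolerance = 1e-9)
  expect_equal(cl$moving_rmsd, 0, tolerance = 1e-9)
})

test_that("constructed rigid lobe rotations are recovered exactly", {
  m <- fx_monomer()
  axis <- c(0.48, -0.6, 0.64); axis <- axis / sqrt(sum(axis^2))
  rot <- apply_domain_rotation(m$structure, m$domains$lobe2, axis, 30)
  cl <- closure_analysis(m$structure, rot, m$domains$lobe1, m$domains$lobe2)
  expect_equal(cl$angle, 30, tolerance = 1e-6)
  expect_gt(abs(sum(cl$axis * axis)), 0.999999)
  expect_lt(cl$fixed_rmsd, 1e-9)
  expect_gt(cl$moving_rmsd, 1)      # the moving lobe really moved
})

test_that("sequential rotations about one axis compose additively", {
  m <- fx_monomer()
  axis <- c(0, 1, 0)
  pivot <- colMeans(select_atoms(m$structure, m$domains$lobe2, "CA")$xyz)
  s1 <- apply_domain_rotation(m$structure, m$domains$lobe2, axis, 25,
                              pivot = pivot)
  s2 <- apply_domain_rotation(s1, m$domains$lobe2, axis, 40, pivot = pivot)
  cl <- closure_analysis(m$structure, s2, m$domains$lobe1, m$domains$lobe2)
  expect_equal(cl$angle, 65, tolerance = 1e-6)
  # wrap past 180: 120 + 120 -> 240 reported as 120 about the opposite axis
  s3 <- apply_domain_rotation(
    apply_domain_rotation(m$structure, m$domains$lobe2, axis, 120,
                          pivot = pivot),
    m$domains$lobe2, axis, 120, pivot = pivot)
  cl3 <- closure_analysis(m$structure, s3, m$domains$lobe1, m$domains$lobe2)
  expect_equal(cl3$angle, 120, tolerance = 1e-6)
})

test_that("residue pairing drops unmatched residues instead of misaligning", {
  m <- fx_monomer()$structure
  trunc <- m
  trunc$atoms <- trunc$atoms[trunc$atoms$resno <= 73, , drop = FALSE]  # drop 2 C-term residues
  val <- rmsd_structures(m, trunc)
  expect_equal(as.numeric(val), 0, tolerance = 1e-12)
  expect_equal(attr(val, "n_atoms"), 73)
  expect_equal(attr(val, "n_dropped"), 2)
})
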