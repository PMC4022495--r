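test_that("single ATOM record parses to one atom at its coordinates", {
  txt <- "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00 10.00           C"
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(length(chain_ids(s)), 1)
  expect_equal(unname(unlist(s$atoms[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(s$atoms$resid, "GLY")
  expect_false(s$atoms$het)
})

test_that("two equal-length chains give two chains with equal residue counts", {
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:5, 1:5, as.numeric(1:5), 0, 0),
    sprintf("ATOM  %5d  CA  ALA B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            6:10, 1:5, as.numeric(1:5), 5, 0))
  s <- read_pdb(paste(lines, collapse = "\n"))
  expect_equal(chain_ids(s), c("A", "B"))
  counts <- table(s$atoms$chain)
  expect_equal(unname(counts[["A"]]), unname(counts[["B"]]))
})

test_that("read-write-read round trip preserves coordinates, names, numbering", {
  m <- fx_monomer()$structure
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb(m, f1)
  s1 <- read_pdb(f1)
  write_pdb(s1, f2)
  s2 <- read_pdb(f2)
  expect_equal(s2$atoms$resno, s1$atoms$resno)
  expect_equal(trimws(s2$atoms$elety), trimws(s1$atoms$elety))
  expect_equal(s2$atoms$resid, s1$atoms$resid)
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                    as.matrix(s1$atoms[, c("x", "y", "z")]))), 5e-4)
  # against the in-memory original, coordinates agree to the 3-decimal field
  expect_lt(max(abs(as.matrix(s1$atoms[, c("x", "y", "z")]) -
                    as.matrix(m$atoms[, c("x", "y", "z")]))), 5e-4)
  unlink(c(f1, f2))
})

test_that("malformed and empty PDB input raise informative errors", {
  expect_error(read_pdb("ATOM      1  CA  GLY A   1       1.0  bad"),
               "line 1")
  bad2 <- paste("HEADER    test",
                "ATOM      1  CA  GLY A   1       1.000   2.000   x.xxx",
                sep = "\n")
  expect_error(read_pdb(bad2), "line 2")
  ef <- tempfile(); writeLines(character(), ef)
  expect_error(read_pdb(ef), "empty")
  unlink(ef)
})

test_that("writing rejects over-long atom names and handles empty structures", {
  s <- read_pdb("ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00 10.00           C")
  s$atoms$elety <- "CAXXX"
  expect_error(write_pdb(s, tempfile()), "longer than 4")
  empty <- protein_structure(s$atoms[0, , drop = FALSE])
  f <- tempfile(); write_pdb(empty, f)
  expect_equal(readLines(f), "END")
  unlink(f)
})

test_that("selection by author-numbered ranges returns the expected residues", {
  # chain numbered 20-246 as in a signal-peptide-less construct
  s <- build_backbone(227, first_resno = 20L)
  sel <- select_atoms(s, "23-110", "CA")
  expect_equal(nrow(sel$xyz), 88)
  expect_equal(range(sel$index$resno), c(23, 110))
  bb <- select_atoms(s, "A:20-29", c("N", "CA", "C", "O"))
  expect_equal(nrow(bb$xyz), 40)
  expect_error(select_atoms(s, "A:500-600", "CA"), "zero atoms")
})

test_that("lobes plus linkers tile the construct without gaps", {
  s <- build_backbone(227, first_resno = 20L)
  union_def <- domain_def("all parts",
                          "20-22,23-110,111-115,116-203,204-209,210-231,232-246")
  sel <- select_atoms(s, union_def, "CA")
  expect_equal(nrow(sel$xyz), 227)
  expect_equal(sel$index$resno, 20:246)
})

test_that("altloc filtering keeps blank and A, drops B; hetero is flagged", {
  lines <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       1.200   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA  ALA A   2       4.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  N   ARG A 300      10.000   0.000   0.000  1.00  0.00           N")
  s <- read_pdb(paste(lines, collapse = "\n"))
  expect_equal(nrow(s$atoms), 3)
  expect_equal(sum(s$atoms$het), 1)
  expect_equal(s$atoms$x[s$atoms$resno == 1], 1.0)
})

test_that("structure_sequence extracts one-letter sequence with author start", {
  s <- build_backbone(5, resid = c("ALA", "GLY", "LYS", "ASP", "TRP"),
                      first_resno = 20L)
  sq <- structure_sequence(s)
  expect_equal(sq$one_letter, "AGKDW")
  expect_equal(sq$first_number, 20)
})
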