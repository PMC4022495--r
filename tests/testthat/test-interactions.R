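asp_lys_pair <- function(d) {
  toy_atoms(atomr("A", 10, "ASP", "OD1", c(0, 0, 0)),
            atomr("A", 10, "ASP", "CG", c(-1.3, 0, 0)),
            atomr("B", 42, "LYS", "NZ", c(d, 0, 0)),
            atomr("B", 42, "LYS", "CE", c(d + 1.5, 0, 0)))
}

test_that("salt bridges respect the distance cutoff", {
  expect_equal(nrow(salt_bridges(asp_lys_pair(3.0), cutoff = 4.0)), 1)
  expect_equal(nrow(salt_bridges(asp_lys_pair(6.0), cutoff = 4.0)), 0)
  sb <- salt_bridges(asp_lys_pair(3.0))
  expect_equal(sb$kind, "salt_bridge")
  expect_equal(sb$distance, 3.0, tolerance = 1e-9)
  # canonical ordering: partner 1 sorts before partner 2
  expect_true(paste(sb$chain1, sb$resno1) <= paste(sb$chain2, sb$resno2))
})

test_that("salt-bridge scope separates intra- from inter-chain pairs", {
  s <- asp_lys_pair(3.0)
  expect_equal(nrow(salt_bridges(s, scope = "inter")), 1)
  expect_equal(nrow(salt_bridges(s, scope = "intra")), 0)
  s$atoms$chain <- "A"
  expect_equal(nrow(salt_bridges(s, scope = "inter")), 0)
  expect_equal(nrow(salt_bridges(s, scope = "intra")), 1)
})

test_that("histidine salt bridges are flagged for unknown protonation", {
  s <- toy_atoms(atomr("A", 1, "HIS", "NE2", c(0, 0, 0)),
                 atomr("B", 2, "GLU", "OE1", c(3.2, 0, 0)))
  sb <- salt_bridges(s)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$flag, "his_protonation_unknown")
})

test_that("hydrogen bonds require distance and a wide donor angle", {
  lin <- toy_atoms(atomr("A", 1, "ALA", "CA", c(-1.5, 0, 0)),
                   atomr("A", 1, "ALA", "N", c(0, 0, 0)),
                   atomr("B", 9, "ALA", "O", c(2.9, 0, 0)))
  expect_equal(nrow(hydrogen_bonds(lin)), 1)
  far <- toy_atoms(atomr("A", 1, "ALA", "CA", c(-1.5, 0, 0)),
                   atomr("A", 1, "ALA", "N", c(0, 0, 0)),
                   atomr("B", 9, "ALA", "O", c(5, 0, 0)))
  expect_equal(nrow(hydrogen_bonds(far)), 0)
  bent <- toy_atoms(atomr("A", 1, "ALA", "CA", c(0, 1.5, 0)),
                    atomr("A", 1, "ALA", "N", c(0, 0, 0)),
                    atomr("B", 9, "ALA", "O", c(0, 2.9, 0)))  # angle ~ 0
  expect_equal(nrow(hydrogen_bonds(bent)), 0)
  # donor without its antecedent: kept on distance, flagged
  noante <- toy_atoms(atomr("A", 1, "ALA", "N", c(0, 0, 0)),
                      atomr("B", 9, "ALA", "O", c(2.9, 0, 0)))
  hb <- hydrogen_bonds(noante)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$flag, "angle_unavailable")
})

test_that("hydrophobic contacts use side-chain carbons of apolar residues", {
  pair <- toy_atoms(atomr("A", 5, "LEU", "CD1", c(0, 0, 0)),
                    atomr("B", 8, "LEU", "CD2", c(4.0, 0, 0)))
  expect_equal(nrow(hydrophobic_contacts(pair, cutoff = 4.5)), 1)
  farp <- toy_atoms(atomr("A", 5, "LEU", "CD1", c(0, 0, 0)),
                    atomr("B", 8, "LEU", "CD2", c(8, 0, 0)))
  expect_equal(nrow(hydrophobic_contacts(farp, cutoff = 4.5)), 0)
  # backbone carbons and polar residues never count
  bb <- toy_atoms(atomr("A", 5, "LEU", "CA", c(0, 0, 0)),
                  atomr("B", 8, "SER", "CB", c(4.0, 0, 0)))
  expect_equal(nrow(hydrophobic_contacts(bb, cutoff = 4.5)), 0)
})

test_that("contact counts grow monotonically with the cutoff", {
  d <- fx_dimer()
  prev <- -1
  for (cut in c(3.5, 4.5, 5.5, 6.5)) {
    n <- nrow(hydrophobic_contacts(d, cutoff = cut, scope = "inter"))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("each residue pair is stored once with its minimum distance", {
  s <- toy_atoms(atomr("A", 5, "LEU", "CD1", c(0, 0, 0)),
                 atomr("A", 5, "LEU", "CD2", c(0.8, 0, 0)),
                 atomr("B", 8, "LEU", "CD1", c(4.0, 0, 0)),
                 atomr("B", 8, "LEU", "CD2", c(4.4, 0, 0)))
  hc <- hydrophobic_contacts(s, cutoff = 6)
  expect_equal(nrow(hc), 1)
  expect_equal(hc$distance, 3.2, tolerance = 1e-9)
})

test_that("swap classification partitions inter-chain contacts", {
  d <- fx_dimer()
  ann <- fx_monomer()$annotation
  contacts <- rbind(salt_bridges(d, scope = "inter"),
                    hydrogen_bonds(d, scope = "inter"),
                    hydrophobic_contacts(d, scope = "inter"))
  rep <- classify_swap_interfaces(d, ann, contacts)
  expect_equal(nrow(rep$c_interface) + nrow(rep$o_interface), nrow(contacts))
  expect_gt(nrow(rep$c_interface), 0)
  expect_equal(nrow(rep$o_interface), 0)
  # two-fold symmetry: per-chain C-interface counts nearly equal
  expect_lte(abs(diff(rep$per_chain_c_counts)), 2)
})

test_that("an isolated monomer yields an empty interface report", {
  m <- fx_monomer()
  rep <- classify_swap_interfaces(m$structure, m$annotation)
  expect_equal(nrow(rep$c_interface), 0)
  expect_equal(nrow(rep$o_interface), 0)
})

test_that("hinge-mediated contacts fall in the O-interface", {
  ann <- swap_annotation(swapped = c(69, 75), hinge = c(66, 68),
                         main_body = c(1, 65))
  s <- toy_atoms(atomr("A", 67, "LEU", "CD1", c(0, 0, 0)),   # hinge
                 atomr("B", 30, "LEU", "CD1", c(4, 0, 0)),   # body
                 atomr("A", 70, "LEU", "CD2", c(20, 0, 0)),  # swapped
                 atomr("B", 40, "LEU", "CD2", c(24, 0, 0)))  # body
  contacts <- hydrophobic_contacts(s, scope = "inter")
  rep <- classify_swap_interfaces(s, ann, contacts)
  expect_equal(nrow(rep$c_interface), 1)
  expect_equal(nrow(rep$o_interface), 1)
  expect_equal(rep$o_interface$resno1, 67)
})

test_that("ligand pocket contacts find anchors and report ligand burial", {
  # free arginine-like hetero ligand with a protein Asp nearby
  lig <- list(atomr("L", 300, "ARG", "N", c(0, 0, 0), het = TRUE),
              atomr("L", 300, "ARG", "CA", c(1.46, 0, 0), het = TRUE),
              atomr("L", 300, "ARG", "C", c(2.2, 1.3, 0), het = TRUE),
              atomr("L", 300, "ARG", "O", c(3.4, 1.3, 0.4), het = TRUE),
              atomr("L", 300, "ARG", "CB", c(1.9, -0.9, 1.1), het = TRUE),
              atomr("L", 300, "ARG", "NH1", c(4.5, -2, 1), het = TRUE))
  prot <- list(atomr("A", 37, "ASP", "OD1", c(4.5, -2, 4.2)),
               atomr("A", 38, "PHE", "CZ", c(1.9, -0.9, 5.0)))
  s <- do.call(toy_atoms, c(lig, prot))
  lp <- ligand_pocket_contacts(s, "ARG")
  expect_true("salt_bridge" %in% lp$contacts$kind)   # NH1 - OD1 at 3.2
  expect_true("hydrophobic" %in% lp$contacts$kind)   # CB - CZ at 3.9
  expect_gt(lp$ligand_sasa_free, 0)
  expect_lt(lp$ligand_sasa, lp$ligand_sasa_free)
  # ligand alone: no protein, no contacts
  lone <- do.call(toy_atoms, lig)
  lp0 <- ligand_pocket_contacts(lone, "ARG")
  expect_equal(nrow(lp0$contacts), 0)
  expect_error(ligand_pocket_contacts(s, "GLN"), "not found")
})
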