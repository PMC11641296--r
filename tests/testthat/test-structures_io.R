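test_that("toy PDB parses with correct record counts, roles and CA flags", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path)
  r <- read_pdb(path)
  expect_equal(nrow(r$protein$atoms), 10)
  expect_equal(nrow(r$waters), 1)
  expect_equal(r$waters$provenance, "experimental")
  expect_equal(sum(r$protein$atoms$is_c_alpha), 3)
  ca_val <- r$protein$atoms[r$protein$atoms$is_c_alpha &
                              r$protein$atoms$residue_name == "VAL", ]
  expect_true(ca_val$is_c_alpha)
  # template context is attached: SER OG is a hydroxyl oxygen
  og <- r$protein$atoms[r$protein$atoms$name == "OG", ]
  expect_equal(og$attached_h_count, 1L)
  expect_equal(og$explicit_valence, 2L)
})

test_that("PDB write -> read round-trip preserves structure to 1e-3 A", {
  cp <- make_complex(fixture_spec(seed = 3, n_bridge_waters = 2))
  dir <- withr::local_tempdir()
  write_pdb(cp$protein, file.path(dir, "p.pdb"),
            waters = cp$waters[cp$waters$provenance == "experimental", ])
  r <- read_pdb(file.path(dir, "p.pdb"))
  expect_equal(nrow(r$protein$atoms), nrow(cp$protein$atoms))
  expect_equal(r$protein$atoms$element, cp$protein$atoms$element)
  expect_lt(max(abs(coords_mat <- as.matrix(r$protein$atoms[, c("x", "y", "z")]) -
                  as.matrix(cp$protein$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_equal(nrow(r$waters), sum(cp$waters$provenance == "experimental"))
})

test_that("malformed and empty PDB files produce informative errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  VAL A   1        bad_x   0.000   0.000"), path)
  expect_error(read_pdb(path), "malformed")
  writeLines(c("REMARK nothing here"), path)
  expect_error(read_pdb(path), "no ATOM/HETATM")
})

test_that("benzene Mol2: aromatic ring perception from the bond block", {
  path <- withr::local_tempfile(fileext = ".mol2")
  write_benzene_mol2(path)
  m <- read_ligand(path)
  expect_equal(nrow(m$atoms), 6)
  expect_true(all(m$atoms$is_aromatic))
  expect_true(all(m$atoms$is_in_ring))
  expect_true(all(m$atoms$heavy_neighbor_count == 2L))
  expect_equal(nrow(m$bonds), 6)
})

test_that("ethanol Mol2: valence arithmetic with explicit hydrogens", {
  path <- withr::local_tempfile(fileext = ".mol2")
  write_ethanol_mol2(path)
  m <- read_ligand(path)
  expect_equal(nrow(m$atoms), 3)  # hydrogens dropped
  o <- m$atoms[m$atoms$element == "O", ]
  expect_equal(o$heavy_neighbor_count, 1L)
  expect_equal(o$attached_h_count, 1L)
  expect_equal(o$explicit_valence, 2L)
  c1 <- m$atoms[1, ]
  expect_equal(c1$attached_h_count, 3L)
  expect_equal(c1$explicit_valence, 4L)
})

test_that("out-of-vocabulary ligand elements warn but are kept", {
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "sel", "2 1 1", "SMALL", "NO_CHARGES", "",
               "@<TRIPOS>ATOM",
               " 1 C1  0.0 0.0 0.0 C.3 1 SEL 0.0",
               " 2 SE1 1.9 0.0 0.0 Se  1 SEL 0.0",
               "@<TRIPOS>BOND", "1 1 2 1"), path)
  expect_warning(m <- read_ligand(path), "vocabulary")
  expect_equal(nrow(m$atoms), 2)
  expect_true("Se" %in% m$atoms$element)
})

test_that("mol2 without a bond block is rejected", {
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "x", "1 0 1", "SMALL", "NO_CHARGES", "",
               "@<TRIPOS>ATOM", " 1 C1 0.0 0.0 0.0 C.3 1 X 0.0"), path)
  expect_error(read_ligand(path), "BOND")
})

test_that("SDF reading agrees with Mol2 reading on the same molecule", {
  lig <- make_complex(fixture_spec(seed = 5))$ligand
  dir <- withr::local_tempdir()
  write_mol2(lig, file.path(dir, "l.mol2"))
  # V2000 block written by hand from the same structure
  a <- lig$atoms; b <- lig$bonds
  sdf <- c("lig", "  synthetic", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
           sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   a$x, a$y, a$z, a$element),
           sprintf("%3d%3d%3d  0", b$i, b$j, as.integer(b$order)),
           "M  END", "$$$$")
  writeLines(sdf, file.path(dir, "l.sdf"))
  m2 <- read_ligand(file.path(dir, "l.mol2"))
  ms <- read_ligand(file.path(dir, "l.sdf"))
  expect_equal(ms$atoms$element, m2$atoms$element)
  expect_equal(ms$atoms$heavy_neighbor_count, m2$atoms$heavy_neighbor_count)
  expect_equal(as.matrix(ms$atoms[, c("x", "y", "z")]),
               as.matrix(m2$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
})

test_that("extract_pocket keeps whole residues by the distance rule", {
  prot <- mol_structure(rbind(
    protein_atom_row(1L, "CA", "C", c(5, 0, 0), "GLY", 1L, 4L, 2L, 2L),
    protein_atom_row(2L, "CA", "C", c(25, 0, 0), "GLY", 2L, 4L, 2L, 2L)
  ), role = "protein")
  cp <- complex_structure("t", prot, bare_ligand(c(0, 0, 0)))
  pk <- extract_pocket(cp, 6)
  expect_equal(pk$protein$atoms$residue_index, 1L)
  # whole-residue retention: a far atom of a near residue is kept
  prot2 <- mol_structure(rbind(
    protein_atom_row(1L, "CA", "C", c(5, 0, 0), "GLY", 1L, 4L, 2L, 2L),
    protein_atom_row(2L, "C", "C", c(14, 0, 0), "GLY", 1L, 4L, 3L, 0L)
  ), role = "protein")
  pk2 <- extract_pocket(complex_structure("t", prot2, bare_ligand(c(0, 0, 0))), 6)
  expect_equal(nrow(pk2$protein$atoms), 2)
  pk2_atom <- extract_pocket(complex_structure("t", prot2, bare_ligand(c(0, 0, 0))),
                             6, residue_mode = "atom")
  expect_equal(nrow(pk2_atom$protein$atoms), 1)
})

test_that("empty pockets error and extraction is idempotent", {
  prot <- tiny_protein(c(30, 0, 0))
  cp <- complex_structure("t", prot, bare_ligand(c(0, 0, 0)))
  expect_error(extract_pocket(cp, 6), "larger cutoff")
  pk1 <- gen_pocket(seed = 11)
  pk2 <- extract_pocket(pk1, 10)
  expect_identical(pk1$protein$atoms, pk2$protein$atoms)
  expect_identical(pk1$waters, pk2$waters)
})

test_that("pocket membership equals the brute-force distance oracle", {
  for (seed in c(2, 9, 17)) {
    cp <- make_complex(fixture_spec(seed = seed, n_bridge_waters = 1))
    cutoff <- 8
    pk <- extract_pocket(cp, cutoff)
    # oracle: whole residues with any atom within cutoff of any ligand atom
    pa <- cp$protein$atoms
    d <- cross_dist(as.matrix(pa[, c("x", "y", "z")]),
                    as.matrix(cp$ligand$atoms[, c("x", "y", "z")]))
    near <- apply(d, 1, min) < cutoff
    keep_res <- unique(pa$residue_index[near])
    expect_setequal(unique(pk$protein$atoms$residue_index), keep_res)
    expect_equal(nrow(pk$protein$atoms), sum(pa$residue_index %in% keep_res))
  }
})
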