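# Shared in-code fixtures and independent oracles.

# -- tiny hand-built protein -------------------------------------------------

# one protein atom row with template-consistent context
protein_atom_row <- function(serial, name, element, xyz, res, ridx,
                             valence = 4L, heavy = 1L, h = 0L,
                             arom = FALSE, ring = FALSE) {
  data.frame(serial = serial, name = name, element = element,
             x = xyz[1], y = xyz[2], z = xyz[3],
             residue_name = res, residue_index = ridx, chain = "A",
             role = "protein", explicit_valence = valence,
             heavy_neighbor_count = heavy, attached_h_count = h,
             is_aromatic = arom, is_in_ring = ring,
             is_c_alpha = name == "CA", stringsAsFactors = FALSE)
}

# a minimal one-residue protein with a CA at `at`
tiny_protein <- function(at = c(0, 0, 0), res = "GLY", ridx = 1L) {
  mol_structure(protein_atom_row(1L, "CA", "C", at, res, ridx,
                                 valence = 4L, heavy = 2L, h = 2L),
                role = "protein")
}

# a bare n-atom carbon ligand at given coordinates (no bonds unless given)
bare_ligand <- function(xyz, bonds = empty_bonds(), elements = "C") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  el <- rep_len(elements, n)
  atoms <- data.frame(serial = seq_len(n), name = paste0(el, seq_len(n)),
                      element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      residue_name = "LIG", residue_index = 1L, chain = "L",
                      role = "ligand", explicit_valence = 4L,
                      heavy_neighbor_count = 0L, attached_h_count = 0L,
                      is_aromatic = FALSE, is_in_ring = FALSE,
                      is_c_alpha = FALSE, stringsAsFactors = FALSE)
  mol_structure(atoms, bonds, role = "ligand")
}

# -- literal small-molecule files (written at test time) ---------------------

write_benzene_mol2 <- function(path) {
  r <- 1.39
  ang <- (0:5) * pi / 3
  atom_lines <- sprintf("%7d C%d %10.4f %10.4f %10.4f C.ar 1 BNZ %8.4f",
                        1:6, 1:6, r * cos(ang), r * sin(ang), 0, 0)
  bond_lines <- sprintf("%6d %5d %5d ar", 1:6, 1:6, c(2:6, 1))
  writeLines(c("@<TRIPOS>MOLECULE", "benzene", "6 6 1", "SMALL", "NO_CHARGES",
               "", "@<TRIPOS>ATOM", atom_lines, "@<TRIPOS>BOND", bond_lines),
             path)
  path
}

write_ethanol_mol2 <- function(path) {
  # CH3-CH2-OH with explicit hydrogens
  atoms <- c(
    " 1 C1  0.0000 0.0000 0.0000 C.3 1 ETH 0.0",
    " 2 C2  1.5200 0.0000 0.0000 C.3 1 ETH 0.0",
    " 3 O1  2.0300 1.3300 0.0000 O.3 1 ETH 0.0",
    " 4 H1 -0.4000 1.0000 0.0000 H   1 ETH 0.0",
    " 5 H2 -0.4000 -0.5000 0.8700 H  1 ETH 0.0",
    " 6 H3 -0.4000 -0.5000 -0.8700 H 1 ETH 0.0",
    " 7 H4  1.9000 -0.5000 0.8700 H  1 ETH 0.0",
    " 8 H5  1.9000 -0.5000 -0.8700 H 1 ETH 0.0",
    " 9 H6  2.9900 1.3300 0.0000 H   1 ETH 0.0")
  bonds <- c("1 1 2 1", "2 2 3 1", "3 1 4 1", "4 1 5 1", "5 1 6 1",
             "6 2 7 1", "7 2 8 1", "8 3 9 1")
  writeLines(c("@<TRIPOS>MOLECULE", "ethanol", "9 8 1", "SMALL", "NO_CHARGES",
               "", "@<TRIPOS>ATOM", atoms, "@<TRIPOS>BOND", bonds), path)
  path
}

# fixed-column toy PDB: three residues plus one water
write_toy_pdb <- function(path) {
  fmt <- "%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  l <- c(
    sprintf(fmt, "ATOM", 1, " N  ", "VAL", "A", 1, 0.0, 0.0, 0.0, 1, 0, "N"),
    sprintf(fmt, "ATOM", 2, " CA ", "VAL", "A", 1, 1.5, 0.0, 0.0, 1, 0, "C"),
    sprintf(fmt, "ATOM", 3, " C  ", "VAL", "A", 1, 2.2, 1.3, 0.0, 1, 0, "C"),
    sprintf(fmt, "ATOM", 4, " O  ", "VAL", "A", 1, 3.4, 1.3, 0.2, 1, 0, "O"),
    sprintf(fmt, "ATOM", 5, " N  ", "ALA", "A", 2, 1.6, 2.4, -0.2, 1, 0, "N"),
    sprintf(fmt, "ATOM", 6, " CA ", "ALA", "A", 2, 2.2, 3.7, -0.3, 1, 0, "C"),
    sprintf(fmt, "ATOM", 7, " CB ", "ALA", "A", 2, 1.9, 4.4, -1.6, 1, 0, "C"),
    sprintf(fmt, "ATOM", 8, " N  ", "SER", "A", 3, 3.1, 4.2, 0.7, 1, 0, "N"),
    sprintf(fmt, "ATOM", 9, " CA ", "SER", "A", 3, 3.8, 5.5, 0.7, 1, 0, "C"),
    sprintf(fmt, "ATOM", 10, " OG ", "SER", "A", 3, 5.1, 5.4, 1.2, 1, 0, "O"),
    "TER",
    sprintf(fmt, "HETATM", 11, " O  ", "HOH", "W", 1, 4.0, 2.0, 2.0, 1, 0, "O"),
    "END")
  writeLines(l, path)
  path
}

# -- independent oracles -----------------------------------------------------

floyd_warshall <- function(n, edges_i, edges_j) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_along(edges_i)) {
    D[edges_i[k], edges_j[k]] <- 1
    D[edges_j[k], edges_i[k]] <- 1
  }
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# empty protein shell (for clash-free hydration fixtures)
empty_protein <- function() {
  mol_structure(protein_atom_row(1L, "CA", "C", c(0, 0, 0), "GLY", 1L,
                                 4L, 2L, 2L)[0, ], role = "protein")
}

# brute-force edge oracle: applies the six pair rules + covalent + backbone +
# residue-internal rules atom pair by atom pair, independent of build_graph
oracle_edges <- function(cplx, waters, T, base_cutoff = 6) {
  nodes <- rbind(cplx$protein$atoms, cplx$ligand$atoms)
  np <- nrow(cplx$protein$atoms); nl <- nrow(cplx$ligand$atoms)
  nw <- nrow(waters)
  if (nw) {
    wdf <- nodes[rep(1, nw), , drop = FALSE]
    wdf$x <- waters$x; wdf$y <- waters$y; wdf$z <- waters$z
    wdf$role <- "water"; wdf$is_c_alpha <- FALSE
    wdf$chain <- "W"; wdf$residue_index <- seq_len(nw)
    nodes <- rbind(nodes, wdf)
  }
  n <- nrow(nodes)
  dist <- function(a, b) sqrt(sum((c(nodes$x[a], nodes$y[a], nodes$z[a]) -
                                   c(nodes$x[b], nodes$y[b], nodes$z[b]))^2))
  bonded <- matrix(FALSE, n, n)
  if (nrow(cplx$ligand$bonds)) {
    bi <- np + cplx$ligand$bonds$i; bj <- np + cplx$ligand$bonds$j
    bonded[cbind(bi, bj)] <- TRUE; bonded[cbind(bj, bi)] <- TRUE
  }
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ri <- nodes$role[i]; rj <- nodes$role[j]
    d <- dist(i, j)
    keep <- FALSE; ty <- NA_character_
    pair <- paste(sort(c(ri, rj)), collapse = "-")
    if (pair == "ligand-ligand") {
      ty <- "LL"; keep <- d < base_cutoff || bonded[i, j]
    } else if (pair == "ligand-protein") {
      ty <- "PL"
      pi_ <- if (ri == "protein") i else j
      keep <- nodes$is_c_alpha[pi_] && d < base_cutoff
    } else if (pair == "protein-protein") {
      ty <- "PP"
      if (nodes$is_c_alpha[i] && nodes$is_c_alpha[j]) {
        keep <- d < base_cutoff ||
          (nodes$chain[i] == nodes$chain[j] &&
             abs(nodes$residue_index[i] - nodes$residue_index[j]) == 1)
      } else if (xor(nodes$is_c_alpha[i], nodes$is_c_alpha[j])) {
        keep <- nodes$chain[i] == nodes$chain[j] &&
          nodes$residue_index[i] == nodes$residue_index[j]
      }
    } else if (pair == "ligand-water") {
      ty <- "WL"; keep <- d < T
    } else if (pair == "protein-water") {
      ty <- "WP"
      pi_ <- if (ri == "protein") i else j
      keep <- nodes$is_c_alpha[pi_] && d < T
    } else if (pair == "water-water") {
      ty <- "WW"; keep <- d < T
    }
    if (keep) out <- rbind(out, data.frame(i = i, j = j, pair_type = ty))
  }
  # drop isolated waters, renumber like build_graph does
  if (nw) {
    widx <- np + nl + seq_len(nw)
    touched <- unique(c(out$i, out$j))
    iso <- setdiff(widx, touched)
    if (length(iso)) {
      keepn <- setdiff(seq_len(n), iso)
      remap <- match(seq_len(n), keepn)
      out$i <- remap[out$i]; out$j <- remap[out$j]
    }
  }
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# small complex via the generator, pocket-extracted
gen_pocket <- function(seed = 1, n_bridge = 2, n_res = 6, n_lig = 6,
                       n_decoy = 2) {
  cp <- make_complex(fixture_spec(seed = seed, n_bridge_waters = n_bridge,
                                  n_residues = n_res, n_ligand_atoms = n_lig,
                                  n_decoy_waters = n_decoy))
  extract_pocket(cp, 10)
}

# random sparse abstract graph in complex_graph form (for SPD/model tests)
random_complex_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n, 0, 20), n, 3)
  nodes <- data.frame(serial = seq_len(n), name = "C", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      residue_name = "LIG", residue_index = 1L, chain = "L",
                      role = "ligand", explicit_valence = 4L,
                      heavy_neighbor_count = 0L, attached_h_count = 0L,
                      is_aromatic = FALSE, is_in_ring = FALSE,
                      is_c_alpha = FALSE, stringsAsFactors = FALSE)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sel <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  edges <- data.frame(i = sel[, 1], j = sel[, 2],
                      pair_type = rep("LL", nrow(sel)),
                      distance = sqrt(rowSums((xyz[sel[, 1], , drop = FALSE] -
                                               xyz[sel[, 2], , drop = FALSE])^2)))
  X <- matrix(rnorm(n * NODE_FEATURE_DIM, sd = 0.3), n)
  structure(list(nodes = nodes, X = X, edges = edges, variant = "G_A",
                 water_threshold_T = 6, base_cutoff = 6,
                 protein_level = "calpha"),
            class = "complex_graph")
}

# permute the nodes of a complex_graph, remapping edges and features
permute_graph <- function(g, perm) {
  inv <- order(perm)
  nodes <- g$nodes[perm, , drop = FALSE]
  rownames(nodes) <- NULL
  ei <- inv[g$edges$i]; ej <- inv[g$edges$j]
  edges <- data.frame(i = pmin(ei, ej), j = pmax(ei, ej),
                      pair_type = g$edges$pair_type,
                      distance = g$edges$distance)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  out <- g
  out$nodes <- nodes
  out$X <- g$X[perm, , drop = FALSE]
  out$edges <- edges
  out
}
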