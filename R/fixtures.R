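## Synthetic-complex generator.
##
## Emits toy but well-formed complexes: an idealized helix-like protein
## chain (template residues on an alpha-helical CA trace with local offsets
## for N, C, O, CB and polar side-chain tips), a branched heteroatom ligand
## beside it, bridge waters planted within hydrogen-bond range (< 3.5 A) of
## both a protein polar atom and a ligand heavy atom, and decoy waters far
## (> 8 A) from the ligand. The affinity label follows a planted law
##   pKd = beta + alpha * n_bridge_waters + N(0, noise_sd),
## so water-aware models can outperform water-blind ones by construction.
## Geometry is idealized, not physical: parsers and featurizers only need
## well-formed records and credible distances.

#' Specification for one synthetic complex
#'
#' @param n_residues protein chain length (helix-like trace).
#' @param n_ligand_atoms ligand heavy atoms (branched chain of C/N/O).
#' @param n_bridge_waters waters bridging protein and ligand (< 3.5 A both).
#' @param n_decoy_waters waters > 8 A from the ligand (contact-filter bait).
#' @param noise_sd label noise standard deviation (pKd units).
#' @param seed RNG seed; all randomness in the complex flows from it.
#' @param alpha pKd gained per bridge water (planted signal strength).
#' @param beta baseline pKd.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 8L, n_ligand_atoms = 8L,
                         n_bridge_waters = 2L, n_decoy_waters = 3L,
                         noise_sd = 0.3, seed = 1L, alpha = 1, beta = 5) {
  if (n_residues < 2 || n_ligand_atoms < 1) stopf("fixture too small")
  if (n_bridge_waters < 0 || n_decoy_waters < 0 || noise_sd < 0)
    stopf("counts and noise_sd must be non-negative")
  structure(list(n_residues = as.integer(n_residues),
                 n_ligand_atoms = as.integer(n_ligand_atoms),
                 n_bridge_waters = as.integer(n_bridge_waters),
                 n_decoy_waters = as.integer(n_decoy_waters),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 alpha = alpha, beta = beta),
            class = "fixture_spec")
}

.fixture_residue_cycle <- c("SER", "ALA", "THR", "VAL", "GLY", "CYS")

.make_protein_atoms <- function(n_res) {
  tpl <- residue_templates()
  rows <- list(); serial <- 0L
  helix_r <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
  add_atom <- function(res, ridx, name, xyz) {
    serial <<- serial + 1L
    k <- which(tpl$residue == res & tpl$name == name)
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = tpl$element[k],
      x = xyz[1], y = xyz[2], z = xyz[3],
      residue_name = res, residue_index = ridx, chain = "A", role = "protein",
      explicit_valence = tpl$explicit_valence[k],
      heavy_neighbor_count = tpl$heavy_neighbor_count[k],
      attached_h_count = tpl$attached_h_count[k],
      is_aromatic = tpl$is_aromatic[k], is_in_ring = tpl$is_in_ring[k],
      is_c_alpha = name == "CA", stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res)) {
    res <- .fixture_residue_cycle[(i - 1L) %% length(.fixture_residue_cycle) + 1L]
    th <- turn * (i - 1L)
    u <- c(cos(th), sin(th), 0)                   # radial (outward) unit
    ca <- c(helix_r * cos(th), helix_r * sin(th), rise * (i - 1L))
    add_atom(res, i, "N", ca + 0.5 * u + c(0, 0, -1.3))
    add_atom(res, i, "CA", ca)
    add_atom(res, i, "C", ca + 0.5 * u + c(0, 0, 1.3))
    add_atom(res, i, "O", ca + 1.6 * u + c(0, 0, 1.5))
    if (res != "GLY") add_atom(res, i, "CB", ca + 1.5 * u)
    if (res == "SER") add_atom(res, i, "OG", ca + 2.9 * u)
    if (res == "THR") {
      add_atom(res, i, "OG1", ca + 2.9 * u)
      add_atom(res, i, "CG2", ca + 1.5 * u + c(0, 0, 1.4))
    }
    if (res == "VAL") {
      add_atom(res, i, "CG1", ca + 2.9 * u)
      add_atom(res, i, "CG2", ca + 1.5 * u + c(0, 0, 1.4))
    }
    if (res == "CYS") add_atom(res, i, "SG", ca + 3.0 * u)
  }
  do.call(rbind, rows)
}

.make_ligand <- function(n_atoms, center) {
  elems <- rep(c("C", "C", "N", "C", "O", "C"), length.out = n_atoms)
  xyz <- matrix(0, n_atoms, 3)
  bonds_i <- integer(0); bonds_j <- integer(0)
  chain_pos <- 0L
  last_chain <- 0L
  for (k in seq_len(n_atoms)) {
    if (k > 1 && k %% 4 == 0) {            # branch off the previous chain atom
      xyz[k, ] <- xyz[last_chain, ] + c(1.4, 0.6, 0)
      bonds_i <- c(bonds_i, last_chain); bonds_j <- c(bonds_j, k)
    } else {
      xyz[k, ] <- c(0.3 * (chain_pos %% 2), 0, 1.5 * chain_pos)
      if (last_chain > 0) { bonds_i <- c(bonds_i, last_chain); bonds_j <- c(bonds_j, k) }
      last_chain <- k
      chain_pos <- chain_pos + 1L
    }
  }
  xyz <- sweep(xyz, 2, colMeans(xyz))        # center the ligand
  xyz <- sweep(xyz, 2, center, "+")
  valence <- tabulate(c(bonds_i, bonds_j), nbins = n_atoms)
  atoms <- data.frame(
    serial = seq_len(n_atoms), name = paste0(elems, seq_len(n_atoms)),
    element = elems, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    residue_name = "LIG", residue_index = 1L, chain = "L", role = "ligand",
    explicit_valence = pmax(valence, 1L), heavy_neighbor_count = valence,
    attached_h_count = 0L, is_aromatic = FALSE, is_in_ring = FALSE,
    is_c_alpha = FALSE, stringsAsFactors = FALSE)
  bonds <- data.frame(i = bonds_i, j = bonds_j, order = 1)
  mol_structure(atoms, bonds, role = "ligand")
}

#' Generate one synthetic complex (optionally writing PDB/Mol2 files)
#'
#' @param spec a [fixture_spec()].
#' @param dir if non-NULL, `<id>_protein.pdb` (with HOH records for the true
#'   waters) and `<id>_ligand.mol2` are written there.
#' @param id complex identifier (default derived from the seed).
#' @return a [complex_structure()] whose waters carry: each bridge water as
#'   one "hydramap" and one "rism" site (two agreeing predictors, 0.15 A
#'   apart) and decoys alternating between the two provenances.
#' @export
make_complex <- function(spec = fixture_spec(), dir = NULL,
                         id = sprintf("syn%05d", spec$seed %% 100000L)) {
  set.seed(spec$seed)
  prot_atoms <- .make_protein_atoms(spec$n_residues)
  zmid <- mean(range(prot_atoms$z))
  ligand <- .make_ligand(spec$n_ligand_atoms, center = c(8.5, 0, zmid))
  # per-complex conformational jitter: no two complexes share a geometry
  jsd <- 0.15
  for (cc in c("x", "y", "z")) {
    prot_atoms[[cc]] <- prot_atoms[[cc]] + stats::rnorm(nrow(prot_atoms), 0, jsd)
    ligand$atoms[[cc]] <- ligand$atoms[[cc]] + stats::rnorm(nrow(ligand$atoms), 0, jsd)
  }
  protein <- mol_structure(prot_atoms, empty_bonds(), role = "protein")

  # bridge waters: midpoints of (protein polar atom, ligand heavy atom)
  # pairs at 3-6.4 A, jittered, kept < 3.5 A from both partners
  polar <- prot_atoms[prot_atoms$element %in% c("N", "O", "S"), , drop = FALSE]
  lxyz <- coords_of(ligand$atoms)
  pd <- cross_dist(coords_of(polar), lxyz)
  cand <- which(pd > 3 & pd < 6.4, arr.ind = TRUE)
  if (nrow(cand) < spec$n_bridge_waters)
    stopf("infeasible geometry: %d bridge waters requested but only %d protein-ligand pairs in range",
          spec$n_bridge_waters, nrow(cand))
  cand <- cand[order(pd[cand]), , drop = FALSE]
  bridges <- matrix(numeric(0), 0, 3)
  used <- 0L
  for (r in seq_len(nrow(cand))) {
    if (used == spec$n_bridge_waters) break
    p <- as.numeric(polar[cand[r, 1], c("x", "y", "z")])
    l <- lxyz[cand[r, 2], ]
    w <- (p + l) / 2 + stats::rnorm(3, 0, 0.05)
    if (sqrt(sum((w - p)^2)) >= 3.5 || sqrt(sum((w - l)^2)) >= 3.5) next
    if (nrow(bridges) && min(sqrt(colSums((t(bridges) - w)^2))) < 1.2) next
    bridges <- rbind(bridges, w)
    used <- used + 1L
  }
  if (used < spec$n_bridge_waters)
    stopf("infeasible geometry: could not place %d non-overlapping bridge waters",
          spec$n_bridge_waters)

  decoys <- matrix(numeric(0), 0, 3)
  if (spec$n_decoy_waters > 0) {
    zs <- stats::runif(spec$n_decoy_waters, min(prot_atoms$z), max(prot_atoms$z))
    decoys <- cbind(-10 + stats::rnorm(spec$n_decoy_waters, 0, 0.3),
                    stats::rnorm(spec$n_decoy_waters, 0, 0.8), zs)
  }
  true_waters <- rbind(bridges, decoys)

  # predicted-water stand-ins: both sources see every bridge; decoys alternate
  jit <- function(m, sd) m + matrix(stats::rnorm(length(m), 0, sd), nrow(m))
  hm <- bridges; rs <- if (nrow(bridges)) jit(bridges, 0.15 / sqrt(3)) else bridges
  if (nrow(decoys)) {
    odd <- seq_len(nrow(decoys)) %% 2L == 1L
    hm <- rbind(hm, decoys[odd, , drop = FALSE])
    rs <- rbind(rs, decoys[!odd, , drop = FALSE])
  }
  waters <- rbind(
    if (nrow(hm)) water_sites(hm, provenance = "hydramap") else empty_water_sites(),
    if (nrow(rs)) water_sites(rs, provenance = "rism") else empty_water_sites(),
    if (nrow(true_waters)) water_sites(true_waters, provenance = "experimental")
    else empty_water_sites()
  )
  label <- spec$beta + spec$alpha * spec$n_bridge_waters +
    stats::rnorm(1, 0, spec$noise_sd)
  cplx <- complex_structure(id, protein, ligand, waters,
                            affinity_label = label)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_pdb(protein, file.path(dir, paste0(id, "_protein.pdb")),
              waters = if (nrow(true_waters)) water_sites(true_waters) else NULL)
    write_mol2(ligand, file.path(dir, paste0(id, "_ligand.mol2")), name = id)
  }
  cplx
}

#' Generate a labelled synthetic dataset
#'
#' Bridge-water counts cycle over `bridge_range` (balanced, so the planted
#' signal is learnable); per-complex seeds derive from `seed`.
#'
#' @param n number of complexes.
#' @param seed master seed.
#' @param bridge_range integer vector of bridge-water counts to cycle.
#' @param dir if non-NULL, files plus a PDBbind-style `INDEX.txt` are written.
#' @param ... further [fixture_spec()] fields (alpha, beta, noise_sd, sizes).
#' @return list of [complex_structure()]s.
#' @export
make_dataset <- function(n, seed = 1L, bridge_range = 0:5, dir = NULL, ...) {
  if (n < 1) stopf("n must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  extra <- list(...)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    args <- c(list(n_bridge_waters = bridge_range[(i - 1L) %% length(bridge_range) + 1L],
                   seed = sub_seeds[i]), extra)
    spec <- do.call(fixture_spec, args)
    out[[i]] <- make_complex(spec, dir = dir, id = sprintf("syn%05d", i))
  }
  if (!is.null(dir)) {
    idx <- vapply(out, function(cp) sprintf("%s  2.00  2016  %.3f  //  synthetic",
                                            cp$id, cp$affinity_label), character(1))
    writeLines(c("# synthetic affinity index (PDBbind-style)",
                 "# id  resolution  year  pKd", idx),
               file.path(dir, "INDEX.txt"))
  }
  out
}

#' Write a synthetic solvent-density grid around planted sites
#'
#' Sum-of-Gaussians density on a uniform grid covering the sites plus a
#' margin; readable by [read_dx()] and consumable by [sites_from_density()].
#'
#' @param sites n x 3 matrix (or [water_sites()]) of planted peak centers.
#' @param spacing grid spacing (A).
#' @param peak_width Gaussian sigma (A).
#' @param margin box margin beyond the sites (A).
#' @param path optional DX output path.
#' @return a [pocket_grid()] (invisibly writes `path` when given).
#' @export
make_density_grid <- function(sites, spacing = 0.5, peak_width = 0.8,
                              margin = 3, path = NULL) {
  if (is.data.frame(sites)) sites <- as.matrix(sites[, c("x", "y", "z")])
  sites <- matrix(as.numeric(sites), ncol = 3)
  if (!nrow(sites)) stopf("need at least one site")
  lo <- apply(sites, 2, min) - margin
  hi <- apply(sites, 2, max) + margin
  dims <- as.integer(floor((hi - lo) / spacing)) + 1L
  grid <- pocket_grid(lo, spacing, dims, numeric(prod(dims)))
  pts <- grid_centers(grid)
  d <- cross_dist(pts, sites)
  grid$values <- rowSums(exp(-d^2 / (2 * peak_width^2)))
  if (!is.null(path)) write_dx(grid, path)
  grid
}

#' Write a ligand structure as a Mol2 file
#'
#' @param ligand a [mol_structure()] with bonds.
#' @param path output path.
#' @param name molecule name.
#' @export
write_mol2 <- function(ligand, path, name = "LIG") {
  a <- ligand$atoms; b <- ligand$bonds
  sybyl <- ifelse(a$is_aromatic, paste0(a$element, ".ar"),
                  ifelse(a$element %in% c("C", "N", "O"),
                         paste0(a$element, ".3"), a$element))
  lines <- c("@<TRIPOS>MOLECULE", name,
             sprintf("%d %d 1", nrow(a), nrow(b)),
             "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM",
             sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %3d %-8s %10.4f",
                     seq_len(nrow(a)), a$name, a$x, a$y, a$z, sybyl,
                     1L, "LIG1", 0),
             "@<TRIPOS>BOND")
  if (nrow(b)) {
    ostr <- ifelse(abs(b$order - 1.5) < 1e-9, "ar",
                   sprintf("%d", as.integer(round(b$order))))
    lines <- c(lines, sprintf("%6d %5d %5d %4s", seq_len(nrow(b)), b$i, b$j, ostr))
  }
  writeLines(lines, path)
  invisible(path)
}
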