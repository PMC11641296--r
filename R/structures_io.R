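## Structure containers and file I/O (PDB / Mol2 / SDF).
##
## Atoms live in a data.frame (one row per heavy atom) carrying coordinates
## plus the chemical context consumed by ECIF typing and node featurization.
## Structures are heavy-atom only; attached hydrogen counts are kept as a
## per-atom field (from residue templates for proteins, from the bond block
## for ligands).

.atom_columns <- c(
  "serial", "name", "element", "x", "y", "z", "residue_name",
  "residue_index", "chain", "role", "explicit_valence",
  "heavy_neighbor_count", "attached_h_count", "is_aromatic",
  "is_in_ring", "is_c_alpha"
)

#' Construct a molecular structure
#'
#' @param atoms data.frame of heavy atoms (see package docs for columns).
#' @param bonds data.frame with integer columns `i`, `j` (1-based atom row
#'   indices) and numeric `order` (aromatic = 1.5). May have zero rows.
#' @param role one of "protein", "ligand".
#' @return object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, bonds = empty_bonds(), role = "ligand") {
  stopifnot(is.data.frame(atoms))
  miss <- setdiff(.atom_columns, names(atoms))
  if (length(miss)) stopf("atoms missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(bonds)) {
    if (any(bonds$i == bonds$j)) stopf("self-bonds are not allowed")
    if (any(bonds$i < 1L | bonds$j < 1L | bonds$i > nrow(atoms) | bonds$j > nrow(atoms)))
      stopf("bond endpoints out of range")
  }
  if (!all(is.finite(coords_of(atoms)))) stopf("non-finite atom coordinates")
  structure(list(atoms = atoms, bonds = bonds, role = role),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("<mol_structure role=%s atoms=%d bonds=%d>\n",
              x$role, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' @rdname mol_structure
#' @export
empty_bonds <- function() {
  data.frame(i = integer(0), j = integer(0), order = numeric(0))
}

#' Construct a table of water sites
#'
#' @param coords n x 3 matrix of oxygen positions (Angstrom).
#' @param score optional per-site score (occupancy / probability mass).
#' @param provenance one of "hydramap", "rism", "experimental" (recycled).
#' @return data.frame with columns x, y, z, score, provenance.
#' @export
water_sites <- function(coords, score = NA_real_, provenance = "experimental") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) && !all(is.finite(coords))) stopf("non-finite water coordinates")
  prov <- rep_len(provenance, max(nrow(coords), 0L))
  ok <- prov %in% c("hydramap", "rism", "experimental")
  if (nrow(coords) && !all(ok)) stopf("unknown water provenance: %s", prov[!ok][1])
  data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
             score = rep_len(as.numeric(score), nrow(coords)),
             provenance = prov, stringsAsFactors = FALSE)
}

empty_water_sites <- function() water_sites(matrix(numeric(0), ncol = 3))

#' Construct a protein-ligand complex
#'
#' @param id complex identifier (e.g. a PDB code).
#' @param protein,ligand `mol_structure` objects.
#' @param waters data.frame from [water_sites()].
#' @param affinity_label measured affinity in pKd/pKi units, or NA.
#' @param pocket_cutoff pocket extraction radius used/intended (Angstrom).
#' @return object of class `complex_structure`.
#' @export
complex_structure <- function(id, protein, ligand, waters = empty_water_sites(),
                              affinity_label = NA_real_, pocket_cutoff = 10) {
  stopifnot(inherits(protein, "mol_structure"), inherits(ligand, "mol_structure"))
  if (nrow(ligand$atoms) < 1L) stopf("ligand must have at least one heavy atom")
  if (!is.na(affinity_label) && !is.finite(affinity_label))
    stopf("affinity_label must be finite when present")
  structure(list(id = id, protein = protein, ligand = ligand, waters = waters,
                 affinity_label = affinity_label, pocket_cutoff = pocket_cutoff),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure %s: %d protein / %d ligand atoms, %d waters, pKd=%s>\n",
              x$id, nrow(x$protein$atoms), nrow(x$ligand$atoms), nrow(x$waters),
              ifelse(is.na(x$affinity_label), "NA", format(x$affinity_label))))
  invisible(x)
}

.two_letter_elements <- c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN", "CA", "CU", "NI", "CO")

.element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  if (nchar(nm) >= 2 && substr(nm, 1, 2) %in% setdiff(.two_letter_elements, c("CA", "NA", "CO")))
    return(paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 2))))
  substr(nm, 1, 1)
}

.norm_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records; hydrogens are dropped (heavy-atom
#' representation; attached hydrogen counts come from residue templates).
#' Water records (HOH/WAT/DOD) become experimental water sites. Alternate
#' locations keep the highest-occupancy conformer (ties: first in file).
#'
#' @param path PDB file path.
#' @return list with elements `protein` (a [mol_structure()]) and `waters`
#'   (a [water_sites()] data.frame, provenance "experimental").
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) stopf("no ATOM/HETATM records in %s", path)
  ln <- lines[keep]
  num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!is.finite(v) & nzchar(trimws(s)))
    if (length(bad) || any(!nzchar(trimws(s))))
      stopf("malformed %s in %s at line %d", what, path,
            lineno[c(bad, which(!nzchar(trimws(s))))[1]])
    v
  }
  lineno <- keep
  serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
  name <- trimws(substr(ln, 13, 16))
  altloc <- substr(ln, 17, 17)
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  resseq <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  x <- num(substr(ln, 31, 38), "x coordinate", lineno)
  y <- num(substr(ln, 39, 46), "y coordinate", lineno)
  z <- num(substr(ln, 47, 54), "z coordinate", lineno)
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[!is.finite(occ)] <- 1
  el <- trimws(substr(ln, 77, 78))
  el <- ifelse(nzchar(el), .norm_element(el),
               vapply(name, .element_from_name, character(1)))

  is_h <- el %in% c("H", "D")
  df <- data.frame(serial = serial, name = name, altloc = altloc,
                   residue_name = resname, chain = chain, residue_index = resseq,
                   x = x, y = y, z = z, occ = occ, element = el,
                   stringsAsFactors = FALSE)[!is_h, , drop = FALSE]

  # alternate locations: per (residue, atom name), keep max occupancy
  if (any(df$altloc != " ")) {
    key <- paste(df$chain, df$residue_index, df$residue_name, df$name)
    ord <- order(key, -df$occ, seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(paste(df$chain, df$residue_index, df$residue_name, df$name)), , drop = FALSE]
    df <- df[order(match(df$serial, serial)), , drop = FALSE]
  }

  is_water <- df$residue_name %in% c("HOH", "WAT", "DOD")
  wat <- df[is_water & df$element == "O", , drop = FALSE]
  waters <- water_sites(as.matrix(wat[, c("x", "y", "z")]), score = NA_real_,
                        provenance = "experimental")
  prot <- df[!is_water, , drop = FALSE]
  if (!nrow(prot)) stopf("empty structure (no non-water atoms) in %s", path)

  tpl <- residue_templates()
  tkey <- paste(tpl$residue, tpl$name)
  idx <- match(paste(prot$residue_name, prot$name), tkey)
  if (anyNA(idx)) {
    unk <- unique(paste(prot$residue_name, prot$name)[is.na(idx)])
    warnf("no residue template for %d atom kind(s) (%s ...); using element defaults",
          length(unk), unk[1])
  }
  def_val <- c(C = 4, N = 3, O = 2, S = 2)
  atoms <- data.frame(
    serial = prot$serial, name = prot$name, element = prot$element,
    x = prot$x, y = prot$y, z = prot$z,
    residue_name = prot$residue_name, residue_index = prot$residue_index,
    chain = prot$chain, role = "protein",
    explicit_valence = ifelse(is.na(idx), unname(def_val[prot$element]),
                              tpl$explicit_valence[idx]),
    heavy_neighbor_count = ifelse(is.na(idx), 1L, tpl$heavy_neighbor_count[idx]),
    attached_h_count = ifelse(is.na(idx), 0L, tpl$attached_h_count[idx]),
    is_aromatic = ifelse(is.na(idx), FALSE, tpl$is_aromatic[idx]),
    is_in_ring = ifelse(is.na(idx), FALSE, tpl$is_in_ring[idx]),
    is_c_alpha = prot$name == "CA",
    stringsAsFactors = FALSE
  )
  atoms$explicit_valence[is.na(atoms$explicit_valence)] <- 4
  list(protein = mol_structure(atoms, empty_bonds(), role = "protein"),
       waters = waters)
}

#' Write a structure (and optional water sites) as a PDB file
#'
#' Protein/ligand atoms become ATOM/HETATM records; water sites are written
#' as HETATM oxygen records of residue HOH.
#'
#' @param structure a [mol_structure()] (or NULL for waters only).
#' @param path output path.
#' @param waters optional [water_sites()] data.frame.
#' @export
write_pdb <- function(structure, path, waters = NULL) {
  out <- character(0)
  serial <- 0L
  if (!is.null(structure)) {
    a <- structure$atoms
    rec <- if (structure$role == "protein") "ATOM  " else "HETATM"
    for (k in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$name[k]
      nmf <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else substr(nm, 1, 4)
      out <- c(out, sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                            rec, serial, nmf, " ", substr(a$residue_name[k], 1, 3),
                            a$chain[k], a$residue_index[k], " ",
                            a$x[k], a$y[k], a$z[k], 1, 0,
                            toupper(a$element[k])))
    }
    out <- c(out, "TER")
  }
  if (!is.null(waters) && nrow(waters)) {
    for (k in seq_len(nrow(waters))) {
      serial <- serial + 1L
      out <- c(out, sprintf("HETATM%5d  O   HOH W%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
                            serial, k, waters$x[k], waters$y[k], waters$z[k], 1, 0))
    }
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Elements accepted for ligand atoms
#'
#' Order fixes the ligand element one-hot block of the node feature vector.
#' @export
LIGAND_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")

.bond_order_num <- function(ord) {
  o <- suppressWarnings(as.numeric(ord))
  o[ord %in% c("ar", "AR", "Ar")] <- 1.5
  o[ord %in% c("am", "AM")] <- 1
  o[ord %in% c("du", "un", "nc")] <- 1
  o[!is.finite(o)] <- 1
  o
}

## derive per-atom context from a bond graph that still includes hydrogens
.perceive_from_bonds <- function(el, bonds_i, bonds_j, order_num, aromatic_flag) {
  n <- length(el)
  valence <- numeric(n); heavy <- integer(n); hcnt <- integer(n)
  arom <- logical(n)
  is_h <- el %in% c("H", "D")
  for (b in seq_along(bonds_i)) {
    i <- bonds_i[b]; j <- bonds_j[b]; o <- order_num[b]
    valence[i] <- valence[i] + o; valence[j] <- valence[j] + o
    if (is_h[j]) hcnt[i] <- hcnt[i] + 1L else heavy[i] <- heavy[i] + 1L
    if (is_h[i]) hcnt[j] <- hcnt[j] + 1L else heavy[j] <- heavy[j] + 1L
    if (aromatic_flag[b]) { arom[i] <- TRUE; arom[j] <- TRUE }
  }
  # ring membership: atoms inside a biconnected component spanning >= 3 vertices
  ring <- logical(n)
  hb <- !is_h[bonds_i] & !is_h[bonds_j]
  if (any(hb)) {
    g <- igraph::graph_from_edgelist(cbind(bonds_i[hb], bonds_j[hb]), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    bc <- igraph::biconnected_components(g)
    for (comp in bc$components) {
      v <- as.integer(comp)
      if (length(v) >= 3) ring[v] <- TRUE
    }
  }
  list(valence = round(valence), heavy = heavy, hcnt = hcnt,
       arom = arom, ring = ring)
}

.finish_ligand <- function(el, xyz, bonds_i, bonds_j, order_chr, arom_bond, path) {
  el <- .norm_element(el)
  ordn <- .bond_order_num(order_chr)
  ctx <- .perceive_from_bonds(el, bonds_i, bonds_j, ordn, arom_bond)
  is_h <- el %in% c("H", "D")
  keep <- which(!is_h)
  remap <- match(seq_along(el), keep)
  bk <- !is_h[bonds_i] & !is_h[bonds_j]
  bonds <- data.frame(i = remap[bonds_i[bk]], j = remap[bonds_j[bk]],
                      order = ordn[bk])
  n <- length(keep)
  bad <- setdiff(unique(el[keep]), LIGAND_ELEMENTS)
  if (length(bad))
    warnf("ligand element(s) outside the 9-element vocabulary kept as-is: %s",
          paste(bad, collapse = ", "))
  atoms <- data.frame(
    serial = seq_len(n), name = paste0(el[keep], seq_len(n)), element = el[keep],
    x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
    residue_name = "LIG", residue_index = 1L, chain = "L", role = "ligand",
    explicit_valence = ctx$valence[keep],
    heavy_neighbor_count = ctx$heavy[keep],
    attached_h_count = ctx$hcnt[keep],
    is_aromatic = ctx$arom[keep], is_in_ring = ctx$ring[keep],
    is_c_alpha = FALSE, stringsAsFactors = FALSE
  )
  mol_structure(atoms, bonds, role = "ligand")
}

#' Read a ligand structure (Mol2 or SDF)
#'
#' Requires an explicit bond block (no distance-based bond perception).
#' Per-atom explicit valence, heavy-neighbour count, attached hydrogens,
#' aromaticity (from bond orders / SYBYL types) and ring membership (from
#' biconnected components of the bond graph) are computed before hydrogens
#' are dropped.
#'
#' @param path file path.
#' @param format "mol2" or "sdf"; default guessed from the extension.
#' @return a [mol_structure()] with role "ligand".
#' @export
read_ligand <- function(path, format = c("auto", "mol2", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE)) "sdf" else "mol2"
  }
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "mol2") .read_mol2(path) else .read_sdf(path)
}

.read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- grep("^@<TRIPOS>", lines)
  names(sec) <- sub("^@<TRIPOS>", "", lines[sec])
  grab <- function(what) {
    i <- sec[names(sec) == what]
    if (!length(i)) return(character(0))
    i <- i[1]
    nxt <- sec[sec > i]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    v <- lines[(i + 1L):end]
    v[nzchar(trimws(v))]
  }
  at <- grab("ATOM")
  bd <- grab("BOND")
  if (!length(at)) stopf("mol2 file %s has no ATOM section", path)
  if (!length(bd)) stopf("mol2 file %s has no BOND section (bond perception is out of scope)", path)
  parse_row <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]
  arows <- lapply(at, parse_row)
  sybyl <- vapply(arows, function(r) r[6], character(1))
  el <- sub("\\..*$", "", sybyl)
  xyz <- t(vapply(arows, function(r) as.numeric(r[3:5]), numeric(3)))
  if (!all(is.finite(xyz))) stopf("malformed ATOM coordinates in %s", path)
  brows <- lapply(bd, parse_row)
  bi <- vapply(brows, function(r) as.integer(r[2]), integer(1))
  bj <- vapply(brows, function(r) as.integer(r[3]), integer(1))
  bo <- vapply(brows, function(r) r[4], character(1))
  arom_bond <- bo %in% c("ar", "AR", "Ar")
  lig <- .finish_ligand(el, xyz, bi, bj, bo, arom_bond, path)
  # SYBYL .ar types mark aromatic atoms even if their H-bond rows don't
  ar_typed <- grepl("\\.ar$", sybyl, ignore.case = TRUE)
  is_h <- .norm_element(el) %in% c("H", "D")
  lig$atoms$is_aromatic <- lig$atoms$is_aromatic | ar_typed[!is_h]
  lig
}

.read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stopf("truncated SDF file: %s", path)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || na < 1) stopf("malformed counts line in %s", path)
  if (is.na(nb) || nb < 1) stopf("SDF file %s has no bond block (bond perception is out of scope)", path)
  ablk <- lines[5:(4 + na)]
  bblk <- lines[(5 + na):(4 + na + nb)]
  xyz <- t(vapply(ablk, function(s) as.numeric(c(substr(s, 1, 10), substr(s, 11, 20), substr(s, 21, 30))), numeric(3)))
  dimnames(xyz) <- NULL
  el <- trimws(substr(ablk, 32, 34))
  bi <- as.integer(substr(bblk, 1, 3)); bj <- as.integer(substr(bblk, 4, 6))
  bo <- trimws(substr(bblk, 7, 9))
  arom_bond <- bo == "4"
  bo[bo == "4"] <- "ar"
  .finish_ligand(el, xyz, bi, bj, bo, arom_bond, path)
}

#' Extract the binding pocket of a complex
#'
#' Keeps protein residues having at least one heavy atom within `cutoff`
#' of any ligand heavy atom (whole residues by default), and water sites
#' within `cutoff` of the ligand or of a retained protein atom.
#'
#' @param cplx a [complex_structure()].
#' @param cutoff pocket radius in Angstrom (default 10; must exceed the
#'   graph edge cutoff so edges are not clipped at the pocket boundary).
#' @param residue_mode "residue" (whole-residue retention, default) or
#'   "atom" (bare atoms within the cutoff).
#' @return a [complex_structure()] restricted to the pocket. Idempotent.
#' @export
extract_pocket <- function(cplx, cutoff = 10, residue_mode = c("residue", "atom")) {
  residue_mode <- match.arg(residue_mode)
  if (cutoff <= 0) stopf("cutoff must be > 0")
  pa <- cplx$protein$atoms
  la <- coords_of(cplx$ligand$atoms)
  if (!nrow(pa)) stopf("complex has no protein atoms")
  dmin <- apply(cross_dist(coords_of(pa), la), 1, min)
  if (residue_mode == "residue") {
    rid <- paste(pa$chain, pa$residue_index)
    keep_res <- unique(rid[dmin < cutoff])
    keep <- rid %in% keep_res
  } else {
    keep <- dmin < cutoff
  }
  if (!any(keep))
    stopf("empty pocket at cutoff %.1f A; try a larger cutoff", cutoff)
  patoms <- pa[keep, , drop = FALSE]
  rownames(patoms) <- NULL
  wat <- cplx$waters
  if (nrow(wat)) {
    wxyz <- as.matrix(wat[, c("x", "y", "z")])
    dl <- apply(cross_dist(wxyz, la), 1, min)
    dp <- apply(cross_dist(wxyz, coords_of(patoms)), 1, min)
    wat <- wat[pmin(dl, dp) < cutoff, , drop = FALSE]
    rownames(wat) <- NULL
  }
  complex_structure(cplx$id,
                    mol_structure(patoms, empty_bonds(), role = "protein"),
                    cplx$ligand, wat, cplx$affinity_label, pocket_cutoff = cutoff)
}
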