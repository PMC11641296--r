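## Node and edge featurization.
##
## Node features are a fixed 58-slot vector:
##   [1:20]  residue type one-hot (protein atoms only)
##   [21:42] protein ECIF atom-type one-hot (22 types, protein atoms only)
##   [43:51] ligand element one-hot {C,N,O,S,F,Cl,Br,I,P} (ligand and water;
##           water sets the O channel)
##   [52]    distance from the atom to the pocket centroid (A) - the single
##           "coordinates" slot, made rigid-motion invariant
##   [53]    implicit valence (attached/implicit hydrogen count)
##   [54:55] aromatic one-hot (yes, no)
##   [56:57] ring one-hot (yes, no)
##   [58]    number of attached hydrogens

#' The 22-type ECIF protein atom vocabulary
#'
#' Fixed-order strings "Element,ExplicitValence,HeavyNeighbors,AttachedH,
#' Aromatic,Ring". Order fixes the one-hot block of the node features.
#' @export
ECIF_PROTEIN_TYPES <- c(
  "C,4,2,2,0,0", "N,4,1,2,0,0", "S,2,2,0,0,0", "C,4,3,0,1,1",
  "N,3,1,2,0,0", "C,4,3,0,0,0", "C,4,1,3,0,0", "N,3,2,1,1,1",
  "S,2,1,1,0,0", "C,4,3,1,0,1", "N,3,2,0,1,1", "C,4,3,1,0,0",
  "O,2,1,1,0,0", "N,4,2,1,0,0", "N,3,2,1,0,0", "N,4,1,3,0,0",
  "C,6,3,0,0,0", "C,4,2,2,0,1", "C,4,2,1,1,1", "O,2,1,0,0,0",
  "N,3,3,0,0,1", "C,5,3,0,0,0"
)

#' Total node feature dimensionality
#' @export
NODE_FEATURE_DIM <- 58L

#' Human-readable labels for the 58 node feature slots
#' @return character vector of length 58.
#' @export
node_feature_schema <- function() {
  c(paste0("residue_", RESIDUE_TYPES),
    paste0("ecif_", ECIF_PROTEIN_TYPES),
    paste0("elem_", LIGAND_ELEMENTS),
    "dist_to_pocket_center",
    "implicit_valence",
    "aromatic_yes", "aromatic_no",
    "ring_yes", "ring_no",
    "n_hydrogens")
}

#' ECIF atom type of a protein atom
#'
#' Assembles "Element,ExplicitValence,HeavyNeighbors,AttachedH,Aromatic,Ring"
#' from the atom's chemical-context fields. Strings outside the fixed
#' 22-type vocabulary are mapped (with a warning) to the nearest same-element
#' type by context distance; if no same-element type exists, an error.
#'
#' @param atom one-row data.frame (a row of `mol_structure$atoms`).
#' @return a type string present in [ECIF_PROTEIN_TYPES].
#' @export
ecif_type <- function(atom) {
  if (atom$role != "protein") stopf("ecif_type applies to protein atoms")
  s <- sprintf("%s,%d,%d,%d,%d,%d", atom$element,
               as.integer(atom$explicit_valence),
               as.integer(atom$heavy_neighbor_count),
               as.integer(atom$attached_h_count),
               as.integer(atom$is_aromatic), as.integer(atom$is_in_ring))
  if (s %in% ECIF_PROTEIN_TYPES) return(s)
  cand <- ECIF_PROTEIN_TYPES[startsWith(ECIF_PROTEIN_TYPES, paste0(atom$element, ","))]
  if (!length(cand))
    stopf("atom type %s has no same-element fallback in the 22-type vocabulary", s)
  parse6 <- function(v) as.numeric(strsplit(sub("^[A-Za-z]+,", "", v), ",")[[1]])
  target <- parse6(s)
  dd <- vapply(cand, function(v) sum(abs(parse6(v) - target)), numeric(1))
  pick <- cand[which.min(dd)]
  warnf("atom type %s not in the 22-type vocabulary; falling back to %s", s, pick)
  pick
}

#' Centroid of a pocket (protein pocket + ligand heavy atoms)
#' @param cplx a (pocket-extracted) [complex_structure()].
#' @return 3-vector.
#' @export
pocket_center <- function(cplx) {
  xyz <- rbind(coords_of(cplx$protein$atoms), coords_of(cplx$ligand$atoms))
  colMeans(xyz)
}

.onehot <- function(n, i) { v <- numeric(n); if (!is.na(i) && i >= 1) v[i] <- 1; v }

#' Encode one atom as a 58-dimensional node feature vector
#'
#' Protein atoms fill the residue and ECIF blocks; ligand atoms fill the
#' element block; water oxygens use the element block's O channel with fixed
#' chemistry (valence 2, two hydrogens, non-aromatic, non-ring). The single
#' "coordinates" slot holds the distance to `center` (pocket centroid).
#'
#' @param atom one-row data.frame; for waters pass role "water", element "O".
#' @param center 3-vector from [pocket_center()].
#' @return numeric vector of length 58.
#' @export
encode_node <- function(atom, center) {
  stopifnot(atom$role %in% c("protein", "ligand", "water"))
  res <- numeric(20); ecif <- numeric(22); elem <- numeric(9)
  if (atom$role == "protein") {
    ri <- match(atom$residue_name, RESIDUE_TYPES)
    res <- .onehot(20, ri)
    ecif <- .onehot(22, match(ecif_type(atom), ECIF_PROTEIN_TYPES))
  } else if (atom$role == "ligand") {
    ei <- match(atom$element, LIGAND_ELEMENTS)
    if (is.na(ei)) warnf("ligand element %s outside the 9-element vocabulary; element block left zero",
                         atom$element)
    elem <- .onehot(9, ei)
  } else { # water
    elem <- .onehot(9, match("O", LIGAND_ELEMENTS))
  }
  if (atom$role == "water") {
    arom <- FALSE; ring <- FALSE; h <- 2; iv <- 2
  } else {
    arom <- isTRUE(atom$is_aromatic); ring <- isTRUE(atom$is_in_ring)
    h <- as.numeric(atom$attached_h_count); iv <- as.numeric(atom$attached_h_count)
  }
  dcen <- sqrt(sum((c(atom$x, atom$y, atom$z) - center)^2))
  v <- c(res, ecif, elem, dcen, iv,
         if (arom) c(1, 0) else c(0, 1),
         if (ring) c(1, 0) else c(0, 1),
         h)
  stopifnot(length(v) == NODE_FEATURE_DIM)
  v
}

#' Pair types for graph edges
#' @export
PAIR_TYPES <- c("LL", "PL", "PP", "WL", "WP", "WW")

.pair_type <- function(role_a, role_b) {
  key <- paste(sort(c(role_a, role_b)), collapse = "-")
  switch(key,
         "ligand-ligand" = "LL",
         "ligand-protein" = "PL",
         "protein-protein" = "PP",
         "ligand-water" = "WL",
         "protein-water" = "WP",
         "water-water" = "WW",
         stopf("unknown role pair %s", key))
}

#' Encode an atom pair as an edge feature
#'
#' @param a,b one-row atom data.frames (roles protein/ligand/water).
#' @return list(distance = Euclidean distance in A, pair_type = one of
#'   "LL","PL","PP","WL","WP","WW"). Symmetric in its arguments.
#' @export
encode_edge <- function(a, b) {
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  if (identical(c(a$x, a$y, a$z), c(b$x, b$y, b$z)) &&
      identical(a$role, b$role) && d == 0)
    stopf("cannot encode an edge between identical atoms")
  list(distance = d, pair_type = .pair_type(a$role, b$role))
}
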