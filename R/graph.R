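## Complex-graph assembly.
##
## Three graph variants share one node scheme (all pocket protein atoms +
## ligand heavy atoms [+ water oxygens]) and one edge rule set:
##   LL  ligand-ligand       heavy atoms     < 6 A, or covalently bonded
##   PL  protein-ligand      Calpha <-> heavy  < 6 A
##   PP  protein-protein     Calpha <-> Calpha < 6 A, plus backbone edges
##                           between consecutive residues and residue-
##                           internal atom->own-Calpha edges
##   WL  water-ligand        O <-> heavy     < T
##   WP  water-protein       O <-> Calpha    < T
##   WW  water-water         O <-> O         < T
## G_A has no waters; G_B/G_C carry waters from one provenance each.
## Comparisons are strict (<). Isolated waters are removed.

#' Build a complex graph (G_A, G_B or G_C)
#'
#' @param cplx a pocket-extracted [complex_structure()].
#' @param variant "G_A" (no waters), "G_B" or "G_C".
#' @param water_provenance which water source feeds G_B/G_C ("hydramap",
#'   "rism", "experimental"); ignored for G_A.
#' @param T water edge distance threshold (A), default 6.
#' @param base_cutoff protein/ligand edge cutoff (A), fixed default 6.
#' @param protein_level "calpha" (inter-molecular edges attach at Calpha,
#'   default) or "heavy" (all protein heavy atoms form distance edges).
#' @return object of class `complex_graph` with fields `nodes` (atom table
#'   with role tags), `X` (n x 58 feature matrix), `edges`
#'   (i, j, distance, pair_type; undirected, i < j), `variant`,
#'   `water_threshold_T`, `base_cutoff`.
#' @export
build_graph <- function(cplx, variant = c("G_B", "G_C", "G_A"),
                        water_provenance = NULL, T = 6, base_cutoff = 6,
                        protein_level = c("calpha", "heavy")) {
  variant <- match.arg(variant)
  protein_level <- match.arg(protein_level)
  if (T <= 0) stopf("edge threshold T must be > 0")
  pa <- cplx$protein$atoms
  la <- cplx$ligand$atoms
  if (variant == "G_A") {
    if (!is.null(water_provenance) || nrow(cplx$waters))
      if (nrow(cplx$waters)) warnf("variant G_A ignores supplied waters")
    waters <- empty_water_sites()
  } else {
    prov <- water_provenance %||%
      switch(variant, G_B = "hydramap", G_C = "rism")
    waters <- cplx$waters[cplx$waters$provenance == prov, , drop = FALSE]
    if (!nrow(waters))
      warnf("no %s waters for %s: graph degenerates to the protein-ligand topology",
            prov, variant)
  }
  np <- nrow(pa); nl <- nrow(la); nw <- nrow(waters)

  wat_atoms <- if (nw) data.frame(
    serial = seq_len(nw), name = "O", element = "O",
    x = waters$x, y = waters$y, z = waters$z,
    residue_name = "HOH", residue_index = seq_len(nw), chain = "W",
    role = "water", explicit_valence = 2L, heavy_neighbor_count = 0L,
    attached_h_count = 2L, is_aromatic = FALSE, is_in_ring = FALSE,
    is_c_alpha = FALSE, stringsAsFactors = FALSE
  ) else NULL
  nodes <- rbind(pa, la, wat_atoms)
  rownames(nodes) <- NULL
  pidx <- seq_len(np); lidx <- np + seq_len(nl); widx <- np + nl + seq_len(nw)

  xyz <- coords_of(nodes)
  ei <- integer(0); ej <- integer(0); ety <- character(0)
  add_pairs <- function(ii, jj, type) {
    if (!length(ii)) return()
    ei <<- c(ei, ii); ej <<- c(ej, jj); ety <<- c(ety, rep(type, length(ii)))
  }
  # LL: distance rule
  if (nl > 1) {
    dll <- cross_dist(xyz[lidx, , drop = FALSE], xyz[lidx, , drop = FALSE])
    hit <- which(upper.tri(dll) & dll < base_cutoff, arr.ind = TRUE)
    add_pairs(lidx[hit[, 1]], lidx[hit[, 2]], "LL")
  }
  # LL: covalent bonds always kept
  if (nrow(cplx$ligand$bonds)) {
    b <- cplx$ligand$bonds
    lo <- pmin(b$i, b$j); hi <- pmax(b$i, b$j)
    add_pairs(lidx[lo], lidx[hi], "LL")
  }
  prot_nodes <- if (protein_level == "calpha") pidx[nodes$is_c_alpha[pidx]] else pidx
  # PL
  if (length(prot_nodes) && nl) {
    dpl <- cross_dist(xyz[prot_nodes, , drop = FALSE], xyz[lidx, , drop = FALSE])
    hit <- which(dpl < base_cutoff, arr.ind = TRUE)
    add_pairs(prot_nodes[hit[, 1]], lidx[hit[, 2]], "PL")
  }
  # PP distance rule
  if (length(prot_nodes) > 1) {
    dpp <- cross_dist(xyz[prot_nodes, , drop = FALSE], xyz[prot_nodes, , drop = FALSE])
    hit <- which(upper.tri(dpp) & dpp < base_cutoff, arr.ind = TRUE)
    add_pairs(prot_nodes[hit[, 1]], prot_nodes[hit[, 2]], "PP")
  }
  # PP backbone: consecutive-residue Calpha pairs (any distance)
  ca <- pidx[nodes$is_c_alpha[pidx]]
  if (length(ca) > 1) {
    for (a in seq_along(ca)) for (b in seq_along(ca)) {
      if (b <= a) next
      if (nodes$chain[ca[a]] == nodes$chain[ca[b]] &&
          abs(nodes$residue_index[ca[a]] - nodes$residue_index[ca[b]]) == 1L)
        add_pairs(ca[a], ca[b], "PP")
    }
  }
  # PP residue-internal: every non-Calpha protein atom to its residue's Calpha
  if (np) {
    rid <- paste(nodes$chain[pidx], nodes$residue_index[pidx])
    ca_of <- ca[match(rid, paste(nodes$chain[ca], nodes$residue_index[ca]))]
    noca <- which(!nodes$is_c_alpha[pidx] & !is.na(ca_of))
    if (length(noca)) add_pairs(pmin(pidx[noca], ca_of[noca]),
                                pmax(pidx[noca], ca_of[noca]), "PP")
  }
  if (nw) {
    # WL
    dwl <- cross_dist(xyz[widx, , drop = FALSE], xyz[lidx, , drop = FALSE])
    hit <- which(dwl < T, arr.ind = TRUE)
    add_pairs(lidx[hit[, 2]], widx[hit[, 1]], "WL")
    # WP (protein side at the configured level)
    if (length(prot_nodes)) {
      dwp <- cross_dist(xyz[widx, , drop = FALSE], xyz[prot_nodes, , drop = FALSE])
      hit <- which(dwp < T, arr.ind = TRUE)
      add_pairs(prot_nodes[hit[, 2]], widx[hit[, 1]], "WP")
    }
    # WW
    if (nw > 1) {
      dww <- cross_dist(xyz[widx, , drop = FALSE], xyz[widx, , drop = FALSE])
      hit <- which(upper.tri(dww) & dww < T, arr.ind = TRUE)
      add_pairs(widx[hit[, 1]], widx[hit[, 2]], "WW")
    }
  }
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  edges <- data.frame(i = lo, j = hi, pair_type = ety, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$i, edges$j)), , drop = FALSE]
  # drop isolated waters and remap indices
  if (nw) {
    touched <- unique(c(edges$i, edges$j))
    iso <- setdiff(widx, touched)
    if (length(iso)) {
      keep <- setdiff(seq_len(nrow(nodes)), iso)
      remap <- match(seq_len(nrow(nodes)), keep)
      nodes <- nodes[keep, , drop = FALSE]; rownames(nodes) <- NULL
      edges$i <- remap[edges$i]; edges$j <- remap[edges$j]
      xyz <- coords_of(nodes)
    }
  }
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  edges$distance <- sqrt(rowSums((xyz[edges$i, , drop = FALSE] -
                                  xyz[edges$j, , drop = FALSE])^2))
  ctr <- pocket_center(cplx)
  X <- t(vapply(seq_len(nrow(nodes)),
                function(k) encode_node(nodes[k, , drop = FALSE], ctr),
                numeric(NODE_FEATURE_DIM)))
  structure(list(nodes = nodes, X = X, edges = edges, variant = variant,
                 water_threshold_T = T, base_cutoff = base_cutoff,
                 protein_level = protein_level),
            class = "complex_graph")
}

#' @export
print.complex_graph <- function(x, ...) {
  cat(sprintf("<complex_graph %s: %d nodes, %d edges, T=%g A>\n",
              x$variant, nrow(x$nodes), nrow(x$edges), x$water_threshold_T))
  invisible(x)
}

#' Summarize a complex graph
#'
#' @param g a [build_graph()] result.
#' @return list with `n_nodes`, node counts by role, `n_edges`, edge counts
#'   by pair type, and a degree histogram (table).
#' @export
graph_stats <- function(g) {
  role_counts <- table(factor(g$nodes$role, levels = c("protein", "ligand", "water")))
  type_counts <- table(factor(g$edges$pair_type, levels = PAIR_TYPES))
  deg <- tabulate(c(g$edges$i, g$edges$j), nbins = nrow(g$nodes))
  list(n_nodes = nrow(g$nodes), nodes_by_role = role_counts,
       n_edges = nrow(g$edges), edges_by_type = type_counts,
       degree = deg, degree_hist = table(deg))
}

#' Serialize a complex graph as JSON lines
#'
#' Line 1: header (variant, thresholds, node/edge counts); then one line per
#' node (role, coords, 58 features) and one per edge (i, j, distance,
#' pair_type). Deterministic: equal graphs produce byte-identical files.
#'
#' @param g a [build_graph()] result.
#' @param path output path.
#' @export
write_graph_jsonl <- function(g, path) {
  hdr <- jsonlite::toJSON(list(kind = "complex_graph", variant = g$variant,
                               T = g$water_threshold_T, base_cutoff = g$base_cutoff,
                               n_nodes = nrow(g$nodes), n_edges = nrow(g$edges)),
                          auto_unbox = TRUE, digits = NA)
  nl <- vapply(seq_len(nrow(g$nodes)), function(k) {
    jsonlite::toJSON(list(role = g$nodes$role[k],
                          xyz = c(g$nodes$x[k], g$nodes$y[k], g$nodes$z[k]),
                          features = as.numeric(g$X[k, ])),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  el <- vapply(seq_len(nrow(g$edges)), function(k) {
    jsonlite::toJSON(list(i = g$edges$i[k], j = g$edges$j[k],
                          distance = g$edges$distance[k],
                          pair_type = g$edges$pair_type[k]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(c(hdr, nl, el), path)
  invisible(path)
}
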