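## Fixed chemical-context templates for protein heavy atoms.
##
## PDB files carry no bonds, so per-atom context (explicit valence, heavy
## neighbour count, attached hydrogens, aromaticity, ring membership) for
## protein atoms comes from this table rather than on-the-fly perception.
## Counts assume a mid-chain residue at physiological protonation
## (carboxylates deprotonated, LYS/ARG protonated, HIS singly protonated
## on NE2). Every row's ECIF string falls inside the fixed 22-type
## protein vocabulary.

#' The 20 standard amino-acid residue codes
#'
#' Order fixes the residue one-hot block of the node feature vector.
#' @export
RESIDUE_TYPES <- c(
  "VAL", "ILE", "LEU", "GLU", "GLN", "ASP", "ASN", "HIS", "TRP", "PHE",
  "TYR", "ARG", "LYS", "SER", "THR", "MET", "ALA", "GLY", "PRO", "CYS"
)

# one row: name element valence heavyn h arom ring
.tpl_row <- function(res, name, el, v, hn, h, ar, rg) {
  data.frame(residue = res, name = name, element = el,
             explicit_valence = v, heavy_neighbor_count = hn,
             attached_h_count = h, is_aromatic = ar == 1L,
             is_in_ring = rg == 1L, stringsAsFactors = FALSE)
}

.build_residue_templates <- function() {
  rows <- list()
  add <- function(res, name, el, v, hn, h, ar = 0L, rg = 0L) {
    rows[[length(rows) + 1L]] <<- .tpl_row(res, name, el, v, hn, h, ar, rg)
  }
  for (res in RESIDUE_TYPES) {
    # backbone; GLY and PRO deviate at CA / N
    if (res == "PRO") add(res, "N", "N", 3L, 3L, 0L, 0L, 1L)
    else add(res, "N", "N", 3L, 2L, 1L)
    if (res == "GLY") add(res, "CA", "C", 4L, 2L, 2L)
    else if (res == "PRO") add(res, "CA", "C", 4L, 3L, 1L, 0L, 1L)
    else add(res, "CA", "C", 4L, 3L, 1L)
    add(res, "C", "C", 4L, 3L, 0L)
    add(res, "O", "O", 2L, 1L, 0L)
    switch(res,
      ALA = {
        add(res, "CB", "C", 4L, 1L, 3L)
      },
      VAL = {
        add(res, "CB", "C", 4L, 3L, 1L)
        add(res, "CG1", "C", 4L, 1L, 3L); add(res, "CG2", "C", 4L, 1L, 3L)
      },
      LEU = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "CG", "C", 4L, 3L, 1L)
        add(res, "CD1", "C", 4L, 1L, 3L); add(res, "CD2", "C", 4L, 1L, 3L)
      },
      ILE = {
        add(res, "CB", "C", 4L, 3L, 1L); add(res, "CG1", "C", 4L, 2L, 2L)
        add(res, "CG2", "C", 4L, 1L, 3L); add(res, "CD1", "C", 4L, 1L, 3L)
      },
      MET = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "CG", "C", 4L, 2L, 2L)
        add(res, "SD", "S", 2L, 2L, 0L); add(res, "CE", "C", 4L, 1L, 3L)
      },
      PHE = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "CG", "C", 4L, 3L, 0L, 1L, 1L)
        for (nm in c("CD1", "CD2", "CE1", "CE2", "CZ"))
          add(res, nm, "C", 4L, 2L, 1L, 1L, 1L)
      },
      TYR = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "CG", "C", 4L, 3L, 0L, 1L, 1L)
        for (nm in c("CD1", "CD2", "CE1", "CE2"))
          add(res, nm, "C", 4L, 2L, 1L, 1L, 1L)
        add(res, "CZ", "C", 4L, 3L, 0L, 1L, 1L)
        add(res, "OH", "O", 2L, 1L, 1L)
      },
      TRP = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "CG", "C", 4L, 3L, 0L, 1L, 1L)
        add(res, "CD1", "C", 4L, 2L, 1L, 1L, 1L)
        add(res, "CD2", "C", 4L, 3L, 0L, 1L, 1L)
        add(res, "NE1", "N", 3L, 2L, 1L, 1L, 1L)
        add(res, "CE2", "C", 4L, 3L, 0L, 1L, 1L)
        for (nm in c("CE3", "CZ2", "CZ3", "CH2"))
          add(res, nm, "C", 4L, 2L, 1L, 1L, 1L)
      },
      SER = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "OG", "O", 2L, 1L, 1L)
      },
      THR = {
        add(res, "CB", "C", 4L, 3L, 1L); add(res, "OG1", "O", 2L, 1L, 1L)
        add(res, "CG2", "C", 4L, 1L, 3L)
      },
      CYS = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "SG", "S", 2L, 1L, 1L)
      },
      ASN = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "CG", "C", 4L, 3L, 0L)
        add(res, "OD1", "O", 2L, 1L, 0L); add(res, "ND2", "N", 3L, 1L, 2L)
      },
      GLN = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "CG", "C", 4L, 2L, 2L)
        add(res, "CD", "C", 4L, 3L, 0L)
        add(res, "OE1", "O", 2L, 1L, 0L); add(res, "NE2", "N", 3L, 1L, 2L)
      },
      ASP = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "CG", "C", 4L, 3L, 0L)
        add(res, "OD1", "O", 2L, 1L, 0L); add(res, "OD2", "O", 2L, 1L, 0L)
      },
      GLU = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "CG", "C", 4L, 2L, 2L)
        add(res, "CD", "C", 4L, 3L, 0L)
        add(res, "OE1", "O", 2L, 1L, 0L); add(res, "OE2", "O", 2L, 1L, 0L)
      },
      LYS = {
        for (nm in c("CB", "CG", "CD", "CE")) add(res, nm, "C", 4L, 2L, 2L)
        add(res, "NZ", "N", 4L, 1L, 3L)
      },
      ARG = {
        for (nm in c("CB", "CG", "CD")) add(res, nm, "C", 4L, 2L, 2L)
        add(res, "NE", "N", 3L, 2L, 1L); add(res, "CZ", "C", 4L, 3L, 0L)
        add(res, "NH1", "N", 3L, 1L, 2L); add(res, "NH2", "N", 3L, 1L, 2L)
      },
      HIS = {
        add(res, "CB", "C", 4L, 2L, 2L); add(res, "CG", "C", 4L, 3L, 0L, 1L, 1L)
        add(res, "ND1", "N", 3L, 2L, 0L, 1L, 1L)
        add(res, "CD2", "C", 4L, 2L, 1L, 1L, 1L)
        add(res, "CE1", "C", 4L, 2L, 1L, 1L, 1L)
        add(res, "NE2", "N", 3L, 2L, 1L, 1L, 1L)
      },
      PRO = {
        for (nm in c("CB", "CG", "CD")) add(res, nm, "C", 4L, 2L, 2L, 0L, 1L)
      },
      GLY = {}
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residue heavy-atom chemical-context template table
#'
#' One row per heavy atom of each of the 20 standard residues, giving the
#' element, explicit valence, heavy-neighbour count, attached-hydrogen count,
#' aromaticity and ring membership used to type protein atoms
#' deterministically (PDB files carry no bonds).
#'
#' @return data.frame with columns residue, name, element, explicit_valence,
#'   heavy_neighbor_count, attached_h_count, is_aromatic, is_in_ring.
#' @export
residue_templates <- function() {
  .hydrographer_env$templates
}

.hydrographer_env <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .hydrographer_env$templates <- .build_residue_templates()
}
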