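## Hydration-site pipelines.
##
## Two complementary routes produce water-site networks for a complex:
##   (a) a knowledge-based route: rectangular box around the ligand ->
##       probe grid -> probability scoring -> flat-kernel mean-shift
##       clustering of high-scoring voxels (HydraMap-style);
##   (b) a solvent-density route: local maxima of a 3D density grid
##       (3D-RISM-style output, parsed from OpenDX text).
## Experimental waters from the PDB are a third source. Sites are filtered
## to protein/ligand contact range before graph building.

#' Hydration pipeline parameters
#'
#' Defaults follow the published parameterization of the grid pipeline:
#' box margin D = 4.0 A, favourable-score cutoff 5.0, cluster radius
#' (mean-shift bandwidth) 2.0 A, minimum cluster size N = 1 voxel,
#' water-to-solute contact distance 4.0 A. Grid spacing is not published;
#' default 1.0 A.
#'
#' @param box_margin_D box expansion beyond the ligand bounding box (A).
#' @param pmf_cutoff minimum voxel score to enter clustering.
#' @param cluster_radius mean-shift bandwidth and mode-merge radius (A).
#' @param min_grids_N minimum voxels per cluster for a valid site.
#' @param contact_distance max water-to-protein/ligand distance kept (A).
#' @param spacing grid spacing (A), in (0, 2].
#' @return list of class `hydration_params`.
#' @export
hydration_params <- function(box_margin_D = 4.0, pmf_cutoff = 5.0,
                             cluster_radius = 2.0, min_grids_N = 1L,
                             contact_distance = 4.0, spacing = 1.0) {
  p <- list(box_margin_D = box_margin_D, pmf_cutoff = pmf_cutoff,
            cluster_radius = cluster_radius, min_grids_N = min_grids_N,
            contact_distance = contact_distance, spacing = spacing)
  if (any(unlist(p) <= 0)) stopf("all hydration parameters must be positive")
  structure(p, class = "hydration_params")
}

#' Axis-aligned pocket box around a ligand
#'
#' @param ligand a [mol_structure()].
#' @param margin expansion on all six faces (A).
#' @return list with 3-vectors `min` and `max`.
#' @export
build_pocket_box <- function(ligand, margin = 4.0) {
  xyz <- coords_of(ligand$atoms)
  if (!nrow(xyz)) stopf("ligand is empty")
  list(min = unname(apply(xyz, 2, min)) - margin,
       max = unname(apply(xyz, 2, max)) + margin)
}

#' Construct a pocket grid object
#'
#' @param origin coordinates of the first voxel center (A).
#' @param spacing voxel edge length (A).
#' @param dims integer 3-vector of voxel counts.
#' @param values numeric array/vector of length prod(dims), x fastest.
#' @return object of class `pocket_grid`.
#' @export
pocket_grid <- function(origin, spacing, dims, values) {
  dims <- unname(as.integer(dims))
  origin <- unname(as.numeric(origin))
  spacing <- unname(as.numeric(spacing))[1]
  if (spacing <= 0) stopf("spacing must be > 0")
  if (any(dims < 1L)) stopf("dims must be positive")
  values <- as.numeric(values)
  if (length(values) != prod(dims)) stopf("values length != prod(dims)")
  if (!all(is.finite(values))) stopf("grid values must be finite")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, values = values), class = "pocket_grid")
}

## voxel centers as an (nvox x 3) matrix, x fastest (matches values order)
grid_centers <- function(grid) {
  d <- grid$dims
  ix <- seq_len(d[1]) - 1L; iy <- seq_len(d[2]) - 1L; iz <- seq_len(d[3]) - 1L
  cbind(grid$origin[1] + rep(ix, times = d[2] * d[3]) * grid$spacing,
        grid$origin[2] + rep(rep(iy, each = d[1]), times = d[3]) * grid$spacing,
        grid$origin[3] + rep(iz, each = d[1] * d[2]) * grid$spacing)
}

## sentinel for sterically impossible voxels (finite to keep grids writable)
CLASH_SCORE <- -1e6

#' Default surrogate probe scorer
#'
#' Sum of Gaussian attractions centered on polar protein atoms (N, O, S).
#' A stand-in for a knowledge-based water potential: it rewards probe
#' positions near hydrogen-bonding partners. The defaults (amplitude 15,
#' width 1.5 A) are scaled so a single partner scores above the favourable
#' cutoff of 5 throughout its first hydration shell (~2.0-2.6 A), outside
#' the 2 A steric-clash zone. Returns a function(points_matrix) -> scores.
#'
#' @param protein a [mol_structure()].
#' @param amplitude per-atom Gaussian height.
#' @param width Gaussian sigma (A).
#' @export
gaussian_polar_scorer <- function(protein, amplitude = 15, width = 1.5) {
  pa <- protein$atoms
  polar <- pa[pa$element %in% c("N", "O", "S"), , drop = FALSE]
  centers <- coords_of(polar)
  function(points) {
    if (!nrow(centers)) return(rep(0, nrow(points)))
    d <- cross_dist(points, centers)
    rowSums(amplitude * exp(-d^2 / (2 * width^2)))
  }
}

#' Score a probe grid over a pocket box
#'
#' Places one probe per voxel center and scores it with `scorer`; voxels
#' within 2.0 A of any protein or ligand heavy atom get the steric-clash
#' sentinel (a large negative value).
#'
#' @param box list(min, max) from [build_pocket_box()].
#' @param spacing voxel size (A), in (0, 2].
#' @param scorer function(points_matrix) -> numeric vector. See
#'   [gaussian_polar_scorer()].
#' @param protein a [mol_structure()]; used for clash detection.
#' @param ligand optional [mol_structure()] adding clash atoms.
#' @return a [pocket_grid()].
#' @export
score_grid <- function(box, spacing, scorer, protein, ligand = NULL) {
  if (spacing <= 0 || spacing > 2) stopf("spacing must be in (0, 2] A")
  dims <- pmax(1L, as.integer(floor((box$max - box$min) / spacing)) + 1L)
  grid <- pocket_grid(box$min, spacing, dims, numeric(prod(dims)))
  pts <- grid_centers(grid)
  vals <- scorer(pts)
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals))[1]
    stopf("scorer returned a non-finite value at voxel %d", bad)
  }
  clash_xyz <- coords_of(protein$atoms)
  if (!is.null(ligand)) clash_xyz <- rbind(clash_xyz, coords_of(ligand$atoms))
  if (nrow(clash_xyz)) {
    dmin <- apply(cross_dist(pts, clash_xyz), 1, min)
    vals[dmin < 2.0] <- CLASH_SCORE
  }
  grid$values <- vals
  grid
}

#' Mean-shift clustering of high-scoring voxels into hydration sites
#'
#' Flat-kernel mean shift (bandwidth = `cluster_radius`) over the centers of
#' voxels whose score passes `pmf_cutoff`, weighted by voxel score. Each
#' seed iterates to its mode (shift < 1e-4 A or 200 iterations); modes
#' within the bandwidth are merged; clusters with fewer than `min_grids_N`
#' member voxels are dropped. Site score = summed member weight.
#'
#' @param grid a [pocket_grid()] from [score_grid()].
#' @param params a [hydration_params()].
#' @return [water_sites()] data.frame with provenance "hydramap" (possibly
#'   zero rows).
#' @export
mean_shift_sites <- function(grid, params = hydration_params()) {
  pass <- which(grid$values >= params$pmf_cutoff & grid$values > CLASH_SCORE)
  if (!length(pass)) return(water_sites(matrix(numeric(0), ncol = 3), provenance = "hydramap"))
  pts <- grid_centers(grid)[pass, , drop = FALSE]
  w <- grid$values[pass]
  bw <- params$cluster_radius
  modes <- pts
  for (k in seq_len(nrow(pts))) {
    m <- pts[k, ]
    for (it in seq_len(200)) {
      d <- sqrt(colSums((t(pts) - m)^2))
      inb <- d <= bw
      newm <- colSums(pts[inb, , drop = FALSE] * w[inb]) / sum(w[inb])
      if (sqrt(sum((newm - m)^2)) < 1e-4) { m <- newm; break }
      m <- newm
    }
    modes[k, ] <- m
  }
  # merge modes within the bandwidth (greedy, highest total weight first)
  assigned <- rep(NA_integer_, nrow(modes))
  centers <- NULL
  ord <- order(-w)
  for (k in ord) {
    if (!is.null(centers)) {
      d <- sqrt(colSums((t(centers) - modes[k, ])^2))
      hit <- which(d <= bw)
      if (length(hit)) { assigned[k] <- hit[1]; next }
    }
    centers <- rbind(centers, modes[k, ])
    assigned[k] <- nrow(centers)
  }
  # cluster membership by converged mode; site position = weighted centroid of members
  out <- lapply(seq_len(nrow(centers)), function(ci) {
    mem <- which(assigned == ci)
    if (length(mem) < params$min_grids_N) return(NULL)
    ctr <- colSums(pts[mem, , drop = FALSE] * w[mem]) / sum(w[mem])
    c(ctr, sum(w[mem]))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || !nrow(out))
    return(water_sites(matrix(numeric(0), ncol = 3), provenance = "hydramap"))
  ord2 <- order(-out[, 4])
  water_sites(out[ord2, 1:3, drop = FALSE], score = out[ord2, 4], provenance = "hydramap")
}

#' Extract hydration sites from a solvent-density grid
#'
#' Voxels that are 26-neighbourhood local maxima with value >= `threshold`
#' times the grid mean become sites; maxima closer than 2.0 A are merged
#' keeping the higher peak.
#'
#' @param grid a [pocket_grid()] (e.g. parsed with [read_dx()]).
#' @param threshold relative density threshold (default 2.0 x bulk mean).
#' @return [water_sites()] with provenance "rism" (possibly zero rows).
#' @export
sites_from_density <- function(grid, threshold = 2.0) {
  d <- grid$dims
  v <- array(grid$values, dim = d)
  if (max(grid$values) - min(grid$values) < .Machine$double.eps * 10)
    return(water_sites(matrix(numeric(0), ncol = 3), provenance = "rism"))
  bulk <- mean(grid$values)
  cut <- threshold * bulk
  peaks <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    val <- v[i, j, k]
    if (val < cut) next
    nb <- v[max(1, i - 1):min(d[1], i + 1),
            max(1, j - 1):min(d[2], j + 1),
            max(1, k - 1):min(d[3], k + 1)]
    if (val >= max(nb) && sum(nb == val) == 1)
      peaks <- rbind(peaks, c(i, j, k, val))
  }
  if (is.null(peaks))
    return(water_sites(matrix(numeric(0), ncol = 3), provenance = "rism"))
  xyz <- t(grid$origin + t((peaks[, 1:3, drop = FALSE] - 1) * grid$spacing))
  val <- peaks[, 4]
  ord <- order(-val)
  xyz <- xyz[ord, , drop = FALSE]; val <- val[ord]
  keep <- rep(TRUE, nrow(xyz))
  for (a in seq_len(nrow(xyz))) {
    if (!keep[a]) next
    if (a < nrow(xyz)) for (b in (a + 1):nrow(xyz)) {
      if (keep[b] && sqrt(sum((xyz[a, ] - xyz[b, ])^2)) < 2.0) keep[b] <- FALSE
    }
  }
  water_sites(xyz[keep, , drop = FALSE], score = val[keep], provenance = "rism")
}

#' Keep water sites in contact with the solute
#'
#' A site survives if at least one protein or ligand heavy atom lies within
#' `contact_distance` of its oxygen. Sites of different provenances are kept
#' separate (the two water-bearing graphs use different sources).
#'
#' @param sites [water_sites()] data.frame.
#' @param cplx a [complex_structure()].
#' @param contact_distance maximum contact distance (A), default 4.0.
#' @return filtered [water_sites()].
#' @export
filter_contact_waters <- function(sites, cplx, contact_distance = 4.0) {
  if (contact_distance <= 0) stopf("contact_distance must be > 0")
  if (!nrow(sites)) return(sites)
  solute <- rbind(coords_of(cplx$protein$atoms), coords_of(cplx$ligand$atoms))
  dmin <- apply(cross_dist(as.matrix(sites[, c("x", "y", "z")]), solute), 1, min)
  out <- sites[dmin < contact_distance, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match predicted against reference water sites
#'
#' Greedy nearest-neighbour one-to-one matching under a distance tolerance:
#' repeatedly pair the globally closest unmatched (predicted, reference)
#' pair while the distance is below `tolerance`.
#'
#' @param predicted,reference [water_sites()] data.frames.
#' @param tolerance maximum match distance (A), default 2.0.
#' @return list(matched = count, misplaced = predicted sites left unmatched).
#' @export
match_waters <- function(predicted, reference, tolerance = 2.0) {
  if (tolerance <= 0) stopf("tolerance must be > 0")
  np <- nrow(predicted); nr <- nrow(reference)
  if (!np || !nr) return(list(matched = 0L, misplaced = np))
  d <- cross_dist(as.matrix(predicted[, c("x", "y", "z")]),
                  as.matrix(reference[, c("x", "y", "z")]))
  matched <- 0L
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] >= tolerance) break
    pi <- (m - 1L) %% np + 1L; ri <- (m - 1L) %/% np + 1L
    matched <- matched + 1L
    d[pi, ] <- Inf; d[, ri] <- Inf
    if (all(!is.finite(d))) break
  }
  list(matched = matched, misplaced = np - matched)
}

#' Read an OpenDX-style volumetric grid
#'
#' Supports the plain-text dialect written by solvent-distribution tools:
#' `object 1 class gridpositions counts nx ny nz`, `origin`, three `delta`
#' rows (orthogonal, uniform spacing) and a `class array` data block with
#' z varying fastest.
#'
#' @param path file path.
#' @return a [pocket_grid()].
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cnt <- grep("gridpositions counts", lines, value = TRUE)
  if (!length(cnt)) stopf("not an OpenDX grid (no gridpositions counts): %s", path)
  dims <- as.integer(utils::tail(strsplit(trimws(cnt[1]), "[[:space:]]+")[[1]], 3))
  org <- grep("^origin", lines, value = TRUE)
  origin <- as.numeric(strsplit(trimws(org[1]), "[[:space:]]+")[[1]][2:4])
  dl <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(dl[1:3], function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]][2:4]), numeric(3)))
  spacing <- dmat[1, 1]
  if (abs(dmat[2, 2] - spacing) > 1e-9 || abs(dmat[3, 3] - spacing) > 1e-9 ||
      any(abs(dmat[row(dmat) != col(dmat)]) > 1e-12))
    stopf("only orthogonal uniform-spacing DX grids are supported")
  dstart <- grep("class array", lines)
  if (!length(dstart)) stopf("no data array in DX file %s", path)
  dend <- grep("^(attribute|object \"|end)", lines)
  dend <- dend[dend > dstart[1]]
  last <- if (length(dend)) min(dend) - 1L else length(lines)
  toks <- unlist(strsplit(trimws(lines[(dstart[1] + 1L):last]), "[[:space:]]+"))
  vals <- as.numeric(toks[nzchar(toks)])
  if (length(vals) != prod(dims)) stopf("DX data length %d != %d", length(vals), prod(dims))
  # DX stores z fastest; pocket_grid stores x fastest
  a <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  pocket_grid(origin, spacing, dims, as.numeric(a))
}

#' Write a grid in the OpenDX text dialect read by [read_dx()]
#'
#' @param grid a [pocket_grid()].
#' @param path output path.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  head <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(d))
  )
  a <- aperm(array(grid$values, dim = d), c(3, 2, 1))  # z fastest on disk
  v <- as.numeric(a)
  rows <- split(v, ceiling(seq_along(v) / 3))
  body <- vapply(rows, function(r) paste(sprintf("%.6e", r), collapse = " "), character(1))
  writeLines(c(head, body, 'attribute "dep" string "positions"'), path)
  invisible(path)
}

#' One-call hydration-site prediction for a complex
#'
#' Runs the requested route and contact-filters the result.
#'
#' @param cplx a [complex_structure()].
#' @param mode "hydramap" (grid + mean shift), "rism" (density peaks of
#'   `density_grid`), or "experimental" (waters already on the complex).
#' @param params a [hydration_params()].
#' @param scorer probe scorer for the hydramap route; default
#'   [gaussian_polar_scorer()] on the complex's protein.
#' @param density_grid a [pocket_grid()] for the rism route.
#' @param density_threshold relative threshold for [sites_from_density()].
#' @return contact-filtered [water_sites()].
#' @export
predict_waters <- function(cplx, mode = c("hydramap", "rism", "experimental"),
                           params = hydration_params(), scorer = NULL,
                           density_grid = NULL, density_threshold = 2.0) {
  mode <- match.arg(mode)
  sites <- switch(mode,
    hydramap = {
      box <- build_pocket_box(cplx$ligand, params$box_margin_D)
      sc <- scorer %||% gaussian_polar_scorer(cplx$protein)
      g <- score_grid(box, params$spacing, sc, cplx$protein, cplx$ligand)
      mean_shift_sites(g, params)
    },
    rism = {
      if (is.null(density_grid)) stopf("rism mode needs a density_grid")
      sites_from_density(density_grid, density_threshold)
    },
    experimental = cplx$waters[cplx$waters$provenance == "experimental", , drop = FALSE]
  )
  filter_contact_waters(sites, cplx, params$contact_distance)
}
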