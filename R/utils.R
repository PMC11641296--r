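#' hydrographer: water-network graphs and biased graph-transformer
#' regression for protein-ligand binding affinity
#'
#' See the methods vignette for the model, its assumptions, and the
#' synthetic-data generator used to exercise the pipeline at desk scale.
#'
#' @keywords internal
#' @importFrom stats rnorm runif sd
#' @importFrom utils tail
"_PACKAGE"

## Pairwise Euclidean distance matrix between two coordinate matrices (n x 3, m x 3).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

coords_of <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
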