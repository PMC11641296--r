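## Graph-transformer affinity regressor.
##
## A transformer encoder over complex-graph nodes whose attention logits are
## biased by (a) a learned scalar per shortest-path-hop bucket (spatial
## encoding) and (b) an edge-path term: the average, over the edges of one
## recorded shortest path, of the inner product between the edge feature and
## a learned per-position weight (edge encoding). Degree centrality enters as
## a learned embedding added to the input projection. A virtual readout node
## attends to every real node and its final state is the graph embedding.
## Two graph branches (default shared weights) are concatenated and fed
## through a softmax-gated linear head to one pKd scalar.
##
## No deep-learning framework is available, so forward, backward (manual
## backprop) and an Adam optimizer are implemented here directly; gradients
## are verified against finite differences in the test suite.

EDGE_FEAT_DIM <- 7L  # distance + 6 pair-type channels

#' Model configuration
#'
#' Published settings: 4 layers, 12 attention heads, edge threshold 6 A.
#' The hidden dimension must be divisible by the head count; with 12 heads
#' the default is 60. Remaining training hyperparameters were not published;
#' package defaults are documented in the methods vignette.
#'
#' @param layers number of transformer layers (>= 1).
#' @param heads attention heads; must divide `hidden_dim`.
#' @param hidden_dim model width d.
#' @param max_spd_bucket shortest-path-distance clamp (also the maximum
#'   distinct path position for edge encoding).
#' @param degree_cap degree clamp for the centrality embedding.
#' @param dropout dropout fraction applied after attention and FFN during
#'   training (default 0: fully deterministic).
#' @param ffn_mult FFN expansion factor.
#' @param seed seed controlling initialization and training randomness.
#' @param shared_weights one stack for both graph branches (default) or two.
#' @param edge_bias_literal_n normalize the edge-path term by the graph's
#'   total edge count N (the literal published formula) instead of the
#'   per-path average (the convention of the cited graph transformer).
#' @param lr,batch_size,epochs Adam learning rate, minibatch size, epochs.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @return list of class `model_config`.
#' @export
model_config <- function(layers = 4L, heads = 12L, hidden_dim = 60L,
                         max_spd_bucket = 20L, degree_cap = 32L,
                         dropout = 0, ffn_mult = 2L, seed = 1L,
                         shared_weights = TRUE, edge_bias_literal_n = FALSE,
                         lr = 1e-4, batch_size = 8L, epochs = 30L,
                         grad_clip = 5) {
  if (layers < 1L) stopf("layers must be >= 1")
  if (hidden_dim %% heads != 0L) stopf("hidden_dim must be divisible by heads")
  structure(list(layers = as.integer(layers), heads = as.integer(heads),
                 hidden_dim = as.integer(hidden_dim),
                 max_spd_bucket = as.integer(max_spd_bucket),
                 degree_cap = as.integer(degree_cap), dropout = dropout,
                 ffn_mult = as.integer(ffn_mult), seed = as.integer(seed),
                 shared_weights = shared_weights,
                 edge_bias_literal_n = edge_bias_literal_n,
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), grad_clip = grad_clip),
            class = "model_config")
}

#' Node degrees of a complex graph
#'
#' Undirected graphs: in-degree = out-degree = degree. This is the quantity
#' consumed by the centrality encoding.
#' @param g a [build_graph()] result.
#' @return integer vector, one entry per node.
#' @export
node_degrees <- function(g) {
  tabulate(c(g$edges$i, g$edges$j), nbins = nrow(g$nodes))
}

.graph_igraph <- function(g) {
  n <- nrow(g$nodes)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, rbind(g$edges$i, g$edges$j))
  ig
}

#' Shortest-path hop matrix (spatial encoding)
#'
#' Unweighted breadth-first hop counts between all node pairs; `Inf` marks
#' unreachable pairs. Bucketing/clamping happens at model encoding time.
#' @param g a [build_graph()] result.
#' @return n x n numeric matrix, zero diagonal, symmetric.
#' @export
spatial_encode <- function(g) {
  ig <- .graph_igraph(g)
  d <- igraph::distances(ig, weights = NA)
  dimnames(d) <- NULL
  d
}

## Precompute everything the model needs from a graph: features, degree
## buckets, SPD buckets, and the per-(pair, path position) edge-feature
## entries used by the edge-path bias. Path choice is canonical (hops first,
## geometric length as tie-break) so predictions are permutation invariant.
#' Precompute model encodings for a graph
#'
#' Returns the node feature matrix, degree buckets, the (n+1)x(n+1) spatial
#' bucket matrix (virtual readout node at index 1), and a dense per-pair
#' path-feature matrix `FP` such that the edge-path bias for all connected
#' pairs is the single product `FP %*% W_E_flat` (per head). Path positions
#' are symmetrized (direction independent) and the per-path average (or,
#' with `edge_bias_literal_n`, division by the total edge count) is folded
#' into `FP`.
#'
#' @param g a [build_graph()] result with at least one node.
#' @param config a [model_config()].
#' @return object of class `encoded_graph`.
#' @export
encode_graph <- function(g, config = model_config()) {
  n <- nrow(g$nodes)
  if (!n) stopf("cannot encode an empty graph")
  maxb <- config$max_spd_bucket
  deg <- node_degrees(g)
  degidx <- pmin(deg, config$degree_cap) + 1L

  spd <- spatial_encode(g)
  # bucket indices: 1 = self (0 hops), 2..maxb+1 = 1..maxb hops (clamped),
  # maxb+2 = unreachable, maxb+3 = virtual-node pairs
  m <- n + 1L
  vb <- maxb + 3L
  bidx <- matrix(vb, m, m)
  sb <- pmin(spd, maxb) + 1L
  sb[is.infinite(spd)] <- maxb + 2L
  bidx[2:m, 2:m] <- sb
  bidx[1, 1] <- 1L
  mode(bidx) <- "integer"
  bucket_ids <- sort(unique(as.vector(bidx)))
  bucket_groups <- lapply(bucket_ids, function(b) which(bidx == b))

  # edge feature per graph edge: distance + pair-type one-hot
  ne <- nrow(g$edges)
  ef <- matrix(0, ne, EDGE_FEAT_DIM)
  if (ne) {
    ef[, 1] <- g$edges$distance
    ef[cbind(seq_len(ne), 1L + match(g$edges$pair_type, PAIR_TYPES))] <- 1
  }
  eid <- matrix(0L, n, n)
  if (ne) {
    eid[cbind(g$edges$i, g$edges$j)] <- seq_len(ne)
    eid[cbind(g$edges$j, g$edges$i)] <- seq_len(ne)
  }

  ig <- .graph_igraph(g)
  w <- if (ne) 1 + 1e-3 * g$edges$distance else numeric(0)
  src <- list(); si <- 0L
  if (n > 1 && ne) {
    for (i in seq_len(n - 1L)) {
      reach <- which(is.finite(spd[i, ]) & seq_len(n) > i & spd[i, ] >= 1)
      if (!length(reach)) next
      sp <- suppressWarnings(
        igraph::shortest_paths(ig, from = i, to = reach, weights = w,
                               output = "vpath"))$vpath
      ii <- lapply(seq_along(reach), function(t) {
        vp <- as.integer(sp[[t]])
        L <- length(vp) - 1L
        if (L < 1L) return(NULL)
        rows <- eid[cbind(vp[-(L + 1L)], vp[-1L])]
        tt <- seq_len(L)
        list(i = i, j = reach[t], L = L, rows = c(rows, rows),
             pos = c(pmin(tt, maxb), pmin(L - tt + 1L, maxb)))
      })
      si <- si + 1L
      src[[si]] <- ii[!vapply(ii, is.null, logical(1))]
    }
  }
  paths <- unlist(src, recursive = FALSE)
  np <- length(paths)
  ntot_edges <- max(1L, ne)
  if (np) {
    pair_i <- vapply(paths, `[[`, integer(1), "i")
    pair_j <- vapply(paths, `[[`, integer(1), "j")
    Ls <- vapply(paths, `[[`, integer(1), "L")
    cnt <- vapply(paths, function(p) length(p$rows), integer(1))
    ent_pair <- rep.int(seq_len(np), cnt)
    ent_pos <- unlist(lapply(paths, `[[`, "pos"))
    ent_rows <- unlist(lapply(paths, `[[`, "rows"))
    denom <- if (config$edge_bias_literal_n) rep(ntot_edges, np) else Ls
    ent_scale <- 0.5 / denom[ent_pair]
    npos <- max(ent_pos)
    # dense pair x (position, feature) accumulation: FP %*% W_E_flat = bias
    FP <- matrix(0, np, npos * EDGE_FEAT_DIM)
    base <- ef[ent_rows, , drop = FALSE] * ent_scale
    # accumulate with a single rowsum over (pair, position) groups
    grp <- (ent_pair - 1L) * npos + ent_pos
    accm <- rowsum(base, grp)
    gids <- as.integer(rownames(accm))
    gp <- (gids - 1L) %/% npos + 1L
    gq <- (gids - 1L) %% npos + 1L
    for (f in seq_len(EDGE_FEAT_DIM))
      FP[cbind(gp, (gq - 1L) * EDGE_FEAT_DIM + f)] <- accm[, f]
    pair_lin_up <- (pair_j) * m + (pair_i + 1L)        # [i+1, j+1] in m x m
    pair_lin_lo <- (pair_i) * m + (pair_j + 1L)        # [j+1, i+1]
  } else {
    pair_i <- pair_j <- integer(0)
    FP <- matrix(0, 0L, 0L); npos <- 0L
    pair_lin_up <- pair_lin_lo <- integer(0)
  }
  uid <- sprintf("eg-%d", local({
    .hydrographer_env$uid <- (.hydrographer_env$uid %||% 0L) + 1L
    .hydrographer_env$uid
  }))
  structure(list(X = g$X, degidx = degidx, bias_idx = bidx,
                 bucket_ids = bucket_ids, bucket_groups = bucket_groups,
                 FP = FP, npos = npos, np = np,
                 pair_lin_up = pair_lin_up, pair_lin_lo = pair_lin_lo,
                 n = n, variant = g$variant, uid = uid),
            class = "encoded_graph")
}

## ---- parameters ------------------------------------------------------------

.rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

.make_stack <- function(cfg) {
  d <- cfg$hidden_dim; f <- cfg$ffn_mult * d
  sx <- sqrt(2 / (NODE_FEATURE_DIM + d))
  sd_ <- sqrt(2 / (2 * d)); sf1 <- sqrt(2 / (d + f)); sf2 <- sqrt(2 / (f + d))
  layers <- lapply(seq_len(cfg$layers), function(l) list(
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    Wq = .rmat(d, d, sd_), bq = rep(0, d),
    Wk = .rmat(d, d, sd_), bk = rep(0, d),
    Wv = .rmat(d, d, sd_), bv = rep(0, d),
    Wo = .rmat(d, d, sd_), bo = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    W1 = .rmat(d, f, sf1), b1 = rep(0, f),
    W2 = .rmat(f, d, sf2), b2 = rep(0, d)
  ))
  list(
    W_in = .rmat(NODE_FEATURE_DIM, d, sx), b_in = rep(0, d),
    deg_emb = .rmat(cfg$degree_cap + 1L, d, 0.02),
    vnode = stats::rnorm(d, sd = 0.02),
    spd_bias = matrix(0, cfg$max_spd_bucket + 3L, cfg$heads),
    W_E = array(0, dim = c(cfg$max_spd_bucket, EDGE_FEAT_DIM, cfg$heads)),
    layers = layers,
    lnf_g = rep(1, d), lnf_b = rep(0, d)
  )
}

#' Initialize a model
#'
#' All randomness (weight init) flows from `config$seed`.
#' @param config a [model_config()].
#' @return list of class `affinity_model`.
#' @export
init_model <- function(config = model_config()) {
  set.seed(config$seed)
  d <- config$hidden_dim
  stacks <- list(.make_stack(config))
  if (!config$shared_weights) stacks <- c(stacks, list(.make_stack(config)))
  structure(list(config = config, stacks = stacks,
                 head_w = stats::rnorm(2 * d, sd = sqrt(1 / (2 * d))),
                 head_b = 0),
            class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<affinity_model: %d layer(s), %d head(s), d=%d, %s weights>\n",
              cfg$layers, cfg$heads, cfg$hidden_dim,
              if (length(x$stacks) == 1) "shared" else "separate"))
  invisible(x)
}

## ---- forward ---------------------------------------------------------------

.softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

.layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, "*") + matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

.layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2, g, "*")
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

## flatten W_E (maxpos x 7 x heads) so that row (pos-1)*7+f matches the FP
## column layout of encode_graph
.we_flat <- function(W_E) {
  d <- dim(W_E)
  matrix(aperm(W_E, c(2, 1, 3)), d[1] * d[2], d[3])
}

## bias matrices (one (n+1)x(n+1) matrix per head) from SPD buckets and the
## edge-path term; index 1 is the virtual node
.bias_matrices <- function(stack, eg, cfg) {
  m <- eg$n + 1L
  cvals <- if (eg$np) {
    Wf <- .we_flat(stack$W_E)
    eg$FP %*% Wf[seq_len(ncol(eg$FP)), , drop = FALSE]
  } else NULL
  B <- vector("list", cfg$heads)
  for (h in seq_len(cfg$heads)) {
    Bh <- matrix(stack$spd_bias[eg$bias_idx, h], m, m)
    if (eg$np) {
      Bh[eg$pair_lin_up] <- Bh[eg$pair_lin_up] + cvals[, h]
      Bh[eg$pair_lin_lo] <- Bh[eg$pair_lin_lo] + cvals[, h]
    }
    B[[h]] <- Bh
  }
  B
}

.forward_graph <- function(stack, eg, cfg, keep_attention = FALSE) {
  d <- cfg$hidden_dim; H <- cfg$heads; dk <- d %/% H
  scale <- 1 / sqrt(dk)
  m <- eg$n + 1L
  bias <- .bias_matrices(stack, eg, cfg)
  x0 <- rbind(stack$vnode,
              eg$X %*% stack$W_in +
                matrix(stack$b_in, eg$n, d, byrow = TRUE) +
                stack$deg_emb[eg$degidx, , drop = FALSE])
  x <- x0
  caches <- vector("list", cfg$layers)
  attn <- if (keep_attention) vector("list", cfg$layers) else NULL
  for (l in seq_len(cfg$layers)) {
    P <- stack$layers[[l]]
    ln1 <- .layernorm_fwd(x, P$ln1_g, P$ln1_b)
    h1 <- ln1$y
    Q <- h1 %*% P$Wq + matrix(P$bq, m, d, byrow = TRUE)
    K <- h1 %*% P$Wk + matrix(P$bk, m, d, byrow = TRUE)
    V <- h1 %*% P$Wv + matrix(P$bv, m, d, byrow = TRUE)
    A <- vector("list", H)
    conc <- matrix(0, m, d)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) * scale +
        bias[[h]]
      Ah <- .softmax_rows(S)
      A[[h]] <- Ah
      conc[, cols] <- Ah %*% V[, cols, drop = FALSE]
    }
    aout <- conc %*% P$Wo + matrix(P$bo, m, d, byrow = TRUE)
    xm <- x + aout
    ln2 <- .layernorm_fwd(xm, P$ln2_g, P$ln2_b)
    u <- ln2$y %*% P$W1 + matrix(P$b1, m, cfg$ffn_mult * d, byrow = TRUE)
    r <- pmax(u, 0)
    fo <- r %*% P$W2 + matrix(P$b2, m, d, byrow = TRUE)
    xn <- xm + fo
    if (!all(is.finite(xn)))
      stopf("non-finite activations in layer %d", l)
    caches[[l]] <- list(x = x, ln1 = ln1, Q = Q, K = K, V = V, A = A,
                        conc = conc, xm = xm, ln2 = ln2, u = u, r = r)
    if (keep_attention) attn[[l]] <- A
    x <- xn
  }
  lnf <- .layernorm_fwd(x, stack$lnf_g, stack$lnf_b)
  list(gemb = lnf$y[1, ], x_final = x, lnf = lnf, caches = caches,
       bias = bias, x0 = x0, attention = attn)
}

.zeros_like_stack <- function(stack) {
  rapply(stack, function(z) z * 0, how = "replace")
}

## backward for one graph branch; returns gradients for the stack and nothing
## else (input features are data, not parameters)
.backward_graph <- function(stack, eg, cfg, fwd, dgemb, gstack) {
  d <- cfg$hidden_dim; H <- cfg$heads; dk <- d %/% H
  scale <- 1 / sqrt(dk)
  m <- eg$n + 1L
  dxf <- matrix(0, m, d)
  dxf[1, ] <- dgemb
  lb <- .layernorm_bwd(dxf, fwd$lnf, stack$lnf_g)
  gstack$lnf_g <- gstack$lnf_g + lb$dg
  gstack$lnf_b <- gstack$lnf_b + lb$db
  dx <- lb$dx
  dB <- lapply(seq_len(H), function(h) matrix(0, m, m))
  for (l in rev(seq_len(cfg$layers))) {
    P <- stack$layers[[l]]; C <- fwd$caches[[l]]
    gl <- gstack$layers[[l]]
    # FFN branch
    dfo <- dx
    gl$W2 <- gl$W2 + crossprod(C$r, dfo)
    gl$b2 <- gl$b2 + colSums(dfo)
    dr <- tcrossprod(dfo, P$W2)
    du <- dr * (C$u > 0)
    gl$W1 <- gl$W1 + crossprod(C$ln2$y, du)
    gl$b1 <- gl$b1 + colSums(du)
    dh2 <- tcrossprod(du, P$W1)
    lb2 <- .layernorm_bwd(dh2, C$ln2, P$ln2_g)
    gl$ln2_g <- gl$ln2_g + lb2$dg; gl$ln2_b <- gl$ln2_b + lb2$db
    dxm <- dx + lb2$dx
    # attention branch
    daout <- dxm
    gl$Wo <- gl$Wo + crossprod(C$conc, daout)
    gl$bo <- gl$bo + colSums(daout)
    dconc <- tcrossprod(daout, P$Wo)
    dQ <- matrix(0, m, d); dK <- matrix(0, m, d); dV <- matrix(0, m, d)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Ah <- C$A[[h]]
      dOh <- dconc[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, C$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(Ah, dOh)
      dS <- Ah * (dA - rowSums(dA * Ah))
      dB[[h]] <- dB[[h]] + dS
      dQ[, cols] <- (dS %*% C$K[, cols, drop = FALSE]) * scale
      dK[, cols] <- crossprod(dS, C$Q[, cols, drop = FALSE]) * scale
    }
    h1 <- C$ln1$y
    gl$Wq <- gl$Wq + crossprod(h1, dQ); gl$bq <- gl$bq + colSums(dQ)
    gl$Wk <- gl$Wk + crossprod(h1, dK); gl$bk <- gl$bk + colSums(dK)
    gl$Wv <- gl$Wv + crossprod(h1, dV); gl$bv <- gl$bv + colSums(dV)
    dh1 <- tcrossprod(dQ, P$Wq) + tcrossprod(dK, P$Wk) + tcrossprod(dV, P$Wv)
    lb1 <- .layernorm_bwd(dh1, C$ln1, P$ln1_g)
    gl$ln1_g <- gl$ln1_g + lb1$dg; gl$ln1_b <- gl$ln1_b + lb1$db
    dx <- dxm + lb1$dx
    gstack$layers[[l]] <- gl
  }
  # input projection / embeddings
  dx0 <- dx
  gstack$vnode <- gstack$vnode + dx0[1, ]
  dXn <- dx0[-1, , drop = FALSE]
  gstack$W_in <- gstack$W_in + crossprod(eg$X, dXn)
  gstack$b_in <- gstack$b_in + colSums(dXn)
  for (k in seq_len(eg$n))
    gstack$deg_emb[eg$degidx[k], ] <- gstack$deg_emb[eg$degidx[k], ] + dXn[k, ]
  # bias terms (same bias used at every layer)
  if (eg$np) Gp <- matrix(0, eg$np, H)
  for (h in seq_len(H)) {
    dBh <- dB[[h]]
    for (bi in seq_along(eg$bucket_ids))
      gstack$spd_bias[eg$bucket_ids[bi], h] <-
        gstack$spd_bias[eg$bucket_ids[bi], h] + sum(dBh[eg$bucket_groups[[bi]]])
    if (eg$np) Gp[, h] <- dBh[eg$pair_lin_up] + dBh[eg$pair_lin_lo]
  }
  if (eg$np) {
    dWf <- crossprod(eg$FP, Gp)                       # (npos*7) x heads
    npos <- eg$npos
    dWarr <- aperm(array(dWf, dim = c(EDGE_FEAT_DIM, npos, H)), c(2, 1, 3))
    gstack$W_E[seq_len(npos), , ] <- gstack$W_E[seq_len(npos), , , drop = FALSE] + dWarr
  }
  gstack
}

#' Predict affinity for one complex (a pair of encoded graphs)
#'
#' Each branch runs its graph through the transformer stack; the two virtual-
#' node embeddings are concatenated and passed through a softmax-gated linear
#' head (see the methods vignette for why "softmax regression" is read this
#' way).
#'
#' @param model an [init_model()] result.
#' @param eg_b,eg_c [encode_graph()] results for the two water-bearing
#'   graphs (or the same encoded G_A twice for the no-water mode).
#' @param return_details also return per-layer attention matrices and the
#'   branch caches (used by tests and by training).
#' @return predicted pKd (scalar), or a list when `return_details = TRUE`.
#' @export
forward_affinity <- function(model, eg_b, eg_c, return_details = FALSE) {
  cfg <- model$config
  if (!eg_b$n || !eg_c$n) stopf("cannot run the model on an empty graph")
  s1 <- model$stacks[[1]]
  s2 <- model$stacks[[min(2L, length(model$stacks))]]
  same <- identical(eg_b$uid, eg_c$uid) && length(model$stacks) == 1L
  f1 <- .forward_graph(s1, eg_b, cfg, keep_attention = return_details)
  f2 <- if (same) f1 else .forward_graph(s2, eg_c, cfg, keep_attention = return_details)
  z <- c(f1$gemb, f2$gemb)
  sz <- exp(z - max(z)); sz <- sz / sum(sz)
  p <- sz * z
  yhat <- sum(model$head_w * p) + model$head_b
  if (!return_details) return(yhat)
  list(yhat = yhat, f1 = f1, f2 = f2, z = z, s = sz, p = p,
       attention = list(branch1 = f1$attention, branch2 = f2$attention))
}

## gradient of the head + both branches for one sample; returns d(yhat)/dparams
## premultiplied by upstream scalar `gout`
.backward_affinity <- function(model, eg_b, eg_c, det, gout, grads) {
  cfg <- model$config
  z <- det$z; s <- det$s
  grads$head_b <- grads$head_b + gout
  grads$head_w <- grads$head_w + gout * det$p
  ws <- model$head_w * s
  dz <- gout * (ws + s * (model$head_w * z - sum(model$head_w * z * s)))
  d <- cfg$hidden_dim
  shared <- length(model$stacks) == 1L
  if (shared && identical(eg_b$uid, eg_c$uid)) {
    # one branch, both gradient slots flow into the same forward pass
    grads$stacks[[1]] <- .backward_graph(model$stacks[[1]], eg_b, cfg, det$f1,
                                         dz[seq_len(d)] + dz[d + seq_len(d)],
                                         grads$stacks[[1]])
    return(grads)
  }
  grads$stacks[[1]] <- .backward_graph(model$stacks[[1]], eg_b, cfg, det$f1,
                                       dz[seq_len(d)], grads$stacks[[1]])
  i2 <- if (shared) 1L else 2L
  grads$stacks[[i2]] <- .backward_graph(model$stacks[[min(2L, length(model$stacks))]],
                                        eg_c, cfg, det$f2,
                                        dz[d + seq_len(d)], grads$stacks[[i2]])
  grads
}

.zero_grads <- function(model) {
  list(stacks = lapply(model$stacks, .zeros_like_stack),
       head_w = model$head_w * 0, head_b = 0)
}

## ---- optimizer -------------------------------------------------------------

.flatten_params <- function(p) rapply(p, as.numeric, how = "unlist")

.assign_flat <- function(p, v) {
  i <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    ln <- length(x)
    out <- x
    out[] <- v[(i + 1L):(i + ln)]
    i <<- i + ln
    out
  }
  rec(p)
}

.model_params <- function(model) list(stacks = model$stacks,
                                      head_w = model$head_w, head_b = model$head_b)

.set_model_params <- function(model, p) {
  model$stacks <- p$stacks
  model$head_w <- p$head_w
  model$head_b <- p$head_b
  model
}

#' Train the affinity model on encoded samples
#'
#' Minimizes mean-squared error on pKd with Adam. All randomness (shuffling)
#' derives from `config$seed`; with `dropout = 0` training is deterministic.
#'
#' @param samples list of samples; each is `list(eg_b=, eg_c=, y=)` with
#'   [encode_graph()] results and a numeric label.
#' @param config a [model_config()].
#' @param model optional warm-start model (default: fresh [init_model()]).
#' @param validation optional samples list; mean MSE is tracked per epoch.
#' @param verbose print per-epoch losses.
#' @return list(model, history = data.frame(epoch, train_loss, val_loss)).
#' @export
train_model <- function(samples, config = model_config(), model = NULL,
                        validation = NULL, verbose = FALSE) {
  if (!length(samples)) stopf("no training samples")
  model <- model %||% init_model(config)
  cfg <- model$config
  theta <- .flatten_params(.model_params(model))
  mom <- theta * 0; vel <- theta * 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  set.seed(cfg$seed + 1L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(samples))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      bidx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      grads <- .zero_grads(model)
      bloss <- 0
      for (si in bidx) {
        sm <- samples[[si]]
        det <- forward_affinity(model, sm$eg_b, sm$eg_c, return_details = TRUE)
        err <- det$yhat - sm$y
        bloss <- bloss + err^2
        grads <- .backward_affinity(model, sm$eg_b, sm$eg_c, det,
                                    2 * err / length(bidx), grads)
      }
      ep_loss <- ep_loss + bloss; nb <- nb + length(bidx)
      gvec <- .flatten_params(grads)
      if (cfg$grad_clip > 0) {
        gn <- sqrt(sum(gvec^2))
        if (gn > cfg$grad_clip) gvec <- gvec * (cfg$grad_clip / gn)
      }
      t <- t + 1L
      mom <- b1 * mom + (1 - b1) * gvec
      vel <- b2 * vel + (1 - b2) * gvec^2
      mhat <- mom / (1 - b1^t); vhat <- vel / (1 - b2^t)
      theta <- theta - cfg$lr * mhat / (sqrt(vhat) + eps)
      model <- .set_model_params(model, .assign_flat(.model_params(model), theta))
    }
    vl <- NA_real_
    if (!is.null(validation) && length(validation)) {
      preds <- vapply(validation, function(sm)
        forward_affinity(model, sm$eg_b, sm$eg_c), numeric(1))
      ys <- vapply(validation, `[[`, numeric(1), "y")
      vl <- mean((preds - ys)^2)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d  train MSE %.4f  val MSE %s", ep,
                      ep_loss / nb, ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
  }
  list(model = model, history = hist)
}

#' Predict affinities for a list of encoded samples
#' @param model trained [init_model()]/[train_model()] model.
#' @param samples list of `list(eg_b=, eg_c=, ...)`.
#' @return numeric vector of predicted pKd values.
#' @export
predict_affinity <- function(model, samples) {
  vapply(samples, function(sm) forward_affinity(model, sm$eg_b, sm$eg_c),
         numeric(1))
}

#' Save / load a model checkpoint (JSON, version + config embedded)
#' @param model an `affinity_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "hydrographer-checkpoint-v1",
              config = unclass(model$config),
              theta = .flatten_params(.model_params(model)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hydrographer-checkpoint-v1"))
    stopf("not a recognised checkpoint: %s", path)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), character(0))])
  model <- init_model(cfg)
  model <- .set_model_params(model, .assign_flat(.model_params(model),
                                                 as.numeric(obj$theta)))
  model
}
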