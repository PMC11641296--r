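# Small configs keep these tests fast; the math being checked is size-free.
tiny_cfg <- function(...) model_config(layers = 2L, heads = 2L, hidden_dim = 8L,
                                       seed = 11L, ...)

encoded_pair <- function(seed = 7, cfg = tiny_cfg()) {
  pk <- gen_pocket(seed = seed, n_bridge = 2, n_res = 5, n_lig = 5)
  list(b = encode_graph(build_graph(pk, "G_B", T = 6), cfg),
       c = encode_graph(build_graph(pk, "G_C", T = 6), cfg),
       pk = pk)
}

test_that("degrees equal an adjacency recount; chain degrees are (1,2,1)", {
  chain <- random_complex_graph(3, 0, seed = 1)
  chain$edges <- data.frame(i = c(1L, 2L), j = c(2L, 3L),
                            pair_type = "LL", distance = c(1, 1))
  expect_equal(node_degrees(chain), c(1L, 2L, 1L))
  g <- random_complex_graph(30, 0.15, seed = 5)
  adj <- matrix(0L, 30, 30)
  adj[cbind(g$edges$i, g$edges$j)] <- 1L
  adj <- adj + t(adj)
  expect_equal(node_degrees(g), unname(rowSums(adj)))
})

test_that("degree indices clamp at the configured cap", {
  n <- 40
  g <- random_complex_graph(n, 0, seed = 2)
  g$edges <- data.frame(i = rep(1L, n - 1L), j = 2:n,
                        pair_type = "LL", distance = 1)
  eg <- encode_graph(g, tiny_cfg())
  expect_equal(eg$degidx[1], 32L + 1L)   # degree 39 clamped to 32
  expect_equal(eg$degidx[2], 1L + 1L)
})

test_that("spatial encoding equals Floyd-Warshall on random graphs", {
  for (seed in 1:20) {
    n <- sample(4:40, 1)
    g <- random_complex_graph(n, runif(1, 0.05, 0.3), seed = seed)
    D <- spatial_encode(g)
    expect_equal(D, floyd_warshall(n, g$edges$i, g$edges$j),
                 info = paste("seed", seed))
  }
})

test_that("path graph and components behave in the spatial encoding", {
  g <- random_complex_graph(5, 0, seed = 3)
  g$edges <- data.frame(i = c(1L, 2L), j = c(2L, 3L), pair_type = "LL",
                        distance = 1)   # nodes 4,5 isolated
  D <- spatial_encode(g)
  expect_equal(D[1, 3], 2)
  expect_true(is.infinite(D[1, 4]))
  cfg <- tiny_cfg()
  eg <- encode_graph(g, cfg)
  expect_equal(eg$bias_idx[2, 5], cfg$max_spd_bucket + 2L)  # unreachable bucket
  expect_equal(eg$bias_idx[2, 4], 2L + 1L)                  # 2 hops
  expect_equal(eg$bias_idx[1, 2], cfg$max_spd_bucket + 3L)  # virtual node
})

test_that("edge-path bias: single-edge paths, zero annihilation, tree oracle", {
  cfg <- tiny_cfg()
  # a path graph has unique shortest paths: independent oracle by replaying
  # BFS paths on the tree
  g <- random_complex_graph(5, 0, seed = 4)
  g$edges <- data.frame(i = 1:4, j = 2:5, pair_type = "LL",
                        distance = c(1.5, 2.5, 3.5, 4.5))
  eg <- encode_graph(g, cfg)
  stack <- hydrographer:::.make_stack(cfg)
  stack$spd_bias[] <- 0
  set.seed(9)
  stack$W_E[] <- rnorm(length(stack$W_E), sd = 0.3)
  B <- hydrographer:::.bias_matrices(stack, eg, cfg)
  efeat <- function(d) c(d, 1, 0, 0, 0, 0, 0)  # LL one-hot in slot 2
  for (h in seq_len(cfg$heads)) {
    W <- stack$W_E[, , h]
    for (i in 1:4) for (j in (i + 1):5) {
      path_edges <- i:(j - 1)                   # unique path i..j
      L <- length(path_edges)
      expected <- 0
      for (t in seq_along(path_edges)) {
        e <- efeat(g$edges$distance[path_edges[t]])
        wsym <- (W[min(t, cfg$max_spd_bucket), ] +
                   W[min(L - t + 1, cfg$max_spd_bucket), ]) / 2
        expected <- expected + sum(e * wsym) / L
      }
      expect_equal(B[[h]][i + 1, j + 1], expected, tolerance = 1e-12)
      expect_equal(B[[h]][j + 1, i + 1], expected, tolerance = 1e-12)
    }
  }
  # adjacent pair: exactly the single-edge term
  expect_equal(B[[1]][2, 3], sum(efeat(1.5) * stack$W_E[1, , 1]))
  # zero edge weights annihilate the bias
  stack$W_E[] <- 0
  B0 <- hydrographer:::.bias_matrices(stack, eg, cfg)
  expect_true(all(vapply(B0, function(m) all(m == 0), logical(1))))
})

test_that("attention rows are stochastic at every layer and head", {
  ep <- encoded_pair()
  m <- init_model(tiny_cfg())
  det <- forward_affinity(m, ep$b, ep$c, return_details = TRUE)
  for (br in det$attention) for (lay in br) for (A in lay) {
    expect_true(all(abs(rowSums(A) - 1) < 1e-5))
    expect_true(all(A >= 0))
  }
  # softmax of a constant matrix is uniform
  U <- hydrographer:::.softmax_rows(matrix(3.7, 6, 6))
  expect_equal(U, matrix(1 / 6, 6, 6))
})

test_that("forward is permutation invariant", {
  cfg <- tiny_cfg()
  pk <- gen_pocket(seed = 13, n_bridge = 2)
  gb <- build_graph(pk, "G_B", T = 6)
  gc_ <- build_graph(pk, "G_C", T = 6)
  m <- init_model(cfg)
  base <- forward_affinity(m, encode_graph(gb, cfg), encode_graph(gc_, cfg))
  set.seed(99)
  for (k in 1:3) {
    pb <- permute_graph(gb, sample(nrow(gb$nodes)))
    pc <- permute_graph(gc_, sample(nrow(gc_$nodes)))
    out <- forward_affinity(m, encode_graph(pb, cfg), encode_graph(pc, cfg))
    expect_equal(out, base, tolerance = 1e-5)
  }
})

test_that("seeded initialization and prediction are deterministic", {
  ep <- encoded_pair()
  m1 <- init_model(tiny_cfg())
  m2 <- init_model(tiny_cfg())
  expect_identical(hydrographer:::.flatten_params(hydrographer:::.model_params(m1)),
                   hydrographer:::.flatten_params(hydrographer:::.model_params(m2)))
  expect_identical(forward_affinity(m1, ep$b, ep$c),
                   forward_affinity(m2, ep$b, ep$c))
})

test_that("zero-initialized head predicts exactly its bias", {
  ep <- encoded_pair()
  m <- init_model(tiny_cfg())
  m$head_w[] <- 0
  m$head_b <- 4.25
  expect_equal(forward_affinity(m, ep$b, ep$c), 4.25)
})

test_that("empty graphs are rejected", {
  ep <- encoded_pair()
  empty <- ep$b
  empty$n <- 0L
  m <- init_model(tiny_cfg())
  expect_error(forward_affinity(m, empty, ep$c), "empty")
})

test_that("manual backprop matches finite differences", {
  cfg <- tiny_cfg()
  ep <- encoded_pair(seed = 17, cfg = cfg)
  for (same_branch in c(FALSE, TRUE)) {
    egc <- if (same_branch) ep$b else ep$c
    m <- init_model(cfg)
    y <- 7.3
    det <- forward_affinity(m, ep$b, egc, return_details = TRUE)
    grads <- hydrographer:::.zero_grads(m)
    grads <- hydrographer:::.backward_affinity(m, ep$b, egc, det,
                                               2 * (det$yhat - y), grads)
    gvec <- hydrographer:::.flatten_params(grads)
    theta <- hydrographer:::.flatten_params(hydrographer:::.model_params(m))
    lossfn <- function(th) {
      mm <- hydrographer:::.set_model_params(
        m, hydrographer:::.assign_flat(hydrographer:::.model_params(m), th))
      (forward_affinity(mm, ep$b, egc) - y)^2
    }
    set.seed(42)
    idx <- sample(length(theta), 40)
    eps <- 1e-6
    num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- tp[i] + eps; lp <- lossfn(tp)
      tp[i] <- tp[i] - 2 * eps; (lp - lossfn(tp)) / (2 * eps)
    }, numeric(1))
    relerr <- abs(num - gvec[idx]) / pmax(1e-6, abs(num) + abs(gvec[idx]))
    expect_lt(max(relerr), 1e-4)
  }
})

test_that("separate-branch weights are honoured", {
  cfg <- model_config(layers = 1L, heads = 2L, hidden_dim = 8L, seed = 3L,
                      shared_weights = FALSE)
  m <- init_model(cfg)
  expect_length(m$stacks, 2)
  ep <- encoded_pair(seed = 23, cfg = cfg)
  # perturbing one branch-2 weight changes the output (a uniform shift of a
  # whole matrix would not: layer normalization removes per-row constants)
  base <- forward_affinity(m, ep$b, ep$c)
  m2 <- m
  m2$stacks[[2]]$W_in[52, 1] <- m2$stacks[[2]]$W_in[52, 1] + 0.5
  expect_false(isTRUE(all.equal(forward_affinity(m2, ep$b, ep$c), base)))
  m3 <- m
  m3$stacks[[2]]$W_in <- m3$stacks[[2]]$W_in * 1  # untouched copy
  expect_equal(forward_affinity(m3, ep$b, ep$c), base)
})

test_that("training reduces loss by half within 200 steps on 20 samples", {
  cfg <- model_config(layers = 1L, heads = 2L, hidden_dim = 16L, seed = 21L,
                      lr = 2e-3, batch_size = 8L, epochs = 67L)
  ds <- make_dataset(20, seed = 77, noise_sd = 0.1, bridge_range = 0:4)
  pks <- lapply(ds, extract_pocket, cutoff = 10)
  enc <- encode_dataset(pks, "full", cfg)
  fit <- train_model(enc, cfg)
  expect_lt(utils::tail(fit$history$train_loss, 1),
            0.5 * fit$history$train_loss[1])
})

test_that("checkpoints round-trip through JSON", {
  cfg <- tiny_cfg()
  ep <- encoded_pair(seed = 29, cfg = cfg)
  m <- init_model(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(forward_affinity(m2, ep$b, ep$c),
               forward_affinity(m, ep$b, ep$c), tolerance = 1e-12)
})
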