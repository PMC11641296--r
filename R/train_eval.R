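## Metrics, splits, thermodynamic conversion, affinity index I/O, and the
## ablation harness (with/without water; single-source modes).

#' Pearson correlation coefficient
#'
#' cov(X, Y) / (sd(X) sd(Y)); the scoring-power metric R_p.
#' @param x measured values, @param y predicted values (length >= 2).
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 2) stopf("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance: correlation undefined")
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

#' Root-mean-square error
#' @param x,y equal-length numeric vectors.
#' @return sqrt(mean((y - x)^2)).
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch: %d vs %d", length(x), length(y))
  if (!length(x)) stopf("need at least 1 observation")
  sqrt(mean((y - x)^2))
}

#' Binding free energy from a dissociation constant
#'
#' Delta G = R T ln(K_d), with R = 1.98720425864083e-3 kcal/(mol K).
#' K_d < 1 M gives a negative (favourable) free energy.
#'
#' @param kd dissociation constant in mol/L (> 0).
#' @param temperature absolute temperature in K (default 298.15).
#' @return free energy in kcal/mol.
#' @export
dg_from_kd <- function(kd, temperature = 298.15) {
  if (any(kd <= 0)) stopf("kd must be positive")
  if (any(temperature <= 0)) stopf("temperature must be positive")
  R_KCAL <- 1.98720425864083e-3
  R_KCAL * temperature * log(kd)
}

#' Train/test split by held-out ids
#'
#' @param all_ids character vector of all complex ids.
#' @param test_ids ids forming the test set (must be a subset of `all_ids`).
#' @return list(train, test) of disjoint id vectors;
#'   |train| + |test| = |all|.
#' @export
make_split <- function(all_ids, test_ids) {
  missing <- setdiff(test_ids, all_ids)
  if (length(missing))
    stopf("%d test id(s) absent from the full set (e.g. %s)",
          length(missing), missing[1])
  train <- setdiff(all_ids, test_ids)
  if (!length(train)) warnf("empty training set: all ids are in the test set")
  list(train = train, test = test_ids,
       sizes = c(all = length(all_ids), train = length(train),
                 test = length(test_ids)))
}

#' Read a PDBbind-style affinity index file
#'
#' Whitespace-delimited rows `id <...> pKd`, tolerant of leading `#` comment
#' lines. By convention the pKd/pKi value is in the 4th column when present,
#' else the 2nd.
#'
#' @param path index file path.
#' @param ic50_ok accept rows whose measurement tag (column 5, when present)
#'   marks an IC50 label; default TRUE with no distinction made downstream.
#' @return data.frame(id, pkd).
#' @export
read_affinity_index <- function(path, ic50_ok = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stopf("no data rows in %s", path)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  id <- vapply(parts, `[`, character(1), 1)
  pkd <- vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[min(4, length(p))]))
    if (!is.finite(v)) v <- suppressWarnings(as.numeric(p[2]))
    v
  }, numeric(1))
  if (!ic50_ok) {
    tag <- vapply(parts, function(p) if (length(p) >= 5) p[5] else "", character(1))
    keep <- !grepl("IC50", tag, ignore.case = TRUE)
    id <- id[keep]; pkd <- pkd[keep]
  }
  if (any(!is.finite(pkd))) stopf("non-numeric affinity in %s", path)
  data.frame(id = id, pkd = pkd, stringsAsFactors = FALSE)
}

## encode one complex for a given water mode; returns list(eg_b, eg_c, y)
.encode_sample <- function(cplx, mode, config, T = 6) {
  mk <- function(variant, prov) {
    g <- build_graph(cplx, variant = variant, water_provenance = prov, T = T)
    encode_graph(g, config)
  }
  sw <- function(prov) {
    any(cplx$waters$provenance == prov)
  }
  res <- switch(mode,
    full = {
      eb <- if (sw("hydramap")) mk("G_B", "hydramap") else mk("G_A", NULL)
      ec <- if (sw("rism")) mk("G_C", "rism") else mk("G_A", NULL)
      list(eb, ec)
    },
    no_water = {
      ea <- mk("G_A", NULL)
      list(ea, ea)
    },
    hydramap_only = {
      eb <- if (sw("hydramap")) mk("G_B", "hydramap") else mk("G_A", NULL)
      list(eb, eb)
    },
    rism_only = {
      ec <- if (sw("rism")) mk("G_C", "rism") else mk("G_A", NULL)
      list(ec, ec)
    },
    stopf("unknown ablation mode: %s", mode)
  )
  list(eg_b = res[[1]], eg_c = res[[2]], y = cplx$affinity_label)
}

#' Encode a dataset of complexes for one water mode
#'
#' @param complexes list of (pocket-extracted) [complex_structure()]s with
#'   finite affinity labels.
#' @param mode "full" (G_B + G_C), "no_water" (G_A twice), "hydramap_only",
#'   "rism_only" (surviving graph duplicated).
#' @param config a [model_config()].
#' @param T water edge threshold (A).
#' @return list of samples consumable by [train_model()].
#' @export
encode_dataset <- function(complexes, mode = "full", config = model_config(),
                           T = 6) {
  if (mode != "no_water") {
    provs <- unlist(lapply(complexes, function(cp) cp$waters$provenance))
    need <- switch(mode, full = c("hydramap", "rism"),
                   hydramap_only = "hydramap", rism_only = "rism")
    for (p in need) if (!any(provs == p))
      warnf("mode %s: no %s water sites anywhere in the dataset; graphs fall back to the protein-ligand topology",
            mode, p)
  }
  suppressWarnings(lapply(complexes, .encode_sample, mode = mode,
                          config = config, T = T))
}

#' Train and evaluate one model per water-ablation mode
#'
#' For each requested mode the dataset is encoded accordingly, one seeded
#' model is trained on the identical train/test split, and test-set R_p and
#' RMSE are reported.
#'
#' @param complexes list of labelled, pocket-extracted complexes.
#' @param modes subset of c("full", "no_water", "hydramap_only", "rism_only").
#' @param config a [model_config()] (seed fixes init/shuffling for all modes).
#' @param test_fraction held-out fraction (seeded split; default 0.2).
#' @param T water edge threshold (A).
#' @return data.frame(mode, r_p, rmse, n_train, n_test).
#' @export
run_ablation <- function(complexes,
                         modes = c("full", "no_water", "hydramap_only", "rism_only"),
                         config = model_config(), test_fraction = 0.2, T = 6) {
  modes <- match.arg(modes, several.ok = TRUE)
  n <- length(complexes)
  set.seed(config$seed)
  test_idx <- sort(sample(n, max(1L, round(test_fraction * n))))
  train_idx <- setdiff(seq_len(n), test_idx)
  out <- NULL
  for (mode in modes) {
    enc <- encode_dataset(complexes, mode = mode, config = config, T = T)
    fit <- train_model(enc[train_idx], config = config)
    preds <- predict_affinity(fit$model, enc[test_idx])
    ys <- vapply(enc[test_idx], `[[`, numeric(1), "y")
    out <- rbind(out, data.frame(mode = mode,
                                 r_p = pearson_r(ys, preds),
                                 rmse = rmse(ys, preds),
                                 n_train = length(train_idx),
                                 n_test = length(test_idx),
                                 stringsAsFactors = FALSE))
  }
  out
}
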