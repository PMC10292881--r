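# Probe aggregation, batch correction, quantile normalization, modality
# harmonization and stratified splitting.

#' Aggregate probe-level methylation to TSS200 promoter gene features
#'
#' For each gene with at least one TSS200-annotated probe present in the
#' matrix, the gene feature is the arithmetic mean of that sample's
#' non-missing TSS200 probe beta values. Probes annotated to other regions
#' (TSS1500, Body, ...) are ignored; genes with no TSS200 probe are absent
#' from the output. Output feature order is sorted by gene id, so the result
#' is invariant to probe order in the input.
#'
#' @param probe_matrix Probe-level `omics_matrix` (beta values; `NA`
#'   permitted).
#' @param manifest A `probe_manifest`.
#' @param max_missing Maximum tolerated fraction of missing aggregated
#'   cells (a cell is missing when all of its TSS200 probes are `NA`).
#' @return A gene-level `omics_matrix` of beta values.
#' @export
aggregate_tss200 <- function(probe_matrix, manifest, max_missing = 0.05) {
  stopifnot(inherits(probe_matrix, "omics_matrix"),
            inherits(manifest, "probe_manifest"))
  tss <- manifest[manifest$region_class == "TSS200", , drop = FALSE]
  tss <- tss[tss$probe_id %in% colnames(probe_matrix$values), , drop = FALSE]
  if (!nrow(tss))
    stop("no TSS200-annotated probes present in the matrix")
  genes <- sort(unique(tss$gene_id))
  M <- probe_matrix$values[, tss$probe_id, drop = FALSE]
  G <- matrix(0, nrow(tss), length(genes),
              dimnames = list(tss$probe_id, genes))
  G[cbind(seq_len(nrow(tss)), match(tss$gene_id, genes))] <- 1
  present <- !is.na(M)
  M0 <- M; M0[!present] <- 0
  sums <- M0 %*% G
  counts <- present %*% G
  out <- sums / counts
  out[counts == 0] <- NA_real_
  miss_frac <- mean(is.na(out))
  if (miss_frac > max_missing)
    stop(sprintf("%.1f%% of aggregated cells are missing (limit %.1f%%)",
                 100 * miss_frac, 100 * max_missing))
  omics_matrix(out, probe_matrix$metadata)
}

#' Empirical-Bayes location/scale batch correction
#'
#' Parametric ComBat-style adjustment without covariates: per-gene
#' standardization against the batch-design fit, empirical-Bayes shrinkage
#' of per-batch location (normal prior) and scale (inverse-gamma prior)
#' estimated by method of moments with the standard iterative fixed point,
#' then back-transformation. A single batch is returned unchanged;
#' zero-variance genes are passed through uncorrected with a warning.
#'
#' @param x An `omics_matrix` (no missing values).
#' @param batch Batch labels, one per sample (default: metadata `batch`).
#' @param conv Convergence tolerance of the EB fixed-point iteration.
#' @return An `omics_matrix` with the same dimensions.
#' @export
combat_correct <- function(x, batch = x$metadata$batch, conv = 1e-6) {
  stopifnot(inherits(x, "omics_matrix"))
  if (anyNA(x$values)) stop("missing values are not allowed in combat_correct")
  batch <- as.character(batch)
  if (length(batch) != nrow(x$values))
    stop("one batch label per sample required")
  tab <- table(batch)
  if (any(tab < 2))
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (length(tab) < 2) return(x)          # one batch: identity

  Y <- t(x$values)                         # genes x samples
  batches <- names(tab)
  n_b <- as.numeric(tab[batches])
  N <- ncol(Y)
  idx <- lapply(batches, function(b) which(batch == b))

  batch_mean <- vapply(idx, function(i) rowMeans(Y[, i, drop = FALSE]),
                       numeric(nrow(Y)))
  batch_mean <- matrix(batch_mean, nrow = nrow(Y))
  grand <- as.numeric(batch_mean %*% (n_b / N))
  fitted <- matrix(0, nrow(Y), N)
  for (b in seq_along(batches)) fitted[, idx[[b]]] <- batch_mean[, b]
  var_pooled <- rowSums((Y - fitted)^2) / N

  flat <- var_pooled < 1e-12
  if (any(flat))
    warning(sum(flat), " zero-variance gene(s) passed through uncorrected")

  sdp <- sqrt(pmax(var_pooled, 1e-12))
  Z <- (Y - grand) / sdp

  Yadj <- Y
  for (b in seq_along(batches)) {
    Zb <- Z[, idx[[b]], drop = FALSE]
    g_hat <- rowMeans(Zb)
    d_hat <- apply(Zb, 1, stats::var)
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a_pr <- (2 * s2 + m^2) / s2
    b_pr <- (m * s2 + m^3) / s2
    g_star <- g_hat; d_star <- d_hat
    nb <- n_b[b]
    repeat {
      g_new <- (nb * t2 * g_hat + d_star * g_bar) / (nb * t2 + d_star)
      ss <- rowSums((Zb - g_new)^2)
      d_new <- (b_pr + 0.5 * ss) / (nb / 2 + a_pr - 1)
      change <- max(abs(g_new - g_star) / pmax(abs(g_star), 1e-8),
                    abs(d_new - d_star) / pmax(abs(d_star), 1e-8))
      g_star <- g_new; d_star <- d_new
      if (change < conv) break
    }
    Yadj[, idx[[b]]] <- sdp / sqrt(d_star) *
      (Z[, idx[[b]], drop = FALSE] - g_star) + grand
  }
  if (any(flat)) Yadj[flat, ] <- Y[flat, ]
  out <- x
  out$values <- t(Yadj)
  dimnames(out$values) <- dimnames(x$values)
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample's empirical distribution to the across-sample mean
#' of order statistics; within-sample rank order is preserved. Tied values
#' receive the mean of the reference quantiles over the tied ranks.
#'
#' @param x An `omics_matrix` (no missing values).
#' @return An `omics_matrix` with identical per-sample distributions.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  V <- x$values
  if (anyNA(V)) stop("missing values are not allowed in quantile_normalize")
  sorted <- t(apply(V, 1, sort))
  ref <- colMeans(sorted)
  cs <- cumsum(ref)
  out <- V
  for (i in seq_len(nrow(V))) {
    lo <- rank(V[i, ], ties.method = "min")
    hi <- rank(V[i, ], ties.method = "max")
    out[i, ] <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
  }
  x$values <- out
  x
}

#' Stack methylation and expression into one multimodal matrix
#'
#' Features are restricted to the intersection of gene ids; samples are
#' stacked with modality carried as a categorical covariate. Per-modality,
#' per-gene z-scaling statistics are computed from training samples only
#' and attached as the `"scaling"` attribute; the returned values are
#' scaled. Constant genes get unit scale.
#'
#' @param meth Gene-level methylation `omics_matrix` (beta values).
#' @param expr Gene-level expression `omics_matrix` (normalized
#'   log-abundance).
#' @param train_ids Sample ids whose statistics define the scaling
#'   (default: all samples).
#' @return A stacked, scaled `omics_matrix` with a `"scaling"` attribute.
#' @export
harmonize_modalities <- function(meth, expr, train_ids = NULL) {
  stopifnot(inherits(meth, "omics_matrix"), inherits(expr, "omics_matrix"))
  genes <- intersect(colnames(meth$values), colnames(expr$values))
  if (!length(genes)) stop("empty gene intersection between modalities")
  genes <- sort(genes)
  keep_cols <- c("sample_id", "age", "tissue", "batch", "modality", "label")
  meta <- rbind(meth$metadata[, intersect(keep_cols, names(meth$metadata))],
                expr$metadata[, intersect(keep_cols, names(expr$metadata))])
  vals <- rbind(meth$values[, genes, drop = FALSE],
                expr$values[, genes, drop = FALSE])
  rownames(vals) <- meta$sample_id
  if (is.null(train_ids)) train_ids <- meta$sample_id
  scaling <- list()
  for (mod in unique(meta$modality)) {
    rows <- meta$modality == mod & meta$sample_id %in% train_ids
    if (!any(rows)) stop("no training samples for modality ", mod)
    mu <- colMeans(vals[rows, , drop = FALSE])
    sd <- apply(vals[rows, , drop = FALSE], 2, stats::sd)
    sd[!is.finite(sd) | sd < 1e-12] <- 1
    scaling[[mod]] <- list(mean = mu, sd = sd)
    mrows <- meta$modality == mod
    vals[mrows, ] <- sweep(sweep(vals[mrows, , drop = FALSE], 2, mu), 2, sd, "/")
  }
  out <- omics_matrix(vals, meta, check_beta = FALSE)
  attr(out, "scaling") <- scaling
  out
}

make_strata <- function(metadata, strata) {
  miss <- setdiff(strata, names(metadata))
  if (length(miss)) stop("strata column(s) missing: ", paste(miss, collapse = ", "))
  apply(metadata[, strata, drop = FALSE], 1, paste, collapse = "/")
}

#' Stratified train/test split with largest-remainder rounding
#'
#' The global test count is `round(n * test_fraction)`; per-stratum counts
#' are the largest-remainder apportionment of that total, so every stratum's
#' test fraction is within one sample of the global fraction. Deterministic
#' under `seed`.
#'
#' @param metadata Per-sample metadata (needs `sample_id` and the strata
#'   columns).
#' @param test_fraction Test fraction in (0, 1); default 0.2.
#' @param strata Character vector of metadata columns; default `"tissue"`.
#' @param seed Integer seed.
#' @return A `split_plan` with `train_ids` and `test_ids`.
#' @export
split_stratified <- function(metadata, test_fraction = 0.2,
                             strata = "tissue", seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  lab <- make_strata(metadata, strata)
  tab <- table(lab)
  if (any(tab < 2))
    stop("stratum with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  sizes <- as.numeric(tab)
  names(sizes) <- names(tab)
  total <- round(sum(sizes) * test_fraction)
  quota <- sizes * test_fraction
  base <- pmin(floor(quota), sizes - 1)
  rem <- total - sum(base)
  frac <- quota - floor(quota)
  ord <- order(-frac, names(sizes))           # deterministic tie-break
  counts <- base
  k <- 1
  while (rem > 0) {
    s <- ord[(k - 1) %% length(ord) + 1]
    if (counts[s] < sizes[s] - 1) { counts[s] <- counts[s] + 1; rem <- rem - 1 }
    k <- k + 1
  }
  test_ids <- local_seed(seed, {
    unlist(lapply(names(sizes), function(s) {
      ids <- metadata$sample_id[lab == s]
      sample(ids, counts[s])
    }), use.names = FALSE)
  })
  structure(list(train_ids = setdiff(metadata$sample_id, test_ids),
                 test_ids = test_ids, strata = strata,
                 test_fraction = test_fraction),
            class = "split_plan")
}

#' Stratified k-fold assignment
#'
#' Within each stratum samples are shuffled and dealt to folds cyclically,
#' so per-stratum fold sizes differ by at most one. Strata smaller than `k`
#' are merged into one pooled stratum (with a message).
#'
#' @param metadata Per-sample metadata.
#' @param k Number of folds (`>= 2`); default 5.
#' @param strata Metadata columns; default tissue and modality.
#' @param seed Integer seed.
#' @return A `split_plan` with a named `folds` integer vector.
#' @export
kfold_stratified <- function(metadata, k = 5,
                             strata = c("tissue", "modality"), seed = 1) {
  if (k < 2) stop("k must be at least 2")
  lab <- make_strata(metadata, strata)
  tab <- table(lab)
  small <- names(tab)[tab < k]
  if (length(small)) {
    message("merging ", length(small), " stratum/strata smaller than k into a pooled stratum")
    lab[lab %in% small] <- ".pooled"
  }
  folds <- local_seed(seed, {
    f <- integer(nrow(metadata))
    names(f) <- metadata$sample_id
    for (s in unique(lab)) {
      ids <- metadata$sample_id[lab == s]
      ids <- sample(ids)
      f[ids] <- rep_len(seq_len(k), length(ids))
    }
    f
  })
  structure(list(train_ids = metadata$sample_id, test_ids = character(0),
                 folds = folds, strata = strata, k = k),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  if (!is.null(x$folds))
    cat(sprintf("<split_plan> %d-fold CV over %d samples (strata: %s)\n",
                x$k, length(x$folds), paste(x$strata, collapse = ", ")))
  else
    cat(sprintf("<split_plan> %d train / %d test (fraction %.2f, strata: %s)\n",
                length(x$train_ids), length(x$test_ids), x$test_fraction,
                paste(x$strata, collapse = ", ")))
  invisible(x)
}
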