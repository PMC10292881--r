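make_probe_fixture <- function() {
  vals <- matrix(c(0.10, 0.30, 0.50, 0.90, 0.20,
                   0.20, 0.40, 0.60, 0.80, 0.40), 2, 5, byrow = TRUE,
                 dimnames = list(c("S1", "S2"),
                                 c("p1", "p2", "p3", "p4", "p5")))
  meta <- data.frame(sample_id = c("S1", "S2"), age = c(30, 40),
                     tissue = "T1", batch = "B1", modality = "methylation",
                     label = "none", stringsAsFactors = FALSE)
  man <- probe_manifest(data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    gene_id = c("gB", "gB", "gA", "gB", "gA"),
    region_class = c("TSS200", "TSS200", "TSS200", "Body", "TSS200")))
  list(om = omics_matrix(vals, meta), man = man)
}

test_that("TSS200 aggregation averages promoter probes and ignores the rest", {
  fx <- make_probe_fixture()
  g <- aggregate_tss200(fx$om, fx$man)
  expect_equal(colnames(g$values), c("gA", "gB"))  # sorted gene order
  # gA = mean(p3, p5); gB = mean(p1, p2); p4 (Body) ignored
  expect_equal(g$values["S1", ], c(gA = mean(c(0.5, 0.2)), gB = mean(c(0.1, 0.3))))
  expect_equal(g$values["S2", ], c(gA = mean(c(0.6, 0.4)), gB = mean(c(0.2, 0.4))))
  # probe-order invariance
  perm <- fx$om
  perm$values <- perm$values[, c(5, 3, 1, 4, 2)]
  expect_equal(aggregate_tss200(perm, fx$man)$values, g$values)
})

test_that("TSS200 aggregation is NA-aware and bounds overall missingness", {
  fx <- make_probe_fixture()
  fx$om$values["S1", "p3"] <- NA     # gA for S1 = p5 alone
  g <- aggregate_tss200(fx$om, fx$man, max_missing = 0.5)
  expect_equal(g$values["S1", "gA"], 0.2)
  fx$om$values["S1", "p5"] <- NA     # both gA probes gone -> NA cell
  expect_equal(aggregate_tss200(fx$om, fx$man, max_missing = 0.5)$values["S1", "gA"],
               NA_real_)
  expect_error(aggregate_tss200(fx$om, fx$man, max_missing = 0.1), "missing")
})

test_that("batch correction with a single batch is the identity", {
  spec <- cohort_spec(n_per_modality = 40, n_genes = 15, n_age_genes = 3,
                      n_batches = 1, seed = 31)
  ex <- simulate_cohort(spec)$expression
  ex$values <- log2(ex$values + 1)
  expect_identical(combat_correct(ex)$values, ex$values)
})

test_that("batch correction matches the reference implementation", {
  spec <- cohort_spec(n_per_modality = 60, n_genes = 40, n_age_genes = 8,
                      n_batches = 2, seed = 37)
  ex <- simulate_cohort(spec)$expression
  ex$values <- log2(ex$values + 1)
  ours <- combat_correct(ex)$values
  ref <- t(sva::ComBat(t(ex$values), batch = ex$metadata$batch,
                       mean.only = FALSE, prior.plots = FALSE))
  expect_lt(max(abs(ours - ref)), 1e-4)
  expect_gt(cor(as.numeric(ours), as.numeric(ref)), 0.999999)
})

test_that("batch correction removes a uniform location shift", {
  # two batches differing only by a constant shift on every gene
  n <- 200; G <- 60; delta <- 1
  vals <- multiclock:::local_seed(43,
    matrix(rnorm(2 * n * G, 5, 0.7), 2 * n, G))
  vals[(n + 1):(2 * n), ] <- vals[(n + 1):(2 * n), ] + delta
  dimnames(vals) <- list(sprintf("S%03d", seq_len(2 * n)),
                         sprintf("g%02d", seq_len(G)))
  meta <- data.frame(sample_id = rownames(vals),
                     batch = rep(c("B1", "B2"), each = n),
                     modality = "expression", stringsAsFactors = FALSE)
  om <- omics_matrix(vals, meta, check_beta = FALSE)
  corr <- combat_correct(om)
  b <- meta$batch
  shift_after <- colMeans(corr$values[b == "B2", ]) -
    colMeans(corr$values[b == "B1", ])
  expect_lt(mean(abs(shift_after)), 0.05 * delta)
})

test_that("batch correction compresses a planted variance ratio", {
  n <- 300; G <- 80
  vals <- multiclock:::local_seed(44,
    rbind(matrix(rnorm(n * G, 3, 1), n, G),
          matrix(rnorm(n * G, 3, 2), n, G)))   # variance ratio 4
  dimnames(vals) <- list(sprintf("S%03d", seq_len(2 * n)),
                         sprintf("g%02d", seq_len(G)))
  meta <- data.frame(sample_id = rownames(vals),
                     batch = rep(c("B1", "B2"), each = n),
                     modality = "expression", stringsAsFactors = FALSE)
  corr <- combat_correct(omics_matrix(vals, meta, check_beta = FALSE))
  vr <- apply(corr$values[meta$batch == "B2", ], 2, var) /
    apply(corr$values[meta$batch == "B1", ], 2, var)
  expect_gte(mean(vr >= 0.8 & vr <= 1.25), 0.95)
})

test_that("batch correction flags degenerate inputs", {
  vals <- matrix(rnorm(40), 8, 5,
                 dimnames = list(paste0("S", 1:8), paste0("g", 1:5)))
  vals[, 3] <- 7                       # zero-variance gene
  meta <- data.frame(sample_id = paste0("S", 1:8),
                     batch = rep(c("B1", "B2"), each = 4),
                     modality = "expression", stringsAsFactors = FALSE)
  om <- omics_matrix(vals, meta, check_beta = FALSE)
  expect_warning(out <- combat_correct(om), "zero-variance")
  expect_equal(out$values[, 3], vals[, 3])
  meta2 <- meta; meta2$batch <- c(rep("B1", 7), "B2")
  om2 <- omics_matrix(vals, meta2, check_beta = FALSE)
  expect_error(suppressWarnings(combat_correct(om2)), "fewer than 2")
  omna <- om; omna$values[1, 1] <- NA
  expect_error(combat_correct(omna), "missing values")
})

qn_fixture <- function(vals) {
  meta <- data.frame(sample_id = rownames(vals), modality = "expression",
                     stringsAsFactors = FALSE)
  omics_matrix(vals, meta, check_beta = FALSE)
}

test_that("quantile normalization equalizes distributions on a hand example", {
  vals <- matrix(c(1, 2, 3,
                   4, 5, 6), 2, 3, byrow = TRUE,
                 dimnames = list(c("S1", "S2"), c("g1", "g2", "g3")))
  out <- quantile_normalize(qn_fixture(vals))$values
  expect_equal(out["S1", ], c(g1 = 2.5, g2 = 3.5, g3 = 4.5))
  expect_equal(out["S2", ], c(g1 = 2.5, g2 = 3.5, g3 = 4.5))
})

test_that("tied values receive the mean of the tied reference quantiles", {
  vals <- matrix(c(1, 1, 2,
                   0, 2, 4), 2, 3, byrow = TRUE,
                 dimnames = list(c("S1", "S2"), c("g1", "g2", "g3")))
  out <- quantile_normalize(qn_fixture(vals))$values
  # reference quantiles: (0.5, 1.5, 3); S1 ties at ranks 1-2 -> mean(0.5, 1.5)
  expect_equal(out["S1", ], c(g1 = 1, g2 = 1, g3 = 3))
  expect_equal(out["S2", ], c(g1 = 0.5, g2 = 1.5, g3 = 3))
})

test_that("quantile normalization matches limma and is idempotent", {
  spec <- cohort_spec(n_per_modality = 50, n_genes = 30, n_age_genes = 5,
                      seed = 47)
  ex <- simulate_cohort(spec)$expression
  ex$values <- log2(ex$values + 1)
  ours <- quantile_normalize(ex)
  ref <- t(limma::normalizeQuantiles(t(ex$values), ties = TRUE))
  expect_lt(max(abs(ours$values - ref)), 1e-10)
  # every sample now has the same sorted profile
  sorted <- t(apply(ours$values, 1, sort))
  expect_lt(max(abs(sweep(sorted, 2, sorted[1, ]))), 1e-10)
  # idempotence (tie-free draws): second pass changes nothing
  expect_equal(quantile_normalize(ours)$values, ours$values)
})

test_that("modality harmonization intersects genes and scales on train only", {
  mv <- matrix(runif(12), 4, 3,
               dimnames = list(paste0("m", 1:4), c("gA", "gB", "gC")))
  ev <- matrix(rnorm(8), 4, 2,
               dimnames = list(paste0("e", 1:4), c("gB", "gA")))
  mm <- data.frame(sample_id = paste0("m", 1:4), modality = "methylation",
                   stringsAsFactors = FALSE)
  em <- data.frame(sample_id = paste0("e", 1:4), modality = "expression",
                   stringsAsFactors = FALSE)
  st <- harmonize_modalities(omics_matrix(mv, mm),
                             omics_matrix(ev, em, check_beta = FALSE),
                             train_ids = c("m1", "m2", "m3", "e1", "e2", "e3"))
  expect_equal(colnames(st$values), c("gA", "gB"))   # intersection, sorted
  expect_equal(rownames(st$values), c(paste0("m", 1:4), paste0("e", 1:4)))
  sc <- attr(st, "scaling")
  expect_equal(sc$methylation$mean, colMeans(mv[1:3, c("gA", "gB")]))
  expect_equal(sc$expression$sd,
               apply(ev[1:3, c("gA", "gB")], 2, sd)[c("gA", "gB")],
               ignore_attr = TRUE)
  # returned values are the scaled ones
  expect_equal(st$values["m1", "gA"],
               (mv["m1", "gA"] - sc$methylation$mean["gA"]) /
                 sc$methylation$sd["gA"], ignore_attr = TRUE)
  # test rows never leak into the statistics
  mv2 <- mv; mv2["m4", ] <- mv["m4", ] + 100
  st2 <- harmonize_modalities(omics_matrix(mv2, mm, check_beta = FALSE),
                              omics_matrix(ev, em, check_beta = FALSE),
                              train_ids = c("m1", "m2", "m3", "e1", "e2", "e3"))
  expect_identical(attr(st2, "scaling"), sc)
  # disjoint gene sets are an error
  ev2 <- ev; colnames(ev2) <- c("gX", "gY")
  expect_error(harmonize_modalities(omics_matrix(mv, mm),
                                    omics_matrix(ev2, em, check_beta = FALSE)),
               "intersection")
})

test_that("stratified split apportions test counts by largest remainder", {
  meta <- data.frame(sample_id = sprintf("S%02d", 1:20),
                     tissue = rep(c("T1", "T2"), c(7, 13)),
                     stringsAsFactors = FALSE)
  sp <- split_stratified(meta, 0.2, "tissue", seed = 5)
  # quotas 1.4 and 2.6 for a total of 4 -> 1 and 3 by largest remainder
  n_test <- table(meta$tissue[match(sp$test_ids, meta$sample_id)])
  expect_equal(as.numeric(n_test[c("T1", "T2")]), c(1, 3))
  # exact partition, no overlap, deterministic
  expect_setequal(c(sp$train_ids, sp$test_ids), meta$sample_id)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_identical(split_stratified(meta, 0.2, "tissue", seed = 5)$test_ids,
                   sp$test_ids)
  expect_false(identical(split_stratified(meta, 0.2, "tissue", seed = 6)$test_ids,
                         sp$test_ids))
  expect_error(split_stratified(meta, 1.2), "\\(0, 1\\)")
  expect_error(split_stratified(meta, 0.2, "missing_col"), "missing_col")
})

test_that("every stratum's test fraction stays within one sample of global", {
  spec <- cohort_spec(n_per_modality = 123, n_genes = 10, n_age_genes = 2,
                      seed = 53)
  sim <- simulate_cohort(spec)
  meta <- rbind(sim$methylation$metadata, sim$expression$metadata)
  sp <- split_stratified(meta, 0.2, c("tissue", "modality"), seed = 7)
  lab <- paste(meta$tissue, meta$modality, sep = "/")
  for (s in unique(lab)) {
    n_s <- sum(lab == s)
    t_s <- sum(lab[match(sp$test_ids, meta$sample_id)] == s)
    expect_lte(abs(t_s - 0.2 * n_s), 1)
  }
})

test_that("k-fold assignment deals evenly and pools small strata", {
  meta <- data.frame(sample_id = sprintf("S%02d", 1:15),
                     tissue = rep(c("T1", "T2"), c(6, 9)),
                     stringsAsFactors = FALSE)
  kf <- kfold_stratified(meta, k = 3, strata = "tissue", seed = 2)
  tab <- table(meta$tissue, kf$folds[meta$sample_id])
  expect_equal(as.numeric(tab["T1", ]), c(2, 2, 2))
  expect_equal(as.numeric(tab["T2", ]), c(3, 3, 3))
  meta2 <- rbind(meta, data.frame(sample_id = "S16", tissue = "T3"))
  expect_message(kf2 <- kfold_stratified(meta2, k = 3, strata = "tissue",
                                         seed = 2), "pooled")
  expect_true(all(table(kf2$folds) >= 1))
  expect_error(kfold_stratified(meta, k = 1), "at least 2")
})
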