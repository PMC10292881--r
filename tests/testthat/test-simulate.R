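test_that("cohort generation is deterministic and respects the beta support", {
  spec <- cohort_spec(n_per_modality = 50, n_genes = 20, n_age_genes = 5,
                      seed = 7)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$methylation$values, b$methylation$values)
  expect_identical(a$expression$values, b$expression$values)
  expect_true(all(a$methylation$values >= 0 & a$methylation$values <= 1))
  expect_true(all(is.finite(a$expression$values)) &&
                all(a$expression$values > 0))
  # probe structure: >= 2 TSS200 probes per gene plus decoys
  tss <- a$manifest[a$manifest$region_class == "TSS200", ]
  expect_true(all(table(tss$gene_id) >= 2))
  expect_true(any(a$manifest$region_class != "TSS200"))
  expect_error(cohort_spec(n_genes = 10, n_age_genes = 11), "exceeds")
})

test_that("zero effect size leaves no gene age-correlated beyond the null", {
  spec <- cohort_spec(n_per_modality = 200, n_genes = 100, n_age_genes = 0,
                      effect_size = 0, seed = 13)
  sim <- simulate_cohort(spec)
  r <- abs(cor(sim$expression$metadata$age, log(sim$expression$values)))
  # Bonferroni-corrected Fisher-z bound for the max null correlation
  bound <- tanh(qnorm(1 - 0.025 / ncol(sim$expression$values)) /
                  sqrt(nrow(sim$expression$values) - 3))
  expect_lt(max(r), bound * 1.1)
})

test_that("planted genes out-correlate decoys in both modalities", {
  spec <- cohort_spec(n_per_modality = 400, n_genes = 500, n_age_genes = 50,
                      effect_size = 1, noise_sd = 0.5, seed = 17)
  sim <- simulate_cohort(spec)
  planted <- sim$truth$age_gene_ids
  gene <- aggregate_tss200(sim$methylation, sim$manifest)
  expr <- sim$expression
  expr$values <- log(expr$values)
  for (mat in list(gene, expr)) {
    r <- abs(cor(mat$metadata$age, mat$values))[1, ]
    names(r) <- colnames(mat$values)
    decoys <- setdiff(names(r), planted)
    expect_gt(mean(r[planted]), quantile(r[decoys], 0.95))
  }
})

test_that("case-control cohorts match arms and plant a learnable signal", {
  spec <- cohort_spec(n_per_modality = 50, n_genes = 60, n_age_genes = 15,
                      seed = 19)
  cc <- simulate_case_control(spec, n_case = 200, n_control = 200,
                              disease_effect = 2, overlap_fraction = 1)
  expect_true(all(cc$truth$disease_gene_ids %in% cc$truth$age_gene_ids))
  lab <- cc$data$metadata$label
  expect_equal(cc$data$metadata$age[lab == "case"],
               cc$data$metadata$age[lab == "control"])   # matched ages
  # oracle: logistic regression on the true disease genes separates arms
  X <- log(cc$data$values[, cc$truth$disease_gene_ids])
  y <- as.integer(lab == "case")
  tr <- c(1:150, 201:350); te <- setdiff(seq_along(y), tr)
  fitg <- suppressWarnings(glm(y ~ ., family = binomial(),
                               data = data.frame(y = y, X)[tr, ]))
  p <- suppressWarnings(predict(fitg, data.frame(X)[te, ], type = "response"))
  auc <- as.numeric(pROC::auc(pROC::roc(y[te], p, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_gt(auc, 0.9)
  expect_error(simulate_case_control(spec, n_case = 1), "at least 2")
})

test_that("no disease effect means chance-level separability", {
  spec <- cohort_spec(n_per_modality = 50, n_genes = 40, n_age_genes = 10,
                      seed = 23)
  cc <- simulate_case_control(spec, n_case = 100, n_control = 100,
                              disease_effect = 0, overlap_fraction = 1)
  lab <- cc$data$metadata$label
  # per-gene t statistics on the disease genes stay null
  tstat <- apply(log(cc$data$values[, cc$truth$disease_gene_ids]), 2,
                 function(v) t.test(v[lab == "case"], v[lab == "control"])$statistic)
  expect_lt(mean(abs(tstat) > 2), 0.15)
})

test_that("trajectory latent age is strictly monotone in the chosen direction", {
  spec <- cohort_spec(n_per_modality = 30, n_genes = 30, n_age_genes = 10,
                      seed = 29)
  rej <- simulate_trajectory(spec, "rejuvenation", n_timepoints = 5,
                             n_replicates = 2)
  la <- tapply(rej$metadata$latent_age, rej$metadata$time, unique)
  expect_true(all(diff(unlist(la)) < 0))
  mat <- simulate_trajectory(spec, "maturation", n_timepoints = 5,
                             n_replicates = 2)
  la2 <- tapply(mat$metadata$latent_age, mat$metadata$time, unique)
  expect_true(all(diff(unlist(la2)) > 0))
  expect_error(simulate_trajectory(spec, "sideways"), "arg")
  expect_error(simulate_trajectory(spec, "maturation", n_timepoints = 2),
               "3 timepoints")
  # near-zero noise: per-gene trend sign equals the planted slope sign
  spec0 <- cohort_spec(n_per_modality = 30, n_genes = 30, n_age_genes = 10,
                       noise_sd = 1e-4, seed = 29)
  m0 <- simulate_trajectory(spec0, "maturation", n_timepoints = 5,
                            n_replicates = 2)
  slopes <- simulate_cohort(spec0)$truth$slopes
  planted <- names(which(abs(slopes) > 0))
  trend <- apply(m0$values[, planted], 2,
                 function(v) coef(lm(v ~ m0$metadata$time))[2])
  expect_equal(sign(trend), sign(slopes[planted]), ignore_attr = TRUE)
})
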