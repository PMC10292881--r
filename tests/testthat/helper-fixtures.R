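# Shared fixtures. Heavy objects (the study-scale clock, its attributions,
# the transfer classifier) are built once per test run and cached.

.fx <- new.env(parent = emptyenv())

# Standard preprocessing chain: TSS200 aggregation; log2(TPM+1), batch
# correction and quantile normalization for expression; tissue-stratified
# 80/20 split; harmonized stacking with train-only scaling.
preprocess_cohort <- function(spec, split_seed = 1) {
  sim <- simulate_cohort(spec)
  mg <- aggregate_tss200(sim$methylation, sim$manifest)
  ex <- sim$expression
  ex$values <- log2(ex$values + 1)
  ex <- quantile_normalize(combat_correct(ex))
  meta <- rbind(mg$metadata, ex$metadata)
  sp <- split_stratified(meta, 0.2, "tissue", split_seed)
  st <- harmonize_modalities(mg, ex, sp$train_ids)
  list(sim = sim, meth_gene = mg, expr = ex, meta = meta,
       split = sp, stacked = st)
}

small_config <- function(seed = 3, max_epochs = 150, patience = 25) {
  clock_config(d_embed = 8, n_heads = 2, n_blocks = 1,
               head_hidden = c(32, 128, 32), max_epochs = max_epochs,
               patience = patience, seed = seed)
}

const_mae <- function(pp) {
  tr <- pp$meta$age[match(pp$split$train_ids, pp$meta$sample_id)]
  te <- pp$meta$age[match(pp$split$test_ids, pp$meta$sample_id)]
  mean(abs(te - mean(tr)))
}

# Study-scale conditions: 500 genes, 50 planted age genes, 600 stacked
# samples, default effect size and noise.
study_fixture <- function() {
  if (is.null(.fx$study)) {
    pp <- preprocess_cohort(cohort_spec(seed = 11))
    fit <- multiclock(pp$stacked, pp$split,
                      clock_config(max_epochs = 300, seed = 2))
    .fx$study <- c(pp, list(fit = fit))
  }
  .fx$study
}

study_attribution <- function() {
  if (is.null(.fx$attr)) {
    fx <- study_fixture()
    test <- fx$stacked[fx$split$test_ids, ]
    attr(test, "prescaled") <- TRUE
    bg_ids <- multiclock:::local_seed(99, sample(fx$split$train_ids, 100))
    bg <- fx$stacked[bg_ids, ]
    attr(bg, "prescaled") <- TRUE
    .fx$attr <- shapley_attribute(fx$fit, test[seq_len(60), ], bg,
                                  n_permutations = 8, seed = 9)
  }
  .fx$attr
}

study_classifier <- function() {
  if (is.null(.fx$clf)) {
    fx <- study_fixture()
    cc <- simulate_case_control(cohort_spec(seed = 11), n_case = 200,
                                n_control = 200, disease_effect = 2,
                                overlap_fraction = 1)
    dat <- cc$data
    dat$values <- log2(dat$values + 1)
    clf <- train_classifier(freeze_and_head(fx$fit), dat, seed = 4)
    .fx$clf <- list(clf = clf, truth = cc$truth, data = dat)
  }
  .fx$clf
}

# Small trained clock on an 8-gene cohort: cheap enough for exhaustive
# Shapley enumeration and checkpoint round-trips.
tiny_clock <- function() {
  if (is.null(.fx$tiny)) {
    pp <- preprocess_cohort(cohort_spec(n_per_modality = 60, n_genes = 8,
                                        n_age_genes = 4, seed = 41))
    fit <- multiclock(pp$stacked, pp$split,
                      clock_config(d_embed = 4, n_heads = 2, n_blocks = 1,
                                   head_hidden = c(16, 32, 16),
                                   max_epochs = 100, patience = 20, seed = 5))
    .fx$tiny <- c(pp, list(fit = fit))
  }
  .fx$tiny
}
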