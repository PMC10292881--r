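# End-to-end orchestration: simulate -> preprocess -> train -> transfer ->
# explain -> enrich -> trajectory, with one root seed, per-stage wall-clock
# timing and checksummed outputs.

#' Pipeline configuration
#'
#' One configuration object drives [run_pipeline()]; all randomness flows
#' from `seed` via fixed offsets per stage. Defaults reproduce the package
#' protocol: 80/20 tissue-stratified test split, 5-fold CV plan stratified
#' by tissue and modality, top-100 age genes, top-200 disease genes,
#' enrichment at raw p < 0.05.
#'
#' @param seed Root seed.
#' @param cohort Named list of [cohort_spec()] overrides.
#' @param clock Named list of [clock_config()] overrides.
#' @param case_control Named list of [simulate_case_control()] overrides
#'   (`n_case`, `n_control`, `disease_effect`, `overlap_fraction`).
#' @param test_fraction Hold-out fraction; default 0.2.
#' @param cv_folds Folds of the recorded CV plan; default 5.
#' @param run_cv Train one clock per fold and record fold MAEs (slow).
#' @param run_baseline Also train the from-scratch baseline classifier.
#' @param top_k_age,top_k_disease Ranked-list sizes; defaults 100 and 200.
#' @param enrichment_alpha Raw significance level; default 0.05.
#' @param n_explain Cap on the number of explained held-out samples.
#' @param n_permutations Shapley permutations per sample.
#' @param background_size Background subsample size; default 100.
#' @param trajectory Named list: `n_timepoints`, `n_replicates`.
#' @param resume Reuse existing stage outputs (checkpoint) when present.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, cohort = list(), clock = list(),
                            case_control = list(), test_fraction = 0.2,
                            cv_folds = 5, run_cv = FALSE,
                            run_baseline = TRUE, top_k_age = 100,
                            top_k_disease = 200, enrichment_alpha = 0.05,
                            n_explain = 60, n_permutations = 8,
                            background_size = 100,
                            trajectory = list(n_timepoints = 6, n_replicates = 4),
                            resume = FALSE) {
  structure(list(seed = as.integer(seed), cohort = cohort, clock = clock,
                 case_control = case_control, test_fraction = test_fraction,
                 cv_folds = cv_folds, run_cv = run_cv,
                 run_baseline = run_baseline, top_k_age = top_k_age,
                 top_k_disease = top_k_disease,
                 enrichment_alpha = enrichment_alpha, n_explain = n_explain,
                 n_permutations = n_permutations,
                 background_size = background_size, trajectory = trajectory,
                 resume = resume),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; unknown keys are an
#' error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

log2p1 <- function(tpm) log2(tpm + 1)

stage_msg <- function(quiet, ...) if (!quiet) message(...)

#' Run the full discovery pipeline on a synthetic cohort
#'
#' Executes the stages in order: cohort simulation, preprocessing (TSS200
#' aggregation; log2(TPM+1), batch correction and quantile normalization
#' for expression; stratified splitting; modality harmonization), clock
#' training, frozen-backbone transfer classification (with optional
#' from-scratch baseline), Shapley gene ranking with recovery against the
#' planted truth, gene-set enrichment of the top age genes, and trajectory
#' validation in both directions. Writes matrices, metrics JSON, gene
#' lists, the enrichment table and a checksummed run manifest under
#' `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return The run manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list(), outputs = list())
  t_all <- proc.time()[3]
  tick <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    res
  }
  out <- function(nm) file.path(out_dir, nm)

  # --- simulate -----------------------------------------------------------
  spec <- NULL
  sim <- tick("simulate", {
    spec <- do.call(cohort_spec, utils::modifyList(list(seed = config$seed),
                                                   config$cohort))
    sim <- simulate_cohort(spec)
    write_omics_matrix(sim$methylation, out("meth_probes.tsv"),
                       out("meth_meta.tsv"))
    write_omics_matrix(sim$expression, out("expr_tpm.tsv"),
                       out("expr_meta.tsv"))
    utils::write.table(as.data.frame(sim$manifest), out("manifest_probes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_ground_truth(sim$truth, out("ground_truth.json"))
    sim
  })
  gmt <- simulate_genesets(sim$truth)
  write_gmt(gmt, out("genesets.gmt"))

  # --- preprocess ---------------------------------------------------------
  pp <- tick("preprocess", {
    meth_gene <- aggregate_tss200(sim$methylation, sim$manifest)
    expr <- sim$expression
    expr$values <- log2p1(expr$values)
    expr <- quantile_normalize(combat_correct(expr))
    meta_all <- rbind(meth_gene$metadata[, c("sample_id", "age", "tissue",
                                             "batch", "modality", "label")],
                      expr$metadata[, c("sample_id", "age", "tissue",
                                        "batch", "modality", "label")])
    split <- split_stratified(meta_all, config$test_fraction, "tissue",
                              config$seed + 10L)
    folds <- kfold_stratified(meta_all, config$cv_folds,
                              c("tissue", "modality"), config$seed + 11L)
    jsonlite::write_json(list(train = split$train_ids, test = split$test_ids,
                              folds = as.list(folds$folds)),
                         out("split.json"), auto_unbox = TRUE)
    stacked <- harmonize_modalities(meth_gene, expr, split$train_ids)
    write_omics_matrix(stacked, out("stacked.tsv"), out("stacked_meta.tsv"))
    list(stacked = stacked, split = split, folds = folds,
         meth_gene = meth_gene, expr = expr)
  })

  # --- train --------------------------------------------------------------
  ckpt <- out("clock.ckpt")
  clk_cfg <- do.call(clock_config,
                     utils::modifyList(list(seed = config$seed + 20L,
                                            max_epochs = 200),
                                       config$clock))
  clock <- tick("train", {
    if (config$resume && file.exists(ckpt)) {
      stage_msg(quiet, "resuming: loading existing clock checkpoint")
      load_checkpoint(ckpt)
    } else {
      m <- multiclock(pp$stacked, pp$split, clk_cfg, quiet = quiet)
      save_checkpoint(m, ckpt)
      m
    }
  })
  jsonlite::write_json(lapply(clock$metrics, unclass), out("clock_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (config$run_cv) {
    cvm <- tick("cross_validate", {
      sapply(seq_len(config$cv_folds), function(f) {
        ids <- names(pp$folds$folds)
        plan <- structure(list(train_ids = ids[pp$folds$folds != f],
                               test_ids = ids[pp$folds$folds == f],
                               strata = pp$folds$strata, test_fraction = NA),
                          class = "split_plan")
        multiclock(pp$stacked, plan, clk_cfg, quiet = TRUE)$metrics$combined$mae
      })
    })
    jsonlite::write_json(list(fold_mae = cvm), out("cv_metrics.json"),
                         digits = NA)
  }

  # --- transfer -----------------------------------------------------------
  cc <- tick("transfer", {
    cc_args <- utils::modifyList(list(spec = spec, seed = config$seed + 30L),
                                 config$case_control)
    ccs <- do.call(simulate_case_control, cc_args)
    dat <- ccs$data
    dat$values <- log2p1(dat$values)
    clf <- freeze_and_head(clock, seed = config$seed + 31L)
    clf <- train_classifier(clf, dat, seed = config$seed + 32L)
    save_checkpoint(clf, out("classifier.ckpt"))
    res <- list(truth = ccs$truth, data = dat, clf = clf)
    if (config$run_baseline) {
      base_cfg <- do.call(clock_config,
                          utils::modifyList(list(seed = config$seed + 33L,
                                                 max_epochs = 60),
                                            config$clock))
      res$baseline <- train_baseline_classifier(dat, clf$split, base_cfg)
      res$comparison <- compare_classifiers(clf$metrics, res$baseline$metrics)
      utils::write.table(res$comparison, out("classifier_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(unclass(clf$metrics), out("classifier_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  # --- explain ------------------------------------------------------------
  expl <- tick("explain", {
    test_dat <- pp$stacked[pp$split$test_ids, ]
    attr(test_dat, "prescaled") <- TRUE
    ntake <- min(config$n_explain, nrow(test_dat$values))
    take <- local_seed(config$seed + 40L,
                       sample(test_dat$metadata$sample_id, ntake))
    bg_ids <- local_seed(config$seed + 41L,
                         sample(pp$split$train_ids,
                                min(config$background_size,
                                    length(pp$split$train_ids))))
    bg <- pp$stacked[bg_ids, ]
    attr(bg, "prescaled") <- TRUE
    at_age <- shapley_attribute(clock, test_dat[take, ], bg,
                                config$n_permutations, config$seed + 42L)
    top_age <- rank_genes(at_age, config$top_k_age)
    writeLines(top_age, out("top_age_genes.txt"))
    utils::write.table(
      data.frame(gene_id = names(sort(at_age$rank)),
                 mean_abs_attr = unname(at_age$aggregate[names(sort(at_age$rank))]),
                 rank = sort(at_age$rank)),
      out("attributions_age.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    # disease attributions from the transfer classifier (held-out cases)
    clf_split <- cc$clf$split
    dd <- cc$data[clf_split$test_ids, ]
    ntake2 <- min(config$n_explain, nrow(dd$values))
    take2 <- local_seed(config$seed + 43L,
                        sample(dd$metadata$sample_id, ntake2))
    bg2 <- cc$data[local_seed(config$seed + 44L,
                              sample(clf_split$train_ids,
                                     min(config$background_size,
                                         length(clf_split$train_ids)))), ]
    at_dis <- shapley_attribute(cc$clf, dd[take2, ], bg2,
                                config$n_permutations, config$seed + 45L)
    top_dis <- rank_genes(at_dis, config$top_k_disease)
    writeLines(top_dis, out("top_disease_genes.txt"))
    rec_age <- recovery_report(utils::head(names(sort(at_age$rank)),
                                           length(sim$truth$age_gene_ids)),
                               sim$truth$age_gene_ids)
    rec_dis <- recovery_report(utils::head(names(sort(at_dis$rank)),
                                           length(cc$truth$disease_gene_ids)),
                               cc$truth$disease_gene_ids)
    jsonlite::write_json(list(age = unclass(rec_age)[c("precision", "recall", "k")],
                              disease = unclass(rec_dis)[c("precision", "recall", "k")]),
                         out("recovery.json"), auto_unbox = TRUE, digits = NA)
    list(top_age = top_age, top_dis = top_dis, rec_age = rec_age,
         rec_dis = rec_dis)
  })

  # --- enrich -------------------------------------------------------------
  enr <- tick("enrich", {
    tab <- fisher_enrichment(expl$top_age, gmt, clock$feature_ids,
                             config$enrichment_alpha)
    utils::write.table(tab, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tab
  })

  # --- trajectory ---------------------------------------------------------
  traj <- tick("trajectory", {
    rej <- predict_trajectory(clock,
             simulate_trajectory(spec, "rejuvenation",
                                 config$trajectory$n_timepoints,
                                 config$trajectory$n_replicates,
                                 seed = config$seed + 50L))
    mat <- predict_trajectory(clock,
             simulate_trajectory(spec, "maturation",
                                 config$trajectory$n_timepoints,
                                 config$trajectory$n_replicates,
                                 seed = config$seed + 51L))
    jsonlite::write_json(list(rejuvenation_rho = rej$rho,
                              maturation_rho = mat$rho),
                         out("trajectory.json"), auto_unbox = TRUE, digits = NA)
    list(rejuvenation = rej, maturation = mat)
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$outputs <- as.list(tools::md5sum(files))
  names(manifest$outputs) <- basename(files)
  manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, clock = clock, classifier = cc$clf,
                 enrichment = enr, trajectory = traj, explain = expl))
}
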