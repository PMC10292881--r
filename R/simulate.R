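# Synthetic multimodal aging cohorts with planted, recorded ground truth.
# All randomness is local: the global RNG state is saved and restored.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Specify a synthetic multimodal aging cohort
#'
#' Defines the study conditions for the generator: cohort sizes, feature
#' count, the number of planted age-informative genes (shared across the
#' methylation and expression modalities), tissue/batch structure, the age
#' range, per-gene slope scale and noise level. Defaults describe a
#' desk-scale cohort of 600 stacked samples (300 per modality) with 500
#' genes, 50 of them age-informative.
#'
#' @param n_per_modality Samples per modality.
#' @param n_genes Number of genes.
#' @param n_age_genes Planted age-informative genes (`<= n_genes`).
#' @param n_tissues,n_batches Number of tissue and batch levels.
#' @param age_range Two increasing ages in years; ages drawn uniformly.
#' @param effect_size Scale of the per-gene age slope on the latent
#'   (logit-beta / log-TPM) scale per unit of centred-and-scaled age.
#' @param noise_sd Residual noise SD on the latent scale.
#' @param seed Integer seed; gene-level parameters are a deterministic
#'   function of it, so matched cohorts, case-control sets and trajectory
#'   courses share the same planted genes and slopes.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_modality = 300, n_genes = 500,
                        n_age_genes = 50, n_tissues = 3, n_batches = 2,
                        age_range = c(20, 80), effect_size = 1,
                        noise_sd = 0.5, seed = 1) {
  if (n_age_genes > n_genes)
    stop("n_age_genes (", n_age_genes, ") exceeds n_genes (", n_genes, ")")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("age_range must be two increasing ages")
  structure(list(n_per_modality = n_per_modality, n_genes = n_genes,
                 n_age_genes = n_age_genes, n_tissues = n_tissues,
                 n_batches = n_batches, age_range = age_range,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Gene-level parameters: a pure function of the spec (seeded by spec$seed).
# Batch 1 is the reference (no location shift, unit scale); batch effects
# follow the location-scale model that parametric ComBat assumes, and are
# applied to the expression modality only.
gene_params <- function(spec) {
  local_seed(spec$seed, {
    g <- sprintf("g%04d", seq_len(spec$n_genes))
    age_idx <- sort(sample.int(spec$n_genes, spec$n_age_genes))
    slope <- numeric(spec$n_genes)
    if (spec$n_age_genes > 0)
      slope[age_idx] <- spec$effect_size *
        stats::runif(spec$n_age_genes, 0.5, 1.5) *
        sample(c(-1, 1), spec$n_age_genes, replace = TRUE)
    names(slope) <- g
    mu_meth <- stats::runif(spec$n_genes, -1.5, 1.5)
    mu_expr <- stats::runif(spec$n_genes, 1, 6)
    tissue_off <- matrix(stats::rnorm(spec$n_genes * spec$n_tissues, 0, 0.3),
                         spec$n_genes, spec$n_tissues,
                         dimnames = list(g, sprintf("T%d", seq_len(spec$n_tissues))))
    batch_mu <- c(0, stats::rnorm(max(spec$n_batches - 1, 0), 0, 0.6))
    batch_s <- c(1, stats::runif(max(spec$n_batches - 1, 0), 0.8, 1.6))
    gamma <- sapply(seq_len(spec$n_batches), function(b)
      if (b == 1) rep(0, spec$n_genes) else stats::rnorm(spec$n_genes, batch_mu[b], 0.2))
    delta <- sapply(seq_len(spec$n_batches), function(b)
      if (b == 1) rep(1, spec$n_genes) else batch_s[b] * exp(stats::rnorm(spec$n_genes, 0, 0.1)))
    gamma <- matrix(gamma, spec$n_genes, spec$n_batches,
                    dimnames = list(g, sprintf("B%d", seq_len(spec$n_batches))))
    delta <- matrix(delta, spec$n_genes, spec$n_batches,
                    dimnames = dimnames(gamma))
    n_tss <- sample(2:3, spec$n_genes, replace = TRUE)
    probe_shift <- lapply(n_tss, function(k) stats::rnorm(k, 0, 0.3))
    list(gene_ids = g, age_idx = age_idx, slope = slope,
         mu_meth = mu_meth, mu_expr = mu_expr, tissue_off = tissue_off,
         gamma = gamma, delta = delta, n_tss = n_tss,
         probe_shift = probe_shift)
  })
}

age_center <- function(age, range) (age - mean(range)) / (diff(range) / 2)

#' Generate a multimodal aging cohort with planted age signal
#'
#' Methylation is generated at probe level: each gene carries 2-3 TSS200
#' probes whose beta values are a logistic transform of a Gaussian latent
#' whose mean drifts linearly with (centred) age for planted genes, plus a
#' non-age-informative Body decoy probe per gene. Expression is log-normal
#' TPM with a linear-in-age log-mean for the same planted genes, a
#' gene-specific tissue offset, and location-scale batch distortion on the
#' log scale.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `methylation` (probe-level `omics_matrix`),
#'   `expression` (TPM `omics_matrix`), `manifest` (`probe_manifest`) and
#'   `truth` (a `ground_truth` list recording planted gene ids, slopes and
#'   batch parameters).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gp <- gene_params(spec)
  n <- spec$n_per_modality
  local_seed(spec$seed + 1L, {
    # --- shared per-sample covariates, drawn independently per modality
    draw_meta <- function(prefix, modality) {
      data.frame(sample_id = sprintf("%s%04d", prefix, seq_len(n)),
                 age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
                 tissue = sprintf("T%d", sample.int(spec$n_tissues, n, replace = TRUE)),
                 batch = if (modality == "expression")
                   sprintf("B%d", sample.int(spec$n_batches, n, replace = TRUE))
                 else "B1",
                 modality = modality, label = "none",
                 stringsAsFactors = FALSE)
    }
    meta_me <- draw_meta("me", "methylation")
    meta_ex <- draw_meta("ex", "expression")

    latent <- function(meta, mu) {
      agec <- age_center(meta$age, spec$age_range)
      tix <- match(meta$tissue, colnames(gp$tissue_off))
      # n x G latent mean
      outer(agec, gp$slope) +
        matrix(mu, nrow(meta), spec$n_genes, byrow = TRUE) +
        t(gp$tissue_off[, tix, drop = FALSE])
    }

    # --- methylation at probe level
    z_me <- latent(meta_me, gp$mu_meth) +
      matrix(stats::rnorm(n * spec$n_genes, 0, spec$noise_sd), n)
    probe_cols <- list(); probe_ids <- character(0)
    man <- list()
    for (gi in seq_len(spec$n_genes)) {
      k <- gp$n_tss[gi]
      for (p in seq_len(k)) {
        pid <- sprintf("cg_%s_t%d", gp$gene_ids[gi], p)
        probe_ids <- c(probe_ids, pid)
        probe_cols[[pid]] <- stats::plogis(
          z_me[, gi] + gp$probe_shift[[gi]][p] +
            stats::rnorm(n, 0, spec$noise_sd / 2))
        man[[pid]] <- c(pid, gp$gene_ids[gi], "TSS200")
      }
      # decoy probe: gene body, no age signal
      pid <- sprintf("cg_%s_b1", gp$gene_ids[gi])
      probe_ids <- c(probe_ids, pid)
      probe_cols[[pid]] <- stats::plogis(
        gp$mu_meth[gi] + stats::rnorm(n, 0, spec$noise_sd))
      man[[pid]] <- c(pid, gp$gene_ids[gi], "Body")
    }
    meth_vals <- do.call(cbind, probe_cols)
    rownames(meth_vals) <- meta_me$sample_id
    manifest <- probe_manifest(data.frame(
      probe_id = vapply(man, `[`, "", 1),
      gene_id = vapply(man, `[`, "", 2),
      region_class = vapply(man, `[`, "", 3),
      stringsAsFactors = FALSE, row.names = NULL))

    # --- expression: log-scale latent + batch location/scale, then exp
    bix <- match(meta_ex$batch, colnames(gp$gamma))
    x_ex <- latent(meta_ex, gp$mu_expr) +
      t(gp$gamma[, bix, drop = FALSE]) +
      matrix(stats::rnorm(n * spec$n_genes, 0, spec$noise_sd), n) *
        t(gp$delta[, bix, drop = FALSE])
    tpm <- exp(x_ex)
    dimnames(tpm) <- list(meta_ex$sample_id, gp$gene_ids)

    truth <- structure(list(
      age_gene_ids = gp$gene_ids[gp$age_idx],
      disease_gene_ids = character(0),
      slopes = gp$slope,
      batch_location = gp$gamma, batch_scale = gp$delta,
      spec = spec), class = "ground_truth")

    list(methylation = omics_matrix(meth_vals, meta_me),
         expression = omics_matrix(tpm, meta_ex, check_beta = FALSE),
         manifest = manifest, truth = truth)
  })
}

#' Generate an age-matched case-control expression cohort
#'
#' Builds on the gene model of a [cohort_spec()]: case samples receive an
#' additive shift of `disease_effect * noise_sd` on the log-TPM scale at the
#' disease genes. `overlap_fraction` controls how many disease genes are
#' drawn from the planted age genes (1 = all, the aging-convergent
#' scenario). Ages and tissues are matched pairwise between arms.
#'
#' @param spec A [cohort_spec()] (defines genes, slopes, noise).
#' @param n_case,n_control Arm sizes (each `>= 2`).
#' @param disease_effect Case shift in units of `spec$noise_sd`.
#' @param overlap_fraction Fraction of disease genes taken from the planted
#'   age genes, in \[0, 1\].
#' @param n_disease_genes Number of disease genes (default: number of
#'   planted age genes).
#' @param seed Seed for the sample-level draws (gene parameters still come
#'   from `spec$seed`).
#' @return A list with `data` (labeled expression `omics_matrix`) and
#'   `truth` (`ground_truth` including `disease_gene_ids`).
#' @export
simulate_case_control <- function(spec, n_case = 200, n_control = 200,
                                  disease_effect = 2, overlap_fraction = 1,
                                  n_disease_genes = spec$n_age_genes,
                                  seed = spec$seed + 2L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n_case < 2 || n_control < 2)
    stop("need at least 2 samples per arm")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  gp <- gene_params(spec)
  local_seed(seed, {
    n_from_age <- round(overlap_fraction * n_disease_genes)
    n_from_age <- min(n_from_age, length(gp$age_idx))
    other <- setdiff(seq_len(spec$n_genes), gp$age_idx)
    n_other <- min(n_disease_genes - n_from_age, length(other))
    dis_idx <- sort(c(sample(gp$age_idx, n_from_age),
                      if (n_other > 0) sample(other, n_other)))
    n_pair <- max(n_case, n_control)
    ages <- stats::runif(n_pair, spec$age_range[1], spec$age_range[2])
    tissues <- sprintf("T%d", sample.int(spec$n_tissues, n_pair, replace = TRUE))
    meta <- data.frame(
      sample_id = c(sprintf("ca%04d", seq_len(n_case)),
                    sprintf("co%04d", seq_len(n_control))),
      age = c(ages[seq_len(n_case)], ages[seq_len(n_control)]),
      tissue = c(tissues[seq_len(n_case)], tissues[seq_len(n_control)]),
      batch = "B1", modality = "expression",
      label = rep(c("case", "control"), c(n_case, n_control)),
      stringsAsFactors = FALSE)
    agec <- age_center(meta$age, spec$age_range)
    tix <- match(meta$tissue, colnames(gp$tissue_off))
    x <- outer(agec, gp$slope) +
      matrix(gp$mu_expr, nrow(meta), spec$n_genes, byrow = TRUE) +
      t(gp$tissue_off[, tix, drop = FALSE]) +
      matrix(stats::rnorm(nrow(meta) * spec$n_genes, 0, spec$noise_sd), nrow(meta))
    shift <- disease_effect * spec$noise_sd
    x[meta$label == "case", dis_idx] <- x[meta$label == "case", dis_idx] + shift
    tpm <- exp(x)
    dimnames(tpm) <- list(meta$sample_id, gp$gene_ids)
    truth <- structure(list(
      age_gene_ids = gp$gene_ids[gp$age_idx],
      disease_gene_ids = gp$gene_ids[dis_idx],
      slopes = gp$slope, disease_shift = shift,
      spec = spec), class = "ground_truth")
    list(data = omics_matrix(tpm, meta, check_beta = FALSE), truth = truth)
  })
}

#' Generate a rejuvenation or maturation time-course
#'
#' Emulates reprogramming (iPSC induction: latent age decreases with time)
#' or fetal development (latent age increases) using the same gene model as
#' [simulate_cohort()], generated directly at gene level on the methylation
#' modality. The latent age at each timepoint is recorded in the metadata
#' (`latent_age`), alongside the `time` covariate.
#'
#' @param spec A [cohort_spec()].
#' @param direction `"rejuvenation"` or `"maturation"`.
#' @param n_timepoints Number of timepoints (`>= 3`).
#' @param n_replicates Replicates per timepoint.
#' @param seed Seed for the sample-level draws.
#' @return An `omics_matrix` of gene-level beta values with `time` metadata.
#' @export
simulate_trajectory <- function(spec, direction = c("rejuvenation", "maturation"),
                                n_timepoints = 6, n_replicates = 4,
                                seed = spec$seed + 3L) {
  stopifnot(inherits(spec, "cohort_spec"))
  direction <- match.arg(direction)
  if (n_timepoints < 3) stop("need at least 3 timepoints")
  gp <- gene_params(spec)
  lo <- spec$age_range[1] + 0.1 * diff(spec$age_range)
  hi <- spec$age_range[2] - 0.1 * diff(spec$age_range)
  latent_age <- if (direction == "rejuvenation")
    seq(hi, lo, length.out = n_timepoints)
  else seq(lo, hi, length.out = n_timepoints)
  local_seed(seed, {
    time <- rep(seq_len(n_timepoints), each = n_replicates)
    la <- latent_age[time]
    agec <- age_center(la, spec$age_range)
    nn <- length(time)
    z <- outer(agec, gp$slope) +
      matrix(gp$mu_meth, nn, spec$n_genes, byrow = TRUE) +
      matrix(stats::rnorm(nn * spec$n_genes, 0, spec$noise_sd), nn)
    beta <- stats::plogis(z)
    meta <- data.frame(
      sample_id = sprintf("tp%02d_r%02d", time, rep(seq_len(n_replicates), n_timepoints)),
      age = NA_real_, tissue = "T1", batch = "B1",
      modality = "methylation", label = "none",
      time = time, latent_age = la, stringsAsFactors = FALSE)
    dimnames(beta) <- list(meta$sample_id, gp$gene_ids)
    omics_matrix(beta, meta)
  })
}

#' Generate a synthetic gene-set library around planted ground truth
#'
#' One `age_signature` set holding the planted age genes plus decoy sets of
#' random genes, for exercising over-representation analysis end to end.
#'
#' @param truth A `ground_truth` object (for `age_gene_ids` and the
#'   universe).
#' @param n_decoy Number of decoy sets.
#' @param set_size Decoy set size.
#' @param seed Seed.
#' @return A `geneset_library`.
#' @export
simulate_genesets <- function(truth, n_decoy = 19, set_size = 25,
                              seed = truth$spec$seed + 4L) {
  universe <- names(truth$slopes)
  local_seed(seed, {
    sets <- c(list(age_signature = truth$age_gene_ids),
              stats::setNames(
                lapply(seq_len(n_decoy), function(i)
                  sample(universe, min(set_size, length(universe)))),
                sprintf("decoy_set_%02d", seq_len(n_decoy))))
    structure(sets, class = "geneset_library")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d age genes, %d disease genes, %d genes total\n",
              length(x$age_gene_ids), length(x$disease_gene_ids),
              length(x$slopes)))
  invisible(x)
}

#' Serialize ground truth to JSON
#'
#' @param truth A `ground_truth` object.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(age_gene_ids = truth$age_gene_ids,
              disease_gene_ids = truth$disease_gene_ids,
              slopes = as.list(truth$slopes))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
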