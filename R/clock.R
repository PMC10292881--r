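#' Configuration of the tabular-transformer age regressor
#'
#' Defaults reproduce the tuned optimum of the architecture: hidden head
#' layers of size 128, 2048 and 128, dropout 0, ELU activation, learning
#' rate 0.00023, AdamW with weight decay 0, and batch size 96. The
#' transformer trunk (categorical tokens for tissue and modality passing
#' through self-attention blocks) defaults to 2 blocks of 4 heads with
#' 16-dimensional embeddings; transformer-internal feedforward layers use
#' the ReLU form, the head uses ELU. Attention logits are scaled by
#' `sqrt(d_k)` by default; `attn_scale = "linear"` divides by `d_k`
#' instead.
#'
#' @param d_embed Categorical embedding width (multiple of `n_heads`).
#' @param n_heads,n_blocks Attention heads per block and block count.
#' @param head_hidden Hidden widths of the dense head.
#' @param dropout Dropout probability (default 0; nonzero not implemented —
#'   kept as an explicit configuration field).
#' @param activation Head activation (`"elu"`).
#' @param attn_scale `"sqrt"` or `"linear"` attention-logit scaling.
#' @param learning_rate,weight_decay,batch_size AdamW settings.
#' @param max_epochs,patience Early-stopping budget on validation MAE.
#' @param val_fraction Fraction of the training split held out for early
#'   stopping.
#' @param seed Integer seed governing initialization and batch order.
#' @return A `clock_config` list.
#' @export
clock_config <- function(d_embed = 16, n_heads = 4, n_blocks = 2,
                         head_hidden = c(128, 2048, 128), dropout = 0,
                         activation = "elu", attn_scale = c("sqrt", "linear"),
                         learning_rate = 0.00023, weight_decay = 0,
                         batch_size = 96, max_epochs = 500, patience = 20,
                         val_fraction = 0.2, seed = 1) {
  attn_scale <- match.arg(attn_scale)
  if (d_embed < 1) stop("d_embed must be positive")
  if (dropout != 0) stop("only dropout = 0 is supported")
  structure(list(d_embed = d_embed, n_heads = n_heads, n_blocks = n_blocks,
                 head_hidden = head_hidden, dropout = dropout,
                 activation = activation, attn_scale = attn_scale,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "clock_config")
}

# Tokenize tissue/modality metadata against a vocabulary; unknown tokens
# are an error rather than a silent "unknown" bucket.
tokenize <- function(metadata, vocab) {
  Z <- vapply(names(vocab), function(col) {
    ix <- match(metadata[[col]], vocab[[col]])
    if (anyNA(ix))
      stop("unknown ", col, " token(s): ",
           paste(unique(metadata[[col]][is.na(ix)]), collapse = ", "))
    ix
  }, integer(nrow(metadata)))
  matrix(Z, nrow = nrow(metadata))
}

carve_validation <- function(metadata, fraction, seed) {
  ok <- tryCatch(
    split_stratified(metadata, fraction, c("tissue", "modality"), seed),
    error = function(e) NULL)
  if (!is.null(ok)) return(ok$test_ids)
  n_val <- max(1, round(nrow(metadata) * fraction))
  local_seed(seed, sample(metadata$sample_id, n_val))
}

#' Fit the multimodal transformer aging clock
#'
#' Trains a tabular-transformer regressor of chronological age (years) on a
#' harmonized multimodal matrix (see [harmonize_modalities()]): tissue and
#' modality tokens pass through self-attention blocks, their contextual
#' embeddings are flattened and concatenated with the scaled continuous
#' gene features, and a 128-2048-128 ELU head with a final linear layer
#' predicts age. Training minimizes mean squared error with AdamW; the
#' checkpoint with the best validation MAE is returned, with early stopping.
#'
#' @param data A harmonized `omics_matrix` (scaled values, `"scaling"`
#'   attribute, ages present for all samples).
#' @param split A `split_plan` from [split_stratified()]; `NULL` fits an
#'   internal tissue-stratified 80/20 split.
#' @param config A [clock_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return An object of class `multiclock` with components `params`,
#'   `config`, `vocab`, `feature_ids`, `scaling`, `split`, `trainlog`,
#'   `metrics` (per-modality and combined test metrics) and `predictions`
#'   (held-out test predictions).
#' @export
multiclock <- function(data, split = NULL, config = clock_config(),
                       quiet = TRUE) {
  stopifnot(inherits(data, "omics_matrix"))
  meta <- data$metadata
  if (is.null(meta$age) || anyNA(meta$age))
    stop("ages must be present for all samples when fitting")
  if (is.null(meta$modality)) stop("modality metadata required")
  if (is.null(meta$tissue)) meta$tissue <- "T1"
  if (is.null(split))
    split <- split_stratified(meta, 0.2, "tissue", config$seed)
  vocab <- list(tissue = sort(unique(meta$tissue)),
                modality = sort(unique(meta$modality)))
  train_meta <- meta[meta$sample_id %in% split$train_ids, , drop = FALSE]
  val_ids <- carve_validation(train_meta, config$val_fraction,
                              config$seed + 7L)
  fit_ids <- setdiff(split$train_ids, val_ids)
  ix <- function(ids) match(ids, meta$sample_id)
  X <- data$values
  Z <- tokenize(meta, vocab)
  params <- init_params(config, ncol(X), lengths(vocab))
  # start the output at the mean training age: centres the regression
  L <- sum(grepl("^head\\d+_W$", names(params)))
  params[[paste0("head", L, "_b")]] <- mean(meta$age[ix(fit_ids)])
  tr <- train_network(params,
                      X[ix(fit_ids), , drop = FALSE],
                      Z[ix(fit_ids), , drop = FALSE],
                      meta$age[ix(fit_ids)],
                      X[ix(val_ids), , drop = FALSE],
                      Z[ix(val_ids), , drop = FALSE],
                      meta$age[ix(val_ids)],
                      config, loss = "mse", quiet = quiet)
  obj <- structure(list(params = tr$params, config = config, vocab = vocab,
                        feature_ids = colnames(X),
                        scaling = attr(data, "scaling"),
                        split = split, val_ids = val_ids,
                        trainlog = tr$log, best_epoch = tr$best_epoch,
                        trained = TRUE),
                   class = "multiclock")
  if (length(split$test_ids)) {
    ti <- ix(split$test_ids)
    pred <- nn_forward(tr$params, X[ti, , drop = FALSE],
                       Z[ti, , drop = FALSE], config)$out[, 1]
    names(pred) <- split$test_ids
    truth <- meta$age[ti]
    metrics <- list(combined = evaluate_regression(pred, truth))
    for (mod in vocab$modality) {
      sel <- meta$modality[ti] == mod
      if (sum(sel) >= 2)
        metrics[[mod]] <- evaluate_regression(pred[sel], truth[sel])
    }
    obj$predictions <- data.frame(sample_id = split$test_ids, age = truth,
                                  predicted = unname(pred),
                                  modality = meta$modality[ti],
                                  stringsAsFactors = FALSE)
    obj$metrics <- metrics
  }
  obj
}

# Apply stored per-modality scaling and predict on raw gene-level data.
scale_to_model <- function(object, data) {
  feats <- object$feature_ids
  miss <- setdiff(feats, colnames(data$values))
  if (length(miss))
    stop("newdata lacks model feature(s): ", paste(utils::head(miss, 5),
                                                   collapse = ", "),
         if (length(miss) > 5) " ...")
  V <- data$values[, feats, drop = FALSE]
  if (!isTRUE(attr(data, "prescaled"))) {
    for (mod in unique(data$metadata$modality)) {
      sc <- object$scaling[[mod]]
      if (is.null(sc)) stop("no stored scaling for modality ", mod)
      rows <- data$metadata$modality == mod
      V[rows, ] <- sweep(sweep(V[rows, , drop = FALSE], 2, sc$mean[feats]),
                         2, sc$sd[feats], "/")
    }
  }
  V
}

#' Predict ages for new samples
#'
#' @param object A fitted `multiclock`.
#' @param newdata A gene-level `omics_matrix` in original units (beta
#'   values / normalized log-abundance); the model's stored per-modality
#'   scaling is applied unless the matrix carries a `prescaled` attribute.
#' @param ... Ignored.
#' @return Named numeric vector of predicted ages in years.
#' @export
predict.multiclock <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "omics_matrix"))
  V <- scale_to_model(object, newdata)
  Z <- tokenize(newdata$metadata, object$vocab)
  pred <- nn_forward(object$params, V, Z, object$config)$out[, 1]
  stats::setNames(pred, newdata$metadata$sample_id)
}

# Raw forward in already-scaled model feature space with fixed tokens;
# used by the Shapley explainer.
predict_scaled <- function(object, X, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow(X), length(Z), byrow = TRUE)
  nn_forward(object$params, X, Z, object$config)$out[, 1]
}

#' @export
print.multiclock <- function(x, ...) {
  cat("Multimodal transformer aging clock\n")
  cat(sprintf("  features: %d genes x %d modalities; tokens: %s\n",
              length(x$feature_ids), length(x$vocab$modality),
              paste(names(x$vocab), collapse = ", ")))
  cat(sprintf("  architecture: %d block(s) x %d head(s), d_embed %d, head %s\n",
              x$config$n_blocks, x$config$n_heads, x$config$d_embed,
              paste(x$config$head_hidden, collapse = "-")))
  cat(sprintf("  trained %d epoch(s), best validation MAE at epoch %d\n",
              nrow(x$trainlog), x$best_epoch))
  if (!is.null(x$metrics))
    cat(sprintf("  test MAE %.2f years (n = %d)\n",
                x$metrics$combined$mae, x$metrics$combined$n))
  invisible(x)
}

#' @export
summary.multiclock <- function(object, ...) {
  cat("Multimodal transformer aging clock -- hold-out test metrics\n\n")
  if (is.null(object$metrics)) {
    cat("  (no test split)\n"); return(invisible(object))
  }
  m <- object$metrics
  tab <- do.call(rbind, lapply(names(m), function(k)
    data.frame(subset = k, MAE = m[[k]]$mae, RMSE = m[[k]]$rmse,
               R2 = m[[k]]$r2, MdAE = m[[k]]$mdae, n = m[[k]]$n)))
  print(tab, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.multiclock <- function(object, ...) object$params

#' @export
residuals.multiclock <- function(object, ...) {
  if (is.null(object$predictions)) stop("model has no held-out predictions")
  stats::setNames(object$predictions$age - object$predictions$predicted,
                  object$predictions$sample_id)
}

#' @export
plot.multiclock <- function(x, which = c("fit", "learning"), ...) {
  which <- match.arg(which)
  if (which == "learning") {
    plot(x$trainlog$epoch, x$trainlog$val_crit, type = "l",
         xlab = "epoch", ylab = "validation MAE (years)",
         main = "Learning curve")
    graphics::abline(v = x$best_epoch, lty = 2)
  } else {
    if (is.null(x$predictions)) stop("model has no held-out predictions")
    plot(x$predictions$age, x$predictions$predicted,
         col = as.integer(factor(x$predictions$modality)),
         xlab = "chronological age (years)", ylab = "predicted age (years)",
         main = "Hold-out predictions")
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Regression metrics for age prediction
#'
#' MAE, RMSE, R-squared (1 - SSE/SST) and median absolute error, all in
#' years except R-squared. With zero-variance truth R-squared is undefined
#' and reported as `NA`.
#'
#' @param predictions,truth Equal-length numeric vectors (`n >= 2`).
#' @return A `regression_metrics` list: `mae`, `rmse`, `r2`, `mdae`, `n`.
#' @export
evaluate_regression <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  if (length(truth) < 2) stop("need at least 2 observations")
  e <- predictions - truth
  sst <- sum((truth - mean(truth))^2)
  structure(list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)),
                 r2 = if (sst > 0) 1 - sum(e^2) / sst else NA_real_,
                 mdae = stats::median(abs(e)), n = length(truth)),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("MAE %.3f  RMSE %.3f  R2 %s  MdAE %.3f  (n = %d)\n",
              x$mae, x$rmse,
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2),
              x$mdae, x$n))
  invisible(x)
}

#' Score a time-course and report its age trend
#'
#' Predicts age for every sample of a trajectory course, averages
#' predictions per timepoint across replicates, and reports the Spearman
#' correlation between time and mean predicted age. A negative trend is the
#' rejuvenation signature (reprogramming), a positive one maturation
#' (development).
#'
#' @param object A fitted `multiclock`.
#' @param trajectory An `omics_matrix` with a numeric `time` metadata
#'   column and at least 3 distinct timepoints.
#' @return A `trajectory_report`: per-timepoint means, `rho`, and `trend`
#'   (`"rejuvenation"`, `"maturation"` or `"none"`).
#' @export
predict_trajectory <- function(object, trajectory) {
  stopifnot(inherits(trajectory, "omics_matrix"))
  tm <- trajectory$metadata$time
  if (is.null(tm)) stop("trajectory metadata needs a `time` column")
  if (length(unique(tm)) < 3) stop("need at least 3 distinct timepoints")
  pred <- predict(object, trajectory)
  means <- tapply(pred, tm, mean)
  tp <- as.numeric(names(means))
  rho <- if (stats::sd(means) < 1e-12) 0
         else stats::cor(tp, as.numeric(means), method = "spearman")
  trend <- if (abs(rho) < 1e-12) "none"
           else if (rho < 0) "rejuvenation" else "maturation"
  structure(list(per_timepoint = data.frame(time = tp,
                                            mean_predicted = as.numeric(means)),
                 rho = rho, trend = trend),
            class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat(sprintf("<trajectory_report> Spearman rho(time, predicted age) = %.3f (%s)\n",
              x$rho, x$trend))
  print(x$per_timepoint, row.names = FALSE, digits = 4)
  invisible(x)
}

CHECKPOINT_SCHEMA <- "multiclock-checkpoint/1"

#' Save a model checkpoint
#'
#' Single-file container embedding a schema-version string and the full
#' architecture configuration, so loading needs no out-of-band information;
#' parameters round-trip bit-exactly.
#'
#' @param model A `multiclock` or `clock_classifier` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(schema = CHECKPOINT_SCHEMA, model = model), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return The stored model object.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt or unreadable checkpoint: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$schema))
    stop("not a multiclock checkpoint: missing schema field")
  if (!identical(obj$schema, CHECKPOINT_SCHEMA))
    stop("checkpoint schema mismatch: stored '", obj$schema,
         "', expected '", CHECKPOINT_SCHEMA, "'")
  obj$model
}
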