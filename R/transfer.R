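# Frozen-backbone transfer learning: the trained age regressor keeps every
# parameter fixed and only a freshly initialized 2-logit head is trained
# for case-control classification, plus the from-scratch full-feature
# baseline it is compared against.

#' Freeze a trained clock and attach a 2-class head
#'
#' All regressor parameters are copied bitwise and frozen; the final linear
#' regression layer is replaced by a freshly initialized 2-logit
#' classification head on the penultimate hidden representation.
#'
#' @param regressor A fitted `multiclock`.
#' @param seed Seed for head initialization.
#' @return A `clock_classifier` with `backbone` (frozen parameters) and
#'   `head` (`W`: hidden x 2, `b`: length 2).
#' @export
freeze_and_head <- function(regressor, seed = regressor$config$seed + 100L) {
  stopifnot(inherits(regressor, "multiclock"))
  if (!isTRUE(regressor$trained))
    warning("backbone regressor appears untrained; transfer will start from random features")
  hidden <- utils::tail(regressor$config$head_hidden, 1)
  head <- local_seed(seed, list(
    W = matrix(stats::rnorm(hidden * 2, 0, 0.01), hidden, 2),
    b = numeric(2)))
  structure(list(backbone = regressor, head = head, classes = c("control", "case"),
                 trained = FALSE),
            class = "clock_classifier")
}

# Penultimate hidden representation of the frozen backbone for raw data.
backbone_hidden <- function(clf, data) {
  bb <- clf$backbone
  V <- scale_to_model(bb, data)
  Z <- tokenize(data$metadata, bb$vocab)
  nn_forward(bb$params, V, Z, bb$config)$hidden
}

softmax2 <- function(L) {
  E <- exp(L - apply(L, 1, max))
  E / rowSums(E)
}

#' Train the transfer-learned case-control classifier
#'
#' Only the 2-logit head is updated (full-batch AdamW on the weighted
#' cross-entropy; the problem is convex given the frozen backbone). Class
#' imbalance is handled with inverse-frequency loss weights. Metrics are
#' reported on the held-out split.
#'
#' @param clf A `clock_classifier` from [freeze_and_head()].
#' @param data Labeled gene-level `omics_matrix` (metadata `label` in
#'   case/control; expression values on the normalized log scale).
#' @param split A `split_plan`; `NULL` fits a tissue-stratified 80/20
#'   split.
#' @param epochs,lr,patience Head-training schedule.
#' @param seed Seed for the internal split.
#' @return The classifier with trained head, plus `metrics`
#'   (`classification_metrics` on the held-out split), `split` and
#'   held-out `probabilities`.
#' @export
train_classifier <- function(clf, data, split = NULL, epochs = 400,
                             lr = 0.01, patience = 50, seed = 1) {
  stopifnot(inherits(clf, "clock_classifier"), inherits(data, "omics_matrix"))
  lab <- data$metadata$label
  if (is.null(lab) || !all(lab %in% c("case", "control")))
    stop("metadata$label must be 'case'/'control' for all samples")
  if (length(unique(lab)) < 2) stop("training data contains a single class")
  if (is.null(split))
    split <- split_stratified(data$metadata, 0.2, "tissue", seed)
  H <- backbone_hidden(clf, data)
  y <- ifelse(lab == "case", 2L, 1L)
  tr <- match(split$train_ids, data$metadata$sample_id)
  te <- match(split$test_ids, data$metadata$sample_id)
  if (length(unique(y[tr])) < 2) stop("training split contains a single class")
  cw <- length(tr) / (2 * tabulate(y[tr], 2))        # inverse frequency
  W <- clf$head$W; b <- clf$head$b
  state <- adamw_state(list(W = W, b = b))
  best <- list(loss = Inf, W = W, b = b, epoch = 0)
  Htr <- H[tr, , drop = FALSE]
  for (ep in seq_len(epochs)) {
    L <- sweep(Htr %*% W, 2, b, "+")
    lg <- loss_grad(L, y[tr], "ce", cw)
    gr <- list(W = crossprod(Htr, lg$dOut), b = colSums(lg$dOut))
    st <- adamw_step(list(W = W, b = b), gr, state, lr)
    W <- st$params$W; b <- st$params$b; state <- st$state
    if (lg$loss < best$loss - 1e-10) {
      best <- list(loss = lg$loss, W = W, b = b, epoch = ep)
    } else if (ep - best$epoch >= patience) break
  }
  clf$head <- list(W = best$W, b = best$b)
  clf$trained <- TRUE
  clf$split <- split
  if (length(te)) {
    P <- softmax2(sweep(H[te, , drop = FALSE] %*% best$W, 2, best$b, "+"))
    prob_case <- P[, 2]
    clf$probabilities <- data.frame(sample_id = split$test_ids,
                                    label = lab[te], prob_case = prob_case,
                                    stringsAsFactors = FALSE)
    clf$metrics <- classification_metrics(lab[te], prob_case)
  }
  clf
}

#' Predict case probabilities with a transfer classifier
#'
#' @param object A trained `clock_classifier`.
#' @param newdata Gene-level `omics_matrix`.
#' @param type `"prob"` (case probability) or `"class"`.
#' @param ... Ignored.
#' @return Named vector of probabilities or class labels.
#' @export
predict.clock_classifier <- function(object, newdata, type = c("prob", "class"),
                                     ...) {
  type <- match.arg(type)
  H <- backbone_hidden(object, newdata)
  P <- softmax2(sweep(H %*% object$head$W, 2, object$head$b, "+"))
  p <- stats::setNames(P[, 2], newdata$metadata$sample_id)
  if (type == "prob") p else ifelse(p >= 0.5, "case", "control")
}

#' @export
print.clock_classifier <- function(x, ...) {
  cat("Transfer-learned case-control classifier (frozen clock backbone)\n")
  cat(sprintf("  head: %d x 2 logits; trained: %s\n",
              nrow(x$head$W), x$trained))
  if (!is.null(x$metrics))
    cat(sprintf("  held-out AUROC %.3f, accuracy %.3f\n",
                x$metrics$auroc, x$metrics$accuracy))
  invisible(x)
}

#' Train the full-feature baseline classifier from scratch
#'
#' The identical architecture (same transformer trunk and head widths, a
#' 2-logit output) trained end to end with no frozen pretrained backbone;
#' the comparison partner for the transfer classifier.
#'
#' @param data Labeled gene-level `omics_matrix` with a `"scaling"`-style
#'   preprocessing already applied or raw log-scale values (scaled
#'   internally per gene using training samples).
#' @param split A `split_plan`; `NULL` fits a tissue-stratified 80/20
#'   split.
#' @param config A [clock_config()] (epoch budget typically reduced).
#' @param quiet Suppress progress output.
#' @return A list with `metrics` (`classification_metrics`), `params` and
#'   `probabilities`.
#' @export
train_baseline_classifier <- function(data, split = NULL,
                                      config = clock_config(max_epochs = 150),
                                      quiet = TRUE) {
  stopifnot(inherits(data, "omics_matrix"))
  lab <- data$metadata$label
  if (is.null(lab) || !all(lab %in% c("case", "control")))
    stop("metadata$label must be 'case'/'control' for all samples")
  if (length(unique(lab)) < 2) stop("training data contains a single class")
  meta <- data$metadata
  if (is.null(split))
    split <- split_stratified(meta, 0.2, "tissue", config$seed)
  vocab <- list(tissue = sort(unique(meta$tissue)),
                modality = sort(unique(meta$modality)))
  y <- ifelse(lab == "case", 2L, 1L)
  tr <- match(split$train_ids, meta$sample_id)
  te <- match(split$test_ids, meta$sample_id)
  # per-gene z-scaling from training samples only
  mu <- colMeans(data$values[tr, , drop = FALSE])
  sd <- apply(data$values[tr, , drop = FALSE], 2, stats::sd)
  sd[sd < 1e-12] <- 1
  X <- sweep(sweep(data$values, 2, mu), 2, sd, "/")
  Z <- tokenize(meta, vocab)
  val_ids <- carve_validation(meta[tr, , drop = FALSE], config$val_fraction,
                              config$seed + 7L)
  fit_ids <- setdiff(split$train_ids, val_ids)
  fi <- match(fit_ids, meta$sample_id); vi <- match(val_ids, meta$sample_id)
  cw <- length(tr) / (2 * tabulate(y[tr], 2))
  params <- init_params(config, ncol(X), lengths(vocab), out_dim = 2)
  res <- train_network(params, X[fi, , drop = FALSE], Z[fi, , drop = FALSE],
                       y[fi], X[vi, , drop = FALSE], Z[vi, , drop = FALSE],
                       y[vi], config, loss = "ce", class_weights = cw,
                       quiet = quiet)
  out <- list(params = res$params, split = split, trainlog = res$log)
  if (length(te)) {
    L <- nn_forward(res$params, X[te, , drop = FALSE], Z[te, , drop = FALSE],
                    config)$out
    p <- softmax2(L)[, 2]
    out$probabilities <- data.frame(sample_id = split$test_ids,
                                    label = lab[te], prob_case = p,
                                    stringsAsFactors = FALSE)
    out$metrics <- classification_metrics(lab[te], p)
  }
  out
}

#' Compare transfer and baseline classifier metrics
#'
#' @param transfer,baseline `classification_metrics` objects.
#' @return A data.frame with both metric sets and their differences
#'   (transfer minus baseline).
#' @export
compare_classifiers <- function(transfer, baseline) {
  keys <- c("accuracy", "auroc", "f1", "mcc")
  data.frame(metric = keys,
             transfer = unlist(transfer[keys]),
             baseline = unlist(baseline[keys]),
             difference = unlist(transfer[keys]) - unlist(baseline[keys]),
             row.names = NULL)
}

#' Binary classification metrics from labels and case probabilities
#'
#' Accuracy, AUROC, F1 and Matthews correlation for the positive class
#' `"case"` at threshold 0.5.
#'
#' @param truth Character labels (`"case"`/`"control"`).
#' @param prob_case Predicted case probabilities.
#' @param threshold Classification threshold.
#' @return A `classification_metrics` list.
#' @export
classification_metrics <- function(truth, prob_case, threshold = 0.5) {
  stopifnot(length(truth) == length(prob_case))
  pred <- prob_case >= threshold
  pos <- truth == "case"
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  m <- confusion_metrics(tp, fp, fn, tn)
  m$auroc <- if (length(unique(pos)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(response = pos, predictor = prob_case,
                                   quiet = TRUE, direction = "<",
                                   levels = c(FALSE, TRUE))))
  m$n_case <- sum(pos); m$n_control <- sum(!pos)
  structure(m[c("accuracy", "auroc", "f1", "mcc", "n_case", "n_control")],
            class = "classification_metrics")
}

#' Classification metrics from a confusion matrix
#'
#' @param tp,fp,fn,tn Confusion-matrix counts.
#' @return List with `accuracy`, `f1`, `mcc`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  acc <- (tp + tn) / (tp + fp + fn + tn)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(accuracy = acc, f1 = f1, mcc = mcc)
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f  AUROC %s  F1 %.3f  MCC %.3f  (%d case / %d control)\n",
              x$accuracy,
              if (is.na(x$auroc)) "NA" else sprintf("%.3f", x$auroc),
              x$f1, x$mcc, x$n_case, x$n_control))
  invisible(x)
}
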