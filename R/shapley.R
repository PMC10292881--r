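# Shapley-value feature attribution: a model-agnostic permutation-sampling
# estimator with background-row imputation, and the exact 2^d enumeration
# computed from the same value function, used as its oracle on small
# models.

# Resolve (object, data, background) into a value function over rows of a
# plain feature matrix, plus the explained matrix and background matrix in
# that space. For fitted models the space is the model's scaled feature
# space and the tokens of each explained sample are held fixed.
shapley_context <- function(object, data, background) {
  if (is.function(object)) {
    X <- if (inherits(data, "omics_matrix")) data$values else data
    B <- if (inherits(background, "omics_matrix")) background$values else background
    fx_fun <- function(M, i) object(M)
    return(list(X = X, B = B, f = fx_fun,
                features = colnames(X) %||% paste0("f", seq_len(ncol(X)))))
  }
  if (inherits(object, "multiclock")) {
    stopifnot(inherits(data, "omics_matrix"), inherits(background, "omics_matrix"))
    X <- scale_to_model(object, data)
    B <- scale_to_model(object, background)
    Zs <- tokenize(data$metadata, object$vocab)
    f <- function(M, i) predict_scaled(object, M, Zs[i, ])
    return(list(X = X, B = B, f = f, features = object$feature_ids))
  }
  if (inherits(object, "clock_classifier")) {
    stopifnot(inherits(data, "omics_matrix"), inherits(background, "omics_matrix"))
    bb <- object$backbone
    X <- scale_to_model(bb, data)
    B <- scale_to_model(bb, background)
    Zs <- tokenize(data$metadata, bb$vocab)
    f <- function(M, i) {
      Z <- matrix(Zs[i, ], nrow(M), ncol(Zs), byrow = TRUE)
      Hh <- nn_forward(bb$params, M, Z, bb$config)$hidden
      softmax2(sweep(Hh %*% object$head$W, 2, object$head$b, "+"))[, 2]
    }
    return(list(X = X, B = B, f = f, features = bb$feature_ids))
  }
  stop("unsupported model object for Shapley attribution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation-sampling Shapley attribution
#'
#' Estimates per-sample, per-feature Shapley values by averaging marginal
#' contributions over random feature orderings, with absent features
#' imputed from a background row drawn per permutation. Each permutation
#' path telescopes exactly, so the efficiency (local accuracy) identity
#' `base + sum(attributions) = f(x)` holds up to floating point; the
#' residual is reported. For fitted clock models the explained quantity is
#' the predicted age; for transfer classifiers, the case probability.
#'
#' @param object A `multiclock`, a `clock_classifier`, or a plain function
#'   mapping a feature matrix to a numeric vector.
#' @param data Samples to explain (`omics_matrix`, or matrix when `object`
#'   is a function). The pipeline explains the held-out test split by
#'   default.
#' @param background Background samples for imputation (typically a seeded
#'   subsample of the training split; default size 100 upstream).
#' @param n_permutations Permutations per sample (`>= 1`).
#' @param seed Integer seed.
#' @return An `attribution_table`: `values` (samples x features),
#'   `base`, `fx`, `residual`, `se` (Monte-Carlo standard errors),
#'   `aggregate` (per-feature mean absolute attribution) and `rank`.
#' @export
shapley_attribute <- function(object, data, background, n_permutations = 10,
                              seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be at least 1")
  ctx <- shapley_context(object, data, background)
  n <- nrow(ctx$X); D <- ncol(ctx$X); B <- nrow(ctx$B)
  if (B < 1) stop("background set must be non-empty")
  phi <- matrix(0, n, D, dimnames = list(rownames(ctx$X), ctx$features))
  se <- phi; base <- numeric(n); fx <- numeric(n)
  local_seed(seed, {
    for (i in seq_len(n)) {
      x <- ctx$X[i, ]
      contrib <- matrix(0, n_permutations, D)
      bvals <- numeric(n_permutations)
      rows_all <- vector("list", n_permutations)
      perms <- vector("list", n_permutations)
      for (p in seq_len(n_permutations)) {
        perm <- sample.int(D)
        bg <- ctx$B[sample.int(B, 1), ]
        pos <- integer(D); pos[perm] <- seq_len(D)
        M <- matrix(bg, D + 1, D, byrow = TRUE)
        mask <- outer(seq_len(D + 1) - 1L, pos, ">=")
        M[mask] <- matrix(x, D + 1, D, byrow = TRUE)[mask]
        rows_all[[p]] <- M
        perms[[p]] <- perm
      }
      preds <- ctx$f(do.call(rbind, rows_all), i)
      for (p in seq_len(n_permutations)) {
        pr <- preds[((p - 1) * (D + 1) + 1):(p * (D + 1))]
        contrib[p, perms[[p]]] <- diff(pr)
        bvals[p] <- pr[1]
      }
      phi[i, ] <- colMeans(contrib)
      se[i, ] <- if (n_permutations > 1)
        apply(contrib, 2, stats::sd) / sqrt(n_permutations) else NA_real_
      base[i] <- mean(bvals)
      fx[i] <- ctx$f(matrix(x, 1), i)
    }
  })
  agg <- colMeans(abs(phi))
  structure(list(values = phi, base = base, fx = fx,
                 residual = fx - base - rowSums(phi),
                 se = se, aggregate = agg,
                 rank = rank_vector(agg)),
            class = "attribution_table")
}

# Dense descending rank with lexicographic tie-break on the feature id.
rank_vector <- function(agg) {
  ord <- order(-agg, names(agg))
  r <- integer(length(agg)); r[ord] <- seq_along(agg)
  stats::setNames(r, names(agg))
}

#' Exact Shapley values by full subset enumeration
#'
#' Enumerates all 2^d feature coalitions; the value of a coalition is the
#' mean model output over background rows with coalition features taken
#' from the explained sample. Feasible for small d only (hard limit 20);
#' serves as the oracle for the sampling estimator.
#'
#' @inheritParams shapley_attribute
#' @return An `attribution_table` (no `se`).
#' @export
shapley_exact <- function(object, data, background) {
  ctx <- shapley_context(object, data, background)
  n <- nrow(ctx$X); D <- ncol(ctx$X); B <- nrow(ctx$B)
  if (D > 20) stop("exact enumeration limited to 20 features (got ", D, ")")
  nmask <- 2^D
  popcount <- vapply(0:(nmask - 1), function(m) sum(bitwAnd(m, 2^(0:(D - 1))) > 0),
                     numeric(1))
  # weight |S|!(D-|S|-1)!/D!; the full coalition never appears as S
  wt <- ifelse(popcount >= D, 0,
               factorial(popcount) * factorial(pmax(D - popcount - 1, 0)) /
                 factorial(D))
  phi <- matrix(0, n, D, dimnames = list(rownames(ctx$X), ctx$features))
  base <- numeric(n); fx <- numeric(n)
  member <- vapply(0:(nmask - 1), function(m) bitwAnd(m, 2^(0:(D - 1))) > 0,
                   logical(D))              # D x nmask
  for (i in seq_len(n)) {
    x <- ctx$X[i, ]
    rows <- ctx$B[rep(seq_len(B), nmask), , drop = FALSE]
    sel <- t(member)[rep(seq_len(nmask), each = B), , drop = FALSE]
    rows[sel] <- matrix(x, nmask * B, D, byrow = TRUE)[sel]
    pv <- ctx$f(rows, i)
    v <- rowMeans(matrix(pv, nmask, B, byrow = TRUE))
    for (j in seq_len(D)) {
      bitj <- 2^(j - 1)
      without <- which(bitwAnd(0:(nmask - 1), bitj) == 0)   # positions m+1
      phi[i, j] <- sum(wt[without] * (v[without + bitj] - v[without]))
    }
    base[i] <- v[1]
    fx[i] <- v[nmask]
  }
  structure(list(values = phi, base = base, fx = fx,
                 residual = fx - base - rowSums(phi),
                 se = NULL, aggregate = colMeans(abs(phi)),
                 rank = rank_vector(colMeans(abs(phi)))),
            class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
  cat(sprintf("<attribution_table> %d sample(s) x %d feature(s); max |residual| %.2e\n",
              nrow(x$values), ncol(x$values), max(abs(x$residual))))
  top <- utils::head(names(sort(x$rank)), 5)
  cat("  top features:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Rank genes by aggregated attribution
#'
#' Descending mean absolute attribution; ties broken lexicographically by
#' gene id.
#'
#' @param attr An `attribution_table`.
#' @param top_k Number of genes to return (positive; capped at the number
#'   of features).
#' @return Character vector of gene ids, best first.
#' @export
rank_genes <- function(attr, top_k) {
  stopifnot(inherits(attr, "attribution_table"))
  if (top_k <= 0) stop("top_k must be positive")
  ord <- names(sort(attr$rank))
  utils::head(ord, min(top_k, length(ord)))
}

#' Precision/recall of a ranked gene list against planted ground truth
#'
#' @param ranked Character vector of ranked gene ids (best first).
#' @param truth_genes Planted gene ids (e.g. `truth$age_gene_ids`), or a
#'   `ground_truth` object (its `age_gene_ids` are used).
#' @return A `recovery_report`: `precision`, `recall`, `k`, `hits`, and
#'   the rank of every planted gene within `ranked` (`NA` if absent).
#' @export
recovery_report <- function(ranked, truth_genes) {
  if (inherits(truth_genes, "ground_truth")) truth_genes <- truth_genes$age_gene_ids
  if (!length(truth_genes)) stop("empty ground truth set")
  hits <- intersect(ranked, truth_genes)
  structure(list(precision = length(hits) / length(ranked),
                 recall = length(hits) / length(truth_genes),
                 k = length(ranked), hits = hits,
                 planted_rank = stats::setNames(match(truth_genes, ranked),
                                                truth_genes)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> precision@%d = %.3f, recall = %.3f (%d hits)\n",
              x$k, x$precision, x$recall, length(x$hits)))
  invisible(x)
}
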