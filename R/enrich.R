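# Over-representation analysis of ranked gene lists: one-sided Fisher
# (hypergeometric upper tail), sample odds ratio with Haldane correction,
# and the Enrichr-style combined score OR * (-ln p).

#' Enrichr-style combined score
#'
#' `odds_ratio * (-ln p)`: monotone decreasing in the p-value and
#' increasing in the odds ratio; 0 when p = 1.
#'
#' @param p Enrichment p-value(s) in (0, 1].
#' @param odds_ratio Positive odds ratio(s).
#' @return Numeric combined score(s).
#' @export
combined_score <- function(p, odds_ratio) {
  if (any(p <= 0)) stop("p = 0 gives an undefined combined score")
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  if (any(odds_ratio <= 0)) stop("odds ratios must be positive")
  odds_ratio * (-log(p))
}

#' Gene-set over-representation of a gene list
#'
#' For each set, forms the 2x2 table of list membership against set
#' membership within the universe and reports the one-sided
#' over-representation p-value (hypergeometric upper tail, P(X >= a)), the
#' sample odds ratio `a*d / (b*c)` with a Haldane 0.5 correction when any
#' cell is zero, and the combined score `OR * (-ln p)`. Rows are sorted by
#' ascending p-value. Significance is flagged at raw `p < alpha` (the
#' headline rule); Benjamini-Hochberg q-values are reported alongside.
#'
#' @param gene_list Character vector of genes (must lie within `universe`).
#' @param library A `geneset_library` (or named list of character
#'   vectors); sets are intersected with the universe.
#' @param universe Character vector of all candidate genes (e.g. the
#'   model's feature space).
#' @param alpha Significance level on the raw p-value; default 0.05.
#' @return A data.frame of class `enrichment_table` with columns
#'   `set_name`, `overlap`, `list_size`, `set_size`, `universe_size`,
#'   `p_value`, `q_value`, `odds_ratio`, `combined_score`, `significant`.
#' @export
fisher_enrichment <- function(gene_list, library, universe, alpha = 0.05) {
  gene_list <- unique(gene_list); universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!length(gene_list)) stop("empty gene list")
  outside <- setdiff(gene_list, universe)
  if (length(outside))
    stop("gene list members outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(library), function(nm) {
    set <- intersect(unique(library[[nm]]), universe)
    K <- length(set)
    a <- length(intersect(gene_list, set))
    b <- n - a; cc <- K - a; d <- N - n - K + a
    p <- if (K == 0) 1 else
      stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
    or <- if (a == 0 || b == 0 || cc == 0 || d == 0)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else (a * d) / (b * cc)
    data.frame(set_name = nm, overlap = a, list_size = n, set_size = K,
               universe_size = N, p_value = p, odds_ratio = or,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  tab$combined_score <- combined_score(tab$p_value, tab$odds_ratio)
  tab$significant <- tab$p_value < alpha
  tab <- tab[order(tab$p_value, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' @export
print.enrichment_table <- function(x, n = 10, ...) {
  cat(sprintf("<enrichment_table> %d set(s), %d significant at raw p\n",
              nrow(x), sum(x$significant)))
  print.data.frame(utils::head(x[, c("set_name", "overlap", "set_size",
                                     "p_value", "odds_ratio",
                                     "combined_score", "significant")], n),
                   row.names = FALSE, digits = 4)
  invisible(x)
}
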