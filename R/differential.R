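#' Two-sample Wilcoxon rank-sum test
#'
#' Thin, contract-checked wrapper around [stats::wilcox.test()]: exact
#' enumeration when both groups have at most 8 observations and the data are
#' tie-free, otherwise the normal approximation with midrank tie correction
#' and continuity correction.
#'
#' @param x,y numeric vectors (non-empty; ties allowed).
#' @return list with `statistic` (the rank-sum W of `x`) and `p.value`
#'   (two-sided).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value  # exact: 0.1
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return adjusted p values in the original order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between two sample groups
#'
#' Per gene: Wilcoxon rank-sum p value, BH adjustment over all tested genes
#' jointly, and the mean log2 difference `mean(group_a) - mean(group_b)`
#' (`group_b` is the reference, e.g. ND). A gene is flagged significant only
#' under the dual threshold: adjusted p below `alpha` AND absolute mean
#' difference above `delta`.
#'
#' @param expression genes x samples log2 matrix.
#' @param annotation data.frame with `sample_id` and the grouping column.
#' @param group_a,group_b group labels; `group_b` is the reference.
#' @param group_col annotation column holding the labels.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param delta absolute mean-difference threshold in log2 units (default 0.2).
#' @return data.frame: `gene`, `p_raw`, `p_adj`, `mean_diff`, `direction`
#'   (up/down relative to the reference), `significant`.
#' @export
differential_genes <- function(expression, annotation, group_a, group_b,
                               group_col = "condition",
                               alpha = 0.05, delta = 0.2) {
  annotation <- annotation[match(colnames(expression), annotation$sample_id), ,
                           drop = FALSE]
  ia <- which(annotation[[group_col]] == group_a)
  ib <- which(annotation[[group_col]] == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both groups need at least 2 samples")
  }
  xa <- expression[, ia, drop = FALSE]
  xb <- expression[, ib, drop = FALSE]
  p_raw <- vapply(seq_len(nrow(expression)), function(g) {
    suppressWarnings(rank_sum_test(xa[g, ], xb[g, ])$p.value)
  }, numeric(1))
  mean_diff <- rowMeans(xa) - rowMeans(xb)
  p_adj <- bh_adjust(p_raw)
  data.frame(gene = rownames(expression),
             p_raw = p_raw,
             p_adj = p_adj,
             mean_diff = unname(mean_diff),
             direction = ifelse(mean_diff > 0, "up", "down"),
             significant = p_adj < alpha & abs(mean_diff) > delta,
             stringsAsFactors = FALSE)
}

#' Subgroup-specific upregulated genes
#'
#' A gene belongs to subgroup s's signature iff it is significantly
#' upregulated in s versus EVERY other subgroup under the dual threshold
#' (adjusted p < `alpha` and mean difference > `delta` in each pairwise
#' comparison; BH is applied within each comparison). The all-pairwise
#' requirement makes the signatures pairwise disjoint by construction. A
#' pooled-rest alternative (s versus all other subgroups merged) is available
#' via `mode = "pooled"`.
#'
#' @param expression genes x samples matrix (typically AD samples only).
#' @param annotation data.frame with `sample_id` and the subgroup column.
#' @param subgroup_col annotation column with subgroup labels.
#' @param alpha,delta dual-threshold parameters as in [differential_genes()].
#' @param mode `"pairwise"` (default) or `"pooled"`.
#' @return Named list (one per subgroup) of gene ids ordered by decreasing
#'   minimum pairwise mean difference (the gene's weakest margin).
#' @export
subgroup_specific_upregulated <- function(expression, annotation,
                                          subgroup_col = "subgroup",
                                          alpha = 0.05, delta = 0.2,
                                          mode = c("pairwise", "pooled")) {
  mode <- match.arg(mode)
  annotation <- annotation[match(colnames(expression), annotation$sample_id), ,
                           drop = FALSE]
  groups <- sort(unique(stats::na.omit(annotation[[subgroup_col]])))
  if (length(groups) < 2) stop("need at least 2 subgroups")
  sizes <- table(annotation[[subgroup_col]])
  if (any(sizes[as.character(groups)] < 2)) {
    stop("every subgroup needs at least 2 samples")
  }
  signatures <- stats::setNames(vector("list", length(groups)), as.character(groups))
  if (mode == "pooled") {
    ann <- annotation
    for (s in groups) {
      ann$.rest <- ifelse(ann[[subgroup_col]] == s, "this", "rest")
      de <- differential_genes(expression, ann, "this", "rest",
                               group_col = ".rest", alpha = alpha, delta = delta)
      hits <- de[de$significant & de$mean_diff > delta, ]
      signatures[[as.character(s)]] <- hits$gene[order(-hits$mean_diff)]
    }
    return(signatures)
  }
  # pairwise: run each unordered comparison once, reuse with flipped sign
  pair_res <- list()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i < j) {
        key <- paste(groups[i], groups[j], sep = "|")
        pair_res[[key]] <- differential_genes(
          expression, annotation, groups[i], groups[j],
          group_col = subgroup_col, alpha = alpha, delta = delta)
      }
    }
  }
  for (s in seq_along(groups)) {
    ok <- rep(TRUE, nrow(expression))
    margin <- rep(Inf, nrow(expression))
    for (t in seq_along(groups)) {
      if (t == s) next
      if (s < t) {
        de <- pair_res[[paste(groups[s], groups[t], sep = "|")]]
        md <- de$mean_diff
      } else {
        de <- pair_res[[paste(groups[t], groups[s], sep = "|")]]
        md <- -de$mean_diff
      }
      ok <- ok & de$p_adj < alpha & md > delta
      margin <- pmin(margin, md)
    }
    genes <- rownames(expression)[ok]
    signatures[[as.character(groups[s])]] <- genes[order(-margin[ok])]
  }
  signatures
}
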