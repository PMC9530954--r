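#' Pairwise clinical-trait comparisons across groups
#'
#' For each trait and each unordered pair of group levels, a Wilcoxon
#' rank-sum test on the non-missing values (pairwise-complete: missingness in
#' one trait never affects another). Pairs where either side has fewer than 2
#' non-missing values are skipped with a notice.
#'
#' @param annotation per-sample data.frame holding the grouping column and
#'   trait columns.
#' @param group_col name of the grouping column (e.g. condition or subgroup).
#' @param traits character vector of numeric trait columns to compare.
#' @return data.frame: `trait`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `statistic`, `p`, `stars`.
#' @export
compare_traits <- function(annotation, group_col, traits) {
  groups <- sort(unique(stats::na.omit(annotation[[group_col]])))
  if (length(groups) < 2) stop("grouping needs at least 2 levels")
  rows <- list()
  for (trait in traits) {
    if (!is.numeric(annotation[[trait]])) {
      stop("trait '", trait, "' is not numeric")
    }
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i >= j) next
        xa <- annotation[[trait]][annotation[[group_col]] == groups[i]]
        xb <- annotation[[trait]][annotation[[group_col]] == groups[j]]
        xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
        if (length(xa) < 2 || length(xb) < 2) {
          message("skipping ", trait, " for ", groups[i], " vs ", groups[j],
                  ": fewer than 2 non-missing values on one side")
          next
        }
        ht <- suppressWarnings(rank_sum_test(xa, xb))
        rows[[length(rows) + 1L]] <- data.frame(
          trait = trait, group_a = as.character(groups[i]),
          group_b = as.character(groups[j]),
          n_a = length(xa), n_b = length(xb),
          statistic = ht$statistic, p = ht$p.value,
          stars = p_stars(ht$p.value), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no comparable trait/pair combinations")
  do.call(rbind, rows)
}

#' Two-sample proportion test (pooled chi-square)
#'
#' Compares two binomial proportions (e.g. the fraction of women per group)
#' with the pooled two-proportion chi-square test; continuity correction is
#' off by default.
#'
#' @param successes_a,n_a,successes_b,n_b counts.
#' @param correct apply continuity correction (default FALSE).
#' @return list with `statistic` (chi-square), `p.value`, `prop` (the two
#'   sample proportions).
#' @export
proportion_test <- function(successes_a, n_a, successes_b, n_b,
                            correct = FALSE) {
  if (n_a < 1 || n_b < 1) stop("group sizes must be >= 1")
  if (successes_a > n_a || successes_b > n_b) stop("successes cannot exceed n")
  pooled <- (successes_a + successes_b) / (n_a + n_b)
  if (pooled == 0 || pooled == 1) {
    stop("degenerate table: pooled proportion is 0 or 1")
  }
  ht <- suppressWarnings(
    stats::prop.test(c(successes_a, successes_b), c(n_a, n_b),
                     correct = correct))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       prop = unname(ht$estimate))
}

#' Spearman rank correlation
#'
#' Midrank-based rho via [stats::cor.test()] on the pairwise-complete
#' observations; exact p for small tie-free samples, t approximation
#' otherwise.
#'
#' @param x,y numeric vectors of equal length; NAs dropped pairwise.
#' @return list with `rho`, `p.value`, `n` (pairs used).
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired non-missing observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), p.value = ht$p.value, n = length(x))
}

#' Kruskal-Wallis rank test across groups
#'
#' Midrank H statistic with tie correction and chi-square p value (k-1 df) via
#' [stats::kruskal.test()]; the degenerate all-identical case returns H = 0,
#' p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, all non-empty).
#' @return list with `statistic` (H), `p.value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!vapply(groups, length, integer(1)))) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) stop("need at least 3 observations in total")
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p.value = 1, df = length(groups) - 1L))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ht <- stats::kruskal.test(values, g)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter))
}

#' Module eigengene of a gene set
#'
#' Summarizes a gene set's expression across samples by the first principal
#' component of the gene-standardized block (each gene scaled to zero mean and
#' unit variance): the first right-singular vector, recentred to zero mean and
#' sign-oriented so that its mean correlation with the member genes is
#' non-negative.
#'
#' @param expression genes x samples matrix restricted to the gene set (or the
#'   full matrix plus `genes`).
#' @param genes optional character vector selecting rows of `expression`.
#' @return Object of class `module_eigengene`: `scores` (named per-sample
#'   eigengene, zero mean), `variance_explained` by the first component,
#'   `orientation` sign applied, `genes` used.
#' @export
module_eigengene <- function(expression, genes = NULL) {
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(expression))
    if (length(missing_g)) stop("genes absent from matrix: ",
                                paste(utils::head(missing_g, 5), collapse = ", "))
    expression <- expression[genes, , drop = FALSE]
  }
  if (ncol(expression) < 3) stop("need at least 3 samples")
  sds <- apply(expression, 1, stats::sd)
  if (all(sds == 0)) stop("all genes constant: eigengene undefined")
  if (any(sds == 0)) expression <- expression[sds > 0, , drop = FALSE]
  z <- (expression - rowMeans(expression)) / apply(expression, 1, stats::sd)
  sv <- svd(z)
  scores <- sv$v[, 1]
  scores <- scores - mean(scores)
  if (stats::sd(scores) == 0) stop("degenerate eigengene")
  cors <- suppressWarnings(stats::cor(t(z), scores))
  orientation <- if (mean(cors, na.rm = TRUE) < 0) -1 else 1
  scores <- orientation * scores
  out <- list(scores = stats::setNames(scores, colnames(expression)),
              variance_explained = sv$d[1]^2 / sum(sv$d^2),
              orientation = orientation,
              genes = rownames(expression))
  class(out) <- "module_eigengene"
  out
}

#' @export
print.module_eigengene <- function(x, ...) {
  cat(sprintf("Module eigengene: %d genes, %d samples, %.1f%% variance explained\n",
              length(x$genes), length(x$scores), 100 * x$variance_explained))
  invisible(x)
}

#' Spearman correlation table of genes (or eigengenes) against traits
#'
#' One (rho, p) per feature x trait cell, computed pairwise-complete; cells
#' with fewer than 3 complete pairs are set to NA. Optional BH adjustment
#' across the whole table.
#'
#' @param features named list of per-sample numeric vectors (e.g. gene
#'   expression rows or eigengene scores), all aligned to `annotation`
#'   sample order, or a genes x samples matrix.
#' @param annotation data.frame with `sample_id` and the trait columns.
#' @param traits character vector of trait columns.
#' @param adjust apply BH across all cells (default FALSE).
#' @return list of matrices `rho`, `p`, `n` (features x traits); `q` when
#'   `adjust` is TRUE.
#' @export
trait_correlation_table <- function(features, annotation, traits,
                                    adjust = FALSE) {
  if (is.matrix(features)) {
    stopifnot(identical(colnames(features), annotation$sample_id))
    features <- stats::setNames(
      lapply(seq_len(nrow(features)), function(i) features[i, ]),
      rownames(features))
  }
  rho <- matrix(NA_real_, length(features), length(traits),
                dimnames = list(names(features), traits))
  p <- rho; n <- rho
  for (i in seq_along(features)) {
    for (j in seq_along(traits)) {
      x <- features[[i]]
      y <- annotation[[traits[j]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- spearman_cor(x, y)
      rho[i, j] <- ct$rho
      p[i, j] <- ct$p.value
      n[i, j] <- ct$n
    }
  }
  out <- list(rho = rho, p = p, n = n)
  if (adjust) {
    q <- p
    q[] <- NA_real_
    ok <- !is.na(p)
    q[ok] <- bh_adjust(p[ok])
    out$q <- q
  }
  out
}
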