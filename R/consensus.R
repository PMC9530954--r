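#' Resampling-based consensus clustering for one cluster count
#'
#' Repeatedly subsamples the samples without replacement, clusters each
#' subsample into `k` groups with the base clusterer, and records for every
#' sample pair how often it co-clusters among the resamples in which both were
#' drawn. The consensus matrix entry `M(i,j)` is that ratio (0, with a
#' warning, for pairs never co-resampled). Final assignments come from
#' average-linkage hierarchical clustering of `1 - M` cut into `k` groups.
#'
#' The base clusterer is k-means (Euclidean distance over genes standardized
#' to zero mean / unit variance across the clustered samples), chosen for
#' determinism and speed; `base = "hclust"` switches to average-linkage
#' hierarchical clustering on Pearson-correlation distance. Resampling and
#' clustering are driven by sample identities in sorted-id order, so permuting
#' the input columns permutes the result consistently.
#'
#' @param expression genes x samples matrix (typically batch-corrected AD
#'   samples).
#' @param k number of clusters (2 <= k <= number of samples).
#' @param n_resamples number of subsampling iterations (default 100).
#' @param sample_fraction fraction of samples drawn per iteration
#'   (default 0.8; 1 disables resampling variation in the drawn set).
#' @param seed integer seed; the full run is deterministic given it.
#' @param base `"kmeans"` (default) or `"hclust"`.
#' @param scale_genes standardize genes before clustering (default TRUE).
#' @param store_resamples keep each resample's drawn samples and cluster
#'   memberships (in sorted-id space) for auditing (default FALSE).
#' @return Object of class `consensus_run`: `k`, consensus matrix `M` (in the
#'   input sample order, symmetric, unit diagonal), co-resample counts
#'   `indicator`, `assignments` (named integer vector), and
#'   `cluster_consensus` scores m(k).
#' @export
consensus_cluster <- function(expression, k, n_resamples = 100L,
                              sample_fraction = 0.8, seed = 1L,
                              base = c("kmeans", "hclust"),
                              scale_genes = TRUE, store_resamples = FALSE) {
  base <- match.arg(base)
  ids <- colnames(expression)
  n <- length(ids)
  if (k < 2 || k > n) stop("need 2 <= k <= number of samples")
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop("sample_fraction must be in (0, 1]")
  }
  if (n_resamples < 1) stop("n_resamples must be >= 1")

  ord <- order(ids)           # canonical order: sorted sample ids
  x <- expression[, ord, drop = FALSE]
  if (scale_genes) {
    cs <- apply(x, 1, stats::sd)
    keep <- cs > 0
    x <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) / cs[keep]
  }
  D <- t(x)  # samples x genes

  n_sub <- max(k, floor(sample_fraction * n))
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  resample_seeds <- with_seed(as.integer(seed),
                              sample.int(2147483646L, n_resamples))
  resamples <- if (store_resamples) vector("list", n_resamples)
  for (r in seq_len(n_resamples)) {
    part <- with_seed(resample_seeds[r], {
      idx <- sort(sample.int(n, n_sub))
      cl <- cluster_once(D[idx, , drop = FALSE], k, base, resample_seeds[r])
      list(idx = idx, cl = cl)
    })
    idx <- part$idx
    if (store_resamples) {
      resamples[[r]] <- list(ids = ids[ord][idx], cluster = part$cl)
    }
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    for (g in seq_len(k)) {
      members <- idx[part$cl == g]
      if (length(members)) {
        co_cluster[members, members] <- co_cluster[members, members] + 1
      }
    }
  }
  if (any(co_sample == 0)) {
    warning("some sample pairs were never co-resampled; their consensus is 0")
  }
  M <- ifelse(co_sample > 0, co_cluster / pmax(co_sample, 1), 0)
  diag(M) <- 1
  M <- (M + t(M)) / 2

  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  assignments <- stats::cutree(hc, k = k)
  names(assignments) <- ids[ord]

  # map back to the input order
  inv <- order(ord)
  M_out <- M[inv, inv]
  dimnames(M_out) <- list(ids, ids)
  ind_out <- co_sample[inv, inv]
  dimnames(ind_out) <- list(ids, ids)
  assignments <- assignments[ids]

  run <- list(k = k, M = M_out, indicator = ind_out,
              assignments = assignments,
              n_resamples = n_resamples, sample_fraction = sample_fraction,
              seed = as.integer(seed), base = base,
              resamples = if (store_resamples) resamples)
  run$cluster_consensus <- cluster_consensus_scores(run)
  class(run) <- "consensus_run"
  run
}

# one base-clustering of a subsample; deterministic given seed.
# kmeans occasionally aborts on an unlucky random initialization (empty
# cluster); retry with a shifted seed, still deterministically.
cluster_once <- function(D, k, base, seed) {
  if (base == "hclust") {
    dc <- stats::as.dist(1 - stats::cor(t(D)))
    return(stats::cutree(stats::hclust(dc, method = "average"), k = k))
  }
  for (attempt in 0:4) {
    set.seed((seed + attempt * 97003) %% 2147483647)
    cl <- tryCatch(
      stats::kmeans(D, centers = k, nstart = 1, iter.max = 50)$cluster,
      error = function(e) NULL)
    if (!is.null(cl)) return(cl)
  }
  stop("k-means failed repeatedly on a resample")
}

#' Cluster consensus scores m(k)
#'
#' For each cluster, the mean consensus over all unordered within-cluster
#' sample pairs. A singleton cluster has no pairs and scores 1 by convention
#' (logged via message).
#'
#' @param run a `consensus_run` (or a list with `M` and `assignments`).
#' @return Named numeric vector, one score in [0, 1] per cluster.
#' @export
cluster_consensus_scores <- function(run) {
  M <- run$M
  assignments <- run$assignments
  ids <- names(assignments)
  out <- vapply(sort(unique(assignments)), function(g) {
    members <- ids[assignments == g]
    if (length(members) < 2) {
      message("singleton cluster ", g, ": consensus set to 1 by convention")
      return(1)
    }
    sub <- M[members, members]
    sum(sub[upper.tri(sub)]) / (length(members) * (length(members) - 1) / 2)
  }, numeric(1))
  names(out) <- as.character(sort(unique(assignments)))
  out
}

#' Select the number of subgroups from cluster-consensus scores
#'
#' Rule: the chosen K is the LARGEST evaluated K whose minimum cluster
#' consensus exceeds `threshold` — among stable partitions, finer structure is
#' preferred. If no K qualifies, `chosen` is `NA` and downstream stages refuse
#' to run without an explicit override.
#'
#' @param score_table data.frame with columns `k` and `min_consensus` (see
#'   [consensus_subtype()]), or a list of `consensus_run` objects.
#' @param threshold consensus threshold (default 0.8).
#' @return Object of class `consensus_selection`: `chosen` (integer or NA),
#'   `table`, `threshold`, `rule`.
#' @export
select_cluster_count <- function(score_table, threshold = 0.8) {
  if (is.list(score_table) && !is.data.frame(score_table)) {
    score_table <- data.frame(
      k = vapply(score_table, function(r) r$k, numeric(1)),
      min_consensus = vapply(score_table,
                             function(r) min(r$cluster_consensus), numeric(1)))
  }
  if (!nrow(score_table)) stop("no cluster counts evaluated")
  qual <- score_table$k[score_table$min_consensus > threshold]
  chosen <- if (length(qual)) max(qual) else NA_integer_
  out <- list(chosen = chosen, table = score_table, threshold = threshold,
              rule = sprintf(
                "largest K with minimum cluster consensus > %.2f", threshold))
  class(out) <- "consensus_selection"
  out
}

#' Consensus subtyping across a range of cluster counts
#'
#' Runs [consensus_cluster()] for K = 2..`k_max` (same resampling scheme and
#' seed for every K) and applies the selection rule of
#' [select_cluster_count()].
#'
#' @inheritParams consensus_cluster
#' @param k_max largest cluster count to evaluate (default 10).
#' @param threshold cluster-consensus selection threshold (default 0.8).
#' @return Object of class `consensus_selection` augmented with `runs` (list
#'   of `consensus_run` keyed by K) and `assignments` for the chosen K (NULL
#'   if none qualifies).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_genes = 300, seed = 5))
#' ad <- cohort$annotation$condition == "AD"
#' sel <- consensus_subtype(cohort$expression[, ad], k_max = 4,
#'                          n_resamples = 20, seed = 5)
#' sel$chosen
#' }
#' @export
consensus_subtype <- function(expression, k_max = 10L, threshold = 0.8,
                              n_resamples = 100L, sample_fraction = 0.8,
                              seed = 1L, base = c("kmeans", "hclust"),
                              scale_genes = TRUE) {
  base <- match.arg(base)
  k_max <- min(k_max, ncol(expression))
  runs <- lapply(2:k_max, function(k) {
    consensus_cluster(expression, k, n_resamples = n_resamples,
                      sample_fraction = sample_fraction, seed = seed,
                      base = base, scale_genes = scale_genes)
  })
  names(runs) <- as.character(2:k_max)
  tab <- data.frame(
    k = 2:k_max,
    min_consensus = vapply(runs, function(r) min(r$cluster_consensus), numeric(1)),
    consensus_scores = vapply(runs, function(r) {
      paste(sprintf("%.4f", r$cluster_consensus), collapse = ",")
    }, character(1)))
  sel <- select_cluster_count(tab[, c("k", "min_consensus")], threshold)
  sel$table <- tab
  sel$runs <- runs
  sel$assignments <- if (!is.na(sel$chosen)) {
    runs[[as.character(sel$chosen)]]$assignments
  }
  sel
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat("Consensus subgroup selection\n")
  cat("  rule:", x$rule, "\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (is.na(x$chosen)) {
    cat("  no K qualifies at threshold", x$threshold, "\n")
  } else {
    cat("  chosen K:", x$chosen, "\n")
    if (!is.null(x$assignments)) {
      cat("  subgroup sizes:", paste(table(x$assignments), collapse = "/"), "\n")
    }
  }
  invisible(x)
}

#' @export
print.consensus_run <- function(x, ...) {
  cat(sprintf("Consensus run: K = %d, %d samples, %d resamples at fraction %.2f\n",
              x$k, ncol(x$M), x$n_resamples, x$sample_fraction))
  cat("  cluster consensus:",
      paste(sprintf("%s=%.3f", names(x$cluster_consensus), x$cluster_consensus),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.consensus_run <- function(x, ...) {
  ordi <- order(x$assignments)
  graphics::image(x$M[ordi, ordi][, rev(seq_len(ncol(x$M)))],
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  axes = FALSE,
                  main = sprintf("Consensus matrix, K = %d", x$k), ...)
  invisible(x)
}
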