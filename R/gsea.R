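#' Ranked gene list for enrichment analysis
#'
#' Computes a per-gene rank metric comparing two sample groups and returns the
#' genes sorted by metric, descending, ties broken by gene id (deterministic).
#' The default metric is signal-to-noise, `(mean_a - mean_b)/(sd_a + sd_b)`;
#' a group standard deviation of (numerically) zero is replaced by
#' `max(0.2 |mean|, 1e-8)` so constant genes never divide by zero. The
#' alternative metric is the signed two-sample t statistic (Welch).
#'
#' @param expression genes x samples matrix.
#' @param annotation data.frame with `sample_id` and the grouping column.
#' @param group_a,group_b labels of the compared groups (`group_b` = reference).
#' @param group_col annotation column with the labels.
#' @param metric `"s2n"` (signal-to-noise, default) or `"t"`.
#' @return Object of class `ranked_list`: data.frame `gene`, `metric`, sorted;
#'   attributes record the metric and groups compared.
#' @export
rank_metric <- function(expression, annotation, group_a, group_b,
                        group_col = "condition", metric = c("s2n", "t")) {
  metric <- match.arg(metric)
  annotation <- annotation[match(colnames(expression), annotation$sample_id), ,
                           drop = FALSE]
  ia <- which(annotation[[group_col]] == group_a)
  ib <- which(annotation[[group_col]] == group_b)
  if (length(ia) < 3) stop("group '", group_a, "' has fewer than 3 samples")
  if (length(ib) < 3) stop("group '", group_b, "' has fewer than 3 samples")
  m <- rank_metric_values(expression, ia, ib, metric)
  ord <- order(-m, rownames(expression), method = "radix")
  out <- data.frame(gene = rownames(expression)[ord], metric = m[ord],
                    stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "groups") <- c(group_a, group_b)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# vectorized metric over column index sets; used by the permutation loop
rank_metric_values <- function(expression, ia, ib, metric) {
  xa <- expression[, ia, drop = FALSE]
  xb <- expression[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (length(ia) - 1)
  vb <- rowSums((xb - mb)^2) / (length(ib) - 1)
  if (metric == "s2n") {
    sda <- sqrt(va); sdb <- sqrt(vb)
    sda <- ifelse(sda < 1e-8, pmax(0.2 * abs(ma), 1e-8), sda)
    sdb <- ifelse(sdb < 1e-8, pmax(0.2 * abs(mb), 1e-8), sdb)
    (ma - mb) / (sda + sdb)
  } else {
    se2 <- va / length(ia) + vb / length(ib)
    (ma - mb) / sqrt(pmax(se2, 1e-16))
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: positions in the gene set increment the running sum
#' by `|metric|^p / sum_hits |metric|^p`, others decrement by
#' `1/(N - N_hits)`. The enrichment score is the signed extremum of the
#' running sum, which returns to 0 at the final position.
#'
#' @param ranked a `ranked_list` from [rank_metric()] (or a data.frame with
#'   `gene` and `metric` columns in rank order).
#' @param gene_set character vector of gene ids.
#' @param p hit-weighting exponent (default 1; 0 gives the unweighted
#'   classic statistic).
#' @return list: `es`, `running` (per-position sum), `hit_positions`,
#'   `peak` (position of the signed extremum).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  genes <- ranked$gene
  n <- length(genes)
  hit <- genes %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0) stop("gene set has no overlap with the ranked list")
  if (n_hit == n) stop("gene set covers the whole ranked list")
  w <- abs(ranked$metric)^p
  w_hit <- w * hit
  denom <- sum(w_hit)
  if (denom == 0) {
    # all hit weights zero (e.g. all-zero metrics at p = 1): fall back to
    # equal hit weights, as with p = 0
    w_hit <- as.numeric(hit)
    denom <- n_hit
  }
  step <- ifelse(hit, w_hit / denom, -1 / (n - n_hit))
  running <- cumsum(step)
  i_max <- which.max(running)
  i_min <- which.min(running)
  es <- if (abs(running[i_max]) >= abs(running[i_min])) running[i_max] else running[i_min]
  peak <- if (es >= 0) i_max else i_min
  list(es = es, running = running, hit_positions = which(hit), peak = peak)
}

#' Leading-edge (core enrichment) genes
#'
#' For a positive enrichment score: the gene-set members at or before the
#' running-sum maximum; for a negative score, members at or after the minimum.
#'
#' @param es_obj result of [enrichment_score()].
#' @param ranked the ranked list the score was computed on.
#' @return character vector of leading-edge gene ids, in rank order.
#' @export
leading_edge <- function(es_obj, ranked) {
  if (es_obj$es == 0) stop("leading edge undefined for ES = 0")
  pos <- es_obj$hit_positions
  keep <- if (es_obj$es > 0) pos[pos <= es_obj$peak] else pos[pos >= es_obj$peak]
  ranked$gene[keep]
}

#' GSEA with phenotype permutation
#'
#' For each gene set: observed enrichment score on the `group_a` vs `group_b`
#' ranked list, then `n_permutations` phenotype-label permutations that
#' regenerate the rank metric and the score each time. Nominal p is the
#' smoothed fraction of same-sign permuted scores at least as extreme as the
#' observed one; NES divides ES by the mean |same-sign permuted ES|; FDR q is
#' the standard NES-based ratio pooled across the evaluated collection. When
#' the number of distinct label splits does not exceed `n_permutations` the
#' permutations are enumerated exhaustively (with a message).
#'
#' @inheritParams rank_metric
#' @param gene_sets named list of gene-id vectors (a collection; a single set
#'   is a collection of one).
#' @param n_permutations permutation count (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param weight hit-weighting exponent passed to [enrichment_score()].
#' @return Object of class `gsea_result`: data.frame per set (`set`, `size`,
#'   `es`, `nes`, `p_nominal`, `fdr_q`, `leading_edge` comma-joined,
#'   `n_permutations`), plus `details` (per-set running sums and leading
#'   edges) and the observed `ranked` list.
#' @export
gsea <- function(expression, annotation, group_a, group_b, gene_sets,
                 group_col = "condition", metric = c("s2n", "t"),
                 n_permutations = 1000L, seed = 1L, weight = 1) {
  metric <- match.arg(metric)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (is.character(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets))) names(gene_sets) <- paste0("set", seq_along(gene_sets))

  annotation <- annotation[match(colnames(expression), annotation$sample_id), ,
                           drop = FALSE]
  ia <- which(annotation[[group_col]] == group_a)
  ib <- which(annotation[[group_col]] == group_b)
  if (length(ia) < 3 || length(ib) < 3) stop("each group needs at least 3 samples")
  pool <- c(ia, ib)
  n_a <- length(ia)

  ranked <- rank_metric(expression, annotation, group_a, group_b,
                        group_col = group_col, metric = metric)
  obs <- lapply(gene_sets, function(gs) {
    eso <- enrichment_score(ranked, gs, p = weight)
    eso$le <- leading_edge(eso, ranked)
    eso
  })

  # permutation assignments of the group_a role within the pooled samples
  n_splits <- choose(length(pool), n_a)
  exhaustive <- is.finite(n_splits) && n_splits <= n_permutations
  if (exhaustive) {
    message("enumerating all ", n_splits, " label splits exhaustively")
    splits <- utils::combn(length(pool), n_a, simplify = FALSE)
  } else {
    splits <- with_seed(as.integer(seed), {
      lapply(seq_len(n_permutations), function(i) sample.int(length(pool), n_a))
    })
  }

  gene_ids <- rownames(expression)
  perm_es <- matrix(NA_real_, length(splits), length(gene_sets),
                    dimnames = list(NULL, names(gene_sets)))
  for (s in seq_along(splits)) {
    pa <- pool[splits[[s]]]
    pb <- pool[-splits[[s]]]
    mvals <- rank_metric_values(expression, pa, pb, metric)
    ord <- order(-mvals, gene_ids, method = "radix")
    rl <- data.frame(gene = gene_ids[ord], metric = mvals[ord],
                     stringsAsFactors = FALSE)
    for (g in seq_along(gene_sets)) {
      perm_es[s, g] <- enrichment_score(rl, gene_sets[[g]], p = weight)$es
    }
  }

  res <- data.frame(set = names(gene_sets),
                    size = vapply(gene_sets, function(gs) sum(gs %in% gene_ids),
                                  numeric(1)),
                    es = vapply(obs, function(o) o$es, numeric(1)),
                    nes = NA_real_, p_nominal = NA_real_, fdr_q = NA_real_,
                    leading_edge = vapply(obs, function(o) {
                      paste(o$le, collapse = ",")
                    }, character(1)),
                    n_permutations = length(splits),
                    stringsAsFactors = FALSE)
  for (g in seq_len(nrow(res))) {
    es_g <- res$es[g]
    same_sign <- perm_es[, g][sign(perm_es[, g]) == sign(es_g)]
    res$p_nominal[g] <- (1 + sum(abs(same_sign) >= abs(es_g))) /
      (1 + length(same_sign))
    res$nes[g] <- if (length(same_sign)) es_g / mean(abs(same_sign)) else NA_real_
  }
  # NES-based FDR across the collection, pooled permuted NES as the null
  perm_nes <- perm_es
  for (g in seq_len(ncol(perm_es))) {
    for (sgn in c(1, -1)) {
      sel <- sign(perm_es[, g]) == sgn
      if (any(sel)) {
        perm_nes[sel, g] <- perm_es[sel, g] / mean(abs(perm_es[sel, g]))
      }
    }
  }
  all_perm_nes <- as.vector(perm_nes)
  for (g in seq_len(nrow(res))) {
    nes_g <- res$nes[g]
    if (!is.finite(nes_g)) next
    if (nes_g >= 0) {
      num <- mean(all_perm_nes[all_perm_nes >= 0] >= nes_g)
      den <- mean(res$nes[res$nes >= 0] >= nes_g)
    } else {
      num <- mean(all_perm_nes[all_perm_nes <= 0] <= nes_g)
      den <- mean(res$nes[res$nes <= 0] <= nes_g)
    }
    res$fdr_q[g] <- min(1, ifelse(den > 0, num / den, 1))
  }
  out <- list(table = res, details = obs, ranked = ranked,
              exhaustive = exhaustive)
  class(out) <- "gsea_result"
  out
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("GSEA (phenotype permutation",
      if (x$exhaustive) ", exhaustive)" else ")", "\n", sep = "")
  tab <- x$table
  tab$leading_edge <- paste0(vapply(strsplit(tab$leading_edge, ","),
                                    length, integer(1)), " genes")
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Hub-gene selection from the leading edge
#'
#' The top `k` leading-edge (core enrichment) genes ranked by absolute rank
#' metric score, ties broken by gene id; fewer are returned when the leading
#' edge is smaller than `k`.
#'
#' @param es_obj result of [enrichment_score()] (or an element of
#'   `gsea()$details`).
#' @param ranked the ranked list the score was computed on.
#' @param k panel size cap (default 10).
#' @return data.frame `gene`, `metric`, ordered by |metric| descending.
#' @export
select_hub_genes <- function(es_obj, ranked, k = 10L) {
  le <- leading_edge(es_obj, ranked)
  if (!length(le)) stop("empty leading edge")
  m <- ranked$metric[match(le, ranked$gene)]
  ord <- order(-abs(m), le, method = "radix")
  take <- utils::head(ord, k)
  data.frame(gene = le[take], metric = m[take], stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' selected gene list and each set of a collection, given the universe size;
#' BH adjustment across the collection.
#'
#' @param selected character vector of selected gene ids (subset of universe).
#' @param gene_sets named list of gene-id vectors (subsets of universe).
#' @param universe character vector of all eligible gene ids.
#' @return data.frame `set`, `set_size`, `overlap`, `p`, `q` (BH).
#' @export
ora_test <- function(selected, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(selected)) stop("empty selection")
  if (!all(selected %in% universe)) stop("selected genes must lie in the universe")
  if (is.character(gene_sets)) gene_sets <- list(set = gene_sets)
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    gs <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(selected, gs))
    p <- stats::phyper(ov - 1, length(gs), length(universe) - length(gs),
                       length(selected), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(gs), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_adjust(res$p)
  res
}
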