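# Independent oracles used by the test suite. Each is a deliberately naive
# re-derivation (enumeration, definitional formula, position-by-position walk)
# kept separate from the implementation it checks.

# exact two-sided rank-sum p by enumerating every assignment of ranks
oracle_rank_sum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  w_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  w_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  })
  mu <- n * m / 2
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  min(1, p)
}

# definitional BH: q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ranks_ge <- which(p[ord] >= p[ord][i])
    q[ord[i]] <- min(1, min(m * p[ord][ranks_ge] / ranks_ge))
  }
  q
}

# independent enrichment-score walker, one position at a time
oracle_es_walk <- function(genes, metrics, gene_set, p = 1) {
  n <- length(genes)
  in_set <- genes %in% gene_set
  total_hit_weight <- sum(abs(metrics[in_set])^p)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      cur <- cur + if (total_hit_weight > 0) {
        abs(metrics[i])^p / total_hit_weight
      } else 1 / sum(in_set)
    } else {
      cur <- cur - 1 / (n - sum(in_set))
    }
    running[i] <- cur
  }
  extreme <- range(running)
  if (abs(extreme[2]) >= abs(extreme[1])) extreme[2] else extreme[1]
}

# trapezoidal area under the empirical ROC curve
oracle_auc_trapezoid <- function(scores, labels, positive = 1) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- labels == positive
  tpr <- c(0, vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# per-batch location/scale standardization restored to the pooled scale:
# the no-shrinkage adjustment oracle
oracle_batch_standardize <- function(expression, batch, stand_mean, sigma2) {
  out <- expression
  for (lvl in levels(batch)) {
    cols <- which(batch == lvl)
    z <- (expression[, cols, drop = FALSE] - stand_mean[, cols, drop = FALSE]) /
      sqrt(sigma2)
    mu <- rowMeans(z)
    s <- apply(z, 1, stats::sd)
    out[, cols] <- ((z - mu) / s) * sqrt(sigma2) + stand_mean[, cols, drop = FALSE]
  }
  out
}

# small two-batch cohort with a pure additive +shift between batches and a
# protected AD/ND condition effect; used across the batch-correction tests
shifted_batch_data <- function(n_genes = 50, n_per_batch = 40, shift = 2,
                               seed = 42, noise_sd = 0.3) {
  set.seed(seed)
  n <- 2 * n_per_batch
  mu <- rnorm(n_genes, 7, 1)
  condition <- rep(rep(c("AD", "ND"), each = n_per_batch / 2), 2)
  x <- matrix(rnorm(n_genes * n, 0, noise_sd), n_genes) + mu
  x[, (n_per_batch + 1):n] <- x[, (n_per_batch + 1):n] + shift
  dimnames(x) <- list(sprintf("g%03d", 1:n_genes), sprintf("s%03d", 1:n))
  annot <- data.frame(sample_id = colnames(x),
                      batch = rep(c("b1", "b2"), each = n_per_batch),
                      condition = condition, stringsAsFactors = FALSE)
  list(expression = x, annotation = annot)
}
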