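# small deterministic two-group matrix for metric tests
metric_fixture <- function() {
  x <- rbind(
    gHi  = c(4, 4, 4, 2, 2, 2),    # means 4 vs 2
    gNull = c(5, 5, 5, 5, 5, 5),   # constant
    gLo  = c(1, 1, 1, 3, 3, 3))
  x <- x + 0  # numeric
  colnames(x) <- paste0("s", 1:6)
  x
}

test_that("signal-to-noise metric follows its formula with an sd floor", {
  set.seed(60)
  x <- matrix(rnorm(5 * 12, 7), 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  x[1, 1:6] <- c(4.5, 3.5, 4.0, 4.2, 3.8, 4.0)   # mean 4, sd ~0.35
  x[1, 7:12] <- c(2.5, 1.5, 2.0, 2.2, 1.8, 2.0)  # mean 2
  annot <- data.frame(sample_id = colnames(x),
                      condition = rep(c("AD", "ND"), each = 6))
  rl <- rank_metric(x, annot, "AD", "ND")
  sda <- sd(x[1, 1:6]); sdb <- sd(x[1, 7:12])
  expect_equal(rl$metric[rl$gene == "g1"], 2 / (sda + sdb))
  # sds of 0.5 exactly: metric (4-2)/(0.5+0.5) = 2
  y <- x
  y[2, ] <- c(4, 4.5, 3.5, 4.561, 3.439, 4, 2, 2.5, 1.5, 2.561, 1.439, 2)
  rl2 <- rank_metric(y, annot, "AD", "ND")
  m2 <- rl2$metric[rl2$gene == "g2"]
  expect_equal(m2, 2 / (sd(y[2, 1:6]) + sd(y[2, 7:12])))
  # zero-sd guard: no division error, metric 0 for equal means
  z <- x
  z[3, ] <- 10
  rl3 <- rank_metric(z, annot, "AD", "ND")
  expect_equal(rl3$metric[rl3$gene == "g3"], 0)
})

test_that("identical groups give zero metrics ordered by gene id", {
  set.seed(61)
  x <- matrix(rnorm(6 * 6, 7), 6,
              dimnames = list(paste0("g", 6:1), paste0("s", 1:6)))
  x <- cbind(x, x)
  colnames(x) <- paste0("s", 1:12)
  annot <- data.frame(sample_id = colnames(x),
                      condition = rep(c("AD", "ND"), each = 6))
  rl <- rank_metric(x, annot, "AD", "ND")
  expect_equal(rl$metric, rep(0, 6))
  expect_identical(rl$gene, sort(rl$gene))
  expect_error(rank_metric(x[, 1:8], annot[1:8, ], "AD", "ND"), "fewer than 3")
})

test_that("enrichment score walks match the by-hand case", {
  ranked <- data.frame(gene = paste0("g", 1:5),
                       metric = c(3, 2, 1, 0.5, 0.2))
  es <- enrichment_score(ranked, c("g1", "g2"), p = 0)
  expect_equal(es$es, 1.0)
  expect_equal(es$running, c(0.5, 1.0, 1 - 1/3, 1 - 2/3, 0), tolerance = 1e-12)
  es_neg <- enrichment_score(ranked, c("g4", "g5"), p = 0)
  expect_equal(es_neg$es, -1.0)
  expect_error(enrichment_score(ranked, "zzz"), "no overlap")
  expect_error(enrichment_score(ranked, ranked$gene), "whole ranked list")
})

test_that("enrichment scores agree with an independent walker", {
  set.seed(62)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    genes <- paste0("g", sample(100, n))
    metrics <- sort(round(rnorm(n), 3), decreasing = TRUE)
    set_size <- sample(1:(n - 1), 1)
    gs <- sample(genes, set_size)
    p <- sample(c(0, 1), 1)
    ranked <- data.frame(gene = genes, metric = metrics)
    expect_equal(enrichment_score(ranked, gs, p = p)$es,
                 oracle_es_walk(genes, metrics, gs, p = p), tolerance = 1e-12)
  }
})

test_that("the running sum returns to zero and ES is scale invariant", {
  set.seed(63)
  genes <- paste0("g", 1:30)
  metrics <- sort(rnorm(30, 0, 2), decreasing = TRUE)
  ranked <- data.frame(gene = genes, metric = metrics)
  gs <- sample(genes, 8)
  for (p in c(0, 1)) {
    es <- enrichment_score(ranked, gs, p = p)
    expect_lt(abs(es$running[30]), 1e-9)
    scaled <- ranked
    scaled$metric <- scaled$metric * 7.3
    expect_equal(enrichment_score(scaled, gs, p = p)$es, es$es,
                 tolerance = 1e-12)
    expect_lte(abs(es$es), 1)
  }
})

test_that("ES matches the reference fgsea statistic", {
  skip_if_not_installed("fgsea")
  set.seed(64)
  genes <- paste0("g", 1:50)
  metrics <- sort(rnorm(50), decreasing = TRUE)
  ranked <- data.frame(gene = genes, metric = metrics)
  stats_vec <- setNames(metrics, genes)
  for (i in 1:5) {
    gs <- sample(genes, 10)
    es <- enrichment_score(ranked, gs, p = 1)$es
    ref <- fgsea::calcGseaStat(stats_vec, selectedStats = match(gs, genes),
                               gseaParam = 1)
    expect_equal(es, ref, tolerance = 1e-6)
  }
})

test_that("leading edge follows the peak of the running sum", {
  ranked <- data.frame(gene = paste0("g", 1:5),
                       metric = c(3, 2, 1, 0.5, 0.2))
  es <- enrichment_score(ranked, c("g1", "g2"), p = 0)
  expect_identical(leading_edge(es, ranked), c("g1", "g2"))
  es_neg <- enrichment_score(ranked, c("g4", "g5"), p = 0)
  expect_identical(leading_edge(es_neg, ranked), c("g4", "g5"))
  # a member ranked after the positive peak is excluded
  es_mix <- enrichment_score(ranked, c("g1", "g5"), p = 0)
  expect_gt(es_mix$es, 0)
  expect_identical(leading_edge(es_mix, ranked), "g1")
})

test_that("phenotype permutation p values match exhaustive enumeration", {
  set.seed(65)
  x <- matrix(rnorm(20 * 6, 7), 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  x[1:5, 1:3] <- x[1:5, 1:3] + 2
  annot <- data.frame(sample_id = colnames(x),
                      condition = rep(c("AD", "ND"), each = 3))
  gs <- list(top = paste0("g", 1:5))
  expect_message(
    res <- gsea(x, annot, "AD", "ND", gs, n_permutations = 20, seed = 1),
    "exhaustively")
  expect_equal(res$table$n_permutations, 20)  # C(6,3) splits
  # independent enumeration of the same 20 splits
  pool <- 1:6
  splits <- utils::combn(6, 3, simplify = FALSE)
  es_all <- vapply(splits, function(idx) {
    m <- rowMeans(x[, pool[idx], drop = FALSE]) -
      rowMeans(x[, pool[-idx], drop = FALSE])
    sda <- apply(x[, pool[idx], drop = FALSE], 1, sd)
    sdb <- apply(x[, pool[-idx], drop = FALSE], 1, sd)
    metric <- m / (sda + sdb)
    ord <- order(-metric, rownames(x), method = "radix")
    oracle_es_walk(rownames(x)[ord], metric[ord], gs$top, p = 1)
  }, numeric(1))
  obs <- res$table$es
  same_sign <- es_all[sign(es_all) == sign(obs)]
  p_oracle <- (1 + sum(abs(same_sign) >= abs(obs))) / (1 + length(same_sign))
  expect_equal(res$table$p_nominal, p_oracle, tolerance = 1e-12)
})

test_that("planted signal yields positive, significant enrichment", {
  cfg <- cohort_config(n_genes = 300, n_marker_genes_per_subtype = 25,
                       marker_effect = 1, batch_location_sd = 0,
                       batch_scale_range = c(1, 1),
                       batches = data.frame(batch_id = "b1",
                                            n_AD = 90, n_ND = 60),
                       seed = 66)
  co <- generate_cohort(cfg)
  ann <- co$annotation
  ann$subgroup <- ifelse(ann$condition == "ND", "ND",
                         paste0("subtype", co$truth$true_subtype[ann$sample_id]))
  res <- gsea(co$expression, ann, "subtype1", "ND",
              list(planted = co$truth$marker_map$subtype1),
              group_col = "subgroup", n_permutations = 1000, seed = 2)
  expect_gt(res$table$es, 0)
  expect_lte(res$table$p_nominal, 0.01)
  le <- strsplit(res$table$leading_edge, ",")[[1]]
  expect_true(all(le %in% co$truth$marker_map$subtype1))
})

test_that("hub selection caps at k, keeps order and breaks ties by id", {
  ranked <- data.frame(gene = sprintf("g%02d", 1:30),
                       metric = c(seq(3, 0.2, length.out = 15), rep(0.1, 15)))
  es <- enrichment_score(ranked, ranked$gene[1:15], p = 1)
  hubs <- select_hub_genes(es, ranked, k = 10)
  expect_equal(nrow(hubs), 10)
  expect_identical(hubs$gene, ranked$gene[1:10])
  hubs7 <- select_hub_genes(enrichment_score(ranked, ranked$gene[1:7], p = 1),
                            ranked, k = 10)
  expect_equal(nrow(hubs7), 7)
  # equal metrics: deterministic id order
  tied <- data.frame(gene = c("gB", "gA", "gC", "gD", "gE"),
                     metric = c(2, 2, 1, -0.5, -0.6))
  es_t <- enrichment_score(tied, c("gA", "gB"), p = 1)
  expect_identical(select_hub_genes(es_t, tied, k = 2)$gene, c("gA", "gB"))
})

test_that("hypergeometric over-representation equals the exact tail sum", {
  universe <- paste0("u", 1:20)
  gs <- list(s = universe[1:5])
  selected <- c(universe[1:3], universe[10:11])  # overlap 3
  res <- ora_test(selected, gs, universe)
  expect_equal(res$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$overlap, 3)
  # selected identical to the set
  res2 <- ora_test(universe[1:5], gs, universe)
  p_brute <- sum(choose(5, 5) * choose(15, 0)) / choose(20, 5)
  expect_equal(res2$p, p_brute, tolerance = 1e-12)
  # zero overlap keeps p <= 1
  res3 <- ora_test(universe[16:18], list(s = universe[1:2]), universe)
  expect_lte(res3$p, 1)
  expect_error(ora_test(character(0), gs, universe), "empty")
  expect_error(ora_test("zzz", gs, universe), "universe")
})
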