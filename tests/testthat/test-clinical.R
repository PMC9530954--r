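test_that("planted CDR offsets show up in the expected pairwise comparisons", {
  co <- generate_cohort(cohort_config(
    n_genes = 30, n_marker_genes_per_subtype = 3,
    batches = data.frame(batch_id = "b1", n_AD = 450, n_ND = 150),
    seed = 70))
  ann <- co$annotation
  ann$subgroup <- ifelse(ann$condition == "ND", "ND",
                         paste0("sub", co$truth$true_subtype[ann$sample_id]))
  res <- compare_traits(ann, "subgroup", c("CDR", "pH"))
  get_p <- function(trait, a, b) {
    res$p[res$trait == trait &
            ((res$group_a == a & res$group_b == b) |
               (res$group_a == b & res$group_b == a))]
  }
  # defaults plant CDR offsets 2.0/1.0/2.0: sub1 vs sub2 and sub2 vs sub3
  # differ, sub1 vs sub3 do not
  expect_lt(get_p("CDR", "sub1", "sub2"), 0.001)
  expect_lt(get_p("CDR", "sub2", "sub3"), 0.001)
  expect_gt(get_p("CDR", "sub1", "sub3"), 0.05)
  # pH is lowered in every AD subgroup
  for (sg in c("sub1", "sub2", "sub3")) expect_lt(get_p("pH", "ND", sg), 0.001)
  expect_true(all(res$n_a >= 2 & res$n_b >= 2))
})

test_that("identical trait values give p = 1 and missing levels are skipped", {
  ann <- data.frame(sample_id = paste0("s", 1:12),
                    grp = rep(c("a", "b", "c"), each = 4),
                    flat = rep(5, 12),
                    partial = c(rnorm(4), rnorm(4), rep(NA, 4)))
  res <- suppressWarnings(suppressMessages(compare_traits(ann, "grp", c("flat", "partial"))))
  expect_true(all(res$p[res$trait == "flat"] == 1))
  # pairs involving the all-missing level are absent
  expect_false(any(res$trait == "partial" & (res$group_a == "c" | res$group_b == "c")))
})

test_that("proportion test matches the pooled z-squared oracle", {
  res <- proportion_test(30, 50, 10, 50)
  expect_equal(round(res$statistic, 2), 16.67)
  expect_lt(res$p.value, 1e-4)
  res_eq <- proportion_test(20, 40, 10, 20)
  expect_equal(res_eq$statistic, 0, tolerance = 1e-12)
  expect_equal(res_eq$p.value, 1)
  set.seed(71)
  for (i in 1:50) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    s1 <- sample(1:(n1 - 1), 1); s2 <- sample(1:(n2 - 1), 1)
    p1 <- s1 / n1; p2 <- s2 / n2; pp <- (s1 + s2) / (n1 + n2)
    z2 <- (p1 - p2)^2 / (pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(proportion_test(s1, n1, s2, n2)$statistic, z2,
                 tolerance = 1e-10)
  }
  expect_error(proportion_test(0, 10, 0, 10), "degenerate")
})

test_that("spearman correlation matches hand-computed values", {
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 5, 7))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  expect_equal(spearman_cor(1:6, -(1:6))$rho, -1)
  expect_error(spearman_cor(c(1, 2), c(3, 4)), "at least 3")
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  # missing values are dropped pairwise without changing the complete subset
  x <- c(1, 2, 3, 4, NA); y <- c(2, 1, 4, 3, 9)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(x[1:4], y[1:4])$rho)
  expect_equal(spearman_cor(x, y)$n, 4)
})

test_that("kruskal-wallis matches the rank-sum identity and hand values", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 4.571, tolerance = 1e-3)
  expect_equal(res$df, 2)
  flat <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
  # k = 2 tie-free: H equals the squared standardized rank-sum statistic
  set.seed(72)
  x <- rnorm(9); y <- rnorm(7, 1)
  H <- kruskal_wallis(list(x, y))$statistic
  n <- 9; m <- 7; N <- n + m
  W <- sum(rank(c(x, y))[1:n])
  z <- (W - n * (N + 1) / 2) / sqrt(n * m * (N + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-10)
})

test_that("module eigengenes summarize their gene set faithfully", {
  set.seed(73)
  # single gene: eigengene is (up to scale) that gene, oriented positively
  x1 <- matrix(rnorm(20, 7), 1,
               dimnames = list("gA", paste0("s", 1:20)))
  me1 <- module_eigengene(x1)
  expect_equal(abs(cor(me1$scores, x1[1, ])), 1, tolerance = 1e-12)
  expect_gt(cor(me1$scores, x1[1, ]), 0)
  expect_equal(mean(me1$scores), 0, tolerance = 1e-12)

  # two perfectly correlated genes: variance explained 1
  base <- rnorm(15)
  x2 <- rbind(gA = 2 * base + 3, gB = -base + 5)
  colnames(x2) <- paste0("s", 1:15)
  me2 <- module_eigengene(x2)
  expect_equal(me2$variance_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(me2$scores, base)), 1, tolerance = 1e-10)

  # duplicating every gene leaves the eigengene unchanged up to sign/scale
  set.seed(74)
  x3 <- matrix(rnorm(8 * 30, 7), 8,
               dimnames = list(paste0("g", 1:8), paste0("s", 1:30)))
  me3 <- module_eigengene(x3)
  me3d <- module_eigengene(rbind(x3, x3 + 0))
  expect_equal(abs(cor(me3$scores, me3d$scores)), 1, tolerance = 1e-9)
  expect_error(module_eigengene(matrix(3, 2, 5,
                                       dimnames = list(c("a", "b"), NULL))),
               "constant")
})

test_that("eigengene-trait coupling recovers the planted sign pattern", {
  co <- generate_cohort(cohort_config(
    n_genes = 200, n_marker_genes_per_subtype = 25,
    batches = data.frame(batch_id = "b1", n_AD = 300, n_ND = 100),
    batch_location_sd = 0, batch_scale_range = c(1, 1), seed = 75))
  ann <- co$annotation
  ad <- ann[ann$condition == "AD", ]
  x_ad <- co$expression[, ad$sample_id]
  # subtype-1 signature eigengene is high exactly in subtype-1 samples,
  # which carry the high CDR offset; subtype-2's carry the low offset
  me1 <- module_eigengene(x_ad, genes = co$truth$marker_map$subtype1)
  me2 <- module_eigengene(x_ad, genes = co$truth$marker_map$subtype2)
  rho1 <- spearman_cor(me1$scores, ad$CDR)$rho
  rho2 <- spearman_cor(me2$scores, ad$CDR)$rho
  expect_gt(rho1, 0)
  expect_lt(rho2, 0)
})

test_that("trait correlation tables are pairwise-complete and symmetric", {
  set.seed(76)
  n <- 60
  cdr <- rnorm(n, 1)
  ann <- data.frame(sample_id = paste0("s", 1:n), CDR = cdr,
                    noise = rnorm(n))
  gene_like <- list(tracker = cdr + rnorm(n, 0, 0.1),
                    shuffled = sample(cdr))
  tab <- trait_correlation_table(gene_like, ann, c("CDR", "noise"))
  expect_gt(tab$rho["tracker", "CDR"], 0.9)
  expect_lt(abs(tab$rho["shuffled", "CDR"]), 0.35)
  # transpose consistency: corr(gene, trait) == corr(trait, gene)
  rev_tab <- trait_correlation_table(list(CDR = cdr),
                                     data.frame(sample_id = paste0("s", 1:n),
                                                tracker = gene_like$tracker),
                                     "tracker")
  expect_equal(tab$rho["tracker", "CDR"], rev_tab$rho["CDR", "tracker"],
               tolerance = 1e-12)
  # injected missingness never changes the complete-subset result
  ann2 <- ann
  ann2$CDR[1:5] <- NA
  tab2 <- trait_correlation_table(gene_like, ann2, c("CDR", "noise"))
  ref <- spearman_cor(gene_like$tracker[-(1:5)], cdr[-(1:5)])$rho
  expect_equal(tab2$rho["tracker", "CDR"], ref, tolerance = 1e-12)
  expect_equal(tab2$n["tracker", "CDR"], n - 5)
  # cells with under 3 pairs are NA
  ann3 <- ann
  ann3$CDR[-(1:2)] <- NA
  tab3 <- trait_correlation_table(gene_like, ann3, "CDR")
  expect_true(is.na(tab3$rho["tracker", "CDR"]))
})
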