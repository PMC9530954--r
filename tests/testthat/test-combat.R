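test_that("single batch, no covariates: Z is the gene-wise z-score", {
  set.seed(1)
  x <- matrix(rnorm(5 * 10, 7), 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  annot <- data.frame(sample_id = colnames(x), batch = "b1",
                      condition = rep(c("AD", "ND"), 5))
  model <- combat_standardize(x, annot, covariates = character(0))
  zs <- t(apply(x, 1, function(r) (r - mean(r)) / (sd(r) * sqrt(9 / 10))))
  expect_equal(model$Z, zs, tolerance = 1e-12)
  expect_equal(rowMeans(model$Z), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowMeans(model$Z^2), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a pure +2 batch shift yields gamma estimates of -1 and +1 sigma", {
  d <- shifted_batch_data(n_genes = 30, n_per_batch = 100, shift = 2,
                          noise_sd = 1e-3, seed = 7)
  model <- combat_standardize(d$expression, d$annotation,
                              covariates = character(0))
  model <- combat_eb(model, eb = FALSE)
  # oracle: per-batch means of the raw data straddle the grand mean by +-1
  gamma_in_y_units <- model$gamma_hat * sqrt(model$sigma2)[col(model$gamma_hat)]
  expect_equal(unname(gamma_in_y_units[1, ]), rep(-1, 30), tolerance = 1e-2)
  expect_equal(unname(gamma_in_y_units[2, ]), rep(1, 30), tolerance = 1e-2)
})

test_that("constant genes are excluded and passed through unchanged", {
  d <- shifted_batch_data(n_genes = 20, n_per_batch = 10, seed = 3)
  d$expression["g005", ] <- 4
  expect_warning(model <- combat_standardize(d$expression, d$annotation),
                 "zero pooled variance")
  expect_true("g005" %in% model$excluded)
  expect_false("g005" %in% rownames(model$Z))
  model <- combat_eb(model)
  corrected <- combat_adjust(d$expression, model)
  expect_identical(corrected["g005", ], d$expression["g005", ])
})

test_that("confounded designs are rejected", {
  set.seed(2)
  x <- matrix(rnorm(40), 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  annot <- data.frame(sample_id = colnames(x),
                      batch = rep(c("b1", "b2"), each = 5),
                      condition = rep(c("AD", "ND"), each = 5))
  expect_error(combat_standardize(x, annot), "confounded")
})

test_that("converged estimates satisfy both fixed-point equations", {
  # random 5-gene instances; substitution into the printed update equations
  # must reproduce the converged values
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(5 * 24, 7, 1), 5,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:24)))
    x[, 13:24] <- x[, 13:24] + rnorm(5, 0, 0.5)
    annot <- data.frame(sample_id = colnames(x),
                        batch = rep(c("b1", "b2"), each = 12),
                        condition = rep(rep(c("AD", "ND"), each = 6), 2))
    model <- combat_eb(combat_standardize(x, annot), tol = 1e-10,
                       max_iter = 5000)
    for (i in 1:2) {
      if (!model$priors$shrunk[i]) next
      n <- model$n_i[[i]]
      t2 <- model$priors$tau2_bar[i]
      g_bar <- model$priors$gamma_bar[i]
      a <- model$priors$lambda_bar[i]
      b <- model$priors$theta_bar[i]
      Zi <- model$Z[, annot$batch == model$priors$batch[i]]
      g_star <- model$gamma_star[i, ]
      d_star <- model$delta2_star[i, ]
      g_sub <- (n * t2 * model$gamma_hat[i, ] + d_star * g_bar) /
        (n * t2 + d_star)
      d_sub <- (b + 0.5 * rowSums((Zi - g_star)^2)) / (n / 2 + a - 1)
      expect_equal(g_sub, g_star, tolerance = 1e-6)
      expect_equal(d_sub, d_star, tolerance = 1e-6)
    }
  }
})

test_that("gamma* is a convex combination of gamma_hat and the prior mean", {
  d <- shifted_batch_data(n_genes = 60, n_per_batch = 20, shift = 1, seed = 5)
  model <- combat_eb(combat_standardize(d$expression, d$annotation))
  for (i in 1:2) {
    lo <- pmin(model$gamma_hat[i, ], model$priors$gamma_bar[i])
    hi <- pmax(model$gamma_hat[i, ], model$priors$gamma_bar[i])
    expect_true(all(model$gamma_star[i, ] >= lo - 1e-9))
    expect_true(all(model$gamma_star[i, ] <= hi + 1e-9))
  }
  expect_true(all(model$delta2_star > 0))
})

test_that("statistically identical batches shrink to no-op corrections", {
  set.seed(11)
  n_i <- 500
  x <- matrix(rnorm(2000 * 2 * n_i, 7, 1), 2000,
              dimnames = list(sprintf("g%04d", 1:2000),
                              sprintf("s%04d", 1:(2 * n_i))))
  annot <- data.frame(sample_id = colnames(x),
                      batch = rep(c("b1", "b2"), each = n_i),
                      condition = rep(c("AD", "ND"), n_i))
  model <- combat_eb(combat_standardize(x, annot))
  # generating values: gamma = 0, delta2 = 1. The raw per-gene estimates
  # carry sampling error sd ~ 1/sqrt(n_i) (location) and ~ sqrt(2/n_i)
  # (scale); shrinkage halves it, so the bulk sits within 0.05 while the
  # extreme of 2000 genes can reach ~4 sigma of the shrunken error.
  expect_lt(max(abs(model$gamma_star)), 0.1)
  expect_lt(stats::quantile(abs(model$gamma_star), 0.95), 0.05)
  expect_lt(mean(abs(model$gamma_star)), 0.02)
  expect_lt(max(abs(model$delta2_star - 1)), 0.15)
  expect_lt(stats::quantile(abs(model$delta2_star - 1), 0.95), 0.05)
  expect_lt(mean(abs(model$delta2_star - 1)), 0.03)
})

test_that("identical location estimates trigger the degenerate-prior fallback", {
  d <- shifted_batch_data(n_genes = 10, n_per_batch = 8, shift = 0,
                          noise_sd = 0.5, seed = 9)
  model <- combat_standardize(d$expression, d$annotation)
  # collapse every gene onto the same profile: gamma_hat identical across
  # genes, so the across-gene prior variance is exactly zero in each batch
  fake <- model
  fake$Z[] <- rep(fake$Z[1, ], each = nrow(fake$Z))
  w <- capture_warnings(m2 <- combat_eb(fake))
  expect_true(any(grepl("degenerate prior", w)))
  i <- which(!m2$priors$shrunk)[1]
  expect_equal(m2$gamma_star[i, ], m2$gamma_hat[i, ])
})

test_that("with shrinkage disabled, adjust equals the per-batch oracle", {
  d <- shifted_batch_data(n_genes = 40, n_per_batch = 30, shift = 2, seed = 21)
  model <- combat_eb(combat_standardize(d$expression, d$annotation), eb = FALSE)
  corrected <- combat_adjust(d$expression, model)
  oracle <- oracle_batch_standardize(
    d$expression, model$batch, model$stand_mean, model$sigma2)
  expect_lt(max(abs(corrected - oracle)), 1e-8)
})

test_that("single-batch passthrough returns the input unchanged", {
  set.seed(31)
  x <- matrix(rnorm(60, 7), 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  annot <- data.frame(sample_id = colnames(x), batch = "b1",
                      condition = rep(c("AD", "ND"), 5))
  res <- suppressMessages(combat_correct(x, annot))
  expect_equal(res$corrected, x, tolerance = 1e-9)
})

test_that("an additive batch shift is removed to tight tolerance", {
  # near-noiseless shift: batch 2 equals batch 1 plus 2 in every gene
  d <- shifted_batch_data(n_genes = 50, n_per_batch = 200, shift = 2,
                          noise_sd = 0.05, seed = 23)
  res <- combat_correct(d$expression, d$annotation)
  b1 <- d$annotation$batch == "b1"
  mean_gap <- rowMeans(res$corrected[, b1]) - rowMeans(res$corrected[, !b1])
  expect_lt(max(abs(mean_gap)), 0.01)
})

test_that("re-standardizing corrected data shrinks gamma at least 10-fold", {
  d <- shifted_batch_data(n_genes = 50, n_per_batch = 100, shift = 2, seed = 25)
  m1 <- combat_eb(combat_standardize(d$expression, d$annotation))
  corrected <- combat_adjust(d$expression, m1)
  m2 <- combat_eb(combat_standardize(corrected, d$annotation))
  expect_lt(max(abs(m2$gamma_hat)), max(abs(m1$gamma_hat)) / 10)
})

test_that("corrected values closely match the reference EB implementation", {
  skip_if_not_installed("sva")
  d <- shifted_batch_data(n_genes = 80, n_per_batch = 50, shift = 1.5,
                          seed = 27)
  res <- combat_correct(d$expression, d$annotation)
  ref <- suppressMessages(sva::ComBat(
    d$expression, batch = d$annotation$batch,
    mod = stats::model.matrix(~condition, data = d$annotation)))
  expect_lt(max(abs(res$corrected - ref)), 1e-3)
})

test_that("batch separation statistic behaves at its extremes", {
  # identically distributed batches: near the null level
  set.seed(41)
  x <- matrix(rnorm(40 * 100, 7), 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:100)))
  annot <- data.frame(sample_id = colnames(x),
                      batch = rep(c("b1", "b2"), 50),
                      condition = "AD")
  expect_lte(batch_check(x, annot)$separation, 0.1)

  # orthogonal constant shift with 2 samples per batch: PC1 is the batch axis
  y <- matrix(rnorm(40 * 4, 0, 0.01), 40,
              dimnames = list(paste0("g", 1:40), paste0("t", 1:4)))
  y[, 3:4] <- y[, 3:4] + 5
  ann2 <- data.frame(sample_id = colnames(y),
                     batch = rep(c("b1", "b2"), each = 2), condition = "AD")
  expect_gt(batch_check(y, ann2)$separation, 0.95)
  expect_error(batch_check(y[, 1:2], ann2[1:2, ]), "3 samples")
})

test_that("correction moves the separation statistic from high to low", {
  d <- shifted_batch_data(n_genes = 100, n_per_batch = 200, shift = 2,
                          seed = 43)
  before <- batch_check(d$expression, d$annotation)$separation
  res <- combat_correct(d$expression, d$annotation)
  after <- batch_check(res$corrected, d$annotation)$separation
  expect_gt(before, 0.5)
  expect_lt(after, 0.1)
  shares <- batch_check(d$expression, d$annotation)$variance_share
  expect_true(all(diff(shares) <= 1e-12))
  expect_true(all(shares >= 0 & shares <= 1))
})
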