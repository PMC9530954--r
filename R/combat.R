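#' Standardize expression data for location/scale batch modeling (Step 1)
#'
#' Fits, per gene, the model `Y_ijg = alpha_g + X beta_g + gamma_ig +
#' delta_ig eps_ijg` by least squares over batch indicators plus protected
#' covariates, with the grand mean `alpha_g` defined as the batch-size-weighted
#' combination of batch means (the standard parametric empirical-Bayes
#' scheme). Returns the standardized residuals
#' `Z_ijg = (Y_ijg - alpha_g - X beta_g) / sigma_g`, which have pooled mean 0
#' and pooled variance 1 per gene.
#'
#' Genes with zero pooled variance cannot be standardized; they are excluded
#' from the model (and later passed through unchanged) with a warning.
#'
#' @param expression genes x samples log2 matrix.
#' @param annotation data.frame with `sample_id`, and the batch/covariate
#'   columns named below.
#' @param batch_col name of the batch column.
#' @param covariates character vector of annotation columns whose signal must
#'   be protected from removal (default `"condition"`); use `character(0)` for
#'   covariate-free standardization.
#' @return A partial model object of class `combat_model` housing the grand
#'   parameters (`alpha`, `beta`, `sigma2`), the standardized matrix `Z`, the
#'   reconstruction mean `stand_mean`, batch structure, and the exclusion list.
#' @export
combat_standardize <- function(expression, annotation,
                               batch_col = "batch",
                               covariates = "condition") {
  ids <- colnames(expression)
  if (is.null(ids) || !identical(sort(ids), sort(annotation$sample_id))) {
    stop("expression columns and annotation sample_id must match")
  }
  annotation <- annotation[match(ids, annotation$sample_id), , drop = FALSE]
  batch <- factor(annotation[[batch_col]])
  n_batches <- nlevels(batch)
  n_array <- ncol(expression)
  n_i <- as.vector(table(batch))
  if (any(n_i < 2)) stop("every batch needs at least 2 samples")

  batch_design <- vapply(levels(batch), function(l) as.numeric(batch == l),
                         numeric(length(batch)))
  covar_design <- NULL
  if (length(covariates)) {
    covar_df <- annotation[, covariates, drop = FALSE]
    for (cv in covariates) {
      if (!is.numeric(covar_df[[cv]])) covar_df[[cv]] <- factor(covar_df[[cv]])
    }
    covar_design <- stats::model.matrix(
      stats::as.formula(paste("~", paste(covariates, collapse = "+"))),
      data = covar_df)[, -1, drop = FALSE]  # drop intercept; batch terms span it
  }
  design <- cbind(batch_design, covar_design)
  if (qr(design)$rank < ncol(design)) {
    stop("design is confounded: covariates are collinear with batch")
  }

  # least squares for all genes at once
  B_hat <- solve(crossprod(design), crossprod(design, t(expression)))
  grand_mean <- crossprod(n_i / n_array, B_hat[seq_len(n_batches), , drop = FALSE])
  fitted <- t(design %*% B_hat)
  sigma2 <- rowMeans((expression - fitted)^2)  # pooled variance, divisor N

  excluded <- rownames(expression)[sigma2 < 1e-12 | !is.finite(sigma2)]
  if (length(excluded)) {
    warning(length(excluded), " gene(s) with zero pooled variance excluded: ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ..." else "")
  }
  keep <- setdiff(rownames(expression), excluded)

  stand_mean <- matrix(grand_mean, nrow = nrow(expression), ncol = n_array,
                       dimnames = dimnames(expression))
  if (!is.null(covar_design) && ncol(covar_design)) {
    beta <- B_hat[-seq_len(n_batches), , drop = FALSE]
    stand_mean <- stand_mean + t(covar_design %*% beta)
  } else {
    beta <- NULL
  }

  Z <- (expression[keep, , drop = FALSE] - stand_mean[keep, , drop = FALSE]) /
    sqrt(sigma2[keep])

  model <- list(
    batch = batch, batch_col = batch_col, covariates = covariates,
    n_i = stats::setNames(n_i, levels(batch)),
    alpha = stats::setNames(as.vector(grand_mean), rownames(expression)),
    beta = beta, sigma2 = sigma2, stand_mean = stand_mean,
    Z = Z, keep = keep, excluded = excluded,
    sample_ids = ids, eb = NULL)
  class(model) <- "combat_model"
  model
}

# inverse-gamma moment matching: mean m = b/(a-1), var s2 = b^2/((a-1)^2(a-2))
aprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (2 * s2 + m^2) / s2
}
bprior <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (m * s2 + m^3) / s2
}

#' Empirical-Bayes batch-effect estimates (Step 2)
#'
#' Per batch i and gene g, the raw location estimate `gamma_hat_ig` (batch mean
#' of Z) and scale estimate `delta2_hat_ig` (batch variance of Z) are shrunk
#' toward batch-level priors `gamma_ig ~ N(gamma_bar_i, tau2_bar_i)` and
#' `delta2_ig ~ InvGamma(lambda_bar_i, theta_bar_i)`, whose hyperparameters are
#' moment-matched across genes within the batch. The posterior estimates solve
#' the coupled fixed-point equations
#' \deqn{\gamma^*_{ig} = \frac{n_i \bar\tau^2_i \hat\gamma_{ig} +
#'   \delta^{2*}_{ig} \bar\gamma_i}{n_i \bar\tau^2_i + \delta^{2*}_{ig}}}
#' \deqn{\delta^{2*}_{ig} = \frac{\bar\theta_i + \frac12 \sum_j (Z_{ijg} -
#'   \gamma^*_{ig})^2}{n_i/2 + \bar\lambda_i - 1}}
#' iterated to convergence.
#'
#' When the raw estimates are degenerate (zero variance across genes), the
#' prior is non-informative and the batch falls back to no shrinkage with a
#' warning.
#'
#' @param model a partial `combat_model` from [combat_standardize()].
#' @param eb logical; `FALSE` disables shrinkage (`gamma* = gamma_hat`,
#'   `delta2* = delta2_hat`), the location/scale oracle mode.
#' @param tol relative convergence tolerance of the fixed-point iteration.
#' @param max_iter iteration cap (warns if reached).
#' @return The completed `combat_model` with per-batch `gamma_hat`,
#'   `delta2_hat`, `gamma_star`, `delta2_star` (batches x genes matrices) and
#'   hyperprior table `priors`.
#' @export
combat_eb <- function(model, eb = TRUE, tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(model, "combat_model"))
  Z <- model$Z
  batch <- model$batch
  lv <- levels(batch)
  ng <- nrow(Z)
  gamma_hat <- matrix(NA_real_, length(lv), ng, dimnames = list(lv, rownames(Z)))
  delta2_hat <- gamma_hat
  for (i in seq_along(lv)) {
    cols <- which(batch == lv[i])
    Zi <- Z[, cols, drop = FALSE]
    gamma_hat[i, ] <- rowMeans(Zi)
    delta2_hat[i, ] <- apply(Zi, 1, stats::var)
  }

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  priors <- data.frame(batch = lv, gamma_bar = NA_real_, tau2_bar = NA_real_,
                       lambda_bar = NA_real_, theta_bar = NA_real_,
                       shrunk = FALSE, iterations = NA_integer_,
                       stringsAsFactors = FALSE)

  if (eb) {
    for (i in seq_along(lv)) {
      g_hat <- gamma_hat[i, ]
      d_hat <- delta2_hat[i, ]
      g_bar <- mean(g_hat)
      t2 <- stats::var(g_hat)
      a <- aprior(d_hat)
      b <- bprior(d_hat)
      priors$gamma_bar[i] <- g_bar
      priors$tau2_bar[i] <- t2
      priors$lambda_bar[i] <- a
      priors$theta_bar[i] <- b
      if (!is.finite(t2) || t2 <= 0 || !is.finite(a) || !is.finite(b)) {
        warning("degenerate prior in batch '", lv[i],
                "': falling back to no shrinkage")
        next
      }
      n <- model$n_i[[lv[i]]]
      cols <- which(batch == lv[i])
      Zi <- Z[, cols, drop = FALSE]
      g_old <- g_hat
      d_old <- d_hat
      iter <- 0L
      repeat {
        iter <- iter + 1L
        g_new <- (n * t2 * g_hat + d_old * g_bar) / (n * t2 + d_old)
        sum2 <- rowSums((Zi - g_new)^2)
        d_new <- (b + 0.5 * sum2) / (n / 2 + a - 1)
        change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                      abs(d_new - d_old) / (abs(d_old) + 1e-12))
        g_old <- g_new
        d_old <- d_new
        if (change < tol || iter >= max_iter) break
      }
      if (iter >= max_iter && change >= tol) {
        warning("EB fixed-point iteration hit the cap of ", max_iter,
                " in batch '", lv[i], "'")
      }
      gamma_star[i, ] <- g_old
      delta2_star[i, ] <- d_old
      priors$shrunk[i] <- TRUE
      priors$iterations[i] <- iter
    }
  }

  model$gamma_hat <- gamma_hat
  model$delta2_hat <- delta2_hat
  model$gamma_star <- gamma_star
  model$delta2_star <- delta2_star
  model$priors <- priors
  model$eb <- eb
  model
}

#' Adjust the data for batch effects (Step 3)
#'
#' Applies `Y*_ijg = sigma_g / delta*_ig (Z_ijg - gamma*_ig) + alpha_g +
#' X beta_g`: removes the shrunk per-batch location and scale from the
#' standardized data and restores the grand parameters, including the
#' protected covariate (condition) signal. Excluded constant genes are passed
#' through unchanged.
#'
#' @param expression the matrix the model was fitted on (id-checked).
#' @param model a completed `combat_model` from [combat_eb()].
#' @return Corrected genes x samples matrix with identical dimnames.
#' @export
combat_adjust <- function(expression, model) {
  stopifnot(inherits(model, "combat_model"))
  if (is.null(model$eb)) stop("model is incomplete: run combat_eb() first")
  if (!identical(colnames(expression), model$sample_ids)) {
    stop("expression sample ids do not match the fitted model")
  }
  if (!all(model$keep %in% rownames(expression))) {
    stop("expression gene ids do not match the fitted model")
  }
  out <- expression
  keep <- model$keep
  batch <- model$batch
  Z <- model$Z
  adj <- Z
  for (i in seq_along(levels(batch))) {
    lvl <- levels(batch)[i]
    cols <- which(batch == lvl)
    adj[, cols] <- (Z[, cols, drop = FALSE] - model$gamma_star[i, ]) /
      sqrt(model$delta2_star[i, ])
  }
  out[keep, ] <- adj * sqrt(model$sigma2[keep]) +
    model$stand_mean[keep, , drop = FALSE]
  if (length(model$excluded)) attr(out, "excluded_genes") <- model$excluded
  out
}

#' One-call empirical-Bayes batch correction
#'
#' Convenience wrapper: [combat_standardize()] then [combat_eb()] then
#' [combat_adjust()]. With a single batch the input is returned unchanged
#' (there is no batch effect to remove).
#'
#' @inheritParams combat_standardize
#' @inheritParams combat_eb
#' @return list with `corrected` (matrix) and `model` (`combat_model`, `NULL`
#'   in the single-batch passthrough case).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_genes = 100, seed = 3))
#' res <- combat_correct(cohort$expression, cohort$annotation)
#' dim(res$corrected)
#' @export
combat_correct <- function(expression, annotation, batch_col = "batch",
                           covariates = "condition", eb = TRUE,
                           tol = 1e-4, max_iter = 100L) {
  if (length(unique(annotation[[batch_col]])) < 2) {
    message("single batch: passthrough, no correction applied")
    return(list(corrected = expression, model = NULL))
  }
  model <- combat_standardize(expression, annotation, batch_col, covariates)
  model <- combat_eb(model, eb = eb, tol = tol, max_iter = max_iter)
  list(corrected = combat_adjust(expression, model), model = model)
}

#' @export
print.combat_model <- function(x, ...) {
  cat("Empirical-Bayes location/scale batch model\n")
  cat(sprintf("  genes: %d fitted (%d excluded)  samples: %d  batches: %d\n",
              length(x$keep), length(x$excluded), length(x$sample_ids),
              nlevels(x$batch)))
  if (!is.null(x$eb)) {
    cat(sprintf("  shrinkage: %s\n", if (isTRUE(x$eb)) "empirical Bayes" else "none"))
    if (isTRUE(x$eb)) {
      cat("  batch hyperpriors:\n")
      print(x$priors, row.names = FALSE, digits = 4)
    }
  } else {
    cat("  (partial model: standardization only)\n")
  }
  invisible(x)
}

#' PCA check that batch structure has been removed
#'
#' Computes principal components of the sample profiles (genes centered) and a
#' batch-separation statistic: the share of variance in the first two
#' component scores explained by batch membership (variance-weighted R^2 of a
#' one-way batch ANOVA on PC1 and PC2). Near 0 means batches are mixed; near 1
#' means the leading structure is batch.
#'
#' @param expression genes x samples matrix.
#' @param annotation data.frame with `sample_id` and the batch column.
#' @param batch_col name of the batch column.
#' @param n_components number of PCs for which to report variance shares.
#' @return Object of class `batch_check`: `variance_share` per PC,
#'   `separation` statistic in [0, 1], and the PC1/PC2 `scores` with batch
#'   labels for plotting.
#' @export
batch_check <- function(expression, annotation, batch_col = "batch",
                        n_components = 10L) {
  if (ncol(expression) < 3) stop("need at least 3 samples")
  annotation <- annotation[match(colnames(expression), annotation$sample_id), ,
                           drop = FALSE]
  batch <- factor(annotation[[batch_col]])
  if (nlevels(batch) < 2) stop("need at least 2 batches")
  pc <- stats::prcomp(t(expression), center = TRUE, scale. = FALSE)
  vshare <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ssb <- 0; sst <- 0
  for (j in seq_len(k)) {
    s <- scores[, j]
    grand <- mean(s)
    means <- tapply(s, batch, mean)
    n_b <- tapply(s, batch, length)
    ssb <- ssb + sum(n_b * (means - grand)^2)
    sst <- sst + sum((s - grand)^2)
  }
  out <- list(variance_share = utils::head(vshare, n_components),
              separation = if (sst > 0) ssb / sst else 0,
              scores = data.frame(sample_id = colnames(expression),
                                  PC1 = scores[, 1],
                                  PC2 = if (k > 1) scores[, 2] else 0,
                                  batch = batch,
                                  stringsAsFactors = FALSE))
  class(out) <- "batch_check"
  out
}

#' @export
print.batch_check <- function(x, ...) {
  cat("Batch-structure check (PCA)\n")
  cat(sprintf("  separation statistic (batch R^2 on PC1-PC2): %.3f\n", x$separation))
  cat(sprintf("  variance shares: %s\n",
              paste(sprintf("%.3f", utils::head(x$variance_share, 5)), collapse = " ")))
  invisible(x)
}

#' @export
plot.batch_check <- function(x, ...) {
  cols <- as.integer(factor(x$scores$batch))
  graphics::plot(x$scores$PC1, x$scores$PC2, col = cols, pch = 19,
                 xlab = "PC1", ylab = "PC2",
                 main = sprintf("Batch separation R^2 = %.3f", x$separation), ...)
  graphics::legend("topright", legend = levels(factor(x$scores$batch)),
                   col = seq_along(unique(cols)), pch = 19, cex = 0.8)
  invisible(x)
}
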