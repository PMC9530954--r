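#' Enumerate all non-empty subsets of a hub-gene panel
#'
#' Deterministic order: by subset size, then lexicographically in the supplied
#' gene order. A panel of k genes yields `2^k - 1` subsets; k is capped at 20
#' to guard against combinatorial blow-up.
#'
#' @param genes character vector of panel gene ids (1 <= length <= 20).
#' @return list of character vectors, each a non-empty subset.
#' @examples
#' length(enumerate_panels(letters[1:10]))  # 1023
#' @export
enumerate_panels <- function(genes) {
  k <- length(genes)
  if (k < 1) stop("panel must contain at least one gene")
  if (k > 20) stop("panel size > 20: exhaustive search refused; consider a greedy search")
  subsets <- unlist(lapply(seq_len(k), function(size) {
    utils::combn(genes, size, simplify = FALSE)
  }), recursive = FALSE)
  subsets
}

# logistic regression with a small L2 penalty on the non-intercept
# coefficients, by IRLS; used as the documented fallback when the
# maximum-likelihood fit separates perfectly
ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 100L, tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    beta_new <- solve(XtW %*% X1 + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' Fit a logistic combination score for a gene panel
#'
#' Maximum-likelihood logistic regression of disease status on the subset's
#' expression values. On perfect separation (or non-convergence) the fit falls
#' back to a ridge-stabilized version (small L2 penalty) with a notice. The
#' fit is fully deterministic.
#'
#' @param expression genes x samples training matrix.
#' @param labels per-sample labels aligned with columns; `positive` is coded 1.
#' @param subset character vector of panel gene ids (rows of `expression`).
#' @param positive label of the positive class (default `"AD"`).
#' @param ridge_lambda penalty used by the fallback.
#' @return list of class `panel_fit`: `coefficients` (named, incl.
#'   `(Intercept)`), `subset`, `ridge` flag.
#' @export
fit_panel_score <- function(expression, labels, subset, positive = "AD",
                            ridge_lambda = 1e-2) {
  if (length(unique(labels)) < 2) stop("training labels contain a single class")
  missing_g <- setdiff(subset, rownames(expression))
  if (length(missing_g)) stop("subset genes absent from matrix: ",
                              paste(missing_g, collapse = ", "))
  X <- t(expression[subset, , drop = FALSE])
  y <- as.integer(labels == positive)
  df <- data.frame(y = y, X, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # complete separation can also end with a near-zero deviance and no warning
  if (!separated && fit$converged && fit$deviance < 1e-6) separated <- TRUE
  if (separated || !fit$converged) {
    message("separation detected for panel {", paste(subset, collapse = ","),
            "}: ridge-stabilized fit used")
    beta <- ridge_logistic(X, y, lambda = ridge_lambda)
    coefs <- stats::setNames(beta, c("(Intercept)", subset))
  } else {
    coefs <- stats::coef(fit)
    names(coefs) <- c("(Intercept)", subset)
  }
  out <- list(coefficients = coefs, subset = subset, ridge = separated,
              positive = positive)
  class(out) <- "panel_fit"
  out
}

#' Combination score of a fitted panel on new samples
#' @param fit a `panel_fit`.
#' @param expression genes x samples matrix containing the panel genes.
#' @return named numeric vector of linear predictor scores.
#' @export
panel_score <- function(fit, expression) {
  X <- t(expression[fit$subset, , drop = FALSE])
  drop(cbind(1, X) %*% fit$coefficients)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive sample scores above a random negative
#' one, with ties counted one half; identical to the trapezoidal area under
#' the empirical ROC curve.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels per-element class labels.
#' @param positive label of the positive class (default `"AD"`).
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), positive = 1)  # 0.75
#' @export
roc_auc <- function(scores, labels, positive = "AD") {
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)   # midranks handle ties at 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' AUC interpretation band
#'
#' AUC above 0.9: `"outstanding"` specificity and sensitivity; in
#' [0.7, 0.9]: `"acceptable"`; below 0.7: `"none"`.
#'
#' @param auc numeric in [0, 1].
#' @return character label.
#' @export
band <- function(auc) {
  if (any(auc < 0 | auc > 1)) stop("AUC must lie in [0, 1]")
  ifelse(auc > 0.9, "outstanding", ifelse(auc >= 0.7, "acceptable", "none"))
}

#' Exhaustive diagnostic-panel search
#'
#' For each subgroup's hub panel, every non-empty gene subset is fitted as a
#' logistic AD/ND classifier on the training samples and scored by AUC on the
#' validation samples. The best panel per subgroup maximizes validation AUC;
#' ties are broken by smaller subset, then lexicographically. Per-subset fit
#' failures are recorded and skipped, never aborting the search.
#'
#' @param train,validation lists with `expression` and `annotation` (as
#'   returned by [holdout_split()]); annotations need `sample_id` and
#'   `condition`. Either may instead be a named list of such pairs, keyed
#'   like `hub_panels`, when each subgroup is to be fitted or evaluated on
#'   its own sample set (e.g. validation positives restricted to that
#'   subgroup's cases).
#' @param hub_panels named list (one per subgroup) of hub gene-id vectors.
#' @param positive positive class label (default `"AD"`).
#' @param ridge_lambda fallback penalty, see [fit_panel_score()].
#' @return Object of class `panel_search`: `rankings` (named list of
#'   data.frames `subset`, `size`, `auc`, `band`, `ridge`, sorted by AUC
#'   descending), `best` (one row per subgroup), `total_evaluations`,
#'   `skipped`.
#' @export
search_best_panels <- function(train, validation, hub_panels,
                               positive = "AD", ridge_lambda = 1e-2) {
  if (!length(hub_panels)) stop("no hub panels supplied")
  pick <- function(obj, sg) {
    if (!is.null(obj$expression)) obj else {
      if (is.null(obj[[sg]])) stop("no train/validation pair for subgroup ", sg)
      obj[[sg]]
    }
  }
  for (sg in names(hub_panels)) {
    v <- pick(validation, sg)
    if (length(unique(v$annotation$condition)) < 2) {
      stop("validation set for ", sg, " must contain both classes")
    }
  }
  rankings <- list()
  best_rows <- list()
  skipped <- list()
  total <- 0L
  for (sg in names(hub_panels)) {
    tr <- pick(train, sg)
    va <- pick(validation, sg)
    subsets <- enumerate_panels(hub_panels[[sg]])
    total <- total + length(subsets)
    rows <- vector("list", length(subsets))
    for (i in seq_along(subsets)) {
      sub <- subsets[[i]]
      res <- tryCatch({
        fit <- suppressMessages(
          fit_panel_score(tr$expression, tr$annotation$condition, sub,
                          positive = positive, ridge_lambda = ridge_lambda))
        sc <- panel_score(fit, va$expression)
        auc <- roc_auc(sc, va$annotation$condition, positive = positive)
        data.frame(subset = paste(sub, collapse = ","),
                   size = length(sub), auc = auc, band = band(auc),
                   ridge = fit$ridge, stringsAsFactors = FALSE)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          subgroup = sg, subset = paste(sub, collapse = ","),
          reason = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        rows[[i]] <- res
      }
    }
    tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(tab) || !nrow(tab)) {
      stop("all panel fits failed for subgroup ", sg)
    }
    # sort: AUC desc, then smaller subsets, then lexicographic
    tab <- tab[order(-tab$auc, tab$size, tab$subset), , drop = FALSE]
    rownames(tab) <- NULL
    rankings[[sg]] <- tab
    best_rows[[sg]] <- cbind(data.frame(subgroup = sg, stringsAsFactors = FALSE),
                             tab[1, , drop = FALSE])
  }
  out <- list(rankings = rankings,
              best = do.call(rbind, best_rows),
              total_evaluations = total,
              skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
  class(out) <- "panel_search"
  out
}

#' @export
print.panel_search <- function(x, ...) {
  cat(sprintf("Exhaustive panel search: %d evaluations over %d subgroup panel(s)\n",
              x$total_evaluations, length(x$rankings)))
  cat("Best panel per subgroup:\n")
  print(x$best, row.names = FALSE, digits = 4)
  if (!is.null(x$skipped)) {
    cat(sprintf("%d subset(s) skipped due to fit errors\n", nrow(x$skipped)))
  }
  invisible(x)
}
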