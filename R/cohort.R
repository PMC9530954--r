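#' Default clinical trait model for the synthetic cohort
#'
#' Describes how each clinical trait is generated conditional on disease status
#' and planted subtype. Continuous traits are truncated Gaussians; `sex` is
#' Bernoulli (probability of female). Offsets are added to the control baseline
#' for AD samples of subtypes 1..3 and are chosen so that subtypes 1 and 3
#' carry high dementia severity (CDR) and tangle burden (NFT) relative to
#' subtype 2, plaque density (NPD, CERAD) is elevated in all AD samples, and
#' tissue pH is lowered in AD — the qualitative clinical signature the pipeline
#' is expected to recover.
#'
#' @return Named list of per-trait models with fields `type`
#'   (`"gaussian"`/`"bernoulli"`), `baseline`, `offsets` (length 3), `sd`,
#'   `lower`, `upper`.
#' @export
default_trait_model <- function() {
  g <- function(baseline, offsets, sd, lower = -Inf, upper = Inf) {
    list(type = "gaussian", baseline = baseline, offsets = offsets, sd = sd,
         lower = lower, upper = upper)
  }
  list(
    CDR   = g(0.5, c(2.0, 1.0, 2.0), 0.5, lower = 0, upper = 3),
    Braak = g(2.0, c(2.5, 1.5, 2.5), 1.0, lower = 0, upper = 6),
    NFT   = g(5.0, c(15, 5, 15), 5.0, lower = 0),
    CERAD = g(1.0, c(1.5, 1.5, 1.5), 0.8, lower = 0, upper = 4),
    NPD   = g(5.0, c(8, 8, 8), 3.0, lower = 0),
    pH    = g(6.6, c(-0.25, -0.25, -0.25), 0.25, lower = 5.5, upper = 7.4),
    age   = g(80, c(0, 0, -3), 8, lower = 60, upper = 105),
    sex   = list(type = "bernoulli", baseline = 0.55, offsets = c(0.1, 0.1, 0))
  )
}

#' Configuration for the synthetic multi-batch cohort generator
#'
#' The generator emulates a merged multi-study case/control brain expression
#' cohort: several batches with additive and multiplicative per-gene batch
#' effects, roughly 40 percent control (ND) samples, three planted AD subtypes
#' each defined by a disjoint block of upregulated marker genes, and clinical
#' traits statistically coupled to subtype.
#'
#' @param n_genes total number of genes.
#' @param n_marker_genes_per_subtype planted upregulated markers per subtype;
#'   `3 * n_marker_genes_per_subtype` must not exceed `n_genes`.
#' @param batches data.frame with columns `batch_id`, `n_AD`, `n_ND`.
#' @param subtype_proportions three fractions summing to 1.
#' @param marker_effect log2 mean shift applied to a subtype's markers in its
#'   AD samples.
#' @param batch_location_sd standard deviation of the per-(batch, gene)
#'   additive offsets (log2 units).
#' @param batch_scale_range length-2 interval for the per-(batch, gene)
#'   multiplicative factors on residual noise.
#' @param noise_sd residual log2 noise standard deviation.
#' @param baseline_mean,baseline_sd law of the per-gene baseline expression
#'   (log2 microarray-like intensities).
#' @param trait_model per-trait generative model, see [default_trait_model()].
#' @param trait_missing_rate fraction of trait values set missing uniformly at
#'   random (emulates incomplete clinical records).
#' @param seed integer seed governing all randomness of the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 2000,
                          n_marker_genes_per_subtype = 100,
                          batches = data.frame(
                            batch_id = c("b1", "b2", "b3"),
                            n_AD = c(40, 80, 80),
                            n_ND = c(30, 50, 50),
                            stringsAsFactors = FALSE),
                          subtype_proportions = c(1, 1, 1) / 3,
                          marker_effect = 1.0,
                          batch_location_sd = 0.5,
                          batch_scale_range = c(0.8, 1.25),
                          noise_sd = 1.0,
                          baseline_mean = 7,
                          baseline_sd = 1.5,
                          trait_model = default_trait_model(),
                          trait_missing_rate = 0,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_marker_genes_per_subtype = as.integer(n_marker_genes_per_subtype),
              batches = batches,
              subtype_proportions = subtype_proportions,
              marker_effect = marker_effect,
              batch_location_sd = batch_location_sd,
              batch_scale_range = batch_scale_range,
              noise_sd = noise_sd,
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              trait_model = trait_model,
              trait_missing_rate = trait_missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-9) {
    stop("subtype_proportions must sum to 1")
  }
  if (length(cfg$subtype_proportions) != 3L) {
    stop("exactly 3 subtype proportions are required")
  }
  if (any(cfg$subtype_proportions < 0)) stop("subtype_proportions must be >= 0")
  if (3L * cfg$n_marker_genes_per_subtype > cfg$n_genes) {
    stop("3 * n_marker_genes_per_subtype must not exceed n_genes")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$batch_location_sd < 0) stop("batch_location_sd must be >= 0")
  if (length(cfg$batch_scale_range) != 2L ||
      any(cfg$batch_scale_range <= 0) ||
      diff(cfg$batch_scale_range) < 0) {
    stop("batch_scale_range must be a positive, non-decreasing interval")
  }
  if (cfg$trait_missing_rate < 0 || cfg$trait_missing_rate >= 1) {
    stop("trait_missing_rate must be in [0, 1)")
  }
  b <- cfg$batches
  if (!all(c("batch_id", "n_AD", "n_ND") %in% names(b))) {
    stop("batches needs columns batch_id, n_AD, n_ND")
  }
  if (anyDuplicated(b$batch_id)) stop("duplicate batch_id")
  if (any(b$n_AD + b$n_ND < 2)) stop("each batch needs at least 2 samples")
  invisible(cfg)
}

# truncated normal by rejection; bounds far from the mean relative to sd keep
# the acceptance rate near 1 for the default trait models
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
  }
  if (length(bad)) out[bad] <- pmin(pmax(out[bad], lower), upper)
  out
}

#' Generate a synthetic multi-batch AD/ND expression cohort
#'
#' Expression for gene g in sample j follows
#' `y = mu_g + marker shift + a_bg + s_bg * eps`, where `mu_g` is the gene
#' baseline, the marker shift equals `marker_effect` for the planted markers of
#' the sample's subtype (AD samples only), `a_bg ~ N(0, batch_location_sd^2)`
#' is the additive batch offset, `s_bg ~ U(batch_scale_range)` multiplies the
#' Gaussian residual `eps ~ N(0, noise_sd^2)` — the location/scale batch model
#' that empirical-Bayes batch correction assumes. Clinical traits are drawn per
#' [default_trait_model()] conditional on condition and subtype.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{expression}{genes x samples log2 matrix with gene/sample ids.}
#'     \item{annotation}{per-sample data.frame: `sample_id`, `batch`,
#'       `condition` (AD/ND), clinical traits.}
#'     \item{truth}{ground truth: `marker_map` (subtype -> gene ids),
#'       `true_subtype` (named, AD samples only), `batch_location` and
#'       `batch_scale` (batch x gene matrices).}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_config(n_genes = 200, seed = 7))
#' dim(cohort$expression)
#' table(cohort$annotation$condition)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  b <- cfg$batches
  n_samples <- sum(b$n_AD) + sum(b$n_ND)
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))

  # stage sub-streams: 0 structure, 1 expression noise, 2 traits
  s0 <- derive_seed(cfg$seed, 0)
  s1 <- derive_seed(cfg$seed, 1)
  s2 <- derive_seed(cfg$seed, 2)

  annot <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    data.frame(batch = rep(b$batch_id[i], b$n_AD[i] + b$n_ND[i]),
               condition = rep(c("AD", "ND"), c(b$n_AD[i], b$n_ND[i])),
               stringsAsFactors = FALSE)
  }))
  annot$sample_id <- sprintf("s%04d", seq_len(n_samples))
  annot <- annot[, c("sample_id", "batch", "condition")]

  m <- cfg$n_marker_genes_per_subtype
  truth <- with_seed(s0, {
    marker_genes <- sample(gene_ids, 3L * m)
    marker_map <- split(marker_genes, rep(1:3, each = m))
    names(marker_map) <- paste0("subtype", 1:3)
    is_ad <- annot$condition == "AD"
    subtype <- rep(NA_integer_, n_samples)
    subtype[is_ad] <- sample(1:3, sum(is_ad), replace = TRUE,
                             prob = cfg$subtype_proportions)
    mu <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    loc <- matrix(stats::rnorm(nrow(b) * cfg$n_genes, 0, cfg$batch_location_sd),
                  nrow = nrow(b),
                  dimnames = list(b$batch_id, gene_ids))
    scl <- matrix(stats::runif(nrow(b) * cfg$n_genes,
                               cfg$batch_scale_range[1],
                               cfg$batch_scale_range[2]),
                  nrow = nrow(b),
                  dimnames = list(b$batch_id, gene_ids))
    list(marker_map = marker_map, subtype = subtype, mu = mu,
         batch_location = loc, batch_scale = scl)
  })

  expr <- with_seed(s1, {
    eps <- matrix(stats::rnorm(cfg$n_genes * n_samples, 0, cfg$noise_sd),
                  nrow = cfg$n_genes)
    x <- matrix(truth$mu, nrow = cfg$n_genes, ncol = n_samples)
    for (k in 1:3) {
      idx <- match(truth$marker_map[[k]], gene_ids)
      cols <- which(!is.na(truth$subtype) & truth$subtype == k)
      if (length(cols)) x[idx, cols] <- x[idx, cols] + cfg$marker_effect
    }
    for (i in seq_len(nrow(b))) {
      cols <- which(annot$batch == b$batch_id[i])
      x[, cols] <- x[, cols] + truth$batch_location[i, ] +
        truth$batch_scale[i, ] * eps[, cols]
    }
    dimnames(x) <- list(gene_ids, annot$sample_id)
    x
  })

  annot <- with_seed(s2, {
    for (trait in names(cfg$trait_model)) {
      tm <- cfg$trait_model[[trait]]
      mean_vec <- rep(tm$baseline, n_samples)
      ad_idx <- which(!is.na(truth$subtype))
      mean_vec[ad_idx] <- tm$baseline + tm$offsets[truth$subtype[ad_idx]]
      if (tm$type == "bernoulli") {
        p <- pmin(pmax(mean_vec, 0), 1)
        annot[[trait]] <- ifelse(stats::runif(n_samples) < p, "F", "M")
      } else {
        annot[[trait]] <- rtrunc_norm(n_samples, mean_vec, tm$sd,
                                      tm$lower, tm$upper)
      }
      if (cfg$trait_missing_rate > 0) {
        drop <- stats::runif(n_samples) < cfg$trait_missing_rate
        annot[[trait]][drop] <- NA
      }
    }
    annot
  })

  true_subtype <- truth$subtype
  names(true_subtype) <- annot$sample_id

  out <- list(
    expression = expr,
    annotation = annot,
    truth = list(marker_map = truth$marker_map,
                 true_subtype = true_subtype[!is.na(true_subtype)],
                 batch_location = truth$batch_location,
                 batch_scale = truth$batch_scale),
    config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic AD/ND cohort\n")
  cat(sprintf("  genes: %d  samples: %d (%d AD / %d ND)  batches: %d\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$annotation$condition == "AD"),
              sum(x$annotation$condition == "ND"),
              length(unique(x$annotation$batch))))
  cat(sprintf("  planted subtypes: %s (markers: %d genes each, effect %.2f log2)\n",
              paste(table(x$truth$true_subtype), collapse = "/"),
              length(x$truth$marker_map[[1]]), x$config$marker_effect))
  invisible(x)
}

#' Stratified holdout split of a cohort
#'
#' Partitions samples into train and validation sets, stratified by condition
#' so both AD and ND are represented in each part; the validation part stands
#' in for an external verification dataset in the diagnostic-panel stage.
#'
#' @param expression genes x samples matrix.
#' @param annotation per-sample annotation data.frame with `sample_id` and
#'   `condition` columns.
#' @param fraction fraction of each condition assigned to validation
#'   (0 < fraction < 1).
#' @param seed integer seed; the same seed always yields the same split.
#' @return list with `train` and `validation`, each a list of `expression` and
#'   `annotation`; the two parts are disjoint and jointly exhaustive.
#' @export
holdout_split <- function(expression, annotation, fraction = 0.3, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (!all(c("AD", "ND") %in% annotation$condition)) {
    stop("both conditions (AD, ND) must be present")
  }
  counts <- table(annotation$condition)
  if (any(counts < 2)) stop("each condition needs at least 2 samples to split")
  val_ids <- with_seed(as.integer(seed), {
    unlist(lapply(sort(unique(annotation$condition)), function(cond) {
      ids <- sort(annotation$sample_id[annotation$condition == cond])
      n_val <- max(1L, round(fraction * length(ids)))
      sample(ids, n_val)
    }), use.names = FALSE)
  })
  take <- function(ids) {
    idx <- annotation$sample_id %in% ids
    list(expression = expression[, annotation$sample_id[idx], drop = FALSE],
         annotation = annotation[idx, , drop = FALSE])
  }
  list(train = take(setdiff(annotation$sample_id, val_ids)),
       validation = take(val_ids))
}
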