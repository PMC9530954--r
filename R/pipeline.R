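#' Build a validated pipeline configuration
#'
#' All thresholds the analysis depends on live in one declarative object:
#' either supply a YAML file path or a named list; unnamed settings take the
#' documented defaults. The configuration must name either an input dataset
#' (`expression_path` + `annotation_path`) or a `synthetic` block of
#' [cohort_config()] arguments.
#'
#' @param config path to a YAML file, or a named list.
#' @param ... individual overrides applied after the file/list (e.g.
#'   `seed = 2`); these mirror CLI flags.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    expression_path = NULL,
    annotation_path = NULL,
    synthetic = NULL,          # list of cohort_config() arguments
    seed = 1L,
    alpha = 0.05,              # BH-adjusted p threshold
    delta = 0.2,               # |mean log2 difference| threshold
    consensus_threshold = 0.8, # cluster-consensus selection rule
    k_max = 10L,
    n_resamples = 100L,
    sample_fraction = 0.8,
    top_k_hubs = 10L,
    n_permutations = 1000L,
    holdout_fraction = 0.3,
    gsea_weight = 1,
    rank_metric = "s2n",
    signature_mode = "pairwise",
    batch_col = "batch",
    protect = "condition",
    eb = TRUE,
    force_k = NULL)            # override when no K qualifies
  overrides <- list(...)
  cfg <- utils::modifyList(defaults, config[names(config) %in% c(names(defaults))])
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, overrides[names(overrides) %in% names(defaults)])
  if (is.null(cfg$synthetic) &&
      (is.null(cfg$expression_path) || is.null(cfg$annotation_path))) {
    stop("configuration must provide expression_path+annotation_path or a synthetic block")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$delta < 0) stop("delta must be >= 0")
  if (cfg$k_max < 2) stop("k_max must be >= 2")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

pipeline_header <- function(cfg, stage) {
  list(pipeline = "adsubtype", stage = stage, seed = cfg$seed,
       alpha = cfg$alpha, delta = cfg$delta,
       consensus_threshold = cfg$consensus_threshold, k_max = cfg$k_max,
       n_resamples = cfg$n_resamples, sample_fraction = cfg$sample_fraction,
       top_k_hubs = cfg$top_k_hubs, n_permutations = cfg$n_permutations,
       holdout_fraction = cfg$holdout_fraction)
}

#' Run the full subtyping pipeline
#'
#' Stages, in order: load or simulate the cohort; stratified holdout split
#' (the validation part stands in for an external verification dataset);
#' empirical-Bayes batch correction with a PCA before/after check; AD-vs-ND
#' differential expression; consensus clustering of the training AD samples
#' with cluster-consensus K selection; subgroup-specific signatures (pairwise
#' and vs-ND families) written as tables and a GMT; GSEA of each subgroup's
#' signature on its subgroup-vs-ND ranked list, with leading-edge hub panels;
#' clinical-trait association tables; exhaustive diagnostic-panel search
#' scored on the validation samples. Every output table carries the run seed
#' and thresholds in a header comment, and the whole run is deterministic
#' given the seed.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param outdir output directory (created if missing).
#' @param ... overrides forwarded to [pipeline_config()].
#' @return (invisibly) a list with the in-memory stage results: `cohort`,
#'   `split`, `correction`, `check_before`, `check_after`, `de_ad_nd`,
#'   `selection`, `signatures`, `signatures_vs_nd`, `gsea`, `hub_panels`,
#'   `clinical`, `panel_search`, `outdir`.
#' @export
run_pipeline <- function(config = list(), outdir, ...) {
  cfg <- pipeline_config(config, ...)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  stage <- "load"
  result <- tryCatch({
    ## ---- data ----
    if (!is.null(cfg$synthetic)) {
      syn_args <- cfg$synthetic
      if (is.null(syn_args$seed)) syn_args$seed <- derive_seed(cfg$seed, 10)
      if (!is.null(syn_args$batches) && is.list(syn_args$batches) &&
          !is.data.frame(syn_args$batches)) {
        syn_args$batches <- do.call(rbind, lapply(syn_args$batches, as.data.frame))
      }
      cohort <- generate_cohort(do.call(cohort_config, syn_args))
      write_ground_truth(cohort$truth, fp("ground_truth.txt"))
    } else {
      cohort <- list(
        expression = read_expression(cfg$expression_path),
        annotation = read_annotation(cfg$annotation_path),
        truth = NULL)
    }
    expr <- cohort$expression
    annot <- cohort$annotation

    ## ---- batch correction ----
    stage <- "correct"
    check_before <- if (length(unique(annot[[cfg$batch_col]])) > 1) {
      batch_check(expr, annot, batch_col = cfg$batch_col)
    }
    correction <- combat_correct(expr, annot, batch_col = cfg$batch_col,
                                 covariates = cfg$protect, eb = cfg$eb)
    corrected <- correction$corrected
    check_after <- if (!is.null(check_before)) {
      batch_check(corrected, annot, batch_col = cfg$batch_col)
    }
    write_expression(corrected, fp("corrected_expression.tsv"),
                     header = pipeline_header(cfg, "correct"))
    if (!is.null(check_before)) {
      write_result_table(
        data.frame(stage = c("before", "after"),
                   batch_separation = c(check_before$separation,
                                        check_after$separation)),
        fp("batch_check.tsv"), pipeline_header(cfg, "correct"))
    }

    ## ---- holdout ----
    stage <- "split"
    split <- holdout_split(corrected, annot, fraction = cfg$holdout_fraction,
                           seed = derive_seed(cfg$seed, 20))
    train <- split$train

    ## ---- AD vs ND differential expression ----
    stage <- "differential"
    de_ad_nd <- differential_genes(train$expression, train$annotation,
                                   "AD", "ND", alpha = cfg$alpha,
                                   delta = cfg$delta)
    write_result_table(de_ad_nd, fp("de_ad_vs_nd.tsv"),
                       pipeline_header(cfg, "differential"))

    ## ---- consensus subtyping of training AD samples ----
    stage <- "subtype"
    ad_ids <- train$annotation$sample_id[train$annotation$condition == "AD"]
    selection <- consensus_subtype(
      train$expression[, ad_ids, drop = FALSE],
      k_max = cfg$k_max, threshold = cfg$consensus_threshold,
      n_resamples = cfg$n_resamples, sample_fraction = cfg$sample_fraction,
      seed = derive_seed(cfg$seed, 30))
    write_result_table(selection$table, fp("consensus_scores.tsv"),
                       pipeline_header(cfg, "subtype"))
    chosen <- selection$chosen
    if (is.na(chosen)) {
      if (is.null(cfg$force_k)) {
        stop("no cluster count reaches consensus > ", cfg$consensus_threshold,
             "; set force_k to override")
      }
      chosen <- as.integer(cfg$force_k)
      assignments <- selection$runs[[as.character(chosen)]]$assignments
    } else {
      assignments <- selection$assignments
    }
    ann_train <- train$annotation
    ann_train$subgroup <- ifelse(
      ann_train$condition == "AD",
      paste0("subgroup", assignments[ann_train$sample_id]), "ND")
    write_annotation(ann_train, fp("annotation_with_subgroups.tsv"),
                     pipeline_header(cfg, "subtype"))
    utils::write.table(
      selection$runs[[as.character(chosen)]]$M,
      fp(sprintf("consensus_matrix_K%d.tsv", chosen)),
      sep = "\t", quote = FALSE)

    ## ---- subgroup signatures ----
    stage <- "signatures"
    ad_ann <- ann_train[ann_train$condition == "AD", , drop = FALSE]
    ad_expr <- train$expression[, ad_ann$sample_id, drop = FALSE]
    signatures <- subgroup_specific_upregulated(
      ad_expr, ad_ann, subgroup_col = "subgroup",
      alpha = cfg$alpha, delta = cfg$delta, mode = cfg$signature_mode)
    signatures_vs_nd <- lapply(sort(unique(ad_ann$subgroup)), function(sg) {
      de <- differential_genes(train$expression, ann_train, sg, "ND",
                               group_col = "subgroup",
                               alpha = cfg$alpha, delta = cfg$delta)
      de$gene[de$significant & de$mean_diff > cfg$delta]
    })
    names(signatures_vs_nd) <- sort(unique(ad_ann$subgroup))
    sig_tab <- data.frame(
      subgroup = rep(names(signatures), lengths(signatures)),
      gene = unlist(signatures, use.names = FALSE))
    write_result_table(sig_tab, fp("signatures.tsv"),
                       pipeline_header(cfg, "signatures"))
    nonempty <- signatures[lengths(signatures) > 0]
    if (!length(nonempty)) stop("every subgroup signature is empty")
    write_gmt(nonempty, fp("signatures.gmt"),
              descriptions = stats::setNames(
                paste0(names(nonempty), " specific upregulated genes"),
                names(nonempty)))

    ## ---- GSEA + hub panels ----
    stage <- "gsea"
    subgroups <- names(nonempty)
    gsea_runs <- list()
    hub_panels <- list()
    for (sg in subgroups) {
      gr <- gsea(train$expression, ann_train, sg, "ND",
                 gene_sets = nonempty[sg], group_col = "subgroup",
                 metric = cfg$rank_metric,
                 n_permutations = cfg$n_permutations,
                 seed = derive_seed(cfg$seed, 40), weight = cfg$gsea_weight)
      gsea_runs[[sg]] <- gr
      hub_panels[[sg]] <- select_hub_genes(gr$details[[1]], gr$ranked,
                                           k = cfg$top_k_hubs)$gene
    }
    gsea_tab <- do.call(rbind, lapply(subgroups, function(sg) {
      cbind(data.frame(subgroup = sg), gsea_runs[[sg]]$table)
    }))
    write_result_table(gsea_tab, fp("gsea_report.tsv"),
                       pipeline_header(cfg, "gsea"))
    hub_tab <- data.frame(
      subgroup = rep(names(hub_panels), lengths(hub_panels)),
      gene = unlist(hub_panels, use.names = FALSE))
    write_result_table(hub_tab, fp("hub_panels.tsv"),
                       pipeline_header(cfg, "gsea"))

    ## ---- clinical association ----
    stage <- "clinical"
    trait_cols <- intersect(c("CDR", "Braak", "NFT", "CERAD", "NPD", "pH", "age"),
                            names(ann_train))
    clinical <- list()
    if (length(trait_cols)) {
      clinical$trait_comparisons <- suppressMessages(
        compare_traits(ann_train, "subgroup", trait_cols))
      write_result_table(clinical$trait_comparisons,
                         fp("trait_comparisons.tsv"),
                         pipeline_header(cfg, "clinical"))
      tt <- trait_correlation_table(
        stats::setNames(lapply(trait_cols, function(tr) ann_train[[tr]]),
                        trait_cols),
        ann_train, trait_cols)
      write_result_table(
        data.frame(trait = rownames(tt$rho), round(tt$rho, 6)),
        fp("trait_trait_spearman.tsv"), pipeline_header(cfg, "clinical"))
      clinical$trait_trait <- tt
      if ("sex" %in% names(ann_train)) {
        groups <- sort(unique(ann_train$subgroup))
        rows <- list()
        for (i in seq_along(groups)) for (j in seq_along(groups)) {
          if (i >= j) next
          sa <- ann_train$sex[ann_train$subgroup == groups[i]]
          sb <- ann_train$sex[ann_train$subgroup == groups[j]]
          sa <- sa[!is.na(sa)]; sb <- sb[!is.na(sb)]
          pt <- try(proportion_test(sum(sa == "F"), length(sa),
                                    sum(sb == "F"), length(sb)), silent = TRUE)
          if (!inherits(pt, "try-error")) {
            rows[[length(rows) + 1]] <- data.frame(
              group_a = groups[i], group_b = groups[j],
              prop_f_a = mean(sa == "F"), prop_f_b = mean(sb == "F"),
              statistic = pt$statistic, p = pt$p.value,
              stars = p_stars(pt$p.value))
          }
        }
        if (length(rows)) {
          clinical$sex_proportions <- do.call(rbind, rows)
          write_result_table(clinical$sex_proportions,
                             fp("sex_proportion_tests.tsv"),
                             pipeline_header(cfg, "clinical"))
        }
      }
      # hub-gene and eigengene trait correlations, per subgroup AD samples
      hub_rows <- list(); eig_rows <- list()
      for (sg in names(hub_panels)) {
        sg_ids <- ad_ann$sample_id[ad_ann$subgroup == sg]
        if (length(sg_ids) < 3) next
        sub_expr <- train$expression[, sg_ids, drop = FALSE]
        sub_ann <- ann_train[match(sg_ids, ann_train$sample_id), , drop = FALSE]
        ct <- trait_correlation_table(
          sub_expr[hub_panels[[sg]], , drop = FALSE], sub_ann, trait_cols)
        hub_rows[[sg]] <- data.frame(
          subgroup = sg, gene = rep(rownames(ct$rho), length(trait_cols)),
          trait = rep(trait_cols, each = nrow(ct$rho)),
          rho = as.vector(ct$rho), p = as.vector(ct$p))
        me <- module_eigengene(sub_expr, genes = intersect(nonempty[[sg]],
                                                           rownames(sub_expr)))
        et <- trait_correlation_table(list(eigengene = me$scores), sub_ann,
                                      trait_cols)
        eig_rows[[sg]] <- data.frame(
          subgroup = sg, trait = trait_cols,
          rho = as.vector(et$rho), p = as.vector(et$p),
          variance_explained = me$variance_explained)
      }
      if (length(hub_rows)) {
        clinical$hub_trait <- do.call(rbind, hub_rows)
        write_result_table(clinical$hub_trait, fp("hub_trait_correlation.tsv"),
                           pipeline_header(cfg, "clinical"))
      }
      if (length(eig_rows)) {
        clinical$eigengene_trait <- do.call(rbind, eig_rows)
        write_result_table(clinical$eigengene_trait,
                           fp("eigengene_trait_correlation.tsv"),
                           pipeline_header(cfg, "clinical"))
      }
    }

    ## ---- diagnostic panel search ----
    stage <- "panels"
    search <- search_best_panels(train, split$validation, hub_panels)
    for (sg in names(search$rankings)) {
      write_result_table(search$rankings[[sg]],
                         fp(sprintf("panel_rankings_%s.tsv", sg)),
                         pipeline_header(cfg, "panels"))
    }
    write_result_table(search$best, fp("best_panels.tsv"),
                       pipeline_header(cfg, "panels"))

    ## ---- provenance ----
    stage <- "provenance"
    prov <- c(
      sprintf("package=adsubtype %s", as.character(utils::packageVersion("adsubtype"))),
      sprintf("r_version=%s.%s", R.version$major, R.version$minor),
      sprintf("seed=%d", cfg$seed),
      sprintf("alpha=%g delta=%g consensus_threshold=%g k_max=%d", cfg$alpha,
              cfg$delta, cfg$consensus_threshold, cfg$k_max),
      sprintf("n_resamples=%d sample_fraction=%g", cfg$n_resamples,
              cfg$sample_fraction),
      sprintf("top_k_hubs=%d n_permutations=%d holdout_fraction=%g",
              cfg$top_k_hubs, cfg$n_permutations, cfg$holdout_fraction),
      sprintf("chosen_k=%d", chosen),
      sprintf("total_panel_evaluations=%d", search$total_evaluations))
    writeLines(prov, fp("provenance.txt"))

    list(cohort = cohort, split = split, correction = correction,
         check_before = check_before, check_after = check_after,
         de_ad_nd = de_ad_nd, selection = selection, chosen_k = chosen,
         signatures = signatures, signatures_vs_nd = signatures_vs_nd,
         gsea = gsea_runs, hub_panels = hub_panels, clinical = clinical,
         panel_search = search, outdir = outdir, config = cfg)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
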