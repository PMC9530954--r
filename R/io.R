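#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; all remaining cells numeric log2 expression values.
#'
#' @param path file path.
#' @return Numeric genes x samples matrix with gene ids as rownames and sample
#'   ids as colnames, in file order.
#' @export
read_expression <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, check.names = FALSE,
                      colClasses = "character", comment.char = "#"),
    error = function(e) stop("malformed expression file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2) stop("expression file needs a gene id column and at least one sample")
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  num
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are written with enough digits that write-then-read round-trips to
#' at least six decimal places.
#'
#' @param x genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @param header optional named header written as `# key=value` lines.
#' @export
write_expression <- function(x, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) {
    for (i in seq_along(header)) {
      writeLines(sprintf("# %s=%s", names(header)[i], as.character(header[[i]])), con)
    }
  }
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a per-sample annotation table
#'
#' Tab-delimited with a header; must contain `sample_id` and `condition`
#' columns. Trait columns may contain missing values (empty or `NA`), which
#' are propagated, not imputed.
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""))
  if (!all(c("sample_id", "condition") %in% names(df))) {
    stop("annotation needs 'sample_id' and 'condition' columns")
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$condition), c("AD", "ND"))
  if (length(bad)) stop("condition must be AD or ND; found: ", paste(bad, collapse = ", "))
  df
}

#' Write a per-sample annotation table
#' @param annot data.frame with `sample_id` column.
#' @param path output path.
#' @param header optional named header written as `# key=value` lines.
#' @export
write_annotation <- function(annot, path, header = NULL) {
  write_result_table(annot, path, header)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a line are dropped with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids, with a `descriptions`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file")
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                   i, length(fields)))
    }
    name <- fields[1]
    if (name %in% names(sets)) stop("duplicate gene set name: ", name)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): duplicate genes deduplicated", i, name))
      genes <- unique(genes)
    }
    if (!length(genes)) stop(sprintf("GMT line %d ('%s') has no genes", i, name))
    sets[[name]] <- genes
    descs[name] <- fields[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Intersect several expression matrices on common genes and merge
#'
#' Utility for merging matrices from different platforms before batch
#' correction: restricts to genes present in every matrix and binds samples.
#'
#' @param matrices list of genes x samples matrices.
#' @return merged matrix over the common genes (order of the first matrix).
#' @export
intersect_expression <- function(matrices) {
  if (length(matrices) < 2) stop("need at least two matrices")
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(common)) stop("no genes common to all matrices")
  all_ids <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_ids)) stop("duplicate sample ids across matrices")
  do.call(cbind, lapply(matrices, function(m) m[common, , drop = FALSE]))
}

#' Write cohort ground truth as a plain-text key/value sidecar
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  lines <- c(
    vapply(names(truth$marker_map), function(k) {
      sprintf("marker_map.%s=%s", k, paste(truth$marker_map[[k]], collapse = ","))
    }, character(1)),
    sprintf("true_subtype.%s=%d", names(truth$true_subtype), truth$true_subtype))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ground-truth sidecar written by [write_ground_truth()]
#' @param path file path.
#' @return list with `marker_map` and `true_subtype`.
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  mm_idx <- startsWith(keys, "marker_map.")
  marker_map <- lapply(vals[mm_idx], function(v) strsplit(v, ",", fixed = TRUE)[[1]])
  names(marker_map) <- sub("^marker_map\\.", "", keys[mm_idx])
  st_idx <- startsWith(keys, "true_subtype.")
  true_subtype <- as.integer(vals[st_idx])
  names(true_subtype) <- sub("^true_subtype\\.", "", keys[st_idx])
  list(marker_map = marker_map, true_subtype = true_subtype)
}
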