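#' Derive a stage-specific random seed from a run seed
#'
#' All randomness in the package flows from one integer run seed; each stage
#' derives its own sub-seed deterministically so that adding a stage never
#' perturbs the random stream of another.
#'
#' @param seed integer run seed.
#' @param stage integer stage offset (>= 0).
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + stage * 1000003) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used to
#' score recovery of planted subtypes by the consensus clustering stage.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return The adjusted Rand index, 1 for identical partitions (up to
#'   relabeling), about 0 for independent ones.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Significance stars for a p value
#'
#' Convention used throughout the result tables: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `ns` otherwise.
#'
#' @param p numeric vector of p values.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
    ifelse(p < 0.001, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", "ns"))))
}

#' Write a result table with a provenance header
#'
#' All pipeline outputs are tab-delimited tables preceded by `#`-prefixed
#' header lines recording the run seed and thresholds, so any table can be
#' traced to its run.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param header named character or list; written as `# key=value` lines.
#' @export
write_result_table <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) {
    keys <- names(header)
    for (i in seq_along(header)) {
      writeLines(sprintf("# %s=%s", keys[i], as.character(header[[i]])), con)
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path file path.
#' @return data.frame (header comment lines are skipped).
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

# run an expression under a local, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
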