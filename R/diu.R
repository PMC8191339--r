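#' Per-gene isoform-by-condition usage table
#'
#' Sums read counts per condition (or keeps per-sample columns) and derives
#' relative usage: an isoform's percentage of all reads of the gene in that
#' condition. Columns with zero total reads get \code{NA} usage and are
#' excluded from testing and from usage standard deviations.
#'
#' @param gene_records isoform records of one gene
#'   (see [read_isoform_models()]).
#' @param sample_map sample map data.frame; defaults to the records'
#'   \code{"sample_map"} attribute.
#' @param gene_id gene label for the table.
#' @param collapse_replicates sum replicate samples within each condition
#'   (default TRUE); when FALSE, columns are individual samples.
#' @return a \code{usage_table}: list with \code{gene_id}, \code{counts}
#'   (isoform x column integer matrix), \code{usage} (percentage matrix,
#'   columns summing to 100 where defined) and \code{testable_cols}
#'   (logical, nonzero column totals).
#' @export
build_usage_table <- function(gene_records, sample_map = NULL,
                              gene_id = NA_character_,
                              collapse_replicates = TRUE) {
  if (length(gene_records) == 0L) stop("gene has zero isoforms")
  if (is.null(sample_map)) sample_map <- attr(gene_records, "sample_map")
  if (is.null(sample_map)) stop("a sample map is required")
  sm <- sample_map[sample_map$include_flag, , drop = FALSE]
  iso_ids <- vapply(gene_records, function(r) r$model$id, "")
  counts <- do.call(rbind, lapply(gene_records, function(r) {
    x <- r$counts[sm$sample]
    x[is.na(x)] <- 0
    x
  }))
  rownames(counts) <- iso_ids
  colnames(counts) <- sm$sample
  if (collapse_replicates) {
    counts <- t(rowsum(t(counts), group = sm$condition, reorder = FALSE))
  }
  usage_table(counts, gene_id = gene_id)
}

#' Construct a usage table from a count matrix
#'
#' @param counts non-negative isoform x condition matrix.
#' @param gene_id gene label.
#' @return a \code{usage_table} (see [build_usage_table()]).
#' @export
usage_table <- function(counts, gene_id = NA_character_) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts in usage table")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("usage table needs >= 1 row and >= 1 column")
  totals <- colSums(counts)
  usage <- sweep(counts, 2L, totals, "/") * 100
  usage[, totals == 0] <- NA_real_
  structure(list(gene_id = gene_id, counts = counts, usage = usage,
                 testable_cols = totals > 0),
            class = "usage_table")
}

#' @export
print.usage_table <- function(x, ...) {
  cat(sprintf("<usage_table> gene %s: %d isoform(s) x %d column(s)\n",
              x$gene_id, nrow(x$counts), ncol(x$counts)))
  print(round(x$usage, 1))
  invisible(x)
}

#' Keep genes with enough reads in enough conditions
#'
#' A gene is testable when at least \code{min_conditions} of its condition
#' columns hold at least \code{min_reads} reads (defaults: >= 50 reads in
#' >= 2 conditions).
#'
#' @param tables list of \code{usage_table}s.
#' @param min_reads minimum reads per condition column (inclusive).
#' @param min_conditions minimum number of such columns (inclusive).
#' @return the retained subset of \code{tables}.
#' @export
filter_testable_genes <- function(tables, min_reads = 50, min_conditions = 2) {
  keep <- vapply(tables, function(t)
    sum(colSums(t$counts) >= min_reads) >= min_conditions, TRUE)
  tables[keep]
}

# chi-squared contingency core: expected E_ij = row_i * col_j / N, no
# continuity correction, df after removal of all-zero rows/columns
.chi2_core <- function(counts) {
  m <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  r <- nrow(m); k <- ncol(m)
  if (r < 2L || k < 2L)
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                testable = FALSE, min_expected = NA_real_,
                rows_used = r, cols_used = k))
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (r - 1L) * (k - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       testable = TRUE, min_expected = min(E),
       rows_used = r, cols_used = k)
}

#' Chi-squared contingency test on an isoform-by-condition count matrix
#'
#' Pearson chi-squared test of homogeneity without continuity correction:
#' \eqn{E_{ij} = n_{i.} n_{.j} / N}, statistic \eqn{\sum (O-E)^2/E}, upper
#' tail of the chi-squared distribution with \eqn{(r-1)(k-1)} degrees of
#' freedom after all-zero rows/columns are dropped. Fewer than two usable
#' rows or columns makes the gene untestable (\code{NA} result). A warning
#' is emitted when any expected count falls below 5.
#'
#' @param counts non-negative matrix (or \code{usage_table}).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{testable}, \code{min_expected}, \code{rows_used},
#'   \code{cols_used}.
#' @export
chi2_contingency_test <- function(counts) {
  if (inherits(counts, "usage_table")) counts <- counts$counts
  res <- .chi2_core(as.matrix(counts))
  if (res$testable && res$min_expected < 5)
    warning("expected count below 5 (min ", signif(res$min_expected, 3),
            "); chi-squared approximation may be poor")
  res
}

#' Bonferroni correction
#'
#' \code{p_adj = min(1, p * m)} with \code{m} the number of tests actually
#' performed; a gene is significant when its adjusted p-value is below
#' \code{alpha}.
#'
#' @param p_values raw p-values of the tested genes.
#' @param alpha family-wise significance level (default 0.05).
#' @param m number of tests (defaults to \code{length(p_values)}).
#' @return list with \code{p_adjusted} and logical \code{significant}.
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  if (length(p_values) == 0L)
    return(list(p_adjusted = numeric(0), significant = logical(0)))
  p_adj <- stats::p.adjust(p_values, method = "bonferroni", n = m)
  list(p_adjusted = p_adj, significant = p_adj < alpha)
}

#' Maximum usage standard deviation of a gene
#'
#' For each isoform, the population standard deviation (divide by n) of its
#' relative usage percentages across testable condition columns; returns
#' the maximum over isoforms, in percentage points.
#'
#' @param table a \code{usage_table}.
#' @return numeric; \code{NA} with a warning when fewer than two testable
#'   columns exist.
#' @export
max_usage_sd <- function(table) {
  u <- table$usage[, table$testable_cols, drop = FALSE]
  if (ncol(u) < 2L) {
    warning("fewer than two testable conditions; usage SD undefined")
    return(NA_real_)
  }
  pop_sd <- apply(u, 1L, function(x) sqrt(mean((x - mean(x))^2)))
  max(pop_sd)
}

#' Differential isoform usage from per-gene count matrices
#'
#' Matrix-level entry point of the workflow in [run_diu()]: expression
#' filter, chi-squared contingency test per gene, Bonferroni correction
#' over the tested count, usage-SD annotation and deterministic ranking.
#' \code{mode = "percent"} applies the test to the relative-usage table
#' instead of counts (kept for comparison; counts is the statistically
#' defensible default and the mode is recorded in the output attributes).
#'
#' @param mats named list (by gene) of isoform x condition count matrices.
#' @param min_reads,min_conditions,alpha see [run_diu()].
#' @param mode \code{"counts"} (default) or \code{"percent"}.
#' @return see [run_diu()].
#' @export
diu_from_matrices <- function(mats, min_reads = 50, min_conditions = 2,
                              alpha = 0.05, mode = c("counts", "percent")) {
  mode <- match.arg(mode)
  tables <- lapply(names(mats), function(g) usage_table(mats[[g]], gene_id = g))
  names(tables) <- names(mats)
  tested <- filter_testable_genes(tables, min_reads, min_conditions)
  rows <- lapply(tested, function(t) {
    input <- if (mode == "percent") {
      u <- t$usage[, t$testable_cols, drop = FALSE]
      u[is.na(u)] <- 0
      u
    } else t$counts
    res <- .chi2_core(input)
    data.frame(gene_id = t$gene_id, n_isoforms = nrow(t$counts),
               n_conditions_tested = res$cols_used,
               chi2_stat = res$statistic, df = res$df,
               p_value = res$p_value, testable = res$testable,
               min_expected = res$min_expected,
               max_usage_sd = suppressWarnings(max_usage_sd(t)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(0), n_isoforms = integer(0),
               n_conditions_tested = integer(0), chi2_stat = numeric(0),
               df = integer(0), p_value = numeric(0), testable = logical(0),
               min_expected = numeric(0), max_usage_sd = numeric(0))
  rownames(out) <- NULL
  untestable <- out[!out$testable, , drop = FALSE]
  out <- out[out$testable, , drop = FALSE]
  m <- nrow(out)
  bf <- bonferroni(out$p_value, alpha = alpha, m = m)
  out$p_bonferroni <- bf$p_adjusted
  out$significant <- bf$significant
  out <- out[order(out$p_value, -out$max_usage_sd, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "untestable") <- untestable$gene_id
  attr(out, "n_tested") <- m
  attr(out, "mode") <- mode
  out
}

#' Differential isoform usage across conditions
#'
#' The complete workflow: group isoforms by assigned gene, build
#' isoform-by-condition count tables (replicates collapsed), keep genes
#' with at least \code{min_reads} reads in at least \code{min_conditions}
#' conditions, apply the chi-squared contingency test per gene, Bonferroni-
#' correct over the number of genes actually tested, attach the maximum
#' usage standard deviation, and rank by p-value (ties: larger SD first,
#' then gene id).
#'
#' @param records isoform records (see [read_isoform_models()]).
#' @param gene_ids named character vector isoform id -> gene id (e.g. from
#'   [classify_isoforms()]); isoforms with \code{NA} gene are skipped.
#' @param sample_map sample map; defaults to the records' attribute.
#' @param min_reads,min_conditions expression filter
#'   (see [filter_testable_genes()]).
#' @param alpha family-wise significance level.
#' @param collapse_replicates sum replicates within conditions before
#'   testing (default TRUE).
#' @param mode apply the test to raw \code{"counts"} (default) or to the
#'   \code{"percent"} usage table.
#' @return data.frame of per-gene results (gene_id, n_isoforms,
#'   n_conditions_tested, chi2_stat, df, p_value, p_bonferroni,
#'   significant, max_usage_sd, min_expected), ranked; the ids of
#'   untestable genes and the tested count are attached as attributes
#'   \code{"untestable"} and \code{"n_tested"}.
#' @export
run_diu <- function(records, gene_ids, sample_map = NULL, min_reads = 50,
                    min_conditions = 2, alpha = 0.05,
                    collapse_replicates = TRUE,
                    mode = c("counts", "percent")) {
  mode <- match.arg(mode)
  if (is.null(sample_map)) sample_map <- attr(records, "sample_map")
  genes <- gene_ids[names(records)]
  grp <- split(names(records), genes)
  mats <- lapply(grp, function(ids) {
    t <- build_usage_table(records[ids], sample_map = sample_map,
                           collapse_replicates = collapse_replicates)
    t$counts
  })
  diu_from_matrices(mats, min_reads = min_reads,
                    min_conditions = min_conditions, alpha = alpha,
                    mode = mode)
}
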