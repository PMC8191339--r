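#' Reads-per-million normalization
#'
#' \code{rpm = count * 1e6 / column_total}. Helper for the synthetic path;
#' real RPM tables are consumed as inputs, not computed here.
#'
#' @param counts gene x sample count matrix (or data.frame with gene ids in
#'   the first column).
#' @return matrix of RPM values with the same shape.
#' @export
compute_rpm <- function(counts) {
  if (is.data.frame(counts) && !is.numeric(counts[[1L]])) {
    ids <- counts[[1L]]
    counts <- as.matrix(counts[, -1L, drop = FALSE])
    rownames(counts) <- ids
  } else {
    counts <- as.matrix(counts)
  }
  totals <- colSums(counts)
  totals[totals == 0] <- 1
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Mean RPM per gene over included samples
#'
#' @param rpm gene x sample RPM data.frame (first column gene id) or
#'   matrix with gene rownames.
#' @param sample_map optional sample map; when given, only samples with
#'   \code{include_flag} enter the mean.
#' @return named numeric vector of per-gene mean RPM.
#' @export
mean_rpm <- function(rpm, sample_map = NULL) {
  if (is.data.frame(rpm) && !is.numeric(rpm[[1L]])) {
    ids <- rpm[[1L]]
    rpm <- as.matrix(rpm[, -1L, drop = FALSE])
    rownames(rpm) <- ids
  }
  if (!is.null(sample_map)) {
    keep <- intersect(colnames(rpm),
                      sample_map$sample[sample_map$include_flag])
    rpm <- rpm[, keep, drop = FALSE]
  }
  rowMeans(rpm)
}

#' Expressed genes by mean RPM
#'
#' Genes whose average RPM across included samples is strictly above the
#' threshold (default 0.05; a gene at exactly the threshold is excluded).
#'
#' @param rpm RPM table or precomputed named mean-RPM vector.
#' @param min_mean_rpm expression threshold (strict).
#' @param sample_map optional sample map (see [mean_rpm()]).
#' @return character vector of gene ids.
#' @export
expressed_genes <- function(rpm, min_mean_rpm = 0.05, sample_map = NULL) {
  mu <- if (is.numeric(rpm) && !is.matrix(rpm)) rpm
        else mean_rpm(rpm, sample_map)
  names(mu)[mu > min_mean_rpm]
}

.bin_labels <- function(edges) {
  n <- length(edges) - 1L
  vapply(seq_len(n), function(i) {
    if (is.infinite(edges[i + 1L])) sprintf(">%g", edges[i])
    else sprintf("%g-%g", edges[i], edges[i + 1L])
  }, "")
}

# lower-exclusive / upper-inclusive binning of mean RPM
.bin_of <- function(x, edges) {
  b <- findInterval(x, edges, left.open = TRUE)
  b[b < 1L | b > length(edges) - 1L] <- NA_integer_
  b
}

#' Isoform detection rate by expression bin
#'
#' Fraction of expressed genes with at least one classified isoform, per
#' expression bin. Bins are lower-exclusive / upper-inclusive; the last bin
#' is open-ended. Empty bins report \code{NA}, not 0.
#'
#' @param gene_rpm named mean-RPM vector of the \emph{expressed} genes
#'   (see [expressed_genes()] / [mean_rpm()]).
#' @param detected character vector of genes with >= 1 classified isoform.
#' @param edges bin edges; default \code{c(0.05, 3, 5, 10, 20, Inf)}.
#' @return data.frame with \code{bin}, \code{n_genes}, \code{n_detected},
#'   \code{fraction}.
#' @export
detection_rate_by_bin <- function(gene_rpm, detected,
                                  edges = c(0.05, 3, 5, 10, 20, Inf)) {
  bins <- .bin_of(gene_rpm, edges)
  labels <- .bin_labels(edges)
  out <- do.call(rbind, lapply(seq_along(labels), function(i) {
    g <- names(gene_rpm)[!is.na(bins) & bins == i]
    data.frame(bin = labels[i], n_genes = length(g),
               n_detected = sum(g %in% detected),
               fraction = if (length(g) == 0L) NA_real_
                          else mean(g %in% detected),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Isoforms per gene, optionally summarized by expression bin
#'
#' Counts classified isoforms per assigned gene (isoforms without a gene,
#' e.g. intergenic, are excluded). When a mean-RPM vector is supplied, a
#' five-number summary of isoform counts is added per expression bin.
#'
#' @param classifications data.frame from [classify_isoforms()].
#' @param gene_rpm optional named mean-RPM vector.
#' @param edges bin edges (see [detection_rate_by_bin()]).
#' @return named integer vector of isoform counts per gene; when
#'   \code{gene_rpm} is given, the per-bin summary data.frame (columns
#'   bin, n_genes, min, q1, median, q3, max) is attached as the
#'   \code{"by_bin"} attribute.
#' @export
isoforms_per_gene <- function(classifications, gene_rpm = NULL,
                              edges = c(0.05, 3, 5, 10, 20, Inf)) {
  g <- classifications$gene_id[!is.na(classifications$gene_id)]
  counts <- table(g)
  out <- stats::setNames(as.integer(counts), names(counts))
  if (!is.null(gene_rpm)) {
    bins <- .bin_of(gene_rpm, edges)
    labels <- .bin_labels(edges)
    by_bin <- do.call(rbind, lapply(seq_along(labels), function(i) {
      genes <- names(gene_rpm)[!is.na(bins) & bins == i]
      x <- out[intersect(genes, names(out))]
      if (length(x) == 0L)
        return(data.frame(bin = labels[i], n_genes = 0L, min = NA_real_,
                          q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                          max = NA_real_, stringsAsFactors = FALSE))
      q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      data.frame(bin = labels[i], n_genes = length(x), min = q[1L],
                 q1 = q[2L], median = q[3L], q3 = q[4L], max = q[5L],
                 stringsAsFactors = FALSE)
    }))
    rownames(by_bin) <- NULL
    attr(out, "by_bin") <- by_bin
  }
  out
}
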