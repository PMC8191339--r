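#' Read a sample-to-condition map
#'
#' The sample map drives replicate collapsing and sample inclusion
#' everywhere in the package. Tab-separated columns: \code{sample},
#' \code{condition}, \code{replicate}, \code{include_flag}. Samples with
#' \code{include_flag} FALSE (e.g. pilot runs) never enter usage tables or
#' expression means.
#'
#' @param path TSV file with a header row.
#' @return data.frame with the four columns above.
#' @export
read_sample_map <- function(path) {
  sm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition")
  if (!all(need %in% names(sm)))
    stop("sample map must have columns: ", paste(need, collapse = ", "))
  if (is.null(sm$replicate)) sm$replicate <- 1L
  if (is.null(sm$include_flag)) sm$include_flag <- TRUE
  sm$include_flag <- as.logical(sm$include_flag)
  if (anyDuplicated(sm$sample))
    stop("duplicated sample ids in sample map")
  sm
}

#' Read BED12 transcript models
#'
#' Converts BED12 blocks to exon intervals: with \code{chromStart = s},
#' block start \code{b} and size \code{w}, the exon is \code{(s + b, s + b
#' + w)} in 0-based half-open coordinates (BED is natively 0-based).
#'
#' @param path BED12 file.
#' @return named list of [transcript_model()] objects.
#' @export
read_bed12_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) return(list())
  blocks <- if (!is.null(S4Vectors::mcols(gr)$blocks)) S4Vectors::mcols(gr)$blocks else NULL
  models <- lapply(seq_along(gr), function(i) {
    s0 <- GenomicRanges::start(gr)[i] - 1L
    nm <- S4Vectors::mcols(gr)$name[i]
    id <- sub("\\|.*$", "", nm)
    if (is.null(blocks) || length(blocks[[i]]) == 0L) {
      exons <- cbind(s0, GenomicRanges::end(gr)[i])
    } else {
      b <- blocks[[i]]  # 1-based, relative to chromStart
      exons <- cbind(s0 + IRanges::start(b) - 1L, s0 + IRanges::end(b))
    }
    transcript_model(id, as.character(GenomicRanges::seqnames(gr)[i]),
                     as.character(GenomicRanges::strand(gr)[i]), exons)
  })
  names(models) <- vapply(models, `[[`, "", "id")
  models
}

#' Read isoform models together with their per-sample read counts
#'
#' @param models_path isoform models as GTF or BED12 (decided by extension:
#'   \code{.bed} is BED12, anything else is parsed as GTF).
#' @param counts_path TSV of read counts: first column the model id, one
#'   column per sample.
#' @param sample_map sample map data.frame (see [read_sample_map()]) or a
#'   path to one.
#' @return list of isoform records; each record is a list with \code{model}
#'   (a [transcript_model()]), \code{counts} (named integer vector over
#'   included samples) and \code{zero_reads} flag. The sample map is attached
#'   as the \code{"sample_map"} attribute.
#' @details Every count row must have a model and vice versa; counts must be
#'   non-negative. Records whose total count is zero are retained but
#'   flagged. Samples excluded by \code{include_flag} are dropped from the
#'   count vectors here, once, so no downstream step sees them.
#' @export
read_isoform_models <- function(models_path, counts_path, sample_map) {
  if (is.character(sample_map)) sample_map <- read_sample_map(sample_map)
  models <- if (grepl("\\.bed(\\.gz)?$", models_path, ignore.case = TRUE)) {
    read_bed12_models(models_path)
  } else {
    ann <- parse_gtf(models_path)
    lapply(ann$transcripts, function(m) { m$gene_id <- NA_character_; m })
  }
  cnt <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  ids <- as.character(cnt[[1L]])
  mat <- as.matrix(cnt[, -1L, drop = FALSE])
  rownames(mat) <- ids
  if (any(mat < 0)) stop("negative read count in ", counts_path)
  unknown_samples <- setdiff(colnames(mat), sample_map$sample)
  if (length(unknown_samples) > 0L)
    stop("count columns missing from sample map: ",
         paste(unknown_samples, collapse = ", "))
  missing_models <- setdiff(ids, names(models))
  if (length(missing_models) > 0L)
    stop("count rows without a model: ", paste(missing_models, collapse = ", "))
  missing_counts <- setdiff(names(models), ids)
  if (length(missing_counts) > 0L)
    stop("models without a count row: ", paste(missing_counts, collapse = ", "))
  keep_samples <- sample_map$sample[sample_map$include_flag]
  keep_samples <- intersect(colnames(mat), keep_samples)
  records <- lapply(names(models), function(id) {
    counts <- mat[id, keep_samples]
    names(counts) <- keep_samples
    list(model = models[[id]], counts = counts,
         zero_reads = sum(counts) == 0)
  })
  names(records) <- names(models)
  attr(records, "sample_map") <- sample_map
  records
}

#' Read short-read splice junctions
#'
#' Accepts STAR \code{SJ.out.tab}-style TSV (nine headerless columns;
#' 1-based inclusive intron coordinates; strand coded 0/1/2) or six-column
#' BED (0-based half-open). Junctions with zero uniquely-mapping supporting
#' reads are excluded; duplicate rows are collapsed with their counts
#' summed; an unknown strand code is treated as unstranded (with a message).
#'
#' @param path junction file.
#' @return a \code{junction_set}: data.frame with columns \code{chrom},
#'   \code{strand}, \code{start}, \code{end} (0-based half-open intron) and
#'   \code{count}.
#' @export
read_short_read_junctions <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1L,
                             stringsAsFactors = FALSE)
  if (ncol(first) >= 9L) {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    strand <- c("0" = "*", "1" = "+", "2" = "-")[as.character(d[[4L]])]
    if (anyNA(strand)) {
      message("unknown strand code(s) in ", path, "; treated as unstranded")
      strand[is.na(strand)] <- "*"
    }
    js <- data.frame(chrom = as.character(d[[1L]]), strand = strand,
                     start = d[[2L]] - 1L, end = d[[3L]],
                     count = d[[7L]], stringsAsFactors = FALSE)
  } else if (ncol(first) >= 5L) {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    strand <- if (ncol(d) >= 6L) as.character(d[[6L]]) else "*"
    strand[!strand %in% c("+", "-")] <- "*"
    js <- data.frame(chrom = as.character(d[[1L]]), strand = strand,
                     start = d[[2L]], end = d[[3L]],
                     count = d[[5L]], stringsAsFactors = FALSE)
  } else {
    stop("junction file must be SJ.out.tab-style (9 columns) or BED (>= 5 columns)")
  }
  js <- js[js$count > 0, , drop = FALSE]
  key <- paste(js$chrom, js$strand, js$start, js$end)
  agg <- rowsum(js$count, key)
  js <- js[!duplicated(key), , drop = FALSE]
  js$count <- agg[paste(js$chrom, js$strand, js$start, js$end), 1L]
  rownames(js) <- NULL
  class(js) <- c("junction_set", "data.frame")
  js
}

#' Build a junction set from models (all junctions, unit counts)
#'
#' @param models list of [transcript_model()] objects.
#' @return a \code{junction_set} with one row per distinct junction.
#' @export
junction_set_from_models <- function(models) {
  rows <- do.call(rbind, lapply(models, function(m) {
    if (m$n_exons < 2L) return(NULL)
    data.frame(chrom = m$chrom, strand = m$strand,
               start = m$junctions[, 1L], end = m$junctions[, 2L],
               count = 1L, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(chrom = character(0), strand = character(0),
                       start = integer(0), end = integer(0), count = integer(0))
  key <- paste(rows$chrom, rows$strand, rows$start, rows$end)
  rows <- rows[!duplicated(key), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("junction_set", "data.frame")
  rows
}

# strand-aware (or not) membership of junctions in a junction set.
# The default ignores strand because nondirectional short-read libraries
# cannot assign one; an unstranded set member matches either query strand.
junctions_in_set <- function(jset, chrom, strand, start, end,
                             strand_aware = FALSE) {
  if (nrow(jset) == 0L) return(rep(FALSE, length(start)))
  if (strand_aware) {
    key <- paste(jset$chrom, jset$strand, jset$start, jset$end)
    q <- paste(chrom, strand, start, end)
    hit <- q %in% key
    # unstranded set members match either strand
    keyu <- paste(jset$chrom[jset$strand == "*"], jset$start[jset$strand == "*"],
                  jset$end[jset$strand == "*"])
    hit | paste(chrom, start, end) %in% keyu
  } else {
    key <- paste(jset$chrom, jset$start, jset$end)
    paste(chrom, start, end) %in% key
  }
}

#' Write isoforms as BED12
#'
#' One BED12 line per record; the name field carries the isoform id and,
#' when classifications are supplied, its category as \code{id|category}.
#' Block arithmetic inverts [read_bed12_models()], so exon structure
#' round-trips exactly.
#'
#' @param records isoform records (see [read_isoform_models()]) or a list of
#'   [transcript_model()] objects.
#' @param path output file.
#' @param classifications optional classification data.frame
#'   (see [classify_isoforms()]) used to annotate the name field.
#' @export
write_bed12 <- function(records, path, classifications = NULL) {
  header <- "track name=isoforms description=\"isoform models\""
  models <- lapply(records, function(r) if (is.list(r) && !is.null(r$model)) r$model else r)
  if (length(models) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  cat_of <- NULL
  if (!is.null(classifications))
    cat_of <- stats::setNames(classifications$category, classifications$isoform_id)
  lines <- vapply(models, function(m) {
    nm <- if (!is.null(cat_of) && m$id %in% names(cat_of))
      paste(m$id, cat_of[[m$id]], sep = "|") else m$id
    sizes <- m$exons[, 2L] - m$exons[, 1L]
    starts <- m$exons[, 1L] - m$span[["start"]]
    strand <- if (m$strand == "*") "." else m$strand
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            m$chrom, m$span[["start"]], m$span[["end"]], nm, strand,
            m$span[["start"]], m$span[["start"]], m$n_exons,
            paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(starts, collapse = ","), ","))
  }, "")
  writeLines(c(header, lines), path)
  invisible(path)
}
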