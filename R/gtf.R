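#' Parse a GTF annotation into an indexed genome annotation
#'
#' Reads exon (and, when present, CDS) features of a GENCODE-dialect GTF and
#' builds a [build_annotation()] index. GTF coordinates (1-based, inclusive)
#' are converted to the internal 0-based half-open convention, so a GTF exon
#' \code{101-200} becomes the interval \code{(100, 200)}. Exon lines of a
#' transcript may appear in any order; they are sorted by start.
#'
#' @param path path to a GTF file.
#' @param keep_biotypes optional character vector; when given, only genes
#'   whose \code{gene_biotype}/\code{gene_type} attribute is in this set are
#'   kept.
#' @return a \code{genome_annotation}.
#' @details Structurally malformed lines (not nine tab-separated fields, or
#'   non-numeric coordinates) abort with an error naming the line number.
#'   Feature records with \code{end <= start} are dropped with a warning
#'   rather than aborting.
#' @export
parse_gtf <- function(path, keep_biotypes = NULL) {
  path <- .validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0L) return(build_annotation(list()))
  if (is.null(df$gene_id) || is.null(df$transcript_id) ||
      anyNA(df$gene_id) || anyNA(df$transcript_id))
    stop("GTF exon/CDS records must carry gene_id and transcript_id attributes")
  bt_col <- intersect(c("gene_biotype", "gene_type"), names(df))[1]
  if (!is.null(keep_biotypes) && !is.na(bt_col))
    df <- df[!is.na(df[[bt_col]]) & df[[bt_col]] %in% keep_biotypes, , drop = FALSE]

  ex <- df[df$type == "exon", , drop = FALSE]
  transcripts <- lapply(split(ex, ex$transcript_id), function(d) {
    transcript_model(d$transcript_id[1L], d$seqnames[1L], d$strand[1L],
                     cbind(d$start - 1L, d$end), gene_id = d$gene_id[1L])
  })

  cds_df <- df[df$type == "CDS", , drop = FALSE]
  cds <- NULL
  if (nrow(cds_df) > 0L) {
    cds <- lapply(split(cds_df, cds_df$transcript_id), function(d) {
      d <- d[order(d$start), , drop = FALSE]
      frame <- if ("phase" %in% names(d)) ifelse(is.na(d$phase), 0L, d$phase) else 0L
      cbind(start = d$start - 1L, end = d$end, frame = as.integer(frame))
    })
  }

  gene_meta <- NULL
  first <- ex[!duplicated(ex$gene_id), , drop = FALSE]
  gene_meta <- data.frame(
    gene_id = first$gene_id,
    name = if ("gene_name" %in% names(first)) first$gene_name else first$gene_id,
    biotype = if (!is.na(bt_col)) first[[bt_col]] else NA_character_,
    stringsAsFactors = FALSE)

  build_annotation(transcripts, gene_meta = gene_meta, cds = cds)
}

# structural pre-check so that parse failures point at a line number;
# records with a non-positive span are dropped (with a warning) before the
# file is handed to rtracklayer. Returns the path actually to be imported.
.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rejected <- integer(0)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e))
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    if (e < s) rejected <- c(rejected, i)
  }
  if (length(rejected) > 0L) {
    warning("rejected ", length(rejected),
            " zero-length GTF record(s) at line(s): ",
            paste(rejected, collapse = ", "))
    clean <- tempfile(fileext = ".gtf")
    writeLines(lines[setdiff(seq_along(lines), rejected)], clean)
    return(clean)
  }
  path
}

.gtf_attr <- function(gene_id, transcript_id, name = NULL, biotype = NULL) {
  a <- sprintf('gene_id "%s"; transcript_id "%s";', gene_id, transcript_id)
  if (!is.null(name) && !is.na(name))
    a <- paste0(a, sprintf(' gene_name "%s";', name))
  if (!is.null(biotype) && !is.na(biotype))
    a <- paste0(a, sprintf(' gene_biotype "%s";', biotype))
  a
}

#' Write transcript models as GTF
#'
#' Emits one \code{exon} feature per exon, converting internal 0-based
#' half-open intervals back to 1-based inclusive GTF coordinates; the
#' round trip through [parse_gtf()] preserves exon coordinates exactly.
#' Models without a gene assignment reuse their own id as \code{gene_id}.
#'
#' @param models list of [transcript_model()] objects.
#' @param path output file.
#' @param source value for the GTF source column.
#' @export
write_models_gtf <- function(models, path, source = "isoscope") {
  lines <- unlist(lapply(models, function(m) {
    gid <- if (is.na(m$gene_id)) m$id else m$gene_id
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
            m$chrom, source, m$exons[, 1L] + 1L, m$exons[, 2L], m$strand,
            .gtf_attr(gid, m$id))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome annotation as GTF (exon + CDS features)
#'
#' @param annotation a \code{genome_annotation}.
#' @param path output file.
#' @param source value for the GTF source column.
#' @export
write_annotation_gtf <- function(annotation, path, source = "isoscope") {
  lines <- unlist(lapply(annotation$transcripts, function(m) {
    g <- annotation$genes[m$gene_id, ]
    attr_str <- .gtf_attr(m$gene_id, m$id, g$name, g$biotype)
    ex <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                  m$chrom, source, m$exons[, 1L] + 1L, m$exons[, 2L],
                  m$strand, attr_str)
    cd <- annotation$cds[[m$id]]
    if (!is.null(cd)) {
      frame <- if ("frame" %in% colnames(cd)) cd[, "frame"] else 0L
      ex <- c(ex, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                          m$chrom, source, cd[, "start"] + 1L, cd[, "end"],
                          m$strand, frame, attr_str))
    }
    ex
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
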