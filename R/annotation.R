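#' @importFrom GenomicRanges GRanges findOverlaps reduce start end seqnames strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

# GRanges from a 0-based half-open interval table (internal convention);
# IRanges is 1-based inclusive, hence the +1 on starts.
.intervals_to_gr <- function(chrom, start, end, strand = NULL) {
  if (is.null(strand)) strand <- "*"
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand = strand)
}

#' Build an indexed genome annotation from transcript models
#'
#' Shared constructor behind [parse_gtf()] and the synthetic-reference
#' generator. Indexes exons for overlap queries, collects the annotated
#' splice-site set per chromosome/strand, records per-transcript TSS and
#' polyA positions (strand-aware) and keeps CDS segments for coding
#' transcripts.
#'
#' @param transcripts list of [transcript_model()] objects, each with a
#'   non-missing \code{gene_id}.
#' @param gene_meta optional data.frame with columns \code{gene_id},
#'   \code{name}, \code{biotype}; genes absent from it get \code{NA} fields.
#' @param cds optional named list (by transcript id) of two/three-column
#'   matrices \code{start}, \code{end}(, \code{frame}) of CDS segments in
#'   0-based half-open coordinates.
#' @return a \code{genome_annotation} object.
#' @export
build_annotation <- function(transcripts, gene_meta = NULL, cds = NULL) {
  if (length(transcripts) == 0L) {
    return(structure(list(
      transcripts = list(), genes = data.frame(), gene_transcripts = list(),
      exon_table = data.frame(), exon_gr = GenomicRanges::GRanges(),
      gene_gr = GenomicRanges::GRanges(), chain_index = list(),
      junction_index = list(), gene_site_keys = list(),
      site_keys = character(0), junction_keys = character(0),
      tss = numeric(0), polya = numeric(0), cds = list()),
      class = "genome_annotation"))
  }
  ids <- vapply(transcripts, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicated transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  gene_ids <- vapply(transcripts, `[[`, "", "gene_id")
  if (anyNA(gene_ids))
    stop("every annotated transcript must carry a gene_id")

  exon_table <- do.call(rbind, lapply(transcripts, function(m) {
    data.frame(chrom = m$chrom, start = m$exons[, 1L], end = m$exons[, 2L],
               strand = m$strand, gene_id = m$gene_id, transcript_id = m$id,
               stringsAsFactors = FALSE)
  }))
  rownames(exon_table) <- NULL
  exon_gr <- .intervals_to_gr(exon_table$chrom, exon_table$start,
                              exon_table$end, exon_table$strand)

  gene_transcripts <- split(ids, gene_ids)
  span_df <- data.frame(
    gene_id = gene_ids,
    chrom = vapply(transcripts, `[[`, "", "chrom"),
    strand = vapply(transcripts, `[[`, "", "strand"),
    start = vapply(transcripts, function(m) m$span[["start"]], integer(1)),
    end = vapply(transcripts, function(m) m$span[["end"]], integer(1)),
    stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(split(span_df, span_df$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
               strand = d$strand[1L], start = min(d$start), end = max(d$end),
               n_transcripts = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- genes$gene_id
  genes$name <- genes$gene_id
  genes$biotype <- NA_character_
  if (!is.null(gene_meta)) {
    i <- match(genes$gene_id, gene_meta$gene_id)
    if ("name" %in% names(gene_meta)) genes$name <- ifelse(is.na(i), genes$name, gene_meta$name[i])
    if ("biotype" %in% names(gene_meta)) genes$biotype <- gene_meta$biotype[i]
  }
  gene_gr <- .intervals_to_gr(genes$chrom, genes$start, genes$end, genes$strand)
  S4Vectors::mcols(gene_gr)$gene_id <- genes$gene_id

  keys <- vapply(transcripts, function(m)
    paste(m$chrom, m$strand, chain_key(m), sep = "|"), "")
  multi <- vapply(transcripts, function(m) m$n_exons > 1L, TRUE)
  chain_index <- split(ids[multi], keys[multi])

  sk_per_tx <- lapply(transcripts, function(m)
    site_keys(m$chrom, m$strand, model_site_positions(m)))
  sk <- unlist(sk_per_tx, use.names = FALSE)
  jk_per_tx <- lapply(transcripts, function(m)
    junction_keys(m$chrom, m$strand, m$junctions[, 1L], m$junctions[, 2L]))
  jk <- unlist(jk_per_tx, use.names = FALSE)
  junction_index <- split(
    rep(ids, vapply(jk_per_tx, length, 0L)), jk)
  junction_index <- lapply(junction_index, unique)
  gene_site_keys <- lapply(gene_transcripts, function(txs)
    unique(unlist(sk_per_tx[txs], use.names = FALSE)))

  tss <- vapply(transcripts, model_tss, numeric(1))
  polya <- vapply(transcripts, model_polya, numeric(1))

  cds <- if (is.null(cds)) list() else cds[intersect(names(cds), ids)]

  structure(list(
    transcripts = transcripts, genes = genes,
    gene_transcripts = gene_transcripts,
    exon_table = exon_table, exon_gr = exon_gr, gene_gr = gene_gr,
    chain_index = chain_index,
    junction_index = junction_index, gene_site_keys = gene_site_keys,
    site_keys = unique(sk), junction_keys = unique(jk),
    tss = tss, polya = polya, cds = cds),
    class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d gene(s), %d transcript(s), %d exon(s), %d coding transcript(s)\n",
              nrow(x$genes), length(x$transcripts), nrow(x$exon_table),
              length(x$cds)))
  invisible(x)
}

#' Query annotated exons overlapping an interval
#'
#' Returns all annotated exons intersecting the 0-based half-open query
#' interval, optionally restricted to one strand.
#'
#' @param annotation a \code{genome_annotation}.
#' @param chrom,start,end query interval (0-based half-open).
#' @param strand optional strand filter (\code{"+"} or \code{"-"}).
#' @return the matching rows of the annotation's exon table.
#' @export
query_exons <- function(annotation, chrom, start, end, strand = NULL) {
  if (nrow(annotation$exon_table) == 0L ||
      !chrom %in% annotation$exon_table$chrom)
    return(annotation$exon_table[integer(0), , drop = FALSE])
  q <- .intervals_to_gr(chrom, start, end)
  hits <- GenomicRanges::findOverlaps(q, annotation$exon_gr, ignore.strand = TRUE)
  out <- annotation$exon_table[S4Vectors::subjectHits(hits), , drop = FALSE]
  if (!is.null(strand)) out <- out[out$strand == strand, , drop = FALSE]
  out
}

# gene ids whose span intersects [start, end); strand = NULL for either strand
.overlapping_genes <- function(annotation, chrom, start, end, strand = NULL) {
  if (length(annotation$gene_gr) == 0L ||
      !chrom %in% annotation$genes$chrom) return(character(0))
  q <- .intervals_to_gr(chrom, start, end, strand)
  hits <- GenomicRanges::findOverlaps(q, annotation$gene_gr,
                                      ignore.strand = is.null(strand))
  unique(annotation$genes$gene_id[S4Vectors::subjectHits(hits)])
}
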