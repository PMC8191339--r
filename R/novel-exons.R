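#' Transcript-order position class of an exon
#'
#' Whether the \code{exon_index}-th exon (in ascending genomic order) of a
#' model is the transcript's first, middle or last exon. Strand-aware: on
#' the minus strand the genomically last exon is transcript-first.
#'
#' @param model a multi-exon [transcript_model()].
#' @param exon_index 1-based index into the genomically sorted exon list.
#' @return \code{"first"}, \code{"middle"} or \code{"last"}.
#' @export
position_class <- function(model, exon_index) {
  if (model$n_exons < 2L)
    stop("position class is undefined for mono-exon models")
  if (exon_index < 1L || exon_index > model$n_exons)
    stop("exon_index out of range")
  genomic_first <- exon_index == 1L
  genomic_last <- exon_index == model$n_exons
  if (!genomic_first && !genomic_last) return("middle")
  if (model$strand == "-") {
    if (genomic_last) "first" else "last"
  } else {
    if (genomic_first) "first" else "last"
  }
}

# the splice junctions leading into an exon: one for a terminal exon, the
# two flanking introns for an internal one (genomic orientation)
.required_junctions <- function(model, exon_index) {
  j <- model$junctions
  idx <- c(if (exon_index > 1L) exon_index - 1L,
           if (exon_index < model$n_exons) exon_index)
  j[idx, , drop = FALSE]
}

#' Find unannotated exons in NNC isoforms
#'
#' A novel exon is an exon of an NNC isoform whose genomic location does
#' not overlap \emph{any} annotated exon at all, on either strand. Exons
#' are deduplicated by exact coordinates; all source isoforms (with the
#' exon's transcript position and flanking junctions in each) are
#' retained.
#'
#' @param nnc_records isoform records or models classified NNC.
#' @param annotation a \code{genome_annotation}.
#' @return data.frame with one row per distinct novel exon:
#'   \code{exon_id}, \code{chrom}, \code{start}, \code{end},
#'   \code{position_class} (of the first-encountered source),
#'   \code{n_sources}, \code{sources} (comma-joined isoform ids). The
#'   per-source detail (position class and required junctions per
#'   occurrence) is attached as the \code{"occurrences"} attribute and is
#'   consumed by [validate_with_junctions()].
#' @export
find_novel_exons <- function(nnc_records, annotation) {
  models <- lapply(nnc_records, function(r)
    if (is.list(r) && !is.null(r$model)) r$model else r)
  occ <- list()
  for (m in models) {
    for (k in seq_len(m$n_exons)) {
      hit <- query_exons(annotation, m$chrom, m$exons[k, 1L], m$exons[k, 2L])
      if (nrow(hit) > 0L) next
      rj <- .required_junctions(m, k)
      occ[[length(occ) + 1L]] <- data.frame(
        chrom = m$chrom, start = m$exons[k, 1L], end = m$exons[k, 2L],
        isoform_id = m$id, exon_index = k,
        position_class = position_class(m, k),
        junctions = paste(rj[, 1L], rj[, 2L], sep = "-", collapse = ";"),
        strand = m$strand, stringsAsFactors = FALSE)
    }
  }
  if (length(occ) == 0L) {
    out <- data.frame(exon_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      position_class = character(0), n_sources = integer(0),
                      sources = character(0), stringsAsFactors = FALSE)
    attr(out, "occurrences") <- do.call(rbind, occ)
    return(out)
  }
  occ <- do.call(rbind, occ)
  key <- paste(occ$chrom, occ$start, occ$end)
  occ$exon_key <- key
  firsts <- occ[!duplicated(key), , drop = FALSE]
  out <- data.frame(
    exon_id = sprintf("novel_exon_%04d", seq_len(nrow(firsts))),
    chrom = firsts$chrom, start = firsts$start, end = firsts$end,
    position_class = firsts$position_class,
    n_sources = as.integer(table(key)[firsts$exon_key]),
    sources = vapply(firsts$exon_key, function(k)
      paste(sort(occ$isoform_id[occ$exon_key == k]), collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  occ$exon_id <- out$exon_id[match(occ$exon_key, firsts$exon_key)]
  attr(out, "occurrences") <- occ
  out
}

#' Expected number of novel terminal exons under uniform placement
#'
#' If novel exons were distributed uniformly over all exons of all observed
#' isoforms, the expected number landing on a first (equivalently, last)
#' exon is \code{n_novel * n_isoforms / total_exons}, since every isoform
#' contributes exactly one first and one last exon.
#'
#' @param records isoform records or models (all observed isoforms).
#' @param n_novel number of novel exons found.
#' @return named numeric vector \code{expected_first},
#'   \code{expected_last} (equal by symmetry).
#' @export
expected_terminal_novel_exons <- function(records, n_novel) {
  models <- lapply(records, function(r)
    if (is.list(r) && !is.null(r$model)) r$model else r)
  n_iso <- length(models)
  total_exons <- sum(vapply(models, `[[`, 0L, "n_exons"))
  if (total_exons == 0L) stop("no exons among the supplied isoforms")
  e <- n_novel * n_iso / total_exons
  c(expected_first = e, expected_last = e)
}

#' Validate novel exons with short-read splice junctions
#'
#' An exon validates when every splice junction leading into it (one for a
#' first/last exon, the two flanking junctions for a middle exon) is
#' present in the short-read junction set. When the same exon occurs in
#' several isoforms at different transcript positions, each source's own
#' requirement is checked and the exon validates if any source's
#' requirement is fully met.
#'
#' @param novel_exons data.frame from [find_novel_exons()].
#' @param junctions a \code{junction_set}
#'   (see [read_short_read_junctions()]).
#' @param strand_aware require matching junction strands (default FALSE:
#'   nondirectional short-read libraries cannot assign one).
#' @return \code{novel_exons} with added columns \code{validated} and
#'   \code{supporting_counts} (comma-joined per-junction read counts of the
#'   first fully supported source, \code{""} otherwise).
#' @export
validate_with_junctions <- function(novel_exons, junctions,
                                    strand_aware = FALSE) {
  occ <- attr(novel_exons, "occurrences")
  novel_exons$validated <- FALSE
  novel_exons$supporting_counts <- ""
  if (is.null(occ) || nrow(novel_exons) == 0L) return(novel_exons)
  jkey <- if (nrow(junctions) == 0L) character(0) else
    paste(junctions$chrom,
          if (strand_aware) junctions$strand else "",
          junctions$start, junctions$end)
  counts <- stats::setNames(junctions$count, jkey)
  for (i in seq_len(nrow(novel_exons))) {
    oi <- occ[occ$exon_id == novel_exons$exon_id[i], , drop = FALSE]
    for (r in seq_len(nrow(oi))) {
      req <- do.call(rbind, lapply(strsplit(oi$junctions[r], ";")[[1L]],
                                   function(x) as.integer(strsplit(x, "-")[[1L]])))
      qk <- paste(oi$chrom[r], if (strand_aware) oi$strand[r] else "",
                  req[, 1L], req[, 2L])
      if (all(qk %in% jkey)) {
        novel_exons$validated[i] <- TRUE
        novel_exons$supporting_counts[i] <- paste(counts[qk], collapse = ",")
        break
      }
    }
  }
  novel_exons
}
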