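#' Isoform categories
#'
#' Multi-exon isoforms fall into FSM / ISM / NIC / NNC / intergenic /
#' genic_other; mono-exon isoforms are reported separately as
#' mono_exon_known / mono_exon_genic / intergenic and are never merged into
#' the splice-chain categories.
#' @export
ISOFORM_CATEGORIES <- c("FSM", "ISM", "NIC", "NNC", "mono_exon_known",
                        "mono_exon_genic", "genic_other", "intergenic")

#' Classify one isoform against the reference annotation
#'
#' SQANTI-style category assignment by splice-junction-chain comparison.
#' For a multi-exon model the decision cascade is:
#' \enumerate{
#'   \item \strong{FSM} if some same-strand reference transcript has an
#'     identical junction chain; among several the matched transcript is the
#'     one minimizing the summed 5'/3' end distances.
#'   \item else \strong{ISM} if the chain is a consecutive \emph{proper}
#'     sub-chain of some reference transcript's chain.
#'   \item else \strong{intergenic} if the model's span overlaps no
#'     annotated gene locus on either strand.
#'   \item else \strong{genic_other} if locus overlap exists only on the
#'     opposite strand and the model shares no same-strand annotated splice
#'     site.
#'   \item else \strong{NIC} if every splice site of the model is in the
#'     same-chromosome, same-strand annotated site set, \strong{NNC}
#'     otherwise (the unannotated sites are reported as
#'     \code{novel_sites}).
#' }
#' Mono-exon models: \code{mono_exon_known} when fully contained in one
#' annotated exon, \code{mono_exon_genic} when overlapping an annotated
#' locus, else \code{intergenic}.
#'
#' @param model a [transcript_model()].
#' @param annotation a \code{genome_annotation}.
#' @return a list with \code{isoform_id}, \code{category}, \code{gene_id},
#'   \code{matched_transcript}, \code{novel_sites} (data.frame of
#'   position/side, non-empty only for NNC) and, for FSM, the end distances
#'   \code{d5_matched}, \code{d3_matched}, \code{d5_gene_min},
#'   \code{d3_gene_min}.
#' @export
classify_isoform <- function(model, annotation) {
  res <- list(isoform_id = model$id, category = NA_character_,
              gene_id = NA_character_, matched_transcript = NA_character_,
              novel_sites = data.frame(position = integer(0),
                                       side = character(0)),
              d5_matched = NA_real_, d3_matched = NA_real_,
              d5_gene_min = NA_real_, d3_gene_min = NA_real_)

  if (model$n_exons == 1L) {
    ex <- query_exons(annotation, model$chrom, model$span[["start"]],
                      model$span[["end"]])
    contained <- nrow(ex) > 0L &&
      any(ex$start <= model$span[["start"]] & ex$end >= model$span[["end"]])
    any_locus <- length(.overlapping_genes(annotation, model$chrom,
                                           model$span[["start"]],
                                           model$span[["end"]])) > 0L
    res$category <- if (contained) "mono_exon_known"
                    else if (any_locus) "mono_exon_genic" else "intergenic"
    if (res$category != "intergenic")
      res$gene_id <- assign_gene(model, annotation)
    return(res)
  }

  key <- paste(model$chrom, model$strand, chain_key(model), sep = "|")
  fsm <- annotation$chain_index[[key]]
  if (!is.null(fsm) && length(fsm) > 0L) {
    res$category <- "FSM"
    res$matched_transcript <- .closest_end_match(model, fsm, annotation)
    res$gene_id <- annotation$transcripts[[res$matched_transcript]]$gene_id
    d <- end_distances_for(model, res$matched_transcript, res$gene_id, annotation)
    res[names(d)] <- d
    return(res)
  }

  ism <- .ism_matches(model, annotation)
  if (length(ism) > 0L) {
    res$category <- "ISM"
    res$matched_transcript <- .closest_end_match(model, ism, annotation)
    res$gene_id <- annotation$transcripts[[res$matched_transcript]]$gene_id
    return(res)
  }

  any_genes <- .overlapping_genes(annotation, model$chrom,
                                  model$span[["start"]], model$span[["end"]])
  if (length(any_genes) == 0L) {
    res$category <- "intergenic"
    return(res)
  }

  sk <- site_keys(model$chrom, model$strand, model_site_positions(model))
  annotated <- sk %in% annotation$site_keys
  same_strand_genes <- .overlapping_genes(annotation, model$chrom,
                                          model$span[["start"]],
                                          model$span[["end"]],
                                          strand = model$strand)
  if (length(same_strand_genes) == 0L && !any(annotated)) {
    res$category <- "genic_other"
    res$gene_id <- assign_gene(model, annotation)
    return(res)
  }

  if (all(annotated)) {
    res$category <- "NIC"
  } else {
    res$category <- "NNC"
    st <- junction_site_table(model)
    st_keys <- site_keys(model$chrom, model$strand, st$position)
    res$novel_sites <- st[!st_keys %in% annotation$site_keys, , drop = FALSE]
  }
  res$gene_id <- assign_gene(model, annotation)
  res
}

# reference transcripts whose chain contains the model chain as a
# consecutive *proper* sub-chain (same chrom and strand)
.ism_matches <- function(model, annotation) {
  jk <- junction_keys(model$chrom, model$strand,
                      model$junctions[, 1L], model$junctions[, 2L])
  candidates <- annotation$junction_index[[jk[1L]]]
  if (is.null(candidates)) return(character(0))
  nq <- nrow(model$junctions)
  hits <- vapply(candidates, function(tx_id) {
    tx <- annotation$transcripts[[tx_id]]
    nr <- nrow(tx$junctions)
    if (nr <= nq) return(FALSE)  # proper: the reference chain must be longer
    ref_jk <- junction_keys(tx$chrom, tx$strand,
                            tx$junctions[, 1L], tx$junctions[, 2L])
    starts <- which(ref_jk == jk[1L])
    any(vapply(starts, function(s)
      s + nq - 1L <= nr && all(ref_jk[s:(s + nq - 1L)] == jk), TRUE))
  }, TRUE)
  candidates[hits]
}

# among chain-matching transcripts pick the one with the closest ends
# (min d5 + d3), ties broken lexicographically for reproducibility
.closest_end_match <- function(model, tx_ids, annotation) {
  tx_ids <- sort(tx_ids)
  d <- vapply(tx_ids, function(t)
    abs(model_tss(model) - annotation$tss[[t]]) +
      abs(model_polya(model) - annotation$polya[[t]]), numeric(1))
  tx_ids[which.min(d)]
}

#' Assign an isoform to a gene
#'
#' The gene whose transcripts share the most splice sites with the model;
#' ties are broken by the largest exonic-overlap base count, then by
#' lexicographic gene id. Returns \code{NA} when the model shares no site
#' and overlaps no annotated exon or locus.
#'
#' @param model a [transcript_model()].
#' @param annotation a \code{genome_annotation}.
#' @return gene id or \code{NA_character_}.
#' @export
assign_gene <- function(model, annotation) {
  cand <- .overlapping_genes(annotation, model$chrom,
                             model$span[["start"]], model$span[["end"]])
  sk <- site_keys(model$chrom, model$strand, model_site_positions(model))
  if (length(sk) > 0L) {
    shares <- vapply(annotation$gene_site_keys, function(gs)
      sum(sk %in% gs), 0L)
    cand <- union(cand, names(shares)[shares > 0L])
  }
  if (length(cand) == 0L) return(NA_character_)
  n_shared <- vapply(cand, function(g)
    if (length(sk) == 0L) 0L else sum(sk %in% annotation$gene_site_keys[[g]]), 0L)
  overlap_bases <- vapply(cand, function(g) .exonic_overlap(model, g, annotation), 0)
  ord <- order(-n_shared, -overlap_bases, cand)
  best <- cand[ord[1L]]
  if (n_shared[ord[1L]] == 0L && overlap_bases[ord[1L]] == 0) {
    # span overlap only (e.g. fully intronic): still the overlapping locus
    return(best)
  }
  best
}

# bases of the model's exons covered by the gene's (reduced) exons
.exonic_overlap <- function(model, gene_id, annotation) {
  et <- annotation$exon_table
  ex <- et[et$gene_id == gene_id & et$chrom == model$chrom, , drop = FALSE]
  if (nrow(ex) == 0L) return(0)
  gene_ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
  model_ir <- IRanges::IRanges(model$exons[, 1L] + 1L, model$exons[, 2L])
  sum(IRanges::width(IRanges::intersect(gene_ir, model_ir)))
}

# strand-aware end distances of a model vs a matched transcript and vs all
# transcripts of a gene (minimum)
end_distances_for <- function(model, matched_tx, gene_id, annotation) {
  tss <- model_tss(model); pa <- model_polya(model)
  gene_txs <- annotation$gene_transcripts[[gene_id]]
  c(d5_matched = abs(tss - annotation$tss[[matched_tx]]),
    d3_matched = abs(pa - annotation$polya[[matched_tx]]),
    d5_gene_min = min(abs(tss - annotation$tss[gene_txs])),
    d3_gene_min = min(abs(pa - annotation$polya[gene_txs])))
}

#' End distances of an FSM isoform
#'
#' Distances (nt) between the isoform's strand-aware 5'/3' ends and (a) the
#' TSS/polyA site of its matched transcript, (b) the closest TSS/polyA site
#' over all transcripts of its assigned gene.
#'
#' @param classification result of [classify_isoform()] with category FSM.
#' @param model the corresponding [transcript_model()].
#' @param annotation a \code{genome_annotation}.
#' @return named numeric vector \code{d5_matched}, \code{d3_matched},
#'   \code{d5_gene_min}, \code{d3_gene_min}.
#' @export
end_distances <- function(classification, model, annotation) {
  if (!identical(classification$category, "FSM"))
    stop("end_distances is defined for FSM isoforms only (got ",
         classification$category, ")")
  end_distances_for(model, classification$matched_transcript,
                    classification$gene_id, annotation)
}

#' Classify a batch of isoforms
#'
#' @param records isoform records (see [read_isoform_models()]) or a list of
#'   [transcript_model()] objects.
#' @param annotation a \code{genome_annotation}.
#' @return data.frame with one row per isoform: id, category, assigned gene,
#'   matched transcript, FSM end distances, exon count and novel splice
#'   sites (as \code{"position:side"} comma-joined string, NNC only).
#' @export
classify_isoforms <- function(records, annotation) {
  models <- lapply(records, function(r)
    if (is.list(r) && !is.null(r$model)) r$model else r)
  rows <- lapply(models, function(m) {
    cl <- classify_isoform(m, annotation)
    data.frame(
      isoform_id = cl$isoform_id, category = cl$category,
      gene_id = cl$gene_id, matched_transcript = cl$matched_transcript,
      d5_matched = cl$d5_matched, d3_matched = cl$d3_matched,
      d5_gene_min = cl$d5_gene_min, d3_gene_min = cl$d3_gene_min,
      n_exons = m$n_exons,
      novel_sites = if (nrow(cl$novel_sites) == 0L) "" else
        paste(cl$novel_sites$position, cl$novel_sites$side,
              sep = ":", collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count FSM isoforms with distant transcript ends
#'
#' Number of FSM isoforms whose 5' (resp. 3') end lies strictly more than
#' \code{threshold} nt away from every annotated TSS (resp. polyA site) of
#' their gene.
#'
#' @param classifications data.frame from [classify_isoforms()].
#' @param threshold distance cutoff in nt (default 500).
#' @return named integer vector \code{n_distant_5prime},
#'   \code{n_distant_3prime}.
#' @export
count_distant_ends <- function(classifications, threshold = 500) {
  f <- classifications[classifications$category == "FSM", , drop = FALSE]
  c(n_distant_5prime = sum(f$d5_gene_min > threshold, na.rm = TRUE),
    n_distant_3prime = sum(f$d3_gene_min > threshold, na.rm = TRUE))
}

#' Discard minority isoforms at each locus
#'
#' Keeps an isoform only if its total read count (over all samples) is at
#' least \code{min_fraction} of the total reads of all isoforms assigned to
#' the same gene; isoforms below 1\% of their locus are discarded by
#' default. Genes with zero total reads keep all their isoforms. Isoforms
#' without a gene assignment form singleton groups and are always kept.
#'
#' @param records isoform records (see [read_isoform_models()]).
#' @param gene_ids named character vector isoform id -> gene id (e.g. from
#'   [classify_isoforms()]).
#' @param min_fraction minimum fraction of the locus reads (default 0.01).
#' @return the retained records (attributes preserved).
#' @export
filter_minority_isoforms <- function(records, gene_ids, min_fraction = 0.01) {
  totals <- vapply(records, function(r) sum(r$counts), numeric(1))
  ids <- names(records)
  grp <- gene_ids[ids]
  grp[is.na(grp)] <- paste0(".solo_", ids[is.na(grp)])
  gene_total <- tapply(totals, grp, sum)
  keep <- totals >= min_fraction * gene_total[grp]
  zero_genes <- names(gene_total)[gene_total == 0]
  if (length(zero_genes) > 0L) {
    message(length(zero_genes), " gene(s) with zero total reads: all their isoforms retained")
    keep[grp %in% zero_genes] <- TRUE
  }
  out <- records[keep]
  attr(out, "sample_map") <- attr(records, "sample_map")
  out
}

#' Cluster intergenic isoforms into loci
#'
#' Single-linkage clustering of intergenic isoforms by genomic span overlap
#' (strand-agnostic): two isoforms belong to the same locus when their
#' spans overlap, directly or through intermediates.
#'
#' @param records isoform records or [transcript_model()] list, already
#'   classified intergenic.
#' @param multiexon_only drop mono-exon isoforms before clustering.
#' @return data.frame with one row per locus: \code{locus_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{n_members},
#'   \code{members} (comma-joined isoform ids).
#' @export
cluster_intergenic_loci <- function(records, multiexon_only = FALSE) {
  models <- lapply(records, function(r)
    if (is.list(r) && !is.null(r$model)) r$model else r)
  if (multiexon_only)
    models <- models[vapply(models, function(m) m$n_exons > 1L, TRUE)]
  if (length(models) == 0L)
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_members = integer(0), members = character(0)))
  chrom <- vapply(models, `[[`, "", "chrom")
  start <- vapply(models, function(m) m$span[["start"]], integer(1))
  end <- vapply(models, function(m) m$span[["end"]], integer(1))
  gr <- .intervals_to_gr(chrom, start, end)
  # min.gapwidth = 0: merge only truly overlapping spans, not adjacent ones
  loci <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, loci, ignore.strand = TRUE)
  member_of <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  ids <- vapply(models, `[[`, "", "id")
  out <- do.call(rbind, lapply(seq_along(loci), function(i) {
    m <- ids[member_of == i]
    data.frame(locus_id = sprintf("locus_%04d", i),
               chrom = as.character(GenomicRanges::seqnames(loci)[i]),
               start = GenomicRanges::start(loci)[i] - 1L,
               end = GenomicRanges::end(loci)[i],
               n_members = length(m),
               members = paste(sort(m), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
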