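# Brute-force oracles, written from first principles and independent of the
# package's indexes: the classifier oracle enumerates every consecutive
# sub-chain of every reference transcript and the full annotated site set;
# the overlap oracle is a linear scan; the clustering oracle computes
# connected components of the pairwise overlap graph.

oracle_junctions <- function(exons) {
  exons <- unname(exons[order(exons[, 1]), , drop = FALSE])
  n <- nrow(exons)
  if (n < 2) return(matrix(numeric(0), ncol = 2))
  cbind(unname(exons[-n, 2]), unname(exons[-1, 1]))
}

# refs: list of list(id, gene_id, chrom, strand, exons)
oracle_classify <- function(chrom, strand, exons, refs) {
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  span <- c(min(exons[, 1]), max(exons[, 2]))
  gene_spans <- list()
  for (r in refs) {
    s <- c(min(r$exons[, 1]), max(r$exons[, 2]))
    g <- gene_spans[[r$gene_id]]
    gene_spans[[r$gene_id]] <- if (is.null(g))
      list(chrom = r$chrom, strand = r$strand, lo = s[1], hi = s[2])
    else list(chrom = g$chrom, strand = g$strand,
              lo = min(g$lo, s[1]), hi = max(g$hi, s[2]))
  }
  overlaps <- function(lo1, hi1, lo2, hi2) lo1 < hi2 && lo2 < hi1

  if (nrow(exons) == 1) {
    for (r in refs) {
      if (r$chrom != chrom) next
      for (k in seq_len(nrow(r$exons)))
        if (r$exons[k, 1] <= exons[1, 1] && r$exons[k, 2] >= exons[1, 2])
          return("mono_exon_known")
    }
    for (g in gene_spans)
      if (g$chrom == chrom && overlaps(span[1], span[2], g$lo, g$hi))
        return("mono_exon_genic")
    return("intergenic")
  }

  q <- oracle_junctions(exons)
  nq <- nrow(q)
  qs <- unname(apply(q, 1, paste, collapse = "-"))
  for (r in refs) {
    if (r$chrom != chrom || r$strand != strand) next
    rj <- oracle_junctions(r$exons)
    if (nrow(rj) == nq &&
        identical(unname(apply(rj, 1, paste, collapse = "-")), qs))
      return("FSM")
  }
  for (r in refs) {
    if (r$chrom != chrom || r$strand != strand) next
    rj <- oracle_junctions(r$exons)
    if (nrow(rj) <= nq) next
    rs <- unname(apply(rj, 1, paste, collapse = "-"))
    for (off in seq_len(nrow(rj) - nq + 1))
      if (identical(rs[off:(off + nq - 1)], qs)) return("ISM")
  }
  hit_any <- hit_same <- FALSE
  for (g in gene_spans) {
    if (g$chrom != chrom) next
    if (overlaps(span[1], span[2], g$lo, g$hi)) {
      hit_any <- TRUE
      if (g$strand == strand) hit_same <- TRUE
    }
  }
  if (!hit_any) return("intergenic")
  site_set <- character(0)
  for (r in refs) {
    if (r$chrom != chrom || r$strand != strand) next
    site_set <- c(site_set, as.character(oracle_junctions(r$exons)))
  }
  q_sites <- as.character(q)
  shared <- sum(q_sites %in% site_set)
  if (!hit_same && shared == 0) return("genic_other")
  if (all(q_sites %in% site_set)) "NIC" else "NNC"
}

# convert a genome_annotation to the oracle's plain reference list
annotation_to_refs <- function(annotation) {
  lapply(annotation$transcripts, function(m)
    list(id = m$id, gene_id = m$gene_id, chrom = m$chrom,
         strand = m$strand, exons = m$exons))
}

# linear-scan overlap query over an exon table
oracle_query_exons <- function(exon_table, chrom, start, end) {
  hit <- exon_table$chrom == chrom & exon_table$start < end &
    exon_table$end > start
  exon_table[hit, , drop = FALSE]
}

# connected components of the span-overlap graph (single linkage)
oracle_components <- function(spans) {
  n <- nrow(spans)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (spans$chrom[i] == spans$chrom[j] &&
          spans$start[i] < spans$end[j] && spans$start[j] < spans$end[i] &&
          comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}
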