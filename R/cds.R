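#' Reference peptides per gene
#'
#' For every coding reference transcript, splices its CDS segments
#' (strand-corrected, applying the GTF frame offset of the transcript-first
#' segment), translates with the standard genetic code, strips the terminal
#' stop and deduplicates peptides within each gene. A CDS whose length is
#' not divisible by three after the frame adjustment is translated up to
#' the last complete codon (with a warning).
#'
#' @param annotation a \code{genome_annotation} carrying CDS features.
#' @param genome \code{DNAStringSet} or FASTA path.
#' @return named list: gene id -> named character vector of peptides (names
#'   are the transcript ids the peptides come from).
#' @export
reference_peptides <- function(annotation, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  out <- list()
  for (tx_id in names(annotation$cds)) {
    m <- annotation$transcripts[[tx_id]]
    cd <- annotation$cds[[tx_id]]
    cd <- cd[order(cd[, "start"]), , drop = FALSE]
    cds_model <- transcript_model(paste0(tx_id, ".cds"), m$chrom, m$strand,
                                  cd[, c("start", "end"), drop = FALSE])
    nt <- spliced_sequence(cds_model, genome)
    frame_col <- if ("frame" %in% colnames(cd)) cd[, "frame"] else rep(0L, nrow(cd))
    offset <- if (m$strand == "-") frame_col[nrow(cd)] else frame_col[1L]
    nt <- Biostrings::subseq(nt, start = offset + 1L)
    extra <- length(nt) %% 3L
    if (extra != 0L) {
      warning("CDS of ", tx_id, " not divisible by 3; translated to last complete codon")
      nt <- Biostrings::subseq(nt, end = length(nt) - extra)
    }
    if (length(nt) == 0L) next
    pep <- .translate_nt(as.character(nt))
    pep <- sub("\\*$", "", pep)
    if (!nzchar(pep)) next
    g <- m$gene_id
    out[[g]] <- c(out[[g]], stats::setNames(pep, tx_id))
  }
  lapply(out, function(p) p[!duplicated(unname(p))])
}

#' Translate the three sense-strand reading frames
#'
#' Frames 0/1/2 of an already strand-corrected transcript sequence. Stop
#' codons are rendered \code{*} and translation continues through them;
#' codons containing \code{N} become \code{X}; trailing incomplete codons
#' are dropped. Reverse-strand frames are \emph{not} computed here — strand
#' is handled upstream by [spliced_sequence()].
#'
#' @param seq nucleotide sequence (character or \code{DNAString}) over
#'   \code{A,C,G,T,N}.
#' @return character vector of the three frame translations.
#' @export
translate_three_frames <- function(seq) {
  s <- toupper(as.character(seq))
  vapply(0:2, function(f) .translate_nt(substr(s, f + 1L, nchar(s))), "")
}

# standard-code translation by codon lookup; trailing partial codon is
# dropped, any codon outside the standard table (e.g. containing N) is X
.translate_nt <- function(s) {
  n <- nchar(s) %/% 3L
  if (n < 1L) return("")
  at <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(s, at, at + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Does an isoform contain a full annotated CDS of its gene?
#'
#' Translates the isoform's spliced sequence in three frames and searches
#' each translation for the reference peptides of the assigned gene
#' (substring match). Genes without CDS annotation yield a not-applicable
#' result that is excluded from containment-rate denominators.
#'
#' @param model a [transcript_model()].
#' @param classification the isoform's [classify_isoform()] result (a list
#'   or one-row data.frame; only \code{gene_id} is used).
#' @param annotation a \code{genome_annotation}.
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param peptides optional precomputed [reference_peptides()] map.
#' @param min_peptide_length peptides shorter than this many amino acids are
#'   ignored as degenerate (default 2).
#' @return list: \code{isoform_id}, \code{gene_id}, \code{multiexon},
#'   \code{applicable}, \code{contains_full_cds}, \code{matched_peptide_id},
#'   \code{frame}.
#' @export
contains_full_cds <- function(model, classification, annotation, genome,
                              peptides = NULL, min_peptide_length = 2L) {
  if (is.null(peptides)) peptides <- reference_peptides(annotation, genome)
  gene <- classification$gene_id
  res <- list(isoform_id = model$id, gene_id = gene,
              multiexon = model$n_exons > 1L, applicable = FALSE,
              contains_full_cds = NA, matched_peptide_id = NA_character_,
              frame = NA_integer_)
  if (is.na(gene) || is.null(peptides[[gene]])) return(res)
  peps <- peptides[[gene]]
  peps <- peps[nchar(peps) >= min_peptide_length]
  if (length(peps) == 0L) return(res)
  res$applicable <- TRUE
  res$contains_full_cds <- FALSE
  frames <- translate_three_frames(spliced_sequence(model, genome))
  for (i in seq_along(peps)) {
    for (f in 1:3) {
      if (grepl(peps[[i]], frames[f], fixed = TRUE)) {
        res$contains_full_cds <- TRUE
        res$matched_peptide_id <- names(peps)[i]
        res$frame <- f - 1L
        return(res)
      }
    }
  }
  res
}

#' CDS containment for a batch of isoforms
#'
#' @param records isoform records or [transcript_model()] list.
#' @param classifications data.frame from [classify_isoforms()].
#' @param annotation a \code{genome_annotation}.
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param min_peptide_length see [contains_full_cds()].
#' @return data.frame with one row per isoform (fields of
#'   [contains_full_cds()] plus \code{category}).
#' @export
cds_containment <- function(records, classifications, annotation, genome,
                            min_peptide_length = 2L) {
  if (is.character(genome)) genome <- read_genome(genome)
  peptides <- reference_peptides(annotation, genome)
  models <- lapply(records, function(r)
    if (is.list(r) && !is.null(r$model)) r$model else r)
  cls <- split(classifications, classifications$isoform_id)
  rows <- lapply(models, function(m) {
    cl <- cls[[m$id]]
    r <- contains_full_cds(m, as.list(cl), annotation, genome,
                           peptides = peptides,
                           min_peptide_length = min_peptide_length)
    data.frame(isoform_id = r$isoform_id, category = cl$category,
               gene_id = r$gene_id, multiexon = r$multiexon,
               applicable = r$applicable,
               contains_full_cds = r$contains_full_cds,
               matched_peptide_id = r$matched_peptide_id, frame = r$frame,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full-CDS containment rate per isoform category
#'
#' Fraction of isoforms containing a full CDS of their gene, computed per
#' category over multi-exon isoforms of coding genes only (the
#' denominator used for category comparisons).
#'
#' @param containment data.frame from [cds_containment()].
#' @return named numeric vector of rates, one per category present.
#' @export
containment_rates <- function(containment) {
  d <- containment[containment$applicable & containment$multiexon, , drop = FALSE]
  if (nrow(d) == 0L) return(stats::setNames(numeric(0), character(0)))
  vapply(split(d, d$category), function(x)
    mean(x$contains_full_cds), numeric(1))
}
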