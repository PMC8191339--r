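#' Load a genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions down to the sequence name.
#'
#' @param path FASTA file.
#' @return a \code{DNAStringSet} named by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Spliced transcript sequence of a model
#'
#' Concatenates the exon sequences in genomic order and reverse-complements
#' the whole result for minus-strand models, yielding the 5'->3' transcript
#' sequence. Length equals the summed exon lengths.
#'
#' @param model a [transcript_model()].
#' @param genome \code{DNAStringSet} (see [read_genome()]) or path to a
#'   FASTA file.
#' @return a \code{DNAString}.
#' @export
spliced_sequence <- function(model, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (!model$chrom %in% names(genome))
    stop("chromosome absent from FASTA: ", model$chrom,
         " (FASTA has: ", paste(names(genome), collapse = ", "), ")")
  chrom_seq <- genome[[model$chrom]]
  if (model$span[["end"]] > length(chrom_seq))
    stop("model '", model$id, "' extends past the end of ", model$chrom)
  parts <- Biostrings::extractAt(
    chrom_seq, IRanges::IRanges(model$exons[, 1L] + 1L, model$exons[, 2L]))
  s <- unlist(parts)
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}
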