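#' Construct a transcript model
#'
#' A transcript model is an exon chain on one chromosome and strand, the
#' shared representation for reference transcripts and observed isoforms.
#' Exons are stored as a two-column integer matrix of 0-based half-open
#' intervals sorted by start; the splice-junction chain (introns) is derived.
#'
#' @param id transcript/isoform identifier.
#' @param chrom chromosome name.
#' @param strand one of \code{"+"}, \code{"-"} or \code{"*"} (unstranded).
#' @param exons two-column matrix or data.frame of exon \code{start}/\code{end}
#'   (0-based, half-open). Rows may be unsorted; they are sorted by start.
#' @param gene_id optional gene the model belongs to (\code{NA} if unknown).
#' @return an object of class \code{transcript_model} with fields \code{id},
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{exons},
#'   \code{junctions} (an \code{(n_exons - 1) x 2} matrix of intron
#'   start/end), \code{span} (length-2 vector) and \code{n_exons}.
#' @examples
#' m <- transcript_model("t1", "chr1", "+", rbind(c(100, 200), c(300, 400)))
#' m$junctions  # one intron: (200, 300)
#' @export
transcript_model <- function(id, chrom, strand, exons, gene_id = NA_character_) {
  stopifnot(length(id) == 1L, length(chrom) == 1L)
  if (!strand %in% c("+", "-", "*"))
    stop("strand must be '+', '-' or '*', got: ", strand)
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L || nrow(exons) < 1L)
    stop("exons must be a matrix with >= 1 row and 2 columns")
  storage.mode(exons) <- "integer"
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  dimnames(exons) <- list(NULL, c("start", "end"))
  if (any(exons[, 1L] < 0L) || any(exons[, 2L] <= exons[, 1L]))
    stop("transcript '", id, "': exon with end <= start or negative start")
  n <- nrow(exons)
  if (n > 1L && any(exons[-n, 2L] >= exons[-1L, 1L]))
    stop("transcript '", id, "': exons overlap or are not separated by a gap")
  junctions <- if (n > 1L) {
    cbind(start = unname(exons[-n, 2L]), end = unname(exons[-1L, 1L]))
  } else {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  structure(
    list(id = as.character(id), gene_id = as.character(gene_id),
         chrom = as.character(chrom), strand = strand,
         exons = exons, junctions = junctions,
         span = c(start = unname(exons[1L, 1L]), end = unname(exons[n, 2L])),
         n_exons = n),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s] %d exon(s)\n",
              x$id, ifelse(is.na(x$gene_id), "-", x$gene_id),
              x$chrom, x$span[["start"]], x$span[["end"]], x$strand, x$n_exons))
  invisible(x)
}

# strand-aware transcript ends: the 5' end is span end on '-'
model_tss <- function(model) {
  if (model$strand == "-") model$span[["end"]] else model$span[["start"]]
}

model_polya <- function(model) {
  if (model$strand == "-") model$span[["start"]] else model$span[["end"]]
}

# the two splice sites of every junction with their donor/acceptor side
# (transcript 5'->3' sense: on the minus strand the donor is the higher
# coordinate, i.e. the intron end boundary)
junction_site_table <- function(model) {
  j <- model$junctions
  if (nrow(j) == 0L)
    return(data.frame(position = integer(0), side = character(0)))
  if (model$strand == "-") {
    data.frame(position = c(j[, "end"], j[, "start"]),
               side = rep(c("donor", "acceptor"), each = nrow(j)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(position = c(j[, "start"], j[, "end"]),
               side = rep(c("donor", "acceptor"), each = nrow(j)),
               stringsAsFactors = FALSE)
  }
}

# splice-site positions (both boundaries of every intron) of a model
model_site_positions <- function(model) {
  as.integer(model$junctions)
}

# string key of a junction chain, used for exact FSM matching
chain_key <- function(model) {
  paste(paste(model$junctions[, 1L], model$junctions[, 2L], sep = "-"),
        collapse = ";")
}

site_keys <- function(chrom, strand, positions) {
  if (length(positions) == 0L) return(character(0))
  paste(chrom, strand, positions, sep = "|")
}

junction_keys <- function(chrom, strand, starts, ends) {
  if (length(starts) == 0L) return(character(0))
  paste(chrom, strand, starts, ends, sep = "|")
}
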