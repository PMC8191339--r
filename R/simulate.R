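#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults that
#' emulate the study design the pipeline targets: multi-isoform genes on
#' both strands, observed isoforms of every category with known truth,
#' five stimulation conditions with two replicates each, shared-usage null
#' counts from a Dirichlet-multinomial with injected usage switches, and a
#' short-read junction file with controllable dropout.
#'
#' @param seed master seed; stage sub-seeds are derived from it so stages
#'   can be rerun independently.
#' @param n_chromosomes,chromosome_length genome shape (bp).
#' @param n_genes genes placed over the genome, both strands, non-overlapping.
#' @param transcripts_per_gene,exons_per_transcript inclusive integer ranges.
#' @param exon_length,intron_length,intergenic_gap inclusive bp ranges.
#' @param category_mix named fractions of observed isoforms per category
#'   (FSM, ISM, NIC, NNC, intergenic); must sum to 1.
#' @param n_isoforms number of observed isoforms to emit.
#' @param fsm_end_jitter bp range of FSM end jitter; with probability
#'   \code{fsm_far_jitter_prob} the jitter is drawn from
#'   \code{fsm_far_jitter} instead, producing ends > 500 nt from any
#'   annotated TSS/polyA site.
#' @param nnc_novel_exon_prob fraction of NNC isoforms carrying an injected
#'   intron-interior novel exon (the rest get a +-5..50 nt splice-site
#'   shift); \code{novel_exon_length} is its bp range.
#' @param n_conditions,n_replicates experimental layout.
#' @param reads_per_condition mean reads per gene per condition;
#'   \code{reads_distribution} is \code{"poisson"} or \code{"fixed"}.
#' @param dirichlet_concentration symmetric Dirichlet concentration of the
#'   shared-usage null.
#' @param switch_fraction fraction of multi-isoform genes given a usage
#'   switch: the two most-used isoforms swap proportions in the second half
#'   of the conditions. \code{switch_usage} optionally pins the base usage
#'   vector (e.g. \code{c(0.8, 0.2)}) for genes with matching isoform count.
#' @param junction_dropout probability that a junction is missing from the
#'   emitted short-read junction file.
#' @param min_cds_codons minimum CDS length (codons, incl. start, excl. stop).
#' @param utr5_max cap (nt) on the 5' UTR preceding the planted CDS; the UTR
#'   is the smaller of this and a fifth of the transcript length.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 42L,
                       n_chromosomes = 2L, chromosome_length = 300000L,
                       n_genes = 30L,
                       transcripts_per_gene = c(1L, 3L),
                       exons_per_transcript = c(4L, 8L),
                       exon_length = c(80L, 300L),
                       intron_length = c(150L, 1000L),
                       intergenic_gap = c(2000L, 6000L),
                       category_mix = c(FSM = 0.4, ISM = 0.15, NIC = 0.2,
                                        NNC = 0.15, intergenic = 0.1),
                       n_isoforms = 500L,
                       fsm_end_jitter = c(0L, 100L),
                       fsm_far_jitter_prob = 0.05,
                       fsm_far_jitter = c(600L, 1500L),
                       nnc_novel_exon_prob = 0.5,
                       novel_exon_length = c(80L, 150L),
                       n_conditions = 5L, n_replicates = 2L,
                       reads_per_condition = 100,
                       reads_distribution = c("poisson", "fixed"),
                       dirichlet_concentration = 2,
                       switch_fraction = 0.1,
                       switch_usage = NULL,
                       junction_dropout = 0.1,
                       min_cds_codons = 40L,
                       utr5_max = 150L) {
  reads_distribution <- match.arg(reads_distribution)
  if (abs(sum(category_mix) - 1) > 1e-9) stop("category_mix must sum to 1")
  if (any(category_mix < 0) || any(category_mix > 1))
    stop("category_mix fractions must lie in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# sample one element of x (guarding R's sample() scalar expansion)
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

.runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

.rdirichlet <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

# codons of the standard code without the three stops
.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Generate a synthetic reference genome and annotation
#'
#' Random genome plus non-overlapping genes on both strands; each gene has
#' one primary transcript and up to \code{transcripts_per_gene} variants
#' (exon skips, terminal truncations, alternative internal boundaries) with
#' distinct junction chains. The primary transcript carries a CDS (length
#' divisible by three, ATG start, single terminal stop, no internal stops)
#' whose codons are written into the genome sequence. Deterministic under a
#' fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with \code{genome} (\code{DNAStringSet}),
#'   \code{annotation} (\code{genome_annotation}) and \code{config}.
#' @export
generate_reference <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genome_chars <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), config$chromosome_length, replace = TRUE))
  names(genome_chars) <- chroms

  transcripts <- list()
  cds <- list()
  genes_left <- config$n_genes
  gi <- 0L
  max_exons <- config$exons_per_transcript[2L]
  max_gene_len <- max_exons * config$exon_length[2L] +
    (max_exons - 1L) * config$intron_length[2L]

  for (ch in chroms) {
    pos <- .runif_int(1L, config$intergenic_gap)
    while (genes_left > 0L &&
           pos + max_gene_len + config$intergenic_gap[2L] < config$chromosome_length) {
      gi <- gi + 1L
      gene_id <- sprintf("gene_%03d", gi)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- .runif_int(1L, config$exons_per_transcript)
      ex_len <- .runif_int(n_ex, config$exon_length)
      in_len <- .runif_int(max(n_ex - 1L, 0L), config$intron_length)
      starts <- pos + cumsum(c(0L, ex_len[-n_ex] + in_len))
      exons <- cbind(starts, starts + ex_len)
      primary_id <- paste0(gene_id, ".t1")
      primary <- transcript_model(primary_id, ch, strand, exons,
                                  gene_id = gene_id)
      gene_txs <- list(primary)
      chains <- chain_key(primary)

      n_extra <- .runif_int(1L, config$transcripts_per_gene) - 1L
      ti <- 1L
      for (k in seq_len(n_extra)) {
        v <- .variant_transcript(primary, config)
        if (is.null(v)) next
        vk <- chain_key(v)
        if (vk %in% chains) next
        ti <- ti + 1L
        gene_txs[[length(gene_txs) + 1L]] <-
          transcript_model(paste0(gene_id, ".t", ti), ch, strand, v$exons,
                           gene_id = gene_id)
        chains <- c(chains, vk)
      }
      transcripts <- c(transcripts, gene_txs)

      cds_info <- .plant_cds(primary, genome_chars[[ch]], config)
      genome_chars[[ch]] <- cds_info$chrom_chars
      cds[[primary_id]] <- cds_info$cds

      genes_left <- genes_left - 1L
      pos <- max(exons[, 2L]) + .runif_int(1L, config$intergenic_gap)
    }
  }
  if (genes_left > 0L)
    stop("could not place all genes; increase chromosome_length or n_chromosomes")

  genome <- Biostrings::DNAStringSet(
    vapply(genome_chars, paste, "", collapse = ""))
  names(genome) <- chroms
  gene_ids <- unique(vapply(transcripts, `[[`, "", "gene_id"))
  annotation <- build_annotation(
    transcripts,
    gene_meta = data.frame(gene_id = gene_ids,
                           name = toupper(gene_ids),
                           biotype = "protein_coding",
                           stringsAsFactors = FALSE),
    cds = cds)
  list(genome = genome, annotation = annotation, config = config)
}

# a structurally distinct sibling transcript of the primary model
.variant_transcript <- function(primary, config) {
  ex <- primary$exons
  n <- nrow(ex)
  op <- sample(c("skip", "truncate", "alt_boundary"), 1L)
  if (op == "skip" && n >= 4L) {
    k <- .sample1(2:(n - 1L))
    ex2 <- ex[-k, , drop = FALSE]
  } else if (op == "truncate" && n >= 4L) {
    if (stats::runif(1) < 0.5) ex2 <- ex[-1L, , drop = FALSE]
    else ex2 <- ex[-n, , drop = FALSE]
  } else if (n >= 3L) {
    k <- .sample1(2:(n - 1L))
    shift <- sample(c(-1L, 1L), 1L) * .runif_int(1L, c(15L, 45L))
    ex2 <- ex
    side <- sample(c("start", "end"), 1L)
    if (side == "start") {
      ns <- ex2[k, 1L] + shift
      if (ns <= ex2[k - 1L, 2L] + 10L || ns >= ex2[k, 2L] - 10L) return(NULL)
      ex2[k, 1L] <- ns
    } else {
      ne <- ex2[k, 2L] + shift
      if (ne <= ex2[k, 1L] + 10L || ne >= ex2[k + 1L, 1L] - 10L) return(NULL)
      ex2[k, 2L] <- ne
    }
  } else {
    return(NULL)
  }
  transcript_model(paste0(primary$id, ".tmp"), primary$chrom, primary$strand,
                   ex2, gene_id = primary$gene_id)
}

# write a valid CDS (ATG ... stop, no internal stops) into the chromosome
# along the primary transcript and return its genomic segments with frames
.plant_cds <- function(primary, chrom_chars, config) {
  # transcript-order genomic positions (1-based into chrom_chars)
  pos <- unlist(lapply(seq_len(primary$n_exons), function(i)
    seq.int(primary$exons[i, 1L] + 1L, primary$exons[i, 2L])))
  if (primary$strand == "-") pos <- rev(pos)
  tx_len <- length(pos)
  utr5 <- min(config$utr5_max, tx_len %/% 5L)
  max_codons <- (tx_len - utr5 - 3L) %/% 3L - 2L
  n_codons <- min(max(config$min_cds_codons, 10L), max_codons)
  if (n_codons < 4L) stop("transcript too short to host a CDS")
  codons <- c("ATG", sample(.SENSE_CODONS, n_codons - 1L, replace = TRUE),
              sample(c("TAA", "TAG", "TGA"), 1L))
  nt <- strsplit(paste(codons, collapse = ""), "")[[1L]]
  cds_pos <- pos[(utr5 + 1L):(utr5 + length(nt))]
  if (primary$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    chrom_chars[cds_pos] <- comp[nt]
  } else {
    chrom_chars[cds_pos] <- nt
  }
  # genomic CDS segments (0-based half-open) with per-segment frame
  ord <- sort(cds_pos)
  breaks <- c(0L, which(diff(ord) > 1L), length(ord))
  segs <- do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(i) {
    s <- ord[breaks[i] + 1L]; e <- ord[breaks[i + 1L]]
    c(start = s - 1L, end = e)
  }))
  # frame: bases of preceding segments modulo 3, in transcript order
  seg_order <- if (primary$strand == "-") rev(seq_len(nrow(segs))) else seq_len(nrow(segs))
  lens <- segs[seg_order, "end"] - segs[seg_order, "start"]
  frames_tx <- c(0L, cumsum(lens)[-length(lens)]) %% 3L
  frames_tx <- (3L - frames_tx) %% 3L  # GTF phase: bases to skip to reach a codon start
  frames <- integer(nrow(segs))
  frames[seg_order] <- frames_tx
  list(chrom_chars = chrom_chars,
       cds = cbind(segs, frame = frames))
}

#' Generate observed isoforms of every category with known truth
#'
#' Emits isoform models by perturbing reference transcripts so that the
#' true category is known by construction: FSM are copies with end jitter;
#' ISM are consecutive proper sub-chains; NIC recombine annotated splice
#' sites (exon skips) into chains matching no transcript; NNC shift a
#' splice site into unannotated positions or carry an injected
#' intron-interior novel exon; intergenic isoforms are multi-exon models
#' placed in annotation gaps. Constructions that would collide with an
#' existing chain (e.g. an exon skip reproducing another transcript) are
#' rejected and resampled.
#'
#' @param reference output of [generate_reference()].
#' @param config a [sim_config()]; defaults to the reference's.
#' @return list with \code{models} (named list of [transcript_model()]),
#'   \code{truth} (data.frame isoform_id, true_category, true_gene) and
#'   \code{novel_exons} (data.frame of injected exon coordinates).
#' @export
generate_observed_isoforms <- function(reference, config = reference$config) {
  set.seed(config$seed + 2L)
  ann <- reference$annotation
  mix <- config$category_mix
  n <- config$n_isoforms
  n_per <- floor(mix * n)
  rem <- n - sum(n_per)
  if (rem > 0L) {
    bump <- order(mix * n - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[bump] <- n_per[bump] + 1L
  }
  cats <- sample(rep(names(mix), n_per))
  models <- vector("list", n)
  truth <- data.frame(isoform_id = sprintf("iso_%04d", seq_len(n)),
                      true_category = cats,
                      true_gene = NA_character_,
                      stringsAsFactors = FALSE)
  novel_exons <- list()
  tx_ids <- names(ann$transcripts)
  multi3 <- tx_ids[vapply(ann$transcripts, function(t) t$n_exons >= 3L, TRUE)]

  for (i in seq_len(n)) {
    id <- truth$isoform_id[i]
    made <- NULL
    for (try in 1:50) {
      made <- switch(cats[i],
        FSM = .make_fsm(id, ann, config),
        ISM = .make_ism(id, ann, multi3, config),
        NIC = .make_nic(id, ann, multi3, config),
        NNC = .make_nnc(id, ann, config),
        intergenic = .make_intergenic(id, ann, config))
      if (!is.null(made)) break
    }
    if (is.null(made))
      stop("failed to construct a ", cats[i], " isoform after 50 tries")
    models[[i]] <- made$model
    truth$true_gene[i] <- made$gene
    if (!is.null(made$novel_exon))
      novel_exons[[length(novel_exons) + 1L]] <-
        cbind(made$novel_exon, isoform_id = id)
  }
  names(models) <- truth$isoform_id
  novel_exons <- if (length(novel_exons) > 0L) {
    ne <- do.call(rbind, novel_exons)
    rownames(ne) <- NULL
    ne
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               isoform_id = character(0))
  }
  list(models = models, truth = truth, novel_exons = novel_exons)
}

.make_fsm <- function(id, ann, config) {
  tx <- ann$transcripts[[sample(names(ann$transcripts), 1L)]]
  ex <- tx$exons
  n <- nrow(ex)
  jit <- function() {
    far <- stats::runif(1) < config$fsm_far_jitter_prob
    d <- .runif_int(1L, if (far) config$fsm_far_jitter else config$fsm_end_jitter)
    sample(c(-1L, 1L), 1L) * d
  }
  ns <- ex[1L, 1L] + jit()
  ne <- ex[n, 2L] + jit()
  ex[1L, 1L] <- max(0L, min(ns, ex[1L, 2L] - 20L))
  ex[n, 2L] <- min(config$chromosome_length,
                   max(ex[n, 1L] + 20L, ne))
  list(model = transcript_model(id, tx$chrom, tx$strand, ex),
       gene = tx$gene_id)
}

.make_ism <- function(id, ann, multi3, config) {
  if (length(multi3) == 0L) return(NULL)
  tx <- ann$transcripts[[sample(multi3, 1L)]]
  L <- nrow(tx$junctions)
  if (L < 2L) return(NULL)
  len <- sample(seq_len(L - 1L), 1L)
  i <- sample(seq_len(L - len + 1L), 1L)
  j <- i + len - 1L
  ex <- tx$exons[i:(j + 1L), , drop = FALSE]
  ex[1L, 1L] <- ex[1L, 1L] + .runif_int(1L, c(0L, max(0L, ex[1L, 2L] - ex[1L, 1L] - 25L)))
  k <- nrow(ex)
  ex[k, 2L] <- ex[k, 2L] - .runif_int(1L, c(0L, max(0L, ex[k, 2L] - ex[k, 1L] - 25L)))
  m <- transcript_model(id, tx$chrom, tx$strand, ex)
  key <- paste(m$chrom, m$strand, chain_key(m), sep = "|")
  if (!is.null(ann$chain_index[[key]])) return(NULL)  # full chain of another tx
  list(model = m, gene = tx$gene_id)
}

.make_nic <- function(id, ann, multi3, config) {
  if (length(multi3) == 0L) return(NULL)
  tx <- ann$transcripts[[.sample1(multi3)]]
  n <- nrow(tx$exons)
  k <- .sample1(2:(n - 1L))
  ex <- tx$exons[-k, , drop = FALSE]
  m <- transcript_model(id, tx$chrom, tx$strand, ex)
  key <- paste(m$chrom, m$strand, chain_key(m), sep = "|")
  if (!is.null(ann$chain_index[[key]])) return(NULL)
  if (length(.ism_matches(m, ann)) > 0L) return(NULL)
  list(model = m, gene = tx$gene_id)
}

.make_nnc <- function(id, ann, config) {
  tx_ids <- names(ann$transcripts)
  tx <- ann$transcripts[[sample(tx_ids, 1L)]]
  if (tx$n_exons < 2L) return(NULL)
  if (stats::runif(1) < config$nnc_novel_exon_prob) {
    # inject an exon wholly inside an intron, clear of all annotated exons
    len <- .runif_int(1L, config$novel_exon_length)
    introns <- tx$junctions
    ok <- which(introns[, 2L] - introns[, 1L] >= len + 80L)
    if (length(ok) == 0L) return(NULL)
    jidx <- if (length(ok) == 1L) ok else sample(ok, 1L)
    lo <- introns[jidx, 1L] + 30L
    hi <- introns[jidx, 2L] - 30L - len
    if (hi < lo) return(NULL)
    st <- .runif_int(1L, c(lo, hi))
    if (nrow(query_exons(ann, tx$chrom, st, st + len)) > 0L) return(NULL)
    new_sites <- site_keys(tx$chrom, tx$strand, c(st, st + len))
    if (any(new_sites %in% ann$site_keys)) return(NULL)
    ex <- rbind(tx$exons[seq_len(jidx), , drop = FALSE],
                c(st, st + len),
                tx$exons[(jidx + 1L):tx$n_exons, , drop = FALSE])
    m <- transcript_model(id, tx$chrom, tx$strand, ex)
    list(model = m, gene = tx$gene_id,
         novel_exon = data.frame(chrom = tx$chrom, start = st, end = st + len,
                                 stringsAsFactors = FALSE))
  } else {
    # shift one splice site by 5..50 nt into an unannotated position
    ex <- tx$exons
    jidx <- sample(seq_len(tx$n_exons - 1L), 1L)
    delta <- sample(c(-1L, 1L), 1L) * .runif_int(1L, c(5L, 50L))
    side <- sample(c("donor_side", "acceptor_side"), 1L)
    if (side == "donor_side") {
      np <- ex[jidx, 2L] + delta
      if (np <= ex[jidx, 1L] + 10L || np >= ex[jidx + 1L, 1L] - 10L) return(NULL)
      if (site_keys(tx$chrom, tx$strand, np) %in% ann$site_keys) return(NULL)
      ex[jidx, 2L] <- np
    } else {
      np <- ex[jidx + 1L, 1L] + delta
      if (np <= ex[jidx, 2L] + 10L || np >= ex[jidx + 1L, 2L] - 10L) return(NULL)
      if (site_keys(tx$chrom, tx$strand, np) %in% ann$site_keys) return(NULL)
      ex[jidx + 1L, 1L] <- np
    }
    m <- transcript_model(id, tx$chrom, tx$strand, ex)
    list(model = m, gene = tx$gene_id)
  }
}

.make_intergenic <- function(id, ann, config) {
  genes <- ann$genes
  chrom <- sample(unique(genes$chrom), 1L)
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  bounds <- cbind(c(0L, g$end), c(g$start, config$chromosome_length))
  margin <- 200L
  need <- 3L * 200L + 2L * 300L + 2L * margin
  ok <- which(bounds[, 2L] - bounds[, 1L] >= need)
  if (length(ok) == 0L) return(NULL)
  b <- bounds[if (length(ok) == 1L) ok else sample(ok, 1L), ]
  n_ex <- sample(2:3, 1L)
  ex_len <- .runif_int(n_ex, c(80L, 200L))
  in_len <- .runif_int(n_ex - 1L, c(100L, 300L))
  total <- sum(ex_len) + sum(in_len)
  lo <- b[1L] + margin
  hi <- b[2L] - margin - total
  if (hi < lo) return(NULL)
  st <- .runif_int(1L, c(lo, hi))
  starts <- st + cumsum(c(0L, ex_len[-n_ex] + in_len))
  ex <- cbind(starts, starts + ex_len)
  m <- transcript_model(id, chrom, sample(c("+", "-"), 1L), ex)
  if (length(.overlapping_genes(ann, chrom, m$span[["start"]],
                                m$span[["end"]])) > 0L) return(NULL)
  list(model = m, gene = NA_character_)
}

#' Simulate per-gene isoform usage count matrices
#'
#' The statistical core of the count simulation, usable standalone (e.g.
#' for error-rate calibration): per gene, a usage vector is drawn from a
#' symmetric Dirichlet and shared by all conditions under the null; switch
#' genes swap the proportions of their two most-used isoforms in the
#' second half of the conditions; per condition, counts are multinomial.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer, or inclusive range, of isoforms per gene.
#' @param n_conditions number of conditions.
#' @param reads_per_condition reads per gene per condition.
#' @param concentration symmetric Dirichlet concentration.
#' @param n_switch number of switch genes (the first \code{n_switch} genes).
#' @param switch_usage optional explicit base usage vector for switch genes
#'   (length must equal their isoform count), e.g. \code{c(0.8, 0.2)}.
#' @param reads_distribution \code{"fixed"} or \code{"poisson"}.
#' @param seed optional seed; when \code{NULL} the current RNG stream is used.
#' @return list with \code{counts} (named list of isoform x condition
#'   matrices) and \code{truth} (data.frame gene_id, switch; plus usage
#'   vectors as the \code{"usage"} attribute).
#' @export
simulate_usage_counts <- function(n_genes, isoforms_per_gene = 3L,
                                  n_conditions = 4L,
                                  reads_per_condition = 100,
                                  concentration = 2,
                                  n_switch = 0L, switch_usage = NULL,
                                  reads_distribution = c("fixed", "poisson"),
                                  seed = NULL) {
  reads_distribution <- match.arg(reads_distribution)
  if (!is.null(seed)) set.seed(seed)
  if (length(isoforms_per_gene) == 1L)
    isoforms_per_gene <- rep(isoforms_per_gene, 2L)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  cond <- paste0("cond", seq_len(n_conditions))
  swapped_conds <- seq_len(n_conditions) > n_conditions / 2
  usage <- vector("list", n_genes)
  counts <- vector("list", n_genes)
  is_switch <- seq_len(n_genes) <= n_switch
  for (g in seq_len(n_genes)) {
    k <- .runif_int(1L, isoforms_per_gene)
    p <- if (is_switch[g] && !is.null(switch_usage) && length(switch_usage) == k)
      switch_usage else .rdirichlet(k, concentration)
    pmat <- matrix(rep(p, n_conditions), nrow = k)
    if (is_switch[g] && k >= 2L) {
      top2 <- order(p, decreasing = TRUE)[1:2]
      p2 <- p; p2[top2] <- p[rev(top2)]
      pmat[, swapped_conds] <- p2
    }
    m <- matrix(0L, nrow = k, ncol = n_conditions,
                dimnames = list(sprintf("%s.iso%d", gene_ids[g], seq_len(k)),
                                cond))
    for (cc in seq_len(n_conditions)) {
      nreads <- if (reads_distribution == "poisson")
        stats::rpois(1L, reads_per_condition) else round(reads_per_condition)
      if (nreads > 0L) m[, cc] <- stats::rmultinom(1L, nreads, pmat[, cc])
    }
    usage[[g]] <- pmat
    counts[[g]] <- m
  }
  names(counts) <- gene_ids
  names(usage) <- gene_ids
  truth <- data.frame(gene_id = gene_ids, switch = is_switch,
                      stringsAsFactors = FALSE)
  attr(truth, "usage") <- usage
  list(counts = counts, truth = truth)
}

#' Simulate read counts and expression for observed isoforms
#'
#' Groups observed isoforms by their true gene (intergenic isoforms form
#' singleton loci), draws usage and counts per condition via
#' [simulate_usage_counts()] semantics, splits condition counts over
#' replicates, and derives a gene x sample RPM table from the gene totals.
#'
#' @param observed output of [generate_observed_isoforms()].
#' @param config a [sim_config()].
#' @return list with \code{counts} (isoform x sample matrix),
#'   \code{sample_map} (data.frame), \code{rpm} (gene x sample RPM
#'   data.frame) and \code{truth} (data.frame gene_id, switch, with usage
#'   vectors attached).
#' @export
simulate_counts <- function(observed, config) {
  set.seed(config$seed + 3L)
  grp_gene <- observed$truth$true_gene
  solo <- is.na(grp_gene)
  grp_gene[solo] <- observed$truth$isoform_id[solo]
  groups <- split(observed$truth$isoform_id, grp_gene)

  cond <- paste0("cond", seq_len(config$n_conditions))
  samples <- as.vector(t(outer(cond, seq_len(config$n_replicates),
                               function(c, r) paste0(c, "_rep", r))))
  sample_map <- data.frame(
    sample = samples,
    condition = rep(cond, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), times = config$n_conditions),
    include_flag = TRUE, stringsAsFactors = FALSE)

  gene_ids <- names(groups)
  multi <- vapply(groups, function(x) length(x) >= 2L, TRUE)
  n_switch <- round(config$switch_fraction * sum(multi))
  switch_genes <- if (n_switch > 0L)
    sample(gene_ids[multi], n_switch) else character(0)
  swapped_conds <- seq_len(config$n_conditions) > config$n_conditions / 2

  counts <- matrix(0L, nrow = nrow(observed$truth), ncol = length(samples),
                   dimnames = list(observed$truth$isoform_id, samples))
  usage <- list()
  for (g in gene_ids) {
    iso <- groups[[g]]
    k <- length(iso)
    p <- if (g %in% switch_genes && !is.null(config$switch_usage) &&
             length(config$switch_usage) == k)
      config$switch_usage else .rdirichlet(k, config$dirichlet_concentration)
    pmat <- matrix(rep(p, config$n_conditions), nrow = k)
    if (g %in% switch_genes && k >= 2L) {
      top2 <- order(p, decreasing = TRUE)[1:2]
      p2 <- p; p2[top2] <- p[rev(top2)]
      pmat[, swapped_conds] <- p2
    }
    usage[[g]] <- pmat
    for (cc in seq_len(config$n_conditions)) {
      nreads <- if (config$reads_distribution == "poisson")
        stats::rpois(1L, config$reads_per_condition)
      else round(config$reads_per_condition)
      per_rep <- rep(nreads %/% config$n_replicates, config$n_replicates)
      extra <- nreads %% config$n_replicates
      if (extra > 0L) per_rep[seq_len(extra)] <- per_rep[seq_len(extra)] + 1L
      for (r in seq_len(config$n_replicates)) {
        if (per_rep[r] == 0L) next
        s <- paste0(cond[cc], "_rep", r)
        counts[iso, s] <- counts[iso, s] +
          as.integer(stats::rmultinom(1L, per_rep[r], pmat[, cc]))
      }
    }
  }

  # expression table covers annotated genes only (intergenic isoforms are
  # their own loci for counting but are not genes)
  gene_counts <- rowsum(counts, grp_gene)
  real_genes <- unique(observed$truth$true_gene[!solo])
  rpm <- compute_rpm(gene_counts[real_genes, , drop = FALSE])
  truth <- data.frame(gene_id = gene_ids,
                      switch = gene_ids %in% switch_genes,
                      stringsAsFactors = FALSE)
  attr(truth, "usage") <- usage
  list(counts = counts, sample_map = sample_map,
       rpm = data.frame(gene_id = rownames(rpm), rpm,
                        check.names = FALSE, row.names = NULL),
       truth = truth)
}

#' Emit a short-read splice-junction file from observed isoforms
#'
#' One junction per distinct intron of the observed models, each dropped
#' independently with probability \code{dropout}; retained junctions get a
#' positive supporting read count.
#'
#' @param models named list of [transcript_model()] objects.
#' @param dropout per-junction dropout probability.
#' @param seed optional seed.
#' @return a \code{junction_set} data.frame.
#' @export
emit_junctions <- function(models, dropout = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  js <- junction_set_from_models(models)
  if (nrow(js) > 0L) {
    keep <- stats::runif(nrow(js)) >= dropout
    js <- js[keep, , drop = FALSE]
    js$count <- stats::rpois(nrow(js), 20) + 1L
    rownames(js) <- NULL
  }
  class(js) <- c("junction_set", "data.frame")
  js
}

#' Write a junction set as a STAR SJ.out.tab-style file
#'
#' @param junctions a \code{junction_set}.
#' @param path output file.
#' @export
write_sj <- function(junctions, path) {
  code <- c("+" = 1L, "-" = 2L, "*" = 0L)[junctions$strand]
  lines <- sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t0\t20",
                   junctions$chrom, junctions$start + 1L, junctions$end,
                   code, junctions$count)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a complete dataset on disk
#'
#' Runs [generate_reference()], [generate_observed_isoforms()],
#' [simulate_counts()] and [emit_junctions()] from one config and writes
#' every file in the formats the analysis functions consume: genome FASTA,
#' annotation GTF, isoform models (GTF and BED12), counts TSV, sample map
#' TSV, gene RPM TSV, SJ.out.tab junctions and a JSON truth manifest.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) a list with all in-memory objects plus the file
#'   paths.
#' @export
simulate_dataset <- function(config = sim_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(config)
  obs <- generate_observed_isoforms(ref, config)
  cnt <- simulate_counts(obs, config)
  js <- emit_junctions(obs$models, dropout = config$junction_dropout,
                       seed = config$seed + 4L)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    annotation = file.path(outdir, "annotation.gtf"),
    models_gtf = file.path(outdir, "isoforms.gtf"),
    models_bed = file.path(outdir, "isoforms.bed"),
    counts = file.path(outdir, "counts.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    rpm = file.path(outdir, "rpm.tsv"),
    junctions = file.path(outdir, "SJ.out.tab"),
    truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(ref$genome, paths$genome)
  write_annotation_gtf(ref$annotation, paths$annotation)
  write_models_gtf(obs$models, paths$models_gtf)
  write_bed12(obs$models, paths$models_bed)
  counts_df <- data.frame(isoform_id = rownames(cnt$counts), cnt$counts,
                          check.names = FALSE, row.names = NULL)
  utils::write.table(counts_df, paths$counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cnt$sample_map, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cnt$rpm, paths$rpm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_sj(js, paths$junctions)
  truth <- list(seed = config$seed,
                isoforms = obs$truth,
                novel_exons = obs$novel_exons,
                switch_genes = cnt$truth$gene_id[cnt$truth$switch])
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       auto_unbox = TRUE)
  invisible(list(reference = ref, observed = obs, counts = cnt,
                 junctions = js, paths = paths, truth = truth))
}
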