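#' Assemble isoform records from models and a count matrix
#'
#' In-memory counterpart of [read_isoform_models()], used by the synthetic
#' pipeline.
#'
#' @param models named list of [transcript_model()] objects.
#' @param counts isoform x sample count matrix (rows named by isoform id).
#' @param sample_map sample map data.frame.
#' @return isoform records (see [read_isoform_models()]).
#' @export
make_records <- function(models, counts, sample_map) {
  records <- lapply(names(models), function(id) {
    x <- counts[id, , drop = TRUE]
    list(model = models[[id]], counts = x, zero_reads = sum(x) == 0)
  })
  names(records) <- names(models)
  attr(records, "sample_map") <- sample_map
  records
}

#' Estimate the family-wise error rate of the usage test by simulation
#'
#' Simulates global-null datasets (every gene's usage vector shared across
#' conditions), runs the full differential-usage procedure — read-count
#' filter, per-gene chi-squared contingency test, Bonferroni correction —
#' on each, and reports the fraction of datasets declaring at least one
#' gene significant.
#'
#' @param n_replicates number of simulated datasets.
#' @param n_genes,isoforms_per_gene,n_conditions,reads_per_condition,concentration
#'   dataset shape (see [simulate_usage_counts()]); reads are multinomial
#'   with a fixed total per condition.
#' @param min_reads,min_conditions,alpha testing parameters
#'   (see [run_diu()]).
#' @param seed RNG seed for the whole simulation.
#' @return list with \code{fwer} (the fraction), \code{n_replicates},
#'   \code{n_datasets_with_hit} and \code{n_tested_per_dataset} (mean).
#' @export
estimate_fwer <- function(n_replicates = 500, n_genes = 200,
                          isoforms_per_gene = 3L, n_conditions = 4L,
                          reads_per_condition = 100, concentration = 2,
                          min_reads = 50, min_conditions = 2, alpha = 0.05,
                          seed = 1L) {
  set.seed(seed)
  hits <- logical(n_replicates)
  n_tested <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_usage_counts(
      n_genes = n_genes, isoforms_per_gene = isoforms_per_gene,
      n_conditions = n_conditions,
      reads_per_condition = reads_per_condition,
      concentration = concentration, n_switch = 0L,
      reads_distribution = "fixed")
    res <- diu_from_matrices(sim$counts, min_reads = min_reads,
                             min_conditions = min_conditions, alpha = alpha)
    hits[r] <- any(res$significant)
    n_tested[r] <- attr(res, "n_tested")
  }
  list(fwer = mean(hits), n_replicates = n_replicates,
       n_datasets_with_hit = sum(hits),
       n_tested_per_dataset = mean(n_tested))
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' simulate -> classify -> CDS containment -> novel exons (+ junction
#' validation) -> differential usage -> expression summary, followed by a
#' recovery report against the generator's ground truth: the
#' classification confusion matrix, novel-exon precision/recall, and
#' switch-gene detection.
#'
#' @param sim result of [simulate_dataset()] (or an equivalent in-memory
#'   list with \code{reference}, \code{observed}, \code{counts},
#'   \code{junctions}).
#' @param min_reads,min_conditions,alpha differential-usage parameters.
#' @param run_cds set FALSE to skip the (slower) CDS containment stage.
#' @return list with \code{classifications}, \code{cds},
#'   \code{novel_exons}, \code{diu}, \code{detection} (per-bin isoform
#'   detection rates) and \code{recovery} (confusion matrix, novel-exon
#'   precision/recall, switch detection).
#' @export
run_pipeline <- function(sim, min_reads = 50, min_conditions = 2,
                         alpha = 0.05, run_cds = TRUE) {
  ann <- sim$reference$annotation
  records <- make_records(sim$observed$models, sim$counts$counts,
                          sim$counts$sample_map)
  cls <- classify_isoforms(records, ann)
  truth <- sim$observed$truth
  confusion <- table(truth = truth$true_category,
                     called = cls$category[match(truth$isoform_id,
                                                 cls$isoform_id)])

  cds <- NULL
  if (run_cds)
    cds <- cds_containment(records, cls, ann, sim$reference$genome)

  nnc_ids <- cls$isoform_id[cls$category == "NNC"]
  ne <- find_novel_exons(records[nnc_ids], ann)
  ne <- validate_with_junctions(ne, sim$junctions)
  truth_ne <- sim$observed$novel_exons
  found_keys <- paste(ne$chrom, ne$start, ne$end)
  truth_keys <- unique(paste(truth_ne$chrom, truth_ne$start, truth_ne$end))
  precision <- if (nrow(ne) == 0L) NA_real_ else
    mean(found_keys %in% truth_keys)
  recall <- if (length(truth_keys) == 0L) NA_real_ else
    mean(truth_keys %in% found_keys)

  gene_ids <- stats::setNames(cls$gene_id, cls$isoform_id)
  diu <- run_diu(records, gene_ids, min_reads = min_reads,
                 min_conditions = min_conditions, alpha = alpha)
  switch_truth <- sim$counts$truth$gene_id[sim$counts$truth$switch]
  detected_switch <- intersect(diu$gene_id[diu$significant], switch_truth)
  false_pos <- setdiff(diu$gene_id[diu$significant], switch_truth)

  mu <- mean_rpm(sim$counts$rpm, sim$counts$sample_map)
  expressed <- expressed_genes(mu)
  detected_genes <- unique(cls$gene_id[!is.na(cls$gene_id)])
  detection <- detection_rate_by_bin(mu[expressed], detected_genes)

  list(classifications = cls, cds = cds, novel_exons = ne, diu = diu,
       detection = detection,
       recovery = list(confusion = confusion,
                       novel_exon_precision = precision,
                       novel_exon_recall = recall,
                       n_switch_true = length(switch_truth),
                       n_switch_detected = length(detected_switch),
                       false_positive_genes = false_pos))
}
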