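# Hand-built toy annotation used across test files.
#
# chr1, gene_a (+):
#   a.t1 exons (100,200) (300,400) (500,600)   junctions (200,300) (400,500)
#   a.t2 exons (450,600) (700,800)             junction  (600,700)
# chr1, gene_b (-):
#   b.t1 exons (2000,2200) (2500,2700) (2900,3000)
# chr2, gene_c (+), single transcript, used for cross-chromosome checks:
#   c.t1 exons (100,250) (400,500)
toy_annotation <- function() {
  txs <- list(
    transcript_model("a.t1", "chr1", "+",
                     rbind(c(100, 200), c(300, 400), c(500, 600)),
                     gene_id = "gene_a"),
    transcript_model("a.t2", "chr1", "+",
                     rbind(c(450, 600), c(700, 800)), gene_id = "gene_a"),
    transcript_model("b.t1", "chr1", "-",
                     rbind(c(2000, 2200), c(2500, 2700), c(2900, 3000)),
                     gene_id = "gene_b"),
    transcript_model("c.t1", "chr2", "+",
                     rbind(c(100, 250), c(400, 500)), gene_id = "gene_c"))
  build_annotation(txs)
}

toy_sample_map <- function() {
  data.frame(
    sample = c("LPS_rep1", "LPS_rep2", "NoStim_rep1"),
    condition = c("LPS", "LPS", "NoStim"),
    replicate = c(1L, 2L, 1L),
    include_flag = TRUE,
    stringsAsFactors = FALSE)
}

# record list around bare models with a trivial count vector
toy_records <- function(models, counts = NULL, sample_map = toy_sample_map()) {
  if (is.null(counts)) {
    counts <- matrix(1L, nrow = length(models), ncol = nrow(sample_map),
                     dimnames = list(vapply(models, `[[`, "", "id"),
                                     sample_map$sample))
  }
  make_records(stats::setNames(models, vapply(models, `[[`, "", "id")),
               counts, sample_map)
}

# small randomized reference for property tests
small_reference <- function(seed, n_genes = 6) {
  generate_reference(sim_config(
    seed = seed, n_chromosomes = 1L, chromosome_length = 120000L,
    n_genes = n_genes, transcripts_per_gene = c(1L, 3L),
    exons_per_transcript = c(3L, 6L),
    exon_length = c(60L, 200L), intron_length = c(120L, 600L),
    intergenic_gap = c(1500L, 4000L)))
}
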