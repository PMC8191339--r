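test_that("the category cascade reproduces the definitional examples", {
  ann <- toy_annotation()

  fsm <- classify_isoform(
    transcript_model("q1", "chr1", "+",
                     rbind(c(120, 200), c(300, 400), c(500, 580))), ann)
  expect_equal(fsm$category, "FSM")
  expect_equal(fsm$matched_transcript, "a.t1")
  expect_equal(fsm$gene_id, "gene_a")

  ism <- classify_isoform(
    transcript_model("q2", "chr1", "+", rbind(c(320, 400), c(500, 600))), ann)
  expect_equal(ism$category, "ISM")
  expect_equal(ism$matched_transcript, "a.t1")

  # both junctions annotated, but in different transcripts of the gene
  nic <- classify_isoform(
    transcript_model("q3", "chr1", "+",
                     rbind(c(150, 200), c(300, 600), c(700, 750))), ann)
  expect_equal(nic$category, "NIC")
  expect_equal(nic$gene_id, "gene_a")

  # donor shifted to unannotated position 410
  nnc <- classify_isoform(
    transcript_model("q4", "chr1", "+", rbind(c(300, 410), c(500, 600))), ann)
  expect_equal(nnc$category, "NNC")
  expect_equal(nnc$novel_sites$position, 410L)
  expect_equal(nnc$novel_sites$side, "donor")

  inter <- classify_isoform(
    transcript_model("q5", "chr1", "+", rbind(c(5000, 5100), c(5200, 5300))),
    ann)
  expect_equal(inter$category, "intergenic")
  expect_true(is.na(inter$gene_id))

  # overlap only on the opposite strand, no shared sites
  anti <- classify_isoform(
    transcript_model("q6", "chr1", "+", rbind(c(2010, 2100), c(2600, 2650))),
    ann)
  expect_equal(anti$category, "genic_other")
})

test_that("mono-exon isoforms get their own categories", {
  ann <- toy_annotation()
  known <- classify_isoform(
    transcript_model("m1", "chr1", "+", cbind(120, 180)), ann)
  expect_equal(known$category, "mono_exon_known")
  genic <- classify_isoform(
    transcript_model("m2", "chr1", "+", cbind(250, 290)), ann)
  expect_equal(genic$category, "mono_exon_genic")
  inter <- classify_isoform(
    transcript_model("m3", "chr1", "+", cbind(4000, 4100)), ann)
  expect_equal(inter$category, "intergenic")
})

test_that("an identical chain is FSM, never ISM, and categories ignore input order", {
  ann <- toy_annotation()
  # a.t2's full chain is one junction; a model with the same chain is FSM
  m <- transcript_model("q", "chr1", "+", rbind(c(460, 600), c(700, 790)))
  expect_equal(classify_isoform(m, ann)$category, "FSM")

  # reference transcript order must not matter
  txs <- list(
    transcript_model("a.t2", "chr1", "+", rbind(c(450, 600), c(700, 800)),
                     gene_id = "gene_a"),
    transcript_model("b.t1", "chr1", "-",
                     rbind(c(2000, 2200), c(2500, 2700), c(2900, 3000)),
                     gene_id = "gene_b"),
    transcript_model("c.t1", "chr2", "+", rbind(c(100, 250), c(400, 500)),
                     gene_id = "gene_c"),
    transcript_model("a.t1", "chr1", "+",
                     rbind(c(100, 200), c(300, 400), c(500, 600)),
                     gene_id = "gene_a"))
  ann2 <- build_annotation(txs)
  probes <- list(
    transcript_model("p1", "chr1", "+",
                     rbind(c(120, 200), c(300, 400), c(500, 580))),
    transcript_model("p2", "chr1", "+", rbind(c(320, 400), c(500, 600))),
    transcript_model("p3", "chr1", "+", rbind(c(300, 410), c(500, 600))))
  for (p in probes)
    expect_equal(classify_isoform(p, ann2)$category,
                 classify_isoform(p, ann)$category)

  # exon-list permutation before sorting must not matter
  shuffled <- transcript_model("p1s", "chr1", "+",
                               rbind(c(500, 580), c(120, 200), c(300, 400)))
  expect_equal(classify_isoform(shuffled, ann)$category, "FSM")
})

test_that("gene assignment prefers shared sites, then exonic overlap", {
  ann <- toy_annotation()
  # chain of gene_a; also make it span toward gene_b without sharing sites
  by_sites <- transcript_model("g1", "chr1", "+",
                               rbind(c(100, 200), c(300, 400), c(500, 1900)))
  expect_equal(assign_gene(by_sites, ann), "gene_a")
  # no shared sites: exonic overlap decides
  by_overlap <- transcript_model("g2", "chr1", "+", cbind(2450, 2750))
  expect_equal(assign_gene(by_overlap, ann), "gene_b")
  # intergenic: none
  off <- transcript_model("g3", "chr1", "+", cbind(4200, 4300))
  expect_true(is.na(assign_gene(off, ann)))
})

test_that("FSM end distances are strand-aware and minimized over the gene", {
  ann <- toy_annotation()
  # 5' end 50 nt inside the first exon of a.t1
  m <- transcript_model("e1", "chr1", "+",
                        rbind(c(150, 200), c(300, 400), c(500, 600)))
  cl <- classify_isoform(m, ann)
  d <- end_distances(cl, m, ann)
  expect_equal(unname(d["d5_matched"]), 50)
  expect_equal(unname(d["d3_matched"]), 0)

  ident <- transcript_model("e2", "chr1", "+",
                            rbind(c(100, 200), c(300, 400), c(500, 600)))
  expect_equal(unname(end_distances(classify_isoform(ident, ann), ident, ann)),
               c(0, 0, 0, 0))

  # gene-level minimum can beat the matched transcript: a.t2's polyA is 800
  m3 <- transcript_model("e3", "chr1", "+",
                         rbind(c(100, 200), c(300, 400), c(500, 800)))
  d3 <- end_distances(classify_isoform(m3, ann), m3, ann)
  expect_equal(unname(d3["d3_matched"]), 200)
  expect_equal(unname(d3["d3_gene_min"]), 0)

  # minus strand: the 5' end is the high coordinate
  m4 <- transcript_model("e4", "chr1", "-",
                         rbind(c(2000, 2200), c(2500, 2700), c(2900, 2960)))
  d4 <- end_distances(classify_isoform(m4, ann), m4, ann)
  expect_equal(unname(d4["d5_matched"]), 40)
  expect_equal(unname(d4["d3_matched"]), 0)

  ism <- classify_isoform(
    transcript_model("e5", "chr1", "+", rbind(c(320, 400), c(500, 600))), ann)
  expect_error(end_distances(ism, NULL, ann), "FSM")
})

test_that("distant-end counting uses a strict threshold on the gene minimum", {
  cls <- data.frame(
    isoform_id = c("a", "b", "c"), category = c("FSM", "FSM", "NNC"),
    d5_gene_min = c(501, 500, 9999), d3_gene_min = c(0, 501, 9999))
  expect_equal(unname(count_distant_ends(cls, threshold = 500)), c(1L, 1L))
  expect_equal(unname(count_distant_ends(cls, threshold = Inf)), c(0L, 0L))
})

test_that("minority filtering discards isoforms below 1% of their locus", {
  models <- list(
    transcript_model("A", "chr1", "+", cbind(100, 200)),
    transcript_model("B", "chr1", "+", cbind(100, 210)),
    transcript_model("C", "chr1", "+", cbind(100, 220)),
    transcript_model("D", "chr1", "+", cbind(100, 230)))
  sm <- toy_sample_map()
  counts <- matrix(0L, 4, 3, dimnames = list(c("A", "B", "C", "D"), sm$sample))
  counts["A", 1] <- 99L; counts["B", 1] <- 1L   # B is exactly 1%: kept
  counts["C", 1] <- 995L; counts["D", 1] <- 5L  # D is 0.5%: discarded
  recs <- make_records(stats::setNames(models, c("A", "B", "C", "D")),
                       counts, sm)
  genes <- c(A = "g1", B = "g1", C = "g2", D = "g2")
  kept <- filter_minority_isoforms(recs, genes)
  expect_setequal(names(kept), c("A", "B", "C"))
  # min_fraction 0 is the identity
  expect_setequal(names(filter_minority_isoforms(recs, genes, 0)),
                  c("A", "B", "C", "D"))
  # zero-total gene keeps everything
  counts0 <- counts; counts0[] <- 0L
  recs0 <- make_records(stats::setNames(models, c("A", "B", "C", "D")),
                        counts0, sm)
  expect_message(kept0 <- filter_minority_isoforms(recs0, genes), "zero")
  expect_length(kept0, 4L)
})

test_that("intergenic locus clustering is single-linkage span overlap", {
  mk <- function(id, s, e) transcript_model(id, "chr1", "+", cbind(s, e))
  loci <- cluster_intergenic_loci(list(mk("a", 0, 100), mk("b", 50, 150),
                                       mk("c", 200, 300)))
  expect_equal(nrow(loci), 2L)
  expect_equal(sort(loci$n_members), c(1L, 2L))
  # adjacency without overlap does not merge
  touch <- cluster_intergenic_loci(list(mk("a", 0, 100), mk("b", 100, 200)))
  expect_equal(nrow(touch), 2L)
  # mono-exon exclusion
  mix <- list(mk("a", 0, 100),
              transcript_model("b", "chr1", "-", rbind(c(50, 80), c(120, 150))))
  expect_equal(nrow(cluster_intergenic_loci(mix, multiexon_only = TRUE)), 1L)
})

test_that("locus clustering equals connected components of the overlap graph", {
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(2:20, 1)
    starts <- sample(0:2000, n, replace = TRUE)
    lens <- sample(20:400, n, replace = TRUE)
    models <- lapply(seq_len(n), function(i)
      transcript_model(paste0("i", i), sample(c("chr1", "chr2"), 1), "+",
                       cbind(starts[i], starts[i] + lens[i])))
    loci <- cluster_intergenic_loci(models)
    spans <- data.frame(
      chrom = vapply(models, `[[`, "", "chrom"),
      start = starts, end = starts + lens)
    comp <- oracle_components(spans)
    expect_equal(nrow(loci), length(unique(comp)))
    # membership partition must match as well
    got <- sort(unname(vapply(strsplit(loci$members, ","), function(x)
      paste(sort(x), collapse = ","), "")))
    ids <- paste0("i", seq_len(n))
    want <- sort(unname(vapply(split(ids, comp), function(x)
      paste(sort(x), collapse = ","), "")))
    expect_equal(got, want)
  }
})

test_that("the classifier agrees with the brute-force oracle on random annotations", {
  set.seed(61)
  for (rep in 1:30) {
    ref <- small_reference(seed = 6100 + rep, n_genes = sample(3:6, 1))
    obs <- generate_observed_isoforms(
      ref, sim_config(seed = 6100 + rep, n_isoforms = 12L,
                      n_chromosomes = 1L, chromosome_length = 120000L))
    refs <- annotation_to_refs(ref$annotation)
    cls <- classify_isoforms(obs$models, ref$annotation)
    for (id in names(obs$models)) {
      m <- obs$models[[id]]
      expect_equal(cls$category[cls$isoform_id == id],
                   oracle_classify(m$chrom, m$strand, m$exons, refs),
                   info = paste("seed", 6100 + rep, "isoform", id))
    }
  }
})
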