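test_that("transcript models derive junction chains and enforce exon invariants", {
  m <- transcript_model("t", "chr1", "+", rbind(c(300, 400), c(100, 200)))
  expect_equal(m$exons[, "start"], c(100L, 300L))  # unsorted input is sorted
  expect_equal(unname(m$junctions), cbind(200L, 300L))
  expect_equal(m$n_exons - 1L, nrow(m$junctions))
  expect_equal(m$span, c(start = 100L, end = 400L))

  single <- transcript_model("s", "chr1", "-", cbind(10, 50))
  expect_equal(nrow(single$junctions), 0L)

  expect_error(transcript_model("bad", "chr1", "+", cbind(100, 100)),
               "end <= start")
  expect_error(transcript_model("bad", "chr1", "+",
                                rbind(c(100, 250), c(200, 300))),
               "overlap")
  expect_error(transcript_model("bad", "chr1", "?", cbind(1, 10)), "strand")
})

test_that("junction chains have strictly increasing coordinates on random models", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    lens <- sample(50:200, n, replace = TRUE)
    gaps <- sample(30:500, n - 1, replace = TRUE)
    starts <- cumsum(c(sample(0:1000, 1), lens[-n] + gaps))
    m <- transcript_model("r", "chr1", sample(c("+", "-"), 1),
                         cbind(starts, starts + lens))
    j <- as.vector(t(m$junctions))
    expect_true(all(diff(j) > 0))
    expect_equal(nrow(m$junctions), m$n_exons - 1L)
  }
})

test_that("GTF parsing converts 1-based inclusive coordinates and indexes genes", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t2";',
    'chr1\tx\texon\t501\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'),
    gtf)
  ann <- parse_gtf(gtf)
  expect_equal(unname(ann$transcripts$t1$exons[1, ]), c(100L, 200L))
  expect_equal(unname(ann$transcripts$t1$junctions), cbind(200L, 300L))
  # two transcripts sharing a gene: one gene, site set is the union
  expect_equal(nrow(ann$genes), 1L)
  expect_setequal(ann$gene_transcripts$g1, c("t1", "t2"))
  expect_setequal(ann$site_keys,
                  c("chr1|+|200", "chr1|+|300", "chr1|+|500"))
})

test_that("malformed GTF lines are reported with their line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\tbroken line"), gtf)
  expect_error(parse_gtf(gtf), "line 2")

  gtf2 <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t500\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf2)
  expect_warning(ann <- parse_gtf(gtf2), "rejected")
  expect_equal(ann$transcripts$t1$n_exons, 1L)
})

test_that("GTF round trip preserves exon coordinates exactly", {
  ref <- small_reference(seed = 21)
  path <- tempfile(fileext = ".gtf")
  write_annotation_gtf(ref$annotation, path)
  back <- parse_gtf(path)
  expect_setequal(names(back$transcripts), names(ref$annotation$transcripts))
  for (id in names(ref$annotation$transcripts)) {
    expect_equal(unname(back$transcripts[[id]]$exons),
                 unname(ref$annotation$transcripts[[id]]$exons))
    expect_equal(back$transcripts[[id]]$strand,
                 ref$annotation$transcripts[[id]]$strand)
  }
})

test_that("exon overlap queries agree with a brute-force linear scan", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(3:25, 1)
    lens <- sample(20:300, n, replace = TRUE)
    starts <- sample(0:5000, n, replace = TRUE)
    txs <- lapply(seq_len(n), function(i)
      transcript_model(paste0("t", i), sample(c("chr1", "chr2"), 1),
                       sample(c("+", "-"), 1),
                       cbind(starts[i], starts[i] + lens[i]),
                       gene_id = paste0("g", i)))
    ann <- build_annotation(txs)
    for (k in 1:5) {
      chrom <- sample(c("chr1", "chr2"), 1)
      qs <- sample(0:5200, 1); qe <- qs + sample(1:400, 1)
      got <- query_exons(ann, chrom, qs, qe)
      want <- oracle_query_exons(ann$exon_table, chrom, qs, qe)
      expect_setequal(paste(got$transcript_id, got$start, got$end),
                      paste(want$transcript_id, want$start, want$end))
    }
  }
})

test_that("BED12 block arithmetic and the write/read round trip are exact", {
  m <- transcript_model("iso1", "chr1", "+", rbind(c(100, 200), c(300, 400)))
  path <- tempfile(fileext = ".bed")
  write_bed12(list(m), path)
  line <- readLines(path)[2]
  f <- strsplit(line, "\t")[[1]]
  expect_equal(as.integer(f[10]), 2L)        # blockCount
  expect_equal(f[11], "100,100,")            # blockSizes
  expect_equal(f[12], "0,200,")              # blockStarts
  back <- read_bed12_models(path)
  expect_equal(unname(back$iso1$exons), unname(m$exons))

  # multi-model round trip on randomized structures
  ref <- small_reference(seed = 41)
  obs <- generate_observed_isoforms(ref)
  p2 <- tempfile(fileext = ".bed")
  write_bed12(obs$models, p2)
  back2 <- read_bed12_models(p2)
  for (id in names(obs$models))
    expect_equal(unname(back2[[id]]$exons), unname(obs$models[[id]]$exons))

  # empty record list: header-only file
  p3 <- tempfile(fileext = ".bed")
  write_bed12(list(), p3)
  expect_length(readLines(p3), 1L)
})

test_that("SJ.out.tab junctions are converted, filtered and deduplicated", {
  path <- tempfile()
  writeLines(c(
    "chr1\t201\t300\t1\t1\t0\t12\t0\t20",
    "chr1\t201\t300\t1\t1\t0\t3\t0\t20",   # duplicate: counts summed
    "chr1\t401\t500\t2\t1\t0\t0\t5\t20",   # zero unique reads: excluded
    "chr2\t100\t150\t7\t0\t0\t4\t0\t10"),  # unknown strand code
    path)
  expect_message(js <- read_short_read_junctions(path), "unstranded")
  expect_equal(nrow(js), 2L)
  plus <- js[js$chrom == "chr1", ]
  expect_equal(c(plus$start, plus$end, plus$count), c(200, 300, 15))
  expect_equal(js$strand[js$chrom == "chr2"], "*")
})

test_that("spliced sequences concatenate exons and reverse-complement minus strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAATTTGGG"))
  plus <- transcript_model("p", "chr1", "+", rbind(c(0, 3), c(6, 9)))
  minus <- transcript_model("m", "chr1", "-", rbind(c(0, 3), c(6, 9)))
  expect_equal(as.character(spliced_sequence(plus, genome)), "AAAGGG")
  expect_equal(as.character(spliced_sequence(minus, genome)), "CCCTTT")
  whole <- transcript_model("w", "chr1", "+", cbind(0, 9))
  expect_equal(as.character(spliced_sequence(whole, genome)), "AAATTTGGG")
  alien <- transcript_model("a", "chrX", "+", cbind(0, 3))
  expect_error(spliced_sequence(alien, genome), "chrX")
})

test_that("isoform records join models, counts and the sample map", {
  dir <- tempfile(); dir.create(dir)
  m1 <- transcript_model("iso1", "chr1", "+", rbind(c(100, 200), c(300, 400)))
  m2 <- transcript_model("iso2", "chr1", "+", cbind(500, 700))
  write_models_gtf(list(m1, m2), file.path(dir, "m.gtf"))
  writeLines(c("isoform_id\tLPS_rep1\tLPS_rep2\tNoStim_rep1",
               "iso1\t10\t0\t5", "iso2\t0\t0\t0"),
             file.path(dir, "c.tsv"))
  recs <- read_isoform_models(file.path(dir, "m.gtf"),
                              file.path(dir, "c.tsv"), toy_sample_map())
  expect_equal(unname(recs$iso1$counts), c(10, 0, 5))
  expect_false(recs$iso1$zero_reads)
  expect_true(recs$iso2$zero_reads)
  # replicate collapse through the usage table
  tab <- build_usage_table(recs["iso1"], toy_sample_map())
  expect_equal(unname(tab$counts["iso1", ]), c(10, 5))
  expect_equal(colnames(tab$counts), c("LPS", "NoStim"))

  writeLines(c("isoform_id\tLPS_rep1", "iso_missing\t3"),
             file.path(dir, "bad.tsv"))
  expect_error(read_isoform_models(file.path(dir, "m.gtf"),
                                   file.path(dir, "bad.tsv"),
                                   toy_sample_map()),
               "iso_missing")
  writeLines(c("isoform_id\tLPS_rep1\tLPS_rep2\tNoStim_rep1",
               "iso1\t-1\t0\t0", "iso2\t0\t0\t0"),
             file.path(dir, "neg.tsv"))
  expect_error(read_isoform_models(file.path(dir, "m.gtf"),
                                   file.path(dir, "neg.tsv"),
                                   toy_sample_map()),
               "negative")
})

test_that("excluded samples never enter the records", {
  sm <- toy_sample_map()
  sm$include_flag[3] <- FALSE  # pilot-style exclusion
  dir <- tempfile(); dir.create(dir)
  m1 <- transcript_model("iso1", "chr1", "+", cbind(100, 300))
  write_models_gtf(list(m1), file.path(dir, "m.gtf"))
  writeLines(c("isoform_id\tLPS_rep1\tLPS_rep2\tNoStim_rep1", "iso1\t10\t2\t99"),
             file.path(dir, "c.tsv"))
  recs <- read_isoform_models(file.path(dir, "m.gtf"),
                              file.path(dir, "c.tsv"), sm)
  expect_named(recs$iso1$counts, c("LPS_rep1", "LPS_rep2"))
})
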