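test_that("usage tables normalize each condition column to 100%", {
  t <- usage_table(matrix(c(30, 70, 0, 0), nrow = 2,
                          dimnames = list(c("isoA", "isoB"), c("LPS", "R848"))),
                   gene_id = "g")
  expect_equal(unname(t$usage[, "LPS"]), c(30, 70))
  expect_true(all(is.na(t$usage[, "R848"])))  # zero column: undefined, flagged
  expect_equal(unname(t$testable_cols), c(TRUE, FALSE))

  set.seed(1)
  for (i in 1:20) {
    m <- matrix(rpois(12, 30), nrow = 3)
    tt <- usage_table(m)
    sums <- colSums(tt$usage)[colSums(m) > 0]
    expect_equal(unname(sums), rep(100, length(sums)), tolerance = 1e-9)
  }
  expect_error(usage_table(matrix(numeric(0), nrow = 0)), ">= 1 row")
  expect_error(usage_table(matrix(-1)), "negative")
})

test_that("the testability filter is inclusive at 50 reads and 2 conditions", {
  mk <- function(totals) usage_table(rbind(totals * 0.6, totals * 0.4))
  keep <- function(totals)
    length(filter_testable_genes(list(mk(totals)))) == 1L
  expect_true(keep(c(60, 55, 10, 5)))
  expect_false(keep(c(60, 45, 49, 5)))
  expect_true(keep(c(50, 50)))
  expect_false(keep(c(50, 49)))
})

test_that("the chi-squared statistic matches hand computation and is symmetric", {
  res <- chi2_contingency_test(matrix(c(50, 50, 50, 50), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, 1)

  res2 <- suppressWarnings(chi2_contingency_test(matrix(c(90, 10, 10, 90), 2)))
  expect_equal(res2$statistic, 128)  # E = 50 everywhere, 4 * 40^2/50
  expect_equal(res2$df, 1L)

  m <- matrix(c(12, 30, 7, 44, 9, 2), nrow = 3)
  a <- suppressWarnings(chi2_contingency_test(m))
  b <- suppressWarnings(chi2_contingency_test(m[c(3, 1, 2), c(2, 1)]))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)

  # degenerate rows/columns are removed before df
  degen <- matrix(c(10, 0, 20, 0, 0, 0, 5, 0, 15), nrow = 3)
  res3 <- chi2_contingency_test(degen)
  expect_equal(res3$df, 1L)
  # fewer than 2 usable rows: untestable
  expect_false(chi2_contingency_test(matrix(c(10, 20), 1))$testable)
})

test_that("the chi-squared test agrees with the stats oracle on random tables", {
  set.seed(101)
  for (i in 1:300) {
    r <- sample(2:5, 1); k <- sample(2:5, 1)
    m <- matrix(rpois(r * k, sample(c(5, 30, 200), 1)) + 1, nrow = r)
    got <- suppressWarnings(chi2_contingency_test(m))
    want <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(want$parameter))
    expect_equal(got$p_value, unname(want$p.value), tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment caps at 1 and thresholds at alpha/m", {
  b <- bonferroni(c(0.001, 1e-6), m = 1872)
  expect_equal(b$p_adjusted, c(1, 1.872e-3))
  expect_equal(b$significant, c(FALSE, TRUE))
  # raw-p threshold for m tests at alpha 0.05 is 0.05/m
  thr <- 0.05 / 1872
  expect_equal(thr, 2.670940e-5, tolerance = 1e-6)
  edge <- bonferroni(c(thr * 0.999, thr * 1.001), m = 1872)
  expect_equal(edge$significant, c(TRUE, FALSE))
  empty <- bonferroni(numeric(0))
  expect_length(empty$p_adjusted, 0L)
})

test_that("maximum usage SD is the population SD over testable conditions", {
  t <- usage_table(rbind(a = c(10, 10, 10, 90), b = c(90, 90, 90, 10)))
  expect_equal(max_usage_sd(t), sqrt(4800 / 4), tolerance = 1e-6)  # 34.641
  flat <- usage_table(rbind(a = c(40, 40, 40), b = c(60, 60, 60)))
  expect_equal(max_usage_sd(flat), 0)
  # with two isoforms the rows are complementary: equal SDs
  two <- usage_table(rbind(a = c(30, 70), b = c(70, 30)))
  u <- two$usage
  sds <- apply(u, 1, function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(unname(sds[1]), unname(sds[2]))
  expect_equal(max_usage_sd(two), unname(sds[1]))
  expect_warning(one <- max_usage_sd(usage_table(cbind(c(10, 90)))), "SD")
  expect_true(is.na(one))
})

test_that("an injected usage switch dominates the ranking; homogeneous genes never fire", {
  sim <- simulate_usage_counts(n_genes = 200, isoforms_per_gene = 2L,
                               n_conditions = 4L, reads_per_condition = 500,
                               concentration = 2, n_switch = 1L,
                               switch_usage = c(0.8, 0.2),
                               reads_distribution = "fixed", seed = 111)
  res <- diu_from_matrices(sim$counts)
  expect_equal(res$gene_id[1], "gene_0001")
  expect_true(res$significant[1])
  expect_equal(attr(res, "n_tested"), 200L)

  # identical counts across conditions: p = 1
  flat <- list(g = matrix(60, nrow = 3, ncol = 4))
  res2 <- diu_from_matrices(flat)
  expect_equal(res2$p_value, 1)
  expect_false(res2$significant)

  # single-isoform gene is untestable and excluded from the tested count
  mix <- list(g1 = matrix(60, nrow = 1, ncol = 4),
              g2 = matrix(c(60, 40, 55, 45, 58, 42, 61, 39), nrow = 2))
  res3 <- diu_from_matrices(mix)
  expect_equal(attr(res3, "untestable"), "g1")
  expect_equal(attr(res3, "n_tested"), 1L)
})

test_that("run_diu groups by assigned gene and collapses replicates", {
  models <- list(
    transcript_model("i1", "chr1", "+", cbind(0, 100)),
    transcript_model("i2", "chr1", "+", cbind(0, 120)),
    transcript_model("i3", "chr1", "+", cbind(500, 700)))
  sm <- data.frame(sample = c("A_r1", "A_r2", "B_r1"),
                   condition = c("A", "A", "B"), replicate = c(1, 2, 1),
                   include_flag = TRUE)
  counts <- rbind(i1 = c(40, 40, 10), i2 = c(10, 10, 70), i3 = c(9, 9, 9))
  colnames(counts) <- sm$sample
  recs <- make_records(stats::setNames(models, c("i1", "i2", "i3")), counts, sm)
  res <- run_diu(recs, c(i1 = "g1", i2 = "g1", i3 = "g2"))
  expect_equal(res$gene_id, "g1")           # g2 untestable (single isoform)
  expect_equal(res$n_isoforms, 2L)
  expect_true(res$chi2_stat > 0)
  # replicate collapse: condition A holds 80 + 20 reads
  tab <- build_usage_table(recs[c("i1", "i2")], sm)
  expect_equal(unname(tab$counts[, "A"]), c(80, 20))
})

test_that("switch detection power is monotone in depth and effect size", {
  effects <- list(c(0.60, 0.40), c(0.75, 0.25), c(0.90, 0.10))
  depths <- c(50, 150, 450)
  rate <- matrix(NA_real_, 3, 3)
  set.seed(121)
  for (e in 1:3) for (d in 1:3) {
    sim <- simulate_usage_counts(
      n_genes = 100, isoforms_per_gene = 2L, n_conditions = 4L,
      reads_per_condition = depths[d], concentration = 2,
      n_switch = 100L, switch_usage = effects[[e]],
      reads_distribution = "fixed")
    res <- diu_from_matrices(sim$counts)
    rate[e, d] <- mean(res$significant)
  }
  slack <- 0.05
  for (e in 1:3) expect_true(all(diff(rate[e, ]) >= -slack))
  for (d in 1:3) expect_true(all(diff(rate[, d]) >= -slack))
  expect_gt(rate[3, 3], rate[1, 1])
})

test_that("significant genes carry systematically larger usage SDs", {
  sim <- simulate_usage_counts(n_genes = 150, isoforms_per_gene = 2L,
                               n_conditions = 4L, reads_per_condition = 200,
                               concentration = 2, n_switch = 25L,
                               switch_usage = c(0.75, 0.25),
                               reads_distribution = "fixed", seed = 131)
  res <- diu_from_matrices(sim$counts)
  expect_true(any(res$significant) && any(!res$significant))
  w <- stats::wilcox.test(res$max_usage_sd[res$significant],
                          res$max_usage_sd[!res$significant],
                          alternative = "greater")
  expect_lt(w$p.value, 0.01)
})
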