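make_toy_genes <- function() {
  gene_model_df(symbol = c("alpha", "beta", "gamma"),
                chrom = c("chr1", "chr1", "chr2"),
                strand = c("+", "-", "+"),
                body_start = c(1000, 5000, 2000),
                body_end = c(3000, 8000, 4000))
}

test_that("TSS distance is signed by strand around the peak midpoint", {
  g_plus <- gene_model_df("g", "chrN", "+", 1000, 4000)
  g_minus <- gene_model_df("g", "chrN", "-", 100, 1000)
  at_tss <- peak_df("chrN", 900, 1100)
  expect_identical(tss_distance(at_tss, g_plus), 0L)
  downstream <- peak_df("chrN", 1100, 1300)  # midpoint 1200
  expect_identical(tss_distance(downstream, g_plus), 200L)
  expect_identical(tss_distance(downstream, g_minus), -200L)
  expect_error(tss_distance(peak_df("chrM", 0, 10), g_plus), "chromosome")
})

test_that("nearest-TSS annotation matches the all-pairs minimum oracle", {
  genes <- make_toy_genes()
  one <- annotate_nearest_tss(peak_df("chr1", 1400, 1600), genes)
  expect_identical(one$gene, "alpha")
  expect_identical(nrow(annotate_nearest_tss(peak_df("chr1", 1400, 1600),
                                             genes, max_dist = 100L)), 0L)
  # equidistant genes: lexicographic tie-break, flagged
  tie_genes <- gene_model_df(c("zeta", "eta"), "chr1", c("+", "+"),
                             c(1000, 2000), c(1500, 2500))
  tie <- annotate_nearest_tss(peak_df("chr1", 1400, 1600), tie_genes)
  expect_identical(tie$gene, "eta")
  expect_true(tie$tie)

  set.seed(42)
  bs <- sample.int(5e5, 100)
  genes <- gene_model_df(sprintf("g%03d", 1:100),
                         sample(c("chr1", "chr2"), 100, TRUE),
                         sample(c("+", "-"), 100, TRUE),
                         body_start = bs,
                         body_end = bs + sample.int(2e4, 100))
  ps <- sample.int(5e5, 50)
  peaks <- peak_df(sample(c("chr1", "chr2"), 50, TRUE), ps, ps + 300)
  got <- annotate_nearest_tss(peaks, genes, max_dist = 50000L)
  expect_lte(max(table(got$peak_id)), 1)  # at most one record per peak
  for (i in seq_len(nrow(peaks))) {
    d <- vapply(seq_len(nrow(genes)), function(j) {
      if (genes$chrom[j] != peaks$chrom[i]) return(NA_integer_)
      as.integer(bf_tss_distance(peaks[i, ], genes[j, ]))
    }, integer(1))
    ok <- which(!is.na(d) & abs(d) <= 50000)
    row <- got[got$peak_id == i, ]
    if (length(ok) == 0) {
      expect_identical(nrow(row), 0L)
    } else {
      best <- ok[abs(d[ok]) == min(abs(d[ok]))]
      expect_identical(row$gene, sort(genes$symbol[best])[1])
      expect_true(all(genes$chrom[match(row$gene, genes$symbol)] == row$chrom))
    }
  }
})

test_that("window annotation equals the brute-force footprint oracle", {
  genes <- make_toy_genes()
  expect_identical(annotate_window(peak_df("chr1", 1500, 1700), genes)$gene,
                   "alpha")
  # 6 kb upstream of a + gene with a 5 kb margin: excluded
  g_far <- gene_model_df("delta", "chr3", "+", 20000, 30000)
  far <- peak_df("chr3", 20000 - 6000 - 200, 20000 - 6000)
  expect_identical(nrow(annotate_window(far, g_far)), 0L)

  set.seed(43)
  bs <- sample.int(2e5, 40)
  genes <- gene_model_df(sprintf("g%02d", 1:40), "chr1",
                         sample(c("+", "-"), 40, TRUE),
                         body_start = bs,
                         body_end = bs + sample.int(1e4, 40))
  ps <- sample.int(2e5, 30)
  peaks <- peak_df("chr1", ps, ps + 400)
  up <- 5000; down <- 1000
  got <- annotate_window(peaks, genes, up, down)
  for (i in seq_len(nrow(peaks))) {
    hits <- character(0)
    for (j in seq_len(nrow(genes))) {
      fs <- if (genes$strand[j] == "+") genes$body_start[j] - up else genes$body_start[j] - down
      fe <- if (genes$strand[j] == "+") genes$body_end[j] + down else genes$body_end[j] + up
      w <- min(peaks$end[i], fe) - max(peaks$start[i], fs)
      if (w >= 1) hits <- c(hits, genes$symbol[j])
    }
    expect_setequal(got$gene[got$peak_id == i], hits)
  }
})

test_that("decay annotation has the stated closed forms and summation score", {
  g <- gene_model_df("g", "chr1", "+", 50000, 70000)
  at_tss <- peak_df("chr1", 49900, 50100)
  rec <- annotate_decay(at_tss, g, window = 100000L)
  expect_equal(rec$score, exp(-0.5), tolerance = 1e-12)
  at_edge <- peak_df("chr1", 149900, 150100)  # midpoint at exactly +100000
  rec <- annotate_decay(at_edge, g, window = 100000L)
  expect_equal(rec$score, exp(-4.5), tolerance = 1e-12)

  set.seed(44)
  ps <- sample.int(2e5, 25)
  peaks <- peak_df("chr1", ps, ps + 200)
  rec <- annotate_decay(peaks, g, window = 100000L)
  d <- vapply(seq_len(nrow(peaks)), function(i) bf_tss_distance(peaks[i, ], g),
              numeric(1))
  inside <- abs(d) <= 100000
  want <- sum(exp(-(0.5 + 4 * abs(d[inside]) / 100000)))
  expect_setequal(rec$peak_id, which(inside))
  expect_equal(unique(rec$score), want, tolerance = 1e-12)
})

test_that("shrinking range parameters never adds annotations", {
  set.seed(45)
  bs <- sample.int(3e5, 20)
  genes <- gene_model_df(sprintf("g%02d", 1:20), "chr1",
                         sample(c("+", "-"), 20, TRUE),
                         body_start = bs,
                         body_end = bs + 5000)
  ps <- sample.int(3e5, 15)
  peaks <- peak_df("chr1", ps, ps + 300)
  key <- function(df) paste(df$peak_id, df$gene)
  wide <- annotate_nearest_tss(peaks, genes, max_dist = 100000L)
  narrow <- annotate_nearest_tss(peaks, genes, max_dist = 10000L)
  expect_true(all(key(narrow) %in% key(wide)))
  wide <- annotate_decay(peaks, genes, window = 100000L)
  narrow <- annotate_decay(peaks, genes, window = 20000L)
  expect_true(all(key(narrow) %in% key(wide)))
  wide <- annotate_window(peaks, genes, 10000L, 5000L)
  narrow <- annotate_window(peaks, genes, 2000L, 500L)
  expect_true(all(key(narrow) %in% key(wide)))
})
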