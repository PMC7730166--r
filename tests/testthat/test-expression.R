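test_that("expression calling uses strict mean Ct < 35", {
  ct <- toy_ct(c(rep(34.9, 4), rep(35.0, 4), rep(20, 4)),
               group = c("control", "control", "case", "case"),
               genes = c("low", "boundary", "GAPDH"))
  ex <- call_expressed(ct)
  expect_true(ex[["low"]])
  expect_false(ex[["boundary"]])

  m <- matrix(c(rep(20, 4), rep(NA_real_, 4), rep(18, 4)), nrow = 4,
              dimnames = list(NULL, c("ok", "void", "GAPDH")))
  ex <- call_expressed(ct_matrix(m, rep(c("control", "case"), 2)))
  expect_false(ex[["void"]])
  expect_identical(attr(ex, "all_missing"), "void")

  # planted non-expressed genes are exactly the ones not called
  cfg <- sim_config(seed = 33, nonexpressed_genes = c("g2", "g5"))
  sim <- make_ct_matrix(cfg, sprintf("g%d", 1:6))
  ex <- call_expressed(sim$ct)
  expect_setequal(names(ex)[ex], sim$truth$expressed)
})

test_that("delta-delta-Ct has its closed forms and matches direct recomputation", {
  ct <- toy_ct(c(rep(25, 6), rep(25, 6)), group = rep(c("control", "case"), 3),
               genes = c("flat", "GAPDH"))
  res <- delta_delta_ct(ct)
  expect_equal(res$fold_change[res$gene == "flat"], 1)

  # case dCt exactly one cycle below control: ddCt = -1, fold change 2
  m <- cbind(gene = c(24, 24, 24, 23, 23, 23), GAPDH = rep(20, 6))
  ct <- ct_matrix(m, c(rep("control", 3), rep("case", 3)))
  res <- delta_delta_ct(ct)
  expect_equal(res$delta_delta_ct[res$gene == "gene"], -1)
  expect_equal(res$fold_change[res$gene == "gene"], 2)

  set.seed(55)
  m <- matrix(runif(23 * 5, 20, 30), nrow = 23,
              dimnames = list(NULL, c(sprintf("g%d", 1:4), "GAPDH")))
  grp <- c(rep("control", 6), rep("case", 17))
  res <- delta_delta_ct(ct_matrix(m, grp))
  for (g in sprintf("g%d", 1:4)) {
    dct <- m[, g] - m[, "GAPDH"]
    want <- mean(dct[grp == "case"]) - mean(dct[grp == "control"])
    row <- res[res$gene == g, ]
    expect_equal(row$delta_delta_ct, want, tolerance = 1e-12)
    expect_equal(row$fold_change, 2^-want, tolerance = 1e-12)
    expect_equal(row$sem_dct_control,
                 sd(dct[grp == "control"]) / sqrt(6), tolerance = 1e-12)
  }
  # fold-change symmetry: fc(d) * fc(-d) = 1
  expect_equal(res$fold_change * 2^res$delta_delta_ct, rep(1, 5),
               tolerance = 1e-12)
})

test_that("the differential stage reproduces the pooled t closed form", {
  a <- c(1.1, 1.9, 1.5); b <- c(2.4, 3.0, 2.7)  # control / case dCt
  m <- cbind(gene = c(a, b) + 20, GAPDH = rep(20, 6))
  ct <- ct_matrix(m, c(rep("control", 3), rep("case", 3)))
  res <- differential_test(ct)
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(b) - mean(a)) / (sp * sqrt(1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  row <- res[res$gene == "gene", ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$p_value, p_hand, tolerance = 1e-12)
  expect_true(row$significant)
  expect_identical(row$direction, "down")  # higher Ct in cases = lower expression

  # identical group means with positive variance: t = 0, p = 1
  m <- cbind(gene = c(1, 2, 3, 1, 2, 3) + 20, GAPDH = rep(20, 6))
  res <- differential_test(ct_matrix(m, c(rep("control", 3), rep("case", 3))))
  expect_equal(res$t[res$gene == "gene"], 0)
  expect_equal(res$p_value[res$gene == "gene"], 1)

  # the endogenous control is degenerate by construction, never significant
  expect_true(res$degenerate[res$gene == "GAPDH"])
  expect_false(res$significant[res$gene == "GAPDH"])
})

test_that("a planted 1.5-cycle shift at 6 vs 17 is essentially always detected", {
  set.seed(66)
  hits <- 0L
  for (r in 1:200) {
    grp <- c(rep("control", 6), rep("case", 17))
    base <- 25 + rnorm(23, 0, 0.3)
    shifted <- base + ifelse(grp == "case", 1.5, 0) + rnorm(23, 0, 0.3)
    m <- cbind(gene = shifted, GAPDH = 18 + rnorm(23, 0, 0.3))
    res <- differential_test(ct_matrix(m, grp))
    if (res$significant[res$gene == "gene"]) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99)
})

test_that("null p-values are uniform (KS on seeded null simulations)", {
  set.seed(77)
  grp <- c(rep("control", 6), rep("case", 17))
  pvals <- vapply(1:2000, function(r) {
    m <- cbind(gene = 25 + rnorm(23, 0, 0.3), GAPDH = rep(18, 23))
    differential_test(ct_matrix(m, grp))$p_value[1]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene clustering is average linkage on 1 - Pearson with stated edge cases", {
  set.seed(88)
  base <- rnorm(10)
  d <- cbind(a = base, b = base, c = -base + rnorm(10, 0, 0.01),
             e = rnorm(10))
  cl <- cluster_genes(d)
  # identical profiles merge first at height 0
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  first <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-first], c("a", "b"))
  # anti-correlated profiles sit at distance ~2
  dd <- as.matrix(1 - cor(d))
  expect_gt(dd["a", "c"], 1.9)
  expect_true(grepl("^\\(", cl$newick))
  expect_s3_class(ape::read.tree(text = cl$newick), "phylo")

  # zero-variance profile: distance 1 to everything, flagged
  dz <- cbind(a = base, z = rep(0, 10))
  clz <- cluster_genes(dz)
  expect_identical(clz$flagged, "z")
  expect_equal(clz$hclust$height[1], 1, tolerance = 1e-12)

  # merge heights equal the naive agglomeration oracle on 5 genes
  d5 <- matrix(rnorm(50), 10, dimnames = list(NULL, letters[1:5]))
  cl5 <- cluster_genes(d5)
  dmat <- 1 - cor(d5)
  expect_equal(sort(cl5$hclust$height),
               sort(bf_average_linkage_heights(dmat)), tolerance = 1e-12)
})

test_that("Ct matrix TSV round-trips including missing wells", {
  m <- matrix(c(20.5, NA, 22, 30, 18, 18.2), nrow = 2,
              dimnames = list(c("P1", "P2"), c("g1", "g2", "GAPDH")))
  ct <- ct_matrix(m, c("control", "case"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ct_matrix(ct, path)
  back <- read_ct_matrix(path)
  expect_equal(back$ct, ct$ct)
  expect_identical(back$group, ct$group)
})
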