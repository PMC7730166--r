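#' Ct matrices
#'
#' Quantification-cycle (Ct) data are stored as a samples x genes numeric
#' matrix with missing wells as `NA`, a group label per sample
#' (`"control"` / `"case"`) and the symbol of the endogenous control gene
#' (default GAPDH). Lower Ct means higher expression.
#'
#' @param ct numeric matrix, rows = samples, columns = genes (colnames
#'   required; rownames optional sample ids).
#' @param group character/factor of length `nrow(ct)` with levels
#'   `control`, `case`.
#' @param endogenous_control symbol of the reference gene, must be a
#'   column of `ct`.
#' @return A `ct_matrix` object.
#' @export
ct_matrix <- function(ct, group, endogenous_control = "GAPDH") {
  ct <- as.matrix(ct)
  if (is.null(colnames(ct))) stop("ct needs gene column names")
  group <- as.character(group)
  if (length(group) != nrow(ct)) stop("one group label per sample required")
  if (!all(group %in% c("control", "case")))
    stop("groups must be 'control' or 'case'")
  if (!endogenous_control %in% colnames(ct))
    stop("endogenous control gene absent from the matrix")
  bad <- !is.na(ct) & (ct <= 0 | ct > 45)
  if (any(bad)) stop("Ct values must lie in (0, 45] or be missing")
  if (is.null(rownames(ct))) rownames(ct) <- sprintf("S%02d", seq_len(nrow(ct)))
  structure(list(ct = ct, group = group,
                 endogenous_control = endogenous_control),
            class = "ct_matrix")
}

#' Read/write a Ct matrix TSV
#'
#' Layout: one row per sample; first column `sample`, second column
#' `group`, remaining columns one per gene. Missing wells are written as
#' `NA`.
#'
#' @param path file path.
#' @param x `ct_matrix`.
#' @param endogenous_control passed to [ct_matrix()] when reading.
#' @return `read_ct_matrix` returns a `ct_matrix`.
#' @export
read_ct_matrix <- function(path, endogenous_control = "GAPDH") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$sample
  ct_matrix(m, df$group, endogenous_control = endogenous_control)
}

#' @rdname read_ct_matrix
#' @export
write_ct_matrix <- function(x, path) {
  df <- data.frame(sample = rownames(x$ct), group = x$group,
                   x$ct, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call genes expressed from mean Ct
#'
#' A gene is called expressed when its mean Ct across non-missing wells is
#' strictly below `threshold` (35 cycles by default, the usual array
#' guidance). Genes with no non-missing well are not expressed and are
#' flagged in the `all_missing` attribute.
#'
#' @param x `ct_matrix`.
#' @param threshold Ct cutoff (strict `<`).
#' @param samples optional restriction: `"all"` (default), `"control"` or
#'   `"case"`.
#' @return Named logical vector over genes.
#' @export
call_expressed <- function(x, threshold = 35, samples = c("all", "control", "case")) {
  samples <- match.arg(samples)
  m <- x$ct
  if (samples != "all") m <- m[x$group == samples, , drop = FALSE]
  mean_ct <- colMeans(m, na.rm = TRUE)
  out <- !is.nan(mean_ct) & mean_ct < threshold
  attr(out, "all_missing") <- colnames(m)[colSums(!is.na(m)) == 0]
  out
}

#' Per-sample delta-Ct normalization
#'
#' `dCt(sample, gene) = Ct(gene) - Ct(endogenous control)` in the same
#' sample. Samples missing the control-gene Ct are dropped with a warning.
#'
#' @param x `ct_matrix`.
#' @return Samples x genes matrix of delta-Ct values with the surviving
#'   group labels in attribute `group`.
#' @export
delta_ct <- function(x) {
  ref <- x$ct[, x$endogenous_control]
  keep <- !is.na(ref)
  if (!all(keep))
    warning(sum(!keep), " sample(s) dropped: missing control-gene Ct")
  d <- x$ct[keep, , drop = FALSE] - ref[keep]
  attr(d, "group") <- x$group[keep]
  d
}

#' Comparative delta-delta-Ct quantification
#'
#' `ddCt(gene) = mean case dCt - mean control dCt`; relative expression
#' (fold change) is `2^-ddCt`, so genes with lower Ct in cases (higher
#' expression) get fold changes above 1.
#'
#' @param x `ct_matrix`.
#' @return Data frame with `gene`, `delta_delta_ct`, `fold_change`, group
#'   means and SEMs of dCt.
#' @export
delta_delta_ct <- function(x) {
  d <- delta_ct(x)
  grp <- attr(d, "group")
  sem <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }
  ctrl <- d[grp == "control", , drop = FALSE]
  case <- d[grp == "case", , drop = FALSE]
  mean_ctrl <- colMeans(ctrl, na.rm = TRUE)
  mean_case <- colMeans(case, na.rm = TRUE)
  ddct <- mean_case - mean_ctrl
  data.frame(
    gene = colnames(d),
    delta_delta_ct = unname(ddct),
    fold_change = unname(2^(-ddct)),
    mean_dct_control = unname(mean_ctrl),
    sem_dct_control = unname(apply(ctrl, 2, sem)),
    mean_dct_case = unname(mean_case),
    sem_dct_case = unname(apply(case, 2, sem)),
    stringsAsFactors = FALSE
  )
}

#' Two-group differential test on delta-Ct
#'
#' A two-sided two-sample t-test (Student's pooled-variance by default,
#' Welch by flag) on per-sample delta-Ct between case and control, gene by
#' gene; significance at `p <= alpha` with no multiple-testing correction
#' by default (a Benjamini-Hochberg option is available). Direction is
#' `up` when the fold change exceeds 1 and the gene is significant, `down`
#' when below 1 and significant, else `unchanged`. Degenerate genes
#' (fewer than 2 usable values in a group, or zero variance in both groups
#' at equal means) get `NA` statistics and are never significant.
#'
#' @param x `ct_matrix`.
#' @param alpha significance level (default 0.05).
#' @param variant `"student"` (default) or `"welch"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame: the [delta_delta_ct()] columns plus `t`, `p_value`,
#'   `significant`, `direction`, `degenerate`.
#' @export
differential_test <- function(x, alpha = 0.05,
                              variant = c("student", "welch"),
                              adjust = c("none", "BH")) {
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  d <- delta_ct(x)
  grp <- attr(d, "group")
  base <- delta_delta_ct(x)
  stat <- lapply(colnames(d), function(g) {
    a <- d[grp == "control", g]; a <- a[!is.na(a)]
    b <- d[grp == "case", g]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2 ||
        (stats::sd(a) == 0 && stats::sd(b) == 0))
      return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
    tt <- stats::t.test(b, a, var.equal = (variant == "student"))
    list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  })
  base$t <- vapply(stat, `[[`, numeric(1), "t")
  base$p_value <- vapply(stat, `[[`, numeric(1), "p")
  base$degenerate <- vapply(stat, `[[`, logical(1), "degenerate")
  p_adj <- if (adjust == "BH") stats::p.adjust(base$p_value, "BH") else base$p_value
  base$significant <- !is.na(p_adj) & p_adj <= alpha
  base$direction <- ifelse(!base$significant, "unchanged",
                           ifelse(base$fold_change > 1, "up", "down"))
  base
}

#' Hierarchical clustering of gene delta-Ct profiles
#'
#' Genes are clustered on `1 - Pearson r` between their delta-Ct profiles
#' across samples, with average linkage — the standard layout of qPCR
#' heat maps. Zero-variance profiles have undefined correlation; their
#' distance to every other gene is set to 1 and they are flagged. Genes
#' are ordered alphabetically before clustering so ties resolve
#' deterministically.
#'
#' @param d samples x genes delta-Ct matrix (e.g. from [delta_ct()]), at
#'   least 2 genes and 2 samples.
#' @return List: `hclust` (the tree), `order` (leaf symbols left to
#'   right), `flagged` (zero-variance genes), `newick` (the tree as a
#'   Newick string via `ape`).
#' @export
cluster_genes <- function(d) {
  if (ncol(d) < 2 || nrow(d) < 2) stop("need >= 2 genes and >= 2 samples")
  d <- d[, order(colnames(d)), drop = FALSE]
  sds <- apply(d, 2, stats::sd)
  flagged <- colnames(d)[sds == 0]
  cr <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  dist_m <- 1 - cr
  dist_m[is.na(dist_m)] <- 1
  diag(dist_m) <- 0
  hc <- stats::hclust(stats::as.dist(dist_m), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$labels[hc$order], flagged = flagged,
       newick = ape::write.tree(phy))
}
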