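# Brute-force oracles, kept independent of the implementation paths they
# check: per-base masks for interval algebra, direct summations for tail
# probabilities and decay scores, exhaustive counting for the consensus
# vote, and a naive average-linkage agglomerator.

# per-base occupancy oracle for half-open intervals on small coordinates
bf_covered_bases <- function(df, max_coord = 1000L) {
  masks <- list()
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    if (is.null(masks[[ch]])) masks[[ch]] <- logical(max_coord)
    s <- df$start[i]; e <- df$end[i]
    if (e > s) masks[[ch]][(s + 1):e] <- TRUE
  }
  masks
}

bf_overlap_width <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  max(0L, min(a$end, b$end) - max(a$start, b$start))
}

bf_subtract <- function(chip, igg, min_bp = 1L) {
  keep <- vapply(seq_len(nrow(chip)), function(i) {
    for (j in seq_len(nrow(igg))) {
      if (bf_overlap_width(chip[i, ], igg[j, ]) >= min_bp) return(FALSE)
    }
    TRUE
  }, logical(1))
  chip[keep, , drop = FALSE]
}

bf_poisson_tail <- function(count, lam) {
  if (count == 0) return(1)
  # direct summation of the upper-tail pmf (truncated far beyond the mass)
  upper <- max(count + 60, ceiling(lam + 60 * sqrt(lam + 1)))
  sum(dpois(count:upper, lam))
}

# exhaustive gene selection by direct counting
bf_select <- function(ev, min_tools = 2L, min_pools = 2L,
                      quorum = "per_pool") {
  sel <- character(0)
  for (g in unique(ev$gene)) {
    e <- ev[ev$gene == g, , drop = FALSE]
    ok <- if (quorum == "per_pool") {
      n_support <- 0L
      for (p in unique(e$pool)) {
        if (length(unique(e$annotator[e$pool == p])) >= min_tools)
          n_support <- n_support + 1L
      }
      n_support >= min_pools
    } else {
      length(unique(e$annotator)) >= min_tools &&
        length(unique(e$pool)) >= min_pools
    }
    if (ok) sel <- c(sel, g)
  }
  sort(sel)
}

# signed midpoint TSS distance, recomputed from scratch
bf_tss_distance <- function(peak, gene) {
  d <- floor((peak$start + peak$end) / 2) - gene$tss
  if (gene$strand == "-") -d else d
}

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_coord = 900L,
                            max_len = 60L) {
  s <- sample.int(max_coord - max_len, n, replace = TRUE)
  interval_df(sample(chroms, n, replace = TRUE), s,
              s + sample.int(max_len, n, replace = TRUE))
}

# naive average-linkage agglomeration recording merge heights
bf_average_linkage_heights <- function(dmat) {
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_to_regex <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(code) {
    b <- IUPAC_SETS[[code]]
    if (length(b) == 1) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# number of planted-base positions compatible with the consensus codes;
# EM phase is identifiable only up to a small shift, so the count is the
# best over ungapped offsets (|offset| <= 2), scored on the overlap only
# (Tomtom-style ungapped alignment)
consensus_matches <- function(consensus, planted, max_shift = 2L) {
  cs <- strsplit(consensus, "")[[1]]
  ps <- strsplit(planted, "")[[1]]
  best <- 0L
  for (off in -max_shift:max_shift) {
    i <- seq_along(cs)
    j <- i + off
    ok <- j >= 1 & j <= length(ps)
    n <- sum(mapply(function(c, p) p %in% IUPAC_SETS[[c]], cs[ok], ps[j[ok]]))
    best <- max(best, n)
  }
  best
}

# small Ct matrix built directly (bypassing the generator) for unit tests
toy_ct <- function(values, group, genes, control = "GAPDH") {
  m <- matrix(values, nrow = length(group), ncol = length(genes),
              dimnames = list(NULL, genes))
  ct_matrix(m, group, endogenous_control = control)
}
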