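#' Simulation configuration
#'
#' One object states the whole synthetic world: genome layout, the
#' replicated pool design (3 pools, 3 annotation tools), planted targets
#' with shared-region gene pairs, peak noise, the qPCR cohort (6 control
#' vs 17 case samples), and the planted sequence motif. Every generator is
#' a pure function of this object: the same config yields bitwise-identical
#' output.
#'
#' @param seed master seed; generators derive fixed offsets from it.
#' @param n_genes genes in the synthetic annotation.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param n_pools,n_tools replicate design.
#' @param n_true_targets genes given a real binding peak in every pool.
#' @param shared_region_pairs number of divergent target-gene pairs that
#'   share one binding region (exercises the region collapse).
#' @param peak_jitter_sd replicate jitter of peak centres, bp.
#' @param fp_peak_rate expected false peaks per pool (Poisson).
#' @param igg_peak_rate fraction of ChIP peaks mirrored in the IgG set.
#' @param n_control_samples,n_case_samples qPCR cohort sizes.
#' @param de_genes named numeric: Ct shift (cycles) added to case samples;
#'   negative shifts mean higher expression (upregulated) in cases.
#' @param ct_noise_sd well-to-well Gaussian noise, cycles.
#' @param nonexpressed_genes genes simulated above the 35-cycle call.
#' @param motif_consensus IUPAC string planted in region sequences.
#' @param motif_prob probability a sequence carries a motif instance.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L,
                       chrom_sizes = c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7),
                       n_pools = 3L, n_tools = 3L,
                       n_true_targets = 19L, shared_region_pairs = 2L,
                       peak_jitter_sd = 20, fp_peak_rate = 5,
                       igg_peak_rate = 0,
                       n_control_samples = 6L, n_case_samples = 17L,
                       de_genes = numeric(), ct_noise_sd = 0.3,
                       nonexpressed_genes = character(),
                       motif_consensus = "GTATRTGTGTGTGT", motif_prob = 1) {
  stopifnot(n_genes >= 1, n_pools >= 1, n_tools >= 1,
            n_true_targets <= n_genes,
            2 * shared_region_pairs <= n_true_targets,
            igg_peak_rate >= 0, igg_peak_rate <= 1,
            motif_prob >= 0, motif_prob <= 1,
            ct_noise_sd >= 0, peak_jitter_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a non-overlapping synthetic gene annotation
#'
#' Genes are laid out in disjoint slots (chromosomes filled in order) with
#' random strands and body lengths of 5-20 kb. The first
#' `2 * shared_region_pairs` genes are arranged as divergent pairs: the
#' second member of each pair is placed head-to-head with the first, TSSs
#' 1 kb apart, so a single peak between them is a shared binding region.
#'
#' @param cfg `sim_config`.
#' @return Gene-model data frame (`gene001`, `gene002`, ...).
#' @export
make_genome_annotation <- function(cfg) {
  set.seed(cfg$seed)
  n_chrom <- length(cfg$chrom_sizes)
  per_chrom <- ceiling(cfg$n_genes / n_chrom)
  slot <- floor(min(cfg$chrom_sizes) / per_chrom)
  if (slot < 80000) stop("chromosomes too small to pack genes without overlap")
  symbol <- sprintf("gene%03d", seq_len(cfg$n_genes))
  chrom <- rep(names(cfg$chrom_sizes), each = per_chrom)[seq_len(cfg$n_genes)]
  slot_idx <- unlist(lapply(table(factor(chrom, levels = names(cfg$chrom_sizes))),
                            seq_len), use.names = FALSE)
  len <- round(stats::runif(cfg$n_genes, 5000, 20000))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  body_start <- (slot_idx - 1) * slot + 30000
  body_end <- body_start + len
  # divergent shared-region pairs: re-anchor the even member against the odd
  if (cfg$shared_region_pairs > 0) {
    for (k in seq_len(cfg$shared_region_pairs)) {
      a <- 2L * k - 1L; b <- 2L * k
      strand[a] <- "+"
      strand[b] <- "-"
      chrom[b] <- chrom[a]
      body_end[b] <- body_start[a] - 1000
      body_start[b] <- body_end[b] - len[b]
      if (body_start[b] < 0) stop("slot too small for a divergent pair")
    }
  }
  gm <- gene_model_df(symbol, chrom, strand, body_start, body_end,
                      refseq = sprintf("SYN_%06d", seq_len(cfg$n_genes)))
  if (any(gm$body_end > cfg$chrom_sizes[gm$chrom]))
    stop("gene placement exceeds chromosome bounds")
  gm
}

# one planted peak (width 300) centred on x
.planted_peak <- function(chrom, x, pool, role = "chip") {
  peak_df(chrom, max(0, round(x) - 150), round(x) + 150,
          score = 100, fold_enrichment = 10, pool = pool, role = role)
}

#' Generate per-pool ChIP and IgG peak sets with planted truth
#'
#' Every true target receives one peak per pool near its TSS (divergent
#' pairs share a single peak at their common junction), jittered between
#' pools by `peak_jitter_sd`. False peaks are added at a Poisson rate per
#' pool, and a fraction `igg_peak_rate` of each pool's ChIP peaks is
#' mirrored at identical coordinates into the IgG set, so IgG subtraction
#' removes them.
#'
#' @param cfg `sim_config`.
#' @param genes gene models from [make_genome_annotation()].
#' @return List with `pools` (per pool: `chip`, `igg` peak data frames)
#'   and `truth` (`targets`, `pairs`, `gene_peaks` mapping each target to
#'   its planted coordinates).
#' @export
make_pool_peaksets <- function(cfg, genes) {
  set.seed(cfg$seed + 1L)
  targets <- genes$symbol[seq_len(cfg$n_true_targets)]
  pair_of <- integer(0)
  if (cfg$shared_region_pairs > 0)
    pair_of <- seq_len(2L * cfg$shared_region_pairs)
  # one planted site per region: pairs anchor at the divergent junction
  region_owner <- setdiff(seq_len(cfg$n_true_targets),
                          pair_of[pair_of %% 2 == 0])
  site_centre <- vapply(region_owner, function(i) {
    if (i %in% pair_of) {
      mean(c(genes$tss[i], genes$tss[i + 1L]))
    } else {
      genes$tss[i]
    }
  }, numeric(1))
  pools <- vector("list", cfg$n_pools)
  gene_peaks <- stats::setNames(vector("list", length(targets)), targets)
  for (p in seq_len(cfg$n_pools)) {
    jitter <- stats::rnorm(length(region_owner), 0, cfg$peak_jitter_sd)
    chip <- do.call(rbind, lapply(seq_along(region_owner), function(ri) {
      .planted_peak(genes$chrom[region_owner[ri]],
                    site_centre[ri] + jitter[ri], pool = p)
    }))
    for (ri in seq_along(region_owner)) {
      i <- region_owner[ri]
      members <- if (i %in% pair_of) genes$symbol[c(i, i + 1L)] else genes$symbol[i]
      for (g in members)
        gene_peaks[[g]] <- rbind(gene_peaks[[g]],
                                 chip[ri, c("chrom", "start", "end")])
    }
    n_fp <- stats::rpois(1, cfg$fp_peak_rate)
    if (n_fp > 0) {
      fp_chrom <- sample(names(cfg$chrom_sizes), n_fp, replace = TRUE)
      fp_x <- stats::runif(n_fp, 1000, cfg$chrom_sizes[fp_chrom] - 1000)
      chip <- rbind(chip, do.call(rbind, lapply(seq_len(n_fp), function(j)
        .planted_peak(fp_chrom[j], fp_x[j], pool = p))))
    }
    mirror <- stats::runif(nrow(chip)) < cfg$igg_peak_rate
    igg <- chip[mirror, , drop = FALSE]
    if (nrow(igg) > 0) {
      igg$role <- "igg"
      igg$pool <- p
    } else {
      igg <- peak_df(role = "igg")
    }
    pools[[p]] <- list(chip = chip, igg = igg)
  }
  gene_peaks <- lapply(gene_peaks, function(d) unique(d))
  list(pools = pools,
       truth = list(targets = targets,
                    pairs = if (length(pair_of)) genes$symbol[pair_of] else character(),
                    n_regions = length(region_owner),
                    gene_peaks = gene_peaks))
}

#' Generate a synthetic Ct matrix with planted structure
#'
#' Expressed genes get stable baselines in 22-30 cycles, the endogenous
#' control sits near 18 cycles, non-expressed genes are drawn uniformly in
#' 36-40 cycles (safely above the 35-cycle call at the default noise), and
#' the configured cycle shifts are added to case samples of the planted
#' differential genes. Gaussian well noise (sd `ct_noise_sd`) is applied
#' everywhere.
#'
#' @param cfg `sim_config`.
#' @param gene_list genes to simulate (the endogenous control is added).
#' @param endogenous_control reference gene symbol.
#' @return List: `ct` (a [ct_matrix()]) and `truth` (`expressed`,
#'   `de_genes` with their shifts).
#' @export
make_ct_matrix <- function(cfg, gene_list, endogenous_control = "GAPDH") {
  set.seed(cfg$seed + 2L)
  stopifnot(all(names(cfg$de_genes) %in% gene_list))
  genes <- union(gene_list, endogenous_control)
  n <- cfg$n_control_samples + cfg$n_case_samples
  group <- c(rep("control", cfg$n_control_samples),
             rep("case", cfg$n_case_samples))
  baseline <- stats::setNames(stats::runif(length(genes), 22, 30), genes)
  baseline[endogenous_control] <- 18
  nonexp <- intersect(cfg$nonexpressed_genes, genes)
  baseline[nonexp] <- stats::runif(length(nonexp), 36, 40)
  ct <- matrix(rep(baseline, each = n), nrow = n,
               dimnames = list(sprintf("S%02d", seq_len(n)), genes))
  for (g in names(cfg$de_genes))
    ct[group == "case", g] <- ct[group == "case", g] + cfg$de_genes[[g]]
  ct <- ct + matrix(stats::rnorm(n * length(genes), 0, cfg$ct_noise_sd),
                    nrow = n)
  ct <- pmin(pmax(ct, 1), 45)
  list(ct = ct_matrix(ct, group, endogenous_control = endogenous_control),
       truth = list(expressed = setdiff(genes, nonexp),
                    de_genes = cfg$de_genes))
}

.IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# sample one concrete realization of an IUPAC consensus
.sample_iupac <- function(consensus) {
  paste(vapply(strsplit(consensus, "", fixed = TRUE)[[1]], function(code) {
    b <- .IUPAC_BASES[[code]]
    if (is.null(b)) stop("unknown IUPAC code: ", code)
    if (length(b) == 1) b else sample(b, 1)
  }, character(1)), collapse = "")
}

#' Plant a degenerate motif in random background sequences
#'
#' Each sequence is uniform-background DNA; with probability `motif_prob`
#' one sampled realization of the IUPAC consensus is written at a uniform
#' position. Truth positions (1-based start, `NA` when absent) are
#' returned for recovery tests.
#'
#' @param cfg `sim_config` (uses `motif_consensus`, `motif_prob`, seed).
#' @param n_seqs number of sequences.
#' @param seq_length sequence length (>= motif length).
#' @return List: `seqs` (named character), `positions`, `consensus`.
#' @export
plant_motif <- function(cfg, n_seqs = 20L, seq_length = 100L) {
  w <- nchar(cfg$motif_consensus)
  if (seq_length < w) stop("seq_length must be >= motif length")
  set.seed(cfg$seed + 3L)
  seqs <- character(n_seqs)
  positions <- rep(NA_integer_, n_seqs)
  for (i in seq_len(n_seqs)) {
    s <- sample(c("A", "C", "G", "T"), seq_length, replace = TRUE)
    if (stats::runif(1) < cfg$motif_prob) {
      pos <- sample(seq_length - w + 1L, 1)
      s[pos:(pos + w - 1L)] <- strsplit(.sample_iupac(cfg$motif_consensus),
                                        "", fixed = TRUE)[[1]]
      positions[i] <- pos
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- sprintf("region%02d", seq_len(n_seqs))
  list(seqs = seqs, positions = positions, consensus = cfg$motif_consensus)
}
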