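#!/usr/bin/env Rscript

# Stage 1 — state the synthetic world and write every pipeline input.
#
# The generators emulate the design of the study: 3 ChIP library pools
# with matched IgG controls, 19 planted target genes of which two
# divergent pairs share a binding region (so 17 distinct regions), a
# qPCR cohort of 6 controls vs 17 cases with five planted expression
# shifts, and binding-region sequences carrying a degenerate GT-rich
# motif. Everything is a pure function of the seed.

suppressPackageStartupMessages(library(peakcons))

seed <- 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  seed = seed, n_genes = 120, n_true_targets = 19, shared_region_pairs = 2,
  peak_jitter_sd = 20, fp_peak_rate = 5, igg_peak_rate = 0.15,
  n_control_samples = 6, n_case_samples = 17,
  de_genes = c(gene001 = -1.5, gene002 = -1.5, gene005 = -1.5,
               gene007 = 1.5, gene010 = 1.5),
  ct_noise_sd = 0.3, nonexpressed_genes = c("gene011", "gene012"),
  motif_consensus = "GTATRTGTGTGTGT", motif_prob = 0.9
)

genes <- make_genome_annotation(cfg)
write.table(genes, file.path(out, "gene_models.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sim <- make_pool_peaksets(cfg, genes)
for (p in seq_along(sim$pools)) {
  write_peaks_bed(sim$pools[[p]]$chip,
                  file.path(out, sprintf("pool%d_chip.bed", p)))
  if (nrow(sim$pools[[p]]$igg) > 0)
    write_peaks_bed(sim$pools[[p]]$igg,
                    file.path(out, sprintf("pool%d_igg.bed", p)))
}
writeLines(sim$truth$targets, file.path(out, "truth_targets.txt"))

ctm <- make_ct_matrix(cfg, c(sprintf("gene%03d", 1:10),
                             cfg$nonexpressed_genes))
write_ct_matrix(ctm$ct, file.path(out, "ct_matrix.tsv"))

pm <- plant_motif(cfg, n_seqs = 17, seq_length = 120)
write_fasta_seqs(pm$seqs, file.path(out, "region_sequences.fa"))

cat(sprintf("simulated %d genes, %d pools (%s chip peaks), %d Ct samples, %d region sequences\n",
            nrow(genes), length(sim$pools),
            paste(vapply(sim$pools, function(p) nrow(p$chip), integer(1)),
                  collapse = "/"),
            nrow(ctm$ct$ct), length(pm$seqs)))
cat(sprintf("truth: %d targets in %d distinct regions; DE planted in %s\n",
            length(sim$truth$targets), sim$truth$n_regions,
            paste(names(cfg$de_genes), collapse = ", ")))
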