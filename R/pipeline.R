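#' Run the target-discovery workflow
#'
#' Executes the full funnel on per-pool inputs: optional peak calling from
#' binned coverage, IgG-control subtraction, the three peak-to-gene
#' annotators, evidence assembly, the tool-and-pool consensus vote, the
#' binding-region collapse, and (when region sequences are supplied)
#' motif discovery. Every stage logs its input/output record counts.
#'
#' @param pools list with one element per pool. Each element is a list
#'   with `chip` (a peak data frame, or a list
#'   `list(treatment =, control =)` of [coverage_track()]s to be called)
#'   and optionally `igg` (peak data frame; may be `NULL` or empty).
#' @param genes gene-model data frame.
#' @param caller [caller_params()] used when coverage is supplied.
#' @param min_tools,min_pools,quorum consensus rule (see
#'   [select_targets()]).
#' @param igg_min_bp minimum overlap triggering IgG subtraction.
#' @param nearest_max_dist,window_upstream,window_downstream,decay_window
#'   annotator parameters (see [annotate_all()]).
#' @param sequences optional named character vector of binding-region
#'   sequences for motif discovery.
#' @param motif_width,motif_n_starts,motif_seed motif-search settings.
#' @param seed seed recorded in the result (and used for the motif search
#'   when `motif_seed` is `NULL`).
#' @return List: `consensus` (a `consensus_result`), `evidence`,
#'   `annotations` (per pool), `peaks` (post-subtraction, per pool),
#'   `gene_peaks`, `motif` (or `NULL`), `log` (stage count table),
#'   `seed`.
#' @export
run_target_discovery <- function(pools, genes,
                                 caller = caller_params(),
                                 min_tools = 2L, min_pools = 2L,
                                 quorum = "per_pool", igg_min_bp = 1L,
                                 nearest_max_dist = 300000L,
                                 window_upstream = 5000L,
                                 window_downstream = 1000L,
                                 decay_window = 100000L,
                                 sequences = NULL, motif_width = 14L,
                                 motif_n_starts = 5L, motif_seed = NULL,
                                 seed = 1L) {
  if (length(pools) == 0) stop("configuration error: no pools supplied")
  log <- list()
  note <- function(stage, n_in, n_out)
    log[[length(log) + 1]] <<- data.frame(stage = stage, n_in = n_in,
                                          n_out = n_out)
  peaks <- vector("list", length(pools))
  for (p in seq_along(pools)) {
    pool <- pools[[p]]
    if (is.null(pool$chip))
      stop(sprintf("configuration error: pool %d has no chip input", p))
    chip <- pool$chip
    if (!is.data.frame(chip)) {
      chip <- call_peaks(chip$treatment, chip$control, params = caller,
                         pool = p, role = "chip")
      note(sprintf("call_peaks.pool%d", p),
           length(pool$chip$treatment$counts), nrow(chip))
    }
    igg <- pool$igg
    if (!is.null(igg) && nrow(igg) > 0) {
      before <- nrow(chip)
      chip <- subtract_overlapping(chip, igg, min_bp = igg_min_bp)
      note(sprintf("igg_subtract.pool%d", p), before, nrow(chip))
    }
    peaks[[p]] <- chip
  }
  total_peaks <- sum(vapply(peaks, nrow, integer(1)))
  if (total_peaks == 0)
    warning("no peaks survive filtering; the result is empty")
  annotations <- lapply(seq_along(peaks), function(p) {
    annotate_all(peaks[[p]], genes, nearest_max_dist = nearest_max_dist,
                 window_upstream = window_upstream,
                 window_downstream = window_downstream,
                 decay_window = decay_window)
  })
  evidence <- evidence_from_pools(annotations, n_tools = 3L)
  note("evidence", total_peaks, nrow(evidence))
  gene_peaks <- .gene_peaks_from_annotations(annotations)
  consensus <- summarize_consensus(evidence, gene_peaks,
                                   min_tools = min_tools,
                                   min_pools = min_pools, quorum = quorum)
  note("consensus", length(unique(evidence$gene)),
       length(consensus$selected_genes))
  motif <- NULL
  if (!is.null(sequences) && length(sequences) > 0) {
    motif <- em_motif_search(sequences, width = motif_width,
                             n_starts = motif_n_starts,
                             seed = motif_seed %||% seed)
    motif <- scan_sites(motif, sequences)
    note("motif", length(sequences), motif$n_sites)
  }
  list(consensus = consensus, evidence = evidence,
       annotations = annotations, peaks = peaks, gene_peaks = gene_peaks,
       motif = motif, log = do.call(rbind, log), seed = seed)
}

# gene -> unique coordinate set of every peak any annotator assigned to it
.gene_peaks_from_annotations <- function(annotations) {
  rec <- do.call(rbind, unlist(annotations, recursive = FALSE))
  if (is.null(rec) || nrow(rec) == 0) return(list())
  lapply(split(rec, rec$gene), function(d) {
    iv <- unique(d[, c("chrom", "start", "end")])
    iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
    rownames(iv) <- NULL
    iv
  })
}

#' Run the candidate-evaluation workflow
#'
#' Maps discovered (mouse) target genes to human orthologs, drops the
#' targets with no known ortholog, unions in the interaction-derived
#' related genes, calls expression at the Ct threshold, and runs the
#' differential stage on expressed genes only.
#'
#' @param targets character vector of (mouse) target gene symbols.
#' @param related_genes character vector of additional (human) genes.
#' @param ortholog_map data frame with columns `mouse_symbol`,
#'   `human_symbol` (`NA` = unknown ortholog).
#' @param ct a [ct_matrix()], or `NULL` to stop after candidate assembly.
#' @param alpha significance level for the differential stage.
#' @param ct_threshold expression-call cutoff in cycles.
#' @param expression_samples which samples feed the expression call
#'   (`"all"`, `"control"` or `"case"`).
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @return List: `candidates` (data frame gene/source), `excluded_no_ortholog`
#'   (mouse symbols), `results` (per-candidate expression table or `NULL`).
#' @export
run_candidate_evaluation <- function(targets, related_genes, ortholog_map,
                                     ct = NULL, alpha = 0.05,
                                     ct_threshold = 35,
                                     expression_samples = "all",
                                     variant = "student") {
  human <- ortholog_map$human_symbol[match(targets, ortholog_map$mouse_symbol)]
  unmapped_in_map <- targets[!is.na(match(targets, ortholog_map$mouse_symbol)) &
                               is.na(human)]
  not_in_map <- targets[is.na(match(targets, ortholog_map$mouse_symbol))]
  if (length(not_in_map) > 0)
    warning("targets absent from the ortholog map are dropped: ",
            paste(not_in_map, collapse = ", "))
  mapped <- unique(human[!is.na(human)])
  extra_related <- setdiff(unique(related_genes), mapped)
  candidates <- rbind(
    data.frame(gene = mapped,
               source = rep("chipseq_target", length(mapped)),
               stringsAsFactors = FALSE),
    data.frame(gene = extra_related,
               source = rep("related", length(extra_related)),
               stringsAsFactors = FALSE)
  )
  candidates <- candidates[order(candidates$source, candidates$gene), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  results <- NULL
  if (!is.null(ct)) {
    present <- intersect(candidates$gene, colnames(ct$ct))
    extra <- setdiff(colnames(ct$ct),
                     c(candidates$gene, ct$endogenous_control))
    if (length(extra) > 0)
      warning("Ct matrix genes outside the candidate set ignored: ",
              paste(extra, collapse = ", "))
    expressed <- call_expressed(ct, threshold = ct_threshold,
                                samples = expression_samples)
    de <- differential_test(ct, alpha = alpha, variant = variant)
    results <- candidates
    results$in_ct <- results$gene %in% present
    results$expressed <- ifelse(results$in_ct, expressed[results$gene], NA)
    idx <- match(results$gene, de$gene)
    for (col in c("delta_delta_ct", "fold_change", "t", "p_value"))
      results[[col]] <- ifelse(results$in_ct & results$expressed,
                               de[[col]][idx], NA_real_)
    results$significant <- results$in_ct & !is.na(results$expressed) &
      results$expressed & de$significant[idx]
    results$direction <- ifelse(results$significant,
                                de$direction[idx], "unchanged")
    results$direction[!results$in_ct | !results$expressed] <- NA
  }
  list(candidates = candidates,
       excluded_no_ortholog = unmapped_in_map,
       results = results)
}
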