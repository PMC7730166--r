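#' Packaged worked-example fixtures
#'
#' Three small tables ship with the package: a published 38-row peak table
#' (19 mouse target genes, two replicate peaks each, some coordinate sets
#' shared between divergent gene pairs), the 16 + 10 candidate gene lists,
#' and a mouse-to-human ortholog map in which exactly three mouse genes
#' have no known human ortholog. Loaders validate the transcription on
#' every read so a corrupted install fails loudly rather than silently.
#'
#' @return `peak_table_fixture()`: a data frame with columns `gene_symbol`,
#'   `refseq_id`, `tss_distance`, `chrom`, `start`, `end`, `length`,
#'   `score`, `fold_enrichment`, `pool`.
#' @export
peak_table_fixture <- function() {
  path <- system.file("extdata", "peak_table.tsv", package = "peakcons",
                      mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(df) != 38 || length(unique(df$gene_symbol)) != 19)
    stop("peak-table fixture corrupted: wrong row or gene count")
  if (!all(df$length == df$end - df$start))
    stop("peak-table fixture corrupted: length != end - start")
  if (!all(df$pool %in% 1:3) || !all(df$score > 50))
    stop("peak-table fixture corrupted: pool or score out of range")
  df
}

#' @return `peak_table_gene_peaks()`: the fixture reshaped to the named list
#'   (gene -> interval data frame) consumed by
#'   [collapse_shared_regions()].
#' @rdname peak_table_fixture
#' @export
peak_table_gene_peaks <- function() {
  df <- peak_table_fixture()
  lapply(split(df, df$gene_symbol),
         function(d) interval_df(d$chrom, d$start, d$end))
}

#' Replay the packaged peak table as consensus evidence
#'
#' Each row of the table is a peak retained by the full published pipeline,
#' i.e. supported by all three annotation tools in its pool; the replay
#' marks the row's gene present for all three annotators in that pool and
#' feeds the result to the consensus vote.
#'
#' @param n_tools number of annotators to credit per row (default 3).
#' @return Evidence data frame suitable for [select_targets()].
#' @rdname peak_table_fixture
#' @export
peak_table_evidence <- function(n_tools = 3L) {
  df <- peak_table_fixture()
  tools <- sprintf("tool%d", seq_len(n_tools))
  ev <- expand.grid(i = seq_len(nrow(df)), annotator = tools,
                    stringsAsFactors = FALSE)
  ev <- data.frame(gene = df$gene_symbol[ev$i], pool = df$pool[ev$i],
                   annotator = ev$annotator, stringsAsFactors = FALSE)
  ev <- unique(ev)
  ev <- ev[order(ev$gene, ev$pool, ev$annotator), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "n_pools") <- 3L
  attr(ev, "n_tools") <- as.integer(n_tools)
  ev
}

#' @return `candidate_genes_fixture()`: data frame with `gene`, `source`
#'   (`chipseq_target` / `related`), `name` — 16 target and 10 related
#'   genes.
#' @rdname peak_table_fixture
#' @export
candidate_genes_fixture <- function() {
  path <- system.file("extdata", "candidate_genes.tsv", package = "peakcons",
                      mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  if (sum(df$source == "chipseq_target") != 16 || sum(df$source == "related") != 10)
    stop("candidate-list fixture corrupted")
  df
}

#' @return `ortholog_fixture()`: data frame with `mouse_symbol`,
#'   `human_symbol` (`NA` where no human ortholog is known).
#' @rdname peak_table_fixture
#' @export
ortholog_fixture <- function() {
  path <- system.file("extdata", "ortholog_map.tsv", package = "peakcons",
                      mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(df) != 19 || sum(is.na(df$human_symbol)) != 3)
    stop("ortholog fixture corrupted")
  df
}
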