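#' Gene models
#'
#' A gene model table has columns `symbol`, `refseq`, `chrom`, `strand`
#' (`"+"`/`"-"`), `tss`, `body_start`, `body_end`. The TSS must sit at the
#' strand-appropriate end of the gene body. Strand lives on genes only;
#' peaks are never strand-aware.
#'
#' @param symbol gene symbols.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param body_start,body_end gene body, half-open.
#' @param refseq optional transcript accessions.
#' @return A gene-model data frame; `tss` is derived from strand.
#' @export
gene_model_df <- function(symbol, chrom, strand, body_start, body_end,
                          refseq = NA_character_) {
  stopifnot(all(strand %in% c("+", "-")), all(body_end >= body_start))
  tss <- ifelse(strand == "+", body_start, body_end)
  data.frame(symbol = as.character(symbol), refseq = as.character(refseq),
             chrom = as.character(chrom), strand = as.character(strand),
             tss = as.numeric(tss), body_start = as.numeric(body_start),
             body_end = as.numeric(body_end), stringsAsFactors = FALSE)
}

#' Read a gene-model TSV
#'
#' Expects columns `symbol`, `refseq`, `chrom`, `strand`, `tss`,
#' `body_start`, `body_end` (header required).
#'
#' @param path file path.
#' @return Gene-model data frame.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("symbol", "refseq", "chrom", "strand", "tss", "body_start", "body_end")
  if (!all(need %in% names(df))) stop("missing gene-model columns")
  df[, need]
}

#' Signed strand-oriented TSS distance
#'
#' Distance from a gene's TSS to the peak midpoint (`floor((start+end)/2)`),
#' oriented by the gene's reading direction: positive means the peak lies
#' downstream of the TSS, negative upstream.
#'
#' @param peaks peak data frame.
#' @param gene single-row gene model.
#' @return Signed integer distances (one per peak).
#' @export
tss_distance <- function(peaks, gene) {
  if (any(peaks$chrom != gene$chrom[1]))
    stop("peak and gene must lie on the same chromosome")
  mid <- floor((peaks$start + peaks$end) / 2)
  d <- mid - gene$tss[1]
  if (gene$strand[1] == "-") d <- -d
  as.integer(d)
}

# internal: empty annotation record table
.empty_annotation <- function() {
  data.frame(peak_id = integer(), chrom = character(), start = numeric(),
             end = numeric(), pool = integer(), gene = character(),
             tss_distance = integer(), annotator = character(),
             score = numeric(), tie = logical(), stringsAsFactors = FALSE)
}

.annotation_row <- function(peaks, i, gene, d, annotator, score = NA_real_,
                            tie = FALSE) {
  data.frame(peak_id = i, chrom = peaks$chrom[i], start = peaks$start[i],
             end = peaks$end[i], pool = peaks$pool[i], gene = gene,
             tss_distance = as.integer(d), annotator = annotator,
             score = score, tie = tie, stringsAsFactors = FALSE)
}

#' Nearest-TSS peak annotation
#'
#' Assigns each peak to the gene with the smallest absolute TSS distance,
#' provided it is within `max_dist`; peaks with no gene in range produce no
#' record. Equidistant genes are broken lexicographically by symbol and the
#' record is flagged `tie = TRUE`.
#'
#' @param peaks peak data frame.
#' @param genes gene-model data frame (non-empty).
#' @param max_dist maximum |TSS distance| in bp.
#' @return Annotation data frame with one row per assigned peak
#'   (`annotator = "nearest_tss"`).
#' @export
annotate_nearest_tss <- function(peaks, genes, max_dist = 300000L) {
  if (nrow(genes) == 0) stop("gene list must be non-empty")
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    d <- vapply(seq_len(nrow(g)), function(j)
      tss_distance(peaks[i, , drop = FALSE], g[j, , drop = FALSE]), integer(1))
    ok <- abs(d) <= max_dist
    if (!any(ok)) return(NULL)
    g <- g[ok, , drop = FALSE]; d <- d[ok]
    best <- abs(d) == min(abs(d))
    tie <- sum(best) > 1
    pick <- which(best)[order(g$symbol[best])][1]
    .annotation_row(peaks, i, g$symbol[pick], d[pick], "nearest_tss", tie = tie)
  })
  rows <- do.call(rbind, out)
  if (is.null(rows)) .empty_annotation() else rows
}

#' Windowed-footprint peak annotation
#'
#' A peak is assigned to every gene whose extended footprint (gene body
#' plus a strand-oriented upstream and downstream margin) it overlaps by at
#' least 1 bp.
#'
#' @param peaks peak data frame.
#' @param genes gene-model data frame.
#' @param upstream_bp,downstream_bp margins in bp (>= 0).
#' @return Annotation data frame (`annotator = "window"`), possibly several
#'   rows per peak.
#' @export
annotate_window <- function(peaks, genes, upstream_bp = 5000L,
                            downstream_bp = 1000L) {
  if (upstream_bp < 0 || downstream_bp < 0) stop("margins must be >= 0")
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    fs <- ifelse(g$strand == "+", g$body_start - upstream_bp,
                 g$body_start - downstream_bp)
    fe <- ifelse(g$strand == "+", g$body_end + downstream_bp,
                 g$body_end + upstream_bp)
    w <- pmin(peaks$end[i], fe) - pmax(peaks$start[i], fs)
    hit <- which(w >= 1)
    if (length(hit) == 0) return(NULL)
    do.call(rbind, lapply(hit, function(j) {
      d <- tss_distance(peaks[i, , drop = FALSE], g[j, , drop = FALSE])
      .annotation_row(peaks, i, g$symbol[j], d, "window")
    }))
  })
  rows <- do.call(rbind, out)
  if (is.null(rows)) .empty_annotation() else rows
}

#' Distance-decay regulatory-potential annotation
#'
#' For each gene, every peak within `window` bp of the TSS contributes
#' `exp(-(0.5 + 4 * d))` with `d = |tss_distance| / window` to the gene's
#' regulatory score; each contributing peak yields a record carrying the
#' gene's total score. A peak at the TSS contributes `exp(-0.5)`, a peak at
#' the window edge `exp(-4.5)`.
#'
#' @param peaks peak data frame.
#' @param genes gene-model data frame.
#' @param window half-width of the regulatory window in bp (> 0).
#' @return Annotation data frame (`annotator = "decay"`) with the per-gene
#'   score in `score`.
#' @export
annotate_decay <- function(peaks, genes, window = 100000L) {
  if (window <= 0) stop("window must be > 0")
  out <- lapply(seq_len(nrow(genes)), function(j) {
    g <- genes[j, , drop = FALSE]
    p <- which(peaks$chrom == g$chrom)
    if (length(p) == 0) return(NULL)
    d <- tss_distance(peaks[p, , drop = FALSE], g)
    ok <- abs(d) <= window
    if (!any(ok)) return(NULL)
    p <- p[ok]; d <- d[ok]
    contrib <- exp(-(0.5 + 4 * abs(d) / window))
    total <- sum(contrib)
    do.call(rbind, lapply(seq_along(p), function(k)
      .annotation_row(peaks, p[k], g$symbol, d[k], "decay", score = total)))
  })
  rows <- do.call(rbind, out)
  if (is.null(rows)) .empty_annotation() else rows
}

#' Run the three annotators on one peak set
#'
#' Convenience wrapper returning the three annotation tables in a named
#' list, the unit consumed by [build_evidence()].
#'
#' @param peaks peak data frame.
#' @param genes gene-model data frame.
#' @param nearest_max_dist,window_upstream,window_downstream,decay_window
#'   per-annotator range parameters.
#' @return Named list of annotation data frames
#'   (`nearest_tss`, `window`, `decay`).
#' @export
annotate_all <- function(peaks, genes, nearest_max_dist = 300000L,
                         window_upstream = 5000L, window_downstream = 1000L,
                         decay_window = 100000L) {
  list(
    nearest_tss = annotate_nearest_tss(peaks, genes, max_dist = nearest_max_dist),
    window = annotate_window(peaks, genes, upstream_bp = window_upstream,
                             downstream_bp = window_downstream),
    decay = annotate_decay(peaks, genes, window = decay_window)
  )
}
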