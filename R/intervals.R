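#' Genomic interval and peak tables
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` in
#' half-open coordinates `[start, end)`, so that `end - start` is the length
#' in bp. Peaks extend intervals with `score` (the enrichment p-value on the
#' -10*log10 scale), `fold_enrichment`, `pool` (replicate pool index) and
#' `role` (one of `"chip"`, `"input"`, `"igg"`).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end non-negative integer coordinates, `end >= start`.
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @export
interval_df <- function(chrom = character(), start = integer(), end = integer()) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (n > 0) {
    if (length(chrom) == 1) chrom <- rep_len(chrom, n)
    if (length(start) == 1) start <- rep_len(start, n)
    if (length(end) == 1) end <- rep_len(end, n)
  }
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(!nzchar(chrom))) stop("chrom names must be non-empty")
  if (any(start < 0)) stop("coordinates must be non-negative")
  if (any(end < start)) stop("end must be >= start")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Build a peak table
#'
#' @inheritParams interval_df
#' @param score peak score, -10*log10 of the enrichment p-value (>= 0).
#' @param fold_enrichment fold enrichment over the local background (>= 0).
#' @param pool integer pool index.
#' @param role library role: `"chip"`, `"input"` or `"igg"`.
#' @return A peak data frame (interval columns plus `length`, `score`,
#'   `fold_enrichment`, `pool`, `role`).
#' @export
peak_df <- function(chrom = character(), start = integer(), end = integer(),
                    score = 0, fold_enrichment = 0, pool = 1L,
                    role = c("chip", "input", "igg")) {
  role <- match.arg(role)
  iv <- interval_df(chrom, start, end)
  n <- nrow(iv)
  score <- rep_len(as.numeric(score), n)
  if (n > 0 && any(score < 0)) stop("scores on the -10*log10 p scale must be >= 0")
  iv$length <- iv$end - iv$start
  iv$score <- score
  iv$fold_enrichment <- rep_len(as.numeric(fold_enrichment), n)
  iv$pool <- rep_len(as.integer(pool), n)
  iv$role <- rep_len(role, n)
  iv
}

#' Peak length in bp
#'
#' Under half-open coordinates the length of a peak is exactly
#' `end - start`, which is how the published peak tables tabulate it.
#'
#' @param peaks interval or peak data frame.
#' @return Integer vector of lengths.
#' @export
peak_length <- function(peaks) {
  as.integer(peaks$end - peaks$start)
}

# internal: half-open data.frame -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

#' Test whether two intervals overlap
#'
#' @param a,b single-row interval data frames (or lists with `chrom`,
#'   `start`, `end`).
#' @param min_bp minimum overlap width in bp (>= 1).
#' @return `TRUE` iff the intervals share a chromosome and overlap by at
#'   least `min_bp` bases under half-open semantics.
#' @export
overlaps <- function(a, b, min_bp = 1L) {
  if (min_bp < 1) stop("min_bp must be >= 1")
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  width <- min(a$end[1], b$end[1]) - max(a$start[1], b$start[1])
  width >= min_bp
}

#' Remove treatment peaks overlapping a control peak set
#'
#' ChIP peaks that overlap any peak called in the IgG (non-specific
#' antibody) library are considered artefactual and dropped; the surviving
#' peaks keep their input order.
#'
#' @param chip peak data frame with role `"chip"`.
#' @param igg peak data frame with role `"igg"`.
#' @param min_bp minimum overlap (bp) that triggers removal.
#' @return The subset of `chip` with no qualifying overlap in `igg`.
#' @export
subtract_overlapping <- function(chip, igg, min_bp = 1L) {
  if (min_bp < 1) stop("min_bp must be >= 1")
  if (nrow(chip) > 0 && !all(chip$role == "chip"))
    stop("treatment peak set must have role 'chip'")
  if (nrow(igg) > 0 && !all(igg$role == "igg"))
    stop("control peak set must have role 'igg'")
  if (nrow(chip) == 0 || nrow(igg) == 0) return(chip)
  hits <- GenomicRanges::findOverlaps(.as_granges(chip), .as_granges(igg),
                                      minoverlap = min_bp)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0) chip else chip[-drop, , drop = FALSE]
}

#' Merge overlapping or adjacent intervals
#'
#' @param intervals interval data frame.
#' @return The minimal set of disjoint half-open intervals covering the same
#'   bases, sorted by `(chrom, start)`.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(interval_df())
  gr <- GenomicRanges::GRanges(
    seqnames = factor(intervals$chrom, levels = sort(unique(intervals$chrom))),
    ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
  )
  red <- GenomicRanges::reduce(sort(gr))
  interval_df(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = GenomicRanges::end(red)
  )
}

# internal: canonical key for a set of intervals (order-insensitive multiset)
.region_key <- function(df) {
  keys <- sprintf("%s:%d-%d", df$chrom, as.integer(df$start), as.integer(df$end))
  paste(sort(keys), collapse = ";")
}

#' Group genes sharing identical binding-region coordinates
#'
#' Two genes (for example a divergently transcribed pair) can be annotated
#' from the very same peaks; grouping genes whose peak coordinate sets are
#' identical yields the number of distinct binding regions behind a target
#' list. Identity is exact coordinate-set equality, not overlap: replicate
#' peaks of one gene need not overlap each other, so only exact sharing
#' reflects a shared region.
#'
#' @param gene_peaks named list mapping gene symbol to an interval data
#'   frame (the gene's peak coordinates); every element must be non-empty.
#' @return A list of region groups, each a list with `genes` (sorted
#'   symbols) and `intervals` (the shared coordinates); groups are ordered
#'   by their first gene symbol.
#' @export
collapse_shared_regions <- function(gene_peaks) {
  if (length(gene_peaks) == 0) return(list())
  if (is.null(names(gene_peaks)) || any(!nzchar(names(gene_peaks))))
    stop("gene_peaks must be a named list keyed by gene symbol")
  sizes <- vapply(gene_peaks, nrow, integer(1))
  if (any(sizes == 0))
    stop("every gene must map to a non-empty coordinate set: ",
         paste(names(gene_peaks)[sizes == 0], collapse = ", "))
  keys <- vapply(gene_peaks, .region_key, character(1))
  groups <- split(names(gene_peaks), keys)
  groups <- lapply(groups, function(g) {
    g <- sort(g)
    list(genes = g, intervals = gene_peaks[[g[1]]][, c("chrom", "start", "end")])
  })
  groups <- unname(groups)
  first <- vapply(groups, function(g) g$genes[1], character(1))
  groups[order(first)]
}

#' Read and write peaks as BED6
#'
#' The name field carries a `pool<k>.<role>` tag and the score field the
#' -10*log10 p-value. Coordinates are BED-native half-open.
#'
#' @param peaks peak data frame.
#' @param path file path.
#' @return `read_peaks_bed` returns a peak data frame; `write_peaks_bed`
#'   returns `path` invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  name <- sprintf("pool%d.%s", peaks$pool, peaks$role)
  bed <- data.frame(peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                    name, peaks$score, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  tag <- strsplit(bed[[4]], ".", fixed = TRUE)
  pool <- as.integer(sub("^pool", "", vapply(tag, `[`, "", 1)))
  role <- vapply(tag, `[`, "", 2)
  out <- peak_df(bed[[1]], bed[[2]], bed[[3]], score = bed[[5]])
  out$pool <- pool
  out$role <- role
  out
}
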