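#' Binned coverage tracks and caller parameters
#'
#' A coverage track is a list with `chrom`, `bin_size` (bp) and `counts`
#' (non-negative reads per bin); `total_reads` is derived. This is the
#' input of the simplified local-Poisson enrichment caller, which is a
#' declared stand-in for a full ChIP-seq caller: no read shifting, no
#' duplicate filtering, no fragment model — just enough of the local
#' background idea to run the pipeline end-to-end on synthetic coverage.
#'
#' @param chrom chromosome name.
#' @param counts integer vector of reads per bin.
#' @param bin_size bin width in bp (>= 1).
#' @return A `coverage_track` list.
#' @export
coverage_track <- function(chrom, counts, bin_size = 200L) {
  counts <- as.numeric(counts)
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
                 counts = counts, total_reads = sum(counts)),
            class = "coverage_track")
}

#' @param bin_size bin width in bp.
#' @param local_windows local background window sizes in bp; each must be a
#'   multiple of `bin_size`.
#' @param score_threshold minimum bin score (-10*log10 p) to enter a peak.
#' @param min_peak_bins minimum run length in bins.
#' @rdname coverage_track
#' @export
caller_params <- function(bin_size = 200L, local_windows = c(1000L, 5000L, 10000L),
                          score_threshold = 50, min_peak_bins = 1L) {
  if (score_threshold <= 0 || min_peak_bins < 1 || bin_size < 1)
    stop("caller thresholds must be positive")
  if (any(local_windows %% bin_size != 0))
    stop("local windows must be multiples of bin_size")
  list(bin_size = as.integer(bin_size), local_windows = as.integer(local_windows),
       score_threshold = as.numeric(score_threshold),
       min_peak_bins = as.integer(min_peak_bins))
}

#' Local Poisson background rate
#'
#' The expected background count for a bin is the maximum of the
#' genome-wide rate and the mean depth-normalized control rate in each
#' local window centred on the bin (windows truncate at chromosome ends).
#' Taking the maximum guards against calling peaks inside locally noisy
#' control regions.
#'
#' @param bin 1-based bin index in the treatment track.
#' @param control_counts depth-normalized control counts per bin.
#' @param params caller parameters (see [caller_params()]).
#' @param genome_lambda genome-wide mean normalized control rate per bin.
#' @return The local lambda (expected reads per bin).
#' @export
local_lambda <- function(bin, control_counts, params, genome_lambda) {
  n <- length(control_counts)
  lam <- genome_lambda
  for (w in params$local_windows) {
    half <- (w %/% params$bin_size) %/% 2L
    lo <- max(1L, bin - half)
    hi <- min(n, bin + half)
    lam <- max(lam, mean(control_counts[lo:hi]))
  }
  lam
}

#' Poisson upper-tail enrichment score
#'
#' Returns `-10 * log10 P[X >= count]` for `X ~ Poisson(lam)`, the score
#' scale used in published peak tables. Computed on the log scale so it is
#' finite for all representable inputs.
#'
#' @param count observed reads in the bin (>= 0).
#' @param lam expected reads under the background (> 0).
#' @return Non-negative score; 0 when `count == 0`.
#' @export
poisson_score <- function(count, lam) {
  if (any(lam <= 0)) stop("lam must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  # P[X >= k] = P[X > k - 1]
  logp <- stats::ppois(count - 1, lam, lower.tail = FALSE, log.p = TRUE)
  score <- -10 * logp / log(10)
  score[count == 0] <- 0
  score
}

#' Call enriched regions from binned coverage
#'
#' Control counts are scaled by the treatment/control total-read ratio,
#' each treatment bin is scored against its local Poisson background, and
#' maximal runs of bins at or above `score_threshold` (of length at least
#' `min_peak_bins`) become peaks. The peak score is the maximum bin score
#' in the run; fold enrichment is the treatment rate over the local lambda
#' at the summit (the first bin attaining the maximum score).
#'
#' @param treatment,control `coverage_track` objects on the same
#'   chromosome with the same binning.
#' @param params caller parameters.
#' @param pool pool index stamped on the output peaks.
#' @param role library role stamped on the output peaks.
#' @return A peak data frame (possibly empty).
#' @export
call_peaks <- function(treatment, control, params = caller_params(),
                       pool = 1L, role = "chip") {
  if (treatment$chrom != control$chrom ||
      treatment$bin_size != control$bin_size ||
      length(treatment$counts) != length(control$counts))
    stop("treatment and control tracks must share chromosome and binning")
  if (treatment$bin_size != params$bin_size)
    stop("params bin_size must match the tracks")
  n <- length(treatment$counts)
  scale <- if (control$total_reads > 0) treatment$total_reads / control$total_reads else 1
  ctrl <- control$counts * scale
  genome_lambda <- mean(ctrl)
  if (genome_lambda <= 0) genome_lambda <- .Machine$double.eps
  lams <- vapply(seq_len(n), local_lambda, numeric(1),
                 control_counts = ctrl, params = params,
                 genome_lambda = genome_lambda)
  scores <- poisson_score(treatment$counts, lams)
  hot <- scores >= params$score_threshold
  if (!any(hot)) {
    return(peak_df(role = role))
  }
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= params$min_peak_bins
  out <- lapply(which(keep), function(i) {
    b0 <- starts[i]; b1 <- ends[i]
    run_scores <- scores[b0:b1]
    summit <- b0 + which.max(run_scores) - 1L
    fold <- treatment$counts[summit] / lams[summit]
    peak_df(treatment$chrom,
            start = (b0 - 1L) * params$bin_size,
            end = b1 * params$bin_size,
            score = max(run_scores), fold_enrichment = fold,
            pool = pool, role = role)
  })
  do.call(rbind, out)
}

#' Read and write binned coverage as bedGraph
#'
#' Adjacent bins with equal counts are not run-length collapsed, so the
#' file maps one line to one bin and round-trips exactly.
#'
#' @param track `coverage_track`.
#' @param path file path.
#' @return `read_bedgraph` returns a `coverage_track`; the writer returns
#'   `path` invisibly.
#' @export
write_bedgraph <- function(track, path) {
  n <- length(track$counts)
  df <- data.frame(track$chrom,
                   (seq_len(n) - 1L) * track$bin_size,
                   seq_len(n) * track$bin_size,
                   track$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  bin_size <- df[[3]][1] - df[[2]][1]
  coverage_track(df[[1]][1], df[[4]], bin_size = bin_size)
}
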