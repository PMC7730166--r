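#' ZOOPS EM motif discovery
#'
#' A deliberately small de novo motif finder used in place of a full motif
#' suite: a position weight matrix (PWM) is fit by expectation-maximization
#' under the ZOOPS model (each sequence contributes zero or one site), both
#' strands are considered, and the best of `n_starts` seeded random
#' restarts is returned. The fit statistic is the log-likelihood ratio
#' (LLR) of the ZOOPS model against the background-only model, with
#' background base frequencies estimated from the input sequences.
#'
#' @param seqs character vector of DNA sequences (A/C/G/T, N tolerated), or
#'   a [Biostrings::DNAStringSet].
#' @param width motif width; every sequence must be at least this long.
#' @param n_starts number of random EM restarts.
#' @param seed integer seed making the search reproducible.
#' @param both_strands scan and learn from both strands (default TRUE).
#' @param max_iter,tol EM stopping rule: stop when the LLR gain drops below
#'   `tol` or after `max_iter` iterations.
#' @param init_pwm optional width x 4 starting matrix; when given, a single
#'   EM run from this start replaces the random restarts (useful for
#'   reproducing a fit or testing invariances).
#' @return A `motif_model` list: `pwm` (width x 4, rows sum to 1),
#'   `width`, `consensus_iupac`, `background`, `llr`, `gamma` (fitted site
#'   probability), `ll_trace` (per-iteration LLR of the winning start),
#'   `n_sites` (filled by [scan_sites()], initially NA), `e_value`
#'   (filled by [motif_evalue()], initially NA).
#' @export
em_motif_search <- function(seqs, width, n_starts = 5L, seed = 1L,
                            both_strands = TRUE, max_iter = 200L, tol = 1e-6,
                            init_pwm = NULL) {
  seqs <- .as_char_seqs(seqs)
  enc <- lapply(seqs, .encode_dna)
  lens <- lengths(enc)
  if (any(lens < width)) stop("width exceeds the shortest sequence length")
  bg <- .background_freqs(enc)
  # both-strand models see every window in both orientations, so the
  # background must be strand-symmetric (A/T and C/G averaged); this also
  # makes the fit exactly invariant to reverse-complementing the input
  if (both_strands) bg <- (bg + rev(bg)) / 2
  set.seed(seed)
  best <- NULL
  if (!is.null(init_pwm)) {
    stopifnot(nrow(init_pwm) == width, ncol(init_pwm) == 4)
    best <- .zoops_em(enc, width, init_pwm, bg, both_strands, max_iter, tol)
  } else {
    for (s in seq_len(n_starts)) {
      theta0 <- .seed_pwm(enc, width)
      fit <- .zoops_em(enc, width, theta0, bg, both_strands, max_iter, tol)
      if (is.null(best) || fit$llr > best$llr) best <- fit
    }
  }
  structure(list(
    pwm = best$pwm, width = as.integer(width),
    consensus_iupac = pwm_to_iupac(best$pwm),
    background = bg, llr = best$llr, gamma = best$gamma,
    ll_trace = best$ll_trace, n_sites = NA_integer_, e_value = NA_real_
  ), class = "motif_model")
}

.as_char_seqs <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  toupper(as.character(seqs))
}

# A=1 C=2 G=3 T=4, anything else (N) = 5L
.encode_dna <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L
  v
}

.DNA_BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(4L, 3L, 2L, 1L, 5L)

.background_freqs <- function(enc) {
  all <- unlist(enc)
  counts <- tabulate(all[all <= 4L], nbins = 4L) + 1
  p <- counts / sum(counts)
  names(p) <- .DNA_BASES
  p
}

.seed_pwm <- function(enc, width, weight = 0.85) {
  i <- sample(length(enc), 1)
  j <- sample(length(enc[[i]]) - width + 1L, 1)
  win <- enc[[i]][j:(j + width - 1L)]
  pwm <- matrix((1 - weight) / 3, nrow = width, ncol = 4)
  for (k in seq_len(width)) {
    if (win[k] <= 4L) pwm[k, win[k]] <- weight else pwm[k, ] <- 0.25
  }
  pwm
}

# window log-ratio scores for one encoded sequence under log(theta/bg);
# lr is width x 5 with the 5th column 0 (N contributes nothing)
.window_scores <- function(v, lr, width) {
  m <- length(v) - width + 1L
  sc <- numeric(m)
  for (k in seq_len(width)) sc <- sc + lr[k, v[k:(k + m - 1L)]]
  sc
}

.zoops_em <- function(enc, width, theta, bg, both_strands, max_iter, tol,
                      pseudo = 0.01) {
  n <- length(enc)
  rc <- lapply(enc, function(v) rev(.COMPLEMENT[v]))
  gamma <- 0.5
  ll_trace <- numeric(0)
  last <- -Inf
  for (iter in seq_len(max_iter)) {
    lr <- cbind(log(theta / matrix(bg, nrow = width, ncol = 4, byrow = TRUE)), 0)
    counts <- matrix(pseudo, nrow = width, ncol = 4)
    z0_sum <- 0
    ll <- 0
    for (i in seq_len(n)) {
      sc_f <- .window_scores(enc[[i]], lr, width)
      sc <- if (both_strands) c(sc_f, .window_scores(rc[[i]], lr, width)) else sc_f
      M <- length(sc)
      ls <- max(sc)
      log_psites <- log(gamma / M) + ls + log(sum(exp(sc - ls)))
      log_p0 <- log1p(-gamma)
      hi <- max(log_psites, log_p0)
      ll_i <- hi + log1p(exp(min(log_psites, log_p0) - hi))
      ll <- ll + ll_i
      z <- exp(log(gamma / M) + sc - ll_i)
      z0_sum <- z0_sum + exp(log_p0 - ll_i)
      # accumulate weighted base counts from all candidate windows
      m <- length(sc_f)
      for (k in seq_len(width)) {
        b_f <- enc[[i]][k:(k + m - 1L)]
        zf <- z[seq_len(m)]
        ok <- b_f <= 4L
        if (any(ok))
          counts[k, ] <- counts[k, ] +
            vapply(1:4, function(b) sum(zf[ok][b_f[ok] == b]), numeric(1))
        if (both_strands) {
          b_r <- rc[[i]][k:(k + m - 1L)]
          zr <- z[m + seq_len(m)]
          okr <- b_r <= 4L
          if (any(okr))
            counts[k, ] <- counts[k, ] +
              vapply(1:4, function(b) sum(zr[okr][b_r[okr] == b]), numeric(1))
        }
      }
    }
    ll_trace <- c(ll_trace, ll)
    theta <- counts / rowSums(counts)
    gamma <- min(max(1 - z0_sum / n, 1e-4), 1 - 1e-4)
    if (ll - last < tol && iter > 1) break
    last <- ll
  }
  list(pwm = theta, gamma = gamma, llr = ll_trace[length(ll_trace)],
       ll_trace = ll_trace)
}

# IUPAC degenerate code tables
.IUPAC_BY_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M",
  "CGT" = "B", "AGT" = "D", "ACT" = "H", "ACG" = "V", "ACGT" = "N"
)
.IUPAC_SETS <- stats::setNames(names(.IUPAC_BY_SET), .IUPAC_BY_SET)

#' Collapse a PWM to an IUPAC consensus string
#'
#' Per column: if the top base alone reaches `pair_threshold` it is written
#' as that base; else if the top two bases jointly reach `pair_threshold` a
#' two-base degenerate code is used; else a single base with probability at
#' least `primary_threshold` is written; else a three-base code if the top
#' three jointly reach `pair_threshold`; otherwise `N`. Ties are broken in
#' fixed A<C<G<T order so the consensus is deterministic.
#'
#' @param pwm width x 4 matrix, rows on the probability simplex.
#' @param primary_threshold minimum single-base probability (default 0.5).
#' @param pair_threshold minimum joint probability for degenerate codes
#'   (default 0.8).
#' @return IUPAC consensus string of length `nrow(pwm)`.
#' @export
pwm_to_iupac <- function(pwm, primary_threshold = 0.5, pair_threshold = 0.8) {
  paste(apply(pwm, 1, function(p) {
    o <- order(p, decreasing = TRUE)
    top <- cumsum(p[o])
    if (top[1] >= pair_threshold) return(.DNA_BASES[o[1]])
    if (top[2] >= pair_threshold)
      return(.IUPAC_BY_SET[paste(sort(.DNA_BASES[o[1:2]]), collapse = "")])
    if (p[o[1]] >= primary_threshold) return(.DNA_BASES[o[1]])
    if (top[3] >= pair_threshold)
      return(.IUPAC_BY_SET[paste(sort(.DNA_BASES[o[1:3]]), collapse = "")])
    "N"
  }), collapse = "")
}

#' Count sequences containing a motif site
#'
#' Scans both strands of each sequence with the PWM log-odds score
#' (`log2(pwm / background)`) and counts sequences with at least one window
#' scoring at least `score_fraction` of the maximum attainable score. The
#' count is also stored in the returned model.
#'
#' @param model `motif_model`.
#' @param seqs sequences as in [em_motif_search()].
#' @param score_fraction fraction of the maximum attainable log-odds score.
#' @return The model with `n_sites` set (use `$n_sites` for the count).
#' @export
scan_sites <- function(model, seqs, score_fraction = 0.8) {
  seqs <- .as_char_seqs(seqs)
  enc <- lapply(seqs, .encode_dna)
  lo <- cbind(log2(model$pwm /
                     matrix(model$background, nrow = model$width, ncol = 4,
                            byrow = TRUE)), 0)
  max_score <- sum(apply(lo[, 1:4, drop = FALSE], 1, max))
  thr <- score_fraction * max_score
  hit <- vapply(enc, function(v) {
    if (length(v) < model$width) return(FALSE)
    sc <- .window_scores(v, lo, model$width)
    rcv <- rev(.COMPLEMENT[v])
    sc <- c(sc, .window_scores(rcv, lo, model$width))
    any(sc >= thr)
  }, logical(1))
  model$n_sites <- sum(hit)
  model
}

#' Permutation E-value for a discovered motif
#'
#' Mononucleotide shuffles of each input sequence preserve length and base
#' composition but destroy positional structure. The motif search is re-run
#' on `n_shuffles` shuffled sequence sets at the same width and the
#' empirical E-value is `(1 + #{shuffled LLR >= observed}) / (1 + n_shuffles)`.
#' This is an add-one permutation p-value, not comparable to analytic
#' E-values reported by full motif suites.
#'
#' @param model fitted `motif_model` (its `llr` is the observed statistic).
#' @param seqs the sequences the model was fit on.
#' @param n_shuffles number of shuffled replicates (>= 1).
#' @param seed integer seed.
#' @param n_starts EM restarts per shuffled set (kept small for speed).
#' @return The model with `e_value` set.
#' @export
motif_evalue <- function(model, seqs, n_shuffles = 100L, seed = 1L,
                         n_starts = 2L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  seqs <- .as_char_seqs(seqs)
  set.seed(seed)
  exceed <- 0L
  for (r in seq_len(n_shuffles)) {
    shuf <- vapply(seqs, function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1))
    fit <- em_motif_search(shuf, width = model$width, n_starts = n_starts,
                           seed = sample.int(2^31 - 1, 1))
    if (fit$llr >= model$llr) exceed <- exceed + 1L
  }
  model$e_value <- (1 + exceed) / (1 + n_shuffles)
  model
}

#' @export
print.motif_model <- function(x, ...) {
  cat("Motif model (ZOOPS EM)\n")
  cat(sprintf("  width     : %d\n", x$width))
  cat(sprintf("  consensus : %s\n", x$consensus_iupac))
  cat(sprintf("  LLR       : %.3f (gamma = %.3f)\n", x$llr, x$gamma))
  if (!is.na(x$n_sites)) cat(sprintf("  sites     : %d\n", x$n_sites))
  if (!is.na(x$e_value)) cat(sprintf("  E-value   : %.4g\n", x$e_value))
  invisible(x)
}

#' Write a motif in minimal MEME text format
#'
#' @param model `motif_model`.
#' @param path output file.
#' @param name motif name used in the file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(model, path, name = "MOTIF_1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    sprintf("Background letter frequencies"),
    paste(sprintf("%s %.5f", .DNA_BASES, model$background), collapse = " "),
    "",
    sprintf("MOTIF %s %s", name, model$consensus_iupac),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %s E= %s",
            model$width,
            ifelse(is.na(model$n_sites), "0", model$n_sites),
            ifelse(is.na(model$e_value), "0", format(model$e_value)))
  ), con)
  utils::write.table(format(model$pwm, digits = 6), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character sequences.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
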