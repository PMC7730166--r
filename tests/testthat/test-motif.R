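test_that("PWM to IUPAC collapse follows the degenerate-code rules", {
  expect_identical(pwm_to_iupac(matrix(c(0, 0.5, 0, 0.5), 1)), "Y")
  expect_identical(pwm_to_iupac(matrix(c(1, 0, 0, 0), 1)), "A")
  expect_identical(pwm_to_iupac(matrix(0.25, 1, 4)), "N")
  # three-base code when no pair reaches the joint threshold
  expect_identical(pwm_to_iupac(matrix(c(0.4, 0.3, 0.05, 0.25), 1)), "H")
  # dominant single base wins even when a pair would also qualify
  expect_identical(pwm_to_iupac(matrix(c(0.9, 0.05, 0.03, 0.02), 1)), "A")
  pwm <- rbind(c(0.97, 0.01, 0.01, 0.01), c(0.45, 0.45, 0.05, 0.05))
  expect_identical(pwm_to_iupac(pwm), "AM")
})

test_that("ZOOPS EM recovers a planted motif and keeps simplex and monotone invariants", {
  cfg <- sim_config(seed = 11, motif_consensus = "GTATATGTGTGTGT", motif_prob = 1)
  pm <- plant_motif(cfg, n_seqs = 20, seq_length = 100)
  m <- em_motif_search(pm$seqs, width = 14, n_starts = 10, seed = 11)
  hits <- max(consensus_matches(m$consensus_iupac, "GTATATGTGTGTGT"),
              consensus_matches(m$consensus_iupac, revcomp("GTATATGTGTGTGT")))
  expect_gte(hits, 12)
  expect_equal(rowSums(m$pwm), rep(1, 14), tolerance = 1e-9)
  expect_true(all(diff(m$ll_trace) >= -1e-8))

  # background-only sequences under the same seeds score strictly lower
  bg_cfg <- sim_config(seed = 11, motif_consensus = "GTATATGTGTGTGT",
                       motif_prob = 0)
  bg <- plant_motif(bg_cfg, n_seqs = 20, seq_length = 100)
  m_bg <- em_motif_search(bg$seqs, width = 14, n_starts = 10, seed = 11)
  expect_lt(m_bg$llr, m$llr)
  expect_error(em_motif_search(pm$seqs, width = 200, seed = 1), "width")
})

test_that("EM with width = sequence length reduces to the smoothed one-hot profile", {
  s <- "GATTACA"
  m <- em_motif_search(s, width = 7, n_starts = 1, seed = 1,
                       both_strands = FALSE)
  enc <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  for (k in 1:7) expect_gt(m$pwm[k, enc[k]], 0.9)
  expect_identical(m$consensus_iupac, s)
})

test_that("the LLR is strand-symmetric when both strands are scanned", {
  # from a common explicit start, the candidate-site set of the
  # reverse-complemented inputs is identical, so the whole EM trajectory
  # (and its LLR trace) must match exactly
  cfg <- sim_config(seed = 19, motif_consensus = "GTATATGTGTGTGT", motif_prob = 1)
  pm <- plant_motif(cfg, n_seqs = 15, seq_length = 80)
  init <- matrix(0.25, nrow = 14, ncol = 4)
  init[cbind(1:14, match(strsplit("GTATATGTGTGTGT", "")[[1]],
                         c("A", "C", "G", "T")))] <- 0.7
  init <- init / rowSums(init)
  m_f <- em_motif_search(pm$seqs, width = 14, seed = 4, init_pwm = init)
  rc_seqs <- vapply(pm$seqs, revcomp, character(1))
  m_r <- em_motif_search(rc_seqs, width = 14, seed = 4, init_pwm = init)
  expect_equal(m_f$llr, m_r$llr, tolerance = 1e-9)
  expect_equal(m_f$ll_trace, m_r$ll_trace, tolerance = 1e-9)
})

test_that("site scanning counts planted sequences and stays quiet on background", {
  cfg <- sim_config(seed = 13, motif_consensus = "GTATATGTGTGTGT", motif_prob = 1)
  pm <- plant_motif(cfg, n_seqs = 20, seq_length = 100)
  m <- em_motif_search(pm$seqs, width = 14, n_starts = 10, seed = 13)
  m <- scan_sites(m, pm$seqs)
  expect_identical(m$n_sites, 20L)
  # a lone sequence that is exactly the model's best word is found
  best_word <- paste(c("A", "C", "G", "T")[apply(m$pwm, 1, which.max)],
                     collapse = "")
  expect_identical(scan_sites(m, best_word)$n_sites, 1L)

  bg <- plant_motif(sim_config(seed = 14, motif_prob = 0), n_seqs = 20,
                    seq_length = 100)
  expect_lte(scan_sites(m, bg$seqs, score_fraction = 0.9)$n_sites, 2L)
})

test_that("permutation E-values rank planted signal below background", {
  cfg <- sim_config(seed = 21, motif_consensus = "GTATATGTGTGTGT", motif_prob = 1)
  pm <- plant_motif(cfg, n_seqs = 10, seq_length = 50)
  m <- em_motif_search(pm$seqs, width = 14, n_starts = 3, seed = 21)

  # extreme ranks are pinned by the add-one formula
  hi <- m; hi$llr <- 1e9
  expect_equal(motif_evalue(hi, pm$seqs, n_shuffles = 5, seed = 1,
                            n_starts = 1)$e_value, 1 / 6)
  lo <- m; lo$llr <- -1e9
  expect_equal(motif_evalue(lo, pm$seqs, n_shuffles = 5, seed = 1,
                            n_starts = 1)$e_value, 1)

  bg <- plant_motif(sim_config(seed = 22, motif_prob = 0), n_seqs = 10,
                    seq_length = 50)
  m_bg <- em_motif_search(bg$seqs, width = 14, n_starts = 3, seed = 22)
  e_sig <- motif_evalue(m, pm$seqs, n_shuffles = 19, seed = 2,
                        n_starts = 1)$e_value
  e_bg <- motif_evalue(m_bg, bg$seqs, n_shuffles = 19, seed = 2,
                       n_starts = 1)$e_value
  expect_lt(e_sig, e_bg)
  expect_equal(e_sig, 1 / 20)
})

test_that("FASTA and minimal MEME-format IO round-trip", {
  seqs <- c(r1 = "ACGTACGTACGTAC", r2 = "GGGTTTAAACCCGG")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta_seqs(seqs, fa)
  expect_identical(read_fasta_seqs(fa), seqs)
  m <- em_motif_search(seqs, width = 6, n_starts = 2, seed = 3)
  meme <- withr::local_tempfile(fileext = ".txt")
  write_meme(m, meme)
  lines <- readLines(meme)
  expect_true(any(grepl("^MOTIF", lines)))
  expect_true(any(grepl("letter-probability matrix", lines)))
})
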