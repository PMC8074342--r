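mk_counts <- function(m, gene_map) {
  structure(list(counts = m, gene_map = gene_map,
                 unassigned = stats::setNames(integer(ncol(m)), colnames(m))),
            class = "nanoiso_counts")
}

test_that("expression filters implement the gene and transcript rules", {
  samples <- paste0("S", 1:4)
  m <- rbind(
    GA_T1 = c(12L, 3L, 11L, 2L),    # tx rule: >=10 in 2 samples
    GA_T2 = c(40L, 9L, 30L, 60L),
    GB_T1 = c(50L, 9L, 40L, 60L),   # gene GB: sample 2 sum = 9 -> dropped
    GC_T1 = c(9L, 9L, 9L, 9L),      # tx never reaches 10 -> dropped
    GC_T2 = c(30L, 30L, 30L, 30L))
  colnames(m) <- samples
  gm <- stats::setNames(c("GA", "GA", "GB", "GC", "GC"), rownames(m))
  f2 <- filter_expression(mk_counts(m, gm),
                          dtu_config(min_tx_samples = 2L))
  expect_setequal(rownames(f2$counts), c("GA_T1", "GA_T2", "GC_T2"))
  # with min_tx_samples = 3, GA_T1 (only 2 samples >= 10) is dropped too
  f3 <- filter_expression(mk_counts(m, gm), dtu_config(min_tx_samples = 3L))
  expect_setequal(rownames(f3$counts), c("GA_T2", "GC_T2"))
  # all-zero matrix filters to empty without error
  z <- matrix(0L, 2, 4, dimnames = list(c("X_T1", "X_T2"), samples))
  fz <- filter_expression(mk_counts(z, stats::setNames(c("X", "X"), rownames(z))),
                          dtu_config())
  expect_equal(nrow(fz$counts), 0L)
})

test_that("simes matches its formula, bounds and the brute-force oracle", {
  expect_equal(simes(c(0.01, 0.04)), 0.02)
  expect_equal(simes(0.3), 0.3)
  expect_error(simes(numeric(0)), "at least one")
  set.seed(31)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:8, 1))
    s <- simes(p)
    expect_equal(s, oracle_simes(p))
    expect_true(s >= min(p) - 1e-15)
    expect_true(s <= min(p) * length(p) + 1e-15)
  }
})

test_that("bh_adjust matches the step-up definition on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  set.seed(32)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:10, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("two-transcript genes give equal and opposite t statistics", {
  set.seed(33)
  m <- matrix(rpois(4 * 6, c(300, 600, 200, 800)), nrow = 4,
              dimnames = list(c("G1_T1", "G1_T2", "G2_T1", "G2_T2"),
                              paste0("S", 1:6)))
  gm <- stats::setNames(c("G1", "G1", "G2", "G2"), rownames(m))
  design <- stats::setNames(rep(c("A", "B"), each = 3), colnames(m))
  for (moderate in c(TRUE, FALSE)) {
    res <- dtu_test(mk_counts(m, gm), design, dtu_config(), moderate = moderate)
    tx <- as.data.frame(res$transcripts)
    for (g in c("G1", "G2")) {
      tt <- tx$t[tx$gene_id == g]
      rl <- tx$relative_logFC[tx$gene_id == g]
      expect_equal(tt[1], -tt[2], tolerance = 1e-10)
      expect_equal(rl[1], -rl[2], tolerance = 1e-10)
      expect_equal(rl[1], tx$logFC[tx$gene_id == g][1] -
                     tx$logFC[tx$gene_id == g][2], tolerance = 1e-10)
    }
    # Simes of two equal p-values is that p-value
    expect_equal(res$genes$p_simes,
                 tx$p[match(res$genes$gene_id, tx$gene_id)], tolerance = 1e-12)
  }
})

test_that("single-transcript genes are excluded from testing but kept in the matrix", {
  m <- matrix(50L, nrow = 3, ncol = 4,
              dimnames = list(c("G1_T1", "G1_T2", "G2_T1"), paste0("S", 1:4)))
  gm <- stats::setNames(c("G1", "G1", "G2"), rownames(m))
  f <- filter_expression(mk_counts(m, gm), dtu_config(min_tx_samples = 2L))
  expect_true("G2_T1" %in% rownames(f$counts))
  design <- stats::setNames(rep(c("A", "B"), each = 2), paste0("S", 1:4))
  set.seed(2)
  f$counts <- f$counts + matrix(rpois(12, 5), 3, 4)
  res <- dtu_test(f, design, dtu_config())
  expect_false("G2" %in% res$genes$gene_id)
  expect_false("G2_T1" %in% res$transcripts$transcript_id)
  # groups of < 2 samples are rejected
  bad_design <- stats::setNames(c("A", "B", "B", "B"), paste0("S", 1:4))
  expect_error(dtu_test(f, bad_design, dtu_config()), ">= 2 samples")
})

test_that("stage-wise adjustment follows the screen-then-confirm recipe", {
  res <- structure(list(
    transcripts = data.table::data.table(
      transcript_id = c("A_T1", "A_T2", "B_T1", "B_T2"),
      gene_id = c("A", "A", "B", "B"),
      logFC = 0, relative_logFC = 0, t = 0, df = 4,
      p = c(0.01, 0.2, 0.5, 0.6),
      p_bh = NA_real_, p_stagewise = NA_real_),
    genes = data.table::data.table(
      gene_id = c("A", "B"), n_tx = 2L,
      p_simes = c(0.02, 0.5),
      p_bh = c(0.04, 0.5), screened = NA)), class = "nanoiso_dtu")
  sw <- stagewise(res, dtu_config(alpha = 0.05))
  expect_equal(sw$genes$screened, c(TRUE, FALSE))
  # G = 2 tested, R = 1 screened: Holm within gene A scaled by 2
  expect_equal(sw$transcripts$p_stagewise,
               c(min(1, 0.02 * 2), min(1, 0.2 * 2), 1, 1))
  # R = G = 1 case: scale factor 1
  res1 <- res
  res1$genes <- res$genes[1]
  res1$transcripts <- res$transcripts[1:2]
  res1$genes$p_bh <- 0.02
  sw1 <- stagewise(res1, dtu_config())
  expect_equal(sw1$transcripts$p_stagewise, c(0.02, 0.2))
  # no screened genes -> no significant transcripts, no division error
  res0 <- res
  res0$genes$p_bh <- c(0.5, 0.6)
  sw0 <- stagewise(res0, dtu_config())
  expect_true(all(sw0$transcripts$p_stagewise == 1))
  # Holm within gene matches its brute-force definition
  set.seed(44)
  p <- stats::runif(5)
  expect_equal(stats::p.adjust(p, "holm"), oracle_holm(p))
})

test_that("evaluation metrics match a hand-counted confusion table", {
  res <- structure(list(
    transcripts = data.table::data.table(
      transcript_id = paste0("T", 1:6),
      gene_id = paste0("G", c(1, 1, 2, 2, 3, 3)),
      p = 0.5, p_bh = c(0.01, 0.2, 0.03, 0.8, 0.04, 0.9),
      p_stagewise = c(0.01, 1, 0.2, 1, 0.03, 1)),
    genes = data.table::data.table(
      gene_id = paste0("G", 1:3), n_tx = 2L, p_simes = 0.5,
      p_bh = c(0.01, 0.2, 0.03), screened = c(TRUE, FALSE, TRUE))),
    class = "nanoiso_dtu")
  truth <- list(
    genes = data.frame(gene_id = paste0("G", 1:3),
                       dtu = c(TRUE, TRUE, FALSE)),
    transcripts = data.frame(transcript_id = paste0("T", 1:6),
                             dtu = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  ev <- as.data.frame(evaluate_dtu(res, truth, dtu_config()))
  g_bh <- ev[ev$level == "gene" & ev$adjustment == "BH", ]
  # gene calls: G1 (TP), G3 (FP); missed G2 -> TP=1 FP=1 FN=1
  expect_equal(c(g_bh$TP, g_bh$FP, g_bh$FN), c(1, 1, 1))
  expect_equal(g_bh$FDR, 0.5)
  expect_equal(g_bh$TPR, 0.5)
  t_bh <- ev[ev$level == "transcript" & ev$adjustment == "BH", ]
  # transcript calls: T1 (TP), T3 (TP), T5 (FP) -> TP=2 FP=1 FN=1
  expect_equal(c(t_bh$TP, t_bh$FP, t_bh$FN), c(2, 1, 1))
  expect_equal(t_bh$FDR, 1 / 3)
  t_sw <- ev[ev$level == "transcript" & ev$adjustment == "stagewise", ]
  expect_equal(c(t_sw$TP, t_sw$FP), c(1, 1))
  # zero calls give FDR 0 by the guarded denominator
  res2 <- res
  res2$transcripts$p_bh <- 1
  res2$transcripts$p_stagewise <- 1
  res2$genes$p_bh <- 1
  res2$genes$screened <- FALSE
  ev2 <- as.data.frame(evaluate_dtu(res2, truth, dtu_config()))
  expect_true(all(ev2$FDR == 0))
  expect_true(all(ev2$TPR == 0))
  # unknown ids are reported
  res3 <- res
  res3$transcripts$transcript_id[1] <- "TX"
  expect_error(evaluate_dtu(res3, truth, dtu_config()), "TX")
})

test_that("squeeze_var recovers prior parameters on simulated variances", {
  set.seed(55)
  d0 <- 8; s02 <- 0.5; d <- 4
  sigma2 <- s02 * d0 / stats::rchisq(5000, d0)
  s2 <- sigma2 * stats::rchisq(5000, d) / d
  sq <- squeeze_var(s2, d)
  expect_equal(sq$df_prior, d0, tolerance = 0.25)
  expect_equal(mean(sq$var_prior), s02, tolerance = 0.1)
  # squeezing pulls extreme variances toward the prior
  expect_true(stats::var(log(sq$var_post)) < stats::var(log(s2)))
  # limma's moments estimator agrees on the same data
  if (requireNamespace("limma", quietly = TRUE)) {
    lf <- limma::fitFDist(s2, df1 = d)
    expect_equal(sq$df_prior, lf$df2, tolerance = 0.05)
    expect_equal(unique(round(sq$var_prior, 6)), round(lf$scale, 6))
  }
})
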