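ann_tiny <- tiny_annotation()

test_that("coverage_stats computes exact exonic overlap fractions", {
  t1 <- transcript_model(ann_tiny, "GA_T1")   # exonic length 1600
  r <- list(blocks = t1$exons, read_length = 1600L)
  cs <- coverage_stats(r, t1)
  expect_equal(unname(cs["transcript_cov"]), 1.0)
  expect_equal(unname(cs["read_aligned_frac"]), 1.0)
  # partial overlap: 960 of 1000 exonic bases
  ex <- data.frame(transcript_id = "T", gene_id = "G", chrom = "chr1",
                   strand = "+", start = 0L, end = 1000L)
  t2 <- transcript_model(build_annotation(ex), "T")
  r2 <- list(blocks = cbind(40L, 1000L), read_length = 960L)
  expect_equal(unname(coverage_stats(r2, t2)["transcript_cov"]), 0.96)
})

test_that("coverage_stats agrees with a brute-force interval oracle on random inputs", {
  set.seed(11)
  for (i in 1:100) {
    ne <- sample(1:5, 1)
    estarts <- sort(sample(seq(0, 5000, by = 10), ne))
    ewidths <- sample(50:400, ne, replace = TRUE)
    exons <- cbind(estarts + cumsum(c(0, rep(500, ne - 1))), 0L)
    exons[, 2] <- exons[, 1] + ewidths
    nb <- sample(1:4, 1)
    bstarts <- sort(sample(seq(0, 6000, by = 7), nb))
    blocks <- cbind(bstarts + cumsum(c(0, rep(300, nb - 1))), 0L)
    blocks[, 2] <- blocks[, 1] + sample(30:500, nb, replace = TRUE)
    t <- list(exons = exons)
    r <- list(blocks = blocks, read_length = sum(blocks[, 2] - blocks[, 1]))
    cs <- coverage_stats(r, t)
    ov <- oracle_overlap(blocks, exons)
    expect_equal(unname(cs["transcript_cov"]), ov / sum(exons[, 2] - exons[, 1]))
    expect_equal(unname(cs["read_aligned_frac"]), ov / r$read_length)
  }
})

test_that("compatibility requires a contiguous sub-chain and a span within tolerance", {
  t1 <- transcript_model(ann_tiny, "GA_T1")
  # full chain
  r_full <- list(blocks = t1$exons, read_length = 1600L)
  expect_true(compatible(r_full, t1))
  # junction not in t
  r_bad <- list(blocks = cbind(c(1000L, 2200L), c(1500L, 2500L)),
                read_length = 800L)
  expect_false(compatible(r_bad, t1))
  # suffix sub-chain
  r_suf <- list(blocks = cbind(c(2400L, 3000L), c(2500L, 3600L)),
                read_length = 700L)
  expect_true(compatible(r_suf, t1))
  # skipping chain of GA_T2 is not a sub-chain of GA_T1
  t2 <- transcript_model(ann_tiny, "GA_T2")
  r_skip <- list(blocks = t2$exons, read_length = 1100L)
  expect_false(compatible(r_skip, t1))
  expect_true(compatible(r_skip, t2))
  # span beyond end_tol
  r_far <- list(blocks = cbind(c(700L, 2000L, 3000L), c(1500L, 2500L, 3600L)),
                read_length = 1900L)
  expect_false(compatible(r_far, t1, end_tol = 100L))
  expect_true(compatible(r_far, t1, end_tol = 400L))
})

test_that("compatible agrees with a brute-force sub-chain scan on random reads", {
  set.seed(13)
  des <- sim_design(n_genes = 6L, n_transcripts = 12L, n_up = 0L, n_down = 0L,
                    n_dtu = 0L)
  ann <- make_annotation(des, 13)
  ids <- ann$transcripts$transcript_id
  for (i in 1:100) {
    tm <- transcript_model(ann, sample(ids, 1))
    ne <- nrow(tm$exons)
    i1 <- sample(ne, 1); i2 <- sample(i1:ne, 1)
    blocks <- tm$exons[i1:i2, , drop = FALSE]
    if (stats::runif(1) < 0.3) blocks[1, 1] <- blocks[1, 1] + sample(0:200, 1)
    if (blocks[1, 1] >= blocks[1, 2]) next
    r <- list(blocks = blocks, read_length = sum(blocks[, 2] - blocks[, 1]))
    target <- transcript_model(ann, sample(ids, 1))
    got <- compatible(r, target, end_tol = 100L)
    # oracle: enumerate all contiguous sub-chains of the target
    rj <- read_junctions(blocks)
    rl <- apply(rj, 1, function(x) c(x[1], x[2]), simplify = FALSE)
    tch <- apply(junction_chain(target$exons), 1, function(x) c(x[1], x[2]),
                 simplify = FALSE)
    want <- if (length(rl) == 0) {
      ov <- oracle_overlap(blocks, target$exons)
      ov / r$read_length >= 0.8
    } else {
      hit <- FALSE
      subs <- c(oracle_subchains(tch), list(tch))
      for (sc in subs) if (chains_equal(rl, sc)) hit <- TRUE
      hit &&
        min(blocks[, 1]) >= min(target$exons[, 1]) - 100L &&
        max(blocks[, 2]) <= max(target$exons[, 2]) + 100L
    }
    expect_equal(got, want)
  }
})

test_that("assignment follows argmax coverage with a strict >0.80 aligned fraction", {
  # two transcripts sharing a junction chain prefix; read matches T1 fully
  ex <- data.frame(
    transcript_id = c("T1", "T1", "T2", "T2", "T2"),
    gene_id = "G", chrom = "chr1", strand = "+",
    start = c(0L, 2000L, 0L, 2000L, 5000L),
    end = c(1000L, 2500L, 1000L, 2500L, 6000L))
  ann <- build_annotation(ex)
  r <- list(chrom = "chr1", strand = "+",
            blocks = cbind(c(0L, 2000L), c(1000L, 2500L)),
            read_length = 1500L)
  # cov(T1) = 1.0, cov(T2) = 0.6 -> T1
  expect_equal(assign_read(r, ann), "T1")
  # read_aligned_frac exactly 0.80 -> unassigned (strict >)
  r2 <- list(chrom = "chr1", strand = "+",
             blocks = cbind(c(0L, 2000L), c(1000L, 2500L)),
             read_length = 1875L)   # 1500/1875 = 0.80
  expect_true(is.na(assign_read(r2, ann)))
  r3 <- list(chrom = "chr1", strand = "+",
             blocks = cbind(c(0L, 2000L), c(1000L, 2500L)),
             read_length = 1874L)
  expect_equal(assign_read(r3, ann), "T1")
})

test_that("count matrix conserves reads per sample", {
  ann <- ann_tiny
  reads <- list(
    S1 = reads_from_counts(ann, c(GA_T1 = 40L, GA_T2 = 30L, GB_T1 = 20L), "S1"),
    S2 = reads_from_counts(ann, c(GA_T1 = 10L, GC_T1 = 15L), "S2"))
  # add an unassignable read to S1 (intergenic)
  extra <- make_reads("junk", "chr1", "+", list(cbind(40000L, 41000L)), "S1")
  reads$S1 <- nanoiso:::combine_reads(list(reads$S1, extra))
  q <- quantify(reads, ann, quant_config())
  m <- q$counts
  expect_equal(unname(colSums(m$counts) + m$unassigned),
               c(91L, 25L))
  expect_equal(m$counts["GA_T1", "S1"], 40L)
  expect_equal(m$counts["GC_T1", "S2"], 15L)
  expect_equal(unname(m$unassigned["S1"]), 1L)
  # gene counts derivable by summing transcripts
  gsum <- rowsum(m$counts, m$gene_map[rownames(m$counts)])
  expect_equal(unname(gsum["GA", "S1"]), 70L)
  # empty sample would give a zero column
  q2 <- quantify(list(S1 = reads$S1,
                      S3 = nanoiso:::empty_reads_container()), ann)
  expect_true(!"S3" %in% colnames(q2$counts$counts) ||
                all(q2$counts$counts[, "S3"] == 0L))
})

test_that("lowering the aligned-fraction threshold never decreases counts", {
  des <- sim_design(n_genes = 10L, n_transcripts = 20L, n_up = 0L,
                    n_down = 0L, n_dtu = 0L)
  ann <- make_annotation(des, 21)
  truth <- make_mix_design(ann, des, 21)
  sim <- simulate_reads(ann, truth, noise_model(), library_size = 2000,
                        sample_mixes = c(S1 = "A"), seed = 21)
  q_hi <- quantify(sim$reads, ann, quant_config(min_read_aligned_frac = 0.9))
  q_lo <- quantify(sim$reads, ann, quant_config(min_read_aligned_frac = 0.5))
  expect_true(all(q_lo$counts$counts >= q_hi$counts$counts))
})

test_that("full-length boundary is inclusive at 0.95", {
  a <- data.table::data.table(
    read_id = c("a", "b", "c"), sample_id = "S1",
    transcript_id = c("T1", "T1", NA),
    transcript_cov = c(0.95, 0.949, NA),
    read_aligned_frac = c(1, 1, NA))
  fl <- full_length_fraction(a, quant_config())
  expect_equal(fl$flags$full_length, c(TRUE, FALSE))
  expect_equal(fl$fraction, 0.5)
})

test_that("log-CPM matches its formula and normalisation properties", {
  m <- matrix(c(0L, 10L, 990L, 5L, 20L, 975L), ncol = 2,
              dimnames = list(c("T1", "T2", "T3"), c("S1", "S2")))
  # formula check at libsize 1e6 scale
  m2 <- matrix(c(0L, 999999L + 1L), ncol = 1,
               dimnames = list(c("A", "B"), "S"))
  lc <- log_cpm(m2[, , drop = FALSE], prior = 0.5)
  expect_equal(lc["A", "S"], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(lc["A", "S"], -1.0000014, tolerance = 1e-6)
  # doubling a column's counts leaves CPM invariant in the prior -> 0 limit
  mp <- m + 1L   # strictly positive counts
  lc1 <- log_cpm(mp, prior = 1e-9)
  lc2 <- log_cpm(cbind(S1 = mp[, 1] * 2L, S2 = mp[, 2]), prior = 1e-9)
  expect_equal(lc1[, "S1"], lc2[, "S1"], tolerance = 1e-6)
  # independent spreadsheet-style evaluation of a 3x2 matrix
  lib <- colSums(m)
  want <- log2(sweep(m + 0.5, 2, lib + 1, "/") * 1e6)
  expect_equal(log_cpm(m), want)
  # zero library size errors
  expect_error(log_cpm(cbind(S1 = c(0L, 0L))), "library size")
})

test_that("zero-noise assignment recovers the source transcript of every read", {
  des <- sim_design(n_genes = 15L, n_transcripts = 30L, n_up = 3L,
                    n_down = 3L, n_dtu = 4L)
  ann <- make_annotation(des, 8)
  truth <- make_mix_design(ann, des, 8)
  sim <- simulate_reads(ann, truth, noise_model(p_trunc = 0, p_jitter = 0, end_sd = 0),
                        library_size = 3000, sample_mixes = c(S1 = "A"), seed = 8)
  q <- quantify(sim$reads, ann, quant_config())
  cmp <- merge(q$assignments, sim$truth_reads, by = c("read_id", "sample_id"))
  expect_equal(cmp$transcript_id.x, cmp$transcript_id.y)
})
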