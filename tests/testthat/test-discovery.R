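ann_tiny <- tiny_annotation()

test_that("reads group by exact junction chain; single-exon reads by overlap", {
  b_chain1 <- cbind(c(1000L, 2000L, 3000L), c(1500L, 2500L, 3600L))
  b_chain2 <- cbind(c(1000L, 3000L), c(1500L, 3600L))
  reads <- make_reads(
    read_id = c("a", "b", "c", "d", "m1", "m2", "m3"),
    chrom = "chr1", strand = "+",
    blocks = list(b_chain1, b_chain1, b_chain1, b_chain2,
                  cbind(12000L, 12400L), cbind(12399L, 12800L),
                  cbind(13500L, 13900L)))
  g <- group_reads(reads, discovery_config())
  spl <- g$groups[g$groups$n_junc > 0L]
  expect_equal(sort(spl$support), c(1L, 3L))
  mono <- g$groups[g$groups$n_junc == 0L]
  # m1/m2 overlap by 1 bp -> one cluster; m3 is > gap away at default 100
  expect_equal(sort(mono$support), c(1L, 2L))
  # every read in exactly one group
  expect_equal(nrow(g$members), 7L)
  expect_equal(anyDuplicated(g$members$read_idx), 0L)
})

test_that("correct_sites snaps within a strict tolerance and is idempotent", {
  # annotated junction (1500, 2000) on chr1:+
  ex <- data.frame(transcript_id = "T1", gene_id = "G1", chrom = "chr1",
                   strand = "+", start = c(1000L, 2000L), end = c(1500L, 2600L))
  ann <- build_annotation(ex)
  mk <- function(d, a) make_reads("r", "chr1", "+",
                                  list(cbind(c(1000L, a), c(d, 2600L))))
  cfg <- discovery_config(junction_tol = 5L)
  # 2 bp and 3 bp off -> snapped
  g <- correct_sites(group_reads(mk(1502L, 2003L), cfg), ann, cfg)
  expect_equal(g$junctions$donor_end, 1500L)
  expect_equal(g$junctions$acceptor_start, 2000L)
  # exactly tol off -> unchanged (strict inequality)
  g <- correct_sites(group_reads(mk(1505L, 2005L), cfg), ann, cfg)
  expect_equal(g$junctions$donor_end, 1505L)
  expect_equal(g$junctions$acceptor_start, 2005L)
  # already annotated -> identical, and correction is idempotent
  g0 <- group_reads(mk(1500L, 2000L), cfg)
  g1 <- correct_sites(g0, ann, cfg)
  expect_equal(as.data.frame(g1$junctions), as.data.frame(g0$junctions))
  g2 <- correct_sites(correct_sites(group_reads(mk(1502L, 2003L), cfg), ann, cfg),
                      ann, cfg)
  expect_equal(g2$junctions$donor_end, 1500L)
})

test_that("snap ties go to the smaller coordinate", {
  expect_equal(nanoiso:::snap_to_sites(15L, c(10L, 20L), 6L), 10L)
  expect_equal(nanoiso:::snap_to_sites(16L, c(10L, 20L), 6L), 20L)
  expect_equal(nanoiso:::snap_to_sites(16L, c(10L, 20L), 4L), 16L)
})

test_that("groups with near-identical chains merge into the better-supported one", {
  b1 <- cbind(c(1000L, 2000L), c(1500L, 2600L))     # junction (1500, 2000)
  b2 <- cbind(c(1000L, 2002L), c(1498L, 2600L))     # 2 bp off at both sites
  reads <- make_reads(
    read_id = sprintf("r%02d", 1:11), chrom = "chr1", strand = "+",
    blocks = c(rep(list(b1), 8), rep(list(b2), 3)))
  g <- merge_similar_groups(group_reads(reads), discovery_config())
  expect_equal(nrow(g$groups), 1L)
  expect_equal(g$groups$support, 11L)
  expect_equal(g$junctions$donor_end, 1500L)  # chain of the larger group kept
  # chains of different lengths never merge
  b3 <- cbind(c(1000L, 2000L, 3000L), c(1500L, 2600L, 3500L))
  reads2 <- make_reads(c("a", "b"), "chr1", "+", list(b1, b3))
  g2 <- merge_similar_groups(group_reads(reads2), discovery_config())
  expect_equal(nrow(g2$groups), 2L)
  # identical chains always merge regardless of read ends (within end_tol)
  b4 <- cbind(c(1010L, 2000L), c(1500L, 2590L))
  reads3 <- make_reads(c("a", "b"), "chr1", "+", list(b1, b4))
  g3 <- merge_similar_groups(group_reads(reads3), discovery_config())
  expect_equal(nrow(g3$groups), 1L)
})

test_that("merge matches a brute-force pairwise oracle on small group sets", {
  # oracle: O(n^2) absorption in descending-support order with the same rule
  oracle_merge_count <- function(chains, supports, starts, ends, tol, etol) {
    ord <- order(-supports)
    kept <- list()
    for (i in ord) {
      placed <- FALSE
      for (k in seq_along(kept)) {
        h <- kept[[k]]
        if (nrow(chains[[i]]) != nrow(h$chain)) next
        if (max(abs(chains[[i]] - h$chain)) >= tol) next
        if (abs(stats::median(starts[[i]]) - stats::median(h$starts)) >= etol) next
        if (abs(stats::median(ends[[i]]) - stats::median(h$ends)) >= etol) next
        kept[[k]]$starts <- c(h$starts, starts[[i]])
        kept[[k]]$ends <- c(h$ends, ends[[i]])
        placed <- TRUE
        break
      }
      if (!placed) kept[[length(kept) + 1L]] <- list(chain = chains[[i]],
                                                     starts = starts[[i]],
                                                     ends = ends[[i]])
    }
    length(kept)
  }
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    base <- cbind(c(1500L, 3000L), c(2000L, 3500L))
    chains <- lapply(seq_len(n), function(i) base + sample(-4:4, 1))
    supports <- sample(1:20, n, replace = TRUE)
    starts <- lapply(seq_len(n), function(i) rep(1000L + sample(-30:30, 1), supports[i]))
    ends <- lapply(seq_len(n), function(i) rep(4000L + sample(-30:30, 1), supports[i]))
    blocks <- lapply(seq_len(n), function(i) {
      ch <- chains[[i]]
      cbind(c(starts[[i]][1], ch[, 2]), c(ch[, 1], ends[[i]][1]))
    })
    reads <- make_reads(
      read_id = sprintf("r%03d", seq_len(sum(supports))),
      chrom = "chr1", strand = "+",
      blocks = rep(blocks, supports))
    g <- merge_similar_groups(group_reads(reads), discovery_config())
    expect_equal(nrow(g$groups),
                 oracle_merge_count(chains, supports, starts, ends, 5L, 100L))
  }
})

test_that("truncated sub-chains collapse into the full-length group", {
  full <- cbind(c(1000L, 2000L, 3000L), c(1500L, 2600L, 3700L)) # junctions (1500,2000),(2600,3000)
  trunc <- cbind(c(2550L, 3000L), c(2600L, 3700L))              # suffix, shares right end
  reads <- make_reads(sprintf("r%d", 1:5), "chr1", "+",
                      c(rep(list(full), 3), rep(list(trunc), 2)))
  g <- collapse_truncations(group_reads(reads), discovery_config())
  expect_equal(nrow(g$groups), 1L)
  expect_equal(g$groups$support, 5L)
  expect_equal(nrow(g$junctions), 2L)
  # a chain with a junction absent from the full form is not collapsed
  other <- cbind(c(2550L, 3100L), c(2600L, 3700L))
  reads2 <- make_reads(sprintf("r%d", 1:5), "chr1", "+",
                       c(rep(list(full), 3), rep(list(other), 2)))
  g2 <- collapse_truncations(group_reads(reads2), discovery_config())
  expect_equal(nrow(g2$groups), 2L)
  # anchored end must be within end_tol
  far <- cbind(c(2550L, 3000L), c(2600L, 3850L))   # right end 150 bp away
  reads3 <- make_reads(sprintf("r%d", 1:5), "chr1", "+",
                       c(rep(list(full), 3), rep(list(far), 2)))
  g3 <- collapse_truncations(group_reads(reads3), discovery_config())
  expect_equal(nrow(g3$groups), 2L)
  # 3prime mode on + strand: a suffix chain (missing 5') is NOT collapsed
  g4 <- collapse_truncations(group_reads(reads),
                             discovery_config(trunc_collapse = "3prime"))
  expect_equal(nrow(g4$groups), 2L)
  # ... but a prefix chain (missing 3') is
  pre <- cbind(c(1010L, 2000L), c(1500L, 2300L))
  reads5 <- make_reads(sprintf("r%d", 1:5), "chr1", "+",
                       c(rep(list(full), 3), rep(list(pre), 2)))
  g5 <- collapse_truncations(group_reads(reads5),
                             discovery_config(trunc_collapse = "3prime"))
  expect_equal(nrow(g5$groups), 1L)
})

test_that("support threshold is a sharp boundary at min_support", {
  ann <- ann_tiny
  for (n in c(9L, 10L)) {
    reads <- reads_from_counts(ann, c(GA_T1 = n, GA_T2 = 25L))
    cat_ <- discover(reads, ann, discovery_config(min_support = 10L))
    expect_equal("GA_T1" %in% cat_$transcripts$transcript_id, n >= 10L)
  }
})

test_that("novel isoforms get host-gene ids in the documented format", {
  # a chain using GA's annotated sites but a novel combination is NIC-like;
  # force novelty by shifting one splice site well beyond tolerance
  b <- cbind(c(1000L, 2000L, 3050L), c(1500L, 2500L, 3600L))
  reads <- make_reads(sprintf("r%d", 1:12), "chr1", "+", rep(list(b), 12))
  cat_ <- discover(reads, ann_tiny, discovery_config())
  expect_equal(nrow(cat_$transcripts), 1L)
  expect_equal(cat_$transcripts$source, "novel")
  expect_equal(cat_$transcripts$gene_id, "GA")
  expect_equal(cat_$transcripts$transcript_id, "GA_1001_3600_1")
  # reads far from any gene found a novel orphan gene
  b2 <- cbind(c(50000L, 52000L), c(51000L, 52500L))
  reads2 <- make_reads(sprintf("q%d", 1:12), "chr1", "+", rep(list(b2), 12))
  cat2 <- discover(reads2, ann_tiny, discovery_config())
  expect_equal(cat2$transcripts$gene_id, "novelgene_chr1_1")
  expect_equal(cat2$transcripts$transcript_id, "novelgene_chr1_1_50001_52500_1")
})

test_that("novel ids embed versioned host-gene ids and 1-based coordinates", {
  ex <- data.frame(
    transcript_id = "ENSMUST0001", gene_id = "ENSMUSG00000023452.19",
    chrom = "chr15", strand = "+",
    start = c(32736304L, 32739000L, 32745000L),
    end = c(32736800L, 32739500L, 32746312L))
  ann <- build_annotation(ex)
  # same gene, novel final splice site -> novel isoform hosted by the gene
  b <- cbind(c(32736304L, 32739000L, 32744500L),
             c(32736800L, 32739500L, 32746312L))
  reads <- make_reads(sprintf("r%d", 1:15), "chr15", "+", rep(list(b), 15))
  cat_ <- discover(reads, ann, discovery_config())
  expect_equal(cat_$transcripts$transcript_id,
               "ENSMUSG00000023452.19_32736305_32746312_1")
})

test_that("discovery is deterministic, order-invariant and monotone in min_support", {
  des <- sim_design(n_genes = 12L, n_transcripts = 24L, n_up = 2L,
                    n_down = 2L, n_dtu = 4L)
  ann <- make_annotation(des, 3)
  truth <- make_mix_design(ann, des, 3)
  sim <- simulate_reads(ann, truth, noise_model(p_jitter = 0.2, end_sd = 20),
                        library_size = 3000, sample_mixes = c(S1 = "A"), seed = 3)
  r <- sim$reads$S1
  cat1 <- discover(r, ann, discovery_config())
  # permute read order
  perm <- sample(nrow(r$reads))
  r2 <- r
  r2$reads <- r$reads[perm]
  r2$reads[, read_idx2 := seq_len(.N)]
  map <- stats::setNames(r2$reads$read_idx2, r2$reads$read_idx)
  r2$blocks <- data.table::copy(r$blocks)[, read_idx := map[as.character(read_idx)]]
  r2$reads[, read_idx := read_idx2][, read_idx2 := NULL]
  data.table::setorder(r2$blocks, read_idx, start)
  cat2 <- discover(r2, ann, discovery_config())
  expect_equal(cat1$transcripts$transcript_id, cat2$transcripts$transcript_id)
  expect_equal(cat1$transcripts$support, cat2$transcripts$support)
  # raising min_support can only shrink the catalog
  cat3 <- discover(r, ann, discovery_config(min_support = 25L))
  expect_true(all(cat3$transcripts$transcript_id %in%
                    cat1$transcripts$transcript_id))
  # conservation: supports + dropped reads = total reads
  expect_equal(sum(cat1$transcripts$support) + attr(cat1, "dropped_reads"),
               nrow(r$reads))
})

test_that("discovery on its own GTF output reproduces the same catalog", {
  des <- sim_design(n_genes = 8L, n_transcripts = 14L, n_up = 2L,
                    n_down = 2L, n_dtu = 2L)
  ann <- make_annotation(des, 4)
  truth <- make_mix_design(ann, des, 4)
  sim <- simulate_reads(ann, truth, noise_model(p_trunc = 0, p_jitter = 0, end_sd = 0),
                        library_size = 2000, sample_mixes = c(S1 = "A"), seed = 4)
  cat1 <- discover(sim$reads$S1, ann, discovery_config())
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(cat1, gtf)
  ann2 <- read_gtf(gtf)
  cat2 <- discover(sim$reads$S1, ann2, discovery_config())
  expect_setequal(cat2$transcripts$transcript_id, cat1$transcripts$transcript_id)
})
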