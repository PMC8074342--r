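#' Sequins-like simulation design
#'
#' Defaults mirror a synthetic spliced spike-in mixture: 76 genes carrying
#' 160 transcripts in total, 21 genes up- and 23 down-regulated in mix B
#' versus mix A (4-fold), and 28 genes with differential transcript usage
#' implemented as a proportion swap between two designated isoforms
#' (0.7/0.3 in mix A, 0.3/0.7 in mix B; gene totals preserved for pure-DTU
#' genes). Transcript-per-gene composition for the default design is fixed
#' at (1x28, 2x26, 3x12, 4x6, 5x4).
#'
#' @param n_genes number of genes.
#' @param n_transcripts total number of transcripts.
#' @param n_up,n_down genes up-/down-regulated in mix B.
#' @param n_dtu genes with transcript-proportion swaps (requires >= 2
#'   isoforms; never overlaps the DE sets unless `allow_overlap`).
#' @param de_logfc absolute log2-fold-change applied to DE genes.
#' @param dtu_props proportions of the designated isoform pair in mix A;
#'   reversed in mix B.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   relative gene abundances.
#' @param min_tx_prop floor on within-gene transcript proportions, so every
#'   expressed isoform keeps a workable expected count.
#' @param exon_n_range,exon_len_range,intron_len_range gene-structure
#'   scaffold parameters (bp).
#' @param tx_per_gene optional explicit per-gene transcript counts.
#' @param allow_overlap allow DE and DTU gene sets to overlap.
#' @return a `sim_design` list.
#' @export
sim_design <- function(n_genes = 76L, n_transcripts = 160L, n_up = 21L,
                       n_down = 23L, n_dtu = 28L, de_logfc = 2,
                       dtu_props = c(0.7, 0.3),
                       abundance_meanlog = 0, abundance_sdlog = 0.7,
                       min_tx_prop = 0.05,
                       exon_n_range = c(4L, 8L),
                       exon_len_range = c(80L, 300L),
                       intron_len_range = c(200L, 2000L),
                       tx_per_gene = NULL, allow_overlap = FALSE) {
  stopifnot(n_up + n_down <= n_genes, length(dtu_props) == 2L,
            abs(sum(dtu_props) - 1) < 1e-9)
  structure(list(n_genes = as.integer(n_genes),
                 n_transcripts = as.integer(n_transcripts),
                 n_up = as.integer(n_up), n_down = as.integer(n_down),
                 n_dtu = as.integer(n_dtu), de_logfc = de_logfc,
                 dtu_props = dtu_props,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 min_tx_prop = min_tx_prop,
                 exon_n_range = as.integer(exon_n_range),
                 exon_len_range = as.integer(exon_len_range),
                 intron_len_range = as.integer(intron_len_range),
                 tx_per_gene = tx_per_gene,
                 allow_overlap = allow_overlap),
            class = "sim_design")
}

#' Read noise model
#'
#' Truncation is modelled as a breakage process: with
#' `length_scaled = TRUE` (default) the probability that a read of a
#' transcript of length L bp is truncated is
#' `1 - (1 - p_trunc)^(L / 1000)`, i.e. `p_trunc` is the truncation
#' probability of a 1 kb transcript and longer transcripts are truncated
#' more often -- the mechanism behind the observation that reads of longer
#' transcripts are less often full-length. `length_scaled = FALSE` applies
#' `p_trunc` uniformly. Truncated reads lose a uniform fraction
#' (`trunc_frac_range`) of the transcript, from the 5' end with probability
#' `trunc_side_weights[1]` (cDNA truncation is 5'-biased), the 3' end, or
#' split over both. Each splice site is jittered by +/- U\{1..jitter_max\}
#' with probability `p_jitter`; read ends are jittered by a rounded
#' Normal(0, end_sd) clipped at 3 standard deviations and inside the gene
#' locus.
#'
#' @param p_trunc truncation probability (per kb when `length_scaled`).
#' @param trunc_side_weights weights for 5prime/3prime/both truncation.
#' @param trunc_frac_range uniform range of the truncated fraction.
#' @param p_jitter per-splice-site jitter probability.
#' @param jitter_max maximum splice-site jitter (bp).
#' @param end_sd standard deviation of transcript start/end jitter (bp).
#' @param length_scaled logical; see above.
#' @param trunc_ref_length reference length (bp) for the per-length scaling.
#' @return a `noise_model` list.
#' @export
noise_model <- function(p_trunc = 0.5,
                        trunc_side_weights = c("5prime" = 0.7, "3prime" = 0.3,
                                               "both" = 0),
                        trunc_frac_range = c(0.05, 0.6),
                        p_jitter = 0.1, jitter_max = 3L, end_sd = 30,
                        length_scaled = TRUE, trunc_ref_length = 1000) {
  stopifnot(p_trunc >= 0, p_trunc <= 1, p_jitter >= 0, p_jitter <= 1,
            jitter_max >= 0, end_sd >= 0, length(trunc_side_weights) == 3L)
  structure(list(p_trunc = p_trunc,
                 trunc_side_weights = trunc_side_weights / sum(trunc_side_weights),
                 trunc_frac_range = trunc_frac_range,
                 p_jitter = p_jitter, jitter_max = as.integer(jitter_max),
                 end_sd = end_sd, length_scaled = length_scaled,
                 trunc_ref_length = trunc_ref_length),
            class = "noise_model")
}

# per-read truncation probability given transcript length
trunc_prob <- function(L, noise) {
  if (noise$length_scaled) {
    1 - (1 - noise$p_trunc)^(L / noise$trunc_ref_length)
  } else {
    rep(noise$p_trunc, length(L))
  }
}

#' Generate a toy multi-isoform annotation
#'
#' Genes are placed without overlap along one artificial chromosome; each
#' gene gets an exon scaffold (exon lengths and intron lengths drawn
#' uniformly from the design ranges) and its isoforms are built by skipping
#' distinct subsets of internal exons while sharing the scaffold's first
#' and last exon. This guarantees that within a gene all junction chains
#' are distinct and none is a contiguous sub-chain of a sibling, so a
#' noise-free dataset is exactly identifiable.
#'
#' @param design a [sim_design()].
#' @param seed integer seed; the GTF output is byte-identical across runs
#'   with the same seed.
#' @return a `nanoiso_annotation` with a `chrom_lengths` attribute.
#' @export
make_annotation <- function(design = sim_design(), seed = 1L) {
  set.seed(child_seed(seed, "annotation"))
  ng <- design$n_genes
  ntx <- tx_composition(design)
  chrom <- "chrS"
  cursor <- 10000L
  rows <- list()
  for (g in seq_len(ng)) {
    k <- ntx[g]
    m_min <- max(4L, as.integer(ceiling(log2(max(k, 2L)))) + 2L)
    m <- sample(seq.int(max(m_min, design$exon_n_range[1L]),
                        max(design$exon_n_range[2L], m_min)), 1L)
    exon_len <- sample(design$exon_len_range[1L]:design$exon_len_range[2L], m,
                       replace = TRUE)
    intron_len <- sample(design$intron_len_range[1L]:design$intron_len_range[2L],
                         m - 1L, replace = TRUE)
    starts <- cursor + cumsum(c(0L, exon_len[-m] + intron_len))
    ends <- starts + exon_len
    strand <- sample(c("+", "-"), 1L)
    gene_id <- sprintf("SYNG%03d", g)
    internal <- seq.int(2L, m - 1L)
    # isoform 1 keeps the full scaffold; others skip distinct non-empty
    # subsets of internal exons
    skips <- list(integer(0))
    if (k > 1L) {
      seen <- character(0)
      while (length(skips) < k) {
        sz <- sample(seq_along(internal), 1L)
        sk <- sort(sample(internal, sz))
        kk <- paste(sk, collapse = ",")
        if (kk %in% seen) next
        seen <- c(seen, kk)
        skips[[length(skips) + 1L]] <- sk
      }
    }
    for (ti in seq_len(k)) {
      keep <- setdiff(seq_len(m), skips[[ti]])
      rows[[length(rows) + 1L]] <- data.table::data.table(
        transcript_id = sprintf("%s_T%d", gene_id, ti),
        gene_id = gene_id, chrom = chrom, strand = strand,
        start = starts[keep], end = ends[keep])
    }
    cursor <- ends[m] + sample(5000:20000, 1L)
  }
  ex <- data.table::rbindlist(rows)
  ann <- build_annotation(ex, source = "reference")
  attr(ann, "chrom_lengths") <- stats::setNames(cursor + 10000L, chrom)
  ann
}

# per-gene transcript counts summing to the design total
tx_composition <- function(design) {
  if (!is.null(design$tx_per_gene)) {
    stopifnot(length(design$tx_per_gene) == design$n_genes,
              sum(design$tx_per_gene) == design$n_transcripts)
    return(as.integer(design$tx_per_gene))
  }
  if (design$n_genes == 76L && design$n_transcripts == 160L) {
    comp <- rep(c(1L, 2L, 3L, 4L, 5L), c(28L, 26L, 12L, 6L, 4L))
  } else {
    comp <- rep(1L, design$n_genes)
    extra <- design$n_transcripts - design$n_genes
    stopifnot(extra >= 0L)
    while (extra > 0L) {
      i <- sample(which(comp < 5L), 1L)
      comp[i] <- comp[i] + 1L
      extra <- extra - 1L
    }
  }
  sample(comp)   # shuffle gene order
}

#' Two-mix abundance design with DE and DTU ground truth
#'
#' Mix A gene abundances are drawn log-normal; mix B applies
#' `2^(+/-de_logfc)` to the designated up/down genes. Within-gene isoform
#' proportions are drawn from a floored Dirichlet; in DTU genes the two
#' most abundant isoforms share their combined proportion as
#' `dtu_props` in mix A and reversed in mix B, so pure-DTU genes keep
#' identical gene-level abundance in both mixes.
#'
#' @param ann annotation from [make_annotation()].
#' @param design a [sim_design()].
#' @param seed integer seed.
#' @return a `nanoiso_truth` object: data.tables `tx` (transcript_id,
#'   gene_id, length, prop_A/B, abund_A/B normalised per mix, dtu) and
#'   `genes` (gene_id, n_tx, de, dtu).
#' @export
make_mix_design <- function(ann, design = sim_design(), seed = 1L) {
  set.seed(child_seed(seed, "mixes"))
  tx <- data.table::copy(ann$transcripts[, .(transcript_id, gene_id,
                                             length = exonic_len)])
  genes <- ann$genes[, .(gene_id, n_tx)]
  multi <- genes$gene_id[genes$n_tx >= 2L]
  if (design$n_dtu > length(multi)) {
    stop("design asks for more DTU genes than genes with >= 2 isoforms")
  }
  dtu_genes <- sort(sample(multi, design$n_dtu))
  pool <- if (design$allow_overlap) genes$gene_id else
    setdiff(genes$gene_id, dtu_genes)
  up_genes <- sort(sample(pool, design$n_up))
  down_genes <- sort(sample(setdiff(pool, up_genes), design$n_down))

  genes[, de := "none"]
  genes[gene_id %in% up_genes, de := "up"]
  genes[gene_id %in% down_genes, de := "down"]
  genes[, dtu := gene_id %in% dtu_genes]
  gene_ab <- stats::rlnorm(nrow(genes), design$abundance_meanlog,
                           design$abundance_sdlog)
  genes[, abund_A := gene_ab]
  genes[, abund_B := abund_A *
          ifelse(de == "up", 2^design$de_logfc,
                 ifelse(de == "down", 2^(-design$de_logfc), 1))]

  tx[, dtu := FALSE]
  prop_list <- vector("list", nrow(genes))
  data.table::setorder(tx, gene_id, transcript_id)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    ids <- tx$transcript_id[tx$gene_id == gid]
    k <- length(ids)
    p <- stats::rgamma(k, shape = 5)
    p <- p / sum(p)
    p <- pmax(p, design$min_tx_prop)
    p <- p / sum(p)
    pa <- p; pb <- p
    if (genes$dtu[i]) {
      pair <- order(-p, ids)[1:2]
      s <- sum(p[pair])
      pa[pair] <- design$dtu_props * s
      pb[pair] <- rev(design$dtu_props) * s
      tx[transcript_id %in% ids[pair], dtu := TRUE]
    }
    prop_list[[i]] <- data.table::data.table(transcript_id = ids,
                                             prop_A = pa, prop_B = pb)
  }
  props <- data.table::rbindlist(prop_list)
  tx <- merge(tx, props, by = "transcript_id")
  tx <- merge(tx, genes[, .(gene_id, g_A = abund_A, g_B = abund_B)],
              by = "gene_id")
  tx[, abund_A := g_A * prop_A]
  tx[, abund_B := g_B * prop_B]
  tx[, `:=`(abund_A = abund_A / sum(abund_A), abund_B = abund_B / sum(abund_B))]
  tx[, `:=`(g_A = NULL, g_B = NULL)]
  data.table::setcolorder(tx, c("transcript_id", "gene_id", "length",
                                "prop_A", "prop_B", "abund_A", "abund_B", "dtu"))
  structure(list(tx = tx[], genes = genes[], design = design),
            class = "nanoiso_truth")
}

#' @export
print.nanoiso_truth <- function(x, ...) {
  cat("nanoiso truth:", nrow(x$tx), "transcripts,",
      sum(x$tx$dtu), "DTU transcripts in", sum(x$genes$dtu), "genes;",
      sum(x$genes$de != "none"), "DE genes\n")
  invisible(x)
}

#' Simulate spliced long-read alignments
#'
#' Per read: a source transcript is drawn from the mix abundances
#' (multinomial), a covered transcript interval is chosen by the truncation
#' model, projected through the exon structure to genomic blocks, and
#' splice-site/end jitter applied. Reads are emitted as alignments (the
#' representation the pipeline consumes); `read_length` equals the covered
#' transcript bases. A per-read truth table records the source transcript,
#' truncation flag and covered fraction.
#'
#' @param ann annotation from [make_annotation()].
#' @param truth mix design from [make_mix_design()].
#' @param noise a [noise_model()].
#' @param library_size reads per sample.
#' @param sample_mixes named character vector sample_id -> mix ("A"/"B").
#' @param seed master seed; per-sample child seeds are derived
#'   deterministically.
#' @param counts optional integer matrix (transcripts x samples) overriding
#'   the multinomial draw (rownames = transcript ids).
#' @return list with `reads` (named list of `nanoiso_reads`), `truth_reads`
#'   (data.table: read_id, sample_id, transcript_id, truncated,
#'   covered_frac), and `true_counts` (transcripts x samples matrix).
#' @export
simulate_reads <- function(ann, truth, noise = noise_model(),
                           library_size = 10000L,
                           sample_mixes = c(A1 = "A", A2 = "A",
                                            B1 = "B", B2 = "B"),
                           seed = 1L, counts = NULL) {
  tx <- truth$tx
  exd <- ann$exons[order(transcript_id, start)]
  txmeta <- ann$transcripts
  strand_map <- stats::setNames(txmeta$strand, txmeta$transcript_id)
  chrom_map <- stats::setNames(txmeta$chrom, txmeta$transcript_id)
  gene_of_tx <- stats::setNames(txmeta$gene_id, txmeta$transcript_id)
  gene_lo <- stats::setNames(ann$genes$start, ann$genes$gene_id)
  gene_hi <- stats::setNames(ann$genes$end, ann$genes$gene_id)
  # per-transcript exon tables with cumulative widths (genomic order)
  exl <- split(exd, by = "transcript_id")
  excum <- lapply(exl, function(d) {
    w <- d$end - d$start
    list(start = d$start, end = d$end, cum = cumsum(w), w = w,
         L = sum(w), strand = d$strand[1L], chrom = d$chrom[1L],
         gene_id = d$gene_id[1L])
  })
  samples <- names(sample_mixes)
  out_reads <- list(); truth_rows <- list()
  true_counts <- matrix(0L, nrow = nrow(tx), ncol = length(samples),
                        dimnames = list(tx$transcript_id, samples))
  for (s in samples) {
    set.seed(child_seed(seed, paste0("sample_", s)))
    mix <- sample_mixes[[s]]
    ab <- if (mix == "A") tx$abund_A else tx$abund_B
    cnt <- if (!is.null(counts)) {
      counts[tx$transcript_id, s]
    } else {
      as.integer(stats::rmultinom(1L, size = library_size, prob = ab))
    }
    true_counts[, s] <- cnt
    n <- sum(cnt)
    if (n == 0L) {
      out_reads[[s]] <- empty_reads_container()
      next
    }
    tid <- rep(tx$transcript_id, cnt)
    L <- rep(tx$length, cnt)
    p_tr <- trunc_prob(L, noise)
    truncated <- stats::runif(n) < p_tr
    side <- rep("none", n)
    lo <- integer(n); hi <- L
    if (any(truncated)) {
      nt <- sum(truncated)
      side[truncated] <- sample(names(noise$trunc_side_weights), nt,
                                replace = TRUE, prob = noise$trunc_side_weights)
      frac <- stats::runif(nt, noise$trunc_frac_range[1L], noise$trunc_frac_range[2L])
      cut <- pmin(L[truncated] - 1L, pmax(1L, as.integer(round(frac * L[truncated]))))
      w5 <- side[truncated] == "5prime"
      w3 <- side[truncated] == "3prime"
      wb <- side[truncated] == "both"
      lo_t <- integer(nt); hi_t <- L[truncated]
      lo_t[w5] <- cut[w5]
      hi_t[w3] <- L[truncated][w3] - cut[w3]
      lo_t[wb] <- as.integer(floor(cut[wb] / 2))
      hi_t[wb] <- L[truncated][wb] - (cut[wb] - as.integer(floor(cut[wb] / 2)))
      lo[truncated] <- lo_t; hi[truncated] <- hi_t
    }
    bad <- hi - lo < 1L
    if (any(bad)) { lo[bad] <- 0L; hi[bad] <- L[bad] }  # degenerate: emit full read

    # transcript -> genomic orientation
    strand <- unname(strand_map[tid])
    glo <- ifelse(strand == "+", lo, L - hi)
    ghi <- ifelse(strand == "+", hi, L - lo)

    rd <- data.table::data.table(ri = seq_len(n), tid = tid, glo = glo,
                                 ghi = ghi, L = L, strand = strand)
    # project per transcript
    blocks_parts <- vector("list", length(unique(tid)))
    bi <- 0L
    for (t1 in unique(tid)) {
      e <- excum[[t1]]
      sel <- rd$tid == t1
      gl <- rd$glo[sel]; gh <- rd$ghi[sel]
      cum0 <- c(0L, e$cum)
      i1 <- findInterval(gl, cum0, rightmost.closed = FALSE)      # first exon
      i2 <- findInterval(gh - 1L, cum0)                            # last exon
      nb <- i2 - i1 + 1L
      ri <- rd$ri[sel]
      rows <- rep.int(seq_along(ri), nb)
      eidx <- sequence(nb, from = i1)
      bstart <- e$start[eidx]
      bend <- e$end[eidx]
      first <- c(TRUE, diff(rows) != 0L)
      last <- c(diff(rows) != 0L, TRUE)
      bstart[first] <- e$start[i1] + (gl - cum0[i1])
      bend[last] <- e$start[i2] + (gh - cum0[i2])
      bi <- bi + 1L
      blocks_parts[[bi]] <- data.table::data.table(
        read_idx = ri[rows], start = bstart, end = bend,
        first = first, last = last)
    }
    blocks <- data.table::rbindlist(blocks_parts)
    data.table::setorder(blocks, read_idx, start)

    # splice-site jitter on internal boundaries
    if (noise$p_jitter > 0 && noise$jitter_max > 0L) {
      don <- which(!blocks$last)       # block ends that are donors
      acc <- which(!blocks$first)      # block starts that are acceptors
      jd <- stats::runif(length(don)) < noise$p_jitter
      ja <- stats::runif(length(acc)) < noise$p_jitter
      if (any(jd)) {
        d <- sample(c(-noise$jitter_max:-1L, 1L:noise$jitter_max), sum(jd),
                    replace = TRUE)
        blocks$end[don[jd]] <- blocks$end[don[jd]] + d
      }
      if (any(ja)) {
        d <- sample(c(-noise$jitter_max:-1L, 1L:noise$jitter_max), sum(ja),
                    replace = TRUE)
        blocks$start[acc[ja]] <- blocks$start[acc[ja]] + d
      }
    }
    # end jitter, clipped at 3 sd and inside the gene locus
    if (noise$end_sd > 0) {
      cap <- as.integer(floor(3 * noise$end_sd))
      g_of_read <- unname(gene_of_tx[tid])
      glo_gene <- unname(gene_lo[g_of_read])
      ghi_gene <- unname(gene_hi[g_of_read])
      j1 <- pmin(pmax(as.integer(round(stats::rnorm(n, 0, noise$end_sd))), -cap), cap)
      j2 <- pmin(pmax(as.integer(round(stats::rnorm(n, 0, noise$end_sd))), -cap), cap)
      firsts <- which(blocks$first); lasts <- which(blocks$last)
      ri_first <- blocks$read_idx[firsts]; ri_last <- blocks$read_idx[lasts]
      ns <- blocks$start[firsts] + j1[ri_first]
      ns <- pmax(ns, glo_gene[ri_first])
      ns <- pmin(ns, blocks$end[firsts] - 1L)
      blocks$start[firsts] <- ns
      ne <- blocks$end[lasts] + j2[ri_last]
      ne <- pmin(ne, ghi_gene[ri_last])
      ne <- pmax(ne, blocks$start[lasts] + 1L)
      blocks$end[lasts] <- ne
    }

    read_ids <- sprintf("%s_r%06d", s, seq_len(n))
    rstats <- blocks[, .(start = min(start), end = max(end),
                         n_blocks = .N, read_length = sum(end - start)),
                     by = read_idx]
    reads_dt <- data.table::data.table(
      read_idx = rstats$read_idx,
      read_id = read_ids[rstats$read_idx],
      sample_id = s,
      chrom = unname(chrom_map[tid[rstats$read_idx]]),
      strand = strand[rstats$read_idx],
      start = rstats$start, end = rstats$end,
      n_blocks = rstats$n_blocks,
      read_length = rstats$read_length,
      aligned_bases = rstats$read_length)
    rc <- list(reads = reads_dt,
               blocks = blocks[, .(read_idx, start, end)])
    attr(rc, "dropped") <- c(unmapped = 0L, secondary = 0L, supplementary = 0L)
    attr(rc, "n_input") <- n
    class(rc) <- "nanoiso_reads"
    out_reads[[s]] <- rc
    truth_rows[[s]] <- data.table::data.table(
      read_id = read_ids, sample_id = s, transcript_id = tid,
      truncated = truncated, covered_frac = (hi - lo) / L)
  }
  list(reads = out_reads,
       truth_reads = data.table::rbindlist(truth_rows),
       true_counts = true_counts)
}

empty_reads_container <- function() {
  rc <- list(reads = data.table::data.table(
    read_idx = integer(0), read_id = character(0), sample_id = character(0),
    chrom = character(0), strand = character(0), start = integer(0),
    end = integer(0), n_blocks = integer(0), read_length = integer(0),
    aligned_bases = integer(0)),
    blocks = data.table::data.table(read_idx = integer(0), start = integer(0),
                                    end = integer(0)))
  attr(rc, "dropped") <- c(unmapped = 0L, secondary = 0L, supplementary = 0L)
  attr(rc, "n_input") <- 0L
  class(rc) <- "nanoiso_reads"
  rc
}

#' Write simulated reads as a SAM file
#'
#' Records are sorted by coordinate; CIGARs use only M and N (the simulator
#' emits gap-free blocks), FLAG encodes the strand, SEQ/QUAL are `*`.
#'
#' @param reads a `nanoiso_reads` container.
#' @param chrom_lengths named integer vector for the `@SQ` header lines.
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_lengths, path) {
  r <- data.table::copy(reads$reads)
  b <- reads$blocks[order(read_idx, start)]
  # vectorised CIGAR assembly: mark the first block of each read with a
  # sentinel, collapse, then split once
  b[, w := end - start]
  b[, gap := start - data.table::shift(end), by = read_idx]
  seg <- ifelse(is.na(b$gap), paste0("\x01", b$w, "M"),
                paste0(b$gap, "N", b$w, "M"))
  cig <- strsplit(paste(seg, collapse = ""), "\x01", fixed = TRUE)[[1L]][-1L]
  first_idx <- b[, .(read_idx = unique(read_idx))]$read_idx
  cigs <- stats::setNames(cig, first_idx)

  rec <- data.table::data.table(
    qname = r$read_id,
    flag = ifelse(r$strand == "-", 16L, 0L),
    rname = r$chrom,
    pos = r$start + 1L,
    mapq = 60L,
    cigar = cigs[as.character(r$read_idx)],
    rnext = "*", pnext = 0L, tlen = 0L, seq = "*", qual = "*")
  data.table::setorder(rec, rname, pos)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  writeLines(hdr, path)
  data.table::fwrite(rec, path, sep = "\t", col.names = FALSE, append = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' Run the full simulator and write all outputs
#'
#' Writes `ref.gtf`, one coordinate-sorted SAM per sample, and the truth
#' tables (`truth_reads.tsv`, `truth_abundance.tsv`, `truth_de.tsv`,
#' `truth_dtu.tsv`, `true_counts.tsv`).
#'
#' @param sim result of [simulate_reads()].
#' @param ann,truth the annotation and mix design the reads were drawn from.
#' @param outdir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_outputs <- function(sim, ann, truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(gtf = file.path(outdir, "ref.gtf"))
  write_gtf(ann, paths$gtf)
  cl <- attr(ann, "chrom_lengths")
  if (is.null(cl)) {
    cl <- tapply(ann$exons$end, ann$exons$chrom, function(e) max(e) + 10000L)
  }
  for (s in names(sim$reads)) {
    p <- file.path(outdir, paste0(s, ".sam"))
    write_sam(sim$reads[[s]], cl, p)
    paths[[paste0("sam_", s)]] <- p
  }
  tr <- file.path(outdir, "truth_reads.tsv")
  data.table::fwrite(sim$truth_reads, tr, sep = "\t")
  paths$truth_reads <- tr
  ta <- file.path(outdir, "truth_abundance.tsv")
  data.table::fwrite(truth$tx, ta, sep = "\t")
  paths$truth_abundance <- ta
  tde <- file.path(outdir, "truth_de.tsv")
  data.table::fwrite(truth$genes[, .(gene_id, de, dtu)], tde, sep = "\t")
  paths$truth_de <- tde
  tdtu <- file.path(outdir, "truth_dtu.tsv")
  data.table::fwrite(truth$tx[, .(transcript_id, gene_id, dtu)], tdtu, sep = "\t")
  paths$truth_dtu <- tdtu
  tc <- file.path(outdir, "true_counts.tsv")
  data.table::fwrite(data.table::data.table(transcript_id = rownames(sim$true_counts),
                                            sim$true_counts),
                     tc, sep = "\t")
  paths$true_counts <- tc
  invisible(paths)
}

#' Expected truncated-read fraction under the noise model
#'
#' Abundance-weighted mean of the per-transcript truncation probability.
#'
#' @param truth mix design from [make_mix_design()].
#' @param noise a [noise_model()].
#' @param mix `"A"` or `"B"`.
#' @return a fraction.
#' @export
expected_truncated_fraction <- function(truth, noise = noise_model(), mix = "A") {
  ab <- if (mix == "A") truth$tx$abund_A else truth$tx$abund_B
  sum(ab * trunc_prob(truth$tx$length, noise))
}

#' Model-implied full-length read fraction
#'
#' With the truncated fraction drawn from `trunc_frac_range` above the
#' full-length coverage margin, truncated reads are never full-length, so
#' the expected full-length fraction is the abundance-weighted probability
#' of escaping truncation. Valid for `end_sd = 0` (no end jitter); end
#' jitter shaves additional coverage and is not accounted for here.
#'
#' @inheritParams expected_truncated_fraction
#' @param full_length_cov the full-length coverage threshold.
#' @return a fraction.
#' @export
expected_full_length_fraction <- function(truth, noise = noise_model(end_sd = 0),
                                          mix = "A", full_length_cov = 0.95) {
  if (noise$end_sd > 0) {
    warning("expected_full_length_fraction() assumes end_sd = 0; value ignores end jitter")
  }
  if (noise$trunc_frac_range[1L] < 1 - full_length_cov - 1e-9) {
    warning("truncation fractions below the coverage margin make truncated reads full-length; value is a lower bound")
  }
  1 - expected_truncated_fraction(truth, noise, mix)
}

#' Simulate a null transcript count matrix (no DTU, no DE)
#'
#' Expected transcript counts are drawn log-normal and identical in both
#' groups; observed counts are Poisson around the expectation, emulating
#' technical replicates of a fixed RNA pool.
#'
#' @param n_genes number of genes.
#' @param tx_range range of transcripts per gene (sampled uniformly).
#' @param n1,n2 samples per group.
#' @param mean_log,sd_log log-normal parameters of expected counts.
#' @param seed integer seed.
#' @return list with `counts` (`nanoiso_counts`) and `design` (named group
#'   vector).
#' @export
simulate_null_counts <- function(n_genes = 1000L, tx_range = 2:4,
                                 n1 = 3L, n2 = 3L,
                                 mean_log = log(200), sd_log = 0.7,
                                 seed = 1L) {
  set.seed(child_seed(seed, "null_counts"))
  ktx <- sample(tx_range, n_genes, replace = TRUE)
  gene_id <- rep(sprintf("G%04d", seq_len(n_genes)), ktx)
  tx_id <- paste0(gene_id, "_T", unlist(lapply(ktx, seq_len)))
  mu <- stats::rlnorm(length(tx_id), mean_log, sd_log)
  ns <- n1 + n2
  m <- matrix(stats::rpois(length(mu) * ns, rep(mu, ns)),
              nrow = length(mu), ncol = ns,
              dimnames = list(tx_id, c(paste0("A", seq_len(n1)),
                                       paste0("B", seq_len(n2)))))
  design <- stats::setNames(rep(c("grp1", "grp2"), c(n1, n2)), colnames(m))
  counts <- structure(list(counts = m,
                           gene_map = stats::setNames(gene_id, tx_id),
                           unassigned = stats::setNames(integer(ns), colnames(m))),
                      class = "nanoiso_counts")
  list(counts = counts, design = design)
}

#' Simulate count matrices from a two-mix design
#'
#' Count-level companion of [simulate_reads()] for statistical testing at
#' scale: expected counts are the mix abundances times the library size
#' (optionally raised so every transcript reaches `min_expected` counts),
#' observed counts are Poisson.
#'
#' @param truth mix design from [make_mix_design()].
#' @param n_per_group samples per mix.
#' @param library_size reads per sample; when `NULL`, chosen as the
#'   smallest size giving every transcript `min_expected` expected counts.
#' @param min_expected see above.
#' @param seed integer seed.
#' @return list with `counts` (`nanoiso_counts`), `design`, and
#'   `library_size`.
#' @export
simulate_mix_counts <- function(truth, n_per_group = 2L, library_size = NULL,
                                min_expected = 100, seed = 1L) {
  set.seed(child_seed(seed, "mix_counts"))
  tx <- truth$tx
  if (is.null(library_size)) {
    mn <- min(c(tx$abund_A, tx$abund_B))
    library_size <- as.integer(ceiling(min_expected / mn))
  }
  sa <- paste0("A", seq_len(n_per_group))
  sb <- paste0("B", seq_len(n_per_group))
  muA <- tx$abund_A * library_size
  muB <- tx$abund_B * library_size
  m <- cbind(
    matrix(stats::rpois(nrow(tx) * n_per_group, rep(muA, n_per_group)),
           ncol = n_per_group, dimnames = list(tx$transcript_id, sa)),
    matrix(stats::rpois(nrow(tx) * n_per_group, rep(muB, n_per_group)),
           ncol = n_per_group, dimnames = list(tx$transcript_id, sb)))
  design <- stats::setNames(rep(c("A", "B"), each = n_per_group), c(sa, sb))
  counts <- structure(list(counts = m,
                           gene_map = stats::setNames(tx$gene_id, tx$transcript_id),
                           unassigned = stats::setNames(integer(ncol(m)), colnames(m))),
                      class = "nanoiso_counts")
  list(counts = counts, design = design, library_size = library_size)
}
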