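# Independent reference implementations (oracles) used only by the tests,
# plus small fixture builders. Oracles deliberately use naive enumeration
# rather than the package's indexed code paths.

# ---- p-value oracles -------------------------------------------------------

oracle_simes <- function(p) {
  k <- length(p)
  ps <- sort(p)
  min(1, min(vapply(seq_len(k), function(i) ps[i] * k / i, 0)))
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in seq(n, 1L)) {
    val <- min(1, p[o[i]] * n / i, prev)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 0
  for (i in seq_len(n)) {
    val <- max(prev, min(1, p[o[i]] * (n - i + 1L)))
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# ---- CIGAR oracle ----------------------------------------------------------

# Random spliced-alignment CIGAR over M/I/D/N/S/H: exon segments (M runs
# with interspersed I/D) separated by N gaps, optional clips at the ends.
random_cigar <- function() {
  n_seg <- sample(1:4, 1)
  seg <- function() {
    parts <- paste0(sample(1:300, 1), "M")
    n_extra <- sample(0:2, 1)
    for (i in seq_len(n_extra)) {
      parts <- c(parts, paste0(sample(1:30, 1), sample(c("I", "D"), 1)),
                 paste0(sample(1:300, 1), "M"))
    }
    paste(parts, collapse = "")
  }
  ops <- seg()
  for (i in seq_len(n_seg - 1L)) {
    ops <- c(ops, paste0(sample(30:5000, 1), "N"), seg())
  }
  if (stats::runif(1) < 0.3) ops <- c(paste0(sample(1:20, 1), "S"), ops)
  if (stats::runif(1) < 0.3) ops <- c(ops, paste0(sample(1:20, 1), "S"))
  if (stats::runif(1) < 0.2) ops <- c(paste0(sample(1:20, 1), "H"), ops)
  paste(ops, collapse = "")
}

# ---- classifier oracle -----------------------------------------------------

# junction chain of a transcript id in an annotation, as a list of c(d, a)
oracle_chain <- function(ann, tid) {
  ex <- as.data.frame(ann$exons[ann$exons$transcript_id == tid, ])
  ex <- ex[order(ex$start), ]
  if (nrow(ex) < 2) return(list())
  lapply(seq_len(nrow(ex) - 1L),
         function(i) c(ex$end[i], ex$start[i + 1L]))
}

chains_equal <- function(a, b) {
  length(a) == length(b) &&
    all(vapply(seq_along(a), function(i) all(a[[i]] == b[[i]]), TRUE))
}

# every contiguous, non-empty, proper sub-chain of a chain
oracle_subchains <- function(chain) {
  out <- list()
  k <- length(chain)
  for (len in seq_len(max(0, k - 1L))) {
    for (off in seq_len(k - len + 1L)) {
      out[[length(out) + 1L]] <- chain[off:(off + len - 1L)]
    }
  }
  out
}

# naive interval-list overlap in bases
oracle_overlap <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    tot <- tot + max(0L, min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1]))
  }
  tot
}

# Brute-force structural classifier following the documented decision list,
# via explicit enumeration of reference chains, sub-chains and site sets.
oracle_classify <- function(t, ann) {
  tx <- as.data.frame(ann$exons)
  same_tx <- unique(tx$transcript_id[tx$chrom == t$chrom & tx$strand == t$strand])
  qchain <- apply(nanoiso::junction_chain(t$exons), 1L, function(r) c(r[1], r[2]),
                  simplify = FALSE)
  if (length(qchain)) {
    for (tid in same_tx) {
      if (chains_equal(qchain, oracle_chain(ann, tid))) return("FSM")
    }
    for (tid in same_tx) {
      for (sc in oracle_subchains(oracle_chain(ann, tid))) {
        if (chains_equal(qchain, sc)) return("ISM")
      }
    }
  }
  # gene-level exonic overlap, same strand
  genes_same <- unique(tx$gene_id[tx$chrom == t$chrom & tx$strand == t$strand])
  ov_genes <- character(0)
  for (g in genes_same) {
    ge <- tx[tx$gene_id == g & tx$chrom == t$chrom & tx$strand == t$strand, ]
    if (oracle_overlap(t$exons, cbind(ge$start, ge$end)) > 0L) {
      ov_genes <- c(ov_genes, g)
    }
  }
  if (length(qchain)) {
    if (length(ov_genes) == 1L) {
      donors <- unique(unlist(lapply(same_tx, function(tid)
        vapply(oracle_chain(ann, tid), `[`, 0, 1L))))
      acceptors <- unique(unlist(lapply(same_tx, function(tid)
        vapply(oracle_chain(ann, tid), `[`, 0, 2L))))
      ok <- all(vapply(qchain, `[`, 0, 1L) %in% donors) &&
        all(vapply(qchain, `[`, 0, 2L) %in% acceptors)
      return(if (ok) "NIC" else "NNC")
    }
    if (length(ov_genes) >= 2L) return("fusion")
  } else if (length(ov_genes) >= 1L) {
    return("genic")
  }
  gn <- as.data.frame(ann$genes)
  span <- c(min(t$exons[, 1]), max(t$exons[, 2]))
  body_hit <- function(str) {
    any(gn$chrom == t$chrom & gn$strand == str &
          gn$end > span[1] & gn$start < span[2])
  }
  anti <- body_hit(setdiff(c("+", "-"), t$strand))
  same_body <- body_hit(t$strand)
  if (anti && !same_body) return("antisense")
  if (anti || same_body) return("genic")
  "intergenic"
}

# ---- fixture builders ------------------------------------------------------

# a small hand-laid annotation used across unit tests:
#  GA (+): GA_T1 3 exons, GA_T2 skips the middle exon
#  GB (-): GB_T1 2 exons
#  GC (+): single-exon gene far downstream
tiny_annotation <- function() {
  ex <- data.frame(
    transcript_id = c("GA_T1", "GA_T1", "GA_T1", "GA_T2", "GA_T2",
                      "GB_T1", "GB_T1", "GC_T1"),
    gene_id = c(rep("GA", 5), "GB", "GB", "GC"),
    chrom = "chr1",
    strand = c(rep("+", 5), "-", "-", "+"),
    start = c(1000L, 2000L, 3000L, 1000L, 3000L, 6000L, 7000L, 12000L),
    end = c(1500L, 2500L, 3600L, 1500L, 3600L, 6400L, 7500L, 12800L))
  nanoiso::build_annotation(ex)
}

# build a nanoiso_reads container from a data.frame with read_id, chrom,
# strand and a list-column of block matrices
make_reads <- function(read_id, chrom, strand, blocks, sample_id = "S1",
                       read_length = NULL, aligned = NULL) {
  n <- length(read_id)
  bl <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    data.table::data.table(read_idx = i, start = blocks[[i]][, 1],
                           end = blocks[[i]][, 2])
  }))
  lens <- vapply(blocks, function(b) sum(b[, 2] - b[, 1]), 0)
  rl <- if (is.null(read_length)) as.integer(lens) else as.integer(read_length)
  al <- if (is.null(aligned)) as.integer(lens) else as.integer(aligned)
  rd <- data.table::data.table(
    read_idx = seq_len(n), read_id = read_id, sample_id = sample_id,
    chrom = chrom, strand = strand,
    start = vapply(blocks, function(b) min(b[, 1]), 0),
    end = vapply(blocks, function(b) max(b[, 2]), 0),
    n_blocks = vapply(blocks, nrow, 0L),
    read_length = rl, aligned_bases = al)
  out <- list(reads = rd, blocks = bl)
  attr(out, "dropped") <- c(unmapped = 0L, secondary = 0L, supplementary = 0L)
  attr(out, "n_input") <- n
  class(out) <- "nanoiso_reads"
  out
}

# n identical zero-noise reads for each transcript (counts named by id)
reads_from_counts <- function(ann, counts, sample_id = "S1") {
  ids <- rep(names(counts), counts)
  blocks <- lapply(ids, function(tid) {
    tm <- nanoiso::transcript_model(ann, tid)
    tm$exons
  })
  meta <- as.data.frame(ann$transcripts)
  rownames(meta) <- meta$transcript_id
  make_reads(sprintf("%s_read%04d", sample_id, seq_along(ids)),
             chrom = meta[ids, "chrom"], strand = meta[ids, "strand"],
             blocks = blocks, sample_id = sample_id)
}

# random toy annotation + query isoforms for the classifier tests
random_classify_case <- function(seed) {
  set.seed(seed)
  des <- nanoiso::sim_design(n_genes = 4L, n_transcripts = sample(6:9, 1),
                             n_up = 0L, n_down = 0L, n_dtu = 0L)
  ann <- nanoiso::make_annotation(des, seed)
  tx <- as.data.frame(ann$transcripts)
  pick <- tx[sample(nrow(tx), 1), ]
  tm <- nanoiso::transcript_model(ann, pick$transcript_id)
  kind <- sample(c("fsm", "ism", "nic", "nnc", "anti", "fusion", "genic",
                   "intergenic", "random"), 1)
  ex <- tm$exons
  q <- tm
  q$transcript_id <- "query"
  if (kind == "fsm") {
    q$exons <- ex
  } else if (kind == "ism" && nrow(ex) >= 3) {
    i <- sample(seq_len(nrow(ex) - 1L), 1)
    len <- sample(seq_len(nrow(ex) - i), 1)
    q$exons <- ex[i:(i + len), , drop = FALSE]
  } else if (kind == "nic") {
    # drop an internal exon if possible: new junction from annotated sites
    if (nrow(ex) >= 3) q$exons <- ex[-sample(2:(nrow(ex) - 1L), 1), , drop = FALSE]
  } else if (kind == "nnc") {
    i <- sample(seq_len(nrow(ex)), 1)
    shift <- sample(c(-40L, 25L, 57L), 1)
    q$exons[i, 2] <- q$exons[i, 2] + shift
    q$exons <- q$exons[order(q$exons[, 1]), , drop = FALSE]
    if (any(q$exons[, 1] >= q$exons[, 2]) ||
        any(q$exons[-1, 1] < q$exons[-nrow(q$exons), 2])) q$exons <- ex
  } else if (kind == "anti") {
    q$strand <- setdiff(c("+", "-"), tm$strand)
  } else if (kind == "fusion") {
    other <- tx[tx$gene_id != pick$gene_id & tx$strand == pick$strand, ]
    if (nrow(other)) {
      om <- nanoiso::transcript_model(ann, other$transcript_id[1])
      q$exons <- rbind(ex, om$exons)
      q$exons <- q$exons[order(q$exons[, 1]), , drop = FALSE]
    }
  } else if (kind == "genic") {
    # an interval inside the first intron
    if (nrow(ex) >= 2) {
      q$exons <- cbind(ex[1, 2] + 10L, ex[2, 1] - 10L)
      if (q$exons[1, 1] >= q$exons[1, 2]) q$exons <- ex
    }
  } else if (kind == "intergenic") {
    far <- max(as.data.frame(ann$genes)$end) + 50000L
    q$exons <- cbind(far, far + 500L)
  } else {
    # random spliced structure near the gene
    s <- pick$start + sample(-200:200, 1)
    widths <- sample(50:200, 3, replace = TRUE)
    gaps <- sample(100:1500, 2, replace = TRUE)
    starts <- s + cumsum(c(0L, widths[-3] + gaps))
    q$exons <- cbind(starts, starts + widths)
  }
  storage.mode(q$exons) <- "integer"
  colnames(q$exons) <- c("start", "end")
  list(ann = ann, q = q)
}
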