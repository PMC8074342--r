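#' Quantification configuration
#'
#' @param min_read_aligned_frac a read is assignable to a transcript only
#'   when strictly more than this fraction of its sequence aligns within the
#'   transcript's exons (default 0.80, strict `>`).
#' @param full_length_cov a read is "full-length" when it covers at least
#'   this fraction of its assigned transcript's exonic bases (default 0.95,
#'   inclusive `>=`).
#' @param cpm_prior pseudo-count added before log2 counts-per-million.
#' @return a `quant_config` list.
#' @export
quant_config <- function(min_read_aligned_frac = 0.80, full_length_cov = 0.95,
                         cpm_prior = 0.5) {
  stopifnot(min_read_aligned_frac > 0, min_read_aligned_frac <= 1,
            full_length_cov > 0, full_length_cov <= 1, cpm_prior >= 0)
  structure(list(min_read_aligned_frac = min_read_aligned_frac,
                 full_length_cov = full_length_cov, cpm_prior = cpm_prior),
            class = "quant_config")
}

#' Coverage statistics of a read against a transcript
#'
#' `transcript_cov` is the fraction of the transcript's exonic bases
#' overlapped by the read's aligned blocks; `read_aligned_frac` is the
#' fraction of the read's bases that align within the transcript's exons.
#' Deletion-consumed reference bases inside blocks are not read bases and
#' are subtracted from the exonic overlap before dividing by the read
#' length.
#'
#' @param r a read: list with `blocks` (matrix start/end), `read_length`,
#'   and optionally `aligned_read_bases` (defaults to the block total).
#' @param t a transcript model ([transcript_model()]).
#' @return named numeric vector `c(transcript_cov, read_aligned_frac)`.
#' @export
coverage_stats <- function(r, t) {
  blocks <- r$blocks
  exons <- t$exons
  exonic_len <- sum(exons[, 2L] - exons[, 1L])
  ov <- interval_overlap(blocks, exons)
  block_total <- sum(blocks[, 2L] - blocks[, 1L])
  aligned <- if (!is.null(r$aligned_read_bases)) r$aligned_read_bases else block_total
  d_bases <- block_total - aligned           # deletion-consumed reference bases
  aligned_ov <- max(0L, ov - d_bases)
  c(transcript_cov = ov / exonic_len,
    read_aligned_frac = aligned_ov / r$read_length)
}

#' Is a read compatible with a transcript?
#'
#' A spliced read is compatible with transcript `t` when its (corrected)
#' junction chain is a contiguous sub-chain of `t`'s chain and its genomic
#' span lies within `t`'s span extended by `end_tol` on each side. A
#' single-exon read is compatible with any transcript whose exonic region
#' contains at least `min_read_aligned_frac` of the read's aligned bases.
#'
#' @param r a read: list with `blocks`, `read_length`, optionally
#'   `aligned_read_bases`.
#' @param t a transcript model.
#' @param cfg a [quant_config()].
#' @param end_tol span tolerance in bp (the discovery-stage end tolerance).
#' @return logical.
#' @export
compatible <- function(r, t, cfg = quant_config(), end_tol = 100L) {
  rj <- read_junctions(r$blocks)
  span <- c(min(r$blocks[, 1L]), max(r$blocks[, 2L]))
  if (nrow(rj) == 0L) {
    ov <- interval_overlap(r$blocks, t$exons)
    block_total <- sum(r$blocks[, 2L] - r$blocks[, 1L])
    aligned <- if (!is.null(r$aligned_read_bases)) r$aligned_read_bases else block_total
    aligned_ov <- max(0L, ov - (block_total - aligned))
    return(aligned > 0L && aligned_ov / aligned >= cfg$min_read_aligned_frac)
  }
  tj <- junction_chain(t$exons)
  if (nrow(tj) < nrow(rj)) return(FALSE)
  if (span[1L] < t$exons[1L, 1L] - end_tol) return(FALSE)
  if (span[2L] > t$exons[nrow(t$exons), 2L] + end_tol) return(FALSE)
  nr <- nrow(rj); nt <- nrow(tj)
  for (off in seq_len(nt - nr + 1L)) {
    if (all(tj[off:(off + nr - 1L), ] == rj)) return(TRUE)
  }
  FALSE
}

#' Assign one read to a catalog transcript
#'
#' Among compatible transcripts for which strictly more than
#' `min_read_aligned_frac` of the read aligns, the read goes to the one
#' with highest transcript coverage; ties are broken by fewer junctions,
#' then lexicographically smaller id. Returns `NA` when no transcript
#' qualifies.
#'
#' @param r a read (list with `blocks`, `read_length`, `chrom`, `strand`,
#'   optionally `aligned_read_bases`).
#' @param catalog a `nanoiso_catalog` or `nanoiso_annotation`.
#' @param cfg a [quant_config()].
#' @param end_tol span tolerance in bp.
#' @return transcript id, or `NA_character_` (unassigned).
#' @export
assign_read <- function(r, catalog, cfg = quant_config(), end_tol = 100L) {
  ann <- as_annotation(catalog)
  cand <- ann$transcripts[chrom == r$chrom & strand == r$strand]
  if (nrow(cand) == 0L) return(NA_character_)
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    t <- transcript_model(ann, cand$transcript_id[i])
    if (!compatible(r, t, cfg, end_tol)) next
    cs <- coverage_stats(r, t)
    if (!(cs[["read_aligned_frac"]] > cfg$min_read_aligned_frac)) next
    rec <- list(id = cand$transcript_id[i], cov = cs[["transcript_cov"]],
                njunc = cand$n_junc[i])
    if (is.null(best) ||
        rec$cov > best$cov ||
        (rec$cov == best$cov && rec$njunc < best$njunc) ||
        (rec$cov == best$cov && rec$njunc == best$njunc && rec$id < best$id)) {
      best <- rec
    }
  }
  if (is.null(best)) NA_character_ else best$id
}

# ---- bulk assignment -------------------------------------------------------

# Enumerate every contiguous sub-chain of every catalog transcript and index
# by (chrom, strand, sub-chain key) -> candidate transcript ids.
subchain_index <- function(ann) {
  tx <- ann$transcripts[n_junc > 0L]
  if (nrow(tx) == 0L) {
    return(data.table::data.table(chrom = character(0), strand = character(0),
                                  subchain = character(0), transcript_id = character(0),
                                  off = integer(0)))
  }
  rows <- vector("list", nrow(tx))
  jx <- ann$exons[, if (.N > 1L) .(donor_end = end[-.N], acceptor_start = start[-1L]),
                  by = .(transcript_id)]
  jsp <- split(jx, by = "transcript_id")
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    jm <- jsp[[tid]]
    parts <- paste0(jm$donor_end, "-", jm$acceptor_start)
    k <- length(parts)
    keys <- character(0); offs <- integer(0)
    for (len in seq_len(k)) {
      for (off in seq_len(k - len + 1L)) {
        keys <- c(keys, paste(parts[off:(off + len - 1L)], collapse = ";"))
        offs <- c(offs, off)
      }
    }
    rows[[i]] <- data.table::data.table(chrom = tx$chrom[i], strand = tx$strand[i],
                                        subchain = keys, transcript_id = tid, off = offs)
  }
  data.table::rbindlist(rows)
}

# Exonic cumulative-coverage evaluations for arbitrary coordinates against
# one transcript's exon matrix (vectorised).
cumcov_eval <- function(exons, x) cumcov_fun(exons)(x)

#' Assign all reads of one or more samples and build the count matrix
#'
#' The bulk path of [assign_read()]: read junction chains are snapped to the
#' catalog's splice sites (tolerance `junction_tol`), reads sharing a chain
#' are matched to candidate transcripts through a contiguous sub-chain
#' index, and exact exonic overlaps are computed per read. Assignment uses
#' argmax transcript coverage with strictly more than
#' `min_read_aligned_frac` of the read aligned, ties broken by fewer
#' junctions then smaller id.
#'
#' @param reads a `nanoiso_reads` container or a list of them (per sample).
#' @param catalog a `nanoiso_catalog` or `nanoiso_annotation`.
#' @param cfg a [quant_config()].
#' @param junction_tol bp tolerance for snapping read splice sites to
#'   catalog sites before exact matching.
#' @param end_tol bp span tolerance for compatibility.
#' @return a list with `assignments` (data.table: read_id, sample_id,
#'   transcript_id, transcript_cov, read_aligned_frac, full_length),
#'   `counts` (a `nanoiso_counts`), and funnel bookkeeping attributes.
#' @export
quantify <- function(reads, catalog, cfg = quant_config(),
                     junction_tol = 5L, end_tol = 100L) {
  reads <- combine_reads(reads)
  ann <- as_annotation(catalog)
  r <- data.table::copy(reads$reads)
  sample_ids <- unique(r$sample_id)
  if (nrow(r) == 0L) {
    counts <- count_matrix(data.table::data.table(read_id = character(0),
                                                  sample_id = character(0),
                                                  transcript_id = character(0)),
                           ann, sample_ids = sample_ids)
    return(list(assignments = data.table::data.table(), counts = counts))
  }

  jt <- reads_junction_table(reads)
  # snap read splice sites to catalog sites
  if (nrow(jt)) {
    jt <- merge(jt, r[, .(read_idx, chrom, strand)], by = "read_idx")
    for (k in unique(paste(jt$chrom, jt$strand))) {
      s <- ann$sites[[k]]
      if (is.null(s)) next
      sel <- paste(jt$chrom, jt$strand) == k
      jt$donor_end[sel] <- snap_to_sites(jt$donor_end[sel], s$donor, junction_tol)
      jt$acceptor_start[sel] <- snap_to_sites(jt$acceptor_start[sel], s$acceptor, junction_tol)
    }
    bad <- jt[, .(bad = any(donor_end >= acceptor_start)), by = read_idx]
    # a snap that inverts a junction is abandoned for that read
    if (any(bad$bad)) {
      revert <- bad$read_idx[bad$bad]
      orig <- reads_junction_table(reads)[read_idx %in% revert]
      jt[read_idx %in% revert, c("donor_end", "acceptor_start") :=
           orig[, .(donor_end, acceptor_start)]]
    }
    ck <- jt[order(read_idx, jidx),
             .(chain_key = paste(paste0(donor_end, "-", acceptor_start), collapse = ";"),
               n_junc = .N), by = read_idx]
    r <- merge(r, ck, by = "read_idx", all.x = TRUE)
  } else {
    r[, `:=`(chain_key = NA_character_, n_junc = NA_integer_)]
  }
  r[is.na(chain_key), `:=`(chain_key = "", n_junc = 0L)]

  idx <- subchain_index(ann)
  tx <- ann$transcripts
  exsp <- split(ann$exons[order(transcript_id, start)], by = "transcript_id")
  exmat <- lapply(exsp, function(d) cbind(d$start, d$end))

  blocks <- reads$blocks[order(read_idx, start)]
  res_list <- list()

  # ---- spliced reads, grouped by (chrom, strand, chain_key) ----
  spl <- r[n_junc > 0L]
  if (nrow(spl)) {
    chains <- unique(spl[, .(chrom, strand, chain_key, n_junc)])
    cand <- merge(chains, idx,
                  by.x = c("chrom", "strand", "chain_key"),
                  by.y = c("chrom", "strand", "subchain"))
    if (nrow(cand)) {
      cand <- merge(cand, tx[, .(transcript_id, t_start = start, t_end = end,
                                 exonic_len, t_njunc = n_junc)],
                    by = "transcript_id")
      spl_keyed <- merge(spl, cand, by = c("chrom", "strand", "chain_key"),
                         allow.cartesian = TRUE)
      # span compatibility
      spl_keyed <- spl_keyed[start >= t_start - end_tol & end <= t_end + end_tol]
      if (nrow(spl_keyed)) {
        # exact exonic overlap per (read, transcript) using the cumulative
        # coverage function of each candidate transcript over block edges
        pairs <- split(spl_keyed, by = "transcript_id")
        part <- vector("list", length(pairs))
        for (pi in seq_along(pairs)) {
          p <- pairs[[pi]]
          em <- exmat[[p$transcript_id[1L]]]
          C <- cumcov_fun(em)
          b <- blocks[read_idx %in% p$read_idx]
          ovb <- b[, .(ov = sum(C(end) - C(start))), by = read_idx]
          p <- merge(p, ovb, by = "read_idx")
          part[[pi]] <- p
        }
        allp <- data.table::rbindlist(part)
        bt <- blocks[read_idx %in% allp$read_idx,
                     .(btot = sum(end - start)), by = read_idx]
        allp <- merge(allp, bt, by = "read_idx")
        allp[, aligned_ov := pmax(0L, ov - (btot - aligned_bases))]
        allp[, `:=`(transcript_cov = ov / exonic_len,
                    read_aligned_frac = aligned_ov / read_length)]
        allp <- allp[read_aligned_frac > cfg$min_read_aligned_frac]
        if (nrow(allp)) {
          data.table::setorder(allp, read_idx, -transcript_cov, t_njunc, transcript_id)
          res_list[["spliced"]] <- allp[!duplicated(read_idx),
                                        .(read_idx, transcript_id,
                                          transcript_cov, read_aligned_frac)]
        }
      }
    }
  }

  # ---- single-exon reads ----
  mono <- r[n_junc == 0L]
  if (nrow(mono)) {
    part <- list()
    for (k in unique(paste(mono$chrom, mono$strand))) {
      mm <- mono[paste(chrom, strand) == k]
      tt <- tx[paste(chrom, strand) == k]
      if (nrow(tt) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(mm$start + 1L, mm$end),
        IRanges::IRanges(tt$start + 1L, tt$end))
      if (length(hits) == 0L) next
      h <- data.table::data.table(ri = S4Vectors::queryHits(hits),
                                  ti = S4Vectors::subjectHits(hits))
      h[, `:=`(read_idx = mm$read_idx[ri], transcript_id = tt$transcript_id[ti],
               exonic_len = tt$exonic_len[ti], t_njunc = tt$n_junc[ti])]
      h <- merge(h, mm[, .(read_idx, read_length, aligned_bases)], by = "read_idx")
      for (tid in unique(h$transcript_id)) {
        em <- exmat[[tid]]
        C <- cumcov_fun(em)
        sel <- h$transcript_id == tid
        b <- blocks[read_idx %in% h$read_idx[sel]]
        ovb <- b[, .(ov = sum(C(end) - C(start)), btot = sum(end - start)),
                 by = read_idx]
        hh <- merge(h[sel], ovb, by = "read_idx")
        part[[paste(k, tid)]] <- hh
      }
    }
    if (length(part)) {
      mp <- data.table::rbindlist(part)
      mp[, aligned_ov := pmax(0L, ov - (btot - aligned_bases))]
      mp[, `:=`(transcript_cov = ov / exonic_len,
                read_aligned_frac = aligned_ov / read_length)]
      # compatibility: transcript exons contain >= min frac of aligned bases
      mp <- mp[aligned_ov / aligned_bases >= cfg$min_read_aligned_frac]
      mp <- mp[read_aligned_frac > cfg$min_read_aligned_frac]
      if (nrow(mp)) {
        data.table::setorder(mp, read_idx, -transcript_cov, t_njunc, transcript_id)
        res_list[["mono"]] <- mp[!duplicated(read_idx),
                                 .(read_idx, transcript_id,
                                   transcript_cov, read_aligned_frac)]
      }
    }
  }

  res <- if (length(res_list)) data.table::rbindlist(res_list) else
    data.table::data.table(read_idx = integer(0), transcript_id = character(0),
                           transcript_cov = numeric(0), read_aligned_frac = numeric(0))
  asg <- merge(r[, .(read_idx, read_id, sample_id)], res, by = "read_idx",
               all.x = TRUE)
  asg[, full_length := !is.na(transcript_id) & transcript_cov >= cfg$full_length_cov]
  counts <- count_matrix(asg, ann, sample_ids = sample_ids)
  out <- list(assignments = asg[, .(read_id, sample_id, transcript_id,
                                    transcript_cov, read_aligned_frac, full_length)],
              counts = counts)
  attr(out, "n_primary") <- nrow(r)
  attr(out, "n_assigned") <- sum(!is.na(asg$transcript_id))
  out
}

#' Build a transcript-by-sample count matrix from read assignments
#'
#' Per sample, assigned reads are tallied per transcript and the remainder
#' recorded as unassigned, so `colSums(counts) + unassigned` equals the
#' number of primary reads (conservation). Gene counts are obtained by
#' summing counts across all transcripts of a gene.
#'
#' @param assignments data.frame with `read_id`, `sample_id`,
#'   `transcript_id` (`NA` = unassigned).
#' @param catalog catalog/annotation supplying transcript order and the
#'   transcript-to-gene map.
#' @param sample_ids column order; defaults to order of appearance.
#' @return a `nanoiso_counts` object: list with integer matrix `counts`
#'   (transcripts x samples), named vector `gene_map`, and `unassigned`
#'   per-sample counts.
#' @export
count_matrix <- function(assignments, catalog, sample_ids = NULL) {
  ann <- as_annotation(catalog)
  a <- data.table::as.data.table(assignments)
  if (is.null(sample_ids)) sample_ids <- unique(a$sample_id)
  tids <- ann$transcripts$transcript_id
  m <- matrix(0L, nrow = length(tids), ncol = length(sample_ids),
              dimnames = list(tids, sample_ids))
  if (nrow(a)) {
    tab <- a[!is.na(transcript_id), .N, by = .(transcript_id, sample_id)]
    if (nrow(tab)) {
      m[cbind(match(tab$transcript_id, tids), match(tab$sample_id, sample_ids))] <- tab$N
    }
  }
  unass <- stats::setNames(integer(length(sample_ids)), sample_ids)
  if (nrow(a)) {
    u <- a[is.na(transcript_id), .N, by = sample_id]
    unass[u$sample_id] <- u$N
  }
  gene_map <- stats::setNames(ann$transcripts$gene_id, tids)
  structure(list(counts = m, gene_map = gene_map, unassigned = unass),
            class = "nanoiso_counts")
}

#' @export
print.nanoiso_counts <- function(x, ...) {
  cat("nanoiso counts:", nrow(x$counts), "transcripts x", ncol(x$counts),
      "samples;", sum(x$unassigned), "unassigned reads\n")
  invisible(x)
}

#' Full-length read fraction
#'
#' A read is full-length when it covers at least `full_length_cov`
#' (default 0.95, inclusive) of its assigned transcript's exonic bases.
#' The fraction is computed over assigned reads.
#'
#' @param assignments the `assignments` table from [quantify()].
#' @param cfg a [quant_config()].
#' @return list with `fraction`, and `flags` (per assigned read).
#' @export
full_length_fraction <- function(assignments, cfg = quant_config()) {
  a <- data.table::as.data.table(assignments)
  a <- a[!is.na(transcript_id)]
  flags <- a$transcript_cov >= cfg$full_length_cov
  list(fraction = if (nrow(a)) mean(flags) else NA_real_,
       flags = data.table::data.table(read_id = a$read_id,
                                      sample_id = a$sample_id,
                                      transcript_id = a$transcript_id,
                                      full_length = flags))
}

#' log2 counts-per-million
#'
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)` with library sizes
#' taken as column sums.
#'
#' @param m a `nanoiso_counts` or a numeric matrix.
#' @param prior pseudo-count (default 0.5).
#' @return numeric matrix of log2-CPM values.
#' @export
log_cpm <- function(m, prior = 0.5) {
  counts <- if (inherits(m, "nanoiso_counts")) m$counts else as.matrix(m)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size in column(s): ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  log2(sweep(sweep(counts + prior, 2, lib + 2 * prior, "/"), 2, 1e6, "*"))
}
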