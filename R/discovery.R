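#' Discovery configuration
#'
#' Tolerances of the isoform discovery stage. Junction correction and
#' merging use a strict `< junction_tol` (default 5 bp) per splice site;
#' transcript start/end comparisons use a strict `< end_tol` (default
#' 100 bp); isoforms need `min_support` (default 10) supporting reads to be
#' retained. `junction_tol` can be tightened (e.g. to 1 bp) for platforms
#' with lower error rates.
#'
#' @param junction_tol bp; splice sites closer than this to an annotated
#'   site of the same kind are snapped to it (strict `<`).
#' @param end_tol bp; transcript start/end tolerance for merging and for
#'   matching a discovered chain to a reference transcript (strict `<`).
#' @param min_support minimum number of supporting reads for a
#'   high-confidence isoform.
#' @param single_exon_cluster_gap bp; single-exon reads whose intervals come
#'   within this gap are clustered together. Defaults to `end_tol`.
#' @param trunc_collapse `"either"` collapses any one-sided truncated
#'   sub-chain; `"3prime"` collapses only chains missing their 3' region.
#' @return a `discovery_config` list.
#' @export
discovery_config <- function(junction_tol = 5L, end_tol = 100L,
                             min_support = 10L,
                             single_exon_cluster_gap = end_tol,
                             trunc_collapse = c("either", "3prime")) {
  trunc_collapse <- match.arg(trunc_collapse)
  stopifnot(junction_tol >= 0, end_tol >= 0, min_support >= 0,
            single_exon_cluster_gap >= 0)
  structure(list(junction_tol = as.integer(junction_tol),
                 end_tol = as.integer(end_tol),
                 min_support = as.integer(min_support),
                 single_exon_cluster_gap = as.integer(single_exon_cluster_gap),
                 trunc_collapse = trunc_collapse),
            class = "discovery_config")
}

# Merge several nanoiso_reads containers into one, re-indexing read_idx.
combine_reads <- function(x) {
  if (inherits(x, "nanoiso_reads")) return(x)
  stopifnot(is.list(x), length(x) >= 1L)
  offset <- 0L
  reads_list <- list(); blocks_list <- list()
  dropped <- c(unmapped = 0L, secondary = 0L, supplementary = 0L)
  n_input <- 0L
  for (r in x) {
    stopifnot(inherits(r, "nanoiso_reads"))
    rr <- data.table::copy(r$reads); bb <- data.table::copy(r$blocks)
    rr[, read_idx := read_idx + offset]
    bb[, read_idx := read_idx + offset]
    offset <- offset + max(0L, if (nrow(rr)) max(r$reads$read_idx) else 0L)
    reads_list[[length(reads_list) + 1L]] <- rr
    blocks_list[[length(blocks_list) + 1L]] <- bb
    d <- attr(r, "dropped"); if (!is.null(d)) dropped <- dropped + d
    ni <- attr(r, "n_input"); if (!is.null(ni)) n_input <- n_input + ni
  }
  out <- list(reads = data.table::rbindlist(reads_list),
              blocks = data.table::rbindlist(blocks_list))
  attr(out, "dropped") <- dropped
  attr(out, "n_input") <- n_input
  class(out) <- "nanoiso_reads"
  out
}

#' Group reads by splice-junction chain
#'
#' Spliced reads are keyed by their exact junction chain (per chromosome and
#' strand); reads whose chains differ only within tolerance are reconciled
#' later by [correct_sites()] and [merge_similar_groups()], which keeps the
#' grouping deterministic and independent of input order. Single-exon reads
#' are clustered by interval overlap, allowing a gap of up to
#' `single_exon_cluster_gap` between a read and the cluster span.
#'
#' @param reads a `nanoiso_reads` container (or list of them, pooled).
#' @param cfg a [discovery_config()].
#' @return a `nanoiso_groups` object with data.tables `groups` (group_id,
#'   chrom, strand, chain_key, n_junc, support), `junctions` and `members`.
#' @export
group_reads <- function(reads, cfg = discovery_config()) {
  reads <- combine_reads(reads)
  r <- reads$reads
  jt <- reads_junction_table(reads)
  ck <- if (nrow(jt)) {
    jt[, .(chain_key = paste(paste0(donor_end, "-", acceptor_start), collapse = ";"),
           n_junc = .N), by = read_idx]
  } else data.table::data.table(read_idx = integer(0), chain_key = character(0),
                                n_junc = integer(0))
  r <- merge(r, ck, by = "read_idx", all.x = TRUE)
  r[is.na(chain_key), `:=`(chain_key = "", n_junc = 0L)]

  spliced <- r[n_junc > 0L]
  mono <- r[n_junc == 0L]

  members_list <- list()
  group_meta <- list()
  gid <- 0L

  if (nrow(spliced)) {
    data.table::setorder(spliced, chrom, strand, chain_key, read_idx)
    spliced[, group_id := .GRP, by = .(chrom, strand, chain_key)]
    spliced[, group_id := group_id + gid]
    gid <- gid + max(spliced$group_id) - gid
    members_list[["spliced"]] <- spliced[, .(group_id, read_idx, read_id,
                                             sample_id, start, end)]
    group_meta[["spliced"]] <- unique(spliced[, .(group_id, chrom, strand,
                                                  chain_key, n_junc)])
  }
  if (nrow(mono)) {
    data.table::setorder(mono, chrom, strand, start, end, read_idx)
    gap <- cfg$single_exon_cluster_gap
    mono[, cluster := {
      if (.N == 1L) 1L else {
        prevmax <- cummax(end)[-.N]   # running max end over earlier reads
        cumsum(c(TRUE, start[-1L] > prevmax + gap))
      }
    }, by = .(chrom, strand)]
    mono[, group_id := .GRP + gid, by = .(chrom, strand, cluster)]
    gid <- gid + length(unique(mono$group_id))
    members_list[["mono"]] <- mono[, .(group_id, read_idx, read_id,
                                       sample_id, start, end)]
    group_meta[["mono"]] <- unique(mono[, .(group_id, chrom, strand,
                                            chain_key = "", n_junc = 0L)])
  }

  members <- data.table::rbindlist(members_list)
  groups <- data.table::rbindlist(group_meta)
  if (nrow(groups) == 0L) return(empty_groups())
  sup <- members[, .(support = .N), by = group_id]
  groups <- merge(groups, sup, by = "group_id")

  junctions <- if (nrow(spliced)) {
    key1 <- spliced[!duplicated(group_id), .(group_id, read_idx)]
    j <- merge(key1, jt, by = "read_idx")[, .(group_id, jidx, donor_end, acceptor_start)]
    data.table::setorder(j, group_id, jidx)
    j
  } else {
    data.table::data.table(group_id = integer(0), jidx = integer(0),
                           donor_end = integer(0), acceptor_start = integer(0))
  }
  new_groups(groups, junctions, members)
}

new_groups <- function(groups, junctions, members) {
  data.table::setorder(groups, group_id)
  out <- list(groups = groups, junctions = junctions, members = members)
  class(out) <- "nanoiso_groups"
  out
}

empty_groups <- function() {
  new_groups(
    data.table::data.table(group_id = integer(0), chrom = character(0),
                           strand = character(0), chain_key = character(0),
                           n_junc = integer(0), support = integer(0)),
    data.table::data.table(group_id = integer(0), jidx = integer(0),
                           donor_end = integer(0), acceptor_start = integer(0)),
    data.table::data.table(group_id = integer(0), read_idx = integer(0),
                           read_id = character(0), sample_id = character(0),
                           start = integer(0), end = integer(0)))
}

#' @export
print.nanoiso_groups <- function(x, ...) {
  cat("nanoiso groups:", nrow(x$groups), "groups,",
      nrow(x$members), "reads\n")
  invisible(x)
}

#' Correct splice sites against the reference annotation
#'
#' Each donor and acceptor coordinate is snapped independently to the
#' nearest annotated site of the same kind on the same (chromosome, strand)
#' when the distance is strictly below `junction_tol`; ties go to the
#' smaller coordinate, and already-annotated sites are left untouched
#' (idempotence). If a correction would invert a junction
#' (donor >= acceptor) the whole group is left uncorrected and a warning is
#' raised.
#'
#' @param group a `nanoiso_groups` object (all groups are corrected).
#' @param ann reference `nanoiso_annotation`.
#' @param cfg a [discovery_config()].
#' @return the corrected `nanoiso_groups`.
#' @export
correct_sites <- function(group, ann, cfg = discovery_config()) {
  x <- group
  j <- data.table::copy(x$junctions)
  if (nrow(j) == 0L) return(x)
  gmeta <- x$groups[, .(group_id, chrom, strand)]
  j <- merge(j, gmeta, by = "group_id")
  j[, `:=`(new_donor = donor_end, new_acceptor = acceptor_start)]
  for (k in unique(paste(j$chrom, j$strand))) {
    s <- ann$sites[[k]]
    if (is.null(s)) next
    sel <- paste(j$chrom, j$strand) == k
    j$new_donor[sel] <- snap_to_sites(j$donor_end[sel], s$donor, cfg$junction_tol)
    j$new_acceptor[sel] <- snap_to_sites(j$acceptor_start[sel], s$acceptor, cfg$junction_tol)
  }
  bad <- j[, .(bad = any(new_donor >= new_acceptor)), by = group_id]
  bad_ids <- bad$group_id[bad$bad]
  if (length(bad_ids)) {
    warning(length(bad_ids), " group(s) left uncorrected: snapping would invert a junction")
    j[group_id %in% bad_ids, `:=`(new_donor = donor_end, new_acceptor = acceptor_start)]
  }
  jn <- j[, .(group_id, jidx, donor_end = new_donor, acceptor_start = new_acceptor)]
  data.table::setorder(jn, group_id, jidx)
  ck <- jn[, .(chain_key = paste(paste0(donor_end, "-", acceptor_start), collapse = ";")),
           by = group_id]
  groups <- data.table::copy(x$groups)
  groups[ck, chain_key := i.chain_key, on = "group_id"]
  new_groups(groups, jn, x$members)
}

# junction coordinate matrices per group id, as a named list
group_chain_matrices <- function(junctions, ids) {
  sp <- split(junctions[junctions$group_id %in% ids],
              by = "group_id", keep.by = TRUE)
  out <- lapply(sp, function(d) {
    d <- d[order(jidx)]
    cbind(donor_end = d$donor_end, acceptor_start = d$acceptor_start)
  })
  names(out) <- vapply(sp, function(d) as.character(d$group_id[1L]), "")
  out
}

#' Merge groups with similar junction chains and transcript ends
#'
#' Groups are first coalesced when their corrected chains are identical.
#' Remaining groups are processed in descending support order (ties broken
#' lexicographically on the chain key); a group is absorbed into an
#' earlier-kept group when the chains have equal length, every paired
#' junction differs by strictly less than `junction_tol` at both the donor
#' and acceptor, and the median read start and end each differ by strictly
#' less than `end_tol`. Absorbed reads are pooled; the kept (larger) group's
#' chain is retained. Chains of different lengths are never merged.
#'
#' @param groups a corrected `nanoiso_groups`.
#' @param cfg a [discovery_config()].
#' @return the merged `nanoiso_groups`.
#' @export
merge_similar_groups <- function(groups, cfg = discovery_config()) {
  x <- groups
  if (nrow(x$groups) == 0L) return(x)
  # step 1: identical corrected chains (and single-exon clusters sharing a
  # key are left to the pairwise pass below, their chain_key is "")
  g <- data.table::copy(x$groups)
  g[, newid := group_id]
  spl <- g[n_junc > 0L]
  if (nrow(spl)) {
    spl[, keep := min(group_id), by = .(chrom, strand, chain_key)]
    g[spl, newid := i.keep, on = "group_id"]
  }
  x <- remap_groups(x, stats::setNames(g$newid, g$group_id))

  # step 2: pairwise merge of near-identical chains within each
  # (chrom, strand, chain length) class
  g <- x$groups
  members <- x$members
  mstats <- members[, .(med_start = as.numeric(stats::median(start)),
                        med_end = as.numeric(stats::median(end))), by = group_id]
  g <- merge(g, mstats, by = "group_id")
  mapping <- stats::setNames(g$group_id, as.character(g$group_id))
  cls <- split(g, by = c("chrom", "strand", "n_junc"))
  member_env <- split(members[, .(group_id, start, end)], by = "group_id")
  for (cl in cls) {
    if (nrow(cl) <= 1L) next
    data.table::setorder(cl, -support, chain_key, group_id)
    nj <- cl$n_junc[1L]
    mats <- if (nj > 0L) group_chain_matrices(x$junctions, cl$group_id) else NULL
    kept <- integer(0)
    kstart <- list(); kend <- list()
    for (i in seq_len(nrow(cl))) {
      gi <- cl$group_id[i]
      mem <- member_env[[as.character(gi)]]
      absorbed <- FALSE
      for (h in kept) {
        if (nj > 0L) {
          a <- mats[[as.character(gi)]]; b <- mats[[as.character(h)]]
          if (max(abs(a[, 1L] - b[, 1L])) >= cfg$junction_tol) next
          if (max(abs(a[, 2L] - b[, 2L])) >= cfg$junction_tol) next
        }
        if (abs(stats::median(mem$start) - stats::median(kstart[[as.character(h)]])) >= cfg$end_tol) next
        if (abs(stats::median(mem$end) - stats::median(kend[[as.character(h)]])) >= cfg$end_tol) next
        mapping[as.character(gi)] <- h
        kstart[[as.character(h)]] <- c(kstart[[as.character(h)]], mem$start)
        kend[[as.character(h)]] <- c(kend[[as.character(h)]], mem$end)
        absorbed <- TRUE
        break
      }
      if (!absorbed) {
        kept <- c(kept, gi)
        kstart[[as.character(gi)]] <- mem$start
        kend[[as.character(gi)]] <- mem$end
      }
    }
  }
  remap_groups(x, mapping)
}

# Apply a group_id -> surviving group_id mapping: pools members/support and
# keeps the surviving group's chain.
remap_groups <- function(x, mapping) {
  key <- as.character(x$groups$group_id)
  tgt <- mapping[key]
  tgt[is.na(tgt)] <- x$groups$group_id[is.na(tgt)]
  # resolve chains (a -> b, b -> c)
  repeat {
    nxt <- mapping[as.character(tgt)]
    nxt[is.na(nxt)] <- tgt[is.na(nxt)]
    if (all(nxt == tgt)) break
    tgt <- nxt
  }
  map_dt <- data.table::data.table(group_id = x$groups$group_id, target = unname(tgt))
  members <- merge(x$members, map_dt, by = "group_id")
  members[, group_id := target][, target := NULL]
  keep <- map_dt$group_id == map_dt$target
  groups <- x$groups[keep]
  junctions <- x$junctions[group_id %in% groups$group_id]
  sup <- members[, .(support = .N), by = group_id]
  groups <- merge(groups[, -"support"], sup, by = "group_id")
  new_groups(groups, junctions, members)
}

#' Collapse likely-truncated isoform groups into their full-length forms
#'
#' A group A is collapsed into a group B when A's chain is a contiguous
#' sub-chain of B's chain anchored at one end (all missing junctions on a
#' single side), and the shared end of A lies strictly within `end_tol` of
#' the corresponding end of B (median over member reads). With
#' `trunc_collapse = "3prime"` only chains missing their 3' region (the
#' truncation the library-prep artefact produces on the annotated strand)
#' are collapsed; the default `"either"` accepts a missing region on either
#' side, since cDNA truncation is typically 5'-biased but not exclusively.
#' Collapsing proceeds from the shortest chain upward; a group matching
#' several full-length candidates goes to the one with highest support.
#' Absorbed reads are pooled transitively.
#'
#' @param groups a corrected/merged `nanoiso_groups`.
#' @param cfg a [discovery_config()].
#' @return the collapsed `nanoiso_groups`.
#' @export
collapse_truncations <- function(groups, cfg = discovery_config()) {
  x <- groups
  g <- x$groups[n_junc > 0L]
  if (nrow(g) <= 1L) return(x)
  mstats <- x$members[group_id %in% g$group_id,
                      .(med_start = as.numeric(stats::median(start)),
                        med_end = as.numeric(stats::median(end))), by = group_id]
  g <- merge(g, mstats, by = "group_id")
  mapping <- stats::setNames(g$group_id, as.character(g$group_id))
  cls <- split(g, by = c("chrom", "strand"))
  for (cl in cls) {
    if (nrow(cl) <= 1L) next
    mats <- group_chain_matrices(x$junctions, cl$group_id)
    data.table::setorder(cl, n_junc, -support, chain_key, group_id)
    for (i in seq_len(nrow(cl))) {
      a_id <- cl$group_id[i]
      a <- mats[[as.character(a_id)]]
      na <- nrow(a)
      cand <- cl[cl$n_junc > na]
      if (nrow(cand) == 0L) next
      best <- NULL
      for (j in seq_len(nrow(cand))) {
        b_id <- cand$group_id[j]
        b <- mats[[as.character(b_id)]]
        nb <- nrow(b)
        hits <- which(b[, 1L] == a[1L, 1L] & b[, 2L] == a[1L, 2L])
        for (off in hits) {
          if (off + na - 1L > nb) next
          sl <- b[off:(off + na - 1L), , drop = FALSE]
          if (!all(sl == a)) next
          miss_left <- off - 1L
          miss_right <- nb - (off + na - 1L)
          one_sided <- xor(miss_left > 0L, miss_right > 0L)
          if (!one_sided) next
          if (cfg$trunc_collapse == "3prime") {
            # missing region must be on the 3' side of the (stranded) form
            miss_3p <- if (cl$strand[1L] == "+") miss_right > 0L else miss_left > 0L
            if (!miss_3p) next
          }
          if (miss_right == 0L) {       # A is a suffix: anchored at right end
            ok <- abs(cl$med_end[i] - cand$med_end[j]) < cfg$end_tol
          } else {                      # A is a prefix: anchored at left end
            ok <- abs(cl$med_start[i] - cand$med_start[j]) < cfg$end_tol
          }
          if (!ok) next
          if (is.null(best) || cand$support[j] > best$support ||
              (cand$support[j] == best$support && b_id < best$id)) {
            best <- list(id = b_id, support = cand$support[j])
          }
        }
      }
      if (!is.null(best)) mapping[as.character(a_id)] <- best$id
    }
  }
  remap_groups(x, mapping)
}

#' Finalise the isoform catalog
#'
#' Groups with fewer than `min_support` reads are dropped (their reads stay
#' accounted for in the read-funnel bookkeeping). A surviving group whose
#' chain equals a reference transcript's chain and whose representative
#' start/end are each strictly within `end_tol` of the reference's is
#' emitted as that reference transcript; any other group becomes a novel
#' transcript whose exons are induced by the chain plus the representative
#' start/end. The representative start (end) is the mode of member read
#' starts (ends), ties resolved to the outermost coordinate.
#'
#' Novel isoforms are named `<gene_id>_<start+1>_<end>_<k>` (1-based
#' inclusive coordinates, `k` a per-gene counter); the host gene is the
#' same-strand annotated gene with maximal exonic overlap, and orphans get
#' `novelgene_<chrom>_<n>` gene ids.
#'
#' @param groups processed `nanoiso_groups`.
#' @param ann reference `nanoiso_annotation`.
#' @param cfg a [discovery_config()].
#' @return a `nanoiso_catalog`: data.tables `transcripts` (with `support`
#'   and `source`), `exons`, and `read_assignment` (read_id, sample_id,
#'   transcript_id; `NA` for reads of dropped groups).
#' @export
finalize_catalog <- function(groups, ann, cfg = discovery_config()) {
  x <- groups
  if (nrow(x$groups) == 0L) {
    ea <- empty_annotation()
    tx0 <- data.table::copy(ea$transcripts)[, support := integer(0)]
    return(new_catalog(tx0, ea$exons,
                       data.table::data.table(read_id = character(0),
                                              sample_id = character(0),
                                              transcript_id = character(0)),
                       n_reads = 0L))
  }
  reps <- x$members[, .(rep_start = coord_mode(start, "min"),
                        rep_end = coord_mode(end, "max")), by = group_id]
  g <- merge(x$groups, reps, by = "group_id")
  n_reads_total <- nrow(x$members)
  kept <- g[support >= cfg$min_support]
  dropped <- g[support < cfg$min_support]

  ref <- ann$transcripts
  tx_rows <- list(); ex_rows <- list()
  assign_map <- data.table::data.table(group_id = kept$group_id,
                                       transcript_id = NA_character_)
  novel <- list()
  for (i in seq_len(nrow(kept))) {
    gi <- kept[i]
    cand <- ref[chrom == gi$chrom & strand == gi$strand & chain_key == gi$chain_key]
    if (nrow(cand)) {
      cand <- cand[abs(start - gi$rep_start) < cfg$end_tol &
                   abs(end - gi$rep_end) < cfg$end_tol]
    }
    if (nrow(cand)) {
      cand[, dist := abs(start - gi$rep_start) + abs(end - gi$rep_end)]
      data.table::setorder(cand, dist, transcript_id)
      tid <- cand$transcript_id[1L]
      tx_rows[[length(tx_rows) + 1L]] <- data.table::data.table(
        group_id = gi$group_id, transcript_id = tid, gene_id = cand$gene_id[1L],
        source = "reference", support = gi$support)
      assign_map$transcript_id[assign_map$group_id == gi$group_id] <- tid
    } else {
      novel[[length(novel) + 1L]] <- gi
    }
  }

  if (length(novel)) {
    nov <- data.table::rbindlist(novel)
    data.table::setorder(nov, chrom, rep_start, rep_end, group_id)
    orphan_counter <- new.env(parent = emptyenv())
    gene_counter <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(nov))) {
      gi <- nov[i]
      chain <- if (gi$n_junc > 0L) {
        jm <- x$junctions[group_id == gi$group_id][order(jidx)]
        cbind(jm$donor_end, jm$acceptor_start)
      } else matrix(integer(0), ncol = 2L)
      s0 <- gi$rep_start; e0 <- gi$rep_end
      if (nrow(chain)) {
        if (s0 >= chain[1L, 1L]) s0 <- chain[1L, 1L] - 1L
        if (e0 <= chain[nrow(chain), 2L]) e0 <- chain[nrow(chain), 2L] + 1L
        exs <- cbind(c(s0, chain[, 2L]), c(chain[, 1L], e0))
      } else {
        exs <- cbind(s0, e0)
      }
      host <- host_gene(ann, gi$chrom, gi$strand, exs)
      if (is.na(host)) {
        key <- gi$chrom
        n <- (if (is.null(orphan_counter[[key]])) 0L else orphan_counter[[key]]) + 1L
        orphan_counter[[key]] <- n
        host <- sprintf("novelgene_%s_%d", gi$chrom, n)
      }
      k <- (if (is.null(gene_counter[[host]])) 0L else gene_counter[[host]]) + 1L
      gene_counter[[host]] <- k
      tid <- sprintf("%s_%d_%d_%d", host, s0 + 1L, e0, k)
      tx_rows[[length(tx_rows) + 1L]] <- data.table::data.table(
        group_id = gi$group_id, transcript_id = tid, gene_id = host,
        source = "novel", support = gi$support)
      ex_rows[[length(ex_rows) + 1L]] <- data.table::data.table(
        transcript_id = tid, gene_id = host, chrom = gi$chrom,
        strand = gi$strand, start = as.integer(exs[, 1L]),
        end = as.integer(exs[, 2L]))
      assign_map$transcript_id[assign_map$group_id == gi$group_id] <- tid
    }
  }

  txmap <- if (length(tx_rows)) data.table::rbindlist(tx_rows) else
    data.table::data.table(group_id = integer(0), transcript_id = character(0),
                           gene_id = character(0), source = character(0),
                           support = integer(0))

  # exon tables: reference-matched isoforms reuse the reference exons
  ref_ids <- txmap[source == "reference", unique(transcript_id)]
  ex_ref <- ann$exons[transcript_id %in% ref_ids]
  exons <- data.table::rbindlist(c(list(ex_ref), ex_rows), use.names = TRUE)

  # several groups may resolve to the same reference transcript: pool support
  tx <- txmap[, .(support = sum(support), source = source[1L],
                  gene_id = gene_id[1L]), by = transcript_id]

  asg <- merge(x$members[, .(group_id, read_id, sample_id)],
               txmap[, .(group_id, transcript_id)], by = "group_id", all.x = TRUE)
  assignment <- asg[, .(read_id, sample_id, transcript_id)]

  ann_out <- build_annotation(exons, source = stats::setNames(tx$source, tx$transcript_id))
  txt <- merge(ann_out$transcripts, tx[, .(transcript_id, support)],
               by = "transcript_id")
  data.table::setorder(txt, chrom, start, transcript_id)
  cat_out <- new_catalog(txt, ann_out$exons, assignment, n_reads = n_reads_total)
  attr(cat_out, "dropped_groups") <- nrow(dropped)
  attr(cat_out, "dropped_reads") <- sum(dropped$support)
  cat_out
}

new_catalog <- function(transcripts, exons, read_assignment, n_reads = NA_integer_) {
  out <- list(transcripts = transcripts, exons = exons,
              read_assignment = read_assignment)
  attr(out, "n_reads") <- n_reads
  class(out) <- "nanoiso_catalog"
  out
}

#' @export
print.nanoiso_catalog <- function(x, ...) {
  n_nov <- sum(x$transcripts$source == "novel")
  cat("nanoiso catalog:", nrow(x$transcripts), "isoforms (",
      n_nov, "novel ),", sum(x$transcripts$support), "supporting reads\n")
  invisible(x)
}

# same-strand annotated gene with maximal exonic overlap, or NA
host_gene <- function(ann, chrom, strand, exons) {
  ex <- ann$exons[ann$exons$chrom == chrom & ann$exons$strand == strand]
  if (nrow(ex) == 0L) return(NA_character_)
  ex <- ex[ex$end > min(exons[, 1L]) & ex$start < max(exons[, 2L])]
  if (nrow(ex) == 0L) return(NA_character_)
  ov <- ex[, .(overlap_bases = {
    gex <- reduce_intervals(cbind(start, end))
    interval_overlap(exons, gex)
  }), by = gene_id]
  ov <- ov[overlap_bases > 0L]
  if (nrow(ov) == 0L) return(NA_character_)
  data.table::setorder(ov, -overlap_bases, gene_id)
  ov$gene_id[1L]
}

# union of possibly overlapping intervals -> disjoint sorted matrix
reduce_intervals <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1L]), , drop = FALSE]
  starts <- m[1L, 1L]; ends <- m[1L, 2L]
  for (i in 2L:nrow(m)) {
    if (m[i, 1L] <= ends[length(ends)]) {
      ends[length(ends)] <- max(ends[length(ends)], m[i, 2L])
    } else {
      starts <- c(starts, m[i, 1L]); ends <- c(ends, m[i, 2L])
    }
  }
  cbind(starts, ends)
}

#' Run the full isoform discovery pipeline
#'
#' Orchestrates group -> correct -> merge -> collapse -> finalize, per
#' (chromosome, strand). Deterministic for fixed inputs and configuration;
#' permuting the input read order leaves the catalog unchanged.
#'
#' @param x SAM/BAM path(s), a `nanoiso_reads` container, or a list of
#'   containers (one per sample).
#' @param ann reference `nanoiso_annotation`.
#' @param cfg a [discovery_config()].
#' @param sample_ids sample labels used when `x` is a vector of file paths.
#' @return a `nanoiso_catalog`.
#' @export
discover <- function(x, ann, cfg = discovery_config(), sample_ids = NULL) {
  if (is.character(x)) {
    if (is.null(sample_ids)) {
      sample_ids <- sub("\\.(bam|sam)$", "", basename(x), ignore.case = TRUE)
    }
    x <- Map(load_alignments, x, sample_ids)
  }
  reads <- combine_reads(x)
  g <- group_reads(reads, cfg)
  g <- correct_sites(g, ann, cfg)
  g <- merge_similar_groups(g, cfg)
  g <- collapse_truncations(g, cfg)
  out <- finalize_catalog(g, ann, cfg)
  attr(out, "n_input") <- attr(reads, "n_input")
  attr(out, "n_primary") <- nrow(reads$reads)
  out
}
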