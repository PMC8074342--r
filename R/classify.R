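#' Structural classification of one isoform against the reference
#'
#' SQANTI-style categories, decided in a fixed order that guarantees
#' mutual exclusivity:
#'
#' 1. **FSM** (full splice match): the junction chain equals a reference
#'    transcript's chain. FSM is junction-defined and therefore invariant
#'    to start/end positions.
#' 2. **ISM** (incomplete splice match): the chain is a contiguous,
#'    non-empty proper sub-chain of a reference transcript's chain.
#' 3. **NIC** (novel in catalog): exonic overlap with exactly one annotated
#'    same-strand gene and every junction is annotated or formed from an
#'    annotated donor plus an annotated acceptor.
#' 4. **NNC** (novel not in catalog): one same-strand gene but at least one
#'    unannotated donor or acceptor.
#' 5. **antisense**: overlaps annotated gene(s) on the opposite strand only.
#' 6. **fusion**: exonic overlap with two or more same-strand genes.
#' 7. **genic**: overlaps a gene body without exonic overlap.
#' 8. **intergenic**: no gene overlap at all.
#'
#' Single-exon isoforms have no junctions; they are classified `genic` when
#' they overlap a same-strand gene's exonic region, otherwise by rules
#' 5/7/8 (mono-exon subcategories are collapsed).
#'
#' For FSM/ISM the matched reference is the transcript sharing the most
#' junctions; ties go to the lexicographically smaller id.
#'
#' @param t a transcript model ([transcript_model()]).
#' @param ann reference `nanoiso_annotation`.
#' @return list with `isoform_id`, `category`, `matched_reference_id`
#'   (`NA` unless FSM/ISM).
#' @export
classify_isoform <- function(t, ann) {
  chain <- junction_chain(t$exons)
  key <- chain_key_str(chain[, 1L], chain[, 2L])
  res <- function(cat, ref = NA_character_) {
    list(isoform_id = t$transcript_id, category = cat, matched_reference_id = ref)
  }
  same <- ann$transcripts[chrom == t$chrom & strand == t$strand]

  if (nrow(chain) > 0L) {
    # 1. FSM
    fsm <- same[chain_key == key & n_junc == nrow(chain)]
    if (nrow(fsm)) {
      data.table::setorder(fsm, transcript_id)
      return(res("FSM", fsm$transcript_id[1L]))
    }
    # 2. ISM: contiguous non-empty proper sub-chain
    padded <- paste0(";", key, ";")
    cands <- same[n_junc > nrow(chain)]
    if (nrow(cands)) {
      hit <- cands[grepl(padded, paste0(";", cands$chain_key, ";"), fixed = TRUE)]
      if (nrow(hit)) {
        data.table::setorder(hit, transcript_id)
        return(res("ISM", hit$transcript_id[1L]))
      }
    }
  }

  sg <- overlapping_genes(ann, t, same_strand = TRUE, exonic = TRUE)
  og <- overlapping_genes(ann, t, same_strand = FALSE, exonic = FALSE)

  if (nrow(chain) > 0L) {
    if (length(sg) == 1L) {
      s <- ann_sites(ann, t$chrom, t$strand)
      ok <- all(chain[, 1L] %in% s$donor) && all(chain[, 2L] %in% s$acceptor)
      return(res(if (ok) "NIC" else "NNC"))
    }
    if (length(sg) >= 2L) return(res("fusion"))
  } else if (length(sg) >= 1L) {
    return(res("genic"))
  }

  # no same-strand exonic overlap from here on
  anti <- overlapping_genes_strand(ann, t, flip = TRUE)
  body_same <- overlapping_genes_strand(ann, t, flip = FALSE)
  if (length(anti) && !length(body_same)) return(res("antisense"))
  if (length(body_same) || length(anti)) return(res("genic"))
  res("intergenic")
}

# genes on t's chromosome whose exons (exonic=TRUE) overlap t's exons;
# same_strand selects the strand relative to t.
overlapping_genes <- function(ann, t, same_strand = TRUE, exonic = TRUE) {
  str <- if (same_strand) t$strand else setdiff(c("+", "-"), t$strand)
  ex <- ann$exons[chrom == t$chrom & strand %in% str]
  if (nrow(ex) == 0L) return(character(0))
  span <- c(min(t$exons[, 1L]), max(t$exons[, 2L]))
  ex <- ex[end > span[1L] & start < span[2L]]
  if (nrow(ex) == 0L) return(character(0))
  hits <- ex[, .(ov = interval_overlap(t$exons, reduce_intervals(cbind(start, end)))),
             by = gene_id]
  sort(hits$gene_id[hits$ov > 0L])
}

# genes whose body (span) overlaps t's span on the same (flip=FALSE) or
# opposite (flip=TRUE) strand
overlapping_genes_strand <- function(ann, t, flip = FALSE) {
  str <- if (flip) setdiff(c("+", "-"), t$strand) else t$strand
  gn <- ann$genes[chrom == t$chrom & strand == str]
  if (nrow(gn) == 0L) return(character(0))
  span <- c(min(t$exons[, 1L]), max(t$exons[, 2L]))
  sort(gn$gene_id[gn$end > span[1L] & gn$start < span[2L]])
}

#' Classify every isoform of a catalog
#'
#' @param catalog a `nanoiso_catalog` (or annotation).
#' @param ann reference `nanoiso_annotation`.
#' @return data.table (isoform_id, category, matched_reference_id), one row
#'   per catalog isoform; categories are mutually exclusive and exhaustive.
#' @export
classify_catalog <- function(catalog, ann) {
  cat_ann <- as_annotation(catalog)
  ids <- cat_ann$transcripts$transcript_id
  rows <- lapply(ids, function(id) {
    rec <- classify_isoform(transcript_model(cat_ann, id), ann)
    data.table::data.table(isoform_id = rec$isoform_id, category = rec$category,
                           matched_reference_id = rec$matched_reference_id)
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(isoform_id = character(0),
                                  category = character(0),
                                  matched_reference_id = character(0))
  }
  out
}

#' Category summary by isoform and read counts
#'
#' Tallies the number of isoforms and the number of assigned reads per
#' structural category; isoform counts sum to the catalog size, read counts
#' to the total assigned reads.
#'
#' @param records classification table from [classify_catalog()].
#' @param counts a `nanoiso_counts` whose rows cover the classified
#'   isoforms.
#' @return data.table (category, n_isoforms, n_reads).
#' @export
category_summary <- function(records, counts) {
  rec <- data.table::as.data.table(records)
  reads_per_iso <- rowSums(counts$counts)
  rec[, n_reads := reads_per_iso[isoform_id]]
  rec[is.na(n_reads), n_reads := 0]
  out <- rec[, .(n_isoforms = .N, n_reads = sum(n_reads)), by = category]
  lv <- c("FSM", "ISM", "NIC", "NNC", "antisense", "fusion", "genic", "intergenic")
  out[, category := factor(category, levels = lv)]
  data.table::setorder(out, category)
  out[, category := as.character(category)]
  out[]
}
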