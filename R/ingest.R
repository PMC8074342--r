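#' Genomic blocks from a SAM CIGAR string
#'
#' Interprets a CIGAR over `M I D N S H = X` against a 1-based SAM position:
#' `M`/`=`/`X` extend the current block and consume read bases, `D` extends
#' the block consuming reference only, `N` closes the block (a splice
#' junction), `I`/`S` consume read bases only and `H` consumes neither.
#' Blocks are reported 0-based half-open. Deletions do not split blocks;
#' only `N` creates junctions, following the standard spliced-alignment
#' convention (small deletions are sequencing noise, not introns).
#'
#' `read_length` counts all read bases including soft clips;
#' `aligned_read_bases` counts `M`/`=`/`X` only (the bases matched to the
#' reference), which is the quantity behind the ">80% of the read aligned"
#' assignment rule.
#'
#' @param pos 1-based leftmost mapping position (SAM POS).
#' @param cigar CIGAR string.
#' @return list with `blocks` (integer matrix, cols start/end), `read_length`
#'   and `aligned_read_bases`.
#' @export
blocks_from_cigar <- function(pos, cigar) {
  if (is.na(cigar) || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  ref_pos <- as.integer(pos) - 1L            # 0-based
  block_start <- NA_integer_
  starts <- integer(0); ends <- integer(0)
  read_len <- 0L; aligned <- 0L
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (is.na(block_start)) block_start <- ref_pos
      ref_pos <- ref_pos + len
      read_len <- read_len + len
      aligned <- aligned + len
    } else if (op == "D") {
      if (is.na(block_start)) block_start <- ref_pos
      ref_pos <- ref_pos + len
    } else if (op == "N") {
      if (!is.na(block_start)) {
        starts <- c(starts, block_start); ends <- c(ends, ref_pos)
        block_start <- NA_integer_
      }
      ref_pos <- ref_pos + len
    } else if (op %in% c("I", "S")) {
      read_len <- read_len + len
    } # H, P: consume neither
  }
  if (!is.na(block_start)) {
    starts <- c(starts, block_start); ends <- c(ends, ref_pos)
  }
  list(blocks = cbind(start = starts, end = ends),
       read_length = read_len, aligned_read_bases = aligned)
}

#' Load primary spliced alignments from a SAM/BAM file
#'
#' Secondary, supplementary and unmapped records are dropped (their counts
#' are kept as attributes and feed the read-funnel report). Plain SAM input
#' is converted on the fly via [Rsamtools::asBam()]. The read strand is
#' taken from the `ts` (transcript strand) tag when present -- `ts:A:-`
#' flips the alignment strand, as produced by spliced aligners for cDNA
#' reads mapping on either genomic strand -- and from the FLAG bit
#' otherwise.
#'
#' @param path SAM or BAM file.
#' @param sample_id sample label attached to every read.
#' @return a `nanoiso_reads` object: list with data.tables `reads`
#'   (read_idx, read_id, sample_id, chrom, strand, start, end, n_blocks,
#'   read_length, aligned_bases) and `blocks` (read_idx, start, end; 0-based
#'   half-open), plus a `dropped` attribute with filter counts.
#' @export
load_alignments <- function(path, sample_id = "S1") {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  all_flags <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = "flag"))[[1]]$flag
  n_total <- length(all_flags)
  n_unmapped <- sum(bitwAnd(all_flags, 4L) > 0L)
  n_secondary <- sum(bitwAnd(all_flags, 256L) > 0L)
  n_supplementary <- sum(bitwAnd(all_flags, 2048L) > 0L)

  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "ts",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  dropped <- c(unmapped = n_unmapped, secondary = n_secondary,
               supplementary = n_supplementary)
  if (n == 0L) {
    out <- list(reads = data.table::data.table(
      read_idx = integer(0), read_id = character(0), sample_id = character(0),
      chrom = character(0), strand = character(0), start = integer(0),
      end = integer(0), n_blocks = integer(0), read_length = integer(0),
      aligned_bases = integer(0)),
      blocks = data.table::data.table(read_idx = integer(0), start = integer(0),
                                      end = integer(0)))
    attr(out, "dropped") <- dropped
    attr(out, "n_input") <- n_total
    class(out) <- "nanoiso_reads"
    return(out)
  }

  rng <- GenomicAlignments::extractAlignmentRangesOnReference(x$cigar, x$pos)
  nb <- S4Vectors::elementNROWS(rng)
  flat <- unlist(rng, use.names = FALSE)
  ot <- GenomicAlignments::cigarOpTable(x$cigar)
  read_len <- as.integer(ot[, "M"] + ot[, "I"] + ot[, "S"] + ot[, "="] + ot[, "X"])
  aligned <- as.integer(ot[, "M"] + ot[, "="] + ot[, "X"])
  strand <- ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+")
  ts <- x$tag$ts
  if (!is.null(ts)) {
    flip <- !is.na(ts) & ts == "-"
    strand[flip] <- ifelse(strand[flip] == "+", "-", "+")
  }
  reads <- data.table::data.table(
    read_idx = seq_len(n),
    read_id = x$qname,
    sample_id = sample_id,
    chrom = as.character(x$rname),
    strand = strand,
    read_length = read_len,
    aligned_bases = aligned,
    n_blocks = nb)
  blocks <- data.table::data.table(
    read_idx = rep.int(seq_len(n), nb),
    start = IRanges::start(flat) - 1L,       # SAM 1-based -> 0-based half-open
    end = IRanges::end(flat))
  span <- blocks[, .(start = min(start), end = max(end)), by = read_idx]
  reads <- merge(reads, span, by = "read_idx", sort = TRUE)
  data.table::setcolorder(reads, c("read_idx", "read_id", "sample_id", "chrom",
                                   "strand", "start", "end", "n_blocks",
                                   "read_length", "aligned_bases"))
  out <- list(reads = reads, blocks = blocks)
  attr(out, "dropped") <- dropped
  attr(out, "n_input") <- n_total
  class(out) <- "nanoiso_reads"
  out
}

#' @export
print.nanoiso_reads <- function(x, ...) {
  d <- attr(x, "dropped")
  cat("nanoiso reads:", nrow(x$reads), "primary alignments",
      sprintf("(dropped: %d unmapped, %d secondary, %d supplementary)\n",
              d[["unmapped"]], d[["secondary"]], d[["supplementary"]]))
  invisible(x)
}

#' Splice junctions of one read alignment
#'
#' The junctions of a read are the gaps between its consecutive aligned
#' blocks; a single-block read has none.
#'
#' @param r a read representation carrying a `blocks` matrix (as returned by
#'   [blocks_from_cigar()]), or the matrix itself.
#' @return integer matrix with columns `donor_end`, `acceptor_start`.
#' @export
read_junctions <- function(r) {
  blocks <- if (is.matrix(r)) r else r$blocks
  junction_chain(blocks)
}

# Junction table for all reads of a container: read_idx, jidx, donor_end,
# acceptor_start (chain order).
reads_junction_table <- function(reads) {
  b <- reads$blocks
  if (nrow(b) == 0L) {
    return(data.table::data.table(read_idx = integer(0), jidx = integer(0),
                                  donor_end = integer(0), acceptor_start = integer(0)))
  }
  b <- b[order(read_idx, start)]
  b[, n := .N, by = read_idx]
  j <- b[n > 1L, .(jidx = seq_len(.N - 1L), donor_end = end[-.N],
                   acceptor_start = start[-1L]), by = read_idx]
  j[]
}
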