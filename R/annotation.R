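#' Build an indexed transcript annotation from an exon table
#'
#' The annotation object is the central lookup structure of the package: it
#' stores the exon chains of every transcript, the set of splice junctions,
#' and sorted per-(chromosome, strand) donor/acceptor site lists that the
#' discovery and quantification stages query when correcting splice sites.
#'
#' Coordinates are 0-based half-open throughout; [read_gtf()] converts from
#' the 1-based inclusive GTF convention at the I/O boundary.
#'
#' @param exons a data.frame/data.table with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand` (`"+"` or `"-"`), `start`, `end`
#'   (0-based half-open). One row per exon.
#' @param source `"reference"` or `"novel"`; recycled per transcript, or a
#'   named vector by transcript_id.
#' @return an object of class `nanoiso_annotation`: a list with data.tables
#'   `exons`, `transcripts`, `genes`, `junctions` and a `sites` index.
#' @export
build_annotation <- function(exons, source = "reference") {
  ex <- data.table::as.data.table(exons)
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(ex))
  if (length(miss)) stop("exon table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(ex) == 0L) return(empty_annotation())
  ex <- ex[, req, with = FALSE]
  ex[, `:=`(start = as.integer(start), end = as.integer(end),
            chrom = as.character(chrom), strand = as.character(strand),
            transcript_id = as.character(transcript_id),
            gene_id = as.character(gene_id))]
  if (any(!ex$strand %in% c("+", "-"))) {
    bad <- unique(ex$transcript_id[!ex$strand %in% c("+", "-")])
    stop("transcripts without a '+'/'-' strand are not supported: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(ex$start >= ex$end)) stop("exons must satisfy start < end")
  data.table::setorder(ex, chrom, transcript_id, start)

  # a transcript id must map to a single (gene, chrom, strand)
  meta <- unique(ex[, .(transcript_id, gene_id, chrom, strand)])
  dup <- meta$transcript_id[duplicated(meta$transcript_id)]
  if (length(dup)) {
    stop("duplicate transcript_id with conflicting gene/chrom/strand: ",
         paste(unique(dup), collapse = ", "))
  }
  # exons of one transcript must not overlap
  ov <- ex[, .(bad = any(start[-1L] < end[-.N])), by = transcript_id]
  if (any(ov$bad)) {
    stop("overlapping exons within transcript(s): ",
         paste(utils::head(ov$transcript_id[ov$bad], 5), collapse = ", "))
  }

  tx <- ex[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
               start = min(start), end = max(end), n_exons = .N,
               exonic_len = sum(end - start)), by = transcript_id]

  # junction chain per transcript: gaps between consecutive exons
  jn <- ex[, if (.N > 1L) .(donor_end = end[-.N], acceptor_start = start[-1L]),
           by = .(transcript_id, gene_id, chrom, strand)]
  if (nrow(jn) && any(jn$donor_end >= jn$acceptor_start)) {
    stop("invalid junction (donor_end >= acceptor_start); exon chains corrupt")
  }
  ck <- if (nrow(jn)) {
    jn[, .(chain_key = chain_key_str(donor_end, acceptor_start), n_junc = .N),
       by = transcript_id]
  } else {
    data.table::data.table(transcript_id = character(0),
                           chain_key = character(0), n_junc = integer(0))
  }
  tx <- merge(tx, ck, by = "transcript_id", all.x = TRUE)
  tx[is.na(chain_key), `:=`(chain_key = "", n_junc = 0L)]

  if (length(source) == 1L) {
    tx[, source := source]
  } else {
    tx[, source := unname(source[transcript_id])]
  }
  data.table::setorder(tx, chrom, start, transcript_id)

  genes <- tx[, .(chrom = chrom[1L], strand = strand[1L], start = min(start),
                  end = max(end), n_tx = .N), by = gene_id]
  data.table::setorder(genes, chrom, start, gene_id)

  junctions <- if (nrow(jn)) {
    unique(jn[, .(chrom, strand, donor_end, acceptor_start)])
  } else {
    data.table::data.table(chrom = character(0), strand = character(0),
                           donor_end = integer(0), acceptor_start = integer(0))
  }
  data.table::setorder(junctions, chrom, strand, donor_end, acceptor_start)

  sites <- list()
  if (nrow(junctions)) {
    for (k in unique(paste(junctions$chrom, junctions$strand))) {
      sel <- paste(junctions$chrom, junctions$strand) == k
      sites[[k]] <- list(
        donor = sort(unique(junctions$donor_end[sel])),
        acceptor = sort(unique(junctions$acceptor_start[sel]))
      )
    }
  }

  structure(list(exons = ex, transcripts = tx, genes = genes,
                 junctions = junctions, sites = sites),
            class = "nanoiso_annotation")
}

empty_annotation <- function() {
  structure(list(
    exons = data.table::data.table(transcript_id = character(0),
                                   gene_id = character(0), chrom = character(0),
                                   strand = character(0), start = integer(0),
                                   end = integer(0)),
    transcripts = data.table::data.table(transcript_id = character(0),
                                         gene_id = character(0),
                                         chrom = character(0),
                                         strand = character(0),
                                         start = integer(0), end = integer(0),
                                         n_exons = integer(0),
                                         exonic_len = integer(0),
                                         chain_key = character(0),
                                         n_junc = integer(0),
                                         source = character(0)),
    genes = data.table::data.table(gene_id = character(0), chrom = character(0),
                                   strand = character(0), start = integer(0),
                                   end = integer(0), n_tx = integer(0)),
    junctions = data.table::data.table(chrom = character(0),
                                       strand = character(0),
                                       donor_end = integer(0),
                                       acceptor_start = integer(0)),
    sites = list()), class = "nanoiso_annotation")
}

#' @export
print.nanoiso_annotation <- function(x, ...) {
  cat("nanoiso annotation:", nrow(x$transcripts), "transcripts,",
      nrow(x$genes), "genes,", nrow(x$junctions), "junctions\n")
  invisible(x)
}

#' Read a GTF annotation
#'
#' Imports exon features from a GTF file (via rtracklayer), converts 1-based
#' inclusive coordinates to the package's 0-based half-open convention,
#' groups exons per transcript and builds all junction/site indices.
#' Transcripts without a `+`/`-` strand are rejected, as are exon records
#' lacking `gene_id`/`transcript_id` attributes and transcripts with
#' internally overlapping exons.
#'
#' @param path path to a GTF file. An empty file yields an empty annotation.
#' @param source annotation source label stored per transcript; defaults to
#'   `"reference"`. If the file carries a `nanoiso_source` attribute (written
#'   by [write_gtf()]) that value wins.
#' @return a `nanoiso_annotation`; see [build_annotation()].
#' @export
read_gtf <- function(path, source = "reference") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines_present <- any(!grepl("^(#|\\s*$)", readLines(path, n = 1000L)))
  if (!lines_present) return(empty_annotation())
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) return(empty_annotation())
  md <- S4Vectors::mcols(gr)
  gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else rep(NA_character_, length(gr))
  tid <- if ("transcript_id" %in% names(md)) as.character(md$transcript_id) else rep(NA_character_, length(gr))
  bad <- which(is.na(gid) | is.na(tid) | gid == "" | tid == "")
  if (length(bad)) {
    stop(sprintf("exon record %d (%s:%d-%d) lacks gene_id/transcript_id",
                 bad[1L], as.character(GenomicRanges::seqnames(gr))[bad[1L]],
                 GenomicRanges::start(gr)[bad[1L]], GenomicRanges::end(gr)[bad[1L]]))
  }
  src <- if ("nanoiso_source" %in% names(md)) {
    s <- as.character(md$nanoiso_source)
    stats::setNames(s, tid)[!duplicated(tid)]
  } else source
  ex <- data.table::data.table(
    transcript_id = tid, gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,   # GTF 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr))
  if (any(ex$strand == "*")) {
    bad <- unique(ex$transcript_id[ex$strand == "*"])
    stop("transcripts without strand are rejected: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  build_annotation(ex, source = src)
}

#' Write an annotation or isoform catalog as GTF
#'
#' Coordinates are converted back to the 1-based inclusive GTF convention.
#' The round trip `read_gtf(write_gtf(x))` reproduces exon coordinates, ids
#' and strands exactly. Novel isoforms keep their generated ids and carry a
#' `nanoiso_source` attribute so the source survives the round trip.
#'
#' @param x a `nanoiso_annotation` or `nanoiso_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path) {
  ann <- as_annotation(x)
  ex <- merge(ann$exons,
              ann$transcripts[, .(transcript_id, source)], by = "transcript_id")
  data.table::setorder(ex, chrom, start, transcript_id)
  if (nrow(ex) == 0L) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand)
  S4Vectors::mcols(gr)$source <- "nanoiso"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  S4Vectors::mcols(gr)$nanoiso_source <- ex$source
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Junction chain of a transcript model
#'
#' Returns the ordered intron list of a transcript: one row per junction with
#' `donor_end` (upstream exon end, 0-based exclusive) and `acceptor_start`
#' (downstream exon start, 0-based inclusive). Single-exon transcripts yield
#' a zero-row matrix. The chain is a function of the exon *set* only.
#'
#' @param t a transcript model from [transcript_model()], or a two-column
#'   exon matrix (start, end).
#' @return integer matrix with columns `donor_end`, `acceptor_start`.
#' @export
junction_chain <- function(t) {
  exons <- if (is.matrix(t)) t else t$exons
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  n <- nrow(exons)
  m <- if (n <= 1L) {
    matrix(integer(0), ncol = 2L)
  } else {
    cbind(exons[-n, 2L], exons[-1L, 1L])
  }
  colnames(m) <- c("donor_end", "acceptor_start")
  if (nrow(m) && any(m[, 1L] >= m[, 2L])) stop("invalid exon chain: overlapping or unsorted exons")
  m
}

#' Extract one transcript model from an annotation or catalog
#'
#' @param ann a `nanoiso_annotation` or `nanoiso_catalog`.
#' @param transcript_id transcript identifier.
#' @return a list with fields `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `exons` (matrix of 0-based half-open start/end) and `source`.
#' @export
transcript_model <- function(ann, transcript_id) {
  ann <- as_annotation(ann)
  tid <- transcript_id                      # avoid data.table column capture
  trow <- ann$transcripts[ann$transcripts$transcript_id == tid]
  if (nrow(trow) == 0L) stop("unknown transcript: ", tid)
  ex <- ann$exons[ann$exons$transcript_id == tid]
  data.table::setorder(ex, start)
  list(transcript_id = tid, gene_id = trow$gene_id,
       chrom = trow$chrom, strand = trow$strand,
       exons = cbind(start = ex$start, end = ex$end),
       source = trow$source)
}

#' Coerce to an annotation object
#'
#' Catalogs produced by [discover()] share the annotation's internal layout,
#' so downstream code (classification, quantification, GTF output) can treat
#' either uniformly.
#'
#' @param x a `nanoiso_annotation` or `nanoiso_catalog`.
#' @return a `nanoiso_annotation`.
#' @export
as_annotation <- function(x) {
  if (inherits(x, "nanoiso_annotation")) return(x)
  if (inherits(x, "nanoiso_catalog")) {
    src <- stats::setNames(x$transcripts$source, x$transcripts$transcript_id)
    return(build_annotation(x$exons, source = src))
  }
  stop("cannot coerce class ", paste(class(x), collapse = "/"), " to annotation")
}

# sorted donor/acceptor site lists for one (chrom, strand); empty lists when
# the annotation has no junction there.
ann_sites <- function(ann, chrom, strand) {
  s <- ann$sites[[paste(chrom, strand)]]
  if (is.null(s)) list(donor = integer(0), acceptor = integer(0)) else s
}
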