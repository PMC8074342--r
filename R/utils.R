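# Internal helpers shared across modules. All genomic intervals in this
# package are 0-based half-open [start, end); GTF and SAM conversions happen
# only at the I/O boundary.

# Collapse a junction table into a canonical chain key, e.g. "100-200;300-500".
# Keys are only ever compared within one (chrom, strand), which callers
# incorporate separately.
chain_key_str <- function(donor_end, acceptor_start) {
  if (length(donor_end) == 0L) return("")
  paste(paste0(donor_end, "-", acceptor_start), collapse = ";")
}

# Vectorised chain keys for a data.table of junctions keyed by `id_col`.
# Returns a data.table(id, chain_key, n_junc). Junctions must already be in
# chain order within each id.
chain_keys_dt <- function(jdt, id_col) {
  if (nrow(jdt) == 0L) {
    return(data.table::data.table(id = integer(0), chain_key = character(0),
                                  n_junc = integer(0)))
  }
  jdt <- data.table::as.data.table(jdt)
  out <- jdt[, .(chain_key = paste(paste0(donor_end, "-", acceptor_start),
                                   collapse = ";"),
                 n_junc = .N),
             by = c(id_col)]
  data.table::setnames(out, id_col, "id")
  out[]
}

# Parse a chain key back into a junction matrix (donor_end, acceptor_start).
parse_chain_key <- function(key) {
  if (is.na(key) || !nzchar(key)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("donor_end", "acceptor_start"))))
  }
  parts <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("donor_end", "acceptor_start")
  m
}

# Snap coordinates to the nearest value of a sorted site vector when the
# distance is strictly below `tol`; ties go to the smaller coordinate.
# Returns the (possibly unchanged) coordinates.
snap_to_sites <- function(x, sites, tol) {
  if (length(sites) == 0L || length(x) == 0L || tol <= 0) return(x)
  i <- findInterval(x, sites)
  lo <- ifelse(i >= 1L, sites[pmax(i, 1L)], NA_integer_)
  hi <- ifelse(i < length(sites), sites[pmin(i + 1L, length(sites))], NA_integer_)
  dlo <- ifelse(is.na(lo), Inf, x - lo)
  dhi <- ifelse(is.na(hi), Inf, hi - x)
  # tie -> smaller coordinate, i.e. prefer `lo` when distances are equal
  best <- ifelse(dlo <= dhi, lo, hi)
  dist <- pmin(dlo, dhi)
  ifelse(dist < tol, best, x)
}

# Total length of the intersection between a set of disjoint sorted blocks
# (matrix cols start, end) and another set of disjoint sorted intervals.
interval_overlap <- function(blocks, exons) {
  if (nrow(blocks) == 0L || nrow(exons) == 0L) return(0L)
  total <- 0L
  for (i in seq_len(nrow(blocks))) {
    s <- pmax(blocks[i, 1L], exons[, 1L])
    e <- pmin(blocks[i, 2L], exons[, 2L])
    total <- total + sum(pmax(0L, e - s))
  }
  as.integer(total)
}

# Cumulative exonic coverage function of a transcript: returns a function
# C(x) = number of exonic bases strictly below coordinate x, vectorised.
# Exons: matrix cols start, end, sorted, disjoint.
cumcov_fun <- function(exons) {
  starts <- exons[, 1L]
  ends <- exons[, 2L]
  cum <- c(0L, cumsum(ends - starts))
  function(x) {
    i <- findInterval(x, starts)          # exon index at or before x
    base <- cum[i + 1L]                   # full exons strictly before exon i
    # subtract the part of exon i at or beyond x
    over <- ifelse(i >= 1L, pmax(0L, ends[pmax(i, 1L)] - pmax(x, starts[pmax(i, 1L)])), 0L)
    base - over
  }
}

# Statistical mode of an integer vector with a deterministic tie-break:
# `outermost = "min"` or `"max"` picks the smallest/largest modal value.
coord_mode <- function(x, outermost = c("min", "max")) {
  outermost <- match.arg(outermost)
  tab <- table(x)
  modes <- as.integer(names(tab)[tab == max(tab)])
  if (outermost == "min") min(modes) else max(modes)
}

# Derive a bounded child seed (< 2^31) from a master seed and a label.
child_seed <- function(seed, label) {
  v <- utf8ToInt(as.character(label))
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483587)
}
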