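#' Default pipeline configuration
#'
#' @return list with `discovery` ([discovery_config()]), `quant`
#'   ([quant_config()]) and `dtu` ([dtu_config()]) sections.
#' @export
default_config <- function() {
  list(discovery = discovery_config(), quant = quant_config(),
       dtu = dtu_config())
}

#' Load and validate a JSON pipeline configuration
#'
#' Every threshold of the pipeline lives in one JSON file with sections
#' `discovery`, `quant` and `dtu` (plus free-form `paths` and `samples`).
#' Missing keys take their documented defaults; unknown sections or keys
#' are rejected with a message naming the offender. A fully resolved copy
#' of the configuration can be written next to the run outputs.
#'
#' @param path JSON file; `{}` yields all defaults.
#' @param resolved_out optional path; when given, the resolved
#'   configuration (defaults filled in) is written there as JSON.
#' @return a validated configuration list as in [default_config()], plus
#'   any `paths`/`samples` entries.
#' @export
load_config <- function(path, resolved_out = NULL) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(raw) == 0L) raw <- list()
  known_sections <- c("discovery", "quant", "dtu", "paths", "samples")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown)) stop("unknown configuration section: ",
                            paste(unknown, collapse = ", "))
  build <- function(section, ctor) {
    user <- raw[[section]]
    if (is.null(user)) user <- list()
    allowed <- names(formals(ctor))
    bad <- setdiff(names(user), allowed)
    if (length(bad)) stop("unknown key in '", section, "': ",
                          paste(bad, collapse = ", "))
    do.call(ctor, user)
  }
  cfg <- list(discovery = build("discovery", discovery_config),
              quant = build("quant", quant_config),
              dtu = build("dtu", dtu_config))
  if (!is.null(raw$paths)) cfg$paths <- raw$paths
  if (!is.null(raw$samples)) cfg$samples <- raw$samples
  if (!is.null(resolved_out)) {
    jsonlite::write_json(lapply(cfg, unclass), resolved_out,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  cfg
}

#' Read-funnel report
#'
#' Summarises how many reads survive each pipeline stage (input records,
#' primary alignments, grouped reads, assigned reads). Counts must be
#' monotone non-increasing; a violation indicates inconsistent run
#' artifacts and raises an error.
#'
#' @param n_input raw records in the input file(s).
#' @param n_primary primary alignments after filtering.
#' @param n_grouped reads placed into isoform groups.
#' @param n_assigned reads assigned to a transcript.
#' @return data.frame (stage, reads).
#' @export
funnel_report <- function(n_input, n_primary, n_grouped, n_assigned) {
  v <- c(input_records = n_input, primary_alignments = n_primary,
         grouped_reads = n_grouped, assigned_reads = n_assigned)
  if (any(diff(v) > 0)) {
    stop("read funnel is not monotone non-increasing: ",
         paste(sprintf("%s=%d", names(v), v), collapse = ", "))
  }
  data.frame(stage = names(v), reads = unname(as.integer(v)))
}
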