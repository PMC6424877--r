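# Tabular I/O for alignment hits and per-tool read assignments.

HIT_COLUMNS <- c("read_id", "subject_id", "subject_taxon", "percent_identity",
                 "align_length", "query_length", "bitscore", "evalue",
                 "subject_start", "subject_end")

validate_hits <- function(hits) {
  miss <- setdiff(HIT_COLUMNS, names(hits))
  if (length(miss))
    stop_kefirmg("hit table is missing columns: ", paste(miss, collapse = ", "))
  if (any(hits$align_length < 1)) stop_kefirmg("align_length must be >= 1")
  if (any(hits$percent_identity <= 0 | hits$percent_identity > 100))
    stop_kefirmg("percent_identity must lie in (0, 100]")
  if (any(hits$evalue < 0)) stop_kefirmg("evalue must be >= 0")
  invisible(hits)
}

#' Read / write a hit table
#'
#' The native hit format is a headered TSV with the columns
#' `read_id, subject_id, subject_taxon, percent_identity, align_length,
#' query_length, bitscore, evalue, subject_start, subject_end`.
#' @param path file path.
#' @return `read_hits()`: a validated hit data.frame.
#' @export
read_hits <- function(path) {
  validate_hits(as.data.frame(fread(path, sep = "\t", header = TRUE)))
}

#' @rdname read_hits
#' @param hits a hit data.frame.
#' @export
write_hits <- function(hits, path) {
  validate_hits(hits)
  fwrite(as.data.table(hits)[, HIT_COLUMNS, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Read a 12-column BLAST tabular (outfmt 6) file as a hit table
#'
#' Standard columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Subject taxa are resolved through
#' `subject_taxa`, a two-column map; query lengths come from `read_lengths`
#' when given, otherwise `qend` of each read's longest hit is used as a lower
#' bound on its length.
#'
#' @param path BLAST outfmt-6 TSV (no header).
#' @param subject_taxa data.frame (`subject_id`, `taxon_id`) or named vector.
#' @param read_lengths optional data.frame (`read_id`, `length`) or named
#'   vector.
#' @return A hit data.frame in the native column layout.
#' @export
read_blast6 <- function(path, subject_taxa, read_lengths = NULL) {
  b6 <- fread(path, sep = "\t", header = FALSE,
              col.names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                            "gapopen", "qstart", "qend", "sstart", "send",
                            "evalue", "bitscore"))
  if (is.data.frame(subject_taxa))
    subject_taxa <- stats::setNames(as.character(subject_taxa[[2L]]),
                                    as.character(subject_taxa[[1L]]))
  unknown <- setdiff(unique(b6$sseqid), names(subject_taxa))
  if (length(unknown))
    stop_kefirmg("no taxon mapping for subject(s): ",
                 paste(utils::head(unknown, 5L), collapse = ", "))
  if (is.null(read_lengths)) {
    ql <- b6[, .(query_length = max(qend)), by = qseqid]
    read_lengths <- stats::setNames(ql$query_length, ql$qseqid)
  } else if (is.data.frame(read_lengths)) {
    read_lengths <- stats::setNames(as.numeric(read_lengths[[2L]]),
                                    as.character(read_lengths[[1L]]))
  }
  out <- data.frame(
    read_id = as.character(b6$qseqid),
    subject_id = as.character(b6$sseqid),
    subject_taxon = unname(subject_taxa[as.character(b6$sseqid)]),
    percent_identity = b6$pident,
    align_length = b6$length,
    query_length = unname(read_lengths[as.character(b6$qseqid)]),
    bitscore = b6$bitscore,
    evalue = b6$evalue,
    subject_start = b6$sstart,
    subject_end = b6$send,
    stringsAsFactors = FALSE)
  validate_hits(out)
}

#' Read / write per-tool read assignments
#'
#' Two-column TSV `read_id<TAB>taxon_id`; the taxon column may hold
#' [UNASSIGNED]. A third `source` column is written when present.
#' @param path file path.
#' @return `read_assignments()`: data.frame `read_id`, `taxon` (+ `source`).
#' @export
read_assignments <- function(path) {
  df <- as.data.frame(fread(path, sep = "\t", header = TRUE,
                            colClasses = "character"))
  names(df)[1:2] <- c("read_id", "taxon")
  df
}

#' @rdname read_assignments
#' @param assignments assignment data.frame.
#' @export
write_assignments <- function(assignments, path) {
  fwrite(assignments, path, sep = "\t")
  invisible(path)
}

# Percent query coverage of a hit, clamped to 100.
query_coverage <- function(hits) {
  pmin(100, 100 * hits$align_length / hits$query_length)
}
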