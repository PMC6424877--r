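#' Sentinel for reads without a taxonomic assignment
#'
#' Constant used throughout the package to mark reads that no classifier (or
#' the LCA pipeline itself) could place on the taxonomy.
#' @export
UNASSIGNED <- "UNASSIGNED"

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_kefirmg <- function(...) stop(..., call. = FALSE)

#' @importFrom data.table := .N .SD data.table as.data.table setDT setnames
#'   fread fwrite setorder setorderv rbindlist
NULL

# Sample from a truncated normal by inverse-CDF; vectorised over n.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Write a headered TSV with a schema comment line.
write_tsv_schema <- function(x, path, schema = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(schema)) writeLines(paste0("# kefirmg schema: ", schema), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_schema <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df
}
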