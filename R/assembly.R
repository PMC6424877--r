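# Contig filtering, assembly contiguity statistics, and MAG bin curation.

#' Build / validate a contig table
#'
#' @param contigs data.frame with `contig_id`, `length` and optional
#'   curation columns `mapped_species` (taxon or NA), `target_similarity`
#'   (logical), `rrna_genus` (taxon or NA).
#' @return The validated data.frame with optional columns filled with NA /
#'   FALSE.
#' @export
contig_set <- function(contigs) {
  contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  if (!all(c("contig_id", "length") %in% names(contigs)))
    stop_kefirmg("contig table needs 'contig_id' and 'length' columns")
  if (anyDuplicated(contigs$contig_id))
    stop_kefirmg("duplicate contig_id")
  if (any(contigs$length < 1)) stop_kefirmg("contig lengths must be >= 1")
  contigs$contig_id <- as.character(contigs$contig_id)
  if (is.null(contigs$mapped_species)) contigs$mapped_species <- NA_character_
  if (is.null(contigs$target_similarity)) contigs$target_similarity <- FALSE
  contigs$target_similarity[is.na(contigs$target_similarity)] <- FALSE
  if (is.null(contigs$rrna_genus)) contigs$rrna_genus <- NA_character_
  contigs
}

#' Drop short contigs
#'
#' Keeps contigs whose length is strictly greater than `min_len` (a contig of
#' exactly `min_len` bp is removed).
#'
#' @param contigs contig data.frame.
#' @param min_len length threshold in bp (default 1000).
#' @return The retained rows.
#' @export
filter_contigs <- function(contigs, min_len = 1000) {
  contigs[contigs$length > min_len, , drop = FALSE]
}

#' Assembly contiguity statistics
#'
#' Computes the usual contiguity summary of a contig set. N50 is the length
#' of the contig at which the descending cumulative contig length first
#' reaches half the assembly size (>= convention); L50 is that contig's
#' 1-based index in the descending order. The median of an even count is the
#' mean of the two central lengths. All values in bp;
#' [format_assembly_stats()] renders the kbp/Mbp table dialect.
#'
#' @param contigs contig data.frame (non-empty).
#' @param cds,trna optional annotation counts passed through to the output.
#' @return list of class `assembly_stats`: `total_size`, `n_contigs`,
#'   `longest`, `mean`, `median`, `n50`, `l50` (+ `cds`, `trna` if given).
#' @examples
#' compute_stats(data.frame(contig_id = letters[1:5],
#'                          length = c(5000, 4000, 3000, 2000, 1000)))
#' @export
compute_stats <- function(contigs, cds = NULL, trna = NULL) {
  if (nrow(contigs) == 0L) stop_kefirmg("cannot summarise an empty contig set")
  len <- sort(as.numeric(contigs$length), decreasing = TRUE)
  total <- sum(len)
  csum <- cumsum(len)
  i50 <- which(csum >= total / 2)[1L]
  out <- list(total_size = total, n_contigs = length(len), longest = len[1L],
              mean = total / length(len), median = stats::median(len),
              n50 = len[i50], l50 = i50)
  if (!is.null(cds)) out$cds <- cds
  if (!is.null(trna)) out$trna <- trna
  structure(out, class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "<assembly_stats> total %.0f bp in %d contigs | longest %.0f | mean %.1f | median %.1f | N50 %.0f | L50 %d\n",
    x$total_size, x$n_contigs, x$longest, x$mean, x$median, x$n50, x$l50))
  invisible(x)
}

#' Format assembly statistics in table units
#'
#' Renders total size in Mbp and longest/mean/median/N50 in kbp or bp, one
#' decimal, without ever storing rounded values internally.
#' @param stats an `assembly_stats`.
#' @param unit `"bp"` (whole-assembly table dialect) or `"kbp"` (MAG table
#'   dialect).
#' @return one-row data.frame of formatted columns.
#' @export
format_assembly_stats <- function(stats, unit = c("bp", "kbp")) {
  unit <- match.arg(unit)
  if (unit == "bp") {
    data.frame(total_size_Mbp = round(stats$total_size / 1e6, 1),
               n_contigs = stats$n_contigs,
               longest_bp = round(stats$longest),
               mean_bp = round(stats$mean),
               median_bp = round(stats$median),
               n50_bp = round(stats$n50))
  } else {
    data.frame(total_size_Mbp = round(stats$total_size / 1e6, 2),
               n_contigs = stats$n_contigs,
               longest_kbp = round(stats$longest / 1e3, 1),
               mean_kbp = round(stats$mean / 1e3, 1),
               n50_kbp = round(stats$n50 / 1e3, 1),
               l50 = stats$l50)
  }
}

#' Remove off-target contigs from a genome bin
#'
#' Curation rule for a bin targeted at one genus: member contigs mapped to a
#' species outside the target genus are discarded, unless they carry the
#' target-genus-similarity flag (evidence of sequence similarity to the
#' target genus despite the off-target mapping). Contigs mapped to the
#' target genus, and unmapped contigs, are kept. Never adds contigs.
#'
#' @param bin list with `bin_id`, `members` (contig ids) and `target_genus`
#'   (taxon id), or just a character vector of member ids plus
#'   `target_genus=`.
#' @param contigs contig data.frame (see [contig_set()]); `mapped_species`
#'   must hold taxon ids resolvable in `tax` where non-NA.
#' @param tax a `taxonomy` used to test whether a mapped species lies inside
#'   the target genus.
#' @param target_genus target genus taxon id (taken from `bin` if omitted).
#' @return Character vector of surviving member contig ids (original order).
#' @export
purify_bin <- function(bin, contigs, tax, target_genus = NULL) {
  stopifnot(inherits(tax, "taxonomy"))
  if (is.list(bin) && !is.null(bin$members)) {
    members <- as.character(bin$members)
    target_genus <- target_genus %||% bin$target_genus
  } else {
    members <- as.character(bin)
  }
  if (is.null(target_genus)) stop_kefirmg("target_genus is required")
  check_ids(tax, target_genus)
  missing <- setdiff(members, contigs$contig_id)
  if (length(missing))
    stop_kefirmg("bin members absent from contig set: ",
                 paste(utils::head(missing, 5L), collapse = ", "))
  rows <- contigs[match(members, contigs$contig_id), , drop = FALSE]
  keep <- vapply(seq_len(nrow(rows)), function(i) {
    sp <- rows$mapped_species[i]
    if (is.na(sp)) return(TRUE)                        # unmapped: keep
    if (is_ancestor(tax, target_genus, sp)) return(TRUE)  # in-genus: keep
    isTRUE(rows$target_similarity[i])                  # off-target: flag rescues
  }, logical(1))
  members[keep]
}

#' Rescue rRNA-carrying contigs into a curated bin
#'
#' rRNA genes frequently assemble apart from the rest of a genome and end up
#' outside its bin. This appends, from the whole contig set, every contig
#' whose rRNA annotation matches the target genus and that is not already a
#' member. Idempotent; never removes contigs.
#'
#' @param members character vector of curated member contig ids.
#' @param contigs contig data.frame with an `rrna_genus` column.
#' @param target_genus genus taxon id to match against `rrna_genus`.
#' @return The extended member vector (appended contigs in contig-set order).
#' @export
add_rrna_contigs <- function(members, contigs, target_genus) {
  rrna <- contigs$contig_id[!is.na(contigs$rrna_genus) &
                              contigs$rrna_genus == target_genus]
  c(members, setdiff(rrna, members))
}
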