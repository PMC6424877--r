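#' Parameters for MEGAN-style LCA read classification
#'
#' The four hit-level filters plus the minimum-support rule used when parsing
#' tabular alignments into per-read taxonomic assignments:
#' * `min_score` — bitscore floor; hits below it are dropped.
#' * `max_expected` — E-value ceiling; hits above it are dropped.
#' * `top_percent` — among surviving hits of a read, keep those whose bitscore
#'   is within `top_percent`% of the best bitscore (>= comparison, so ties at
#'   the cutoff are retained).
#' * `min_support` — taxa holding fewer directly-assigned reads than this are
#'   folded upwards (see [apply_min_support()]).
#' * `lca_percent` — only the value 100 (plain naive LCA over all retained
#'   taxa) is supported; other values are rejected.
#'
#' Two presets mirror common parameterisations for whole-metagenome and
#' marker-gene read sets: `"megan-main"` = (100, 0.01, 10, 150),
#' `"megan-marker"` = (80, 0.01, 100, 10).
#'
#' @param min_score bitscore floor (default 100).
#' @param max_expected E-value ceiling (default 0.01).
#' @param top_percent percent window below the best bitscore (default 10).
#' @param min_support minimum directly-assigned read count (default 150).
#' @param lca_percent must be 100.
#' @return An object of class `lca_params`.
#' @examples
#' lca_params(preset = "megan-marker")
#' @export
lca_params <- function(min_score = 100, max_expected = 0.01,
                       top_percent = 10, min_support = 150,
                       lca_percent = 100, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("megan-main", "megan-marker"))
    if (preset == "megan-main") {
      min_score <- 100; max_expected <- 0.01
      top_percent <- 10; min_support <- 150
    } else {
      min_score <- 80; max_expected <- 0.01
      top_percent <- 100; min_support <- 10
    }
  }
  if (lca_percent != 100)
    stop_kefirmg("only lca_percent = 100 (plain naive LCA) is supported")
  if (top_percent < 0 || top_percent > 100)
    stop_kefirmg("top_percent must be in [0, 100]")
  if (min_support < 0) stop_kefirmg("min_support must be >= 0")
  structure(list(min_score = min_score, max_expected = max_expected,
                 top_percent = top_percent, min_support = min_support,
                 lca_percent = lca_percent),
            class = "lca_params")
}

#' @rdname lca_params
#' @param preset `"megan-main"` or `"megan-marker"`; overrides the numeric
#'   arguments.
#' @export
print.lca_params <- function(x, ...) {
  cat(sprintf(
    "<lca_params> min_score=%g max_expected=%g top_percent=%g min_support=%g\n",
    x$min_score, x$max_expected, x$top_percent, x$min_support))
  invisible(x)
}

#' Filter the alignment hits of one read
#'
#' Applies the score floor and E-value ceiling first, then keeps hits whose
#' bitscore is at least `(1 - top_percent/100)` times the best surviving
#' bitscore. Idempotent; an empty input yields an empty output.
#'
#' @param hits data.frame of hits sharing one `read_id`, with at least
#'   `bitscore` and `evalue` columns.
#' @param params an [lca_params()] object.
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, params) {
  stopifnot(inherits(params, "lca_params"))
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$read_id)) > 1L)
    stop_kefirmg("filter_hits() expects the hits of a single read")
  keep <- hits$bitscore >= params$min_score & hits$evalue <= params$max_expected
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  cutoff <- (1 - params$top_percent / 100) * max(hits$bitscore)
  hits[hits$bitscore >= cutoff, , drop = FALSE]
}

#' Assign reads to taxa by naive LCA over filtered hits
#'
#' For each read, the surviving hits' subject taxa are reduced to their lowest
#' common ancestor; reads with no surviving hit become [UNASSIGNED]. The
#' min-support adjustment is applied afterwards unless `min_support = 0`.
#'
#' @param hits hit table (multiple reads) with columns `read_id`,
#'   `subject_taxon`, `bitscore`, `evalue`.
#' @param tax a `taxonomy`.
#' @param params an [lca_params()] object.
#' @param source label recorded in the `source` column (default "lca").
#' @param apply_support apply [apply_min_support()] with `params$min_support`
#'   (default TRUE).
#' @return data.frame with one row per read: `read_id`, `taxon`, `source`.
#' @export
assign_reads <- function(hits, tax, params, source = "lca",
                         apply_support = TRUE) {
  stopifnot(inherits(tax, "taxonomy"), inherits(params, "lca_params"))
  check_ids(tax, unique(hits$subject_taxon))
  dt <- as.data.table(hits)
  # vectorised filter: floors first, then per-read top-percent window
  dt <- dt[bitscore >= params$min_score & evalue <= params$max_expected]
  assignments <- if (nrow(dt)) {
    dt <- dt[, .SD[bitscore >= (1 - params$top_percent / 100) * max(bitscore)],
             by = read_id]
    dt[, .(taxon = lca(tax, subject_taxon)), by = read_id]
  } else {
    data.table(read_id = character(), taxon = character())
  }
  all_reads <- unique(as.character(hits$read_id))
  out <- data.frame(read_id = all_reads, stringsAsFactors = FALSE)
  out$taxon <- assignments$taxon[match(out$read_id, assignments$read_id)]
  out$taxon[is.na(out$taxon)] <- UNASSIGNED
  out$source <- source
  if (apply_support && params$min_support > 0)
    out <- apply_min_support(out, tax, params$min_support)
  out
}

#' Fold weakly-supported taxa upwards (min-support rule)
#'
#' Taxa whose directly-assigned read count falls below `min_support` do not
#' appear in the output: their reads move to the nearest ancestor-or-self
#' whose cumulative (clade) read count — computed on the input assignment —
#' reaches `min_support`. Reads with no such ancestor below the root become
#' [UNASSIGNED] (alternatively, set `unsupported_to = "unassigned"` to send
#' every under-supported taxon's reads straight to [UNASSIGNED]). The total
#' read count is conserved and reads already at the root stay there.
#'
#' @param assignments data.frame with `read_id`, `taxon` (and optionally
#'   `source`) columns; `taxon` may be [UNASSIGNED].
#' @param tax a `taxonomy`.
#' @param min_support minimum read count.
#' @param unsupported_to `"push_up"` (default) or `"unassigned"`.
#' @return The adjusted assignment data.frame (same rows, taxa updated).
#' @export
apply_min_support <- function(assignments, tax, min_support,
                              unsupported_to = c("push_up", "unassigned")) {
  unsupported_to <- match.arg(unsupported_to)
  stopifnot(inherits(tax, "taxonomy"))
  if (min_support <= 0 || nrow(assignments) == 0L) return(assignments)
  assigned <- assignments$taxon != UNASSIGNED
  taxa <- assignments$taxon[assigned]
  if (length(taxa) == 0L) return(assignments)
  check_ids(tax, unique(taxa))

  direct <- table(taxa)
  # clade counts: each taxon's count contributes to all its ancestors
  clade <- new.env(parent = emptyenv())
  for (tx in names(direct)) {
    for (anc in root_path(tax, tx)) {
      prev <- if (is.null(clade[[anc]])) 0L else clade[[anc]]
      clade[[anc]] <- prev + as.integer(direct[[tx]])
    }
  }
  dest <- vapply(names(direct), function(tx) {
    if (direct[[tx]] >= min_support || tx == tax$root_id) return(tx)
    if (unsupported_to == "unassigned") return(UNASSIGNED)
    path <- rev(root_path(tax, tx))      # self first, root last
    path <- path[path != tax$root_id]    # root is never a push-up target
    for (anc in path) {
      if (!is.null(clade[[anc]]) && clade[[anc]] >= min_support) return(anc)
    }
    UNASSIGNED
  }, character(1))
  assignments$taxon[assigned] <- dest[assignments$taxon[assigned]]
  assignments
}

#' Summarise read assignments as counts and percentages of all reads
#'
#' Percentages use the full read count of the data set as denominator, so
#' unclassified reads dilute every taxon's share rather than disappearing.
#' Reads absent from `assignments` (e.g. never aligned) count as unassigned.
#'
#' @param assignments data.frame with `read_id` and `taxon`.
#' @param total_reads total reads in the data set; must be >=
#'   `nrow(assignments)` and > 0.
#' @return data.frame `taxon`, `count`, `percent` sorted by decreasing count,
#'   with an [UNASSIGNED] row; `sum(count) == total_reads`.
#' @export
summarize_assignments <- function(assignments, total_reads) {
  if (total_reads <= 0) stop_kefirmg("total_reads must be positive")
  if (total_reads < nrow(assignments))
    stop_kefirmg("total_reads is smaller than the number of assignment records")
  counts <- table(assignments$taxon)
  out <- data.frame(taxon = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  extra <- total_reads - nrow(assignments)
  if (UNASSIGNED %in% out$taxon) {
    out$count[out$taxon == UNASSIGNED] <-
      out$count[out$taxon == UNASSIGNED] + extra
  } else if (extra > 0 || nrow(out) == 0L) {
    out <- rbind(out, data.frame(taxon = UNASSIGNED, count = extra))
  }
  out$percent <- 100 * out$count / total_reads
  out[order(-out$count, out$taxon), , drop = FALSE]
}
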