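#' Merge per-read assignments from several classifiers by priority
#'
#' Each read takes the taxon of the first tool, in `priority` order, that
#' assigned it to something other than [UNASSIGNED]; a read every tool left
#' unassigned stays [UNASSIGNED]. Reads missing from a tool's table count as
#' unassigned for that tool (a message reports how many); with
#' `strict = TRUE` a missing read is an error instead.
#'
#' @param tools named list of assignment data.frames (`read_id`, `taxon`),
#'   one per classifier.
#' @param priority character vector of tool names, highest priority first;
#'   must be unique and present in `tools`.
#' @param reads optional read universe; defaults to the union of all tables.
#' @param strict error (rather than treat as unassigned) when a read is
#'   missing from a tool's table.
#' @return data.frame `read_id`, `taxon`, `source` where `source` is the
#'   winning tool name (or "none").
#' @examples
#' a <- data.frame(read_id = c("r1", "r2"), taxon = c("X", "UNASSIGNED"))
#' b <- data.frame(read_id = c("r1", "r2"), taxon = c("Y", "Z"))
#' consensus_assign(list(t1 = a, t2 = b), priority = c("t1", "t2"))
#' @export
consensus_assign <- function(tools, priority = names(tools), reads = NULL,
                             strict = FALSE) {
  if (length(priority) == 0L) stop_kefirmg("priority list is empty")
  if (anyDuplicated(priority)) stop_kefirmg("priority list has duplicates")
  missing_tools <- setdiff(priority, names(tools))
  if (length(missing_tools))
    stop_kefirmg("unknown tool in priority list: ",
                 paste(missing_tools, collapse = ", "))
  if (is.null(reads))
    reads <- unique(unlist(lapply(tools[priority],
                                  function(t) as.character(t$read_id))))
  out <- data.frame(read_id = reads, taxon = UNASSIGNED, source = "none",
                    stringsAsFactors = FALSE)
  open <- rep(TRUE, length(reads))   # reads still unassigned
  for (tool in priority) {
    tab <- tools[[tool]]
    m <- match(reads, tab$read_id)
    n_missing <- sum(is.na(m))
    if (n_missing > 0L) {
      if (strict)
        stop_kefirmg("tool '", tool, "' is missing ", n_missing, " read(s)")
      message("consensus_assign: tool '", tool, "' is missing ", n_missing,
              " read(s); treated as unassigned")
    }
    call <- as.character(tab$taxon[m])
    hit <- open & !is.na(call) & call != UNASSIGNED
    out$taxon[hit] <- call[hit]
    out$source[hit] <- tool
    open <- open & !hit
    if (!any(open)) break
  }
  out
}

#' Roll consensus assignments up into a genus-level category table
#'
#' Implements the genus-centric summary used for stacked-bar community
#' profiles: assignments at subspecies, species or species-group rank (or at
#' unranked nodes below a genus) roll up to their genus; genus-rank
#' assignments stay; assignments above genus fall into the "above genus"
#' category; root-level assignments and [UNASSIGNED] reads are "unassigned".
#' Genus categories holding strictly less than `minority_threshold` percent
#' of all reads are merged into "minorities". Percentages are over
#' `total_reads`, so every read of the data set lands in exactly one
#' category and the table sums to 100.
#'
#' @param assignments consensus assignment data.frame (`read_id`, `taxon`).
#' @param tax a `taxonomy`.
#' @param total_reads total reads in the data set (>= nrow(assignments)).
#' @param sample sample label stored in the table.
#' @param minority_threshold percent (default 0.5); genus categories below it
#'   merge into "minorities".
#' @return A `genus_table`: data.frame `sample`, `category`, `percent`,
#'   `count`, with attribute `total_reads`. Genus categories are named by the
#'   genus node's name.
#' @export
build_genus_table <- function(assignments, tax, total_reads,
                              sample = "sample",
                              minority_threshold = 0.5) {
  stopifnot(inherits(tax, "taxonomy"))
  if (total_reads <= 0) stop_kefirmg("total_reads must be positive")
  if (total_reads < nrow(assignments))
    stop_kefirmg("total_reads smaller than assignment table")
  taxa <- as.character(assignments$taxon)
  check_ids(tax, setdiff(unique(taxa), UNASSIGNED))

  categorize <- function(tx) {
    if (tx == UNASSIGNED || tx == tax$root_id) return("unassigned")
    g <- ancestor_at_rank(tax, tx, "genus")
    rk <- tax$rank[[tx]]
    if (!is.na(g)) return(tax$name[[g]])
    if (rk %in% c("subspecies", "species", "species_group")) {
      warning("taxon '", tx, "' has rank below genus but no genus ancestor; ",
              "counted as 'above genus'", call. = FALSE)
    }
    "above genus"
  }
  cat_by_taxon <- vapply(unique(taxa), categorize, character(1))
  cats <- unname(cat_by_taxon[taxa])
  counts <- table(cats)
  df <- data.frame(category = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  extra <- total_reads - nrow(assignments)
  if ("unassigned" %in% df$category) {
    df$count[df$category == "unassigned"] <-
      df$count[df$category == "unassigned"] + extra
  } else {
    df <- rbind(df, data.frame(category = "unassigned", count = extra))
  }
  df$percent <- 100 * df$count / total_reads
  special <- c("above genus", "unassigned")
  minor <- !(df$category %in% special) & df$percent < minority_threshold &
    df$count > 0
  if (any(minor)) {
    m <- data.frame(category = "minorities", count = sum(df$count[minor]),
                    percent = sum(df$percent[minor]))
    df <- rbind(df[!minor, , drop = FALSE], m)
  }
  df <- df[df$count > 0 | df$category == "unassigned", , drop = FALSE]
  df <- df[order(-df$percent, df$category), , drop = FALSE]
  out <- data.frame(sample = sample, category = df$category,
                    percent = df$percent, count = df$count,
                    stringsAsFactors = FALSE)
  attr(out, "total_reads") <- total_reads
  class(out) <- c("genus_table", "data.frame")
  out
}

#' Per-category change between two genus tables (percentage points)
#'
#' @param table_t1,table_t2 `genus_table` objects (or data.frames with
#'   `category` and `percent`); a category absent from one table counts as 0.
#' @return data.frame `category`, `percent_t1`, `percent_t2`, `delta` with
#'   `delta = percent_t2 - percent_t1`.
#' @examples
#' t1 <- data.frame(category = "Bifidobacterium", percent = 17.8)
#' t2 <- data.frame(category = "Bifidobacterium", percent = 25.4)
#' compute_temporal_shift(t1, t2)$delta   # +7.6 points
#' @export
compute_temporal_shift <- function(table_t1, table_t2) {
  cats <- union(table_t1$category, table_t2$category)
  p1 <- table_t1$percent[match(cats, table_t1$category)]
  p2 <- table_t2$percent[match(cats, table_t2$category)]
  p1[is.na(p1)] <- 0
  p2[is.na(p2)] <- 0
  out <- data.frame(category = cats, percent_t1 = p1, percent_t2 = p2,
                    delta = p2 - p1, stringsAsFactors = FALSE)
  out[order(-abs(out$delta), out$category), , drop = FALSE]
}

#' Select genera for fragment-recruitment profiling
#'
#' A genus qualifies when its percentage strictly exceeds
#' `selection_threshold` in at least one of the supplied genus tables
#' (typically one table per sample x classification method). The special
#' categories "above genus", "minorities" and "unassigned" never qualify.
#'
#' @param tables list of `genus_table` objects (or data.frames with
#'   `category`, `percent`).
#' @param selection_threshold percent (default 0.1); strict comparison.
#' @return Sorted character vector of genus category names (possibly empty).
#' @export
select_recruitment_genera <- function(tables, selection_threshold = 0.1) {
  if (length(tables) == 0L) stop_kefirmg("need at least one genus table")
  special <- c("above genus", "minorities", "unassigned")
  hits <- unlist(lapply(tables, function(tb) {
    tb$category[!(tb$category %in% special) &
                  tb$percent > selection_threshold]
  }))
  sort(unique(hits))
}

#' Write a genus table as long-format TSV
#' @param table a `genus_table`.
#' @param path file path.
#' @export
write_genus_table <- function(table, path) {
  write_tsv_schema(
    data.frame(sample = table$sample, category = table$category,
               percent = round(table$percent, 2)),
    path, "genus_table v1")
}
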