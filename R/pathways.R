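# Four-level biosynthetic-potential scoring from per-gene evidence statuses.

#' Gene evidence statuses and pathway calls
#'
#' Per-gene evidence statuses, from strongest to weakest support:
#' `FOUND_COMPLETE` (gene found and fully assembled), `FOUND_PARTIAL` (found
#' but not assembled fully), `NOT_FOUND` (no evidence), `LOSS_OF_FUNCTION`
#' (conclusive evidence of a disrupting mutation, e.g. a nonsense mutation).
#'
#' Pathway calls, ordered `VERY_LIKELY > LIKELY > UNLIKELY > VERY_UNLIKELY`,
#' correspond to the green/yellow/gray/black categories of
#' biosynthetic-potential matrices.
#' @name pathway-levels
NULL

#' @rdname pathway-levels
#' @export
GENE_STATUSES <- c("FOUND_COMPLETE", "FOUND_PARTIAL", "NOT_FOUND",
                   "LOSS_OF_FUNCTION")

#' @rdname pathway-levels
#' @export
PATHWAY_CALLS <- c("VERY_LIKELY", "LIKELY", "UNLIKELY", "VERY_UNLIKELY")

#' Score one pathway from its gene statuses
#'
#' Precedence, strongest evidence first: any `LOSS_OF_FUNCTION` makes the
#' pathway `VERY_UNLIKELY` (a broken gene is conclusive, however complete the
#' rest); otherwise any `NOT_FOUND` gives `UNLIKELY`; otherwise any
#' `FOUND_PARTIAL` gives `LIKELY`; all genes `FOUND_COMPLETE` gives
#' `VERY_LIKELY`.
#'
#' @param statuses non-empty character vector of [GENE_STATUSES] values.
#' @return One of [PATHWAY_CALLS].
#' @examples
#' score_pathway(c("FOUND_COMPLETE", "FOUND_PARTIAL"))        # LIKELY
#' score_pathway(c("FOUND_COMPLETE", "LOSS_OF_FUNCTION"))     # VERY_UNLIKELY
#' @export
score_pathway <- function(statuses) {
  if (length(statuses) == 0L)
    stop_kefirmg("cannot score a pathway with no gene statuses")
  bad <- setdiff(statuses, GENE_STATUSES)
  if (length(bad))
    stop_kefirmg("unknown gene status: ", paste(unique(bad), collapse = ", "))
  if ("LOSS_OF_FUNCTION" %in% statuses) return("VERY_UNLIKELY")
  if ("NOT_FOUND" %in% statuses) return("UNLIKELY")
  if ("FOUND_PARTIAL" %in% statuses) return("LIKELY")
  "VERY_LIKELY"
}

#' Score every (taxon, pathway) cell of a status table
#'
#' Applies [score_pathway()] element-wise over a long-format status table. A
#' gene defined for a pathway but missing from the table defaults to
#' `NOT_FOUND` (absence of evidence), with a warning naming the gap count.
#'
#' @param statuses data.frame `taxon`, `pathway`, `gene`, `status`.
#' @param definitions data.frame `pathway`, `gene` listing each pathway's
#'   required genes.
#' @param taxa taxa to score (default: those present in `statuses`).
#' @return data.frame `taxon`, `pathway`, `call` (one row per combination),
#'   calls as a factor ordered by [PATHWAY_CALLS].
#' @export
score_matrix <- function(statuses, definitions, taxa = NULL) {
  if (!all(c("pathway", "gene") %in% names(definitions)))
    stop_kefirmg("definitions need 'pathway' and 'gene' columns")
  if (nrow(definitions) == 0L) stop_kefirmg("no pathway definitions given")
  undef <- setdiff(unique(statuses$pathway), unique(definitions$pathway))
  if (length(undef))
    stop_kefirmg("status table references undefined pathway(s): ",
                 paste(undef, collapse = ", "))
  taxa <- taxa %||% unique(as.character(statuses$taxon))
  pathways <- unique(as.character(definitions$pathway))
  grid <- expand.grid(taxon = taxa, pathway = pathways,
                      stringsAsFactors = FALSE)
  n_missing <- 0L
  grid$call <- vapply(seq_len(nrow(grid)), function(i) {
    genes <- definitions$gene[definitions$pathway == grid$pathway[i]]
    sub <- statuses[statuses$taxon == grid$taxon[i] &
                      statuses$pathway == grid$pathway[i], , drop = FALSE]
    st <- sub$status[match(genes, sub$gene)]
    n_missing <<- n_missing + sum(is.na(st))
    st[is.na(st)] <- "NOT_FOUND"
    score_pathway(st)
  }, character(1))
  if (n_missing > 0L)
    warning(n_missing, " (taxon, pathway, gene) cell(s) had no status; ",
            "defaulted to NOT_FOUND", call. = FALSE)
  grid$call <- factor(grid$call, levels = PATHWAY_CALLS)
  grid
}

#' Read pathway definitions / gene status tables from TSV
#'
#' Definitions: columns `pathway`, `gene`. Statuses: columns `taxon`,
#' `pathway`, `gene`, `status`.
#' @param path file path.
#' @return data.frame.
#' @export
read_pathway_definitions <- function(path) {
  df <- read_tsv_schema(path)
  if (anyDuplicated(df[c("pathway", "gene")]))
    stop_kefirmg("duplicate gene within a pathway definition")
  df
}

#' @rdname read_pathway_definitions
#' @export
read_gene_statuses <- function(path) read_tsv_schema(path)
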