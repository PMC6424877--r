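#' Rank labels recognised by the taxonomy model
#'
#' Ordered from the root down. `species_group` sits between genus and species,
#' matching how infra-generic groups are ranked in the NCBI taxonomy;
#' `no_rank` nodes may appear anywhere and are transparent to rank queries.
#' @export
TAXONOMY_RANKS <- c("root", "domain", "phylum", "class", "order", "family",
                    "genus", "species_group", "species", "subspecies",
                    "no_rank")

#' Build a taxonomy from a node table
#'
#' Constructs a rooted taxonomy from records of the form
#' (taxon_id, parent_id, rank, name). The root is the single node whose
#' `parent_id` equals its own `taxon_id`. Taxon ids are opaque strings, so
#' numeric NCBI ids and name-keyed synthetic taxa both work.
#'
#' @param nodes data.frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name` (name optional; defaults to the id).
#' @return An object of class `taxonomy`: a list with the node table plus
#'   named lookup vectors `parent`, `rank`, `name` and the `root_id`.
#' @examples
#' tax <- load_taxonomy(data.frame(
#'   taxon_id  = c("r", "g", "s"),
#'   parent_id = c("r", "r", "g"),
#'   rank      = c("root", "genus", "species")))
#' lca(tax, c("s", "g"))
#' @export
load_taxonomy <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  req <- c("taxon_id", "parent_id", "rank")
  if (!all(req %in% names(nodes)))
    stop_kefirmg("taxonomy table needs columns: ", paste(req, collapse = ", "))
  if (nrow(nodes) == 0L) stop_kefirmg("taxonomy table is empty")
  nodes$taxon_id <- as.character(nodes$taxon_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$rank <- as.character(nodes$rank)
  if (is.null(nodes$name)) nodes$name <- nodes$taxon_id
  nodes$name <- as.character(nodes$name)

  dup <- nodes$taxon_id[duplicated(nodes$taxon_id)]
  if (length(dup))
    stop_kefirmg("duplicate taxon_id: ", paste(unique(dup), collapse = ", "))
  bad_rank <- setdiff(unique(nodes$rank), TAXONOMY_RANKS)
  if (length(bad_rank))
    stop_kefirmg("unknown rank label: ", paste(bad_rank, collapse = ", "))

  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  roots <- nodes$taxon_id[nodes$taxon_id == nodes$parent_id]
  if (length(roots) != 1L)
    stop_kefirmg("taxonomy must have exactly one root (parent_id == taxon_id); found ",
                 length(roots))
  missing <- setdiff(nodes$parent_id, nodes$taxon_id)
  if (length(missing)) {
    orphan <- nodes$taxon_id[nodes$parent_id %in% missing][1L]
    stop_kefirmg("node '", orphan, "' references missing parent '",
                 nodes$parent_id[nodes$taxon_id == orphan], "'")
  }

  tax <- structure(
    list(nodes = nodes,
         parent = parent,
         rank = stats::setNames(nodes$rank, nodes$taxon_id),
         name = stats::setNames(nodes$name, nodes$taxon_id),
         root_id = roots),
    class = "taxonomy")

  # cycle / reachability check: every node must reach the root in <= n steps
  n <- nrow(nodes)
  for (id in nodes$taxon_id) {
    cur <- id
    for (step in seq_len(n + 1L)) {
      if (cur == roots) break
      cur <- parent[[cur]]
      if (step > n) stop_kefirmg("cycle detected involving node '", id, "'")
    }
    if (cur != roots) stop_kefirmg("node '", id, "' does not reach the root")
  }
  tax
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " nodes, root = '", x$root_id, "'\n",
      sep = "")
  invisible(x)
}

#' Read / write a taxonomy TSV
#'
#' Four tab-separated columns `taxon_id`, `parent_id`, `rank`, `name` with a
#' header row; UTF-8. `write_taxonomy()` round-trips with `read_taxonomy()`.
#' @param path file path.
#' @return `read_taxonomy()` a `taxonomy`; `write_taxonomy()` the path,
#'   invisibly.
#' @export
read_taxonomy <- function(path) load_taxonomy(read_tsv_schema(path))

#' @rdname read_taxonomy
#' @param tax a `taxonomy` object.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy"))
  write_tsv_schema(tax$nodes[, c("taxon_id", "parent_id", "rank", "name")],
                   path, "taxonomy v1")
}

check_ids <- function(tax, ids) {
  unknown <- setdiff(ids, names(tax$parent))
  if (length(unknown))
    stop_kefirmg("unknown taxon id: ", paste(unknown, collapse = ", "))
}

#' Path from a node up to the root
#'
#' @param tax a `taxonomy`.
#' @param id taxon id.
#' @return Character vector of taxon ids ordered root first, `id` last.
#' @export
root_path <- function(tax, id) {
  check_ids(tax, id)
  path <- character()
  cur <- id
  while (TRUE) {
    path <- c(cur, path)
    if (cur == tax$root_id) break
    cur <- tax$parent[[cur]]
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxon — the
#' placement a naive LCA read classifier gives a read whose alignment hits
#' span those taxa.
#'
#' @param tax a `taxonomy`.
#' @param ids non-empty character vector of taxon ids (duplicates allowed).
#' @return A single taxon id.
#' @export
lca <- function(tax, ids) {
  ids <- unique(as.character(ids))
  if (length(ids) == 0L) stop_kefirmg("lca() needs at least one taxon")
  check_ids(tax, ids)
  common <- root_path(tax, ids[1L])
  for (id in ids[-1L]) {
    p <- root_path(tax, id)
    k <- min(length(common), length(p))
    eq <- common[seq_len(k)] == p[seq_len(k)]
    keep <- if (all(eq)) k else which(!eq)[1L] - 1L
    common <- common[seq_len(keep)]
  }
  common[length(common)]
}

#' Nearest ancestor-or-self at a given rank
#'
#' Walks the root path from `id` upwards and returns the first node carrying
#' exactly the requested rank. `no_rank` nodes are transparent (skipped).
#'
#' @param tax a `taxonomy`.
#' @param id taxon id.
#' @param rank one of [TAXONOMY_RANKS] (except `no_rank`).
#' @return The matching taxon id, or `NA_character_` if the root path holds no
#'   node of that rank.
#' @export
ancestor_at_rank <- function(tax, id, rank) {
  if (!rank %in% TAXONOMY_RANKS || rank == "no_rank")
    stop_kefirmg("unknown or unqueryable rank label: '", rank, "'")
  check_ids(tax, id)
  cur <- id
  while (TRUE) {
    if (tax$rank[[cur]] == rank) return(cur)
    if (cur == tax$root_id) return(NA_character_)
    cur <- tax$parent[[cur]]
  }
}

#' Is `a` an ancestor-or-self of `b`?
#'
#' @param tax a `taxonomy`.
#' @param a,b taxon ids.
#' @return `TRUE` iff `a` lies on `b`'s root path (reflexive).
#' @export
is_ancestor <- function(tax, a, b) {
  check_ids(tax, c(a, b))
  cur <- b
  while (TRUE) {
    if (cur == a) return(TRUE)
    if (cur == tax$root_id) return(FALSE)
    cur <- tax$parent[[cur]]
  }
}

# depth (root = 0); used for ordering in min-support push-up
node_depth <- function(tax, ids) {
  vapply(ids, function(id) length(root_path(tax, id)) - 1L, integer(1))
}
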