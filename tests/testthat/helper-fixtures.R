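# Fixture builders and independent brute-force oracles shared by the suite.

# A minimal linear taxonomy: root -> ... -> species, one node per rank.
chain_taxonomy <- function() {
  load_taxonomy(data.frame(
    taxon_id  = c("root", "dom", "fam", "gen", "sp1", "sp2"),
    parent_id = c("root", "root", "dom", "fam", "gen", "gen"),
    rank      = c("root", "domain", "family", "genus", "species", "species")))
}

# Random rooted taxonomy of n nodes: each new node attaches to a uniformly
# chosen existing node with a random rank.
random_taxonomy <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- c("root", sprintf("t%03d", seq_len(n - 1L)))
    parent <- c("root",
                vapply(seq_len(n - 1L),
                       function(i) ids[sample.int(i, 1L)], character(1)))
    rank <- c("root", sample(setdiff(TAXONOMY_RANKS, "root"), n - 1L,
                             replace = TRUE))
  })
  load_taxonomy(data.frame(taxon_id = ids, parent_id = parent, rank = rank))
}

# Brute-force LCA: intersect complete ancestor sets, pick the deepest member.
oracle_lca <- function(tax, ids) {
  paths <- lapply(ids, function(id) root_path(tax, id))
  common <- Reduce(intersect, paths)
  depth <- vapply(common, function(x) length(root_path(tax, x)), integer(1))
  common[which.max(depth)]
}

# Brute-force two-pass hit filter (floors first, then top-percent window).
oracle_filter <- function(hits, params) {
  pass <- hits[hits$bitscore >= params$min_score &
                 hits$evalue <= params$max_expected, , drop = FALSE]
  if (nrow(pass) == 0L) return(pass)
  best <- -Inf
  for (i in seq_len(nrow(pass))) best <- max(best, pass$bitscore[i])
  keep <- logical(nrow(pass))
  for (i in seq_len(nrow(pass)))
    keep[i] <- pass$bitscore[i] >= (1 - params$top_percent / 100) * best
  pass[keep, , drop = FALSE]
}

# Independent sort-and-scan assembly statistics.
oracle_stats <- function(lengths) {
  sl <- sort(lengths, decreasing = TRUE)
  total <- sum(sl)
  run <- 0
  l50 <- NA_integer_
  for (i in seq_along(sl)) {
    run <- run + sl[i]
    if (run >= total / 2) { l50 <- i; break }
  }
  list(total_size = total, n_contigs = length(sl), longest = sl[1L],
       mean = total / length(sl), median = stats::median(sl),
       n50 = sl[l50], l50 = l50)
}

# A hit row in the native layout with convenient defaults.
make_hit <- function(read_id = "r1", subject_id = "s", subject_taxon = "sp1",
                     percent_identity = 99, align_length = 200,
                     query_length = 200, bitscore = 150, evalue = 1e-10,
                     subject_start = 1, subject_end = 200) {
  data.frame(read_id = read_id, subject_id = subject_id,
             subject_taxon = subject_taxon,
             percent_identity = percent_identity,
             align_length = align_length, query_length = query_length,
             bitscore = bitscore, evalue = evalue,
             subject_start = subject_start, subject_end = subject_end,
             stringsAsFactors = FALSE)
}

# Single-genome reference db for presence-call scenarios.
single_genome_db <- function(length = 200000) {
  reference_db(data.frame(genome_id = "gX", species = "s_o_oeni",
                          genus = "g_oenococcus", length = length))
}

# Recruited-read table placed directly (bypassing alignment) for
# presence-call scenarios.
make_recruited <- function(n, genome = "gX", positions, identities) {
  data.frame(read_id = sprintf("r%05d", seq_len(n)), genome_id = genome,
             position = positions, genome_position = positions,
             identity = identities, stringsAsFactors = FALSE)
}
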