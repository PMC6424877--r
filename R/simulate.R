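# Deterministic synthetic communities with planted ground truth.
#
# Every generator is a pure function of (parameters, seed): RNG use is scoped
# with withr::with_seed so global RNG state is never touched.

#' Define a synthetic community
#'
#' A community is a set of reference genomes with relative abundances and a
#' per-member read-identity model. A member whose identity model sits near
#' 100% emulates a species whose genome is in the reference database; a
#' member with a lower model (say mean 77, sd 3) emulates a novel relative —
#' reads that align to the reference of a related species in a uniform
#' 70–85% identity band.
#'
#' @param members data.frame with columns `genome_id`, `species` (taxon id),
#'   `abundance` (fractions summing to 1), `identity_mean`, `identity_sd`
#'   (percent), `genome_length` (bp, >= 10000).
#' @return A validated `community_profile` object.
#' @export
community_profile <- function(members) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  req <- c("genome_id", "species", "abundance", "identity_mean",
           "identity_sd", "genome_length")
  miss <- setdiff(req, names(members))
  if (length(miss))
    stop_kefirmg("community members missing columns: ",
                 paste(miss, collapse = ", "))
  if (abs(sum(members$abundance) - 1) > 1e-9)
    stop_kefirmg("member abundances must sum to 1 (got ",
                 sum(members$abundance), ")")
  if (any(members$identity_mean <= 50 | members$identity_mean > 100))
    stop_kefirmg("identity means must lie in (50, 100]")
  if (any(members$genome_length < 10000))
    stop_kefirmg("genome lengths must be >= 10000 bp")
  if (anyDuplicated(members$genome_id))
    stop_kefirmg("duplicate genome_id among members")
  structure(members, class = c("community_profile", "data.frame"))
}

#' Simulate reads from a community with a truth table
#'
#' Read counts per genome are multinomial in the abundances; read lengths are
#' drawn from a normal(`length_mean`, `length_sd`) truncated to
#' `length_range` (defaults give a median near 205 bp over a 20–260 bp
#' range, the shape typical of quality-trimmed short-read data sets); start
#' positions are uniform within the genome; each read carries a planted
#' `true_identity` drawn from its member's identity model truncated to
#' (50, 100].
#'
#' @param profile a [community_profile()].
#' @param n number of reads (>= 1).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param length_mean,length_sd,length_range read-length model (bp).
#' @return list with `reads` (read_id, genome_id, start, length,
#'   true_identity) and `truth` (read_id, genome_id, species, true_identity).
#' @export
generate_reads <- function(profile, n, seed, length_mean = 205,
                           length_sd = 30, length_range = c(20, 260)) {
  stopifnot(inherits(profile, "community_profile"))
  if (n < 1) stop_kefirmg("n must be >= 1")
  withr::with_seed(seed, {
    idx <- sample.int(nrow(profile), n, replace = TRUE,
                      prob = profile$abundance)
    len <- round(rtruncnorm(n, length_mean, length_sd,
                            length_range[1], length_range[2]))
    len <- pmin(pmax(len, length_range[1]), length_range[2])
    glen <- profile$genome_length[idx]
    start <- floor(stats::runif(n, 1, glen - len + 1))
    ident <- rtruncnorm(n, profile$identity_mean[idx],
                        profile$identity_sd[idx], 50, 100)
    ident <- pmin(ident, 100)
    ident[ident <= 50] <- 50 + 1e-6
    reads <- data.frame(
      read_id = sprintf("read_%06d", seq_len(n)),
      genome_id = profile$genome_id[idx],
      start = start, length = len, true_identity = ident,
      stringsAsFactors = FALSE)
  })
  truth <- data.frame(read_id = reads$read_id, genome_id = reads$genome_id,
                      species = profile$species[match(reads$genome_id,
                                                      profile$genome_id)],
                      true_identity = reads$true_identity,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate an alignment hit table for synthetic reads
#'
#' Each read receives a top hit to its source genome at its planted identity,
#' plus 0–3 decoy hits to other genomes of the same genus (when any exist)
#' at an identity lowered by Uniform(5, 20) percentage points — enough spread
#' that top-percent filtering keeps some decoys and drops others. Decoys
#' that would fall to 50% identity or below are not emitted. Bitscore and
#' E-value are monotone surrogates, `bitscore = align_length *
#' (2*identity/100 - 1)` and `evalue = 10^(-bitscore/10)`: within a read,
#' order and thresholds behave like alignment statistics, but absolute
#' values are not calibrated to any aligner.
#'
#' @param reads the `reads` table from [generate_reads()].
#' @param db a [reference_db()] containing every source genome (plus any
#'   decoy genomes).
#' @param seed integer seed.
#' @param coverage_range alignment length as a fraction of read length,
#'   drawn uniformly from this interval (default `c(1, 1)`: full-length
#'   alignments; widen to exercise query-coverage filters).
#' @return A hit data.frame in the native layout (see [read_hits()]).
#' @export
generate_alignment_hits <- function(reads, db, seed,
                                    coverage_range = c(1, 1)) {
  stopifnot(inherits(db, "reference_db"))
  missing <- setdiff(unique(reads$genome_id), db$genome_id)
  if (length(missing))
    stop_kefirmg("read source genome(s) absent from reference db: ",
                 paste(missing, collapse = ", "))
  n <- nrow(reads)
  withr::with_seed(seed, {
    frac <- stats::runif(n, coverage_range[1], coverage_range[2])
    alen <- pmax(1L, round(reads$length * frac))
    top <- data.frame(
      read_id = reads$read_id, subject_id = reads$genome_id,
      percent_identity = reads$true_identity,
      align_length = alen, query_length = reads$length,
      subject_start = reads$start,
      subject_end = reads$start + alen - 1L,
      stringsAsFactors = FALSE)
    len_of <- stats::setNames(db$length, db$genome_id)
    sibs_of <- lapply(stats::setNames(db$genome_id, db$genome_id),
                      function(g) db$genome_id[db$genus ==
                        db$genus[db$genome_id == g] & db$genome_id != g])
    decoy_n <- sample(0:3, n, replace = TRUE)
    # expand to one candidate row per (read, same-genus sibling), give each a
    # random priority, and keep the decoy_n highest-priority sibs per read
    n_sibs <- lengths(sibs_of)[reads$genome_id]
    idx <- rep.int(seq_len(n), n_sibs)
    cand <- data.table(
      i = idx,
      subject_id = unlist(sibs_of[reads$genome_id], use.names = FALSE))
    if (nrow(cand)) {
      cand[, prio := stats::runif(.N)]
      setorder(cand, i, prio)
      cand <- cand[, rk := seq_len(.N), by = i][rk <= decoy_n[i]]
      cand[, percent_identity :=
             reads$true_identity[i] - stats::runif(.N, 5, 20)]
      cand <- cand[percent_identity > 50]
    }
    decoys <- if (nrow(cand)) {
      dlen <- unname(len_of[cand$subject_id])
      dstart <- floor(stats::runif(nrow(cand), 1, dlen - alen[cand$i] + 1))
      data.frame(
        read_id = reads$read_id[cand$i], subject_id = cand$subject_id,
        percent_identity = cand$percent_identity,
        align_length = alen[cand$i], query_length = reads$length[cand$i],
        subject_start = dstart, subject_end = dstart + alen[cand$i] - 1L,
        stringsAsFactors = FALSE)
    } else NULL
    hits <- rbind(top, decoys)
  })
  hits$bitscore <- hits$align_length * (2 * hits$percent_identity / 100 - 1)
  hits$evalue <- 10^(-hits$bitscore / 10)
  sp <- stats::setNames(db$species, db$genome_id)
  hits$subject_taxon <- unname(sp[hits$subject_id])
  hits <- hits[order(hits$read_id, -hits$bitscore), , drop = FALSE]
  rownames(hits) <- NULL
  validate_hits(hits[, HIT_COLUMNS])
}

#' Describe a synthetic classifier
#'
#' @param tool tool name.
#' @param assignment_probability probability that the tool assigns a read at
#'   all.
#' @param blind_spot taxa (any rank) the tool's database lacks: reads whose
#'   true species falls under a blind-spot taxon are always unassigned —
#'   emulating, e.g., a classifier database holding no sequences of a genus.
#' @param misassignment_rate probability that an assigned read gets a
#'   substitute (wrong) species.
#' @param low_identity_threshold reads with planted identity below this are
#'   assigned to their genus rather than their species (a divergent read is
#'   rarely placed at species level).
#' @return A `tool_profile` object.
#' @export
tool_profile <- function(tool, assignment_probability,
                         blind_spot = character(),
                         misassignment_rate = 0,
                         low_identity_threshold = 90) {
  if (assignment_probability < 0 || assignment_probability > 1 ||
      misassignment_rate < 0 || misassignment_rate > 1)
    stop_kefirmg("probabilities must lie in [0, 1]")
  structure(list(tool = tool,
                 assignment_probability = assignment_probability,
                 blind_spot = blind_spot,
                 misassignment_rate = misassignment_rate,
                 low_identity_threshold = low_identity_threshold),
            class = "tool_profile")
}

#' Simulate per-tool read assignments
#'
#' For every tool profile: reads under a blind-spot taxon are [UNASSIGNED];
#' otherwise, with the tool's assignment probability, the read is assigned
#' its true species (or its genus when the planted identity is low), with a
#' small misassignment probability substituting a random other species.
#'
#' @param truth the `truth` table from [generate_reads()].
#' @param profiles list of [tool_profile()]s.
#' @param tax a `taxonomy` containing all species in `truth`.
#' @param seed integer seed.
#' @return Named list (one per tool) of data.frames `read_id`, `taxon`.
#' @export
generate_tool_assignments <- function(truth, profiles, tax, seed) {
  stopifnot(inherits(tax, "taxonomy"))
  check_ids(tax, unique(truth$species))
  species_pool <- tax$nodes$taxon_id[tax$nodes$rank == "species"]
  out <- list()
  withr::with_seed(seed, {
    uniq_sp <- unique(truth$species)
    genus_of <- vapply(uniq_sp, function(s) {
      g <- ancestor_at_rank(tax, s, "genus")
      if (is.na(g)) s else g
    }, character(1))
    for (p in profiles) {
      stopifnot(inherits(p, "tool_profile"))
      n <- nrow(truth)
      blind_sp <- uniq_sp[vapply(uniq_sp, function(s)
        any(vapply(p$blind_spot, function(b) is_ancestor(tax, b, s),
                   logical(1))), logical(1))]
      blind <- truth$species %in% blind_sp
      assigned <- stats::runif(n) < p$assignment_probability & !blind
      low <- truth$true_identity < p$low_identity_threshold
      taxon <- rep(UNASSIGNED, n)
      taxon[assigned] <- ifelse(low[assigned],
                                genus_of[truth$species[assigned]],
                                truth$species[assigned])
      wrong <- assigned & stats::runif(n) < p$misassignment_rate
      if (any(wrong) && length(species_pool) > 1L) {
        for (i in which(wrong)) {
          alt <- setdiff(species_pool, truth$species[i])
          taxon[i] <- alt[sample.int(length(alt), 1L)]
        }
      }
      out[[p$tool]] <- data.frame(read_id = truth$read_id, taxon = taxon,
                                  stringsAsFactors = FALSE)
    }
  })
  out
}

#' Simulate a contig set with known true statistics
#'
#' Lengths follow a rounded lognormal. The returned `true_stats` are
#' computed here by a direct sort-and-scan pass, independent of
#' [compute_stats()], so the two can be cross-checked.
#'
#' @param n number of contigs (>= 1).
#' @param seed integer seed.
#' @param meanlog,sdlog lognormal parameters of the length distribution
#'   (defaults give a few-kbp-scale assembly).
#' @param min_len floor applied to sampled lengths (bp).
#' @return list with `contigs` (contig_id, length) and `true_stats`
#'   (total_size, n_contigs, longest, mean, median, n50, l50).
#' @export
generate_contig_set <- function(n, seed, meanlog = 7.8, sdlog = 0.9,
                                min_len = 500) {
  if (n < 1) stop_kefirmg("n must be >= 1")
  withr::with_seed(seed, {
    len <- pmax(min_len, round(stats::rlnorm(n, meanlog, sdlog)))
  })
  contigs <- data.frame(contig_id = sprintf("contig_%05d", seq_len(n)),
                        length = len, stringsAsFactors = FALSE)
  # independent sort-and-scan statistics
  sl <- sort(len, decreasing = TRUE)
  total <- sum(sl)
  running <- 0
  i50 <- 0L
  for (i in seq_along(sl)) {
    running <- running + sl[i]
    if (running >= total / 2) { i50 <- i; break }
  }
  true_stats <- list(total_size = total, n_contigs = n, longest = sl[1L],
                     mean = total / n, median = stats::median(sl),
                     n50 = sl[i50], l50 = i50)
  list(contigs = contigs, true_stats = true_stats)
}

#' Simulate a contaminated genome bin with curation truth
#'
#' Plants a bin targeted at one genus containing: contigs mapped to
#' target-genus species (kept), unmapped contigs (kept), contaminant contigs
#' mapped to off-target species — some carrying the target-genus-similarity
#' flag (kept) and some not (discarded) — plus rRNA-annotated contigs inside
#' and outside the bin. The truth lists the contigs a correct curation
#' retains after purification and after rRNA rescue.
#'
#' @param seed integer seed.
#' @param tax a `taxonomy`; defaults to [example_taxonomy()].
#' @param target_genus genus taxon id (default `"g_oenococcus"` of the
#'   example taxonomy).
#' @param n_target,n_unmapped,n_contam_plain,n_contam_flagged,n_rrna_out
#'   planted contig counts per class.
#' @return list with `contigs` (full contig table), `bin` (bin_id, members,
#'   target_genus), `truth_purified` and `truth_final` (curated member ids),
#'   and `tax`.
#' @export
generate_bin_fixture <- function(seed, tax = example_taxonomy(),
                                 target_genus = "g_oenococcus",
                                 n_target = 15, n_unmapped = 5,
                                 n_contam_plain = 5, n_contam_flagged = 3,
                                 n_rrna_out = 2) {
  check_ids(tax, target_genus)
  in_genus <- tax$nodes$taxon_id[tax$nodes$rank == "species" &
    vapply(tax$nodes$taxon_id, function(s) is_ancestor(tax, target_genus, s),
           logical(1))]
  off_genus <- setdiff(tax$nodes$taxon_id[tax$nodes$rank == "species"],
                       in_genus)
  if (!length(in_genus) || !length(off_genus))
    stop_kefirmg("taxonomy needs species inside and outside the target genus")
  n_bin <- n_target + n_unmapped + n_contam_plain + n_contam_flagged
  withr::with_seed(seed, {
    lens <- pmax(1001L, round(stats::rlnorm(n_bin + n_rrna_out, 8.2, 0.7)))
    map_target <- sample(in_genus, n_target, replace = TRUE)
    map_contam <- sample(off_genus, n_contam_plain + n_contam_flagged,
                         replace = TRUE)
  })
  ids <- sprintf("bin_contig_%03d", seq_len(n_bin + n_rrna_out))
  contigs <- data.frame(
    contig_id = ids,
    length = lens,
    mapped_species = c(map_target, rep(NA_character_, n_unmapped),
                       map_contam, rep(NA_character_, n_rrna_out)),
    target_similarity = c(rep(FALSE, n_target + n_unmapped + n_contam_plain),
                          rep(TRUE, n_contam_flagged),
                          rep(FALSE, n_rrna_out)),
    rrna_genus = c(rep(NA_character_, n_bin), rep(target_genus, n_rrna_out)),
    stringsAsFactors = FALSE)
  members <- ids[seq_len(n_bin)]
  truth_purified <- ids[c(seq_len(n_target + n_unmapped),
                          n_target + n_unmapped + n_contam_plain +
                            seq_len(n_contam_flagged))]
  truth_final <- c(truth_purified, ids[n_bin + seq_len(n_rrna_out)])
  list(contigs = contig_set(contigs),
       bin = list(bin_id = "bin_1", members = members,
                  target_genus = target_genus),
       truth_purified = truth_purified, truth_final = truth_final,
       tax = tax)
}

#' Simulate a gene-status table with expected pathway calls
#'
#' Statuses are sampled from the four evidence levels with the given
#' probabilities; the expected call for each (taxon, pathway) is computed by
#' an explicit worst-status precedence lookup, independent of
#' [score_pathway()]'s branch logic.
#'
#' @param definitions data.frame `pathway`, `gene` (non-empty).
#' @param taxa character vector of taxa.
#' @param seed integer seed.
#' @param probs sampling probabilities over [GENE_STATUSES].
#' @return list with `statuses` (taxon, pathway, gene, status) and
#'   `expected` (taxon, pathway, call).
#' @export
generate_gene_status_table <- function(definitions, taxa, seed,
                                       probs = c(0.55, 0.2, 0.2, 0.05)) {
  if (nrow(definitions) == 0L) stop_kefirmg("no pathway definitions given")
  grid <- merge(expand.grid(taxon = taxa,
                            pathway = unique(definitions$pathway),
                            stringsAsFactors = FALSE),
                definitions, by = "pathway")
  grid <- grid[order(grid$taxon, grid$pathway, grid$gene), , drop = FALSE]
  withr::with_seed(seed, {
    grid$status <- sample(GENE_STATUSES, nrow(grid), replace = TRUE,
                          prob = probs)
  })
  # expected call = worst evidence level present, via rank lookup
  sev <- match(grid$status, GENE_STATUSES)   # 1 best .. 4 worst
  agg <- stats::aggregate(sev, by = list(taxon = grid$taxon,
                                         pathway = grid$pathway), FUN = max)
  expected <- data.frame(taxon = agg$taxon, pathway = agg$pathway,
                         call = PATHWAY_CALLS[agg$x],
                         stringsAsFactors = FALSE)
  rownames(grid) <- NULL
  list(statuses = grid[, c("taxon", "pathway", "gene", "status")],
       expected = expected)
}

#' Write synthetic reads to disk
#'
#' Writes either the lengths-only TSV dialect (read_id, genome_id, start,
#' length, true_identity) or a FASTA of placeholder sequences (random bases
#' of the right lengths — the simulator models identity as a scalar, not by
#' mutating sequence).
#'
#' @param reads the `reads` table from [generate_reads()].
#' @param path output file.
#' @param format `"tsv"` or `"fasta"`.
#' @param seed seed for placeholder bases (FASTA only).
#' @export
write_reads <- function(reads, path, format = c("tsv", "fasta"), seed = 1) {
  format <- match.arg(format)
  if (format == "tsv") return(write_tsv_schema(reads, path, "reads v1"))
  withr::with_seed(seed, {
    lines <- character(2L * nrow(reads))
    lines[c(TRUE, FALSE)] <- paste0(">", reads$read_id)
    lines[c(FALSE, TRUE)] <- vapply(reads$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  })
  writeLines(lines, path)
  invisible(path)
}
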