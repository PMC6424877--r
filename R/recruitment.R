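#' Reference genome database for fragment recruitment
#'
#' Holds the genomes reads are recruited against, in a fixed concatenation
#' order with cumulative base-pair offsets so multi-genome plots (e.g. all
#' genomes of one genus laid end to end) share one x-axis.
#'
#' @param genomes data.frame with columns `genome_id`, `species`, `genus`,
#'   `length` (bp). Concatenation order = row order.
#' @return An object of class `reference_db` (the table plus an `offset`
#'   column: bp preceding each genome).
#' @export
reference_db <- function(genomes) {
  genomes <- as.data.frame(genomes, stringsAsFactors = FALSE)
  req <- c("genome_id", "species", "genus", "length")
  miss <- setdiff(req, names(genomes))
  if (length(miss))
    stop_kefirmg("reference table missing columns: ",
                 paste(miss, collapse = ", "))
  if (anyDuplicated(genomes$genome_id))
    stop_kefirmg("duplicate genome_id in reference table")
  if (any(genomes$length < 1)) stop_kefirmg("genome lengths must be >= 1")
  genomes$genome_id <- as.character(genomes$genome_id)
  genomes$offset <- cumsum(c(0, utils::head(genomes$length, -1L)))
  structure(genomes, class = c("reference_db", "data.frame"))
}

#' Parameters for fragment recruitment and presence calling
#'
#' * `min_identity`, `min_query_coverage` — the recruitment filters (percent;
#'   defaults 60/60).
#' * `pos_bin_size`, `id_bin_size` — histogram bin sizes for recruitment
#'   matrices (bp / percent identity; defaults 5000 / 1).
#' * `high_identity_floor` — identity above which a read counts as
#'   "near-identical" for breadth (default 95).
#' * `novel_band` — identity interval typical of an unsequenced close
#'   relative (default c(70, 90)).
#' * `breadth_min` — minimum fraction of position windows that must hold a
#'   qualifying read (default 0.6).
#' @return An object of class `recruitment_params`.
#' @export
recruitment_params <- function(min_identity = 60, min_query_coverage = 60,
                               pos_bin_size = 5000, id_bin_size = 1,
                               high_identity_floor = 95,
                               novel_band = c(70, 90), breadth_min = 0.6) {
  if (min_identity <= 0 || min_identity > 100)
    stop_kefirmg("min_identity must be in (0, 100]")
  if (pos_bin_size <= 0 || id_bin_size <= 0)
    stop_kefirmg("bin sizes must be positive")
  if (length(novel_band) != 2L || novel_band[1] >= novel_band[2])
    stop_kefirmg("novel_band must be an increasing length-2 interval")
  structure(list(min_identity = min_identity,
                 min_query_coverage = min_query_coverage,
                 pos_bin_size = pos_bin_size, id_bin_size = id_bin_size,
                 high_identity_floor = high_identity_floor,
                 novel_band = novel_band, breadth_min = breadth_min),
            class = "recruitment_params")
}

#' Recruit each read to its single best reference hit
#'
#' Per read: hits below `min_identity` are discarded; among survivors the
#' highest-bitscore hit wins (ties broken by lower E-value, then
#' lexicographic `subject_id`); the read is dropped entirely if that chosen
#' hit's query coverage is below `min_query_coverage`. This
#' identity-filter -> top-hit -> coverage-check order is fixed: checking
#' coverage on any hit other than the chosen top hit would change results.
#' The recruited position is the subject-alignment midpoint in concatenated
#' database coordinates (reverse-strand hits, `subject_start > subject_end`,
#' are normalised by swapping).
#'
#' @param hits hit table (see [read_hits()]); `subject_id` must name genomes
#'   of `db`.
#' @param db a [reference_db()].
#' @param params a [recruitment_params()].
#' @return data.frame `read_id`, `genome_id`, `position` (bp, concatenated),
#'   `genome_position` (bp within the genome), `identity`; at most one row
#'   per read.
#' @export
recruit_top_hits <- function(hits, db, params = recruitment_params()) {
  stopifnot(inherits(db, "reference_db"),
            inherits(params, "recruitment_params"))
  unknown <- setdiff(unique(hits$subject_id), db$genome_id)
  if (length(unknown))
    stop_kefirmg("subject(s) not in reference db: ",
                 paste(utils::head(unknown, 5L), collapse = ", "))
  dt <- as.data.table(hits)
  dt <- dt[percent_identity >= params$min_identity]
  empty <- data.frame(read_id = character(), genome_id = character(),
                      position = numeric(), genome_position = numeric(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (nrow(dt) == 0L) return(empty)
  setorder(dt, read_id, -bitscore, evalue, subject_id)
  top <- dt[, .SD[1L], by = read_id]
  top <- top[pmin(100, 100 * align_length / query_length) >=
               params$min_query_coverage]
  if (nrow(top) == 0L) return(empty)
  lo <- pmin(top$subject_start, top$subject_end)
  hi <- pmax(top$subject_start, top$subject_end)
  mid <- (lo + hi) / 2
  off <- db$offset[match(top$subject_id, db$genome_id)]
  data.frame(read_id = top$read_id, genome_id = top$subject_id,
             position = off + mid, genome_position = mid,
             identity = top$percent_identity, stringsAsFactors = FALSE)
}

#' Genus-level recruitment percentages of all reads
#'
#' For every genus of the reference database: 100 x (reads recruited by any
#' genome of that genus) / `total_reads`. A TOTAL row holds the sum of the
#' genus rows (the overall recruited fraction). Values are returned at full
#' precision; round to two decimals for reporting.
#'
#' @param recruited output of [recruit_top_hits()].
#' @param total_reads total reads in the data set.
#' @param db a [reference_db()].
#' @return data.frame `genus`, `count`, `percent` with one row per genus of
#'   `db` (zeros included) plus a final `TOTAL` row.
#' @export
recruitment_percentages <- function(recruited, total_reads, db) {
  stopifnot(inherits(db, "reference_db"))
  if (total_reads <= 0) stop_kefirmg("total_reads must be positive")
  if (total_reads < nrow(recruited))
    stop_kefirmg("total_reads smaller than the recruited read count")
  genus <- db$genus[match(recruited$genome_id, db$genome_id)]
  counts <- table(factor(genus, levels = unique(db$genus)))
  out <- data.frame(genus = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$count / total_reads
  rbind(out, data.frame(genus = "TOTAL", count = sum(out$count),
                        percent = sum(out$percent)))
}

#' Position-by-identity recruitment matrix
#'
#' Histograms recruited reads on a (position bin, identity bin) grid over the
#' concatenated coordinates of the selected genomes, then normalises counts
#' by the largest bin, giving values between 0 and 1 for plotting. An empty
#' recruitment yields an all-zero matrix (no division by zero).
#'
#' @param recruited output of [recruit_top_hits()].
#' @param db a [reference_db()].
#' @param genomes genome ids to include (default: all of `db`).
#' @param params a [recruitment_params()] (bin sizes).
#' @return An object of class `recruitment_matrix`: list with `counts` and
#'   `normalized` matrices (rows = position bins, columns = identity bins),
#'   `pos_breaks`, `id_breaks`, `genomes` and the genome offsets used.
#' @export
build_matrix <- function(recruited, db, genomes = db$genome_id,
                         params = recruitment_params()) {
  stopifnot(inherits(db, "reference_db"))
  if (length(genomes) == 0L) stop_kefirmg("genome selection is empty")
  unknown <- setdiff(genomes, db$genome_id)
  if (length(unknown))
    stop_kefirmg("unknown genome(s): ", paste(unknown, collapse = ", "))
  sel <- db[match(genomes, db$genome_id), , drop = FALSE]
  sel$sel_offset <- cumsum(c(0, utils::head(sel$length, -1L)))
  span <- sum(sel$length)
  pos_breaks <- seq(0, span + params$pos_bin_size, by = params$pos_bin_size)
  id_breaks <- seq(0, 100, by = params$id_bin_size)
  if (utils::tail(id_breaks, 1L) < 100) id_breaks <- c(id_breaks, 100)
  counts <- matrix(0L, nrow = length(pos_breaks) - 1L,
                   ncol = length(id_breaks) - 1L)
  r <- recruited[recruited$genome_id %in% genomes, , drop = FALSE]
  if (nrow(r)) {
    pos <- sel$sel_offset[match(r$genome_id, sel$genome_id)] +
      r$genome_position
    pi_ <- findInterval(pos, pos_breaks, rightmost.closed = TRUE,
                        left.open = TRUE)
    pi_[pos <= 0] <- 1L
    ii <- findInterval(r$identity, id_breaks, rightmost.closed = TRUE,
                       left.open = TRUE)
    for (k in seq_along(pi_)) counts[pi_[k], ii[k]] <- counts[pi_[k], ii[k]] + 1L
  }
  mx <- max(counts)
  structure(list(counts = counts,
                 normalized = if (mx > 0) counts / mx else counts * 0,
                 pos_breaks = pos_breaks, id_breaks = id_breaks,
                 genomes = sel$genome_id, offsets = sel$sel_offset),
            class = "recruitment_matrix")
}

#' Call species presence from recruitment breadth and identity
#'
#' Quantifies the visual read a recruitment plot gives: a species is
#' `present` when near-identical reads (identity >= `high_identity_floor`)
#' cover at least `breadth_min` of its position windows; it is a
#' `novel_relative` when reads in the `novel_band` identity interval cover
#' that breadth and the median recruited identity falls inside the band —
#' the signature of a related species whose own genome is not in the
#' database; otherwise it is `absent` (including the case of high-identity
#' reads confined to a few conserved regions).
#'
#' @param recruited output of [recruit_top_hits()].
#' @param db a [reference_db()].
#' @param genome genome id to call (windows span this genome).
#' @param params a [recruitment_params()].
#' @return list with `genome`, `species`, `status` (one of `present`,
#'   `novel_relative`, `absent`), and metrics `breadth_high`, `breadth_novel`,
#'   `median_identity`, `n_reads`, plus the thresholds used.
#' @export
call_presence <- function(recruited, db, genome,
                          params = recruitment_params()) {
  stopifnot(inherits(db, "reference_db"))
  i <- match(genome, db$genome_id)
  if (is.na(i)) stop_kefirmg("genome '", genome, "' not in reference db")
  len <- db$length[i]
  n_win <- max(1L, ceiling(len / params$pos_bin_size))
  r <- recruited[recruited$genome_id == genome, , drop = FALSE]
  win <- pmin(n_win, floor(r$genome_position / params$pos_bin_size) + 1L)
  hi <- r$identity >= params$high_identity_floor
  nv <- r$identity >= params$novel_band[1] & r$identity <= params$novel_band[2]
  breadth_high <- length(unique(win[hi])) / n_win
  breadth_novel <- length(unique(win[nv])) / n_win
  med <- if (nrow(r)) stats::median(r$identity) else NA_real_
  status <- if (breadth_high >= params$breadth_min) {
    "present"
  } else if (breadth_novel >= params$breadth_min && !is.na(med) &&
             med >= params$novel_band[1] && med <= params$novel_band[2]) {
    "novel_relative"
  } else {
    "absent"
  }
  list(genome = genome, species = db$species[i], status = status,
       breadth_high = breadth_high, breadth_novel = breadth_novel,
       median_identity = med, n_reads = nrow(r),
       params = list(high_identity_floor = params$high_identity_floor,
                     novel_band = params$novel_band,
                     breadth_min = params$breadth_min,
                     window_bp = params$pos_bin_size))
}

#' Write a recruitment matrix as long-format TSV
#' @param matrix a `recruitment_matrix`.
#' @param path file path.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "recruitment_matrix"))
  idx <- which(matrix$counts >= 0, arr.ind = TRUE)
  df <- data.frame(pos_bin = matrix$pos_breaks[idx[, 1L]],
                   id_bin = matrix$id_breaks[idx[, 2L]],
                   count = matrix$counts[idx],
                   normalized = matrix$normalized[idx])
  df <- df[order(df$pos_bin, df$id_bin), , drop = FALSE]
  write_tsv_schema(df, path, "recruitment_matrix v1")
}
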