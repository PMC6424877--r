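test_that("reference_db computes strictly increasing offsets", {
  db <- example_reference_db()
  expect_equal(db$offset, cumsum(c(0, head(db$length, -1))))
  expect_true(all(diff(db$offset) > 0))
  expect_error(reference_db(data.frame(genome_id = c("a", "a"),
                                       species = "s", genus = "g",
                                       length = 10)), "duplicate")
})

test_that("recruitment drops low-identity and low-coverage reads", {
  db <- single_genome_db()
  # best hit below the 60% identity floor -> unrecruited
  h <- make_hit(subject_id = "gX", percent_identity = 59.9)
  expect_identical(nrow(recruit_top_hits(h, db)), 0L)
  # top hit covers 55% but a weaker hit covers 80%: the coverage check
  # applies to the chosen top hit only, so the read is dropped
  h2 <- rbind(
    make_hit(subject_id = "gX", percent_identity = 95, align_length = 110,
             query_length = 200, bitscore = 200, subject_end = 110),
    make_hit(subject_id = "gX", percent_identity = 80, align_length = 160,
             query_length = 200, bitscore = 150, subject_end = 160))
  expect_identical(nrow(recruit_top_hits(h2, db)), 0L)
  # same hits but top hit covering enough -> recruited at the top hit
  h3 <- h2
  h3$align_length[1] <- 150
  out <- recruit_top_hits(h3, db)
  expect_identical(nrow(out), 1L)
  expect_equal(out$identity, 95)
  expect_error(recruit_top_hits(make_hit(subject_id = "nope"), db),
               "not in reference db")
})

test_that("ties break by E-value then subject id; strand is normalised", {
  db <- reference_db(data.frame(genome_id = c("gA", "gB"),
                                species = c("s1", "s2"),
                                genus = c("g1", "g1"),
                                length = c(10000, 10000)))
  h <- rbind(
    make_hit(subject_id = "gB", bitscore = 100, evalue = 1e-10),
    make_hit(subject_id = "gA", bitscore = 100, evalue = 1e-20))
  expect_identical(recruit_top_hits(h, db)$genome_id, "gA")
  h2 <- rbind(
    make_hit(subject_id = "gB", bitscore = 100, evalue = 1e-10),
    make_hit(subject_id = "gA", bitscore = 100, evalue = 1e-10))
  expect_identical(recruit_top_hits(h2, db)$genome_id, "gA")
  # reverse-strand hit: subject_start > subject_end swaps before midpoint
  rev <- make_hit(subject_id = "gA", subject_start = 300, subject_end = 101)
  expect_equal(recruit_top_hits(rev, db)$genome_position, 200.5)
  # concatenated position adds the genome offset
  fwd_b <- make_hit(subject_id = "gB", subject_start = 101,
                    subject_end = 300)
  expect_equal(recruit_top_hits(fwd_b, db)$position, 10000 + 200.5)
})

test_that("each read is recruited at most once, to its true genome", {
  db <- example_reference_db()
  sim <- generate_reads(example_community(), 5000, seed = 101)
  hits <- generate_alignment_hits(sim$reads, db, seed = 102)
  rec <- recruit_top_hits(hits, db)
  expect_identical(anyDuplicated(rec$read_id), 0L)
  expect_true(all(rec$read_id %in% sim$reads$read_id))
  # reads with planted identity >= 65 have no decoy within 5 points
  # (decoys are at least 5 points lower), so recruitment matches truth
  strong <- sim$truth$read_id[sim$truth$true_identity >= 65]
  m <- match(intersect(rec$read_id, strong), rec$read_id)
  src <- sim$truth$genome_id[match(rec$read_id[m], sim$truth$read_id)]
  expect_identical(rec$genome_id[m], src)
})

test_that("genus percentages divide by all reads and sum to the TOTAL row", {
  db <- example_reference_db()
  none <- recruitment_percentages(
    data.frame(read_id = character(), genome_id = character()), 100, db)
  expect_true(all(none$percent == 0))
  rec <- data.frame(read_id = c("r1", "r2", "r3"),
                    genome_id = c("gen_o_oeni", "gen_o_kitaharae",
                                  "gen_d_bruxellensis"))
  out <- recruitment_percentages(rec, 10, db)
  expect_equal(out$percent[out$genus == "g_oenococcus"], 20)  # 2 genomes, 1 genus
  expect_equal(out$percent[out$genus == "TOTAL"], 30)
  expect_equal(sum(out$percent[out$genus != "TOTAL"]),
               out$percent[out$genus == "TOTAL"])
  expect_error(recruitment_percentages(rec, 0, db), "positive")
  expect_error(recruitment_percentages(rec, 2, db), "smaller")
})

test_that("raising min_identity never increases a genus percentage", {
  db <- example_reference_db()
  sim <- generate_reads(example_community(), 4000, seed = 111)
  hits <- generate_alignment_hits(sim$reads, db, seed = 112)
  p60 <- recruitment_percentages(
    recruit_top_hits(hits, db, recruitment_params(min_identity = 60)),
    4000, db)
  p80 <- recruitment_percentages(
    recruit_top_hits(hits, db, recruitment_params(min_identity = 80)),
    4000, db)
  expect_true(all(p80$percent <= p60$percent + 1e-12))
})

test_that("recruitment matrices histogram correctly and guard emptiness", {
  db <- single_genome_db(20000)
  params <- recruitment_params(pos_bin_size = 5000, id_bin_size = 1)
  # all reads in one cell
  rec <- make_recruited(5, positions = rep(2500, 5),
                        identities = rep(98.5, 5))
  m <- build_matrix(rec, db, params = params)
  expect_equal(max(m$normalized), 1)
  expect_equal(sum(m$counts), 5)
  expect_equal(sum(m$normalized == 1), 1)
  # empty recruitment: zero matrix, no NaN
  m0 <- build_matrix(rec[0, ], db, params = params)
  expect_true(all(m0$counts == 0) && all(m0$normalized == 0))
  expect_false(anyNA(m0$normalized))
  expect_error(build_matrix(rec, db, genomes = character()), "empty")
  expect_error(build_matrix(rec, db, genomes = "zz"), "unknown genome")
  expect_error(build_matrix(rec, db,
                            params = recruitment_params(pos_bin_size = -1)),
               "positive")
})

test_that("matrix counts match a brute-force double-loop histogram", {
  db <- single_genome_db(50000)
  params <- recruitment_params(pos_bin_size = 7000, id_bin_size = 2.5)
  withr::with_seed(121, {
    n <- 400
    rec <- make_recruited(n, positions = stats::runif(n, 1, 50000),
                          identities = stats::runif(n, 55, 100))
  })
  m <- build_matrix(rec, db, params = params)
  brute <- matrix(0L, nrow = nrow(m$counts), ncol = ncol(m$counts))
  for (k in seq_len(nrow(rec))) {
    pi_ <- NA; ii <- NA
    for (b in seq_len(nrow(brute)))
      if (rec$position[k] > m$pos_breaks[b] &&
          rec$position[k] <= m$pos_breaks[b + 1]) pi_ <- b
    for (b in seq_len(ncol(brute)))
      if (rec$identity[k] > m$id_breaks[b] &&
          rec$identity[k] <= m$id_breaks[b + 1]) ii <- b
    brute[pi_, ii] <- brute[pi_, ii] + 1L
  }
  expect_equal(m$counts, brute)
  expect_equal(sum(m$counts), nrow(rec))
  expect_equal(max(m$normalized), 1)
})

test_that("presence calls separate present, novel relative and absent", {
  db <- single_genome_db(200000)   # 40 windows of 5 kb
  n <- 2000
  # present: near-identical reads across the genome
  withr::with_seed(131, {
    pres <- make_recruited(n, positions = stats::runif(n, 1, 200000),
                           identities = pmin(100, stats::rnorm(n, 99, 0.5)))
  })
  cp <- call_presence(pres, db, "gX")
  expect_identical(cp$status, "present")
  expect_gte(cp$breadth_high, 0.6)
  # novel relative: uniform positions, identity band around 77
  withr::with_seed(132, {
    nov <- make_recruited(n, positions = stats::runif(n, 1, 200000),
                          identities = stats::rnorm(n, 77, 3))
  })
  cn <- call_presence(nov, db, "gX")
  expect_identical(cn$status, "novel_relative")
  expect_lt(abs(cn$median_identity - 77), 1.5)
  # absent: perfect identity but confined to 10% of the windows
  withr::with_seed(133, {
    abs_ <- make_recruited(500, positions = stats::runif(500, 1, 20000),
                           identities = rep(100, 500))
  })
  ca <- call_presence(abs_, db, "gX")
  expect_identical(ca$status, "absent")
  # no reads at all: absent with NA median
  c0 <- call_presence(pres[0, ], db, "gX")
  expect_identical(c0$status, "absent")
  expect_true(is.na(c0$median_identity))
  expect_error(call_presence(pres, db, "zz"), "not in reference db")
})

test_that("recruitment and matrix plots render and write files", {
  db <- single_genome_db(20000)
  withr::with_seed(141, {
    rec <- make_recruited(100, positions = stats::runif(100, 1, 20000),
                          identities = stats::runif(100, 60, 100))
  })
  m <- build_matrix(rec, db)
  f <- withr::local_tempfile(fileext = ".png")
  plot_recruitment(m, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  # zero matrix renders without error
  m0 <- build_matrix(rec[0, ], db)
  f0 <- withr::local_tempfile(fileext = ".png")
  expect_no_error(plot_recruitment(m0, f0))
  expect_true(file.size(f0) > 0)
})
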