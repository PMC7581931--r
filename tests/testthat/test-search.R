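loose_params <- function(...) {
  search_params(min_aligned_length = 8, min_percent_identity = 1e-6,
                kmer_size = 8, min_seed_count = 1, ...)
}

test_that("build_index enumerates k-mer postings and excludes N windows", {
  db <- habitat_ref(tibble::tibble(
    sequence_id = "r1", sequence = "ACGTACGTACGTACGT", # 16 nt
    category = "soil", project_id = "p"))
  idx <- build_index(db, kmer_size = 12)
  expect_equal(nrow(idx$postings), 5) # 16 - 12 + 1

  dbN <- habitat_ref(tibble::tibble(
    sequence_id = "r1", sequence = paste(rep("ACGTN", 6), collapse = ""),
    category = "soil", project_id = "p"))
  expect_equal(nrow(build_index(dbN, kmer_size = 12)$postings), 0)

  db2 <- habitat_ref(tibble::tibble(
    sequence_id = c("r1", "r2"), sequence = "ACGTAAGGCTTCAGTC", # non-periodic
    category = "soil", project_id = "p"))
  idx2 <- build_index(db2, kmer_size = 12)
  expect_true(all(table(idx2$postings$kmer) == 2))

  expect_error(build_index(db, kmer_size = 6), "8")
})

test_that("align_pair recovers identity and single-mismatch arithmetic", {
  withr::with_seed(5, {
    s200 <- random_seq(200)
    hit <- align_pair(s200, s200, search_params())
    expect_equal(hit$percent_identity, 100)
    expect_equal(hit$aligned_length, 200L)
    expect_equal(hit$score, 200)

    src <- random_seq(150)
    q <- src
    old <- substr(q, 75, 75)
    substr(q, 75, 75) <- setdiff(c("A", "C", "G", "T"), old)[1]
    hit1 <- align_pair(q, src, search_params())
    expect_equal(hit1$aligned_length, 150L)
    expect_equal(hit1$percent_identity, 100 * 149 / 150)
  })
})

test_that("align_pair matches the exhaustive Smith-Waterman oracle on short pairs", {
  withr::with_seed(42, {
    for (i in 1:40) {
      q <- random_seq(sample(20:60, 1))
      s <- random_seq(sample(20:60, 1))
      got <- align_pair(q, s, loose_params())
      want <- oracle_sw(q, s)
      if (want$score == 0 || want$aligned_length < 8) {
        next # below the minimal reporting span
      }
      expect_equal(got$score, want$score)
      expect_equal(got$matches, want$matches)
      expect_equal(got$aligned_length, want$aligned_length)
    }
  })
})

test_that("search_queries finds identical, reverse-complement, and no short hits", {
  db <- make_toy_db(c("soil", "marine"), n_per_cat = 2, len = 200, seed = 9)
  idx <- build_index(db, 12)

  q <- tibble::tibble(sequence_id = "q1", sequence = db$sequence[1])
  hits <- search_queries(q, db, search_params(), idx)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$reference_id, db$sequence_id[1])
  expect_equal(hits$percent_identity, 100)
  expect_equal(hits$strand, "+")

  rc <- tibble::tibble(
    sequence_id = "q_rc",
    sequence = as.character(Biostrings::reverseComplement(Biostrings::DNAString(db$sequence[2]))))
  hits_rc <- search_queries(rc, db, search_params(), idx)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$reference_id, db$sequence_id[2])
  expect_equal(hits_rc$strand, "-")

  short <- tibble::tibble(sequence_id = "q_short",
                          sequence = substr(db$sequence[1], 1, 100))
  expect_equal(nrow(search_queries(short, db, search_params(), idx)), 0)

  expect_warning(
    out <- search_queries(tibble::tibble(sequence_id = character(0), sequence = character(0)),
                          db, search_params(), idx),
    "no query")
  expect_equal(nrow(out), 0)
})

test_that("raising thresholds never increases the number of hits", {
  db <- make_toy_db(c("soil", "marine"), n_per_cat = 5, len = 200, seed = 21)
  idx <- build_index(db, 12)
  queries <- tibble::tibble(
    sequence_id = paste0("q", 1:5),
    sequence = vapply(db$sequence[1:5], function(s) {
      withr::with_seed(nchar(s), {
        b <- strsplit(s, "")[[1]]
        flip <- sample(length(b), 6)
        for (i in flip) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
        paste(b, collapse = "")
      })
    }, character(1)))
  n_len <- vapply(c(100, 150, 190), function(len) {
    nrow(search_queries(queries, db,
                        search_params(min_aligned_length = len,
                                      min_percent_identity = 80,
                                      min_seed_count = 1), idx))
  }, numeric(1))
  expect_true(all(diff(n_len) <= 0))
  n_pid <- vapply(c(80, 95, 99.9), function(pid) {
    nrow(search_queries(queries, db,
                        search_params(min_aligned_length = 100,
                                      min_percent_identity = pid,
                                      min_seed_count = 1), idx))
  }, numeric(1))
  expect_true(all(diff(n_pid) <= 0))
})

test_that("reverse-complementing queries flips strands but keeps hit pairs", {
  db <- make_toy_db("soil", n_per_cat = 4, len = 180, seed = 31)
  idx <- build_index(db, 12)
  queries <- tibble::tibble(sequence_id = paste0("q", 1:4), sequence = db$sequence)
  fwd <- search_queries(queries, db, search_params(), idx)
  rc <- queries |>
    dplyr::mutate(sequence = vapply(sequence, function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, character(1)))
  rev <- search_queries(rc, db, search_params(), idx)
  key <- function(h) paste(h$query_id, h$reference_id)
  expect_setequal(key(fwd), key(rev))
  merged <- dplyr::inner_join(fwd, rev, by = c("query_id", "reference_id"))
  expect_true(all(merged$strand.x != merged$strand.y))
})

test_that("every reference hits itself at 100 percent identity", {
  db <- make_toy_db(c("soil", "marine"), n_per_cat = 3, len = 160, seed = 41)
  idx <- build_index(db, 12)
  queries <- tibble::tibble(sequence_id = db$sequence_id, sequence = db$sequence)
  hits <- search_queries(queries, db, search_params(), idx)
  self <- hits[hits$query_id == hits$reference_id, ]
  expect_equal(nrow(self), nrow(db))
  expect_true(all(self$percent_identity == 100))
})

test_that("tabular import filters rows and infers strand from subject order", {
  path <- tempfile(fileext = ".tsv")
  rows <- c(
    "q1\tr1\t99.00\t149\t1\t0\t1\t149\t1\t149\t1e-50\t250",   # too short
    "q1\tr2\t99.00\t200\t2\t0\t1\t200\t300\t101\t1e-60\t350", # minus strand
    "q2\tr3\t98.00\t180\t3\t1\t1\t180\t1\t181\t1e-55\t300"
  )
  writeLines(rows, path)
  hits <- import_tabular_hits(path, search_params(min_percent_identity = 90))
  expect_equal(nrow(hits), 2)
  minus <- hits[hits$reference_id == "r2", ]
  expect_equal(minus$strand, "-")
  expect_equal(minus$ref_start, 101L)
  expect_equal(minus$ref_end, 300L)

  # passthrough with no filters triggered
  all_hits <- import_tabular_hits(path, search_params(min_aligned_length = 10,
                                                      min_percent_identity = 1,
                                                      kmer_size = 8))
  expect_equal(nrow(all_hits), 3)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c(rows[1], "q9\tr9\t99.0\t200"), bad)
  expect_error(import_tabular_hits(bad, search_params()), "line 2")
})

test_that("tabular export round-trips through import", {
  db <- make_toy_db("soil", n_per_cat = 2, len = 200, seed = 51)
  idx <- build_index(db, 12)
  queries <- tibble::tibble(sequence_id = "q1", sequence = db$sequence[1])
  hits <- search_queries(queries, db, search_params(), idx)
  path <- tempfile(fileext = ".tsv")
  write_tabular_hits(hits, path)
  line <- readLines(path)[1]
  expect_equal(strsplit(line, "\t")[[1]][3], "100.00") # 2-decimal pident
  back <- import_tabular_hits(path, search_params())
  expect_equal(back$reference_id, hits$reference_id)
  expect_equal(back$aligned_length, hits$aligned_length)
  expect_equal(back$strand, hits$strand)
})
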