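#' Similarity-search parameters
#'
#' Controls the significance filters and scoring scheme of the internal
#' aligner. The defaults are the pipeline defaults: hits must span at least
#' 150 aligned bases (the shortest span we consider reliable for habitat
#' assignment of 16S fragments; 200 or 250 are common stricter choices) at
#' 97% identity or better (the conventional species-level cutoff).
#'
#' @param min_aligned_length Minimum alignment span in bases (gaps included).
#' @param min_percent_identity Minimum percent identity in (0, 100].
#' @param kmer_size Seed k-mer size in bases, in \[8, 16\].
#' @param min_seed_count Number of distinct shared k-mers required before a
#'   reference is aligned at all (two-hit seeding, default 2). Genuine hits
#'   at the default thresholds share dozens of k-mers, so this prunes only
#'   chance seed matches; set to 1 for maximally sensitive seeding.
#' @param match,mismatch,gap_open,gap_extend Alignment scores. A gap of
#'   length L scores `gap_open + L * gap_extend`.
#' @param max_hits_per_query Keep at most this many hits per query
#'   (best-scoring first); `Inf` keeps all.
#' @param search_both_strands Also search the reverse complement of each
#'   query.
#' @param max_evalue Maximum E-value accepted when importing external
#'   tabular hits (the internal aligner computes no E-values).
#' @return A `search_params` list.
#' @export
search_params <- function(min_aligned_length = 150,
                          min_percent_identity = 97,
                          kmer_size = 12,
                          min_seed_count = 2,
                          match = 1L, mismatch = -2L,
                          gap_open = -5L, gap_extend = -2L,
                          max_hits_per_query = Inf,
                          search_both_strands = TRUE,
                          max_evalue = Inf) {
  stopifnot(kmer_size >= 8, kmer_size <= 16)
  if (min_aligned_length < kmer_size) {
    abort("min_aligned_length must be >= kmer_size")
  }
  if (!(min_percent_identity > 0 && min_percent_identity <= 100)) {
    abort("min_percent_identity must be in (0, 100]")
  }
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0,
            max_hits_per_query >= 1, min_seed_count >= 1)
  structure(list(
    min_aligned_length = as.integer(min_aligned_length),
    min_percent_identity = min_percent_identity,
    kmer_size = as.integer(kmer_size),
    min_seed_count = as.integer(min_seed_count),
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    max_hits_per_query = max_hits_per_query,
    search_both_strands = isTRUE(search_both_strands),
    max_evalue = max_evalue
  ), class = "search_params")
}

empty_hits <- function() {
  tibble(
    query_id = character(0), reference_id = character(0),
    percent_identity = numeric(0), aligned_length = integer(0),
    matches = integer(0), mismatches = integer(0), gap_openings = integer(0),
    query_start = integer(0), query_end = integer(0),
    ref_start = integer(0), ref_end = integer(0),
    strand = character(0), score = numeric(0)
  )
}

#' Build an exact-match k-mer index over a reference database
#'
#' Postings map each k-mer to the references (and offsets) containing it;
#' windows containing N are excluded. The index is used to shortlist
#' candidate references before alignment.
#'
#' @param db A [habitat_ref()] tibble.
#' @param kmer_size Seed length in bases, in \[8, 16\].
#' @return A `kmer_index` with a `postings` tibble (`kmer`, `reference_id`,
#'   `offset`) and a per-kmer candidate lookup.
#' @export
build_index <- function(db, kmer_size = 12) {
  if (!(kmer_size >= 8 && kmer_size <= 16)) abort("kmer_size must be in [8, 16]")
  km_list <- lapply(db$sequence, sequence_kmers, k = kmer_size)
  n_each <- lengths(km_list)
  postings <- tibble(
    kmer = unlist(km_list, use.names = FALSE) %||% character(0),
    reference_id = rep(db$sequence_id, n_each),
    offset = unlist(lapply(km_list, function(k) as.integer(attr(k, "offset"))),
                    use.names = FALSE) %||% integer(0)
  )
  by_kmer <- new.env(parent = emptyenv(), size = max(2L, nrow(postings)))
  split_refs <- lapply(split(rep(seq_len(nrow(db)), n_each), postings$kmer), unique)
  kmer_names <- names(split_refs)
  for (i in seq_along(split_refs)) assign(kmer_names[i], split_refs[[i]], envir = by_kmer)
  structure(list(
    kmer_size = as.integer(kmer_size),
    reference_ids = db$sequence_id,
    postings = postings,
    by_kmer = by_kmer
  ), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k = %d, %d postings over %d references\n",
              x$kmer_size, nrow(x$postings), length(x$reference_ids)))
  invisible(x)
}

# Row indices of references sharing >= min_count distinct k-mers with
# `sequence`.
index_candidates <- function(index, sequence, min_count = 1) {
  kmers <- unique(sequence_kmers(sequence, index$kmer_size))
  if (!length(kmers)) return(integer(0))
  hits <- unlist(mget(kmers, envir = index$by_kmer, ifnotfound = list(integer(0))),
                 use.names = FALSE)
  if (!length(hits)) return(integer(0))
  counts <- tabulate(hits, nbins = length(index$reference_ids))
  which(counts >= min_count)
}

hit_row_from_stats <- function(stats, query_id, reference_id, strand, query_len) {
  qs <- as.integer(stats[["query_start"]]); qe <- as.integer(stats[["query_end"]])
  if (strand == "-") {
    # stats were computed on the reverse complement; map back to the
    # original query frame, keeping coordinates ascending on the query
    new_qs <- query_len - qe + 1L
    qe <- query_len - qs + 1L
    qs <- new_qs
  }
  tibble(
    query_id = query_id, reference_id = reference_id,
    percent_identity = 100 * stats[["matches"]] / stats[["aligned_length"]],
    aligned_length = as.integer(stats[["aligned_length"]]),
    matches = as.integer(stats[["matches"]]),
    mismatches = as.integer(stats[["mismatches"]]),
    gap_openings = as.integer(stats[["gap_openings"]]),
    query_start = qs, query_end = qe,
    ref_start = as.integer(stats[["ref_start"]]),
    ref_end = as.integer(stats[["ref_end"]]),
    strand = strand, score = stats[["score"]]
  )
}

#' Align one query against one reference
#'
#' Computes the optimal affine-gap local alignment (full Smith-Waterman
#' dynamic programming over the plus strand) and returns it as a one-row hit
#' table, or a zero-row table when no alignment reaches the length and
#' identity thresholds. Percent identity is `100 * matches / aligned_length`
#' with gaps counted in the alignment length; N bases never count as
#' matches.
#'
#' @param query,reference DNA strings over \{A,C,G,T,N\}.
#' @param params A [search_params()] object.
#' @param query_id,reference_id Ids used in the returned row.
#' @return A hit tibble with 0 or 1 row.
#' @export
align_pair <- function(query, reference, params = search_params(),
                       query_id = "query", reference_id = "reference") {
  assert_dna(toupper(query), context = "query")
  assert_dna(toupper(reference), context = "reference")
  stats <- cpp_sw_align(toupper(query), toupper(reference),
                        params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
  if (stats[["aligned_length"]] == 0) return(empty_hits())
  row <- hit_row_from_stats(stats, query_id, reference_id, "+", nchar(query))
  filter_hits(row, params)
}

filter_hits <- function(hits, params) {
  dplyr::filter(
    hits,
    .data$aligned_length >= params$min_aligned_length,
    .data$percent_identity >= params$min_percent_identity
  )
}

align_query_against <- function(query_id, query_seq, db, index, params) {
  strands <- if (params$search_both_strands) c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    seq_used <- if (strand == "+") query_seq else reverse_complement(query_seq)
    cand <- index_candidates(index, seq_used, params$min_seed_count)
    if (!length(cand)) next
    stats <- cpp_sw_align_batch(seq_used, db$sequence[cand],
                                params$match, params$mismatch,
                                params$gap_open, params$gap_extend)
    keep <- which(stats[, "aligned_length"] > 0)
    for (i in keep) {
      rows[[length(rows) + 1L]] <- hit_row_from_stats(
        stats[i, ], query_id, db$sequence_id[cand[i]], strand, nchar(query_seq))
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- dplyr::bind_rows(rows)
  # one hit per (query, reference): best score, ties to plus strand
  hits <- hits |>
    dplyr::arrange(.data$reference_id, dplyr::desc(.data$score), .data$strand) |>
    dplyr::distinct(.data$reference_id, .keep_all = TRUE)
  hits <- filter_hits(hits, params)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score),
                         .data$query_start, .data$reference_id)
  if (is.finite(params$max_hits_per_query) && nrow(hits) > params$max_hits_per_query) {
    hits <- hits[seq_len(params$max_hits_per_query), ]
  }
  hits
}

#' Search query sequences against a reference database
#'
#' Shortlists candidate references by shared k-mers (both strands when
#' enabled), aligns each candidate with the affine-gap local aligner, keeps
#' the best-scoring alignment per (query, reference) pair, and discards hits
#' below the length/identity thresholds.
#'
#' @param queries A data frame with `sequence_id` and `sequence` columns
#'   (e.g. from [read_fasta()]), or a named character vector of sequences.
#' @param db A [habitat_ref()] tibble.
#' @param params A [search_params()] object.
#' @param index Optional prebuilt [build_index()]; built on the fly otherwise.
#' @return A hit tibble, one row per retained (query, reference) alignment.
#' @export
search_queries <- function(queries, db, params = search_params(), index = NULL) {
  if (!is.data.frame(queries)) {
    if (is.null(names(queries))) abort("queries must be a data frame or a named character vector")
    queries <- tibble(sequence_id = names(queries), sequence = unname(queries))
  }
  stopifnot(all(c("sequence_id", "sequence") %in% names(queries)))
  if (nrow(queries) == 0) {
    warn("no query sequences supplied; returning an empty hit table")
    return(empty_hits())
  }
  queries$sequence <- toupper(queries$sequence)
  assert_dna(queries$sequence, queries$sequence_id, "query sequence")
  if (is.null(index)) index <- build_index(db, params$kmer_size)
  if (index$kmer_size != params$kmer_size) {
    abort("index kmer_size does not match params$kmer_size")
  }
  res <- purrr::map2(queries$sequence_id, queries$sequence,
                     function(id, s) align_query_against(id, s, db, index, params))
  dplyr::bind_rows(res)
}

#' Import hits from a 12-column BLAST tabular file
#'
#' Reads `-outfmt 6` rows (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore), drops rows failing the length,
#' identity, or E-value filters, and infers the strand from the subject
#' coordinate order (sstart > send means minus strand; subject coordinates
#' are stored ascending).
#'
#' @param path Path to the tabular file.
#' @param params A [search_params()] object supplying the filters.
#' @return A hit tibble with an extra `evalue` column.
#' @export
import_tabular_hits <- function(path, params = search_params()) {
  if (!file.exists(path)) abort(sprintf("hit file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(dplyr::mutate(empty_hits(), evalue = numeric(0)))
  fields <- stringr::str_split(lines, "\t")
  bad <- which(lengths(fields) != 12)
  if (length(bad)) {
    abort(sprintf("line %d of %s has %d columns; expected the 12 BLAST outfmt-6 columns",
                  bad[1], path, lengths(fields)[bad[1]]))
  }
  m <- do.call(rbind, fields)
  num <- function(j) as.numeric(m[, j])
  sstart <- num(9); send <- num(10)
  hits <- tibble(
    query_id = m[, 1], reference_id = m[, 2],
    percent_identity = num(3), aligned_length = as.integer(num(4)),
    matches = as.integer(round(num(3) / 100 * num(4))),
    mismatches = as.integer(num(5)), gap_openings = as.integer(num(6)),
    query_start = as.integer(num(7)), query_end = as.integer(num(8)),
    ref_start = as.integer(pmin(sstart, send)),
    ref_end = as.integer(pmax(sstart, send)),
    strand = ifelse(sstart > send, "-", "+"),
    score = num(12), evalue = num(11)
  )
  if (anyNA(hits$percent_identity) || anyNA(hits$score)) {
    abort(sprintf("non-numeric fields in %s", path))
  }
  hits <- filter_hits(hits, params)
  dplyr::filter(hits, .data$evalue <= params$max_evalue)
}

#' Export hits as 12-column BLAST tabular
#'
#' Percent identity is printed with two decimals; minus-strand hits are
#' written with descending subject coordinates (the tabular convention). The
#' internal aligner computes no E-values, so the E-value column is written
#' as 0; the bitscore column carries the raw alignment score.
#'
#' @param hits A hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  evalue <- if ("evalue" %in% names(hits)) hits$evalue else rep(0, nrow(hits))
  minus <- hits$strand == "-"
  sstart <- ifelse(minus, hits$ref_end, hits$ref_start)
  send <- ifelse(minus, hits$ref_start, hits$ref_end)
  out <- data.frame(
    hits$query_id, hits$reference_id, sprintf("%.2f", hits$percent_identity),
    hits$aligned_length, hits$mismatches, hits$gap_openings,
    hits$query_start, hits$query_end, sstart, send, evalue, hits$score
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
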