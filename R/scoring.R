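new_habitat_score <- function(subject_id, scores, n_hits, mapped, coverage = NULL) {
  out <- tibble(
    subject_id = subject_id,
    category = names(scores) %||% character(0),
    score = unname(scores)
  )
  if (!mapped) out <- out[0, ]
  class(out) <- c("habitat_score", class(tibble()))
  attr(out, "subject_id") <- subject_id
  attr(out, "n_hits") <- as.integer(n_hits)
  attr(out, "mapped") <- mapped
  if (!is.null(coverage)) attr(out, "coverage") <- coverage
  out
}

#' @export
print.habitat_score <- function(x, ...) {
  if (!attr(x, "mapped")) {
    cat(sprintf("<habitat_score> %s: unmapped (no significant hits)\n",
                attr(x, "subject_id")))
  } else {
    cat(sprintf("<habitat_score> %s: %d categories from %d hit(s)\n",
                attr(x, "subject_id"), nrow(x), attr(x, "n_hits")))
  }
  NextMethod()
}

#' Is a score mapped, and by how many hits?
#' @param x A `habitat_score`.
#' @return `is_mapped`: logical; `n_hits`: integer.
#' @export
is_mapped <- function(x) isTRUE(attr(x, "mapped"))

#' @rdname is_mapped
#' @export
n_hits <- function(x) attr(x, "n_hits")

score_vector <- function(x) setNames(x$score, x$category)

#' Habitat preference score of one query sequence
#'
#' The habitat preference score is the composition of environmental
#' categories among the query's significant hits: with `n_c` hit references
#' labeled category `c`, the default score is `n_c / sum(n_c)`. Because a
#' query can hit (nearly) identical references from several environments,
#' the score is genuinely one-to-many and is always presented as a
#' composition summing to one. With `normalize_by_category_size`, hit counts
#' are divided by each category's database size before renormalizing, which
#' counteracts the dominance of very large categories.
#'
#' @param hits A hit tibble for a single query (one row per reference).
#' @param db The [habitat_ref()] tibble the hits refer to.
#' @param normalize_by_category_size Divide hit counts by category size
#'   before renormalizing (default `FALSE`).
#' @return A `habitat_score` tibble (`subject_id`, `category`, `score`) with
#'   attributes `n_hits` and `mapped`. Zero hits give an unmapped score.
#' @export
#' @examples
#' db <- habitat_ref(tibble::tibble(
#'   sequence_id = c("r1", "r2", "r3"),
#'   sequence = c("ACGT", "ACGT", "ACGT"),
#'   category = c("soil", "soil", "marine"),
#'   project_id = "p1"
#' ))
#' hits <- tibble::tibble(query_id = "q", reference_id = c("r1", "r2", "r3"))
#' score_query(hits, db)
score_query <- function(hits, db, normalize_by_category_size = FALSE) {
  subject_id <- if (nrow(hits)) unique(hits$query_id) else "query"
  if (length(subject_id) > 1) {
    abort("score_query expects hits from a single query; use score_queries() for many")
  }
  if (nrow(hits) == 0) {
    return(new_habitat_score(subject_id, numeric(0), 0L, FALSE))
  }
  if (anyDuplicated(hits$reference_id)) {
    abort("each reference may appear at most once among one query's hits")
  }
  idx <- match(hits$reference_id, db$sequence_id)
  if (anyNA(idx)) {
    abort(sprintf("hit(s) reference ids absent from the database: %s",
                  paste(head(hits$reference_id[is.na(idx)], 5), collapse = ", ")))
  }
  cats <- db$category[idx]
  n_c <- table(cats)
  w <- as.numeric(n_c)
  if (normalize_by_category_size) {
    sizes <- category_sizes(db)
    s_c <- setNames(sizes$n_sequences, sizes$category)
    w <- w / s_c[names(n_c)]
  }
  scores <- sort(setNames(w / sum(w), names(n_c)), decreasing = TRUE)
  new_habitat_score(subject_id, scores, nrow(hits), TRUE)
}

#' Habitat preference scores for many queries
#'
#' Runs [search_queries()] once and applies [score_query()] per query,
#' including unmapped entries for queries without significant hits.
#'
#' @inheritParams search_queries
#' @inheritParams score_query
#' @return A named list of `habitat_score` objects, one per query.
#' @export
score_queries <- function(queries, db, params = search_params(),
                          normalize_by_category_size = FALSE, index = NULL) {
  if (!is.data.frame(queries)) {
    queries <- tibble(sequence_id = names(queries), sequence = unname(queries))
  }
  hits <- search_queries(queries, db, params, index)
  by_query <- split(hits, factor(hits$query_id, levels = queries$sequence_id))
  out <- lapply(queries$sequence_id, function(id) {
    h <- by_query[[id]]
    if (is.null(h) || nrow(h) == 0) {
      new_habitat_score(id, numeric(0), 0L, FALSE)
    } else {
      score_query(h, db, normalize_by_category_size)
    }
  })
  setNames(out, queries$sequence_id)
}

#' Community feature profiles
#'
#' Bundles a feature (sOTU) count table with the representative sequence of
#' each feature.
#'
#' @param counts A data frame: `feature_id` plus one non-negative integer
#'   column per sample.
#' @param sequences A named character vector or a data frame
#'   (`feature_id`, `sequence`) giving every feature's sequence.
#' @return A `community_profile` object.
#' @export
community_profile <- function(counts, sequences) {
  counts <- as_tibble(counts)
  stopifnot("feature_id" %in% names(counts), ncol(counts) >= 2)
  counts$feature_id <- as.character(counts$feature_id)
  sample_ids <- setdiff(names(counts), "feature_id")
  for (col in sample_ids) {
    if (any(counts[[col]] < 0)) abort(sprintf("negative counts in sample '%s'", col))
  }
  seqs <- as_named_vector(sequences, "feature_id", "sequence", "feature sequences")
  missing_seq <- setdiff(counts$feature_id, names(seqs))
  if (length(missing_seq)) {
    abort(sprintf("no sequence for feature(s): %s",
                  paste(head(missing_seq, 5), collapse = ", ")))
  }
  seqs <- toupper(seqs[counts$feature_id])
  assert_dna(seqs, names(seqs), "feature sequence")
  structure(list(counts = counts, sequences = seqs,
                 sample_ids = sample_ids, feature_ids = counts$feature_id),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("<community_profile> %d features x %d samples\n",
              length(x$feature_ids), length(x$sample_ids)))
  invisible(x)
}

#' Habitat preference score of a community sample
#'
#' Aggregates per-feature habitat scores into one community composition:
#' the read-abundance-weighted mean of the mapped features' score vectors,
#' renormalized over mapped features only (an unweighted mean when
#' `weight_by_abundance = FALSE`). Unmapped features are excluded, not
#' spread across categories, and are reported through the coverage pair:
#' the fraction of (present) features mapped and the fraction of reads
#' belonging to mapped features.
#'
#' @param profile A [community_profile()].
#' @param per_feature_scores Named list of `habitat_score` objects keyed by
#'   feature id (e.g. from [score_queries()]).
#' @param sample_id Which sample column to aggregate.
#' @param weight_by_abundance Weight features by read counts (default).
#' @return A `habitat_score` with a `coverage` attribute
#'   `c(features = ..., reads = ...)`.
#' @export
score_community <- function(profile, per_feature_scores, sample_id,
                            weight_by_abundance = TRUE) {
  stopifnot(inherits(profile, "community_profile"))
  if (!sample_id %in% profile$sample_ids) {
    abort(sprintf("sample '%s' not in profile", sample_id))
  }
  counts <- setNames(profile$counts[[sample_id]], profile$feature_ids)
  present <- names(counts)[counts > 0]
  if (!length(present)) {
    return(new_habitat_score(sample_id, numeric(0), 0L, FALSE,
                             coverage = c(features = 0, reads = 0)))
  }
  missing_scores <- setdiff(present, names(per_feature_scores))
  if (length(missing_scores)) {
    abort(sprintf("no habitat score supplied for feature(s): %s",
                  paste(head(missing_scores, 5), collapse = ", ")))
  }
  mapped <- present[vapply(per_feature_scores[present], is_mapped, logical(1))]
  coverage <- c(
    features = length(mapped) / length(present),
    reads = sum(counts[mapped]) / sum(counts[present])
  )
  if (!length(mapped)) {
    return(new_habitat_score(sample_id, numeric(0), 0L, FALSE,
                             coverage = c(features = 0, reads = 0)))
  }
  weights <- if (weight_by_abundance) counts[mapped] else rep(1, length(mapped))
  if (sum(weights) == 0) {
    return(new_habitat_score(sample_id, numeric(0), 0L, FALSE,
                             coverage = c(features = 0, reads = 0)))
  }
  weights <- weights / sum(weights)
  vecs <- lapply(per_feature_scores[mapped], score_vector)
  cats <- sort(unique(unlist(lapply(vecs, names))))
  agg <- setNames(numeric(length(cats)), cats)
  for (i in seq_along(mapped)) {
    v <- vecs[[i]]
    agg[names(v)] <- agg[names(v)] + weights[i] * v
  }
  agg <- sort(agg / sum(agg), decreasing = TRUE)
  total_hits <- sum(vapply(per_feature_scores[mapped], n_hits, integer(1)))
  new_habitat_score(sample_id, agg, total_hits, TRUE, coverage = coverage)
}

#' Merge environmental categories into named groups
#'
#' Sums the scores of each group's member categories (e.g. a brine-related
#' group of marine, salt_marsh, and seawater). Groups must be disjoint;
#' categories not covered by any group are collected into an `other` bucket
#' by default so the composition total is preserved.
#'
#' @param x A `habitat_score` or a [score_matrix()] result.
#' @param groups Named list of character vectors (or the tibble from
#'   [read_group_file()]).
#' @param other Emit an `"other"` group for uncovered categories
#'   (default `TRUE`); when `FALSE` uncovered categories are dropped.
#' @return An object of the same class over group names.
#' @export
merge_categories <- function(x, groups, other = TRUE) {
  UseMethod("merge_categories")
}

check_groups <- function(groups) {
  if (is.data.frame(groups)) groups <- split(as.character(groups$category), groups$group)
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    shared <- unique(all_members[duplicated(all_members)])
    abort(sprintf("groups overlap on category(ies): %s", paste(shared, collapse = ", ")))
  }
  groups
}

merge_score_vector <- function(scores, groups, other) {
  out <- vapply(groups, function(members) sum(scores[intersect(members, names(scores))]),
                numeric(1))
  uncovered <- setdiff(names(scores), unlist(groups, use.names = FALSE))
  if (other) out <- c(out, other = sum(scores[uncovered]))
  out
}

#' @export
merge_categories.habitat_score <- function(x, groups, other = TRUE) {
  groups <- check_groups(groups)
  if (!is_mapped(x)) return(x)
  merged <- merge_score_vector(score_vector(x), groups, other)
  new_habitat_score(attr(x, "subject_id"), merged, n_hits(x), TRUE,
                    coverage = attr(x, "coverage"))
}

#' Sample-by-category habitat score matrix
#'
#' The end-to-end community operation: each feature sequence is searched and
#' scored once, then every sample is aggregated with [score_community()].
#' Rows of mapped samples sum to one over the category columns.
#'
#' @param profile A [community_profile()].
#' @param db A [habitat_ref()] tibble.
#' @param params A [search_params()] object.
#' @inheritParams score_query
#' @inheritParams score_community
#' @param index Optional prebuilt [build_index()].
#' @return A `habitat_score_matrix` tibble: `sample_id`, `mapped`,
#'   `coverage_features`, `coverage_reads`, then one column per category
#'   present in `db` (attribute `"categories"` names them).
#' @export
score_matrix <- function(profile, db, params = search_params(),
                         normalize_by_category_size = FALSE,
                         weight_by_abundance = TRUE, index = NULL) {
  stopifnot(inherits(profile, "community_profile"))
  queries <- tibble(sequence_id = profile$feature_ids,
                    sequence = unname(profile$sequences))
  feature_scores <- score_queries(queries, db, params,
                                  normalize_by_category_size, index)
  categories <- sort(unique(db$category))
  rows <- lapply(profile$sample_ids, function(sid) {
    sc <- score_community(profile, feature_scores, sid, weight_by_abundance)
    v <- setNames(numeric(length(categories)), categories)
    if (is_mapped(sc)) {
      sv <- score_vector(sc)
      v[names(sv)] <- sv
    }
    cov <- attr(sc, "coverage")
    dplyr::bind_cols(
      tibble(sample_id = sid, mapped = is_mapped(sc),
             coverage_features = unname(cov["features"]),
             coverage_reads = unname(cov["reads"])),
      as_tibble(as.list(v))
    )
  })
  out <- dplyr::bind_rows(rows)
  new_score_matrix(out, categories)
}

new_score_matrix <- function(x, categories) {
  class(x) <- c("habitat_score_matrix", class(tibble()))
  attr(x, "categories") <- categories
  x
}

#' Category columns of a score matrix
#' @param x A `habitat_score_matrix`.
#' @return Character vector of category column names.
#' @export
score_categories <- function(x) attr(x, "categories")

#' @export
merge_categories.habitat_score_matrix <- function(x, groups, other = TRUE) {
  groups <- check_groups(groups)
  categories <- score_categories(x)
  meta <- x[setdiff(names(x), categories)]
  merged <- lapply(seq_len(nrow(x)), function(i) {
    v <- unlist(x[i, categories])
    as_tibble(as.list(merge_score_vector(v, groups, other)))
  })
  out <- dplyr::bind_cols(meta, dplyr::bind_rows(merged))
  new_score_matrix(out, names(merged[[1]]))
}

#' Sum a group of category columns per sample
#' @param x A `habitat_score_matrix`.
#' @param category_group Character vector of category names.
#' @return Numeric vector named by sample id.
#' @export
grouped_scores <- function(x, category_group) {
  present <- intersect(category_group, score_categories(x))
  if (!length(present)) {
    return(setNames(rep(0, nrow(x)), x$sample_id))
  }
  setNames(rowSums(as.matrix(x[present])), x$sample_id)
}

#' Write / read a score matrix as TSV
#' @param x A `habitat_score_matrix`.
#' @param path Output/input path.
#' @return `path` (write) or a `habitat_score_matrix` (read).
#' @export
write_score_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- c("sample_id", "mapped", "coverage_features", "coverage_reads")
  if (!all(meta %in% names(tab))) {
    abort("not a habscore score matrix: missing sample_id/coverage columns")
  }
  new_score_matrix(as_tibble(tab), setdiff(names(tab), meta))
}
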