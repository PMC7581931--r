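#' Habitat-labeled reference databases
#'
#' A reference database is a tibble of class `habitat_ref` with one row per
#' reference 16S sequence and columns `sequence_id`, `sequence`, `category`
#' (one environmental-category label per sequence) and `project_id` (the
#' research project the sequence was mined from). Category and per-project
#' sizes are always recomputed from the rows, so they can never drift out of
#' step with the sequences.
#'
#' @param x A data frame with columns `sequence_id`, `sequence`, `category`,
#'   `project_id`.
#' @return A `habitat_ref` tibble.
#' @export
habitat_ref <- function(x) {
  required <- c("sequence_id", "sequence", "category", "project_id")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(sprintf("reference table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)[required]
  x$sequence_id <- as.character(x$sequence_id)
  x$category <- as.character(x$category)
  x$project_id <- as.character(x$project_id)
  if (anyDuplicated(x$sequence_id)) {
    dups <- unique(x$sequence_id[duplicated(x$sequence_id)])
    abort(sprintf("duplicate sequence_id in reference database: %s",
                  paste(head(dups, 5), collapse = ", ")))
  }
  if (any(!nzchar(x$category)) || any(is.na(x$category))) {
    abort("every reference needs a non-empty environmental category")
  }
  x$sequence <- toupper(x$sequence)
  assert_dna(x$sequence, x$sequence_id, "reference sequence")
  class(x) <- c("habitat_ref", class(tibble()))
  x
}

#' @export
print.habitat_ref <- function(x, ...) {
  cat(sprintf("<habitat_ref> %d reference sequences, %d categories, %d projects\n",
              nrow(x), dplyr::n_distinct(x$category),
              dplyr::n_distinct(paste(x$category, x$project_id))))
  NextMethod()
}

#' Load a reference database from FASTA plus a label table
#'
#' The label table is a TSV with header columns `sequence_id`, `category`,
#' `project_id`. Every labeled id must be present in the FASTA (missing ids
#' are a hard error listing the offenders); FASTA records without a label are
#' skipped with a warning. Alternatively, labels embedded in FASTA headers as
#' `id|category|project` can be used via `header_labels = TRUE`.
#'
#' @param fasta_path Path to the reference FASTA (plain or gzip).
#' @param labels_path Path to the label TSV; ignored when `header_labels`.
#' @param header_labels Parse `id|category|project_id` FASTA headers instead
#'   of a sidecar table.
#' @return A [habitat_ref()] tibble.
#' @export
load_reference_db <- function(fasta_path, labels_path = NULL, header_labels = FALSE) {
  fa <- read_fasta(fasta_path)
  if (header_labels) {
    parts <- stringr::str_split_fixed(fa$sequence_id, stringr::fixed("|"), 3)
    if (any(!nzchar(parts[, 2]) | !nzchar(parts[, 3]))) {
      abort("header_labels = TRUE requires every FASTA id to look like id|category|project_id")
    }
    return(habitat_ref(tibble(
      sequence_id = parts[, 1], sequence = fa$sequence,
      category = parts[, 2], project_id = parts[, 3]
    )))
  }
  if (is.null(labels_path)) abort("labels_path is required unless header_labels = TRUE")
  labels <- readr::read_tsv(labels_path, show_col_types = FALSE, progress = FALSE)
  need <- c("sequence_id", "category", "project_id")
  if (!all(need %in% names(labels))) {
    abort(sprintf("label table must have columns: %s", paste(need, collapse = ", ")))
  }
  labels$sequence_id <- as.character(labels$sequence_id)
  if (anyDuplicated(labels$sequence_id)) {
    dups <- unique(labels$sequence_id[duplicated(labels$sequence_id)])
    abort(sprintf("duplicate sequence_id in label table: %s",
                  paste(head(dups, 5), collapse = ", ")))
  }
  missing_in_fasta <- setdiff(labels$sequence_id, fa$sequence_id)
  if (length(missing_in_fasta)) {
    abort(sprintf("label table references %d id(s) absent from the FASTA: %s",
                  length(missing_in_fasta),
                  paste(head(missing_in_fasta, 5), collapse = ", ")))
  }
  unlabeled <- setdiff(fa$sequence_id, labels$sequence_id)
  if (length(unlabeled)) {
    warn(sprintf("skipping %d FASTA record(s) without labels", length(unlabeled)))
  }
  joined <- dplyr::inner_join(fa[c("sequence_id", "sequence")], labels, by = "sequence_id")
  habitat_ref(joined)
}

#' Per-category sequence counts of a reference database
#' @param db A [habitat_ref()] tibble.
#' @return A tibble with `category` and `n_sequences`, largest first.
#' @export
category_sizes <- function(db) {
  db |>
    dplyr::count(.data$category, name = "n_sequences") |>
    dplyr::arrange(dplyr::desc(.data$n_sequences), .data$category)
}

#' Per-project sequence counts of a reference database
#' @param db A [habitat_ref()] tibble.
#' @return A tibble with `category`, `project_id`, `n_sequences`.
#' @export
project_sizes <- function(db) {
  db |>
    dplyr::count(.data$category, .data$project_id, name = "n_sequences") |>
    dplyr::arrange(.data$category, .data$project_id)
}

#' Cap the contribution of any single research project
#'
#' Public metagenome projects differ enormously in size; without a cap, a
#' single large project could dominate its category's label pool. For every
#' (category, project) pair with more than `cap` sequences, `cap` sequences
#' are kept by uniform sampling without replacement; smaller projects are
#' kept whole. Deterministic for a fixed seed, and idempotent: re-capping an
#' already-capped database changes nothing.
#'
#' @param db A [habitat_ref()] tibble.
#' @param cap Maximum sequences retained per (category, project); default 100.
#' @param seed Integer seed controlling the subsampling.
#' @return A capped `habitat_ref` tibble (original row order preserved), with
#'   attributes `cap` and `cap_seed` recording the rule applied.
#' @export
cap_per_project <- function(db, cap = 100, seed = 1L) {
  stopifnot(inherits(db, "habitat_ref"), cap >= 1)
  cap <- as.integer(cap)
  groups <- split(seq_len(nrow(db)), paste(db$category, db$project_id, sep = "\r"))
  groups <- groups[order(names(groups))] # deterministic group order
  keep <- withr::with_seed(seed, {
    unlist(lapply(groups, function(rows) {
      if (length(rows) <= cap) rows else sort(sample(rows, cap))
    }), use.names = FALSE)
  })
  out <- habitat_ref(db[sort(keep), ])
  attr(out, "cap") <- cap
  attr(out, "cap_seed") <- as.integer(seed)
  out
}

#' Summarize category sizes and cumulative coverage
#'
#' Reports, per environmental category, its sequence count and fraction of
#' all sequences, plus the cumulative fraction covered by the largest `k`
#' categories. With the bundled ProkAtlas category-size table this reproduces
#' the headline coverage arithmetic of the public release (the four largest
#' categories — soil, marine, freshwater, rhizosphere — cover 55.3% of the
#' 361,474 sequences, and the 26 largest cover more than 90%).
#'
#' @param x A [habitat_ref()] tibble, a named vector of per-category counts,
#'   or a data frame with columns `category` and `n_sequences`.
#' @return A tibble sorted by decreasing size with columns `category`,
#'   `n_sequences`, `fraction`, `rank`, `cumulative_fraction`.
#' @export
#' @examples
#' category_summary(c(soil = 50, marine = 30, freshwater = 20))
category_summary <- function(x) {
  if (inherits(x, "habitat_ref")) {
    counts <- category_sizes(x)
  } else if (is.data.frame(x)) {
    if (!all(c("category", "n_sequences") %in% names(x))) {
      abort("count table must have columns 'category' and 'n_sequences'")
    }
    counts <- as_tibble(x)[c("category", "n_sequences")]
  } else {
    v <- as_named_vector(x, "category", "n_sequences", "category counts")
    counts <- tibble(category = names(v), n_sequences = as.numeric(v))
  }
  counts <- dplyr::filter(counts, .data$n_sequences > 0)
  if (nrow(counts) == 0) abort("category_summary needs at least one category with count > 0")
  counts |>
    dplyr::arrange(dplyr::desc(.data$n_sequences), .data$category) |>
    dplyr::mutate(
      fraction = .data$n_sequences / sum(.data$n_sequences),
      rank = dplyr::row_number(),
      cumulative_fraction = cumsum(.data$fraction)
    )
}

#' Bundled category sizes of the public ProkAtlas database release
#'
#' Per-category sequence and project counts of the public habitat-labeled
#' 16S reference release (361,474 sequences from 5,368 shotgun metagenome
#' projects across 115 environmental categories).
#'
#' @return A tibble with `category`, `n_sequences`, `n_projects`.
#' @export
prokatlas_category_counts <- function() {
  path <- system.file("extdata", "prokatlas_category_counts.tsv", package = "habscore")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_tibble(tab)
}

#' Persist a reference database to a directory
#'
#' Writes `references.fasta`, `labels.tsv` and a `manifest.json` holding the
#' recounted category sizes and any capping parameters, so a later
#' [read_reference_db()] can verify integrity.
#'
#' @param db A [habitat_ref()] tibble.
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_reference_db <- function(db, path) {
  stopifnot(inherits(db, "habitat_ref"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_fasta(db[c("sequence_id", "sequence")], file.path(path, "references.fasta"))
  readr::write_tsv(db[c("sequence_id", "category", "project_id")],
                   file.path(path, "labels.tsv"), progress = FALSE)
  sizes <- category_sizes(db)
  manifest <- list(
    format = "habscore_reference_db",
    version = as.character(utils::packageVersion("habscore")),
    n_sequences = nrow(db),
    category_sizes = as.list(setNames(sizes$n_sequences, sizes$category)),
    cap = attr(db, "cap"),
    cap_seed = attr(db, "cap_seed")
  )
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a persisted reference database
#'
#' Recounts categories after loading and refuses to return a database whose
#' counts disagree with the stored manifest (e.g. a truncated FASTA), rather
#' than silently loading a partial collection.
#'
#' @param path Directory written by [write_reference_db()].
#' @return A [habitat_ref()] tibble.
#' @export
read_reference_db <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) abort(sprintf("no manifest.json under %s", path))
  manifest <- tryCatch(jsonlite::read_json(manifest_path),
                       error = function(e) abort(sprintf("malformed manifest: %s", conditionMessage(e))))
  if (!identical(manifest$format, "habscore_reference_db")) {
    abort("manifest.json is not a habscore reference-db manifest")
  }
  db <- load_reference_db(file.path(path, "references.fasta"), file.path(path, "labels.tsv"))
  if (nrow(db) != manifest$n_sequences) {
    abort(sprintf("reference db at %s is corrupt: %d sequences on disk, manifest says %d",
                  path, nrow(db), manifest$n_sequences))
  }
  sizes <- category_sizes(db)
  stored <- unlist(manifest$category_sizes)
  if (!setequal(names(stored), sizes$category) ||
      !all(stored[sizes$category] == sizes$n_sequences)) {
    abort(sprintf("reference db at %s is corrupt: category counts disagree with manifest", path))
  }
  if (length(manifest$cap)) attr(db, "cap") <- as.integer(manifest$cap)
  if (length(manifest$cap_seed)) attr(db, "cap_seed") <- as.integer(manifest$cap_seed)
  db
}
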