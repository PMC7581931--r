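#' Read a FASTA file into a tibble
#'
#' Sequence ids are the header text up to the first whitespace; the remainder
#' of the header is kept in a `description` column. Sequences are upper-cased
#' and validated against the \{A,C,G,T,N\} alphabet. Gzip-compressed files are
#' read transparently.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A tibble with columns `sequence_id`, `sequence`, `description`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a soil clone", "ACGTACGT", ">s2", "GGGCCC"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate sequence ids in %s: %s", path,
                  paste(head(dups, 5), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  assert_dna(seqs, ids)
  tibble(sequence_id = ids, sequence = unname(seqs), description = desc)
}

#' Write sequences to FASTA
#'
#' @param x A data frame with columns `sequence_id` and `sequence` (an
#'   optional `description` column is appended to the header).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line-wrapping width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80) {
  stopifnot(all(c("sequence_id", "sequence") %in% names(x)))
  headers <- x$sequence_id
  if ("description" %in% names(x)) {
    headers <- ifelse(nzchar(x$description),
                      paste(x$sequence_id, x$description), x$sequence_id)
  }
  set <- Biostrings::DNAStringSet(setNames(x$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a feature (sOTU) count table
#'
#' Tab-separated, first column `feature_id`, remaining columns per-sample
#' read counts. Counts must be non-negative integers; violations are reported
#' with their line number.
#'
#' @param path Path to the TSV (plain or gzip).
#' @return A tibble: `feature_id` plus one integer column per sample.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("feature table not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) abort("feature table needs a feature_id column plus >=1 sample column")
  names(tab)[1] <- "feature_id"
  tab$feature_id <- as.character(tab$feature_id)
  if (anyDuplicated(tab$feature_id)) {
    abort(sprintf("duplicate feature ids: %s",
                  paste(head(unique(tab$feature_id[duplicated(tab$feature_id)]), 5), collapse = ", ")))
  }
  for (col in names(tab)[-1]) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      abort(sprintf("non-numeric counts in column '%s' (line %d)",
                    col, which(is.na(suppressWarnings(as.numeric(v))))[1] + 1L))
    }
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf("invalid count in column '%s' at line %d: counts must be non-negative integers",
                    col, bad[1] + 1L))
    }
    tab[[col]] <- as.integer(v)
  }
  tab
}

#' Write a feature count table as TSV
#' @param x Tibble as returned by [read_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated with a header; the first column is taken as `sample_id`.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with `sample_id` first.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("metadata file not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab)[1] <- "sample_id"
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) abort("duplicate sample ids in metadata")
  tab
}

#' Read a category-group file
#'
#' Tab-separated with header columns `group` and `category`; each row assigns
#' one environmental category to a named group (e.g. the brine-related group
#' marine + salt_marsh + seawater).
#'
#' @param path Path to the group TSV.
#' @return A named list of character vectors, one per group.
#' @export
read_group_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("group file not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("group", "category") %in% names(tab))) {
    abort("group file must have columns 'group' and 'category'")
  }
  split(as.character(tab$category), tab$group)
}

#' Write a machine-readable run manifest
#'
#' Records inputs, parameters, seed and package version next to a run's
#' outputs so the run can be reproduced.
#'
#' @param path Output JSON path.
#' @param subcommand Name of the operation performed.
#' @param inputs Named list of input paths.
#' @param params Named list of resolved parameters.
#' @param seed Integer seed used, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, subcommand, inputs = list(), params = list(), seed = NULL) {
  manifest <- list(
    tool = "habscore",
    version = as.character(utils::packageVersion("habscore")),
    subcommand = subcommand,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    params = params,
    seed = seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
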