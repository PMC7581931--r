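#' Configuration for the synthetic reference-database generator
#'
#' The generator creates an ancestor pool per environmental category,
#' optionally shares ancestors between category pairs with probability
#' `overlap[a, b]`, and emits one reference per pool member: an ancestor
#' copy mutated at `mutation_rate`, assigned round-robin to that category's
#' projects. Ancestors are i.i.d. uniform nucleotide strings; this captures
#' the similarity structure the search and scoring logic depends on without
#' attempting 16S secondary-structure or GC realism.
#'
#' @param n_categories Number of environmental categories.
#' @param pool_size_per_category Ancestors (and hence references) per
#'   category.
#' @param overlap Symmetric matrix of pairwise pool-sharing probabilities
#'   with unit diagonal; `NULL` means disjoint pools (identity matrix).
#' @param seq_length Ancestor length in bases (default 1500, full-length
#'   16S).
#' @param n_projects_per_category Projects per category (default 5).
#' @param mutation_rate Per-base substitution probability in \[0, 0.25\]
#'   (default 0.01).
#' @param indels Also introduce short indels at one tenth of the mutation
#'   rate (off by default; substitutions-only keeps identities exactly
#'   interpretable).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_categories = 3,
                              pool_size_per_category = 50,
                              overlap = NULL,
                              seq_length = 1500,
                              n_projects_per_category = 5,
                              mutation_rate = 0.01,
                              indels = FALSE,
                              seed = 1L) {
  if (is.null(overlap)) overlap <- diag(n_categories)
  overlap <- as.matrix(overlap)
  if (!isTRUE(all.equal(overlap, t(overlap))) || any(diag(overlap) != 1)) {
    abort("overlap must be symmetric with unit diagonal")
  }
  if (any(overlap < 0 | overlap > 1)) abort("overlap entries must be in [0, 1]")
  if (mutation_rate < 0 || mutation_rate > 0.25) {
    abort("mutation_rate must be in [0, 0.25]")
  }
  stopifnot(n_categories >= 1, pool_size_per_category >= 1,
            seq_length >= 1, n_projects_per_category >= 1)
  structure(list(
    n_categories = as.integer(n_categories),
    pool_size_per_category = as.integer(pool_size_per_category),
    overlap = overlap,
    seq_length = as.integer(seq_length),
    n_projects_per_category = as.integer(n_projects_per_category),
    mutation_rate = mutation_rate,
    indels = isTRUE(indels),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_sequence <- function(sequence, rate, indels = FALSE) {
  if (rate == 0 && !indels) return(sequence)
  bases <- strsplit(sequence, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  if (indels) {
    # sparse 1-base indels; kept rare so identities stay near 1 - rate
    ind <- which(stats::runif(length(bases)) < rate / 10)
    for (i in rev(ind)) {
      if (stats::runif(1) < 0.5) {
        bases <- append(bases, sample(c("A", "C", "G", "T"), 1), after = i)
      } else {
        bases <- bases[-i]
      }
    }
  }
  paste(bases, collapse = "")
}

synthetic_category_names <- function(n) {
  if (n <= 26) paste0("cat_", letters[seq_len(n)]) else sprintf("cat_%03d", seq_len(n))
}

#' Generate a habitat-labeled reference database with known ground truth
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_reference` list: `db` (a [habitat_ref()]),
#'   `ancestors` (tibble `ancestor_id`, `sequence`), and `pool` (tibble
#'   `category`, `ancestor_id`, `reference_id`, `project_id`) recording true
#'   pool membership.
#' @export
generate_reference_db <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    n <- config$n_categories
    cats <- synthetic_category_names(n)
    pool_size <- config$pool_size_per_category
    ancestors <- character(0)
    pools <- vector("list", n) # ancestor indices per category
    for (b in seq_len(n)) {
      members <- integer(0)
      for (a in seq_len(b - 1)) {
        if (config$overlap[a, b] > 0) {
          shared <- pools[[a]][stats::runif(length(pools[[a]])) < config$overlap[a, b]]
          members <- unique(c(members, shared))
        }
      }
      if (length(members) > pool_size) members <- members[seq_len(pool_size)]
      n_new <- pool_size - length(members)
      if (n_new > 0) {
        new_seqs <- random_dna(n_new, config$seq_length)
        new_idx <- length(ancestors) + seq_len(n_new)
        ancestors <- c(ancestors, new_seqs)
        members <- c(members, new_idx)
      }
      pools[[b]] <- members
    }
    anc_ids <- sprintf("anc_%04d", seq_along(ancestors))
    rows <- lapply(seq_len(n), function(b) {
      members <- pools[[b]]
      ref_ids <- sprintf("%s_ref_%03d", cats[b], seq_along(members))
      proj <- sprintf("%s_proj_%02d",
                      cats[b],
                      ((seq_along(members) - 1L) %% config$n_projects_per_category) + 1L)
      seqs <- vapply(members, function(m) {
        mutate_sequence(ancestors[m], config$mutation_rate, config$indels)
      }, character(1))
      tibble(category = cats[b], ancestor_id = anc_ids[members],
             reference_id = ref_ids, project_id = proj, sequence = seqs)
    })
    pool <- dplyr::bind_rows(rows)
    db <- habitat_ref(tibble(
      sequence_id = pool$reference_id, sequence = pool$sequence,
      category = pool$category, project_id = pool$project_id
    ))
    structure(list(
      db = db,
      ancestors = tibble(ancestor_id = anc_ids, sequence = ancestors),
      pool = pool[c("category", "ancestor_id", "reference_id", "project_id")],
      config = config
    ), class = "synthetic_reference")
  })
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat(sprintf("<synthetic_reference> %d categories x %d references, %d ancestors\n",
              x$config$n_categories, x$config$pool_size_per_category,
              nrow(x$ancestors)))
  invisible(x)
}

mixture_check <- function(mixture, categories) {
  mix <- as_named_vector(mixture, "category", "proportion", "mixture")
  if (abs(sum(mix) - 1) > 1e-9) abort("mixture proportions must sum to 1")
  if (any(mix < 0)) abort("mixture proportions must be non-negative")
  unknown <- setdiff(names(mix), categories)
  if (length(unknown)) {
    abort(sprintf("mixture names unknown category(ies): %s", paste(unknown, collapse = ", ")))
  }
  mix
}

# Allocate features to categories (largest remainder) and build per-feature
# sequences and expected read weights such that each category's expected
# read share equals its mixture proportion exactly.
build_feature_panel <- function(truth, alloc_proportions, n_features, mutation_rate) {
  cats <- names(alloc_proportions)
  n_by_cat <- largest_remainder(alloc_proportions, n_features)
  # every category with positive proportion gets at least one feature
  zero_pos <- which(n_by_cat == 0 & alloc_proportions > 0)
  for (i in zero_pos) {
    donor <- which.max(n_by_cat)
    n_by_cat[donor] <- n_by_cat[donor] - 1L
    n_by_cat[i] <- 1L
  }
  anc_seq <- setNames(truth$ancestors$sequence, truth$ancestors$ancestor_id)
  rows <- lapply(seq_along(cats), function(ci) {
    k <- n_by_cat[ci]
    if (k == 0) return(NULL)
    pool <- truth$pool[truth$pool$category == cats[ci], ]
    picks <- sample(nrow(pool), k, replace = k > nrow(pool))
    tibble(category = cats[ci], ancestor_id = pool$ancestor_id[picks])
  })
  panel <- dplyr::bind_rows(rows)
  panel$feature_id <- sprintf("feat_%03d", seq_len(nrow(panel)))
  panel$sequence <- vapply(panel$ancestor_id, function(a) {
    mutate_sequence(anc_seq[[a]], mutation_rate)
  }, character(1))
  panel$n_in_category <- as.vector(table(panel$category)[panel$category])
  panel
}

#' Generate one community sample with a known habitat mixture
#'
#' Features are allocated to category pools by largest remainder on the
#' mixture proportions; each feature's sequence is a freshly mutated copy of
#' a pool ancestor, and read counts are multinomial with each category's
#' features sharing that category's proportion equally, so the expected read
#' composition equals the requested mixture.
#'
#' @param truth A [generate_reference_db()] result.
#' @param mixture Named proportions over categories, summing to 1.
#' @param n_features Number of features (sOTUs) to draw.
#' @param total_reads Total reads in the sample (column sum is exact).
#' @param mutation_rate Per-base substitution rate for feature sequences.
#' @param seed Integer seed.
#' @param sample_id Name of the generated sample column.
#' @return A `synthetic_community` list: `profile`
#'   (a [community_profile()]), `truth` (tibble `feature_id`, `category`,
#'   `ancestor_id`), and `mixture`.
#' @export
generate_community <- function(truth, mixture, n_features = 30,
                               total_reads = 10000, mutation_rate = 0.01,
                               seed = 1L, sample_id = "sample_1") {
  stopifnot(inherits(truth, "synthetic_reference"))
  mix <- mixture_check(mixture, unique(truth$pool$category))
  mix <- mix[mix > 0]
  withr::with_seed(seed, {
    panel <- build_feature_panel(truth, mix, n_features, mutation_rate)
    probs <- unname(mix[panel$category]) / panel$n_in_category
    counts <- as.integer(rmultinom(1, total_reads, probs))
    profile <- community_profile(
      counts = tibble(feature_id = panel$feature_id, !!sample_id := counts),
      sequences = setNames(panel$sequence, panel$feature_id)
    )
    structure(list(
      profile = profile,
      truth = panel[c("feature_id", "category", "ancestor_id")],
      mixture = mix
    ), class = "synthetic_community")
  })
}

#' Generate a gradient community study
#'
#' Emulates gradient designs (salinity transects, chronosequences): a shared
#' feature panel is drawn covering every category present at either
#' endpoint, and sample i's expected composition linearly interpolates from
#' `from_mixture` to `to_mixture` at coordinate t = (i-1)/(n_samples-1),
#' which is recorded as the `gradient` covariate in the metadata.
#'
#' @inheritParams generate_community
#' @param n_samples Number of samples along the gradient (>= 3).
#' @param from_mixture,to_mixture Named endpoint mixtures, each summing
#'   to 1.
#' @return A `synthetic_gradient` list: `profile` (multi-sample
#'   [community_profile()]), `metadata` (tibble `sample_id`, `gradient`),
#'   `mixtures` (tibble of true per-sample proportions), and `truth` (the
#'   feature panel).
#' @export
generate_gradient_study <- function(truth, n_samples = 10,
                                    from_mixture, to_mixture,
                                    n_features = 30, total_reads = 10000,
                                    mutation_rate = 0.01, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_reference"))
  if (n_samples < 3) abort("generate_gradient_study needs n_samples >= 3")
  cats_all <- unique(truth$pool$category)
  from <- mixture_check(from_mixture, cats_all)
  to <- mixture_check(to_mixture, cats_all)
  cats <- union(names(from)[from > 0], names(to)[to > 0])
  from_full <- setNames(ifelse(cats %in% names(from), from[cats], 0), cats)
  to_full <- setNames(ifelse(cats %in% names(to), to[cats], 0), cats)
  from_full[is.na(from_full)] <- 0
  to_full[is.na(to_full)] <- 0
  withr::with_seed(seed, {
    mean_mix <- (from_full + to_full) / 2
    panel <- build_feature_panel(truth, mean_mix[mean_mix > 0], n_features, mutation_rate)
    t_coord <- (seq_len(n_samples) - 1) / (n_samples - 1)
    sample_ids <- sprintf("sample_%02d", seq_len(n_samples))
    counts <- tibble(feature_id = panel$feature_id)
    mixtures <- list()
    for (i in seq_len(n_samples)) {
      mix_i <- (1 - t_coord[i]) * from_full + t_coord[i] * to_full
      probs <- unname(mix_i[panel$category]) / panel$n_in_category
      probs[is.na(probs)] <- 0
      counts[[sample_ids[i]]] <- as.integer(rmultinom(1, total_reads, probs))
      mixtures[[i]] <- dplyr::bind_cols(tibble(sample_id = sample_ids[i],
                                               gradient = t_coord[i]),
                                        as_tibble(as.list(mix_i)))
    }
    profile <- community_profile(counts, setNames(panel$sequence, panel$feature_id))
    structure(list(
      profile = profile,
      metadata = tibble(sample_id = sample_ids, gradient = t_coord),
      mixtures = dplyr::bind_rows(mixtures),
      truth = panel[c("feature_id", "category", "ancestor_id")]
    ), class = "synthetic_gradient")
  })
}

#' Write a ready-to-run synthetic study directory
#'
#' Emits the same file formats the pipeline consumes: the reference FASTA
#' and label table (plus manifest) under `reference_db/`, the feature table,
#' feature FASTA, and (for gradient studies) the metadata TSV.
#'
#' @param study A `synthetic_community` or `synthetic_gradient`.
#' @param truth The [generate_reference_db()] result used to build it.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference_db(truth$db, file.path(dir, "reference_db"))
  profile <- study$profile
  write_feature_table(profile$counts, file.path(dir, "feature_table.tsv"))
  write_fasta(tibble(sequence_id = profile$feature_ids,
                     sequence = unname(profile$sequences)),
              file.path(dir, "features.fasta"))
  if (!is.null(study$metadata)) {
    readr::write_tsv(study$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  }
  readr::write_tsv(study$truth, file.path(dir, "feature_truth.tsv"), progress = FALSE)
  invisible(dir)
}
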