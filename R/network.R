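#' Category-by-representative composition matrix
#'
#' Tabulates, for each environmental category, how many of its reference
#' sequences map to each representative entry (e.g. a clustered centroid or
#' an external taxonomy entry). Categories whose references are all unmapped
#' are excluded with a warning.
#'
#' @param db A [habitat_ref()] tibble.
#' @param mapping Tibble (`reference_id`, `representative_id`) or named
#'   character vector mapping references to representative entries. Every
#'   mapped reference must exist in `db`; db references absent from the
#'   mapping are dropped with a warning.
#' @return A `category_composition` tibble: `category` plus one count column
#'   per representative.
#' @export
composition_matrix <- function(db, mapping) {
  map <- as_named_vector(mapping, "reference_id", "representative_id", "mapping")
  unknown <- setdiff(names(map), db$sequence_id)
  if (length(unknown)) {
    abort(sprintf("mapping references id(s) absent from the database: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  unmapped <- setdiff(db$sequence_id, names(map))
  if (length(unmapped)) {
    warn(sprintf("%d reference(s) without a representative are dropped", length(unmapped)))
  }
  sub <- db[db$sequence_id %in% names(map), ]
  lost <- setdiff(unique(db$category), unique(sub$category))
  if (length(lost)) {
    warn(sprintf("category(ies) excluded, all references unmapped: %s",
                 paste(lost, collapse = ", ")))
  }
  counts <- sub |>
    dplyr::mutate(representative_id = unname(map[.data$sequence_id])) |>
    dplyr::count(.data$category, .data$representative_id) |>
    tidyr::pivot_wider(names_from = "representative_id", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$category)
  class(counts) <- c("category_composition", class(tibble()))
  counts
}

composition_as_matrix <- function(x) {
  if (inherits(x, "category_composition") ||
      (is.data.frame(x) && "category" %in% names(x))) {
    m <- as.matrix(x[setdiff(names(x), "category")])
    rownames(m) <- x$category
    m
  } else {
    as.matrix(x)
  }
}

#' Greedy centroid clustering of reference sequences
#'
#' Desk-scale stand-in for mapping references onto an external
#' representative set: in input order, each sequence joins the first
#' existing centroid it aligns to at `identity_threshold` percent identity
#' or better over at least `params$min_aligned_length` bases, and otherwise
#' founds a new centroid. Deterministic given the input order.
#'
#' @param db A [habitat_ref()] tibble.
#' @param identity_threshold Percent identity required to join a centroid
#'   (default 97).
#' @param params A [search_params()] supplying the alignment scheme and
#'   minimum alignment span.
#' @return A tibble (`reference_id`, `representative_id`) where the
#'   representative is the founding sequence's id.
#' @export
cluster_representatives <- function(db, identity_threshold = 97,
                                    params = search_params()) {
  if (nrow(db) == 0) abort("cannot cluster an empty database")
  join_params <- params
  join_params$min_percent_identity <- identity_threshold
  centroid_ids <- character(0)
  centroid_seqs <- character(0)
  centroid_kmers <- list()
  assignment <- character(nrow(db))
  for (i in seq_len(nrow(db))) {
    s <- db$sequence[i]
    km <- unique(sequence_kmers(s, params$kmer_size))
    joined <- NA_character_
    for (j in seq_along(centroid_ids)) {
      if (!length(intersect(km, centroid_kmers[[j]]))) next
      hit <- align_pair(s, centroid_seqs[j], join_params)
      if (nrow(hit)) { joined <- centroid_ids[j]; break }
    }
    if (is.na(joined)) {
      centroid_ids <- c(centroid_ids, db$sequence_id[i])
      centroid_seqs <- c(centroid_seqs, s)
      centroid_kmers[[length(centroid_ids)]] <- km
      joined <- db$sequence_id[i]
    }
    assignment[i] <- joined
  }
  tibble(reference_id = db$sequence_id, representative_id = assignment)
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v))`: 0 for identical
#' compositions, 1 for disjoint supports. Computed through
#' `vegan::vegdist`.
#'
#' @param u,v Non-negative numeric vectors of equal length with positive
#'   sums.
#' @return A single dissimilarity in \[0, 1\].
#' @export
#' @examples
#' bray_curtis(c(2, 1), c(1, 1)) # 0.2
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) abort("u and v must have equal length")
  if (any(u < 0) || any(v < 0)) abort("Bray-Curtis requires non-negative vectors")
  if (sum(u) == 0 || sum(v) == 0) abort("Bray-Curtis is undefined for zero-sum vectors")
  as.numeric(vegan::vegdist(rbind(u, v), method = "bray"))
}

#' Build the environment co-occurrence network
#'
#' Categories become nodes; an undirected, unweighted edge joins two
#' categories whenever the Bray-Curtis dissimilarity of their representative
#' compositions is strictly below `threshold` (default 0.9). Node centrality
#' is the pair-counting betweenness of [betweenness_pairs()] by default, or
#' the standard fractional (Freeman) betweenness with
#' `betweenness = "fractional"`.
#'
#' @param x A [composition_matrix()] result (or a numeric matrix with
#'   category rownames).
#' @param threshold Edge rule: dissimilarity < threshold (strict).
#' @param betweenness `"pairs"` (default) or `"fractional"`.
#' @return A `category_network`: list with `nodes` (tibble `category`,
#'   `betweenness`), `edges` (tibble `from`, `to`, `bray_curtis`),
#'   `dissimilarity` (matrix), `threshold`, and the `igraph` `graph`.
#' @export
build_network <- function(x, threshold = 0.9, betweenness = c("pairs", "fractional")) {
  betweenness <- match.arg(betweenness)
  m <- composition_as_matrix(x)
  if (nrow(m) < 2) abort("build_network needs at least 2 categories")
  if (any(rowSums(m) <= 0)) abort("every category needs a positive composition row sum")
  D <- as.matrix(vegan::vegdist(m, method = "bray"))
  pairs <- which(upper.tri(D) & D < threshold, arr.ind = TRUE)
  edges <- tibble(
    from = rownames(D)[pairs[, 1]],
    to = rownames(D)[pairs[, 2]],
    bray_curtis = D[pairs]
  )
  g <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = FALSE,
                                     vertices = rownames(D))
  btw <- if (betweenness == "pairs") {
    betweenness_pairs_vector(g)
  } else {
    igraph::betweenness(g, directed = FALSE)
  }
  nodes <- tibble(category = rownames(D),
                  betweenness = unname(btw[rownames(D)]))
  structure(list(nodes = nodes, edges = edges, dissimilarity = D,
                 threshold = threshold, betweenness_kind = betweenness, graph = g),
            class = "category_network")
}

#' @export
print.category_network <- function(x, ...) {
  cat(sprintf("<category_network> %d categories, %d edges (Bray-Curtis < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' @export
tidy.category_network <- function(x, ...) x$edges

#' @export
glance.category_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_components = igraph::count_components(x$graph),
    threshold = x$threshold,
    betweenness = x$betweenness_kind
  )
}

betweenness_pairs_vector <- function(g) {
  D <- igraph::distances(g)
  nodes <- rownames(D)
  n <- length(nodes)
  out <- setNames(numeric(n), nodes)
  if (n < 3) return(out)
  for (v in seq_len(n)) {
    others <- setdiff(seq_len(n), v)
    cnt <- 0
    for (a in seq_along(others)) {
      s <- others[a]
      if (a == length(others)) break
      for (t in others[(a + 1):length(others)]) {
        d <- D[s, t]
        if (is.finite(d) && D[s, v] + D[v, t] == d) cnt <- cnt + 1
      }
    }
    out[v] <- cnt
  }
  out
}

#' Pair-counting betweenness centrality
#'
#' For each node v, counts the unordered pairs \{s, t\} (s, t distinct from
#' v and connected to each other) such that at least one shortest s-t path
#' passes through v. This counts each pair once, unlike the standard
#' fractional betweenness which splits credit across all shortest paths.
#' Disconnected pairs contribute nothing; the graph may be disconnected.
#'
#' @param graph An `igraph` object, a two-column edge data frame, or a
#'   [build_network()] result.
#' @param nodes Optional full node set (for isolated vertices) when `graph`
#'   is an edge data frame.
#' @return A tibble (`node`, `betweenness`).
#' @export
#' @examples
#' betweenness_pairs(data.frame(from = c("A", "B"), to = c("B", "C")))
betweenness_pairs <- function(graph, nodes = NULL) {
  g <- if (inherits(graph, "category_network")) {
    graph$graph
  } else if (igraph::is_igraph(graph)) {
    graph
  } else if (is.data.frame(graph)) {
    stopifnot(ncol(graph) >= 2)
    verts <- nodes %||% unique(c(as.character(graph[[1]]), as.character(graph[[2]])))
    igraph::graph_from_data_frame(graph[1:2], directed = FALSE, vertices = verts)
  } else {
    abort("graph must be an igraph object, an edge data frame, or a category_network")
  }
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  v <- betweenness_pairs_vector(g)
  tibble(node = names(v), betweenness = unname(v))
}

#' Export a network as edge-list and node TSVs
#' @param net A [build_network()] result.
#' @param edges_path,nodes_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(net, edges_path, nodes_path) {
  readr::write_tsv(net$edges, edges_path, progress = FALSE)
  readr::write_tsv(net$nodes, nodes_path, progress = FALSE)
  invisible(c(edges_path, nodes_path))
}
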