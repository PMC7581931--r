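test_that("composition_matrix tabulates category-by-representative counts", {
  db <- habitat_ref(tibble::tibble(
    sequence_id = c("a1", "a2", "b1"),
    sequence = "ACGT",
    category = c("soil", "soil", "marine"),
    project_id = "p"))
  m <- composition_matrix(db, c(a1 = "rep1", a2 = "rep1", b1 = "rep1"))
  expect_equal(m$rep1[m$category == "soil"], 2L)
  expect_equal(m$rep1[m$category == "marine"], 1L)

  w <- capture_warnings(m2 <- composition_matrix(db, c(a1 = "rep1", a2 = "rep1")))
  expect_true(any(grepl("without a representative", w)))
  expect_true(any(grepl("excluded.*marine", w)))
  expect_false("marine" %in% m2$category)

  expect_error(composition_matrix(db, c(zz = "rep1")), "absent")

  # identity mapping: each reference its own representative, one count each
  m3 <- composition_matrix(db, setNames(db$sequence_id, db$sequence_id))
  counts <- as.matrix(m3[setdiff(names(m3), "category")])
  expect_equal(colSums(counts)[sort(db$sequence_id)],
               setNames(c(1, 1, 1), sort(db$sequence_id)))
  expect_true(all(counts %in% c(0, 1)))
})

test_that("greedy clustering merges near-identical sequences only", {
  p <- search_params(min_aligned_length = 80, kmer_size = 12, min_seed_count = 1)
  withr::with_seed(61, {
    base <- random_seq(120)
    db_same <- habitat_ref(tibble::tibble(
      sequence_id = c("x", "y"), sequence = base,
      category = "soil", project_id = "p"))
    map_same <- cluster_representatives(db_same, 97, p)
    expect_equal(unique(map_same$representative_id), "x")

    db_diff <- habitat_ref(tibble::tibble(
      sequence_id = c("x", "y"), sequence = c(random_seq(120), random_seq(120)),
      category = "soil", project_id = "p"))
    map_diff <- cluster_representatives(db_diff, 97, p)
    expect_equal(dplyr::n_distinct(map_diff$representative_id), 2)
  })
})

test_that("one ancestor's 1%-mutated copies collapse to a single representative", {
  withr::with_seed(67, {
    anc <- random_seq(500)
    copies <- vapply(1:10, function(i) {
      b <- strsplit(anc, "")[[1]]
      hit <- which(runif(length(b)) < 0.01)
      for (j in hit) b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1)
      paste(b, collapse = "")
    }, character(1))
  })
  db <- habitat_ref(tibble::tibble(
    sequence_id = sprintf("c%02d", 1:10), sequence = copies,
    category = "soil", project_id = "p"))
  p <- search_params(min_aligned_length = 150, kmer_size = 12, min_seed_count = 1)
  map <- cluster_representatives(db, 97, p)
  expect_equal(dplyr::n_distinct(map$representative_id), 1)
  # oracle: all pairwise identities really are >= 97%
  for (i in 1:9) {
    for (j in (i + 1):10) {
      o <- oracle_sw(copies[i], copies[j])
      expect_gte(100 * o$matches / o$aligned_length, 97)
    }
  }
})

test_that("bray_curtis follows the min-overlap formula", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_error(bray_curtis(c(0, 0), c(1, 1)), "zero-sum")
})

test_that("bray_curtis is symmetric, bounded, permutation- and scale-stable", {
  withr::with_seed(71, {
    for (i in 1:20) {
      u <- rpois(6, 5) + c(1, rep(0, 5))
      v <- rpois(6, 5) + c(1, rep(0, 5))
      bc <- bray_curtis(u, v)
      expect_gte(bc, 0); expect_lte(bc, 1)
      expect_equal(bc, bray_curtis(v, u))
      # joint coordinate permutation
      perm <- sample(6)
      expect_equal(bc, bray_curtis(u[perm], v[perm]))
      # joint scaling
      expect_equal(bc, bray_curtis(3 * u, 3 * v), tolerance = 1e-12)
      # formula oracle
      expect_equal(bc, 1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v)),
                   tolerance = 1e-12)
    }
  })
})

test_that("build_network applies the strict dissimilarity threshold", {
  m <- tibble::tibble(category = c("a", "b"), r1 = c(3L, 3L), r2 = c(1L, 1L))
  net <- build_network(m, threshold = 0.9)
  expect_equal(nrow(net$edges), 1) # identical compositions, BC = 0

  m2 <- tibble::tibble(category = c("a", "b"), r1 = c(3L, 0L), r2 = c(0L, 2L))
  expect_equal(nrow(build_network(m2, threshold = 0.9)$edges), 0) # BC = 1

  expect_equal(nrow(build_network(m, threshold = 0)$edges), 0) # strict <

  expect_error(build_network(m[1, ]), "at least 2")
})

test_that("raising the network threshold never removes an edge", {
  withr::with_seed(73, {
    m <- tibble::tibble(category = sprintf("c%d", 1:6))
    for (r in 1:8) m[[paste0("r", r)]] <- rpois(6, 2)
    m[rowSums(m[-1]) == 0, 2] <- 1L
    prev <- -1
    for (th in c(0.2, 0.5, 0.7, 0.9, 1.01)) {
      n <- nrow(build_network(m, threshold = th)$edges)
      expect_gte(n, prev)
      prev <- n
    }
  })
})

test_that("pair-counting betweenness matches hand cases", {
  path_net <- betweenness_pairs(data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_equal(setNames(path_net$betweenness, path_net$node),
               c(A = 0, B = 1, C = 0))

  star <- betweenness_pairs(data.frame(from = "hub", to = c("l1", "l2", "l3")))
  v <- setNames(star$betweenness, star$node)
  expect_equal(v[["hub"]], 3) # choose(3, 2)
  expect_equal(unname(v[c("l1", "l2", "l3")]), c(0, 0, 0))

  # complete graph: no pair needs an intermediary
  cg <- igraph::make_full_graph(5)
  expect_true(all(betweenness_pairs(cg)$betweenness == 0))
})

test_that("pair-counting betweenness equals brute-force path enumeration", {
  withr::with_seed(79, {
    for (i in 1:25) {
      n <- sample(3:7, 1)
      adj <- matrix(0L, n, n)
      for (a in 1:(n - 1)) {
        for (b in (a + 1):n) {
          if (runif(1) < 0.4) adj[a, b] <- adj[b, a] <- 1L
        }
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      igraph::V(g)$name <- paste0("n", seq_len(n))
      got <- betweenness_pairs(g)
      want <- oracle_betweenness_pairs(adj)
      expect_equal(got$betweenness, want)
    }
  })
})

test_that("pair-counting betweenness on trees counts pairs crossing each node", {
  # path of 5 nodes: inner node i separates (left count) x (right count) pairs
  edges <- data.frame(from = paste0("n", 1:4), to = paste0("n", 2:5))
  got <- betweenness_pairs(edges)
  expect_equal(setNames(got$betweenness, got$node),
               c(n1 = 0, n2 = 3, n3 = 4, n4 = 3, n5 = 0))
})

test_that("network construction end-to-end from a synthetic database", {
  truth <- generate_reference_db(simulation_config(
    n_categories = 3, pool_size_per_category = 8, seq_length = 250,
    overlap = matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), 3, 3), seed = 83))
  p <- search_params(min_aligned_length = 100, kmer_size = 12, min_seed_count = 1)
  mapping <- cluster_representatives(truth$db, 97, p)
  mat <- composition_matrix(truth$db, mapping)
  net <- build_network(mat, threshold = 0.9)
  expect_equal(nrow(net$nodes), 3)
  # heavily overlapping pools are joined, the disjoint one is not
  expect_true(any(net$edges$from == "cat_a" & net$edges$to == "cat_b"))
  expect_false(any(grepl("cat_c", c(net$edges$from, net$edges$to))))
  g <- glance(net)
  expect_equal(g$n_nodes, 3)
  expect_equal(tidy(net), net$edges)
})
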