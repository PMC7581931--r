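test_that("mann_whitney_u reproduces exact textbook cases", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  r2 <- mann_whitney_u(1:5, 6:10)
  expect_equal(r2$U, 0)
  expect_equal(r2$p_value, 2 / 252, tolerance = 1e-12)

  # identical multisets: U = n^2 / 2 under midranks
  r3 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$U, 9 / 2)
  expect_equal(r3$method, "normal_approx_tie_corrected")

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("U(x) + U(y) = n_x * n_y under midranks", {
  withr::with_seed(13, {
    for (i in 1:20) {
      x <- sample(1:10, sample(2:8, 1), replace = TRUE)
      y <- sample(1:10, sample(2:8, 1), replace = TRUE)
      ux <- mann_whitney_u(x, y)$U
      uy <- mann_whitney_u(y, x)$U
      expect_equal(ux + uy, length(x) * length(y))
    }
  })
})

test_that("exact p-values match full enumeration for tie-free small samples", {
  withr::with_seed(17, {
    for (nx in 2:6) {
      for (ny in 2:6) {
        vals <- sample(seq(0, 1, length.out = 200), nx + ny)
        x <- vals[seq_len(nx)]
        y <- vals[nx + seq_len(ny)]
        got <- mann_whitney_u(x, y)
        want <- oracle_mw_exact(x, y)
        expect_equal(got$U, want$U)
        expect_equal(got$p_value, want$p, tolerance = 1e-12)
      }
    }
  })
})

test_that("spearman_rho matches rank-then-Pearson and handles monotone cases", {
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 4, 9))$rho, 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  withr::with_seed(19, {
    for (i in 1:20) {
      x <- rnorm(10)
      y <- rnorm(10)
      got <- spearman_rho(x, y)$rho
      want <- stats::cor(rank(x), rank(y), method = "pearson")
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  withr::with_seed(23, {
    x <- rnorm(12)
    y <- rnorm(12)
    base <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(exp(x), y)$rho, base)
    expect_equal(spearman_rho(x, y^3 + 5 * y)$rho, base)
    expect_equal(spearman_rho(rank(x), y)$rho, base)
  })
})

make_score_matrix <- function(values, categories = names(values[[1]])) {
  rows <- lapply(names(values), function(sid) {
    tibble::tibble(sample_id = sid, mapped = TRUE,
                   coverage_features = 1, coverage_reads = 1,
                   !!!as.list(values[[sid]]))
  })
  habscore:::new_score_matrix(dplyr::bind_rows(rows), categories)
}

test_that("group_score_test compares in-group vs out-group score sums", {
  mat <- make_score_matrix(list(
    a1 = c(soil = 0.9, marine = 0.1),
    a2 = c(soil = 0.8, marine = 0.2),
    b1 = c(soil = 0.1, marine = 0.9),
    b2 = c(soil = 0.2, marine = 0.8)))
  labels <- c(a1 = "soil_src", a2 = "soil_src", b1 = "sea_src", b2 = "sea_src")
  r <- group_score_test(mat, labels, "soil_src", "soil")
  expect_equal(r$n_in, 2)
  expect_equal(r$n_out, 2)
  expect_equal(r$U, 4) # in-group statistic; out-group U is 0
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$median_in, 0.85)
  expect_equal(r$median_out, 0.15)

  # identical in/out distributions: exact p = 1
  mat2 <- make_score_matrix(list(
    a1 = c(soil = 0.30, marine = 0.70), a2 = c(soil = 0.70, marine = 0.30),
    b1 = c(soil = 0.31, marine = 0.69), b2 = c(soil = 0.69, marine = 0.31)))
  r2 <- group_score_test(mat2, c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2"),
                         "g1", "soil")
  expect_equal(r2$p_value, 1)

  expect_error(
    group_score_test(mat, c(a1 = "x", a2 = "x", b1 = "x", b2 = "x"), "x", "soil"),
    "with and without")
})

test_that("in-group medians exceed out-group medians on targeted synthetic data", {
  wins <- 0L
  for (seed in 1:3) {
    truth <- generate_reference_db(simulation_config(
      n_categories = 2, pool_size_per_category = 15, seq_length = 300, seed = seed))
    samples <- list()
    labels <- character(0)
    for (i in 1:3) {
      comm <- generate_community(truth, c(cat_a = 0.8, cat_b = 0.2),
                                 n_features = 8, total_reads = 2000,
                                 seed = seed * 50 + i,
                                 sample_id = sprintf("in_%d", i))
      samples[[length(samples) + 1]] <- comm
      labels[sprintf("in_%d", i)] <- "target"
      comm2 <- generate_community(truth, c(cat_a = 0.2, cat_b = 0.8),
                                  n_features = 8, total_reads = 2000,
                                  seed = seed * 50 + 25 + i,
                                  sample_id = sprintf("out_%d", i))
      samples[[length(samples) + 1]] <- comm2
      labels[sprintf("out_%d", i)] <- "background"
    }
    idx <- build_index(truth$db, 12)
    mats <- lapply(samples, function(s) score_matrix(s$profile, truth$db, index = idx))
    mat <- dplyr::bind_rows(lapply(mats, tibble::as_tibble))
    mat <- habscore:::new_score_matrix(mat, c("cat_a", "cat_b"))
    r <- group_score_test(mat, labels, "target", "cat_a")
    if (r$median_in > r$median_out) wins <- wins + 1L
  }
  expect_equal(wins, 3L)
})

test_that("gradient_correlation relates grouped scores to a covariate", {
  mat <- make_score_matrix(list(
    s1 = c(brine = 0.1, soil = 0.9),
    s2 = c(brine = 0.2, soil = 0.8),
    s3 = c(brine = 0.3, soil = 0.7)))
  r <- gradient_correlation(mat, c(s1 = 1, s2 = 2, s3 = 3), "brine")
  expect_equal(r$rho, 1)
  expect_equal(r$n, 3)

  expect_error(
    suppressWarnings(gradient_correlation(mat, c(s1 = 1, s2 = 2), "brine")),
    ">= 3 usable")
  expect_warning(
    gradient_correlation(
      make_score_matrix(list(s1 = c(brine = 0.1), s2 = c(brine = 0.2),
                             s3 = c(brine = 0.3), s4 = c(brine = 0.4))),
      c(s1 = 1, s2 = 2, s3 = 3), "brine"),
    "without scores or gradient")
  # constant grouped scores are a hard error from the correlation layer
  expect_error(
    gradient_correlation(
      make_score_matrix(list(s1 = c(brine = 0.5), s2 = c(brine = 0.5),
                             s3 = c(brine = 0.5))),
      c(s1 = 1, s2 = 2, s3 = 3), "brine"),
    "constant")
})

test_that("group_score_tests adds BH correction across groups on request", {
  mat <- make_score_matrix(list(
    a1 = c(soil = 0.9, marine = 0.05, gut = 0.05),
    a2 = c(soil = 0.8, marine = 0.15, gut = 0.05),
    b1 = c(soil = 0.1, marine = 0.85, gut = 0.05),
    b2 = c(soil = 0.2, marine = 0.75, gut = 0.05)))
  labels <- c(a1 = "in", a2 = "in", b1 = "out", b2 = "out")
  res <- group_score_tests(mat, labels, "in",
                           list(soil_rel = "soil", brine = "marine"),
                           adjust = TRUE)
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_adjusted >= res$p_value))
})
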