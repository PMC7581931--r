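# Independent oracles used by the property tests. These are deliberately
# plain, full-matrix R implementations, kept separate from the package's
# code paths.

# Exhaustive affine-gap Smith-Waterman over full score matrices.
# Same conventions as the package aligner: a gap of length L scores
# gap_open + L * gap_extend; N never matches; best cell is the first maximum
# in row-major order; traceback prefers substitution, then gap-in-reference
# (up), then gap-in-query (left), and gap opening over extension on ties.
oracle_sw <- function(q, s, match = 1, mismatch = -2, gap_open = -5, gap_extend = -2) {
  qb <- strsplit(q, "")[[1]]
  sb <- strsplit(s, "")[[1]]
  n <- length(qb); m <- length(sb)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F_ <- matrix(NEG, n + 1, m + 1)
  subst <- function(a, b) if (a == b && a %in% c("A", "C", "G", "T")) match else mismatch
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend, E[i, j - 1] + gap_extend)
      F_[i, j] <- max(H[i - 1, j] + gap_open + gap_extend, F_[i - 1, j] + gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + subst(qb[i - 1], sb[j - 1]), F_[i, j], E[i, j])
    }
  }
  best <- max(H)
  if (best <= 0) {
    return(list(score = 0, matches = 0, mismatches = 0, gap_openings = 0,
                aligned_length = 0))
  }
  hit <- which(t(H) == best, arr.ind = TRUE) # t() => row-major order
  j <- hit[1, 1]; i <- hit[1, 2]
  matches <- 0; mismatches <- 0; gap_open_n <- 0; gap_bases <- 0
  state <- "H"
  while (TRUE) {
    if (state == "H") {
      if (H[i, j] <= 0) break
      diag <- H[i - 1, j - 1] + subst(qb[i - 1], sb[j - 1])
      if (diag == H[i, j]) {
        if (subst(qb[i - 1], sb[j - 1]) == match) matches <- matches + 1
        else mismatches <- mismatches + 1
        i <- i - 1; j <- j - 1
      } else if (F_[i, j] == H[i, j]) {
        state <- "F"
      } else {
        state <- "E"
      }
    } else if (state == "E") {
      gap_bases <- gap_bases + 1
      if (H[i, j - 1] + gap_open + gap_extend == E[i, j]) {
        gap_open_n <- gap_open_n + 1; state <- "H"
      }
      j <- j - 1
    } else {
      gap_bases <- gap_bases + 1
      if (H[i - 1, j] + gap_open + gap_extend == F_[i, j]) {
        gap_open_n <- gap_open_n + 1; state <- "H"
      }
      i <- i - 1
    }
  }
  list(score = best, matches = matches, mismatches = mismatches,
       gap_openings = gap_open_n,
       aligned_length = matches + mismatches + gap_bases)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of rank
# assignments (tie-free inputs only).
oracle_mw_exact <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  nx <- length(x); ny <- length(y); n <- nx + ny
  u_obs <- sum(outer(x, y, ">"))
  ranks <- seq_len(n)
  combos <- utils::combn(n, nx)
  mid <- nx * ny / 2
  u_all <- apply(combos, 2, function(ix) {
    rx <- ranks[ix]
    sum(rx) - nx * (nx + 1) / 2 # rank-sum identity for U
  })
  list(U = u_obs, p = mean(abs(u_all - mid) >= abs(u_obs - mid)))
}

# Brute-force pair-counting betweenness: enumerate every shortest path of
# every connected pair via BFS predecessor recursion, and count, per node,
# the pairs for which it appears strictly inside at least one such path.
oracle_betweenness_pairs <- function(adj) {
  n <- nrow(adj)
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; queue <- c(queue, w) }
      }
    }
    d
  }
  all_paths <- function(s, t, d) {
    # every shortest s-t path, walking back from t through predecessors
    walk <- function(w) {
      if (w == s) return(list(s))
      preds <- which(adj[, w] == 1 & d == d[w] - 1)
      unlist(lapply(preds, function(p) {
        lapply(walk(p), function(path) c(path, w))
      }), recursive = FALSE)
    }
    walk(t)
  }
  counts <- rep(0, n)
  for (s in seq_len(n - 1)) {
    d <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (is.infinite(d[t])) next
      inner <- unique(unlist(lapply(all_paths(s, t, d), function(p) {
        setdiff(p, c(s, t))
      })))
      counts[inner] <- counts[inner] + 1
    }
  }
  counts
}

# Small helpers for fixture construction ------------------------------------

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

make_toy_db <- function(categories, n_per_cat = 2, len = 200, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(categories, function(cat) {
      tibble::tibble(
        sequence_id = sprintf("%s_ref_%d", cat, seq_len(n_per_cat)),
        sequence = vapply(seq_len(n_per_cat), function(i) random_seq(len), character(1)),
        category = cat,
        project_id = paste0(cat, "_p1")
      )
    })
    habitat_ref(dplyr::bind_rows(rows))
  })
}

write_toy_fasta <- function(df, path) {
  writeLines(paste0(">", df$sequence_id, "\n", df$sequence), path)
  path
}
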