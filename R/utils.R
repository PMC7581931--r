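# Internal helpers shared across modules.

# DNA alphabet accepted throughout the package: A, C, G, T plus N for
# ambiguous calls. Other IUPAC degeneracy codes are rejected at load.
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

assert_dna <- function(sequences, ids = names(sequences), context = "sequence") {
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    offenders <- if (is.null(ids)) which(bad) else ids[bad]
    abort(sprintf(
      "%d %s(s) contain characters outside {A,C,G,T,N}: %s",
      sum(bad), context, paste(head(offenders, 5), collapse = ", ")
    ))
  }
  if (any(!nzchar(sequences))) {
    abort(sprintf("empty %s(s) are not allowed", context))
  }
  invisible(sequences)
}

reverse_complement <- function(sequence) {
  vapply(sequence, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Enumerate the k-mers of one sequence; windows containing N are dropped.
sequence_kmers <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1)
  kmers <- substring(sequence, starts, starts + k - 1)
  keep <- !grepl("N", kmers, fixed = TRUE)
  structure(kmers[keep], offset = starts[keep])
}

# Largest-remainder allocation of `n` integer slots to proportions `p`.
largest_remainder <- function(p, n) {
  stopifnot(all(p >= 0), n >= 0)
  if (sum(p) == 0) return(rep(0L, length(p)))
  quota <- n * p / sum(p)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    order_rem <- order(quota - base, decreasing = TRUE)
    base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
  }
  as.integer(base)
}

as_named_vector <- function(x, name_col, value_col, what) {
  if (is.data.frame(x)) {
    if (!all(c(name_col, value_col) %in% names(x))) {
      abort(sprintf("%s must have columns '%s' and '%s'", what, name_col, value_col))
    }
    setNames(x[[value_col]], x[[name_col]])
  } else if (!is.null(names(x))) {
    x
  } else {
    abort(sprintf("%s must be a named vector or a data frame", what))
  }
}
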