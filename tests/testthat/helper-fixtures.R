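# Shared fixture builders for the test suite. All randomness is seeded at
# the call site so fixtures are reproducible.

# small hand-buildable dosage table
make_dosage_tbl <- function(m, cultivars = sprintf("CV%02d", seq_len(nrow(m))),
                            markers = sprintf("M%02d", seq_len(ncol(m)))) {
  storage.mode(m) <- "integer"
  colnames(m) <- markers
  dplyr::bind_cols(tibble::tibble(cultivar = cultivars), tibble::as_tibble(m))
}

# a random valid dosage table
random_dosage_tbl <- function(n, L, seed, missing_rate = 0) {
  set.seed(seed)
  m <- matrix(sample(0:4, n * L, replace = TRUE), n, L)
  if (missing_rate > 0) m[runif(n * L) < missing_rate] <- NA_integer_
  make_dosage_tbl(m)
}

# brute-force complete-linkage agglomeration: returns sorted merge heights
brute_complete_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# independent per-locus Kosman oracle: shared-allele-count formulation
kosman_oracle_locus <- function(x, y) {
  1 - (min(x, y) + min(4 - x, 4 - y)) / 4
}

# simulate a standard 90-sample plate of balanced dosages
balanced_truth <- function(n_per_class = 18) {
  stats::setNames(rep(0:4, each = n_per_class),
                  sprintf("S%03d", seq_len(5 * n_per_class)))
}
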