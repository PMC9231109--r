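# Per-marker population statistics and the genotype accumulation curve.

#' Reference-allele frequency of a marker
#'
#' Sum of reference-allele dosages divided by 4 x the number of non-missing
#' calls.
#'
#' @param dosages A dosage table.
#' @param marker Marker id (column name). If omitted, frequencies for all
#'   markers are returned as a named vector.
#' @return Numeric frequency (or named vector).
#' @export
ref_freq <- function(dosages, marker = NULL) {
  validate_dosage_table(dosages)
  f <- marker_ref_freqs(dosages)
  if (is.null(marker)) return(f)
  if (!marker %in% names(f)) abort(sprintf("unknown marker '%s'", marker))
  if (is.nan(f[[marker]])) abort(sprintf("marker '%s' has no non-missing dosage", marker))
  f[[marker]]
}

#' Polymorphism information content of a bi-allelic marker
#'
#' PIC = 1 - REF^2 - (1 - REF)^2, which peaks at 0.5 for a balanced
#' frequency and vanishes for a fixed allele.
#'
#' @param ref_freq Reference-allele frequency in \[0, 1\]. Vectorised.
#' @return PIC in \[0, 0.5\].
#' @examples
#' pic(c(0.5, 0.25, 1))
#' @export
pic <- function(ref_freq) {
  if (any(ref_freq < 0 | ref_freq > 1, na.rm = TRUE)) {
    abort("`ref_freq` must lie in [0, 1].")
  }
  1 - ref_freq^2 - (1 - ref_freq)^2
}

#' Per-marker summary statistics
#'
#' @param dosages A dosage table.
#' @return Tibble with one row per marker: `marker_id`, `n_called`,
#'   `ref_freq`, `maf` (= min(REF, 1-REF)), `pic`, `monomorphic` (single
#'   distinct non-missing dosage).
#' @export
marker_summary <- function(dosages) {
  validate_dosage_table(dosages)
  m <- dosage_matrix(dosages)
  if (nrow(m) == 0) abort("empty dosage table.")
  f <- marker_ref_freqs(dosages)
  tibble(
    marker_id = colnames(m),
    n_called = colSums(!is.na(m)),
    ref_freq = unname(f),
    maf = pmin(unname(f), 1 - unname(f)),
    pic = pic(unname(f)),
    monomorphic = apply(m, 2, function(col) length(unique(col[!is.na(col)])) <= 1)
  )
}

# Count distinguishable multilocus genotypes in a dosage matrix restricted to
# `loci`. A missing value is treated as compatible with any dosage, so two
# profiles are counted apart only when they provably differ at an observed
# locus; indistinguishability components are found by union-find.
count_distinct_profiles <- function(m, loci) {
  sub <- m[, loci, drop = FALSE]
  if (!anyNA(sub)) {
    return(length(unique(apply(sub, 1, paste, collapse = ","))))
  }
  n <- nrow(sub)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(sub[i, ]) & !is.na(sub[j, ])
      if (!any(ok) || all(sub[i, ok] == sub[j, ok])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Genotype accumulation curve
#'
#' For each loci count k = 1..`max_loci`, draws random k-subsets of markers
#' (without replacement) and counts the distinguishable multilocus genotypes
#' among the cultivars; the curve of mean counts against k shows how many
#' loci a fingerprinting panel needs. When the number of possible k-subsets
#' does not exceed `n_perm` the subsets are enumerated exhaustively and the
#' mean is exact.
#'
#' Profiles with missing dosages are matched conservatively: a missing value
#' is compatible with any dosage, so missingness never inflates the apparent
#' number of distinguishable genotypes.
#'
#' @param dosages A dosage table.
#' @param max_loci Largest subset size (default: all markers, capped at 100).
#' @param n_perm Random subsets per k (default 100).
#' @param seed Integer seed (required; the curve is resampled).
#' @return An object of class `accum_curve`: tibble (`n_loci`,
#'   `mean_genotypes`, `exact`) with attributes `n_perm`, `seed`,
#'   `n_cultivars`, `max_distinct`.
#' @export
accumulation_curve <- function(dosages, max_loci = NULL, n_perm = 100, seed) {
  validate_dosage_table(dosages)
  if (missing(seed)) abort("`seed` is required.")
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  m <- dosage_matrix(dosages)
  L <- ncol(m)
  max_loci <- min(max_loci %||% min(L, 100L), L)
  if (max_loci < 1) abort("`max_loci` must be >= 1.")
  set.seed(as.integer(seed))
  res <- purrr::map(seq_len(max_loci), function(k) {
    n_sub <- suppressWarnings(choose(L, k))
    if (is.finite(n_sub) && n_sub <= n_perm) {
      subs <- combn(L, k, simplify = FALSE)
      exact <- TRUE
    } else {
      subs <- replicate(n_perm, sample.int(L, k), simplify = FALSE)
      exact <- FALSE
    }
    counts <- vapply(subs, function(s) count_distinct_profiles(m, s), numeric(1))
    tibble(n_loci = k, mean_genotypes = mean(counts), exact = exact)
  }) |> list_rbind()
  structure(res, class = c("accum_curve", class(res)),
            n_perm = n_perm, seed = seed, n_cultivars = nrow(m),
            max_distinct = count_distinct_profiles(m, seq_len(L)))
}

#' @rdname accumulation_curve
#' @param x An `accum_curve`.
#' @param ... Unused.
#' @export
tidy.accum_curve <- function(x, ...) as_tibble(unclass(x))

#' @rdname accumulation_curve
#' @export
glance.accum_curve <- function(x, ...) {
  tibble(n_cultivars = attr(x, "n_cultivars"),
         max_distinct = attr(x, "max_distinct"),
         n_perm = attr(x, "n_perm"),
         max_loci = max(x$n_loci),
         plateau = max(x$mean_genotypes))
}

#' @export
autoplot.accum_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$n_loci, y = .data$mean_genotypes)) +
    geom_line(colour = "steelblue") +
    geom_point(size = 0.8) +
    geom_hline(yintercept = attr(object, "n_cultivars"), linetype = "dashed") +
    labs(x = "Number of loci sampled",
         y = "Mean multilocus genotypes distinguished") +
    theme_classic()
}

#' Export an accumulation curve as CSV
#'
#' @param curve An `accum_curve`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_accumulation_csv <- function(curve, path) {
  readr::write_csv(select(as_tibble(unclass(curve)), "n_loci", "mean_genotypes"), path)
  invisible(path)
}
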