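# Random match probability, collision sizing, and the two fingerprinting
# service tools (marker-subset selection, identity assignment).

#' Tetraploid genotype-class frequency under random mating
#'
#' For a bi-allelic tetraploid locus with reference-allele frequency `p`,
#' the expected population frequency of the five dosage classes under random
#' mating (chromosomal segregation) is binomial: the nulliplex class has
#' frequency \eqn{q^4}, simplex \eqn{4pq^3}, duplex \eqn{6p^2q^2}, triplex
#' \eqn{4p^3q} and quadruplex \eqn{p^4}, with \eqn{q = 1 - p}. At a balanced
#' frequency (p = 0.5) these are 0.0625, 0.25, 0.375, 0.25, 0.0625.
#'
#' @param ref_freq Reference-allele frequency, in \[0, 1\]. Vectorised.
#' @param dosage Reference-allele dosage, integer in 0..4. Vectorised.
#' @return Numeric vector of class frequencies.
#' @examples
#' genotype_class_freq(0.5, 0:4)
#' @export
genotype_class_freq <- function(ref_freq, dosage) {
  if (any(ref_freq < 0 | ref_freq > 1, na.rm = TRUE)) {
    abort("`ref_freq` must lie in [0, 1].")
  }
  if (any(dosage != as.integer(dosage) | dosage < 0 | dosage > PLOIDY, na.rm = TRUE)) {
    abort("`dosage` must be an integer in 0..4.")
  }
  dbinom(dosage, size = PLOIDY, prob = ref_freq)
}

#' Random match probability of a multilocus dosage profile
#'
#' Applies the product rule: the per-locus genotype-class frequencies of the
#' profile are multiplied across (assumed independent) markers. No diploid
#' heterozygote x2 factor applies to tetraploid dosage classes. The
#' reciprocal, rounded to the nearest integer, gives the familiar
#' "one in X" phrasing.
#'
#' @param profile Integer vector of dosages (0..4), one per marker. NAs are
#'   dropped together with their frequency.
#' @param ref_freqs Reference-allele frequencies, one per marker (recycled if
#'   length one). Ignored (with those positions) where `profile` is NA.
#' @return A one-row tibble: `n_loci`, `probability`, `one_in` plus the
#'   per-locus frequencies as a list column `locus_freqs`.
#' @examples
#' match_probability(c(2, 2, 2, 3), 0.5)   # one in 76
#' @export
match_probability <- function(profile, ref_freqs) {
  if (length(profile) == 0) {
    warn("empty profile: match probability 1 (no discrimination).")
    return(tibble(n_loci = 0L, probability = 1, one_in = 1,
                  locus_freqs = list(numeric(0))))
  }
  ref_freqs <- rep_len(ref_freqs, length(profile))
  keep <- !is.na(profile) & !is.na(ref_freqs)
  f <- genotype_class_freq(ref_freqs[keep], profile[keep])
  p <- prod(f)
  tibble(n_loci = sum(keep), probability = p,
         one_in = round(1 / p), locus_freqs = list(f))
}

#' Probability of zero dosage difference between two random cultivars
#'
#' The chance that two independent cultivars drawn from a random-mating
#' population share the same dosage at one bi-allelic tetraploid marker:
#' the sum of squared class frequencies. Minimised at ref_freq = 0.5
#' (about 0.27), which is why balanced markers discriminate best.
#'
#' @inheritParams genotype_class_freq
#' @return Numeric vector of collision probabilities.
#' @examples
#' prob_zero_dosage_diff(0.5)  # 0.2734
#' @export
prob_zero_dosage_diff <- function(ref_freq) {
  vapply(ref_freq, function(p) sum(genotype_class_freq(p, 0:PLOIDY)^2), numeric(1))
}

#' Panel size at which one chance collision is expected
#'
#' With `n_markers` independent markers each giving per-marker zero-difference
#' probability `per_marker_p`, the expected number of indistinguishable pairs
#' in a panel of n samples is n(n-1)/2 * p^k. This returns the panel size at
#' which that expectation reaches one: the positive real root of
#' n(n-1)/2 * p^k = 1, rounded to the nearest whole sample. At p = 0.27 and
#' k = 10 this gives 986.
#'
#' @param per_marker_p Per-marker probability of zero dosage difference,
#'   in (0, 1].
#' @param n_markers Number of independent markers (>= 1).
#' @return A one-row tibble: `n_samples`, `collision_p` (= p^k), `capped`
#'   (TRUE when p^k underflowed and the size is a lower bound).
#' @examples
#' panel_size_for_one_collision(0.27, 10)   # 986 samples
#' @export
panel_size_for_one_collision <- function(per_marker_p, n_markers) {
  stopifnot(per_marker_p > 0, per_marker_p <= 1, n_markers >= 1)
  pk <- per_marker_p^n_markers
  capped <- FALSE
  if (pk == 0) {
    # underflow: report the largest representable size as a floor
    n <- .Machine$integer.max
    capped <- TRUE
  } else {
    n <- round((1 + sqrt(1 + 8 / pk)) / 2)
    if (n > .Machine$integer.max) {
      n <- .Machine$integer.max
      capped <- TRUE
    }
  }
  tibble(n_samples = as.integer(n), collision_p = pk, capped = capped)
}

#' Rank markers by their power to distinguish two cultivars
#'
#' For a purity-test request on two named cultivars, ranks every shared
#' marker by the absolute dosage difference between them (high to low, ties
#' by marker id). Markers with no dosage difference are retained but flagged
#' uninformative so assays on them can be avoided.
#'
#' @param db A genotype database (see [genotype_db()]).
#' @param cultivar_a,cultivar_b Cultivar names present in the database.
#' @return Tibble: `marker_id`, `dosage_a`, `dosage_b`, `abs_diff`,
#'   `informative`, sorted by decreasing `abs_diff`.
#' @export
marker_subset <- function(db, cultivar_a, cultivar_b) {
  wide <- assemble_database(db)
  cv <- wide[[1]]
  for (nm in c(cultivar_a, cultivar_b)) {
    if (!nm %in% cv) abort(sprintf("cultivar '%s' not in database", nm))
  }
  m <- dosage_matrix(wide)
  a <- m[cultivar_a, ]
  b <- m[cultivar_b, ]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) abort("the two cultivars share no genotyped marker.")
  out <- tibble(
    marker_id = colnames(m)[keep],
    dosage_a = unname(a[keep]),
    dosage_b = unname(b[keep]),
    abs_diff = abs(unname(a[keep]) - unname(b[keep]))
  ) |>
    mutate(informative = .data$abs_diff > 0L) |>
    arrange(desc(.data$abs_diff), .data$marker_id)
  out
}

#' Assign a putative cultivar identity to a query dosage profile
#'
#' Compares a query profile against every cultivar in the genotype database
#' by Kosman distance over pairwise-complete loci, ranks candidates by
#' ascending distance, and declares matches where the Kosman similarity
#' (1 - distance) reaches `similarity_threshold`. The report carries the
#' random match probability of the query profile under the database's
#' marker frequencies.
#'
#' @param query Named integer vector of dosages (names = marker ids), or a
#'   one-row dosage table.
#' @param db A genotype database (see [genotype_db()]).
#' @param similarity_threshold Kosman similarity at or above which a database
#'   cultivar is declared a match (default 0.85).
#' @param min_loci Minimum pairwise-complete loci required to score a
#'   candidate (default 6).
#' @return An object of class `match_report`: list with `query` (name),
#'   `candidates` (tibble: cultivar, distance, similarity, loci_compared,
#'   declared ranked by distance), `matches` (declared subset),
#'   `match_probability` (tibble from [match_probability()]), and the
#'   thresholds used.
#' @export
identify_cultivar <- function(query, db, similarity_threshold = 0.85,
                              min_loci = 6L) {
  if (is.data.frame(query)) {
    validate_dosage_table(query, "query")
    if (nrow(query) != 1) abort("`query` must be a single profile.")
    qname <- query[[1]][1]
    q <- dosage_matrix(query)[1, ]
  } else {
    if (is.null(names(query))) abort("`query` vector must be named by marker id.")
    qname <- "query"
    q <- query
  }
  wide <- assemble_database(db)
  m <- dosage_matrix(wide)
  shared <- intersect(colnames(m), names(q))
  if (length(shared) == 0) abort("query shares no marker with the database.")
  qs <- q[shared]
  ms <- m[, shared, drop = FALSE]

  scored <- purrr::map(rownames(ms), function(cv) {
    d <- kosman_distance(qs, ms[cv, ], min_loci = 0L)
    tibble(cultivar = cv, distance = d$distance, loci_compared = d$loci_compared)
  }) |> list_rbind() |>
    mutate(distance = ifelse(.data$loci_compared < min_loci, NA_real_, .data$distance))
  if (all(is.na(scored$distance))) {
    abort(sprintf("no database cultivar shares >= %d genotyped loci with the query.", min_loci))
  }
  candidates <- scored |>
    filter(!is.na(.data$distance)) |>
    mutate(similarity = 1 - .data$distance,
           declared = .data$similarity >= similarity_threshold) |>
    arrange(.data$distance, .data$cultivar) |>
    select("cultivar", "distance", "similarity", "loci_compared", "declared")

  freqs <- marker_ref_freqs(wide)[shared]
  ok <- !is.na(qs) & !is.na(freqs)
  mp <- match_probability(unname(qs[ok]), unname(freqs[ok]))

  structure(
    list(query = qname, candidates = candidates,
         matches = filter(candidates, .data$declared),
         match_probability = mp,
         similarity_threshold = similarity_threshold, min_loci = min_loci),
    class = "match_report"
  )
}

marker_ref_freqs <- function(dosages) {
  m <- dosage_matrix(dosages)
  colSums(m, na.rm = TRUE) / (PLOIDY * colSums(!is.na(m)))
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("Identity report for query '%s'\n", x$query))
  cat(sprintf("  candidates scored : %d (>= %d shared loci)\n",
              nrow(x$candidates), x$min_loci))
  cat(sprintf("  declared matches  : %d at similarity >= %.2f\n",
              nrow(x$matches), x$similarity_threshold))
  if (nrow(x$matches)) {
    best <- x$matches[1, ]
    cat(sprintf("  best match        : %s (Kosman distance %.4f over %d loci)\n",
                best$cultivar, best$distance, best$loci_compared))
  }
  mp <- x$match_probability
  cat(sprintf("  random match prob : %.4g over %d loci (one in %s)\n",
              mp$probability, mp$n_loci, format(mp$one_in, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' @rdname identify_cultivar
#' @param x A `match_report`.
#' @param ... Unused.
#' @export
tidy.match_report <- function(x, ...) x$candidates

#' @rdname identify_cultivar
#' @export
glance.match_report <- function(x, ...) {
  tibble(query = x$query,
         n_candidates = nrow(x$candidates),
         n_matches = nrow(x$matches),
         best_match = if (nrow(x$matches)) x$matches$cultivar[1] else NA_character_,
         best_distance = if (nrow(x$matches)) x$matches$distance[1] else NA_real_,
         probability = x$match_probability$probability,
         one_in = x$match_probability$one_in)
}
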