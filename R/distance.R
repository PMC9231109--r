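# Kosman allele-dosage distance, pairwise comparison and clustering.
#
# For bi-allelic tetraploid loci the Kosman dissimilarity between two
# cultivars reduces per locus to |x - y| / 4 (the arithmetic form), which
# equals 1 - (min(x, y) + min(4 - x, 4 - y)) / 4 (the shared-allele-count
# form); the locus values are averaged over all pairwise-complete loci.

#' Kosman dosage distance between two profiles
#'
#' @param x,y Integer dosage vectors (0..4, NA allowed) over the same
#'   markers. If both are named, they are aligned on shared names.
#' @param min_loci Minimum pairwise-complete loci required; below it the
#'   distance is NA (default 6, matching the database policy of accepting
#'   profiles assayed at six or more markers).
#' @return A one-row tibble: `distance` in \[0, 1\] and `loci_compared`.
#' @examples
#' kosman_distance(c(2, 1, 0), c(2, 3, 1), min_loci = 1)  # 0.25
#' @export
kosman_distance <- function(x, y, min_loci = 6L) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  }
  if (length(x) != length(y)) abort("profiles must cover the same markers.")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0) abort("no shared non-missing loci between the two profiles.")
  d <- if (n < min_loci) NA_real_ else mean(abs(x[ok] - y[ok])) / PLOIDY
  tibble(distance = d, loci_compared = as.integer(n))
}

#' Summed absolute dosage difference between two profiles
#'
#' The raw count of allele-dosage differences over pairwise-complete loci,
#' the unit in which near-duplicate cultivars are described (pairs differing
#' by two or fewer dosages).
#'
#' @inheritParams kosman_distance
#' @return Integer count.
#' @export
dosage_diff_sum <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  }
  if (length(x) != length(y)) abort("profiles must cover the same markers.")
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) abort("no shared non-missing loci between the two profiles.")
  as.integer(sum(abs(x[ok] - y[ok])))
}

#' All pairwise Kosman distances in a dosage table
#'
#' @param dosages A dosage table (cultivar column + marker columns).
#' @param min_loci Minimum pairwise-complete loci to report a distance
#'   (default 6); thinner overlaps give NA with a warning.
#' @param similarity_threshold Pairs with Kosman similarity (1 - D) at or
#'   above this are flagged `similar` (default 0.85).
#' @param duplicate_band Pairs with D at or below this are additionally
#'   flagged `duplicate` (default 0.02, the band in which known duplicated
#'   accessions fall).
#' @return An object of class `kosman_pairwise`: a tibble with one row per
#'   unordered pair (`cultivar_a`, `cultivar_b`, `distance`,
#'   `loci_compared`, `similar`, `duplicate`).
#' @export
kosman_pairwise <- function(dosages, min_loci = 6L,
                            similarity_threshold = 0.85,
                            duplicate_band = 0.02) {
  validate_dosage_table(dosages)
  m <- dosage_matrix(dosages)
  if (nrow(m) < 2) abort("need at least two cultivars.")
  obs <- !is.na(m)
  m0 <- m; m0[!obs] <- 0L
  # |x - y| summed over pairwise-complete loci, via the identity
  # sum|x-y| over complete loci computed pair-by-pair (vectorised by row)
  n <- nrow(m)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  dist_v <- numeric(nrow(idx)); loci_v <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    ok <- obs[i, ] & obs[j, ]
    loci_v[r] <- sum(ok)
    dist_v[r] <- if (loci_v[r] > 0) mean(abs(m[i, ok] - m[j, ok])) / PLOIDY else NA_real_
  }
  too_thin <- !is.na(loci_v) & loci_v < min_loci & loci_v > 0
  no_loci <- loci_v == 0
  if (any(too_thin | no_loci)) {
    warn(sprintf("%d pair(s) share fewer than %d loci; distance set to NA.",
                 sum(too_thin | no_loci), min_loci))
    dist_v[too_thin] <- NA_real_
  }
  out <- tibble(
    cultivar_a = rownames(m)[idx[, 1]],
    cultivar_b = rownames(m)[idx[, 2]],
    distance = dist_v,
    loci_compared = loci_v
  ) |>
    mutate(similar = !is.na(.data$distance) & (1 - .data$distance) >= similarity_threshold,
           duplicate = !is.na(.data$distance) & .data$distance <= duplicate_band)
  structure(out, class = c("kosman_pairwise", class(out)),
            cultivars = rownames(m),
            similarity_threshold = similarity_threshold,
            duplicate_band = duplicate_band)
}

#' Square distance matrix from pairwise Kosman results
#'
#' @param pairwise A `kosman_pairwise` tibble.
#' @return Symmetric numeric matrix with zero diagonal, labelled by cultivar.
#' @export
kosman_matrix <- function(pairwise) {
  cvs <- attr(pairwise, "cultivars") %||%
    sort(unique(c(pairwise$cultivar_a, pairwise$cultivar_b)))
  n <- length(cvs)
  m <- matrix(0, n, n, dimnames = list(cvs, cvs))
  ia <- match(pairwise$cultivar_a, cvs)
  ib <- match(pairwise$cultivar_b, cvs)
  m[cbind(ia, ib)] <- pairwise$distance
  m[cbind(ib, ia)] <- pairwise$distance
  m
}

#' Complete-linkage clustering of cultivars
#'
#' Agglomerative complete-linkage clustering of the pairwise Kosman distance
#' matrix (via [stats::hclust()]), the standard display of cultivar
#' relationships in fingerprinting reports.
#'
#' @param pairwise A `kosman_pairwise` tibble or a square distance matrix.
#' @return An `hclust` object (leaves = cultivars, heights = merge
#'   distances).
#' @seealso [write_newick()] to export the dendrogram.
#' @export
cluster_complete <- function(pairwise) {
  m <- if (is.matrix(pairwise)) pairwise else kosman_matrix(pairwise)
  if (nrow(m) < 2) abort("need at least two cultivars to cluster.")
  if (anyNA(m)) abort("distance matrix contains NA; drop under-genotyped cultivars first.")
  hclust(as.dist(m), method = "complete")
}

#' Export a dendrogram as a Newick tree
#'
#' @param clust An `hclust` object from [cluster_complete()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_newick <- function(clust, path) {
  phy <- ape::as.phylo(clust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Histogram of the pairwise Kosman distance distribution
#'
#' @param pairwise A `kosman_pairwise` tibble.
#' @param binwidth Histogram bin width on the distance axis (default 0.01).
#' @return A ggplot object.
#' @export
plot_distance_hist <- function(pairwise, binwidth = 0.01) {
  ggplot(as_tibble(pairwise), aes(x = .data$distance)) +
    geom_histogram(binwidth = binwidth, fill = "grey35", colour = "white") +
    labs(x = "Kosman genetic distance", y = "Number of cultivar pairs") +
    theme_classic()
}

#' @export
autoplot.kosman_pairwise <- function(object, ...) plot_distance_hist(object, ...)
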