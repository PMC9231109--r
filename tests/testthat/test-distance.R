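# Kosman dosage distance, pairwise comparison and clustering.

test_that("kosman distance matches hand-computed values", {
  expect_equal(kosman_distance(c(2, 1, 0), c(2, 3, 1), min_loci = 1)$distance, 0.25)
  expect_equal(kosman_distance(c(0, 0), c(4, 4), min_loci = 1)$distance, 1)
  x <- c(3, 1, 4, 0, 2, 2)
  expect_equal(kosman_distance(x, x)$distance, 0)
  expect_error(kosman_distance(c(NA, NA), c(1, NA), min_loci = 1), "no shared")
})

test_that("arithmetic form equals the shared-allele-count oracle on all single-locus pairs", {
  for (a in 0:4) for (b in 0:4) {
    expect_equal(abs(a - b) / 4, kosman_oracle_locus(a, b),
                 info = sprintf("pair (%d,%d)", a, b))
  }
})

test_that("kosman distance satisfies the metric axioms on short profiles", {
  profiles <- as.matrix(expand.grid(0:4, 0:4))
  d <- function(x, y) kosman_distance(x, y, min_loci = 1)$distance
  n <- nrow(profiles)
  dm <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) dm[i, j] <- d(profiles[i, ], profiles[j, ])
  expect_true(all(dm == t(dm)))                     # symmetry
  expect_true(all(diag(dm) == 0))                   # identity
  expect_true(all(dm >= 0 & dm <= 1))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {    # triangle inequality
    if (dm[i, k] > dm[i, j] + dm[j, k] + 1e-12) {
      fail(sprintf("triangle violated at (%d,%d,%d)", i, j, k))
    }
  }
  succeed()
})

test_that("adding loci moves the distance in the expected direction", {
  set.seed(3)
  for (rep in 1:25) {
    L <- sample(2:10, 1)
    x <- sample(0:4, L, replace = TRUE)
    y <- sample(0:4, L, replace = TRUE)
    d0 <- kosman_distance(x, y, min_loci = 1)$distance
    same <- sample(0:4, 1)
    d_same <- kosman_distance(c(x, same), c(y, same), min_loci = 1)$distance
    expect_lte(d_same, d0 + 1e-12)
    d_max <- kosman_distance(c(x, 0), c(y, 4), min_loci = 1)$distance
    expect_gte(d_max, d0 - 1e-12)
  }
})

test_that("dosage difference sums match hand computation", {
  expect_equal(dosage_diff_sum(c(1, 2), c(1, 2)), 0L)
  expect_equal(dosage_diff_sum(2, 3), 1L)
  expect_equal(dosage_diff_sum(c(0, 4), c(4, 0)), 8L)
})

test_that("pairwise distances equal a brute-force double loop", {
  d <- random_dosage_tbl(10, 15, seed = 5, missing_rate = 0.1)
  pw <- kosman_pairwise(d, min_loci = 1)
  m <- as.matrix(d[, -1]); rownames(m) <- d[[1]]
  for (r in sample(nrow(pw), 20)) {
    a <- m[pw$cultivar_a[r], ]; b <- m[pw$cultivar_b[r], ]
    ok <- !is.na(a) & !is.na(b)
    expect_equal(pw$distance[r], mean(abs(a[ok] - b[ok])) / 4)
    expect_equal(pw$loci_compared[r], sum(ok))
  }
  # symmetry/diagonal via the square matrix view
  sq <- kosman_matrix(pw)
  expect_true(isSymmetric(sq))
  expect_true(all(diag(sq) == 0))
})

test_that("duplicated cultivars are flagged as similar pairs at distance zero", {
  d <- random_dosage_tbl(6, 12, seed = 9)
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d[1, ], cultivar = "CV01_copy"))
  pw <- kosman_pairwise(d2, min_loci = 1)
  dup_row <- dplyr::filter(pw, cultivar_a == "CV01", cultivar_b == "CV01_copy")
  expect_equal(dup_row$distance, 0)
  expect_true(dup_row$similar && dup_row$duplicate)
})

test_that("thin overlaps are reported NA with a warning", {
  d <- make_dosage_tbl(rbind(c(1L, NA, NA, NA, NA, NA),
                             c(1L, 2L, 2L, 2L, 2L, 2L)))
  expect_warning(pw <- kosman_pairwise(d, min_loci = 6), "fewer than 6")
  expect_true(is.na(pw$distance[1]))
  expect_equal(pw$loci_compared[1], 1L)
})

test_that("complete-linkage heights equal the brute-force agglomeration oracle", {
  set.seed(21)
  for (rep in 1:5) {
    d <- random_dosage_tbl(8, 30, seed = 100 + rep)
    pw <- kosman_pairwise(d, min_loci = 1)
    sq <- kosman_matrix(pw)
    hc <- cluster_complete(pw)
    expect_equal(sort(hc$height), brute_complete_linkage_heights(sq),
                 tolerance = 1e-12)
  }
})

test_that("closest pair merges first; duplicates merge at height zero", {
  sq <- matrix(c(0, 0.1, 0.9,
                 0.1, 0, 0.9,
                 0.9, 0.9, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- cluster_complete(sq)
  expect_equal(hc$height, c(0.1, 0.9))
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))  # a and b first
  d <- random_dosage_tbl(5, 10, seed = 2)
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d[2, ], cultivar = "dup"))
  hc2 <- cluster_complete(kosman_pairwise(d2, min_loci = 1))
  expect_equal(min(hc2$height), 0)
  expect_error(cluster_complete(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "at least two")
})

test_that("newick export round-trips leaf set and heights through ape", {
  d <- random_dosage_tbl(7, 20, seed = 31)
  hc <- cluster_complete(kosman_pairwise(d, min_loci = 1))
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, tf)
  phy <- ape::read.tree(tf)
  expect_setequal(phy$tip.label, d$cultivar)
  # ape halves merge heights so that leaf-to-leaf path = cophenetic distance
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(max(depths), max(hc$height) / 2, tolerance = 1e-6)
})

test_that("distance histogram builds a ggplot", {
  pw <- kosman_pairwise(random_dosage_tbl(6, 10, seed = 4), min_loci = 1)
  expect_s3_class(plot_distance_hist(pw), "ggplot")
  expect_s3_class(ggplot2::autoplot(pw), "ggplot")
})
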