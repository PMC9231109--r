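# Random match probability, collision sizing, and the two service tools.

test_that("tetraploid genotype-class frequencies match the random-mating model", {
  expect_equal(genotype_class_freq(0.5, 0:4),
               c(0.0625, 0.25, 0.375, 0.25, 0.0625))
  expect_equal(genotype_class_freq(1.0, 4), 1.0)
  # (1-0.41)^4, hand-computed
  expect_equal(genotype_class_freq(0.41, 0), 0.59^4, tolerance = 1e-12)
  expect_error(genotype_class_freq(1.2, 2), "0, 1")
  expect_error(genotype_class_freq(0.5, 5), "0..4")
})

test_that("class frequencies sum to one across a frequency grid", {
  for (p in seq(0, 1, by = 0.01)) {
    expect_equal(sum(genotype_class_freq(p, 0:4)), 1, tolerance = 1e-12)
  }
})

test_that("match probability reproduces the worked product-rule examples", {
  mp <- match_probability(c(2, 2, 2, 3), 0.5)
  expect_equal(round(mp$probability, 4), 0.0132)
  expect_equal(mp$one_in, 76L)
  # per-locus frequencies known, product rule applied directly
  f <- c(0.3495, 0.3671, 0.3318, 0.2704)
  expect_equal(round(prod(f), 5), 0.01151)
  expect_equal(as.integer(round(1 / prod(f))), 87L)
  # degenerate single fixed marker
  mp1 <- match_probability(4, 1.0)
  expect_equal(mp1$probability, 1)
  expect_warning(mp0 <- match_probability(integer(0), numeric(0)), "empty")
  expect_equal(mp0$probability, 1)
})

test_that("match probability is non-increasing as markers are appended", {
  set.seed(42)
  for (rep in 1:20) {
    prof <- sample(0:4, 8, replace = TRUE)
    freqs <- runif(8, 0.05, 0.95)
    probs <- vapply(seq_along(prof), function(k) {
      match_probability(prof[1:k], freqs[1:k])$probability
    }, numeric(1))
    expect_true(all(diff(probs) <= 1e-15))
  }
})

test_that("zero-dosage-difference probability matches enumeration and dips at 0.5", {
  expect_equal(round(prob_zero_dosage_diff(0.5), 2), 0.27)
  expect_equal(prob_zero_dosage_diff(0.5), 0.2734375)
  expect_equal(prob_zero_dosage_diff(1.0), 1.0)
  # brute force over all 25 ordered dosage pairs at p = 0.6
  p <- 0.6
  brute <- 0
  for (a in 0:4) for (b in 0:4) {
    if (a == b) brute <- brute +
        genotype_class_freq(p, a) * genotype_class_freq(p, b)
  }
  expect_equal(prob_zero_dosage_diff(p), brute, tolerance = 1e-12)
  # minimum at balanced frequency
  grid <- seq(0, 1, by = 0.005)
  vals <- prob_zero_dosage_diff(grid)
  expect_equal(grid[which.min(vals)], 0.5)
})

test_that("panel size for one expected collision matches the collision model", {
  # root of n(n-1)/2 * p^k = 1, rounded: verified against the expectation
  # at the returned size bracketing 1
  res <- panel_size_for_one_collision(0.27, 10)
  expect_equal(res$n_samples, 986L)
  n <- res$n_samples
  expected_pairs <- function(n, p, k) n * (n - 1) / 2 * p^k
  # the continuous root lies within half a sample of the answer
  root <- (1 + sqrt(1 + 8 / 0.27^10)) / 2
  expect_lt(abs(root - n), 0.5)
  expect_equal(panel_size_for_one_collision(1, 1)$n_samples, 2L)
  # p = 0.5, k = 4: root of n(n-1) = 32 is 6.18 -> 6; expectation brackets 1
  res2 <- panel_size_for_one_collision(0.5, 4)
  expect_equal(res2$n_samples, 6L)
  expect_lt(expected_pairs(res2$n_samples, 0.5, 4), 1)
  expect_gte(expected_pairs(res2$n_samples + 1, 0.5, 4), 1)
})

test_that("marker subset ranks by dosage difference with uninformative flags", {
  d <- make_dosage_tbl(rbind(c(2, 2, 0, 4, 1),
                             c(2, 3, 3, 4, 1),
                             c(0, 0, 0, 0, 0)),
                       cultivars = c("A", "B", "C"))
  db <- merge_into_database(genotype_db(), d, "sequencing")$db
  r <- marker_subset(db, "A", "B")
  expect_equal(r$marker_id, c("M03", "M02", "M01", "M04", "M05"))
  expect_equal(r$abs_diff, c(3L, 1L, 0L, 0L, 0L))
  expect_equal(r$informative, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # identical profiles: everything uninformative
  r2 <- marker_subset(db, "A", "A")
  expect_true(all(!r2$informative))
  expect_error(marker_subset(db, "A", "Z"), "not in database")
})

test_that("identity assignment ranks the true cultivar first", {
  set.seed(7)
  d <- random_dosage_tbl(12, 21, seed = 7)
  db <- merge_into_database(genotype_db(), d, "sequencing")$db
  # query = CV03 with 2 single-dosage edits over 21 markers
  q <- d[3, ]
  q[[1]] <- "query"
  q[["M01"]] <- min(4L, q[["M01"]] + 1L)
  q[["M02"]] <- max(0L, q[["M02"]] - 1L)
  rep <- identify_cultivar(q, db)
  expect_equal(rep$candidates$cultivar[1], "CV03")
  expect_equal(rep$candidates$distance[1], 2 / (21 * 4), tolerance = 1e-12)
  expect_true("CV03" %in% rep$matches$cultivar)
  # exact copy matches at distance zero
  rep0 <- identify_cultivar(d[5, ], db)
  expect_equal(rep0$candidates$cultivar[1], "CV05")
  expect_equal(rep0$candidates$distance[1], 0)
  # glance carries the product-rule probability
  g <- glance(rep)
  expect_true(g$probability > 0 && g$probability < 1)
})

test_that("identity assignment is invariant to database row order", {
  d <- random_dosage_tbl(10, 12, seed = 11)
  q <- d[4, ]; q[[1]] <- "q"
  db1 <- merge_into_database(genotype_db(), d, "sequencing")$db
  db2 <- merge_into_database(genotype_db(), d[sample(10), ], "sequencing")$db
  r1 <- identify_cultivar(q, db1)
  r2 <- identify_cultivar(q, db2)
  expect_equal(r1$candidates, r2$candidates)
})
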