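# Panel selection: the filter cascade, the greedy selector, and evaluation.

mk_tbl <- function(...) tibble::tibble(...)

test_that("the candidate filter applies MAF, coding and density rules with reasons", {
  mk <- mk_tbl(
    marker_id = c("low_maf", "noncoding", "dense_lo", "dense_hi", "far", "lost"),
    chromosome = c("c1", "c1", "c1", "c1", "c2", NA),
    position = c(1e6, 2e6, 3e6, 3.05e6, 1e6, NA),
    maf = c(0.30, 0.45, 0.40, 0.45, 0.48, 0.5),
    is_coding = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
  res <- filter_candidates(mk, min_maf = 0.336, coding_only = TRUE,
                           density_bp = 1e5)
  expect_setequal(res$retained$marker_id, c("dense_hi", "far"))
  reasons <- setNames(res$rejections$reason, res$rejections$marker_id)
  expect_match(reasons[["low_maf"]], "maf")
  expect_match(reasons[["noncoding"]], "non-coding")
  expect_match(reasons[["dense_lo"]], "denser")
  expect_match(reasons[["lost"]], "unmapped")
  # well-spaced coding markers all retained
  mk2 <- mk_tbl(marker_id = sprintf("m%d", 1:5), chromosome = "c1",
                position = (1:5) * 1e6, maf = 0.45, is_coding = TRUE)
  res2 <- filter_candidates(mk2)
  expect_equal(nrow(res2$retained), 5)
})

test_that("relaxing the MAF floor or the density radius never shrinks the retained set", {
  set.seed(83)
  for (rep in 1:5) {
    n <- 40
    mk <- mk_tbl(marker_id = sprintf("m%02d", 1:n),
                 chromosome = sample(c("c1", "c2"), n, TRUE),
                 position = sample.int(2e7, n),
                 maf = runif(n, 0.05, 0.5), is_coding = TRUE)
    strict <- filter_candidates(mk, min_maf = 0.336, density_bp = 5e5)
    lax_maf <- filter_candidates(mk, min_maf = 0.2, density_bp = 5e5)
    lax_den <- filter_candidates(mk, min_maf = 0.336, density_bp = 1e5)
    expect_true(all(strict$retained$marker_id %in% lax_maf$retained$marker_id))
    expect_true(all(strict$retained$marker_id %in% lax_den$retained$marker_id))
  }
})

test_that("flanking-variant rules mirror the assay-design constraints", {
  mk <- mk_tbl(
    marker_id = c("ok", "close", "two_up", "none"),
    chromosome = "c1", position = 1:4 * 1e6,
    flanking_offsets = list(c(-50L, 40L), c(-15L), c(-60L, -30L, 45L), integer(0))
  )
  res <- filter_flanking(mk)
  expect_setequal(res$retained$marker_id, c("ok", "none"))
  reasons <- setNames(res$rejections$reason, res$rejections$marker_id)
  expect_match(reasons[["close"]], "closer than 20")
  expect_match(reasons[["two_up"]], "upstream")
})

test_that("greedy selection respects PIC order, tie-breaks and spacing", {
  d <- random_dosage_tbl(8, 30, seed = 91)
  mk <- mk_tbl(marker_id = names(d)[-1],
               chromosome = rep(c("c1", "c2", "c3"), each = 10),
               position = rep(seq(1e6, 10e6, by = 1e6), 3),
               pic = 0.5, maf = 0.5)
  spec <- select_panel(d, mk, k = 25, min_spacing_bp = 1e6)
  expect_true(spec$complete)
  # all PIC equal: selection follows chromosome then position order
  expect_equal(spec$marker_ids[1:3], mk$marker_id[1:3])
  # spacing constraint: two top-PIC markers too close -> only one enters
  mk2 <- mk_tbl(marker_id = c("top1", "top2", "other"),
                chromosome = "c1", position = c(1e6, 1.3e6, 5e6),
                pic = c(0.5, 0.5, 0.4), maf = c(0.5, 0.5, 0.4))
  spec2 <- select_panel(d[, 1:4] |> rlang::set_names(c("cultivar", mk2$marker_id)),
                        mk2, k = 2, min_spacing_bp = 5.8e5)
  expect_true("top1" %in% spec2$marker_ids)
  expect_false("top2" %in% spec2$marker_ids)
  expect_true("other" %in% spec2$marker_ids)
})

test_that("selected panels always satisfy their stated constraints", {
  for (seed in 1:4) {
    pop <- simulate_population(population_sim_config(
      n_cultivars = 25, n_markers = 120, n_duplicate_pairs = 0,
      missing_rate = 0, seed = seed))
    stats_tbl <- marker_summary(pop$dosages)
    mk <- dplyr::left_join(pop$markers, stats_tbl, by = "marker_id")
    res <- filter_candidates(mk, min_maf = 0.2, density_bp = 1e5)
    spec <- select_panel(pop$dosages, res$retained, k = 15,
                         min_spacing_bp = 3e5)
    sel <- spec$markers
    for (chr in unique(sel$chromosome)) {
      p <- sort(sel$position[sel$chromosome == chr])
      if (length(p) > 1) expect_true(all(diff(p) >= 3e5))
    }
    expect_true(all(sel$maf > 0.2))
  }
})

test_that("an unreachable panel size returns a best-effort panel with a diagnostic", {
  d <- random_dosage_tbl(5, 4, seed = 13)
  mk <- mk_tbl(marker_id = names(d)[-1], chromosome = "c1",
               position = c(1e6, 1.1e6, 1.2e6, 1.3e6), pic = 0.5, maf = 0.5)
  spec <- select_panel(d, mk, k = 3, min_spacing_bp = 5e5)
  expect_false(spec$complete)
  expect_match(spec$diagnostic, "selectable")
  expect_lt(length(spec$marker_ids), 3)
})

test_that("panel evaluation equals brute force on a hand matrix", {
  d <- make_dosage_tbl(rbind(c(0L, 2L, 4L),
                             c(0L, 2L, 4L),
                             c(1L, 3L, 4L),
                             c(4L, 0L, 0L)))
  ev <- evaluate_panel(d, c("M01", "M02", "M03"))
  m <- as.matrix(d[, -1])
  dists <- c(); diffs <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    dists <- c(dists, mean(abs(m[i, ] - m[j, ])) / 4)
    diffs <- c(diffs, sum(abs(m[i, ] - m[j, ])))
  }
  expect_equal(ev$min_distance, min(dists))
  expect_equal(ev$mean_distance, mean(dists))
  expect_equal(ev$min_dosage_diff, min(diffs))
  expect_equal(nrow(ev$indistinguishable_pairs), 1)  # rows 1 and 2
  expect_error(evaluate_panel(d, character(0)), "empty panel")
  expect_error(evaluate_panel(d, "nope"), "not in dosage table")
})

test_that("removing markers never raises the panel's minimum dosage difference", {
  # the locus-averaged distance can move either way when loci are dropped;
  # the raw dosage-difference count is what shrinks monotonically
  d <- random_dosage_tbl(10, 12, seed = 101)
  panel <- names(d)[-1]
  ev_full <- evaluate_panel(d, panel)
  for (k in c(9, 6, 3)) {
    ev_sub <- evaluate_panel(d, panel[1:k])
    expect_lte(ev_sub$min_dosage_diff, ev_full$min_dosage_diff)
    ev_full <- ev_sub
  }
})

test_that("panel specs expose tidy, glance and per-chromosome summaries", {
  pop <- simulate_population(population_sim_config(
    n_cultivars = 20, n_markers = 60, n_duplicate_pairs = 0, seed = 47))
  mk <- dplyr::left_join(pop$markers, marker_summary(pop$dosages), by = "marker_id")
  spec <- select_panel(pop$dosages, mk, k = 10, min_spacing_bp = 1e5)
  expect_equal(nrow(tidy(spec)), 10)
  g <- glance(spec)
  expect_true(g$complete)
  expect_gte(g$min_distance, 0)
  cs <- chromosome_summary(spec$markers)
  expect_true(all(cs$n_markers >= 1))
})
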