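# Allele-dosage calling from two-channel KASP endpoint fluorescence.
#
# The caller works on the allele-fraction axis r = FAM / (FAM + HEX), where
# the five tetraploid dosage classes form five ordered clusters. A
# five-component one-dimensional Gaussian mixture with shared variance is
# fitted by EM from a deterministic, equally spaced initialisation (no
# random restarts: the fit is reproducible without a seed). Components may
# end up empty, since a plate need not contain all five classes. A marker
# fails QC as "allele competition" when two adjacent fitted class centres
# collapse closer than twice the pooled within-class spread — the signature
# of one allele's primer outcompeting the other.

#' Transform KASP signals to the allele-fraction axis
#'
#' Adds `r` = FAM / (FAM + HEX), `total` and a `no_amp` flag to a KASP well
#' tibble. Wells whose total signal does not exceed 1.5 x the largest
#' no-template-control total are flagged as failed amplification (as is a
#' well with both channels zero).
#'
#' @param plate A KASP well tibble (see [read_kasp_csv()]).
#' @return The tibble with `r`, `total` and `no_amp` columns.
#' @export
transform_signals <- function(plate) {
  need <- c("sample", "marker", "signal_fam", "signal_hex", "is_ntc")
  miss <- setdiff(need, names(plate))
  if (length(miss)) abort(sprintf("plate missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(plate$signal_fam < 0 | plate$signal_hex < 0, na.rm = TRUE)) {
    abort("negative fluorescence signal.")
  }
  total <- plate$signal_fam + plate$signal_hex
  floor_total <- if (any(plate$is_ntc)) 1.5 * max(total[plate$is_ntc], na.rm = TRUE) else 0
  r <- ifelse(total > 0, plate$signal_fam / total, NA_real_)
  plate |>
    mutate(r = r, total = total,
           no_amp = !.data$is_ntc & (is.na(total) | total <= floor_total | total == 0))
}

# EM for a 1-D five-component Gaussian mixture with shared variance and
# deterministic equally spaced initialisation. Means are kept in dosage
# order; empty components retain their running mean.
em_ordered_mixture <- function(r, k = PLOIDY + 1L, max_iter = 500, tol = 1e-10) {
  mu <- seq(0, 1, length.out = k)
  sigma <- 0.05
  w <- rep(1 / k, k)
  n <- length(r)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(r, mu[j], sigma), numeric(n))
    if (!is.matrix(dens)) dens <- matrix(dens, nrow = n)
    rowsum_d <- pmax(rowSums(dens), .Machine$double.xmin)
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    w <- nk / n
    upd <- nk > 1e-8
    mu[upd] <- colSums(resp[, upd, drop = FALSE] * r) / nk[upd]
    sigma <- sqrt(max(sum(resp * (outer(r, mu, "-"))^2) / n, 1e-8))
    mu <- sort(mu)  # shared variance: order components along r
    ll <- sum(log(rowsum_d))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  dens <- vapply(seq_len(k), function(j) w[j] * dnorm(r, mu[j], sigma), numeric(n))
  if (!is.matrix(dens)) dens <- matrix(dens, nrow = n)
  resp <- dens / pmax(rowSums(dens), .Machine$double.xmin)
  list(mu = mu, sigma = sigma, w = w, resp = resp, loglik = ll_old, n_iter = iter)
}

#' Call tetraploid allele dosages from a KASP plate
#'
#' Fits the ordered five-component mixture on the allele-fraction axis and
#' assigns each amplified well the maximum-posterior dosage when that
#' posterior reaches `threshold` (otherwise the call is missing:
#' missing-over-wrong). Per-marker QC: `pass`, `fail_competition` (adjacent
#' class centres closer than 2 x the pooled spread), or `fail_unresolved`
#' (fewer than two distinct fraction values).
#'
#' @param plate A KASP well tibble for one marker.
#' @param expected Optional dosage table of expected dosages; when given,
#'   the result carries a concordance table.
#' @param threshold Posterior required for a confident call (default 0.8).
#' @return An object of class `kasp_fit`; see [tidy.kasp_fit()] and
#'   [glance.kasp_fit()].
#' @export
call_dosages <- function(plate, expected = NULL, threshold = 0.8) {
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1].")
  marker <- unique(plate$marker)
  if (length(marker) != 1) abort("`plate` must contain exactly one marker.")
  tp <- transform_signals(plate)
  usable <- !tp$is_ntc & !tp$no_amp & !is.na(tp$r)
  if (sum(usable) < 10) abort("fewer than 10 amplified wells; cannot fit the mixture.")
  r <- tp$r[usable]

  calls <- tp |>
    mutate(dosage = NA_integer_, confidence = NA_real_)

  if (length(unique(round(r, 10))) < 2) {
    status <- "fail_unresolved"
    fit <- NULL
  } else {
    fit <- em_ordered_mixture(r)
    post <- fit$resp
    best <- max.col(post, ties.method = "first")
    conf <- post[cbind(seq_along(best), best)]
    d <- as.integer(best - 1L)
    d[conf < threshold] <- NA_integer_
    calls$dosage[usable] <- d
    calls$confidence[usable] <- conf
    occupied <- fit$w > 1e-3
    gaps <- diff(fit$mu)
    # competition check on centres adjacent among occupied components
    occ_mu <- fit$mu[occupied]
    status <- if (length(occ_mu) >= 2 && min(diff(occ_mu)) < 2 * fit$sigma) {
      "fail_competition"
    } else if (any(diff(fit$mu) <= 0)) {
      "fail_unresolved"
    } else {
      "pass"
    }
  }

  conc <- NULL
  if (!is.null(expected)) {
    conc <- concordance(select(filter(calls, !.data$is_ntc),
                               "sample", "marker", "dosage"), expected)
  }
  structure(
    list(marker = marker, calls = calls, status = status,
         centers = if (!is.null(fit)) fit$mu else NA_real_,
         sigma = if (!is.null(fit)) fit$sigma else NA_real_,
         weights = if (!is.null(fit)) fit$w else NA_real_,
         threshold = threshold, concordance = conc),
    class = "kasp_fit"
  )
}

#' @export
print.kasp_fit <- function(x, ...) {
  cat(sprintf("KASP dosage fit for marker '%s': %s\n", x$marker, x$status))
  n_conf <- sum(!is.na(x$calls$dosage))
  cat(sprintf("  confident calls: %d / %d amplified wells (threshold %.2f)\n",
              n_conf, sum(!x$calls$is_ntc & !x$calls$no_amp), x$threshold))
  if (!all(is.na(x$centers))) {
    cat("  class centres (r): ", paste(sprintf("%.3f", x$centers), collapse = " "),
        sprintf("  spread %.4f\n", x$sigma))
  }
  if (!is.null(x$concordance)) {
    cat(sprintf("  mismatch vs expected: %.1f%%\n",
                100 * x$concordance$overall))
  }
  invisible(x)
}

#' Tidy / glance methods for KASP dosage fits
#'
#' `tidy()` returns the per-well call table; `glance()` a one-row fit
#' summary.
#'
#' @param x A `kasp_fit`.
#' @param ... Unused.
#' @export
tidy.kasp_fit <- function(x, ...) {
  select(x$calls, "well", "sample", "marker", "r", "dosage", "confidence",
         "no_amp", "is_ntc")
}

#' @rdname tidy.kasp_fit
#' @export
glance.kasp_fit <- function(x, ...) {
  tibble(marker = x$marker, status = x$status,
         n_wells = nrow(x$calls),
         n_confident = sum(!is.na(x$calls$dosage)),
         sigma = x$sigma,
         min_center_gap = if (all(is.na(x$centers))) NA_real_ else min(diff(x$centers)),
         mismatch_rate = if (is.null(x$concordance)) NA_real_ else x$concordance$overall)
}

#' @export
autoplot.kasp_fit <- function(object, expected = NULL, ...) {
  df <- object$calls
  if (!is.null(expected)) {
    exp_long <- tidyr::pivot_longer(expected, -1, names_to = "marker",
                                    values_to = "expected_dosage") |>
      rename(sample = 1)
    df <- left_join(df, exp_long, by = c("sample", "marker")) |>
      mutate(colour_by = factor(.data$expected_dosage))
    colour_lab <- "expected dosage"
  } else {
    df <- mutate(df, colour_by = factor(.data$dosage))
    colour_lab <- "called dosage"
  }
  ggplot(df, aes(x = .data$signal_fam, y = .data$signal_hex,
                 colour = .data$colour_by, shape = .data$is_ntc)) +
    geom_point(size = 2) +
    labs(title = sprintf("Marker %s (%s)", object$marker, object$status),
         x = "FAM signal", y = "HEX signal", colour = colour_lab,
         shape = "NTC") +
    theme_classic()
}

#' Concordance between dosage calls and expected genotypes
#'
#' @param calls Tibble with `sample`, `marker`, `dosage` columns (e.g.
#'   bound rows of `tidy()` on several fits).
#' @param expected A dosage table of expected dosages.
#' @return List: `per_marker` (tibble: marker, n_compared, mismatches,
#'   ranked by mismatches descending), `overall` (mismatch fraction),
#'   `n_compared`.
#' @export
concordance <- function(calls, expected) {
  validate_dosage_table(expected, "expected")
  exp_long <- tidyr::pivot_longer(expected, -1, names_to = "marker",
                                  values_to = "expected_dosage") |>
    rename(sample = 1)
  joined <- inner_join(calls, exp_long, by = c("sample", "marker")) |>
    filter(!is.na(.data$dosage), !is.na(.data$expected_dosage))
  if (!nrow(joined)) abort("no overlapping (sample, marker) genotypes to compare.")
  per_marker <- joined |>
    group_by(marker = .data$marker) |>
    summarise(n_compared = dplyr::n(),
              mismatches = sum(.data$dosage != .data$expected_dosage),
              .groups = "drop") |>
    arrange(desc(.data$mismatches), .data$marker)
  list(per_marker = per_marker,
       overall = sum(per_marker$mismatches) / sum(per_marker$n_compared),
       n_compared = sum(per_marker$n_compared))
}
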