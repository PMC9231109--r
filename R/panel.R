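# The filter cascade and greedy selector that reduce a large candidate SNP
# set to a small, well-spaced fingerprinting panel.

#' Filter candidate markers on frequency, annotation and density
#'
#' The cascade rejects, in order: unmapped markers (no chromosome or
#' position), markers at or below the MAF floor, non-coding markers (when
#' `coding_only`), and the lower-MAF member of any within-chromosome pair
#' closer than `density_bp` (ties broken towards the lexicographically
#' earlier marker id). Each rejection is logged with its reason.
#'
#' @param markers Marker tibble with at least `marker_id`, `chromosome`,
#'   `position` and `maf` (or `ref_freq`, from which MAF is derived);
#'   `is_coding` is required when `coding_only = TRUE`.
#' @param min_maf Strict MAF floor (default 0.336).
#' @param coding_only Reject non-coding markers (default TRUE).
#' @param density_bp Minimum within-chromosome separation below which the
#'   lower-MAF member of a pair is dropped (default 1e5, i.e. 0.1 Mb).
#' @return List: `retained` (marker tibble), `rejections` (tibble:
#'   marker_id, reason).
#' @export
filter_candidates <- function(markers, min_maf = 0.336, coding_only = TRUE,
                              density_bp = 1e5) {
  if (!"maf" %in% names(markers)) {
    if (!"ref_freq" %in% names(markers)) abort("markers need `maf` or `ref_freq`.")
    markers$maf <- pmin(markers$ref_freq, 1 - markers$ref_freq)
  }
  rej <- list()
  reject <- function(ids, reason) {
    if (length(ids)) rej[[length(rej) + 1]] <<- tibble(marker_id = ids, reason = reason)
  }
  unmapped <- is.na(markers$chromosome) | is.na(markers$position)
  reject(markers$marker_id[unmapped], "unmapped")
  cur <- markers[!unmapped, ]

  low <- is.na(cur$maf) | cur$maf <= min_maf
  reject(cur$marker_id[low], sprintf("maf <= %.3f", min_maf))
  cur <- cur[!low, ]

  if (coding_only) {
    if (!"is_coding" %in% names(cur)) abort("`is_coding` column required when coding_only = TRUE.")
    nc <- !cur$is_coding
    reject(cur$marker_id[nc], "non-coding")
    cur <- cur[!nc, ]
  }

  # density: drop a marker iff a strictly better (higher MAF; ties by
  # earlier id) marker lies within density_bp on the same chromosome
  if (nrow(cur) > 1) {
    dominated <- rep(FALSE, nrow(cur))
    for (i in seq_len(nrow(cur))) {
      near <- cur$chromosome == cur$chromosome[i] &
        abs(cur$position - cur$position[i]) < density_bp &
        seq_len(nrow(cur)) != i
      if (any(near)) {
        better <- cur$maf[near] > cur$maf[i] |
          (cur$maf[near] == cur$maf[i] & cur$marker_id[near] < cur$marker_id[i])
        dominated[i] <- any(better)
      }
    }
    reject(cur$marker_id[dominated], sprintf("denser than %g bp", density_bp))
    cur <- cur[!dominated, ]
  }

  list(retained = as_tibble(cur),
       rejections = if (length(rej)) list_rbind(rej) else
         tibble(marker_id = character(), reason = character()))
}

#' Filter markers on their flanking-variant environment
#'
#' A KASP assay tolerates at most one flanking variant upstream and one
#' downstream of the target SNP, and none within 20 bases; markers whose
#' `flanking_offsets` (signed bp offsets) violate either rule are dropped.
#'
#' @param markers Marker tibble with a `flanking_offsets` list column.
#' @param min_gap_bp No flanking variant closer than this (default 20).
#' @param max_per_side At most this many per side (default 1).
#' @return List: `retained`, `rejections` as in [filter_candidates()].
#' @export
filter_flanking <- function(markers, min_gap_bp = 20, max_per_side = 1) {
  if (!"flanking_offsets" %in% names(markers)) {
    abort("markers need a `flanking_offsets` list column.")
  }
  verdict <- purrr::map_chr(markers$flanking_offsets, function(off) {
    off <- off[!is.na(off)]
    if (any(abs(off) < min_gap_bp)) return(sprintf("flanking variant closer than %d bp", min_gap_bp))
    if (sum(off < 0) > max_per_side) return("more than one upstream flanking variant")
    if (sum(off > 0) > max_per_side) return("more than one downstream flanking variant")
    ""
  })
  list(retained = markers[verdict == "", ],
       rejections = tibble(marker_id = markers$marker_id[verdict != ""],
                           reason = verdict[verdict != ""]))
}

#' Select a fingerprinting panel by greedy PIC with spacing
#'
#' Orders candidates by descending PIC (ties: chromosome, then position)
#' and accepts each in turn if it lies at least `min_spacing_bp` from every
#' already-selected marker on the same chromosome, until `k` markers are
#' selected. If the first pass falls short, a top-up pass re-examines the
#' spacing-rejected candidates in descending MAF order and admits any that
#' land in a within-chromosome gap wider than twice the mean selected
#' interval (automating the manual filling of low-density regions).
#'
#' @param dosages Dosage table used to evaluate the panel.
#' @param markers Candidate marker tibble (`marker_id`, `chromosome`,
#'   `position`, `pic`; `maf` used by the top-up pass).
#' @param k Panel size (default 25).
#' @param min_spacing_bp Minimum within-chromosome spacing
#'   (default 5.8e5, i.e. 0.58 Mb).
#' @return An object of class `panel_spec`: list with `marker_ids` (ordered
#'   as selected), `markers` (tibble), `constraints`, `evaluation` (from
#'   [evaluate_panel()]), `complete` (reached k) and `diagnostic`.
#' @export
select_panel <- function(dosages, markers, k = 25, min_spacing_bp = 5.8e5) {
  need <- c("marker_id", "chromosome", "position", "pic")
  miss <- setdiff(need, names(markers))
  if (length(miss)) abort(sprintf("markers missing column(s): %s", paste(miss, collapse = ", ")))
  if (k < 1) abort("`k` must be >= 1.")
  if (k > nrow(markers)) abort("`k` exceeds the number of candidates.")
  cand <- arrange(markers, desc(.data$pic), .data$chromosome, .data$position)
  sel <- integer(0)
  fits <- function(i, chosen) {
    same <- chosen[cand$chromosome[chosen] == cand$chromosome[i]]
    !length(same) || all(abs(cand$position[same] - cand$position[i]) >= min_spacing_bp)
  }
  for (i in seq_len(nrow(cand))) {
    if (length(sel) >= k) break
    if (fits(i, sel)) sel <- c(sel, i)
  }
  if (length(sel) < k) {
    # top-up: spacing-rejected candidates, best MAF first, into wide gaps
    rejected <- setdiff(seq_len(nrow(cand)), sel)
    if ("maf" %in% names(cand)) rejected <- rejected[order(-cand$maf[rejected])]
    sel_pos <- split(cand$position[sel], cand$chromosome[sel])
    gaps <- unlist(purrr::map(sel_pos, function(p) diff(sort(p))))
    mean_gap <- if (length(gaps)) mean(gaps) else Inf
    for (i in rejected) {
      if (length(sel) >= k) break
      same <- sel[cand$chromosome[sel] == cand$chromosome[i]]
      p <- sort(cand$position[same])
      in_wide_gap <- if (length(p) < 2) TRUE else {
        ins <- findInterval(cand$position[i], p)
        ins >= 1 && ins < length(p) && (p[ins + 1] - p[ins]) > 2 * mean_gap
      }
      if (in_wide_gap) sel <- c(sel, i)
    }
  }
  chosen <- cand[sel, ]
  ev <- evaluate_panel(dosages, chosen$marker_id)
  structure(
    list(marker_ids = chosen$marker_id, markers = chosen,
         constraints = list(k = k, min_spacing_bp = min_spacing_bp),
         evaluation = ev, complete = length(sel) == k,
         diagnostic = if (length(sel) == k) NULL else
           sprintf("only %d of %d markers selectable under a %g bp spacing constraint",
                   length(sel), k, min_spacing_bp)),
    class = "panel_spec"
  )
}

#' Evaluate a marker panel's discriminating power on a cohort
#'
#' @param dosages Dosage table covering the panel markers.
#' @param panel Character vector of marker ids (subset of the table's
#'   markers).
#' @return List: `min_distance`, `mean_distance` (pairwise Kosman over the
#'   panel), `min_dosage_diff`, `indistinguishable_pairs` (tibble of pairs
#'   at distance 0), `n_pairs`.
#' @export
evaluate_panel <- function(dosages, panel) {
  validate_dosage_table(dosages)
  if (length(panel) == 0) abort("empty panel.")
  missing_mk <- setdiff(panel, names(dosages)[-1])
  if (length(missing_mk)) {
    abort(sprintf("panel marker(s) not in dosage table: %s", paste(missing_mk, collapse = ", ")))
  }
  sub <- dosages[, c(names(dosages)[1], panel)]
  pw <- suppressWarnings(kosman_pairwise(sub, min_loci = 1L))
  m <- dosage_matrix(sub)
  dd <- purrr::map2_int(pw$cultivar_a, pw$cultivar_b,
                        function(a, b) dosage_diff_sum(m[a, ], m[b, ]))
  list(min_distance = suppressWarnings(min(pw$distance, na.rm = TRUE)),
       mean_distance = mean(pw$distance, na.rm = TRUE),
       min_dosage_diff = min(dd),
       indistinguishable_pairs = filter(as_tibble(pw), .data$distance == 0) |>
         select("cultivar_a", "cultivar_b"),
       n_pairs = nrow(pw))
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("SNP panel: %d marker(s) selected%s\n", length(x$marker_ids),
              if (x$complete) "" else " (incomplete)"))
  cat(sprintf("  constraints: k = %d, min spacing %g bp\n",
              x$constraints$k, x$constraints$min_spacing_bp))
  ev <- x$evaluation
  cat(sprintf("  evaluation: min D %.4f, mean D %.4f, min dosage diff %d, %d indistinguishable pair(s)\n",
              ev$min_distance, ev$mean_distance, ev$min_dosage_diff,
              nrow(ev$indistinguishable_pairs)))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' @rdname select_panel
#' @param x A `panel_spec`.
#' @param ... Unused.
#' @export
tidy.panel_spec <- function(x, ...) as_tibble(x$markers)

#' @rdname select_panel
#' @export
glance.panel_spec <- function(x, ...) {
  ev <- x$evaluation
  tibble(n_markers = length(x$marker_ids), complete = x$complete,
         min_distance = ev$min_distance, mean_distance = ev$mean_distance,
         min_dosage_diff = ev$min_dosage_diff,
         n_indistinguishable = nrow(ev$indistinguishable_pairs))
}

#' Per-chromosome summary of a marker set
#'
#' @param markers Marker tibble with `chromosome`, `position` and `maf`.
#' @return Tibble: chromosome, n_markers, largest position, mean interval,
#'   MAF range.
#' @export
chromosome_summary <- function(markers) {
  markers |>
    group_by(chromosome = .data$chromosome) |>
    summarise(n_markers = dplyr::n(),
              largest_mb = max(.data$position) / 1e6,
              mean_interval_mb = if (dplyr::n() > 1)
                mean(diff(sort(.data$position))) / 1e6 else NA_real_,
              maf_min = min(.data$maf), maf_max = max(.data$maf),
              .groups = "drop")
}
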