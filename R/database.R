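# The germplasm genotype database: long records of (cultivar, marker,
# dosage, provenance). Sequencing-derived and assay-derived dosages coexist;
# when they disagree the assay call wins, because the assay is what the
# fingerprinting service will run going forward.

#' Create an empty genotype database
#'
#' @return A `genotype_db` tibble with columns `cultivar`, `marker_id`,
#'   `dosage`, `provenance`.
#' @export
genotype_db <- function() {
  structure(
    tibble(cultivar = character(), marker_id = character(),
           dosage = integer(), provenance = character()),
    class = c("genotype_db", class(tibble()))
  )
}

#' Merge a dosage table into a genotype database
#'
#' Adds every non-missing dosage in `dosages` under the stated provenance.
#' Re-merging an identical record is idempotent; a new value for an existing
#' (cultivar, marker, provenance) replaces it. Cross-provenance conflicts
#' (sequencing vs assay disagreeing) are detected and returned; they are
#' resolved at assembly time in favour of the assay.
#'
#' @param db A `genotype_db`.
#' @param dosages A dosage table.
#' @param provenance Either `"sequencing"` or `"assay"`.
#' @return List: `db` (updated database), `conflicts` (tibble: cultivar,
#'   marker_id, sequencing, assay).
#' @export
merge_into_database <- function(db, dosages, provenance) {
  if (!provenance %in% c("sequencing", "assay")) {
    abort("`provenance` must be 'sequencing' or 'assay'.")
  }
  validate_dosage_table(dosages)
  long <- tidyr::pivot_longer(dosages, -1, names_to = "marker_id",
                              values_to = "dosage") |>
    filter(!is.na(.data$dosage)) |>
    mutate(provenance = provenance) |>
    rename(cultivar = 1)
  combined <- bind_rows(as_tibble(db), long) |>
    group_by(.data$cultivar, .data$marker_id, .data$provenance) |>
    slice_tail(n = 1) |>   # newest record wins within a provenance
    ungroup()
  conflicts <- combined |>
    tidyr::pivot_wider(names_from = "provenance", values_from = "dosage") |>
    (\(d) if (all(c("sequencing", "assay") %in% names(d))) {
      filter(d, !is.na(.data$sequencing), !is.na(.data$assay),
             .data$sequencing != .data$assay)
    } else {
      tibble(cultivar = character(), marker_id = character(),
             sequencing = integer(), assay = integer())
    })()
  db_out <- structure(arrange(combined, .data$cultivar, .data$marker_id,
                              .data$provenance),
                      class = c("genotype_db", class(tibble())))
  list(db = db_out, conflicts = conflicts)
}

#' Assemble a genotype database into a dosage table
#'
#' One row per cultivar, one column per marker; where sequencing and assay
#' provenance both carry a dosage, the assay value is used.
#'
#' @param db A `genotype_db` (or the list returned by
#'   [merge_into_database()]).
#' @return A dosage table.
#' @export
assemble_database <- function(db) {
  if (is.list(db) && !is.data.frame(db) && !is.null(db$db)) db <- db$db
  if (!nrow(db)) abort("genotype database is empty.")
  resolved <- as_tibble(db) |>
    mutate(.rank = ifelse(.data$provenance == "assay", 2L, 1L)) |>
    group_by(.data$cultivar, .data$marker_id) |>
    arrange(.data$.rank, .by_group = TRUE) |>
    slice_tail(n = 1) |>
    ungroup() |>
    select("cultivar", "marker_id", "dosage")
  wide <- tidyr::pivot_wider(resolved, names_from = "marker_id",
                             values_from = "dosage")
  validate_dosage_table(wide)
  wide
}
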