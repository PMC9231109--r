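# Internal helpers shared across modules.
#
# The package-wide exchange format for genotypes is the "dosage table": a
# tibble whose first column (`cultivar`, character, unique) names the sample
# and whose remaining columns (unique marker ids) hold reference-allele
# dosages as integers in 0..4, with NA for missing calls.  Tetraploidy is
# assumed throughout; the ALT dosage is always 4 - REF dosage.

PLOIDY <- 4L

# dosage table -> integer matrix (rownames = cultivars)
dosage_matrix <- function(dosages) {
  stopifnot(is.data.frame(dosages), ncol(dosages) >= 2)
  m <- as.matrix(dosages[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- dosages[[1]]
  m
}

# integer matrix -> dosage table
dosage_tibble <- function(m, cultivars = rownames(m)) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(cultivar = cultivars), out)
  out
}

validate_dosage_table <- function(dosages, arg = "dosages") {
  if (!is.data.frame(dosages) || ncol(dosages) < 2) {
    abort(sprintf("`%s` must be a data frame with a cultivar column and >= 1 marker column.", arg))
  }
  cv <- dosages[[1]]
  if (anyDuplicated(cv)) {
    abort(sprintf("duplicate cultivar name(s): %s",
                  paste(unique(cv[duplicated(cv)]), collapse = ", ")))
  }
  mk <- names(dosages)[-1]
  if (anyDuplicated(mk)) {
    abort(sprintf("duplicate marker id(s): %s",
                  paste(unique(mk[duplicated(mk)]), collapse = ", ")))
  }
  m <- dosage_matrix(dosages)
  bad <- which(!is.na(m) & (m < 0L | m > PLOIDY))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    abort(sprintf("dosage out of range 0..4 at cultivar '%s', marker '%s' (value %s)",
                  rownames(m)[i[1]], colnames(m)[i[2]], m[bad[1]]))
  }
  invisible(dosages)
}

# Deterministic sub-seed derivation so one user seed drives several
# independent random stages without their streams overlapping.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + stream * 8191L) %% .Machine$integer.max
}

well_labels <- function(n) {
  rows <- rep(LETTERS[1:8], each = 12)
  cols <- rep(1:12, times = 8)
  if (n > 96) {
    plate <- rep(seq_len(ceiling(n / 96)), each = 96)[seq_len(n)]
    idx <- ((seq_len(n) - 1) %% 96) + 1
    return(sprintf("P%d_%s%02d", plate, rows[idx], cols[idx]))
  }
  sprintf("%s%02d", rows[seq_len(n)], cols[seq_len(n)])
}
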