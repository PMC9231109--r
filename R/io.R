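# Readers and writers for the formats the pipeline touches: tetraploid VCF,
# dosage CSV, KASP endpoint-fluorescence CSV and marker annotation CSV.

#' Read tetraploid reference-allele dosages from a VCF
#'
#' Extracts per-sample reference-allele dosage (the count of REF alleles in
#' the tetraploid GT, 0..4) from a VCF, filtering low-coverage genotypes.
#' Depth comes from FORMAT/DP when present, otherwise from the sum of
#' FORMAT/AD; genotypes with depth less than or equal to `min_depth` are set
#' missing (the published service filtered to more than 100 reads). Phased
#' separators are accepted and treated as unphased. Markers at which more
#' than two alleles are observed are reported multi-allelic and excluded
#' from the returned table by default; monomorphic markers are reported but
#' kept. Records with non-tetraploid GT are listed in the report and set
#' missing.
#'
#' @param path VCF file (plain or bgzipped).
#' @param min_depth Strict lower depth bound for a genotype call
#'   (default 100).
#' @param drop_multiallelic Exclude multi-allelic markers from the dosage
#'   table (default TRUE).
#' @return List: `dosages` (dosage table), `markers` (tibble: marker_id,
#'   chromosome, position, ref_allele, alt_allele, ref_freq, maf, pic),
#'   `qc` (list: multi_allelic, monomorphic, non_tetraploid tibble,
#'   n_low_depth).
#' @export
read_vcf_dosages <- function(path, min_depth = 100, drop_multiallelic = TRUE) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)

  # depth: DP, else summed AD
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DP" %in% fmt_keys) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  } else if ("AD" %in% fmt_keys) {
    ad <- vcfR::extract.gt(v, element = "AD")
    dp <- apply(ad, c(1, 2), function(x) {
      if (is.na(x)) NA_real_ else sum(as.numeric(strsplit(x, ",")[[1]]))
    })
  } else {
    dp <- matrix(Inf, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }

  n_mark <- nrow(gt)
  dos <- matrix(NA_integer_, n_mark, length(samples),
                dimnames = list(ids, samples))
  bad_ploidy <- list()
  observed_alleles <- integer(n_mark)
  for (i in seq_len(n_mark)) {
    alleles_seen <- character(0)
    for (j in seq_along(samples)) {
      g <- gt[i, j]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      parts <- strsplit(g, "[/|]")[[1]]
      if (length(parts) != PLOIDY || any(parts == ".")) {
        bad_ploidy[[length(bad_ploidy) + 1]] <-
          tibble(marker_id = ids[i], sample = samples[j], gt = g)
        next
      }
      alleles_seen <- union(alleles_seen, parts)
      d <- dp[i, j]
      if (!is.na(d) && d <= min_depth) next
      dos[i, j] <- sum(parts == "0")
    }
    observed_alleles[i] <- length(alleles_seen)
  }
  n_low_depth <- sum(!is.na(dp) & dp <= min_depth & !is.na(gt) & gt != ".")

  multi <- ids[observed_alleles > 2]
  mono_mask <- apply(dos, 1, function(r) length(unique(r[!is.na(r)])) <= 1)
  mono <- ids[mono_mask]

  keep <- if (drop_multiallelic) !(ids %in% multi) else rep(TRUE, n_mark)
  dmat <- t(dos[keep, , drop = FALSE])
  dosages <- dosage_tibble(dmat, cultivars = samples)

  f <- colSums(dmat, na.rm = TRUE) / (PLOIDY * pmax(colSums(!is.na(dmat)), 1L))
  markers <- tibble(
    marker_id = ids[keep],
    chromosome = fix[keep, "CHROM"],
    position = as.integer(fix[keep, "POS"]),
    ref_allele = fix[keep, "REF"],
    alt_allele = fix[keep, "ALT"],
    ref_freq = unname(f),
    maf = pmin(unname(f), 1 - unname(f)),
    pic = pic(unname(f))
  )
  qc <- list(
    multi_allelic = multi,
    monomorphic = mono,
    non_tetraploid = if (length(bad_ploidy)) list_rbind(bad_ploidy) else
      tibble(marker_id = character(), sample = character(), gt = character()),
    n_low_depth = n_low_depth
  )
  list(dosages = dosages, markers = markers, qc = qc)
}

#' Read / write a dosage CSV
#'
#' The dosage CSV has a first column `cultivar` and one column per marker
#' with values 0..4 or NA. Round-trips losslessly.
#'
#' @param path File path.
#' @return `read_dosage_csv()`: a validated dosage table.
#' @export
read_dosage_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (names(df)[1] != "cultivar") names(df)[1] <- "cultivar"
  mk <- names(df)[-1]
  for (col in mk) {
    vals <- df[[col]]
    bad <- !is.na(vals) & !vals %in% as.character(0:PLOIDY)
    if (any(bad)) {
      abort(sprintf("invalid dosage '%s' at cultivar '%s', marker '%s' in %s",
                    vals[which(bad)[1]], df$cultivar[which(bad)[1]], col, path))
    }
    df[[col]] <- as.integer(vals)
  }
  validate_dosage_table(df)
  as_tibble(df)
}

#' @rdname read_dosage_csv
#' @param dosages A dosage table.
#' @return `write_dosage_csv()`: the path, invisibly.
#' @export
write_dosage_csv <- function(dosages, path) {
  validate_dosage_table(dosages)
  readr::write_csv(dosages, path, na = "NA")
  invisible(path)
}

#' Read / write a KASP endpoint-fluorescence CSV
#'
#' Columns: `well`, `sample`, `marker`, `signal_fam`, `signal_hex`,
#' `is_ntc` (logical; no-template control wells).
#'
#' @param path File path.
#' @return `read_kasp_csv()`: a tibble of well readings.
#' @export
read_kasp_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          well = readr::col_character(),
                          sample = readr::col_character(),
                          marker = readr::col_character(),
                          signal_fam = readr::col_double(),
                          signal_hex = readr::col_double(),
                          is_ntc = readr::col_logical()
                        ))
  need <- c("well", "sample", "marker", "signal_fam", "signal_hex", "is_ntc")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("KASP CSV missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(df$signal_fam < 0 | df$signal_hex < 0, na.rm = TRUE)) {
    abort("negative fluorescence signal in KASP CSV.")
  }
  df
}

#' @rdname read_kasp_csv
#' @param plate A KASP well tibble.
#' @export
write_kasp_csv <- function(plate, path) {
  readr::write_csv(plate, path, na = "NA")
  invisible(path)
}

#' Read / write a marker annotation CSV
#'
#' Columns: `marker_id`, `chromosome`, `position`, `ref_allele`,
#' `alt_allele`, `is_coding`, `flanking_offsets` (semicolon-separated signed
#' base-pair offsets of flanking variants from the target SNP; empty for
#' none), and optionally `ref_freq`, `maf`, `pic`.
#'
#' @param path File path.
#' @return `read_marker_csv()`: a marker tibble with `flanking_offsets`
#'   parsed into a list column of integer vectors.
#' @export
read_marker_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("marker_id", "chromosome", "position")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("marker CSV missing column(s): %s", paste(miss, collapse = ", ")))
  if ("flanking_offsets" %in% names(df) && !is.list(df$flanking_offsets)) {
    df$flanking_offsets <- purrr::map(as.character(df$flanking_offsets), function(s) {
      if (is.na(s) || s == "") integer(0) else as.integer(strsplit(s, ";")[[1]])
    })
  }
  as_tibble(df)
}

#' @rdname read_marker_csv
#' @param markers A marker tibble.
#' @export
write_marker_csv <- function(markers, path) {
  if ("flanking_offsets" %in% names(markers) && is.list(markers$flanking_offsets)) {
    markers$flanking_offsets <-
      purrr::map_chr(markers$flanking_offsets, paste, collapse = ";")
  }
  readr::write_csv(markers, path, na = "NA")
  invisible(path)
}
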