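# Synthetic tetraploid populations and KASP fluorescence plates.
#
# The simulator reproduces the statistical structure the analysis assumes:
# bi-allelic markers with reference-allele frequencies concentrated near
# 0.5, dosages drawn from the tetraploid random-mating class frequencies
# (binomial in the allele frequency), a few near-duplicate cultivar pairs,
# and five-cluster two-channel endpoint fluorescence with an optional
# allele-competition failure mode.

#' Configuration for the tetraploid population simulator
#'
#' Defaults emulate a fingerprinting cohort: 190 cultivars genotyped at 500
#' bi-allelic SNPs spread over the 12 potato chromosomes, with REF
#' frequencies drawn uniformly from \[0.35, 0.65\] (markers pre-selected for
#' balanced frequencies) and three duplicated accession pairs differing by
#' at most two allele dosages.
#'
#' @param n_cultivars Number of cultivars (>= 2), duplicates included.
#' @param n_markers Number of bi-allelic SNP markers (>= 1).
#' @param ref_freq_sampler Function of n returning n REF frequencies in
#'   (0, 1); default uniform on \[0.35, 0.65\].
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_lengths Lengths in bp (recycled); defaults to the
#'   approximate sizes of the 12 potato chromosomes.
#' @param n_duplicate_pairs Number of duplicated accession pairs.
#' @param max_dup_edits Maximum single-dosage edits separating a duplicate
#'   from its source (default 2).
#' @param missing_rate Fraction of dosages set missing, in \[0, 1).
#' @param seed Integer seed (required).
#' @return A `population_sim_config` list.
#' @export
population_sim_config <- function(n_cultivars = 190, n_markers = 500,
                                  ref_freq_sampler = function(n) stats::runif(n, 0.35, 0.65),
                                  n_chromosomes = 12,
                                  chromosome_lengths = c(88.6, 48.3, 61.9, 71.8, 51.9, 58.5,
                                                         55.9, 54.7, 61.5, 59.4, 45.1, 59.3) * 1e6,
                                  n_duplicate_pairs = 3, max_dup_edits = 2,
                                  missing_rate = 0.01, seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (n_cultivars < 2) abort("`n_cultivars` must be >= 2.")
  if (n_markers < 1) abort("`n_markers` must be >= 1.")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  if (n_chromosomes < 1) abort("`n_chromosomes` must be >= 1.")
  chromosome_lengths <- rep_len(chromosome_lengths, n_chromosomes)
  if (any(chromosome_lengths <= 0)) abort("chromosome lengths must be positive.")
  if (n_duplicate_pairs < 0 || max_dup_edits < 0) abort("counts must be >= 0.")
  if (2 * n_duplicate_pairs > n_cultivars) abort("too many duplicate pairs for the cohort size.")
  structure(list(n_cultivars = as.integer(n_cultivars),
                 n_markers = as.integer(n_markers),
                 ref_freq_sampler = ref_freq_sampler,
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_lengths = chromosome_lengths,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 max_dup_edits = as.integer(max_dup_edits),
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "population_sim_config")
}

#' Simulate a tetraploid cultivar population
#'
#' Each marker gets a REF frequency from the configured sampler; cultivar
#' dosages at that marker are i.i.d. draws from the tetraploid random-mating
#' class frequencies (binomial(4, REF)). The last `n_duplicate_pairs`
#' cultivars are near-copies of the first ones, separated by at most
#' `max_dup_edits` single-dosage edits (+/-1, clipped to 0..4) at uniformly
#' chosen markers. Marker positions are uniform over chromosomes (sampled
#' proportionally to length) and strictly increasing within each.
#'
#' @param config A [population_sim_config()].
#' @return List: `dosages` (dosage table), `markers` (tibble: marker_id,
#'   chromosome, position, ref_allele, alt_allele, is_coding,
#'   flanking_offsets list column, sim_ref_freq), `duplicate_pairs`
#'   (tibble: source, duplicate, n_edits).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "population_sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_cultivars
  L <- config$n_markers

  p <- config$ref_freq_sampler(L)
  if (any(p <= 0 | p >= 1)) abort("ref_freq_sampler must return values strictly inside (0, 1).")

  dos <- vapply(p, function(pp) stats::rbinom(n, PLOIDY, pp), integer(n))
  if (!is.matrix(dos)) dos <- matrix(dos, nrow = n)

  n_base <- n - config$n_duplicate_pairs
  cultivars <- sprintf("CV%03d", seq_len(n_base))
  dup_pairs <- tibble(source = character(), duplicate = character(), n_edits = integer())
  if (config$n_duplicate_pairs > 0) {
    src_idx <- seq_len(config$n_duplicate_pairs)
    dup_names <- paste0(cultivars[src_idx], "_d")
    for (k in seq_along(src_idx)) {
      row <- dos[src_idx[k], ]
      n_edits <- sample.int(config$max_dup_edits + 1L, 1) - 1L
      if (n_edits > 0 && L >= 1) {
        at <- sample.int(L, min(n_edits, L))
        row[at] <- pmin(PLOIDY, pmax(0L, row[at] + sample(c(-1L, 1L), length(at), replace = TRUE)))
        n_edits <- length(at)
      }
      dos[n_base + k, ] <- row
      dup_pairs <- bind_rows(dup_pairs,
                             tibble(source = cultivars[src_idx[k]],
                                    duplicate = dup_names[k], n_edits = n_edits))
    }
    cultivars <- c(cultivars, dup_names)
  }

  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dos)) < config$missing_rate
    dos[miss] <- NA_integer_
  }

  # marker map: chromosome proportional to length, positions sorted within
  chrom_names <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  chrom <- sample(seq_len(config$n_chromosomes), L, replace = TRUE,
                  prob = config$chromosome_lengths)
  pos <- integer(L)
  for (c in seq_len(config$n_chromosomes)) {
    on_c <- which(chrom == c)
    if (!length(on_c)) next
    raw <- sort(sample.int(config$chromosome_lengths[c], length(on_c)))
    pos[on_c[order(on_c)]] <- raw
  }
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; p <- p[ord]
  dos <- dos[, ord, drop = FALSE]

  bases <- c("A", "C", "G", "T")
  refs <- sample(bases, L, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(bases, r), 1), character(1))
  flank <- purrr::map(seq_len(L), function(i) {
    k <- min(stats::rpois(1, 0.8), 3L)
    if (k == 0) return(integer(0))
    sort(sample(c(-80:-5, 5:80), k))
  })
  markers <- tibble(
    marker_id = sprintf("SNP%04d", seq_len(L)),
    chromosome = chrom_names[chrom],
    position = pos,
    ref_allele = refs,
    alt_allele = alts,
    is_coding = stats::runif(L) < 0.9,
    flanking_offsets = flank,
    sim_ref_freq = p
  )
  colnames(dos) <- markers$marker_id
  list(dosages = dosage_tibble(dos, cultivars = cultivars),
       markers = markers, duplicate_pairs = dup_pairs)
}

#' Configuration for the KASP plate simulator
#'
#' The two channels follow the allele balance: the FAM mean is proportional
#' to d/4 and the HEX mean to 1 - d/4 (each over a small baseline), with
#' multiplicative log-normal noise, which reproduces the arc of five
#' clusters seen on real endpoint-fluorescence scatter plots. Competition
#' failure modes compress the allele fraction towards one channel so that
#' adjacent dosage clusters collapse, mimicking preferential amplification
#' of one allele's primer.
#'
#' @param signal_baseline,signal_amplitude Channel mean = baseline +
#'   amplitude * fraction (arbitrary fluorescence units).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   signal noise (> 0; default 0.06).
#' @param n_ntc Number of no-template control wells (default 2).
#' @param ntc_level Mean total signal of NTC wells (default 60).
#' @param fail_mode `"none"`, `"allele1_competition"` (FAM outcompetes HEX)
#'   or `"allele2_competition"`.
#' @param competition_gamma Compression exponent under a failure mode
#'   (default 0.08; smaller = more severe collapse).
#' @param seed Integer seed (required).
#' @return A `kasp_sim_config` list.
#' @export
kasp_sim_config <- function(signal_baseline = 100, signal_amplitude = 900,
                            noise_cv = 0.06, n_ntc = 2, ntc_level = 60,
                            fail_mode = c("none", "allele1_competition",
                                          "allele2_competition"),
                            competition_gamma = 0.08, seed) {
  if (missing(seed)) abort("`seed` is required.")
  fail_mode <- match.arg(fail_mode)
  if (noise_cv <= 0) abort("`noise_cv` must be > 0.")
  if (n_ntc < 0) abort("`n_ntc` must be >= 0.")
  if (competition_gamma <= 0 || competition_gamma >= 1) {
    abort("`competition_gamma` must be in (0, 1).")
  }
  structure(list(signal_baseline = signal_baseline,
                 signal_amplitude = signal_amplitude,
                 noise_cv = noise_cv, n_ntc = as.integer(n_ntc),
                 ntc_level = ntc_level, fail_mode = fail_mode,
                 competition_gamma = competition_gamma,
                 seed = as.integer(seed)),
            class = "kasp_sim_config")
}

#' Simulate a KASP endpoint-fluorescence plate for one marker
#'
#' @param dosages Named integer vector of true dosages (0..4), one per
#'   sample; names become sample ids.
#' @param marker Marker id for the plate.
#' @param config A [kasp_sim_config()].
#' @return A KASP well tibble (`well`, `sample`, `marker`, `signal_fam`,
#'   `signal_hex`, `is_ntc`) with the true dosage attached as attribute
#'   `truth`.
#' @export
simulate_kasp_plate <- function(dosages, marker, config) {
  stopifnot(inherits(config, "kasp_sim_config"))
  if (any(!dosages %in% 0:PLOIDY, na.rm = TRUE)) abort("dosages must be in 0..4.")
  set.seed(derive_seed(config$seed, 2L))
  if (is.null(names(dosages))) names(dosages) <- sprintf("S%03d", seq_along(dosages))

  f <- dosages / PLOIDY
  f <- switch(config$fail_mode,
              none = f,
              allele1_competition = f^config$competition_gamma,
              allele2_competition = 1 - (1 - f)^config$competition_gamma)
  # dosage 0 / 4 stay anchored: 0^g = 0, 1^g = 1
  mu_fam <- config$signal_baseline + config$signal_amplitude * f
  mu_hex <- config$signal_baseline + config$signal_amplitude * (1 - f)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  n <- length(dosages)
  fam <- stats::rlnorm(n, log(mu_fam) - sdlog^2 / 2, sdlog)
  hex <- stats::rlnorm(n, log(mu_hex) - sdlog^2 / 2, sdlog)
  fam[is.na(dosages)] <- NA_real_; hex[is.na(dosages)] <- NA_real_

  ntc <- config$n_ntc
  ntc_fam <- stats::rlnorm(ntc, log(config$ntc_level / 2), sdlog)
  ntc_hex <- stats::rlnorm(ntc, log(config$ntc_level / 2), sdlog)

  plate <- tibble(
    well = well_labels(n + ntc),
    sample = c(names(dosages), if (ntc) sprintf("NTC%d", seq_len(ntc)) else character(0)),
    marker = marker,
    signal_fam = c(fam, ntc_fam),
    signal_hex = c(hex, ntc_hex),
    is_ntc = c(rep(FALSE, n), rep(TRUE, ntc))
  )
  attr(plate, "truth") <- tibble(sample = names(dosages), marker = marker,
                                 dosage = as.integer(dosages))
  plate
}

#' Write a simulated population and plates to disk as a fixture bundle
#'
#' Produces a VCF (tetraploid GT with constant high DP), a dosage CSV, a
#' marker annotation CSV and a combined KASP CSV, all of which round-trip
#' losslessly through the package readers.
#'
#' @param population The list from [simulate_population()].
#' @param plates Optional list of KASP well tibbles (combined into one CSV).
#' @param out_dir Output directory (created if absent).
#' @param depth DP value written for every called genotype (default 500).
#' @return Named character vector of file paths.
#' @export
write_fixture_bundle <- function(population, plates = NULL, out_dir,
                                 depth = 500L) {
  if (is.null(population$dosages) || nrow(population$dosages) == 0) {
    abort("empty population: nothing to write.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             dosage_csv = file.path(out_dir, "dosages.csv"),
             marker_csv = file.path(out_dir, "markers.csv"))
  write_dosage_csv(population$dosages, paths[["dosage_csv"]])
  write_marker_csv(population$markers, paths[["marker_csv"]])
  write_vcf_dosages(population$dosages, population$markers, paths[["vcf"]],
                    depth = depth)
  if (!is.null(plates) && length(plates)) {
    paths <- c(paths, kasp_csv = file.path(out_dir, "kasp.csv"))
    write_kasp_csv(bind_rows(plates), paths[["kasp_csv"]])
  }
  paths
}

# Minimal VCF 4.2 writer for tetraploid dosage fixtures (GT:DP per sample).
write_vcf_dosages <- function(dosages, markers, path, depth = 500L) {
  validate_dosage_table(dosages)
  m <- dosage_matrix(dosages)
  mk <- markers[match(colnames(m), markers$marker_id), ]
  if (anyNA(mk$marker_id)) abort("markers table does not cover all dosage columns.")
  gt_of <- function(d) {
    if (is.na(d)) return("./.:.")
    paste0(paste(c(rep("0", d), rep("1", PLOIDY - d)), collapse = "/"),
           ":", depth)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=spudprint-simulator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(m)), collapse = "\t")), con)
  ord <- order(mk$chromosome, mk$position)
  for (j in ord) {
    fields <- vapply(m[, j], gt_of, character(1))
    writeLines(paste(c(mk$chromosome[j], mk$position[j], mk$marker_id[j],
                       mk$ref_allele[j] %||% "A", mk$alt_allele[j] %||% "T",
                       ".", "PASS", ".", "GT:DP", fields), collapse = "\t"), con)
  }
  invisible(path)
}
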