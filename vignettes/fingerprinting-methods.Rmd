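---
title: "Methods: SNP fingerprinting of tetraploid potato with spudprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP fingerprinting of tetraploid potato with spudprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spudprint)
```

## The problem

Commercial potato cultivars are autotetraploid (2n = 4x = 48), so at a
bi-allelic SNP a cultivar carries 0–4 copies of the reference allele. That
**allele dosage** is the unit of identity throughout this package: a
cultivar's fingerprint is its vector of dosages over a small panel of
well-chosen SNPs, and two cultivars are distinguishable exactly when those
vectors differ. spudprint implements the full workflow a fingerprinting
service needs: choosing the panel from a large candidate SNP set, calling
dosages from two-channel KASP endpoint fluorescence, measuring genetic
distance between dosage profiles, maintaining a genotype database, and
quantifying how strong a declared identity match is.

## Population model

Under random mating, dosage classes at a bi-allelic tetraploid locus with
reference-allele frequency $p$ follow the binomial quintet

$$P(D = d) = \binom{4}{d} p^d (1-p)^{4-d}, \qquad d \in \{0, \dots, 4\},$$

giving $(0.0625, 0.25, 0.375, 0.25, 0.0625)$ at $p = 0.5$
(`genotype_class_freq()`). Three quantities derive from it:

* **Random match probability** (`match_probability()`): the product of
  per-locus class frequencies of a profile across independent markers (the
  product rule). No diploid heterozygote $\times 2$ factor applies: the
  dosage class already identifies the unordered tetraploid genotype. The
  reciprocal is reported as a rounded "one in X".
* **Collision probability** (`prob_zero_dosage_diff()`):
  $\sum_d P(D=d)^2$, the chance two random cultivars agree at one locus;
  minimal (≈ 0.2734) at $p = 0.5$, which is why balanced markers
  discriminate best.
* **Panel sizing** (`panel_size_for_one_collision()`): with $k$ independent
  markers of per-marker collision probability $p_0$, the expected number of
  indistinguishable pairs in a cohort of $n$ is
  $\tfrac{n(n-1)}{2} p_0^k$. We report the cohort size at which that
  expectation reaches one — the positive real root of
  $\tfrac{n(n-1)}{2}p_0^k = 1$, rounded to the nearest whole sample. We
  chose root-rounding over the smallest-$n$-above-threshold convention
  deliberately: the expectation at the rounded root differs from 1 by less
  than half a sample's worth, and the rounded value is the natural answer
  to "at what panel size do we expect one chance collision" (at
  $p_0 = 0.27$, $k = 10$ it gives 986; the strict threshold convention
  would give 987 for an expectation only 0.02% past 1).

Marker informativeness is summarised by PIC $= 1 - p^2 - (1-p)^2$,
maximal (0.5) at $p = 0.5$, and MAF $= \min(p, 1-p)$.

## Kosman dosage distance

For bi-allelic tetraploid loci the Kosman dissimilarity between profiles
$x$ and $y$ reduces per locus to $|x_\ell - y_\ell|/4$, averaged over
pairwise-complete loci. This equals the shared-allele-count form
$1 - (\min(x,y) + \min(4-x, 4-y))/4$ on every dosage pair, an identity the
test suite checks exhaustively; the arithmetic form is used because it is
the clearer statement for dosage data. Two policy thresholds follow field
practice: a pair with Kosman **similarity** ($1 - D$) of at least 0.85 is
flagged a possible same-variety match, and a much stricter band
$D \le 0.02$ flags likely duplicated accessions. Distances computed over
fewer than 6 pairwise-complete loci are suppressed (NA) — the same floor
the database applies when admitting assay-derived profiles — so that thin
overlaps cannot masquerade as confident matches. Note that the
locus-averaged distance is *not* monotone under dropping loci (removing a
concordant locus raises the average); the raw dosage-difference count
(`dosage_diff_sum()`) is, and is what panel evaluation monitors.

Cultivar relationships are displayed with complete-linkage hierarchical
clustering of the pairwise distance matrix (`cluster_complete()`, a thin
wrapper over `stats::hclust`), exported as Newick via ape. Complete
linkage is the conservative choice for fingerprinting: a cluster's height
is the *largest* distance inside it, so tight clusters are genuinely tight.

## Genotype accumulation curve

`accumulation_curve()` asks how many loci a panel needs: for each subset
size $k$ it draws random $k$-subsets of markers and counts distinguishable
multilocus genotypes, reporting the mean. Two numerical choices matter:

* When $\binom{L}{k} \le$ `n_perm` the subsets are enumerated exhaustively
  and the mean is exact (flagged in the `exact` column); sampling is used
  only beyond that. Small worked cases in the tests are therefore compared
  against brute-force enumeration with equality, not tolerance.
* Missing dosages are treated as wildcards: a profile with NA at a sampled
  locus is considered compatible with any value there, and the count is
  the number of connected components of the compatibility graph
  (union–find). This is conservative — missingness can only merge
  genotypes, never split them — so the curve never overstates the panel's
  discriminating power. It is order-independent, unlike greedy matching.
  The default of 100 permutations per $k$ follows common tool practice.

## Dosage calling from KASP fluorescence

A KASP assay reads two endpoint fluorescence channels, FAM (allele 1, here
the reference allele) and HEX (allele 2). `transform_signals()` projects
each well onto the allele fraction $r = \mathrm{FAM}/(\mathrm{FAM} +
\mathrm{HEX}) \in [0,1]$, where the five dosage classes form five ordered
clusters. Wells whose total signal does not exceed 1.5× the largest
no-template-control total are marked failed amplification (a well with
both channels zero is failed amplification too, not a division error).

`call_dosages()` fits a five-component one-dimensional Gaussian mixture on
$r$ by EM with **deterministic initialisation** at equally spaced centres
$(0, 0.25, 0.5, 0.75, 1)$ and a shared variance. The published tetraploid
caller this substitutes for fits a richer model (arcsine-transformed
ratios, population priors); we prefer a transparent fit that needs no seed
and whose failure modes are inspectable. Specifics:

* Shared variance keeps the ordering of centres stable; components are
  kept sorted along $r$, and a component may go empty (a plate need not
  contain all five classes) — its centre simply stops updating.
* A well is assigned the maximum-posterior dosage only when that posterior
  reaches the assignment threshold (default 0.8); otherwise the call is
  missing. Missing-over-wrong is the right bias for an identity service.
  Raising the threshold can only reduce the number of confident calls.
* **QC**: a marker fails as `fail_competition` when two occupied adjacent
  class centres sit closer than $2\sigma$ (pooled spread) — the signature
  of one allele's primer outcompeting the other, which collapses adjacent
  dosage clusters into an unresolvable smear. Fewer than two distinct
  fraction values gives `fail_unresolved`. Calling is equivariant under
  swapping the two channels together with reversing dosage orientation
  ($d \mapsto 4 - d$).

`concordance()` compares calls against expected genotypes (e.g.
sequencing-derived) and ranks markers by mismatch count, supporting the
decision to drop assays whose KASP probe evidently reads a different locus
than the sequencing probe did.

## Panel selection

`filter_candidates()` applies the cascade used when mining a large SNP
resource: drop unmapped markers, markers at or below the MAF floor
(default 0.336), non-coding markers (coding regions have lower assay
failure rates), and then a density rule — within a chromosome, a marker is
dropped iff a strictly higher-MAF marker (ties towards the earlier id)
lies within `density_bp` (default 0.1 Mb). The dominance form of the
density rule was chosen over iterative removal because it is provably
monotone: relaxing the radius or the MAF floor can never shrink the
retained set. `filter_flanking()` enforces assay-design constraints on the
flanking-variant environment: at most one variant upstream and one
downstream of the target SNP, none within 20 bp.

`select_panel()` is greedy by descending PIC (ties: chromosome, then
position), accepting a marker only if it keeps at least `min_spacing_bp`
(default 0.58 Mb) from every selected marker on its chromosome. When the
first pass cannot reach $k$ (default 25), a top-up pass revisits the
spacing-rejected candidates in descending MAF order and admits those
falling in within-chromosome gaps wider than twice the mean selected
interval — automating the manual "fill the sparse regions" step a curator
would otherwise do. The greedy-by-PIC rule with stated tie-breaks replaces
an unspecified manual final choice; it is deterministic, which the tests
rely on. `evaluate_panel()` reports minimum/mean pairwise Kosman distance,
the minimum dosage-difference count and any indistinguishable pairs.

## Genotype database and identity assignment

The database holds long records (cultivar, marker, dosage, provenance ∈
{sequencing, assay}). Both provenances are kept; `assemble_database()`
resolves conflicts assay-over-sequencing, because the assay is what the
service will keep running — a sequencing-era call that the assay
contradicts would otherwise haunt every future comparison.
`identify_cultivar()` ranks all database cultivars by Kosman distance to
the query (minimum 6 shared loci), declares matches at similarity ≥ 0.85,
and attaches the query profile's random match probability under the
database's own marker frequencies. `marker_subset()` ranks markers by
|Δdosage| between two named cultivars so a purity test can run only the
informative assays.

## The simulator

No public cohort exists at this scale (the real panel's SNP identities are
restricted), so `simulate_population()` generates one with the structure
the analysis assumes: by default 190 cultivars × 500 SNPs over 12
chromosomes with lengths matching the potato genome, REF frequencies
uniform on [0.35, 0.65] (markers are pre-selected for balance), dosages
i.i.d. binomial(4, REF) per marker, three duplicated accession pairs
differing by at most two single-dosage edits, and 1% missingness — each
default mirroring the cohort the method was developed on, fixed once and
not tuned thereafter. Positions are uniform per chromosome (strictly
increasing), and a Poisson(0.8) number of flanking variants at ±5–80 bp
exercises the flanking filter.

`simulate_kasp_plate()` models channel means as baseline + amplitude ×
allele fraction (FAM ∝ $d/4$, HEX ∝ $1-d/4$) with multiplicative
log-normal noise (CV 0.06), which reproduces the arc of five clusters seen
on real endpoint scatter plots. No signal-distribution parameters are
published for the assay chemistry; the defaults were calibrated once to
make the five clusters separable at realistic plate sizes, i.e. to the
qualitative phenomenology, not to any test outcome. Competition failure
compresses the allele fraction by a power law ($f^{\gamma}$ towards FAM,
$1-(1-f)^{\gamma}$ towards HEX, $\gamma = 0.08$), collapsing the four
upper (or lower) dosage clusters the way preferential primer
amplification does. What the simulator does **not** model: read-level
sequencing noise, plate spatial effects, DNA quality gradients, mixed-DNA
samples, or linkage between markers. Passing tests therefore demonstrate
correctness of the algorithms under the stated population model, not
robustness to every artefact of real plates.

All simulator randomness flows from one integer seed through a small
deterministic sub-seed derivation, so a population and its plates are
jointly reproducible and fixtures are byte-identical across runs.

## Problem sizes in the tests

The shipped tests run the caller on 25 plates of 94 wells, goodness-of-fit
on 10,000 simulated cultivars, exhaustive metric checks over all 25
single-locus dosage pairs, and panel fuzzing over 120-marker candidate
sets — sizes chosen so the whole suite completes in well under a minute
per file while leaving each statistical check adequately powered.

## Known limitations

* Ploidies other than four are out of scope end to end; the Kosman
  reduction used here is specific to bi-allelic tetraploid dosages.
* The product rule assumes marker independence; panels are spaced to make
  linkage negligible, but no LD correction is applied.
* The mixture caller assumes roughly homoscedastic clusters on the
  fraction axis; severe heteroscedasticity would be flagged as failure
  rather than modelled.
* The accumulation curve's wildcard rule is intentionally conservative
  under missingness; with heavy missingness it can understate
  distinguishability.
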