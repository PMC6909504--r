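---
title: "Methods: allele-specific chromatin analysis with imprintseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific chromatin analysis with imprintseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintseq)
```

# The scientific problem

At imprinted domains, a germline differentially methylated region (DMR)
carries CpG methylation on one parental allele only. Because CTCF binding
is methylation-sensitive, the unmethylated allele gains CTCF-anchored loop
anchors that the methylated allele lacks. The measurable consequences are
(i) mono-allelic CTCF ChIP-seq peaks on top of a background of bi-allelic
sites, (ii) an allele-specific sub-TAD visible as redistributed 4C-seq
contacts within the parent TAD, (iii) insulation structure in Hi-C
matrices, (iv) allele-biased expression of the domain's genes, and (v)
altered 3D distances between probes flanking the new boundary. `imprintseq`
implements the quantitative analysis for each of these readouts, plus a
seeded generator of synthetic data with exactly this structure so that
every stage can be validated against planted truth.

# Coordinate conventions

All internal coordinates are 0-based half-open, the BED convention.
Region strings written 1-based inclusive (e.g.
`"chr7:141,530,000-143,520,000"`) are converted by `parse_region()`.
Restriction fragments are half-open tiles between cut sites; a blunt
4-cutter such as DpnII cuts at the motif start (`^GATC`), and only the
relative fragment structure matters downstream. Reads are assigned to the
fragment or bin containing their 5' end; fragments are assigned to regions
by their midpoint, which is unambiguous for fragments straddling a border.
Fragment and bin indices are 1-based in the R API.

# ChIP-seq stage

Coverage is counted in 50-bp bins from reads extended to 200 bp
(strand-aware: plus-strand reads grow 3'-ward, minus-strand reads grow
5'-ward from their 3' end, clipped at the chromosome).

**Blacklisting.** Bins with no input signal, or input at or above
`median + 3·IQR` of the input distribution, are removed before
normalisation. Quantiles are type-7 (linear interpolation), the most
common default; the estimator is not otherwise constrained by the
procedure. The thresholds are inclusive, so a constant positive input
(IQR = 0) flags every bin — a documented degenerate case rather than an
error.

**Quantile normalisation.** Each track's value at rank *r* becomes the
across-sample mean of the sorted values at rank *r*; a tied group shares
the mean of the reference values its ranks span. Ranks are preserved
within each track, and on tie-free data all marginal distributions become
exactly identical. The same implementation serves the RNA-seq stage.
Note that with ties the marginals are only identical up to tie-group
averaging; this is inherent to rank ties, not an implementation choice.

**Peak calling.** A peak core is a maximal run of ≥ 4 consecutive bins
with normalised value ≥ 20 *in at least one sample* (the union criterion
across companion tracks), extended by 1 bin on each side; overlapping
extended peaks merge. The value threshold applies after quantile
normalisation — the natural reading of the pipeline order, since peaks are
compared across samples on a common scale. The reported `peak_value` is
the maximum normalised value over the un-extended core (configurable to
mean or sum): the run rule is itself a max-type criterion, and the maximum
is insensitive to the extension bins. A peak is *differential* when the
two samples' peak values over the same core differ by ≥ 3-fold
(inclusive); a zero opposite value yields fold `Inf`, hence differential.

# Allelic read assignment

A read is `maternal` if at least one overlapped SNP matches the maternal
base and none matches the paternal base (symmetrically `paternal`),
`conflicting` if both alleles match at different SNPs, otherwise
`uninformative`. Matching requires exact base equality; ambiguous codes
count as mismatches. Conflicting reads are excluded from allelic tracks
and only counted — with validation (not quantification) as the purpose,
exclusion is the conservative default.

# 4C-seq stage

A 4C profile is one value per restriction fragment for one (viewpoint,
allele, replicate).

* **Viewpoint masking.** The viewpoint fragment and one fragment each side
  are masked (NA) before any normalisation or distribution: self-ligation
  and undigested templates dominate these fragments in real 4C libraries.
  The flank width is configurable.
* **Smoothing** (`smooth_track()`, default 11 fragments) is a centred
  running mean with truncated windows at the edges. Smoothed tracks are
  for visualisation and ratio tracks only.
* **Window normalisation** (`normalize_to_window()`) scales each track so
  its total over a fixed window — in practice the several TADs around the
  viewpoint — equals `target_total = 1e6` ("signal per million in
  window"). The constant is arbitrary: ratios, shares and the G test are
  invariant to it, and likewise to whether the normaliser divides by the
  window sum or mean. The operation is idempotent.
* **Sub-domain distributions** use *unsmoothed* normalised data (smoothing
  would bleed signal across sub-domain borders); signal is expressed per
  Mb and as a share of the partition total.
* **The fragment-fraction G test** classifies each usable fragment as
  maternal-higher or paternal-higher; exact ties (including 0/0
  fragments) belong to neither class and are dropped but counted. The
  2×2 region-by-direction table is tested with
  `G = 2 Σ O·ln(O/E)`, zero cells contributing 0 (the `x ln x → 0`
  limit), against χ²(1). Williams' correction is available but off by
  default. A zero margin makes the test undefined and raises an error
  rather than a silent NA. The test assumes fragments are independent
  under the null — true for multinomial sampling noise, but not for
  shared bin-level biological noise, which is why the synthetic null
  draws both alleles from the same expected profile.

# Hi-C stage

**ICE balancing** iteratively divides the matrix by the outer product of
its relative row sums until all unmasked row sums agree to a relative
tolerance of 1e-5 (cap 200 iterations; non-convergence warns with the
final residual). All-zero rows are masked and preserved; symmetry is
preserved exactly; the bias vector is strictly positive.

**Insulation index.** The index at bin *i* is the mean of the w×w square
of contacts spanning `(i−w..i−1) × (i+1..i+w)` — mean rather than sum, so
the index is comparable across window sizes; the variant is configurable
in principle but the mean is what the boundary logic assumes. Bins
without a full square are masked; squares overlapping masked rows use
available entries when at least half are present. Boundaries are local
minima strictly below both neighbours (a plateau of equal minima reports
its centre bin) with index at or below the cutoff. Because an absolute
cutoff (such as the published 21.75 of the original TADtool analysis) is
specific to one normalisation scale, the caller also accepts a percentile
cutoff; the planted-recovery studies use the 10th percentile of the valid
index values.

# RNA-seq stage

Replicate TPM columns are quantile-normalised together and averaged per
sample. Detection: combined TPM ≥ 5 in either sample. Differential:
highest TPM ≥ 5 **and** fold (larger/smaller) ≥ 1.5 **and**
highest TPM × fold ≥ 50, all inclusive. A zero denominator is floored at
0.1 TPM before the fold — the rule is otherwise undefined at zero, and the
floor keeps the product criterion meaningful; the floor is configurable.

# DNA-FISH stage

Spot centres outside the nucleus mask (sphere or axis-aligned ellipsoid)
are discarded. Channels are paired by **mutual** nearest neighbours:
each A-spot takes its closest B-spot only if it is also that B-spot's
closest A-spot, so noise spots never steal partners when counts differ
between channels. Distances are normalised by genomic separation (per Mb
by default; the functional form is configurable since physical-to-genomic
scaling is model-dependent). Two conditions are compared with a
two-tailed unpaired Mann-Whitney test: `U = #{x_i > y_j} + ties/2`.
For pooled samples up to 20 the two-sided p-value is exact — complete
enumeration of group assignments via midranks when ties are present, the
exact tie-free U distribution otherwise — and larger samples use the
normal approximation with tie-corrected variance and continuity
correction.

# The synthetic generator: what it emulates and what it does not

The default geometry is a 3-Mb chromosome with a 1.6-Mb TAD split into
three named sub-domains (0.45 / 0.6 / 0.55 Mb), mirroring the scale of a
maternally CTCF-structured imprinted domain, with DpnII-like fragments at
~400 bp mean spacing (exponential spacings). Noise models are the
standard count distributions: Poisson for ChIP bins, multinomial
(conditional on the read total) for 4C, negative binomial for Hi-C
(dispersion 0.1 by default; dispersion 0 returns the deterministic
expectation). Contacts decay as `|i−j|^(−1)` with multiplicative TAD
(×2–3) and allele-specific sub-domain boosts. Every generator takes an
explicit seed and is bit-stable under it.

Study conditions fixed by design (and used unchanged by the tests and the
acceptance script):

* **4C power study**: 2-fold maternal boost of the central sub-domain,
  1e5 reads per allele, viewpoint inside the boosted sub-domain.
  The **null** draws both alleles' multinomials from the *same* expected
  profile: bin-level matrix noise shared by the ~25 fragments of a bin
  would correlate fragment classifications and invalidate the
  fragment-independence the G test assumes, so the null isolates exactly
  the sampling noise the test is built for.
* **Redistribution study**: the maternal expected profile has the distal
  sub-domain's mass halved and moved into the central sub-domain
  (`plant_redistribution()`), leaving the two sub-domains' combined mass
  unchanged by construction — the generator-level statement of "contacts
  redistribute between sub-TADs while their combined signal stays equal
  across alleles".
* **ChIP landscape** (`chip_peak_landscape()`): 20 strong bi-allelic peaks
  (heights 20–50), 20 weak bi-allelic peaks (heights 2–18) and one
  maternal-specific site (paternal height 5, allele fold 8) on 4000 bins.
  The weak peaks matter: real peak landscapes have a continuous height
  spectrum, and quantile normalisation across alleles relies on it — with
  only a few strong peaks the rank gap distorts values near the mono-
  allelic site. ChIP background is Poisson(1); the input sample is
  deeply covered (Poisson(50)) so that blacklisting flags planted
  artifacts rather than random zero bins.
* **TAD study** (`tad_study()`): three 500-kb TADs tiling 1.5 Mb at 10-kb
  bins, within-TAD boost ×3, junctions at bins 51 and 101, insulation
  window 50 kb (the 500-kb default scaled to the toy domain).
* **FISH**: spots in 4-µm-radius spherical nuclei, expected inter-probe
  distance `0.9·(separation/Mb)^(1/3)` µm (globular-polymer scaling,
  configurable), isotropic Gaussian localisation noise.
* **SNP density**: 1 SNP per 150 bp in the read-assignment fixtures, a
  configurable stand-in for a dense strain-hybrid SNP map.

The generator does **not** emulate read-level sequencing artifacts
(quality scores, mappability, PCR duplicates), trans-chromosomal contacts,
replicate batch effects, or microscope point-spread functions. Passing
tests therefore demonstrate that the *computations* are correct and that
the planted effects are recoverable at realistic depths — not that the
pipeline is robust to every artifact of real libraries.

# Numerical choices

* Chi-square tail probabilities and type-7 quantiles delegate to R's
  `pchisq`/`quantile`; the test suite verifies them against adaptive
  quadrature (to 1e-10) and sort-based oracles.
* Writers are deterministic: rows sorted by (chrom, start), scores printed
  with 6 significant digits, no track lines.
* Exact Mann-Whitney enumeration is limited to pooled n ≤ 22 when ties are
  present (`choose(22, 11)` assignments); tie-free exact p-values have no
  practical limit.
* Plateau minima in boundary calling report the centre bin — a
  deterministic tie-break; edge runs of the insulation profile cannot be
  confirmed as minima and are never boundaries.
* Degenerate inputs fail loudly: zero G-test margins, all-zero viewpoint
  rows, empty partitions and empty FISH channels are errors, not NAs.

# Problem sizes

The validation suite runs 1000 randomized instances per oracle comparison
(tracks of 50–80 bins, matrices up to 15×15, pooled Mann-Whitney samples
up to 16), 100 seeds for the 4C power/size and ChIP recovery studies,
50 seeds for TAD-junction recall and 500 nuclei for the FISH calibration
check — sizes chosen so the full suite completes in well under a minute
per module on a laptop while keeping Monte-Carlo error far below the
asserted margins.

# Known limitations

* Interval utilities assume per-chromosome analyses; multi-chromosome
  matrices are not modelled.
* The G test treats fragments as independent; overdispersed biological
  replicates would need a replicate-aware test (variance-stabilised
  z-scores from a dedicated 4C package) rather than this fragment-level
  one.
* The insulation caller reports boundary bins, not domain calls; nested
  sub-TAD segmentation is left to interpretation of the profile.
* `read_bed`/`read_bedgraph` handle the plain dialects of these formats,
  not browser extensions.
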