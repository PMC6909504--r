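# imprintseq

Allele-specific chromatin analysis of imprinted domains, in R.

At imprinted loci, germline differential DNA methylation blocks CTCF binding
on one parental chromosome. The allele that does bind CTCF acquires extra
loop anchors, which restructure the local topologically associating domain
(TAD) into allele-specific sub-TADs and redistribute chromatin contacts —
without changing the total contact budget of the domain. `imprintseq`
implements the complete quantitative toolkit needed to detect and test this
kind of allelic chromatin organisation:

* **Allelic ChIP-seq peak calling** on 50-bp coverage bins: input-based
  blacklisting (bins with zero input or ≥ median + 3·IQR), quantile
  normalisation across samples, peak calling when ≥ 4 consecutive bins are
  ≥ 20 in at least one sample (extended 1 bin each side), and differential
  (allelic) calls at ≥ 3-fold difference in peak values.
* **Allelic read assignment** from strain SNPs (maternal / paternal /
  uninformative / conflicting) and strand-aware 200-bp read extension.
* **Allelic 4C-seq quantification** per restriction fragment: 11-fragment
  running-mean smoothing, normalisation of each track to the signal inside
  a fixed multi-TAD window, log2 maternal/paternal ratio tracks, per-Mb
  sub-domain signal distributions, and the fragment-fraction **G test of
  independence**: classify each fragment as maternal-higher or
  paternal-higher, tabulate by region into a 2×2 table, and test

  `G = 2 · Σᵢⱼ Oᵢⱼ · ln(Oᵢⱼ / Eᵢⱼ)  ~  χ²(1)`

  with expected counts `Eᵢⱼ` from the table margins.
* **TAD calling on Hi-C matrices**: ICE (iterative correction) balancing of
  10-kb binned contact matrices and insulation-index boundary calling
  (mean contact in a sliding w×w square across the diagonal, default
  window 500 kb; boundaries are sub-cutoff local minima).
* **Mono-parental RNA-seq filtering**: quantile-normalised, replicate-
  averaged TPM tables; detection at TPM ≥ 5 and the compound differential
  rule (fold ≥ 1.5 and max TPM × fold ≥ 50).
* **3D DNA-FISH statistics**: nucleus-mask filtering of segmented spot
  centres, mutual-closest-neighbour probe pairing, genomic-distance
  normalisation, and a two-tailed unpaired Mann-Whitney test (exact for
  small samples, tie-corrected normal approximation otherwise).
* A **seeded synthetic-data generator** that emulates a 3-Mb imprinted
  domain (a 1.6-Mb TAD split into three sub-domains, planted bi- and
  mono-allelic CTCF peaks, a maternal-specific sub-TAD, SNP-bearing reads
  of known parental origin, TPM tables, FISH nuclei), so the whole pipeline
  is testable without any sequencing data.

Real data enter through plain-text formats: BED, bedGraph, TSV tables and
dense matrix text (`read_bed()`, `read_bedgraph()`, `read_matrix_txt()`,
`read_tsv()`).

## Worked example

Simulate an allelic 4C study with a planted 2-fold maternal sub-TAD and
test whether contacts distribute differently between the sub-domains on
the two parental chromosomes:

```r
library(imprintseq)

st  <- fourc_study(seed = 42, condition = "boost")
a   <- st$partition[st$partition$name == "dlk1_meg3", ]
b   <- st$partition[st$partition$name != "dlk1_meg3", ]
allelic_subdomain_test(st$maternal, st$paternal, a, b)
#> allelic_comparison (fragments with maternal > paternal signal):
#>          maternal_higher paternal_higher
#> region_a            1014             372
#> region_b             346            1929
#> fractions maternal-higher: 0.732 vs 0.152; G = 1279, p = 5.23e-280 (283 ties dropped)
```

73% of fragments in the planted sub-TAD have higher maternal signal versus
15% elsewhere in the TAD; the G test rejects independence decisively.
The per-Mb sub-domain distribution of the same maternal track:

```r
subdomain_distribution(st$maternal, st$partition)
#>        name   start     end signal density_per_mb      share
#> 1    begain  700000 1150000  55900      124222.22 0.05789147
#> 2 dlk1_meg3 1150000 1750000 859340     1432233.33 0.88995443
#> 3 mirg_dio3 1750000 2300000  50360       91563.64 0.05215410
```

The allelic ChIP pipeline on the default planted peak landscape (40
bi-allelic peaks plus one maternal-specific site at 155 kb, allele fold 8)
recovers exactly the planted mono-allelic peak:

```r
sim <- simulate_chip_bins(chip_peak_landscape(), n_bins = 4000, seed = 42)
bl  <- blacklist_from_input(sim$input)
qn  <- quantile_normalize(list(sim$maternal, sim$paternal), blacklist = bl)
dc  <- call_differential(call_peaks(qn[[1]], companion_tracks = qn[2]),
                         qn[[1]], qn[[2]])
dc[dc$status == "differential", c("start", "end", "value_a", "value_b", "fold")]
#>     start    end value_a value_b     fold
#> 17 154700 155300   46.25 8.15625 5.670498
```

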