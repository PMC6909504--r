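# Seeded synthetic-data generators emulating an imprinted domain: planted
# bi-/mono-allelic ChIP peaks, two-haplotype contact matrices with a
# maternal-specific sub-TAD, viewpoint-sampled 4C fragment counts,
# SNP-bearing reads of known parental origin, mono-parental TPM tables and
# 3D FISH spot coordinates.  Every generator takes an explicit seed and is
# bit-stable under it.
#
# Noise models: Poisson for ChIP bins, multinomial (conditional on the read
# total) for 4C, negative binomial for Hi-C counts (dispersion 0 = no
# noise, i.e. the deterministic expectation).

#' Default imprinted-domain geometry
#'
#' One 3-Mb chromosome carrying a 1.6-Mb TAD split into three named
#' sub-domains (mimicking the Begain / Dlk1-Meg3 / Mirg-Dio3 organisation of
#' a maternally CTCF-structured locus).
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @return List with `chrom`, `chrom_length`, `tad` (interval data frame,
#'   possibly several rows) and `partition` (named sub-domain intervals).
#' @export
domain_spec <- function(chrom = "chrSim", chrom_length = 3e6) {
  tad <- gintervals(chrom, 7e5, 2.3e6)
  partition <- gintervals(chrom, c(7e5, 1.15e6, 1.75e6),
                          c(1.15e6, 1.75e6, 2.3e6),
                          name = c("begain", "dlk1_meg3", "mirg_dio3"))
  list(chrom = chrom, chrom_length = chrom_length, tad = tad,
       partition = partition)
}

#' Simulate a DpnII-like fragment map
#'
#' Exponentially spaced cut sites with a given mean spacing (a 4-cutter's
#' genome-wide average is ~256 bp; ~400 bp mimics the mappable-fragment
#' spacing of the locus).
#'
#' @param chrom_length chromosome length in bp.
#' @param mean_spacing mean fragment length in bp (default 400).
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return A [restriction_map()].
#' @export
simulate_fragment_map <- function(chrom_length, mean_spacing = 400, seed,
                                  chrom = "chrSim") {
  set.seed(seed)
  gaps <- stats::rexp(ceiling(2 * chrom_length / mean_spacing),
                      rate = 1 / mean_spacing)
  cuts <- round(cumsum(gaps))
  cuts <- unique(cuts[cuts > 0 & cuts < chrom_length])
  digest(cuts = cuts, chrom_length = chrom_length, chrom = chrom)
}

#' Simulate a pair of allelic contact matrices
#'
#' Expected contact between bins `i`, `j` is
#' `base * |i-j|^decay_exponent`, multiplied by `tad_boost` when both bins
#' lie in the same TAD and further by the allele's sub-domain boost when
#' both lie in the same sub-domain.  Counts are negative-binomial around
#' that expectation (`noise_dispersion = 0` returns the expectation
#' itself); matrices are symmetric with a zero diagonal (self-contacts are
#' uninformative in binned Hi-C).
#'
#' @param spec a [domain_spec()].
#' @param bin_width bin width in bp (default 10 kb); a chromosome length
#'   that is not a multiple is truncated to whole bins with a warning.
#' @param base contact scale at unit bin distance.
#' @param decay_exponent power-law distance-decay exponent (< 0).
#' @param tad_boost within-TAD contact multiplier (>= 1).
#' @param subtad_boost named list per allele (`maternal`, `paternal`) of
#'   named per-sub-domain multipliers, e.g.
#'   `list(maternal = c(dlk1_meg3 = 2), paternal = NULL)`.
#' @param noise_dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); 0 = deterministic.
#' @param seed RNG seed.
#' @return List with `maternal` and `paternal` [contact_matrix()] objects
#'   and their `expected` matrices.
#' @export
simulate_contact_matrix <- function(spec, bin_width = 10000, base = 100,
                                    decay_exponent = -1, tad_boost = 2,
                                    subtad_boost = list(maternal = NULL,
                                                        paternal = NULL),
                                    noise_dispersion = 0.1, seed) {
  if (decay_exponent >= 0) stop("decay_exponent must be < 0")
  if (tad_boost < 1) stop("boosts must be >= 1")
  set.seed(seed)
  if (spec$chrom_length %% bin_width != 0)
    warning("chromosome length not a multiple of bin_width; last bin truncated")
  n <- floor(spec$chrom_length / bin_width)
  mids <- (seq_len(n) - 0.5) * bin_width
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E0 <- base * pmax(d, 1)^decay_exponent
  diag(E0) <- 0
  in_iv <- function(iv) mids >= iv["start"] & mids < iv["end"]
  for (k in seq_len(nrow(spec$tad))) {
    inb <- mids >= spec$tad$start[k] & mids < spec$tad$end[k]
    E0[inb, inb] <- E0[inb, inb] * tad_boost
  }
  make_allele <- function(allele) {
    E <- E0
    boosts <- subtad_boost[[allele]]
    if (!is.null(boosts)) {
      if (any(boosts < 1)) stop("boosts must be >= 1")
      for (nm in names(boosts)) {
        part <- spec$partition[spec$partition$name == nm, , drop = FALSE]
        if (nrow(part) == 0) stop("unknown sub-domain: ", nm)
        inb <- mids >= part$start & mids < part$end
        E[inb, inb] <- E[inb, inb] * boosts[[nm]]
      }
    }
    if (noise_dispersion > 0) {
      up <- upper.tri(E)
      mu <- E[up]
      noisy <- stats::rnbinom(length(mu), mu = mu,
                              size = 1 / noise_dispersion)
      M <- matrix(0, n, n)
      M[up] <- noisy
      M <- M + t(M)
    } else M <- E
    cm <- contact_matrix(M, bin_width, origin = 0, chrom = spec$chrom)
    attr(cm, "expected") <- E
    cm
  }
  list(maternal = make_allele("maternal"),
       paternal = make_allele("paternal"))
}

#' Redistribute expected 4C signal between two bin sets
#'
#' Scales the probability mass over `bins_a` by `factor` and compensates on
#' `bins_b` so the combined mass over A and B is unchanged — a pure
#' redistribution planting, leaving the two regions' combined signal equal
#' across alleles by construction.
#'
#' @param row non-negative expected-signal row (one value per bin).
#' @param bins_a,bins_b disjoint bin index vectors.
#' @param factor multiplier on `bins_a` (> 0).
#' @return Modified row.
#' @export
plant_redistribution <- function(row, bins_a, bins_b, factor) {
  if (length(intersect(bins_a, bins_b))) stop("bin sets must be disjoint")
  sa <- sum(row[bins_a]); sb <- sum(row[bins_b])
  if (sb == 0) stop("no mass on bins_b to compensate with")
  comp <- (sa + sb - factor * sa) / sb
  if (comp <= 0) stop("factor too large: compensation would be non-positive")
  row[bins_a] <- row[bins_a] * factor
  row[bins_b] <- row[bins_b] * comp
  row
}

#' Simulate 4C fragment counts from a viewpoint
#'
#' The 4C profile is the viewpoint row of the contact distribution:
#' `n_reads` are multinomially distributed over fragments with
#' probabilities proportional to the viewpoint row, spread uniformly over
#' the fragments of each bin (fragment midpoint rule).
#'
#' @param matrix a [contact_matrix()] (or pass `row_probs` directly).
#' @param viewpoint_bin 1-based viewpoint bin index.
#' @param n_reads total reads (> 0); the track sums to this exactly.
#' @param fragment_map a [restriction_map()] covering the matrix span.
#' @param seed RNG seed.
#' @param allele,replicate labels stored on the track.
#' @param row_probs optional explicit expected row overriding the matrix
#'   row (e.g. after [plant_redistribution()]).
#' @return A [fragment_track()] with the viewpoint fragment index set.
#' @export
simulate_4c_counts <- function(matrix = NULL, viewpoint_bin, n_reads,
                               fragment_map, seed, allele = "combined",
                               replicate = 1L, row_probs = NULL) {
  if (n_reads <= 0) stop("n_reads must be > 0")
  if (is.null(row_probs)) {
    n <- nrow(matrix$values)
    if (viewpoint_bin < 1 || viewpoint_bin > n)
      stop("viewpoint bin outside matrix")
    row_probs <- matrix$values[viewpoint_bin, ]
    bin_width <- matrix$bin_width
    origin <- matrix$origin
  } else {
    bin_width <- attr(row_probs, "bin_width")
    origin <- attr(row_probs, "origin")
    if (is.null(bin_width)) stop("row_probs needs bin_width/origin attributes")
  }
  if (sum(row_probs) <= 0) stop("all-zero viewpoint row")
  set.seed(seed)
  mids <- fragment_midpoints(fragment_map)
  fbin <- floor((mids - origin) / bin_width) + 1
  fbin[fbin < 1 | fbin > length(row_probs)] <- NA
  per_bin <- tabulate(fbin[!is.na(fbin)], nbins = length(row_probs))
  probs <- ifelse(is.na(fbin), 0, row_probs[fbin] / pmax(per_bin[fbin], 1))
  counts <- as.numeric(stats::rmultinom(1, size = n_reads,
                                        prob = probs / sum(probs)))
  vp_pos <- origin + (viewpoint_bin - 0.5) * bin_width
  vp_frag <- locate_fragment(fragment_map, min(vp_pos,
                                               max(mids)))
  fragment_track(fragment_map, counts, viewpoint = vp_frag,
                 allele = allele, replicate = replicate)
}

#' Simulate allelic ChIP coverage bins plus an input track
#'
#' Per-bin counts are Poisson around background plus rectangular peak
#' contributions.  Each planted peak has `height` = expected paternal
#' per-bin coverage and `allele_fold` = maternal/paternal ratio, so the
#' maternal expectation at peak bins is `height * allele_fold`
#' (`allele_fold = 1` plants a bi-allelic peak).  The input track is
#' peak-free background at `input_rate`, with optional planted artifact
#' regions (spikes) and zero regions for blacklist testing.
#'
#' @param peaks data frame: `center` (bp), `width` (bp), `height`,
#'   `allele_fold`.
#' @param background_rate ChIP background Poisson rate per bin (default 1).
#' @param n_bins number of 50-bp bins.
#' @param bin_width bin width in bp (default 50).
#' @param input_rate input-sample background rate (default 50).
#' @param artifact_regions optional interval data frame: input bins inside
#'   are multiplied by 20 (alignment-artifact spikes).
#' @param zero_regions optional interval data frame: input bins inside are
#'   set to 0.
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return List of [binned_track()]s `maternal`, `paternal`, `input`, plus
#'   `expected` (per-allele expectation vectors).
#' @export
simulate_chip_bins <- function(peaks, background_rate = 1, n_bins,
                               bin_width = 50, input_rate = 50,
                               artifact_regions = NULL, zero_regions = NULL,
                               seed, chrom = "chrSim") {
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (!is.null(peaks) && nrow(peaks) &&
      (any(peaks$height <= 0) || any(peaks$allele_fold <= 0)))
    stop("peak height and allele_fold must be > 0")
  set.seed(seed)
  s <- (seq_len(n_bins) - 1) * bin_width
  mids <- s + bin_width / 2
  e_mat <- rep(background_rate, n_bins)
  e_pat <- rep(background_rate, n_bins)
  if (!is.null(peaks)) for (k in seq_len(nrow(peaks))) {
    inb <- abs(mids - peaks$center[k]) <= peaks$width[k] / 2
    e_pat[inb] <- e_pat[inb] + peaks$height[k]
    e_mat[inb] <- e_mat[inb] + peaks$height[k] * peaks$allele_fold[k]
  }
  mat <- binned_track(chrom, 0, bin_width, stats::rpois(n_bins, e_mat))
  pat <- binned_track(chrom, 0, bin_width, stats::rpois(n_bins, e_pat))
  e_in <- rep(input_rate, n_bins)
  inp <- binned_track(chrom, 0, bin_width, stats::rpois(n_bins, e_in))
  if (!is.null(artifact_regions)) {
    hit <- bins_in_intervals(inp, artifact_regions)
    inp$values[hit] <- inp$values[hit] * 20
  }
  if (!is.null(zero_regions)) {
    hit <- bins_in_intervals(inp, zero_regions)
    inp$values[hit] <- 0
  }
  list(maternal = mat, paternal = pat, input = inp,
       expected = list(maternal = e_mat, paternal = e_pat))
}

#' Simulate SNP-bearing reads of known parental origin
#'
#' Reads are placed uniformly on the chromosome; each carries a hidden true
#' allele label (maternal with probability `maternal_fraction`).  The
#' sequence is the reference base (`A`) everywhere except at SNP positions,
#' where the true allele's base is copied; each base is then substituted
#' with probability `error_rate` by a uniformly chosen different base.
#'
#' @param snps a [snp_table()].
#' @param n_reads number of reads.
#' @param read_length read length in bp (>= 1).
#' @param maternal_fraction probability a read is maternal (in `[0, 1]`).
#' @param error_rate per-base substitution probability.
#' @param chrom_length chromosome length in bp.
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return Read data frame (`chrom`, `start`, `length`, `strand`,
#'   `sequence`) with the hidden `true_allele` column.
#' @export
simulate_snp_reads <- function(snps, n_reads, read_length, maternal_fraction,
                               error_rate = 0, chrom_length, seed,
                               chrom = "chrSim") {
  if (read_length < 1) stop("read_length must be >= 1")
  if (maternal_fraction < 0 || maternal_fraction > 1)
    stop("maternal_fraction must be in [0, 1]")
  set.seed(seed)
  starts <- sample.int(chrom_length - read_length + 1, n_reads,
                       replace = TRUE) - 1
  truth <- ifelse(stats::runif(n_reads) < maternal_fraction,
                  "maternal", "paternal")
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_reads), function(i) {
    b <- rep("A", read_length)
    idx <- which(snps$positions >= starts[i] &
                   snps$positions < starts[i] + read_length)
    if (length(idx)) {
      src <- if (truth[i] == "maternal") snps$maternal else snps$paternal
      b[snps$positions[idx] - starts[i] + 1] <- src[idx]
    }
    if (error_rate > 0) {
      err <- which(stats::runif(read_length) < error_rate)
      for (j in err) b[j] <- sample(setdiff(bases, b[j]), 1)
    }
    paste(b, collapse = "")
  }, "")
  data.frame(chrom = chrom, start = starts, length = read_length,
             strand = strand, sequence = seqs, true_allele = truth,
             stringsAsFactors = FALSE)
}

#' Simulate a two-sample TPM table with planted differential transcripts
#'
#' Baseline transcript abundances are log-normal; `differential_spec` rows
#' plant transcripts at a given TPM in the up-sample and `1/fold` of it in
#' the other.  Replicate columns get multiplicative log-normal noise and
#' each column is rescaled to sum to 1e6 (the TPM convention).
#'
#' @param n_transcripts number of transcripts.
#' @param differential_spec data frame: `transcript` (index), `tpm`
#'   (up-sample abundance before rescaling), `fold` (> 1), `up_in`
#'   (`"PR8"` or `"AK2"`); NULL for a null table.
#' @param n_reps replicates per sample (default 3).
#' @param cv replicate coefficient of variation (> 0; zero-variance specs
#'   are rejected).
#' @param seed RNG seed.
#' @return Data frame `transcript`, `PR8_1..n`, `AK2_1..n`; the planted
#'   truth is attached as attribute `truth`.
#' @export
simulate_expression <- function(n_transcripts, differential_spec = NULL,
                                n_reps = 3, cv = 0.1, seed) {
  if (cv <= 0) stop("degenerate (zero-variance) spec rejected")
  set.seed(seed)
  base <- stats::rlnorm(n_transcripts, meanlog = log(5), sdlog = 1.5)
  mu <- list(PR8 = base, AK2 = base)
  if (!is.null(differential_spec)) for (k in seq_len(nrow(differential_spec))) {
    i <- differential_spec$transcript[k]
    up <- differential_spec$up_in[k]
    dn <- setdiff(c("PR8", "AK2"), up)
    mu[[up]][i] <- differential_spec$tpm[k]
    mu[[dn]][i] <- differential_spec$tpm[k] / differential_spec$fold[k]
  }
  sdlog <- sqrt(log(1 + cv^2))
  out <- data.frame(transcript = paste0("tx", seq_len(n_transcripts)),
                    stringsAsFactors = FALSE)
  for (s in c("PR8", "AK2")) for (r in seq_len(n_reps)) {
    v <- mu[[s]] * stats::rlnorm(n_transcripts, -sdlog^2 / 2, sdlog)
    out[[paste0(s, "_", r)]] <- v / sum(v) * 1e6
  }
  attr(out, "truth") <- differential_spec
  out
}

#' Simulate 3D FISH spot pairs inside spherical nuclei
#'
#' For each nucleus and probe pair, spot A is placed uniformly inside a
#' sphere of the given radius and spot B at distance
#' `scale_model(genomic separation)` in a random direction, plus isotropic
#' Gaussian noise; placements leaving the nucleus are redrawn.
#'
#' @param n_nuclei number of nuclei.
#' @param probe_pairs character vector of pair labels.
#' @param genomic_separations separations in bp, one per pair.
#' @param scale_model function mapping separation (bp) to expected distance
#'   (micrometres); default globular-polymer cube-root scaling
#'   `0.9 * (sep/1e6)^(1/3)`.
#' @param noise_sd isotropic per-axis Gaussian noise (micrometres).
#' @param radius nucleus radius (micrometres, default 4).
#' @param seed RNG seed.
#' @return Spot data frame: `nucleus`, `pair`, `channel` (`A`/`B`), `x`,
#'   `y`, `z`, `intensity`; nucleus `radius` attached as attribute.
#' @export
simulate_fish_nuclei <- function(n_nuclei, probe_pairs, genomic_separations,
                                 scale_model = function(sep)
                                   0.9 * (sep / 1e6)^(1/3),
                                 noise_sd = 0.05, radius = 4, seed) {
  if (length(probe_pairs) != length(genomic_separations))
    stop("one genomic separation per probe pair")
  if (any(genomic_separations <= 0)) stop("separations must be > 0")
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_nuclei)) for (k in seq_along(probe_pairs)) {
    d <- scale_model(genomic_separations[k])
    repeat {
      a <- stats::rnorm(3)
      a <- a / sqrt(sum(a^2)) * radius * stats::runif(1)^(1/3)
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      b <- a + d * u + stats::rnorm(3, sd = noise_sd)
      if (sum(b^2) <= radius^2) break
    }
    rows[[length(rows) + 1]] <- data.frame(
      nucleus = i, pair = probe_pairs[k], channel = c("A", "B"),
      x = c(a[1], b[1]), y = c(a[2], b[2]), z = c(a[3], b[3]),
      intensity = 1, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "radius") <- radius
  out
}

#' Default planted ChIP peak landscape
#'
#' The peak set used by the allelic ChIP-seq worked example: 20 strong
#' bi-allelic peaks (expected heights 20-50, a realistic continuous
#' spectrum above the value-20 calling threshold), 20 weak bi-allelic peaks
#' (heights 2-18, below threshold, filling the rank spectrum the way a real
#' genome-wide peak landscape does), and one maternal-specific peak
#' (paternal height 5, allele fold 8 -- a Meg3-DMR-like site) at 155 kb.
#'
#' @return Peak specification data frame for [simulate_chip_bins()].
#' @export
chip_peak_landscape <- function() {
  data.frame(center = c(seq(10000, 190000, length.out = 20),
                        seq(14500, 185500, length.out = 20), 155000),
             width = 500,
             height = c(seq(20, 50, length.out = 20),
                        seq(2, 18, length.out = 20), 5),
             allele_fold = c(rep(1, 40), 8))
}

#' Simulate a complete allelic 4C study
#'
#' Builds the default imprinted-domain geometry, a seeded fragment map, a
#' deterministic expected contact profile and one multinomial 4C sample per
#' allele (1e5 reads each by default), then masks the viewpoint and
#' normalises both tracks to the full-domain window.  Three conditions:
#' \describe{
#'   \item{`boost`}{maternal contacts within the dlk1_meg3 sub-domain
#'     doubled (a maternal-specific sub-TAD).}
#'   \item{`redistribution`}{maternal mirg_dio3 contacts halved with the
#'     mass moved into dlk1_meg3, leaving the two sub-domains' combined
#'     signal equal across alleles by construction.}
#'   \item{`null`}{identical expected profiles; only sampling noise
#'     differs.}
#' }
#'
#' @param seed RNG seed (sub-seeds `seed+1`, `seed+2` drive the two
#'   multinomial draws).
#' @param condition `"boost"`, `"redistribution"` or `"null"`.
#' @param n_reads reads per allele (default 1e5).
#' @param viewpoint_bin viewpoint bin (default 140, inside dlk1_meg3).
#' @return List: `maternal`, `paternal` (normalised [fragment_track()]s),
#'   `partition`, `window`, `map`, `spec`.
#' @export
fourc_study <- function(seed, condition = c("boost", "redistribution",
                                            "null"),
                        n_reads = 1e5, viewpoint_bin = 140) {
  condition <- match.arg(condition)
  spec <- domain_spec()
  fm <- simulate_fragment_map(spec$chrom_length, 400, seed = seed)
  window <- gintervals(spec$chrom, 0, spec$chrom_length)
  bw <- 10000
  boost <- if (condition == "boost")
    list(maternal = c(dlk1_meg3 = 2), paternal = NULL)
  else list(maternal = NULL, paternal = NULL)
  sim <- simulate_contact_matrix(spec, bin_width = bw, noise_dispersion = 0,
                                 seed = seed, subtad_boost = boost)
  if (condition == "redistribution") {
    n <- nrow(sim$paternal$values)
    mids <- (seq_len(n) - 0.5) * bw
    part_bins <- function(nm) {
      p <- spec$partition[spec$partition$name == nm, ]
      which(mids >= p$start & mids < p$end)
    }
    row_p <- sim$paternal$values[viewpoint_bin, ]
    row_m <- plant_redistribution(row_p, part_bins("mirg_dio3"),
                                  part_bins("dlk1_meg3"), 0.5)
    attr(row_m, "bin_width") <- bw; attr(row_m, "origin") <- 0
    attr(row_p, "bin_width") <- bw; attr(row_p, "origin") <- 0
    mat <- simulate_4c_counts(viewpoint_bin = viewpoint_bin,
                              n_reads = n_reads, fragment_map = fm,
                              seed = seed + 1, allele = "maternal",
                              row_probs = row_m)
    pat <- simulate_4c_counts(viewpoint_bin = viewpoint_bin,
                              n_reads = n_reads, fragment_map = fm,
                              seed = seed + 2, allele = "paternal",
                              row_probs = row_p)
  } else {
    mat <- simulate_4c_counts(sim$maternal, viewpoint_bin, n_reads, fm,
                              seed = seed + 1, allele = "maternal")
    pat <- simulate_4c_counts(sim$paternal, viewpoint_bin, n_reads, fm,
                              seed = seed + 2, allele = "paternal")
  }
  mat <- normalize_to_window(mask_viewpoint(mat), window)
  pat <- normalize_to_window(mask_viewpoint(pat), window)
  list(maternal = mat, paternal = pat, partition = spec$partition,
       window = window, map = fm, spec = spec)
}

#' Simulate a three-TAD matrix with known junctions
#'
#' A 1.5-Mb chromosome tiled by three 500-kb TADs at 10-kb bins
#' (within-TAD contacts boosted 3-fold, negative-binomial noise), the
#' fixture for insulation-based boundary recovery.  The true junction bins
#' are 51 and 101.
#'
#' @param seed RNG seed.
#' @param noise_dispersion negative-binomial dispersion (default 0.1).
#' @return List: `matrix` (a [contact_matrix()]), `truth` (junction bins),
#'   `window_bp` (the insulation window matched to the toy scale, 50 kb).
#' @export
tad_study <- function(seed, noise_dispersion = 0.1) {
  spec <- list(chrom = "chrSim", chrom_length = 1.5e6,
               tad = gintervals("chrSim", c(0, 5e5, 1e6),
                                c(5e5, 1e6, 1.5e6)),
               partition = gintervals("chrSim", 0, 1.5e6, name = "all"))
  sim <- simulate_contact_matrix(spec, bin_width = 10000, tad_boost = 3,
                                 noise_dispersion = noise_dispersion,
                                 seed = seed)
  list(matrix = sim$maternal, truth = c(51L, 101L), window_bp = 50000)
}
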