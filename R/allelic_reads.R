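# Allelic read assignment from strain SNPs, and strand-aware read extension.
#
# Reads are rows of a data frame: chrom, start (0-based), length, strand
# ("+"/"-") and an optional sequence string.  SNP tables come from hybrid
# crosses (e.g. C57BL/6 x JF1): at each position the two parental genomes
# carry different bases, so a read overlapping a SNP can be assigned to the
# allele whose base it carries.

#' Construct a SNP table
#'
#' @param positions strictly increasing 0-based SNP positions.
#' @param maternal,paternal single characters per position; must differ
#'   at every SNP.
#' @return Data frame with class `snp_table`.
#' @export
snp_table <- function(positions, maternal, paternal) {
  if (any(diff(positions) <= 0)) stop("SNP positions must be strictly increasing")
  maternal <- toupper(as.character(maternal))
  paternal <- toupper(as.character(paternal))
  if (any(maternal == paternal)) stop("alleles must differ at every SNP")
  structure(data.frame(positions = positions, maternal = maternal,
                       paternal = paternal, stringsAsFactors = FALSE),
            class = c("snp_table", "data.frame"))
}

#' Assign a read to a parental allele
#'
#' Compares the read's bases at overlapped SNP positions with the two
#' parental bases.  A read is `maternal` if at least one SNP matches the
#' maternal base and none matches the paternal base (symmetrically for
#' `paternal`); `conflicting` if both alleles match at different SNPs;
#' `uninformative` if no SNP is overlapped or every overlapped base matches
#' neither allele.  Ambiguous (non-ACGT) read bases count as mismatches.
#'
#' @param read list or one-row data frame with `start`, `length`, `sequence`.
#' @param snps a [snp_table()].
#' @return List of class `allele_call` with `label`, `n_maternal_matches`,
#'   `n_paternal_matches`, `n_mismatches`.
#' @export
assign_allele <- function(read, snps) {
  if (is.null(read$sequence) || is.na(read$sequence))
    stop("read has no sequence")
  if (nchar(read$sequence) != read$length)
    stop("sequence length does not match read length")
  s <- read$start; e <- read$start + read$length
  idx <- which(snps$positions >= s & snps$positions < e)
  n_mat <- 0L; n_pat <- 0L; n_mis <- 0L
  if (length(idx)) {
    bases <- toupper(substring(read$sequence,
                               snps$positions[idx] - s + 1,
                               snps$positions[idx] - s + 1))
    n_mat <- sum(bases == snps$maternal[idx])
    n_pat <- sum(bases == snps$paternal[idx])
    n_mis <- length(idx) - n_mat - n_pat
  }
  label <- if (n_mat > 0 && n_pat == 0) "maternal"
  else if (n_pat > 0 && n_mat == 0) "paternal"
  else if (n_mat > 0 && n_pat > 0) "conflicting"
  else "uninformative"
  structure(list(label = label, n_maternal_matches = n_mat,
                 n_paternal_matches = n_pat, n_mismatches = n_mis),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  cat(sprintf("allele_call: %s (mat %d, pat %d, mismatch %d)\n", x$label,
              x$n_maternal_matches, x$n_paternal_matches, x$n_mismatches))
  invisible(x)
}

#' Assign many reads at once
#'
#' @param reads data frame of reads (`chrom`, `start`, `length`, `strand`,
#'   `sequence`).
#' @param snps a [snp_table()].
#' @return `reads` with added columns `label`, `n_maternal_matches`,
#'   `n_paternal_matches`, `n_mismatches`.
#' @export
assign_alleles <- function(reads, snps) {
  calls <- lapply(seq_len(nrow(reads)), function(i)
    assign_allele(reads[i, , drop = FALSE], snps))
  reads$label <- vapply(calls, `[[`, "", "label")
  reads$n_maternal_matches <- vapply(calls, `[[`, 0L, "n_maternal_matches")
  reads$n_paternal_matches <- vapply(calls, `[[`, 0L, "n_paternal_matches")
  reads$n_mismatches <- vapply(calls, `[[`, 0L, "n_mismatches")
  reads
}

#' Strand-aware read extension
#'
#' Extends reads to a fixed fragment-size proxy (200 bp in the ChIP
#' pipeline): plus-strand reads grow 3'-ward from their start, minus-strand
#' reads grow 5'-ward from their 3' end.  Results are clipped to
#' `[0, chrom_length)`, so reads near the chromosome edge yield shorter
#' intervals, never negative coordinates.
#'
#' @param read list/one-row data frame with `chrom`, `start`, `length`,
#'   `strand`.
#' @param target_length extension target in bp (>= read length).
#' @param chrom_length chromosome length for clipping (default unbounded).
#' @return One-row interval data frame.
#' @export
extend_read <- function(read, target_length = 200, chrom_length = Inf) {
  if (target_length < read$length)
    stop("target_length must be >= read length")
  if (identical(read$strand, "-")) {
    e <- read$start + read$length
    s <- e - target_length
  } else {
    s <- read$start
    e <- s + target_length
  }
  s <- max(0, s); e <- min(chrom_length, e)
  gintervals(read$chrom, s, e)
}

#' @rdname extend_read
#' @param reads data frame of reads.
#' @export
extend_reads <- function(reads, target_length = 200, chrom_length = Inf) {
  e0 <- reads$start + reads$length
  minus <- reads$strand == "-"
  s <- ifelse(minus, e0 - target_length, reads$start)
  e <- ifelse(minus, e0, reads$start + target_length)
  gintervals(reads$chrom, pmax(0, s), pmin(chrom_length, e))
}

#' Binned coverage of a set of intervals
#'
#' Each interval adds, to every bin it overlaps, the number of its bases in
#' that bin (per-base accumulation).  Used to turn extended reads into 50-bp
#' coverage tracks.
#'
#' @param intervals interval data frame.
#' @param origin,bin_width,n_bins bin grid (see [bin_positions()]).
#' @param chrom chromosome of the track.
#' @param per_base if `FALSE`, each overlapped bin gets +1 instead of the
#'   base count.
#' @return A [binned_track()].
#' @export
coverage_track <- function(intervals, origin, bin_width, n_bins,
                           chrom = "chr1", per_base = TRUE) {
  v <- numeric(n_bins)
  iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(iv))) {
    b0 <- max(1, floor((iv$start[k] - origin) / bin_width) + 1)
    b1 <- min(n_bins, ceiling((iv$end[k] - origin) / bin_width))
    if (b0 > b1) next
    for (b in b0:b1) {
      bs <- origin + (b - 1) * bin_width
      ov <- min(iv$end[k], bs + bin_width) - max(iv$start[k], bs)
      v[b] <- v[b] + if (per_base) ov else 1
    }
  }
  binned_track(chrom, origin, bin_width, v)
}
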