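# Coordinate backbone shared by every stage.
#
# All internal coordinates are 0-based half-open [start, end), the BED
# convention.  Region strings printed in the 1-based inclusive style
# ("chr7:141,530,000-143,520,000") are converted on input by parse_region().

#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open) and an optional `name`.  Most pipeline functions
#' accept any data frame with those columns; this constructor just validates.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; `0 <= start < end` per row.
#' @param name optional character vector of interval names.
#' @return A data frame of intervals sorted by (chrom, start).
#' @export
gintervals <- function(chrom, start, end, name = NULL) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (any(!nzchar(chrom))) stop("chromosome names must be non-empty")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- rep_len(as.character(name), n)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Parse a 1-based inclusive region string
#'
#' Converts `"chr7:141,530,000-143,520,000"` (the style used for the 4C
#' normalisation windows) to a 0-based half-open interval.
#'
#' @param x character vector of `"chrom:start-end"` strings; commas allowed.
#' @return An interval data frame (see [gintervals()]).
#' @export
parse_region <- function(x) {
  x <- gsub(",", "", x, fixed = TRUE)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed region string: ", paste(x[bad], collapse = ", "))
  chrom <- vapply(m, `[`, "", 2L)
  start1 <- as.numeric(vapply(m, `[`, "", 3L))
  end1 <- as.numeric(vapply(m, `[`, "", 4L))
  gintervals(chrom, start1 - 1, end1)
}

#' In-silico restriction digestion
#'
#' Builds the restriction-fragment map that is the atomic unit of 4C
#' quantification.  Either scans a DNA sequence for a blunt-cutter motif
#' (cut placed at the motif start, the DpnII `^GATC` convention) or accepts
#' an explicit list of cut positions.  Fragments tile `[0, chrom_length)`.
#'
#' @param sequence DNA string to scan (optional if `cuts` given).
#' @param cuts explicit 0-based cut positions (optional if `sequence` given).
#' @param motif recognition motif, default `"GATC"` (DpnII).
#' @param chrom_length chromosome length in bp; inferred from `sequence`
#'   when omitted.
#' @param chrom chromosome name stored in the map.
#' @param enzyme enzyme name stored in the map.
#' @return A `restriction_map`: list with `chrom`, `boundaries` (strictly
#'   increasing, first 0, last `chrom_length`) and `enzyme`.
#' @export
digest <- function(sequence = NULL, cuts = NULL, motif = "GATC",
                   chrom_length = NULL, chrom = "chr1", enzyme = "DpnII") {
  if (is.null(sequence) && is.null(cuts))
    stop("provide either a sequence or explicit cut positions")
  if (!is.null(sequence)) {
    if (!nzchar(sequence)) stop("empty sequence")
    if (!nzchar(motif)) stop("empty motif")
    if (nchar(motif) > nchar(sequence)) stop("motif longer than sequence")
    if (is.null(chrom_length)) chrom_length <- nchar(sequence)
    # lookahead regex finds overlapping occurrences too
    hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
    cuts <- if (hits[1] == -1) numeric(0) else as.numeric(hits) - 1
  }
  if (is.null(chrom_length)) stop("chrom_length required with explicit cuts")
  cuts <- as.numeric(cuts)
  if (any(cuts < 0 | cuts > chrom_length))
    stop("cut positions outside [0, chrom_length]")
  boundaries <- sort(unique(c(0, cuts[cuts > 0 & cuts < chrom_length],
                              chrom_length)))
  restriction_map(chrom, boundaries, enzyme)
}

#' @rdname digest
#' @param boundaries strictly increasing positions tiling the chromosome.
#' @export
restriction_map <- function(chrom, boundaries, enzyme = "DpnII") {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2) stop("need >= 2 boundaries")
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  structure(list(chrom = as.character(chrom), boundaries = boundaries,
                 enzyme = as.character(enzyme)),
            class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat(sprintf("restriction_map: %s, %d %s fragments spanning [%d, %d)\n",
              x$chrom, n_fragments(x), x$enzyme,
              as.integer(x$boundaries[1]),
              as.integer(x$boundaries[length(x$boundaries)])))
  invisible(x)
}

#' Number of fragments in a restriction map
#' @param map a `restriction_map`.
#' @export
n_fragments <- function(map) length(map$boundaries) - 1L

#' Fragment intervals of a restriction map
#' @param map a `restriction_map`.
#' @return Interval data frame, one row per fragment.
#' @export
fragments <- function(map) {
  b <- map$boundaries
  gintervals(map$chrom, b[-length(b)], b[-1])
}

#' Fragment midpoints
#' @param map a `restriction_map`.
#' @export
fragment_midpoints <- function(map) {
  b <- map$boundaries
  (b[-length(b)] + b[-1]) / 2
}

#' Locate the fragment containing a position
#'
#' Half-open convention: a position equal to an internal boundary belongs to
#' the fragment starting there.  Indices are 1-based.
#'
#' @param map a `restriction_map`.
#' @param position integer vector of 0-based positions.
#' @return Integer vector of fragment indices, `boundaries[i] <= p < boundaries[i+1]`.
#' @export
locate_fragment <- function(map, position) {
  b <- map$boundaries
  if (any(position < b[1] | position >= b[length(b)]))
    stop("position outside the fragment map")
  findInterval(position, b[-length(b)])
}

#' Fixed-width binned coverage track
#'
#' @param chrom chromosome name.
#' @param origin start position of bin 1.
#' @param bin_width bin width in bp (50 for ChIP, 10000 for Hi-C).
#' @param values numeric vector, one value per bin (NA = masked).
#' @param n_outside count of positions that fell outside the track when
#'   binning (see [bin_positions()]).
#' @return A `binned_track` object.
#' @export
binned_track <- function(chrom, origin, bin_width, values, n_outside = 0L) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  v <- as.numeric(values)
  if (any(!is.finite(v) & !is.na(v))) stop("track values must be finite or NA")
  structure(list(chrom = as.character(chrom), origin = as.numeric(origin),
                 bin_width = as.numeric(bin_width), values = v,
                 n_outside = as.integer(n_outside)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %s, %d bins of %g bp from %g (total signal %.6g)\n",
              x$chrom, length(x$values), x$bin_width, x$origin,
              sum(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Start positions of each bin
#' @param track a `binned_track`.
#' @export
bin_starts <- function(track) {
  track$origin + (seq_along(track$values) - 1) * track$bin_width
}

#' Count positions into fixed-width bins
#'
#' Bin `k` (1-based) counts positions with
#' `origin + (k-1)*w <= p < origin + k*w`.  Out-of-range positions are not
#' silently dropped: their count is stored in the track's `n_outside` field.
#'
#' @param positions integer vector of 0-based positions (e.g. read 5' ends).
#' @param origin start of bin 1.
#' @param bin_width bin width in bp.
#' @param n_bins number of bins.
#' @param chrom chromosome name for the resulting track.
#' @return A `binned_track` of counts.
#' @export
bin_positions <- function(positions, origin, bin_width, n_bins,
                          chrom = "chr1") {
  if (bin_width <= 0) stop("bin_width must be > 0")
  idx <- floor((positions - origin) / bin_width) + 1
  inside <- idx >= 1 & idx <= n_bins
  counts <- tabulate(idx[inside], nbins = n_bins)
  binned_track(chrom, origin, bin_width, counts,
               n_outside = sum(!inside))
}

# logical mask of bins whose [start, end) overlaps any of the intervals
bins_in_intervals <- function(track, intervals) {
  s <- bin_starts(track)
  e <- s + track$bin_width
  hit <- rep(FALSE, length(s))
  if (is.null(intervals) || nrow(intervals) == 0) return(hit)
  iv <- intervals[intervals$chrom == track$chrom, , drop = FALSE]
  for (k in seq_len(nrow(iv)))
    hit <- hit | (s < iv$end[k] & e > iv$start[k])
  hit
}

# merge possibly-overlapping intervals, per chromosome
merge_intervals <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(intervals)
  res_chrom <- character(0); res_start <- numeric(0); res_end <- numeric(0)
  for (ch in sort(unique(intervals$chrom))) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    s <- iv$start[1]; e <- iv$end[1]
    if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
      if (iv$start[k] <= e) {
        e <- max(e, iv$end[k])
      } else {
        res_chrom <- c(res_chrom, ch); res_start <- c(res_start, s)
        res_end <- c(res_end, e)
        s <- iv$start[k]; e <- iv$end[k]
      }
    }
    res_chrom <- c(res_chrom, ch); res_start <- c(res_start, s)
    res_end <- c(res_end, e)
  }
  gintervals(res_chrom, res_start, res_end)
}
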