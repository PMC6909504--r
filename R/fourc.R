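# Allelic 4C-seq quantification.
#
# A 4C profile is one value per restriction fragment for one (viewpoint,
# allele, replicate).  Visualisation tracks are smoothed over 11 fragments
# and normalised to the signal inside a fixed window (the 5 TADs around the
# viewpoint); sub-domain distributions use unsmoothed normalised data with
# signal expressed per Mb.  Allelic differences between regions are tested
# by the fraction of fragments with increased maternal versus paternal
# signal, via a G test of independence on the resulting 2x2 table.

#' Per-fragment 4C signal track
#'
#' @param map a [restriction_map()].
#' @param values one non-negative value per fragment (NA = masked).
#' @param viewpoint optional 1-based index of the viewpoint fragment.
#' @param allele `"maternal"`, `"paternal"` or `"combined"`.
#' @param replicate replicate identifier.
#' @return A `fragment_track` object.
#' @export
fragment_track <- function(map, values, viewpoint = NULL,
                           allele = "combined", replicate = 1L) {
  if (length(values) != n_fragments(map))
    stop("need one value per fragment")
  v <- as.numeric(values)
  if (any(v[!is.na(v)] < 0) || any(!is.finite(v) & !is.na(v)))
    stop("fragment values must be finite and >= 0")
  structure(list(map = map, values = v, viewpoint = viewpoint,
                 allele = allele, replicate = replicate),
            class = "fragment_track")
}

#' @export
print.fragment_track <- function(x, ...) {
  cat(sprintf("fragment_track: %s allele, %d fragments on %s, total %.6g\n",
              x$allele, n_fragments(x$map), x$map$chrom,
              sum(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Mask the viewpoint fragment and its neighbours
#'
#' Self-ligation and undigested fragments dominate the signal right at the
#' viewpoint; the viewpoint fragment plus `flank` fragments on each side are
#' set NA and excluded from normalisation sums and distributions.
#'
#' @param track a [fragment_track()] with a `viewpoint` index.
#' @param flank fragments masked on each side (default 1).
#' @export
mask_viewpoint <- function(track, flank = 1) {
  if (is.null(track$viewpoint)) stop("track has no viewpoint fragment")
  n <- length(track$values)
  idx <- max(1, track$viewpoint - flank):min(n, track$viewpoint + flank)
  track$values[idx] <- NA
  track
}

#' Running-mean smoothing over fragments
#'
#' Centred running mean over `window` fragments (default 11, the
#' visualisation smoothing).  Edges use the truncated available window;
#' masked (NA) fragments are excluded from each window's mean and stay NA
#' in the output.
#'
#' @param track a [fragment_track()].
#' @param window odd window size in fragments (default 11).
#' @return Smoothed `fragment_track`.
#' @export
smooth_track <- function(track, window = 11) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  v <- track$values
  n <- length(v)
  if (window > n) stop("window exceeds track length")
  h <- (window - 1) / 2
  sm <- vapply(seq_len(n), function(i)
    mean(v[max(1, i - h):min(n, i + h)], na.rm = TRUE), 0)
  sm[is.na(v)] <- NA
  sm[is.nan(sm)] <- NA
  track$values <- sm
  track
}

#' Which fragments fall inside a set of intervals
#'
#' Fragment-to-region assignment uses the fragment midpoint, which is
#' unambiguous for fragments straddling region borders.
#'
#' @param map a [restriction_map()].
#' @param intervals interval data frame.
#' @return Logical vector over fragments.
#' @export
fragments_in <- function(map, intervals) {
  mid <- fragment_midpoints(map)
  hit <- rep(FALSE, length(mid))
  iv <- intervals[intervals$chrom == map$chrom, , drop = FALSE]
  for (k in seq_len(nrow(iv)))
    hit <- hit | (mid >= iv$start[k] & mid < iv$end[k])
  hit
}

#' Normalise a track to the signal within a window
#'
#' Scales all values so that the total over fragments inside the window
#' (fragment midpoint rule) equals `target_total`.  With the default
#' `target_total = 1e6` values are "signal per million in window"; ratios
#' and sub-domain shares are invariant to the constant.  Idempotent.
#'
#' @param track a [fragment_track()].
#' @param window interval data frame (the 5-TAD normalisation region).
#' @param target_total normalised in-window total (default 1e6).
#' @return Normalised `fragment_track`.
#' @export
normalize_to_window <- function(track, window, target_total = 1e6) {
  inwin <- fragments_in(track$map, window)
  tot <- sum(track$values[inwin], na.rm = TRUE)
  if (tot <= 0) stop("no signal inside the normalisation window")
  track$values <- track$values * (target_total / tot)
  track
}

#' Per-fragment log2 maternal/paternal ratio track
#'
#' @param maternal,paternal smoothed+normalised [fragment_track()]s on the
#'   same map.
#' @param pseudocount added to both values before the ratio (default 0).
#' @return A `fragment_track` of `log2((mat + pc) / (pat + pc))`.
#' @export
ratio_track <- function(maternal, paternal, pseudocount = 0) {
  if (!identical(maternal$map$boundaries, paternal$map$boundaries))
    stop("fragment maps differ")
  r <- log2((maternal$values + pseudocount) / (paternal$values + pseudocount))
  out <- maternal
  out$values <- r
  out$allele <- "ratio"
  class(out) <- "fragment_track"
  out
}

#' Sub-domain signal distribution
#'
#' Sums unsmoothed, window-normalised signal over each part of a sub-domain
#' partition (fragments assigned by midpoint) and expresses it per Mb; also
#' returns each part's share of the combined partition signal.
#'
#' @param track normalised [fragment_track()].
#' @param partition interval data frame with a `name` column (the
#'   sub-domains).
#' @return Data frame: `name`, `start`, `end`, `signal`, `density_per_mb`,
#'   `share`.
#' @export
subdomain_distribution <- function(track, partition) {
  if (is.null(partition) || nrow(partition) == 0) stop("empty partition")
  sig <- vapply(seq_len(nrow(partition)), function(k)
    sum(track$values[fragments_in(track$map, partition[k, , drop = FALSE])],
        na.rm = TRUE), 0)
  len_mb <- (partition$end - partition$start) / 1e6
  data.frame(name = if (!is.null(partition$name)) partition$name
             else paste0("part", seq_len(nrow(partition))),
             start = partition$start, end = partition$end,
             signal = sig, density_per_mb = sig / len_mb,
             share = sig / sum(sig), stringsAsFactors = FALSE)
}

#' G test of independence on a 2x2 table
#'
#' Likelihood-ratio statistic `G = 2 * sum O * ln(O / E)` with expected
#' counts from the margins; zero cells contribute 0 (the `x ln x -> 0`
#' limit).  The p-value is the chi-square (df 1) upper tail.
#'
#' @param table 2x2 matrix of non-negative counts; all margins must be > 0.
#' @param williams apply Williams' correction (off by default).
#' @return A [test_result()] with the table attached as attribute `table`.
#' @export
g_test_2x2 <- function(table, williams = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero margin: G test undefined")
  E <- outer(rs, cs) / n
  terms <- ifelse(tab > 0, tab * log(tab / E), 0)
  G <- 2 * sum(terms)
  if (williams) {
    q <- 1 + ((n / rs[1] + n / rs[2] - 1) * (n / cs[1] + n / cs[2] - 1)) /
      (6 * n)
    G <- G / q
  }
  res <- test_result("G", G, chisq_sf(max(G, 0), 1), df = 1, n = n)
  attr(res, "table") <- tab
  res
}

#' Allelic sub-domain fragment-fraction test
#'
#' Classifies every fragment (midpoint rule) in two disjoint regions as
#' maternal-higher or paternal-higher, drops ties (counted), builds the 2x2
#' region-by-direction table and applies the G test of independence.  Both
#' tracks must be normalised on the same map so the comparison is
#' scale-consistent.
#'
#' @param maternal,paternal normalised [fragment_track()]s.
#' @param region_a,region_b disjoint interval data frames (e.g. a sub-TAD
#'   versus the remainder of the TAD).
#' @return An `allelic_comparison`: list with `table`, `g_statistic`,
#'   `p_value`, `fractions` (per-region maternal-higher fraction), `n_ties`.
#' @export
allelic_subdomain_test <- function(maternal, paternal, region_a, region_b) {
  if (!identical(maternal$map$boundaries, paternal$map$boundaries))
    stop("fragment maps differ")
  map <- maternal$map
  in_a <- fragments_in(map, region_a)
  in_b <- fragments_in(map, region_b)
  if (any(in_a & in_b)) stop("regions must be disjoint")
  m <- maternal$values; p <- paternal$values
  usable <- !is.na(m) & !is.na(p)
  mat_hi <- usable & m > p
  pat_hi <- usable & p > m
  tie <- usable & m == p
  tab <- matrix(c(sum(mat_hi & in_a), sum(pat_hi & in_a),
                  sum(mat_hi & in_b), sum(pat_hi & in_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("region_a", "region_b"),
                                c("maternal_higher", "paternal_higher")))
  g <- g_test_2x2(tab)
  structure(list(table = tab, g_statistic = g$statistic,
                 p_value = g$p_value,
                 fractions = tab[, 1] / rowSums(tab),
                 n_ties = sum(tie & (in_a | in_b))),
            class = "allelic_comparison")
}

#' @export
print.allelic_comparison <- function(x, ...) {
  cat("allelic_comparison (fragments with maternal > paternal signal):\n")
  print(x$table)
  cat(sprintf("fractions maternal-higher: %.3f vs %.3f; G = %.4g, p = %.3g (%d ties dropped)\n",
              x$fractions[1], x$fractions[2], x$g_statistic, x$p_value,
              x$n_ties))
  invisible(x)
}
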