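# ChIP-seq peak pipeline on 50-bp binned coverage: input-based region
# blacklisting, quantile normalisation across samples, peak calling by the
# run rule (>= 4 consecutive bins >= 20 in at least one sample, extended one
# bin each side), and >= 3-fold differential (allelic) peak calls.

#' Blacklist abnormal regions from an input track
#'
#' Flags bins with no input signal at all, or with signal at or above
#' `median + 3 * IQR` of the input value distribution, and returns them as
#' merged intervals.  Quantiles are linear-interpolation (type 7).  Note the
#' inclusive threshold: a constant positive input (IQR 0) flags every bin.
#'
#' @param input_track input-sample [binned_track()].
#' @param n_iqr multiplier on the IQR (default 3).
#' @return Interval data frame of blacklisted regions (possibly empty).
#' @export
blacklist_from_input <- function(input_track, n_iqr = 3) {
  v <- input_track$values
  if (length(v) == 0) stop("empty input track")
  thr <- stats::median(v) + n_iqr * iqr7(v)
  flag <- v == 0 | v >= thr
  if (all(flag)) warning("all bins blacklisted (degenerate input)")
  if (!any(flag))
    return(gintervals(character(0), numeric(0), numeric(0))[0, ])
  s <- bin_starts(input_track)
  iv <- gintervals(input_track$chrom, s[flag], s[flag] + input_track$bin_width)
  merge_intervals(iv)
}

#' Quantile normalisation across tracks
#'
#' Makes the marginal distribution of every track identical: each output
#' value is the across-sample mean of the sorted input values at that
#' value's rank, with tied ranks averaged.  Accepts a list of
#' [binned_track()]s (masked/blacklisted bins NA, excluded and preserved) or
#' a plain numeric matrix (columns = samples).
#'
#' @param tracks list of `binned_track`s of equal length, or a matrix.
#' @param blacklist optional interval data frame; overlapped bins are set NA
#'   before normalisation.
#' @return Same shape as the input, normalised.
#' @export
quantile_normalize <- function(tracks, blacklist = NULL) {
  if (is.matrix(tracks)) return(qn_matrix(tracks))
  if (length(tracks) < 2) stop("need >= 2 tracks")
  n <- length(tracks[[1]]$values)
  if (any(vapply(tracks, function(t) length(t$values), 0L) != n))
    stop("tracks differ in length")
  X <- vapply(tracks, function(t) {
    v <- t$values
    if (!is.null(blacklist)) v[bins_in_intervals(t, blacklist)] <- NA
    v
  }, numeric(n))
  keep <- stats::complete.cases(X)
  Xn <- X
  Xn[keep, ] <- qn_matrix(X[keep, , drop = FALSE])
  Xn[!keep, ] <- NA
  lapply(seq_along(tracks), function(j) {
    t <- tracks[[j]]; t$values <- Xn[, j]; t
  })
}

# core quantile-normalisation on a complete matrix; a tied group shares the
# mean of the reference values its ranks span
qn_matrix <- function(X) {
  ms <- rowMeans(apply(X, 2, sort))
  apply(X, 2, function(col) {
    out <- numeric(length(col))
    out[order(col)] <- ms
    stats::ave(out, match(col, col), FUN = mean)
  })
}

#' Call peaks by the consecutive-bin rule
#'
#' A peak core is a maximal run of at least `min_run` consecutive bins whose
#' normalised value is at least `min_value` in this track *or in any
#' companion track* (the "in at least 1 cell type" rule).  Cores are
#' extended by `extend_bins` bins on each side and overlapping extended
#' peaks are merged.  The reported `peak_value` is a summary of this track's
#' values over the un-extended core bins (default: maximum).
#'
#' @param track quantile-normalised [binned_track()].
#' @param min_value minimum bin value (default 20).
#' @param min_run minimum run length in bins (default 4).
#' @param extend_bins extension on each side in bins (default 1).
#' @param companion_tracks optional list of tracks on the same bins; a run
#'   qualifying in any of them also seeds a peak.
#' @param stat peak-value summary over core bins: `"max"` (default),
#'   `"mean"` or `"sum"`.
#' @return Data frame of peaks: `chrom`, `start`, `end` (extended, bp),
#'   `core_start`, `core_end` (bins, 1-based), `peak_value`.
#' @export
call_peaks <- function(track, min_value = 20, min_run = 4, extend_bins = 1,
                       companion_tracks = NULL, stat = c("max", "mean", "sum")) {
  stat <- match.arg(stat)
  if (min_run < 1) stop("min_run must be >= 1")
  all_tracks <- c(list(track), companion_tracks)
  n <- length(track$values)
  core <- rep(FALSE, n)
  for (t in all_tracks) {
    qual <- !is.na(t$values) & t$values >= min_value
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ok <- r$values & r$lengths >= min_run
    for (k in which(ok)) core[starts[k]:ends[k]] <- TRUE
  }
  runs <- rle(core)
  rends <- cumsum(runs$lengths)
  rstarts <- rends - runs$lengths + 1
  ki <- which(runs$values)
  if (!length(ki))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), core_start = integer(0),
                      core_end = integer(0), peak_value = numeric(0)))
  cs <- rstarts[ki]; ce <- rends[ki]
  es <- pmax(1L, cs - extend_bins); ee <- pmin(n, ce + extend_bins)
  # merge peaks whose extended spans touch/overlap
  ord <- order(es)
  cs <- cs[ord]; ce <- ce[ord]; es <- es[ord]; ee <- ee[ord]
  m_es <- es[1]; m_ee <- ee[1]; m_cs <- cs[1]; m_ce <- ce[1]
  out <- NULL
  flush <- function(acc, m_es, m_ee, m_cs, m_ce)
    rbind(acc, data.frame(es = m_es, ee = m_ee, cs = m_cs, ce = m_ce))
  if (length(es) > 1) for (k in 2:length(es)) {
    if (es[k] <= m_ee + 1L) {
      m_ee <- max(m_ee, ee[k]); m_ce <- max(m_ce, ce[k])
    } else {
      out <- flush(out, m_es, m_ee, m_cs, m_ce)
      m_es <- es[k]; m_ee <- ee[k]; m_cs <- cs[k]; m_ce <- ce[k]
    }
  }
  out <- flush(out, m_es, m_ee, m_cs, m_ce)
  w <- track$bin_width
  pv <- vapply(seq_len(nrow(out)), function(k)
    peak_stat(track$values[out$cs[k]:out$ce[k]], stat), 0)
  data.frame(chrom = track$chrom,
             start = track$origin + (out$es - 1) * w,
             end = track$origin + out$ee * w,
             core_start = out$cs, core_end = out$ce,
             peak_value = pv, stringsAsFactors = FALSE)
}

peak_stat <- function(v, stat) {
  switch(stat, max = max(v, na.rm = TRUE), mean = mean(v, na.rm = TRUE),
         sum = sum(v, na.rm = TRUE))
}

#' Measure peak values of a sample over fixed peak intervals
#'
#' @param peaks peak data frame from [call_peaks()].
#' @param track a quantile-normalised [binned_track()] on the same bins.
#' @param stat summary over core bins (`"max"`, `"mean"`, `"sum"`).
#' @return Numeric vector of peak values.
#' @export
peak_values <- function(peaks, track, stat = c("max", "mean", "sum")) {
  stat <- match.arg(stat)
  vapply(seq_len(nrow(peaks)), function(k)
    peak_stat(track$values[peaks$core_start[k]:peaks$core_end[k]], stat), 0)
}

#' Call differential (allelic) peaks
#'
#' Computes, over each peak's core bins, the two samples' peak values and
#' their fold difference `max/min`.  A peak is `differential` when the fold
#' is at least `fold_threshold` (inclusive); a zero opposite value gives
#' fold `Inf`, hence differential.
#'
#' @param peaks peaks from [call_peaks()].
#' @param track_a,track_b quantile-normalised tracks on the same bins.
#' @param fold_threshold fold cut-off (default 3).
#' @param stat peak-value summary (default `"max"`).
#' @return `peaks` with added `value_a`, `value_b`, `fold`, `status`.
#' @export
call_differential <- function(peaks, track_a, track_b, fold_threshold = 3,
                              stat = c("max", "mean", "sum")) {
  stat <- match.arg(stat)
  if (nrow(peaks) && max(peaks$core_end) > length(track_a$values))
    stop("peak outside track range")
  va <- peak_values(peaks, track_a, stat)
  vb <- peak_values(peaks, track_b, stat)
  lo <- pmin(va, vb); hi <- pmax(va, vb)
  fold <- ifelse(lo == 0, Inf, hi / lo)
  peaks$value_a <- va
  peaks$value_b <- vb
  peaks$fold <- fold
  peaks$status <- ifelse(fold >= fold_threshold, "differential", "shared")
  peaks
}
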