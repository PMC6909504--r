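# Hi-C contact-matrix stage: ICE balancing and insulation-index TAD-border
# calling on 10-kb binned matrices.

#' Binned contact matrix
#'
#' @param values square symmetric matrix of non-negative numerics.
#' @param bin_width bin width in bp (default 10 kb).
#' @param origin genomic start of bin 1.
#' @param chrom chromosome name.
#' @param balanced has the matrix been ICE-balanced.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(values, bin_width = 10000, origin = 0,
                           chrom = "chr1", balanced = FALSE) {
  m <- as.matrix(values)
  if (nrow(m) != ncol(m) || nrow(m) < 3) stop("need a square matrix, dim >= 3")
  if (max(abs(m - t(m))) > 1e-9) stop("matrix not symmetric")
  if (any(m < 0)) stop("contacts must be non-negative")
  structure(list(chrom = chrom, origin = origin, bin_width = bin_width,
                 values = m, balanced = isTRUE(balanced)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d x %d bins of %g bp%s, total %.6g\n",
              x$chrom, nrow(x$values), ncol(x$values), x$bin_width,
              if (x$balanced) " (balanced)" else "", sum(x$values)))
  invisible(x)
}

#' Iterative correction (ICE) balancing
#'
#' Repeatedly divides the matrix by the outer product of its relative row
#' sums until every unmasked row sum is within `tolerance` (relative) of
#' the mean row sum.  All-zero rows are masked and left untouched.  The
#' multiplicative bias vector is returned as attribute `bias`
#' (strictly positive on unmasked rows), with `iterations` and the final
#' `residual`.
#'
#' @param matrix a [contact_matrix()] or plain symmetric matrix.
#' @param tolerance relative row-sum tolerance (default 1e-5).
#' @param max_iter iteration cap (default 200); non-convergence warns with
#'   the final residual.
#' @return Balanced `contact_matrix`.
#' @export
ice_balance <- function(matrix, tolerance = 1e-5, max_iter = 200) {
  cm <- if (inherits(matrix, "contact_matrix")) matrix
  else contact_matrix(matrix)
  m <- cm$values
  mask <- rowSums(m) == 0
  bias <- rep(1, nrow(m))
  resid <- Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    s <- rowSums(m)[!mask]
    r <- s / mean(s)
    resid <- max(abs(r - 1))
    iters <- it
    if (resid <= tolerance) break
    rf <- rep(1, nrow(m))
    rf[!mask] <- r
    bias <- bias * rf
    m <- m / outer(rf, rf)
  }
  if (resid > tolerance)
    warning(sprintf("ICE did not converge in %d iterations (residual %.3g)",
                    max_iter, resid))
  out <- contact_matrix(m, cm$bin_width, cm$origin, cm$chrom, balanced = TRUE)
  attr(out, "bias") <- bias
  attr(out, "mask") <- mask
  attr(out, "iterations") <- iters
  attr(out, "residual") <- resid
  out
}

#' Insulation index along the diagonal
#'
#' The index at bin `i` is the mean of the matrix entries in the `w x w`
#' square spanning bins `(i-w .. i-1) x (i+1 .. i+w)`, with
#' `w = window_bp / bin_width` (default 500 kb / 10 kb = 50 bins).  Bins
#' without a full square (within `w` of either matrix edge) are masked NA.
#' Squares touching masked (all-zero) rows use the available entries and
#' are themselves masked when fewer than half the entries are available.
#'
#' @param matrix balanced [contact_matrix()].
#' @param window_bp square size in bp; must be a multiple of the bin width.
#' @return An `insulation_profile`: list with `values` (NA-masked),
#'   `window_bp`, `bin_width`, `chrom`, `origin`.
#' @export
insulation_index <- function(matrix, window_bp = 500000) {
  cm <- matrix
  if (window_bp %% cm$bin_width != 0)
    stop("window must be a multiple of the bin width")
  w <- window_bp / cm$bin_width
  n <- nrow(cm$values)
  if (2 * w >= n) stop("window too large for the matrix")
  mask <- attr(cm, "mask")
  if (is.null(mask)) mask <- rowSums(cm$values) == 0
  m <- cm$values
  m[mask, ] <- NA
  m[, mask] <- NA
  vals <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    sq <- m[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    avail <- sum(!is.na(sq))
    vals[i] <- if (avail >= length(sq) / 2) mean(sq, na.rm = TRUE) else NA
  }
  structure(list(values = vals, window_bp = window_bp,
                 bin_width = cm$bin_width, chrom = cm$chrom,
                 origin = cm$origin),
            class = "insulation_profile")
}

#' @export
print.insulation_profile <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("insulation_profile: window %g bp, %d valid bins, range [%.4g, %.4g]\n",
              x$window_bp, length(v), min(v), max(v)))
  invisible(x)
}

#' Call TAD boundaries from an insulation profile
#'
#' Boundaries are local minima of the insulation index (strictly lower than
#' the nearest valid value on both sides; a plateau of equal minimal values
#' yields its centre bin) whose index value is at or below the cut-off.
#' The cut-off may be absolute (the published pipeline used 21.75 on its
#' own normalisation scale) or a percentile of the valid index values.
#'
#' @param profile an [insulation_index()] result.
#' @param cutoff absolute index cut-off.
#' @param cutoff_percentile alternative: percentile (0-1) of valid values.
#' @return Integer vector of boundary bin indices (1-based).
#' @export
call_boundaries <- function(profile, cutoff = NULL, cutoff_percentile = NULL) {
  v <- profile$values
  valid <- which(!is.na(v))
  if (!length(valid)) return(integer(0))
  if (is.null(cutoff)) {
    if (is.null(cutoff_percentile))
      stop("provide cutoff or cutoff_percentile")
    cutoff <- quantile7(v[valid], cutoff_percentile)
  }
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  vv <- v[valid]
  r <- rle(vv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- integer(0)
  for (k in seq_along(r$values)) {
    if (k == 1 || k == length(r$values)) next  # edge runs: minimum unconfirmed
    if (r$values[k] < r$values[k - 1] && r$values[k] < r$values[k + 1] &&
        r$values[k] <= cutoff) {
      centre <- floor((starts[k] + ends[k]) / 2)
      out <- c(out, valid[centre])
    }
  }
  out
}
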