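# 3D DNA-FISH distance statistics: nucleus-mask filtering of segmented spot
# centres, mutual-closest-neighbour pairing between probe channels,
# genomic-distance normalisation and a two-tailed unpaired Mann-Whitney test
# (exact for small samples).

#' Keep only spots inside the nucleus mask
#'
#' The mask is a sphere or axis-aligned ellipsoid (centre + radius/semiaxes),
#' standing in for the DAPI 3D-segmented object.  Removed spots are counted
#' in attribute `n_removed`.
#'
#' @param spots data frame with columns `x`, `y`, `z` (micrometres).
#' @param mask list with `center` (length 3) and `radius` (length 1 for a
#'   sphere, length 3 for an ellipsoid).
#' @return Filtered spot data frame.
#' @export
filter_spots <- function(spots, mask) {
  if (is.null(mask$center) || is.null(mask$radius)) stop("mask undefined")
  r <- rep_len(mask$radius, 3)
  d2 <- ((spots$x - mask$center[1]) / r[1])^2 +
    ((spots$y - mask$center[2]) / r[2])^2 +
    ((spots$z - mask$center[3]) / r[3])^2
  out <- spots[d2 <= 1, , drop = FALSE]
  attr(out, "n_removed") <- sum(d2 > 1)
  out
}

#' Mutual-closest-neighbour pairing between two probe channels
#'
#' Each spot in channel A is matched to its nearest (Euclidean) spot in
#' channel B; only mutual nearest neighbours are kept, so unmatched noise
#' spots never steal a partner when spot counts differ between channels.
#'
#' @param channel_a,channel_b data frames with `x`, `y`, `z` columns
#'   (>= 1 spot each).
#' @return Data frame: `a`, `b` (row indices) and `distance` (micrometres).
#' @export
pair_closest <- function(channel_a, channel_b) {
  if (nrow(channel_a) == 0 || nrow(channel_b) == 0) stop("empty channel")
  A <- as.matrix(channel_a[c("x", "y", "z")])
  B <- as.matrix(channel_b[c("x", "y", "z")])
  d <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d[d < 0] <- 0
  d <- sqrt(d)
  nn_ab <- apply(d, 1, which.min)
  nn_ba <- apply(d, 2, which.min)
  keep <- which(nn_ba[nn_ab] == seq_len(nrow(A)))
  data.frame(a = keep, b = nn_ab[keep],
             distance = d[cbind(keep, nn_ab[keep])])
}

#' Normalise a physical distance by genomic separation
#'
#' Distances between probe pairs with different genomic separations are made
#' comparable by dividing by a function of the separation — by default the
#' separation in Mb (linear model); the globular-polymer cube-root model is
#' a natural alternative.
#'
#' @param distance measured distance(s), micrometres.
#' @param genomic_separation separation(s) in bp (> 0).
#' @param model function of separation-in-Mb giving the divisor; default
#'   `identity` (linear per Mb).
#' @return Normalised distance(s).
#' @export
normalize_distance <- function(distance, genomic_separation,
                               model = identity) {
  if (any(genomic_separation <= 0)) stop("genomic separation must be > 0")
  distance / model(genomic_separation / 1e6)
}

#' Two-tailed unpaired Mann-Whitney test
#'
#' The statistic is `U = #\{(i, j): x_i > y_j\} + ties / 2`.  For pooled
#' sample sizes up to `exact_max` (default 20) the two-sided p-value is
#' exact, by complete enumeration of all group assignments of the pooled
#' values (ties handled through midranks); larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param mode `"auto"` (exact when `length(x) + length(y) <= exact_max`),
#'   `"exact"` or `"normal"`.
#' @param exact_max pooled-size limit for enumeration (default 20).
#' @return A [test_result()] (`statistic` = U, two-sided `p_value`).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal"),
                         exact_max = 20) {
  mode <- match.arg(mode)
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("empty sample")
  pooled <- c(x, y)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2   # #\{x>y\} + ties/2
  use_exact <- mode == "exact" || (mode == "auto" && nx + ny <= exact_max)
  if (use_exact) {
    has_ties <- any(duplicated(pooled))
    if (!has_ties && nx + ny > 22) {
      # tie-free: exact null distribution of U without enumeration
      p <- min(1, 2 * min(stats::pwilcox(u, nx, ny),
                          stats::pwilcox(nx * ny - u, nx, ny)))
    } else {
      if (nx + ny > 22) stop("tied sample too large for exact enumeration")
      comb <- utils::combn(nx + ny, nx)
      usums <- colSums(matrix(rk[comb], nrow = nx)) - nx * (nx + 1) / 2
      eps <- 1e-9
      p <- min(1, 2 * min(mean(usums <= u + eps), mean(usums >= u - eps)))
    }
    test_result("U", u, p, exact = TRUE, n = nx + ny)
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
    z <- (abs(u - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    test_result("U", u, p, df = NA, exact = FALSE, n = n)
  }
}
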