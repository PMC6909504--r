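# Independent brute-force oracles.  Each re-derives the quantity by direct
# enumeration / per-element loops, deliberately avoiding the package's code
# paths.

oracle_scan_motif <- function(sequence, motif) {
  k <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(nchar(sequence) - k + 1))
    if (substr(sequence, i, i + k - 1) == motif) hits <- c(hits, i - 1L)
  hits
}

oracle_bin <- function(positions, origin, bin_width, n_bins) {
  v <- numeric(n_bins)
  for (p in positions) {
    for (k in seq_len(n_bins)) {
      if (p >= origin + (k - 1) * bin_width && p < origin + k * bin_width) {
        v[k] <- v[k] + 1
        break
      }
    }
  }
  v
}

oracle_smooth <- function(v, window) {
  h <- (window - 1) / 2
  n <- length(v)
  sapply(seq_len(n), function(i) {
    w <- v[max(1, i - h):min(n, i + h)]
    mean(w[!is.na(w)])
  })
}

# sort/average/unsort quantile normalisation with tie-group averaging
oracle_qn <- function(X) {
  ms <- rowMeans(apply(X, 2, sort))
  out <- X
  for (j in seq_len(ncol(X))) {
    col <- X[, j]
    r <- rank(col, ties.method = "min")
    cnt <- table(col)
    for (i in seq_along(col)) {
      span <- r[i]:(r[i] + cnt[[as.character(col[i])]] - 1)
      out[i, j] <- mean(ms[span])
    }
  }
  out
}

# exhaustive peak enumeration: all qualifying runs, union across tracks,
# extension, merging
oracle_peaks <- function(tracks_values, min_value = 20, min_run = 4,
                         extend_bins = 1) {
  n <- length(tracks_values[[1]])
  core <- rep(FALSE, n)
  for (v in tracks_values) {
    for (s in seq_len(n - min_run + 1)) {
      win <- v[s:(s + min_run - 1)]
      if (all(!is.na(win)) && all(win >= min_value))
        core[s:(s + min_run - 1)] <- TRUE
    }
  }
  # extended bin set, then maximal runs of it; record the core bins inside
  ext <- rep(FALSE, n)
  for (i in which(core))
    ext[max(1, i - extend_bins):min(n, i + extend_bins)] <- TRUE
  peaks <- NULL
  i <- 1
  while (i <= n) {
    if (ext[i]) {
      j <- i
      while (j < n && ext[j + 1]) j <- j + 1
      cb <- which(core[i:j]) + i - 1
      peaks <- rbind(peaks, data.frame(ext_start = i, ext_end = j,
                                       core_start = min(cb),
                                       core_end = max(cb)))
      i <- j + 1
    } else i <- i + 1
  }
  peaks
}

oracle_insulation <- function(m, w) {
  n <- nrow(m)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    tot <- 0; cnt <- 0
    for (r in (i - w):(i - 1)) for (cc in (i + 1):(i + w)) {
      tot <- tot + m[r, cc]; cnt <- cnt + 1
    }
    vals[i] <- tot / cnt
  }
  vals
}

oracle_mw_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

oracle_subdomain_signal <- function(map, values, part) {
  b <- map$boundaries
  tot <- 0
  for (i in seq_len(length(b) - 1)) {
    mid <- (b[i] + b[i + 1]) / 2
    if (mid >= part$start && mid < part$end && !is.na(values[i]))
      tot <- tot + values[i]
  }
  tot
}

# per-base coverage accumulation
oracle_coverage <- function(intervals, origin, bin_width, n_bins) {
  v <- numeric(n_bins)
  for (k in seq_len(nrow(intervals))) {
    for (p in seq(intervals$start[k], intervals$end[k] - 1)) {
      b <- floor((p - origin) / bin_width) + 1
      if (b >= 1 && b <= n_bins) v[b] <- v[b] + 1
    }
  }
  v
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
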