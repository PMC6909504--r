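# RNA-seq detection and differential-expression compound rule on TPM tables
# from two mono-parental samples (e.g. parthenogenetic PR8 vs androgenetic
# AK2 ESC lines): quantile-normalise the replicate columns together, average
# per sample, then apply the detection (TPM >= 5) and differential
# (fold >= 1.5 and max TPM x fold >= 50) thresholds.

#' Combine replicate TPM columns into per-sample values
#'
#' Quantile-normalises all replicate columns jointly (shared implementation
#' with the ChIP stage), then averages the replicates of each sample.
#' With a single replicate per sample, normalisation is skipped with a
#' warning.
#'
#' @param table data frame with a `transcript` column plus numeric replicate
#'   columns.
#' @param samples named list mapping sample name to its replicate column
#'   names, e.g. `list(PR8 = c("PR8_1","PR8_2"), AK2 = c("AK2_1","AK2_2"))`.
#' @return Data frame `transcript` + one combined column per sample.
#' @export
combine_replicates <- function(table, samples) {
  cols <- unlist(samples)
  if (!all(cols %in% names(table))) stop("missing replicate columns")
  X <- as.matrix(table[cols])
  if (any(X < 0)) stop("negative TPM")
  if (any(lengths(samples) < 2)) {
    warning("single replicate: quantile normalisation skipped")
  } else {
    X <- quantile_normalize(X)
    colnames(X) <- cols
  }
  out <- data.frame(transcript = table$transcript, stringsAsFactors = FALSE)
  for (s in names(samples))
    out[[s]] <- rowMeans(X[, samples[[s]], drop = FALSE])
  out
}

#' Detected-transcript flag
#'
#' A transcript is detected when its combined TPM in either sample is at
#' least `tpm_min` (inclusive).
#'
#' @param combined output of [combine_replicates()] (transcript + 2 sample
#'   columns).
#' @param tpm_min detection threshold (default 5 TPM).
#' @return Logical vector.
#' @export
detect_genes <- function(combined, tpm_min = 5) {
  sm <- sample_matrix(combined)
  apply(sm, 1, max) >= tpm_min
}

#' Compound differential-expression rule
#'
#' Differential iff the higher combined TPM is at least `tpm_min`, the fold
#' difference (larger/smaller, the smaller floored at `zero_floor` to keep
#' the ratio defined) is at least `fold_min`, and the product
#' `max TPM x fold` is at least `product_min`.  All thresholds inclusive.
#'
#' @param combined output of [combine_replicates()].
#' @param tpm_min,fold_min,product_min rule thresholds (defaults 5, 1.5, 50).
#' @param zero_floor floor applied to the smaller TPM before the fold
#'   (default 0.1).
#' @return Data frame: `transcript`, the two sample columns, `detected`,
#'   `fold`, `differential`, `direction`.
#' @export
call_differential_expression <- function(combined, tpm_min = 5,
                                         fold_min = 1.5, product_min = 50,
                                         zero_floor = 0.1) {
  sm <- sample_matrix(combined)
  if (any(sm < 0)) stop("negative TPM")
  hi <- pmax(sm[, 1], sm[, 2])
  lo <- pmax(pmin(sm[, 1], sm[, 2]), zero_floor)
  fold <- hi / lo
  diff <- hi >= tpm_min & fold >= fold_min & hi * fold >= product_min
  data.frame(transcript = combined$transcript,
             combined[colnames(sm)],
             detected = hi >= tpm_min,
             fold = fold,
             differential = diff,
             direction = ifelse(!diff, "none",
                                ifelse(sm[, 1] >= sm[, 2],
                                       colnames(sm)[1], colnames(sm)[2])),
             stringsAsFactors = FALSE)
}

sample_matrix <- function(combined) {
  num <- vapply(combined, is.numeric, TRUE) & names(combined) != "transcript"
  sm <- as.matrix(combined[num])
  if (ncol(sm) != 2) stop("expected exactly two combined sample columns")
  sm
}
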