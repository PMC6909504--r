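# Plain-text readers/writers: BED, bedGraph, TSV tables, dense matrix text.
# Writers are deterministic: rows sorted by (chrom, start), scores printed
# with 6 significant digits, no track lines.

fmt_num <- function(x) {
  out <- format(signif(x, 6), trim = TRUE, scientific = FALSE)
  out[is.na(x)] <- "NA"
  out
}

#' Write intervals as BED
#'
#' @param intervals data frame with `chrom`, `start`, `end` and optionally
#'   `name` / `score` columns (0-based half-open).
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  iv <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  cols <- data.frame(chrom = iv$chrom,
                     start = format(iv$start, trim = TRUE, scientific = FALSE),
                     end = format(iv$end, trim = TRUE, scientific = FALSE),
                     stringsAsFactors = FALSE)
  if (!is.null(iv$name)) cols$name <- iv$name
  if (!is.null(iv$score)) cols$score <- fmt_num(iv$score)
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#' @param path BED file (3+ columns, no header).
#' @return Interval data frame; 4th/5th columns become `name`/`score`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df
}

#' Write a track as bedGraph
#'
#' Accepts a [binned_track()], a `fragment_track` (scores laid over fragment
#' intervals), or a data frame with `chrom`, `start`, `end`, `score`.
#'
#' @param x the track to write.
#' @param path output file.
#' @param drop_na drop masked (NA) entries rather than printing `NA`.
#' @export
write_bedgraph <- function(x, path, drop_na = TRUE) {
  df <- as_bedgraph_df(x)
  if (drop_na) df <- df[!is.na(df$score), , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- data.frame(chrom = df$chrom,
                    start = format(df$start, trim = TRUE, scientific = FALSE),
                    end = format(df$end, trim = TRUE, scientific = FALSE),
                    score = fmt_num(df$score),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_bedgraph_df <- function(x) {
  if (inherits(x, "binned_track")) {
    s <- bin_starts(x)
    data.frame(chrom = x$chrom, start = s, end = s + x$bin_width,
               score = x$values, stringsAsFactors = FALSE)
  } else if (inherits(x, "fragment_track")) {
    fr <- fragments(x$map)
    data.frame(chrom = fr$chrom, start = fr$start, end = fr$end,
               score = x$values, stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end", "score") %in% names(x)))
    x
  } else stop("cannot interpret object as a bedGraph track")
}

#' Read a bedGraph file
#' @param path bedGraph file; `track`/`#` lines are skipped.
#' @return Data frame with `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "score")
  df[1:4]
}

#' Write a contact matrix as dense whitespace-delimited text
#' @param x a `contact_matrix` or plain square matrix.
#' @param path output file.
#' @export
write_matrix_txt <- function(x, path) {
  m <- if (inherits(x, "contact_matrix")) x$values else x
  lines <- apply(m, 1, function(r) paste(fmt_num(r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dense matrix from whitespace-delimited text
#' @param path input file.
#' @return Numeric matrix.
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Write / read tab-separated tables with a header
#' @param df data frame to write.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
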