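#' Read a per-window read-count table
#'
#' Expects a BED-like TSV with columns chromosome, 1-based window start and
#' raw read count (header optional, detected). Windows are returned sorted by
#' chromosome then start. All windows must share one width, except that the
#' terminal window of each chromosome may be shorter (flagged `partial`).
#'
#' @param path path to a TSV of window counts.
#' @param window_size window width in bp used to lay out the windows.
#' @return data.frame of class `coverage_windows` with columns `chrom`,
#'   `start` (1-based), `end`, `width`, `count`, `partial` and a `ratio`
#'   column of `NA` until [normalize_coverage()] fills it.
#' @export
read_coverage <- function(path, window_size) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  raw <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  names(raw)[1:3] <- c("chrom", "start", "count")
  if (any(raw$count < 0)) stop("negative read count in coverage table")
  w <- coverage_windows(raw$chrom, as.integer(raw$start),
                        as.integer(raw$count), window_size)
  w
}

#' Assemble a coverage-window table
#'
#' @param chrom,start,count parallel vectors of window chromosome, 1-based
#'   start and raw read count.
#' @param window_size nominal window width in bp.
#' @param chrom_length optional named vector of chromosome lengths used to
#'   truncate terminal windows; otherwise terminal windows keep nominal width.
#' @return a `coverage_windows` data.frame (see [read_coverage()]).
#' @export
coverage_windows <- function(chrom, start, count, window_size,
                             chrom_length = NULL) {
  if (any(count < 0)) stop("negative read count")
  o <- order(chrom, start)
  w <- data.frame(chrom = chrom[o], start = start[o],
                  count = count[o], stringsAsFactors = FALSE)
  w$end <- w$start + window_size - 1L
  w$partial <- FALSE
  for (ch in unique(w$chrom)) {
    idx <- which(w$chrom == ch)
    st <- w$start[idx]
    if (length(st) > 1) {
      gaps <- diff(st)
      if (any(gaps < window_size)) {
        if (any(gaps <= 0)) stop("overlapping or duplicated windows on ", ch)
        stop("inconsistent window width on ", ch,
             ": starts spaced ", min(gaps), " bp apart, expected ",
             window_size)
      }
    }
    if (!is.null(chrom_length) && ch %in% names(chrom_length)) {
      len <- chrom_length[[ch]]
      last <- idx[length(idx)]
      if (w$end[last] > len) {
        w$end[last] <- as.integer(len)
        w$partial[last] <- TRUE
      }
    }
  }
  w$width <- w$end - w$start + 1L
  w$ratio <- NA_real_
  w <- w[, c("chrom", "start", "end", "width", "count", "partial", "ratio")]
  attr(w, "window_size") <- window_size
  class(w) <- c("coverage_windows", "data.frame")
  w
}

#' Write a coverage-window table as TSV
#'
#' @param w a `coverage_windows` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(w, path) {
  utils::write.table(w[, c("chrom", "start", "count")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("chrom", "start", "count"))
  invisible(path)
}
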