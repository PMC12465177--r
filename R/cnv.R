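#' Sex-aware expected ploidy model
#'
#' Expected normalized depth ratio per chromosome class: autosomes 1.0; X
#' 0.5 in males, 1.0 in females; Y 0.5 in males, 0.0 in females.
#'
#' @param sex `"male"` or `"female"`.
#' @param x_chrom,y_chrom chromosome names treated as X and Y.
#' @return a list of class `ploidy_model`.
#' @export
ploidy_model <- function(sex = c("male", "female"),
                         x_chrom = "X", y_chrom = "Y") {
  sex <- match.arg(sex)
  structure(list(sex = sex, x_chrom = x_chrom, y_chrom = y_chrom),
            class = "ploidy_model")
}

expected_ratio <- function(model, chrom) {
  e <- rep(1, length(chrom))
  if (model$sex == "male") {
    e[chrom %in% model$x_chrom] <- 0.5
    e[chrom %in% model$y_chrom] <- 0.5
  } else {
    e[chrom %in% model$y_chrom] <- 0
  }
  e
}

#' Normalize window counts against a robust autosomal baseline
#'
#' Fills the `ratio` column: window count divided by a robust estimate of the
#' disomic autosomal mean count. Within each autosome the extreme windows
#' (two-sided trimming, `trim` of the total mass) are masked from that
#' chromosome's mean; the genome baseline is the median of the
#' per-autosome means, so that a whole-chromosome aneuploidy — however large
#' the chromosome — cannot drag the baseline. Multiplying all counts by a
#' constant leaves every ratio unchanged.
#'
#' @param w a `coverage_windows` table (see [read_coverage()]).
#' @param model a [ploidy_model()].
#' @param trim total trimmed fraction of each autosome's windows (default
#'   0.01, i.e. 0.5% in each tail).
#' @param min_autosomal_windows required autosomal window count (default 100).
#' @return `w` with `ratio` filled; the baseline mean is attached as
#'   attribute `autosomal_mean`.
#' @export
normalize_coverage <- function(w, model, trim = 0.01,
                               min_autosomal_windows = 100) {
  auto <- !(w$chrom %in% c(model$x_chrom, model$y_chrom))
  if (sum(auto) < min_autosomal_windows) {
    stop("need at least ", min_autosomal_windows, " autosomal windows")
  }
  # put partial terminal windows on the same per-bp footing
  dens <- w$count / w$width * attr(w, "window_size")
  per_chrom <- vapply(split(dens[auto], w$chrom[auto]),
                      mean, 0, trim = trim / 2)
  base <- stats::median(per_chrom)
  if (!is.finite(base) || base <= 0) stop("all-zero autosomal counts")
  w$ratio <- dens / base
  attr(w, "autosomal_mean") <- base
  w
}

new_call <- function(chrom, call, median_ratio, n_windows,
                     seg_start = NA_integer_, seg_end = NA_integer_) {
  data.frame(chrom = chrom, call = call, median_ratio = median_ratio,
             n_windows = as.integer(n_windows),
             seg_start = as.integer(seg_start),
             seg_end = as.integer(seg_end), stringsAsFactors = FALSE)
}

#' Whole-chromosome copy-number call
#'
#' Compares the chromosome's median normalized ratio `m` with its expected
#' ratio `e` under the ploidy model: trisomy when `m/e` is within `delta` of
#' 1.5, monosomy within `delta` of 0.5, disomy within `delta` of 1;
#' otherwise `no_call` (a candidate for the terminal-segment scan).
#'
#' @param w normalized `coverage_windows` of a single chromosome.
#' @param model a [ploidy_model()].
#' @param delta ratio tolerance (default 0.15).
#' @param min_windows minimum supporting windows (default 10); fewer yields
#'   `no_call` with a warning.
#' @return one-row data.frame (chrom, call, median_ratio, n_windows,
#'   seg_start, seg_end).
#' @export
call_chromosome <- function(w, model, delta = 0.15, min_windows = 10) {
  chrom <- unique(w$chrom)
  stopifnot(length(chrom) == 1)
  if (nrow(w) < min_windows) {
    warning("fewer than ", min_windows, " windows on ", chrom, "; no call")
    return(new_call(chrom, "no_call", NA_real_, nrow(w)))
  }
  e <- expected_ratio(model, chrom)[1]
  m <- stats::median(w$ratio)
  if (e == 0) {
    call <- if (m <= delta) "disomy" else "no_call"  # absent Y stays quiet
    return(new_call(chrom, call, m, nrow(w)))
  }
  rel <- m / e
  call <- if (abs(rel - 1) <= delta) "disomy"
          else if (abs(rel - 1.5) <= delta) "trisomy"
          else if (abs(rel - 0.5) <= delta) "monosomy"
          else "no_call"
  new_call(chrom, call, m, nrow(w))
}

#' Terminal-segment copy-number scan
#'
#' Single-changepoint least-squares scan anchored at either chromosome end:
#' for every candidate breakpoint the windows are modelled at the expected
#' ratio before it and at half (loss) or 1.5x (gain) after it; the
#' configuration minimizing the squared error wins. A `partial_monosomy`
#' (or `partial_gain`) is called when the best terminal segment spans at
#' least `min_windows` windows, improves on the no-event fit, and its mean
#' ratio lies within `delta` of the event level. Interior events are out of
#' scope for calling.
#'
#' @param w normalized, position-sorted `coverage_windows` of one chromosome.
#' @param model a [ploidy_model()].
#' @param delta ratio tolerance (default 0.15).
#' @param min_windows minimum windows in the terminal segment (default 10).
#' @return one-row data.frame as in [call_chromosome()], with `seg_start`
#'   and `seg_end` delimiting the event segment when called.
#' @export
detect_terminal_segment <- function(w, model, delta = 0.15, min_windows = 10) {
  chrom <- unique(w$chrom)
  stopifnot(length(chrom) == 1)
  w <- w[order(w$start), , drop = FALSE]
  n <- nrow(w)
  e <- expected_ratio(model, chrom)[1]
  if (e == 0 || n < 2 * min_windows) {
    return(new_call(chrom, "no_call", stats::median(w$ratio), n))
  }
  r <- w$ratio
  sse0 <- sum((r - e)^2)
  best <- list(sse = sse0, side = NA, k = NA, level = NA, call = "no_call")
  for (level in c(0.5 * e, 1.5 * e)) {
    base_sq <- (r - e)^2
    ev_sq <- (r - level)^2
    # right-terminal segment of k windows
    cs_base <- cumsum(base_sq)
    cs_ev_rev <- cumsum(rev(ev_sq))
    ks <- min_windows:(n - min_windows)
    sse_r <- cs_base[n - ks] + cs_ev_rev[ks]
    # left-terminal segment of k windows
    cs_ev <- cumsum(ev_sq)
    cs_base_rev <- cumsum(rev(base_sq))
    sse_l <- cs_ev[ks] + cs_base_rev[n - ks]
    for (side in c("right", "left")) {
      sse <- if (side == "right") sse_r else sse_l
      k <- ks[which.min(sse)]
      if (min(sse) < best$sse) {
        seg <- if (side == "right") r[(n - k + 1):n] else r[1:k]
        if (abs(mean(seg) - level) <= delta) {
          best <- list(sse = min(sse), side = side, k = k, level = level,
                       call = if (level < e) "partial_monosomy"
                              else "partial_gain")
        }
      }
    }
  }
  if (best$call == "no_call") {
    return(new_call(chrom, "no_call", stats::median(r), n))
  }
  idx <- if (best$side == "right") (n - best$k + 1):n else 1:best$k
  new_call(chrom, best$call, stats::median(r[idx]), best$k,
           seg_start = w$start[idx[1]], seg_end = w$end[idx[length(idx)]])
}

#' Genome-wide karyotype scan
#'
#' Normalizes all windows, emits one whole-chromosome call per chromosome,
#' and hands every `no_call` chromosome to the terminal-segment scan. Also
#' returns a Manhattan-style export table (chrom, window start, ratio) for
#' plotting.
#'
#' @param w a `coverage_windows` table covering the genome.
#' @param model a [ploidy_model()].
#' @param delta,min_windows see [call_chromosome()].
#' @param trim see [normalize_coverage()].
#' @return list of class `cnv_scan` with `$calls` (data.frame, one row per
#'   chromosome) and `$manhattan` (chrom, start, ratio).
#' @export
genome_scan <- function(w, model, delta = 0.15, min_windows = 10,
                        trim = 0.01) {
  w <- normalize_coverage(w, model, trim = trim)
  calls <- lapply(split(seq_len(nrow(w)), w$chrom), function(idx) {
    cw <- w[idx, , drop = FALSE]
    call <- call_chromosome(cw, model, delta, min_windows)
    if (call$call == "no_call" && nrow(cw) >= min_windows) {
      term <- detect_terminal_segment(cw, model, delta, min_windows)
      if (term$call != "no_call") call <- term
    }
    call
  })
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  structure(list(calls = calls,
                 manhattan = data.frame(chrom = w$chrom, start = w$start,
                                        ratio = w$ratio)),
            class = "cnv_scan")
}
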