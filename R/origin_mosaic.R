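#' Mosaicism / origin test configuration
#'
#' @param error_rate per-read miscall probability (default 0.005).
#' @param alpha test level (default 0.05).
#' @param min_depth minimum usable read depth per site (default 10).
#' @return a list of class `mosaic_config`.
#' @export
mosaic_config <- function(error_rate = 0.005, alpha = 0.05, min_depth = 10) {
  stopifnot(error_rate > 0, error_rate < 0.5, alpha > 0, alpha < 1)
  structure(list(error_rate = error_rate, alpha = alpha,
                 min_depth = min_depth),
            class = "mosaic_config")
}

#' Label trio sites by which parent carries the alt allele
#'
#' Sites whose alt allele appears in exactly one parent are informative for
#' parental-origin inference; sites where both or neither parent carries the
#' alt are uninformative. Only sites carried by the case are considered.
#'
#' @param vs a [variant_set()] restricted to the region of interest.
#' @param case,sire,dam sample ids of the trio.
#' @return data.frame with columns `idx` (variant row), `class`
#'   (`sire_only_alt` / `dam_only_alt` / `uninformative`), `alt_depth`,
#'   `ref_depth` from the case.
#' @export
classify_informative_sites <- function(vs, case, sire, dam) {
  if (!all(c(case, sire, dam) %in% vs$samples)) {
    return(data.frame(idx = integer(0), class = character(0),
                      alt_depth = integer(0), ref_depth = integer(0)))
  }
  dc <- vs$dosage[, case]
  ds <- vs$dosage[, sire]
  dd <- vs$dosage[, dam]
  keep <- which(!is.na(dc) & dc >= 1)
  cls <- vapply(keep, function(i) {
    s <- isTRUE(ds[i] >= 1)
    d <- isTRUE(dd[i] >= 1)
    if (s && !d) "sire_only_alt" else if (d && !s) "dam_only_alt"
    else "uninformative"
  }, "")
  data.frame(idx = keep, class = cls,
             alt_depth = vs$alt_depth[keep, case],
             ref_depth = vs$ref_depth[keep, case])
}

#' Pooled alt-allele read fraction with exact binomial CI
#'
#' Pools alt and ref read counts over all usable sites (depth at or above
#' `min_depth`) and returns the alt fraction with its Clopper-Pearson
#' interval.
#'
#' @param sites data.frame with `alt_depth` and `ref_depth` columns (e.g.
#'   from [classify_informative_sites()]).
#' @param config a [mosaic_config()].
#' @return list with `fraction`, `ci` (length-2 vector), `alt_reads`,
#'   `total_reads`, `n_sites`.
#' @export
estimate_alt_fraction <- function(sites, config = mosaic_config()) {
  tot <- sites$alt_depth + sites$ref_depth
  use <- !is.na(tot) & tot >= config$min_depth
  if (!any(use)) stop("no site with usable depth >= ", config$min_depth)
  a <- sum(sites$alt_depth[use])
  n <- sum(tot[use])
  if (n == 0) stop("zero usable read depth")
  bt <- stats::binom.test(a, n)
  list(fraction = a / n, ci = as.numeric(bt$conf.int),
       alt_reads = a, total_reads = n, n_sites = sum(use))
}

#' Parental origin of an extra chromosome copy from allelic read fractions
#'
#' On a trisomic chromosome the case carries two copies from one parent.
#' Under a paternal extra copy, sites whose alt allele is carried only by the
#' sire (both transmitted paternal copies carrying it) are read at an alt
#' fraction of 2/3 and dam-only sites at 1/3; a maternal extra copy mirrors
#' these expectations. The call is made by a binomial log-likelihood ratio
#' pooled over informative sites.
#'
#' @param sites output of [classify_informative_sites()] on the trisomic
#'   chromosome (uninformative sites are ignored).
#' @param config a [mosaic_config()].
#' @param llr_threshold absolute log-likelihood ratio (nats) required to
#'   call an origin (default 10).
#' @return list with `origin` (`"paternal"`, `"maternal"` or
#'   `"undetermined"`), `llr` (paternal minus maternal log-likelihood),
#'   `n_sites`, `fraction` (pooled alt fraction over informative sites).
#' @export
infer_extra_copy_origin <- function(sites, config = mosaic_config(),
                                    llr_threshold = 10) {
  inf <- sites[sites$class %in% c("sire_only_alt", "dam_only_alt"), ,
               drop = FALSE]
  tot <- inf$alt_depth + inf$ref_depth
  use <- !is.na(tot) & tot >= config$min_depth
  inf <- inf[use, , drop = FALSE]
  tot <- tot[use]
  if (!nrow(inf)) {
    return(list(origin = "undetermined", llr = 0, n_sites = 0L,
                fraction = NA_real_))
  }
  p_pat <- ifelse(inf$class == "sire_only_alt", 2 / 3, 1 / 3)
  p_mat <- 1 - p_pat
  ll_pat <- sum(stats::dbinom(inf$alt_depth, tot, p_pat, log = TRUE))
  ll_mat <- sum(stats::dbinom(inf$alt_depth, tot, p_mat, log = TRUE))
  llr <- ll_pat - ll_mat
  origin <- if (llr > llr_threshold) "paternal"
            else if (llr < -llr_threshold) "maternal"
            else "undetermined"
  list(origin = origin, llr = llr, n_sites = nrow(inf),
       fraction = sum(inf$alt_depth) / sum(tot))
}

#' Exact binomial test for low-level mosaicism in one tissue
#'
#' Tests whether the alt read fraction exceeds the sequencing error rate
#' (one-sided exact binomial test). A significant excess at a fraction below
#' 0.35 is `low_level_mosaic`; a fraction between 0.35 and 0.65 is
#' `constitutive_het`; anything else is `absent`. Depth below `min_depth`
#' returns `undetermined`.
#'
#' @param alt_depth,total_depth alt-supporting and total read counts.
#' @param config a [mosaic_config()].
#' @return one of `"absent"`, `"low_level_mosaic"`, `"constitutive_het"`,
#'   `"undetermined"`.
#' @export
test_mosaicism <- function(alt_depth, total_depth, config = mosaic_config()) {
  if (is.na(total_depth) || total_depth < config$min_depth) {
    return("undetermined")
  }
  frac <- alt_depth / total_depth
  if (frac >= 0.35 && frac <= 0.65) return("constitutive_het")
  p <- stats::binom.test(alt_depth, total_depth, p = config$error_rate,
                         alternative = "greater")$p.value
  if (p < config$alpha && frac < 0.35) "low_level_mosaic" else "absent"
}

#' Combine per-tissue mosaicism results for a parent
#'
#' Germline (gonadal) mosaicism is the configuration seen in a transmitting
#' sire: the variant detectable at low level in semen but absent from blood.
#'
#' @param tissue_status named character vector mapping tissue (e.g. `semen`,
#'   `blood`) to a [test_mosaicism()] status.
#' @return one of `"germline_mosaic"`, `"somatic_and_germline"`,
#'   `"not_mosaic"`, `"indeterminate"`.
#' @export
classify_parental_mosaicism <- function(tissue_status) {
  get <- function(nm) {
    if (nm %in% names(tissue_status)) tissue_status[[nm]] else NA_character_
  }
  semen <- get("semen")
  blood <- get("blood")
  if (is.na(semen) || is.na(blood) ||
      "undetermined" %in% c(semen, blood)) {
    return("indeterminate")
  }
  if (semen == "low_level_mosaic" && blood == "absent") "germline_mosaic"
  else if (semen == "low_level_mosaic" && blood == "low_level_mosaic") {
    "somatic_and_germline"
  }
  else if (semen == "absent" && blood == "absent") "not_mosaic"
  else if (semen == "constitutive_het" && blood == "constitutive_het") {
    "not_mosaic"  # constitutive carrier, not a mosaic
  }
  else "indeterminate"
}
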