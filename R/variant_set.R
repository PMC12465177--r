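#' Construct a variant set
#'
#' The central container of the package: a table of biallelic variant sites
#' together with per-sample genotype dosages and per-allele read depths.
#' Multiallelic sites are always decomposed so that one row describes exactly
#' one REF/ALT pair; a sample's dosage at a row counts copies of that row's
#' ALT allele (0, 1, 2, or `NA` for missing). Hemizygous calls (male X,
#' monosomic segments) carry dosage 0 or 1 with the `hemizygous` flag set.
#'
#' @param variants data.frame with columns `chrom` (character), `pos`
#'   (1-based integer), `ref`, `alt` (allele strings over A/C/G/T), and
#'   optionally `gene` (symbol or `NA`) and `cds_pos`.
#' @param dosage integer matrix, variants x samples; entries in 0:2 or `NA`.
#' @param ref_depth,alt_depth integer matrices of per-allele read counts,
#'   same shape as `dosage`; `NA` where depths are unknown.
#' @param hemizygous logical matrix marking single-copy calls; hemizygous
#'   dosages must be 0, 1 or `NA`.
#' @param annotations optional list (length = number of variants) of named
#'   character vectors carrying free-form annotations such as predictor
#'   verdicts or consequence labels.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, dosage,
                        ref_depth = NULL, alt_depth = NULL,
                        hemizygous = NULL, annotations = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  dosage <- as.matrix(dosage)
  n <- nrow(variants)
  if (nrow(dosage) != n) stop("dosage must have one row per variant")
  samples <- colnames(dosage)
  if (is.null(samples)) stop("dosage must carry sample names as colnames")
  if (!("gene" %in% names(variants))) variants$gene <- NA_character_
  if (!("cds_pos" %in% names(variants))) variants$cds_pos <- NA_integer_
  rownames(variants) <- NULL
  empty <- function() matrix(NA_integer_, n, length(samples),
                             dimnames = list(NULL, samples))
  if (is.null(ref_depth)) ref_depth <- empty()
  if (is.null(alt_depth)) alt_depth <- empty()
  if (is.null(hemizygous)) {
    hemizygous <- matrix(FALSE, n, length(samples),
                         dimnames = list(NULL, samples))
  }
  strip <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(NULL, samples)
    m
  }
  x <- structure(list(variants = variants,
                      samples = samples,
                      dosage = strip(dosage),
                      ref_depth = strip(ref_depth),
                      alt_depth = strip(alt_depth),
                      hemizygous = strip(hemizygous),
                      annotations = annotations),
                 class = "variant_set")
  validate_variant_set(x)
  x
}

#' Validate a variant set
#'
#' Checks the container invariants: positive 1-based positions, non-empty
#' chromosome names, REF different from ALT, alleles drawn from A/C/G/T,
#' dosages in 0:2 (0:1 where hemizygous), non-negative depths, and matching
#' matrix shapes.
#'
#' @param x a `variant_set`.
#' @return `x`, invisibly; stops with an informative error otherwise.
#' @export
validate_variant_set <- function(x) {
  v <- x$variants
  if (any(!nzchar(v$chrom))) stop("chromosome names must be non-empty")
  if (any(v$pos < 1)) stop("positions must be 1-based (>= 1)")
  if (any(v$ref == v$alt)) stop("ref and alt alleles must differ")
  ok_allele <- grepl("^[ACGT]+$", v$ref) & grepl("^[ACGT]+$", v$alt)
  if (any(!ok_allele)) {
    stop("symbolic or non-ACGT alleles rejected at row(s) ",
         paste(which(!ok_allele), collapse = ", "))
  }
  dims <- vapply(unclass(x)[c("dosage", "ref_depth", "alt_depth",
                              "hemizygous")],
                 function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1L) stop("genotype matrices differ in shape")
  d <- x$dosage
  if (any(d < 0 | d > 2, na.rm = TRUE)) stop("dosages must lie in 0:2")
  if (any(x$hemizygous & !is.na(d) & d > 1)) {
    stop("hemizygous calls cannot have dosage 2")
  }
  if (any(x$ref_depth < 0, na.rm = TRUE) || any(x$alt_depth < 0, na.rm = TRUE)) {
    stop("read depths must be non-negative")
  }
  invisible(x)
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Number of variants in a variant set
#' @param x a `variant_set`.
#' @return integer count of variant rows.
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a variant set
#'
#' @param x a `variant_set`.
#' @param i variant (row) index; missing keeps all.
#' @param j sample names or indices; missing keeps all.
#' @param ... unused.
#' @return a `variant_set` restricted to the requested rows/samples.
#' @export
`[.variant_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$variants))
  if (missing(j)) j <- x$samples
  variant_set(x$variants[i, , drop = FALSE],
              x$dosage[i, j, drop = FALSE],
              x$ref_depth[i, j, drop = FALSE],
              x$alt_depth[i, j, drop = FALSE],
              x$hemizygous[i, j, drop = FALSE],
              if (!is.null(x$annotations)) x$annotations[i])
}

#' Deterministic variant ordering
#'
#' Sorts variants by (chrom, pos, alt) so that all downstream filter output
#' is reproducible irrespective of input order.
#'
#' @param x a `variant_set`.
#' @return the reordered `variant_set`.
#' @export
sort_variants <- function(x) {
  o <- order(x$variants$chrom, x$variants$pos, x$variants$alt)
  x[o, ]
}
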