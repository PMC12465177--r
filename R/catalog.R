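#' Load the ruminant skeletal-disorder catalog
#'
#' Loads the machine-readable nosology shipped with the package: a table of
#' previously reported skeletal disorders of cattle and sheep with a known
#' molecular cause (`nosology`), a table of the 39 newly characterised cases
#' (`cases`), and the SNV/indel alleles underlying those cases (`alleles`,
#' one row per distinct allele; an allele shared by two cases appears once
#' and lists both case ids). Alternative files with the same layout may be
#' supplied for the three tables.
#'
#' @param nosology,cases,alleles optional paths overriding the bundled TSVs.
#' @return a list of class `skeletal_catalog` with elements `nosology`,
#'   `cases` and `alleles` (data.frames).
#' @export
load_catalog <- function(nosology = NULL, cases = NULL, alleles = NULL) {
  path <- function(given, default) {
    if (!is.null(given)) given
    else system.file("extdata", default, package = "mendelscope",
                     mustWork = TRUE)
  }
  rd <- function(p) utils::read.table(p, header = TRUE, sep = "\t",
                                      quote = "", stringsAsFactors = FALSE,
                                      na.strings = c("NA", ""),
                                      fill = TRUE, comment.char = "")
  cat <- structure(list(nosology = rd(path(nosology, "nosology.tsv")),
                        cases = rd(path(cases, "cases.tsv")),
                        alleles = rd(path(alleles, "alleles.tsv"))),
                   class = "skeletal_catalog")
  validate_catalog(cat)
  cat
}

split_ids <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ","), function(v) {
    as.integer(trimws(v[nzchar(trimws(v))]))
  })
}

#' Validate the catalog invariants
#'
#' Rejects duplicate case ids across the cases table, cases-table rows with
#' no case id, and MOI codes outside the declared vocabulary
#' (AR, AD, AcD, AID, XLD, unknown/empty).
#'
#' @param cat a `skeletal_catalog`.
#' @return `cat`, invisibly.
#' @export
validate_catalog <- function(cat) {
  ids <- split_ids(cat$cases$case_ids)
  if (any(lengths(ids) == 0)) stop("cases-table row without a case id")
  flat <- unlist(ids)
  if (anyDuplicated(flat)) {
    stop("duplicate case id(s): ",
         paste(unique(flat[duplicated(flat)]), collapse = ", "))
  }
  moi_vocab <- c("AR", "AD", "AcD", "AID", "XLD", "unknown")
  bad <- function(m) !is.na(m) & !(m %in% moi_vocab)
  if (any(bad(cat$cases$moi)) || any(bad(cat$nosology$moi))) {
    stop("MOI code outside vocabulary ", paste(moi_vocab, collapse = "/"))
  }
  ok_class <- c("pathogenic", "likely_pathogenic", "uncertain", "none")
  cls <- cat$cases$classification
  if (any(!is.na(cls) & !(cls %in% ok_class))) stop("unknown classification")
  invisible(cat)
}

#' Count distinct values of a field (or field tuple) in a catalog table
#'
#' `"case_id"` expands the comma-separated `case_ids` lists before counting;
#' the pair `c("disorder", "species")` is the disorder-identity key used for
#' the case series. For the nosology table, `horn_traits = FALSE` drops the
#' horn-trait rows before counting.
#'
#' @param cat a `skeletal_catalog`.
#' @param table `"nosology"` or `"cases"`.
#' @param fields character vector of column names, or `"case_id"`.
#' @param horn_traits include horn-trait rows of the nosology table.
#' @return integer distinct count.
#' @export
count_distinct <- function(cat, table = c("nosology", "cases"), fields,
                           horn_traits = TRUE) {
  table <- match.arg(table)
  df <- cat[[table]]
  if (table == "nosology" && !horn_traits) {
    df <- df[!df$horn_trait, , drop = FALSE]
  }
  if (nrow(df) == 0) return(0L)
  if (identical(fields, "case_id")) {
    if (table != "cases") stop("case ids exist only in the cases table")
    return(length(unique(unlist(split_ids(df$case_ids)))))
  }
  bad <- setdiff(fields, names(df))
  if (length(bad)) {
    stop("unknown field(s) ", paste(bad, collapse = ", "),
         "; valid fields: ", paste(names(df), collapse = ", "))
  }
  nrow(unique(df[, fields, drop = FALSE]))
}

#' Tally variant classifications
#'
#' At `level = "allele"` the tally counts distinct SNV/indel alleles (an
#' allele shared by several cases counts once; aneuploidies are not alleles
#' and are excluded). At `level = "finding"` it counts cases-table rows
#' (one finding per catalogued case group, aneuploidies included). The two
#' conventions match how the case series is summarised: pathogenic calls are
#' reported per allele, likely-pathogenic calls per finding.
#'
#' @param cat a `skeletal_catalog`.
#' @param level `"allele"` or `"finding"`.
#' @return named integer vector over classification labels.
#' @export
tally_classifications <- function(cat, level = c("allele", "finding")) {
  level <- match.arg(level)
  labs <- c("pathogenic", "likely_pathogenic", "uncertain", "none")
  x <- if (level == "allele") cat$alleles$classification
       else cat$cases$classification
  x[is.na(x)] <- "none"
  tab <- table(factor(x, levels = labs))
  stats::setNames(as.integer(tab), labs)
}

#' Molecular diagnostic rate of the case series
#'
#' The fraction of cases whose catalog entry carries a pathogenic or
#' likely-pathogenic classification, over all catalogued cases.
#'
#' @param cat a `skeletal_catalog`.
#' @param include_aneuploidies count aneuploidy diagnoses (default `TRUE`).
#' @return list with `numerator`, `denominator` and `rate`.
#' @export
diagnostic_rate <- function(cat, include_aneuploidies = TRUE) {
  df <- cat$cases
  if (nrow(df) == 0) stop("empty catalog")
  ids <- split_ids(df$case_ids)
  total <- length(unique(unlist(ids)))
  solved <- !is.na(df$classification) &
    df$classification %in% c("pathogenic", "likely_pathogenic")
  if (!include_aneuploidies) {
    solved <- solved & !(df$variant_type %in% "aneuploidy")
  }
  num <- length(unique(unlist(ids[solved])))
  list(numerator = num, denominator = total, rate = num / total)
}

#' Diagnostic rate stratified by sequencing design
#'
#' @param cat a `skeletal_catalog`.
#' @return data.frame with one row per design and columns `design`,
#'   `numerator`, `denominator`, `rate`.
#' @export
diagnostic_rate_by_design <- function(cat) {
  df <- cat$cases
  out <- lapply(split(df, df$design), function(g) {
    sub <- cat
    sub$cases <- g
    r <- diagnostic_rate(sub)
    data.frame(design = g$design[1], numerator = r$numerator,
               denominator = r$denominator, rate = r$rate)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
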