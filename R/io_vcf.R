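#' Read a VCF file into a variant set
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}), consuming only the GT and AD
#' FORMAT fields. Multiallelic sites are decomposed into one record per ALT
#' allele with per-sample dosages recomputed against that allele; per-sample
#' total allele counts at a site are conserved by the decomposition.
#' Coordinates are kept 1-based inclusive throughout.
#'
#' When a pedigree is supplied, X-chromosome calls in male samples are
#' re-coded hemizygous at load time (dosage 0/1 against a single copy);
#' pseudoautosomal regions are not modelled.
#'
#' @param path path to a VCF (plain text or bgzip).
#' @param roster optional character vector of sample ids that must be present;
#'   an absent sample raises an error naming it.
#' @param pedigree optional pedigree data.frame (see [read_ped()]) used to
#'   re-code male X calls as hemizygous.
#' @param x_chrom chromosome name(s) treated as X. Default `"X"`.
#' @return a [variant_set()].
#' @export
read_vcf <- function(path, roster = NULL, pedigree = NULL, x_chrom = "X") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  samples <- colnames(v@gt)[-1]
  if (!is.null(roster)) {
    missing <- setdiff(roster, samples)
    if (length(missing)) {
      stop("sample(s) absent from VCF header: ", paste(missing, collapse = ", "))
    }
    samples <- roster
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  has_ad <- any(grepl("(^|:)AD(:|$)", v@gt[, "FORMAT"]))
  if (!has_ad) {
    warning("AD field missing; allele depths set to missing")
    ad <- matrix(NA_character_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  } else {
    ad <- vcfR::extract.gt(v, element = "AD")
  }
  gene <- sub(".*GENE=([^;]+).*", "\\1",
              ifelse(is.na(fix[, "INFO"]), "", fix[, "INFO"]))
  gene[!grepl("GENE=", ifelse(is.na(fix[, "INFO"]), "", fix[, "INFO"]))] <- NA

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- gt[i, samples]
    alleles <- strsplit(ifelse(is.na(gts), "./.", gts), "[/|]")
    ads <- strsplit(ifelse(is.na(ad[i, samples]), "", ad[i, samples]), ",")
    for (k in seq_along(alts)) {
      dos <- vapply(alleles, function(a) {
        a <- suppressWarnings(as.integer(a))
        if (anyNA(a)) return(NA_integer_)
        sum(a == k)
      }, integer(1))
      hemi <- vapply(alleles, function(a) {
        length(a) == 1L && !is.na(suppressWarnings(as.integer(a[1])))
      }, logical(1))
      rd <- vapply(ads, function(d) {
        d <- suppressWarnings(as.integer(d))
        if (length(d) < k + 1 || is.na(d[1])) NA_integer_ else d[1]
      }, integer(1))
      adp <- vapply(ads, function(d) {
        d <- suppressWarnings(as.integer(d))
        if (length(d) < k + 1 || is.na(d[k + 1])) NA_integer_ else d[k + 1]
      }, integer(1))
      rows[[length(rows) + 1L]] <- list(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k], gene = gene[i],
        dosage = dos, hemi = hemi, rd = rd, ad = adp)
    }
  }
  variants <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 0L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    gene = vapply(rows, `[[`, "", "gene"),
    stringsAsFactors = FALSE)
  pick <- function(fld, proto) {
    m <- t(vapply(rows, `[[`, proto, fld))
    colnames(m) <- samples
    m
  }
  proto_i <- rep(NA_integer_, length(samples))
  vs <- variant_set(variants,
                    dosage = pick("dosage", proto_i),
                    ref_depth = pick("rd", proto_i),
                    alt_depth = pick("ad", proto_i),
                    hemizygous = pick("hemi", rep(NA, length(samples))) > 0)
  if (!is.null(pedigree)) vs <- recode_hemizygous(vs, pedigree, x_chrom)
  vs
}

#' Re-code male X genotypes as hemizygous
#'
#' Diploid-style calls (0/0, 0/1, 1/1) on the X chromosome of male samples
#' are collapsed to single-copy dosage: 0/0 -> 0, 1/1 -> 1, and heterozygous
#' calls -> missing (a male cannot be X-heterozygous outside unmodelled
#' pseudoautosomal regions).
#'
#' @param vs a [variant_set()].
#' @param pedigree pedigree data.frame with `id` and `sex` columns.
#' @param x_chrom chromosome name(s) treated as X.
#' @return the re-coded `variant_set`.
#' @export
recode_hemizygous <- function(vs, pedigree, x_chrom = "X") {
  males <- intersect(pedigree$id[pedigree$sex == "male"], vs$samples)
  on_x <- vs$variants$chrom %in% x_chrom
  if (!length(males) || !any(on_x)) return(vs)
  for (s in males) {
    d <- vs$dosage[on_x, s]
    d[!is.na(d) & d == 1] <- NA_integer_   # impossible diploid het in a male
    d[!is.na(d) & d == 2] <- 1L
    vs$dosage[on_x, s] <- d
    vs$hemizygous[on_x, s] <- TRUE
  }
  vs
}

#' Write a variant set as VCF v4.2
#'
#' Emits a minimal plain-text VCF carrying GT and AD for every sample.
#' Hemizygous calls are written as single-allele genotypes. Reading the file
#' back with [read_vcf()] reproduces all fields.
#'
#' @param vs a [variant_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$samples), collapse = "\t"))
  fmt_gt <- function(dos, hemi) {
    if (is.na(dos)) return(if (isTRUE(hemi)) "." else "./.")
    if (isTRUE(hemi)) as.character(dos)
    else c("0/0", "0/1", "1/1")[dos + 1]
  }
  body <- vapply(seq_len(nrow(vs$variants)), function(i) {
    v <- vs$variants[i, ]
    info <- if (is.na(v$gene)) "." else paste0("GENE=", v$gene)
    cells <- vapply(vs$samples, function(s) {
      gt <- fmt_gt(vs$dosage[i, s], vs$hemizygous[i, s])
      ad <- if (is.na(vs$ref_depth[i, s]) || is.na(vs$alt_depth[i, s])) "."
            else paste(vs$ref_depth[i, s], vs$alt_depth[i, s], sep = ",")
      paste(gt, ad, sep = ":")
    }, "")
    paste(c(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".", info, "GT:AD",
            cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
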