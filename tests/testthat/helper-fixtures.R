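# in-code fixtures shared across test files

write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  writeLines(c(hdr, lines), path)
  path
}

write_toy_ped <- function(rows, path = tempfile(fileext = ".ped")) {
  writeLines(rows, path)
  path
}

# a minimal variant_set built directly from a dosage matrix; one chromosome,
# consecutive positions, gene labels optional
make_vs <- function(dosage, gene = NULL, chrom = "1",
                    ref_depth = NULL, alt_depth = NULL, hemizygous = NULL) {
  n <- nrow(dosage)
  variants <- data.frame(chrom = chrom, pos = seq_len(n) * 100L,
                         ref = "G", alt = "A",
                         gene = if (is.null(gene)) NA_character_ else gene,
                         stringsAsFactors = FALSE)
  variant_set(variants, dosage, ref_depth = ref_depth,
              alt_depth = alt_depth, hemizygous = hemizygous)
}

trio_ped <- function(case_sex = "female") {
  as_pedigree(data.frame(
    id = c("sire1", "dam1", "case1"),
    sire = c(NA, NA, "sire1"), dam = c(NA, NA, "dam1"),
    sex = c("male", "female", case_sex),
    affected = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE))
}
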