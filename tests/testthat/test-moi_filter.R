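test_that("recessive filter keeps case-homozygous variants absent in that state from controls", {
  # rows: retained / control-hom violation / carrier controls allowed /
  #        parent not het / case not hom
  dosage <- cbind(case1 = c(2L, 2L, 2L, 2L, 1L),
                  sire1 = c(1L, 1L, 1L, 2L, 1L),
                  dam1 = c(1L, 1L, 1L, 1L, 0L),
                  ctl1 = c(0L, 2L, 1L, 0L, 0L),
                  ctl2 = c(1L, 0L, 1L, 0L, 0L))
  vs <- make_vs(dosage)
  sc <- filter_scenario("recessive_hom", "case1", c("ctl1", "ctl2"),
                        list(case1 = c(sire = "sire1", dam = "dam1")),
                        design = "trio")
  res <- filter_recessive_hom(vs, sc)
  expect_equal(res$retained$variants$pos, c(100L, 300L))
  expect_match(res$audit$reason[res$audit$pos == 200], "homozygous-alt control")
  expect_match(res$audit$reason[res$audit$pos == 400], "parent")
})

test_that("recessive filter requires homozygosity in every case of a multi-case design", {
  dosage <- cbind(case1 = c(2L, 2L), case2 = c(2L, 1L),
                  ctl1 = c(0L, 0L))
  vs <- make_vs(dosage)
  sc <- filter_scenario("recessive_hom", c("case1", "case2"), "ctl1",
                        design = "multiple_cases")
  res <- filter_recessive_hom(vs, sc)
  expect_equal(res$retained$variants$pos, 100L)
})

test_that("dominant filter keeps private heterozygous variants with 0/0 parents", {
  dosage <- cbind(case1 = c(1L, 1L, 1L, 2L),
                  sire1 = c(0L, 0L, 1L, 0L),
                  dam1 = c(0L, 0L, 0L, 0L),
                  ctl1 = c(0L, 1L, 0L, 0L))
  vs <- make_vs(dosage)
  sc <- filter_scenario("dominant_private", "case1", "ctl1",
                        list(case1 = c(sire = "sire1", dam = "dam1")),
                        design = "trio")
  res <- filter_dominant_private(vs, sc)
  expect_equal(res$retained$variants$pos, 100L)
  expect_match(res$audit$reason[res$audit$pos == 200], "control carrier")
  expect_match(res$audit$reason[res$audit$pos == 300], "parent")
  expect_match(res$audit$reason[res$audit$pos == 400], "not heterozygous")
})

test_that("x-linked filtering accepts hemizygous-alt male cases", {
  dosage <- cbind(case1 = c(1L, 1L), ctl1 = c(0L, 1L))
  hemi <- cbind(case1 = c(TRUE, TRUE), ctl1 = c(FALSE, FALSE))
  vs <- make_vs(dosage, chrom = "X", hemizygous = hemi)
  sc <- filter_scenario("x_linked", "case1", "ctl1", design = "single_case")
  res <- filter_dominant_private(vs, sc)
  expect_equal(res$retained$variants$pos, 100L)
})

test_that("compound-het filter retains trans pairs jointly private to the case", {
  # gene G: v1 from sire, v2 from dam; controls carry each singly
  dosage <- cbind(case1 = c(1L, 1L, 1L, 1L),
                  sire1 = c(1L, 0L, 1L, 1L),
                  dam1 = c(0L, 1L, 0L, 0L),
                  ctl1 = c(1L, 0L, 0L, 0L),
                  ctl2 = c(0L, 1L, 0L, 0L))
  # rows 3+4: both alleles on the paternal haplotype (cis) -> rejected
  vs <- make_vs(dosage, gene = c("G", "G", "H", "H"))
  sc <- filter_scenario("recessive_compound_het", "case1",
                        c("ctl1", "ctl2"),
                        list(case1 = c(sire = "sire1", dam = "dam1")),
                        design = "trio")
  res <- filter_compound_het(vs, sc)
  expect_identical(res$genes, "G")
  expect_identical(nrow(res$pairs), 1L)
})

test_that("compound-het pairs die when one control carries both alleles or is homozygous", {
  dosage <- cbind(case1 = c(1L, 1L), sire1 = c(1L, 0L), dam1 = c(0L, 1L),
                  ctl1 = c(1L, 1L))
  vs <- make_vs(dosage, gene = c("G", "G"))
  sc <- filter_scenario("recessive_compound_het", "case1", "ctl1",
                        list(case1 = c(sire = "sire1", dam = "dam1")),
                        design = "trio")
  expect_identical(nrow(filter_compound_het(vs, sc)$pairs), 0L)

  dosage2 <- cbind(case1 = c(1L, 1L), sire1 = c(1L, 0L), dam1 = c(0L, 1L),
                   ctl1 = c(2L, 0L))
  vs2 <- make_vs(dosage2, gene = c("G", "G"))
  expect_identical(nrow(filter_compound_het(vs2, sc)$pairs), 0L)
})

test_that("each filter matches its brute-force oracle on random toy cohorts", {
  for (seed in 1:150) {
    rc <- random_cohort(seed)
    vs <- make_vs(rc$dosage, gene = rc$gene)
    # recessive
    sc <- filter_scenario("recessive_hom", rc$cases, rc$controls,
                          rc$parents, design = rc$design)
    got <- filter_recessive_hom(vs, sc)$audit
    want <- oracle_recessive_hom(rc$dosage, vs$hemizygous, rc$cases,
                                 rc$controls, rc$parents)
    expect_identical(got$retained[order(got$pos)], want,
                     label = paste("recessive seed", seed))
    # dominant
    scd <- filter_scenario("dominant_private", rc$cases, rc$controls,
                           rc$parents, design = rc$design)
    gotd <- filter_dominant_private(vs, scd)$audit
    wantd <- oracle_dominant_private(rc$dosage, vs$hemizygous, rc$cases,
                                     rc$controls, rc$parents, rc$design)
    expect_identical(gotd$retained[order(gotd$pos)], wantd,
                     label = paste("dominant seed", seed))
    # compound het
    scc <- filter_scenario("recessive_compound_het", rc$cases, rc$controls,
                           rc$parents, design = rc$design)
    gotc <- suppressWarnings(filter_compound_het(vs, scc))$pairs
    wantc <- oracle_compound_het(rc$dosage, vs$hemizygous, rc$gene,
                                 rc$cases, rc$controls, rc$parents)
    key <- function(i) paste0("1:", i * 100, "G>A")
    wantk <- sort(vapply(wantc,
                         function(p) paste(key(p[1]), key(p[2])), ""))
    gotk <- sort(paste(gotc$key1, gotc$key2))
    expect_identical(gotk, wantk, label = paste("comphet seed", seed))
  }
})

test_that("adding a control can only shrink or preserve the retained sets", {
  for (seed in 1:40) {
    rc <- random_cohort(seed + 500)
    if (!length(rc$controls)) next
    vs <- make_vs(rc$dosage, gene = rc$gene)
    fewer <- rc$controls[-1]
    for (moi in c("recessive_hom", "dominant_private")) {
      f <- if (moi == "recessive_hom") filter_recessive_hom
           else filter_dominant_private
      all_ctl <- f(vs, filter_scenario(moi, rc$cases, rc$controls,
                                       rc$parents, design = rc$design))
      sub_ctl <- f(vs, filter_scenario(moi, rc$cases, fewer,
                                       rc$parents, design = rc$design))
      expect_true(all(all_ctl$retained$variants$pos %in%
                      sub_ctl$retained$variants$pos))
    }
  }
})

test_that("de novo assessment distinguishes clean, mosaic-suspect and missing parents", {
  dosage <- cbind(case1 = 1L, sire1 = 0L, dam1 = 0L)
  ad <- cbind(case1 = 9L, sire1 = 0L, dam1 = 0L)
  rd <- cbind(case1 = 11L, sire1 = 20L, dam1 = 25L)
  vs <- make_vs(dosage, ref_depth = rd, alt_depth = ad)
  expect_identical(assess_de_novo(vs, 1, "case1", "sire1", "dam1"),
                   "de_novo")
  expect_identical(assess_de_novo(vs, 1, "case1", NA, "dam1"),
                   "undetermined")
  # a 0/0 sire with 3 alt reads of 30 exceeds the error model
  ad2 <- cbind(case1 = 9L, sire1 = 3L, dam1 = 0L)
  rd2 <- cbind(case1 = 11L, sire1 = 27L, dam1 = 25L)
  vs2 <- make_vs(dosage, ref_depth = rd2, alt_depth = ad2)
  expect_identical(assess_de_novo(vs2, 1, "case1", "sire1", "dam1"),
                   "mosaic_parent_suspected")
  # a carrier parent means inherited; absent in case is an error
  dosage3 <- cbind(case1 = 1L, sire1 = 1L, dam1 = 0L)
  vs3 <- make_vs(dosage3, ref_depth = rd, alt_depth = ad)
  expect_identical(assess_de_novo(vs3, 1, "case1", "sire1", "dam1"),
                   "inherited")
  dosage4 <- cbind(case1 = 0L, sire1 = 0L, dam1 = 0L)
  vs4 <- make_vs(dosage4, ref_depth = rd, alt_depth = ad)
  expect_error(assess_de_novo(vs4, 1, "case1", "sire1", "dam1"), "absent")
})

test_that("predictor consensus needs the configured number of deleterious calls", {
  expect_true(consensus_deleterious(c(SIFT = "deleterious",
                                      PolyPhen2 = "deleterious",
                                      MAPP = "tolerated")))
  expect_false(consensus_deleterious(character(0)))
  expect_false(consensus_deleterious(c(SIFT = "deleterious")))
  expect_true(consensus_deleterious(c(SIFT = "deleterious",
                                      MAPP = "deleterious")))
  # unrecognised keys never count
  expect_false(consensus_deleterious(c(foo = "deleterious",
                                       bar = "deleterious")))
})

test_that("the classification ladder reproduces the catalogued archetypes", {
  expect_identical(classify_variant(list(
    consequence = "truncating", private = TRUE,
    segregation_consistent = TRUE, de_novo_support = TRUE)), "pathogenic")
  expect_identical(classify_variant(list(
    consequence = "missense", private = TRUE, predictor_consensus = TRUE,
    segregation_consistent = TRUE)), "likely_pathogenic")
  expect_identical(classify_variant(list(
    consequence = "intronic", private = TRUE)), "uncertain")
  # all-unknown evidence is uncertain
  expect_identical(classify_variant(list(consequence = NA)), "uncertain")
})
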