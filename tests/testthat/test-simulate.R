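test_that("control cohorts follow Hardy-Weinberg at the recorded frequencies", {
  cfg <- sim_config(seed = 1, n_controls = 1000, n_background_variants = 50)
  co <- simulate_cohort(cfg)
  expect_identical(dim(co$genotypes), c(50L, 1000L))
  # a frequency-0.5 site carries ~50% heterozygotes
  mid <- which(abs(co$freqs - 0.5) < 0.05)
  if (length(mid)) {
    het <- rowMeans(co$genotypes[mid, , drop = FALSE] == 1)
    expect_true(all(abs(het - 2 * co$freqs[mid] * (1 - co$freqs[mid]))
                    < 0.06))
  }
  # per-site alt frequency matches the drawn truth
  obs <- rowMeans(co$genotypes) / 2
  expect_lt(max(abs(obs - co$freqs)), 0.06)
})

test_that("seeded simulation is fully deterministic", {
  cfg <- sim_config(seed = 99, scenario = "recessive_hom",
                    n_controls = 40, n_background_variants = 60)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$variants$dosage, d2$variants$dosage)
  expect_identical(d1$variants$alt_depth, d2$variants$alt_depth)
  expect_identical(d1$coverage$count, d2$coverage$count)
  expect_identical(d1$truth, d2$truth)
})

test_that("family scenarios plant genotype configurations matching their MOI", {
  find_planted <- function(ds) {
    keys <- paste0(ds$variants$variants$chrom, ":", ds$variants$variants$pos,
                   ds$variants$variants$ref, ">", ds$variants$variants$alt)
    match(ds$truth$planted, keys)
  }
  dn <- simulate_dataset(sim_config(seed = 2, scenario = "de_novo_dominant"))
  i <- find_planted(dn)
  expect_identical(unname(dn$variants$dosage[i, c("case1", "sire1", "dam1")]),
                   c(1L, 0L, 0L))
  rc <- simulate_dataset(sim_config(seed = 3, scenario = "recessive_hom"))
  i <- find_planted(rc)
  expect_identical(unname(rc$variants$dosage[i, c("case1", "sire1", "dam1")]),
                   c(2L, 1L, 1L))
  ch <- simulate_dataset(sim_config(seed = 4, scenario = "compound_het",
                                    n_controls = 100))
  ii <- find_planted(ch)
  expect_identical(length(ii), 2L)
  d <- ch$variants$dosage
  expect_true(all(d[ii, "case1"] == 1L))
  # one allele per parent, never both in one control
  ctl <- grep("^ctl", colnames(d), value = TRUE)
  expect_false(any(d[ii[1], ctl] >= 1 & d[ii[2], ctl] >= 1))
  xl <- simulate_dataset(sim_config(seed = 5, scenario = "x_linked_de_novo"))
  i <- find_planted(xl)
  expect_identical(xl$variants$variants$chrom[i], "X")
  expect_identical(unname(xl$variants$dosage[i, "case1"]), 1L)
  ms <- simulate_dataset(sim_config(seed = 6, scenario = "mosaic_sire"))
  i <- find_planted(ms)
  expect_identical(unname(ms$variants$dosage[i, c("case1", "case2",
                                                  "sire1")]),
                   c(1L, 1L, 0L))
  expect_error(sim_config(scenario = "de_novo_dominant",
                          design = "single_case"), "trio")
})

test_that("allele depths track genotype-specific alt fractions", {
  set.seed(10)
  cfg <- sim_config(seed = 10, mean_depth = 20, error_rate = 0)
  dosage <- matrix(rep(c(0L, 1L, 2L), each = 2000), ncol = 1,
                   dimnames = list(NULL, "s"))
  d <- simulate_allele_depths(dosage, cfg)
  frac <- tapply(seq_len(6000), rep(1:3, each = 2000), function(idx) {
    sum(d$alt_depth[idx, 1]) / sum(d$alt_depth[idx, 1] + d$ref_depth[idx, 1])
  })
  expect_equal(unname(frac[1]), 0)
  expect_lt(abs(frac[2] - 0.5), 0.02)
  expect_equal(unname(frac[3]), 1)
})

test_that("simulated coverage reflects sex and planted ploidy events", {
  cfg <- sim_config(seed = 12, case_sex = "male", window_size = 50000)
  sim <- simulate_coverage(cfg, sex = "male")
  w <- sim$windows
  auto_mean <- mean(w$count[w$chrom %in% c("1", "2", "3") & !w$partial])
  x_mean <- mean(w$count[w$chrom == "X" & !w$partial])
  expect_lt(abs(x_mean / auto_mean - 0.5), 0.03)

  tri <- simulate_coverage(sim_config(seed = 13, scenario = "trisomy",
                                      window_size = 50000))
  wt <- tri$windows
  ev_mean <- mean(wt$count[wt$chrom == "1" & !wt$partial])
  base <- mean(wt$count[wt$chrom %in% c("2", "3") & !wt$partial])
  expect_lt(abs(ev_mean / base - 1.5), 0.03)

  tm <- simulate_coverage(sim_config(seed = 14,
                                     scenario = "terminal_monosomy"))
  expect_identical(tm$truth$chrom, "1")
  expect_equal(tm$truth$seg_end - tm$truth$seg_start + 1, 2.7e6)
})

test_that("emitted VCF/PED round-trip through the readers reproduces the truth", {
  ds <- simulate_dataset(sim_config(seed = 20, scenario = "recessive_hom",
                                    n_controls = 10,
                                    n_background_variants = 30))
  vp <- tempfile(fileext = ".vcf")
  pp <- tempfile(fileext = ".ped")
  write_vcf(ds$variants, vp)
  write_ped(ds$pedigree, pp)
  back <- read_vcf(vp)
  expect_equal(back$variants, ds$variants$variants)
  expect_equal(back$dosage, ds$variants$dosage)
  expect_equal(back$alt_depth, ds$variants$alt_depth)
  ped <- read_ped(pp)
  expect_identical(sort(ped$id), sort(ds$pedigree$id))
  expect_identical(ped$role[match(ds$pedigree$id, ped$id)],
                   ds$pedigree$role)
})

test_that("no scenario leaks: event-free cohorts yield empty candidate sets", {
  clean <- 0
  for (seed in 1:10) {
    ds <- simulate_dataset(sim_config(seed = seed, scenario = "none",
                                      n_controls = 500,
                                      n_background_variants = 300))
    rep <- run_case(ds$variants, ds$pedigree)
    clean <- clean + (nrow(rep$candidates) == 0)
  }
  expect_gte(clean / 10, 0.95)
})
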