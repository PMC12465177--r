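test_that("informative-site labelling follows parental carriage", {
  dosage <- cbind(case1 = c(1L, 1L, 1L, 1L, 0L),
                  sire1 = c(1L, 0L, 1L, 0L, 1L),
                  dam1 = c(0L, 1L, 1L, 0L, 0L))
  vs <- make_vs(dosage,
                alt_depth = matrix(10L, 5, 3,
                                   dimnames = list(NULL, colnames(dosage))),
                ref_depth = matrix(10L, 5, 3,
                                   dimnames = list(NULL, colnames(dosage))))
  sites <- classify_informative_sites(vs, "case1", "sire1", "dam1")
  expect_identical(sites$class,
                   c("sire_only_alt", "dam_only_alt", "uninformative",
                     "uninformative"))
  # absent trio member yields an empty site list
  empty <- classify_informative_sites(vs, "case1", "ghost", "dam1")
  expect_identical(nrow(empty), 0L)
})

test_that("pooled alt fraction carries an exact binomial interval", {
  sites <- data.frame(alt_depth = c(120L, 80L), ref_depth = c(60L, 40L))
  est <- estimate_alt_fraction(sites)
  expect_equal(est$fraction, 200 / 300)
  ref <- binom.test(200, 300)$conf.int
  expect_equal(est$ci, as.numeric(ref))
  expect_equal(round(est$ci, 2), c(0.61, 0.72))
  zero <- estimate_alt_fraction(data.frame(alt_depth = 0L, ref_depth = 100L))
  expect_equal(zero$fraction, 0)
  expect_error(estimate_alt_fraction(
    data.frame(alt_depth = 1L, ref_depth = 2L)), "depth")
})

test_that("alt fraction at dosage-2-of-3 sites converges to two-thirds", {
  set.seed(31)
  sites <- simulate_trisomy_sites(2000, depth = 20, origin = "paternal")
  two_thirds <- sites[sites$alt_copies == 2L, ]
  est <- estimate_alt_fraction(two_thirds)
  expect_lt(abs(est$fraction - 2 / 3), 0.02)
})

test_that("extra-copy origin calls are correct and label-symmetric", {
  set.seed(32)
  pat <- simulate_trisomy_sites(500, origin = "paternal")
  res <- infer_extra_copy_origin(pat)
  expect_identical(res$origin, "paternal")
  expect_gt(res$llr, 10)
  # swapping site labels flips the call
  flipped <- pat
  flipped$class <- ifelse(pat$class == "sire_only_alt",
                          "dam_only_alt", "sire_only_alt")
  res_f <- infer_extra_copy_origin(flipped)
  expect_identical(res_f$origin, "maternal")
  expect_equal(res_f$llr, -res$llr)
  # balanced disomic fractions stay undetermined
  bal <- data.frame(class = rep(c("sire_only_alt", "dam_only_alt"), 50),
                    alt_depth = 10L, ref_depth = 10L)
  expect_identical(infer_extra_copy_origin(bal)$origin, "undetermined")
  none <- data.frame(class = character(0), alt_depth = integer(0),
                     ref_depth = integer(0))
  expect_identical(infer_extra_copy_origin(none)$origin, "undetermined")
})

test_that("maternal-extra trisomies are never mistaken for paternal across seeds", {
  calls <- character(100)
  for (s in 1:100) {
    set.seed(s)
    sites <- simulate_trisomy_sites(400, origin = "maternal")
    calls[s] <- infer_extra_copy_origin(sites)$origin
  }
  expect_gte(mean(calls == "maternal"), 0.99)
  expect_false(any(calls == "paternal"))
})

test_that("the mosaicism test separates absent, mosaic and constitutive states", {
  expect_identical(test_mosaicism(6, 40), "low_level_mosaic")
  expect_identical(test_mosaicism(0, 40), "absent")
  expect_identical(test_mosaicism(19, 40), "constitutive_het")
  expect_identical(test_mosaicism(3, 5), "undetermined")
  # exact test at the boundary: one error read of 40 is explainable
  expect_identical(test_mosaicism(1, 40), "absent")
})

test_that("type-I error of the mosaicism test stays at or below alpha", {
  set.seed(77)
  cfg <- mosaic_config()
  alt <- rbinom(10000, 40, cfg$error_rate)
  status <- vapply(alt, test_mosaicism, "", total_depth = 40, config = cfg)
  expect_lte(mean(status == "low_level_mosaic"), cfg$alpha)
})

test_that("tissue combinations map to parental mosaicism classes", {
  expect_identical(classify_parental_mosaicism(
    c(semen = "low_level_mosaic", blood = "absent")), "germline_mosaic")
  expect_identical(classify_parental_mosaicism(
    c(semen = "low_level_mosaic", blood = "low_level_mosaic")),
    "somatic_and_germline")
  expect_identical(classify_parental_mosaicism(
    c(semen = "absent", blood = "absent")), "not_mosaic")
  expect_identical(classify_parental_mosaicism(
    c(semen = "constitutive_het", blood = "constitutive_het")), "not_mosaic")
  expect_identical(classify_parental_mosaicism(c(blood = "absent")),
                   "indeterminate")
})
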