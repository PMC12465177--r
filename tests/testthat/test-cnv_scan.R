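flat_windows <- function(counts_by_chrom, window_size = 10000) {
  rows <- do.call(rbind, lapply(names(counts_by_chrom), function(ch) {
    cnt <- counts_by_chrom[[ch]]
    data.frame(chrom = ch,
               start = seq(1L, by = window_size, length.out = length(cnt)),
               count = cnt, stringsAsFactors = FALSE)
  }))
  coverage_windows(rows$chrom, rows$start, rows$count, window_size)
}

test_that("normalization fixes autosomal ratios at 1 and male X at 0.5", {
  w <- flat_windows(list("1" = rep(200L, 300), "2" = rep(200L, 300),
                         "3" = rep(200L, 300), "X" = rep(100L, 200)))
  m <- ploidy_model("male")
  w <- normalize_coverage(w, m)
  expect_equal(unique(w$ratio[w$chrom != "X"]), 1)
  expect_equal(unique(w$ratio[w$chrom == "X"]), 0.5)
  expect_error(normalize_coverage(
    flat_windows(list("1" = rep(0L, 300))), m), "zero")
  expect_error(normalize_coverage(
    flat_windows(list("1" = rep(10L, 50))), m), "autosomal windows")
})

test_that("ratios and calls are invariant to a constant scaling of counts", {
  set.seed(9)
  w1 <- flat_windows(list("1" = rpois(400, 150), "2" = rpois(400, 150),
                          "3" = rpois(300, 225)))
  w10 <- w1
  w10$count <- w10$count * 10L
  m <- ploidy_model("female")
  s1 <- genome_scan(w1, m)
  s10 <- genome_scan(w10, m)
  expect_equal(s1$manhattan$ratio, s10$manhattan$ratio)
  expect_identical(s1$calls$call, s10$calls$call)
  expect_identical(s1$calls$call[s1$calls$chrom == "3"], "trisomy")
})

test_that("whole-chromosome calls follow the median-ratio bands", {
  m <- ploidy_model("female")
  mk <- function(level) {
    w <- flat_windows(list("1" = rep(200L, 300), "2" = rep(200L, 300),
                           "3" = as.integer(rep(200 * level, 100))))
    normalize_coverage(w, m)
  }
  pick <- function(w) w[w$chrom == "3", ]
  expect_identical(call_chromosome(pick(mk(1.5)), m)$call, "trisomy")
  expect_identical(call_chromosome(pick(mk(1.0)), m)$call, "disomy")
  expect_identical(call_chromosome(pick(mk(0.5)), m)$call, "monosomy")
  expect_identical(call_chromosome(pick(mk(1.25)), m)$call, "no_call")
  expect_warning(res <- call_chromosome(pick(mk(1))[1:5, ], m), "windows")
  expect_identical(res$call, "no_call")
})

test_that("the terminal scan recovers a planted terminal loss and stays quiet otherwise", {
  m <- ploidy_model("female")
  w <- flat_windows(list("1" = c(rep(200L, 2230), rep(100L, 270)),
                         "2" = rep(200L, 500)))
  w <- normalize_coverage(w, m)
  res <- detect_terminal_segment(w[w$chrom == "1", ], m)
  expect_identical(res$call, "partial_monosomy")
  expect_identical(res$n_windows, 270L)
  expect_equal(res$seg_end - res$seg_start + 1, 2.7e6)
  flat <- detect_terminal_segment(w[w$chrom == "2", ], m)
  expect_identical(flat$call, "no_call")
  # a left-terminal gain is found on the correct side
  wg <- flat_windows(list("1" = c(rep(300L, 100), rep(200L, 900)),
                          "2" = rep(200L, 500)))
  wg <- normalize_coverage(wg, m)
  g <- detect_terminal_segment(wg[wg$chrom == "1", ], m)
  expect_identical(g$call, "partial_gain")
  expect_identical(g$seg_start, 1L)
})

test_that("noisy breakpoint recovery improves with finer windows", {
  set.seed(21)
  err_for <- function(window_size, n_rep = 20) {
    errs <- numeric(n_rep)
    len <- 25e6
    loss <- 2.7e6
    for (r in seq_len(n_rep)) {
      cfg <- sim_config(seed = r, mean_depth = 14,
                        scenario = "terminal_monosomy",
                        window_size = window_size,
                        genome = data.frame(chrom = c("1", "2"),
                                            length = c(len, 20e6),
                                            class = "autosome"))
      sim <- simulate_coverage(cfg)
      w <- normalize_coverage(sim$windows, ploidy_model("female"))
      res <- detect_terminal_segment(w[w$chrom == "1", ],
                                     ploidy_model("female"))
      errs[r] <- abs(res$seg_start - sim$truth$seg_start)
    }
    mean(errs)
  }
  expect_lte(err_for(10000), err_for(200000))
})

test_that("genome_scan finds exactly the planted event and nothing else", {
  cfg <- sim_config(seed = 4, scenario = "trisomy", event_chrom = "2",
                    case_sex = "male")
  sim <- simulate_coverage(cfg, sex = "male")
  scan <- genome_scan(sim$windows, ploidy_model("male"))
  expect_identical(scan$calls$call[scan$calls$chrom == "2"], "trisomy")
  expect_identical(sum(scan$calls$call == "trisomy"), 1L)
  expect_true(all(scan$calls$call[scan$calls$chrom %in% c("1", "3")] ==
                  "disomy"))
})

test_that("event-free male genomes produce no aneuploidy calls across seeds", {
  bad <- 0
  for (seed in 1:25) {
    cfg <- sim_config(seed = seed, scenario = "none", case_sex = "male",
                      window_size = 50000)
    sim <- simulate_coverage(cfg, sex = "male")
    scan <- genome_scan(sim$windows, ploidy_model("male"))
    bad <- bad + sum(scan$calls$call %in%
                     c("trisomy", "monosomy", "partial_monosomy",
                       "partial_gain"))
  }
  expect_identical(bad, 0)
})
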