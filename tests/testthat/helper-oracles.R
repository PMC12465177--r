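# Naive, loop-based re-evaluations of the textual filter definitions.
# Deliberately written without reusing any package internals so they can
# serve as independent oracles for the vectorised filters.

oracle_recessive_hom <- function(dosage, hemi, cases, controls, parents) {
  keep <- logical(nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    ok <- TRUE
    for (cs in cases) {
      d <- dosage[i, cs]
      hom <- !is.na(d) && (d == 2 || (hemi[i, cs] && d == 1))
      if (!hom) ok <- FALSE
    }
    for (ct in controls) {
      d <- dosage[i, ct]
      if (!is.na(d) && (d == 2 || (hemi[i, ct] && d == 1))) ok <- FALSE
    }
    for (cs in cases) {
      for (p in parents[[cs]]) {
        if (!(p %in% colnames(dosage))) next
        d <- dosage[i, p]
        if (!is.na(d) && !(d == 1 && !hemi[i, p])) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  keep
}

oracle_dominant_private <- function(dosage, hemi, cases, controls, parents,
                                    design) {
  keep <- logical(nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    ok <- TRUE
    for (cs in cases) {
      d <- dosage[i, cs]
      if (is.na(d) || d != 1) ok <- FALSE
    }
    for (ct in controls) {
      d <- dosage[i, ct]
      if (!is.na(d) && d >= 1) ok <- FALSE
    }
    if (design %in% c("trio", "single_parent")) {
      for (cs in cases) {
        for (p in parents[[cs]]) {
          if (!(p %in% colnames(dosage))) next
          d <- dosage[i, p]
          if (!is.na(d) && d != 0) ok <- FALSE
        }
      }
    }
    keep[i] <- ok
  }
  keep
}

oracle_compound_het <- function(dosage, hemi, gene, cases, controls,
                                parents) {
  res <- list()
  for (i in seq_len(nrow(dosage) - 1)) {
    for (j in seq(i + 1, nrow(dosage))) {
      if (is.na(gene[i]) || is.na(gene[j]) || gene[i] != gene[j]) next
      ok <- TRUE
      for (cs in cases) {
        di <- dosage[i, cs]; dj <- dosage[j, cs]
        if (is.na(di) || di != 1 || is.na(dj) || dj != 1) ok <- FALSE
      }
      for (ct in controls) {
        di <- dosage[i, ct]; dj <- dosage[j, ct]
        hom_i <- !is.na(di) && (di == 2 || (hemi[i, ct] && di == 1))
        hom_j <- !is.na(dj) && (dj == 2 || (hemi[j, ct] && dj == 1))
        if (hom_i || hom_j) ok <- FALSE
        if (!is.na(di) && di >= 1 && !is.na(dj) && dj >= 1) ok <- FALSE
      }
      for (cs in cases) {
        p <- parents[[cs]]
        if (!all(c("sire", "dam") %in% names(p))) next
        if (!(p[["sire"]] %in% colnames(dosage)) ||
            !(p[["dam"]] %in% colnames(dosage))) next
        si <- !is.na(dosage[i, p[["sire"]]]) && dosage[i, p[["sire"]]] >= 1
        sj <- !is.na(dosage[j, p[["sire"]]]) && dosage[j, p[["sire"]]] >= 1
        di_ <- !is.na(dosage[i, p[["dam"]]]) && dosage[i, p[["dam"]]] >= 1
        dj_ <- !is.na(dosage[j, p[["dam"]]]) && dosage[j, p[["dam"]]] >= 1
        if (!((si && dj_) || (sj && di_))) ok <- FALSE
      }
      if (ok) res[[length(res) + 1L]] <- c(i, j)
    }
  }
  res
}

# random toy cohort for the oracle-equivalence property
random_cohort <- function(seed, max_samples = 8, max_variants = 50) {
  set.seed(seed)
  n_cases <- sample(1:2, 1)
  design <- sample(c("trio", "single_parent", "half_sibs",
                     "multiple_cases", "single_case"), 1)
  if (design %in% c("half_sibs", "multiple_cases")) n_cases <- 2
  if (design %in% c("trio", "single_parent", "single_case")) n_cases <- 1
  cases <- paste0("case", seq_len(n_cases))
  parents <- stats::setNames(vector("list", n_cases), cases)
  samples <- cases
  if (design == "trio") {
    parents[["case1"]] <- c(sire = "sire1", dam = "dam1")
    samples <- c(samples, "sire1", "dam1")
  } else if (design == "single_parent") {
    parents[["case1"]] <- c(sire = "sire1")
    samples <- c(samples, "sire1")
  } else if (design == "half_sibs") {
    for (cs in cases) parents[[cs]] <- c(sire = "sire1")
    samples <- c(samples, "sire1")
  } else {
    for (cs in cases) parents[[cs]] <- character(0)
  }
  n_ctl <- sample(0:max(0, max_samples - length(samples)), 1)
  controls <- if (n_ctl > 0) paste0("ctl", seq_len(n_ctl)) else character(0)
  samples <- c(samples, controls)
  n_var <- sample(5:max_variants, 1)
  dosage <- matrix(sample(c(0L, 1L, 2L, NA), n_var * length(samples),
                          replace = TRUE,
                          prob = c(0.45, 0.3, 0.15, 0.1)),
                   n_var, length(samples),
                   dimnames = list(NULL, samples))
  gene <- sample(c("G1", "G2", "G3", NA), n_var, replace = TRUE)
  list(dosage = dosage, gene = gene, cases = cases, controls = controls,
       parents = parents, design = design)
}
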