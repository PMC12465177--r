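#' Define a filtering scenario
#'
#' A scenario binds a mode-of-inheritance hypothesis to a cohort design:
#' which samples are the affected case(s), which are controls, and which
#' parents are available per case.
#'
#' @param moi one of `"recessive_hom"`, `"recessive_compound_het"`,
#'   `"dominant_private"`, `"x_linked"`.
#' @param cases character vector of case sample ids (>= 1).
#' @param controls character vector of control sample ids.
#' @param parents named list mapping each case id to a named character
#'   vector with optional entries `sire` and `dam`.
#' @param design cohort design label: `"trio"`, `"single_parent"`,
#'   `"half_sibs"`, `"multiple_cases"` or `"single_case"`. A trio design
#'   requires both parents for every case.
#' @param missing_control policy for missing control genotypes:
#'   `"reference"` (the permissive default: a missing control call never
#'   disqualifies a variant) or `"exclude"` (a variant with any missing
#'   control call is dropped).
#' @return a list of class `filter_scenario`.
#' @export
filter_scenario <- function(moi = c("recessive_hom", "recessive_compound_het",
                                    "dominant_private", "x_linked"),
                            cases, controls = character(0),
                            parents = list(),
                            design = c("trio", "single_parent", "half_sibs",
                                       "multiple_cases", "single_case"),
                            missing_control = c("reference", "exclude")) {
  moi <- match.arg(moi)
  design <- match.arg(design)
  missing_control <- match.arg(missing_control)
  if (!length(cases)) stop("scenario requires at least one case")
  if (design == "trio") {
    ok <- vapply(cases, function(cs) {
      p <- parents[[cs]]
      !is.null(p) && all(c("sire", "dam") %in% names(p))
    }, logical(1))
    if (!all(ok)) stop("trio design requires both parents for every case")
  }
  structure(list(moi = moi, cases = cases, controls = controls,
                 parents = parents, design = design,
                 missing_control = missing_control),
            class = "filter_scenario")
}

is_carrier <- function(d) !is.na(d) & d >= 1L
is_hom_alt <- function(d, hemi) !is.na(d) & (d == 2L | (hemi & d == 1L))

control_mat <- function(vs, scenario) {
  ctl <- intersect(scenario$controls, vs$samples)
  list(d = vs$dosage[, ctl, drop = FALSE],
       hemi = vs$hemizygous[, ctl, drop = FALSE])
}

# per-variant parent check; returns TRUE/FALSE vector over variants
check_parents <- function(vs, scenario, test) {
  ok <- rep(TRUE, n_variants(vs))
  for (cs in scenario$cases) {
    for (p in scenario$parents[[cs]]) {
      if (!(p %in% vs$samples)) next
      d <- vs$dosage[, p]
      known <- !is.na(d)
      ok <- ok & (!known | test(d, vs$hemizygous[, p]))
    }
  }
  ok
}

finish_filter <- function(vs, keep, reason) {
  o <- order(vs$variants$chrom, vs$variants$pos, vs$variants$alt)
  audit <- data.frame(vs$variants[, c("chrom", "pos", "ref", "alt", "gene")],
                      retained = keep, reason = reason,
                      stringsAsFactors = FALSE)[o, ]
  rownames(audit) <- NULL
  structure(list(retained = sort_variants(vs[which(keep), ]),
                 audit = audit),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("filter_result:", sum(x$audit$retained), "of", nrow(x$audit),
      "variants retained\n")
  invisible(x)
}

#' Filter for homozygous private variants (recessive hypothesis)
#'
#' Retains variants that are homozygous-alt (or hemizygous-alt) in every
#' case and never homozygous-alt in any control; heterozygous control
#' carriers are permitted. Available parents with a non-missing call must be
#' heterozygous carriers. Missing case genotypes fail; missing control
#' genotypes follow the scenario's `missing_control` policy.
#'
#' @param vs a [variant_set()].
#' @param scenario a [filter_scenario()] with `moi = "recessive_hom"`.
#' @return a `filter_result`: `$retained` (sorted `variant_set`) and
#'   `$audit` (per-variant pass/fail table).
#' @export
filter_recessive_hom <- function(vs, scenario) {
  stopifnot(inherits(scenario, "filter_scenario"),
            scenario$moi == "recessive_hom")
  cs <- scenario$cases
  if (!all(cs %in% vs$samples)) stop("case sample missing from variant set")
  case_ok <- rep(TRUE, n_variants(vs))
  for (s in cs) case_ok <- case_ok & is_hom_alt(vs$dosage[, s], vs$hemizygous[, s])
  ctl <- control_mat(vs, scenario)
  ctl_hom <- rowSums(is_hom_alt(ctl$d, ctl$hemi)) > 0
  ctl_miss <- if (scenario$missing_control == "exclude") {
    rowSums(is.na(ctl$d)) > 0
  } else rep(FALSE, n_variants(vs))
  par_ok <- check_parents(vs, scenario,
                          function(d, hemi) d == 1L & !hemi)
  keep <- case_ok & !ctl_hom & !ctl_miss & par_ok
  reason <- ifelse(!case_ok, "case not homozygous-alt",
            ifelse(ctl_hom, "homozygous-alt control",
            ifelse(ctl_miss, "missing control genotype",
            ifelse(!par_ok, "parent not a heterozygous carrier", "retained"))))
  finish_filter(vs, keep, reason)
}

#' Filter for heterozygous private variants (dominant / X-linked hypothesis)
#'
#' Retains variants heterozygous (or hemizygous-alt on the male X) in every
#' case and carried by no control in any state. In trio and single-parent
#' designs every available, non-missing parental call must be homozygous
#' reference.
#'
#' @param vs a [variant_set()].
#' @param scenario a [filter_scenario()] with `moi` `"dominant_private"` or
#'   `"x_linked"`.
#' @return a `filter_result` (see [filter_recessive_hom()]).
#' @export
filter_dominant_private <- function(vs, scenario) {
  stopifnot(inherits(scenario, "filter_scenario"),
            scenario$moi %in% c("dominant_private", "x_linked"))
  cs <- scenario$cases
  if (!all(cs %in% vs$samples)) stop("case sample missing from variant set")
  case_ok <- rep(TRUE, n_variants(vs))
  for (s in cs) {
    d <- vs$dosage[, s]
    case_ok <- case_ok & !is.na(d) & d == 1L
  }
  ctl <- control_mat(vs, scenario)
  ctl_carrier <- rowSums(is_carrier(ctl$d)) > 0
  ctl_miss <- if (scenario$missing_control == "exclude") {
    rowSums(is.na(ctl$d)) > 0
  } else rep(FALSE, n_variants(vs))
  par_ok <- if (scenario$design %in% c("trio", "single_parent")) {
    check_parents(vs, scenario, function(d, hemi) d == 0L)
  } else rep(TRUE, n_variants(vs))
  keep <- case_ok & !ctl_carrier & !ctl_miss & par_ok
  reason <- ifelse(!case_ok, "case not heterozygous",
            ifelse(ctl_carrier, "control carrier",
            ifelse(ctl_miss, "missing control genotype",
            ifelse(!par_ok, "parent carries the variant", "retained"))))
  finish_filter(vs, keep, reason)
}

#' Filter for compound-heterozygous allele pairs (recessive hypothesis)
#'
#' Within each annotated gene, retains unordered pairs of variants such
#' that every case is heterozygous for both alleles, no control carries both
#' alleles simultaneously, no control is homozygous for either, and — when
#' both parents of a case are genotyped — a trans configuration is
#' pedigree-consistent (one allele attributable to each parent).
#'
#' @param vs a [variant_set()]; variants without a gene label are skipped
#'   with a warning.
#' @param scenario a [filter_scenario()] with `moi = "recessive_compound_het"`.
#' @return list of class `comphet_result` with `$pairs` (data.frame: gene and
#'   the two variant keys) and `$genes` (unique retained genes).
#' @export
filter_compound_het <- function(vs, scenario) {
  stopifnot(inherits(scenario, "filter_scenario"),
            scenario$moi == "recessive_compound_het")
  cs <- scenario$cases
  if (anyNA(vs$variants$gene)) {
    warning("skipping ", sum(is.na(vs$variants$gene)),
            " variant(s) without a gene label")
  }
  key <- function(i) paste0(vs$variants$chrom[i], ":", vs$variants$pos[i],
                            vs$variants$ref[i], ">", vs$variants$alt[i])
  # candidate alleles: heterozygous in every case
  cand <- rep(TRUE, n_variants(vs))
  for (s in cs) {
    d <- vs$dosage[, s]
    cand <- cand & !is.na(d) & d == 1L
  }
  cand <- cand & !is.na(vs$variants$gene)
  ctl_ids <- intersect(scenario$controls, vs$samples)
  dctl <- vs$dosage[, ctl_ids, drop = FALSE]
  hctl <- vs$hemizygous[, ctl_ids, drop = FALSE]
  ctl_hom <- rowSums(is_hom_alt(dctl, hctl)) > 0
  pairs <- list()
  for (g in unique(vs$variants$gene[cand])) {
    idx <- which(cand & vs$variants$gene == g & !ctl_hom)
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq((a + 1), length(idx))) {
        i <- idx[a]; j <- idx[b]
        both <- is_carrier(dctl[i, ]) & is_carrier(dctl[j, ])
        if (any(both)) next
        trans_ok <- TRUE
        for (s in cs) {
          p <- scenario$parents[[s]]
          sire <- if ("sire" %in% names(p)) p[["sire"]] else NULL
          dam <- if ("dam" %in% names(p)) p[["dam"]] else NULL
          if (is.null(sire) || is.null(dam) ||
              !(sire %in% vs$samples) || !(dam %in% vs$samples)) next
          si <- is_carrier(vs$dosage[i, sire])
          sj <- is_carrier(vs$dosage[j, sire])
          di <- is_carrier(vs$dosage[i, dam])
          dj <- is_carrier(vs$dosage[j, dam])
          if (!((si && dj) || (sj && di))) trans_ok <- FALSE
        }
        if (!trans_ok) next
        pairs[[length(pairs) + 1L]] <-
          data.frame(gene = g, key1 = key(min(i, j)), key2 = key(max(i, j)),
                     stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(gene = character(0), key1 = character(0),
                           key2 = character(0))
  pairs <- pairs[order(pairs$gene, pairs$key1, pairs$key2), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, genes = unique(pairs$gene)),
            class = "comphet_result")
}

#' Assess whether a case variant is de novo
#'
#' A variant is called de novo when both parents are homozygous reference
#' with no alt-supporting reads (up to `max_parent_alt`) at adequate depth.
#' A parent called 0/0 whose alt reads nonetheless exceed what sequencing
#' error explains (one-sided exact binomial test at rate `error_rate`) makes
#' the call `mosaic_parent_suspected`. A missing parent, or inadequate
#' parental depth, yields `undetermined`; a parent carrying the allele makes
#' the variant `inherited`.
#'
#' @param vs a [variant_set()].
#' @param i variant row index.
#' @param case case sample id (must carry the variant).
#' @param sire,dam parental sample ids (`NA` when unavailable).
#' @param config list of `max_parent_alt` (default 0), `min_depth` (10),
#'   `error_rate` (0.005) and `alpha` (0.05).
#' @return one of `"de_novo"`, `"inherited"`, `"mosaic_parent_suspected"`,
#'   `"undetermined"`.
#' @export
assess_de_novo <- function(vs, i, case, sire, dam,
                           config = list(max_parent_alt = 0, min_depth = 10,
                                         error_rate = 0.005, alpha = 0.05)) {
  d_case <- vs$dosage[i, case]
  if (is.na(d_case) || d_case < 1) stop("variant absent in case ", case)
  parents <- c(sire, dam)
  if (anyNA(parents) || !all(parents %in% vs$samples)) return("undetermined")
  status <- character(0)
  for (p in parents) {
    d <- vs$dosage[i, p]
    if (is.na(d)) return("undetermined")
    if (d >= 1) return("inherited")
    ad <- vs$alt_depth[i, p]
    rd <- vs$ref_depth[i, p]
    tot <- ad + rd
    if (is.na(tot) || tot < config$min_depth) {
      status <- c(status, "undetermined")
    } else if (ad > config$max_parent_alt &&
               stats::pbinom(ad - 1, tot, config$error_rate,
                             lower.tail = FALSE) < config$alpha) {
      status <- c(status, "mosaic")
    } else if (ad <= config$max_parent_alt) {
      status <- c(status, "clean")
    } else {
      status <- c(status, "undetermined")
    }
  }
  if ("mosaic" %in% status) "mosaic_parent_suspected"
  else if (all(status == "clean")) "de_novo"
  else "undetermined"
}

#' Consensus deleteriousness over in-silico predictors
#'
#' @param annotations named character vector of predictor verdicts (values
#'   `"deleterious"` or anything else); absent predictors count as
#'   non-deleterious.
#' @param config list with `min_deleterious_tools` (default 2) and
#'   `predictors` (recognised keys).
#' @return `TRUE` when at least `min_deleterious_tools` recognised predictors
#'   call the variant deleterious.
#' @export
consensus_deleterious <- function(annotations,
                                  config = consensus_config()) {
  if (config$min_deleterious_tools < 1) stop("min_deleterious_tools >= 1")
  if (is.null(annotations) || !length(annotations)) return(FALSE)
  keys <- intersect(names(annotations), config$predictors)
  sum(annotations[keys] == "deleterious") >= config$min_deleterious_tools
}

#' Default predictor-consensus configuration
#'
#' @param min_deleterious_tools minimum concordant deleterious calls.
#' @param predictors recognised predictor annotation keys.
#' @return a list usable as `config` in [consensus_deleterious()].
#' @export
consensus_config <- function(min_deleterious_tools = 2,
                             predictors = c("PredictSNP1", "PolyPhen2",
                                            "SIFT", "SNAP", "MAPP",
                                            "PhDSNP", "MutPred2")) {
  list(min_deleterious_tools = min_deleterious_tools, predictors = predictors)
}

#' Classify a candidate variant from its evidence profile
#'
#' Deterministic rule ladder approximating domestic-animal variant
#' classification practice: pathogenic requires a truncating consequence (or
#' a known disease-allele match) that is private, segregation-consistent and
#' supported by de novo evidence or multiple affected carriers;
#' likely-pathogenic relaxes the consequence to missense/in-frame backed by
#' predictor consensus; everything else is of uncertain significance.
#' Unknown (NA) evidence never counts in favour.
#'
#' @param evidence list with fields `consequence` (one of `"truncating"`,
#'   `"missense"`, `"inframe"`, `"intronic"`, `"other"`),
#'   `known_disease_allele`, `private`, `segregation_consistent`,
#'   `de_novo_support`, `multiple_affected_carriers`, `predictor_consensus`
#'   (logical or `NA`).
#' @return `"pathogenic"`, `"likely_pathogenic"` or `"uncertain"`.
#' @export
classify_variant <- function(evidence) {
  f <- function(nm) isTRUE(evidence[[nm]])
  conseq <- evidence$consequence
  if (is.null(conseq) || is.na(conseq)) conseq <- "other"
  if ((identical(conseq, "truncating") || f("known_disease_allele")) &&
      f("private") && f("segregation_consistent") &&
      (f("de_novo_support") || f("multiple_affected_carriers"))) {
    return("pathogenic")
  }
  if (conseq %in% c("missense", "inframe") && f("private") &&
      f("predictor_consensus") && f("segregation_consistent")) {
    return("likely_pathogenic")
  }
  "uncertain"
}
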