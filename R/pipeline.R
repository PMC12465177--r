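#' Run the end-to-end diagnostic workflow for one case (or case group)
#'
#' Mirrors the diagnostic narrative of the framework: verify recorded
#' parentage by identity-by-descent, filter SNVs/indels under every
#' applicable mode-of-inheritance hypothesis (homozygous recessive, compound
#' heterozygous, dominant/X-linked private), assess de novo status for
#' dominant candidates when a trio is available, classify surviving
#' candidates, and — only when no candidate SNV/indel survives — fall back to
#' the read-depth karyotype scan, adding parental-origin inference for a
#' detected aneuploidy when trio genotypes exist.
#'
#' @param vs a [variant_set()] over cases, available parents and controls.
#' @param ped a `pedigree` describing cases and parents (see [read_ped()]).
#' @param coverage optional `coverage_windows` table for the CNV stage.
#' @param controls control sample ids (default: all `vs` samples absent from
#'   the pedigree).
#' @param freqs optional per-site alt-allele frequencies for the IBD check
#'   (skipped when absent or when fewer than `min_sites` usable sites exist).
#' @param config list of knobs: `override_parentage` (proceed despite an
#'   exclusion, default FALSE), `run_cnv` (force/disable the CNV stage,
#'   default NULL = automatic fallback), `delta`, `min_windows`,
#'   `mosaic` (a [mosaic_config()]), `min_ibd_sites`.
#' @return list of class `case_report`: `design`, `kinship`, per-scenario
#'   `filters` (audit + retained keys), `candidates` (classified findings),
#'   `cnv`, `origin`, and `outcome` (`pathogenic_found`,
#'   `likely_pathogenic_found`, `uncertain_only`, `unsolved`).
#' @export
run_case <- function(vs, ped, coverage = NULL, controls = NULL,
                     freqs = NULL, config = list()) {
  cfg <- utils::modifyList(
    list(override_parentage = FALSE, run_cnv = NULL, delta = 0.15,
         min_windows = 10, mosaic = mosaic_config(), min_ibd_sites = 500),
    config)
  cases <- ped$id[ped$role == "case"]
  if (!length(cases)) stop("pedigree contains no affected case")
  if (is.null(controls)) controls <- setdiff(vs$samples, ped$id)
  parents <- stats::setNames(lapply(cases, function(cs) {
    p <- c(sire = ped$sire[ped$id == cs], dam = ped$dam[ped$id == cs])
    p <- p[!is.na(p) & p %in% vs$samples]
    p
  }), cases)
  n_par <- vapply(parents, length, 0L)
  design <- if (isTRUE(attr(ped, "half_sib_design"))) "half_sibs"
            else if (length(cases) > 1) "multiple_cases"
            else if (n_par[1] == 2) "trio"
            else if (n_par[1] == 1) "single_parent"
            else "single_case"

  # stage 1: parentage verification
  kin <- NULL
  if (!is.null(freqs)) {
    usable <- sum(!is.na(freqs) & freqs >= 0.05 & freqs <= 0.95)
    if (usable >= cfg$min_ibd_sites) {
      kin <- verify_pedigree(ped, vs$dosage, freqs,
                             min_sites = cfg$min_ibd_sites)
      bad <- kin$verdict %in% c("excluded", "unrelated_like")
      if (any(bad) && !cfg$override_parentage) {
        stop("parentage excluded for link(s): ",
             paste(kin$offspring[bad], kin$parent[bad],
                   sep = "-", collapse = ", "),
             "; rerun with override_parentage = TRUE to proceed")
      }
    }
  }

  mk <- function(moi) filter_scenario(moi, cases, controls, parents, design)
  filters <- list(
    recessive_hom = filter_recessive_hom(vs, mk("recessive_hom")),
    compound_het = suppressWarnings(
      filter_compound_het(vs, mk("recessive_compound_het"))),
    dominant_private = filter_dominant_private(vs, mk("dominant_private")))

  key_of <- function(i) paste0(vs$variants$chrom[i], ":", vs$variants$pos[i],
                               vs$variants$ref[i], ">", vs$variants$alt[i])
  candidates <- list()
  add_candidate <- function(key, gene, moi, de_novo, classification) {
    candidates[[length(candidates) + 1L]] <<- data.frame(
      key = key, gene = gene, moi = moi, de_novo = de_novo,
      classification = classification, stringsAsFactors = FALSE)
  }
  ann_of <- function(vset, i) {
    a <- if (is.null(vset$annotations)) NULL else vset$annotations[[i]]
    if (is.null(a)) character(0) else a
  }
  classify_hit <- function(vset, i, moi, de_novo_status) {
    a <- ann_of(vset, i)
    get_a <- function(nm) if (nm %in% names(a)) a[[nm]] else NA_character_
    conseq <- if ("consequence" %in% names(a)) a[["consequence"]] else "other"
    classify_variant(list(
      consequence = conseq,
      known_disease_allele = identical(get_a("known_disease_allele"), "yes"),
      private = TRUE, segregation_consistent = TRUE,
      de_novo_support = identical(de_novo_status, "de_novo") ||
        identical(de_novo_status, "mosaic_parent_suspected"),
      multiple_affected_carriers = length(cases) > 1,
      predictor_consensus = consensus_deleterious(a)))
  }
  for (moi in c("recessive_hom", "dominant_private")) {
    ret <- filters[[moi]]$retained
    for (i in seq_len(n_variants(ret))) {
      dn <- "undetermined"
      if (moi == "dominant_private" &&
          design %in% c("trio", "single_parent")) {
        p <- parents[[cases[1]]]
        dn <- assess_de_novo(ret, i, cases[1],
                             if ("sire" %in% names(p)) p[["sire"]] else NA,
                             if ("dam" %in% names(p)) p[["dam"]] else NA,
                             config = list(
                               max_parent_alt = 0,
                               min_depth = cfg$mosaic$min_depth,
                               error_rate = cfg$mosaic$error_rate,
                               alpha = cfg$mosaic$alpha))
      }
      vkey <- paste0(ret$variants$chrom[i], ":", ret$variants$pos[i],
                     ret$variants$ref[i], ">", ret$variants$alt[i])
      add_candidate(vkey, ret$variants$gene[i], moi, dn,
                    classify_hit(ret, i, moi, dn))
    }
  }
  ch <- filters$compound_het$pairs
  for (r in seq_len(nrow(ch))) {
    i <- match(ch$key1[r], vapply(seq_len(n_variants(vs)), key_of, ""))
    add_candidate(paste(ch$key1[r], ch$key2[r], sep = "|"), ch$gene[r],
                  "recessive_compound_het", "undetermined",
                  classify_hit(vs, i, "recessive_compound_het",
                               "undetermined"))
  }
  candidates <- if (length(candidates)) do.call(rbind, candidates)
                else data.frame(key = character(0), gene = character(0),
                                moi = character(0), de_novo = character(0),
                                classification = character(0))

  # stage 3: structural fallback
  cnv <- NULL; origin <- NULL
  want_cnv <- if (is.null(cfg$run_cnv)) nrow(candidates) == 0 else cfg$run_cnv
  if (want_cnv && !is.null(coverage)) {
    sex <- ped$sex[ped$id == cases[1]]
    model <- ploidy_model(if (sex == "male") "male" else "female")
    cnv <- genome_scan(coverage, model, delta = cfg$delta,
                       min_windows = cfg$min_windows)
    events <- cnv$calls[cnv$calls$call %in%
                        c("trisomy", "monosomy", "partial_monosomy",
                          "partial_gain"), , drop = FALSE]
    if (nrow(events) && design == "trio") {
      p <- parents[[cases[1]]]
      ev_chrom <- events$chrom[1]
      idx <- vs$variants$chrom == ev_chrom
      if (any(idx)) {
        sites <- classify_informative_sites(vs[which(idx), ], cases[1],
                                            p[["sire"]], p[["dam"]])
        origin <- infer_extra_copy_origin(sites, cfg$mosaic)
      }
    }
  }

  aneuploidy_found <- !is.null(cnv) &&
    any(cnv$calls$call %in% c("trisomy", "monosomy", "partial_monosomy",
                              "partial_gain"))
  cls <- candidates$classification
  outcome <- if (any(cls == "pathogenic") || aneuploidy_found) {
    "pathogenic_found"
  } else if (any(cls == "likely_pathogenic")) {
    "likely_pathogenic_found"
  } else if (nrow(candidates)) "uncertain_only" else "unsolved"

  structure(list(cases = cases, design = design, kinship = kin,
                 filters = filters, candidates = candidates, cnv = cnv,
                 origin = origin, outcome = outcome),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("case_report [", x$design, "] cases:",
      paste(x$cases, collapse = ", "), "\n")
  cat("  candidates:", nrow(x$candidates), " outcome:", x$outcome, "\n")
  invisible(x)
}

#' Summarise a set of case reports
#'
#' Tabulates diagnostic outcomes overall and by cohort design, counting a
#' case as solved when its report carries a pathogenic or likely-pathogenic
#' finding (aneuploidies included).
#'
#' @param reports list of `case_report` objects from [run_case()].
#' @return list with `table` (data.frame design x outcome counts),
#'   `by_design` (per-design solved rates) and `rate` (overall solved
#'   fraction of cases).
#' @export
cohort_summary <- function(reports) {
  if (!length(reports)) stop("no case reports supplied")
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(design = r$design, outcome = r$outcome,
               n_cases = length(r$cases), stringsAsFactors = FALSE)
  }))
  solved <- rows$outcome %in% c("pathogenic_found", "likely_pathogenic_found")
  by_design <- do.call(rbind, lapply(split(seq_len(nrow(rows)), rows$design),
    function(idx) {
      data.frame(design = rows$design[idx[1]],
                 solved = sum(rows$n_cases[idx][solved[idx]]),
                 total = sum(rows$n_cases[idx]),
                 rate = sum(rows$n_cases[idx][solved[idx]]) /
                        sum(rows$n_cases[idx]),
                 stringsAsFactors = FALSE)
    }))
  rownames(by_design) <- NULL
  list(table = rows, by_design = by_design,
       rate = sum(rows$n_cases[solved]) / sum(rows$n_cases))
}
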