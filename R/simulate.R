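#' Toy genome model
#'
#' Three autosomes plus X and Y, small enough for desk-scale simulation but
#' large enough that window-based scans have hundreds of windows per
#' chromosome.
#'
#' @return data.frame with columns `chrom`, `length` (bp), `class`
#'   (`autosome`/`X`/`Y`).
#' @export
toy_genome <- function() {
  data.frame(chrom = c("1", "2", "3", "X", "Y"),
             length = c(25e6, 20e6, 15e6, 20e6, 5e6),
             class = c("autosome", "autosome", "autosome", "X", "Y"),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a control cohort of
#' unrelated diploid genomes with site-specific allele frequencies under
#' Hardy-Weinberg, family designs (trio, single-parent, paternal half-sibs,
#' multiple or single cases), planted causal variants per mode-of-inheritance
#' scenario, per-sample allele depths at short-read coverage, and per-window
#' read counts with optional ploidy events.
#'
#' @param seed integer RNG seed; a fixed seed reproduces every output.
#' @param n_controls number of control genomes (default 200).
#' @param n_background_variants background (non-causal) sites (default 500).
#' @param af_shape Beta shape parameters of the site frequency distribution
#'   (default c(0.5, 0.5), the classic U-shape of neutral sites).
#' @param af_range truncation range for frequencies (default c(0.01, 0.99)).
#' @param mean_depth mean sequencing depth per diploid sample (default 20).
#' @param read_length read length in bp used to convert depth into window
#'   read counts (default 150).
#' @param error_rate per-read miscall probability (default 0.005, shared
#'   with [mosaic_config()]).
#' @param genome genome model data.frame (default [toy_genome()]).
#' @param scenario planted-event scenario: `"none"`, `"de_novo_dominant"`,
#'   `"recessive_hom"`, `"compound_het"`, `"x_linked_de_novo"`,
#'   `"mosaic_sire"`, `"trisomy"`, `"terminal_monosomy"`.
#' @param design family design (default chosen to suit the scenario).
#' @param case_sex sex of the case(s) (default `"female"`).
#' @param mosaic_fraction semen alt-allele fraction of a mosaic sire (0.1).
#' @param event_chrom chromosome carrying a planted ploidy event (default
#'   first autosome).
#' @param terminal_loss_mb length of a planted terminal monosomy in Mb (2.7).
#' @param window_size coverage window width in bp (default 10000).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_controls = 200,
                       n_background_variants = 500,
                       af_shape = c(0.5, 0.5), af_range = c(0.01, 0.99),
                       mean_depth = 20, read_length = 150,
                       error_rate = 0.005, genome = toy_genome(),
                       scenario = c("none", "de_novo_dominant",
                                    "recessive_hom", "compound_het",
                                    "x_linked_de_novo", "mosaic_sire",
                                    "trisomy", "terminal_monosomy"),
                       design = NULL, case_sex = "female",
                       mosaic_fraction = 0.1, event_chrom = NULL,
                       terminal_loss_mb = 2.7, window_size = 10000) {
  scenario <- match.arg(scenario)
  if (is.null(design)) {
    design <- switch(scenario,
                     mosaic_sire = "half_sibs",
                     none = "trio",
                     "trio")
  }
  if (scenario %in% c("de_novo_dominant", "x_linked_de_novo") &&
      design != "trio") {
    stop("scenario ", scenario, " requires a trio design")
  }
  if (scenario == "mosaic_sire" && design != "half_sibs") {
    stop("mosaic_sire scenario requires the paternal half-sib design")
  }
  if (is.null(event_chrom)) {
    event_chrom <- genome$chrom[genome$class == "autosome"][1]
  }
  structure(list(seed = seed, n_controls = n_controls,
                 n_background_variants = n_background_variants,
                 af_shape = af_shape, af_range = af_range,
                 mean_depth = mean_depth, read_length = read_length,
                 error_rate = error_rate, genome = genome,
                 scenario = scenario, design = design, case_sex = case_sex,
                 mosaic_fraction = mosaic_fraction,
                 event_chrom = event_chrom,
                 terminal_loss_mb = terminal_loss_mb,
                 window_size = window_size),
            class = "sim_config")
}

draw_freqs <- function(n, config) {
  f <- stats::rbeta(n, config$af_shape[1], config$af_shape[2])
  pmin(pmax(f, config$af_range[1]), config$af_range[2])
}

#' Simulate a Hardy-Weinberg control cohort
#'
#' Draws site frequencies from the configured Beta distribution and control
#' genotypes as Binomial(2, f) per site per individual. Background sites are
#' placed at random autosomal positions.
#'
#' @param config a [sim_config()].
#' @return list with `variants` (data.frame chrom/pos/ref/alt/gene), `freqs`,
#'   and `genotypes` (sites x controls dosage matrix, samples `ctl1...`).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  simulate_cohort_impl(config)
}

simulate_cohort_impl <- function(config) {
  n <- config$n_background_variants
  autos <- config$genome[config$genome$class == "autosome", , drop = FALSE]
  chrom <- sample(autos$chrom, n, replace = TRUE,
                  prob = autos$length / sum(autos$length))
  pos <- vapply(chrom, function(ch) {
    sample.int(autos$length[autos$chrom == ch], 1)
  }, 0L)
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  freqs <- draw_freqs(n, config)
  g <- matrix(stats::rbinom(n * config$n_controls, 2, rep(freqs,
                            config$n_controls)),
              nrow = n,
              dimnames = list(NULL, paste0("ctl", seq_len(config$n_controls))))
  list(variants = data.frame(chrom = chrom, pos = as.integer(pos),
                             ref = ref, alt = alt, gene = NA_character_,
                             stringsAsFactors = FALSE),
       freqs = freqs, genotypes = g)
}

transmit <- function(parent_dosage) {
  # one gamete per site from a diploid parent
  stats::rbinom(length(parent_dosage), 1, parent_dosage / 2)
}

#' Simulate a family with an optionally planted causal variant
#'
#' Parental genotypes are drawn from the cohort site frequencies and
#' offspring genotypes follow Mendelian transmission. The planted scenario
#' variant is appended as an extra site configured per the hypothesised mode
#' of inheritance: de novo dominant (absent in parents, heterozygous in the
#' case), recessive (parents het, case homozygous), compound het (two
#' alleles of one gene, one inherited from each parent; controls may carry
#' either allele singly but never both), X-linked de novo (female case
#' heterozygous on X), mosaic sire (sire called homozygous reference, all
#' affected half-sibs heterozygous; semen alt fraction = `mosaic_fraction`).
#'
#' @param config a [sim_config()].
#' @param cohort optional precomputed [simulate_cohort()] result (it is
#'   regenerated from the seed when omitted).
#' @return list with `pedigree`, `variants`, `dosage` (sites x all samples),
#'   `freqs` and `truth` (a `scenario_truth` list).
#' @export
simulate_family <- function(config, cohort = NULL) {
  set.seed(config$seed)
  if (is.null(cohort)) cohort <- simulate_cohort_impl(config)
  simulate_family_impl(config, cohort)
}

simulate_family_impl <- function(config, cohort) {
  design <- config$design
  scen <- config$scenario
  n_cases <- if (design %in% c("half_sibs", "multiple_cases")) 2L else 1L
  cases <- paste0("case", seq_len(n_cases))
  ped_rows <- list()
  fam <- list()  # sample -> dosage vector (background sites)
  freqs <- cohort$freqs
  n_bg <- length(freqs)
  draw_parent <- function() stats::rbinom(n_bg, 2, freqs)

  add <- function(id, sire = NA, dam = NA, sex, affected,
                  tissue = "unknown") {
    ped_rows[[length(ped_rows) + 1L]] <<- data.frame(
      family = "F1", id = id, sire = sire, dam = dam, sex = sex,
      affected = affected, tissue = tissue, stringsAsFactors = FALSE)
  }

  if (design == "trio") {
    fam$sire1 <- draw_parent(); fam$dam1 <- draw_parent()
    fam$case1 <- transmit(fam$sire1) + transmit(fam$dam1)
    add("sire1", sex = "male", affected = FALSE, tissue = "blood")
    add("dam1", sex = "female", affected = FALSE, tissue = "blood")
    add("case1", "sire1", "dam1", sex = config$case_sex, affected = TRUE,
        tissue = "ear")
  } else if (design == "single_parent") {
    fam$sire1 <- draw_parent()
    dam_latent <- draw_parent()
    fam$case1 <- transmit(fam$sire1) + transmit(dam_latent)
    add("sire1", sex = "male", affected = FALSE, tissue = "blood")
    add("case1", "sire1", NA, sex = config$case_sex, affected = TRUE,
        tissue = "ear")
  } else if (design == "half_sibs") {
    fam$sire1 <- draw_parent()
    for (cs in cases) {
      dam_latent <- draw_parent()
      fam[[cs]] <- transmit(fam$sire1) + transmit(dam_latent)
      add(cs, "sire1", NA, sex = config$case_sex, affected = TRUE,
          tissue = "ear")
    }
    add("sire1", sex = "male", affected = FALSE, tissue = "blood")
  } else if (design == "multiple_cases") {
    for (cs in cases) {
      fam[[cs]] <- stats::rbinom(n_bg, 2, freqs)
      add(cs, sex = config$case_sex, affected = TRUE, tissue = "ear")
    }
  } else {  # single_case
    fam$case1 <- stats::rbinom(n_bg, 2, freqs)
    add("case1", sex = config$case_sex, affected = TRUE, tissue = "ear")
  }

  variants <- cohort$variants
  ctl <- cohort$genotypes
  truth <- list(scenario = scen, planted = NULL, moi = NULL,
                mosaic_fraction = NULL)

  plant_site <- function(chrom, pos, gene) {
    data.frame(chrom = chrom, pos = as.integer(pos), ref = "G", alt = "A",
               gene = gene, stringsAsFactors = FALSE)
  }
  append_site <- function(site, fam_dosage, ctl_dosage, freq) {
    variants <<- rbind(variants, site)
    for (id in names(fam)) {
      fam[[id]] <<- c(fam[[id]], fam_dosage[[id]])
    }
    ctl <<- rbind(ctl, ctl_dosage)
    freqs <<- c(freqs, freq)
  }
  zero_ctl <- function() rep(0L, ncol(ctl))
  auto1 <- config$genome$chrom[config$genome$class == "autosome"][1]

  if (scen == "de_novo_dominant") {
    site <- plant_site(auto1, 1e6, "GENE_DNV")
    fd <- stats::setNames(as.list(rep(0L, length(fam))), names(fam))
    for (cs in cases) fd[[cs]] <- 1L
    append_site(site, fd, zero_ctl(), 0)
    truth$planted <- paste0(auto1, ":1000000G>A")
    truth$moi <- "de_novo_dominant"
  } else if (scen == "recessive_hom") {
    site <- plant_site(auto1, 2e6, "GENE_AR")
    fd <- list()
    for (id in names(fam)) {
      fd[[id]] <- if (id %in% cases) 2L
                  else if (grepl("^(sire|dam)", id)) 1L else 0L
    }
    append_site(site, fd, zero_ctl(), 0)
    truth$planted <- paste0(auto1, ":2000000G>A")
    truth$moi <- "recessive_hom"
  } else if (scen == "compound_het") {
    # two alleles of one gene; a few controls carry each singly, never both
    n_ctl <- ncol(ctl)
    c1 <- zero_ctl(); c2 <- zero_ctl()
    k <- min(5L, n_ctl %/% 4L)
    if (k > 0) {
      pick <- sample.int(n_ctl, 2 * k)
      c1[pick[seq_len(k)]] <- 1L
      c2[pick[k + seq_len(k)]] <- 1L
    }
    site1 <- plant_site(auto1, 3e6, "GENE_CH")
    site2 <- plant_site(auto1, 3.001e6, "GENE_CH")
    site2$ref <- "C"; site2$alt <- "T"
    fd1 <- list(); fd2 <- list()
    for (id in names(fam)) {
      fd1[[id]] <- if (id %in% cases || grepl("^sire", id)) 1L else 0L
      fd2[[id]] <- if (id %in% cases || grepl("^dam", id)) 1L else 0L
    }
    append_site(site1, fd1, c1, k / (2 * n_ctl))
    append_site(site2, fd2, c2, k / (2 * n_ctl))
    truth$planted <- c(paste0(auto1, ":3000000G>A"),
                       paste0(auto1, ":3001000C>T"))
    truth$moi <- "recessive_compound_het"
    truth$gene <- "GENE_CH"
  } else if (scen == "x_linked_de_novo") {
    x <- config$genome$chrom[config$genome$class == "X"][1]
    site <- plant_site(x, 1e6, "GENE_XL")
    fd <- stats::setNames(as.list(rep(0L, length(fam))), names(fam))
    fd$case1 <- 1L  # heterozygous female case
    append_site(site, fd, zero_ctl(), 0)
    truth$planted <- paste0(x, ":1000000G>A")
    truth$moi <- "x_linked_de_novo"
  } else if (scen == "mosaic_sire") {
    site <- plant_site(auto1, 4e6, "GENE_MOS")
    fd <- list()
    for (id in names(fam)) fd[[id]] <- if (id %in% cases) 1L else 0L
    append_site(site, fd, zero_ctl(), 0)
    truth$planted <- paste0(auto1, ":4000000G>A")
    truth$moi <- "dominant_mosaic_sire"
    truth$mosaic_fraction <- config$mosaic_fraction
    truth$mosaic_tissue <- "semen"
  }

  ped <- as_pedigree(do.call(rbind, ped_rows))
  dosage <- cbind(do.call(cbind, fam), ctl)
  colnames(dosage) <- c(names(fam), colnames(ctl))
  list(pedigree = ped, variants = variants, dosage = dosage,
       freqs = freqs, truth = truth)
}

#' Add per-sample allele depths to simulated genotypes
#'
#' Per sample and site, total depth is Poisson(mean depth x ploidy/2) and
#' alt reads are Binomial(depth, f) with f = error rate for homozygous
#' reference, 0.5 for heterozygous, 1 - error rate for homozygous alternate
#' (and the planted mosaic fraction for a mosaic sire's germline tissue,
#' handled separately via [simulate_mosaic_tissue_depths()]).
#'
#' @param dosage sites x samples dosage matrix.
#' @param config a [sim_config()].
#' @param hemizygous optional logical matrix marking single-copy genotypes
#'   (halved depth, dosage 1 read as pure alt).
#' @return list of matrices `ref_depth` and `alt_depth`.
#' @export
simulate_allele_depths <- function(dosage, config, hemizygous = NULL) {
  n <- length(dosage)
  ploidy_half <- if (is.null(hemizygous)) 1 else ifelse(hemizygous, 0.5, 1)
  depth <- stats::rpois(n, config$mean_depth * ploidy_half)
  eps <- config$error_rate
  f <- matrix(eps, nrow(dosage), ncol(dosage))
  f[dosage == 1] <- 0.5
  f[dosage == 2] <- 1 - eps
  if (!is.null(hemizygous)) f[hemizygous & dosage == 1] <- 1 - eps
  f[is.na(dosage)] <- NA
  alt <- suppressWarnings(stats::rbinom(n, depth, as.vector(f)))
  alt_m <- matrix(alt, nrow(dosage), ncol(dosage),
                  dimnames = dimnames(dosage))
  dep_m <- matrix(depth, nrow(dosage), ncol(dosage),
                  dimnames = dimnames(dosage))
  ref_m <- dep_m - alt_m
  ref_m[is.na(alt_m)] <- NA_integer_
  list(ref_depth = ref_m, alt_depth = alt_m)
}

#' Simulate alt/total read counts for a mosaic parent's tissues
#'
#' @param config a [sim_config()]; the semen alt fraction is
#'   `mosaic_fraction`, blood carries error-rate reads only.
#' @param depth per-tissue total depth (default 40, typical of a targeted
#'   re-check).
#' @return data.frame with columns `tissue`, `alt_depth`, `total_depth`.
#' @export
simulate_mosaic_tissue_depths <- function(config, depth = 40) {
  semen_alt <- stats::rbinom(1, depth, config$mosaic_fraction)
  blood_alt <- stats::rbinom(1, depth, config$error_rate)
  data.frame(tissue = c("semen", "blood"),
             alt_depth = c(semen_alt, blood_alt),
             total_depth = c(depth, depth), stringsAsFactors = FALSE)
}

#' Simulate informative trio sites on a trisomic chromosome
#'
#' Emulates the canonical informative configurations of a whole-chromosome
#' trisomy: sites where the duplicated parent is homozygous alt and the
#' other parent homozygous ref (case carries 2 of 3 alt copies, expected
#' read fraction 2/3), and sites where the single-copy parent contributes
#' the alt (1 of 3 copies, expected fraction 1/3).
#'
#' @param n_sites number of informative sites (split evenly between the two
#'   classes).
#' @param depth mean per-site read depth (Poisson).
#' @param origin `"paternal"` or `"maternal"` extra copy.
#' @return data.frame compatible with [infer_extra_copy_origin()]: `class`,
#'   `alt_depth`, `ref_depth`, `alt_copies`.
#' @export
simulate_trisomy_sites <- function(n_sites, depth = 20,
                                   origin = c("paternal", "maternal")) {
  origin <- match.arg(origin)
  n2 <- ceiling(n_sites / 2)
  n1 <- n_sites - n2
  dup <- if (origin == "paternal") "sire_only_alt" else "dam_only_alt"
  oth <- if (origin == "paternal") "dam_only_alt" else "sire_only_alt"
  cls <- c(rep(dup, n2), rep(oth, n1))
  copies <- c(rep(2L, n2), rep(1L, n1))
  tot <- stats::rpois(n_sites, depth)
  alt <- stats::rbinom(n_sites, tot, copies / 3)
  data.frame(class = cls, alt_depth = alt, ref_depth = tot - alt,
             alt_copies = copies, stringsAsFactors = FALSE)
}

#' Simulate a genome-wide coverage-window table
#'
#' Window counts are Poisson with rate mean_depth x width / read_length x
#' ploidy/2. Ploidy follows the genome model and case sex (X and Y at one
#' copy in males, Y absent in females) and the planted event: a trisomic
#' chromosome at 3 copies, a terminal monosomy at 1 copy over the terminal
#' `terminal_loss_mb` of the event chromosome.
#'
#' @param config a [sim_config()]; `scenario` `"trisomy"` or
#'   `"terminal_monosomy"` plants the corresponding event on
#'   `config$event_chrom`.
#' @param sex sample sex for the sex-chromosome baseline (default
#'   `config$case_sex`).
#' @return list with `windows` (a `coverage_windows` table) and `truth`
#'   (event chromosome and segment).
#' @export
simulate_coverage <- function(config, sex = config$case_sex) {
  set.seed(config$seed)
  simulate_coverage_impl(config, sex)
}

simulate_coverage_impl <- function(config, sex = config$case_sex) {
  ws <- config$window_size
  rows <- list()
  truth <- list(event = config$scenario, chrom = NA, seg_start = NA,
                seg_end = NA)
  for (i in seq_len(nrow(config$genome))) {
    ch <- config$genome$chrom[i]
    len <- config$genome$length[i]
    cls <- config$genome$class[i]
    starts <- seq(1L, len, by = ws)
    width <- pmin(starts + ws - 1, len) - starts + 1
    ploidy <- rep(switch(cls,
                         autosome = 2,
                         X = if (sex == "male") 1 else 2,
                         Y = if (sex == "male") 1 else 0),
                  length(starts))
    if (config$scenario == "trisomy" && ch == config$event_chrom) {
      ploidy[] <- 3
      truth$chrom <- ch
    }
    if (config$scenario == "terminal_monosomy" &&
        ch == config$event_chrom) {
      loss_start <- len - config$terminal_loss_mb * 1e6 + 1
      hit <- starts >= loss_start
      ploidy[hit] <- 1
      truth$chrom <- ch
      truth$seg_start <- as.integer(min(starts[hit]))
      truth$seg_end <- as.integer(len)
    }
    lambda <- config$mean_depth * width / config$read_length * ploidy / 2
    rows[[i]] <- data.frame(chrom = ch, start = as.integer(starts),
                            count = stats::rpois(length(starts), lambda),
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  lens <- stats::setNames(config$genome$length, config$genome$chrom)
  w <- coverage_windows(all$chrom, all$start, all$count, ws,
                        chrom_length = lens)
  list(windows = w, truth = truth)
}

#' Simulate a complete scenario dataset
#'
#' One call produces everything a diagnostic run consumes: the control
#' cohort, the family with its planted variant, per-sample allele depths,
#' the pedigree, a coverage-window table (with the planted ploidy event when
#' the scenario is structural), and the ground-truth record for recovery
#' scoring. Byte-identical under a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with `variants` (a [variant_set()]
#'   over cases, parents and controls), `pedigree`, `coverage`, `truth` and
#'   `freqs`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  cohort <- simulate_cohort_impl(config)
  fam <- simulate_family_impl(config, cohort)
  x_chrom <- config$genome$chrom[config$genome$class == "X"]
  hemi <- matrix(FALSE, nrow(fam$variants), ncol(fam$dosage),
                 dimnames = list(NULL, colnames(fam$dosage)))
  males <- fam$pedigree$id[fam$pedigree$sex == "male"]
  on_x <- fam$variants$chrom %in% x_chrom
  for (s in intersect(males, colnames(hemi))) hemi[on_x, s] <- TRUE
  depths <- simulate_allele_depths(fam$dosage, config, hemizygous = hemi)
  truth_origin <- NULL
  if (config$scenario == "trisomy" && all(c("sire1", "dam1", "case1") %in%
                                          colnames(fam$dosage))) {
    # paternal extra copy as a duplicated paternal gamete: the case carries
    # two identical paternal copies plus one maternal copy on the event
    # chromosome, so alt fractions sit at 2/3 (paternal alt) or 1/3
    # (maternal alt) — the canonical informative-site configuration
    ev <- which(fam$variants$chrom == config$event_chrom)
    if (length(ev)) {
      pg <- transmit(fam$dosage[ev, "sire1"])
      mg <- transmit(fam$dosage[ev, "dam1"])
      copies <- 2L * pg + mg
      fam$dosage[ev, "case1"] <- ifelse(copies == 0L, 0L,
                                        ifelse(copies == 3L, 2L, 1L))
      dep <- stats::rpois(length(ev), config$mean_depth * 1.5)
      f <- pmin(pmax(copies / 3, config$error_rate), 1 - config$error_rate)
      alt <- stats::rbinom(length(ev), dep, f)
      depths$alt_depth[ev, "case1"] <- alt
      depths$ref_depth[ev, "case1"] <- dep - alt
      truth_origin <- "paternal"
    }
  }
  # a mosaic sire is *called* homozygous reference in blood; his genotype
  # matrix entry stays 0 and the planted site carries error-level alt reads
  ann <- vector("list", nrow(fam$variants))
  if (!is.null(fam$truth$planted)) {
    keys <- paste0(fam$variants$chrom, ":", fam$variants$pos,
                   fam$variants$ref, ">", fam$variants$alt)
    conseq <- if (config$scenario == "compound_het") "missense"
              else "truncating"
    for (k in fam$truth$planted) {
      i <- match(k, keys)
      ann[[i]] <- c(consequence = conseq,
                    SIFT = "deleterious", PolyPhen2 = "deleterious")
    }
  }
  vs <- variant_set(fam$variants, fam$dosage,
                    ref_depth = depths$ref_depth,
                    alt_depth = depths$alt_depth,
                    hemizygous = hemi, annotations = ann)
  vs <- sort_variants(vs)
  cov <- simulate_coverage_impl(config, sex = config$case_sex)
  truth <- fam$truth
  truth$coverage_event <- cov$truth
  if (!is.null(truth_origin)) truth$origin <- truth_origin
  structure(list(variants = vs, pedigree = fam$pedigree,
                 coverage = cov$windows, truth = truth,
                 freqs = fam$freqs[order(fam$variants$chrom,
                                         fam$variants$pos,
                                         fam$variants$alt)]),
            class = "sim_dataset")
}
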