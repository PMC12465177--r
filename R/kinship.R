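#' Opposing-homozygote rate between two samples
#'
#' The fraction of comparable sites (both samples called) at which one sample
#' is homozygous reference and the other homozygous alternate. True
#' parent-offspring pairs show a rate near zero (genotyping error only);
#' unrelated pairs at allele frequency p show an expected rate of
#' `2 p^2 (1-p)^2`.
#'
#' @param g1,g2 integer dosage vectors (0/1/2, `NA` missing) over the same
#'   sites.
#' @param min_sites minimum comparable sites (default 500).
#' @return list with `rate`, `n_opposing`, `n_comparable`.
#' @export
opposing_homozygote_rate <- function(g1, g2, min_sites = 500) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n < min_sites) {
    stop("only ", n, " comparable sites; need >= ", min_sites)
  }
  opp <- sum((g1[ok] == 0 & g2[ok] == 2) | (g1[ok] == 2 & g2[ok] == 0))
  list(rate = opp / n, n_opposing = opp, n_comparable = n)
}

#' Method-of-moments identity-by-descent estimation for a sample pair
#'
#' Follows the classic PLINK `--genome` formulation: observed
#' identity-by-state (IBS) counts are equated with their expectations given
#' the cohort allele frequencies under each IBD state, solving sequentially
#' for P(IBD=0), P(IBD=1), P(IBD=2); the proportions are truncated to
#' \[0, 1\] and renormalized, and `pi_hat = P(IBD=1)/2 + P(IBD=2)`.
#' Sites with allele frequency outside `freq_window` are excluded.
#'
#' The pair verdict is `parent_offspring_consistent` when `pi_hat` falls in
#' `pihat_band`, P(IBD=0) is below `max_p0` and the opposing-homozygote rate
#' does not exceed `max_opposing` (a ~20x short-read error allowance);
#' `excluded` when opposing homozygotes exceed the allowance;
#' `unrelated_like` when `pi_hat` is near zero; otherwise `ambiguous`.
#'
#' @param g1,g2 dosage vectors over the same sites.
#' @param freqs alt-allele frequencies per site (from the control cohort).
#' @param freq_window usable frequency range (default c(0.05, 0.95)).
#' @param pihat_band parent-offspring acceptance band (default c(0.4, 0.6)).
#' @param max_p0 ceiling on P(IBD=0) for a parent-offspring call (0.05).
#' @param max_opposing opposing-homozygote error allowance (0.001).
#' @param min_sites minimum usable sites (default 500).
#' @return list of class `pair_relatedness`: `p_ibd` (length-3), `pi_hat`,
#'   `opposing` (rate/counts), `n_sites`, `verdict`.
#' @export
moment_ibd <- function(g1, g2, freqs, freq_window = c(0.05, 0.95),
                       pihat_band = c(0.4, 0.6), max_p0 = 0.05,
                       max_opposing = 0.001, min_sites = 500) {
  stopifnot(length(g1) == length(g2), length(freqs) == length(g1))
  use <- !is.na(g1) & !is.na(g2) &
    freqs >= freq_window[1] & freqs <= freq_window[2]
  if (!any(use)) stop("no usable polymorphic sites in the frequency window")
  g1 <- g1[use]; g2 <- g2[use]; p <- freqs[use]
  n <- length(p)
  if (n < min_sites) stop("only ", n, " usable sites; need >= ", min_sites)
  q <- 1 - p
  ibs <- 2L - abs(g1 - g2)
  ibs[(g1 == 1 & g2 == 1)] <- 2L   # het/het shares both alleles
  ibs[(g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0)] <- 0L
  n_ibs <- tabulate(ibs + 1L, nbins = 3L)  # counts of IBS 0,1,2
  # expected per-site IBS probabilities given IBD state, summed over sites
  e0_ibs0 <- sum(2 * p^2 * q^2)
  e0_ibs1 <- sum(4 * p^3 * q + 4 * p * q^3)
  e0_ibs2 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibs1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e1_ibs2 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  p0 <- n_ibs[1] / e0_ibs0
  p1 <- (n_ibs[2] - p0 * e0_ibs1) / e1_ibs1
  p2 <- (n_ibs[3] - p0 * e0_ibs2 - p1 * e1_ibs2) / n
  pr <- pmin(pmax(c(p0, p1, p2), 0), 1)
  pr <- pr / sum(pr)
  pi_hat <- pr[2] / 2 + pr[3]
  opp <- list(rate = n_ibs[1] / n, n_opposing = n_ibs[1], n_comparable = n)
  verdict <- if (pi_hat >= pihat_band[1] && pi_hat <= pihat_band[2] &&
                 pr[1] < max_p0 && opp$rate <= max_opposing) {
    "parent_offspring_consistent"
  } else if (pi_hat < 0.1) {
    "unrelated_like"
  } else if (opp$rate > max_opposing) {
    "excluded"   # relatedness present, but opposing homozygotes rule out
                 # a direct parent-offspring relation
  } else {
    "ambiguous"
  }
  structure(list(p_ibd = pr, pi_hat = pi_hat, opposing = opp,
                 n_sites = n, verdict = verdict),
            class = "pair_relatedness")
}

#' Verify every recorded parent-offspring link of a pedigree
#'
#' Runs [moment_ibd()] on each recorded sire/dam link with genotypes
#' available, reporting the verdict and evidence per link.
#'
#' @param ped a `pedigree` (see [read_ped()]).
#' @param genotypes dosage matrix, sites x samples (column names = ids).
#' @param freqs alt-allele frequencies per site.
#' @param ... passed to [moment_ibd()].
#' @return data.frame with columns `offspring`, `parent`, `relation`,
#'   `pi_hat`, `p_ibd0`, `opposing_rate`, `verdict` (links lacking genotypes
#'   get verdict `"no_data"`).
#' @export
verify_pedigree <- function(ped, genotypes, freqs, ...) {
  links <- list()
  for (i in seq_len(nrow(ped))) {
    for (rel in c("sire", "dam")) {
      par <- ped[[rel]][i]
      if (is.na(par)) next
      off <- ped$id[i]
      if (!(off %in% colnames(genotypes)) ||
          !(par %in% colnames(genotypes))) {
        links[[length(links) + 1L]] <- data.frame(
          offspring = off, parent = par, relation = rel,
          pi_hat = NA_real_, p_ibd0 = NA_real_, opposing_rate = NA_real_,
          verdict = "no_data", stringsAsFactors = FALSE)
        next
      }
      r <- moment_ibd(genotypes[, off], genotypes[, par], freqs, ...)
      links[[length(links) + 1L]] <- data.frame(
        offspring = off, parent = par, relation = rel,
        pi_hat = r$pi_hat, p_ibd0 = r$p_ibd[1],
        opposing_rate = r$opposing$rate, verdict = r$verdict,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(links)) {
    return(data.frame(offspring = character(0), parent = character(0),
                      relation = character(0), pi_hat = numeric(0),
                      p_ibd0 = numeric(0), opposing_rate = numeric(0),
                      verdict = character(0)))
  }
  out <- do.call(rbind, links)
  rownames(out) <- NULL
  out
}
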