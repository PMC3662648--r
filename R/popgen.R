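# Validation-panel population statistics: observed/expected heterozygosity,
# the conditional exact Hardy-Weinberg test, a permutation test of linkage
# disequilibrium, Holm (sequential Bonferroni) correction, and the
# small-pool apparent-fixation probability.

#' Observed and expected heterozygosity at one biallelic locus
#'
#' Ho is the heterozygote fraction among genotyped individuals; He is 2pq
#' with p the sample allele frequency (no small-sample correction).
#'
#' @param genotypes character vector in c("AA","Aa","aa", NA); "aA" is
#'   accepted as heterozygous, NA/"missing" entries are dropped
#' @return list(Ho, He, n, p) with n the genotyped count and p the "A"
#'   frequency
#' @export
locus_heterozygosity <- function(genotypes) {
  g <- genotypes[!is.na(genotypes) & genotypes != "missing"]
  if (length(g) == 0) stopf("no non-missing genotypes")
  if (!all(g %in% c("AA", "Aa", "aA", "aa")))
    stopf("genotypes must be AA/Aa/aa")
  n <- length(g)
  n_het <- sum(g %in% c("Aa", "aA"))
  n_AA <- sum(g == "AA")
  p <- (2 * n_AA + n_het) / (2 * n)
  list(Ho = n_het / n, He = 2 * p * (1 - p), n = n, p = p)
}

# conditional probability of h heterozygotes given n individuals and nA
# copies of allele A:  P(h) = [n! / (nAA! h! naa!)] 2^h / choose(2n, nA)
hwe_het_logprob <- function(h, n, nA) {
  nAA <- (nA - h) / 2
  naa <- n - nAA - h
  lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1) +
    h * log(2) - lchoose(2 * n, nA)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional on the observed allele counts, enumerates all possible
#' heterozygote counts and sums the probabilities of configurations no more
#' probable than the observed one (two-sided, probability ordering). A
#' monomorphic sample returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1)
#' @return exact p-value in (0,1\]
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stopf("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stopf("need at least one genotyped individual")
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  hs <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2L)
  lp <- hwe_het_logprob(hs, n, nA)
  p_obs <- hwe_het_logprob(n_Aa, n, nA)
  min(1, sum(exp(lp[lp <= p_obs + 1e-9])))
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Uses the log-likelihood-ratio statistic G on the genotype-pair
#' contingency table; the null distribution is generated by permuting one
#' locus's genotypes across individuals.
#'
#' @param g1,g2 genotype vectors (equal length; pairs with missing entries
#'   dropped)
#' @param n_permutations number of permutations
#' @param seed integer seed
#' @return list(p, G, testable); `testable` FALSE (p = NA) when either
#'   locus is monomorphic after filtering
#' @export
ld_permutation_test <- function(g1, g2, n_permutations = 10000L, seed = 1L) {
  keep <- !is.na(g1) & !is.na(g2) & g1 != "missing" & g2 != "missing"
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
    return(list(p = NA_real_, G = NA_real_, testable = FALSE))
  g_stat <- function(a, b) {
    tab <- table(a, b)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    idx <- tab > 0
    2 * sum(tab[idx] * log(tab[idx] / e[idx]))
  }
  g_obs <- g_stat(g1, g2)
  set.seed(derive_seed(seed, 601L))
  exceed <- 0L
  for (i in seq_len(n_permutations)) {
    if (g_stat(g1, sample(g2)) >= g_obs - 1e-12) exceed <- exceed + 1L
  }
  list(p = (exceed + 1) / (n_permutations + 1), G = g_obs, testable = TRUE)
}

#' Holm (sequential Bonferroni) correction
#'
#' Step-down procedure: sort p-values ascending and reject while
#' p_(i) <= alpha / (m - i + 1), stopping at the first failure.
#'
#' @param p_values numeric vector of p-values in \[0,1\]
#' @param alpha family-wise error level
#' @return logical vector of rejection decisions in the input order
#' @export
holm_correction <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must be in [0,1]")
  stats::p.adjust(p_values, method = "holm") <= alpha
}

#' Probability a small pool sample looks fixed
#'
#' For a site with population minor-allele frequency q sampled as n diploid
#' individuals (2n chromosomes), the probability the sample carries only
#' one allele is (1-q)^(2n) + q^(2n). This is the ascertainment bias that
#' inflates apparent fixation in small pools.
#'
#' @param q population allele frequency in \[0,1\]
#' @param n diploid individuals per pool
#' @return probability in \[0,1\]
#' @export
apparent_fixation_probability <- function(q, n) {
  if (any(q < 0 | q > 1)) stopf("q must be in [0,1]")
  if (n < 1) stopf("n must be >= 1")
  (1 - q)^(2 * n) + q^(2 * n)
}

#' Simulated apparent-fixation rate, optionally through the caller's eyes
#'
#' Draws `n_sites` independent sites at population frequency q in a pool of
#' n diploids. With `depth = Inf` a site appears fixed exactly when its 2n
#' chromosomes carry one allele (the closed form's experiment). With finite
#' depth, reads are drawn Binomial(Poisson(depth), sample frequency) and a
#' site additionally appears fixed when the minor allele fails the calling
#' thresholds (reads per allele, variant frequency); sites below
#' `min_coverage` are excluded, mirroring the pipeline's detection bar.
#'
#' @param q population allele frequency
#' @param n diploid individuals per pool
#' @param n_sites simulated sites
#' @param depth mean read depth, or Inf for chromosome sampling only
#' @param policy a `calling_policy` supplying the detection thresholds
#' @param seed integer seed
#' @return list(rate, n_eval, se): apparent-fixation rate, sites evaluated,
#'   Monte-Carlo standard error
#' @export
simulate_apparent_fixation <- function(q, n, n_sites = 10000L, depth = Inf,
                                       policy = calling_policy(), seed = 1L) {
  set.seed(derive_seed(seed, 701L))
  k <- stats::rbinom(n_sites, 2L * n, q)  # minor-allele chromosomes
  if (!is.finite(depth)) {
    fixed <- k == 0L | k == 2L * n
    rate <- mean(fixed)
    return(list(rate = rate, n_eval = n_sites,
                se = sqrt(rate * (1 - rate) / n_sites)))
  }
  d <- stats::rpois(n_sites, depth)
  ok <- d >= policy$min_coverage
  alt <- stats::rbinom(n_sites, d, k / (2 * n))
  minor <- pmin(alt, d - alt)
  called_poly <- minor >= policy$min_reads_per_allele &
    minor / pmax(d, 1L) >= policy$min_variant_freq
  fixed <- !called_poly
  rate <- mean(fixed[ok])
  list(rate = rate, n_eval = sum(ok),
       se = sqrt(rate * (1 - rate) / max(1L, sum(ok))))
}

#' Per-locus, per-group panel statistics
#'
#' Computes Ho, He, allele frequency, and the exact Hardy-Weinberg p-value
#' for every locus within every group of a genotype panel, then applies the
#' Holm correction across the testable HWE p-values.
#'
#' @param panel data.table with columns locus, group, genotype (as written
#'   by [simulate_validation_panel()] or read from TSV)
#' @param alpha family-wise error level for the Holm correction
#' @return data.table: locus, group, n, p, Ho, He, hwe_p, hwe_reject
#' @export
panel_statistics <- function(panel, alpha = 0.05) {
  stopifnot(all(c("locus", "group", "genotype") %in% names(panel)))
  stats_dt <- as.data.table(panel)[, {
    h <- locus_heterozygosity(genotype)
    n_AA <- sum(genotype == "AA")
    n_Aa <- sum(genotype %in% c("Aa", "aA"))
    n_aa <- sum(genotype == "aa")
    list(n = h$n, p = h$p, Ho = h$Ho, He = h$He,
         hwe_p = hwe_exact_test(n_AA, n_Aa, n_aa),
         monomorphic = h$He == 0)
  }, by = .(locus, group)]
  testable <- !stats_dt$monomorphic
  stats_dt[, hwe_reject := FALSE]
  if (any(testable))
    stats_dt[testable, hwe_reject := holm_correction(hwe_p, alpha)]
  stats_dt[]
}

#' Write a genotype panel / panel statistics as TSV
#' @param x data.table (panel or statistics)
#' @param path output TSV
#' @export
write_panel_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Read a genotype panel from TSV
#' @param path TSV with columns locus, individual, group (or site +
#'   elevation), genotype
#' @return data.table
#' @export
read_panel_tsv <- function(path) {
  dt <- fread(path, sep = "\t")
  if (!"group" %in% names(dt) && all(c("site", "elevation") %in% names(dt)))
    dt[, group := paste(site, elevation, sep = "_")]
  dt[]
}
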