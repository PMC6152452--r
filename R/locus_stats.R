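# Extract the two allele columns of locus `l` (index or name) from an
# mlg_matrix, dropping individuals missing at that locus.
locus_alleles <- function(g, l, loci = NULL) {
  if (is.character(l)) {
    locus_names <- sub("\\.1$", "", colnames(g)[seq(1, ncol(g), 2)])
    l <- match(l, locus_names)
    if (is.na(l)) stop("unknown locus")
  }
  a <- g[, 2 * l - 1]
  b <- g[, 2 * l]
  keep <- !is.na(a)
  cbind(a = a[keep], b = b[keep])
}

#' Observed allele frequencies at a locus
#'
#' @param g An [mlg_matrix()] of genotypes.
#' @param locus Locus index or name.
#' @return A list with `freq` (named frequency vector over observed
#'   alleles), `n` (gene copies) and `n_ind` (individuals scored).
#' @export
allele_frequencies <- function(g, locus) {
  ab <- locus_alleles(g, locus)
  if (!nrow(ab)) stop("all genotypes missing at this locus")
  tab <- table(c(ab[, 1], ab[, 2]))
  freq <- as.vector(tab) / sum(tab)
  names(freq) <- names(tab)
  list(freq = freq, n = as.integer(sum(tab)), n_ind = nrow(ab))
}

#' Observed and unbiased expected heterozygosity
#'
#' `h_obs` is the fraction of scored individuals that are heterozygous;
#' `h_exp` is unbiased gene diversity, `(2n / (2n - 1)) * (1 - sum(p^2))`
#' with `n` the number of individuals scored (the small-sample correction
#' used by the classic population-genetics packages). The biased form
#' `1 - sum(p^2)` is returned alongside for comparison.
#'
#' @param g An [mlg_matrix()].
#' @param locus Locus index or name.
#' @return A list `h_obs`, `h_exp`, `h_exp_biased`, `n_ind`.
#' @export
heterozygosities <- function(g, locus) {
  ab <- locus_alleles(g, locus)
  n <- nrow(ab)
  if (n < 2) stop("need at least 2 scored individuals")
  af <- allele_frequencies(g, locus)
  gd <- 1 - sum(af$freq^2)
  list(h_obs = mean(ab[, 1] != ab[, 2]),
       h_exp = 2 * n / (2 * n - 1) * gd,
       h_exp_biased = gd,
       n_ind = n)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' The test statistic is the Pearson chi-square of the observed genotype
#' counts against their Hardy-Weinberg expectations at the observed allele
#' frequencies. Its null distribution is generated by randomly re-pairing
#' the observed gene copies `n_permutations` times;
#' `p = (1 + #(null >= observed)) / (n_permutations + 1)`. Asymptotic
#' chi-square theory is invalid for 7-10 alleles at ~40 individuals, hence
#' the Monte-Carlo approach.
#'
#' @param g An [mlg_matrix()].
#' @param locus Locus index or name.
#' @param n_permutations Number of random re-pairings.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @return A list `p_value`, `statistic`, `testable`, `method`,
#'   `n_permutations`. Monomorphic loci return `testable = FALSE` with an
#'   `NA` p-value.
#' @export
hwe_test <- function(g, locus, n_permutations = 10000L, seed = NULL) {
  run <- function() {
    ab <- locus_alleles(g, locus)
    n <- nrow(ab)
    alleles <- sort(unique(c(ab[, 1], ab[, 2])))
    k <- length(alleles)
    if (k < 2)
      return(list(p_value = NA_real_, statistic = NA_real_,
                  testable = FALSE, method = "monte_carlo_exact",
                  n_permutations = 0L))
    copies <- c(match(ab[, 1], alleles), match(ab[, 2], alleles))
    p <- tabulate(copies, k) / (2 * n)
    E <- n * (2 * outer(p, p))
    diag(E) <- n * p^2
    ut <- upper.tri(E, diag = TRUE)
    Ev <- E[ut]
    code_of <- function(a, b) {
      i <- pmin(a, b)
      j <- pmax(a, b)
      (i - 1L) * k + j
    }
    ij <- which(ut, arr.ind = TRUE)
    codes_ut <- (ij[, 1] - 1L) * k + ij[, 2]  # codes aligned with Ev order
    stat <- function(a, b) {
      O <- tabulate(code_of(a, b), k * k)[codes_ut]
      sum((O - Ev)^2 / Ev)
    }
    obs <- stat(match(ab[, 1], alleles), match(ab[, 2], alleles))
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- sample(copies)
      s <- stat(perm[seq_len(n)], perm[n + seq_len(n)])
      if (s >= obs - 1e-12) ge <- ge + 1L
    }
    list(p_value = (1 + ge) / (n_permutations + 1), statistic = obs,
         testable = TRUE, method = "monte_carlo_exact",
         n_permutations = as.integer(n_permutations))
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Chakraborty-type null-allele frequency estimate
#'
#' `r = (H_E - H_O) / (H_E + H_O)`: the null-allele frequency consistent
#' with the observed homozygote excess under Hardy-Weinberg proportions.
#' May be negative under heterozygote excess. Vectorised.
#'
#' @param h_obs,h_exp Observed and expected heterozygosity.
#' @return The estimate; `NA` where `h_obs + h_exp == 0` (not testable).
#' @export
null_allele_chakraborty <- function(h_obs, h_exp) {
  ifelse(h_obs + h_exp == 0, NA_real_, (h_exp - h_obs) / (h_exp + h_obs))
}

#' Monte-Carlo test for homozygote excess (null-allele signal)
#'
#' One-sided test: draws `n_sim` Hardy-Weinberg genotype samples at the
#' observed allele frequencies and compares their homozygote counts with
#' the observed count. Small p indicates more homozygotes than HWE predicts,
#' the classic null-allele footprint.
#'
#' @param g An [mlg_matrix()].
#' @param locus Locus index or name.
#' @param n_sim Number of simulated samples.
#' @param seed Optional seed.
#' @return A list `p_value`, `n_hom_obs`, `n_ind`.
#' @export
null_allele_test <- function(g, locus, n_sim = 2000L, seed = NULL) {
  run <- function() {
    ab <- locus_alleles(g, locus)
    n <- nrow(ab)
    af <- allele_frequencies(g, locus)
    obs_hom <- sum(ab[, 1] == ab[, 2])
    k <- length(af$freq)
    if (k < 2) return(list(p_value = NA_real_, n_hom_obs = obs_hom, n_ind = n))
    sims <- vapply(seq_len(n_sim), function(i) {
      a <- sample.int(k, n, replace = TRUE, prob = af$freq)
      b <- sample.int(k, n, replace = TRUE, prob = af$freq)
      sum(a == b)
    }, numeric(1))
    list(p_value = (1 + sum(sims >= obs_hom)) / (n_sim + 1),
         n_hom_obs = obs_hom, n_ind = n)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Weir-Cockerham inbreeding coefficient F_IS
#'
#' Single-population variance components per allele and locus:
#' `b = n/(n-1) * (p(1-p) - (2n-1)/(4n) * hbar)` (among individuals) and
#' `c = hbar/2` (within individuals), with `hbar` the observed frequency of
#' heterozygotes carrying the allele. `f = 1 - sum(c)/sum(b + c)`, summed
#' over alleles (per locus) or over alleles and loci (multilocus).
#'
#' @param g An [mlg_matrix()].
#' @param loci Optional locus-name vector (defaults to all loci in `g`).
#' @return A list with `per_locus` (data frame `locus`, `f`, `n_ind`;
#'   monomorphic loci are `NA` with a note) and `multilocus`.
#' @export
fis_weir_cockerham <- function(g, loci = NULL) {
  locus_names <- sub("\\.1$", "", colnames(g)[seq(1, ncol(g), 2)])
  if (is.null(loci)) loci <- locus_names
  sum_c <- sum_bc <- 0
  rows <- vector("list", length(loci))
  for (li in seq_along(loci)) {
    l <- match(loci[li], locus_names)
    ab <- locus_alleles(g, l)
    n <- nrow(ab)
    if (n < 2) stop("need >=2 scored individuals at locus ", loci[li])
    alleles <- sort(unique(c(ab[, 1], ab[, 2])))
    if (length(alleles) < 2) {
      rows[[li]] <- data.frame(locus = loci[li], f = NA_real_, n_ind = n,
                               note = "monomorphic", stringsAsFactors = FALSE)
      next
    }
    cnt <- tabulate(match(c(ab[, 1], ab[, 2]), alleles), length(alleles))
    p <- cnt / (2 * n)
    is_het <- ab[, 1] != ab[, 2]
    hbar <- vapply(alleles, function(a)
      sum(is_het & (ab[, 1] == a | ab[, 2] == a)) / n, numeric(1))
    b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    cc <- hbar / 2
    rows[[li]] <- data.frame(locus = loci[li],
                             f = 1 - sum(cc) / sum(b + cc),
                             n_ind = n, note = "", stringsAsFactors = FALSE)
    sum_c <- sum_c + sum(cc)
    sum_bc <- sum_bc + sum(b + cc)
  }
  list(per_locus = do.call(rbind, rows),
       multilocus = 1 - sum_c / sum_bc)
}

#' Probability of identity (unbiased and sibling)
#'
#' With `a_k = sum(p_i^k)` and `N` gene copies sampled:
#' * biased P_ID = `2 a2^2 - a4` (match probability of two unrelated
#'   individuals at the given frequencies);
#' * `pid_unb` = the small-sample unbiased estimator
#'   `(N^3 (2 a2^2 - a4) - 2 N^2 (a3 + 2 a2) + N (9 a2 + 2) - 6) /
#'   ((N-1)(N-2)(N-3))`, equal to the exact probability that two genotypes
#'   formed from four gene copies drawn without replacement from the sample
#'   match;
#' * `pid_sib` = `0.25 + 0.5 a2 + 0.5 a2^2 - 0.25 a4` (full siblings).
#' Cumulative values are the products over loci.
#'
#' @param freqs List of per-locus frequency vectors.
#' @param n_copies Integer vector of gene copies per locus (for `pid_unb`;
#'   loci with `N <= 3` get `NA` there).
#' @return A list with `per_locus` (data frame `locus`, `pid_biased`,
#'   `pid_unb`, `pid_sib`) and `cumulative` (named vector of the three
#'   products; the unbiased product skips untestable loci).
#' @export
probability_of_identity <- function(freqs, n_copies) {
  rows <- lapply(seq_along(freqs), function(l) {
    p <- freqs[[l]]
    N <- n_copies[l]
    a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
    biased <- 2 * a2^2 - a4
    sib <- 0.25 + 0.5 * a2 + 0.5 * a2^2 - 0.25 * a4
    unb <- if (!is.na(N) && N > 3) {
      (N^3 * (2 * a2^2 - a4) - 2 * N^2 * (a3 + 2 * a2) +
         N * (9 * a2 + 2) - 6) / ((N - 1) * (N - 2) * (N - 3))
    } else NA_real_
    clip <- function(x) if (is.na(x)) x else min(max(x, .Machine$double.xmin), 1)
    data.frame(locus = names(freqs)[l] %||% as.character(l),
               pid_biased = clip(biased), pid_unb = clip(unb),
               pid_sib = clip(sib), stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  list(per_locus = per_locus,
       cumulative = c(
         pid_biased = prod(per_locus$pid_biased),
         pid_unb = prod(per_locus$pid_unb[!is.na(per_locus$pid_unb)]),
         pid_sib = prod(per_locus$pid_sib)))
}

#' Per-locus summary statistics table
#'
#' Assembles, per locus: number of alleles, observed and unbiased expected
#' heterozygosity, Monte-Carlo exact HWE p-value, Chakraborty null-allele
#' estimate with its homozygote-excess p-value, Weir-Cockerham F_IS, and
#' the probability-of-identity columns; cumulative P_ID products are
#' attached as attribute `"cumulative_pid"` together with the multilocus
#' F_IS as attribute `"multilocus_fis"`.
#'
#' @param g An [mlg_matrix()] of one genotype per individual.
#' @param n_permutations Permutations for the HWE and null-allele tests.
#' @param seed Optional seed for the Monte-Carlo tests.
#' @return A data frame with one row per locus.
#' @export
locus_stats_table <- function(g, n_permutations = 10000L, seed = NULL) {
  locus_names <- sub("\\.1$", "", colnames(g)[seq(1, ncol(g), 2)])
  fis <- fis_weir_cockerham(g)
  freqs <- list()
  n_copies <- integer(length(locus_names))
  rows <- lapply(seq_along(locus_names), function(l) {
    af <- allele_frequencies(g, l)
    freqs[[l]] <<- af$freq
    n_copies[l] <<- af$n
    h <- heterozygosities(g, l)
    hw <- hwe_test(g, l, n_permutations = n_permutations,
                   seed = if (is.null(seed)) NULL else seed + l)
    nt <- null_allele_test(g, l, n_sim = n_permutations,
                           seed = if (is.null(seed)) NULL else seed + 1000 + l)
    data.frame(locus = locus_names[l],
               n_alleles = length(af$freq),
               n_ind = af$n_ind,
               h_obs = h$h_obs,
               h_exp = h$h_exp,
               hwe_p = hw$p_value,
               null_ch = null_allele_chakraborty(h$h_obs, h$h_exp),
               null_p = nt$p_value,
               f_is = fis$per_locus$f[l],
               stringsAsFactors = FALSE)
  })
  names(freqs) <- locus_names
  pid <- probability_of_identity(freqs, n_copies)
  out <- do.call(rbind, rows)
  out$pid_unb <- pid$per_locus$pid_unb
  out$pid_sib <- pid$per_locus$pid_sib
  attr(out, "cumulative_pid") <- pid$cumulative
  attr(out, "multilocus_fis") <- fis$multilocus
  out
}
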