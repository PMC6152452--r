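loci_ls <- data.frame(locus = c("L1", "L2"), repeat_unit = c(2L, 2L))

cohort <- function(gl) mlg_cohort(gl, loci_ls)

gm2 <- function(...) {
  m <- matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)
  rownames(m) <- loci_ls$locus
  m
}

test_that("allele frequencies are plain counts over non-missing genotypes", {
  g <- cohort(list(I1 = gm2(100, 100, 150, 150),
                   I2 = gm2(100, 102, NA, NA)))
  af <- allele_frequencies(g, "L1")
  expect_equal(unname(af$freq), c(0.75, 0.25))
  expect_equal(af$n, 4L)
  af2 <- allele_frequencies(g, "L2")
  expect_equal(unname(af2$freq), 1)
  expect_equal(af2$n_ind, 1L)
  g3 <- cohort(list(I1 = gm2(100, 100, NA, NA)))
  expect_error(allele_frequencies(g3, "L2"), "missing")
})

test_that("sampled allele frequencies recover the generating distribution", {
  set.seed(401)
  p <- c(0.5, 0.3, 0.2)
  n <- 5000
  a1 <- sample(c(100L, 102L, 104L), n, TRUE, p)
  a2 <- sample(c(100L, 102L, 104L), n, TRUE, p)
  g <- matrix(c(pmin(a1, a2), pmax(a1, a2)), ncol = 2,
              dimnames = list(NULL, c("L1.1", "L1.2")))
  af <- allele_frequencies(g, 1)
  for (i in 1:3)
    expect_lt(abs(unname(af$freq[i]) - p[i]),
              3 * sqrt(p[i] * (1 - p[i]) / (2 * n)))
})

test_that("heterozygosities match closed forms", {
  # two individuals with four distinct alleles: H_O = 1, unbiased H_E = 1
  g <- cohort(list(I1 = gm2(100, 102, 150, 150),
                   I2 = gm2(104, 106, 150, 150)))
  h <- heterozygosities(g, "L1")
  expect_equal(h$h_obs, 1)
  expect_equal(h$h_exp, 1)
  # monomorphic locus
  h2 <- heterozygosities(g, "L2")
  expect_equal(h2$h_obs, 0)
  expect_equal(h2$h_exp, 0)
  expect_error(heterozygosities(cohort(list(I1 = gm2(1, 2, 3, 4))), "L1"),
               "2 scored")
})

test_that("unbiased H_E is unbiased and H_O is consistent under HWE simulation", {
  set.seed(402)
  p <- c(0.4, 0.35, 0.25)
  gd_true <- 1 - sum(p^2)
  n <- 30
  reps <- 500
  he <- ho <- numeric(reps)
  for (r in seq_len(reps)) {
    a1 <- sample(c(100L, 102L, 104L), n, TRUE, p)
    a2 <- sample(c(100L, 102L, 104L), n, TRUE, p)
    g <- matrix(c(pmin(a1, a2), pmax(a1, a2)), ncol = 2,
                dimnames = list(NULL, c("L1.1", "L1.2")))
    h <- heterozygosities(g, 1)
    he[r] <- h$h_exp
    ho[r] <- h$h_obs
  }
  expect_lt(abs(mean(he) - gd_true), 3 * sd(he) / sqrt(reps))
  expect_lt(abs(mean(ho) - gd_true), 3 * sd(ho) / sqrt(reps))
})

test_that("the HWE Monte-Carlo test rejects a total heterozygote deficit", {
  # 50 individuals, two alleles at 0.5/0.5, all homozygous
  gl <- c(lapply(1:25, function(i) gm2(100, 100, 150, 150)),
          lapply(1:25, function(i) gm2(102, 102, 150, 150)))
  names(gl) <- sprintf("I%02d", 1:50)
  g <- cohort(gl)
  hw <- hwe_test(g, "L1", n_permutations = 2000, seed = 403)
  expect_lt(hw$p_value, 0.001)
  # monomorphic locus is not testable
  expect_false(hwe_test(g, "L2", 100)$testable)
})

test_that("the HWE test detects null alleles with good power at n = 100", {
  # null allele at frequency 0.25: null carriers look like homozygotes
  set.seed(404)
  visible <- c(100L, 102L, 104L)
  p_all <- c(0.3, 0.25, 0.2, 0.25)  # last = null
  reps <- 60
  hits <- 0
  for (r in seq_len(reps)) {
    a1 <- sample(1:4, 100, TRUE, p_all)
    a2 <- sample(1:4, 100, TRUE, p_all)
    both_null <- a1 == 4 & a2 == 4
    a1[a1 == 4] <- a2[a1 == 4]   # null copy hidden: appears homozygous
    a2[a2 == 4] <- a1[a2 == 4]
    keep <- !both_null
    sz <- visible
    g <- matrix(c(pmin(sz[a1[keep]], sz[a2[keep]]),
                  pmax(sz[a1[keep]], sz[a2[keep]])), ncol = 2,
                dimnames = list(NULL, c("L1.1", "L1.2")))
    if (hwe_test(g, 1, n_permutations = 400)$p_value < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("the Chakraborty estimator reproduces published values and is antisymmetric", {
  expect_equal(round(null_allele_chakraborty(0.50, 0.69), 2), 0.16)  # Mu05
  expect_equal(round(null_allele_chakraborty(0.59, 0.80), 2), 0.15)  # G1D
  expect_equal(null_allele_chakraborty(0.7, 0.7), 0)
  expect_true(is.na(null_allele_chakraborty(0, 0)))
  # sign property: positive iff H_E > H_O
  set.seed(405)
  ho <- runif(200)
  he <- runif(200)
  r <- null_allele_chakraborty(ho, he)
  expect_equal(r > 0, he > ho)
})

test_that("homozygote-excess Monte-Carlo test flags a null-allele locus", {
  set.seed(406)
  gl <- c(lapply(1:30, function(i) gm2(100, 100, 150, 152)),
          lapply(1:10, function(i) gm2(102, 102, 150, 152)),
          lapply(1:10, function(i) gm2(100, 102, 150, 152)))
  names(gl) <- sprintf("I%02d", seq_along(gl))
  g <- cohort(gl)
  nt <- null_allele_test(g, "L1", n_sim = 500, seed = 407)
  expect_lt(nt$p_value, 0.05)
})

test_that("Weir-Cockerham F_IS hits the maximal-excess bound and recovers simulated inbreeding", {
  # every individual heterozygous for the same two alleles: f = -1
  gl <- lapply(1:20, function(i) gm2(100, 102, 150, 152))
  names(gl) <- sprintf("I%02d", 1:20)
  f <- fis_weir_cockerham(cohort(gl))
  expect_equal(f$multilocus, -1)
  expect_equal(f$per_locus$f, c(-1, -1))

  # F = 0 recovery at n = 500
  cfg <- sim_config(n_individuals = 500, inbreeding_f = 0, n_subpops = 1,
                    target_fst = 0, subpop_share = 1, seed = 408)
  set.seed(cfg$seed)
  tr <- simulate_individuals(simulate_allele_frequencies(cfg), cfg)
  expect_lt(abs(fis_weir_cockerham(tr$genotypes)$multilocus), 0.05)
})

test_that("probability of identity matches closed forms and multiplies over loci", {
  p <- c(a = 0.5, b = 0.5)
  pid <- probability_of_identity(list(L1 = p), n_copies = 100L)
  expect_equal(pid$per_locus$pid_biased, 0.375)    # 2 a2^2 - a4
  expect_equal(pid$per_locus$pid_sib, 0.59375)
  # cumulative = product over loci
  pid5 <- probability_of_identity(rep(list(p), 5), n_copies = rep(100L, 5))
  expect_equal(unname(pid5$cumulative["pid_sib"]), 0.59375^5)
  expect_equal(unname(pid5$cumulative["pid_biased"]), 0.375^5)
  # N <= 3 is not testable for the unbiased form
  expect_true(is.na(probability_of_identity(list(p), 3L)$per_locus$pid_unb))
})

test_that("the unbiased P_ID equals exact enumeration of 4-copy draws on tiny samples", {
  for (counts in list(c(3L, 2L, 1L), c(4L, 3L), c(2L, 2L, 2L, 1L))) {
    N <- sum(counts)
    p <- counts / N
    got <- probability_of_identity(list(p), N)$per_locus$pid_unb
    expect_equal(got, enum_pid_unb(counts), tolerance = 1e-12)
  }
})

test_that("P_IDsib upper-bounds the other identity probabilities on random frequency vectors", {
  set.seed(409)
  for (i in 1:1000) {
    k <- sample(2:10, 1)
    p <- rgamma(k, 1)
    p <- p / sum(p)
    N <- sample(10:200, 1)
    row <- probability_of_identity(list(p), N)$per_locus
    expect_gte(row$pid_sib, row$pid_unb - 1e-9)
    expect_gte(row$pid_sib, row$pid_biased - 1e-9)
  }
})

test_that("adding a locus never increases cumulative P_ID", {
  set.seed(410)
  freqs <- lapply(1:6, function(l) {
    p <- rgamma(5, 1)
    p / sum(p)
  })
  for (metric in c("pid_biased", "pid_sib")) {
    cums <- vapply(1:6, function(k)
      probability_of_identity(freqs[1:k],
                              rep(80L, k))$cumulative[[metric]],
      numeric(1))
    expect_true(all(diff(cums) <= 1e-15))
  }
})

test_that("the locus summary table carries consistent columns on study-like data", {
  ds <- get_study_consensus()
  ind <- filter_for_analysis(
    identify_individuals(filter_by_locus_coverage(ds, 8)$retained), 1)
  g <- mlg_matrix(ind$genotypes, ds$loci, id_col = "individual_id")
  st <- locus_stats_table(g, n_permutations = 300, seed = 411)
  expect_equal(st$locus, ds$loci$locus)
  expect_true(all(st$n_alleles >= 2))
  expect_true(all(st$h_obs >= 0 & st$h_obs <= 1))
  expect_true(all(st$h_exp >= 0 & st$h_exp <= 1))
  expect_equal(st$null_ch > 0, st$h_exp > st$h_obs)
  expect_true(all(st$pid_sib >= st$pid_unb))
  cum <- attr(st, "cumulative_pid")
  expect_equal(unname(cum["pid_sib"]), prod(st$pid_sib))
})
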