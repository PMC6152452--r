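loci_st <- data.frame(locus = c("L1", "L2", "L3"), repeat_unit = 2L)

gm3 <- function(...) {
  m <- matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)
  rownames(m) <- loci_st$locus
  m
}

sim_two_pops <- function(fst, n_per, n_loci = 10, k = 6, seed = 1) {
  loci <- data.frame(locus = sprintf("L%02d", seq_len(n_loci)),
                     repeat_unit = 2L, n_alleles = k)
  cfg <- sim_config(n_individuals = 2 * n_per, loci = loci,
                    n_subpops = 2, target_fst = fst,
                    dirichlet_concentration = 5, seed = seed)
  set.seed(seed)
  fr <- simulate_allele_frequencies(cfg)
  tr <- simulate_individuals(fr, cfg)
  list(g = tr$genotypes, groups = tr$individuals$subpop)
}

test_that("theta is non-positive for two copies of the same group and recovers a Balding-Nichols target", {
  set.seed(501)
  sp <- sim_two_pops(fst = 0, n_per = 30, seed = 502)
  # split one panmictic sample arbitrarily in two
  th <- pairwise_fst(sp$g, rep(1:2, 30), n_permutations = 200, seed = 503)
  expect_lte(th$theta, 0.02)
  expect_gt(th$p_value, 0.05)

  # the realised divergence of two Balding-Nichols draws is itself random
  # (few degrees of freedom), so recovery is asserted on the replicate mean
  th10 <- vapply(1:12, function(r)
    with(sim_two_pops(fst = 0.10, n_per = 100, seed = 5040 + r),
         wc_theta(g, groups)), numeric(1))
  expect_gt(mean(th10), 0.05)
  expect_lt(mean(th10), 0.15)
})

test_that("the F_ST permutation p-value is invariant to group label order", {
  sp <- sim_two_pops(fst = 0.05, n_per = 20, seed = 505)
  a <- pairwise_fst(sp$g, sp$groups, n_permutations = 300, seed = 506)
  flipped <- ifelse(sp$groups == 1, "B", "A")
  b <- pairwise_fst(sp$g, flipped, n_permutations = 300, seed = 506)
  expect_equal(a$theta, b$theta)
  expect_equal(a$p_value, b$p_value)
})

test_that("shared-allele distance matches multiset arithmetic", {
  a <- gm3(100, 102, 150, 152, 200, 202)
  g <- mlg_cohort(list(I1 = a, I2 = a), loci_st)
  d <- shared_allele_distance(g)
  expect_equal(d["I1", "I2"], 0)
  b <- gm3(104, 106, 154, 156, 204, 206)   # fully disjoint
  d2 <- shared_allele_distance(mlg_cohort(list(I1 = a, I2 = b), loci_st))
  expect_equal(d2["I1", "I2"], 1)
  # single informative locus: (100,102) vs (100,100) shares one allele
  c1 <- gm3(100, 102, NA, NA, NA, NA)
  c2 <- gm3(100, 100, NA, NA, NA, NA)
  d3 <- shared_allele_distance(mlg_cohort(list(I1 = c1, I2 = c2), loci_st))
  expect_equal(d3["I1", "I2"], 0.5)
  # pair with no shared scored loci is undefined
  e1 <- gm3(100, 102, NA, NA, NA, NA)
  e2 <- gm3(NA, NA, 150, 152, NA, NA)
  d4 <- shared_allele_distance(mlg_cohort(list(I1 = e1, I2 = e2), loci_st))
  expect_true(is.na(d4["I1", "I2"]))
  expect_equal(nrow(attr(d4, "undefined_pairs")), 1)
})

test_that("Kosman dissimilarity equals the shared-allele distance on complete diploid data", {
  set.seed(507)
  for (i in 1:250) {
    gl <- list(I1 = rand_mlg(loci_st$locus, k = 4),
               I2 = rand_mlg(loci_st$locus, k = 4))
    g <- mlg_cohort(gl, loci_st)
    expect_equal(kosman_dissimilarity(g), shared_allele_distance(g),
                 ignore_attr = TRUE)
  }
  # het vs hom sharing one allele at a single locus -> 0.5
  g <- mlg_cohort(list(I1 = gm3(100, 102, NA, NA, NA, NA),
                       I2 = gm3(100, 100, NA, NA, NA, NA)), loci_st)
  expect_equal(kosman_dissimilarity(g)["I1", "I2"], 0.5)
})

test_that("distance matrices are symmetric with zero diagonal even with missing data", {
  set.seed(508)
  gl <- lapply(1:12, function(i) rand_mlg(loci_st$locus, k = 4, miss = 0.2))
  names(gl) <- sprintf("I%02d", 1:12)
  g <- mlg_cohort(gl, loci_st)
  for (d in list(shared_allele_distance(g), kosman_dissimilarity(g))) {
    expect_equal(unname(d), unname(t(d)))
    expect_equal(unname(diag(d)), rep(0, 12))
    expect_true(all(d[!is.na(d)] >= 0 & d[!is.na(d)] <= 1))
  }
})

test_that("neighbor joining solves the three-point formulas exactly", {
  d <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  # terminal branches: a = (dAB + dAC - dBC)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["A"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["B"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["C"]), (9 + 10 - 5) / 2)
})

test_that("neighbor joining recovers additive four-taxon matrices and beats alternative topologies", {
  # additive tree: ((A:2,B:3):1,(C:2,D:4))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  bl <- c(A = 2, B = 3, C = 2, D = 4)
  internal <- 1
  d["A", "B"] <- d["B", "A"] <- bl["A"] + bl["B"]
  d["C", "D"] <- d["D", "C"] <- bl["C"] + bl["D"]
  for (i in c("A", "B")) for (j in c("C", "D"))
    d[i, j] <- d[j, i] <- bl[i] + bl[j] + internal
  tr <- neighbor_joining(d)
  # path distances reproduce the matrix to numerical precision
  pd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pd, d, tolerance = 1e-9)
  # brute-force least squares picks the same split
  rss <- c(AB = ls_rss_4taxa(d, c(1, 2)), AC = ls_rss_4taxa(d, c(1, 3)),
           AD = ls_rss_4taxa(d, c(1, 4)))
  expect_equal(names(which.min(rss)), "AB")
  # NJ put A,B as a cherry
  cherries <- tr$edge[, 1][match(1:2, tr$edge[, 2])]
  expect_equal(cherries[1], cherries[2])
})

test_that("identical individuals form a zero-length cherry after clamping", {
  set.seed(509)
  g0 <- rand_mlg(loci_st$locus, k = 5)
  gl <- list(I1 = g0, I2 = g0, I3 = rand_mlg(loci_st$locus, k = 5),
             I4 = rand_mlg(loci_st$locus, k = 5))
  d <- kosman_dissimilarity(mlg_cohort(gl, loci_st))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  i12 <- match(c("I1", "I2"), tr$tip.label)
  expect_equal(tr$edge.length[match(i12, tr$edge[, 2])], c(0, 0))
  d_na <- d
  d_na[1, 2] <- d_na[2, 1] <- NA
  expect_error(neighbor_joining(d_na), "undefined")
})

test_that("genotype PCA conserves variance, maps duplicates together and separates diverged populations", {
  sp <- sim_two_pops(fst = 0.2, n_per = 40, seed = 510)
  pca <- pca_genotypes(sp$g)
  expect_equal(sum(pca$eigenvalues), pca$total_variance)
  expect_equal(sum(pca$explained), 1)
  # sign of PC1 separates the groups with >= 95% accuracy
  side <- pca$scores[, 1] > 0
  acc <- max(mean(side == (sp$groups == 1)), mean(side == (sp$groups == 2)))
  expect_gte(acc, 0.95)
  # duplicated individual lands on identical coordinates
  g2 <- rbind(sp$g, dup = sp$g[1, ])
  pca2 <- pca_genotypes(g2)
  expect_equal(unname(pca2$scores[nrow(g2), ]), unname(pca2$scores[1, ]))
})

test_that("dissimilarity-vs-distance keeps resampled individuals and flags long-range matches", {
  set.seed(511)
  g0 <- rand_mlg(loci_st$locus, k = 6)
  gl <- list(S1 = g0, S2 = g0, S3 = rand_mlg(loci_st$locus, k = 6),
             S4 = rand_mlg(loci_st$locus, k = 6))
  g <- mlg_cohort(gl, loci_st)
  # S1/S2: same individual resampled at the same place; S1 vs S3 ~160 km
  lat <- c(41.2, 41.2, 40.25, 41.25)
  lon <- c(41.8, 41.8, 40.2, 41.85)
  out <- dissimilarity_vs_distance(g, lat, lon, n_permutations = 99)
  p12 <- out$pairs[out$pairs$id1 == "S1" & out$pairs$id2 == "S2", ]
  expect_equal(p12$distance_m, 0)
  expect_equal(p12$dissimilarity, 0)
  p13 <- out$pairs[out$pairs$id1 == "S1" & out$pairs$id2 == "S3", ]
  expect_gt(p13$distance_m, 100e3)
  expect_equal(nrow(out$pairs), 6)
  expect_false(is.na(out$mantel_r))
})

test_that("a mobile individual shows as a zero-dissimilarity pair at long distance in the study-like data", {
  sim <- get_study_sim()
  ds <- get_study_consensus()
  part <- filter_by_locus_coverage(ds, 8)$retained
  m <- mlg_matrix(consensus_calls(part), part$loci)
  s <- part$samples[match(rownames(m), part$samples$sample_id), ]
  out <- dissimilarity_vs_distance(m, s$lat, s$lon, n_permutations = 99)
  # panmictic-ish region: no isolation by distance expected
  expect_gt(out$mantel_p, 0.01)
  expect_true(all(abs(out$running$mean_dissim[
    !is.na(out$running$mean_dissim)] -
      mean(out$pairs$dissimilarity)) < 0.2))
})

test_that("running average stays flat under panmixia across two sites", {
  set.seed(512)
  loci <- data.frame(locus = sprintf("L%02d", 1:8), repeat_unit = 2L,
                     n_alleles = 6L)
  hits <- 0
  reps <- 100
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_individuals = 30, loci = loci, n_subpops = 2,
                      target_fst = 0, dirichlet_concentration = 5,
                      seed = 512000 + r)
    fr <- simulate_allele_frequencies(cfg)
    tr <- simulate_individuals(fr, cfg)
    lat <- cfg$subpop_centers$lat[tr$individuals$subpop] + rnorm(30, 0, 0.2)
    lon <- cfg$subpop_centers$lon[tr$individuals$subpop] + rnorm(30, 0, 0.2)
    out <- dissimilarity_vs_distance(tr$genotypes, lat, lon,
                                     n_permutations = 99)
    if (out$mantel_p > 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("the admixture sampler is degenerate at K = 1 and accurate on diverged populations", {
  sp <- sim_two_pops(fst = 0.15, n_per = 30, seed = 513)
  one <- admixture_cluster(sp$g, K = 1, sweeps = 200, burn_in = 50,
                           seed = 514)
  expect_equal(unname(one$q_matrix[, 1]), rep(1, 60))
  expect_error(admixture_cluster(sp$g, K = 2, sweeps = 100, burn_in = 100),
               "exceed")
  two <- admixture_cluster(sp$g, K = 2, sweeps = 1500, burn_in = 500,
                           seed = 515)
  expect_equal(unname(rowSums(two$q_matrix)), rep(1, 60), tolerance = 1e-9)
  expect_gte(assignment_accuracy(two$q_matrix, sp$groups), 0.9)
})

test_that("the admixture evidence prefers K = 1 on panmictic data", {
  set.seed(516)
  loci <- data.frame(locus = sprintf("L%02d", 1:10), repeat_unit = 2L,
                     n_alleles = 6L)
  wins <- 0
  reps <- 12
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_individuals = 40, loci = loci, n_subpops = 1,
                      subpop_share = 1, target_fst = 0,
                      dirichlet_concentration = 3, seed = 516000 + r)
    set.seed(cfg$seed)
    fr <- simulate_allele_frequencies(cfg)
    tr <- simulate_individuals(fr, cfg)
    lnp <- vapply(1:3, function(K)
      admixture_cluster(tr$genotypes, K, sweeps = 800, burn_in = 300,
                        seed = 517000 + 10 * r + K)$lnP_estimate,
      numeric(1))
    if (which.max(lnp) == 1) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.8)
})
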