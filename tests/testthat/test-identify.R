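loci2 <- data.frame(locus = c("L1", "L2", "L3"), repeat_unit = c(2L, 2L, 4L))

gmat <- function(...) {
  m <- matrix(as.integer(c(...)), ncol = 2, byrow = TRUE)
  rownames(m) <- loci2$locus
  colnames(m) <- c("a1", "a2")
  m
}

test_that("allele mismatch counting uses the maximal multiset intersection", {
  a <- gmat(100, 102, 150, 150, 200, 204)
  expect_equal(genotype_mismatch_count(a, a)$total, 0L)
  b <- gmat(100, 100, 150, 150, 200, 204)
  expect_equal(genotype_mismatch_count(a, b)$total, 1L)
  c2 <- gmat(104, 106, 150, 150, 200, 204)
  expect_equal(genotype_mismatch_count(a, c2)$total, 2L)
  # missing loci are wildcards but recorded
  d <- gmat(100, 102, NA, NA, 200, 204)
  mm <- genotype_mismatch_count(a, d)
  expect_equal(mm$total, 0L)
  expect_true(mm$detail$missing_overlap[2])
  expect_error(genotype_mismatch_count(a, gmat(1, 2, 3, 4, 5, 6)[1:2, ]),
               "locus set")
})

test_that("mismatch counts agree with a brute-force pairing oracle on random genotypes", {
  set.seed(301)
  for (i in 1:300) {
    g1 <- rand_mlg(loci2$locus, k = 3, miss = 0.15)
    g2 <- rand_mlg(loci2$locus, k = 3, miss = 0.15)
    expect_equal(genotype_mismatch_count(g1, g2)$total,
                 bf_mismatch_total(g1, g2))
  }
})

test_that("pair classification attributes dropout, size shift and missing data per the matching criteria", {
  base <- gmat(100, 108, 150, 152, 200, 204)
  # large-allele dropout: homozygote for the smaller allele
  drop <- gmat(100, 100, 150, 152, 200, 204)
  pc <- classify_pair(base, drop, loci2)
  expect_equal(pc$verdict, "same")
  expect_equal(pc$attributions$attribution, "dropout")
  # dropout of the *smaller* allele is not the named phenomenon
  wrong_drop <- gmat(108, 108, 150, 152, 200, 204)
  expect_equal(classify_pair(base, wrong_drop, loci2)$verdict, "distinct")
  # one-repeat-unit stutter shift (dinucleotide L2: 152 -> 154)
  shift <- gmat(100, 108, 150, 154, 200, 204)
  pc2 <- classify_pair(base, shift, loci2)
  expect_equal(pc2$verdict, "same")
  expect_equal(pc2$attributions$attribution, "size_shift")
  # a 2-bp shift at the tetranucleotide L3 is not stutter
  bad_shift <- gmat(100, 108, 150, 152, 200, 202)
  expect_equal(classify_pair(base, bad_shift, loci2)$verdict, "distinct")
  # missing data explains a locus without adding mismatches
  miss <- gmat(100, 108, NA, NA, 200, 204)
  pc3 <- classify_pair(base, miss, loci2)
  expect_equal(pc3$verdict, "same")
  expect_equal(pc3$attributions$attribution, "missing_data")
  # two differences with one unexplained -> distinct
  two <- gmat(100, 100, 150, 160, 200, 204)
  expect_equal(classify_pair(base, two, loci2)$verdict, "distinct")
  # identical genotypes -> same with no attributions
  pc4 <- classify_pair(base, base, loci2)
  expect_equal(pc4$verdict, "same")
  expect_equal(pc4$n_mismatch_alleles, 0L)
})

test_that("pair classification is symmetric", {
  set.seed(302)
  for (i in 1:200) {
    g1 <- rand_mlg(loci2$locus, k = 3, miss = 0.1)
    g2 <- rand_mlg(loci2$locus, k = 3, miss = 0.1)
    expect_identical(classify_pair(g1, g2, loci2)$verdict,
                     classify_pair(g2, g1, loci2)$verdict)
  }
})

make_identify_ds <- function(genotypes, provinces = NULL, sry = NULL) {
  ids <- names(genotypes)
  samples <- data.frame(
    sample_id = ids,
    province = provinces %||% rep("A", length(ids)),
    source = "tissue", year = 2010L, lat = 41, lon = 41.5,
    stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(ids, function(id)
    data.frame(sample_id = id, replicate = 1L,
               locus = rownames(genotypes[[id]]),
               a1 = genotypes[[id]][, 1], a2 = genotypes[[id]][, 2],
               stringsAsFactors = FALSE)))
  bear_dataset(samples, long, loci = loci2, sry = sry)
}

test_that("identical genotypes cluster into one individual; provinces are unioned", {
  g <- gmat(100, 102, 150, 152, 200, 204)
  ds <- make_identify_ds(list(S1 = g, S2 = g,
                              S3 = gmat(104, 106, 154, 156, 208, 212)),
                         provinces = c("Artvin", "Bayburt", "Artvin"))
  ind <- cluster_samples(ds)
  expect_equal(nrow(ind$individuals), 2)
  i1 <- ind$individuals[ind$individuals$n_members == 2, ]
  expect_equal(i1$provinces_seen, "Artvin;Bayburt")
  expect_equal(i1$n_provinces, 2L)
})

test_that("clustering output is invariant to input sample order", {
  set.seed(303)
  gl <- lapply(1:8, function(i) rand_mlg(loci2$locus, k = 6))
  names(gl) <- sprintf("S%02d", 1:8)
  ds1 <- make_identify_ds(gl)
  ds2 <- make_identify_ds(gl[sample(names(gl))])
  i1 <- cluster_samples(ds1)
  i2 <- cluster_samples(ds2)
  expect_equal(i1$individuals$member_sample_ids,
               i2$individuals$member_sample_ids)
  expect_equal(i1$genotypes, i2$genotypes)
})

test_that("consolidated genotypes prefer confirmed heterozygotes over dropout-suspect homozygotes", {
  het <- gmat(100, 108, 150, 152, 200, 204)
  hom <- gmat(100, 100, 150, 152, 200, 204)   # dropout suspect at L1
  ds <- make_identify_ds(list(S1 = hom, S2 = het))
  ind <- cluster_samples(ds)
  expect_equal(nrow(ind$individuals), 1)
  gL1 <- ind$genotypes[ind$genotypes$locus == "L1", ]
  expect_equal(c(gL1$a1, gL1$a2), c(100L, 108L))
})

test_that("analysis filter drops consolidated genotypes with too many missing loci", {
  full <- gmat(100, 102, 150, 152, 200, 204)
  one_missing <- gmat(104, 106, NA, NA, 208, 212)
  two_missing <- gmat(110, 112, NA, NA, NA, NA)
  ds <- make_identify_ds(list(S1 = full, S2 = one_missing,
                              S3 = two_missing))
  ind <- cluster_samples(ds)
  kept <- filter_for_analysis(ind, max_missing_loci = 1L)
  expect_equal(nrow(kept$individuals), 2)
  expect_false(any(kept$individuals$n_missing_loci > 1))
})

test_that("sex assignment handles clean calls, SRY dropout and the minority-positive conflict case", {
  g <- gmat(100, 102, 150, 152, 200, 204)
  gl <- list(S1 = g, S2 = g, S3 = g, S4 = g, S5 = g)
  sry <- data.frame(sample_id = names(gl), replicate = 1L,
                    sry_positive = c(TRUE, rep(FALSE, 4)),
                    stringsAsFactors = FALSE)
  ds <- make_identify_ds(gl, sry = sry)
  ind <- identify_individuals(ds)
  # one positive against four negative exact matches -> conflict, reported
  expect_equal(ind$individuals$sex, "conflict")
  expect_length(ind$sex_conflicts, 1)

  sry$sry_positive <- rep(FALSE, 5)
  ds2 <- make_identify_ds(gl, sry = sry)
  expect_equal(identify_individuals(ds2)$individuals$sex, "female")

  sry$sry_positive <- rep(TRUE, 5)
  ds3 <- make_identify_ds(gl, sry = sry)
  expect_equal(identify_individuals(ds3)$individuals$sex, "male")
})

test_that("with zero simulation error, sex calls are perfect and identification is exact", {
  cfg <- sim_config(n_individuals = 20, samples_per_individual = 1.5,
                    dropout_rate = 0, false_allele_rate = 0,
                    stutter_rate = 0, sry_dropout = 0,
                    sry_misamplification = 0,
                    locus_failure_rate = c(pole = 0, tree = 0,
                                           barbed_wire = 0, hair_trap = 0,
                                           capture_hair = 0, tissue = 0),
                    seed = 9)
  sim <- simulate_dataset(cfg)
  ds <- consensus_genotypes(sim$dataset)
  ind <- identify_individuals(filter_by_locus_coverage(ds, 8)$retained)
  cmp <- compare_to_truth(ind, sim$truth)
  expect_equal(cmp$n_split, 0)
  expect_equal(cmp$n_lump, 0)
  expect_equal(cmp$recovery_rate, 1)
  # sex accuracy 100%
  truth_sex <- sim$truth$individuals$sex[
    match(sim$truth$sample_map$individual_id[
      match(vapply(strsplit(ind$individuals$member_sample_ids, ";"),
                   `[`, character(1), 1),
            sim$truth$sample_map$sample_id)],
      sim$truth$individuals$individual_id)]
  expect_equal(ind$individuals$sex, truth_sex)
})
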