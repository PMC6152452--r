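#!/usr/bin/env Rscript
# Stage 5: population structure.
#
# Pairwise Weir-Cockerham F_ST with a permutation test, shared-allele
# distances with a neighbor-joining tree, PCA, genetic dissimilarity versus
# geographic distance (all genotyped samples, retaining resampled
# individuals), and Bayesian admixture clustering over K = 1..4.

suppressPackageStartupMessages(library(bearid))

ds <- read_genotype_table("results/genotypes.csv", loci = gkm_panel())
ds <- consensus_genotypes(ds)
part <- filter_by_locus_coverage(ds, 8)
ind <- identify_individuals(part$retained)
kept <- filter_for_analysis(ind, 1)
g <- mlg_matrix(kept$genotypes, gkm_panel(), id_col = "individual_id")

# F_ST between provinces (individuals seen in a single province)
provs <- kept$individuals$provinces_seen[
  match(rownames(g), kept$individuals$individual_id)]
single <- !grepl(";", provs)
if (min(table(provs[single])) >= 2) {
  fst <- pairwise_fst(g[single, ], provs[single], n_permutations = 10000,
                      seed = 5)
  cat(sprintf("Province F_ST: theta = %.4f, permutation P = %.3f (n = %d)\n",
              fst$theta, fst$p_value, sum(single)))
} else {
  cat("Too few single-province genotypes in one province for F_ST\n")
}

# shared-allele NJ tree
d <- shared_allele_distance(g)
if (!anyNA(d)) {
  tr <- neighbor_joining(d)
  ape::write.tree(tr, "results/nj_shared_alleles.nwk")
  cat("Wrote results/nj_shared_alleles.nwk\n")
}

# PCA
pca <- pca_genotypes(g)
coords <- data.frame(individual_id = rownames(g),
                     province = provs,
                     PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
write.table(coords, "results/pca.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pca$explained[1], 100 * pca$explained[2]))

# dissimilarity vs distance over all retained samples
m <- mlg_matrix(consensus_calls(part$retained), part$retained$loci)
s <- part$retained$samples[match(rownames(m),
                                 part$retained$samples$sample_id), ]
dvd <- dissimilarity_vs_distance(m, s$lat, s$lon, n_permutations = 999)
write.table(dvd$running, "results/dissimilarity_running_average.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("Isolation by distance: Mantel r = %.3f, P = %.3f over %d pairs\n",
            dvd$mantel_r, dvd$mantel_p, nrow(dvd$pairs)))
zero_far <- dvd$pairs[dvd$pairs$dissimilarity == 0 &
                        dvd$pairs$distance_m > 100e3, ]
if (nrow(zero_far))
  cat("Identical genotypes sampled >100 km apart:",
      paste(zero_far$id1, zero_far$id2, collapse = "; "), "\n")

# admixture clustering
lnp <- vapply(1:4, function(K) {
  fit <- admixture_cluster(g, K, sweeps = 6000, burn_in = 2000,
                           seed = 50 + K)
  if (K == 2)
    write.table(round(fit$q_matrix, 3), "results/admixture_q_K2.tsv",
                sep = "\t", quote = FALSE, col.names = FALSE)
  fit$lnP_estimate
}, numeric(1))
write.table(data.frame(K = 1:4, lnP = lnp), "results/admixture_lnP.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("Admixture lnP by K:", paste(sprintf("K=%d: %.1f", 1:4, lnp),
                                 collapse = ", "), "\n")
cat("Most supported K =", which.max(lnp), "\n")
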