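# Shared fixtures, built in code.

# Small two-province dataset with clean genotypes (2 concordant replicates
# per hair sample, one tissue sample).
toy_dataset <- function() {
  loci <- data.frame(locus = c("L1", "L2"), repeat_unit = c(2L, 2L))
  samples <- data.frame(
    sample_id = c("H1", "H2", "T1"),
    province = c("A", "B", "A"),
    source = c("tree", "pole", "tissue"),
    year = c(2010L, 2012L, 2011L),
    lat = c(41.2, 40.3, 41.25),
    lon = c(41.8, 40.2, 41.85),
    stringsAsFactors = FALSE
  )
  geno <- rbind(
    c("H1", 1L, "L1", 100L, 102L), c("H1", 1L, "L2", 150L, 150L),
    c("H1", 2L, "L1", 100L, 102L), c("H1", 2L, "L2", 150L, 150L),
    c("H2", 1L, "L1", 104L, 106L), c("H2", 1L, "L2", 152L, 154L),
    c("H2", 2L, "L1", 104L, 106L), c("H2", 2L, "L2", 152L, 154L),
    c("T1", 1L, "L1", 100L, 100L), c("T1", 1L, "L2", 154L, 156L)
  )
  replicates <- data.frame(
    sample_id = geno[, 1], replicate = as.integer(geno[, 2]),
    locus = geno[, 3], a1 = as.integer(geno[, 4]),
    a2 = as.integer(geno[, 5]), stringsAsFactors = FALSE
  )
  sry <- data.frame(
    sample_id = c("H1", "H1", "H2", "H2", "T1"),
    replicate = c(1L, 2L, 1L, 2L, 1L),
    sry_positive = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  bear_dataset(samples, replicates, loci = loci, sry = sry)
}

# Build an mlg cohort matrix directly from a loci x 2 genotype list.
mlg_cohort <- function(gl, loci) {
  long <- do.call(rbind, lapply(names(gl), function(id)
    data.frame(sample_id = id, locus = rownames(gl[[id]]),
               a1 = gl[[id]][, 1], a2 = gl[[id]][, 2],
               stringsAsFactors = FALSE)))
  mlg_matrix(long, loci)
}

# Memoised study-like simulation shared across test files.
get_study_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) cache[[key]] <- generate_study_like_dataset(seed)
    cache[[key]]
  }
})

get_study_consensus <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- consensus_genotypes(get_study_sim(seed)$dataset)
    cache[[key]]
  }
})
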