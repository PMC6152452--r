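# Independent oracles, kept deliberately separate from the package's own
# implementations.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Allele-pair mismatch by brute force over both possible pairings.
bf_pair_mismatch <- function(p1, p2) {
  m1 <- (p1[1] != p2[1]) + (p1[2] != p2[2])
  m2 <- (p1[1] != p2[2]) + (p1[2] != p2[1])
  min(m1, m2)
}

bf_mismatch_total <- function(g1, g2) {
  tot <- 0L
  for (l in seq_len(nrow(g1))) {
    if (is.na(g1[l, 1]) || is.na(g2[l, 1])) next
    tot <- tot + bf_pair_mismatch(g1[l, ], g2[l, ])
  }
  tot
}

# Minimal Genepop reader (independent of the package's writer).
parse_genepop <- function(path) {
  lines <- readLines(path)
  pop_at <- grep("^\\s*Pop\\s*$", lines, ignore.case = TRUE)
  loci <- lines[2:(pop_at[1] - 1)]
  pops <- list()
  bounds <- c(pop_at, length(lines) + 1L)
  for (p in seq_along(pop_at)) {
    entry <- lines[seq(bounds[p] + 1L, bounds[p + 1L] - 1L)]
    ids <- trimws(sub(",.*$", "", entry))
    codes <- strsplit(trimws(sub("^[^,]*,", "", entry)), "\\s+")
    mat <- do.call(rbind, lapply(codes, function(cc) {
      a1 <- as.integer(substr(cc, 1, 3))
      a2 <- as.integer(substr(cc, 4, 6))
      c(rbind(a1, a2))
    }))
    rownames(mat) <- ids
    pops[[p]] <- mat
  }
  list(loci = loci, pops = pops)
}

# Minimal reader for the two-row-per-individual cluster matrix format.
parse_cluster_input <- function(path) {
  lines <- readLines(path)
  loci <- strsplit(lines[1], "\\s+")[[1]]
  body <- do.call(rbind, strsplit(lines[-1], "\\s+"))
  ids <- body[, 1]
  vals <- apply(body[, -1, drop = FALSE], 2, as.integer)
  odd <- seq(1, nrow(body), by = 2)
  out <- list()
  for (r in odd) {
    stopifnot(ids[r] == ids[r + 1])
    g <- rbind(vals[r, ], vals[r + 1, ])
    g[g == -9] <- NA_integer_
    out[[ids[r]]] <- g
  }
  list(loci = loci, genotypes = out)
}

# Exact probability two genotypes built from 4 gene copies drawn without
# replacement from the sample match, by full enumeration (tiny N only).
enum_pid_unb <- function(counts) {
  N <- sum(counts)
  alleles <- rep(seq_along(counts), counts)
  tot <- 0
  hit <- 0
  idx <- seq_len(N)
  for (i in idx) for (j in idx) for (k in idx) for (l in idx) {
    if (anyDuplicated(c(i, j, k, l))) next
    g1 <- sort(c(alleles[i], alleles[j]))
    g2 <- sort(c(alleles[k], alleles[l]))
    tot <- tot + 1
    if (all(g1 == g2)) hit <- hit + 1
  }
  hit / tot
}

# Monte-Carlo version of the same oracle for realistic N (vectorised:
# rejection sampling of 4 distinct copy indices per draw).
mc_pid_unb <- function(counts, n_pairs) {
  copies <- rep(seq_along(counts), counts)
  N <- length(copies)
  hits <- logical(0)
  while (length(hits) < n_pairs) {
    m <- ceiling((n_pairs - length(hits)) * 1.3)
    idx <- matrix(sample.int(N, 4 * m, replace = TRUE), m, 4)
    distinct <- (idx[, 1] != idx[, 2]) & (idx[, 1] != idx[, 3]) &
      (idx[, 1] != idx[, 4]) & (idx[, 2] != idx[, 3]) &
      (idx[, 2] != idx[, 4]) & (idx[, 3] != idx[, 4])
    idx <- idx[distinct, , drop = FALSE]
    a <- matrix(copies[idx], nrow(idx), 4)
    match_ <- (pmin(a[, 1], a[, 2]) == pmin(a[, 3], a[, 4])) &
      (pmax(a[, 1], a[, 2]) == pmax(a[, 3], a[, 4]))
    hits <- c(hits, match_)
  }
  hits <- hits[seq_len(n_pairs)]
  c(p = mean(hits), se = stats::sd(hits) / sqrt(n_pairs))
}

# Least-squares branch fit of a 4-taxon topology; returns the RSS.
ls_rss_4taxa <- function(d, split) {
  # split: c(i,j) grouped vs the rest; 5 branches: 4 terminal + 1 internal
  taxa <- rownames(d)
  pair1 <- split
  pair2 <- setdiff(seq_len(4), split)
  combs <- utils::combn(4, 2)
  X <- matrix(0, ncol(combs), 5)
  y <- numeric(ncol(combs))
  for (cix in seq_len(ncol(combs))) {
    i <- combs[1, cix]
    j <- combs[2, cix]
    y[cix] <- d[i, j]
    X[cix, i] <- 1
    X[cix, j] <- 1
    same_side <- (i %in% pair1 && j %in% pair1) ||
      (i %in% pair2 && j %in% pair2)
    if (!same_side) X[cix, 5] <- 1
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# Random complete multilocus genotype over small allele sets.
rand_mlg <- function(loci, k = 4, miss = 0) {
  m <- matrix(NA_integer_, length(loci), 2,
              dimnames = list(loci, c("a1", "a2")))
  for (l in seq_along(loci)) {
    if (stats::runif(1) < miss) next
    a <- sort(sample(100 + 2 * seq_len(k), 2, replace = TRUE))
    m[l, ] <- a
  }
  m
}
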