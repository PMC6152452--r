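# Weir-Cockerham theta (F_ST) variance components for >=2 groups.
# g: mlg_matrix; groups: factor/vector of group labels per row.
# Returns c(a = sum_a, abc = sum_(a+b+c)) over alleles and loci.
wc_theta_components <- function(g, groups) {
  groups <- as.factor(groups)
  L <- ncol(g) / 2
  sum_a <- sum_abc <- 0
  for (l in seq_len(L)) {
    a1 <- g[, 2 * l - 1]
    a2 <- g[, 2 * l]
    keep <- !is.na(a1)
    if (sum(keep) < 2) next
    gl <- droplevels(groups[keep])
    if (nlevels(gl) < 2) next
    a1 <- a1[keep]
    a2 <- a2[keep]
    n_i <- as.vector(table(gl))
    if (any(n_i < 1)) next
    r <- length(n_i)
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2) next
    is_het <- a1 != a2
    for (al in alleles) {
      x <- (a1 == al) + (a2 == al)          # allele dosage per individual
      p_i <- tapply(x, gl, sum) / (2 * n_i)
      h_i <- tapply(is_het & x == 1, gl, sum) / n_i
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a_comp <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b_comp <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) /
           (4 * nbar) * hbar)
      c_comp <- hbar / 2
      sum_a <- sum_a + a_comp
      sum_abc <- sum_abc + a_comp + b_comp + c_comp
    }
  }
  c(a = sum_a, abc = sum_abc)
}

#' Weir-Cockerham theta (F_ST) between groups
#'
#' @param g An [mlg_matrix()].
#' @param groups Group label per row of `g`.
#' @return The multilocus theta (sums of variance components over alleles
#'   and loci).
#' @export
wc_theta <- function(g, groups) {
  comp <- wc_theta_components(g, groups)
  unname(comp["a"] / comp["abc"])
}

#' Pairwise F_ST with a permutation test
#'
#' Weir-Cockerham theta between two groups; significance from permuting
#' individuals between the groups:
#' `p = (1 + #(theta_perm >= theta_obs)) / (n_permutations + 1)`.
#'
#' @param g An [mlg_matrix()].
#' @param groups Two-level group label per row.
#' @param n_permutations Number of label permutations (the study used
#'   10,000).
#' @param seed Optional seed (RNG state restored).
#' @return A list `theta`, `p_value`, `n_permutations`.
#' @export
pairwise_fst <- function(g, groups, n_permutations = 10000L, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("pairwise_fst needs exactly 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >=2 individuals")
  run <- function() {
    obs <- wc_theta(g, groups)
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      if (wc_theta(g, sample(groups)) >= obs - 1e-12) ge <- ge + 1L
    }
    list(theta = obs, p_value = (1 + ge) / (n_permutations + 1),
         n_permutations = as.integer(n_permutations))
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

# Shared-allele counts for all pairs: returns list(shared, loci_shared)
# matrices (sum over loci of the pairwise multiset intersection, and the
# number of loci scored in both).
pairwise_sharing <- function(g) {
  n <- nrow(g)
  L <- ncol(g) / 2
  shared <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  loci_shared <- matrix(0L, n, n, dimnames = dimnames(shared))
  for (l in seq_len(L)) {
    a1 <- g[, 2 * l - 1]
    a2 <- g[, 2 * l]
    ok <- !is.na(a1)
    both <- outer(ok, ok, `&`)
    # multiset intersection of pairs {a,b},{c,d}:
    # sum over distinct alleles of min(count_i, count_j)
    s <- matrix(0L, n, n)
    for (i in which(ok)) {
      ai <- c(a1[i], a2[i])
      tot <- rep(0L, n)
      for (x in unique(ai)) {
        ci <- sum(ai == x)
        cj <- (a1 == x) + (a2 == x)
        cj[!ok] <- 0L
        tot <- tot + pmin(ci, cj)
      }
      s[i, ] <- tot
    }
    s[!both] <- 0L
    shared <- shared + s
    loci_shared <- loci_shared + both
  }
  list(shared = shared, loci_shared = loci_shared)
}

#' Proportion-of-shared-alleles distance
#'
#' `D = 1 - sum_l(shared_l) / (2 * L_shared)` over loci scored in both
#' members of a pair, with `shared_l` the multiset intersection (0, 1 or 2)
#' of the two allele pairs. Pairs with no shared scored loci are `NA` and
#' reported in attribute `"undefined_pairs"`.
#'
#' @param g An [mlg_matrix()].
#' @return A symmetric distance matrix with zero diagonal, values in [0,1].
#' @export
shared_allele_distance <- function(g) {
  ps <- pairwise_sharing(g)
  d <- 1 - ps$shared / (2 * ps$loci_shared)
  d[ps$loci_shared == 0] <- NA_real_
  diag(d) <- 0
  undef <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  attr(d, "undefined_pairs") <- undef
  check_distance_matrix(d)
  d
}

#' Kosman-Leonard genetic dissimilarity
#'
#' Per locus `d_l = 1 - shared_l / 2` (0, 0.5 or 1); the pair dissimilarity
#' is the mean of `d_l` over loci scored in both. For complete diploid data
#' this equals [shared_allele_distance()] exactly.
#'
#' @param g An [mlg_matrix()].
#' @return A symmetric distance matrix with zero diagonal.
#' @export
kosman_dissimilarity <- function(g) {
  n <- nrow(g)
  L <- ncol(g) / 2
  dsum <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  nl <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    gl <- g[, c(2 * l - 1, 2 * l), drop = FALSE]
    ok <- !is.na(gl[, 1])
    sub <- pairwise_sharing(gl)
    dl <- 1 - sub$shared / 2
    both <- outer(ok, ok, `&`)
    dl[!both] <- 0
    dsum <- dsum + dl
    nl <- nl + both
  }
  d <- dsum / nl
  d[nl == 0] <- NA_real_
  diag(d) <- 0
  check_distance_matrix(d)
  d
}

check_distance_matrix <- function(d) {
  stopifnot(isTRUE(all.equal(d, t(d))), all(diag(d) == 0))
  invisible(d)
}

#' Unrooted neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); negative branch lengths are
#' clamped to zero with the negative excess transferred to the adjacent
#' branch so that path lengths between leaves are preserved where possible.
#'
#' @param d A symmetric distance matrix (no `NA`s).
#' @return An \pkg{ape} `phylo` object; use [ape::write.tree()] for newick.
#' @export
neighbor_joining <- function(d) {
  if (any(is.na(d))) stop("distance matrix contains undefined entries")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    excess <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    child <- tr$edge[e, 2]
    adj <- which(tr$edge[, 1] == child)
    if (length(adj)) tr$edge.length[adj] <- tr$edge.length[adj] + excess
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Principal component analysis of multilocus genotypes
#'
#' Individuals are scored as allele dosages (0/1/2 copies of each observed
#' allele); missing entries are imputed with the allele's mean dosage; the
#' matrix is column-centred and eigendecomposed.
#'
#' @param g An [mlg_matrix()].
#' @return A list `scores` (individuals x PCs), `explained` (proportion of
#'   variance per PC), `eigenvalues`, `total_variance`.
#' @export
pca_genotypes <- function(g) {
  if (nrow(g) < 3) stop("need at least 3 individuals")
  X <- allele_dosage_matrix(g)
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, colMeans(X))
  if (all(abs(X) < 1e-12)) stop("zero-variance genotype matrix")
  pc <- stats::prcomp(X, center = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x, explained = ev / sum(ev), eigenvalues = ev,
       total_variance = sum(ev))
}

# Individuals x alleles dosage matrix (NA where the locus is missing).
allele_dosage_matrix <- function(g) {
  L <- ncol(g) / 2
  locus_names <- sub("\\.1$", "", colnames(g)[seq(1, ncol(g), 2)])
  blocks <- lapply(seq_len(L), function(l) {
    a1 <- g[, 2 * l - 1]
    a2 <- g[, 2 * l]
    alleles <- sort(unique(stats::na.omit(c(a1, a2))))
    m <- vapply(alleles, function(al) (a1 == al) + (a2 == al),
                numeric(nrow(g)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(g))
    colnames(m) <- paste(locus_names[l], alleles, sep = ".")
    m
  })
  do.call(cbind, blocks)
}

#' Genetic dissimilarity versus geographic distance
#'
#' For every pair of genotyped samples: great-circle distance (m) and
#' Kosman dissimilarity, a running average of dissimilarity in a sliding
#' distance window, and a Mantel correlation (permutation p) between the
#' two matrices. Run on all genotyped samples (not unique individuals) so
#' resampling of mobile individuals is retained.
#'
#' @param g An [mlg_matrix()] (one row per sample).
#' @param lat,lon Coordinates per row of `g`.
#' @param window Sliding-window width in metres (default 20 km).
#' @param n_permutations Mantel permutations.
#' @return A list `pairs` (data frame `id1`, `id2`, `distance_m`,
#'   `dissimilarity`), `running` (data frame `distance_m`, `mean_dissim`),
#'   `mantel_r`, `mantel_p`, `n_skipped` (pairs without coordinates).
#' @export
dissimilarity_vs_distance <- function(g, lat, lon, window = 20000,
                                      n_permutations = 999) {
  n <- nrow(g)
  dd <- kosman_dissimilarity(g)
  geo <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- seq(i + 1, n)
    geo[i, j] <- geo[j, i] <- haversine_m(lat[i], lon[i], lat[j], lon[j])
  }
  ut <- upper.tri(dd)
  ok <- ut & !is.na(geo) & !outer(is.na(lat), is.na(lat), `|`) & !is.na(dd)
  idx <- which(ok, arr.ind = TRUE)
  pairs <- data.frame(
    id1 = rownames(g)[idx[, 1]], id2 = rownames(g)[idx[, 2]],
    distance_m = geo[ok], dissimilarity = dd[ok],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$distance_m), ]
  grid <- seq(0, max(pairs$distance_m), length.out = 200)
  running <- data.frame(
    distance_m = grid,
    mean_dissim = vapply(grid, function(x) {
      sel <- abs(pairs$distance_m - x) <= window / 2
      if (any(sel)) mean(pairs$dissimilarity[sel]) else NA_real_
    }, numeric(1)))
  complete <- !is.na(lat) & !is.na(lon)
  mr <- mp <- NA_real_
  if (sum(complete) >= 4 && !any(is.na(dd[complete, complete]))) {
    mt <- vegan::mantel(stats::as.dist(geo[complete, complete]),
                        stats::as.dist(dd[complete, complete]),
                        permutations = n_permutations)
    mr <- unname(mt$statistic)
    mp <- mt$signif
  }
  list(pairs = pairs, running = running, mantel_r = mr, mantel_p = mp,
       n_skipped = sum(ut) - nrow(pairs))
}

#' Gibbs sampler for the Bayesian admixture model
#'
#' The standard admixture model: each cluster has Dirichlet(1)-prior allele
#' frequencies per locus; each individual has membership proportions
#' `q ~ Dirichlet(alpha)` with fixed `alpha`; each gene copy carries a
#' latent cluster-of-origin updated by its conditional multinomial. Missing
#' loci are skipped. The model evidence proxy is
#' `lnP = mean(lnL) - var(lnL)/2` over post-burn-in sweeps, with `lnL` the
#' log-likelihood of the data given the current frequencies and memberships.
#'
#' @param g An [mlg_matrix()].
#' @param K Number of clusters (K = 1 runs with no latent structure).
#' @param sweeps Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before averaging.
#' @param alpha Admixture (Dirichlet) parameter: `"sample"` (default)
#'   updates it by a Metropolis step with a uniform prior on
#'   (0, `alpha_max`], which lets it grow under panmixia (collapsing the
#'   memberships to uniform) and shrink under real structure; a numeric
#'   value fixes it.
#' @param alpha_max Upper bound of the uniform prior on `alpha`.
#' @param seed Optional seed (RNG state restored).
#' @return A list of class `cluster_posterior`: `K`, `q_matrix` (posterior
#'   mean memberships, rows sum to 1), `log_likelihood_trace`,
#'   `lnP_estimate`.
#' @export
admixture_cluster <- function(g, K, sweeps = 6000L, burn_in = 2000L,
                              alpha = "sample", alpha_max = 10,
                              seed = NULL) {
  if (K < 1) stop("K must be >= 1")
  if (sweeps <= burn_in) stop("sweeps must exceed burn_in")
  sample_alpha <- identical(alpha, "sample")
  run <- function() {
    n <- nrow(g)
    L <- ncol(g) / 2
    # recode alleles per locus to 1..k_l
    codes <- matrix(NA_integer_, n, 2 * L)
    k_l <- integer(L)
    for (l in seq_len(L)) {
      al <- sort(unique(stats::na.omit(c(g[, 2 * l - 1], g[, 2 * l]))))
      k_l[l] <- length(al)
      codes[, 2 * l - 1] <- match(g[, 2 * l - 1], al)
      codes[, 2 * l] <- match(g[, 2 * l], al)
    }
    q <- matrix(1 / K, n, K)
    P <- lapply(seq_len(L), function(l)
      matrix(1 / k_l[l], K, k_l[l]))
    z <- array(1L, dim = c(n, 2 * L))
    a_cur <- if (sample_alpha) 1 else alpha
    # log density of the q rows under a symmetric Dirichlet(a)
    lp_alpha <- function(a, S) n * (lgamma(K * a) - K * lgamma(a)) +
      (a - 1) * S
    trace <- numeric(sweeps)
    q_acc <- matrix(0, n, K)
    n_acc <- 0L
    for (sw in seq_len(sweeps)) {
      # update latent origins and tally per-cluster allele counts
      counts_ik <- matrix(0, n, K)
      counts_P <- lapply(seq_len(L), function(l)
        matrix(0, K, k_l[l]))
      for (l in seq_len(L)) {
        for (cp in c(2 * l - 1, 2 * l)) {
          a <- codes[, cp]
          obs <- which(!is.na(a))
          if (!length(obs)) next
          if (K == 1) {
            zk <- rep(1L, length(obs))
          } else {
            pr <- q[obs, , drop = FALSE] *
              t(P[[l]][, a[obs], drop = FALSE])
            cum <- pr %*% upper.tri(diag(K), diag = TRUE)
            u <- stats::runif(length(obs)) * cum[, K]
            zk <- 1L + rowSums(cum[, -K, drop = FALSE] < u)
          }
          z[obs, cp] <- zk
          counts_ik[cbind(obs, zk)] <- counts_ik[cbind(obs, zk)] + 1
          cp_tab <- counts_P[[l]]
          for (kk in seq_len(K)) {
            sel <- a[obs][zk == kk]
            if (length(sel))
              cp_tab[kk, ] <- cp_tab[kk, ] + tabulate(sel, k_l[l])
          }
          counts_P[[l]] <- cp_tab
        }
      }
      # update q and P from their Dirichlet conditionals
      if (K == 1) {
        q[, 1] <- 1
      } else {
        gam <- matrix(stats::rgamma(n * K, shape = a_cur + counts_ik),
                      n, K)
        q <- gam / rowSums(gam)
        q <- pmax(q, 1e-12)
        q <- q / rowSums(q)
        if (sample_alpha) {
          S <- sum(log(q))
          prop <- a_cur + stats::rnorm(1, 0, 0.3)
          if (prop > 0 && prop <= alpha_max &&
              log(stats::runif(1)) < lp_alpha(prop, S) - lp_alpha(a_cur, S))
            a_cur <- prop
        }
      }
      for (l in seq_len(L)) {
        gam <- matrix(stats::rgamma(K * k_l[l],
                                    shape = 1 + counts_P[[l]]),
                      K, k_l[l])
        P[[l]] <- gam / rowSums(gam)
      }
      # log-likelihood given (P, q), marginal over origins
      ll <- 0
      for (l in seq_len(L)) {
        for (cp in c(2 * l - 1, 2 * l)) {
          a <- codes[, cp]
          obs <- which(!is.na(a))
          if (!length(obs)) next
          pr <- rowSums(q[obs, , drop = FALSE] *
                          t(P[[l]][, a[obs], drop = FALSE]))
          ll <- ll + sum(log(pr))
        }
      }
      trace[sw] <- ll
      if (sw > burn_in) {
        q_acc <- q_acc + q
        n_acc <- n_acc + 1L
      }
    }
    post <- trace[(burn_in + 1):sweeps]
    qm <- q_acc / n_acc
    rownames(qm) <- rownames(g)
    structure(list(K = as.integer(K), q_matrix = qm,
                   log_likelihood_trace = trace,
                   lnP_estimate = mean(post) - stats::var(post) / 2),
              class = "cluster_posterior")
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' @export
print.cluster_posterior <- function(x, ...) {
  cat("<cluster_posterior> K =", x$K,
      " lnP =", format(x$lnP_estimate, digits = 6), "\n")
  invisible(x)
}

#' Best-permutation assignment accuracy against known labels
#'
#' Resolves label switching by taking, over all permutations of cluster
#' labels, the maximum fraction of individuals whose modal cluster matches
#' their true group.
#'
#' @param q A q-matrix (individuals x K).
#' @param truth Integer/factor true group per individual (<= K levels).
#' @return The best-permutation accuracy in [0, 1].
#' @export
assignment_accuracy <- function(q, truth) {
  truth <- as.integer(as.factor(truth))
  K <- ncol(q)
  modal <- max.col(q)
  perms <- permutations_of(seq_len(K))
  best <- 0
  for (p in perms) best <- max(best, mean(p[modal] == truth))
  best
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}
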