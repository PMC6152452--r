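#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the GKM brown bear study design: 48 individuals, the
#' ten-locus panel with its observed allele counts (7-10 alleles per locus),
#' two weakly differentiated provinces (Balding-Nichols target F_ST 0.005),
#' male-biased detection (83.3% males), resampling of mobile bears, and
#' source-dependent genotyping failure calibrated to the study's published
#' success rates (poles 26.39%, rubbing trees 54.72%, barbed wire 83.33%,
#' hair traps 42.86%).
#'
#' @param n_individuals Number of true individuals.
#' @param loci Locus table (columns `locus`, `repeat_unit`, optionally
#'   `n_alleles`); defaults to [gkm_panel()].
#' @param allele_range Range the per-locus allele counts are drawn from when
#'   `loci$n_alleles` is absent.
#' @param dirichlet_concentration Concentration of the Dirichlet prior on
#'   ancestral allele frequencies.
#' @param inbreeding_f Within-population inbreeding coefficient used when
#'   drawing genotypes (probability both gene copies are identical by
#'   descent).
#' @param n_subpops Number of subpopulations.
#' @param subpop_share Proportions of individuals per subpopulation.
#' @param target_fst Balding-Nichols divergence parameter.
#' @param sex_ratio_male Probability an individual is male.
#' @param samples_per_individual Poisson mean of *extra* samples per
#'   individual (each individual yields 1 + Poisson(mean) samples).
#' @param source_mix Probability vector over noninvasive sources.
#' @param dropout_rate Per-gene-copy, per-replicate allelic dropout
#'   probability.
#' @param false_allele_rate Per-locus, per-replicate probability that one
#'   gene copy is misread as a random other allele of the locus.
#' @param stutter_rate Per-gene-copy probability of a +-1 repeat-unit size
#'   shift (direction equiprobable).
#' @param locus_failure_rate Named per-source vector of per-locus,
#'   per-replicate amplification-failure probabilities; `NULL` calibrates
#'   them from `success_targets` (see [calibrate_locus_failure()]).
#' @param success_targets Named per-source target proportions of samples
#'   passing the >=8-loci consensus filter; defaults are the study's
#'   published rates.
#' @param sry_misamplification Probability a female replicate spuriously
#'   amplifies SRY.
#' @param sry_dropout Probability a male replicate fails to amplify SRY.
#' @param years Candidate collection years.
#' @param jitter_km SD of the spatial scatter of samples around their
#'   subpopulation centre, in km.
#' @param subpop_centers Data frame of `lat`/`lon` centres (one row per
#'   subpopulation); defaults place two centres ~170 km apart as in the
#'   study region.
#' @param seed Integer seed giving full determinism.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 48L,
                       loci = gkm_panel(),
                       allele_range = c(7L, 10L),
                       dirichlet_concentration = 1,
                       inbreeding_f = 0,
                       n_subpops = 2L,
                       subpop_share = NULL,
                       target_fst = 0.005,
                       sex_ratio_male = 0.833,
                       samples_per_individual = 2.2,
                       source_mix = c(pole = 72, tree = 53,
                                      barbed_wire = 12, hair_trap = 7) / 144,
                       dropout_rate = 0.01,
                       false_allele_rate = 0.002,
                       stutter_rate = 0.002,
                       locus_failure_rate = NULL,
                       success_targets = c(pole = 0.2639, tree = 0.5472,
                                           barbed_wire = 0.8333,
                                           hair_trap = 0.4286,
                                           capture_hair = 0.90, tissue = 1),
                       sry_misamplification = 0.01,
                       sry_dropout = 0.05,
                       years = 2008:2014,
                       jitter_km = 25,
                       subpop_centers = NULL,
                       seed = 1L) {
  probs <- c(inbreeding_f, target_fst, sex_ratio_male, dropout_rate,
             false_allele_rate, stutter_rate, sry_misamplification,
             sry_dropout, source_mix)
  if (any(probs < 0 | probs > 1)) stop("probability parameters must be in [0,1]")
  if (abs(sum(source_mix) - 1) > 1e-8) stop("source_mix must sum to 1")
  if (target_fst >= 0.5) stop("target_fst must be in [0, 0.5)")
  if (is.null(subpop_share)) subpop_share <- rep(1 / n_subpops, n_subpops)
  if (is.null(subpop_centers)) {
    subpop_centers <- data.frame(
      lat = c(41.20, 40.25, 40.8, 41.6, 40.0, 41.9)[seq_len(n_subpops)],
      lon = c(41.80, 40.20, 42.5, 40.9, 41.5, 42.9)[seq_len(n_subpops)]
    )
  }
  rm(probs)
  structure(as.list(environment()), class = "sim_config")
}

# Allele size ladders per locus: realistic fragment sizes on the
# repeat-unit grid, distinct base sizes per locus.
locus_allele_sizes <- function(loci, counts) {
  lapply(seq_len(nrow(loci)), function(l)
    as.integer(100 + 11 * (l - 1) +
                 loci$repeat_unit[l] * (0:(counts[l] - 1))))
}

#' Simulate per-subpopulation allele frequencies
#'
#' Ancestral frequencies per locus are Dirichlet(concentration); each
#' subpopulation draws its frequency vector from the Balding-Nichols
#' construction, Dirichlet(p * (1 - F) / F) with F = `target_fst`, so that
#' E(p_sub) = p and Var(p_sub) = F p (1 - p). With `target_fst = 0` every
#' subpopulation equals the ancestral vector. Uses the current RNG stream.
#'
#' @param config A [sim_config()].
#' @return A list with `loci`, `sizes` (allele size ladders), `ancestral`
#'   (per-locus frequency vectors named by allele size) and `subpop` (list of
#'   per-locus vectors per subpopulation).
#' @export
simulate_allele_frequencies <- function(config) {
  loci <- config$loci
  counts <- if ("n_alleles" %in% names(loci)) loci$n_alleles else
    sample(seq(config$allele_range[1], config$allele_range[2]),
           nrow(loci), replace = TRUE)
  sizes <- locus_allele_sizes(loci, counts)
  ancestral <- lapply(seq_len(nrow(loci)), function(l) {
    stats::setNames(rdirichlet1(rep(config$dirichlet_concentration,
                                    counts[l])), sizes[[l]])
  })
  f <- config$target_fst
  subpop <- lapply(seq_len(config$n_subpops), function(s) {
    lapply(ancestral, function(p) {
      if (f <= 0) p else stats::setNames(rdirichlet1(p * (1 - f) / f),
                                         names(p))
    })
  })
  list(loci = loci, sizes = sizes, ancestral = ancestral, subpop = subpop)
}

#' Simulate true multilocus genotypes
#'
#' At each locus an individual is autozygous with probability
#' `inbreeding_f` (one allele drawn and duplicated); otherwise two alleles
#' are drawn independently from its subpopulation's frequencies.
#'
#' @param freqs Output of [simulate_allele_frequencies()].
#' @param config A [sim_config()].
#' @return A list (`truth`) with `individuals` (id, subpop, sex),
#'   `genotypes` (n x 2L [mlg_matrix()] of true allele sizes) and `loci`.
#' @export
simulate_individuals <- function(freqs, config) {
  n <- config$n_individuals
  shares <- round(config$subpop_share * n)
  shares[1] <- n - sum(shares[-1])
  subpop <- rep(seq_along(shares), shares)
  loci <- freqs$loci
  L <- nrow(loci)
  g <- matrix(NA_integer_, n, 2 * L,
              dimnames = list(sprintf("B%03d", seq_len(n)),
                              paste(rep(loci$locus, each = 2), 1:2,
                                    sep = ".")))
  for (l in seq_len(L)) {
    for (s in seq_along(shares)) {
      idx <- which(subpop == s)
      if (!length(idx)) next
      p <- freqs$subpop[[s]][[l]]
      sz <- as.integer(names(p))
      a1 <- sz[sample.int(length(sz), length(idx), replace = TRUE, prob = p)]
      a2 <- sz[sample.int(length(sz), length(idx), replace = TRUE, prob = p)]
      ibd <- stats::runif(length(idx)) < config$inbreeding_f
      a2[ibd] <- a1[ibd]
      g[idx, 2 * l - 1] <- pmin(a1, a2)
      g[idx, 2 * l] <- pmax(a1, a2)
    }
  }
  list(
    individuals = data.frame(
      individual_id = rownames(g),
      subpop = subpop,
      sex = ifelse(stats::runif(n) < config$sex_ratio_male, "male", "female"),
      stringsAsFactors = FALSE
    ),
    genotypes = g,
    loci = loci
  )
}

# --- vectorised replicate-error engine -------------------------------------
# G1, G2: m x L matrices of true alleles (canonical order). Returns one
# replicate per row with locus failure q, per-copy dropout, per-copy stutter
# (+-1 repeat unit) and per-locus false alleles injected, plus error masks.
sim_replicate_matrix <- function(G1, G2, ru, sizes, q, dropout, false_rate,
                                 stutter) {
  m <- nrow(G1)
  L <- ncol(G1)
  runifm <- function() matrix(stats::runif(m * L), m, L)
  fail <- runifm() < q
  d1 <- runifm() < dropout
  d2 <- runifm() < dropout
  A1 <- ifelse(d1 & !d2, G2, G1)
  A2 <- ifelse(d2 & !d1, G1, G2)
  gone <- fail | (d1 & d2)
  RU <- matrix(ru, m, L, byrow = TRUE)
  s1 <- runifm() < stutter
  s2 <- runifm() < stutter
  dir1 <- matrix(sample(c(-1L, 1L), m * L, replace = TRUE), m, L)
  dir2 <- matrix(sample(c(-1L, 1L), m * L, replace = TRUE), m, L)
  A1 <- A1 + ifelse(s1, dir1 * RU, 0L)
  A2 <- A2 + ifelse(s2, dir2 * RU, 0L)
  fa <- matrix(FALSE, m, L)
  for (l in seq_len(L)) {
    hit <- which(stats::runif(m) < false_rate)
    if (!length(hit)) next
    fa[hit, l] <- TRUE
    copy <- sample(c(1L, 2L), length(hit), replace = TRUE)
    newa <- sizes[[l]][sample.int(length(sizes[[l]]), length(hit),
                                  replace = TRUE)]
    i1 <- hit[copy == 1L]
    i2 <- hit[copy == 2L]
    A1[i1, l] <- newa[copy == 1L]
    A2[i2, l] <- newa[copy == 2L]
  }
  A1[gone] <- NA_integer_
  A2[gone] <- NA_integer_
  swap <- !is.na(A1) & A1 > A2
  tmp <- A1[swap]
  A1[swap] <- A2[swap]
  A2[swap] <- tmp
  list(a1 = A1, a2 = A2,
       dropout = (d1 | d2) & !gone,
       stutter = (s1 | s2) & !gone,
       false_allele = fa & !gone,
       failed = gone)
}

# Consensus of two replicates, vectorised over samples x loci.
pair_consensus_matrix <- function(r1, r2) {
  miss1 <- is.na(r1$a1)
  miss2 <- is.na(r2$a1)
  agree <- !miss1 & !miss2 & r1$a1 == r2$a1 & r1$a2 == r2$a2
  mismatch <- !miss1 & !miss2 & !agree
  a1 <- ifelse(miss1, r2$a1, r1$a1)
  a2 <- ifelse(miss1, r2$a2, r1$a2)
  none <- mismatch | (miss1 & miss2)
  a1[none] <- NA_integer_
  a2[none] <- NA_integer_
  list(a1 = a1, a2 = a2, mismatch = mismatch, single = xor(miss1, miss2))
}

# Simulated probability that a sample passes the two-round replicate rule
# and the >=min_loci coverage filter, for a per-locus failure rate q.
simulated_success_prob <- function(q, config, freqs, m = 3000L,
                                   min_loci = 8L) {
  L <- nrow(freqs$loci)
  ru <- freqs$loci$repeat_unit
  G1 <- G2 <- matrix(NA_integer_, m, L)
  for (l in seq_len(L)) {
    p <- freqs$ancestral[[l]]
    sz <- as.integer(names(p))
    a <- sz[sample.int(length(sz), m, replace = TRUE, prob = p)]
    b <- sz[sample.int(length(sz), m, replace = TRUE, prob = p)]
    G1[, l] <- pmin(a, b)
    G2[, l] <- pmax(a, b)
  }
  reps <- replicate(4, sim_replicate_matrix(
    G1, G2, ru, freqs$sizes, q, config$dropout_rate,
    config$false_allele_rate, config$stutter_rate), simplify = FALSE)
  c1 <- pair_consensus_matrix(reps[[1]], reps[[2]])
  c2 <- pair_consensus_matrix(reps[[3]], reps[[4]])
  use2 <- rowSums(c1$mismatch) > 0
  discarded <- use2 & rowSums(c2$mismatch) > 0
  scored <- ifelse(use2, rowSums(!is.na(c2$a1)), rowSums(!is.na(c1$a1)))
  mean(!discarded & scored >= min_loci)
}

#' Calibrate per-locus failure rates to target genotyping success
#'
#' Solves, by bisection, for the per-locus per-replicate amplification
#' failure probability `q` such that a sample run through the two-round
#' replicate rule and the >=8-loci filter succeeds with the target
#' probability, given the configured dropout/stutter/false-allele rates.
#' Monte-Carlo evaluations use common random numbers under a sub-seed
#' derived from `config$seed`, so the result is deterministic.
#'
#' @param target Target success proportion in (0, 1].
#' @param config A [sim_config()].
#' @param freqs Output of [simulate_allele_frequencies()].
#' @param m Monte-Carlo samples per evaluation.
#' @param min_loci Coverage threshold.
#' @return The calibrated failure probability.
#' @export
calibrate_locus_failure <- function(target, config, freqs, m = 3000L,
                                    min_loci = 8L) {
  cal_seed <- (config$seed %% 100000L) * 17L + 11L
  eval_q <- function(q) with_local_seed(cal_seed, simulated_success_prob(
    q, config, freqs, m = m, min_loci = min_loci))
  if (eval_q(0) <= target) return(0)
  lo <- 0
  hi <- 0.98
  for (it in 1:18) {
    mid <- (lo + hi) / 2
    if (eval_q(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

resolve_failure_rates <- function(config, freqs) {
  if (!is.null(config$locus_failure_rate)) return(config$locus_failure_rate)
  vapply(config$success_targets, function(t)
    calibrate_locus_failure(t, config, freqs), numeric(1))
}

# Build a bear_dataset from a sampling plan (one row per sample:
# sample_id, individual_id, source, province, year, lat, lon).
build_samples <- function(plan, truth, freqs, config, failure_rates) {
  loci <- freqs$loci
  L <- nrow(loci)
  ru <- loci$repeat_unit
  idx <- match(plan$individual_id, truth$individuals$individual_id)
  G1 <- truth$genotypes[idx, seq(1, 2 * L, by = 2), drop = FALSE]
  G2 <- truth$genotypes[idx, seq(2, 2 * L, by = 2), drop = FALSE]

  rep_rows <- list()
  err_rows <- list()
  emit <- function(ids, r, eng, rows) {
    data.frame(sample_id = rep(ids, times = L),
               replicate = r,
               locus = rep(loci$locus, each = length(ids)),
               a1 = as.vector(eng$a1[rows, , drop = FALSE]),
               a2 = as.vector(eng$a2[rows, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }
  is_tissue <- plan$source == "tissue"
  if (any(is_tissue)) {
    ti <- which(is_tissue)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      sample_id = rep(plan$sample_id[ti], times = L),
      replicate = 1L,
      locus = rep(loci$locus, each = length(ti)),
      a1 = as.vector(G1[ti, , drop = FALSE]),
      a2 = as.vector(G2[ti, , drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  for (src in setdiff(unique(plan$source), "tissue")) {
    rows <- which(plan$source == src)
    q <- unname(failure_rates[src])
    if (is.na(q)) stop("no failure rate for source ", src)
    reps <- replicate(4, sim_replicate_matrix(
      G1[rows, , drop = FALSE], G2[rows, , drop = FALSE], ru, freqs$sizes,
      q, config$dropout_rate, config$false_allele_rate,
      config$stutter_rate), simplify = FALSE)
    c1 <- pair_consensus_matrix(reps[[1]], reps[[2]])
    need2 <- rowSums(c1$mismatch) > 0
    ids <- plan$sample_id[rows]
    for (r in 1:2)
      rep_rows[[length(rep_rows) + 1L]] <-
        emit(ids, r, reps[[r]], seq_along(rows))
    if (any(need2)) {
      for (r in 3:4)
        rep_rows[[length(rep_rows) + 1L]] <-
          emit(ids[need2], r, lapply(reps[[r]], function(x)
            x[need2, , drop = FALSE]), seq_len(sum(need2)))
    }
    nrep <- ifelse(need2, 4L, 2L)
    err_rows[[length(err_rows) + 1L]] <- data.frame(
      sample_id = ids,
      n_replicates = nrep,
      n_dropout = rowSums(Reduce(`+`, lapply(reps[1:2], `[[`, "dropout"))) +
        need2 * rowSums(Reduce(`+`, lapply(reps[3:4], `[[`, "dropout"))),
      n_stutter = rowSums(Reduce(`+`, lapply(reps[1:2], `[[`, "stutter"))) +
        need2 * rowSums(Reduce(`+`, lapply(reps[3:4], `[[`, "stutter"))),
      n_false_allele =
        rowSums(Reduce(`+`, lapply(reps[1:2], `[[`, "false_allele"))) +
        need2 * rowSums(Reduce(`+`, lapply(reps[3:4], `[[`, "false_allele"))),
      n_locus_failure =
        rowSums(Reduce(`+`, lapply(reps[1:2], `[[`, "failed"))) +
        need2 * rowSums(Reduce(`+`, lapply(reps[3:4], `[[`, "failed"))),
      stringsAsFactors = FALSE)
  }
  replicates <- do.call(rbind, rep_rows)
  replicates <- replicates[order(match(replicates$sample_id, plan$sample_id),
                                 replicates$replicate), ]
  rownames(replicates) <- NULL

  # SRY flags per replicate
  key <- unique(replicates[c("sample_id", "replicate")])
  sex <- truth$individuals$sex[match(
    plan$individual_id[match(key$sample_id, plan$sample_id)],
    truth$individuals$individual_id)]
  male <- sex == "male"
  pos <- logical(nrow(key))
  pos[male] <- stats::runif(sum(male)) >= config$sry_dropout
  pos[!male] <- stats::runif(sum(!male)) < config$sry_misamplification
  sry <- data.frame(key, sry_positive = pos, stringsAsFactors = FALSE)

  samples <- plan[c("sample_id", "province", "source", "year", "lat", "lon")]
  ds <- bear_dataset(samples, replicates, loci = loci, sry = sry)
  errors <- if (length(err_rows)) do.call(rbind, err_rows) else NULL
  list(dataset = ds, errors = errors)
}

#' Simulate field sampling of a true population
#'
#' Each individual yields `1 + Poisson(samples_per_individual)` samples with
#' sources drawn from `source_mix`, coordinates jittered around the
#' individual's subpopulation centre, and two (or, after a first-round
#' mismatch, four) replicate genotypes carrying injected dropout, stutter,
#' false-allele and locus-failure errors at source-specific rates. SRY flags
#' reflect true sex subject to the configured dropout/misamplification.
#'
#' @param truth Output of [simulate_individuals()].
#' @param freqs Output of [simulate_allele_frequencies()].
#' @param config A [sim_config()].
#' @return A list with `dataset` (a [bear_dataset()]), `truth` (with
#'   `sample_map` added) and `errors` (per-sample injected-error counts).
#' @export
simulate_sampling <- function(truth, freqs, config) {
  failure_rates <- resolve_failure_rates(config, freqs)
  n <- nrow(truth$individuals)
  n_samp <- 1L + stats::rpois(n, config$samples_per_individual)
  ind <- rep(truth$individuals$individual_id, n_samp)
  m <- length(ind)
  src <- names(config$source_mix)[sample.int(
    length(config$source_mix), m, replace = TRUE,
    prob = config$source_mix)]
  sp <- truth$individuals$subpop[match(ind, truth$individuals$individual_id)]
  jit <- config$jitter_km / 111
  plan <- data.frame(
    sample_id = sprintf("S%04d", seq_len(m)),
    individual_id = ind,
    source = src,
    province = paste0("P", sp),
    year = sample(config$years, m, replace = TRUE),
    lat = config$subpop_centers$lat[sp] + stats::rnorm(m, 0, jit),
    lon = config$subpop_centers$lon[sp] + stats::rnorm(m, 0, jit),
    stringsAsFactors = FALSE
  )
  built <- build_samples(plan, truth, freqs, config, failure_rates)
  truth$sample_map <- plan[c("sample_id", "individual_id")]
  list(dataset = built$dataset, truth = truth, errors = built$errors)
}

#' Simulate a complete dataset from a configuration
#'
#' Top-level generator: seeds the RNG from `config$seed` (full determinism:
#' the same seed yields a bit-identical dataset), then draws frequencies,
#' true genotypes and the sampling/error process.
#'
#' @param config A [sim_config()].
#' @return As [simulate_sampling()], plus `freqs` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  freqs <- simulate_allele_frequencies(config)
  truth <- simulate_individuals(freqs, config)
  out <- simulate_sampling(truth, freqs, config)
  out$freqs <- freqs
  out$config <- config
  out
}

#' Generate a study-like synthetic dataset
#'
#' Reproduces the GKM study's sampling frame exactly: 154 samples (147 hair
#' of which 3 invasive capture hairs, 7 tissue), two provinces (Artvin-like:
#' 42 individuals, 127 hair + 7 tissue samples; Bayburt-like: 6 individuals,
#' 20 hair samples), one mobile individual sampled in both provinces
#' (~160 km apart), source counts 72/53/12/7 (poles/trees/barbed wire/hair
#' traps), hair collection years with the study's margins (2008-2014), and
#' per-source genotyping success calibrated to the published rates.
#'
#' @param seed Integer seed.
#' @param config Optional [sim_config()] override (its `seed` is replaced).
#' @return A list with `dataset`, `truth` (including `sample_map`),
#'   `errors`, `freqs`, `config`.
#' @export
generate_study_like_dataset <- function(seed = 1L, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = as.integer(seed))
  config$seed <- as.integer(seed)
  config$n_individuals <- 48L
  config$n_subpops <- 2L
  config$subpop_share <- c(42, 6) / 48
  set.seed(config$seed)

  freqs <- simulate_allele_frequencies(config)
  truth <- simulate_individuals(freqs, config)
  # subpop 1 = Artvin-like (individuals 1..42), subpop 2 = Bayburt-like
  provinces <- c("Artvin", "Bayburt")
  mobile <- truth$individuals$individual_id[1]
  artvin_ids <- truth$individuals$individual_id[truth$individuals$subpop == 1]
  bayburt_ids <- truth$individuals$individual_id[truth$individuals$subpop == 2]

  # Artvin: 7 tissue, 3 capture hairs, 60 poles, 45 trees, 12 barbed wire,
  # 7 hair traps; Bayburt: 12 poles, 8 trees (all 2012).
  artvin_sources <- c(rep("tissue", 7), rep("capture_hair", 3),
                      rep("pole", 60), rep("tree", 45),
                      rep("barbed_wire", 12), rep("hair_trap", 7))
  bayburt_sources <- c(rep("pole", 12), rep("tree", 8))
  artvin_hair_years <- sample(rep(c(2008L, 2009L, 2010L, 2011L, 2012L, 2014L),
                                  c(34, 15, 27, 30, 12, 9)))
  tissue_years <- c(2010L, 2010L, 2010L, 2011L, 2011L, 2011L, 2011L)

  tissue_owners <- sample(setdiff(artvin_ids, mobile), 7)
  n_art_hair <- length(artvin_sources) - 7L
  art_hair_owner <- c(artvin_ids,
                      sample(artvin_ids, n_art_hair - length(artvin_ids),
                             replace = TRUE))
  art_hair_owner <- sample(art_hair_owner)
  bay_owner <- c(mobile, bayburt_ids,
                 sample(bayburt_ids, length(bayburt_sources) - 1L -
                          length(bayburt_ids), replace = TRUE))
  bay_owner <- sample(bay_owner)

  plan <- data.frame(
    sample_id = sprintf("S%04d", seq_len(154L)),
    individual_id = c(tissue_owners, art_hair_owner, bay_owner),
    source = c(rep("tissue", 7), artvin_sources[-(1:7)], bayburt_sources),
    province = c(rep(provinces[1], 134), rep(provinces[2], 20)),
    year = c(tissue_years, artvin_hair_years, rep(2012L, 20)),
    stringsAsFactors = FALSE
  )
  centre <- config$subpop_centers[c(rep(1, 134), rep(2, 20)), ]
  jit <- config$jitter_km / 111
  plan$lat <- centre$lat + stats::rnorm(154, 0, jit)
  plan$lon <- centre$lon + stats::rnorm(154, 0, jit)

  failure_rates <- resolve_failure_rates(config, freqs)
  built <- build_samples(plan, truth, freqs, config, failure_rates)
  truth$sample_map <- plan[c("sample_id", "individual_id")]
  list(dataset = built$dataset, truth = truth, errors = built$errors,
       freqs = freqs, config = config,
       failure_rates = failure_rates)
}

#' Compare identified individuals with the simulation truth
#'
#' A truth individual is *detectable* when at least one of its samples
#' survives genotyping; it is *recovered* when at least one identified
#' individual consists purely of its samples. A *lump* is an identified
#' individual mixing samples of several truth individuals; a *split* is a
#' detectable truth individual whose samples land in more than one
#' identified individual.
#'
#' @param ind A `bear_individuals` object ([cluster_samples()]).
#' @param truth Truth list with `sample_map`.
#' @return A list: `n_detectable`, `n_recovered`, `recovery_rate`,
#'   `n_split`, `n_lump`.
#' @export
compare_to_truth <- function(ind, truth) {
  map <- truth$sample_map
  mem <- ind$membership
  mem$truth_id <- map$individual_id[match(mem$sample_id, map$sample_id)]
  by_cluster <- split(mem$truth_id, mem$individual_id)
  pure <- vapply(by_cluster, function(t) length(unique(t)) == 1, logical(1))
  n_lump <- sum(!pure)
  detectable <- unique(mem$truth_id)
  by_truth <- split(mem$individual_id, mem$truth_id)
  n_split <- sum(vapply(by_truth, function(cl) length(unique(cl)) > 1,
                        logical(1)))
  recovered <- vapply(detectable, function(t) {
    cl <- unique(by_truth[[t]])
    any(pure[cl])
  }, logical(1))
  list(n_detectable = length(detectable),
       n_recovered = sum(recovered),
       recovery_rate = mean(recovered),
       n_split = n_split,
       n_lump = n_lump)
}
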