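# Size of the multiset intersection of two allele pairs (0, 1 or 2).
pair_shared <- function(p1, p2) {
  s <- 0L
  used <- c(FALSE, FALSE)
  for (a in p1) {
    hit <- which(!used & p2 == a)
    if (length(hit)) {
      used[hit[1]] <- TRUE
      s <- s + 1L
    }
  }
  s
}

#' Count allele mismatches between two multilocus genotypes
#'
#' Per locus the mismatch count is 2 minus the size of the maximal multiset
#' intersection of the two allele pairs; loci missing in either genotype
#' contribute 0 mismatches (wildcard) but are recorded as missing-overlap.
#'
#' @param g1,g2 Loci x 2 genotype matrices ([mlg()]) over the same locus set.
#' @return A list with `total` (integer) and `detail` (data frame with
#'   columns `locus`, `n_mismatch`, `missing_overlap`).
#' @export
genotype_mismatch_count <- function(g1, g2) {
  loci <- rownames(g1)
  if (is.null(loci) || !identical(sort(loci), sort(rownames(g2))))
    stop("genotypes must share the same locus set")
  g2 <- g2[loci, , drop = FALSE]
  n <- integer(length(loci))
  missing_overlap <- logical(length(loci))
  for (l in seq_along(loci)) {
    if (is.na(g1[l, 1]) || is.na(g2[l, 1])) {
      missing_overlap[l] <- is.na(g1[l, 1]) != is.na(g2[l, 1]) ||
        is.na(g1[l, 1])
      n[l] <- 0L
    } else {
      n[l] <- 2L - pair_shared(g1[l, ], g2[l, ])
    }
  }
  list(total = sum(n),
       detail = data.frame(locus = loci, n_mismatch = n,
                           missing_overlap = missing_overlap,
                           stringsAsFactors = FALSE))
}

#' Classify a pair of genotypes as the same or distinct individuals
#'
#' Applies the study's matching rule: genotypes are assigned to the same
#' individual when they differ by at most two alleles and every difference
#' can be attributed to a recognised genotyping artifact:
#' * `dropout` — one genotype heterozygous, the other homozygous for the
#'   *smaller* of its two alleles (large-allele dropout: long fragments
#'   amplify worse);
#' * `size_shift` — the unshared alleles differ by exactly one repeat unit
#'   (PCR stutter);
#' * `missing_data` — the locus is missing in exactly one genotype
#'   (contributes no allele mismatch but is recorded).
#' Any other difference is `unexplained` and forces a `distinct` verdict.
#'
#' @param g1,g2 Loci x 2 genotype matrices over the same locus set.
#' @param loci Locus table with `locus` and `repeat_unit` columns.
#' @param max_mismatch Maximum total allele mismatches for a `same` verdict.
#' @return A list of class `pair_classification`: `n_mismatch_alleles`,
#'   `attributions` (data frame locus/attribution), `verdict`.
#' @export
classify_pair <- function(g1, g2, loci, max_mismatch = 2L) {
  mm <- genotype_mismatch_count(g1, g2)
  ru <- stats::setNames(loci$repeat_unit, loci$locus)
  det <- mm$detail
  attr_rows <- list()
  for (i in seq_len(nrow(det))) {
    lc <- det$locus[i]
    if (det$missing_overlap[i] &&
        xor(is.na(g1[lc, 1]), is.na(g2[lc, 1]))) {
      attr_rows[[length(attr_rows) + 1L]] <-
        data.frame(locus = lc, attribution = "missing_data",
                   stringsAsFactors = FALSE)
      next
    }
    if (det$n_mismatch[i] == 0L) next
    a <- g1[lc, ]
    b <- g2[lc, ]
    attribution <- "unexplained"
    if (det$n_mismatch[i] == 1L) {
      het <- if (a[1] != a[2] && b[1] == b[2]) list(het = a, hom = b)
             else if (b[1] != b[2] && a[1] == a[2]) list(het = b, hom = a)
             else NULL
      if (!is.null(het) && het$hom[1] == min(het$het))
        attribution <- "dropout"
      else {
        unshared <- unshared_alleles(a, b)
        if (length(unshared) == 2 &&
            abs(unshared[1] - unshared[2]) == ru[lc])
          attribution <- "size_shift"
      }
    }
    attr_rows[[length(attr_rows) + 1L]] <-
      data.frame(locus = lc, attribution = attribution,
                 stringsAsFactors = FALSE)
  }
  attributions <- if (length(attr_rows)) do.call(rbind, attr_rows)
    else data.frame(locus = character(0), attribution = character(0))
  verdict <- if (mm$total <= max_mismatch &&
                 !any(attributions$attribution == "unexplained"))
    "same" else "distinct"
  structure(list(n_mismatch_alleles = mm$total, attributions = attributions,
                 verdict = verdict),
            class = "pair_classification")
}

# The one allele of each pair left out of the maximal multiset matching.
unshared_alleles <- function(a, b) {
  a_left <- as.integer(a)
  b_left <- as.integer(b)
  for (x in a) {
    i <- match(x, b_left)
    if (!is.na(i)) {
      b_left <- b_left[-i]
      a_left <- a_left[-match(x, a_left)]
    }
  }
  c(a_left[1], b_left[1])
}

#' Cluster samples into unique individuals
#'
#' Builds a graph over retained samples with an edge for every pair whose
#' [classify_pair()] verdict is `same`, and takes connected components as
#' individuals. Components containing a pairwise `distinct` verdict
#' (non-transitive chaining) are flagged and split by removing their
#' weakest edges (largest mismatch count) until consistent. The consolidated
#' genotype prefers, per locus, confirmed heterozygote calls over
#' dropout-suspect homozygotes and non-missing over missing. Individual
#' numbering is deterministic by first (alphabetical) member sample id.
#'
#' @param ds A [bear_dataset()] whose samples carry consensus genotypes
#'   (tissue samples included).
#' @param max_mismatch Matching threshold (the study used 2).
#' @return A list of class `bear_individuals` with `individuals` (summary
#'   data frame), `membership` (sample_id -> individual_id), `genotypes`
#'   (long consolidated calls), `loci`, and `flagged_components`.
#' @export
cluster_samples <- function(ds, max_mismatch = 2L) {
  calls <- consensus_calls(ds)
  ids <- sort(unique(calls$sample_id))
  loci <- ds$loci
  gl <- lapply(ids, function(sid) mlg(calls[calls$sample_id == sid, ], loci))
  names(gl) <- ids
  n <- length(ids)
  edges <- list()
  verdicts <- matrix("", n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pc <- classify_pair(gl[[i]], gl[[j]], loci, max_mismatch)
      verdicts[i, j] <- verdicts[j, i] <- pc$verdict
      if (pc$verdict == "same")
        edges[[length(edges) + 1L]] <-
          data.frame(from = ids[i], to = ids[j],
                     n_mismatch = pc$n_mismatch_alleles,
                     stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
    else data.frame(from = character(0), to = character(0),
                    n_mismatch = integer(0))

  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = ids)
  flagged <- character(0)
  repeat {
    comp <- igraph::components(g)$membership
    bad <- NULL
    for (k in unique(comp)) {
      members <- names(comp)[comp == k]
      if (length(members) < 2) next
      pairs <- utils::combn(members, 2)
      conflict <- any(verdicts[t(pairs)] == "distinct")
      if (conflict) { bad <- k; flagged <- union(flagged, members); break }
    }
    if (is.null(bad)) break
    members <- names(comp)[comp == bad]
    within <- edges$from %in% members & edges$to %in% members
    # weakest edge = least concordant surviving link
    w <- which(within)[which.max(edges$n_mismatch[within])]
    g <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, c(edges$from[w], edges$to[w])))
    edges <- edges[-w, , drop = FALSE]
  }
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- groups[order(vapply(groups, function(m) sort(m)[1], character(1)))]
  ind_ids <- sprintf("IND%03d", seq_along(groups))

  membership <- data.frame(
    sample_id = unlist(groups, use.names = FALSE),
    individual_id = rep(ind_ids, lengths(groups)),
    stringsAsFactors = FALSE
  )
  genos <- list()
  summaries <- list()
  for (k in seq_along(groups)) {
    members <- sort(groups[[k]])
    cons <- consolidate_genotype(gl[members], loci$locus)
    genos[[k]] <- data.frame(individual_id = ind_ids[k], locus = loci$locus,
                             a1 = cons[, 1], a2 = cons[, 2],
                             stringsAsFactors = FALSE)
    provs <- sort(unique(
      ds$samples$province[ds$samples$sample_id %in% members]))
    summaries[[k]] <- data.frame(
      individual_id = ind_ids[k],
      n_members = length(members),
      member_sample_ids = paste(members, collapse = ";"),
      provinces_seen = paste(provs, collapse = ";"),
      n_provinces = length(provs),
      n_missing_loci = sum(is.na(cons[, 1])),
      flagged = any(members %in% flagged),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(individuals = do.call(rbind, summaries),
         membership = membership,
         genotypes = do.call(rbind, genos),
         loci = loci,
         flagged_components = flagged),
    class = "bear_individuals"
  )
}

# Per-locus consolidation across member genotypes: prefer heterozygote calls
# (a homozygote disagreeing with a het is a dropout suspect), then modal.
consolidate_genotype <- function(gl, loci) {
  out <- matrix(NA_integer_, length(loci), 2,
                dimnames = list(loci, c("a1", "a2")))
  for (l in seq_along(loci)) {
    calls <- do.call(rbind, lapply(gl, function(g) g[l, ]))
    calls <- calls[!is.na(calls[, 1]), , drop = FALSE]
    if (!nrow(calls)) next
    het <- calls[calls[, 1] != calls[, 2], , drop = FALSE]
    pool <- if (nrow(het)) het else calls
    key <- paste(pool[, 1], pool[, 2])
    out[l, ] <- pool[match(names(which.max(table(key))), key), ]
  }
  out
}

#' @export
print.bear_individuals <- function(x, ...) {
  cat("<bear_individuals>", nrow(x$individuals), "unique genotypes from",
      nrow(x$membership), "samples\n")
  if ("sex" %in% names(x$individuals))
    cat("  sex:", paste(sprintf("%s=%d", names(table(x$individuals$sex)),
                                as.integer(table(x$individuals$sex))),
                        collapse = ", "), "\n")
  if (length(x$flagged_components))
    cat("  flagged (non-transitive matching):",
        paste(x$flagged_components, collapse = ", "), "\n")
  invisible(x)
}

#' Filter individuals for downstream genetic analyses
#'
#' The study discarded unique genotypes with missing data at more than one
#' locus before computing population-genetic statistics.
#'
#' @param ind A `bear_individuals` object from [cluster_samples()].
#' @param max_missing_loci Maximum missing loci allowed (default 1).
#' @return The filtered `bear_individuals` object.
#' @export
filter_for_analysis <- function(ind, max_missing_loci = 1L) {
  keep <- ind$individuals$individual_id[
    ind$individuals$n_missing_loci <= max_missing_loci]
  ind$individuals <- ind$individuals[
    ind$individuals$individual_id %in% keep, , drop = FALSE]
  ind$membership <- ind$membership[
    ind$membership$individual_id %in% keep, , drop = FALSE]
  ind$genotypes <- ind$genotypes[
    ind$genotypes$individual_id %in% keep, , drop = FALSE]
  ind
}

#' Assign sex to identified individuals from SRY amplification
#'
#' A sample is SRY-positive when any of its replicates amplified the
#' Y-linked SRY locus. Per individual: all member samples positive -> male;
#' all negative -> female; mixed evidence with positives in the majority ->
#' male (SRY dropout is common in degraded hair DNA); a minority positive
#' against a majority of negatives -> `conflict`, reported rather than
#' silently resolved.
#'
#' @param ind A `bear_individuals` object.
#' @param ds The [bear_dataset()] carrying the `sry` table.
#' @return `ind` with a `sex` column added to `$individuals` and a
#'   `sex_conflicts` element listing conflicted individuals.
#' @export
assign_sex <- function(ind, ds) {
  if (is.null(ds$sry)) {
    ind$individuals$sex <- NA_character_
    return(ind)
  }
  sample_pos <- tapply(ds$sry$sry_positive, ds$sry$sample_id, any)
  sex <- character(nrow(ind$individuals))
  for (k in seq_len(nrow(ind$individuals))) {
    members <- ind$membership$sample_id[
      ind$membership$individual_id == ind$individuals$individual_id[k]]
    pos <- sample_pos[members]
    pos <- pos[!is.na(pos)]
    if (!length(pos)) { sex[k] <- NA_character_; next }
    npos <- sum(pos)
    nneg <- sum(!pos)
    sex[k] <- if (nneg == 0) "male"
      else if (npos == 0) "female"
      else if (npos >= nneg) "male"
      else "conflict"
  }
  ind$individuals$sex <- sex
  ind$sex_conflicts <- ind$individuals$individual_id[sex == "conflict" &
                                                       !is.na(sex)]
  ind
}

#' Identify unique individuals in a genotyped dataset
#'
#' Convenience wrapper: clusters retained samples into individuals and
#' assigns sex from the SRY flags.
#'
#' @inheritParams cluster_samples
#' @return A `bear_individuals` object with sex assigned.
#' @export
identify_individuals <- function(ds, max_mismatch = 2L) {
  assign_sex(cluster_samples(ds, max_mismatch), ds)
}
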