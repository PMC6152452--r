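#' Consensus call for one locus across replicates
#'
#' All non-missing replicate calls must agree for a locus to be accepted.
#' A locus confirmed by a single replicate (all others missing) is accepted
#' but flagged `confirmed_single`; disagreeing calls yield a missing
#' consensus with status `mismatch`; all-missing yields `failed`.
#'
#' @param calls A replicates x 2 integer matrix of allele pairs (rows may be
#'   all-`NA` for failed replicates), or a list of length-2 vectors.
#' @return A list with `call` (length-2 integer vector, `NA` if no
#'   consensus) and `status` (one of `"confirmed"`, `"confirmed_single"`,
#'   `"mismatch"`, `"failed"`).
#' @export
consensus_locus <- function(calls) {
  if (is.list(calls)) calls <- do.call(rbind, calls)
  if (is.null(dim(calls))) calls <- matrix(calls, ncol = 2)
  if (nrow(calls) == 0) stop("consensus_locus: no replicate calls")
  present <- !is.na(calls[, 1])
  if (!any(present))
    return(list(call = c(NA_integer_, NA_integer_), status = "failed"))
  obs <- calls[present, , drop = FALSE]
  obs <- obs[, c(which.min(obs[1, ]), which.max(obs[1, ])), drop = FALSE]
  agree <- all(obs[, 1] == obs[1, 1]) && all(obs[, 2] == obs[1, 2])
  if (!agree)
    return(list(call = c(NA_integer_, NA_integer_), status = "mismatch"))
  status <- if (sum(present) == 1 && nrow(calls) > 1) "confirmed_single"
            else "confirmed"
  list(call = as.integer(sort(obs[1, ])), status = status)
}

# Consensus over one round (a list of loci x 2 replicate matrices).
# Returns list(calls = loci x 2 matrix, status = per-locus character).
round_consensus <- function(reps, loci) {
  L <- length(loci)
  out <- matrix(NA_integer_, L, 2, dimnames = list(loci, c("a1", "a2")))
  status <- character(L)
  for (l in seq_len(L)) {
    cl <- consensus_locus(do.call(rbind, lapply(reps, function(r) r[l, ])))
    out[l, ] <- cl$call
    status[l] <- cl$status
  }
  list(calls = out, status = status)
}

#' Consensus genotype for one sample
#'
#' Implements the two-round replicate rule used for noninvasive samples:
#' replicates 1-2 form round one; if any locus mismatches between them a
#' second round (replicates 3-4) is demanded and the consensus is built from
#' that round alone; a mismatch in round two discards the sample. Tissue
#' samples (single replicate) pass through unchanged.
#'
#' @param reps List of loci x 2 genotype matrices ([mlg()]), one per
#'   replicate, in genotyping order.
#' @param tissue Logical; single-replicate invasive sample.
#' @param loci Character vector of locus names (defaults to rownames of the
#'   first replicate).
#' @return A list with `calls` (loci x 2 consensus matrix), `locus_status`,
#'   `status` (`"ok"` or `"discarded"`), and `round_used` (0 for tissue).
#' @export
consensus_sample <- function(reps, tissue = FALSE, loci = rownames(reps[[1]])) {
  n <- length(reps)
  if (tissue) {
    if (n != 1) stop("tissue samples must have exactly 1 replicate")
    st <- ifelse(is.na(reps[[1]][, 1]), "failed", "confirmed")
    return(list(calls = reps[[1]], locus_status = st, status = "ok",
                round_used = 0L))
  }
  if (!n %in% c(2L, 4L))
    stop("non-tissue samples must have 2 or 4 replicates (got ", n, ")")
  r1 <- round_consensus(reps[1:2], loci)
  if (!any(r1$status == "mismatch"))
    return(list(calls = r1$calls, locus_status = r1$status, status = "ok",
                round_used = 1L))
  if (n == 2)
    return(list(calls = r1$calls, locus_status = r1$status,
                status = "discarded", round_used = 1L))
  r2 <- round_consensus(reps[3:4], loci)
  if (any(r2$status == "mismatch"))
    return(list(calls = r2$calls, locus_status = r2$status,
                status = "discarded", round_used = 2L))
  list(calls = r2$calls, locus_status = r2$status, status = "ok",
       round_used = 2L)
}

#' Compute consensus genotypes for every sample in a dataset
#'
#' @param ds A [bear_dataset()].
#' @return The dataset with `$consensus` (long calls with per-locus status)
#'   and `$qc` (per-sample status, round used, loci scored, single-replicate
#'   confirmations) filled in.
#' @export
consensus_genotypes <- function(ds) {
  loci <- ds$loci$locus
  cons <- vector("list", nrow(ds$samples))
  qc <- vector("list", nrow(ds$samples))
  for (i in seq_len(nrow(ds$samples))) {
    sid <- ds$samples$sample_id[i]
    sub <- ds$replicates[ds$replicates$sample_id == sid, ]
    rep_ids <- sort(unique(sub$replicate))
    reps <- lapply(rep_ids, function(r) mlg(sub[sub$replicate == r, ], loci))
    cs <- consensus_sample(reps, tissue = ds$samples$source[i] == "tissue",
                           loci = loci)
    cons[[i]] <- data.frame(
      sample_id = sid, locus = loci,
      a1 = cs$calls[, 1], a2 = cs$calls[, 2],
      status = cs$locus_status, stringsAsFactors = FALSE
    )
    qc[[i]] <- data.frame(
      sample_id = sid, status = cs$status, round_used = cs$round_used,
      n_loci_scored = sum(!is.na(cs$calls[, 1])),
      n_confirmed_single = sum(cs$locus_status == "confirmed_single"),
      stringsAsFactors = FALSE
    )
  }
  ds$consensus <- do.call(rbind, cons)
  ds$qc <- do.call(rbind, qc)
  rownames(ds$consensus) <- rownames(ds$qc) <- NULL
  ds
}

#' Partition samples by locus coverage
#'
#' A sample is retained when its consensus genotype scores at least
#' `min_loci` of the panel's loci (and was not discarded by the replicate
#' rule). The study's filter is 8 of 10.
#'
#' @param ds A [bear_dataset()] with consensus computed.
#' @param min_loci Minimum number of scored loci.
#' @return A list with `retained` and `failed` (both [bear_dataset()]s
#'   restricted to the respective samples).
#' @export
filter_by_locus_coverage <- function(ds, min_loci = 8L) {
  if (is.null(ds$qc)) stop("run consensus_genotypes() first")
  if (min_loci > nrow(ds$loci))
    stop("min_loci exceeds the number of loci in the panel")
  ok <- ds$qc$status == "ok" & ds$qc$n_loci_scored >= min_loci
  keep <- ds$qc$sample_id[ok]
  list(retained = subset_samples(ds, keep),
       failed = subset_samples(ds, setdiff(ds$samples$sample_id, keep)))
}

#' Restrict a dataset to a set of samples
#' @param ds A [bear_dataset()].
#' @param ids Sample ids to keep.
#' @return The restricted dataset.
#' @export
subset_samples <- function(ds, ids) {
  ds$samples <- ds$samples[ds$samples$sample_id %in% ids, , drop = FALSE]
  ds$replicates <- ds$replicates[ds$replicates$sample_id %in% ids, ,
                                 drop = FALSE]
  if (!is.null(ds$sry))
    ds$sry <- ds$sry[ds$sry$sample_id %in% ids, , drop = FALSE]
  if (!is.null(ds$consensus))
    ds$consensus <- ds$consensus[ds$consensus$sample_id %in% ids, ,
                                 drop = FALSE]
  if (!is.null(ds$qc))
    ds$qc <- ds$qc[ds$qc$sample_id %in% ids, , drop = FALSE]
  ds
}
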