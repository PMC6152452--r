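#' Tabulate genotyping success against a metadata field
#'
#' Builds a success/failure contingency table for hair samples, where
#' success means passing the replicate-consensus rule and scoring at least
#' `min_loci` loci. By convention the source analysis uses noninvasive
#' samples only (poles, trees, barbed wire, hair traps), while the year
#' analysis uses all hair samples; tissue is always excluded.
#'
#' @param ds A [bear_dataset()] with consensus computed.
#' @param by Metadata column of `ds$samples` (`"source"` or `"year"`).
#' @param min_loci Coverage threshold defining success.
#' @param noninvasive_only Restrict to noninvasive sources; defaults to
#'   `TRUE` when `by = "source"`.
#' @return An integer matrix with rows `success`/`failure` and one column
#'   per level of `by`, of class `contingency_table`.
#' @export
tabulate_success <- function(ds, by = "source", min_loci = 8L,
                             noninvasive_only = (by == "source")) {
  if (is.null(ds$qc)) stop("run consensus_genotypes() first")
  s <- ds$samples[ds$samples$source != "tissue", , drop = FALSE]
  if (noninvasive_only)
    s <- s[s$source %in% noninvasive_sources(), , drop = FALSE]
  if (!nrow(s)) stop("no samples to tabulate")
  qc <- ds$qc[match(s$sample_id, ds$qc$sample_id), ]
  success <- qc$status == "ok" & qc$n_loci_scored >= min_loci
  tab <- table(factor(ifelse(success, "success", "failure"),
                      levels = c("success", "failure")),
               s[[by]])
  out <- unclass(as.matrix(tab))
  names(dimnames(out)) <- NULL
  class(out) <- c("contingency_table", class(out))
  out
}

#' Build a contingency table from counts
#'
#' @param success,failure Named integer vectors of counts per column.
#' @return A `contingency_table` matrix.
#' @export
contingency_table <- function(success, failure) {
  stopifnot(identical(names(success), names(failure)),
            all(success >= 0), all(failure >= 0))
  out <- rbind(success = success, failure = failure)
  class(out) <- c("contingency_table", class(out))
  out
}

#' Pearson chi-square test of independence
#'
#' No continuity correction (matching the convention needed to reproduce
#' published 2x2 statistics). Expected counts below 5 yield a warning, not
#' an error.
#'
#' @param tab A 2 x c (or r x c) contingency matrix.
#' @return A list `statistic`, `df`, `p_value`, `expected`,
#'   `low_expected` (logical).
#' @export
chi_square_independence <- function(tab) {
  tab <- unclass(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need >=2 rows and >=2 columns")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(ct$expected < 5)
  if (low) warning("expected counts below 5; chi-square approximation weak")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected,
       low_expected = low)
}

#' Pool columns of a contingency table
#'
#' @param tab A `contingency_table`.
#' @param groups Named list mapping new column names to vectors of old
#'   column names; columns not mentioned are dropped.
#' @return The pooled `contingency_table`.
#' @export
pool_columns <- function(tab, groups) {
  out <- vapply(groups, function(cols)
    rowSums(unclass(tab)[, cols, drop = FALSE]), numeric(nrow(tab)))
  out <- matrix(as.integer(out), nrow = nrow(tab),
                dimnames = list(rownames(tab), names(groups)))
  class(out) <- c("contingency_table", class(out))
  out
}

#' Per-column success rates
#'
#' @param tab A `contingency_table` with a `success` row.
#' @return Percentages `100 * success / column total`, rounded to 2
#'   decimals; zero-total columns are `NA` (flagged by a warning).
#' @export
success_rates <- function(tab) {
  tot <- colSums(unclass(tab))
  if (any(tot == 0)) warning("zero column total; rate undefined")
  out <- round(100 * unclass(tab)["success", ] / tot, 2)
  out[tot == 0] <- NA_real_
  out
}
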