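#' The GKM brown bear microsatellite panel
#'
#' The ten dinucleotide/tetranucleotide loci used to genotype Grand Kackar
#' Mountains brown bears, with their repeat-unit sizes and the number of
#' alleles observed in the study population. The allele counts parameterise
#' the synthetic-data generator; the repeat units drive stutter-shift
#' attribution during individual identification.
#'
#' @return A data frame with columns `locus`, `repeat_unit` (bp) and
#'   `n_alleles`.
#' @export
gkm_panel <- function() {
  data.frame(
    locus = c("G10C", "G10X", "UarD1585", "UarT739", "UarD3139",
              "UarD3684", "G1D", "Mu05", "Mu23", "Mu50"),
    repeat_unit = c(2L, 2L, 2L, 4L, 2L, 2L, 2L, 2L, 2L, 2L),
    n_alleles = c(9L, 9L, 10L, 7L, 9L, 8L, 8L, 8L, 7L, 10L),
    stringsAsFactors = FALSE
  )
}

#' Sample sources recognised by the pipeline
#' @export
bear_sources <- function() {
  c("pole", "tree", "barbed_wire", "hair_trap", "tissue", "capture_hair")
}

noninvasive_sources <- function() c("pole", "tree", "barbed_wire", "hair_trap")

#' Construct a bear genotype dataset
#'
#' The central container of the pipeline. `samples` holds one row of field
#' metadata per sample; `replicates` holds the per-replicate allele calls in
#' long format (one row per sample x replicate x locus); `sry` holds the
#' per-replicate SRY (Y-chromosome) amplification flags used for sexing.
#' Allele calls are canonicalised on construction: within a locus the pair is
#' stored sorted (`a1 <= a2`) and a call with exactly one observed allele is
#' stored as a provisional homozygote with `single_allele = TRUE`.
#'
#' @param samples Data frame with columns `sample_id`, `province`, `source`
#'   (one of [bear_sources()]), `year`, `lat`, `lon`.
#' @param replicates Data frame with columns `sample_id`, `replicate`,
#'   `locus`, `a1`, `a2` (integer allele sizes in bp, `NA` = missing) and
#'   optionally `single_allele`.
#' @param loci Data frame with columns `locus` and `repeat_unit`; defaults to
#'   the loci present in `replicates` with repeat unit 2.
#' @param sry Optional data frame with columns `sample_id`, `replicate`,
#'   `sry_positive`.
#' @return An object of class `bear_dataset` with elements `samples`,
#'   `replicates`, `loci`, `sry`, and (after the respective pipeline stages)
#'   `consensus`, `qc`, `individuals`.
#' @export
bear_dataset <- function(samples, replicates, loci = NULL, sry = NULL) {
  stopifnot(is.data.frame(samples), is.data.frame(replicates))
  need_s <- c("sample_id", "province", "source", "year", "lat", "lon")
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) stop("samples is missing columns: ", paste(miss, collapse = ", "))
  need_r <- c("sample_id", "replicate", "locus", "a1", "a2")
  miss <- setdiff(need_r, names(replicates))
  if (length(miss)) stop("replicates is missing columns: ", paste(miss, collapse = ", "))
  bad_src <- setdiff(unique(samples$source), bear_sources())
  if (length(bad_src)) stop("unknown sample source(s): ", paste(bad_src, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in samples table")

  if (is.null(loci)) {
    loci <- data.frame(locus = unique(replicates$locus), repeat_unit = 2L,
                       stringsAsFactors = FALSE)
  }
  if (anyDuplicated(loci$locus)) stop("locus names must be unique")
  if (any(loci$repeat_unit < 1)) stop("repeat_unit must be >= 1")
  unknown <- setdiff(unique(replicates$locus), loci$locus)
  if (length(unknown)) stop("replicates reference unknown loci: ",
                            paste(unknown, collapse = ", "))

  replicates <- canonicalize_calls(replicates)
  structure(
    list(samples = samples, replicates = replicates, loci = loci, sry = sry,
         consensus = NULL, qc = NULL, individuals = NULL),
    class = "bear_dataset"
  )
}

#' Canonicalise allele calls
#'
#' Sorts each allele pair (`a1 <= a2`) and converts single-allele
#' observations (exactly one of the pair missing) into provisional
#' homozygotes flagged `single_allele = TRUE`. Idempotent.
#'
#' @param calls Data frame with columns `a1`, `a2` and optionally
#'   `single_allele`.
#' @return The same data frame, canonicalised.
#' @export
canonicalize_calls <- function(calls) {
  a1 <- calls$a1
  a2 <- calls$a2
  single <- if ("single_allele" %in% names(calls)) calls$single_allele else
    rep(FALSE, nrow(calls))
  single[is.na(single)] <- FALSE
  one_missing <- xor(is.na(a1), is.na(a2))
  obs <- ifelse(is.na(a1), a2, a1)
  a1[one_missing] <- obs[one_missing]
  a2[one_missing] <- obs[one_missing]
  single <- single | one_missing
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  calls$a1 <- as.integer(a1)
  calls$a2 <- as.integer(a2)
  calls$single_allele <- single
  calls
}

#' @export
print.bear_dataset <- function(x, ...) {
  cat("<bear_dataset>\n")
  cat("  samples:   ", nrow(x$samples), " (",
      paste(sprintf("%s=%d", names(table(x$samples$source)),
                    as.integer(table(x$samples$source))), collapse = ", "),
      ")\n", sep = "")
  cat("  loci:      ", nrow(x$loci), "\n", sep = "")
  cat("  replicates:", nrow(unique(x$replicates[c("sample_id", "replicate")])),
      "genotyping runs\n")
  if (!is.null(x$consensus))
    cat("  consensus: computed (", sum(x$qc$status == "ok"), " samples ok, ",
        sum(x$qc$status != "ok"), " discarded)\n", sep = "")
  if (!is.null(x$individuals))
    cat("  individuals:", nrow(x$individuals$individuals), "\n")
  invisible(x)
}

#' Extract a single multilocus genotype as a loci x 2 matrix
#'
#' @param df Long-format calls (`locus`, `a1`, `a2`) for one genotype.
#' @param loci Locus table (or character vector of locus names) fixing row
#'   order; loci absent from `df` are missing.
#' @return Integer matrix with one row per locus and columns `a1`, `a2`.
#' @export
mlg <- function(df, loci) {
  locus_names <- if (is.data.frame(loci)) loci$locus else loci
  m <- matrix(NA_integer_, nrow = length(locus_names), ncol = 2,
              dimnames = list(locus_names, c("a1", "a2")))
  idx <- match(df$locus, locus_names)
  keep <- !is.na(idx)
  m[idx[keep], 1] <- as.integer(df$a1[keep])
  m[idx[keep], 2] <- as.integer(df$a2[keep])
  m
}

#' Number of missing loci in a multilocus genotype
#' @param g A loci x 2 genotype matrix from [mlg()].
#' @return Integer count of loci with no allele call.
#' @export
n_missing_loci <- function(g) sum(is.na(g[, 1]))

#' Stack multilocus genotypes into a cohort matrix
#'
#' Converts long-format genotypes for many samples/individuals into the
#' n x (2 x loci) integer matrix used by the statistics functions: columns
#' are `<locus>.1`, `<locus>.2`, rows are ids.
#'
#' @param calls Long data frame with an id column plus `locus`, `a1`, `a2`.
#' @param loci Locus table or character vector fixing column order.
#' @param id_col Name of the id column (default `"sample_id"`).
#' @return Integer matrix with rownames = ids.
#' @export
mlg_matrix <- function(calls, loci, id_col = "sample_id") {
  locus_names <- if (is.data.frame(loci)) loci$locus else loci
  ids <- unique(calls[[id_col]])
  L <- length(locus_names)
  m <- matrix(NA_integer_, nrow = length(ids), ncol = 2 * L,
              dimnames = list(ids, paste(rep(locus_names, each = 2),
                                         1:2, sep = ".")))
  ri <- match(calls[[id_col]], ids)
  ci <- match(calls$locus, locus_names)
  ok <- !is.na(ri) & !is.na(ci)
  m[cbind(ri[ok], 2 * ci[ok] - 1)] <- as.integer(calls$a1[ok])
  m[cbind(ri[ok], 2 * ci[ok])] <- as.integer(calls$a2[ok])
  m
}

# Column indices of locus l in an mlg_matrix.
locus_cols <- function(l) c(2L * l - 1L, 2L * l)
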