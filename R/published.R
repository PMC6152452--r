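#' Published GKM summary tables
#'
#' The per-locus summary statistics and genotyping-success counts published
#' for the Grand Kackar Mountains brown bear population, bundled as package
#' data. The locus summary carries the printed (2-decimal) observed and
#' expected heterozygosities, null-allele estimates and F_IS per locus, with
#' `null_free` marking the five loci without a significant null-allele
#' signal; the success tables carry the success/failure counts of
#' noninvasive hair samples by field source and of all hair samples by
#' collection year.
#'
#' @return `gkm_published_locus_summary()`: a data frame with one row per
#'   locus. `gkm_published_success_by_source()` /
#'   `gkm_published_success_by_year()`: [contingency_table()] matrices.
#' @export
gkm_published_locus_summary <- function() {
  utils::read.delim(system.file("extdata", "gkm_locus_summary.tsv",
                                package = "bearid"),
                    stringsAsFactors = FALSE)
}

#' @rdname gkm_published_locus_summary
#' @export
gkm_published_success_by_source <- function() {
  d <- utils::read.delim(system.file("extdata", "gkm_success_by_source.tsv",
                                     package = "bearid"),
                         stringsAsFactors = FALSE)
  contingency_table(stats::setNames(d$success, d$source),
                    stats::setNames(d$failure, d$source))
}

#' @rdname gkm_published_locus_summary
#' @export
gkm_published_success_by_year <- function() {
  d <- utils::read.delim(system.file("extdata", "gkm_success_by_year.tsv",
                                     package = "bearid"),
                         stringsAsFactors = FALSE)
  contingency_table(stats::setNames(d$success, d$year),
                    stats::setNames(d$failure, d$year))
}
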