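#' Default column schema for genotype tables
#'
#' Maps the metadata fields the reader expects onto the column names used in
#' a delimited genotype table. Allele columns are identified by the locus
#' name plus the two `allele_suffixes` (e.g. `Mu05_1`, `Mu05_2`).
#'
#' @param sample_id,replicate,province,source,year,lat,lon,sry Column names.
#' @param allele_suffixes Length-2 suffixes of the per-locus allele columns.
#' @return A named list usable as the `schema` argument of
#'   [read_genotype_table()].
#' @export
genotype_schema <- function(sample_id = "sample_id", replicate = "replicate",
                            province = "province", source = "source",
                            year = "year", lat = "lat", lon = "lon",
                            sry = "sry", allele_suffixes = c("_1", "_2")) {
  list(sample_id = sample_id, replicate = replicate, province = province,
       source = source, year = year, lat = lat, lon = lon, sry = sry,
       allele_suffixes = allele_suffixes)
}

#' Read a delimited genotype table
#'
#' Reads a CSV/TSV table with one row per sample x replicate and two allele
#' columns per locus, and returns a canonicalised [bear_dataset()]. Missing
#' alleles may be encoded by any of `missing_codes`; a call with exactly one
#' observed allele becomes a provisional homozygote flagged `single_allele`.
#'
#' @param path File path; `.tsv`/`.txt` are read tab-separated, else comma.
#' @param schema Column-name map from [genotype_schema()].
#' @param loci Optional locus table (columns `locus`, `repeat_unit`). When
#'   given, allele-column pairs in the file that do not correspond to a
#'   listed locus raise an error; when `NULL`, loci are auto-detected from
#'   the paired allele columns.
#' @param missing_codes Values treated as a missing allele.
#' @return A [bear_dataset()].
#' @export
read_genotype_table <- function(path, schema = genotype_schema(), loci = NULL,
                                missing_codes = c("0", "NA", "")) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  sfx <- schema$allele_suffixes
  a1_cols <- grep(paste0(sfx[1], "$"), names(raw), value = TRUE)
  file_loci <- sub(paste0(sfx[1], "$"), "", a1_cols)
  file_loci <- file_loci[paste0(file_loci, sfx[2]) %in% names(raw)]
  if (!is.null(loci)) {
    locus_names <- if (is.data.frame(loci)) loci$locus else loci
    unknown <- setdiff(file_loci, locus_names)
    if (length(unknown))
      stop("unknown locus column(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    file_loci <- intersect(locus_names, file_loci)
  }
  if (!length(file_loci)) stop("no paired allele columns found in ", path)

  id <- raw[[schema$sample_id]]
  rep_idx <- if (schema$replicate %in% names(raw))
    as.integer(raw[[schema$replicate]]) else rep(1L, nrow(raw))
  if (anyDuplicated(paste(id, rep_idx, sep = "\r")))
    stop("duplicated sample_id x replicate in ", path)

  parse_allele <- function(x) {
    x <- trimws(x)
    out <- rep(NA_integer_, length(x))
    is_missing <- is.na(x) | x %in% missing_codes
    ok <- !is_missing & grepl("^-?[0-9]+$", x)
    out[ok] <- as.integer(x[ok])
    bad <- which(!is_missing & !ok)
    attr(out, "bad_rows") <- bad
    out
  }
  bad_lines <- integer(0)
  reps <- do.call(rbind, lapply(file_loci, function(lc) {
    a1 <- parse_allele(raw[[paste0(lc, sfx[1])]])
    a2 <- parse_allele(raw[[paste0(lc, sfx[2])]])
    bad_lines <<- union(bad_lines,
                        c(attr(a1, "bad_rows"), attr(a2, "bad_rows")))
    data.frame(sample_id = id, replicate = rep_idx, locus = lc,
               a1 = as.integer(a1), a2 = as.integer(a2),
               stringsAsFactors = FALSE)
  }))
  if (length(bad_lines))
    stop("non-integer allele value(s) at file line(s) ",
         paste(sort(bad_lines) + 1L, collapse = ", "), " of ", path)

  first <- !duplicated(id)
  getcol <- function(nm, default) {
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]][first] else default
  }
  samples <- data.frame(
    sample_id = id[first],
    province = getcol(schema$province, NA_character_),
    source = getcol(schema$source, "tissue"),
    year = suppressWarnings(as.integer(getcol(schema$year, NA))),
    lat = suppressWarnings(as.numeric(getcol(schema$lat, NA))),
    lon = suppressWarnings(as.numeric(getcol(schema$lon, NA))),
    stringsAsFactors = FALSE
  )
  sry <- NULL
  if (!is.null(schema$sry) && schema$sry %in% names(raw)) {
    sry <- data.frame(sample_id = id, replicate = rep_idx,
                      sry_positive = raw[[schema$sry]] %in%
                        c("1", "TRUE", "true", "T", "yes", "male"),
                      stringsAsFactors = FALSE)
  }
  if (is.null(loci)) {
    loci <- data.frame(locus = file_loci, repeat_unit = 2L,
                       stringsAsFactors = FALSE)
  } else if (!is.data.frame(loci)) {
    loci <- data.frame(locus = loci, repeat_unit = 2L, stringsAsFactors = FALSE)
  }
  bear_dataset(samples, reps, loci = loci[loci$locus %in% file_loci, ],
               sry = sry)
}

#' Write a dataset back to a delimited genotype table
#'
#' Inverse of [read_genotype_table()] under the default schema; one row per
#' sample x replicate, missing alleles written as 0. Provisional homozygotes
#' (single-allele observations) are written with the second allele missing so
#' the flag survives a round trip.
#'
#' @param ds A [bear_dataset()].
#' @param path Output path (`.tsv`/`.txt` for tab-separated, else CSV).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ds, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  reps <- ds$replicates
  key <- unique(reps[c("sample_id", "replicate")])
  out <- merge(key, ds$samples, by = "sample_id", sort = FALSE)
  if (!is.null(ds$sry))
    out <- merge(out, ds$sry, by = c("sample_id", "replicate"),
                 all.x = TRUE, sort = FALSE)
  for (lc in ds$loci$locus) {
    sub <- reps[reps$locus == lc, ]
    i <- match(paste(out$sample_id, out$replicate),
               paste(sub$sample_id, sub$replicate))
    a1 <- sub$a1[i]
    a2 <- sub$a2[i]
    a2[!is.na(sub$single_allele[i]) & sub$single_allele[i]] <- NA
    a1[is.na(a1)] <- 0L
    a2[is.na(a2)] <- 0L
    out[[paste0(lc, "_1")]] <- a1
    out[[paste0(lc, "_2")]] <- a2
  }
  if ("sry_positive" %in% names(out)) {
    out$sry <- as.integer(out$sry_positive)
    out$sry_positive <- NULL
  }
  out <- out[order(out$sample_id, out$replicate), ]
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export consensus genotypes in Genepop 4 format
#'
#' Writes one Genepop `Pop` block per value of a grouping metadata field.
#' Allele sizes are recoded to 3-digit codes by rank within each locus
#' (smallest allele = 001); missing genotypes are written as `000000`.
#'
#' @param ds A [bear_dataset()] with consensus computed, or with single-
#'   replicate samples (tissue) only.
#' @param path Output path.
#' @param group_by Metadata column of `ds$samples` defining the `Pop` blocks.
#' @param title Title line of the file.
#' @return `path` invisibly, with the per-locus allele code maps attached as
#'   attribute `"code_map"`.
#' @export
write_genepop <- function(ds, path, group_by = "province",
                          title = "bearid export") {
  calls <- consensus_calls(ds)
  loci <- ds$loci$locus
  code_map <- lapply(loci, function(lc) {
    al <- sort(unique(stats::na.omit(
      c(calls$a1[calls$locus == lc], calls$a2[calls$locus == lc]))))
    if (length(al) > 999) stop("locus ", lc, " has more than 999 alleles")
    stats::setNames(seq_along(al), al)
  })
  names(code_map) <- loci
  enc <- function(lc, a1, a2) {
    cm <- code_map[[lc]]
    ifelse(is.na(a1), "000000",
           paste0(sprintf("%03d", cm[as.character(a1)]),
                  sprintf("%03d", cm[as.character(a2)])))
  }
  m <- mlg_matrix(calls, loci)
  samples <- ds$samples[ds$samples$sample_id %in% rownames(m), ]
  groups <- split(samples$sample_id, samples[[group_by]])
  lines <- c(title, loci)
  for (g in names(groups)) {
    lines <- c(lines, "Pop")
    for (sid in groups[[g]]) {
      gi <- m[sid, ]
      fields <- vapply(seq_along(loci), function(l)
        enc(loci[l], gi[2 * l - 1], gi[2 * l]), character(1))
      lines <- c(lines, paste0(sid, " ,  ", paste(fields, collapse = " ")))
    }
  }
  writeLines(lines, path)
  out <- path
  attr(out, "code_map") <- code_map
  invisible(out)
}

#' Export genotypes in two-row-per-individual matrix format
#'
#' The integer matrix layout used by Bayesian clustering programs: two rows
#' per individual (one per gene copy), one id column followed by one column
#' per locus, missing = -9, whitespace-separated with a locus-name header.
#'
#' @param ds A [bear_dataset()] (uses identified individuals when present,
#'   otherwise per-sample consensus genotypes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_input <- function(ds, path) {
  if (!is.null(ds$individuals)) {
    calls <- ds$individuals$genotypes
    m <- mlg_matrix(calls, ds$loci, id_col = "individual_id")
  } else {
    m <- mlg_matrix(consensus_calls(ds), ds$loci)
  }
  loci <- ds$loci$locus
  lines <- paste(loci, collapse = " ")
  for (id in rownames(m)) {
    g <- m[id, ]
    r1 <- g[seq(1, length(g), by = 2)]
    r2 <- g[seq(2, length(g), by = 2)]
    r1[is.na(r1)] <- -9L
    r2[is.na(r2)] <- -9L
    lines <- c(lines,
               paste(c(id, r1), collapse = " "),
               paste(c(id, r2), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Long-format consensus calls of a dataset
#'
#' Returns the consensus genotype calls of all samples that passed the
#' replicate rule; for datasets without a consensus stage (e.g.
#' single-replicate tissue-only sets) falls back to replicate 1.
#'
#' @param ds A [bear_dataset()].
#' @return A data frame with `sample_id`, `locus`, `a1`, `a2` (and `status`
#'   when consensus has been computed).
#' @export
consensus_calls <- function(ds) {
  if (!is.null(ds$consensus)) {
    ok <- ds$qc$sample_id[ds$qc$status == "ok"]
    ds$consensus[ds$consensus$sample_id %in% ok, ]
  } else {
    ds$replicates[ds$replicates$replicate == 1L, ]
  }
}

#' Validate a dataset and report anomalies
#'
#' Report-only checks: non-tissue samples with fewer than two replicates,
#' alleles off the repeat-unit grid of their locus (size not congruent with
#' the locus's modal residue class), and coordinate outliers (further than
#' `max_km` from the median sampling location). Never mutates the data.
#'
#' @param ds A [bear_dataset()].
#' @param json Optional path; when given the report is also written as JSON.
#' @param max_km Coordinate-outlier threshold in kilometres.
#' @return A list of class `bear_validation` with elements `few_replicates`,
#'   `off_grid`, `coordinate_outliers` and `clean` (logical).
#' @export
validate_dataset <- function(ds, json = NULL, max_km = 500) {
  reps_per <- table(ds$replicates$sample_id[!duplicated(
    ds$replicates[c("sample_id", "replicate")])])
  nrep <- as.integer(reps_per[ds$samples$sample_id])
  nrep[is.na(nrep)] <- 0L
  few <- ds$samples$sample_id[ds$samples$source != "tissue" & nrep < 2]

  off_grid <- do.call(rbind, lapply(seq_len(nrow(ds$loci)), function(i) {
    lc <- ds$loci$locus[i]
    ru <- ds$loci$repeat_unit[i]
    al <- stats::na.omit(c(ds$replicates$a1[ds$replicates$locus == lc],
                           ds$replicates$a2[ds$replicates$locus == lc]))
    if (!length(al) || ru <= 1) return(NULL)
    res <- al %% ru
    modal <- as.integer(names(which.max(table(res))))
    bad <- sort(unique(al[res != modal]))
    if (!length(bad)) return(NULL)
    data.frame(locus = lc, allele = bad, expected_residue = modal,
               stringsAsFactors = FALSE)
  }))
  if (is.null(off_grid))
    off_grid <- data.frame(locus = character(0), allele = integer(0),
                           expected_residue = integer(0))

  s <- ds$samples[!is.na(ds$samples$lat) & !is.na(ds$samples$lon), ]
  coord_out <- character(0)
  if (nrow(s) >= 3) {
    d <- haversine_m(s$lat, s$lon, stats::median(s$lat), stats::median(s$lon))
    coord_out <- s$sample_id[d > max_km * 1000]
  }
  rep_out <- list(
    few_replicates = as.character(few),
    off_grid = off_grid,
    coordinate_outliers = as.character(coord_out),
    clean = length(few) == 0 && nrow(off_grid) == 0 && length(coord_out) == 0
  )
  class(rep_out) <- "bear_validation"
  if (!is.null(json)) {
    jsonlite::write_json(unclass(rep_out), json, auto_unbox = TRUE,
                         dataframe = "rows")
  }
  rep_out
}

#' @export
print.bear_validation <- function(x, ...) {
  cat("<bear_validation>", if (x$clean) "clean\n" else "\n")
  if (length(x$few_replicates))
    cat("  non-tissue samples with <2 replicates:",
        paste(x$few_replicates, collapse = ", "), "\n")
  if (nrow(x$off_grid))
    cat("  off-grid alleles:",
        paste(sprintf("%s:%d", x$off_grid$locus, x$off_grid$allele),
              collapse = ", "), "\n")
  if (length(x$coordinate_outliers))
    cat("  coordinate outliers:",
        paste(x$coordinate_outliers, collapse = ", "), "\n")
  invisible(x)
}
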