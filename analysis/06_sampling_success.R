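#!/usr/bin/env Rscript
# Stage 6: genotyping success by hair-sample source and year.
#
# Contingency analysis on the simulated campaign, alongside the same tests
# on the published count tables.

suppressPackageStartupMessages(library(bearid))

ds <- read_genotype_table("results/genotypes.csv", loci = gkm_panel())
ds <- consensus_genotypes(ds)

tab_src <- tabulate_success(ds, by = "source")
tab_yr <- tabulate_success(ds, by = "year")
write.table(tab_src, "results/success_by_source.tsv", sep = "\t",
            quote = FALSE)
write.table(tab_yr, "results/success_by_year.tsv", sep = "\t", quote = FALSE)

report <- function(label, tab) {
  ct <- suppressWarnings(chi_square_independence(tab))
  cat(sprintf("%s: chi-square = %.2f, df = %d, P = %.4g\n",
              label, ct$statistic, ct$df, ct$p_value))
}
cat("Simulated campaign:\n")
print(tab_src)
print(success_rates(tab_src))
report("  by source", tab_src)
pooled <- pool_columns(tab_src, list(tree_or_wire = c("tree", "barbed_wire"),
                                     pole = "pole"))
report("  trees+wire vs poles", pooled)
report("  by year", tab_yr)

cat("\nPublished counts:\n")
src <- gkm_published_success_by_source()
print(success_rates(src))
report("  by source", src)
report("  trees+wire vs poles",
       pool_columns(src, list(tree_or_wire = c("tree", "barbed_wire"),
                              pole = "pole")))
report("  by year", gkm_published_success_by_year())
cat("Wrote results/success_by_source.tsv and results/success_by_year.tsv\n")
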