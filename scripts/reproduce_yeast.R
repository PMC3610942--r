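#!/usr/bin/env Rscript
# Reproduces the preprocessing counts of the yeast segregant analysis
# (gene filtering, marker merging, marker-pair eligibility, post-scan
# merging) from the published cross data.  The expression and genotype
# tables of the 109-segregant BY x RM cross (glucose and ethanol
# conditions) must be downloaded manually from the article page of the
# original expression study (PLoS Biology, doi:10.1371/journal.pbio.0060083)
# and converted to the package's TSV formats:
#
#   scratch/yeast/expression_glucose.tsv   genes x samples
#   scratch/yeast/expression_ethanol.tsv   genes x samples
#   scratch/yeast/genotype.tsv             markers x samples, calls 0/1
#   scratch/yeast/intervals.tsv            marker_id chrom start end
#
# The full two-locus scan over all gene pairs x eligible marker pairs is
# CPU-weeks of work and is NOT run here; pass --scan to run it anyway.

suppressPackageStartupMessages(library(epi2d))

dir <- "scratch/yeast"
need <- file.path(dir, c("expression_glucose.tsv", "expression_ethanol.tsv",
                         "genotype.tsv", "intervals.tsv"))
if (!all(file.exists(need))) {
  message("yeast input files not found under ", dir, ":\n  ",
          paste(basename(need)[!file.exists(need)], collapse = "\n  "),
          "\nDownload and convert them first (see header comment).")
  quit(status = 1, save = "no")
}

glu <- read_expression_table(need[1], condition = "glucose")
eth <- read_expression_table(need[2], condition = "ethanol")
geno <- read_genotype_table(need[3], need[4])

cat("genes measured:            ", nrow(glu), "\n")
filtered <- filter_genes_by_missing(list(glu, eth), 10)
cat("genes after missing filter:", nrow(filtered[[1]]), "\n")

cat("markers genotyped:         ", nrow(geno$calls), "\n")
merged <- merge_markers(geno, 5L)
cat("merged markers:            ", nrow(merged$geno$calls), "\n")

pairs <- eligible_marker_pairs(merged$geno, 15L)
cat("eligible marker pairs:     ", nrow(pairs), "\n")

post <- merge_markers(geno, 15L)
cat("post-scan merged markers:  ", nrow(post$geno$calls), "\n")

if ("--scan" %in% commandArgs(trailingOnly = TRUE)) {
  for (cond in list(filtered[[1]], filtered[[2]])) {
    al <- align_samples(normal_quantile_transform(cond), merged$geno)
    res <- exhaustive_scan(al$expr, al$geno, scan_config())
    out <- sprintf("scratch/yeast/results_%s.tsv",
                   attr(cond, "condition"))
    write_scan_results(res, out)
    cat("wrote ", out, "\n", sep = "")
  }
}
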