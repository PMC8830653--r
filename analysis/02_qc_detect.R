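#!/usr/bin/env Rscript
# Stage 2: SNP quality control and ROHet detection, per population.
#
# QC: call rate >= 90%, MAF >= 5%, autosomes only. The exact-HWE filter is
# disabled for these simulated genotypes: the generator introduces no
# genotyping artifacts, and its planted heterozygosity-rich segments are
# true signal an HWE screen would discard (see the methods vignette).
# Detection: consecutive scanning with the standard ROHet parameters
# (>= 1 Mb, >= 15 SNPs, gap <= 1 Mb, <= 1 opposite genotype, no missing).

suppressPackageStartupMessages(library(rohet))

for (lab in c("A", "B")) {
  d <- file.path("results", paste0("pop", lab))
  g0 <- read_ped_map(file.path(d, paste0("pop", lab, ".ped")),
                     file.path(d, paste0("pop", lab, ".map")))
  fq <- filter_snps(g0, hwe_alpha = 0)
  print(fq$report)
  write.table(qc_report_table(fq$report),
              file.path(d, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  runs <- detect_runs(fq$geno)
  write.table(runs, file.path(d, "runs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  runs_to_bed(runs, file.path(d, "runs.bed"))
  cat(sprintf(
    "population %s: %d ROHet in %d of %d animals (mean %.2f per animal)\n",
    lab, nrow(runs), length(unique(runs$id)), length(fq$geno$ids),
    nrow(runs) / length(fq$geno$ids)))
}
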