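#!/usr/bin/env Rscript
# Stage 3: descriptive statistics of the detected ROHet.
#
# Per-individual run counts and genome coverage (fROHet), the 1-2 / 2-4 /
# >4 Mb length-class table, per-chromosome counts with their correlation
# against chromosome length, and the same headline statistics recomputed
# from the reference Duroc summary totals for comparison.

suppressPackageStartupMessages(library(rohet))

for (lab in c("A", "B")) {
  d <- file.path("results", paste0("pop", lab))
  runs <- read.delim(file.path(d, "runs.tsv"))
  map <- read.table(file.path(d, paste0("pop", lab, ".map")),
                    col.names = c("chrom", "snp_id", "cm", "bp"))
  phen <- read_phenotypes(file.path(d, paste0("pop", lab,
                                              "_phenotypes.tsv")))
  l_gen <- map_genome_length(map)

  isum <- summarize_individuals(runs, phen$id, l_gen)
  write.table(isum, file.path(d, "individual_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lc <- classify_lengths(runs)
  write.table(lc, file.path(d, "length_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cs <- summarize_chromosomes(runs, map)
  write.table(cs, file.path(d, "chromosome_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("population %s (L_gen %.3f Gb):\n", lab, l_gen / 1e9))
  cat(sprintf("  coverage %.2f +/- %.2f Mb per animal, mean fROHet %.4f\n",
              mean(isum$total_length_bp) / 1e6,
              sd(isum$total_length_bp) / 1e6, mean(isum$f_rohet)))
  cat(sprintf("  length classes: %s\n",
              paste(sprintf("%s %.1f%%", lc$class, lc$percentage),
                    collapse = ", ")))
  cc <- tryCatch(chromosome_correlation(cs), error = function(e) NULL)
  if (!is.null(cc)) {
    cat(sprintf("  count vs chromosome length: r=%.3f (p=%.3g)\n",
                cc$r_count, cc$p_count))
  }
}

cat("\nreference Duroc populations, recomputed from printed totals:\n")
pub <- read.table(
  system.file("extdata", "duroc_reference_summary.tsv", package = "rohet"),
  header = TRUE, sep = "\t")
for (i in seq_len(nrow(pub))) {
  r <- population_report(
    pub$total_runs[i], pub$n_individuals[i],
    mean_coverage_bp = pub$mean_coverage_mb[i] * 1e6,
    sd_coverage_bp = pub$sd_coverage_mb[i] * 1e6,
    l_gen_bp = pub$l_gen_gb[i] * 1e9,
    class_counts = c(pub$count_1_2mb[i], pub$count_2_4mb[i],
                     pub$count_gt4mb[i]),
    class_labels = c("1-2 Mb", "2-4 Mb", ">4 Mb"))
  cat(sprintf(
    "  %s: %.2f runs/pig, coverage %.2f +/- %.2f Mb, fROHet %.3f, 1-2 Mb %.2f%%\n",
    pub$population[i], r$mean_runs_per_individual, r$mean_coverage_mb,
    r$sd_coverage_mb, r$f_rohet, r$length_classes$percentage[1]))
}
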