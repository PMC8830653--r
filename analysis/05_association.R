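#!/usr/bin/env Rscript
# Stage 5: region-presence association with the quantitative traits.
#
# Unique shared regions (coverage-based carriership, >= 20 carriers) are
# tested per trait under y = farm + birth_year + sex + region + e; each
# trait's significance threshold is FDR * N / M with FDR = 0.01, N the
# regions with p < 0.01 and M all effective regions. The planted ADG
# region should surface; the null trait calibrates the false-positive
# side.

suppressPackageStartupMessages(library(rohet))

for (lab in c("A", "B")) {
  d <- file.path("results", paste0("pop", lab))
  runs <- read.delim(file.path(d, "runs.tsv"))
  phen <- read_phenotypes(file.path(d, paste0("pop", lab,
                                              "_phenotypes.tsv")))
  pred <- build_region_predictors(runs, phen$id, min_carriers = 20,
                                  mode = "cover")
  sc <- scan_regions(pred, phen, traits = c("ADG", "NULLTRAIT"))
  write.table(sc$associations, file.path(d, "associations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sc$thresholds, file.path(d, "assoc_thresholds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("population %s: %d effective regions (>= 20 carriers)\n",
              lab, nrow(pred$regions)))
  for (i in seq_len(nrow(sc$thresholds))) {
    th <- sc$thresholds[i, ]
    nsig <- sum(sc$associations$significant &
                  sc$associations$trait == th$trait)
    cat(sprintf("  %-10s threshold p < %-8.3g (N=%d, M=%d): %d significant\n",
                th$trait, th$p_threshold, th$n_below, th$m_total, nsig))
  }

  truth <- jsonlite::read_json(file.path(d, paste0("pop", lab,
                                                   "_truth.json")),
                               simplifyVector = TRUE)
  focal <- truth$regions[1, ]
  hits <- sc$associations[sc$associations$trait == "ADG" &
                            sc$associations$chrom == focal$chrom &
                            sc$associations$start_bp <= focal$end_bp &
                            sc$associations$end_bp >= focal$start_bp, ]
  if (nrow(hits)) {
    best <- hits[which.min(hits$p), ]
    cat(sprintf(
      "  focal planted region: best overlapping fit beta=%.2f (se %.2f, p=%.3g, %d carriers), significant: %s\n",
      best$beta, best$se, best$p, best$n_carriers, best$significant))
  } else {
    cat("  focal planted region: no overlapping effective region\n")
  }

  ps <- pleiotropy_summary(sc$associations)
  if (nrow(ps)) {
    write.table(ps, file.path(d, "pleiotropy.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cat(sprintf("  pleiotropic regions (>= 2 traits): %d\n",
              sum(ps$pleiotropic)))
}
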