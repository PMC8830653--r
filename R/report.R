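#' Population-level report statistics
#'
#' Recomputes the headline descriptive statistics of a heterozygosity-runs
#' study from raw totals: mean runs per individual, mean +/- SD genome
#' coverage, the genome fraction fROHet, and the length-class percentage
#' table. Usable both on pipeline output and on published totals (each
#' number is a plain function of the inputs, so every report entry can be
#' recomputed from the stage tables alone).
#'
#' @param total_runs total number of detected runs.
#' @param n_individuals number of genotyped individuals.
#' @param mean_coverage_bp mean per-individual summed run length (bp).
#' @param sd_coverage_bp SD of per-individual summed run length (bp).
#' @param l_gen_bp total autosome length (bp).
#' @param class_counts optional named/ordered vector of per-length-class
#'   run counts.
#' @param class_labels labels for `class_counts`.
#' @return list: `mean_runs_per_individual`, `mean_coverage_mb`,
#'   `sd_coverage_mb`, `f_rohet`, `length_classes` (or `NULL`).
#' @export
population_report <- function(total_runs, n_individuals,
                              mean_coverage_bp = NA_real_,
                              sd_coverage_bp = NA_real_,
                              l_gen_bp = 2.45e9,
                              class_counts = NULL,
                              class_labels = names(class_counts)) {
  stopifnot(n_individuals > 0)
  list(
    mean_runs_per_individual = total_runs / n_individuals,
    mean_coverage_mb = mean_coverage_bp / 1e6,
    sd_coverage_mb = sd_coverage_bp / 1e6,
    f_rohet = frohet(mean_coverage_bp, l_gen_bp),
    length_classes = if (!is.null(class_counts)) {
      length_class_table(class_counts, class_labels)
    } else NULL
  )
}

#' Human-readable pipeline summary
#'
#' Prints total runs, mean runs per individual, mean +/- SD coverage, mean
#' fROHet, the length-class table, island count and per-trait significant
#' region counts; sections whose stage output is missing are omitted with
#' a notice.
#'
#' @param res pipeline result list from [run_pipeline()].
#' @return Invisibly, a list of the printed numbers.
#' @export
report_tables <- function(res) {
  out <- list()
  cat("== Runs of heterozygosity: population report ==\n")
  if (!is.null(res$runs) && !is.null(res$individual_summary)) {
    isum <- res$individual_summary
    cov_mb <- isum$total_length_bp / 1e6
    out$total_runs <- nrow(res$runs)
    out$mean_runs_per_individual <- nrow(res$runs) / nrow(isum)
    out$mean_coverage_mb <- mean(cov_mb)
    out$sd_coverage_mb <- stats::sd(cov_mb)
    out$mean_f_rohet <- mean(isum$f_rohet)
    cat(sprintf("total runs: %d over %d individuals (mean %.2f per individual)\n",
                out$total_runs, nrow(isum),
                out$mean_runs_per_individual))
    cat(sprintf("coverage: %.2f +/- %.2f Mb per individual; mean fROHet %.3f (L_gen %.3g Gb)\n",
                out$mean_coverage_mb, out$sd_coverage_mb,
                out$mean_f_rohet, res$l_gen_bp / 1e9))
  } else {
    cat("[no run/summary output]\n")
  }
  if (!is.null(res$length_classes)) {
    cat("length classes:\n")
    lc <- res$length_classes
    for (i in seq_len(nrow(lc))) {
      cat(sprintf("  %-9s %8d runs  %6.2f%%  mean %.3f Mb\n",
                  lc$class[i], lc$count[i], lc$percentage[i],
                  lc$mean_length_mb[i]))
    }
    out$length_classes <- lc
  } else {
    cat("[no length-class output]\n")
  }
  if (!is.null(res$chromosome_correlation)) {
    cc <- res$chromosome_correlation
    cat(sprintf("chromosome-length correlation: count r=%.3f (p=%.3g), coverage r=%.3f (p=%.3g)\n",
                cc$r_count, cc$p_count, cc$r_coverage, cc$p_coverage))
    out$chromosome_correlation <- cc
  }
  if (!is.null(res$islands)) {
    cat(sprintf("islands: %d regions at incidence threshold %.3f\n",
                nrow(res$islands), res$threshold))
    out$n_islands <- nrow(res$islands)
    out$threshold <- res$threshold
  } else {
    cat("[no island output]\n")
  }
  if (!is.null(res$associations)) {
    sig <- res$associations[res$associations$significant %in% TRUE, ,
                            drop = FALSE]
    tab <- table(factor(sig$trait, levels = unique(res$associations$trait)))
    cat("association: significant regions per trait:\n")
    for (tr in names(tab)) {
      th <- res$thresholds$p_threshold[res$thresholds$trait == tr]
      cat(sprintf("  %-10s %4d significant (p < %.3g)\n",
                  tr, tab[[tr]], th))
    }
    out$significant_per_trait <- as.list(tab)
    if (!is.null(res$pleiotropy) && nrow(res$pleiotropy)) {
      cat(sprintf("pleiotropy: %d regions significant for >= 2 traits\n",
                  sum(res$pleiotropy$pleiotropic)))
      out$n_pleiotropic <- sum(res$pleiotropy$pleiotropic)
    }
  } else {
    cat("[no association output]\n")
  }
  invisible(out)
}
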