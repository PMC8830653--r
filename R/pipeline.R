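#' Assemble a pipeline configuration
#'
#' Merges user settings over the stage defaults. Input is either a
#' simulated population (`population =`) or PED/MAP (+ phenotype) paths.
#' Pass a YAML file path instead of a list to load settings from disk.
#'
#' @param population optional output of [simulate_population()]; when
#'   given, `ped`/`map`/`phenotypes` paths are ignored.
#' @param ped,map,phenotypes input file paths (see [read_ped_map()],
#'   [read_phenotypes()]).
#' @param outdir optional output directory; when set, every stage writes
#'   its TSV/BED output there plus a JSON run manifest.
#' @param label population label used in messages and the manifest.
#' @param qc list of [filter_snps()] arguments.
#' @param runs list of [detect_runs()] arguments.
#' @param summaries list: `l_gen_bp` (default: from the map) and
#'   `class_boundaries_mb`.
#' @param islands list: `top_fraction`, `max_gap_bp`, `min_snp`.
#' @param assoc list: `traits` (default: every numeric phenotype column),
#'   `covariates`, `min_carriers`, `mode`, `fdr`, `p0`, or `NULL` to skip
#'   the association stage.
#' @return A `rohet_config` list.
#' @export
pipeline_config <- function(population = NULL, ped = NULL, map = NULL,
                            phenotypes = NULL, outdir = NULL,
                            label = "pop",
                            qc = list(), runs = list(), summaries = list(),
                            islands = list(), assoc = list()) {
  cfg <- list(
    population = population, ped = ped, map = map, phenotypes = phenotypes,
    outdir = outdir, label = label,
    qc = utils::modifyList(list(call_rate_min = 0.90, maf_min = 0.05,
                                hwe_alpha = 1e-6, autosome_max = 18L,
                                hwe_test = "exact"), qc),
    runs = utils::modifyList(list(min_length_bp = 1e6, min_snp = 15,
                                  max_gap_bp = 1e6, max_opposite = 1,
                                  max_missing = 0, target_state = "HET",
                                  gap_scope = "all"), runs),
    summaries = utils::modifyList(list(l_gen_bp = NULL,
                                       class_boundaries_mb = c(1, 2, 4)),
                                  summaries),
    islands = utils::modifyList(list(top_fraction = 0.01, max_gap_bp = 1e6,
                                     min_snp = 2), islands),
    assoc = if (is.null(assoc)) NULL else
      utils::modifyList(list(traits = NULL,
                             covariates = c("farm", "birth_year", "sex"),
                             min_carriers = 20, mode = "exact",
                             fdr = 0.01, p0 = 0.01), assoc)
  )
  class(cfg) <- "rohet_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return A `rohet_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.write_stage <- function(outdir, name, df) {
  if (is.null(outdir)) return(invisible(NULL))
  path <- file.path(outdir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full heterozygosity-runs pipeline on one population
#'
#' Stages, in order: genotype input, SNP QC, run detection, per-individual /
#' length-class / per-chromosome summaries, incidence track + top-occurrence
#' islands, and (when phenotypes are available) the region-presence
#' association scan with its FDR-derived threshold and pleiotropy table.
#' One population per invocation; thresholds (top-1% incidence, FDR) are
#' population-specific.
#'
#' @param config a `rohet_config` from [pipeline_config()], a list of its
#'   arguments, or a YAML path.
#' @param quiet suppress stage messages.
#' @return list with elements `geno` (post-QC), `qc_report`, `runs`,
#'   `individual_summary`, `length_classes`, `chromosome_summary`,
#'   `chromosome_correlation`, `incidence`, `threshold`, `islands`,
#'   `predictors`, `associations`, `thresholds`, `pleiotropy`, `l_gen_bp`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "rohet_config")) {
    config <- do.call(pipeline_config, config)
  }
  say <- function(...) if (!quiet) message("[", config$label, "] ", ...)
  stage <- "input"
  res <- list()
  tryCatch({
    phen <- NULL
    if (!is.null(config$population)) {
      g0 <- config$population$geno
      phen <- config$population$phenotypes
    } else {
      if (is.null(config$ped) || is.null(config$map)) {
        stop("config needs either a population or ped+map paths")
      }
      g0 <- read_ped_map(config$ped, config$map)
      if (!is.null(config$phenotypes)) {
        phen <- read_phenotypes(config$phenotypes)
      }
    }
    say("input: ", length(g0$ids), " individuals, ", nrow(g0$map), " SNPs")

    stage <- "qc"
    fq <- do.call(filter_snps, c(list(g0), config$qc))
    g <- fq$geno
    res$qc_report <- fq$report
    res$geno <- g
    say("qc: ", fq$report$n_retained, "/", fq$report$n_input,
        " SNPs retained")

    stage <- "detect"
    runs <- do.call(detect_runs, c(list(g), config$runs))
    res$runs <- runs
    say("detect: ", nrow(runs), " runs in ", length(unique(runs$id)),
        " individuals")

    stage <- "summaries"
    l_gen <- config$summaries$l_gen_bp
    if (is.null(l_gen)) l_gen <- map_genome_length(g$map)
    res$l_gen_bp <- l_gen
    res$individual_summary <- summarize_individuals(runs, g$ids, l_gen)
    res$length_classes <- if (nrow(runs)) {
      classify_lengths(runs, config$summaries$class_boundaries_mb)
    } else NULL
    res$chromosome_summary <- summarize_chromosomes(runs, g$map)
    res$chromosome_correlation <-
      if (nrow(res$chromosome_summary) >= 3 && nrow(runs) &&
          stats::sd(res$chromosome_summary$n_runs) > 0) {
        chromosome_correlation(res$chromosome_summary)
      } else NULL
    say("summaries: mean fROHet ",
        signif(mean(res$individual_summary$f_rohet), 3))

    stage <- "islands"
    res$incidence <- snp_incidence(runs, g$map, length(g$ids))
    res$threshold <- occurrence_threshold(res$incidence,
                                          config$islands$top_fraction)
    res$islands <- call_islands(res$incidence, res$threshold,
                                config$islands$max_gap_bp,
                                config$islands$min_snp)
    say("islands: threshold ", signif(res$threshold, 3), ", ",
        nrow(res$islands), " islands")

    if (!is.null(config$assoc) && !is.null(phen)) {
      stage <- "assoc"
      traits <- config$assoc$traits
      if (is.null(traits)) {
        traits <- names(phen)[vapply(phen, is.numeric, logical(1))]
      }
      pred <- build_region_predictors(runs, g$ids,
                                      config$assoc$min_carriers,
                                      config$assoc$mode)
      res$predictors <- pred
      if (nrow(pred$regions) && length(traits)) {
        sc <- scan_regions(pred, phen, traits,
                           covariate_cols = config$assoc$covariates,
                           fdr = config$assoc$fdr, p0 = config$assoc$p0)
        res$associations <- sc$associations
        res$thresholds <- sc$thresholds
        res$pleiotropy <- if (length(traits) >= 2) {
          pleiotropy_summary(sc$associations)
        } else NULL
        say("assoc: ", nrow(pred$regions), " effective regions x ",
            length(traits), " traits; ",
            sum(sc$associations$significant), " significant")
      } else {
        say("assoc: no effective regions (or no traits); scan skipped")
      }
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    od <- config$outdir
    .write_stage(od, "qc_report", qc_report_table(res$qc_report))
    .write_stage(od, "runs", res$runs)
    runs_to_bed(res$runs, file.path(od, "runs.bed"))
    .write_stage(od, "individual_summary", res$individual_summary)
    if (!is.null(res$length_classes)) {
      .write_stage(od, "length_classes", res$length_classes)
    }
    .write_stage(od, "chromosome_summary", res$chromosome_summary)
    .write_stage(od, "incidence", res$incidence)
    .write_stage(od, "islands", res$islands)
    if (!is.null(res$associations)) {
      .write_stage(od, "associations", res$associations)
      .write_stage(od, "assoc_thresholds", res$thresholds)
      if (!is.null(res$pleiotropy) && nrow(res$pleiotropy)) {
        .write_stage(od, "pleiotropy", res$pleiotropy)
      }
    }
    manifest <- list(
      label = config$label,
      params = config[c("qc", "runs", "summaries", "islands", "assoc")],
      n_individuals = length(res$geno$ids),
      n_snps_retained = nrow(res$geno$map),
      n_runs = nrow(res$runs),
      threshold = res$threshold,
      n_islands = nrow(res$islands),
      inputs = if (!is.null(config$ped)) {
        as.list(tools::md5sum(c(config$ped, config$map)))
      } else "in-memory population",
      files = list.files(od, pattern = "\\.(tsv|bed)$")
    )
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <- manifest
  }
  res
}
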