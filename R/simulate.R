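#' Synthetic study configuration
#'
#' Defines the generative conditions for a self-contained heterozygosity
#' study: a multi-chromosome 50K-chip-like SNP map, baseline per-SNP
#' heterozygosity in Hardy-Weinberg proportions, planted
#' heterozygosity-rich segments carried by configurable fractions of
#' individuals, and quantitative traits driven by farm/year/sex fixed
#' effects plus a planted-region presence effect and Gaussian noise.
#'
#' Defaults describe a 500-animal population on an 18-autosome map with
#' 217 SNPs per chromosome at mean 62.5 kb spacing (the density of a ~40K
#' post-QC porcine array, scaled to ~1/10 of the genome). Several regions
#' with graded carrier fractions are planted so that the top-1% occurrence
#' threshold is a meaningful order statistic; the focal region (carrier
#' fraction 0.4) drives the first trait with an effect of 5 trait units
#' against residual SD 1.
#'
#' @param n_individuals number of animals.
#' @param n_chromosomes number of autosomes.
#' @param snps_per_chromosome SNPs per autosome.
#' @param mean_spacing_bp mean inter-SNP spacing (exponential draws).
#' @param baseline_het baseline per-SNP heterozygote probability; the
#'   implied allele frequency follows Hardy-Weinberg proportions.
#' @param planted_regions data.frame with columns `chrom`, `start_bp`,
#'   `end_bp`, `carrier_fraction`, `within_region_het`; regions must be
#'   pairwise disjoint and inside the expected chromosome span.
#' @param trait_models list of per-trait lists with fields `name`,
#'   `region` (planted-region row index or `NA` for a null trait),
#'   `beta` (presence effect in trait units), `sd` (residual SD),
#'   `intercept`, and effect vectors `farm_effects`, `year_effects`,
#'   `sex_effects` (first level is the reference).
#' @param n_farms,n_years number of farm and birth-year levels, assigned
#'   uniformly at random.
#' @param seed RNG seed used by [simulate_population()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 500,
                       n_chromosomes = 18,
                       snps_per_chromosome = 217,
                       mean_spacing_bp = 62500,
                       baseline_het = 0.30,
                       planted_regions = default_planted_regions(),
                       trait_models = default_trait_models(),
                       n_farms = 3, n_years = 3,
                       seed = 1L) {
  stopifnot(baseline_het >= 0, baseline_het <= 1,
            n_individuals >= 0, n_chromosomes >= 0,
            snps_per_chromosome >= 0, mean_spacing_bp > 0)
  if (!is.null(planted_regions) && nrow(planted_regions)) {
    stopifnot(all(planted_regions$carrier_fraction >= 0),
              all(planted_regions$carrier_fraction <= 1),
              all(planted_regions$within_region_het >= 0),
              all(planted_regions$within_region_het <= 1),
              all(planted_regions$start_bp < planted_regions$end_bp))
    # pairwise disjoint within a chromosome
    for (ch in unique(planted_regions$chrom)) {
      r <- planted_regions[planted_regions$chrom == ch, , drop = FALSE]
      r <- r[order(r$start_bp), , drop = FALSE]
      if (nrow(r) > 1 && any(r$start_bp[-1] <= r$end_bp[-nrow(r)])) {
        stop("planted regions overlap on chromosome ", ch)
      }
    }
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_chromosomes = as.integer(n_chromosomes),
         snps_per_chromosome = as.integer(snps_per_chromosome),
         mean_spacing_bp = mean_spacing_bp,
         baseline_het = baseline_het,
         planted_regions = planted_regions,
         trait_models = trait_models,
         n_farms = as.integer(n_farms), n_years = as.integer(n_years),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default planted heterozygosity-rich regions
#'
#' Eight disjoint segments of ~1.2-1.5 Mb (roughly 20-25 SNPs at the
#' default spacing) with carrier fractions graded from 0.4 down to 0.08, so
#' the population has a realistic spectrum of heterozygosity hotspots and
#' the top-1% incidence quantile separates true hotspots from background.
#' Region 1 is the focal region used by the default trait model.
#'
#' @return data.frame of planted regions.
#' @export
default_planted_regions <- function() {
  data.frame(
    chrom = c(1L, 3L, 5L, 8L, 9L, 11L, 15L, 17L),
    start_bp = c(3.0e6, 5.0e6, 2.0e6, 7.0e6, 9.0e6, 4.0e6, 6.0e6, 3.0e6),
    end_bp   = c(4.5e6, 6.3e6, 3.4e6, 8.2e6, 10.3e6, 5.2e6, 7.1e6, 4.2e6),
    carrier_fraction = c(0.40, 0.25, 0.22, 0.20, 0.18, 0.15, 0.12, 0.08),
    within_region_het = 0.95,
    stringsAsFactors = FALSE
  )
}

#' Default trait models
#'
#' An ADG-like trait (g/day scale intercept) driven by focal region 1 with
#' effect `beta = 5` against residual SD 1, plus a null trait with no
#' region effect for calibration checks.
#'
#' @return list of trait-model lists.
#' @export
default_trait_models <- function() {
  list(
    list(name = "ADG", region = 1L, beta = 5, sd = 1, intercept = 600,
         farm_effects = c(0, 10, 18), year_effects = c(0, -5, 6),
         sex_effects = c(0, 12)),
    list(name = "NULLTRAIT", region = NA_integer_, beta = 0, sd = 1,
         intercept = 0, farm_effects = c(0, 2, 4),
         year_effects = c(0, 1, -1), sex_effects = c(0, 3))
  )
}

#' Simulate a SNP map
#'
#' Per-chromosome positions are cumulative sums of inter-SNP spacings drawn
#' from an exponential distribution with the configured mean (rounded up to
#' at least 1 bp, so positions are strictly increasing).
#'
#' @param cfg a [sim_config()].
#' @return SNP map data.frame: `chrom`, `snp_id`, `bp`.
#' @export
simulate_map <- function(cfg) {
  m <- cfg$snps_per_chromosome
  if (cfg$n_chromosomes == 0L || m == 0L) {
    return(data.frame(chrom = integer(0), snp_id = character(0),
                      bp = integer(0), stringsAsFactors = FALSE))
  }
  maps <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
    sp <- pmax(1, round(stats::rexp(m, rate = 1 / cfg$mean_spacing_bp)))
    data.frame(chrom = ch,
               snp_id = sprintf("snp%d_%d", ch, seq_len(m)),
               bp = as.integer(cumsum(sp)), stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Simulate genotypes with planted heterozygosity-rich segments
#'
#' Background genotypes are drawn per SNP independently (no linkage
#' disequilibrium) in Hardy-Weinberg proportions at the allele frequency
#' implied by `baseline_het` (`q` solves `2q(1-q) = baseline_het`). For
#' each planted region, a random carrier subset of size
#' `round(carrier_fraction * n)` is heterozygous at region SNPs with
#' probability `within_region_het`, homozygous otherwise. No calls are
#' missing.
#'
#' @param map SNP map from [simulate_map()].
#' @param cfg a [sim_config()].
#' @return list: `geno` (a `rohet_geno`) and `truth` (planted regions with
#'   carrier id lists and the SNP index range of each region).
#' @export
simulate_genotypes <- function(map, cfg) {
  n <- cfg$n_individuals
  m <- nrow(map)
  ids <- sprintf("ind%04d", seq_len(n))
  h <- cfg$baseline_het
  if (h > 0.5) stop("baseline_het > 0.5 has no Hardy-Weinberg solution")
  q <- (1 - sqrt(1 - 2 * h)) / 2

  u <- matrix(stats::runif(n * m), n, m)
  p0 <- (1 - q)^2
  geno <- matrix(0L, n, m)
  geno[u >= p0 & u < p0 + h] <- 1L
  geno[u >= p0 + h] <- 2L

  regions <- cfg$planted_regions
  carriers <- list()
  if (!is.null(regions) && nrow(regions)) {
    regions$snp_from <- NA_integer_
    regions$snp_to <- NA_integer_
    for (r in seq_len(nrow(regions))) {
      cols <- which(map$chrom == regions$chrom[r] &
                      map$bp >= regions$start_bp[r] &
                      map$bp <= regions$end_bp[r])
      if (!length(cols)) {
        warning("planted region ", r, " covers no SNP")
        carriers[[r]] <- character(0)
        next
      }
      regions$snp_from[r] <- cols[1]
      regions$snp_to[r] <- cols[length(cols)]
      n_car <- round(regions$carrier_fraction[r] * n)
      if (n_car < 1) {
        warning("planted region ", r, ": carrier fraction yields 0 carriers")
        carriers[[r]] <- character(0)
        next
      }
      who <- sample.int(n, n_car)
      carriers[[r]] <- ids[who]
      wrh <- regions$within_region_het[r]
      u2 <- matrix(stats::runif(n_car * length(cols)), n_car, length(cols))
      block <- matrix(1L, n_car, length(cols))
      # non-heterozygous region calls fall back to a Hardy-Weinberg
      # homozygote split at the background allele frequency
      hom_alt_frac <- if (q > 0) q^2 / (q^2 + (1 - q)^2) else 0
      hom <- u2 >= wrh
      block[hom] <- ifelse(stats::runif(sum(hom)) < hom_alt_frac, 2L, 0L)
      geno[who, cols] <- block
    }
  } else {
    regions <- data.frame()
  }

  g <- genotype_matrix(geno, map, ids)
  truth <- list(regions = regions, carriers = carriers, ids = ids)
  list(geno = g, truth = truth)
}

#' Simulate phenotypes from the fixed-effects generative model
#'
#' `y = intercept + farm + year + sex + beta * carrier + N(0, sd)`, the
#' same generative form the association stage fits. Farm, birth-year and
#' sex levels are assigned uniformly at random and shared across traits.
#'
#' @param truth the `truth` element from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return data.frame: `id`, `farm`, `birth_year`, `sex`, then one column
#'   per trait.
#' @export
simulate_phenotypes <- function(truth, cfg) {
  stopifnot(length(cfg$trait_models) > 0)
  ids <- truth$ids
  n <- length(ids)
  ph <- data.frame(
    id = ids,
    farm = sprintf("farm%d", sample.int(cfg$n_farms, n, replace = TRUE)),
    birth_year = sprintf("y%d", sample.int(cfg$n_years, n, replace = TRUE)),
    sex = c("M", "F")[sample.int(2L, n, replace = TRUE)],
    stringsAsFactors = FALSE
  )
  farm_i <- as.integer(factor(ph$farm,
                              levels = sprintf("farm%d", 1:cfg$n_farms)))
  year_i <- as.integer(factor(ph$birth_year,
                              levels = sprintf("y%d", 1:cfg$n_years)))
  sex_i <- as.integer(factor(ph$sex, levels = c("M", "F")))
  for (tm in cfg$trait_models) {
    x <- if (!is.na(tm$region) && length(truth$carriers) >= tm$region) {
      as.numeric(ids %in% truth$carriers[[tm$region]])
    } else {
      numeric(n)
    }
    ph[[tm$name]] <- tm$intercept + tm$farm_effects[farm_i] +
      tm$year_effects[year_i] + tm$sex_effects[sex_i] +
      tm$beta * x + stats::rnorm(n, 0, tm$sd)
  }
  ph
}

#' Simulate a complete study population
#'
#' Seeds the RNG from `cfg$seed` and generates map, genotypes and
#' phenotypes; byte-identical outputs under a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return list: `geno`, `phenotypes`, `truth`, `cfg`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- simulate_map(cfg)
  sg <- simulate_genotypes(map, cfg)
  ph <- simulate_phenotypes(sg$truth, cfg)
  list(geno = sg$geno, phenotypes = ph, truth = sg$truth, cfg = cfg)
}

#' Write a simulated population to disk
#'
#' Emits PED/MAP genotypes, a tab-separated phenotype table and a JSON
#' truth file (planted regions and carrier ids) under `dir`.
#'
#' @param pop output of [simulate_population()].
#' @param dir output directory (created if absent).
#' @param prefix file name stem (default `"pop"`).
#' @return Invisibly, the named vector of paths.
#' @export
write_population <- function(pop, dir, prefix = "pop") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ped = file.path(dir, paste0(prefix, ".ped")),
             map = file.path(dir, paste0(prefix, ".map")),
             phen = file.path(dir, paste0(prefix, "_phenotypes.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_ped_map(pop$geno, paths[["ped"]], paths[["map"]])
  utils::write.table(pop$phenotypes, paths[["phen"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- pop$truth
  jsonlite::write_json(
    list(regions = truth$regions, carriers = truth$carriers),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
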