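test_that("simulated maps are deterministic, sorted and sized as configured", {
  cfg <- sim_config(n_individuals = 10, n_chromosomes = 2,
                    snps_per_chromosome = 100, mean_spacing_bp = 60000,
                    planted_regions = NULL, seed = 601)
  set.seed(cfg$seed)
  map <- simulate_map(cfg)
  set.seed(cfg$seed)
  map2 <- simulate_map(cfg)
  expect_identical(map, map2)
  expect_equal(nrow(map), 200L)
  for (ch in 1:2) {
    bp <- map$bp[map$chrom == ch]
    expect_true(all(diff(bp) > 0))
    # exponential spacings with mean 60 kb: span ~6 Mb, loose +/-50% band
    expect_gt(max(bp), 3e6)
    expect_lt(max(bp), 9e6)
  }
  empty <- sim_config(n_individuals = 5, n_chromosomes = 2,
                      snps_per_chromosome = 0, planted_regions = NULL,
                      seed = 1)
  expect_equal(nrow(simulate_map(empty)), 0L)
})

test_that("an empty map flows through detection without error", {
  g <- genotype_matrix(matrix(integer(0), 3, 0),
                       data.frame(chrom = integer(0),
                                  snp_id = character(0), bp = integer(0)),
                       c("a", "b", "c"))
  expect_equal(nrow(detect_runs(g)), 0L)
  s <- summarize_individuals(detect_runs(g), g$ids, 1e9)
  expect_equal(s$n_runs, c(0L, 0L, 0L))
})

test_that("planted carriers, and only carriers, carry runs when baseline is 0", {
  cfg <- sim_config(
    n_individuals = 40, n_chromosomes = 2, snps_per_chromosome = 60,
    baseline_het = 0,
    planted_regions = data.frame(chrom = 1L, start_bp = 5e5, end_bp = 2.2e6,
                                 carrier_fraction = 0.5,
                                 within_region_het = 1.0),
    seed = 602
  )
  pop <- simulate_population(cfg)
  runs <- detect_runs(pop$geno)
  carriers <- pop$truth$carriers[[1]]
  expect_setequal(unique(runs$id), carriers)
  expect_true(all(runs$chrom == 1L))
  focal <- pop$truth$regions[1, ]
  expect_true(all(runs$start_bp >= focal$start_bp))
  expect_true(all(runs$end_bp <= focal$end_bp))
})

test_that("baseline_het = 1 turns every chromosome into one run", {
  cfg <- sim_config(n_individuals = 5, n_chromosomes = 2,
                    snps_per_chromosome = 40, baseline_het = 1,
                    planted_regions = NULL, seed = 603)
  expect_error(simulate_population(cfg), "Hardy-Weinberg")
  # het probability 0.5 is the HWE ceiling; the all-HET limit is exercised
  # by planting a whole-chromosome region at within_region_het = 1
  cfg2 <- sim_config(
    n_individuals = 5, n_chromosomes = 1, snps_per_chromosome = 40,
    baseline_het = 0,
    planted_regions = data.frame(chrom = 1L, start_bp = 1L, end_bp = 1e9,
                                 carrier_fraction = 1,
                                 within_region_het = 1),
    seed = 603
  )
  pop <- simulate_population(cfg2)
  runs <- detect_runs(pop$geno)
  expect_equal(nrow(runs), 5L)
  expect_equal(as.integer(table(runs$id)), rep(1L, 5))
  expect_equal(runs$n_snp, rep(40L, 5))
})

test_that("simulated MAF respects the QC floor across seeds", {
  for (seed in 1:20) {
    cfg <- sim_config(n_individuals = 150, n_chromosomes = 1,
                      snps_per_chromosome = 80, planted_regions = NULL,
                      seed = seed)
    pop <- simulate_population(cfg)
    st <- snp_stats(pop$geno)
    expect_true(all(st$maf >= 0.05), info = paste("seed", seed))
  }
})

test_that("phenotypes recover the generative effects exactly when noiseless", {
  cfg <- sim_config(
    n_individuals = 200, seed = 604,
    trait_models = list(list(name = "T", region = 1L, beta = 5, sd = 0,
                             intercept = 100, farm_effects = c(0, 3, 6),
                             year_effects = c(0, 2, 4),
                             sex_effects = c(0, 1)))
  )
  pop <- simulate_population(cfg)
  x <- as.numeric(pop$geno$ids %in% pop$truth$carriers[[1]])
  ft <- fit_region_trait(pop$phenotypes$T,
                         pop$phenotypes[, c("farm", "birth_year", "sex")],
                         x)
  expect_equal(ft$beta, 5, tolerance = 1e-9)
  expect_lt(ft$p, 1e-8)
})

test_that("effect estimates are unbiased over repeated phenotype draws", {
  cfg <- sim_config(n_individuals = 300, seed = 605)
  pop <- simulate_population(cfg)
  x <- as.numeric(pop$geno$ids %in% pop$truth$carriers[[1]])
  set.seed(605)
  betas <- replicate(60, {
    ph <- simulate_phenotypes(pop$truth, cfg)
    fit_region_trait(ph$ADG, ph[, c("farm", "birth_year", "sex")], x)$beta
  })
  expect_lt(abs(mean(betas) - 5), 0.15)
})

test_that("population files are byte-identical under a fixed seed", {
  cfg <- sim_config(n_individuals = 8, n_chromosomes = 2,
                    snps_per_chromosome = 30, seed = 606,
                    planted_regions = NULL)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  p1 <- write_population(simulate_population(cfg), d1)
  p2 <- write_population(simulate_population(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     info = k)
  }
})

test_that("overlapping planted regions are rejected, tiny fractions warned", {
  expect_error(sim_config(planted_regions = data.frame(
    chrom = 1L, start_bp = c(1e6, 2e6), end_bp = c(3e6, 4e6),
    carrier_fraction = 0.2, within_region_het = 0.95
  )), "overlap")
  cfg <- sim_config(n_individuals = 4, n_chromosomes = 1,
                    snps_per_chromosome = 50,
                    planted_regions = data.frame(
                      chrom = 1L, start_bp = 5e5, end_bp = 1.5e6,
                      carrier_fraction = 0.01, within_region_het = 0.95),
                    seed = 607)
  set.seed(607)
  map <- simulate_map(cfg)
  expect_warning(simulate_genotypes(map, cfg), "0 carriers")
})
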