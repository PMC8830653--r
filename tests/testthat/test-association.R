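test_that("unique-region predictors tally carriers under both modes", {
  ids <- sprintf("a%02d", 1:50)
  # 25 animals share one exact run; 19 share another; one animal has a
  # larger run containing the first region
  runs <- rbind(
    data.frame(id = ids[1:25], chrom = 7L, start_bp = 26.87e6,
               end_bp = 28.12e6),
    data.frame(id = ids[26:44], chrom = 7L, start_bp = 40e6,
               end_bp = 41.5e6),
    data.frame(id = ids[45], chrom = 7L, start_bp = 26e6, end_bp = 29e6)
  )
  runs$n_snp <- 20L; runs$n_opposite <- 0L
  runs$length_bp <- runs$end_bp - runs$start_bp

  exact <- build_region_predictors(runs, ids, min_carriers = 20,
                                   mode = "exact")
  expect_equal(nrow(exact$regions), 1L)
  expect_equal(exact$regions$n_carriers, 25L)
  expect_equal(sum(exact$carriers[, 1]), 25L)

  cover <- build_region_predictors(runs, ids, min_carriers = 20,
                                   mode = "cover")
  # region (26.87, 28.12) is contained in animal 45's big run too
  r1 <- cover$regions[cover$regions$start_bp == 26.87e6, ]
  expect_equal(r1$n_carriers, 26L)
  # the 19-carrier region stays below the effective filter either way
  expect_false(any(exact$regions$start_bp == 40e6))
  expect_false(any(cover$regions$start_bp == 40e6))

  # identical runs in all animals: one predictor carried by everyone
  all_same <- data.frame(id = ids, chrom = 1L, start_bp = 1e6,
                         end_bp = 2.5e6, n_snp = 20L, n_opposite = 0L,
                         length_bp = 1.5e6)
  p2 <- build_region_predictors(all_same, ids)
  expect_equal(p2$regions$n_carriers, length(ids))
})

test_that("carrier tallies equal a hand-rolled count on random run tables", {
  set.seed(501)
  ids <- sprintf("a%02d", 1:30)
  runs <- do.call(rbind, lapply(ids, function(id) {
    k <- sample(0:2, 1)
    if (!k) return(NULL)
    s <- sample(seq(1e6, 2e7, by = 1e6), k)
    data.frame(id = id, chrom = sample(1:2, k, replace = TRUE),
               start_bp = s, end_bp = s + sample(c(1e6, 2e6, 3e6), k,
                                                 replace = TRUE))
  }))
  for (mode in c("exact", "cover")) {
    pred <- build_region_predictors(runs, ids, min_carriers = 1,
                                    mode = mode)
    reg <- pred$regions
    for (j in seq_len(nrow(reg))) {
      manual <- vapply(ids, function(id) {
        r <- runs[runs$id == id & runs$chrom == reg$chrom[j], ,
                  drop = FALSE]
        if (mode == "exact") {
          any(r$start_bp == reg$start_bp[j] & r$end_bp == reg$end_bp[j])
        } else {
          any(r$start_bp <= reg$start_bp[j] & r$end_bp >= reg$end_bp[j])
        }
      }, logical(1))
      expect_equal(unname(pred$carriers[, j]), unname(manual))
      expect_equal(reg$n_carriers[j], sum(manual))
    }
  }
})

test_that("two-group OLS matches the closed form", {
  ft <- fit_region_trait(y = c(1, 2, 3, 4), covariates = NULL,
                         x = c(0, 0, 1, 1))
  expect_equal(ft$beta, 2.0, tolerance = 1e-12)
  expect_equal(ft$se, sqrt(0.5), tolerance = 1e-10)
  expect_equal(ft$df, 2)
  expect_equal(ft$p, 2 * pt(2 / sqrt(0.5), 2, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("degenerate fits are flagged, not mistaken for evidence", {
  ft <- fit_region_trait(rep(3.3, 10), NULL, x = rep(c(0, 1), 5))
  expect_equal(ft$beta, 0)
  expect_equal(ft$p, 1)
  expect_equal(ft$note, "constant response")
  ft2 <- fit_region_trait(rnorm(10), NULL, x = rep(1, 10))
  expect_true(is.na(ft2$p))
  expect_equal(ft2$note, "constant predictor")
})

test_that("OLS with covariates equals the normal-equations oracle", {
  set.seed(502)
  for (i in 1:20) {
    n <- 120
    cv <- data.frame(
      farm = sample(paste0("f", 1:3), n, replace = TRUE),
      birth_year = sample(paste0("y", 1:4), n, replace = TRUE),
      sex = sample(c("M", "F"), n, replace = TRUE)
    )
    x <- rbinom(n, 1, 0.3)
    y <- rnorm(n, sd = 2) + 0.5 * x + as.integer(factor(cv$farm))
    ft <- fit_region_trait(y, cv, x)
    X <- cbind(model.matrix(~ farm + birth_year + sex, cv), x)
    oc <- ols_normal_equations_oracle(X, y)
    expect_equal(ft$beta, unname(oc$beta), tolerance = 1e-8)
    expect_equal(ft$se, unname(oc$se), tolerance = 1e-8)
    expect_equal(ft$t, unname(oc$t), tolerance = 1e-8)
    expect_equal(ft$p, unname(oc$p), tolerance = 1e-8)
    expect_equal(ft$df, oc$df)
  }
})

test_that("single-level covariates are dropped instead of breaking the fit", {
  set.seed(503)
  n <- 40
  cv <- data.frame(farm = "onlyfarm",
                   birth_year = sample(c("y1", "y2"), n, replace = TRUE),
                   sex = sample(c("M", "F"), n, replace = TRUE))
  x <- rbinom(n, 1, 0.5)
  y <- rnorm(n) + x
  ft <- fit_region_trait(y, cv, x)
  expect_false(is.na(ft$p))
  X <- cbind(model.matrix(~ birth_year + sex, cv), x)
  oc <- ols_normal_equations_oracle(X, y)
  expect_equal(ft$beta, unname(oc$beta), tolerance = 1e-10)
})

test_that("the FDR scan threshold follows fdr * N / M", {
  th <- fdr_scan_threshold(c(0.001, 0.005, 0.2, 0.5, 0.8, 0.9, 0.95,
                             0.3, 0.4, 0.6))
  expect_equal(th$p_threshold, 0.01 * 2 / 10)
  expect_equal(th$n_below, 2L)
  th0 <- fdr_scan_threshold(c(0.2, 0.5, 0.9))
  expect_equal(th0$p_threshold, 0)
  th1 <- fdr_scan_threshold(c(0.001, 0.002, 0.0005))
  expect_equal(th1$p_threshold, 0.01)
  # adding a p-value >= p0 never increases the threshold
  set.seed(504)
  for (i in 1:50) {
    p <- runif(sample(3:30, 1))
    base <- fdr_scan_threshold(p)$p_threshold
    more <- fdr_scan_threshold(c(p, runif(1, min = 0.01)))$p_threshold
    expect_lte(more, base + 1e-15)
  }
})

test_that("scan statistics are invariant to animal ordering", {
  set.seed(505)
  pop <- simulate_population(sim_config(n_individuals = 120, seed = 505))
  runs <- detect_runs(pop$geno)
  pred <- build_region_predictors(runs, pop$geno$ids, min_carriers = 10,
                                  mode = "cover")
  sc <- scan_regions(pred, pop$phenotypes, c("ADG", "NULLTRAIT"))
  perm <- sample(nrow(pop$phenotypes))
  sc2 <- scan_regions(pred, pop$phenotypes[perm, ], c("ADG", "NULLTRAIT"))
  expect_equal(sc$associations$beta, sc2$associations$beta,
               tolerance = 1e-10)
  expect_equal(sc$associations$p, sc2$associations$p, tolerance = 1e-10)
  expect_equal(sc$thresholds, sc2$thresholds)
})

test_that("pleiotropy summary counts traits per significant region", {
  a <- data.frame(
    region_id = c("r1", "r1", "r1", "r2", "r3"),
    chrom = c(6L, 6L, 6L, 7L, 8L), start_bp = 1:5, end_bp = 2:6,
    trait = c("BF", "LMP", "TN", "ADG", "LMA"),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  ps <- pleiotropy_summary(a)
  expect_equal(nrow(ps), 2L)
  r1 <- ps[ps$region_id == "r1", ]
  expect_equal(r1$n_traits, 3L)
  expect_equal(r1$traits, "BF,LMP,TN")
  expect_true(r1$pleiotropic)
  expect_false(ps$pleiotropic[ps$region_id == "r2"])

  none <- a
  none$significant <- FALSE
  expect_equal(nrow(pleiotropy_summary(none)), 0L)
})

test_that("a planted effect on two traits flags the region pleiotropic", {
  set.seed(506)
  cfg <- sim_config(
    n_individuals = 250, seed = 506,
    trait_models = list(
      list(name = "T1", region = 1L, beta = 4, sd = 1, intercept = 10,
           farm_effects = c(0, 1, 2), year_effects = c(0, 1, -1),
           sex_effects = c(0, 2)),
      list(name = "T2", region = 1L, beta = -3, sd = 1, intercept = 50,
           farm_effects = c(0, 2, 1), year_effects = c(0, -2, 1),
           sex_effects = c(0, 1))
    )
  )
  pop <- simulate_population(cfg)
  runs <- detect_runs(pop$geno)
  pred <- build_region_predictors(runs, pop$geno$ids, min_carriers = 20,
                                  mode = "cover")
  sc <- scan_regions(pred, pop$phenotypes, c("T1", "T2"))
  ps <- pleiotropy_summary(sc$associations)
  focal <- pop$truth$regions[1, ]
  hit <- ps$chrom == focal$chrom & ps$start_bp <= focal$end_bp &
    ps$end_bp >= focal$start_bp & ps$pleiotropic
  expect_true(any(hit))
})
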