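simple_map <- function(n, chrom = 1L, spacing = 1e5) {
  data.frame(chrom = chrom, snp_id = paste0("c", chrom, "s", seq_len(n)),
             bp = as.integer(seq_len(n) * spacing))
}

test_that("incidence counts covered individuals per SNP", {
  map <- simple_map(20)
  expect_true(all(snp_incidence(.empty <- data.frame(
    id = character(0), chrom = integer(0), start_bp = integer(0),
    end_bp = integer(0), length_bp = integer(0)
  ), map, 10)$incidence == 0))

  # 4 of 10 individuals share one run covering SNPs 5..10
  runs <- data.frame(id = paste0("i", 1:4), chrom = 1L,
                     start_bp = 5e5, end_bp = 1e6)
  tr <- snp_incidence(runs, map, 10)
  expect_equal(tr$incidence, c(rep(0, 4), rep(0.4, 6), rep(0, 10)))
})

test_that("incidence equals the interval-stabbing oracle on random runs", {
  set.seed(401)
  map <- rbind(simple_map(30, 1L), simple_map(25, 2L))
  ids <- paste0("i", 1:12)
  runs <- do.call(rbind, lapply(ids, function(id) {
    k <- sample(0:3, 1)
    if (!k) return(NULL)
    ch <- sample(1:2, k, replace = TRUE)
    # non-overlapping runs per individual per chromosome
    out <- lapply(unique(ch), function(c2) {
      nb <- sum(ch == c2)
      lim <- if (c2 == 1L) 30L else 25L
      pick <- sort(sample(seq_len(lim), min(2 * nb, lim)))
      s <- pick[seq(1, length(pick) - 1, by = 2)]
      e <- pick[seq(2, length(pick), by = 2)]
      data.frame(id = id, chrom = c2, start_bp = s * 1e5, end_bp = e * 1e5)
    })
    do.call(rbind, out)
  }))
  tr <- snp_incidence(runs, map, length(ids))
  expect_equal(tr$incidence, incidence_oracle(runs, map, length(ids)))
})

test_that("the top-occurrence threshold is the type-1 empirical quantile", {
  map <- simple_map(100)
  tr <- data.frame(chrom = map$chrom, snp_id = map$snp_id, bp = map$bp,
                   incidence = seq(0.01, 1, by = 0.01))
  thr <- occurrence_threshold(tr, top_fraction = 0.01)
  expect_equal(thr, 0.99)
  expect_equal(sum(tr$incidence >= thr), 2L) # the top SNP plus the tie set

  tr$incidence <- rep(0.2, 100)
  expect_warning(thr2 <- occurrence_threshold(tr), "constant")
  expect_equal(thr2, 0.2)
})

test_that("flagged SNPs within tie sets keep the flagged count near 1%", {
  set.seed(402)
  inc <- runif(5000)
  tr <- data.frame(chrom = 1L, snp_id = as.character(1:5000),
                   bp = 1:5000, incidence = inc)
  thr <- occurrence_threshold(tr, 0.01)
  n_flagged <- sum(inc >= thr)
  expect_gte(n_flagged, 50)    # at least top_fraction * n
  expect_lte(n_flagged, 51)    # continuous incidences: no big tie set
})

test_that("islands merge by gap, honour min_snp and report singletons", {
  map <- simple_map(60)
  inc <- rep(0, 60)
  inc[10:15] <- 0.5      # island 1: 1.0-1.5 Mb
  inc[40:42] <- 0.6      # island 2: 4.0-4.2 Mb (gap 2.5 Mb splits)
  inc[55] <- 0.9         # singleton
  tr <- data.frame(chrom = map$chrom, snp_id = map$snp_id, bp = map$bp,
                   incidence = inc)
  isl <- call_islands(tr, threshold = 0.4, max_gap_bp = 1e6)
  expect_equal(nrow(isl), 2L)
  expect_equal(isl$start_bp, c(1e6, 4e6))
  expect_equal(isl$end_bp, c(1.5e6, 4.2e6))
  expect_equal(isl$peak_incidence, c(0.5, 0.6))
  singles <- attr(isl, "singletons")
  expect_equal(nrow(singles), 1L)
  expect_equal(singles$start_bp, 5.5e6)

  none <- call_islands(tr, threshold = 0.95)
  expect_equal(nrow(none), 0L)
})

test_that("island calling is idempotent and chromosome-order invariant", {
  set.seed(403)
  map <- rbind(simple_map(40, 2L), simple_map(40, 1L))
  tr <- snp_incidence(
    data.frame(id = rep(paste0("i", 1:6), each = 2),
               chrom = rep(c(1L, 2L), 6),
               start_bp = rep(c(5e5, 2e6), 6),
               end_bp = rep(c(1.5e6, 3.1e6), 6)),
    map, 10)
  a <- call_islands(tr, 0.5)
  b <- call_islands(tr[sample(nrow(tr)), ], 0.5)
  attr(a, "singletons") <- NULL
  attr(b, "singletons") <- NULL
  expect_equal(a, b)
})

test_that("island overlap is symmetric and contained in both inputs", {
  a <- data.frame(chrom = c(1L, 2L), start_bp = c(1e6, 5e6),
                  end_bp = c(3e6, 8e6))
  b <- data.frame(chrom = c(1L, 3L), start_bp = c(2e6, 1e6),
                  end_bp = c(4e6, 2e6))
  ab <- overlap_islands(a, b)
  ba <- overlap_islands(b, a)
  expect_equal(ab, ba)
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$start_bp, 2e6)
  expect_equal(ab$end_bp, 3e6)
  for (i in seq_len(nrow(ab))) {
    inside <- function(x) any(x$chrom == ab$chrom[i] &
                                x$start_bp <= ab$start_bp[i] &
                                x$end_bp >= ab$end_bp[i])
    expect_true(inside(a))
    expect_true(inside(b))
  }
  expect_equal(nrow(overlap_islands(a, b[0, ])), 0L)
})

test_that("a planted high-incidence region is recovered as an island", {
  set.seed(404)
  pop <- simulate_population(sim_config(n_individuals = 300, seed = 404))
  runs <- detect_runs(pop$geno)
  tr <- snp_incidence(runs, pop$geno$map, length(pop$geno$ids))
  thr <- occurrence_threshold(tr, 0.01)
  focal <- pop$truth$regions[1, ]
  in_region <- tr$chrom == focal$chrom & tr$bp >= focal$start_bp &
    tr$bp <= focal$end_bp
  # planted SNPs sit above the top-1% threshold
  expect_gt(mean(tr$incidence[in_region] >= thr), 0.9)
  isl <- call_islands(tr, thr)
  # compare against the planted region's SNP footprint (first/last mapped
  # SNP inside the interval), the finest truth the map can express
  foot_start <- pop$geno$map$bp[focal$snp_from]
  foot_end <- pop$geno$map$bp[focal$snp_to]
  ov <- vapply(seq_len(nrow(isl)), function(i) {
    if (isl$chrom[i] != focal$chrom) return(0)
    reciprocal_overlap(isl$start_bp[i], isl$end_bp[i],
                       foot_start, foot_end)
  }, numeric(1))
  expect_gte(max(ov), 0.8)
})
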