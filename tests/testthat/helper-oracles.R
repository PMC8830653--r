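# Shared fixtures and independent oracles for the test suite.

# one-individual genotype object from a run-state vector
# (1 = heterozygous, 0 = homozygous, NA = missing)
mk_geno1 <- function(states, bp, chrom = 1L, id = "i1") {
  g <- ifelse(is.na(states), NA_integer_, ifelse(states == 1L, 1L, 0L))
  genotype_matrix(matrix(g, 1),
                  data.frame(chrom = chrom,
                             snp_id = paste0("c", chrom, "s", seq_along(bp)),
                             bp = as.integer(bp)),
                  id)
}

# multi-individual genotype object from a code matrix (0/1/2/NA)
mk_geno <- function(codes, bp, chrom = 1L) {
  codes <- as.matrix(codes)
  snp_id <- if (length(bp)) {
    paste0("c", chrom[1], "s", seq_along(bp))
  } else character(0)
  genotype_matrix(codes,
                  data.frame(chrom = rep_len(chrom, length(bp)),
                             snp_id = snp_id,
                             bp = as.integer(bp)),
                  sprintf("i%03d", seq_len(nrow(codes))))
}

# random single-chromosome instance for detection equivalence suites
random_runs_instance <- function(max_snp = 40) {
  n <- sample(5:max_snp, 1)
  st <- sample(c(1L, 0L, NA), n, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  bp <- cumsum(sample(c(1e4, 5e4, 2e5, 6e5, 1.2e6), n, replace = TRUE))
  list(
    g = mk_geno1(st, bp),
    params = list(
      min_length_bp = sample(c(0, 1e5, 5e5), 1),
      min_snp = sample(2:6, 1),
      max_gap_bp = sample(c(2e5, 5e5, 1e9), 1),
      max_opposite = sample(0:2, 1),
      max_missing = sample(0:1, 1),
      target_state = sample(c("HET", "HOM"), 1),
      gap_scope = sample(c("all", "target"), 1)
    )
  )
}

# Hardy-Weinberg exact test by the upward recurrence over heterozygote
# counts (independent of the package's closed-form log-factorial route)
hwe_recurrence_oracle <- function(n_aa, n_ab, n_bb) {
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  hs <- seq(na %% 2, min(na, nb), by = 2)
  lp <- numeric(length(hs))
  if (length(hs) > 1) {
    for (k in 2:length(hs)) {
      h <- hs[k - 1]
      aa <- (na - h) / 2
      bb <- (nb - h) / 2
      lp[k] <- lp[k - 1] + log(4 * aa * bb) - log((h + 1) * (h + 2))
    }
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# textbook Pearson correlation with t-based two-sided p
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# OLS via the normal equations, returning the last coefficient's stats
ols_normal_equations_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  k <- ncol(X)
  t <- b[k] / se[k]
  list(beta = b[k], se = se[k], t = t, df = df,
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

# naive interval-stabbing per-SNP coverage count
incidence_oracle <- function(runs, map, n_individuals) {
  cov <- integer(nrow(map))
  for (j in seq_len(nrow(map))) {
    hit <- runs$chrom == map$chrom[j] &
      runs$start_bp <= map$bp[j] & runs$end_bp >= map$bp[j]
    cov[j] <- length(unique(runs$id[hit]))
  }
  cov / n_individuals
}

# sorted comparable view of a run table
runs_key <- function(r) {
  r <- r[order(r$id, r$chrom, r$start_bp), , drop = FALSE]
  rownames(r) <- NULL
  r
}

published_summary <- function() {
  utils::read.table(
    system.file("extdata", "duroc_reference_summary.tsv", package = "rohet"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE
  )
}
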