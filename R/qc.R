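#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test of Hardy-Weinberg proportions at a biallelic SNP,
#' conditional on the observed allele counts: the p-value is the sum of the
#' probabilities of every heterozygote count that is no more probable than
#' the observed one. The conditional distribution is evaluated in closed
#' form with log-factorials over all heterozygote counts compatible with the
#' allele counts (same parity as the minor-allele count). This is the test
#' PLINK applies by default for its `--hwe` filter.
#'
#' @param n_aa,n_ab,n_bb genotype counts: homozygous reference,
#'   heterozygous, homozygous alternate. Nonnegative, total > 0.
#' @return Exact two-sided p-value in `[0, 1]`.
#' @examples
#' hwe_exact_p(25, 50, 25) # observed equals the modal configuration: p = 1
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("negative genotype count")
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("HWE test undefined for zero genotyped individuals")
  na <- 2L * n_aa + n_ab  # reference allele count
  nb <- 2L * n_bb + n_ab
  hs <- seq.int(na %% 2L, min(na, nb), by = 2L)
  # log P(het = h | n, na) up to the shared normalising constant
  lp <- lfactorial(n) - lfactorial((na - hs) / 2) - lfactorial(hs) -
    lfactorial((nb - hs) / 2) + hs * log(2)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Chi-square (1 df) Hardy-Weinberg test
#'
#' Classical goodness-of-fit alternative to [hwe_exact_p()], offered for
#' comparison; anticonservative at rare alleles.
#'
#' @inheritParams hwe_exact_p
#' @return Asymptotic p-value.
#' @export
hwe_chisq_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("HWE test undefined for zero genotyped individuals")
  p <- (2 * n_aa + n_ab) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_aa, n_ab, n_bb)
  if (any(e == 0)) return(1)
  stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
}

#' Per-SNP allele and genotype summaries
#'
#' @param g a `rohet_geno` object.
#' @return data.frame with one row per SNP: genotype counts (`n_aa`, `n_ab`,
#'   `n_bb`, `n_missing`), `call_rate` and `maf` (minor allele frequency from
#'   non-missing calls; `NaN` when no call is present).
#' @export
snp_stats <- function(g) {
  geno <- g$geno
  n_aa <- colSums(geno == 0L, na.rm = TRUE)
  n_ab <- colSums(geno == 1L, na.rm = TRUE)
  n_bb <- colSums(geno == 2L, na.rm = TRUE)
  n_mis <- colSums(is.na(geno))
  called <- n_aa + n_ab + n_bb
  p_alt <- (2 * n_bb + n_ab) / (2 * called)
  data.frame(
    snp_id = g$map$snp_id, chrom = g$map$chrom, bp = g$map$bp,
    n_aa = n_aa, n_ab = n_ab, n_bb = n_bb, n_missing = n_mis,
    call_rate = called / nrow(geno),
    maf = pmin(p_alt, 1 - p_alt),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' SNP quality control
#'
#' Removes SNPs failing any of four rules, in this order of attribution:
#' call rate below `call_rate_min`, minor allele frequency below `maf_min`,
#' Hardy-Weinberg exact-test p-value below `hwe_alpha`, and non-autosomal
#' position (chromosome label missing or outside `1..autosome_max`). Every
#' rule is evaluated on the full input; a SNP failing several rules is
#' counted once, under the first rule it fails.
#'
#' @param g a `rohet_geno` object.
#' @param call_rate_min minimum fraction of non-missing calls (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param hwe_alpha HWE p-value threshold (default `1e-6`). Set to `0`, `NA`
#'   or `NULL` to disable the HWE rule (e.g. for simulated genotypes with no
#'   genotyping artifacts).
#' @param autosome_max largest autosome label retained (default 18, the
#'   *Sus scrofa* autosome count).
#' @param hwe_test `"exact"` (default) or `"chisq"`.
#' @return list with elements `geno` (the filtered `rohet_geno`) and
#'   `report` (a `rohet_qc` removal report).
#' @export
filter_snps <- function(g, call_rate_min = 0.90, maf_min = 0.05,
                        hwe_alpha = 1e-6, autosome_max = 18L,
                        hwe_test = c("exact", "chisq")) {
  stopifnot(inherits(g, "rohet_geno"))
  hwe_test <- match.arg(hwe_test)
  if (length(g$ids) == 0L) stop("zero individuals in genotype matrix")
  st <- snp_stats(g)
  m <- nrow(st)

  fail_cr <- st$call_rate < call_rate_min
  fail_maf <- !fail_cr & (is.nan(st$maf) | st$maf < maf_min)

  do_hwe <- !is.null(hwe_alpha) && !is.na(hwe_alpha) && hwe_alpha > 0
  hwe_p <- rep(NA_real_, m)
  if (do_hwe) {
    hfun <- if (hwe_test == "exact") hwe_exact_p else hwe_chisq_p
    todo <- which(!fail_cr & !fail_maf)
    hwe_p[todo] <- vapply(
      todo, function(j) hfun(st$n_aa[j], st$n_ab[j], st$n_bb[j]), numeric(1)
    )
  }
  fail_hwe <- !fail_cr & !fail_maf & do_hwe & !is.na(hwe_p) &
    hwe_p < hwe_alpha
  fail_auto <- !fail_cr & !fail_maf & !fail_hwe &
    (is.na(st$chrom) | st$chrom < 1L | st$chrom > autosome_max)

  keep <- !(fail_cr | fail_maf | fail_hwe | fail_auto)
  report <- structure(
    list(
      n_input = m,
      removed = c(call_rate = sum(fail_cr), maf = sum(fail_maf),
                  hwe = sum(fail_hwe), non_autosomal = sum(fail_auto)),
      n_retained = sum(keep),
      n_individuals = length(g$ids),
      params = list(call_rate_min = call_rate_min, maf_min = maf_min,
                    hwe_alpha = if (do_hwe) hwe_alpha else 0,
                    autosome_max = autosome_max, hwe_test = hwe_test)
    ),
    class = "rohet_qc"
  )
  if (!any(keep)) {
    print(report)
    stop("quality control removed every SNP")
  }
  list(geno = subset_snps(g, keep), report = report)
}

#' @export
print.rohet_qc <- function(x, ...) {
  cat("SNP quality control:", x$n_input, "SNPs in,",
      x$n_retained, "retained (", x$n_individuals, "individuals )\n")
  r <- x$removed
  cat(sprintf("  removed: call rate %d | MAF %d | HWE %d | non-autosomal %d\n",
              r[["call_rate"]], r[["maf"]], r[["hwe"]],
              r[["non_autosomal"]]))
  invisible(x)
}

#' QC report as a data.frame (TSV-ready)
#' @param report a `rohet_qc` object.
#' @return data.frame with columns `rule` and `n_removed`, plus retained and
#'   input totals as attributes-free rows.
#' @export
qc_report_table <- function(report) {
  stopifnot(inherits(report, "rohet_qc"))
  data.frame(
    rule = c(names(report$removed), "retained", "input"),
    n_snps = c(unname(report$removed), report$n_retained, report$n_input),
    stringsAsFactors = FALSE
  )
}

#' Modal-genotype fill for missing calls
#'
#' Optional simple imputation: each missing call is replaced by the SNP's
#' most frequent observed genotype state. Off by default everywhere; missing
#' calls otherwise interrupt run detection per the `max_missing` rule.
#'
#' @param g a `rohet_geno` object.
#' @return A `rohet_geno` with no missing calls (SNPs with zero observed
#'   calls are left missing).
#' @export
fill_modal_genotype <- function(g) {
  geno <- g$geno
  for (j in seq_len(ncol(geno))) {
    gj <- geno[, j]
    if (!anyNA(gj)) next
    tab <- tabulate(gj + 1L, nbins = 3L)
    if (sum(tab) == 0L) next
    geno[is.na(gj), j] <- which.max(tab) - 1L
  }
  genotype_matrix(geno, g$map, g$ids, alleles = g$alleles, fam = g$fam)
}
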