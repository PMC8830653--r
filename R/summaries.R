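#' Genome fraction covered by runs of heterozygosity
#'
#' `fROHet = L_ROHet / L_gen`: an individual's total run length divided by
#' the total autosome length, analogous to the ROH-based inbreeding
#' coefficient F_ROH.
#'
#' @param total_length_bp summed run length for an individual, in bp.
#' @param l_gen_bp total autosome length in bp.
#' @return The coverage fraction.
#' @examples
#' frohet(66.53e6, 2.45e9) # ~0.027
#' @export
frohet <- function(total_length_bp, l_gen_bp) {
  stopifnot(l_gen_bp > 0)
  total_length_bp / l_gen_bp
}

#' Total autosome length implied by a SNP map
#'
#' Default genome denominator for [frohet()]: the sum of per-chromosome
#' spans (largest mapped position per chromosome). Override with a fixed
#' assembly length (e.g. 2.45e9 for the pig autosomes) when comparability
#' with published values matters.
#'
#' @param map a SNP map data.frame (`chrom`, `bp`).
#' @return Total length in bp.
#' @export
map_genome_length <- function(map) {
  sum(tapply(map$bp, map$chrom, max))
}

#' Per-individual run summaries
#'
#' @param runs data.frame from [detect_runs()].
#' @param ids character vector of all genotyped individuals (individuals
#'   without runs get zero-filled rows).
#' @param l_gen_bp total autosome length in bp for the fROHet denominator.
#' @return data.frame: `id`, `n_runs`, `total_length_bp`, `f_rohet`.
#' @export
summarize_individuals <- function(runs, ids, l_gen_bp) {
  stopifnot(l_gen_bp > 0)
  ids <- as.character(ids)
  f <- factor(runs$id, levels = ids)
  n_runs <- as.integer(table(f))
  total <- as.numeric(tapply(runs$length_bp, f, sum, default = 0))
  total[is.na(total)] <- 0
  data.frame(id = ids, n_runs = n_runs, total_length_bp = total,
             f_rohet = frohet(total, l_gen_bp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Length-class table from per-class run counts
#'
#' Lower-level constructor behind [classify_lengths()], usable directly on
#' published per-class counts.
#'
#' @param counts integer vector of per-class run counts.
#' @param labels class labels (same length as `counts`).
#' @param mean_length_mb optional per-class mean lengths in Mb.
#' @return data.frame: `class`, `count`, `percentage`, `mean_length_mb`.
#' @export
length_class_table <- function(counts, labels = names(counts),
                               mean_length_mb = NA_real_) {
  total <- sum(counts)
  data.frame(class = labels, count = as.numeric(counts),
             percentage = if (total > 0) 100 * counts / total else
               rep(NA_real_, length(counts)),
             mean_length_mb = mean_length_mb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify runs into length categories
#'
#' Assigns every run to one of the half-open length classes defined by
#' `boundaries_mb` (defaults: `[1, 2)`, `[2, 4)` and `[4, Inf)` Mb) and
#' tabulates counts, percentages of all runs and mean length per class.
#'
#' @param runs data.frame from [detect_runs()].
#' @param boundaries_mb ascending class boundaries in Mb; the first boundary
#'   must not exceed the shortest run (it is the detection minimum).
#' @return data.frame as in [length_class_table()].
#' @export
classify_lengths <- function(runs, boundaries_mb = c(1, 2, 4)) {
  stopifnot(!is.unsorted(boundaries_mb, strictly = TRUE))
  b <- boundaries_mb * 1e6
  if (nrow(runs) && min(runs$length_bp) < b[1]) {
    stop("run shorter than the first class boundary (",
         boundaries_mb[1], " Mb): detection contract violated")
  }
  k <- length(b)
  labels <- c(sprintf("%g-%g Mb", boundaries_mb[-k], boundaries_mb[-1]),
              sprintf(">%g Mb", boundaries_mb[k]))
  cls <- cut(runs$length_bp, breaks = c(b, Inf), right = FALSE,
             labels = labels)
  counts <- as.integer(table(cls))
  means <- as.numeric(tapply(runs$length_bp / 1e6, cls, mean))
  length_class_table(counts, labels, means)
}

#' Per-chromosome run summaries
#'
#' @param runs data.frame from [detect_runs()].
#' @param map SNP map data.frame (`chrom`, `bp`); chromosome length is taken
#'   as the largest mapped position.
#' @return data.frame: `chrom`, `chrom_length_bp`, `n_runs`,
#'   `total_length_bp`.
#' @export
summarize_chromosomes <- function(runs, map) {
  chroms <- sort(unique(map$chrom))
  f <- factor(runs$chrom, levels = chroms)
  data.frame(
    chrom = chroms,
    chrom_length_bp = as.numeric(tapply(map$bp, factor(map$chrom,
                                                       levels = chroms), max)),
    n_runs = as.integer(table(f)),
    total_length_bp = {
      s <- as.numeric(tapply(runs$length_bp, f, sum, default = 0))
      s[is.na(s)] <- 0
      s
    },
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Correlation of run abundance with chromosome length
#'
#' Pearson correlations (two-sided t-test, n-2 df) between chromosome length
#' and (a) the run count and (b) the summed run coverage per chromosome.
#'
#' @param chrom_summary data.frame from [summarize_chromosomes()]; at least
#'   3 chromosomes.
#' @return list: `r_count`, `p_count`, `r_coverage`, `p_coverage`.
#' @export
chromosome_correlation <- function(chrom_summary) {
  stopifnot(nrow(chrom_summary) >= 3)
  len <- chrom_summary$chrom_length_bp
  if (stats::sd(len) == 0 || stats::sd(chrom_summary$n_runs) == 0 ||
      stats::sd(chrom_summary$total_length_bp) == 0) {
    stop("zero variance: chromosome-length correlation undefined")
  }
  a <- stats::cor.test(len, chrom_summary$n_runs, method = "pearson")
  b <- stats::cor.test(len, chrom_summary$total_length_bp,
                       method = "pearson")
  list(r_count = unname(a$estimate), p_count = a$p.value,
       r_coverage = unname(b$estimate), p_coverage = b$p.value)
}
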