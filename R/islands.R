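#' Per-SNP run incidence
#'
#' For every SNP on the map, the fraction of individuals whose detected run
#' covers the SNP's position (a run covers a SNP iff
#' `start_bp <= bp <= end_bp` on the same chromosome). Because one
#' individual's runs on a chromosome never overlap, the per-SNP count equals
#' the number of distinct covered individuals.
#'
#' @param runs data.frame from [detect_runs()].
#' @param map SNP map data.frame (`chrom`, `snp_id`, `bp`).
#' @param n_individuals total genotyped individuals (the denominator).
#' @return data.frame (the incidence track): `chrom`, `snp_id`, `bp`,
#'   `n_covered`, `incidence`.
#' @export
snp_incidence <- function(runs, map, n_individuals) {
  stopifnot(n_individuals > 0)
  cov <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    bp <- map$bp[idx]
    r <- runs[runs$chrom == ch, , drop = FALSE]
    if (!nrow(r)) next
    i1 <- findInterval(r$start_bp - 0.5, bp) + 1L # first SNP >= start
    i2 <- findInterval(r$end_bp + 0.5, bp)        # last SNP <= end
    keep <- i1 <= i2
    if (!any(keep)) next
    d <- integer(length(bp) + 1L)
    add <- tabulate(i1[keep], nbins = length(bp))
    sub <- tabulate(i2[keep] + 1L, nbins = length(bp) + 1L)
    d[seq_along(bp)] <- add
    d <- d - sub
    cov[idx] <- cumsum(d[seq_along(bp)])
  }
  data.frame(chrom = map$chrom, snp_id = map$snp_id, bp = map$bp,
             n_covered = cov, incidence = cov / n_individuals,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-occurrence incidence threshold
#'
#' The empirical `1 - top_fraction` quantile (type 1, inverse CDF) of the
#' per-SNP incidences. SNPs with incidence at or above the threshold are
#' island members; ties at the threshold are all included, so "top 1%" is a
#' set, not an exact count.
#'
#' @param track incidence track from [snp_incidence()].
#' @param top_fraction fraction of SNPs defining the island set
#'   (default 0.01).
#' @return The threshold incidence value.
#' @export
occurrence_threshold <- function(track, top_fraction = 0.01) {
  x <- track$incidence
  stopifnot(length(x) > 0, top_fraction > 0, top_fraction < 1)
  thr <- unname(stats::quantile(x, probs = 1 - top_fraction, type = 1))
  if (min(x) == max(x)) {
    warning("constant incidence track: threshold equals the constant; ",
            "every SNP is flagged")
  }
  thr
}

#' Merge above-threshold SNPs into islands
#'
#' Consecutive SNPs with incidence at or above `threshold` on the same
#' chromosome, separated by at most `max_gap_bp`, are merged into one
#' island whose bounds are the first and last member SNP positions. Flagged
#' SNPs that end up in groups smaller than `min_snp` are reported
#' separately as singletons, not as islands.
#'
#' @param track incidence track from [snp_incidence()].
#' @param threshold incidence threshold, typically from
#'   [occurrence_threshold()].
#' @param max_gap_bp largest distance between successive member SNPs merged
#'   into the same island (default 1 Mb, matching the detection gap).
#' @param min_snp minimum member SNPs for a reported island (default 2).
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `n_snp`,
#'   `peak_incidence`; groups below `min_snp` are attached as the
#'   `"singletons"` attribute.
#' @export
call_islands <- function(track, threshold, max_gap_bp = 1e6, min_snp = 2) {
  stopifnot(threshold >= 0, threshold <= 1)
  flagged <- track[track$incidence >= threshold, , drop = FALSE]
  empty <- data.frame(chrom = integer(0), start_bp = integer(0),
                      end_bp = integer(0), n_snp = integer(0),
                      peak_incidence = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(flagged)) {
    attr(empty, "singletons") <- empty
    return(empty)
  }
  out <- list()
  small <- list()
  for (ch in sort(unique(flagged$chrom))) {
    f <- flagged[flagged$chrom == ch, , drop = FALSE]
    f <- f[order(f$bp), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(f$bp) > max_gap_bp)))
    for (gid in unique(grp)) {
      gset <- f[grp == gid, , drop = FALSE]
      row <- data.frame(chrom = ch, start_bp = min(gset$bp),
                        end_bp = max(gset$bp), n_snp = nrow(gset),
                        peak_incidence = max(gset$incidence),
                        stringsAsFactors = FALSE)
      if (nrow(gset) >= min_snp) out[[length(out) + 1L]] <- row
      else small[[length(small) + 1L]] <- row
    }
  }
  islands <- if (length(out)) do.call(rbind, out) else empty
  rownames(islands) <- NULL
  attr(islands, "singletons") <-
    if (length(small)) do.call(rbind, small) else empty
  islands
}

.islands_granges <- function(x, seqlevels) {
  GenomicRanges::GRanges(
    seqnames = factor(as.character(x$chrom), levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start_bp, end = x$end_bp)
  )
}

#' Intersect two island sets
#'
#' Symmetric interval intersection (e.g. islands of two populations): the
#' returned intervals are contained in both inputs.
#'
#' @param a,b island data.frames from [call_islands()] (columns `chrom`,
#'   `start_bp`, `end_bp`).
#' @return data.frame of overlapping intervals: `chrom`, `start_bp`,
#'   `end_bp`, `width_bp`.
#' @export
overlap_islands <- function(a, b) {
  empty <- data.frame(chrom = integer(0), start_bp = integer(0),
                      end_bp = integer(0), width_bp = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  lv <- as.character(sort(unique(c(a$chrom, b$chrom))))
  ov <- GenomicRanges::intersect(.islands_granges(a, lv),
                                 .islands_granges(b, lv))
  if (!length(ov)) return(empty)
  data.frame(
    chrom = as.integer(as.character(GenomicRanges::seqnames(ov))),
    start_bp = GenomicRanges::start(ov),
    end_bp = GenomicRanges::end(ov),
    width_bp = GenomicRanges::width(ov),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Reciprocal overlap of two intervals
#'
#' Overlap length divided by the longer interval's length; 0 when disjoint.
#' Used to compare a recovered island with a planted truth interval.
#'
#' @param start1,end1,start2,end2 interval bounds (same chromosome assumed).
#' @return fraction in `[0, 1]`.
#' @export
reciprocal_overlap <- function(start1, end1, start2, end2) {
  ov <- max(0, min(end1, end2) - max(start1, start2))
  ov / max(end1 - start1, end2 - start2)
}
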