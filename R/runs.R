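# Run detection: consecutive scanning for runs of heterozygosity (or, with
# the target state flipped, runs of homozygosity).
#
# Output definition shared by detect_runs() and brute_force_runs():
# a window [s, e] of map-consecutive SNPs *qualifies* when
#   - SNPs s and e carry the target state (runs never start or end on an
#     opposite-state or missing SNP);
#   - at most max_opposite opposite-state SNPs lie inside;
#   - at most max_missing missing calls lie inside;
#   - no gap between consecutive SNPs inside exceeds max_gap_bp
#     (gap_scope = "all"; with "target", only gaps between consecutive
#     target-state SNPs are constrained);
#   - e - s + 1 >= min_snp and bp[e] - bp[s] >= min_length_bp.
# Scanning emits, left to right, the qualifying window with the smallest
# start and, for that start, the largest end, then resumes after its end.
# Emitted runs are therefore maximal and non-overlapping.

#' Run-detection parameters
#'
#' Assembles and validates the consecutive-strategy detection parameters.
#' Defaults are the standard ROHet settings for a ~50K porcine array:
#' minimum run length 1 Mb, at least 15 SNPs, maximum inter-SNP gap 1 Mb,
#' at most one opposite genotype and no missing calls inside a run.
#'
#' @param min_length_bp minimum run length in bp (`end_bp - start_bp`).
#' @param min_snp minimum number of SNPs spanned (>= 2).
#' @param max_gap_bp largest tolerated gap between consecutive SNPs in a run.
#' @param max_opposite maximum opposite-state SNPs inside a run.
#' @param max_missing maximum missing calls inside a run.
#' @param target_state `"HET"` for runs of heterozygosity (default) or
#'   `"HOM"` for runs of homozygosity.
#' @param gap_scope `"all"` (default) measures gaps between all consecutive
#'   SNPs in the run's span; `"target"` only between consecutive
#'   target-state SNPs.
#' @return A named list of validated parameters.
#' @export
run_params <- function(min_length_bp = 1e6, min_snp = 15, max_gap_bp = 1e6,
                       max_opposite = 1, max_missing = 0,
                       target_state = c("HET", "HOM"),
                       gap_scope = c("all", "target")) {
  target_state <- match.arg(target_state)
  gap_scope <- match.arg(gap_scope)
  stopifnot(min_length_bp >= 0, min_snp >= 2, max_gap_bp >= 0,
            max_opposite >= 0, max_missing >= 0)
  list(min_length_bp = min_length_bp, min_snp = as.integer(min_snp),
       max_gap_bp = max_gap_bp, max_opposite = as.integer(max_opposite),
       max_missing = as.integer(max_missing), target_state = target_state,
       gap_scope = gap_scope)
}

# states: 1 = target, 0 = opposite, NA = missing, for one chromosome slice;
# bp strictly increasing. Returns integer matrix with columns s, e (indices).
.scan_chromosome <- function(states, bp, p) {
  n <- length(states)
  if (n == 0L) return(matrix(integer(0), 0L, 2L))

  if (p$gap_scope == "all") {
    brk <- which(diff(bp) > p$max_gap_bp)
  } else {
    tidx <- which(!is.na(states) & states == 1L)
    brk <- if (length(tidx) >= 2L) {
      tidx[which(diff(bp[tidx]) > p$max_gap_bp)]
    } else integer(0)
  }
  seg_lo <- c(1L, brk + 1L)
  seg_hi <- c(brk, n)

  out <- vector("list", length(seg_lo))
  for (k in seq_along(seg_lo)) {
    lo <- seg_lo[k]; hi <- seg_hi[k]
    if (lo > hi) next
    st <- states[lo:hi]
    idx <- lo:hi
    tpos <- idx[!is.na(st) & st == 1L]
    if (!length(tpos)) next
    opp_pos <- idx[!is.na(st) & st == 0L]
    mis_pos <- idx[is.na(st)]
    bpos <- sort(c(opp_pos, mis_pos))

    # candidate starts: first target SNP of the segment and the first target
    # SNP after each blocker (opposite or missing call)
    cand_after <- c(lo - 1L, bpos)
    si <- findInterval(cand_after, tpos) + 1L
    si <- si[si <= length(tpos)]
    s <- unique(tpos[si])
    if (!length(s)) next

    # furthest end for each start: last target SNP before the blocker that
    # would overrun either the opposite or the missing budget
    o_before <- findInterval(s - 0.5, opp_pos)
    m_before <- findInterval(s - 0.5, mis_pos)
    ko <- o_before + p$max_opposite + 1L
    km <- m_before + p$max_missing + 1L
    bound <- rep(hi + 1L, length(s))
    ok <- ko <= length(opp_pos)
    bound[ok] <- pmin(bound[ok], opp_pos[ko[ok]])
    ok <- km <= length(mis_pos)
    bound[ok] <- pmin(bound[ok], mis_pos[km[ok]])
    e <- tpos[findInterval(bound - 0.5, tpos)]

    qual <- (e - s + 1L) >= p$min_snp & (bp[e] - bp[s]) >= p$min_length_bp
    # greedy left-to-right selection of non-overlapping maximal windows
    keep <- integer(0)
    cur <- -1L
    for (j in seq_along(s)) {
      if (!qual[j] || s[j] <= cur) next
      keep <- c(keep, j)
      cur <- e[j]
    }
    if (length(keep)) out[[k]] <- cbind(s[keep], e[keep])
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(matrix(integer(0), 0L, 2L))))
}

# opposite-state SNP count inside [s, e] for reporting
.count_state <- function(states, s, e, value) {
  pos <- which(!is.na(states) & states == value)
  findInterval(e + 0.5, pos) - findInterval(s - 0.5, pos)
}

.states_for_target <- function(geno_row, target_state) {
  if (target_state == "HET") {
    st <- ifelse(geno_row == 1L, 1L, 0L)
  } else {
    st <- ifelse(geno_row != 1L, 1L, 0L)
  }
  st[is.na(geno_row)] <- NA_integer_
  st
}

.empty_runs <- function() {
  data.frame(id = character(0), chrom = integer(0), start_bp = integer(0),
             end_bp = integer(0), n_snp = integer(0),
             n_opposite = integer(0), length_bp = integer(0),
             stringsAsFactors = FALSE)
}

#' Detect runs of heterozygosity with the consecutive strategy
#'
#' Scans each individual's genotypes chromosome by chromosome in map order
#' and emits maximal, non-overlapping runs satisfying the detection
#' parameters (see [run_params()] for their meaning and defaults). With
#' `target_state = "HOM"` the same engine detects runs of homozygosity.
#'
#' @param g a `rohet_geno` object (QC-filtered; the map must be sorted,
#'   which [genotype_matrix()] guarantees).
#' @inheritParams run_params
#' @return data.frame with one row per run: `id`, `chrom`, `start_bp`,
#'   `end_bp` (positions of the first and last SNP of the run), `n_snp`
#'   (all SNPs spanned, target and opposite), `n_opposite`, and
#'   `length_bp = end_bp - start_bp`.
#' @export
detect_runs <- function(g, min_length_bp = 1e6, min_snp = 15,
                        max_gap_bp = 1e6, max_opposite = 1, max_missing = 0,
                        target_state = c("HET", "HOM"),
                        gap_scope = c("all", "target")) {
  stopifnot(inherits(g, "rohet_geno"))
  p <- run_params(min_length_bp, min_snp, max_gap_bp, max_opposite,
                  max_missing, match.arg(target_state), match.arg(gap_scope))
  chroms <- unique(g$map$chrom)
  ch_idx <- lapply(chroms, function(ch) which(g$map$chrom == ch))
  bp_all <- g$map$bp

  res <- vector("list", length(g$ids))
  for (i in seq_along(g$ids)) {
    states_all <- .states_for_target(g$geno[i, ], p$target_state)
    acc <- vector("list", length(chroms))
    for (c_i in seq_along(chroms)) {
      idx <- ch_idx[[c_i]]
      bp <- bp_all[idx]
      states <- states_all[idx]
      win <- .scan_chromosome(states, bp, p)
      if (!nrow(win)) next
      s <- win[, 1]; e <- win[, 2]
      acc[[c_i]] <- data.frame(
        id = g$ids[i], chrom = chroms[c_i],
        start_bp = bp[s], end_bp = bp[e],
        n_snp = e - s + 1L,
        n_opposite = .count_state(states, s, e, 0L),
        length_bp = bp[e] - bp[s],
        stringsAsFactors = FALSE
      )
    }
    acc <- acc[!vapply(acc, is.null, logical(1))]
    if (length(acc)) res[[i]] <- do.call(rbind, acc)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(.empty_runs())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Exhaustive-enumeration run detector (test oracle)
#'
#' Reference implementation of the run definition by brute force: every
#' contiguous SNP window is enumerated and checked against all constraints
#' directly, then non-overlapping maximal windows are selected left to
#' right (smallest start, then largest end). Intended for validating
#' [detect_runs()] on small instances; refuses chromosomes with more than
#' 60 SNPs.
#'
#' @inheritParams detect_runs
#' @return Same layout as [detect_runs()].
#' @export
brute_force_runs <- function(g, min_length_bp = 1e6, min_snp = 15,
                             max_gap_bp = 1e6, max_opposite = 1,
                             max_missing = 0,
                             target_state = c("HET", "HOM"),
                             gap_scope = c("all", "target")) {
  stopifnot(inherits(g, "rohet_geno"))
  p <- run_params(min_length_bp, min_snp, max_gap_bp, max_opposite,
                  max_missing, match.arg(target_state), match.arg(gap_scope))
  if (nrow(g$map) && max(table(g$map$chrom)) > 60L) {
    stop("brute_force_runs is a test oracle; chromosomes must have <= 60 SNPs")
  }
  res <- list()
  for (i in seq_along(g$ids)) {
    states_all <- .states_for_target(g$geno[i, ], p$target_state)
    for (ch in unique(g$map$chrom)) {
      idx <- which(g$map$chrom == ch)
      bp <- g$map$bp[idx]
      states <- states_all[idx]
      n <- length(states)
      if (n == 0L) next
      wins <- list()
      for (s in seq_len(n)) {
        if (is.na(states[s]) || states[s] != 1L) next
        for (e in s:n) {
          if (is.na(states[e]) || states[e] != 1L) next
          w <- states[s:e]
          if (sum(!is.na(w) & w == 0L) > p$max_opposite) next
          if (sum(is.na(w)) > p$max_missing) next
          if (p$gap_scope == "all") {
            if (e > s && any(diff(bp[s:e]) > p$max_gap_bp)) next
          } else {
            tb <- bp[s:e][!is.na(w) & w == 1L]
            if (length(tb) > 1L && any(diff(tb) > p$max_gap_bp)) next
          }
          if ((e - s + 1L) < p$min_snp) next
          if ((bp[e] - bp[s]) < p$min_length_bp) next
          wins[[length(wins) + 1L]] <- c(s, e)
        }
      }
      if (!length(wins)) next
      wm <- do.call(rbind, wins)
      cur <- -1L
      sel <- list()
      repeat {
        open <- wm[wm[, 1] > cur, , drop = FALSE]
        if (!nrow(open)) break
        s0 <- min(open[, 1])
        e0 <- max(open[open[, 1] == s0, 2])
        sel[[length(sel) + 1L]] <- c(s0, e0)
        cur <- e0
      }
      sm <- do.call(rbind, sel)
      res[[length(res) + 1L]] <- data.frame(
        id = g$ids[i], chrom = ch,
        start_bp = bp[sm[, 1]], end_bp = bp[sm[, 2]],
        n_snp = sm[, 2] - sm[, 1] + 1L,
        n_opposite = vapply(seq_len(nrow(sm)), function(r) {
          w <- states[sm[r, 1]:sm[r, 2]]
          sum(!is.na(w) & w == 0L)
        }, integer(1)),
        length_bp = bp[sm[, 2]] - bp[sm[, 1]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) return(.empty_runs())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export runs as BED intervals
#'
#' Converts the closed 1-based `[start_bp, end_bp]` run coordinates to the
#' BED convention (0-based, half-open): `bed_start = start_bp - 1`,
#' `bed_end = end_bp`.
#'
#' @param runs data.frame from [detect_runs()].
#' @param path optional output path; when given, a headerless 4-column BED
#'   (`chrom`, `start`, `end`, `id`) is written there.
#' @return The BED data.frame, invisibly when `path` is given.
#' @export
runs_to_bed <- function(runs, path = NULL) {
  bed <- data.frame(chrom = runs$chrom, start = runs$start_bp - 1L,
                    end = runs$end_bp, name = runs$id,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}
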