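#' Build unique-region presence/absence predictors from runs
#'
#' A unique region is a distinct `(chrom, start_bp, end_bp)` triple among
#' all detected runs. Carriership is coded 1/0 per animal under one of two
#' modes: `"exact"` (default) — the animal has a run with exactly those
#' coordinates; `"cover"` — the animal has a run fully containing the
#' region. Regions carried by fewer than `min_carriers` animals are dropped
#' ("effective" regions only).
#'
#' Exact identity presumes many animals share literally identical runs, as
#' happens on imputed array data where run ends snap to the same map
#' positions; on data with stochastic run boundaries, `"cover"` is the
#' usable notion of sharing.
#'
#' @param runs data.frame from [detect_runs()].
#' @param ids character vector of all genotyped animals (carrier matrix
#'   rows).
#' @param min_carriers minimum carriers for an effective region
#'   (default 20).
#' @param mode `"exact"` or `"cover"`.
#' @return list: `regions` (data.frame `region_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_carriers`) and `carriers` (logical matrix, animals x
#'   regions).
#' @export
build_region_predictors <- function(runs, ids, min_carriers = 20,
                                    mode = c("exact", "cover")) {
  mode <- match.arg(mode)
  ids <- as.character(ids)
  empty <- list(
    regions = data.frame(region_id = character(0), chrom = integer(0),
                         start_bp = integer(0), end_bp = integer(0),
                         n_carriers = integer(0), stringsAsFactors = FALSE),
    carriers = matrix(FALSE, length(ids), 0L, dimnames = list(ids, NULL))
  )
  if (!nrow(runs)) return(empty)

  rd <- data.table::as.data.table(runs[, c("id", "chrom", "start_bp",
                                           "end_bp")])
  reg <- unique(rd[, c("chrom", "start_bp", "end_bp")])
  data.table::setorder(reg, chrom, start_bp, end_bp)

  if (mode == "exact") {
    pairs <- unique(rd)
    data.table::setnames(pairs, c("id", "chrom", "start_bp", "end_bp"))
  } else {
    r2 <- data.table::copy(rd)
    data.table::setnames(r2, c("start_bp", "end_bp"), c("r_start", "r_end"))
    reg2 <- data.table::copy(reg)
    # an animal carries the region iff one of its runs contains it
    pairs <- r2[reg2,
                on = .(chrom, r_start <= start_bp, r_end >= end_bp),
                .(id = x.id, chrom = i.chrom, start_bp = i.start_bp,
                  end_bp = i.end_bp),
                nomatch = NULL, allow.cartesian = TRUE]
    pairs <- unique(pairs)
  }

  key_reg <- paste(reg$chrom, reg$start_bp, reg$end_bp, sep = ":")
  key_pair <- paste(pairs$chrom, pairs$start_bp, pairs$end_bp, sep = ":")
  carriers <- matrix(FALSE, length(ids), nrow(reg),
                     dimnames = list(ids, key_reg))
  carriers[cbind(match(pairs$id, ids), match(key_pair, key_reg))] <- TRUE

  n_car <- colSums(carriers)
  keep <- n_car >= min_carriers
  regions <- data.frame(
    region_id = key_reg[keep],
    chrom = reg$chrom[keep], start_bp = reg$start_bp[keep],
    end_bp = reg$end_bp[keep], n_carriers = as.integer(n_car[keep]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(regions = regions, carriers = carriers[, keep, drop = FALSE])
}

# design matrix for the fixed effects; single-level factors are dropped
# (e.g. one farm in a population), remaining levels dummy-coded against the
# first sorted level
.covariate_design <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    return(matrix(1, nrow = NROW(covariates), ncol = 1,
                  dimnames = list(NULL, "(Intercept)")))
  }
  cv <- as.data.frame(covariates, stringsAsFactors = FALSE)
  for (nm in names(cv)) cv[[nm]] <- droplevels(factor(cv[[nm]]))
  cv <- cv[, vapply(cv, nlevels, integer(1)) > 1L, drop = FALSE]
  if (!ncol(cv)) {
    return(matrix(1, nrow = nrow(as.data.frame(covariates)), ncol = 1,
                  dimnames = list(NULL, "(Intercept)")))
  }
  stats::model.matrix(~ ., data = cv)
}

#' Fit one region-by-trait fixed-effects model
#'
#' Ordinary least squares for
#' `y = farm + birth_year + sex + region_presence + e`, with a two-sided
#' Wald t-test on the presence coefficient (`n - rank` residual df) — the
#' single-marker linear model of genome scan tools, re-fit here per region
#' predictor. Animals with a missing trait value are dropped pairwise by
#' the caller.
#'
#' @param y numeric trait values.
#' @param covariates data.frame of categorical covariates (may be `NULL`);
#'   covariates with a single level are dropped automatically.
#' @param x 0/1 (or logical) region-presence vector.
#' @return one-row data.frame: `beta`, `se`, `t`, `df`, `p`, `note`
#'   (`NA` or a skip/degenerate flag).
#' @export
fit_region_trait <- function(y, covariates, x) {
  x <- as.numeric(x)
  stopifnot(length(y) == length(x))
  res <- data.frame(beta = NA_real_, se = NA_real_, t = NA_real_,
                    df = NA_real_, p = NA_real_, note = NA_character_,
                    stringsAsFactors = FALSE)
  if (stats::var(x) == 0) {
    res$note <- "constant predictor"
    return(res)
  }
  if (stats::var(y) == 0) {
    res[, c("beta", "p")] <- c(0, 1)
    res$note <- "constant response"
    return(res)
  }
  X <- cbind(.covariate_design(if (is.null(covariates)) {
    data.frame(row.names = seq_along(y))
  } else covariates), region = x)
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  if (r < ncol(X) || is.na(fit$coefficients["region"])) {
    stop("rank-deficient design matrix (", ncol(X), " columns, rank ", r,
         "); check covariate coding")
  }
  df <- length(y) - r
  if (df <= 0) stop("no residual degrees of freedom")
  s2 <- sum(fit$residuals^2) / df
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  k <- which(colnames(X) == "region")
  se <- sqrt(s2 * XtX_inv[k, k])
  beta <- unname(fit$coefficients["region"])
  if (se == 0) {
    res[, c("beta", "se", "df")] <- c(beta, 0, df)
    res$p <- if (abs(beta) < 1e-12) 1 else 0
    res$note <- "zero residual variance"
    return(res)
  }
  tval <- beta / se
  data.frame(beta = beta, se = se, t = tval, df = df,
             p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
             note = NA_character_, stringsAsFactors = FALSE)
}

#' FDR-derived genome-scan significance threshold
#'
#' `p_threshold = fdr * N / M`, where `N` is the number of tested regions
#' with `p < p0` and `M` the total number of effective regions in the scan.
#'
#' @param pvalues p-values of one trait's scan (non-empty).
#' @param fdr target false discovery rate (default 0.01).
#' @param p0 nominal cut used to count `N` (default 0.01).
#' @return list: `p_threshold`, `n_below`, `m_total`, `fdr`, `p0`.
#' @export
fdr_scan_threshold <- function(pvalues, fdr = 0.01, p0 = 0.01) {
  pvalues <- pvalues[!is.na(pvalues)]
  stopifnot(length(pvalues) > 0)
  n_below <- sum(pvalues < p0)
  # min() keeps the p_threshold <= fdr invariant exact when N = M, where
  # fdr * N / M can exceed fdr by one ulp
  list(p_threshold = min(fdr, fdr * n_below / length(pvalues)),
       n_below = n_below, m_total = length(pvalues), fdr = fdr, p0 = p0)
}

#' Region-by-trait association scan
#'
#' Fits [fit_region_trait()] for every effective region against every
#' requested trait, with per-trait casewise deletion of missing phenotypes
#' and a per-trait FDR-derived threshold from [fdr_scan_threshold()].
#'
#' @param predictors output of [build_region_predictors()].
#' @param phenotypes data.frame with an `id` column, the covariate columns
#'   and the trait columns; one row per animal.
#' @param traits character vector of trait column names.
#' @param covariate_cols character vector of covariate column names
#'   (default `c("farm", "birth_year", "sex")`).
#' @param fdr,p0 threshold parameters, see [fdr_scan_threshold()].
#' @return list: `associations` (region x trait rows with `beta`, `se`,
#'   `t`, `df`, `p`, `significant`, `note`) and `thresholds` (per-trait
#'   `p_threshold`, `n_below`, `m_total`).
#' @export
scan_regions <- function(predictors, phenotypes, traits,
                         covariate_cols = c("farm", "birth_year", "sex"),
                         fdr = 0.01, p0 = 0.01) {
  regions <- predictors$regions
  carriers <- predictors$carriers
  stopifnot("id" %in% names(phenotypes),
            all(traits %in% names(phenotypes)))
  covariate_cols <- intersect(covariate_cols, names(phenotypes))
  ph <- phenotypes[match(rownames(carriers), phenotypes$id), , drop = FALSE]
  if (anyNA(ph$id)) stop("phenotype table lacks some genotyped animals")

  assoc <- list()
  thr <- list()
  for (tr in traits) {
    y_all <- ph[[tr]]
    use <- !is.na(y_all)
    y <- y_all[use]
    cv <- if (length(covariate_cols)) {
      ph[use, covariate_cols, drop = FALSE]
    } else NULL
    rows <- vector("list", nrow(regions))
    for (j in seq_len(nrow(regions))) {
      ft <- fit_region_trait(y, cv, carriers[use, j])
      rows[[j]] <- cbind(regions[j, , drop = FALSE], trait = tr, ft)
    }
    res <- do.call(rbind, rows)
    th <- fdr_scan_threshold(res$p, fdr = fdr, p0 = p0)
    res$significant <- !is.na(res$p) & res$p < th$p_threshold
    assoc[[tr]] <- res
    thr[[tr]] <- data.frame(trait = tr, p_threshold = th$p_threshold,
                            n_below = th$n_below, m_total = th$m_total,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, assoc)
  rownames(out) <- NULL
  thresholds <- do.call(rbind, thr)
  rownames(thresholds) <- NULL
  list(associations = out, thresholds = thresholds)
}

#' Pleiotropy summary across traits
#'
#' Tallies, per region, the traits for which it is significant; regions
#' significant for two or more traits are flagged pleiotropic.
#'
#' @param associations the `associations` data.frame from [scan_regions()]
#'   (at least two traits scanned).
#' @return data.frame: `region_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_traits`, `traits`, `pleiotropic`; empty when nothing is
#'   significant.
#' @export
pleiotropy_summary <- function(associations) {
  stopifnot(length(unique(associations$trait)) >= 2)
  sig <- associations[associations$significant %in% TRUE, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(region_id = character(0), chrom = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_traits = integer(0), traits = character(0),
                      pleiotropic = logical(0), stringsAsFactors = FALSE))
  }
  sp <- split(sig, sig$region_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(region_id = d$region_id[1], chrom = d$chrom[1],
               start_bp = d$start_bp[1], end_bp = d$end_bp[1],
               n_traits = nrow(d),
               traits = paste(sort(d$trait), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out$pleiotropic <- out$n_traits >= 2L
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a phenotype/covariate table
#'
#' Headered TSV/CSV with one row per animal: an id column, categorical
#' covariates and quantitative traits. Column names can be remapped.
#'
#' @param path input file (tab- or comma-separated, sniffed from the
#'   extension: `.csv` means comma).
#' @param id_col name of the animal id column (renamed to `id`).
#' @return data.frame with a character `id` column first.
#' @export
read_phenotypes <- function(path, id_col = "id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ph <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% names(ph)) stop("no column '", id_col, "' in ", path)
  names(ph)[names(ph) == id_col] <- "id"
  ph$id <- as.character(ph$id)
  if (anyDuplicated(ph$id)) stop("duplicate animal id in phenotype table")
  ph[, c("id", setdiff(names(ph), "id")), drop = FALSE]
}
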