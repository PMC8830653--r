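#' Construct a genotype matrix object
#'
#' Bundles diploid SNP-array genotype states with their map. Genotype states
#' are coded as the count of the alternate allele: `0` = homozygous reference,
#' `1` = heterozygous, `2` = homozygous alternate, `NA` = missing call. The
#' map gives the genomic coordinate system used by every downstream stage.
#'
#' @param geno integer matrix, individuals in rows, SNPs in columns, values
#'   in `c(0L, 1L, 2L, NA)`.
#' @param map data.frame with columns `chrom` (integer autosome label),
#'   `snp_id` (unique character), `bp` (1-based base-pair position, strictly
#'   increasing within each chromosome). One row per column of `geno`.
#' @param ids character vector of unique animal identifiers, one per row of
#'   `geno`.
#' @param alleles optional data.frame with columns `ref` and `alt`, one row
#'   per SNP; defaults to generic `"A"`/`"B"` labels.
#' @param fam optional data.frame of PED family fields (`famid`, `id`, `pat`,
#'   `mat`, `sex`, `phen`) preserved for round-tripping.
#'
#' @return An object of class `rohet_geno`: a list with elements `ids`,
#'   `map`, `geno`, `alleles` and `fam`.
#' @export
genotype_matrix <- function(geno, map, ids, alleles = NULL, fam = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ids <- as.character(ids)
  map <- as.data.frame(map, stringsAsFactors = FALSE)

  if (!all(c("chrom", "snp_id", "bp") %in% names(map))) {
    stop("map must have columns chrom, snp_id, bp")
  }
  if (nrow(map) != ncol(geno)) {
    stop("map has ", nrow(map), " SNPs but genotype matrix has ",
         ncol(geno), " columns")
  }
  if (length(ids) != nrow(geno)) {
    stop("ids length does not match genotype matrix rows")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate animal id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in map")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  ord <- order(map$chrom, map$bp)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
    if (!is.null(alleles)) alleles <- alleles[ord, , drop = FALSE]
  }
  for (ch in unique(map$chrom[!is.na(map$chrom)])) {
    p <- map$bp[!is.na(map$chrom) & map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  if (is.null(alleles)) {
    alleles <- data.frame(ref = rep("A", nrow(map)), alt = rep("B", nrow(map)),
                          stringsAsFactors = FALSE)
  }
  rownames(map) <- NULL
  rownames(alleles) <- NULL
  dimnames(geno) <- list(ids, map$snp_id)
  structure(
    list(ids = ids, map = map, geno = geno, alleles = alleles, fam = fam),
    class = "rohet_geno"
  )
}

#' @export
print.rohet_geno <- function(x, ...) {
  cat("rohet genotype matrix:", length(x$ids), "individuals x",
      nrow(x$map), "SNPs on", length(unique(x$map$chrom)),
      "chromosome(s)\n")
  het <- mean(x$geno == 1L, na.rm = TRUE)
  mis <- mean(is.na(x$geno))
  cat(sprintf("  mean heterozygosity %.3f, missing rate %.4f\n", het, mis))
  invisible(x)
}

#' Number of individuals / SNPs in a genotype object
#' @param g a `rohet_geno` object.
#' @return integer count.
#' @export
n_individuals <- function(g) length(g$ids)

#' @rdname n_individuals
#' @export
n_snps <- function(g) nrow(g$map)

#' Read PLINK-style PED/MAP text files
#'
#' Parses the whitespace-delimited text dialect: MAP rows are
#' `(chrom, snp_id, cM, bp)`; PED rows are `(famid, id, pat, mat, sex, phen)`
#' followed by two allele columns per SNP. The allele code `"0"` means a
#' missing call. A SNP is heterozygous iff its two alleles differ and neither
#' is missing. SNPs are re-sorted by `(chrom, bp)`.
#'
#' Sites with more than two distinct non-missing alleles are rejected: the
#' model downstream is strictly biallelic.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return A [genotype_matrix()] object.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character",
                               col.names = c("chrom", "snp_id", "cm", "bp"))
  bp <- suppressWarnings(as.numeric(map_raw$bp))
  if (anyNA(bp)) {
    stop("non-numeric bp position in MAP file: ",
         paste(utils::head(map_raw$bp[is.na(bp)], 3), collapse = ", "))
  }
  chrom <- suppressWarnings(as.integer(map_raw$chrom))
  # non-numeric chromosome labels (X, Y, MT, unplaced contigs) are kept here
  # as NA and dropped later by the autosome QC rule
  map <- data.frame(chrom = chrom, snp_id = map_raw$snp_id,
                    bp = as.integer(bp), stringsAsFactors = FALSE)
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PED file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  nt <- lengths(toks)
  if (any(nt != want)) {
    stop("PED line ", which(nt != want)[1], " has ", nt[nt != want][1],
         " fields; expected ", want, " for ", m, " SNPs")
  }
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  fam <- data.frame(famid = tok[, 1], id = tok[, 2], pat = tok[, 3],
                    mat = tok[, 4], sex = tok[, 5], phen = tok[, 6],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(fam$id)) {
    stop("duplicate animal id in PED: ",
         paste(unique(fam$id[duplicated(fam$id)]), collapse = ", "))
  }
  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]

  n <- nrow(tok)
  geno <- matrix(NA_integer_, n, m)
  ref <- character(m)
  alt <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]
    x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(obs) > 2L) {
      stop("SNP ", map$snp_id[j], " has ", length(obs),
           " alleles; only biallelic sites are supported")
    }
    ref[j] <- if (length(obs)) obs[1] else "A"
    alt[j] <- if (length(obs) == 2L) obs[2] else "B"
    g <- (x1 != ref[j]) + (x2 != ref[j])
    g[miss] <- NA_integer_
    geno[, j] <- as.integer(g)
  }
  genotype_matrix(geno, map, fam$id,
                  alleles = data.frame(ref = ref, alt = alt,
                                       stringsAsFactors = FALSE),
                  fam = fam)
}

#' Write a genotype object as PED/MAP text files
#'
#' Inverse of [read_ped_map()]: genotype states round-trip exactly.
#' Heterozygotes are written as `ref alt`, missing calls as `0 0`.
#'
#' @param g a `rohet_geno` object.
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "rohet_geno"))
  map_out <- data.frame(g$map$chrom, g$map$snp_id, 0, g$map$bp)
  utils::write.table(map_out, map_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)

  n <- length(g$ids)
  m <- nrow(g$map)
  fam <- g$fam
  if (is.null(fam)) {
    fam <- data.frame(famid = g$ids, id = g$ids, pat = "0", mat = "0",
                      sex = "0", phen = "-9", stringsAsFactors = FALSE)
  }
  ref <- g$alleles$ref
  alt <- g$alleles$alt
  pair <- matrix("", n, 2L * m)
  for (j in seq_len(m)) {
    gj <- g$geno[, j]
    x1 <- ifelse(is.na(gj), "0", ifelse(gj == 2L, alt[j], ref[j]))
    x2 <- ifelse(is.na(gj), "0", ifelse(gj == 0L, ref[j], alt[j]))
    pair[, 2L * j - 1L] <- x1
    pair[, 2L * j] <- x2
  }
  body <- cbind(fam$famid, fam$id, fam$pat, fam$mat, fam$sex, fam$phen, pair)
  writeLines(apply(body, 1L, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Subset a genotype object to a set of SNP columns
#' @param g a `rohet_geno` object.
#' @param keep logical or integer index over SNPs.
#' @return A `rohet_geno` with the selected SNPs.
#' @keywords internal
subset_snps <- function(g, keep) {
  genotype_matrix(g$geno[, keep, drop = FALSE],
                  g$map[keep, , drop = FALSE],
                  g$ids,
                  alleles = g$alleles[keep, , drop = FALSE],
                  fam = g$fam)
}
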