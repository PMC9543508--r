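#' Per-SNP pooled read-count table
#'
#' The central observational object: biallelic reference/alternate read
#' counts at each SNP for one or more pooled populations, with 1-based
#' genomic coordinates. Positions must be strictly increasing within each
#' chromosome.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt integer matrices (SNPs x populations) of reference and
#'   alternate read counts.
#' @param pop_ids ordered population labels; defaults to the column names
#'   of `ref` or `pop1..popP`.
#' @param pool_size number of diploid individuals bulked per pool
#'   (recycled to one value per population). Default 100.
#' @return An object of class `snp_table`: a list with elements `chrom`,
#'   `pos`, `ref`, `alt`, `pop_ids`, `pool_size`.
#' @examples
#' tab <- snp_table(chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'                  ref = matrix(c(12L, 30L), 2, 1),
#'                  alt = matrix(c(8L, 20L), 2, 1), pop_ids = "A1")
#' allele_freq(tab)
#' @export
snp_table <- function(chrom, pos, ref, alt, pop_ids = NULL, pool_size = 100) {
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  storage.mode(ref) <- "integer"
  storage.mode(alt) <- "integer"
  n <- length(chrom)
  if (length(pos) != n || nrow(ref) != n || nrow(alt) != n)
    stop("chrom, pos, ref and alt must agree in number of SNPs")
  if (ncol(ref) != ncol(alt))
    stop("ref and alt must have the same number of populations")
  if (is.null(pop_ids)) pop_ids <- colnames(ref)
  if (is.null(pop_ids)) pop_ids <- paste0("pop", seq_len(ncol(ref)))
  if (length(pop_ids) != ncol(ref))
    stop("pop_ids length must equal the number of populations")
  if (anyNA(ref) || anyNA(alt) || any(ref < 0L) || any(alt < 0L))
    stop("read counts must be non-negative and non-missing")
  pos <- as.integer(pos)
  # strictly increasing within chromosome
  bad <- which(chrom[-1] == chrom[-n] & diff(pos) <= 0L)
  if (n > 1L && length(bad))
    stop(sprintf("positions not strictly increasing within chromosome at record %d (%s:%d)",
                 bad[1] + 1L, chrom[bad[1] + 1L], pos[bad[1] + 1L]))
  colnames(ref) <- colnames(alt) <- pop_ids
  structure(list(chrom = as.character(chrom), pos = pos, ref = ref,
                 alt = alt, pop_ids = as.character(pop_ids),
                 pool_size = rep_len(pool_size, length(pop_ids))),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs, %d populations (%s), %d chromosome(s)\n",
              n_snps(x), length(x$pop_ids), paste(x$pop_ids, collapse = ", "),
              length(unique(x$chrom))))
  invisible(x)
}

#' Number of SNPs in a `snp_table`
#' @param x a `snp_table`.
#' @export
n_snps <- function(x) length(x$pos)

#' Subset a `snp_table` by SNP index
#' @param x a `snp_table`.
#' @param i logical or integer index over SNPs.
#' @param ... unused.
#' @export
`[.snp_table` <- function(x, i, ...) {
  snp_table(x$chrom[i], x$pos[i], x$ref[i, , drop = FALSE],
            x$alt[i, , drop = FALSE], x$pop_ids, x$pool_size)
}

#' Read depth per SNP and population
#' @param x a `snp_table`.
#' @return integer matrix `ref + alt`.
#' @export
depth <- function(x) x$ref + x$alt

#' Alternate-allele frequency per SNP and population
#'
#' `alt / (ref + alt)`; `NaN` where depth is zero.
#' @param x a `snp_table`.
#' @export
allele_freq <- function(x) {
  m <- depth(x)
  f <- x$alt / m
  f[m == 0L] <- NaN
  f
}
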