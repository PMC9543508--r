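#' Windowed nucleotide diversity from pooled counts
#'
#' Average pairwise mismatches per site (pi) in fixed windows. Each SNP
#' contributes the read-based heterozygosity `(m/(m-1)) * 2*p*(1-p)`
#' (the small-depth unbiased correction for sampling reads with
#' replacement); the per-window sum is divided by the window width, so
#' monomorphic and unsequenced sites contribute zero. Windows are
#' half-open `[start, start + window_bp)` starting at position 1.
#'
#' @param x a [snp_table].
#' @param pop population label or index.
#' @param window_bp window width in base pairs (default 50000).
#' @return data.frame of class `pi_track` with columns `chrom`,
#'   `window_start`, `window_end` (1-based inclusive), `pi`, `n_snps`.
#' @export
windowed_pi <- function(x, pop, window_bp = 50000) {
  j <- if (is.character(pop)) match(pop, x$pop_ids) else as.integer(pop)
  if (is.na(j) || j < 1L || j > length(x$pop_ids))
    stop("unknown population: ", pop)
  m <- depth(x)[, j]
  skip <- m < 2L
  if (any(skip)) message(sum(skip), " site(s) with depth < 2 skipped")
  p <- x$alt[, j] / m
  het <- ifelse(skip, 0, (m / (m - 1)) * 2 * p * (1 - p))
  win <- (x$pos - 1L) %/% as.integer(window_bp)
  out <- do.call(rbind, lapply(unique(x$chrom), function(ch) {
    i <- x$chrom == ch
    nw <- max(win[i]) + 1L
    s <- vapply(seq_len(nw) - 1L, function(w) sum(het[i & win == w]), 0)
    k <- vapply(seq_len(nw) - 1L, function(w) sum(i & win == w & !skip), 0L)
    data.frame(chrom = ch,
               window_start = (seq_len(nw) - 1L) * window_bp + 1L,
               window_end = seq_len(nw) * window_bp,
               pi = s / window_bp, n_snps = k)
  }))
  rownames(out) <- NULL
  class(out) <- c("pi_track", "data.frame")
  out
}

#' Export a pi track as BED
#'
#' Standard BED convention: 0-based half-open intervals.
#' @param track a `pi_track` from [windowed_pi()].
#' @param path output path.
#' @export
write_pi_bed <- function(track, path) {
  bed <- data.frame(track$chrom, track$window_start - 1L, track$window_end,
                    sprintf("%.8g", track$pi))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Genome-wide pairwise FST for two pools
#'
#' Multi-locus ratio-of-averages estimator in the Weir-Cockerham identity
#' framework, with both sampling stages of pool-seq corrected: reads are
#' drawn with replacement from the pool (factor `m/(m-1)`) and the pool's
#' `2n` chromosomes are a finite sample from the population (factor
#' `2n/(2n-1)`). Per locus, the unbiased within-pool diversity is
#' `pi_w = mean of 2*p*q * m/(m-1) * 2n/(2n-1)` and the between-pool
#' diversity is `pi_b = pA*qB + pB*qA` (unbiased because pools are
#' independent). FST = sum(pi_b - pi_w) / sum(pi_b).
#'
#' @param x a [snp_table].
#' @param popA,popB population labels or indices.
#' @return a single genome-wide FST value (can be slightly negative under
#'   no differentiation).
#' @export
pairwise_fst <- function(x, popA, popB) {
  ja <- if (is.character(popA)) match(popA, x$pop_ids) else as.integer(popA)
  jb <- if (is.character(popB)) match(popB, x$pop_ids) else as.integer(popB)
  if (anyNA(c(ja, jb))) stop("unknown population label")
  m <- depth(x)
  use <- m[, ja] >= 2L & m[, jb] >= 2L
  if (sum(use) < 2L) stop("fewer than 2 informative SNPs")
  comp <- fst_components(x$alt[use, ja], m[use, ja], x$pool_size[ja],
                         x$alt[use, jb], m[use, jb], x$pool_size[jb])
  sum(comp$pib - comp$piw) / sum(comp$pib)
}

# per-locus within/between diversity components (internal, vectorized)
fst_components <- function(altA, mA, nA, altB, mB, nB) {
  pA <- altA / mA; pB <- altB / mB
  corrA <- (mA / (mA - 1)) * (2 * nA / (2 * nA - 1))
  corrB <- (mB / (mB - 1)) * (2 * nB / (2 * nB - 1))
  piw <- 0.5 * (2 * pA * (1 - pA) * corrA + 2 * pB * (1 - pB) * corrB)
  pib <- pA * (1 - pB) + pB * (1 - pA)
  list(piw = piw, pib = pib)
}
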