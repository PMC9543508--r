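# shared in-code fixtures; everything is generated, nothing is stored

# a snp_table with given per-population alt frequencies and constant depth
freq_table <- function(freqs, m = 100L, pop_ids = NULL, pool_size = 100,
                       chrom = NULL, pos = NULL) {
  freqs <- as.matrix(freqs)
  S <- nrow(freqs)
  alt <- round(freqs * m)
  storage.mode(alt) <- "integer"
  if (is.null(chrom)) chrom <- rep("chr1", S)
  if (is.null(pos)) pos <- seq_len(S) * 100L
  snp_table(chrom, pos, matrix(m, S, ncol(freqs)) - alt, alt,
            pop_ids, pool_size)
}

# a random valid count table for round-trip / filter tests
random_table <- function(S = 200, P = 4, mean_depth = 80, seed = 1,
                         n_chrom = 2) {
  set.seed(seed)
  m <- matrix(rpois(S * P, mean_depth), S, P)
  p <- matrix(runif(S * P), S, P)
  alt <- matrix(rbinom(S * P, as.vector(m), as.vector(p)), S, P)
  snp_table(rep(paste0("chr", seq_len(n_chrom)), each = ceiling(S / n_chrom))[1:S],
            rep(seq_len(ceiling(S / n_chrom)) * 1000L, n_chrom)[1:S],
            m - alt, alt, paste0("P", seq_len(P)))
}

# small simulation config for fast tests
mini_config <- function(N, mating, n_chrom = 2, snps_per_chrom = 150, ...) {
  sim_config(N = N, mating = mating, n_chrom = n_chrom,
             snps_per_chrom = snps_per_chrom, ...)
}

# random snp_observation on the angular scale
random_obs <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snp_observation(x = runif(4, 0, pi),
                  v = runif(4, 0.01, 0.5),
                  depth_var = 1 / sample(40:120, 4),
                  pool_var = 1 / 200)
}
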