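#' Founder allele frequencies from the three-family crossing design
#'
#' Emulates an ancestor built by crossing three pairs of grandparents to
#' make three F1s, selfing each F1 into an F2 panel, and intercrossing
#' the panels: every SNP is carried by `4 * n_f1` grandparental
#' haplotypes (12 by default), each an independent Bernoulli draw from a
#' per-SNP base frequency, so ancestor frequencies lie on the lattice
#' `{0, 1/12, ..., 1}`. Monomorphic draws are discarded and redrawn so
#' exactly `n_snps` polymorphic SNPs are returned.
#'
#' @param n_snps number of polymorphic SNPs required.
#' @param n_f1 number of F1 families (default 3, i.e. 12 haplotypes).
#' @param base_freq per-SNP base allele frequency: a single value, a
#'   vector, or `NULL` (default) to draw each SNP's base frequency
#'   uniformly on `[0.1, 0.9]`.
#' @return numeric vector of `n_snps` ancestor frequencies in
#'   `(0, 1)` on the haplotype lattice.
#' @export
founder_freqs_from_cross <- function(n_snps, n_f1 = 3, base_freq = NULL) {
  if (n_f1 < 1) stop("n_f1 must be at least 1")
  H <- 4L * as.integer(n_f1)
  out <- numeric(0)
  while (length(out) < n_snps) {
    need <- n_snps - length(out)
    q <- if (is.null(base_freq)) stats::runif(need, 0.1, 0.9)
         else rep_len(base_freq, need)
    cnt <- stats::rbinom(need, H, q)
    poly <- cnt > 0L & cnt < H
    out <- c(out, cnt[poly] / H)
  }
  out[seq_len(n_snps)]
}

#' Configuration for a synthetic four-population experiment
#'
#' Default design: one shared outbred ancestor; populations A1 and A2
#' evolve by full selfing, B1 and B2 by outcrossing, each for nine
#' generations, followed by pooled sequencing of 100 plants at Poisson
#' read depth.
#'
#' @param pops named list of per-population settings; each entry is a
#'   list with `mating`, `N` and optionally `selection` (a list of
#'   [selected_locus()]).
#' @param n_chrom,snps_per_chrom genome dimensions (defaults 14 x 2000).
#' @param t generations (default 9).
#' @param pool_n pooled individuals (default 100).
#' @param mean_depth mean Poisson depth (default 75).
#' @param base_freq base frequency for [founder_freqs_from_cross()].
#' @export
experiment_config <- function(pops = list(
                                A1 = list(mating = "selfing", N = 43),
                                A2 = list(mating = "selfing", N = 13),
                                B1 = list(mating = "outcrossing", N = 366),
                                B2 = list(mating = "outcrossing", N = 219)),
                              n_chrom = 14, snps_per_chrom = 2000, t = 9,
                              pool_n = 100, mean_depth = 75,
                              base_freq = NULL) {
  if (is.null(names(pops)) || any(!nzchar(names(pops))))
    stop("pops must be a named list")
  structure(list(pops = pops, n_chrom = as.integer(n_chrom),
                 snps_per_chrom = as.integer(snps_per_chrom),
                 t = as.integer(t), pool_n = as.integer(pool_n),
                 mean_depth = mean_depth, base_freq = base_freq),
            class = "experiment_config")
}

#' Generate a complete synthetic experiment
#'
#' Draws one shared ancestor from the crossing-design founder model,
#' evolves each configured population independently with the forward
#' simulator, passes each through the pooled-sequencing layer, and
#' returns the read-count table together with a truth record (seeds,
#' selection, realized population-level null variances) sufficient to
#' regenerate the bundle bit-identically.
#'
#' @param config an [experiment_config()].
#' @param seed integer master seed; per-population sub-seeds are derived
#'   from it and recorded.
#' @return list of class `experiment_bundle` with `counts` (a
#'   [snp_table]), `ancestor_freq`, `truth`, `config`.
#' @export
generate_experiment <- function(config = experiment_config(), seed = 1) {
  seed <- as.integer(seed)
  set.seed(seed)
  L <- config$n_chrom * config$snps_per_chrom
  anc <- founder_freqs_from_cross(L, base_freq = config$base_freq)
  # favored alleles are rare in the shared ancestor: every population
  # founds the selected site at p0, not at a lattice frequency
  for (ps in config$pops) {
    for (sl in if (is.null(ps$selection)) list() else ps$selection) {
      idx <- if (is.null(sl$snp_index)) config$snps_per_chrom %/% 2L + 1L
             else as.integer(sl$snp_index)
      anc[(sl$chrom - 1L) * config$snps_per_chrom + idx] <- sl$p0
    }
  }
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, length(config$pops))
  pop_ids <- names(config$pops)
  results <- vector("list", length(config$pops))
  for (i in seq_along(config$pops)) {
    ps <- config$pops[[i]]
    cfg <- sim_config(N = ps$N, mating = ps$mating, t = config$t,
                      n_chrom = config$n_chrom,
                      snps_per_chrom = config$snps_per_chrom,
                      selection = if (is.null(ps$selection)) list()
                                  else ps$selection,
                      founder_freqs = anc, pool_n = config$pool_n,
                      mean_depth = config$mean_depth)
    set.seed(sub_seeds[i])
    results[[i]] <- run_replicate(cfg)
  }
  m <- vapply(results, `[[`, integer(L), "pool_depth")
  alt <- vapply(results, `[[`, integer(L), "pool_alt")
  counts <- snp_table(chrom = rep(paste0("chr", seq_len(config$n_chrom)),
                                  each = config$snps_per_chrom),
                      pos = rep(seq_len(config$snps_per_chrom) * 1000L,
                                config$n_chrom),
                      ref = m - alt, alt = alt, pop_ids = pop_ids,
                      pool_size = config$pool_n)
  truth <- list(seed = seed, sub_seeds = sub_seeds,
                mating = vapply(config$pops, `[[`, "", "mating"),
                N = vapply(config$pops, function(p) as.integer(p$N),
                           1L),
                selection = lapply(config$pops, `[[`, "selection"),
                realized_v = vapply(results, `[[`, 0, "null_variance"),
                attempts = vapply(results, `[[`, 1L, "attempts"))
  names(truth$realized_v) <- pop_ids
  structure(list(counts = counts, ancestor_freq = anc, truth = truth,
                 config = config, replicates = results),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("experiment_bundle: %d SNPs x %d populations (seed %d)\n",
              n_snps(x$counts), length(x$truth$N), x$truth$seed))
  cat("realized null variances:\n")
  print(round(x$truth$realized_v, 4))
  invisible(x)
}

#' Census sizes and per-capita seed mass of the selection experiment
#'
#' The adult population sizes (N) and per-adult seed mass (mg) for
#' generations 1-9 of the four experimental populations (A1, A2 without
#' pollinators; B1, B2 with bees), with arithmetic and harmonic mean
#' summaries.
#'
#' @return list with `N` and `seed_mass` (9 x 4 matrices), `mean_N`,
#'   `harmonic_mean_N`, `mean_seed_mass`.
#' @export
census_fixture <- function() {
  pops <- c("A1", "A2", "B1", "B2")
  N <- matrix(c(753, 643, 813, 652,
                424, 458, 652, 488,
                770, 835, 1353, 816,
                697, 762, 940, 719,
                312, 420, 579, 758,
                1188, 1404, 2268, 2058,
                953, 788, 1034, 1002,
                1321, 1388, 1399, 1304,
                950, 998, 1043, 1023),
              nrow = 9, byrow = TRUE, dimnames = list(1:9, pops))
  sm <- matrix(c(1.18, 1.70, 6.61, 9.24,
                 0.38, 0.54, 11.20, 10.00,
                 0.54, 0.41, 5.50, 6.45,
                 1.90, 1.38, 9.54, 15.76,
                 8.31, 4.04, 9.14, 13.89,
                 0.55, 0.11, 3.19, 2.29,
                 0.67, 0.61, 4.54, 5.45,
                 1.37, 0.82, 12.20, 12.48,
                 2.41, 1.58, 11.45, 12.42),
               nrow = 9, byrow = TRUE, dimnames = list(1:9, pops))
  list(N = N, seed_mass = sm,
       mean_N = colMeans(N),
       harmonic_mean_N = apply(N, 2, function(x) length(x) / sum(1 / x)),
       mean_seed_mass = colMeans(sm))
}
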