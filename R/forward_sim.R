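#' Configuration for a forward simulation
#'
#' Individual-based simulation of a constant-size diploid population over
#' `t` generations with `n_chrom` chromosomes of `snps_per_chrom` linked
#' biallelic SNPs. Meiosis places a single obligate crossover at a random
#' internal inter-SNP interval of each chromosome. Mating is either full
#' selfing or random outcrossing; selection, if any, acts multiplicatively
#' across one or two favored loci.
#'
#' @param N census size (constant across generations).
#' @param mating `"selfing"` or `"outcrossing"`.
#' @param t generations of evolution (default 9).
#' @param n_chrom number of chromosomes (default 14).
#' @param snps_per_chrom SNPs per chromosome (default 2000).
#' @param selection list of [selected_locus()] entries (0, 1 or 2); two
#'   loci must sit on distinct chromosomes.
#' @param founder_freqs per-SNP ancestor frequencies (length
#'   `n_chrom * snps_per_chrom`), or `NULL` to draw them from
#'   [founder_freqs_from_cross()] at run time.
#' @param pool_n individuals grown from the final generation and bulked
#'   for sequencing (default 100; 0 disables the pool stage).
#' @param mean_depth mean Poisson read depth per SNP in the pool
#'   (default 75).
#' @return a `sim_config` list.
#' @export
sim_config <- function(N, mating = c("selfing", "outcrossing"), t = 9,
                       n_chrom = 14, snps_per_chrom = 2000,
                       selection = list(), founder_freqs = NULL,
                       pool_n = 100, mean_depth = 75) {
  mating <- match.arg(mating)
  if (N < 2) stop("N must be at least 2")
  if (t < 1) stop("t must be at least 1")
  if (length(selection) > 2) stop("at most two selected loci supported")
  if (length(selection) == 2 &&
      selection[[1]]$chrom == selection[[2]]$chrom)
    stop("two selected loci must be on distinct chromosomes")
  L <- n_chrom * snps_per_chrom
  if (!is.null(founder_freqs)) {
    if (length(founder_freqs) != L)
      stop("founder_freqs must have length n_chrom * snps_per_chrom")
    if (any(founder_freqs < 0 | founder_freqs > 1))
      stop("founder frequencies must lie in [0, 1]")
  }
  structure(list(N = as.integer(N), t = as.integer(t),
                 n_chrom = as.integer(n_chrom),
                 snps_per_chrom = as.integer(snps_per_chrom),
                 mating = mating, selection = selection,
                 founder_freqs = founder_freqs,
                 pool_n = as.integer(pool_n), mean_depth = mean_depth),
            class = "sim_config")
}

#' A selected locus for the forward simulation
#'
#' Genotype fitnesses are `1`, `1 + h*s`, `1 + s` for carriers of 0, 1, 2
#' favored alleles; fitness multiplies across loci. The favored allele
#' starts at frequency `p0` (redrawn until at least one copy exists).
#'
#' @param chrom chromosome carrying the locus.
#' @param snp_index SNP index within the chromosome; `NULL` places it at
#'   the middle of the chromosome.
#' @param s selection coefficient (> 0; default 0.8).
#' @param p0 initial favored-allele frequency (default 0.02).
#' @param h dominance of the favored allele (default 0.5).
#' @export
selected_locus <- function(chrom, snp_index = NULL, s = 0.8, p0 = 0.02,
                           h = 0.5) {
  if (s <= 0) stop("s must be positive")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  list(chrom = as.integer(chrom), snp_index = snp_index, s = s, p0 = p0,
       h = h)
}

# genome-wide 0-based indices of the selected loci
sel_indices <- function(config) {
  vapply(config$selection, function(sl) {
    idx <- if (is.null(sl$snp_index)) config$snps_per_chrom %/% 2L + 1L
           else as.integer(sl$snp_index)
    (sl$chrom - 1L) * config$snps_per_chrom + idx - 1L
  }, integer(1))
}

resolve_founders <- function(config) {
  if (!is.null(config$founder_freqs)) return(config$founder_freqs)
  founder_freqs_from_cross(config$n_chrom * config$snps_per_chrom)
}

#' Draw founder genotypes at linkage equilibrium
#'
#' Each of the `2N` allele copies at each SNP is an independent
#' Bernoulli draw from the ancestor frequency; selected loci are seeded
#' at `p0` (redrawn until the favored allele is present).
#'
#' @param config a [sim_config()].
#' @return a `population_state`: list with `haplos` (2N x L 0/1 integer
#'   matrix), `chrom_len`, `generation = 0`.
#' @export
draw_founders <- function(config) {
  p <- resolve_founders(config)
  L <- length(p)
  nhap <- 2L * config$N
  haplos <- matrix(stats::rbinom(nhap * L, 1L, rep(p, each = nhap)),
                   nrow = nhap, ncol = L)
  for (k in seq_along(config$selection)) {
    l <- sel_indices(config)[k] + 1L
    repeat {
      col <- stats::rbinom(nhap, 1L, config$selection[[k]]$p0)
      if (sum(col) > 0L) break
    }
    haplos[, l] <- col
  }
  structure(list(haplos = haplos,
                 chrom_len = rep(config$snps_per_chrom, config$n_chrom),
                 generation = 0L),
            class = "population_state")
}

#' Form one gamete from a diploid parent
#'
#' Per chromosome: a random starting haplotype and a single crossover at
#' a uniform internal inter-SNP interval (after SNP `k`,
#' `k in 1..Lc-1`). With one obligate crossover, the two chromosome ends
#' always derive from different parental haplotypes.
#'
#' @param ind 2 x L matrix: the parent's two haplotypes.
#' @param chrom_len integer vector of SNPs per chromosome (sums to L).
#' @return length-L 0/1 vector.
#' @export
make_gamete <- function(ind, chrom_len) {
  out <- integer(ncol(ind))
  off <- 0L
  for (Lc in chrom_len) {
    s <- if (stats::runif(1) < 0.5) 1L else 2L
    if (Lc == 1L) {
      out[off + 1L] <- ind[s, off + 1L]
    } else {
      k <- 1L + as.integer(stats::runif(1) * (Lc - 1L))
      k <- min(k, Lc - 1L)
      out[off + seq_len(k)] <- ind[s, off + seq_len(k)]
      out[off + (k + 1L):Lc] <- ind[3L - s, off + (k + 1L):Lc]
    }
    off <- off + Lc
  }
  out
}

#' Multiplicative fitness of individuals at the selected loci
#'
#' @param dosage matrix (individuals x loci) of favored-allele counts
#'   (0, 1, 2).
#' @param selection list of [selected_locus()] entries.
#' @return fitness vector (all 1 when `selection` is empty).
#' @export
ind_fitness <- function(dosage, selection) {
  w <- rep(1, nrow(dosage))
  for (k in seq_along(selection)) {
    s <- selection[[k]]$s
    h <- selection[[k]]$h
    w <- w * c(1, 1 + h * s, 1 + s)[dosage[, k] + 1L]
  }
  w
}

#' Advance a population by one generation (reference R engine)
#'
#' Seed parents are drawn proportional to relative fitness (uniformly
#' when neutral); the pollen parent equals the seed parent under selfing
#' or is drawn independently under outcrossing. Each offspring receives
#' one gamete from each parent.
#'
#' @param pop a `population_state`.
#' @param config the [sim_config()].
#' @return the next `population_state`.
#' @export
next_generation <- function(pop, config) {
  N <- config$N
  haplos <- pop$haplos
  if (length(config$selection)) {
    idx <- sel_indices(config) + 1L
    dosage <- haplos[seq(1, 2 * N, 2), idx, drop = FALSE] +
      haplos[seq(2, 2 * N, 2), idx, drop = FALSE]
    w <- ind_fitness(dosage, config$selection)
    if (sum(w) <= 0) stop("total fitness is zero")
    seed <- sample.int(N, N, replace = TRUE, prob = w)
    pollen <- if (config$mating == "selfing") seed
              else sample.int(N, N, replace = TRUE, prob = w)
  } else {
    seed <- sample.int(N, N, replace = TRUE)
    pollen <- if (config$mating == "selfing") seed
              else sample.int(N, N, replace = TRUE)
  }
  nxt <- matrix(0L, 2 * N, ncol(haplos))
  for (i in seq_len(N)) {
    nxt[2L * i - 1L, ] <- make_gamete(haplos[c(2L * seed[i] - 1L,
                                               2L * seed[i]), , drop = FALSE],
                                      pop$chrom_len)
    nxt[2L * i, ] <- make_gamete(haplos[c(2L * pollen[i] - 1L,
                                          2L * pollen[i]), , drop = FALSE],
                                 pop$chrom_len)
  }
  structure(list(haplos = nxt, chrom_len = pop$chrom_len,
                 generation = pop$generation + 1L),
            class = "population_state")
}

# robust per-replicate null variance of angular change vs the ancestor
measure_null_variance <- function(p_final, p_anc, chrom_len, m = NULL,
                                  estimator = "var") {
  d <- angular(p_final) - angular(p_anc)
  dep <- if (is.null(m)) 0 else mean(1 / m)
  v <- max(0, robust_scale2(d, estimator) - dep)
  chrom_id <- rep(seq_along(chrom_len), chrom_len)
  per_chrom <- vapply(seq_along(chrom_len), function(c) {
    dc <- if (is.null(m)) 0 else mean(1 / m[chrom_id == c])
    max(0, robust_scale2(d[chrom_id == c], estimator) - dc)
  }, 0)
  list(v = v, per_chrom = per_chrom, cv = cv_percent(per_chrom))
}

#' Run one simulation replicate
#'
#' Draws founders, evolves `t` generations, applies sweep conditioning
#' (replicates in which any favored allele ends at frequency <= 0.5 are
#' discarded and fully re-run), grows a pool of `pool_n` offspring for
#' sequencing, and summarizes the replicate: realized founder and final
#' frequencies, pooled frequencies and Poisson read depths, robust null
#' variance of the angular frequency change relative to the ancestor
#' (genome-wide and per chromosome, population- and pool-based), and the
#' favored-allele trajectories.
#'
#' @param config a [sim_config()].
#' @param engine `"cpp"` (fast kernel, default) or `"r"` (reference
#'   implementation).
#' @param max_attempts cap on conditioning re-runs (default 10000).
#' @param estimator scale estimator for the per-replicate null variance;
#'   default `"var"`, the plain variance of the angular frequency change,
#'   which is the statistic whose replicate mean matches the analytic
#'   drift expectation (a neutral simulation contains no selected
#'   outliers, so no robustness is needed).
#' @return a `sim_result` list.
#' @export
run_replicate <- function(config, engine = c("cpp", "r"),
                          max_attempts = 10000, estimator = "var") {
  engine <- match.arg(engine)
  p_anc <- resolve_founders(config)
  chrom_len <- rep(config$snps_per_chrom, config$n_chrom)
  sidx <- sel_indices(config)
  ss <- vapply(config$selection, `[[`, 0, "s")
  sh <- vapply(config$selection, `[[`, 0, "h")
  sp0 <- vapply(config$selection, `[[`, 0, "p0")

  if (engine == "cpp") {
    raw <- cpp_evolve(p_anc, as.integer(chrom_len), config$N, config$t,
                      config$mating == "selfing", as.integer(sidx),
                      ss, sh, sp0, config$pool_n, as.integer(max_attempts))
  } else {
    cfg <- config
    cfg$founder_freqs <- p_anc
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("conditioning failed after ", max_attempts, " attempts")
      pop <- draw_founders(cfg)
      founder_freq <- colMeans(pop$haplos)
      traj <- matrix(NA_real_, config$t + 1L, length(sidx))
      if (length(sidx)) traj[1L, ] <- founder_freq[sidx + 1L]
      for (g in seq_len(config$t)) {
        pop <- next_generation(pop, cfg)
        if (length(sidx)) traj[g + 1L, ] <- colMeans(pop$haplos)[sidx + 1L]
      }
      final_freq <- colMeans(pop$haplos)
      if (!length(sidx) || all(final_freq[sidx + 1L] > 0.5)) break
    }
    raw <- list(founder_freq = founder_freq, final_freq = final_freq,
                attempts = attempts, traj = traj)
    if (config$pool_n > 0L) {
      cfg2 <- cfg
      cfg2$N <- config$N
      poolpop <- next_generation_subset(pop, cfg, config$pool_n)
      raw$pool_freq <- colMeans(poolpop)
    }
  }

  nv <- measure_null_variance(raw$final_freq, p_anc, chrom_len,
                              estimator = estimator)
  res <- list(config = config, founder_freq = raw$founder_freq,
              final_freq = raw$final_freq, ancestor_freq = p_anc,
              attempts = raw$attempts, traj = raw$traj,
              sweep_success = TRUE, null_variance = nv$v,
              per_chromosome_v = nv$per_chrom, cv = nv$cv)
  if (!is.null(raw$pool_freq)) {
    res$pool_freq <- raw$pool_freq
    m <- stats::rpois(length(raw$pool_freq), config$mean_depth)
    alt <- stats::rbinom(length(m), m, raw$pool_freq)
    res$pool_depth <- m
    res$pool_alt <- alt
    ok <- m > 0
    nvp <- measure_null_variance(ifelse(ok, alt / m, 0)[ok], p_anc[ok],
                                 tabulate(rep(seq_along(chrom_len),
                                              chrom_len)[ok],
                                          length(chrom_len)),
                                 m = m[ok], estimator = estimator)
    res$null_variance_pool <- nvp$v
    res$cv_pool <- nvp$cv
  }
  class(res) <- "sim_result"
  res
}

# R-engine helper: pool_n offspring from the final generation
next_generation_subset <- function(pop, config, n_off) {
  cfg <- config
  cfg$N <- config$N
  N <- config$N
  if (length(cfg$selection)) {
    idx <- sel_indices(cfg) + 1L
    dosage <- pop$haplos[seq(1, 2 * N, 2), idx, drop = FALSE] +
      pop$haplos[seq(2, 2 * N, 2), idx, drop = FALSE]
    w <- ind_fitness(dosage, cfg$selection)
  } else w <- rep(1, N)
  seed <- sample.int(N, n_off, replace = TRUE, prob = w)
  pollen <- if (cfg$mating == "selfing") seed
            else sample.int(N, n_off, replace = TRUE, prob = w)
  out <- matrix(0L, 2L * n_off, ncol(pop$haplos))
  for (i in seq_len(n_off)) {
    out[2L * i - 1L, ] <- make_gamete(pop$haplos[c(2L * seed[i] - 1L,
                                                   2L * seed[i]), ,
                                                 drop = FALSE],
                                      pop$chrom_len)
    out[2L * i, ] <- make_gamete(pop$haplos[c(2L * pollen[i] - 1L,
                                              2L * pollen[i]), ,
                                            drop = FALSE],
                                 pop$chrom_len)
  }
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("sim_result: N=%d %s, %d gen, %d SNPs; null variance",
                     " %.4f (CV %.1f%%), attempts %d\n"),
              x$config$N, x$config$mating, x$config$t,
              length(x$final_freq), x$null_variance, x$cv, x$attempts))
  invisible(x)
}

#' Calibrate census size against an observed null variance
#'
#' Runs `reps_per_N` neutral replicates at every `N` on a grid and
#' returns the `N` whose mean replicate null variance is closest to
#' `target_v` (ties broken toward smaller `N`). By default the null
#' variance is measured from population frequencies without pool or read
#' sampling noise, matching how the calibrated sizes back-compute from
#' the analytic drift expectation; set `use_pool = TRUE` to measure it
#' through the pooled-sequencing layer instead.
#'
#' @param target_v observed null variance to match (> 0).
#' @param mating `"selfing"` or `"outcrossing"`.
#' @param grid candidate `N` values.
#' @param reps_per_N replicates per grid point (default 100).
#' @param config_args further arguments to [sim_config()] (genome
#'   dimensions etc.).
#' @param seed optional RNG seed.
#' @param use_pool measure the null variance from pooled reads
#'   (default FALSE).
#' @param estimator scale estimator per replicate (default `"var"`, see
#'   [run_replicate()]).
#' @return list with `N_star`, `table` (N, mean_v, sd_v) and `target_v`.
#' @export
calibrate_N <- function(target_v, mating, grid, reps_per_N = 100,
                        config_args = list(), seed = NULL,
                        use_pool = FALSE, estimator = "var") {
  if (target_v <= 0) stop("target_v must be positive")
  if (!is.null(seed)) set.seed(seed)
  grid <- sort(unique(as.integer(grid)))
  mean_v <- numeric(length(grid))
  sd_v <- numeric(length(grid))
  for (i in seq_along(grid)) {
    args <- c(list(N = grid[i], mating = mating), config_args)
    if (!use_pool && is.null(args$pool_n)) args$pool_n <- 0L
    cfg <- do.call(sim_config, args)
    vs <- vapply(seq_len(reps_per_N), function(r) {
      res <- run_replicate(cfg, estimator = estimator)
      if (use_pool) res$null_variance_pool else res$null_variance
    }, 0)
    mean_v[i] <- mean(vs)
    sd_v[i] <- stats::sd(vs)
  }
  err <- abs(mean_v - target_v)
  N_star <- grid[which.min(err)]  # which.min breaks ties toward smaller N
  if (target_v > max(mean_v) || target_v < min(mean_v))
    warning("target_v outside the achievable range of the grid; ",
            "boundary N returned")
  list(N_star = N_star,
       table = data.frame(N = grid, mean_v = mean_v, sd_v = sd_v),
       target_v = target_v)
}

#' Minor-allele-frequency distributions of best-matching neutral runs
#'
#' Selects the `k_best` replicates whose null variance is nearest to the
#' observed value and returns their minor-allele-frequency histograms.
#' The minor allele is oriented per SNP by the mean final frequency
#' across all replicates in the ensemble.
#'
#' @param replicates list of `sim_result` objects.
#' @param observed_v observed null variance.
#' @param k_best replicates to keep (default 10).
#' @param breaks histogram breaks on `[0, 0.5]`.
#' @return list with `density` (k_best x bins matrix), `mids`,
#'   `selected` (indices into `replicates`), `v` (their null variances).
#' @export
matched_neutral_afd <- function(replicates, observed_v, k_best = 10,
                                breaks = seq(0, 0.5, by = 0.025)) {
  if (length(replicates) < k_best)
    stop("need at least k_best replicates")
  v <- vapply(replicates, `[[`, 0, "null_variance")
  sel <- order(abs(v - observed_v))[seq_len(k_best)]
  freqs <- vapply(replicates, function(r) {
    if (!is.null(r$pool_freq)) r$pool_freq else r$final_freq
  }, numeric(length(replicates[[1]]$final_freq)))
  mean_f <- rowMeans(freqs)
  dens <- t(vapply(sel, function(i) {
    f <- freqs[, i]
    minor <- ifelse(mean_f <= 0.5, f, 1 - f)
    h <- graphics::hist(pmin(minor, 0.5), breaks = breaks, plot = FALSE)
    h$density
  }, numeric(length(breaks) - 1L)))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(density = dens, mids = mids, selected = sel, v = v[sel])
}
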