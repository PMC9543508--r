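#' Angular (arcsine square root) transform of an allele frequency
#'
#' `x = 2*asin(sqrt(p))`, in radians on `[0, pi]`. On this scale the
#' sampling variance of a binomial frequency estimate from `m` reads is
#' approximately `1/m`, independent of `p`, and drift variance over `t`
#' generations is approximately `t/(2*Ne)`.
#'
#' @param p allele frequency in `[0, 1]` (vectorized).
#' @return transformed frequency in radians.
#' @export
angular <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  2 * asin(sqrt(p))
}

#' @rdname angular
#' @param x transformed frequency in radians on `[0, pi]`.
#' @export
inverse_angular <- function(x) {
  if (any(x < 0 | x > pi + 1e-12, na.rm = TRUE)) stop("x must lie in [0, pi]")
  sin(x / 2)^2
}

#' Expected variance of angular frequency change under neutral drift
#'
#' `t/(2*Ne) + 1/(2*n) + 1/m`: drift over `t` generations, one round of
#' sampling `n` diploids into the sequencing pool, and `m` reads from the
#' pool. Use `Inf` to drop the pool or read term.
#'
#' @param t generations.
#' @param Ne effective population size.
#' @param n diploid individuals in the pool (default `Inf`).
#' @param m read depth (default `Inf`).
#' @export
expected_drift_variance <- function(t, Ne, n = Inf, m = Inf) {
  if (any(c(t, Ne, n, m) <= 0)) stop("all arguments must be positive")
  t / (2 * Ne) + 1 / (2 * n) + 1 / m
}

#' Effective size of a partially inbred population
#'
#' `Ne = N/(1+F)` where `F` is the inbreeding coefficient.
#' @param N census size.
#' @param f inbreeding coefficient in `[0, 1]`.
#' @export
effective_size <- function(N, f) {
  if (any(N <= 0)) stop("N must be positive")
  if (any(f < 0 | f > 1)) stop("F must lie in [0, 1]")
  N / (1 + f)
}

# scale-squared estimators of a numeric vector: robust Gaussian ("iqr",
# "mad") or the plain variance ("var", used for neutral simulations where
# no selected outliers exist and the frequency-change distribution can be
# strongly non-Gaussian)
robust_scale2 <- function(d, estimator = c("iqr", "mad", "var")) {
  estimator <- match.arg(estimator)
  switch(estimator,
         iqr = (diff(stats::quantile(d, c(0.25, 0.75), names = FALSE)) /
                  1.349)^2,
         mad = stats::mad(d)^2,
         var = stats::var(d))
}

#' Robust null divergence between two populations
#'
#' Dispersion of the per-SNP difference of angular-transformed
#' frequencies, estimated by a robust Gaussian scale estimator so that a
#' minority of selected outlier loci does not inflate it, minus the mean
#' read-depth sampling variance `mean(1/mA + 1/mB)`. Under independent
#' evolution the result estimates `vA + vB`, the sum of the two lineage
#' null variances. Floored at zero.
#'
#' @param xA,xB per-SNP transformed frequencies (radians).
#' @param mA,mB per-SNP read depths (default `Inf`, i.e. no depth noise).
#' @param estimator `"iqr"` (default, `(IQR/1.349)^2`), `"mad"`, or
#'   `"var"` (plain, non-robust variance).
#' @param min_snps minimum number of SNPs required (default 500).
#' @return list with `d_hat`, `n_snps_used`, `raw_scale2`, `depth_term`.
#' @export
robust_null_divergence <- function(xA, xB, mA = Inf, mB = Inf,
                                   estimator = c("iqr", "mad", "var"),
                                   min_snps = 500) {
  if (length(xA) != length(xB)) stop("xA and xB must have equal length")
  if (length(xA) < min_snps)
    stop("need at least ", min_snps, " SNPs, got ", length(xA))
  d <- xA - xB
  s2 <- robust_scale2(d, estimator)
  dep <- mean(1 / mA + 1 / mB)
  list(d_hat = max(0, s2 - dep), n_snps_used = length(d),
       raw_scale2 = s2, depth_term = dep)
}

pair_index <- function(P) {
  idx <- utils::combn(P, 2)
  t(idx)  # 6 x 2 for P = 4
}

# all pairwise robust divergences for a table (or x/m matrices)
pairwise_divergences <- function(xmat, mmat, estimator = "iqr",
                                 min_snps = 500, pop_ids = NULL) {
  P <- ncol(xmat)
  pr <- pair_index(P)
  if (is.null(pop_ids)) pop_ids <- colnames(xmat)
  if (is.null(pop_ids)) pop_ids <- paste0("pop", seq_len(P))
  d <- apply(pr, 1, function(ij) {
    robust_null_divergence(xmat[, ij[1]], xmat[, ij[2]],
                           mmat[, ij[1]], mmat[, ij[2]],
                           estimator = estimator, min_snps = min_snps)$d_hat
  })
  names(d) <- paste(pop_ids[pr[, 1]], pop_ids[pr[, 2]], sep = "-")
  d
}

#' Block-bootstrap covariance of pairwise null divergences
#'
#' The genome is split into consecutive windows of `window_snps` SNPs (in
#' genome order; the final short window is kept). Windows are resampled
#' with replacement `n_boot` times; all pairwise robust null divergences
#' are recomputed in each replicate, and their covariance matrix over
#' replicates is returned. For four populations this is the 6x6 matrix
#' `V` weighting the generalized least squares fit.
#'
#' @param x a [snp_table] (all populations used).
#' @param window_snps SNPs per bootstrap window (default 500).
#' @param n_boot bootstrap replicates (default 1000).
#' @param estimator robust scale estimator, see
#'   [robust_null_divergence()].
#' @return covariance matrix (pairs x pairs) with dimnames naming the
#'   population pairs.
#' @export
bootstrap_covariance <- function(x, window_snps = 500, n_boot = 1000,
                                 estimator = "iqr") {
  xm <- angular(pmin(pmax(allele_freq(x), 0), 1))
  mm <- depth(x)
  boot_cov_xm(xm, mm, window_snps, n_boot, estimator, x$pop_ids)
}

boot_cov_xm <- function(xm, mm, window_snps = 500, n_boot = 1000,
                        estimator = "iqr", pop_ids = NULL) {
  S <- nrow(xm)
  win <- (seq_len(S) - 1L) %/% as.integer(window_snps)
  W <- max(win) + 1L
  if (W < 2L) stop("need at least 2 windows of ", window_snps, " SNPs")
  if (n_boot < 2L) stop("n_boot must be at least 2")
  widx <- split(seq_len(S), win)
  reps <- vapply(seq_len(n_boot), function(b) {
    take <- unlist(widx[sample.int(W, W, replace = TRUE)], use.names = FALSE)
    pairwise_divergences(xm[take, , drop = FALSE], mm[take, , drop = FALSE],
                         estimator = estimator, min_snps = 2,
                         pop_ids = pop_ids)
  }, numeric(nrow(pair_index(ncol(xm)))))
  stats::cov(t(reps))
}

#' Incidence matrix relating populations to pairwise divergences
#'
#' Rows are unordered population pairs (in [utils::combn()] order),
#' columns are populations; entry 1 iff the population belongs to the
#' pair. Full column rank for four populations.
#' @param pop_ids population labels.
#' @export
incidence_matrix <- function(pop_ids) {
  P <- length(pop_ids)
  pr <- pair_index(P)
  X <- matrix(0, nrow(pr), P,
              dimnames = list(paste(pop_ids[pr[, 1]], pop_ids[pr[, 2]],
                                    sep = "-"), pop_ids))
  for (r in seq_len(nrow(pr))) X[r, pr[r, ]] <- 1
  X
}

#' Generalized least squares estimate of lineage null variances
#'
#' Solves `y = X v + e` where `y` holds the pairwise null divergences,
#' `X` is the pair-population incidence matrix and `V = Cov(y)`:
#' `v = (X' V^-1 X)^-1 X' V^-1 y`. Negative components are floored at
#' zero with a warning.
#'
#' @param y named vector of pairwise divergences (6 values for 4
#'   populations, [utils::combn()] pair order).
#' @param V covariance matrix of `y`; identity if `NULL`.
#' @param pop_ids population labels (recovered from `names(y)` if
#'   omitted).
#' @return named vector of per-population null variances.
#' @export
gls_null_variances <- function(y, V = NULL, pop_ids = NULL) {
  if (is.null(pop_ids)) {
    if (is.null(names(y))) stop("provide pop_ids or named y")
    pop_ids <- unique(unlist(strsplit(names(y), "-", fixed = TRUE)))
  }
  X <- incidence_matrix(pop_ids)
  if (nrow(X) != length(y)) stop("y length does not match pair count")
  if (is.null(V)) V <- diag(length(y))
  Vi <- tryCatch(solve(V), error = function(e) {
    warning("V is singular; using pseudo-inverse")
    pseudo_inverse(V)
  })
  XtVi <- t(X) %*% Vi
  v <- tryCatch(drop(solve(XtVi %*% X, XtVi %*% y)),
                error = function(e) {
                  warning("normal equations singular; using pseudo-inverse")
                  drop(pseudo_inverse(XtVi %*% X) %*% (XtVi %*% y))
                })
  if (any(v < 0)) {
    warning("negative null variance estimate(s) floored at 0: ",
            paste(pop_ids[v < 0], collapse = ", "))
    v <- pmax(v, 0)
  }
  names(v) <- pop_ids
  v
}

pseudo_inverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Estimate lineage null variances from a four-population count table
#'
#' The full pipeline: angular transform of pooled frequencies, robust
#' pairwise null divergences with the read-depth term removed,
#' block-bootstrap covariance of the six divergences, and a generalized
#' least squares fit distilling them into one null variance per
#' population. Optionally repeats the fit per chromosome to measure
#' intragenomic variability (coefficient of variation of per-chromosome
#' estimates).
#'
#' @param x a [snp_table] with at least 3 populations (6 pairs need 4).
#' @param window_snps,n_boot,estimator see [bootstrap_covariance()].
#' @param per_chromosome also fit each chromosome separately (default
#'   TRUE when there are at least 2 chromosomes with enough SNPs).
#' @param min_snps minimum SNPs for a divergence estimate; chromosomes
#'   below it are excluded with a warning.
#' @return object of class `null_variance_estimate`: list with `v`,
#'   `pairwise` (the six divergences), `bootstrap_V`, `per_chromosome_v`
#'   (chromosomes x populations, or NULL), `cv` (percent, per
#'   population), `n_snps`.
#' @export
estimate_null_variances <- function(x, window_snps = 500, n_boot = 1000,
                                    estimator = "iqr",
                                    per_chromosome = TRUE, min_snps = 500) {
  xm <- angular(pmin(pmax(allele_freq(x), 0), 1))
  mm <- depth(x)
  y <- pairwise_divergences(xm, mm, estimator, min_snps, x$pop_ids)
  V <- boot_cov_xm(xm, mm, window_snps, n_boot, estimator, x$pop_ids)
  v <- gls_null_variances(y, V, x$pop_ids)
  pcv <- NULL; cv <- NULL
  if (per_chromosome && length(unique(x$chrom)) >= 2L) {
    res <- tryCatch(
      per_chromosome_null_variances(xm, mm, x$chrom, window_snps,
                                    n_boot, estimator, min_snps,
                                    x$pop_ids),
      error = function(e) {
        warning("per-chromosome fit skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      pcv <- res$per_chromosome_v
      cv <- res$cv
    }
  }
  structure(list(v = v, pairwise = y, bootstrap_V = V,
                 per_chromosome_v = pcv, cv = cv, n_snps = nrow(xm)),
            class = "null_variance_estimate")
}

#' @export
print.null_variance_estimate <- function(x, ...) {
  cat("null variance estimates (radians^2):\n")
  print(round(x$v, 5))
  if (!is.null(x$cv)) {
    cat("interchromosomal CV (%):\n")
    print(round(x$cv, 2))
  }
  invisible(x)
}

# per-chromosome GLS fits on precomputed angular matrices
per_chromosome_null_variances <- function(xm, mm, chrom, window_snps = 500,
                                          n_boot = 1000, estimator = "iqr",
                                          min_snps = 500, pop_ids = NULL) {
  chroms <- unique(chrom)
  keep <- vapply(chroms, function(ch) sum(chrom == ch) >= min_snps,
                 logical(1))
  if (!all(keep))
    warning("chromosome(s) with < ", min_snps, " SNPs excluded: ",
            paste(chroms[!keep], collapse = ", "))
  chroms <- chroms[keep]
  if (length(chroms) < 2L) stop("need at least 2 usable chromosomes")
  rows <- lapply(chroms, function(ch) {
    i <- chrom == ch
    y <- pairwise_divergences(xm[i, , drop = FALSE], mm[i, , drop = FALSE],
                              estimator, min_snps, pop_ids)
    Vc <- boot_cov_xm(xm[i, , drop = FALSE], mm[i, , drop = FALSE],
                      min(window_snps, floor(sum(i) / 2)), n_boot,
                      estimator, pop_ids)
    suppressWarnings(gls_null_variances(y, Vc, pop_ids))
  })
  pcv <- do.call(rbind, rows)
  rownames(pcv) <- chroms
  list(per_chromosome_v = pcv, cv = apply(pcv, 2, cv_percent))
}

#' Per-chromosome null variances and their coefficient of variation
#'
#' Runs the full robust-divergence + bootstrap + GLS pipeline separately
#' on each chromosome and summarizes intragenomic variability as
#' `cv = 100 * sd / mean` of the per-chromosome estimates for each
#' population.
#'
#' @inheritParams estimate_null_variances
#' @return list with `per_chromosome_v` (chromosomes x populations) and
#'   `cv` (percent per population).
#' @export
per_chromosome_cv <- function(x, window_snps = 500, n_boot = 1000,
                              estimator = "iqr", min_snps = 500) {
  xm <- angular(pmin(pmax(allele_freq(x), 0), 1))
  per_chromosome_null_variances(xm, depth(x), x$chrom, window_snps,
                                n_boot, estimator, min_snps, x$pop_ids)
}

#' Coefficient of variation in percent
#' @param x numeric vector.
#' @export
cv_percent <- function(x) 100 * stats::sd(x) / mean(x)

#' Typical allele-frequency change implied by a null variance
#'
#' Adds one standard deviation `sqrt(v)` to the angular-transformed
#' starting frequency, clips to `[0, pi]`, and back-transforms; the
#' symmetric downward change is returned as well.
#'
#' @param v null variance (radians^2), non-negative.
#' @param p0 starting allele frequency in (0, 1).
#' @return list with `delta_p` (upward change `p_plus - p0`), `p_plus`,
#'   `p_minus`.
#' @export
typical_delta_p <- function(v, p0 = 0.5) {
  if (any(v < 0)) stop("v must be non-negative")
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must lie in (0, 1)")
  x0 <- angular(p0)
  p_plus <- inverse_angular(pmin(pi, x0 + sqrt(v)))
  p_minus <- inverse_angular(pmax(0, x0 - sqrt(v)))
  list(delta_p = p_plus - p0, p_plus = p_plus, p_minus = p_minus)
}
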