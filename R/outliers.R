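#' The nine competing models of per-SNP evolution
#'
#' Each model partitions the four populations (A1, A2, B1, B2 order)
#' into groups sharing one allele-frequency parameter:
#' model 0 one group (drift); models 1-4 one focal population vs the
#' rest (adaptation in A1, A2, B1, B2); model 5 treatment parallelism
#' (\{A1,A2\} vs \{B1,B2\}); model 6 \{A1,A2\} | \{B1\} | \{B2\};
#' model 7 \{B1,B2\} | \{A1\} | \{A2\}; model 8 four singletons
#' (independence). `k` = number of groups = number of estimated
#' frequencies.
#'
#' @return named list of partitions; each partition is a list of integer
#'   vectors of population indices.
#' @export
model_partitions <- function() {
  list(`0` = list(1:4),
       `1` = list(1L, 2:4),
       `2` = list(2L, c(1L, 3L, 4L)),
       `3` = list(3L, c(1L, 2L, 4L)),
       `4` = list(4L, 1:3),
       `5` = list(1:2, 3:4),
       `6` = list(1:2, 3L, 4L),
       `7` = list(3:4, 1L, 2L),
       `8` = list(1L, 2L, 3L, 4L))
}

#' Per-SNP observation for the outlier models
#'
#' Bundles the angular-transformed observed frequencies with the three
#' variance components: lineage null variance `v`, read-depth variance
#' `1/m`, and the pool-sampling term `1/(2n)` (included by the pipeline;
#' defaults to 0 here so low-level callers state it explicitly). The
#' total per-population variance is their sum.
#'
#' @param x numeric 4-vector of transformed frequencies (radians).
#' @param v numeric 4-vector of lineage null variances.
#' @param depth_var numeric 4-vector of `1/m` read-depth variances.
#' @param pool_var scalar `1/(2n)` term (default 0).
#' @export
snp_observation <- function(x, v, depth_var, pool_var = 0) {
  if (length(x) != 4L || length(v) != 4L || length(depth_var) != 4L)
    stop("x, v and depth_var must have length 4")
  s2 <- v + depth_var + pool_var
  if (any(v < 0) || any(depth_var < 0) || pool_var < 0 || any(s2 <= 0))
    stop("variances must be non-negative with positive totals")
  structure(list(x = x, v = v, depth_var = depth_var, pool_var = pool_var,
                 s2 = s2), class = "snp_observation")
}

#' Gaussian log likelihood of one model at one SNP
#'
#' Within each group `g` of the partition, observations are
#' `x_i ~ Normal(xi_g, s2_i)`; the MLE of `xi_g` is the inverse-variance
#' weighted mean, clipped to `[0, pi]`. The log likelihood sums the
#' normal densities across populations.
#'
#' @param model model id 0-8 or a partition (list of index vectors).
#' @param obs a [snp_observation()].
#' @return list with `LL`, `xi` (per-group MLEs) and `k`.
#' @export
loglik <- function(model, obs) {
  part <- if (is.list(model)) model
          else model_partitions()[[as.character(model)]]
  if (is.null(part)) stop("unknown model id")
  xi <- vapply(part, function(g) {
    w <- 1 / obs$s2[g]
    min(pi, max(0, sum(obs$x[g] * w) / sum(w)))
  }, 0)
  LL <- 0
  for (j in seq_along(part)) {
    g <- part[[j]]
    LL <- LL + sum(stats::dnorm(obs$x[g], xi[j], sqrt(obs$s2[g]),
                                log = TRUE))
  }
  list(LL = LL, xi = xi, k = length(part))
}

#' Fit all nine models to one SNP
#'
#' Selects the best model by minimum AIC (`AIC = 2k - 2LL`; ties toward
#' the lower model id) and, when the best model is not drift, computes
#' the likelihood-ratio statistic `2(LL_best - LL_0)` against a
#' chi-square with `k_best - 1` degrees of freedom.
#'
#' @param obs a [snp_observation()].
#' @return list of class `fit_result`: `LL` and `AIC` (per model),
#'   `best_model`, `lrt_stat`, `df`, `p_value`, `xi_best`.
#' @export
fit_snp <- function(obs) {
  parts <- model_partitions()
  fits <- lapply(parts, loglik, obs = obs)
  LL <- vapply(fits, `[[`, 0, "LL")
  k <- vapply(fits, `[[`, 0, "k")
  aic <- 2 * k - 2 * LL
  best <- which.min(aic)  # ties resolved toward lower id
  if (best == 1L) {
    lrt <- 0; df <- 0L; p <- 1
  } else {
    lrt <- max(0, 2 * (LL[best] - LL[1]))
    df <- k[best] - 1L
    p <- stats::pchisq(lrt, df, lower.tail = FALSE)
  }
  structure(list(LL = LL, AIC = aic, best_model = as.integer(best - 1L),
                 lrt_stat = lrt, df = as.integer(df), p_value = p,
                 xi_best = fits[[best]]$xi),
            class = "fit_result")
}

#' Fit the nine models to every SNP (vectorized)
#'
#' @param x matrix (SNPs x 4) of angular-transformed observed
#'   frequencies.
#' @param v length-4 vector of lineage null variances.
#' @param m matrix (SNPs x 4) of read depths (or `Inf` to drop the
#'   depth term).
#' @param pool_var scalar `1/(2n)` pool-sampling addition to every
#'   variance. The pipeline passes `1/(2 * pool_size)`; the default here
#'   is 0 so callers supplying null variances that already absorb the
#'   pool round are not double-counted.
#' @return data.frame with per-model AIC columns (`AIC0`..`AIC8`),
#'   `best_model`, `lrt_stat`, `df`, `p_value`.
#' @export
fit_all_snps <- function(x, v, m, pool_var = 0) {
  x <- as.matrix(x)
  S <- nrow(x)
  s2 <- matrix(rep(v, each = S), S, 4) + 1 / as.matrix(m) + pool_var
  parts <- model_partitions()
  w <- 1 / s2
  base <- rowSums(-0.5 * log(2 * pi * s2))
  LL <- matrix(0, S, length(parts))
  for (mi in seq_along(parts)) {
    dev <- 0
    for (g in parts[[mi]]) {
      wg <- w[, g, drop = FALSE]
      xi <- pmin(pi, pmax(0, rowSums(x[, g, drop = FALSE] * wg) /
                               rowSums(wg)))
      dev <- dev + rowSums(wg * (x[, g, drop = FALSE] - xi)^2)
    }
    LL[, mi] <- base - 0.5 * dev
  }
  k <- lengths(parts)
  aic <- 2 * rep(k, each = S) - 2 * LL
  dim(aic) <- dim(LL)
  best <- max.col(-aic, ties.method = "first")
  lrt <- pmax(0, 2 * (LL[cbind(seq_len(S), best)] - LL[, 1]))
  df <- k[best] - 1L
  p <- ifelse(best == 1L, 1, stats::pchisq(lrt, df, lower.tail = FALSE))
  out <- as.data.frame(aic)
  names(out) <- paste0("AIC", seq_along(parts) - 1L)
  out$best_model <- best - 1L
  out$lrt_stat <- lrt
  out$df <- as.integer(df)
  out$p_value <- p
  out
}

#' Sidak-corrected per-test significance threshold
#'
#' `1 - (1 - alpha)^(1/M)` for `M` tests at family-wise level `alpha`.
#' @param M number of tests (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @export
sidak_threshold <- function(M, alpha = 0.05) {
  if (M < 1) stop("M must be at least 1")
  1 - (1 - alpha)^(1 / M)
}

#' Flag outlier SNPs from per-SNP model fits
#'
#' Likelihood-ratio p-values are assessed only where drift is not the
#' best model by AIC. Flagged SNPs (p below the Sidak threshold, or
#' below the Benjamini-Hochberg cutoff if `method = "BH"`) are grouped
#' into runs of consecutive flagged SNPs per chromosome.
#'
#' @param fits data.frame from [fit_all_snps()].
#' @param chrom,pos SNP coordinates (optional; indices used if absent).
#' @param M number of tests for the correction (default `nrow(fits)`).
#' @param alpha significance level (default 0.05).
#' @param method `"sidak"` (default) or `"BH"`.
#' @return list with `outliers` (data.frame of flagged SNPs with a `run`
#'   id), `threshold`, `table` (full Manhattan-ready data.frame with
#'   `outlier` flag).
#' @export
detect_outliers <- function(fits, chrom = NULL, pos = NULL, M = nrow(fits),
                            alpha = 0.05, method = c("sidak", "BH")) {
  method <- match.arg(method)
  S <- nrow(fits)
  if (is.null(chrom)) chrom <- rep("genome", S)
  if (is.null(pos)) pos <- seq_len(S)
  tested <- fits$best_model != 0L
  if (method == "sidak") {
    thr <- sidak_threshold(M, alpha)
    flag <- tested & fits$p_value < thr
  } else {
    padj <- rep(1, S)
    padj[tested] <- stats::p.adjust(fits$p_value[tested], "BH")
    thr <- alpha
    flag <- tested & padj < alpha
  }
  tab <- data.frame(chrom = chrom, pos = pos,
                    best_model = fits$best_model,
                    lrt_stat = fits$lrt_stat, p_value = fits$p_value,
                    outlier = flag)
  run <- integer(S)
  if (any(flag)) {
    new_run <- flag & !c(FALSE, flag[-S] & chrom[-S] == chrom[-1])
    run[flag] <- cumsum(new_run)[flag]
  }
  tab$run <- run
  list(outliers = tab[flag, , drop = FALSE], threshold = thr, table = tab)
}

#' Percentage of SNPs best supported by each model
#'
#' @param fits data.frame from [fit_all_snps()] (or any object with a
#'   `best_model` column).
#' @return named numeric vector over models 0-8 summing to 100.
#' @export
model_support_summary <- function(fits) {
  counts <- tabulate(fits$best_model + 1L, nbins = 9L)
  pct <- 100 * counts / sum(counts)
  names(pct) <- paste0("model", 0:8)
  pct
}
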