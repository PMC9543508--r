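#' Filter a SNP count table
#'
#' Applies, in order: (a) a minimum per-population depth rule (drop the
#' SNP if any population has fewer than `min_depth` reads), (b) a cap at
#' the `depth_quantile` quantile of the total depth (summed over
#' populations) computed on SNPs passing (a), (c) a minor-allele-frequency
#' rule (drop only if the MAF is below `maf` in every population), and
#' (d) an optional site whitelist. Each SNP is tallied at the first rule
#' that removes it.
#'
#' @param x a [snp_table].
#' @param min_depth minimum reads per population (default 50).
#' @param depth_quantile quantile defining the total-depth cap
#'   (default 0.95); `NULL` disables the cap.
#' @param maf minor-allele-frequency threshold (default 0.05).
#' @param whitelist optional character vector of `"chrom:pos"` keys to
#'   retain.
#' @param depth_cap optional absolute total-depth cap; when supplied it
#'   is used instead of recomputing the quantile, which makes repeated
#'   filtering with a previously reported cap idempotent (the relative
#'   quantile rule, by construction, trims the top of whatever
#'   distribution it is handed).
#' @return list with elements `table` (the filtered [snp_table]) and
#'   `report` (a `filter_report` with per-rule removal tallies and the
#'   computed `depth_cap`).
#' @export
filter_snps <- function(x, min_depth = 50, depth_quantile = 0.95,
                        maf = 0.05, whitelist = NULL, depth_cap = NULL) {
  if (!inherits(x, "snp_table")) stop("x must be a snp_table")
  n <- n_snps(x)
  if (n < 1L) stop("empty table")
  m <- depth(x)
  keep <- rep(TRUE, n)

  fail_depth <- apply(m < min_depth, 1, any)
  n_depth <- sum(fail_depth)
  keep <- !fail_depth

  n_quant <- 0L
  if (is.null(depth_cap) && !is.null(depth_quantile) && any(keep)) {
    tot <- rowSums(m)
    depth_cap <- stats::quantile(tot[keep], depth_quantile, names = FALSE)
  }
  if (is.null(depth_cap)) depth_cap <- NA_real_
  if (!is.na(depth_cap)) {
    tot <- rowSums(m)
    fail_q <- keep & tot > depth_cap
    n_quant <- sum(fail_q)
    keep <- keep & !fail_q
  }

  p <- allele_freq(x)
  mafm <- pmin(p, 1 - p)
  mafm[is.na(mafm)] <- 0
  fail_maf <- keep & apply(mafm < maf, 1, all)
  n_maf <- sum(fail_maf)
  keep <- keep & !fail_maf

  n_wl <- 0L
  if (!is.null(whitelist)) {
    key <- paste0(x$chrom, ":", x$pos)
    fail_wl <- keep & !(key %in% whitelist)
    n_wl <- sum(fail_wl)
    keep <- keep & !fail_wl
  }

  if (!any(keep)) warning("all SNPs removed by filters")
  report <- structure(list(n_input = n, n_removed_depth = n_depth,
                           n_removed_quantile = n_quant,
                           n_removed_maf = n_maf,
                           n_removed_whitelist = n_wl,
                           n_retained = sum(keep),
                           depth_cap = depth_cap),
                      class = "filter_report")
  list(table = x[keep], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("filter_report: %d SNPs in; removed %d (depth), ",
                     "%d (depth cap %.0f), %d (MAF), %d (whitelist); ",
                     "%d retained\n"),
              x$n_input, x$n_removed_depth, x$n_removed_quantile,
              x$depth_cap, x$n_removed_maf, x$n_removed_whitelist,
              x$n_retained))
  invisible(x)
}
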