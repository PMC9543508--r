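#' Default pipeline configuration
#'
#' All tunables of the analysis are explicit keys so any deviation from
#' the defaults is visible in the run report: the 50-read minimum depth,
#' 95th-percentile total-depth cap, 5% MAF rule, 500-SNP bootstrap
#' windows, 1000 bootstrap replicates, 9 generations, selection
#' coefficient 0.8 with initial frequency 0.02, and alpha 0.05.
#'
#' @param stages character vector of stages to run, in order; any subset
#'   of `c("synth", "filter", "nullvar", "calibrate", "outliers")`.
#' @param profile `"default"` (14 x 2000 genome) or `"mini"`
#'   (2 x 200, for smoke tests).
#' @export
pipeline_config <- function(stages = c("synth", "filter", "nullvar",
                                       "outliers"),
                            profile = c("default", "mini")) {
  profile <- match.arg(profile)
  genome <- if (profile == "mini") list(n_chrom = 2L, snps_per_chrom = 200L)
            else list(n_chrom = 14L, snps_per_chrom = 2000L)
  list(stages = stages, profile = profile, genome = genome,
       pops = list(A1 = list(mating = "selfing", N = 43),
                   A2 = list(mating = "selfing", N = 13),
                   B1 = list(mating = "outcrossing", N = 366),
                   B2 = list(mating = "outcrossing", N = 219)),
       t = 9L, pool_n = 100L, mean_depth = 75,
       filter = list(min_depth = 50, depth_quantile = 0.95, maf = 0.05),
       nullvar = list(window_snps = if (profile == "mini") 50L else 500L,
                      n_boot = if (profile == "mini") 100L else 1000L,
                      min_snps = if (profile == "mini") 100L else 500L,
                      estimator = "iqr"),
       calibrate = list(grid = NULL, reps_per_N = 50L, use_pool = FALSE),
       outliers = list(alpha = 0.05, method = "sidak"))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order — synthetic-experiment
#' generation, SNP filtering, null-variance estimation, optional
#' census-size calibration, and outlier testing — writing per-stage TSV
#' outputs and a JSON run report (seeds, parameters, per-stage
#' summaries) to `out_dir`. Later stages read the in-memory outputs of
#' earlier ones; `counts_file` can seed the pipeline with an existing
#' sync table instead of the synth stage.
#'
#' @param config list from [pipeline_config()] (or a path to a JSON file
#'   with the same structure).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; each stochastic stage receives a derived,
#'   recorded sub-seed.
#' @param counts_file optional sync file used instead of the `synth`
#'   stage.
#' @return the run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempdir(),
                         seed = 1, counts_file = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  set.seed(seed)
  sub_seeds <- stats::setNames(
    sample.int(.Machine$integer.max %/% 2L, length(config$stages)),
    config$stages)
  report <- list(package_version = as.character(utils::packageVersion(
                   "draftscope")),
                 seed = seed, sub_seeds = as.list(sub_seeds),
                 config = config, stages = list())
  tab <- NULL
  if (!is.null(counts_file)) tab <- read_counts(counts_file)
  nv <- NULL
  bundle <- NULL

  for (stage in config$stages) {
    if (stage == "synth") {
      ec <- experiment_config(pops = config$pops,
                              n_chrom = config$genome$n_chrom,
                              snps_per_chrom = config$genome$snps_per_chrom,
                              t = config$t, pool_n = config$pool_n,
                              mean_depth = config$mean_depth)
      bundle <- generate_experiment(ec, seed = sub_seeds[["synth"]])
      tab <- bundle$counts
      write_counts(tab, file.path(out_dir, "counts.sync"))
      report$stages$synth <- list(n_snps = n_snps(tab),
                                  realized_v =
                                    as.list(bundle$truth$realized_v))
    } else if (stage == "filter") {
      if (is.null(tab)) stop("filter stage needs counts (synth stage ",
                             "or counts_file)")
      fr <- filter_snps(tab, config$filter$min_depth,
                        config$filter$depth_quantile, config$filter$maf)
      tab <- fr$table
      write_counts(tab, file.path(out_dir, "counts.filtered.sync"))
      report$stages$filter <- unclass(fr$report)
    } else if (stage == "nullvar") {
      if (is.null(tab)) stop("nullvar stage needs counts")
      set.seed(sub_seeds[["nullvar"]])
      nv <- estimate_null_variances(tab, config$nullvar$window_snps,
                                    config$nullvar$n_boot,
                                    config$nullvar$estimator,
                                    min_snps = config$nullvar$min_snps)
      utils::write.table(
        data.frame(pop = names(nv$v), v = nv$v,
                   cv = if (is.null(nv$cv)) NA else nv$cv),
        file.path(out_dir, "null_variances.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$nullvar <- list(v = as.list(nv$v),
                                    cv = if (is.null(nv$cv)) NULL
                                         else as.list(nv$cv),
                                    pairwise = as.list(nv$pairwise))
    } else if (stage == "calibrate") {
      if (is.null(nv)) stop("calibrate stage needs nullvar results")
      set.seed(sub_seeds[["calibrate"]])
      cal <- lapply(seq_along(nv$v), function(i) {
        mating <- config$pops[[names(nv$v)[i]]]$mating
        grid <- config$calibrate$grid
        if (is.null(grid))
          grid <- if (mating == "selfing") seq(5L, 100L, 5L)
                  else seq(100L, 600L, 25L)
        calibrate_N(max(nv$v[i], 1e-4), mating, grid,
                    config$calibrate$reps_per_N,
                    config_args = list(
                      n_chrom = config$genome$n_chrom,
                      snps_per_chrom = config$genome$snps_per_chrom,
                      t = config$t),
                    use_pool = config$calibrate$use_pool)$N_star
      })
      names(cal) <- names(nv$v)
      report$stages$calibrate <- cal
    } else if (stage == "outliers") {
      if (is.null(tab) || is.null(nv))
        stop("outliers stage needs counts and nullvar results")
      xm <- angular(pmin(pmax(allele_freq(tab), 0), 1))
      fits <- fit_all_snps(xm, nv$v, depth(tab),
                           pool_var = 1 / (2 * tab$pool_size[1]))
      det <- detect_outliers(fits, tab$chrom, tab$pos,
                             alpha = config$outliers$alpha,
                             method = config$outliers$method)
      utils::write.table(det$table, file.path(out_dir, "outliers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$outliers <- list(
        n_outliers = nrow(det$outliers),
        n_runs = length(unique(det$outliers$run)),
        threshold = det$threshold,
        model_support = as.list(model_support_summary(fits)))
    } else {
      stop("unknown stage: ", stage)
    }
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
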