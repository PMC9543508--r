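test_that("founders are drawn from the ancestor frequencies", {
  cfg <- mini_config(N = 500, "outcrossing",
                     founder_freqs = rep(0, 300), pool_n = 0)
  pop <- draw_founders(cfg)
  expect_true(all(pop$haplos == 0L))
  expect_equal(dim(pop$haplos), c(1000L, 300L))

  cfg2 <- mini_config(N = 1000, "outcrossing",
                      founder_freqs = rep(0.3, 300), pool_n = 0)
  set.seed(1)
  pop2 <- draw_founders(cfg2)
  expect_equal(mean(pop2$haplos), 0.3, tolerance = 0.01)

  expect_error(sim_config(N = 10, "selfing", n_chrom = 1,
                          snps_per_chrom = 10,
                          founder_freqs = rep(1.5, 10)), "\\[0, 1\\]")
})

test_that("selected loci are seeded at p0 with at least one copy", {
  set.seed(2)
  sel <- list(selected_locus(chrom = 1, s = 0.8, p0 = 0.02))
  cfg <- sim_config(N = 500, "selfing", n_chrom = 1, snps_per_chrom = 51,
                    selection = sel, pool_n = 0)
  copies <- replicate(60, {
    pop <- draw_founders(cfg)
    sum(pop$haplos[, 26])  # middle SNP
  })
  expect_true(all(copies > 0))
  expect_equal(mean(copies), 1000 * 0.02, tolerance = 0.2)
})

test_that("gametes carry one obligate crossover per chromosome", {
  # homozygous parent -> gamete identical to either haplotype
  hap <- rbinom(40, 1, 0.5)
  ind <- rbind(hap, hap)
  expect_equal(make_gamete(ind, c(20L, 20L)), hap)

  # distinguishable haplotypes: each chromosome is a prefix of one parent
  # and a suffix of the other (exactly one switch, never zero)
  set.seed(6)
  L <- 11
  ind2 <- rbind(rep(0L, L), rep(1L, L))
  gam <- replicate(4000, make_gamete(ind2, L))
  switches <- apply(gam, 2, function(g) sum(diff(g) != 0))
  expect_true(all(switches == 1))
  # ends always derive from different parental haplotypes
  expect_true(all(gam[1, ] != gam[L, ]))
  # adjacent-interval recombination frequency ~ 1/(L-1)
  for (j in 1:(L - 1)) {
    r <- mean(gam[j, ] != gam[j + 1, ])
    expect_equal(r, 1 / (L - 1), tolerance = 0.45)
  }
  # starting haplotype is unbiased
  expect_equal(mean(gam[1, ]), 0.5, tolerance = 0.06)
})

test_that("fitness is multiplicative across loci", {
  sel2 <- list(selected_locus(1, s = 0.8), selected_locus(2, s = 0.8))
  expect_equal(ind_fitness(cbind(2L, 0L), sel2[1]), c(1.8))
  expect_equal(ind_fitness(cbind(1L, 0L), sel2[1]), c(1.4))
  expect_equal(ind_fitness(cbind(2L, 2L), sel2), c(1.8 * 1.8))
  expect_equal(ind_fitness(matrix(0L, 3, 0), list()), rep(1, 3))
})

test_that("neutral fixation probability equals the founding frequency", {
  set.seed(10)
  cfg <- sim_config(N = 4, "outcrossing", t = 80, n_chrom = 1,
                    snps_per_chrom = 2, founder_freqs = rep(0.25, 2),
                    pool_n = 0)
  fixed <- replicate(600, run_replicate(cfg)$final_freq[1] == 1)
  expect_lt(abs(mean(fixed) - 0.25), 3 * sqrt(0.25 * 0.75 / 600))
})

test_that("one generation of selection follows the deterministic recursion", {
  # s = 0.8, h = 0.5, p = 0.5: p' = (p^2(1+s) + pq(1+hs)) / wbar
  p <- 0.5; s <- 0.8; h <- 0.5
  wbar <- 1 + 2 * p * (1 - p) * h * s + p^2 * s
  p_exp <- (p^2 * (1 + s) + p * (1 - p) * (1 + h * s)) / wbar
  sel <- list(selected_locus(1, s = s, p0 = p, h = h))
  cfg <- sim_config(N = 2000, "outcrossing", t = 1, n_chrom = 1,
                    snps_per_chrom = 11, selection = sel,
                    founder_freqs = rep(0.5, 11), pool_n = 0)
  set.seed(3)
  dp <- replicate(80, {
    r <- run_replicate(cfg)
    r$traj[2, 1] - r$traj[1, 1]
  })
  expect_lt(abs(mean(dp) - (p_exp - p)), 0.004)
})

test_that("selfing halves heterozygosity each generation in expectation", {
  set.seed(4)
  cfg <- sim_config(N = 250, "selfing", t = 3, n_chrom = 30,
                    snps_per_chrom = 1, founder_freqs = rep(0.5, 30),
                    pool_n = 0)
  hets <- replicate(8, {
    pop <- draw_founders(cfg)
    h0 <- mean(pop$haplos[seq(1, 500, 2), ] != pop$haplos[seq(2, 500, 2), ])
    for (g in 1:3) pop <- next_generation(pop, cfg)
    ht <- mean(pop$haplos[seq(1, 500, 2), ] != pop$haplos[seq(2, 500, 2), ])
    ht / h0
  })
  expect_equal(mean(hets), (1 / 2)^3, tolerance = 0.12)
})

test_that("cpp and R engines agree statistically", {
  cfg <- mini_config(N = 25, "selfing", snps_per_chrom = 80, pool_n = 0,
                     founder_freqs = NULL)
  cfg$founder_freqs <- rep(0.4, 160)
  set.seed(12)
  v_cpp <- mean(replicate(50, run_replicate(cfg, engine = "cpp")$null_variance))
  v_r <- mean(replicate(50, run_replicate(cfg, engine = "r")$null_variance))
  expect_equal(v_cpp / v_r, 1, tolerance = 0.3)
})

test_that("run_replicate is deterministic given the seed", {
  cfg <- mini_config(N = 20, "selfing", pool_n = 50)
  set.seed(77)
  r1 <- run_replicate(cfg)
  set.seed(77)
  r2 <- run_replicate(cfg)
  expect_identical(r1$final_freq, r2$final_freq)
  expect_identical(r1$pool_alt, r2$pool_alt)
  expect_identical(r1$null_variance, r2$null_variance)
})

test_that("sweep conditioning retains only successful runs", {
  set.seed(13)
  sel <- list(selected_locus(1, s = 0.8, p0 = 0.02))
  cfg <- mini_config(N = 60, "selfing", selection = sel, pool_n = 0)
  r <- run_replicate(cfg)
  idx <- draftscope:::sel_indices(cfg) + 1L
  expect_gt(r$final_freq[idx], 0.5)
  expect_true(r$sweep_success)
  expect_gte(r$attempts, 1L)
})

test_that("null variance decreases with N and selfing exceeds outcrossing", {
  set.seed(15)
  mv <- sapply(c(10, 25, 60), function(N) {
    cfg <- mini_config(N = N, "selfing", pool_n = 0)
    mean(replicate(25, run_replicate(cfg)$null_variance))
  })
  expect_true(all(diff(mv) < 0))
  cfg_out <- mini_config(N = 60, "outcrossing", pool_n = 0)
  v_out <- mean(replicate(25, run_replicate(cfg_out)$null_variance))
  expect_gt(mv[3], v_out)
})

test_that("calibrate_N recovers a self-generated target", {
  set.seed(16)
  cfg_args <- list(n_chrom = 4, snps_per_chrom = 100)
  target_cfg <- do.call(sim_config,
                        c(list(N = 30, mating = "selfing", pool_n = 0),
                          cfg_args))
  target <- mean(replicate(120, run_replicate(target_cfg)$null_variance))
  cal <- calibrate_N(target, "selfing", grid = seq(18, 42, 4),
                     reps_per_N = 80, config_args = cfg_args, seed = 17)
  expect_lte(abs(cal$N_star - 30), 4)
  # unreachable target -> boundary with warning
  expect_warning(cal2 <- calibrate_N(50, "selfing", grid = c(20, 40),
                                     reps_per_N = 3,
                                     config_args = cfg_args),
                 "outside")
  expect_equal(cal2$N_star, 20L)
})

test_that("matched neutral AFD selects nearest replicates and shapes", {
  set.seed(18)
  cfg <- mini_config(N = 10, "selfing", pool_n = 0)
  reps <- lapply(1:15, function(i) run_replicate(cfg))
  v <- sapply(reps, `[[`, "null_variance")
  all_sel <- matched_neutral_afd(reps, observed_v = mean(v), k_best = 15)
  expect_setequal(all_sel$selected, 1:15)
  one <- matched_neutral_afd(reps, observed_v = v[7], k_best = 3)
  expect_equal(one$selected[1], 7L)
  # small-N selfing: U-shaped minor-allele distribution (mass at the
  # extreme bins exceeds the middle bins)
  d <- colMeans(all_sel$density)
  expect_gt(d[1], mean(d[8:13]))
})
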