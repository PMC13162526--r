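test_that("gene dropping obeys Mendelian transmission", {
  cfg <- sim_config(n_founders = 8, n_families = 6, family_size = 10,
                    n_markers = 500, missing_rate = 0, seed = 11)
  sim <- simulate_genotypes(cfg)
  fd <- sim$founders$dosage
  off <- sim$geno$dosage
  expect_false(anyNA(off))

  # opposite-homozygote parents force heterozygous offspring at that marker
  checked <- 0L
  for (f in unique(sim$pedigree$family)) {
    kids <- sim$pedigree$clone_id[sim$pedigree$family == f]
    s <- sim$pedigree$sire[match(kids[1], sim$pedigree$clone_id)]
    d <- sim$pedigree$dam[match(kids[1], sim$pedigree$clone_id)]
    forcing <- which(abs(fd[s, ] - fd[d, ]) == 2)
    if (length(forcing)) {
      expect_true(all(off[kids, forcing] == 1))
      checked <- checked + length(forcing)
    }
    # parent homozygous 0 cannot transmit an alternate allele
    zero_s <- which(fd[s, ] == 0 & fd[d, ] == 0)
    if (length(zero_s)) expect_true(all(off[kids, zero_s] == 0))
  }
  expect_gt(checked, 50)
})

test_that("het x het matings segregate 1:2:1 within binomial error", {
  cfg <- sim_config(n_founders = 4, n_families = 1, family_size = 500,
                    n_markers = 300, missing_rate = 0,
                    maf_range = c(0.4, 0.5), seed = 12)
  sim <- simulate_genotypes(cfg)
  fd <- sim$founders$dosage
  s <- sim$pedigree$sire[1]; d <- sim$pedigree$dam[1]
  hh <- which(fd[s, ] == 1 & fd[d, ] == 1)
  expect_gt(length(hh), 30)
  pooled <- table(factor(sim$geno$dosage[, hh], levels = 0:2))
  props <- pooled / sum(pooled)
  # pooled over >15k offspring-marker draws; 1/4, 1/2, 1/4 with slack for
  # within-marker correlation
  expect_equal(unname(as.numeric(props)), c(0.25, 0.5, 0.25), tolerance = 0.08)
})

test_that("missingness masking and determinism behave as configured", {
  cfg0 <- sim_config(n_founders = 6, n_families = 4, family_size = 6,
                     n_markers = 400, missing_rate = 0, seed = 5)
  expect_false(anyNA(simulate_genotypes(cfg0)$geno$dosage))

  cfg1 <- sim_config(n_founders = 6, n_families = 4, family_size = 6,
                     n_markers = 400, missing_rate = 0.1, seed = 5)
  d <- simulate_genotypes(cfg1)$geno$dosage
  expect_lt(abs(mean(is.na(d)) - 0.1), 0.01)

  a <- simulate_genotypes(cfg1)
  b <- simulate_genotypes(cfg1)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$pedigree, b$pedigree)
})

test_that("QTL variance fractions are realized and recoverable by regression", {
  cfg <- sim_config(n_founders = 12, n_families = 84, family_size = 12,
                    n_markers = 400, missing_rate = 0,
                    polygenic_h2 = 0, dominance_fraction = 0, seed = 21)
  gen <- simulate_genotypes(cfg)
  truth <- simulate_trait(gen$geno, cfg)
  expect_equal(truth$qtl$var_frac_realized, truth$qtl$var_frac_target,
               tolerance = 1e-10)
  # regression of the phenotype on each QTL dosage recovers its fraction
  y <- simulate_clone_values(truth, seed = 99)
  for (q in seq_len(nrow(truth$qtl))) {
    x <- gen$geno$dosage[, truth$qtl$marker_id[q]]
    r2 <- summary(stats::lm(y ~ x))$r.squared
    expect_lt(abs(r2 - truth$qtl$var_frac_target[q]), 0.05)
  }
  # QTL sit on their requested chromosomes
  expect_equal(truth$qtl$chrom, cfg$qtl_spec$chrom)
})

test_that("trait simulation handles the null architecture and scales variances", {
  cfg <- sim_config(n_founders = 6, n_families = 4, family_size = 6,
                    n_markers = 200, missing_rate = 0,
                    qtl_spec = data.frame(chrom = character(0),
                                          var_frac = numeric(0)),
                    polygenic_h2 = 0, dominance_fraction = 0, seed = 3)
  gen <- simulate_genotypes(cfg)
  truth <- simulate_trait(gen$geno, cfg)
  expect_true(all(truth$tbv == 0))
  expect_equal(unname(truth$variances["residual"]), 1)

  # realized additive variance composes from QTL fractions plus the
  # (QTL-orthogonalized) polygenic tail; residual covariance between the
  # two QTL under family structure leaves a modest wobble
  cfg2 <- sim_config(n_founders = 12, n_families = 25, family_size = 12,
                     n_markers = 200, missing_rate = 0,
                     polygenic_h2 = 0.1, dominance_fraction = 0, seed = 3)
  gen2 <- simulate_genotypes(cfg2)
  truth2 <- simulate_trait(gen2$geno, cfg2)
  expect_lt(abs(truth2$variances[["additive"]] -
                  (sum(cfg2$qtl_spec$var_frac) + 0.1)), 0.1)
  # and the per-QTL marginal fractions are hit exactly
  expect_equal(truth2$qtl$var_frac_realized, truth2$qtl$var_frac_target,
               tolerance = 1e-10)
})

test_that("trial simulation respects the augmented design and location effects", {
  cfg <- sim_config(n_founders = 8, n_families = 8, family_size = 8,
                    n_markers = 200, missing_rate = 0, seed = 7)
  gen <- simulate_genotypes(cfg)
  truth <- simulate_trait(gen$geno, cfg)
  ph <- simulate_trials(truth, cfg)

  # check clones appear exactly once in every block of each trial
  for (loc in unique(ph$location)) {
    sub <- ph[ph$location == loc, ]
    checks <- unique(sub$clone_id[sub$is_check])
    expect_length(checks, cfg$checks_per_block)
    tab <- table(sub$clone_id[sub$is_check], sub$block_id[sub$is_check])
    expect_true(all(tab == 1))
    # test clones appear exactly once per location
    expect_true(all(table(sub$clone_id[!sub$is_check]) == 1))
  }
  # location main effects order the location means (low < mid < high)
  loc_means <- tapply(ph$plot_mean, ph$location, mean)
  expect_equal(order(cfg$location_effects), order(unname(loc_means)))

  # degenerate design: all variances zero, flat trait -> every score = mu
  cfg0 <- sim_config(n_founders = 6, n_families = 4, family_size = 6,
                     n_markers = 200, missing_rate = 0,
                     qtl_spec = data.frame(chrom = character(0),
                                           var_frac = numeric(0)),
                     polygenic_h2 = 0, dominance_fraction = 0,
                     mu = 5, location_effects = c(0, 0, 0),
                     var_clone_location = 0, var_block = 0, var_residual = 0,
                     subsample_sd = 0, seed = 8)
  gen0 <- simulate_genotypes(cfg0)
  truth0 <- simulate_trait(gen0$geno, cfg0)
  ph0 <- simulate_trials(truth0, cfg0)
  expect_true(all(as.matrix(ph0[paste0("score_", 1:6)]) == 5))

  # capacity violation is a design error
  cfg_small <- sim_config(n_founders = 6, n_families = 30, family_size = 10,
                          n_markers = 100, blocks_per_trial = 2,
                          plots_per_block = 15, seed = 9)
  gen_s <- simulate_genotypes(cfg_small)
  truth_s <- simulate_trait(gen_s$geno, cfg_small)
  expect_error(simulate_trials(truth_s, cfg_small), "design error")
})
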