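test_that("fold plans partition clones into balanced folds, deterministically", {
  plan <- make_folds(10, k = 5, reps = 5, seed = 3)
  expect_equal(dim(plan$assignment), c(5L, 10L))
  for (r in 1:5)
    expect_true(all(table(plan$assignment[r, ]) == 2))
  # k x reps evaluation cells
  expect_equal(plan$k * plan$reps, 25L)

  plan2 <- make_folds(10, k = 5, reps = 5, seed = 3)
  expect_identical(plan$assignment, plan2$assignment)

  plan3 <- make_folds(23, k = 5, reps = 2, seed = 4)
  for (r in 1:2) {
    sizes <- table(plan3$assignment[r, ])
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sum(sizes), 23)
  }
  expect_error(make_folds(3, k = 5), "at least as many clones")
})

test_that("validation-set h2 separates signal from noise and is deterministic", {
  # At validation-set size (~50 related clones) the genetic/residual split is
  # weakly identified: most eigenvalues of a family-structured G are similar,
  # so the posterior mean is pulled toward its prior. The check is therefore
  # a separation and ranking check against the independent REML route, not
  # an absolute bound.
  sim <- family_sim()
  zc <- impute_and_center(sim$geno)
  G <- vanraden_grm(zc$Z, zc$p)$values
  ids <- sim$geno$clone_ids[1:50]
  Gv <- G[ids, ids]

  h2_noise <- sapply(1:4, function(s) {
    set.seed(s + 80)
    y <- setNames(rnorm(50), ids)
    suppressWarnings(validation_h2(y, Gv, n_iter = 1500, burn_in = 300,
                                   seed = s))
  })
  # fitted GEBVs as responses: genetic signal concentrated in the kernel
  set.seed(81)
  ytr <- setNames(drop(t(chol(Gv + diag(0.5, 50))) %*% rnorm(50)), ids)
  yg <- fit_gblup(ytr, Gv)$gebv
  h2_sig <- sapply(1:4, function(s)
    validation_h2(yg, Gv, n_iter = 1500, burn_in = 300, seed = s))
  expect_gt(mean(h2_sig), mean(h2_noise) + 0.05)

  # REML on the same data ranks the two cases the same way
  reml_noise <- suppressWarnings({
    set.seed(81 + 1)
    fit_gblup(setNames(rnorm(50), ids), Gv)$h2
  })
  reml_sig <- fit_gblup(yg, Gv)$h2
  expect_gt(reml_sig, reml_noise)

  a <- validation_h2(yg, Gv, n_iter = 1000, burn_in = 200, seed = 5)
  b <- validation_h2(yg, Gv, n_iter = 1000, burn_in = 200, seed = 5)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(validation_h2(yg[1:3], Gv[1:3, 1:3]), "at least 5")
})

test_that("accuracy is predictive ability over root validation heritability", {
  dat <- polygenic_trait(0.4, n_markers = 500, n_families = 8,
                         family_size = 10, seed = 90)
  ids <- names(dat$y)
  val <- ids[1:16]
  train <- setdiff(ids, val)
  data <- cv_data(dat$geno)
  cell <- evaluate_fold("gblup", dat$y, train, val, data, h2_val = 0.64,
                        config = run_config(n_iter = 800, burn_in = 100))
  expect_equal(cell$accuracy, cell$r_a / 0.8)
  # h2_val = 1 makes accuracy equal predictive ability
  cell1 <- evaluate_fold("gblup", dat$y, train, val, data, h2_val = 1,
                         config = run_config(n_iter = 800, burn_in = 100))
  expect_equal(cell1$accuracy, cell1$r_a)
  expect_error(evaluate_fold("gblup", dat$y, ids, val, data, h2_val = 1),
               "overlap")
})

test_that("the harness pairs models on one fold plan and fills every cell", {
  dat <- polygenic_trait(0.4, n_markers = 400, n_families = 6,
                         family_size = 10, seed = 91)
  cfg <- run_config(n_iter = 600, burn_in = 100, k = 4, reps = 2, seed = 17)
  cv <- run_cv(c("gblup", "brr"), dat$geno, dat$y, cfg)
  expect_equal(nrow(cv$results), 4 * 2 * 2)
  # all models share the identical fold plan
  cv2 <- run_cv("gblup", dat$geno, dat$y, cfg)
  expect_identical(cv$plan$assignment, cv2$plan$assignment)
  # validation sets within a repeat partition the clones
  for (r in 1:2) {
    sub <- cv$results[cv$results$rep == r & cv$results$model == "gblup", ]
    expect_equal(sum(sub$n_val), length(dat$y))
  }
  # the shared h2 denominator makes cells comparable across models
  wide <- merge(cv$results[cv$results$model == "gblup", c("rep", "fold", "h2_val")],
                cv$results[cv$results$model == "brr", c("rep", "fold", "h2_val")],
                by = c("rep", "fold"))
  expect_equal(wide$h2_val.x, wide$h2_val.y)
  expect_error(run_cv("ridge_of_doom", dat$geno, dat$y, cfg), "unknown model")
})

test_that("a degenerate cell is recorded missing while the run continues", {
  dat <- polygenic_trait(0.4, n_markers = 300, n_families = 6,
                         family_size = 8, seed = 92)
  y_flat <- setNames(rep(2.5, length(dat$y)), names(dat$y))
  cfg <- run_config(n_iter = 600, burn_in = 100, k = 4, reps = 1, seed = 18)
  cv <- suppressWarnings(run_cv("gblup", dat$geno, y_flat, cfg))
  expect_equal(nrow(cv$results), 4L)
  expect_true(all(is.na(cv$results$r_a)))
  expect_equal(cv$summary$n_failed, 4L)
})

test_that("the pipeline wrapper runs end to end and writes its outputs", {
  cfg <- run_config(n_iter = 500, burn_in = 100, k = 4, reps = 1, seed = 19,
                    sim = sim_config(n_founders = 8, n_families = 6,
                                     family_size = 8, n_markers = 300,
                                     seed = 20))
  out <- withr::local_tempdir()
  res <- run_pipeline(cfg, models = c("gblup", "bayes_b"), out_dir = out)
  expect_s3_class(res$cv, "cv_result")
  expect_equal(nrow(res$cv$results), 8L)
  expect_true(file.exists(file.path(out, "blues.csv")))
  expect_true(file.exists(file.path(out, "qc_markers.json")))
  expect_true(file.exists(file.path(out, "cv_results.csv")))
  rep_json <- jsonlite::read_json(file.path(out, "qc_markers.json"))
  expect_equal(rep_json$retained + Reduce(`+`, rep_json$removed),
               rep_json$input)
})
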