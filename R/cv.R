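#' Repeated k-fold plans
#'
#' Each repeat is a fresh uniform random partition of the clones into `k`
#' folds whose sizes differ by at most one. Deterministic given the seed.
#' With `k = 5` and `reps = 5` the downstream harness evaluates 25
#' (repeat, fold) cells per model.
#'
#' @param n number of clones.
#' @param k folds per repeat.
#' @param reps number of repeats.
#' @param seed integer seed.
#' @return list of class `fold_plan`: `n`, `k`, `reps`, `seed`,
#'   `assignment` (reps x n matrix of fold indices).
#' @export
make_folds <- function(n, k = 5, reps = 5, seed = 1L) {
  if (n < k) hcn_stop("need at least as many clones (", n, ") as folds (", k, ")")
  set.seed(seed)
  assignment <- t(vapply(seq_len(reps),
                         function(r) sample(rep_len(seq_len(k), n)),
                         integer(n)))
  structure(list(n = n, k = as.integer(k), reps = as.integer(reps),
                 seed = as.integer(seed), assignment = assignment),
            class = "fold_plan")
}

#' Validation-set narrow-sense heritability
#'
#' Fits the kernel-regression model on the validation clones only,
#' partitioning their phenotypic variance into a genetic component
#' (covariance given by the supplied relationship matrix, by default the
#' VanRaden G) and a residual, with variance components sampled from
#' scaled inverse chi-square full conditionals by MCMC. Returns the
#' posterior-mean `sigma2_a / (sigma2_a + sigma2_e)` over post-burn-in
#' samples. Values at or below 0.01 are flagged (`attr(x, "unstable")`),
#' since the accuracy ratio `r_a / sqrt(h2)` is then unstable.
#'
#' @param y_val named responses of the validation clones (>= 5).
#' @param K relationship matrix covering the validation clones.
#' @param n_iter,burn_in MCMC settings.
#' @param seed integer seed.
#' @param df0,s0 residual-variance prior (see [prior_spec()]).
#' @return heritability in (0, 1).
#' @export
validation_h2 <- function(y_val, K, n_iter = 6000, burn_in = 700, seed = 1L,
                          df0 = 5, s0 = NULL) {
  if (length(y_val) < 5) hcn_stop("need at least 5 validation clones")
  fit <- fit_rkhs(y_val, K, n_iter = n_iter, burn_in = burn_in, seed = seed,
                  df0 = df0, s0 = s0)
  h2 <- fit$h2
  if (h2 <= 0.01) {
    warning("validation-set h2 <= 0.01; accuracy is unstable")
    attr(h2, "unstable") <- TRUE
  }
  h2
}

#' Evaluate one train/validation split for one model
#'
#' Fits the model on the training clones, predicts the validation clones,
#' and returns the predictive ability `r_a` (Pearson correlation between
#' validation BLUEs and predictions), the validation-set heritability and
#' the accuracy `r_a / sqrt(h2_val)`. Constant predictions give a missing
#' `r_a` with a warning.
#'
#' @param model one of `"gblup"`, `"bayes_a"`, `"bayes_b"`, `"bayes_c"`,
#'   `"brr"`, `"bl"`, `"rkhs"`.
#' @param y full named response vector.
#' @param train_ids,validation_ids disjoint clone id sets.
#' @param data precomputed matrices from [cv_data()].
#' @param h2_val validation-set heritability (see [validation_h2()]);
#'   computed here if NULL.
#' @param config a [run_config()] supplying MCMC settings.
#' @param seed integer seed for the samplers.
#' @return list: `r_a`, `h2_val`, `accuracy`, `predictions`.
#' @export
evaluate_fold <- function(model, y, train_ids, validation_ids, data,
                          h2_val = NULL, config = run_config(), seed = 1L) {
  if (length(intersect(train_ids, validation_ids)))
    hcn_stop("training and validation sets overlap")
  mc <- config$mcmc
  y_tr <- y[train_ids]
  pred <- switch(
    model,
    gblup = {
      fit <- fit_gblup(y_tr, data$G$values[train_ids, train_ids])
      predict_gebv(fit, data$G, validation_ids, blend = 0.02)
    },
    rkhs = {
      fit <- fit_rkhs(y_tr, data$K$values[train_ids, train_ids],
                      n_iter = mc$n_iter, burn_in = mc$burn_in, seed = seed,
                      df0 = mc$df0, s0 = mc$s0)
      predict_gebv(fit, data$K, validation_ids, blend = 0.02)
    },
    {
      fit <- fit_bayes(y_tr, data$Z[train_ids, , drop = FALSE],
                       prior = prior_spec(model, df0 = mc$df0, s0 = mc$s0),
                       n_iter = mc$n_iter, burn_in = mc$burn_in, seed = seed)
      predict_bayes(fit, data$Z[validation_ids, , drop = FALSE])
    })
  if (is.null(h2_val))
    h2_val <- validation_h2(y[validation_ids],
                            data$G$values[validation_ids, validation_ids],
                            n_iter = mc$n_iter, burn_in = mc$burn_in,
                            seed = seed, df0 = mc$df0, s0 = mc$s0)
  r_a <- if (sd(pred) == 0) {
    warning("constant predictions for model '", model, "'; r_a undefined")
    NA_real_
  } else cor(y[validation_ids], pred)
  list(r_a = r_a, h2_val = as.numeric(h2_val),
       accuracy = r_a / sqrt(as.numeric(h2_val)), predictions = pred)
}

#' Precompute the matrices shared by all models in a CV run
#'
#' @param geno a QCed [genotype_table()].
#' @param theta,distance Gaussian-kernel settings (see [gaussian_kernel()]).
#' @return list: `Z` (centered dosages), `p`, `G` (VanRaden), `K`
#'   (Gaussian kernel).
#' @export
cv_data <- function(geno, theta = 1, distance = "squared_euclidean_mean") {
  zc <- impute_and_center(geno)
  list(Z = zc$Z, p = zc$p,
       G = vanraden_grm(zc$Z, zc$p),
       K = gaussian_kernel(zc$M, theta = theta, distance = distance))
}

#' Repeated k-fold cross-validation of genomic prediction models
#'
#' Every model is evaluated on the same fold plan (paired comparison).
#' Per (repeat, fold) cell, the validation-set heritability is computed
#' once with the VanRaden-G kernel model and shared by all models, so
#' accuracies are comparable across models; the paper-style accuracy is
#' `r_a / sqrt(h2_val)` and negative accuracies arise only from negative
#' predictive ability. A model failure marks its cell missing and the run
#' continues.
#'
#' @param models character vector of model labels (see [evaluate_fold()]).
#' @param geno aligned, QCed [genotype_table()].
#' @param blues a `blue_set` or named response vector aligned with `geno`.
#' @param config a [run_config()]; supplies folds, repeats, seed, MCMC
#'   settings and the kernel.
#' @return An object of class `cv_result`: list with `results` (long
#'   data.frame: rep, fold, model, n_val, r_a, h2_val, accuracy),
#'   `summary` (per-model mean/min/max over cells), `plan`.
#' @export
run_cv <- function(models, geno, blues, config = run_config()) {
  y <- if (inherits(blues, "blue_set"))
    setNames(blues$blues$blue, blues$blues$clone_id) else blues
  if (is.null(names(y))) hcn_stop("blues must carry clone ids")
  if (!identical(sort(names(y)), sort(geno$clone_ids)))
    hcn_stop("genotypes and BLUEs cover different clones; run match_geno_pheno()")
  y <- y[geno$clone_ids]
  bad <- setdiff(models, c("gblup", "bayes_a", "bayes_b", "bayes_c",
                           "brr", "bl", "rkhs"))
  if (length(bad)) hcn_stop("unknown model(s): ", paste(bad, collapse = ", "))
  data <- cv_data(geno, theta = config$rkhs$theta,
                  distance = config$rkhs$distance)
  plan <- make_folds(length(y), k = config$cv$k, reps = config$cv$reps,
                     seed = config$cv$seed)
  mc <- config$mcmc
  rows <- list()
  for (r in seq_len(plan$reps)) {
    for (f in seq_len(plan$k)) {
      val_ids <- names(y)[plan$assignment[r, ] == f]
      train_ids <- setdiff(names(y), val_ids)
      cell_seed <- derive_seed(config$cv$seed, r * 1000L + f)
      h2_val <- tryCatch(
        validation_h2(y[val_ids], data$G$values[val_ids, val_ids],
                      n_iter = mc$n_iter, burn_in = mc$burn_in,
                      seed = cell_seed, df0 = mc$df0, s0 = mc$s0),
        error = function(e) NA_real_)
      for (mi in seq_along(models)) {
        m <- models[mi]
        cell <- tryCatch(
          evaluate_fold(m, y, train_ids, val_ids, data,
                        h2_val = h2_val, config = config,
                        seed = derive_seed(cell_seed, mi)),
          error = function(e) {
            warning("model '", m, "' failed in rep ", r, " fold ", f, ": ",
                    conditionMessage(e))
            list(r_a = NA_real_, h2_val = as.numeric(h2_val),
                 accuracy = NA_real_)
          })
        rows[[length(rows) + 1L]] <-
          data.frame(rep = r, fold = f, model = m, n_val = length(val_ids),
                     r_a = cell$r_a, h2_val = cell$h2_val,
                     accuracy = cell$accuracy, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, summary = summarize_cv(results),
                 plan = plan),
            class = "cv_result")
}

summarize_cv <- function(results) {
  out <- do.call(rbind, lapply(split(results, results$model), function(d) {
    ok <- is.finite(d$r_a)
    data.frame(model = d$model[1],
               n_cells = nrow(d), n_failed = sum(!ok),
               mean_ra = mean(d$r_a[ok]), min_ra = suppressWarnings(min(d$r_a[ok])),
               max_ra = suppressWarnings(max(d$r_a[ok])),
               mean_accuracy = mean(d$accuracy[ok]),
               min_accuracy = suppressWarnings(min(d$accuracy[ok])),
               max_accuracy = suppressWarnings(max(d$accuracy[ok])),
               mean_h2_val = mean(d$h2_val, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$mean_accuracy), ]
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", x$plan$reps, "x", x$plan$k, "folds,",
      nrow(x$results), "model-cells\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a cross-validation result (long CSV + JSON summary)
#' @param cv a `cv_result`.
#' @param dir output directory (created if needed).
#' @export
write_cv_result <- function(cv, dir) {
  stopifnot(inherits(cv, "cv_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cv$results, file.path(dir, "cv_results.csv"), row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(cv$summary, file.path(dir, "cv_summary.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full pipeline on simulated or supplied data
#'
#' Simulate (when no data are given), QC, BLUE estimation, genotype/
#' phenotype matching, and repeated k-fold cross-validation, with stage
#' logging of dimensions. One entry point covering the whole analysis
#' chain.
#'
#' @param config a [run_config()].
#' @param models model labels to compare.
#' @param geno,pheno optional data; defaults to a simulation from
#'   `config$sim`.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return list: `qc`, `blues`, `geno`, `cv`.
#' @export
run_pipeline <- function(config = run_config(),
                         models = c("gblup", "bayes_a", "bayes_b", "bayes_c",
                                    "brr", "bl", "rkhs"),
                         geno = NULL, pheno = NULL, out_dir = NULL) {
  if (is.null(geno) || is.null(pheno)) {
    hcn_log("simulating data set (seed ", config$sim$seed, ")")
    sim <- simulate_dataset(config$sim)
    geno <- geno %||% sim$geno
    pheno <- pheno %||% sim$pheno
  }
  qc <- run_qc(geno, config$qc)
  hcn_log("QC: ", qc$marker_report$retained, " markers, ",
          qc$clone_report$retained, " clones retained")
  blues <- fit_mixed_model(pheno)
  hcn_log("BLUEs: ", nrow(blues$blues), " clones; H2 = ", round(blues$H2, 3))
  matched <- match_geno_pheno(qc$geno, blues)
  cv <- run_cv(models, matched$geno, matched$blues, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_blues(matched$blues, file.path(out_dir, "blues.csv"))
    write_qc_report(qc$marker_report, file.path(out_dir, "qc_markers.json"))
    write_qc_report(qc$clone_report, file.path(out_dir, "qc_clones.json"))
    write_cv_result(cv, out_dir)
  }
  list(qc = qc, blues = matched$blues, geno = matched$geno, cv = cv)
}
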