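#' Gaussian kernel over marker dosages
#'
#' `K_ij = exp(-d_ij * theta)` with `d_ij` the squared Euclidean distance
#' between dosage profiles divided by the marker count (default), or the
#' plain Euclidean distance. The per-marker scaling makes `theta` portable
#' across marker counts. The diagonal is exactly 1 and the matrix is
#' positive semi-definite for any `theta > 0`.
#'
#' @param dosages clone x marker matrix with no missing values (impute
#'   upstream, see [impute_and_center()]; centered or raw dosages give the
#'   same distances).
#' @param theta decay rate (> 0).
#' @param distance `"squared_euclidean_mean"` or `"euclidean"`.
#' @return A `relationship_matrix` of kind `"gaussian_K"`.
#' @export
gaussian_kernel <- function(dosages, theta = 1,
                            distance = c("squared_euclidean_mean", "euclidean")) {
  distance <- match.arg(distance)
  if (theta <= 0) hcn_stop("theta must be positive")
  if (anyNA(dosages)) hcn_stop("dosages contain missing values; impute first")
  sq <- rowSums(dosages^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(dosages)
  d2[d2 < 0] <- 0
  d <- switch(distance,
              squared_euclidean_mean = d2 / ncol(dosages),
              euclidean = sqrt(d2))
  K <- exp(-d * theta)
  diag(K) <- 1
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(dosages), rownames(dosages))
  relationship_matrix(K, kind = "gaussian_K")
}

#' Fit kernel regression (RKHS) by Gibbs sampling
#'
#' Gaussian-process regression `y = 1 mu + u + e` with
#' `u ~ N(0, K sigma2_u)`, sampled in the whitened coordinates of the
#' eigendecomposition of `K` (coordinates with negligible eigenvalues are
#' dropped). Variance components get scaled inverse chi-square priors:
#' the residual with `(df0, s0)` (`s0 = NULL` derives the scale from the
#' response as in [prior_spec()]), the kernel variance with `dfu` degrees
#' of freedom and a scale derived from `var(y)` and `r2`. Reported
#' narrow-sense heritability is the posterior mean of
#' `sigma2_u / (sigma2_u + sigma2_e)`.
#'
#' @param y named numeric vector of training responses.
#' @param K kernel (`relationship_matrix` or plain symmetric matrix)
#'   covering the training clones; any PSD kernel works, e.g. the
#'   VanRaden G, in which case the fit is the Bayesian counterpart of
#'   GBLUP.
#' @param n_iter,burn_in chain length and burn-in (defaults 6000 / 700).
#' @param seed integer seed.
#' @param df0,s0 residual variance prior (see [prior_spec()]).
#' @param dfu kernel-variance prior degrees of freedom.
#' @param r2 prior proportion of variance attributed to the kernel term.
#' @return A `model_fit` with `gebv` (posterior-mean genetic values `u`),
#'   `h2`, `vc`, `chains`, `mcmc`; predict with [predict_gebv()].
#' @export
fit_rkhs <- function(y, K, n_iter = 6000, burn_in = 700, seed = 1L,
                     df0 = 5, s0 = NULL, dfu = 5, r2 = 0.5) {
  if (is.null(names(y))) hcn_stop("y must be a named vector (clone ids)")
  if (burn_in >= n_iter) hcn_stop("burn_in must be smaller than n_iter")
  V <- as_rel_values(K)
  missing_cl <- setdiff(names(y), rownames(V))
  if (length(missing_cl))
    hcn_stop("kernel is missing clone(s): ", paste(head(missing_cl), collapse = ", "))
  V <- V[names(y), names(y)]
  n <- length(y)
  e <- eigen(V, symmetric = TRUE)
  tol <- 1e-8 * max(e$values, 1)
  if (min(e$values) < -tol)
    hcn_stop("kernel is not positive semi-definite (eigenvalue ",
             signif(min(e$values), 3), "); consider blending with the identity")
  pos <- e$values > tol
  q <- sum(pos)
  if (q == 0) hcn_stop("kernel has rank 0")
  U <- e$vectors[, pos, drop = FALSE]
  d <- e$values[pos]

  vy <- var(y)
  if (!is.finite(vy) || vy == 0) vy <- 1e-8
  s0 <- s0 %||% ((1 - r2) * vy * (df0 + 2) / df0)
  su <- r2 * vy / mean(d) * (dfu + 2) / dfu

  set.seed(seed)
  mu <- mean(y)
  sigma2u <- r2 * vy / mean(d)
  sigma2e <- (1 - r2) * vy
  u <- rep(0, n)
  n_keep <- n_iter - burn_in
  u_sum <- rep(0, n); mu_sum <- 0
  se_chain <- numeric(n_keep); h2_chain <- numeric(n_keep)
  su_chain <- numeric(n_keep)
  for (it in seq_len(n_iter)) {
    w <- drop(crossprod(U, y - mu))
    prec <- 1 / sigma2e + 1 / (sigma2u * d)
    alpha <- rnorm(q, mean = (w / sigma2e) / prec, sd = sqrt(1 / prec))
    u <- drop(U %*% alpha)
    mu <- rnorm(1, mean(y - u), sqrt(sigma2e / n))
    sigma2u <- (sum(alpha^2 / d) + dfu * su) / rchisq(1, q + dfu)
    resid <- y - mu - u
    sigma2e <- (sum(resid^2) + df0 * s0) / rchisq(1, n + df0)
    if (!is.finite(sigma2e) || sigma2e <= 0)
      hcn_stop("non-finite residual variance at iteration ", it)
    if (it > burn_in) {
      k <- it - burn_in
      u_sum <- u_sum + u
      mu_sum <- mu_sum + mu
      se_chain[k] <- sigma2e
      h2_chain[k] <- sigma2u / (sigma2u + sigma2e)
      su_chain[k] <- sigma2u
    }
  }
  gebv <- setNames(u_sum / n_keep, names(y))
  structure(list(model = "rkhs", beta = mu_sum / n_keep, gebv = gebv,
                 vc = c(sigma2_g = mean(su_chain),
                        sigma2_e = mean(se_chain)),
                 h2 = mean(h2_chain),
                 chains = list(sigma2e = se_chain, h2 = h2_chain),
                 mcmc = list(n_iter = n_iter, burn_in = burn_in, seed = seed,
                             df0 = df0, s0 = s0, su = su)),
            class = "model_fit")
}

#' Predict validation genetic values from a kernel-regression fit
#'
#' Same conditional-mean construction as [predict_gebv()]:
#' `u_val = K_vt K_tt^-1 u_train` (plus the grand mean if `add_beta`).
#'
#' @param fit a `model_fit` from [fit_rkhs()].
#' @param K_full kernel covering training and validation clones.
#' @param validation_ids clone ids to predict.
#' @param blend identity blend for the training-block inverse.
#' @param add_beta if TRUE, add the posterior-mean grand mean.
#' @return named numeric vector of predictions.
#' @export
predict_rkhs <- function(fit, K_full, validation_ids, blend = 0.02,
                         add_beta = FALSE) {
  out <- predict_gebv(fit, K_full, validation_ids, blend = blend)
  if (add_beta) out <- out + fit$beta
  out
}
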