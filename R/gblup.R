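#' Fit GBLUP by EM-REML on a relationship matrix
#'
#' Fits `y = 1 beta + g + e` with `g ~ N(0, K sigma2_g)` and
#' `e ~ N(0, I sigma2_e)` by REML. Variance components are estimated with
#' EM updates in the eigenbasis of `K` (monotone in the REML likelihood),
#' with an Aitken acceleration step that is only accepted when it improves
#' the objective. `beta` is the generalized-least-squares grand mean and
#' training breeding values come from the mixed-model equations,
#' `g_hat = sigma2_g K (sigma2_g K + sigma2_e I)^-1 (y - 1 beta)`.
#'
#' @param y named numeric vector of training responses (clone BLUEs).
#' @param K relationship matrix (`relationship_matrix` or plain symmetric
#'   matrix) covering at least the training clones.
#' @param tol relative convergence tolerance on the variance components.
#' @param max_iter maximum EM iterations.
#' @return An object of class `model_fit`: list with `model`, `beta`,
#'   `gebv` (named, training clones), `vc` (`sigma2_g`, `sigma2_e`), `h2`
#'   (`sigma2_g / (sigma2_g + sigma2_e)`), `converged`, `n_iter`,
#'   `loglik` (REML log-likelihood trace).
#' @export
fit_gblup <- function(y, K, tol = 1e-6, max_iter = 200) {
  if (is.null(names(y))) hcn_stop("y must be a named vector (clone ids)")
  V <- as_rel_values(K)
  missing_cl <- setdiff(names(y), rownames(V))
  if (length(missing_cl))
    hcn_stop("relationship matrix is missing clone(s): ",
             paste(head(missing_cl), collapse = ", "))
  V <- V[names(y), names(y)]
  n <- length(y)
  e <- eigen(V, symmetric = TRUE)
  d <- pmax(e$values, 0)
  yt <- drop(crossprod(e$vectors, y))
  xt <- drop(crossprod(e$vectors, rep(1, n)))
  pos <- d > 1e-10 * max(d, 1)
  q <- sum(pos)
  if (q == 0) hcn_stop("relationship matrix has rank 0")

  vy <- var(y)
  if (vy == 0) vy <- 1e-8
  sg <- vy / 2; se <- vy / 2
  reml_ll <- function(sg, se) {
    Vi <- sg * d + se
    W <- 1 / Vi
    xwx <- sum(W * xt^2)
    beta <- sum(W * xt * yt) / xwx
    r <- yt - xt * beta
    -0.5 * (sum(log(Vi)) + log(xwx) + sum(W * r^2))
  }
  em_step <- function(sg, se) {
    Vi <- sg * d + se
    W <- 1 / Vi
    xwx <- sum(W * xt^2)
    beta <- sum(W * xt * yt) / xwx
    r <- yt - xt * beta
    Py <- W * r
    Pd <- W - (W * xt)^2 / xwx           # diagonal of rotated P
    sg_new <- sum(sg^2 * d[pos] * Py[pos]^2 + sg - sg^2 * d[pos] * Pd[pos]) / q
    se_new <- sum(se^2 * Py^2 + se - se^2 * Pd) / n
    c(max(sg_new, 1e-12), max(se_new, 1e-12))
  }

  ll <- reml_ll(sg, se)
  ll_trace <- ll
  hist3 <- matrix(NA_real_, 3, 2)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    new <- em_step(sg, se)
    hist3 <- rbind(hist3[-1, , drop = FALSE], log(new))
    # Aitken delta-squared acceleration on the log scale, kept only if it
    # improves the REML objective (preserves monotonicity)
    if (it %% 5 == 0 && !anyNA(hist3)) {
      dx1 <- hist3[2, ] - hist3[1, ]
      dx2 <- hist3[3, ] - hist3[2, ]
      denom <- dx2 - dx1
      acc <- ifelse(abs(denom) > 1e-12, hist3[3, ] - dx2^2 / denom, hist3[3, ])
      cand <- exp(acc)
      if (all(is.finite(cand)) && all(cand > 0) &&
          reml_ll(cand[1], cand[2]) > reml_ll(new[1], new[2]))
        new <- cand
    }
    rel <- max(abs(new - c(sg, se)) / pmax(abs(c(sg, se)), 1e-10))
    sg <- new[1]; se <- new[2]
    ll_trace <- c(ll_trace, reml_ll(sg, se))
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM-REML did not reach tolerance ", tol, " in ", max_iter,
            " iterations; returning last iterate")

  Vi <- sg * d + se
  W <- 1 / Vi
  xwx <- sum(W * xt^2)
  beta <- sum(W * xt * yt) / xwx
  Py <- W * (yt - xt * beta)
  gebv <- drop(e$vectors %*% (sg * d * Py))
  names(gebv) <- names(y)
  structure(list(model = "gblup", beta = beta, gebv = gebv,
                 vc = c(sigma2_g = sg, sigma2_e = se),
                 h2 = sg / (sg + se), converged = converged,
                 n_iter = it, loglik = ll_trace),
            class = "model_fit")
}

#' Predict breeding values for validation clones from a GBLUP fit
#'
#' Conditional expectation under the joint Gaussian:
#' `g_val = K_vt K_tt^-1 g_train`, with the training block inverted after
#' blending (see [grm_inverse()]). A validation clone genomically identical
#' to a training clone receives that clone's training value (at
#' `blend = 0`); a clone unrelated to all training clones receives the
#' prior mean 0.
#'
#' @param fit a `model_fit` from [fit_gblup()] (or [fit_rkhs()]).
#' @param K_full relationship matrix covering training and validation clones.
#' @param validation_ids clone ids to predict.
#' @param blend identity blend used when inverting the training block.
#' @return named numeric vector of validation GEBVs.
#' @export
predict_gebv <- function(fit, K_full, validation_ids, blend = 0.02) {
  stopifnot(inherits(fit, "model_fit"))
  V <- as_rel_values(K_full)
  train_ids <- names(fit$gebv)
  missing_cl <- setdiff(c(train_ids, validation_ids), rownames(V))
  if (length(missing_cl))
    hcn_stop("relationship matrix is missing clone(s): ",
             paste(head(missing_cl), collapse = ", "))
  K_tt <- V[train_ids, train_ids]
  K_vt <- V[validation_ids, train_ids, drop = FALSE]
  inv <- grm_inverse(K_tt, blend = blend)$inverse
  drop(K_vt %*% inv %*% fit$gebv)
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit [", x$model, "]: ", length(x$gebv), " clones; h2 = ",
      round(x$h2, 3), "; beta = ", signif(x$beta, 4), "\n", sep = "")
  invisible(x)
}

#' Serialize a model fit to JSON (variance components, h2, beta)
#' @param fit a `model_fit`.
#' @param path output path.
#' @export
write_model_fit <- function(fit, path) {
  stopifnot(inherits(fit, "model_fit"))
  jsonlite::write_json(list(model = fit$model, beta = fit$beta,
                            vc = as.list(fit$vc), h2 = fit$h2),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
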