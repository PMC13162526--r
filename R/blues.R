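#' Fit the multi-location mixed model and extract clone BLUEs
#'
#' Fits the two-stage model for plot means
#' `y = mu + clone + block(trial) + clone:trial + e` by REML. Clones are
#' fixed in the BLUE fit (best linear unbiased estimates of clone means);
#' a companion fit with clone random supplies the clone variance needed for
#' broad-sense heritability. Location and year are folded into a single
#' trial factor (location-year combinations). Terms that cannot be
#' estimated are dropped: the clone-by-trial interaction needs at least two
#' trials, the block term at least two blocks.
#'
#' @param pheno a [phenotype_set()]; the response is `plot_mean`.
#' @return An object of class `blue_set`: list with `blues` (data.frame
#'   `clone_id`, `blue`, `se`), `vc` (variance components `sigma2_c`,
#'   `sigma2_b`, `sigma2_cl`, `sigma2_e` and a `converged` flag), `H2`
#'   (broad-sense heritability), `grand_mean`.
#' @export
fit_mixed_model <- function(pheno) {
  stopifnot(inherits(pheno, "phenotype_set"))
  df <- as.data.frame(pheno)
  df$clone <- factor(df$clone_id)
  df$trial <- factor(paste(df$location, df$year, sep = ":"))
  df$block <- factor(paste(df$trial, df$block_id, sep = ":"))
  n_clone <- nlevels(df$clone)
  if (n_clone < 2) hcn_stop("need at least 2 clones")
  if (nrow(df) <= n_clone)
    hcn_stop("singular design: clones are confounded with plots ",
             "(no residual degrees of freedom for the clone term)")

  has_trial <- nlevels(df$trial) > 1
  has_block <- nlevels(df$block) > 1
  re_terms <- c(if (has_block) "(1 | block)",
                if (has_trial) "(1 | clone:trial)")
  re_part <- if (length(re_terms)) paste("+", paste(re_terms, collapse = " + ")) else ""

  # BLUE fit: clone fixed, no intercept -> coefficients are clone means
  f_fixed <- stats::as.formula(paste("plot_mean ~ 0 + clone", re_part))
  fit_f <- if (length(re_terms)) {
    lme4::lmer(f_fixed, data = df, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE))
  } else stats::lm(f_fixed, data = df)
  beta <- if (length(re_terms)) lme4::fixef(fit_f) else stats::coef(fit_f)
  if (anyNA(beta))
    hcn_stop("singular design: clone effects inestimable (clone confounded ",
             "with trial/block structure)")
  V <- as.matrix(stats::vcov(fit_f))
  se <- sqrt(diag(V))
  clone_levels <- levels(df$clone)
  blues <- data.frame(clone_id = clone_levels,
                      blue = as.numeric(beta)[match(paste0("clone", clone_levels),
                                                    names(beta))],
                      se = se[match(paste0("clone", clone_levels), names(beta))],
                      row.names = NULL, stringsAsFactors = FALSE)

  # companion fit: clone random, for variance components and H2
  f_rand <- stats::as.formula(paste("plot_mean ~ 1 + (1 | clone)", re_part))
  fit_r <- lme4::lmer(f_rand, data = df, REML = TRUE,
                      control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                  check.nobs.vs.nRE = "ignore",
                                                  calc.derivs = FALSE))
  vc_tab <- as.data.frame(lme4::VarCorr(fit_r))
  getvc <- function(grp) {
    v <- vc_tab$vcov[vc_tab$grp == grp]
    if (length(v)) v[1] else 0
  }
  conv <- length(fit_r@optinfo$conv$lme4$messages %||% character(0)) == 0
  if (!conv) warning("REML fit did not converge cleanly; ",
                     "variance components are the last iterate")
  vc <- list(sigma2_c = getvc("clone"),
             sigma2_b = getvc("block"),
             sigma2_cl = getvc("clone:trial"),
             sigma2_e = getvc("Residual"),
             converged = conv)
  structure(list(blues = blues, vc = vc,
                 H2 = broad_sense_H2(vc),
                 grand_mean = as.numeric(lme4::fixef(fit_r)[1])),
            class = "blue_set")
}

#' Broad-sense heritability from variance components
#'
#' `H2 = sigma2_c / (sigma2_c + sigma2_cl + sigma2_e)`: the clone variance
#' over the sum of clone, clone-by-location and residual variances, on the
#' plot basis (no division by location or replicate counts).
#'
#' @param vc list with `sigma2_c`, `sigma2_cl`, `sigma2_e` (block variance,
#'   if present, does not enter the formula).
#' @return heritability in \[0, 1\].
#' @examples
#' broad_sense_H2(list(sigma2_c = 4.2, sigma2_cl = 2.8, sigma2_e = 3.0)) # 0.42
#' @export
broad_sense_H2 <- function(vc) {
  s <- c(vc$sigma2_c, vc$sigma2_cl %||% 0, vc$sigma2_e)
  if (any(s < 0)) hcn_stop("variance components must be non-negative")
  denom <- sum(s)
  if (denom == 0) hcn_stop("all variance components are zero; H2 undefined")
  vc$sigma2_c / denom
}

#' @export
print.blue_set <- function(x, ...) {
  cat("blue_set:", nrow(x$blues), "clone BLUEs; H2 =", round(x$H2, 3), "\n")
  cat("  variance components: clone", signif(x$vc$sigma2_c, 4),
      "| block", signif(x$vc$sigma2_b, 4),
      "| clone x trial", signif(x$vc$sigma2_cl, 4),
      "| residual", signif(x$vc$sigma2_e, 4), "\n")
  invisible(x)
}

#' Write clone BLUEs to CSV
#' @param blues a `blue_set`.
#' @param path output path.
#' @export
write_blues <- function(blues, path) {
  stopifnot(inherits(blues, "blue_set"))
  write.csv(blues$blues, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
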