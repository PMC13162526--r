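#' Run configuration
#'
#' Bundles the analysis knobs: QC thresholds, MCMC settings, cross-validation
#' layout and the RKHS kernel. Defaults mirror the reported HCN analysis
#' settings (MAF >= 0.05, call rate >= 80%, clone missingness <= 20%,
#' 6000 MCMC iterations with 700 burn-in, residual prior df 5, 5 folds x
#' 5 repeats). `s0 = NULL` requests a data-derived residual prior scale
#' (prior mode `(1 - 0.5) * var(y)`); pass `s0 = 500` to reproduce the
#' reported fixed scale.
#'
#' @param maf_min minimum minor allele frequency to retain a marker.
#' @param call_rate_min minimum marker call rate.
#' @param clone_missing_max maximum clone missing-call fraction (strict >).
#' @param n_iter,burn_in MCMC chain length and burn-in.
#' @param df0 prior degrees of freedom for the residual variance.
#' @param s0 prior scale for the residual variance, or NULL for data-derived.
#' @param k,reps cross-validation folds and repeats.
#' @param seed integer seed driving folds and samplers.
#' @param theta Gaussian-kernel decay rate (> 0).
#' @param distance kernel distance: `"squared_euclidean_mean"` (squared
#'   Euclidean divided by marker count) or `"euclidean"`.
#' @param sim a [sim_config()] block, used by the simulator.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(maf_min = 0.05, call_rate_min = 0.80,
                       clone_missing_max = 0.20,
                       n_iter = 6000, burn_in = 700, df0 = 5, s0 = NULL,
                       k = 5, reps = 5, seed = 1L,
                       theta = 1, distance = c("squared_euclidean_mean", "euclidean"),
                       sim = sim_config()) {
  distance <- match.arg(distance)
  frac <- c(maf_min = maf_min, call_rate_min = call_rate_min,
            clone_missing_max = clone_missing_max)
  if (any(frac < 0 | frac > 1)) hcn_stop("QC thresholds must lie in [0, 1]")
  if (maf_min > 0.5) hcn_stop("maf_min cannot exceed 0.5")
  if (burn_in >= n_iter) hcn_stop("burn_in must be smaller than n_iter")
  if (df0 <= 0 || (!is.null(s0) && s0 <= 0)) hcn_stop("df0 and s0 must be positive")
  if (k < 2) hcn_stop("k must be at least 2")
  if (reps < 1) hcn_stop("reps must be at least 1")
  if (theta <= 0) hcn_stop("theta must be positive")
  structure(list(qc = list(maf_min = maf_min, call_rate_min = call_rate_min,
                           clone_missing_max = clone_missing_max),
                 mcmc = list(n_iter = as.integer(n_iter),
                             burn_in = as.integer(burn_in),
                             df0 = df0, s0 = s0),
                 cv = list(k = as.integer(k), reps = as.integer(reps),
                           seed = as.integer(seed)),
                 rkhs = list(theta = theta, distance = distance),
                 sim = sim),
            class = "run_config")
}

#' Simulation configuration
#'
#' Parameters of the synthetic study population: a modest founder set from
#' which full-sib families (half-sib across shared parents) are gene-dropped,
#' an oligogenic trait with two major QTL (defaults: ~30% of phenotypic
#' variance on chr16 and ~7% on chr14, matching the genetic architecture
#' reported for cassava HCN) plus a small polygenic tail and optional
#' dominance, and a multi-location augmented trial design (29 blocks of 15
#' plots with 2 repeated checks) scored 1-9 with 6 subsamples per plot.
#'
#' @param n_founders number of founder clones.
#' @param n_families number of full-sib families.
#' @param family_size offspring per family.
#' @param n_markers number of SNP markers.
#' @param n_chromosomes chromosomes the markers are spread over (cassava: 18).
#' @param maf_range founder allele-frequency range (uniform draw).
#' @param missing_rate fraction of genotype calls masked as missing.
#' @param qtl_spec data.frame with columns `chrom`, `var_frac`: one major QTL
#'   per row, its target fraction of phenotypic variance.
#' @param polygenic_h2 phenotypic-variance fraction of the polygenic tail.
#' @param dominance_fraction dominance deviation variance at the QTL, as a
#'   fraction of total genetic variance. The default 0.17 is the
#'   non-additive share implied by a broad-sense heritability of 0.42
#'   against a narrow-sense heritability of 0.35 (1 - 0.35/0.42).
#' @param n_locations number of trial locations.
#' @param location_effects location mean shifts around `mu` (recycled or
#'   trimmed to `n_locations`). Defaults echo a low/mid/high site pattern.
#' @param mu grand mean on the 1-9 score scale.
#' @param blocks_per_trial,plots_per_block,checks_per_block augmented design.
#' @param var_clone_location clone x location interaction variance.
#' @param var_block block-within-trial variance.
#' @param var_residual plot residual variance.
#' @param subsample_sd sd of the 6 within-plot subsample readings around the
#'   latent plot value (free parameter; no field estimate exists).
#' @param seed integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 12, n_families = 25, family_size = 12,
                       n_markers = 2000, n_chromosomes = 18,
                       maf_range = c(0.1, 0.5), missing_rate = 0.02,
                       qtl_spec = data.frame(chrom = c("chr14", "chr16"),
                                             var_frac = c(0.07, 0.30)),
                       polygenic_h2 = 0.03, dominance_fraction = 0.17,
                       n_locations = 3,
                       location_effects = c(-0.8, 0.3, 0.5),
                       mu = 6.1,
                       blocks_per_trial = 29, plots_per_block = 15,
                       checks_per_block = 2,
                       var_clone_location = 0.15, var_block = 0.10,
                       var_residual = 0.40, subsample_sd = 0.5,
                       seed = 1L) {
  if (n_founders < 2) hcn_stop("n_founders must be at least 2")
  stopifnot(is.data.frame(qtl_spec), all(c("chrom", "var_frac") %in% names(qtl_spec)))
  fr <- c(missing_rate, polygenic_h2, dominance_fraction, qtl_spec$var_frac)
  if (any(fr < 0 | fr > 1)) hcn_stop("all variance fractions and rates must lie in [0, 1]")
  if (sum(qtl_spec$var_frac) + polygenic_h2 > 1)
    hcn_stop("QTL variance fractions plus polygenic_h2 exceed 1")
  if (any(maf_range < 0 | maf_range > 0.5) || maf_range[1] > maf_range[2])
    hcn_stop("maf_range must be an increasing pair within [0, 0.5]")
  if (checks_per_block >= plots_per_block)
    hcn_stop("checks_per_block must be smaller than plots_per_block")
  structure(list(n_founders = as.integer(n_founders),
                 n_families = as.integer(n_families),
                 family_size = as.integer(family_size),
                 n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 maf_range = maf_range, missing_rate = missing_rate,
                 qtl_spec = qtl_spec, polygenic_h2 = polygenic_h2,
                 dominance_fraction = dominance_fraction,
                 n_locations = as.integer(n_locations),
                 location_effects = rep_len(location_effects, n_locations),
                 mu = mu,
                 blocks_per_trial = as.integer(blocks_per_trial),
                 plots_per_block = as.integer(plots_per_block),
                 checks_per_block = as.integer(checks_per_block),
                 var_clone_location = var_clone_location,
                 var_block = var_block, var_residual = var_residual,
                 subsample_sd = subsample_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a run configuration from YAML
#'
#' Flat sections mirroring [run_config()] (`qc`, `mcmc`, `cv`, `rkhs`,
#' `sim`). Unknown keys are errors so typos are caught rather than ignored.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- list(qc = c("maf_min", "call_rate_min", "clone_missing_max"),
                mcmc = c("n_iter", "burn_in", "df0", "s0"),
                cv = c("k", "reps", "seed"),
                rkhs = c("theta", "distance"),
                sim = names(formals(sim_config)))
  bad_sections <- setdiff(names(raw), names(known))
  if (length(bad_sections))
    hcn_stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  for (s in names(raw)) {
    bad <- setdiff(names(raw[[s]]), known[[s]])
    if (length(bad))
      hcn_stop("unknown key(s) in section '", s, "': ", paste(bad, collapse = ", "))
  }
  args <- c(raw$qc, raw$mcmc, raw$cv, raw$rkhs)
  if (!is.null(raw$sim)) {
    if (!is.null(raw$sim$qtl_spec)) raw$sim$qtl_spec <- as.data.frame(raw$sim$qtl_spec)
    if (!is.null(raw$sim$maf_range)) raw$sim$maf_range <- as.numeric(raw$sim$maf_range)
    args$sim <- do.call(sim_config, raw$sim)
  }
  do.call(run_config, args)
}
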