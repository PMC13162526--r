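#' Simulate family-structured genotypes by gene dropping
#'
#' Founders are drawn marker-by-marker with allele frequencies uniform in
#' `maf_range` under linkage equilibrium. Full-sib families are produced by
#' gene dropping: each parent transmits one of its two alleles per marker,
#' markers independent. Families sharing a parent are half-sib. Missing
#' calls are masked uniformly at `missing_rate` on the offspring table.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (default `cfg$seed`).
#' @return list with `geno` (offspring [genotype_table()]), `pedigree`
#'   (data.frame `clone_id`, `sire`, `dam`, `family`), and `founders`
#'   (founder [genotype_table()], no missingness).
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_founders < 2) hcn_stop("n_founders must be at least 2")
  set.seed(seed)
  m <- cfg$n_markers
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  marker_ids <- sprintf("S%04d", seq_len(m))
  chrom <- paste0("chr", rep_len(seq_len(cfg$n_chromosomes), m))
  meta <- data.frame(marker_id = marker_ids, chrom = chrom,
                     pos = as.integer(10000 * seq_len(m)),
                     stringsAsFactors = FALSE)

  nf <- cfg$n_founders
  # two haplotypes per founder
  hapA <- matrix(rbinom(nf * m, 1, rep(p, each = nf)), nrow = nf)
  hapB <- matrix(rbinom(nf * m, 1, rep(p, each = nf)), nrow = nf)
  founder_ids <- sprintf("F%03d", seq_len(nf))
  founders <- hapA + hapB
  dimnames(founders) <- list(founder_ids, marker_ids)

  sires <- integer(cfg$n_families)
  dams <- integer(cfg$n_families)
  for (f in seq_len(cfg$n_families)) {
    pair <- sample.int(nf, 2, replace = FALSE)
    sires[f] <- pair[1]; dams[f] <- pair[2]
  }

  n_off <- cfg$n_families * cfg$family_size
  off <- matrix(0L, nrow = n_off, ncol = m)
  clone_ids <- character(n_off)
  fam_of <- integer(n_off)
  row <- 0L
  for (f in seq_len(cfg$n_families)) {
    s <- sires[f]; d <- dams[f]
    for (k in seq_len(cfg$family_size)) {
      row <- row + 1L
      from_sire <- ifelse(runif(m) < 0.5, hapA[s, ], hapB[s, ])
      from_dam <- ifelse(runif(m) < 0.5, hapA[d, ], hapB[d, ])
      off[row, ] <- from_sire + from_dam
      clone_ids[row] <- sprintf("C%04d", row)
      fam_of[row] <- f
    }
  }
  dimnames(off) <- list(clone_ids, marker_ids)
  off_num <- off * 1.0
  if (cfg$missing_rate > 0) {
    mask <- runif(length(off_num)) < cfg$missing_rate
    off_num[mask] <- NA_real_
  }
  pedigree <- data.frame(clone_id = clone_ids,
                         sire = founder_ids[sires[fam_of]],
                         dam = founder_ids[dams[fam_of]],
                         family = fam_of, stringsAsFactors = FALSE)
  list(geno = genotype_table(off_num, marker_meta = meta),
       pedigree = pedigree,
       founders = genotype_table(founders * 1.0, marker_meta = meta))
}

#' Simulate an oligogenic trait on a genotype table
#'
#' One QTL per `qtl_spec` row is chosen as the highest-MAF marker on the
#' target chromosome (deterministic given the table). Additive QTL effects
#' are scaled so each realized variance fraction matches its target exactly
#' in the sample, on a scale where total phenotypic variance is 1. The
#' polygenic tail is a sum of small Gaussian effects over the remaining
#' markers scaled to `polygenic_h2`; an optional dominance deviation at the
#' QTL (heterozygosity coding, residualized on dosage) is scaled to
#' `dominance_fraction` of the total genetic variance. True breeding values
#' are the additive genetic values.
#'
#' @param geno a [genotype_table()] (missing calls are mean-imputed
#'   internally before computing genetic values).
#' @param cfg a [sim_config()].
#' @param seed integer seed (default `cfg$seed`).
#' @return list of class `sim_truth`: `tbv` (named additive values),
#'   `genetic_values` (additive + dominance), `qtl` (data.frame with
#'   marker, chromosome, effect, target and realized variance fraction),
#'   `variances` (additive, dominance, residual fractions of unit
#'   phenotypic variance), `polygenic_effects`.
#' @export
simulate_trait <- function(geno, cfg, seed = cfg$seed) {
  stopifnot(inherits(geno, "genotype_table"), inherits(cfg, "sim_config"))
  set.seed(derive_seed(seed, 101))
  M <- geno$dosage
  # mean-impute residual missing calls for value computation
  if (anyNA(M)) {
    mu_j <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu_j[idx[, 2]]
  }
  n <- nrow(M)
  meta <- geno$marker_meta
  if (is.null(meta)) hcn_stop("marker metadata (chromosomes) required to place QTL")
  p <- colMeans(M) / 2
  maf <- pmin(p, 1 - p)

  qtl_ids <- character(nrow(cfg$qtl_spec))
  qtl_eff <- numeric(nrow(cfg$qtl_spec))
  qtl_comp <- matrix(0, n, nrow(cfg$qtl_spec))
  add <- rep(0, n)
  for (q in seq_len(nrow(cfg$qtl_spec))) {
    on_chr <- which(meta$chrom == cfg$qtl_spec$chrom[q])
    if (!length(on_chr))
      hcn_stop("no markers on chromosome ", cfg$qtl_spec$chrom[q])
    j <- on_chr[which.max(maf[on_chr])]
    z <- M[, j] - mean(M[, j])
    if (sd(z) == 0)
      hcn_stop("chromosome ", cfg$qtl_spec$chrom[q],
               " is monomorphic; requested QTL variance unattainable")
    beta <- sqrt(cfg$qtl_spec$var_frac[q]) / sd(z)
    qtl_ids[q] <- geno$marker_ids[j]
    qtl_eff[q] <- beta
    qtl_comp[, q] <- beta * z
    add <- add + beta * z
  }

  poly_idx <- setdiff(seq_len(ncol(M)), match(qtl_ids, geno$marker_ids))
  poly_eff <- rep(0, ncol(M))
  if (cfg$polygenic_h2 > 0 && length(poly_idx)) {
    alpha <- rnorm(length(poly_idx))
    Zp <- scale(M[, poly_idx, drop = FALSE], center = TRUE, scale = FALSE)
    g_poly <- drop(Zp %*% alpha)
    # family structure correlates background markers with the QTL; project
    # the tail onto the QTL-orthogonal complement so variance fractions add
    if (length(qtl_ids))
      g_poly <- stats::lm.fit(cbind(1, qtl_comp), g_poly)$residuals
    s <- sd(g_poly)
    if (s == 0) hcn_stop("polygenic background markers are monomorphic")
    poly_eff[poly_idx] <- alpha * sqrt(cfg$polygenic_h2) / s
    add <- add + g_poly * sqrt(cfg$polygenic_h2) / s
  }

  dom <- rep(0, n)
  if (cfg$dominance_fraction > 0) {
    for (q in seq_along(qtl_ids)) {
      j <- match(qtl_ids[q], geno$marker_ids)
      h <- as.numeric(abs(M[, j] - 1) < 0.5)      # heterozygote indicator
      z <- M[, j] - mean(M[, j])
      h_res <- h - mean(h) - z * (sum((h - mean(h)) * z) / sum(z^2))
      dom <- dom + h_res
    }
    if (sd(dom) > 0) {
      f <- cfg$dominance_fraction
      target <- f / (1 - f) * var(add)           # fraction of total genetic var
      dom <- dom * sqrt(target) / sd(dom)
    }
  }

  realized <- vapply(seq_along(qtl_ids), function(q) {
    j <- match(qtl_ids[q], geno$marker_ids)
    var(qtl_eff[q] * (M[, j] - mean(M[, j])))
  }, numeric(1))

  structure(list(
    tbv = setNames(add, geno$clone_ids),
    genetic_values = setNames(add + dom, geno$clone_ids),
    qtl = data.frame(marker_id = qtl_ids, chrom = cfg$qtl_spec$chrom,
                     effect = qtl_eff,
                     var_frac_target = cfg$qtl_spec$var_frac,
                     var_frac_realized = realized, stringsAsFactors = FALSE),
    variances = c(additive = var(add), dominance = var(dom),
                  residual = max(0, 1 - var(add) - var(dom))),
    polygenic_effects = setNames(poly_eff, geno$marker_ids)),
    class = "sim_truth")
}

#' Simulate clone-level phenotypes at a stated heritability
#'
#' Adds Gaussian noise to the simulated genetic values so that total
#' phenotypic variance is 1 and the genetic fraction equals the simulated
#' one (QTL fractions + polygenic tail + dominance). This is the clone-mean
#' analogue of a BLUE vector and the response used in the parameter-recovery
#' and model-comparison experiments.
#'
#' @param truth a `sim_truth` from [simulate_trait()].
#' @param seed integer seed.
#' @param mu grand mean added to all values.
#' @return named numeric vector of clone phenotypes.
#' @export
simulate_clone_values <- function(truth, seed, mu = 0) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(derive_seed(seed, 202))
  g <- truth$genetic_values
  ve <- truth$variances[["residual"]]
  mu + g + rnorm(length(g), 0, sqrt(ve))
}

#' Simulate multi-location augmented trials with ordinal scoring
#'
#' Clones are laid out in an augmented design per location: each block holds
#' `checks_per_block` repeated check clones plus unreplicated test entries;
#' every test clone appears once per location. The latent plot value is
#' grand mean + location effect + genetic value + block effect + clone x
#' location effect + plot residual; six subsample scores per plot add
#' subsample noise and are mapped to the 1-9 scale by rounding to the
#' nearest integer (half-integer cut points) and clamping.
#'
#' @param truth a `sim_truth` from [simulate_trait()].
#' @param cfg a [sim_config()].
#' @param seed integer seed (default `cfg$seed`).
#' @return A [phenotype_set()].
#' @export
simulate_trials <- function(truth, cfg, seed = cfg$seed) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  set.seed(derive_seed(seed, 303))
  clones <- names(truth$genetic_values)
  n <- length(clones)
  checks <- clones[seq_len(cfg$checks_per_block)]
  tests <- setdiff(clones, checks)
  per_block <- cfg$plots_per_block - cfg$checks_per_block
  capacity <- per_block * cfg$blocks_per_trial
  if (length(tests) > capacity)
    hcn_stop("design error: ", length(tests), " test clones exceed trial capacity ",
             capacity, " (", cfg$blocks_per_trial, " blocks x ", per_block,
             " test plots)")
  n_blocks <- ceiling(length(tests) / per_block)

  rows <- vector("list", cfg$n_locations)
  for (L in seq_len(cfg$n_locations)) {
    loc <- paste0("LOC", L)
    loc_eff <- cfg$location_effects[L]
    cl_loc <- setNames(rnorm(n, 0, sqrt(cfg$var_clone_location)), clones)
    order_tests <- sample(tests)
    block_of <- rep(seq_len(n_blocks), each = per_block)[seq_along(order_tests)]
    block_eff <- rnorm(n_blocks, 0, sqrt(cfg$var_block))
    plot_clone <- c(order_tests, rep(checks, n_blocks))
    plot_block <- c(block_of, rep(seq_len(n_blocks), each = cfg$checks_per_block))
    is_check <- c(rep(FALSE, length(order_tests)),
                  rep(TRUE, n_blocks * cfg$checks_per_block))
    latent <- cfg$mu + loc_eff + truth$genetic_values[plot_clone] +
      block_eff[plot_block] + cl_loc[plot_clone] +
      rnorm(length(plot_clone), 0, sqrt(cfg$var_residual))
    scores <- matrix(rnorm(6 * length(latent), mean = rep(latent, each = 6),
                           sd = cfg$subsample_sd),
                     ncol = 6, byrow = TRUE)
    scores <- pmax(pmin(round(scores), 9), 1)
    df <- data.frame(clone_id = plot_clone, location = loc, year = 2020L,
                     block_id = paste0(loc, "_B", sprintf("%02d", plot_block)),
                     is_check = is_check, stringsAsFactors = FALSE)
    colnames(scores) <- paste0("score_", 1:6)
    rows[[L]] <- cbind(df, scores)
  }
  phenotype_set(do.call(rbind, rows))
}

#' Simulate a complete study data set
#'
#' Convenience wrapper: gene-dropped genotypes, oligogenic trait, and
#' multi-location ordinal trial phenotypes from one [sim_config()].
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (default `cfg$seed`).
#' @return list with `geno`, `pheno`, `truth`, `pedigree`, `founders`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = cfg$seed) {
  gen <- simulate_genotypes(cfg, seed = seed)
  truth <- simulate_trait(gen$geno, cfg, seed = seed)
  pheno <- simulate_trials(truth, cfg, seed = seed)
  list(geno = gen$geno, pheno = pheno, truth = truth,
       pedigree = gen$pedigree, founders = gen$founders)
}
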