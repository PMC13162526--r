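# Shared fixtures, built in code and cached per test run.

toy_geno <- function() {
  genotype_table(matrix(c(0, 1, 2,
                          2, NA, 0,
                          1, 1, 1),
                        nrow = 3, byrow = FALSE,
                        dimnames = list(c("cloneA", "cloneB", "cloneC"),
                                        c("m1", "m2", "m3"))))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# mid-sized family-structured data set reused across GRM/model tests
family_sim <- function() {
  cached("family_sim", {
    cfg <- sim_config(n_founders = 12, n_families = 10, family_size = 10,
                      n_markers = 2000, missing_rate = 0, seed = 42)
    sim <- simulate_genotypes(cfg)
    sim$cfg <- cfg
    sim
  })
}

# clone-level phenotypes on a polygenic architecture at a given h2
polygenic_trait <- function(h2, n_markers = 2000, n_families = 25,
                            family_size = 12, seed = 1) {
  cfg <- sim_config(n_founders = 12, n_families = n_families,
                    family_size = family_size, n_markers = n_markers,
                    qtl_spec = data.frame(chrom = character(0),
                                          var_frac = numeric(0)),
                    polygenic_h2 = h2, dominance_fraction = 0,
                    missing_rate = 0, seed = seed)
  gen <- simulate_genotypes(cfg)
  truth <- simulate_trait(gen$geno, cfg)
  y <- simulate_clone_values(truth, seed = derive_seed_t(seed))
  list(geno = gen$geno, truth = truth, y = y)
}

derive_seed_t <- function(seed) as.integer((seed * 131 + 7) %% .Machine$integer.max)

# iid Hardy-Weinberg panel (no family structure)
hwe_geno <- function(n = 200, m = 3000, seed = 9) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), nrow = n,
              dimnames = list(sprintf("i%03d", seq_len(n)),
                              sprintf("s%04d", seq_len(m))))
  genotype_table(d * 1.0)
}
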