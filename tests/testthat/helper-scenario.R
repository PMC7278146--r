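# Shared synthetic scenario, built once per test run and memoised.
.scenario_cache <- new.env(parent = emptyenv())

# Medium pooled experiment reused across test files: 30 individuals,
# 4000 SNPs, depth 50, no true effects unless asked otherwise.
shared_scenario <- function(key = "null", ...) {
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  args <- switch(key,
    null = list(n_individuals = 30, n_snps = 4000, qtl_fraction = 0, seed = 11),
    effects = list(n_individuals = 30, n_snps = 4000, qtl_fraction = 0.05,
                   mean_depth = 100, seed = 12),
    ...
  )
  cfg <- do.call(sim_config, args)
  geno <- simulate_genotypes(cfg)
  truth <- simulate_truth(geno, cfg,
                          effect_magnitude = if (key == "effects") log(2) else NULL)
  counts <- simulate_pool_counts(geno, truth, cfg)
  out <- list(cfg = cfg, geno = geno, truth = truth, counts = counts)
  .scenario_cache[[key]] <- out
  out
}

# Independent simplex-constrained least-squares oracle: plain projected
# gradient with a bisection-based simplex projection (different algorithm
# from the package's sort-based projection and accelerated solver).
oracle_simplex_ls <- function(G, f, w, iters = 200000, tol = 1e-14) {
  proj_bisect <- function(v) {
    f_tau <- function(tau) sum(pmax(v - tau, 0)) - 1
    lo <- min(v) - 1
    hi <- max(v)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f_tau(mid) > 0) lo <- mid else hi <- mid
    }
    pmax(v - (lo + hi) / 2, 0)
  }
  H <- crossprod(G * w, G)
  cvec <- crossprod(G, w * f)
  L <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  x <- rep(1 / ncol(G), ncol(G))
  for (k in seq_len(iters)) {
    x_new <- proj_bisect(as.vector(x - (H %*% x - cvec) / L))
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

# Closed-form two-sided mid-p exact binomial, written out independently of
# the package internals, for oracle checks.
oracle_midp <- function(x, n, p) {
  lower <- pbinom(x - 1, n, p) + dbinom(x, n, p) / 2
  upper <- 1 - pbinom(x, n, p) + dbinom(x, n, p) / 2
  pmin(1, 2 * pmin(lower, upper))
}
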