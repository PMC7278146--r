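# The statistical core: simplex-constrained proportion regression,
# pre-frequency prediction, and the exact frequency-shift test.

test_that("a single individual always gets proportion 1", {
  g <- structure(list(
    variants = data.frame(chrom = "chr1", pos = 1:3, id = c("a", "b", "c"),
                          ref = "A", alt = "G"),
    dosage = matrix(c(0, 0.5, 1), 3, 1, dimnames = list(c("a", "b", "c"), "ind1")),
    haplotypes = matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 3, 2,
                        dimnames = list(c("a", "b", "c"), NULL))
  ), class = "pool_genotypes")
  counts <- data.frame(id = c("a", "b", "c"), ref_count = c(30, 10, 0),
                       alt_count = c(0, 20, 30))
  fit <- estimate_pool_proportions(g, counts)
  expect_equal(unname(fit$proportions), 1)
})

test_that("noiseless frequencies are interpolated exactly", {
  set.seed(41)
  n_ind <- 3
  n_snp <- 200
  dos <- matrix(sample(c(0, 0.5, 1), n_snp * n_ind, TRUE), n_snp, n_ind)
  rownames(dos) <- sprintf("s%03d", seq_len(n_snp))
  colnames(dos) <- paste0("ind", 1:3)
  g <- structure(list(
    variants = data.frame(chrom = "chr1", pos = seq_len(n_snp),
                          id = rownames(dos), ref = "A", alt = "G"),
    dosage = dos, haplotypes = matrix(0L, n_snp, 6)
  ), class = "pool_genotypes")
  pi_true <- c(0.5, 0.3, 0.2)
  f <- as.vector(dos %*% pi_true)
  depth <- 1000L
  counts <- data.frame(id = rownames(dos),
                       ref_count = round(depth * (1 - f)),
                       alt_count = round(depth * f))
  fit <- estimate_pool_proportions(g, counts)
  expect_lt(max(abs(fit$proportions - pi_true)), 1e-6)
  expect_lt(fit$residual_norm, 1e-4)
})

test_that("the solver matches an independent projected-gradient oracle", {
  for (seed in c(1, 2, 3)) {
    cfg <- sim_config(n_individuals = 25, n_snps = 2500, qtl_fraction = 0,
                      seed = seed)
    g <- simulate_genotypes(cfg)
    tr <- simulate_truth(g, cfg)
    counts <- simulate_pool_counts(g, tr, cfg)
    fit <- estimate_pool_proportions(g, counts)
    use <- counts$depth >= 20
    G <- g$dosage[counts$id[use], ]
    f <- (counts$alt_count / counts$depth)[use]
    w <- (counts$depth / mean(counts$depth[use]))[use]
    oracle <- oracle_simplex_ls(G, f, w)
    expect_lt(max(abs(fit$proportions - oracle)), 1e-6)
    expect_gt(cor(fit$proportions, tr$true_proportions), 0.8)
  }
})

test_that("degenerate regressions are reported", {
  sc <- shared_scenario("null")
  few <- sc$counts[1:10, ]
  expect_error(estimate_pool_proportions(sc$geno, few),
               "underdetermined", class = "poolqtl_validation_error")
  g2 <- sc$geno
  g2$dosage[, 2] <- g2$dosage[, 1]  # duplicate individuals
  expect_warning(estimate_pool_proportions(g2, sc$counts), "identical genotype")
})

test_that("pre-frequency prediction is the proportion-weighted dosage mean", {
  sc <- shared_scenario("null")
  pre <- predict_pre_frequencies(sc$geno, sc$truth$true_proportions)
  expect_equal(unname(pre),
               as.vector(sc$geno$dosage %*% sc$truth$true_proportions),
               tolerance = 1e-12)
  # all-heterozygous SNP predicts 0.5 under any proportions
  g <- sc$geno
  g$dosage[1, ] <- 0.5
  expect_equal(unname(predict_pre_frequencies(g, sc$truth$true_proportions)[1]), 0.5)
  # uniform proportions over dosages (0, 1) give 0.5
  g$dosage[2, ] <- rep(c(0, 1), length.out = ncol(g$dosage))
  unif <- rep(1 / ncol(g$dosage), ncol(g$dosage))
  expect_equal(unname(predict_pre_frequencies(g, unif)[2]), 0.5)
  expect_error(predict_pre_frequencies(g, unif * 2),
               class = "poolqtl_validation_error")
})

test_that("the doubled-tail p-value has its closed form and the center is null", {
  counts <- data.frame(id = c("a", "b"), ref_count = c(0L, 10L),
                       alt_count = c(20L, 10L), depth = c(20L, 20L))
  pre <- c(a = 0.5, b = 0.5)
  rec <- test_frequency_shift(counts, pre, method = "tail")
  expect_equal(rec$p_value[1], 2 * 0.5^20, tolerance = 1e-12)
  expect_gt(rec$p_value[2], 0.8)  # alt = depth * pre sits at the null center
  expect_equal(rec$z[2], 0)
  # monomorphic and shallow SNPs are excluded with a message
  counts2 <- rbind(counts, data.frame(id = "c", ref_count = 5L, alt_count = 5L,
                                      depth = 10L))
  expect_message(test_frequency_shift(counts2, c(pre, c = 0), method = "tail"),
                 "excluded 1")
})

test_that("mid-p values match the independent closed form on random counts", {
  set.seed(8)
  n <- 500
  depth <- rpois(n, 60) + 20L
  pre <- runif(n, 0.05, 0.95)
  alt <- rbinom(n, depth, pre)
  counts <- data.frame(id = sprintf("s%03d", 1:n), ref_count = depth - alt,
                       alt_count = alt, depth = depth)
  rec <- test_frequency_shift(counts, setNames(pre, counts$id))
  expect_equal(rec$p_value, oracle_midp(alt, depth, pre), tolerance = 1e-12)
})

test_that("null p-values are calibrated and approximately uniform", {
  sc <- shared_scenario("null")
  pre <- predict_pre_frequencies(sc$geno, sc$truth$true_proportions)
  rec <- suppressMessages(test_frequency_shift(sc$counts, pre))
  n <- nrow(rec)
  for (alpha in c(0.05, 0.01)) {
    expect_lt(abs(mean(rec$p_value < alpha) - alpha),
              3 * sqrt(alpha * (1 - alpha) / n))
  }
  expect_gt(suppressWarnings(stats::ks.test(rec$p_value, "punif"))$p.value, 0.01)
})

test_that("detection power rises with effect size and depth", {
  cfg_base <- sim_config(n_individuals = 30, n_snps = 1500, qtl_fraction = 1,
                         seed = 77)
  power_at <- function(beta, depth) {
    cfg <- sim_config(n_individuals = 30, n_snps = 1500, qtl_fraction = 1,
                      mean_depth = depth, seed = 77)
    g <- simulate_genotypes(cfg)
    tr <- simulate_truth(g, cfg, effect_magnitude = beta)
    counts <- simulate_pool_counts(g, tr, cfg)
    pre <- predict_pre_frequencies(g, tr$true_proportions)
    rec <- suppressMessages(test_frequency_shift(counts, pre))
    mean(rec$p_value < 1e-3)
  }
  p_small <- power_at(log(1.3), 50)
  p_mid <- power_at(log(2), 50)
  p_big <- power_at(log(4), 50)
  expect_true(p_small <= p_mid && p_mid <= p_big)
  expect_gt(power_at(log(2), 200), p_mid)
})

test_that("call_qtls handles degenerate cutoffs and sorts by p", {
  rec <- data.frame(id = letters[1:4], p_value = c(0.5, 1e-4, 0.02, 1e-6))
  expect_equal(nrow(call_qtls(rec, 1.1)), 4L)
  expect_equal(nrow(call_qtls(rec, 0)), 0L)
  expect_equal(call_qtls(rec, 0.01)$id, c("d", "b"))
})

test_that("cutoff optimization maximizes fold enrichment against a reference", {
  set.seed(55)
  p <- c(runif(300, 0, 1e-3), runif(4000))
  in_ref <- c(runif(300) < 0.5, runif(4000) < 0.02)
  grid <- 10^-(1:5)
  res <- optimize_cutoff(p, in_ref, grid)
  # brute-force scan oracle
  bg <- mean(in_ref[p > 0.5])
  fold <- vapply(grid, function(cc) mean(in_ref[p < cc]) / bg, numeric(1))
  expect_equal(res$cutoff, min(grid[fold == max(fold, na.rm = TRUE)]))
  # reference equal to the p < 1e-3 call set: fold maximal at 1e-3
  res2 <- optimize_cutoff(p, p < 1e-3, grid)
  expect_equal(res2$profile$fold[res2$profile$cutoff == 1e-3],
               max(res2$profile$fold, na.rm = TRUE))
  expect_true(res2$background_floored)
  # random reference: fold flat around 1 wherever enough SNPs are selected
  res3 <- optimize_cutoff(p, runif(length(p)) < 0.3, grid)
  stable <- res3$profile$n_selected >= 100
  expect_lt(max(abs(res3$profile$fold[stable] - 1), na.rm = TRUE), 0.35)
  expect_error(optimize_cutoff(rep(1e-4, 10), rep(TRUE, 10), grid),
               class = "poolqtl_validation_error")
})

test_that("proportion recovery improves as the SNP count doubles", {
  rmse_at <- function(n_snps) {
    cfg <- sim_config(n_individuals = 20, n_snps = n_snps, qtl_fraction = 0,
                      seed = 19)
    g <- simulate_genotypes(cfg)
    tr <- simulate_truth(g, cfg)
    counts <- simulate_pool_counts(g, tr, cfg)
    fit <- estimate_pool_proportions(g, counts)
    sqrt(mean((fit$proportions - tr$true_proportions)^2))
  }
  expect_lt(rmse_at(4000), rmse_at(2000))
})
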