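# The statistical core: pool-proportion deconvolution, pre-assay frequency
# prediction, and the per-SNP frequency-shift test.
#
# Model.  The pooled library mixes individuals j = 1..J with unknown
# proportions pi_j >= 0, sum pi = 1.  At SNP i with dosage fractions g_ij,
# the expected pre-assay pooled alternative-allele frequency is
# f_pre(i) = sum_j pi_j g_ij.  A cis-acting variant multiplies the allelic
# odds in the assayed material, so the post-assay frequency departs from
# f_pre.  pi is estimated by depth-weighted least squares of the observed
# post-assay frequencies on the genotype matrix, constrained to the
# probability simplex; because genome-wide (trans) differences between
# individuals inflate pre- and post-assay frequencies alike, the regression
# absorbs them and the per-SNP test isolates cis effects.

# Euclidean projection onto the probability simplex (sort-based algorithm).
.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  pmax(v + (1 - css[rho]) / rho, 0)
}

#' Estimate pool proportions from post-assay allele frequencies
#'
#' Solves the simplex-constrained weighted least-squares problem
#' `min_pi sum_i w_i (f_post(i) - g_i . pi)^2` with `pi >= 0`,
#' `sum(pi) = 1` and weights `w_i` proportional to read depth (the variance
#' of `f_post` scales as `1/depth`).  The solver is an accelerated projected
#' gradient (FISTA with restart) on the precomputed normal equations, run to
#' a tight fixed-point tolerance; the problem is strongly convex whenever the
#' genotype columns are linearly independent, so the minimizer is unique.
#'
#' @param genotypes a [`pool_genotypes`][simulate_genotypes] object.
#' @param counts data.frame (id, ref_count, alt_count\[, depth\]).
#' @param min_depth SNPs below this depth are excluded from the regression.
#' @param max_iter,tol iteration cap and fixed-point tolerance.
#' @return object of class `"pool_proportions"`: `proportions` (named,
#'   nonnegative, unit sum), `residual_norm`, `n_snps_used`, `iterations`,
#'   `converged`.
#' @export
estimate_pool_proportions <- function(genotypes, counts, min_depth = 20L,
                                      max_iter = 50000L, tol = 1e-13) {
  G_all <- genotypes$dosage
  n_ind <- ncol(G_all)
  if (!"depth" %in% names(counts)) counts$depth <- counts$ref_count + counts$alt_count
  counts <- counts[counts$depth >= min_depth & counts$id %in% rownames(G_all), , drop = FALSE]
  if (n_ind == 1L)
    return(structure(list(proportions = setNames(1, colnames(G_all)),
                          residual_norm = NA_real_, n_snps_used = nrow(counts),
                          iterations = 0L, converged = TRUE),
                     class = "pool_proportions"))
  if (nrow(counts) < n_ind)
    .validation_error("underdetermined: %d usable SNPs for %d individuals",
                      nrow(counts), n_ind)
  G <- G_all[counts$id, , drop = FALSE]
  if (anyDuplicated(t(G)))
    warning("identical genotype columns: proportions for those individuals ",
            "are identifiable only in sum")
  f <- counts$alt_count / counts$depth
  w <- counts$depth / mean(counts$depth)
  H <- crossprod(G * w, G)        # t(G) %*% diag(w) %*% G
  cvec <- crossprod(G, w * f)
  L <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  x <- rep(1 / n_ind, n_ind)
  y <- x
  tk <- 1
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    grad <- H %*% y - cvec
    x_new <- .project_simplex(as.vector(y - grad / L))
    if (sum((x_new - x) * (y - x_new)) > 0) {  # restart on non-monotone step
      y <- x_new
      tk <- 1
    } else {
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      y <- x_new + (tk - 1) / t_new * (x_new - x)
      tk <- t_new
    }
    if (max(abs(x_new - x)) < tol) { x <- x_new; converged <- TRUE; break }
    x <- x_new
  }
  resid <- sqrt(sum(w * (f - as.vector(G %*% x))^2))
  structure(list(proportions = setNames(as.vector(x), colnames(G_all)),
                 residual_norm = resid, n_snps_used = nrow(counts),
                 iterations = iter, converged = converged),
            class = "pool_proportions")
}

#' @export
print.pool_proportions <- function(x, ...) {
  cat(sprintf("pool_proportions over %d individuals (from %d SNPs)\n",
              length(x$proportions), x$n_snps_used))
  cat(sprintf("  range %.4f .. %.4f, residual norm %.4f\n",
              min(x$proportions), max(x$proportions), x$residual_norm))
  invisible(x)
}

#' Predict pre-assay allele frequencies from genotypes and proportions
#'
#' `f_pre(i) = sum_j pi_j g_ij`; exactly 0 or 1 for pool-monomorphic SNPs.
#'
#' @inheritParams estimate_pool_proportions
#' @param proportions a `"pool_proportions"` object or bare numeric vector on
#'   the simplex.
#' @return named numeric vector of frequencies per SNP.
#' @export
predict_pre_frequencies <- function(genotypes, proportions) {
  pi_hat <- if (inherits(proportions, "pool_proportions")) proportions$proportions
            else proportions
  if (any(pi_hat < 0) || abs(sum(pi_hat) - 1) > 1e-9)
    .validation_error("proportions must be nonnegative and sum to 1")
  pre <- as.vector(genotypes$dosage %*% pi_hat)
  # clamp numerical dust so monomorphic SNPs are exactly 0/1
  pre[pre < 0] <- 0
  pre[pre > 1] <- 1
  setNames(pre, rownames(genotypes$dosage))
}

# Two-sided exact binomial p-values, vectorized.
# method "midp": p = min(1, 2*min(P(X < x) + P(X = x)/2, P(X > x) + P(X = x)/2)).
# The mid-p correction removes the systematic conservativeness of doubling
# discrete tails, giving near-nominal type-I error and near-uniform null
# p-values once depth and frequency vary across SNPs.
# method "tail": classical doubled tail, p = min(1, 2*min(P(X <= x), P(X >= x))).
.binom_two_sided <- function(x, n, p, method = c("midp", "tail")) {
  method <- match.arg(method)
  lo <- pbinom(x, n, p)
  hi <- pbinom(x - 1, n, p, lower.tail = FALSE)
  if (method == "midp") {
    mass <- dbinom(x, n, p)
    pmin(1, 2 * pmin(lo - mass / 2, hi - mass / 2))
  } else {
    pmin(1, 2 * pmin(lo, hi))
  }
}

#' Test each SNP for a cis-acting allele-frequency shift
#'
#' Compares the observed post-assay alternative-allele count with
#' Binomial(depth, f_pre) by a two-sided exact binomial test (mid-p by
#' default; see Details).  SNPs that are monomorphic in the pool
#' (`pre_freq` 0 or 1) or below `min_depth` are excluded, with a message.
#' The standardized shift `z = (post - pre) / sqrt(pre (1 - pre) / depth)`
#' is reported for ranking and plotting; inference uses the exact test only.
#'
#' @details With discrete counts, doubling the exact tail probabilities
#' (`method = "tail"`) is strictly conservative at every depth, which breaks
#' type-I-error calibration.  The default `method = "midp"` halves the
#' probability of the observed count in each tail, the standard correction
#' for discrete tests; its null distribution is close to uniform when depth
#' and pre-frequency vary across SNPs.
#'
#' @param counts data.frame (id, ref_count, alt_count\[, depth\]).
#' @param pre_freq named vector of predicted pre-assay frequencies (from
#'   [predict_pre_frequencies()]); matched to `counts` by `id`.
#' @param min_depth minimum depth for a SNP to be tested.
#' @param method `"midp"` (default) or `"tail"`.
#' @return data.frame of frequency records: id, depth, alt_count, post_freq,
#'   pre_freq, z, p_value; attribute `n_excluded` counts dropped SNPs.
#' @export
test_frequency_shift <- function(counts, pre_freq, min_depth = 20L,
                                 method = c("midp", "tail")) {
  method <- match.arg(method)
  if (!"depth" %in% names(counts)) counts$depth <- counts$ref_count + counts$alt_count
  pre <- pre_freq[counts$id]
  usable <- !is.na(pre) & pre > 0 & pre < 1 & counts$depth >= min_depth
  n_excl <- sum(!usable)
  if (n_excl > 0)
    message(sprintf("test_frequency_shift: excluded %d SNPs (monomorphic, shallow or unmatched)",
                    n_excl))
  counts <- counts[usable, , drop = FALSE]
  pre <- as.numeric(pre[usable])
  post <- counts$alt_count / counts$depth
  z <- (post - pre) / sqrt(pre * (1 - pre) / counts$depth)
  p <- .binom_two_sided(counts$alt_count, counts$depth, pre, method)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  out <- data.frame(id = counts$id, depth = counts$depth,
                    alt_count = counts$alt_count, post_freq = post,
                    pre_freq = pre, z = z, p_value = p,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Select significant QTLs at a p-value cutoff
#'
#' @param records frequency-record data.frame from [test_frequency_shift()].
#' @param p_cutoff significance cutoff (default 1e-3, the fold-enrichment
#'   optimum of the pooled design; see [optimize_cutoff()]).
#' @return the significant records, sorted by increasing p-value.
#' @export
call_qtls <- function(records, p_cutoff = 1e-3) {
  out <- records[records$p_value < p_cutoff, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Choose the p-value cutoff by fold enrichment against a reference set
#'
#' For each candidate cutoff `c`, computes
#' `fold(c) = P(reference | p < c) / P(reference | p > 0.5)`: how much more
#' often SNPs called at `c` fall in a previously reported QTL set than
#' clearly-null SNPs do.  Returns the cutoff maximizing the fold, ties broken
#' toward the smaller cutoff.
#'
#' @param p_values numeric vector of per-SNP p-values.
#' @param in_reference logical vector: is each SNP in the reference QTL set?
#' @param candidate_cutoffs cutoff grid (default `10^-(1:6)`).
#' @return list(`cutoff`, `profile` = data.frame(cutoff, n_selected, fold)).
#' @export
optimize_cutoff <- function(p_values, in_reference,
                            candidate_cutoffs = 10^-(1:6)) {
  stopifnot(length(p_values) == length(in_reference),
            length(candidate_cutoffs) > 0)
  bg <- p_values > 0.5
  if (!any(bg)) .validation_error("no SNPs with p > 0.5: background rate undefined")
  bg_rate <- mean(in_reference[bg])
  bg_floored <- bg_rate == 0
  if (bg_floored) bg_rate <- 1 / (sum(bg) + 1)  # no background overlap at all
  fold <- vapply(candidate_cutoffs, function(cc) {
    sel <- p_values < cc
    if (!any(sel)) return(NA_real_)
    mean(in_reference[sel]) / bg_rate
  }, numeric(1))
  n_sel <- vapply(candidate_cutoffs, function(cc) sum(p_values < cc), integer(1))
  profile <- data.frame(cutoff = candidate_cutoffs, n_selected = n_sel, fold = fold)
  ok <- which(!is.na(fold))
  if (length(ok) == 0) .validation_error("no candidate cutoff selects any SNP")
  best <- ok[fold[ok] == max(fold[ok])]
  list(cutoff = min(candidate_cutoffs[best]), profile = profile,
       background_floored = bg_floored)
}

#' One-call pooled QTL mapping
#'
#' Runs the full statistical pipeline: estimate pool proportions, predict
#' pre-assay frequencies, and test every SNP for a frequency shift.
#'
#' @inheritParams estimate_pool_proportions
#' @inheritParams test_frequency_shift
#' @param phenotype_class label stored with the records (e.g. `"binding"`,
#'   `"accessibility"`, `"looping"`).
#' @return frequency-record data.frame with variant columns merged in and a
#'   `proportions` attribute holding the [estimate_pool_proportions()] fit.
#' @export
map_pool_qtls <- function(genotypes, counts, min_depth = 20L,
                          phenotype_class = "binding",
                          method = c("midp", "tail")) {
  fit <- estimate_pool_proportions(genotypes, counts, min_depth = min_depth)
  pre <- predict_pre_frequencies(genotypes, fit)
  rec <- test_frequency_shift(counts, pre, min_depth = min_depth, method = method)
  rec <- merge(genotypes$variants, rec, by = "id", sort = FALSE)
  rec$phenotype_class <- phenotype_class
  rec <- rec[order(match(rec$id, genotypes$variants$id)), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "proportions") <- fit
  rec
}
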