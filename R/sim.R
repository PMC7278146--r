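#' Configuration for a synthetic pooled-assay experiment
#'
#' Bundles and validates every knob of the synthetic-data generator.  The
#' defaults mirror the pooled design at desk scale: 65 cell lines pooled into
#' one library, 20,000 biallelic SNPs at ~50x pooled depth, unequal pool
#' proportions drawn from a symmetric Dirichlet, and a 5% fraction of SNPs
#' carrying a multiplicative cis-acting allelic effect.
#'
#' @param n_individuals number of diploid individuals in the pool.
#' @param n_snps number of biallelic SNPs.
#' @param maf_range length-2 numeric in (0, 0.5]; minor-allele frequencies are
#'   drawn uniformly from this interval.
#' @param ld_block_size SNPs per linkage block.  Haplotype alleles are copied
#'   along a block with a small per-SNP flip probability (`ld_flip_prob`), so
#'   adjacent SNPs within a block are in strong LD; blocks are independent.
#'   `ld_block_size = 1` gives independent SNPs.  A trailing partial block is
#'   allowed.
#' @param ld_flip_prob per-SNP allele flip probability along a block; smaller
#'   values give tighter LD.
#' @param dirichlet_alpha concentration of the symmetric Dirichlet from which
#'   pool proportions are drawn.  5 gives realistic spread (a few-fold range
#'   between best- and worst-represented lines).
#' @param qtl_fraction fraction of SNPs with a true cis-effect.
#' @param effect_size_sd standard deviation of the true log allelic
#'   fold-change at effect SNPs.
#' @param mean_depth expected read depth per SNP (Poisson).
#' @param ref_bias probability that a reference-allele locus is unaffected by
#'   the biased toy aligner; at a fraction `1 - ref_bias` of SNP loci the
#'   alternative-allele context is duplicated elsewhere in the toy genome, so
#'   alt-carrying reads multimap and are lost unless the swap filter removes
#'   the locus (see [make_toy_genome()]).
#' @param n_loops number of chromatin loops to simulate.
#' @param anchor_width loop anchor width in bp (the loop-call bin resolution).
#' @param seed integer seed; every `simulate_*` call derives its own stream
#'   from it, so regeneration is bit-identical.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 65, n_snps = 20000,
                       maf_range = c(0.05, 0.5), ld_block_size = 10,
                       ld_flip_prob = 0.05, dirichlet_alpha = 5,
                       qtl_fraction = 0.05, effect_size_sd = log(2),
                       mean_depth = 50, ref_bias = 0.7, n_loops = 200,
                       anchor_width = 5000, seed = 1L) {
  for (nm in c("n_individuals", "n_snps", "ld_block_size", "n_loops", "anchor_width"))
    if (!.is_count(get(nm))) .validation_error("%s must be a positive integer", nm)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    .validation_error("maf_range must be an ordered pair within (0, 0.5]")
  if (!.is_prob(qtl_fraction)) .validation_error("qtl_fraction must be in [0, 1]")
  if (!(ref_bias > 0 && ref_bias <= 1)) .validation_error("ref_bias must be in (0, 1]")
  if (dirichlet_alpha <= 0) .validation_error("dirichlet_alpha must be positive")
  if (effect_size_sd < 0) .validation_error("effect_size_sd must be nonnegative")
  if (mean_depth <= 0) .validation_error("mean_depth must be positive")
  if (!.is_prob(ld_flip_prob)) .validation_error("ld_flip_prob must be in [0, 1]")
  if (length(seed) != 1L || !is.finite(seed)) .validation_error("seed must be a single integer")
  structure(list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range), ld_block_size = as.integer(ld_block_size),
    ld_flip_prob = ld_flip_prob, dirichlet_alpha = dirichlet_alpha,
    qtl_fraction = qtl_fraction, effect_size_sd = effect_size_sd,
    mean_depth = mean_depth, ref_bias = ref_bias, n_loops = as.integer(n_loops),
    anchor_width = as.integer(anchor_width), seed = as.integer(seed)
  ), class = "sim_config")
}

# Independent seed stream per generator stage so each simulate_* call is
# reproducible on its own.  Offsets stay far below 2^31.
.set_stage_seed <- function(config, offset) set.seed(config$seed * 101L + offset)

#' Apply a multiplicative allelic fold-change to a frequency
#'
#' The cis-effect model acts on the allelic odds:
#' `f' = f exp(b) / (f exp(b) + 1 - f)`.  It is symmetric in the alleles,
#' keeps frequencies in `[0, 1]`, and leaves pool-monomorphic frequencies
#' (0 or 1) fixed regardless of `beta`.
#'
#' @param f pre-effect allele frequency (vector).
#' @param beta log allelic fold-change (vector, recycled).
#' @return shifted frequencies.
#' @export
shift_frequency <- function(f, beta) {
  out <- f * exp(beta) / (f * exp(beta) + 1 - f)
  out[f == 0] <- 0
  out[f == 1] <- 1
  out
}

#' Simulate phased diploid genotypes with block LD structure
#'
#' Draws a per-SNP minor-allele frequency uniformly within
#' `config$maf_range`, then generates `2 * n_individuals` haplotypes.  Within
#' an LD block each haplotype copies its allele from the previous SNP,
#' flipping with probability `ld_flip_prob`, which yields high r-squared
#' between adjacent SNPs; the first SNP of each block is drawn independently
#' at its MAF, so blocks are unlinked.  The two haplotypes of an individual
#' are independent, so genotypes are in Hardy-Weinberg equilibrium.
#'
#' @param config a [sim_config()].
#' @return An object of class `"pool_genotypes"`: a list with `variants`
#'   (data.frame: chrom, pos, id, ref, alt), `dosage` (n_snps x n_individuals
#'   matrix of alternative-allele dosage fractions in 0/0.5/1) and
#'   `haplotypes` (n_snps x 2*n_individuals 0/1 matrix; columns `j*2-1, j*2`
#'   belong to individual `j`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .set_stage_seed(config, 0L)
  n <- config$n_snps
  h <- 2L * config$n_individuals
  maf <- runif(n, config$maf_range[1], config$maf_range[2])
  block <- (seq_len(n) - 1L) %/% config$ld_block_size
  hap <- matrix(0L, nrow = n, ncol = h)
  for (i in seq_len(n)) {
    if (i == 1L || block[i] != block[i - 1L]) {
      hap[i, ] <- as.integer(runif(h) < maf[i])
    } else {
      flip <- runif(h) < config$ld_flip_prob
      hap[i, ] <- ifelse(flip, 1L - hap[i - 1L, ], hap[i - 1L, ])
    }
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  variants <- data.frame(
    chrom = "chr1", pos = seq_len(n) * 500L,
    id = sprintf("snp%06d", seq_len(n)), ref = ref, alt = unname(alt),
    stringsAsFactors = FALSE
  )
  dosage <- (hap[, seq(1L, h, by = 2L), drop = FALSE] +
               hap[, seq(2L, h, by = 2L), drop = FALSE]) / 2
  rownames(dosage) <- rownames(hap) <- variants$id
  colnames(dosage) <- sprintf("ind%03d", seq_len(config$n_individuals))
  colnames(hap) <- paste0(rep(colnames(dosage), each = 2L), c("_h1", "_h2"))
  structure(list(variants = variants, dosage = dosage, haplotypes = hap),
            class = "pool_genotypes")
}

#' @export
print.pool_genotypes <- function(x, ...) {
  cat(sprintf("pool_genotypes: %d SNPs x %d individuals (phased)\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Simulate the hidden truth of a pooled experiment
#'
#' Draws the pool-proportion vector from a symmetric Dirichlet
#' (`dirichlet_alpha`), assigns a true log allelic fold-change to a random
#' `qtl_fraction` of SNPs (exactly 0 elsewhere), and records the expected
#' pooled pre-assay alternative-allele frequency of every SNP, the
#' proportion-weighted mean of the individual dosages.
#'
#' @param genotypes a [`pool_genotypes`][simulate_genotypes] object.
#' @param config the matching [sim_config()].
#' @param effect_magnitude if non-`NULL`, effect SNPs get `|beta|` equal to
#'   this value with random sign instead of `rnorm(0, effect_size_sd)` draws.
#' @return A list of class `"sim_truth"`: `true_proportions` (unit-sum,
#'   nonnegative), `true_effects` (per-SNP beta, named by SNP id),
#'   `true_pre_freqs` (per-SNP pooled frequency), `qtl_ids`.
#' @export
simulate_truth <- function(genotypes, config, effect_magnitude = NULL) {
  stopifnot(inherits(genotypes, "pool_genotypes"), inherits(config, "sim_config"))
  .set_stage_seed(config, 1L)
  g <- rgamma(config$n_individuals, shape = config$dirichlet_alpha, rate = 1)
  pi_true <- g / sum(g)
  n <- nrow(genotypes$dosage)
  beta <- numeric(n)
  n_qtl <- round(config$qtl_fraction * n)
  qtl_idx <- sort(sample.int(n, n_qtl))
  if (n_qtl > 0) {
    beta[qtl_idx] <- if (is.null(effect_magnitude)) {
      rnorm(n_qtl, 0, config$effect_size_sd)
    } else {
      effect_magnitude * sample(c(-1, 1), n_qtl, replace = TRUE)
    }
  }
  names(beta) <- genotypes$variants$id
  pre <- as.vector(genotypes$dosage %*% pi_true)
  names(pre) <- genotypes$variants$id
  structure(list(
    true_proportions = setNames(pi_true, colnames(genotypes$dosage)),
    true_effects = beta, true_pre_freqs = pre,
    qtl_ids = genotypes$variants$id[qtl_idx]
  ), class = "sim_truth")
}

#' Simulate post-assay pooled allele counts
#'
#' Per SNP the expected pre-assay frequency `f_pre` is shifted by the SNP's
#' true effect via [shift_frequency()]; read depth is Poisson(`mean_depth`)
#' and the alternative-allele count is Binomial(depth, f_post).  SNPs that
#' are monomorphic in the pool keep `f_post = f_pre` whatever their beta.
#'
#' @inheritParams simulate_truth
#' @param truth a [`sim_truth`][simulate_truth] object.
#' @return data.frame (id, ref_count, alt_count, depth) with one row per SNP.
#' @export
simulate_pool_counts <- function(genotypes, truth, config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(truth$true_effects) != nrow(genotypes$dosage))
    .validation_error("truth and genotypes describe different SNP sets")
  .set_stage_seed(config, 2L)
  f_post <- shift_frequency(truth$true_pre_freqs, truth$true_effects)
  depth <- rpois(length(f_post), config$mean_depth)
  alt <- rbinom(length(f_post), depth, f_post)
  data.frame(id = genotypes$variants$id, ref_count = depth - alt,
             alt_count = alt, depth = depth, stringsAsFactors = FALSE)
}

#' Simulate a chromatin loop set
#'
#' Places `n_loops` loops on the simulated chromosome with `anchor_width`-bp
#' anchors and log-normal contact intensities (median ~100 contacts/loop),
#' separated by 20-200 kb.  Anchors never overlap within a loop.
#'
#' @inheritParams simulate_truth
#' @param intensity_meanlog,intensity_sdlog log-normal parameters of expected
#'   contacts per loop.
#' @return data.frame in BEDPE column order (chrom1, start1, end1, chrom2,
#'   start2, end2, name, score) with an extra `intensity` column; coordinates
#'   0-based half-open.
#' @export
simulate_loops <- function(genotypes, config, intensity_meanlog = log(100),
                           intensity_sdlog = 0.5) {
  .set_stage_seed(config, 3L)
  span <- max(genotypes$variants$pos)
  w <- config$anchor_width
  s1 <- sort(sample.int(max(span - 250000L - 2L * w, w), config$n_loops, replace = TRUE))
  gap <- sample(20000:200000, config$n_loops, replace = TRUE)
  s2 <- s1 + w + gap
  data.frame(
    chrom1 = "chr1", start1 = s1, end1 = s1 + w,
    chrom2 = "chr1", start2 = s2, end2 = s2 + w,
    name = sprintf("loop%04d", seq_len(config$n_loops)),
    score = 0,
    intensity = exp(rnorm(config$n_loops, intensity_meanlog, intensity_sdlog)),
    stringsAsFactors = FALSE
  )
}

#' Simulate allele-tagged Hi-C contact pairs over loops
#'
#' Each loop produces Poisson(`intensity`) contact pairs with ends uniform in
#' its two anchors.  If at least one SNP lies inside either anchor, one such
#' SNP is chosen as the loop's tag SNP and every contact is tagged with a
#' ref/alt allele drawn at the SNP's pooled frequency, shifted by the SNP's
#' true looping effect through [shift_frequency()].  Loops without an anchor
#' SNP yield untagged contacts (`snp_id`/`allele` `NA`), which downstream
#' counting drops.
#'
#' @inheritParams simulate_pool_counts
#' @param loops a loop data.frame as from [simulate_loops()].
#' @return data.frame (chromA, posA, chromB, posB, snp_id, allele, loop)
#'   with 1-based contact end positions.
#' @export
simulate_allelic_contacts <- function(genotypes, truth, loops, config) {
  if (nrow(loops) == 0L) .validation_error("loops must be non-empty")
  if (any(loops$chrom1 == loops$chrom2 & loops$end1 > loops$start2))
    .validation_error("loop anchors must not overlap within a loop")
  .set_stage_seed(config, 4L)
  v <- genotypes$variants
  out <- vector("list", nrow(loops))
  for (k in seq_len(nrow(loops))) {
    n_c <- rpois(1L, loops$intensity[k])
    if (n_c == 0L) next
    posA <- loops$start1[k] + sample.int(loops$end1[k] - loops$start1[k], n_c, replace = TRUE)
    posB <- loops$start2[k] + sample.int(loops$end2[k] - loops$start2[k], n_c, replace = TRUE)
    in_anchor <- v$chrom == loops$chrom1[k] &
      ((v$pos > loops$start1[k] & v$pos <= loops$end1[k]) |
         (v$pos > loops$start2[k] & v$pos <= loops$end2[k]))
    snp_ids <- v$id[in_anchor]
    if (length(snp_ids) == 0L) {
      snp <- NA_character_; allele <- rep(NA_character_, n_c)
    } else {
      snp <- if (length(snp_ids) == 1L) snp_ids else sample(snp_ids, 1L)
      f <- shift_frequency(truth$true_pre_freqs[[snp]], truth$true_effects[[snp]])
      allele <- ifelse(runif(n_c) < f, "alt", "ref")
    }
    out[[k]] <- data.frame(
      chromA = loops$chrom1[k], posA = posA, chromB = loops$chrom2[k],
      posB = posB, snp_id = snp, allele = allele, loop = loops$name[k],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Simulate a trait-labelled GWAS lead-SNP catalog
#'
#' Builds one or more "target" traits whose lead SNPs are planted near true
#' QTL positions, plus background traits with uniformly placed leads.  For a
#' target trait a fraction `enrich_fraction` of its leads is placed within
#' `enrich_distance` bp of a randomly chosen QTL; the remainder (and all
#' background leads) are uniform over `[1, genome_length]`.  Per-trait lead
#' counts are drawn log-normally (median `lead_count_median`), mimicking the
#' wide spread of association counts across real catalog traits.
#'
#' @param qtl_positions integer vector of true QTL positions (1-based).
#' @param config a [sim_config()] (only `seed` is used).
#' @param genome_length chromosome length in bp.
#' @param n_background number of background traits.
#' @param enrich_fraction fraction of target leads planted near QTLs; must be
#'   in `[0, 1]`.
#' @param enrich_distance max planting distance in bp.
#' @param target_traits character vector of target trait names.
#' @param lead_count_median,lead_count_sdlog log-normal lead-count parameters.
#' @return data.frame (trait, chrom, pos, id, is_target).
#' @export
simulate_lead_snp_catalog <- function(qtl_positions, config, genome_length,
                                      n_background = 27L, enrich_fraction = 0.5,
                                      enrich_distance = 500L,
                                      target_traits = "target_trait",
                                      lead_count_median = 100,
                                      lead_count_sdlog = 0.6) {
  if (enrich_fraction > 1 || enrich_fraction < 0)
    .validation_error("enrich_fraction must be in [0, 1]")
  if (length(target_traits) < 1L || n_background < 1L)
    .validation_error("need at least one target and one background trait")
  if (length(qtl_positions) == 0L) .validation_error("qtl_positions is empty")
  .set_stage_seed(config, 5L)
  traits <- c(target_traits, sprintf("background_%02d", seq_len(n_background)))
  is_target <- c(rep(TRUE, length(target_traits)), rep(FALSE, n_background))
  rows <- vector("list", length(traits))
  for (t in seq_along(traits)) {
    n_lead <- max(20L, round(exp(rnorm(1, log(lead_count_median), lead_count_sdlog))))
    pos <- sample.int(genome_length, n_lead, replace = TRUE)
    if (is_target[t]) {
      n_pl <- round(enrich_fraction * n_lead)
      if (n_pl > 0) {
        anchor <- sample(qtl_positions, n_pl, replace = TRUE)
        off <- if (enrich_distance > 0)
          sample.int(2L * enrich_distance + 1L, n_pl, replace = TRUE) - enrich_distance - 1L
        else rep(0L, n_pl)
        pos[seq_len(n_pl)] <- pmin(pmax(anchor + off, 1L), genome_length)
      }
    }
    rows[[t]] <- data.frame(
      trait = traits[t], chrom = "chr1", pos = pos,
      id = sprintf("%s_lead%04d", gsub("[^A-Za-z0-9]", "_", traits[t]), seq_len(n_lead)),
      is_target = is_target[t], stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
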