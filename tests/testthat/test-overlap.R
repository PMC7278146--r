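# QTL-set overlap, directional concordance, density profiles and anchor
# signal comparisons.

mk_set <- function(pos, chrom = "chr1", ref = "A", alt = "G") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

test_that("exact overlap handles disjoint, identical and partial sets", {
  a <- mk_set(1:10)
  b <- mk_set(11:20)
  rep1 <- exact_overlap(list(A = a, B = b))
  expect_equal(unname(rep1$intersections["A&B"]), 0L)
  rep2 <- exact_overlap(list(A = a, B = a))
  expect_equal(unname(rep2$intersections["A&B"]), 10L)
  c3 <- mk_set(5:14)
  rep3 <- exact_overlap(list(A = a, B = b, C = c3))
  expect_equal(unname(rep3$intersections[c("A&B", "A&C", "B&C", "A&B&C")]),
               c(0L, 6L, 4L, 0L))
  # inclusion-exclusion consistency
  expect_true(all(rep3$intersections["A&B&C"] <= rep3$intersections[c("A&B", "A&C", "B&C")]))
  expect_true(all(rep3$intersections[c("A&B", "A&C", "B&C")] <= max(rep3$sizes)))
  expect_message(exact_overlap(list(A = rbind(a, a[1, ]), B = b)), "deduplicated")
})

test_that("variant identity uses alleles unless disabled", {
  a <- mk_set(1:5, alt = "G")
  b <- mk_set(1:5, alt = "T")
  expect_equal(unname(exact_overlap(list(A = a, B = b))$intersections["A&B"]), 0L)
  expect_equal(unname(exact_overlap(list(A = a, B = b),
                                    use_alleles = FALSE)$intersections["A&B"]), 5L)
})

test_that("LD overlap finds proxies and collapses to exact matching without them", {
  sc <- shared_scenario("null")
  g <- sc$geno
  v <- g$variants
  # adjacent SNPs within an LD block are strong proxies
  block_pairs <- data.frame(a = v$id[seq(1, 1000, 10)], b = v$id[seq(2, 1001, 10)])
  r2 <- r2_phased(g$haplotypes, block_pairs$a, block_pairs$b)
  strong <- head(which(!is.na(r2) & r2 > 0.8), 10)
  expect_gte(length(strong), 5)
  setA <- v[match(block_pairs$a[strong], v$id), c("chrom", "pos", "ref", "alt")]
  setB <- v[match(block_pairs$b[strong], v$id), c("chrom", "pos", "ref", "alt")]
  ex <- exact_overlap(list(A = setA, B = setB))
  ld <- ld_overlap(list(A = setA, B = setB), g, r2_threshold = 0.8)
  expect_equal(unname(ex$intersections["A&B"]), 0L)
  expect_equal(unname(ld$counts["A", "B"]), length(strong))
  # an unreachable threshold reduces LD overlap to exact overlap
  ld1 <- ld_overlap(list(A = setA, B = setB), g, r2_threshold = 1.0)
  expect_equal(unname(ld1$counts["A", "B"]),
               unname(ex$intersections["A&B"]))
  # monotonicity: LD overlap >= exact overlap
  expect_gte(unname(ld$counts["A", "B"]), unname(ex$intersections["A&B"]))
})

test_that("LD overlap counts equal manual enumeration on hand-built haplotypes", {
  hap <- rbind(
    q1 = c(0L, 0L, 1L, 1L, 0L, 1L),
    q2 = c(1L, 0L, 1L, 0L, 0L, 1L),
    l1 = c(0L, 0L, 1L, 1L, 0L, 1L),   # identical to q1 -> r2 = 1
    l2 = c(0L, 1L, 1L, 0L, 1L, 0L)    # weakly related to both q1 and q2
  )
  g <- structure(list(
    variants = data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                          id = rownames(hap), ref = "A", alt = "G",
                          stringsAsFactors = FALSE),
    dosage = matrix(0.5, 4, 3, dimnames = list(rownames(hap), NULL)),
    haplotypes = hap
  ), class = "pool_genotypes")
  A <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "G")
  B <- data.frame(chrom = "chr1", pos = c(300L, 400L), ref = "A", alt = "G")
  ld <- ld_overlap(list(A = A, B = B), g, r2_threshold = 0.8, max_distance = 1e5)
  expect_equal(unname(ld$counts["A", "B"]), 1L)  # only q1 via proxy l1
  expect_equal(unname(ld$counts["B", "A"]), 1L)
})

test_that("directional concordance detects a shared causal direction", {
  mk_q <- function(pos, up) data.frame(chrom = "chr1", pos = pos, ref = "A",
                                       alt = "G", pre_freq = 0.5,
                                       post_freq = ifelse(up, 0.7, 0.3))
  up <- c(rep(TRUE, 15), rep(FALSE, 15))
  conc <- directional_concordance(mk_q(1:30, up), mk_q(1:30, up))
  expect_equal(conc$n_concordant, 30L)
  expect_equal(sum(conc$table) - sum(diag(conc$table)), 0L)  # off-diagonal zeros
  expect_lt(conc$p_value, 1e-4)
  # random favored alleles: no association
  set.seed(91)
  conc2 <- directional_concordance(mk_q(1:200, runif(200) < 0.5),
                                   mk_q(1:200, runif(200) < 0.5))
  expect_gt(conc2$p_value, 0.001)
  empty <- directional_concordance(mk_q(1:3, TRUE), mk_q(11:13, TRUE))
  expect_true(is.na(empty$p_value))
})

test_that("density profile equals a brute-force distance histogram and is translation invariant", {
  set.seed(93)
  features <- data.frame(chrom = "chr1", start = seq(0L, 90000L, 10000L),
                         end = seq(1000L, 91000L, 10000L))
  centers <- floor((features$start + features$end) / 2) + 1L
  qtls <- data.frame(chrom = "chr1", pos = sample.int(95000L, 300))
  prof <- density_profile(qtls, features, window = 2000, nbins = 20)
  # brute force
  d <- vapply(qtls$pos, function(p) {
    dd <- p - centers
    dd[which.min(abs(dd))]
  }, numeric(1))
  d <- d[abs(d) <= 2000]
  brute <- hist(d, breaks = prof$breaks, plot = FALSE)$counts / length(d)
  expect_equal(prof$density, brute)
  shifted <- density_profile(
    transform(qtls, pos = pos + 55000L),
    transform(features, start = start + 55000L, end = end + 55000L),
    window = 2000, nbins = 20)
  expect_equal(shifted$density, prof$density)
  expect_error(density_profile(qtls, features[0, ], window = 2000),
               class = "poolqtl_validation_error")
})

test_that("QTLs at feature centers give a central spike with high enrichment", {
  features <- data.frame(chrom = "chr1", start = seq(0L, 90000L, 10000L),
                         end = seq(1000L, 91000L, 10000L))
  centers <- floor((features$start + features$end) / 2) + 1L
  qtls <- data.frame(chrom = "chr1", pos = rep(centers, 4))
  set.seed(94)
  nonsig <- data.frame(chrom = "chr1", pos = sample.int(95000L, 2000))
  prof <- density_profile(qtls, features, window = 5000, nbins = 50,
                          nonsig_qtls = nonsig)
  expect_gt(prof$ratio, 2)
  expect_lt(prof$p_value, 1e-6)
  central_bin <- which.min(abs(prof$mids))
  expect_equal(sum(prof$density), 1)
  expect_gt(prof$density[central_bin], 0.9)
})

test_that("anchor signal means equal direct interval-intersection sums", {
  loops_a <- data.frame(chrom1 = "chr1", start1 = 0L, end1 = 1000L,
                        chrom2 = "chr1", start2 = 5000L, end2 = 6000L)
  loops_b <- data.frame(chrom1 = "chr1", start1 = 20000L, end1 = 21000L,
                        chrom2 = "chr1", start2 = 30000L, end2 = 31000L)
  signal <- data.frame(chrom = "chr1",
                       start = c(500L, 5200L, 20500L),
                       end = c(800L, 5700L, 20800L),
                       score = c(2, 4, 1))
  res <- anchor_signal_comparison(loops_a, loops_b, signal)
  expect_equal(res$mean_a, (300 * 2 + 500 * 4) / 2000)
  expect_equal(res$mean_b, (300 * 1) / 2000)
  # doubled signal on one group is detected with enough loops
  many_a <- do.call(rbind, replicate(12, loops_a, simplify = FALSE))
  many_a$start1 <- many_a$start1 + (0:11) * 100000L
  many_a$end1 <- many_a$end1 + (0:11) * 100000L
  many_a$start2 <- many_a$start2 + (0:11) * 100000L
  many_a$end2 <- many_a$end2 + (0:11) * 100000L
  many_b <- transform(many_a, start1 = start1 + 5e7, end1 = end1 + 5e7,
                      start2 = start2 + 5e7, end2 = end2 + 5e7)
  base_score <- seq(0.5, 3, length.out = 12)
  sig_a <- data.frame(chrom = "chr1", start = many_a$start1, end = many_a$end1,
                      score = 2 * base_score)
  sig_b <- data.frame(chrom = "chr1", start = many_b$start1, end = many_b$end1,
                      score = base_score)
  res2 <- anchor_signal_comparison(many_a, many_b, rbind(sig_a, sig_b))
  expect_lt(res2$p_value, 0.05)
  # identically distributed signal on both groups: null
  sig_b_same <- transform(sig_b, score = 2 * base_score)
  res3 <- anchor_signal_comparison(many_a, many_b, rbind(sig_a, sig_b_same))
  expect_gt(res3$p_value, 0.4)
})
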