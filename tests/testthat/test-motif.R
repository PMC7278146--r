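# PWM scanning and the two motif-enrichment designs.

rand_seq <- function(n, len = 101, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
         character(1))
}

plant <- function(windows, consensus, rate, seed = 2) {
  set.seed(seed)
  hit <- runif(length(windows)) < rate
  for (i in which(hit)) {
    off <- sample.int(nchar(windows[i]) - nchar(consensus) + 1L, 1L)
    substr(windows[i], off, off + nchar(consensus) - 1L) <- consensus
  }
  windows
}

test_that("the consensus scores the analytic maximum, on both strands", {
  pwm <- pwm_from_consensus("ACGTTGCA")
  hit <- scan_pwm("ACGTTGCA", pwm)
  expect_equal(hit$score, pwm$max_score, tolerance = 1e-12)
  expect_equal(hit$score, sum(log2(apply(pwm$probs, 2, max) / 0.25)),
               tolerance = 1e-12)
  expect_true(hit$hit)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ACGTTGCA")))
  hit_rc <- scan_pwm(rc, pwm)
  expect_equal(hit_rc$score, hit$score, tolerance = 1e-12)
  expect_equal(hit_rc$strand, "-")
})

test_that("scanning a sequence and its reverse complement gives equal best scores", {
  pwm <- pwm_from_consensus("TTGACGTC")
  seqs <- rand_seq(20, len = 60, seed = 5)
  for (s in seqs[1:5]) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(scan_pwm(s, pwm)$score, scan_pwm(rc, pwm)$score, tolerance = 1e-12)
  }
})

test_that("scores equal hand-summed log-odds at every offset of a toy PWM", {
  counts <- matrix(c(8, 1, 1, 0,
                     0, 9, 1, 0,
                     2, 2, 3, 3,
                     0, 0, 0, 10,
                     5, 5, 0, 0), nrow = 4)
  pwm <- make_pwm(counts, "toy")
  s <- "GACTTACGTA"
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  hand_best <- -Inf
  for (off in 1:(nchar(s) - 5 + 1)) {
    sc <- sum(vapply(1:5, function(j) pwm$log_odds[codes[off + j - 1], j], numeric(1)))
    hand_best <- max(hand_best, sc)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  codes_rc <- match(strsplit(rc, "")[[1]], c("A", "C", "G", "T"))
  for (off in 1:(nchar(s) - 5 + 1)) {
    sc <- sum(vapply(1:5, function(j) pwm$log_odds[codes_rc[off + j - 1], j], numeric(1)))
    hand_best <- max(hand_best, sc)
  }
  expect_equal(scan_pwm(s, pwm)$score, hand_best, tolerance = 1e-12)
  # shorter than the motif: no hit
  expect_false(scan_pwm("ACG", pwm)$hit)
  # N bases score as background (log-odds 0)
  expect_equal(scan_pwm("NNNNN", pwm, both_strands = FALSE)$score, 0)
})

test_that("JASPAR pfm and MEME minimal files parse to column-normalized PWMs", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TOY1",
               "A [ 3 10  0  2 ]",
               "C [ 5  0  2  1 ]",
               "G [ 1  0  8  1 ]",
               "T [ 1  0  0  6 ]",
               ">MA0002.1 TOY2",
               "2 0 0 9",
               "2 9 0 0",
               "3 0 9 0",
               "3 1 1 1"), f)
  lib <- read_jaspar_pfm(f)
  expect_length(lib, 2L)
  expect_true(all(abs(colSums(lib[["MA0001.1_TOY1"]]$probs) - 1) < 1e-6))
  expect_equal(ncol(lib[["MA0002.1_TOY2"]]$probs), 4L)

  m <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF TOY3", "letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0",
               " 0.7 0.1 0.1 0.1",
               " 0.1 0.7 0.1 0.1",
               " 0.1 0.1 0.7 0.1",
               " 0.1 0.1 0.1 0.7"), m)
  lib2 <- read_meme_minimal(m)
  expect_equal(names(lib2), "TOY3")
  expect_equal(unname(lib2$TOY3$probs["A", 1]), 0.7, tolerance = 0.01)
})

test_that("identical window sets give fold 1 everywhere and no significance", {
  w <- rand_seq(100, seed = 7)
  lib <- list(M1 = pwm_from_consensus("ACGTACGTA"), M2 = pwm_from_consensus("TTTTGGGG"))
  res <- motif_enrichment(w, w, lib)
  expect_true(all(res$fold == 1))
  expect_false(any(res$significant))
})

test_that("a planted consensus is recovered with closed-form binomial p-values", {
  consensus <- "TGACGTCATT"
  lib <- list(planted = pwm_from_consensus(consensus),
              decoy1 = pwm_from_consensus("ACACACACAC"),
              decoy2 = pwm_from_consensus("GGGTTTAAAC"))
  sig <- plant(rand_seq(400, seed = 11), consensus, 0.3, seed = 12)
  bg <- plant(rand_seq(400, seed = 13), consensus, 0.02, seed = 14)
  res <- motif_enrichment(sig, bg, lib)
  top <- res[1, ]
  expect_equal(top$motif, "planted")
  expect_true(top$significant)
  expect_gt(top$fold, 5)
  # closed-form oracle from the counted hits
  p_oracle <- 1 - pbinom(top$n_hits, 400, top$n_bg_hits / 400) +
    dbinom(top$n_hits, 400, top$n_bg_hits / 400) / 2
  expect_equal(top$p_value, min(1, p_oracle), tolerance = 1e-12)
  expect_false(any(res$significant[res$motif != "planted"]))
})

test_that("allele-specific enrichment is driven only by the center base", {
  # motif whose consensus requires the alt allele at its center position
  flank <- 20L
  motif_len <- 9L
  set.seed(21)
  chrom_seq <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  n_q <- 120
  pos <- seq(100L, 19000L, length.out = n_q)
  consensus <- "TTACGGCAA"  # center (5th) base G
  qtls <- data.frame(chrom = "chr1", pos = as.integer(pos), ref = "A", alt = "G",
                     pre_freq = 0.5, post_freq = 0.8)  # favored allele = alt
  # plant the consensus context around each QTL so that only the center base decides
  genome <- chrom_seq
  for (p in qtls$pos) {
    substr(genome, p - 4L, p + 4L) <- consensus
    substr(genome, p, p) <- "A"  # reference allele breaks the motif
  }
  genome <- setNames(genome, "chr1")
  lib <- list(centerdep = pwm_from_consensus(consensus),
              decoy = pwm_from_consensus("CCCTTTGGA"))
  res <- allele_specific_enrichment(qtls, genome, lib, flank = flank)
  open_row <- res[res$motif == "centerdep" & res$direction == "open_enriched", ]
  closed_row <- res[res$motif == "centerdep" & res$direction == "closed_enriched", ]
  expect_true(open_row$significant)
  expect_gt(open_row$fold, 5)
  expect_false(closed_row$significant)
  # brute-force rescan oracle for the differential counts
  w_open <- extract_allele_windows(genome, qtls, flank, "alt")
  w_closed <- extract_allele_windows(genome, qtls, flank, "ref")
  k_open <- sum(vapply(w_open, function(w) scan_pwm(w, lib$centerdep)$hit, logical(1)))
  k_closed <- sum(vapply(w_closed, function(w) scan_pwm(w, lib$centerdep)$hit, logical(1)))
  expect_equal(open_row$n_hits, k_open)
  expect_equal(open_row$n_bg_hits, k_closed)
  # degenerate input: identical alleles -> all folds exactly 1
  qtls_same <- transform(qtls, alt = ref)
  res_same <- allele_specific_enrichment(qtls_same, genome, lib, flank = flank)
  expect_true(all(res_same$fold == 1))
})
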