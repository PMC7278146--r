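# Reference mapping bias and its removal by allele-swap remapping.
#
# Aligner indices contain only reference alleles, so reads carrying the
# alternative allele at a SNP can fail to map, or map elsewhere, more often
# than reference reads -- inflating reference-allele frequencies.  The filter
# implemented here takes every mapped read that overlaps SNPs, rewrites it
# with every other combination of alleles at those SNPs, remaps the rewritten
# copies, and keeps the read only if all copies map uniquely back to the
# original position.  Loci where one allele misbehaves thus lose *all* their
# reads rather than one allele's worth, which removes the bias.
#
# The aligner is an injected contract (a function from sequence to candidate
# positions); a bundled best-stratum exact/1-mismatch matcher over a toy
# genome makes the filter fully testable without real alignments.

#' Build a toy genome with SNPs and optional planted reference bias
#'
#' Generates a random genome with `n_snps` SNP loci at fixed spacing.  For a
#' fraction `1 - ref_bias` of the loci, the alternative-allele sequence
#' context (wide enough to cover any overlapping read) is copied to the end
#' of the genome as a decoy.  Against the bundled best-stratum aligner,
#' alt-carrying reads at decoyed loci match the decoy exactly (versus one
#' mismatch at the true locus) and are therefore mapped away -- a
#' deterministic reference-favoring aligner in the sense that only
#' reference-carrying reads survive at those loci.
#'
#' @param n_snps number of SNP loci.
#' @param read_length read length the genome is designed for.
#' @param spacing distance between SNPs in bp (>= `read_length` keeps loci
#'   independent).
#' @param ref_bias fraction of loci left unbiased; in (0, 1].
#' @param seed integer seed.
#' @return list of class `"toy_genome"`: `sequence` (character), `variants`
#'   (chrom, pos, id, ref, alt, biased), `read_length`.
#' @export
make_toy_genome <- function(n_snps = 60, read_length = 30, spacing = 150,
                            ref_bias = 0.7, seed = 1L) {
  if (!(ref_bias > 0 && ref_bias <= 1)) .validation_error("ref_bias must be in (0, 1]")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  len <- n_snps * spacing + 2L * read_length
  genome <- sample(bases, len, replace = TRUE)
  pos <- read_length + spacing * (seq_len(n_snps) - 1L) + 1L  # 1-based
  ref <- genome[pos]
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  n_biased <- round((1 - ref_bias) * n_snps)
  biased <- rep(FALSE, n_snps)
  biased[sample.int(n_snps, n_biased)] <- TRUE
  decoys <- character(0)
  pad <- strrep("N", 5L)  # stops reads matching across decoy boundaries
  for (i in which(biased)) {
    win <- genome[(pos[i] - read_length + 1L):(pos[i] + read_length - 1L)]
    win[read_length] <- alt[i]
    decoys <- c(decoys, paste0(pad, paste(win, collapse = "")))
  }
  structure(list(
    sequence = paste0(paste(genome, collapse = ""), paste(decoys, collapse = "")),
    variants = data.frame(chrom = "toy", pos = pos,
                          id = sprintf("tsnp%03d", seq_len(n_snps)),
                          ref = ref, alt = unname(alt), biased = biased,
                          stringsAsFactors = FALSE),
    read_length = read_length
  ), class = "toy_genome")
}

#' Best-stratum exact-match toy aligner
#'
#' Returns an aligner contract: a deterministic function mapping a read
#' sequence to the 0-based genome positions of its best matches (exact
#' matches if any exist, otherwise matches with up to `max_mismatch`
#' mismatches; `N` in the genome never matches).
#'
#' @param genome a character genome sequence or a `"toy_genome"`.
#' @param max_mismatch mismatch tolerance of the fallback stratum.
#' @return function(sequence) -> integer vector of 0-based positions.
#' @export
make_exact_aligner <- function(genome, max_mismatch = 1L) {
  seq <- if (inherits(genome, "toy_genome")) genome$sequence else genome
  subject <- Biostrings::DNAString(seq)
  function(sequence) {
    pat <- Biostrings::DNAString(sequence)
    hits <- Biostrings::matchPattern(pat, subject, max.mismatch = 0)
    if (length(hits) == 0 && max_mismatch > 0)
      hits <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatch)
    as.integer(IRanges::start(hits)) - 1L
  }
}

.substitute_base <- function(sequence, offset0, base) {
  substr(sequence, offset0 + 1L, offset0 + 1L) <- base
  sequence
}

#' Simulate reads over the SNPs of a toy genome
#'
#' For each SNP, `depth` reads overlapping the SNP at uniform offsets are
#' drawn from the genome; each read carries the alternative allele with the
#' SNP's pooled frequency `freqs` (otherwise the reference base already
#' present).  A read is annotated with every SNP it covers.
#'
#' @param toy a [make_toy_genome()] object.
#' @param freqs per-SNP alternative-allele frequencies (recycled).
#' @param depth reads per SNP.
#' @param seed integer seed.
#' @return list of reads; each read is a list with `sequence`, `position`
#'   (0-based) and `snps` (data.frame id, offset, allele, ref, alt).
#' @export
simulate_snp_reads <- function(toy, freqs, depth = 50, seed = 1L) {
  set.seed(seed)
  v <- toy$variants
  rl <- toy$read_length
  freqs <- rep_len(freqs, nrow(v))
  reads <- list()
  for (i in seq_len(nrow(v))) {
    offs <- sample.int(rl, depth, replace = TRUE) - 1L
    is_alt <- runif(depth) < freqs[i]
    for (r in seq_len(depth)) {
      start0 <- v$pos[i] - 1L - offs[r]
      s <- substr(toy$sequence, start0 + 1L, start0 + rl)
      cov <- which(v$pos > start0 & v$pos <= start0 + rl)
      snps <- data.frame(id = v$id[cov], offset = v$pos[cov] - 1L - start0,
                         allele = "ref", ref = v$ref[cov], alt = v$alt[cov],
                         stringsAsFactors = FALSE)
      if (is_alt[r]) {
        k <- which(cov == i)
        snps$allele[k] <- "alt"
        s <- .substitute_base(s, snps$offset[k], snps$alt[k])
      }
      reads[[length(reads) + 1L]] <- list(sequence = s, position = start0, snps = snps)
    }
  }
  reads
}

#' Generate every allele-swapped version of a read
#'
#' For a read covering `k` SNPs, returns the `2^k - 1` reads obtained by
#' flipping the carried allele at every non-empty subset of the covered SNPs
#' (the original combination is excluded).  Swapped reads differ from the
#' original only at SNP offsets.
#'
#' @param read a read as produced by [simulate_snp_reads()].
#' @return list of swapped reads (empty if the read covers no SNP).
#' @export
swap_alleles <- function(read) {
  k <- nrow(read$snps)
  if (is.null(k) || k == 0L) return(list())
  out <- vector("list", 2L^k - 1L)
  n <- 0L
  for (mask in 1:(2L^k - 1L)) {
    flip <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
    s <- read$sequence
    snps <- read$snps
    for (j in which(flip)) {
      snps$allele[j] <- if (snps$allele[j] == "ref") "alt" else "ref"
      s <- .substitute_base(s, snps$offset[j],
                            if (snps$allele[j] == "alt") snps$alt[j] else snps$ref[j])
    }
    n <- n + 1L
    out[[n]] <- list(sequence = s, position = read$position, snps = snps)
  }
  out
}

#' Map reads with an aligner contract
#'
#' Keeps reads whose best alignment stratum is a unique position equal to the
#' read's origin; others are dropped and categorized (`unmapped`,
#' `multimapped`, `moved`).  This reproduces the state of a real pipeline
#' after alignment, before any bias filtering: at biased loci, alt-carrying
#' reads are the ones lost.
#'
#' @param reads list of reads.
#' @param aligner function from [make_exact_aligner()] or compatible.
#' @return list(`mapped` = retained reads, `log` = named integer category
#'   counts).
#' @export
map_reads <- function(reads, aligner) {
  cat_count <- c(unmapped = 0L, multimapped = 0L, moved = 0L)
  keep <- logical(length(reads))
  for (i in seq_along(reads)) {
    hits <- aligner(reads[[i]]$sequence)
    if (length(hits) == 0L) cat_count["unmapped"] <- cat_count["unmapped"] + 1L
    else if (length(hits) > 1L) cat_count["multimapped"] <- cat_count["multimapped"] + 1L
    else if (hits != reads[[i]]$position) cat_count["moved"] <- cat_count["moved"] + 1L
    else keep[i] <- TRUE
  }
  list(mapped = reads[keep], log = cat_count)
}

#' Allele-swap remapping filter
#'
#' A read is retained iff every allele-swapped version of it maps uniquely to
#' the read's original position.  Reads covering more than `max_snps` SNPs
#' are discarded outright (combinatorial swap blow-up).  Discards are
#' categorized by the first failing swap: `moved` (unique hit elsewhere),
#' `multimapped`, `unmapped`, or `too_many_snps`.
#'
#' Filtering is idempotent: re-filtering the retained reads retains all of
#' them.
#'
#' @inheritParams map_reads
#' @param max_snps maximum covered SNPs per read.
#' @return list(`retained` = reads, `log` = data.frame(read, category) for
#'   discards, `summary` = named category counts).
#' @export
filter_biased_reads <- function(reads, aligner, max_snps = 5L) {
  categories <- character(0)
  index <- integer(0)
  keep <- logical(length(reads))
  for (i in seq_along(reads)) {
    read <- reads[[i]]
    k <- nrow(read$snps)
    if (is.null(k)) k <- 0L
    if (k > max_snps) {
      categories <- c(categories, "too_many_snps"); index <- c(index, i)
      next
    }
    fail <- NULL
    if (k > 0L) {
      for (sw in swap_alleles(read)) {
        hits <- aligner(sw$sequence)
        if (length(hits) == 0L) { fail <- "unmapped"; break }
        if (length(hits) > 1L) { fail <- "multimapped"; break }
        if (hits != read$position) { fail <- "moved"; break }
      }
    }
    if (is.null(fail)) keep[i] <- TRUE
    else { categories <- c(categories, fail); index <- c(index, i) }
  }
  summary <- table(factor(categories,
                          levels = c("moved", "multimapped", "unmapped", "too_many_snps")))
  list(retained = reads[keep],
       log = data.frame(read = index, category = categories, stringsAsFactors = FALSE),
       summary = c(summary))
}

#' Count alleles from annotated reads
#'
#' Each read contributes one count to exactly one allele at every SNP it
#' covers.
#'
#' @param reads list of reads.
#' @return data.frame (id, ref_count, alt_count, depth).
#' @export
count_alleles <- function(reads) {
  if (length(reads) == 0L)
    return(data.frame(id = character(0), ref_count = integer(0),
                      alt_count = integer(0), depth = integer(0)))
  snp_tab <- do.call(rbind, lapply(reads, `[[`, "snps"))
  ref <- tapply(snp_tab$allele == "ref", snp_tab$id, sum)
  alt <- tapply(snp_tab$allele == "alt", snp_tab$id, sum)
  ids <- sort(unique(snp_tab$id))
  data.frame(id = ids, ref_count = as.integer(ref[ids]),
             alt_count = as.integer(alt[ids]),
             depth = as.integer(ref[ids] + alt[ids]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter SNPs by pooled minor-allele frequency
#'
#' Only SNPs with pooled MAF above the cutoff (default 2.5%) enter the QTL
#' pipeline; rarer alleles give too few informative reads.
#'
#' @param genotypes a [`pool_genotypes`][simulate_genotypes] object.
#' @param min_maf exclusive MAF lower bound.
#' @return the genotypes object restricted to passing SNPs.
#' @export
filter_maf <- function(genotypes, min_maf = 0.025) {
  af <- rowMeans(genotypes$dosage)
  maf <- pmin(af, 1 - af)
  keep <- maf > min_maf
  structure(list(
    variants = genotypes$variants[keep, , drop = FALSE],
    dosage = genotypes$dosage[keep, , drop = FALSE],
    haplotypes = genotypes$haplotypes[keep, , drop = FALSE]
  ), class = "pool_genotypes")
}
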