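# PWM scanning and the two motif-enrichment designs: significant vs
# non-significant QTL windows (+/- 50 bp), and favored-allele vs
# disfavored-allele flipped windows (+/- 20 bp).  In the flipped design the
# two window sets differ only at the center base, so any differential motif
# necessarily overlaps the variant itself.

.BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix
#'
#' Converts a count (or probability) matrix into a PWM with per-cell
#' pseudocounts and a log2-odds scoring matrix against a background base
#' composition.  The hit threshold is a fraction of the maximum achievable
#' log-odds score -- deterministic and configurable, unlike tool-internal
#' calibrations.
#'
#' @param counts 4 x L numeric matrix (rows A, C, G, T).
#' @param name motif name.
#' @param pseudocount added to every cell before normalization.
#' @param background length-4 base composition (default uniform).
#' @param threshold_frac hit threshold as a fraction of the maximum score.
#' @return object of class `"pwm"` with elements `name`, `probs`,
#'   `log_odds`, `background`, `max_score`, `threshold`.
#' @export
make_pwm <- function(counts, name = "motif", pseudocount = 0.01,
                     background = rep(0.25, 4), threshold_frac = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) .validation_error("PWM matrix must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4L) .validation_error("PWM length must be >= 4")
  if (any(counts < 0)) .validation_error("PWM entries must be nonnegative")
  background <- background / sum(background)
  probs <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  lo <- log2(probs / background)
  rownames(probs) <- rownames(lo) <- .BASES
  max_score <- sum(apply(lo, 2, max))
  structure(list(name = name, probs = probs, log_odds = lo,
                 background = background, max_score = max_score,
                 threshold = threshold_frac * max_score),
            class = "pwm")
}

#' Build a PWM from a consensus sequence
#'
#' Columns put probability `match_prob` on the consensus base and the
#' remainder uniformly on the others -- handy for planting known motifs in
#' synthetic windows.
#'
#' @param consensus character string over A/C/G/T.
#' @param match_prob probability of the consensus base per column.
#' @inheritParams make_pwm
#' @return a `"pwm"` object.
#' @export
pwm_from_consensus <- function(consensus, name = consensus, match_prob = 0.94,
                               threshold_frac = 0.8) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% .BASES)) .validation_error("consensus must be over A/C/G/T")
  m <- matrix((1 - match_prob) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(.BASES, NULL))
  m[cbind(match(bases, .BASES), seq_along(bases))] <- match_prob
  make_pwm(m * 100, name = name, threshold_frac = threshold_frac)
}

#' Read PWMs from a JASPAR pfm file
#'
#' Accepts the JASPAR format with `>ID name` headers followed by four count
#' rows, either bracketed (`A [ 3 0 ... ]`) or raw.
#'
#' @param path pfm file.
#' @inheritParams make_pwm
#' @return named list of `"pwm"` objects.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.01, threshold_frac = 0.8) {
  lines <- .open_lines(path)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) .io_error("%s: no JASPAR records found", path)
  out <- list()
  for (s in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[s]])
    name <- gsub("\\s+", "_", trimws(hdr))
    end <- if (s < length(starts)) starts[s + 1L] - 1L else length(lines)
    rows <- lines[(starts[s] + 1L):end][1:4]
    mat <- t(vapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", rows[1])), "\\s+")[[1]]))))
    out[[name]] <- make_pwm(mat, name = name, pseudocount = pseudocount,
                            threshold_frac = threshold_frac)
  }
  out
}

#' Read PWMs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections
#' (positions as rows, columns A, C, G, T).
#'
#' @inheritParams read_jaspar_pfm
#' @return named list of `"pwm"` objects.
#' @export
read_meme_minimal <- function(path, pseudocount = 0.01, threshold_frac = 0.8) {
  lines <- .open_lines(path)
  motif_idx <- grep("^MOTIF\\s", lines)
  if (length(motif_idx) == 0L) .io_error("%s: no MOTIF blocks found", path)
  out <- list()
  for (s in seq_along(motif_idx)) {
    name <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[motif_idx[s]])), "\\s+")[[1]][1]
    block_end <- if (s < length(motif_idx)) motif_idx[s + 1L] - 1L else length(lines)
    block <- lines[motif_idx[s]:block_end]
    lp <- grep("letter-probability matrix", block)
    if (length(lp) == 0L) .io_error("%s: MOTIF %s lacks a probability matrix", path, name)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[lp[1]]))
    rows <- block[(lp[1] + 1L):(lp[1] + w)]
    mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4)))
    out[[name]] <- make_pwm(t(mat) * 100, name = name, pseudocount = pseudocount,
                            threshold_frac = threshold_frac)
  }
  out
}

.encode_seq <- function(sequence) {
  codes <- match(strsplit(toupper(sequence), "")[[1]], .BASES)  # N -> NA
  codes
}

.revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# Best log-odds score of a PWM over every offset of an encoded sequence.
# NA codes (N bases) contribute 0 (expected background score).
.scan_one_strand <- function(codes, lo) {
  L <- ncol(lo)
  S <- length(codes)
  if (S < L) return(list(score = -Inf, position = NA_integer_))
  noff <- S - L + 1L
  idx <- outer(seq_len(noff) - 1L, seq_len(L), "+")  # noff x L positions
  base_codes <- matrix(codes[idx], nrow = noff)
  cell <- lo[cbind(as.vector(base_codes), rep(seq_len(L), each = noff))]
  cell[is.na(cell)] <- 0
  scores <- rowSums(matrix(cell, nrow = noff))
  best <- which.max(scores)
  list(score = scores[best], position = best)
}

#' Scan a sequence with a PWM
#'
#' Maximum log2-odds score over all offsets and both strands; a hit is
#' declared when the best score reaches the PWM's threshold.  `N` bases
#' score as background (log-odds 0).  Scanning a sequence and its reverse
#' complement yields identical best scores.
#'
#' @param sequence character string over A/C/G/T/N.
#' @param pwm a `"pwm"` object.
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @return list(`score`, `position` (1-based start of the best hit on the
#'   forward coordinates), `strand`, `hit`).
#' @export
scan_pwm <- function(sequence, pwm, both_strands = TRUE) {
  fwd <- .scan_one_strand(.encode_seq(sequence), pwm$log_odds)
  best <- list(score = fwd$score, position = fwd$position, strand = "+")
  if (both_strands) {
    rev <- .scan_one_strand(.encode_seq(.revcomp(sequence)), pwm$log_odds)
    if (rev$score > best$score) {
      pos_fwd <- nchar(sequence) - rev$position - ncol(pwm$log_odds) + 2L
      best <- list(score = rev$score, position = pos_fwd, strand = "-")
    }
  }
  best$hit <- is.finite(best$score) && best$score >= pwm$threshold
  best
}

# Hit matrix: windows x motifs.
.scan_hits <- function(windows, pwm_library) {
  vapply(pwm_library,
         function(pwm) vapply(windows, function(w) scan_pwm(w, pwm)$hit, logical(1)),
         logical(length(windows)))
}

#' Extract allele-substituted sequence windows around variants
#'
#' Returns the `2 * flank + 1`-bp window centered on each variant with the
#' chosen allele substituted at the center (windows are odd-length so a
#' single substituted base sits exactly at the center).
#'
#' @param genome named character vector (or `Biostrings::DNAStringSet`) of
#'   chromosome sequences.
#' @param variants data.frame (chrom, pos, ref, alt).
#' @param flank bp of context on each side.
#' @param allele `"ref"`, `"alt"`, or a character vector of bases (one per
#'   variant).
#' @return character vector of windows; variants too close to a contig edge
#'   yield `NA`.
#' @export
extract_allele_windows <- function(genome, variants, flank = 20L, allele = "ref") {
  if (inherits(genome, "DNAStringSet")) genome <- setNames(as.character(genome), names(genome))
  base <- if (length(allele) == 1L && allele %in% c("ref", "alt"))
    variants[[allele]] else rep_len(allele, nrow(variants))
  out <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    chrom_seq <- genome[[variants$chrom[i]]]
    if (is.null(chrom_seq)) next
    p <- variants$pos[i]
    if (p - flank < 1L || p + flank > nchar(chrom_seq)) next
    w <- substr(chrom_seq, p - flank, p + flank)
    substr(w, flank + 1L, flank + 1L) <- base[i]
    out[i] <- w
  }
  out
}

#' Known-motif enrichment: significant vs non-significant QTL windows
#'
#' Scans both window sets with a PWM library and tests, per motif, whether
#' the hit fraction among significant-QTL windows exceeds the
#' non-significant (background) hit fraction, using an upper-tail binomial
#' test with the background fraction as null rate (floored at
#' `1/(n_background + 1)` and flagged when zero).  Benjamini-Hochberg FDR is
#' reported with significance called at `fdr_cutoff` (default 0.1%).
#'
#' @param significant_windows,nonsignificant_windows character vectors of
#'   equal-flank sequence windows ([extract_allele_windows()]).
#' @param pwm_library named list of `"pwm"` objects.
#' @param fdr_cutoff FDR significance cutoff (default 0.001).
#' @param method p-value flavor (see [test_frequency_shift()] Details).
#' @return data.frame (motif, n_hits, n_bg_hits, frac, frac_bg, fold,
#'   p_value, fdr, significant, bg_floored), sorted by p-value.
#' @export
motif_enrichment <- function(significant_windows, nonsignificant_windows,
                             pwm_library, fdr_cutoff = 0.001,
                             method = c("midp", "tail")) {
  method <- match.arg(method)
  sig <- significant_windows[!is.na(significant_windows)]
  bg <- nonsignificant_windows[!is.na(nonsignificant_windows)]
  if (length(sig) == 0L || length(bg) == 0L)
    .validation_error("both window sets must be non-empty")
  hits_sig <- .scan_hits(sig, pwm_library)
  hits_bg <- .scan_hits(bg, pwm_library)
  k <- colSums(matrix(hits_sig, ncol = length(pwm_library)))
  kb <- colSums(matrix(hits_bg, ncol = length(pwm_library)))
  n <- length(sig)
  nb <- length(bg)
  floored <- kb == 0
  p0 <- ifelse(floored, 1 / (nb + 1), kb / nb)
  p <- pmin(1, .binom_upper(k, n, p0, method))
  fold <- (k / n) / p0
  fold[k == 0 & kb == 0] <- 1  # no hits either side: no evidence, ratio 1
  out <- data.frame(motif = names(pwm_library), n_hits = k, n_bg_hits = kb,
                    frac = k / n, frac_bg = kb / nb, fold = fold,
                    p_value = p, fdr = p.adjust(p, "BH"),
                    bg_floored = floored, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$significant <- out$fdr < fdr_cutoff
  out[order(out$p_value), ]
}

#' Allele-specific motif enrichment with flipped center bases
#'
#' Builds two window sets around the same QTLs that differ only at the
#' center base: the favored (open/bound) allele -- the allele whose
#' post-assay frequency exceeds its predicted pre-assay frequency -- and
#' the disfavored (closed/less-bound) allele.  Each direction is tested
#' with the opposite set as background, so every significant motif
#' necessarily overlaps the variant position.
#'
#' @param qtls data.frame with chrom, pos, ref, alt, pre_freq, post_freq.
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param pwm_library named list of `"pwm"` objects.
#' @param flank bp of identical context on each side (default 20; windows
#'   are `2 * flank + 1` bp).
#' @inheritParams motif_enrichment
#' @return data.frame with one row per motif and direction
#'   (`"open_enriched"` / `"closed_enriched"`): motif, direction, n_hits,
#'   n_bg_hits, fold, p_value, fdr, significant.
#' @export
allele_specific_enrichment <- function(qtls, genome, pwm_library, flank = 20L,
                                       fdr_cutoff = 0.001,
                                       method = c("midp", "tail")) {
  method <- match.arg(method)
  favored <- ifelse(qtls$post_freq > qtls$pre_freq, qtls$alt, qtls$ref)
  disfavored <- ifelse(qtls$post_freq > qtls$pre_freq, qtls$ref, qtls$alt)
  w_open <- extract_allele_windows(genome, qtls, flank, favored)
  w_closed <- extract_allele_windows(genome, qtls, flank, disfavored)
  ok <- !is.na(w_open) & !is.na(w_closed)
  w_open <- w_open[ok]
  w_closed <- w_closed[ok]
  if (length(w_open) == 0L) .validation_error("no usable QTL windows")
  h_open <- matrix(.scan_hits(w_open, pwm_library), ncol = length(pwm_library))
  h_closed <- matrix(.scan_hits(w_closed, pwm_library), ncol = length(pwm_library))
  n <- length(w_open)
  one_direction <- function(kf, kb, direction) {
    floored <- kb == 0
    p0 <- ifelse(floored, 1 / (n + 1), kb / n)
    p <- pmin(1, .binom_upper(kf, n, p0, method))
    fold <- (kf / n) / p0
    fold[kf == 0 & kb == 0] <- 1  # no hits either side: no evidence, ratio 1
    data.frame(motif = names(pwm_library), direction = direction, n_hits = kf,
               n_bg_hits = kb, fold = fold, p_value = p,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- rbind(
    one_direction(colSums(h_open), colSums(h_closed), "open_enriched"),
    one_direction(colSums(h_closed), colSums(h_open), "closed_enriched")
  )
  out$fdr <- p.adjust(out$p_value, "BH")
  out$significant <- out$fdr < fdr_cutoff
  out[order(out$p_value), ]
}
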