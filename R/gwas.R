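# GWAS-association analyses: windowed lead-SNP enrichment around QTLs,
# ranking of traits by high-LD pair ratio, and comparison of r-squared
# distributions between significant and non-significant QTLs.

# Upper-tail binomial p-value, mid-p by default (see .binom_two_sided for
# why mid-p: discrete upper tails are otherwise conservative and null
# p-values pile up short of uniform).
.binom_upper <- function(k, n, p0, method = c("midp", "tail")) {
  method <- match.arg(method)
  if (method == "midp") pbinom(k, n, p0, lower.tail = FALSE) + dbinom(k, n, p0) / 2
  else pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Lead-SNP window enrichment around QTLs
#'
#' For each trait, counts its lead SNPs falling within +/- `window` bp of
#' any QTL (a lead overlapping several QTL windows counts once), and tests
#' the count against the pooled in-window rate of the background traits with
#' an upper-tail binomial test.  Fold is the ratio of the trait's in-window
#' rate to the background rate.  Benjamini-Hochberg FDR across traits is
#' reported alongside the raw p-values.
#'
#' @param qtls data.frame with chrom and pos columns (significant QTLs).
#' @param leads lead-SNP data.frame (trait, chrom, pos, id).
#' @param window half-width of the window in bp (default 1000).
#' @param background_traits character vector naming the background traits;
#'   every other trait in `leads` is tested against their pooled rate.
#' @param method p-value flavor, `"midp"` (default) or `"tail"`.
#' @return data.frame (trait, n_leads, overlap_count, fold, p_value, fdr,
#'   is_background), one row per trait; attribute `p0` is the background
#'   in-window rate (floored at `1/(total background leads + 1)` and flagged
#'   by attribute `p0_floored` when no background lead overlaps).
#' @export
window_enrichment <- function(qtls, leads, window = 1000L, background_traits,
                              method = c("midp", "tail")) {
  method <- match.arg(method)
  if (length(background_traits) < 1L)
    .validation_error("at least one background trait is required")
  in_window <- rep(FALSE, nrow(leads))
  for (ch in unique(leads$chrom)) {
    qi <- which(qtls$chrom == ch)
    li <- which(leads$chrom == ch)
    if (length(qi) == 0L || length(li) == 0L) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(start = leads$pos[li], width = 1L),
      IRanges::IRanges(start = qtls$pos[qi] - window, end = qtls$pos[qi] + window)
    )
    in_window[li] <- ov
  }
  traits <- unique(leads$trait)
  k <- vapply(traits, function(t) {
    sel <- leads$trait == t
    sum(tapply(in_window[sel], leads$id[sel], any))  # a lead counts once
  }, integer(1))
  n <- vapply(traits, function(t) length(unique(leads$id[leads$trait == t])),
              integer(1))
  is_bg <- traits %in% background_traits
  if (!any(is_bg)) .validation_error("no background trait present in the catalog")
  p0 <- sum(k[is_bg]) / sum(n[is_bg])
  p0_floored <- FALSE
  if (p0 == 0) {
    p0 <- 1 / (sum(n[is_bg]) + 1)
    p0_floored <- TRUE
  }
  p <- .binom_upper(k, n, p0, method)
  out <- data.frame(trait = traits, n_leads = n, overlap_count = k,
                    fold = (k / n) / p0, p_value = pmin(1, p),
                    fdr = p.adjust(pmin(1, p), "BH"), is_background = is_bg,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "p0") <- p0
  attr(out, "p0_floored") <- p0_floored
  out[order(out$p_value), ]
}

#' Rank traits by their high-LD pair ratio
#'
#' Per trait, the ratio of QTL/lead pairs with r-squared above `threshold`
#' to all pairs; traits are returned in decreasing ratio order (ties broken
#' by pair count, then name).  Traits with zero pairs cannot appear in the
#' input and are implicitly excluded.
#'
#' @param pairs LD-pair data.frame from [pair_qtls_with_leads()].
#' @param threshold r-squared threshold (default 0.8).
#' @return data.frame (trait, n_pairs, n_high, ratio), ranked.
#' @export
r2_ratio_ranking <- function(pairs, threshold = 0.8) {
  traits <- unique(pairs$trait)
  n_pairs <- vapply(traits, function(t) sum(pairs$trait == t), integer(1))
  n_high <- vapply(traits, function(t) sum(pairs$trait == t & pairs$r2 > threshold),
                   integer(1))
  out <- data.frame(trait = traits, n_pairs = n_pairs, n_high = n_high,
                    ratio = n_high / n_pairs, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$ratio, -out$n_pairs, out$trait), ]
}

#' Compare r-squared distributions of significant vs non-significant QTLs
#'
#' One-sided Mann-Whitney test that pairs involving significant QTLs have
#' larger r-squared than pairs involving non-significant QTLs, plus the fold
#' change of the high-LD fraction (r-squared > `threshold`) between the two
#' groups.
#'
#' @param r2_significant,r2_nonsignificant numeric vectors of pair
#'   r-squared values for the two QTL groups.
#' @param threshold high-LD threshold (default 0.8).
#' @return list(`p_value`, `fold`, `frac_significant`, `frac_nonsignificant`,
#'   `small_sample` flag set when either group has fewer than 10 pairs).
#' @export
r2_distribution_comparison <- function(r2_significant, r2_nonsignificant,
                                       threshold = 0.8) {
  if (length(r2_significant) == 0L || length(r2_nonsignificant) == 0L)
    .validation_error("both groups must be non-empty")
  p <- suppressWarnings(
    wilcox.test(r2_significant, r2_nonsignificant, alternative = "greater")$p.value
  )
  f_sig <- mean(r2_significant > threshold)
  f_non <- mean(r2_nonsignificant > threshold)
  fold <- if (f_non == 0) {
    f_sig / (1 / (length(r2_nonsignificant) + 1))
  } else f_sig / f_non
  list(p_value = p, fold = fold, frac_significant = f_sig,
       frac_nonsignificant = f_non,
       small_sample = length(r2_significant) < 10L || length(r2_nonsignificant) < 10L)
}
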