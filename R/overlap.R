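# Overlap among QTL sets (exact and LD-based), directional allele
# concordance, QTL density around feature sites, and loop-anchor signal
# comparison.

# Variant identity key.  Default includes alleles; position-only matching is
# available for sources that do not report alleles.
.variant_key <- function(df, use_alleles = TRUE) {
  if (use_alleles && all(c("ref", "alt") %in% names(df)))
    paste(df$chrom, df$pos, df$ref, df$alt)
  else paste(df$chrom, df$pos)
}

#' Exact-match overlap among named QTL sets
#'
#' Intersects QTL sets by variant identity (chromosome, position and, by
#' default, alleles) and reports the size of every intersection of two or
#' more sets.  Duplicate variants within a set are deduplicated with a
#' message.  Counts obey inclusion-exclusion by construction: every
#' higher-order intersection is no larger than any of its margins.
#'
#' @param qtl_sets named list of data.frames with chrom, pos (and optionally
#'   ref, alt) columns.
#' @param use_alleles include alleles in variant identity (default `TRUE`).
#' @return object of class `"overlap_report"`: list with `sizes` (named),
#'   `intersections` (named by `"A&B"`-style keys), and `mode = "exact"`.
#' @export
exact_overlap <- function(qtl_sets, use_alleles = TRUE) {
  stopifnot(is.list(qtl_sets), !is.null(names(qtl_sets)), length(qtl_sets) >= 2L)
  keys <- lapply(qtl_sets, function(df) {
    k <- .variant_key(df, use_alleles)
    if (anyDuplicated(k))
      message(sprintf("exact_overlap: %d duplicate variants deduplicated", sum(duplicated(k))))
    unique(k)
  })
  sizes <- vapply(keys, length, integer(1))
  nm <- names(qtl_sets)
  inters <- list()
  for (m in 2:length(nm)) {
    for (combo in asplit(combn(nm, m), 2)) {
      inters[[paste(combo, collapse = "&")]] <-
        length(Reduce(intersect, keys[combo]))
    }
  }
  structure(list(sizes = sizes, intersections = unlist(inters), mode = "exact"),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report (%s matching)\n", x$mode))
  cat("  sizes:", paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  for (nm in names(x$intersections))
    cat(sprintf("  %s: %d\n", nm, x$intersections[[nm]]))
  invisible(x)
}

#' LD-based overlap among QTL sets
#'
#' A variant of set A matches set B if it is an exact match, or if some
#' variant of B within `max_distance` bp has phased-haplotype r-squared
#' above `r2_threshold` with it.  Counts are reported per ordered set pair
#' (matching is not symmetric in general: `counts[A, B]` is the number of A
#' variants with a proxy in B).
#'
#' @inheritParams exact_overlap
#' @param genotypes LD panel ([`pool_genotypes`][simulate_genotypes]);
#'   set variants are matched into it by position.
#' @param r2_threshold exclusive r-squared threshold (default 0.8).
#' @param max_distance proxy search radius in bp (default 100 kb).
#' @return object of class `"overlap_report"` with a `counts` matrix and
#'   `mode = "ld"`.
#' @export
ld_overlap <- function(qtl_sets, genotypes, r2_threshold = 0.8,
                       max_distance = 1e5, use_alleles = TRUE) {
  stopifnot(length(qtl_sets) >= 2L)
  v <- genotypes$variants
  panel_key <- paste(v$chrom, v$pos)
  nm <- names(qtl_sets)
  prep <- lapply(qtl_sets, function(df) {
    df <- df[!duplicated(.variant_key(df, use_alleles)), , drop = FALSE]
    df$panel_row <- match(paste(df$chrom, df$pos), panel_key)
    df
  })
  counts <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  for (a in nm) for (b in setdiff(nm, a)) {
    A <- prep[[a]]; B <- prep[[b]]
    exact <- .variant_key(A, use_alleles) %in% .variant_key(B, use_alleles)
    matched <- exact
    for (ch in unique(A$chrom)) {
      ai <- which(A$chrom == ch & !matched & !is.na(A$panel_row))
      bi <- which(B$chrom == ch & !is.na(B$panel_row))
      if (length(ai) == 0L || length(bi) == 0L) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start = A$pos[ai], width = 1L),
        IRanges::IRanges(start = B$pos[bi] - (max_distance - 1L),
                         end = B$pos[bi] + (max_distance - 1L))
      )
      if (length(ov) == 0L) next
      r2 <- r2_phased(genotypes$haplotypes,
                      A$panel_row[ai[S4Vectors::queryHits(ov)]],
                      B$panel_row[bi[S4Vectors::subjectHits(ov)]])
      hit <- tapply(!is.na(r2) & r2 > r2_threshold,
                    ai[S4Vectors::queryHits(ov)], any)
      matched[as.integer(names(hit))] <- matched[as.integer(names(hit))] | hit
    }
    counts[a, b] <- sum(matched)
  }
  structure(list(sizes = vapply(prep, nrow, integer(1)), counts = counts,
                 mode = "ld"),
            class = "overlap_report")
}

#' Directional allele concordance between two QTL sets
#'
#' For each QTL the favored allele is the one whose observed post-assay
#' frequency exceeds the predicted pre-assay frequency (the bound allele of
#' a binding QTL, the open allele of an accessibility QTL).  For variants
#' shared between the two sets, cross-tabulates the favored alleles and
#' tests association with Fisher's exact test: concordance means the
#' TF-bound allele tends to be the open allele.
#'
#' @param qtls_a,qtls_b frequency-record data.frames (needing chrom, pos,
#'   ref, alt, pre_freq, post_freq).
#' @param use_alleles include alleles in variant identity.
#' @return list(`table` = 2x2 favored-allele cross-tabulation,
#'   `n_shared`, `n_concordant`, `p_value` (`NA` when no variant is
#'   shared)).
#' @export
directional_concordance <- function(qtls_a, qtls_b, use_alleles = TRUE) {
  fav <- function(df) ifelse(df$post_freq > df$pre_freq, "alt", "ref")
  ka <- .variant_key(qtls_a, use_alleles)
  kb <- .variant_key(qtls_b, use_alleles)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L)
    return(list(table = table(factor(character(0), c("ref", "alt")),
                              factor(character(0), c("ref", "alt"))),
                n_shared = 0L, n_concordant = 0L, p_value = NA_real_))
  fa <- fav(qtls_a)[match(shared, ka)]
  fb <- fav(qtls_b)[match(shared, kb)]
  tab <- table(factor(fa, c("ref", "alt")), factor(fb, c("ref", "alt")))
  p <- if (all(dim(tab) == c(2L, 2L))) fisher.test(tab)$p.value else NA_real_
  list(table = tab, n_shared = length(shared), n_concordant = sum(fa == fb),
       p_value = p)
}

#' QTL density profile around feature sites
#'
#' Bins the signed distance from each QTL to the nearest feature center
#' within `+/- window` bp, normalized per QTL in window.  When a
#' non-significant comparison set is given, the central-window density is
#' compared between the two sets: enrichment ratio plus an upper-tail
#' binomial p-value with the non-significant central fraction as null rate.
#' The profile is translation-invariant by construction.
#'
#' @param qtls data.frame with chrom, pos.
#' @param features data.frame of intervals (chrom, start, end; 0-based
#'   half-open) or points (chrom, pos); centers are used.
#' @param window half-width in bp (default 5000).
#' @param nbins number of bins across `2 * window`.
#' @param nonsig_qtls optional comparison QTL set (same columns as `qtls`).
#' @param central_halfwidth half-width of the central comparison window.
#' @param method p-value flavor (see [window_enrichment()]).
#' @return list(`breaks`, `mids`, `density` (per-QTL normalized),
#'   `n_in_window`, and -- with a comparison set -- `density_nonsig`,
#'   `ratio`, `p_value`).
#' @export
density_profile <- function(qtls, features, window = 5000L, nbins = 50L,
                            nonsig_qtls = NULL, central_halfwidth = 500L,
                            method = c("midp", "tail")) {
  if (is.null(features) || nrow(features) == 0L) .validation_error("feature list is empty")
  method <- match.arg(method)
  centers <- if (all(c("start", "end") %in% names(features))) {
    data.frame(chrom = features$chrom,
               pos = floor((features$start + features$end) / 2) + 1L)
  } else data.frame(chrom = features$chrom, pos = features$pos)
  signed_dist <- function(df) {
    out <- rep(NA_real_, nrow(df))
    for (ch in unique(df$chrom)) {
      ci <- which(centers$chrom == ch)
      qi <- which(df$chrom == ch)
      if (length(ci) == 0L || length(qi) == 0L) next
      cp <- sort(centers$pos[ci])
      idx <- findInterval(df$pos[qi], cp)
      lo <- pmax(idx, 1L)
      hi <- pmin(idx + 1L, length(cp))
      d_lo <- df$pos[qi] - cp[lo]
      d_hi <- df$pos[qi] - cp[hi]
      out[qi] <- ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi)
    }
    out[abs(out) <= window]
  }
  breaks <- seq(-window, window, length.out = nbins + 1L)
  d_sig <- signed_dist(qtls)
  h_sig <- hist(d_sig, breaks = breaks, plot = FALSE)
  res <- list(breaks = breaks, mids = h_sig$mids,
              density = if (length(d_sig)) h_sig$counts / length(d_sig) else h_sig$counts,
              n_in_window = length(d_sig))
  if (!is.null(nonsig_qtls)) {
    d_non <- signed_dist(nonsig_qtls)
    h_non <- hist(d_non, breaks = breaks, plot = FALSE)
    res$density_nonsig <- if (length(d_non)) h_non$counts / length(d_non) else h_non$counts
    k <- sum(abs(d_sig) <= central_halfwidth)
    p0 <- if (length(d_non)) sum(abs(d_non) <= central_halfwidth) / length(d_non) else 0
    floored <- p0 == 0
    if (floored) p0 <- 1 / (length(d_non) + 1)
    res$ratio <- (k / max(length(d_sig), 1L)) / p0
    res$p_value <- min(1, .binom_upper(k, max(length(d_sig), 1L), p0, method))
    res$p0_floored <- floored
  }
  res
}

#' Compare anchor signal between loops with and without clQTLs
#'
#' Computes, for each loop, the mean of a coverage-like score over its two
#' anchors (score-weighted by overlap width, divided by total anchor width)
#' and compares the two loop groups with a Mann-Whitney test.
#'
#' @param loops_a,loops_b loop data.frames (chrom1, start1, end1, chrom2,
#'   start2, end2), e.g. loops with / without clQTLs in their anchors.
#' @param signal data.frame (chrom, start, end, score), 0-based half-open
#'   weighted intervals.
#' @param alternative passed to [stats::wilcox.test()] (default
#'   `"two.sided"`).
#' @return list(`mean_a`, `mean_b`, `per_loop_a`, `per_loop_b`, `p_value`,
#'   `no_signal` flag when nothing overlaps).
#' @export
anchor_signal_comparison <- function(loops_a, loops_b, signal,
                                     alternative = "two.sided") {
  sig_gr <- GenomicRanges::GRanges(signal$chrom,
                                   IRanges::IRanges(signal$start + 1L, signal$end),
                                   score = signal$score)
  loop_means <- function(loops) {
    anchors <- GenomicRanges::GRanges(
      c(loops$chrom1, loops$chrom2),
      IRanges::IRanges(c(loops$start1, loops$start2) + 1L,
                       c(loops$end1, loops$end2))
    )
    ov <- GenomicRanges::findOverlaps(anchors, sig_gr)
    wsum <- numeric(length(anchors))
    if (length(ov) > 0) {
      inter_w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(anchors)[S4Vectors::queryHits(ov)],
        IRanges::ranges(sig_gr)[S4Vectors::subjectHits(ov)]
      ))
      contrib <- inter_w * sig_gr$score[S4Vectors::subjectHits(ov)]
      agg <- tapply(contrib, S4Vectors::queryHits(ov), sum)
      wsum[as.integer(names(agg))] <- agg
    }
    n <- nrow(loops)
    (wsum[seq_len(n)] + wsum[n + seq_len(n)]) /
      (IRanges::width(IRanges::ranges(anchors))[seq_len(n)] +
         IRanges::width(IRanges::ranges(anchors))[n + seq_len(n)])
  }
  ma <- loop_means(loops_a)
  mb <- loop_means(loops_b)
  no_signal <- all(ma == 0) && all(mb == 0)
  p <- if (no_signal) NA_real_ else
    suppressWarnings(wilcox.test(ma, mb, alternative = alternative)$p.value)
  list(mean_a = mean(ma), mean_b = mean(mb), per_loop_a = ma, per_loop_b = mb,
       p_value = p, no_signal = no_signal)
}
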