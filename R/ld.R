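# Linkage disequilibrium from phased haplotypes, and enumeration of
# QTL / GWAS-lead-SNP pairs within a distance bound.

#' Pairwise r-squared from phased haplotypes
#'
#' Computes `r^2 = D^2 / (pA (1-pA) pB (1-pB))` with
#' `D = P(ab) - pA pB` by direct haplotype counting -- no EM is needed since
#' the input is phased.  Monomorphic SNPs have undefined r-squared and
#' return `NA`.  The statistic is symmetric in its arguments and invariant
#' to swapping allele labels at either SNP.
#'
#' @param haplotypes 0/1 matrix, SNPs x haplotypes (rownames are SNP ids),
#'   e.g. `genotypes$haplotypes`.
#' @param snp_a,snp_b SNP ids or row indices; vectors of equal length give
#'   one r-squared per pair.
#' @return numeric vector of r-squared values in \[0, 1\] (or `NA`).
#' @export
r2_phased <- function(haplotypes, snp_a, snp_b) {
  a <- haplotypes[snp_a, , drop = FALSE]
  b <- haplotypes[snp_b, , drop = FALSE]
  pa <- rowMeans(a)
  pb <- rowMeans(b)
  pab <- rowMeans(a * b)
  denom <- pa * (1 - pa) * pb * (1 - pb)
  r2 <- (pab - pa * pb)^2 / denom
  r2[denom == 0] <- NA_real_
  unname(r2)
}

#' Pair QTLs with GWAS lead SNPs within a distance bound
#'
#' Enumerates every (QTL, lead-SNP) pair on the same chromosome separated by
#' strictly less than `max_distance` bp, grouped by trait, and attaches the
#' phased-haplotype r-squared of each pair.  Pairs whose lead SNP is absent
#' from the haplotype panel, or monomorphic in it, are skipped and counted.
#' A lead coinciding with a QTL position is matched to the QTL's panel SNP
#' (distance 0, r-squared 1 when identical).
#'
#' @param qtls data.frame with columns id, chrom, pos (e.g. significant
#'   records from [call_qtls()] merged with variants).
#' @param leads lead-SNP data.frame (trait, chrom, pos, id).
#' @param genotypes a [`pool_genotypes`][simulate_genotypes] object; its
#'   haplotypes are the LD panel and leads are matched into it by position.
#' @param max_distance exclusive distance bound in bp (default 100 kb).
#' @return data.frame (trait, qtl_id, lead_id, distance, r2); attribute
#'   `n_skipped` counts pairs without a usable panel SNP for the lead.
#' @export
pair_qtls_with_leads <- function(qtls, leads, genotypes, max_distance = 1e5) {
  v <- genotypes$variants
  panel_key <- paste(v$chrom, v$pos)
  lead_row <- match(paste(leads$chrom, leads$pos), panel_key)
  out <- list()
  n_skipped <- 0L
  for (ch in unique(qtls$chrom)) {
    qi <- which(qtls$chrom == ch)
    li <- which(leads$chrom == ch)
    if (length(qi) == 0L || length(li) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = qtls$pos[qi], width = 1L),
      IRanges::IRanges(start = leads$pos[li] - (max_distance - 1L),
                       end = leads$pos[li] + (max_distance - 1L))
    )
    if (length(ov) == 0L) next
    qq <- qi[S4Vectors::queryHits(ov)]
    ll <- li[S4Vectors::subjectHits(ov)]
    has_panel <- !is.na(lead_row[ll])
    n_skipped <- n_skipped + sum(!has_panel)
    qq <- qq[has_panel]; ll <- ll[has_panel]
    if (length(qq) == 0L) next
    r2 <- r2_phased(genotypes$haplotypes, qtls$id[qq], v$id[lead_row[ll]])
    mono <- is.na(r2)
    n_skipped <- n_skipped + sum(mono)
    out[[ch]] <- data.frame(
      trait = leads$trait[ll][!mono], qtl_id = qtls$id[qq][!mono],
      lead_id = leads$id[ll][!mono],
      distance = abs(qtls$pos[qq] - leads$pos[ll])[!mono],
      r2 = r2[!mono], stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(trait = character(0), qtl_id = character(0),
               lead_id = character(0), distance = integer(0), r2 = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}
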