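# Allele-specific Hi-C: turn contact pairs into the per-SNP allele-count
# phenotype that clQTL calling feeds through the same regression machinery
# as the other assays.

#' Assign alleles to Hi-C contact pairs from phased SNPs
#'
#' Converts base-level SNP observations on contact pairs into ref/alt tags.
#' A pair is tagged when at least one covered SNP is informative (its
#' observed base equals the SNP's ref or alt allele); pairs whose covered
#' SNPs imply conflicting alleles are discarded and counted, as are pairs
#' with no informative SNP.
#'
#' @param contact_pairs data.frame (pair_id, chromA, posA, chromB, posB), one
#'   row per pair.
#' @param observations data.frame (pair_id, snp_id, base): bases observed at
#'   SNP positions covered by the pair's reads.
#' @param genotypes a [`pool_genotypes`][simulate_genotypes] object (supplies
#'   ref/alt alleles of the phased SNP universe).
#' @return data.frame (chromA, posA, chromB, posB, snp_id, allele) of tagged
#'   contacts; attribute `discarded` gives counts of `conflicting` and
#'   `untagged` pairs.
#' @export
assign_contact_alleles <- function(contact_pairs, observations, genotypes) {
  v <- genotypes$variants
  obs <- merge(observations, v[, c("id", "ref", "alt")],
               by.x = "snp_id", by.y = "id")
  obs$allele <- ifelse(obs$base == obs$ref, "ref",
                       ifelse(obs$base == obs$alt, "alt", NA_character_))
  obs <- obs[!is.na(obs$allele), , drop = FALSE]
  n_alleles <- tapply(obs$allele, obs$pair_id, function(a) length(unique(a)))
  consistent <- names(n_alleles)[n_alleles == 1L]
  conflicting <- sum(n_alleles > 1L)
  obs1 <- obs[!duplicated(obs$pair_id) & obs$pair_id %in% consistent, , drop = FALSE]
  out <- merge(contact_pairs, obs1[, c("pair_id", "snp_id", "allele")], by = "pair_id")
  untagged <- nrow(contact_pairs) - nrow(out) - conflicting
  out <- out[, c("chromA", "posA", "chromB", "posB", "snp_id", "allele")]
  rownames(out) <- NULL
  attr(out, "discarded") <- c(conflicting = conflicting, untagged = untagged)
  out
}

#' Count loop-supported alleles per SNP
#'
#' A tagged contact contributes to its SNP's count iff its two ends fall in
#' the two anchors of a loop containing that SNP (or, when
#' `both_in_one_anchor`, both ends in one anchor).  A SNP inside anchors of
#' several overlapping loops receives each contact once (no double
#' counting).  The output feeds [map_pool_qtls()] unchanged -- clQTLs are
#' called with the identical regression and test machinery -- so SNPs
#' outside every loop anchor are never tested.
#'
#' Anchor membership is half-open: a position `p` is inside BED-style anchor
#' `(s, e)` iff `s < p <= e`.
#'
#' @param contacts tagged contacts (chromA, posA, chromB, posB, snp_id,
#'   allele), e.g. from [simulate_allelic_contacts()] or
#'   [assign_contact_alleles()]; untagged rows (`NA`) are dropped.
#' @param loops loop data.frame (chrom1, start1, end1, chrom2, start2, end2,
#'   name).
#' @param genotypes supplies SNP positions.
#' @param both_in_one_anchor count contacts with both ends in the same
#'   anchor (default `TRUE`).
#' @return data.frame (id, ref_count, alt_count, depth, loop_ids).
#' @export
loop_allele_counts <- function(contacts, loops, genotypes,
                               both_in_one_anchor = TRUE) {
  if (nrow(loops) == 0L) .validation_error("loops must be non-empty")
  contacts <- contacts[!is.na(contacts$snp_id) & !is.na(contacts$allele), , drop = FALSE]
  if (nrow(contacts) == 0L)
    return(data.frame(id = character(0), ref_count = integer(0),
                      alt_count = integer(0), depth = integer(0),
                      loop_ids = character(0)))
  v <- genotypes$variants
  snp_pos <- setNames(v$pos, v$id)
  snp_chrom <- setNames(v$chrom, v$id)
  hits <- vector("list", nrow(loops))
  inside <- function(chrom, pos, lc, s, e) chrom == lc & pos > s & pos <= e
  for (k in seq_len(nrow(loops))) {
    a_in1 <- inside(contacts$chromA, contacts$posA, loops$chrom1[k], loops$start1[k], loops$end1[k])
    a_in2 <- inside(contacts$chromA, contacts$posA, loops$chrom2[k], loops$start2[k], loops$end2[k])
    b_in1 <- inside(contacts$chromB, contacts$posB, loops$chrom1[k], loops$start1[k], loops$end1[k])
    b_in2 <- inside(contacts$chromB, contacts$posB, loops$chrom2[k], loops$start2[k], loops$end2[k])
    ok <- (a_in1 & b_in2) | (a_in2 & b_in1)
    if (both_in_one_anchor) ok <- ok | (a_in1 & b_in1) | (a_in2 & b_in2)
    if (!any(ok)) next
    sp <- snp_pos[contacts$snp_id]
    sc <- snp_chrom[contacts$snp_id]
    snp_in <- inside(sc, sp, loops$chrom1[k], loops$start1[k], loops$end1[k]) |
      inside(sc, sp, loops$chrom2[k], loops$start2[k], loops$end2[k])
    sel <- which(ok & !is.na(snp_in) & snp_in)
    if (length(sel) > 0)
      hits[[k]] <- data.frame(contact = sel, snp_id = contacts$snp_id[sel],
                              allele = contacts$allele[sel], loop = loops$name[k],
                              stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits))
    return(data.frame(id = character(0), ref_count = integer(0),
                      alt_count = integer(0), depth = integer(0),
                      loop_ids = character(0)))
  loop_ids <- tapply(hits$loop, hits$snp_id,
                     function(x) paste(sort(unique(x)), collapse = ","))
  # one count per contact per SNP even when several loops match
  hits <- hits[!duplicated(hits[, c("contact", "snp_id")]), , drop = FALSE]
  ref <- tapply(hits$allele == "ref", hits$snp_id, sum)
  alt <- tapply(hits$allele == "alt", hits$snp_id, sum)
  ids <- sort(unique(hits$snp_id))
  data.frame(id = ids, ref_count = as.integer(ref[ids]),
             alt_count = as.integer(alt[ids]),
             depth = as.integer(ref[ids] + alt[ids]),
             loop_ids = as.character(loop_ids[ids]),
             row.names = NULL, stringsAsFactors = FALSE)
}
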