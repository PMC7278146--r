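# Assign QTLs to candidate target genes through chromatin-loop anchors:
# a QTL and a gene TSS sitting in the same anchor of a loop, or in the two
# anchors of one loop, form a candidate regulatory pair.

#' Assign QTLs to target genes via loop anchors
#'
#' For every loop, finds QTLs and gene reference points (TSS by default) in
#' its anchors and emits pairs in two evidence classes: `same_anchor` (both
#' in one anchor) and `cross_anchor` (QTL in one anchor, gene in the other).
#' Pairs are deduplicated per (QTL, gene, class) and carry the sorted ids of
#' all supporting loops, so the output is invariant to loop ordering and
#' every pair is reproducible from its cited loops.
#'
#' Anchor membership is half-open: position `p` is inside BED-style anchor
#' `(s, e)` iff `s < p <= e`.
#'
#' @param qtls data.frame with id, chrom, pos.
#' @param loops loop data.frame (chrom1, start1, end1, chrom2, start2, end2,
#'   name).
#' @param genes data.frame (name, chrom, tss, tes, strand).
#' @param gene_point `"tss"` (default) or `"body"` (any overlap of the
#'   tss-tes span with an anchor).
#' @return data.frame (qtl_id, gene, class, loop_ids).
#' @export
assign_qtl_genes <- function(qtls, loops, genes, gene_point = c("tss", "body")) {
  gene_point <- match.arg(gene_point)
  pairs <- list()
  inside <- function(chrom, pos, lc, s, e) chrom == lc & pos > s & pos <= e
  gene_in <- function(k, anchor) {
    lc <- loops[[paste0("chrom", anchor)]][k]
    s <- loops[[paste0("start", anchor)]][k]
    e <- loops[[paste0("end", anchor)]][k]
    if (gene_point == "tss") inside(genes$chrom, genes$tss, lc, s, e)
    else genes$chrom == lc & pmin(genes$tss, genes$tes) <= e &
      pmax(genes$tss, genes$tes) > s
  }
  for (k in seq_len(nrow(loops))) {
    q1 <- inside(qtls$chrom, qtls$pos, loops$chrom1[k], loops$start1[k], loops$end1[k])
    q2 <- inside(qtls$chrom, qtls$pos, loops$chrom2[k], loops$start2[k], loops$end2[k])
    g1 <- gene_in(k, 1L)
    g2 <- gene_in(k, 2L)
    emit <- function(qsel, gsel, class) {
      if (!any(qsel) || !any(gsel)) return(NULL)
      expand.grid(qtl_id = qtls$id[qsel], gene = genes$name[gsel],
                  stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE) |>
        transform(class = class, loop = loops$name[k])
    }
    pairs[[length(pairs) + 1L]] <- emit(q1, g1, "same_anchor")
    pairs[[length(pairs) + 1L]] <- emit(q2, g2, "same_anchor")
    pairs[[length(pairs) + 1L]] <- emit(q1, g2, "cross_anchor")
    pairs[[length(pairs) + 1L]] <- emit(q2, g1, "cross_anchor")
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs))
    return(data.frame(qtl_id = character(0), gene = character(0),
                      class = character(0), loop_ids = character(0)))
  key <- paste(pairs$qtl_id, pairs$gene, pairs$class)
  loop_ids <- tapply(pairs$loop, key, function(x) paste(sort(unique(x)), collapse = ","))
  first <- pairs[!duplicated(key), , drop = FALSE]
  out <- data.frame(qtl_id = first$qtl_id, gene = first$gene, class = first$class,
                    loop_ids = as.character(loop_ids[paste(first$qtl_id, first$gene, first$class)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$qtl_id, out$gene, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes targeted by every QTL class
#'
#' Intersects the target-gene lists of two or more QTL classes and reports,
#' for each shared gene, the number of distinct supporting QTLs per class.
#'
#' @param pair_lists named list (one element per QTL class) of pair
#'   data.frames from [assign_qtl_genes()].
#' @return data.frame with `gene` plus one `n_qtls_<class>` column per
#'   class; empty when the lists share no gene.
#' @export
shared_targets <- function(pair_lists) {
  stopifnot(is.list(pair_lists), length(pair_lists) >= 2L, !is.null(names(pair_lists)))
  genes <- Reduce(intersect, lapply(pair_lists, function(p) unique(p$gene)))
  out <- data.frame(gene = sort(genes), stringsAsFactors = FALSE)
  for (cls in names(pair_lists)) {
    p <- pair_lists[[cls]]
    counts <- tapply(p$qtl_id, p$gene, function(x) length(unique(x)))
    out[[paste0("n_qtls_", cls)]] <- as.integer(counts[out$gene])
  }
  out
}
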