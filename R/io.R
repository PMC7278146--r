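# Readers and writers for the standard formats the pipeline touches.
# Conventions, fixed package-wide: VCF, lead-SNP and QTL-table positions are
# 1-based; BED/BEDPE intervals are 0-based half-open.  A variant at position p
# overlaps interval [s, e) written as BED (s, e) iff s < p <= e.

.open_lines <- function(path) {
  if (!file.exists(path)) .io_error("file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Normalize chromosome names
#'
#' Harmonizes the mixed "chr1"/"1" conventions of GWAS, VCF and interval
#' sources.
#'
#' @param x character vector of chromosome names.
#' @param style `"keep"` (default), `"add"` (ensure a `chr` prefix) or
#'   `"strip"` (remove it).
#' @return normalized character vector.
#' @export
normalize_chrom <- function(x, style = c("keep", "add", "strip")) {
  style <- match.arg(style)
  switch(style,
    keep = x,
    strip = sub("^chr", "", x),
    add = ifelse(grepl("^chr", x), x, paste0("chr", x))
  )
}

#' Read phased diploid genotypes from a VCF
#'
#' Parses a VCF (via \pkg{vcfR}) keeping phased, biallelic SNP records with a
#' complete `GT` for every sample; unphased, multiallelic, non-SNP or missing
#' records are skipped with a reported count.  Dosage fraction is (number of
#' alternative alleles)/2.
#'
#' @param path VCF file (optionally gzipped).
#' @param chrom_style passed to [normalize_chrom()].
#' @return A [`pool_genotypes`][simulate_genotypes] object (variants, dosage,
#'   haplotypes).
#' @export
read_phased_vcf <- function(path, chrom_style = "keep") {
  if (!file.exists(path)) .io_error("file not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  ok_snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"]) & fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  phased <- matrix(grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
  ok <- ok_snp & rowSums(!phased) == 0L & !is.na(fix[, "POS"])
  n_skip <- sum(!ok)
  if (n_skip > 0)
    message(sprintf("read_phased_vcf: skipped %d unphased/multiallelic/non-SNP records", n_skip))
  if (!any(ok)) .io_error("no usable phased biallelic SNP records in %s", path)
  fix <- fix[ok, , drop = FALSE]
  gt <- gt[ok, , drop = FALSE]
  h1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  n_ind <- ncol(gt)
  hap <- matrix(0L, nrow = nrow(gt), ncol = 2L * n_ind)
  hap[, seq(1L, 2L * n_ind, 2L)] <- h1
  hap[, seq(2L, 2L * n_ind, 2L)] <- h2
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix[is.na(ids) | ids == ".", "CHROM"],
                                          fix[is.na(ids) | ids == ".", "POS"])
  variants <- data.frame(
    chrom = normalize_chrom(fix[, "CHROM"], chrom_style),
    pos = as.integer(fix[, "POS"]), id = ids,
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE
  )
  dosage <- (h1 + h2) / 2
  rownames(dosage) <- rownames(hap) <- variants$id
  colnames(dosage) <- colnames(gt)
  colnames(hap) <- paste0(rep(colnames(gt), each = 2L), c("_h1", "_h2"))
  structure(list(variants = variants, dosage = dosage, haplotypes = hap),
            class = "pool_genotypes")
}

#' Write phased genotypes as VCF v4.2
#'
#' Emits `GT` fields with `|` separators, suitable for [read_phased_vcf()]
#' round-trips.
#'
#' @param genotypes a [`pool_genotypes`][simulate_genotypes] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  hap <- genotypes$haplotypes
  samples <- colnames(genotypes$dosage)
  n_ind <- length(samples)
  gt <- matrix(paste(hap[, seq(1L, 2L * n_ind, 2L), drop = FALSE],
                     hap[, seq(2L, 2L * n_ind, 2L), drop = FALSE], sep = "|"),
               nrow = nrow(hap))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- do.call(paste, c(list(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS",
                                ".", "GT"),
                           lapply(seq_len(n_ind), function(j) gt[, j]),
                           sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

.parse_coords <- function(fields, path, idx, ncol_min) {
  bad <- lengths(fields) < ncol_min
  if (any(bad))
    .io_error("%s: malformed line %d (expected >= %d fields)", path,
              idx[which(bad)[1]], ncol_min)
  fields
}

.check_interval <- function(start, end, path, idx) {
  if (any(is.na(start) | is.na(end)))
    .io_error("%s: non-numeric coordinate at line %d", path,
              idx[which(is.na(start) | is.na(end))[1]])
  if (any(start < 0))
    .io_error("%s: negative coordinate at line %d", path, idx[which(start < 0)[1]])
  if (any(end <= start))
    .io_error("%s: end <= start at line %d", path, idx[which(end <= start)[1]])
}

#' Read a BED3+ interval file
#'
#' @param path BED file (0-based half-open; optionally gzipped); narrowPeak
#'   files work, extra columns land in `name`/`score`.
#' @param chrom_style passed to [normalize_chrom()].
#' @return data.frame (chrom, start, end\[, name, score\]).
#' @export
read_bed <- function(path, chrom_style = "keep") {
  lines <- .open_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- .parse_coords(strsplit(lines[keep], "\t"), path, idx, 3L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  .check_interval(start, end, path, idx)
  out <- data.frame(chrom = normalize_chrom(vapply(fields, `[`, "", 1L), chrom_style),
                    start = start, end = end, stringsAsFactors = FALSE)
  if (all(lengths(fields) >= 4L)) out$name <- vapply(fields, `[`, "", 4L)
  if (all(lengths(fields) >= 5L))
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  out
}

#' Write intervals as BED
#' @param intervals data.frame (chrom, start, end, optionally name, score).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromatin loops from a BEDPE file
#'
#' Six-column BEDPE, 0-based half-open anchors; columns 7-8 become
#' `name`/`score` when present.  Same-chromosome loops must have anchor1
#' before anchor2 and non-overlapping anchors.
#'
#' @inheritParams read_bed
#' @return data.frame (chrom1, start1, end1, chrom2, start2, end2, name,
#'   score).
#' @export
read_bedpe <- function(path, chrom_style = "keep") {
  lines <- .open_lines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- .parse_coords(strsplit(lines[keep], "\t"), path, idx, 6L)
  num <- function(k) suppressWarnings(as.numeric(vapply(fields, `[`, "", k)))
  s1 <- num(2L); e1 <- num(3L); s2 <- num(5L); e2 <- num(6L)
  .check_interval(s1, e1, path, idx)
  .check_interval(s2, e2, path, idx)
  c1 <- normalize_chrom(vapply(fields, `[`, "", 1L), chrom_style)
  c2 <- normalize_chrom(vapply(fields, `[`, "", 4L), chrom_style)
  bad <- c1 == c2 & (s2 < s1 | (s2 >= s1 & e1 > s2))
  if (any(bad))
    .io_error("%s: line %d anchors out of order or overlapping", path, idx[which(bad)[1]])
  out <- data.frame(chrom1 = c1, start1 = s1, end1 = e1, chrom2 = c2,
                    start2 = s2, end2 = e2, stringsAsFactors = FALSE)
  out$name <- if (all(lengths(fields) >= 7L)) vapply(fields, `[`, "", 7L)
              else sprintf("loop%04d", seq_len(nrow(out)))
  out$score <- if (all(lengths(fields) >= 8L)) num(8L) else 0
  out
}

#' Write loops as BEDPE
#' @param loops data.frame as returned by [read_bedpe()] or [simulate_loops()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name", "score")
  write.table(loops[, intersect(cols, names(loops)), drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trait-labelled GWAS lead-SNP table
#'
#' Tab-separated with header; requires columns `trait`, `chrom`, `pos`, `id`
#' (1-based positions).  Extra columns are preserved.
#'
#' @inheritParams read_bed
#' @return data.frame grouped by `trait`.
#' @export
read_lead_snps <- function(path, chrom_style = "keep") {
  if (!file.exists(path)) .io_error("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  need <- c("trait", "chrom", "pos", "id")
  if (!all(need %in% names(df)))
    .io_error("%s: missing columns %s", path,
              paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$pos < 1)) .io_error("%s: non-positive position", path)
  df$chrom <- normalize_chrom(df$chrom, chrom_style)
  df
}

#' @rdname read_lead_snps
#' @param leads lead-SNP data.frame.
#' @param path output path.
#' @export
write_lead_snps <- function(leads, path) {
  write.table(leads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Canonical QTL-table columns.  `column_map` lets published files with other
# headers (e.g. a supplementary table) be read without editing the file:
# names are canonical, values are the file's headers.
.qtl_cols <- c("chrom", "pos", "id", "ref", "alt", "phenotype_class",
               "pre_freq", "post_freq", "depth", "p_value")

#' Read a QTL result table
#'
#' Tab-separated with header.  The canonical dialect uses columns `chrom`,
#' `pos`, `id`, `ref`, `alt`, `phenotype_class`, `pre_freq`, `post_freq`,
#' `depth`, `p_value`; `column_map` renames a foreign file's headers onto
#' these (e.g. `c(p_value = "p.overall")`).
#'
#' @inheritParams read_bed
#' @param column_map named character vector mapping canonical names to the
#'   file's column names.
#' @return data.frame in the canonical dialect.
#' @export
read_qtl_table <- function(path, column_map = NULL, chrom_style = "keep") {
  if (!file.exists(path)) .io_error("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      if (!column_map[[canon]] %in% names(df))
        .io_error("%s: mapped column '%s' not found", path, column_map[[canon]])
      names(df)[names(df) == column_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(c("chrom", "pos", "id", "p_value"), names(df))
  if (length(missing_cols) > 0)
    .io_error("%s: missing columns %s", path, paste(missing_cols, collapse = ", "))
  ok <- rep(TRUE, nrow(df))
  for (cc in intersect(c("pre_freq", "post_freq"), names(df)))
    ok <- ok & df[[cc]] >= 0 & df[[cc]] <= 1
  ok <- ok & df$p_value > 0 & df$p_value <= 1
  if ("depth" %in% names(df)) ok <- ok & df$depth >= 1
  if (any(!ok)) .io_error("%s: %d rows violate QTL-record invariants", path, sum(!ok))
  df$chrom <- normalize_chrom(df$chrom, chrom_style)
  df
}

#' @rdname read_qtl_table
#' @param qtls QTL data.frame.
#' @export
write_qtl_table <- function(qtls, path) {
  write.table(qtls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allele-tagged Hi-C contacts from TSV
#'
#' Accepts the package's own contact dialect (chromA, posA, chromB, posB,
#' snp_id, allele) or any validPairs-like table via `column_map`.
#'
#' @inheritParams read_qtl_table
#' @return data.frame of contacts.
#' @export
read_contacts <- function(path, column_map = NULL, chrom_style = "keep") {
  if (!file.exists(path)) .io_error("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (!is.null(column_map))
    for (canon in names(column_map))
      names(df)[names(df) == column_map[[canon]]] <- canon
  need <- c("chromA", "posA", "chromB", "posB", "snp_id", "allele")
  if (!all(need %in% names(df)))
    .io_error("%s: missing columns %s", path,
              paste(setdiff(need, names(df)), collapse = ", "))
  df$chromA <- normalize_chrom(df$chromA, chrom_style)
  df$chromB <- normalize_chrom(df$chromB, chrom_style)
  df
}

#' @rdname read_contacts
#' @param contacts contact data.frame.
#' @export
write_contacts <- function(contacts, path) {
  write.table(contacts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-count table (id, ref_count, alt_count, depth)
#' @inheritParams read_bed
#' @return data.frame of per-SNP counts.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) .io_error("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "ref_count", "alt_count")
  if (!all(need %in% names(df)))
    .io_error("%s: missing columns %s", path,
              paste(setdiff(need, names(df)), collapse = ", "))
  if (!"depth" %in% names(df)) df$depth <- df$ref_count + df$alt_count
  df
}

#' @rdname read_counts
#' @param counts counts data.frame.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
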