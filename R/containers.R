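# Core in-memory containers. Coordinate conventions: variant positions are
# 1-based inclusive in memory; tract intervals are half-open 0-based
# ([start, end)), matching BED on disk. A variant at 1-based position p lies
# in tract [s, e) iff s <= p - 1 < e.

#' Construct a phased haplotype panel
#'
#' A `haplotype_panel` stores phased biallelic genotypes as a binary
#' haplotype-by-variant matrix (0 = REF, 1 = ALT, NA = missing) together with
#' the variant table and the sample ordering. Haplotype rows are ordered
#' `sample1:hap0, sample1:hap1, sample2:hap0, ...`. The ancestral allele
#' annotation (needed by the nSL scan) defaults to the reference allele.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, optionally `id` and `ancestral`.
#' @param alleles integer matrix, `2 * n_samples` rows by `nrow(variants)`
#'   columns, entries in \{0, 1, NA\}.
#' @param sample_ids character vector of sample names.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, alleles, sample_ids) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (is.null(variants$id)) {
    variants$id <- paste0(variants$chrom, "_", variants$pos, "_",
                          variants$ref, "_", variants$alt)
  }
  if (is.null(variants$ancestral)) variants$ancestral <- variants$ref
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(sample_ids)) {
    stopf("alleles has %d rows; expected 2 x %d samples",
          nrow(alleles), length(sample_ids))
  }
  if (ncol(alleles) != nrow(variants)) {
    stopf("alleles has %d columns for %d variants", ncol(alleles), nrow(variants))
  }
  bad <- alleles[!is.na(alleles) & alleles != 0L & alleles != 1L]
  if (length(bad)) stopf("allele entries must be 0, 1 or NA")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stopf("variant positions must be strictly increasing within %s", ch)
    }
  }
  rownames(alleles) <- paste0(rep(sample_ids, each = 2L), ":", rep(0:1, length(sample_ids)))
  colnames(alleles) <- variants$id
  structure(list(variants = variants, alleles = alleles,
                 sample_ids = as.character(sample_ids)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d samples (%d haplotypes) x %d variants\n",
              length(x$sample_ids), nrow(x$alleles), nrow(x$variants)))
  invisible(x)
}

#' Diploid alternate-allele dosage matrix
#'
#' @param panel A [haplotype_panel()].
#' @return Numeric matrix, samples x variants, entries 0/1/2 (NA if either
#'   haplotype is missing).
#' @export
dosage <- function(panel) {
  a <- panel$alleles
  idx0 <- seq(1L, nrow(a), by = 2L)
  d <- a[idx0, , drop = FALSE] + a[idx0 + 1L, , drop = FALSE]
  rownames(d) <- panel$sample_ids
  d
}

#' Construct an anchored phenotype table
#'
#' Phenotype-by-sample matrix with one genomic anchor (TSS or CpG position)
#' per phenotype; the anchor drives the cis-window definition in the QTL scan.
#'
#' @param values numeric matrix, phenotypes x samples.
#' @param anchors data.frame with `phenotype_id`, `chrom`, `pos`, `strand`.
#' @param sample_ids character vector matching `ncol(values)`.
#' @return An object of class `phenotype_table`.
#' @export
phenotype_table <- function(values, anchors, sample_ids) {
  values <- as.matrix(values)
  anchors <- as.data.frame(anchors, stringsAsFactors = FALSE)
  stopifnot(all(c("phenotype_id", "chrom", "pos") %in% names(anchors)))
  if (is.null(anchors$strand)) anchors$strand <- "+"
  if (nrow(values) != nrow(anchors)) stopf("one anchor per phenotype required")
  if (ncol(values) != length(sample_ids)) stopf("values/sample_ids mismatch")
  if (anyDuplicated(anchors$phenotype_id)) stopf("duplicate phenotype ids")
  rownames(values) <- anchors$phenotype_id
  colnames(values) <- sample_ids
  structure(list(values = values, anchors = anchors,
                 sample_ids = as.character(sample_ids)),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("<phenotype_table> %d phenotypes x %d samples\n",
              nrow(x$values), length(x$sample_ids)))
  invisible(x)
}

TRACT_LABELS <- c("ASIAN", "PAPUAN", "UNKNOWN", "DENISOVAN", "NEANDERTHAL")

#' Construct a per-haplotype ancestry tract set
#'
#' Intervals are half-open, 0-based (`[start, end)`), per sample and
#' haplotype (hap 0 or 1). Modern-ancestry layers use labels
#' ASIAN/PAPUAN/UNKNOWN and must tile the chromosome per haplotype; archaic
#' layers use DENISOVAN/NEANDERTHAL and may be sparse.
#'
#' @param records data.frame with `chrom`, `start`, `end`, `sample_id`,
#'   `hap`, `label`.
#' @return An object of class `ancestry_tracts` (a data.frame).
#' @export
ancestry_tracts <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "sample_id", "hap", "label") %in% names(records)))
  if (nrow(records)) {
    if (any(records$start >= records$end)) stopf("tract start must be < end")
    if (any(records$hap != 0L & records$hap != 1L)) stopf("hap must be 0 or 1")
    bad <- setdiff(unique(records$label), TRACT_LABELS)
    if (length(bad)) stopf("unknown tract label(s): %s", paste(bad, collapse = ", "))
  }
  o <- order(records$sample_id, records$hap, records$chrom, records$start)
  records <- records[o, , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("ancestry_tracts", "data.frame")
  records
}

# Check the tiling invariant of a modern-ancestry layer.
assert_tiling <- function(tracts, chrom_length) {
  sp <- split(tracts, paste(tracts$sample_id, tracts$hap))
  for (t in sp) {
    t <- t[order(t$start), ]
    if (t$start[1] != 0 || t$end[nrow(t)] != chrom_length ||
        (nrow(t) > 1 && any(t$start[-1] != t$end[-nrow(t)]))) {
      stopf("tracts do not tile [0, %d) for %s hap %d",
            chrom_length, t$sample_id[1], t$hap[1])
    }
  }
  invisible(TRUE)
}

#' Construct a per-variant summary-statistics table
#'
#' @param df data.frame with at least `variant_id`, `chrom`, `pos`, and a
#'   usable effect parameterization: (`beta`, `se`) or (`p`, `maf`, `n`).
#' @param dataset_id character label of the originating dataset.
#' @return An object of class `summary_stats` (a data.frame).
#' @export
summary_stats <- function(df, dataset_id = "dataset") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(df)))
  for (col in c("beta", "se", "p", "maf", "n")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  if (any(!is.na(df$se) & df$se <= 0)) stopf("se must be > 0 where present")
  if (any(!is.na(df$p) & (df$p <= 0 | df$p > 1))) stopf("p must be in (0, 1]")
  if (any(!is.na(df$maf) & (df$maf <= 0 | df$maf > 0.5))) {
    stopf("maf must be in (0, 0.5]")
  }
  attr(df, "dataset_id") <- dataset_id
  class(df) <- c("summary_stats", "data.frame")
  df
}
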