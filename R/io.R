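# Readers/writers for the on-disk formats (phased VCF 4.2, BED-style tract
# and phenotype tables, summary-statistic TSV, YAML config, JSON ground
# truth) plus the standard QC filters and the inverse-normal transform.
# Disk convention: BED is half-open 0-based; VCF positions are 1-based.

#' Read a phased VCF into a haplotype panel
#'
#' Keeps biallelic SNPs only; multi-allelic records and indels are skipped
#' with a logged count. GT must be phased (`|`) for all included samples; a
#' missing GT (`.`) yields missing alleles. The ancestral allele is taken
#' from an `AA=` INFO key when present, otherwise the REF allele.
#'
#' @param path path to a VCF (optionally gzipped).
#' @return A [haplotype_panel()]. The number of skipped records is attached
#'   as attribute `n_skipped`.
#' @export
read_vcf_phased <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT)
  n_skipped <- sum(!is_snp)
  if (n_skipped) aq_log("info", n_skipped, " non-biallelic-SNP record(s) skipped")
  fix <- fix[is_snp, , drop = FALSE]
  gt <- gt[is_snp, , drop = FALSE]
  sample_ids <- colnames(gt)[-1L]
  fmt <- gt[, 1L]
  gt <- gt[, -1L, drop = FALSE]
  gt_idx <- vapply(strsplit(fmt, ":"), function(x) match("GT", x), integer(1))
  if (anyNA(gt_idx)) stopf("record without GT field")
  m <- nrow(fix)
  alleles <- matrix(NA_integer_, nrow = 2L * length(sample_ids), ncol = m)
  for (j in seq_len(m)) {
    cells <- gt[j, ]
    cells[is.na(cells)] <- "."
    if (gt_idx[j] != 1L) {
      cells <- vapply(strsplit(cells, ":"), `[`, character(1), gt_idx[j])
    } else {
      cells <- sub(":.*$", "", cells)
    }
    miss <- cells %in% c(".", "./.", ".|.")
    unphased <- grepl("/", cells) & !miss
    if (any(unphased)) {
      stopf("unphased GT at %s:%s sample %s", fix$CHROM[j], fix$POS[j],
            sample_ids[which(unphased)[1]])
    }
    parts <- strsplit(cells, "|", fixed = TRUE)
    a0 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
    a1 <- suppressWarnings(as.integer(vapply(parts, function(x) x[2] %||% NA_character_, character(1))))
    a0[miss] <- NA_integer_; a1[miss] <- NA_integer_
    alleles[seq(1L, by = 2L, length.out = length(sample_ids)), j] <- a0
    alleles[seq(2L, by = 2L, length.out = length(sample_ids)), j] <- a1
  }
  aa <- rep(NA_character_, m)
  if (!is.null(fix$INFO)) {
    has_aa <- !is.na(fix$INFO) & grepl("(^|;)AA=", fix$INFO)
    aa[has_aa] <- sub(".*(^|;)AA=([^;]+).*", "\\2", fix$INFO[has_aa])
  }
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, "_", fix$POS, "_", fix$REF, "_", fix$ALT),
                                     fix$ID),
                         ancestral = ifelse(is.na(aa), fix$REF, aa),
                         stringsAsFactors = FALSE)
  panel <- haplotype_panel(variants, alleles, sample_ids)
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Write a haplotype panel as a phased VCF 4.2
#'
#' @param panel A [haplotype_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  n <- length(panel$sample_ids)
  a <- panel$alleles
  gt <- matrix("", nrow = nrow(v), ncol = n)
  for (i in seq_len(n)) {
    a0 <- a[2L * i - 1L, ]; a1 <- a[2L * i, ]
    cell <- paste0(a0, "|", a1)
    cell[is.na(a0) | is.na(a1)] <- ".|."
    gt[, i] <- cell
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=admixqtl",
              paste0("##contig=<ID=", unique(v$chrom), ">"),
              "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS",
                paste0("AA=", v$ancestral), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read an ancestry tract set as BED6
#'
#' Columns: chrom, start (0-based), end (exclusive), sample_id, hap, label.
#' @param tracts An [ancestry_tracts()].
#' @param path file path.
#' @return `path` / an [ancestry_tracts()].
#' @export
write_tracts_bed <- function(tracts, path) {
  dt <- data.table::as.data.table(unclass(tracts))
  data.table::fwrite(dt[, c("chrom", "start", "end", "sample_id", "hap", "label")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_tracts_bed
#' @export
read_tracts_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "sample_id", "hap", "label"))
  ancestry_tracts(as.data.frame(dt))
}

#' Write / read a phenotype table as a BED-style matrix
#'
#' Layout: `#chr start end phenotype_id group_id strand` then one column per
#' sample. The anchor is stored as `[pos - 1, pos)`.
#' @param phen A [phenotype_table()].
#' @param path file path.
#' @return `path` / a [phenotype_table()].
#' @export
write_phenotype_bed <- function(phen, path) {
  a <- phen$anchors
  dt <- data.table::data.table(`#chr` = a$chrom, start = a$pos - 1L, end = a$pos,
                               phenotype_id = a$phenotype_id,
                               group_id = a$group %||% "phenotype",
                               strand = a$strand)
  dt <- cbind(dt, data.table::as.data.table(phen$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotype_bed
#' @export
read_phenotype_bed <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  meta <- as.data.frame(dt[, 1:6])
  names(meta) <- c("chrom", "start", "end", "phenotype_id", "group", "strand")
  anchors <- data.frame(phenotype_id = meta$phenotype_id, chrom = meta$chrom,
                        pos = meta$end, strand = meta$strand,
                        group = meta$group, stringsAsFactors = FALSE)
  values <- as.matrix(dt[, -(1:6)])
  phenotype_table(values, anchors, colnames(values))
}

#' Write / read per-variant summary statistics as TSV
#'
#' @param stats A [summary_stats()] table.
#' @param path file path.
#' @param dataset_id dataset label used when reading.
#' @return `path` / a [summary_stats()].
#' @export
write_sumstats <- function(stats, path) {
  cols <- c("variant_id", "chrom", "pos", "ref", "alt", "beta", "se", "p", "maf", "n")
  cols <- intersect(cols, names(stats))
  data.table::fwrite(data.table::as.data.table(unclass(stats))[, cols, with = FALSE],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path, dataset_id = basename(path)) {
  dt <- data.table::fread(path, header = TRUE)
  summary_stats(as.data.frame(dt), dataset_id = dataset_id)
}

#' Read / write a simulation config as YAML
#'
#' @param path YAML file mirroring the [sim_config()] fields.
#' @return A [sim_config()] / `path`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param cfg A [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))], path)
  invisible(path)
}

#' Write ground truth as JSON
#'
#' @param truth ground-truth object from [simulate_cohort()].
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(causal_map = truth$causal_map,
                            la_driven_flags = as.list(truth$la_driven_flags),
                            archaic_flags = as.list(truth$archaic_flags),
                            shared_pop_map = truth$shared_pop_map),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Genotype QC filters
#'
#' Removes variants failing MAF > `maf_min` or missingness < `miss_max`.
#' When a genotype-probability matrix is supplied, genotypes with
#' GP <= `gp_min` are first set to missing and missingness re-evaluated.
#'
#' @param panel A [haplotype_panel()].
#' @param maf_min minor-allele-frequency threshold (variants with
#'   MAF <= `maf_min` are removed; default 0.05).
#' @param miss_max maximum tolerated fraction of missing genotypes
#'   (default 0.3).
#' @param gp optional samples x variants genotype-probability matrix.
#' @param gp_min genotype-probability threshold (default 0.90).
#' @return The filtered [haplotype_panel()].
#' @export
filter_genotypes <- function(panel, maf_min = 0.05, miss_max = 0.3,
                             gp = NULL, gp_min = 0.90) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1,
            gp_min >= 0, gp_min <= 1)
  a <- panel$alleles
  if (!is.null(gp)) {
    stopifnot(nrow(gp) == length(panel$sample_ids), ncol(gp) == ncol(a))
    low <- gp <= gp_min
    low2 <- low[rep(seq_len(nrow(gp)), each = 2L), , drop = FALSE]
    a[low2] <- NA_integer_
  }
  miss <- colMeans(is.na(a))
  af <- colMeans(a, na.rm = TRUE)
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  keep <- maf > maf_min & miss < miss_max
  if (!any(keep)) warning("all variants removed by genotype QC")
  haplotype_panel(panel$variants[keep, , drop = FALSE],
                  a[, keep, drop = FALSE], panel$sample_ids)
}

#' Expression-level filter
#'
#' Keeps genes with FPKM > `min_fpkm` and read count > `min_count` in at
#' least `min_samples` samples.
#'
#' @param counts,fpkm congruent gene x sample matrices.
#' @param min_fpkm,min_count,min_samples thresholds (defaults 0.1, 6, 50).
#' @return logical keep vector, named by gene.
#' @export
filter_expression <- function(counts, fpkm, min_fpkm = 0.1, min_count = 6,
                              min_samples = 50) {
  stopifnot(all(dim(counts) == dim(fpkm)))
  if (min_samples > ncol(counts)) {
    stopf("min_samples (%d) exceeds number of samples (%d)", min_samples, ncol(counts))
  }
  ok <- rowSums(fpkm > min_fpkm & counts > min_count) >= min_samples
  stats::setNames(ok, rownames(counts))
}

#' Rank-based inverse-normal transform
#'
#' Maps values to `qnorm((rank - 0.5) / n)` with ties broken by average
#' rank; preserves rank order and is invariant to monotone transforms of the
#' input. Operates per row when given a matrix.
#'
#' @param x numeric vector or matrix (rows = phenotypes).
#' @return transformed vector/matrix of the same shape.
#' @export
inverse_normal_transform <- function(x) {
  one <- function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 3) stopf("inverse-normal transform needs >= 3 non-missing values")
    if (length(unique(v[ok])) == 1L) {
      warning("all values identical; inverse-normal transform returns zeros")
      v[ok] <- 0
      return(v)
    }
    r <- rank(v[ok], ties.method = "average")
    v[ok] <- qnorm((r - 0.5) / sum(ok))
    v
  }
  if (is.matrix(x)) t(apply(x, 1L, one)) else one(x)
}
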