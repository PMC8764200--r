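# nSL selection scan: per-SNP number-of-segregating-sites-by-length
# statistic contrasting haplotype homozygosity tract lengths of ancestral
# vs derived allele carriers, frequency-bin normalization, 50-kb window
# test statistic with the 30% outlier rule, and rank-based empirical p
# values.

#' Per-SNP raw nSL statistic for a whole panel
#'
#' For every pair of haplotypes within the ancestral (A) and derived (D)
#' allele classes at each focal SNP, computes the number of consecutive
#' segregating sites over which the pair is identical in the maximal
#' interval containing the focal site; `SL_A` and `SL_D` are the class-wise
#' pair means and `raw_nsl = ln(SL_A / SL_D)`. Negative values mean the
#' derived class is more haplotype-homozygous (sweep-like). Variants with
#' missing alleles are excluded (logged); SNPs with an allele class of size
#' < 2 or without an ancestral annotation matching REF or ALT are skipped
#' with a reason code.
#'
#' Pairwise extension is truncated at `max_extend` segregating sites per
#' flank, and physical gaps larger than `max_gap` bp act as barriers, the
#' configurable analogues of selscan's decay cap and maximum gap.
#'
#' @param panel A [haplotype_panel()] with phased, complete haplotypes.
#' @param max_extend maximum extension, in loci per flank (default 1333).
#' @param max_gap maximum allowed physical gap in bp (default 50000).
#' @return data.frame per SNP: `variant_id`, `pos`, `daf`, `raw_nsl`,
#'   `n_anc`, `n_der`, `skip_reason` (NA when computed).
#' @export
nsl_scan <- function(panel, max_extend = 1333L, max_gap = 50000) {
  H <- panel$alleles
  v <- panel$variants
  has_na <- colSums(is.na(H)) > 0L
  if (any(has_na)) {
    aq_log("info", sum(has_na), " variant(s) with missing alleles excluded from nSL")
    H <- H[, !has_na, drop = FALSE]
    v <- v[!has_na, , drop = FALSE]
  }
  m <- nrow(v)
  n_hap <- nrow(H)
  # derived coding: 1 = derived allele
  anc_is_ref <- v$ancestral == v$ref
  anc_is_alt <- v$ancestral == v$alt
  annotated <- anc_is_ref | anc_is_alt
  Hd <- H
  if (any(anc_is_alt)) {
    Hd[, anc_is_alt] <- 1L - Hd[, anc_is_alt, drop = FALSE]
  }
  daf <- colMeans(Hd)
  n_der <- round(daf * n_hap)
  n_anc <- n_hap - n_der
  # gap barriers between consecutive sites (applied to every pair)
  gaps <- which(diff(v$pos) > max_gap)
  gap_bar <- gaps + 0.5
  slA <- numeric(m); cntA <- numeric(m)
  slD <- numeric(m); cntD <- numeric(m)
  cap <- 2 * max_extend + 1
  s_seq <- seq_len(m)
  for (a in seq_len(n_hap - 1L)) {
    ha <- Hd[a, ]
    wa0 <- 1 - ha
    for (b in seq.int(a + 1L, n_hap)) {
      hb <- Hd[b, ]
      mism <- which(ha != hb)
      bar <- c(0, sort(c(mism, gap_bar)), m + 1)
      i <- findInterval(s_seq - 0.25, bar)
      j <- findInterval(s_seq + 0.25, bar)
      ext <- ceiling(bar[j + 1L]) - floor(bar[i]) - 1
      ext <- pmin(ext, cap)
      wA <- wa0 * (1 - hb)
      wD <- ha * hb
      slA <- slA + ext * wA
      cntA <- cntA + wA
      slD <- slD + ext * wD
      cntD <- cntD + wD
    }
  }
  raw <- rep(NA_real_, m)
  ok <- annotated & cntA >= 1 & cntD >= 1
  raw[ok] <- log((slA[ok] / cntA[ok]) / (slD[ok] / cntD[ok]))
  reason <- rep(NA_character_, m)
  reason[!annotated] <- "no_ancestral_annotation"
  reason[annotated & (cntA < 1 | cntD < 1)] <- "allele_class_too_small"
  data.frame(variant_id = v$id, pos = v$pos, daf = daf,
             raw_nsl = raw, n_anc = n_anc, n_der = n_der,
             skip_reason = reason, stringsAsFactors = FALSE)
}

#' Raw nSL at a single focal SNP
#'
#' @param panel A [haplotype_panel()].
#' @param focal variant index or id.
#' @inheritParams nsl_scan
#' @return scalar raw nSL (NA when skipped).
#' @export
nsl_per_snp <- function(panel, focal, max_extend = 1333L, max_gap = 50000) {
  res <- nsl_scan(panel, max_extend, max_gap)
  if (is.character(focal)) focal <- match(focal, res$variant_id)
  res$raw_nsl[focal]
}

#' Normalize raw nSL scores within derived-allele-frequency bins
#'
#' Within each of `n_bins` equal-width DAF bins, subtracts the bin mean and
#' divides by the bin SD. Bins with fewer than 2 scores or zero SD yield
#' missing normalized values (logged).
#'
#' @param raw raw nSL values.
#' @param daf derived allele frequencies (same length).
#' @param n_bins number of frequency bins (default 10).
#' @return vector of normalized scores (NA where undefined).
#' @export
normalize_nsl <- function(raw, daf, n_bins = 10L) {
  stopifnot(length(raw) == length(daf))
  bin <- cut(daf, breaks = seq(0, 1, length.out = n_bins + 1L),
             include.lowest = TRUE)
  out <- rep(NA_real_, length(raw))
  for (b in levels(bin)) {
    sel <- which(bin == b & !is.na(raw))
    if (length(sel) < 2L) {
      if (length(sel) == 1L) aq_log("info", "frequency bin ", b, " has a single SNP; normalized value missing")
      next
    }
    s <- sd(raw[sel])
    if (s == 0) {
      warning(sprintf("frequency bin %s has zero SD; normalized values missing", b))
      next
    }
    out[sel] <- (raw[sel] - mean(raw[sel])) / s
  }
  out
}

#' Windowed nSL test statistic and outlier call
#'
#' Non-overlapping windows anchored at position 0. Per window: the number
#' of SNPs with a normalized score, the proportion with
#' `|normalized| > extreme`, the outlier flag
#' (`prop_extreme > outlier_prop`), and a rank-based empirical p value of
#' the proportion across retained windows. Windows with fewer than
#' `min_snps` scored SNPs are discarded.
#'
#' @param normalized normalized nSL scores (NA allowed; NA scores do not
#'   count toward `n_snps`).
#' @param positions 1-based SNP positions.
#' @param window window size in bp (default 50,000).
#' @param min_snps minimum scored SNPs per retained window (default 21).
#' @param extreme |score| threshold (default 2).
#' @param outlier_prop outlier proportion threshold (default 0.30).
#' @return data.frame per retained window: `win_start`, `win_end`,
#'   `n_snps`, `prop_extreme`, `outlier_flag`, `empirical_p`.
#' @export
window_statistics <- function(normalized, positions, window = 50000,
                              min_snps = 21L, extreme = 2, outlier_prop = 0.30) {
  stopifnot(!is.unsorted(positions))
  ok <- !is.na(normalized)
  w <- floor((positions[ok] - 1) / window)
  ext <- abs(normalized[ok]) > extreme
  n_snps <- tapply(ext, w, length)
  n_ext <- tapply(ext, w, sum)
  keep <- n_snps >= min_snps
  if (!any(keep)) {
    return(data.frame(win_start = numeric(0), win_end = numeric(0),
                      n_snps = integer(0), prop_extreme = numeric(0),
                      outlier_flag = logical(0), empirical_p = numeric(0)))
  }
  wid <- as.numeric(names(n_snps))[keep]
  prop <- as.numeric(n_ext[keep] / n_snps[keep])
  data.frame(win_start = wid * window, win_end = (wid + 1) * window,
             n_snps = as.integer(n_snps[keep]), prop_extreme = prop,
             outlier_flag = prop > outlier_prop,
             empirical_p = empirical_p(prop), row.names = NULL)
}

#' Rank-based empirical p values
#'
#' `p_i = rank_i / N` with rank 1 assigned to the largest (most extreme)
#' value and ties sharing the mean rank, i.e. sorting all scores and
#' dividing the rank by the total number of values.
#'
#' @param values numeric vector (length >= 1).
#' @return empirical p values in `(0, 1]`.
#' @export
empirical_p <- function(values) {
  if (!length(values)) stopf("empirical_p needs >= 1 value")
  rank(-values, ties.method = "average") / length(values)
}

#' Heuristic colocalization of QTL and nSL selection signals
#'
#' Converts both sides to Wakefield ABFs via the (p, MAF, n) route -- the
#' selection side using rank-based empirical nSL p values -- and runs the
#' standard posterior computation. The selection side's empirical p values
#' are not sampling p values, so this is an exploratory ranking device, not
#' a calibrated posterior; results should be read comparatively.
#'
#' @param qtl_stats [summary_stats()] for the QTL trait.
#' @param nsl_stats [summary_stats()] with `p` = empirical nSL p, plus
#'   `maf` and `n`.
#' @param priors A [coloc_priors()].
#' @param prior_sd Wakefield prior SD.
#' @return A `coloc_result` with a `label`.
#' @export
selection_qtl_overlap <- function(qtl_stats, nsl_stats,
                                  priors = coloc_priors(), prior_sd = 0.15) {
  gwas_coloc(qtl_stats, nsl_stats, priors, prior_sd)
}
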