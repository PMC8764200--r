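# Attribution of QTLs to modern local ancestry or archaic introgression:
# ancestry/archaic dosage construction from tract intervals, the
# V = alpha x PAP + beta regression with the R^2 > 0.7 rule, intersection
# filtering of archaic haplotype calls, and per-SNP REF/ALT-on-archaic
# annotation.

# Per-haplotype interval lookup: label covering each 1-based position, NA
# when uncovered. Records must be non-overlapping within the haplotype.
hap_label_at <- function(starts, ends, labels, pos) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; labels <- labels[o]
  idx <- findInterval(pos - 1, starts)
  out <- rep(NA_character_, length(pos))
  ok <- idx >= 1L
  ok[ok] <- pos[ok] - 1 < ends[idx[ok]]
  out[ok] <- labels[idx[ok]]
  out
}

#' Local-ancestry dosage at variant positions
#'
#' For each sample and variant, counts the haplotypes whose tract labeled
#' `label` covers the variant position (half-open intervals: position `p`
#' is in `[start, end)` iff `start <= p - 1 < end`, so a position on a
#' boundary belongs to the right-hand tract). For the modern layer the
#' dosage is missing when any covering tract is UNKNOWN (pairwise deletion
#' downstream, avoiding bias toward zero) or when a haplotype has no
#' covering record (logged).
#'
#' @param tracts An [ancestry_tracts()] layer.
#' @param positions 1-based variant positions.
#' @param sample_ids cohort sample ordering.
#' @param label tract label to count (`"PAPUAN"`, `"DENISOVAN"`,
#'   `"NEANDERTHAL"`).
#' @param sparse treat uncovered positions as 0 rather than missing
#'   (appropriate for archaic layers, which do not tile the chromosome);
#'   default `TRUE` for archaic labels.
#' @return samples x positions integer matrix with entries 0/1/2/NA.
#' @export
ancestry_dosage <- function(tracts, positions, sample_ids, label = "PAPUAN",
                            sparse = label %in% c("DENISOVAN", "NEANDERTHAL")) {
  n <- length(sample_ids)
  m <- length(positions)
  out <- matrix(0L, n, m, dimnames = list(sample_ids, NULL))
  key <- paste(tracts$sample_id, tracts$hap)
  sp <- split(seq_len(nrow(tracts)), key)
  n_outside <- 0L
  for (i in seq_len(n)) {
    acc <- integer(m)
    nas <- logical(m)
    for (h in 0:1) {
      rows <- sp[[paste(sample_ids[i], h)]]
      if (is.null(rows)) {
        lab <- rep(NA_character_, m)
      } else {
        lab <- hap_label_at(tracts$start[rows], tracts$end[rows],
                            tracts$label[rows], positions)
      }
      if (sparse) {
        acc <- acc + as.integer(!is.na(lab) & lab == label)
      } else {
        uncov <- is.na(lab)
        n_outside <- n_outside + sum(uncov)
        nas <- nas | uncov | (lab == "UNKNOWN" & !uncov)
        acc <- acc + as.integer(!is.na(lab) & lab == label)
      }
    }
    if (!sparse && any(nas)) acc[nas] <- NA_integer_
    out[i, ] <- acc
  }
  if (n_outside > 0) {
    aq_log("info", n_outside, " haplotype-position pair(s) outside all tracts -> missing")
  }
  out
}

#' Regress a genotype vector on an ancestry dosage (V = alpha x PAP + beta)
#'
#' OLS of the count of QTL B alleles on the ancestry dosage; R^2 is the
#' squared Pearson correlation and the variant is flagged ancestry-driven
#' when `R^2 > r2_threshold`. Samples with missing values are excluded
#' pairwise; a constant regressor yields a record with missing R^2 and a
#' warning.
#'
#' @param v genotype dosage vector (0/1/2).
#' @param pap ancestry dosage vector (0/1/2, NA allowed).
#' @param r2_threshold flagging threshold (default 0.7).
#' @param variant_id optional id stamped on the record.
#' @return one-row data.frame: `variant_id`, `alpha`, `beta0`, `r2`,
#'   `n_used`, `driven_flag`.
#' @export
la_driven_fit <- function(v, pap, r2_threshold = 0.7, variant_id = NA_character_) {
  ok <- !is.na(v) & !is.na(pap)
  if (sum(ok) < 3) stopf("need >= 3 samples with non-missing V and PAP")
  v <- v[ok]; pap <- pap[ok]
  if (length(unique(pap)) < 2L) {
    warning("ancestry dosage is constant; R^2 undefined")
    return(data.frame(variant_id = variant_id, alpha = NA_real_,
                      beta0 = NA_real_, r2 = NA_real_, n_used = length(v),
                      driven_flag = FALSE, stringsAsFactors = FALSE))
  }
  alpha <- cov(v, pap) / var(pap)
  beta0 <- mean(v) - alpha * mean(pap)
  r2 <- if (var(v) == 0) 0 else cor(v, pap)^2
  data.frame(variant_id = variant_id, alpha = alpha, beta0 = beta0, r2 = r2,
             n_used = length(v), driven_flag = is.finite(r2) && r2 > r2_threshold,
             stringsAsFactors = FALSE)
}

#' @rdname la_driven_fit
#' @param den archaic dosage vector (Denisovan or Neanderthal).
#' @export
archaic_driven_fit <- function(v, den, r2_threshold = 0.7,
                               variant_id = NA_character_) {
  la_driven_fit(v, den, r2_threshold, variant_id)
}

#' Attribute QTL variants to an ancestry layer
#'
#' Runs [la_driven_fit()] for each QTL top variant against the dosage of
#' the requested layer. Intended to be applied to FDR-significant QTLs.
#'
#' @param variant_ids QTL variants to test.
#' @param panel A [haplotype_panel()].
#' @param tracts the tract layer carrying `layer` labels.
#' @param layer `"PAPUAN"`, `"DENISOVAN"` or `"NEANDERTHAL"`.
#' @param r2_threshold flagging threshold (default 0.7).
#' @return data.frame of fits, one row per variant.
#' @export
ancestry_qtl_attribution <- function(variant_ids, panel, tracts,
                                     layer = c("PAPUAN", "DENISOVAN", "NEANDERTHAL"),
                                     r2_threshold = 0.7) {
  layer <- match.arg(layer)
  idx <- match(variant_ids, panel$variants$id)
  if (anyNA(idx)) stopf("unknown variant id(s)")
  pos <- panel$variants$pos[idx]
  ad <- ancestry_dosage(tracts, pos, panel$sample_ids, layer)
  D <- dosage(panel)[, idx, drop = FALSE]
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    out[[k]] <- withCallingHandlers(
      la_driven_fit(D[, k], ad[, k], r2_threshold, variant_ids[k]),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  do.call(rbind, out)
}

ir_from <- function(d) IRanges::IRanges(start = d$start + 1L, end = d$end)

# Total bp overlap of each interval in `a` with the union of intervals `b`.
overlap_bp <- function(a, b) {
  if (!length(b)) return(rep(0, length(a)))
  br <- IRanges::reduce(b)
  hits <- IRanges::findOverlaps(a, br)
  ov <- IRanges::width(IRanges::pintersect(a[S4Vectors::queryHits(hits)],
                                           br[S4Vectors::subjectHits(hits)]))
  out <- rep(0, length(a))
  tab <- tapply(ov, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(tab))] <- tab
  out
}

#' High-confidence archaic haplotype filter
#'
#' Starting from ChromoPainter-style Denisovan calls, keeps each interval
#' iff its overlap fraction with the first HMM call set exceeds
#' `min_overlap_frac` AND with the second HMM set exceeds
#' `min_overlap_frac` AND its overlap with the Neanderthal call set is at
#' most `min_overlap_frac` (fractions of the filtered interval's own
#' length). The mirrored rule builds the Neanderthal high-confidence set by
#' passing Neanderthal calls as `cp_d` and Denisovan calls as `cp_n`.
#' Filtering is per haplotype and order-independent.
#'
#' @param cp_d intervals to filter ([ancestry_tracts()]-like data.frame).
#' @param hmm1,hmm2 supporting interval sets (must overlap).
#' @param cp_n conflicting interval set (must not overlap).
#' @param min_overlap_frac overlap fraction threshold (default 1e-5, the
#'   ">0.001%" rule).
#' @return the retained subset of `cp_d` rows.
#' @export
high_confidence_archaic <- function(cp_d, hmm1, hmm2, cp_n,
                                    min_overlap_frac = 1e-5) {
  for (d in list(cp_d, hmm1, hmm2, cp_n)) {
    if (nrow(d) && any(d$end <= d$start)) stopf("zero-length interval")
  }
  if (!nrow(cp_d)) return(cp_d)
  keys <- paste(cp_d$sample_id, cp_d$hap)
  keep <- logical(nrow(cp_d))
  for (k in unique(keys)) {
    sel <- keys == k
    a <- ir_from(cp_d[sel, , drop = FALSE])
    sub <- function(d) {
      s <- paste(d$sample_id, d$hap) == k
      ir_from(d[s, , drop = FALSE])
    }
    len <- IRanges::width(a)
    f1 <- overlap_bp(a, sub(hmm1)) / len
    f2 <- overlap_bp(a, sub(hmm2)) / len
    fn <- overlap_bp(a, sub(cp_n)) / len
    keep[sel] <- f1 > min_overlap_frac & f2 > min_overlap_frac &
      fn <= min_overlap_frac
  }
  out <- cp_d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate SNPs by REF/ALT occurrence on high-confidence archaic haplotypes
#'
#' For each SNP and each sample group, counts group haplotypes covered by a
#' high-confidence interval that carry the ALT state, and those carrying
#' REF. SNPs monomorphic within the group are skipped with a reason code.
#'
#' @param panel A [haplotype_panel()].
#' @param high_confidence filtered interval set (from
#'   [high_confidence_archaic()]).
#' @param groups named list of sample-id vectors.
#' @return list with `counts` (variant_id, group, ref_on_archaic,
#'   alt_on_archaic) and `skipped` (variant_id, group, reason).
#' @export
annotate_snps_on_archaic <- function(panel, high_confidence, groups) {
  pos <- panel$variants$pos
  counts <- list(); skipped <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (!length(ids)) stopf("group '%s' has zero haplotypes", g)
    if (!all(ids %in% panel$sample_ids)) stopf("group '%s' has unknown samples", g)
    hap_rows <- as.vector(rbind(2L * match(ids, panel$sample_ids) - 1L,
                                2L * match(ids, panel$sample_ids)))
    A <- panel$alleles[hap_rows, , drop = FALSE]
    cov <- matrix(FALSE, length(hap_rows), ncol(A))
    key <- paste(high_confidence$sample_id, high_confidence$hap)
    sp <- split(seq_len(nrow(high_confidence)), key)
    for (r in seq_along(hap_rows)) {
      sid <- ids[ceiling(r / 2)]
      h <- (r + 1L) %% 2L  # rows alternate hap0, hap1
      rows <- sp[[paste(sid, h)]]
      if (is.null(rows)) next
      s <- high_confidence$start[rows]; e <- high_confidence$end[rows]
      o <- order(s)
      idx <- findInterval(pos - 1, s[o])
      ok <- idx >= 1L
      ok[ok] <- pos[ok] - 1 < e[o][idx[ok]]
      cov[r, ] <- ok
    }
    af <- colMeans(A, na.rm = TRUE)
    mono <- is.nan(af) | af == 0 | af == 1
    alt_ct <- colSums(cov & !is.na(A) & A == 1L)
    ref_ct <- colSums(cov & !is.na(A) & A == 0L)
    counts[[g]] <- data.frame(variant_id = panel$variants$id[!mono], group = g,
                              ref_on_archaic = ref_ct[!mono],
                              alt_on_archaic = alt_ct[!mono],
                              stringsAsFactors = FALSE)
    if (any(mono)) {
      skipped[[g]] <- data.frame(variant_id = panel$variants$id[mono], group = g,
                                 reason = "monomorphic_in_group",
                                 stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, counts) %||%
         data.frame(variant_id = character(), group = character(),
                    ref_on_archaic = integer(), alt_on_archaic = integer()),
       skipped = do.call(rbind, skipped) %||%
         data.frame(variant_id = character(), group = character(),
                    reason = character()))
}
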