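# Cross-dataset effect-size sharing, population-specificity classification,
# MAF contrasts relative to the target cohort's minor allele, and
# annotation enrichment against matched random variant sets.

#' Effect-size sharing rule
#'
#' Two effect estimates count as shared when they have the same (nonzero)
#' sign and their magnitudes are within a factor of 2 of each other, i.e.
#' `min(|b1|, |b2|) / max(|b1|, |b2|) >= factor` with `factor = 0.5` ("same
#' sign and within a factor of 0.5", read as effect ratio in `[0.5, 2]`).
#'
#' @param b1,b2 effect estimates.
#' @param factor magnitude-ratio threshold (default 0.5).
#' @return logical vector (NA when either effect is zero/missing).
#' @export
effects_shared <- function(b1, b2, factor = 0.5) {
  out <- sign(b1) == sign(b2) & sign(b1) != 0 &
    pmin(abs(b1), abs(b2)) / pmax(abs(b1), abs(b2)) >= factor
  out[is.na(b1) | is.na(b2) | (b1 == 0 & b2 == 0)] <- NA
  out
}

#' Pairwise sharing matrix across datasets
#'
#' For each dataset pair, the fraction of effect pairs satisfying the
#' sharing rule, conditioned on pairs significant in at least one of the
#' two datasets (the union convention; switchable to `"either"`-equivalent
#' `"both"`).
#'
#' @param betas pairs x datasets matrix of effect estimates.
#' @param significant logical matrix of the same shape.
#' @param factor magnitude-ratio threshold (default 0.5).
#' @param condition `"union"` (default: significant in i or j) or `"both"`.
#' @return dataset x dataset matrix of sharing fractions (diagonal 1).
#' @export
pairwise_sharing <- function(betas, significant, factor = 0.5,
                             condition = c("union", "both")) {
  condition <- match.arg(condition)
  stopifnot(all(dim(betas) == dim(significant)))
  K <- ncol(betas)
  ids <- colnames(betas) %||% paste0("dataset", seq_len(K))
  out <- matrix(1, K, K, dimnames = list(ids, ids))
  for (i in seq_len(K - 1)) for (j in seq.int(i + 1, K)) {
    sel <- if (condition == "union") significant[, i] | significant[, j]
           else significant[, i] & significant[, j]
    sel <- sel & !is.na(betas[, i]) & !is.na(betas[, j]) &
      !(betas[, i] == 0 & betas[, j] == 0)
    if (!any(sel)) {
      out[i, j] <- out[j, i] <- NA_real_
      next
    }
    sh <- effects_shared(betas[sel, i], betas[sel, j], factor)
    out[i, j] <- out[j, i] <- mean(sh, na.rm = TRUE)
  }
  out
}

#' Classify phenotypes as target-population specific
#'
#' A phenotype is specific to the target dataset iff it is significant
#' there, its effect is not shared (sharing rule) with any other dataset,
#' and its colocalization label against every other dataset is `"NONE"`
#' (i.e. no evidence even at the relaxed CCV > 0.5, CCV/DCV > 2 tier).
#' Candidates with a missing colocalization result are marked indeterminate,
#' never specific.
#'
#' @param significant_target logical vector per phenotype.
#' @param betas pairs x datasets matrix (first column = target).
#' @param coloc_labels phenotypes x other-datasets character matrix of
#'   [classify_coloc()] labels (NA = missing).
#' @param factor sharing-rule threshold.
#' @return data.frame: `phenotype_id`, `specific`, `indeterminate`.
#' @export
specificity_classify <- function(significant_target, betas, coloc_labels,
                                 factor = 0.5) {
  stopifnot(nrow(betas) == length(significant_target),
            nrow(coloc_labels) == length(significant_target),
            ncol(betas) == ncol(coloc_labels) + 1L)
  ids <- rownames(betas) %||% paste0("phenotype", seq_along(significant_target))
  n_other <- ncol(coloc_labels)
  specific <- logical(length(significant_target))
  indet <- logical(length(significant_target))
  for (i in seq_along(significant_target)) {
    if (!significant_target[i]) next
    labs <- coloc_labels[i, ]
    if (any(is.na(labs))) { indet[i] <- TRUE; next }
    shared_any <- FALSE
    for (k in seq_len(n_other)) {
      sh <- effects_shared(betas[i, 1L], betas[i, k + 1L], factor)
      if (isTRUE(sh)) shared_any <- TRUE
    }
    specific[i] <- !shared_any && all(labs == "NONE")
  }
  data.frame(phenotype_id = ids, specific = specific, indeterminate = indet,
             stringsAsFactors = FALSE)
}

#' MAF contrast relative to the target cohort's minor allele
#'
#' For each variant, reports the target minor allele frequency and the
#' external frequency of the *same* allele (not folded), per the convention
#' of computing both populations' frequencies in relation to the minor
#' allele of the target data. Per-set means are reported without hypothesis
#' testing.
#'
#' @param target_af named vector of target ALT allele frequencies.
#' @param external_af named vector of external ALT allele frequencies for
#'   harmonized variants (same REF/ALT orientation).
#' @param variant_sets named list of variant-id vectors (e.g. shared /
#'   specific eSNPs).
#' @return list with `per_variant` (variant_id, target_maf, external_freq)
#'   and `per_set` (set, n, mean_target_maf, mean_external_freq). Variants
#'   absent from `external_af` are dropped with a log message.
#' @export
maf_contrast <- function(target_af, external_af, variant_sets) {
  ids <- names(target_af)
  keep <- ids %in% names(external_af)
  if (any(!keep)) aq_log("info", sum(!keep), " variant(s) not harmonizable; dropped")
  ids <- ids[keep]
  ta <- target_af[ids]
  minor_is_alt <- ta <= 0.5
  target_maf <- ifelse(minor_is_alt, ta, 1 - ta)
  ext <- external_af[ids]
  external_freq <- ifelse(minor_is_alt, ext, 1 - ext)
  per_variant <- data.frame(variant_id = ids, target_maf = as.numeric(target_maf),
                            external_freq = as.numeric(external_freq),
                            stringsAsFactors = FALSE)
  per_set <- do.call(rbind, lapply(names(variant_sets), function(s) {
    sel <- per_variant$variant_id %in% variant_sets[[s]]
    data.frame(set = s, n = sum(sel),
               mean_target_maf = mean(per_variant$target_maf[sel]),
               mean_external_freq = mean(per_variant$external_freq[sel]),
               stringsAsFactors = FALSE)
  }))
  list(per_variant = per_variant, per_set = per_set)
}

#' Annotation enrichment against matched random variant sets
#'
#' Builds a null distribution from `n_sets` random variant sets drawn from
#' the pool, matching the query variant-by-variant on MAF decile and
#' distance-to-anchor decile (decile edges from the pool). The statistic is
#' the count of query variants falling inside the annotation intervals;
#' `z = (obs - mean_null) / sd_null` and
#' `empirical p = (1 + #{null >= obs}) / (n_sets + 1)`. Unmatched strata
#' fall back to the nearest stratum with a warning. A zero null SD (e.g. an
#' annotation covering everything) is reported as non-informative
#' (`z = NA`).
#'
#' @param query data.frame with `pos`, `maf`, `dist` (distance to anchor).
#' @param pool data.frame with the same columns; must be at least 10x the
#'   query size.
#' @param annotations named list of interval data.frames (`start`, `end`,
#'   half-open 0-based).
#' @param n_sets number of matched null sets (default 100).
#' @param seed RNG seed.
#' @return data.frame per annotation: `annotation`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `empirical_p`.
#' @export
matched_set_enrichment <- function(query, pool, annotations, n_sets = 100L,
                                   seed = 1L) {
  if (nrow(pool) < 10 * nrow(query)) stopf("pool must be >= 10x query size")
  set.seed(seed)
  decile <- function(x, edges) {
    findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  }
  maf_edges <- quantile(pool$maf, probs = seq(0, 1, 0.1), names = FALSE)
  dist_edges <- quantile(pool$dist, probs = seq(0, 1, 0.1), names = FALSE)
  q_strat <- paste(decile(query$maf, maf_edges), decile(query$dist, dist_edges))
  p_strat <- paste(decile(pool$maf, maf_edges), decile(pool$dist, dist_edges))
  strat_idx <- split(seq_len(nrow(pool)), p_strat)
  in_annot <- function(pos, iv) {
    if (!nrow(iv)) return(rep(FALSE, length(pos)))
    o <- order(iv$start)
    idx <- findInterval(pos - 1, iv$start[o])
    ok <- idx >= 1L
    ok[ok] <- pos[ok] - 1 < iv$end[o][idx[ok]]
    ok
  }
  # pre-resolve fallback strata
  warned <- FALSE
  draw_set <- function() {
    picks <- integer(nrow(query))
    for (i in seq_len(nrow(query))) {
      cand <- strat_idx[[q_strat[i]]]
      if (is.null(cand)) {
        if (!warned) {
          warning("unmatched stratum; sampling from nearest stratum")
          warned <<- TRUE
        }
        qm <- decile(query$maf[i], maf_edges)
        qd <- decile(query$dist[i], dist_edges)
        keys <- do.call(rbind, strsplit(names(strat_idx), " "))
        d <- abs(as.integer(keys[, 1]) - qm) + abs(as.integer(keys[, 2]) - qd)
        cand <- strat_idx[[which.min(d)]]
      }
      picks[i] <- cand[sample.int(length(cand), 1L)]
    }
    picks
  }
  null_sets <- replicate(n_sets, draw_set())
  out <- lapply(names(annotations), function(an) {
    iv <- annotations[[an]]
    obs <- sum(in_annot(query$pos, iv))
    pool_in <- in_annot(pool$pos, iv)
    null_counts <- colSums(matrix(pool_in[null_sets], nrow = nrow(query)))
    s <- sd(null_counts)
    data.frame(annotation = an, observed = obs,
               null_mean = mean(null_counts), null_sd = s,
               z = if (s > 0) (obs - mean(null_counts)) / s else NA_real_,
               empirical_p = (1 + sum(null_counts >= obs)) / (n_sets + 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
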