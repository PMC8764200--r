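# Bayesian colocalization of two association signals from summary
# statistics: Wakefield approximate Bayes factors per SNP, posterior
# probabilities of the five causal configurations (H0..H4), multi-signal
# masking, prior-sensitivity classification, and a single-causal-variant
# mode for GWAS traits without LD information.

#' Colocalization priors
#'
#' @param p1,p2 per-SNP prior probability of association with trait 1 / 2
#'   (default 1e-4).
#' @param p12 per-SNP prior probability of association with both traits
#'   (default 1e-5).
#' @param sensitivity_grid p12 values for the post hoc sensitivity analysis
#'   (default 25 log-spaced points across `[1e-8, 1e-4]`).
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         sensitivity_grid = 10^seq(-8, -4, length.out = 25)) {
  if (!(p12 > 0 && p12 <= min(p1, p2) && min(p1, p2) < 1)) {
    stopf("priors must satisfy 0 < p12 <= min(p1, p2) < 1")
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 sensitivity_grid = sort(sensitivity_grid)),
            class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' `logABF = 0.5 (log(1 - r) + r z^2)` with `z = beta / se` and
#' `r = prior_sd^2 / (prior_sd^2 + se^2)`. When betas are unavailable,
#' effect estimates are reconstructed from (p, maf, n) via the normal
#' quantile and `var(beta_hat) ~ 1 / (2 maf (1 - maf) n)`.
#'
#' @param beta,se effect estimates and standard errors (either both given,
#'   or `NULL` to use the p/maf/n route).
#' @param p,maf,n summary statistics used when `beta`/`se` are absent.
#' @param prior_sd prior SD of the true effect (Wakefield W^0.5; default
#'   0.15, the conventional value for quantitative traits).
#' @return vector of log ABFs.
#' @export
wakefield_abf <- function(beta = NULL, se = NULL, p = NULL, maf = NULL,
                          n = NULL, prior_sd = 0.15) {
  if (is.null(beta) || is.null(se)) {
    if (is.null(p) || is.null(maf) || is.null(n)) {
      stopf("need (beta, se) or (p, maf, n)")
    }
    z <- qnorm(pmin(pmax(p, 1e-300), 1) / 2, lower.tail = FALSE)
    se <- sqrt(1 / (2 * maf * (1 - maf) * n))
    beta <- z * se   # magnitude only; ABF depends on z^2
  }
  if (any(se <= 0)) stopf("se must be > 0")
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log(1 - r) + r * z^2)
}

#' Posterior probabilities of the colocalization hypotheses
#'
#' Computes PP0..PP4 for the standard five hypotheses (no association;
#' trait-1 only; trait-2 only; two distinct causal variants; one shared
#' causal variant) from per-SNP log ABFs over a common variant list, with
#' all hypothesis sums accumulated in log space. CCV (common causal
#' variant) = PP4; DCV (distinct causal variants) = PP3.
#'
#' @param labf1,labf2 log-ABF vectors over identical variant lists.
#' @param priors A [coloc_priors()].
#' @param sensitivity evaluate PP4/PP3 across `priors$sensitivity_grid`
#'   (default `TRUE`).
#' @return list of class `coloc_result`: `pp` (named PP0..PP4), `ccv`,
#'   `dcv`, `ratio`, `n_variants`, and (when requested) `sensitivity`
#'   (data.frame `p12`, `ccv`, `dcv`, `ratio`) plus
#'   `sensitivity_lower_bound`.
#' @export
coloc_posteriors <- function(labf1, labf2, priors = coloc_priors(),
                             sensitivity = TRUE) {
  m <- length(labf1)
  if (length(labf2) != m) stopf("ABF vectors differ in length")
  if (m < 2) stopf("colocalization needs >= 2 shared variants")
  ls1 <- logsumexp(labf1)
  ls2 <- logsumexp(labf2)
  ls12 <- logsumexp(labf1 + labf2)
  lcross <- logdiffexp(ls1 + ls2, ls12)   # sum_{i != j} A1_i A2_j
  pp_at <- function(p12) {
    lh <- c(0,
            log(priors$p1) + ls1,
            log(priors$p2) + ls2,
            log(priors$p1) + log(priors$p2) + lcross,
            log(p12) + ls12)
    lz <- logsumexp(lh)
    exp(lh - lz)
  }
  pp <- pp_at(priors$p12)
  names(pp) <- paste0("PP", 0:4)
  res <- list(pp = pp, ccv = pp[["PP4"]], dcv = pp[["PP3"]],
              ratio = pp[["PP4"]] / max(pp[["PP3"]], .Machine$double.xmin),
              n_variants = m)
  if (sensitivity) {
    grid <- priors$sensitivity_grid
    sens <- t(vapply(grid, function(g) {
      q <- pp_at(g)
      c(ccv = q[5], dcv = q[4], ratio = q[5] / max(q[4], .Machine$double.xmin))
    }, numeric(3)))
    res$sensitivity <- data.frame(p12 = grid, ccv = sens[, 1], dcv = sens[, 2],
                                  ratio = sens[, 3])
    pass <- res$sensitivity$ccv > 0.8 & res$sensitivity$ratio > 5
    res$sensitivity_lower_bound <- if (any(pass)) min(grid[pass]) else NA_real_
  }
  class(res) <- "coloc_result"
  res
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d variants; PP0..PP4 = %s; CCV/DCV = %.3g\n",
              x$n_variants, paste(sprintf("%.3f", x$pp), collapse = " "),
              x$ratio))
  invisible(x)
}

#' Classify a colocalization result
#'
#' STRONG: CCV > 0.8 and CCV/DCV > 5 at the default prior. ROBUST: STRONG
#' and the same classification already holds at some sensitivity-grid p12
#' below 1e-6. RELAXED_ONLY: fails STRONG but passes CCV > 0.5 and
#' CCV/DCV > 2. NONE otherwise.
#'
#' @param result A `coloc_result`.
#' @return one of `"ROBUST"`, `"STRONG"`, `"RELAXED_ONLY"`, `"NONE"`.
#' @export
classify_coloc <- function(result) {
  strong <- result$ccv > 0.8 && result$ratio > 5
  relaxed <- result$ccv > 0.5 && result$ratio > 2
  if (strong) {
    lb <- result$sensitivity_lower_bound
    if (!is.null(lb) && !is.na(lb) && lb < 1e-6) return("ROBUST")
    return("STRONG")
  }
  if (relaxed) return("RELAXED_ONLY")
  "NONE"
}

#' In-sample LD (r^2) matrix from dosages
#'
#' @param panel A [haplotype_panel()].
#' @param variant_ids variants to include (default all).
#' @return squared Pearson correlation matrix of dosages.
#' @export
ld_matrix <- function(panel, variant_ids = panel$variants$id) {
  idx <- match(variant_ids, panel$variants$id)
  if (anyNA(idx)) stopf("unknown variant id(s)")
  D <- dosage(panel)[, idx, drop = FALSE]
  r <- suppressWarnings(cor(D, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  r^2
}

#' Detect independently associated signals in one dataset
#'
#' Iteratively accepts the minimum-p variant with `p < p_thresh` among
#' variants whose r^2 with every previously accepted lead is below
#' `r2_max`; stops when no candidate remains.
#'
#' @param stats A [summary_stats()] table (must carry `p`).
#' @param ld r^2 matrix over `stats$variant_id` (rows/cols in that order).
#' @param p_thresh signal-calling threshold (default 1e-6).
#' @param r2_max maximum r^2 for two signals to count as independent
#'   (default 0.01).
#' @return character vector of lead variant ids (possibly empty).
#' @export
detect_signals <- function(stats, ld, p_thresh = 1e-6, r2_max = 0.01) {
  m <- nrow(stats)
  if (!all(dim(ld) == c(m, m))) stopf("LD matrix dimension mismatch")
  leads <- integer(0)
  avail <- rep(TRUE, m)
  p <- stats$p
  repeat {
    cand <- which(avail & !is.na(p) & p < p_thresh)
    if (!length(cand)) break
    i <- cand[which.min(p[cand])]
    leads <- c(leads, i)
    avail <- avail & ld[, i] < r2_max
    avail[i] <- FALSE
  }
  stats$variant_id[leads]
}

align_stats <- function(stats1, stats2) {
  shared <- intersect(stats1$variant_id, stats2$variant_id)
  if (length(shared) < 2) stopf("fewer than 2 shared variants")
  list(s1 = stats1[match(shared, stats1$variant_id), , drop = FALSE],
       s2 = stats2[match(shared, stats2$variant_id), , drop = FALSE],
       shared = shared)
}

stats_to_labf <- function(s, prior_sd = 0.15) {
  if (all(!is.na(s$beta)) && all(!is.na(s$se))) {
    wakefield_abf(beta = s$beta, se = s$se, prior_sd = prior_sd)
  } else {
    wakefield_abf(p = s$p, maf = s$maf, n = s$n, prior_sd = prior_sd)
  }
}

#' Colocalization of two traits with multi-signal masking
#'
#' Detects independent signals in each dataset; when either trait carries
#' several, every (signal_i, signal_j) pair is tested on the variant subset
#' with r^2 below `r2_max` to every *other* lead of its own dataset
#' ("any-but-one" masking). With one signal each, reduces to the unmasked
#' test.
#'
#' @param stats1,stats2 [summary_stats()] tables.
#' @param ld r^2 matrix over the union of variant ids (dimnames required),
#'   e.g. from [ld_matrix()].
#' @param priors A [coloc_priors()].
#' @param p_thresh,r2_max signal detection parameters (defaults 1e-6, 0.01).
#' @param prior_sd Wakefield prior SD.
#' @return list of `coloc_result`s, each annotated with `signal_pair`
#'   (lead ids) and `label`.
#' @export
coloc_with_masking <- function(stats1, stats2, ld, priors = coloc_priors(),
                               p_thresh = 1e-6, r2_max = 0.01,
                               prior_sd = 0.15) {
  al <- align_stats(stats1, stats2)
  ids <- al$shared
  if (is.null(dimnames(ld))) stopf("LD matrix needs dimnames")
  ld_s <- ld[ids, ids, drop = FALSE]
  leads1 <- detect_signals(al$s1, ld_s, p_thresh, r2_max)
  leads2 <- detect_signals(al$s2, ld_s, p_thresh, r2_max)
  run_one <- function(keep, pair_label) {
    res <- coloc_posteriors(stats_to_labf(al$s1[keep, , drop = FALSE], prior_sd),
                            stats_to_labf(al$s2[keep, , drop = FALSE], prior_sd),
                            priors)
    res$signal_pair <- pair_label
    res$label <- classify_coloc(res)
    res
  }
  first_or_na <- function(x) if (length(x)) x[1] else NA_character_
  if (length(leads1) <= 1 && length(leads2) <= 1) {
    return(list(run_one(rep(TRUE, length(ids)),
                        c(first_or_na(leads1), first_or_na(leads2)))))
  }
  out <- list()
  l1 <- if (length(leads1)) leads1 else NA_character_
  l2 <- if (length(leads2)) leads2 else NA_character_
  for (a in l1) for (b in l2) {
    keep <- rep(TRUE, length(ids))
    for (other in setdiff(leads1, a)) keep <- keep & ld_s[, other] < r2_max
    for (other in setdiff(leads2, b)) keep <- keep & ld_s[, other] < r2_max
    if (sum(keep) < 2) {
      aq_log("info", "masked variant set < 2 for pair ", a, " x ", b, "; skipped")
      next
    }
    out[[length(out) + 1L]] <- run_one(keep, c(a, b))
  }
  out
}

#' Single-causal-variant colocalization (GWAS mode)
#'
#' Unmasked colocalization on the variant intersection, for trait pairs
#' where no LD information is available (e.g. public GWAS summary
#' statistics), hence no multi-signal masking is attempted.
#'
#' @param qtl_stats,gwas_stats [summary_stats()] tables.
#' @param priors A [coloc_priors()].
#' @param prior_sd Wakefield prior SD.
#' @return A `coloc_result` with a `label`.
#' @export
gwas_coloc <- function(qtl_stats, gwas_stats, priors = coloc_priors(),
                       prior_sd = 0.15) {
  al <- align_stats(qtl_stats, gwas_stats)
  res <- coloc_posteriors(stats_to_labf(al$s1, prior_sd),
                          stats_to_labf(al$s2, prior_sd), priors)
  res$label <- classify_coloc(res)
  res
}
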