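# Covariate-adjusted cis-QTL scan: OLS nominal pass over all variants
# within a 1-Mb window of each phenotype anchor, a residualize-then-permute
# permutation pass calibrating the per-phenotype top association, and
# Benjamini-Hochberg selection across phenotypes.

#' QTL scan configuration
#'
#' @param cis_window cis window half-width in bp (default 1,000,000).
#' @param n_permutations permutations for the top-association pass
#'   (default 10,000; must be >= 100).
#' @param fdr_threshold FDR threshold for discovery (default 0.01; the
#'   sharing analysis conventionally relaxes this to 0.10).
#' @param n_genotype_pcs genotype principal components used as covariates
#'   (default 5).
#' @param n_latent_factors latent phenotype factors used as covariates;
#'   `NULL` means `ceiling(0.25 * n_samples)`.
#' @param beta_approx fit a Beta tail approximation to the permutation null
#'   instead of using the empirical counting p (default `FALSE`).
#' @param fdr_method `"BH"` (default) or `"storey"`.
#' @param seed permutation seed.
#' @return list of class `qtl_scan_config`.
#' @export
qtl_scan_config <- function(cis_window = 1e6, n_permutations = 10000L,
                            fdr_threshold = 0.01, n_genotype_pcs = 5L,
                            n_latent_factors = NULL, beta_approx = FALSE,
                            fdr_method = c("BH", "storey"), seed = 1L) {
  stopifnot(cis_window > 0, n_permutations >= 100,
            fdr_threshold > 0, fdr_threshold < 1)
  structure(list(cis_window = cis_window,
                 n_permutations = as.integer(n_permutations),
                 fdr_threshold = fdr_threshold,
                 n_genotype_pcs = as.integer(n_genotype_pcs),
                 n_latent_factors = n_latent_factors,
                 beta_approx = beta_approx,
                 fdr_method = match.arg(fdr_method),
                 seed = as.integer(seed)),
            class = "qtl_scan_config")
}

# Orthonormal basis of [1 | covariates]; residualize M against it.
residualize <- function(M, Q) M - Q %*% crossprod(Q, M)

covariate_basis <- function(covariates, n) {
  C <- cbind(intercept = rep(1, n), covariates)
  r <- qr(C)
  if (r$rank < ncol(C)) {
    bad <- sort(r$pivot[-seq_len(r$rank)])
    nm <- colnames(C) %||% paste0("V", seq_len(ncol(C)))
    stopf("covariate matrix is rank deficient; collinear column(s): %s",
          paste(nm[bad], collapse = ", "))
  }
  qr.Q(r)
}

#' Compute genotype-PC and latent-factor covariates
#'
#' Genotype PCs are the leading principal components of the standardized
#' dosage matrix (population-structure surrogate). Latent factors are the
#' leading principal components of the phenotype matrix after residualizing
#' it on the genotype PCs: a simple, testable surrogate for PEER-style
#' hidden technical factors, with the count kept at 25% of the sample size
#' by default.
#'
#' @param panel A [haplotype_panel()].
#' @param phenotypes A [phenotype_table()] (may be `NULL` if
#'   `n_latent_factors = 0`).
#' @param cfg A [qtl_scan_config()].
#' @return samples x covariates matrix, columns mean-centered, named
#'   `PC1..`, `LF1..`.
#' @export
compute_covariates <- function(panel, phenotypes, cfg = qtl_scan_config()) {
  n <- length(panel$sample_ids)
  n_lf <- cfg$n_latent_factors %||% ceiling(0.25 * n)
  if (n < cfg$n_genotype_pcs + n_lf + 2) {
    stopf("need at least %d samples for %d PCs + %d latent factors",
          cfg$n_genotype_pcs + n_lf + 2, cfg$n_genotype_pcs, n_lf)
  }
  out <- NULL
  if (cfg$n_genotype_pcs > 0) {
    D <- dosage(panel)
    D[is.na(D)] <- mean(D, na.rm = TRUE)
    sds <- apply(D, 2L, sd)
    X <- scale(D[, sds > 0, drop = FALSE])
    sv <- svd(X, nu = cfg$n_genotype_pcs, nv = 0)
    pcs <- sv$u %*% diag(sv$d[seq_len(cfg$n_genotype_pcs)], cfg$n_genotype_pcs)
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    out <- pcs
  }
  if (n_lf > 0) {
    if (is.null(phenotypes)) stopf("phenotypes required for latent factors")
    Y <- t(phenotypes$values)
    Q <- covariate_basis(out, n)
    Yr <- residualize(scale(Y, scale = FALSE), Q)
    sv <- svd(Yr, nu = n_lf, nv = 0)
    lf <- sv$u %*% diag(sv$d[seq_len(n_lf)], n_lf)
    colnames(lf) <- paste0("LF", seq_len(ncol(lf)))
    out <- cbind(out, lf)
  }
  if (is.null(out)) out <- matrix(numeric(0), nrow = n, ncol = 0)
  out <- scale(out, scale = FALSE)
  attr(out, "scaled:center") <- NULL
  full <- cbind(1, out)
  if (qr(full)$rank < ncol(full)) {
    r1 <- qr(full)
    keep <- r1$pivot[seq_len(r1$rank)]
    bad <- setdiff(seq_len(ncol(full)), keep) - 1L
    stopf("covariate matrix is rank deficient; collinear column(s): %s",
          paste(colnames(out)[bad], collapse = ", "))
  }
  rownames(out) <- panel$sample_ids
  out
}

cis_variants <- function(panel, chrom, anchor_pos, window) {
  which(panel$variants$chrom == chrom &
          abs(panel$variants$pos - anchor_pos) <= window)
}

#' Nominal cis association pass
#'
#' OLS of each (covariate-residualized, for speed via Frisch-Waugh) phenotype
#' on the dosage of every variant within the cis window; two-sided t test on
#' the dosage coefficient. Monomorphic variants are skipped.
#'
#' @param panel A [haplotype_panel()].
#' @param phenotypes A [phenotype_table()].
#' @param covariates samples x covariates matrix (may have 0 columns).
#' @param cfg A [qtl_scan_config()].
#' @return data.frame: `phenotype_id`, `variant_id`, `beta`, `se`, `p`.
#' @export
nominal_scan <- function(panel, phenotypes, covariates, cfg = qtl_scan_config()) {
  n <- length(panel$sample_ids)
  Q <- covariate_basis(covariates, n)
  df <- n - ncol(Q) - 1L
  D <- dosage(panel)
  Dr <- residualize(D, Q)
  Y <- t(phenotypes$values)
  Yr <- residualize(Y, Q)
  out <- vector("list", nrow(phenotypes$anchors))
  for (j in seq_len(nrow(phenotypes$anchors))) {
    a <- phenotypes$anchors[j, ]
    cis <- cis_variants(panel, a$chrom, a$pos, cfg$cis_window)
    if (!length(cis)) next
    gg <- colSums(Dr[, cis, drop = FALSE]^2)
    poly <- apply(D[, cis, drop = FALSE], 2L, function(g) length(unique(g[!is.na(g)])) > 1L)
    if (any(!poly)) aq_log("debug", sum(!poly), " monomorphic variant(s) skipped")
    keep <- poly & gg > 1e-12
    if (!any(keep)) next
    cis <- cis[keep]; gg <- gg[keep]
    y <- Yr[, j]
    gy <- colSums(Dr[, cis, drop = FALSE] * y)
    b <- gy / gg
    sigma2 <- pmax(sum(y^2) - b^2 * gg, 0) / df
    se <- sqrt(sigma2 / gg)
    tstat <- b / se
    p <- 2 * pt(-abs(tstat), df)
    out[[j]] <- data.frame(phenotype_id = a$phenotype_id,
                           variant_id = panel$variants$id[cis],
                           beta = b, se = se, p = p,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- data.frame(phenotype_id = character(),
                                      variant_id = character(), beta = numeric(),
                                      se = numeric(), p = numeric())
  rownames(res) <- NULL
  res
}

# Beta(a, b) MLE for the permutation-null minimum p values.
fit_beta_mle <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- var(x)
  k <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * k, (1 - m) * k), 1e-3))
  nll <- function(par) -sum(dbeta(x, exp(par[1]), exp(par[2]), log = TRUE))
  fit <- optim(start, nll, method = "Nelder-Mead")
  exp(fit$par)
}

#' Permutation pass for the top cis association of each phenotype
#'
#' Each phenotype is residualized on the covariates once, the residuals are
#' permuted `n_permutations` times (residualize-then-permute keeps the
#' covariate structure fixed under the null), and the null statistic is the
#' minimum nominal p over the cis window in each permutation. The adjusted
#' p value is `(1 + #{null <= observed}) / (1 + n_permutations)`; optionally
#' a Beta tail approximation fitted to the null minima is used instead.
#' Top-variant ties break toward the smaller nominal p, then the smaller
#' genomic position.
#'
#' @inheritParams nominal_scan
#' @return data.frame of per-phenotype records: `phenotype_id`,
#'   `top_variant_id`, `beta`, `se`, `nominal_p`, `perm_p`, `n_cis_variants`.
#' @export
permutation_pass <- function(panel, phenotypes, covariates, cfg = qtl_scan_config()) {
  n <- length(panel$sample_ids)
  Q <- covariate_basis(covariates, n)
  df <- n - ncol(Q) - 1L
  if (df < 2) stopf("not enough residual degrees of freedom")
  D <- dosage(panel)
  D[is.na(D)] <- 0
  Dr <- residualize(D, Q)
  Y <- t(phenotypes$values)
  Yr <- residualize(Y, Q)
  B <- cfg$n_permutations
  set.seed(substream_seed(cfg$seed, "permutations"))
  perms <- replicate(B, sample.int(n))
  out <- vector("list", nrow(phenotypes$anchors))
  for (j in seq_len(nrow(phenotypes$anchors))) {
    a <- phenotypes$anchors[j, ]
    cis <- cis_variants(panel, a$chrom, a$pos, cfg$cis_window)
    if (!length(cis)) next
    G <- Dr[, cis, drop = FALSE]
    gg <- colSums(G^2)
    keep <- gg > 1e-12 &
      apply(D[, cis, drop = FALSE], 2L, function(g) length(unique(g)) > 1L)
    if (!any(keep)) next
    cis <- cis[keep]; G <- G[, keep, drop = FALSE]; gg <- gg[keep]
    y <- Yr[, j]
    yy <- sum(y^2)
    if (yy < 1e-24) next
    r_obs <- colSums(G * y) / sqrt(gg * yy)
    # |r| is monotone in the nominal t statistic, so max |r| <-> min p.
    # Permuted residuals are re-residualized on the covariates so the null
    # statistics live in the same subspace as the observed one.
    YP <- residualize(matrix(y[perms], nrow = n), Q)
    yyp <- colSums(YP^2)
    R <- crossprod(G, YP) / sqrt(outer(gg, yyp))
    null_max <- apply(abs(R), 2L, max)
    obs_max <- max(abs(r_obs))
    r2p <- function(r) {
      tt <- abs(r) * sqrt(df) / sqrt(pmax(1 - r^2, 1e-12))
      2 * pt(-tt, df)
    }
    if (isTRUE(cfg$beta_approx)) {
      ab <- fit_beta_mle(r2p(null_max))
      perm_p <- pbeta(r2p(obs_max), ab[1], ab[2])
      perm_p <- max(perm_p, 1e-300)
    } else {
      perm_p <- (1 + sum(null_max >= obs_max)) / (1 + B)
    }
    nominal <- r2p(r_obs)
    top_local <- order(nominal, panel$variants$pos[cis])[1L]
    v <- cis[top_local]
    b <- colSums(G[, top_local, drop = FALSE] * y) / gg[top_local]
    sigma2 <- pmax(yy - b^2 * gg[top_local], 0) / df
    out[[j]] <- data.frame(phenotype_id = a$phenotype_id,
                           top_variant_id = panel$variants$id[v],
                           beta = b, se = sqrt(sigma2 / gg[top_local]),
                           nominal_p = nominal[top_local], perm_p = perm_p,
                           n_cis_variants = length(cis),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(phenotype_id = character(), top_variant_id = character(),
                      beta = numeric(), se = numeric(), nominal_p = numeric(),
                      perm_p = numeric(), n_cis_variants = integer())
  }
  rownames(res) <- NULL
  res
}

#' FDR selection over permutation p values
#'
#' Benjamini-Hochberg (default) or Storey q values over the per-phenotype
#' permutation p values; phenotypes with `fdr_q < threshold` are returned as
#' significant.
#'
#' @param records output of [permutation_pass()].
#' @param threshold FDR threshold.
#' @param method `"BH"` or `"storey"`.
#' @return `records` with an `fdr_q` column and a logical `significant`.
#' @export
fdr_select <- function(records, threshold = 0.01, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (!nrow(records)) {
    records$fdr_q <- numeric(0); records$significant <- logical(0)
    return(records)
  }
  p <- records$perm_p
  if (method == "BH") {
    q <- p.adjust(p, method = "BH")
  } else {
    pi0 <- min(1, mean(p > 0.5) / 0.5)
    q <- pmin(pi0 * p.adjust(p, method = "BH"), 1)
  }
  records$fdr_q <- q
  records$significant <- q < threshold
  records
}

#' Closed-form power of the cis-QTL slope test
#'
#' Power of the two-sided t test for the per-allele dosage slope, with
#' noncentrality `|beta| sqrt(2 maf (1 - maf) n) / sigma` and `n - 2`
#' degrees of freedom (Hardy-Weinberg dosage variance `2 maf (1 - maf)`).
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @param n sample size (>= 3).
#' @param beta per-allele effect, phenotype SD units.
#' @param sigma residual SD (> 0).
#' @param alpha two-sided significance level.
#' @param df degrees of freedom (default `n - 2`).
#' @return detection probability.
#' @export
analytic_power <- function(maf, n, beta, sigma = 1, alpha = 0.05, df = n - 2) {
  if (any(sigma <= 0)) stopf("sigma must be > 0")
  stopifnot(all(maf > 0), all(maf <= 0.5), all(n >= 3))
  ncp <- abs(beta) * sqrt(2 * maf * (1 - maf) * n) / sigma
  tcrit <- qt(1 - alpha / 2, df)
  1 - pt(tcrit, df, ncp) + pt(-tcrit, df, ncp)
}

#' Full cis-QTL map: covariates, permutation pass, FDR selection
#'
#' @inheritParams nominal_scan
#' @param covariates optional precomputed covariate matrix; `NULL` computes
#'   genotype PCs + latent factors per `cfg`.
#' @return data.frame of per-phenotype QTL records with `fdr_q` and
#'   `significant`.
#' @export
map_qtl <- function(panel, phenotypes, cfg = qtl_scan_config(), covariates = NULL) {
  if (is.null(covariates)) covariates <- compute_covariates(panel, phenotypes, cfg)
  rec <- permutation_pass(panel, phenotypes, covariates, cfg)
  fdr_select(rec, cfg$fdr_threshold, cfg$fdr_method)
}
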