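# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (explicit loops, per-base scans, direct
# enumeration) and share no code with the implementation paths they check.

# Random toy haplotype panel with consecutive positions (gap/decay caps
# inactive) and ancestral = REF.
make_toy_panel <- function(n_hap = 8, m = 20, seed = 1, pos_step = 100) {
  set.seed(seed)
  stopifnot(n_hap %% 2 == 0)
  alleles <- matrix(rbinom(n_hap * m, 1L, runif(m, 0.2, 0.8)[rep(seq_len(m), each = n_hap)]),
                    n_hap, m)
  variants <- data.frame(chrom = "chr1", pos = seq_len(m) * pos_step,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  haplotype_panel(variants, alleles, sprintf("S%02d", seq_len(n_hap / 2)))
}

# Exhaustive O(n^2 m) pairwise-extension nSL oracle at one focal SNP.
nsl_oracle <- function(panel, focal) {
  H <- panel$alleles
  v <- panel$variants
  m <- ncol(H)
  anc_ref <- v$ancestral[focal] == v$ref[focal]
  anc_alt <- v$ancestral[focal] == v$alt[focal]
  if (!anc_ref && !anc_alt) return(NA_real_)
  der <- if (anc_ref) 1L else 0L
  cls_d <- which(H[, focal] == der)
  cls_a <- which(H[, focal] != der)
  if (length(cls_a) < 2 || length(cls_d) < 2) return(NA_real_)
  ext <- function(a, b) {
    l <- focal
    while (l - 1 >= 1 && H[a, l - 1] == H[b, l - 1]) l <- l - 1
    r <- focal
    while (r + 1 <= m && H[a, r + 1] == H[b, r + 1]) r <- r + 1
    r - l + 1
  }
  pair_mean <- function(cls) {
    tot <- 0; np <- 0
    for (i in seq_along(cls)[-length(cls)]) {
      for (j in seq.int(i + 1, length(cls))) {
        tot <- tot + ext(cls[i], cls[j]); np <- np + 1
      }
    }
    tot / np
  }
  log(pair_mean(cls_a) / pair_mean(cls_d))
}

# Direct enumeration of all causal configurations for two traits.
coloc_enum_oracle <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  A1 <- exp(labf1); A2 <- exp(labf2)
  m <- length(A1)
  S0 <- 1
  S1 <- 0; S2 <- 0; S3 <- 0; S4 <- 0
  for (i in seq_len(m)) {
    S1 <- S1 + p1 * A1[i]
    S2 <- S2 + p2 * A2[i]
    S4 <- S4 + p12 * A1[i] * A2[i]
    for (j in seq_len(m)) if (j != i) S3 <- S3 + p1 * p2 * A1[i] * A2[j]
  }
  s <- c(S0, S1, S2, S3, S4)
  s / sum(s)
}

# Per-base brute-force version of the archaic interval filter, one haplotype.
archaic_filter_oracle <- function(cp_d, hmm1, hmm2, cp_n, span, thr = 1e-5) {
  base_vec <- function(iv) {
    x <- logical(span)
    for (k in seq_len(nrow(iv))) {
      if (iv$end[k] > iv$start[k]) x[(iv$start[k] + 1):iv$end[k]] <- TRUE
    }
    x
  }
  b1 <- base_vec(hmm1); b2 <- base_vec(hmm2); bn <- base_vec(cp_n)
  keep <- logical(nrow(cp_d))
  for (k in seq_len(nrow(cp_d))) {
    sel <- (cp_d$start[k] + 1):cp_d$end[k]
    len <- length(sel)
    keep[k] <- sum(b1[sel]) / len > thr && sum(b2[sel]) / len > thr &&
      sum(bn[sel]) / len <= thr
  }
  keep
}

# Random interval set on [0, span) for one haplotype.
random_intervals <- function(n, span, max_len, sample_id = "S1", hap = 0L) {
  s <- sort(sample.int(span - 2L, n))
  e <- pmin(s + sample.int(max_len, n, replace = TRUE), span)
  ok <- e > s
  data.frame(chrom = "chr1", start = s[ok], end = e[ok],
             sample_id = sample_id, hap = hap,
             label = "DENISOVAN", stringsAsFactors = FALSE)
}

# Summary stats for a fresh cohort over unlinked SNPs with an optional
# causal variant; returns stats plus the genotype matrix (for LD).
region_study <- function(m = 60, n = 500, causal = NULL, beta = 0.5,
                         seed = 1, freqs = NULL, dataset_id = "d",
                         y = NULL, G = NULL) {
  set.seed(seed)
  if (is.null(freqs)) freqs <- runif(m, 0.1, 0.9)
  if (is.null(G)) G <- matrix(rbinom(n * m, 2L, rep(freqs, each = n)), n, m)
  if (is.null(y)) {
    y <- rnorm(n)
    if (!is.null(causal)) y <- y + beta * G[, causal]
  }
  gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  ssg <- colSums(gc^2)
  b <- colSums(gc * yc) / ssg
  sigma2 <- (sum(yc^2) - b^2 * ssg) / (n - 2)
  se <- sqrt(sigma2 / ssg)
  p <- 2 * pt(-abs(b / se), n - 2)
  fhat <- colMeans(G) / 2
  maf <- pmin(pmax(pmin(fhat, 1 - fhat), 1e-4), 0.5)
  st <- summary_stats(data.frame(
    variant_id = sprintf("v%03d", seq_len(m)), chrom = "chr1",
    pos = seq_len(m) * 1000, beta = b, se = se,
    p = pmin(pmax(p, 1e-300), 1), maf = maf,
    n = n, stringsAsFactors = FALSE), dataset_id)
  list(stats = st, G = G, y = y, freqs = freqs)
}
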