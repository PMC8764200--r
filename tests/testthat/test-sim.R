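# Synthetic admixed cohort generator.

test_that("Balding-Nichols frequencies: divergence limits, Monte-Carlo expectation, informative flags", {
  cfg0 <- sim_config(fst_divergence = 1e-4, n_variants = 2000,
                     frac_informative = 0, seed = 11)
  fr <- simulate_ancestral_frequencies(cfg0)
  # F -> 0: both population frequencies converge to the ancestral p
  expect_lt(mean(abs(fr$freq_asn - fr$p_anc)), 0.01)
  expect_lt(mean(abs(fr$freq_pap - fr$freq_asn)), 0.02)

  # F = 0.2: mean |freq difference| matches a direct Monte-Carlo draw of the
  # Beta mixture (1e6 draws)
  cfg <- sim_config(fst_divergence = 0.2, n_variants = 10000,
                    frac_informative = 0, seed = 12)
  fr <- simulate_ancestral_frequencies(cfg)
  set.seed(999)
  nmc <- 1e6
  p <- runif(nmc, 0.05, 0.95)
  k <- (1 - 0.2) / 0.2
  mc <- mean(abs(rbeta(nmc, p * k, (1 - p) * k) - rbeta(nmc, p * k, (1 - p) * k)))
  obs <- mean(abs(fr$freq_asn - fr$freq_pap))
  expect_lt(abs(obs - mc) / mc, 0.05)

  # forced ancestry-informative variants are at 0.99/0.01 and flagged
  cfg2 <- sim_config(n_variants = 1000, frac_informative = 0.1, seed = 13)
  fr2 <- simulate_ancestral_frequencies(cfg2)
  inf <- fr2[fr2$la_informative, ]
  expect_equal(nrow(inf), 100)
  expect_true(all((inf$freq_pap == 0.99 & inf$freq_asn == 0.01) |
                    (inf$freq_pap == 0.01 & inf$freq_asn == 0.99)))

  expect_error(sim_config(fst_divergence = 0), "fst_divergence")
  expect_error(sim_config(fst_divergence = 1), "fst_divergence")
})

test_that("ancestry tract process: boundaries, tiling, and mean tract length", {
  cfg <- sim_config(chrom_length = 5e7, admix_generations = 100,
                    recomb_rate = 1e-8, unknown_frac = 0, seed = 21)
  t1 <- simulate_tracts(cfg, theta = 1)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$label, "PAPUAN")
  expect_equal(c(t1$start, t1$end), c(0, 5e7))
  t0 <- simulate_tracts(cfg, theta = 0)
  expect_false(any(t0$label == "PAPUAN"))
  expect_error(simulate_tracts(cfg, theta = 1.2), "theta")

  # tiling invariant and interior-tract mean length: switch points arrive at
  # rate g*r and the state is redrawn Bernoulli(theta), so complete
  # (interior) tracts have mean length 1 / (g r 2 theta (1-theta))
  lens <- numeric(0)
  for (i in 1:400) {
    tr <- simulate_tracts(cfg, theta = 0.5, sample_id = "S1", hap = 0L, seed = 1000 + i)
    expect_equal(tr$start[1], 0)
    expect_equal(tr$end[nrow(tr)], 5e7)
    if (nrow(tr) > 1) expect_equal(tr$start[-1], tr$end[-nrow(tr)])
    if (nrow(tr) > 2) lens <- c(lens, (tr$end - tr$start)[2:(nrow(tr) - 1)])
  }
  expected <- 1 / (100 * 1e-8 * 2 * 0.5 * 0.5)
  expect_lt(abs(mean(lens) - expected) / expected, 0.05)
})

test_that("cohort ancestry proportions match configured theta and UNKNOWN masking is applied", {
  cfg <- sim_config(n_individuals_per_pop = c(A = 25, B = 25), pop_theta = c(0.1, 0.9),
                    chrom_length = 2e7, unknown_frac = 0.2, seed = 31)
  frac <- function(theta, n) {
    vapply(seq_len(n), function(i) {
      tr <- simulate_tracts(cfg, theta, sample_id = paste0("x", i), hap = 0L,
                            seed = 5000 + i + round(1e4 * theta))
      len <- tr$end - tr$start
      called <- sum(len[tr$label != "UNKNOWN"])
      sum(len[tr$label == "PAPUAN"]) / called
    }, numeric(1))
  }
  for (theta in c(0.1, 0.9)) {
    f <- frac(theta, 60)
    se <- sd(f) / sqrt(length(f))
    expect_lt(abs(mean(f) - theta), 2 * se + 0.01)
  }
  # UNKNOWN coverage near the configured fraction
  tr <- do.call(rbind, lapply(1:50, function(i)
    simulate_tracts(cfg, 0.5, sample_id = paste0("u", i), seed = 7000 + i)))
  unk <- sum((tr$end - tr$start)[tr$label == "UNKNOWN"]) / sum(tr$end - tr$start)
  expect_gt(unk, 0.1); expect_lt(unk, 0.3)
})

test_that("archaic segments nest in Papuan tracts and scale with Papuan fraction", {
  cfg <- sim_config(unknown_frac = 0, chrom_length = 2e7, seed = 41)
  # zero Papuan bases -> zero Denisovan segments
  t0 <- simulate_tracts(cfg, theta = 0, sample_id = "z", seed = 1)
  a0 <- simulate_archaic_segments(t0, cfg, seed = 2)
  expect_equal(sum(a0$label == "DENISOVAN"), 0L)

  cov_for <- function(theta, n, off) {
    vapply(seq_len(n), function(i) {
      tr <- simulate_tracts(cfg, theta, sample_id = paste0("c", i), seed = off + i)
      ar <- simulate_archaic_segments(tr, cfg, seed = off + 10000 + i)
      den <- ar[ar$label == "DENISOVAN", , drop = FALSE]
      # Denisovan segments lie inside Papuan tracts
      pap <- tr[tr$label == "PAPUAN", , drop = FALSE]
      if (nrow(den)) {
        inside <- vapply(seq_len(nrow(den)), function(k)
          any(pap$start <= den$start[k] & den$end[k] <= pap$end), logical(1))
        expect_true(all(inside))
      }
      sum(den$end - den$start) / cfg$chrom_length
    }, numeric(1))
  }
  hi <- cov_for(0.95, 400, 20000)
  lo <- cov_for(0.05, 400, 40000)
  ratio <- mean(hi) / mean(lo)
  expect_gt(ratio, 19 * 0.6)
  expect_lt(ratio, 19 / 0.6)

  # Papuan fraction vs Denisovan fraction strongly positively correlated
  # across diploid individuals spanning the ancestry cline (default scale)
  cfgd <- sim_config(unknown_frac = 0, seed = 41)
  thetas <- rep(c(0.053, 0.268, 0.95), each = 35)
  pap_f <- numeric(length(thetas)); den_f <- numeric(length(thetas))
  for (i in seq_along(thetas)) {
    p <- 0; d <- 0
    for (h in 0:1) {
      tr <- simulate_tracts(cfgd, thetas[i], sample_id = paste0("r", i), hap = h,
                            seed = 60000 + 2 * i + h)
      ar <- simulate_archaic_segments(tr, cfgd, seed = 70000 + 2 * i + h)
      p <- p + sum((tr$end - tr$start)[tr$label == "PAPUAN"])
      d <- d + sum((ar$end - ar$start)[ar$label == "DENISOVAN"])
    }
    pap_f[i] <- p / (2 * cfgd$chrom_length)
    den_f[i] <- d / (2 * cfgd$chrom_length)
  }
  expect_gt(cor(pap_f, den_f), 0.9)

  # archaic layers never overlap each other on a haplotype
  tr <- simulate_tracts(cfg, 0.6, sample_id = "ov", seed = 81)
  ar <- simulate_archaic_segments(tr, cfg, seed = 82)
  den <- ar[ar$label == "DENISOVAN", ]; nea <- ar[ar$label == "NEANDERTHAL", ]
  if (nrow(den) && nrow(nea)) {
    for (k in seq_len(nrow(nea))) {
      expect_false(any(nea$start[k] < den$end & den$start < nea$end[k]))
    }
  }
})

test_that("genotypes track local ancestry for informative variants and are reproducible", {
  cfg <- sim_config(n_individuals_per_pop = c(P = 60), pop_theta = 0.5,
                    n_variants = 40, chrom_length = 1e6, unknown_frac = 0,
                    frac_informative = 0, seed = 51)
  fr <- simulate_ancestral_frequencies(cfg)
  fr$freq_pap[1:10] <- 0.99; fr$freq_asn[1:10] <- 0.01   # la-driven
  fr$freq_pap[11:20] <- 0.5; fr$freq_asn[11:20] <- 0.5   # ancestry-blind
  pos <- sort(sample.int(1e6, 40))
  samples <- data.frame(sample_id = sprintf("P_%03d", 1:60), theta = 0.5)
  tr <- do.call(rbind, lapply(1:60, function(i) rbind(
    simulate_tracts(cfg, 0.5, samples$sample_id[i], 0L, seed = 100 + i),
    simulate_tracts(cfg, 0.5, samples$sample_id[i], 1L, seed = 200 + i))))
  tr <- ancestry_tracts(tr)
  panel <- simulate_genotypes(fr, pos, tr, samples, cfg, seed = 300)
  pap <- ancestry_dosage(tr, pos, samples$sample_id, "PAPUAN", sparse = FALSE)
  dos <- dosage(panel)
  match_frac <- vapply(1:10, function(v) mean(dos[, v] == pap[, v]), numeric(1))
  expect_gt(mean(match_frac), 0.95)
  cors <- vapply(11:20, function(v) {
    if (sd(dos[, v]) == 0 || sd(pap[, v]) == 0) 0 else cor(dos[, v], pap[, v])
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.15)
  panel2 <- simulate_genotypes(fr, pos, tr, samples, cfg, seed = 300)
  expect_identical(panel$alleles, panel2$alleles)
})

test_that("simulate_cohort is byte-deterministic and satisfies ground-truth invariants", {
  cfg <- sim_config(n_individuals_per_pop = c(A = 15, B = 10), pop_theta = c(0.1, 0.9),
                    n_variants = 400, chrom_length = 5e6, n_genes = 15, n_cpgs = 15,
                    seed = 61)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  # every causal variant lies within the cis window of its phenotype
  cm <- s1$truth$causal_map
  expect_gt(nrow(cm), 0)
  vpos <- s1$panel$variants$pos[match(cm$variant_id, s1$panel$variants$id)]
  apos <- s1$phenotypes$anchors$pos[match(cm$phenotype_id, s1$phenotypes$anchors$phenotype_id)]
  expect_true(all(abs(vpos - apos) <= 1e6))
  # flagged variants exist in the panel
  expect_true(all(names(s1$truth$la_driven_flags) %in% s1$panel$variants$id))
  # archaic-informative variants segregate exactly with Denisovan coverage
  den_flag <- names(s1$truth$archaic_flags)[s1$truth$archaic_flags == "DEN"]
  if (length(den_flag)) {
    v <- match(den_flag[1], s1$panel$variants$id)
    den <- ancestry_dosage(s1$archaic, s1$panel$variants$pos[v],
                           s1$panel$sample_ids, "DENISOVAN")
    expect_equal(unname(dosage(s1$panel)[, v]), unname(den[, 1]))
  }
})

test_that("external pseudo-datasets recover the causal variant and validate n", {
  set.seed(1)
  fr <- data.frame(p_anc = runif(30, 0.2, 0.8), freq_asn = NA, freq_pap = NA,
                   la_informative = FALSE)
  pos <- seq_len(30) * 1000
  st <- simulate_external_study(fr, pos, n = 20000, causal_idx = 7, beta = 0.5,
                                seed = 5)
  expect_equal(which.min(st$p), 7L)
  st2 <- simulate_external_study(fr, pos, n = 20000, causal_idx = 7, beta = 0.5,
                                 seed = 6, redraw_F = 0.1, dataset_id = "eur")
  expect_equal(which.min(st2$p), 7L)
  expect_error(simulate_external_study(fr, pos, n = 5), "n >= 10")
})
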