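# Ancestry/archaic dosages, the V = alpha x PAP + beta regression, archaic
# interval filtering, and per-SNP annotation.

two_hap_tracts <- function(lab0, lab1, L = 1000, sample_id = "S1") {
  ancestry_tracts(data.frame(
    chrom = "chr1",
    start = c(sapply(lab0, `[[`, 1), sapply(lab1, `[[`, 1)),
    end = c(sapply(lab0, `[[`, 2), sapply(lab1, `[[`, 2)),
    sample_id = sample_id,
    hap = rep(c(0L, 1L), c(length(lab0), length(lab1))),
    label = c(sapply(lab0, `[[`, 3), sapply(lab1, `[[`, 3))))
}

test_that("ancestry dosage: saturation, boundary convention, UNKNOWN handling, brute-force oracle", {
  tr <- two_hap_tracts(list(list(0, 1000, "PAPUAN")), list(list(0, 1000, "PAPUAN")))
  d <- ancestry_dosage(tr, c(1, 500, 1000), "S1", "PAPUAN", sparse = FALSE)
  expect_equal(unname(d[1, ]), c(2L, 2L, 2L))

  # boundary at 500: positions are 1-based, intervals [start,end) 0-based,
  # so position 501 (0-based 500) belongs to the right-hand tract
  tr2 <- two_hap_tracts(list(list(0, 500, "ASIAN"), list(500, 1000, "PAPUAN")),
                        list(list(0, 1000, "ASIAN")))
  d2 <- ancestry_dosage(tr2, c(500, 501), "S1", "PAPUAN", sparse = FALSE)
  expect_equal(unname(d2[1, ]), c(0L, 1L))

  # UNKNOWN at the position makes the dosage missing
  tr3 <- two_hap_tracts(list(list(0, 500, "UNKNOWN"), list(500, 1000, "PAPUAN")),
                        list(list(0, 1000, "PAPUAN")))
  d3 <- ancestry_dosage(tr3, c(100, 600), "S1", "PAPUAN", sparse = FALSE)
  expect_true(is.na(d3[1, 1]))
  expect_equal(unname(d3[1, 2]), 2L)

  # brute-force membership oracle on simulated tracts at random positions
  cfg <- sim_config(chrom_length = 1e6, unknown_frac = 0.1, seed = 7)
  trs <- ancestry_tracts(rbind(
    simulate_tracts(cfg, 0.5, "S1", 0L, seed = 1),
    simulate_tracts(cfg, 0.5, "S1", 1L, seed = 2)))
  set.seed(3)
  pos <- sort(sample.int(1e6, 1000))
  d4 <- ancestry_dosage(trs, pos, "S1", "PAPUAN", sparse = FALSE)
  oracle <- vapply(pos, function(p) {
    labs <- vapply(0:1, function(h) {
      t <- trs[trs$hap == h, ]
      t$label[t$start <= p - 1 & p - 1 < t$end]
    }, character(1))
    if (any(labs == "UNKNOWN")) NA_integer_ else sum(labs == "PAPUAN")
  }, integer(1))
  expect_equal(unname(d4[1, ]), oracle)
})

test_that("V = alpha x PAP + beta fit: identity, null, threshold, degenerate regressor", {
  pap <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  fit <- la_driven_fit(pap, pap)
  expect_equal(fit$r2, 1)
  expect_equal(fit$alpha, 1)
  expect_equal(fit$beta0, 0)
  expect_true(fit$driven_flag)

  # driven_flag tracks the R^2 > 0.7 rule exactly on random data
  set.seed(4)
  for (i in 1:50) {
    v <- rbinom(40, 2, 0.4)
    p2 <- pmin(pmax(v + rbinom(40, 1, 0.4) - rbinom(40, 1, 0.4), 0), 2)
    f <- la_driven_fit(v, p2)
    expect_identical(f$driven_flag, unname(f$r2 > 0.7))
  }

  # ancestry-independent genotype: R^2 < 0.05 almost always at n = 1000
  set.seed(5)
  r2s <- replicate(50, {
    la_driven_fit(rbinom(1000, 2, 0.5), rbinom(1000, 2, 0.5))$r2
  })
  expect_gt(mean(r2s < 0.05), 0.98)

  expect_warning(fc <- la_driven_fit(c(0, 1, 2, 1), rep(2, 4)), "constant")
  expect_true(is.na(fc$r2))
  expect_false(fc$driven_flag)
  expect_error(la_driven_fit(c(1, NA), c(1, 2)), ">= 3")

  # archaic variant tagging Denisovan coverage perfectly
  den <- c(0, 1, 2, 0, 1, 0, 0, 2, 1, 0)
  fa <- archaic_driven_fit(den, den)
  expect_equal(fa$r2, 1)
  # Denisovan absent in cohort -> constant 0 dosage -> missing R^2
  expect_warning(f0 <- archaic_driven_fit(c(0, 1, 2, 1), rep(0, 4)), "constant")
  expect_true(is.na(f0$r2))
})

test_that("archaic interval filter matches the per-base oracle, including >0.001% boundaries", {
  mk <- function(s, e, label = "DENISOVAN", sample_id = "S1", hap = 0L) {
    data.frame(chrom = "chr1", start = s, end = e, sample_id = sample_id,
               hap = hap, label = label, stringsAsFactors = FALSE)
  }
  # worked boundary case: 100 bp overlap of a 1 Mb interval = 1e-4 > 1e-5
  cp <- mk(0, 1e6)
  hmm1 <- mk(999900, 2e6)
  hmm2 <- mk(0, 2e6)
  nea <- mk(3e6, 4e6, "NEANDERTHAL")
  expect_equal(nrow(high_confidence_archaic(cp, hmm1, hmm2, nea)), 1L)
  # exactly at the threshold (10 bp of 1 Mb = 1e-5, not >) -> dropped
  expect_equal(nrow(high_confidence_archaic(cp, mk(999990, 2e6), hmm2, nea)), 0L)
  # zero overlap with hmm1 -> dropped
  expect_equal(nrow(high_confidence_archaic(cp, mk(2e6, 3e6), hmm2, nea)), 0L)
  # 50% overlap with the Neanderthal set -> dropped
  expect_equal(nrow(high_confidence_archaic(cp, hmm1, hmm2, mk(5e5, 2e6, "NEANDERTHAL"))), 0L)
  expect_error(high_confidence_archaic(mk(5, 5), hmm1, hmm2, nea), "zero-length")

  # randomized configurations against the per-base oracle; order-independent
  set.seed(6)
  span <- 3000L
  for (i in 1:60) {
    cp_d <- random_intervals(sample(1:5, 1), span, 400)
    h1 <- random_intervals(sample(1:6, 1), span, 500)
    h2 <- random_intervals(sample(1:6, 1), span, 500)
    cn <- random_intervals(sample(1:4, 1), span, 300)
    cn$label <- "NEANDERTHAL"
    got <- high_confidence_archaic(cp_d, h1, h2, cn)
    want <- cp_d[archaic_filter_oracle(cp_d, h1, h2, cn, span), , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got, want)
    shuf <- cp_d[sample.int(nrow(cp_d)), , drop = FALSE]
    got2 <- high_confidence_archaic(shuf, h1, h2, cn)
    expect_equal(got2[order(got2$start), ]$start, want$start)
  }
})

test_that("SNP annotation on high-confidence haplotypes equals an exhaustive scan", {
  panel <- make_toy_panel(n_hap = 8, m = 15, seed = 9, pos_step = 50)
  hc <- ancestry_tracts(data.frame(
    chrom = "chr1", start = c(0, 300, 100), end = c(250, 600, 500),
    sample_id = c("S01", "S02", "S03"), hap = c(0L, 1L, 0L),
    label = "DENISOVAN"))
  groups <- list(g1 = c("S01", "S02"), g2 = c("S01", "S02", "S03", "S04"))
  res <- annotate_snps_on_archaic(panel, hc, groups)

  # exhaustive haplotype-by-haplotype oracle
  for (g in names(groups)) {
    ids <- groups[[g]]
    sub <- res$counts[res$counts$group == g, ]
    for (k in seq_len(nrow(sub))) {
      v <- match(sub$variant_id[k], panel$variants$id)
      pos <- panel$variants$pos[v]
      refc <- altc <- 0L
      for (s in ids) for (h in 0:1) {
        row <- 2L * match(s, panel$sample_ids) - 1L + h
        covered <- any(hc$sample_id == s & hc$hap == h &
                         hc$start <= pos - 1 & pos - 1 < hc$end)
        if (covered) {
          if (panel$alleles[row, v] == 1L) altc <- altc + 1L else refc <- refc + 1L
        }
      }
      expect_equal(sub$ref_on_archaic[k], refc)
      expect_equal(sub$alt_on_archaic[k], altc)
    }
  }
  # SNPs outside every interval count (0, 0)
  far <- res$counts[res$counts$group == "g2" &
                      res$counts$variant_id == panel$variants$id[15], ]
  if (nrow(far)) expect_equal(unname(unlist(far[, 3:4])), c(0L, 0L))

  # monomorphic SNP in the group is skipped with a reason
  panel2 <- panel
  panel2$alleles[, 2] <- 0L
  res2 <- annotate_snps_on_archaic(panel2, hc, groups)
  expect_true(all(c("g1", "g2") %in%
                    res2$skipped$group[res2$skipped$variant_id == panel$variants$id[2]]))
  expect_true(all(res2$skipped$reason == "monomorphic_in_group"))
  expect_error(annotate_snps_on_archaic(panel, hc, list(bad = character(0))),
               "zero haplotypes")
})

test_that("planted ancestry-tagging variants are recovered and null variants rarely flagged", {
  cfg <- sim_config(n_individuals_per_pop = c(M = 48, S = 48, K = 19),
                    pop_theta = c(0.053, 0.268, 0.95),
                    n_variants = 150, chrom_length = 2e6,
                    frac_informative = 0.2, frac_archaic_informative = 0,
                    unknown_frac = 0, n_genes = 5, n_cpgs = 0, frac_causal = 0,
                    seed = 77)
  sim <- simulate_cohort(cfg)
  fits <- ancestry_qtl_attribution(sim$panel$variants$id, sim$panel, sim$tracts,
                                   "PAPUAN")
  truthy <- sim$truth$la_driven_flags[fits$variant_id]
  sens <- mean(fits$driven_flag[truthy])
  fpr <- mean(fits$driven_flag[!truthy], na.rm = TRUE)
  expect_gt(sens, 0.9)
  expect_lt(fpr, 0.02)
})
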