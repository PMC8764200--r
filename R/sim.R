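# Synthetic admixed cohort generator. The cohort emulates three island
# populations on an Asian<->Papuan ancestry cline (default mean haploid
# Papuan proportions 0.053 / 0.268 / 0.950 across 48 + 48 + 19 individuals),
# archaic Denisovan segments nested in Papuan tracts plus
# ancestry-independent Neanderthal segments, Balding-Nichols allele
# frequency divergence between the two ancestries, planted cis effects on
# anchored phenotypes with latent-factor noise, and external pseudo-cohorts
# for sharing/colocalization analyses. Every stage records ground truth.

#' Simulation configuration
#'
#' Validated parameter bundle for the synthetic cohort generator. Defaults
#' describe the study conditions the package is tested under: a 115-sample
#' cohort across three populations on an Asian-Papuan admixture cline with
#' one 50-Mb chromosome.
#'
#' @param n_individuals_per_pop integer vector, individuals per population.
#' @param pop_theta per-population Papuan (haploid) admixture proportion in
#'   `[0, 1]`.
#' @param n_variants number of biallelic SNPs to simulate.
#' @param chrom_length chromosome length in bp.
#' @param fst_divergence Balding-Nichols F in (0, 1) separating the Asian and
#'   Papuan ancestral allele frequencies.
#' @param admix_generations generations since admixture (tract-length scale).
#' @param recomb_rate recombination rate, Morgans per bp.
#' @param archaic_seg_rate expected Denisovan segments per Mb of Papuan tract.
#' @param archaic_seg_mean_len mean archaic segment length, bp.
#' @param nea_seg_rate expected Neanderthal segments per Mb of chromosome
#'   (placed independently of modern ancestry).
#' @param n_genes,n_cpgs number of expression / methylation phenotypes.
#' @param frac_causal fraction of phenotypes with a planted cis effect.
#' @param effect_size_sd SD of planted per-allele effects (phenotype SD units).
#' @param effect_size_fixed optional fixed effect size; when non-`NULL` every
#'   causal phenotype gets exactly this beta (used for power experiments).
#' @param n_latent number of shared latent noise factors.
#' @param latent_sd SD of per-phenotype latent-factor loadings.
#' @param noise_sd SD of the i.i.d. residual noise.
#' @param frac_informative fraction of variants forced ancestry-informative
#'   (frequency ~1 in one ancestry, ~0 in the other); recorded in ground truth.
#' @param frac_archaic_informative fraction of variants rewritten to tag
#'   Denisovan haplotypes exactly; recorded in ground truth.
#' @param unknown_frac expected fraction of bases masked to UNKNOWN ancestry.
#' @param unknown_mean_len mean length of UNKNOWN mask intervals, bp.
#' @param seed master seed; all sub-streams derive from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals_per_pop = c(Mentawai = 48L, Sumba = 48L, Korowai = 19L),
                       pop_theta = c(0.053, 0.268, 0.950),
                       n_variants = 10000L,
                       chrom_length = 5e7,
                       fst_divergence = 0.15,
                       admix_generations = 100,
                       recomb_rate = 1e-8,
                       archaic_seg_rate = 0.3,
                       archaic_seg_mean_len = 5e4,
                       nea_seg_rate = 0.25,
                       n_genes = 150L,
                       n_cpgs = 150L,
                       frac_causal = 0.25,
                       effect_size_sd = 0.8,
                       effect_size_fixed = NULL,
                       n_latent = 10L,
                       latent_sd = 0.4,
                       noise_sd = 1,
                       frac_informative = 0.05,
                       frac_archaic_informative = 0.02,
                       unknown_frac = 0.2,
                       unknown_mean_len = 2e4,
                       seed = 1L) {
  cfg <- list(n_individuals_per_pop = n_individuals_per_pop,
              pop_theta = pop_theta, n_variants = as.integer(n_variants),
              chrom_length = chrom_length, fst_divergence = fst_divergence,
              admix_generations = admix_generations, recomb_rate = recomb_rate,
              archaic_seg_rate = archaic_seg_rate,
              archaic_seg_mean_len = archaic_seg_mean_len,
              nea_seg_rate = nea_seg_rate,
              n_genes = as.integer(n_genes), n_cpgs = as.integer(n_cpgs),
              frac_causal = frac_causal, effect_size_sd = effect_size_sd,
              effect_size_fixed = effect_size_fixed,
              n_latent = as.integer(n_latent), latent_sd = latent_sd,
              noise_sd = noise_sd, frac_informative = frac_informative,
              frac_archaic_informative = frac_archaic_informative,
              unknown_frac = unknown_frac, unknown_mean_len = unknown_mean_len,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$pop_theta) != length(cfg$n_individuals_per_pop)) {
    stopf("pop_theta and n_individuals_per_pop must have equal length")
  }
  if (any(cfg$pop_theta < 0 | cfg$pop_theta > 1)) stopf("pop_theta must lie in [0, 1]")
  fr <- c(cfg$frac_causal, cfg$frac_informative, cfg$frac_archaic_informative,
          cfg$unknown_frac)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  cnt <- c(cfg$n_individuals_per_pop, cfg$n_variants, cfg$n_genes + cfg$n_cpgs)
  if (any(cnt < 1) || cfg$n_genes < 0 || cfg$n_cpgs < 0) stopf("counts must be >= 1")
  if (cfg$fst_divergence <= 0 || cfg$fst_divergence >= 1) {
    stopf("fst_divergence must lie in (0, 1)")
  }
  if (cfg$admix_generations <= 0) stopf("admix_generations must be > 0")
  if (cfg$noise_sd <= 0) stopf("noise_sd must be > 0")
  invisible(cfg)
}

#' Empty ground-truth container
#'
#' Holds the generator's ground truth: the phenotype-to-causal-variant map,
#' per-variant ancestry-informative flags, per-variant archaic flags
#' (`NONE`/`DEN`/`NEA`), and the phenotype-to-dataset map of where planted
#' effects are active.
#'
#' @return An object of class `ground_truth`.
#' @export
new_ground_truth <- function() {
  structure(list(
    causal_map = data.frame(phenotype_id = character(), variant_id = character(),
                            beta = numeric(), stringsAsFactors = FALSE),
    la_driven_flags = logical(0),
    archaic_flags = character(0),
    shared_pop_map = list()
  ), class = "ground_truth")
}

#' Draw Balding-Nichols allele frequencies for the two ancestries
#'
#' Each variant gets an ancestral frequency `p ~ Uniform(0.05, 0.95)` and
#' per-ancestry frequencies `Beta(p (1-F)/F, (1-p)(1-F)/F)`. A configurable
#' fraction of variants is forced ancestry-informative (frequency 0.99 in one
#' ancestry, 0.01 in the other) and flagged in the returned table.
#'
#' @param cfg A [sim_config()].
#' @param seed optional sub-stream seed (defaults to a sub-stream of
#'   `cfg$seed`).
#' @return data.frame with columns `p_anc`, `freq_asn`, `freq_pap`,
#'   `la_informative`.
#' @export
simulate_ancestral_frequencies <- function(cfg, seed = substream_seed(cfg$seed, "freqs")) {
  validate_sim_config(cfg)
  set.seed(seed)
  m <- cfg$n_variants
  p <- runif(m, 0.05, 0.95)
  k <- (1 - cfg$fst_divergence) / cfg$fst_divergence
  clamp <- function(x) pmin(pmax(x, 1e-4), 1 - 1e-4)
  fa <- clamp(rbeta(m, p * k, (1 - p) * k))
  fp <- clamp(rbeta(m, p * k, (1 - p) * k))
  inf <- rep(FALSE, m)
  n_inf <- floor(cfg$frac_informative * m)
  if (n_inf > 0) {
    idx <- sample.int(m, n_inf)
    orient <- runif(n_inf) < 0.5
    fp[idx] <- ifelse(orient, 0.99, 0.01)
    fa[idx] <- ifelse(orient, 0.01, 0.99)
    inf[idx] <- TRUE
  }
  data.frame(p_anc = p, freq_asn = fa, freq_pap = fp, la_informative = inf)
}

#' Simulate local-ancestry tracts for one haploid genome
#'
#' Two-state Markov process along the chromosome: recombination switch points
#' arrive as a Poisson process with rate `admix_generations x recomb_rate`
#' per bp and the ancestry after each switch point is redrawn
#' Bernoulli(theta), so the stationary Papuan probability is `theta` and the
#' mean visible tract length is `1 / (g r 2 theta (1 - theta))`. A fraction
#' of bases is optionally re-masked to UNKNOWN to emulate low-confidence
#' local-ancestry assignment.
#'
#' @param cfg A [sim_config()].
#' @param theta Papuan admixture proportion for this genome, in `[0, 1]`.
#' @param sample_id,hap identifiers stamped on the returned records.
#' @param seed sub-stream seed.
#' @return An [ancestry_tracts()] layer tiling `[0, chrom_length)`.
#' @export
simulate_tracts <- function(cfg, theta, sample_id = "S1", hap = 0L,
                            seed = substream_seed(cfg$seed, paste0("tracts:", sample_id, ":", hap))) {
  if (theta < 0 || theta > 1) stopf("theta must lie in [0, 1]")
  set.seed(seed)
  L <- cfg$chrom_length
  rate <- cfg$admix_generations * cfg$recomb_rate
  n_ev <- rpois(1L, L * rate)
  ev <- sort(runif(n_ev, 0, L))
  states <- runif(n_ev + 1L) < theta   # TRUE = PAPUAN
  bnd <- c(0, ev, L)
  # merge consecutive equal states
  keep <- c(TRUE, states[-1L] != states[-length(states)])
  starts <- bnd[-length(bnd)][keep]
  ends <- c(starts[-1L], L)
  labels <- ifelse(states[keep], "PAPUAN", "ASIAN")
  if (cfg$unknown_frac > 0) {
    n_u <- rpois(1L, cfg$unknown_frac * L / cfg$unknown_mean_len)
    if (n_u > 0) {
      us <- runif(n_u, 0, L)
      ue <- pmin(us + rexp(n_u, 1 / cfg$unknown_mean_len), L)
      cuts <- sort(unique(c(starts, ends[length(ends)], us, ue)))
      seg_s <- cuts[-length(cuts)]
      seg_e <- cuts[-1L]
      base <- labels[findInterval(seg_s, starts)]
      mid <- (seg_s + seg_e) / 2
      in_unknown <- vapply(mid, function(x) any(us <= x & x < ue), logical(1))
      base[in_unknown] <- "UNKNOWN"
      keep2 <- c(TRUE, base[-1L] != base[-length(base)])
      starts <- seg_s[keep2]
      ends <- c(starts[-1L], L)
      labels <- base[keep2]
    }
  }
  ancestry_tracts(data.frame(chrom = "chr1", start = starts, end = ends,
                             sample_id = sample_id, hap = as.integer(hap),
                             label = labels, stringsAsFactors = FALSE))
}

empty_tracts <- function() {
  ancestry_tracts(data.frame(chrom = character(), start = numeric(),
                             end = numeric(), sample_id = character(),
                             hap = integer(), label = character(),
                             stringsAsFactors = FALSE))
}

# Merge overlapping [start, end) intervals; rows assumed same hap/label.
reduce_intervals <- function(starts, ends) {
  if (!length(starts)) return(list(start = numeric(0), end = numeric(0)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], ends[i])
    } else {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    }
  }
  list(start = out_s, end = out_e)
}

#' Simulate archaic introgression segments for one haploid genome
#'
#' Denisovan segments are placed only inside PAPUAN tracts, as a Poisson
#' process with `archaic_seg_rate` segments per Mb of Papuan tract and
#' exponential lengths (clipped at the enclosing tract), so Denisovan
#' coverage scales with the Papuan fraction of the genome. Neanderthal
#' segments are placed independently of modern ancestry at `nea_seg_rate`
#' per Mb. The two archaic layers never overlap on the same haplotype
#' (Neanderthal segments intersecting a Denisovan segment are dropped).
#'
#' @param tracts modern-ancestry [ancestry_tracts()] for one haplotype.
#' @param cfg A [sim_config()].
#' @param seed sub-stream seed.
#' @return An archaic-layer [ancestry_tracts()] (possibly empty).
#' @export
simulate_archaic_segments <- function(tracts, cfg,
                                      seed = substream_seed(cfg$seed, paste0("archaic:", tracts$sample_id[1] %||% "NA", ":", tracts$hap[1] %||% 0))) {
  set.seed(seed)
  if (!nrow(tracts)) return(empty_tracts())
  sample_id <- tracts$sample_id[1]
  hap <- tracts$hap[1]
  pap <- tracts[tracts$label == "PAPUAN", , drop = FALSE]
  den_s <- numeric(0); den_e <- numeric(0)
  if (nrow(pap)) {
    for (i in seq_len(nrow(pap))) {
      len <- pap$end[i] - pap$start[i]
      n <- rpois(1L, len / 1e6 * cfg$archaic_seg_rate)
      if (n > 0) {
        s <- runif(n, pap$start[i], pap$end[i])
        e <- pmin(s + rexp(n, 1 / cfg$archaic_seg_mean_len), pap$end[i])
        ok <- e > s
        den_s <- c(den_s, s[ok]); den_e <- c(den_e, e[ok])
      }
    }
    d <- reduce_intervals(den_s, den_e)
    den_s <- d$start; den_e <- d$end
  }
  L <- cfg$chrom_length
  n_nea <- rpois(1L, L / 1e6 * cfg$nea_seg_rate)
  nea_s <- numeric(0); nea_e <- numeric(0)
  if (n_nea > 0) {
    s <- runif(n_nea, 0, L)
    e <- pmin(s + rexp(n_nea, 1 / cfg$archaic_seg_mean_len), L)
    ok <- e > s
    d <- reduce_intervals(s[ok], e[ok])
    nea_s <- d$start; nea_e <- d$end
    if (length(den_s)) {
      overlaps_den <- vapply(seq_along(nea_s), function(i) {
        any(nea_s[i] < den_e & den_s < nea_e[i])
      }, logical(1))
      nea_s <- nea_s[!overlaps_den]; nea_e <- nea_e[!overlaps_den]
    }
  }
  n_d <- length(den_s); n_n <- length(nea_s)
  if (n_d + n_n == 0L) return(empty_tracts())
  ancestry_tracts(data.frame(
    chrom = "chr1",
    start = c(den_s, nea_s), end = c(den_e, nea_e),
    sample_id = sample_id, hap = as.integer(hap),
    label = c(rep("DENISOVAN", n_d), rep("NEANDERTHAL", n_n)),
    stringsAsFactors = FALSE))
}

# Label of the tract covering each (1-based) variant position on one
# haplotype whose tracts tile the chromosome.
tract_label_at <- function(tracts_one_hap, pos) {
  t <- tracts_one_hap[order(tracts_one_hap$start), , drop = FALSE]
  idx <- findInterval(pos - 1, t$start)
  if (any(idx == 0) || any(pos - 1 >= t$end[pmax(idx, 1L)])) {
    stopf("variant position outside all tracts")
  }
  t$label[idx]
}

#' Simulate phased genotypes given ancestry tracts and per-ancestry frequencies
#'
#' Each haplotype's allele at each site is Bernoulli with the allele
#' frequency of the local ancestry at that position; UNKNOWN bases use the
#' individual's theta-weighted mixture frequency. The simulated reference
#' allele doubles as the ancestral allele annotation.
#'
#' @param freqs output of [simulate_ancestral_frequencies()].
#' @param positions sorted 1-based variant positions.
#' @param tracts modern-ancestry layer for the whole cohort.
#' @param samples data.frame with `sample_id` and `theta` per individual.
#' @param cfg A [sim_config()].
#' @param seed sub-stream seed.
#' @return A [haplotype_panel()].
#' @export
simulate_genotypes <- function(freqs, positions, tracts, samples, cfg,
                               seed = substream_seed(cfg$seed, "genotypes")) {
  set.seed(seed)
  m <- length(positions)
  stopifnot(nrow(freqs) == m)
  n <- nrow(samples)
  alleles <- matrix(0L, nrow = 2L * n, ncol = m)
  key <- paste(tracts$sample_id, tracts$hap)
  sp <- split(seq_len(nrow(tracts)), key)
  for (i in seq_len(n)) {
    sid <- samples$sample_id[i]
    theta <- samples$theta[i]
    mix <- theta * freqs$freq_pap + (1 - theta) * freqs$freq_asn
    for (h in 0:1) {
      rows <- sp[[paste(sid, h)]]
      if (is.null(rows)) stopf("no tracts for %s hap %d", sid, h)
      lab <- tract_label_at(tracts[rows, , drop = FALSE], positions)
      f <- ifelse(lab == "PAPUAN", freqs$freq_pap,
                  ifelse(lab == "ASIAN", freqs$freq_asn, mix))
      alleles[2L * (i - 1L) + h + 1L, ] <- as.integer(runif(m) < f)
    }
  }
  variants <- data.frame(chrom = "chr1", pos = positions,
                         ref = "A", alt = "G",
                         id = sprintf("var%05d", seq_len(m)),
                         ancestral = "A", stringsAsFactors = FALSE)
  haplotype_panel(variants, alleles, samples$sample_id)
}

#' Simulate anchored phenotypes with planted cis effects
#'
#' Phenotype model: `y = beta * dosage + sum_k L_k w_k + eps`, with latent
#' factor scores `L` shared across phenotypes, loadings `w` per phenotype,
#' and `eps ~ N(0, noise_sd^2)`. A fraction `frac_causal` of phenotypes gets
#' a causal variant sampled within 1 Mb of its anchor; the causal map is
#' recorded in the returned ground truth.
#'
#' @param panel A [haplotype_panel()].
#' @param truth A ground-truth object (updated and returned).
#' @param cfg A [sim_config()].
#' @param seed sub-stream seed.
#' @return list with `phenotypes` (a [phenotype_table()]) and `truth`.
#' @export
simulate_phenotypes <- function(panel, truth, cfg,
                                seed = substream_seed(cfg$seed, "phenotypes")) {
  set.seed(seed)
  n <- length(panel$sample_ids)
  if (n == 0L) stopf("panel sample set is empty")
  dos <- dosage(panel)
  n_ph <- cfg$n_genes + cfg$n_cpgs
  ids <- c(sprintf("gene%04d", seq_len(cfg$n_genes)),
           sprintf("cpg%04d", seq_len(cfg$n_cpgs)))
  group <- c(rep("expression", cfg$n_genes), rep("methylation", cfg$n_cpgs))
  anchor_pos <- sort(sample.int(cfg$chrom_length, n_ph))
  # keep anchor order random w.r.t. phenotype kind
  anchor_pos <- anchor_pos[sample.int(n_ph)]
  scores <- matrix(rnorm(n * cfg$n_latent), n, cfg$n_latent)
  n_causal <- round(cfg$frac_causal * n_ph)
  causal_ph <- if (n_causal > 0) sort(sample.int(n_ph, n_causal)) else integer(0)
  values <- matrix(0, n_ph, n)
  cmap <- vector("list", n_ph)
  pos <- panel$variants$pos
  for (j in seq_len(n_ph)) {
    y <- rnorm(n, 0, cfg$noise_sd)
    if (cfg$n_latent > 0) {
      w <- rnorm(cfg$n_latent, 0, cfg$latent_sd)
      y <- y + drop(scores %*% w)
    }
    if (j %in% causal_ph) {
      cand <- which(abs(pos - anchor_pos[j]) <= 1e6)
      if (length(cand)) {
        v <- cand[sample.int(length(cand), 1L)]
        if (abs(pos[v] - anchor_pos[j]) > 1e6) stopf("causal variant outside cis window")
        beta <- if (!is.null(cfg$effect_size_fixed)) cfg$effect_size_fixed else
          rnorm(1L, 0, cfg$effect_size_sd)
        y <- y + beta * dos[, v]
        cmap[[j]] <- data.frame(phenotype_id = ids[j],
                                variant_id = panel$variants$id[v],
                                beta = beta, stringsAsFactors = FALSE)
      } else {
        aq_log("warn", "no cis variant within 1 Mb of anchor for ", ids[j])
      }
    }
    values[j, ] <- y
  }
  truth$causal_map <- do.call(rbind, c(list(truth$causal_map), cmap[!vapply(cmap, is.null, logical(1))]))
  anchors <- data.frame(phenotype_id = ids, chrom = "chr1", pos = anchor_pos,
                        strand = "+", group = group, stringsAsFactors = FALSE)
  list(phenotypes = phenotype_table(values, anchors, panel$sample_ids),
       truth = truth)
}

#' Simulate an external pseudo-cohort and emit per-SNP summary statistics
#'
#' Draws an independent cohort of size `n` over the same variant set, with
#' its own allele frequencies (optionally re-diverged under the
#' Balding-Nichols model to emulate MAF differences between populations),
#' regresses a trait on each variant marginally, and returns beta/se/p/MAF/n
#' per SNP. The trait carries the given effect at `causal_idx` (or none).
#'
#' @param freqs frequency table from [simulate_ancestral_frequencies()]
#'   (rows matching `positions`).
#' @param positions 1-based variant positions.
#' @param n cohort size (>= 10).
#' @param causal_idx index into `positions` of the causal variant, or `NULL`.
#' @param beta per-allele effect size at the causal variant.
#' @param redraw_F optional Balding-Nichols F for re-drawing this dataset's
#'   frequencies around the ancestral frequency; `NULL` uses `p_anc` as is.
#' @param dataset_id label stored on the result.
#' @param variant_ids optional ids (default `var#####`).
#' @param seed RNG seed.
#' @return A [summary_stats()] table (monomorphic draws are dropped).
#' @export
simulate_external_study <- function(freqs, positions, n, causal_idx = NULL,
                                    beta = 0, redraw_F = NULL,
                                    dataset_id = "external", variant_ids = NULL,
                                    seed = 1L) {
  if (n < 10) stopf("external pseudo-dataset needs n >= 10")
  set.seed(seed)
  m <- length(positions)
  stopifnot(nrow(freqs) == m)
  f <- freqs$p_anc
  if (!is.null(redraw_F)) {
    k <- (1 - redraw_F) / redraw_F
    f <- pmin(pmax(rbeta(m, f * k, (1 - f) * k), 1e-4), 1 - 1e-4)
  }
  G <- matrix(rbinom(n * m, 2L, rep(f, each = n)), n, m)
  y <- rnorm(n)
  if (!is.null(causal_idx)) y <- y + beta * G[, causal_idx]
  gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  ssg <- colSums(gc^2)
  poly <- ssg > 0
  bhat <- rep(NA_real_, m)
  bhat[poly] <- colSums(gc[, poly, drop = FALSE] * yc) / ssg[poly]
  ssy <- sum(yc^2)
  sigma2 <- (ssy - bhat^2 * ssg) / (n - 2)
  se <- sqrt(pmax(sigma2, 1e-300) / ssg)
  tval <- bhat / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  fhat <- colMeans(G) / 2
  maf <- pmin(fhat, 1 - fhat)
  if (is.null(variant_ids)) variant_ids <- sprintf("var%05d", seq_len(m))
  out <- data.frame(variant_id = variant_ids, chrom = "chr1", pos = positions,
                    ref = "A", alt = "G",
                    beta = bhat, se = se, p = pmin(pmax(p, 1e-300), 1),
                    maf = maf, n = n, stringsAsFactors = FALSE)
  out <- out[poly & maf > 0, , drop = FALSE]
  summary_stats(out, dataset_id = dataset_id)
}

#' Simulate GWAS / external eQTL summary statistics for several pseudo-datasets
#'
#' For each phenotype in `truth$shared_pop_map` and each requested dataset,
#' simulates an independent cohort over the phenotype's cis window. "Shared"
#' phenotypes reuse the cohort's true causal variant in that dataset;
#' "specific" phenotypes carry the effect only where listed.
#'
#' @param panel the cohort [haplotype_panel()] (provides the variant grid).
#' @param freqs frequency table aligned with `panel`.
#' @param truth ground truth with a populated `shared_pop_map` (named list:
#'   phenotype id -> character vector of dataset ids where the effect is
#'   active) and `causal_map`.
#' @param phenotypes the cohort [phenotype_table()] (provides anchors).
#' @param datasets data.frame with `dataset_id` and `n`.
#' @param cfg A [sim_config()].
#' @param beta effect size used in datasets where the effect is active.
#' @param redraw_F optional Balding-Nichols F for per-dataset frequency
#'   divergence.
#' @return Nested list: `stats[[phenotype_id]][[dataset_id]]` is a
#'   [summary_stats()] table over the phenotype's cis variants.
#' @export
simulate_gwas_and_external_eqtl <- function(panel, freqs, truth, phenotypes,
                                            datasets, cfg, beta = 0.5,
                                            redraw_F = NULL) {
  if (!length(truth$shared_pop_map)) stopf("truth$shared_pop_map is empty")
  if (any(datasets$n < 10)) stopf("external pseudo-dataset needs n >= 10")
  pos <- panel$variants$pos
  out <- list()
  for (ph in names(truth$shared_pop_map)) {
    arow <- phenotypes$anchors[phenotypes$anchors$phenotype_id == ph, ]
    cis <- which(abs(pos - arow$pos) <= 1e6)
    cm <- truth$causal_map[truth$causal_map$phenotype_id == ph, ]
    causal_global <- if (nrow(cm)) match(cm$variant_id[1], panel$variants$id) else NA_integer_
    causal_local <- if (!is.na(causal_global)) match(causal_global, cis) else NULL
    out[[ph]] <- list()
    for (k in seq_len(nrow(datasets))) {
      did <- datasets$dataset_id[k]
      active <- did %in% truth$shared_pop_map[[ph]]
      out[[ph]][[did]] <- simulate_external_study(
        freqs[cis, , drop = FALSE], pos[cis], n = datasets$n[k],
        causal_idx = if (active && !is.null(causal_local) && !is.na(causal_local)) causal_local else NULL,
        beta = beta, redraw_F = redraw_F, dataset_id = did,
        variant_ids = panel$variants$id[cis],
        seed = substream_seed(cfg$seed, paste0("ext:", ph, ":", did)))
    }
  }
  out
}

#' Simulate a full admixed cohort with ground truth
#'
#' Orchestrates the whole generator: allele frequencies, per-haplotype
#' modern-ancestry tracts and archaic layers, phased genotypes, and anchored
#' phenotypes with planted cis effects. Ancestry-informative variants are
#' flagged in `truth$la_driven_flags`; a fraction of variants is rewritten to
#' segregate exactly with Denisovan haplotypes and flagged `"DEN"` in
#' `truth$archaic_flags`. Identical configuration (including seed) yields
#' bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @return list with `panel`, `tracts` (modern layer), `archaic` (archaic
#'   layer), `phenotypes`, `freqs`, `truth`, `samples` (sample/population/
#'   theta table) and `cfg`.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  freqs <- simulate_ancestral_frequencies(cfg)
  set.seed(substream_seed(cfg$seed, "positions"))
  positions <- sort(sample.int(cfg$chrom_length - 2L, cfg$n_variants)) + 1L
  pops <- names(cfg$n_individuals_per_pop) %||% paste0("pop", seq_along(cfg$n_individuals_per_pop))
  if (is.null(names(cfg$n_individuals_per_pop))) names(cfg$n_individuals_per_pop) <- pops
  samples <- data.frame(
    sample_id = sprintf("%s_%03d", rep(pops, cfg$n_individuals_per_pop),
                        unlist(lapply(cfg$n_individuals_per_pop, seq_len))),
    population = rep(pops, cfg$n_individuals_per_pop),
    theta = rep(cfg$pop_theta, cfg$n_individuals_per_pop),
    stringsAsFactors = FALSE)
  tr_list <- vector("list", 2L * nrow(samples))
  ar_list <- vector("list", 2L * nrow(samples))
  for (i in seq_len(nrow(samples))) {
    for (h in 0:1) {
      t <- simulate_tracts(cfg, samples$theta[i], samples$sample_id[i], h)
      tr_list[[2L * (i - 1L) + h + 1L]] <- t
      ar_list[[2L * (i - 1L) + h + 1L]] <- simulate_archaic_segments(t, cfg)
    }
  }
  tracts <- ancestry_tracts(do.call(rbind, tr_list))
  archaic <- ancestry_tracts(do.call(rbind, ar_list))
  panel <- simulate_genotypes(freqs, positions, tracts, samples, cfg)
  truth <- new_ground_truth()
  truth$la_driven_flags <- stats::setNames(freqs$la_informative, panel$variants$id)
  truth$archaic_flags <- stats::setNames(rep("NONE", cfg$n_variants), panel$variants$id)
  n_arch <- floor(cfg$frac_archaic_informative * cfg$n_variants)
  if (n_arch > 0 && nrow(archaic)) {
    set.seed(substream_seed(cfg$seed, "archaic-informative"))
    den_dos_hap <- archaic_coverage_haplotypes(archaic, panel, "DENISOVAN")
    cover <- colSums(den_dos_hap)
    cand <- which(cover >= 4 & !freqs$la_informative)
    if (length(cand)) {
      pick <- cand[sample.int(length(cand), min(n_arch, length(cand)))]
      for (v in pick) panel$alleles[, v] <- den_dos_hap[, v]
      truth$archaic_flags[pick] <- "DEN"
    }
  }
  ph <- simulate_phenotypes(panel, truth, cfg)
  list(panel = panel, tracts = tracts, archaic = archaic,
       phenotypes = ph$phenotypes, freqs = freqs, truth = ph$truth,
       samples = samples, cfg = cfg)
}

# Haplotype x variant indicator of archaic coverage for one label.
archaic_coverage_haplotypes <- function(archaic, panel, label) {
  m <- nrow(panel$variants)
  pos <- panel$variants$pos
  out <- matrix(0L, nrow = 2L * length(panel$sample_ids), ncol = m)
  sub <- archaic[archaic$label == label, , drop = FALSE]
  if (!nrow(sub)) return(out)
  key <- paste(sub$sample_id, sub$hap)
  sp <- split(seq_len(nrow(sub)), key)
  for (i in seq_along(panel$sample_ids)) {
    for (h in 0:1) {
      rows <- sp[[paste(panel$sample_ids[i], h)]]
      if (is.null(rows)) next
      s <- sub$start[rows]; e <- sub$end[rows]
      covered <- vapply(pos, function(x) any(s <= x - 1 & x - 1 < e), logical(1))
      out[2L * (i - 1L) + h + 1L, covered] <- 1L
    }
  }
  out
}
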