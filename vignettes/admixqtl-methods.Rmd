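---
title: "Methods: cis-QTL mapping, colocalization and ancestry attribution in admixed cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-QTL mapping, colocalization and ancestry attribution in admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixqtl)
```

# Scope

`admixqtl` implements an analysis framework for cohorts on an admixture
cline (here, an Asian–Papuan cline with archaic Denisovan and Neanderthal
introgression): permutation-based cis-QTL mapping for expression and
methylation phenotypes, Bayesian colocalization of association signals,
attribution of QTL genotypes to modern local ancestry or archaic
haplotypes, an nSL selection scan, cross-dataset effect-size sharing, and a
matched-random-set annotation enrichment. Because the human data such
studies use are access-controlled, the package ships a synthetic cohort
generator with complete ground truth; every downstream stage is validated
against that truth and against independent oracles (brute-force
enumeration, per-base interval scans, closed-form power).

# The cis-QTL model

For each phenotype $y$ (inverse-normal transformed per phenotype) and each
variant within 1 Mb of the phenotype's genomic anchor (TSS for genes, CpG
position for methylation probes), we fit

$$ y = \mu + \beta g + C\gamma + \varepsilon, $$

where $g \in \{0,1,2\}$ is the alternate-allele dosage from phased
haplotypes and $C$ contains five genotype principal components
(population-structure surrogate) plus latent phenotype factors, by default
$\lceil 0.25\, n \rceil$ of them. The latent factors are the leading
principal components of the covariate-residualized phenotype matrix — a
deliberately simple, testable surrogate for PEER-style variational factor
models, retaining the same role (absorbing broad technical/biological
variance) and the same factor-count rule. The two-sided $t$ test on
$\hat\beta$ gives the nominal p value.

## Permutation pass

The per-phenotype top association is calibrated by permutation: the
phenotype is residualized on the covariates once, the residual vector is
permuted $B$ times (default 10,000), each permuted vector is
**re-residualized** on the covariates, and the null statistic is the
minimum nominal p over the cis window. The adjusted p value is
$(1 + \#\{\text{null} \le \text{obs}\})/(1 + B)$, bounded below by
$1/(B+1)$. Re-residualizing matters: a permuted residual is no longer
orthogonal to the covariate space, and with $\sim$34 covariates at
$n = 115$ the uncorrected null is visibly anti-conservative. The
residualize–permute–re-residualize scheme (Freedman–Lane) keeps the
observed and null statistics in the same subspace with matched norms; on a
fully null synthetic cohort the permutation p values are
Kolmogorov–Smirnov-uniform. A Beta tail approximation to the null minima
is available (`beta_approx = TRUE`) but the empirical counting p is the
default. Discovery uses Benjamini–Hochberg q values over the per-phenotype
permutation p values (threshold 0.01 by default, conventionally relaxed to
0.10 for cross-population sharing analyses); a Storey-type variant is
behind a flag. Top-variant ties break toward the smaller nominal p, then
the smaller position.

`analytic_power()` gives the closed-form power of the slope test with
noncentrality $|\beta|\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}/\sigma$,
used as the independent oracle for effect-recovery checks.

# Colocalization

Per-SNP evidence is the Wakefield approximate Bayes factor
$\log \mathrm{ABF} = \tfrac12[\log(1-r) + r z^2]$ with $z = \beta/se$ and
$r = W/(W + se^2)$; $\sqrt W$ defaults to 0.15, the conventional prior SD
for quantitative traits (the source analyses do not state a value). When
betas are unavailable, $(p, \mathrm{maf}, n)$ are converted via the normal
quantile and $\mathrm{var}(\hat\beta) \approx 1/(2\,\mathrm{maf}
(1-\mathrm{maf})\,n)$.

Posteriors over the five hypotheses (no association / trait 1 only /
trait 2 only / two distinct causal variants / one common causal variant)
are accumulated in log space; for panels of up to six SNPs they agree with
direct enumeration over all causal configurations to $10^{-10}$
(a test-suite invariant). CCV = PP4, DCV = PP3. Classification:

* **STRONG**: CCV > 0.8 and CCV/DCV > 5 at the default prior
  ($p_{12} = 10^{-5}$);
* **ROBUST**: STRONG, and the same classification already holds at some
  $p_{12} < 10^{-6}$ on a 25-point log-spaced sensitivity grid spanning
  $[10^{-8}, 10^{-4}]$;
* **RELAXED_ONLY**: fails STRONG but passes CCV > 0.5 and CCV/DCV > 2;
* **NONE** otherwise.

Note that adding a constant to one trait's log-ABFs rescales H1, H3 and H4
jointly but not H0/H2, so PP0–PP2 are not invariant to such shifts; the
CCV/DCV ratio is, and that is the invariant the suite asserts.

Multi-signal traits are handled by masking: independent signals are
detected iteratively (accept the minimum-p variant with $p < 10^{-6}$
among variants with $r^2 < 0.01$ to every accepted lead), and each signal
pair is tested on the variant subset in linkage equilibrium with every
*other* lead of its own dataset. With one signal per trait this reduces
exactly to the unmasked test. GWAS traits without LD information use the
single-causal-variant mode (no masking). The QTL–selection overlap reuses
this machinery with rank-based empirical nSL p values on one side; those
are not sampling p values, so that overlap is a ranking heuristic and is
documented as such.

# Ancestry and archaic attribution

Local-ancestry dosage PAP counts, per sample and position, haplotypes
whose tract is labeled PAPUAN (half-open intervals; a position on a
boundary belongs to the right-hand tract). If any covering tract is
UNKNOWN the dosage is missing and the sample is dropped pairwise — counting
UNKNOWN as zero would bias the slope toward zero. For each QTL variant we
fit $V = \alpha \times \mathrm{PAP} + \beta$, where $V$ is the count of
QTL B alleles, and flag the variant ancestry-driven when $R^2 > 0.7$
(squared Pearson correlation; the threshold is exposed as a parameter).
The same regression against Denisovan or Neanderthal coverage dosages
yields the archaic attributions. The intended pipeline order is: map QTLs,
select FDR-significant records, then attribute their top variants.

High-confidence archaic haplotypes come from an intersection filter: a
ChromoPainter-style Denisovan interval is kept iff it overlaps each of two
HMM-based call sets by more than 0.001% and overlaps the Neanderthal call
set by at most 0.001% — fractions of the filtered interval's own length.
The source description leaves the denominator ambiguous (CP interval, HMM
interval, or union); we use the filtered interval's length and expose the
threshold (`min_overlap_frac = 1e-5`). The mirrored argument order builds
the Neanderthal set. The filter is validated against a per-base brute-force
oracle on randomized configurations including exact-threshold boundaries.

# nSL selection scan

For each focal SNP with an ancestral-allele annotation, haplotype pairs
within the ancestral and derived classes are extended to the maximal
interval of segregating sites containing the focal site over which the
pair is identical; $SL_A$, $SL_D$ are class-wise pair means and
$\mathrm{nSL} = \ln(SL_A/SL_D)$ (negative at sweep-like sites). Pairwise
extension is truncated at 1,333 loci per flank and physical gaps over
50 kb act as barriers — configurable analogues of selscan's decay cap and
maximum gap, with defaults mirroring the published run parameters. Raw
scores are normalized (z-scored) within ten equal-width derived-allele-
frequency bins genome-wide; the 50-kb windows enter only through the test
statistic, since binning *within* windows would leave too few SNPs per
stratum at desk scale. Windows with fewer than 21 scored SNPs are
discarded; a window is an outlier when more than 30% of its scores exceed
|2|. Empirical p values are rank/N with average ties, rank 1 being the
most extreme value. Variants with any missing alleles are excluded from
the scan (a haplotype statistic needs complete data) and SNPs whose
ancestral annotation matches neither allele are skipped with a reason
code.

# Sharing and specificity

Two effect estimates are "shared" when they have the same sign and are
within a factor of 0.5 — read as magnitude ratio in $[0.5, 2]$, the
multivariate-shrinkage convention; the phrase alone does not pin down a
direction, so this reading is stated prominently. Pairwise sharing
fractions condition on pairs significant in the union of each dataset pair
(switchable to both-significant). Full multivariate adaptive shrinkage
(data-driven covariances, extreme deconvolution, posterior effects) is out
of scope: the reported sharing criterion is exactly this threshold rule on
per-dataset OLS effects. A phenotype is target-specific iff it is
significant in the target, unshared with every other dataset, and its
colocalization label against every other dataset is NONE (i.e. it fails
even the relaxed tier); a missing colocalization makes it indeterminate,
never specific. Enrichment of variant sets in annotations uses 100 random
sets matched variant-by-variant on MAF decile and distance-to-anchor
decile drawn from a user-supplied pool — an LD-free stand-in for
LD-block-based matched variant sets, adequate at desk scale where no LD
reference panel exists.

# The synthetic cohort generator

The generator emulates the study conditions end to end, with defaults
chosen once:

* **Cohort**: 115 individuals — 48 + 48 + 19 across three populations with
  mean haploid Papuan proportions 0.053, 0.268 and 0.950, matching the
  reported cline.
* **Chromosome**: one 50-Mb chromosome with 10,000 SNPs. One chromosome
  suffices for a desk-scale testbed; positions are uniform.
* **Allele frequencies**: Balding–Nichols with ancestral
  $p \sim U(0.05, 0.95)$ and per-ancestry
  $\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$, $F = 0.15$ — a realistic
  divergence for the two ancestry sources. A configurable fraction of
  variants is forced ancestry-informative (0.99/0.01) and recorded in the
  ground truth; a further fraction is rewritten to segregate exactly with
  Denisovan haplotypes.
* **Tracts**: a two-state Markov process — switch points Poisson at
  $g \cdot r$ per bp ($g = 100$ generations, $r = 10^{-8}$ Morgans/bp),
  state redrawn Bernoulli($\theta$) at each switch — giving stationary
  Papuan probability $\theta$ and mean visible tract length
  $1/(2 g r \theta(1-\theta))$. The admixture time and tract-length law for
  these populations are not published; these are calibration choices, not
  claims. A configurable fraction of bases (default 20%, matching the
  71–85% confident-assignment range) is re-masked UNKNOWN to exercise the
  unknown-handling path.
* **Archaic layers**: Denisovan segments only inside Papuan tracts at 0.3
  segments per Papuan-tract Mb with exponential 50-kb lengths — calibrated
  so per-population Denisovan coverage spans roughly 0.05–1.4% of the
  haploid genome across the cline, and Papuan fraction and Denisovan
  fraction are strongly correlated across individuals ($r \approx 0.95$
  at this chromosome length; the genome-wide analogue is reported near
  0.995). Neanderthal segments are placed ancestry-independently (0.25/Mb)
  and never overlap Denisovan segments on a haplotype.
* **Phenotypes**: $y = \beta g + \sum_k L_k w_k + \varepsilon$ with shared
  latent factor scores, per-phenotype loadings (SD 0.4), unit residual SD,
  causal variants within 1 Mb of the anchor, and effects
  $\beta \sim N(0, 0.8^2)$ (or a fixed value for power experiments) for a
  quarter of phenotypes by default.
* **External pseudo-cohorts**: independent cohorts over the same variant
  grid, optionally with Balding–Nichols re-diverged frequencies, sharing
  (or not) the causal variant; marginal per-SNP beta/se/p/MAF/n are
  emitted.

All randomness flows from one master seed through tagged sub-streams
(`substream_seed()`), so equal configurations give byte-identical output;
the CLI inherits this property.

What the generator does **not** emulate: within-ancestry linkage
disequilibrium (sites are independent given the tract labels), realistic
site-frequency spectra, multi-chromosome genomes, or methylation array
artifacts. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to real-data
LD structure — in particular the unlinked-variant design makes permutation
calibration and signal masking *easier* than on real data.

# Numerical choices and degenerate inputs

* Monomorphic in-sample variants are skipped in scans and annotation
  (with reason codes); constant ancestry dosages yield missing $R^2$, never
  a crash.
* Hypothesis sums in colocalization use log-sum-exp; H3 uses a guarded
  log-difference.
* Frequency bins with fewer than two scores or zero SD yield missing
  normalized nSL values.
* The inverse-normal transform uses $\Phi^{-1}((\mathrm{rank}-0.5)/n)$
  with average ties; all-constant input returns zeros with a warning.
* Empty QC output is a warning, not an error; a phenotype with no cis
  variants yields no record.
* Problem sizes in the validation suite (e.g. a 2,000-phenotype null
  cohort at 1,000 permutations, 100-replicate colocalization recovery,
  1,000 interval-filter configurations) were chosen as the smallest sizes
  at which the targeted properties are statistically sharp.

# Known limitations

* PEER and mashr are represented by their roles (phenotype-PCA factors;
  the sign/factor-2 sharing rule), not reimplemented.
* The nSL implementation is exact but quadratic in haplotypes; it is
  sized for cohort-scale panels (hundreds of haplotypes), not biobanks.
* GWAS-mode colocalization inherits the single-causal-variant assumption;
  with multiple causal variants and no LD it can dilute PP4.
* Tract simulation is Markovian; real ancestry switch processes are not,
  and real tract-length heavy tails are not reproduced.

# A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 100, n_cpgs = 100, n_variants = 2000,
                  chrom_length = 1e7, seed = 42)
sim <- simulate_cohort(cfg)
sc <- qtl_scan_config(n_permutations = 1000, fdr_threshold = 0.01, seed = 1)
qtl <- map_qtl(sim$panel, sim$phenotypes, sc)
sig <- qtl[qtl$significant, ]
attrib <- ancestry_qtl_attribution(sig$top_variant_id, sim$panel,
                                   sim$tracts, "PAPUAN")
table(attrib$driven_flag)
```
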