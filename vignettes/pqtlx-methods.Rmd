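---
title: "Cross-tissue pQTL colocalization, tissue enrichment and MR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue pQTL colocalization, tissue enrichment and MR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pqtlx asks a simple biological question with several statistical moving
parts: when a protein's abundance is under genetic control in two tissues
(say plasma and brain), is it the *same* causal variant acting in both, and
does it push abundance in the same direction? The answer feeds two
downstream analyses: whether cross-tissue genetic concordance tracks where
the gene is expressed, and whether the choice of tissue changes the causal
effect a Mendelian randomization (MR) analysis would attribute to the
protein.

This vignette documents the statistical model behind each stage, every
tunable parameter with its default and units, what the bundled synthetic
data generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## Harmonization

Both tissues' summary statistics are reduced to one aligned variant universe
per protein. Variant identity is chromosome, position and the *unordered*
allele pair; rsIDs are annotation only. Where the second dataset reports the
swapped allele order, its effect is negated and its effect-allele frequency
(EAF) mirrored. Palindromic variants (A/T, C/G) cannot be strand-resolved
from alleles alone, so they are oriented by frequency proximity (match
`eaf` against `1 - eaf`) when the minor-allele frequency is at most 0.40 in
both datasets, and dropped otherwise — the standard compromise between
losing variants and silently mis-orienting them.

Filters and their defaults, all configurable:

* cis window: 500 kb (bp) around the gene *body*, boundaries inclusive.
  A transcription-start-site anchor is available (`anchor = "tss"`); the
  gene-body anchor is the default because it is the most permissive literal
  reading of "within 500 kb of the gene".
* MAF filter: `min(eaf, 1 - eaf) > 0.05`, strict.
* Locus eligibility: minimum p `< 5e-8` (strict) in **both** tissues. This
  deliberately removes loci where a colocalization failure would merely
  reflect low power in one dataset.

## Multi-signal colocalization

A locus may carry several independent cis signals. Signals are detected per
trait by stepwise approximate conditional analysis on the standardized
scale: with marginal z-scores and per-variant sample sizes, `b = z / sqrt(n)`
and, given a selected index set S and reference LD correlation matrix R,

    b_{j|S}  = b_j - R_jS (R_SS + eps I)^{-1} b_S
    se_{j|S} = sqrt((1 - q_j) / n_j),   q_j = R_jS (R_SS + eps I)^{-1} R_Sj

The ridge `eps = 1e-6` keeps the solve stable; variants with `q_j > 0.95`
are collinear with the selected set and are neither selectable nor assigned
a conditional effect (they are treated as null — their effect is not
identifiable from reference LD). Selection stops when no conditional |z|
reaches 5.4513 (two-sided p = 5e-8) or when K = 10 signals are reached.
Ties in |z| break to the smaller position so results are deterministic.
The conditional SE omits residual-variance shrinkage: the exact per-signal
residual variance is not identifiable from summary statistics, and at these
sample sizes the large-n approximation `var(b_j) = 1/n` is standard.

Each signal then carries leave-one-out conditional statistics (conditioned
on the other leads only), and every cross-trait signal pair is scored with
Wakefield approximate Bayes factors,

    log ABF = 0.5 log(V / (V + W)) + (z^2 / 2) (W / (V + W)),  V = se^2,

with prior effect variance `W = 0.15^2` on the standardized scale, under
the classical five-hypothesis enumeration (no signal / trait-A only /
trait-B only / two distinct variants / one shared variant) with priors
`p1 = p2 = 1e-4`, `p12 = 1e-5` — the field-standard defaults. The cross
term `L1*L2 - L12` is evaluated stably in log space; a single-variant locus
forces the distinct-variant hypothesis probability to exactly zero.
Per-variant posterior inclusion probabilities (PIPs) under the shared
hypothesis are `A_k B_k / sum(A B)`; the 0.95-mass credible set is the
smallest PIP-descending prefix. Signal pairs are matched greedily by
descending PP4 with each signal used at most once, which prevents one
strong signal from being counted against several partners; the locus-level
colocalization probability is the maximum PP4 across matched pairs and the
locus is called colocalized when it strictly exceeds 0.8.

Direction concordance compares the signs of the two traits' *marginal*
betas at the matched pair's lead (max-PIP) variant. Marginal rather than
conditional estimates are used — and the best pair's lead rather than
per-trait leads — because the magnitudes of the two datasets' effects are
not comparable across platforms, only their signs; this convention is
flagged here because either choice is defensible. The cohort summary
reports Spearman's rank correlation of those lead-variant effect pairs
across colocalized loci (absent with fewer than two).

## Tissue-specific expression enrichment

Counts are filtered to genes with at least 5 reads in at least 20% of
samples, both thresholds inclusive. The detection fraction is taken
globally over all samples rather than per tissue — the simpler reading when
the text is ambiguous — with the per-tissue alternative available through
the filter's arguments. Between-sample normalization is trimmed mean of
M-values (TMM) as implemented in edgeR: reference sample chosen by the
75th-percentile rule, 30%/5% double trimming of the M/A distributions,
precision-weighted trimmed mean, factors rescaled to geometric mean 1;
normalized expression is CPM-like, `count / (library size x factor) x 1e6`.

Per gene and tissue the median normalized expression across samples is
standardized twice with robust statistics: stage 1 centers and scales each
tissue's distribution across genes by its median and scaled MAD (constant
1.4826, so scores are comparable to Gaussian z-scores); stage 2 does the
same across tissues within each gene. A tissue is *elevated* for a gene
when its final z strictly exceeds 2. Degenerate cases are excluded rather
than imputed: a tissue whose stage-1 MAD is zero is dropped with an
error-level log, and a gene whose stage-2 MAD is zero is excluded with the
reason recorded — this avoids infinite z-scores and keeps exclusions
testable. Colocalized and non-colocalized proteins are then contrasted per
tissue with a 2x2 Pearson chi-squared test (df = 1, no continuity
correction, matching default large-sample practice; the Yates correction
is available through the contrast function's `correct` argument). Tables with a zero
marginal have an undefined statistic and are reported as absent.

## Mendelian randomization

For each colocalized signal pair the shared lead variant (PIP argmax) is
the instrument; the same lead is used for both tissue sources, the closest
reading of instrumenting "the colocalized credible set" (a per-tissue-lead
variant would differ only through LD noise). Proteins without colocalized
loci are excluded entirely. Instruments must be pairwise independent
(r-squared < 0.01 against the LD panel); a violation is an error rather
than a silent prune, since independence is part of the analysis contract.

With one instrument the estimate is the Wald ratio `beta_y / beta_x` with
first-order delta SE `se_y / |beta_x|` (the dominant two-sample MR
convention; a second-order SE including the exposure-side uncertainty is
available via `second_order = TRUE`). With two or more instruments a
fixed-effect inverse-variance weighted average is used — heterogeneity is
not identifiable from two instruments, so random-effects weighting is out
of scope. Significance is `p < 1e-5`, strict. Each protein's plasma- and
brain-instrumented estimates are emitted side by side with a
direction-concordance flag.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with recorded
ground truth. Genotypes are dichotomized Gaussians: within each LD block a
latent AR(1) process with correlation `rho = 0.9` is drawn twice (two
haplotypes) and thresholded at the MAF quantile; dosage is the sum. This
gives exact, analytically tractable control of block structure and MAF at
desk scale — where a coalescent simulation would add realism (recombination
gradients, rare variants, haplotype sharing) that none of the calibration
properties need. Note that dichotomization attenuates the latent
correlation: at `rho = 0.9` the adjacent *dosage* correlation is roughly
0.55–0.7 depending on the MAFs (the tetrachoric relationship), which is the
relevant quantity for LD-based analysis and is what the tests check against
a numerically integrated oracle.

Default locus geometry: 100 variants in 5 blocks, 1 kb spacing, MAF uniform
in \[0.05, 0.5\], gene body at the locus centre. Scenario labels plant the
qualitative configurations the pipeline must distinguish: a shared causal
variant with concordant or discordant signs, distinct causal variants in
separate blocks (redrawn until their panel r-squared is below 0.1), a
single-tissue signal, or no signal. Each causal signal explains
`h2 = 0.05` of protein variance; cohort sizes default to `n_a = 35,000`
and `n_b = 1,000`, echoing the order-of-magnitude power asymmetry between
large plasma cohorts and small brain cohorts, with an LD reference panel of
5,000. Phenotypes are linear in standardized dosage with Gaussian noise;
summary statistics are per-variant marginal OLS, matching the standardized
scale assumed by the conditional analysis. The outcome cohort
(`n = 100,000` by default) receives `theta x protein + N(0,1)` through the
mediating tissue's protein model, so discordant loci produce
opposite-signed MR estimates by construction.

Expression counts are negative binomial (dispersion 0.1) around log-normal
per-gene baselines (log-mean `log 50`, log-sd 1) and log-normal library
scales (log-sd 0.3), with 50 tissues of 10 samples each and 5% of genes
planted 8-fold up in one tissue. These sizes are a deliberate desk-scale
reduction of an atlas-style resource; they preserve the two-stage z-score's
operating characteristics without its data volume.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: proteomic platform measurement error and
normalization artefacts, fine-scale recombination and rare variants,
population stratification, sample overlap between exposure and outcome
GWAS, trans effects, and tissue-sharing correlation structure in
expression. Calibration results here certify the *method implementation*,
not field performance on consortium data.

## Study-level defaults and problem sizes

The default simulated study has 40 proteins with scenario mix 40%
shared-concordant, 10% shared-discordant, 25% distinct, 15% single-tissue
and 10% null, which yields the intended cohort-level picture: most tested
loci colocalize and roughly a fifth of colocalized loci are discordant.
Every other threshold defaults to the analysis values above and is recorded
in the emitted run report. Calibration tests use 100–200 loci per scenario
and the MR type-I check uses 1,000 single-variant replicates; these sizes
were chosen so the whole suite runs comfortably on a laptop while leaving
the binomial noise on each checked proportion well inside its margin.

## Numerical notes

* Hypothesis enumeration and PIPs are computed entirely in log space with
  log-sum-exp; posteriors normalize to 1 within 1e-9 by construction.
* p-values that underflow double precision (|z| above ~38) are clamped to
  the smallest positive double rather than dropped — at the default study
  conditions the causal variant itself underflows.
* Written TSVs render numerics with 17 significant digits, so write/read
  round trips are exact to better than 1e-12 relative.
* All generators are pure functions of `(config, seed)`: seeds are forked
  per stage and per locus by a counter scheme, so stage reordering cannot
  silently change draws, and rerunning a study with the same seed
  reproduces every output byte for byte.
* Ties (equal conditional |z|, equal PIP) break to the smaller genomic
  position.

## Known limitations

* Conditional analysis inherits reference-LD error; with very large
  cohorts and small panels, spurious secondary signals are possible. The
  collinearity guard and the panel size default (5,000) keep this rare in
  the calibrated regime, but the K > 1 machinery is only as good as the
  panel.
* The Wald SE ignores exposure-side uncertainty; with weak instruments
  this understates the variance (mitigated here by the genome-wide
  significance requirement on instruments).
* The two-stage enrichment z-score operates on raw CPM-scale medians;
  extremely skewed genes can dominate a tissue's stage-1 scale. Robust
  (median/MAD) statistics bound, but do not eliminate, this influence.
* `detect_signals` assumes one sample size per variant is trustworthy;
  missing n falls back to the locus median with a warning.
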