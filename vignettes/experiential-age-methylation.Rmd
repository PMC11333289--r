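---
title: "Deriving and validating experiential-age methylation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating experiential-age methylation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaclock)
```

## The problem

DNA methylation drifts with age at specific CpG loci, and linear
combinations of per-CpG beta values ("epigenetic clocks") can estimate an
organism's chronological age.  For long-lived, repeatedly dividing cell
lineages — memory T cells above all — two notions of age come apart: the
**host's chronological age** and the lineage's **experiential age (EA)**,
the cumulative number of divisions its ancestors have undergone.  Serial
transplantation experiments can push a T cell lineage through several host
lifetimes of replicative history while its hosts stay young, so a cohort of
such samples decouples the two axes.  This package provides the full
analysis chain for deriving an EA signature from such a cohort — per-CpG
differential methylation testing, area-statistic DMR segmentation,
signature scoring, clock comparison and saturation diagnostics, enrichment
and genomic annotation — together with a synthetic-cohort generator that
makes every step testable against a planted ground truth.

## The drift model behind the simulator

The generator assigns every CpG site one of four classes and a baseline
methylation $b_i$, then evolves the expected beta value as a function of
divisions $D$ and host age $A$ (months):

* **gain**: $\mu_i(D) = b_i + (1 - b_i)\,(1 - e^{-kD})$, with low baseline
  ($b = 0.05$).  A saturating exponential is the simplest bounded drift
  law: methylation cannot exceed 1, so any locus-level accumulation
  process with a roughly constant per-division hit rate saturates, which
  is also what makes clocks trained on a short age range plateau beyond
  it.  Gain loci are planted in contiguous runs (8 CpGs within 400 bp by
  default) so that region segmentation is genuinely exercised.
* **loss**: $\mu_i(D) = b_i\,e^{-rD}$ from a high baseline, producing the
  slow genome-wide demethylation expected of aged, highly divided
  lineages.
* **hostage**: $\mu_i(A) = b_i + (1 - b_i)(1 - e^{-r_A A})$ — loci that
  track the *host's* age only.  They default to 1% of sites with at most
  ~0.1 beta change over a 30-month lifespan, encoding the premise that in
  T cells division-coupled drift dominates host-age-coupled drift.
* **stable**: constant at baseline.  Baselines for stable sites are drawn
  from a bimodal mixture (60% Beta(16, 4), 30% Beta(2, 18), 10%
  Beta(4, 4)), the familiar two-humped WGBS beta distribution.

Counts are generated per (site, sample): coverage is negative binomial
(mean 20, size 5 — a standard WGBS-like depth model; the source design
specifies no coverage distribution), and methylated counts are
beta-binomial around $\mu$ with overdispersion $\varphi = 0.02$,
representing biological replicate-to-replicate variation.

Reference parameter values: the gain rate $k$ solves
$(1-b)(1-e^{-16k}) = 0.4$, i.e. gain loci rise by $\Delta\beta = 0.4$
between 0 and 16 divisions — the two-group study condition used
throughout the tests; `gain_rate_for_delta()` exposes the calibration.
With this $k$, 95% of the asymptotic change is reached near $D \approx
88$, so a ladder spanning $D \in [0, 160]$ probes both the linear regime
and the plateau.  One host lifetime is taken as 30 months.  The
rest-period design defaults to 5 boost cycles with 10 divisions per cycle
after a 60-day rest versus 7 after a 30-day rest (shorter rests allow
less expansion per cycle); 5 cycles keeps both arms inside the dynamic
range of the gain law, which is where a rest-length contrast is
informative.

What the generator deliberately does **not** emulate: read-level
artifacts (bisulfite conversion errors, mapping bias, strand asymmetry),
SNP-confounded CpGs, correlated dispersion structure along the genome,
and smoothly varying regional methylation.  Passing the recovery tests
therefore shows the statistical chain is correct and calibrated under the
stated noise model — not that it is robust to every artifact of real
WGBS data.

## Per-CpG test and DMR segmentation

Each covered site (coverage filter: strictly more than 5 reads in every
sample, exposed as `min_exclusive`) is tested between two groups with a
Wald statistic on arcsine-square-root transformed proportions:
$y = \arcsin\sqrt{(m + 0.5)/(t + 1)}$ stabilizes the binomial variance at
approximately $1/(4t)$.  Group means are coverage-weighted; the variance
combines the known sampling term $1/(4(t+0.5))$, averaged within group,
with a pooled moment-estimated biological variance floored at $10^{-4}$
(the floor prevents zero-variance degeneracy at identical counts, and
dominating the known sampling floor keeps the statistic close to normal
despite the few degrees of freedom available for the moment estimate).
The package's null simulations check the resulting candidate fraction at
$p < 0.01$ stays near nominal.  This test is a deliberately simple,
fully specified replacement for dispersion-shrinkage DMR callers; it does
not smooth across CpGs and does not borrow information between sites, so
per-site power is somewhat lower than smoothing callers achieve.

Candidates ($p < 0.01$) are segmented into DMRs: maximal same-sign runs
with inter-candidate gaps of at most 300 bp, at least 3 candidate CpGs,
and same-sign regions closer than 100 bp merged.  Only the $p$ threshold
is fixed by the reference procedure; the three segmentation parameters
follow common DMR-caller defaults and are all exposed.  A region's
signed **area statistic** is the sum of member $z$ values — members being
all same-sign candidates in the final interval, so the statistic is
recomputable from coordinates alone, an invariant the tests assert to
$10^{-12}$.  Signatures are the top-$K$ regions by $|$area$|$
($K = 150$ by default; $K = 139$ matches the senescence-resistance
program cardinality), ties broken by coordinate for determinism, as are
all other ties in the package.

## Scores, clocks and the plateau

A signature is scored per sample as the unweighted mean over regions of
the pooled ratio $\sum m / \sum t$ across member CpGs — pooling counts
rather than averaging per-CpG betas weights CpGs by the evidence
available and is invariant to splitting a region only when recomputed
from pooled counts (also asserted in the tests).  Weighted clocks
(`score = intercept + sum(w * beta)`) accept any external weight table;
their scores are age estimates and may be negative.  Missing clock sites
default to imputation from shipped reference means (cohort means as
fallback), refusing above 20% missingness — array/WGBS site mismatch is
the common failure mode and silent dropping changes weighted scores.

Saturation is quantified by fitting $s = a + b(1 - e^{-cD})$ with
Levenberg–Marquardt least squares ($c \ge 0$, five fixed starting rates
spanning $0.1$–$5$ per age range; base `nls` is not used because it
aborts on zero-residual data) against a linear fit, compared by AIC
computed from the residual sum of squares.  `saturation_age`
($-\ln(0.05)/c$) is where 95% of the asymptotic change is reached.  The
saturating family is a diagnostic construct for detecting and locating a
plateau, not a mechanistic claim about drift kinetics.

## Enrichment and annotation choices

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum; genes
are ranked by $\mathrm{sign}(\Delta\beta)\times(-\log_{10} p)$ of their
single largest-magnitude DMR, with the region $p$ taken as the normal
tail of $\mathrm{area}/\sqrt{n_{\mathrm{CpG}}}$ (a Stouffer combination
— the simplest defensible region-level $p$ given only per-site
statistics).  Significance comes from gene-label permutations; the
$p$-value counts same-sign permutations at least as extreme, normalized
over the same-sign permutations with a +1 correction.  Normalizing over
all permutations instead would roughly halve null $p$-values (the null
ES splits across signs), an anti-conservative behavior the calibration
tests reject; the convention used here matches standard preranked GSEA
practice and keeps null $p$-values inside the binomial envelope of
uniformity.

Region-set enrichment against term domains uses the exact one-sided
binomial tail with no multiple-testing adjustment, with the term
probability equal to merged domain span over genome size and hits counted
by region midpoint.  `basal_domains()` builds simple TSS −5 kb/+1 kb
regulatory domains; full regulatory-domain heuristics of web-based tools
are out of scope — the statistic, not the domain construction, is the
reproducible core.

Annotation is midpoint-based so every region gets exactly one feature
label (precedence promoter > 5′ UTR > 3′ UTR > exon > intron >
intergenic) and one CpG context.  Windows follow standard conventions —
promoter −2000/+500 bp around the TSS, shores ±2 kb of islands, shelves
the next 2 kb — and are all configurable, since no single convention is
canonical.  UTRs derive from CDS versus transcript bounds; genes without
CDS contribute only exon/intron.

## Coordinates, formats, determinism

Internally everything is 0-based half-open (BED-interoperable);
Bismark-coverage I/O (1-based inclusive) converts at the boundary.  Input
counts are assumed strand-collapsed per CpG dyad — **no strand merging is
performed**.  Simulation is bit-reproducible for a fixed seed, and the
pipeline derives per-stage seeds by hashing stage names from one master
seed, so adding a stage does not reshuffle downstream randomness.
Methylation fractions in coverage files are formatting only; counts are
the authoritative data and round-trip exactly.

## Problem sizes

The validation suite runs on cohorts of 20,000 sites (200 planted
8-CpG runs) with 3 replicates per condition for recovery, decoupling,
ladder and rest-design checks, 50,000 sites for null calibration, and
21-sample ladders to $D = 160$ for the plateau analysis — sizes at which
the Monte-Carlo properties being asserted (recovery above 90%, candidate
fraction in [0.005, 0.02], Pearson $r \ge 0.95$, slope ratio below 25%)
are stable across seeds while the whole suite stays fast on a laptop.

## Known limitations

* The per-CpG test assumes coverage-filtered input; sites with a
  zero-coverage group yield missing statistics rather than shrunken ones.
* No covariate adjustment or paired designs in the site test.
* Signature scores are means of region methylation: comparable within a
  cohort and monotone in drift, but not calibrated ages in years; mapping
  scores to age units requires an external anchor.
* `classify_feature()` resolves multi-isoform genes only through the
  single transcript provided per gene.
* The simulator's independence across sites understates the correlation
  of real methylomes; planted-recovery rates on real data will be lower.
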