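---
title: "Methods: junction-aware cis-eQTL analysis and the direction-of-effect flip"
author: "spliceflip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-aware cis-eQTL analysis and the direction-of-effect flip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceflip)
```

## The problem this package addresses

When a gene expresses both a protein-coding splice variant and non-coding
variants that retain an intron, "the expression of the gene" is not one
quantity. A microarray probe that binds across an exon-exon junction
detects only the transcripts that splice that junction; RNA-seq total
quantification (FPKM) sums every variant. If a regulatory variant pushes
the coding variant up and the intron-retaining variants down, the *same*
SNP can be a significant eQTL with a positive effect on the
junction-restricted measurement and a negative effect on total
expression. Cross-study comparisons that ignore this will report
"opposite" eQTL directions that are in fact consistent.

`spliceflip` implements the full analysis chain needed to detect and
reconcile this phenomenon: split-read junction quantification from
alignments, covariate-adjusted differential expression, cohort-wise
cis-eQTL/spliceQTL with meta-analysis, LD-block clustering, GWAS-catalog
cross-referencing, and a per-SNP direction report across measurement
modes. A synthetic multi-cohort generator with planted effects makes
every stage testable end to end without any external data.

## Junction quantification

Split reads are recognised by the `N` operation in the CIGAR string. The
reference walk treats `M`, `D`, `N`, `=`, `X` as consuming reference and
`I`, `S`, `H` as not; each `N` yields one junction whose intron is the
reference interval the operation consumes. All coordinates are 1-based
inclusive throughout (SAM, GFF3 and VCF conventions); the package never
converts to half-open coordinates.

Junctions are keyed by (chromosome, strand, intron start, intron end).
Reads are treated as unstranded: strand is inherited from the host gene,
defined as the gene whose span fully contains the intron. When several
genes qualify, the smallest span wins and the ambiguity is logged;
junctions matching no gene keep strand `unknown` and are excluded from
normalization. Duplicate reads are not collapsed, and no minimum overhang
is required on either side of a junction (a mapping-quality floor is
available via `min_mapq`); both are deliberate defaults for simulated,
error-free alignments and are configurable points for real data.

## Normalizing split-read counts

Raw junction counts confound three things: sequencing depth, the gene's
overall expression, and relative splice usage — only the last is the
spliceQTL signal. Normalization therefore proceeds in two steps for
sample $i$ and junction $j$ with host gene $g$:

$$\mathrm{norm}(i,j) = \frac{\,c_{ij} / (L_i/\tilde L)\,}{\max(g_i,\varepsilon)},
\qquad
g_i = \frac{G_{ig}/(L_i/\tilde L)}{\operatorname{median}_k\, G_{kg}/(L_k/\tilde L)}$$

where $c_{ij}$ is the raw split-read count, $L_i$ the sample's total
mapped reads, $\tilde L$ the across-sample median library size, and
$G_{ig}$ the number of reads mapped to gene $g$ in sample $i$.
$\varepsilon = 10^{-8}$ guards genes with no reads. Multiplying one
sample's counts by a constant leaves its normalized values unchanged
(library invariance), and multiplying one gene's reads in one sample by a
constant leaves that gene's normalized junction values unchanged
(gene-wise invariance); both are exact and tested.

A design point worth recording: the gene factor $g_i$ uses *all* reads
mapped to the gene, not just its split reads. If it used split reads
only, the two junction proportions of a three-exon gene would sum to a
(scaled) constant and could never move in the same direction — yet the
phenomenon of interest is precisely both junctions rising while total
expression falls. Correcting for gene-level transcript abundance (all
reads) preserves that degree of freedom while still removing the gene's
expression level from the junction signal.

## Cohort definition and expression preparation

Samples enter the case/control analysis only if they are over 40 years
old (strict), have at least 5 pack-years, are current or ex-smokers, and
carry no other lung disease flag. Among included samples, COPD is
FEV1/FVC < 70 and non-COPD is FEV1/FVC >= 70 (boundary on the non-COPD
side), using pre-bronchodilator values.

Expression is adjusted per feature for age, sex and smoking with a Huber
M-estimator (tuning constant 1.345, iterated to coefficient tolerance
1e-9), and the adjusted value is the residual plus the fitted intercept
so that units and location remain interpretable (e.g. log2 intensity).
A perfect linear fit has no residual scale for the M-estimator, so the
implementation falls back to the least-squares solution in that
degenerate case; adjustment is idempotent to below 1e-8. Smoking is
encoded as a current-smoking indicator; within the included cohort
(never-smokers excluded upstream) this is identical to a current/ex
two-level coding.

Group differences use a two-sided Mann-Whitney U test with average ranks
for ties. When both groups have at most 8 observations the two-sided
p-value comes from exhaustive enumeration of all group assignments of the
observed pooled values — exact even under ties, with
$p = \min(1,\, 2\min(P(U \le u), P(U \ge u)))$ — otherwise from the
normal approximation with tie and continuity corrections. Correlations
with lung function (FEV1 %predicted, FEV1/FVC) are Spearman rank
correlations, overall and per group.

## The QTL engine

For each feature anchor the cis window is $\pm$1 Mb, boundary inclusive.
SNPs with minor allele frequency below 0.05 are removed (strict
inequality, folded at 0.5, computed from mean dosage within each cohort's
samples). The association model per cohort is ordinary least squares

$$y_i = \beta\,d_i + \gamma_1\,\mathrm{age}_i + \gamma_2\,\mathrm{male}_i
 + \gamma_3\,\mathrm{smoker}_i + \epsilon_i$$

with $d_i$ the alternate-allele dosage (0..2), a two-sided t-test on
$\beta$, and pairwise deletion of missing values. Fits with fewer than
(covariates + 3) complete samples or zero dosage variance are flagged
untestable rather than dropped. The *genotype of high expression* is the
alt/alt homozygote when $\beta > 0$ and ref/ref otherwise; flipping the
ref/alt coding flips the genotype string but not $|\beta|$ or the
p-value.

Cohorts are combined by inverse-variance-weighted fixed effects:
$\beta_m = \sum w_c \beta_c / \sum w_c$, $w_c = 1/\mathrm{se}_c^2$,
$\mathrm{se}_m = (\sum w_c)^{-1/2}$, with a Wald p-value; a
DerSimonian-Laird random-effects combination is available behind
`method = "random"`. Fixed effects is the minimal assumption for a
three-cohort design of one tissue and is the default. Multiplicity is
controlled by Bonferroni over all SNP-feature tests in the run (the
family is configurable to per-feature), with Benjamini-Hochberg FDR
emitted alongside so both thresholds are inspectable; significance is
`bonferroni_p < 0.05`. The spliceQTL path is the same engine applied to
the normalized junction matrix. The engine takes its expression matrix
as-is; the caller chooses the transform (the pipeline passes log2
intensities, log2 FPKM, and untransformed normalized junction values).

## LD blocks, proxies and GWAS cross-reference

LD is the squared Pearson correlation of dosages over pairwise-complete
samples (composite LD). This is a deliberate divergence from
haplotype-phase estimators: only dosages exist in this data model, and
panel-based r² values from external LD services are not reproducible from
study genotypes anyway. Significant SNPs ranked by ascending meta p-value
(ties by position) are clustered greedily: the top unassigned SNP seeds a
block, every unassigned SNP with $r^2 > 0.8$ (strict) joins it, and
seedings without members become independent signals; blocks plus
independents always partition the input. Proxy lookup uses $r^2 \ge 0.8$
(the usual proxy-tool convention) within 500 kb. The GWAS cross-reference
reports direct catalog hits and proxy hits per eSNP with trait, study and
r².

## The synthetic cohort generator

The generator is the package's study-conditions definition, not a test
fixture.

**Genotypes.** Dosages are sums of two haplotypes drawn under
Hardy-Weinberg proportions. Within a declared block each haplotype draws
one shared latent uniform; each SNP keeps it with probability
$q = (r^2_{\mathrm{target}})^{1/4}$ or redraws, which makes the pairwise
dosage r² between members equal the requested value (member-member allele
correlation $q^2$; dosage r² $= q^4$). Requested $r^2 = 1$ duplicates
haplotypes exactly.

**Covariates.** Ages, pack-years, spirometry and sex/smoking proportions
are drawn from truncated-normal / log-normal approximations of a typical
surgical COPD case/control cohort (ages centred in the mid-60s,
pack-years median near 40, COPD FEV1/FVC centred near 58, non-COPD near
75). These marginals are configuration, not claims about any real cohort.
COPD membership is by construction (ratio < 70), and GOLD stage derives
from FEV1 %predicted (>= 80: 1, 50-79: 2, 30-49: 3, < 30: 4).

**Abundances.** Each splice variant's abundance is log-linear in dosage,
disease status and covariates with Gaussian log-scale noise (default SD
0.25, a typical biological coefficient of variation); age is centred at
60 so baselines stay interpretable.

**Reads.** The default gene has three exons (300/200/400 bp) separated by
500 and 800 bp introns, with coding `V1` (splices both introns), `V2`
(retains intron 2) and `V3` (retains intron 1); the probe targets the
exon2-exon3 junction and hence detects `V1` and `V3`. Reads are
single-end, error-free, placed uniformly along each variant's transcript,
with per-variant counts Poisson with mean
`abundance * depth_factor * L/1000` (fragment mass proportional to
transcript length, consistent with the FPKM formula, in which per-variant
length then cancels). CIGARs contain only `M` and `N`; reads within
retained introns are contiguous `M`. There is no paired-end structure,
base-quality or error model, or aligner emulation — so passing tests
demonstrate the pipeline's statistical behaviour, not robustness to
alignment artefacts.

**The default flip scenario.** Per alternate-allele dosage the coding
variant changes by +0.35 log-units (baseline 10), the intron-2-retaining
variant by -0.35 (baseline 40) and the intron-1-retaining variant by
-0.05 (baseline 20), with focal-SNP MAF 0.30 and a +0.3 COPD shift on the
coding variant. These magnitudes were chosen to satisfy four analytic
constraints simultaneously, and the package's tests verify each:

* probe-detected abundance ($V_1+V_3$) is monotone *increasing* in dosage
  (30, 33.2, 38.2), so the junction-restricted eQTL is positive at any
  allele frequency — this requires the coding gain to dominate the
  detected sum, hence the weak effect on $V_3$;
* total abundance is monotone *decreasing* (71.75, 63.1, 59.4 including
  the averaged disease factor), strictly through dosage 2 — this requires
  the undetected intron-2-retaining variant to carry a large baseline,
  otherwise the coding variant's growth flattens the total between
  dosages 1 and 2 and the "lowest-total genotype" becomes an exact tie;
* both normalized junction trajectories rise with dosage (each junction
  sum declines more slowly than gene-level abundance);
* the COPD shift makes probe-detected expression higher in disease.

A concordant specification (equal betas on all variants) and an all-null
specification are provided for contrast and calibration runs.

## Numerical and reporting choices

P-values are floored at the smallest positive double so they remain in
(0, 1]. The flip flag compares probe and total effect signs only when
both pass a significance gate (default p < 0.05 each); it is `NA`
otherwise, so sign noise on null effects is never reported as a flip. The
direction report states each junction's effect separately. The
orchestrator derives all stage seeds from one master seed and writes
every artifact as tab-separated text (plus SAM/GFF3/VCF), with a JSON
manifest that contains no timestamps — two runs of one configuration are
byte-identical, which is tested at the file level.

## Problem sizes used by the test suite

The suite exercises: 1,000 random CIGARs against an independent per-base
reference-walk oracle; 2,000 null simulations at n = 300 for type-I
calibration plus 100 replicates at n = 500 for effect recovery; 200
random tied samples against exhaustive Mann-Whitney enumeration; 50
seeds of planted three-block LD recovery at n = 300; 20 seeds of the
flip scenario at n = 500; and 20 full-pipeline global-null runs at the
default study conditions (n = 240, three cohorts). These sizes are the
package's chosen calibration conditions and complete in a few minutes on
one CPU.

## Known limitations

The r² estimator is composite (dosage-based) and will differ from
phased-panel r²; block memberships derived from external reference panels
are therefore not reproducible here. The meta-analysis uses the standard
normal reference for the IVW Wald statistic, which is very mildly
anti-conservative for small per-cohort sizes. The generator's reads are
idealised; junction quantification on real alignments should revisit the
overhang, duplicate and mapping-quality defaults. The exact Mann-Whitney
path enumerates up to `choose(16, 8)` assignments and is intentionally
capped at group sizes of 8.
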