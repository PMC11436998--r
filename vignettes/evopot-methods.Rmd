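---
title: "Methods: population-genetic assessment and translocation planning with evopot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genetic assessment and translocation planning with evopot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and intended use

`evopot` supports conservation-genetic assessment of small, fragmented
populations — the situation typical of amphibians at a range edge —
from two marker classes: genome-wide bi-allelic SNPs (e.g. RAD-seq
panels of thousands of loci scored on tens of individuals) and classical
multi-allelic microsatellite panels (few loci, hundreds of individuals).
Its endpoint is practical: given per-locality diversity, pairwise
differentiation, cluster structure and putatively adaptive variation, it
ranks candidate donor–recipient locality pairs for translocation or
supportive breeding, with an auditable per-rule trace.

The package operates strictly downstream of genotype calling. Read
processing, locus assembly and genotype-quality control are out of
scope; inputs are genotype matrices (VCF, STRUCTURE two-row text, 0/1/2
CSV, or paired-column microsatellite CSV), a locality table with WGS84
coordinates, and a per-locality table of environmental predictors.

## Data model and filters

A `genotype_matrix` stores diploid calls as two integer allele matrices
with a shared missingness mask; SNP alleles are REF/ALT indices (0/1,
enforced bi-allelic), microsatellite alleles are integer fragment sizes
and are never binned. Matrix-level filters follow common RAD-seq
practice and are applied in this order: loci genotyped in fewer than
80% of individuals are dropped, then SNPs with overall minor-allele
frequency below 5% (both thresholds configurable; comparisons are
strict, so a locus exactly at a threshold is kept). An optional
per-individual call-rate filter (default 0.7) mirrors the
microsatellite convention of discarding samples that failed
amplification at more than 30% of loci.

## Diversity statistics

Within each locality and locus, observed heterozygosity $H_O$ is the
fraction of heterozygous genotypes among non-missing calls, and expected
heterozygosity uses Nei's unbiased estimator
$H_E = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)$ with $n$ the
individuals called at the locus. Locality values are means over loci;
loci monomorphic within a locality (but retained by the global filters)
are included in the means by default, since excluding them inflates
diversity in small samples — a flag reverses this. Localities sampled
below a minimum $n$ (defaults: 10 individuals for microsatellites, 4
for SNP panels) are flagged rather than dropped, so the report is
complete but honest about precision.

The multilocus inbreeding coefficient is
$F_{IS} = 1 - \bar H_O / \bar H_E$; its confidence interval is a
percentile bootstrap over loci (default 1000 resamples, $\alpha=0.05$),
and inbreeding is called significant when the interval excludes zero.
Bootstrapping over loci (not individuals) matches the quantity's
interpretation as a genome-wide parameter estimated from exchangeable
loci.

Hardy–Weinberg tests come in two flavours: a $\chi^2$ goodness-of-fit
against expected genotype proportions (df $= G - k$ for $G$ genotype
classes and $k$ alleles), and a Monte-Carlo exact test that permutes
allele copies among individuals within the locality and ranks tables by
their conditional probability given the allele counts — the standard
exact-test ordering, suitable for multi-allelic loci and small samples
where the $\chi^2$ approximation fails. The Monte-Carlo test is
deterministic under its seed.

### Rarefaction

Allelic richness and private-allele counts are standardised to a common
subsample of $g$ *gene copies* via hypergeometric expectations: for a
locus with $N$ sampled copies of which $N_i$ carry allele $i$,

$$A_g = \sum_i \left[1 - \binom{N-N_i}{g} \Big/ \binom{N}{g}\right],$$

and the expected number of private alleles is the presence probability
in the focal locality times the product of absence probabilities in
size-$g$ subsamples of every other locality, summed over alleles and
averaged over loci. $g$ defaults to 2 gene copies — the smallest
informative standardisation, appropriate when the most sparsely sampled
localities hold one or two individuals; analyses wanting "two diploid
individuals" can set $g=4$. Binomial coefficients are evaluated on the
log scale for numerical stability. Localities with fewer than $g$
copies at a locus are flagged and that locus excluded from their mean.

## Differentiation and isolation by distance

$F_{ST}$ uses the Weir & Cockerham (1984) sample-size-corrected
estimator: per locus and allele the among-population ($a$),
among-individual ($b$) and within-individual ($c$) variance components
are computed with the $\bar n$/$n_c$ corrections, and the multilocus
estimate is the ratio of sums $\hat\theta = \sum a / \sum (a+b+c)$ —
the standard choice over a mean of per-locus ratios, which is biased
for loci with small denominators. Small negative estimates are an
estimator property and are preserved in the matrix; the Rousset
transform $\theta/(1-\theta)$ optionally floors them at zero first, and
caps $\theta \ge 1$ at a large sentinel instead of returning infinity.
Pairwise confidence intervals are percentile bootstraps over loci
(default 100 replicates, a common reporting convention).

Isolation by distance is tested by a Mantel correlation between the
linearised $F_{ST}$ matrix and geographic distance (plain Euclidean
distance on decimal degrees by default, matching locality-scale
regional studies; great-circle kilometres available). Significance uses
simultaneous row/column permutations with the $+1$ correction and a
mandatory seed; for seven or fewer localities an exact mode enumerates
all $n!$ permutations. The default 999 permutations balance resolution
(minimum attainable $p = 0.001$) against runtime.

## Clustering

Population structure follows the DAPC recipe: genotypes coded as allele
counts (dosage for SNPs, per-allele counts for microsatellites),
per-locus mean imputation of missing calls, column centring, PCA by
SVD; then k-means over a candidate range of $k$ (default 2–6, a
sensible scan for regional structure) on retained components, scored by
the spherical-variance BIC $n\ln(\mathrm{WSS}_k/n) + k\ln n$ with the
minimum selecting $k$. Discriminant axes and membership probabilities
come from linear discriminant analysis on the retained components
($\le k-1$ axes). The number of components to retain is chosen by the
a-score: observed reassignment rate minus its mean over label-permuted
replicates, maximised over candidate counts — guarding against the
overfitting that retaining too many components causes. Cluster labels
from external sources (e.g. Bayesian admixture programs) can be
supplied directly to the decision framework, which consumes labels, not
the fitting method.

## Genotype–environment association

Predictors are first screened for collinearity by iteratively dropping
the variable with the highest variance-inflation factor until all
VIF < 5. The association engine is redundancy analysis: the centred,
mean-imputed dosage matrix $Y$ is regressed on the standardised
predictor matrix $X$ (locality-level values copied to individuals), and
the fitted values $X(X^\top X)^{-1}X^\top Y$ are decomposed by SVD.
Eigenvalues are $d^2/(n-1)$; locus loadings are the unit right singular
vectors (the scale-free choice — outlier detection standardises per
axis anyway); site scores are reported both as projections of $Y$ onto
the loadings (weighted-average scores) and as the constrained
linear-combination scores; biplot vectors are correlations of each
predictor with the constrained scores. Because locality-level
predictors span at most $K-1$ dimensions after centring, at least
$P+1$ localities are required for $P$ predictors; rank-deficient
designs are refused by name.

Candidate loci are flagged per constrained axis when their loading lies
more than 2.5 standard deviations from the mean loading (the
conventional cut-off), unioned over all constrained axes (configurable;
a locus flagged on several axes counts once), and each candidate is
assigned to the predictor with which its dosage is most strongly
correlated in absolute value.

### Individual adaptive categorisation

Individuals are categorised by refitting the RDA on candidate loci only
under one predictor pair at a time — a climate pair (maximum
temperature of the warmest month + summer precipitation) and a
topographic pair (terrain ruggedness + wetness index). Each
individual's site score is projected onto the unit biplot vector of
each predictor; the predictor with the largest absolute projection
labels the individual when that projection exceeds $t$ standard
deviations of the projections (default $t = 0.5$, deliberately
configurable because published analyses do not standardise this
threshold), otherwise the individual is *intermediate*. Label maps are
explicit: for the climate pair the temperature predictor's sign maps to
warm/cold; for the topographic pair each predictor carries its own
positive-side label (rough for ruggedness, moist for wetness) — these
two are ecological complements, not opposite poles, so they never
conflict in the decision rules. The pairwise refit (rather than a
four-predictor fit restricted to candidates) keeps each categorisation
interpretable as a position along one environmental contrast; both
analyses run independently and report per-locality category
proportions that sum to one.

## Decision framework

The framework turns the analyses into an auditable ranking of ordered
donor–recipient pairs. Hard rules — a failure disqualifies the pair
regardless of anything else: the two localities belong to the same
majority cluster; no adaptive category held by a majority of the donor
is the opposite pole (warm vs cold) of one held by a majority of the
recipient; the donor is not flagged as a suspected introduction (an
introduced population may be viable and valuable in place while still
being a poor gene-flow source). Soft rules — counted but not
disqualifying: donor diversity at least the recipient's (within a
tolerance); donor inbreeding CI not wholly above zero; pairwise
$\theta$ under a bound; connectivity (linearised $F_{ST}$ and distance
both at or below a quantile of all pairs — a deliberate proxy, since
explicit migration-surface estimation is outside the package's scope);
recipient habitat flagged suitable by an external assessment. Every
threshold lives in one `decision_config()` block that the report
echoes. Rules whose inputs are missing return `not_evaluable` and
exclude the pair from "all-pass" status rather than silently passing.

Pairs are ordered by hard passes, then soft passes, then ascending
$\theta$, distance, and ids — a deterministic total order; the report
serialises byte-identically for identical inputs. Localities of
conservation concern are flagged when low diversity (allelic richness
*and* heterozygosity below a quantile of the locality distribution)
coincides with isolation (mean linearised $F_{ST}$ or mean distance
above a quantile); boundary quantiles 0/1 disable the respective
criterion.

## The synthetic-data generator

Because the statistics above are only trustworthy if they recover known
truth, the package ships a generator producing data with the structure
the analyses assume. Neutral SNPs follow the Balding–Nichols island
model: ancestral frequencies uniform on (0.1, 0.9), deme frequencies
Beta-distributed around them with a target $F_{ST}$, genotypes binomial
— Hardy–Weinberg within demes by construction, with a closed-form
differentiation target and no external simulator. Microsatellites use
the Dirichlet analogue with concentration $(1-F)/F$. Adaptive loci are
planted by shifting a locus's per-deme frequency logit by
$\beta \times$ the standardised value of a driving predictor.
Environmental predictors mirror the two predictor pairs used in
practice: a climate pair following a latitudinal gradient and a
topographic pair on an orthogonal longitudinal gradient, each secondary
variable coupled to its primary at 0.25 of the gradient with
locality-level noise (SD 0.5 on the standardised scale) — weak enough
that all four predictors typically survive the VIF screen at small
numbers of localities, as in real regional panels. Missingness is
completely at random (no mechanism being asserted). Everything is
deterministic given one seed, fanned out to stages by a stable hash so
stages are individually reproducible.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: linkage between loci, mutation models,
spatially explicit landscape resistance, non-equilibrium demography
(bottlenecks, admixture), genotyping error, and informative
missingness. Parameter-recovery results on this generator validate the
estimators, not any particular empirical dataset.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: $F_{ST}$ targets of exactly 0
or 1 are refused; localities with zero callable loci yield `NA` with a
flag rather than propagating `NaN`; $F_{IS}$ is undefined (`NA`) where
mean $H_E$ is zero; ties in ranking break by locality id. Hypergeometric
terms use `lchoose`; PCA/RDA rank is truncated at a relative singular
value of $10^{-9}$. Validation suites run at desk scale: oracle
equivalence on matrices up to 5 localities × 5 individuals × 5 loci
against exhaustive enumeration and literal-formula implementations;
parameter recovery on 10 demes × 30 individuals × 2000 SNPs
($F = 0.10$); clustering on 3 demes at $F = 0.15$; GEA calibration and
power on 8 demes × 20 × 2000 with 40 planted loci at $\beta = 2$ —
sizes chosen so the whole suite completes in well under a minute while
leaving Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

Diversity comparisons across marker classes are not attempted: SNP and
microsatellite panels are reported separately, and estimator
differences between them (e.g. ascertainment toward common SNPs) are
left to the analyst. The GEA is a plain RDA: population structure is
not conditioned out, so loci tracking drift that happens to align with
an environmental gradient can be flagged — the per-axis false-flag
rate on simulated data quantifies this. The categorisation threshold
$t$ is a genuine free parameter; results should be reported alongside
it. The connectivity rule is a proxy, not a migration estimate. The
framework encodes guideline-style qualitative reasoning; its
thresholds are defaults to be reviewed per programme, not biological
constants.
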