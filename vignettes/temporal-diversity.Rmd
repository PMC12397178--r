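---
title: "Temporal diversity and differentiation in heterotic-group breeding programs: models and methods"
author: "breedpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal diversity and differentiation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedpop)
```

`breedpop` quantifies how the population structure of a hybrid breeding
program evolves over its registration history: how far the complementary
heterotic pools have drifted apart, how much diversity each pool has lost,
and whether formerly distinct sub-pools have merged into one. This vignette
documents the statistical models, the tunable parameters, the numerical
choices, and what the built-in simulator does and does not emulate.

## Data model and quality control

Genotypes are biallelic SNP dosages (0/1/2 alternate-allele counts, `NA`
missing) of inbred or doubled-haploid (DH) lines. Every statistic in the
package is invariant to allele polarity, so the orientation of the
genotyping array is immaterial.

`qc_filter()` applies its rules in a fixed, documented order:

1. samples with call rate below 90% are removed (checked first, so a sample
   failing several rules is reported for call rate);
2. samples with heterozygosity above 15% are removed — the heterozygosity
   rate is the number of dosage-1 calls over *non-missing* calls, the
   standard denominator;
3. heterozygous calls in DH lines are set to missing (a DH line is fully
   homozygous by construction, so such calls are genotyping errors);
4. markers with call rate below 90% are removed, with call rates computed on
   the retained samples. Computing marker call rates *after* sample removal
   is the common practice and the default; the pre-removal variant is
   available via `samples_first = FALSE` because the order is a genuine
   free choice.

The filter is idempotent. No imputation is performed: all downstream
statistics operate on pairwise-complete data, and `fill_major_allele()`
exists only for consumers that need a complete matrix. Model-based
imputation/phasing is deliberately out of scope.

Eras are non-overlapping ten-year registration intervals
(`assign_eras()`; defaults: pre-1990 = era 0, …, 2020+ = era 4). All
analyses stratify by era × group.

## Differentiation: Weir–Cockerham theta

`wc_fst()` implements the two-population Weir & Cockerham (1984)
variance-component estimator with unequal sample sizes, including the
observed-heterozygosity term \(\bar h\) (inbred collections still carry a
residual fraction of heterozygous calls, and the term costs nothing):

\[
a = \frac{\bar n}{n_c}\Big(s^2 - \frac{1}{\bar n - 1}\big(\bar p(1-\bar p)
    - \tfrac{r-1}{r}s^2 - \tfrac{\bar h}{4}\big)\Big),\qquad
c = \frac{\bar h}{2},
\]
\[
b = \frac{\bar n}{\bar n - 1}\Big(\bar p(1-\bar p) - \tfrac{r-1}{r}s^2
    - \tfrac{2\bar n - 1}{4\bar n}\bar h\Big),\qquad
\theta = \frac{a}{a + b + c},\quad r = 2 .
\]

A marker is *undefined* when either population has fewer than two called
genotypes or when \(a+b+c = 0\) (monomorphic in both pools); undefined
markers are excluded from every summary. Negative per-marker thetas are kept
— clamping would bias the averages.

Two genome-wide values are always reported. The **unweighted mean** of
per-marker θ is the plain "genome-wide average" of the per-marker statistic;
the **ratio of sums** \(\sum a / \sum (a+b+c)\) is the estimator with the
recovery guarantee. The distinction matters: per-marker θ is a ratio of
noisy components, and its mean is biased downward when allele frequencies
are diffuse. Under a Balding–Nichols divergence of F = 0.2 (200 diploids
per pool, 5,000 markers) the ratio of sums recovers ≈ 0.20 while the
unweighted mean sits near 0.15. The package's validation suite therefore
checks parameter recovery on the ratio of sums and reports both everywhere.

`P[θ > 0.75]`, the proportion of highly differentiated markers, uses a
strict inequality.

### Resampling variance protocol

`bootstrap_fst()` mimics a bootstrap: each of 200 replicates (default)
draws 10% of each population at random **with replacement**, recomputes the
per-marker θ on the subsample, and records the unweighted mean over markers
defined in that replicate (markers monomorphic within a subsample drop out
of that replicate, mirroring full-data handling). Resampling is restricted
to inbred lines by default: selection-line cohorts contain many full- and
half-sib families whose resampling would understate dissimilarity. Drawing
within each group is the default; a pooled variant exists
(`per_group = FALSE`), in which a replicate that loses one group entirely
yields an `NA` replicate mean rather than a silent redraw. With
`frac = 1, with_replacement = FALSE` every replicate reproduces the
full-data estimate exactly, which pins down the protocol's correctness.

## Diversity: He and MAF checks

Gene diversity is \(H_e = 2p(1-p)\) (identical for either allele), and the
minor-allele frequency spectrum is summarised by three strict-threshold
fixation indicators: P[MAF < 0.01] (effectively monomorphic),
P[MAF < 0.05] (*extreme-tail* markers, close to fixation or extinction) and
P[MAF > 0.45] (hyper-polymorphic). Heterozygous genotypes contribute one
allele of each type; denominators count defined markers only. No
rarefaction or allelic-richness correction is applied to unequal cell
sizes; cells below `min_n = 5` samples are flagged `low_support` instead.
Whether selection lines enter per-era summaries is exposed through the
`line_type` filter, since both conventions are defensible.

## Hamming distances

`hamming_matrix()` counts genotype mismatches — any dosage difference is
one mismatch, independent of allelic state — normalized by the
pairwise-complete marker count, so values are proportions in [0, 1]
comparable across pairs with different missingness. The allele-level
variant (`|d_i - d_j|/2` per marker) is available via `allele_level = TRUE`.
Within-group era summaries exclude self-pairs; pair order is immaterial.
Distances are computed on inbred lines by default in the pipeline, for the
same family-structure reason as the resampling protocol.

## LD decay

`pairwise_ld()` computes r² as the squared Pearson correlation of dosage
vectors over jointly non-missing samples — the composite, unphased measure.
On near-fully inbred material this coincides with the haplotype-based
measure, which is why no phasing is attempted. Only intrachromosomal pairs
within 1 Mb are considered; pairs with undefined correlation are dropped,
and pairs with r² exactly 0 are dropped by default ("non-null pairwise
correlations"), with `drop_zero = FALSE` available. For n unrelated lines
and unlinked markers the expected r² is ≈ 1/(n−1), the sampling floor to
keep in mind when comparing cells of different size.

Pairs are binned into 5-kb half-open windows up to 1 Mb
(`floor(dist/5000)`; a pair at exactly 1 Mb joins the last bin; empty bins
are retained). `fit_ldd()` then fits the decay curve on the binned means,
weighted by pair counts — fitting at the bin level rather than on millions
of raw pairs matches plotting-level smoothing and keeps the optimisation
small.

The curve is a cubic B-spline (20 basis functions by default, capped at the
number of non-empty bins) with a second-order difference penalty. Shape is
constrained to be **monotone decreasing and convex**: writing
\(\Delta_j = (\beta_{j+1}-\beta_j)/h_j\) for the knot-scaled coefficient
differences (which control the sign of the spline's derivatives), the
constraints are \(\Delta_j \le 0\) and \(\Delta_{j+1} \ge \Delta_j\). The
coefficient vector is reparameterized as
\(\beta = M\,w\) with \(w \ge 0\) (free intercept split into a positive
difference, the last slope as \(-u\), and non-negative second differences),
so the constrained weighted penalized least-squares problem becomes a
non-negative least-squares problem solved exactly by Lawson–Hanson NNLS
(`pracma::lsqnonneg`), plus a 1e-8 ridge for conditioning. The fit
satisfies the constraints *by construction*; the test suite still verifies
first differences ≤ 1e-8 and second differences ≥ −1e-8 on the evaluation
grid for every fit.

The smoothing parameter is chosen by generalized cross-validation of the
*unconstrained* penalized smoother over a fixed grid
\(10^{-4} \ldots 10^{4}\) (17 log-spaced points); the selected λ is then
used in the constrained solve. GCV on the unconstrained smoother is a
documented simplification — the effective degrees of freedom of an
inequality-constrained fit are data-dependent — and behaves well because
the constraints are inactive wherever the data are genuinely decaying.
Degenerate inputs: a constant bin profile is reproduced exactly (within the
ridge, < 1e-6); increasing bin means yield a flat curve (constraints
active); fewer than 5 non-empty bins is an error.

Three scalars summarise a fit: r² at 0, r² at 1 Mb (endpoint evaluations)
and the mean LD, the trapezoid-rule area under the fitted curve on a 1-kb
grid divided by the 1 Mb distance covered. With a 1-kb grid the trapezoid
error is negligible against the spline's own smoothing; by monotonicity,
r²(1 Mb) ≤ mean LD ≤ r²(0).

## Population structure

`pca_eigenstrat()` centres each marker by \(2\hat p\) and scales by
\(\sqrt{2\hat p(1-\hat p)}\) with \(\hat p\) the sample alternate-allele
frequency; markers monomorphic in the analysed subset are skipped, and
missing dosages are mean-filled after standardization (zero), the standard
convention. Coordinates come from a truncated SVD; variance explained is
relative to all axes.

`supervised_admixture()` estimates each line's ancestry vector \(q\) on the
K-simplex given fixed reference allele frequencies, maximizing the binomial
log-likelihood by multiplicative EM updates (non-decreasing likelihood,
stop at gain < 1e-8 or 2,000 iterations; panel frequencies clipped to
[1e-3, 1−1e-3]). It covers the supervised workflow where group reference
frequencies are known; externally estimated Q matrices are read in the
ADMIXTURE `.Q` dialect by `read_qmatrix()` (row sums validated within
1e-3). Unsupervised admixture model fitting is out of scope by design. If
the panels are indistinguishable the likelihood is flat; this is detected
and uniform rows are returned with a warning rather than an arbitrary
corner solution.

`cmap()` is the largest entry of a Q-matrix row (range 1/K … 1); every
line is assigned to its argmax cluster regardless of the value (ties broken
towards the lowest index, with a message), and lines with CMAP strictly
below 0.75 are additionally classified admixed.

`kmeans_bic()` reports \(BIC = n\log(WSS/n) + K\log n\) for k-means on the
leading principal components (best of 10 restarts). This is a *diagnostic*,
not a model selector: on continuous coordinates the optimal k-means WSS
falls roughly like \(K^{-2/d}\), so \(n\log(WSS/n)\) keeps decreasing
faster than the \(K\log n\) penalty grows and an interior minimum at the
true K generally does not exist — pedigree-structured germplasm shows
exactly this. The readable signal is the *elbow*: the drop into the true K
dwarfs all later changes, which is what the test suite asserts.

## The breeding-program simulator

`simulate_program()` is a first-class module, not a fixture: it generates
fully labelled datasets with the statistical structure the analysis
assumes, so that every metric can be validated against a known truth.

What it emulates, and the defaults chosen:

- **Genome** — 10 chromosomes × 200 markers on 100 Mb / 150 cM each,
  marker positions uniform at random (so that distance bins up to 1 Mb are
  populated); crossovers Poisson(1.5) per meiosis, positions uniform on
  the genetic map (Haldane, no interference).
- **Founders** — three ancestral pools (SS, IDT, LAN) of 40 fully
  homozygous lines each, drawn from Balding–Nichols frequencies around an
  ancestral \(p \sim U(0.1, 0.9)\) with drift parameters
  F = 0.20 (SS), 0.25 (IDT), 0.15 (LAN): modest initial divergence, the
  IDT pool narrowest and the LAN pool broadest, matching the historical
  founding-base narrative of these lineages.
- **Breeding** — five eras × 4 cycles, census 150 lines per pool;
  testcross selection by default (truncation on expected hybrid value with
  a fixed opposite-pool tester, dominance 0.5 × |additive effect| at
  heterozygous QTL), 100 QTL with N(0, 1) effects, h² = 0.5, top 20%
  selected — a finite architecture so that fixation at QTL-linked markers
  is observable in the MAF checks. Offspring are DH lines (one doubled
  recombinant gamete of the F1 between two distinct parents);
  `make_dh = FALSE` gives classical random-union-of-gametes diploids for
  Wright–Fisher checks. Note the DH effective size: census N of DH lines
  drifts like a haploid population of size N (variance p(1−p)/N per
  generation).
- **Gene flow and merge** — before era 3, each IDT offspring is replaced
  with probability 0.05 per generation by an IDT × LAN cross derivative
  (and symmetrically); at era 3 the IDT and LAN parent sets merge into a
  single NSS pool of census 300. Under these defaults the program
  reproduces the qualitative trajectory signature: rising SS–NSS θ,
  IDT–LAN θ collapsing to a few percent of its starting value, falling
  NSS He, rising extreme-tail proportions, shrinking within-NSS Hamming
  distances and rising NSS mean LD.
- **Truth records** — ancestry is pedigree-expected (each cross averages
  its parents' fractions), the QTL table is emitted, and identical
  configurations (seed included) give bit-identical outputs.

Subgroup labels deserve a note. Before the merge, lines carry their pool of
origin. After the merge every line's pedigree ancestry converges towards
the pool mean, which is not exactly centred, so a raw
"IDT-majority vs LAN-majority" rule degenerates to a single label. Merged
NSS samples are therefore split along their residual IDT–LAN ancestry
gradient (median split), which is what a K = 3 cluster assignment produces
on a homogenized pool; under homogenization the differentiation between the
two halves tends to zero regardless of where the split falls.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: array ascertainment bias (real SNP panels
over-represent intermediate frequencies), pedigree-structured families of
sister lines within eras, genotyping error and missingness patterns
(simulated data are complete), realistic marker densities (18k-style arrays
are ~10× denser), and the assignment uncertainty of *unsupervised*
clustering. The last point matters for CMAP: supervised admixture against
well-estimated group frequencies over 2,000 markers is extremely confident,
so simulated admixed fractions at K = 2 are near zero in every era, unlike
the large era-0 admixed fractions an unsupervised analysis reports on
weakly structured founders. The CMAP machinery is validated instead by
recovery of known mixture proportions (a 50/50 cross between F = 0.3 panels
is recovered with RMSE < 0.05 over 100 lines).

## Pipeline determinism and validation scale

`run_analysis()` derives every stochastic stage's seed from the master seed
by fixed offsets (resampling: seed + 1000 + era; k-means: seed + 2000), so
toggling one stage never shifts another's draws, and identical
configuration + seed reproduce the written bundle byte for byte (no
timestamps enter the outputs; progress logs go to stderr).

The validation suite runs at deliberately desk-sized scales chosen by the
package: 200 random toy datasets (≤ 20 samples per pool, ≤ 50 markers) for
exact oracle agreement with an independent transcription of the 1984
formulas (|Δ| < 1e-12); Balding–Nichols recovery at F = 0.2 with 200
diploids per pool and 5,000 markers; neutral drift of 100 DH lines over 40
cycles against the Wright–Fisher expectation \(1-(1-1/2N)^t\) within
±0.05; and the full five-era default program (1,950 lines × 2,000 markers,
which simulates in seconds) for the directional trajectory checks over
three seeds.

## Known limitations

- Only the two-population θ is implemented (r > 2 and haplotype-based
  F_ST are out of scope); multi-group comparisons are pairwise.
- The LD module covers intrachromosomal composite r² only — no D′,
  haplotype blocks, or interchromosomal LD.
- The GCV grid for the decay spline is fixed; pathological bin profiles
  could in principle prefer a λ outside it, in which case the fit is merely
  smoother/rougher than optimal, never shape-violating.
- Imputation and phasing are external concerns; heavily missing data
  reduce the defined-marker counts rather than being filled in.
- The simulator's ancestry truth is pedigree-expected, not local: it
  validates admixture *proportions*, not local-ancestry segments.
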