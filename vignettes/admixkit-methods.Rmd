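---
title: "Methods: dissecting admixed genomes with admixkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting admixed genomes with admixkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analytic strategy

Recently admixed genomes are mosaics: each chromosome alternates between
segments inherited from different continental source populations. `admixkit`
works backwards along that history. It first assigns every marker of every
phased haplotype to an ancestral population with a hidden Markov model, then
splits each genome into per-ancestry **virtual genomes** by masking all other
segments to missing. The downstream questions are asked of those virtual
genomes separately: within-continent population structure (a subspace PCA
tolerant of massive missingness), the age of the admixture event (ancestry
block counts under a hybrid-isolation model), and recent positive selection
in the ancestral populations (an ancestry-aware iHS scan). A synthetic-cohort
simulator generates data with known truth for every stage, so each claim the
package makes is testable end to end.

```{r}
library(admixkit)
study <- simulate_substructure_study(n_ind = 200, M = 8000, seed = 1)
pair  <- mask_to_virtual(study$panel, study$track, target = 1)
fit   <- fit_sspca(pair, d = 2)
confusion_fraction(pcs_from_factors(fit)$scores[, 1], study$subpop)
```

# Local ancestry: a haploid Markov-HMM

Each phased haplotype is decoded independently. The hidden state at marker
$m$ is the ancestral population $k \in \{1,\dots,K\}$; over a gap of $d$
Morgans the chain switches with probability $1 - e^{-\tau d}$ and, when it
switches, draws the new state from the individual's ancestry proportion
vector $q$. The switch intensity $\tau$ (generations) defaults to 12 — the
time scale estimated for recent New World admixture — and should be set to
the dating module's estimate when one is available; decoding is insensitive
to factor-of-two errors in $\tau$ because the emission evidence dominates.

Emissions are ancestry-specific allele frequencies. With `markov_order = 0`
markers are conditionally independent; with `markov_order = 1` the emission
at marker $m$ is the frequency of the observed allele *conditional on the
previous observed allele* within ancestry $k$, estimated from two-site
haplotype counts in the reference panel. Order 1 captures the first-order
component of background LD within the ancestral populations — the same idea,
truncated at one marker, that autoregressive ancestry HMMs push to deeper
conditioning. Reference frequencies are clipped to $[0.001, 0.999]$ so a
finite panel can never assign zero likelihood to a path.

Numerics: the forward and backward vectors are rescaled at every marker; the
summed log scaling factors give the exact log-likelihood, which the test
suite checks against exhaustive enumeration of all $K^M$ hidden paths on
small instances (agreement to $10^{-8}$ or better).

Contaminated reference panels (e.g. individuals selected by a 95%
global-ancestry threshold who still carry foreign segments) are handled by
`refine_reference_panel()`: alternately re-estimate frequencies from cells
currently assigned to the claimed ancestry, re-decode the references, and
mask foreign segments, until assignments change at fewer than 0.1% of cells
or 10 iterations.

**What accuracy to expect.** Detection of a foreign segment requires the
accumulated log-likelihood ratio across its markers to overcome the switch
penalty. At the package's default density (20,000 markers over 3435 cM,
about 5.8 markers/cM) and continental differentiation ($F_{ST} = 0.15$),
segments shorter than roughly 5 cM carry too little evidence, which bounds
the per-marker error rate near 7–10% in our simulations. Dense genotyping
arrays carry ~30× more information per centiMorgan, which is why error rates
below 2% are achievable on real continental data but not at desk scale; the
test suite therefore asserts a 12% ceiling at its simulation density rather
than the real-data figure.

# Virtual genomes and ancestry blocks

`mask_to_virtual()` builds the two $N \times M$ per-allele matrices
$G^1, G^2$ (the unordered allele pair per individual and SNP), observed only
where the corresponding haplotype's ancestry call equals the target — and,
when posteriors are available, the call's posterior reaches
`posterior_threshold` (default 0.9; below-threshold cells are missing in
*every* virtual genome, a conservative choice since the paper trail does not
say whether hard or thresholded calls were used).

`extract_blocks()` run-length-encodes each haplotype per chromosome, then
removes blocks with fewer than `min_snps` markers (default 10) — these are
typically artifacts of local-ancestry error — by absorbing their span into
the left flank (the right flank for a leftmost block; equal flanks merge).
The left-flank rule is an arbitrary but deterministic tie-break. A genome
with no ancestry switch has one block per chromosome per haplotype, so a
diploid genome over 22 autosomes has a baseline of 44 blocks.

Individuals with less than 25% target ancestry carry too few informative
segments for substructure analysis; `select_individuals()` excludes them
(inclusive comparison: exactly 25% is retained).

# Subspace PCA on masked matrices

Covariance-based PCA with mean imputation is the wrong tool for virtual
genomes: two individuals with 30% target ancestry share observed genotypes
at under 1% of markers, and the sampling variability of each covariance
entry depends on how much data its pair of individuals shares, biasing the
leading components so that high-missingness individuals become outliers.
`fit_sspca()` instead fits a low-rank factorization **only to observed
entries**: find $A$ ($N \times d$) and $S$ ($M \times d$) minimizing

$$R = \sum_{h=1}^{2} \sum_{(n,m)\ \mathrm{observed}} \left(G^h_{nm} - (A S')_{nm}\right)^2 ,$$

with one score vector per individual shared by both allele matrices. Columns
are standardized to mean 0, variance 1 (sample variance, $n-1$) over their
observed entries, pooling the two exchangeable allele matrices for one set
of column statistics; columns monomorphic in their observed part are dropped
from the fit and reported rather than imputed, keeping $R$ well defined.

Two solvers are provided. The default is alternating least squares: each
half-step solves the per-row normal equations exactly, so $R$ is
non-increasing by construction (the suite asserts the inequality at every
half-step), and the objective value comes free from the least-squares
identity $R = \sum x^2_{\mathrm{obs}} - \sum A \cdot (X S)$. A
gradient-descent solver with learning rate $\lambda$ and halving
backtracking is retained as the closer analogue of the classical update
rules; both converge when the relative decrease of $R$ falls below `tol`
(default $10^{-8}$, `max_iter` 500 — conventional values, chosen rather than
prescribed). $A$ is initialized from standard normal draws under `seed`;
since any invertible $d \times d$ transform of $(A, S)$ leaves $A S'$
unchanged, all tests compare subspaces, not coordinates.

After convergence the factors are canonicalized by a thin SVD of the
rank-$d$ reconstruction: columns of $A$ orthonormal, columns of $S$
orthogonal with norms equal to the singular values, components ordered by
explained reconstruction, each component's largest-magnitude loading
positive. (For an $M \times d$ matrix with $M > d$ it is the *columns* of
$S$ that can be mutually orthogonal; we read the conventional constraint
that way.) On complete data the fitted subspace equals the covariance
eigenspace to principal angles below $10^{-6}$, and the achieved $R$ on
small masked problems matches a general-purpose optimizer run from multiple
starts.

`project_onto_pcs()` regresses any new row's observed entries on the
unit-norm loadings restricted to the observed positions — for a complete row
this reproduces the row's own PC score exactly; rows with fewer than $d$
observed entries are flagged rather than scored.

Separation quality is summarized by the **confusion fraction** $\xi$: the
minimum, over all thresholds and both polarities, of the fraction of
individuals on the wrong side of a single cut on one component (0 = perfect
separation, at most 0.5). `mask_error_sweep()` re-runs the whole
mask→fit→$\xi$ chain after corrupting the true ancestry labels segment-wise
with probability $\varepsilon$, reproducing the robustness analysis design.
Note that segment-level corruption *dilutes* rather than erases the
substructure signal — the retained cells still carry their true origin — so
$\xi(\varepsilon)$ rises appreciably only when the substructure signal is
close to the detection threshold, as it is for real within-continent
differentiation; the sweep harness therefore uses a deliberately marginal
configuration ($F_{ST} = 0.002$, site-independent panels).

# Dating the admixture event

Under hybrid isolation (one founding admixture event $T$ generations ago,
no later gene flow), a haploid genome of genetic length $L$ cM accumulates
$0.01\,TL$ recombination events in expectation, of which a fraction
$2z(1-z)$ join haplotypes of opposite ancestry and become visible switches.
The expected diploid count of ancestry blocks is therefore

$$E[\mathrm{blocks}] = 0.04\,T\,L\,z(1-z) + 2 \times 22 ,$$

44 at $z \in \{0,1\}$, maximal at $z = 1/2$, and increasing in $T$ — the
parabolic family of curves against which observed counts are matched.
`estimate_admixing_time()` fits pooled least squares over an integer grid
(default 5–25 generations; ties resolve to the smaller $T$, and a quadratic
interpolation of the residual profile is reported as a labelled
refinement). Least squares is our choice of loss; the visual
curve-superposition this mirrors does not define one.

Marker density interacts with the short-block filter: at 20,000 markers a
<10-SNP block is ~1.7 cM, removing ~10% of true blocks (each removal merges
two opposite flanks, costing two blocks), which biases $\hat T$ from 12 to
about 10 at default density. At array-like density (tested at 60,000
markers, ~17 markers/cM) the filter removes almost nothing and $\hat T$ is
unchanged within one generation — the regime in which the filter's
robustness claim holds. The dating tests therefore check recovery within
±2 generations at default density and filter-invariance at array density.

# The ancestry-aware selection scan

For a core SNP, EHH at distance $x$ is the probability that two random
haplotypes carrying the same core allele are identical from the core to $x$,
computed as $\sum_g \binom{c_g}{2} / \binom{n}{2}$ over extended-haplotype
classes. Two ancestry-aware modifications restrict the statistic to one
ancestral component of admixed genomes: haplotypes qualify only if their
core SNP derives from the target ancestry, and (mode `"truncate"`) a
haplotype whose ancestry switches away before $x$ is treated as different
from all others beyond its switch point — it becomes a permanent singleton
class. The alternative mode `"exclude400"` drops haplotypes with any switch
within 400 SNPs of the core; on switch-free data the modes coincide exactly.

iHH integrates the EHH curve trapezoidally over physical distance, from the
core outward until EHH falls below `ehh_cutoff` (default 0.05), linearly
interpolated to the crossing; segments spanning gaps larger than 20 kb are
scaled down proportionally (the standard large-gap guard; the distance
measure is our choice — the synthetic map is 1 cM/Mb so genetic and physical
integration coincide). Curves that reach a chromosome end above the cutoff
are edge-flagged and excluded from normalization. The raw score is
$\ln(\mathrm{iHH}_A / \mathrm{iHH}_D)$ for SNPs with derived-allele
frequency in $[0.05, 0.95]$; swapping the allele annotation negates it
exactly. The compiled scan (`ihs_scan()`) is checked SNP-by-SNP against an
independent pure-R implementation (`raw_ihs()`, built on `compute_ehh()` and
`compute_ihh()`).

**Standardization** is two-staged within each chromosome. The location of
the raw score is *odd in the derived allele frequency*: a low-frequency
derived allele is young and rides a long haplotype (negative score), and its
mirror-image SNP gives the positive counterpart — structure that no function
of the *minor* allele frequency can capture, because folding $p$ and $1-p$
together superimposes the two branches. Stage 1 therefore centers each score
at a fitted mid-quartile polynomial in derived frequency (the frequency
dimension the original statistic was standardized on). Stage 2 is the scale
step: quantile regressions of the 25th and 75th percentiles of the centered
scores on MAF, with each score recentered at the fitted mid-quartile and
scaled by the fitted IQR divided by 1.34898, the IQR of the standard
normal — without that constant the scores could not be standard normal. The
basis is linear by default with a quadratic option (`qr_basis`); genome-scale
scans on sparse synthetic maps need the quadratic because the null spread
varies strongly and convexly with frequency (and the cubic centering
polynomial pairs with it). The quantile fits minimize the check loss with a
Nelder-Mead simplex from a least-squares start — a two-to-four-parameter
convex problem — and were verified coefficient-for-coefficient against an
external quantile-regression implementation during development. A fitted IQR
that is non-positive anywhere over the observed MAF range triggers a
frequency-bin fallback with a warning.

Candidate regions are seeded by a 50-kb window around every SNP with
$|\mathrm{iHS}| > 2.5$ (about the top 1% of standardized scores), extended
outward 50 kb at a time while the next window contains at least one such
SNP, and merged when they meet; retained regions need at least 20 scored
SNPs of which at least 10% are above threshold, ranked by maximum
$|\mathrm{iHS}|$. Calls use $|\mathrm{iHS}|$ only, so they are invariant to
score sign and coordinate translation.

Overlap between SNP sets from two scans is assessed against the expectation
$n_A n_B / M$ with a hypergeometric upper tail and, optionally, a
circular-shift permutation that rotates one set's genome-order indicator —
preserving the local clustering of hits that the hypergeometric null
ignores. The two nulls can differ by orders of magnitude on clustered hits;
both are reported with method labels, and neither is claimed to reproduce
any particular published p-value, whose null was not specified.

# The synthetic-cohort generator

The generator provides exactly the statistical structure the analyses
assume, with ground truth:

* **Differentiated sources.** Per-population allele frequencies follow the
  Balding-Nichols model, $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ around an
  ancestral frequency $p \sim U(0.05, 0.95)$ (array-like common variants),
  clipped to $[0.01, 0.99]$; $\mathrm{Var}(f) = F\,p(1-p)$.
* **Haplotype-copying LD.** A fraction `founder_frac` (default 0.25) of each
  source panel is drawn site-independently; the rest copy a random founder,
  switching template between markers with probability
  $1 - e^{-\rho\,d_{cM}}$ (`ld_rho`, default 0.2/cM). This yields
  identity-by-descent sharing that decays over a ~5 cM scale and, within an
  allele class at a locus, on the order of ten distinct haplotype lineages —
  the per-locus haplotype diversity regime of dense array data — while
  leaving classical allelic $r^2$ modest, as appropriate for
  site-independent founders. These defaults were fixed by requiring the
  neutral raw-iHS null to be smooth and approximately Gaussian within
  frequency strata, the regime the normalization assumes and which real
  array data exhibit; smaller founder pools produce a lumpy, discretized
  null, and much faster switching collapses EHH within one marker spacing.
* **Hybrid-isolation admixture.** Per haplotype, switch points are a Poisson
  process at rate $T$ per Morgan; each segment's ancestry is drawn afresh
  from the individual's proportion vector, so an ancestry *change* occurs at
  a fraction $2z(1-z)$ of points and the diploid expectation
  $0.04\,T\,L\,z(1-z) + 44$ is matched exactly (verified over a $(T, z)$
  grid). Alleles within a segment are copied from a single random source
  haplotype (segment-coherent). This is stationary redrawing, not pedigree
  simulation: it matches the expectation formula exactly at $O(\text{switches})$
  cost. `simulate_ancestry_tracks()` exposes the cheap track-only path for
  block-count studies.
* **Sweeps.** `inject_sweep()` copies one founder haplotype's interval
  (`founder_span_cm` around the core, derived allele forced at the core)
  into a `carrier_freq` fraction of haplotypes, each truncated per side at
  an exponential distance (floored at 0.1 cM so every carrier carries the
  core) — a founder-copy construction, not a forward simulation, sufficient
  to create the long-haplotype signal iHS detects.
* **Mask corruption.** `corrupt_ancestry_labels()` flips each maximal
  constant-ancestry segment independently with probability $\varepsilon$
  (uniform relabeling for $K > 2$), emulating segment-level local-ancestry
  error.
* **Genome.** 22 autosomes with human-like relative genetic lengths scaled
  to 3435 cM total; markers placed uniformly at 1 cM/Mb.

The default scales — 20,000 markers, 200 source haplotypes, 400 admixed
individuals at $z = 0.5$, $T = 12$ — are the package's standing study
conditions; tests that need many replicates state smaller sizes explicitly.

**What the simulator does not emulate**, and hence what green tests do *not*
establish about real cohorts: coalescent allele ages (derived alleles here
have no age-frequency relationship beyond class size), recombination
hotspots and variable marker spacing, array ascertainment beyond the
frequency window, genotype and phasing error, trio structure, and continuous
gene flow (the dating model is exact only under hybrid isolation; under
ongoing flow the estimate reads as a gene-flow-weighted average time).

# Numerical and design notes

* Coordinates: VCF 1-based; BED 0-based half-open; blocks span first to last
  member marker (no midpoint extension), so per-haplotype BED records cover
  every marker exactly once but leave unobserved gaps between blocks open.
* The ALS normal equations use an analytic solve for $d \le 2$ and a ridge
  fallback ($10^{-8}$-scaled) only on numerically singular rows.
* `standardize_ihs()` pools chromosomes with fewer than 200 usable scores
  into one normalization group, with a warning.
* All writers emit a provenance comment (package version and seed), never a
  timestamp, so identical configuration and seed give byte-identical
  artifacts; `run_pipeline()` checks this by manifest MD5s.
* The pipeline derives fixed per-stage seeds from the global seed, so stages
  can be re-run in isolation.

# Known limitations

* The neutral standardized-iHS null at desk scale retains slightly more tail
  mass than a standard normal (about 1.5–2% of scores beyond 2.5 versus
  1.24% for exact normality; KS distance ≈ 0.008): per-chromosome quantile
  fits on ~700 scores jitter the scale, and the copying-model null is mildly
  leptokurtic. Dense real-data scans fit per-chromosome quantiles on tens of
  thousands of scores and do not see the first effect.
* Local-ancestry error at 20,000-marker density is bounded by missed short
  segments (~7–10%), not by the decoder; see above.
* The order-1 emission is a one-marker truncation of full haplotype-aware
  decoding; it is declared as an approximation, not claimed equivalent to
  deeper autoregressive models.
* Dating assumes hybrid isolation and error-free block counts; decoded (as
  opposed to true) tracks at sparse density inflate short-block artifacts
  and bias $\hat T$ downward even after filtering.
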