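# admixkit

Tools for dissecting recently admixed genomes, for population geneticists
working with phased genotype panels from cohorts such as Latin American
mestizo populations. An admixed genome is a mosaic of chromosomal segments
inherited from different continental source populations; `admixkit` infers
that mosaic and then interrogates each ancestral component separately:

1. **Local ancestry** — a haploid hidden Markov model along each phased
   haplotype: states are ancestral populations, transitions occur at rate
   `tau` per Morgan with the new state drawn from the individual's ancestry
   proportions, and emissions are ancestry-specific allele frequencies,
   optionally conditioned on the previous allele (`markov_order = 1`) to
   capture background LD. Includes iterative refinement of contaminated
   reference panels and global ancestry by averaging local posteriors.
2. **Virtual genomes** — each genome is split into per-ancestry components
   by masking all other segments to missing (`mask_to_virtual()`), giving
   the two per-allele matrices `G1`, `G2` used downstream.
3. **Subspace PCA** — within-continent structure from masked matrices by
   low-rank factorization fitted *only to observed entries*: find `A`
   (N×d scores) and `S` (M×d loadings) minimizing
   `R = Σ_h Σ_obs (G^h − A Sᵀ)²`, via alternating least squares (monotone in
   `R`) or gradient descent. Unlike mean-imputed covariance PCA, the fit is
   insensitive to per-individual missingness, which varies enormously across
   virtual genomes. Group separation is scored by the confusion fraction ξ
   (misclassification at the best single threshold on one component).
4. **Admixture dating** — under hybrid isolation, the expected diploid count
   of ancestry blocks is `0.04·T·L·z(1−z) + 2×22` for admixing time `T`
   (generations), genome length `L` (cM), and ancestry proportion `z`;
   `estimate_admixing_time()` fits observed per-individual block counts to
   these curves by pooled least squares.
5. **Selection scan** — an ancestry-aware iHS: EHH computed on haplotypes
   whose core SNP derives from one ancestry, truncating a haplotype at its
   ancestry switch point; iHH by trapezoidal integration to the 0.05 EHH
   cutoff; `raw iHS = ln(iHH_ancestral/iHH_derived)`; standardization by
   MAF-dependent quantile-regression IQR (scaled by 1.34898) after centering
   on derived frequency; candidate regions by 50-kb seed/extend/merge with
   ≥20 SNPs and ≥10% above |iHS| = 2.5; overlap enrichment between scans by
   hypergeometric or circular-shift permutation nulls.
6. **Simulator** — Balding–Nichols differentiated sources, haplotype-copying
   LD, Poisson hybrid-isolation admixture with ground-truth tracks,
   founder-copy sweeps, and segment-level mask corruption, so every stage is
   testable against known truth.

## Worked example

Simulate 100 admixed diploid genomes whose "European-like" half derives from
one of two subtly differentiated subpopulations, mask to that ancestry, and
recover the substructure and the admixing time:

```r
library(admixkit)
study <- simulate_substructure_study(n_ind = 100, M = 6000,
                                     n_source_hap = 120, seed = 7)
pair <- mask_to_virtual(study$panel, study$track, target = 1)
pair
#> masked_pair: ancestry anc1 , 100 individuals x 6000 markers
#>   observed fraction per individual: median 0.50 (range 0.44-0.57)

fit <- fit_sspca(pair, d = 2, seed = 7)
fit
#> sspca fit: d = 2 , solver = als
#>   reconstruction error R = 530857.2 after 286 iterations
#>   singular values: 134.3, 84.52
#>   dropped 401 monomorphic-in-observed column(s)

confusion_fraction(pcs_from_factors(fit)$scores[, 1], study$subpop)
#> confusion fraction xi = 0.0000 (threshold -0.7222, 'A' below)

blocks <- extract_blocks(study$track, study$markers, min_snps = 1)
estimate_admixing_time(
  data.frame(z = study$z[, 1], count = blocks$diploid_counts))
#> admixture dating from 100 diploid block counts
#>   T_hat = 11 generations (grid 5 - 25 )
#>   quadratic interpolation: 11.15 generations
```

Half the genome of every individual is masked, yet PC1 of the subspace PCA
separates the two source subpopulations perfectly (ξ = 0). The dating
estimate sits one generation below the simulated truth (T = 12) because at
6,000 markers a few percent of ancestry switches fall between the same
marker pair and merge; see the methods vignette
(`vignettes/admixkit-methods.Rmd`) for the density analysis and for the
short-block filter's behaviour.

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "admixkit", package = "admixkit")`, with
subcommands `run`, `simulate`, `infer-ancestry`, `mask`, `blocks`,
`date-admixture`, `sspca`, `ihs-scan`, `regions`, `overlap` and
`expected-blocks`; `run_pipeline()` executes the whole chain with one seed
and writes a checksummed manifest.

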