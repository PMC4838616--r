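---
title: "napusdiv: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{napusdiv: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`napusdiv` implements the population-genomic analysis chain used for sparse,
high-missingness SNP panels from reduced-representation sequencing of
*Brassica napus*-like allotetraploids (two subgenomes, A01–A10 and C01–C09;
strongly selfing accessions; median per-SNP call rates near 25%). The chain
runs from a raw multi-sample VCF to: a filtered genotype matrix,
probabilistic PCA, Hudson F~ST~, projected folded site-frequency spectra
with π and Tajima's *D*, minor-allele sharing partitions, gene-set
permutation tests, inversion-signature region scans, and neighbor-joining
phylogenies. A synthetic-data generator reproduces the statistical structure
these methods assume, so every stage is testable offline.

# The filter cascade

Stages run in a pinned order: (1) removal of indels, multiallelic sites and
sites fixed for the alternate allele among called samples; (2) masking of
genotypes with depth `DP < 4` (a call at exactly 4x is kept — the rule is
strict "less than"); (3) recoding of heterozygotes with strong allelic
imbalance to the majority-read homozygote; (4) masking of genotypes whose
per-sample locus mismatch count exceeds 3 (exactly 3 is kept); (5) dropping
SNPs called in fewer than 30 samples (exactly 30 is kept); (6) dropping
samples with more than 80% missingness.

Two points were genuinely open and are parameterized rather than asserted:

* **"Strong allelic imbalance"** has no canonical definition in this
  pipeline family; we use minor-read fraction < 0.2
  (`het_imbalance_threshold`), a common reduced-representation heuristic.
  A heterozygote whose AD field is absent cannot be assessed and is set
  missing.
* **Stage order.** Depth masking and het recoding read disjoint FORMAT
  fields (DP vs AD) and each only rewrites the genotype, so those two
  stages commute exactly; the order that *does* matter is fixed-alternate
  removal before het recoding (a site can become all-alternate only after
  recoding; the pinned order keeps it) and site call-rate filtering before
  sample call-rate filtering. Both orderings are regression-tested.

Outlier samples whose PCA position contradicts their recorded label are
*flagged* (`flag_discordant_samples()`), never auto-removed: in practice
that removal decision rests on passport review, which is human judgment.

# Probabilistic PCA

Dosages {0, 1, 2} are column-centered on observed means and left unscaled
(standard genotype PCA coding). Missing entries are latent: each EM cycle
imputes them with the current low-rank reconstruction and then performs the
complete-data EM update of the loading matrix and isotropic noise variance
— the same algorithm as `pcaMethods::ppca`, the standard choice for
genotype matrices of this kind. On
complete data this is exact EM and the final SVD step makes the result
identical to classical PCA; with missing data the tracked objective is the
observed-data reconstruction error, which decreases monotonically and is
the convergence criterion (`tol` on its relative change, default 1e-6).
The likelihood itself is monotone in the exact-EM (complete-data) regime;
with missing data the imputation scheme is the standard approximation, so
the test suite asserts monotone reconstruction error there instead.

Defaults: `q = 10` components (enough to exhaust genuine structure in
panels with a handful of subpopulations),
seeded random loading initialization (fixed default seed, so results are
reproducible), sign convention flipping each loading vector so its
largest-magnitude entry is positive. Cluster support assigns samples to
nearest group centroids in PC1–PC2; groups under 3 samples are flagged
low-confidence.

One caveat established while validating: when two groups are *equally*
differentiated from the rest, the top two eigenvalues are degenerate and
"PC1" is only defined up to rotation; score correlations across fits are
then meaningless. Validation worlds therefore use asymmetric
differentiation, which is also what real panels show.

# Hudson F~ST~ with inbreeding

Per SNP, with sample frequencies $p_1, p_2$ on $n_1, n_2$ chromosomes:

$$N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
\qquad D = p_1(1-p_2) + p_2(1-p_1)$$

and the genome-wide estimate is $\sum N / \sum D$ (ratio of averages;
negative per-SNP values are retained so the ratio stays unbiased). SNP sets
are ascertained per subpopulation — "ascertained in X" means both alleles
present among X's called genotypes — and every pair is estimated twice,
once per ascertainment side.

Selfing makes the two alleles within an individual correlated, so $n$
chromosomes carry less information than $n$ independent draws. The
correction deflates each subpopulation's chromosome count to
$n/(1+\hat F)$ with $\hat F = 1 - \sum H_{obs} / \sum H_{exp}$ (ratio of
sums over SNPs — a mean of per-SNP ratios diverges at near-fixed sites),
clipped to [0, 1]. With this deflation the numerator's sampling-variance
correction is exactly unbiased under inbreeding (the algebra telescopes:
$E[\hat p(1-\hat p)]\,(1+F)/(n-1-F) = p(1-p)(1+F)/n$). The flag
`inbreeding_adjust` keeps uncorrected Hudson available.

# Folded SFS, π and Tajima's D

Each SNP's allele count $j$ among $m_{obs}$ called chromosomes is projected
to $m = 100$ chromosomes by the hypergeometric mass
$P(k) = \binom{j}{k}\binom{m_{obs}-j}{m-k}/\binom{m_{obs}}{m}$, folded so
$k$ and $m-k$ share a class ($k = m/2$ counted once). SNPs with
$m_{obs} < m$ cannot be downsampled and are excluded (counted and
reported). Fractional expected masses are used directly — deterministic
and lower-variance than multinomial resampling. Projected-monomorphic mass
($k = 0$) is reported separately and never enters the segregating mass.

Per-site diversity at minor count $k$ is $2k(m-k)/(m(m-1))$; summing over
the SFS gives the total pairwise mismatch, and π divides by the effective
length $L$. The length is defined as
$L = (\text{projected SNP count}) / (\text{SNP density})$ with density =
SNPs per covered bp computed before projection exclusions, per subgenome.
(Multiplying the SNP count by a per-bp density would *shrink* L below the
SNP count, which is dimensionally incoherent; dividing count by density is
the only form in which π = Π/L holds, and it is the one implemented.)

Tajima's *D* uses the classical constants at $n = m = 100$; the pairwise
estimator is computed through the fold-invariant $k(m-k)$ form. Note the
well-known finite-sample property that E[*D*] under neutrality is slightly
negative (≈ −0.09 at $n = 100$; the numerator is mean-zero but correlates
with the estimated standard deviation in the denominator) — the
calibration test accounts for the Monte-Carlo error of its own mean rather
than pretending E[*D*] = 0 exactly.

# Allele sharing

The minor allele is defined on the three major subpopulations pooled
(WE + WA + SP; the small winter-America group is excluded throughout);
pooled-frequency ties at exactly 0.5 go to the alternate allele (arbitrary
but fixed). Presence means ≥ 1 copy among a subpopulation's called
genotypes (a heterozygote counts one copy). Seven-cell Venn partitions are
computed per subgenome, and size-matched downsampling (default 100
replicates) re-draws each oversized subpopulation without replacement,
recomputing the minor-allele definition per replicate.

# Gene-set permutation test

Each focal gene is represented by exactly `r = 40` SNPs: all SNPs inside
the gene, then nearest flanking SNPs ordered by distance to the gene
boundary, equidistant left/right candidates breaking leftward (the tie and
alternation rules are otherwise arbitrary; these are fixed and
documented). The null draws SNP sets matched to the observed composition
per subgenome × genic/intergenic stratum, without replacement within a
draw. The p-value is the raw count of null statistics at least as extreme
as the observed mean divided by the iteration count — no add-one
correction; p = 0 is
reported with a "< 1/iterations" annotation. The iteration count is a
required argument (1,000–10,000 is typical; resolution is 1/iterations);
the test direction is likewise required rather than defaulted, because
"elevated Fst" and "altered Π" call for different sidedness.

# Region scanning and inversion banding

Outlier SNPs exceed the genome-wide mean + 3 SD of the per-SNP statistic
(F~ST~ or Π); flagged SNPs within 1 Mb merge into regions, and regions
with < 10 flagged SNPs are dropped. Within a candidate region, PPCA
restricted to the region's SNPs is clustered on PC1 by 1-D k-means at
k = 2 and 3 with deterministic range-spread initial centers (quantile
seeding fails when band occupancies are unbalanced). A k qualifies when
mean silhouette ≥ 0.5 *and* every adjacent cluster pair is separated by a
gap larger than 0.5× their average within-cluster spread; three-band
requires k = 3 with the middle cluster's mean between the outer means.
These thresholds turn a judgment that is usually made visually into a
reproducible rule, and
all are exposed as arguments. Band occupancies are reported per
subpopulation label over all samples jointly.

# Neighbor joining

Distances weight genotypes 0 / 0.5 / 1 (dosage over 2) and average the
absolute weight difference over loci called in both samples
(pairwise deletion). Because missing loci differ per pair, sparse pairs
are unstable; pairs sharing fewer than `min_shared = 50` loci are
undefined and block tree building with an explicit message. NJ follows
Saitou–Nei with ties broken on the smallest index pair and negative branch
lengths clamped to zero with the deficit moved to the sibling (totals
preserved). Midpoint rooting places the root halfway along the longest
leaf-to-leaf path, rooting at a node when the midpoint lands exactly on
one. Bootstrap (default 1,000 replicates) resamples loci with replacement,
and supports are the percentage of replicate trees containing each
original-tree bipartition; bipartition keys are normalized to the side not
containing the lexicographically smallest sample id so they are stable
across trees. Replicates producing an undefined pair are redrawn (counted,
capped at 10× the replicate number).

# The synthetic-data generator

`sim_config()` defaults state the world the package targets: 347 WE +
212 WA + 185 SP + 38 WAm samples; 30,881 SNPs split 38.8%/61.2% between
subgenomes over ~315 Mb + ~527 Mb (≈ 1 SNP / 27.5 kb); per-subpopulation
Balding–Nichols F of 0.18/0.18/0.28/0.20 (pairwise F~ST~ between two
groups ≈ the mean of their F values — the joint three-population matrix is
matched only marginally, a documented limitation); F~IS~ = 0.9 (strongly
selfing accessions); per-SNP call rates Beta-distributed with mean 0.35
and concentration 1.5 (right-skewed, median below the mean as in real SBG
panels) scaled by a log-normal per-sample factor; read depth negative
binomial with mean 8 and size 2, which puts ~35% of genotypes under the 4×
threshold; and one inversion on C02 at frequency 0.5 in spring and 0.02 in
the winter groups. Missingness is coupled to depth in the emitted VCFs:
called genotypes carry DP ≥ 4, uncalled ones DP < 4.

Inversions are modeled as two fixed haplotype allele vectors differing at
each SNP with probability 0.8 (sharp PC1 banding, as observed in real
regions) plus 1% per-copy noise; carriers of one copy are heterozygous at
differing sites. The generator produces no linkage disequilibrium outside
inversion regions, no coalescent ancestry, and no base-quality error
model — so a green test establishes that the statistics recover the
*stated* allele-frequency/missingness/inversion structure, not that they
are robust to LD or alignment artifacts.

`emit_raw_vcf()` can plant, at exact configurable counts, every violation
class the filter cascade removes (indels, triallelic sites, fixed-alt
sites, low-depth genotypes, imbalanced heterozygotes, high-mismatch
genotypes), returning the truth bookkeeping that the tests assert against.

# Numerical choices and degenerate inputs

* Hypergeometric masses via `dhyper`; per-SNP masses sum to 1 within
  1e-12, and identity projection (`m_obs = m`) is exact.
* Monomorphic tracks flag no outliers (SD = 0); tracks shorter than 100
  defined values are an error, not a silent pass.
* A SNP uncalled in every pooled subpopulation has no minor allele and is
  excluded from sharing partitions.
* `p = 0` permutation outcomes, non-converged PPCA fits, and excluded
  projection SNPs are all *reported states*, never exceptions.
* All randomness is seed-controlled; identical seeds give byte-identical
  outputs (simulation, downsampling, permutation, bootstrap).

# Known limitations

* The inbreeding deflation is one standard operationalization of
  "F~ST~ under inbreeding"; the original description is by citation only.
* Ascertainment ("polymorphic in X") conditions on the *sample*, which at
  small sample sizes slightly biases recovered F~ST~ downward relative to
  the generating value; the dual-ascertainment design exposes exactly this
  sensitivity.
* The weighted p-distance is equivalent up to a constant factor to
  alternatives that normalize per-locus weights differently; the constant
  does not affect NJ topology.
* Region banding assumes bands are separable on PC1 alone; inversions at
  very low frequency (no homozygous carriers sampled) produce two-band or
  "none" diagnoses by construction.
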