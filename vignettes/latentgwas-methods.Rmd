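---
title: "Methods: GWAS on learned imaging phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GWAS on learned imaging phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`latentgwas` implements a desk-scale imaging-genetics workflow: learn
low-dimensional phenotypes from 3D brain volumes with a multi-task
conditional variational autoencoder (VAE), reduce them to principal
components, run a covariate-adjusted GWAS on the component scores, and
carry the hits through phenome-wide scans, voxel-wise maps, polygenic-score
comparison, and LD-score regression.  Every input the pipeline needs can be
simulated from a seed, because the cohorts this class of analysis was
developed on (biobank MRI + genotypes) are access-restricted.  This
vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

## The feature model

Each volume $x$ (standardised intensities on a fixed template grid) is
encoded into a latent Gaussian $q(z \mid x) = \mathcal N(\mu(x),
\operatorname{diag} e^{\lambda(x)})$.  Training minimises

$$\lambda_\text{recon}\,\mathrm{MSE}(x, \hat x)
 + \lambda_\text{kld}\,\mathrm{KL}\!\left(q(z \mid x)\,\|\,\mathcal N(0, I)\right)
 + \lambda_\text{pred}\,\mathrm{MSE}(y, \hat y),$$

with weights $1$, $10^{-4}$, $10^{-2}$ — the published configuration of the
multi-task objective.  The decoder and the prediction head receive the
sampled latent (reparameterisation trick) concatenated with standardised
age and sex, so the latent code need not carry covariate information; the
auxiliary target $y$ is a continuous dementia-severity score, pushing the
representation toward neurodegeneration-relevant structure.  Inference-time
encoding returns the latent mean.

Architecture is a deliberate desk-scale choice: a fixed $2\times$
average-pooling stem followed by dense encoder/decoder layers (mirrored
shapes) and a 2-layer head, trained with Adam (step size $2 \cdot 10^{-3}$)
and manual analytic gradients (verified against finite differences in the
test suite).  Reference analyses of this kind use deep 3D convolutional
encoders at $96^3$ resolution, 500 epochs, and latent width 128; defaults
here are $32^3$ volumes, latent 16, 30 epochs, batch 64, sized so a full
training run takes seconds on one CPU while preserving the objective,
the conditioning mechanism, and the multi-task structure.  The
reconstruction error is measured on the pooled grid the dense layers see.

Three numerical conventions matter.  The KL term is summed over latent
dimensions and averaged over the batch; the reconstruction error is a per
voxel mean; log-variances are clamped to $[-8, 8]$ with the clamp masked
out of the gradient.  Because Adam normalises per-parameter step sizes, the
small prediction weight $10^{-2}$ does not starve the head of training —
the bottleneck for prediction quality is the latent code, not the head.

**Conditioning as deconfounding.**  With age fed to the decoder, the model
can explain age-driven intensity without spending latent capacity on it.
This is an *asymptotic* property: early in training the conditioned model
(which optimises faster) transiently shows a *higher* latent–age
correlation than its unconditioned twin, and the expected ordering emerges
only once reconstruction has converged past the covariate-dominant variance
mode — at these problem sizes, around 40–60 epochs.  The conditioning
comparison in the tests therefore trains for 60 epochs (still seconds per
fit) and asserts direction only, over a majority of 5 seeds.

The alternative feature path, `slice_average_encode()`, averages a 2D
feature function over axial slices.  No pretrained image-network weights
ship with the package; a seeded random projection is the default feature
function, and any user-supplied 2D encoder can be plugged in.

## PCA traits

`fit_pca()` centres the latent features but does not rescale them:
explained-variance ratios then refer to the features' native variances,
which is what statements like "the first 10 PCs explain most of the
variance" quantify.  Whether the reference analyses standardised features
before PCA is not documented; centring-only is the choice least likely to
inflate low-variance dimensions.  Before association testing, component
scores are standardised to unit variance (`pca_traits()`), so per-allele
effects are in trait-SD units.  Default `k = 10` components per model.

## Synthetic data as study conditions

`simulate_genotypes()` draws diploid dosages by thresholding two
independent latent Gaussian haplotypes per LD block at the
allele-frequency quantile.  Within a block the latent correlation is
AR(1) (`block_corr^|i-j|`), giving r² that decays with distance; blocks
are independent, span under 250 kb, and are laid out in contiguous chunks
over chromosomes 1–22 with ≥1 Mb gaps.  Two independent haplotypes give
Hardy–Weinberg genotype frequencies by construction; missingness is
applied uniformly at random.  This is a copula model, not a coalescent:
it produces tunable LD and exact HWE but no allele-frequency spectrum,
recombination hotspots, or imputation-quality structure.

`simulate_cohort()` renders ellipsoidal ROIs at fixed template positions
(the shared label map plays the role of template registration, drawn with
a 1.45 parcel margin so genetically enlarged structures stay inside their
parcel).  Planted effects act additively on ROI radius (voxel units per
allele) or mean intensity; age and sex shift all ROI intensities —
emulating global, atrophy-like covariate structure; Gaussian noise enters
at the ROI level and the voxel level.  The dementia score is
$0.8 \times$ (ventricle radius) $+\ \mathcal N(0, 0.3^2)$ — continuous
rather than an ordinal clinical rating, so the prediction head's loss can
be a plain squared error.  Default cohort conditions: ages uniform on
45–80, balanced sex, three batches, top-10 genotype PCs as
population-structure covariates, $32^3$ voxel volumes with 6 ROIs.

`simulate_sumstats()` draws per-variant z-score pairs from the bivariate
normal whose moments are exactly the LD-score-regression expectations
($E[\chi^2_j] = 1 + N h^2 \ell_j / M$;
$E[z_{1j} z_{2j}] = \sqrt{N_1 N_2}\, r_g \sqrt{h^2_1 h^2_2}\, \ell_j / M$),
which makes it the natural oracle for the LDSC estimators: passing
recovery tests shows the estimators are correct under their own model, not
that real polygenic architectures satisfy it.

What passing tests on these simulations does **not** show: robustness to
MRI artefacts (bias fields, motion), non-linear registration error,
realistic LD structure, ascertainment, or case–control phenotype
imbalance.

## GWAS

QC applies, in order: MAF ≥ 0.1 %, missingness ≤ 10 % (samples first, then
variants), Hardy–Weinberg p ≥ 0.001, and windowed greedy LD pruning at
r² = 0.8 — the published filter set.  Pruning keeps the earlier-position
variant of an offending pair (deterministic) in a 500 kb window; only the
r² threshold is published, the window and tie rule are package choices.

The association scan is covariate-adjusted least squares: traits and
mean-imputed dosages are residualised against the covariate design
(intercept, age, sex, batch dummies, genotype PCs), and the per-variant
slope, SE, and t follow from the Frisch–Waugh identity, exactly equal to
the full multiple regression.  This replaces the linear mixed model used
at biobank scale: the mixed model's variance components mainly absorb
relatedness and population structure, and at desk scale the genotype-PC
adjustment controls the same confounding axis while remaining exactly
testable against a per-variant `lm()` oracle.  A variant with zero dosage
variance is reported with beta 0, p 1, and a flag rather than an error.

Clumping is greedy and distance-based: ascending by p, each index
(p ≤ 10⁻⁹) claims all unclaimed variants with p ≤ 5·10⁻⁸ within ±250 kb
on its chromosome; ties break by position.  The published analysis names
the 250 kb window and the two thresholds but not the secondary behaviour
of its clumping tool, so distance-only greedy is implemented as
documented.  Cross-trait aggregation takes the per-variant minimum p with
its originating trait tag; locus tables from two models are matched
greedily by nearest index within 250 kb.  Replication requires the
discovery index to reach p < 0.05 in the held-out split with a concordant
beta sign (the replication criterion is not published; nominal + sign
concordance is the package's choice).  Coordinates are 1-based and
windows inclusive throughout.

## Interpretation

`phewas_scan()` dispatches on declared phenotype type — continuous
phenotypes are rank inverse-normal transformed (Blom offset) and fit by
least squares, binary ones by logistic regression, always adjusting for
age and sex — a two-type reduction of the full decision tree that
phenome-scan tools apply.  One-class binary phenotypes are flagged
untestable.  The Bonferroni threshold is always computed as
$\alpha / (\text{traits} \times \text{phenotypes})$; a published threshold
of ≈6.5·10⁻⁷ for 20 × 7,744 tests does not equal 0.05/154,880 ≈ 3.2·10⁻⁷,
so the computed value is used rather than the printed one.

`voxel_spm()` computes per-voxel Pearson correlation with a per-sample
variable, converts it to $t = r\sqrt{(n-2)/(1-r^2)}$, and thresholds at
the two-sided t quantile Bonferroni-corrected over in-mask voxels — the
stated correction for the voxel maps.  Per-ROI summaries are the fraction
of significant voxels (`roi_fraction()`), and a variance-weighted per-voxel
R² ratio, $\sum_v r_v^2 \sigma_v^2 / \sum_v \sigma_v^2$
(`roi_variance_explained()`); the aggregation formula behind published
per-ROI variance-explained figures is not stated, and variance weighting
was chosen because it is invariant to adding constant voxels and reduces
to ordinary R² when all voxels respond identically.

## Polygenic scores

PGS construction is clumping + thresholding: for each candidate p
threshold the summary statistics are clumped (index = member = candidate
threshold), index-variant betas become weights, and the threshold with the
best held-out-fold R² wins.  Continuous-shrinkage methods need an external
LD reference panel and a Gibbs sampler, out of scope here; C+T is the
standard transparent baseline.  Scoring matches effect alleles, flips
dosage (2 − d) when the coding is reversed, skips irreconcilable variants
with a count, and warns on strand-ambiguous pairs.

`multi_pgs_eval()` fits base and extended linear models on a random 60 %
split and compares out-of-sample R² on the remaining 40 % — the published
evaluation design.  The permutation test mirrors the published scheme:
each of 1,000 permutations reassigns, per test sample with a fair coin,
one model's prediction to each of two hybrid vectors and records the
hybrid ΔR²; the p-value is two-sided with add-one correction,
$(1 + \#\{|\Delta_\text{perm}| \ge |\Delta_\text{obs}|\})/(1 + B)$.
Sidedness is not published; two-sided is the conservative choice.

## LD-score regression

`ld_scores()` computes $\ell_j = \sum_k \tilde r^2_{jk}$ over neighbours
within 1 Mb, self-term included, with the small-sample adjustment
$\tilde r^2 = r^2 - (1 - r^2)/(n - 2)$.  `ldsc_h2()` regresses χ² on ℓ
with a free intercept; the slope times $M/N$ is $h^2$.  Weights are
updated once from a first pass ($1/\ell$, then
$1/(\ell\,(1 + N h^2_0 \ell / M)^2)$) — a simplified two-step version of
the reference weighting schedule, validated by parameter recovery rather
than by matching another implementation.  Standard errors come from a
20-block contiguous jackknife.  `ldsc_rg()` regresses $z_1 z_2$ on ℓ,
scales the slope to a genetic covariance, and divides by the geometric
mean of the two heritabilities; the jackknife recomputes the full ratio
per deleted block.  Reported $r_g$ is clipped to $[-1.25, 1.25]$ with the
raw value retained; non-positive heritability estimates flag $r_g$
undefined.  The intercept of the χ² regression is a noisy quantity at
desk-scale M — its standard error is of order 1 — so intercept checks are
coverage statements, not point comparisons.

`shared_regions()` implements the z-product screen: candidates need focal
p < 10⁻⁴ and |z-product| > 15 against both partner traits, with the
product's sign matching the sign of the genetic correlation where one is
supplied (applied to the second partner by default, as in the analysis
this mirrors, which constrained the diffusion-MRI pair).  The p-value
condition binds the focal trait; which trait it constrained is not
published.  Candidates group greedily around the variant with the largest
|z-product with partner b| — "central" is not defined in the source
analysis, so the strongest-product rule is used — absorbing candidates
within ±250 kb.

## Pipeline, seeding, and problem sizes

`run_pipeline()` chains simulate → features → gwas → interpret → pgs →
gencorr, writes every artifact (dosage TSV + sidecar, NIfTI volumes,
summary-statistic TSVs, locus/PGS/LDSC tables) under one directory, and
returns an MD5 manifest; identical configuration and seed reproduce
identical hashes.  One global seed fans out to per-stage child seeds
through a deterministic hash (`child_seed()`), so any stage can be re-run
alone with the same randomness.  Structured per-stage logging records the
parameters actually used.

The demo configuration — 500 samples, 2,000 variants in 25-variant LD
blocks, $32^3$ volumes with 6 ROIs, 10 PCs — was sized so the full
pipeline, including VAE training, completes in about a minute on one CPU;
the recovery analyses in the test suite use up to 2,000 samples and 50
seeded replicates.  These sizes are the package's study conditions, chosen
once; the acceptance checks run under them.

## Known limitations

- The genotype model has no recombination map, allele-frequency spectrum,
  or imputation; LD is exchangeable-block AR(1).
- The dense VAE sees pooled volumes; it cannot learn fine spatial texture
  a convolutional encoder would, and the dementia head's R² is
  correspondingly modest.
- The LDSC weighting schedule is simplified; intercepts are wide at small
  M, and estimates are validated by recovery, not by concordance with the
  reference implementation.
- PheWAS reduces phenotype typing to continuous/binary; ordinal and
  date/compound types are out of scope.
- The linear scan does not model relatedness; cryptic family structure
  would inflate test statistics, as for any non-mixed-model GWAS.
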