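---
title: "Population structure inference from sparse pseudo-haploid SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure inference from sparse pseudo-haploid SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopop)
```

## The problem

Reduced-representation sequencing (SLAF-seq, RAD-seq) and low-coverage
shotgun data often leave too few reads per site for reliable diploid
genotype calls. A standard remedy, borrowed from the ancient-DNA
literature, is the *pseudo-haploid* call: at every covered site one
sequencing read (one allele) is sampled at random, so each individual
carries a single 0/1 call per SNP and a large fraction of calls is
missing. This changes the statistics of everything downstream: there is
no heterozygosity, allele sharing between two samples of the same
individual is no longer trivially 1, and naive covariance matrices are
built from very different subsets of SNPs per pair of individuals.

`haplopop` implements a coherent analysis chain for such data —
relatedness screening, PCA, F_ST, f-statistics — together with a
generative simulator that produces datasets with known truth, so every
estimator in the package can be validated by parameter recovery rather
than by eyeball.

## The synthetic-data generator

The generator is ordinary forward simulation under the Balding–Nichols
model:

1. Ancestral allele frequencies $p_j \sim \mathrm{Uniform}(l, h)$
   (defaults $l = 0.05$, $h = 0.95$, avoiding rare-variant boundary
   effects that reduced-representation panels rarely retain).
2. Population frequencies
   $p_{kj} \sim \mathrm{Beta}\!\big(p_j \tfrac{1-F_k}{F_k},\,
   (1-p_j)\tfrac{1-F_k}{F_k}\big)$, so
   $\mathrm{E}[p_{kj}] = p_j$ and
   $\mathrm{Var}[p_{kj}] = p_j (1-p_j) F_k$. $F_k = 0$ copies the
   ancestral frequencies exactly. Balding–Nichols was chosen because its
   $F$ parameter maps directly onto the Weir–Cockerham $\theta$ the
   package estimates, giving closed-form targets for recovery tests.
3. Diploid dosages $g_{ij} \sim \mathrm{Binomial}(2, q_{ij})$ with
   $q_{ij} = \sum_k a_{ik} p_{kj}$ for an ancestry-proportion matrix
   $a$ (identity by default: each individual is pure for its
   population).
4. Pseudo-haploid calls: homozygotes map deterministically, each
   heterozygote contributes one allele by a fair coin.
5. Missingness: each call is independently dropped with a
   per-individual rate (missing completely at random). The default rate
   of 0.4 sits in the middle of what per-individual SNP coverage looks
   like in sparse reduced-representation panels, where individual call
   counts commonly span a few percent to two-thirds missing. MCAR is a
   deliberate simplification: the package's filters act only on marginal
   missing fractions, so informative missingness (e.g. coverage
   correlated with library quality) would affect power but not
   correctness of the filters.

Two kinds of known contaminants can be planted. *Duplicate pairs*
re-draw the pseudo-haploid calls from the same underlying diploid
genotype, emulating two independently built libraries of one individual.
*Migrants* are individuals simulated from one population's frequencies
but labelled with another population's capture label, emulating
long-distance dispersers genotyped at the capture site; they are pure
individuals of their source by default (an admixed ancestry row can be
supplied instead). Everything the generator knows — true population per
individual, duplicate pairs, the frequency tables — is returned as
ground truth for tests.

The default six-population configuration uses
$F = (0.10, 0.06, 0.03, 0.025, 0.025, 0.08)$ and sample sizes
$(8, 7, 26, 25, 22, 26)$. Under Balding–Nichols, the expected pairwise
$\theta$ between populations $k$ and $l$ is approximately
$(F_k + F_l)/2$, so these values span pairwise differentiation of
roughly 0.03–0.09 — the "low but nonzero" regime typical of
high-gene-flow aquatic species, where two sites are distinct but single
individuals can plausibly be misassigned. What the generator does *not*
emulate: linkage disequilibrium within blocks (SNPs are independent
given the frequencies), restriction-site dropout, base-calling error,
and reference bias. Passing tests therefore demonstrate correctness of
the estimators under the model's assumptions, not robustness to these
real-data artifacts.

## Pairwise mismatch rates and duplicate screening

For two individuals the PMR is the fraction of jointly observed SNPs at
which their pseudo-haploid calls differ. Under Hardy–Weinberg
proportions at frequency $p$, two *unrelated* individuals mismatch with
probability $2p(1-p)$, while two pseudo-haploid draws from the *same*
diploid individual mismatch only when the individual is heterozygous and
the two coins disagree: $2p(1-p) \cdot \tfrac12$. The duplicate-to-
unrelated PMR ratio is therefore $\tfrac12$ site by site, and more
generally a pair with coefficient of relationship $r$ is expected at
$(1 - r/2)$ times the unrelated baseline. `detect_duplicates()` flags
pairs below `factor` times the median within-group PMR; the default
`factor = 0.6` sits midway between the duplicate expectation (0.5) and
unrelated pairs (1.0), and the default `min_overlap = 500` jointly
observed SNPs keeps the binomial noise on a flagged pair's PMR below
about 0.02 at typical mismatch levels. Neither threshold is taken from
any external convention; both are exposed.

Flagged pairs are merged into connected components and the member with
the highest call count is kept per component — components rather than
pairs, because duplicate relations are transitive in the presence of
triplicates. Ties are broken lexicographically so the result is
deterministic. The screen intentionally stops at flagging: a pair at
half-median PMR may be a re-sequenced sample, identical twins, or a
labelling mistake, and genotype data of this kind cannot distinguish
those causes.

## PCA with missing data

The genotype matrix is centred per SNP by the mean over non-missing
calls. The similarity between individuals $i$ and $k$ is the mean
product of centred values over the SNPs observed in *both* — a
pairwise-complete covariance. Missing cells are never imputed, and
because each cell averages over a different SNP set the matrix can be
slightly indefinite; negative eigenvalues are reported as-is and
excluded from the variance-explained denominator rather than clipped.
Cells with fewer than `min_pairs` (default 100) complete pairs are
flagged but kept.

Principal components are the eigenvectors of this matrix, in descending
eigenvalue order, with each component's sign fixed so that its
largest-magnitude loading is positive. Coordinates are raw eigenvector
entries by default; scaling by the square root of the eigenvalue is
available as an option, since conventions differ and with two-group
structure the choice only rescales axes. With zero missingness the whole
construction reduces exactly to standard PCA of the centred matrix (the
test suite checks eigenvalues against a singular-value decomposition).

`subset_pca()` eigendecomposes a row/column submatrix of the
*previously computed* similarity matrix. This is not equivalent to
recomputing from the subset's genotypes (re-centring changes the per-SNP
means); the submatrix route is the default because it keeps coordinates
of retained individuals comparable across nested analyses, and the
recompute route is available by rebuilding the matrix from a subset
dataset.

## Weir–Cockerham F_ST for haploid calls

Each pseudo-haploid call is one sampled allele, so the package uses the
haploid analysis-of-variance form of the Weir–Cockerham estimator. Per
locus, with group call counts $n_i$, sample frequencies $p_i$,
$N = \sum n_i$, $r$ groups with data and
$\bar p = \sum n_i p_i / N$:

$$\mathrm{MSP} = \frac{\sum_i n_i (p_i - \bar p)^2}{r - 1}, \quad
  \mathrm{MSG} = \frac{\sum_i n_i p_i (1 - p_i)}{\sum_i (n_i - 1)}, \quad
  n_c = \frac{N - \sum_i n_i^2 / N}{r - 1},$$

with locus numerator $A = \mathrm{MSP} - \mathrm{MSG}$ and denominator
$B = \mathrm{MSP} + (n_c - 1)\,\mathrm{MSG}$, and
$\hat\theta = \sum_\ell A_\ell / \sum_\ell B_\ell$ — the ratio of
averages, which is the standard stabilisation against rare SNPs (an
average of per-locus ratios would be dominated by loci with tiny $B$).
A diploid path is deliberately absent: pseudo-haploid calls carry no
heterozygosity, and fabricating one would bias the estimator. Loci enter
when at least two groups have calls, the pooled frequency is
polymorphic, and the within-group degrees of freedom
$\sum (n_i - 1)$ are positive. On Balding–Nichols simulations this
estimator recovers the simulated $F$ within Monte-Carlo error at
$F \in \{0, 0.05, 0.1\}$ (see the test suite).

Significance uses a label permutation test: group labels are reassigned
uniformly at random (a permutation, preserving group sizes — not a
bootstrap) across the pool of individuals, the identical statistic is
recomputed, and the empirical p-value is
$(\#\{\hat\theta_{perm} \ge \hat\theta_{obs}\} + 1)/(n_{perm} + 1)$.
Ties count as exceedances and the p-value can never be exactly zero;
with 2,500 permutations its floor is $1/2501 = 4.00\times10^{-4}$. For
pairwise rows the pool defaults to *all* listed groups (labels shuffle
across the whole study, so a pair's null distribution reflects
study-wide label exchangeability); restricting the pool to the two
groups involved is available via `perm_scope = "pair"`. Permutations
under which the statistic is undefined (e.g. a permuted group ends up
with no calls at any polymorphic locus) are redrawn and counted in a
log field — discarding them silently would bias the p-value
denominator.

## f3 / f4 statistics and the block jackknife

Group allele frequencies are pooled over all haploid calls; a group
contributes wherever it has at least one call, with no minimum-call
threshold, so even single-individual outlier groups can be compared
(at the price of noisy frequencies, which the jackknife error
absorbs). Then

$$f_3(t; a, b) = \overline{(p_t - p_a)(p_t - p_b)}, \qquad
  f_4(a, b; c, d) = \overline{(p_a - p_b)(p_c - p_d)}$$

averaged over SNPs where all involved groups have data. No
finite-sample bias correction is applied to f3: the usual correction
subtracts a heterozygosity-based term that is undefined for
pseudo-haploid calls. The raw f3 is therefore biased upward by an
additive sampling-noise term; this cancels when f3 values sharing the
same target are *compared* (the shared-drift ranking use case), but
absolute f3 values should not be compared across datasets with
different sample sizes. f4 is unaffected because the two frequency
differences involve disjoint groups. Per-SNP products are averaged
without a denominator normalisation — these are f-statistics, not
D-statistics.

Standard errors come from a delete-one-block jackknife over contiguous
genomic blocks, which is robust to linkage between nearby SNPs. Blocks
are built greedily per chromosome with a half-open span
`[start, start + block_bp)` (default 3,000,000 bp, restarting at every
chromosome); a SNP at `start + block_bp` opens a new block, so no block
ever spans more than `block_bp` bases. Because blocks carry unequal SNP
counts, the weighted (Busing-style) jackknife is used with SNP-count
weights $m_j$: with $g$ blocks, total weight $n$, $h_j = n/m_j$ and
leave-one-out estimates $\theta_{-j}$,

$$\theta_J = g\hat\theta - \sum_j (1 - m_j/n)\,\theta_{-j}, \qquad
  \widehat{\mathrm{Var}} = \frac1g \sum_j
  \frac{(h_j\hat\theta - (h_j - 1)\theta_{-j} - \theta_J)^2}{h_j - 1},$$

which reduces exactly to the classical
$\tfrac{g-1}{g}\sum (\theta_{-j} - \bar\theta_{-\cdot})^2$ when all
weights are equal. Z-scores are estimate over standard error; fewer
than two usable blocks leaves the error undefined and the row flagged.
Enumeration helpers cover all triplets (each target with every
unordered pair) and all canonical quartets ($a<b$, $c<d$,
$(a,b)<(c,d)$; three per 4-subset — every other ordering follows from
the sign symmetries, which the tests verify).

## Filters

Two SNP filters mirror common PLINK-style practice: a frequency filter
(drop SNPs missing in more than `max_missing` of individuals or with
pooled minor-allele frequency below `maf_min`; defaults 0.5 and 0.01)
and a count filter for the PCA/f-statistics stage (missingness
threshold 0.6 and minimum minor-allele count 3, i.e. removing SNPs with
two or fewer minor alleles, whose centred values are dominated by a
couple of calls). Individuals with more than 70% missing data are
removed after SNP filtering. Minor alleles are defined per SNP from the
pooled non-missing calls of the currently retained individuals, and
missing fractions use the current (post-upstream-filter) denominators,
so the stages compose sequentially; all filters are idempotent and all
thresholds are arguments.

## The pipeline

`run_pipeline()` chains the stages in the order a practitioner would:
simulate or read → frequency filter → PMR screen and dedupe →
count/individual filter → PCA → F_ST with permutations → block
partition and f-statistics → migrant detection → report. All
randomness flows from one root seed through named per-stage substreams
(each stage's seed is a deterministic hash of the root seed and the
stage name), so an identical configuration reproduces identical output
files and any single stage can be rerun in isolation with its own
stream.

Migrant candidates are individuals whose nearest group centroid —
group medians over the first six PCs by default, leave-self-out so a
candidate cannot drag its own centroid — disagrees with their capture
label. Medians rather than means keep centroids robust to the outliers
being sought; six components are enough to separate the six-group
default design while staying clear of noise axes. Each candidate is
then confirmed with $f_4(\mathrm{pool}, X;\, P, Q)$, where $X$ is the
candidate alone, $P$ its capture group (without it), $Q$ the inferred
source and the pool merges all remaining groups: a significantly
positive value ($Z > 2$ by default) means $X$ shares drift with $Q$
rather than with its capture group. With fewer than three groups no
third-party pool exists and the candidate is reported unconfirmed.

## Validation problem sizes

The test suite validates at sizes chosen to make Monte-Carlo bands
tight while keeping the suite quick: parameter recovery uses 20 seeds
of 2×50 individuals × 5,000 SNPs per $F$ value; permutation
calibration 200 replicates at 199 permutations; f4 null calibration 20
five-population star phylogenies of 5,000 SNPs; and the end-to-end
replica 10 seeds of a six-population design (sizes 8, 7, 26, 25, 22,
26; four duplicate pairs; nine planted migrants; 50,000 SNPs at 40%
missingness), which recovers all planted duplicates and at least seven
of nine migrants in at least 80% of seeds.

## Known limitations

- The generator's independence assumptions (no LD, MCAR missingness)
  are simplifications; block-jackknife errors are validated against
  their own model, not against LD-structured data.
- f3 values are uncorrected for sampling noise in the target group
  (see above) and are comparable only within a dataset.
- The PMR screen detects near-identical pairs; it is not a general
  kinship estimator and will not reliably separate e.g. half from full
  siblings.
- Pairwise-complete similarity matrices can be indefinite; coordinates
  on components with near-zero or negative eigenvalues are not
  interpretable and variance-explained fractions refer to the positive
  spectrum only.
- The permutation test assumes exchangeability of individuals across
  the pooled groups under the null; strong within-group family
  structure would violate this.
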