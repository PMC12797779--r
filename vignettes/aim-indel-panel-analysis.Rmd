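---
title: "Methods: forensic and population-genetic analysis of AIM-InDel panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forensic and population-genetic analysis of AIM-InDel panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popkit)
```

`popkit` characterises panels of biallelic ancestry-informative
insertion/deletion markers (AIM-InDels). This vignette is the package's
account of the statistical methods: the models and their assumptions, the
conventions adopted where several are defensible, the tunable parameters
and their defaults, what the synthetic data generator does and does not
emulate, and the numerical choices that matter in edge cases.

## Data model

All analyses start from a `genotype_table`: unphased diploid genotypes at
biallelic loci, stored as insertion-allele dosages in {0, 1, 2, `NA`}.
Because the markers are biallelic and phase is never observed on a
capillary-electrophoresis platform, the dosage is a lossless encoding of
the unordered genotype. The insertion allele is coded 1 and the deletion
allele 0 throughout, matching the usual recoding of 1000-Genomes ped
extracts for InDel panels. Population labels are deliberately *not* part
of the ped dialect: they are joined from two side tables (sample →
population, population → superpopulation), which is how 1000G panel files
are distributed. Half-missing ped genotypes are treated as fully missing;
every consuming module then defines its own convention (frequency
estimation drops them from *n*; the SVM imputes training means; kinship
simulation never produces them).

## Forensic parameters

With insertion frequency $p$, $q = 1-p$, observed heterozygosity $h$ and
$H = 1-h$:

* $He = \frac{2n}{2n-1}\,(1 - p^2 - q^2)$ — Nei's unbiased small-sample
  gene diversity. The correction factor is the convention of the standard
  forensic summary tools; the uncorrected diversity is recoverable as
  $He\,(2n-1)/2n$.
* $PIC = 1 - p^2 - q^2 - 2p^2q^2$ (Botstein), which is bounded above by
  the uncorrected gene diversity — a property the test suite checks.
* $MP = \sum_g \hat f_g^2$ over **observed** genotype frequencies, not
  Hardy–Weinberg expectations. Observed-frequency match probability is the
  forensic convention and keeps $PD = 1 - MP$ exactly complementary.
* $PE = h^2(1 - 2hH^2)$, the trio (both-parents-tested) exclusion formula
  driven by observed heterozygosity. Other PE variants exist (duo,
  identity); the trio form is what forensic panel reports quote, so it is
  the default and the only one exposed.

Panel-level values are $CPD = 1 - \prod_i (1 - PD_i)$ and likewise $CPE$,
computed as `-expm1(sum(log1p(-x)))`. For 56 strong loci
$\prod (1-PD_i)$ underflows toward $10^{-20}$; log-space accumulation
keeps the result exact and makes `CPD` print as 1 only when it genuinely
rounds there at double precision.

## Hardy–Weinberg and linkage screening

The HWE test is the exact conditional test: given allele counts, the
heterozygote count $h$ follows the Levene distribution
$P(h) \propto 2^h / (n_{II}!\,h!\,n_{DD}!)$, and the two-sided p-value
sums all admissible configurations with probability not exceeding the
observed one (with a $1+10^{-12}$ relative tolerance so exact ties are
included rather than lost to floating-point noise). A mid-p variant is
available but off by default. The implementation is validated against a
full enumeration oracle for all $n \le 10$ and calibrated on simulated
null panels: the test is super-uniform, so its rejection rate at
$\alpha = 0.05$ must stay at or below nominal.

The LD screen is a permutation test on dosages: the statistic is
$n \cdot r^2$ (composite-LD style), the null is generated by re-pairing
individuals, and $p = (1 + \#\{S_{perm} \ge S_{obs}\})/(1 + n_{perm})$
with default $n_{perm} = 9{,}999$ (a seed is mandatory — there is no
hidden global-RNG dependence). For $n \le 7$ all $n!$ pairings can be
enumerated exactly. A haplotype-EM test would add nothing here: the panel
design assumes unlinked markers, the screen only has to confirm
independence, and dosage correlation is the quantity the downstream
product-LR actually relies on. Loci with zero dosage variance yield
$p = 1$ with a warning rather than an error, so monomorphic cells do not
abort a screen.

Both screens report Bonferroni thresholds computed from the number of
tests actually performed. For 56 loci this is $0.05/56 = 0.00089$. For
pairwise LD over 56 loci the natural count is $\binom{56}{2} = 1540$ per
population; published panel reports sometimes quote other denominators
(e.g. 1595), which cannot be reconstructed from a locus count alone — the
package therefore always derives the threshold from the realised test
count and prints that count alongside.

## Kinship likelihood ratios

A pairwise relationship is the IBD triple $(k_0, k_1, k_2)$. The joint
probability of an ordered genotype pair is

$$P(g_1, g_2) = k_0 P(g_1)P(g_2) + k_1 P(g_1)\,T(g_2 \mid g_1) +
  k_2 P(g_1)[g_1 = g_2],$$

with Hardy–Weinberg genotype probabilities and the one-shared-allele
kernel $T$ (a random allele of individual 1 is copied; the other allele is
a fresh population draw). The per-locus likelihood ratio against
unrelatedness has the closed form
$k_0 + k_1 T(g_2|g_1)/P(g_2) + k_2[g_1=g_2]/P(g_2)$, and the panel LR is
the product over loci — justified exactly by the HWE and no-LD screening
above — accumulated as $\log_{10}$ sums. Mutation, silent alleles and
genotyping error are not modelled; for a simulation study of a screened
panel these are the standard defaults. Monomorphic loci carry $LR = 1$
and are skipped with a warning.

Simulation draws, per pair and locus, an IBD state from
$(k_0, k_1, k_2)$ and then alleles accordingly. `threshold_accuracy`
reports the proportion of simulated related pairs with $LR \ge t$: this
is a *sensitivity*, not a two-class accuracy. The distinction matters —
at stringent thresholds like $10^4$ the proportion drops below 50%, which
no two-class accuracy over balanced related/unrelated samples could do,
since unrelated pairs essentially never reach such LRs. The pipeline
therefore reports unrelated-pair exceedance rates (false-positive rates)
alongside. Properties enforced by the tests: $E[LR] = 1$ under
unrelatedness for any numerator model; the combined $\log_{10}LR$ equals
the sum of independently recomputed per-locus terms; full-sibling
sensitivity dominates half-sibling sensitivity at every threshold.

## Differentiation and informativeness

Pairwise $F_{ST}$ defaults to the two-population Nei $G_{ST}$: per-locus
$H_S$ (mean within-population diversity) and $H_T$ (diversity of the
unweighted mean frequency), combined as a ratio of sums across loci and
clamped at zero. A Weir–Cockerham $\theta$ (sample-size weighted, with
HWE-expected heterozygosity, ratio-of-sums) is available via
`method = "wc"`. The two estimate different functionals: under a
Balding–Nichols model where each population diverges from a common
ancestor at parameter $F$, the $G_{ST}$ variant converges to roughly
$F/(2-F)$ (about $F/2$ for small $F$) because the two-population total
diversity only sees half the variance that drove each population from the
ancestor, whereas $\theta$ estimates $F$ itself. This mapping was
calibrated empirically during development (at $F = 0.05$: $G_{ST}$ ≈
0.026, $\theta$ ≈ 0.050 over 200 replicates of $L = 500$, $n = 200$), and
the parameter-recovery tests use $\theta$ for that reason. Nei's
$D_A = \frac{1}{L}\sum_l (1 - \sum_j \sqrt{x_{lj} y_{lj}})$ is computed
over both alleles of each locus.

Rosenberg's informativeness for assignment is computed per locus as

$$I_n = \sum_j \Big[ -\bar p_j \ln \bar p_j +
  \frac{1}{K}\sum_{i=1}^K p_{ij}\ln p_{ij} \Big], \qquad 0\ln 0 \equiv 0,$$

with unweighted group means, in nats ($PSD = I_n/\ln 2$). Cumulative
informativeness is the sum over loci (additive for unlinked markers). For
the continental summaries the default grouping is one-vs-rest at $K = 2$
— the focal superpopulation against the pooled remainder — because that
is the operational question ("can this panel pull East Asians out of
everyone else?"); a named-pair mode covers the pairwise-continent
comparison, and a joint $K$-group mode exists for completeness.
Group-level frequencies are unweighted means of member populations, so a
large cohort cannot dominate its continent.

## Ordination, trees, clustering

PCA is a centred (optionally standardised) SVD; per-variable cos² is the
squared correlation between variable and component scores
(correlation-circle semantics, summing to 1 across components in the
standardised full-rank case), and contributions are normalised squared
loadings. Zero-variance variables are dropped with a warning under
standardisation. MDS is classical Torgerson scaling via double-centering;
non-positive eigenvalues are truncated with a warning when fewer than the
requested components remain. Neighbor-joining uses the Saitou–Nei
Q-criterion (via `ape::nj`); negative branch lengths — a known NJ
artefact on noisy, non-additive matrices — are clamped to zero with the
excess moved to the sibling edge, preserving leaf-to-leaf path lengths on
either side. Heatmap orderings use average-linkage clustering on
Euclidean row/column distances; other linkages and correlation distances
are defensible for display purposes, and no claim is made that this
ordering is uniquely correct — it is deterministic, which is what the
pipeline needs.

## Ancestry SVM and the label-noise protocol

Classification targets the five continental superpopulations, the level
at which AIM panels are actually informative, with per-locus dosages as
features. The split is 80/20 stratified by class with a fixed seed;
missing dosages are imputed with training-set means only (the test
verifies no leakage). Hyperparameters $(C, \gamma)$ of the RBF SVM are
searched over log-uniform ranges $C \in [10^{-2}, 10^3]$,
$\gamma \in [10^{-4}, 10]$ with a randomised search scored by stratified
4-fold cross-validated weighted F1, 40 evaluations by default, refit on
the full training set. A randomised search was chosen over a
model-based (Bayesian) optimiser deliberately: the search space is
2-dimensional and smooth, at this budget the two find equivalent optima,
and the randomised form is exactly reproducible from one integer seed
with no additional machinery.

The noise protocol selects $\lceil fN \rceil$ training labels uniformly
and permutes them among themselves — "shuffling", which preserves the
class multiset. Because a shuffled label can land back on its own class,
the realised fraction of changed labels is below nominal — in expectation
$f\,(1 - \sum_i c_i^2)$ for class proportions $c_i$ — and it is logged
for every repetition rather than assumed. Nominal fractions default to
{0.01, 0.1, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8} (normal:noisy ratios 99:1 down
to 2:8) with 10 repetitions; evaluation sets are never touched by noise.
A replace-with-random-class mechanism is available behind a flag.

## Synthetic data: what it does and does not emulate

The generator is a hierarchical Balding–Nichols model: ancestral
insertion frequencies uniform on a MAF range (default 0.2–0.5, reflected
to either allele), superpopulation frequencies
$\mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ around the ancestor
at $F_{between} = 0.15$, sub-populations around their superpopulation at
$F_{within} = 0.02$, and target groups nested in one superpopulation at
$F = 0.01$ — chosen to mirror a continental reference plus a regional
study cohort whose F_ST to its nearest reference population is of order
0.01. Genotypes are binomial HWE draws; loci are independent. The
`paper_like` preset uses 26 sub-populations in the 7/5/5/5/4 continental
layout plus three target groups sized 18/14/10 at 20 individuals per
reference population (~560 samples), which keeps the full pipeline and
test suite fast; sizes scale linearly via `n_per_pop` for 1000G-scale
runs.

Panel loci are not raw draws: batches of loci are passed through the AIM
selection filter (global MAF ≥ 0.1; maximum frequency difference > 0.5
among the three major continental analogues; > 0.2 for any pair involving
the remaining two groups) until 56 survive. The filter's third rule is
applied as "pairs involving the remaining continental groups", the only
reading of the screening criteria that is well defined for five groups.
This selection step matters: it reproduces the ascertainment bias that
makes real AIM panels much more differentiated than random markers, which
is why the synthetic panel supports near-perfect continental
classification, cumulative one-vs-rest $I_n$ above 3 for the major
clusters, and sibling-LR sensitivities in the high-90s/low-30s range at
LR ≥ 1 / LR ≥ 10⁴.

What the generator does **not** emulate: haplotype structure and real LD
(draws are independent by construction), admixture and migration
(American-analogue populations are as "clean" as any other, whereas real
admixed cohorts classify worse), mutation, genotyping error, and
null-allele artefacts. Tests passing on this data therefore demonstrate
correctness of the estimators and protocols under the model assumptions
the screening steps are designed to verify — not robustness to the messy
features of real cohorts, which only real data can show.

## Determinism and problem sizes

Every stochastic function takes an explicit integer seed;
`derive_seed(seed, label)` hashes a label into a decoupled 31-bit stream
so pipeline stages and repetitions are independently reproducible, and
reruns of `run_pipeline` with the same config produce byte-identical
CSVs. The test suite and the acceptance script size their simulations to
run comfortably on a single CPU — e.g. 1000 simulated pairs per kinship
table (matching the usual reporting convention), 2000 replicates for HWE
calibration, $L = 500$, $n = 200$ for divergence parameter recovery, and
reduced search budgets/repetitions for the SVM property checks — sizes at
which the Monte-Carlo tolerances asserted in the tests (±3 binomial SE)
are meaningful.

## Known limitations

Multi-allelic markers, sex-linked loci, pedigrees beyond pairwise IBD,
admixture-graph or model-based ancestry inference (STRUCTURE-style), and
bootstrap support on NJ trees are out of scope. The per-locus
allele-frequency tables behind the published Tibetan-cohort reference
values used by two acceptance checks are distributed on request by their
authors only; in their absence those checks report their input as
unavailable rather than substituting synthetic look-alikes.
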