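---
title: "Selective regimes on protamine genes: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective regimes on protamine genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Protamines are small arginine-rich nuclear proteins that replace histones
during spermatogenesis and compact the sperm genome. Protamine 1 is present
in all mammals; protamine 2 is translated as a precursor whose N-terminal
("cleaved") domain is proteolytically removed, leaving the mature domain.
Because the two protamines are partly redundant, a gene copy can drift
toward *relaxation of selective constraint* — a regime in which its
nonsynonymous/synonymous rate ratio is indistinguishable from 1 — and in
extreme cases pseudogenize. Sperm competition (measured by relative testes
mass) is hypothesized to oppose this degeneration in promiscuous lineages.

`protsel` implements the full inferential chain needed to ask these
questions of in-frame coding alignments on a known species tree:

1. a Goldman–Yang codon substitution model with branch-partition and
   site-mixture omega structures, fitted by maximum likelihood;
2. likelihood-ratio tests with an explicit decision rule separating
   positive selection from relaxation in a focal clade;
3. Bayes empirical Bayes (BEB) classification of sites into purifying
   (class 1, omega < 1), neutral (class 2, omega = 1) and positively
   selected / relaxed (class 3, omega > 1) classes;
4. per-species cumulative root-to-tip omega from a free-ratio model;
5. phylogenetic generalized least squares (pGLS) of root-to-tip omega
   against relative testes mass under an exponential covariance;
6. annotation of protamine functional regions (DNA-anchoring domains,
   phosphorylation motifs, configured cleavage sites) and per-region
   selective profiles;
7. a simulator that is the exact generative twin of the likelihood, so the
   whole chain is testable without any external data.

## The codon model

The substitution process runs on the 61 sense codons of the universal code.
The instantaneous rate from codon $i$ to $j$ is nonzero only for
single-nucleotide changes:

$$ q_{ij} = \pi_j \times \begin{cases}
  1 & \text{synonymous transversion}\\
  \kappa & \text{synonymous transition}\\
  \omega & \text{nonsynonymous transversion}\\
  \omega\kappa & \text{nonsynonymous transition}
\end{cases} $$

with $\pi$ the equilibrium codon distribution, $\kappa > 0$ the
transition/transversion ratio and $\omega \ge 0$ the dN/dS ratio. The
generator is scaled so branch lengths are expected substitutions per codon;
for site mixtures the scale is the mixture-average rate, so a branch length
means the same thing to every site class. The model is reversible by
construction, and the likelihood is computed by Felsenstein pruning on
compressed site patterns with per-node rescaling (no underflow on long
alignments); tip gaps and IUPAC ambiguities are treated as missing data,
summing over compatible codons.

Equilibrium frequencies are empirical — `equal`, `F1X4`, `F3X4` (default)
or `F61` with add-one smoothing — and are not optimized or counted as free
parameters within a fit. Because the frequency models are not nested,
`select_freq_model()` compares them by AIC, counting their empirical
parameters (0/3/9/60); the choice is the user's to log per run.

**Omega structures.** `M0` (one ratio); a branch partition with a
foreground clade versus background (the clade's stem branch is included in
the foreground by default — the usual clade-test convention; configurable);
`free_ratio` (one omega per branch); and the site mixtures `M1a`
(purifying $\omega_0 \in [0,1)$ plus neutral $\omega_1 = 1$), `M2a` (adds
$\omega_2 \ge 1$), `M7` (beta(p, q) on (0,1)) and `M8` (beta plus a
selection class $\omega_s \ge 1$). The beta is discretized into K = 10
equal-probability categories represented by their medians (K is an
argument).

## Clade tests: positive selection vs relaxation

Three models are fitted: Model 1 (one ratio), Model 2 (two ratio with the
focal clade pinned at $\omega = 1$ — the relaxation null) and Model 3 (two
ratio, both free). Both LRTs have one degree of freedom. The decision rule
(`clade_rule()`):

* **Positive**: Model 1 vs 3 significant, Model 2 vs 3 significant, and
  the foreground $\hat\omega > 1$;
* **Relaxation**: Model 1 vs 3 significant but Model 2 vs 3 not — the
  clade's rate differs from the background yet is statistically
  indistinguishable from neutrality;
* **None** otherwise.

Significance defaults to 0.05 (configurable), with no multiple-testing
correction, matching how such clade scans are conventionally reported. The
site-model LRTs (M1a vs M2a, M7 vs M8) use 2 degrees of freedom against a
standard chi-square; because the null pins parameters at a boundary of the
alternative's space this reference is conservative, which the calibration
study below confirms rather than corrects.

## BEB site classification

Naive empirical Bayes plugs the mixture MLEs into Bayes' rule and ignores
their sampling error. BEB instead places a discrete uniform grid prior on
the mixture parameters (10 points per free dimension; proportions on (0,1),
purifying omegas on (0,1), selection omegas on (1,11), beta shapes on
(0,2)), weights each grid point by its integrated likelihood, and averages
the per-site class posteriors over that posterior. A one-point grid reduces
exactly to the plug-in posterior, which the tests assert. For M7/M8 the
beta categories implied by each grid point are snapped to a fixed omega
lattice on (0,1) so site likelihoods are computed once per lattice value —
an approximation confined to the beta component's discretization, which is
itself an approximation of the same order. Class-3 flags (posterior > 0.95
or > 0.99) are only defined for class-3-capable models (M2a, M8); M1a/M7
report them as not allowed. A site's class is its maximum-posterior class,
with the posterior mean and standard error of omega reported alongside —
"close to 1" is thus operationalized as membership of the $\omega = 1$
class rather than a numeric band.

## Root-to-tip omega and the comparative analysis

Per-branch expected dN and dS are obtained from the scaled generator by
splitting its substitution flux into synonymous and nonsynonymous parts and
normalizing each by the corresponding site proportion at the mutational
null ($\omega = 1$); under $\omega = 1$, dN = dS for any $\kappa$ and
$\pi$. A species' cumulative omega is the **ratio of the sums** of dN and
dS along the unique root-to-tip path — not the mean of per-branch ratios,
a distinction a unit test encodes deliberately. Species whose path has zero
synonymous substitutions get an undefined ratio and are dropped from the
comparative step with a warning.

pGLS uses the exponential correlation $C_{ij} = \exp(-\alpha d_{ij})$ with
$d$ the patristic distance; $\alpha \ge 0$ measures how fast phylogenetic
covariance decays (large $\alpha$ recovers OLS — asserted to 1e-6 in the
tests). $\alpha$ is estimated by maximizing the GLS profile likelihood on a
log scale over $[10^{-4}, 10^3]$; the slope CI is a normal approximation
conditional on $\hat\alpha$, using the unbiased residual variance (a
t-interval is available via `ci_type = "t"`). The reported correlation is
the Pearson correlation of the whitened, GLS-centered variables, i.e. the
standardized slope, guaranteed to lie in [-1, 1]. At n = 14 with $\alpha$
estimated per dataset the nominal 95% interval empirically covers ~88–91%
(normal vs t) — the coverage study in the test suite documents this rather
than hiding it. Relative testes mass is observed testes mass divided by the
allometric expectation $a\,M^b$; the coefficients are required inputs with
no hidden defaults.

## Domain annotation

DNA-anchoring domains are maximal runs of three or more Arg/Lys flanked by
a cysteine within `flank_window` residues (default 5 — "short peptide
segment" is not a quantified notion, so the window is explicit and
configurable) on at least one side; the reported interval extends to the
qualifying cysteines and overlapping intervals are merged. Phosphorylation
motifs use ProSite-style consensus patterns — PKC `[ST]-x-[RK]`, PKA
`[RK]-[RK]-x-[ST]`, CK2 `[ST]-x-x-[DE]` — with all overlapping matches
reported; the kinase set is per-gene configuration. Cleavage sites of the
protamine 2 precursor are experimentally determined positions supplied in
reference-sequence coordinates and mapped through the reference row's gaps
to alignment columns. All coordinates are 0-based, half-open.

## The synthetic-data module

`simulate_codon_alignment()` draws root codons from $\pi$, assigns each
site a mixture class, and draws child states from the exact $e^{Qt}$ rows
per branch, sharing the generator construction and scaling with the
likelihood — the simulator is the model's generative twin, so simulation
followed by fitting is a closed consistency loop. A Gillespie mode
(`simulate_branch_counts()`) realizes event-by-event paths to count actual
synonymous/nonsynonymous substitutions against their expectations.
`simulate_traits()` draws the predictor and the noise from the same
$\exp(-\alpha d)$ covariance the pGLS assumes, with
`slope_for_correlation()` converting a target standardized correlation
into a slope. The default generating frequencies
(`protamine_like_freqs()`) skew base composition the way arginine-rich
protamine sequences do.

What the simulator does **not** emulate: insertions/deletions and
alignment error, lineage-specific base composition, selection on codon
usage, recombination, and rate variation beyond the omega structures.
Passing recovery tests therefore demonstrate the estimator chain is
correct and well calibrated *under its own assumptions*; they do not
certify robustness to misalignment or compositional drift in real data.
Sequences carrying frameshifts or premature stops must be screened with
`integrity_check()` before alignment — the codon alignment container
rejects in-frame stops by design.

## Study conditions and problem sizes

The recovery and calibration studies (in `R/protocols.R`, driven by the
`analysis/` scripts, re-run by `scripts/acceptance.R`) use fixed
conditions chosen to mirror the rodent protamine setting at sizes a desk
machine handles:

* **Clade recovery**: 16-taxon tree with an 8-tip focal clade, background
  omega 0.3, kappa 2, 800 codons, 20 replicates per foreground truth
  (2.44, 2.75, 1.66 — point estimates reported for protamine 1, cleaved
  and mature protamine 2 in cricetid rodents). Fitted foreground omegas
  are averaged.
* **Site-model recovery**: 17-taxon tree, 500 codons, 10 replicates; M8
  seeded at (p0 0.58495, p 0.0050, q 0.04910, omega_s 2.65844) recovering
  omega_s; M1a seeded at p0 0.63016 (its purifying omega, unreported in
  the source tables, is set to 0.05) recovering p0.
* **LRT calibration**: 200 null replicates of 60 codons on a 5-taxon
  tree; each null (M1a) fit starts cold — a sloppy null inflates the
  statistic — the alternative warm-starts from it and is refitted cold if
  it lands below the null.
* **pGLS recovery**: 14-taxon tree (the 17-taxon tree minus the outgroup,
  the pseudogenized species and the database-only species), 500
  replicates, truths -0.69 (alpha 15.5) and -0.574 (alpha 8.17).
* **BEB false flags**: M2a with 5% of sites at omega 3; pooled over 4
  replicates of 300 codons, the fraction of PP > 0.95 flags on truly
  non-class-3 sites.

## Numerical choices

* Optimization: bounded quasi-Newton (L-BFGS-B) on transformed parameters
  (log for positive, logit for proportions and $\omega_0$, $\log(x-1)$ for
  selection omegas); omega search bounds $[10^{-6}, 50]$, kappa
  $[0.1, 20]$; convergence factor `factr = 1e8` (~1e-4 log-units), which
  is why nested-fit assertions carry a 5e-3 tolerance.
* Branch lengths: fully free, a single scale multiplier of the input
  tree's lengths (used throughout the simulation studies, where the input
  topology's relative lengths are trustworthy), or fixed.
* Warm starts: nested ladders (M0 → M1a → M2a, M0 → M7 → M8, one-ratio →
  two-ratio) initialize the alternative from the null; the default is a
  single start, with `n_starts` available for cold multi-starts (the
  3-start agreement is a test). This replaces always-on multi-start
  because warm-started refits are empirically better behaved and keep fit
  time proportional to problem size.
* The pruning pass runs in compiled code: partial likelihoods propagate in
  the generator's eigenbasis, tip edges reduce to column selection of the
  transition matrix, columns are rescaled at every completed node, and tiny
  negative probabilities from the spectral reconstruction are clamped to
  zero (unclamped they become Inf·0 = NaN under rescaling and present the
  optimizer with a false cliff).
* Site mixtures are optimized with branch lengths in raw generator time,
  making per-class pruning passes memoizable across gradient evaluations
  (keys at full precision — rounding them corrupts finite differences);
  fitted scales are converted back to substitutions per codon. Spectral
  decompositions are cached by (kappa, omega) within a fit.
* Consensus ties become IUPAC ambiguity codes, and ambiguity is missing
  data downstream; columns with any gap/ambiguity are removed before
  fitting by default (`cleandata = TRUE`, configurable).
* Percent identity excludes columns with a gap in either sequence from
  the denominator; the exact convention of alignment-viewer identity
  reports varies, so this rule is fixed and documented.

## Known limitations

No branch-site models, no non-universal genetic codes, no MG94-style or
empirical-exchangeability codon models, no indel model. The chi-square
reference for the boundary LRTs is conservative. BEB for M7/M8 uses the
omega-lattice approximation described above. The pGLS slope interval is
conditional on $\hat\alpha$ and slightly anticonservative at small n.
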