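---
title: "Models and methods in evoscales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in evoscales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`evoscales` compares rates of molecular and phenotypic evolution within and
between species, and predicts macroevolutionary rates from microevolutionary
parameters. This vignette is the package's own account of the models it
implements, the choices made where the design was genuinely open, and what
the synthetic-data tests do and do not demonstrate.

## Trees, units and the combined phylogeny

Every tree carries an explicit branch-length unit tag — `"Myr"`,
`"subs/site"`, `"relative"` or `"coalescent"` — and operations that mix
units fail loudly. This is deliberate: cross-scale analyses juggle
relatively dated intraspecific trees, time-calibrated species trees and
substitution-scaled gene trees, and silent unit confusion is the most
dangerous failure mode of the whole exercise.

An intraspecific tree enters the species-level analysis in three steps:

1. **Calibration**: a relatively dated ultrametric tree (root depth 1) is
   rescaled so its crown matches a crown age supplied by the user — in
   practice taken from the species-level phylogeny. When the topologies of
   the two posteriors disagree about where that crown is, no automatic
   matching is attempted; the crown age is an explicit input.
2. **Grafting**: the focal species' tip is replaced by the intraspecific
   tree, with the recipient stem shortened so every tip stays at the
   present. If the intraspecific crown is older than the stem allows, the
   operation fails rather than silently rescaling — a deeper-than-stem
   coalescent is a data problem the user must see.
3. **Pairing**: posterior uncertainty at both scales is propagated by
   randomly combining the two tree distributions (the shorter distribution
   in order, partners drawn uniformly with replacement), reproducibly under
   a seed.

Pruning preserves the root-to-tip depth of every retained tip: when the
most recent common ancestor of the kept tips sits below the original root,
the dropped root path is kept as a root edge. Ultrametricity is judged at a
relative tolerance of 1e-6 of tree height, absorbing the floating-point
noise of posterior samples. Node support values are read and written but
ignored by every computation.

## Molecular rates

The likelihood engine is a standard Felsenstein pruning recursion over site
patterns with per-pattern rescaling, under JC or HKY with the rate matrix
normalised to one expected substitution per site per unit branch length.
Gaps and Ns are missing data (partial likelihood 1 in every state); IUPAC
ambiguity codes other than N are mapped to N. The branch-length optimiser
is a cyclic per-branch bounded scalar maximisation: Brent's method on the
log branch length within [1e-9, 10] substitutions/site, with the partial
likelihoods above and below the focal branch recomputed freshly for each
branch, and passes repeated until the log-likelihood improves by less than
1e-6. This derivative-free scheme is slower than Newton-type optimisers but
deterministic and robust on the many effectively-zero branches of
intraspecific trees. The substitution model defaults to HKY with empirical
base frequencies and a transition/transversion ratio profiled once per
pass; JC is retained because closed forms exist for testing (the two-taxon
ML length equals the analytic distance −(3/4)·log(1 − 4p/3)).

The mean rate of a gene relative to a dated tree is the ratio of
branch-length sums, in substitutions·site⁻¹·Myr⁻¹ — per site, because only
per-site rates are comparable between datasets of different length.
Replication over a tree distribution yields a per-tree rate sample
summarised by its median and equal-tailed 2.5–97.5% percentile interval
(the interval construction is a package choice); two rates are declared
significantly different when their intervals do not overlap. Note what this
sample does and does not capture: the alignment is fixed, so the interval
reflects dating/topology uncertainty, not sequence-sampling noise.

The haplotype-pruning prediction mimics the loss of transient polymorphism
at speciation: all but one conspecific individual are pruned from the
combined tree, branch lengths re-optimised, and the predicted species-level
rate read off the retained terminal branch. Because a single terminal
branch carries only a handful of substitutions, individual predictions are
extremely noisy; the procedure is therefore pooled over every individual
and many trees, and its interval is expected to be wide.

## Trait drift and its diffusion limit

The drift simulator evolves a species-mean trait from three intraspecific
parameters: the trait variance s² (held constant), the effective population
size Ne, and the generation time τ in years. Each generation, Ne
individuals are drawn from N(mean, s²) and the next mean is their sample
mean. Since the sample mean of Ne normal draws is exactly N(mean, s²/Ne),
the implementation draws each generation's update from that law directly
(accumulated in compiled code) — an exact shortcut, not an approximation.
Generations per branch are `max(1, round(branch_Myr * 1e6 / tau))`: branch
durations are not multiples of τ, and a zero-generation branch would freeze
evolution. Increments aggregate to Brownian motion with rate

σ²_pred = s²·10⁶ / (Ne·τ)  (trait²/Myr),

and a `"diffusion"` mode adds one N(0, σ²_pred·branch) increment per branch
— the distributionally equivalent fast path for long branches. The
equivalence of the two modes is a tested property (two-sample KS per tip),
not an assumption. The root value defaults to the grand mean of the
observed species means. Replicates get independent seeds derived from one
master seed, so any subset can be regenerated on its own.

## BM/OU fitting and the prediction test

Brownian motion is fitted by generalised least squares on the phylogenetic
covariance C (shared root-to-MRCA path lengths): θ̂ = (1ᵀC⁻¹x)/(1ᵀC⁻¹1),
σ̂² = (x−θ̂1)ᵀC⁻¹(x−θ̂1)/n with the ML divisor n (not REML), so
log-likelihoods are comparable across models. The Ornstein–Uhlenbeck model
uses V_ij = σ²/(2α)·e^(−2α(T−C_ij))·(1−e^(−2αC_ij)) with the root state
fixed at the optimum θ — the identifiable choice on ultrametric trees; the
stationary-root variant is out of scope. For each candidate α, θ and σ² are
profiled analytically; α is searched on a 40-point log grid spanning
[1e-6, 50]/T and refined by bounded 1-D optimisation, a deterministic
scheme whose profile likelihood is continuous in α (tested). Model choice
is by AICc = −2logL + 2k + 2k(k+1)/(n−k−1), ties going to the smaller
model. Constant traits yield σ̂² = 0 with an unbounded likelihood; fits
report σ² = 0 and downstream selection is skipped in that degenerate case.

The prediction test asks how often drift-simulated rates fall inside the
empirical 95% rate interval; predicted and empirical distributions are
declared not significantly different when that fraction is at least 0.05.
The model fitted to simulations is always the one selected on the
empirical data. When no posterior tree distribution is available to supply
an empirical rate distribution, the package builds one by parametric
bootstrap of the selected empirical fit — a stand-in whose width reflects
sampling noise rather than dating uncertainty, which the documentation
flags in the output. Specificity is probed by rescaling Ne (e.g. ×100,
÷100) and rerunning the whole pipeline: a prediction that still "works"
under grossly wrong Ne would indicate a lack of power, not a real link
between scales.

The pmc-style power analysis simulates B datasets under each fitted model
and uses δ = 2(logL_OU − logL_BM). The power is the fraction of
OU-simulated datasets exceeding the null 95th percentile. For the type-I
summary a second, independent batch of BM datasets is simulated and
rejected at the first batch's critical value: with data truly generated
under BM this rate should sit near the nominal 5%. (The power statistic
itself is *not* a type-I rate — the fitted OU on BM data has a
boundary-biased α and inflates it — which is why the independent batch
exists.)

## Selection tests

McDonald–Kreitman counting is codon-aware: for a codon pair differing at
d sites, synonymous and non-synonymous steps are averaged over all d!
minimal mutational paths that avoid stop codons (for standard-code sense
codons a stop-free minimal path always exists; exhaustively verified in the
tests). Counts therefore may be fractional; they always sum to the
nucleotide Hamming distance. Within the ingroup each segregating codon
state is counted once against the most frequent state — no frequency
weighting, singletons retained; fixed differences are counted only at
ingroup-monomorphic codons; codons containing a gap or N in any sequence
are wholly excluded. The 2×2 test is Fisher's exact test (counts rounded
for the test, raw counts kept for NI = (Pn/Ps)/(Dn/Ds) and α = 1 − NI,
reported as missing when a denominator is zero).

The depth association is an *unpaired* two-sample rank test (Mann–Whitney
U) of water depth between the two amino-acid state groups — the sampling
design has no pairing, and the output records this choice — exact when both
groups have ≤ 12 observations without ties, normal approximation with tie
correction otherwise. States carried by fewer than two individuals are
dropped, and exactly two states must remain.

## The synthetic study and what passing tests mean

`make_study_fixture()` emulates the full study design with known truth:

* a 26-species birth–death tree, crown 10 Myr, speciation 0.3 and
  extinction 0.1 per Myr — a moderate-extinction reef-fish-like radiation;
* a 53-individual Kingman coalescent nested in the species with the longest
  stem, calibrated to a 0.15 Myr crown. The crown age is pinned by mutual
  consistency of the three rate scales the package is designed to recover:
  with a per-site within-species rate near 7.5e-3/Myr and a 251-codon
  fragment, a ~0.15 Myr crown implies the handful of segregating sites
  realistic for a conserved protein-coding gene, and keeps the
  polymorphism contribution to any single pruned terminal branch small —
  the regime in which a species-level rate is predictable from one
  haplotype. A several-fold deeper clade would imply implausibly many
  polymorphisms and a prediction dominated by them;
* a 753-site codon-safe alignment under HKY (κ = 4), evolving at 1.16e-3
  substitutions/site/Myr along the species backbone and 7.48e-3 within the
  focal clade — the elevated within-species rate emulates transient
  polymorphism destined to be lost, the phenomenon the rate comparison is
  meant to detect;
* drift parameters s² = 1, Ne = 1000, τ = 5 yr (σ²_pred = 200 trait²/Myr);
* posterior-like tree distributions of 20 trees built by node-age jitter
  (lognormal sd 0.1 per node, plus a lognormal crown-age factor) on the
  fixed true topology;
* a balanced biallelic site with an 8 m depth effect around a 10 m mean
  (sd 4 m), depths truncated at 0.5 m.

Desk-scale replicate sizes are the package's own choices: 15 trees per rate
distribution, 10 individuals × 5 trees for the pruning prediction, 300
exact-mode drift simulations on the species tree, 50 calibration runs of 40
simulations each on a 10-tip tree, B = 200 bootstrap replicates, 500
replicates for the null calibrations.

What the fixture does *not* emulate: topology uncertainty (jitter moves
node ages only), sequence-sampling noise in the rate intervals (one
alignment realisation per fixture), selection on sequences, rate
heterogeneity among sites, migration or population structure, and any
change of s² through time. Passing tests therefore show that the estimators
recover known truth under the model assumptions at realistic sizes — not
that those assumptions hold for any particular empirical system.

## Numerical choices collected

* Ultrametricity tolerance: relative 1e-6 of tree height.
* Branch-length bounds [1e-9, 10] subs/site; optimiser tolerance 1e-7 on
  the log length; convergence when a full pass gains < 1e-6 log-likelihood;
  at most 25 passes, with a warning and the best-found solution on
  non-convergence.
* Zero-variation alignments drive all branches to the lower bound;
  impossible site patterns propagate to a −Inf log-likelihood rather than
  an error.
* α grid: 40 log-spaced points on [1e-6, 50]/T, Brent refinement between
  the neighbouring grid points; α below 1e-12 uses the exact BM limit of
  the OU covariance.
* Percentile intervals are equal-tailed 2.5–97.5%, quantile type 7.
* Fisher tests round fractional MK counts to the nearest integer; NI uses
  the raw counts.
* Newick writers emit 10 significant digits, so equal trees serialise to
  equal bytes.
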