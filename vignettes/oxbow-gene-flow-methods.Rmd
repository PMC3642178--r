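---
title: "Testing meander-loop-cutoff gene flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing meander-loop-cutoff gene flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question and the design

Meander loop cutoff (MLC) severs a river meander at its neck, leaving an
oxbow lake and — crucially for population genetics — transferring the land
inside the loop, together with every resident organism, to the opposite
bank. If a river is a barrier to gene flow for a terrestrial species, MLC is
a mechanism that can breach it passively and *directionally*: alleles move
from the loop's original bank to its new one.

`oxbowflow` implements the full analysis used to test this hypothesis on a
two-lineage system meeting at a large meandering river. The sampling design
is a triplet per ancient oxbow: the **cis** site inside the old loop
(currently on, say, the east bank but historically part of the west bank),
the **trans** site just outside the loop on the same current bank, and the
**control** site directly across the current river; two distal **pure**
sites far from the river anchor the two lineages. Seven directional
predictions follow (similarity of cis to control rather than trans; excess
wrong-side individuals at cis; asymmetric recent immigration control→cis
and control→trans; higher equilibrium Nm across the river than along the
bank; a better fit of the *historical* river course to the distribution of
side-diagnostic private alleles; and detectable divergence of cis itself).
`evaluate_predictions()` scores all seven per marker and latitude, by the
*direction* of point estimates — significance is retained as evidence, not
used as the verdict, mirroring how such scoreboards are usually read.

# The synthetic study

Because the package must be exercisable end-to-end without any field data,
`simulate_study()` implements a forward-time Wright–Fisher model of the
design, and `make_fixture("paper_shape")` emits a study with the exact
geometry of the motivating design: 15 sampling locations pooling to 11
analysis sites, 260 diploids, 13 microsatellite loci and one 809-bp mtDNA
fragment.

The demographic model has three phases:

1. **Bank divergence.** Two pools of `pool_size` diploids (default 100)
   evolve in complete isolation for `t_split` generations (default 400),
   starting from a common ancestral state. The ancestral microsatellite
   pool is initialized from per-locus discretized-normal allele-frequency
   profiles (centers 20–40 repeats, SD 2–5) — a stand-in for a stationary
   stepwise-mutation profile that avoids simulating a long ancestral
   burn-in; the ancestral mtDNA is a single random haplotype, so
   between-bank mtDNA divergence accumulates only after the split.
2. **Local founding.** `t_local` generations before present (default 100)
   a river neighbourhood is founded from the pools: `demes_per_bank`
   stepping-stone demes per bank (default 3, `deme_size` 100, adjacent
   demes exchanging `m_along` = 0.02 per generation; facing demes exchange
   `m_cross`, default 0) plus one meander-loop deme attached to the
   mid-west-bank deme. Before the cutoff the loop is continuous riverside
   habitat joined by a wide neck, so its coupling to the bank,
   `m_loop` = 0.1, is stronger than between distance-separated demes.
3. **Cutoff and leakage.** `t_cutoff` generations before present (default
   20) the loop deme is relabelled to the east bank, exchanges nothing for
   `t_iso` generations (default 10; the young oxbow still isolates it),
   and then exchanges with its new east-bank neighbour (the trans deme) at
   `m_along` — this leakage is what the control→trans prediction probes.

Microsatellites mutate under a strict single-step model at
`msat_mut_rate` = 5e-3 per copy per generation with reflecting bounds at
repeat codes [5, 60] (so alleles always fit the 3-digit GENEPOP dialect).
The mutation rate is at the high end of the plausible microsatellite range;
it keeps within-site gene diversity at realistic levels (H~E~ ≈ 0.6–0.75)
despite the small deme sizes that make the simulator fast. mtDNA is copied
from one uniformly chosen parent (no explicit sexes — the markers require
only a maternally inherited haploid locus) and mutates at
`mtdna_mut_rate` = 7.5e-5 per site per generation, calibrated together
with `t_split` so that the two bank haplogroups differ by roughly 6%
uncorrected distance (the divergence reported for the motivating system)
with shallow within-group diversity. Pure sites are sampled from the
distal pools, which keep evolving in isolation through the local phase.

Three oxbows are simulated as three independent local phases founded from
one shared bank-divergence phase (`simulate_oxbow_study()`), so all
latitudes share the same deep lineages but have independent local
histories — one seed stream drives everything, and identical
configurations are reproduced byte-for-byte.

**The no-cutoff null.** False-positive calibration needs a world in which
the cis/trans/control labels carry no information. Simply omitting the
transfer does *not* achieve that: a deme labelled "cis" on a structured
river still sits on one definite bank, so several direction tests become
systematically false rather than coin flips. The `no_cutoff_null` fixture
therefore makes the river region *exchangeable*: all river demes are
founded from an even mixture of the two pools and connected as a complete
graph with equal migration weights, so every permutation of river demes is
an automorphism of the model and each direction statistic is symmetric by
construction. The pure sites keep their deep divergence, so private
alleles and haplogroups remain defined.

**What the generator does not emulate.** Continuous space and
isolation-by-distance within sites; sex-biased dispersal; genotyping
artifacts (null alleles, allelic dropout); mutation-rate heterogeneity
among loci; and channel-switching histories that could mimic MLC. A green
test suite on this generator shows the *estimators and the inference
chain* behave as intended under the MLC mechanism — not that real data are
free of the confounders above.

# Statistics

All estimators are computed from first principles on the genotype table:

* **Diversity** (`diversity_summary()`): Nei's unbiased gene diversity
  `(n/(n-1))(1 - Σp²)` with `n` gene copies; observed heterozygosity by
  direct counting; Weir–Cockerham *F*~IS~ from the variance components `b`
  and `c` summed over alleles and loci (`f = 1 - Σc/Σ(b+c)`), monomorphic
  loci excluded as undefined; rarefied allelic richness
  `Σ_a [1 - C(N-N_a, g)/C(N, g)]`. Two rarefaction depths are reported:
  `A_R` at `g` = 40 gene copies (capped at the global minimum) and `A_R*`
  at the global minimum depth; both are arguments.
* **Differentiation** (`pairwise_fst()`, `gst_hedrick()`, `d_est_jost()`):
  Weir–Cockerham θ with a permutation test (individuals shuffled between
  the pair); Hedrick's `G'_ST = G_ST / [(k-1)(1-H_S)/(k-1+H_S)]` and
  Jost's `D = [(H_T-H_S)/(1-H_S)]·k/(k-1)` with Nei–Chesser unbiased
  `H_S`/`H_T` and harmonic-mean sample sizes. The global `D` is the
  variance-corrected harmonic mean of per-locus values with negative
  values floored at zero first (the convention of the standard
  differentiation calculator); the arithmetic mean is reported alongside.
  Estimators are not truncated at zero — small negatives are legitimate
  sampling outcomes.
* **Disequilibrium** (`hwe_exact_test()`, `ld_permutation_test()`,
  `bonferroni()`): the conditional exact HWE test with the
  probability-ordering rejection region — exhaustively enumerated for
  two-allele tables (the Levene distribution), Monte-Carlo re-pairing of
  gene copies otherwise (default 20,000 replicates; raise `mc_reps` for
  publication-grade p-values); a G-statistic permutation test for linkage
  disequilibrium; Bonferroni flags with the boundary `p = α/m` counted as
  significant.
* **Pooling check** (`amova_pooling_check()`): one-level differentiation
  among member sampling locations by multilocus θ with a permutation null;
  locations are pooled into their parent site only when p > 0.05, applied
  at load time from the metadata's `parent_id` column.

# Samplers

**Admixture clustering** (`admixture_mcmc()`): the uncorrelated-frequencies
admixture model — allele-copy origins Z, cluster frequencies P with a
Dirichlet(1) prior and per-individual ancestry Q with a symmetric
Dirichlet(α) prior — updated by Gibbs sweeps. α is sampled by Metropolis
with a uniform(0, 10] prior by default (fixing it is an option); sampling α
is what lets the model collapse to effectively one cluster on unstructured
data, which in turn makes the likelihood-based choice of K behave. The
model log-likelihood is estimated as `mean(lnL) - var(lnL)/2` over
post-burnin sweeps, and `select_k()` ranks K by that estimate and by the
Evanno second-order statistic
`ΔK = mean_r |L_r(K+1) - 2L_r(K) + L_r(K-1)| / sd(L(K))` across paired
replicate runs (defined only for interior K of a contiguous range of at
least three). Labels are aligned across runs by ordering clusters on mean
ancestry among the west-pure individuals, which replaces heavier
label-matching machinery. Default chain lengths (2,000 sweeps, 500
burn-in) are scaled down from the very long runs used in field studies;
they are arguments everywhere.

**Recent migration** (`recent_migration_mcmc()`): a first-generation-migrant
assignment model. Each individual sampled at site r is an immigrant from
site s with prior probability `m[r,s]` (rows are free Dirichlet — no upper
bound on total immigration); its genotype likelihood under a source uses
that source's allele frequencies with a per-population inbreeding
coefficient F (hom: `p²(1-F) + pF`; het: `2pq(1-F)`) to absorb within-site
heterozygote deficits. The environmental-covariate regression layer of the
program that inspired this analysis is deliberately not reproduced — only
the asymmetric rate point estimates and their 95% HPD intervals are used
downstream. The sampler is a compiled Metropolis-within-Gibbs kernel with
the frequencies collapsed: origins are updated by random-scan Gibbs under
the leave-one-out Dirichlet-multinomial predictive likelihood, `m` rows by
conjugate Dirichlet Gibbs, and each F by logit-scale random-walk
Metropolis with a Beta(1, 5) prior. Three numerical choices matter and
were made deliberately:

* *Collapsing the frequencies* removes the self-overfitting that
  otherwise anchors every individual to its sampling site (with explicit
  per-site frequency parameters, a site's own sample always fits itself
  best and immigrant-heavy modes are unreachable in practice).
* *Random-scan order* removes update-order artifacts: with a fixed scan,
  whichever site updates first systematically seeds merge modes in
  near-symmetric posteriors.
* *The posterior mean of m is Rao-Blackwellized* (the conjugate
  conditional mean `(1+counts)/(R+n_r)` averaged over sweeps), which cuts
  Monte-Carlo noise enough that small but systematic asymmetries resolve
  at modest chain lengths; HPD intervals are still computed from the
  sampled draws (shortest-interval method).

The posterior for near-identical populations is genuinely multimodal
("everyone is a resident" vs "site A is mostly immigrants from B"), and
replicate chains can land in different modes; `check_convergence()`
measures across-replicate spread of the posterior means and flags — not
fails — runs that disagree, which is the behaviour the original analysis
obtained by comparing six independent runs.

**Private-alleles Nm** (`private_allele_nm()`): the mean within-site
frequency of alleles private to one of the two sites, inverted through the
published log-linear calibration `ln p̄(1) = a + b ln(Nm)` with the (a, b)
pairs for reference sample sizes 10/25/50 interpolated log-linearly at the
observed mean sample size. The method assumes an infinite island model at
quasi-equilibrium and is approximate by design; the test suite checks it
recovers Nm = 1 within a factor of two (median over replicates) on a small
island system, which is about what the method can promise. A pair with no
private alleles yields an explicit `no-private-alleles` status, never a
number.

# The channel test

`find_private_alleles()` records every allele seen in exactly one pure
site, with its pure-site frequency and whole-dataset frequency.
`filter_diagnostic()` applies the two inclusive thresholds (≥ 15%
prevalence in the own pure site, ≥ 10% overall) and keeps one allele per
locus — the highest overall frequency, ties broken toward the lower allele
code (the original analysis does not state its tie-break; one had to be
chosen and is documented here). The mtDNA haplogroups enter as two
mirrored pseudo-alleles sharing one allele-group level by default (the
"seven groups" reading: six microsatellite alleles plus mtDNA as one
group); `shared_group = FALSE` gives them separate levels.

`build_design()` produces one row per site × allele group with `k`
carriers (≥ 1 copy; haplogroup membership for mtDNA) of `n` scored
individuals, and two native flags: under the *historical* channel a site is
native to an allele when its historical bank matches the allele's origin
side (cis grouped with control), under the *current* channel when its
current bank matches (cis grouped with trans). Only cis rows differ
between the designs, so with no cis data the AIC difference is exactly
zero — a useful structural check. Pure sites contribute rows by default
(they anchor the native effect); `include_pure = FALSE` drops them.

`fit_mixed_logit()` fits `cbind(k, n-k) ~ native + (1|latitude) +
(1|allele_group)` by maximum likelihood with the Laplace approximation
(via `lme4::glmer`); ML rather than any REML-like variant because the AICs
are compared across models, and the AIC penalty counts four parameters
(intercept, slope, two variances). The odds ratio and its standard-error
interval come from the native coefficient on the log-odds scale. Complete
separation and boundary (singular) variance fits are flagged on the
result, not silently ignored. The test suite validates the Laplace
marginal likelihood against a brute-force adaptive Gauss-Hermite
quadrature over all crossed random intercepts jointly on small fixtures;
agreement is well within 1e-3 when the binomial denominators are
reasonably large. `compare_channels()` reports
`ΔAIC = AIC(current) - AIC(historical)`, so positive values favour the
historical channel, and refits the microsatellite-only branch whenever
mtDNA rows are present.

# Haplogroup assignment

The original analysis assigned individuals to the two mtDNA clades from a
maximum-likelihood gene tree with bootstrap support. With ~6% divergence
between haplogroups and ~1–2% within, clade membership is determined by
which pure-site reference set a sequence is nearest to, so
`assign_haplogroups()` uses nearest-reference uncorrected p-distance
(pairwise deletion of gaps and Ns, via `ape`'s distance machinery) and
leaves exact ties unassigned. This preserves the decision actually used
downstream (clade membership) without a tree-inference dependency.

# Scaling choices and problem sizes

Monte-Carlo calibration of the whole chain uses a compact study — deme and
pool size 60, `t_split` 250, `t_local` 60, cutoff 15 generations with 8 of
isolation, `mtdna_mut_rate` 1.2e-4 to keep the 6% divergence target, 15
diploids per river site and 12 per pure site — run at reduced chain
lengths (500–1,000 sweeps). `mlc_mechanism_check()` packages one such
replicate: direction of D~est~ similarity (cis–control vs cis–trans),
excess non-native ancestry at cis, the study-level immigration asymmetry
(the mean over the three oxbows of `m[cis←control] - m[control←cis]` —
averaging over latitudes is how the study-level claim is read, and it
stabilizes a statistic whose per-latitude margin is small), and the sign
of ΔAIC. The acceptance suite runs 25 cutoff replicates (each expected in
≥ 80% of seeds) and 50 exchangeable nulls (each direction test's success
count must be statistically compatible with 50%).

# Known limitations

* The battery's seventh prediction (divergence of the cis site itself) is
  usually "No" on synthetic data: the simulated loop deme reconnects to
  the bank after `t_iso` generations, whereas the empirical pattern that
  motivated the prediction involves oxbows that stayed sealed much
  longer. The cell is still computed (own-cluster at the best K, or cis
  in the top divergence pair) — it simply reflects the generator's
  demography.
* The migration model estimates first-generation immigration only; a
  transfer ~20 generations old is detected through profile similarity,
  not through literal migrant individuals, so its directional margin is
  small (though consistent). The HPD intervals are honest about this.
* The Barton–Slatkin calibration constants are the commonly reproduced
  values; the private-alleles method itself is only accurate to small
  factors under real violations of the infinite-island assumption.
* Oxbow ages in years cannot be mapped to `t_cutoff` without a generation
  time, which the system does not fix; `t_cutoff` is a free parameter.
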