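---
title: "Methods: testing selection divergence between gene duplicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing selection divergence between gene duplicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

After a gene duplication, the two copies can diverge in function, and
selection on a functional site may persist in one copy while relaxing in the
other. The motivating case is an epithelial sodium channel: the ancestral
alpha-like subunit carries an aspartate in an extracellular Na+ sensing
site, while the delta paralog (born from an alpha duplication in early jawed
vertebrates) has lost that residue repeatedly. `paralogsel` implements the
three quantitative layers such a study needs:

1. **Trait-level**: does the site-loss *rate* differ between the paralog
   lineages, and did key ancestors carry the site?
2. **Codon-level**: does per-site dN/dS differ between the paralog branch
   partitions at the residues of interest?
3. **Phenotype-level**: does the electrophysiological readout (Na+
   self-inhibition) and the tissue expression pattern track the site?

# The trait model

The trait is binary: site absent (0) or present (1). It evolves along a
rooted tree with branch lengths in expected substitutions per site as a
two-state continuous-time Markov chain with gain rate `q01` and loss rate
`q10` (events per unit branch length). The *independent* model applies
(`q01`, `q10`) everywhere. The *dependent* model adds one parameter: a
separate loss rate `q10_delta` on a designated set of branches (the delta
clades, stem branches included), sharing `q01`. The models are nested, so
`2 * (logL_dep - logL_indep)` is referred to the upper tail of
chi-square(1); because `q10_delta = q10` is an interior point of the
dependent model's parameter space, the plain chi-square(1) reference (not a
boundary mixture) is the correct one here, and it is also what this kind of
analysis conventionally reports. A boundary-mixture option exists but is off
by default.

Likelihoods are computed by Felsenstein pruning with the closed-form 2x2
transition matrix `P(t) = exp(Qt)`, `Q = [[-q01, q01], [q10, -q10]]`. Tips
scored `unknown` contribute partials `(1, 1)` — they are genuinely
uninformative, and a tree of only unknowns has log-likelihood exactly 0.
The tip tables demand an explicit row for every tip: outgroup sequences
without site information must be entered as `unknown` rather than being
silently defaulted.

**Root prior.** The default is the stationary distribution of the
default-class rates, `pi_present = q01 / (q01 + q10)`; `uniform` and fixed
states are options. The choice matters for rate-ratio summaries, so it is
explicit and testable rather than implicit. Under the dependent model the
root is treated as belonging to the default (alpha-like) class, since
`q10_delta` describes the derived delta lineages only.

**Fossilization.** An ancestral hypothesis is tested by fixing the state at
the most recent common ancestor of a taxon set: after the node's child
partials are combined, the disallowed state's partial is zeroed. The two
constrained likelihoods always satisfy
`L(present) + L(absent) = L(unconstrained)`; the test suite verifies this
partition identity to 1e-9 relative, which is a sharp end-to-end check on
the constraint plumbing.

# Fitting, MCMC, and marginal likelihoods

**Maximum likelihood** works on log-rates with box constraints
`[1e-6, 1e3]` and multi-start (a fixed start at 0.1 for every rate plus
starts drawn from the prior; the dependent fit can also be seeded with the
independent solution so nesting is never violated numerically). Likelihood
surfaces for these models are ridge-prone near the boundary when one state
is rare, which is why multi-start is the default rather than an option.

**MCMC** is a Gaussian random walk on log-rates, one parameter per
iteration, with exponential priors of mean 0.1 on the natural scale (all
rates in the motivating analysis sit within an order of magnitude of 0.1).
Defaults: 1,010,000 iterations, 10,000 burn-in, thinning 1,000, i.e. 1,000
retained samples. Proposal scales adapt toward 44% acceptance during
burn-in *only*, preserving detailed balance afterwards. Rate ratios
(`q01:q10`, `q01:q10_delta`) are summarized as the median of per-sample
ratios, not the ratio of medians — the per-sample ratio is the well-defined
posterior quantity. With a flat likelihood (all tips unknown) the chain must
reproduce its prior; the acceptance suite checks this with a KS test on
1,000 thinned samples.

**Stepping-stone marginal likelihoods** use the power schedule
`beta_k = (k/K)^(1/0.4)` (quantiles of Beta(0.4, 1), the shape exposed in
`ss_config()`), K = 100 stones of 10,000 iterations by default, chains
warm-started stone to stone, with the first 10% of each stone discarded.
The estimator accumulates `log mean(L^(beta_{k+1}-beta_k))` over stones
sampled at `beta_k`, starting from the prior at `beta = 0`. On 6-tip,
2-parameter problems the estimate agrees with a 2-D trapezoid quadrature of
`integral L(theta) p(theta) dtheta` to well under 0.3 log units (typically
~0.005). Model preference is reported as a log Bayes factor
`2 * (logML_1 - logML_2)` with the conventional bands: at most 2 weak,
2–5 positive, above 5 strong.

# Trait extraction from the alignment

The site of interest is defined by a reference sequence and an ungapped
residue position (e.g. the human alpha subunit aspartate); the mapped
alignment column is the one holding that residue. Calls: the target residue
scores `present`; any other standard amino acid scores `absent`; `X` (and
the ambiguity codes B, Z, J) score `unknown`. A gap is ambiguous between
"the residue was deleted" and "the sequence is missing here": if *every*
column within +/-5 of the site is a gap or `X`, the region is treated as
missing (`unknown`), while a lone gap flanked by real residues is treated
as a true deletion (`absent` by default; the `lone_gap` switch flips this,
because the distinction is a judgment call the source data do not resolve).

# The codon model and site tests

Selection at the codon level uses an MG94-style model crossed with HKY
nucleotide exchangeability: a codon's rate to a single-nucleotide neighbor
is `kappa` (transitions) or 1 (transversions), times the F3x4 frequency of
the target nucleotide at the changed position, times a synonymous rate
`alpha_s` or nonsynonymous rate `beta_s`. Multi-nucleotide changes have
rate zero; the chain lives on the 61 sense codons of the standard code, and
the generator is time-reversible with respect to the F3x4 codon frequencies
(stop-codon mass renormalized away). Position frequencies are floored at
1e-4 and renormalized: on short alignments a nucleotide can be unobserved
at a position, and a structurally zero codon frequency would break
reversibility (and the symmetrized eigendecomposition the likelihood kernel
relies on). One `kappa` (HKY) rather than a full REV nucleotide model is
deliberate: a six-codon region cannot support five extra nuisance
parameters.

A **nuisance stage** fits `kappa`, a single global omega and one
tree-length scale by ML (F3x4 frequencies from counts, held fixed), and
freezes them. Per-site tests then share the global normalization, so
`alpha_s` and `beta_s` are on the scale of the global synonymous rate:

* **FEL-style**: on a chosen branch subset (the alpha-subunit branches or
  the delta-subunit branches; remaining branches stay at the global omega),
  fit `(alpha_s, beta_s)`, test `beta_s = alpha_s` by chi-square(1), report
  `dN/dS = beta_s / alpha_s` and the direction (`dN<dS` when `beta < alpha`).
* **Contrast-FEL-style**: fit a shared `alpha_s` and partition-specific
  `beta_alpha`, `beta_delta` over the whole tree (branch partition by clade
  membership, stems included), test `beta_alpha = beta_delta` by
  chi-square(1), report both dN/dS values and their ratio.

Raw per-site LRT p-values are reported without multiple-testing correction,
matching how such per-site tables are conventionally presented; a q-value
layer is easy to add downstream and deliberately out of scope. Sites with
no variation are flagged untestable (FEL) or reported with p = 1 (a
partition without variation in the contrast). LRT statistics below 1e-4 —
the optimizer's resolution — are clamped to zero so that exactly symmetric
data (e.g. a delta partition cloned from alpha) report p = 1 rather than
0.99-something. Gap/ambiguous codons are fully ambiguous missing data
(partial 1 over all 61 states).

# Electrophysiology and expression

Na+ self-inhibition (SSI) is quantified from a voltage-clamp trace as

```
SSI = (I_peak - I_ss) / (I_peak - I_amil)
```

with all currents *signed* (inward negative) so the formula is
sign-convention safe: 0 means no decay from the peak, 1 means decay all the
way to the amiloride baseline. `I_peak` is the inward extremum within 15 s
of the bath switch (bounded because the decay time constant is ~2-3 s, so a
wider window would catch drift); `I_ss` averages a +/-5 s window centered
1 minute after the switch (the source protocol names the time point, not
the averaging window; both are configurable); `I_amil` averages the final
5 s, which must start at least 10 s (configurable) after amiloride to allow
block equilibration. Group comparisons are Student's t-tests (two-sample or
paired) and one-way ANOVA followed by Sidak-adjusted
(`1 - (1 - p)^m`) pairwise tests.

Expression calls are `RPKM/FPKM = count / ((length/1e3) * (total/1e6))`
with the conventional 0.3 background threshold. The two stated inequalities
("below 0.3 is background", "above 0.3 is expressed") are both strict, so
the measure-zero boundary value is resolved to *background*.

# The synthetic world

Every input class has a simulator, and their defaults are the stated world
the tests live in:

* **Trees**: Yule (birth 0.2, death 0), so a 1,000-tip tree has expected
  total branch length near `(n-1)/0.2 = 5,000` substitutions/site. The rate
  scale was chosen once so that the acceptance-rate settings
  (`q01 = 0.1, q10 = 0.02, q10_delta = 0.3`) produce tens to hundreds of
  gain and loss events per tree — the information content the recovery and
  calibration criteria presuppose. The delta clade is the internal node
  whose tip count is closest to the requested fraction (smallest node id on
  ties), a deterministic, seed-stable rule.
* **Traits**: exact event-driven CTMC sampling (exponential waiting times)
  along each branch, not endpoint matrix sampling, so internal-branch
  realizations exist for debugging and the simulator can be checked against
  the transition matrix on a single branch.
* **Codon alignments**: per-site MG94xHKY simulation with
  partition-specific omega on delta branches; for codon harnesses trees are
  rescaled to about one expected neutral substitution per codon per branch
  (total length ~2 per tip pair), emulating deep vertebrate divergence —
  with shallower trees a nonsynonymous rate of `0.02` at a single codon
  simply produces no events and the 25-fold contrast is unidentifiable.
* **Traces**: baseline, one-sample rise to the peak (so the sampled
  extremum equals the nominal peak exactly on noiseless traces),
  single-exponential decay with tau = 2.5 s, fast relaxation to the
  amiloride baseline, Gaussian noise.
* **Counts**: expressed genes get true RPKM at least 4, background at most
  0.15, Poisson count sampling around the designed rate (or exact rounding
  in deterministic mode); a 5e6-read library keeps Poisson zeros from
  blurring the threshold.

What a green test does *not* establish: the simulators use clocklike Yule
trees, site-independent codon evolution, a single decay exponential and
iid Poisson counts. Real data violate all of these (rate variation,
alignment error, correlated sites, drift in traces, overdispersed counts),
so the suite validates the *inference machinery*, not robustness to
real-data pathologies.

# Numerical choices, in one place

* Rate bounds `[1e-6, 1e3]` (trait) and `[1e-8, 100]` (site rates); site
  estimates at the lower bound are reported as exactly 0.
* Optimizers: L-BFGS-B on log-parameters; 1-D null fits via `optimize`.
* Pruning rescales partials per node; the codon kernel works in the
  symmetrized eigenbasis of the reversible generator and processes all
  sites of an alignment as one BLAS-backed matrix product per edge.
* Zero-length branches are legal (transition matrix = identity).
* MCMC adaptation only during burn-in; stepping-stone stones inherit the
  adapted scales and re-adapt only within their own discarded fraction.
* All simulators and pipelines are pure functions of (spec, seed); the
  pipelines derive stage seeds from one top-level seed via a deterministic
  hash of the stage name, each kept below 2^31.

# Known limitations

* Two trait states only; no correlated-trait (two-character) mode, no
  reversible-jump model averaging, no tree-uncertainty integration.
* The codon nuisance model is MG94xHKY with one global omega and one
  branch-length scale; no synonymous rate variation across branches, no
  MEME/FUBAR-style random effects.
* Contrast-FEL p-values are raw LRT p-values; the original tool's q-value
  machinery is not reproduced.
* Whether clade *stem* branches belong to the delta class is a modeling
  choice; stems are included here (the clade-tagging rule), and the choice
  is explicit and overridable by passing an edge mask directly to the site
  tests.
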