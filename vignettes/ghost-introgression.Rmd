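---
title: "Ghost introgression in species trios: what each class of method can identify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ghost introgression in species trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghosttrio)
```

## The model

`ghosttrio` works on the species tree `AB|C` with a distant outgroup `O`
under the multispecies coalescent with introgression (MSci). Looking
backwards in time, lineages sampled from each species coalesce within their
population at pairwise rate `2/θ` (θ = 4Nμ, in mutation units, so the
within-population pairwise coalescent time has mean θ/2); populations merge
at the species divergence times τ (also in mutation units, i.e. expected
substitutions per site); and at the introgression time `τ_H` each lineage
of the *recipient* species independently switches to the donor population
with probability γ. Three single-edge scenarios are modelled:

* **GHOST** — the donor is an unsampled lineage that diverged from the stem
  above the ingroup root at `τ_G` and injects into species A at `τ_H`;
* **INFLOW** — C donates into B at `τ_H` (`τ_H < τ_T`);
* **OUTFLOW** — B donates into C at `τ_H`.

Two derived branch lengths carry all the topology-level information: the
speciation-history internal branch `l_T = τ_R − τ_T`, during which only
a and b can coalesce, and the introgressed-history internal branch `l_S`,
during which only b and c can coalesce. `l_S` is `τ_G − τ_R` under GHOST
and `τ_R − τ_H` under INFLOW. Under OUTFLOW the introgressed c-lineage
enters population B, and once B merges into T at `τ_T` *all three* lineages
share one population, so every later coalescence is exchangeable across
pairs and contributes no directional signal: the effective exclusive window
is `l_S = τ_T − τ_H` (the branch between nodes T and S in the network). The
scenario-invariance tests in `test-simulate.R` confirm that with these
definitions the rooted-triple law below is exact in all three scenarios.
In coalescent units, `C_T = 2 l_T/θ_T` and `C_S = 2 l_S/θ_S`, where `θ_S`
belongs to the population hosting the exclusive b–c window (the stem
segment for GHOST, C for INFLOW, B for OUTFLOW).

## What topologies and site patterns can and cannot say

The rooted-triple probabilities are

$$P(G_3) = \tfrac13(1-\gamma)e^{-C_T} + \tfrac13\gamma e^{-C_S},\quad
  P(G_1) = (1-\gamma)(1-e^{-C_T}) + P(G_3),\quad
  P(G_2) = \gamma(1-e^{-C_S}) + P(G_3),$$

with `G1 = ab|c`, `G2 = a|bc`, `G3 = ac|b` (`topology_probs()`). Only two
free quantities survive, so the three parameters `(γ, C_T, C_S)` lie on a
ridge: given observed frequencies, every γ in
`(P(G2)−P(G3), 1−(P(G1)−P(G3)))` fits exactly (`gamma_bounds_mpl()`), and
the expressions carry no trace of the scenario label. `triple_profile()`
exhibits this directly: the profile log-likelihood over γ is flat on the
plug-in interval, and the maximized value is identical whichever scenario
label is attached. A point estimate from such a method is an arbitrary draw
from the ridge, which is how the package emulates the dispersed estimates a
pseudo-likelihood network search reports.

Site patterns behave the same way. Under an infinite-sites model with a
common θ the per-site frequencies of the polarized biallelic patterns obey
`f(BBAA) = (1−γ)l_T + f(BABA)` and `f(ABBA) = γ l_S + f(BABA)`
(`site_pattern_freqs()`), so `BABA` is the rarest pattern in *all three*
scenarios. A HyDe-style test therefore always identifies B as the hybrid —
correct for inflow, wrong for ghost introgression and outflow — and its
γ estimator has expectation `1/(1 + (1/γ−1) C_T/C_S)`
(`gamma_hyde_expected()`): unbiased only when `C_T = C_S`, otherwise pushed
towards 0 or 1. Detectability is governed by
`min{(1−γ)l_T, γl_S}` (`hyde_detectability()`).

## What branch lengths add

The joint density of (topology, first coalescence `t1`, root age `t2`) is
assembled by enumerating the recipient path (probability γ vs 1−γ), the
epoch structure of the populations, and which pair coalesces first; within
an epoch each co-resident pair coalesces at rate `2/θ`. Everything reduces
to piecewise-constant hazards on the break grid
`{τ_H, τ_T, τ_R, (τ_G), τ_O}`, evaluated in log space with half-open
`[start, end)` segments (`joint_density()`, `msci_loglik()`). The pairwise
marginals (`pairwise_density()`) are mixtures of piecewise-exponential
components whose support minima order differently by scenario —
`min(t_ab) < min(t_ac) = min(t_bc)` for GHOST,
`min(t_bc) < min(t_ab) < min(t_ac)` for INFLOW,
`min(t_bc) < min(t_ab) = min(t_ac)` for OUTFLOW — while the pair not
involving the recipient keeps a single smooth shifted-exponential component.
These differences are what `msci_fit()`/`msci_select()` exploit: with exact
gene trees the true scenario wins by hundreds of log-likelihood units at
the settings studied here, and γ, τ_T, τ_R, τ_S and θ are recovered.

The densities were derived from the model structure (the itinerary
enumeration is forced by the MSci process) and validated against the
simulator by quadrature identities and Kolmogorov–Smirnov tests rather than
against any printed formula.

## The simulator

`simulate_gene_trees()` is an event-driven coalescent simulator on the
species network (any number of sequences per ingroup species, one outgroup
sequence); introgression is lineage-level — each recipient lineage present
at `τ_H` flips an independent γ-coin, matching the semantics of standard
coalescent simulators' population-splitting events. `simulate_triples()` is
a vectorized sampler of `(topology, t1, t2)` for the one-sequence case used
for large locus counts; the two are cross-checked against each other and
against the closed forms. Sequences evolve by HKY (or JC69) via
`phangorn::simSeq()` with branch lengths in expected substitutions per
site. Defaults mirror the simulation study the package reproduces: 1000
loci of 1000 bp, θ = 0.036 for every population, outgroup 5 coalescent
units above the root, ghost stem 1.5 CU, and HKY with equal base
frequencies. The study source does not state the transition/transversion
setting used downstream of the coalescent, so κ defaults to 1
(transition:transversion = 0.5, the Seq-Gen-style default) and is
configurable and recorded in the dataset manifest.

The grid parameterization (`msci_from_grid()`) fixes the sister divergence
at 1.5 CU from the present and reads `C1` as the introgression time from
the present and `C2` as `C_T`, which reproduces the published grid
settings, including the direction of every reported γ bias (overestimation
for inflow, over- or under-estimation for outflow depending on
`(C1, C2)`, near-unbiasedness when the two internal branches match). One
published figure caption places the ghost-attachment time below the ingroup
root, which is geometrically impossible for an outgroup ghost; the package
keeps the ghost join strictly above the root (1.5 CU in the grids) and
places the density discontinuities at `{τ_T, τ_R, τ_G}`. The illustration
presets (`scenario_presets()`) follow the same resolution.

What the generator deliberately does not emulate: recombination within
loci, rate heterogeneity among sites and lineages (no clock violations),
indels, and sequencing error. Passing tests therefore speak to the
identifiability structure of the MSci process itself, not to robustness
against alignment error or model misspecification in real data.

## The corrected site-pattern test

Pooling sites across loci ignores that sites within a locus share one
genealogy, which makes naive multinomial tests wildly anticonservative.
`hyde_jackknife()` therefore treats one locus as one block and normalizes
the difference between the two rarest pooled patterns by a delete-one-block
jackknife standard error. Because the identity of the two rival patterns is
itself chosen from the data, the statistic under the null is the absolute
value of an asymptotically standard normal variable; a one-sided tail on it
would reject at twice the nominal rate, so the tail is doubled. The null
calibration test (100 MSC replicates) confirms the ≈5% size. Multiple
tests are corrected by Benjamini–Hochberg (`bh_adjust()`, wrapping
`stats::p.adjust`). The hybrid call and the γ estimate follow the
hybrid-speciation reading of a significant result: parents are the two taxa
sharing the derived state in the rarest pattern, and γ is the empirical
analogue of the expectation above, oriented so that it measures the share
inherited from the non-sister parent.

## Numerical choices

* Densities are evaluated in log space; segment boundaries are half-open
  `[start, end)`; zero-rate segments contribute `-Inf` cleanly.
* `msci_fit()` optimizes on an unconstrained scale through transforms that
  enforce the time ordering and the support bounds the data imply (e.g. no
  a–b coalescence below τ_T; under OUTFLOW the root time has no such bound
  because introgressed loci can close below τ_R, so only a search cap is
  used). Multi-start: one moment-based start plus Latin-hypercube
  perturbations (8 starts by default, screened by their objective, the best
  half optimized coarsely, the winner polished at `reltol 1e-10`);
  deterministic given `seed`.
* `τ_H` under GHOST has no effect on the likelihood with one sequence per
  species (the introgressed a-lineage travels alone either way); it is held
  fixed and flagged, mirroring the non-identifiability reported for
  full-likelihood analyses of this design. Under INFLOW/OUTFLOW `τ_H`
  coincides with node S and is smoothly identified by the support of
  `t_bc`, so it is optimized freely rather than profiled on a grid.
* Per-population θ mode frees one θ per population that can host a
  coalescence in the scenario (T, R, ancestral root, plus the donor-side
  tip population where relevant); tip populations that never host a
  coalescence with one sequence per species are not estimable and share the
  ancestral value.
* `C_T`, `C_S` in `triple_profile()` are capped at 50 CU (`e^{-50} ≈ 2e-22`
  stands in for ∞); the flat region is located by bisection on the profile
  itself, not by assuming the plug-in formula.

## Problem sizes used by the test suite

The packaged tests reproduce the study's properties at desk scale, chosen
once as follows: theory–simulation agreement over nine grid cells at
10^5 loci (vectorized sampler); the γ bias law at θ = 0.0036 — the
closed forms assume infinite sites, and the small θ keeps multiple hits
negligible while the study-scale θ = 0.036 is used everywhere the claim is
directional — with 20 replicates × 1000 loci × 500 bp per `C_T/C_S` ratio;
hybrid-misdirection and null-calibration runs at θ = 0.036 with
20 × 1000 × 500 bp and 100 × 400 × 500 bp respectively; and scenario
selection with 20 replicates × 1000 loci per generating scenario at
`(C1, C2, γ) = (0.3, 0.5, 0.3)`. The grid driver (`run_grid()`) defaults to
20 replicates per cell for the same reason; the published design's 100
replicates are one argument away.

## Known limitations

* One sequence per species in all estimators (the simulator supports more);
  with multiple sequences `τ_H` would become identifiable in principle, but
  the multi-sequence likelihood is not implemented.
* Gene trees are taken as observed. Real pipelines estimate them from
  sequences with error, which degrades branch-length methods first; the
  package quantifies the information content of exact gene trees, an upper
  bound on what sequence-based full-likelihood methods can extract.
* Single introgression edge, three ingroup species, strict clock. Networks
  with several edges, more taxa, or post-introgression divergence are out
  of scope.
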