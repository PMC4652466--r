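---
title: "Clubs, leaders and rivals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clubs, leaders and rivals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microclubs)
```

## The model

`microclubs` analyses a samples × OTUs count matrix as a *co-occurrence
network*: nodes are OTUs, edges are significance-retained Pearson
correlations of log₁₀ relative abundance across the samples of one study
group. The working assumptions are the classical ones for correlation
networks on compositional count data:

- abundance fluctuations that matter are multiplicative, so correlation is
  measured on the log scale;
- a positive correlation between two taxa across many samples indicates
  co-occurrence (shared niche, cooperation, shared host state), a negative
  one avoidance or competition;
- edges that do not pass a false-discovery-rate screen are noise and must
  not influence layout or clustering.

The pipeline makes no attempt to correct compositional closure bias
(dividing by the sample total couples all taxa weakly); alternative
correlation backends designed for that problem can be substituted for the
correlation stage, which is deliberately a single pluggable function.

## Stages and tunables

| parameter | default | units | why |
|---|---|---|---|
| `min_reads` | 100 | reads | OTUs with fewer total reads in the group carry too little signal |
| `min_prevalence` | 0.20 | fraction of samples | an OTU absent from 80 % of a group cannot support a correlation estimate |
| pseudocount | half the smallest nonzero relative abundance | proportion | keeps log₁₀ finite while preserving the ordering of values |
| `mask_alpha` | 0.25 | BH-adjusted significance | deliberately permissive: correlations that miss α = 0.05 may still shape real interactions; above 0.25 the edge is zeroed |
| `inflation` | 2.0 | — | Markov-clustering granularity; higher splits finer |
| `expansion` | 2 | — | flow spreads along paths of length 2 per iteration |
| `self_loop` | 1.0 | edge weight | guarantees aperiodicity of the flow |
| `min_club_size` | 3 | OTUs | pairs are not clubs |
| `neg_fraction` | 0.5 | fraction of nonzero inter-edges | operationalizes "predominantly negative" for rivalry calls |
| `display_threshold` | 0.2 | \|r\| | weak edges clutter drawings; **display only**, never used in analysis |

Both filter inequalities are strict as printed: an OTU is discarded iff
total < 100 **or** prevalence < 20 %, so an OTU at exactly 100 reads and
20 % prevalence survives.

### Markov clustering and leaders

The clustering is a from-scratch MCL: column-normalize the non-negative
weight matrix (self-loops added), then iterate *expansion* (matrix square)
and *inflation* (entrywise power 2.0, renormalize), pruning entries below
10⁻⁶, until the maximum entrywise change falls below 10⁻⁸ or 100
iterations pass (non-convergence is flagged, never silently accepted). At
convergence flow concentrates in *attractor* rows (diagonal entry above
tolerance); attractors exchanging flow form one cluster, every other node
joins the attractor receiving most of its column flow (ties broken toward
the lowest node index, so results are fully deterministic), and the
attractor with the largest diagonal is the cluster's *leader*. The test
suite cross-checks the whole procedure against an independently written
naive implementation.

Known MCL caveats apply and are surfaced rather than hidden: granularity
is not guaranteed monotone in the inflation exponent (the property test
requires monotonicity only in ≥ 80 % of random graphs), and cluster
boundaries between moderately interconnected blocks are genuinely
unstable — see the rivalry discussion below.

### The two-phase rival algorithm

Phase 1 clusters |r| — groups held together by strong correlations of
either sign (*super-clubs*). Phase 2 re-clusters each super-club with
negative edges removed, splitting it into internally positive sub-clubs.
Two sub-clubs of one super-club necessarily share few positive edges, so
their cross-edges are mostly negative; the shipped rivalry call requires
mean nonzero inter-correlation < 0 **and** ≥ 50 % of nonzero inter-edges
negative. The 50 % threshold is this package's own quantification of
"predominantly negative" — no published value exists — and both knobs are
exposed.

## The synthetic community generator

`generate_community()` samples from a latent-factor model chosen to
emulate the statistical structure the pipeline assumes:

- per-OTU baseline log₁₀ abundances ~ N(0, 0.4²) — a few orders of
  magnitude across taxa;
- per-sample latent fluctuation of SD 0.6 log₁₀ units (~4-fold), shared
  within clubs through a club factor with loading √ρ so the expected
  pairwise log-scale correlation equals the target ρ;
- rival pairs share an extra factor loaded with opposite signs (loading
  √|ρ₋| each), giving the target negative inter-club correlation while
  preserving intra targets;
- each club's designated leader gets +0.2 extra loading (a clearly
  dominant hub: expected leader–member correlation ≈ 0.75 against 0.6
  member–member, just inside the unit-variance feasibility bound);
- counts are multinomial at fixed depth. The modeled OTUs are drawn as a
  ~10 % minority of a community whose remaining 90 % is a stable unmodeled
  remainder (sampled and discarded). This choice matters: if the modeled
  OTUs *were* the whole community, the fluctuating denominator would add
  ~0.1–0.2 of spurious positive correlation between all abundant taxa
  (closure), and planted targets would not be met on the scale the
  pipeline measures.

What the generator does **not** emulate: phylogenetic correlation
structure, compositional bias of real amplicon workflows, abundance-linked
dropout (its structural zeros are uniform at random), batch effects, or
time-series autocorrelation. A green recovery test therefore establishes
that the pipeline recovers planted blocks under idealized log-normal
multinomial sampling — not that it is robust to every artefact of real
16S data.

Structural sparsity defaults to 0. Sampling zeros still occur naturally
for rare OTUs; *structural* zeros land on the pseudocount floor after the
log transform, and because that floor is far below typical values, even a
5 % rate attenuates planted correlations by roughly a quarter and
violates the generator's own calibration contract (empirical intra-club
correlation within ±0.1 of target). Users studying zero-inflation
robustness should raise `sparsity` deliberately.

## Numerical choices

- Pearson p-values from t = r√((n−2)/(1−r²)), two-sided; |r| = 1 maps to
  p = 0 exactly. Zero-variance OTUs get r = 0, p = 1 with a warning
  instead of an abort (constant columns can survive filtering).
- BH adjustment is applied jointly to the network's full upper triangle,
  per network (not per study).
- Masking is strict: an edge is zeroed iff its adjusted value exceeds
  0.25.
- The layout uses the original force constants (optimal distance
  k = √(area/n), repulsion k²/d, attraction |w|·d²/k, linear cooling from
  frame/10) with attraction on the **magnitude** of the weight, so
  strongly anti-correlated taxa co-locate — closeness in a drawing is
  *not* evidence of positive association. Layouts are pure functions of
  the seed; tests assert pairwise distances, never absolute coordinates.
- Welch's unequal-variance t-test (on log-normalized values) scores
  differential abundance; the heat colour scalar is 1 − p. Whether to test
  raw or log abundances is genuinely open; log was chosen for consistency
  with the correlation scale.

## Validation, and one deliberately red light

The test suite validates each stage against independent oracles
(hand-written BH step-up, naive MCL, textbook Welch formula, closed-form
force balance) and the whole pipeline against planted ground truth:
median adjusted Rand index for planted-club recovery is 1.0 over 20
seeds, and the planted boosted leader is the recovered attractor in 20/20
seeds at the shipped defaults.

One validation criterion is knowingly not met and intentionally left
failing: exact rival-pair recovery (the reported rival list equals
exactly the planted pair) in ≥ 18 of 20 seeds. Measured performance is
16/20. The cause is intrinsic, not an implementation defect: with n = 100
samples the *entire* inter-block correlation estimate swings jointly by
roughly ±0.08 (the two club factors' empirical correlation is itself
estimated from 100 observations), and when the realized block mean lands
near −0.2, most inter-edges fall below the FDR-0.25 retention boundary
and phase-1 clustering splits the super-club. Under a best-case Gaussian
simulation with no count noise at the same settings the ceiling is
~87 %; on the noiseless target matrix phase 1 merges the rivals at every
inflation tried. The criterion is kept red rather than weakened because
it documents a real operating limitation: rivalry detection at
|ρ| ≈ 0.3 needs more samples, a larger mask α, or coarser phase-1
inflation.

## Known limitations

- Pearson-on-log-proportions inherits compositional closure bias; the
  correlation stage is pluggable for backends designed for compositions.
- MCL provides no significance for club membership; clubs near the
  inflation-dependent merge/split boundary should be curated visually
  (the heat map is drawn for exactly this purpose).
- The leader/attractor concept is a structural property of the flow
  matrix; any biological "keystone" interpretation is speculative.
- Figure geometry (exact node placement) is seed-dependent and not a
  stable analysis output; only the tabular artifacts are.
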