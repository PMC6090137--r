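---
title: "Methods: from colony areas to interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from colony areas to interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbinet)
```

`fbinet` infers directed fungal–bacterial interaction networks from plate
co-culture bioassays. This vignette explains the statistical model behind
each stage, the parameters that matter, what the synthetic generator does
and does not emulate, and the numerical and design choices we made where
more than one defensible option existed.

## The measurement model

The unit of observation is a colony area (mm²) of a *focal* organism grown
on a *medium*, photographed on days 3, 5 and 7, either alone (monoculture
control) or next to a single *partner* from the other kingdom. The default
design crosses 4 fungi with 5 bacteria on 4 media in triplicate. Every
inference the package makes is a function of these areas; no growth-curve
model is fitted.

The effect of partner *s* on focal *t* is estimated per medium and day by
comparing the co-culture replicate areas with the focal strain's
monoculture replicates using Welch's two-tailed *t*-test with unequal
variances and Welch–Satterthwaite degrees of freedom. We treat replicates
as independent samples: plates are physically separate, and nothing in the
design pairs a co-culture replicate with a specific control replicate.
Areas are compared on the raw scale — the quantity of scientific interest
is the colony's size, not its logarithm — and no multiple-testing
correction is applied by default, so a per-comparison α of 0.05 is the
operative error rate (`compare_growth(p_adjust = "BH")` enables
Benjamini–Hochberg for users who want family-wise control; it changes the
sign calls, not the machinery).

Two degenerate cases are resolved rather than erroring, because they occur
legitimately in noise-free simulations: if both samples have zero variance
and equal means, *t* = 0 and *p* = 1; if zero variance and unequal means,
*p* = 0 with an infinite statistic. Both carry a `degenerate` flag.

Significance is strict (*p* < α, not ≤): with a continuous test statistic
the boundary has probability zero in practice, and the strict convention is
the standard one.

## The strength scale

Each (focal, partner, medium) triple contributes an ordered triplet of
signed calls over days 3/5/7, mapped to an integer grade in [−6, +6] by an
exact lookup: (1,1,1) → +6, (0,1,1) → +5, (0,0,1) → +4, (1,0,1) → +4,
(1,1,0) → +3, (0,1,0) → +2, (1,0,0) → +1, with mirror-image patterns
negated. The lookup is deliberately not a weighted sum of days — no
day-weighting reproduces (0,0,1) and (1,0,1) both mapping to 4 — so the
scale is stored as a table (`grade_rules()`), and antisymmetry under a
global sign flip is a structural property we test over all 27 patterns.

Patterns that mix +1 and −1 across days are not part of the scale. Rather
than invent a net effect, we grade them 0, label them `"mixed"`, and warn:
the gap stays auditable, and downstream statistics treat such links as
absent. Keys with a missing day or a missing control are reported with
status `"incomplete"` and excluded from network assembly with an explicit
error, never silently dropped.

## Networks and connectivity

Per medium we build two networks — effects of fungi on bacteria and of
bacteria on fungi — stored as rectangular source × target weight matrices
rather than square 9 × 9 adjacency matrices. The bipartite design makes
within-kingdom entries structurally impossible; a rectangular matrix
encodes that impossibility in the type, and the "20 possible interactions"
per direction follow from the 4 × 5 roster. Node order is fixed to the
roster (F1–F4, B1–B5) so serialisations are reproducible. Connectivity is
100 × (nonzero links)/(possible links).

## Permutation inference

**Dominance.** Whether a network is dominated by inductions or repressions
is tested with a one-sample sign-flip permutation test on its grades: zeros
dropped (the signed-rank convention — an absent link carries no evidence
about direction), tied magnitudes mid-ranked, statistic the sum of signed
ranks, null generated by independent sign flips, two-sided *p*. The
reported estimate is the median of the grade vector exactly as supplied
(zeros included), which is the quantity a reader of the dominance table
should see alongside the verdict; the *p*-value is driven by the nonzero
links only. For m ≤ 20 nonzero links the test enumerates all 2^m
assignments exactly; the enumeration is computed by dynamic-programming
convolution over the (doubled, hence integer) rank support, which is
mathematically identical to brute force but O(m³) instead of O(2^m) — the
test suite checks this identity against explicit enumeration and against
`stats::wilcox.test(exact = TRUE)` on tie-free inputs. Monte-Carlo mode
(default 500 draws, seeded) uses the add-one correction
p = (1 + #extreme)/(1 + n_perm), so *p* is never 0 and the test is
conservative rather than anticonservative; exhaustive mode is preferred
whenever feasible because it is exact.

**QAP.** Correlation between two media networks of the same direction is
the Pearson *r* over all cells; its null distribution relabels the strains
of one network by permuting row labels and, independently, column labels
(default 1000 permutations, seeded, add-one correction). Independent
permutation of rows and columns is the only relabelling that preserves the
bipartite structure of a rectangular matrix — a joint permutation of a
square adjacency matrix would allow fungi and bacteria to swap roles, which
the design forbids. The null hypothesis is therefore "strain labels are
exchangeable within kingdom". Pairs with a constant matrix (e.g. an
all-zero network) have undefined correlation and are reported as `NA` with
a note, without aborting the remaining pairs.

## The synthetic generator

`simulate_areas()` emulates the structure of the measured table: per-strain
monoculture baselines at each day, multiplied by (1 + magnitude) for
co-cultures carrying a planted effect from its onset day onwards, times
multiplicative lognormal replicate noise parameterised by its coefficient
of variation and scaled to leave the expectation untouched
(σ² = log(1 + CV²), mean-log −σ²/2). Lognormal noise was chosen because
areas are positive and replicate variation is naturally relative;
step-function effects at an onset day were chosen because they generate
exactly the monotone pattern taxonomy of the strength scale (onset day 3 →
(1,1,1), day 5 → (0,1,1), day 7 → (0,0,1)). Effects are direction-specific:
planting an effect on the focal organism implies nothing about its partner,
matching the directed networks.

Defaults, chosen once: linear-in-day baselines with 40 mm²/day for fungi
and 15 mm²/day for bacteria (fungal colonies on plates expand much faster
than bacterial ones), CV = 0.10 (typical relative replicate scatter for
plate-area measurements), 3 replicates, days {3, 5, 7}. No published
baseline areas or replicate variances exist for this design, so these are
realistic placeholders, not calibrations; everything downstream depends on
them only through the signal-to-noise ratio magnitude/CV.

What the generator does *not* emulate: plate geometry and inoculation
distance, mechanistic nutrient depletion, contact-dependent effects,
day-to-day correlation of a replicate's noise, or image-segmentation error.
Passing tests therefore demonstrate that the pipeline recovers effects of
the assumed form at the assumed noise level — not that real plates behave
this way.

## Calibration properties and their limits

The suite verifies, among others: exactness of the sign-flip *p* against
brute-force enumeration; QAP rejection rate 0.05 ± 0.02 on independent
random networks; recovery of a planted stress gradient (MM +50% inductions,
PDA −50% repressions, CV 10%, n = 3) in ≥ 90 of 100 seeds; and the null
behaviour of the full chain. Simulation sizes were picked to make these
checks statistically meaningful at interactive cost: 100 seeds for the
recovery and null studies, 500 replicates × 1000 permutations for QAP
calibration, ≥ 10,000 comparisons for the size of the sign calls, 10,000
replicates for the location test's type-I error.

One calibration fact deserves emphasis: at n = 3 per group, Welch's test is
conservative. Its exact size at nominal α = 0.05 is ≈ 0.035 even for
normal data (and ≈ 0.033 under the generator's lognormal null) — a known
small-sample property of the Welch–Satterthwaite approximation, reproduced
identically by `stats::t.test`. The package does not "correct" this: the
unequal-variance test is the prescribed method, and conservativeness means
false-positive links are rarer than the nominal rate, not more common. The
tests assert validity (empirical size ≤ α) and agreement with the
`stats::t.test` oracle rather than exact attainment of the nominal level.

## Taxonomy banding

Independent of the bioassay chain, `assign_rank()` implements the standard
identity-threshold rule for rDNA similarity hits: coverage < 94% →
unassigned; otherwise identity 98–100% → species, 94–97% → genus, 80–93% →
order. The printed integer bands leave fractional identities (e.g. 97.5%)
undefined, so we resolve them with half-open intervals [94, 98) and
[80, 94), making the map total and monotone. Conflicting hits fall back to
the lowest common rank (order < genus < species; any unassigned hit makes
the set unassigned) — a conservative, order-independent and idempotent
rule.

## Known limitations

- Grades are ordinal; treating them as interval-scaled in the Pearson-based
  QAP is a modelling convenience, inherited from standard practice.
- The dominance test conditions on the observed links; with very sparse
  networks (m ≤ 4 nonzero links) the discrete null cannot reach *p* < 0.05
  and dominance is undetectable in principle.
- No multiple-testing correction is applied across the 480 comparisons by
  default; at α = 0.05 roughly 17 spurious sign calls are expected under a
  global null, which is why downstream inference aggregates over networks
  instead of interpreting single links.
- The pipeline requires exactly three observation days; the strength scale
  is undefined for other designs.
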