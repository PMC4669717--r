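---
title: "Signature-reversal drug repositioning: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal drug repositioning: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
```

## The screen

The package implements a signature-reversal screen: if a drug's treatment
profile systematically opposes the expression signature of a disease —
pushing the disease's up-regulated genes down and its down-regulated genes
up — the drug is a repositioning candidate. The pipeline has four stages:
per-cohort signature extraction, connectivity scoring against a compendium
of drug-treatment rank profiles, per-drug retention, and multi-cohort
fusion. All stages consume plain-text formats (TSV/GCT matrices, GRP tag
lists, rank-table TSVs) and are deterministic given a seed.

## Signature extraction

Expression values are log2 intensities, probes × samples, with case/control
labels. `quantile_normalize_log2()` forces every sample column onto the
mean-of-sorted-columns distribution; it is a deliberate substitute for full
RMA preprocessing — the screen's definition only requires "a normalized
log2 matrix", and background correction/median polish would not change any
downstream contract. Ties map to the mean of the target values across the
tied rank span, which keeps the operation deterministic and idempotent.

`select_signature()` performs volcano selection with the classic
pooled-variance two-sample Student *t* (df = n₁+n₂−2, two-sided *p*), not
Welch — the historical microarray convention for this screen — and no
multiple-testing correction, because the screen is defined by a raw
*P* < 10⁻⁴ cutoff and adding FDR control would change the probe counts the
thresholds were published with. Fold change is the difference of group
means on the log2 scale (a ratio of geometric means on the linear scale).
The fourfold boundary is inclusive (|Δlog2| ≥ 2); the source description
uses both "at least fourfold" and "greater than fourfold" in adjacent
sentences, and we implement the inclusive reading with
`inclusive = FALSE` available for the strict one. Degenerate probes where
both groups have zero variance get *t* = 0, *p* = 1 when the means agree
and *p* = 0 with a `degenerate` flag when they differ. Tag lists are
ordered by |t| descending purely for reporting — the KS statistic is
insensitive to tag order.

## Connectivity scoring

For tag positions `V(1) < … < V(t)` in a universe of `n` ranks,

* `a = max_j [ j/t − V(j)/n ]`, `b = max_j [ V(j)/n − (j−1)/t ]`,
* score `a` if `a > b`, else `−b`.

Both `a` and `b` are non-negative by construction (the `j = t` term of `a`
and the `j = 1` term of `b` are ≥ 0), so an exactly zero score is
impossible and the null distribution of the score is mildly asymmetric —
near `a ≈ b` ties resolve to the negative branch. Two consequences we
verified and document rather than "fix":

* **Reversal is antisymmetric only up to the rank grid.** Reversing a
  ranking maps `(a, b)` to `(b − 1/n, a + 1/n)` exactly; the score negates
  up to −1/n except in the O(1/n) band `0 ≤ b − a ≤ 2/n`, where both a
  profile and its reversal score negative. The property tests assert the
  exact `(a, b)` relation, not a false exact antisymmetry.
* **"p ≥ 0.5 for a zero observation" presumes a symmetric null**, which
  the enumerated subset null is not; the contract holds for any symmetric
  null supplied explicitly and is tested that way.

Per instance, `ES = KS_up − KS_down` when the two sides disagree in sign,
else 0; one-sided signatures use the surviving side. Instance ES values are
scaled into [−1, 1] by dividing positives by the largest positive ES and
negatives by |smallest negative ES|, so each present side pins its extreme
to ±1.

### Ordering ties and the drug-level null

Drug-level enrichment is the same KS statistic applied to a drug's instance
positions within the instance list ordered by scaled score. Under a null
compendium roughly **half of all instances score exactly ES = 0** (the
same-sign rule), so the handling of ties in that ordering matters. Breaking
ties lexicographically by instance id — superficially the most
deterministic choice — is wrong here: instance ids encode the drug, so all
of a drug's tied instances become adjacent, every drug's positions cluster,
and the measured null hit rate triples. We instead assign each instance id
a tie-break key drawn once from a seeded uniform stream (keys assigned in
lexicographic id order), which restores exact exchangeability of tied
instances while remaining deterministic in the query seed and invariant to
the input order of instances.

The drug *p*-value null is the natural exchangeability null — the drug's
`t` instances occupy a uniformly random `t`-subset of the `n` positions —
one-sided in the observed direction because the retention rule conditions
on the sign first (hit ⇔ enrichment < 0 and *p* < 0.05). Exact enumeration
is used when `C(n,t) ≤ 10⁶`; otherwise seeded Monte Carlo with
`p = (1 + #extreme)/(n_perm + 1)`. Within one query, drugs sharing the same
`(n, t)` reuse one null sample: the null depends only on `(n, t)`, so this
is statistically identical to per-drug sampling and an order of magnitude
cheaper. The source publication never defines the null behind its reported
drug *p*-values; ours is declared, not inferred.

## Fusion

"Fusion" is the union of per-cohort hit lists — the screen retained drugs
found by *any* cohort, explicitly not the intersection — with per-drug
support counts and exact-membership Venn region sizes over all non-empty
cohort subsets. Drug names are lower-cased and trimmed before set
operations. The packaged category map assigns the screen's experimentally
validated drugs to six functional groups; unmapped drugs are `unknown`.

## The synthetic world

`make_cohort()` draws a per-probe baseline from Uniform(4, 12) log2 units
(the usual dynamic range of log2 intensities) and adds Normal(0, σ) noise
per sample; case samples get ±`effect_log2` on the planted probes.
Defaults — 2000 probes, 100 + 100 planted, effect 3.0 log2, σ = 0.3,
20 case / 10 control — keep the planted *t* statistics far past the screen
thresholds while leaving the null probes honestly null, and mirror the
roughly 2:1 tumor:normal imbalance of real cohorts at desk scale (2000
probes scaled down from 22,283 so exact enumeration and the full test
suite stay under a minute).

`make_compendium()` builds rank profiles from latent Normal(0, 1) values:
reverser instances subtract their strength on the planted up probes and add
it on the planted down probes (mimickers mirror this), and the profile is
the descending order of the latents. Only ranks are generated because the
connectivity stage consumes nothing else. Defaults: 40 drugs × 5 instances
with the first four drugs as reversers at strength 2.0.

What a green test does **not** establish: the generator has no probe-level
intensity artifacts, batch effects, dose–response structure, correlated
genes, or cell-line stratification, and the quantile substitute is not RMA
— so recovery rates here bound nothing about a specific reprocessing of
the original cohorts.

Seeding: every generator is a pure function of its seed via a local-RNG
wrapper (the caller's RNG state is untouched). The pipeline fans one base
seed out by a fixed scheme, `(seed mod 10⁶)·1000 + offset + index` with
offsets 100/500/600 for cohorts/compendium/query, keeping all derived seeds
below 2³¹.

## Numerical and degenerate-input choices

* Signature tags absent from the compendium universe are dropped and
  counted (mirroring platform restriction), erroring only if a required
  side empties.
* An empty signature is a warning, not an error; the pipeline then skips
  the query and records zero hits for that cohort.
* A single-drug compendium scores enrichment −1/n and can never reach
  *p* < 0.05.
* `p_drug = 0` yields an empty screen rather than an error.
* Report files are written with 17 significant digits so round trips and
  re-runs are byte-identical; manifests carry no timestamps.

## Known limitations

GEO accession fetching, RMA itself, dose/cell-line-stratified queries,
weighted (GSEA-style) enrichment variants, and reproduction of the original
service's numbers are out of scope. The 215-drug published fusion count is
tied to a specific compendium version and is not a test target; the
acceptance burden is carried by the property-based suite.
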