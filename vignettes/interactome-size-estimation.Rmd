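---
title: "Estimating interactome size from LC/HT dataset overlap"
author: "interactomeSize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating interactome size from LC/HT dataset overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interactomeSize)
```

## The estimation problem

Interaction datasets are incomplete samples of an unknown population: the
set of all `N` genuine binary physical protein–protein interactions of an
organism. Capture–recapture logic applies: if a literature-curated (LC)
sample of `m` true interactions and a high-throughput (HT) sample of `n`
true interactions were drawn *independently*, their overlap `k` would
follow a hypergeometric law `H(N, m, n)`, and matching `k` to its mean
`n·m/N` yields the Lincoln–Petersen estimator `N̂ = n·m/k`.

The catch is independence. Y2H — the assay behind most HT screens — is
also the single most common assay in small-scale studies, so LC data is
enriched in interactions that are *easy to find by Y2H*. HT screens find
the same easy interactions, `k` is inflated, and `N̂` is biased downward.
Two observations motivate the correction implemented here:

1. **Detectability bias is measurable.** Binning an IST-annotated screen
   (interaction sequence tags: per-interaction hit counts, a proxy for
   how readily the assay detects the pair) shows LC coverage rising with
   IST count (`ist_coverage_curve()`).
2. **Well-studied proteins escape the bias.** Proteins cited by many
   papers have been probed with labor-intensive assays (reconstituted
   complexes, biochemical activity, co-crystal structures), so their
   curated interactions sample the interactome more evenly — visible as an
   evidence-code shift (`evidence_code_enrichment()`) and as HT coverage
   of LC dropping when LC is restricted to well-studied proteins
   (`ht_coverage_vs_cutoff()`).

The estimator therefore replaces `m` with `m′`, the true positives among
LC interactions *involving a well-studied protein*, and models the
overlap as `H(N, m′, n)`.

## Error-rate accounting

None of the three counts is observed directly; each is corrected for the
dataset's error rate.

**HT true positives (per-component accounting).** For an HT dataset or
union, `n = |HT| − Σᵢ |HTᵢ|·FDRᵢ`, the union size counting shared pairs
once while each component contributes its full false-positive mass
(`ht_true_positives()`). This is the literal per-component form; no
redistribution is attempted for HT pairs confirmed in LC.

**FDR chaining.** Only one screen's FDR must be assumed (the reference,
default 0.25, swept over 0.15–0.35 by `sweep_reference_fdr()`). Every
other screen's FDR follows from the hypothesis that pre-2000 LC data
covers the same fraction of *true positives* in every screen: writing `α`
for the ratio of two screens' raw pre-2000-LC coverage proportions,
`FDR₁ = α·FDR₂ + 1 − α` (`chain_fdr()`). The pre-2000 restriction (the
publication year of the oldest genome-scale screen) removes the
"confirmation bias" of small-scale studies that retest HT hits. Rounded
coverage proportions can push `α` past `1/(1−FDR₂)`; the raw chained value
is then clamped into `[0, 1]` with a warning rather than raised, because
legitimate configurations reach the boundary through input rounding
alone.

**LC true positives.** Recuration of single-paper curated interactions
has estimated that ~35% are erroneous. Accordingly
`m′ = |LC_WS| − 0.35·|LC_WS-Unique|`, where the unique subset holds
well-studied LC interactions supported by exactly one paper and absent
from the HT dataset under consideration (`single_paper_unique()`,
`lc_ws_true_positives()`). Interactions with two papers or an HT
confirmation are taken as genuine, as is the entire HT∩LC overlap
(detected by two independent routes).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| well-studied cutoff | 125 papers | minimum citing papers for a protein to count as well-studied; sweep 100–150 |
| `ws_mode` | `"any"` | one endpoint suffices ("involving a well-studied protein"); `"both"` available |
| reference FDR | 0.25 | assumed FDR of the reference screen; every other FDR chained from it |
| LC unique FP rate | 0.35 | recuration-based error rate of single-paper, HT-absent interactions |
| pre-2000 year | 2000 | cut for the chaining restriction |
| HT-paper threshold | 100 pairs | a publication supporting strictly more pairs is high-throughput and excluded from curation |

The `"any"` default for `ws_mode` follows the singular phrasing of the
restriction ("involving a well-studied protein"); both modes are
implemented and configurable. Publication years come from a dedicated
year column when the input has one, otherwise from the `"Author (1999)"`
pattern of the source column — selectable through the loader's column
map, since curated dumps differ in where they record the year.

## Confidence intervals

The published interval for this class of estimate is described only as a
"normal approximation"; that phrase does not pin down one construction,
so two standard ones are implemented (`confint()`), both built on the
hypergeometric variance of the overlap evaluated at the point estimate,
`Var(k) = n (m′/N̂)(1 − m′/N̂)(N̂ − n)/(N̂ − 1)`:

* `transformed_overlap` (default): normal interval on `k`, transformed
  endpoint-wise through `N̂ = m′n/k`. Asymmetric — the upper arm is
  longer, matching the shape of intervals reported for such estimates.
  When the normal lower bound on `k` is non-positive the upper limit is
  reported as `Inf`.
* `delta`: first-order delta method on `N̂` itself; symmetric.

On the headline inputs (`m′ = 1922.75`, `n = 2814`, `k = 144`) the two
give 32,587–44,362 and 31,824–43,323. When LC covers every HT true
positive (`k = n`) the variance is zero and the interval collapses —
the estimator degenerates to `N̂ = m′`.

A CI on the size is *not* propagated from FDR uncertainty; the FDR's
influence is explored by sweeping instead, which is the more honest
presentation given that the reference FDR is an assumption, not an
estimate with a standard error.

## The synthetic benchmark

`generate_world()` builds ground-truth interactomes embodying exactly the
premises above, so the bias-correction claim is testable with known `N`:

* **Degree heterogeneity** via weighted pair sampling with log-normal
  per-protein weights (`degree_concentration`), rather than an explicit
  scale-free generator — the estimator's behaviour depends on sampling
  weights, not on a specific topology, and this avoids committing to one.
* **Study levels** as a Gaussian-copula, rank-correlated noisy transform
  of degree (`study_degree_correlation`, default 0.6), mapped through a
  log-normal marginal (meanlog 3, sdlog 1.2 — medians of tens of papers
  with a heavy tail, putting roughly 6% of proteins above the
  125-paper cutoff, a realistic well-studied fraction). Only a
  correlation is modelled because only a correlation is established
  empirically.
* **Detectability** per true pair, uniform by default, floored at 0.02;
  it plays the role of IST counts, and exported screens discretise it to
  pseudo-IST integers (`1 + Poisson(8·detectability)`).

`sample_ht_dataset()` captures true pairs with probability proportional
to `detectability^assay_exponent` (normalised so `capture_prob` is the
expected captured fraction) and then adds uniformly random false pairs to
hit the target FDR deterministically — so the realised FDR, attached to
the sample as an oracle label, differs from the target only by rounding.

`sample_lc_dataset()` weights capture by
`detectability^e · (mean endpoint papers + 1)^study_bias` and synthesises
per-record publications (single-paper with Poisson extras), years (a
configurable pre-2000 fraction) and evidence codes (Y2H with probability
equal to detectability, labor-intensive codes otherwise). False positives
are injected among single-paper records at a configurable rate. The
exponent `e` is the modelling crux: with `ws_assay_agnostic = TRUE` it is
scaled by the *fraction of endpoints that are not well-studied* — 0 when
both endpoints are well-studied, ½ for mixed pairs, 1 otherwise. Scrutiny
is a property of a protein, not of a pair: an interaction between a
well-studied and an obscure protein has only been probed deeply from one
side. A consequence is that the well-studied restriction (which keeps
mixed pairs under `ws_mode = "any"`) removes most but not all of the
detectability bias, so the corrected estimator lands strictly between the
naive one and the truth — mirroring the residual underestimation expected
on real data.

`recovery_experiment()` repeats world → samples → both estimator variants
over replicates and reports mean relative bias, RMSE and CI coverage. The
benchmark's default study conditions are worlds of 6,000 proteins and
20,000 true interactions with an HT screen of ~2,500 pairs at FDR 0.25
and an LC sample of ~6,000 pairs, 200 replicates — yeast-scale inputs at
which the test suite checks recovery within 3% and nominal-range CI
coverage, in minutes on one CPU.

What the benchmark does *not* emulate: real evidence-code co-occurrence
structure, protein abundance/localisation effects on assay success,
curation of the same interaction under different identifiers, or any
fitted correspondence to real yeast statistics. Passing tests show the
estimator and its bias correction behave as designed under the model's
own assumptions — not that those assumptions hold in any particular
organism's literature.

## Numerical and degenerate-input choices

* True-positive counts stay fractional throughout; rounding happens only
  in reports (sizes to integers, TPs to 2 decimals).
* `estimate_size()` refuses a zero overlap with an actionable message;
  sweep rows with zero overlap are flagged (`flagged = TRUE`, size `NA`)
  rather than failing the sweep.
* IST binning walks IST values in ascending order and never splits a tie
  group; a trailing underfull group merges into its predecessor (the
  open-ended tail bin has no principled boundary, so it absorbs).
* The degree regression excludes degree-zero proteins (log undefined),
  sorts by paper count with ties broken by protein id for determinism,
  merges a final short bin into its predecessor, and uses base-10 logs
  (the base only shifts the intercept).
* Evidence enrichment uses the chi-square two-proportion test without
  continuity correction by default (correction available by flag).
* Self-pairs are kept everywhere (curated data contains homodimers); a
  loader flag drops them. Dataset sizes always count distinct canonical
  pairs — a pair is stored once, endpoints sorted case-insensitively.

## Known limitations

* The FDR chaining rests on equal LC coverage of true positives across
  screens; screens probing systematically different interactome regions
  violate it, and the chained FDR for an assay class poorly represented
  in pre-2000 literature (e.g. PCA) is an upper bound rather than an
  estimate.
* Small overlaps make the estimate volatile; the CI widens accordingly
  but the normal approximation itself degrades below roughly `k ≈ 30`.
* The 35% single-paper FP rate is imported from one recuration study; if
  it overstates curation error the size is underestimated, linearly in
  the rate.
* Residual detectability bias among mixed pairs means even the corrected
  estimate should be read as a lower bound on `N`.
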