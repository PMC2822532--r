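---
title: "Methods: functional labels, mixture frequency laws, and splice-function networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional labels, mixture frequency laws, and splice-function networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicefun)
```

## The model

A transcriptional unit (TU) produces one or more splice-variant protein
isoforms. Each isoform carries a set of controlled-vocabulary annotation
keywords; the **functional label (FL)** of an isoform is the canonical form
of that set — unique elements, byte-wise sorted. FLs approximate protein
function: two isoforms with the same FL are treated as functionally
indistinguishable, and the diversity of FLs within a TU measures how much
alternative splicing diversifies that locus's functional output.

The central assumptions are that (i) keyword sets are a usable proxy for
molecular function, (ii) set identity — not semantic similarity — defines
functional equality, and (iii) the isoform catalogue is a representative
sample of the locus's products. None of these is innocuous: keyword
vocabularies are incomplete, annotation transfers errors from homologs,
and isoform catalogues reflect sequencing depth. The pipeline therefore
treats every downstream statistic as a property of the *annotated
catalogue*, not of biology directly.

On this representation the package computes four layers:

1. **Classification.** A TU is *monoform* if its annotated isoforms share
   a single FL, *polyform* if they realize at least two, *unannotated*
   otherwise. The headline statistic is the polyform/monoform percentage
   `100·n_poly/n_mono`, displayed at two decimals; unannotated TUs are
   excluded from it because an empty keyword set carries no information
   about functional diversity.
2. **Functional switches.** Within each polyform TU, all unordered pairs
   of annotated isoforms are compared by the Jaccard index of their
   keyword sets; a pair with index 0 (disjoint sets) is a switch
   candidate. We deliberately define candidates by *index* 0 rather than
   *distance* 0: a switch means the two isoforms share no annotated
   function at all, which is disjointness. Pairs involving an isoform
   with no keywords are skipped — the Jaccard measure is undefined
   against an empty set, and absence of annotation is not evidence of
   absence of function. The reported fraction defaults to a denominator
   of annotated TUs; `denominator = "all"` and `"polyform"` are available
   because the population of interest is a modelling choice, not a fact.
3. **Frequency laws.** Three relation histograms — FLs per TU, TUs per
   FL, SVs per TU — are summarized (totals, events/objects ratio,
   singleton count `n1` and percentage `p1`, adjusted Fisher–Pearson
   skewness) and fitted with the mixture
   `P(X=m) = s·P₁(m) + (1−s)·P₂(m)` on `m = 1..J`, `J` the maximum
   observed abundance. `P₁` is a discretized exponential (low-complexity
   body), `P₂` a generalized discrete Pareto (GDP) tail
   `f(m) = C/(m+b)^(k+1)` with `k > 0`, `b > −1`, normalized by the
   finite sum to `J`. The admissible region includes `b = 0` (standard
   Pareto) and small negative shifts; the truncation acknowledges that
   `J` is sample-size dependent, and an infinite-support mode
   (`J = Inf`, Euler–Maclaurin evaluation of the Hurwitz-zeta sum) is
   available for asymptotic work.
4. **Splice-function networks (SFNs).** The TU×FL contingency matrix
   (cells: isoforms of a TU carrying an FL) is projected onto an FL–FL
   graph: each polyform TU contributes one unit of weight to every
   unordered pair of its distinct FLs. A TU contributes each pair once
   regardless of how many isoform pairs realize it — the edge weight is
   "number of TUs shared", a count of loci, not of isoform combinations.
   Reported statistics: nodes, edges, mean degree, degree heterogeneity,
   components, and hub FLs ranked by distinct-neighbor degree (weighted
   degree exported alongside, since "number of links" is ambiguous in a
   weighted graph).

Keyword over-representation between TU groups uses the upper-tail
hypergeometric test with the TU as the counting unit (a keyword counts
once per TU however many isoforms carry it), and a modified Bonferroni
correction: multiply each raw p-value by the number of distinct keywords
present in the study set, cap at 1, report below the threshold
(default 1e−4). This correction matches the behavior of classic
term-enrichment tools built on the same test.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `breakpoint` (`fit_mixture`) | 10 | First abundance of the tail regime; SV-per-TU distributions show the body/tail change around 9–10 isoforms. Configurable per relation. |
| `threshold` (`enrich`) | 1e−4 | Adjusted-p reporting cutoff, the conventional stringency for keyword enrichment screens. |
| GDP `k`, `b` | fitted | `k+1` is the log–log slope (≈2 in the Zipf–Lotka regime); `b` shifts the head, `b=0` is the pure power law. Constraint `b > −1` keeps `(1+b)` positive. |
| `method` (fits) | `"ls"` | Least squares on raw frequencies emulates a curve-fitting workflow on plotted histogram points and is the default for descriptive tables; `"mle"` (multinomial likelihood, Wald errors) is the statistically efficient choice and is used in all parameter-recovery work, where least-squares standard errors would be miscalibrated. |
| `include_isolated` (`build_sfn`) | `FALSE` | Whether degree-0 catalogue FLs join the graph; published node counts may or may not include the single-node aggregates, so both are one flag apart. |
| `scope` (`build_catalogue`) | — | Any organism mnemonic; FL ids are `FL{scope}{n}`. |

## FL identifier assignment

Catalogue ids are assigned in lexicographic order of the canonical keyword
tuples, 1-based, no padding. Published FL numberings from the original
curated datasets cannot be reproduced because their sort key is not
recorded; lexicographic order is the deterministic choice — permuting the
input protein order provably yields the identical catalogue, which the
test suite asserts. Keywords are opaque, case-sensitive strings: the
package never normalizes case, since collapsing vocabulary variants is an
upstream curation decision, not an algorithmic one.

## The synthetic-data generator

`generate_organism()` emulates what the analysis consumes: a curated
mammalian isoform protein set. Its defaults are the study conditions of
the human catalogue that anchors the pipeline's reference statistics:

* polyform target 0.127 among annotated TUs and 30% unannotated TUs
  (roughly 70% of proteins attributable to keywords);
* SV counts per TU from the mixture with body weight `s = 0.985`, body
  rate `exp_b = 0.49`, tail `k = 4.16`, `b = 8.75`, breakpoint 10,
  `J = 73` — the human-scale parameterization of the SV–TU relation;
* distinct-FL counts per TU from a truncated discretized exponential on
  `2..9` (cap 9, the maximum observed FLs per TU) with rate 2.0, chosen
  once so the mean FLs per TU lands near the observed 1.15 at the target
  polyform fraction;
* FL identities drawn from a pool of `n_tus/4` labels with Zipf weights
  `w_i ∝ 1/i`, which yields the heavy-tailed TUs-per-FL relation with
  frequency slope ≈ 2; keyword sets are random sorted vocabulary subsets
  (mean size 3 over a 400-keyword vocabulary), kept distinct across pool
  entries so FL identity is well defined.

SV counts are drawn i.i.d. from the mixture and then *assigned* to TUs so
that every TU has at least as many isoforms as distinct FLs: processing
FL demands from high to low, each TU receives a uniformly random
still-unassigned SV count among those large enough. This preserves the
drawn SV marginal exactly (the empirical Kolmogorov–Smirnov distance to
the configured mixture stays below 0.02 at 2·10⁴ TUs) while satisfying
the combinatorial constraint; infeasible demands are demoted rather than
resampled upward, so the SV law is never distorted toward the tail.

What the generator does **not** emulate: keyword semantics (labels are
arbitrary subsets, so switch candidates are far more frequent than in
real annotations, where related isoforms share vocabulary); correlations
between a TU's FL identities (real polyform TUs combine *related*
functions); cross-organism homology (each simulated organism is
independent, so catalogue intersections of simulated organisms are near
empty); and annotation noise. Passing tests on synthetic data therefore
demonstrate algorithmic correctness and parameter recovery, not that real
proteomes follow these laws.

`fixture_dataset()` and `fixture_histogram()` build *exact* degenerate
objects whose marginals equal specified counts — class counts for
percentage checks, `(total_events, total_objects, n1, J)` for descriptive
rows, with remaining objects spread over two adjacent interior abundances
to match the event total exactly. The descriptive statistics under test
depend only on those marginals, so exactness is the point; the interior
spread is otherwise arbitrary.

## Numerical choices

* **GDP normalization** uses the finite sum to `J`; the stored constant
  satisfies `|Σ C/(m+b)^(k+1) − 1| < 1e−12` by construction. The
  `J = Inf` mode sums 10⁴ head terms plus an Euler–Maclaurin tail, which
  agrees with the Riemann zeta function to better than 1e−8 at `b = 0`.
* **Fit start values** come from log-linear (exponential) or log–log
  (GDP) regressions of the nonzero frequencies; least-squares fits use
  Levenberg–Marquardt with box constraints `k ≥ 1e−8`, `b ≥ −1+1e−8`,
  `b_exp ≥ 1e−9`. A fitted exponential rate at the zero boundary (flat
  data) is an error, not a result.
* **Regime coupling.** Within a fitted range the GDP model is
  renormalized over that range and scaled by the object count observed
  there, so only shape parameters are free and noiseless model curves are
  recovered to machine precision (the suite checks ≥4–6 significant
  digits).
* **Mixture weight** `s` is the fraction of objects below the breakpoint
  — the quantity the two-regime split actually identifies. Joint EM
  estimation is a possible extension but would estimate a different
  object: the published procedure fits the regimes separately.
* **Tail degeneracy.** A tail regime with fewer than 2 support points
  yields an absent (`NULL`/`NAN`) tail component and `s ≈ 1`, the
  expected outcome for a wholly exponential distribution; exactly 2
  support points fall back to the standard Pareto, which is identifiable
  there.
* **Ties** in keyword and hub rankings break lexicographically; all sorts
  use byte-wise (`radix`) order so results are locale-independent.
* **Skewness** is the adjusted Fisher–Pearson sample skewness (type 2) of
  the object-level occurrence values, 0 by convention for constant data.
* **Degenerate inputs** error early with specific messages: empty
  histograms, two empty sets in a Jaccard comparison, breakpoints outside
  `[2, J]`, inconsistent hypergeometric margins, infeasible fixture
  specs.

## Problem sizes

The test suite and the acceptance script run at 2·10⁴ objects for
exponential and mixture recovery, 5·10⁴ for standard-Pareto recovery,
2·10⁴ TUs for generator marginals, and 10³ random parameter draws for the
normalization identity — sizes at which the recovery tolerances (3
standard errors; 10–15% relative error; ±0.05 on the mixture weight) hold
with comfortable margin while the whole suite completes in well under a
minute of fitting time.

## Known limitations

* FL equality is exact set identity; near-identical keyword sets are
  distinct FLs, inflating catalogue size where annotation is inconsistent.
* The switch test is annotation-driven: disjoint keyword sets may reflect
  incomplete annotation rather than a genuine functional switch, and the
  candidate list should be treated as a screen.
* Least-squares fits on raw frequencies weight the histogram head
  heavily; use `method = "mle"` for inference and treat LS output as
  descriptive curve parameters.
* Two-regime mixture estimation conditions on the breakpoint; it is a
  fixed design parameter, not estimated from data.
* SIF export cannot carry edge weights (the format has no attribute
  field); use GraphML when weights must survive a round trip.
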