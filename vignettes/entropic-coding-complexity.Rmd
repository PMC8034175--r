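---
title: "Entropic measures of coding-transition complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic measures of coding-transition complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gementropy)
```

## The problem

A crosswalk between two medical coding systems assigns each *source* code a
*map*: the set of candidate *target* codes that can represent it, together
with a combination structure. A GEM-style crosswalk file encodes this one
row at a time — source code, target code, and a five-digit flag whose
digits mark approximate equivalence, no-map status, combination membership,
and the scenario and choice-list identifiers of combination rows. A
*scenario* is one clinically coherent way of decomposing the source concept
into several target codes; within a scenario, each *choice list* must
contribute exactly one code. A *stand-alone* candidate translates the
source code on its own.

The question this package answers is: **how hard will each source concept
be to translate?** Hard maps need more documentation detail, invite more
coding errors, and complicate longitudinal comparisons of data recorded
under both systems.

## The model

For a map with candidates $y_1,\dots,y_m$, each padded on the right to a
common length $n$, two complementary sources of difficulty are measured in
bits.

**Alphabet entropy.** Treating the candidates as an $m \times n$ character
matrix, with $p_{ij}$ the relative frequency of symbol $i$ in column $j$,

$$H(A) = -\sum_{j=1}^{n} \sum_{i} p_{ij}\log_2 p_{ij},$$

the sum of the per-position symbol entropies. Columns in which all
candidates agree contribute nothing; a column that splits the candidates
contributes up to $\log_2 m$. $H(A)$ grows with the amount of clinical
detail a coder must resolve character by character.

**Representation entropy.** Let $m_0$ be the number of stand-alone
candidates and, for scenario $i$, let $m_{ij}$ be the size of its $j$-th
choice list. The number of valid representations of the source code is

$$v = m_0 + \sum_{i=1}^{s}\prod_{j} m_{ij}, \qquad H(B) = \log_2 v .$$

The product index runs over the choice lists of each scenario: scenarios
may differ in list count, so a single global index would be incoherent.

**Baseline.** $UR = \log_2 m$ is the uncertainty-rate of earlier work,
which sees only the candidate count. When a map has no combination rows,
$v = m_0 = m$ and $H(B) = UR$ exactly. With combinations the two diverge:
a map with $m = 16$ candidates arranged in scenarios whose products sum to
$v = 216$ has $H(B) = 7.75$ bits against $UR = 4$; a map whose 16
candidates form two fixed 8-code combinations has $v = 2$ and
$H(B) = 1$ bit. Both shapes ship as fixtures (`make_worked_map()`), with
the closed-form $v$ validated against brute-force enumeration
(`enumerate_representations()`).

A single-candidate map ($m = 1$) scores zero on all three measures: there
is no surprise about the translation.

## Interpretation conventions

Several choices are genuinely open where crosswalk conventions or the
measure definitions are silent; the package resolves them as follows.

* **Padding.** Codes are padded on the right with `~`, to the maximum
  length *within the map* (not a global constant), and the pad symbol
  counts as an ordinary alphabet symbol in $H(A)$: candidates of different
  lengths genuinely disagree about trailing positions, and that is coding
  uncertainty, not an artifact.
* **Candidates are a set.** $m$ counts *distinct* target codes; a code
  listed both stand-alone and inside a scenario is one candidate, and it is
  not counted in $m_0$ (stand-alone means *only* stand-alone). With
  distinct candidate rows, the smallest positive $H(A)$ for $m = 3$ is
  $2 \times 0.918$ bits — two 1/3-vs-2/3 columns — since a single
  non-constant column cannot keep three rows distinct.
* **$p_{ij}$ weighting.** Each candidate row carries equal weight inside
  $H(A)$; empirical code frequencies enter only at the later weighting
  stage, where they scale the normalized scores.
* **No-map codes.** Source codes flagged as having no counterpart are
  excluded from measures, normalization and summaries, and counted in the
  `n_excluded` attribute. A source code mixing no-map and mapped rows (not
  observed in real files, but possible) keeps its mapped rows with a
  warning.
* **Flag digits.** Position 4 identifies the row's scenario and position 5
  its choice list. The alternative reading — a per-row *count* of
  scenarios — is incoherent with per-row choice-list identifiers.

## Normalization, ranking, agreement

Within one mapping direction, each measure is centered and divided by its
sample standard deviation ($n-1$ denominator), yielding $Z(\alpha)$,
$Z(\beta)$, $Z(UR)$. Normalization runs across all included maps of the
direction, before any class grouping, so scores are comparable across
classes. A zero-variance measure normalizes to all zeros rather than NaN.

Optional weighting multiplies each Z score by the empirical probability of
the source concept (historical visit shares); codes absent from the
frequency table get probability zero, so complexity a facility never
encounters drops out of the rankings.

Clinical classes — chapter-level code ranges, shipped as editable YAML for
ICD-9-CM Vol. 3, ICD-9-CM diagnoses, ICD-10-CM and ICD-10-PCS — are scored
by the *sum* of each Z column over their members. Sums, not means, mirror
the ranked-bar presentation the measures are designed for: a class's total
signed deviation from average complexity. Since z-scores sum to zero over
a direction, class sums are signed gains and losses that cancel overall.

Agreement between the rankings induced by the three measures is quantified
with Kendall $\tau_b$ (tie-corrected; class-score ties are possible).
`stats::cor(method = "kendall")` provides the computation; the tests check
it against an independent pair-counting oracle and closed-form cases.
Quartiles (summaries and IQRs) use linear interpolation between order
statistics (quantile type 7).

Outliers on a chosen Z column are isolated either by absolute threshold
(strictly greater) or as the top fraction $\lceil f N \rceil$; the
published workflow isolates the top 1 %.

## The word network

Descriptions of outlier maps are lowercased and tokenized to alphabetic
words; a compact standard English stopword list (shipped, configurable),
a residual list of coding-manual filler (`other`, `unspecified`, `nec`,
`nos`, `procedure(s)`; configurable) and tokens of length ≤ 2 are dropped.
The co-occurrence window is the whole description — clinical titles are
short — and repetition within a description is not double-counted. Edge
weight is the number of descriptions containing both words.

Word salience is eigenvector centrality on the largest connected
component, computed by power iteration on the shifted adjacency matrix
$A + I$: the shift preserves the principal eigenvector while breaking the
$\pm\lambda$ symmetry of bipartite components, which would otherwise make
plain iteration oscillate. Tolerance is $10^{-8}$ on the max-norm change,
at most 1000 iterations (non-convergence is an error), scores scaled to a
maximum of 1; words outside the main component score 0. Community
detection is deliberately not computed: the graph is exported (CSV +
GraphML) for external network tools.

## The synthetic generator

`generate_crosswalk()` emits GEM-format crosswalks with recorded ground
truth so every stage is testable without downloads. Defaults emulate a
procedure-coding transition: 3–4 character numeric source codes,
7-character alphanumeric targets drawn from a 33-symbol alphabet that
omits the easily confused letters I, O and U (real procedure codes
similarly drop I and O), 5 % no-map codes, 55 %
one-to-one maps, a tail of maps up to $m = 8$, and combination structure
in 60 % of the maps large enough to support it ($m \ge 4$). These defaults
are the package's reference conditions; tests and the acceptance script
run at 150–1500 source codes, sizes chosen so the whole suite completes in
about a minute while still exercising every structure class.

One structural guarantee matters: within a generated map, the stand-alone
pool and each scenario's pool are disjoint, and choice lists within a
scenario partition its pool. Representations from different scenarios can
then never coincide, so the closed-form $v$ provably equals the number of
distinct representations — which the tests verify against exhaustive
enumeration anyway. Real GEMs *do* reuse codes across scenarios; the
worked fixtures cover that regime with structures whose representations
stay distinct (different cardinalities across scenarios), again checked
against the enumeration oracle.

All randomness flows through one seeded stream that is insulated from the
caller's RNG state; a fixed spec yields byte-identical files.

What the generator does not emulate: correlations between map structure
and clinical class, realistic description text, and the heavy skew of real
crosswalks (71 924 backward-procedure codes, 96 % one-to-one). Passing
tests therefore demonstrate correctness of the measures and pipeline
mechanics, not distributional claims about any particular real transition.

## Degenerate inputs and numerical notes

* `0 log 0` is taken as 0 throughout; all logarithms are base 2.
* Measures are undefined at $m = 0$ and raise an error if forced;
  `compute_measures()` excludes such maps up front.
* Enumeration aborts beyond a configurable cap ($10^6$ representations by
  default); the closed form has no cap.
* `normalize_measures()` requires at least two records; `tau_matrix()`
  returns NA off-diagonals when a score column is constant (all-tied
  rankings leave $\tau_b$ undefined, 0/0).
* Duplicate crosswalk rows are dropped and counted; same source/target
  pairs with different flags are kept with a warning (they are distinct
  combination rows in real files).

## Limitations

The measures quantify *structural* translation complexity only. They do
not see documentation quality, coder experience, or guideline conventions,
and a high-entropy map may be routine for a specialist. Rankings from
$H(A)$ and $H(B)$ can legitimately disagree — maps with high alphabet
variation but a single valid combination, or many combinations of nearly
identical codes — and such divergences are exactly the concepts the
workflow suggests auditing manually. Validation against real transition
outcomes (error rates, denials) requires data this package does not
include.
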