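---
title: "IPOWA-CRITIC: attitude-weighted criterion importance for multicriteria ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IPOWA-CRITIC: attitude-weighted criterion importance for multicriteria ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critowa)
```

## The problem

A decision-maker must rank a set of alternatives — here, greenhouse tomato
production strategies combining shading systems, grafting and irrigation
regimes — on several incommensurable criteria: production, profit, water
consumption, CO~2~ fixation, labor, fruit maturity and nutritional
composition. CRITIC (CRiteria Importance Through Inter-criteria
Correlation) derives *objective* criterion weights from the decision matrix
itself: a criterion matters more when it discriminates strongly between
alternatives (high dispersion of its normalized column, the *contrast
intensity*) and when it disagrees with the other criteria (low
correlation, the *conflict*), since a criterion that merely repeats others
adds little information.

Classic CRITIC treats every alternative identically. This package
generalizes both halves of the weight with ordered weighted averaging
(OWA): a positional weight vector $\omega$ over ranks lets the
decision-maker over- or under-weight the contributions of the
best-performing alternatives (the *attitudinal character*), an induced
variable reorders contributions by each alternative's overall closeness to
the ideal rather than by raw magnitude, and a per-alternative probability
vector $v$ — here, expert confidence that a strategy would actually be
deployed commercially — is blended in with a coefficient
$\delta \in [0, 1]$.

## Operators

For arguments $a_1,\dots,a_n$, positional weights $\omega$, probabilities
$v$, inducing values $u$ and blend $\delta$:

* **OWA**: $\sum_j \omega_j b_j$ with $b_j$ the $j$-th largest argument.
* **POWA**: the probabilities travel with their arguments under the sort
  and the applied weight at rank $j$ is
  $\hat v_j = \delta\,\omega_j + (1-\delta)\,v_{\sigma(j)}$.
* **IOWA**: arguments are reordered by $u$ descending instead of by their
  own size.
* **IPOWA**: both — reorder by $u$, blend with the travelling
  probabilities.

All four are bounded by the extreme arguments, idempotent, and invariant
under joint permutation of $(a, u, v)$. Descending sorts are *stable*:
tied values keep their original order, so results are reproducible and
rank vectors are always permutations.

## Weighted correlation

The conflict half of the CRITIC weight needs a correlation operator that
accepts the same positional/probabilistic machinery. Writing
$d_i = (a_i - \mu_a)(b_i - \mu_b)$, $k_i = (a_i - \mu_a)^2$,
$h_i = (b_i - \mu_b)^2$, the package computes

$$ r \;=\; \frac{\sum_j \hat v_j\, d_{\sigma(j)}}
  {\sqrt{\sum_j \hat v_j\, k_{\sigma(j)}\;\sum_j \hat v_j\, h_{\sigma(j)}}} $$

with **one shared ordering** $\sigma$ coupling all three sums:
descending by the cross-product terms $d_i$ for `pearson_owa()` and
`pearson_powa()`, and descending by the induced variable $u$ for
`pearson_ipowa()`. The shared coupling is a deliberate design choice, not
a notational convenience: if each sum were sorted independently, the
weighted Cauchy–Schwarz inequality no longer applies and the "correlation"
can leave $[-1, 1]$ by an arbitrary margin (e.g. centered samples
$a = (3, -1, -2)$, $b = (-2, -1, 3)$ with $\omega = (0, 0, 1)$ give
$r = -6$), and uniform positional weights would no longer collapse the
operator to the classical Pearson coefficient, because the numerator would
no longer be a sum over paired samples. With the shared coupling both
properties hold identically: uniform $\omega$ (and $\delta = 1$, plain
means) recovers textbook Pearson to machine precision, and
$|r| \le 1$ for any valid weights — both are property-tested on a thousand
random instances.

The centering means $\mu_a, \mu_b$ are arithmetic by default
(`moment_spec(mean_mode = "plain")`). Setting `mean_mode = "owa"` replaces
selected centers by the OWA aggregate of the sample; the integer `case`
(1–16) enumerates which of the four centers (numerator $a$ and $b$,
denominator $a$, denominator $b$) switch, with case 1 all-OWA and case 16
all-plain. Mixed cases intentionally break the numerator/denominator
coupling and may leave $[-1, 1]$; the magnitude bound is only guaranteed
for the consistent cases (1 and 16), which is what the pipeline uses.

Degenerate input (a constant sample, hence zero weighted variance) is an
error by default; `zero_variance = "zero"` maps the correlation to 0
instead, reading a constant criterion as conflict-free — useful when
screening synthetic data in bulk.

## The pipeline

`run_pipeline()` executes, in order:

1. **Normalize** (`normalize_matrix()`): min–max closeness to the ideal,
   $x_{ij} = (m_{ij} - \min_j)/(\max_j - \min_j)$ for benefit criteria and
   the mirrored form for cost criteria, so every column spans $[0, 1]$
   with 1 ideal. A constant column is an error naming the criterion. The
   row totals $u_i = \sum_j x_{ij}$ become the inducing variable: an
   alternative close to ideal on many criteria induces a high rank.
2. **Dispersion** (`dispersion_vector()`): per-criterion OWA standard
   deviation $\sqrt{\sum_h \omega_h X_{(h)j}}$ over squared deviations
   sorted by size (default), or — `sd_ordering = "induced"` — sorted by
   $u_i$ and blended with the probabilities at $\delta$.
3. **Conflict** (`conflict_matrix()`): all pairwise `pearson_ipowa()`
   correlations of the normalized columns, induced by $u$, probabilities
   blended at $\delta$. Symmetric, unit diagonal.
4. **Information** (`information_content()`):
   $C_j = \mathrm{sd}_j \sum_k (1 - r_{jk})$.
5. **Weights** (`criterion_weights()`): $\omega_j = C_j / \sum_k C_k$.
6. **Scores and ranks**: four rules that differ only in what gets sorted
   before the weighted sum —

   | rule | weights | row scores |
   |---|---|---|
   | `ipowa_critic` | criterion order | criterion order |
   | `s` | criterion order | sorted descending |
   | `w` | sorted descending | criterion order |
   | `sw` | sorted descending | sorted descending |

   The `sw` rule pairs the sorted sequences rank-to-rank, which by the
   rearrangement inequality is the maximum over all pairings, so
   `sw` scores dominate the plain weighted sum row by row (tested).
   `rank_alternatives()` assigns rank 1 to the highest score, stable on
   ties.

Passing `weights =` to `run_pipeline()` scores with a supplied criterion
weight vector instead of the derived one — the mechanism used to reproduce
a published analysis whose weight table is known while still reporting the
derived intermediate tables.

## Tunable parameters

* `delta` (dimensionless, $[0,1]$; default **0.6**): share of the
  positional-attitude component against the probability component, the
  setting of the packaged case study (60% attitude / 40% probability).
  $\delta = 1$ with uniform positional weights and plain means reduces the
  whole pipeline to classic CRITIC (tested against a direct
  implementation of the original formula).
* `positional_weights` (length $|I|$): default is the case study's
  elicited vector for 12 alternatives
  (0.200, 0.180, 0.170, 0.150, 0.130, 0.100, 0.020, then five 0.010);
  an elicited vector has no principled interpolation to other sizes, so
  any other $|I|$ requires explicit weights rather than a silent guess.
* `probabilities` / `confidences` (per alternative, $[0,1]$): explicit
  probabilities win; otherwise confidences are normalized by their sum.
  The fixture ships both columns of the original study because they are
  mutually inconsistent there (the printed probabilities are not the
  normalized confidences); the printed probabilities are the default and
  no intent is guessed.
* `renormalize`: printed weight tables often sum to 1 only after rounding
  (the fixture's probability column sums to 1.001); this flag rescales by
  the sum instead of failing. Validation tolerance is $10^{-9}$.

## Numerical choices

* Population convention throughout: weights summing to one already
  normalize every moment; no $n-1$ correction anywhere.
* All computation is done in double precision; rounding to 3 decimals
  happens only at display/CSV time (the JSON report twin keeps full
  precision).
* Stable ties everywhere (sorts and ranks), so identical inputs give
  byte-identical outputs.
* Degenerate guards: constant criterion at normalization, zero total
  information at weighting, zero weighted variance at correlation, and a
  dropped (renormalized) VIKOR term when group utility or regret is
  constant across alternatives.

## The case study and what "reproduced" means

`tomato_example()` loads twelve strategies by seven criteria (water
consumption is the one cost criterion) plus the study's aggregation
settings. Two precision caveats, both consequences of working from
published tables rather than raw data, are handled explicitly in the
test-suite rather than papered over:

* The two quality criteria are published at 2 decimals against small
  column ranges (3.18 and 0.76 in their units), so their normalized values
  carry a propagated uncertainty of up to $0.02/\mathrm{range}$ — a few
  thousandths. Comparisons against the published normalized table use that
  propagated bound per column; the five high-precision columns match
  cell-for-cell at 3 decimals.
* The published score table prints two ties that its own rank table
  resolves inconsistently: one pair in original order, one pair by
  unrounded scores. The tests assert every non-tied rank exactly and
  check that the package's full-precision scores order the unrounded-tie
  pair as published.

With the study's published criterion-weight vector injected, the plain
weighted sum and the doubly sorted rule reproduce the corresponding
published score columns within ±0.001 (the print precision), and the rank
agreement between the scoring rules reproduces the published Spearman
values (64%, 97%, 83%) to the percent.

The derived weight vector itself differs from the published one (0.095,
0.099, 0.192, 0.254, 0.094, 0.112, 0.154 versus 0.089, 0.090, 0.236,
0.274, 0.079, 0.110, 0.122): neither the published dispersion row nor the
published conflict matrix is reproducible from the published inputs under
either documented ordering, so the weight table is treated as an input for
reproduction purposes, not as a target. The published baseline rankings
(classic CRITIC, TOPSIS, VIKOR, SAW) are likewise internally inconsistent
with their stated settings; the baselines here are validated against
direct-formula oracles and properties instead.

## The synthetic generator

`generate_synthetic()` draws value columns uniformly on per-criterion
ranges (default $[0, 100]$), assigns a benefit/cost mix (default one cost
criterion among seven, mirroring the case study), and draws confidences
uniformly on $[0.05, 1]$; the emitted config uses $\delta = 0.6$ and
uniform positional weights, since the study's elicited positional vector
is meaningful only for its own 12-rank setting. It emulates the *shape*
of real decision problems — mixed directions, heterogeneous scales, a
confidence vector — but not their structure: real criteria are correlated
(that correlation is exactly what CRITIC exploits), while independent
uniform columns are nearly conflict-free on average. Passing the property
suite on synthetic data therefore demonstrates the algebraic invariants
(bounds, reductions, permutation/scale invariance, rank-permutation
validity), not predictive performance on real agronomic data.

## Problem sizes used by the test-suite

Property tests run on a few hundred random operator instances (a thousand
in the acceptance block) of dimension 2–10, and on 6×4 to 12×7 synthetic
matrices; the case-study fixture itself is 12×7. The entire suite is pure
arithmetic on small dense matrices and completes in well under a minute.

## Known limitations

* Mixed-mean correlation cases (2–15) are exposed for completeness but
  unbounded in principle; use cases 1/16 unless you know why you need a
  mixed case.
* No significance testing, Kendall's $\tau$, or robust correlation; no
  fuzzy/interval extensions; no group aggregation beyond the single
  confidence vector.
* The positional-weight default is intentionally narrow (12 alternatives);
  this is a feature, not a gap.
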