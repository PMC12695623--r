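---
title: "Connectivity screening: model, design choices, and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity screening: model, design choices, and what the synthetic tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmapscreen)
```

## The screening problem

A connectivity screen starts from a *signed signature*: the genes that go up
and the genes that go down in a cell state one would like a drug to induce
(or to avoid inducing). The compendium side is a library of *instances* —
one treatment-versus-control expression experiment per compound, dose and
cell line — each reduced to a full ranking of a common gene universe, rank 1
being the gene most up-regulated by the treatment. The screen asks, for each
compound: do my up-tags land near the top and my down-tags near the bottom
of its instances' rankings (a mimic), the reverse (an anti-mimic), or
neither (noise)?

## The statistic and the null rule

For a tag list of size $t$ with ascending rank positions
$V(1) < \dots < V(t)$ in a universe of $N$ genes,

$$a = \max_{j}\Big(\tfrac{j}{t} - \tfrac{V(j)}{N}\Big), \qquad
  b = \max_{j}\Big(\tfrac{V(j)}{N} - \tfrac{j-1}{t}\Big),$$

and the enrichment score is $a$ if $a > b$, else $-b$. This is the maximal
deviation between the empirical distribution of tag positions and the
uniform distribution, signed by which side of the ranking the tags favour.
On integer ranks both maxima are exact rationals; they are evaluated in
double precision with no tolerance, and the tie $a = b$ resolves to $-b$
(frozen and documented — the tie is measure-zero for random rankings but
must be deterministic). A useful consequence of the definitions: $b > 0$
always and $a \ge 0$ always, so the score is never exactly zero and its
sign is always well defined.

An instance's raw connectivity is $s = \mathrm{ks}_{up} - \mathrm{ks}_{down}$
**only** when the two tag lists score with opposite signs; when they agree in
sign the instance carries no coherent directional information about the
query and is declared *null* with $s = 0$. Null instances are retained: they
count toward the instance count and the denominator of the non-null ratio,
so a compound whose replicates are mostly incoherent is penalised rather
than silently cleaned up.

Raw scores are scaled onto $[-1, +1]$ per query across **all** instances of
the run (not per compound, and not per cell line): positives divide by the
largest positive raw score, negatives by the magnitude of the most negative
one. This reproduces the conventional single ±1 axis on which screen hits
are displayed, and makes "the best mimic in this run" land at exactly +1.
The cost is that scaled scores are relative to the run: adding instances can
change every scaled value. Cross-run comparisons should use raw scores.

## Compound-level statistics

- **Mean ± s.d.** of scaled scores over the compound's instances (sample
  s.d.; 0 for singletons). The spread reported alongside compound scores is
  the standard deviation across instances, and is labelled as such.
- **Permutation p-value.** The null hypothesis is "this compound's mean is
  what an arbitrary set of $n$ instances from this run would produce". $B$
  resamples of size $n$ are drawn without replacement from the pooled scaled
  scores and $p = (1 + \#\{|\bar{x}_b| \ge |\bar{x}_{obs}|\})/(B+1)$,
  two-sided and pseudo-counted so $p \in (0, 1]$. Resampling instance scores
  rather than re-labelling genes keeps the null anchored to the empirical
  score distribution of the compendium — heavy tails and the null-rule atom
  at zero are preserved exactly. Default $B = 1000$ (p floor $1/1001$,
  granular enough for BH at a few hundred compounds); a seed is mandatory.
- **FDR.** Benjamini–Hochberg step-up over the compounds' p-values
  (delegated to `stats::p.adjust`, validated against a brute-force oracle in
  the tests).
- **Non-null ratio.** Fraction of the compound's instances that are
  non-null *and* agree with the majority direction (the sign of the sum of
  non-null scores). The denominator is all instances, nulls included; the
  alternative (non-null instances only) would not distinguish a compound
  with 1 coherent instance out of 6 from one with 6 out of 6.
- **Specificity.** Connectivity to the query is only interesting if the
  compound does not connect equally well to arbitrary gene sets. Each
  background set (an unsigned, MSigDB-style list) is turned into a
  *surrogate signed query* by a seeded random halving into pseudo-up and
  pseudo-down tags, subsampled to at most the real query's $(t_{up},
  t_{down})$; each surrogate is scored and scaled over the whole run exactly
  like the real query, then averaged within each compound. Specificity is
  the fraction of surrogates whose |mean| for the compound stays *below* the
  compound's |mean| for the real query. Random halving is one of several
  defensible signing conventions (an unsigned single-list |ES| is the main
  alternative); it was chosen because it exercises the same two-sided
  statistic and null rule as the real query, so background and query scores
  are directly comparable. Sets with fewer than 5 universe-matched genes are
  dropped with a warning, and at least 20 usable sets are required for the
  exceedance fraction to have any resolution.
- **Reliability.** The composite used to rank the screen:
  $\sum_k w_k c_k$ with components $|\bar{x}|$, $1-p$, $1-\mathrm{FDR}$,
  $\min(n/n_{cap}, 1)$, non-null ratio, and specificity, equal weights by
  default. The exact combination published with the original screen lives in
  supplementary material not reproduced here, so the composite is exposed
  through `weights` and `n_cap` as configuration, not code: if the original
  formula is recovered it should be dropped in via config. The equal-weight
  default is monotone in every component, bounded in $[0,1]$, and
  property-tested for both. The instance-count cap $n_{cap} = 4$ encodes
  that a fourth replicate still adds evidence but a fortieth mostly does
  not. Note the composite is direction-blind ($|\bar{x}|$): strong
  anti-mimics rank as high as strong mimics, and the separate `direction`
  column tells them apart — in drug-repurposing practice both ends of the
  axis are actionable.

Ranking ties (identical reliability) break by $|\bar{x}|$ descending, then
compound name ascending, so reports are byte-reproducible.

## The synthetic compendium generator

The generator exists so that every stage — file I/O, scoring, aggregation,
calibration, recovery — is testable with no external download. Each instance
draws i.i.d. standard-normal latent gene scores; a mimic instance adds
$+\lambda$ to the planted up-tags and $-\lambda$ to the down-tags
(anti-mimics reversed) and the permutation is the descending sort of the
latent scores. The additive-shift design gives a graded, probit-scale handle
on enrichment strength rather than an all-or-nothing block placement; a
"hard" mode that forces tags into the extreme rank blocks exists for
boundary tests. Replicates share the compound's label and $\lambda$ but draw
independent noise.

Default geometry: 1000 genes, 200 compounds × 3 instances, $t_{up} =
t_{down} = 50$, $\lambda = 3$, 10% mimics, 5% anti-mimics, 50 background
sets of 100 genes. These are the sizes at which the calibration and recovery
properties are asserted in the test suite (the null-calibration run uses 0%
planted compounds; the recovery run uses 10% mimics and no anti-mimics,
since recall-by-reliability-rank is only meaningful when the direction-blind
ranking is not shared with planted negatives). Fractions of compounds are
realistic for a library in which a specific cell state has a limited number
of true modulators; $\lambda = 3$ puts planted tags roughly 3 noise
standard deviations from centre — strong but not block-extreme, comparable
to a clearly active compound. Background sets are uniform random draws and
may overlap the planted signature, as real curated collections would.

What the generator does **not** emulate: probe-level measurement noise,
batch and platform structure, dose–response ordering, correlated replicates,
and the long-tailed compound-effect sizes of a real compendium. Passing the
recovery tests therefore shows the pipeline's statistics are internally
correct and calibrated against its own null model — not that any particular
real-data screen will separate as cleanly.

## Numerical and reproducibility choices

- Integer ranks throughout; permutation validity (each column a permutation
  of $1..N$) is a hard load-time check, and rank-sum $N(N+1)/2$ is the
  fast invariant used in tests.
- Rank orientation is frozen as 1 = most up-regulated; readers expose
  `invert_ranks` for compendia stored the other way.
- Gene matching between query and universe is exact string equality after
  whitespace trimming and case-folding; unmatched tags drop with a logged
  warning. No ortholog or probe mapping is attempted.
- Ties in expression log-ratios and in signature log-fold-changes break by
  input order (stable sorts), never by hash order.
- One run-level seed drives everything; per-stage child seeds are derived
  deterministically from it (seed × stage label hash), so a stage can be
  re-run in isolation with the seed recorded in the run metadata JSON. Two
  runs with identical inputs and seed produce byte-identical reports — this
  is asserted, not aspired to.

## Limitations

- Scaled scores are run-relative (see above); raw scores travel.
- The permutation null treats instances as exchangeable across compounds
  and cell lines; a cell-line-stratified null is out of scope.
- The specificity estimate has resolution $1/K$ for $K$ background sets;
  with the default $K = 50$, specificity is quantised to 0.02 steps.
- The reliability composite is a documented default, not the (unpublished)
  original supplementary formula; conclusions that hinge on exact
  reliability values should be checked under alternative weights.
- The classic two-sided KS statistic is implemented deliberately; weighted
  GSEA-style running sums and LINCS-era tau/WTCS scores are different
  statistics and out of scope.
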