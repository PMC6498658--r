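---
title: "Coalitions and bipolarisation in media policy debates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalitions and bipolarisation in media policy debates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discoursenet)
```

## The problem

When a contested public-health policy — a sugar-sweetened-beverage levy, a
minimum alcohol price — is debated in the news media, stakeholders
(charities, industry bodies, government departments, campaigners) are
quoted agreeing or disagreeing with recurring arguments ("a tax would be
regressive", "taxation reduces consumption"). Coding each such attribution
yields *statements*: an actor, a concept, a binary polarity, a date. The
advocacy-coalition view of policy change holds that actors organise into
competing coalitions with shared belief systems; discourse network analysis
makes those coalitions visible by turning co-agreement patterns into a
weighted actor network and clustering it.

`discoursenet` implements this pipeline end to end: statement ingestion,
the congruence network construction, coalition detection, coalition-level
descriptive measures, and a sliding-window *bipolarisation* time series
that tracks how sharply the debate splits into two camps over time. A
synthetic debate generator with planted coalitions provides ground truth
for validating every stage.

## From statements to a network

For actor $i$ and concept $k$, mentions are aggregated to a net stance
$s_{ik} \in \{+1, -1, 0\}$: the sign of (agreements − disagreements), with
an exact tie recorded as ambivalent (0). Aggregating to a sign first is
what makes the network insensitive to how *often* an actor is quoted.

For each actor pair, the congruence count $c_{ij}$ is the number of
concepts with $s_{ik} = s_{jk} \ne 0$, and the conflict count $d_{ij}$ the
number with $s_{ik} = -s_{jk} \ne 0$. The **subtract transformation** with
**average activity normalisation** gives the tie weight

$$ w_{ij} \;=\; \frac{c_{ij} - d_{ij}}{(a_i + a_j)/2}, $$

where $a_i$ is the number of distinct concepts actor $i$ mentions (its
*activity*). Because $|c_{ij} - d_{ij}| \le \min(a_i, a_j)$, weights are
bounded in $[-1, 1]$: $+1$ means the pair agrees on every concept either
of them raises, $-1$ full opposition. A threshold $\tau$ then zeroes every
weight below it — including all net-conflict (negative) weights — keeping
only robust argumentative similarity as ties. The default $\tau = 0.4$
(inclusive) is the value used for the UK sugar-levy debate networks this
package was built around; it is configurable, and nodes that lose all
their ties are retained as isolates rather than dropped.

Two conventions are worth making explicit because the field's coding tools
leave them implicit. Ambivalent stances contribute to neither count but
*do* count towards activity by default (the actor mentioned the concept);
`count_ambivalent = FALSE` switches to the stricter reading. And
duplicate or conflicting statements by one actor on one concept are
absorbed by the sign aggregation, so statement rate never leaks into the
weights.

## Coalition detection and measures

Coalitions are detected with Girvan–Newman edge-betweenness clustering on
the binarised thresholded graph (tie present iff $w_{ij} \ge \tau$), with
the dendrogram cut at maximum modularity by default, or at a requested
number of clusters. Clustering runs unweighted because the published
descriptive measures for such networks are tie-count based and the
behaviour of weighted betweenness in the original analysis software is
undocumented; partition quality (modularity) is always evaluated on the
retained weights. Isolates are reported alongside the partition, not as
singleton coalitions — a node that survives no tie is not meaningfully a
coalition of one.

Per coalition and for the whole network, `summarise_measures()` reports:

* **size** — node counts (the full-network row counts isolates too);
* **density** — ties over the theoretical maximum $\binom{|V|}{2}$,
  binarised;
* **centralisation** — Freeman degree centralisation
  $\sum_i (d_{\max} - d_i) / ((|V|-1)(|V|-2))$, 0 for regular graphs, 1
  for a star, reported as a percentage;
* **external ratio** — per actor, extra-coalition ties over all its ties,
  averaged (unweighted) over the coalition or over the actors of one
  organisation type. Zero-tie actors have an undefined ratio; they are
  excluded from the average and counted.

A `measures.weighted`-style switch exists on the measure functions
(`weighted = TRUE`) because published tables rarely state whether tie
weights entered these statistics; the binarised form is the default.

Detected coalitions are labelled *supportive* or *sceptical* by the sign
of their members' mean stance over a caller-supplied set of reference
concepts that express support for the policy.

## Bipolarisation over time

Bipolarisation is the tendency of the network to fall into exactly two
mutually segregated coalitions. At any point it is measured as the
**maximum modularity over an ensemble of two-cluster partitions**:
eleven bisection techniques are applied (Girvan–Newman cut at $k=2$,
leading-eigenvector bisection, spectral embedding with 2-means under three
seeds, Kernighan–Lin-style greedy refinement from three random starts,
greedy agglomerative cut at 2, random-walk distance with 2-medoids, and
multilevel bisection), modularity

$$ Q = \sum_{c} \left( e_{cc} - a_c^2 \right) $$

is evaluated for each on the weighted thresholded network, and the maximum
is taken. The ensemble's exact membership is configurable; only its size
and the $k=2$ constraint follow the published analysis, whose eleven
techniques are not individually named. A member that fails on a degenerate
graph (e.g. a component structure that cannot be cut into exactly two
clusters) is skipped with a warning — the ensemble never aborts. For two
clusters $Q \le 1/2$, attained by two equal disconnected cliques.

The time series slides a window of $W$ statements (default 200, the
published window) one statement at a time over the debate, re-running the
whole pipeline per window. Each point is dated at the window's median
statement; windows slide over statements sorted by (date, article id,
input order) so tied dates are deterministic. Windows whose network has
fewer than two connected actors yield missing values, kept as gaps. A
LOESS smoother (default span 0.3, degree 1) is fitted over the *window
index* rather than calendar time, since windows are equally sized in
statements, not days; missing windows are excluded from the fit.

## The synthetic debate generator

`generate_debate()` emulates the statistical structure of a two-coalition
media debate: a supportive and a sceptical coalition (default 40 + 40
actors) plus a few intermediaries (default 6); a concept vocabulary
(default 20) in which each concept has a coalition-preferred stance (half
framed so the supportive side agrees, half the reverse, the sceptical side
always opposite); and a statement stream (default 3000 over a 19-month
range) in which each statement's actor is drawn from a skewed activity
distribution, its concept uniformly, and its stance follows the actor's
coalition polarity with probability `p_on_message` (default 0.95),
flipping otherwise. Intermediaries take either stance with equal
probability — they blur the boundary between camps rather than belonging
to both. A piecewise schedule can change `p_on_message` over time to plant
polarisation regimes, and everything is reproducible from one seed.

Actor activity uses Pareto-distributed emission weights with tail exponent
1.5 (`activity_skew`). We chose the Pareto draw over a rank-weight
(Zipf-style) multinomial deliberately: with 80-odd actors a rank-weight
scheme concentrates roughly two-fifths of all statements on the single
top-ranked actor, which is not what skewed debate participation looks
like — real debates have a handful of dominant voices (a celebrity
campaigner, a lead agency) that are large but far from a majority, and the
Pareto draw reproduces exactly that (top-actor shares around 7–17% of
statements at the defaults).

What the generator does *not* emulate: concept popularity is uniform
(real debates concentrate on a few hot concepts), there are no consensus
concepts on which both coalitions genuinely agree, article-level
correlation is minimal (articles group consecutive same-period
statements), and actors never migrate between coalitions. Passing
recovery tests on this generator therefore shows the pipeline recovers
*clean planted block structure*; it does not show robustness to the
messier dependence structure of real coded debates.

`evaluate_recovery()` scores a detected partition against the planted
coalitions by the adjusted Rand index, excluding intermediaries (which
have no planted side) and actors outside the partition (isolates).

## Numerical and design choices

* **Half-open windows** `[start, end)` everywhere, ISO-8601 dates; the
  two-period split of the sugar-levy debate defaults to 2016-01-15
  ("mid-January"), configurable.
* **Matrix ingestion** accepts labelled square CSV exports, tolerates
  numeric asymmetry up to `1e-9` (averaging the halves), zeroes the
  diagonal, and marks provenance `"unknown"` — whether such an export is
  pre- or post-threshold is generally not recorded in the file, so
  nothing downstream assumes either.
* **Ties in stance aggregation** are ambivalent by definition; ties in
  the coalition-label mean are labelled `other`.
* **Ensemble seeding**: stochastic members receive per-member seeds
  derived deterministically from one master seed, so ensembles, series
  and whole report bundles are byte-reproducible.
* **Modularity** is computed in-package as the weighted
  $\sum_c (e_{cc} - a_c^2)$ double sum (and cross-checked in the test
  suite against both a literal double-sum oracle and an independent graph
  library to `1e-12`).
* **Problem sizes**: validation uses debates of 80–90 actors with
  3000-statement streams for coalition recovery, and shortened
  260–420-statement streams (61–221 windows of 200) for sliding-window
  properties; small-instance oracle checks enumerate all bipartitions up
  to 14 nodes.

## Known limitations

The bipolarisation measure saturates on sparse windows. Any sparse graph
— including a structureless random one — admits two-cluster partitions
with modularity in the 0.40–0.45 range, and merging the fragments of a
near-empty network into two balanced groups scores close to the 0.5
ceiling. Window networks built from 200 statements are sparse, so the
measure's effective dynamic range over a noise gradient is compressed:
strongly disciplined debates separate cleanly from mixed ones, but
moderate noise levels can be indistinguishable from heavy noise. The
threshold contributes a second nonlinearity: the expected within-coalition
weight under stance-flip noise is $(2p-1)^2$ at full concept overlap,
which crosses the default $\tau = 0.4$ between discipline levels 0.8 and
0.85, so coalition structure is suppressed abruptly rather than gradually.
Interpretation of *absolute* bipolarisation levels should therefore lean
on the within-debate trend — which is how the curve is used for real
debates — rather than on comparisons across debates of different density.

Girvan–Newman's maximum-modularity cut can subdivide genuinely cohesive
coalitions when within-coalition density is modest; the $k=2$ cut and the
ensemble exist precisely to interrogate the two-camp structure directly.
Finally, nothing in the package addresses the upstream coding step —
reliability of the human coding, article selection, statement attribution
— which dominates the error budget of any real discourse network study.
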