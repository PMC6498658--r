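# discoursenet

Discourse network analysis of media policy debates in R.

When a contested policy — a sugar-sweetened-beverage levy, say — is
debated in the press, stakeholders are quoted agreeing or disagreeing with
recurring arguments. Coding those attributions yields *statements* (actor,
concept, binary stance, date, article). `discoursenet` turns a statement
table into an actor congruence network, detects advocacy coalitions,
summarises them, and tracks how sharply the debate polarises over time.
It is aimed at researchers doing media content analysis of policy debates
who want the network stage of that workflow to be scripted, seeded and
testable.

## The method

For actors *i, j* with net stances *s(i,k)* ∈ {+1, −1, ambivalent} over
concepts *k*, let *c(i,j)* count concepts with identical non-ambivalent
stances and *d(i,j)* concepts with opposing stances. The tie weight is the
subtract transformation with average activity normalisation,

    w(i,j) = (c(i,j) − d(i,j)) / ((a(i) + a(j)) / 2)  ∈  [−1, 1],

where *a(i)* is the number of distinct concepts actor *i* mentions.
Weights below a threshold τ (default 0.4, inclusive) are zeroed, retaining
only robust argumentative similarity. Coalitions are found by
Girvan–Newman edge-betweenness clustering; coalition tables report size,
density, Freeman degree centralisation and external ratio (extra-coalition
ties over all ties, averaged per coalition or stakeholder type).
*Bipolarisation* is the maximum Newman–Girvan modularity Q over an
ensemble of eleven two-cluster partitions, computed in a 200-statement
window slid one statement at a time and smoothed with LOESS.

A synthetic debate generator plants two coalitions with configurable
discipline, skewed (Pareto) actor activity and intermediaries, so every
stage can be validated against known ground truth (adjusted Rand index).

## Worked example

```r
library(discoursenet)

deb <- generate_debate(debate_config(seed = 42))   # planted 40+40+6 debate
fit <- discourse_network(deb$statements,
                         pro_concepts = pro_concepts(deb$truth), seed = 42)
fit
#> Discourse network model
#>   statements: 3000 | actors: 86 | concepts: 20
#>   threshold: 0.4 | ties kept: 1439 | isolates: 4
#>   coalitions (Girvan-Newman): 2 of sizes 42/40, Q = 0.499
#>   bipolarisation (max k = 2 modularity): 0.499

fit$measures
#>         scope size centralisation_pct density external_ratio
#>  full_network   86                7.9    0.39             NA
#>     sceptical   40               10.7    0.90              0
#>    supportive   42               12.4    0.86              0
#> isolates (reported separately): 4

evaluate_recovery(deb$truth, fit$partition)
#> [1] 1
```

The two planted coalitions are recovered exactly (ARI 1): 42 supportive
and 40 sceptical actors (four low-activity actors lost all ties at the
threshold and are reported as isolates), with dense within-coalition
blocks (density 0.86–0.90), no surviving cross-coalition ties (external
ratio 0) and bipolarisation at the theoretical two-clique ceiling of 0.5.

For real data, read a coded statement table with `read_statements()` (CSV/
TSV plus a `statement_schema()` column mapping), or an exported adjacency
matrix with `read_matrix()`; `filter_window()` splits periods;
`polarisation_series()` + `loess_smooth()` produce the temporal curve;
`run_full_analysis()` writes the whole bundle (matrices, GraphML,
partitions, measures, series, log) per period. A command-line wrapper
lives at `inst/scripts/run_analysis.R` with `generate`, `run-all` and
`network` subcommands.

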