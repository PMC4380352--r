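# relflux

Relational models from dyadic action fluxes.

relflux is for researchers in computational behavioral science — and anyone
with a log of who-did-what-to-whom (ethological records, online-game
economies, agent-based simulations) — who want to describe dyadic
relationships in the vocabulary of relational models theory (RMT):
Communal Sharing (CS), Authority Ranking (AR), Equality Matching (EM) and
Market Pricing (MP), plus the limiting null and unilateral/asocial
interactions.

## The model

Each of two agents A and B can, at any exchange, perform one of N social
actions or do nothing (∅). The ordered pair of their choices is an
*elementary interaction*; there are (N+1)² of them (9 for N=2, 16 for
N=3), exactly one being the null interaction ∅⇄∅. A *relationship* is the
set of elementary-interaction types a dyad realizes. Since doing nothing
cannot coexist with doing something, and the empty set is identified with
the null relationship, the relationship space has

&nbsp;&nbsp;&nbsp;&nbsp;2^((N+1)² − 1)

elements — 256 for two actions (the naive 2⁹ = 512 subsets collapse once
the null interaction is handled). Every relationship decomposes uniquely
into six exhaustive categories:

| category   | structure                                     | RMT   |
|------------|-----------------------------------------------|-------|
| EM         | (s, s) — alternated same-action exchange      | EM    |
| NULL       | ∅⇄∅                                           | null  |
| MP         | {(s, t), (t, s)} — both orderings realized    | MP    |
| AR         | (s, t) alone — roles not exchangeable         | AR    |
| CS         | {(s, ∅), (∅, s)} — bilateral, not alternated  | CS    |
| UNILATERAL | (s, ∅) alone                                  | asocial (special case) |

On event logs, the classifier separates the alternated categories
(EM/MP/AR) from CS with an alternation score (fraction of adjacent
direction switches) tested against a permutation null, and attributes
each event to exactly one detection using the precedence NULL, EM, MP,
AR, CS, UNILATERAL. Social units can be recovered by thresholding the
weighted interaction graph, and the log re-expressed between units so
group-level relationships (e.g. tit-for-tat retaliation between groups)
become visible.

## Worked example

A composite relationship in the style of two friends who share freely
(CS), direct/comply on a task (AR), split gas costs (EM), and sell a bike
for money (MP):

```r
library(relflux)

specs <- list(
  generator_spec("CS", "share",               n_rounds = 8, seed = 11),
  generator_spec("AR", c("direct", "comply"), n_rounds = 8, seed = 12),
  generator_spec("EM", "pay_gas",             n_rounds = 8, seed = 13),
  generator_spec("MP", c("pay", "bike"),      n_rounds = 8, seed = 14))
stream <- generate_composite(specs, seed = 15)
classify_dyad(stream)
#> <dyad_classification: A -- B, 78 events, 4 detection(s)>
#>   EM(pay_gas) [m=8, n=8, score=1.000, p=0.0004998]
#>   MP{bike, pay} [m=16, n=16, score=1.000, p=0.0009995]
#>   AR(direct by A, comply by B) [m=8, n=8, score=1.000, p=0.0004998]
#>   CS(share) [m=8, n=6, score=0.615]
```

`m` and `n` are the per-direction event counts supporting each detection,
`score` the alternation score of the relevant subsequence (1 = strict
turn-taking), and `p` its permutation p-value; CS carries no p-value
because it is defined by the *absence* of significant alternation. All 78
events are attributed, each to exactly one detection.

The same categories exist as pure set algebra, without any event log:

```r
rel <- relationship(rbind(c("X", "X"),
                          c("Y", null_action()),
                          c(null_action(), "Y")))
decompose_relationship(rel)
#> EM(X)
#> CS(Y)
```

A command-line wrapper covers the pipeline (`enumerate`, `simulate`,
`classify`, `groups`); see `inst/scripts/relflux` and `?run_cli`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline combinatorial
quantities from scratch — it enumerates the two-action
elementary-interaction set and the full relationship space with the
installed package, counts them, and writes the results as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/flux-categories.Rmd`) describes the
model and its assumptions, the classifier's parameters and their
defaults, what the synthetic generator does and does not emulate, and
known limitations (including the conservatism of the discrete permutation
test).
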