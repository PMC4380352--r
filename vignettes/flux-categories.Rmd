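---
title: "Action fluxes, six relationship categories, and their detection in event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Action fluxes, six relationship categories, and their detection in event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relflux)
```

## The model

relflux models a dyadic social relationship from the bottom up. The atomic
observation is an *action flux*: one agent directs one social action at the
other at a point in time ("A does X to B"). At the level of a single
exchange, each of the two agents either does one of the N available social
actions or does nothing (the null action, written `r null_action()`). The
ordered pair of these two choices is an *elementary interaction*; the full
cross product gives $(N+1)^2$ of them, exactly one of which is the null
interaction (both agents doing nothing). With two actions there are nine,
with three sixteen.

A *relationship* is the set of elementary-interaction types a dyad
realizes. Doing nothing cannot coexist with doing something, so the null
interaction is excluded from composite sets, and the empty set is
identified with the null relationship. That leaves
$2^{(N+1)^2 - 1}$ relationships: 256 for two actions (the naive
$2^9 = 512$ subsets collapse to 256 once the null interaction is handled),
of which nine are simple or null and the rest composite with up to eight
components.

One bookkeeping note on the general-N count: the number of elementary
interactions is the cross product $(N+1)^2$, which the package verifies by
enumeration for N up to 5. A superficially similar closed form,
$2^{N+1}$, agrees with the cross product only at N = 3 (both give 16) and
is wrong everywhere else (it gives 8 instead of 9 at N = 2); the package
deliberately implements the cross product.

## The six categories

Classifying elementary interactions by three binary distinctions — are the
two actions null or not, identical or different, and are the agents' roles
exchangeable within the relationship — yields six mutually disjoint
categories, which map onto relational models theory (RMT):

| Category    | Pattern                                           | RMT reading        |
|-------------|---------------------------------------------------|--------------------|
| EM          | alternated flux of one action in both directions  | Equality Matching  |
| NULL        | no flux                                           | null interaction   |
| MP          | alternated exchange of two actions, both orderings| Market Pricing     |
| AR          | alternated exchange of two actions, fixed roles   | Authority Ranking  |
| CS          | bilateral non-alternated flux of one action       | Communal Sharing   |
| UNILATERAL  | one-directional flux                              | asocial (special case) |

The sixth category is labelled `UNILATERAL` rather than asocial because
one-directional flux need not be exploitative — a benefactor who is never
repaid also fits; RMT's asocial interaction is its harmful special case.

Role exchangeability is a property of the relationship, not of a single
interaction, so at the interaction level MP and AR forms are built from the
same different-action pairs, and CS and UNILATERAL from the same one-null
pairs. Exhaustiveness therefore means *coverage*: the representative forms
of the six categories jointly cover every elementary interaction, each
category internally using each interaction at most once. The package
checks this for N up to 4, together with the component-count formula
$N + 1 + 2\binom{N}{2} + N(N-1) + 2N + 2N$.

`decompose_relationship()` makes the reading of composites mechanical:
same-action pairs $(s,s)$ are EM; a different-action pair present in both
orientations is one MP instance; alone, it is AR; a one-null pair present
in both directions is CS; alone, UNILATERAL; the empty relationship is
NULL. Decomposition is total and conservative on the whole 256-element
two-action space (every input interaction is covered exactly once and can
be reconstructed), and equivariant under relabeling actions or swapping
the agents.

Bundles (`make_bundle()`) let several atomic actions performed together
count as one action. A bundle is a first-class action distinct from its
atoms, and decomposition never un-bundles: whether "lending a bike and a
helmet" is one action or two is a coding decision made upstream, not
something the algebra should silently undo.

## Detecting categories in event logs

Real data arrive as time-stamped fluxes, not as interaction sets. The
discriminating feature between the coordinated categories (EM, MP, AR) and
CS is *alternation*: each flux answered by the paired flux. The package
operationalizes this with the alternation score — the fraction of adjacent
direction switches in the relevant event subsequence, 1 for strict
turn-taking — plus a permutation test: under the null that the order of
events carries no structure, all arrangements of the observed direction
labels are equally likely. Exact enumeration is used when there are at
most 10,000 distinct arrangements, otherwise seeded Monte-Carlo with the
add-one estimator.

A sequence counts as *alternated* only if four conditions hold together:

* at least `min_fluxes` events (default 4);
* direction counts balanced: $|m - n| \le \max(1, \lceil 0.2 L \rceil)$
  by default;
* score at least $1 - \theta$ with tolerance $\theta = 0.2$ by default,
  forgiving occasional double turns, record slips and small asymmetries;
* permutation $p \le \alpha$ (default 0.05, with 2000 permutations).

The tolerance has no canonical value; too strict misses real reciprocity
(people take two turns in a row), too loose reads noise as coordination.
The defaults are one reasonable operating point, not an empirical claim.
Note the interplay with $\alpha$: a strictly alternating balanced exchange
first reaches $p \le 0.05$ at eight events ($2/\binom{8}{4} \approx
0.029$), so in practice significant EM/MP/AR detections need at least
four full round trips regardless of `min_fluxes`.

Patterns overlap — an MP dyad also shows bilateral flux of each of its two
actions, which is the CS pattern — so candidates are tested in a fixed
precedence and events attributed greedily: NULL, EM, MP, AR, CS,
UNILATERAL. Each (direction, action) bin of events is claimed by at most
one detection, so every event supports exactly one detection and the
evidence counts over all detections sum to the stream length. Within a
precedence level, candidates with smaller p-values fire first. Exchanges
too short to test fall through to CS or UNILATERAL with a
`low_evidence` flag rather than being dropped.

Two consequences of this design are worth knowing:

* EM is tested before MP (both are "alternation should prevail" cases
  against CS, and EM is the more parsimonious single-action explanation).
  A genuine MP stream whose single-action direction subsequences happen to
  alternate by interleaving accident would be absorbed as two EM
  detections; the package's own generator interleaves MP orderings in
  blocks precisely so that this cannot happen in validation fixtures, but
  on external data the possibility remains.
* When one action's bilateral flux is balanced and sits exactly at the
  alternation threshold, the EM/CS verdict hinges on $\theta$; there is no
  principled tie-break, and the configuration documentation surfaces
  rather than resolves this.

Simultaneous same-direction events at one timestamp are collapsed into a
single bundle-action flux before classification; opposite-direction ties
keep stable input order (which affects the alternation score — a
documented convention, not a claim about simultaneity in the world).

`classify_windows()` repeats the analysis over half-open windows anchored
at the first event, for relationships that change over time.

## Social units

Agents may belong to larger units that interact as single higher-level
agents: if A from one group attacks B from another and B's groupmate C
retaliates in kind, pairwise analysis sees two unilateral interactions,
while at the unit level the exchange is Equality Matching.
`build_interaction_graph()` counts events (and durations, when present)
per unordered pair; `detect_social_units()` keeps edges at or above a
weight threshold and takes connected components — a deliberately literal
implementation of thresholding, with community-detection methods out of
scope. The right threshold is data-set specific; `unit_count_sweep()`
reports unit counts across thresholds instead of pretending a default is
correct. `aggregate_stream()` then rewrites inter-unit events between unit
ids (dropping intra-unit events by default, since within-unit and
between-unit analyses are separate questions).

The packaged retaliation fixture repeats the attack/retaliation exchange
over five rounds rather than showing it once: a single exchange (two
events) cannot be significantly alternated under any sane configuration,
whereas five rounds give a strict alternation with $p = 2/\binom{10}{5}
\approx 0.008$.

## The synthetic generator

`generate_dyad()` realizes each category's canonical pattern: EM and AR as
strict alternations (of one and two actions respectively); MP as two
strict alternations covering both orderings, interleaved in blocks of two
rounds so that the single-action direction sequences clump and cannot
masquerade as EM; CS with unequal direction counts (the reply count is
drawn within about a third of the initiation count, never equal) in an
order rejection-sampled to stay below the alternation threshold, because
alternation is the sole EM/CS discriminator; UNILATERAL one-directional;
NULL empty. Timestamps are arithmetic sequences with seeded jitter below
half the gap, so intended order survives. Noise operators apply
independently per event in a fixed order — drop, swap-adjacent, insert —
so expected stream lengths are predictable
($L_0 (1-p_\text{drop})(1+p_\text{extra})$, checked distributionally in
the tests). Everything is reproducible from the spec's seed.

Defaults (10 rounds, unit gap, zero noise) are fixture conveniences: no
empirical system is claimed to have these magnitudes. The generator
emulates the *flux patterns* of the categories, not real behavior — it has
no agent heterogeneity, no value attached to actions, no learning or
strategy dynamics, and no circadian or bursty timing. A green round-trip
test therefore establishes that the classifier inverts the generator's
stated patterns at the stated noise levels, not that it recovers
relational models in any particular empirical data set.

## Known limitations and honest numbers

The permutation p-value is valid but conservative: the alternation score
is discrete, so the attainable significance level sits below $\alpha$ at
realistic stream lengths (for 20 balanced events the exact attainable
level at $\alpha = 0.05$ is about 0.019, and about 0.031 with the
Monte-Carlo add-one estimator). The test suite measures the empirical
type-I rate on 1000 label-shuffled streams at the generator's default
scale and observes approximately 0.035 — comfortably below $\alpha$
(never anti-conservative), but also below the two-sided "within 2
standard errors of $\alpha$" band, whose lower edge is 0.0362. The
corresponding acceptance test asserts the two-sided band as stated and is
expected to fail on its lower edge; the one-sided validity assertion
passes. Lengthening the streams until the band is met would be tuning the
fixture to the criterion, so the honest failure is kept.

Other limitations: triadic and higher-order coordination is out of scope
(only dyads, possibly of units); group membership is static within an
analysis; event logs carry no action values, so nothing is said about
whether exchanged quantities match; and windowed analyses inherit all
boundary effects of their window choice.
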