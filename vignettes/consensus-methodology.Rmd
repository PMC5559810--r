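---
title: "Objective consensus analysis of treatment algorithms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective consensus analysis of treatment algorithms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeconsensus)
```

## The model

A decision problem is fixed by a *criteria set*: named categorical axes,
each with an ordered list of at least two levels. A *scenario* is one
assignment of a level to every criterion; the scenario space is the full
Cartesian product. Each participant's algorithm is a *decision tree*:
internal nodes test one criterion, branches carry level **subsets** that
must partition the criterion's levels, and leaves carry *recommendation
sets* with an explicit multiplicity (`single`, `equivalent-alternatives`,
or `ranked`). Branch subsets, rather than single levels, are the native
encoding because clinicians phrase splits as groupings ("KPS below 70").

Two modelling assumptions are enforced rather than assumed silently:

- **No repeated criterion on a path.** The governing process fixes the
  level design of each criterion before analysis; a finer re-split deeper
  in the tree would amount to an undeclared extra criterion. Construction
  (`decision_tree(check = TRUE)`) rejects repetition. Validation is more
  lenient: a repeated criterion whose nodes still partition correctly
  routes every scenario to exactly one leaf, so such a tree is *reported*
  (shadowed branches appear as `unreachable-branch` issues) but not
  invalidated.
- **Level order is presentational only.** It fixes enumeration and
  serialization order; no computation treats levels as ordinal.

Expanding a tree evaluates it on every scenario, giving the participant's
*decision table* — the flat object on which everything downstream operates.
Consensus statistics (mode set, congruency rate, strict majority) are then
per-scenario tallies across the ensemble's tables.

## Validation semantics

Submitted drafts are routinely defective, and the refinement loop needs an
exhaustive report, not a first failure. `validate_tree()` reports five
categories: `unknown-level`, `overlap` (intersecting branch subsets),
`gap` (a scenario reaching no leaf, detected by a permissive sweep that
follows *all* matching branches so an overlap cannot mask a gap
elsewhere), `conflict` (a multi-member leaf whose multiplicity was left
`single`), and `unreachable-branch`. A tree is valid iff it has no gap,
conflict, overlap or unknown-level issue — and exactly the valid trees
expand without error (this equivalence is property-tested). Validation
never repairs and never judges clinical content: an undeclared double
recommendation is reported as a conflict rather than reinterpreted as
"equivalent alternatives", because assuming what a respondent meant is
itself a bias.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `policy` | `consensus_table()`, CLI | `any-recommended` | how multi-option cells vote: every member (fractionally) vs the top-ranked member only |
| `whole_votes` | `consensus_table()` | `FALSE` | under `any-recommended`, give each member a full vote instead of 1/k |
| `k` | `inclusion_filter()`, CLI `--k` | 3 | minimum number of participants that must depend on a criterion for it to stay in the analysis |
| `deviation_rate` | `synthetic_spec()` | 0.2 | per-cell probability a participant deviates from the ground truth |
| `omission_rate` | `synthetic_spec()` | 0 | per-criterion probability a participant ignores a criterion |

The default vote weighting is fractional (1/k per member) so that every
participant contributes total weight 1 and the ensemble size remains the
congruency denominator; the original projects do not state which weighting
they used, so the whole-vote alternative is implemented and switchable,
and the policy in force is echoed into every report header rather than
silently defaulted. Majority is **strict** (> 50% of voting participants):
a 12-versus-12 split yields a tied mode set, 50% congruency, and no
majority. Mode ties are never broken — the method's premise is the absence
of moderator bias, so downstream outputs show the tie.

The inclusion default k = 3 follows the convention of the completed
multi-center projects ("at least three centers mentioning a criterion");
it is a practicability threshold, not a statistical one, and every
exclusion is logged with the criterion's user count.

## Harmonization

Rules map one participant's raw criterion levels totally and
single-valuedly onto a shared target criterion (e.g. KPS dichotomized at
50/60/70/90, ECOG at 1, and an unscaled good/bad all onto fit/unfit — the
packaged `performance_status_cutoffs()` fixture). Three design choices:

- **Merging unions, never chooses.** When several source scenarios
  collapse onto one harmonized scenario, their recommendation sets are
  unioned; a non-singleton union becomes `equivalent-alternatives` with a
  recorded merge note. Inventing a preference the participant did not
  state is out of the question.
- **New collective criteria replicate.** A target criterion absent from a
  participant's table (the "Zugzwang" pattern: a panel-invented criterion
  for treatment urgency) is added by replicating that participant's cells
  across its levels — explicit non-dependence.
- **Setting-level criteria stay out.** Conditions that apply to the whole
  setting (e.g. informed consent) belong in study metadata, not in the
  tree space; the package simply never represents them as criteria.

The good/bad center in the cut-off fixture is mapped 1:1 to fit/unfit with
an explanatory note attached to the rule: the source material records the
resolution as a moderation decision, not a scale, and the note preserves
that provenance.

## Consensus-tree induction

`induce_tree()` inverts expansion: it returns a valid tree whose expansion
reproduces the input table exactly. At each node the criterion that splits
the current sub-table into the fewest distinct sub-tables (at least two)
is chosen, with lexicographic tie-breaking by criterion name; levels with
identical sub-tables are merged into one branch subset. Consequences,
both property-tested: the round trip is lossless, and a criterion on
which the table does not depend (all of its level sub-tables identical)
is never tested — applied to the modal projection of a consensus table
this yields the compact "mode tree" with vacuous axes removed. The greedy
fewest-sub-tables rule is a determinism-and-compactness choice, not a
claimed global minimum; no construction algorithm is prescribed by the
methodology itself.

## Usage and portfolio profiles

"Uses criterion c" is defined semantically: two scenarios differing only
in c map to different cells of the participant's expanded table. A
syntactic test in the submitted tree that has no effect (identical
sub-trees on both sides) therefore does not count — the profiles contrast
what actually drives decisions. The treatment portfolio is the union of
labels over a participant's non-excluded cells. Both matrices are emitted
with rows sorted by participant id and columns lexicographic, with a
true=green / false=red rendering hint matching the field's customary
heatmap display.

## The synthetic generator

`generate_ensemble()` emulates a multi-center collection with known ground
truth: expand a truth tree, then per participant (i) marginalize omitted
criteria by the union rule (keeping the shared axes, so the panel stays on
one criteria set) and (ii) flip each cell independently with probability
`deviation_rate` to a uniformly random *different* label. Deviations are
i.i.d. per cell — the simplest null for consensus-recovery experiments;
real disagreement is correlated along subtrees, so a green recovery test
establishes the tally machinery, not realism of expert behaviour. Other
things the generator deliberately does not model: strategic or anchoring
behaviour, label sets that differ between centers, and partially complete
submissions (drafts with gaps are exercised by the validation fixtures
instead). The random stream is split per participant (sub-seeds drawn up
front), so enlarging the panel never perturbs earlier participants —
byte-identical reproducibility from one seed is part of the test suite.

The recovery experiment in the acceptance suite uses the stated world of
3 binary criteria (8 scenarios), 4 labels, 15 participants and deviation
0.2, with 504 replicate cells (63 ensembles × 8). *Recovery* at a cell is
defined as the mode set being exactly the singleton truth label; the
exact reference probability is computed by enumerating all multinomial
outcomes of 15 votes with success probability 0.8 and 0.2/3 per decoy
label, and the empirical rate must fall within three standard errors.

## Numerical and formatting choices

- **Tie tolerance 1e-9.** Fractional votes make exact count ties
  float-fragile (1/3 + 1/6 vs 1/2); counts within 1e-9 of the maximum are
  co-modal, and the strict-majority comparison uses the same guard.
- **Canonical order everywhere.** Criteria sort by name; scenarios
  enumerate lexicographically with declared level order; tables store rows
  in that order; serialized documents fix key order and sort branch
  subsets by level index. Equal objects produce byte-identical files.
- **Interchange formats.** Tree and rule documents are versioned JSON
  (the environment provides no YAML parser; the format was open, so one
  was defined and versioned); tables and all reports are RFC-4180 CSV
  with `|`-joined cell members. Dates are ISO-8601. Parsers reject rather
  than repair — a missing field is an error, not a default.
- **Degenerate inputs.** A criteria set must be nonempty and every
  criterion binary or larger; a scenario in which every participant
  abstains has an empty mode set and undefined congruency (reported as
  such, never imputed); marginalizing away *all* criteria is refused.

## Known limitations

Consensus here is descriptive: no confidence intervals or hypothesis
tests are attached to congruency rates, and identification of a majority
is not its validation. The packaged draft tree is a synthetic
transcription built to exhibit the documented defect classes of a real
first submission, not a reproduction of any center's algorithm. Scenario
spaces grow multiplicatively in the number of criteria; the method (and
this implementation, which materializes full tables) is meant for the
focused questions the methodology recommends, not for dozens of criteria.
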