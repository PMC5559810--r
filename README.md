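# treeconsensus

Objective consensus analysis of clinical decision trees ("patterns of
algorithms"): compare *how* different centers, experts or guideline panels
decide, not how often each treatment is given.

## The problem

For many clinical decisions no randomized evidence exists, and practice
diverges across centers. One way to measure that divergence is to collect
each participant's treatment **algorithm** as a decision tree over a set of
categorical criteria (fitness, age group, performance status, …), expand
every tree over **every permutation of the decision criteria**, and compare
the recommendations scenario by scenario. Because the comparison is a
mechanical sweep over the full Cartesian product, no moderator has to
summarize or reinterpret anybody's opinion — consensus and controversy fall
out of the tally.

For a scenario *s* (one assignment of a level to every criterion) and an
ensemble of *n* voting participants, the package computes per scenario:

- **counts** c(r, s) — vote weight for recommendation r; a participant
  recommending k equivalent options casts 1/k per option under the
  `any-recommended` policy (total weight 1), or one full vote for the
  top-ranked option under `main-recommended`;
- **mode set** — argmax_r c(r, s), reported with all ties;
- **congruency rate** — max_r c(r, s) / n, the fraction agreeing with the
  modal recommendation (reported as a percentage);
- **strict majority** — the unique r with c(r, s) > n/2, if any. An exact
  50/50 split is *no* majority.

Around that core the package provides the supporting machinery a real
multi-center collection needs: structural validation of submitted drafts
(gaps, conflicting multiple recommendations, overlapping branches),
harmonization of heterogeneous criteria (e.g. Karnofsky 50/60/70/90 and
ECOG cut-offs all mapped to a shared fit/unfit criterion), an inclusion
threshold for rarely used criteria, induction of a compact consensus tree
from the modal recommendations, criteria-usage and treatment-portfolio
profile matrices, and a reproducible synthetic-ensemble generator.

## Worked example

```r
library(treeconsensus)

cs <- criteria_set(criterion("fitness", c("fit", "unfit")),
                   criterion("age", c("<70", ">=70")))

trA <- decision_tree("A", tree_node("fitness", list(
         tree_branch("fit",   tree_leaf("chemo")),
         tree_branch("unfit", tree_leaf("BSC")))), cs)
trB <- decision_tree("B", tree_leaf("BSC"), cs)   # always best supportive care

ct <- consensus_table(list(expand_tree(trA), expand_tree(trA), expand_tree(trB)))
ct$cells
#>    age fitness n_voting  mode congruency majority
#> 1  <70     fit        3 chemo  0.6666667    chemo
#> 2  <70   unfit        3   BSC  1.0000000      BSC
#> 3 >=70     fit        3 chemo  0.6666667    chemo
#> 4 >=70   unfit        3   BSC  1.0000000      BSC

induce_tree(mode_projection(ct))
#> Decision tree of participant 'consensus-mode' (finalised 2026-09-09)
#> Criteria used: fitness
#> fitness in {fit}
#>   -> [single] chemo
#> fitness in {unfit}
#>   -> [single] BSC
```

Two of three centers give chemotherapy to fit patients (mode `chemo`,
congruency 66.7%, a strict majority); everyone agrees on best supportive
care for unfit patients (congruency 100%). The induced consensus tree
drops `age` automatically: no participant's recommendation depends on it.

Validation of a deliberately imperfect draft (shipped with the package):

```r
validate_tree(draft_tree_example())
#> Validation report for 'draft-center': NOT VALID
#>   3 issue(s): conflict=1, gap=1, overlap=1
#>   [conflict] root/fitness={fit}: leaf offers 2 recommendations (FOLFIRINOX, Gem) without declared multiplicity
#>   [overlap] root/fitness={unfit}/age: branches 1 and 2 of 'age' both capture: >=75
#>   [gap] root: no recommendation stated for scenario (age=<75, fitness=unfit)
```

## Command line

A front-end script is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ocm.R", package = "treeconsensus"))') \
    consensus tree_A.json tree_B.json --out results/ --policy any-recommended
```

Subcommands: `validate`, `harmonize` (`--rules`, `--k`), `consensus`
(`--policy`, `--whole-votes`), `profiles`, `simulate` (`--spec`, `--seed`).
Every run writes a manifest echoing the configuration and the participants'
tree-finalisation dates.

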