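# polypharm

Scoring and prioritization of multi-target kinase inhibitor candidates.

Community challenges in polypharmacology ask teams to predict single small
molecules that inhibit a panel of disease *pro-targets* (kinases whose
inhibition is therapeutic) while sparing *anti-targets* (kinases whose
inhibition worsens the phenotype or is toxic). Evaluating such challenges
requires a reproducible scoring harness: turn measured dissociation
constants (Kd) into binding calls, apply a point rubric with bonus criteria,
analyse the chemical similarity structure of the submissions, and profile
candidates with medicinal-chemistry filters. `polypharm` implements that
harness end to end for organizers, method developers and anyone who wants a
transparent re-scoring of this kind of challenge.

## What it computes

**Binding calls.** A compound *binds* a pro-target when Kd <= 10 uM and
*avoids* an anti-target when the assay shows no hit at 30 uM (Kd > 30 uM or
censored, written `>30000` in the CSV dialect). Kd in (10, 30] uM neither
binds nor avoids.

**Rubric points.** Each problem's rubric maps the number of satisfied
targets per criterion to points (e.g. 1, 3 or 9 points for binding 1, 2 or
3 of BRAF/SRC/S6K; 1-4 points for avoiding up to four anti-targets), plus
bonus criteria: novelty (max ECFP6 Tanimoto Tc < 0.4 against known
actives), patentability (< 2 reported prior-art hits), drug-likeness (>= 3
of the 4 Lipinski rules: MW <= 500, cLogP <= 5, HBD <= 5, HBA <= 10) and -
where the rubric includes it - predicted CNS penetration (TPSA < 75 A^2).
Anti-target avoidance earns points only when at least one pro-target is
bound. The final team score is P1 + P2 + 1 bonus point for interactome
participation.

**Similarity analyses.** 1024-bit path-based hashed fingerprints feed
pairwise Tanimoto matrices, duplicate detection among top-ranked
submissions (by canonical structure identity), thresholded similarity
networks (edges kept at Tc >= 0.4) with connected-component subclusters,
and cross-team similar-pair reports (Tc > 0.5, strict).

**ADME composite.** Six published rule sets (Lipinski, Ghose, Veber, Egan,
Muegge, lead-likeness) and two structural-alert catalogs (PAINS, 480
patterns; Brenk, 105 patterns) yield an eight-category composite score:
one point per category with zero violations/alerts, so 8 = cleanest.

**Activity classes.** pIC50 labeling - inactive (pIC50 < 5), weak
(5 <= pIC50 < 6), potent (pIC50 >= 6) - with class distributions and
deterministic hold-out splits.

**Synthetic data.** A seeded generator builds complete challenge instances
(scaffold-decorated compound libraries, Kd panels with planted
ideal/near-miss/background roles, YAML submission sets with an optional
planted rank-1 duplicate, reference-active sets), so the whole pipeline
runs and is testable without any external download.

Chemistry (SMILES parsing, canonical identity, fingerprints, descriptors,
SMARTS matching) is backed by Open Babel through ChemmineOB.

## Worked example

```r
library(polypharm)

cfg  <- generator_config(seed = 7, library_size = 20, n_teams = 8,
                         per_team = 2)
inst <- generate_challenge(cfg)
sc   <- score_submission_set(inst$submissions, inst$panel, inst$rubric,
                             reference = inst$reference$smiles,
                             library   = inst$library)
sc$scoreboard
#>     team problem  compound target_points bonus_points problem_total
#>  Team_01       1  SYN00017            21            7            28
#>  Team_02       1 SYN00017b            21            7            28
#>  Team_03       1  SYN00015             8            7            15
#>  Team_05       1  SYN00009             0            7             7
#>  Team_06       1  SYN00006             0            7             7
#>  Team_04       1  SYN00004             0            5             5
#>  ...
```

Teams 1 and 2 submitted the same planted ideal binder under different
SMILES forms: it binds all four pro-targets and is censored on every
anti-target, so it earns the rubric's maximum 21 target points (5 + 9 +
3 + 4) plus all three bonuses. Team 3's near-miss binds only the
BRAF-analog (1 point) which unlocks the avoidance points (3 + 4), and the
background teams score bonus-only totals. The per-criterion breakdown of
any team is a score card:

```r
sc$cards[["Team_01"]]
#> <score_card> SYN00017 (problem 1, star_mode per_criterion)
#>                  criterion points max_points          satisfied
#>            binds RET_M918T      5          5          RET_M918T
#>         binds BRAF/SRC/S6K      9          9       BRAF;SRC;S6K
#>               avoids MKNK1      3          3              MKNK1
#>  avoids TTK/ERK8/PDK1/PAK3      4          4 TTK;ERK8;PDK1;PAK3
#>  criterion passed points                    detail
#>    novelty   TRUE      2 max reference Tc = 0.0115
#>     patent   TRUE      2             0 patent hits
#>   druglike   TRUE      3     4/4 Lipinski criteria
#> problem total: 28 (targets 21 + bonus 7)
```

`run_pipeline(pipeline_config(...))` wraps the same computation together
with the dedup report, similarity matrices and networks, the ADME
composite table and a run manifest, writing CSV/JSON/GraphML when an
output directory is given. `inst/scripts/mtd-pipeline.R` is a thin shell
front end (`simulate`, `run`, `classes`, ...) over these functions.

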