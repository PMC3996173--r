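---
title: "On-going record linkage: model, map, and maintenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{On-going record linkage: model, map, and maintenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ongolink)
```

## The problem

Health researchers routinely need event-based longitudinal views of whole
populations, assembled from administrative datasets (hospital admissions,
emergency presentations, death registrations, ...) that share no person
identifier. Specialised linkage units solve this with probabilistic record
linkage, and increasingly do so *on-goingly*: datasets arrive in monthly
batches containing new, amended, and deleted records, previously created
links are retained and extended, and researchers receive de-identified group
keys extracted at a point in time. That operating mode raises problems a
once-off linkage never meets: links must be updateable without relinking
everything; an extraction must remain explainable and reproducible after the
map has moved on; and a record that a custodian amends or withdraws must
leave the map as if its old version had never arrived.

`ongolink` implements this full operating surface: a Fellegi–Sunter matcher,
an event-sourced linkage map with complete group history, merge-based and
best-link grouping, pair-information-based unwinding of deletions and
amendments, project and bring-your-own scenarios, an automated
verify–clean–link–group pipeline, and a synthetic data generator with
ground truth so the whole system is testable without real person data.

## The matching model

Each configured field $i$ carries an $m_i$ (probability the field agrees on
a true-match pair) and a $u_i$ (probability it agrees on a non-match pair),
with $0 < u_i < m_i < 1$. A candidate pair's weight is the log-likelihood
ratio accumulated over fields:

$$ W = \sum_i w_i, \qquad
   w_i = \begin{cases}
     \log_2(m_i/u_i) & \text{field } i \text{ agrees} \\
     \log_2\!\big((1-m_i)/(1-u_i)\big) & \text{field } i \text{ disagrees} \\
     0 & \text{field } i \text{ missing on either side.}
   \end{cases} $$

Pairs with $W$ at or above the upper threshold are matches; strictly below
the lower threshold, non-matches; in between, "possible" matches. There is
no clerical review queue: possible pairs are resolved by a configured
policy (`treat_as_nonmatch` by default), and the stored classification
records that the decision was automatic. Both boundary conventions are
fixed and tested: the upper threshold is inclusive for *match*, the lower
inclusive for *possible*.

The $m$/$u$ probabilities are configuration inputs, not estimated from the
data: no EM step is performed. This keeps every run a pure function of
(records, configuration), which the rest of the system depends on.

### Comparators

Operational linkage units rarely standardise on one set of field
comparators, so they are configuration-declared rather than hard-coded:

* `exact` — string equality after cleaning.
* `truncated(k)` — equality of the first `k` characters.
* `approximate(sim_threshold, method)` — agreement iff a string similarity
  reaches the threshold. Two similarities ship: Jaro–Winkler (implemented in
  the package, checked against classic published values) and normalised
  Levenshtein (backed by `utils::adist`).
* `date_parts` — ISO dates agree iff at least two of {year, month, day} are
  equal, or the year is equal and day/month are transposed. This tolerates
  the two dominant error modes in recorded dates of birth (single-component
  typos and day/month swaps) while keeping chance agreement low.

### Blocking

Only pairs sharing at least one blocking key are ever compared. A pass is an
ordered list of field transforms (`full`, `prefix(k)`, `initial`, `year`,
`constant`); a record whose every component is missing gets a sentinel key
that joins no block. The bundled default configuration uses five passes —
surname prefix + birth year, full date of birth, given-name prefix + birth
year, surname prefix + given prefix, and full address — chosen so that
*every high-weight field features in at least one pass*. That property
matters beyond efficiency: the delete/amend equivalence guarantees below
hold exactly when candidate coverage is symmetric between "the record was
amended" and "the amended version had been added in the first place", and a
field that carries match-deciding weight but appears in no pass is the way
such symmetry breaks. A `constant` pass turns blocking off entirely
(exhaustive comparison), which the equivalence oracles use.

### Default parameters

The bundled config (`default_linkage_config()`) uses, per field:

| field | comparator | m | u | agree / disagree weight (log2) |
|---|---|---|---|---|
| given_name | Jaro–Winkler ≥ 0.85 | 0.92 | 0.04 | +4.52 / −3.58 |
| surname | Jaro–Winkler ≥ 0.88 | 0.95 | 0.02 | +5.57 / −4.29 |
| dob | date_parts | 0.97 | 0.004 | +7.92 / −5.05 |
| sex | exact | 0.98 | 0.5 | +0.97 / −4.64 |
| address | exact | 0.75 | 0.01 | +6.23 / −1.99 |

with thresholds 12 (match) and 6 (possible), in log2 units. These are
ordinary magnitudes for name-based linkage: a full agreement scores ≈ 25;
the strongest plausible coincidence between distinct persons (shared
surname, agreeing date of birth, same sex, different given name and
address) scores ≈ 8.9 — in the possible band, excluded from grouping by the
default policy.

## The linkage map: events, not rows

The map's source of truth is an append-only event log (`RECORD_ADDED`,
`PAIR_ACCEPTED`, `GROUP_CREATED`, `RECORD_JOINED_GROUP`, `GROUPS_MERGED`,
`RECORD_REMOVED`, `GROUP_RECONSTITUTED`, `RECORD_AMENDED`,
`SNAPSHOT_MARK`), each entry carrying a free-text reason. Of the three ways
a unit can keep history — none, snapshots, or full history in the map — the
package stores full history and *derives* snapshots from it: group state at
any sequence number is a pure fold of the log prefix (`state_at()`), so an
extraction's snapshot mark is just an event, and rollback is replay. Design
consequences:

* **Sequence numbers, not wall-clock time, order history.** Timestamps are
  annotations; determinism is testable.
* **Group identity.** A merge closes both predecessor groups and mints a
  fresh id (no "which id survives" tie-break); reconstitution after a
  removal likewise mints fresh ids when the group actually splits. A
  dissolved group id is never reused, so history can always name the group
  a record was in at any sequence number.
* **Pair store.** Only match-classified pairs (with their agreement
  vectors) are stored in the map — they are exactly what unwinding needs.
  Possible and non-match comparisons appear in run reports, not the map,
  which would otherwise grow with every comparison ever made.
* **Persistence** is JSON-lines, one event per line, with numerics written
  at full precision so a written-and-reread log replays to a state
  `identical()` to the original.

## Grouping strategies

Under **merge_allowed** (the default), groups are the transitive closure of
accepted pairs: a new pair may join a record to a group or merge two
existing groups. With all-records candidate scope this is the only strategy
for which arrival order provably cannot affect the final partition — batches
are commercial artefacts, and the grouping should not depend on them.

Under **best_link**, for use against a high-quality population spine, an
incoming record joins only the group of its single highest-weight match
pair; its match pairs into other groups are stored flagged
`suppressed_by_best_link`, and no ingestion ever merges two pre-existing
groups. The cost is permanent: a person split across two spine groups (a
false negative in the spine) is never repaired, no matter how clearly a
later record bridges the two. Ties are broken deterministically: more
agreeing fields first, then the group created earliest. Within a batch,
records are processed strictly in batch order, each choosing among the
groups of records already placed (existing groups and earlier batch
records), which realises "internal pairs before external pairs" without
ever allowing a merge.

Candidate scope is independently configurable: `all_records` compares
incoming records against every live record sharing a key;
`most_recent_per_group` only against the group member with the highest
`RECORD_ADDED` sequence number — cheaper, but history-dependent, so the
equivalence guarantees below are documented as holding only under
`all_records`.

## Deletions, amendments, open records

Simply dropping a deleted record from its group is dangerous: the record may
have been the only bridge between two sub-groups that now stay together
indefinitely. The package's only production path is therefore *unwinding*:
the record's pairs are deactivated and its former group is reconstituted
into the connected components of the remaining members over the remaining
stored pairs. (The naive removal appears in the test suite only as the
oracle of what must *not* happen.)

An amendment supersedes the old version, unwinds exactly as a deletion,
then sends the new version (version number + 1) through the standard
candidate/score/group path with its candidate set forced to include all
former co-group members as well as the blocking candidates of the *amended*
values — the superset interpretation, chosen because re-linking should both
re-evaluate old associations and discover new ones. Within a mixed "open
records" batch the order is delete → amend → add, so a new record can never
match a version being retired in the same batch.

Two equivalences follow, and are enforced by property tests under
merge_allowed + all_records: after `add X; delete X` the partition equals
one where X never existed, and after `add X; amend X→X′` it equals one
where X′ was added originally. Under incomplete blocking the amend path's
co-member candidates are a strict superset of the fresh-add path's, so the
equivalence could in principle differ when a true-match pair evades every
blocking pass (with the five default passes this needs three or more
simultaneous field corruptions); the bundled configuration is built so the
checks hold exactly at the study's corruption rates.

## Pipeline, scenarios, extractions

`run_pipeline()` executes verify → clean → link → group; a failed stage
skips all later stages, and the event log's content is untouched by any
failed run (checked by content comparison, not by trust). Cleaning is
schema-driven (trim, case-fold, punctuation stripping, null-token lists,
multi-format day-first date parsing), deterministic and idempotent; the
automation level is adjustable with `stop_after` for units that want manual
gates. Three scenario dispatches share the pipeline: `ongoing` ingests into
the central map, `project` runs in a fresh isolated map that can be
destroyed as a unit, and `byo` links a researcher's cohort read-only —
cohort keys are computed against the map without appending a single event.
The hybrid "link to the system but don't join it" case is exactly `byo`
versus `ongoing` on the same file.

`extract_keys()` marks a snapshot, writes the keys at that sequence number
(byte-stable ordering), and records the extraction; `--as-of` a previous
extraction id reproduces the earlier key file bit-identically from the log
prefix.

## The synthetic data generator

The generator exists so every guarantee above is testable end-to-end
without real person data. `generate_population()` draws names and addresses
from small bundled frequency pools, makes a configurable fraction of
persons share a surname (15%) or date of birth (5%) with someone else to
create plausible near-matches, and attaches life events (surname changes,
20% of persons; address changes, 30%) that scenario amendments can apply.
Two properties are enforced at generation: addresses are unique across
persons, and no two persons are simultaneously same-surname,
date-of-birth-agreeing (under `date_parts`) and given-name-similar (under
Jaro–Winkler ≥ 0.85) — i.e. identities are never *confusable under the
bundled matcher*. With zero corruption, linkage under the default config
then recovers the truth partition exactly, which pins the whole pipeline's
correctness to ground truth.

`emit_records()` corrupts emitted records with per-field single-character
typos (substitute/insert/delete/transpose, uniformly chosen), per-field
missingness, and per-record structural transpositions (day/month swap,
given/surname swap). `script_scenario()` turns a population into ordered
batch files with an `_action` column of adds, amendments (applying life
events) and deletions of previously emitted records. Everything is
deterministic given the seed. `evaluate_linkage()` scores any key file
against the truth map by pairwise precision and recall (with zero predicted
pairs, precision is reported as 1.0 alongside an explicit flag rather than
dividing by zero).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: realistic name/address frequency distributions (the
pools are small and synthetic), correlated error modes (e.g. twins sharing
surname+dob+address, households, transcription error bursts), dataset-
specific field availability, and populations at the >10^6 scale where
chance agreement inflates weights. Threshold calibration for production
data remains the operator's task.

## Problem sizes and numerical choices

The property checks run at sizes chosen to exercise the system well beyond
its unit fixtures while staying convenient for routine re-runs: order
invariance over 20 random arrival orders of 200 records in 5 batches;
incremental-versus-batch equality on the same 200 records under exhaustive
blocking; 50 random delete-equivalence and 50 amend-equivalence scenarios
of 50 records each; truth recovery on a 100-person population emitting two
records per person into each of two datasets (400 records), at corruption
rates 0 and at typo 5% / missing 2%; and 1000 random graphs of up to 50
nodes for the reconstitution-versus-components oracle. The quality bar at
realistic corruption (pairwise precision and recall ≥ 0.95) is a
repository-calibrated bar for these study conditions, not an external
claim.

Numerical conventions worth knowing when extending the package: weights are
log2 and compared with plain `>=`/`<` (no epsilon — the same inputs always
produce bit-identical weights, which replay requires); candidate pairs are
canonically oriented by record uid; within an ingestion, accepted pairs are
processed in (weight, uid) order so event streams are deterministic; and
all output files are written with byte-ordered rows so repeated extractions
are comparable with `cmp`.

## Known limitations

* $m$/$u$ estimation (EM), machine-learned classifiers, and
  privacy-preserving (encoded) comparison are out of scope by design.
* Single-writer: the event log has no concurrency control.
* The full fold in `state_at()` is linear in the log; a long-lived
  deployment would add periodic state caching (the log remains the source
  of truth either way).
* Static thresholds: no correction for the growth in chance agreement as
  files grow.
* Best-link suppressed pairs are stored but not currently consulted by
  reconstitution; unwinding under best_link uses membership-bearing pairs
  only.
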