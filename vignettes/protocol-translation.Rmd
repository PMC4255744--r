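---
title: "Translating laboratory protocols into machine-amenable workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating laboratory protocols into machine-amenable workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protsem)
```

## The problem

Biomedical protocols are written in natural language, and natural language
omits things. A sentence like *"Incubate at 30°C overnight"* does not say
**what** is incubated, under **what condition**, or how long *overnight*
actually is — and a culture grown for 12 hours is not the same experiment
as one grown for 18. `protsem` formalises protocols as sequences of
**experimental actions**, each with typed **descriptors**, checks whether
everything essential for reproduction has been recorded, and compiles the
result into a Petri net whose simulation deadlocks exactly at the first
step that cannot be reproduced as written.

## The action/descriptor model

The reference model is a catalog of experimental actions (`load_catalog()`).
Each action is identified by an accession (`EXACT2_000049` = *incubate*),
carries a verb label plus synonyms, and declares which descriptor kinds are
**essential** (the action "cannot be reproduced adequately" without them)
and which are **optional**. Descriptor kinds are fixed in a registry
(`descriptor_kinds()`): each kind has one semantic relation to the action —
participants (`biochemical_entity`, `equipment`) via *is-participant-of*,
measured qualities (`temperature`, `volume`, `speed`, `concentration`) via
*is-quality-of*, and propositions (`period`, `condition`, `goal`,
`protocol_method`, `time_point`) via *is-proposition* — and one value class
(quantity, entity reference, or free text).

Essentiality is action-specific: *store* requires temperature, period,
biochemical entity, condition and equipment; *incubate* requires
biochemical entity, condition, temperature and period, with equipment,
protocol method and goal optional; temperature is optional for *filter*
and *resuspend* because these actions are conventionally performed at
ambient temperature unless stated otherwise. This is deliberately a hard
binary classification rather than a probabilistic one: a probabilistic
"action X has descriptor Y with probability p" model would complicate both
authoring and checking without changing the operational question (*can a
reader reproduce this step?*).

The catalog is bundled as YAML (schema in `catalog.schema.json`) with 87
actions — 33 carried over from the previous catalog generation, 51 added
in the current one, and 3 imported from OBI. Only a subset of the
membership is fixed by published sources; the remainder is a curated
editorial choice of common protocol verbs, documented in the catalog file
itself. Editorial defaults for unlisted actions: the biochemical entity is
essential (every action acts *on* something), quantity descriptors are
optional unless the action's definition names them (*dilute* names a
concentration, *centrifuge* a speed and period, *freeze* a temperature).
The `time_point` kind, intended for workflow modelling, is not yet
referenced by any bundled action; it is registered as a quantity-valued
proposition by analogy with `period`. External imports are recorded as
MIREOT triples (source ontology URI, term URI, target superclass URI) —
the minimal information needed to reference an external term without
copying its axioms; full description-logic semantics are out of scope.

## The translation pipeline

`translate_protocol()` composes six deterministic stages; there is no
randomness anywhere, so identical input yields byte-identical output.

1. **Normalization** (`normalize_text()`): line endings to LF, unicode
   micro/degree variants folded (`µ`→`μ`, `℃`→`°C`), `30 °C`
   joined to `30°C`, horizontal whitespace collapsed. Idempotent.
2. **Abbreviation expansion** (`expand_abbreviations()`): whole-token,
   *case-sensitive* replacement from the lab configuration (`TCA` →
   `Trichloroacetic acid`). Case sensitivity matters: protocol
   abbreviations are conventionally uppercase, and `ON` must not fire
   inside `CONICAL` or match the preposition *on*. The substitution log
   keeps original and expanded spans, so the original text is exactly
   reconstructible.
3. **Sentence splitting** (`split_sentences()`): boundaries at `.` `!` `?`
   followed by whitespace, and at line breaks; periods inside decimal
   numbers (`0.1%`) and after textual abbreviations (`e.g.`) are not
   boundaries. Spans are 0-based half-open and tile the document's
   non-whitespace exactly once.
4. **Action identification** (`find_candidate_verbs()`,
   `identify_actions()`): protocols use the imperative register, so no
   statistical POS tagger is needed — candidates are the sentence-initial
   token and tokens coordinated by *and*/*then*/comma, excluding
   infinitive position (*to pellet* is a goal, not an action). Candidates
   are lemmatized (regular `-s`/`-ed`/`-ing` stripping with undoubling and
   e-restoration, checked against the catalog verb lexicon) and matched
   against catalog labels and synonyms; catalog validation guarantees at
   most one action per verb. A sentence with several actions yields that
   many instances, each with its own sentence copy; a sentence with none
   is kept verbatim as an unmatched note — including negated instructions
   (*"Do not smoke"*), which the model deliberately does not represent.
5. **Descriptor extraction** (`extract_descriptors()`): number–unit pairs
   from the versioned clue table (`clue_table()`) are assigned to the
   kinds the action allows (`°C` → temperature with Units Ontology id
   `UO:0000027`, `min` → period, `μg/mL` → concentration, ...); default
   tokens resolve through the lab defaults (`overnight` → 16 h, `RT` →
   22 °C) with provenance `default`; entities and equipment are linked to
   their dictionary IDs (case-insensitive, longest match wins);
   condition/goal/method phrases are captured verbatim after their cue
   words (*under*, *in the presence of*, *with* + gerund; *in order to*;
   *according to*). Only `°C` → `UO:0000027` is externally fixed; the
   remaining unit accessions are curated from the public UO namespace,
   and units with no canonical accession (rpm, ×g) carry none.
6. **Carry-forward inference** (`infer_carry_forward()`): a step missing
   its essential participant inherits the most recent preceding step's
   biochemical entity, flagged `inferred` and unconfirmed. Only the
   participant is carried — temperatures or periods of one step are not
   evidence about the next.

Tie-breaks and degenerate inputs are resolved explicitly. When two
mentions compete for one quantity kind in a sentence copy, provenance
`extracted` beats `default`, an entity-attached concentration (`0.1% BSA`)
yields to a free-standing one (*at a concentration of 100 μg/mL*), and
otherwise the mention nearest the action verb wins; losers are retained as
notes, never silently dropped. A number attached to an unrecognised
unit-like token is kept as a note with an empty unit id and logged under
`unknown_units`. Empty input produces an empty protocol, not an error.

A default token may appear for an action whose essential set does not
include its kind (e.g. *overnight* on an action with optional period); the
value is still recorded as an optional descriptor rather than suppressed —
recorded-but-optional information is harmless, silently discarded
information is not.

## Completeness checking and user correction

`check_completeness()` reports, per step, the essential kinds with no
value and the inferred values awaiting confirmation; the protocol is
`complete` exactly when both lists are empty everywhere. Inferred values
*must* be confirmed (or corrected) by the user before completeness —
inference is a suggestion, not evidence. Unmatched sentences do not block
completeness: they persist as free-text notes, which is where
out-of-model content (cautions, troubleshooting) belongs.
`apply_user_answers()` is the batch form of the interactive dialogue: it
only ever adds or confirms values (monotone completion) and rejects
answers for kinds the action does not allow.
`record_update_suggestions()` closes the loop: verbs the user mapped by
hand become synonym suggestions for manual catalog curation — the catalog
is never mutated automatically.

## Petri-net compilation

`compile_net()` encodes each step as a transition, sequencing places chain
the steps (`P0 → T1 → P1 → ...`; `P0` holds the start token), and each
essential descriptor kind of each step becomes a condition place. Two
design choices are worth stating:

* **Condition places use self-loop (read) arcs.** The firing rule for
  descriptor conditions is not externally fixed, and a consuming arc
  would make a satisfied condition disappear after one firing. A
  condition such as *temperature: 30°C* is state, not a consumable
  resource, so the compiler emits `D → T` and `T → D` with weight 1, and
  the token count on every condition place is invariant under any firing
  sequence (a tested property).
* **Optional descriptors are omitted entirely.** Only essentials gate
  firing; an unmarked-but-ignorable place would blur what a deadlock
  means.

A condition place is marked iff its descriptor value is present with
provenance `extracted`, `default` or `user`, or is inferred *and
confirmed*. This makes the central equivalence — `simulate_run()`
completes iff `check_completeness()` reports complete — true by
construction, and the test suite verifies it empirically over randomly
damaged protocols rather than trusting the construction. All arc weights
are 1; the data model admits weighted arcs and hand-built branching nets,
but the compiler never emits them, and non-deterministic branching
protocols are out of compile scope. Nets export to PNML (ISO/IEC 15909-2
place/transition), Graphviz DOT (circles for places, squares for
transitions) and lossless JSON.

## The synthetic-fixture generator

No public corpus of protocols with gold-standard parses accompanies the
model, so the test bed is generative: `generate_protocol()` emits seeded
imperative sentences of the form

```
<Verb> <entity> [at <T>°C | at RT] [for <n> min | overnight]
[in <equipment>] [<condition>] [in order to <goal>].
```

with verbs drawn from the catalog, entities and equipment from the lab
configuration (sometimes via their aliases or abbreviations), and records
the intended parse — including resolved defaults — as ground truth. The
grammar is deliberately *within clue-table coverage*, so the pipeline is
required to recover the truth exactly (recall = precision = value
accuracy = 1.0); the `adversarial` flag appends out-of-grammar sentences
(negations, unknown verbs) that must land among the unmatched notes.

What passing these tests shows — and what it does not: they demonstrate
that the pipeline is a correct inverse of its own grammar and clue table,
and that the validator and the compiled nets agree. They say nothing
about recall on free-form published protocols, whose phrasing variety,
anaphora and formatting the generator does not emulate; on real text the
clue table is meant to be extended through the suggestion workflow above.
Reported corpus-level identification rates for this class of system
(83–95%) are not reproducible here because no corpus is distributed with
the model.

## Problem sizes and verification

The shipped test suite exercises, among other things: 200 seeded fixture
protocols (1–6 steps) for exact round-trip recovery; 110 random fixtures
with ~30% of essential values deleted for the net/validator equivalence,
token conservation and firing-order invariants; and 300 seeds for
generator distinctness. `scripts/acceptance.R` recomputes the worked
examples, catalog counts, descriptor-model sizes and all of the above
rates from scratch on each run. These sizes were chosen once as
comfortably large for properties that are either exact or fail loudly.

## Known limitations

* Entity linking is exact (case-insensitive) dictionary matching; fuzzy
  matching and live PubChem/ChEBI lookups are out of scope.
* Only plain UTF-8 text is accepted; users convert doc/pdf upstream.
* Goal capture is limited to *in order to* and clause-final infinitives
  with catalog verbs; whether a goal verb should ever also count as an
  action is flagged for user review rather than decided silently.
* Carry-forward only crosses step boundaries linearly; cross-protocol
  references ("see step 3 of protocol B") are not resolved.
* The Petri-net layer models sequencing and condition satisfaction, not
  time: timed, stochastic and coloured nets are out of scope.
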