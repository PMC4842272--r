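---
title: "knowsub: methods and design of a substance-centric decision engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{knowsub: methods and design of a substance-centric decision engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knowsub)
```

## The problem

Regulatory screening of chemicals (REACH-style PBT/vPvB assessment) is a
knowledge-intensive workflow: an agency tracks thousands of substances, each
with a bundle of identifiers (EC and CAS numbers, IUPAC names, SMILES,
internal names), collects measured and expert-assessed facts about them, and
derives formal hazard decisions — persistent (P), bioaccumulative (B), toxic
(T) and their combinations — that must be *explainable*, *revisable* and
*auditable*. knowsub is a desk-scale engine for exactly this: an RDF graph as
the single source of truth, decision modules built from scoring rules and
diagnostic workflows, and a provenance layer that can reconstruct the
decision state at any past instant.

## Knowledge representation

**Graph model.** Substances are resources of class `ks:Substance` with
datatype properties `ks:hasLabel`, `ks:hasCAS`, `ks:hasEC`, `ks:hasIUPAC`,
`ks:hasSMILES`, `ks:hasInternalName` and `ks:hasMemo`. Chemical properties
(`ks:ChemProperty` instances `persistent`, `bioaccumulative`, `toxic`) attach
via `ks:hasChemProperty`. A substance class such as "PBT substance" is an
intersection of required property assertions; membership is computed by a
deterministic scan (`members_of()`) that provably coincides with the
equivalent SPARQL query (`classdef_sparql()`), which the test suite checks on
randomized stores. A full OWL-DL reasoner is deliberately not used: the
intersection pattern is the only class construct the engine needs, and a scan
is deterministic, dependency-free and fast at desk scale.

**Turtle and SPARQL.** The store reads and writes RDF 1.1 Turtle (prefixes,
prefixed names, `a`, literals with escapes, `;`/`,` lists). Blank nodes and
collections are rejected — the substance vocabulary never produces them,
which keeps graph isomorphism equal to triple-set equality, so the round-trip
guarantee is exactly testable. The query engine implements the SPARQL 1.1
subset the dynamic views use: `SELECT`/`ASK`, basic graph patterns,
`OPTIONAL`, and `FILTER NOT EXISTS`. Row order, which SPARQL leaves
unspecified, is fixed lexicographically so renders and CSV exports are
byte-reproducible. Both components are implemented in the package itself,
and the test suite cross-checks the writer and the query engine against the
Python `rdflib` toolchain on the worked example.

## Identifier quality control

CAS numbers carry a mod-10 check digit (weights 1, 2, 3, ... from the
rightmost non-check digit leftward), EC numbers a mod-11 check digit
(weights 1..6 left to right; a remainder of 10 means the body admits no
valid check digit at all). `validate_cas()`/`validate_ec()` implement these
public schemes; the suite verifies them against brute-force enumeration of
all ten candidate digits on 10,000 random bodies each. The quality dashboard
(`run_quality_checks()`) reports three kinds of findings: failing checksums,
identifier values shared by several substances (possible duplicate
registrations), and *contraindicative* identifier sets — several distinct
values for a scheme that should be single-valued (CAS, EC, IUPAC, SMILES);
internal names stay legitimately multi-valued. SMILES is checked
syntactically only (token legality, balanced brackets and ring closures):
here it is an identifier, not a structure to interpret, so no chemistry
toolkit is involved.

## Decision modules

A module bundles hierarchical **questions** (one-choice, multi-choice,
numeric, date, text; each may carry a unit and an explanation text),
a **decision hierarchy**, **scoring rules** and **workflows**, written in a
line-oriented plain-text dialect (see `parse_module()`); a YAML manifest
assembles modules into a registry whose `depends_on` graph must be acyclic.
Question and decision ids are global across the registry: a value entered in
one module is reused by every other, and the PBT module derives its decision
from the P, B and T decisions of the upstream modules.

**Three-valued conditions.** Conditions evaluate to true, false or
*undefined* (Kleene logic; `NA` in R). A comparison on an unanswered
question is undefined; `AND` short-circuits on false, `OR` on true.
`known(q)` is true when `q` is answered and *undefined* — not false — when
it is not: this keeps evaluation monotone under fact extension (adding facts
can only resolve undefined, never flip true and false), which in turn is
what makes explanations sound (removing facts can only un-fire rules).
Rules never fire on undefined conditions: no closed-world defaults.

**Scoring rules.** Each rule contributes a score category from the
heuristic ladder N7..N1, P1..P7 = −80, −40, −20, −10, −5, −2, −1, +1, +2,
+5, +10, +20, +40, +80 to its target decision; fired categories sum, and the
sum maps to a state: *excluded* at ≤ −42 (checked first, safety before
positivity), *established* at ≥ +42, *suggested* at ≥ +10, otherwise
*undefined*. The ladder and thresholds follow the established heuristic
scoring convention of diagnostic rule engines; both are configurable per
registry. Non-monotonicity is operationalized by **stateless full
re-evaluation**: every call recomputes all states from the current fact set,
so results are independent of fact insertion order and retracting a fact is
exactly equivalent to a session that never saw it. An incremental truth
maintenance system would save little at desk scale (hundreds of rules) and
would have to re-prove both properties.

**Workflows.** A workflow is a directed acyclic graph of ask-, decide- and
exit-nodes; edges carry optional guards. Traversal starts at the unique
start node, tests outgoing edges in declaration order and takes the first
true guard; it stops at an exit, when no guard is true, or before an
ask-node whose question is still unanswered (the trace records reasoning
that actually happened — with no facts it is just the start node). Visited
decide-nodes set their decision's state directly and override a rule-derived
state for the same decision; this resolution was an open design point and is
fixed this way because a workflow encodes an explicit, ordered procedure
whereas scores aggregate unordered evidence. Acyclicity is enforced at parse
time so traversal and tracing are total and deterministic.

**Fixpoint evaluation.** Modules are evaluated in dependency order and the
pass repeats until the state map stops changing (bounded by the module
count + 2). For dependency-respecting registries one pass already is the
fixpoint — a property the tests assert — but the iteration also gives
forward references a deterministic meaning.

## Explanations, traces and mirroring

`ks_explain()` returns the *responsible facts* (question, value, timestamp)
and the fired rules / taken workflow edges behind one decision, following
decision reuse transitively (the PBT explanation contains the facts behind
P, B and T). Its defining invariant — re-evaluating with only the
responsible facts reproduces the explained state — is guaranteed by the
monotone three-valued semantics and is property-tested on random registries.
`mirror_decisions()` writes every non-undefined state into the graph
(`ks:hasDecision` to a state resource carrying `ks:decisionId`,
`ks:decisionState`, `ks:decisionModule`), replacing previous states, so the
dynamic views always show the currently valid decisions and retractions
propagate to every view.

## Interviews

`start_interview()` builds an agenda from the workflow front — ask-nodes
reachable along edges whose guards are not yet false — plus the module's
declared questions not asked by any workflow, in declaration order (the
field's tools show questionnaire grouping but no ordering rule; declaration
order is the deterministic choice). Answering re-runs inference and
recomputes the agenda; answered questions, including values reused from
other modules, are never re-asked, and `NA` ("unknown") is an admissible
answer anywhere — screening practice requires skipping unavailable data.
Because evaluation is stateless, a finished interview yields exactly the
decisions of bulk-evaluating the same answers, in any agenda-respecting
order.

## Provenance and the time machine

The fact history is append-only: each fact carries substance, question,
typed value, an ISO-8601 UTC timestamp, a monotone sequence number breaking
same-instant ties, author, source (`user`/`import`/`derived`) and an
optional Klimisch reliability score (1–4) for measured data. Corrections
are new facts; timestamps within one (substance, question) key may not
decrease. `decisions_at(t)` re-evaluates the facts valid at `t` (latest
fact per question with timestamp ≤ t) — the registry itself is assumed
fixed across time, i.e. the time machine replays data, not knowledge-base
versions. Decision memos (free text, optionally attaching a formal
decision) are mirrored into the graph so SPARQL views reach them.

## Views and tabular IO

A dynamic view is a named SPARQL SELECT re-executed on every rendering —
no caching, so the PBT screening list follows every retraction. Exports are
RFC-4180 CSV (or TSV); spreadsheet interoperability is CSV by design, and
the CLI help says so loudly. Bulk import reads a CSV with a `label` column,
optional `ec`/`cas`/`iupac`/`smiles` columns and arbitrary question columns
recorded as import-sourced facts; rows with failing checksums are rejected
with reasons, and merging keys on CAS, then EC, then exact label — the
priority that mirrors duplicate-registration grouping.

## The worked example and the synthetic generators

The bundled example models the fantasy substance **Kryptonite**
(`kryptonite_example()`): a Turtle ontology, four modules and a scripted
answer set. Its CAS (9999999-99-5) and EC (999-999-2) are deliberately
fictional but checksum-valid. The module parameters are configuration
defaults reconstructed from public regulatory practice, clearly marked in
the module files and overridable there:

| parameter | default | source of the convention |
|---|---|---|
| ThCO2 / ThOD pass level | 60 % | OECD 301 ready biodegradability |
| DOC removal pass level | 70 % | OECD 301 |
| P / vP half-life (water) | > 40 d / > 60 d | REACH Annex XIII |
| B / vB BCF | ≥ 2000 / ≥ 5000 L/kg | REACH Annex XIII |
| log Kow screen (suggests B) | ≥ 4.5 | REACH Annex XIII screening |
| T chronic NOEC | < 0.01 mg/L | REACH Annex XIII |

The generators (`generate_substances()`, `generate_random_store()`,
`generate_random_registry()`, `generate_random_facts()`) are pure functions
of their seed. They emulate the *structural* features the engine exercises —
identifier sets with a controllable fraction of checksum failures, random
property assertions, random rule bases of bounded depth — and deliberately
not the content of real registration data: no real CAS/EC numbers (reserved
high-number ranges, labelled SYNTHETIC), no realistic chemical structures,
no correlated endpoints. Passing tests therefore demonstrate the engine's
logical guarantees (oracle equivalence, order invariance, explanation
soundness, round trips), not the regulatory validity of any bundled
threshold.

```{r example}
ex <- kryptonite_example()
facts <- current_facts(ex$answers, ex$substance)
dm <- ks_evaluate(ex$registry, facts)
dm

mirror_decisions(ex$store, ex$substance, dm)
render_view(ex$store, ex$views$pbt_screening)

ks_explain(ex$registry, ex$answers, "PBT")
```

## Numerical and procedural choices

* Problem sizes in the shipped checks: random stores up to 100 substances
  (50 stores), 10,000 random identifier bodies per scheme, 1,000 random
  fact sets against the brute-force rule interpreter, 200 explanation
  soundness cases, 100 permutations/time points, 20 scripted interviews —
  sizes at which every property is exhaustively meaningful on a single CPU.
* Ties and order: SPARQL rows sort lexicographically; simultaneous
  workflow guards take the first declared edge with a logged warning;
  same-instant facts order by sequence number; agenda ties break by
  declaration order.
* Degenerate inputs: empty module text parses to an empty module; an empty
  requirement set makes every substance a class member; a store without
  substances renders header-only views; retracting an unanswered question
  is a warning no-op.

## Known limitations

* SPARQL support is the subset above — no property paths, aggregation,
  named graphs or remote endpoints; duplicate/contraindication queries run
  as tabular queries over the triple table rather than as SPARQL.
* No OWL reasoning beyond the intersection-of-property-values pattern.
* Single-process, in-memory store; collaboration features of a wiki
  platform (concurrent editing, user roles) are out of scope.
* SMILES validation is lexical; structure-based duplicate detection and
  InChI are out of scope.
* The time machine replays facts under the current registry; historical
  knowledge-base versions are not modelled.
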