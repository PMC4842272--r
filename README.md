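# knowsub

A substance-centric knowledge engine for regulatory chemical hazard
screening, in the style of REACH PBT/vPvB assessment.

Agencies screening chemicals keep, per substance, a bundle of identifiers
(EC and CAS numbers, IUPAC name, SMILES, internal names), a growing log of
facts (measured endpoints, expert assessments), and formal hazard decisions
— persistent (P), bioaccumulative (B), toxic (T), PBT, vPvB — that must be
explainable, revisable and auditable. knowsub packages that workflow for R:

* **RDF graph store** — substances, properties, decisions and memos as
  triples; Turtle read/write; a SPARQL SELECT/ASK subset (basic graph
  patterns, `OPTIONAL`, `FILTER NOT EXISTS`) powering *dynamic views*:
  named queries re-executed on every rendering and exportable as CSV.
* **Identifier QC** — the public CAS mod-10 and EC mod-11 check-digit
  schemes, duplicate detection and contraindicative-identifier findings on
  a quality dashboard.
* **Decision modules** — hierarchical questions and decisions,
  non-monotonic scoring rules with three-valued (Kleene) conditions, and
  acyclic diagnostic workflows, written in a plain-text dialect. Fired rule
  scores (N7..N1, P1..P7 = −80..+80) sum per decision and map to
  *established* (≥ 42) / *suggested* (≥ 10) / *excluded* (≤ −42) /
  *undefined*.
* **Inference with truth maintenance** — stateless full re-evaluation makes
  decisions independent of fact entry order and makes retraction exact;
  every decision carries an explanation (the responsible facts with
  timestamps) and workflow reasoning traces.
* **Interviews** — agenda-driven question sessions per module; answers from
  other modules are reused, "unknown" is always admissible.
* **Provenance** — an append-only timestamped fact history, decision memos,
  and a *time machine*: the decision state valid at any past instant.

## Worked example

The package bundles the fantasy substance *Kryptonite* (synthetic,
checksum-valid identifiers) and four example modules — Persistence,
Bioaccumulation, Toxicity, PBT:

```r
library(knowsub)
ex <- kryptonite_example()
facts <- current_facts(ex$answers, ex$substance)
dm <- ks_evaluate(ex$registry, facts)
dm
#> <ks_decision_map>
#>   [Persistence] nrb: established (score 80)
#>   [Persistence] P: established (score 85)
#>   [Persistence] vP: established (score 80)
#>   [Bioaccumulation] B: established (score 0)
#>   [Bioaccumulation] vB: established (score 0)
#>   [Toxicity] T: established (score 80)
#>   [PBT] PBT: established (score 80)
#>   [PBT] vPvB: established (score 80)
```

A ThCO2 of 45 % misses the 60 % ready-biodegradability pass level (rule
score +80 → *not readily biodegradable* established), the 75-day water
half-life establishes P and vP, the workflow routes the measured BCF of
5300 L/kg through the vB decide-node (hence B; their scores are 0 because
they are workflow-, not rule-derived), and the chronic NOEC of 0.004 mg/L
establishes T. The PBT module reuses P, B and T to establish PBT.

Mirror the decisions into the graph and render the screening view:

```r
mirror_decisions(ex$store, ex$substance, dm)
render_view(ex$store, ex$views$pbt_screening)
#> # A tibble: 1 × 3
#>   label      ec        cas
#>   <chr>      <chr>     <chr>
#> 1 Kryptonite 999-999-2 9999999-99-5
```

Every decision is explainable — and retraction is exact:

```r
ks_explain(ex$registry, ex$answers, "PBT")
#> Decision PBT: established
#>   dt50_water = 75  [2016-04-23 10:01:00 UTC]
#>   ThCO2 = 45  [2016-04-23 10:00:00 UTC]
#>   bcf_available = yes  [2016-04-23 10:02:00 UTC]
#>   BCF = 5300  [2016-04-23 10:03:00 UTC]
#>   chronic_noec = 0.004  [2016-04-23 10:04:00 UTC]

dm2 <- ks_evaluate(ex$registry, retract(facts, "BCF"))
dm2$state[dm2$decision %in% c("B", "PBT")]
#> [1] "undefined" "undefined"
```

A command-line front end over the same functions lives at
`inst/cli/knowsub.R`:

```sh
Rscript inst/cli/knowsub.R query inst/extdata/kryptonite.ttl \
        inst/extdata/views/pbt_substances.rq
#> label
#> Kryptonite
```

## Documentation

The methods vignette (`vignettes/knowsub-methods.Rmd`) describes the graph
model, the three-valued rule semantics and state thresholds, the workflow
traversal and explanation invariants, the provenance model, all default
thresholds with their regulatory conventions, and the limits of the
synthetic fixtures.
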