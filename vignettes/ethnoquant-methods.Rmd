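---
title: "Consensus indices and network analysis for ethnomedicinal surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus indices and network analysis for ethnomedicinal surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnoquant)
```

## The data model

An ethnomedicinal survey aggregates informant interviews into *use
reports*: one informant citing one species against one ailment. The
package's unit of data is the disorder × species record — the row format of
published survey tables — carrying a mention count (the number of use
reports behind the pair), the organism kind (plant, animal or fungus),
used-part and preparation label sets, and the administration route.

Validation enforces the invariants every downstream stage relies on:
positive integer mentions, a closed kind vocabulary, non-empty label sets,
and uniqueness of (disorder, species) pairs *after* scientific-name
normalization. Normalization collapses whitespace and applies an alias
table of known orthographic variants; it is idempotent, so re-validating a
validated table is a no-op. Species identity is the full scientific name
including the author string: infraspecific taxa (e.g. *Bupleurum falcatum*
L. vs *Bupleurum falcatum* var. *scorzoneraefolium*) are deliberately
distinct, because survey species counts treat them as distinct remedies.

The packaged dataset (`liver_survey()`) is a transcription of a published
survey of liver-disorder remedies in southern Korea: 121 records across
seven ailment categories, 94 species, 1,514 use reports. Two orthographic
variants in the printed table are resolved by the default alias table
(a dropped terminal *s* in *Scolopendra subspinipes mutilans*, and spacing
of the author string of *Capsella bursapastoris*); without them the
distinct-species count would be inflated and the affected fidelity levels
deflated. The printed FL column is retained verbatim in `fl_printed` for
auditing but never enters any computation.

## The indices

For each ailment category, with $n_{ur}$ use reports over $n_t$ distinct
species, the informant consensus factor is

$$\mathrm{ICF} = \frac{n_{ur} - n_t}{n_{ur} - 1},$$

1 when all reports agree on one species and 0 when every report cites a
different one. The formula divides by zero at $n_{ur} \le 1$; the package
reports these categories as *undefined* (`NA`) rather than substituting 0
or 1, since either substitution would silently distort cross-category
comparisons.

For a species cited $N_p$ times for a given ailment and $N$ times in
total, the fidelity level is

$$\mathrm{FL}(\%) = \frac{N_p \times 100}{N}.$$

The denominator pools the species' records across the *entire* table, not
within one ailment — the definition that reproduces published FL values
(e.g. water dropwort cited 4/39 times for hangover, FL 10.3).

### Numerical choices

Both indices are ratios of small integers. Display values use
half-away-from-zero rounding on the exact rational (implemented in integer
arithmetic, `ratio_display()`), because that is the convention of printed
survey tables and because IEEE round-half-even would disagree at exact
halves. The FL = 100% census compares the integer counts $N_p = N$, never
the rounded display, so a species at exact FL 50 can never be
misclassified however its printed value reads.

The audit operation (`audit_printed_fl()`) flags records whose printed FL
differs from the recomputed display value by more than a tolerance
(default 0.05, i.e. agreement at the printed precision). On the packaged
survey it flags exactly two records — *Plantago asiatica* carries printed
FL 100.0 for both hepatitis and jaundice, impossible under the definition
for a species recorded for two disorders; the recomputed 50.0 is treated
as authoritative, which is also why the jaundice census counts 16 species
rather than 17.

### Known unreproducible figures in the source

Several headline numbers printed alongside the packaged survey cannot be
derived from its own table and are therefore *not* computed or asserted
anywhere: the claim of 28 species at FL 100% (no counting rule recovers it;
the table yields larger counts), the "254 ethnomedicinal practices" and its
150/99/5 split (the counting unit, apparently species × usage combinations,
is not recoverable from aggregated rows), family/genus totals (the table
has no such columns; `summarize_survey()` deliberately reports no taxonomy
without an external mapping), a 6.90% animal mention share (no subset of
the three named animals' totals over 1,514 yields it), and one species
total printed as 10 in prose but 23 in the table (the table is followed).
One printed percentage is internally inconsistent at the last digit: 59/94
species is printed as 62.7% although every other percentage in the source
follows half-away-from-zero rounding (which gives 62.8); the package
reports 62.8. Similarly, the source's claim that liver cirrhosis was
treated with "only animals" except one plant and one fungus overlooks a
third exception recorded in its own table (*Oenanthe javanica*, a plant
cited twice for cirrhosis); `disorder_kind_composition()` reports all
three.

## The network

`build_network()` represents the survey as a two-mode graph: disorder
nodes, species nodes (kind attached as a vertex attribute, keeping the
graph strictly bipartite), and one mention-weighted edge per record. Edge
weights are a superset of the published unweighted analysis: unweighted
degree alone reproduces the published claims, while weights make species
strength equal the FL denominator $N$ — a cross-module conservation law
the tests verify. One-mode projections weight edges by shared-neighbor
counts (species mode: disorders treating both species). Layout and
drawing are out of scope; GraphML and edge-list exports feed dedicated
viewers, and the network `autoplot()` shows the degree distribution
instead.

## The synthetic generator

The generator emulates a multi-ailment survey with a single consensus
knob. Each species gets a home disorder (round-robin over the pool) and,
with probability `multi_use_prob`, becomes eligible for every disorder —
without such sharing all fidelity levels are trivially 100%. For each
disorder, weights over its eligible species are drawn from a symmetric
Dirichlet with concentration $\alpha$ (via normalized gamma draws) and
`reports_per_disorder` reports are allocated multinomially; species with
at least one report become records. Small $\alpha$ piles reports onto few
species (ICF near 1), large $\alpha$ spreads them evenly (low ICF);
`expected_icf_curve()` traces this monotone relationship as a simulation
diagnostic (the tests use 100 replicates per grid point over a 5-point
grid with 3 disorders, a pool of 30 and 60 reports per disorder —
problem sizes chosen to make the Monte-Carlo means stable at a few
seconds' runtime).

Defaults (5 disorders, pool of 60, 200 reports per disorder,
$\alpha = 0.5$, kind probabilities 0.6/0.35/0.05, `multi_use_prob` 0.2)
are sized to resemble a single-theme field survey like the packaged one:
a few ailment categories, tens of candidate species, a few hundred reports
per category, plant-dominated, with a strong but not degenerate consensus.
Generation is fully deterministic given the configuration and seed.

What the generator does *not* emulate: informant-level structure (ages,
villages, repeat interviews), correlated species eligibility (taxonomic or
ecological similarity), and heaped mention counts. Passing property tests
on synthetic surveys therefore demonstrates the correctness of the index
and network computations under the data model, not the realism of any
particular field survey.

## Design notes

- `read_survey()`/`write_survey()` guarantee round-trip identity on
  validated tables; set-valued fields are serialized comma-separated
  inside a quoted field, the convention of the printed tables themselves.
- Disorder labels are matched case-insensitively against the seven
  canonical category spellings of the packaged survey; unrecognized labels
  pass through untouched, so simulated or third-party surveys validate
  unchanged.
- ICF/FL implementations are grouped-summary code; the test suite checks
  them against an independent per-report enumeration oracle (materialize
  one row per individual report, recount from scratch) on 200 random
  tables per run, plus endpoint laws and conservation identities.
- Ties: ranked species lists break mention ties by name ascending; degree
  rankings break ties by strength descending, then name; the modal kind of
  a disorder neighborhood breaks count ties alphabetically.
- The command-line layer (`ethnoquant_run()`, wrapped by
  `exec/ethnoquant`) returns distinct exit codes for usage (1),
  validation (2) and I/O (3) failures, logs to standard error, and writes
  data to files or standard output only.

## Limitations

The package computes no inferential statistics on ICF/FL (no standard
errors or tests — the indices are descriptive), implements no further
ethnobotanical indices (use value, relative frequency of citation,
cultural importance), and performs no taxonomic name resolution beyond
the explicit alias table.
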