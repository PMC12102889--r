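---
title: "Automated codelist construction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated codelist construction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codelistr)
```

## The procedure

`codelistr` semi-automates the construction of clinical codelists (SNOMED CT
code sets) for EHR research. The expensive resource is clinician time; the
package's job is to confine that time to the decisions only a clinician can
make. The pipeline has three automated tiers wrapped around two manual
inputs:

1. **Ontology mapping.** Baseline codelists arriving in legacy UK ontologies
   (Read v2, CTV3, Medcode) are converted to SNOMED CT through a cross-map
   table. A source code mapping to several SNOMED concepts is *expanded* to
   all of them: draft codelists favour recall, because everything downstream
   (shrinking, review) only ever prunes. Codes absent from the map are
   excluded from the working list but itemised completely in a mapping
   report — the conservation invariant (`mapped + unmapped = input`, with
   already-SNOMED codes passing through as identity mappings) is tested
   property-style.
2. **Name harmonisation.** The same condition appears across baselines as
   `Pulmonary hypertension`, `pulmonary_hypertension`, `PULMONARY
   HYPERTENSIONS`, or `Chronic Obstructive Pulmonary Disease (COPD)` vs
   `COPD`. Matching happens on a canonical key (see below); names whose
   alias sets intersect are unified by connected components over the
   alias-overlap relation. Unification is *exact string equality between
   normalised aliases*, never fuzzy similarity: a fuzzy merge cannot be
   audited after the fact, and a wrongly merged clinical concept is a worse
   failure mode than a duplicate row a human can spot in the definitive-
   condition report.
3. **Clinician directives** (manual input one) assign each definitive
   condition `keep`, `group` or `split` — names only, no codes. `keep`
   conditions are drafted fully automatically by keyword search; `group`
   merges all related lists under one name; `split` distributes a list over
   priority-ranked keyword rules with an always-materialised
   `"<Condition> Other"` fallback, so the split is a true partition of the
   source entry set.
4. **Shrinking.** Draft codes found in the condition's mapped trusted lists
   are marked `auto_validated`; the rest `needs_review`. Matching is by
   SNOMED identifier only — terms drift across terminology releases, the
   identifier is the identity. Shrinking deletes nothing.
5. **Clinical review** (manual input two) sees only the `needs_review`
   residue. Whether a list needs review at all follows four criteria
   (unreviewed subset of a verified list; unreviewed combination of verified
   lists; no published codelist; involves test codes — in which case only
   the test codes need review). Boundary codes (suggestive but not exclusive
   of the condition, `Boundary_case = 1` in the CSV contract) need two
   reviewer votes; a 1–1 split is held `pending` until a third casting vote.
   Every status change is appended to an immutable audit log.

## Name normalisation rules

The canonical key is: case-fold; treat `_` and `-` as spaces; drop
parenthesised content (it becomes a separate alias, so
`"Chronic Obstructive Pulmonary Disease (COPD)"` yields the key
`"chronic obstructive pulmonary disease"` plus alias `"copd"`); replace
remaining punctuation by spaces; collapse whitespace; strip a per-token
trailing plural `s`.

Plural stripping is deliberately a dumb, auditable suffix rule rather than a
stemmer: a token loses a trailing `s` only if it is longer than three
characters, does not end in `ss`, `is` or `us`, and is not in a configurable
exception list. The suffix guards protect the Latin/Greek clinical
vocabulary (*arthritis*, *tinnitus*, *mellitus*, *sepsis*) without
enumerating it; the exception list (`plural_exception_terms()`) covers the
remainder (*varices*, *diabetes*, *measles*, …). The function is idempotent
and case-insensitive, which the test suite asserts over generated names.

## Keyword matching

Draft generation and splitting match keywords against code terms after
case-folding and whitespace normalisation, as *substrings* by default:
`alcohol` should capture `Alcoholic liver disease`. A `whole_word` switch
exists for conditions where that over-captures. When the pipeline derives
keywords from a condition's aliases it drops aliases shorter than four
characters: two-letter abbreviations like `AF` are precious for name
unification but toxic as substring probes.

`find_related_conditions()` defaults its search terms to the whole
normalised condition name (one phrase), not its individual tokens: grouping
directives of the form "merge everything called *Alcohol Problems Others*"
refer to the phrase, and token-level defaults would relate every `disease`
to every other.

## The shrink statistic

For condition $k$ with draft set $D_k$ ($n_k = |D_k|$) and resolved trusted
set $T_k$:

$$\mathrm{shrink}_k = \mathrm{round}\!\left(100 \cdot \frac{|D_k \cap T_k|}{n_k},\, 2\right),
\qquad
\mathrm{overall} = \mathrm{round}\!\left(100 \cdot \frac{\sum_k |D_k \cap T_k|}{\sum_k n_k},\, 2\right).$$

The overall figure is *code-weighted* — it answers "what fraction of codes
never needed a clinician" — and is therefore bounded by the row extremes; a
macro (unweighted) average is emitted alongside because the two can differ
substantially when list sizes are skewed. Percentages are reported to two
decimal places. A condition with no entry in the trusted-source map resolves
to the empty trusted set: it is newly introduced and shrinks 0%.

Three edge rules are worth stating. An empty draft has an undefined
percentage and is an error, not a 0 or 100. Re-shrinking an already-shrunk
collection is a no-op (idempotence), and prior `approved`/`excluded` review
outcomes survive re-shrinking — a clinician's decision outranks the
automaton. Codes appearing under several conditions are *flagged* in the
report but kept in every list: cross-condition overlap is often clinically
intentional (a code can evidence two conditions), so deletion is left to
humans.

## The synthetic study

The generator (`fixture_spec()`, `generate_baselines()`,
`generate_trusted_source()`, `write_fixture_project()`) emulates the
structure of a real project: two baseline releases sharing conditions under
planted name variants (case, underscores, plurals, parenthesised
abbreviations), a fraction of one baseline's codes re-expressed in CTV3 with
a consistent mapping table, and a trusted source covering each condition's
draft with probability-$p_k$ mass. Defaults, chosen once as the study
conditions: 20 conditions of 4–30 codes; variant probabilities 0.5 / 0.4 /
0.3 / 0.25 (case / underscore / plural / abbreviation); legacy fraction 0.2;
coverage mixture 65% of conditions fully covered, 25% partial (uniform on
0.30–0.95), 10% uncovered — mirroring the typical pattern in which most
lists are fully validated by the trusted source, a minority partially, and a
few novel conditions not at all, which lands the overall reduction in the
>80% regime.

Coverage is planted as an **exact count**: the trusted list for condition
$k$ contains exactly $\lfloor p_k n_k \rfloor$ codes sampled from the draft
(plus distractor codes absent from every draft), so the expected shrink row
is $\mathrm{round}(100 \lfloor p_k n_k\rfloor / n_k, 2)$ *exactly*, not in
expectation. The end-to-end test runs the whole pipeline from the written
files and requires byte-identical agreement with the planted report. SNOMED
identifiers are generated with valid Verhoeff check digits from disjoint
numeric ranges (baseline vs distractor), so id collisions are impossible by
construction and strict identifier validation passes.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: real SNOMED content and its hierarchy (terms
here are templated `"<modifier> <condition> <qualifier>"` strings; condition
names are pairwise non-containing, so keyword drafts are separable by
construction, which real terminologies do not guarantee); term-frequency
realism; mapping tables with gaps or assurance downgrades (the planted map
is complete); and clinician disagreement patterns. Keyword-search recall on
real releases depends on term conventions and must be checked with the
definitive-condition and draft reports, which is precisely why every stage
writes an auditable CSV.

## Numerical and interface choices

- All collection orderings in outputs are sorted (canonical key, then
  ontology, then code id), and manifests carry no timestamps, so repeated
  runs are byte-identical and release diffs are meaningful.
- Codes are keyed by (ontology, code id), never code id alone — a CTV3 code
  and a SNOMED id can collide textually before mapping.
- Identifiers are always text. An 18-digit SCTID overflows a double, and
  legacy codes carry leading letters; nothing in the package ever parses a
  code as a number.
- Status merging uses a fixed lattice (`approved` > `auto_validated` >
  `needs_review` > `draft`) with `excluded` sticky: when lists merge, a
  recorded exclusion must not be resurrected by a more optimistic duplicate.
- Split rules are ranked by an explicit integer priority, not file order, so
  re-sorting a rules table cannot change the partition; duplicate priorities
  are a configuration error.
- Review sheets round-trip: exporting, importing an untouched sheet, and
  exporting again is byte-stable, and `pending` is an explicit outcome so a
  half-finished panel meeting can be saved and resumed safely.
- Error families are structured conditions (format / configuration /
  dependency / reconciliation), which the shell wrapper maps to distinct
  exit codes.

## Problem sizes used by the shipped checks

The test suite and acceptance script run the full pipeline on 20-condition
projects (a few hundred codes), conservation properties on 100 random small
fixtures, and set-arithmetic oracles on instances of up to 1,000 codes —
sizes chosen so the whole suite re-runs in minutes on one CPU while still
exercising every code path; the operations themselves are set algebra and
scale linearly in the number of codes.

## Known limitations

- SNOMED hierarchy (is-a) relations are out of scope: lists are flat, and
  no subsumption-based retrieval or validation is attempted.
- Medication (DMD) codes flow through the same machinery but have no
  dedicated semantics.
- Reverse mapping (SNOMED back to legacy ontologies) is not provided.
- Fuzzy name similarity is intentionally absent from unification; partially
  overlapping aliases surface as separate conditions for a human to resolve
  via directives.
- Prevalence checking of finished codelists against EHR cohorts is a
  downstream activity outside the package.
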