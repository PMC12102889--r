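# codelistr

Automated construction, trusted-source validation and review auditing of
clinical codelists.

## The problem

Research on electronic health records starts with *codelists* (value sets,
code sets): named sets of clinical codes — in UK primary care, SNOMED CT
concept identifiers — that operationalise one clinical concept, e.g.
`195967001` (Asthma) and `281239006` (Exacerbation of asthma) under an
"Asthma" codelist. Multimorbidity studies need hundreds of such lists, and
building them by hand ties up scarce clinician time for months: baseline
releases name the same condition inconsistently, part of the codes sit in
legacy ontologies (Read v2, CTV3, Medcode), and every draft code nominally
needs clinical sign-off.

`codelistr` automates everything around the clinical judgement itself:

1. **Preprocess** — map legacy codes to SNOMED CT via TRUD-style cross-map
   tables, itemising (never silently dropping) anything unmappable.
2. **Derive** — harmonise condition names across baselines into a definitive
   condition list (case/underscore/plural/abbreviation variants unify by
   alias overlap).
3. **Directives** — consume the clinicians' keep/group/split instructions,
   which operate on condition *names* only, never on individual codes.
4. **Generate** — build draft codelists by keyword search over the
   preprocessed sources; apply group merges and priority-ranked keyword
   splits (with an always-materialised "… Other" fallback list).
5. **Shrink** — auto-validate draft codes found in a trusted, previously
   clinically validated source (e.g. the CALIBER phenotype library), and
   quantify the clinician workload that removes.
6. **Review** — export only the residual codes to a review sheet, adjudicate
   boundary codes (two reviewers, third casting vote on a 1–1 split), and
   append every decision to an immutable audit log.

## The workload-reduction statistic

For condition *k*, let *D<sub>k</sub>* be its draft SNOMED code set
(*n<sub>k</sub>* = |*D<sub>k</sub>*|) and *T<sub>k</sub>* the union of the
trusted lists mapped to it. Shrinking marks *a<sub>k</sub>* =
|*D<sub>k</sub>* ∩ *T<sub>k</sub>*| codes `auto_validated` and the rest
`needs_review`, and reports

- per-condition: `shrink_pct`<sub>k</sub> = 100 · *a<sub>k</sub>* / *n<sub>k</sub>* (2 d.p.);
  100.00 is a "fully shrunk" list needing no clinician time,
- overall (code-weighted): 100 · Σ*a<sub>k</sub>* / Σ*n<sub>k</sub>* — never a
  mean of row percentages; the unweighted macro average is emitted alongside
  for transparency.

No code is ever deleted by shrinking: statuses change, the record stays
complete, and cross-condition duplicate codes are flagged but left in place.

## Worked example

```r
library(codelistr)

drafts <- codelist_collection(list(
  codelist("Asthma", code_entries(
    c("195967001", "281239006", "233678006"),
    c("Asthma", "Exacerbation of asthma", "Childhood asthma"))),
  codelist("Chronic Tinnitus", code_entries(
    c("15188001", "60862001"), c("Hearing loss", "Tinnitus")))
), "drafts")

trusted <- codelist_collection(list(
  codelist("kuan asthma", code_entries(c("195967001", "281239006"), "Asthma"))
), "caliber")

tmap <- trusted_source_map("Asthma" = "kuan asthma", trusted = trusted)
res <- shrink_collection(drafts, tmap, trusted)
res$report
#> <shrink_report> 2 condition(s), 5 code(s): 2 auto-validated (40.00% overall, 33.34% macro), 3 left for review
#> # A tibble: 2 x 5
#>   canonical_key    n_draft n_auto_validated n_remaining shrink_pct
#>   <chr>              <int>            <int>       <int>      <dbl>
#> 1 asthma                 3                2           1       66.7
#> 2 chronic tinnitus       2                0           2        0
summary_sentence(res$report)
#> "automation validated 40.00% of codes, leaving 3 for review"
```

Two of Asthma's three draft codes were already validated by the trusted list
(66.67%), so one code goes to review; Chronic Tinnitus has no trusted list —
it is newly introduced, shrinks 0%, and needs full review.
`export_review_sheet(res$collection)` then emits exactly those three codes
with empty reviewer/outcome columns for the panel.

A whole project is driven the same way from files on disk via
`run_phase()` (`synth`, `preprocess`, `derive`, `generate`, `shrink`,
`report`, `review-export`, `review-import`) with a YAML config and per-phase
checksum manifests; `inst/scripts/codelist_pipeline.R` wraps this for the
shell.

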