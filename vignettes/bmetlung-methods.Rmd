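---
title: "Methods: report classification and exact contingency inference for lung brain metastases"
author: "bmetlung authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: report classification and exact contingency inference for lung brain metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmetlung)
```

## The problem

Brain metastases are among the commonest specimens in surgical
neuropathology, and lung cancer is their commonest source. Where a lung
metastasis lodges in the brain (frontal, parietal, temporal or occipital
lobe, cerebellum, or elsewhere) is not independent of the histologic
subtype of the primary tumour: small cell carcinoma is over-represented
in the cerebellum, adenocarcinoma in the frontal lobe. Pathology archives
encode this information only as free text, so studying the association at
cohort scale needs three ingredients that this package provides:

1. a **rule-based classifier** (hierarchical free-text string matching)
   that turns each report into a diagnostic category, a primary site, a
   lung-cancer subtype and a *set* of neuroanatomical location codes;
2. **cohort tabulations** that respect the awkward unit-of-analysis
   problem (a patient can have lesions at several sites, so lesions
   exceed patients) — the site-overlap matrix, subtype-by-site lesion
   tables, and biomarker tables;
3. an **exact inference engine** for the resulting sparse contingency
   tables: two-sided Fisher tests for 2x2 tables, the Freeman–Halton
   exact r x c test with full enumeration, a fixed-margin Monte-Carlo
   estimator for tables too large to enumerate, and the all-pairs 2x2
   decomposition visualised as a binned, clustered heatmap.

Because patient-level clinical text cannot be redistributed, the package
also contains a **synthetic corpus generator** that emulates the joint
statistical structure of a 10-year regional cohort of 234 lung
brain-metastasis patients, paired with ground-truth labels so that every
pipeline stage is testable end to end.

## The classifier

Matching is case-insensitive substring/stem matching over normalised text
(lower-cased, whitespace collapsed), driven by an editable lexicon
(`default_lexicon()`): one rule per line with an axis, a unique priority
within that axis, a pattern and an emitted label. There is deliberately no
statistical NLP — the procedure being modelled is string matching, and a
transparent rule table is what makes its failure modes auditable.

Two design points matter:

* **Hierarchy / supersession.** When several rules of one axis fire, the
  highest priority wins. For subtypes, the specific patterns
  (small cell, adenocarcinoma, squamous cell carcinoma) all outrank the
  generic non-small cell pattern, so
  *"non-small cell carcinoma, favour adenocarcinoma"* codes as
  adenocarcinoma, and only reports matching nothing but the generic
  pattern become NSCLC-NOS. The small cell pattern uses a negative
  look-behind (`(?<!non-)small cell`) so that the generic phrase never
  fires it. Diagnostic categories follow a fixed six-level hierarchy
  (unclassified < cardiovascular < miscellaneous < other brain lesions
  < probable metastasis < primary brain tumour).
* **Negation scope.** A keyword inside a sentence (period/semicolon
  delimited) that carries a negation cue ("no ...", "negative for ...",
  "without ...") is ignored. The cue list is deliberately narrow so that
  stain-result sentences such as "p63: negative" are untouched. This
  minimal same-sentence rule is needed once distractor sentences appear
  in noisy text; anything more elaborate (dependency scope, double
  negation) is out of scope for a string-matching model.

Location coding returns the **set** of all matching site codes; stem
matching makes hyphenated dual-site phrasings ("temporo-parietal") map to
both lobes. No match yields `unknown`, which never co-occurs with a named
site. Non-lobar sites (brainstem, thalamus, dura, ventricles, ...) map to
a single `other` code. Reports firing two distinct organ keywords get
primary site `multiple/ambiguous` and fall out of the single-primary lung
cohort, mirroring the cohort definition.

## Immunostain refinement and biomarkers

Reports signed out as generic non-small cell carcinoma are refined with
TTF-1 and p63: TTF-1 positive with p63 *not positive* re-classifies as
adenocarcinoma; TTF-1 negative with p63 positive as squamous cell
carcinoma; anything else stays NSCLC-NOS, and any other reported subtype
passes through unchanged (the rule is idempotent and a missing TTF-1
never reclassifies). "Not positive" — negative *or not performed* — is a
deliberate reading: p63 was available in only ~20% of cohort cases, and
treating absent p63 as non-positive is the only interpretation under
which TTF-1 alone can resolve the large share of generic NSCLC that the
reference cohort reports resolved. p40 is parsed but excluded from
refinement (performed in only five cohort cases).

PD-L1 tumour proportion scores are binned `<1%` negative, `1–49%` low
positive, `>=50%` positive; the bin is a pure function of the TPS and the
boundary behaviour (0.9 / 1.0 / 49.9 / 50.0) is pinned by tests. A
malformed TPS (non-numeric, >100%) warns and leaves the marker not-done.
ALK is tabulated as the union of the immunostain and FISH results, the
immunostain taking precedence when both are present.

## Cohort tabulations

*Site-overlap matrix.* Cell (i, i) counts patients whose site set contains
site i; cell (i, j) patients whose set contains both. Derived rows: Sum,
Diagonal, Off-diagonal (= Sum − Diagonal), Pure (patients with exactly
that one site) and Mixed (patients with >1 site). When no patient carries
more than two codes, `Pure = Diagonal − Off-diagonal` — an identity the
generator respects by default (`max_sites = 2`), because it is what makes
the Pure/Mixed rows recoverable from a *printed* matrix without
patient-level data. A `max_sites = 3` stress mode exists; the identity
(and its test) does not apply there.

*Lesion counting.* A "lesion" is operationalised as a patient × distinct
**named**-site pair; patients whose set holds only `unknown`/`other`
contribute a single lesion to the merged "unknown/other" presentation
column. This is exactly the counting that reconciles the reference
cohort's tables: the named-site columns of the lesion table equal the
overlap-matrix diagonal, the unknown/other column equals the pure
unknown + pure other patients (3), and dropping it leaves the 252-lesion,
20-cell table used for the global test. Multiple specimens from one site
collapse to one lesion. Internal `other` and `unknown` codes are kept
separate everywhere else and merged only at presentation.

*Biomarker tables* follow the same lesion semantics on the site axis
(patients coded only unknown/other are excluded there, matching the
reference table footnote) and plain patient counting on the subtype axis.
The bundled reference tables carry a known internal inconsistency (the
biomarker overview lists 65 adequate EGFR results, the EGFR-by-site table
sums to 71); each table reproduces its own printed counts and the
discrepancy is documented rather than resolved.

## Exact inference

All tests are two-sided by **probability ordering**: the p-value is the
null probability of every fixed-margin table whose probability does not
exceed the observed table's, with a relative tie tolerance of 1e-7 (so
tables tied up to floating-point rounding count as ties). This is the
convention of the standard exact-test implementation in R, which produced
the reference p-values this package reproduces.

* `fisher_2x2()` sums the hypergeometric support directly.
* `fisher_rxc_exact()` enumerates every margin-compatible table in
  compiled code, walking columns left-to-right with each cell bounded by
  its remaining row margin (every completed prefix extends to exactly one
  table, so the walk visits exactly the valid tables). A
  dynamic-programming pre-count guards feasibility: above the ceiling
  (default 5e7 tables) the function refuses and directs the caller to the
  Monte-Carlo estimator. The 3 x 5 PD-L1-by-site table (n = 87) has
  36,761,908 margin-compatible tables and enumerates in under a second;
  the 4 x 5 subtype-by-site lesion table (n = 252) has ~5.7e13 and
  cannot be enumerated.
* `fisher_rxc_mc()` samples tables from the fixed-margin null with
  Patefield's sequential-conditional algorithm (base R's `r2dtable`) and
  applies the add-one correction
  `p = (1 + #{P(T) <= P(obs)}) / (reps + 1)`, so the estimate is never
  exactly zero; the binomial standard error is reported and a fixed seed
  reproduces the estimate bit-for-bit.
* `all_pairs_2x2()` decomposes an r x c table into every unordered
  row-pair × column-pair 2x2 table (60 of them for 4 x 5);
  `bin_pvalue()` applies the half-open five-colour bins
  (red [0, 0.05), pink [0.05, 0.1), white [0.1, 0.2),
  light blue [0.2, 0.4), dark blue [0.4, 1]); `heatmap_order()` gives
  deterministic complete-linkage/Euclidean leaf orders, with rows
  pre-sorted by label so the ordering is invariant to input permutation.

No multiple-testing correction is applied anywhere — the analysis being
reproduced applies none, and this is documented rather than "fixed".
Mid-p variants and odds-ratio confidence intervals are out of scope.

## The synthetic generator

`generator_config()` defaults *are* the cohort conditions the package is
designed around:

| Parameter | Default | Meaning |
|---|---|---|
| `category_mix` | met 0.185, unclassifiable 0.015, ... | diagnostic case mix of a brain-biopsy service |
| `primary_site_mix` | lung 234/511, ... | primary sites among confirmed single-primary metastases |
| `subtype_site_joint` | reference lesion-table proportions | refined subtype × site joint for lung metastases |
| `overlap_rate` | 36/234 | chance a lung patient carries two site codes |
| `ihc_availability` | TTF-1 206/234, p63 46/234, p40 5/234 | per-stain performed fractions |
| `reclass_rates` | AC 37/152, SCC 4/23 | share of refined AC/SCC reported as generic NSCLC |
| biomarker bands | 0 (2011–13), 0.064 (2014–15), 0.696 (2016–20) | any-marker testing by accession band |
| `multi_case_rate` | 27/511 | patients with a second, later case |

The probable-metastasis and unclassifiable rates come from the cohort's
reported case funnel; the split of the remaining mass across primary
brain tumours, cardiovascular and miscellaneous lesions, the non-lung
primary mix beyond the lung fraction, the ROS-1 testing rate and the ALK
IHC/FISH split are not published anywhere, so they are fixed once at
field-plausible values (a tertiary service dominated by primary brain
tumours; breast/melanoma/colorectal/kidney as the common non-lung
primaries; accession years uniform over 2011–2020). Biomarker positivity
rates given testing follow the reference biomarker overview; biomarker
status is drawn independently of site and subtype, so the synthetic
corpus deliberately carries **no** PD-L1-by-site association — those
statistics are validated from the bundled printed tables, not from
synthetic text.

Reported subtype and immunostains are generated *backwards* from the
refined subtype so that, by construction, applying the refinement rules
to the truth stains returns the truth refined label: a refined-AC case is
reported as generic NSCLC with TTF-1 positive (and p63 negative or
absent) with probability 37/152, and so on. Because those reclassified
cases force a stain to be present, the generator solves for the
conditional availability in the remaining cases so the corpus-wide
TTF-1/p63 availability still hits the configured targets; the suite
checks this within three binomial standard errors at n = 10,000.

Rendering is canonical at zero noise — every true label appears as
exactly its canonical keyword, which is what makes the 100% round-trip
audit a meaningful oracle for the classifier. One `lexical_noise` level
scales three independent degradation channels: synonym/abbreviation
substitution (some harmless, some outside the lexicon), negated
distractor sentences, and hyphenated dual-site phrasings. Accuracy is
monotonically non-increasing in noise (tested over seeds). What the
generator does **not** emulate: full gross/microscopic prose, OCR
artefacts, template boilerplate, misspellings, or correlated biomarker
biology — so a perfect round-trip on synthetic text bounds classifier
logic errors, not real-corpus accuracy (the cohort's reported real-text
location accuracy was ~94%, and nothing here certifies that number).

## Numerical and reproducibility choices

Every stochastic entry point takes an explicit integer seed
(`generator_config(seed=)`, `fisher_rxc_mc(seed=)`), and fixed seeds give
byte-identical corpora, estimates and pipeline outputs (the rendered
heatmap image excepted). Degenerate inputs are handled explicitly: empty
corpora are rejected at configuration time with the offending field
named; tables with zero row/column margins are reduced before testing
and collapse to p = 1 when fewer than two rows or columns survive; an
all-zero 2x2 extraction inside the all-pairs decomposition carries no
information and is likewise assigned p = 1; zero margins in conditional
distributions yield missing values, not errors.
Problem sizes used by the suite — corpora of 150–10,000 cases, 1e6
Monte-Carlo replicates for the global lesion-table test, full enumeration
for the PD-L1 table — were chosen so the whole suite runs on a single
CPU in a few minutes.

## Limitations

* The lexicon ships with canonical patterns sufficient for the synthetic
  idiom and the documented examples; deploying against a real laboratory
  corpus requires extending it (it is a plain TSV for exactly that
  reason).
* The classifier is sentence-local: negation scope across sentences,
  uncertainty hedges ("suspicious for"), and report-section structure
  are not modelled.
* Cohort funnel magnitudes from the real corpus (case counts, manual
  review scores, real-text accuracy) are inherently corpus-dependent;
  the procedures are implemented and exercised, the numbers are not
  reproduction targets.
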