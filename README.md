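# bmetlung

Classification and exact contingency inference for lung cancer brain
metastasis pathology reports.

## What this is for

Surgical-neuropathology archives hold, as free text, everything needed to
ask where lung cancer metastasizes in the brain and whether that
distribution depends on the histologic subtype (adenocarcinoma, squamous
cell, small cell, NSCLC-NOS) or on biomarker status (EGFR, ALK, RAS,
BRAF V600, ROS-1, PD-L1). `bmetlung` re-implements that
report-to-statistics pipeline as a reusable R package for pathology
informaticians and biostatisticians:

* **`classify_corpus()`** — a hierarchical free-text string-matching
  classifier: six mutually exclusive diagnostic categories, a primary
  site for probable metastases, a lung subtype honouring the
  supersession hierarchy (specific subtypes supersede the generic
  "non-small cell carcinoma" pattern), and a *set* of neuroanatomical
  location codes (hyphenated forms like "temporo-parietal" map to both
  lobes). Driven by an editable plain-text lexicon.
* **`refine_subtype()` / `parse_biomarkers()`** — immunostain-based
  refinement of generic NSCLC (TTF-1 positive & p63 not positive → 
  adenocarcinoma; TTF-1 negative & p63 positive → squamous cell
  carcinoma) and lung biomarker extraction with PD-L1 tumour proportion
  score bins (<1% negative, 1–49% low positive, ≥50% positive).
* **`overlap_matrix()` / `site_by_subtype()` / `biomarker_tables()`** —
  patient-level cohort tables: the symmetric site-overlap matrix with its
  Sum/Diagonal/Off-diagonal/Pure/Mixed semantics, and subtype-by-site
  lesion tables where a patient contributes one lesion per distinct
  named site.
* **`fisher_2x2()` / `fisher_rxc_exact()` / `fisher_rxc_mc()`** — exact
  inference with the two-sided probability-ordering rule: the
  Freeman–Halton r×c test by full enumeration in compiled code (with a
  dynamic-programming feasibility pre-count), and a fixed-margin
  Monte-Carlo estimator (Patefield sampling, add-one correction) for
  tables too large to enumerate. `all_pairs_2x2()`, `bin_pvalue()` and
  `heatmap_order()` build the binned, clustered p-value heatmaps.
* **`generate_corpus()`** — a synthetic report generator with ground
  truth, emulating the joint structure of a 234-patient lung
  brain-metastasis cohort (category mix, subtype×site joint, 36/234
  multi-site overlap rate, immunostain availability, year-banded
  biomarker availability), so the whole pipeline is testable without any
  real patient data.

The statistic at the core is Fisher's exact test generalised to r×c
tables: with fixed margins, table probabilities are multivariate
hypergeometric, P(T) = (∏ᵢ rᵢ! ∏ⱼ cⱼ!) / (n! ∏ᵢⱼ xᵢⱼ!), and the
two-sided p-value is Σ P(T) over all margin-compatible tables with
P(T) ≤ P(observed).

## Worked example

Reproduce the headline inference from the bundled reference-cohort
tables (no external data needed):

```r
library(bmetlung)
ref <- reference_cohort()

# site-overlap semantics: Pure/Mixed recovered from the printed matrix
s <- overlap_summary(ref$overlap)
s$pure
#> [1] 79 31 14 22 49  2  1
attr(s, "mixed")
#> [1] 36

# the simplified 4x5 lesion table: 252 lesions in 20 cells
simp <- simplify_table(ref$lesions, "unknown/other")
sum(simp)
#> [1] 252

# global subtype-by-site association (too many tables to enumerate:
# the feasibility guard reports ~5.7e13, so Monte-Carlo)
fisher_rxc_mc(simp, reps = 1e6, seed = 1)
#> Exact test (monte-carlo): p = 0.000699
#>   Monte-Carlo: reps = 1000000, se = 2.64e-05

# PD-L1 by site: full enumeration of 36,761,908 fixed-margin tables
fisher_rxc_exact(ref$biomarker_site$pdl1)
#> Exact test (exact-rxc-enumeration): p = 0.036539
#>   tables enumerated: 36,761,908

# all-pairs decomposition and heatmap bins
pm <- all_pairs_2x2(simp)   # 60 p-values, subtype-pairs x site-pairs
table(bin_pvalue(pm))
#>        red       pink      white light blue  dark blue
#>         13          4          6         11         26
```

The Monte-Carlo p of ~0.0007 says the lesion distribution over sites
differs by subtype far beyond what fixed margins explain (small cell
carcinoma piles into the cerebellum, adenocarcinoma into the frontal
lobe); the exact PD-L1 p of 0.0365 says PD-L1 status is likewise
site-dependent.

End-to-end on synthetic data:

```r
cfg <- generator_config(n_cases = 400, seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")
res$manifest$counts   # corpus -> patients -> metastases -> lung funnel
aud <- audit_agreement(classify_corpus(generate_corpus(cfg)$reports),
                       generate_corpus(cfg)$truth)
aud$accuracy          # all 1.0 at zero lexical noise
```

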