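---
title: "Sub-ontology functional analysis: model, choices, and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-ontology functional analysis: model, choices, and what the synthetic tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clonal mosaicism produces large chromosomal alterations that each affect
hundreds of genes, most of them rare across a cohort. A conventional
case/control test on one gene (or one GO term) at a time discards exactly
the rare events that may carry the biology. `subgofa` takes the opposite
route: it asks whether *patients resemble each other functionally* within a
delimited region of the Gene Ontology, and whether that resemblance
separates cases from controls.

## The procedure

1. **Segmentation.** Every GO term roots a *sub-ontology*: the term plus
   its full descendant closure over `is_a` and `part_of` edges
   (`enumerate_subgos()`). Other relationship types are ignored.
2. **Annotation.** Each sample's mosaic regions are intersected with a gene
   track (any overlap of at least 1 bp includes the gene; strand is
   ignored), and the sample inherits the union of its genes' GO
   annotations (`annotate_cohort()`).
3. **Similarity.** Within one sub-ontology, a sample's term set is
   restricted to the sub-ontology's nodes and compared with every other
   sample by best-match-average Lin similarity,
   `sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))`, where the
   most-informative-common-ancestor search is *confined to the
   sub-ontology*. This restriction is the heart of the method: inside
   sub-ontology *S*, the root of *S* has positive information content, so
   two patients sharing any function under *S* are visibly similar there,
   while in the global ontology that resemblance is flattened by the
   zero-IC namespace root.
4. **Clustering.** The pairwise similarity matrix becomes a distance
   matrix (`d = 1 - s`) and Ward linkage cuts the cohort into two groups
   (`ward_two_clusters()`).
5. **Testing.** The 2x2 group-by-phenotype table is evaluated with a
   two-sided Fisher's exact test; Benjamini-Hochberg FDR is applied across
   all *tested* sub-ontologies. Roots below the FDR threshold are reported
   as candidate disease-associated functions.

Two conventional baselines (`fisher_per_gene()`, `fisher_per_term()`) test
per-feature presence with the same Fisher/BH machinery, and
`detection_ratio()` scores any method's selected genes against a curated
disease-gene list.

## Information content

Methods of this class rarely pin down the IC corpus, so it is a choice
here: by default IC comes from the supplied gene-to-GO map
(annotations propagated to ancestors; `p(t)` = fraction of annotated genes
reaching `t`; `IC = -ln p`). Terms outside the corpus get add-one smoothed
content `ln(N + 1)` so they stay finite and maximally informative. A purely
topological fallback (`mode = "structure"`, `p(t)` = descendant share of
the namespace) is available when no corpus is trusted. The logarithm base
cancels in Lin's ratio.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_subgo_nodes` | 2 | smallest sub-ontology enumerated; a single-term sub-ontology reduces to term presence, which the per-term baseline already covers |
| `min_eligible` | 2 | samples with a non-empty restricted set required *per class* before a sub-ontology is tested; smaller tables are reported as `skipped` and excluded from the FDR family |
| `mica_scope` | `"subgo"` | confine the MICA search to the sub-ontology (the method's premise); `"global"` reproduces a conventional unrestricted similarity |
| `ward_method` | `"ward.D2"` | squared-distance Ward update on `d = 1 - s`; `"ward.D"` gives the classical update |
| FDR threshold | 0.05 (reporting) | a reporting flag, not part of the computation; sweeps are explicit via `threshold_sweep()` |

Samples whose restricted set is empty keep similarity 0 to everyone
(diagonal 0) and still enter the clustering — they collapse into one group
and the eligibility rule keeps them from driving degenerate tests.

## Numerical choices

* **Fisher's exact test** uses exact integer hypergeometric weights (built
  by Pascal-recurrence addition, every weight below 2^53) for table totals
  up to 55, so the two-sided "sum all tables no more probable than the
  observed" rule involves no floating-point ambiguity; larger tables use
  log-space sums with the customary 1e-7 relative tie guard. Zero-margin
  tables return p = 1 with a `zero_margin` flag.
* **MICA ties** (equal IC among common ancestors) resolve to the smallest
  term id, keeping runs bit-reproducible.
* **Degenerate similarity** (all pairwise distances equal) still clusters
  deterministically and is flagged `degenerate`.
* The per-sub-ontology loop shares one global MICA table across
  sub-ontologies and re-derives only those term pairs whose global MICA
  falls outside the current restriction; the best-match-average is a
  row-max table plus a matrix product. Both compiled kernels are checked
  in the tests against naive scalar implementations.

## What the synthetic generators emulate

The package carries its whole test surface: seeded generators for an
ontology (OBO 1.2, single namespace, term *i* drawing 1..`max_parents`
parents uniformly from earlier terms), a non-overlapping gene track, a
leaf-biased gene-to-GO map (annotation probability proportional to
`1 / (1 + #descendants)`, so rare specific terms exist), and a
case/control cohort in which a fraction `effect` of cases receives one
mosaic region re-centred on a gene annotated under a *planted* sub-ontology
root. Controls are drawn from a larger pool by sex and age-decade
stratified sampling with largest-remainder quotas
(`matched_control_sample()`), emulating matched-control construction; ages
are normal per class and the case class defaults (52% male,
67.25 +/- 9.5 years) follow a lung-cancer-like cohort profile.

Two frozen condition sets are used throughout the tests:

* **Default conditions** (`fixture_config()`): 200 samples (100 cases /
  100 matched controls from a pool of 300), 150 terms, 300 genes, 1-3
  mosaic regions of 2-8 Mb per sample on four 100 Mb chromosomes. The
  planted module is a compact root (around 6 nodes, 3-15 genes) chosen
  deterministically; at `effect = 1` the planted root ranks first by FDR
  with very small FDR, and at `effect = 0` no root reaches FDR 0.05.
* **Rare-function conditions** (`low_frequency_config()`): a sparser world
  (800 terms, 1000 genes, 1-2 annotations per gene, 1-2 regions of 1-3 Mb)
  with a *wide* planted module (20-40 genes under a root of around a dozen
  terms, each member term annotated to at most 5 genes) and `effect =
  0.35`. The 35 affected cases scatter across the module, so each
  individual signal term is carried by at most 10% of samples — too rare
  for the per-term baseline to reach FDR 0.3 — while the module as a whole
  still separates the classes. This is the regime the method is built
  for, and the setting where its detection ratio exceeds the baselines'.

The synthetic disease-gene list (the stand-in for a curated
disease-association catalogue) is defined as the genes annotated under the
planted root; all fixture files are labelled synthetic.

What these fixtures do **not** emulate: chromosome-arm hotspot structure,
mosaic cell fractions or dosage, realistic GO depth (the random DAG is
shallower than GO, so ancestors of a true signal root light up more easily
than in the real ontology), and gene-symbol synonymy. Passing tests
therefore demonstrate correctness of the machinery and the qualitative
low-frequency behaviour, not effect sizes on real cohorts.

## Calibration under the null

With `effect = 0` the planted mechanism is absent and cluster membership is
independent of the labels, so the cluster-by-phenotype table is
hypergeometric and the exact p-values are valid but *conservative*: a
two-sided exact test on a discrete 2x2 table puts mass exactly at 1 and
stochastically exceeds uniform at any sample size. Calibration is
accordingly checked one-sidedly — no excess of small p-values
(Kolmogorov-Smirnov, `alternative = "greater"`) — alongside the operational
check that no root reaches FDR 0.05. A two-sided uniformity test would
reject any exact discrete test and carries no information about spurious
findings.

## Design decisions that were genuinely open

* **Eligibility rule** (2 non-empty samples per class), the **distance
  transform** (`1 - s`), and the **Ward variant** (`ward.D2`) are explicit
  substitutes for choices the method class leaves unstated; each is a
  single switch so the alternatives remain reachable.
* **FDR family** = sub-ontologies actually tested in the run; skipped ones
  carry no p-value and would otherwise dilute the correction.
* **"Genes detected"** by the sub-ontology method = union, over
  significant roots, of genes whose annotation intersects the sub-ontology
  and that occur in at least one sample's region gene list — the
  permissive reading; the per-root gene sets are retained on the result so
  stricter readings can be derived.
* **Detection-ratio comparisons treat an empty selection as detecting
  nothing**: any positive ratio beats it. This mirrors reporting a
  "not applicable" outcome when a method rejects every feature.
* **Namespace coverage and leaf sub-ontologies** are exposed as options
  (`namespace`, `min_subgo_nodes`) rather than fixed, since the reference
  count of sub-ontologies does not pin them down.

## Problem sizes

The default test and acceptance conditions (200 samples, 95-100 tested
sub-ontologies; the rare-function world with around 500 tested
sub-ontologies) were chosen so that a full pipeline run completes in
seconds and the entire property suite in minutes on one CPU, while staying
at the sample-size cap the method targets (analysis datasets of at most
200 samples).

## Known limitations

* The upward "leak": ancestors of a genuinely associated root share its
  carriers and can also reach significance, enlarging the permissive gene
  union. On the shallow synthetic DAG this is pronounced; on the real GO
  the greater depth and noise attenuate it. The per-root gene sets allow
  post-hoc pruning (e.g. keeping minimal significant roots).
* Fisher p-values on small or lopsided cluster splits are coarse; with
  `k = 2` fixed, a cohort with more than two latent groups will split
  along its strongest axis only.
* Gene-symbol matching in detection ratios is case-insensitive string
  equality; no synonym resolution.
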