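---
title: "Vote-counting multi-omics meta-analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vote-counting multi-omics meta-analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsvote)
library(dplyr)
```

## The problem

Circulating biomarkers of coronary artery disease (CAD) have been reported
across microRNA, protein and metabolite studies that differ in platform,
compartment (plasma, serum, platelets), cohort size and statistical
reporting. Classical effect-size meta-analysis (random-effects pooling,
Stouffer weighting) breaks down here: the molecule coverage across studies is
extremely sparse, detection platforms are incommensurable, and most studies
publish only the differentially expressed (DE) tail of their measurements.
`omicsvote` implements the alternative that works under those conditions:
**vote counting** over per-study DE lists, with direction-frequency
stratification and a majority consensus rule, followed by pathway
over-representation, dimensionality reduction of the cross-study fold-change
matrix, and assembly of a heterogeneous molecular network annotated with the
meta-analysis results.

## Harmonisation model

Every input table row is one molecule's differential expression in one study:
a signed fold-change, a p-value in (0, 1], an omics layer (MIR, GENE, PRO,
MET), plus compartment and species annotations.

**Fold-change canonicalization.** Source tables mix two dialects: signed
(−1.4 means a 1.4-fold decrease) and ratio (0.5 means a 2-fold decrease).
Both are mapped onto a canonical signed value with magnitude ≥ 1 and a
direction in {up, down, none}; a ratio r < 1 becomes direction *down* with
magnitude 1/r. Canonicalization happens on read, **before** any averaging —
the order matters because averaging ratios on their raw scale would bias
towards up-regulation, and we fixed the canonicalize-first convention once.

**Within-study redundancy.** When one study reports the same molecule
several times, the reports are combined by averaging the signed fold-changes
and combining p-values with Fisher's method,
\(X = -2 \sum_i \ln p_i \sim \chi^2_{2k}\).
Averaging is on the **linear signed scale** by default because the source
tables report linear fold-changes and the frequency stratification below
operates on linear magnitudes; a `fc_average = "log2"` switch averages
signed log2 fold-changes instead. Groups whose reports disagree in direction
can average to a magnitude below 1; such groups are reported as direction
"none" with a warning, since the curated corpora this package models never
exhibit that case and any silent choice would be arbitrary.

**Synonyms.** Molecule aliases resolve through a flat synonym table
(one synonym per line, each claimed by exactly one cluster).  Matching is
case-insensitive after whitespace normalisation, because published tables
mix casing styles for the same entity (e.g. `hsa-mir-144` next to
`hsa-miR-505-3p`, `ApoA-IV` next to `APOA-IV`). Unresolvable names are
returned, never dropped.

## The meta-analysis

Four parameters matter; all are carried by a `threshold_scheme`:

| parameter | default | meaning |
|---|---|---|
| `p_cutoff` | 0.05 | records must satisfy p < 0.05 (strict) |
| `de_fc_cutoff` | MIR/GENE 2.0, PRO 1.5, MET 1.3 | layer-specific \|FC\| cutoff (inclusive), the `case_study` preset |
| `strata` | 1.3, 1.5, 2.0 | fold-change grid for the frequency table |
| `min_votes` | 2 | minimum number of study DE lists containing a molecule |

A second preset, `curation`, relaxes the protein cutoff to 1.3 (the
database-curation rule). Cutoff comparisons are **inclusive** (≥): where
published tables print a ">" in a header but "≥" in the methods text, the
methods wording wins, and fixtures avoid boundary values so the choice is
observable only in unit tests.

`filter_de()` applies the gates; `vote_count()` tallies, per molecule, the
number of distinct study DE lists containing it (studies, not records — a
molecule reported twice in one study contributes one vote).
`regulation_frequency_table()` then computes, over *all* p-gated reports of
the retained molecules, the percentage of reports that are down- or
up-regulated at magnitude ≥ s for each stratum s; the remainder is "not
regulated" (NR) at that stratum. "Reported" counts every contributing study,
including reports below all strata — this is forced by published rows that
are 100% NR at every stratum yet carry a report count of 2. Percentages are
rounded half-away-from-zero to one decimal (28.6 = 2/7, 14.3 = 1/7), the
convention of the published tables.

**Consensus direction.** A direction wins when its report frequency reaches
the prevalence threshold (60%; thresholds ≤ 50 are rejected because both
directions could tie). The published rule does not say which stratum the 60%
is read at; we default to each molecule's **layer-specific DE cutoff**
(2.0 for miRNA/gene, 1.5 for protein, 1.3 for metabolite under
`case_study`), which makes the consensus consistent with the evidence that
retained the molecule in the first place, and we expose a fixed `stratum`
argument for the alternative reading. The stratum actually used is logged in
every output row.

**Overall fold-change.** The value overlaid on the network is the mean of
the signed fold-changes of the reports agreeing with the consensus
direction; discordant molecules are flagged (`NA`), not dropped.

```{r worked}
records <- canonicalize_records(tibble::tibble(
  study_id = sprintf("s%d", 1:7), molecule_id = "APOB", layer = "PRO",
  fc = c(-1.6, -1.4, -1.25, -1.1, -1.0, 1.1, 1.2), p_value = 0.01
), "signed")
regulation_frequency_table(records)
```

## The synthetic-corpus generator

The generator (`corpus_config()`, `generate_corpus()`) emulates the shape of
the curated CAD subset, not raw instrument output: it starts at the
per-study DE-table level, as the corpus it models does.

* **Study counts** default to the CAD subset: 2 miRNA, 9 protein,
  10 metabolite studies (GENE 0), 50 molecules per layer.
* **Missingness** is independent Bernoulli per (study, molecule) with
  `detection_prob` (default 0.5) — the corpora this emulates have a high
  degree of missing values; independence is a simplification (real
  missingness correlates with platform).
* **Planted DE molecules** (fraction 0.3) draw |log2 FC| from a Normal(2,
  0.75) truncated positive — fold-changes centred on 4×, spanning roughly
  1.5–16×, consistent with what curated DE reports show, microRNAs
  especially — and show the planted direction with probability
  `direction_concordance` (default 0.8, matching the visibly contradictory
  regulation in published report tables). Their p-values are
  Beta(0.5, 1) rescaled below 0.05, so planted molecules always pass the
  p-gate.
* **Null molecules** draw |log2 FC| half-Normal with sd 0.15 and p-values
  Uniform(0, 1).

The log-normal magnitude / beta p-value noise model is this package's own
choice — the corpora it models come with no generative model — selected
because it is standard DE-simulation practice and admits analytic
cross-checks: the null rate of passing `filter_de` is exactly
\(0.05 \cdot 2(1 - \Phi(\log_2 c / 0.15))\) for cutoff c, which the test
suite verifies empirically over 200 replicates. Identical configuration and
seed reproduce a byte-identical corpus.

What passing synthetic benchmarks does **not** show: robustness to
correlated missingness, platform batch effects, within-study p-value/FC
dependence, or synonym noise — real corpora have all four, the generator has
none.

## Enrichment

`hypergeometric_ora()` scores each set by the upper tail
\(P(X \ge \text{hits})\) of the hypergeometric law with population
|universe|, successes |set|, draws |query|. The universe defaults to the
union of the loaded collection's members because the background used by
external web services is generally unstated; supply an explicit universe to
change that. Mixed gene/compound queries should be scored as two
independent runs against a gene collection and a compound collection — the
published dual-column layout this mirrors scores them separately.
Benjamini–Hochberg adjustment is optional; raw p-values are the default
report, matching the published tables.

The pathway **topology score** is the sum over matched nodes of the degree
centrality deg(v)/(n−1). It is additive, label-invariant, and can exceed 1
when several matched hubs are present. The exact normalisation used by
external services is not recoverable from their outputs, so published
topology values are treated as non-reproducible; only the score's properties
are asserted.

## Dimensionality reduction

`build_de_matrix()` arranges signed log2 fold-changes as molecules ×
studies, keeps molecules reported in ≥ 3 independent studies (default), and
imputes missing cells as exactly 0 with a parallel mask — zero is "no
evidence of change" on the log2 scale, and the mask keeps imputation
reversible and auditable.

PCA runs on column-centered, non-standardised data (covariance PCA) with a
`standardize` switch, since the convention of the external tool being
emulated is unstated; variance fractions sum to 1 and are checked against a
direct eigendecomposition of the covariance in the tests. NMDS minimises
Kruskal stress-1 over monotone-regressed disparities of Euclidean distances
(via vegan's engine), best of 20 seeded random restarts; stress is
non-increasing in the embedding dimension. Published full-database variance
fractions depend on an unpublished 654 × 75 matrix and are not reproduced
here; the properties are.

## Network assembly

Edge evidence arrives as SIF or TSV files typed by kind (ppi,
miRNA-target predicted/validated, TF-target, gene-enzyme, enzyme-reaction,
reaction-compound, gene-disease). Loading deduplicates keeping the maximum
confidence and skips (with a count) edges whose endpoints do not resolve.
Protein-protein interaction edges require a confidence and are filtered at
≥ 0.7 (inclusive — a "minimum confidence score of 0.7" includes 0.7).

The **inverse-regulation filter** keeps a miRNA-target edge only when the
two endpoints carry opposite consensus directions — the biologically
credible configuration for a repressor. "Highly expressed" miRNAs have no
published cutoff, so the filter uses consensus direction only by default and
exposes an optional |overall FC| floor. `assemble_network()` types nodes
from the edge kinds touching them, attaches direction, overall fold-change
and report count to query nodes, marks provenance (query / inferred / gda),
and prunes isolated inferred nodes. Gene-disease rows add the gene
(provenance `gda`) and the disease term; the disease term becomes a node of
kind `disease` — an extension of the molecular kind set, chosen so that
contextualisation edges have a well-defined endpoint. Reaction nodes may
connect only to enzymes and compounds, and exports (GraphML, SIF + node
attributes) are sorted, hence byte-stable.

## Pipeline, determinism, problem sizes

`pipeline_config()` (buildable from YAML) collects every tunable;
`run_stage()` chains simulate → harmonize → meta → enrich → dimred →
network, writing a manifest (artifact hashes, seed, package version,
resolved config) per stage. All randomness flows from the single top-level
seed; rerunning a stage on identical inputs reproduces identical artifacts.
There is no shell entry point: the package's functions and this vignette are
the interface, which is how an analysis package of this kind is used.

The test suite exercises deliberately modest problem sizes — corpora of
15–21 studies and 45–150 molecules, 50-seed recovery benchmarks, 200-replicate
null calibrations, enumeration oracles on universes ≤ 25 — chosen so the
full suite completes in well under a minute per file while still giving the
Monte-Carlo comparisons a few thousand trials each.

## Known limitations

* Vote counting discards effect-size precision by design; it is the right
  tool for heterogeneous sparse corpora, not a replacement for
  random-effects models where those apply.
* The consensus stratum choice (layer cutoff) is a convention; published
  sources are ambiguous, and a different stratum can flip borderline calls.
* The generator's independence assumptions (above) make synthetic
  benchmarks optimistic relative to real curated corpora.
* Synonym resolution is exact-match after normalisation; no fuzzy matching,
  no ortholog inference — synonym tables are taken as given.
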