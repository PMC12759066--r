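---
title: "Methods: scoring AlphaFold-Multimer interfaces across ORC orthologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring AlphaFold-Multimer interfaces across ORC orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(afmetrics)
```

## 1. Problem and model

The package supports a comparative screen over metazoan origin recognition
complex (ORC) subunits. Some lineages have lost ORC6; the screen asks whether
the ORC6-binding domain (ORC6-BD) of ORC3 degenerates in those lineages and
whether an alternative ORC3-tether–MCM2 interface appears in predicted
complexes. Three kinds of evidence are combined:

* **presence/absence** of subunits from homology-search hit tables,
* **domain conservation** from alignments and predicted monomer structures,
* **interface support** from five-model AlphaFold-Multimer predictions.

Everything downstream of the predictor is deterministic given the inputs:
the same files and parameters always give the same calls.

## 2. Interface scoring model

### 2.1 Contacts

A residue pair (one residue per chain) is a *contact* when any pair of
non-hydrogen atoms lies strictly below the cutoff distance
(`contact_cutoff = 8` Å). Strictness matters: a pair at exactly 8 Å is not a
contact, which makes the rule checkable against brute-force enumeration with
no boundary ambiguity. Hydrogens are excluded because predicted models place
them inconsistently and most depositions omit them.

### 2.2 Confidence filtering

Two filters remove low-confidence contacts:

* **pLDDT** — a contact is dropped if either residue has pLDDT below
  `plddt_min = 50` (kept at exactly 50). pLDDT is read from the PDB B-factor
  column; atoms of one residue must agree within 0.01 or the reader errors,
  since disagreement indicates a malformed file rather than real signal.
* **pAE** — the predicted aligned error is directional; the two directions
  are combined (`pae_combine = "mean"` by default, `"max"`/`"min"`
  selectable) and the contact is dropped when the combined value exceeds
  `pae_max = 15` Å (kept at exactly 15). The mean is the default because it
  uses both directions without letting a single noisy direction dominate.

### 2.3 Canonical restriction

`restrict_canonical()` keeps only contacts whose residue on the designated
chain falls inside a stated domain window (ORC6-BD or the C-terminal
tether). An absent window keeps nothing: a lineage without the domain cannot
have a canonical interface by definition.

### 2.4 Average-models score

Over the union $U$ of filtered contacts across the $n=5$ models, with
$m(c)$ the number of models containing contact $c$:

$$ S = \frac{1}{n}\cdot\frac{\sum_{c \in U} m(c)}{|U|}, \qquad S = 0 \text{ when } U = \emptyset. $$

$S$ lies in $\{0\} \cup [1/n, 1]$; it is exactly 1 when all models agree on
one contact set and exactly 0 when nothing survives filtering. A prediction
is *confident* when $S > 0.5$ strictly — at least a majority-model average
support. The interface pAE reported alongside is the mean combined pAE over
contact instances (union-unique pooling is available), `NA` when there are
no contacts.

```{r}
pred <- gen_multimer(fixture_spec(interface_pairs = cbind(5:10, 5:10),
                                  shared_fraction = 1, seed = 7))
dom <- domain_range(pred$target_id, "ORC6_BD", 1, 30)
score_target(pred, dom, score_config(), domain_chain = "A")$average_models
```

## 3. Ortholog presence screen

Hit tables (one row per homology-search hit) are reduced to a
presence/absence matrix by `call_orthologs()`:

* **Identity floors** separate orthologs from paralog noise: 30% for ORC
  subunits, 50% for MCM2, overridable per subunit (a `.default` entry sets
  the fallback). MCM2 is held to a higher floor because MCM paralogs
  (MCM3–7) are globally similar and cross-match at moderate identity,
  whereas ORC subunits are mutually dissimilar.
* The **representative** accession per species and subunit is the surviving
  hit with the highest query coverage, ties broken by identity then
  accession, making the choice deterministic.
* A taxon group is **excluded** from downstream comparisons when two or more
  of ORC1–6 are absent across the whole group — pervasive absence signals
  poor sampling rather than biology. Missing only ORC6 is precisely the
  signal of interest and never triggers exclusion.
* `classify_orc6_status()` calls a group ORC6-negative only when ORC1–5 are
  each found somewhere in the group; otherwise the group is *unresolved*,
  because an incomplete proteome cannot distinguish loss from non-detection.

`sequence_qc()` drops sequences with ambiguous X residues and partial
sequences that do not cover the region under study (the ORC3 insertion
domain, or the MCM2 N-terminus). Partial ORC3 sequences are eligible only in
data-poor groups (fewer than 10 members), where discarding them would cost
more than their truncation risk.

## 4. Alignment domain mapping

`map_range()` maps a reference residue window through alignment columns to a
target sequence: the target span runs from the first to the last non-gap
target position under the window's columns, so insertions inside the window
are included. An all-gap target window means the domain is absent.
`percent_identity()` divides matches by the number of reference non-gap
positions in the window (case-insensitive; X never matches), so target
insertions do not inflate the denominator.

## 5. Structural conservation

* `superpose()` implements Kabsch superposition via SVD and returns the
  rotation, translation, and RMSD; it accepts models or raw coordinate
  matrices.
* `detect_helices()` computes backbone dihedrals and marks a residue
  helical when $\varphi \in [-100, -30]$ and $\psi \in [-80, -5]$; runs
  shorter than `min_helix_len = 6` are discarded as incidental turns.
* `classify_orc6bd()` calls the domain *conserved* when the window exists,
  contains the expected three helices, and is not expanded beyond
  `insertion_tolerance = 0.3` (30%) relative to the reference length;
  *absent* when the window is missing; *non_conserved* otherwise.
* `classify_tether()` requires only sufficient length
  (`tether_min_len = 12`) and no helical architecture, because the tether
  is an extended segment.
* `plddt_summary()` averages pLDDT over a window and flags a reliable
  backbone at mean pLDDT of 70 or more (inclusive), the conventional
  "confident backbone" boundary.

## 6. Statistics

`mann_whitney()` computes the midrank Mann–Whitney U and an exact two-tailed
p-value by enumerating group assignments whenever the smaller group has at
most 8 observations and the enumeration stays below 5×10^5 combinations;
otherwise it uses the normal approximation with tie and continuity
corrections. The exact path handles ties, so two identical groups give
p = 1 exactly. p-values are reported rounded to 4 decimals alongside the
unrounded value. `taxon_heatmap()` tabulates category percentages per taxon
group (summing to 100 within a group); `classification_report()` gives the
confusion counts and accuracy of confident-interaction calls against ground
truth.

## 7. Synthetic fixtures: what they emulate

Real AlphaFold outputs are large and their ground truth is unknown, so the
test suite and the demo cohort run on generated fixtures whose truth is
exact *by construction*:

* `gen_multimer()` writes five PDB models plus confidence JSON per target.
  Designated interface residue pairs are placed 5 Å apart, all other
  inter-chain pairs at least 10 Å apart, so the 8 Å rule recovers exactly
  the designed contacts. `shared_fraction` controls how many contacts all
  five models share versus appear in a single model, giving a closed-form
  expected score. Decoy contacts carry low pLDDT or high pAE and must be
  invisible after filtering. Each model receives a random rigid motion
  (seeded), which the scoring must be invariant to.
* `gen_domain_structure()` builds backbones from ideal dihedrals
  (helix $\varphi=-57°, \psi=-47°$; coil $\varphi=-140°, \psi=150°$) via
  internal-coordinate chain construction, producing three-helix, degenerate
  (two-helix), or no-domain architectures.
* `gen_alignment()` and `gen_hit_table()` produce alignments with controlled
  degeneracy and hit tables with known true/false positives.

Fixture sizes (30-residue chains, 12-species cohorts) are package choices
that keep tests fast while exercising every code path; all thresholds above
are scientific parameters, not tuned values.

## 8. Demo pipeline

`run_pipeline(demo_cohort_config(out, seed))` runs six stages — fixture
generation, presence screen, domain mapping, structural conservation,
interface scoring, statistical summary — over a 12-species, 4-taxon cohort
designed to mirror the biological contrast (ORC6-positive vertebrates and
molluscs with conserved domains and shared interfaces; ORC6-negative
nematodes and tardigrades with absent or degenerate domains and no
surviving interface). It writes TSV tables per stage and a manifest with
MD5 checksums; identical seeds reproduce outputs byte for byte.

## 9. Open modelling choices

Where the underlying science does not dictate a unique convention, the
package picks one and documents it: the mean as default pAE combination;
strict inequalities at every filter boundary; counting a contact's support
per model instance rather than per unique pAE value; calling unresolved
rather than negative on incomplete proteomes. Each choice is encoded in a
single parameter or function so alternatives can be explored without
touching the scoring core.
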