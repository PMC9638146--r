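---
title: "emPAI-based EV proteome comparison: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{emPAI-based EV proteome comparison: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evquant)
```

`evquant` compares the proteomes of two groups of label-free MS/MS runs —
typically extracellular-vesicle (EV) preparations from two mouse strains —
using only peptide identification counts. This vignette documents the models
behind each stage, the parameters that matter, and the choices made where
the design was genuinely open.

## Observable peptides and emPAI

Spectral-count quantification needs a per-protein denominator: how many
peptides *could* have been observed. We digest each database protein in
silico with trypsin (cleavage C-terminal of K or R, suppressed before P —
the Keil rule; a `trypsin/P` variant without suppression is selectable,
since search engines support both and published searches rarely state which
was used). Peptides with up to `max_missed_cleavages` uncut internal sites
are enumerated, and `N_observable` counts those whose mass (monoisotopic by
default) lies in the observable window.

Defaults, all configurable through `digest_params()`:

| parameter | default | rationale |
|---|---|---|
| protease | trypsin (Keil) | conventional tryptic-digest rule |
| missed cleavages | 1 | common database-search setting |
| mass window | 500–3000 Da | typical LC-MS/MS precursor range |
| mass type | monoisotopic | standard for peptide-level work |

Peptides containing residues without a defined mass (B, Z, X, U, O) are
excluded from the count — and reported — rather than assigned a guessed
mass. The initiator methionine is not removed and N-terminal modifications
are ignored; for counting purposes these choices shift `N_observable` by at
most one peptide. Distinctness is by peptide coordinates `(start, end)`, so
a repeated sequence at two positions counts twice, consistently between the
digestion routine and the brute-force oracle used in the tests.

With `N_observed` distinct identified peptides in one run,

\[ \mathrm{emPAI} = 10^{N_\mathrm{obs}/N_\mathrm{obsble}} - 1, \qquad
   M\% = 100 \cdot \frac{\mathrm{emPAI}}{\sum \mathrm{emPAI}} . \]

Normalization is **per run**, over the proteins identified in that same run,
so each run's M% sums to 100; this treats each MS/MS search as its own
compositional measurement. A pooled mode (normalizing to the grand total
over all the group's runs) is available behind `normalize = "pooled"` for
sensitivity analysis, because the alternative reading — one normalization
across pooled searches — cannot be ruled out in published descriptions.

## Replicate aggregation: missing is not zero

A protein detected in only some of a group's runs has a mean M% computed
over those runs only, with its own sample size `n` (at most the group's run
count) and SEM. Imputing zeros would conflate abundance with detectability,
which the detection model below shows are linked but not identical. The SEM
of a protein seen in a single run is reported as `NA` — one observation
carries no spread information.

## Two-group comparison

Detected proteins are partitioned into unique-to-A / shared / unique-to-B
("unique" = detected in ≥ 1 run of one group and none of the other; no
minimum-`n` requirement, matching how identification Venn diagrams are
constructed). For shared proteins the fold change is the **ratio of group
mean M%** (not the mean of per-run ratios, which would weight runs
unequally and is undefined for partially overlapping detections). The
absolute fold change `max(r, 1/r) = 2^|log2 r|` folds both directions onto
a common scale ≥ 1; the direction is kept separately as the abundance
class. The cutoff 1.3 is inclusive (`abs_fc >= cutoff`), and exact ties
(`ratio == 1`) have no direction, so they stay below the cutoff even at
`cutoff = 1`.

Per-protein tests are unpaired two-sample t-tests on the detected-run M%
values, pooled-variance by default (the row-wise default of common
multiple-t-test spreadsheet tools), Welch selectable. A protein needs ≥ 2
detected runs per group to be testable. When both groups have zero variance
and equal means, p = 1 by convention (reported). The default significance
gate is the unadjusted per-comparison `alpha = 0.05`; Holm–Šidák
(step-down, `1-(1-p_{(i)})^{m-i+1}` with monotonicity enforcement,
implemented here because `stats::p.adjust` does not provide it) and BH are
available where family-wise or FDR control is wanted. The volcano flag
combines both thresholds — `p < alpha` **and** `abs_fc >= cutoff` — since
either alone admits proteins the other filters out.

Signature matching counts signature members (case-insensitive gene symbols,
whitespace-stripped) in the increased and decreased classes, with
percentages of the signature size; composition profiles renormalize a
protein family's mean M% to shares of the family total.

## Enrichment and kappa grouping

Over-representation uses the one-sided hypergeometric upper tail per term,
with each term intersected with the background first. The default
background is **all proteins quantified in the experiment**, not a
whole-genome list: EV preparations sample a restricted proteome, and a
genome-wide background would inflate every term. FDR is
Benjamini–Hochberg (Bonferroni selectable).

Significant terms are grouped by Cohen's kappa ≥ 0.4 (the conventional
default of kappa-grouping enrichment tools) computed between binary
term-membership vectors over the union of genes annotated to any
significant term. Groups are **connected components** of the kappa graph —
a deliberate simplification of iterative leading-term merging heuristics:
it is order-independent, deterministic, and refines monotonically as the
threshold rises, three properties the tests rely on. The lowest-p term of
each component is its representative and names the group. When the two
pairwise membership patterns agree perfectly and chance agreement is also
perfect (`Pe = 1`), kappa is defined as 1 if observed agreement is perfect
and 0 otherwise. Terms are labelled cluster-specific when strictly more
than 60% of their genes overlapping the two clusters' union come from one
cluster.

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` emulate the replicate structure the
analysis assumes: two groups of 9 and 13 runs (the kind of unbalanced
replicate design these EV studies use), true molar fractions drawn
log-normal(0, 1) and renormalized, a fraction (default 10%) of proteins
with a planted absolute fold change (default 3, half up, half down in group
A), and abundance-dependent detection: each observable peptide of a protein
with molar fraction `c` is detected independently per run with probability

\[ p = 1 - e^{-k c}, \]

the simplest saturating abundance–detection link consistent with emPAI's
premise. A protein enters a run's table when ≥ 1 peptide was detected
(`min_peptides` raises the evidence threshold). The default `k = 18` was
calibrated once, from the closed-form protein-level detection probability
`1 − exp(−k·c·N_observable)` at the default configuration, so that the
median protein is identified in ~60–80% of runs — reproducing the variable
per-protein `n` seen in real replicate tables (median ≈ 0.70, IQR ≈
0.40–0.89 at 500 proteins).

What the generator deliberately does **not** model: run-level batch
effects (detections are independent across runs; a run-effect multiplier is
a documented extension point), shared peptides between proteins, spectrum-
level noise, retention-time structure, and decoy/FDR filtering upstream of
the identification tables. Tests passing on this generator therefore
validate the quantification and inference chain under clean replicate
structure, not robustness to correlated run effects or protein-inference
ambiguity.

Simulation studies in the test-suite and acceptance script use 40–500
proteins and 2–13 runs per group; the 500-protein, 9-vs-13 design is the
package's reference study size, chosen to match the replicate structure the
pipeline targets while keeping each simulated study comfortably
reproducible on a laptop.

## Numerical choices and degenerate inputs

- emPAI is undefined for `N_observable = 0`; such proteins are dropped from
  quantification with a warning rather than failing the group.
- M% normalization errors on an all-zero run (nothing identified with
  positive emPAI).
- `abs_fc` is computed as `pmax(ratio, 1/ratio)` rather than
  `2^abs(log2(ratio))` to avoid round-trip floating-point error at cutoff
  boundaries; the two are mathematically identical.
- Adjustment procedures leave `NA` (untestable) p-values untouched and
  exclude them from the family size `m`.
- Kappa grouping breaks representative ties by the first (lowest-p) term in
  the result's sort order, which is itself deterministic (p, then term id).
- All report writers emit UTF-8 TSV with "." decimals and no timestamps, so
  a rerun with identical config and seed is byte-identical.

## Known limitations

- Protein inference is out of scope: accessions are taken as given, shared
  peptides are not reassigned.
- The t-tests assume approximate normality of per-run M%; with very few
  detected runs the tests are underpowered, and proteins detected in < 2
  runs per group are reported untested rather than forced through.
- Compositional coupling: because M% sums to 100 within a run, a large
  planted change in abundant proteins slightly shifts all other proteins'
  M%; the null false-positive rate is controlled in the tests under the
  default design, not under extreme compositions.
- Enrichment treats gene sets as flat symbol lists (GMT); ontology
  hierarchy and term fusion are not modelled.
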