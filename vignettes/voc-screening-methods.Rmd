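---
title: "Methods: VOC profiling, control-anchored triage, and contact-area fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VOC profiling, control-anchored triage, and contact-area fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocscreen)
```

This vignette documents the models, parameter choices and numerical
decisions behind `vocscreen`, in the order the pipeline runs.

## 1. VOC profile summarization

The input is a compound × sample table of percent abundances from a
headspace GC-MS experiment, with `ND` marking compounds not detected in a
sample. Two conventions govern all downstream arithmetic:

* **Presence and ranking treat `ND` as missing.** A compound's presence
  count and its per-sample rank only consider samples where it was
  actually detected.
* **Abundance-weighted aggregation treats `ND` as zero.** When pooling
  abundance across samples (`mean_abundance()`, group summaries, the
  molar-content share), an undetected compound contributes nothing, which
  is the natural reading of a detection limit in share-of-content
  statements.

Abundance columns are used exactly as printed and are *not* renormalized
to 100 %: in the packaged table, column A.3 sums to roughly 112 %, and
since the normalization basis of the source percentages is not stated,
silently rescaling would manufacture precision that the data do not
carry. Chemical class comes from an explicit class column, never from the
molecular formula: a C15H24 formula is compatible with non-sesquiterpene
skeletons, so formula-based inference could silently misclassify.

Raw peak filtering keeps peaks with RSI > 600 (spectral-library match
quality) and S/N > 50 dB. Both inequalities are **strict**, matching the
"higher than / above" semantics of the thresholds; `gen_peak_table()`
plants rows exactly at 600 and at 50 to pin this behaviour down.

One quirk of the packaged table is preserved deliberately: the narrative
accompanying the source data calls 3-Carene the *second* most abundant
compound of sample A.2 at 34.8 %, but in the printed column 34.8 % is the
largest value. The table ships cell-faithful; the discrepancy is noted in
the test suite rather than patched in the data.

## 2. Control-anchored triage

Docking scores (kcal/mol, more negative = stronger predicted binding) for
the first three poses of every ligand at a site are treated as replicates
in a one-way ANOVA, followed by all-pairs Tukey HSD and a compact letter
display (CLD). This is a deliberate, documented abuse of the ANOVA
machinery: poses of one ligand are pseudo-replicates of a single search,
not independent measurements, so the letters are a triage heuristic and
not an inferential claim about true binding free energies.

The CLD uses the insert-and-absorb algorithm: start with all ligands in
one letter column; for each significantly different pair, duplicate every
column containing both and strike one member from each copy; absorb
columns that became subsets of others. The result guarantees both
directions — two ligands share no letter *iff* their Tukey-adjusted
p-value is below α — and the test suite checks this equivalence against a
studentized-range computation done by hand from the group means and
pooled error mean square. Letters are assigned in ascending-mean order
(letter `a` starts at the strongest binder); exact mean ties are broken
by ligand id so the display is deterministic.

The classification rule is anchored on the controls:

* the **top anchor** is the positive control with the lowest (most
  negative) mean score;
* the **worst anchor** is the negative control with the highest mean;
* a candidate is **TOP** if it shares ≥ 1 letter with the top anchor,
  **WORST** if it shares ≥ 1 letter with the worst anchor, otherwise
  **MIDDLE**; sharing with both anchors resolves to the nearer mean, an
  exact tie to MIDDLE.

"Closeness to the anchors" was genuinely open to interpretation;
letter-sharing was chosen because the letters are precisely what the
ANOVA grouping of such screens reports, making the rule reproducible from
published material alone. Controls and candidates enter one joint ANOVA
per site — the anchors need letters, which they can only get inside the
same model. The significance level defaults to α = 0.05 (conventional;
the source analyses do not state one).

`cross_site_overlap()` compares label sets across sites and flags the
specific pattern of a ligand TOP in exactly one site but WORST in all
others — the signature of a potentially site-selective binder.

The headline quantity "share of molar content able to bind" depends on
two unstated choices: which groups count as binding (TOP only, or
TOP + MIDDLE) and how sites combine (any site, all sites, one site).
`molar_content_share()` therefore exposes both as explicit arguments and
the package asserts no default claim; widening either choice can only
grow the share, which the tests verify.

## 3. Descriptor correlograms

`correlogram()` computes Pearson r and two-sided p per (descriptor, site)
on pairwise-complete observations, requiring at least 3 pairs; a
zero-variance vector yields `NA`, never 0, because "no measurable
correlation" and "undefined correlation" are different statements. No
multiple-testing correction is applied by default — the correlogram is a
descriptive screen — but Benjamini–Hochberg is available via `p_adjust`.
Two variants exist: `WITH_CONTROLS` uses all docked ligands;
`CANDIDATES_ONLY` restricts to the profiled compounds, whose vectors are
strict sub-vectors of the former.

`compute_basic_descriptors()` is best-effort plumbing, mirroring a
workflow where authoritative descriptors come from dedicated external
calculators and are *ingested* via `load_descriptors()`. It computes only
what a single conformer supports deterministically: molecular weight,
N+O acceptor counts, donor counts (requiring explicit hydrogens),
rotatable bonds (distance-perceived bonds, acyclic = graph bridges,
terminal bonds excluded), and `max_length`, the maximum pairwise
interatomic distance of the conformer *as given* — no conformer search,
for determinism. A proposed "extensibility" descriptor has no defining
formula in the source material and is not implemented.

## 4. Probe-excluded contact areas

The contact-area method referenced by the source analyses is described
only semantically (null area ⇔ an interposable water molecule; larger
area ⇔ tighter packing), so the geometric definition here is this
package's own reimplementation choice, selected because it reproduces
those semantics exactly and admits an analytic oracle:

* every atom is inflated by the probe radius (default 1.4 Å, the
  standard water probe);
* the expanded sphere of each ligand atom is sampled with a
  deterministic spherical Fibonacci lattice (`n_points` = 960 by
  default; no RNG, so results are bit-reproducible);
* a sample point buried inside one or more expanded receptor spheres is
  assigned to the atom burying it deepest (ties to the lowest serial),
  and contributes 4πR²/N to that pair's area.

Two spheres whose expanded radii cannot overlap give *exactly* zero area
at any lattice size — the probe-interposition semantics hold without
sampling error. For an isolated pair the sampled area converges to the
spherical cap 2πR_i·h with h = R_i − (d² + R_i² − R_j²)/2d; at
`n_points = 10000` the agreement is within 2 % over the full distance
range, degrading only as the cap shrinks to a sliver (the relative error
is boundary-perimeter-driven). 960 points suffice for fingerprint
aggregation; 10 000 are used where areas are compared to the closed
form.

Areas are computed on ligand-atom spheres and *attributed to receptor
atoms*: the fingerprint asks which receptor residues the ligand poses
press against, so the directionality follows the aggregation unit.
Hydrogens are dropped by default because docking outputs differ in
protonation conventions; van der Waals radii come from a Bondi-style
element table (unknown elements fall back to 1.70 Å with a warning).
Heme groups are receptor material and are subdivided into `HFN`, `HCC`,
`HCR`, `HCO` via an editable atom-name scheme. The porphyrin methyl and
vinyl substituent carbons are placed in `HCC`, reserving `HCR` for the
propionate-chain carbons only: the sp2/sp3 wording that motivates the
split does not fully determine the substituents, and grouping them with
the ring keeps `HCR` synonymous with "the arms that carry the
carboxylates".

Aggregation over poses and ligands uses the simple pooled mean of
per-pose residue areas and the fraction of poses with any contact
(frequency); per-ligand reweighting under unequal pose counts is not
attempted because no normalization rule is stated for the source maps.
Exported maps are recentred at the geometric centre of the receptor
atoms involved in contacts and carry a 5 Å grid spacing for plotting.

## 5. Synthetic data: what it does and does not emulate

`gen_scores()` plants a three-cluster panel: TOP-like candidates at the
best positive-control mean (default −9 kcal/mol), WORST-like at the worst
negative-control mean (−4), MIDDLE-like midway, with Gaussian pose noise
(default sd 0.25 kcal/mol, a tenth of the 2.5 kcal/mol anchor-to-midpoint
separation — the regime where recovery should be near-perfect, and the
default test condition). Gaussian noise is chosen for analytic
tractability of recovery thresholds; real docking-score noise has no
claimed distribution. The generator emulates the *anchored group
structure* of a real screen, not docking physics: real panels have
continuous score gradations, correlated poses, and candidates that
genuinely straddle group boundaries, so a 90 %+ recovery on planted
panels validates the statistical machinery, not the biological claims of
any particular screen. Real docking magnitudes, real correlogram values
and the real molar-content share all depend on score inputs that exist
only as published figures; they are deliberately not asserted anywhere.

`gen_toy_complex()` writes isolated sphere pairs, ≥ 20 Å apart so no
cross-pair contact is possible, as a valid PDB plus the closed-form area
expected per pair. `gen_peak_table()` straddles both peak thresholds
including exact-boundary rows. All generators are pure functions of
their arguments; the same spec and seed yield byte-identical output.

## 6. Problem sizes and test design

The suite runs in a few seconds: the 23 × 5 packaged table, triage
panels of ~20–24 ligands × 3 poses, 50 random CLD panels of 4–8 ligands
checked pair-by-pair against the hand-computed studentized-range oracle,
a 25-point distance grid at 10 000 lattice points, and toy complexes of
≤ 6 atoms. These sizes were chosen to exercise every code path and
tolerance with comfortable margins, not to simulate production load; the
contact-area engine scales linearly in ligand atoms × lattice points and
handles full binding-site complexes (hundreds of receptor atoms within
range) in seconds per pose.

## 7. Known limitations

* The ANOVA treats poses as replicates (see §2); group labels inherit
  that caveat.
* Contact areas are sampling-based; tiny slivers of contact near the
  probe-interposition threshold carry the largest relative error.
* `compute_basic_descriptors()` perceives bonds from distances and knows
  nothing about bond orders, aromaticity or charge; its counts are
  rough stand-ins for proper cheminformatics toolkit values.
* The PDB loader keeps the first altloc only and assigns radii per
  element, ignoring atom-type refinements (e.g. aromatic vs aliphatic
  carbon).
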