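---
title: "Comparative analysis of GPCR activation states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of GPCR activation states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrstates)
library(dplyr)
```

## The scientific problem

G-protein-coupled receptors (GPCRs) switch between inactive and active
conformations. Comparing experimentally determined structures of the two
states, across the receptor classes A, B1, C and F, reveals two levels of
activation machinery: *macroswitches* — whole-helix translations and
rotations of the seven transmembrane helices (TM1–TM7) — and
*microswitches* — residue positions whose contact patterns differ between
states. Because different receptors are solved in different states, the
comparison is made at class level using generic residue numbers
(`3x50`-style labels keyed to the most conserved position of each helix),
which make positions comparable across receptors.

`gpcrstates` implements this workflow end to end:

1. **Template selection** — filter an annotation catalog of structures to
   one representative inactive and one active template per receptor.
2. **Contact detection** — typed residue–residue contacts (van der Waals,
   hydrophobic, hydrogen bond, ionic, aromatic) keyed by generic position.
3. **State-specific contact analysis** — per-class contact frequencies in
   the inactive versus active template sets, a class-specific
   frequency-difference threshold, a residue-pair conservation cut-off, and
   classification of determinant positions into *inactivators*,
   *activators* and *switches*.
4. **Helix geometry** — per-helix translation and rotation between states
   at the extracellular end, membrane mid and intracellular end.
5. **Interface mapping** — overlap of determinants with ligand- and
   G-protein-interacting positions.
6. **Mutant statistics** — potency/efficacy shifts of alanine mutants and
   the exact two-sided Wilcoxon rank-sum comparison of predicted
   state-changing versus nonstate-changing positions.

A synthetic-data module generates every input the pipeline consumes —
ideal helical bundles with imposed rigid motions, contact ensembles with
programmed frequencies, alignments with programmed conservation,
annotation catalogs and mutant tables — so the entire analysis runs and is
tested without downloading a single structure.

## Template selection

Representatives are chosen by quality filters: receptor completeness
≥ 83% of generic positions, G-protein completeness ≥ 43% (for active
complexes), sequence identity to the human receptor > 90%, resolution
≤ 3.6 Å, degree-active ≤ 20% (inactive) or ≥ 90% (active), and
state-consistent ligand modality (inverse agonist/antagonist versus
agonist). Active templates additionally require a G-protein complex. An
alternative published variant of two cut-offs (completeness ≥ 86%,
resolution ≤ 4.0 Å) exists in the literature record; both are expressible
through `selection_criteria()` and we deliberately do not reconcile them —
the defaults follow the main protocol.

Boundary semantics are inclusive (`<=`/`>=`) everywhere except sequence
identity, which is strict (`> 90%`), matching the stated protocol. The
per-receptor tie-break — best resolution, then highest completeness, then
lexicographic structure id — is our own choice (the protocol does not
state one); it exists purely to make selection deterministic.

```{r}
rows <- make_annotation_catalog(seed = 1)
catalog <- select_representatives(rows, selection_criteria())
count_selection(catalog)
```

The emulated catalog plants representative-eligible rows so that selection
reproduces the published census (42 inactive / 27 active distinct
templates, 13 receptors with both states, 45 of 68 templates at ≤ 3.0 Å).
Two published counting conventions coexist: per-class template counts
count *entries* (the GABA~B~ heterodimer contributes two artificial
monomer entries per parent structure), while the headline active count and
the "68 templates used" count *distinct parent structures*. The summary
reports both (`n_active_entries` versus `n_active_parents`) rather than
forcing agreement.

## Contact detection

A residue pair is in contact when any criterion holds between heavy
atoms: van der Waals overlap (summed radii + 0.6 Å), donor–acceptor
distance ≤ 3.5 Å, opposite-charge group N/O distance ≤ 4.5 Å,
carbon–carbon distance ≤ 4.5 Å, or aromatic ring-centroid distance
≤ 5.5 Å. These are standard structural-biology cutoffs; the source
protocol defers its exact definitions to a web tool's settings menu, so
all values are parameters of `contact_params()` and are recorded in every
output header for reproducibility.

Sequence neighbours need care: peptide-bond neighbours always touch via
backbone, yet genuine adjacent side-chain contacts (an `N7x49`–`P7x50`
kind of interaction) must be kept. The *adjacent rule* therefore admits
pairs within two sequence positions only through atom pairs involving at
least one side-chain atom. Both this rule and the minimum sequence
separation are switchable, since it is not documented whether the original
analysis admitted backbone–backbone pairs.

`detect_contacts()` uses a cell-list spatial index; its correctness is
defined by `detect_contacts_bruteforce()`, an exhaustive O(n²) atom-pair
scan with no indexing. The test suite asserts exact set equality between
the two on dozens of randomized fixtures.

## State-specific contacts and determinants

```{r, eval = FALSE}
freqs <- compute_pair_frequencies(inactive_sets, active_sets, "A")
specific <- filter_state_specific(freqs, class_thresholds())
specific <- conservation_filter(specific, class_alignment)
determinants <- classify_positions(specific, class_alignment)
```

Frequencies are computed per class: the percentage of inactive (or
active) templates forming the contact. The denominator counts templates
in which *both* positions are resolved, so unmodelled loops do not deflate
frequencies; `denominator = "all"` switches to the naive convention, and
both are exercised in tests. A pair counts once per template regardless of
how many interaction types it satisfies. Comparisons use exact counts;
only display is rounded.

The frequency-difference thresholds are calibrated to each class's
structural coverage — A: 40, B1: 67, C: 75, F: 100 percentage points —
and are applied inclusively (a pair at exactly the threshold is kept). The
conservation cut-off keeps a contact when ≥ 30% of the class's receptors
carry one of the amino-acid pairs observed to form it; receptors missing
either position count as non-matching.

Determinant roles follow the partition rule: a position with only
inactivating state-specific contacts is an *inactivator*, only activating
an *activator*, and both a *switch*. The original wording ("whether their
most frequent contact occurs in inactive, active and both states") is
ambiguous when a position has several contacts; the partition rule
reproduces the stated roles, is well defined in every case, and makes
switch status equivalent to "contacts across both states", which is how
segment-level switches are defined too.

## Helix movement and rotation

`superpose_pair()` fits the active structure onto the inactive one using
Cα atoms of shared transmembrane positions within ±6 Å of the membrane
mid. The protocol does not state its reference frame; fitting on the
mid-membrane core is our choice, made so that end movements are measured
against the least mobile part of the bundle. The membrane frame itself
comes either from an external embedding (accepted unchanged) or from the
built-in fallback: the first principal axis of all transmembrane Cα,
oriented extracellularly using ECL2 (or the TM4/TM5 ends that flank it).

Translations are distances between region Cα centroids: the terminal four
shared residues for each end, the five residues nearest the mid-plane for
the mid region. Rotation fits the rigid transform of the region residues
between states and reports the *twist* component of its rotation about the
local helix axis (twist–swing decomposition). Two numerical details
matter and are tested:

* A raw principal component of a short Cα window is tilted several
  degrees by the helical spiral; the local axis is therefore fitted to a
  running mean over ~one helical turn, and the twist decomposition is
  second-order insensitive to the residual axis error.
* The centroid-distance definition of translation necessarily includes
  the swing of an off-axis centroid under rotation; pure translations are
  recovered to machine precision, and composed motions are checked against
  the analytically derived centroid displacement.

Positive rotation is counterclockwise viewed from the extracellular side.
Regions with fewer than three shared residues (e.g. unwound helix ends)
are reported "not measurable" rather than extrapolated. Class consensus
counts receptors moving strictly more than 1.0 Å.

## Mutant statistics

`wilcoxon_rank_sum_exact()` computes the two-sample rank-sum test with
mid-ranks for ties. For group sizes up to 10 the permutation distribution
is computed exactly by a shift-algorithm dynamic program over doubled
ranks (so tied mid-ranks stay integral); the two-sided p doubles the
smaller tail and caps at 1, a convention that is deterministic even when
ties make the distribution asymmetric. Larger groups use a normal
approximation with tie and continuity corrections. The implementation is
validated against full `combn` enumeration for all group sizes ≤ 8 and
against `stats::wilcox.test` in the tie-free exact regime.

With six mutants per group the exact two-sided support is `{2k/924}`. The
emulated mutant table is constructed so the group means are exactly
1.07 versus 0.22 (G~s~) and 1.25 versus 0.25 (G~15~) log-units and the
exact p-values land on support points: `18/924 ≈ 0.0195` and
`4/924 ≈ 0.0043` for potency, `646/924 ≈ 0.6991` and `286/924 ≈ 0.3095`
for efficacy. Replicate rows are symmetric around each mutant's value so
replicate averaging is exact. The test enters mutant-level values (one
averaged value per mutant), the reading consistent with n = 6 per group.

```{r}
cmp <- compare_mutant_groups(delta_from_wt(make_mutant_table(seed = 1)))
tidy(cmp)
```

## What the synthetic data do and do not show

The generators emulate the *bookkeeping conditions* of the study — filter
boundaries, template counts, programmed contact frequencies, conservation
fractions, imposed rigid motions, two-group shift magnitudes — under full
ground-truth control. They do not emulate real structural data: side-chain
rotamers are idealized stalks, helices are unkinked, loops are absent, and
contact geometry is engineered rather than packed. Passing tests therefore
demonstrate that the *measurement machinery* is correct (exact
bookkeeping, oracle-equivalent contact detection, parameter recovery
within stated tolerances), not that the published biological claims would
re-derive from experimental coordinates; that requires the full structure
corpus, which the pipeline accepts through the same interfaces
(`load_structure()` + mapping tables + catalog).

Problem sizes used throughout the tests and the acceptance script — 7×25
residue bundles, ensembles of 2–4 templates per state, 20–50 randomized
contact fixtures, 5-draw noise batches — were chosen as the smallest sizes
at which every boundary and invariant is exercised with exact expected
values.

## Known limitations

* Helix kink/unwinding detection is out of scope; unwound regions
  surface only as "not measurable".
* Water-mediated and cation–π contacts are not modelled; hydrogens are
  never placed.
* Generic-number assignment is consumed as input (mapping tables), never
  computed from alignment.
* The degree-active annotation is an input column; `tm6_opening_proxy()`
  is a clearly non-canonical Cα-distance stand-in for sanity checks only.
* Rotamer-change annotation of determinants is not implemented.
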