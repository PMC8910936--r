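---
title: "Indel-free regions and allosteric interfaces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indel-free regions and allosteric interfaces: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsp70ifr)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the numerical conventions, and the design
choices made where more than one reasonable convention exists. The running
system is bacterial Hsp70 (DnaK): a nucleotide-binding domain (NBD,
reference residues 1–398) and a substrate-binding domain (SBD, 399–603)
whose ATP-driven docking creates a transient interdomain interface. The
package's question is whether the residues forming that interface sit in
stretches of the family alignment that carry no insertions or deletions.

## 1. Indel calling on a multiple sequence alignment

All alignment analyses start from a fixed, externally computed protein MSA
(`read_alignment` accepts aligned FASTA and Clustal); the package never
re-aligns.

**Column classes.** For each column the gap fraction decides its class:
more than 50% gaps makes it an *insertion* column (the residues present
are inserts relative to the family), between 0 and 50% a *deletion site*,
and 0 an *ungapped* column. A gap fraction of exactly 0.5 is a deletion
site: an insertion needs a strict majority of gaps. The classes are
mutually exclusive and exhaustive by construction.

**Events.** Per sequence, an insertion event is a maximal run of residues
in insertion columns, and a deletion event a maximal run of gaps in
non-insertion columns. A gap in an insertion column carries no information
about that sequence (it simply lacks someone else's insert), so such
columns are transparent: they do not interrupt a deletion run. Event
lengths count informative columns only.

**Indel probability.** Each alignment position gets the fraction of
sequences carrying an event whose run covers it. "Covers" means the
event's maximal run includes the column; insertion events contribute at
the insertion columns themselves. This is the simplest overlap convention
consistent with the event definition.

**Indel-free regions.** IFRs live in reference coordinates (the non-gap
columns of a designated reference row, mapped 1..L by
`map_to_reference`), so their lengths are residue counts in the reference
protein. A maximal run of reference positions is an IFR when no sequence
has an event at any contained position and no insertion column between
consecutive contained positions carries one. One waiver exists, the
*fusion rule*: a breaker whose events are confined to at most
`fuse_max_seqs` sequences (default 1), each of length at most
`fuse_max_len` (default 1), is ignored, the flanking runs are fused, and
the result is flagged with provenance. The defaults encode the view that
a single one-residue insert in a single species is an idiosyncrasy, not a
family-level feature; both limits are arguments because that judgement is
a modelling choice. Regions shorter than `min_length` (default 4) are
dropped; survivors are ranked by length, longest first, and labelled
IFR-I, IFR-II, … with roman numerals. Ties in length are ordered by
start position.

**Wu–Kabat variability.** Per analyzed column, `N * k / n`, with `N` the
number of sequences carrying a residue there, `k` the number of distinct
amino acids and `n` the count of the commonest one. Columns whose
consensus character is a gap are pure insertion space and are marked not
analyzed (`NA`) rather than given a value. The index is 1 for a fully
conserved column and `N * k` only when every residue is unique. Consensus
ties break lexicographically, with the gap character sorting first, so
profiles are deterministic.

**Conservation.** A column is conserved when its most frequent residue
reaches `identity_threshold` of its non-gap characters; gaps are excluded
from both numerator and denominator, and all-gap columns are never
conserved. The default threshold is 1.0 (strict identity) because no
weaker published convention is available for this analysis; fractions
computed at other thresholds are not comparable across choices, so the
threshold is always explicit.

## 2. Kimura distances per subdomain

Pairwise evolutionary distances use the Kimura protein correction over
comparable columns (both rows non-gap): with `S = m / npos` the exact
match fraction and `D = 1 - S`,

```
distance = -ln(1 - D - 0.2 D^2) x 100.
```

The ×100 scale is the distmat convention and the package default; raw
units via `scale = 1`. Ambiguity codes X, B and Z never count as matches,
including to themselves. The correction is undefined at `npos = 0` and
saturates where `1 - D - 0.2 D^2 <= 0` (D above ≈ 0.854); both cases
raise errors rather than returning `NaN`, because a silent `NaN` in a
distance matrix poisons every downstream mean. In the small-D limit the
distance approaches D itself (first-order agreement within 1% at
D ≤ 0.01, asserted in the tests).

`subdomain_matrices` slices the alignment by reference intervals (NBD,
SBD, lobe I, lobe II, βSBD, αSBD by default) and computes the full
pairwise matrix per slice. `distance_correlation` pairs two such matrices
by sequence pair and fits an ordinary least-squares line; equal
per-subdomain substitution rates correspond to slope 1. The regression
convention (OLS with intercept) is ours. Note that a meaningful slope
needs between-pair spread: a star-shaped family in which every sequence
diverged equally gives a cloud with no leverage, and the slope estimate
degenerates — the tests therefore use sequences of graded divergence for
this property.

## 3. Structural differencing and contact extraction

`read_structure` keeps one Cα per residue of the requested chain,
resolving alternate locations to the highest-occupancy copy (ties by
altloc identifier) and skipping — with a warning — residues that lack a
Cα. Distance matrices are plain Euclidean all-against-all tables.

The conformational difference map is the **absolute** difference
`|d_closed − d_open|`, restricted to residues present in both models
(matching is by author residue number). Absolute values are used because
the map is read as "how much did this pair move", and signed means cancel
antagonistic movements; the per-residue maximum shift and the
distance-invariant pairs (default tolerance 0.01 Å — exact zero is hostile
to floating point) both derive from this map. Matrix means always exclude
the diagonal and count each unordered pair once; between-block means run
over the full rectangle.

A contact is an NBD×SBD pair with `d_open < 7` Å and
`|d_closed − d_open| > 2` Å. Both inequalities are strict: a pair exactly
at a threshold fails it. The distance-only pre-filter list is retained as
an attribute because the intermediate count is a quantity of interest in
its own right. Extraction is invariant to residue ordering in the input
file (models are sorted by residue number at construction).

## 4. PCA and kernel-density clustering of contacts

Each contact is summarized by six numbers: the open-form Cα coordinates
of its NBD residue followed by those of its SBD residue, mean-centered
per coordinate. Only the open form enters, because the contacts exist
only there. This feature definition is the major modelling assumption of
the clustering stage — the choice of what to feed the PCA is genuinely
open, and the feature builder is deliberately a separate function so it
can be swapped. Scores are the projection onto the first principal
component, with the sign fixed so the contact with the smallest NBD
residue number scores negative (pure reproducibility convention).

Scores are clustered by gaps in a Gaussian kernel density evaluated on a
512-point grid spanning the scores ± 3 bandwidths:

- **Bandwidth.** Chosen by minimizing the unbiased integrated-squared-
  error cost `C(w) = (1/n²) Σ φ(d_ij; 2w²) − (2/n²) Σ_{i≠j} φ(d_ij; w²)`
  over a logarithmic grid (the Shimazaki–Shinomoto kernel-bandwidth
  optimization), with Silverman's rule as fallback for degenerate or tiny
  samples. For the sample sizes this analysis sees (tens of contacts) the
  cost minimum is shallow and the minimizer is unstable toward
  undersmoothing, so among all candidates within 5% of the minimum
  (relative to the cost range) the largest bandwidth is taken: prefer the
  smoothest near-optimal density. The 5% default comes from a sweep of 85
  seeded blob scenarios (2–6 planted clusters, plus two-blob and
  single-blob controls) in which it recovers every planted cluster count.
- **Cuts.** Local density minima separate clusters when the valley drops
  below `valley_fraction` (default 0.5) of the smaller neighbouring peak;
  shallower valleys are merged iteratively, starting with the shallowest.
  Modes below `peak_min_fraction` (default 0.1) of the global maximum are
  never cluster seeds — an ISE-optimal density is mildly undersmoothed by
  design and grows small satellite bumps in the tails that are sampling
  noise, not clusters. Both criteria are ours; the underlying notion is
  only that clusters are "well-separated density agglomerates".
- Labels are contiguous from 1 in ascending score order, invariant under
  translation and positive scaling of the scores; scores within
  `bandwidth/10` of a cut are flagged as boundary cases. All-identical
  scores yield one cluster with a warning.

## 5. Integration: contacts against the alignment

`annotate_contacts` maps each contact residue to its alignment column and
records IFR membership, indel-position status (reference-mapped indel
probability > 0), conservation and Wu–Kabat variability. IFR membership
takes precedence over indel status: the only indels an IFR may contain
are fusion-waived singletons, and the trichotomy (in IFR / at indel
position / elsewhere) should partition residues.

`enrichment_summary` compares contact residues against all other
analyzed columns of the same domain (contact columns are excluded from
the background) on conserved fraction and mean variability, with a
two-sided Welch t-test for the variability difference. Sidedness is a
convention choice; two-sided is the conservative default. Two identical
samples give t = 0, p = 1; two different constant samples give t = ∞,
p = 0 (an exact separation the t statistic cannot express).

## 6. The synthetic-data generator

`simulate_alignment` draws a uniform-random ancestor over the 20 amino
acids and mutates each descendant independently (a star phylogeny):
substitutions i.i.d. per region rate, indel events started per site at
the region indel rate with geometric lengths (mean per region; an
optional point-mass mixture mimics empirical length spectra that decay
and then show secondary modes near 11 and 17 residues). Events render
into a single shared coordinate system — one column per reference
position plus an insertion slot after each anchor sized to the longest
insert there — so the returned truth tables (events, realized indel-free
runs, per-column conservation) are exact by construction, and the same
seed reproduces byte-identical output. Two guardrails keep truth exact:
deletions are truncated at the boundary of the region they start in (so
zero-rate regions are indel-free by construction), and an insertion
anchored strictly inside a deletion run of the same sequence is dropped
(it would split the rendered run in two). Scenarios implying more than
90% expected gap content are refused.

What the generator does *not* emulate: phylogenetic correlation (all
descendants are independent), alignment-algorithm artefacts (no
re-alignment happens, so there is no misalignment noise), indel rate
variation within a region, and realistic amino-acid substitution
matrices (mutations are uniform over the other 19 residues). Passing
recovery tests therefore demonstrates that the *callers* are correct
given a correct alignment; they say nothing about robustness to
alignment error, which dominates real small-indel calling. The unmutated
ancestor is included as row `"REF"` so reference mapping is exact; it
participates in column statistics like any other row.

`simulate_structure_pair` builds bead models in which each planted or
decoy contact pair occupies an isolated spatial slot (60 Å apart), the
SBD bead placed at the exact target open/closed distance from its fixed
NBD partner, and unpaired beads far from everything. Planted pairs must
satisfy both contact thresholds and decoys must violate exactly one; a
residue may appear in at most one pair, otherwise the scenario is
refused as infeasible. The models are valid PDB output
(`write_structure_pdb`) but have no protein geometry beyond the planted
distances.

## 7. Problem sizes, defaults and limitations

The shipped tests and the acceptance script use 12–40 sequences of
200–603 residues, planted IFRs of 40/80/150 residues with hotspot indel
rates of 0.3 per site (probability-profile and recovery properties), 200
replicates for the Welch power property and 1000 resamples for its null
uniformity, and 15 points per planted cluster for the KDE recovery
property — sizes at which every property is sharp while a full test run
stays in seconds.

Default subdomain intervals (NBD 1–398, SBD 399–603, lobe I 1–183,
lobe II 184–398, βSBD 399–507, αSBD 508–603) follow common DnaK usage;
only the NBD/SBD split is firmly conventional, so all boundaries are
arguments of `subdomain_partition`. The disordered C-terminal tail
(604+) is excluded by the partition rather than hard-coded.

Known limitations: no structure superposition or RMSD (difference maps
are superposition-free by construction, which is why they are used); no
mmCIF input; no all-atom or side-chain contact definitions; no
phylogeny-aware indel placement or tree inference; conservation
fractions depend on an identity threshold the analysis cannot pin down
from first principles. The real-structure reproduction requires the user
to supply the 4B9Q/2KHO PDB files (see `?dnak_structure_paths`); the
package does not download them.
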