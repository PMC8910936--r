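# hsp70ifr

Tools for asking whether the residues that wire two protein domains
together during an allosteric transition sit in regions of the protein
family that evolution protects from insertions and deletions.

The motivating system is bacterial Hsp70 (DnaK), an ATP-regulated
chaperone built from a nucleotide-binding domain (NBD, residues 1–398 in
*E. coli* numbering) and a substrate-binding domain (SBD, 399–603). ATP
binding docks the open SBD onto the NBD and creates a set of transient
NBD–SBD contacts. An indel anywhere in the participating stretches shifts
every downstream pairing at once, so interface regions are expected to be
depleted of indels — detectable as long *indel-free regions* (IFRs) in a
multiple sequence alignment of the family.

## What the package computes

**Alignment side** (input: a protein MSA with a reference row):

- per-column gap statistics with the majority-gap rule: a column whose gap
  fraction exceeds 0.5 is an insertion column, otherwise a deletion site
  (`column_profiles`);
- per-sequence indel events as maximal runs, a per-position indel
  probability profile, and event-length histograms (`call_indel_events`,
  `indel_probability_profile`, `indel_length_distribution`);
- indel-free regions in reference coordinates, with a fusion rule that
  waives breakers confined to at most one sequence and one residue,
  ranked IFR-I, IFR-II, … by length (`find_ifrs`);
- Wu–Kabat variability `N·k/n` per analyzed column (`N` sequences with a
  residue, `k` distinct amino acids, `n` count of the commonest), and a
  conservation mask (`wu_kabat`, `conservation_mask`);
- Kimura protein distances `-ln(1 - D - 0.2 D²)·100` over gap-free
  columns, per-subdomain distance matrices and between-subdomain
  rate correlations (`kimura_distance`, `subdomain_matrices`,
  `distance_correlation`);
- ancestor/descendant indel comparison for a pair of aligned rows
  (`compare_indels`).

**Structure side** (input: PDB files of the open and closed conformations):

- Cα–Cα distance matrices, the absolute difference map between
  conformations, block means by subdomain, per-residue maximum shifts and
  distance-invariant pairs (`ca_distance_matrix`, `difference_map`,
  `matrix_mean`, `max_shift_per_residue`, `invariant_pairs`);
- interdomain contact extraction: NBD×SBD pairs with open-form distance
  < 7 Å whose distance changes by > 2 Å between conformations
  (`extract_contacts`).

**Integration and clustering:**

- contact residues annotated with IFR membership, indel-position status,
  conservation and variability; enrichment summaries with Welch's t-test
  (`annotate_contacts`, `enrichment_summary`);
- PCA of the contacts' open-form coordinates, and clustering of PC1
  scores by gaps in a Gaussian kernel density with an optimized bandwidth
  (`build_features`, `pc1_scores`, `kde_clusters`).

**Synthetic data:** a seeded generator for alignments with planted
indel hotspots and IFRs (`simulate_alignment`) and two-conformation bead
structures with planted contacts (`simulate_structure_pair`), so the whole
pipeline is testable without downloads.

The published 31-contact table for *E. coli* DnaK (open 4B9Q / closed
2KHO), with cluster labels and conservation flags, ships as a plain-text
table (`dnak_contact_clusters`). The two PDB files themselves are not
redistributed; `dnak_structure_paths` documents where to drop them to run
the full structural reproduction.

## Worked example

A 20-sequence alignment of a 603-residue family with two planted
indel-free regions (101–200 and 399–520) amid indel hotspots, plus a bead
structure pair with three planted interface contacts:

```r
library(hsp70ifr)

regions <- data.frame(
  start = c(1, 101, 201, 399, 521), end = c(100, 200, 398, 520, 603),
  substitution_rate = 0.1, indel_rate = c(0.08, 0, 0.08, 0, 0.08),
  mean_indel_length = 2)
sim <- simulate_alignment(alignment_scenario(20, 603, regions, seed = 7))
a    <- sim$alignment
prof <- column_profiles(a)
ev   <- call_indel_events(a, prof)
map  <- map_to_reference(a, "REF")
ip   <- indel_probability_profile(ev, a, map)
(ifrs <- find_ifrs(ip, map, ev, min_length = 30))[, c(1:3, 6:7)]
#>   rank_label ref_start ref_end length fused
#> 1      IFR-I       399     520    122 FALSE
#> 2     IFR-II       101     201    101 FALSE
```

(IFR-II ends at 201, one residue past the planted region: that hotspot
site happened to stay untouched in all 20 sequences, and an IFR is a
property of the realized alignment.)

```r
st <- simulate_structure_pair(structure_scenario(
  n_nbd = 200, n_sbd = 122,
  contacts = data.frame(nbd_res = c(110, 150, 190), sbd_res = c(410, 450, 510),
                        d_open = c(5, 6, 4), d_closed = c(10, 12, 20)),
  seed = 7))
ct <- extract_contacts(st$open, st$closed)
annotate_contacts(ct, map, ifrs, ip, conservation_mask(a),
                  wu_kabat(a, prof))[, c("nbd_res", "sbd_res", "nbd_in_ifr", "sbd_in_ifr")]
#>   nbd_res sbd_res nbd_in_ifr sbd_in_ifr
#> 1     110     410     IFR-II      IFR-I
#> 2     150     450     IFR-II      IFR-I
#> 3     190     510     IFR-II      IFR-I
```

Every planted interface residue is recovered inside a planted IFR — the
pattern the real DnaK analysis reports for its two largest IFRs. On the
curated DnaK contact list:

```r
str(contact_residue_counts(dnak_contact_clusters()))
#> List of 4
#>  $ n_contacts    : int 31
#>  $ n_residues    : int 37
#>  $ n_nbd_residues: int 22
#>  $ n_sbd_residues: int 15
```

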