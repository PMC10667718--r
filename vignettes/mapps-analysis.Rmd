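---
title: "Models and methods behind mappkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mappkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mappkit)
```

# The problem

MHC-associated peptide proteomics (MAPPs) asks which fragments of a
therapeutic antibody are loaded onto MHC class II (HLA-DR) by a donor's
dendritic cells and can therefore be shown to CD4+ T cells — an ex vivo
proxy for clinical immunogenicity risk (anti-drug antibodies, ADA). The
wet-lab half of the assay (dendritic-cell culture, immunoaffinity
enrichment, LC-MS/MS) is out of scope here. `mappkit` implements the
in-silico half: it consumes peptide-spectrum-match (PSM) tables as a search
engine would export them and produces the panel-level quantities a MAPPs
report is built from — accepted peptide inventories, nested-set clusters,
donor presentation frequencies, biotransformation frequencies, replicate
concordance, and peptide-coverage heat maps.

# Identification filtering

Three rules decide whether a PSM is accepted; all three come from common
practice with Sequest-style scores:

* **Confidence tiers.** XCorr windows of 2–2.3, 2.5–3 and 2.8–3.5 are
  *medium* confidence for charge 2, 3 and ≥ 4; strictly above the upper
  bound is *high*; below the medium floor is rejected. The medium windows
  are read as closed intervals, which makes every boundary testable
  (`assign_confidence(2, 2.3)` is medium, `assign_confidence(2, 2.31)` is
  high).
* **Modification cap.** At most four variable modifications per peptide
  (methionine oxidation +15.995 Da; asparagine/glutamine deamidation
  +0.984 Da). An unlocalized deamidation counts once — a modification is a
  modification regardless of localization confidence.
* **FDR 1%.** Peptide-level false discovery control against a concatenated
  target–decoy search. The estimator is the canonical minimal target–decoy
  analysis: at each observed score threshold `s`,
  `FDR(s) = #decoys(≥ s) / max(1, #targets(≥ s))` (naive, no +1
  correction), and a record's q-value is the minimum FDR over all
  thresholds at or below its score. q-values are clamped to [0, 1] and are
  non-increasing in XCorr by construction. This is a stand-in for
  semi-supervised rescoring engines, which are deliberately out of scope:
  the 1% FDR is treated as a contract, not an algorithm. q-values are
  computed within each sample, since each LC-MS run is its own
  target–decoy competition.

# Mapping and clustering

Spectra are searched with no enzyme specificity, so any contiguous
substring of a chain is a legal placement; all placements are kept,
including overlapping ones and peptides occurring in both chains. Peptide
identity throughout the counting layer is the bare amino-acid sequence —
charge states and modifications do not split counts. An `il_equivalent`
matching mode (I and L folded together) is available because mass
spectrometry cannot distinguish the two residues; the default is exact
matching, since search engines report database-derived sequences.

Eluted MHC-II peptides arrive as *nested sets*: ladders with ragged N- and
C-termini sharing one binding core. `build_clusters()` groups placements
greedily per chain — intervals sorted by start, then decreasing length;
each interval joins the first cluster whose *current core* it overlaps by
at least `min_core_overlap` residues, shrinking that core to the
intersection; otherwise it seeds a new cluster. The default
`min_core_overlap = 9` is the canonical MHC class II binding-core length;
the grouping threshold itself is a package convention, since the nested-set
concept names a phenomenon, not a procedure. Core shrinking (rather than
single-linkage) guarantees every cluster keeps a genuine common core;
single-linkage can chain peptides that share nothing. Whenever a
brute-force connected-components oracle (edges = pairwise overlap ≥ 9)
yields components whose members all share a ≥ 9-residue segment, the greedy
partition provably equals it; in general it refines it. "Non-empty common
intersection" is read as "shares a common core", i.e. a segment of at
least `min_core_overlap` residues, matching the cluster invariant that a
core is at least that long.

Cluster cores and envelopes are both reported: the intersection of member
intervals (the consensus region) and the union extent. A donor *presents*
a cluster if at least one of its accepted peptides falls in it — a
presence/absence reading matching heat-map interpretation, with no minimum
peptide count.

# Panel metrics and rounding conventions

All percentages round half away from zero (base `round()` is
round-half-even, which would be surprising in a report):

* `pct_therapeutic` — 100 × (HC + LC peptides) / total distinct accepted
  peptides, to 2 significant figures. The denominator includes the
  self-peptide background, which is why reported values are fractions of a
  percent against totals of 10⁴–3×10⁴.
* `cluster_presentation_frequency` — one decimal (5 of 7 donors → 71.4).
* `modification_donor_frequency` — nearest integer (8 of 18 → 44).
* `region_homology` — ungapped positional identity of equal-length
  regions, nearest integer. No alignment is performed; unequal lengths are
  an error. For a 26-residue region differing at 4 positions this gives
  22/26 → 85; published comparisons sometimes print 84 for the same
  counts, suggesting a different rounding or region convention, so the
  function documents its own rule rather than chasing a printed digit.
* `replicate_concordance` — cluster-level Jaccard (matched pairs / union)
  after greedy one-to-one cross-run matching by descending core overlap;
  two empty runs agree vacuously at 100. Peptide-level Jaccard is
  available as a secondary metric.
* Peptide length statistics use the lower median, so the reported median
  is always an observed length.

# The synthetic generator

`simulate_panel()` states a world once and the tests live in it:

* **Cores and ladders.** 9-mer cores are planted ≥ 20 residues from chain
  ends and pairwise separated by > 25 residues, so envelopes of adjacent
  clusters cannot interact (maximum one-sided extension is 14 residues).
  Each (donor, core) presents with probability 0.7 — roughly the 5-of-7
  donor patterns real panels show. A presented core emits a
  Poisson(5)-sized (min 1) ladder per sample.
* **Lengths.** Terminal extensions are 2 + Geometric(0.35) per side, total
  capped at 25 by trimming. This gives support 13–25 with distributional
  median 16, the reported median for MHC class II eluted peptides. The
  +2 shift is the one calibration the length target requires (a bare
  geometric puts the median near 13) and was fixed analytically from
  `qnbinom(0.5, 2, 0.35) = 3` before any test was run. The median-16
  statement is about the peptides the generator emits; a *deduplicated*
  inventory of distinct sequences runs about one residue longer, because
  short ladder members recur across donors and collapse when counted
  once.
* **Scores.** True PSMs score `medium_floor(charge) + LogNormal(log 0.5,
  0.8)`: never tier-rejected, both tiers populated (about a quarter of
  true PSMs land in the medium window). Decoys and false targets score
  `LogNormal(log 1.1, 0.35)`. These distributions are a modeling
  convenience, not a claim about Sequest; their consequence — replicate
  variation comes only from dropout — is exactly what the concordance and
  recovery properties assert.
* **Background.** Each sample draws 10⁴–3×10⁴ self peptides from a
  synthetic 50-protein proteome, rejection-sampled never to
  substring-match the therapeutic chains, so therapeutic-uniqueness truth
  is exact. False spectra (25% of the background count) land on the decoy
  half of the concatenated database with probability 0.5; the target half
  of those are the false identifications the FDR machinery must control.
* **Modifications.** Met-ox (per-M probability 0.15) and deamidation
  (per-N/Q 0.10, 30% unlocalized) are injected into therapeutic peptides
  only — the biotransformation metrics concern the therapeutic — capped at
  four tokens to match the downstream filter.
* **Provenance.** Donor/replicate/day/analyst labels and per-peptide
  replicate dropout (0.02) give the panel its repeated-measures structure.

What a green test does **not** establish: the generator has no retention
time, intensity or spectral dimension; no correlated HLA-haplotype
structure (presentation is independent Bernoulli per donor × core); no
shared peptides between donors' backgrounds; and real search-engine score
distributions are heavier-tailed. Results on synthetic panels validate the
bookkeeping and the statistics, not the mass spectrometry. The
replicate-concordance acceptance check runs with a scaled-down background
(2000–3000 peptides per sample), since concordance is a statement about
therapeutic clusters and the full-scale background only adds runtime.

# Numerical and degenerate-input choices

Empty inputs are values, not errors: an empty PSM table filters to an
empty accepted set, an empty panel report is written with zero rows, and
`length_statistics(character(0))` returns an explicit empty value. Errors
are reserved for contract violations (charge outside 2–7, malformed
modification tokens, out-of-bounds CDR intervals), always with the file
line or record index. Ties in clustering are broken by the documented sort
order; ties in XCorr share one threshold in the q-value computation.
Everything downstream of a seed is deterministic, including SVG output,
which is why end-to-end reruns are byte-identical and golden-file tests
are possible.

# Known limitations

Protein-level FDR is intentionally not implemented (peptide-level only).
CDR intervals are user-supplied — no Kabat/IMGT/Chothia numbering. Cluster
numbering is reproducible (HC before LC, by envelope start) but not meant
to match any published figure's labels. The heat map is a static SVG;
interactive viewers are out of scope.
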