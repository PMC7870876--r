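---
title: "Methods: models, filters and design choices in svxl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, filters and design choices in svxl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svxl)
```

`svxl` analyses cross-linking mass-spectrometry (XL-MS) experiments on
membrane organelles downstream of the search engine: it quantifies the
proteome, validates and aggregates cross-link spectrum matches (CSMs), builds
and compares interaction networks, maps links onto atomic structures, and
classifies membrane topology. This vignette explains the underlying models,
the tunable parameters and the design decisions, and states what the bundled
synthetic-data generator does and does not emulate.

## Quantification model

iBAQ treats the summed MS intensity of a protein's peptides, divided by the
number of theoretically observable tryptic peptides, as proportional to molar
amount. Two conventions are deliberately explicit because the field leaves
them vague:

* **Trypsin rule.** Cleavage strictly C-terminal of K or R, suppressed before
  proline. The proline exception is the conventional rule used by the major
  search engines; `tryptic_digest()` is tested against an independent
  character-scan oracle.
* **Observability window.** "Theoretically observable" is defined here as
  fully-cleaved peptides of 7–30 residues (configurable via `window=`). Both
  bounds matter: very short peptides are rarely identified and very long ones
  rarely elute and fragment well. A protein whose tryptic peptides all fall
  outside the window (an atypical cleavage-site distribution, as for some
  proton-pump stator subunits) has an *undefined* iBAQ; such records are
  flagged and excluded from the normalisation denominator rather than set
  to zero, because a zero would silently distort every other protein's
  relative iBAQ.

Relative iBAQ normalises per replicate and sums to one over quantified
proteins; it is scale invariant, so instrument response differences between
replicates cancel. Medians (not means) across replicates drive stoichiometry
ratios and top-N ranking — with the 4–5 replicates typical of such
experiments a single outlier replicate would otherwise dominate. Ties in
top-N selection break lexicographically by protein id so the reduced search
database is reproducible.

## CSM validation and aggregation

A CSM validates when *each* of its two peptides shows a run of at least
`min_adjacent = 4` consecutive indices within a single ion series (b or y)
whose relative intensities reach `min_rel_intensity = 0.01` of the base peak.
Two choices here were genuinely open:

* "Reasonable intensity" is made mechanical as a relative-intensity floor.
  0.01 is permissive on purpose: the rule's discriminating power comes from
  adjacency, and the floor only guards against noise-level peaks extending a
  run.
* Runs are counted within one series, never across b and y. An "adjacent
  fragment series" is a property of consecutive backbone cleavages read in
  one direction; mixing series would count the same bond twice.

Validated CSMs aggregate to one cross-link per unique canonical residue pair
per condition (conditions are never merged). The canonical order —
`(protein, residue)` pairs sorted lexicographically/numerically — makes
aggregation invariant to the arbitrary alpha/beta peptide order reported by
search engines. A link is `homo_oligomeric` when any supporting CSM has both
peptides on the same protein with overlapping coordinate intervals or the
same absolute residue on both sides: such a match cannot arise from one
protein copy. Homo-oligomeric evidence takes precedence over plain `intra`
when both support the same residue pair, because a single oligomer-derived
CSM is already proof of two copies. A residue pair observed with different
peptide forms (missed cleavages) counts as one link: the unit counted is the
residue pair, not the peptide pair.

Replicate filtering retains validated links seen in at least
`min_replicates = 2` biological replicates; the operation is monotone and
idempotent, which the test suite asserts as properties rather than examples.

## Networks

Protein-level edges come from inter-molecular and homo-oligomeric links only;
plain intra-molecular links say nothing about protein pairs. Edges carry a
replicate *tier* (`multi` vs `single`) instead of being filtered, mirroring
the common blue/grey rendering of such networks — low-support edges stay
visible and flagged. Hub degree counts distinct partners and excludes
self-edges (an oligomer is not a partner). Sub-network extraction enumerates
all connected vertex subsets of a given size containing the anchors; the
enumeration is exact and deterministic, which is affordable because these
networks have tens of vertices, not thousands.

`compare_conditions()` partitions edges by unordered protein pair into
retained / lost / gained. The scientific use is crowding analysis: contacts
that persist when the same membrane proteins are given more space (vesicles
fused with protein-free liposomes) are stable modules; contacts that vanish
were plausibly proximity artefacts of the crowded membrane. The function
itself is symmetric bookkeeping — swapping the conditions swaps lost and
gained — and encodes no interpretation.

## Structure mapping

Distances are Cα–Cα with a default satisfaction threshold of 30 Å, the
conventional maximum span for a BS3-bridged lysine pair at Cα resolution.
Side-chain—side-chain metrics would need full side-chain coordinates, which
Cα-only models (including the generator's) lack.

When a protein is present in several chain copies, the reported distance is
the *minimum* over all admissible chain pairs and each residue pair yields
exactly one mapped record: a cross-link is explained if any copy arrangement
explains it. Homo-oligomeric links must place their two residues on distinct
chains; plain intra-molecular links prefer a single chain and fall back to
inter-chain placement only when no single chain resolves both residues.
Links whose residues are unresolved in every candidate chain are reported
`unmapped`, never dropped — missing density is information (flexible or
truncated regions), not absence of the link.

The random-cross-linking null draws residue *pairs* uniformly (with
replacement over pairs, excluding identical-residue self-pairs) from the
observed cross-linked lysines mappable to the structure, rather than drawing
residues independently: the observed data are pairings of reactive sites, so
the null must be too. Sampling is seed-deterministic; distances reuse the
exact mapping rules above. On real structures the null is broader and
longer-tailed than the observed distribution; on the generator's toy models
the effect is exaggerated (see below).

Conformational-state calls map every link onto two models: satisfied only in
A → `a_exclusive`, only in B → `b_exclusive`, both → `shared`, otherwise
`neither`. Unmappable counts as not-satisfied for exclusivity but is reported
distinctly, because "absent from the model" and "present but violated" are
different evidence.

## Topology and cleavage

Topology is an input annotation (UniProt-style segments), never predicted.
Segments are inclusive at both boundaries and must not overlap; a residue
outside every segment is `unannotated`, which propagates to the link label
rather than being guessed. The module reports compartment pairs and
label-site counts only — whether a labelled luminal loop implies cytosolic
accessibility is an interpretation left to the analyst. Proteolytic cleavage
(`cleave_sequence`) checks the expected residue at the cut site and conserves
sequence content; in the simulator, a cleavage event removes the released
fragment's residues from cross-linking, emulating toxin-treated conditions.

## The synthetic-data generator

`default_ground_truth()` defines the desk-scale study conditions used by the
tests and the acceptance script:

* 7 proteins with copy numbers 70 : 31 : 15 : 2 : 2 : 2 : 2, emulating the
  published synaptic-vesicle stoichiometry of its three major components and
  low-copy proton-pump subunits;
* 22 planted contacts — two per inter-protein pair (so that a single
  dropout-unlucky link cannot erase a true edge), two open-exclusive and two
  closed-exclusive contacts, one crowding contact with no structural basis,
  two homo-oligomer links and three plain intra links;
* 4 replicates, dropout 0.2, decoy rate 0.1, intensity CV 0.2. Dropout and
  CV are typical of label-free membrane proteomics; the decoy rate is
  deliberately above the 5 % FDR a search engine would pass through, to
  stress the replicate filter.

Sequences are built from tryptic blocks of 7–11 non-K/R/P residues ending in
K (occasionally R), so every planted lysine lies in an observable,
fragmentable peptide. Peptide response factors are lognormal but rescaled to
per-protein mean 1, which makes relative iBAQ recover copy fractions
*exactly* at zero noise — that exactness is what turns several tests into
sharp oracles. Intensity noise is multiplicative lognormal (standard for MS
intensities, preserves positivity) with the stated CV.

Toy structures are explicit Cα point sets written as PDB: residues involved
in contacts that must be close in a given model are co-located in small
jitter clusters (pairwise ≤ ~14 Å), clusters and unconstrained chains are
placed hundreds of Å apart, and contacts of the opposite exclusive state are
explicit far constraints. A contact required both close and far within one
cluster is rejected as unsatisfiable. This construction makes the open/closed
guarantees certain rather than probabilistic.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: no spectrum-level noise or m/z values (fragment
annotations are index lists, which is all the adjacency rule needs), no
retention-time or chromatography structure, no shared peptides between
proteins, no realistic protein fold (toy distances are bimodal: ~10 Å or
several hundred Å, so the null-vs-observed gap is far larger than on a real
structure), and no search-engine score model (scores are opaque uniform
draws). Conclusions about FDR behaviour, chromatographic artefacts or
absolute distance distributions require real data.

## Problem sizes and numerical notes

The test suite and `scripts/acceptance.R` run the full pipeline at the
default conditions above (~75 CSMs, ~28 links, 9-chain toy structures),
plus 1,000-sequence digestion oracle sweeps and 10⁵-draw null-sampler
checks; everything completes in well under a minute on one CPU. Replicate
medians use `stats::median`; normalisation tolerances in tests are 10⁻¹²
(pure arithmetic); the null sampler's enumeration check uses a 1 % tolerance
at 10⁵ draws, consistent with its Monte-Carlo standard error. Half-open
histogram bins `[k·w, (k+1)·w)` ensure each distance lands in exactly one
bin; the satisfaction rule itself is `distance ≤ threshold`, independent of
binning.

## Known limitations

* Cross-link FDR estimation is upstream (the search engine's) and out of
  scope; the replicate filter is a reproducibility filter, not an FDR.
* Isoform collapsing is off by default; networks report isoforms separately.
* Solvent-accessible-surface distances (SASD) are not computed; Cα–Cα
  straight-line distance can underestimate the effective span across a
  membrane or through a protein core.
* The tolerant CSM reader maps common column aliases but cannot guess
  arbitrary dialects; unknown columns pass through untouched.
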