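# svxl — downstream analysis of cross-linking MS on synaptic vesicle membranes

Chemical cross-linking mass spectrometry (XL-MS) covalently joins spatially
proximal residues — for the amine-reactive BS3 cross-linker, lysine side
chains and protein N-termini within roughly 30 Å Cα–Cα — and identifies the
linked peptide pairs from their fragment spectra. Applied to an intact
organelle such as the synaptic vesicle, it yields residue-resolved protein
interaction networks without antibodies or detergent solubilisation. `svxl`
implements the downstream analysis such an experiment needs once the search
engine has produced cross-link spectrum matches (CSMs) and peptide
intensities:

- **Quantification** (`compute_ibaq`, `estimate_stoichiometry`,
  `top_n_database`): intensity-based absolute quantification,
  iBAQ(p) = Σᵢ Iᵢ(p) / N_obs(p), where N_obs is the number of theoretically
  observable fully-tryptic peptides (default length window 7–30); relative
  iBAQ as a molar-fraction proxy; stoichiometry ratios against a reference
  subunit; top-N abundance ranking for a reduced search database.
- **Cross-link validation and aggregation** (`validate_fragments`,
  `aggregate_csms`, `filter_replicates`): a CSM validates when both peptides
  show a run of ≥ 4 adjacent b- or y-ions of reasonable intensity; validated
  CSMs aggregate to unique residue-pair cross-links classified intra / inter /
  homo-oligomeric (the latter by the equal-or-overlapping-peptide rule), then
  filtered by replicate support (default ≥ 2).
- **Interaction networks** (`build_network`, `network_degree`,
  `extract_subnetworks`, `compare_conditions`): protein-level edges with
  replicate tiers, hub degrees, anchored sub-network enumeration, and
  cross-condition retained/lost/gained partitions that separate stable
  interaction modules from crowding-induced contacts.
- **Structure mapping** (`load_structure`, `map_links`,
  `distance_histogram`, `random_null`, `state_compatibility`): Cα–Cα
  distances minimised over all admissible chain pairs (multi-copy subunits
  are mapped once), the ≤ 30 Å satisfaction rule, a random-cross-linking null
  over the observed lysines, and open/closed conformational-state calls.
- **Membrane topology** (`classify_link_topology`, `accessibility_report`,
  `cleave_sequence`): cytosolic/TMH/luminal annotation of residues and links,
  labelling-site accessibility summaries, and proteolytic-cleavage modelling
  (e.g. botulinum neurotoxin B cutting Synaptobrevin-2 between Q76 and F77).
- **Synthetic data** (`default_ground_truth`, `simulate_proteome`,
  `simulate_csms`, `simulate_structures`, `write_simulation`): a generator
  that plants known copy numbers, contacts, decoys, dropout and two-state toy
  structures, so every stage of the pipeline is verifiable against a
  manifest.

## Worked example

```r
library(svxl)

truth <- default_ground_truth(seed = 1)           # 7 proteins, 22 contacts
quant <- compute_ibaq(simulate_proteome(truth),
                      setNames(truth$proteins$sequence,
                               truth$proteins$protein_id))
estimate_stoichiometry(quant, reference = "SYT1",
                       members = c("SYB2", "SYP", "SYT1"))
#> # A tibble: 3 x 3
#>   protein_id ratio ratio_sd
#>   <chr>      <dbl>    <dbl>
#> 1 SYB2        4.59    0.425
#> 2 SYP         2.00    0.110
#> 3 SYT1        1       0

links <- filter_replicates(aggregate_csms(simulate_csms(truth)), 2)
network <- build_network(links)
network_recovery(truth, network)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1

models <- simulate_structures(truth)
calls <- state_compatibility(links, models$open, models$closed)
table(calls$verdict)
#> a_exclusive b_exclusive     neither      shared
#>           2           2           1          16
```

The stoichiometry ratios recover the planted 70:31:15 copy numbers
(4.67:2.07:1) within the simulated 20 % intensity noise; the filtered network
reproduces the planted inter-protein contact map exactly; and the
conformational-state calls recover the planted open-exclusive and
closed-exclusive contacts, with the planted crowding contact (no structural
basis in either model) called `neither`.

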