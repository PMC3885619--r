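# coevokit

Detection and quantification of inter-protein co-evolution between two
interacting gene families — the situation of an obligate heterodimer
such as the MAGO–Y14 core of the exon junction complex, where one
member of each family must keep binding the other in every organism
across the eukaryotic tree.

Two families under that constraint leave measurable traces:

* their pairwise evolutionary **distance matrices** correlate beyond
  what shared speciation explains (*MirrorTree*; here with the
  speciation signal removed by regression on a neutral marker such as
  18S rRNA, and significance from a **Mantel permutation test**:
  `p = (1 + #{R_perm >= R_obs}) / (1 + n_perm)`);
* specific **residue pairs** change together: for sites *i* (family A)
  and *j* (family B), the profiles `theta_k = B(a_k1, a_k2) / t_k` of
  BLOSUM transition scores normalized by Poisson-corrected divergence
  over sequence pairs *k* are correlated (CAPS-style statistic), with
  significance from a resampling null of unrelated column pairs and
  grouping of significant pairs by connectivity;
* the families evolve slowly under purifying selection, measurable as
  **dN/dS** by modified Nei–Gojobori counting with a Kimura-2P-style
  correction (`d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)` applied to the
  transitional/transversional split of each difference class);
* some residues are **clade-specific** (fixed in one clade, absent from
  a contrasted clade, strictly or at residue-class level);
* the interaction trait itself is ancestral: **Fitch parsimony** and a
  symmetric two-state **Mk model** trace presence/absence of
  heterodimerization on the species tree.

The package implements all of the above plus a phylogenetic simulator
of co-evolving families (correlated lineage rates, planted compensatory
site pairs, clock-like marker, decoy family, paralog duplications) with
exported ground truth, used to validate every detector.

## Worked example

```r
library(coevokit)

tr  <- simulate_tree(36, seed = 1)                 # pure-birth species tree
sim <- simulate_families(tr, sim_config(), seed = 2)

mean_pairwise_identity(sim$famA)   # 82.2  (slow MAGO-like family)
mean_pairwise_identity(sim$famB)   # 55.8  (faster Y14-like family)

# distance-matrix co-evolution, corrected by the neutral marker
tol_mirrortree(sim$famA, sim$famB, sim$pairing,
               marker = sim$marker, n_perm = 9999, seed = 3)
#> MirrorTree: R = 0.8651 (uncorrected 0.9166), p = 0.0001 [correction: residual]

# the decoy family is the negative control
decoy_pairing <- dplyr::distinct(dplyr::mutate(sim$pairing,
                 member_b = paste0(organism_id, "_D1")))
tol_mirrortree(sim$famA, sim$decoy, decoy_pairing,
               marker = sim$marker, n_perm = 9999, seed = 3)
#> MirrorTree: R = -0.1504 (uncorrected 0.1474), p = 0.9206 [correction: residual]

# correlated-mutation scan with connectivity grouping
scan <- caps_scan(sim$famA, sim$famB, sim$pairing, seed = 4)
scan
#> <caps_result> 21875 site pairs scored, 1063 significant (rho > 0.757), 8 groups

# ancestral state of the (invariant) interaction trait
states <- setNames(rep(1L, 36), tr$tip.label)
fitch_trace(tr, states)
#> Fitch trace: root set {1}, 0 change(s)
mk2_marginal(tr, states)
#> Mk2 marginal trace: rate = 7.136e-05, logLik = -0.6939, P(root = 1) = 1.0000
```

The corrected MirrorTree correlation of the co-evolving pair (0.87) is
far above the decoy's (-0.15): after removing the speciation signal,
only genuinely coupled families stay correlated. The scan's significant
site pairs include the simulator's five planted compensatory pairs
(`sim$truth$coupled_pairs`), and an interaction present in every extant
organism reconstructs as present at the root under both parsimony and
likelihood — the pattern expected of an obligate heterodimer that
originated with the families themselves.

Result objects are tibble-friendly: `tidy()` gives per-pair/per-node
tables, `glance()` one-row summaries, `autoplot()` standard ggplot2
views. `run_pipeline()` chains every stage and writes stage TSVs plus a
consolidated JSON report.

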