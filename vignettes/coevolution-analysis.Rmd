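---
title: "Detecting inter-protein co-evolution with coevokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting inter-protein co-evolution with coevokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevokit)
```

## The problem

Two protein families that function only as an obligate heterodimer — the
motivating case is the MAGO/Y14 core of the exon junction complex, which
pairs one MAGO with one Y14 in every eukaryote examined — face a joint
constraint: any substitution that degrades the interface must either be
avoided (purifying selection) or compensated by a substitution in the
partner. Over long timescales the second mechanism leaves a statistical
fingerprint: the two families' evolutionary histories are more similar
than speciation alone explains, and specific residue positions in the two
alignments change together.

`coevokit` implements the full detection pipeline for this fingerprint:

1. **Rates and selection** — pairwise p-distances with Poisson
   correction, Kimura-2P nucleotide distances, and dN/dS per codon pair
   by modified Nei–Gojobori counting with a Kimura-2P-style correction,
   plus two-sample Z comparisons of per-pair rate values between
   families.
2. **MirrorTree with speciation correction** — correlation of the two
   families' paralog-expanded distance matrices after removing the
   component explained by a clock-like neutral marker (an 18S rRNA
   analog), with a Mantel permutation test.
3. **Correlated mutations** — a CAPS-style scan for pairs of alignment
   columns (one per family) whose substitution-score profiles across
   sequence pairs correlate, followed by connectivity grouping and
   region/domain overlap reporting.
4. **Clade-specific residues** — columns where one clade is fixed for a
   residue (or residue class) absent from a contrasted clade, and their
   overlap with the correlated-mutation calls.
5. **Ancestral states** — Fitch parsimony and a two-state Mk model for
   the binary "heterodimerizes / does not" trait on a species tree.
6. **A simulator** that generates co-evolving families with known ground
   truth, used throughout the test suite and the acceptance script.

## Models and statistics

### Distances and dN/dS

p-distances use pairwise deletion by default: each sequence pair is
compared over the columns where neither carries a gap or unknown symbol;
a pair with no comparable columns is flagged missing, never reported as
zero. The Poisson correction $d = -\ln(1 - p)$ accounts for multiple
hits; $p \ge 1$ is reported as saturation, not silently truncated.

The Kimura two-parameter distance
$d = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q)$ separates
transition ($P$) and transversion ($Q$) proportions. In the regime where
all substitution types are equally likely, transversions are two of the
three change types, so $Q = 2P$ and the formula collapses to the
familiar $-\tfrac34\ln(1 - \tfrac43 p)$; the test suite asserts this
identity to 1e-12.

`dnds_pair()` counts synonymous and nonsynonymous sites with
transition/transversion weighting (`kappa`, default 2): at each codon
position the single transition carries weight `kappa` and each
transversion weight 1, and the position contributes the weighted
fraction of its viable changes that are synonymous. Changes to stop
codons are excluded from both numerator and denominator — the
convention that makes a stop-rejecting neutral mutation process estimate
$\omega = 1$ without bias, which the suite verifies (mean
$\hat\omega \in [0.8, 1.2]$ over 20 neutral pairs of 300 codons).
Differences between codons are averaged with equal weight over the
shortest substitution pathways, skipping pathways through stop codons.
The correction applies the Kimura-2P form separately to the synonymous
and nonsynonymous difference proportions using their
transitional/transversional split. Very short sequences can leave
$p_S > 1$; the pair is then flagged `dS_saturated` rather than given an
arbitrary value.

Family-level comparisons (`z_compare()`) use a two-sample Z on the
pooled per-pair values. Pairwise distances are not independent, so the
p-values are approximate and documented as such.

### MirrorTree with neutral-marker correction

For each row of the pairing table (one organism plus one member of each
family; an organism with $m$ A-paralogs and $n$ B-paralogs contributes
$m \times n$ rows), `build_paired_matrices()` populates index-aligned
matrices $X$ and $Y$ of Poisson-corrected protein distances, and $S$ of
marker distances keyed by organism. Both families track the species
tree, so $X$ and $Y$ correlate even without co-evolution;
`speciation_correct()` removes the marker-explained component by
regression residuals, $X' = X - \hat\beta_X S$ with $\hat\beta_X$ the
least-squares slope of the off-diagonal $X$ cells on the $S$ cells.
Residual correction is the default because protein and rRNA distances
live on different scales; element-wise subtraction is available
(`mode = "subtract"`). Same-organism cells ($S = 0$) pass through
unchanged, and a constant marker skips the correction with a warning.

`mantel_test()` computes the Pearson correlation over off-diagonal
upper-triangle cells and builds the null by jointly permuting row and
column labels of one matrix:
$p = (1 + \#\{R_\pi \ge R_{\mathrm{obs}}\}) / (1 + n_{\mathrm{perm}})$,
one-sided for positive association by default (a two-sided option
exists). Duplicated-organism rows are permuted as ordinary labels. The
default `n_perm = 9999` resolves p-values to 1e-4; the statistic is
cross-checked against an independent implementation (vegan) in the test
suite, and the permutation p is verified uniform under independence.

### Correlated mutations (CAPS-style)

For a sequence pair $(i, j)$ and an alignment column, the normalized
transition score is $\theta = B(a_i, a_j) / t_{ij}$ with $B$ a
substitution matrix (BLOSUM62 by default, configurable) and $t_{ij}$
the Poisson-corrected distance between the two sequences — older pairs
are discounted because they have had longer to accumulate coincidental
double substitutions. Co-evolution between a family-A column and a
family-B column is the Pearson correlation of their $\theta$ vectors
over the shared sequence pairs (pairs correspond through the organism
pairing; site pairs sharing fewer than 3 usable entries are skipped).

Three numerical choices matter here:

* **Minimum divergence.** $\theta$ diverges as $t_{ij} \to 0$, so a
  single near-identical pair (young paralogs) would dominate every
  site's profile and drown the signal. Pairs below
  `min_divergence = 0.05` corrected distance are dropped (configurable).
* **Column usability.** Columns with more than 50% gaps are excluded
  (configurable), as are invariant columns, which carry no variance.
* **The null.** Every site shares the $1/t$ normalization, so even
  unrelated columns correlate substantially — the baseline must be
  measured, not assumed zero. `significance_filter()` builds the null
  from randomly paired unrelated columns (one family's site labels
  shuffled, the sequence-pair alignment intact) and calls a pair
  significant above the $(1-\alpha)$ null quantile. On independently
  evolving families this calibrates to $\approx \alpha$ by
  construction, which the suite verifies.

Significant pairs are grouped by connectivity (connected components of
the bipartite site graph), numbered deterministically by smallest
family-A site so outputs are diff-stable. Each group reports the mean
correlation of its member pairs and `mean_Dc`, implemented as the mean
per-site variance of the member sites' $\theta$ values (the underlying
published quantity is described only loosely, so the definition is
stated here and in the function documentation).
`residue_region_report()` maps significant sites to ungapped
reference-residue numbers (1-based inclusive everywhere), counts them
inside annotated regions (core domain, RNA-binding domain, minimal
interaction domains), flags conserved versus changed columns, and
classifies groups as touching both families' domains, one, or neither.

### Clade-specific residues

`detect_clade_specific()` calls a column when at least one clade
(meeting `min_clade_size`, default 2 — singletons never drive a call)
is uniform under the rule and its residue set is disjoint from another
qualifying clade's. The strict rule requires within-clade identity; the
class rule relaxes uniformity to the five-class partition
(small-nonpolar G/A/S/T, hydrophobic C/V/I/L/P/F/Y/M/W, polar N/Q/H,
negative D/E, positive K/R) while keeping residue-level disjointness,
so strict calls are always a subset of class calls. Gaps disqualify a
clade at that column. The default contrast is pairwise (any qualifying
clade pair produces a call); requiring all clades to qualify
simultaneously is available via `contrast = "all"`. Overlap summaries
against the correlated-mutation results report counts, covered groups
and pooled percentages.

### Ancestral states

`fitch_trace()` is the standard bottom-up intersection/union pass for a
binary trait; the suite checks it against a brute-force minimum over
all internal labelings, exhaustively for every rooted 5-tip topology
and tip assignment. `mk2_marginal()` computes marginal posterior state
probabilities under a single symmetric rate (equal root prior) with a
down-pass/up-pass sweep; a richer model is unidentifiable for a trait
that is present in nearly every extant taxon, which is exactly the
situation for obligate heterodimerization. The rate can be fixed or
optimized by bounded 1-D search; trees without branch lengths get the
cladogram convention of unit branches. Marginals are verified against
exhaustive enumeration to 1e-10, and the likelihood is invariant to
re-rooting, as a symmetric model requires.

## What the simulator emulates — and what it does not

`simulate_tree()` draws a pure-birth tree rescaled to height 1;
`simulate_families()` evolves four alignments along it:

* **Family A** (MAGO-like): uniform-exchange amino-acid substitutions at
  `rate_a = 0.13` per site per unit branch length, chosen so the default
  36-organism bundle averages ~80% pairwise identity, matching the slow,
  conserved family of the motivating system.
* **Family B** (Y14-like): `rate_b = 0.48`, giving ~50% identity — the
  faster partner.
* Per-branch lognormal rate multipliers (log-sd 0.6) shared between A
  and B with correlation 0.9 by default: lineages that speed up do so in
  both families, the signature MirrorTree detects.
* **Coupled site pairs** (5 by default, spread along the alignments):
  the family-A members run at `coupled_rate = 0.75` — compensatory
  positions are by definition the changing ones — and each substitution
  there triggers a same-branch substitution at the family-B partner with
  probability `compensation_prob`. The partner residue is chosen to
  score well against the new family-A residue under BLOSUM62
  (favorable case); `compensation_mode = "random"` provides the hard
  case. Partner sites change only through this channel: an
  uncompensated change at a compensated site is treated as deleterious.
* **Neutral marker**: 1500 nt evolving strictly clock-like at rate 0.5 —
  the 18S rRNA analog used for speciation correction.
* **Decoy family** (LFY analog): family-B-like rates with lineage
  multipliers independent of both families — the negative control.
* **Paralogs**: by default the first organism carries duplicates of both
  families, branching at its ancestral node and evolving jointly under
  the same compensatory process, mimicking the cereal duplicates that
  force the paralog-expanded pairing.

The simulator deliberately omits indels (so alignments are exact),
codon-level selection (dN/dS is validated on separately generated
neutral nucleotide fixtures), site-rate heterogeneity beyond the coupled
channel, and compositional biases. Passing tests therefore demonstrate
that the detectors recover the statistical structure they target —
correlated lineage rates and same-branch compensatory substitutions —
not that real alignments are this clean. On real data, alignment error,
indels and long-branch saturation will all lower power.

### Problem sizes used in the checks

The acceptance-style checks run at the scales the methods were designed
for: Mantel calibration on 1000 independent 10x10 matrix pairs with 999
permutations; MirrorTree discrimination on 100 simulated bundles of 30
organisms x 200 columns; planted-pair recovery on 50 such bundles with
5 coupled pairs at compensation 1.0 (decoy false-positive rates pooled
over 15 bundles); the Fitch oracle exhaustively over all 105 rooted
5-tip topologies x 32 tip assignments; neutral dN/dS on 20 pairs of 300
codons. `scripts/acceptance.R` re-measures the same quantities from
scratch at moderately reduced replicate counts and one full 36-organism
default-condition pipeline run.

## Worked example

```{r example, eval = FALSE}
tr <- simulate_tree(36, seed = 1)
sim <- simulate_families(tr, sim_config(), seed = 2)

# MirrorTree with 18S-analog correction, decoy control
mt <- tol_mirrortree(sim$famA, sim$famB, sim$pairing,
                     marker = sim$marker, n_perm = 9999, seed = 3)
glance(mt)
autoplot(mt)

# correlated mutations, grouping, clade overlap
scan <- caps_scan(sim$famA, sim$famB, sim$pairing, seed = 4)
glance(scan)
calls_a <- detect_clade_specific(sim$famA, sim$clades)
calls_b <- detect_clade_specific(sim$famB, sim$clades)
caps_clade_overlap(scan, calls_a, calls_b)

# ancestral state of an invariant interaction trait
states <- setNames(rep(1L, 36), tr$tip.label)
fitch_trace(tr, states)
mk2_marginal(tr, states)

# or everything at once
report <- run_pipeline(sim, seed = 5, outdir = "run1")
```

## Known limitations

* The correlated-mutation statistic inherits the known weaknesses of
  divergence-normalized profile correlation: the shared $1/t$ factor
  produces a high baseline, power depends on the coupled sites actually
  substituting, and the resampling null measures the baseline rather
  than removing it. Treat significant pairs as candidates, not proof.
* The speciation correction is linear; lineage-specific marker rate
  variation (violations of the marker clock) leaks into the corrected
  matrices.
* The Mk model uses a single symmetric rate. For traits with strongly
  asymmetric gain/loss this is the wrong model, but such a trait would
  also not be near-invariant.
* dN/dS by counting methods saturates quickly (dS above ~2); saturated
  pairs are flagged and excluded from family means, and the counts of
  exclusions are reported.
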