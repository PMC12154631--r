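---
title: "Mapping allosteric rewiring from coupled alternate conformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping allosteric rewiring from coupled alternate conformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altrin)
```

## The problem and the model

High-resolution crystallographic electron density often supports several
discrete conformations for a residue. Multiconformer models (such as qFit
output) encode these as *alternate conformations* — altloc-labelled atom
groups with fractional occupancies. When alternate conformations of
*different* residues sit within contact distance of each other, their motions
are physically coupled: one rotamer excursion requires, permits, or blocks
another. Networks of such couplings, traced across a whole protein family,
are a structural readout of allosteric wiring.

`altrin` turns one multiconformer structure into a weighted **residue
interaction network (RIN)** and a set of related structures into a
**multinetwork** that supports quantitative comparison between structural
subsets (ligand-bound vs apo, one loop state vs another, one enzyme vs its
paralogs).

### Individual-network stage

For two residues $a$ and $b$ that are not sequence-adjacent, the edge weight
is

$$w_{ab} = \frac{P_{ab}}{U_a + U_b},$$

where $P_{ab}$ counts distinct atom pairs between the *alternate-conformation
atoms* of the two residues (atoms carrying a non-blank altloc label) lying
within the contact cutoff (default 4 Å), over all conformer combinations, and
$U_x$ is the number of unique heavy-atom names of residue $x$. Dividing by
residue size keeps a tryptophan from out-scoring a serine merely by atom
count. At least one of the two residues must have at least `min_conformers`
(default 2) alternate conformations: a flexible residue packing against a
rigid one is still a coupling candidate, while two rigid residues are not.
Only non-blank-altloc atoms generate contacts — blank-altloc (shared) atoms
would swamp the heterogeneity signal in high-resolution structures, where
nearly every residue touches its neighbours.

Sequence-adjacent residues are always in covalent contact, so generic spatial
counting would flood the network with trivial edges. They are handled by a
separate rule: maximal runs of consecutive residues in which *every* residue
has two or more backbone conformers are detected, extending residue by
residue while the condition holds; within a run, each adjacent pair receives
an edge weighted by its backbone altloc-atom contact count, normalized the
same way. A run interrupted by a single rigid-backbone residue contributes
nothing across the gap.

Implementation note: candidate residue pairs are pre-filtered with a
centroid-plus-radius bound that can never discard a pair containing a
contact, so results are identical to the unfiltered $O(n^2 \cdot
\text{atoms}^2)$ computation — the test suite asserts this equivalence
against a brute-force oracle to $10^{-9}$.

### Multinetwork stage

Per-structure networks are re-keyed from author residue numbers to the
columns of a structure-based multiple sequence alignment, so that analogous
residues across the family share a node. Residues aligned to reference-gap
columns keep their column key but carry no reference number ("no analogous
residue"); edges with an unmapped endpoint are dropped and counted.

Structures at better resolution carry more modeled alternate conformations
and would otherwise dominate any aggregate. Each aligned network with total
edge weight $T > 1$ is therefore rescaled so its total becomes $\ln(1 + T)$
(every edge multiplied by $\ln(1+T)/T$); totals at or below 1 are left
unchanged, since the scaling would inflate them. The raw total and scale
factor are recorded so the normalization is invertible.

A **sum network** adds normalized weights per edge over any metadata-defined
subset, optionally divided by subset size (*per-structure averaging* —
required whenever subsets of different sizes are compared). The per-residue
**weighted degree** (sum of incident edge weights) summarizes each node, and
$\Delta\text{degree}(r) = \text{degree}_A(r) - \text{degree}_B(r)$, computed
on untrimmed, per-structure-averaged subset sums, maps rewiring between
conditions. The sign convention is first-named minus second. As a negative
control, the structures are split into random complementary halves and
$\Delta$degree is averaged over 70 splits (seeded, bit-reproducible); a
featureless averaged profile indicates contrasts are not partition
artifacts. Before interpreting any contrast, a one-tailed Mann–Whitney U
test on the two subsets' resolution distributions guards against resolution
imbalance masquerading as rewiring; the implementation enumerates all group
assignments exactly when `choose(nA+nB, nA)` is small (exact even under
ties) and uses the tie-corrected normal approximation otherwise.

For presentation, sum networks are usually pruned to their strongest edges.
`trim_top_fraction()` keeps the top `ceiling(f * n)` edges, retains all
edges tied at the threshold (determinism without arbitrary ordering), and
records `f` so a repeated trim at the same fraction is a no-op — the
fraction always refers to the untrimmed parent network.

## Community structure and colocalization

Communities are found by the Girvan–Newman procedure: iteratively delete the
edge of highest betweenness, recording the partition and weighted modularity
each time the graph gains a component. Edge weights enter betweenness as
connection strengths (distance $= 1/w$, so strong couplings are short) and
enter modularity as weights. The chosen level is the first whose modularity
is within $\varepsilon$ (default 0.005) of the running maximum and whose
gain over the next level is below $\varepsilon$ — the modularity plateau.
On clique-and-bridge benchmark graphs this plateau partition coincides with
exhaustive modularity maximization (asserted in the tests up to 8 nodes by
full set-partition enumeration); on graphs without clear community
structure, such as weighted paths, greedy betweenness removal is known to
fall short of the exhaustive optimum, which is a property of the algorithm
itself.

To ask whether the network colocalizes with an external residue set (a
coevolving sector, NMR-dynamic residues, interface residues), every residue
of a representative structure is scored by how many network residues lie
within 4 Å of it (minimum heavy-atom distance, self excluded). The
nearby-counts of the set of interest are compared with those of size-matched
random residue sets — drawn uniformly without replacement, pooled over
`n_random` draws — by a two-sample Kolmogorov–Smirnov test, alongside the
Jaccard ratio of the two residue sets. The exact two-sample KS distribution
is used whenever `n1 * n2 <= 2e6`: the asymptotic formula is measurably
conservative at typical set sizes (empirical type-I error 0.023 at nominal
0.05 with sets of 30), while the exact path restores calibration (~0.04,
inside the tested [0.03, 0.07] band). A per-draw mode (one KS test per draw,
median p) is available; pooling is the default. Curated mutations can be
binned by their nearby-count (left-inclusive bins, last bin closed, empty
bins reported as undefined rather than 0), and degree can be regressed on
per-column sequence conservation — the modal non-gap residue frequency, with
gaps counted in the denominator by default (`exclude_gaps` switches the
convention; deposited conservation percentages in the literature use either).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `contact_cutoff` | 4.0 Å | heavy-atom distance for a contact |
| `min_conformers` | 2 (one side) | conformers needed to contribute altloc atoms |
| `size_normalization` | `sum_atoms` | divide by $U_a+U_b$; `geometric_mean` available |
| log normalization | $\ln(1+T)$ | base and offset configurable |
| `keep_fraction` | 0.05 | sum-network pruning fraction |
| plateau `eps` | 0.005 | modularity-plateau tolerance |
| `n_samples` | 70 | random-half control splits |
| `n_random` | 100 | random sets per colocalization test |

The 4 Å cutoff and the residue-size normalization follow long-standing
practice for distance-based protein RINs; the specific log-normalization
target $\ln(1+T)$ and the per-adjacent-pair treatment of sequential backbone
runs are this package's concrete realizations of the coarser published
descriptions, and both are isolated behind parameters precisely because they
are interpretive choices. Occupancies do not weight contact counts, and
zero-occupancy conformers are retained: couplings are treated as present or
absent, not probability-weighted.

## What the synthetic generator does and does not emulate

`fixture_spec()`/`generate_structure()`/`generate_family()` produce
structures whose *network content is known by construction*: residues on an
extended chain with 6 Å spacing (sequence-adjacent backbones in peptide-bond
contact, residues two apart at 8.6 Å minimum), planted long-range contacts
realized by altloc stub-atom pairs in lanes separated by 9 Å above the
chain, backbone-altloc runs with a 1 Å conformer displacement (the scale of
typical qFit alternate conformations), Gaussian coordinate noise, and
per-structure decoy contacts sized so the shared planted edges are exactly
the top 20% of the family sum network. Families come with an aligned FASTA
(including a one-residue insertion to exercise gap handling), a metadata
table, and subset labels, with an optional subset-specific contact that
plants a known $\Delta$degree signal.

The generator makes no attempt at chemical realism: no rotamer libraries, no
electron density, no occupancy refinement, no crystal contacts. Passing
tests therefore demonstrate that the bookkeeping — altloc assembly, distance
counting, alignment mapping, normalization algebra, statistics — is exact,
not that the method's biological interpretation on real qFit models is
validated. One behavior worth knowing when designing contrasts on real data,
visible even in the synthetic families: because log normalization rescales
whole networks, a subset-specific edge slightly shifts the normalized weight
of *shared* edges too, so $\Delta$degree shows small systematic background
away from the truly rewired residues, concentrated on the heaviest shared
edges.

## Numerical and degenerate-case choices

* Edges are stored with the lower residue key first and sorted; betweenness
  ties break by canonical edge order — all outputs are deterministic for a
  fixed input and seed.
* Blank-altloc atoms belong to every conformer of their residue, so a
  residue with only side-chain altlocs still has a complete backbone per
  conformer.
* Conformer occupancy sums outside $(0, 1.02]$ are logged, never fatal
  (deposited models round occupancies).
* Hydrogens are excluded everywhere (models vary in hydrogen treatment
  across resolutions); waters and non-protein heteroatoms never contribute
  atoms; selenomethionine counts as methionine.
* Sequence/structure reconciliation tolerates up to 2% mismatched positions
  (engineered mutants are common in crystal structures) and reports the
  first mismatch on failure.
* An all-gap alignment column has conservation 0; a constant conservation
  vector makes the degree regression degenerate — reported as $R^2 = 0$
  with a warning rather than an error.
* Structure attributes written into the PDB B-factor field are clamped to
  the field range $[-99.99, 999.99]$ with a warning; unmapped residues get
  a sentinel value.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated
fixtures: families of 10–12 structures of 30–40 residues, oracle-equivalence
sweeps over 22 structures of up to 50 residues, 2000 simulated draws for the
KS calibration, and 70-sample random-half controls. These sizes give stable
statistics for every assertion while keeping a full run in well under a
minute; all of them scale linearly if larger checks are wanted.

## Known limitations

* Interactions are typed only by distance; no hydrogen-bond/salt-bridge
  classification or physics-based scoring (the edge model is deliberately
  extensible there).
* The sequential-backbone treatment is the package's interpretation of a
  loosely specified published procedure; it is the largest interpretive
  choice and is flagged as such.
* Community detection by Girvan–Newman is greedy and can miss the global
  modularity optimum on graphs without pronounced communities.
* $\Delta$degree carries no significance machinery beyond the random-half
  control; it is a comparison, not a test.
* Colocalization counts depend on the chosen representative structure.

## A minimal session

```{r example}
spec <- fixture_spec(
  n_residues = 30, n_structures = 10,
  planted_contacts = data.frame(i = c(4L, 12L), j = c(25L, 28L)),
  backbone_runs = list(18:20), noise_sd = 0.15, seed = 1)
fam <- generate_family(spec, subset_effect = c(6L, 22L))

rins <- lapply(fam$structures, build_network)
aligned <- lapply(names(rins), function(id)
  log_normalize(align_rin(rins[[id]], fam$maps[[id]])))
mn <- build_multinetwork(aligned, fam$metadata,
                         ref_of_col = fam$maps[[fam$reference_id]]$ref_of_col)

trimmed <- trim_top_fraction(sum_network(mn), 0.2)
girvan_newman(trimmed)

d <- delta_degree(mn, fam$subset_a, fam$subset_b,
                  label_a = "closed", label_b = "open")
head(d[order(-d$delta), ])
```
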