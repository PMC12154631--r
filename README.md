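# altrin

Residue interaction networks from alternate conformations in multiconformer
crystal structures.

## What problem this solves

Multiconformer crystallographic models (qFit output and similar) represent
residues with several discrete alternate conformations — altloc-labelled
atom groups at fractional occupancy. When alternate conformations of
different residues lie within contact distance, their motions are coupled,
and family-wide patterns of such couplings trace allosteric wiring. `altrin`
is for structural biologists who have a set of related multiconformer
structures (one protein family, many crystal forms, ligand states, loop
states) and want to:

1. build a weighted **residue interaction network (RIN)** per structure from
   altloc-atom contacts,
2. align those networks onto common reference numbering through a
   structure-based multiple sequence alignment,
3. aggregate them into normalized **sum networks**, and
4. compare structural subsets quantitatively — degree differences, random
   negative controls, community structure, colocalization with residue sets
   of interest.

## The model in brief

For non-sequence-adjacent residues *a*, *b* the edge weight is

&nbsp;&nbsp;&nbsp;&nbsp;*w(a,b) = P(a,b) / (U(a) + U(b))*

where *P* counts atom pairs between the residues' alternate-conformation
atoms within 4 Å (over all conformer combinations, each distinct pair once)
and *U* is each residue's unique heavy-atom count; at least one residue must
have ≥ 2 conformers. Sequence-adjacent residues get edges only through
maximal runs of consecutive backbone-altloc residues (peptide-coupled
motion). Per structure, networks with total weight *T* > 1 are rescaled to a
total of ln(1 + *T*) so high-resolution structures cannot dominate the
aggregate. Subset sum networks are compared per residue by weighted-degree
difference (Δdegree), with 70-sample random-half controls, one-tailed
Mann–Whitney resolution-balance checks, Girvan–Newman communities at the
modularity plateau, and Kolmogorov–Smirnov colocalization statistics.
Details and rationale: `vignettes/coupled-conformation-networks.Rmd`.

## Worked example

The package ships a synthetic-structure generator with known ground truth,
so the whole pipeline runs without any downloads:

```r
library(altrin)

spec <- fixture_spec(
  n_residues = 30, n_structures = 10,
  planted_contacts = data.frame(i = c(4L, 12L), j = c(25L, 28L)),
  backbone_runs = list(18:20), noise_sd = 0.15, seed = 1)
fam <- generate_family(spec, subset_effect = c(6L, 22L))

rins <- lapply(fam$structures, build_network)
rins[[1]]
#> Residue interaction network syn01
#>   nodes: 30  edges: 7  total weight: 3.1641

aligned <- lapply(names(rins), function(id)
  log_normalize(align_rin(rins[[id]], fam$maps[[id]])))
mn <- build_multinetwork(aligned, fam$metadata,
                         ref_of_col = fam$maps[[fam$reference_id]]$ref_of_col)

trimmed <- trim_top_fraction(sum_network(mn), 0.2)
trimmed
#> Sum network over 10 structures: 9 nodes, 5 edges
girvan_newman(trimmed)
#> Community partition: 4 communities, modularity 0.5077

d <- delta_degree(mn, fam$subset_a, fam$subset_b,
                  label_a = "closed", label_b = "open")
head(d[order(-d$delta), ], 4)
#>    column ref_resno      delta
#> 23     23        22 0.17071445
#> 6       6         6 0.13462673
#> 13     13        13 0.05757429
#> 18     18        17 0.05352569
```

The first structure's 7 edges are the two family-wide planted contacts, two
sequential-backbone edges inside the 18–20 run, two per-structure decoy
contacts, and the subset-specific contact at residues 6/22 (planted in the
first half of the family only). Trimming the 10-structure sum network to its top 20% recovers
exactly the five family-wide edges, and the Δdegree contrast between the
"closed" and "open" halves peaks precisely at the planted subset-specific
residues (reference numbers 22 and 6) — the remaining profile is
log-normalization background, an order of magnitude weaker.

On real data, replace the generator with a directory of multiconformer PDB
files, the family MSA, and a metadata table; `run_pipeline()` (or
`inst/cli/altrin.R run --config config.yaml`) drives the same stages from a
single declarative configuration and writes TSV/GraphML networks, degree and
Δdegree profiles, community tables, a B-factor-mapped structure for
rendering, and a JSON run report.

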