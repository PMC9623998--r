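# denshot

Densest-subgraph prediction of protein–protein interaction hot spots.

## The problem

In a protein–protein binding interface the binding free energy is not
spread evenly over residues: a few *hot spots* contribute most of it. A
residue is experimentally a hot spot when mutating it to alanine raises
the binding free energy by ΔΔG ≥ 2.0 kcal/mol, with ΔG = RT ln K_d
(T = 298.15 K). Alanine-scanning data are scarce, so graph-theoretic
predictors that need no training data are attractive — but classical ones
(minimum-cut trees, bicliques) have low recall.

`denshot` predicts hot spots from a single **residue interaction
network** (RIN): vertices are interface residues, and two residues on
*different* chains are joined when some atom pair (a, b) satisfies

    d(a, b) ≤ r(a) + r(b) + 2.75 Å

where r is the van der Waals radius (Bondi table by default) and 2.75 Å
is the diameter of a water molecule. Only residues with at least one
contact become vertices. Candidate hot spots are then the members of
high-density subgraphs, ρ(S) = |E(S)| / |V(S)|.

## The methods

All four extractors are exact, built on the densest-subgraph LP
relaxation (edge variables x_e, vertex variables y_v; maximise Σx subject
to x_e ≤ y at both endpoints, Σy ≤ 1; the optimum equals the maximum
density D, and thresholding y at 1/|V| yields a densest subgraph):

- **DS** — one densest subgraph (`find_densest`).
- **Min-DS** — *all* minimal densest subgraphs, found by greedy LP
  descent inside a densest subgraph plus peeling; distinct minimal
  densest subgraphs are always vertex-disjoint
  (`find_all_minimal_densest`).
- **Max-DS** — the unique maximal densest subgraph (union of all densest
  subgraphs), by ILP or by iterated LP growth
  (`find_maximal_densest_ilp`, `find_maximal_densest_iterative`).
- **Min-SDS** — the recommended predictor: keeps peeling minimal densest
  subgraphs while their density stays ≥ θ·D for a tolerance θ ∈ (0, 1)
  (default θ = 0.85), so secondary binding interfaces with slightly lower
  density are also reported (`min_sds`).

Predictions are scored against alanine-scanning labels with precision,
recall, F1 and F2 (F2 weights recall, which matters because many true
hot spots are unmeasured).

## Worked example

```r
library(denshot)

# disjoint K4, K3 and K2 — maximum density D = 3/2
g <- worked_example_graph()
min_sds(g, theta = 0.6)
#> min-sds extraction: 2 subgraph(s), graph maximum density 6/4 (1.5), theta = 0.6
#> <min-sds> 4 vertices, 6 edges, density 6/4 (1.5)
#>   {a1, a2, a3, a4}
#> <min-sds> 3 vertices, 3 edges, density 3/3 (1)
#>   {b1, b2, b3}
```

At θ = 0.6 the threshold is 0.6 · 3/2 = 0.9: the K4 (density 3/2) and the
triangle (density 1) are selected, the lone edge (density 1/2) is not.
At θ = 0.3 all three components are returned; at θ = 0.9 only the K4.

From a structure file:

```r
atoms <- parse_structure("complex.pdb")
net   <- build_rin(atoms)                 # residue interaction network
res   <- min_sds(net, theta = 0.85)      # predicted hot-spot subgraphs
recs  <- read_skempi("skempi_v2.csv")    # alanine-scanning Kd table
labs  <- label_hotspots(recs, net)       # ddG >= 2.0 kcal/mol labels
evaluate_prediction(res, labs)           # tp/fp/fn, P, R, F1, F2
```

A thin command-line front end wraps the same functions
(`inst/scripts/denshot`): `build-rin`, `predict`, `evaluate`,
`sweep-theta`, `make-fixtures`.

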