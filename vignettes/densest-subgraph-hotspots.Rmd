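---
title: "Densest-subgraph methods for interaction hot spots: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Densest-subgraph methods for interaction hot spots: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denshot)
```

## The model

A protein complex is reduced to a residue interaction network: vertices
are residues, and an edge joins two residues on *different* chains when
some atom pair (a, b) satisfies d(a, b) ≤ r(a) + r(b) + 2.75 Å — the van
der Waals radii plus one water diameter, i.e. the two atoms could not
accommodate a water molecule between them. Residues without any contact
are dropped. Hot spots cluster at tightly packed interface cores, and
tight packing means many inter-chain contacts, so candidate hot spots
are sought in subgraphs of high density

$$\rho(S) = \frac{|E(S)|}{|V(S)|},$$

over vertex-induced subgraphs $S$. The package provides four extractors.

**DS.** The densest-subgraph LP relaxation: a variable $x_{ij} \in [0,1]$
per edge and $y_i \in [0,1]$ per vertex,

$$\max \sum_{(i,j)\in E} x_{ij}
\quad\text{s.t.}\quad x_{ij} \le y_i,\; x_{ij} \le y_j,\;
\sum_i y_i \le 1,\; x, y \ge 0.$$

The optimum equals the maximum density $D$, and for any optimal solution
the threshold set $\{i : y_i \ge 1/|V|\}$ induces a densest subgraph.
The threshold (rather than $y_i > 0$) guards against solver round-off.

**Min-DS.** A *minimal* densest subgraph has no proper induced subgraph
that is also densest. Two distinct minimal densest subgraphs cannot
intersect — their intersection would again be densest and smaller — so
the family of all of them is vertex-disjoint and can be enumerated by
peeling: find one, delete its vertices, repeat while the residual
maximum density still equals $D$. One minimal densest subgraph is found
by greedy LP descent: starting from an extracted densest subgraph $S$,
look for a densest subgraph of density $D$ inside $S \setminus \{v\}$
and shrink to it; when no single-vertex removal preserves $D$, no
proper subset of $S$ can be densest — any such subset would survive
inside some $S \setminus \{v\}$ — so $S$ is inclusion-minimal. The
descent needs at most $|S|$ shrink rounds of at most $|S|$ LP solves,
so it stays polynomial. An ILP realisation (minimise the selected
cardinality under the densest-subgraph constraints) was prototyped and
rejected: its LP relaxation bounds the cardinality by roughly
$\sum y_i \le 1$, which prunes nothing, and branch and bound degrades
exponentially on dense networks where the greedy descent is fastest.

**Max-DS.** The *maximal* densest subgraph — the union of all densest
subgraphs — is unique. It is computed two ways, which must agree: (i)
the same ILP maximising $\sum z_i$ without the linking row, and (ii)
iterated LP growth: starting from any densest subgraph $R$, re-solve the
LP with $y_i \ge 1/|V|$ for $i \in R$ and
$\sum_{i \notin R} y_i \ge 1/|V|$ (some selected vertex must lie outside
$R$); a feasible optimum reaching $D$ yields a densest subgraph strictly
containing $R$, otherwise $R$ is maximal. The growth terminates within
$|V|$ LP calls. One practical subtlety surfaced in testing: at
degenerate optima the mandatory outside mass can be spread over several
vertices that all sit below the $1/|V|$ threshold, so the growth step
falls back from the threshold set to the support $\{y_i > 0\}$, which at
any optimum is itself a densest subgraph containing $R$ plus an outside
vertex; the fallback is verified by exact recount before use.

**Min-SDS.** Interfaces away from the primary binding core have slightly
lower contact density, and a strict "densest" criterion misses their hot
spots. Min-SDS peels minimal densest subgraphs like Min-DS but keeps
going while the current subgraph's density is at least $\theta \cdot D$,
where $D$ is the maximum density of the *original* network and
$\theta \in (0,1)$ is a tolerance. The boundary is inclusive: density
exactly $\theta D$ is selected (the stop rule is a strict $<$).

## Hot-spot labels and evaluation

Binding free energy from a dissociation constant:
$\Delta G = RT \ln K_d$ with
$RT = (8.314/4184)(273.15 + 25.0) \approx 0.59245$ kcal/mol, i.e.
$T = 298.15$ K fixed even when source records carry other temperatures —
the labelling convention is deliberately uniform. A residue is a hot
spot when $\Delta\Delta G = \Delta G_{mut} - \Delta G_{wt} \ge 2.0$
kcal/mol for an alanine substitution; only alanine records are used.
Replicate measurements aggregate by maximum ΔΔG by default (a residue
shown to cross the threshold in any experiment counts; `aggregate =
"mean"` is the documented alternative). Predictions — the union of a
method's vertex sets — are scored as TP/FP/FN with precision, recall,
$F_1$ and $F_2 = 5PR/(4P+R)$; a residue predicted but never measured
counts as a false positive, matching the pessimistic convention of
alanine-scanning benchmarks. Hot spots recorded in the mutation table
but absent from the network cannot be predicted by any graph method and
are excluded from FN by default (`fn_universe = "network"`); the strict
alternative (`"all"`) counts them.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| contact margin | 2.75 | Å | diameter of a water molecule |
| radii table | Bondi (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80) | Å | standard consensus set; swappable, fallback 1.80 for unknown elements |
| θ (Min-SDS) | 0.85 | — | the F2-score of hot-spot recovery peaks here on alanine-scanning benchmarks |
| ΔΔG threshold | 2.0 | kcal/mol | the experimental hot-spot definition |
| membership ε | 1e-6 | — | tolerance on the y ≥ 1/\|V\| test |

## Numerical choices

Density comparisons that drive control flow — the Min-DS/Min-SDS
stopping rules, recount assertions — are exact integer
cross-multiplications of edge and vertex counts, never floating point;
θ is held at its printed decimal (e.g. 85/100), so "density ≥ θD" is an
exact integer comparison too. LP objectives are only ever compared with
a numeric tolerance. Every extracted vertex set is re-counted on the
graph and asserted against the expected exact density before being
returned, so solver round-off cannot alter a reported subgraph. The LP
engine is a deterministic two-phase dense-tableau simplex with Bland's
anti-cycling rule; the ILPs use depth-first branch and bound with
deterministic branching. The ≥-D rows carry a 1e-9 slack, far below the
1/|V|² density granularity of any network in the package's practical
range (up to a few thousand vertices), so the slack can never admit a
lower-density support. Determinism end to end: identical inputs give
byte-identical reports.

Tie-breaks are lexicographic on vertex identifiers (C-locale). The
minimal-densest descent scans candidate removals
largest-identifier-first, which steers ties between disjoint equal
candidates (two identical triangles, say) to the lexicographically
least vertex set and makes every run reproducible.

Degenerate inputs: edgeless graphs are rejected by all solver
operations (no densest subgraph is defined); isolated vertices are legal
input but can never appear in an extracted subgraph — including them
strictly lowers density.

## Design decisions that were genuinely open

- *Realisation of "a minimal densest subgraph".* Greedy LP descent was
  chosen over a minimum-cardinality ILP: both yield an inclusion-minimal
  densest subgraph (which is all the peeling needs — the enumerated
  family is the same either way), but the descent is polynomial while
  the ILP's relaxation is too weak to prune. The whole family is
  machine-checked against an exhaustive oracle.
- *Min-SDS stop rule reference density.* The threshold compares against
  the maximum density of the original network, not of the shrinking
  residual — the tolerance is meant relative to the strongest interface.
- *Boundary convention.* Density exactly θD is selected; the stop is
  strictly below.
- *Structure parsing conventions* (where crystallographic practice is
  the only guide): first model of multi-model files; highest-occupancy
  alternate location, ties to label 'A'; waters excluded; HETATM
  excluded except MSE (read as MET); hydrogens used when present, never
  added. All recorded in the network sidecar so variants can be
  compared.
- *Temperature* fixed at 298.15 K in ΔG regardless of per-record
  experimental temperatures, keeping labels commensurable.

## What the synthetic generators emulate

`random_graph` / `planted_graph` give seeded Erdős–Rényi backgrounds
with planted near-clique blocks: ground truth for recovery tests of the
extractors. `write_toy_structure` emits genuine PDB files of
single-carbon residues placed so that *exactly* a prescribed inter-chain
contact pattern holds (two lone carbons touch iff within
1.70 + 1.70 + 2.75 = 6.15 Å); cliques become compact point clusters,
other patterns are embedded from their graph distances, and the realised
geometry is verified against the request before writing — an
unsatisfiable pattern is an error, not a silent approximation. These
toys exercise the full pipeline (parse → contacts → network → solvers →
metrics) but deliberately lack side chains, realistic packing densities,
occupancy/altloc noise and intra-chain structure, so passing tests
demonstrate correctness of the mapping and the optimisation, not
predictive performance on real interfaces.

Problem sizes used by the test-suite and the verification script — 200
random graphs of 5–12 vertices against a 2^|V| exhaustive oracle, toy
complexes of a dozen residues — were chosen so that every solver claim
is checked against an independent enumeration; the extractors themselves
have no such size ceiling (LP/ILP growth is polynomial in practice for
interface-scale networks of a few hundred residues).

## Known limitations

- The Max-DS ILP is exact but exponential in the worst case; the
  iterated LP growth is the polynomial alternative and is required to
  agree with it.
- The contact rule treats all atoms equally: no hydrogen-bond detection,
  no solvent accessibility, no biological-assembly selection — a network
  is built from the chains present in the file's first model.
- Hot-spot labels inherit the sparsity of alanine-scanning data; recall
  against the recorded labels understates true recall, which is why F2
  (recall-weighted) is the headline metric and why unmeasured predicted
  residues counting as FP is a pessimistic convention.
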