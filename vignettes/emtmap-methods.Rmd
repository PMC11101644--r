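---
title: "Models and methods behind emtmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emtmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtmap)
```

# The scientific problem

Epithelial-mesenchymal transition (EMT) driven by TGF&beta; signalling is a
central route to metastasis in breast cancer. Curated disease maps encode
what is known about this signalling as species (proteins, genes, RNAs,
complexes, phenotypes) connected by signed reactions. `emtmap` provides the
computational side of working with such maps: a common data model with
census and validation, automatic translation into a Boolean logical model,
stochastic simulation with activity-level readouts and phenotype calling,
and topological analysis including maximal clique centrality (MCC) hub
ranking. A seeded generator of random signed maps with plantable feedback
motifs, plus a curated EMT-core fixture, make every analysis testable
without external data.

# The map data model

A `regulatory_map` holds a species table (`id`, display `name`, `kind` in
{protein, gene, rna, complex, phenotype, degradation, unknown},
`compartment`, free-text notes) and an interaction table (ordered sources,
one target, a category such as state transition / complex association /
transport, and a sign in {activation, inhibition, neutral}). Species
identity is the file id, never the display name: the same molecule curated
in two compartments remains two nodes, matching how process-description
maps separate cytoplasmic and nuclear forms. Degradation sinks are retained
as species but excluded by default from logic inference and topology; they
are bookkeeping, not regulators.

Two readers cover the common distribution formats. `read_edge_table()`
parses SIF-like delimited tables with a configurable column dialect and a
single documented sign-token table; unknown sign tokens are an error, never
silently coerced, because a silently flipped sign corrupts every downstream
rule. `read_celldesigner_sbml()` parses SBML with CellDesigner extension
annotations, taking species kinds from the species class and interaction
categories/signs from reaction and modification types; plain SBML degrades
gracefully to `kind = "unknown"`. Each SBML modifier arc becomes its own
signed interaction (the interaction type carries one sign), so interaction
and reaction counts coincide exactly for modifier-free models.

# Boolean translation

`infer_rules()` follows the CaSQ convention. For a target with activating
reactions $r_1,\dots,r_k$ (sources within a reaction combined by AND) and
inhibitors $i_1,\dots,i_m$:

$$f(t) = (r_1 \lor \cdots \lor r_k) \land \lnot (i_1 \lor \cdots \lor i_m)$$

A species with only inhibitors is constitutively ON unless inhibited; a
species with no regulators becomes an input with the identity rule.
Transport reactions translate as activation of the destination form by the
source form, preserving signal flow across compartments. Logical-activation
arcs join the activator OR-block like ordinary activations. This template
makes every rule monotone in the sign of each regulator, a property the
test suite checks by exhaustive truth tables.

Models round-trip through SBML-qual Level 3 Version 1 with binary levels
(`write_sbml_qual()`, `read_sbml_qual()`); multilevel files are rejected
explicitly rather than truncated.

# Simulation semantics

The engine implements general asynchronous updating: each step resamples
any clamped inputs Bernoulli($p$) and then updates one node chosen
uniformly at random. A clamp is the probability that an externally
controlled input is ON, so clamping the stimulus at 1.0 or 0.0 recovers
the two canonical scenarios. Synchronous updating is available for
fixed-point checks and the classical orbit analyses. All randomness flows
from one integer seed; identical configurations give identical
trajectories, and ensembles use consecutive seeds so an `activity_profile`
is reproducible from its base seed alone.

Activity levels are fractions of time ON within consecutive non-overlapping
windows (default 50 single-node updates), averaged across an ensemble
(default 100 runs). These defaults were chosen once as study conditions:
with a ~20-node model, 50 updates correspond to roughly 2.5 sweeps of the
network, and 100 runs bound the binomial standard error of a window mean by
0.05. The "epithelial" preset starts the configured epithelial markers ON,
mesenchymal markers OFF, all other non-input nodes OFF, and inputs at
their clamp.

`attractors_exhaustive()` enumerates the full state space (at most 20
nodes). Synchronous attractors are the cycles of the deterministic update
map; asynchronous attractors are the terminal strongly connected components
of the single-node-update state-transition graph, with fixed points
verified by $f(s) = s$. The test suite cross-checks this engine against an
independent reachability-closure oracle on all models up to 8 nodes and
confirms on 200 random models up to 12 nodes that long simulations end
inside a reported attractor.

`detect_oscillation()` flags a node whose window means, after discarding a
burn-in (default: first 20% of windows), stay strictly inside
$(\varepsilon, 1-\varepsilon)$ with $\varepsilon = 0.05$ and are
non-monotone. The thresholds make "oscillatory behaviour" operational:
sustained limit-cycle dynamics keep ensemble window means near 0.5, while
bistable switches settle onto 0 or 1 and are not flagged.

# Phenotype calling

A `marker_config` names disjoint epithelial and mesenchymal marker sets and
a majority threshold $t \in (0.5, 1]$ (default 0.75). A state is epithelial
when the epithelial ON-fraction is at least $t$ and the mesenchymal
fraction at most $1 - t$; mesenchymal under the mirror condition; otherwise
*hybrid* whenever at least one marker is ON on each side, and undetermined
when one side is entirely OFF without a majority call. The hybrid clause is
deliberately based on marker coexistence rather than a fractional floor: a
fractional floor of $1 - t$ would, with five markers per side, refuse the
canonical hybrid configuration in which E-cadherin persists alongside
active SNAIL and ZEB. Profiles are binarised at 0.5 before classification;
the cut is configurable.

The default marker sets for the EMT core are epithelial {E-cadherin, ZO-1,
miR-200, GRHL2, OVOL2} and mesenchymal {SNAIL, ZEB, TWIST, Goosecoid,
N-cadherin}, with EMT as a dedicated phenotype node. The package supports
both readouts — the emergent marker-based label and the phenotype node's
own activity — because both are used in practice.

# The EMT-core fixture

`emt_core_fixture()` is a deterministic 21-node, 38-interaction abstraction
of TGF&beta;-induced EMT signalling, shipped both in code and as a
plain-text edge table plus JSON manifest under `extdata`. Receptor
activation is collapsed to TGFB &rarr; receptor complex &rarr; SMAD
complex; SNAIL/SLUG and ZEB1/ZEB2 are merged into family nodes, as the
merged R-SMAD is used because which R-SMAD carries the signal is not
settled. The architecture wires the known feedback skeleton: mutual
inhibition of SNAIL-miR-34 and ZEB-miR-200, mutual inhibition of ZEB with
the phenotype-stability factors GRHL2 and OVOL2, the AKT-TWIST
double-positive loop, the GSK-3&beta; brake on SNAIL relieved by AKT, the
NF-kB-NKILA negative feedback oscillator, and an EMT phenotype node driven
by SNAIL/ZEB/TWIST and opposed by E-cadherin.

Under the AND-NOT translation convention a mutually inhibitory pair whose
epithelial side has no other regulator can never flip: the miRNA stays ON
and vetoes its partner forever. The curated literature resolves this with
upstream control, and the fixture follows it: p53 sustains miR-200 and
miR-34, MDM2 degrades p53, and SNAIL/ZEB additionally repress the
epithelial miRNAs and stability factors. One edge, SMAD &rarr; MDM2, is an
abstraction of TGF&beta;-dependent relief of the p53 brake; it is flagged
as such in the fixture manifest. With this wiring the model has exactly one
input (TGFB), a unique epithelial fixed point when the stimulus is clamped
OFF, and a stereotyped epithelial &rarr; hybrid &rarr; mesenchymal
transition with transient marker coexistence when the stimulus is clamped
ON — while NF-kB and NKILA keep oscillating.

# Topology and hub detection

`topology_report()` computes the standard battery on a directed or
undirected view. Conventions matter and are fixed as follows: shortest-path
statistics are computed over connected pairs only, so maps with many
components keep finite diameters; self-loops are excluded from clustering
and neighbour counts and reported separately; the clustering coefficient is
the mean Watts-Strogatz local coefficient with degree &lt; 2 nodes
contributing zero; density is $e/(n(n-1))$ directed and $2e/(n(n-1))$
undirected on the simple projection of that mode. Directed eccentricities
are computed over out-reachable pairs; published directed radii of 1 from
desktop tools are artefacts of unreachable-pair handling and are not a
target.

`fit_power_law()` fits a least-squares line on the log-log binned degree
histogram. By default degrees are aggregated into powers-of-two bins and
converted to count densities before fitting: raw per-degree fits are
systematically flattened by single-occupancy tail bins (a
preferential-attachment graph fits near 1.5 raw but near its true exponent
~2.3 with logarithmic binning). The raw fit remains available as an option.

MCC scores follow the CytoHubba definition: $\mathrm{MCC}(v) = \sum_{C \ni
v} (|C|-1)!$ over maximal cliques $C$ of the simple undirected projection,
which reduces to the edge count for nodes whose only maximal cliques are
edges; isolated nodes score zero. Maximal cliques are enumerated exactly
(Bron-Kerbosch with pivoting via igraph), and the tests re-derive all
scores by brute-force subset enumeration on 200 random graphs. Ranking ties
break lexicographically for determinism.

# The synthetic generator

`generate_random_map()` draws exactly `n_edges` distinct directed signed
edges (no self-loops) among non-motif nodes, with a binomially drawn number
of inhibitory edges at the requested fraction, then injects the requested
two-node motifs verbatim (mutual inhibition, negative feedback,
double-positive feedback). Motif nodes are excluded from the random wiring
so that their dynamics are attributable to the planted motif — this is what
makes the planted-motif recovery check meaningful: across seeded batches,
the oscillation detector flags nodes in planted negative-feedback loops
(sustained cycles) and does not flag nodes in mutual-inhibition motifs
(bistable switches). The generator emulates sparse signed regulatory
wiring, not the degree sequence, compartment structure, or annotation
richness of a curated map; passing tests on synthetic maps therefore
validate the machinery, not biological conclusions about any particular
pathway.

# Problem sizes and numerical choices

The shipped test and acceptance workloads use: 100-run ensembles of 5000
asynchronous updates for the fixture scenarios; 200 seeded random models of
4-12 nodes for the oracle suites (exhaustive state spaces up to 4096
states); and 100 maps per condition for motif recovery. These sizes keep
every invariant exhaustively checkable while the full suite runs in
minutes. Exact integer arithmetic is used for MCC ((|C|-1)! stays exact in
double precision for the clique sizes reachable here); all set orderings use
locale-independent C collation; and every stochastic function takes an
explicit seed, with ensemble members at consecutive seeds.

# Known limitations

* Boolean abstraction: no kinetics, no dose-response; activity levels are
  ensemble ON-fractions, not concentrations.
* The full curated breast-cancer map is distributed separately; its census
  and topology values can be verified by placing its SBML/CSV files under
  `extdata/supplementary`, but the package does not bundle them.
* Multilevel logical models and probabilistic update schemes are out of
  scope; SBML-qual support is binary by design.
* The CellDesigner reader covers the annotation subset needed for kind,
  category and sign; layout, complex nesting and full modification
  vocabularies are ignored.
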