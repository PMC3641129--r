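---
title: "Methods: complex prediction on ontology augmented networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complex prediction on ontology augmented networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coan)
```

# The model

`coan` treats complex prediction as clustering on an *attributed* graph.
The inputs are an undirected simple PPI network over opaque protein
identifiers and a protein → GO-slim map (GO slims rather than full GO terms:
broad categories are what co-complex proteins plausibly share, and they keep
the number of dummy vertices small). The method makes three assumptions
worth stating plainly:

* complexes are denser than their surroundings in the PPI graph — dense
  enough to contain at least one clique of 3 or more members;
* co-complex proteins tend to share annotations, so annotation similarity is
  corroborating evidence, not an independent oracle;
* interaction data are binary. Confidence scores, if present in the input,
  are ignored.

## The augmented graph and its random walk

Each GO slim becomes a dummy vertex adjacent to every protein it annotates;
dummy vertices are never adjacent to each other. The single-step transition
probability from a protein is uniform over *all* its incident edges, PPI and
annotation alike — `1/(|N(v)|+|A(v)|)` — and from a slim uniform over its
proteins, `1/|N(a)|`. PPI and annotation edges thus carry equal weight; no
per-edge-class weighting is exposed. Differential weighting of annotations
is a plausible refinement but would add a tuning dimension the rest of the
procedure gives no way to calibrate.

Isolated vertices get all-zero rows rather than self-loops: they can never
join a clique of three, so their walk behaviour is irrelevant, and zero rows
keep every row sum at 1 or 0.

The unified closeness is the delay-damped walk sum

$$R \;=\; \sum_{l \ge 1} c\,(1-c)^l P^l \;=\; c\,(1-c)\,P\,(I-(1-c)P)^{-1},$$

restricted to the protein block after the matrix algebra, so walks *through*
dummy vertices still contribute — that is precisely how a shared slim raises
a pair's closeness. Row sums of $P$ are at most 1, so the spectral radius of
$(1-c)P$ is at most $1-c<1$: the series always converges, and every entry
lies in $[0, 1-c]$.

**The delay parameter `c`** (default 0.1) geometrically down-weights longer
walks. Small `c` lets closeness diffuse over longer ranges; large `c` makes
it nearly local. 0.1 is the conventional restart-strength regime in
random-walk proximity measures on biological networks and is deliberately
mild: the clique seeds already enforce locality, so `R` mainly has to
discriminate *among* nearby proteins.

## Seeding and expansion

Maximal cliques (≥ `min_clique`, default 3) are enumerated on the original
PPI network only — dummy vertices never enter cliques — via
`igraph::max_cliques`, with members and clique lists sorted so the output
order is reproducible. Each clique's **density** is the *mean* pairwise
symmetrized closeness $r(u,v) = (R_{uv}+R_{vu})/2$: a mean, not a sum, so
cliques of different sizes compete on one scale (a sum would simply reward
size). `R` is asymmetric because rows of `P` are normalized by unequal
degrees; density and connectivity treat closeness as a property of the
unordered pair, hence the symmetrization.

Seed selection repeatedly takes the densest candidate, then subtracts its
members from every overlapping candidate; a remainder keeps competing only
if it still has `min_clique` members, with its density recomputed and the
ranking refreshed each round. Ties in density break toward the larger
clique, then the lexicographically smaller member tuple — an arbitrary but
fixed rule that makes runs bit-reproducible. The result is a pairwise
disjoint seed set.

Expansion is a **single pass against the fixed seed**: the candidates are
the seed's PPI neighbours, and a candidate joins when its connectivity
score — mean closeness to the seed divided by the seed's density — reaches
`extend_thres`. Normalizing by seed density makes the score roughly
unit-scaled (a protein "as close to the seed as its members are to each
other" scores 1), which is what makes a fixed default of 0.6 meaningful
across graphs. Because accepted proteins do not recruit further candidates,
raising the threshold can only shrink each predicted complex — the
monotonicity the threshold sweep (`sweep_extend_thres`) displays. Seeds are
disjoint but expanded complexes may overlap; exact duplicates are collapsed.

## Evaluation

Predictions are matched to references by neighborhood affinity
$NA(P,B)=|P\cap B|^2/(|P||B|)$ with an inclusive threshold
($NA \ge \omega$, default $\omega = 0.2$, the field's customary setting).
Precision is the matched fraction of predictions, recall the matched
fraction of references. Sensitivity/PPV/accuracy use the reference ×
prediction overlap contingency table; predictions with zero total overlap
are excluded from the PPV denominator — they would otherwise deflate PPV by
an amount that depends only on how many empty columns the table happens to
carry. This exclusion is a documented choice, pinned by tests.

# The synthetic benchmark

`benchmark_spec()` plants `n_complexes = 10` disjoint complexes of 4–10
members: intra-complex pairs wired with `p_in = 0.9` then thinned by a
false-negative rate `p_fn = 0.1` (matching the lossy character of
high-throughput interaction detection), all other pairs wired with
`p_out = 0.02`, on top of `n_background = 60` extra proteins. Each complex
owns `terms_per_complex = 2` dedicated slims, carried by each member with
`p_share = 0.9`; every protein picks up each noise slim with
`p_noise_ann = 0.05`. The vocabulary (`n_terms = 30`) is the 20 dedicated
slims plus 10 noise slims — enough noise vocabulary that spurious
annotations exist without drowning the signal, comparable to a GO-slim set's
breadth relative to a small interactome. A single RNG stream seeded from
`seed` (default 42) is consumed in a fixed order (sizes, intra-complex
wiring, thinning, background wiring, shared annotations, noise annotations),
so instances are reproducible.

What the generator does **not** emulate: scale-free background degree
distributions, overlapping complexes (curated yeast catalogues are mostly
disjoint at this granularity, but real complexes do share members), shared
annotations *between* complexes, and dataset-specific identifier noise.
Recovery scores on this benchmark therefore demonstrate that the machinery
works as designed — not that it attains any particular accuracy on real
interactomes, where annotation coverage is far spottier and edge noise is
structured.

One subtlety the benchmark exposes: annotation edges *dilute* each
protein's per-edge transition probability (the out-degree grows), so adding
annotations lowers absolute closeness values across the board. The gain is
in contrast — within-complex closeness relative to background rises, which
is what the density ranking and connectivity score consume. The test suite
asserts the contrast version; a controlled, degree-padded pair test asserts
the pairwise version (a shared slim strictly raises $r(u,v)$ when
out-degrees are held fixed).

# Numerical choices

* The closed form is evaluated by solving the linear system
  $(I-(1-c)P)^{\mathsf T} X = (c(1-c)P)^{\mathsf T}$, never by explicit
  inversion.
* Dense storage by default, sparse (`Matrix`) above 2000 vertices or on
  request; the two agree to 1e-10 and are tested against each other.
* The truncated-series cross-check sizes its length from the geometric tail
  bound $\sum_{l>L} c(1-c)^l = (1-c)^{L+1}$, keeping the truncation error
  below 1e-12 so a 1e-10 comparison genuinely tests the closed form.
* Degenerate inputs degrade quietly: an empty network predicts an empty
  complex set; a zero-density seed gives every candidate a connectivity
  score of 0; empty prediction or reference sets evaluate to zeros with a
  warning.

Problem sizes in the test suite — ~130-protein benchmark instances,
20–50-vertex random graphs for the matrix oracles, exhaustive clique
enumeration up to 12 vertices — are chosen so each oracle (series
summation, subset enumeration, a straight-line pipeline re-implementation)
stays brute-force honest while the full suite runs in well under a minute.

# Known limitations

* Cubic-time dense linear algebra: fine to a few thousand proteins; genome-
  scale networks want the sparse path and patience, or an iterative solver
  this package deliberately does not include.
* Proteins outside every maximal clique of size ≥ 3 can only be *recruited*
  into complexes, never seed them; complexes with no clique core are
  invisible.
* Identifier matching between the PPI network and the annotation source is
  the user's responsibility; annotations for unknown proteins are dropped
  with a message.
* Equal PPI/annotation edge weighting is a fixed modelling choice, not a
  tuned one.
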