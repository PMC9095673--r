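---
title: "Degron masking and degronon detection: models, parameters and design choices"
author: "degronon package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degron masking and degronon detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronon)
```

# The biological model

Most substrates of the ubiquitin--proteasome system (UPS) carry a
*tripartite degron*: a **primary degron**, the short linear motif through
which an E3 ubiquitin ligase recognizes the substrate; one or more
**secondary degrons**, the lysines that actually receive ubiquitin
(Ubsites); and a **tertiary degron**, an intrinsically disordered region
(IDR) near the Ubsite through which the 26S proteasome engages and starts
unfolding the chain. All three elements sit preferentially inside IDRs,
which are dense in overlapping interaction motifs. When a partner protein
binds a site that overlaps -- or lies within a few residues of -- a degron
element, the element is *masked*: the E3 cannot dock, the E2 cannot reach
the lysine, or the proteasome cannot thread the IDR. Masking partners
("alternate partners", APs) therefore stabilize the substrate, and because
motif-mediated interactions have comparable, weak affinities, the outcome
of the competition between an E3 and the APs is driven largely by their
relative cellular abundances.

Scaled up to the whole interactome, the same logic predicts that stable
complexes and pathways should co-degrade: physically interacting,
functionally coherent proteins should show correlated half-lives. We call
a group of proteins with this signature -- a chain of physical interactions
in which every member is functionally similar to the first and shares its
half-life -- a **degronon**.

The package implements four analysis layers on these ideas, plus a
synthetic-data layer that generates every input with known ground truth.

# Degron masking (interval layer)

Coordinates are 1-based and inclusive throughout, the UniProt convention
for sequence features. `classifyRegionRelation()` compares a degron
`[d1, d2]` with a binding site `[s1, s2]`:

* **overlap** -- at least one shared residue
  (`overlap_length = |[d1,d2] ∩ [s1,s2]|`);
* **adjacent** -- disjoint, with `gap` residues strictly between the two
  intervals and `gap <= window` (default 10 residues);
* **none** -- otherwise.

Two conventions needed fixing. First, *contiguous* disjoint intervals have
`gap = 0`; a site ending immediately before a degron is certainly "within
10 amino acids", so `gap = 0` is classified adjacent. Second, whether
adjacent sites count as *masking* in the census is genuinely ambiguous in
the field's usage; `maskingCensus(countAdjacent = )` defaults to counting
them, and the per-pair relation table always preserves the distinction so
both tallies can be reported.

The census applies the standard filter stack: interactions with confidence
score below 0.3 are discarded (per interaction -- every feature of a
dropped pair goes with it); partners annotated to a UPS-related GO term
*or any descendant of one* are removed, so that E3s, proteasome subunits
and other degradation machinery are not mistaken for stabilizing partners.
The UPS blacklist ships as a required config input; the synthetic ontology
provides its own branch, and for real GO a curated list must be supplied
(the conventional choice is the ubiquitin-dependent catabolism and
proteasome branches). A partner with an interaction but no mapped binding
feature counts toward the partner total but can never be masking.
Mutation-evidence features (the "mutation decreasing/disrupting
interaction" annotation headings) are treated as binding-site evidence
with equal weight: a mutation in or near a degron that changes the
interaction localizes the physical interface just as a deletion construct
does. The feature kind is preserved in outputs.

**Tertiary degron inference.** Given a per-residue disorder profile,
`inferTertiaryDegron()` returns the maximal run of at least 20 consecutive
residues with score $\ge 0.5$ that minimizes sequence distance to the
Ubsite (distance 0 if the run contains it). 0.5 is the conventional
disorder threshold for per-residue predictors scaled to $[0,1]$; both the
threshold and the 20-residue minimum (the length needed for productive
proteasomal engagement) are exposed as parameters. Equidistant runs are
broken toward the upstream run -- an arbitrary but deterministic
convention, stated here because nothing in the biology prefers either
side.

# Abundance competition (rank-bin layer)

PaxDb-style datasets give each protein an abundance in parts per million
of the expressed proteome, so a dataset sums to $\sim 10^6$ (the validator
warns outside $[0.9, 1.1] \times 10^6$, as real files drift slightly).
Because datasets differ widely in coverage, cross-dataset comparisons use
**rank bins**: proteins are sorted from highest to lowest ppm and mapped
onto 100 equally populated bins, bin 1 being the top 1% most abundant.

`rankBins()` uses the grid form

$$\mathrm{bin}(p) = 1 + \left\lfloor \frac{100\,(r_p - 1)}{N} \right\rfloor,$$

with $r_p$ the descending-ppm rank. This form keeps every occupancy
difference at most one *and* places the top-ranked protein in bin 1 for
every dataset size $N$, including $N < 100$ (a ceiling-of-quantile form
only does so for $N \ge 100$). Ties in ppm are ordered by protein
identifier so the assignment is deterministic; tie handling can shift bin
boundaries, which is why it is pinned down rather than left to the sort's
whim.

Role-wise comparisons pool each (protein, dataset) occurrence as one
observation, once per module role occurrence by default
(`poolPerModule = FALSE` collapses a protein that serves the same role in
several modules -- a kinase like GSK3B recurs across many substrate
modules, and both pooling conventions are defensible, so both are
available). Group comparisons use the two-sided Mann--Whitney U-test
(`twoGroupTest()`, exact for both groups $\le 8$ without ties, otherwise
the tie-corrected normal approximation); correlations are Spearman's rank
correlation with average ranks and the large-sample P approximation,
reported with $n$ and undefined below $n = 3$. The summed-AP mode only
uses datasets in which *every* AP of the substrate was measured, since a
partial sum would understate the masking reservoir.

# Wang semantic similarity

Functional similarity uses the Wang graph-based measure over Biological
Process, implemented from its recursion rather than delegated: the
semantic contribution of term $t$ to itself is $S_t(t) = 1$ and decays
multiplicatively along each edge toward the root,

$$S_t(a) = \max_{c \in \mathrm{children}(a) \cap \mathrm{anc}(t)}
w_{c \to a}\, S_t(c),$$

with edge weights $w_{is\_a} = 0.8$ and $w_{part\_of} = 0.6$ (the
measure's conventional defaults; both exposed in `semSimParams()` and
recorded in output metadata, since the analysis convention fixes neither).
Term similarity aggregates over common ancestors,

$$\mathrm{sim}(t_1, t_2) = \frac{\sum_{a \in A_1 \cap A_2}
\left(S_{t_1}(a) + S_{t_2}(a)\right)}{SV(t_1) + SV(t_2)},$$

and gene similarity combines the term-pair matrix by best-match averaging,
here the arithmetic mean of (mean of row maxima, mean of column maxima).
Note that some implementations instead use
$(\sum \text{row max} + \sum \text{col max})/(m + n)$; the two agree for
equal-size term sets and differ slightly otherwise -- the symmetric
mean-of-means is fixed as this package's default for reproducibility.
Annotations are filtered to IDA/IPI evidence (direct assay, physical
interaction) in the BP namespace before any similarity is computed;
obsolete terms are dropped with a warning. Only `is_a` and `part_of`
edges enter the ancestor closure -- the measure defines weights for these
two relations only, so `regulates`-style edges are ignored.

The implementation computes S-values by dynamic programming in
topological order of the ancestor closure. Its test oracle is a memo-free
depth-first enumeration of all paths taking the maximum path product --
the same quantity by a different algorithm -- compared to $10^{-9}$ on
random DAGs.

# Network co-degradation and degronons

For a half-life table (a single dataset; ratios are never computed across
tables), every network edge with both half-lives yields the ratio
$\min/\max \in (0, 1]$ and a category: **very different** $[0, 0.5)$,
**different** $[0.5, 0.8)$, **similar** $[0.8, 1.0]$. A ratio landing
exactly on 0.5 or 0.8 goes to the upper category -- the interval labels
are conventionally printed with overlapping endpoints, so a tie rule is
required and this one is fixed and tested.

**Null model.** `randomizeNetwork()` follows the standard three-step
recipe: a degree-preserving edge shuffle that forbids self-loops and
multi-edges (igraph's `sample_degseq`), a node-label permutation sampled
without replacement, and finally removal of any edge that also occurs in
the original network. The diagnostics report the (typically well under
1%) edges lost in step 3, confirm zero residual overlap, and verify the
degree multiset empirically. Envelopes use 10 random networks
(mean $\pm$ 1 sd per histogram bin).

**Paths.** All-pairs shortest-path machinery serves two purposes: the
distance profile (ratios of unordered pairs bucketed by distance 1, 2,
..., $\ge 6$; the distance-1 bucket must and does equal the edge-pair
analysis) and degronon detection. Because standard all-pairs
shortest-path routines return an arbitrary representative path, detection
uses its own breadth-first search expanding neighbors in lexicographic
order, which makes the chosen path per ordered pair unique and
deterministic; the tie-break is recorded in output metadata. A degronon
is a path in which every member has BP similarity $\ge 0.6$ to the first
protein, of length $\ge 6$ hops; paths whose members lack similarity data
are excluded from the high-similarity subset rather than counted as
failing. Ordered paths are enumerated from both ends (a path from A and
its reverse from B are distinct candidates); identical ordered member
lists are deduplicated and the count after also merging reversals is
reported separately, since either convention is defensible.

# The synthetic-data layer

The generators emulate the structure the analyses assume, with ground
truth recorded for recovery testing. Their defaults are the package's
study conditions, chosen once:

* **Substrates** (20 by default): length 200--800, one primary degron of
  6--14 residues, a Ubsite lysine, and a disorder profile built from
  piecewise-constant blocks (ordered $\approx 0.25$, disordered
  $\approx 0.75$) with bounded uniform noise, so threshold-0.5 runs
  coincide exactly with the planted blocks; a qualifying $\ge 20$-residue
  disordered block is planted at or near the Ubsite and the nearest
  qualifying run is recorded as the true tertiary degron.
* **Interactions** (20 partners per substrate): a Bernoulli(0.5) subset
  carries a feature overlapping a degron; the rest carry a feature with no
  relation to any degron, or none. Confidence scores are a two-component
  mixture (15% in $[0.05, 0.29]$, the rest in $[0.35, 0.95]$) so the
  below-0.3 subset is known exactly; 10% of partners carry UPS-branch GO
  terms. Each substrate also gets one E3 bound to its primary degron and
  annotated into the UPS branch -- the filters must remove it.
* **Ontology and annotations**: one BP root; per-module branches whose
  leaves are the module's shared specific terms (3 by default); a UPS
  branch with two levels of descendants supplying the blacklist; and
  twelve shallow background branches (60 leaves) from which background
  genes draw 3--4 scattered terms. The scattering matters: concentrating
  background annotations under a single branch gives random gene pairs a
  best-match-average similarity of about 0.59--0.63 -- right at the 0.6
  cutoff -- whereas a multi-branch background keeps them clearly below it,
  which is the regime a real process ontology is in. IEA records and a
  small molecular-function root are included as filter fodder.
* **Abundances** (50 datasets): per dataset, $\log_{10}$ ppm is drawn
  around role medians (substrate 1.5, E3 1.0, AP
  $1.0 + \log_{10}(\text{fold})$ with fold 10 -- the E3-vs-AP effect size
  the analysis is designed to detect), plus a dataset-level latent factor
  (sd 0.2) shared by substrates and E3s that induces their cross-dataset
  correlation, plus per-protein noise (sd 0.4); 10% of proteins are
  dropped per dataset and the remainder renormalized to exactly $10^6$
  ppm. Null-calibration runs set both the role contrasts *and* the latent
  factor to zero: a latent factor that loads on one comparison group but
  not the other changes variances even with equal medians, and is itself
  a planted effect.
* **Co-degradation network**: five modules of eight proteins. Each module
  is a backbone chain plus one chord between chain positions 1 and 3, and
  one bridge edge into the background. The chord placement is the one
  non-obvious choice: a chord $(i, i{+}2)$ in the chain interior removes
  node $i{+}1$ from every maximal geodesic, so its membership could never
  be recovered by shortest-path detection; at the chain head, the module
  keeps diameter 6 and every backbone member still lies on some
  $\ge 6$-hop geodesic. Module half-lives share a module mean with 5%
  coefficient of variation (pairwise ratios then exceed 0.8 with
  probability $\approx 0.998$); background half-lives are independent
  log-normal with log-sd 0.6 (median pairwise ratio $\approx 0.56$).
  Within-module co-expression centers on 0.7, background on 0.
* **Background density.** The 500 background proteins get a sparse random
  graph with mean degree 1. This is a deliberate power choice, not a
  claim about real interactome density: the planted similar-category
  excess is $\approx 40 \cdot 0.75 / E$ for $E$ total edges, while the
  10-network envelope's standard deviation is
  $\approx \sqrt{0.17 / E}$, so at mean degree 1
  ($E \approx 295$) the excess sits near four envelope sd, at mean
  degree 2 it drops toward two -- the boundary of reliable detection.
  Since the module edge budget is capped by the diameter constraint, the
  background density is the only free knob, and it is fixed here once.

Every generator draws from its own RNG stream derived from the master
seed (a fixed offset per operation), so adding or rerunning one generator
never perturbs another's output, and identical configs produce
byte-identical files.

**What passing these tests does and does not show.** The generators
reproduce the *structural* properties the analyses rely on -- interval
geometry, mixture confidence scores, a typed acyclic ontology,
sum-normalized abundances with role effects, planted modules with
correlated half-lives. They do not mimic real interaction-score
calibration, real GO term semantics or depth distribution, the degree
distribution of real interactomes, or biological missingness patterns.
Recovery of planted structure therefore validates the machinery and its
thresholds, not the biological claims themselves; on real data the same
code paths consume the corresponding database exports.

# Numerical and degenerate-input conventions

* Ratios and bins are computed on exact arithmetic; no tolerance is
  involved anywhere except float comparisons in tests ($10^{-9}$ for the
  similarity oracle).
* Empty inputs: an empty abundance dataset is an input error for
  `rankBins()`; an empty role group is reported absent and not tested; a
  correlation with fewer than 3 points is reported absent (`NA`), not 0.
* Unparseable MITAB confidences or feature ranges (`?`/`n` positions) are
  dropped with warnings at the reader, never silently.
* The degree-sequence shuffle retries up to 20 times before raising an
  error that records the seed.
* Pipeline reports carry no timestamps, so identical configs give
  byte-identical outputs; provenance is the full config plus a hash.

# Problem sizes used by the test and acceptance suites

Unit tests run on reduced conditions (5 substrates, 2 modules, 60
background nodes, 8 datasets) chosen so that each property is decided by
construction rather than by statistical power; the acceptance suite runs
the default conditions above (540-node network, 50 datasets, 1000-node
network for the randomization contract, exhaustive interval pairs to
coordinate 60, dataset sizes 1 to 1000 for the rank-bin law, 100 random
DAGs for the similarity oracle). These sizes are the package's validation
conditions; scaling any of them up changes runtimes, not conclusions.

# Known limitations

* Tertiary degrons are inferred, never experimentally grounded; the
  inference is exactly the stated rule and inherits the disorder
  predictor's calibration.
* Degronon detection inspects one deterministic shortest path per ordered
  pair; co-degrading modules that are not geodesically thin (dense
  complexes) are found only through the paths that happen to traverse
  them.
* The UPS blacklist shipped for synthetic runs is a reconstruction of a
  plausible ubiquitin/proteasome branch; analyses of real data should
  supply a curated term list.
* Half-life ratios are dataset-relative; nothing in the package attempts
  cross-dataset half-life normalization.
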