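---
title: "Ancestral genome reconstruction from neighboring gene pairs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral genome reconstruction from neighboring gene pairs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the character model, the inference machinery, the
reconstruction algorithms, the parameters that matter, and the design
choices that were genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The data model

A genome is a set of replicons; a replicon is an ordered, stranded
string over the orthologous-family alphabet Σ. Singleton genes (no
homolog in any other input genome) are written `*`; they occupy
positions — and therefore interrupt gene runs — but are never
characters. The input contract requires that no non-singleton family
occur twice within one genome: paralog resolution is an upstream
problem, and the reconstruction depends on the one-gene-per-genome
property both for the character model (binary presence) and for the
run assembly (a family's two gene ends are unique). Replicon strings
are linear by default; a `circular` flag adds the wrap-around adjacency
during NGP extraction. We default to linear because the string
formalism of the method is linear, and the behaviour of the original
system on this point is not documented; both modes are supported and
tested.

Internal tree nodes are named by joining their descendant leaf labels
with underscores in left-to-right order (`14_8_20` is the ancestor of
leaves `14`, `8`, `20`), which makes every report row traceable to a
clade without an extra lookup table. Leaf labels therefore must not
contain underscores.

## Characters: genes and neighboring gene pairs

Every gene is represented by its two ends — head (5′) and tail (3′) —
so that a physical adjacency between two genes is a pair of facing
ends. On the forward strand a gene contributes (head, tail) in reading
order, on the reverse strand (tail, head). The canonical key of an
adjacency sorts its two ends lexicographically, which makes the feature
invariant under the reading direction of the replicon — the same
biological adjacency yields the same key no matter how the replicon is
written. Adjacencies never span replicon boundaries.

Two extraction modes exist for runs of singletons between two
family-bearing genes: opaque (default — only immediate physical
adjacency counts) and transparent (`skip_singletons = TRUE`, singletons
are skipped). The original description defines the pair as physical
adjacency, which is our default; transparency reproduces the behaviour
of the antecedent gene-order method that ignored non-shared genes, and
is recorded in the run configuration either way.

## Ancestral state inference

**Maximum parsimony.** Binary Fitch parsimony, vectorized across
characters: a down-pass takes the intersection of the children's state
sets where non-empty (else the union), an up-pass resolves ambiguous
sets by preferring the parent's resolved state. Ambiguity at the root
resolves to *absence*. This tie policy is deliberately conservative —
it mirrors the stringent presence cutoffs used on the likelihood side —
and the change counts it implies equal the exhaustive minimum over all
internal labelings (verified by enumeration up to six leaves in the
test suite).

**Maximum likelihood.** The two-state continuous-time Markov model with
gain rate `q01` and loss rate `q10` per unit branch length; transition
probabilities use the standard closed form, the root prior is the
stationary distribution of the fitted model. Per-character marginal
posteriors of presence combine subtree partial likelihoods with the
above-tree contribution, with per-character log-scaling against
underflow. Rates are fitted by bounded (1e-6 to 1e3) multi-start
L-BFGS-B on the log-rate scale, maximizing the summed log-likelihood of
a *character class* — one shared model for gene characters, one for NGP
characters. Per-character fitting is statistically ill-posed for rare
characters (most NGP characters are observed in a handful of genomes),
so a class-level model is the default protocol; nothing in the
interface prevents fitting any subset separately. A uniform root prior
is available but not default: the stationary prior is the conventional
default of comparative-methods software for this model, and it keeps
the posterior of a character absent everywhere well-behaved.

Zero or missing branch lengths are replaced by 1e-6 — the likelihood
is undefined at exactly zero, and the substitute is far below any
realistic branch length, so it acts as "no time elapsed" without
numerical trouble.

**Presence calls.** A character is called present where its posterior
is at or above the cutoff (boundary inclusive). Both cutoffs default to
0.9: pair precision/recall sweeps on simulated data (the acceptance
suite re-runs one) show precision monotonically rising and recall
falling with the pair cutoff, and 0.9 sits at the knee. A called NGP
whose member families are not both called is dropped (consistency
filter); the dropped keys are reported.

## Gene-run assembly

The called families and NGPs of a node form a weighted undirected
graph on gene ends: one intra-gene edge per family (weight 1), one
inter-gene edge per called NGP (weight = 1/posterior under ML, 1 under
MP). Kruskal's algorithm reduces each connected component to a minimum
spanning tree; ties are broken by the canonical edge key, so the forest
is deterministic. A *legitimate path* alternates intra- and inter-gene
edges strictly and terminates on intra-gene edges, so every gene on it
is wholly included and carries an orientation (traversing head→tail
reports `+`).

Selecting "the legitimate path with the lowest score" literally is
degenerate: all edge weights are ≥ 1, so the minimum-weight legitimate
path is always a single adjacency of two genes, and iterating it would
shred every component into gene pairs. The default rule is therefore
*longest path first* (most genes; ties by lowest total weight, then a
deterministic traversal order), which reproduces intact genomes exactly
— the identity property in the test suite — and uses the weights
precisely where they matter, to choose between competing branches. The
literal reading remains available as `path_rule = "lowest-score"`.
Because every node of the spanning tree has at most one intra-gene
edge, contracting genes turns each component into a tree of genes whose
legitimate paths are found by a linear-time dynamic program with
end-port alternation constraints; on a tree this is equivalent to
scoring all pairwise paths (they are unique), just cheaper than the
all-pairs computation the original description invokes. Selected paths
are removed, fragments re-enter the queue, and fragments reduced to one
gene become leftovers. A reportable run has at least 2 genes
(configurable).

## Replicon architecture

Processing is bottom-up. A node's called families are partitioned into
co-inheritance groups by the exact pair (replicon of the family in
child 1, replicon in child 2); families present in one child only form
single-slot groups; families present in neither child are set aside.
Groups sharing a replicon in the same child slot are linked in the
node's group graph. The outgroup of a non-root node is its sibling
(whose groups derive from the sibling's children, both already
processed — the processing order sorts nodes by the larger of their own
and their sibling's subtree heights, which makes all four dependencies
available); the root uses the user-designated outgroup genomes.

Cross-links between target and outgroup groups require at least
`min_shared` shared families, default **1**, and each target group is
attributed to the single outgroup component it shares the most families
with. Within one outgroup component, attributed groups that are
connected in the target group graph merge into one replicon; everything
else becomes its own replicon. Two failure modes shaped these defaults,
both visible on simulated data with known truth. A higher cutoff (e.g.
3) structurally bars every group smaller than the cutoff from
placement: each small loss pattern or translocated fragment becomes a
satellite one-to-two-gene replicon, inflating architectures by dozens
of replicons. Conversely, a promiscuous attribution (linking a group to
*every* component it shares one family with) lets single stray families
leak a plasmid group into the chromosome component, collapsing
chromosome and plasmid into one replicon. Best-match attribution with
cutoff 1 avoids both; on simulations with gene-scale events only, the
reconstructed replicon count matches the truth at better than 90% of
internal nodes (the acceptance suite measures this), and the remaining
errors are near-root collapses where the outgroup signal is weakest.

Families with no pattern (absent from both children but called at the
node, which the marginal posteriors permit) attach to the majority
replicon of the gene run they sit on, else to the largest replicon —
this preserves the partition property without inventing replicons.

**Run-driven replicon merge.** The group criterion is stringent and
over-splits; gene runs straddling two replicons are the corrective
signal. For each run of at least 4 genes whose members map to more than
one replicon, with N1 genes on the modal replicon and N2 on a
challenger, the relative signal is N2/(N1+N2) (in (0, 0.5]); runs below
a relative floor of 0.1 are ignored; the absolute strength is the run
length. The N1/N2 quantities are as originally defined, but the exact
relative formula and the floor are not recoverable from the method's
description, so both are explicit, configurable parameters reported in
the run metadata. Per node and replicon pair, absolute strengths are
summed and the strongest relative signal is kept; proposals are pooled
over all nodes and split by 2-means on the standardized
(absolute, relative) plane. K = 2 is the only reading consistent with a
line between accepting and rejecting proposals. The accepted cluster is
the one whose standardized centroid has the larger coordinate sum — the
"high" side of the dividing line; a pure norm criterion would
occasionally accept a far-outlying *weak* cluster. Degenerate pools are
handled deterministically: a single proposal is accepted iff it clears
fixed floors (relative ≥ 0.25, absolute ≥ 8); identical proposals offer
no separation and are all rejected. Accepted pairs merge transitively;
merging never increases the replicon count.

**Chromosome restoration.** The replicon with the most core genes
(families present in every input genome) becomes the main chromosome —
ties by total gene count, then lexicographic id; any other replicon
with at least 5% of the total core-gene count becomes a secondary
chromosome; the rest are plasmids. All rule thresholds in the package
(presence cutoffs, 5% core rule, 60% operon support, 80% leave-one-out
sharing, minimum run length 4) are boundary-inclusive (≥).
Chromid-style intermediate replicon classes are out of scope.

## Event inference

Along every branch: gene gains/losses are set differences of called
families (observed families for leaf children). Replicon events come
from a bipartite mapping between parent and child replicons — an edge
requires sharing at least max(3, 20% of the smaller replicon) families;
a parent mapping to two or more children is a split, two or more
parents into one child a merge, unmapped replicons are losses/gains.
These mapping thresholds are this package's own formalization (event
calling was never formalized in the original description) and are
configurable. Reversals are maximal blocks, within a parent run and its
best-matching child run, of consecutive shared genes whose order is
exactly inverted *and* whose strands are all flipped; because
reconstructed runs have no intrinsic reading direction, the child run
is first oriented to majority-strand agreement with the parent —
otherwise every conserved run read backwards would masquerade as a
reversal. Run fates are classified as conserved / extended /
fragmented(k) / lost with the 80% sharing rule shared with the
leave-one-out protocol. On multi-event branches these calls are
reported as-is; only single-event branches are expected to match a
simulation log exactly.

## The simulator

The simulator is the evaluation substrate: it generates a rooted
bifurcating topology by uniform recursive splitting (the designated
outgroup leaves form one child clade of the root), draws branch lengths
i.i.d. uniform on [0.05, 0.35], and evolves the start genome along the
tree. Per branch, each event type draws a Poisson(rate × length) count
and the events apply in shuffled order: gain inserts a fresh family at
a uniform position; loss deletes a uniform gene; duplication copies a
gene — as a `*` singleton by default, honoring the no-paralog input
contract (a flag emits true paralogs for testing upstream-refinement
scenarios); reversal inverts a geometric-length segment flipping
strands; translocation moves a segment to another replicon;
transposition within its replicon; replicon gain seeds a new plasmid
with a translocated segment; merge concatenates two replicons; split
cuts one at a uniform boundary; replicon loss deletes a non-main
replicon (the main chromosome is immune, so a genome always keeps at
least one replicon). Inapplicable draws are skipped. Every applied
event is logged with concrete operands; replaying the log from the root
genome reproduces every node genome exactly, and that replay identity
is a tested contract.

Default conditions are a 1,000-family chromosome plus 200-family
plasmid evolved into 21 genomes (2 outgroups). Default rates per unit
branch length — gain 60, loss 60, duplication 20, reversal 40,
transposition 8, translocation 1, replicon events 0.15 each — were
chosen so that reconstructed-run statistics on simulated data resemble
those of real bacterial-order datasets (ancestral run coverage largely
within 60–95%, mean runs of a few to a few dozen genes, deep ancestors
markedly more fragmented than shallow ones) rather than the
near-identical genomes that an order of magnitude lower rates produce.
The asymmetry between reversal and translocation is biological:
inversions dominate large-scale bacterial rearrangement, while
inter-replicon traffic is comparatively rare. What the simulator does
*not* emulate: horizontal transfer between contemporaneous lineages (no
concept of time), sequence-level evolution, paralogous family
structure (unless requested), replicon-specific rate variation, and
any correlation between events. Passing tests on simulated data
therefore demonstrate the machinery's correctness under the model's
own assumptions — not performance on real genomes, where ortholog
assignment noise and HGT will degrade all signals.

## Evaluation protocols

Pair precision/recall compares called NGP keys against the true keys of
the simulated ancestor. Coverage statistics mirror the standard
per-ancestor report (number of runs, longest run, genes on runs,
percentage of called genes). Operon support classifies a run as
supported when ≥ 60% of its internal family pairs are known operon
pairs (pairs keyed direction-insensitively, matching NGP
canonicalization); operon pairs classify as highly/moderately/less
conserved at ≥ 10, 6–9 and 2–5 genomes. The leave-one-out protocol
reruns the full reconstruction once per left-out genome on the pruned
tree and checks each focal-node run of ≥ 4 genes for recovery under
the 1-fragment rule (some replicate run shares ≥ 80% of its genes) and
the 2-fragment rule (the two largest-sharing replicate runs cover 80%
together); a run counts as recovered overall at ≥ ⌈0.818 × replicates⌉
— the fraction generalizes the original 18-of-22 criterion to any
genome count. Consensus annotation transfers the modal member
annotation to a family (ties lexicographic), reported as k/n.

## Numerical and scale choices

All stochastic steps (simulation, rate-fit starts, K-means restarts)
derive from explicit seeds; two runs with the same seed are
bit-identical, which the suite asserts on full report directories. The
test suite exercises enumeration oracles at the largest sizes where
exhaustive computation is instant (trees to six leaves, end graphs to
ten nodes), the identity reconstruction at the full 1,200-gene scale,
and the simulation studies at ten datasets of the default scale —
sizes chosen to probe every code path at the scale the method targets
while keeping a complete run of the suite in the minutes range.
`fitRates` warns and returns the boundary minimum-rate model when every
character is constant across leaves (rates are then unidentifiable);
`pairPrecisionRecall` reports precision as `NA` when nothing was
reconstructed rather than inventing a number.

## Known limitations

The replicon assembly degrades near the root, where the outgroup is
thinnest: occasional chromosome–plasmid collapses survive the merge
step. Gene runs are reconstructed as unordered sets of runs — the
method deliberately does not order runs along a replicon, so
between-run adjacency is not inferred. Translocation-heavy histories
blur co-inheritance patterns faster than the group criterion can
resolve them. The ML model treats characters independently; linked
gain/loss of neighboring genes (operons!) violates this and is exactly
why NGP characters help. And everything downstream of ortholog
assignment inherits its errors; the package deliberately refuses
paralogous input rather than guessing.
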