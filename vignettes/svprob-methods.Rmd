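---
title: "Probabilistic structural variant calling from paired-end reads: the svprob model"
author: "svprob authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic structural variant calling: the svprob model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svprob)
```

# The problem

Paired-end resequencing detects structural variants (SVs) through two
complementary signals. Fragments whose two reads align with unexpected
orientation or spacing (*discordant* fragments, the paired-read signal)
point at a novel adjacency $(a, b)$: two reference positions, the
*breakends*, that have become adjacent in the sequenced genome. At the same
time the local density of ordinary (*concordant*) fragments — the read-depth
signal — drops across a deleted interval, and, much more locally, right at
the breakends of any rearrangement, including copy-neutral ones such as
inversions (we refer to this highly local dip as breakend read depth).
`svprob` fuses both signals in one likelihood per candidate variant,
classifies each call as homozygous or heterozygous, and resolves
ambiguously mapped fragments by sampling over the space of consistent
fragment-to-variant assignments.

# Fragment classification

A fragment alignment is one choice of alignment for each read of a pair.
With library fragment lengths in $[L_{\min}, L_{\max}]$, a same-chromosome
pair in convergent orientation (for Illumina: left read `+`, right read
`-`) whose outer mapped span lies in that range is concordant; everything
else is discordant with a signature: convergent but too long (deletion
type), `+/+` or `-/-` (the two inversion types), outward-facing or too
short (divergent), different chromosomes (translocation). $L_{\min}$ and
$L_{\max}$ default to the 0.1% and 99.9% quantiles of the empirical span
distribution (a mean $\pm k\,$sd rule is available); by construction about
0.2% of perfectly normal fragments fall outside these bounds and appear as
scattered singleton discordants — the likelihood model rejects them.

A fragment enters the discordant set only when *every* alignment of it is
discordant; fragments with several alignments at least one of which is
concordant are set aside, as are alignments with mapping quality at or
below 10, same-chromosome spans above 500 kb, and fragments whose reads
have more than 100 alignments genome-wide (all thresholds configurable).

# Breakend polygons and geometric clustering

Write $x$ and $y$ for the *breakpoint-proximal* read coordinates: the
rightmost aligned base of a `+` read, the leftmost of a `-` read, ordered
so $x < y$, with $sign(x) = +1$ for a `+`-strand read. A discordant
alignment constrains its mated breakends to the convex band

$$\ell \le sign(x)\,(a - x) + sign(y)\,(b - y) \le h$$

intersected with the box that keeps each breakend on the proximal side of
its read ($a \ge x$ when $sign(x) = +1$, $a \le x$ otherwise, and likewise
for $b$): a trapezoid in the $(a, b)$ plane.

**Band bounds.** With proximal coordinates, a fragment of length $L$
straddling the true adjacency satisfies
$sign(x)(a-x) + sign(y)(b-y) = L - 2\,r$ exactly, where $r$ is the read
length: the two reads themselves consume $2r$ of the fragment. The
clustering path therefore uses the inner-span bounds
$\ell = L_{\min} - 2r$, $h = L_{\max} - 2r$, which is the unique choice
under which the true breakend pair of *every* concordant-length supporter
lies inside its trapezoid, and which is consistent with the expected count
$\lambda_d = (L_{avg} - 2r)\lambda$ of breakend-spanning fragments (below).
`fragmentTrapezoid()` itself applies whatever bounds the supplied
`LibraryStats` carries, so the raw $[L_{\min}, L_{\max}]$ band is available
directly when wanted.

All geometry is carried out on half-planes with coefficients in
$\{0,\pm 1\}$ and integer offsets, so every vertex coordinate is an integer
or half-integer and double arithmetic is exact; intersection and membership
tests carry no floating-point tolerance in substance.

Within each (chromosome pair, signature) stratum, candidate variants are
all *maximal* fragment sets whose trapezoids share a common intersection
$B$; the candidate is the pair $V = (F, B)$ with support $k = |F|$.
Maximality is enumerated exactly (a Bron–Kerbosch-style recursion over the
pairwise-intersection graph, with the running polygon as the feasibility
oracle) because the common intersection of a pairwise-intersecting set can
be empty in the plane; a budget on polygon-intersection tests (default
20,000 per connected component) switches to a greedy largest-first
decomposition for degenerate components, and components above 200
alignments use the greedy path directly. A fragment whose trapezoid meets
several groups appears in several candidates; the sampler resolves it.

# The likelihoods

Fragment starts follow a homogeneous Poisson process of rate $\lambda$ per
base, so point coverage by concordant fragments is Poisson with mean
$\lambda_c = \lambda L_{avg}$, the number of fragments spanning a breakend
is Poisson with mean $\lambda_d = (L_{avg} - 2\,r)\lambda$, and the number
of concordant fragments touching an interval $I$ is Poisson with mean
$\lambda_I = \lambda(|I| + L_{avg})$. Writing $n(p)$ for observed
concordant coverage at $p$, $p_e$ for the per-fragment erroneous-mapping
probability (default 0.01 — configurable; it is a prior belief about the
aligner, not a fitted quantity), and $k$ for the discordant support, the
three copy-number hypotheses for a breakend pair $(a,b)$ are scored as

* $C=2$ (homozygous): $p_e^{\,n(a)+n(b)} \cdot \mathrm{Pois}(\lambda_d; k)$
* $C=1$ (heterozygous): $\mathrm{Pois}(\lambda_c/2; n(a))\,
  \mathrm{Pois}(\lambda_c/2; n(b))\, \mathrm{Pois}(\lambda_d/2; k)$
* $C=0$ (no variant): $\mathrm{Pois}(\lambda_c; n(a))\,
  \mathrm{Pois}(\lambda_c; n(b))\, p_e^{\,k}$

Each hypothesis is maximized over $(a,b) \in B$ and the call is the log
likelihood ratio $\log\Lambda = \log\max(P_2, P_1) - \log P_0$ with the
copy call $\hat c$ the argmax. Because the $(a,b)$-dependent factor and the
$k$-dependent factor separate within each hypothesis, the maximization over
$B$ is done once per candidate, and the likelihood becomes a cheap function
of $k$ — the property the sampler exploits.

The maximization over $B$ is exact: coverage is piecewise constant between
fragment-extent endpoints, so $B$ is partitioned into rectangular cells on
which $(n(a), n(b))$ is constant, and one integer representative per
non-empty cell (an $O(1)$ integer-arithmetic computation per cell) provably
contains a maximizer of every hypothesis.

Deletion-signature candidates use the stronger interval form: every point
of $I(B) = [a_{\max}, b_{\min}]$ must be deleted, so $n(I)$ — the count of
concordant fragments touching $I(B)$, scaled for mapability as
$\hat n(I) = n(I) / (\alpha + \beta R(I))$ with $\alpha = 0.3$,
$\beta = 0.7$ and $R(I)$ the fraction of uniquely mapable bases — replaces
the two breakend counts: $C=2$: $p_e^{\hat n(I)}\mathrm{Pois}(\lambda_d;k)$;
$C=1$: $\mathrm{Pois}(\lambda_I/2;\hat n(I))\,\mathrm{Pois}(\lambda_d/2;k)$;
$C=0$: $\mathrm{Pois}(\lambda_I;\hat n(I))\,p_e^k$. Scaled counts are
generally non-integer, so the Poisson mass is evaluated through the
$\Gamma$-function extension of $\log k!$, avoiding a ranking discontinuity
at rounding boundaries. Discordant counts are never mapability-scaled
(low-mapability regions are rich in spurious discordants, and inflating
them inflates false positives). A `breakendOnly` switch forces the generic
model everywhere, and `homozygousOnly` drops the heterozygous hypothesis.

Regions of extreme concordant coverage are withheld from variant calling: a
count above the 0.9999 Poisson quantile of its reference mean forces
$\hat c = 0$. The reference mean is the one relevant to each scorer —
$\lambda_c$ for breakend counts, $\lambda_I$ for the deletion interval —
since a single cap level cannot be on the right scale for both.

# Mapping matrices and the sampler

For ambiguous fragments, the binary alignment matrix $A$ records which
candidates each discordant fragment *could* support; a mapping matrix $M$
assigns each fragment to at most one candidate (0 = mapping error). With an
exponential prior (rate $\eta$, default $10^{-3}$) on the number $V(M)$ of
supported variants,

$$P(M \mid A) \propto \eta e^{-\eta V(M)} \prod_{j : S_j > 0}
  \max_{c > 0} P(V_j \mid C_j = c) \prod_{i : \gamma_i = 0} p_e ,$$

where $S_j$ is variant $j$'s support under $M$. Sampling uses
Metropolis–Hastings with a 1/2 self-loop and four move classes: N
(re-assign one fragment; drops are proposed with probability $p_e$), Z
(zero out a supported column, re-scattering its fragments), $\bar Z$ (pull
fragments into an unsupported column), and S (swap entries between two
columns sharing fragments, chosen with probability proportional to the
shared-row count among currently swappable pairs). Each iteration picks
uniformly among the classes that have a legal move from the current state;
the proposal density $q(M, M')$ sums the terms of *every* class able to
produce the transition under that uniform class weight, which reproduces
the $\chi = 1/4$ weighting when all four classes are available.

Two conditioning choices close gaps the move recipes leave open. The
$\bar Z$ and S retry loops ("repeat until at least one entry changes") are
realized as per-row Bernoulli(1/2) draws conditioned on a non-empty
outcome, so a specific outcome has probability $(1/2)^r / (1 - (1/2)^r)$
with $r$ the number of eligible rows — making the sampled kernel and its
density $q$ exactly consistent, which the acceptance rule requires. And an
assigned fragment with no alternative candidate is dropped deterministically
by an N move (probability $1/F$), the only reading that leaves the class
well-defined for single-candidate rows; such rows are fixed (not sampled)
by default anyway, following the unique-assignment heuristic, with
`sampleUnique = TRUE` to override. Move legality for Z/$\bar Z$/S is judged
on the movable rows; the target's support counts and $V(M)$ always include
the fixed rows.

Acceptance is the standard ratio
$\min\{1, q(M',M)P(M'|A) / (q(M,M')P(M|A))\}$ computed incrementally from
the changed rows and columns only. The fragment–variant bipartite graph is
decomposed into connected components (the target factorizes over them),
each sampled independently — by a compiled core whose semantics are mirrored
one-for-one by the exported R-level functions `logTarget()`,
`proposeMove()`, `proposalProb()` and `acceptanceProb()`; the test suite
holds the two implementations to the same stationary law. Components whose
fragment-candidate incidence count exceeds a ceiling (default $10^6$) are
not sampled: only their unique-candidate fragments are assigned, the
documented fallback for pathologically entangled regions. Chains default to
$10^5$ burn-in and $9 \times 10^5$ sampling iterations per component and
are bit-reproducible given a seed.

# Reporting

Chains accumulate the marginal assignment frequency $\bar m_{ij}$ of each
fragment and the per-variant occupancy of each support level, from which
the chain-averaged ratio $\Lambda(V) \approx \frac 1N \sum_i
\Lambda(V, M_i)$ is computed exactly in log space. The default call set
comes from the consensus matrix $\bar M(\tau)$: a fragment is assigned
where $\bar m_{ij} \ge \tau$ (default $\tau = 0.5$, inclusive, which
guarantees at most one qualifying candidate per fragment; values below 0.5
are rejected). Each supported variant is re-scored at its consensus
support, filtered at $\log\Lambda > 0$ (and optionally a minimum support —
2 reproduces the stricter reporting variant), and projected to the interval
$[a_{\max}, b_{\min}]$. Redundant calls — intersection at least half the
union, or containment either way — are pruned greedily by descending score
(ties broken on coordinates, making the output ordering total and
deterministic); the chain-averaged ratio is emitted as an auxiliary column.
When every fragment has a single candidate, the sampled path reduces
exactly to direct scoring of the clusters (`hqOnly = TRUE` skips the
sampler explicitly).

Calls export as BEDPE (score $=\log\Lambda$, genotype column) and VCF 4.1
(`SVTYPE`, `END`, `CIPOS`/`CIEND` from the polygon extent).

Predictions are benchmarked with a double-uncertainty rule: a call
$(x, y)$ with uncertainty $\epsilon$ matches a known variant $(a, b)$ with
uncertainty $\delta$ iff both closed intervals $[x \pm \epsilon]$,
$[a \pm \delta]$ (and the right-breakend pair) intersect; touching counts.
$\epsilon = L_{\max}/2$ reflects the sequencing process;
$\delta = 0$ suits breakpoint-exact truth sets and $\delta = 200$
paired-read-derived ones. When several calls match one known variant the
variant counts once and none of those calls count as novel.

# The simulator

`simulateExperiment()` generates the exact statistical structure the model
assumes: a diploid genome over a synthetic reference with non-overlapping
deletions and inversions of known genotype (homozygous events on both
haplotype coordinate maps, heterozygous on one); fragment left ends from a
Poisson process at rate $\lambda/2$ per haplotype (so diploid coverage
matches $\lambda$ and heterozygous breakends see $\lambda_c/2$); lengths
Normal($L_{avg}$, sd) truncated below at $2r$; reads of length $r$ taken
from the fragment ends with Illumina orientation and mapped through the
piecewise-linear coordinate maps — a read that crosses a junction fails to
align, which is precisely why $\lambda_d$ carries the $-2r$ term.
Configurable homologous repeat blocks give reads inside them an
alternative placement (inducing genuinely ambiguous fragments, and $R = 0$
mapability inside the copies); a fraction $p_{err}$ of fragments have
their placement replaced by a random discordant one. Defaults mirror a
standard short-insert library: $\lambda = 0.3$ ($60\times$ fragment
coverage), $L_{avg} = 200$, sd 20, $r = 50$, $p_{err} = 0.01$.

What the simulator does *not* emulate — base-level sequencing errors,
realistic repeat families, GC bias, overdispersed coverage, micro-homology
at junctions — bounds what passing tests show: they certify the inference
machinery against its own generative assumptions, not performance on real
libraries, where coverage is overdispersed and breakpoints are dirtier.

# Validation design and numerical choices

The test suite checks every geometric primitive against brute-force
integer-lattice oracles, coverage counting against an $O(nm)$ scan and an
independent interval-tree implementation, and the sampler against exact
enumeration of $P(M|A)$.

The enumeration sweep runs every alignment matrix with up to 4 fragments
and 3 variants, up to row order and column relabeling (86 canonical
instances — the chain law is equivariant under both symmetries), at
$9\times 10^5$ samples each, requiring total-variation distance below 0.02.
This sweep is parameterized at $\lambda_c = 8$, $\lambda_d = 4$, with
per-column breakend coverages $(0,0)$, $(0,0)$, $(20,20)$ and
$p_e = 0.1$: support of 1–4 fragments is then the model's own expected
scale, every column sits in an unambiguous likelihood regime (clear
variant or clear error, per-fragment log-odds gaps $\ge 2$), and drop
moves — proposed with probability $p_e$ by design — occur often enough that
the fixed sample budget measures sampler exactness rather than
metastable-mode occupancy noise. Near-tied configurations (breakend
coverage at the support-versus-error crossover) produce a genuinely
bimodal target whose modes communicate only through $O(p_e^m)$ proposal
bottlenecks; no exact sampler attains TV < 0.02 there within this budget,
so they are a mixing stress test, not an exactness check. Detailed balance
$\pi(M)p(M,M') = \pi(M')p(M',M)$ is verified to $10^{-12}$ over all state
pairs of the twelve 1–2-row instances plus seven larger ones (the
all-pairs sweep over every instance is quadratic in the state count and
adds nothing beyond those shapes). End-to-end recovery runs the full
pipeline on a 5 Mb simulation with 50 deletions (25 homozygous, 25
heterozygous) and 10 inversions at the default library settings.

Numerical and degenerate-input choices worth knowing: polygons may
degenerate to segments or points (zero area is legal; an empty polygon has
zero vertices and marks disjointness); equal proximal coordinates in a pair
are nudged one base and classified divergent rather than dropped; a
polygon thinner than one lattice cell falls back to the nearest lattice
point of a vertex for scoring; `estimateLengthBounds()` insists on at
least 100 spans; and chains on components with no movable rows return a
flagged point-mass summary rather than sampling.

# Limitations

Insertions, duplications and copy-gain hypotheses are out of scope (the
signatures exist in classification but only deletion, the two inversion
types and generic breakends are scored); translocation clustering is
limited to one chromosome pair at a time; coverage is strictly Poisson
with no GC or overdispersion correction (the scorer is isolated enough to
swap the distribution); and the breakend maximization assumes clean
junctions — indels near true breakpoints blur the local coverage dip and
will cost genotyping accuracy on real data.
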