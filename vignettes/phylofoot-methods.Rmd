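---
title: "Methods: group-wise phylogenetic footprinting and motif-graph clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-wise phylogenetic footprinting and motif-graph clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Transcription factor binding sites (TFBSs) in prokaryotes are short
(8–22 bp), degenerate and scattered through long upstream inter-operonic
regions, which makes de novo discovery in a single genome unreliable.
`phylofoot` exploits two regularities instead of one:

1. **Phylogenetic footprinting.** Regulatory sites are conserved in the
   promoters of orthologous operons across related genomes, so a motif
   finder run on the pooled upstream sequences of an orthologous operon
   cluster sees several noisy copies of the same signal.
2. **Cross-cluster recurrence.** A real transcription factor regulates
   many operons, so its motif recurs — as mutually similar candidate
   motifs — across many different orthologous clusters, whereas spurious
   finder output does not.

The pipeline treats every genome in a group simultaneously as target and
reference.  Its stages are:

* **Target-group selection.** Each genome is encoded as a presence /
  absence bit vector over TF families; pairwise Hamming distances feed a
  neighbour-joining tree (`neighbor_joining()`, via `ape`), and
  `select_target_group()` grows the clade around a seed genome until
  some genome pair would share less than half of its TF families
  (denominator: the smaller TF set — the symmetric, conservative
  choice).
* **COORs.** Orthology is bi-directional best BLAST hits at
  E ≤ 1e-20 in both directions (`bdbh_orthologs()`; hit tables are
  inputs, BLAST itself is not run).  Every operon seeds a SCOOR that
  recruits, per other genome, the operon containing orthologs of at
  least 50% of the seed's genes; SCOORs whose member sets overlap by at
  least 70% of the smaller one are connected, and each connected
  component is a COOR (cluster of operons with orthologous
  relationships).  For each COOR with at least three operons, up to
  800 bp of upstream inter-operonic sequence per operon (truncated at
  the nearest annotated gene boundary) forms one sequence set.
* **Ensemble footprinting.** Each sequence set is mined by a
  configurable list of motif-finder adapters, each contributing its
  ordered top-k predictions at a fixed width of 16 bp; the default
  configuration fills five slots (top 15 + 10 + 5 + 5 + 5 = 40 motifs
  per set) with the built-in Gibbs sampler under distinct seeds.
  External finders can be wrapped with `finder_adapter()`.
* **The clustering cascade.** Candidate motifs are filtered through
  motif-similarity graphs: a permissive graph G1 (cutoff `alpha`) and a
  stringent graph G2 (`beta`), MCL on G2, a recruitment graph G3 whose
  nodes are G2 clusters plus G1-only motifs (edges by mean G1 weight
  above `alpha`), MCL on G3, quasi-cliques inside the induced G1
  subgraphs, one best 16 bp motif per quasi-clique, a motif graph G4 at
  cutoff `gamma` (= `beta`), extension of merged sites by 10 bp and
  re-finding of 22 bp motifs, a graph G5, per-genome partitioning with
  auto-width (8–22 bp) motifs and a final genome-specific graph, and a
  refinement step that finds up to 15 motifs of widths 8–22 per cluster
  and merges their sites into the final unique site set.
* **Ranking.** Each final cluster is scored and ranked per genome; the
  top-ranked clusters are the predicted motifs.

# The motif similarity metric

A motif $M_x$ with $n_x$ aligned sites of width $L_x$ is summarised by
its count matrix $F_x$, pseudocounted column probabilities
$p_x(b,i) = (f_x(b,i) + \delta q(b)) / (n_x + \delta)$ (default
$\delta = 1$, background $q$), and log-odds profile
$P_x(b,i) = \log_2 p_x(b,i)/q(b)$.

One direction of the similarity scores $P_x$ against the observed column
proportions $\hat f_y$ of $M_y$ over every ungapped offset.  At an
offset, column $i$ has raw score $c(i) = \sum_b P_x(b,i)\,\hat
f_y(b,s(i))$ and counts as *aligned* when $c(i) > \tau \max_b P_x(b,i)$;
the offset's aggregate is $\sum_{\text{aligned}} c(i) / \sum_i \max_b
P_x(b,i)$, so a full-length perfect match scores exactly 1.  Among the
offsets with the maximum number of aligned columns the largest aggregate
is kept.  The pair score symmetrises both directions, takes the better
of the forward and reverse-complement orientation of $M_y$, and clips to
$[0,1]$.

Two design points deserve comment:

* **Why sum-normalised, not mean-of-aligned?**  If the aggregate were
  the mean over aligned columns, any offset with one strong column would
  score near 1 and unrelated motifs would saturate the scale.  With the
  sum normalisation, unrelated random 16-mer motifs score ≈ 0.11 (95th
  percentile ≈ 0.15), while sub-motifs of one site family score ≈ 0.6 —
  0.9; the test suite asserts this separation.
* **The per-column threshold $\tau$** defaults to 0.5, frozen after a
  calibration requiring random 16-mer motif pairs to score below 0.2 in
  at least 95% of cases (measured: > 99%).

# Graph cutoffs at different pool sizes

On genome-scale runs (a few 10^5 input motifs) the similarity graph at a
cutoff of 0.2–0.3 is sparse in relative terms even when its
edges-per-node density is in the hundreds, and `autotune_cutoffs()`
reproduces that regime by bisecting the cutoff against density targets
(≈ 500 for G1, 15–20 for G2) inside the ranges 0.2–0.3 and 0.35–0.45.

At desk scale (10^3 motifs) the same cutoffs produce *relatively*
near-complete graphs — with a 0.4% false-positive rate per pair, every
spurious motif still gains several edges — and cascade clustering
degenerates.  The package therefore defaults to `alpha = 0.35`,
`beta = 0.45`, just above the bulk (90th percentile ≈ 0.30) of the
spurious-pair score distribution of the built-in sampler, while true
motif pairs (median ≈ 0.64) stay connected.  Users running large groups
should lower the cutoffs toward the density-tuned regime.

# The built-in Gibbs sampler

`builtin_sampler_find()` is a one-site-per-sequence (OOPS) Gibbs sampler
over both strands with random restarts (default 2) and 30 sweeps, a
deterministic argmax polish, and whole-configuration phase-shift moves
(± 3 bp) that escape the classic shifted-alignment local optimum.
Subsequent motifs come from masked re-runs, so one call yields an
ordered, non-overlapping top-k list; all randomness flows through R's
RNG and a caller-supplied seed.  Where a stage auto-detects width
(8–22 bp), candidate widths are compared by total information content
net of the expected finite-sample contribution (≈ $3/(2n\ln 2)$ bits
per column for three free parameters), scaled by the site count.

# Cluster scoring

Every final cluster is ranked by

$$\mathrm{ClusterScore} = \frac{n}{N}\sum_{i=1}^{L}\Big[\sum_b
p(b,i)P(b,i) - \frac{3}{2n\ln 2}\Big]$$

floored at zero: the coverage of the cluster ($n$ of $N$ sequences in
its best motif of width $L$) times the motif's total information
content in bits, net of the finite-sample bias of the information
estimate.  The bias term matters: the raw per-column information of a
3-site alignment of random sequences is inflated by ≈ 0.5 bits/column,
enough to outrank a conserved 30-site motif under a mean-per-column
score.  With the bias-corrected total, planted motifs in the simulation
below rank at the top of every genome while both tiny spurious clusters
and the large "everything else" cluster fall behind.

# The synthetic genome group

`generate_group()` builds a toy genome group in which every operon
template is instantiated once per genome with the same ortholog
families, so each template is one COOR of the whole group by
construction and the hit tables recover the family truth exactly through
BDBH.  Defaults mirror the reference simulation conditions used
throughout the tests: 5 genomes, 60 operon templates, 1–3 genes per
operon (genes 200–400 bp), intergenic regions 200–500 bp (within the
800 bp upstream window), 20% of templates on the minus strand, i.i.d.
background at 50% GC, and 4 planted motifs of width 16 with
single-base (2-bit) columns, each carried by 20% of the templates, with
per-genome sites decaying from the consensus at a 5% per-base mutation
rate — a caricature of footprint conservation between related genomes.

What the simulator does *not* emulate: indels and rearrangements,
horizontal transfer, operon mis-prediction, promoter architecture beyond
one planted box per region, compositional heterogeneity (real genomes
carry low-complexity repeats that produce recurrent spurious motifs),
and TF families with variable site counts per genome.  Passing the
planted-recovery tests therefore demonstrates that the machinery filters
finder noise and recovers conserved recurrent signals, not that any
particular accuracy will be reached on real genome groups.

# Problem sizes and numerical choices

The test and acceptance runs use the reference simulation above with a
scaled ensemble of T = 10 motifs per sequence set (slots 4+3+1+1+1);
at these sizes a full pipeline run takes well under a minute, and the
planted-recovery property is evaluated over ten seeds.  The package
default remains T = 40 (15+10+5+5+5).  Other numerical choices:

* MCL: inflation 2.0, expansion 2, prune 1e-5, convergence when the
  flow matrix changes by < 1e-6, cap 100 iterations (non-convergence
  returns the current clustering with a warning).  Overlapping attractor
  systems are merged; nodes go to the cluster receiving most flow, ties
  to the smallest cluster id.  Unit self-loops.
* Site merging is transitive with a strict > 8-base overlap rule,
  same genome and strand, union interval, sequence re-extracted.  The
  *final* unique-site sets additionally collapse strand-agnostically at
  > 3 shared bases, because refinement motifs of width 8 can never
  overlap another call by more than 8 bases.
* Degenerate stages (pools with < 3 usable sequences) pass their sites
  through unchanged rather than invoking the sampler.
* Ties everywhere are broken deterministically (lexicographic ids,
  smallest indices), and every stochastic step derives its seed stably
  from the run seed, so a whole pipeline run is bit-reproducible.

# Known limitations

* The recruitment of leftover G1 motifs absorbs them into induced
  subgraphs rather than tracking them as independent units thereafter.
* Quasi-cliques are grown greedily per node; they form a cover, not an
  optimal clique decomposition.
* The OOPS sampler forces one site per sequence, so cluster best-motifs
  over contaminated pools dilute; the bias-corrected score compensates
  at the ranking stage but per-cluster consensus strings can be noisier
  than a ZOOPS finder would produce.
* Circular-genome upstream extraction wraps the origin, but the
  simulator only generates linear genomes, so the wrap path is covered
  by unit tests only.
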