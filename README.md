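# phylofoot

Genome-wide, de novo prediction of transcription factor binding sites
(TFBSs) — simultaneously in every genome of a group of related
prokaryotes.

## Who this is for

Microbial regulatory genomics: you have a clade of sequenced genomes
(with annotations, operon predictions and pairwise protein hit tables)
and want a ranked catalogue of candidate cis-regulatory motifs *per
genome*, without chromatin data and without knowing the transcription
factors in advance.

## The method

TFBSs are short (8–22 bp) and degenerate, so single-genome motif
finding drowns in noise.  `phylofoot` stacks two independent sources of
signal:

1. **Phylogenetic footprinting over orthologous operons.**  Orthology
   (bi-directional best hits, E ≤ 10⁻²⁰ both ways) links operons across
   genomes into *clusters of operons with orthologous relationships*
   (COORs): every operon seeds a semi-cluster (SCOOR) recruiting, per
   other genome, the operon carrying orthologs of ≥ 50% of its genes;
   SCOORs overlapping by ≥ 70% of the smaller one are connected, and
   each connected component is a COOR.  For each COOR (≥ 3 operons), up
   to 800 bp of upstream inter-operonic sequence per operon is pooled
   and mined by an ensemble of motif finders (top 15+10+5+5+5 = 40
   candidate motifs of width 16 per set by default; a built-in Gibbs
   site sampler fills every slot, external finders plug in via an
   adapter contract).
2. **Graph clustering of recurrent motifs.**  True motifs recur as
   mutually similar candidates across many COORs; spurious finder
   output does not.  Candidates are filtered through a cascade of
   motif-similarity graphs — a permissive graph G1 (cutoff α) and a
   stringent graph G2 (β) clustered by Markov clustering (MCL), a
   recruitment graph G3, quasi-cliques inside induced G1 subgraphs,
   re-found quasi-clique motifs (G4), 10 bp-extended 22 bp motifs (G5),
   and genome-specific re-clustering — after which each surviving
   per-genome cluster is refined over widths 8–22 and ranked by

   *ClusterScore* = (n/N) · Σᵢ [ Σ_b p(b,i) P(b,i) − 3/(2n ln 2) ],

   the coverage of the cluster's best motif times its total information
   content (bits) net of finite-sample bias, where
   P(b,i) = log₂ p(b,i)/q(b) is the log-odds profile against the
   background q.  Motif–motif similarity itself is the symmetrised best
   ungapped alignment of one motif's profile matrix against the other's
   observed column frequencies, in both orientations, normalised so a
   perfect full-length match scores 1.

A target-group selector is included: genomes are encoded as TF-family
presence bit vectors, a neighbour-joining tree over Hamming distances
is built, and the clade around a seed genome grows until some pair
would share < 50% of its TF families.

A first-class synthetic-data module (`generate_group()`) simulates a
complete genome group — sequences, annotations, operons, hit tables,
TF table — with planted motifs and a truth table, so the entire
pipeline and its evaluation run without any external data.

## Worked example

```r
library(phylofoot)

# 1. a synthetic group of 3 related genomes with 2 planted motifs
bundle <- generate_group(fixture_config(n_genomes = 3, n_operons = 12,
                                        n_planted_motifs = 2, seed = 42))

# 2. orthology -> COORs -> upstream sequence sets
map   <- build_ortholog_map(bundle$hit_tables, bundle$annotation)
coors <- build_coors(bundle$operons, map)
sets  <- build_sequence_sets(coors, bundle$operons, bundle$genomes,
                             bundle$annotation)
length(coors)
#> [1] 12

# 3. ensemble footprinting (two small finder slots for the example)
ens <- ensemble_config(slots = list(
  list(adapter = builtin_adapter("gibbs1"), k = 4L),
  list(adapter = builtin_adapter("gibbs2"), k = 3L)), seed = 42)
motifs <- collect_input_motifs(sets, ens)
length(motifs)
#> [1] 84

# 4. the clustering cascade and per-genome ranking
res <- run_clustering_pipeline(motifs, bundle$genomes,
                               clustering_config(seed = 42))
head(subset(ranked_report(res), genome_id == "g01"), 4)
#>   genome_id rank cluster_id    score n N  L          consensus n_unique_sites
#> 1       g01    1   g01_c001 6.912821 6 6 18 CTGTAGATTACTTGTACG              6
#> 2       g01    2   g01_c004 4.966407 8 8  8           AATCGATC              8
#> 3       g01    3   g01_c016 4.426564 6 6  8           GCCCTGTA              4
#> 4       g01    4   g01_c008 3.446042 4 4 15    CCTCCCATGTTGGTC              4

# 5. how well did the top clusters recover the planted sites?
top <- do.call(rbind, unlist(lapply(res$ranked, function(rg)
  lapply(head(rg, 4), `[[`, "sites")), recursive = FALSE))
rec <- vapply(seq_len(nrow(bundle$truth_sites)), function(i)
  any(top$genome_id == bundle$truth_sites$genome_id[[i]] &
        pmin(top$end, bundle$truth_sites$end[[i]]) -
          pmax(top$start, bundle$truth_sites$start[[i]]) >= 9),
  logical(1))
recovery_percent(sum(rec), length(rec))
#> [1] 100
```

The rank-1 cluster of genome `g01` is an 18 bp motif covering all 6 of
its sequences with ≈ 6.9 bits of bias-corrected, coverage-weighted
information — one of the two planted motifs (each planted in
`round(0.2 × 12) = 2` COORs, i.e. 6 sites per genome here); every
planted site in the group is recovered by the top 4 clusters per
genome.  `write_results()` exports a report TSV, a MEME-format motif
file and a BED-like site table; `exec/phylofoot` wraps the same steps
as a command line (`simulate`, `select-group`, `run`, `evaluate`).

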