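# mobdiv

Comparative repeat analysis of low-depth ("sample") sequencing data, with a
fully ground-truthed simulator of hybrid genome origins.

## The problem

Shotgun sequencing at a fraction of 1x coverage cannot assemble nuclear
genes, but it measures a genome's high-copy repeat content — transposable
element (TE) families above all — and it recovers the maternally inherited
plastome. Those two signals can disagree. In groups shaped by ancient
hybridization, allopolyploidy and biased fractionation (the bamboos are the
motivating case: three woody lineages, all ancient polyploids, whose
plastid and nuclear histories conflict), the *repartition* of abundant
repeat clusters across lineages carries a nuclear-genome signal that
plastomes cannot see: a subgenome can be purged block by block after a
hybridization while TEs that jumped into the retained subgenome survive,
leaving the lost ancestor detectable in repeat data alone.

`mobdiv` implements that analysis end to end for R users:

* **Read clustering** — pooled, species-prefixed reads are partitioned into
  repeat clusters (proxy TE families) under the transitive >80 %
  local-alignment identity rule, with a k-mer prefilter and a streaming
  union–find implementation that scales to pooled multi-species read sets
  (`cluster_pooled_reads()`, or `build_similarity_graph()` +
  `cluster_reads()` for the exact graph), plus superfamily classification
  against a repeat library (`classify_clusters()`).
* **Repartition** — cluster×species abundance matrices
  (`abundance_matrix()`), top-cluster selection by cumulative read fraction
  (`select_top_clusters()`; coverage arithmetic C = L·N/G via
  `coverage()`), and the four-clade shared/exclusive Venn partition
  (`clade_presence()`, `venn_partition()`).
* **Similarity structure** — species×species Pearson correlation over
  top-cluster abundances, average-linkage dendrogram, Newick export, and a
  clade-grouping report (`correlation_matrix()`, `hierarchical_cluster()`,
  `grouping_check()`).
* **Plastome phylogeny & conflict** — p/JC69 distances, neighbor joining,
  column-resampling bootstrap, Robinson–Foulds distance and monophyly tests
  (`plastome_distances()`, `neighbor_joining()`, `bootstrap_support()`,
  `robinson_foulds()`, `is_monophyletic()`).
* **Simulation** — a first-class generator of the evolutionary scenario the
  analysis targets: ancestral diploid genomes with distinctive mobilomes,
  hybridization with maternal plastome inheritance, allopolyploidy, biased
  fractionation with TE jump survival, amplification bursts, species
  divergence, and paired-read sampling at configurable coverage with full
  truth tables (`default_scenario()`, `null_scenario()`,
  `simulate_scenario()`, `sample_reads()`, …).
* **Pipeline** — one seeded, configured, logged run of all stages
  (`pipeline_config()`, `run_pipeline()`), artifact export
  (FASTQ/FASTA/TSV/Newick/JSON), and truth-based verification
  (`verify_report()`).

## Worked example

```r
library(mobdiv)

cfg <- pipeline_config(seed = 42)   # default hybridization scenario
rep <- run_pipeline(cfg)
print(rep)
#> <ssa_report>
#>   clusters: 213 (9,346 clustered reads); top 32 clusters reach 51.1% of reads
#>   top-cluster superfamilies: Copia 6, DNA 4, Gypsy 20, other 1, simple 1
#>   four-clade common clusters: 5
#>   dendrogram deep split: Arundinarieae+PWB | NWB+Olyreae

verify_report(rep)
#> <ssa_scorecard>
#>   ARI (clusters vs truth families): 0.9977
#>   dendrogram grouping pattern: TRUE
#>   plastome woody paraphyly: TRUE
#>   Venn asymmetry ordering: TRUE; conserved: TRUE
#>   clade-collapsed RF (nuclear vs plastome): 2
```

Reading the scorecard: the recovered read clusters match the simulated TE
families almost perfectly (Adjusted Rand Index 0.998 over repeat-derived
clustered reads); the repeat dendrogram groups the herbaceous Olyreae with
the Neotropical woody bamboos and the temperate Arundinarieae with the
Paleotropical woody bamboos, each clade forming a coherent block; the
outgroup-rooted plastome tree instead shows the woody bamboos as
paraphyletic, with both Bambuseae lineages sister to the Olyreae — so the
clade-level nuclear and plastid topologies differ (Robinson–Foulds distance
2), reproducing the cytonuclear discordance the hybridization model
predicts. The Venn line reports that clusters shared *exclusively* by
Olyreae+NWB outnumber Olyreae+Arundinarieae, and Arundinarieae+PWB
outnumber Arundinarieae+NWB, with Olyreae+PWB minimal — the asymmetric
sharing produced by biased fractionation with TE jump survival.

Under `null_scenario()` (vertical descent, no hybridization) the same
pipeline yields concordant nuclear and plastid topologies (RF 0): the
conflict above is caused by the simulated hybridizations, not by the
method.

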