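---
title: "Repeat repartition analysis of low-depth sequencing data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat repartition analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mobdiv)
```

## The problem

Low-depth "sample sequencing" of a genome (a fraction of 1x coverage) is too
shallow to assemble nuclear genes, but it samples high-copy repeats --
transposable elements (TEs) above all -- at depths proportional to their
genomic abundance, and it yields enough plastid reads to reconstruct the
maternally inherited plastome. `mobdiv` implements the comparative analysis
built on those two signals for a group of taxa (developed here around the
bamboos, whose three woody lineages are ancient allopolyploids):

1. pooled reads from all species are partitioned into **repeat clusters**,
   the operational proxy for TE families: reads belong to the same family
   when they are linked, directly or transitively, by local alignments with
   more than 80% identity;
2. a **cluster-by-species abundance matrix** is tabulated, the most abundant
   clusters accounting for a chosen fraction (default 50%) of all clustered
   reads are selected, and their presence across four clades (herbaceous
   Olyreae; temperate Arundinarieae; Neotropical and Paleotropical woody
   bamboos, NWB and PWB) is summarized as a 15-region Venn repartition;
3. a **species correlation matrix** over top-cluster abundances is
   hierarchically clustered into a dendrogram -- the nuclear repeat signal;
4. a **neighbor-joining plastome tree** is built and compared with the
   repeat dendrogram; disagreement between the two (cytonuclear discordance)
   is quantified by the Robinson-Foulds distance between their clade-level
   topologies.

Because real multi-gigabase data cannot be bundled or processed at desk
scale, the package includes a first-class synthetic-data generator that
simulates the evolutionary scenario the analysis is designed to detect, with
complete ground truth. Every stage of the pipeline is validated against that
truth.

## The simulated evolutionary model

The generator encodes a hybridization model of woody bamboo origins with
three diploid ancestors: a herbaceous genome H and two woody genomes C and D,
each carrying a distinctive mobilome plus a small set of ancient families
shared by all three.

* **Tropical woody ancestor**: an ancient cross between a maternal H and a
  paternal C genome. The allopolyploid is transient: biased fractionation
  removes the H subgenome block by block and the lineage returns to diploidy.
  Crucially, TEs of the H mobilome that transposed into retained C blocks
  *after* the hybridization survive the loss of the H subgenome -- this jump
  survival is what lets a vanished ancestor remain visible in repeat data.
  The maternal plastome, however, is retained outright.
* **NWB**: the tropical woody lineage hybridizes again with the herbaceous
  lineage (once before the Chusqueinae split, twice more in the
  Arthrostylidiinae+Guaduinae sublineage, whose last fractionation is
  incomplete, leaving it tetraploid). Each round re-injects the contemporary
  herbaceous mobilome.
* **PWB**: hybridizes with the D genome, with fractionation biased in favor
  of C; the D mobilome persists through jump survival.
* **Arundinarieae**: an independent C x D allotetraploid with no herbaceous
  maternal parent -- hence a plastome lineage different from everyone else's.
* An outgroup lineage contributes a plastome only, to root the plastome tree.

The observable consequences, which the pipeline must recover rather than
assume: all Olyreae, NWB and PWB tips share the H plastome while the
Arundinarieae do not (plastid paraphyly of the woody bamboos); repeat content
pairs Olyreae with NWB and Arundinarieae with PWB (four coherent blocks in
the correlation dendrogram); exclusive shared clusters are asymmetric
(Olyreae shares far more with NWB than with Arundinarieae or PWB, and
Arundinarieae shares more with PWB than with NWB).

`null_scenario()` provides the control: four clades diverging vertically
from one ancestor, no hybridization, with lineage-specific repeat families
arising on the deep stems and in the clade ancestors and inherited
vertically. There the plastome tree and the repeat dendrogram agree
(clade-collapsed RF = 0), demonstrating that the discordance produced by
`default_scenario()` is caused by the hybridization events and not by the
pipeline.

## Generator design choices

* **Blocks.** Nuclear genomes are ordered lists of 50 kb blocks tagged with
  their parental origin; fractionation deletes whole blocks of one parent
  independently with probability `f`. Block size is a free parameter; real
  "chromosome segments" have no fixed size, and none of the statistics
  depend on the block length except through the granularity of loss.
* **Substitution model.** I.i.d. site substitution at rate *d* per branch
  (capped at the 0.75 saturation of four equifrequent bases), no indels.
  Plastomes therefore stay positionally aligned along the whole simulation,
  which removes multiple sequence alignment -- out of scope -- from the
  pipeline.
* **Mobilomes.** 30 families per ancestor (40% Gypsy, 25% Copia, 20% DNA
  transposons, 10% simple repeats, 5% other), consensus lengths 300-800 bp,
  log-uniform abundance weights. Ancestor-specific families are derived from
  common templates by 0.30 substitutions/site applied per ancestor; the
  resulting pairwise identity near 0.5 guarantees families from different
  ancestors never co-cluster at the 0.80 threshold. (Reading the 0.30 as a
  pairwise divergence would leave pairwise identity around 0.75, close
  enough to the threshold for local alignments to jump it.) Eight ancient
  families are shared identically by all ancestors and model the clusters
  found in all four clades.
* **Divergence scale.** Within-family copy divergence is 0.05; nuclear
  branch lengths are a few parts per thousand. The repeat families that
  dominate abundance-ranked cluster sets are the recently amplified ones,
  with high within-family identity -- the generator reproduces that regime,
  and it is also the regime in which the >80% transitive clustering is
  meaningful. With long branches the same families fragment into per-clade
  clusters and the comparative analysis degrades, which is a property of
  the method, not a bug of the generator.
* **Insertion sites.** New copies insert at positions keeping at least one
  read length of background between copies. The model deliberately excludes
  nested and abutting TE structure: copies packed side by side create
  recurring junction loci whose straddling reads carry the sequence of two
  families, and under transitive clustering a handful of such reads merge
  otherwise unrelated families. (That chimera-bridging is a real failure
  mode of graph clustering on real data; here it is excluded by
  construction so that family recovery can be scored cleanly.)
* **Amplification bursts.** Each hybridization transfers the donor's
  mobilome by sampling families in proportion to their abundance weights
  (faithful profile transfer). Each extant clade ancestor additionally
  amplifies its own mobilome with a lineage-specific lognormal reweighting
  (`jitter`): lineages demonstrably amplify repeats differentially, and
  without such signatures two clades carrying the same subgenomes (e.g.,
  Arundinarieae and PWB, both C+D) would have statistically
  indistinguishable profiles and could not form separate dendrogram blocks.
* **Scale.** Genomes are ~2-4.5 Mb haploid, standing in ~1000x scaled-down
  for 2-8 Gb bamboo genomes; reads are 150 bp pairs at per-species coverages
  spanning 0.5-5.1x (median near 1.3x). Consensus lengths are scaled down
  with the genomes so that per-family read depth -- the quantity that
  controls whether a family's reads form one connected cluster -- matches
  the regime of the real analysis.
* **Seeds.** One master seed; every node, event, read sample, subsample and
  bootstrap derives its own stream by stable string hashing. Two runs with
  the same (configuration, seed) are byte-identical.

## Clustering

Read clustering follows the family definition: candidate read pairs must
share at least 2 canonical (strand-free) 15-mers; candidates are verified by
local alignment (match +1, mismatch -1, gap -2, both strands), and an edge
requires identity strictly above 0.80 over a span of at least 55% of the
shorter read. Clusters are connected components with at least
`min_cluster_size` reads. The identity definition (matches / alignment
columns, minimum-overlap rule) is configurable because the >80% family rule
is stated in the literature without alignment parameters; the 55% overlap
mirrors the convention of the established graph-clustering tool for
unassembled reads.

Two implementations share these semantics. `build_similarity_graph()` +
`cluster_reads()` materialize the graph and are exact relative to the
prefilter (or fully exhaustive with `prefilter = FALSE`, the oracle mode
used in tests). `cluster_pooled_reads()` streams reads through an
incremental value-sampled k-mer index and a union-find structure, skipping
alignments between reads already connected -- a skipped verification cannot
change a connected-component partition. Buckets are capped (64 reads per
k-mer) and only the strongest candidate per foreign component is verified,
so the streamed partition can only refine the exhaustive one, and at
repeat-family read depths the redundancy of within-family links makes the
refinement trivial; below `exact_below` reads the exhaustive mode runs
instead. The suite checks the refinement guarantee, truth recovery, and
exact brute-force equality on dozens of small random read sets.

The per-species read cap (default 1750) emulates the fixed-total
subsampling of read-clustering tools and bounds desk-scale runtime; it is
applied deterministically from the master seed. The default pipeline's
problem size -- 16 species, ~28,000 pooled reads after capping -- was chosen
so a full run takes a few minutes.

Superfamily classification assigns each read to the library consensus with
the highest shared-k-mer containment (k = 12, floor 0.08) and labels a
cluster by plurality vote, or "unknown" when fewer than half its reads hit
any consensus; this reimplements, as a vote, the role a repeat-library
masking step plays in the original analysis.

## Repartition, correlation, trees

Top clusters are the shortest abundance-ranked prefix reaching the requested
fraction of clustered reads (ties broken by cluster id, so the selection is
deterministic and permutation-stable). A cluster counts as present in a
clade when at least `min_species` of its species have at least `min_reads`
reads (1 and 1 by default; the literature leaves the presence criterion
unstated, so it is exposed and the tests exercise its sensitivity). The
Venn partition reports all 15 non-empty clade subsets, per-clade totals, and
conservation identities that are asserted exactly in the tests.

Correlations are Pearson on log(1 + reads-per-million) abundances (the
transform and linkage behind the published heatmap are unstated; defaults
are Pearson / log1p-normalized / distance 1 - r / average linkage, all
configurable -- the acceptance checks use the grouping structure only, never
heights). The plastome tree is neighbor joining on JC69 distances, with
optional nonparametric bootstrap by column resampling; simulated plastomes
are substitution-only, hence positionally homologous, so distance methods
are sufficient and exactly testable (NJ must recover additive matrices
exactly -- verified on 100 random trees). Bayesian or maximum-likelihood
inference would add nothing to the topological claims made here and is
deliberately out of scope.

Truth recovery is scored with the Adjusted Rand Index between recovered
clusters and truth families over clustered reads that derive from a repeat
family. Background reads carry no family identity: the clustering
legitimately groups co-sampled background loci into small clusters, and
collapsing all background reads into a single reference class would score
that correct behavior as disagreement. The all-reads ARI (background as one
class) is reported alongside in the scorecard as `ari_all`.

## What the simulation does and does not show

The generator emulates: distinct ancestral mobilomes, maternal plastome
inheritance through hybridization, subgenome-biased fractionation with TE
jump survival, differential amplification, species-level divergence, and
uniform low-coverage paired-read sampling. It does not emulate: TE
structural features (LTR pairs, target-site duplications), indels,
recombination, selection, GC/coverage biases, sequencing error, chimeric
inserts, or karyotype structure. Consequently, passing tests demonstrate
that the pipeline's inferences follow from its inputs under the stated
model -- they do not certify performance on real sequencing artifacts, and
thresholds tuned here (e.g., the 0.80 identity rule's interaction with
within-family divergence) should be revisited for data with higher error
rates.

Known limitations: connected-component clustering cannot split chimeric
clusters (an optional modularity pass is a natural extension); the Venn
presence criterion at `min_reads = 1` is sensitive to single stray reads at
very low coverage; the correlation dendrogram is a similarity summary, not
a phylogeny, and its within-clade orderings are data artifacts with no
acceptance meaning; NJ branch supports are resampling frequencies, not
posterior probabilities.
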