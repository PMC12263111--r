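---
title: "Assessing how gene annotation shapes orthology inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing how gene annotation shapes orthology inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoqc)
```

## The problem

Orthologs — genes in different species descending from a common ancestral
gene through a speciation event — are the backbone of comparative
genomics. Orthology is inferred from annotated protein-coding gene
repertoires (proteomes), and those repertoires differ substantially
between annotation pipelines run on the *same* assembly: genes are
missed, split into fragments, or invented, and gene models disagree on
exon structure. `orthoqc` quantifies how much of that annotation
variation propagates into orthology results, using four complementary
views:

1. **Gene-model agreement.** Two gene models of one assembly *agree*
   when at least one transcript of each forms a *complete match*: same
   chromosome and strand, identical intron chains, with the outer
   boundaries of the terminal exons left free (annotations rarely agree
   on UTR extent). Mono-exonic transcripts, whose intron chain is empty,
   must overlap to match, and never match multi-exonic ones. Gene-level
   agreement between annotations $A$ and $B$ is summarised by a Jaccard
   index over the genes involved:
   $J = (|M_A| + |M_B|) / (n_A + n_B)$,
   where $M_A$ are the genes of $A$ with a completely matched transcript
   (one-to-many matches count every gene involved on both sides). The
   exact numerator/denominator convention for this statistic is not
   standardised; this package's choice is symmetric, equals 1 on
   identical annotations, and handles one-to-many matches naturally. The
   comparison is still run in both query/reference directions and the
   two indexes averaged, mirroring how asymmetric tools are used; with
   this package's symmetric matcher the two directions coincide.

2. **Ortholog proportions.** For each proteome, the fraction of
   canonical proteins (one per gene — here, the longest isoform, ties
   broken to the smallest protein id) that appear in at least one
   cross-species ortholog pair. Proteins in no pair are *singletons*;
   an excess of short singletons is the classic signature of fragmented
   or spurious annotation.

3. **HOG quality.** Hierarchical orthologous groups (HOGs) are nested
   sets of homologs descending from one ancestral gene at a given
   taxonomic level; the *rootHOG* is the top-level group. Failures to
   recognise homology split families into extra rootHOGs, so better
   proteomes yield fewer, larger, more complete rootHOGs. The package
   computes rootHOG counts, size distributions, *completeness* (species
   present in the HOG divided by species in the HOG's level clade) and
   exact phyletic-pattern counts (e.g. strict single-copy HOGs, or
   "two copies in a polyploid lineage, absent in the outgroup").

4. **Species-tree discordance.** If orthology calls are correct, a gene
   tree built only from orthologs should match the species tree. The
   benchmark samples seed proteins uniformly; a trial *succeeds* when
   the seed's ortholog set covers at least `min_species` species
   (default 10 of 20) and a gene tree can be built from one
   representative per species. *Recall* is the number of successes;
   *accuracy* is the mean scaled Robinson–Foulds (RF) distance between
   gene trees and the pruned species tree, where the scaled RF divides
   the symmetric difference of non-trivial bipartitions by the total
   bipartition count of both trees, reaching 1 for binary trees sharing
   no split.

Protein-length diagnostics tie these together: per-species median
lengths, two-sample Kolmogorov–Smirnov (KS) distances between length
distributions (the statistic $D$ is used as a distance, not a test),
ortholog-vs-singleton length splits, and Pearson correlations of median
length against ortholog proportion.

## Design choices in the metrics

* **Coordinates** are 0-based half-open internally; conversion to the
  1-based inclusive GFF3 convention happens only at the file boundary.
  This keeps intron arithmetic free of off-by-one cases.
* **Complete-match classification** ignores CDS phase and UTRs: only
  exon structure is compared. Candidate pairing is restricted to
  transcripts on the same chromosome and strand (an interval index for
  mono-exonic models, exact signature grouping for intron chains), a
  pure optimisation verified against all-pairs brute force in the test
  suite.
* **Gene-tree construction** for the discordance benchmark is not
  standardised by the benchmark's users; this package fixes a
  deterministic, dependency-light default — global pairwise alignment
  (BLOSUM62, affine gaps 11/1) p-distances, excluding gap columns, fed
  to neighbor joining with negative branch lengths clamped to zero. A
  trial whose distance matrix is all zeros carries no signal and counts
  as a failure. Mean RF is averaged over successful trials only; failed
  trials affect recall only. A failed seed gene is *not* redrawn: it
  counts as a failed trial.
* **RF scaling** uses the two trees' actual bipartition counts rather
  than the binary maximum $2(n-3)$, so multifurcating (e.g.
  taxonomy-derived) species trees scale correctly.
* **KS distances** are computed between every unordered pair of species
  and averaged; only $D$ is reported, never a p-value.
* **Medians** of even-sized samples are the midpoint of the two central
  order statistics, so integer samples may have half-integral medians.

## The simulator: what it emulates, and what it does not

No ground truth exists for real genomes, so every metric is validated on
simulated data with known answers. The generator:

* evolves `n_families` gene families down a rooted species tree
  (default: 20 species, random topology, edge lengths uniform on
  [0.1, 1] rescaled to depth 1 — the lower bound keeps internal edges
  recoverable from desk-scale sequences). Along each branch every copy
  duplicates at `birth_rate` and dies at `death_rate` (both per unit
  branch length); optional whole-genome duplications double every copy
  at a named clade's stem with a retention probability per extra copy.
  Orthology is *defined* by the family trees: two extant genes are
  orthologs iff their last common ancestor is a speciation node. The
  observed layer adds only annotation-driven failure modes, so
  annotation effects are cleanly separated from inference-algorithm
  effects, which are out of scope.
* draws each family's root protein length from a discretized lognormal
  (median 300 aa, sigma 0.4 — typical of eukaryotic proteomes) and
  substitutes sites independently at `substitution_rate` per site per
  unit branch length. Lengths are preserved (no indels), so any length
  signal downstream comes from the perturbation operators alone.
* synthesises a toy gene model per gene (near-equal exons, one per
  ~150 aa, 200 bp introns, 1 kb intergenic gaps) so the gene-model
  agreement machinery can be exercised end to end through GFF3.
* perturbs the annotation per gene, each gene on its own RNG substream:
  missed with `miss_prob`; fragmented with `frag_prob` into
  `n_fragments` pieces at uniform interior cut points (gene model split
  at the corresponding coding positions); otherwise kept with terminal
  exon boundaries jittered by up to `boundary_jitter` bp (which leaves
  intron chains — and hence complete matches — intact by construction).
  Spurious genes are injected per species at `spurious_rate` per true
  gene with short lognormal lengths (median 120 aa). Because every gene
  draws its uniforms unconditionally from its own substream, raising a
  probability only grows the affected gene set — the levels of a
  perturbation sweep are coupled, which makes monotonicity checks exact
  rather than statistical.
* derives *observed* orthology from the truth plus the ledger: intact
  genes inherit all true pairs; a fragment inherits its parent's pairs
  iff its length is at least `overlap_threshold` (default 0.6) times
  the parent length, emulating aligner overlap criteria; spurious and
  missed genes contribute nothing. Observed rootHOGs follow the same
  logic; fragments failing the threshold lose homology to full-length
  members but still match each other, so per family they form a
  separate, incomplete "split" HOG when they span at least two species
  — reproducing the over-splitting that fragmentation causes in real
  pipelines.

The simulator does **not** emulate indels, codon-level evolution,
rate heterogeneity, horizontal transfer, alternative isoforms, or any
particular orthology inference algorithm. Passing tests therefore show
that the *metrics* behave correctly and directionally on data with
annotation-style noise — not that any specific real-world pipeline will
achieve particular values.

## A worked run

```{r demo, eval = FALSE}
library(orthoqc)

config <- demo_config(seed = 1)      # 12 species, 60 families
report <- run_pipeline(config)
render_report(report, "qc_report")

report$sources$perturbed$proportions   # per-species ortholog proportions
report$sources$perturbed$hog_metrics   # rootHOG count, completeness, ...
report$sources$perturbed$benchmark     # discordance recall + mean RF
```

The same pipeline accepts file-backed sources (FASTA + GFF3 + pairwise
ortholog TSV + OrthoXML/profile TSV per annotation method) through
`run_config()`, and a command-line wrapper
(`system.file("cli/orthoqc.R", package = "orthoqc")`) exposes
`simulate`, `agreement`, `orthoprop`, `hogstats`, `treebench`,
`lengthstats` and `report` subcommands.

## Numerical conventions and degenerate inputs

* All randomness flows from one integer seed through named substreams
  (hashed per family, gene, trial), so results are reproducible
  trial-by-trial and invariant to adding more simulation units.
* An empty annotation yields Jaccard index 0 with a warning; RF needs at
  least four shared leaves; KS and medians reject empty samples;
  correlations reject constant series; a proteome gene with no isoforms
  after filtering is an error.
* Alignments with zero non-gap columns get distance 1 with a warning.
* Benchmark sampling is with replacement, so trial counts may exceed the
  number of available seed proteins.

## Problem sizes used in the validation suite

The test suite validates the oracle equivalences on hundreds of random
fixtures (trees of up to 7 leaves against an independent RF
implementation, KS samples up to n = 200 against the brute-force
supremum, annotations of up to 20 genes against all-pairs matching),
checks neighbor joining on 200 additive matrices of 4–12 leaves, and
runs the simulation-based checks at 20 species with 50–300 families and
150–300 benchmark trials. These sizes were chosen so the full suite
runs comfortably on a laptop while keeping binomial tolerances (3
standard deviations at n = 1000 genes) tight enough to detect real
defects.

## Known limitations

* The gene-model matcher implements only the complete-match class, not
  the full vocabulary of partial-overlap classes used by transcript
  comparison tools.
* The Jaccard denominator convention is this package's documented
  choice; other tools may normalise differently, so absolute values are
  comparable within runs of this package, not across tools.
* Observed-orthology emulation is deliberately simple (length-threshold
  inheritance); it reproduces the direction and rough magnitude of
  annotation effects, not the idiosyncrasies of any specific inference
  algorithm.
* The discordance benchmark's NJ/p-distance gene trees are a stand-in
  for whatever tree-building stack a production benchmark would use;
  the distance function is pluggable at the API level.
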