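---
title: "Methods: assembly curation and polyploid-origin analysis"
author: "PolyploidTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly curation and polyploid-origin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PolyploidTools)
```

PolyploidTools implements the bespoke computational steps of a hexaploid
conifer genome project as reusable, tested functions: genome sizing from a
k-mer spectrum, telomere/centromere-guided scaffold curation, staged
filtering of predicted gene models, orthogroup copy-number classification,
divergence estimators, a gene-tree test of autopolyploid versus
allopolyploid origin, and windowed population-genetic summaries. Every
stage can be exercised on seeded synthetic inputs, so the whole pipeline is
testable without any sequencing data. This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic data do and do not establish.

## Genome size from a k-mer spectrum

For a haploid sample sequenced to depth $c$, the spectrum of 31-mer
multiplicities shows an error component decaying from coverage 1 and a main
peak at $c$. In a hexaploid, k-mers identical across two or three
subgenomes form secondary peaks near $2c$ and $3c$. With $T$ the total
number of k-mer instances at or above an error cutoff, the haploid genome
size is the instance-mass quotient

$$G = T / c.$$

Summing $T$ over the entire spectrum above the cutoff (including the $2c$
and $3c$ peaks) and dividing by the 1x depth counts subgenome-shared
sequence once per copy, which is the quantity a haploid assembly of a
polyploid should be compared against.

Numerical choices:

* **Smoothing.** Valley and peak detection run on a median-of-3 smoothed
  series, the minimal filter that stops a single noisy bin from faking a
  turning point without distorting peak shape.
* **Error cutoff** (`findErrorCutoff`) is the first local minimum of the
  smoothed series scanning up from coverage 1; a plateau valley resolves to
  its first bin. A spectrum that never turns upward yields cutoff 1 with a
  warning.
* **Main peak** (`findMainPeak`) is the smoothed argmax above the cutoff
  with ties broken toward the smaller coverage. Because a Poisson-shaped
  peak holds identical mass at $c-1$ and $c$ (`dpois(c-1, c) == dpois(c, c)`),
  a raw argmax can land one bin short; `estimateGenomeSize`'s automatic
  mode therefore refines the argmax by a count-weighted centroid over a
  $\pm 3\sqrt{c}$ window (capped at $0.4c$ so the $2c$ component stays
  outside). The centroid of a Poisson component is its rate, so this
  recovers $c$ exactly on simulated spectra; without it the $1/c$
  quantisation error (3.3% at $c = 30$) would exceed the 2% recovery
  tolerance the package holds itself to.
* **Subgenome peaks** (`findSubgenomePeaks`) are local maxima inside
  $mc \pm 0.25c$ for $m = 2, 3$, and must reach 0.5% of the main peak's
  height; windows without a genuine maximum report nothing, so absent
  peaks are never invented.

`foldCoverage` expresses a library's depth as
`reads × mean length / genome size`, the arithmetic used to report
per-library coverage against a fixed genome-size estimate.

## Scaffold curation

Chromosome ends carry tandem arrays of the 7-bp telomere unit
`CCCT[A/C]AA`; the orientation of an array (which strand carries the
C-rich motif) says which way the chromosome terminates: `+` arrays mark 5'
ends, `-` arrays 3' ends. Centromeres are dense clusters of a 148-bp
tandem repeat whose consensus ships as a plain-text fixture
(`centromereConsensus()`).

* `scanTelomeres` chains exact motif matches (both degenerate variants,
  both strands) separated by at most three unit lengths, then charges the
  run's budget with the *actual* mismatching bases found in the gaps
  (each in-phase 7-bp frame is compared to the closer variant). Runs of at
  least `min_array_bp = 100` bp with at most `max_mismatch_frac = 0.1`
  mismatch are reported. Counting whole voided copies instead of bases
  would overstate a single substitution seven-fold.
* `scanCentromeres` takes ungapped sliding matches of the consensus at
  `min_identity = 0.8` on both strands and merges overlapping windows into
  maximal hits of at least `min_hit_bp = 100` bp.
* `mergeCentromericHits` single-links hits separated by strictly fewer
  than 250,000 intervening bases — the literal reading of "separated by
  less than 250 Kbp" — and reports each region's envelope and copy count.
  Merging is idempotent and matches a brute-force transitive closure in
  the tests.
* `splitScaffolds` cuts every scaffold holding two centromeric regions.
  Between a region pair: (a) each internal telomere array whose
  orientation faces its nearer centromere marks a chromosome end, and the
  cut falls at the array boundary distal to that centromere, keeping the
  telomere with its arm — a fused two-chromosome scaffold is thus cut
  twice, excising the junction; (b) with no internal telomere, the cut
  falls at the midpoint of the largest N-gap between the regions (the
  likeliest joining error); (c) otherwise the pair is flagged unresolved
  and left uncut. Splitting concatenates back to the input exactly.
* `assemblyStats` reports N50 and, against a fixed genome size, NG50 for
  scaffolds and for contigs (scaffolds cut at runs of
  `contig_gap_min = 10` or more Ns).

The scan thresholds are deliberate package choices: the original analysis
named tools but not thresholds, so the defaults are tuned to make
planted-truth recovery exact on synthetic scaffolds, and all are exposed
as arguments.

## Gene-model filtering

Ab initio prediction over a huge, repeat-rich polyploid genome emits far
more models than genes. The reduction runs in a fixed, reported order —
structural → functional evidence → retroelement → mono-exonic →
overlap resolution — and every stage's removed + retained counts
reconcile with its input.

1. **Structural** (`structuralFilter`): complete ORF (leading M, trailing
   stop, no internal stop), total CDS ≥ 100 bp and a codon multiple,
   every exon and intron ≥ 9 bp.
2. **Functional evidence** (`functionalFilter`): a model is kept iff it
   has *any* of a sequence-similarity hit, at least one protein domain, or
   a gene-family assignment. The source rule lists three evidence kinds
   whose joint absence discards a gene; the alternative parse (a single
   domain alignment is itself insufficient) contradicts the list
   structure and is not implemented.
3. **Retroelement** (`retroelementFilter`): removal requires the
   retro-domain flag *and* a gene span at least 70% softmasked (boundary
   inclusive); either alone keeps the model. The softmask fraction is
   lowercase bases over the gene span, the most direct reading of the
   rule.
4. **Mono-exonic** (`monoexonicFilter`): each mono-exonic protein is
   locally aligned to all multi-exonic proteins
   (`Biostrings::pairwiseAlignment`, identity scoring); a best hit with
   ≥ 75% identity over ≥ 70% of the mono-exonic protein's length marks a
   processed pseudogene and removes the model. Identity is matches over
   aligned columns, coverage is aligned query residues over query length
   — the source defines neither, so both definitions are stated here and
   the opposite reading (keep only supported mono-exonics) is available
   via `remove_matches = FALSE`.
5. **Overlap resolution** (`resolveOverlaps`): where prediction and
   transcriptome-derived models share CDS bases on the same strand, the
   transcriptome model wins — transcriptome evidence is what raised
   annotation completeness in the source project. Transcript alignments
   themselves pass `alignmentEvidenceFilter` (identity and coverage
   ≥ 0.95, inclusive) before becoming models.

## Orthogroup copy-number classes

With diploid relatives represented once per gene, copy counts carry the
ploidy signal. `speciesSpecific`, `absentInSet`, `copyClass` (3:1:1,
2:1:1), and `foldDeviation` implement the class definitions;
`flagTandem` marks families whose focal members lie within 100 kb on one
scaffold (tandem duplicates mimic polyploid copies and are excluded from
the origin test); `phyloCandidates` applies the length rules (every
member strictly > 300 aa and ≥ 75% of the family maximum, read
per-member against the maximum) and draws a seeded deterministic sample.
The expansion baseline is the mean count over non-focal species that
possess the family — the least assumption-laden comparator where the
source states none — and is scale-consistent. `copiaProximity` returns
genes with a repeat insertion overlapping or within 3 kb of the gene
span, anchored on the span rather than the TSS since the source states no
anchor. `clusterProteinsGreedy` provides the optional 70%-identity
duplication-status clustering as a greedy centroid approximation
(identity = matches / shorter length), documented as such.

## Divergence estimators

`kimura2p` excludes columns with a gap or ambiguity in either sequence
(mirroring gap-as-ambiguity treatment), then applies
$K = -\frac12\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$; when the logarithm's
argument is non-positive the pair is reported saturated rather than given
a distance. When transitions occur at the per-type transversion rate
($P/Q = 1/2$) K2P collapses to the Jukes–Cantor distance, which the tests
verify to $10^{-6}$.

`pairwiseDnDs` is the Nei–Gojobori counting estimator: per-codon
synonymous site fractions from the standard code averaged over both
sequences (changes to stop codons count as nonsynonymous, so
$N + S = 3 \times$ codons); observed differences classified along
minimal mutational pathways with multi-hit codons averaged uniformly over
pathway orders and stop-crossing pathways excluded; Jukes–Cantor
correction $d = -\frac34\ln(1 - 4p/3)$. This replaces maximum-likelihood
codon models deliberately: it is transparent, dependency-free and
adequate at the low divergences of interest, but it ignores
transition/transversion bias and codon frequencies and carries a mild
downward bias on $\omega$ at higher divergence because stop-containing
codons are excluded from the comparison while to-stop changes still count
as nonsynonymous sites. The neutrality check in the tests therefore runs
at 1% divergence, where the estimator is within a few percent of 1.

## The polyploid-origin topology test

Autopolyploidy predicts that the focal species' gene copies are each
other's closest relatives in every gene tree; allopolyploidy places some
copies with a donor lineage. `classifyTopology` roots each tree strictly
on the designated outgroup (midpoint rooting silently changes calls and
is refused), tests focal-copy monophyly, and, when monophyletic, names
the sister lineage from the sibling subtree: exactly one candidate
present → that candidate, both or neither → `unclear`. An optional
support threshold (off by default; 70 is the common bootstrap convention
when enabled) downgrades weakly supported calls to `unclear`.
`tallyTopologies` aggregates calls and copy-number breakdowns. The test
operationalises exactly "focal copies form a clade" and makes no further
claim about hybridisation history.

## Windowed diversity and Fst

Per-site diversity is $\pi = 2j(n-j)/(n(n-1))$ with $n$ non-missing
alleles and $j$ alternate alleles. Windows are 1-based inclusive,
anchored at position 1, advanced by the step (defaults 10,000/1,000), and
a window's $\pi$ divides the summed site values by the window length in
bp, so invariant sequence dilutes the estimate as it should; empty
windows inside the covered span report 0.

`wcComponents` implements the Weir–Cockerham (1984) per-site variance
components $a$, $b$, $c$ with observed heterozygosity, unequal sample
sizes and $r$ populations; missing genotypes shrink per-population sample
sizes rather than dropping the site, and a site needs at least two
populations with two genotypes each. Windowed $\theta$ is the
ratio-of-sums $\sum a / \sum(a+b+c)$ (the behaviour of the windowed mode
in standard VCF tooling; a mean-of-ratios switch exists), negative
estimates are reported as computed, and because the source's genome-wide
averages do not state their denominator, both the ratio-of-sums mean and
the mean of per-site ratios are returned.

## Synthetic data: what it emulates and what it does not

All generators fan one integer seed into fixed per-generator substreams,
so identical (seed, configuration) gives identical bytes and one stage
can be regenerated without disturbing the others.

* `simScaffolds` plants telomere arrays, fragmented centromeric clusters,
  mid-arm N-gaps and optional fused scaffolds (two centromeres with
  internal, outward-facing telomeres separated by junk sequence — or an
  N-gap junction instead). Default arm length is 150 kb so that the two
  centromeric regions of a fused scaffold sit farther apart than the
  250 kb merge distance, as real chromosome arms trivially are.
* `simHistogram` emits geometric error mass plus Poisson-shaped peaks at
  $c, 2c, 3c$ with areas $f_1 G, f_2 G/2, f_3 G/3$ (shares default
  0.6/0.25/0.15), Poisson sampling noise, and an overdispersion knob.
* `simGeneModels` plants valid genes, structurally broken genes (8-bp
  intron, 99-bp CDS, missing stop), softmasked retro-flagged genes, and
  mono-exonic pseudogene copies at a configured protein identity
  (default 0.8, full coverage). Nucleotide and protein content are not
  mutually consistent (proteins are not translations of the planted
  CDS); the filters consume coordinates, proteins and flags, so this
  does not affect what the tests establish.
* `simOrthogroups` plants disjoint copy-number classes with counts chosen
  so each classifier recovers exactly its planted set; tandem families
  place two focal members 50 kb apart.
* `simGeneTrees` builds scenario topologies directly (auto: focal clade;
  allo: one copy inside the donor lineage) with optional
  nearest-neighbour-interchange noise via `phangorn::rNNI` — topology
  noise, not branch-length noise, because topology is what the classifier
  consumes.
* `simVariants` draws Balding–Nichols genotypes: ancestral frequency
  uniform on (0.05, 0.95), population frequencies
  Beta$(p(1-F)/F, (1-p)(1-F)/F)$, binomial diploids. Defaults (2
  populations × 30 diploids, 20,000 loci, $F = 0.05$) are the scale at
  which the Weir–Cockerham estimator recovers $F$ within ±0.01.

Passing on these inputs establishes that the *rules* are implemented
faithfully — recovery of planted truth, exact arithmetic on printed
values, agreement with independent transcriptions of published formulas.
It does not establish robustness to real-data phenomena the generators do
not model: sequencing error in reads, repeat families resembling but not
matching the consensus, fragmented or chimeric gene models beyond the
planted classes, gene flow or selection in the population model, or
alignment error in gene trees.

## Study-condition counts that are data-bound

Several figures of the original study (15 split locations, 33 empirical
centromeric regions, per-assembly N50 tables, the 135/78/26 topology
tally, genome-wide $\pi$ and Fst values) depend on the deposited data and
are not desk-reproducible; the package reproduces the *rules* that
generated them and checks those rules on planted truth instead. The
desk-reproducible arithmetic (coverage folds, $T/c$, the 148-bp unit, the
33-region merge construction, the LTR span ratio) is asserted exactly in
the test suite.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data at reduced scale, chosen to
exercise every rule while keeping a full run around a minute: scaffolds
of ~0.3–0.6 Mb (three per seed) for sequence-level scans, hit-level
layouts for the 100-seed merge-count property, spectra to $3.6c$ bins
over $G \in \{10^6, 10^7\}$, 20-seed orthogroup recovery, 200 noise-free
gene trees, 10,000 neutral codons, and 20,000 Balding–Nichols loci for
the Fst recovery check.

## Coordinate conventions

Internally everything is 1-based closed via `IRanges`/`GenomicRanges`,
the native convention of the Bioconductor containers the package is
built on; GFF3 and VCF already use it, and BED's 0-based half-open
coordinates are converted at the boundary by `rtracklayer`. All
conversions are involutions and round-trip exactly in the tests.
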