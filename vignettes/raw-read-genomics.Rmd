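---
title: "Characterising repeat-rich genomes from raw reads: methods and design"
author: "bactrokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising repeat-rich genomes from raw reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactrokit)
```

# The problem

Draft assemblies of repeat-rich insect genomes systematically collapse or
drop the sequences that matter most for questions about genome evolution:
satellite DNA arrays, dispersed transposon families, and the ribosomal
repeat unit. This package implements a family of analyses that work
*directly on raw short reads* (nominally 100 bp, paired), using an assembly
only where one is genuinely needed, so that repeat content, genome size and
early inter-species divergence can be quantified even when the assembly
cannot represent them. The motivating system is a trio of very closely
related tephritid fruit flies (*Bactrocera tryoni* and its siblings), but
nothing in the machinery is species-specific.

Every analysis is exercised end-to-end on synthetic data with exact planted
truth, generated by the package itself.

# The synthetic-data generator

`genomeSpec()` / `buildGenome()` construct a genome from three feature
classes placed in random order over random unique background:

* **Satellite arrays** — a monomer (100–300 bp; the default 166 bp matches
  the alphoid-typical range) repeated head-to-tail. The truth records the
  array coordinates and the monomer.
* **Transposon copies** — a ~1.5 kb canonical element; a configurable
  fraction of copies is fragmented into 2–3 ordered pieces with short
  random spacers, emulating the decayed copies that dominate real genomes.
* **Gene models** — 5' UTR, 2–3 phased CDS exons with introns, 3' UTR, on
  either strand, with start/stop codons and no internal stops. These drive
  the region-partitioned substitution analysis and the transcript-coverage
  genome-size estimator.

`siblingSpec()` / `deriveSibling()` derive a sibling-species genome by
applying per-region substitution rates, planted deletions (> 10 bp) and
per-transposon insert-size jitter, recording every edit. The default rates
(exon 0.003, intron 0.006, 5' UTR 0.0036, 3' UTR 0.0026, non-coding 0.007)
mirror the published divergence pattern between the closest sibling pair:
a few changes per kilobase, lowest in coding sequence.

`simulateReads()` draws uniform start positions, samples each read's strand
with probability 1/2, and applies i.i.d. substitution errors. Qualities are
constant placeholders: no stage of the method is quality-aware. Paired mode
draws ~300 bp fragments (SD 30) and reports both ends.

Three generator policies deserve explanation, because they define what the
recovery tests do and do not demonstrate:

* **Deletions are planted at micro-homology-free junctions.** If the base
  flanking a deletion equals the base at the corresponding position across
  the junction, the deletion's coordinate is not identifiable — any aligner
  may shift the gap — so exact-coordinate truth would be ill-posed.
* **Deletions keep substitution-free ±12 bp surroundings.** A fixed
  substitution immediately adjacent to a junction sits near the end of
  every read that crosses it and degrades flank coverage *by construction*;
  real data contains such junctions, and the flank filter rightly discards
  them (see below), but a recall benchmark should not be dominated by them.
* **Deletion fixtures are uniquely mappable.** Zero-coverage calling under
  a mapping-quality filter cannot distinguish a deletion from the interior
  of a multi-copy repeat (both have no confidently-placed reads); the
  package's `findDeletions()` therefore accepts an optional raw-coverage
  track to mask such mappability artifacts, and the recall/precision
  benchmarks run on repeat-free sequence.

The generator emulates uniform coverage, substitution-only errors and fully
homozygous genomes. It does not model indel sequencing errors, GC bias,
quality gradients or within-individual polymorphism; passing recovery tests
therefore demonstrate correctness of the algorithms under the stated
statistical structure, not robustness to every artifact of real sequencing.

# The internal read mapper

A deliberately small seed-and-extend mapper
(`mapReads()`) stands in for an external aligner so that the whole pipeline
is self-contained; SAM import (`readSam()`) lets an external mapper replace
it, since every downstream stage depends only on the alignment/pileup
contract.

* Exact 19 bp seeds anchor candidate diagonals; candidates are evaluated
  ungapped, and re-aligned with a banded affine dynamic program (match +1,
  mismatch −1, gap open −3, gap extend −1) when the ungapped fit is poor,
  so reads spanning a reference deletion receive a deletion operation.
* Read ends may be soft-clipped (flat penalty), and each alignment must
  terminate in 10 consecutive matches; otherwise the end is trimmed into
  the clip. Without this, the overhang of a junction-spanning read aligns
  as a mismatch tail *into* the deleted interval and destroys the
  zero-coverage signal.
* Mapping quality expresses placement uniqueness: 60 for a unique best
  placement, 0 for an exact score tie, `3 × (best − second)` otherwise.
  Alternative placements within one gap window of the best describe the
  same locus (e.g. the clipped half versus the gapped path of one junction
  read) and do not count against uniqueness. The published thresholds
  (q > 20 general, q < 30 initial exclusion, q = 55 unique-mapping) are all
  kept as configuration, though under this coarse quality model they mostly
  coincide.

`pileupFromAlignments()` accumulates per-site base counts from alignments
passing the quality floor; a deletion operation contributes no base at the
deleted sites, so their depth excludes the read — the property the deletion
caller depends on.

# k-mer machinery

`countKmers()` counts exact k-mers (2-bit packed, k ≤ 31), skipping windows
with non-ACGT characters. The strand policy matters and differs by use:

* `"canonical"` (k-mer merged with its reverse complement) for genome-size
  and abundance estimation, because reads are unstranded;
* `"as-read"` for the extension walk and the satellite spacing statistic,
  which are strand-directional: canonical merging would corrupt overlaps.

**Genome size, method 1.** `kmerHistogram()` + `genomeSizeFromHistogram()`:
size = total k-mer instances / main-peak multiplicity. The trough between
the error spike and the main peak is found on a window-3 median-smoothed
spectrum; the peak is the raw-count argmax beyond the trough (smoothing
flattens sharp modes and would bias the peak left). Error k-mers inflate
the total, so the estimator runs high at realistic error rates — a known
property of the method, which is why the second estimator exists.

**Genome size, method 2.** `coverageFilterCascade()` +
`estimateGenomeSize()` implement the single-copy transcript-coverage
estimator with the full filter cascade: initial mapping with low-quality
placements excluded, removal of the low (< 10×, truncated or erroneous
models) and high (> 60×, repeat-dominated) coverage bands, the median 50%
by coverage rank, removal of segments with ≥ 5 consecutive Ns or annotation
quality score > 0.2 (the score is an input column; computing it is out of
scope), and a final unique-mapping (q = 55) re-estimate using per-segment
*median* coverage excluding the 100 bp flanks. The peak of the per-segment
median distribution is the mode of a bin-width-1 histogram reported at the
bin centre — hence half-integer peaks — and genome size is total bases /
peak. Adjacent tied bins average; non-adjacent ties raise an error listing
the candidates. The band cut is applied before the rank filter; at 35×
with 0.5% errors the estimator recovers a 2 Mbp synthetic genome within 5%.

# Repeat discovery

**Greedy k-mer extension** (`kmerExtend()`): starting from the most
abundant 18-mer, repeatedly append the final base of the highest-count
18-mer whose 17-mer prefix matches the current suffix; then extend
leftwards symmetrically; a direction stops when no overlapping k-mer exists
or the chosen k-mer was already used. No k-mer is used twice; seeds already
consumed are skipped but count toward the 50,000-seed cap; products longer
than k + 50 bp are kept. Ties break lexicographically, making the output
deterministic. A tandem monomer of length L shows up as a walk of length
L + k − 1 that stops on re-meeting its own starting k-mer; monomers are
compared up to rotation (`minimalRotation()`, `rotationIdentity()`) since a
circular product's phase is arbitrary.

**Align-and-extend** (`alignAndExtend()`): find all assembly matches of
the working consensus at ≥ 80% identity covering most of its length,
extract each matched segment with up to 200 bp of flank, stack the segments
in consensus coordinates, and extend outward column-by-column wherever
≥ 60% of at least 3 covering segments agree; iterate to convergence.
Segments are stacked positionally rather than multiple-aligned: at the
scale this package runs, flanks are indel-free, making column stacking
exact; strongly diverged flanks simply fail the 60% consensus and stop the
extension, which is the intended behaviour.

**Finalization** (`finalizeConsensus()`): map the raw reads back to the
library, install the majority base at every covered position, cull entries
sharing > 80% identity with a longer entry, and report the mapped-read
fraction (q > 20) and mean mismatch count (NM) — the library's support
statistics. Statistics are computed against the *culled* library: duplicate
entries would otherwise tie their own reads at q = 0.

**Species-specific libraries** (`speciesSpecificVariants()`): sibling reads
are mapped to the reference library and every site where the sibling
majority allele differs at a frequency strictly above 50% is substituted
(1 bp deletions likewise; insertion evidence is flagged but not
incorporated, as the pileup stores insertion counts, not sequence).
Zero-coverage entries are left unchanged and flagged.

# Satellite arrangement and abundance

For a read of length R uniformly placed on a long head-to-tail array, a
read containing one 12-mer also contains a second at signed offset d with
probability (R − 12 − |d| + 1)/(R − 12 + 1) (`expectedCooccurrence()`);
for adjacent tiling 12-mers on 100 bp reads this is 77/89 ≈ 0.87. Because
every tiling k-mer recurs with period L, a k-mer at monomer position p can
co-occur with the anchor at offset p (same copy) *and* p − L (adjacent
copy); enumerating both representatives within |d| ≤ R − k
(`expectedOffsets()`) gives 13 offsets for the 166 bp monomer — the
negative ones are junction-spanning and exist only in tandem context,
which is what makes the statistic diagnostic.

`arrangementProfile()` scans reads for the anchor (≤ 1 substitution,
either strand), accumulates the offsets and orientations of all other
tiling k-mers in anchor-forward frame, and classifies: head-to-tail tandem
when ≥ 90% of co-occurrences sit on expected offsets in consistent
orientation *and* the junction offsets are populated near their analytic
expectation; head-to-head when orientation-flipped co-occurrences are
frequent; dispersed otherwise.

`estimateAbundance()` converts mean tiling-18-mer counts into genomic copy
number by dividing by the per-k-mer depth, depth × (R − 18 + 1)/R — the
coverage adjustment made explicit. The variable-element count additionally
sums each tiling k-mer's edit-distance-≤ 1 neighbourhood (substitutions
plus internal single-base insertions/deletions, deduplicated). Boundary and
homopolymer-edge indel neighbours are excluded: they reproduce the adjacent
one-base-shifted window of the same array and are not identifiable as
variants (including them triples the estimate on a pure array). Total
genomic span is monomer length × variable count.

# Inter-species divergence

`callFixedDifferences()` calls a site as a fixed (near-homozygous)
difference when depth ≥ 10 and the leading non-reference allele reaches
90% of the depth (the tool the study used reports homozygous calls around
this region; the threshold is configurable). Deletion runs of 1–2 bp and
short insertion evidence passing the same gates become indel calls.

`partitionByRegion()` classifies every callable site (depth ≥ 10) as exon
(CDS), 5'/3' UTR, intron or non-coding — precedence exon > UTR > intron —
and reports per-class rates with callable-site denominators, which makes
them reproducible. Within CDS, *all* fixed differences in a codon are
applied jointly before translation (`classifyCodingEffect()`): `stop_gain`
requires the jointly mutated codon to be a stop, and `stop_compensated`
marks codons where one substitution alone would have created a stop but a
second in the same codon negates it. 1–2 bp indels in CDS count as
non-synonymous. Both the raw per-callable-site dN and dS and the
opportunity-normalized ratio (Nei–Gojobori-style site counting) are
reported, because the two conventions differ by a factor of ~3 and the
literature quotes both; on neutral simulations the normalized ratio is ~1.

`rrnaVariantProfile()` reports, for a deep pileup over a multicopy
consensus (the rRNA transcribed unit being the canonical case), the
per-site fraction of mapped bases differing from the consensus, windowed
means, and region labels (18S/ITS1/5.8S/2S/ITS2/28S/ETS/IGS) from an input
annotation; `simulateRrnaPool()` generates matching test pools whose
divergent copies vary only in the spacers, as higher-frequency variants do
in real arrays.

# Structural divergence

**Deletions** (`findDeletions()`): maximal zero-coverage runs longer than
10 bp whose ten bordering bases on *both* sides all exceed 20× — minimum,
not mean: the strictest reading of requiring high coverage for all
bordering bases. Runs at scaffold edges are rejected and counted. Two
optional robustness filters extend the basic contract: the raw-coverage
ambiguity mask described above, and a noise floor (default 2) under which
isolated covered bases inside a run are treated as uncovered — a read whose
junction-adjacent sequencing error coincidentally matches the deleted base
aligns one base into a real deletion, and such one-off placements should
not veto the run. Deletions shorter than 11 bp are out of scope by
construction: short gaps are routinely absorbed into gapped alignments.

The flank filter is deliberately unforgiving, and at junction-adjacent
bases primary-only alignment yields about *half* the genome-wide depth
(each junction read is placed on its majority side only). The recall
benchmarks therefore run at 90× — the coverage regime the method was
designed for — where the filter passes essentially all clean junctions;
at 40–60× it rejects a large fraction, which mirrors the heavy candidate
attrition the approach shows on real data.

**Repeat association** (`repeatAssociationTest()`): are deletions
preferentially adjacent to repeats? Repeat-library occurrences are located
once on the assembly (internal matcher, ≥ 80% identity over ≥ 80 bp), and a
1000 bp deletion flank "contains a repeat" when it overlaps an occurrence
by ≥ 80 bp — equivalent to per-flank-sequence alignment, since flanks are
assembly substrings. The null re-draws each deletion's position
independently and uniformly (its two flanks still separated by that
deletion's length), 1000 times, with overlaps allowed; p is one-sided with
add-one correction. The alternative null of shifting the whole deletion
constellation rigidly degenerates whenever the calls span the scaffold
(the admissible offset range collapses), so the independent-placement
reading is used.

**Transposon spans** (`mergeElements()`, `compareSpans()`): fragments of
the canonical element within 1.5 kb merge transitively into composite
elements; merged extents of twice the canonical length or more split at
their largest internal gap. The 1000 bp flanks bordering each element are
located in the sibling contigs (requiring a unique placement — a flank
inside a multi-copy element cannot be located — and both flanks on one
contig in consistent orientation); the distance between the homologous
inner flank edges gives the sibling span, and |sibling − reference| the
insert-size change. An equal number of random control pairs with matched
insert sizes is measured identically, and the two sets of absolute changes
are compared with a two-tailed Welch t-test (variances are expected to
differ). Planted ±50 bp jitter is detected at p < 0.01 on the default
fixture; a jitter-free sibling is null.

# Configuration and the pipeline driver

`defaultConfig()` names every threshold used anywhere in the package, with
the values above as defaults; `readConfig()`/`writeConfig()` round-trip
YAML and reject unknown keys. `runPipeline()` chains
simulate → k-mers → repeat discovery → satellite statistics → both
genome-size estimators → fixed differences by region → deletions (+
association) → spans, fanning a single global seed out to per-stage seeds
at fixed offsets so a fixed seed reproduces the report byte-for-byte. The
default configuration uses a 300 kb genome at 40×, sized so the full run
takes well under a minute; at that depth the deletion stage flank-rejects a
substantial fraction of its candidates, as discussed above, and the report
records those counts.

# Problem sizes used by the test suite

Recovery tests run on: a 2 Mbp gene-bearing genome at 35× (0.5% error) for
genome size; a ~115 kb genome with a 250-copy satellite array and 12
transposon copies at 30× (error-free) for repeat discovery; a 300 kb
gene-only genome at 90× (0.2% error, paired) for substitution-rate and
deletion recovery; and a 300 kb genome with 14 transposon copies for the
span comparison. Analytic quantities (co-occurrence probability, offset
enumeration, size and span arithmetic) are cross-checked against
brute-force enumeration, and the core operations (k-mer counting, zero-run
scanning, joint-codon classification over all 64 × 64 pairs, pileup depth)
against independent brute-force implementations.

# Known limitations

* The mapper is desk-scale: a hash seed index with per-seed occurrence
  caps, no split/supplementary alignments, no base-quality awareness.
* Zero-coverage deletion calling requires uniquely mappable flanks; inside
  repeat arrays it reports mapping ambiguity, not deletions (masked when a
  raw-coverage track is supplied).
* Satellite abundance cannot distinguish a boundary indel variant from the
  adjacent array window; such variants are invisible to the k-mer
  neighbourhood by construction.
* Repeat classification by homology to curated libraries is out of scope;
  discovered consensus sequences are labelled "unclassified" unless the
  caller supplies labels.
* The two genome-size estimators are both reported and deliberately not
  reconciled; on real data they are known to disagree, with the k-mer
  estimator biased upward by error k-mers and heterozygosity.
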