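---
title: "ORF-centric classification of long-read direct RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ORF-centric classification of long-read direct RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotx)
```

## The problem

Nanopore direct RNA sequencing (dRNA-seq) reads native polyadenylated mRNA
molecules in full, 3' to 5', without reverse transcription or amplification.
On a compact, gene-dense genome — the motivating case is a nuclear DNA virus
where ten-odd promoters, a handful of polyadenylation sites and dozens of
splice donors/acceptors combine into thousands of distinct mRNAs — each read
is a complete record of one transcript: its promoter, its exact exon chain,
and its termination site. The analytical difficulty is that the read ends
are systematically imprecise, while the splice junctions are (after
error correction and spliced alignment) essentially exact. nanotx therefore
treats the three signals differently:

* **5' ends** under-read the true transcription start site (TSS) by roughly
  8–15 nt, reproducibly per promoter. Ends are clustered within a window,
  and coding-potential analysis compensates with a 5' extension.
* **3' ends** are imprecise in the opposite way: alignments are almost
  always soft-clipped at the polyadenylation site (TTS), with larger clips
  than at the 5' end. Ends are again clustered within a window, and only
  reads with an independently confirmed polyA tail (QC `PASS`, ≥ 20 nt) are
  used for tail-length analysis.
* **Splice junctions** are taken verbatim: two chains that differ by a
  single nucleotide at any donor or acceptor are different transcripts.

## The classification model

**End clustering.** Observed 5' (or 3') end positions are tallied per strand
and clustered greedily: the most frequently observed position seeds a
cluster and absorbs every position within ±`window` nt (default 15 for both
ends, independently configurable); the most abundant *remaining* position
seeds the next cluster, until all positions are assigned. Count ties seed on
the smaller genomic coordinate, which makes the procedure deterministic and
invariant to input order. A consequence worth noting: any two cluster
representatives on one strand are necessarily more than `window` nt apart.
Clustering is computed on the pooled multi-sample tally so group identities
are stable across time points (a per-sample mode exists for exploration).

**Transcript groups.** Every read is assigned the key
(strand, TSS-cluster representative, exact ordered junction chain,
TTS-cluster representative). One group per distinct key; per-sample read
counts and polyA summaries (mean, n−1 standard deviation, n over usable
reads) are attached. Because published counts of "splice patterns" sometimes
collapse end variation, `rollup_splice_chains()` also reports the coarser
strand + junction-chain granularity.

**Pseudo-transcripts and the 5'-most-ORF rule.** Each group's consensus
exon model (cluster representatives at the ends, verbatim junctions inside)
is spliced out of the genome, reverse-complemented for minus-strand groups,
and extended by `extension` genomic bases upstream of the TSS
representative (default 10 nt). The extension is the crux: because dRNA-seq
under-reads 5' ends by ~8–15 nt, a start codon lying within that distance
of the true TSS is invisible at extension 0 and the transcript would be
mis-assigned to the next AUG downstream. Scanning then proceeds over every
AUG in the extended sequence; each opens a candidate ORF read to the first
in-frame stop (UAA/UAG/UGA) or, failing that, to the transcript end
(retained but flagged `incomplete`). Candidates shorter than `min_aa`
residues (default 10) are dropped unless their start codon coincides with a
canonical feature, so very short canonical peptides stay representable
while random micro-ORFs do not inflate the rank list.

Canonical identity is positional: an ORF matches a feature iff its
start-codon genomic position and strand equal the feature's. This
deliberately ignores the downstream exon structure, which is what lets
N-terminally identical fusion transcripts share a name while their genomic
footprints (recorded per ORF call) still distinguish them. If the feature
table supplies an expected protein length and the called ORF is shorter —
typically because a splice removed coding sequence — the match is kept and
flagged `truncated`; how much truncation still "counts" is left to the
user, since any fixed cutoff would be arbitrary.

The group is named by its rank-1 (5'-most) ORF if canonical; otherwise
ranks 2, 3, … are scanned and the first canonical hit is taken with the
`second_methionine` flag, reflecting leaky-scanning translation of a
downstream AUG. Groups with no canonical AUG anywhere are `no_known_orf`.
Per feature, the highest-count group whose *rank-1* ORF is that feature is
the "dominant transcript" (ties to the smaller TSS representative); usage
tables report, per sample, the percentage of reads whose rank-1 ORF is each
feature, plus a no-known-ORF row — the columns intentionally do not sum to
100 because second-Methionine reads belong to neither.

**polyA dynamics.** Tail lengths come from an external per-read estimator
(nanopolish-polyA-style TSV); only `PASS`-tagged reads with ≥ `min_polya`
nt (default 20) enter summaries. Per transcript class (group, or feature
via the annotation), per-sample means are compared across consecutive time
points with the Wilcoxon signed-rank test — each class contributes one
paired data point — and, as a companion, the Mann–Whitney U test on the
same means treated as unpaired. Both are two-sided; no multiple-testing
correction is applied. The paired test is the primary instrument because
the classes are the experimental units followed over time. A read-level
unpaired mode exists but is not the default, since pooling reads would let
a few huge classes dominate.

**Junction validation.** An independent short-read junction set (TSV or
BED12) acts as an untargeted splicing survey. A spliced read is
*concordant* iff every one of its junctions appears in the set
(exact coordinates and strand; an optional ±k fuzz exists for exploration
but defaults to 0). Unspliced reads carry no junctions, so the statement is
vacuous for them: they are tallied separately and excluded from the
concordance denominator, though the all-reads fraction is also reported.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `tss_window`, `tts_window` | 15 | nt | end-position scatter of dRNA-seq; both ends use the same default but are set independently because nothing forces them equal |
| `extension` | 10 | nt | recovers start codons hidden by the 8–15 nt 5' under-read without reaching past most promoters |
| `min_aa` | 10 | residues | drops random micro-ORFs; canonical starts override it |
| `min_polya` | 20 | nt | distinguishes genuine polyadenylation from fragment 3' ends |
| `min_mapq` | 0 | — | primary alignments only; no quality filter by default |
| `require_polya_for_grouping` | FALSE | — | whether the PASS/≥20 filter gates *grouping* too, or only end/tail analyses; left configurable because either reading is defensible |

## Statistical implementation notes

The signed-rank and U statistics are computed through `stats::wilcox.test`
with the exact/approximate regime controlled explicitly: exact null
distributions for ≤ 25 informative pairs (signed-rank) or n+m ≤ 12 (U)
when the data are tie-free, otherwise the normal approximation with tie
correction and continuity correction. Zero paired differences are dropped
and their count reported; all-zero pairings are refused as degenerate, as
are fewer than 5 informative pairs. The test suite checks both statistics
against brute-force enumeration (all 2^n sign assignments; all C(n+m, n)
group assignments) on randomized inputs, so the exact-regime behaviour is
pinned independently of the library.

## The synthetic transcriptome

`make_genome()` builds a 20 kb double-stranded "virus" with six
transcription units and 15 isoforms across both strands: a three-isoform
early-like unit whose alternative transcripts include a splice into the
coding sequence (a designed `truncated` case), a unit with a decoy upstream
ORF (a designed `second_methionine` case), a major-late-like unit in which
five coding exons and an exon-skipping variant share a two-exon leader, an
ORF deliberately missing from the feature table (`no_known_orf`), and
spliced plus unspliced minus-strand units. All introns are GT/AG on the
coding strand.

Two construction details matter for interpreting test results:

* **Non-coding fill is drawn from a {C, A} alphabet** (coding-strand
  sense). Since AUG needs a T/U, no spurious start codon can arise in a
  5'UTR, in the promoter-upstream window that the 5' extension reaches
  into, or across a splice boundary. Designed ORFs are then written on
  top. This makes the intended rank-1 ORF of every isoform a construction
  invariant — which `make_genome()` re-verifies at build time, aborting on
  infeasible geometry — at the cost of unrealistic base composition in
  non-coding DNA.
* **The rescue-sensitive units have 5 nt 5'UTRs.** With the under-read
  uniform on 8–15 nt and a 10 nt extension, a start codon 5 nt into the
  transcript is recovered for *every* possible end-cluster representative
  (15 = 10 + 5), so the extension experiment measures the mechanism rather
  than the luck of the modal truncation draw.

The noise model reproduces the qualitative signatures of real dRNA-seq
alignments: uniform 8–15 nt 5' truncation; with probability
`fragmentation_rate` (default 0.05) a uniformly placed internal 5' end
standing in for RNA breakage; ±5 nt TTS jitter; soft clips with a small 5'
mode (1–2 nt) and a larger 3' mode; per-read lognormal polyA lengths
(sdlog 0.4, matching a standard deviation around 40–50 at means near 100)
whose class means decline by a per-sample factor (default 0.8, i.e. 20%)
across time points; a PASS rate of 0.6; and a short-read junction set from
which each true junction drops out independently with probability 0.05.
Per-sample isoform weights shift from early- toward late-unit transcripts
across the three simulated time points. Reads are emitted as mapped SAM
records — the pipeline's contract begins at spliced alignments, so no
base-error or signal-level simulation is attempted.

What the simulator does *not* emulate, and what passing tests therefore do
not show: residual base-calling/alignment error at exon boundaries
(junction wobble), reference-sample sequence divergence, host-transcript
contamination, expression-dependent coverage bias along transcripts, and
non-AUG initiation. Results on real data depend on upstream error
correction and spliced alignment quality in ways the synthetic data cannot
probe.

## Numerical and edge-case conventions

* Coordinates are 1-based inclusive genome positions everywhere internally
  (GFF3 convention); BED is converted on read and write.
* Reverse-strand reads assign the CIGAR-leading soft clip to the transcript
  3' end, per dRNA-seq chemistry; deletions of any size stay intra-exon and
  only `N` opens an intron.
* Tie-breaks: cluster seeding → smaller coordinate; nearest-cluster
  assignment of an untallied end → earlier-seeded cluster; dominant
  transcript → smaller TSS representative; soft-clip and read-length modes
  → smaller value.
* An end position outside every cluster window becomes its own singleton
  cluster rather than being discarded.
* 5' extensions are clipped at the genome boundary and the achieved length
  recorded; junction dinucleotides at the genome edge are reported partial
  with a warning.
* With noisy ends a cluster representative can occasionally fall on the
  wrong side of a group's outermost splice site, leaving a negative-length
  terminal exon in the consensus model. Such groups are real read classes
  but have no valid consensus sequence: they annotate as `no known ORF`
  with zero ORF calls and are omitted from GFF output (with a message).
* The junction-dropout concordance check deserves a note: dropout removes a
  junction from the *set*, so all reads sharing it succeed or fail
  together and read-level outcomes within one draw are correlated. The
  analytic expectation 1−(1−d)^k for k-junction transcripts is therefore
  tested over repeated independent junction-set draws, scoring one verdict
  per draw for each of two junction-disjoint 2-junction isoforms (one per
  strand), which yields genuinely independent Bernoulli trials.

## Problem sizes used by the test suite

The bundled checks run at deliberately modest scale so the whole suite
completes in about a minute of CPU: exact end-to-end recovery uses three
samples of 5,000 noise-free reads over the 15-isoform genome; the
extension-rescue comparison uses one sample of 3,000 reads with 8–15 nt
truncation; the polyA trend detection uses three samples of 10,000 reads
(the smallest of the 15 classes then holds enough PASS reads for its mean
to be stable); clustering is verified against a brute-force replay on
1,000 random tallies; the exact tests against enumeration on hundreds of
random vectors; the dropout expectation over 400 junction-set draws. These
sizes are choices of the package's own test design, not statements about
the scale the pipeline handles — grouping is linear in reads and the same
code processes hundreds of thousands of alignments comfortably.

## Known limitations

* Canonical matching is AUG-positional only; non-AUG initiation and
  internal ribosome entry are out of scope.
* Junction matching has no tolerance by default; aligner wobble around
  splice sites on noisy real data will show up as novel junctions rather
  than being absorbed.
* The pipeline quantifies transcripts, not translation: a
  `second_methionine` call says a downstream canonical AUG exists, not
  that it is used.
* Clustering windows are fixed, not adaptive; promoters closer than the
  window to each other would merge.
* polyA statistics treat per-read estimates as given; estimator bias is
  inherited, not modelled.
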