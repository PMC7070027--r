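# nanotx pipeline configuration (flat key-value YAML).
# Any key can be overridden on the CLI, e.g. `nanotx all --config this.yaml
# --extension 10`.

# --- inputs ---------------------------------------------------------------
genome: genome.fasta            # reference the long reads were mapped to
features: features.tsv          # name / strand / start_codon_pos / cds_end /
                                # expected_aa (canonical ORF table)
known_sites: known_sites.tsv    # optional: name / position / strand, for the
                                # TSS/TTS offset report
junctions: illumina_junctions.tsv  # short-read junction set (TSV or BED12)

alignments:                     # sample -> spliced SAM/BAM (primary records)
  t16h: t16h.sam
  t24h: t24h.sam
  t48h: t48h.sam
polya:                          # sample -> nanopolish-polyA-style TSV with
  t16h: t16h_polya.tsv          # columns readname / qc_tag / polya_length
  t24h: t24h_polya.tsv
  t48h: t48h_polya.tsv
sample_order: [t16h, t24h, t48h]

# --- parameters -----------------------------------------------------------
tss_window: 15        # nt half-width for clustering transcript 5' ends
tts_window: 15        # nt half-width for clustering polyadenylation sites
extension: 10         # nt prepended 5' of each pseudo-transcript before ORF
                      # scanning (compensates for nanopore 5' under-read)
min_aa: 10            # minimum non-canonical ORF length, residues
min_polya: 20         # minimum usable polyA tail length, nt (PASS reads only)
min_mapq: 0
min_support: 1        # short-read junction support floor
require_polya_for_grouping: false
seed: 1
outdir: nanotx_out

# --- upstream preprocessing (documentation only; nanotx never runs these) --
# The pipeline consumes spliced alignments and per-read polyA estimates.
# A typical upstream for direct RNA-seq of a virus-infected host:
#   lordec-correct -T 4 -k 19 -s 3 -a 10000 -2 illumina_reads.fastq \
#       -i nanopore_reads.fastq -o corrected_K19.fasta
#   # iterate with increasing k-mers: K19, K19, K31, K31, K41, K41, K51, K51
#   minimap2 -ax splice -uf -k14 --sam-hit-only genome.fasta \
#       corrected_reads.fasta > mapped.sam
#   nanopolish polya ...   # produces the per-read polyA TSV
#   hisat2 ...             # short-read mapping; extract junctions to TSV/BED
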