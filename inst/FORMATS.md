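# File formats

All tables are tab-separated with a header row; sequences use the alphabet
`A,C,G,T,N,-` (`-` = alignment gap) and MSA columns are 1-based closed
intervals.

## Reference bundle (input)

* `<bundle>.fasta` — aligned FASTA.  Genomic rows all share one width (the
  genomic alignment); exonic rows share the exonic-alignment width.
* `<bundle>.tsv` — metadata:
  | column | meaning |
  |---|---|
  | record | `allele` or `feature` |
  | gene   | gene symbol (e.g. `A`) |
  | name   | allele name, or feature label (`UTR5`, `exon1`, `intron1`, ...) |
  | level  | `genomic` / `exonic` |
  | start,end | feature rows only: genomic-alignment column range |

  Feature labels starting with `exon` mark coding columns.

## Integrated MSA (output)

* `integrated_msa.fasta` — every allele in the common column space.
* `imputed_mask.tsv` — `allele, column, imputed` (rows only where
  `imputed = 1`; all other positions are 0).  Metadata header comments note
  that donor choice uses exact-match similarity with lexicographic
  tie-breaking.

## Reads

* FASTQ pairs `<prefix>_1.fastq` / `<prefix>_2.fastq` (Phred+33).
* BAM/SAM input: reads overlapping the configured HLA region
  (default hg19 `chr6:28477797-33448354`), unmapped reads, and mates of
  selected reads.

## Per-run outputs (`out_dir/`)

* `filter_log.tsv` — `id, paired, s_star, s_bar_star, accepted` (HR-score
  filter decisions).
* `reads_realigned.tsv` — `id, best_type, sym, phat`: `sym` is the
  full-width MSA-column string (`.` = not covered, `-` = read asserts a
  gap); `phat` lists mismatch probabilities of covered columns.
* `genotype.tsv` — `gene, rank, allele1, allele2, count, fraction`
  (unordered pairs, posterior sample fractions).
* `consensus.fasta` + `consensus_support.tsv` — the two inferred
  haplotype sequences in MSA columns; support = fraction of posterior
  samples agreeing with the modal symbol (below the support threshold the
  symbol is reported as `N`).
* `trace.tsv` — `sweep, log_posterior` of the cold chain.
* `manifest.json` — config snapshot, seed, input digests, stage counts.

## Somatic / LOH reports

* somatic TSV — `gene, haplotype, column, kind, normal_symbol,
  tumor_symbol, normal_support, tumor_support`.
* LOH TSV — `column, allele1_symbol, allele2_symbol, normal_a1, normal_a2,
  tumor_a1, tumor_a2, log_or, ci_low, ci_high`.  The log odds ratio and
  Woolf 95% CI (Haldane–Anscombe pseudocount 0.5) are a reconstruction:
  negative values mean allele 1 is depleted in the tumor.

## Configuration

Flat `key = value` lines; `#` comments; comma-separated vectors.  Keys are
documented in `?run_pipeline`.
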