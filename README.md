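# rnetseq

Pause-site, translocation-state and transcription-error analysis for
RNase-footprinted native elongating transcript sequencing (RNET-seq)
of bacterial RNA polymerase.

## The problem

In an RNET-seq experiment, elongation complexes are purified from
cells and the nascent RNA is trimmed with RNases from its 5′ side,
leaving the 3′-proximal segment that the polymerase protects. The 3′
end of each sequenced fragment marks a polymerase position on the
genome, and the protected length encodes the translocation state of
the enzyme: 14 nt for a post-translocated complex, 15 nt for a
pre-translocated complex, and 15 + *b* nt for a complex backtracked by
*b* base pairs. This package turns strand-specific alignments of such
reads into:

* **pause sites**, called per nucleotide with the *P*(φ, δ) statistic —
  a position pauses if, among the δ ≥ δ_min reads of a length class
  covering it, a fraction φ ≥ φ_min has its 3′ end there (standard
  regimes: *P*(0.9, 100) for bulk reads, *P*(0.9, 50) per length
  class), filtered on the mean mapping quality of the 3′-end reads;
* **pause-motif matrices** on the non-template strand anchored at the
  3′ end (offset −1; no offset 0), with per-offset information content
  IC_j = 2 + Σ_b p log₂ p bits and a log-likelihood-ratio motif score,
  plus the −9/−10/−11 upstream-G register diagnostic that links the
  motif geometry to the translocation state;
* **per-position transcription-error rates** for all 12 substitution
  types, reconstructed from CIGAR/MD tags in transcript orientation,
  with per-opportunity denominators, the mean + SD enrichment
  threshold, and the error-rate-versus-backtracking trend;
* **gene and region metrics**: strand-aware union counting (sense and
  antisense), reads-per-million normalisation (10⁶ × count / total),
  rRNA copy-number averaging, 50-bp Up/Head/Tail/Down windows with
  Welch strain comparisons, sense/antisense correlation, pause
  categorisation by RNA type and TSS-proximity profiles.

A fully tested synthetic generator (`generate_genome()`,
`plant_pauses()`, `simulate_reads()`) plants pause elements, dwell
weights, translocation-state footprints, RNase T1 cleavage bias, 3′
G-to-A misincorporations at CpG elements and sequencing noise, and
emits FASTA/GFF3/FASTQ/lossless SAM plus a per-read truth table — so
every stage can be validated against known ground truth.

## Worked example

```r
library(rnetseq)
gen <- generate_genome(20000, gc = 0.5, n_genes = 20, seed = 1)
pl  <- plant_pauses(gen$genome, gen$genes, 30,
                    motif_class = "WT_PIE", seed = 2)
sim <- simulate_reads(pl$genome, gen$genes, pl$pauses,
                      strain_profile("WT"), 250000, seed = 3)

tracks <- build_pileup(sim$alignments, pl$genome, "elong")
pauses <- filter_mapq(call_pauses(tracks, 0.9, 50), 10)$kept
head(pauses, 3)
#>   replicon  pos strand   phi delta mapq_mean length_class
#> 1  sim_chr  279      + 0.930   948        42        elong
#> 2  sim_chr  408      + 0.920   903        42        elong
#> 3  sim_chr 1136      + 0.917  2278        42        elong

pie <- frequency_matrix(extract_windows(pauses, pl$genome))
pie
#> <pie_matrix> 30 sites, offsets -15..5, total IC 10.1 bits
#>   consensus: CATGGGCGGGTCTGCGGACT

round(sort(information_content(pie)$per_offset, decreasing = TRUE)[1:5], 2)
#> -10  -3  -2  -1   1
#> 1.8 1.8 1.8 1.8 1.8
```

All 30 planted sites are recovered at *P*(0.9, 50) (φ ≈ 0.92–0.93 at
the sites: planted dwell is 200× the local elongation occupancy, so a
small fraction of reads still run through). The information content
concentrates at exactly the planted offsets — G₋₁₀ upstream and
T₋₃G₋₂C₋₁/G₊₁ around the active site — and the modal read length of
the simulated wild-type library is 16 nt (18 nt under the
Gre-deletion profile, whose backtracked complexes protect longer
fragments).

The same analyses run from files: `write_sam()` emits lossless
alignments whose MD tags `read_alignments()` reconstructs exactly, and
`run_pipeline(default_config(seed = 1))` drives
simulate → ingest → pause → motif → errors → genes end to end,
writing TSV/BED/FASTA/GFF3 artifacts and a checksummed manifest.

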