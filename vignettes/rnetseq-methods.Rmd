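---
title: "Methods: pause sites, translocation states and transcription errors from RNase-footprinted NET-seq"
author: "rnetseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pause sites, translocation states and transcription errors from RNase-footprinted NET-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnetseq)
```

## The measurement model

In RNase-footprinted native elongating transcript sequencing
(RNET-seq), transcribing RNA polymerase complexes are purified from
bacterial cells and the nascent RNA is trimmed from its 5′ side with
RNases, leaving only the 3′-proximal segment protected by the enzyme.
Two facts make the resulting short reads unusually informative:

1. **The 3′ end of every read marks the genomic position of a
   polymerase.** Piling up 3′ ends per strand therefore maps where
   polymerases dwell — pause sites appear as positions where a large
   fraction of the covering reads terminate.
2. **The protected length encodes the translocation state.** A
   post-translocated complex (9-bp RNA–DNA hybrid, empty active site)
   protects 14 nt; a pre-translocated complex (10-bp hybrid) protects
   15 nt; a complex backtracked by *b* bp protects 15 + *b* nt,
   because the extruded 3′ RNA remains inaccessible to RNases. Reads
   shorter than 14 nt are sub-footprint species from initiation
   complexes and carry no translocation information.

Throughout the package the 3′-end base has offset −1; the next
downstream base is +1; there is no offset 0. Sequences are reported in
*transcript orientation* (the non-template strand), so a "G-to-A
error" always means a genomic G read as A regardless of which genome
strand the gene lies on.

## Pause calling: P(φ, δ)

For each strand of each replicon, `build_pileup()` tallies per
position the coverage depth δ of a read-length class and the number of
3′ ends. A position is a pause site under `call_pauses(phi_min,
delta_min)` iff the 3′-end fraction φ = ends/δ is at least `phi_min`
and δ ≥ `delta_min`. Standard regimes are P(0.9, 100) for bulk
analyses (with the depth threshold scaled by the ~1.6-fold difference
in sequencing depth between strains, e.g. P(0.9, 160)), P(0.7, 100)
when more sites are needed for categorisation, and P(0.9, 50) for
single-length classes. Adjacent qualifying positions are reported
independently — pausing is a per-nucleotide property here.

Two readings of δ are possible: coverage depth of the class at the
position, or the 3′-end count itself. The phrasing "the fraction of
those reads in which that position is at the 3′ end" points at the
coverage reading, which is the default; `delta_on_end3 = TRUE` exposes
the alternative. For single-length classes, δ is computed within the
class only, since per-length pause sets anchor the per-length motif
matrices.

Multi-mapped reads contribute to pileups at **every** reported
location (excluding them would create coverage holes at rRNA and IS
repeats; including them creates false φ peaks, which is why sites are
additionally filtered on `mapq_mean > 10`, the mean mapping quality of
the 3′-end reads). The error matrices, by contrast, use unique-best
reads only: a mismatch at an ambiguous placement is as likely a
paralog difference as an error.

## Pause motifs

`extract_windows()` cuts the non-template-strand sequence around each
called 3′ end (default offsets −15..+5), reverse-complementing
minus-strand sites so all windows read in transcript orientation.
`frequency_matrix()` tallies base counts per offset;
`information_content()` reports IC_j = 2 + Σ_b p log₂ p bits per
offset (uniform background, pseudocount 0.25 per base per column,
optional small-sample correction 3/(2·ln2·n)); `motif_score()` is a
log-likelihood-ratio score Σ n·log₂(p/q) against a configurable
background (genome composition by default). The exact "MAP" score of
the original analysis is not reproducible from the available
description, so the LLR score is labelled MAP-like.

The diagnostic `g_position_profile()` asks, per read-length class,
which of the offsets −9/−10/−11 carries the strongest G signal. The
G–dC base pair at the upstream end of the RNA–DNA hybrid sits at −9,
−10 or −11 in the post-translocated, pre-translocated and 1-bp
backtracked registers respectively, so this single number summarises
how the upstream pause subelement tracks the translocation state:
15-nt (pre-translocated) classes should report −10 in a Gre⁺
background, and 16–18-nt (backtracked) classes −11 when Gre factors
are absent.

## Transcription errors from CIGAR/MD

`read_alignments()` reconstructs, for substitution-only alignments,
the reference sequence of every read from its MD tag (or the supplied
genome), flips minus-strand reads into transcript orientation, and
exposes per-base (reference, read) pairs indexed from the 3′ end.
Alignments with indels or clipping are excluded and counted — the
analysis covers the 12 substitution types only.

`accumulate_errors()` builds, per exact read length, mismatch counts
and *opportunity* counts (reads whose reference base at the offset is
the given base). Rates are per-opportunity: a "G-to-A rate at −1" is
meaningful only over reads that end at a reference G. A
`per_aligned_base` switch exposes the read-count denominator instead.
`enrichment_threshold()` pools one substitution type's rates over
offsets −12..−1 of the 14–18-nt classes and flags positions above
mean + 1 SD. `error_rate_by_backtrack()` tabulates the 3′-end rate
against read length with a Spearman trend test: because length tracks
backtracking distance, a rising trend links misincorporation to
backtracked pausing.

## The synthetic generator

`generate_genome()`, `plant_pauses()` and `simulate_reads()` emulate
the statistical structure the analysis assumes, with complete ground
truth:

* **Genome and annotation.** A random single replicon (default 20 kb,
  GC 0.5) carrying non-overlapping genes on both strands with TSS,
  CDS bounds, 5′/3′ UTRs, operon labels, log-normal expression levels
  (sdlog 0.7), and optionally seven byte-identical rRNA copies to
  defeat unique mapping. At least one convergent gene pair is always
  present. The terminal 50 bp stay read-free, so circularity never
  produces origin-spanning alignments.
* **Occupancy.** Each strand position has weight 1 (floor) plus the
  expression level of an overlapping gene (plus a 30 % run-through
  tail for 100 bp past the gene end, which is what gives convergent
  gene pairs their antisense signal). A planted pause multiplies its
  local weight by `dwell_weight` (default 200, which puts φ ≈ 0.9
  within reach at modest depth). 3′-end positions are drawn from these
  weights.
* **States and lengths.** Reads at planted sites draw their
  translocation state from the site's distribution — at strong pause
  elements {post .15, pre .60, bt1 .15, bt2 .05, bt3 .05} for the
  Gre⁺ motif and {.05, .15, .20, .25, .35} for the backtrack-prone
  motif. Background reads use strain-level distributions calibrated so
  the genome-wide modal read length reproduces the observed 16 nt
  (WT-like, {.10 .20 .45 .15 .10}) versus 18 nt (Gre-deletion-like,
  {.05 .10 .15 .25 .45}) contrast; the read-length mode is a property
  of the background read mass, so the strain contrast must live in the
  background, not only at pause sites. Protected length is 14 + t.
* **Planted motifs.** `WT_PIE` writes G at −10 and TGC at −3..−1 with
  G at +1; `dGre_PIE` writes G at −11 and T at −4/−7. Sites with a
  non-zero misincorporation rate additionally receive the CpG error
  element C₋₂G₋₁, so their 3′-end base is a reference G whose
  misreading is a genuine G-to-A event and whose penultimate RNA base
  is C.
* **Misincorporation.** Reads that drew a backtracked state *and* end
  at a reference G are misread as A at the 3′ terminus with the
  site-specific (or strain-default, 8×10⁻³ for the Gre-deletion
  profile, 0 for WT) probability. Conditioning on backtracking, rather
  than forcing a state change after the fact, keeps every error read
  backtracked (≥ 16 nt) *and* makes the configured probability exactly
  the conditional G→A rate of the 16–18-nt classes, so the 18-nt
  estimator recovers the parameter within binomial error.
* **5′-end channels.** With probability `rnase_t1_bias` (default 0.5)
  the 5′ trim point shifts up to 2 nt upstream to leave a G
  immediately 5′ of the read (RNase T1 cuts GpN bonds); this smears
  the length classes upward and is why the post- and pre-translocated
  classes are underestimated in real data. Independently, a fraction
  `p_untrimmed` (default 0.15) of reads keeps 3–12 nt of untrimmed 5′
  RNA (capped at 30 nt): these are the ≥ 21-nt "bulk" reads, which
  carry no RNase signature and no state information but still mark
  pause positions with their 3′ ends. A fraction `p_initiation`
  (default 0.08) of reads are 6–13-nt initiation-complex footprints
  starting at a TSS, reproducing the TSS-proximal pileup of
  sub-footprint reads.
* **Sequencing noise.** Uniform per-base substitutions at 10⁻⁴,
  mirroring the platform error floor; constant Q38 qualities.

The lossless SAM written by `write_sam()` carries all-match CIGARs
with NM/MD tags encoding every planted mismatch, so the ingest path is
exercised end to end and the truth table can be compared against the
reconstruction exactly.

### What the generator does not emulate

No polymerase kinetics (dwell weights are occupancy ratios, not rate
constants), no NTP or factor concentrations, no RNA secondary
structure or hairpin-stabilised pausing, no ribosome coupling, no
adapter/ligation artifacts, no quality-score variation, no indel
errors, and no local composition biases beyond the planted motifs.
Passing tests therefore demonstrate that the *analysis* is correct and
well-calibrated on data obeying the stated measurement model — not
that the model captures everything in real libraries.

## Gene and region metrics

`count_gene_reads()` uses a strand-aware union rule: a read counts for
a gene iff its interval overlaps that gene and no other same-strand
gene; multi-gene reads are dropped as ambiguous and reported.
Antisense counts apply the same rule with the read strand flipped.
rRNA counts are divided by the copy number (seven) to represent one
average operon copy. Normalisation is reads-per-million:
10⁶ × count / total mapped reads.

`region_windows()` defines, in transcription orientation, Up (50 bp
strictly upstream of the start codon), Head (first 50 CDS bp), Tail
(last 50 CDS bp) and Down (50 bp past the stop codon); genes with a
CDS under 100 bp get overlapping Head/Tail windows and are flagged.
`compare_strains()` runs a two-tailed Welch test per region over mRNA
genes with gene-level normalised counts above 0.1 in both strains
(p > 0.05 labelled n.s.); a paired test is available but the unpaired
Welch form is the default. `sense_antisense_correlation()` reports the
Pearson r of normalised sense versus antisense counts per region
class. `categorize_pauses()` assigns pauses to mRNA CDS / 5′ UTR /
3′ UTR / tRNA / rRNA / ncRNA / antisense / intergenic with sense
features taking precedence over antisense over intergenic, and
`tss_distance_profile()` bins signed distances to the nearest
same-strand TSS (default 25-bp bins to ±500 bp; the bin parameters are
calibration choices, as no canonical values exist).

## Numerical and design choices

* Coordinates are 0-based half-open internally, 1-based in TSV
  reports, 0-based half-open in BED — the SAM/BED interoperability
  convention.
* Pseudocount 0.25 per base per column keeps IC finite at small n
  without dominating at n ≥ 50; motif scores default to the genome
  composition background while IC uses the uniform display background.
* The naive mapper reports all hits at the minimal mismatch count with
  mapq 42 (unique), 3 (2–4 best) or 0 (> 4) — a documented stand-in
  convention, checked against an exhaustive scan.
* Degenerate inputs: empty pause sets produce empty (but well-formed)
  tables and files; windows that do not fit the contig are skipped and
  counted; zero-depth positions have φ = 0 by convention; constant
  rate vectors yield an NA Spearman trend rather than a spurious one.
* Problem sizes in the test-suite were chosen for statistical
  resolution: pause recovery and motif tests use a 20-kb genome with
  30 planted sites and 250–350 k reads (so the 18-nt class holds over
  10⁵ reads and per-class depths clear δ = 50); the two-strain region
  comparison uses 80 genes and 200 k reads per strain, the size at
  which the unpaired Welch test reliably resolves a 2× Up-region dwell
  increase against the cross-gene expression spread (which an unpaired
  test cannot pair out).

## Worked example

```{r example, eval = FALSE}
gen <- generate_genome(20000, gc = 0.5, n_genes = 20, seed = 1)
pl  <- plant_pauses(gen$genome, gen$genes, 30,
                    motif_class = "WT_PIE", seed = 2)
sim <- simulate_reads(pl$genome, gen$genes, pl$pauses,
                      strain_profile("WT"), 250000, seed = 3)
tracks <- build_pileup(sim$alignments, pl$genome, "elong")
pauses <- filter_mapq(call_pauses(tracks, 0.9, 50), 10)$kept
pie <- frequency_matrix(extract_windows(pauses, pl$genome))
print(pie)
```

## Known limitations

Single-replicon genomes only; substitution-only alignments (indel
reads are excluded, not modelled); the mapper is for desk-scale
synthetic genomes, not a production aligner; the MAP-like motif score
is an LLR stand-in for an unavailable formula; operons default to
single genes, so the monocistronic/first-gene restriction of the
Up-region analysis is trivially satisfied; and the generator's state
distributions are calibration choices — the real WT/ΔGre occupancies
are not quantitatively known.
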