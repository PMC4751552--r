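---
title: "Methods: detecting mRNA editing from matched DNA and RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting mRNA editing from matched DNA and RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscreen)
```

## The problem and the model

mRNA editing is a post-transcriptional change that makes a transcript differ
from its genomic template. In vertebrates the two validated mechanisms are
ADAR-mediated A-to-I deamination (inosine is read as G by sequencers, so it
appears as A>G) and APOBEC-mediated C-to-U (read as C>T). With unstranded
sequencing libraries, the complements T>C and G>A are indistinguishable from
these and are therefore also counted as canonical.

Sequencing the genomic DNA and the mRNA of the *same individual* lets an
editing event be defined directly as a within-individual DNA/RNA difference,
removing the confound of unreferenced germline polymorphism that plagues
designs using only a species consensus or SNP databases. A position is a
**candidate** for one sample when:

1. the DNA pileup is strictly homozygous by counts — every read supports one
   allele A (counting MAF = 1), whether A matches the reference assembly or
   not;
2. the RNA pileup supports exactly the alleles \{A, B\} or \{B\} for a single
   alternative B ≠ A (positions whose RNA supports two or more alternatives
   are triallelic and discarded);
3. both pileups have depth ≥ 15 reads;
4. the difference is a substitution (insertions and deletions never emit a
   per-base observation here, so they cannot form candidates).

Most candidates produced this way are artifacts, which is the methodological
point of the pipeline: every candidate is evaluated by six independent
artifact flags, and only events reproduced in at least three biological
replicates of a tissue are reported.

## The six artifact flags

| flag | rule | default |
|---|---|---|
| extremity | edited-allele observations mostly within the first/last 10 bases of their reads | fraction > 0.5 |
| strand | \|p~f~ − p~r~\| of per-strand edited-allele proportions above Δ; a strand with zero coverage is flagged | Δ > 0.5 |
| splice | site within 1–3 bases of the exon side or 3–8 bases of the intron side of an annotated junction | inclusive, distance 1 = adjacent base |
| homopolymer | the 4 bases immediately 5′ *or* 3′ of the site are identical | run of 4 |
| SSR | a perfect tandem repeat (motif 1–6 bp, ≥ 3 copies, ≥ 9 bp), expanded by ±3 bp, contains the site | SciRoKo-like defaults |
| multimapping | the 40 bp edited-allele consensus occurs verbatim (or reverse-complemented) in any raw DNA read of the same sample, including unaligned reads | exact match |

Flags are computed independently and never short-circuit, so per-filter
attrition is always reportable. `is_unbiased()` is true iff all six are
false.

Choices the protocol leaves open, and what this package does:

* **"mostly supported" (extremity)** is read as a strict majority
  (threshold 0.5, configurable). Distance to the read end is
  `min(read_offset, read_length - 1 - read_offset)`, measured in the stored
  (aligner-orientation) sequence; the original's orientation convention is
  unstated and the symmetric minimum makes the two conventions coincide.
* **Homopolymer sidedness**: "the four neighboring positions" could mean one
  side or a centered window. The flag fires when *either* flank of 4 is a
  single-base run — the stringent reading; the site's own base need not
  match.
* **Consensus centering**: a 40-mer has no central base. The edited allele
  is placed at 0-based index 19 (the 20th base). Near a contig end the
  window is clipped and marked truncated.
* **Consensus ties** break toward the reference base, and flank positions
  covered by no edited read take the reference; only reads that carry the
  edited allele at the site vote.
* **Multimapping tolerance**: the original pattern-search mismatch allowance
  is unstated; the default is exact (k = 0), with a Hamming-k option.
* **RNA allele support**: the original used a likelihood-based pileup
  caller; this package replaces it with explicit counts. An allele is
  supported with ≥ 2 reads by default (`min_alt_reads`) — deterministic,
  auditable, and dominated downstream by the artifact filters and the
  replication rule.
* **DNA discordance tolerance** defaults to 0 (strict MAF = 1) but is a knob
  (`max_discordant_frac`) for noisy data, and pileups are capped at 10 000
  reads in input order, mirroring the original pileup command's ceiling.

## Replication, spectrum, clusters

Unbiased candidates are merged within tissue by the key
(chrom, pos, DNA allele, RNA allele) — both alleles are part of the event
identity so cross-sample allele conflicts can never silently merge. The
replicate count of an event is the number of distinct samples supporting
it; the default reporting threshold is ≥ 3 of 8, and sweeping the threshold
is monotone by construction. The 12-class substitution spectrum and the
transversion fraction quantify residual noise: true editing should be
dominated by the four canonical classes, and requiring replication should
drive the transversion share down. `deduplicate_union()` gives the
cross-tissue unique-site list and the tissue-shared subset;
`find_clusters()` groups same-chromosome sites whose successive gaps are at
most 2 kb and reports each cluster's span (`max(pos) − min(pos)`).

## Localization and coding consequence

A minimal re-implementation of the annotation categories the screening
report actually uses: exon (CDS missense / CDS synonymous / noncoding),
intron, upstream/downstream flank, intergenic. Overlap precedence is
exon > intron > flank > intergenic; when several genes overlap a site,
every gene name is reported and the most severe category wins. Two radii
are used because the source protocol uses both: 5 kb for calling a site
"flanking" and 10 kb for naming the nearest gene of an intergenic site.
The coding consequence builds only the affected codon — walking the CDS
segments in translation order, honoring the first segment's phase and
reverse-complementing on the minus strand — and compares the translated
amino acids; a brute-force full-CDS translation serves as the test oracle.

## Editing level and factor tests

The editing level of a site in a sample is the edited-allele fraction of
the RNA signal divided by the measured DNA allele fraction of the same
assay, clamped to [0, 1]. The division cancels amplification/sequencing
bias common to both templates; with perfectly homozygous DNA the correction
factor is 1. The source protocol's sentence defining the standardization is
ambiguous; this ratio-of-fractions form is scale-invariant in all four
signals (a property test) and is the documented surrogate. Group effects
(genotype, age, feeding, sex) are tested with the classical two-sided
unpaired *homoscedastic* Student t-test (pooled variance,
df = n~a~ + n~b~ − 2), per the protocol's explicit choice; Welch's test is
available as an option. Stars follow 0.05 / 0.01 / 0.001. Degenerate
inputs: zero pooled variance with equal means gives t = 0, p = 1; with
unequal means the p-value is the smallest representable positive number.
No multiple-testing correction is applied (the source reports raw
p-values).

## What the simulator emulates — and what it does not

`sim_config()` defaults state the study's world: 8 biological replicates,
101 bp reads (the study sequenced 2 × 101 bp; single-end simulation
suffices because no filter uses mate information), ~30× depth in both
sources, zero sequencing error for truth tests (0.1–1% is a reasonable
robustness setting), one 10 kb contig with two 2-exon genes, one per
strand. Editing rates for planted edits are 0.4–0.5 — mid-range levels at
which Binomial(30, rate) support virtually never drops below the 2-read
floor — with one edit expressed in 5/8 samples and one in 8/8.

One site is planted per artifact class, each constructed so that exactly
its intended filter fires: strand-artifact sites put the alternative base
on one alignment strand only; extremity sites only within 10 bp of read
ends; a splice-adjacent site sits 2 bp inside an exon end; homopolymer and
SSR sites get AAAA / (AC)~6~ contexts written verbatim; a paralog site's
alternative allele is also present in extra "unassembled" DNA reads that
appear only in the FASTQ, never in the SAM; a genomic SNP is homozygous-
alternative in both DNA and RNA and must *not* become a candidate. For all
other sites the neighborhood is regenerated until it is free of
homopolymer/SSR context, so cross-class false flagging is zero by
construction. Alternative reads alternate between strands (so a real edit
never trips the strand filter by chance at depth 30), and mid-read
placements keep them clear of the extremity window.

The truth table is derived from the *realized* simulation (which reads
actually carry the alternative base), so expected detection is exact under
any seed, not just in expectation. What a green end-to-end test
establishes: the pipeline recovers every planted expressed edit, attributes
each artifact to its intended filter, and lets nothing else through — at
zero sequencing error on a small genome. What it does not establish:
behavior under realistic error profiles, quality-score effects, alignment
ambiguity (reads are generated already aligned), GC/coverage bias, or the
genome-scale candidate counts of the original study, which require the
original ~157M-read datasets.

## Numerical and engineering choices

* Coordinates are 1-based inclusive everywhere (SAM/GFF convention);
  half-open arithmetic appears only inside interval code, never in output.
* The CIGAR walk emits one observation per M/=/X base; S and I consume read
  only, D and N reference only, H and P nothing; records whose CIGAR length
  disagrees with the stored sequence are skipped with a warning. A naive
  per-base walker is the test oracle (10^4 random CIGARs).
* N bases never count as allele support anywhere.
* The SSR finder reports maximal perfect tandem arrays of primitive motifs,
  counting full copies only (interval length = motif × copies); a quadratic
  brute-force enumerator is the oracle (10^4 random strings).
* The Fig-2-style attrition report uses per-sample candidate rows as the
  denominator for per-filter fractions (each row is what a filter actually
  judges) and reports unique-event counts alongside; fractions are always
  against the initial pool, not the surviving one.
* All simulator randomness flows from one master seed; identical seeds give
  byte-identical output files.

## Known limitations

Quality scores are ignored (the source pipeline recalibrated them upstream,
which is out of scope and documented as such); no indel calling; the
annotator has no UTR sub-categories and no deleteriousness scores; the CLI
folds the per-stage commands into `simulate` / `run` / `check-table2`
because the stages always execute as one deterministic chain, while each
stage remains an exported, individually tested function.
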