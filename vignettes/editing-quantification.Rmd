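---
title: "Quantifying A-to-I RNA editing from strand-specific RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying A-to-I RNA editing from strand-specific RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

## The measurement

Adenosine deaminases convert adenosine (A) to inosine (I) in RNA. Inosine
base-pairs like guanosine, so when RNA from edited cells is reverse
transcribed and sequenced, edited positions show up as A>G mismatches
against the reference genome. `editscan` quantifies this signal in bacteria
and their phages: per-position editing fractions, transcriptome-wide
mismatch-class rates, binomial site calls, condition comparisons across an
infection timecourse, and reports at user-supplied target loci (for
example, tmRNA/ssrA-like positions previously reported as edited, or the
tRNA-Arg position edited by the host's endogenous TadA deaminase, which
serves as a positive control in this kind of experiment).

The library protocol matters. In a dUTP-type strand-specific library the
sequenced strand is the first-strand cDNA, antisense to the transcript.
Two consequences drive the whole design:

* only reads aligning **antisense** to an annotated gene are informative,
  and
* the gene's strand decides which reference-space mismatch class is
  transcript A>G: `(ref A, alt G)` for `+` strand genes and
  `(ref T, alt C)` for `-` strand genes.

## Read filtering

Four exclusion rules turn raw alignments into the quantified set, applied
in a fixed order so every read lands in exactly one audit category:

1. unmapped reads;
2. reads overlapping annotated **rRNA** genes, on either strand (rRNA
   dominates bacterial RNA even after depletion, and its positions are not
   analysed);
3. **multi-mapping** reads — origin ambiguous, so their mismatches cannot
   be attributed; both common aligner dialects are recognised (hit-count
   tag `NH` > 1, or MAPQ 0);
4. reads whose CIGAR contains an **insertion or deletion** relative to the
   reference (alignment around indels misplaces substitutions).

Surviving reads must be antisense to exactly one gene. Reads antisense to
no gene are `wrong_strand`/`unassigned`; reads antisense to two genes at
once (possible when a read spans a short intergenic gap) are `ambiguous`
and dropped. The order of rules only affects the audit tally, never the
kept set, since each rule is a pure predicate of the read; we fix the
order (unmapped, rRNA, multi-mapper, indel, strand) for reproducible
accounting. Soft-clipped reads are *not* discarded — only I/D CIGAR
operations are disqualifying — but soft-clipped bases never enter the
pileup.

By default a read partially overhanging a gene end still counts for that
gene (`any_overlap`); the alternative `full_overlap` policy is available.
The choice affects only gene assignment, not per-position counts.

## Pileup and per-site statistics

`build_pileup()` lays each kept read's bases into reference space along
its CIGAR (insertions contribute nothing; deletion gaps contribute
nothing, so they never inflate N counts) and tallies A/C/G/T/N per
position. Base calls below `min_base_quality` (default Q20) are excluded
from both counts and coverage. The per-position counting is checked
against an independent naive per-read counter in the test suite.

`site_stats()` rotates counts into transcript orientation by gene strand
and computes, at each transcript adenosine, the editing fraction

$$\hat f = \frac{n_G}{n_A + n_G},$$

the estimator of the fraction of edited molecules at that site. N calls
enter neither numerator nor denominator.

## Transcriptome-wide rates and site calling

`transcriptome_rates()` aggregates the twelve substitution classes X>Y
over all *expressed* positions of non-rRNA genes. "Expressed" is not
quantified in the kind of figure this reproduces, so it is a parameter:
coverage of at least `expressed_threshold` kept reads, default 10.
Whether the original analyses weighted positions by coverage is likewise
not stated; we report the coverage-weighted rate
$\sum n_{\mathrm{alt}} / \sum (n_{\mathrm{ref}} + n_{\mathrm{alt}})$ as
the primary statistic (it equals the coverage-weighted mean of per-site
fractions, an identity the tests assert exactly) and the unweighted
per-position mean alongside.

Published analyses of this kind report raw frequencies without a formal
test. To make a statement like "more than 99% of adenosines remained
adenosines" operational, `call_sites()` adds an explicit calling rule of
our own design: an exact binomial upper-tail test of $n_G$ in
$n_A + n_G$ trials against a background rate, Benjamini–Hochberg adjusted
across all tested sites, called at `q <= 0.05` with the extra requirement
$\hat f$ > background. The background defaults to the median of the
eleven non-A>G class rates, which self-calibrates: under a uniform
sequencing-error model every class has background `error_rate / 3`.

`compare_conditions()` joins control and treatment per-site fractions
(per timepoint, when a `timepoint` column is present; timepoints are
opaque ordered labels in minutes, 0 = uninfected — no trend model is
fitted), and summarises the fraction of expressed adenosines *not* called
edited in the treatment arm. `targeted_report()` evaluates a user list of
loci (contig, 1-based position, strand) with the strand-appropriate base
pair, flagging low-coverage loci rather than omitting them. Host and
phage contigs are treated identically throughout, so either can be
inspected separately.

## The synthetic-data module

Real editing datasets require sequencing runs; the generator instead
produces a miniature community whose truth is known exactly, so every
pipeline stage is testable offline.

* `design_genome()` lays out a host contig (mRNA + rRNA + tRNA genes) and
  a phage contig. Defaults, chosen once as a realistic compact design:
  mRNA genes of 200–400 bp with log-normal (meanlog 0, sdlog 1)
  expression weights; two 500 bp rRNA genes at weight 50, emulating the
  residual rRNA load the filter must discard; tRNA genes of 76–90 bp at
  weight 5; 20 phage mRNAs whose weight multiplier is a free parameter
  (the host:phage mixture over an infection at MOI 2 is not quantified
  anywhere we could anchor it to).
* `generate_reference()` draws sequence at a requested GC content and
  guarantees every transcript contains an adenosine.
* `plant_decoy()` duplicates a gene's sequence into unannotated
  intergenic space; reads from that gene then genuinely align to several
  positions and are truth-flagged multi-mapping (MAPQ 0, `NH` ≥ 2, both
  dialects at once).
* `simulate_reads()` draws transcript molecules in proportion to
  expression weight, edits each molecule independently at each configured
  site (Bernoulli at `true_rate`, A>G in transcript space) **before**
  fragmentation — reads sharing a molecule share its edits, which makes
  the per-site estimator's target exactly `true_rate` — then applies
  uniform substitution errors (each alternate base equally likely, so any
  single mismatch class has the analytically convenient background
  `error_rate / 3`), writes constant Q30 qualities, and emits each read
  antisense to its gene. Reads are wholly contained in transcripts
  (bacterial genes are intronless; no junctions) with uniform fragment
  start positions. A configurable fraction of reads receives a 1-bp
  insertion or deletion. Single-end reads only: the strand rule is then
  unambiguous; the filter nevertheless accepts paired data by treating
  each mate independently (each mate is counted in the pileup — the
  protocol sequences single-stranded cDNA, so this is the simplest
  faithful default).

What the generator does **not** emulate: position-dependent quality and
error profiles, coverage biases (GC, fragmentation, 3'/5' decay), splice
junctions, UMI structure, true rRNA depletion chemistry, or secondary
structure effects on editability. Passing tests therefore demonstrate the
*pipeline arithmetic* — filtering, counting, strand handling, calling —
on data whose generating process is known, not robustness to every
artefact of real libraries.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; 1-based conversions occur
  only at SAM/GFF/TSV boundaries. A reverse-complement transform of the
  entire dataset (genome, annotation, alignments) leaves every editing
  summary invariant — asserted in the tests, which pins down the
  coordinate arithmetic on both strands.
* Sites with zero informative calls are skipped rather than reported with
  undefined fractions; classes with empty denominators are `NA` with a
  warning.
* Ties and edge cases in calling: `n_alt = 0` gives p = 1; a background
  of exactly 0 (error-free data) makes any single alternate call
  significant, which is correct under the stated model.
* TSV outputs use a single dialect (tab-separated, header, `.` for
  missing); the run manifest records a config hash, the seed and
  per-stage row counts, and identical configs reproduce byte-identical
  outputs.
* `--threads` is accepted for interface compatibility; results never
  depend on it.

## Verification scale

The test suite and acceptance script exercise the pipeline at deliberately
compact sizes chosen to keep full verification runs to minutes on one
core while preserving the statistical content: the transcriptome-wide
null check uses 200 host mRNA genes plus phage/rRNA/decoy load at 50×
mean depth over 20 replicate seeds (roughly 75,000 reads and 13,000
expressed adenosine positions per arm and replicate); targeted-locus
recovery uses ≥1000× coverage at a 4% site; the positive control uses a
40% site at 200× over 100 replicate seeds; pileup correctness uses 200
randomised small instances against a naive counter.

## Known limitations

* No alignment is performed; real data must arrive pre-aligned (the
  simulator emits truth alignments). Aligner-specific multi-mapping
  conventions beyond MAPQ/`NH` are not interpreted.
* The binomial model treats base calls at a site as independent across
  reads; overlapping mates from one fragment would be double-counted if
  paired data were supplied.
* The calling layer is this package's operational definition, not a
  published procedure; its q-threshold and background estimator are
  configurable and reported in every output.
* Editing is modelled as site-independent; cooperative or
  structure-dependent editing is out of scope.
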