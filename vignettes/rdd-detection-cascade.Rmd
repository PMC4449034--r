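---
title: "Detecting RNA-DNA differences with a replicated filtering cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNA-DNA differences with a replicated filtering cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddcascade)
```

## The model

An RNA-DNA difference (RDD) is a genomic position where DNA sequencing of
an individual supports a single (homozygous) allele while RNA sequencing of
the same sample supports that allele plus an additional one. Genuine RNA
editing — in vertebrates, overwhelmingly A-to-I deamination read as A>G,
with C-to-U (C>T) as the second canonical chemistry — produces exactly this
signature, but so do at least seven distinct technical processes. The
package treats detection as a cascade of falsifiable null explanations:
a candidate survives only if *every* artifact model fails to account for it.

The unit of evidence is a per-replicate pileup summary at a candidate site:
DNA and RNA allele counts, the per-mapping-strand counts of the alternative
allele and of total coverage, and the within-read offsets (in sequencing
orientation) of the reads carrying the alternative allele. Alignment,
duplicate removal and recalibration are upstream concerns; the cascade
consumes their result as a documented TSV so it can be tested without
alignment tooling.

## Stages, thresholds, and why

`filter_config()` collects every threshold:

| stage | rule | default | rationale |
|---|---|---|---|
| depth_genotype | DNA hom (major ≥ `dna_hom_fraction`), RNA het, depth ≥ `min_depth` in both | 0.98 / 15 reads | 15 reads bounds the binomial noise on the edited fraction; the 98% homozygosity is provisional, the strict rule comes next |
| dna_alt_zero | edited-allele DNA count zero over **all** replicates | 0 | total absence of the alternative in DNA is the most stringent reading of homozygosity |
| replicate_support | ≥ `min_replicates` replicates share position and allele | 2 | one sample's artifact (sample swap, somatic event, lane effect) cannot recur in an independent animal |
| read_extremity | median pooled alt offset in the terminal `end_window` bases fails, boundary inclusive | 10 bases | miscalls concentrate at read ends where quality decays and local alignment is weakest |
| strand_bias | both strands covered and delta ≤ `strand_delta_max` | 0.5 | true transcripts are sampled from both strands of the sequencing library; one-strand support indicates mapping artifacts |
| biallelic | third alleles strictly < `third_allele_max` of pooled RNA | 5% | a genuine edit adds one allele; additional alleles at above-error levels indicate a noisy or paralog-fed site |
| splice_region | within `splice_window_exonic` / `splice_window_intronic` of a non-coding exon boundary | 3 / 8 bases | spliced-read misalignment piles mismatches around junctions; the windows are the convention used by variant-effect annotation |
| homopolymer | in, or adjacent to, a run ≥ `homopolymer_min_run` | 5 | slippage errors at and immediately next to runs; adjacency is included because the first base after a run is the dominant miscall position (a `adjacent = FALSE` switch restores strict containment) |
| dna_pattern | 41-mer (flanks of `pattern_flank` with the edited base centred) found in supporting replicates' DNA reads | 20 bp/side, 0 mismatches | if the "edited" sequence exists in the genomic reads, an unassembled or diverged paralog explains the RNA without editing; matching is exact in both orientations, with a configurable mismatch count |

Deliberate boundary choices, each locked by a unit test: a median offset of
exactly 10 fails (inclusive window); a strand delta of exactly 0.5 passes;
a third-allele fraction of exactly 5% fails (strict inequality); a strand
with zero coverage makes the delta undefined and is treated as failure —
when a conservative and a permissive reading are both defensible, the
cascade takes the conservative one.

Two structural decisions deserve note. First, the read-end window is a
fixed 10 bases rather than 10% of the read length; at the 100-base reads
the pipeline is designed around these coincide, and `end_window` is
configurable for other lengths. Second, the post-support evidence
(offsets, strand counts, allele counts) is pooled across the supporting
replicates rather than evaluated per replicate: pooling uses all reads,
gives the median and the strand delta their best resolution, and makes
each filter a pure predicate of one candidate. Purity has a testable
consequence — the final surviving set is invariant under any permutation
of the six post-support stages (asserted on synthetic data); only the
per-stage accounting depends on the order.

At the calling stage, the RNA heterozygosity floor (alternative ≥ 5% of
reads and ≥ 2 reads, with the DNA allele also present at the same floor) is
an explicit stand-in for an upstream variant caller's behaviour and is
configurable. The edited allele is the majority non-DNA allele; whether
*additional* alternatives disqualify the site is deliberately left to the
biallelic stage, which is the cascade's designated multiallelic check —
folding that test into the caller would leave the biallelic filter
unreachable. A maximum pileup coverage of 10,000 reads is honoured on
load as a validation warning; it mirrors an upstream pileup cap rather
than a property this package enforces by truncation.

## The synthetic data generator

`simulate_dataset()` builds a single ~50 kb chromosome containing a
three-exon coding gene, a four-exon non-coding gene, a block of planted
homopolymer runs (each flanked so the run is maximal at its configured
length), a 2 kb segment duplicated elsewhere on the chromosome with
substitutions every 50 bp, and open intergenic space. Outside the planted
runs the sequence is rejection-sampled to contain no run of five or more,
so planted sites interact only with their assigned feature.

Counts are generated at the observation level from per-class multinomials
— not by full read simulation — because that is the level at which every
filter's contract is defined; only the DNA reads consumed by the pattern
filter are emitted as literal substrings of the paralog copy (plus a
background of error-bearing reference reads). Design choices:

* **Replication and depth.** 8 biological replicates; mean DNA depth 30 and
  RNA depth 50 per replicate (Poisson), scaled from a whole-genome screen
  to desk size while keeping depths well above the 15-read floor.
* **Editing frequencies.** True edits draw from 0.18–0.87, the span of
  editing levels observed among final candidates in the chicken screen;
  edits are planted on A (or T) templates with the canonical G (or C)
  allele.
* **Sequencing error.** 2×10⁻⁴ per retained base, symmetric across the
  three non-reference bases — the residual miscall rate after the
  quality/mapping filtering the pipeline assumes upstream, and the simplest
  null for the biallelic filter. It also sets the only stochastic leak in
  the cascade: the strict DNA zero-count rule removes a true edit whenever
  at least one of ~240 DNA reads miscalls to the edited base (~2% of
  sites), which is the dominant term in the simulator's ~0.95 sensitivity.
* **Artifact signatures.** Read-end artifacts confine all alt offsets to
  one randomly chosen read end (an even mixture of both ends would leave
  the pooled median mid-read and defeat the filter's own definition).
  Strand artifacts put every alt read on one strand with apparent
  frequency drawn from 0.40–0.60: with balanced coverage the one-strand
  delta is 2f/(1+f), so detectability under the delta ≤ 0.5 rule requires
  f > 1/3 — low-frequency one-strand artifacts are invisible to this
  filter by design, in the simulator as in reality. Multiallelic artifacts
  carry a second alternative at 10–18%, clearly above the 5% cap but below
  the majority allele. Germline heterozygotes are 50/50 in both molecules.
  Homopolymer, splice and paralog artifacts are placed deterministically
  in their features; paralog sites sit at copy-substitution positions
  spaced ≥ 50 bp so each 41-mer matches the copy exactly.

What the generator does **not** emulate: indels, base-quality structure,
fragment-length and GC biases, expression-level variation across sites,
correlated errors between replicates, and genuinely hyper-edited reads.
Passing the recovery tests therefore demonstrates that each filter removes
the failure mode it was designed for at realistic effect sizes — not that
the cascade's real-data operating characteristics are these numbers.

## Editing levels and the ANOVA

`generate_editing_level_dataset()` produces a balanced tissue × stage ×
replicate table (3 × 3 × 4 by default) on the logit scale — baseline +
tissue + stage + interaction + Gaussian noise (SD 0.4), mapped through the
inverse logit so levels stay in (0, 1). `anova_tissue_stage()` fits
`editing_level ~ tissue * stage` by least squares and reports sequential
(type-I) sums of squares; on a balanced design all SS types coincide, and
unbalanced input is rejected with a pointer to the balanced generator. An
all-equal response leaves F undefined; the fit is flagged `degenerate`
(detected against the scale of the data, since the total SS is itself zero
there) rather than erroring. Calibration is asserted by simulation: 2,000
null datasets give rejection rates within 0.04–0.06 at α = 0.05 for all
three tests, and a planted monotone stage effect is detected with higher
power by the stage test than by the interaction test.

## Clustering and characterization

Clusters are maximal groups of ≥ 2 same-chromosome sites with consecutive
gaps ≤ `cluster_max_gap` — a single linear scan, checked in tests against a
brute-force maximality oracle. The default gap of 1,000 bp is a round
value chosen inside a robustness plateau: on the packaged 36-candidate
table every cluster statistic is identical for any gap in [807, 2864] bp,
because the widest intra-cluster gap is 807 bp and the narrowest
between-group gap is 2,865 bp. Strand-collapsed change labels use the
A/C-first orientation, with {A>G, T>C, C>T, G>A} canonical. The
consequence classifier is deliberately minimal — upstream/downstream
(5 kb flank), UTRs, introns, splice regions, and codon translation on the
gene strand for synonymous/missense calls; stop-codon changes are reported
as missense, and non-coding exons get their own term. It is not a
substitute for transcript-set-aware effect prediction, and the packaged
candidate table keeps its published consequence strings.

## Problem sizes and determinism

Every stochastic component takes an explicit integer seed through
`simulation_config()`; the genome, truth table, observations, reads and
editing-level table are deterministic functions of the configuration, and
re-running a manifest reproduces byte-identical outputs. The shipped test
suite works at the scale the defaults define: 50 true edits and 30 sites
per artifact class on a 50 kb genome (~260 sites × 8 replicates) for
recovery, eight independent simulations for the canonical-enrichment
curve, 2,000 replicates for ANOVA calibration — sizes chosen so the
binomial and F-distribution approximations are sharp while a full run of
the suite stays in the minutes range.

## Known limitations

* The cascade's absolute survivor counts on real whole-genome data depend
  on upstream alignment and calling choices the package does not model.
* The strict DNA zero-count rule trades sensitivity for precision; at high
  DNA depth it removes a small, quantifiable fraction of true sites.
* The strand-bias rule cannot detect one-strand artifacts with apparent
  frequency below 1/3 (delta ≤ 0.5 is then satisfied identically).
* The pattern search is exact by default; diverged paralogs with
  within-flank substitutions require raising `pattern_max_mismatch`.
* Cluster statistics on small candidate sets are sensitive to single sites;
  the plateau analysis above should be repeated for any new dataset.
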