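---
title: "Misincorporation mapping of hard-stop RNA modifications"
author: "misincmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Misincorporation mapping of hard-stop RNA modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misincmap)
```

## The model

N1-methyladenosine (m1A) and a handful of other base modifications carry a
methyl group on the Watson-Crick face. Standard reverse transcriptases
(e.g. SuperScript III) usually arrest at such a "hard-stop" base; in the
minority of events where the enzyme traverses it, the cDNA frequently
carries the wrong base at that position, most often an A-to-T transition
for m1A, with the two other substitutions present as minority classes.
Sequenced reads therefore carry two complementary signatures of a hard
stop: truncated 5' ends one base downstream of the modification, and a
reproducible, heterogeneous mismatch pile-up at the modified position.

For a site with stoichiometry $s$ (fraction of molecules modified),
read-through probability $r$ and misincorporation probability $m$ given
read-through, the mismatch fraction among reads that *cover* the position
is

$$ q = \frac{s\,r\,m}{s\,r + (1 - s)} $$

because truncated cDNAs stop one base 3' of the site and never cover it.
`expected_mismatch_rate()` implements this closed form; the simulator and
the test suite check the whole read-level pipeline against it.

Sequencing error produces mismatches too, but (i) at rates near the
per-base error rate rather than $q$, (ii) without reproducibility across
independent libraries, and (iii) without the characteristic three-class
heterogeneity. The filter chain in `call_candidate_sites()` operationalises
exactly these three distinctions.

## The filter chain

Per replicate, `build_pileup()` counts A/C/G/T at every covered position
after three normalisations:

* **PCR-duplicate collapsing** (`collapse_duplicates()`): one read per
  (sequence, start, strand, UMI), or per (sequence, start, strand, length,
  bases) when no UMI is present. All downstream depths are unique-read
  depths.
* **End clipping** (`end_clip`, default 10 nt): read ends are enriched for
  sequencing error, so the first and last ten aligned bases never count.
* **A per-read mismatch ceiling** (`max_mismatches_per_read`, default 1),
  re-imposing at the pileup stage the mismatch cap that the original
  alignments were produced under. Alignment itself is upstream of this
  package.

`call_candidate_sites()` then sums counts across replicates and keeps a
position when all of the following hold (defaults in parentheses):

1. combined unique-read depth at least `min_combined_depth` (500);
2. combined misincorporation rate at least `min_rate` (1%);
3. independent detection in at least `min_replicate_fraction` (half) of
   replicates, where a replicate detects the site when its own depth is at
   least `per_replicate_min_depth` (20) and its own rate at least
   `per_replicate_min_rate` (1%);
4. positions listed in the variant mask (genomic variants, dbSNP-style
   annotations) and positions whose reference base is N are never called.

A retained site is additionally flagged `high_confidence` when at least
`min_heterogeneity` (5%) of its combined mismatches fall outside the modal
mismatch class. We define heterogeneity as the minority-mismatch fraction,
$1 - \max_b c_b / \sum_b c_b$ over the three non-reference bases. The
alternative reading — requiring all three alternative bases to be present —
is subsumed by this fraction at any practical threshold and is less stable
at moderate depth, where a genuine minority class can stochastically drop
to zero. Homogeneous signatures (A-to-I editing, unmasked heterozygous
alleles, which produce a single mismatch class) fail this gate even though
they pass depth, rate and reproducibility.

The depth threshold of 500 unique reads is chosen so that a site at 20%
stoichiometry yields roughly 100 reverse-transcription encounters with the
modification, of which roughly a quarter read through and most of those
misincorporate — comfortably above the 1% rate gate in every replicate
subset. All thresholds are exposed in `filter_config()`.

### Read-through estimation

`estimate_readthrough()` divides depth at the site by the median depth over
the `flank_window` (default 20 nt) positions immediately 3' of it.
Truncations deplete coverage at the site and on its 5' side while the 3'
flank regains coverage from the truncated cDNAs themselves, so at a
full-stoichiometry site the ratio estimates the enzyme's read-through
probability; at partial stoichiometry it estimates $s\,r + (1-s)$, the
fraction of molecules traversing the site. Run this estimator on an
*unclipped* pileup: end clipping removes the first ten aligned bases of
every truncated read and would otherwise shadow coverage in the first ten
flank positions, biasing the median upward.

## CLIP truncation analytics

In antibody CLIP libraries the reverse transcriptase also stops at the
crosslinked antibody-peptide adduct, so read 5' ends map antibody binding
sites at nucleotide resolution. The package provides:

* `termination_profiles()` — counts of read 5' ends at offsets 0..4 from
  each transcription-start site (TSS), for a CLIP library and an RNA-seq
  library built with the same cloning strategy. Only TSSs with at least
  `min_tss_coverage` (5) unique reads at the TSS position in *both*
  libraries enter. Fractions are computed per TSS and then averaged so
  every TSS carries equal weight, and the spread is reported as the
  standard error across TSSs; pooling reads before normalising would let a
  few deep transcripts dominate the aggregate.
* `call_clusters()` — transitive merging of same-strand overlapping reads
  into maximal intervals, scored by the maximum stacked depth (peak height)
  rather than the total read count; "stacked" describes a local pile, not
  interval membership. Default retention score is 20.
* `metagene()` — a deliberately simple metagene: each cluster or read is
  reduced to its midpoint, mapped to a region-relative fraction (5'UTR,
  CDS, 3'UTR; 30 bins each), and the per-bin density is divided by the
  RNA-seq read-midpoint density in the same bin. Bins with zero RNA-seq
  density are reported missing rather than infinite; transcripts lacking
  any of the three regions are skipped. Normalisation to RNA-seq is the
  operative idea; no attempt is made to reproduce any particular external
  metagene tool bin-for-bin.
* `tss_start_enrichment()` — a 2x2 cross-tabulation of TSSs by start
  nucleotide (A versus other) and cluster overlap, tested with a two-sided
  Fisher's exact test. The background is the full TSS catalogue, not only
  expressed transcripts; restricting the catalogue is the caller's choice.
  Degenerate margins report fractions with a p-value of 1 and a warning.

## Site-list curation

`curate()` applies three defect filters to an external site list in a fixed
order — missing or retired gene identifier, non-adenosine nucleotide,
duplicate genomic coordinate (isoform duplicates keep their first record)
— and tallies each. `tss_overlap()` then counts curated sites coinciding
with annotated TSSs, with CAGE/m6Am-inferred TSSs, and with their union;
`make_curation_fixture()` builds a deterministic synthetic 474-record list
whose defect classes are mutually disjoint (3 bad-gene, 37 non-A, 82
duplicates, 352 kept) with TSS catalogues arranged so 19 kept sites are
annotated TSSs, 134 are CAGE/m6Am TSSs and 13 are both, i.e. 140 at a
transcription start in total. The 19/134/13 split is the unique composition
consistent with those published totals under the union reading, which we
adopt. Matching tolerance defaults to 0 (exact coordinate); CAGE evidence
is regional in nature, so a tolerance flag is provided.

## The simulator

`simulate_dataset()` generates the full study design from one seed:
random transcripts (uniform base composition; a configurable fraction
forced to start with adenosine, default 0.85, mimicking Initiator-driven
starts), each its own plus-strand reference sequence with TSS at position
0 and 5'UTR/CDS/3'UTR annotations at 20%/50%/30% of the length.

Per molecule: a transcript is drawn, cut into consecutive fragments
averaging `fragment_mean` (250 nt, with the first fragment always starting
at the cap — this is what concentrates RNA-seq read 5' ends at offset 0);
reverse transcription proceeds 3' to 5' through each fragment and, at a
modified position on a modified molecule, terminates with probability
$1-r$ (the truncated cDNA is retained and cloned, as in both protocols) or
reads through, misincorporating with probability $m$ from an A->T-dominated
spectrum (0.8/0.1/0.1). Reads are the first `read_length` (50) nt from the
cDNA's truncation end. Uniform sequencing error (default $10^{-3}$),
per-fragment 8-nt UMIs and single-copy PCR duplication (rate 0.1) follow.
Heterozygous SNP decoys place a pure alternative base on half the
molecules, homozygous on all; editing decoys place A->G on a configurable
fraction (0.2). In CLIP mode, a crosslinked molecule (rate 0.9) terminates
at TSS offset 0..4 drawn from a mixture defaulting to
0.45/0.40/0.07/0.05/0.03 — weights beyond "mostly 0 and +1" are free
parameters of the generator — and non-crosslinked fragments survive the
washes with probability 0.05. An optional `dimroth_loss` parameter models
heat/base-driven conversion of the modification to a silent isomer as a
stoichiometry loss; it defaults to 0.

Defaults follow the published account of the data they emulate: 20
replicates, 50-nt reads from ~250-nt inserts, 20% stoichiometry, 20-30%
read-through ("most" read-throughs misincorporating), A->T-dominated
spectra.

### Truth placement and problem sizes

Because reads are anchored at the cDNA truncation end, coverage is not
uniform along a transcript: the first ~40 nt (the cap-proximal window that
every molecule's first fragment sequences) run roughly an order of
magnitude deeper than the body. `truth_placement = "five_prime"` puts
planted modification and editing sites in that window (offsets 14-36,
clear of the 10-nt clip), which both matches the TSS-proximal question
this method family addresses and lets a simulation reach >1000x combined
site depth with ~30,000 reads per dataset. The recovery experiments in the
test suite use 100 such datasets (3 transcripts x 400 nt, 20 replicates,
750 molecules each, stoichiometries 0.1-0.5); the acceptance script uses
25. Interior placement remains the default for generic use.

What the generator does *not* emulate: realistic transcript-abundance
distributions (molecules are drawn uniformly), indel errors, base-quality
structure, sequence-dependent misincorporation spectra, alignment
ambiguity, and double-stranded library artefacts. Passing the recovery
suite therefore demonstrates that the filter chain separates planted
hard-stop signatures from error, SNPs and homogeneous editing under the
stated generative model — not that it is robust to every artefact of real
libraries, where alignment quality and annotation errors add failure modes
of their own.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere in memory; SAM/VCF convert
  on input, TSV output is 1-based. BED is consumed and produced 0-based.
* Heterogeneity ties on the modal mismatch base are broken in fixed base
  order A<C<G<T; the value is tie-break-invariant since only the modal
  count enters.
* `misincorporation_rate()` and `heterogeneity_fraction()` refuse zero
  depth and zero mismatches respectively rather than returning NaN —
  callers must not interrogate uncovered positions.
* Depth-0 pileup columns are never materialised; deletions contribute no
  count at the deleted position (only the four nucleotides are counted);
  N read bases and N reference positions contribute nothing.
* Duplicate collapsing keeps the first read in input order; cluster
  calling and candidate calling are input-order invariant.
* The simulator draws all randomness from R's default generator under one
  integer seed; a dataset is a deterministic, platform-stable function of
  its configuration.

## Limitations

Misincorporation mapping reveals misincorporations, not chemical identity:
a called site is a putative hard-stop modification, and distinguishing
m1A from, say, m3C or m2,2G requires orthogonal biochemistry. Sites in the
first ~250 nt of short RNAs processed from longer precursors, and the 5'
ends of mRNAs generally, are hard to assess in standard RNA-seq because
coverage decays toward the cap. Low-stoichiometry sites fall below the
rate gate by design; lowering `min_rate` trades sensitivity against the
sequencing-error floor.
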