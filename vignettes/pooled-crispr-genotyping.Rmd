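---
title: "Genotyping pooled CRISPR/Cas9 mutant libraries from barcoded amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping pooled CRISPR/Cas9 mutant libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcrispr)
```

## The problem

Pooled CRISPR/Cas9 transformation turns one *Agrobacterium* infection into a
whole mutant population: a plasmid library carrying hundreds of sgRNAs is
transformed in bulk, and every regenerated plant receives an essentially
random guide (occasionally two or more). The genotype of each plant is then
unknown until sequenced. Two questions must be answered for every plant:

1. **Which sgRNA(s) does it carry?** Answered by amplifying the integrated
   sgRNA cassette and reading the 20-nt spacer.
2. **What did Cas9 do at the corresponding target site?** Answered by deep
   sequencing a short amplicon spanning the predicted cut site and calling
   indel/substitution alleles.

Because thousands of plants are genotyped at once, both PCRs carry 9-nt
sample barcodes on the 5' ends of the primers; combining a forward barcodes
with b reverse barcodes distinguishes a x b samples from a + b primers, so
44 primers suffice for a 384-sample batch (the optimal split, 22 x 22,
distinguishes 484).

`poolcrispr` implements this workflow end to end — library design checks,
barcode design, demultiplexing, sgRNA identification, editing-event calling,
cohort summaries and T0-to-T1 inheritance analysis — together with a
truth-tracked read simulator used to validate the whole pipeline.

## Guide selection and the off-target mismatch filter

Candidate targets are all 20-nt protospacers adjacent to an NGG PAM, on
either strand (`enumerate_sites()`). The off-target filter is a minimum
Hamming distance over the protospacer against every *other* NGG site:
a guide is kept only when that minimum is **greater than 2 mismatches**
(`filter_sgrnas()`, threshold exclusive). Design choices worth noting:

* The PAM must be NGG at both sites but contributes no mismatches; only
  the 20-nt target sequence is compared.
* `N` never matches any base, including another `N` — conservative in the
  direction of rejecting guides.
* A guide with no competing site at all reports the sentinel distance 21
  (one more than the maximum possible), keeping the statistic integral and
  totally ordered.
* Only NGG sites are searched. NAG-PAM off-targets are not counted; with a
  mismatch filter this strict the additional NAG class changes little, and
  the filter stays exactly the published rule.
* Within a gene, accepted guides are ranked by position (5'-most first).
  This is a declared stand-in: the original selection used an external
  scoring service whose ranking is not reproducible.

Primer pairs for the target amplicons obey three sequencing-driven
constraints (`validate_amplicon()`): products at most 280 bp (short-read
chemistry), at least a 30 bp gap between each primer's inner edge and the
cut site (so typical indels cannot destroy a priming site), and melting
temperatures inside 58-60 °C so one cycling condition serves every pool.
Tm uses the salt-free approximation `64.9 + 41*(GC - 16.4)/len`; the
constraint band is the published one, the formula is a package choice.
Accepted primer pairs are split into balanced sub-pools
(`partition_pools()`): 969 pairs over 24 pools gives nine pools of 41 and
fifteen of 40.

## Barcodes and demultiplexing

`design_barcodes()` builds 9-nt barcode sets by greedy randomized search
under three constraints: minimum pairwise Hamming distance (default 3),
GC fraction 30-70%, and homopolymer runs of at most 3. The distance
default guarantees that any single sequencing error still decodes uniquely
to its source barcode; GC and homopolymer bounds are synthesis-friendliness
conventions. The construction is deliberately greedy rather than optimal:
reproducibility under a seed matters more here than squeezing out the last
few codewords.

`demultiplex()` reads the forward barcode as the 5'-terminal 9-mer and the
reverse barcode as the reverse complement of the 3'-terminal 9-mer (a
single merged-read model). Decoding is nearest-neighbour within
`max_mismatch`; reads tied between two barcodes are counted *ambiguous*,
never assigned — mis-genotyping a plant is worse than dropping a read. The
default is exact matching (`max_mismatch = 0`). The radius is rejected
up front unless it is below half the realized minimum barcode distance.

## sgRNA identification

The spacer is extracted from cassette reads as the 20 nt immediately 5' of
an exact occurrence of the invariant scaffold anchor (default: the first
12 nt of the scaffold, `GTTTTAGAGCTA`). Matching against the library is by
exact 20-mer identity — the published protocol extracted spacers from
perfectly matched cassette sequence, and exact matching keeps multi-guide
calls unambiguous. A guide is called when it has at least `min_reads = 10`
supporting reads *and* at least `min_fraction = 0.05` of extracted
spacers; the thresholds are declared defaults, not inferred from data, and
calling is monotone in both. Plants with no extracted spacer are Negative.
Cohort multiplicities are tabulated into Negative/1/2/3/>3 classes, where
">3" means four or more (the simulator draws that class as exactly 4).

## Editing-event calling

Target reads are aligned globally to their reference amplicon under affine
gap scoring (match +2, mismatch -4, gap open -10, gap extend -1 per base).
Among co-optimal placements, indels are normalized to their **leftmost**
equivalent position — insertions rotate their inserted sequence while
shifting — so that event identity `(kind, start, length, alt_seq)` is
well-defined across reads, plants and generations. Maximal runs of
contiguous mismatches form one substitution event (a 2-nt run is one `/2`,
not two `/1`). Events are rendered in compact notation: `-n` deletion,
`+n` insertion, `/n` substitution.

A read counts as *edited* when it carries at least one retained event
overlapping the window `cut_offset ± 10` bp. The window is a package
choice: the observed indel bulk is 1-4 bp at the cut, and ±10 bp covers it
while excluding distal PCR artefacts. Retention requires
`min_event_reads = 2` supporting reads *and* a `min_event_freq = 0.005`
read fraction — a noise floor against sequencing error and PCR mosaicism.
Reads aligning at below 60% identity are excluded from the denominator as
off-target amplification. The central statistic is

> editing frequency = edited reads / total aligned reads,

and a plant is **edited** when the frequency strictly exceeds 1% — exactly
1.0% classifies as non-edited, a boundary the tests pin down explicitly. A
single event at frequency ≥ 0.9 raises a `putative_homozygous` flag; the
flag never feeds any statistic. Adjacent events on one read are reported
separately rather than merged into compound-allele tokens: published
compound notations are not formally defined, so the package keeps its own
canonical per-event tokens.

## Inheritance (T0 to T1)

An editing type is *heritable* when a progeny plant carries an event
identical to one of its parent's — same kind, left-normalized position,
length, and (for insertions/substitutions) the same sequence. Per-plant
heritability is the matched fraction of the parent's events; a parent with
no passing events leaves heritability undefined (reported missing,
excluded from means). The cohort rollup reports the mean per-plant
heritability (per-line means are also reported, per-plant is primary),
the share of fully faithful progeny, and the share of progeny with at
least one novel event — continued Cas9 activity across generations.
`frequency_trajectory()` flags lines whose progeny editing frequencies all
exceed the parent's, the characteristic escalation of weakly edited
primary transformants.

## The simulator: what it emulates, and what it does not

`simulate_t0()` / `synthesize_reads()` generate a cohort with the
statistical structure the analysis assumes, with every random choice
recorded as ground truth down to the individual read. Defaults mirror the
genotyped cohort the package is built around:

* sgRNA multiplicity per plant: 21.81 / 73.55 / 4.20 / 0.29 / 0.14 % for
  0/1/2/3/4+ guides;
* editing-outcome mixture: 77.66% deletions, 17.90% insertions, 4.44%
  substitutions; deletion lengths geometric on 1-30 bp (p = 0.55),
  insertions dominated by +1 (P(1) = 0.9, geometric tail to 10 bp),
  substitution runs uniform on 1-4 bp;
* events per plant and target: 13% one event, 39% two, 7% ten or more,
  the remainder spread evenly over 3-9;
* per-plant edited-read fraction: a uniform mixture with 75.6% of mass on
  (0.8, 1), emulating the strongly edited bulk, a middle component on
  (0.01, 0.8) and a small sub-threshold component. The published
  per-plant frequency distribution is only available as a histogram
  figure; this mixture reproduces its class shares, not its shape.

Events are placed so that their interval overlaps `cut ± 5` bp *after*
left-normalization, guaranteeing that a correctly recovered event also
falls inside the ±10 bp calling window. Reads carry constant Q40 quality
strings: the analysis is count-based and never consults qualities.
Sequencing error is i.i.d. per-base substitution (default 0.001);
`chimera_rate` swaps a read's barcode pair for another plant's, emulating
index hopping / template switching. Alleles are sampled multinomially at
their true frequencies, so the per-read truth table — not the intended
frequency — is the reference for exact-recovery tests.

Not modelled: indel sequencing errors, quality-dependent error profiles,
PCR duplicates and amplification bias, paired-end merging artefacts, and
somatic mosaicism beyond the allele-frequency mixture. A passing
end-to-end test therefore demonstrates the pipeline's correctness on
structurally faithful data, not robustness to every real-world artefact.

`simulate_t1()` transmits each parental event independently with
probability `inherit_prob` (default 0.8478) and adds one novel event per
progeny with probability `novel_rate` (default 0.0836); per-target
editing frequencies are redrawn on (0.8, 1) because editing consolidates
in progeny. Independent transmission is a simplification — real alleles
segregate — but the identity-matching statistics downstream are agnostic
to phasing.

## Numerical choices and degenerate inputs

* Percentages print half-up to 2 decimals (`4/1380` is 0.29); base R's
  round-half-even would disagree with printed cohort tables.
* All coordinates are 0-based, forward-strand; the cut offset is the base
  immediately 3' of the blunt cut (`start + 17` on `+`, `start + 6` on `-`
  when `start` is the 23-mer window start).
* Zero reads yield an empty non-edited profile (frequency 0), empty
  demultiplexing input yields an all-zero report, an empty genome yields
  an empty site table; none of these error.
* Site enumeration caps at 10^6 sites: the all-vs-all mismatch filter is
  quadratic and the package's contract is desk-scale amplicon panels, not
  genome-scale indexes.
* Alignment ties are broken deterministically by the left-shift
  normalization; the test suite checks the result against exhaustive
  enumeration of all co-optimal alignments on short amplicons.

## Validation strategy and problem sizes

The test suite validates each operation against independent oracles
(brute-force site scans, exhaustive pairwise Hamming, exhaustive
co-optimal alignment enumeration) and the pipeline end to end against the
simulator's per-read truth. The end-to-end check runs the full study
geometry — 1,380 plants at depth 500, error-free — and requires 100% sgRNA
assignment recovery and every realized event at its exact read count;
parameter-recovery checks run 20 progeny cohorts of ~275 plants. With
sequencing error enabled, recovery is asserted for major alleles with
tolerance for error-induced read loss. Noise thresholds
(`min_event_reads`, `min_event_freq`) are zeroed in the error-free
recovery tests: they exist to absorb noise that those runs deliberately
lack.

## Worked example

```{r example, eval = FALSE}
lib <- simulate_library(n_genes = 10, sgrnas_per_gene = 2, seed = 1)
scheme <- barcode_scheme(design_barcodes(8, seed = 2),
                         design_barcodes(8, seed = 3),
                         sample_ids = sprintf("T0_%04d", 1:60))
cfg <- sim_config(n_plants = 60, depth = 300, seed = 4)
truth <- simulate_t0(cfg, lib$library, lib$amplicons, scheme)
reads <- synthesize_reads(truth, lib$library, lib$amplicons, scheme)

res <- run_genotyping(reads$cassette, reads$target, scheme,
                      lib$library, lib$amplicons, max_mismatch = 1)
mult <- multiplicity_summary(
  res$sgrna$multiplicity[truth$plants$plant_id], 60)
ed <- summarize_editing(plant_max_profiles(res$profiles),
                        n_analyzed = sum(truth$plants$n_sgrnas > 0))
```

## Known limitations

* Off-target counting is Hamming-only (no bulges) and NGG-only.
* Guide ranking within a gene is positional, not activity-scored.
* Compound alleles (several events on one physical allele) are reported
  event-wise; the optional compound rendering is deliberately out of the
  default path.
* The demultiplexer models single merged reads, not paired FASTQ pairs.
* Heritability matching requires exact event identity; a 1-bp placement
  difference after normalization counts as novel, which is the intended,
  strict reading of "identical".
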