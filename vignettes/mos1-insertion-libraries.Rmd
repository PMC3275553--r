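---
title: "Modelling Mos1 insertion libraries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Mos1 insertion libraries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mos1tk)
```

`mos1tk` re-creates, at desk scale, the computational side of building a
genome-wide *Mos1* transposon insertion collection: simulating the insertion
library, recovering insertion sites by in-silico inverse PCR, mapping the
flanks, collapsing redundant alleles, and characterising the genome-wide
distribution of the result. This vignette explains the models behind each
stage, the parameters that matter, and the design decisions taken where the
underlying protocol left room for interpretation.

## Coordinate conventions

All coordinates are 1-based closed intervals, the GFF convention. *Mos1*
inserts at a TA dinucleotide, so an allele occupies the 2-bp span
`[position, position + 1]` where `position` is the first base of the target
TA. Strand is not recorded for alleles: TA is its own reverse complement and
insertion sites are conventionally reported strand-free. BED output converts
to 0-based half-open coordinates on write only.

## The synthetic library

`sim_config()` fixes the study conditions; `simulate_genome()`,
`simulate_insertions()` and `inject_artifacts()` realise them.

**Genome.** Random sequence at a configurable GC content (default 0.36,
nematode-like — TA-site density rises as GC falls, and the default yields
roughly one TA per 9–10 bp). Gene models are placed without overlap, allocated
to chromosomes in proportion to length, with exon counts and exon/intron
lengths drawn uniformly from configured ranges (defaults 3–8 exons of
50–300 bp separated by 40–400 bp introns, about one gene per 5 kb — the gene
density of the worm genome). Coding exons equal exons for protein-coding
genes; UTRs are not modelled, which slightly inflates the CDS fraction
relative to a real annotation but affects insertions and the TA baseline
identically. A small fraction of genes (default 5%) is non-coding and excluded
from the protein-coding universe used by the coverage table.

**Insertions.** Each strain draws a Poisson number of insertions. The
protocol's pooled-library measurements put the mean at 2.0 insertions per
haploid genome, which is the default; the distribution around that mean was
never reported, so Poisson — the natural model for independent integration
events — is an assumption, and strains drawing zero insertions are retained
(they later fail inverse PCR, emulating unproductive lines). Sites are drawn
without replacement within a strain from the genome's TA sites, uniformly by
default; hotspot weights multiply individual sites, and a germline-gene weight
exists but defaults to 1 because the real collection showed no germline
enrichment.

**Plates, serials, and allele names.** Strains are numbered sequentially in
production order and packed into 24-well plates, and molecular
characterization records one allele per strain, named `ttTi<serial>` — exactly
as in the real project, where allele numbers run in strain-production order
and one band per strain was sequenced. This choice matters: it is what makes
allele-number proximity informative. Two alleles from the same plate differ by
fewer than 24 numbers, so the "< 25" signature of plate-local contamination is
an emergent property of the numbering, not something the simulator asserts.

**Artifacts.** Two mechanisms observed in the real collection are modelled.
A *resident insertion* — a *Mos1* copy already fixed in the starting strain —
is added to a Bernoulli(`resident_fraction`, default 0.03) subset of strains;
for carriers the recorded allele becomes the resident coordinate, since its
amplicon is recovered from every carrier lysate. *Cross-contamination*
(probability `contamination_rate` per recorded allele, default 0.05) copies an
allele's template into a different random well of the same plate; the
recipient strain then records the contaminant coordinate under its own serial.
Both defaults are order-of-magnitude choices consistent with the redundancy
level seen in the real data (roughly a fifth of characterized alleles were
redundant, dominated by a single resident site carried by hundreds of
strains). Chained events can overwrite one another; the generator records
which injected events survive in the final table so tests can compare
recovered redundancy against injected truth exactly.

## In-silico inverse PCR

For an insertion at `position`, the genomic flank runs 3′ of the TA junction
on the plus strand, from `position + 2` through the end of the nearest
downstream recognition site (`GATC` for MboI, `GGCC` for HaeIII):

```
flank_len = site_start − (position + 2) + 4
amplicon_len = primer_offset + flank_len
```

A band is purified only when `amplicon_len` strictly exceeds the enzyme's
size threshold — 270 bp for the MboI protocol, 325 bp for HaeIII. The
transposon-internal contribution (`primer_offset`) is set equal to the
threshold: the primer geometry of the original nested PCR was not published,
and this choice reproduces the filter's intent exactly — a product passes iff
it contains at least one informative flanking base, and transposon-only
products are rejected. Only one transposon end is simulated (one nested primer
pair); two-end simulation would double band counts without changing any
downstream logic.

When a strain yields several passing bands, the shortest passing amplicon is
selected as the strongest-band proxy (shorter templates amplify more
efficiently); ties break on lower (chromosome, position). Strains with no
passing MboI band are retried with HaeIII, mirroring the two-enzyme protocol.

Sequencing noise has two knobs: `q_fail` (read unusable) and `q_jitter`
(junction reported with a uniform offset in ±10 bp, the protocol's stated
precision limit for poor-quality junctions). With both at zero the pipeline is
fully deterministic given the seed.

## Mapping

Flank reads are located by exact substring search over both strands of every
chromosome (Biostrings). BLASTN heuristics would add nothing for error-free
substrings, but the published filter semantics are preserved: reads matching
two or more loci are *ambiguous* and discarded; reads shorter than
`min_flank_map_len` are not attempted. The default of 18 bp keeps the expected
number of chance hits far below one on megabase genomes (4^18 ≈ 7 × 10^10).
A unique hit defines a junction immediately 5′ of the match (3′ of it for
minus-strand hits, mapped back to plus-strand coordinates), which is snapped
to the nearest TA within `snap_radius` (10 bp).

One numerical caveat: when the junction was jittered by up to 10 bp, snapping
to the *nearest* TA can, in TA-dense regions, choose a site on the far side of
the shifted junction. The pre-snap junction is always within the jitter radius
of the truth, but the snapped coordinate is only guaranteed within
`jitter + snap_radius` (20 bp). Such reads are flagged `precise = FALSE`, so
the 10-bp collapse step treats them conservatively anyway.

## Redundancy collapse

Alleles more than 10 bp apart are considered unique — the conservative
convention of the original analysis. Within each chromosome, alleles sorted by
(position, allele number) are chained by single linkage: an allele joins the
open cluster iff it lies within `dedupe_max_sep` of the previous allele. The
protocol behind the published counts was not spelled out; single-linkage
chaining is the simplest reading consistent with "more than 10 bp apart", and
it reproduces the published 13,334 → 10,858 collapse when run on the exported
supplementary table. Each cluster's representative is its lowest allele number
(the earliest-isolated allele; the published choice among coincident alleles
was explicitly arbitrary). Classification then counts redundant alleles whose
coordinate exactly equals their representative's — equivalent to matching any
unique allele, since an equal-coordinate unique allele would have been chained
into the same cluster — and, among those, the pairs with allele-number
difference below 25.

## Distribution statistics

* **Chromosome proportionality** — chi-square goodness of fit of
  per-chromosome allele counts against expectations proportional to
  chromosome length, `df = n_chrom − 1`. A single-chromosome genome returns
  p = 1 by convention.
* **Gaps** — nearest-neighbour distances 5′→3′ within each chromosome, pooled
  across chromosomes for the mean (the convention that reproduces the
  published 9,230-bp mean over 10,852 gaps); cumulative fractions use strict
  `<`. Chromosomes with fewer than two alleles contribute no gaps, and an
  empty gap set reports its mean as missing rather than zero.
* **CDS context** — an insertion is in-CDS iff at least one base of its 2-bp
  span lies in the merged CDS union; the same rule applies to TA occurrences
  for the motif baseline. The published text treats "TA (or AT)" loosely; the
  default motif set is `{TA}` (the actual insertion target), and
  `motifs = c("TA", "AT")` is available where the broader reading is wanted.
* **Gene-set enrichment** — exact two-sided binomial: the p-value sums
  `P(j)` over all outcomes with `P(j) ≤ P(k)` (with the customary
  `1 + 1e-7` relative tolerance for floating-point ties). The null proportion
  for the germline question is hit *protein-coding* genes over the
  protein-coding universe (4,586 / 20,414). The alternative null — all hit
  genes including non-coding, 4,948 / 20,414 — would push the test below
  0.05 and contradict the published non-significance, which is why the
  protein-coding universe is the implemented default.

## Coverage and locator

MosTIC reachability is operationalised as ±`mostic_flank` (1,500 bp) windows
around each allele's 2-bp span, clamped to chromosome ends, with overlapping
*and bookended* windows merged so contigs are maximal contiguous intervals. A
protein-coding gene counts as reachable iff its span overlaps a contig by at
least 1 bp (containment is a special case). The locator answers the inverse
query — alleles within a gene, or within a distance of it — by padding the
gene span (or its exons, with `exon_only = TRUE`) and intersecting with allele
spans; "close to exons" is given the same distance parameter as the gene-level
query, since no separate definition was published. Setting the locator
distance to 1,500 bp reproduces, gene by gene, membership in the coverage
table's reachable set; the two modules are cross-checked against each other
and against a per-base bitmap oracle in the test suite.

## Problem sizes, determinism and limitations

The default simulation — three 1-Mb chromosomes, 600 genes, 500 strains —
runs the full pipeline in well under a minute and gives a few hundred mapped
alleles: large enough for the binomial and chi-square checks to have power,
small enough to iterate on. All randomness flows from a single integer seed
through independently derived per-stage streams, so any stage can be re-run
reproducibly in isolation; fixed seeds give byte-identical FASTA/GFF/TSV
outputs.

What the generator does *not* emulate, and what passing tests therefore do
not establish about real data: sequence-composition biases of a real genome
(repeats — the main driver of the ~50% ambiguity rate in the real project —
are absent, so synthetic ambiguity is rare), UTR structure, alternative
transcripts, chromosomal heterogeneity in gene density, and any thermodynamic
realism in PCR (no chimeric ligation products, no band-intensity model beyond
the shortest-amplicon proxy). The real-data figures that depend on the worm
genome — 50.4% of insertions in CDS versus a 57.3% CDS genome fraction and a
55% TA baseline, or specific locator answers — are reproduced only when the
real annotation and allele list are supplied; the package's tests establish
the arithmetic on published count tables and the internal consistency of
every stage against ground truth and brute-force oracles.
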