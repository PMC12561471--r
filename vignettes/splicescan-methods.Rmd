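---
title: "Methods: AS-event enumeration, motif targeting, and PSI-based differential splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AS-event enumeration, motif targeting, and PSI-based differential splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescan)
```

## The analysis this package implements

Many RNA-binding proteins (RBPs) recognize short, nearly exact sequence
motifs on pre-mRNA. When such a motif concentrates at exon–intron
junctions on the sense strand, the protein is a candidate regulator of
splicing, and its loss should shift percent-spliced-in (PSI) values of
the events it touches. `splicescan` provides the full desk-side chain of
that argument:

1. build a gene model from FASTA + GTF (`read_genome_fasta()`,
   `read_gtf()`);
2. enumerate alternative-splicing (AS) events of the five classic
   classes — skipped exon (SE), retained intron (RI), mutually exclusive
   exons (MXE), alternative 5′/3′ splice site (A5SS/A3SS) — from
   transcript pairs (`enumerate_events()`);
3. scan the genome for exact motif occurrences on both strands and
   classify each hit as exonic, intronic, junction-spanning or
   intergenic, sense or antisense (`scan_motif()`, `annotate_hits()`);
4. compute the fraction of each event class "targeted" by the motif
   within a window of its splice sites (`targeted_events()`) and the
   hit-to-splice-site distance profiles (`distance_density()`,
   `event_site_distance_profile()`);
5. quantify PSI from junction read counts and call differential
   inclusion between conditions (`compute_psi()`,
   `differential_inclusion()`), plus exon-level RPKM for targeted
   follow-up of single regions (`exon_rpkm()`).

A seeded simulator (`sim_config()`, `simulate_splice_genome()`,
`simulate_junction_counts()`) generates toy genomes with planted ground
truth so each stage's estimator can be validated end to end.

## Coordinates and the gene model

All internal coordinates are 0-based half-open; GTF's 1-based inclusive
convention is converted exactly once at the file boundary (and back on
write). A "splice boundary" is a single integer position `b` sitting
between bases `b-1` and `b`. This makes junction arithmetic free of
off-by-one ambiguity: an intron between exons `(s1,e1)` and `(s2,e2)` is
exactly `(e1, s2)`, and exon lengths plus intron lengths always add to
the transcript span (a tested invariant).

Only `exon` features are consumed from GTF. AS-event enumeration needs
exon structure alone; CDS/UTR sub-annotations are deliberately ignored,
and region-level coverage questions (e.g. the 5′UTR part of one exon)
are handled by user-supplied intervals in `exon_rpkm()`.

## Event definitions

Events are detected per unordered transcript pair and deduplicated by
their canonical coordinate tuple, so isoform-rich genes do not inflate
counts:

* **SE** — transcript A carries internal exon `(s2,e2)` between flanks
  ending at `e1` and starting at `s3`; transcript B has the direct
  junction `e1→s3` and no exon overlapping `(s2,e2)`.
* **RI** — one exon of A spans exactly two consecutive exons of B, with
  both outer boundaries shared; the retained intron is the gap.
* **A5SS/A3SS** — two junctions share one boundary and differ at the
  other; the differing boundaries must come from *overlapping* exon
  forms. Donor/acceptor labels follow the strand (on `-`, the genomic
  left edge of an intron is the acceptor). Without the overlapping-exon
  requirement, the flanking junctions of every SE and MXE would
  spuriously count as alternative splice sites; with it, each simulated
  gene yields exactly its one intended event (a tested round trip).
* **MXE** — internal exons of A and B share both flanking junction
  partners, do not overlap, and neither transcript contains both.

A useful symmetry worth stating precisely: relabeling a gene's strand
with coordinates fixed exchanges donor and acceptor roles and therefore
swaps A5SS↔A3SS, while reverse-complementing the whole frame (mirroring
positions *and* flipping the strand) preserves every class — both are
property-tested against a brute-force oracle.

## Motif orientation and scanning

RBP motifs from SELEX experiments are often printed 3′→5′. For the
default primary motif here the printed string, read 5′→3′, contains
`AG|GUAAGU` — the canonical 5′ splice-donor consensus — so the package's
default (`orientation = "as_printed"`) treats the printed string as the
5′→3′ query after U→T substitution; `orientation = "reversed"` is kept
as an explicit switch and both modes log the resulting query, so the
typographic ambiguity stays visible instead of being silently resolved.
Matching is exact (the motif is a single string, not a PWM); overlapping
occurrences are all reported, `N` never matches, and the scanner is
property-tested against a naive position-by-position oracle on both
strands.

A hit is **junction-spanning** when a splice boundary falls strictly
inside its interval — a hit merely abutting a boundary belongs to the
flanking feature. This strict-interior rule is the unambiguous geometric
reading of "targeting the exon–intron junction" and is what the
simulator plants. Signed hit-to-boundary distances are measured from the
hit's 5′-most base in the gene's transcription orientation, positive
downstream; the anchor choice is conventional, consistent between
`annotate_hits()` and the event-level profiles.

## Targeting and its window

An event is *targeted* when a sense-strand hit intersects
`[site - W, site + W + 1)` for any of its splice sites. The window
half-width `W` (default 50 bp) is an explicit, logged parameter of every
summary rather than a hidden constant: targeted fractions are
monotonically non-decreasing in `W` (tested), so reporting a fraction
without its window would be meaningless. A more permissive whole-span
definition is reported alongside (`targeted_span`) for sensitivity
checks. Per-class fractions carry exact (Clopper–Pearson) binomial 95%
intervals, and `compare_targeting()` contrasts two runs per class with
Fisher's exact test and Benjamini–Hochberg correction across the five
classes.

## PSI and the junction-count model

For each event, PSI is effective inclusion over total informative reads.
Where inclusion is read out on two junction classes (SE: upstream and
downstream inclusion junctions; RI: the two exon–intron boundary
classes; MXE: each side's two junctions), the two class counts are
averaged before forming the ratio. The averaging is not cosmetic: an
inclusion isoform exposes two informative junctions against one for the
exclusion isoform, so raw inclusion reads arrive at probability
`2*psi/(1+psi)` rather than `psi`; halving restores an estimator whose
ratio converges to PSI. The simulator draws counts from exactly this
model — Poisson totals, a per-replicate inclusion proportion from a Beta
distribution with mean `psi_true` and intra-class correlation `rho`,
binomial reads at the junction-representation-adjusted probability, and
a uniform split across junction classes — so estimator and generator are
consistent by construction, and pooled PSI recovers truth with mean
absolute error ≈ 0.03 at depth 100, `rho = 0.01`, three replicates
(tested at 1000 events).

## The differential test

Replicates are overdispersed: biological variability makes the
per-replicate inclusion proportion itself random (beta-binomial, with
intra-class correlation `rho`). A test on pooled counts that ignores
this is anti-conservative — in the package's own asymmetric-truth
simulation the pooled Fisher test realized an FDR of ~0.16 at a nominal
q ≤ 0.05. The default test is therefore a **beta-binomial
likelihood-ratio test** with a single dispersion shared across events
(method-of-moments estimate from within-condition variation, in the
spirit of shared-dispersion moderation in count-based differential
tools): per event, the likelihood under one common inclusion proportion
is compared to separate per-condition proportions, with `rho` held at
the shared estimate. This restores calibration (realized FDR ≈ 0.04,
null call fraction ≈ 0) at essentially no cost in power for
moderate-to-large effects. When no overdispersion is estimable — single
replicates, or a zero estimate — the test reduces to the two-sided
exact test on the pooled 2×2 table, which can also be forced with
`test = "pooled"`.

Calls require both `q <= q_max` (default 0.05) and
`|delta PSI| >= dpsi_min` (default 0.1, on pooled PSI); both thresholds
are echoed in results and run manifests. Direction is reported as
increased/decreased/unchanged so that asymmetric regulation — many more
introns gaining than losing retention after knockout, say — is visible
as a tally, which is how the simulation studies here summarize recovery
of planted 100-up/30-down truth.

## What the simulator does and does not emulate

Each simulated gene has exactly two isoforms realizing one event of a
class drawn from `event_mix`; defaults plant a sense-strand motif copy
straddling a random event splice site with probability 0.40 for
A3SS/A5SS and 0.20 for SE/RI/MXE, mirroring the targeted proportions the
package is designed to measure; exons are 80–200 bp, introns 120–300 bp,
alternative-site shifts 20–60 bp, read depth 100 with `rho = 0.01` and
three replicates per condition — magnitudes a mammalian short-read
splicing study would find unremarkable. Background sequence is uniform
over {A,C,G,T} and *scrubbed* of chance motif occurrences beyond the
configured background rate (default 0), so junction enrichment in the
emitted genome is attributable to planting alone and enrichment tests
are sharp.

Passing tests on these data therefore demonstrate correctness of the
geometry, the estimators and the calibration — not robustness to what
real data add: isoform-rich genes (a complexity knob exists but default
genes are minimal two-isoform constructs), non-uniform base composition,
inexact motif matches, alignment artifacts in junction counts, and
coverage that varies along the transcript. Genome-scale hit counts from
a real annotation are build-dependent and are not comparison targets.

## Numerical and degenerate-input choices

* PSI is undefined (NA), not 0, below `min_reads` informative reads
  (default 10).
* Events with zero informative reads in either condition are excluded
  from testing, with a message and a count in the result.
* Empty event classes propagate as zero-count rows with NA intervals,
  and class comparisons skip them with a warning rather than failing.
* The beta-binomial likelihood is evaluated on effective
  (possibly non-integer) counts; the 1-D profile likelihood optimizations
  run on `mu` in `(1e-6, 1 - 1e-6)`.
* Output tables are canonically sorted (events by `event_id`, hits by
  position) and run manifests record md5 checksums keyed by file name,
  so identical seeds give byte-identical runs wherever they execute —
  the determinism contract is tested at the pipeline level.

Simulation sizes used by the test suite — 2500 genes (≈500 events per
class) for targeted-proportion recovery, 1000 retained-intron events for
PSI and differential studies, 20 replicates for null calibration — are
the package's chosen working scales: large enough that binomial
confidence intervals separate 0.40 from 0.20 and FDR estimates are
stable, small enough to run comfortably on a laptop.
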