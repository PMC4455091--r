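---
title: "Predicting the genomic location of chromatin-bound proteins from ChIP-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the genomic location of chromatin-bound proteins from ChIP-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipms)
```

## The method

ChIP-MS turns chromatin immunoprecipitation inside out: instead of asking
*where* one protein binds, it precipitates chromatin carrying a
characteristic histone modification — H3K4me3 (active promoters), H3K4me1
(enhancers), H3K27ac (highly active promoters and enhancers), H3K9me3
(heterochromatin) — and identifies by mass spectrometry *which* proteins
came along.  A protein that is reproducibly more abundant in the H3K4me1
fraction than in the others is, with high probability, an enhancer binder.
`chipms` implements this inference and the genomic analyses used to
validate it.

### emPAI and the inclusion filters

Protein abundance in each ChIP channel is quantified by the exponentially
modified protein abundance index,

$$\mathrm{emPAI} = 10^{N_\mathrm{obs}/N_\mathrm{obl}} - 1,$$

where $N_\mathrm{obs}$ is the number of peptides observed for the protein
and $N_\mathrm{obl}$ the number theoretically observable.  The
normalisation compensates for protein size; the exponentiation makes the
score roughly linear in protein amount.  Whether $N_\mathrm{obs}$ counts
spectra or distinct peptides depends on the search-engine export; every
downstream rule is a ratio or an argmax over channels of the same protein,
so the choice cancels.  The synthetic generator emits peptide counts.

Three filters define the analyzable cohort
(`ms_location_pipeline()`):

1. **Mascot gate.** A protein requires a Mascot score of at least 50 in at
   least one histone-modification channel.  Individual observations below
   45 are discarded; scores in [45, 60) are kept only when flagged
   `manually_validated` — in that band individual MS/MS spectra need
   analyst inspection, which cannot be automated, so tables without the
   column default to `TRUE` (permissive).  Each sample additionally
   carries a peptide significance threshold (scores 28–29 at *P* < 0.05
   are typical); with the default 45-floor it is not binding but it
   becomes active if the floor is lowered.
2. **GFP control (5-fold).**  The best histone-mark averaged emPAI must be
   at least five times *every individual* GFP-control replicate emPAI.
   "Any of the controls" is read as a universal condition; a positive
   mark signal over an all-zero control passes, an all-zero profile fails.
3. **Discrimination (3-fold).**  Some ordered pair of mark channels must
   differ at least three-fold, excluding proteins that bind chromatin
   indiscriminately.  Equivalently: max ≥ 3 × min with a positive
   maximum; a positive value over a zero passes, 0/0 fails.

Channel emPAIs are averaged over the two replicates, a missing replicate
contributing 0 — non-detection is treated as absence, not missingness.
Comparisons use ≥ with no epsilon; inputs are exact decimals.
Cytoskeletal/cytoplasmic exclusion is a user-supplied identifier list, not
a hard-coded annotation.

### Location calls and the H3K27ac ratio

The location-defining channel with the highest averaged emPAI decides the
call: H3K4me3 → promoter, H3K4me1 → enhancer, H3K9me3 → heterochromatin.
Ties resolve in that priority order; in particular equal H3K4me3 and
H3K4me1 give "promoter", because active promoters legitimately carry
flanking H3K4me1.  The H3K4me1/H3K9me3 tie is not covered by the promoter
rule; resolving it toward "enhancer" mirrors the same priority convention
and is flagged in the output (`tie` column).  A factor whose only signal
is H3K27ac cannot be placed (that mark spans both active promoters and
active enhancers) and is called `k27ac_only`; such factors are reported
but excluded from accuracy tallies.

The activity read-out is the **H3K27ac ratio**,
emPAI(H3K27ac) / max(emPAI(H3K4me3), emPAI(H3K4me1)); normalising by the
factor's own best H3K4 signal cancels the large protein-to-protein
differences in MS detectability.  The ratio is undefined when both H3K4
emPAIs are zero, and flagged unreliable when their maximum is below 0.1
(configurable), i.e. near the detection limit.

### Genome-wide correlation validation

For factors with ChIP-seq data, location calls are validated without peak
calling: the genome is divided into 1-kb bins (0-based half-open, final
partial bin kept), each track is normalised to reads per million (total
mapped reads as denominator, configurable), and the input is subtracted —
in that order, with negative values retained, since the statistic is
rank-based and clamping would create massive ties among background bins.
Reads supplied as intervals are apportioned to bins by fractional overlap
(mass-conserving); a 5′-position mode is also available.  Per track the
4,000 highest bins are selected (ties at the cutoff broken by genome
coordinate), the factor's and the four marks' selections are unioned, and
Spearman correlations of the factor with each mark are computed over that
unified list.  The highest-correlating location-defining mark gives the
correlation-based call; H3K27ac is reported alongside as the activity
read-out but excluded from the argmax, exactly as in the emPAI rule.

### Regions, ranking and heatmaps

Promoter regions are H3K4me3 peak summits within 1 kb (inclusive,
strand-ignored, nearest of possibly several TSS) of a transcription start
site.  Enhancer regions are H3K4me1 summits with no H3K4me3 signal within
±4.1 kb; "signal" defaults to any called H3K4me3 peak overlapping the
window, with an RPM-threshold track mode as alternative.  Promoters are
ranked by H3K27ac reads in their central 2 kb, enhancers in their central
8.2 kb (broad enhancers count fully); sorts are stable and descending with
coordinate-order ties.  Heatmap rows follow the ranking; columns are 51
bins of 160 bp.  Note 51 × 160 = 8,160 bp while the display is described
as ±4.1 kb (8,200 bp); the binned span is centred on the summit (±4,080
bp) and the 40-bp discrepancy accepted rather than adding a 52nd partial
bin.  Matrices are normalised to RPM using the track's total reads over
all displayed promoter *and* enhancer regions, so panels of one factor
share a constant.  A separate promoter/enhancer definition — ±1 kb of
RNA-Pol-II summits near a TSS, respectively of P300 summits away from any
TSS — supports read-overlap fraction summaries; a read overlapping both
kinds is counted once per kind.

### Peak filters, summit overlap, targets

Peak post-filters retain calls with p ≤ 1 × 10⁻¹⁰ (2 × 10⁻¹⁰ for weaker
antibodies) and, for low-coverage factor ChIPs, at least 100 aligned
reads.  Two peaks overlap when their summits are within 125 bp
(inclusive).  Multiway (Venn) counts pool all summits and cluster by
single linkage; proximity is not transitive, so chains merge — a
documented convention, since the alternative (anchoring on a reference
set) is equally defensible but not stated by the sources this emulates.

Bound genes have a summit within a TSS window (1 kb for a
promoter-proximal binder, 20 kb for a distal one; any of a gene's TSS
qualifies).  Target genes are bound genes with ≥ 2-fold expression change
— two-sided by default, with a direction argument — and adjusted
p ≤ 0.10 where the rule carries a significance cut (the distal-binder
rule does not; pass `max_adj_p = NULL`).  Probe-level fold changes are
aggregated by the mean; the adjusted p of a multi-probe gene is taken
from its most significant probe (the sources are silent here; the minimum
is the permissive choice and is documented).  Counts are normalised by
median-of-ratios size factors computed over genes with all-positive
counts, expression is summarised as mean normalised counts × 1000 / gene
length, sets are compared by a two-sided Mann–Whitney test (exact for
small tie-free sets, tie-corrected normal approximation otherwise), and
tissue-of-maximal-expression enrichment is the set fraction over the
atlas-wide fraction.

## The synthetic-data generator

The generator replaces the study's wet-lab inputs with a seeded model
that has the statistical structure the analysis assumes, plus planted
ground truth.  Defaults (chosen once, stated here as the package's own
study conditions): 2 chromosomes × 5 Mb; 200 promoters, 400 enhancers,
20 heterochromatin blocks in distinct 14-kb slots (hence non-overlapping,
promoters at TSS, enhancers > 5 kb from any TSS); 60 factors, 20 per
class; 50,000 reads per track with 60% in signal over uniform background;
lognormal emPAI noise with σ = 0.3; lognormal per-region activity
multipliers (σ = 0.5) driving H3K27ac; negative-binomial expression
counts (dispersion 0.05) with 30 planted targets at fourfold
down-regulation and unequal library sizes.  These sizes keep full
generation and evaluation near ten seconds on one CPU while leaving every
statistical decision non-trivial.

Design points worth knowing:

- **Two-tier factor occupancy.**  A factor occupies its whole class
  territory weakly (quarter weight) and a designated 60-region subset
  strongly; peaks are called at the strong sites.  Real factors occupy
  their compartment broadly with graded intensity; modelling only a
  sparse subset would make every *unbound* class region a discordant bin
  and bias the correlation argmax toward the mark with the smallest
  territory.
- **Planted decoys** exercise each filter: GFP-sticky background proteins
  (fail the control rule), indiscriminate binders (fail discrimination)
  and sub-threshold identifications (fail the Mascot gate).
- **Expression p-values are planted labels**, not recomputed statistics:
  target probes draw adjusted p from (0.001, 0.05), others from (0.2, 1).
  The package consumes moderated-statistics columns rather than
  recomputing them, so the generator plants them directly.
- **Determinism.**  Each generator derives a fixed child seed from the
  run seed, so modules can be regenerated independently and the same
  configuration is byte-identical on disk across runs.

What passing tests on this generator do *not* show: robustness to
mappability artefacts, copy-number variation, antibody cross-reactivity,
fragment-length effects, or protein-inference ambiguity — none of which
are modelled.  The generator demonstrates that the rules are implemented
correctly and recover truth under the stated noise, not that the noise
model matches any particular instrument.

## Numerical choices and degenerate inputs

- Fold tests with zero denominators: positive/0 passes, 0/0 fails.
- Spearman over fewer than two bins, or over bins where either track has
  zero variance, is undefined: flagged `NA` with a warning, never an
  error; a missing required correlation yields a no-call.
- `top_bins` with fewer nonzero bins than requested returns all nonzero
  bins with a warning; an all-zero track is an error.
- Region, ranking and activity-map orderings are fully deterministic
  (score descending, then genome coordinate / identifier), so permuted
  inputs produce identical output files.
- Coordinates are 0-based half-open internally; BED passes through
  unchanged, TSV TSS tables are 1-based with a conversion flag.

## Problem sizes

The default test-suite and acceptance runs use the generator defaults
above (10 Mb genome, 10,000 correlation bins, 65 tracks of 50k reads);
unit tests use a 3 Mb variant.  Both complete in well under a minute on a
single core; the sizes are the package's chosen desk-scale study
conditions, compact enough to iterate on while keeping every filter and
estimator away from degenerate regimes.
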