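---
title: "Desk-scale structural analyses for RNF213: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale structural analyses for RNF213: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structkit)
```

## Scope

RNF213 is the major susceptibility factor for Moyamoya disease, a
cerebrovascular disorder. The 584 kDa, 5148-residue mouse protein folds into
an N-terminal stalk (N-arm), a dynein-like core of six AAA ATPase units, and
a multidomain E3 ubiquitin-ligase module. `structkit` implements the
computational analyses that accompany the structural characterization of
such a protein at desk scale:

* intrinsic-disorder profiling (FoldIndex, single-window and composite);
* per-column sum-of-pairs sequence conservation with sliding-window smoothing;
* validation of atomic models against crosslinking mass-spectrometry (XL-MS)
  data: link-level FDR filtering, Calpha-distance mapping, distance-band
  satisfaction statistics and per-domain breakdowns;
* curation of missense disease mutations, transfer of residue numbering
  between orthologs, CADD severity binning, and domain-clustering statistics;
* least-squares (Kabsch) superposition of atomic models;
* extraction of ATP-hydrolysis rates from NADH-coupled ATPase assay traces.

Cryo-EM reconstruction, model building and refinement, crosslink spectral
search, MSA construction and CADD scoring are upstream of this package;
their outputs (PDB/mmCIF models, aligned FASTA, link-level TSV tables,
HGVS + CADD tables, plate-reader CSV) are its inputs.

Because the real inputs are large depositions, every stage has a paired
generator (`make_toy_structure()`, `make_crosslinks()`, `make_msa()`,
`make_mutation_table()`, `make_nadh_trace()`) that emits the same on-disk
formats with planted ground truth, so the full pipeline runs and is tested
without downloading anything.

## Disorder profiling

FoldIndex scores a window of sequence as

$$ I = 2.785\,H - |R| - 1.151, $$

where $H$ is the mean Kyte–Doolittle hydropathy rescaled to $[0,1]$ via
$(KD + 4.5)/9$ and $R$ is the mean net charge. Positive values predict
ordered, negative disordered sequence; the construction bounds scores to
$[-2.151, 1.634]$. Two conventions are deliberately fixed and configurable:

* **Charge model.** K and R contribute $+1$, D and E $-1$, histidine $0$.
  Treating His as neutral at assay pH is the common convention; callers who
  disagree can score windows themselves via `foldindex_window()` on
  modified inputs.
* **Edge policy.** `foldindex_profile()` reports one score per position
  using *full-width clamped windows*: near the termini the window is
  shifted inward rather than shortened. Every reported value is therefore a
  genuine $w$-residue FoldIndex score (a truncated half-window would change
  the statistic's scale at the termini), and a window equal to the sequence
  length yields a constant profile equal to the whole-sequence score.

`composite_disorder()` stacks profiles for several window sizes
(default 10, 20, 50, 100 — small windows resolve short linkers, large
windows suppress noise) and multiplies each by $1/w$ so that the curves
share a scale on one plot. Scaling by a positive constant preserves signs,
so the ordered/disordered calls are window-consistent.

## Conservation

`conservation_sp()` scores column $c$ of an alignment as the average
substitution-matrix value over all residue pairs,

$$ SP(c) = \frac{2}{N_c (N_c - 1)} \sum_{j<k} M(a_j, a_k), $$

with BLOSUM62 and no sequence weighting. Pairs involving gaps are excluded;
columns with fewer than two residues yield a flagged `NA`. A fully conserved
column scores the matrix diagonal (11 for tryptophan, 4 for alanine).
Optional z-normalization across columns is off by default — raw sums are
what a full-length conservation plot smooths. `sliding_smooth()` applies a
centered 100-residue moving mean with truncated windows at the termini
(here, unlike in the disorder profile, the quantity is already
per-position, so a truncated mean is the right edge behavior and keeps
constant profiles constant).

## Crosslink validation

DSS crosslinks lysines whose Calpha atoms lie roughly 15–30 Å apart, so the
fraction of observed links inside that band measures how well an atomic
model explains the XL-MS data; around 90% in-band is the hallmark of a
correctly traced model. Fixed policies:

* distances are Euclidean Calpha–Calpha (solvent-accessible surface
  distances are out of scope);
* band endpoints are inclusive; a single-cutoff mode (`band = c(0, 30)`)
  is available;
* the default residue filter is lysine-only. The search chemistry also
  permits S/T/Y links at lower specificity; the headline statistic is
  defined on K–K links;
* links with an end outside the modeled residue range are excluded from the
  denominator and counted separately. On a model that begins at residue 476
  of a 5148-residue protein this is the only defensible choice — links into
  the unmodeled N-terminus say nothing about the model;
* self-links are rejected at construction (the protein is monomeric by
  SEC/DLS, so intra/inter-molecular ambiguity does not arise).

## Mutation mapping

`parse_hgvs_p()` accepts one- and three-letter missense notation and
recognizes delins records as typed non-missense entries; clustering
statistics use missense records only. Mutations annotated on the human
protein are transferred to mouse numbering through a global alignment
(`pairwise_align()`: Needleman–Wunsch, BLOSUM62, gap open 11/extend 1,
deterministic traceback via Biostrings) or through a supplied curated
alignment (`as_alignment()`). `transfer_numbering()` is strictly monotone
and round-trips wherever neither direction hits a gap.

Severity uses CADD scores as given. Two thresholds coexist on purpose:
coloring bins are left-closed ($[0,15)$, $[15,20)$, $[20,\infty)$), while
the *severe* count for clustering is strict (`cadd > 20`), matching the
printed ">20" convention; a score of exactly 20 colors "high" but does not
count as severe.

The clustering statistic counts severe mutations falling in the four E3
sub-domains (E3-back, E3-shell, E3-core, CTD; the RING can be added via
`e3_subdomains(include_ring = TRUE)`). Only the RING boundaries inside the
E3 module are published, so the shipped back/shell/core split is an
editable approximation — the four-domain union, which is what the statistic
depends on, is fully determined by published ranges (E3 module minus RING,
plus the CTD). The CTD range itself (4927–5148) is inferred from the E3
module's end and the chain terminus. `domain_enrichment()` adds an exact
hypergeometric tail against a residue-length-proportional null: drawing the
severe positions uniformly over the protein, $P(X \ge k)$ for $k$ hits in
target domains covering $K$ of $L$ residues.

## ATPase kinetics

In the NADH-coupled assay, pyruvate kinase regenerates ATP and lactate
dehydrogenase oxidizes one NADH per regenerated ATP, so NADH fluorescence
decays at the hydrolysis rate. Under the pseudo-zero-order approximation
the decay is linear until the NADH pool is exhausted, and

$$ \text{rate} = \frac{-\text{signal slope} / \text{calibration slope}}
   {[\text{enzyme}]} $$

in ATP per enzyme molecule per minute (`ring_count` divides out multiple
AAA rings per molecule; RNF213 carries its six AAA units in one chain, so
the default is 1).

`detect_linear_region()` scans all contiguous windows covering at least 20%
of the trace and keeps the longest with $r^2 \ge 0.99$ and a negative
slope, ties to the earliest start. Two numerical refinements matter in
practice:

* **Boundary peeling.** An $r^2$ threshold alone lets the chosen window
  creep a few dozen points past the exhaustion kink (each plateau point
  barely dents $r^2$ but all pull the slope toward zero; we measured a
  5–7% rate bias on synthetic traces). After the scan, contiguous runs of
  points at either window end whose residuals exceed 2.5 standard
  deviations of the window fit are peeled off and the fit repeated. On
  synthetic traces this restores sub-percent accuracy; it is on by default
  and disabled with `refine = FALSE`.
* **Threshold vs. signal-to-noise.** With 1% multiplicative noise on a
  ~5000 a.u. signal, a shallow but perfectly linear decay (a slow enzyme
  over 12 h) has an $r^2$ around 0.94 — below the 0.99 default. The default
  suits clean, steep decays; for noisy shallow traces pass a lower
  `r2_min` (the parameter-recovery analyses here use 0.9) or set the
  region manually.

The generator `make_nadh_trace()` follows the assay conditions: 0.1 µM
enzyme, 50 µM NADH, readings over 12 h, multiplicative Gaussian noise, NADH
clipped at zero. Recovery analyses sample ~240 points per trace over
`min(720 min, 1.2 ×` exhaustion time`)` so that both the decay and (where
reached) the plateau are represented; across rates 0.1–50 min⁻¹ at 1%
noise the median relative error of recovered rates is well under 2%
(computed by the test suite and `scripts/acceptance.R`).

## Superposition

`superpose()` implements the closed-form Kabsch solution (SVD of the
cross-covariance, determinant-corrected to a proper rotation) over Calpha
pairs matched by chain, residue number and insertion code. Because the atom
selection behind a published RMSD is often unstated, an optional trimming
mode (`trim = TRUE`) iteratively discards pairs deviating by more than 2
standard deviations and re-fits (at most 5 rounds); the trimmed RMSD is
reported *alongside* the all-pair RMSD, never instead of it. Degenerate
selections (fewer than 3 pairs, collinear points) are rejected with typed
errors. Correctness is asserted in the tests by recovery of planted rigid
transforms to below 1e-6 Å and by cross-checking the math against bio3d's
independent fitting routine.

## What the synthetic data does and does not show

The generators emulate the *statistical structure* of the real inputs:
backbone-spaced Calpha chains with a broad pair-distance spectrum, link
tables at 5% FDR with a planted in-band fraction, alignments with
controlled per-column identity, mutation tables with planted severity
clustering on the real 5148-residue domain architecture, and decay traces
with known rate and noise. They do not emulate real-data pathologies:
non-lysine reactive-site ambiguity, FDR miscalibration, alignment errors
between distant orthologs, instrument drift or temperature steps in
plate-reader data, or coordinate error correlated along the chain. Passing
tests therefore demonstrate that the computations are correct and
self-consistent, not that any particular deposited model is well built;
running the same functions on the deposited models and supplementary tables
(PDB 6TAX/6TAY and the published crosslink and mutation lists) is the
corresponding real-data exercise and needs only the downloads.

Problem sizes used by the test-suite and acceptance analyses: 4308-atom
superpositions, 600-residue crosslink models with 100 links, 1,000 planted
mutation plans, 100 kinetic traces of ~240 points.

## Degenerate inputs and tie-breaks

* Residues without a Calpha are parsed, flagged, and excluded from
  distances and superpositions; distance queries against them raise a
  typed `no-calpha` error, distinct from `unmodeled`.
* Conservation columns with fewer than two residues, empty crosslink
  mappings, and zero-severe-mutation enrichment all return flagged
  `NA`/degenerate results rather than errors.
* Alignment traceback ties are resolved deterministically by Biostrings;
  linear-region ties go to the earliest start; severity bins are
  left-closed.
* All generators draw from R's RNG under `withr::with_seed()`: no global
  state is consumed or disturbed, and equal seeds give byte-identical
  outputs.
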