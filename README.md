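# structkit

Desk-scale structural analyses for RNF213, the giant (584 kDa, 5148-residue)
E3 ubiquitin ligase and major susceptibility factor for Moyamoya disease, a
progressive cerebrovascular disorder. The protein folds into an N-terminal
stalk, a dynein-like core of six AAA ATPase units, and a multidomain E3
module; characterizing it structurally involves a set of computations that
this package implements as tested, reusable functions:

* **Disorder profiling** — FoldIndex scores
  `I = 2.785·H − |R| − 1.151` (H: rescaled Kyte–Doolittle hydropathy,
  R: mean net charge), per window, per position, and as composite
  multi-window profiles normalized by the reciprocal window size.
* **Conservation** — per-column sum-of-pairs scores
  `SP(c) = 2/(N(N−1)) · Σ_{j<k} M(a_j, a_k)` under BLOSUM62 with no
  sequence weighting, smoothed with a 100-residue sliding window.
* **Crosslink-MS model validation** — link-level FDR filtering (5%
  default), mapping of crosslinks onto atomic models, and the fraction of
  lysine–lysine links whose Cα–Cα distance falls in the 15–30 Å band
  expected for the DSS crosslinker (~90% for a correctly traced model),
  with per-domain breakdowns.
* **Disease-mutation mapping** — HGVS p. parsing, reference validation,
  human→mouse numbering transfer through a global alignment
  (e.g. human p.R4810K ↔ mouse p.R4753K), CADD severity bins
  (0–15 / 15–20 / 20+), clustering counts of severe (CADD > 20) mutations
  in the four E3 sub-domains, and an exact hypergeometric enrichment test.
* **Superposition** — closed-form Kabsch least-squares fit over common Cα
  atoms with optional iterative outlier trimming, both RMSDs reported.
* **ATPase kinetics** — NADH-standard calibration, automatic detection of
  the linearly decaying region, and hydrolysis rates
  `(−signal slope / calibration slope) / [enzyme]` in ATP·enzyme⁻¹·min⁻¹
  under the pseudo-zero-order approximation (per-AAA-ring variant included).

Every stage has a synthetic-data generator with planted ground truth
(`make_toy_structure`, `make_crosslinks`, `make_msa`, `make_mutation_table`,
`make_nadh_trace`) emitting the same on-disk formats the pipeline reads
(PDB, FASTA, TSV, CSV), so the whole package runs and is tested without any
download. The real inputs — deposited models (PDB 6TAX/6TAY), link-level
crosslink tables, and curated HGVS+CADD mutation lists — drop into the same
functions.

## Worked example

```r
library(structkit)

tab <- read_domain_table(system.file("extdata", "rnf213_domains.tsv",
                                     package = "structkit"))
assign_domain(c(1000, 2500, 4753), tab)
#> [1] "N-arm"     "AAA core"  "E3 module"

# --- crosslink validation on a model with a planted 90% satisfaction ---
model <- make_toy_structure(600, "random-walk", seed = 42,
                            resnames = "LYS", start_resnum = 476)
xl    <- make_crosslinks(model, 100, 0.9, seed = 43)
mp    <- map_crosslinks(fdr_filter(xl$records, 0.05), model,
                        residue_filter = "K", band = c(15, 30))
st    <- satisfaction_stats(mp)
#> 90% of 100 mapped K-K crosslinks lie within 15-30 A

# --- severe-mutation clustering in the E3 module ---
mt <- make_mutation_table(50, 28, 21, tab, seed = 44)
cc <- domain_cluster_counts(mt$records, tab)
#> 21 of 28 severe mutations (CADD > 20) fall in the four E3 sub-domains
domain_enrichment(mt$records, tab)
#> enrichment odds ratio 7.3, hypergeometric p = 6.4e-07

# --- ATPase rate from a simulated NADH decay ---
conc <- c(0.05, 1, 25, 50, 100)
cal  <- fit_calibration(conc, 100 * conc + 50)
tr   <- make_nadh_trace(5, duration = 150, dt = 0.5, seed = 45)
atpase_rate(tr$trace, cal)$rate
#> ATPase rate: 5.00 ATP per enzyme per minute (planted 5)
```

The in-band percentage, the 21/28 clustering count and the planted rate are
recovered exactly because the generators record their ground truth; the
enrichment p-value answers "could 21 of 28 severe mutations land in these
domains by residue-proportional chance?" (no: p ≈ 6e-07).

To analyze real data instead, point the same functions at downloaded files:
`read_structure("6tax.cif")`, `load_crosslinks("supp4_links.tsv")`,
`load_mutation_table("supp2_mutations.tsv")`, `read_trace("plate.csv")`,
and `superpose(read_structure("6tax.cif"), read_structure("6tay.cif"))`.

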