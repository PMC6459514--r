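---
title: "Multiplex ligation-based SNP genotyping: model, simulation and calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex ligation-based SNP genotyping: model, simulation and calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligatyper)
```

## The assay

Multiplex ligation detection reaction (MLDR) genotyping interrogates a fixed
set of known SNVs and small deletions in a single ligation reaction, read out
on a capillary sequencer as fluorescent fragments. For each target site three
5'-phosphorylated probes are used: two allele-specific 5' probes and one
common 3' probe. Each 5' probe carries a dye-specific tag sequence at its 5'
end and an allele-specific annealing sequence whose 3'-terminal base sits on
the variant position — the base a DNA ligase proofreads. Only the probe
matching the template allele is sealed to the common 3' probe, and a second
(labeling) ligation attaches the dye encoded by the tag. Each allele of each
locus therefore maps to a *ligation product* with a fixed two-dimensional
address: a dye channel (one of four, here abstracted as B/G/Y/R) and an
electrophoretic size in nucleotides. A non-hybridizing *stuffer* appended to
the common 3' probe shifts a locus's products along the size axis so that
products sharing a dye never co-migrate. Decoding an electropherogram is then
a lookup: each peak belongs to the unique product with its dye whose expected
size is within the matching tolerance.

The package implements this scheme end to end:

* `builtin_panel_hl32()` — a 32-variant hereditary hearing loss panel
  (GJB2, GJB3, SLC26A4, MT-RNR1, COCH, POU3F4, PAX3, MITF, SOX10, CEACAM16)
  in 18 multiplex PCR amplicon groups;
* `design_probe_set()` / `assign_layout()` / `design_panel()` — probe and
  layout design from flanking sequence;
* `validation_samples_table1()`, `control_samples_table4()`,
  `cohort_samples_table5()`, `cohort_from_counts()` — cohort genotype
  fixtures; `simulate_sample()` / `simulate_cohort()` — peak simulation;
* `size_call()`, `match_products()`, `call_locus()`, `call_sample()`,
  `call_batch()`, `concordance()` — the decoding pipeline;
* `classify_sample()`, `summarize_cohort()`, `compound_het_table()`,
  `gene_share()` — inheritance-aware interpretation.

## Panel model and layout design

A panel (`lg_panel`) couples an ordered variant table to a product table of
(dye, size) addresses. Its central invariant is decodability: any two
products on the same dye must differ in expected size by at least twice the
size-matching tolerance. `validate_layout()` returns every violating pair;
an empty result is the machine-checkable definition of a usable panel.
Same-size products on *different* dyes are legal and canonical — four dyes
deliberately allow four products from two loci to co-migrate.

`assign_layout()` solves the placement problem. Each locus has a base
product length (its probe arms plus the 12-nt dye tag, or the bottom of the
size window for abstract layouts) and per-allele offsets fixed by allele
length differences: a k-base deletion allele yields a product k nt shorter
than its reference partner, since the stuffer rides on the shared 3' probe.
The solver is a deterministic greedy first-fit: loci in input order, stuffer
lengths quantized to `stuffer_step`, dye tuples tried in B<G<Y<R order, each
placement checked against all previously occupied same-dye positions at the
`min_separation` spacing. On failure it retries with loci reordered by
descending product count, then reports the instance infeasible with a slot
count. Greedy first-fit is not guaranteed optimal in packing density, but
determinism matters more here than density: the built-in panel layout must
be byte-stable, and 65 products occupy under a third of the
4 dyes x 61 slots available in the default 80–260 nt window. Feasibility is
monotone in the obvious directions (wider window, smaller separation), which
the tests assert.

Defaults: size window 80–260 nt (a typical fragment-analysis read range),
minimum same-dye separation 3 nt, i.e. matching tolerance ±1.5 nt. The
printed source of the built-in panel states no product sizes, stuffer
increments or dye pairings, so the embedded layout is the solver's
deterministic output under these defaults, not a transcription.

Two transcription quirks of the built-in panel are worth knowing. The
c.571T>G entry is listed in its source with allelic change "T/C",
contradicting the variant name; the panel follows the name (used
consistently in the cohort tables) and records the discrepancy in
`panel$notes`. The COCH c.1625 site carries two alternate alleles (G>A and
G>T); it is modeled as one tri-allelic locus with three products on three
distinct dyes, so the panel holds 32 variants and 65 products.

## Probe design and the melting-temperature model

`design_probe_set()` chooses annealing-arm lengths (shortest first, hence
deterministically) so that every arm's Tm lands in `target_tm ± tm_window`
(default 62 ± 3 °C). The two allele probes share their upstream arm and
differ only at the 3' terminus; deletion alleles are probed across the
deletion junction, the alt probe reading 2 nt into the sequence beyond the
deleted bases. When no length in `[min_probe_len, max_probe_len]` reaches
the window (e.g. a low-complexity A/T run), the error reports the achieved
Tm range.

Tm uses the two-state nearest-neighbor model with the unified duplex
parameter set (stacking ΔH/ΔS per dinucleotide, duplex-initiation terms for
terminal A:T and G:C pairs, symmetry correction for self-complementary
sequences) and the entropic monovalent-salt correction
ΔS' = ΔS + 0.368·(N−1)·ln[Na⁺]. Tm = 1000·ΔH / (ΔS' + R·ln(CT/x)) − 273.15,
with x = 4 for non-self-complementary duplexes, at the default 50 mM Na⁺
and 250 nM total oligo. The parameter table is fixed in code; the test suite
pins the implementation against independently computed oracle values to
within 0.5 °C.

## Simulation: what it emulates and what it does not

`simulate_sample()` produces a peak-level electropherogram, not a raw
fluorescence trace. For every locus one log-normal signal intensity is
drawn (median 2000 RFU, log-SD 0.35 — ordinary well-amplified fragment
heights) and partitioned between allele products: 50/50 with Gaussian jitter
(SD 0.05) for heterozygotes, by the homoplasmy fraction for mitochondrial
loci. Measured sizes scatter around expected sizes with SD 0.15 nt —
roughly the sizing precision of a capillary instrument and 10x smaller than
the matching tolerance, which is what makes near-perfect decoding the
expected outcome rather than an accident. A Poisson number (mean 2) of
spurious baseline peaks per sample is placed uniformly in dye x size, with
heights of 20–80 RFU, deliberately below the 100 RFU calling threshold:
they exercise the matcher without modeling real artifact chemistry.
Per-allele dropout is available (`dropout_prob`) but off by default.
Peaks are emitted both in nt and in raw migration units through a smooth
quadratic migration model, together with a 20-nt-spaced ladder, so the
size-calling step can be exercised honestly.

Not modeled: stutter, pull-up between dye channels, saturation, baseline
drift, or trace-level noise. Consequently a 100% concordance result on
simulated cohorts validates the *decoding logic* — layout, sizing,
matching, ratio calling — under calibrated instrument-like noise; it is not
a claim about wet-lab assay performance, which the original validation
against Sanger sequencing established.

Cohort fixtures are reconstructed from printed zygosity counts. The
49-sample validation cohort treats the per-variant counts (29 het + 20 hom
= 49) as one-per-patient primary findings and layers the nine reported
dual-variant samples on top of carriers of the first-listed variant;
cross-gene pairs (e.g. GJB2 het plus mitochondrial c.1555A>G) are dual-gene
findings, not compound heterozygotes, and mitochondrial findings are
homoplasmic (fraction 1.0). The 171-patient cohort is generated by
`cohort_from_counts()`, which preserves the per-variant marginals exactly.
Its printed compound-het table over-demands the c.235delC heterozygote
budget (pairs want 7, the marginal provides 4); in the default `reconcile`
mode pairs are processed in printed order and capped at the remaining
budget (the c.235delC/c.299_300delAT pair realizes 3), with a warning;
`strict` mode errors instead. Marginals — and therefore every published
frequency — are identical under either choice.

## Calling

Size calling follows the local Southern method: for a peak bracketed by
ladder points i, i+1, the reciprocal curve L = c + a/(m − b) is fitted
through triplets (i−1, i, i+1) and (i, i+1, i+2) and the two estimates
averaged. A collinear triplet makes the hyperbola degenerate; the fit
detects this (and a pole falling inside the triplet's span) and falls back
to linear interpolation, so a perfectly linear ladder sizes peaks by exact
linear interpolation. Peaks outside the ladder span are linearly
extrapolated and flagged `off_size`. The mapping is strictly monotone, and
on a ladder generated from any reciprocal migration curve the fit recovers
sizes to numerical precision (tested at 1e-9 nt).

Matching assigns each above-threshold peak to the unique same-dye product
within ±1.5 nt (the matching tolerance equals half the layout separation by
construction — the layout guarantee is exactly what makes the lookup
unambiguous). Multiple peaks in one product window keep the tallest and
flag the locus `ambiguous`.

Zygosity uses the allele ratio r = alt/(ref+alt) over above-threshold
heights: het for r in [0.25, 0.75], homozygote override for r < 0.1 or
r > 0.9, ambiguous no-call in the dead zones, no-call `low_signal` when
nothing clears 100 RFU. The bands are conventional fragment-analysis
practice (the source assay reports only categorical zygosity) and are
exposed in `call_thresholds()`. Mitochondrial loci report the fraction
itself; at or above 0.95 the locus is homoplasmic alt (genotype 1/1),
at or below 0.05 reference, between the two heteroplasmic (0/1 with the
fraction retained). The 0.95 cutoff operationalizes "homoplasmic", which
the source describes without a threshold.

`concordance()` scores per (sample, locus) cell and demands exact zygosity
agreement for a truth-positive cell to count as detected; sensitivity and
specificity are percentages over truth-positive and truth-negative cells.
This cell-level, exact-match definition is the strictest reasonable reading
of an assay-validation claim and is stated here because the source gives no
formula.

## Interpretation

`classify_sample()` applies gene-mode rules with a fixed precedence:
AR homozygote → `confirmed_homozygous`; homoplasmic mitochondrial alt →
`confirmed_mt`; two hets in one AR gene →
`possible_compound_het_phase_unknown` (without parental phasing these may
be cis, so they are *not* counted as confirmed); any alt at an AD locus →
`ad_positive`; at the X-linked locus → `xl_positive`; any remaining finding
(single AR het, heteroplasmic mitochondrial) → `carrier_monoallelic`; else
`negative`. GJB3 is treated as autosomal recessive, matching the source's
reasoning (literature also reports dominant alleles); the inheritance
column is data, not code, so a different assignment is a one-line panel
edit.

`summarize_cohort()` counts *entries* — variant-carrier occurrences — so a
dual-variant patient contributes two entries. Entry semantics is the only
convention under which the published cohort figures are simultaneously
consistent (57 findings = 33.33% of 171, with 35 het = 20.47% and 22 hom =
12.87%, GJB2 30/171, SLC26A4 14/171), and the summary also reports the
deduplicated patient-level carrier rate alongside. `diagnostic_yield`
counts only `confirmed_*` samples (22/171 = 12.87%). One printed cell —
"64.33%" for c.299_300delAT — is arithmetically impossible (11/171 = 6.43%)
and is excluded from the golden checks as a typo.

## Numerical and determinism choices

* All generators take explicit integer seeds; cohort simulation derives a
  per-sample seed from the base seed, so output is order-stable and
  reproducible byte for byte (the CLI writes a JSON manifest per run).
* The built-in panel is computed once per session and cached; two calls
  return identical objects, and serialization is byte-stable.
* Greedy layout ties break by variant order then dye order B<G<Y<R.
* Size comparisons carry a 1e-9 guard against floating-point edge ties.
* Problem sizes used by the test suite: the 49+50 validation/control round
  trip, the 171-patient cohort, 100 random 4-locus panels for the
  encode/decode identity, and a 1000-sample batch for the noise-margin
  check — all chosen to finish in seconds while leaving the statistical
  margins (0.5 nt ≈ 3.3 sigma of sizing noise) meaningful.

## Limitations

Peak-level simulation cannot surface trace-processing failure modes
(pull-up, stutter misassignment). Probe design screens thermodynamics only
— no cross-hybridization or secondary-structure checks — and the built-in
panel ships without probe sequences (its originals are proprietary), so
sequence-level design applies to user panels with supplied flanks.
Genomic coordinates are not modeled; variants are keyed by their printed
names. Tri-allelic loci are designed only at the layout level, and calling
reports ref against the strongest alt allele.
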