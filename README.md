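# ligatyper

Multiplex ligation-based SNP genotyping in R: panel layout design,
electropherogram simulation, genotype calling, and inheritance-aware
interpretation.

## The problem

Targeted screening panels for hereditary hearing loss (and similar
recessive/mitochondrial disorders) interrogate a few dozen known mutations
at once using a multiplex ligation detection reaction (MLDR): per target
site, two allele-specific 5' probes (each carrying a dye-encoding 5' tag,
differing at the 3'-terminal base the ligase proofreads) and one common 3'
probe. A double ligation produces, per allele, a fluorescent fragment with
a characteristic **(dye, size)** address; a variable-length stuffer on the
3' probe shifts a locus along the size axis so that same-dye products never
co-migrate. Reading a capillary electropherogram back into genotypes is
then a matter of ladder-based size calling, address lookup, and
allele-ratio zygosity rules:

- a decodable panel satisfies: for all products *p ≠ q* with
  dye(p) = dye(q), |size(p) − size(q)| ≥ 2·tol (tol = 1.5 nt by default);
- zygosity from the allele ratio r = h_alt / (h_ref + h_alt):
  het for r ∈ [0.25, 0.75], homozygote override for r < 0.1 or r > 0.9,
  ambiguous otherwise; mitochondrial loci report r as the homoplasmy
  fraction (homoplasmic when r ≥ 0.95);
- interpretation under each gene's inheritance mode (AR / AD / X-linked /
  maternal): only AR homozygotes and homoplasmic mitochondrial carriers
  count as a confirmed molecular diagnosis; two hets in one AR gene are a
  possible compound heterozygote of unknown phase.

The package is aimed at assay developers and analysts who want to design
collision-free multiplex layouts, stress-test decoding logic on simulated
cohorts, and reproduce published cohort statistics from peak-level data.
It ships a built-in 32-variant, 10-gene, 18-amplicon hearing loss panel
plus generators for its published validation (n=49), control (n=50) and
patient (n=171) cohorts.

## Worked example

```r
library(ligatyper)

panel <- builtin_panel_hl32()
panel
#> Ligation genotyping panel: HL32
#>   32 variants in 10 genes; 65 ligation products
#>   size window 80-260 nt, matching tolerance +/-1.5 nt, dyes B/G/Y/R
#>   18 multiplex PCR amplicon groups
#>   layout: collision-free

# simulate the 49 validation samples + 50 controls, call, score
truths <- c(validation_samples_table1(panel), control_samples_table4(panel))
tables <- simulate_cohort(panel, truths, noise_model(), seed = 1)
calls  <- call_batch(panel, tables)
concordance(truth_matrix(truths, panel), calls)
#> Concordance over 63 positive and 3105 negative (sample, locus) cells
#>   sensitivity: 100.00%   specificity: 100.00%

# the 171-patient cohort reconstructed from its published marginals
cohort <- cohort_samples_table5(panel, seed = 1)   # warns: one pair capped
s <- summarize_cohort(truth_matrix(cohort, panel), panel)
s
#> Cohort summary (n = 171)
#>     gene chrom        variant hom het frequency
#>     GJB2    13 c.176_191del16   0   1     0.58%
#>     GJB2    13      c.235delC  12   4     9.36%
#>     ...
#> Detection rate (entries/n): 33.33%  (carrier samples: 29.82%)
#> Heterozygous entries: 20.47%   Homozygous entries: 12.87%
#> Diagnostic yield (confirmed by inheritance mode): 12.87%

round(gene_share(s, "GJB2", "c.235delC"), 2)
#> [1] 53.33
```

The numbers mean: every simulated positive was recovered with its exact
zygosity and no control locus produced a false positive (sensitivity and
specificity 100%); among 171 patients there are 57 variant findings
(33.33%), 35 heterozygous (20.47%) and 22 homozygous (12.87%) — the 22 AR
homozygotes and homoplasmic mitochondrial carriers being confirmed
diagnoses — and c.235delC accounts for 53.33% of GJB2 findings.

A command-line front end with `validate` / `simulate` / `call` /
`summarize` / `design` subcommands lives at `inst/cli/ligatyper`
(see `?cli_main`), writing TSV/JSON outputs plus a reproducibility
manifest per run. The methods vignette
(`vignettes/ligation-genotyping.Rmd`) documents the assay model, the noise
model, all thresholds, and design decisions.

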