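# mirmzt

Small-RNA sequencing analysis for maternal-to-zygotic transition (MZT)
experiments: priority-ordered read annotation, isomiR classification
(canonical / noncanonical / 3′ non-templated addition), TMM-normalized
negative-binomial differential expression, expression-class clustering, and
gene-list overlap statistics — with a synthetic-data module that makes the
whole pipeline testable end to end without any downloads.

## Who this is for

Groups profiling bulk small RNAs (miRNA, siRNA, piRNA) across early
embryogenesis in a two-genotype (wild type vs. a mutant losing zygotic
synthesis) × three-timepoint (unfertilized eggs, pre- and post-zygotic
genome activation embryos) × three-replicate design, and anyone who needs a
transparent, fully tested reference implementation of the component
algorithms.

## The statistics at the core

* **isomiR taxonomy.** For a mature miRNA with interval *m* inside its
  hairpin, the *noncanonical window* is *[m₅′ − 2, m₃′ + 5]*. A read *r*
  with a perfect genome match is **canonical** iff *r = m*, **noncanonical**
  iff *r ⊆ window, r ≠ m*. Reads with **no** perfect genome match are NTA
  candidates: trim the 3′-terminal 3 nt, realign the body perfectly, keep
  anchors inside a window, realign the full read ungapped to the hairpin
  with ≤ 3 mismatches, and accept only terminal mismatch patterns
  **MMX / MXX / XXX** (tail = the mismatching suffix, 1–3 nt).
* **Multi-mapper weights.** A read with *k* perfect loci contributes 1/*k*
  per locus; weighted mass is conserved exactly.
* **Expression.** RPM = count / mapped-library-size × 10⁶; features kept if
  RPM > 1 in ≥ 6 of 18 libraries; TMM normalization (30 % M-trim, 5 %
  A-trim, precision weights, geometric-mean-1 factors); per-feature NB GLM
  with cell means per genotype×timepoint, likelihood-ratio test vs. the
  contrast-merged model (χ², 1 df), Benjamini–Hochberg FDR ≤ 0.05.
* **Profiles.** log₂(mean RPM + 1) over wild-type sample sets, hierarchical
  clustering cut at *k* = 5 → classes A–E (nonmaternal/low-zygotic through
  high-maternal/constant).
* **Overlap.** One-tailed Fisher test: *p* = P[X ≥ a],
  X ~ Hypergeometric(N, |A|, |B|); sample odds ratio (a·d)/(b·c).

## Worked example

```r
library(mirmzt)

## a published-scale overlap table row: BRAT-bound mRNAs vs the targets of
## zygotic miRNAs (N = 6191, |A| = 1197, |B| = 363, overlap 107)
r <- fisher_overlap(6191, 1197, 363, 107, cmle = TRUE)
sprintf("OR = %.2f (CMLE %.2f), one-tailed p = %.2g",
        r$odds_ratio, r$odds_ratio_cmle, r$p_one_tailed)
#> "OR = 1.82 (CMLE 1.82), one-tailed p = 1.1e-06"

## a small synthetic experiment through every stage
cfg <- simulation_config(n_mirnas_per_class = 2, genome_length = 60000,
                         library_depth_mean = 4000, seed = 11)
demo <- run_demo(tempdir(), cfg)

demo$run$isoform_summary[, c("dataset", "canonical_pct",
                             "noncanonical_pct", "nta_pct")]
#>     dataset canonical_pct noncanonical_pct nta_pct
#>   wt.UF0_2h          75.0              7.4    17.6
#>    wt.F0_2h          75.7              9.4    14.9
#>    wt.F2_4h          75.6              8.9    15.5
#>  mut.UF0_2h          74.2             12.1    13.8
#>   mut.F0_2h          76.8             11.0    12.2
#>  mut.F2_4h          73.0              9.2    17.9

head(demo$run$de$F2_4h[order(demo$run$de$F2_4h$PValue), ], 3)
#>  feature     logFC       LRT       PValue         FDR
#>  mir-004 -2.673570 13.775895 0.0002059620 0.001235772
#>  mir-010  1.865509 11.901028 0.0005610298 0.001683089
#>  mir-003 -2.990455  7.386325 0.0065721621 0.013144324

demo$run$downregulated
#> "mir-003" "mir-004"
```

The isoform percentages recover the planted 75/10/15 mixture (± sampling
noise at this tiny 4 000-read depth); the differential-expression stage
flags the miRNAs whose zygotic synthesis was suppressed in the simulated
mutant (negative logFC at FDR ≤ 5 % → `downregulated`), and
`demo$run$classes$classes` holds the A–E expression-class assignments.
At the default scale (50 miRNAs, 18 × 50 000 reads) the full run takes
about 1.5 minutes; every stage writes a provenance-stamped TSV under the
output directory.

A command-line wrapper lives at `inst/cli/mirmzt.R`
(`simulate`, `preprocess`, `all`, `overlap`, `demo` subcommands); see
`?run_cli`.

## Layout

* `R/` — modules: `simulate_*`/`reference` (synthetic data), `preprocess`,
  `align`/`annotate`, `isomir`, `quantify`, `profiles`, `overlap`,
  `pipeline`, `cli`.
* `vignettes/methods.Rmd` — the model, parameter rationale, what the
  simulator does and does not emulate, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code).
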