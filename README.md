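# mfclone

Clonal relatedness analysis of multifocal tumors from somatic variant
calls.

When a patient presents with several tumor nodules in one organ —
multifocal hepatocellular carcinoma is the motivating case — the nodules
either descend from one clone that spread (intrahepatic metastasis, IM) or
arose independently in a damaged organ (multicentric occurrence, MO). The
two histories carry different prognoses and must not be conflated in
downstream analysis. `mfclone` makes the call from the somatic SNVs/indels
of multi-region, multi-timepoint biopsies and carries it through to
patient-level classification, tumor-unit construction and similarity
analysis.

## What it computes

For a biopsy pair with variant sets *A*, *B* and per-variant cohort
frequencies *f<sub>v</sub>* (fraction of patients carrying *v*, floored at
*f*<sub>min</sub>):

- **Clonality score** — a rarity-weighted cosine overlap,
  *S(A,B) = Σ<sub>v∈A∩B</sub> w(v) / √(Σ<sub>A</sub> w · Σ<sub>B</sub> w)*
  with *w(v) = −log₁₀ max(f<sub>v</sub>, f<sub>min</sub>)*, so rare shared
  variants dominate.
- **Permutation p-value** — profiles of the observed sizes are redrawn from
  the cohort variant pool with probability proportional to frequency
  (without replacement within a replicate);
  *p = (1 + #{S<sub>perm</sub> ≥ S<sub>obs</sub>}) / (n<sub>perm</sub> + 1)*;
  a pair is **clonal** when *p ≤ 0.05*.
- **Patient class** — all nodule pairs clonal → IM; all non-clonal → MO;
  both → mixed.
- **Tumor units** — TMPs (connected clonal components of ≥ 2 nodules) and
  TNEMs (solitary tumors), with union-aggregated mutations, per-bin
  maximum-deviation copy number, representative (first) biopsies, fraction
  of genome altered, TMB and driver-gene counts.
- **Pair-class similarity** — clonal vs non-clonal vs random inter-patient
  biopsy pairs compared by layer correlations, categorical concordance and
  the standard two-sided tests (Mann–Whitney/Kruskal–Wallis, Fisher,
  chi-squared).

A synthetic-cohort generator with full ground truth (clonal partitions,
trunk variants, class-dependent expression programs) backs every test; see
`vignettes/clonality-methods.Rmd` for the model and its assumptions.

## Worked example

```r
library(mfclone)
library(dplyr)

res <- run_pipeline(pipeline_config(
  simulation = simulation_config(),  # 22 patients: 10 IM, 9 MO, 3 mixed
  n_perm = 999, seed = 1
), quiet = TRUE)

glance(res)
#> # A tibble: 1 x 9
#>   n_patients n_pairs n_clonal_pairs n_nonclonal_pairs  n_im  n_mo n_mixed n_tmp n_tnem
#>        <int>   <int>          <int>             <int> <int> <int>   <int> <int>  <int>
#> 1         22     195             96                99    10     9       3    13     33

res$patients |> count(label)
#> # A tibble: 3 x 2
#>   label     n
#>   <chr> <int>
#> 1 IM       10
#> 2 MO        9
#> 3 mixed     3
```

Of the 195 inter-nodule biopsy pairs, 96 are called clonal and 99
non-clonal, and all 22 simulated patients land in their generating class:
the 10 IM patients contribute one multi-nodule TMP each (13 TMPs with the 3
mixed patients), the 9 MO patients only TNEMs, and the mixed patients one of
each. `tidy(res)` returns the
per-pair score/p-value table, `res$records` the pair-class similarity
records (e.g. `plot_pair_class_metric(res$records, "cor_expr")`), and
`res$unit_metrics` per-unit FGA/TMB/driver counts. The same pipeline runs
from files (`pipeline_config(paths = ...)`) over a sample sheet TSV,
MAF-like mutation table, SEG copy-number segments and expression/signature
matrices; `write_cohort()` emits exactly those formats.

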