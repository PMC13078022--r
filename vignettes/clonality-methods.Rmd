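---
title: "Deciding whether multifocal tumors share a clonal origin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether multifocal tumors share a clonal origin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfclone)
library(dplyr)
```

## The problem

A third or more of hepatocellular carcinoma (HCC) patients present with
several tumor nodules in the liver at once. Two very different histories can
produce that picture: a single tumor seeded daughter lesions within the liver
(intrahepatic metastasis, IM), or chronic liver damage — the "field effect" —
gave rise to several independent tumors (multicentric occurrence, MO). The
distinction matters clinically (IM disease is more aggressive) and
analytically (treating independent tumors as one entity, or metastases as
replicates, corrupts any downstream comparison).

`mfclone` decides the question from somatic variant calls. Biopsies from the
same clone share *trunk* mutations acquired before dissemination; biopsies
from independent tumors share variants only through chance recurrence, which
is overwhelmingly a property of common, hotspot-like variants. The package
scores every pair of biopsies from different nodules of a patient, converts
pair calls into a patient-level classification (IM / MO / mixed), groups
nodules into *tumor units* — TMPs (sets of clonally related tumors, i.e.
tumors that demonstrably metastasized) and TNEMs (solitary tumors with no
evidence of metastasis) — and quantifies how similar clonal, non-clonal and
inter-patient biopsy pairs are across molecular layers.

## The clonality statistic

For a pair of variant profiles $A$ and $B$ the score is a rarity-weighted
cosine overlap:

$$S(A,B) \;=\; \frac{\sum_{v \in A \cap B} w(v)}
{\sqrt{\sum_{v \in A} w(v)\; \cdot\; \sum_{v \in B} w(v)}},
\qquad w(v) = -\log_{10}\!\big(\max(f_v, f_{\min})\big),$$

where $f_v$ is the *cohort frequency* of variant $v$: the fraction of
patients in whose tumors $v$ was called. A variant is counted once per
patient regardless of how many biopsies carry it, so multiply-biopsied
clones do not inflate frequencies. The floor $f_{\min}$ (default
$1/(2\,n_\text{patients})$, i.e. half a patient) keeps weights finite. The
score is symmetric, equals 0 exactly when nothing is shared and 1 exactly
when the profiles coincide; sharing one 1-in-44-patients variant
($w \approx 1.6$) counts for as much as sharing five hotspot variants
carried by half the cohort ($w \approx 0.3$).

Significance comes from a frequency-matched permutation null: each replicate
redraws variant sets of the observed sizes $|A|$ and $|B|$ from the cohort
variant pool with probability proportional to cohort frequency, without
replacement within a replicate, and rescores. With $n_\text{perm}$
replicates,

$$p = \frac{1 + \#\{S_\text{perm} \ge S_\text{obs}\}}{n_\text{perm} + 1},$$

so $p \ge 1/(n_\text{perm}+1)$ and ties count against significance
(conservative). A pair sharing no variant has $S_\text{obs}=0$; every null
score is $\ge 0$, so its p-value is exactly 1 and no permutations are spent.
A pair is called **clonal** when $p \le \alpha$ with $\alpha = 0.05$
(boundary inclusive, the conventional two-sided significance rule used
throughout the package). The permutation loop is compiled (Rcpp) and uses
exponential-key weighted sampling; each pair draws its RNG stream from
`(master seed, biopsy pair)`, so results are independent of iteration order
and fully reproducible.

Why cohort frequencies rather than an external population resource: somatic
recurrence is cohort- and tissue-specific, the same table is available for
any input the package ingests, and the null then matches the frequency
structure the score itself uses. The cost is estimation noise in small
cohorts — a variant seen once in 22 patients gets frequency 1/22 even if it
is much rarer — which makes the null slightly conservative for null pairs
(it overweights rare variants, inflating null sharing). We consider
conservative pair calls the right failure mode for a classifier whose
positive call asserts metastasis.

## From pairs to patients and tumor units

* **Nodule relation.** A nodule pair is *clonal* if **any** supporting
  biopsy pair is clonal. One confident match is positive evidence of shared
  origin, while dropout can mask sharing in other biopsy combinations;
  conflicting biopsy-level calls are flagged, never silently resolved.
* **Patient class.** All nodule pairs clonal → IM; all non-clonal → MO; both
  kinds → mixed. The relation graph must be complete, and pairs of biopsies
  from the *same* nodule are never used — they carry no information about
  relatedness between tumors.
* **Tumor units.** TMPs are the connected components (≥ 2 nodules) of the
  clonal relation; singletons are TNEMs. Components treat clonality as
  transitive. An intransitive triangle (A~B, B~C, but A and C called
  unrelated) is possible under noisy calls; the component rule keeps the
  three nodules together, flags the unit and warns. For such graphs the
  patient label (mixed, because both pair kinds exist) intentionally does
  not match a reconstruction from the units — the flag is the signal to
  inspect the calls.
* **Aggregation.** A unit's mutation profile is the exact union over member
  biopsies. Its copy-number profile takes, per bin, the state with the
  largest absolute deviation from neutral ploidy, so a deep loss in one
  biopsy survives neutral states elsewhere; a gain/loss tie of equal
  magnitude resolves to the gain and is flagged. Scalar summaries (TMB,
  set scores) use the earliest biopsy of each member nodule (timepoint
  ties → lexicographically smallest biopsy id, flagged), and clinical status
  uses the nodule containing the unit's globally earliest biopsy.

## The pair-class similarity framework

Every intra-patient inter-nodule pair is labeled clonal or non-clonal by the
test; 50 inter-patient pairs (sampled uniformly from all cross-patient tumor
biopsy pairs under a named substream) provide the between-individuals
yardstick. Per pair the package computes layer correlations (copy-number
states, signature activities, expression; Spearman by default, Pearson
optional) and categorical concordance (grade, growth pattern, molecular
subtype; for liver segment, "same or neighboring Couinaud segment" counts as
concordant under a configurable adjacency). Group comparisons use the
standard two-sided machinery: Mann–Whitney U (exact when the pooled sample
is ≤ 10 and tie-free, tie-corrected normal approximation otherwise),
Kruskal–Wallis for ≥ 3 groups, Fisher's exact test (probability-mass rule)
for 2×2 tables and chi-squared without continuity correction for larger
ones. No multiple-testing correction is applied by default — single
pre-specified comparisons at $\alpha = 0.05$ — but `adjust_pvalues()` adds
Benjamini–Hochberg FDRs for exploratory tables.

The headline sharing statistic for clonal pairs pools driver-gene variant
occurrences over all clonal pairs (a variant occurrence is *shared* if
present in both members); the mean of per-pair fractions is reported
alongside, since the two denominators can differ when pair sizes vary.
For non-clonal and inter-patient pairs the package reports how often both
members carry *different* variants of the same driver gene — convergent
evolution, which must not be mistaken for clonality and is the reason
variant identity is matched at `chrom:pos:ref:alt` resolution, never at
gene level.

## The synthetic cohort generator

Real multifocal multi-omics cohorts are controlled-access, so validation
runs on generated cohorts with known truth. The generator emulates:

* **Cohort structure** — by default 22 patients (10 IM, 9 MO, 3 mixed), 2–4
  tumor nodules each, 1–2 biopsies per nodule at consecutive timepoints, and
  1–2 non-tumor liver (NTL) biopsies per patient.
* **Mutations** — a pool of 10,000 variants with power-law frequency
  spectrum $f_r \propto r^{-\gamma}$. Clonal sets share a Poisson(20) trunk
  drawn frequency-proportionally; every nodule adds Poisson(30) private
  variants; every biopsy drops each nodule variant with probability 0.05
  (sampling/calling dropout). The exponent $\gamma = 0.5$ was chosen from
  carriage targets, not fitted: it puts the most common pool variant in
  roughly a fifth of nodules (hotspot-like) and keeps the expected chance
  overlap between two independent profiles below about one variant. Steeper
  spectra concentrate frequency-proportional draws so hard that every
  nodule carries the same top-ranked variants, which neither resembles
  somatic data nor leaves the test anything to discriminate.
* **Copy number** — 440 one-megabase bins on 22 chromosomes; per chromosome
  a clone-shared event (probability 0.25; gain to 3–4 or loss to 0–1 over a
  contiguous run) and nodule-private events (probability 0.1), so clonal
  pairs co-segregate events and independent nodules do not.
* **Expression** — 1,000 genes at gene-level means $\mathcal{N}(6, 1.2)$
  with clone-level ($\sigma = 0.5$), nodule-level ($\sigma = 0.3$) and
  biopsy-level ($\sigma = 0.5$) variation. Tumors in multi-nodule clonal
  sets shift a 50-gene cell-cycle set by +1 log2 unit (proliferative
  programs of metastasizing clones); the NTL of MO patients shifts a
  50-gene fibrosis set by +1 log2 unit (field-effect surrogate; mixed
  patients are left unshifted as genuinely ambiguous). There is deliberately
  no patient-level expression effect in tumors: with one, non-clonal pairs
  would be more similar than inter-patient pairs by construction, assuming
  away the question the framework asks.
* **Signatures** — five liver-relevant signature labels with
  Dirichlet-distributed weights per clone, scaled by each biopsy's mutation
  count.

What the generator does **not** emulate: subclonal structure and cancer-cell
fractions, allele-specific copy number, purity and coverage variation,
realistic signature profiles, and batch structure. Passing tests therefore
demonstrate that the statistical machinery behaves as specified under its
own model — calibration of the null, sensitivity to rare shared trunk
variants, exact aggregation — not that any particular real cohort would be
classified correctly.

## Numerical choices and problem sizes

* Defaults: `n_perm = 999`, `alpha_clonal = 0.05`, `f_min = 1/(2 n)`,
  `bin_size` 1 Mb, `callable_mb = 35` (typical exome footprint),
  `n_inter = 50`.
* Validation sizes, chosen as the smallest that make the binomial noise
  bands informative: calibration uses 1,000 truly independent pairs
  (1,000 two-nodule MO patients) — the observed null clonal-call rate must
  fall in the binomial 95% band [0.037, 0.065] around the nominal 0.05;
  sensitivity uses ~150 clonal pairs qualified by sharing ≥ 5 trunk variants
  of pool frequency ≤ 0.01 (≥ 95% must be called clonal); label recovery
  uses five cohorts of 25 patients (≥ 90% required); classification
  invariants are enumerated exhaustively over all relation graphs on ≤ 5
  nodules.
* Degenerate inputs: empty variant profiles have no defined score (error);
  constant profiles have no defined correlation (`NA` with warning);
  zero-variance reference genes are excluded from set scores with a
  warning; a kind with zero units reports `NA` summaries, not zeros.

## Limitations

The clonality call is mutation-based only; copy-number evidence enters the
similarity framework but not the test itself, and no phylogeny or seeding
order is reconstructed. Cohort-frequency weighting needs a cohort — for a
single patient the null degenerates and an external recurrence resource
would be required. The mixed class inherits the union of IM and MO biology;
where a statement depends on that composition the package reports classes
separately rather than pooling.
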