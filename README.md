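# wellington

Strand-aware digital genomic footprinting for DNase-seq data, in R.

## The problem

Transcription factors bound to open chromatin protect their binding sites
from DNase I cleavage, leaving *footprints*: short (~11–26 bp) spans inside
DNase I hypersensitive sites (DHSs) that are depleted of cuts relative to
their immediate flanks. In data produced by the double-hit DNase-seq
protocol, size selection of the sequenced fragments additionally imprints a
characteristic **strand imbalance** around bound sites: tags aligning to the
+ strand pile up immediately *upstream* of the protected region, and tags
aligning to the − strand immediately *downstream*. Footprinting methods that
ignore alignment strand mistake junctions between adjacent shoulders for
protein-bound depletions; exploiting the imbalance removes these "ghost"
false positives without any prior motif knowledge.

## The statistic

For every base of every DHS, consider a candidate footprint of length
*l*<sub>FP</sub> centred there, with shoulders of length *l*<sub>SH</sub> on
each side. Let FP⁺ and SH⁺ be the + strand 5′-cut counts inside the
footprint and in the *upstream* shoulder, and FP⁻, SH⁻ the − strand counts
inside the footprint and in the *downstream* shoulder. Under the null that
counts are proportional to region length, each strand is a binomial sample
with success probability *p* = *l*<sub>FP</sub> / (*l*<sub>FP</sub> +
*l*<sub>SH</sub>), and the two strands are treated as independent. With
*T*(*k*, *n*) = P(X ≤ *k*) for X ~ Binomial(*n*, *p*), the footprint
p-value is the product of the two lower tails:

> p = T(FP⁺, FP⁺ + SH⁺) · T(FP⁻, FP⁻ + SH⁻)

The per-base score (as a log₁₀ p-value) is the minimum over a grid of
footprint lengths (default 11–26 bp) and shoulder lengths (default fixed at
35 bp), assigned to the footprint-centre base. Footprints are then called by
greedy selection of non-overlapping windows below a p-value cutoff. Three
modes are available: **forward** (the test above), **reverse** (the mirrored
pairing, a negative control whose hits are artefacts), and **1D** (a
strand-agnostic pooled test, for comparison and for single-hit data).

## Worked example

Simulate a 600 bp DHS with two planted 16 bp footprints (90% cut depletion,
3× shoulder boost), write it to an indexed BAM, and recover the footprints:

```r
library(wellington)

d <- simulate_dhs(simulation_spec(seed = 7))
d
#> # Synthetic DHS chrS:100-700: 2 planted footprints, 708 cuts (seed 7)

bam <- emit_alignments(d, "example.bam")
profile <- extract_cuts(bam, genomic_intervals("chrS", 100, 700))
track <- score_interval(profile, length_grid(), mode = "forward")
glance(track)
#> # A tibble: 1 × 8
#>   chrom start   end mode    n_bases n_scored min_log10p pos_min
#>   <chr> <int> <int> <chr>     <int>    <int>      <dbl>   <int>
#> 1 chrS    100   700 forward     600      520      -15.9     459

footprints <- call_footprints(track, log10p_cutoff = -10)
footprints
#> # A tibble: 2 × 10
#>   chrom start   end name  score strand centre  l_fp  l_sh log10p
#>   <chr> <int> <int> <chr> <dbl> <chr>   <int> <int> <int>  <dbl>
#> 1 chrS    448   470 FP_1   15.9 .         459    22    35  -15.9
#> 2 chrS    617   633 FP_2   12.1 .         625    16    35  -12.1

recapitulation_rate(footprints, d$truth)
#> # A tibble: 1 × 4
#>    rate n_sites n_recapitulated footprint_bp
#>   <dbl>   <int>           <int>        <int>
#> 1     1       2               2           38
```

Both planted footprints are called (minimum score log₁₀ p ≈ −15.9 at base
459, inside the first planted print), each recovering its planted interval
under the 70% reciprocal-containment rule. `score` in the footprint table is
−log₁₀ p; `l_fp`/`l_sh` are the per-site maximum-evidence window lengths.
Running the same track in `mode = "reverse"` calls nothing at this cutoff.

`autoplot()` methods render cut profiles, score tracks, average strand
profiles, imbalance heat-map matrices and ROC curves; `tidy()`/`glance()`
turn tracks and ROC objects into tibbles.

## Command line

```sh
Rscript exec/wellington_footprints.R reads.bam dhs.bed outdir \
    [--fp-min 11 --fp-max 26 --fp-step 1 --shoulder 35 \
     --mode forward|reverse|1d --cutoffs=-10,-20,-30 --min-mapq 0 --pad 0]
Rscript exec/wellington_sim.R --out prefix [--n-dhs 20 --seed 1 ...]
```

`wellington_footprints.R` writes `scores.wig` (fixedStep log₁₀ p-values)
and one BED6 `footprints.p<cutoff>.bed` per cutoff; `wellington_sim.R`
emits simulated DHSs as an indexed BAM plus truth and DHS BED files.

## Validation utilities

`recapitulated()` / `recapitulation_rate()` implement the 70%
reciprocal-containment criterion against ChIP-seq confirmed sites;
`roc_auc()`, `positive_predictive_value()` and `nucleotide_performance()`
score bound/unbound motif-instance classification; `mean_signal_profile()`
and `motif_content()` aggregate per-base tracks and motif locations over
footprints; `average_strand_profile()` and `imbalance_matrix()` reproduce
the strand-resolved aggregate views in which the imbalance is visible.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the classification
boundary of the reciprocal-containment rule (by sweeping the overlap of a
20 bp footprint against a 20 bp site one base at a time) and writes the
result as JSON.
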