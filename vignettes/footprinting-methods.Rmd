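---
title: "Strand-aware footprinting: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-aware footprinting: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellington)
```

## The model

DNase I cleaves accessible DNA; a protein bound at a specific site shields
its binding site from cleavage. In DNase-seq, each sequenced tag's 5′ end
marks one cleavage event, so a bound site appears as a short span (a
*footprint*) whose per-base 5′ cut counts are depleted relative to the
surrounding open chromatin. In libraries made with the double-hit protocol,
size selection keeps fragments cut at both ends, which biases sequencing
toward fragments that *span* protected sites: their upstream ends align to
the + strand and their downstream ends to the − strand. Around a bound site
this produces an excess of +strand cuts just upstream and −strand cuts just
downstream — the strand imbalance this package exploits.

For a candidate footprint of length $\ell_{FP}$ centred at a base, with
shoulders of $\ell_{SH}$ bp on each side, let $FP^+$ and $SH^+$ be the
+strand cut counts in the footprint and the *upstream* shoulder, and $FP^-$,
$SH^-$ the −strand counts in the footprint and the *downstream* shoulder.
Under the null hypothesis that counts are proportional to region length,
$FP^+ \mid FP^+ + SH^+$ is binomial with success probability
$p = \ell_{FP} / (\ell_{FP} + \ell_{SH})$, and likewise for the − strand.
The footprint p-value is the product of the two inclusive lower tails,

$$
p\text{-value} \;=\; T\!\big(FP^+,\, FP^+ + SH^+\big)\cdot
                     T\!\big(FP^-,\, FP^- + SH^-\big),
\qquad T(k, n) = \Pr\big(X \le k\big),\; X \sim \mathrm{Bin}(n, p),
$$

treating the strands as independent: a sequenced fragment contributes at
most one read of either orientation near a given site, so the two strand
counts come from (essentially) disjoint fragment ends.

**Assumptions worth keeping in mind.** The null is local uniformity of the
cut rate over footprint-plus-shoulders; sequence-dependent cleavage bias,
TF-specific cleavage signatures and nucleosome edges all violate it to some
degree and are not modelled. The test is one model for all factors; methods
that learn per-motif models can exploit factor-specific shapes but cannot
score arbitrary loci.

### Tail convention

A literal "probability of at least $k$ successes" complement would make the
score $\Pr(X < k)$, which is identically 0 whenever the footprint contains
zero cuts — yet an empty footprint against full shoulders is the *strongest*
possible evidence. We therefore use the inclusive lower tail
$\Pr(X \le k)$, under which the empty-footprint case behaves correctly:
$T(0, n) = (1-p)^n$, e.g. $(35/51)^{100} \approx 4.5\times10^{-17}$ for
$\ell_{FP}=16$, $\ell_{SH}=35$ and 50 shoulder cuts per strand. This
inclusive tail is the documented, tested contract throughout.

### Modes

* **forward** — the test above; significant sites show the canonical
  imbalance.
* **reverse** — the mirrored pairing (upstream shoulder on the − strand,
  downstream on the + strand). Reverse-only hits are "ghost" depletions
  between or beside true footprints; the mode exists as a negative control,
  and `reverse` on a profile is implemented exactly as `forward` on the
  strand-swapped profile, a duality the suite property-tests.
* **one_d** — a strand-agnostic variant for comparison and for single-hit
  data, where the imbalance is weak. Its exact published form is not
  available to us, so we state ours: pool both strands over the footprint
  ($k = FP^+ + FP^-$) and both strands over *both* shoulders, and take a
  single lower tail with success probability
  $\ell_{FP} / (\ell_{FP} + 2\ell_{SH})$, the length-proportional null on
  the pooled track. We chose this over the superficially simpler
  "$SH^+ + SH^-$ only" pooling because that form is not invariant under
  swapping the strand labels of the input — an asymmetry a strand-agnostic
  statistic should not have. Swap-invariance of `one_d` is asserted in the
  test suite.

### Window-length selection and centring

At every base the statistic is evaluated over a grid of
$(\ell_{FP}, \ell_{SH})$ values — defaults $\ell_{FP} \in \{11,\dots,26\}$
(step 1, exposed as a flag since the original step size is unstated) and
$\ell_{SH} = 35$ — and the minimum p-value with its arg-min lengths is
assigned to the centre base. We read the per-footprint "maximum likelihood"
selection of lengths as this exhaustive evidence-maximising grid search: it
is deterministic and reduces to the stated defaults. A footprint of length
$\ell$ centred at $c$ occupies $[\,c - \lfloor \ell/2 \rfloor,\;
c - \lfloor \ell/2 \rfloor + \ell\,)$, fixing the centre for even lengths;
interval midpoints elsewhere in the package
(`interval midpoint = start + floor(length/2)`) use the same convention so
scores, calls and aggregations line up.

Scores are stored and thresholded as $\log_{10}$ p-values: interesting
thresholds (e.g. $10^{-30}$, the published figure-level cutoff) underflow in
linear space at deep coverage, so all tail arithmetic is done with
`pbinom(log.p = TRUE)`.

### Calling

Candidates at or below the cutoff are visited best-score-first (ties broken
by leftmost coordinate, for cross-platform determinism) and accepted iff
their span shares no base with an accepted footprint — overlap means any
shared base, the strictest reading of greedy selection; touching footprints
are allowed. Bases whose window would leave the DHS score 0 and are never
called; the optional `pad` argument instead extends each DHS with reads from
outside it before scoring and trims the track back afterwards. No padding is
the default because the scanning unit is the DHS as provided.

## The synthetic world

`simulation_spec()` states one generative world and the whole suite tests
against it: per-base per-strand Poisson counts at 0.5 cuts/bp/strand
(deep-coverage ENCODE scale), 600 bp DHSs (typical hypersensitive-site
size), two planted 16 bp footprints with 90% depletion on both strands, a
3× boost of the +strand rate over the 35 bp upstream of each footprint and
of the −strand rate downstream, footprints ≥ 90 bp apart (so shoulders of
neighbouring prints never overlap) and at least $\ell_{SH} + \ell_{FP}$ from
the DHS edges (so every planted centre is scoreable). `emit_alignments()`
turns a profile into single-end 36 bp reads (ENCODE-era tag length), one
record per cut, such that cut extraction inverts emission exactly — the
keystone round-trip contract.

What the generator does **not** emulate: fragment-level double-hit size
selection (only its marginal rate structure), sequence-dependent cleavage
bias, TF-specific multi-modal cleavage shapes, nucleosome positioning, and
mapping artefacts. A green recovery test therefore establishes that the
statistic and caller detect the stated depletion-plus-imbalance pattern at
realistic coverage — not that they are robust to every feature of real
chromatin.

## Validation choices

* The recapitulation rule classifies a footprint/site pair as a hit when at
  least 70% of either interval is contained in the other; the boundary is
  exactly at 70% (14 of 20 bases) and the threshold is a parameter.
* The footprint evidence at a motif site (for ROC and PPV) is the minimum
  $\log_{10}$ p over the bases the site covers; the published analyses pair
  p-values with motif instances without stating the reduction, and the
  site-minimum is the natural "best footprint touching the site" choice.
* The nucleotide performance coefficient is the standard base-level
  $TP/(TP+FP+FN)$; the source analyses cite an external assessment for the
  formula, which is not reprinted, so the standard form is implemented and
  tested (including invariance under splitting intervals).
* ROC curves group tied scores into a single step and integrate
  trapezoidally, which makes the area equal to the mid-rank Mann–Whitney
  statistic divided by $n_1 n_2$; the suite checks exactly that identity.
* Missing values in per-base signal tracks (conservation tracks have gaps)
  are excluded from per-offset means, not zero-filled.
* Heat-map row ordering is parameterised by an arbitrary per-site key
  (default: total cuts in the window), since the occupancy score used for
  the published ordering is defined elsewhere.

## Numerical and degenerate-input policy

Zero counts everywhere give p = 1 (score 0) rather than an error; a grid
that fits nowhere in a profile warns and returns an all-zero track; WIG
output prints scores at full double precision (`%.17g`) so parsed tracks are
bit-identical; BED scores are $-\log_{10}p$ rounded to two decimals; empty
DHS lists produce empty outputs and a success exit.

## Known limitations

Single-hit-protocol data carry weaker imbalance, and the forward test loses
its advantage over `one_d` there; the package provides the modes but no
protocol detection. There is no FDR control across footprints, no
replicate merging, and no cleavage-bias correction. The simulator's
independence assumptions make its power estimates optimistic relative to
real chromatin.
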