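---
title: "The CNBP (DM2) complex repeat locus: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CNBP (DM2) complex repeat locus: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnbprepeat)
```

## The locus and its grammar

Myotonic dystrophy type 2 (DM2) is caused by an uninterrupted CCTG
expansion in intron 1 of *CNBP* on chromosome 3q21.3. The CCTG array sits
inside a composite tandem repeat that this package treats as a formal
grammar:

$$(TG)_v\,(TCTG)_w\,(CCTG)_x\,(NCTG)_y\,(CCTG)_z$$

where NCTG denotes the interruption tetramers GCTG, TCTG or ACTG. In
healthy-range alleles the CCTG array is usually broken by such a window,
which stabilises the locus; pathogenic alleles carry a pure CCTG tract of
75 to roughly 11,000 units. The tract length in base pairs is
$2v + 4(w + x + y + z)$, the sizing convention under which the sequenced
extreme structures sum exactly to their fragment-analysis sizes
(`(TG)18(TCTG)10(CCTG)23` = 168 bp; `(TG)16(TCTG)7(CCTG)5(NCTG)3(CCTG)4`
= 108 bp).

Three conventions pin the representation down; they are the only ones
under which rendering and parsing are mutually inverse:

* **Interruption window.** The block is the *minimal* window spanning the
  first to the last non-CCTG tetramer; internal CCTGs belong to the
  window and count towards $y$. This is also the only convention that
  reproduces the bp arithmetic of the worked 138/130-bp structures.
* **Uninterrupted alleles** store all CCTG units in $x$ ($y = 0$ forces
  $z = 0$).
* **A nonempty window requires $x \ge 1$.** Otherwise a window beginning
  with TCTG could donate its leading labels to the $w$ segment and the
  decomposition would not be unique.

The parser resolves the TG/tetramer boundary greedily: a maximal run of
TG dinucleotides, then an in-frame tetramer section. Greediness is not a
heuristic here -- `TGTC`, `TGGC`, ... are not admissible tetramers, so the
greedy parse is the unique grammar-consistent one. The test suite checks
this against an independent brute-force enumerator of *all*
segmentations: on random tracts up to 80 bp, exactly one valid
segmentation exists and it equals the parser output.

By default `decompose_tract()` requires the grammar region to span the
whole input. Because every rendered tract has length $2v + 4k$, a single
inserted base always breaks that parity and fails loudly; there is no
silent re-framing of corrupted input. `full = FALSE` switches to
location-within-context (exactly one parseable region must exist, and
its 0-based half-open coordinates plus the matching strand are
reported); the reverse complement is tried only when the forward strand
fails.

## Allele classification

Structural classes follow the four-class scheme of sequenced
healthy-range alleles and key on the window size $y$, not the CCTG
total, because the printed CCTG ranges of the two interrupted classes
overlap: `short_interrupted` ($y=3$), `long_interrupted` ($y=5$),
`short_uninterrupted` ($y=0$, total $\le 12$), `long_uninterrupted`
($y=0$, total $\ge 22$); anything else is `unclassified` rather than
forced into a class.

Diagnostic categories apply configurable thresholds
(`class_thresholds()`) to the *effective* uninterrupted CCTG count: the
longest CCTG run for sequenced alleles, the upper bound of the mosaic
count range for fragment-only alleles (conservative with respect to
escalation; both bounds are kept in reports). Defaults are normal
$\le 26$, gray-zone premutation 27--74, pathogenic $\ge 75$. The
literature also contains a "<25 copies" phrasing of the normal bound;
we follow the guideline formulation ("up to 26 with one or more
interruptions") and expose `normal_max` as a parameter rather than
hard-coding the discrepancy away. Interrupted alleles are always normal
regardless of their CCTG total, since pathogenicity is a property of the
pure array.

## The diagnostic workflow model

The simulator mirrors the three-step molecular protocol:

1. **SR-PCR** sizes alleles up to 40 CCTG repeats; larger alleles yield
   no product. Two distinct bands exclude an expansion. Gray alleles of
   27--40 repeats *are* amplifiable: they appear as a sized band and are
   recognised by sizing plus sequencing, so they are called premutation
   even in a two-band genotype.
2. **TP-PCR** is modeled as a Bernoulli detector with probability
   `detection_rate` (default 0.99, the reported aggregate detection rate
   of the TP-PCR/LR-PCR combination) that fires when any allele reaches
   the gray-zone bound. Only the aggregate rate is reported in the
   diagnostic literature, so no ladder-signal shape is modeled.
3. **LR-PCR** is modeled as a perfect resolver of one-band ambiguity up
   to the premutation range: a detected signal over a pathogenic allele
   is `positive`, over a gray allele `premutation`; a pathogenic
   expansion missed by the detector (probability `1 - detection_rate`)
   leaves the test `inconclusive` rather than falsely negative.

With `detection_rate = 1` the workflow's confusion matrix against the
generating status is exactly diagonal on simulated cohorts, and at rate
$p$ its sensitivity on expanded genotypes converges to $p$; both are
asserted in the tests at 3 binomial standard errors. All randomness
flows through one seeded generator (`run_assay(seed = )`).

## Packaged fixtures

Two deterministic fixtures reconstruct published summary data in
computable form; both are built in code, bit-identically across runs.

**Sequenced-allele catalogue (103 alleles).** The printed composition is
exact: 64 alleles with core `(CCTG)5(NCTG)3(CCTG)7` (62.1%), 21 with
`(CCTG)6(NCTG)3(CCTG)7` (20.4%), 9 copies each of the full 138-bp and
130-bp motifs (8.7% each), 91 three-tetramer vs 7 five-tetramer windows
over the 98 interrupted alleles (92.9%/7.1%), and 5 uninterrupted
alleles including `(CCTG)10`, `(CCTG)12` and the 168-bp structure. The
flanks of the remaining alleles are not individually published, so they
are fixed, documented choices spread over the observed ranges ($v$
14--26, $w$ 7--11); the percentage denominators (103 and 98) reproduce
every printed decimal exactly.

**Length spectrum (756 chromosomes, 25 lengths).** Only five per-length
frequencies are published (138 bp 21%, 134 bp 13%, 140 bp 11%, 136 bp
10%, 142 bp 7%); these are fixed as `round(p * 756)` chromosomes. The
residual 287 chromosomes are spread over 20 further even lengths in
108--168 bp (both endpoints included) by largest-remainder assignment
under a geometric decay away from the mode (ratio 0.7 per 2 bp, floor of
one chromosome per length). The decay constant is a fixture choice, not
an estimate: it makes the spectrum unimodal with sparse tails, as
published spectra of this locus are. Expected heterozygosity of the
resulting spectrum is $1 - \sum p_i^2 \approx 0.899$, consistent with
the reported ~90% locus heterozygosity -- which is also why we read the
one passage describing "homozygosity frequency of 90%" as a slip for
heterozygosity. Unimodality is assessed after pooling sorted lengths
into consecutive pairs (4-bp bins), which absorbs single-length noise.

```{r}
st <- spectrum_stats(build_length_spectrum())
c(distinct = st$distinct_alleles, mode_bp = st$mode_bp, mode_pct = st$mode_pct)
round(expected_heterozygosity(build_length_spectrum()), 3)
```

## The cohort generator

`simulate_cohort()` emulates a referral cohort of a diagnostic registry,
with defaults set once to the study conditions:

* `positivity = 0.328` (187/570 confirmed tests) and
  `premutation_rate = 5/570` (five characterised carriers);
* expanded-allele counts uniform on `expansion_range = c(75, 11000)`
  (the reported range; a uniform draw also matches the reported mean of
  roughly 5,000), with a somatic-mosaicism range of relative width
  `mosaic_width = 0.05` around the drawn centre, matching reported
  ranges such as 51--53 and 53--55;
* gray-zone carriers get one uninterrupted allele of 27--74 repeats with
  a full decomposition (so it can be rendered and sized); expanded
  alleles are represented by their count range only and are never
  rendered (a full expansion would be up to ~44 kb of CCTG);
* normal alleles are two independent draws from the packaged spectrum
  (Hardy--Weinberg sampling), instantiated as grammar-valid sequences by
  `length_to_decomposition()`, a deterministic priority rule (modal
  three-tetramer core first, flanks absorb the length variation --
  mirroring the observation that $v$ and $w$ are the hypervariable
  parts);
* indication labels are per-label Bernoulli draws:
  rates among positives from the published profile of confirmed patients
  (myotonia 0.35, familiarity 0.37, hyperCKaemia 0.19, asthenia 0.18,
  weakness 0.15, cataract 0.11, cardiac/endocrine 0.04, myalgia 0.15);
  rates among negatives back-solved so the cohort-wide profile matches
  the request-level rates at 32.8% positivity;
* positives receive an onset age drawn from Normal(49, 16.9).

What the generator does *not* emulate: linkage between indications
(labels are independent given status), founder haplotype structure,
intergenerational transmission dynamics, germline instability of short
uninterrupted alleles, and any genotype--phenotype correlation (onset
age is independent of repeat count, as reported for this locus but not
modeled beyond that). Passing tests therefore validate the arithmetic
and the workflow logic under idealised sampling, not the clinical
realism of any individual record. In particular, onset age and the
indication profile are generator *parameters*; the package deliberately
offers no estimator that would present them as findings recoverable
from simulated data.

## Numerical conventions

* Percentages are rounded half away from zero to one decimal, the
  reporting style of the reconstructed tables (base `round()`'s banker's
  rounding would turn 32.85 into 32.8 or 32.9 depending on parity).
* The spectrum mode breaks ties deterministically towards the smaller
  length and flags the tie.
* Coordinates are 0-based half-open throughout; strands are `+`/`-`.
* Count-only alleles below the SR-PCR cap are sized as $76 + 4n$ bp
  (nominal flanks $v = 20$, $w = 9$, the range medians); this only
  matters for hypothetical fragment-only calls in the 27--40 range,
  since simulated carriers carry full decompositions.
* Problem sizes in the checks: grammar round trips run over $10^4$
  random decompositions ($v \le 40$, $w \le 15$, $x+y+z \le 80$), the
  brute-force segmentation oracle over $10^3$ tracts of at most 80 bp,
  and the workflow/recovery properties over one seeded cohort of
  $10^4$ individuals, where 3-binomial-SE tolerances are tight enough
  to be meaningful (about 1.4 percentage points on positivity).

## Known limitations

* The catalogue's unpublished flank sizes and the spectrum's residual
  tail are documented reconstructions; statistics that depend only on
  the published marginals (core frequencies, window split, mode, range,
  heterozygosity) are exact, while any statistic that would depend on
  the joint distribution of flanks and cores is fixture-dependent.
* The assay model has no stutter, no electropherogram signal, no
  Southern-blot sizing of full expansions, and a binary LR-PCR; it is a
  decision-tree model of call logic, not of chemistry.
* Penetrance of gray-zone alleles is deliberately out of scope: carriers
  are a diagnostic category here, never a phenotype prediction.
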