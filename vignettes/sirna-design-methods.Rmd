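---
title: "Methods: guideline-based siRNA design and knockdown dose-response modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guideline-based siRNA design and knockdown dose-response modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnadesign)
```

## Scope

`sirnadesign` designs 21-nt siRNA duplexes against mRNA targets for direct
injection RNAi in insect embryos (the setting it was calibrated for is
silkworm, *Bombyx mori*), screens the chosen cores against a transcriptome
for near-exact off-target matches, and models the dose dependence of the
resulting knockdown. Everything operates on plain tabular data: transcripts,
candidate sites, off-target hits and dose-response observations are all
tibbles, so the functions compose with dplyr pipelines.

## The design guideline

A candidate is a 19-nt *core* on the mRNA (sense orientation) together with
the 12-nt flank on each side. The duplex built from a core has a sense
strand `core + next-2-mRNA-bases` and an antisense (guide) strand
`revcomp(core) + UU`, i.e. 19 paired bases and 2-nt 3′ overhangs on both
strands. Eight criteria grade a candidate:

| criterion      | quantity                                           | role        |
|----------------|----------------------------------------------------|-------------|
| `GC_CORE`      | GC% of the 19-nt core, wants 35–55%                | hard filter |
| `SENSE_5P`     | first core base, wants G/C                          | hard filter |
| `ANTISENSE_5P` | complement of the last core base, wants A/U         | hard filter |
| `AU_SEED7`     | A/U count in the antisense 5′ 7-mer, wants ≥ 4      | hard filter |
| `POSITION`     | core start ≥ 75 nt past the end of the AUG codon    | filter      |
| `FLANK_GC`     | GC% pooled over the 24 flanking nt, wants 50%       | rank        |
| `OVERHANG_S`   | sense overhang class: UU > AA > U· / ·U > other     | rank        |
| `OVERHANG_AS`  | antisense overhang pairs with the target (mRNA `AA` upstream) | rank |

The first four criteria describe the duplex itself: moderate GC content and
an AU-rich, loosely paired antisense 5′ end bias RISC loading toward the
guide strand. The position criterion keeps the duplex clear of
translation-initiation factor binding. Flanking GC matters empirically:
target regions whose 12-bp flanks averaged 58%, 37% or 25% GC silenced
poorly compared with sites flanked at about 50%, so deviation from 50% is
the primary ranking key rather than a hard cutoff — no validated numeric
band exists, and `design_params(flank_gc_max_dev = )` is provided for users
who want to impose one.

`design_sirnas()` runs the staged procedure: enumerate every placement with
complete flanks; keep candidates passing the four sequence filters; keep
those far enough downstream of the AUG; rank the survivors by
`(flank-GC deviation, sense-overhang class, antisense-overhang class,
position)`; and flag the best two non-overlapping candidates as selected.
Ties in every key are broken by position, so the output is a total,
deterministic order. All survivors are returned, not only the selected
pair, so the full ranking can be inspected.

### Interpretation choices

Several readings were genuinely open and are fixed here as package policy:

* **"More than 3 A/U"** in the seed 7-mer means a count of at least 4.
* **"75 bp downstream of the initiation codon"** is measured from the base
  after the codon: `start − (cds_start + 3) ≥ 75`. This is the conservative
  reading that keeps the whole duplex clear of the initiation region.
* **Core GC** is computed over the 19 paired bases, not the 21-nt strand:
  the overhangs are partly synthetic (`UU`) and do not pair with the target.
* **Flank GC** is pooled over the concatenated 24 nt rather than averaged
  per side, matching how a single flank-GC value per site is reported in
  practice.
* **Sense overhang patterns** `U·`/`·U` are read as "U then any base" and
  "any base then U". The sense overhang is always the verbatim next two
  mRNA bases — an unfavorable pattern demotes rank but is never silently
  substituted, so every reported strand can be checked against the target.
* **The antisense overhang** is always synthesized as `UU`; it counts as
  ideal only when the mRNA bases upstream of the core are `AA`, so that the
  overhang still base-pairs with the target. It is rank-only: there is no
  evidence it was ever used to reject a site.
* The initiation-codon position is user input (`cds_map`), defaulting to
  the first AUG; the package does no ORF prediction.
* IUPAC ambiguity codes are rejected rather than skipped: a masked window
  cannot be scored, and fully sequenced cDNAs are the intended input.

## Off-target screening

The historical specificity check was a BLASTN search of an EST database
that is no longer reachable. `scan_offtargets()` replaces it with an
offline, exhaustive ungapped scan: every placement of the core on either
strand of any subject within a Hamming distance of `max_mismatches`
(default 2, the conventional 17/19-identity band). Matching is seeded from
a k-mer index and verified window by window; the pigeonhole principle
(cutting the core into `max_mismatches + 1` disjoint words, one of which
must be exact) guarantees completeness, and the index is rebuilt at word
size `floor(19 / (max_mismatches + 1))` whenever the configured word is too
long to guarantee that. This is stricter than BLAST's heuristic — it cannot
miss a qualifying hit — but it is ungapped only, and it does not model
seed-region-only (miRNA-like) off-targeting.

## Dose-response model

Relative expression from qPCR uses the standard difference of differences
of cycle thresholds, target normalized to a reference gene in both treated
and control samples, with amplification efficiency fixed at 2 (no
standard-curve correction):

\[ \mathrm{rel} = 2^{-\Delta\Delta C_t}. \]

Knockdown versus injected dose \(x\) (µM) is modelled as exponential decay

\[ y(x) = a\,e^{-bx}, \]

with \(a\) the relative mRNA level at dose 0 (unitless, ideally 1) and
\(b\) the decay rate per µM. `fit_decay()` fits it by ordinary least
squares of \(\log y\) on \(x\) — exact, closed-form and deterministic —
rather than by iterative nonlinear least squares. The reported correlation
`R` is the magnitude of the Pearson correlation on the log scale; on the
reference knockdown series this choice reproduces the reported correlation
of 0.9133 to four decimals, which is why `R` is defined on that scale.
Points with \(y \le 0\) cannot enter a log-linear fit and are rejected with
the offending dose named; at least three points at two distinct doses are
required.

The *median effective concentration* is the dose at which the model
predicts half the control-level mRNA:

\[ EC_{50} = \ln(a / 0.5) / b, \]

an absolute 0.5 level rather than \(a/2\). On the reference parameter pair
\((a, b) = (0.9, 0.028)\) this gives 20.99 µM, matching the printed 21 µM
(the \(a/2\) reading would give 24.8 and is therefore not adopted).

```{r ec50}
effective_concentration(decay_fit(a = 0.9, b = 0.028), level = 0.5)
```

## What the synthetic generators emulate

`simulate_transcript()` draws i.i.d. background bases at a chosen GC
fraction, forces an AUG at the coding start, and can overwrite a
guideline-perfect 43-nt block (12-nt flanks pooling to exactly 50% GC, a
core passing every hard filter, `AA`/`UU` overhang context) at a known
offset. By construction the planted site attains the best possible rank
key, so planted-site recall is a sharp end-to-end test of the staged
pipeline. `simulate_dose_data()` draws
\(y = a e^{-bx} e^{\varepsilon}\), \(\varepsilon \sim N(0, \sigma^2)\):
multiplicative lognormal noise keeps ratios positive and matches the
log-linear estimator, so with \(\sigma = 0\) the fit must recover \((a,b)\)
to numerical precision.

What the generators do **not** emulate: codon structure, UTR composition,
secondary structure and accessibility of the target site, transcriptome-
scale sequence correlations, or qPCR efficiency drift and replicate
pipetting structure. Passing the simulation-based tests therefore shows
the algorithms implement the stated rules exactly; it does not certify
silencing efficacy on real transcripts beyond what the underlying
guideline itself was validated on.

## Numerical and testing choices

* Coordinates are 0-based half-open internally; every report is 1-based
  inclusive. Percentages are exact internally and rounded only at report
  time (1 decimal in the TSV).
* All generators take a mandatory seed; identical inputs give
  byte-identical outputs everywhere (report rows are sorted on a total
  key; timestamps never enter the data stream).
* The test suite checks the staged design against an independently written
  brute-force enumerate-filter-sort oracle on 50 seeded transcripts of
  300–2000 nt at 30–70% background GC, and the seeded off-target scan
  against a brute-force Hamming scan on 20 decoy transcriptomes of
  10 × 1 kb with planted 0/1/2-mismatch copies — sizes chosen so the whole
  suite runs in under a minute on one core while covering the composition
  range of real insect transcripts. Stochastic recovery of the decay rate
  uses 200 simulations of the reference design (4 doses × 4 replicates,
  \(\sigma = 0.1\)): the median fitted \(b\) must sit within 5% of truth
  and at least 90% of fits within 25% — a band appropriate to n = 16
  log-linear fits.
* Criterion boundaries are asserted exactly where the guideline states
  them: GC 35%/55% pass and 30%/60% fail (checked with 20-nt cores, where
  these percentages are exact base counts); 4 A/U in the seed passes and 3
  fails; offset 75 passes and 74 fails.

## Known limitations

* No thermodynamic asymmetry or free-energy model, and no composite
  scoring of the Reynolds/Ui-Tei kind beyond the criteria above; the
  ranking is lexicographic, not weighted.
* The off-target scan is ungapped and transcript-level only.
* The dose-response model is a single-gene exponential decay; it has no
  plateau term, so it extrapolates to complete silencing at high dose.
  Four-parameter logistic fits are out of scope.
* One pair of siRNAs per gene is the designed-for use case; pooled-dose
  arithmetic beyond reporting is not implemented.
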