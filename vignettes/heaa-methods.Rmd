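---
title: "Methods: bisulfite amplicon processing and the HEAA age clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bisulfite amplicon processing and the HEAA age clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heaa)
```

## The problem

Ageing baleen whales without killing them is hard: the classical method
counts growth layer groups in the earplug, which requires a dead animal. DNA
methylation offers a non-lethal alternative. In humpback whales
(*Megaptera novaeangliae*), methylation at three promoter CpG sites —
*GRIA2*+202, *CDKN2A*+297 and *TET2*+31 — changes with age in a way that
supports a simple linear clock, the Humpback Epigenetic Age Assay (HEAA):

$$\widehat{\mathrm{age}} = 5.4717\,x + 3.9705\,y - 0.6793\,z + 1.4695$$

where $x$, $y$, $z$ are the DNA methylation frequencies, in percent, at the
three sites. This package implements the full measurement chain that feeds
that clock from targeted bisulfite amplicon sequencing — read simulation,
read processing, methylation calling, age estimation and cohort
age-structure analysis — and ships the published Hachijojima cohort table
(25 skin biopsies, 21 whales) as a worked dataset.

The clock coefficients are treated as given constants: the calibration
against known-age whales (and its leave-one-out cross-validation) predates
this package and is out of its scope. No refitting is done anywhere.

## The measurement model

A biopsy yields genomic DNA; three promoter fragments are amplified by a
two-step bisulfite PCR. Bisulfite converts unmethylated cytosine to uracil
(read as T after PCR) while 5-methylcytosine stays C, so at a CpG site the
fraction of sequenced molecules carrying C estimates the methylation
fraction. Coverage depth — the number of molecules read at the site — is
the precision index: the binomial standard error of a frequency $p$ at
coverage $n$ is $\sqrt{p(1-p)/n}$.

Each first-PCR primer carries a universal tail on which the sequencing
primers sit. Consequently a 250 bp read starts at the amplicon's
primer-defined end, and when the amplicon is shorter than 250 bp the read
runs through into the reverse complement of the *opposite* tail. That
read-through sequence is exactly what the adapter-trimming stage removes.

Only the bisulfite-converted top strand is simulated and aligned: the
first-PCR primers define the amplified strand, so a directional library is
the faithful model and halves alignment ambiguity.

## Synthetic data: what it emulates and what it does not

The amplicon interiors are synthetic. The published assay gives the primers
but neither the amplicon sequences nor genomic coordinates, so
`build_reference()` generates primer-anchored sequences with a known,
exhaustive CpG inventory (the interior is drawn from a C-free alphabet and
cytosines are planted deliberately), and the site labels "+202", "+297",
"+31" are display names bound to a reference offset. Default amplicon
lengths (240 / 234 / 228 bp) keep the pair overlap long and the
read-through short.

`generate_cohort()` works backwards from the clock so that every simulated
sample has an exactly clock-consistent truth: the true age is drawn from a
normal(12, 6.5) truncated to the requested range (the observed cohort's age
structure is roughly normal with mean 12.02), $y$ and $z$ are drawn
uniformly within the empirically observed per-gene ranges
(1.34–4.64% for *CDKN2A*, 5.59–19.19% for *TET2*), and $x$ is solved from
the clock (redrawing $y$, $z$ when the solution leaves [0, 100]%). Defaults
mirror the study: 21 individuals, 4 replicate pairs, 15:6 male:female,
ages in [2, 31].

`simulate_reads()` converts each molecule in silico — the target CpG stays
C with probability `meth_fraction`, other CpGs with probability
`background_meth` (default 0.02, a largely unmethylated promoter), and
every unmethylated C converts with probability `conversion_efficiency` —
then applies uniform substitution errors and a configurable quality
profile (flat Q35 by default, with an optional 3′ decay ramp used to
exercise the Q20 trimmer). The exact number of molecules drawn methylated
at each target CpG is recorded per gene, so the whole downstream chain has
an exact oracle: with no sequencing error and complete conversion, the
called frequency must equal `methylated molecules / reads` to the last bit.

What the simulator does **not** model — and therefore what passing tests do
not demonstrate about real data: indels and homopolymer artefacts,
position- or context-dependent error, index hopping, chimeric PCR products,
PCR duplication bias, strand asymmetries, and incomplete-conversion
heterogeneity between molecules. The conversion-failure knob exists
(`conversion_efficiency < 1` inflates apparent methylation by
$(1-m)(1-\mathrm{ce})$, which a unit test demonstrates) but the default is
complete conversion, matching the idealised end-to-end oracle conditions.

## Read processing: deliberate simplicity

The three read-level stages are native, deterministic analogues of the
usual tools, chosen because amplicon pairs span the whole fragment:

* **Adapter trimming** — exact-match only: a full internal occurrence of the
  read-through adapter truncates the read at its start; otherwise the
  longest read suffix equal to an adapter prefix (at least `min_match = 3`
  bases) is removed. No error-tolerant matching: a sequencing error inside
  a short read-through stub leaves it untrimmed, and such pairs later fail
  to merge and are dropped *with accounting* rather than risk a
  mis-registered overlap. At a 0.5% error rate this costs roughly 10–15% of
  pairs — visible in `stage_counts.tsv` — and removes molecules at random
  with respect to methylation state.
* **Quality filtering** — end trimming, not a sliding window: bases are
  trimmed from the 3′ then the 5′ end while the terminal quality is ≤ Q20;
  survivors of length ≤ 40 are discarded (40 is discarded, 41 kept). A pair
  is dropped when either mate fails.
* **Merging** — read 2 is reverse-complemented and all overlap lengths are
  scanned from the maximum down to `min_overlap = 10`; the longest overlap
  with mismatch fraction ≤ 0.25 is accepted. At disagreements the
  higher-quality base wins, ties going to read 1 so the output is a pure
  function of input order; consensus quality is the maximum of the two at
  agreements and the winner's elsewhere.

## Methylation calling

Alignment is ungapped (the simulator is substitution-only and amplicons are
primer-defined), with the asymmetric bisulfite rule: read T over reference
C is a conversion-consistent match; everything else that differs is a hard
mismatch. Every reference and every offset at which the read fits is
scored; fewest hard mismatches wins, ties resolved by panel order then
smallest offset, and the read is rejected if the best mismatch fraction
exceeds 0.1.

At the assay CpG, C counts as methylated, T as unmethylated, and any other
base (a sequencing error) is excluded from coverage — counting it either
way would bias the frequency. Zero coverage raises an explicit no-call
error, which is deliberately distinct from a frequency of 0. Calls below
the coverage floor (default 1,000× for simulated data; the published assay
operated above 10,000×) are flagged, never silently dropped.

## Age estimation and reporting conventions

The clock runs at full precision; rounding happens once, at the reporting
boundary, half away from zero to 2 decimals. A numerical guard of 1e-9 on
the scaled value protects exact halves that binary floating point places
infinitesimally low (the mean of 15.53 and 14.02 must report 14.78).

The 95% interval is attached with a fixed half-width of 4.47 years. The
assay's stated CI of 8.95 would suggest ±4.475, but every published
interval is exactly the point age ±4.47, so the table's arithmetic is
taken as authoritative; the half-width is a configurable constant. Only
the lower bound is clamped at zero. Point estimates can be negative for
high *TET2* frequencies; they are reported as computed and flagged,
because clamping the estimate would silently bias cohort means.

Cohort statistics are computed from the 2-decimal *reported* ages, not
full-precision clock output: an individual's consensus age is the re-rounded
mean of its reported sample ages, and cohort and per-sex means are means of
those values. This is the convention that reproduces the published
per-individual (8.38 / 10.82 / 14.78 / 11.76) and per-sex (12.23 / 11.48)
figures. The age structure uses half-open 5-year bins labelled in the
"a.00–b.99" display convention, with modal ties resolved to the youngest
bin; 5 years is the conventional age at sexual maturity for this
population, so the first bin separates immature animals.

## Numerical and design choices

* Seeds: every stochastic operation takes one explicit integer seed;
  the pipeline derives per-sample seeds as `seed + sample index`, and
  outputs are byte-identical across reruns with the same configuration.
* Tie-breaks are all deterministic and documented: read 1 at equal merge
  quality, panel order then leftmost offset at equal alignment score,
  youngest bin at modal ties.
* Mismatch-fraction thresholds are compared with a 1e-12 slack so that
  fractions exactly at the limit are accepted regardless of floating-point
  representation.
* Degenerate inputs: empty reads are discarded by the length floor; an
  unalignable read is flagged, not an error; an empty cohort is an error
  for binning but an empty *replicate* set is a legitimate empty result.
* Problem sizes: the simulated study runs 25 samples × 3 genes × 2,000
  molecules (coverage ≈ 1,600–2,000 after merging losses), which makes the
  binomial noise of a frequency about 0.3–0.7 percentage points — small
  enough that the clock's behaviour is visible, large enough to run
  comfortably on a laptop. The published data's 10,000–66,000× coverages
  shrink that noise by a further factor of 3–6.

## Known limitations

* The amplicon interiors being synthetic, nothing here validates primer
  specificity, off-target amplification or the true CpG density of the real
  loci.
* Exact-match adapter trimming discards error-bearing read-through pairs
  instead of rescuing them; with long amplicons (short read-through) the
  loss is small, but it grows as the amplicon shortens.
* The clock's calibration error (the dominant uncertainty in real use) is
  represented only through the fixed CI half-width; the pipeline measures
  and propagates counting noise, not calibration bias, and the assay is
  known to compress estimates for old animals.
* Cohort statistics on reported ages inherit double-rounding: a consensus
  age can differ by 0.01 from the full-precision mean. This is intentional
  (it is the published convention) but worth remembering when comparing
  against full-precision reanalyses.
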