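---
title: "Models and methods behind m5cmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind m5cmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`m5cmap` implements the two computational arms by which an RNA
m^5^C methyltransferase is localized to its substrate cytosines: miCLIP
crosslink-site mapping with size-matched-input normalization, and targeted
RNA bisulfite quantification with replicate-level statistics. This
vignette describes the underlying models, the parameters that matter, the
numerical choices, and what the synthetic study fixture does and does not
emulate.

## The measurement models

**miCLIP.** A catalytic-cysteine mutant of the enzyme (C459A in
NOP2/NSUN1) stalls as a covalent adduct on the substrate cytosine.
Reverse transcription of the immunoprecipitated RNA terminates at the
adduct, so after adapter trimming the first base of a read (the "+1"
site) is the crosslinked cytosine. The analysis therefore reduces reads
to two per-position counts per reference: `stops[i]`, deduplicated reads
whose 5′ end is `i`, and `coverage[i]`, deduplicated reads overlapping
`i`. Wild-type IP libraries share the binding footprint (for NOP2/NSUN1,
the 5′ETS of the pre-rRNA) but lack the truncation spike; SMInput
libraries, taken before immunoprecipitation, provide the abundance
background for region-level enrichment.

**Bisulfite.** Bisulfite deaminates unmethylated cytosine to uracil (read
T); m^5^C resists. On a targeted amplicon every reference C yields a
binomial readout: the converted fraction estimates the unmethylated
proportion of molecules at that site. Conditions (control and two
knockdowns) are compared per site across biological replicates.

## Crosslink-site calling

Per position of the mutant profile a call requires, at the defaults:
coverage ≥ 20; stop fraction `stops/coverage` ≥ 0.1; stop support ≥ 10
reads; and a depth-scaled ratio over the WT background ≥ 4, computed as

    ratio = ((stops_mut + eps) / S_mut) / ((bg_wt + eps) / S_wt),  eps = 0.5

with `S` the deduplicated library sizes. Two choices here deserve
explanation, because the naive rule — point WT counts, no support
minimum — fails at desk-scale depth:

* **Local WT background.** `bg_wt` is the mean WT stop count over a
  centred 21-nt window. A single-position background estimate is a
  Poisson draw with mean ~1 at these depths; conditioning a 4-fold ratio
  on it makes every zero-WT fluctuation a candidate call. A truncation
  spike is single-nucleotide sharp while the WT background varies slowly,
  so smoothing the background (and only the background) is the
  local-lambda idea familiar from peak callers. When the WT neighbourhood
  is empty the rule reduces to the plain pseudocount arithmetic (50 stops
  against nothing: `50.5 / 0.5 = 101`).
* **Minimum stop support (10 reads).** A purely fractional threshold
  admits calls supported by 2–3 reads wherever coverage sits near the
  minimum, and near reference 5′ ends the expected stop fraction is
  `1/position` regardless of depth. Planted sites at the shipped
  conditions carry 40–65 supporting stops; requiring 10 removes the
  low-support tail without touching any plausible true call.

With both in place, across 20 independent simulated contrasts at the
default conditions (20,000 reads/library) the caller returns exactly the
two planted sites — 28S:4447 and vtRNA1.2:27 — with no false positives,
and the top-ranked call is always a planted site.

The `site_offset` switch (default 0) selects the convention that the
read's first base *is* the crosslinked cytosine; `-1` reports the base
before the stop instead, for chemistries where termination occurs one
nucleotide short.

## Windowed enrichment

Read-start counts in 50-nt windows (step 25) are tested IP vs SMInput
with a two-sided Fisher exact test on the in/out 2×2 table,
BH-adjusted across all windows, with fold change
`((in_IP + 1)/S_IP) / ((in_SMI + 1)/S_SMI)`. A window is significant at
adjusted *p* < 0.05 and fold change ≥ 2 — the study's stated decision
rule, kept exactly. Under a null with identical generative laws for IP
and SMInput, the mean fraction of significant windows across repeated
simulations stays below 0.05 (it is near zero, as BH controls FDR against
a global null).

## Alignment

The aligner is a seed-and-extend local Smith–Waterman: exact 12-mer seeds
against an index of the (few, small) references propose diagonals, which
are extended with a banded affine-gap DP (band `8 + ceil(0.1 |read|)`).
Scoring defaults are match +2, mismatch −3, gap open −5, gap extend −2; a
gap of length L costs `open + (L−1)·extend`. Records are emitted when the
score reaches 0.66 of the read's maximum; ties break by reference name,
then earliest target end with a diagonal-preferring traceback — fully
deterministic, and for exact substring queries equivalent to leftmost
placement. Search is sense-only: CLIP reads and amplicon reads are sense
to the RNA.

In bisulfite mode both reads and references are collapsed C→T for seeding
and scoring ("three-letter" alignment against the converted reference),
which makes the score invariant to a read's conversion pattern; the
original read sequence is preserved and conversion is tallied afterwards
from aligned match columns through the CIGAR (deletion columns are
skipped; non-C/T bases count as errors and are excluded from the
converted-fraction denominator, reported separately).

Single-best-hit reporting replaces repeat-family-aware multi-mapping: the
synthetic reference set contains no repeat families, so the ambiguity the
original genome-wide pipelines resolve does not arise here.

## Bisulfite quantification

Converted fractions are reported per replicate where the informative
depth `n_C + n_T` reaches 10. The headline per-condition statistic is the
mean of per-replicate fractions (matching a replicate-dots-with-SD
display); the read-pooled fraction across replicates is reported
alongside, and the two agree to within binomial error at these depths.
Conditions are compared with a two-tailed pooled-variance Student's
*t*-test on the replicate fractions (`df = n1 + n2 − 2`); Welch's
correction is available behind a flag but off by default, following the
study's stated test. The overall conversion rate pools
`Σ n_T / Σ (n_T + n_C)` over all cytosines except the excluded target
sites, so it measures chemistry efficiency on unprotected positions.

## The synthetic study fixture

`build_reference()` generates a seeded random reference set whose
*coordinates* mimic the 47S pre-rRNA precursor (5′ETS 3655, 18S 1869,
ITS1 1077, 5.8S 157, ITS2 1167, 28S 5070, 3′ETS 361 nt; total 13,356),
plus an 88-nt vault RNA, box C/D and H/ACA snoRNA mimics, and decoys.
Sequence content is uniform random DNA — only the coordinate frame
carries meaning, so region-local labels such as `28S:4447` are directly
comparable — and cytosines are forced at 28S-local 4447 and vtRNA-local
27 so the canonical sites exist in every realization.

Key generator parameters, all configurable, defaults chosen once:

* **Truncation probability 0.6** at both crosslink sites in the mutant
  IP: strong but not complete RT arrest.
* **Binding windows** at fixed fractions of the 5′ETS (around the early
  and late processing-site regions), five-fold start-density enrichment,
  applied to both WT and mutant IP.
* **Class weights** (read mixture over rRNA / snoRNA / vtRNA / decoy)
  calibrated to the observed library compositions: mutant IP 97.8% rRNA,
  WT IP 98.5%, vtRNA present only at background in WT; SMInput flatter.
* **Insert length uniform 50–110 nt**, drawn from the per-reference
  feasible range (a short RNA yields fragments up to its own length, not
  a pile of full-length molecules). The length default is tied to the
  calling regime: background stops are Poisson with mean ~1.3 per
  position here, so the 0.1 stop-fraction threshold separates signal
  from noise only once per-position coverage reaches ~100, which at
  20,000 reads per library requires a mean insert near 80 nt. Shorter
  defaults put the caller in a regime where its stated thresholds cannot
  be false-positive-free at desk scale.
* **UMI length 10**, placed 5′ of the insert; 3′ adapter
  `AGATCGGAAGAGCACACGTC` (the eCLIP-style RNA adapter in DNA space);
  constant base quality `I`.
* **PCR duplication rate 0.1** for CLIP-style libraries (exact duplicate
  injection, for deduplication testing).
* **Bisulfite**: conversion efficiency 0.97 for unprotected cytosines;
  converted fraction at 28S:4447 of 0.16 / 0.28 / 0.34 for control and
  the two knockdowns; sequencing error 0.001/base; single-end reads
  spanning the full amplicon (28S-local 4178–4534). Single-end
  full-amplicon reads carry the same counting statistics as
  overlap-merged 2×250 paired reads while keeping the contract simple.
* **Design**: two miCLIP replicates of each of IP-WT, IP-mutant and
  their paired SMInputs; three bisulfite conditions × three replicates;
  bisulfite depth 50,000 reads/library, scaled down from the ~130,000
  aligned reads per sample of the original amplicon runs.

What the generator does **not** emulate: position-dependent quality,
indel errors, RNase cut-site sequence preferences, RNA secondary
structure effects on RT or on bisulfite accessibility, PCR bias beyond
exact duplicates, and biological replicate-to-replicate variation in
methylation stoichiometry (replicates differ only by sampling noise).
Passing tests therefore demonstrate the correctness of the computational
contracts under the stated statistical structure, not robustness to every
artifact of real libraries.

## Read preparation conventions

The preparation order is trim → UMI-extract → length-filter. The 18-nt
minimum applies to the insert after UMI removal (the UMI is not
biological sequence); adapter matching uses minimum overlap 3 at maximum
error rate 0.1 — conventional trimming values. Trimming removes the
longest qualifying suffix; note that after a correct trim, ~2% of inserts
end in a chance 3–4-mer adapter prefix, so trimming is idempotent only up
to such chance matches. UMI extraction and length filtering are exactly
idempotent. Deduplication keys on (reference, start, strand, UMI,
aligned length) — read-length-aware UMI collapsing — keeping the
highest-scoring record, ties resolved by read id, so the result is
independent of input order.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout the tibbles (SAM
  convention); BED/bedGraph outputs are 0-based half-open.
* RPM tracks error on empty libraries rather than emitting NaN; ratio
  tracks use +1 pseudocounts on coverage.
* `conversion_table` requires informative depth ≥ 10 to report a
  fraction (NA below); an amplicon without cytosines is an error.
* Profile construction rejects records extending past reference bounds
  as corrupt input.
* All simulators are deterministic given their integer seed, to the byte
  in FASTQ output.

## Problem sizes in the shipped tests

The unit suites run on a compact reference set (full-length 28S so the
4447 coordinate exists; other regions scaled down) with libraries of
300–8,000 reads. The recovery suite runs the shipped conditions at full
desk scale: 9 bisulfite libraries of 50,000 reads and 20,000-read miCLIP
contrasts over 20 seeds. The aligner is cross-checked against a plain-R
full dynamic-programming Smith–Waterman oracle on 200 random instances;
Fisher p-values against direct hypergeometric enumeration; the *t*-test
against the closed-form pooled-variance formula at 1e-10; deduplication
against a distinct-key set construction.

## Known limitations

Single-reference best-hit alignment is inappropriate for repeat families;
the windowed Fisher test assumes independent read starts (UMI
deduplication makes this reasonable); the local-lambda WT background
assumes the WT stop landscape varies slowly on the 21-nt scale, which a
WT enzyme with its own strong single-nucleotide stop would violate; and
the bisulfite arm models complete chemistry on accessible cytosines — it
cannot detect conversion resistance caused by structure rather than
methylation, which is a known caveat of the assay itself.
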