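---
title: "Mapping and quantifying tRNA modifications by mass spectrometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and quantifying tRNA modifications by mass spectrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modomap)
```

## The problem

Blood-feeding mosquitoes such as *Aedes aegypti* remodel their tRNA pool
after a blood meal: yolk-protein (vitellogenin) synthesis in the fat body
creates a codon demand — notably for tyrosine codons — that is met by
changes in tRNA transcription and in anticodon modification levels.
Establishing which hypermodified nucleoside sits at the wobble position
(position 34) of tyrosine tRNA, and how modification levels move across
the blood-feeding time course, rests on a chain of computations around
liquid-chromatography tandem mass spectrometry: predicting ribonuclease
digestion products of modified tRNA, computing their masses and fragment
ions, matching observed spectra, normalizing nucleoside peak areas, and
relating the results to tRNA gene references and codon usage. `modomap`
implements that chain as a tested, reusable package with seeded
synthetic-data generators, so every stage can be validated by parameter
recovery without any external download.

## The modification registry and sequence model

Residues are registered by code with a parent canonical base and either
an elemental formula or a monoisotopic mass increment relative to the
parent nucleoside. Residue mass is the nucleoside-5′-monophosphate mass
minus water; the canonical residue masses are A 329.05252, C 305.04129,
G 345.04744 and U 306.02530 Da. The inventory covers the modifications
detected in mosquito tRNA hydrolysates, including the queuosine family
(Q, manQ, galQ, oQ), methylations, pseudouridines, dihydrouridine, the
position-37 hypermodifications (i⁶A, t⁶A and their 2-methylthio forms)
and wobble uridine derivatives; mcm⁵s²U is registered even though it is
frequently below reliable detection, since carrying it costs nothing.
Isomers — pseudouridine versus uridine, mannosyl- versus
galactosyl-queuosine — are deliberately mass-equal under distinct codes:
mass spectrometry alone cannot separate them, and keeping separate codes
makes that explicit.

Sequences use bracket notation (`ACU[manQ]UAGp`): single characters for
canonical residues, bracketed codes for modifications, a leading `p` for
a 5′ monophosphate, and a trailing `p` or `>p` for a 3′ linear or
2′,3′-cyclic phosphate. Positions are 1-based to match tRNA position
nomenclature (position 34 is the wobble base, 37 the residue 3′ of the
anticodon). Formatting brackets every non-canonical code, including
single-character ones, so that formatted strings re-parse losslessly.

## In-silico digestion

RNase T1 cleaves 3′ of guanosine and leaves linear 3′-phosphates;
cusativin cleaves 3′ of cytidine, leaves 2′,3′-cyclic phosphates, and
does not cleave between consecutive cytidines. Both enzymes are blocked
by modification of the cleavage-site residue. Two reading choices were
genuinely open and are resolved as follows:

* "does not cleave at modifications" is implemented as: *any*
  modification of the cleavage-site residue blocks cleavage, while
  modification of the downstream residue never does. This is the
  simplest rule consistent with the observed retained manQ-containing
  products.
* the cusativin CpC rule is applied on parent bases regardless of the
  modification status of either cytidine, since the rule is stated
  without qualification. Whether cusativin cleaves after a modified C
  followed by a non-C is not documented; the chosen rule blocks it.

Cleavage after the final residue is vacuous, so the 3′-terminal product
always inherits the parent's 3′ chemistry (a mature tRNA ends in
CCA-3′-OH); the 5′-most product inherits the parent's 5′ chemistry, and
all internal boundaries follow the enzyme (downstream fragments get
5′-OH). Missed cleavages are enumerated combinatorially up to a cap. A
brute-force per-bond oracle — an independent re-implementation that
tests every inter-residue bond against the rules — backs the engine in
the test suite on seeded random modified sequences.

## Mass and fragment-ion arithmetic

The neutral mass of an oligonucleotide is the residue-mass sum plus a
terminal adjustment: +water for one phosphate per residue (5′-OH/3′-p or
5′-p/3′-OH), zero for a 2′,3′-cyclic phosphate (a linear phosphate minus
water), −HPO₃ per missing and +HPO₃ per extra phosphate. Negative-mode
m/z is (M − |z|·1.007276)/|z|. Collision-induced dissociation of the
phosphodiester backbone is interpreted through the c/y ion series:
cᵢ is the sum of the first *i* residue masses (plus HPO₃ for a
phosphorylated 5′ end) and yⱼ = M + water − c₍ₙ₋ⱼ₎, so the
complementarity cᵢ + y₍ₙ₋ᵢ₎ = M + water holds exactly and is asserted to
1 µDa in the tests. Only c/y are implemented — the series used to read
anticodon oligonucleotides — with a/w left as an extension point.

Two conventions deserve note. First, the charge states behind printed
integer m/z values of digestion products are not stated anywhere;
`match_charge_state()` therefore searches charges 1–5 instead of
assuming, and confirms 3− as the unique state reproducing all four
anticodon-product integers (856, 1054, 1000, 958) within the m/z
600–2000 oligonucleotide scan window. Second, positive-mode
protonated-nucleoside values for modified nucleosides are reproduced by
adding the hydrogen-atom mass (1.007825) rather than the proton mass
(1.007276): the reference value for mannosyl-queuosine, 572.2204,
corresponds to that convention, which is common in nucleoside LC–MS
tables. Negative mode always uses true proton arithmetic, and both
conventions are exposed as a switch. The 2-bromo-deoxycytidine internal
standard's monitored m/z (306.0078) is carried as acquisition metadata
only, not derived from composition.

## Spectrum matching and localization

Candidates are filtered on precursor m/z at charges 1–5 (10 ppm default,
Orbitrap-class) and scored against fragment peaks at charges 1–2 with a
0.5 Da tolerance (ion-trap-class). Scoring is presence/absence — the
matched fraction of theoretical c/y ions under greedy nearest-peak
assignment with each observed peak consumed once — mirroring the
qualitative manual interpretation the workflow formalizes; intensity
weighting is an extension point. Localization generates one candidate
per legal placement of the modification plus the unmodified candidate
and ranks by score, breaking ties by smaller mean absolute fragment
error. On noiseless synthetic spectra the true placement is recovered
for 100/100 random 8–12-mers, and with uniform decoy peaks added at a
10:1 decoy:true ratio the true placement still ranks first in at least
95/100 seeded cases; both are acceptance-tested. Duplicate instrument
runs are reported per run; no merging rule is imposed.

## Relative quantification

Nucleoside XIC peak areas are normalized per sample by the summed areas
of the four canonical nucleosides, which cancels per-sample scaling
(tRNA input, matrix effects) exactly; the four canonical normalized
abundances sum to 1 by construction (to floating-point precision).
Fold change is the per-time mean normalized abundance divided by the
non-blood-fed mean, so the reference time point is 1 identically.
Modifications not detected in a sample are treated as censored (missing)
rather than zero — "not consistently detected" describes a detection
limit, not absence — and are excluded from fits.

The "general linear model" for per-nucleoside time effects is ordinary
least squares on the time-point factor with the overall F-test; no
random effects are used since none are specified, and with a constant
response the F statistic is defined as 0 (p = 1). The
modification-by-enzyme "multivariate multiple regression" is realized
as per-(modification, enzyme) univariate fits, because the published
layout reports per-pair, per-term F values and modifications with
several candidate enzymes are evaluated one enzyme at a time. Treatment
(non-blood-fed versus blood-fed) is a function of the time factor, so
the two strata cannot be estimated in one model; the package fits
`level ~ expression × treatment` and `level ~ expression × time`
separately and reports sequential-ANOVA rows per term. Significance is
called at raw p < 0.05 to match the published convention; a
Benjamini–Hochberg adjustment can be applied by the user via
`p.adjust()` on the returned p-value columns. Microarray probe pairs are
averaged per gene per sample before fold-change computation.

## Reference construction and expression calls

tRNAscan-SE 2.0 tabular output is parsed with 1-based inclusive
coordinates; minus-strand genes (begin > end) are reverse-complemented
so the stored precursor is the transcribed strand, and genomic intron
bounds are converted to sequence-local coordinates at the parse
boundary. The note column consumes the high-confidence filter (pseudo /
truncated flags). Precursor deduplication collapses byte-identical
sequences only — isodecoders differing by a single nucleotide are kept —
and records which id each duplicate collapsed into. Mature sequences
are the precursor minus the intron plus a 3′ CCA; no other maturation
step (e.g. histidine's extra 5′ G) is applied, matching the reference
construction being reproduced. Expression is mean TPM > 1 per
condition; the boundary TPM = 1 is called not expressed, since
"expressed" is defined strictly above 1 and "not expressed" strictly
below, leaving the boundary to a documented choice. Exclusivity
("expressed only post blood-feeding") is evaluated on per-condition
means because replicate handling is not otherwise specified.

## Codon usage

Codons are counted in frame from position 1 (T and U interchangeable;
trailing partial codons dropped with a warning; ambiguous codons skipped
and tallied). RSCU is count over synonymous-family mean, with stop
codons excluded and RSCU > 1.5 / < 0.5 marking preferred / unpreferred
codons (strict inequalities). The tyrosine-enrichment test is Fisher's
exact test on raw tyrosine versus alanine codon counts between two
transcript sets; raw counts are the only valid input for an exact test,
so percentage rescaling is not applied. The implementation delegates to
`stats::fisher.test` and is verified in the tests against an independent
hypergeometric-enumeration oracle over all small 2×2 tables.

## What the generators emulate — and what they do not

* `sim_trna_genes()`: isodecoder families with exact duplicate gene
  copies (default 200 genes, 42 duplicates, collapsing to 158 unique
  precursors — the scale of the high-confidence mosquito gene set) and
  introns confined to Tyr-GTA, Ile-TAT and Leu-CAA, inserted after
  position 37 at 10–20 nt. Gene bodies are random sequences: cloverleaf
  structure, promoter elements and real isodecoder similarity are not
  modelled.
* `sim_spectrum()`: complete c/y ladders at 1–2⁻, optional Gaussian m/z
  jitter, and uniform decoys over the m/z 600–2000 acquisition window.
  Real spectra have intensity structure, neutral losses and incomplete
  ladders; passing the decoy test shows robustness to chemical noise,
  not to systematic co-elution.
* `sim_peak_areas()`: three replicates per time point (NBF, 6H–72H),
  canonical areas lognormal around fixed means, modification areas as
  truth abundance × canonical sum × mean-preserving lognormal noise
  (CV 10% by default). The default truths encode a
  queuosine-family-like trajectory: flat through 24H, halved at 48–72H.
  Lognormal noise was chosen because peak areas are positive with
  multiplicative matrix effects; correlated noise between nucleosides of
  one run is not modelled.
* `sim_cds_set()`: i.i.d. codon draws with a mild TAC bias and the
  tyrosine codon probability multiplied by a configurable factor
  (default 2 — the vitellogenin-versus-ribosomal-protein contrast) in
  the target set. Real CDS have positional and amino-acid composition
  structure beyond codon frequencies.

Passing the parameter-recovery tests therefore demonstrates correctness
of the computations under the stated noise models, not performance on
real chromatograms or genomes.

## Problem sizes and numerical choices

The test suite runs the digestion oracle on 200 random modified
30-mers, fragment complementarity on 1,000 random products,
localization on 100 clean and 100 decoy-laden spectra, fold-change
recovery on 500 seeded simulations at n = 3 and CV 10% (0.5× and 2×
truths recovered within ±20% in ≥95% of runs), the Fisher oracle on all
2×2 tables with grand total ≤ 30 plus 2,000 random tables with margins
up to 50, and exact truth recovery for reference building on a
200-gene set. These sizes keep the full suite under a minute while
exercising every guarantee; all randomness is seeded. Floating-point
equalities are asserted at 1e-6 Da for fragment complementarity, 1e-4
Da for registry masses against formulas, and machine precision (a few
ulp) for the normalization sum.

## Known limitations

* Average (non-monoisotopic) masses, isotope envelopes and retention
  time prediction are out of scope.
* a/w fragment series, intensity-weighted scoring and mzML ingestion
  are extension points, not implemented.
* Kinetic/partial digestion is not modelled; missed cleavages are
  combinatorial.
* Ordination statistics (NMDS/anosim/PERMANOVA) and differential
  expression are deliberately left to the established packages that
  already provide them (`vegan`, `DESeq2`); this package consumes their
  inputs/outputs where needed.
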