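# modomap

Mapping and relative quantification of transfer-RNA modifications by
mass spectrometry, built around the tRNA biology of blood-feeding
mosquitoes (*Aedes aegypti*). After a blood meal, vitellogenin synthesis
in the fat body creates a tyrosine codon demand; establishing that
mannosyl-queuosine (manQ) — not queuosine or galactosyl-queuosine — sits
at the wobble position (34) of tyrosine tRNA, and following modification
levels across the blood-feeding time course, requires a chain of
computations that this package implements as tested, reusable functions:

* **Modification-aware sequence model** — a registry of canonical and
  modified nucleosides (monoisotopic residue masses from formulas or
  increments; isomers mass-equal but distinct) and bracket-notation
  parsing (`ACU[manQ]UAGp`, trailing `p`/`>p` for linear/cyclic 3′
  phosphates).
* **In-silico ribonuclease digestion** — RNase T1 (cleaves 3′ of
  unmodified G, linear phosphate products) and cusativin (cleaves 3′ of
  unmodified C, skips CpC, cyclic phosphate products), with missed
  cleavages and product-uniqueness counting.
* **Mass and fragment arithmetic** — neutral masses with full terminus
  chemistry, negative-mode m/z at any charge, c/y fragment series with
  the exact complementarity cᵢ + yₙ₋ᵢ = M + H₂O, and protonated
  nucleoside m/z.
* **Spectrum matching** — precursor filtering (ppm), presence/absence
  fragment scoring, and modification localization with ranked
  placements; MGF and TSV peak lists.
* **Relative quantification** — canonical-sum normalization of XIC peak
  areas, fold changes versus the non-blood-fed (NBF) reference,
  per-nucleoside time-course models and modification-by-enzyme
  interaction regressions; microarray probe averaging.
* **tRNA references** — tRNAscan-SE 2.0 parsing (strand, introns,
  high-confidence filter), exact-duplicate removal, mature sequences
  (intron out, CCA on), TPM > 1 expression calls with
  condition-exclusive sets.
* **Codon usage** — in-frame codon counts, RSCU, and Fisher's exact
  tyrosine-versus-alanine codon enrichment between transcript sets.
* **Seeded generators** — synthetic tRNA gene sets, fragment spectra,
  peak-area tables and codon-biased CDS sets, each with a truth table,
  so the whole workflow is testable by parameter recovery.

The numbered scripts under `analysis/` run the stages end to end
(simulate → mapping → quantification → reference → codon usage) and
write their tables under `results/`.

## Worked example

Digest the tyrosine anticodon arm carrying manQ at the wobble position,
and confirm the diagnostic products and their m/z:

```r
library(modomap)

digest("GGACU[manQ]UAGAUCCUUG", RNASE_T1)$product
#> [1] "Gp"            "Gp"            "ACU[manQ]UAGp" "AUCCUUG"

neutral_mass("ACU[manQ]UAGp")
#> [1] 2571.423
round(mz(neutral_mass("ACU[manQ]UAGp"), charge = 3))   # negative mode
#> [1] 856
round(mz(neutral_mass("U[manQ]UAGAUCC>p"), charge = 3))
#> [1] 1054

nucleoside_mz("manQ")   # protonated nucleoside, positive mode
#> [1] 572.2204
```

No cleavage occurs at the modified guanosine (manQ), so the T1 digest
leaves the anticodon-spanning product `ACU[manQ]UAGp` intact; its
triply deprotonated ion is the m/z 856 species, and the cusativin
counterpart `U[manQ]UAGAUCC>p` gives m/z 1054. Localizing the
modification from a fragment spectrum:

```r
pl <- sim_spectrum("U[manQ]UAGAUCC>p", decoy_ratio = 10, seed = 15)
localize(pl, "UGUAGAUCC>p", "manQ")[1, c("position", "product", "score")]
#>   position          product score
#> 1        2 U[manQ]UAGAUCC>p     1
```

The top-ranked placement puts manQ at position 2 of the product — tRNA
position 34, the wobble base. See `analysis/` for the quantification,
reference-building and codon-enrichment stages, and
`vignettes/trna-modification-mapping.Rmd` for the methods.

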