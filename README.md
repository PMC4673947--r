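# cytoIR

Dose prediction from FTIR spectra of drug-exposed cells.

## The problem

Conventional cytotoxicity bioassays (clonogenic survival, viability stains)
report *whether* cells die, not *which* molecular sites a chemical hits or
what exposure a given biochemical state implies. Fourier-transform infrared
(FTIR) spectroscopy reads the whole biochemical state of a cell film at once:
DNA base vibrations (guanine ~1725 cm⁻¹, thymine ~1665 cm⁻¹, adenine
1613 cm⁻¹, cytosine 1499 cm⁻¹), the protein amide I region, and phosphate
stretches at 1228/1087 cm⁻¹. A DNA-binding drug such as cisplatin shifts the
guanine band to ~1713 cm⁻¹ and the thymine band to ~1657 cm⁻¹ once exposure
passes ~1.5 µg/mL, and moves the amide β-sheet band from 1639 to 1624 cm⁻¹
above ~2 µg/mL.

`cytoIR` turns that readout into a quantitative dose bioassay:

1. **Biochemical Index Spectra (BIS)** — each exposed spectrum minus the mean
   control spectrum, isolating the drug-induced changes (a positive marker
   near 1648 cm⁻¹ and a negative one near 1490 cm⁻¹ whose magnitudes fade
   with dose).
2. **PLS regression** — a from-scratch univariate NIPALS partial least
   squares model. With centered predictors X (BIS intensities) and response
   y (dose), each component extracts a weight `w ∝ Xᵀy`, score `t = Xw`,
   loadings `p = Xᵀt/tᵀt`, `q = yᵀt/tᵀt`, then deflates `X ← X − t pᵀ`,
   `y ← y − q t`; predictions are `ŷ = (X − x̄) W(PᵀW)⁻¹q + ȳ`. The number
   of latent variables is chosen per training set by k-fold cross-validation.
3. **Evaluation protocol** — repeated stratified 40/16 train/test splits
   (20 by default) over spectral windows (1000–3000 cm⁻¹ and its four
   500 cm⁻¹ segments), scoring RMSE and `R² = 1 − SSres/SStot`.
4. **Dose–response** — a two-parameter Hill model
   `mortality% = 100·cʰ/(EC50ʰ + cʰ)` fitted to clonogenic mortality tables
   to estimate the LC50.

Because no raw spectra are publicly deposited for this assay, the package
ships a first-class synthetic-data generator that emulates the designed
experiment — 9 cisplatin concentrations (0–4 µg/mL) × 7 replicates, Gaussian
vibrational bands with logistic dose-dependent shifts, replicate noise,
baseline drift and scale jitter — so the entire pipeline is testable end to
end.

## Worked example

```r
library(cytoIR)

# simulate the designed experiment and preprocess it
x <- preprocessSpectra(generateDesign(generatorConfig(seed = 1)))
x
#> SpectrumCollection: 63 spectra on 2001-point grid 1000-3000 cm^-1 (spacing 1)
#> doses (ug/mL): 0 (n=7), 0.125 (n=7), 0.25 (n=7), 0.5 (n=7), 1 (n=7),
#>   1.5 (n=7), 2 (n=7), 3 (n=7), 4 (n=7)

# where is the guanine band at high dose?
s3 <- generateSpectrum(3, noiseFreeConfig())
detectPeaks(absorbance(s3)[, 1], wavenumbers(s3), 1690, 1740, "positive")
#>      center centerExact height prominence     sign
#> 1713   1713        1713    0.3        0.3 positive

# 20 stratified 40/16 splits on the full window
rec <- evaluateWindows(x, windows = list(c(1000, 3000)), nModels = 20, seed = 1)
summarizeEvaluation(rec)[, c("window", "meanR2Test", "sdR2Test", "meanRmseTest")]
#>      window meanR2Test sdR2Test meanRmseTest
#> 1 1000-3000      0.994  0.00153          0.1

# LC50 from the published clonogenic mortality table
fitHill(cisplatinMortality())
#> HillFit: EC50 = 0.3036 ug/mL, slope = 1.522, residual SS = 28.95
```

The detected apex at 1713 cm⁻¹ is the platinum-bound guanine band; the mean
held-out R² of 0.994 (RMSE 0.1 µg/mL) says the BIS carries enough dose
information for PLS to predict the applied cisplatin concentration to about
a tenth of a microgram per millilitre under the generator's noise model; and
the Hill fit's EC50 of 0.30 µg/mL is the 24-hour LC50 of cisplatin in this
assay.

`runPipeline("out", seed = 1)` chains every stage (simulate → preprocess →
BIS → windowed evaluation → dose-response) and writes six CSV products plus
a JSON manifest; `inst/scripts/cytoir.R` wraps it for the shell.

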