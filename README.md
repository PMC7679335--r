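# gslms

Negative-mode MS/MS annotation of glycosphingolipids and quantification of
sphingolipid experiments, in R.

## What problem this solves

Human podocytes (and other specialised cells) express glycosphingolipids
whose identity hinges on *sialylation-site isomerism*: GM1b versus GM1a,
GD1alpha versus GD1a/GD1b, and the sialylated globopentaosylceramides. The
isomers have identical mass, so MS1 cannot separate them; the call rests on
which glycosidic fragment ions an MS2 spectrum does and does not contain,
and on how the species behave under *Vibrio cholerae* sialidase (which
spares inner sialic acids). `gslms` implements that annotation engine and
the quantification stages around a typical sphingolipid study:

* **Mass engine** — monoisotopic `[M − zH]^z−` precursors (z = 1, 2) and
  Domon–Costello B/C/Y/Z glycosidic fragments with up to two cleavages,
  over glycan trees from a plain-text, user-extensible structure registry.
  Negative mode: B = Σresidues − 1.007276; C = B + 18.010565; Y = ceramide
  + Σresidues − 1.007276; Z = Y − 18.010565.
* **Isomer assignment** — diagnostic ions derived automatically per
  candidate set; exclusion by presence of foreign diagnostics, by
  collective absence of a candidate's own specific ions, or by sialidase
  contradiction; verdicts are *assigned / excluded / ambiguous*, and errors
  degrade to ambiguity rather than to wrong calls.
* **In-silico sialidase** — a Neu5Ac is resistant iff it sits on a
  chain-internal backbone hexose; exhaustive and single-step digestion with
  registry-based product renaming.
* **Quantification** — HPTLC lane tables to percent-of-total composition
  profiles; fold changes versus Mock (`100 (x − mock)/mock`); 11-fraction
  sucrose-gradient analysis with DRM (fractions 5–6) / HD (fractions
  10–11) pooling; Welch t / one-way ANOVA plumbing.
* **Enzyme kinetics** — 4-methylumbelliferone calibration, activities in
  pmol/h per mg protein or per 10^6 cells, and CBE / AMP-DNM inhibitor
  arithmetic separating lysosomal (GCase) from non-lysosomal (NLGase)
  glucosylceramidase.
* **Synthetic data** — seeded generators for every input format (spectra,
  lanes, gradients, time courses), so the whole pipeline is testable
  without instrument data.

## Worked example

The published GM1-class MS2 series (precursor 1626.90 with the Y-ladder
1335.79 … 646.56 and *no* ion at 1261.78) plus the sialidase result
(conversion to gangliotetraosylceramide):

```r
library(gslms)

gm1 <- spectrum(c(1626.90, 1335.79, 1173.75, 970.67, 808.62, 646.56),
                precursor_mz = 1626.90, precursor_charge = 1)
assign_structure(gm1, c("GM1a", "GM1b"), ceramide = "d18:1/24:1",
                 digestion = digestion_observation("GM1", "GA1", "exhaustive"))
#> Structure assignment
#>   GM1a       excluded   Y-series   60%  coverage  100%  all 4 candidate-specific diagnostic ion(s) absent + digestion contradiction
#>   GM1b       assigned   Y-series  100%  coverage  100%
#>   verdict: GM1b
```

GM1a is excluded because the ions only it can produce — above all the
Y-type fragment at m/z 1261.8 retaining the inner sialic acid — are all
missing while its shared backbone ions are present, and because an
exhaustive sialidase digest of GM1a would leave GM1a (inner Neu5Ac is
resistant), not GA1. GM1b survives with its complete Y-ladder matched and
is assigned.

The pieces are available individually:

```r
precursor_mz(build_structure("GM1b", "d18:1/24:1"), charge = 1)
#> [1] 1626.948

vapply(sialidase_digest(build_structure("GD1alpha"), "single_step"), `[[`, "", "name")
#> [1] "GM1b"                          "[Hex3 HexNAc1 Neu5Ac1 isomer]"
```

(the second single-step intermediate, GM1b's GalNAc-sialylated companion,
has no conventional name and is reported by composition).

A simulated genotype experiment, quantified:

```r
lanes <- simulate_profile_experiment(synthetic_config(seed = 1))
head(percent_change(rowMeans(lanes$G1), rowMeans(lanes$Mock)), 4)
#>   species percent_change sd
#> 1      SM       53.81855  0
#> 2  Gb3Cer       -2.87139  0
#> 3  LacCer      -41.71780  0
#> 4  GlcCer      -27.77997  0
```

The recovered changes sit near the configured effect table (SM +52%,
Gb3Cer 0%, LacCer −42%, GlcCer −29% for the G1 condition) within the 5%
lane noise.

A command-line surface covers the same ground
(`mass`, `fragments`, `digest`, `assign`, `quantify`, `drm`, `enzyme`,
`simulate`):

```sh
Rscript inst/cli/gsltools.R digest GM1b
# GA1
```

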