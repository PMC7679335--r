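---
title: "Annotating glycosphingolipid MS/MS spectra and quantifying sphingolipid experiments with gslms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating glycosphingolipid MS/MS spectra and quantifying sphingolipid experiments with gslms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gslms)
```

## The problem

Cultured human podocytes express an unusual panel of glycosphingolipids
(GSLs): alongside the ubiquitous sphingomyelin and GM3, they carry
0-series and alpha-series gangliosides (GM1b, GD1alpha) and globo-series
species up to mono- and disialylated globopentaosylceramide. Distinguishing
these from their far more common isomers (GM1a; GD1a/GD1b) matters because
the isomers differ only in *where* the sialic acids sit, not in mass: an
MS1 measurement cannot separate them, and even MS2 requires reasoning about
which fragments each candidate can and cannot produce. `gslms` packages
that reasoning — plus the quantitative stages of a typical sphingolipid
study (thin-layer chromatography densitometry, sucrose-gradient raft
analysis, fluorogenic enzyme assays) — into testable, scriptable functions.

## The structural model

A GSL is modelled as a rooted tree of monosaccharide residues attached to a
ceramide (`glycan_topology()`, `build_structure()`). Two deliberate
simplifications:

* **Mass-level residue symbols.** Glc and Gal are both `Hex`; GalNAc and
  GlcNAc are both `HexNAc`. They are isobaric, and low-energy CID cannot
  tell them apart. Named structures keep conventional sugar labels purely
  as documentation.
* **No linkage positions.** Alpha-2,3 versus alpha-2,6 and so on are not
  represented. The discrimination logic only ever uses *which residue is
  attached to which* — the resolution that glycosidic fragmentation and
  exoglycosidase treatment can actually test. Encoding linkage would claim
  chemistry the data cannot verify.

The registry (`default_registry()`) ships 18 named topologies (ganglio-
and globo-series plus ceramide and sphingomyelin) in a fixed insertion
order, so candidate enumeration (`isomer_set()`) is reproducible. It
serializes to a plain-text edge-list table (`write_registry()`), so users
can add structures without touching code. Sphingomyelin carries its
phosphocholine headgroup as a fixed mass and is excluded from glycosidic
fragmentation.

## Mass conventions

All chemistry is negative-mode, deprotonated (`[M - zH]^z-`, z = 1 or 2),
monoisotopic. Fragment types follow the Domon–Costello glycosidic
nomenclature: B/C ions retain the non-reducing terminus, Y/Z the ceramide;
C = B + water, Y = Z + water. Internal fragments from two nested cleavages
carry either cap (`CY`, `BY`). Up to two cleavages are enumerated
(`enumerate_fragments()`): two is exactly what the observed internal ions
require (for example the sialylated-arm ion at m/z 835.3 of GD1alpha), and
it keeps enumeration quadratic in the glycan size.

Numerical choices worth stating:

* The proton mass is 1.007276 Da; water is carried at the conventional
  18.010565 Da (within 1e-6 of 2H + O), so the C−B and Y−Z spacings equal
  that constant exactly.
* The default match tolerance is **0.10 Da**. Unit-resolution ion-trap
  spectra of these lipids sit within about 0.06 Da of monoisotopic theory
  across the published series; 0.10 Da absorbs that with margin and is
  configurable everywhere.
* One known exception: the published singly charged Gb5Cer (d18:1/16:0)
  Y-series (1387.92 down to 536.63) sits ~0.12 Da *above* monoisotopic
  theory, unlike every other series — a local calibration offset in the
  source data. The engine does not special-case it; that series is simply
  excluded from tight-tolerance regression tests.

## Isomer discrimination

Given a spectrum and a set of isobaric candidates, `derive_diagnostics()`
enumerates all theoretical ions of every candidate (two cleavages, singly
charged), merges the pooled m/z list at the tolerance, and keeps the
clusters produced by a *proper subset* of candidates. These are derived
automatically rather than hard-coded, so new isomer families work; the
published diagnostics (1261.78 for GM1a, 1235.81 for GD1a, 581.22 for
GD1b) fall out as regression tests.

`assign_structure()` then excludes a candidate when:

1. **Foreign ions are present.** At least two distinct diagnostic ions the
   candidate cannot produce are observed. Two are required so that a single
   stray noise peak can never flip a verdict.
2. **Its own specific ions are collectively missing.** Every
   single-cleavage diagnostic ion owned solely by the candidate is absent
   while at least one of its shared sequence ions is matched. Only
   single-cleavage diagnostics count here: internal (double-cleavage)
   fragments are low-abundance, and their absence from a curated peak list
   is not evidence. This asymmetry matters in practice — the GM1 spectrum
   that identifies GM1b prints a complete Y-ladder but no minor internal
   ions, and treating those as mandatory would exclude everything.
3. **Digestion contradicts it.** If a sialidase observation is supplied,
   candidates whose predicted products cannot account for the observed
   comigration bands are excluded. Observed names may be migration classes
   ("GM1") that cannot resolve isomers; matching is by glycan composition.

The sole survivor is *assigned* only with positive evidence: at least half
of its single-cleavage Y-series matched, **or** at least 80% of the
assignable peaks (those explained by some candidate — contaminants foreign
to the whole family are ignored) explained by it, with at least three such
peaks. The two routes reflect the two kinds of published evidence: the GM1b
call rests on a complete Y-ladder, while the GD1alpha call rests entirely
on non-reducing-end sialyl-arm ions (a Y-series-only rule could never
assign it). Everything else is *ambiguous* — errors are required to
degrade to ambiguity, never to a wrong assignment.

## In-silico sialidase

*Vibrio cholerae* sialidase does not act on inner sialic acids. The rule
implemented in `sialidase_digest()` generalizes this: a Neu5Ac is
**resistant** if and only if it is attached to a backbone hexose that is
extended toward the non-reducing end (a chain-internal Hex, as in GM1a);
every other Neu5Ac — on a terminal residue, on a HexNAc, or the outer unit
of a disialyl element — is labile. This single rule reproduces the three
observed outcomes (GM1b to GA1; GD1alpha to GM1-class intermediates and
then GA1; GM1a untouched) and makes the GalNAc-linked sialic acid of
GD1alpha labile, as observed. For the sialylated globopentaosylceramides
the engine predicts the asialo product on the *same* backbone (Gb5Cer);
reports that call this band "GA1" reflect comigration shorthand, and the
package deliberately does not reproduce that naming.

## Quantification stages

* `composition_from_lanes()` turns lane tables (species by replicate) into
  percent-of-total profiles; an optional background row is subtracted
  first, with negatives clipped at zero and a warning (the convention when
  densitometry baselines overshoot).
* `percent_change()` implements the Mock-reference semantics,
  `100 (x - mock)/mock`, on absolute per-species signal by default.
  Percent-composition inputs are also accepted, but closure effects make
  absolute signal the better default. SDs propagate to first order when
  both inputs carry them; replicate-level computation is preferred when
  raw replicates exist.
* `gradient_analysis()` summarizes 11-fraction sucrose gradients. DRM =
  fractions 5–6 and HD = fractions 10–11 by default — the
  caveolin-1-positive / calnexin-positive pools — and both sets are
  overridable because other gradient recipes pool differently.
* `fit_calibration()` / `compute_activity()` convert fluorogenic
  4-methylumbelliferone time courses into pmol/h per mg protein (or per
  10^6 cells). Activities come from the least-squares slope over all time
  points (with two points this degenerates to the difference quotient);
  the calibration R-squared gate (0.98) and the saturation warning (final
  product below half of maximum) are configurable.
  `resolve_glucosidases()` separates the two beta-glucosidases acting on
  the same substrate via their inhibitors: CBE silences the lysosomal
  enzyme, AMP-DNM the non-lysosomal one, so GCase is the activity under
  AMP-DNM and NLGase the activity under CBE; the inhibitor-resolved sum is
  checked against the uninhibited total (warning above 20% discrepancy).
  Each assay file requires its own calibration — lysate and live-cell
  assays are never assumed to share one.
* `group_compare()` is deliberately thin plumbing: Welch's t for two
  groups, one-way ANOVA beyond, both straight from `stats`.

## What the synthetic generators emulate — and what they do not

The generators (`simulate_ms2()`, `simulate_profile_experiment()`,
`simulate_gradient()`, `simulate_kinetics()`) produce every input the
pipeline consumes, with one root seed fanning out to per-stage substreams
so identical configurations are byte-identical.

Defaults are the study conditions: the shipped base composition is the
podocyte profile (SM 26.3%, Gb3Cer 18%, LacCer 15.6%, GlcCer 12.5%, Cer
5.7%, GM3 5.2%, Gb5Cer 4.9%, MSGb5Cer 4.5%, GM1b 3.4%, GA1 2.4%, GD1alpha
1.0%, DSGb5Cer 0.4% — the published values sum to 99.9 and are renormalized
to 100); the genotype effect table encodes the reported changes (WT: LacCer
−42%, Gb3Cer +30%; G1/G2: MSGb5Cer +50%, DSGb5Cer +53%, GD1alpha +58%, SM
+52%, Gb5Cer −34%, GA1 −36%, Cer −86%, GlcCer −29%, LacCer −42%); lanes use
CV 5% with n = 3; spectra use a 0.03 Da calibration offset, detection
probability 1 and 10 uniform noise peaks; gradients load 225 nCi. Values
the source never states were fixed once at realistic levels and not
revisited: the DRM/(DRM+HD) share is 0.5 for Mock/WT and 0.35 for the risk
variants (a visible but not extreme raft depletion), 80% of the load sits
in the DRM+HD pools, and per-fraction noise is 2% CV — scintillation
counting of a single gradient is precise; biological variation lives
between experiments, not within a profile.

What passing tests on these simulations do **not** show: real ion-trap
spectra have structure the simulator omits (isotope envelopes, variable
fragment intensities, co-isolated precursors, cross-ring cleavages), real
lane quantification has spatial artifacts, and the lognormal noise models
are conveniences. The simulations validate the *logic* — that the
assignment engine inverts its own forward model at realistic noise, and
that the quantification stages recover configured parameters — not
instrument performance.

Problem sizes used by the shipped tests were chosen to characterize the
statistics adequately at desk scale: 200 simulated spectra per isomer
family for assignment accuracy, 100 seeded runs for effect-recovery, 20
for the null-effect calibration check.

## Design choices on open points

* Globopentaosylceramide entries are encoded with globo topology
  (Gal-GalNAc-Gal-Gal-Glc backbone); the transcript evidence motivating
  that series assignment is outside this package's scope.
* Where reported descriptions of the DSGb5Cer sialylation sites differ,
  the registry follows the explicit site statement: one Neu5Ac on the
  terminal Gal and one on the adjacent GalNAc.
* Fold changes for raft (DRM) species default to absolute pooled nCi per
  species rather than percent composition, matching how matched-loading
  comparisons are read.
* The command-line surface is an in-package function (`gsl_cli()`) plus a
  two-line Rscript wrapper, so every CLI path is unit-testable in-process.

## Known limitations

No isotope envelopes, no cross-ring (A/X) fragments, no positive-mode
chemistry, no adducts, no retention-time modelling, no peak picking from
profile data, and no Michaelis–Menten treatment of the enzyme assays
(substrate concentrations are metadata only). O-acetylated sialic acids
and fucosylated structures are absent from the default registry, though
`dHex` is a supported residue and such structures can be added through the
registry table.
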