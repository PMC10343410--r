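---
title: "Suspect and target screening of LC-HRMS beverage data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suspect and target screening of LC-HRMS beverage data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmscreen)
```

# Overview

`hrmscreen` turns a set of centroided LC-qTOF runs, a handful of suspect
lists and an MSP spectral database into a table of identified compounds with
explicit confidence levels, and — where reference standards exist — into
concentrations. This vignette explains the underlying models, the tunable
parameters, and the design decisions taken where the methodology is
genuinely open.

# Mass arithmetic

All screening decisions rest on exact monoisotopic masses computed from an
embedded most-abundant-isotope table (C 12 exactly, H 1.0078250,
N 14.0030740, O 15.9949146, plus S, P, Na, K, Cl, F, Br, I, Si). Ion m/z
values follow the proton charge-carrier convention: (de)protonation shifts
the neutral mass by ±1.007276 Da — the proton mass, i.e. the hydrogen atom
minus the electron that travels with the charge — and the ammonium adduct
adds the NH₄⁺ cation mass (18.033825 Da). Four adducts are built in
(`[M-H]-`, `[M+H]+`, `[M-H2O+H]+`, `[M+NH4]+`); others can be declared with
an explicit mass delta. Only singly charged ions are modelled; isotope
patterns and radical ions are out of scope.

Formula strings are accepted in three dialects (plain Hill notation,
Unicode subscripts, underscore-delimited counts) because real suspect lists
mix them; all are canonicalized at parse time, and formula arithmetic
refuses to produce negative element counts.

# Virtual-metabolite enumeration

The enumeration models two phase-II-style transformations: glucosylation and
methylation. The mass bookkeeping is condensation chemistry — each glucose
adds C₆H₁₀O₅ (162.052824 Da, glucose minus water) and each methyl adds CH₂
(14.015650 Da) — which is the standard convention for conjugate formation
and reproduces, for example, C₂₀H₁₆O₁₃ for a glucosylated ellagic acid.
Default limits are two glucose units and one methyl group, with a hydrogen
"building block" retaining the parent, so each scaffold yields
(2+1) × (1+1) = 6 products. SMILES strings are carried through untouched:
masses and diagnostic ions, not structures, drive every downstream decision,
so no attachment-site chemistry is attempted. Other conjugations (sulfation,
glucuronidation) are deliberately not default building blocks.

Because library spectra rarely exist for enumerated metabolites, their
fragmentation is predicted from diagnostic ions only: the ionized aglycone
(the scaffold retaining any methyls) and the glucose neutral-loss series
(precursor − k × 162.0528, k = 1..n). The deprotonated/protonated sugar
moiety is reported as an optional, non-required ion since it is often below
the acquisition range.

# The synthetic-run generator

`generateRun()` produces centroided runs from a recipe:

- **Chromatography.** Each compound is a Gaussian elution profile with apex
  RT, width σ (default 0.05 min — a typical UPLC peak base width of ~15 s)
  and a prescribed integrated area. Intensities below 10⁻⁴ of the apex are
  truncated.
- **Survey scans** every `scanInterval` minutes (default 0.02 min, ~25
  points across a peak) carry each compound's precursor plus uniform random
  noise centroids (3 per scan, intensities uniform on [0, `noiseLevel`]).
- **DDA** triggers one MS2 scan at each compound's apex for the `ddaTopN`
  largest compounds; fragment intensities are the compound's relative
  pattern scaled to the precursor apex.
- **DIA** alternates low-energy survey scans with high-energy scans that
  superpose the fragments of *all* co-eluting compounds, each fragment trace
  proportional to its precursor's profile — the property the pseudo-spectrum
  stage exploits.

Everything is reproducible under the recipe seed. The generator emulates
what the screening logic needs — peak areas, accurate masses, co-elution,
acquisition modes, blank-to-sample ratios — and deliberately omits
chromatographic tailing, ion suppression, matrix effects, isotope peaks and
detector saturation. Green tests therefore validate the *decision logic*,
not instrument physics: real data will stress peak detection and
deconvolution harder than these fixtures do.

The bundled juice study (`juiceFixture()`) encodes 29 compounds of a
pomegranate-based drink series (organic acids, fatty acids, amino acids,
flavonoids and their metabolites, sugars) across three samples (80/90/100%
pomegranate) and a procedure blank, with three abundance patterns
(increasing with the secondary-juice share, e.g. quercetin; decreasing,
e.g. ethyl gallate; flat, e.g. fructose). Fragment *intensities* are not
part of the catalogue — only fragment m/z values are — so the fixture uses a
rank-decreasing profile (100, 80, 60, 40, 20) for both sample and library
spectra. Cosine scores on the fixture are therefore near 1 and are not
meaningful reproduction targets; the reproduced contracts are the gate
outcomes (which side of 0.7/0.6 a match falls) and the final level
assignments. Two procedural contaminants (dodecyl sulfate, azelaic acid)
are planted at a sample/blank area ratio of 3 to exercise the blank rule in
both directions; genuine compounds sit at ratio 10. The fixture VMSL
enumerates seven scaffolds — the six compounds shared with the
literature-based list (quercetin, kaempferol, apigenin, gentisic, gallic and
chlorogenic acid) plus ellagic acid, whose glucoside is the diagnostic-ion
identification — and the literature list deliberately omits ellagic acid so
the cross-list intersection stays exactly those six.

Within the catalogue, two embedded ions retain small internal
inconsistencies of their sources (oleic and pyroglutamic acid reference m/z
~1.8 and ~0.8 mDa from the computed values); they are kept as data, flagged
in tests with a wider 2 mDa comparison, and never silently "corrected". One
amino acid whose recorded experimental m/z is ~22 mDa from its formula
(norvaline) is planted at the theoretical value instead, since the recorded
value would contradict the ±5 mDa accurate-mass gate it passed.

# MS1 screening

EICs are extracted per suspect in an absolute ±0.005 Da window (accurate
mass tolerance of a calibrated qTOF; absolute rather than ppm, and
configurable). Peak detection reports local maxima at least `minHeightSnr`
(default 3) times the baseline noise, estimated as the median of the trace —
robust because a targeted trace is mostly baseline. Two numerical guards
matter in the targeted setting:

- an apex must be flanked by non-zero scans; a single-scan spike is not a
  chromatographic peak (this suppresses false features on the EICs of
  suspects that are simply absent);
- peak bounds extend from the apex to 5% of the apex height or to a local
  minimum, whichever comes first, and the area is the trapezoid integral
  over the bounds. A Gaussian truncated at 5% of its apex retains 98.6% of
  its area, so areas are accurate to well under 2% at the default scan
  spacing.

Feature prioritization ("most abundant antioxidants") is top-k by area with
deterministic tie-breaks (earlier apex, then name). The procedure-blank rule
keeps a feature iff no blank feature matches it (same suspect, apex within
0.2 min) or its area is at least five-fold the blank's; both the ratio and
the matching window are configurable, and the kept set shrinks monotonically
in the ratio.

# Fragmentation matching

Fragment spectra come from two routes. The `maaK` (default 15) most abundant
compounds per sample and polarity take the **DDA** route: the MS2 scan whose
precursor lies within the mass window and whose RT is nearest the feature
apex. All other compounds — and DDA-routed compounds for which no MS2 scan
qualifies — take the **DIA** route.

Full DIA spectral deconvolution is out of scope; in its place stands a
documented, testable correlation gate: every fragment m/z bin observed in
the high-energy scans inside the feature's RT bounds is kept iff its trace
correlates with the precursor EIC at Pearson r ≥ 0.8 *and* its trace apex
lies within 0.1 min of the feature apex. On the generator's data this is
exact (fragment traces are proportional to their precursor's profile); on
real data it is a simplification that shares fragments between perfectly
co-eluting isomers.

Spectra are compared by plain intensity cosine over greedily paired peaks
(nearest |Δm/z| first, one-to-one, 0.01 Da tolerance; equal to the optimal
assignment whenever peaks are well separated). Unmatched peaks contribute to
the norms only, so spurious extra peaks dilute the score rather than
inflating it. No m/z weighting is applied — scores must be comparable with
mainstream library-search defaults.

# Confidence levels

`assignLevel()` is an ordered rule cascade; the first rule that fires
decides, the rationale records the evaluated values, and adding evidence can
only improve the level:

| level | rule | default gate |
|-------|------|--------------|
| 1 | reference standard: RT agreement and match to the standard's spectrum | ≤ 0.5 min, score ≥ 0.6 |
| 2a | experimental library spectrum match | score > 0.7 (strict) |
| 2b | all required diagnostic ions present | 0.01 Da |
| 3 | in-silico fragment support | ≥ 1 fragment matched |
| 4 | molecular formula confirmed | mass fit |
| 5 | exact mass only | ±0.005 Da |

Two gates deserve comment. The strict 0.7 threshold applies only to the
library (2a) rule; level 1 instead requires ≥ 0.6 against the *standard's*
spectrum plus RT agreement, because a standard measured on the same system
carries the burden of proof on retention time, and genuine standard matches
with modest scores (0.6–0.7) are common for small, fragment-poor molecules.
The 0.5 min RT tolerance covers the largest standard-vs-sample drift in the
bundled catalogue (0.4 min) with margin. Formula confirmation (level 4)
rests on mass fit alone — a documented divergence from practice, since the
fixtures carry no isotope patterns to score. Predicted retention times are
carried as metadata for prioritization but are never a hard gate.

One chromatographic peak identifies one compound: when isobaric suspects
(e.g. an enumerated kaempferol diglucoside sharing C₂₇H₃₀O₁₆ with rutin)
claim the same feature (m/z within twice the mass window, apex within
0.1 min), the best-evidenced candidate stays primary and the others are
flagged co-candidates, visible in the annotation table but excluded from
compound-level counts.

# Quantification

External calibration uses unweighted ordinary least squares on the five
working levels (0.5, 1, 2.5, 5, 10 mg/L), reporting slope/intercept with
classical standard errors and R². Concentration is the algebraic inverse
(response − b)/a, averaged over replicates with an SD, and the
limit-of-quantification flag (default 0.5 mg/kg) applies to the final mean
concentration, not to the raw response. The mg/L → mg/kg conversion is an
explicit factor with default 1: the bundled fixtures are self-consistent
under that convention, and an extraction that weighs 200 mg of drink into
200 µL of solvent can be accommodated by setting the factor accordingly —
the package takes no position on recovery correction or matrix-matched
calibration.

The quantification fixture generates replicate responses at concentrations
(c − SD, c, c + SD), so a zero-noise run reproduces its reference means and
SDs exactly — a round-trip identity, not a statistical claim. With 2%
proportional response noise the refitted calibrations stay above R² = 0.97.

# Problem sizes and determinism

The shipped study uses a 0.02 min scan interval over 15 min (negative mode)
or 8 min (positive mode) gradients: ~750 survey scans per run, 14 runs
(3 samples × 2 polarities × 2 acquisition modes, plus a blank per polarity),
about 65 merged suspects, and a 28-record MSP library. The full pipeline
runs in a few seconds on one core. Every stochastic element (noise
positions, intensities) derives from the recipe seed; reruns are
byte-identical, and the acceptance script threads one user-supplied seed
through all of it.

# Known limitations

- No isotope-pattern or adduct-network evidence: level 4 is weaker than the
  same label in standard practice.
- The DIA stand-in cannot separate perfectly co-eluting precursors that
  share fragments.
- Suspect lists are consumed as CSV; compiling them (text mining, retention
  time prediction) is upstream of this package, as is vendor raw-file
  conversion and mass calibration.
- The cosine is unweighted; electrospray intensity variability between
  instruments is absorbed only by the score gates.
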