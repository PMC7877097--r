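---
title: "Methods: decoding, analyzing and composing 1D analytical spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding, analyzing and composing 1D analytical spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

speckit is a headless toolkit for the server-side half of a web-based
spectra editor: it decodes and composes JCAMP-DX and mzML files, detects
the spectrum type, picks and edits peaks, performs the NMR-specific
analyses (referencing, integration, multiplicity and coupling-constant
inference), processes raw FIDs, classifies IR band intensities, and
assembles the edited-file-plus-images bundle that an electronic lab
notebook stores next to an upload. This vignette documents the models,
the numerical choices and the limits of what the tests demonstrate.

## The data model

Everything flows through one container, the `spectrum`: a strictly
monotonic abscissa (ppm, wavenumber, or m/z), an ordinate, a kind tag
(`NMR_1H`, `NMR_13C`, `IR`, `MS`) and a metadata map (observe frequency,
solvent, units, title). NMR and IR data are line plots; MS data are stick
(bar) plots. Peak logic operates on an *effective* intensity in which
peaks are always maxima: IR transmittance traces (recognised from the
y-units label, or from a high baseline with `max(y) > 5`) are inverted as
`max(y) - y`; everything else is used as-is.

Type detection reads the JCAMP data-type record first (substring match on
MASS / INFRARED / NMR, case-insensitive), splits NMR on the observe-
nucleus record, and falls back to the x-units record (`1/CM`, `M/Z`,
`PPM`/`HZ`) for sloppy files. When no rule fires the reader raises an
explicit unrecognised-type error instead of guessing. The standard
itself does not fix default picking thresholds, so the package documents
its own: 1% of the maximum effective intensity for ¹H, 5% for ¹³C, 20%
of the deepest band for IR, 5% of the base peak for MS, all overridable
through `threshold.*` configuration keys.

## JCAMP-DX codec

The parser accepts single-block, compound and NTUPLES documents with LF
or CRLF line endings; labels are matched after dropping case, spaces,
dashes, slashes and underscores, so `##.OBSERVE FREQUENCY` and vendor
variants match, while private `##$...` records round-trip verbatim. The
ordinate forms AFFN/PAC, SQZ, DIF, DUP and mixed DIFDUP are decoded per
the standard's pseudo-digit tables; in DIF mode the first ordinate of
each continuation line is treated as a check value (verified, consumed,
never emitted) and the trailing check line is recognised the same way.
By default the parser is lenient - real instrument exports frequently
fail the x-sequence and DIF checks - and reports failures as classed
warnings with line numbers; `strict = TRUE` promotes them to errors.

The writer emits records in canonical order, regenerates the grid
records, and stores ordinates as `round(y / YFACTOR)`, so a re-parse
agrees within `YFACTOR/2` and exactly for integer ordinates. `YFACTOR`
is 1 for integral tables and `max(|y|)/2^23` otherwise, which keeps the
quantization error below about 6·10⁻⁸ relative. Tables of at most 64
points are written human-readable (AFFN); longer tables use DIFDUP.
Lines are capped at 78 characters. Peak tables (`(XY..XY)`) print m/z
with 17 significant digits, which round-trips IEEE doubles bit-exactly.

## mzML reading

Binary data arrays are base64 text, optionally zlib-compressed, holding
little-endian 32- or 64-bit floats; arrays are identified by PSI-MS
accession (with a name fallback). R's `memCompress(type = "gzip")`
produces and consumes exactly the RFC 1950 zlib stream the mzML standard
means, which the tests cross-check against the independent mzR reader.
32-bit arrays are widened on read, with the original precision recorded
per scan. Scans are listed in file order, never reordered by id, and
the first scan is the default selection; profile scans pass through
unchanged because peak selection happens downstream by threshold, not by
centroiding. Unsupported encodings (numpress) and formats (mzXML, CDF)
raise named errors rather than being skipped.

## Peak picking and edits

Picking returns strict local maxima of the effective intensity at or
above the threshold. A plateau (a run of exactly equal ordinates above
both neighbouring runs) reports its central grid point, left-of-center
for even runs - a deterministic, symmetric tie-break. On continuous
synthetic data ties have probability zero, so picking coincides with the
elementary scan `y[i-1] < y[i] >= y[i+1]`, which the test suite uses as
an independent oracle. No smoothing is applied before picking: the
editor's noise control is the threshold, and adding a filter would make
the picked set depend on a second hidden parameter.

This choice has a consequence worth stating: with a threshold far below
the noise level, any noisy trace produces spurious local maxima,
particularly on the flanks of strong lines where the trace crosses the
threshold slowly. Thresholded local-maximum picking is therefore well
posed only when the threshold clears the noise by several standard
deviations. The synthetic generator's default noise (2·10⁻⁴ of the
tallest line for NMR, 0.05 %T for IR) reflects routine spectra of
concentrated samples and keeps the default thresholds comfortably above
the noise; the recovery tests hold under these conditions and would not
hold for noise at the threshold itself.

Edits are auditable: removals flip peaks to `status = "removed"` but
keep them in the list, additions enter with `origin = "user"` and an
ordinate interpolated from the trace. Removal targets match the nearest
active peak within one grid step - shell-driven edits are as imprecise
as mouse clicks, but the tolerance must stay bounded.

## NMR analysis

**Referencing.** The solvent table ships as an editable CSV of the
standard residual-shift compilation values (CDCl₃ 7.26/77.16, DMSO-d₆
2.50/39.52, CD₃OD 3.31/49.00, D₂O 4.79, and others). Correction is a
rigid shift of the axis by (expected − observed); differences between
any two shifts are exactly preserved.

**Integration.** Each range's raw area is the trapezoidal area above a
local linear baseline through the range ends; integrals are normalized
so the reference range equals the reference value exactly. The baseline
is anchored on the mean of the outermost three grid points per side so a
single noisy endpoint cannot tilt it. Accuracy depends on the range
width: the anchor noise enters multiplied by the width, so ranges of
roughly ±25 linewidths around a signal (±0.1 ppm for 1-2 Hz lines at
400 MHz) recover a 2:3 area ratio within about 1%, while ranges three
times wider triple that error. The tests integrate over ±0.1 ppm.

**Multiplicity.** Peak spacings are converted to Hz via the observe
frequency. Binomial n-line patterns (d through sept) require equal
spacings within max(0.15 Hz, 5% of J) and line intensities within 30% of
the binomial ratios; a dd must decompose into two spacings with
near-equal line intensities and resolvably different J; dt and td are
fitted by brute-force enumeration of two-coupling trees over the
observed gaps, with the label chosen by which coupling is larger.
Named J are restricted to [0.5, 25] Hz. Anything failing any rule is
reported as an unresolved multiplet `m` with no fabricated couplings -
the conservative direction, since a wrong named label poisons the
downstream report. Before analysis the line positions are refined by a
quadratic fit over ±2 grid points around each apex, which brings the J
precision well below the grid spacing (about 0.05 Hz worst-case on the
study set below).

**The recovery study.** `gen_multiplet_study()` defines the conditions
under which recovery is measured: labels cycle over s/d/t/q/dd, J
uniform in [2, 18] Hz, 1 Hz Lorentzian lines at 400 MHz, a 2 ppm window
sampled at 4096 points (≈0.2 Hz/point), and noise at 1% of the tallest
line - an amplitude SNR of 100, which is ordinary for ¹H spectra and
safely above the floor where thresholded picking stops being well posed.
For dd fixtures the two J are drawn at least two linewidths apart: a dd
whose couplings merge produces a 1:2:1 three-line pattern that is
*physically* a triplet, so it cannot serve as ground truth for label
recovery. Under these conditions the analyzer names ≥95% of multiplets
correctly (measured ≈98%), with residual failures dominated by small-J
cases where a noise maximum survives in the partially-filled valley
between lines; the fallback in every such case is `m`, never a wrong
named label.

**Reports.** Signals serialize in the journal style
(`¹H NMR (400 MHz, CDCl₃) δ = 8.52 (s, 1H), 7.45 (dd, J = 12.0, 4.0 Hz,
1H)`), shifts and J descending, integrals rounded to the nearest 0.5 H;
¹³C reports list shifts only.

## FID processing

The pipeline is deliberately basic: group-delay handling (circular shift
of the integer part, first-order phase for the fractional part),
exponential apodization (default 0.3 Hz for ¹H, 1.0 Hz for ¹³C),
zero-filling to the next power of two times a factor (default 2), FFT,
ppm axis from `(freq − center)/observe_freq + carrier`, automatic phase
correction, real part, and degree-2 polynomial baseline correction
fitted to the lowest-variance quarter of 32 windowed segments. The
first FID point is halved before the transform, the textbook correction
for the DC offset of a one-sided discrete transform.

Automatic phasing minimizes the negative-lobe area of the real part over
a coarse-to-fine grid (5°/20° down to 0.05°/0.2°), the simplest
defensible objective for well-resolved 1D spectra. Two details matter in
practice. First, the first-order term is parameterized about a pivot at
the tallest peak; otherwise ph1 can impersonate ph0 for a single-line
spectrum and the returned pair is degenerate. Second, a small penalty
(0.05 per 180° of ph1) keeps the first-order term at zero unless a
genuine ramp pays for it; without the penalty the optimizer chases the
faint linear phase that discrete one-sided acquisition leaves across a
line's wings. With both, an injected zero-order error is recovered
within 0.1° on noiseless lines and an injected 90° ramp within 3°
(which requires a multi-line spectrum - a single line cannot constrain
ph1). Advanced phase and baseline methods are explicitly out of scope.

## IR intensity labels

Band depth relative to the deepest band classifies intensities:
vs ≥ 0.8, s ≥ 0.6, m ≥ 0.3, w ≥ 0.1, vw below. The five classes are the
field's reporting standard; the numeric cut-offs are this package's
documented choice and are configurable. Reports print the label in
brackets after the wavenumber: `1700 (vs), 1520 (m)`.

## Composition and the artifact bundle

The composed `*.edit.jdx` re-emits the original records and the full,
untouched data table, and adds the edit state as private records
(`##$CSTHRESHOLD`, `##$CSPEAKS`, `##$CSEDITS`, `##$CSSIGNALS`), so the
file stays valid JCAMP-DX for any reader while this package recovers
peaks and signals losslessly. Edits annotate; they never mutate the
trace. The bundle holds the byte-identical original, the composed file,
and two PNG renditions (1600×1000 full, 320×240 thumbnail - the
dimensions are this package's choice) rendered with the cairo device,
which is byte-deterministic for fixed inputs; rebuilding a bundle from
identical inputs is therefore byte-idempotent, and any peak edit
regenerates both images.

## The synthetic generator, and what the tests do not show

NMR fixtures are sums of Lorentzians at coupling-tree positions with
binomial weights and areas proportional to nH; the matching FID is the
sum of damped complex exponentials whose discrete transform reproduces
the trace within 1% RMS (0.24% measured). IR fixtures are a 100%
baseline minus Gaussian bands; mzML fixtures are standards-conformant
documents with base64/zlib arrays. Noise is additive Gaussian and fully
seeded, and generation restores the caller's RNG state.

The generator deliberately omits solvent ridges, ¹³C satellites,
isotope patterns, field drift, baseline roll and strong-coupling
(second-order) lineshapes. Passing tests therefore demonstrate that the
codecs are faithful and the analyses correct for well-resolved
first-order spectra at routine SNR; they do not demonstrate robustness
to crowded aromatic regions, rolling baselines, or second-order
distortions, and the multiplicity rules will (correctly) answer `m` in
such cases rather than attempt a deconvolution.

## Problem sizes used by the checks

The test suite and the acceptance script use 100 round-trip fixtures per
kind at 256 points, 50 random ASDF tables, 500 multiplets at 4096
points, 100 integration replicates at 8192 points, 50 processed FIDs at
4096 complex points, 100 codec arrays, and a 4×25 detection corpus -
sizes at which every property is measured at full stated scale while the
whole suite stays fast enough to run routinely.
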