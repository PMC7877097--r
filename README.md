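# speckit

A headless R toolkit for the one-dimensional analytical spectra that
synthetic-chemistry data management runs on: ¹H/¹³C NMR, IR and mass
spectrometry. It re-implements the server side of a web-based spectra
editor — decode and compose the open exchange formats, detect the
spectrum type, pick and edit peaks, run the NMR analyses, process raw
FIDs, and emit the edited-file + image bundle an electronic lab notebook
stores next to each upload — with no web stack attached.

What it does:

* **JCAMP-DX codec** (`parse_jcamp`, `write_jcamp`, `read_jcamp`):
  single-block, compound and NTUPLES documents; all ASDF ordinate forms
  (AFFN/PAC, SQZ, DIF, DUP, DIFDUP) with check-value verification;
  lenient by default, `strict = TRUE` to promote checks to errors;
  private `##$` records round-trip verbatim; ZIP containers unpack
  transparently. Re-encoded tables agree within `YFACTOR/2`, exactly
  for integer ordinates.
* **mzML reader** (`parse_mzml`, `select_scan`, `scan_to_jcamp`):
  base64 / zlib binary arrays, 32- and 64-bit floats, scan list in file
  order with the first scan selected by default, conversion to a
  JCAMP-DX peak table that preserves m/z bit-exactly.
* **Type detection and thresholds** (`detect_type`,
  `default_threshold`): data-type record first, observe nucleus to
  split NMR, x-units as fallback; per-kind default picking thresholds
  (1% ¹H, 5% ¹³C, 20% of the deepest IR band, 5% of the MS base peak).
* **Peak picking and edits** (`pick_peaks`, `apply_edits`,
  `format_peak_list`, `refine_peaks`): thresholded strict local maxima
  on the peak-direction-corrected intensity (IR transmittance bands are
  minima), an auditable add/remove edit history, rounded and ordered
  text output.
* **NMR analysis** (`reference_correct`, `nmr_integrate`,
  `analyze_multiplet`, `nmr_report`): residual-solvent referencing from
  a shipped table, baseline-anchored trapezoidal integration normalized
  to a reference range, multiplicity and J inference (s, d, t, q,
  quint, sext, sept, dd, dt, td) with conservative validation rules
  that fall back to `m` rather than fabricate couplings, and
  journal-style reports.
* **FID processing** (`process_fid`, `auto_phase`, `baseline_correct`):
  group delay → exponential apodization → zero-fill → FFT → ppm axis →
  automatic negative-area phasing (pivoted ph0/ph1 grid search) →
  polynomial baseline.
* **Composer and bundle** (`compose_edited_jcamp`, `render_png`,
  `build_bundle`, `ir_intensity_label`): composed `<stem>.edit.jdx`
  carrying the edit state in private records, IR intensities appended in
  brackets (`1700 (vs)`), deterministic 1600×1000 and 320×240 PNG
  renditions, byte-idempotent bundles.
* **Synthetic fixtures** (`gen_nmr`, `gen_ir`, `gen_ms_mzml`,
  `gen_multiplet_study`): seeded generators with machine-readable
  ground truth, so every module is testable offline.
* **CLI** (`exec/speckit`, `spec_cli()`): `detect`, `convert`, `pick`,
  `analyze`, `report`, `render`, `bundle`, `synth`.

## Worked example

A synthetic ¹H spectrum with a dd (J = 12, 4 Hz) at 7.45 ppm and a 3H
singlet at 3.40 ppm, written to JCAMP-DX and analyzed back:

```r
library(speckit)

g <- gen_nmr(list(list(center = 7.45, label = "dd", J = c(12, 4), nH = 1),
                  list(center = 3.40, label = "s", nH = 3)),
             n = 8192, seed = 42)
write_jcamp(spectrum_to_jcamp(g$spectrum), path = "example.jdx")

doc <- read_jcamp("example.jdx")
detect_type(doc)
#> [1] "NMR_1H"

s  <- jcamp_to_spectrum(doc)
pl <- pick_peaks(s)                      # default 1%-of-max threshold
format_peak_list(pl, digits = 2)
#> [1] "7.47, 7.46, 7.44, 7.43, 3.40"

rp <- refine_peaks(pl)                   # sub-grid apex positions
dd <- rp[rp$x > 7.2 & rp$x < 7.7, ]
analyze_multiplet(dd, s$meta$observe_freq)
#> $label          $J
#> [1] "dd"        [1] 11.99  4.04

nmr_integrate(s, list(c(3.3, 3.5), c(7.35, 7.55)), ref_value = 3)
#>     lo   hi    raw integral
#> 1 3.30 3.50 2.9553    3.000
#> 2 7.35 7.55 0.9907    1.006
```

The four dd line positions round-trip through the file format, the peak
list and the apex refinement to within 0.05 Hz of the generating
couplings, and the second signal integrates to 1.006 against the 3H
reference — the 1:3 area ratio built into the fixture. Formatted the way
an experimental section prints it:

```r
#> ¹H NMR (400 MHz, CDCl3) δ = 7.45 (dd, J = 12.0, 4.0 Hz, 1H), 3.40 (s, 3H)
```

And the storage bundle an embedding application keeps per upload:

```r
build_bundle("example.jdx")
#> <artifact_bundle> example.jdx
#>   example.edit.jdx (36800 bytes)
#>   example.edit.png (33818 bytes)
#>   example.thumb.png (3246 bytes)
```

The same pipeline drives the CLI:

```sh
speckit synth nmr -o demo.jdx --seed 3
speckit detect demo.jdx          # NMR_1H
speckit report demo.jdx          # 7.01, 6.99, 3.40
speckit bundle demo.jdx -o out/
```

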