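---
title: "neuroqc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuroqc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the model behind `neuroqc`, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the design was genuinely open.

## The validation model

Quality control is organised around two nested concepts.

A **Test** is one checkpoint over an imaging session (or over each of its
scans). It is a value of class `qc_test` carrying an identifier, a
*docstring* — the human-readable specification of what is verified, copied
verbatim into every report so reports are self-sufficient — a level
(`session` or `scan`), a run function returning a `qc_result`
(`has_passed`, a boolean, plus `data`, a list of detail items), and the
names of two fixture sessions: one on which the Test must pass and one on
which it must fail.

A **Validator** is an ordered list of Tests. `run_validator()` executes
them sequentially and *never short-circuits*: a failing (or crashing)
Test is recorded and the sequence continues, so every report is a
complete checklist rather than a truncated one. Any decision to gate
downstream pipelines on failures is deliberately left to the caller,
via the report's summary. Exceptions inside a Test are converted to a
failed result carrying the error message; a defective checkpoint can
never abort validation.

Scan-level Tests run on every scan of the session; the session outcome is
the conjunction, with per-scan outcomes recorded in `data`. A Test may
declare an `on_fail_flag`: when it fails, the implicated scans are
downgraded (`usable` → `questionable` → `unusable`) via
`set_quality_flag()`. Automated flag changes may only downgrade; an
upgrade is a human decision and requires `force = TRUE`.

Reports carry provenance — validator name, timestamp, and the code SHA
recorded in the installed package's metadata (`"unknown"` when the
package was not built from a tracked checkout) — and are persisted as a
resource of the validated session in three forms: the normative JSON
schema, Markdown, and HTML rendered from the Markdown by a small internal
renderer. PDF generation is a documented extension point on top of the
persisted Markdown rather than a hard dependency.

### Self-testing

The fixture pair attached to every Test makes the framework
self-testing: `self_check()` re-executes each shipped Test against its
passing and its failing fixture and reports
`(passed_on_passing, failed_on_failing)` per Test. Because all Tests
share one template, this harness requires no modification as checkpoints
are added — a new Test is covered the moment it declares its fixtures.
The fixtures are generated, read-only inputs, so the self-check table is
a fixed point: running it twice yields identical results.

## Shipped checkpoints and their parameters

All thresholds live in one configuration object, `qc_config()`, and are
site defaults to be calibrated — they deliberately describe a single-site
installation (Siemens Biograph64 VG51C PET, Philips Ingenia CX MR, FDG
and flutemetamol tracers).

| Parameter | Default | Unit | Notes |
|---|---|---|---|
| `weight_interval` | [40, 150] | kg | subject weight gate |
| `dose_interval` | [1.5e8, 3.5e8] | Bq | injected tracer dose gate |
| `allowed_tracers` | FDG, FLUTEMETAMOL | — | case-insensitive match |
| `subject_id_pattern` | `^[A-Z]+[0-9]{5}$` | regex | full match required |
| `consistency_keys` | PatientID, StudyDate, Manufacturer, ManufacturerModelName | — | cross-scan consistency |
| `t1_designation` | `"T1"` | substring | marks T1-weighted SeriesDescription |
| per-pipeline `version` / `manifest` / `max_seconds` / `volume_intervals` | see `qc_config()` | — | derivative checks |

Decisions worth recording:

* **Interval endpoints are inclusive.** "Between 40 and 150 kg" is
  ambiguous; a physical reading exactly at a bound is acceptable, so both
  gates use closed intervals. The test suite pins this with an integer
  sweep whose passing set is exactly 40..150.
* **String comparisons** (tracer, scanner model) trim whitespace and
  ignore case; the raw values are echoed in `data` so nothing is hidden
  by normalisation.
* **Subject-id format.** The default pattern is an arbitrary but
  plausible cohort convention (uppercase prefix + five digits),
  configurable; the match is anchored on both ends so partial matches and
  interior whitespace fail.
* **Runnability checks pass with a note when inapplicable.** A
  quantification pipeline bound to one tracer (Centiloid ↔ flutemetamol,
  FDG quantification ↔ FDG) cannot be "failed" by a session of the other
  tracer; reporting that as failure would make every clean session red.
  Sessions whose tracer does not match (or is missing — the tracer
  check itself catches that) yield a pass with a "not applicable" note.
* **Manifest checks tolerate extras.** Pipelines add logs freely;
  unexpected files are reported in `data` but only *missing* expected
  items fail the check.
* **Volume checks are orthogonal to presence checks.** A label keyed in
  the safety-interval map but absent from the computed volume table is
  ignored by `volumes_within_intervals()`: label *presence* is
  `has_all_subfields()`'s job, and keeping the two disjoint means each
  defect flips exactly one checkpoint.
* **Global tissue volumes use fraction-of-image intervals.** Absolute
  mm³ gates for gray/white matter would be tied to one field of view;
  fractions of the total image volume transfer between synthetic
  phantoms and real acquisitions. Hippocampal-subfield gates remain in
  mm³, the unit in which such safety ranges are naturally quoted. Both
  default sets are broad, literature-plausible placeholders marked
  "site-calibrate me" in the configuration source.

## Snapshot rendering

`plot_segment()` reads NIfTI volumes, reorients them to RAS (so voxel
axes 1/2/3 are sagittal/coronal/axial), and renders grids of slices.
Numerical choices:

* **Slice selection** takes `n` evenly spaced indices within the
  bounding range of the nonzero segmentation along the plane axis. A
  candidate landing on a slice with fewer than `min_voxels` foreground
  voxels (possible when the segmentation has several disjoint blobs) is
  snapped to the nearest adequately filled slice, ties toward the lower
  index — deterministic and never empty. An all-zero segmentation is an
  error.
* **Background windowing** maps the 1st–99th intensity percentiles to
  [0, 1] grayscale: deterministic and robust to hot voxels.
* **No resampling.** Background and segmentation must share a voxel
  grid; a mismatch errors out rather than silently interpolating.
* **Colors** come from a fixed categorical palette keyed by sorted label
  value, so a structure keeps its color across sessions; an explicit
  colormap may override any label.
* **Contours** are the in-slice 4-neighborhood boundary: a foreground
  pixel is on the contour iff at least one of its four neighbors (image
  border included) carries a different label. The test suite checks this
  operator against an independent brute-force oracle.
* **Opacity 0 is the exact identity** on the background rendering
  (blending is `(1 − α)·bg + α·color` with `α = 0`), pinned to byte
  equality in the tests.
* **Animation** ramps the overlay opacity linearly 0 → peak → 0 over a
  configurable frame count; frame 1 is the pure background and the middle
  frame equals the static render at peak opacity. Frames are encoded as a
  looping GIF89a with a fixed 216-color cube palette; the LZW stream is
  emitted as literal codes with periodic clear codes, a valid encoding
  every decoder accepts, chosen for simplicity and byte determinism over
  compression ratio.

Static PNGs are byte-deterministic for fixed inputs and specification;
repeated renders are compared by checksum in the tests.

## Collection and review

`aggregate_aseg()` parses FreeSurfer-format `aseg.stats` tables
(`# ColHeaders` header line, whitespace-delimited body; structure names
are used verbatim as spreadsheet columns) into one row per session.
`aggregate_tests()` reads only the *persisted* report JSONs — it reflects
what was actually validated, not what would validate now. Both skip
non-qualifying sessions with notes instead of failing.

The review store is an append-only TSV log: every score/comment action is
a new row, the "current" view is the latest row per (snapshot, rater),
and a per-append lock directory (atomic `dir.create`) protects concurrent
raters. The score scale defaults to 0–2 (fail / doubtful / pass) — a
deliberate choice, configurable per call, since no canonical scale
exists. Navigation (`next_failed()`) and the store are plain functions
over tibbles, so the user interface is replaceable; the shipped surface
is a generated static HTML gallery page plus the command-line wrapper,
which keeps the package free of a web-server dependency.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions under which the framework is exercised.

* `make_phantom()` builds an ellipsoidal two-shell "head" (dim outer
  shell 0.3, bright core 0.8) with seeded Gaussian noise (sd 0.05),
  1 mm isotropic, RAS sform.
* `make_labelmap()` places each label as a compact blob with *exactly*
  the requested voxel count, so volume recovery is exact by
  construction.
* `make_session()` writes the full on-disk layout with clean defaults
  chosen to sit comfortably inside every gate: weight 75 kg, dose
  2.0e8 Bq, FDG tracer, the configured scanner strings, well-formed
  subject ids. MR sessions carry complete derivative resources
  (label maps, genuine-dialect `aseg.stats`, manifest files, provenance
  records with plausible execution times).
* Each defect identifier flips its targeted checkpoint and only that one
  — except defects that break stated preconditions of other checkpoints
  (losing the usable T1 also disables the matching quantification
  pipeline; removing the label maps breaks every test that reads them).
  One defect, `missing_labelmap`, exists specifically to give the
  snapshot tests their failing fixture; manifests deliberately exclude
  the label-map file so this defect stays disjoint from
  `missing_manifest_file`.
* Determinism: every output is a pure function of (parameters, seed);
  per-session seeds derive as `seed + index`, the caller's RNG state is
  saved and restored, and the test suite pins whole-project determinism
  by checksumming generated trees.

Default volumes are 32×32×32 voxels (8×8×8 where only metadata matters),
chosen so a complete fixture project of ~30 sessions builds in seconds
while still exercising every code path at realistic structure: multiple
tissue shells, multiple labels, anisotropic-capable headers.

What the generator does **not** emulate — and hence what green tests do
not show about real data: realistic brain anatomy or tracer kinetics,
DICOM pixel data and the conversion step (sidecars are taken as given),
scanner-specific metadata quirks beyond the checked keys, partial-volume
effects in segmentations, or the failure *rates* of real pipelines. The
framework's correctness claims are about the checking machinery, not
about the clinical validity of any particular threshold.

## Known limitations

* Validation targets pipeline outputs; the pipelines themselves are
  never executed.
* No DICOM reader: a sidecar-producing converter is assumed upstream,
  and the metadata model is limited to the checked keys.
* Default safety intervals and manifests are placeholders; a site must
  calibrate them before the derivative checks carry clinical meaning.
* The review layer ships storage, navigation and a static page, not a
  multi-user web application; rater identity is a free-text field, not
  authentication.
* Image-content quality metrics (motion, SNR, registration accuracy)
  are out of scope; the checks are metadata- and structure-level.
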