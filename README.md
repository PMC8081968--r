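# neuroqc

Automated quality control for neuroimaging projects stored on a local
filesystem.

Large MR/PET cohort studies accumulate thousands of imaging sessions, and
most quality problems — a mistyped subject identifier, a wrong scanner
model, an out-of-range tracer dose, a segmentation missing a subfield, a
pipeline run with the wrong software version — are mundane, mechanical and
perfectly checkable by a machine. `neuroqc` provides the machinery:

* **A validator framework.** A *Test* is one checkpoint with a
  human-readable docstring, a binary outcome (`has_passed`) and a detail
  payload (`data`). A *Validator* is an ordered set of Tests run against
  one imaging session; it emits a validation report (JSON + Markdown +
  HTML) persisted as a resource of the session, with provenance
  (validator name, code SHA, timestamp). Failures never short-circuit the
  sequence, so every report is a complete checklist.
* **Self-testing checks.** Every Test names one fixture session on which
  it must pass and one on which it must fail; `self_check()` re-executes
  the whole registry against both sides, so the test suite never needs
  per-test updates as checkpoints are added.
* **Shipped validators.** `PetSessionValidator` (nine acquisition checks:
  tracer registration, cross-scan metadata consistency, scanner model,
  subject weight within 40–150 kg, injected dose within 1.5e8–3.5e8 Bq,
  subject-id format, usable T1-weighted image, Centiloid and FDG
  quantification runnability), `ArchivingValidator` for MR sessions, and
  derivative validators for ASHS, SPM12, FreeSurfer, DTIFIT and ANTs
  outputs (file manifests, software versions, execution times,
  segmentation label completeness, volume safety intervals, snapshot
  generation).
* **Snapshot rendering.** `plot_segment()` compiles grids of segmentation
  slices overlaid on the anatomy (solid or contour, any opacity), as
  deterministic PNGs or looping opacity-fade GIFs, fully offscreen.
* **Project-wide collection.** `aggregate_tests()`, `aggregate_aseg()`,
  `collect_files()` and `collect_snapshots()` turn a whole project into
  spreadsheets and flat snapshot folders in one call.
* **Assisted visual review.** An append-only TSV score store
  (`upsert_review()`, `current_reviews()`, `export_reviews()`),
  checkpoint-aware navigation (`next_failed()` jumps from one failed case
  to the next) and a static HTML gallery.
* **A synthetic-data generator.** `make_project()` /
  `make_selfcheck_project()` build complete projects — NIfTI phantoms,
  metadata sidecars, derivative resources, genuine-format `aseg.stats`
  tables — with controllable single-defect injections, providing every
  fixture the framework needs.

Projects live in a plain directory tree mirroring the usual imaging
database hierarchy:

```
<root>/<subject>/<session>/session.json
<root>/<subject>/<session>/scans/<scan_id>/{image.nii.gz, image.json}
<root>/<subject>/<session>/resources/<NAME>/...
```

Metadata sidecars are JSON files with DICOM-derived keys (PatientID,
PatientWeight, Radiopharmaceutical, RadionuclideTotalDose,
ManufacturerModelName, SeriesDescription, StudyDate, ...). All thresholds
and expected strings live in one configuration object (`qc_config()`).

## Worked example

Generate a small synthetic PET project in which session 2 was injected
with an under-dosed tracer, then validate it:

```r
library(neuroqc)

proj <- make_project(tempfile("proj"), 3,
                     defect_plan = list("2" = "dose_low"),
                     seed = 17, kind = "PET")
report <- run_validator(pet_session_validator(),
                        proj$sessions[["S00002"]], proj)
glance(report)
#> # A tibble: 1 × 7
#>   validator           session_id subject_id generated     code_sha passed failed
#>   <chr>               <chr>      <chr>      <chr>         <chr>     <int>  <int>
#> 1 PetSessionValidator S00002     ALFA00002  2026-09-29T0… unknown       8      1
tidy(report)[, c("test_id", "has_passed")]
#> # A tibble: 9 × 2
#>   test_id                       has_passed
#>   <chr>                         <lgl>
#> 1 IsTracerCorrect               TRUE
#> 2 IsSeriesDescriptionConsistent TRUE
#> 3 IsScannerVersionCorrect       TRUE
#> 4 IsSubjectWeightConsistent     TRUE
#> 5 IsTracerDoseConsistent        FALSE
#> 6 IsSubjectIdCorrect            TRUE
#> 7 HasUsableT1                   TRUE
#> 8 IsCentiloidRunnable           TRUE
#> 9 IsFDGQuantificationRunnable   TRUE
```

Exactly the targeted checkpoint fails: the injected dose (1.0e8 Bq) lies
below the 1.5e8 Bq gate. The persisted report
(`resources/PetSessionValidator/report.{json,md,html}`) contains one
section per test with its docstring, and `autoplot(report)` draws the
checklist. Running the continuous-integration harness over the shipped
registry:

```r
sc <- self_check(qc_registry(),
                 make_selfcheck_project(tempfile("sc"), seed = 42))
dplyr::count(sc, validator, ok)
#> # A tibble: 7 × 3
#>   validator            ok        n
#>   <chr>                <lgl> <int>
#> 1 ANTSValidator        TRUE      3
#> 2 ASHSValidator        TRUE      5
#> 3 ArchivingValidator   TRUE      4
#> 4 DTIFITValidator      TRUE      3
#> 5 FreeSurfer6Validator TRUE      4
#> 6 PetSessionValidator  TRUE      9
#> 7 SPM12Validator       TRUE      5
```

Every shipped test passes on its passing fixture and fails on its failing
one.

A command-line wrapper ships at `inst/cli/neuroqc.R`
(`neuroqc run`, `self-check`, `snap`, `collect`, `fixtures`, `review`);
see the comments at its top for the full grammar, e.g.
`Rscript inst/cli/neuroqc.R collect freesurfer6 aseg <project-root>`
writes one spreadsheet of all FreeSurfer structural volumes.

## Scope

`neuroqc` validates pipeline *outputs*; it does not run SPM, FreeSurfer,
ASHS or FSL themselves, does not parse DICOM (a sidecar-producing
converter is assumed upstream), and ships site-neutral default thresholds
that are meant to be calibrated locally. See the methods vignette
(`vignettes/neuroqc-methods.Rmd`) for the model, the design decisions and
the known limitations.
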