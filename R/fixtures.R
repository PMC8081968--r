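# All generators are pure functions of (parameters, seed): the global RNG
# state is saved and restored around every seeded computation.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 1 mm isotropic RAS-oriented NIfTI wrapper for generated volumes.
as_ras_nifti <- function(arr) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1)
  RNifti::sform(img) <- structure(diag(4), code = 2L)
  img
}

DEFECT_IDS <- c("weight_low", "weight_high", "dose_low", "dose_high",
                "bad_scanner", "missing_tracer", "bad_subject_id",
                "inconsistent_metadata", "missing_nifti", "no_usable_t1",
                "missing_subfield", "missing_manifest_file", "wrong_version",
                "overlong_execution", "abnormal_volume", "missing_labelmap")

check_defects <- function(defects) {
  bad <- setdiff(defects, DEFECT_IDS)
  if (length(bad)) {
    abort(sprintf("unknown defect id(s): %s", paste(bad, collapse = ", ")))
  }
  defects
}

#' Generate a synthetic head phantom
#'
#' An ellipsoidal "head" with two tissue intensity shells (an outer
#' skull/scalp shell and a brighter inner brain core) plus seeded Gaussian
#' noise, with a 1 mm isotropic NIfTI header. Deterministic per seed.
#'
#' @param shape Integer volume dimensions (default `c(32, 32, 32)`).
#' @param seed RNG seed.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @return A `niftiImage`.
#' @export
make_phantom <- function(shape = c(32, 32, 32), seed = 1, noise_sd = 0.05) {
  ctr <- (shape + 1) / 2
  semi_outer <- shape / 2 - 1
  semi_inner <- shape / 3
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  r2 <- function(semi) {
    ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
      ((g$z - ctr[3]) / semi[3])^2
  }
  vol <- numeric(nrow(g))
  vol[r2(semi_outer) <= 1] <- 0.3
  vol[r2(semi_inner) <= 1] <- 0.8
  noise <- with_seed(seed, stats::rnorm(length(vol), 0, noise_sd))
  vol <- pmin(pmax(vol + noise, 0), 1)
  as_ras_nifti(array(vol, shape))
}

#' Generate a synthetic segmentation label map
#'
#' Each requested label occupies exactly its requested voxel count, grown
#' as a compact blob around a label-specific center, so
#' [compute_label_volumes()] recovers the counts exactly. Deterministic
#' per seed.
#'
#' @param shape Integer volume dimensions.
#' @param label_counts Named integer vector/list, label value to voxel
#'   count; the counts must fit inside the volume.
#' @param seed RNG seed (jitters the blob centers).
#' @return A `niftiImage` label map with a 1 mm isotropic header.
#' @export
make_labelmap <- function(shape = c(32, 32, 32), label_counts = c(), seed = 1) {
  counts <- unlist(label_counts)
  if (sum(counts) > prod(shape)) {
    abort("requested voxel counts exceed the volume size")
  }
  vol <- array(0, shape)
  if (length(counts)) {
    labels <- sort(as.numeric(names(counts)))
    g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                     z = seq_len(shape[3]))
    centers <- with_seed(seed, {
      base <- sapply(seq_along(labels), function(i) {
        frac <- i / (length(labels) + 1)
        shape * frac
      })
      base + matrix(stats::runif(3 * length(labels), -1, 1), 3)
    })
    free <- rep(TRUE, nrow(g))
    for (i in seq_along(labels)) {
      key <- as.character(labels[i])
      d2 <- (g$x - centers[1, i])^2 + (g$y - centers[2, i])^2 +
        (g$z - centers[3, i])^2
      d2[!free] <- Inf
      take <- order(d2, seq_along(d2))[seq_len(counts[[key]])]
      vol[take] <- labels[i]
      free[take] <- FALSE
    }
  }
  as_ras_nifti(vol)
}

write_sidecar <- function(path, metadata) {
  write_json_file(metadata, path)
}

default_metadata <- function(kind, subject_id, config) {
  md <- list(
    PatientID = subject_id,
    Manufacturer = if (kind == "PET") "SIEMENS" else "Philips",
    ManufacturerModelName = if (kind == "PET") config$expected_pet_scanner
                            else config$expected_mr_scanner,
    StudyDate = "20240501",
    Modality = if (kind == "PET") "PT" else "MR"
  )
  if (kind == "PET") {
    md$SeriesDescription <- "PET WB AC"
    md$Radiopharmaceutical <- "FDG"
    md$PatientWeight <- 75
    md$RadionuclideTotalDose <- 2.0e8
  } else {
    md$SeriesDescription <- "T1 MPRAGE SENSE"
  }
  md
}

write_provenance <- function(dir, version, elapsed_seconds) {
  write_json_file(list(software_version = version,
                       started = "2024-05-01T08:00:00Z",
                       finished = qc_timestamp(
                         parse_time("2024-05-01T08:00:00Z") + elapsed_seconds)),
                  file.path(dir, "provenance.json"))
}

write_aseg_stats <- function(file, seed) {
  structures <- c("Left-Lateral-Ventricle", "Left-Hippocampus",
                  "Left-Amygdala", "Right-Lateral-Ventricle",
                  "Right-Hippocampus", "Right-Amygdala")
  base <- c(7500, 4200, 1700, 7100, 4300, 1750)
  vols <- round(base + with_seed(seed, stats::rnorm(length(base), 0, 100)), 1)
  lines <- c(
    "# Title Segmentation Statistics",
    "# generator neuroqc synthetic fixture (synthetic aseg.stats)",
    "# anatomy_type volume",
    "# ColHeaders  Index SegId NVoxels Volume_mm3 StructName normMean normStdDev normMin normMax normRange",
    sprintf("%3d %4d %7d %9.1f  %-28s %8.4f %8.4f %8.4f %8.4f %8.4f",
            seq_along(structures), c(4, 17, 18, 43, 53, 54),
            as.integer(vols), vols, structures,
            100, 10, 50, 150, 100)
  )
  writeLines(lines, file)
  stats::setNames(vols, structures)
}

write_pipeline_resources <- function(sess_dir, shape, seed, config, defects) {
  res_root <- file.path(sess_dir, "resources")
  ashs_counts <- c("1" = 500, "2" = 400, "3" = 300, "4" = 200, "5" = 100)
  if ("missing_subfield" %in% defects) ashs_counts <- ashs_counts[-3]
  if ("abnormal_volume" %in% defects) ashs_counts[["1"]] <- 5
  spm_counts <- c("1" = round(0.10 * prod(shape)), "2" = round(0.05 * prod(shape)))
  if ("abnormal_volume" %in% defects) spm_counts[["1"]] <- round(0.005 * prod(shape))
  fs_counts <- c("17" = 300, "53" = 300)
  other_counts <- c("1" = 400)
  labelmaps <- list(ASHS = ashs_counts, SPM12 = spm_counts,
                    FREESURFER6 = fs_counts, DTIFIT = other_counts,
                    ANTS = other_counts)
  elapsed <- c(ASHS = 1800, SPM12 = 600, FREESURFER6 = 40000, DTIFIT = 300,
               ANTS = 900)
  for (pipe in names(config$pipelines)) {
    pc <- config$pipelines[[pipe]]
    pdir <- file.path(res_root, pipe)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    if (!"missing_labelmap" %in% defects) {
      RNifti::writeNifti(
        make_labelmap(shape, labelmaps[[pipe]], seed = seed + match(pipe, names(config$pipelines))),
        file.path(pdir, pc$labelmap))
    }
    manifest <- pc$manifest
    if ("missing_manifest_file" %in% defects) manifest <- manifest[-1]
    for (item in manifest) {
      f <- file.path(pdir, item)
      dir.create(dirname(f), recursive = TRUE, showWarnings = FALSE)
      if (grepl("aseg\\.stats$", item)) {
        write_aseg_stats(f, seed = seed)
      } else if (grepl("\\.csv$", item)) {
        counts <- labelmaps[[pipe]]
        utils::write.csv(
          data.frame(label = names(counts), volume_mm3 = as.numeric(counts)),
          f, row.names = FALSE)
      } else {
        writeLines(sprintf("%s synthetic log (seed %d)", pipe, seed), f)
      }
    }
    version <- if ("wrong_version" %in% defects) "0.0.1-dev" else pc$version
    secs <- if ("overlong_execution" %in% defects) 2 * pc$max_seconds
            else elapsed[[pipe]]
    write_provenance(pdir, version, secs)
  }
}

#' Generate one synthetic imaging session on disk
#'
#' Writes a complete session directory (descriptor, scans with NIfTI
#' volumes and JSON metadata sidecars, and — for MR sessions — the full
#' set of derivative pipeline resources: label maps, stats tables,
#' manifest files, provenance records). A clean session passes its
#' validator fully; each injected defect flips its targeted test to fail.
#'
#' @param root Project root directory.
#' @param kind `"MR"` or `"PET"`.
#' @param subject_id,session_id Identifiers (the defaults satisfy the
#'   shipped subject-id pattern).
#' @param defects Character vector of defect identifiers among:
#'   `r paste(DEFECT_IDS, collapse = ", ")`.
#' @param seed RNG seed.
#' @param tracer PET radiopharmaceutical (default FDG).
#' @param shape Voxel dimensions of generated volumes.
#' @param derivatives Write derivative pipeline resources (default: MR
#'   sessions only).
#' @param config A [qc_config()] (metadata defaults follow its expected
#'   scanner strings).
#' @return The session directory path, invisibly.
#' @export
make_session <- function(root, kind = c("MR", "PET"),
                         subject_id = "ALFA00001", session_id = "S00001",
                         defects = character(), seed = 1, tracer = "FDG",
                         shape = c(32, 32, 32),
                         derivatives = (kind[1] == "MR"),
                         config = qc_config()) {
  kind <- match.arg(kind)
  check_defects(defects)
  if ("bad_subject_id" %in% defects) subject_id <- "alfa_01"
  sess_dir <- file.path(root, subject_id, session_id)
  scan_dir <- file.path(sess_dir, "scans", "0001")
  dir.create(scan_dir, recursive = TRUE, showWarnings = FALSE)
  write_json_file(list(session_id = session_id, subject_id = subject_id,
                       modality = kind),
                  file.path(sess_dir, "session.json"))
  md <- default_metadata(kind, subject_id, config)
  if (kind == "PET") md$Radiopharmaceutical <- tracer
  if ("weight_low" %in% defects) md$PatientWeight <- 20
  if ("weight_high" %in% defects) md$PatientWeight <- 210
  if ("dose_low" %in% defects) md$RadionuclideTotalDose <- 1.0e8
  if ("dose_high" %in% defects) md$RadionuclideTotalDose <- 5.0e8
  if ("bad_scanner" %in% defects) md$ManufacturerModelName <- "ACME Imager 3000"
  if ("missing_tracer" %in% defects) md$Radiopharmaceutical <- NULL
  write_sidecar(file.path(scan_dir, "image.json"), md)
  if (!"missing_nifti" %in% defects) {
    RNifti::writeNifti(make_phantom(shape, seed = seed),
                       file.path(scan_dir, "image.nii.gz"))
  }
  if ("no_usable_t1" %in% defects && kind == "MR") {
    writeLines("unusable", file.path(scan_dir, "quality_flag"))
  }
  if ("inconsistent_metadata" %in% defects) {
    scan2 <- file.path(sess_dir, "scans", "0002")
    dir.create(scan2, recursive = TRUE, showWarnings = FALSE)
    md2 <- md
    md2$StudyDate <- "20240502"
    write_sidecar(file.path(scan2, "image.json"), md2)
    RNifti::writeNifti(make_phantom(shape, seed = seed + 1),
                       file.path(scan2, "image.nii.gz"))
  }
  if (derivatives) {
    write_pipeline_resources(sess_dir, shape, seed, config, defects)
  }
  invisible(sess_dir)
}

#' Generate a synthetic imaging project
#'
#' Builds `n_sessions` sessions (subjects `ALFA00001`, ...) with optional
#' per-session defect plans. PET sessions additionally get a companion MR
#' session for the same subject providing a usable T1-weighted image,
#' unless that session's plan includes `no_usable_t1` (companions count as
#' sessions of the project). Reproducible per seed: per-session seeds are
#' derived as `seed + index`.
#'
#' @param root Output project root (created).
#' @param n_sessions Number of primary sessions.
#' @param defect_plan Named list mapping session index (as character or
#'   integer) to a character vector of defect ids.
#' @param seed Global RNG seed.
#' @param kind Modality of the primary sessions.
#' @param shape Voxel dimensions of generated volumes.
#' @param config A [qc_config()].
#' @return The loaded `nqc_project`.
#' @export
make_project <- function(root, n_sessions, defect_plan = list(), seed = 1,
                         kind = c("MR", "PET"), shape = c(32, 32, 32),
                         config = qc_config()) {
  kind <- match.arg(kind)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_sessions)) {
    defects <- check_defects(unlist(defect_plan[[as.character(i)]]) %||%
                               character(0))
    subject <- sprintf("ALFA%05d", i)
    make_session(root, kind, subject_id = subject,
                 session_id = sprintf("S%05d", i), defects = defects,
                 seed = seed + i, shape = shape, config = config)
    if (kind == "PET" && !"no_usable_t1" %in% defects) {
      # the companion shares the (possibly malformed) subject so that only
      # the targeted test is affected by a defect
      if ("bad_subject_id" %in% defects) subject <- "alfa_01"
      make_session(root, "MR", subject_id = subject,
                   session_id = sprintf("S%05d_t1", i), seed = seed + i,
                   shape = shape, derivatives = FALSE, config = config)
    }
  }
  load_project(root)
}

selfcheck_pet_fixtures <- function() {
  list(
    pet_clean = list(),
    pet_clean_flute = list(tracer = "FLUTEMETAMOL"),
    pet_missing_tracer = list(defects = "missing_tracer"),
    pet_inconsistent_metadata = list(defects = "inconsistent_metadata"),
    pet_bad_scanner = list(defects = "bad_scanner"),
    pet_weight_low = list(defects = "weight_low"),
    pet_weight_high = list(defects = "weight_high"),
    pet_dose_low = list(defects = "dose_low"),
    pet_dose_high = list(defects = "dose_high"),
    pet_bad_subject_id = list(defects = "bad_subject_id"),
    pet_no_usable_t1 = list(defects = "no_usable_t1"),
    pet_no_usable_t1_flute = list(defects = "no_usable_t1",
                                  tracer = "FLUTEMETAMOL")
  )
}

selfcheck_mr_fixtures <- function() {
  list(
    mr_clean = list(),
    mr_missing_nifti = list(defects = "missing_nifti"),
    mr_bad_subject_id = list(defects = "bad_subject_id"),
    mr_bad_scanner = list(defects = "bad_scanner"),
    mr_inconsistent_metadata = list(defects = "inconsistent_metadata"),
    mr_missing_subfield = list(defects = "missing_subfield"),
    mr_abnormal_volume = list(defects = "abnormal_volume"),
    mr_missing_manifest_file = list(defects = "missing_manifest_file"),
    mr_wrong_version = list(defects = "wrong_version"),
    mr_overlong_execution = list(defects = "overlong_execution"),
    mr_missing_labelmap = list(defects = "missing_labelmap")
  )
}

#' Generate the self-check fixture project
#'
#' Builds the project containing every passing and failing fixture session
#' referenced by the shipped Tests (see [self_check()]): one clean PET and
#' one clean MR session (with full derivative resources), plus one
#' single-defect session per shipped defect. Each PET fixture subject gets
#' a companion MR session providing a usable T1-weighted image, except the
#' `no_usable_t1` fixtures (the FDG one has its T1 flagged `unusable`, the
#' flutemetamol one has no MR session at all, exercising both failure
#' paths).
#'
#' @param root Output project root (created).
#' @param seed Global RNG seed; per-session seeds are derived from it.
#' @param shape Voxel dimensions of generated volumes.
#' @param config A [qc_config()].
#' @return The loaded `nqc_project`; session ids are the fixture labels
#'   (`pet_clean`, `mr_missing_nifti`, ...).
#' @export
make_selfcheck_project <- function(root, seed = 42, shape = c(32, 32, 32),
                                   config = qc_config()) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  idx <- 0L
  pets <- selfcheck_pet_fixtures()
  for (label in names(pets)) {
    idx <- idx + 1L
    args <- pets[[label]]
    defects <- args$defects %||% character(0)
    subject <- sprintf("ALFA1%04d", idx)
    make_session(root, "PET", subject_id = subject, session_id = label,
                 defects = defects, seed = seed + idx,
                 tracer = args$tracer %||% "FDG", shape = shape,
                 config = config)
    if (label == "pet_no_usable_t1") {
      # companion exists but its T1 is flagged unusable
      make_session(root, "MR", subject_id = subject,
                   session_id = paste0(label, "_t1"),
                   defects = "no_usable_t1", seed = seed + idx,
                   shape = shape, derivatives = FALSE, config = config)
    } else if (label != "pet_no_usable_t1_flute") {
      # companion shares the (possibly malformed) subject id so that only
      # the targeted test is affected by each defect
      if ("bad_subject_id" %in% defects) subject <- "alfa_01"
      make_session(root, "MR", subject_id = subject,
                   session_id = paste0(label, "_t1"), seed = seed + idx,
                   shape = shape, derivatives = FALSE, config = config)
    }
  }
  mrs <- selfcheck_mr_fixtures()
  for (label in names(mrs)) {
    idx <- idx + 1L
    defects <- mrs[[label]]$defects %||% character(0)
    make_session(root, "MR", subject_id = sprintf("ALFA2%04d", idx),
                 session_id = label, defects = defects, seed = seed + idx,
                 shape = shape, config = config)
  }
  load_project(root)
}
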