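#' Construct a 3-D image volume
#'
#' The shared spatial container used throughout the package: a 3-D scalar
#' grid with voxel spacing in millimetres. DWI signal volumes carry
#' arbitrary units; ADC volumes carry units of 1e-6 mm^2/s.
#'
#' @param data A numeric 3-D array.
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm, all > 0.
#' @param orientation Label recording the axis-order convention. Volumes are
#'   stored axis-order (x, y, z) and are never resampled; the tag is
#'   metadata only.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, orientation = "xyz") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 1L))
    stop("grid dimensions must be >= 1 in every axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive voxel sizes in mm")
  structure(
    list(data = data, spacing = spacing, orientation = orientation),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume> %s voxels @ %s mm, range [%.4g, %.4g]\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing), collapse = "x"),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Construct a DWI series
#'
#' A per-patient, per-timepoint set of co-registered diffusion-weighted
#' volumes indexed by b-value (s/mm^2). All member volumes must share grid
#' dimensions and spacing; at least two distinct b-values are required.
#'
#' @param patient_id Opaque patient identifier.
#' @param timepoint Integer timepoint: 0 (baseline), 1 (interim),
#'   2 (end of treatment).
#' @param volumes Named list of [image_volume] objects; names are b-values.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(patient_id, timepoint, volumes) {
  if (!is.list(volumes) || is.null(names(volumes)))
    stop("`volumes` must be a list named by b-value")
  bvals <- suppressWarnings(as.numeric(names(volumes)))
  if (any(is.na(bvals)))
    stop("volume names must be numeric b-values in s/mm^2")
  if (length(unique(bvals)) < 2L)
    stop("a DWI series needs at least two distinct b-values")
  for (v in volumes)
    if (!inherits(v, "image_volume")) stop("all volumes must be image_volume objects")
  d0 <- dim(volumes[[1L]]$data)
  s0 <- volumes[[1L]]$spacing
  for (v in volumes[-1L]) {
    if (!identical(dim(v$data), d0))
      stop(sprintf("shape mismatch between b-value volumes: %s vs %s",
                   paste(d0, collapse = "x"), paste(dim(v$data), collapse = "x")))
    if (max(abs(v$spacing - s0)) > 1e-9)
      stop("spacing mismatch between b-value volumes")
  }
  timepoint <- as.integer(timepoint)
  if (!timepoint %in% 0:2) stop("`timepoint` must be 0, 1 or 2")
  structure(
    list(patient_id = as.character(patient_id), timepoint = timepoint,
         volumes = volumes),
    class = "dwi_series"
  )
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series> patient %s, T%d, b = {%s} s/mm^2, grid %s\n",
              x$patient_id, x$timepoint, paste(names(x$volumes), collapse = ", "),
              paste(dim(x$volumes[[1L]]$data), collapse = "x")))
  invisible(x)
}

#' Extract one b-value volume from a series
#'
#' @param series A [dwi_series].
#' @param b Numeric b-value to retrieve (s/mm^2).
#' @return The matching [image_volume].
#' @export
get_bvolume <- function(series, b) {
  stopifnot(inherits(series, "dwi_series"))
  bvals <- as.numeric(names(series$volumes))
  i <- which(abs(bvals - b) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("b-value %g not present in series (available: %s)",
                 b, paste(names(series$volumes), collapse = ", ")))
  series$volumes[[i]]
}

# plain numeric array from a niftiImage: strip RNifti's internal
# attributes and squeeze a trailing singleton 4th dimension
.nifti_to_array <- function(img) {
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) d <- d[1:3]
  array(as.vector(img), dim = d)
}

#' Read a DWI series from NIfTI files
#'
#' Reads one NIfTI-1 volume per b-value and assembles them into a validated
#' [dwi_series]. A single stitched whole-body volume per b-value is assumed;
#' all volumes of one patient/timepoint must already be on the same grid
#' (no resampling or registration is performed).
#'
#' @param paths Named character vector of file paths; names are b-values in
#'   s/mm^2, e.g. `c("50" = "p01_t0_b50.nii.gz", "800" = ...)`.
#' @param patient_id,timepoint Passed through to [dwi_series()].
#' @return A [dwi_series]. Signal values are passed through unmodified.
#' @export
read_series <- function(paths, patient_id, timepoint) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("`paths` must be named by b-value")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing volume file(s): ", paste(missing, collapse = ", "))
  vols <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    sp <- RNifti::pixdim(img)
    if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
      stop(sprintf("missing or invalid spacing metadata in %s", p))
    image_volume(.nifti_to_array(img), sp[1:3])
  })
  dwi_series(patient_id, timepoint, vols)
}

#' Write an image volume to NIfTI
#'
#' @param vol An [image_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a single NIfTI volume as an image_volume
#'
#' @param path NIfTI file path.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop(sprintf("missing or invalid spacing metadata in %s", path))
  image_volume(.nifti_to_array(img), sp[1:3])
}

RESPONSE_LABELS <- c("CMR", "PMR", "SMD", "PMD")

MANIFEST_COLUMNS <- c("patient_id",
                      "t0_b50", "t0_b800", "t1_b50", "t1_b800",
                      "t2_b50", "t2_b800", "label_t1", "label_t2")

#' Load a cohort manifest
#'
#' The manifest lists, per patient, the file locations of the b50/b800
#' volumes at the three timepoints plus the Lugano response labels at
#' interim (T1) and end of treatment (T2). Labels are consumed as input
#' metadata (reference standard from PET reading); they are never computed.
#'
#' Accepted dialects: a CSV file with columns `patient_id, t0_b50, t0_b800,
#' t1_b50, t1_b800, t2_b50, t2_b800, label_t1, label_t2`, or a YAML file
#' with a top-level `patients` list whose entries carry the same keys.
#'
#' @param path Manifest file (`.csv`, `.yaml` or `.yml`).
#' @param check_files If `TRUE`, verify that every referenced volume exists.
#'   Relative paths are resolved against the manifest's directory.
#' @return A `cohort_manifest`: a data.frame with the columns above, rows in
#'   file order.
#' @export
load_manifest <- function(path, check_files = FALSE) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    doc <- yaml::read_yaml(path)
    pts <- doc$patients
    if (is.null(pts)) stop("YAML manifest must have a top-level `patients` list")
    df <- do.call(rbind, lapply(pts, function(p) {
      as.data.frame(p[MANIFEST_COLUMNS], stringsAsFactors = FALSE)
    }))
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    stop("unsupported manifest format: .", ext)
  }
  if (nrow(df) == 0L) stop("empty cohort: manifest lists no patients")
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols))
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, MANIFEST_COLUMNS]

  # aggregate all validation problems into one report
  problems <- character(0)
  if (anyDuplicated(df$patient_id))
    problems <- c(problems, paste0("duplicate patient_id: ",
      paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", ")))
  for (lab_col in c("label_t1", "label_t2")) {
    bad <- !df[[lab_col]] %in% RESPONSE_LABELS
    if (any(bad))
      problems <- c(problems, sprintf(
        "invalid %s %s for patient(s) %s (must be one of %s)",
        lab_col, paste(sQuote(unique(df[[lab_col]][bad])), collapse = ", "),
        paste(df$patient_id[bad], collapse = ", "),
        paste(RESPONSE_LABELS, collapse = "/")))
  }
  if (check_files) {
    base <- dirname(normalizePath(path))
    for (col in MANIFEST_COLUMNS[2:7]) {
      p <- df[[col]]
      p <- ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
      bad <- !file.exists(p)
      if (any(bad))
        problems <- c(problems, sprintf("missing %s volume for patient(s) %s",
                                        col, paste(df$patient_id[bad], collapse = ", ")))
      df[[col]] <- p
    }
  }
  if (length(problems))
    stop("manifest validation failed:\n  - ", paste(problems, collapse = "\n  - "))
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest
#'
#' @param manifest A `cohort_manifest` (or plain data.frame with the
#'   manifest columns).
#' @param path Output path; dialect chosen from the extension
#'   (`.csv`, `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(manifest)[, MANIFEST_COLUMNS]
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(list(patients = lapply(seq_len(nrow(df)), function(i)
      as.list(df[i, ]))), path)
  } else stop("unsupported manifest format: .", ext)
  invisible(path)
}
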