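# Region ids in the ground-truth label grid
REGION_AIR <- 0L
REGION_BODY <- 1L
REGION_BRAIN <- 2L
REGION_KIDNEY <- 3L
REGION_SPLEEN <- 4L
REGION_MARROW <- 5L
REGION_LESION <- 6L   # lesion k gets id REGION_LESION + k - 1

#' Specify a lymphoma lesion for the phantom
#'
#' An ellipsoidal hypercellular lesion: bright on the b800 image (high
#' baseline signal, restricted diffusion) with Gaussian ADC heterogeneity.
#'
#' @param center Ellipsoid centre in mm (grid coordinates x voxel spacing).
#' @param radii Semi-axes in mm, all > 0.
#' @param adc_mean,adc_sd Lesion ADC distribution in 1e-6 mm^2/s.
#' @param s0 Baseline (b = 0 extrapolated) signal, arbitrary units, > 0.
#' @return A `lesion_spec`.
#' @export
lesion_spec <- function(center, radii, adc_mean = 900, adc_sd = 150,
                        s0 = 500) {
  radii <- rep_len(as.numeric(radii), 3L)
  if (any(radii <= 0)) stop("lesion radii must be positive")
  if (adc_sd < 0) stop("adc_sd must be >= 0")
  if (s0 <= 0) stop("s0 must be positive")
  structure(list(center = as.numeric(center), radii = radii,
                 adc_mean = adc_mean, adc_sd = adc_sd, s0 = s0),
            class = "lesion_spec")
}

#' Specify a whole-body DWI phantom
#'
#' A stylised torso: an elliptical body cylinder in air, with optional
#' physiologically hyperintense organ templates — brain (top of grid),
#' paired kidneys, spleen, and a central bone-marrow stripe along the
#' spine — plus any number of lesions. Organ geometry scales with the grid
#' so the same spec works at reduced sizes. Region ADC values are drawn
#' voxelwise from Gaussians (truncated at 0); signals follow the
#' mono-exponential model at each b-value; Rician noise of width
#' `noise_sigma` is applied independently per b-value volume.
#'
#' Default tissue parameters (s0 arbitrary units; ADC in 1e-6 mm^2/s)
#' are chosen so that on the b800 image lesions are about 7x brighter than
#' background soft tissue, and brain/kidneys/spleen/activated marrow are
#' hyperintense enough to contaminate low-threshold masks — the confounders
#' a fully automatic unedited segmentation must live with.
#'
#' @param dim Grid dimensions (voxels), default `c(96, 96, 220)`.
#' @param spacing Voxel spacing in mm, default `c(2, 2, 5)`.
#' @param lesions List of [lesion_spec()] objects.
#' @param organs Include the hyperintense organ templates (default `TRUE`).
#'   Turn off for clean single-lesion recovery experiments.
#' @param noise_sigma Rician noise sigma in signal units (default 5).
#' @param marrow_activated If `TRUE`, the bone-marrow stripe uses its
#'   chemo-activated (brighter) signal level.
#' @param tissue Named list overriding per-region parameters; each entry is
#'   `list(s0 =, adc_mean =, adc_sd =)` for regions `air`, `body`, `brain`,
#'   `kidney`, `spleen`, `marrow` (plus `marrow_active_s0`).
#' @param seed Integer seed making the rendered series reproducible.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96, 96, 220), spacing = c(2, 2, 5),
                         lesions = list(), organs = TRUE,
                         noise_sigma = 5, marrow_activated = FALSE,
                         tissue = list(), seed = 1L) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 4L)) stop("grid must be 3-D, >= 4 voxels per axis")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  for (l in lesions) if (!inherits(l, "lesion_spec")) stop("lesions must be lesion_spec objects")
  defaults <- list(
    air = list(s0 = 2, adc_mean = 3000, adc_sd = 200),
    body = list(s0 = 100, adc_mean = 1400, adc_sd = 200),
    brain = list(s0 = 400, adc_mean = 800, adc_sd = 100),
    kidney = list(s0 = 450, adc_mean = 1800, adc_sd = 150),
    spleen = list(s0 = 350, adc_mean = 900, adc_sd = 100),
    marrow = list(s0 = 150, adc_mean = 600, adc_sd = 100),
    marrow_active_s0 = 300
  )
  tissue <- utils::modifyList(defaults, tissue)
  fov <- dim * spacing
  structure(list(dim = dim, spacing = as.numeric(spacing), fov = fov,
                 lesions = lesions, organs = isTRUE(organs),
                 noise_sigma = noise_sigma,
                 marrow_activated = isTRUE(marrow_activated),
                 tissue = tissue, seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre coordinate grids in mm, as three arrays
.coord_grids <- function(dim, spacing) {
  cx <- (seq_len(dim[1L]) - 0.5) * spacing[1L]
  cy <- (seq_len(dim[2L]) - 0.5) * spacing[2L]
  cz <- (seq_len(dim[3L]) - 0.5) * spacing[3L]
  list(x = array(rep(cx, times = dim[2L] * dim[3L]), dim = dim),
       y = array(rep(rep(cy, each = dim[1L]), times = dim[3L]), dim = dim),
       z = array(rep(cz, each = dim[1L] * dim[2L]), dim = dim))
}

.inside_ellipsoid <- function(g, center, radii) {
  ((g$x - center[1L]) / radii[1L])^2 +
    ((g$y - center[2L]) / radii[2L])^2 +
    ((g$z - center[3L]) / radii[3L])^2 <= 1
}

# ground-truth region label grid for a phantom spec
.render_labels <- function(spec) {
  g <- .coord_grids(spec$dim, spec$spacing)
  fov <- spec$fov
  labels <- array(REGION_AIR, dim = spec$dim)

  # body: elliptical cylinder over the lower 85% of z
  body <- (((g$x - fov[1L] / 2) / (0.42 * fov[1L]))^2 +
             ((g$y - fov[2L] / 2) / (0.40 * fov[2L]))^2 <= 1) &
    g$z <= 0.85 * fov[3L]
  labels[body] <- REGION_BODY

  if (spec$organs) {
    # brain: ellipsoid sitting above the torso
    brain <- .inside_ellipsoid(g, c(fov[1L] / 2, fov[2L] / 2, 0.92 * fov[3L]),
                               c(0.22 * fov[1L], 0.24 * fov[2L], 0.07 * fov[3L]))
    labels[brain] <- REGION_BRAIN
    # kidneys: paired ellipsoids mid-abdomen
    for (sgn in c(-1, 1)) {
      kid <- .inside_ellipsoid(
        g, c(fov[1L] / 2 + sgn * 0.18 * fov[1L], 0.58 * fov[2L], 0.38 * fov[3L]),
        c(0.07 * fov[1L], 0.08 * fov[2L], 0.05 * fov[3L]))
      labels[kid & body] <- REGION_KIDNEY
    }
    # spleen: single ellipsoid upper-left abdomen
    spl <- .inside_ellipsoid(
      g, c(0.72 * fov[1L], 0.45 * fov[2L], 0.48 * fov[3L]),
      c(0.08 * fov[1L], 0.07 * fov[2L], 0.045 * fov[3L]))
    labels[spl & body] <- REGION_SPLEEN
    # bone marrow: thin spinal stripe along z through the torso
    mar <- (((g$x - fov[1L] / 2) / (0.045 * fov[1L]))^2 +
              ((g$y - 0.68 * fov[2L]) / (0.045 * fov[2L]))^2 <= 1) &
      g$z <= 0.85 * fov[3L]
    labels[mar] <- REGION_MARROW
  }

  overlap_warned <- FALSE
  for (k in seq_along(spec$lesions)) {
    les <- spec$lesions[[k]]
    vox <- .inside_ellipsoid(g, les$center, les$radii)
    if (!overlap_warned && any(labels[vox] >= REGION_BRAIN &
                               labels[vox] < REGION_LESION)) {
      warning("lesion overlaps an organ template; lesion takes precedence")
      overlap_warned <- TRUE
    }
    labels[vox] <- REGION_LESION + k - 1L   # lesion takes precedence
  }
  labels
}

#' Render a phantom into a two-b-value DWI series with ground truth
#'
#' Draws the voxelwise ADC field region by region, computes the noiseless
#' signals `S(b) = s0 * exp(-b * ADC)` at b = 50 and b = 800 s/mm^2, and
#' applies Rician noise (`sqrt((S + e1)^2 + e2^2)`, `e ~ N(0, sigma)`)
#' independently per b-value. Same seed, same output, bit for bit.
#'
#' @param spec A [phantom_spec()].
#' @return List: `series` (a [dwi_series]), `adc_truth` (array, 1e-6
#'   mm^2/s, the drawn field before noise), `labels` (region id array;
#'   lesion k has id `5 + k`), `lesion_volumes` (data.frame of per-lesion
#'   voxel count, voxel volume in cm^3, and analytic ellipsoid volume),
#'   `spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  labels <- .render_labels(spec)
  nvox <- prod(spec$dim)
  adc <- array(NA_real_, dim = spec$dim)
  s0 <- array(NA_real_, dim = spec$dim)

  region_par <- list()
  region_par[[REGION_AIR + 1L]] <- spec$tissue$air
  region_par[[REGION_BODY + 1L]] <- spec$tissue$body
  region_par[[REGION_BRAIN + 1L]] <- spec$tissue$brain
  region_par[[REGION_KIDNEY + 1L]] <- spec$tissue$kidney
  region_par[[REGION_SPLEEN + 1L]] <- spec$tissue$spleen
  marrow <- spec$tissue$marrow
  if (spec$marrow_activated) marrow$s0 <- spec$tissue$marrow_active_s0
  region_par[[REGION_MARROW + 1L]] <- marrow

  for (rid in REGION_AIR:REGION_MARROW) {
    idx <- labels == rid
    n <- sum(idx)
    if (n == 0L) next
    par <- region_par[[rid + 1L]]
    adc[idx] <- pmax(stats::rnorm(n, par$adc_mean, par$adc_sd), 0)
    s0[idx] <- par$s0
  }
  for (k in seq_along(spec$lesions)) {
    les <- spec$lesions[[k]]
    idx <- labels == (REGION_LESION + k - 1L)
    n <- sum(idx)
    if (n == 0L) next
    adc[idx] <- pmax(stats::rnorm(n, les$adc_mean, les$adc_sd), 0)
    s0[idx] <- les$s0
  }

  signal_at <- function(b) {
    s <- s0 * exp(-b * adc * 1e-6)
    if (spec$noise_sigma > 0) {
      e1 <- array(stats::rnorm(nvox, 0, spec$noise_sigma), dim = spec$dim)
      e2 <- array(stats::rnorm(nvox, 0, spec$noise_sigma), dim = spec$dim)
      s <- sqrt((s + e1)^2 + e2^2)
    }
    s
  }
  s50 <- signal_at(50)
  s800 <- signal_at(800)

  series <- dwi_series(
    patient_id = sprintf("phantom_seed%d", spec$seed), timepoint = 0L,
    volumes = list("50" = image_volume(s50, spec$spacing),
                   "800" = image_volume(s800, spec$spacing)))

  lesion_volumes <- if (length(spec$lesions)) {
    vvol <- prod(spec$spacing) / 1000
    do.call(rbind, lapply(seq_along(spec$lesions), function(k) {
      nv <- sum(labels == (REGION_LESION + k - 1L))
      r <- spec$lesions[[k]]$radii
      data.frame(lesion = k, n_voxels = nv, volume_cm3 = nv * vvol,
                 analytic_cm3 = 4 / 3 * pi * prod(r) / 1000)
    }))
  } else data.frame(lesion = integer(0), n_voxels = integer(0),
                    volume_cm3 = numeric(0), analytic_cm3 = numeric(0))

  list(series = series, adc_truth = adc, labels = labels,
       lesion_volumes = lesion_volumes, spec = spec)
}

#' Longitudinal treatment-response scenario
#'
#' Per-timepoint multipliers describing how a patient's lesions evolve
#' under chemotherapy: lesion volume shrinks (radii scale with the cube
#' root of the volume factor) and lesion ADC rises as cellularity drops.
#' The ADC factor is applied to both the lesion ADC mean and spread, since
#' treatment-induced cell death raises and broadens the diffusion
#' distribution. Chemo-activated bone marrow brightening at T1/T2 is
#' modelled via the `marrow_activation` flag.
#'
#' Default effect sizes: complete responders (CMR) shrink to 15% of
#' baseline volume at interim and 5% at end of treatment with ADC up 30%
#' then 40%; partial responders (PMR) shrink to 60% / 50% with ADC up
#' 5% / 10%; progressive disease (PMD) regrows to 130% at T2 with a slight
#' ADC drop; `"CMR_late"` describes interim-partial patients who convert to
#' complete response by end of treatment.
#'
#' @param class Response class: `"CMR"`, `"PMR"`, `"PMD"` or `"CMR_late"`.
#' @param volume_factors Length-2 lesion volume scale at (T1, T2), each in
#'   (0, 1] for responders.
#' @param adc_factors Length-2 lesion ADC multipliers at (T1, T2).
#' @param marrow_activation Raise marrow signal at T1/T2 (default `TRUE`).
#' @return A `response_scenario`.
#' @export
response_scenario <- function(class = c("CMR", "PMR", "PMD", "CMR_late"),
                              volume_factors = NULL, adc_factors = NULL,
                              marrow_activation = TRUE) {
  class <- match.arg(class)
  defaults <- switch(class,
    CMR = list(vol = c(0.15, 0.05), adc = c(1.30, 1.40)),
    CMR_late = list(vol = c(0.50, 0.07), adc = c(1.05, 1.35)),
    PMR = list(vol = c(0.60, 0.50), adc = c(1.05, 1.10)),
    PMD = list(vol = c(1.00, 1.30), adc = c(1.00, 0.95)))
  if (is.null(volume_factors)) volume_factors <- defaults$vol
  if (is.null(adc_factors)) adc_factors <- defaults$adc
  if (any(volume_factors <= 0)) stop("volume factors must be positive")
  structure(list(class = class, volume_factors = volume_factors,
                 adc_factors = adc_factors,
                 marrow_activation = isTRUE(marrow_activation)),
            class = "response_scenario")
}

#' Apply a response scenario to a baseline phantom
#'
#' Produces the three per-timepoint phantom specs: T0 is the baseline spec
#' unchanged; at T1/T2 each lesion's radii are scaled by the cube root of
#' the volume factor (so ground-truth volume scales by the factor itself),
#' its ADC mean and sd are multiplied by the ADC factor, and the marrow
#' stripe switches to its activated signal when flagged. Per-timepoint
#' seeds are offset so noise realisations differ between visits.
#'
#' @param spec Baseline [phantom_spec()].
#' @param scenario A [response_scenario()].
#' @return Named list of `phantom_spec`s: `t0`, `t1`, `t2`.
#' @export
apply_scenario <- function(spec, scenario) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scenario, "response_scenario"))
  at_time <- function(tp) {
    if (tp == 0L) {
      out <- spec
    } else {
      vf <- scenario$volume_factors[tp]
      af <- scenario$adc_factors[tp]
      out <- spec
      out$lesions <- lapply(spec$lesions, function(l) {
        l$radii <- l$radii * vf^(1 / 3)
        l$adc_mean <- l$adc_mean * af
        l$adc_sd <- l$adc_sd * af
        l
      })
      out$marrow_activated <- scenario$marrow_activation
    }
    out$seed <- spec$seed + 101L * tp
    out
  }
  list(t0 = at_time(0L), t1 = at_time(1L), t2 = at_time(2L))
}

#' Simulate a longitudinal WB-DWI cohort on disk
#'
#' Generates `n_cmr + n_pmr` patients (interim response classes), renders
#' b50/b800 NIfTI volumes at T0/T1/T2, and writes a cohort manifest plus a
#' ground-truth table. Lesion count, position, size and ADC parameters are
#' randomised per patient within physiological ranges. End-of-treatment
#' labels follow `t2_outcomes` for the interim-PMR patients (default
#' pattern `CMR, PMR, PMR, PMR, PMD, PMD`, recycled, so a 14 + 6 cohort
#' yields 15 CMR / 3 PMR / 2 PMD at EOT); interim-CMR patients stay CMR.
#' Each patient's rendering scenario matches their label trajectory, so
#' labels are consistent with the simulated biology. Fully reproducible
#' from `seed`.
#'
#' @param n_cmr,n_pmr Number of interim complete / partial responders.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param dim,spacing Grid geometry passed to [phantom_spec()].
#' @param noise_sigma Rician sigma in signal units.
#' @param organs Include hyperintense organ templates.
#' @param t2_outcomes EOT outcome pattern for interim-PMR patients.
#' @param lesion_count_range,lesion_radius_range,adc_mean_range,adc_sd_range
#'   Per-patient randomisation ranges (count; mm; 1e-6 mm^2/s).
#' @param manifest_format `"csv"` or `"yaml"`.
#' @return List: `manifest` (a `cohort_manifest`, also written to disk),
#'   `manifest_path`, `ground_truth` (data.frame, also written as
#'   `ground_truth.csv`), `out_dir`.
#' @export
make_cohort <- function(n_cmr = 14, n_pmr = 6, out_dir, seed = 1L,
                        dim = c(96, 96, 220), spacing = c(2, 2, 5),
                        noise_sigma = 5, organs = TRUE,
                        t2_outcomes = c("CMR", "PMR", "PMR", "PMR", "PMD", "PMD"),
                        lesion_count_range = c(1L, 4L),
                        lesion_radius_range = c(12, 30),
                        adc_mean_range = c(750, 1050),
                        adc_sd_range = c(100, 200),
                        manifest_format = "csv") {
  if (n_cmr + n_pmr <= 0) stop("empty cohort: need at least one patient")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  label_t1 <- c(rep("CMR", n_cmr), rep("PMR", n_pmr))
  label_t2 <- label_t1
  if (n_pmr > 0)
    label_t2[n_cmr + seq_len(n_pmr)] <- rep_len(t2_outcomes, n_pmr)

  n <- n_cmr + n_pmr
  ids <- sprintf("P%02d", seq_len(n))
  fov <- dim * spacing
  rows <- vector("list", n)
  gt <- vector("list", n)

  for (i in seq_len(n)) {
    scen_class <- if (label_t1[i] == "CMR") "CMR"
      else if (label_t2[i] == "CMR") "CMR_late"
      else label_t2[i]
    n_les <- sample(seq(lesion_count_range[1L], lesion_count_range[2L]), 1L)
    lesions <- lapply(seq_len(n_les), function(k) {
      r <- stats::runif(3, lesion_radius_range[1L], lesion_radius_range[2L])
      ctr <- c(stats::runif(1, 0.35, 0.65) * fov[1L],
               stats::runif(1, 0.30, 0.55) * fov[2L],
               stats::runif(1, 0.15, 0.70) * fov[3L])
      lesion_spec(center = ctr, radii = r,
                  adc_mean = stats::runif(1, adc_mean_range[1L], adc_mean_range[2L]),
                  adc_sd = stats::runif(1, adc_sd_range[1L], adc_sd_range[2L]),
                  s0 = stats::runif(1, 450, 550))
    })
    base <- phantom_spec(dim = dim, spacing = spacing, lesions = lesions,
                         organs = organs, noise_sigma = noise_sigma,
                         seed = seed + 1000L * i)
    specs <- apply_scenario(base, response_scenario(scen_class))

    paths <- list()
    for (tp in 0:2) {
      ph <- render_phantom(specs[[tp + 1L]])
      for (b in c(50, 800)) {
        fn <- sprintf("%s_t%d_b%d.nii.gz", ids[i], tp, b)
        write_volume(get_bvolume(ph$series, b), file.path(out_dir, fn))
        paths[[sprintf("t%d_b%d", tp, b)]] <- fn
      }
      gt[[i]] <- rbind(gt[[i]], data.frame(
        patient_id = ids[i], timepoint = tp,
        scenario = scen_class,
        n_lesions = n_les,
        lesion_volume_cm3 = sum(ph$lesion_volumes$volume_cm3),
        lesion_adc_mean = mean(vapply(specs[[tp + 1L]]$lesions,
                                      `[[`, numeric(1), "adc_mean")),
        stringsAsFactors = FALSE))
    }
    rows[[i]] <- data.frame(patient_id = ids[i],
                            t0_b50 = paths$t0_b50, t0_b800 = paths$t0_b800,
                            t1_b50 = paths$t1_b50, t1_b800 = paths$t1_b800,
                            t2_b50 = paths$t2_b50, t2_b800 = paths$t2_b800,
                            label_t1 = label_t1[i], label_t2 = label_t2[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  class(manifest) <- c("cohort_manifest", "data.frame")
  manifest_path <- file.path(out_dir, paste0("manifest.", manifest_format))
  write_manifest(manifest, manifest_path)
  ground_truth <- do.call(rbind, gt)
  utils::write.csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  list(manifest = manifest, manifest_path = manifest_path,
       ground_truth = ground_truth, out_dir = out_dir)
}
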