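# Small in-code fixtures shared across test files.

random_volume <- function(dim = c(4, 4, 4), spacing = c(2, 2, 5), seed = 1) {
  set.seed(seed)
  image_volume(array(runif(prod(dim), 1, 100), dim = dim), spacing)
}

# a minimal valid two-b-value series with exact mono-exponential signals
exact_series <- function(adc_field, s0 = 1000, spacing = c(2, 2, 5),
                         b = c(50, 800), patient_id = "T", timepoint = 0) {
  vols <- lapply(b, function(bv)
    image_volume(s0 * exp(-bv * adc_field * 1e-6), spacing))
  names(vols) <- b
  dwi_series(patient_id, timepoint, vols)
}

# single-lesion phantom without organ templates: clean recovery conditions
clean_lesion_spec <- function(seed, noise_sigma = 0, dim = c(48, 48, 64),
                              spacing = c(4, 4, 6), adc_mean = 900,
                              adc_sd = 150, s0 = 500, radii = c(20, 20, 24)) {
  fov <- dim * spacing
  les <- lesion_spec(center = fov / 2, radii = radii,
                     adc_mean = adc_mean, adc_sd = adc_sd, s0 = s0)
  phantom_spec(dim = dim, spacing = spacing, lesions = list(les),
               organs = FALSE, noise_sigma = noise_sigma, seed = seed)
}

# synthesise a long-format feature table directly (no images), one feature
# per patient, for statistics-level cohort tests
synth_feature_table <- function(values, patient_ids, timepoint = 2,
                                feature_name = "DV", threshold = 40) {
  data.frame(patient_id = patient_ids, timepoint = timepoint,
             threshold_percent = threshold, feature_name = feature_name,
             value = values, n_voxels = 100L, stringsAsFactors = FALSE)
}

# manifest data.frame without files on disk (for statistics-level tests)
synth_manifest <- function(patient_ids, label_t1, label_t2 = label_t1) {
  df <- data.frame(patient_id = patient_ids,
                   t0_b50 = "x", t0_b800 = "x", t1_b50 = "x", t1_b800 = "x",
                   t2_b50 = "x", t2_b800 = "x",
                   label_t1 = label_t1, label_t2 = label_t2,
                   stringsAsFactors = FALSE)
  class(df) <- c("cohort_manifest", "data.frame")
  df
}
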