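#' Gaussian peak specification for a synthetic voltammogram
#'
#' DPV oxidation signals are modeled as Gaussian peaks on a linear
#' baseline — the simplest shape consistent with observed anodic DPV
#' profiles of aged distillates.
#'
#' @param center Peak potential (V vs Ag/AgCl(sat)).
#' @param height Peak current (uA), >= 0.
#' @param width Gaussian sigma (V), > 0.
#' @return An object of class `"peak_spec"`.
#' @export
peak_spec <- function(center, height, width = 0.03) {
  stop_if_not_scalar_number(center, "center")
  stop_if_not_scalar_number(height, "height")
  stop_if_not_scalar_number(width, "width")
  if (height < 0) stop("`height` must be non-negative", call. = FALSE)
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  structure(list(center = center, height = height, width = width),
            class = "peak_spec")
}

#' Simulate a differential-pulse voltammogram
#'
#' Generates `current(E) = intercept + slope * E + sum of Gaussian peaks +
#' Gaussian noise` on a regular potential grid, by default -0.3 to 1.0 V
#' in 5 mV steps (261 points), matching the standard anodic DPV protocol
#' for the distillate index.
#'
#' @param peaks List of [peak_spec()] objects.
#' @param baseline_slope Linear baseline slope (uA/V).
#' @param baseline_intercept Baseline intercept (uA).
#' @param noise_sd Gaussian noise standard deviation (uA).
#' @param potential_range Scan limits (V), increasing.
#' @param step Grid step (V), > 0.
#' @param seed Optional RNG seed; identical seeds give identical scans.
#' @param sample_id,day,toast_level,replicate Metadata carried on the
#'   result.
#' @return A [voltammogram()].
#' @export
gen_voltammogram <- function(peaks = list(), baseline_slope = 0,
                             baseline_intercept = 0, noise_sd = 0,
                             potential_range = c(-0.3, 1.0), step = 0.005,
                             seed = NULL, sample_id = NA_character_,
                             day = NA_real_, toast_level = NA_character_,
                             replicate = 1L) {
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  E <- seq(potential_range[1], potential_range[2], by = step)
  for (idx in seq_along(peaks)) {
    p <- peaks[[idx]]
    stopifnot(inherits(p, "peak_spec"))
    if (p$center < potential_range[1] || p$center > potential_range[2]) {
      stop(sprintf("peak %d (center %.3f V) lies outside the scan range",
                   idx, p$center), call. = FALSE)
    }
  }
  cur <- baseline_intercept + baseline_slope * E
  for (p in peaks) {
    cur <- cur + p$height * exp(-(E - p$center)^2 / (2 * p$width^2))
  }
  cur <- with_seed(seed, cur + stats::rnorm(length(E), sd = noise_sd))
  voltammogram(E, cur, sample_id = sample_id, day = day,
               toast_level = toast_level, replicate = replicate)
}

#' Kinetic simulation scenario
#'
#' Parameters of a simulated ECI trajectory: the bi-exponential
#' extraction/adsorption model (canonical signs: `-a1_mag` on the fast
#' term, `+a2_mag` on the slow one) up to `late_onset`, plus an additive
#' linear ramp of slope `late_slope` afterwards emulating the late
#' release from deeper pores — the bi-exponential form alone cannot
#' produce that fourth, rising phase. Gaussian noise of `noise_sd` is
#' added per point.
#'
#' @param eci_eq Equilibrium index (uA/V).
#' @param a1_mag Fast (extraction) amplitude magnitude (uA/V), >= 0.
#' @param k1 Fast rate constant (1/day), > 0.
#' @param a2_mag Slow (adsorption) amplitude magnitude (uA/V), >= 0.
#' @param k2 Slow rate constant (1/day), > 0.
#' @param late_slope Slope of the late linear rise (uA/V/day).
#' @param late_onset Day the late rise starts (default 60).
#' @param noise_sd Measurement noise (uA/V), >= 0; the default 0.02 is
#'   about 5% of the curve maximum under the light-toast parameters.
#' @param seed Optional RNG seed.
#' @return An object of class `"kinetic_scenario"`.
#' @export
kinetic_scenario <- function(eci_eq, a1_mag, k1, a2_mag, k2,
                             late_slope = 0, late_onset = 60,
                             noise_sd = 0.02, seed = NULL) {
  for (nm in c("eci_eq", "a1_mag", "k1", "a2_mag", "k2", "late_slope",
               "late_onset", "noise_sd")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (k1 <= 0 || k2 <= 0) stop("rate constants must be positive",
                               call. = FALSE)
  if (a1_mag < 0 || a2_mag < 0) stop("amplitude magnitudes must be >= 0",
                                     call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (late_onset < 0) stop("`late_onset` must be non-negative",
                           call. = FALSE)
  structure(list(eci_eq = eci_eq, a1_mag = a1_mag, k1 = k1,
                 a2_mag = a2_mag, k2 = k2, late_slope = late_slope,
                 late_onset = late_onset, noise_sd = noise_sd,
                 seed = seed),
            class = "kinetic_scenario")
}

#' Reference kinetic scenario for a toast level
#'
#' [kinetic_scenario()] preloaded with the published parameter magnitudes
#' of the given toast level ([reference_kinetics()]).
#'
#' @param toast_level `"light"`, `"medium"` or `"intense"`.
#' @param ... Overrides passed to [kinetic_scenario()] (`late_slope`,
#'   `late_onset`, `noise_sd`, `seed`).
#' @return A `"kinetic_scenario"`.
#' @export
toast_scenario <- function(toast_level = c("light", "medium", "intense"),
                           ...) {
  toast_level <- match.arg(toast_level)
  r <- reference_kinetics()
  r <- r[r$toast_level == toast_level, ]
  kinetic_scenario(eci_eq = r$ECI_eq, a1_mag = r$A1, k1 = r$k1,
                   a2_mag = r$A2, k2 = r$k2, ...)
}

#' Simulate an ECI time series
#'
#' Evaluates the scenario's kinetic model at the requested days (canonical
#' sign convention), adds the late linear ramp beyond `late_onset` and
#' per-point Gaussian noise. Identical seeds give bit-identical series.
#'
#' @param scenario A [kinetic_scenario()].
#' @param days Non-negative, sorted day indices (default 0-90 daily).
#' @param replicates Measurements per day.
#' @param toast_level Label stored in the series.
#' @return An [eci_series()].
#' @export
gen_eci_series <- function(scenario, days = 0:90, replicates = 1L,
                           toast_level = "sample") {
  stopifnot(inherits(scenario, "kinetic_scenario"))
  days <- as.numeric(days)
  if (any(days < 0)) stop("days must be non-negative", call. = FALSE)
  if (is.unsorted(days)) stop("days must be sorted", call. = FALSE)
  p <- kinetic_params(scenario$eci_eq, -scenario$a1_mag, scenario$k1,
                      scenario$a2_mag, scenario$k2)
  base <- eci_model(p, days) +
    scenario$late_slope * pmax(days - scenario$late_onset, 0)
  day_all <- rep(days, times = replicates)
  rep_all <- rep(seq_len(replicates), each = length(days))
  base_all <- rep(base, times = replicates)
  vals <- with_seed(scenario$seed,
                    base_all + stats::rnorm(length(base_all),
                                            sd = scenario$noise_sd))
  eci_series(day_all, vals, toast_level, rep_all)
}

#' Texture simulation scenario
#'
#' Parameters of a synthetic stave-surface image: a sinusoidal grain
#' pattern (period/orientation/amplitude), randomly placed dark char
#' speckles, and Gaussian pixel noise, on a uniform base gray level. The
#' simulator is generic plumbing — it emulates the heterogeneity
#' structure of toasted wood photographs, not wood chemistry.
#'
#' @param image_size Side length in pixels (square image).
#' @param grain_period Grain wavelength (pixels), > 0.
#' @param grain_orientation Grain direction (degrees).
#' @param grain_amplitude Grain modulation depth (gray levels), >= 0.
#' @param speckle_density Fraction of pixels turned into char speckles,
#'   in `[0, 1]`.
#' @param speckle_contrast Gray-level drop of a speckle, >= 0.
#' @param base_level Base gray level (0-255).
#' @param noise_sd Pixel noise standard deviation (gray levels), >= 0.
#' @param seed Optional RNG seed.
#' @return An object of class `"texture_scenario"`.
#' @export
texture_scenario <- function(image_size = 128L, grain_period = 24,
                             grain_orientation = 0, grain_amplitude = 20,
                             speckle_density = 0.05, speckle_contrast = 60,
                             base_level = 140, noise_sd = 5,
                             seed = NULL) {
  if (speckle_density < 0 || speckle_density > 1) {
    stop("`speckle_density` must lie in [0, 1]", call. = FALSE)
  }
  if (grain_period <= 0) stop("`grain_period` must be positive",
                              call. = FALSE)
  if (grain_amplitude < 0 || speckle_contrast < 0 || noise_sd < 0) {
    stop("amplitudes, contrasts and noise must be non-negative",
         call. = FALSE)
  }
  if (base_level < 0 || base_level > 255) {
    stop("`base_level` must lie in [0, 255]", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 grain_period = grain_period,
                 grain_orientation = grain_orientation,
                 grain_amplitude = grain_amplitude,
                 speckle_density = speckle_density,
                 speckle_contrast = speckle_contrast,
                 base_level = base_level, noise_sd = noise_sd,
                 seed = seed),
            class = "texture_scenario")
}

#' Texture scenario presets per toast level
#'
#' Increasing toast darkens the surface and raises its heterogeneity
#' (more char speckle at higher contrast), mirroring the reported ordering
#' of image texture across toast levels (intense roughest, light/medium
#' similar).
#'
#' @param toast_level `"light"`, `"medium"` or `"intense"`.
#' @param ... Overrides passed to [texture_scenario()].
#' @return A `"texture_scenario"`.
#' @export
texture_preset <- function(toast_level = c("light", "medium", "intense"),
                           ...) {
  toast_level <- match.arg(toast_level)
  args <- switch(toast_level,
    light = list(base_level = 150, grain_amplitude = 22,
                 speckle_density = 0.02, speckle_contrast = 45,
                 noise_sd = 5),
    medium = list(base_level = 115, grain_amplitude = 20,
                  speckle_density = 0.05, speckle_contrast = 70,
                  noise_sd = 5),
    intense = list(base_level = 70, grain_amplitude = 18,
                   speckle_density = 0.14, speckle_contrast = 130,
                   noise_sd = 8))
  do.call(texture_scenario, utils::modifyList(args, list(...)))
}

#' Simulate a stave-surface grayscale image
#'
#' @param scenario A [texture_scenario()].
#' @return An integer matrix with gray levels 0-255; identical seeds give
#'   identical images.
#' @export
gen_texture_image <- function(scenario) {
  stopifnot(inherits(scenario, "texture_scenario"))
  n <- scenario$image_size
  th <- scenario$grain_orientation * pi / 180
  rc <- outer(seq_len(n), rep(1, n))          # row coordinate
  cc <- outer(rep(1, n), seq_len(n))          # column coordinate
  phase <- 2 * pi * (cc * cos(th) + rc * sin(th)) / scenario$grain_period
  img <- scenario$base_level + scenario$grain_amplitude * sin(phase)
  img <- with_seed(scenario$seed, {
    nspeck <- round(scenario$speckle_density * n * n)
    if (nspeck > 0) {
      pos <- sample.int(n * n, nspeck)
      img[pos] <- img[pos] - scenario$speckle_contrast
    }
    img + stats::rnorm(n * n, sd = scenario$noise_sd)
  })
  quantize(matrix(pmin(pmax(img, 0), 255), n, n))
}

#' Voltammograms tracking a kinetic scenario
#'
#' Convenience generator for end-to-end tests: one synthetic DPV scan per
#' day whose two peak heights are chosen so that the scan's ECI equals
#' the scenario's noiseless kinetic curve at that day (the target index
#' is split evenly between the two peaks). Days where the model value is
#' negative are clipped to zero signal.
#'
#' @param scenario A [kinetic_scenario()].
#' @param days Days to scan.
#' @param toast_level Metadata label.
#' @param noise_sd Per-scan current noise (uA).
#' @param seed Optional RNG seed.
#' @return List of [voltammogram()] objects.
#' @export
gen_voltammogram_series <- function(scenario, days = 1:30,
                                    toast_level = "sample", noise_sd = 0,
                                    seed = NULL) {
  stopifnot(inherits(scenario, "kinetic_scenario"))
  p <- kinetic_params(scenario$eci_eq, -scenario$a1_mag, scenario$k1,
                      scenario$a2_mag, scenario$k2)
  target <- pmax(eci_model(p, days) +
                   scenario$late_slope * pmax(days - scenario$late_onset,
                                              0), 0)
  with_seed(seed, lapply(seq_along(days), function(ix) {
    eci <- target[ix]
    gen_voltammogram(
      peaks = list(peak_spec(0.34, 0.34 * eci / 2),
                   peak_spec(0.50, 0.50 * eci / 2)),
      noise_sd = noise_sd, day = days[ix], toast_level = toast_level)
  }))
}
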