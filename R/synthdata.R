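#' Synthetic daily meteorological forcing
#'
#' Generates a 365-day series of daily mean temperature, incident
#' photosynthetically usable radiation and precipitation as seasonal
#' sinusoids plus optional day-to-day Gaussian noise. The defaults emulate
#' the semi-humid continental monsoon climate of the study region (annual
#' mean temperature 11.8 C, annual precipitation 644 mm concentrated in
#' July--August), which is the climate the packaged baseline configuration
#' was calibrated under.
#'
#' `temperature(d) = temp_mean + temp_amplitude * cos(2*pi*(d - temp_peak_day)/365) + noise`
#' and radiation analogously, floored at zero. Precipitation is a seasonally
#' weighted expectation (von Mises-shaped concentration around
#' `precip_peak_day`) with multiplicative lognormal noise; it is carried for
#' completeness but not consumed by the growth model.
#'
#' @param temp_mean,temp_amplitude annual mean and seasonal amplitude of
#'   daily mean temperature (degrees C).
#' @param temp_peak_day Julian day of the warmest day of the climatological
#'   year.
#' @param rad_mean,rad_amplitude annual mean and amplitude of incident
#'   photosynthetically usable radiation (MJ m-2 d-1).
#' @param rad_peak_day Julian day of peak radiation (summer solstice).
#' @param precip_total_mm annual precipitation (mm).
#' @param precip_peak_day Julian day around which precipitation concentrates.
#' @param temp_sd,rad_sd day-to-day noise standard deviations; both default
#'   to 0 so that the default series is the smooth climatological year.
#' @param seed integer seed used when noise is drawn; the generator is a pure
#'   function of its arguments.
#' @return A data frame with columns `day`, `temperature`, `radiation`,
#'   `precipitation` covering days 1--365.
#' @examples
#' frc <- synth_forcing()
#' mean(frc$temperature)  # ~11.8
#' @export
synth_forcing <- function(temp_mean = 11.8, temp_amplitude = 14.5,
                          temp_peak_day = 205,
                          rad_mean = 8, rad_amplitude = 4.5,
                          rad_peak_day = 172,
                          precip_total_mm = 644, precip_peak_day = 210,
                          temp_sd = 0, rad_sd = 0, seed = 1L) {
  stopifnot(temp_amplitude >= 0, rad_amplitude >= 0,
            temp_sd >= 0, rad_sd >= 0)
  day <- 1:365
  temp <- temp_mean + temp_amplitude * cos(2 * pi * (day - temp_peak_day) / 365)
  rad <- rad_mean + rad_amplitude * cos(2 * pi * (day - rad_peak_day) / 365)
  w <- exp(2 * cos(2 * pi * (day - precip_peak_day) / 365))
  precip <- precip_total_mm * w / sum(w)
  if (temp_sd > 0 || rad_sd > 0) {
    withr::with_seed(as.integer(seed), {
      temp <- temp + stats::rnorm(365, 0, temp_sd)
      rad <- rad + stats::rnorm(365, 0, rad_sd)
      precip <- precip * stats::rlnorm(365, -0.125, 0.5)
    })
  }
  data.frame(day = day,
             temperature = temp,
             radiation = pmax(rad, 0),
             precipitation = pmax(precip, 0))
}

#' The packaged baseline forcing year
#'
#' The smooth climatological forcing year the HWNR baseline configuration is
#' calibrated against: [synth_forcing()] with its default climate normals and
#' zero day-to-day noise.
#' @return A 365-row forcing data frame (see [synth_forcing()]).
#' @export
hwnr_forcing <- function() synth_forcing()

#' Synthetic multi-band reflectance scene with known biomass truth
#'
#' Builds a surface-reflectance cube emulating a spaceborne hyperspectral
#' scene of a reed wetland, together with the ground truth needed to test
#' the retrieval stage end to end. The scene holds five classes -- water,
#' target reed vegetation, coexistent emergent vegetation, floating
#' vegetation and other vegetation -- laid out in vertical strips whose
#' widths are proportional to `class_weights`. For reed pixels a true
#' above-ground biomass (AGB) field is drawn (mean + north--south linear
#' trend + Gaussian noise) and the scene's green-window reflectance is set by
#' inverting the empirical retrieval line, so that at zero reflectance noise
#' [retrieve_agb()] of [band_window_max()] returns the truth exactly. Other
#' classes get smooth template spectra. Everything is clipped to [0, 1].
#'
#' @param nrow,ncol raster dimensions in pixels.
#' @param wavelengths band-center wavelengths in nm; default 32 evenly spaced
#'   centers spanning 400--1000 nm, so the 510--560 nm retrieval window
#'   contains two bands.
#' @param agb_mean,agb_sd mean and pixel-to-pixel standard deviation of the
#'   true reed AGB field (g m-2); the default emulates a July scene.
#' @param agb_trend total north-to-south increase of the AGB field across the
#'   scene (g m-2), emulating the observed spatial gradient.
#' @param reflectance_sd additive reflectance noise standard deviation
#'   applied to every band.
#' @param class_weights relative strip widths of the five classes, in the
#'   order water, reed, coexistent, floating, other.
#' @param pixel_size pixel edge length in metres (metadata only).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list with elements `cube` (array nrow x ncol x nband with
#'   attribute `wavelengths`), `wavelengths`, `class_map` (integer matrix,
#'   1 = water, 2 = reed, 3 = coexistent, 4 = floating, 5 = other),
#'   `true_agb` (matrix, NA off the reed class), `classes` (names) and
#'   `pixel_size`.
#' @export
synth_reflectance_cube <- function(nrow = 40, ncol = 40,
                                   wavelengths = seq(400, 1000, length.out = 32),
                                   agb_mean = 2863.59, agb_sd = 131.86,
                                   agb_trend = 200,
                                   reflectance_sd = 0,
                                   class_weights = c(1, 2, 1, 0.5, 0.5),
                                   pixel_size = 10,
                                   seed = 1L) {
  stopifnot(nrow >= 2, ncol >= 5, length(class_weights) == 5,
            all(class_weights > 0), reflectance_sd >= 0, agb_sd >= 0,
            !is.unsorted(wavelengths, strictly = TRUE))
  classes <- c("water", "reed", "coexistent", "floating", "other")
  # vertical strips proportional to class_weights
  edges <- round(ncol * cumsum(class_weights) / sum(class_weights))
  edges <- pmax(cummax(edges), seq_along(edges))  # ensure >= 1 column each
  class_map <- matrix(0L, nrow, ncol)
  lo <- 1
  for (k in 1:5) {
    class_map[, lo:edges[k]] <- k
    lo <- edges[k] + 1
  }
  nb <- length(wavelengths)
  in_window <- wavelengths >= 510 & wavelengths <= 560
  if (!any(in_window)) {
    stop("no band center in the 510-560 nm window; wavelengths: ",
         paste(round(wavelengths, 1), collapse = ", "))
  }

  withr::with_seed(as.integer(seed), {
    reed <- class_map == 2L
    true_agb <- matrix(NA_real_, nrow, ncol)
    trend <- (row(class_map) - 1) / max(nrow - 1, 1) * agb_trend - agb_trend / 2
    true_agb[reed] <- agb_mean + trend[reed] + stats::rnorm(sum(reed), 0, agb_sd)
    true_agb[reed] <- pmax(true_agb[reed], 0)
    x_true <- (4.8574 - true_agb / 1000) / 15.859
    bad <- which(!is.na(x_true) & (x_true < 0 | x_true > 1))
    if (length(bad)) {
      stop("true AGB range [", round(min(true_agb[bad]), 1), ", ",
           round(max(true_agb[bad]), 1),
           "] g m-2 implies window reflectance outside [0, 1]")
    }

    cube <- array(NA_real_, c(nrow, ncol, nb))
    for (k in 1:5) {
      idx <- class_map == k
      n_px <- sum(idx)
      if (!n_px) next
      template <- class_spectrum(classes[k], wavelengths)
      for (b in seq_len(nb)) {
        v <- rep(template[b], n_px)
        if (reflectance_sd > 0) v <- v + stats::rnorm(n_px, 0, reflectance_sd)
        slice <- cube[, , b]
        slice[idx] <- v
        cube[, , b] <- slice
      }
    }
    # overwrite the reed green window so the retrieval line inverts exactly:
    # the first in-window band carries x, any others sit strictly below it
    win_bands <- which(in_window)
    for (j in seq_along(win_bands)) {
      b <- win_bands[j]
      slice <- cube[, , b]
      v <- if (j == 1) x_true[reed] else 0.95 * x_true[reed]
      if (reflectance_sd > 0 && j > 1) {
        v <- v + stats::rnorm(sum(reed), 0, reflectance_sd)
      }
      if (reflectance_sd > 0 && j == 1) {
        v <- v + stats::rnorm(sum(reed), 0, reflectance_sd)
      }
      slice[reed] <- v
      cube[, , b] <- slice
    }
    cube[] <- pmin(pmax(cube, 0), 1)
  })
  attr(cube, "wavelengths") <- wavelengths
  list(cube = cube, wavelengths = wavelengths, class_map = class_map,
       true_agb = true_agb, classes = classes, pixel_size = pixel_size)
}

# Smooth template spectra (fractional surface reflectance) for the five
# scene classes. Shapes are schematic: water dark and decreasing into the
# NIR; vegetation classes show a green bump, red absorption and a NIR
# plateau of class-specific strength.
class_spectrum <- function(class, wl) {
  gauss <- function(mu, sd) exp(-((wl - mu) / sd)^2)
  nir <- 1 / (1 + exp(-(wl - 715) / 12))  # red edge
  switch(class,
    water      = pmax(0.05 - 0.00008 * (wl - 400), 0.003) + 0.02 * gauss(560, 60),
    reed       = 0.03 + 0.05 * gauss(550, 40) + 0.42 * nir,
    coexistent = 0.03 + 0.09 * gauss(545, 45) + 0.34 * nir,
    floating   = 0.04 + 0.12 * gauss(555, 50) + 0.22 * nir,
    other      = 0.035 + 0.07 * gauss(552, 42) + 0.50 * nir,
    stop("unknown class: ", class)
  )
}

#' Synthetic dated AGB observations from a known model run
#'
#' Runs the growth model under known "true" parameters and samples the
#' simulated above-ground biomass at the given Julian days, optionally adding
#' Gaussian observation noise. Stands in for the sparse satellite-retrieved
#' AGB means used to calibrate the model; the default dates mirror a
#' mid-June, late-July and early-November acquisition.
#'
#' @param params true [reed_params()].
#' @param schedule a [phenology_schedule()].
#' @param forcing a 365-day forcing data frame (see [synth_forcing()]).
#' @param dates Julian days of the observations.
#' @param noise_sd observation noise standard deviation (g m-2).
#' @param seed integer seed for the noise draw.
#' @return A data frame with columns `day` and `agb` (g m-2).
#' @export
synth_agb_observations <- function(params, schedule, forcing,
                                   dates = c(168, 212, 305),
                                   noise_sd = 0, seed = 1L) {
  stopifnot(all(dates >= 1), all(dates <= 365), noise_sd >= 0)
  traj <- integrate_season(params, schedule, forcing)
  agb <- traj$agb[match(dates, traj$day)]
  if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      agb <- agb + stats::rnorm(length(dates), 0, noise_sd)
    })
  }
  data.frame(day = as.integer(dates), agb = agb)
}
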