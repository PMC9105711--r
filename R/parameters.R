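#' Growth-model parameters
#'
#' Constructs and validates the full parameter set of the reed growth model.
#' Defaults are the calibrated Hanshiqiao Wetland Nature Reserve (HWNR) set:
#' together with [phenology_schedule()] and [hwnr_forcing()] they reproduce
#' the site's printed seasonal outputs (peak above-ground biomass about
#' 2.93 kg m-2 in late August, maximum below-ground biomass about
#' 2.49 kg m-2, annual carbon sequestration about 2040 gC m-2 yr-1).
#'
#' All biomass pools are dry matter per unit ground area (g DM m-2), all
#' rates are per day.
#'
#' @param p_max maximum specific net daily photosynthesis rate
#'   (g g-1 d-1) of well-lit young shoot tissue at the optimum temperature.
#' @param i_half half-saturation irradiance of the light response
#'   (MJ m-2 d-1).
#' @param k_ext canopy extinction coefficient per unit layer biomass
#'   (m2 g-1): irradiance decays as `exp(-k_ext * biomass_above)`.
#' @param t_opt,t_width optimum and width (degrees C) of the Gaussian
#'   temperature response `exp(-((T - t_opt)/t_width)^2)`.
#' @param a_half half-saturation age (days) of layer photosynthetic capacity:
#'   tissue in a layer of age `a` retains a fraction `a_half/(a_half + a)` of
#'   its initial capacity.
#' @param k_np constant of nutrient availability, dimensionless, baseline 1.
#'   Production is scaled by the concave factor `k_np^np_exp`, equal to 1
#'   at `k_np = 1`.
#' @param np_exp sublinear exponent of the nutrient response
#'   (dimensionless, on the `k_np` scale).
#' @param q10 temperature coefficient of respiration (per 10 degrees C,
#'   reference 20 C).
#' @param r_above,r_below specific respiration rates (d-1) of above- and
#'   below-ground organs at 20 C.
#' @param m_shoot,m_root,m_rhizome specific mortality rates (d-1).
#' @param m_shoot_senescent,m_flower_senescent elevated shoot and
#'   inflorescence mortality rates (d-1) applied from `t_s` onward.
#' @param f_up upward translocation rate (d-1): fraction of old-rhizome
#'   biomass mobilized per day on `[t_r, t_e)`.
#' @param r_mobilization respiratory cost of mobilizing rhizome reserves:
#'   extra below-ground respiration equal to this fraction of the upward
#'   flux is charged while upward translocation is active (growth
#'   respiration of remobilized dry matter).
#' @param f_up_root fraction of the upward flux routed to roots (the rest
#'   seeds the shoot layers).
#' @param f_shoot_to_rhizome fraction of gross shoot production diverted
#'   below ground from `t_p` onward.
#' @param f_down_root fraction of that downward flux routed to roots (the
#'   rest builds new rhizomes).
#' @param f_flower fraction of gross shoot production directed to the
#'   inflorescence from `t_f` onward.
#' @param f_senescence_transfer fraction of senescent shoot biomass loss
#'   relocated to new rhizomes instead of dying, from `t_s` onward.
#' @param f_elong fraction of allocatable shoot growth used for elongation
#'   (filling the topmost partial canopy layer and opening new ones); the
#'   remainder thickens existing layers in proportion to their biomass.
#' @param shoot_density biomass capacity of a fully occupied 1 cm canopy
#'   layer (g DM m-2 cm-1); controls how fast the canopy gains height.
#' @param bgb_init initial below-ground biomass on Julian day 1
#'   (g DM m-2), held entirely in old rhizomes.
#'
#' @return An object of class `reed_params` (named list).
#' @examples
#' p <- reed_params()
#' p$p_max
#' reed_params(k_np = 1.5)$k_np
#' @export
reed_params <- function(p_max = 0.197,
                        i_half = 0.2,
                        k_ext = 0.016,
                        t_opt = 26.3,
                        t_width = 12,
                        a_half = 80,
                        k_np = 1,
                        np_exp = 0.25,
                        q10 = 2.5,
                        r_above = 0.0008,
                        r_below = 0.0012,
                        m_shoot = 0.0055,
                        m_root = 0.004,
                        m_rhizome = 0.0013,
                        m_shoot_senescent = 0.026,
                        m_flower_senescent = 0.03,
                        f_up = 0.007,
                        r_mobilization = 0.6,
                        f_up_root = 0.15,
                        f_shoot_to_rhizome = 0.46,
                        f_down_root = 0.2,
                        f_flower = 0.08,
                        f_senescence_transfer = 0.48,
                        f_elong = 0.25,
                        shoot_density = 12,
                        bgb_init = 2200) {
  p <- as.list(environment())
  validate_params(p)
  structure(p, class = "reed_params")
}

validate_params <- function(p) {
  rates <- c("p_max", "i_half", "k_ext", "t_width", "a_half", "np_exp",
             "q10", "r_above", "r_below", "m_shoot", "m_root", "m_rhizome",
             "m_shoot_senescent", "m_flower_senescent", "f_up",
             "r_mobilization", "shoot_density", "bgb_init")
  fracs <- c("f_up_root", "f_shoot_to_rhizome", "f_down_root", "f_flower",
             "f_senescence_transfer", "f_elong")
  for (nm in c(rates, fracs, "k_np", "t_opt")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite number", call. = FALSE)
    }
  }
  neg <- rates[vapply(rates, function(nm) p[[nm]] < 0, logical(1))]
  if (length(neg)) {
    stop("negative rate parameter(s): ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  bad <- fracs[vapply(fracs, function(nm) p[[nm]] < 0 || p[[nm]] > 1,
                      logical(1))]
  if (length(bad)) {
    stop("fraction parameter(s) outside [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (p$p_max <= 0) stop("p_max must be > 0", call. = FALSE)
  if (p$k_np <= 0) stop("k_np must be > 0", call. = FALSE)
  if (p$shoot_density <= 0) stop("shoot_density must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.reed_params <- function(x, ...) {
  cat("Reed growth-model parameters\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

# Concave nutrient-availability multiplier, normalized to 1 at k_np = 1.
# The sublinear exponent captures diminishing returns of nutrient enrichment
# on gross production.
nutrient_factor <- function(k_np, np_exp) {
  k_np^np_exp
}

#' Read or write a model configuration file
#'
#' A model configuration bundles parameters, a `phenology:` block of integer
#' Julian days, and the site area (ha) in a single YAML file.
#'
#' @param path file path of the YAML configuration.
#' @return `read_model_config()` returns a list with elements `params`
#'   (a [reed_params()] object), `phenology` (a [phenology_schedule()]) and
#'   `area_ha`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(reed_params, cfg$parameters %||% list())
  phen <- cfg$phenology %||% list()
  schedule <- do.call(phenology_schedule, phen)
  list(params = params, phenology = schedule,
       area_ha = cfg$area_ha %||% NA_real_)
}

#' @rdname read_model_config
#' @param params a [reed_params()] object.
#' @param schedule a [phenology_schedule()].
#' @param area_ha site area in hectares.
#' @export
write_model_config <- function(path, params, schedule, area_ha = NA_real_) {
  cfg <- list(parameters = unclass(params),
              phenology = lapply(unclass(schedule), as.integer),
              area_ha = area_ha)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area of the HWNR reed stand
#'
#' The mapped distribution area of the common-reed stand in the study site's
#' core zone, in hectares, used when scaling per-square-metre carbon to a
#' site total.
#' @export
hwnr_area_ha <- function() 86.58
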