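# ---- internal state-vector layout -------------------------------------------
# y = [layer biomass (1..L, bottom -> top), flower, roots, old_rhizome,
#      new_rhizome, 9 flux accumulators]
# The accumulators (cumulative gross photosynthesis, above/below respiration,
# above/below mortality, upward / downward / senescence translocation) are
# integrated by the same RK4 pass as the pools, so the daily mass-balance
# identity dB = P - R - M (+ internal Tr, which cancels) holds to machine
# precision by construction.
N_ACC <- 9L
ACC_NAMES <- c("P", "R_above", "R_below", "M_above", "M_below",
               "tr_up", "tr_down", "tr_senescence", "allocation")

new_state_vector <- function(layers, flower = 0, roots = 0,
                             old_rhizome = 0, new_rhizome = 0) {
  c(layers, flower, roots, old_rhizome, new_rhizome, numeric(N_ACC))
}

#' Irradiance profile through a layered canopy
#'
#' Beer--Lambert attenuation over cumulated layer biomass: the irradiance
#' reaching layer `j` (layers given from the canopy top downward) is
#' `I0 * exp(-k_ext * sum(biomass of layers above j))`. The canopy top always
#' receives the full incident radiation.
#'
#' @param shoot_layers biomass per 1 cm layer (g DM m-2), ordered from the
#'   canopy top downward.
#' @param incident_radiation irradiance at the canopy top (MJ m-2 d-1).
#' @param k_ext extinction coefficient per unit layer biomass (m2 g-1).
#' @return Numeric vector of per-layer irradiance, non-increasing from top
#'   to bottom.
#' @examples
#' light_profile(c(10, 10, 10), 12, 0.005)
#' @export
light_profile <- function(shoot_layers, incident_radiation, k_ext) {
  if (any(shoot_layers < 0)) stop("negative layer biomass")
  if (incident_radiation < 0) stop("incident radiation must be >= 0")
  above <- cumsum(c(0, shoot_layers[-length(shoot_layers)]))
  incident_radiation * exp(-k_ext * above)
}

#' Gross photosynthesis of one canopy layer
#'
#' `p_max * phi_np * phi_age * biomass * I/(I + i_half) *
#'  exp(-((T - t_opt)/t_width)^2)` where `phi_np` is the concave nutrient
#' factor `k_np^np_exp` (equal to 1 at the baseline `k_np = 1`) and `phi_age = a_half/(a_half + age)` is the
#' age-related decline of photosynthetic capacity.
#'
#' @param layer_biomass layer biomass (g DM m-2).
#' @param layer_irradiance irradiance reaching the layer (MJ m-2 d-1).
#' @param temperature daily mean air temperature (degrees C).
#' @param params a [reed_params()] object.
#' @param age layer age in days (0 = opened today).
#' @return Gross production (g DM m-2 d-1); zero when biomass or irradiance
#'   is zero.
#' @export
layer_photosynthesis <- function(layer_biomass, layer_irradiance, temperature,
                                 params, age = 0) {
  stopifnot(all(layer_biomass >= 0), all(layer_irradiance >= 0), all(age >= 0))
  p <- params
  nf <- nutrient_factor(p$k_np, p$np_exp)
  tfac <- exp(-((temperature - p$t_opt) / p$t_width)^2)
  afac <- p$a_half / (p$a_half + age)
  p$p_max * nf * layer_biomass *
    layer_irradiance / (layer_irradiance + p$i_half) * tfac * afac
}

#' Temperature-dependent respiration loss
#'
#' First-order loss with a Q10 temperature response referenced to 20 C:
#' `rate * biomass * q10^((T - 20)/10)`.
#'
#' @param biomass pool biomass (g DM m-2).
#' @param temperature daily mean temperature (degrees C).
#' @param rate specific respiration rate at 20 C (d-1).
#' @param q10 temperature coefficient.
#' @return Loss (g DM m-2 d-1).
#' @export
respiration <- function(biomass, temperature, rate, q10) {
  stopifnot(all(biomass >= 0))
  rate * biomass * q10^((temperature - 20) / 10)
}

#' Daily mortality losses per compartment
#'
#' First-order losses; the shoot and inflorescence rates switch to their
#' elevated senescent values from `t_s` onward, while below-ground rates are
#' unchanged. The returned values are gross tissue death; the share of
#' senescent shoot loss relocated below ground is handled by
#' [translocation()].
#'
#' @param state a `reed_state` (see [reed_state()]).
#' @param day Julian day.
#' @param schedule a [phenology_schedule()].
#' @param params a [reed_params()].
#' @return Named list of losses (g DM m-2 d-1) for `shoot`, `flower`,
#'   `roots`, `old_rhizome`, `new_rhizome`.
#' @export
mortality <- function(state, day, schedule, params) {
  flags <- active_processes(day, schedule)
  p <- params
  m_sh <- if (flags$senescence_active) p$m_shoot_senescent else p$m_shoot
  m_fl <- if (flags$senescence_active) p$m_flower_senescent else p$m_shoot
  list(shoot = m_sh * sum(state$layers),
       flower = m_fl * state$flower,
       roots = p$m_root * state$roots,
       old_rhizome = p$m_rhizome * state$old_rhizome,
       new_rhizome = p$m_rhizome * state$new_rhizome)
}

#' Net inter-organ translocation fluxes
#'
#' Computes the net daily translocation per compartment, which always sums
#' to zero (translocation redistributes but never creates mass):
#' * on `[t_r, t_e)` a flux `f_up * old_rhizomes` (capped at the pool) leaves
#'   the old rhizomes, split between the shoot base and the roots;
#' * from `t_p` onward a fraction `f_shoot_to_rhizome` of current gross shoot
#'   production is diverted to new rhizomes and roots;
#' * from `t_f` onward a fraction `f_flower` of gross shoot production is
#'   directed to the inflorescence;
#' * from `t_s` onward a fraction `f_senescence_transfer` of the senescent
#'   shoot biomass loss is relocated to new rhizomes instead of dying.
#'
#' @inheritParams mortality
#' @param gross_production current gross shoot photosynthesis
#'   (g DM m-2 d-1).
#' @return Named numeric vector of net fluxes (g DM m-2 d-1) for
#'   `shoot`, `flower`, `roots`, `old_rhizome`, `new_rhizome`; sums to zero.
#' @export
translocation <- function(state, day, schedule, params, gross_production) {
  stopifnot(gross_production >= 0)
  flags <- active_processes(day, schedule)
  p <- params
  up <- if (flags$upward_translocation_active) {
    min(p$f_up * state$old_rhizome, state$old_rhizome)
  } else 0
  up_root <- p$f_up_root * up
  down <- if (flags$downward_translocation_active) {
    p$f_shoot_to_rhizome * gross_production
  } else 0
  to_flower <- if (flags$panicle_fluxes_active) {
    p$f_flower * gross_production
  } else 0
  # diversions cannot exceed the production they are taken from
  tot <- down + to_flower
  if (tot > gross_production && tot > 0) {
    scl <- gross_production / tot
    down <- down * scl
    to_flower <- to_flower * scl
  }
  down_root <- p$f_down_root * down
  sen <- if (flags$senescence_active) {
    p$f_senescence_transfer * p$m_shoot_senescent * sum(state$layers)
  } else 0
  c(shoot = (up - up_root) - down - to_flower - sen,
    flower = to_flower,
    roots = up_root + down_root,
    old_rhizome = -up,
    new_rhizome = (down - down_root) + sen)
}

#' Allocate net shoot growth over canopy layers
#'
#' A fraction `f_elong` of the allocatable shoot growth is used for
#' elongation: it fills the topmost partially occupied 1 cm layer and, once
#' that layer reaches `shoot_density`, opens new layers above it. The
#' remaining `1 - f_elong` thickens existing layers in proportion to their
#' biomass (so with `f_elong = 0` an established canopy never gains height).
#' An empty canopy seeds its first layer from the elongation pathway
#' regardless of `f_elong`. Total allocated biomass always equals the input.
#'
#' @param shoot_production_net allocatable shoot growth (g DM m-2 d-1),
#'   must be non-negative.
#' @param state a `reed_state`; only `state$layers` is used.
#' @param params a [reed_params()]; uses `f_elong` and `shoot_density`.
#' @return Numeric vector of per-layer additions (bottom to top), possibly
#'   longer than `state$layers` when new layers open.
#' @export
elongation <- function(shoot_production_net, state, params) {
  stopifnot(shoot_production_net >= 0)
  b <- state$layers
  alloc <- allocate_shoot_growth(b, shoot_production_net,
                                 params$f_elong, params$shoot_density)
  alloc
}

# Split `amount` into proportional thickening and sequential top fill.
# `b` bottom -> top; returns an addition vector at least as long as b.
allocate_shoot_growth <- function(b, amount, f_elong, shoot_density) {
  total <- sum(b)
  if (amount <= 0) return(numeric(length(b)))
  if (total <= 0) {
    prop_amt <- 0
    fill_amt <- amount
  } else {
    fill_amt <- f_elong * amount
    prop_amt <- amount - fill_amt
  }
  occupied <- which(b > 0)
  jt <- if (length(occupied)) occupied[length(occupied)] else 1L
  # headroom needed above the top layer (none when nothing elongates)
  extra <- if (fill_amt > 0) ceiling(fill_amt / shoot_density) + 1L else 0L
  add <- numeric(max(length(b), min(jt + extra, length(b) + extra), 1L))
  if (prop_amt > 0) add[seq_along(b)] <- prop_amt * b / total
  rem <- fill_amt
  j <- jt
  while (rem > 1e-15) {
    cap <- shoot_density - (if (j <= length(b)) b[j] else 0) - add[j]
    if (cap > 0) {
      take <- min(rem, cap)
      add[j] <- add[j] + take
      rem <- rem - take
    }
    if (j >= length(add)) {   # safety: dump remainder in the top layer
      add[j] <- add[j] + rem
      rem <- 0
    }
    j <- j + 1L
  }
  add
}

# ---- core derivative --------------------------------------------------------
# Fixed-size derivative used by the RK4 integrator. `ages` has length L and
# is held constant within a day. `flags` are the day's process switches.
reed_derivs <- function(y, L, ages, temperature, radiation, flags, p) {
  b <- pmax(y[seq_len(L)], 0)
  flower <- max(y[L + 1L], 0)
  roots <- max(y[L + 2L], 0)
  old <- max(y[L + 3L], 0)
  newr <- max(y[L + 4L], 0)

  if (any(!is.finite(y))) stop("non-finite state encountered")

  # light from the top: biomass above layer j (bottom -> top storage)
  csum <- cumsum(b)
  above <- csum[L] - csum
  irr <- radiation * exp(-p$k_ext * above)
  nf <- nutrient_factor(p$k_np, p$np_exp)
  tfac <- exp(-((temperature - p$t_opt) / p$t_width)^2)
  afac <- p$a_half / (p$a_half + ages)
  P_l <- p$p_max * nf * b * irr / (irr + p$i_half) * tfac * afac
  P_sh <- sum(P_l)

  q10f <- p$q10^((temperature - 20) / 10)
  R_l <- p$r_above * b * q10f
  R_fl <- p$r_above * flower * q10f
  R_rt <- p$r_below * roots * q10f
  R_old <- p$r_below * old * q10f
  R_new <- p$r_below * newr * q10f

  m_sh <- if (flags$senescence_active) p$m_shoot_senescent else p$m_shoot
  m_fl <- if (flags$senescence_active) p$m_flower_senescent else p$m_shoot
  loss_l <- m_sh * b                      # gross shoot tissue loss
  sen_fr <- if (flags$senescence_active) p$f_senescence_transfer else 0
  sen_tr <- sen_fr * sum(loss_l)          # relocated to new rhizomes
  M_fl <- m_fl * flower
  M_rt <- p$m_root * roots
  M_old <- p$m_rhizome * old
  M_new <- p$m_rhizome * newr

  up <- if (flags$upward_translocation_active) min(p$f_up * old, old) else 0
  up_root <- p$f_up_root * up
  R_mob <- p$r_mobilization * up   # respiratory cost of remobilization
  down <- if (flags$downward_translocation_active) {
    p$f_shoot_to_rhizome * P_sh
  } else 0
  to_flower <- if (flags$panicle_fluxes_active) p$f_flower * P_sh else 0
  tot <- down + to_flower
  if (tot > P_sh && tot > 0) {
    scl <- P_sh / tot
    down <- down * scl
    to_flower <- to_flower * scl
  }
  down_root <- p$f_down_root * down

  alloc <- P_sh - down - to_flower + (up - up_root)
  # within the step, growth thickens layers in proportion to their biomass
  # (smooth in the state); the daily elongation share is remapped to the
  # canopy top by the stepper afterwards (operator splitting)
  tot_b <- sum(b)
  add <- if (tot_b > 0) alloc * b / tot_b else c(alloc, numeric(L - 1L))

  dy <- numeric(L + 4L + N_ACC)
  dy[seq_len(L)] <- add - R_l - loss_l
  dy[L + 1L] <- to_flower - R_fl - M_fl
  dy[L + 2L] <- up_root + down_root - R_rt - M_rt
  dy[L + 3L] <- -up - R_mob - R_old - M_old
  dy[L + 4L] <- (down - down_root) + sen_tr - R_new - M_new
  # accumulators: P, R_above, R_below, M_above, M_below, up, down, senescence
  dy[L + 5L] <- P_sh
  dy[L + 6L] <- sum(R_l) + R_fl
  dy[L + 7L] <- R_rt + R_old + R_new + R_mob
  dy[L + 8L] <- (sum(loss_l) - sen_tr) + M_fl
  dy[L + 9L] <- M_rt + M_old + M_new
  dy[L + 10L] <- up
  dy[L + 11L] <- down
  dy[L + 12L] <- sen_tr
  dy[L + 13L] <- alloc
  dy
}

# Move the elongation share of a step's allocated shoot growth from the
# proportional distribution to the canopy top: subtract it pro rata and
# refill sequentially (topmost partial layer first, opening new layers at
# shoot_density). Returns the remapped layer vector.
remap_elongation <- function(layers, alloc_amount, params) {
  total <- sum(layers)
  fill <- min(params$f_elong * max(alloc_amount, 0), total)
  if (fill <= 0 || total <= 0) return(layers)
  reduced <- layers * (1 - fill / total)
  add <- allocate_shoot_growth(reduced, fill, 1, params$shoot_density)
  if (length(add) > length(reduced)) {
    reduced <- c(reduced, numeric(length(add) - length(reduced)))
  }
  reduced + add
}

#' Construct a plant state
#'
#' Bundles the five biomass compartments of the growth model: per-layer
#' shoot biomass (1 cm layers, bottom to top), inflorescence, roots, old
#' rhizomes and new rhizomes. Above-ground biomass (AGB) is the layer sum
#' plus the inflorescence; below-ground biomass (BGB) is roots plus old plus
#' new rhizomes; height in cm equals the number of occupied layers.
#'
#' @param layers per-layer shoot biomass (g DM m-2), bottom to top.
#' @param flower,roots,old_rhizome,new_rhizome pool biomass (g DM m-2).
#' @param ages optional layer ages in days (defaults to 0).
#' @return An object of class `reed_state`.
#' @export
reed_state <- function(layers = numeric(0), flower = 0, roots = 0,
                       old_rhizome = 0, new_rhizome = 0, ages = NULL) {
  if (any(c(layers, flower, roots, old_rhizome, new_rhizome) < 0)) {
    stop("all biomass pools must be >= 0")
  }
  if (is.null(ages)) ages <- numeric(length(layers))
  stopifnot(length(ages) == length(layers))
  structure(list(layers = layers, ages = ages, flower = flower, roots = roots,
                 old_rhizome = old_rhizome, new_rhizome = new_rhizome),
            class = "reed_state")
}

#' @export
print.reed_state <- function(x, ...) {
  cat(sprintf(paste0("Reed state: AGB %.1f (height %d cm), ",
                     "BGB %.1f g DM m-2\n"),
              sum(x$layers) + x$flower, sum(x$layers > 0),
              x$roots + x$old_rhizome + x$new_rhizome))
  invisible(x)
}

state_to_vector <- function(state) {
  new_state_vector(state$layers, state$flower, state$roots,
                   state$old_rhizome, state$new_rhizome)
}

#' Instantaneous biomass budget of every compartment
#'
#' Evaluates the daily budget `dB/dt = P - R - M + Tr` for each compartment
#' at the given state, day and forcing: gross photosynthesis summed over
#' canopy layers, Q10 respiration, first-order (phenology-switched)
#' mortality and the net inter-organ translocation of [translocation()].
#'
#' @param state a [reed_state()].
#' @param day Julian day.
#' @param forcing either a single-row forcing data frame or a list with
#'   `temperature` and `radiation`.
#' @param params a [reed_params()].
#' @param schedule a [phenology_schedule()].
#' @return A list with `dBdt` (named vector over the five compartments) and
#'   `fluxes` (named vectors `P`, `R`, `M`, `Tr` over compartments).
#' @export
derivatives <- function(state, day, forcing, params, schedule) {
  flags <- active_processes(day, schedule)
  headroom <- 10L
  layers <- c(state$layers, numeric(headroom))
  ages <- c(state$ages, numeric(headroom))
  L <- length(layers)
  y <- new_state_vector(layers, state$flower, state$roots,
                        state$old_rhizome, state$new_rhizome)
  dy <- reed_derivs(y, L, ages, forcing$temperature, forcing$radiation,
                    flags, params)
  acc <- dy[(L + 5L):(L + 4L + N_ACC)]
  names(acc) <- ACC_NAMES
  p <- params
  q10f <- p$q10^((forcing$temperature - 20) / 10)
  m <- mortality(state, day, schedule, params)
  sen_fr <- if (flags$senescence_active) p$f_senescence_transfer else 0
  P <- c(shoot = acc[["P"]], flower = 0, roots = 0, old_rhizome = 0,
         new_rhizome = 0)
  up_gross <- if (flags$upward_translocation_active) {
    min(p$f_up * state$old_rhizome, state$old_rhizome)
  } else 0
  R <- c(shoot = sum(p$r_above * pmax(layers, 0) * q10f),
         flower = p$r_above * state$flower * q10f,
         roots = p$r_below * state$roots * q10f,
         old_rhizome = p$r_below * state$old_rhizome * q10f +
           p$r_mobilization * up_gross,
         new_rhizome = p$r_below * state$new_rhizome * q10f)
  M <- c(shoot = m$shoot * (1 - sen_fr), flower = m$flower, roots = m$roots,
         old_rhizome = m$old_rhizome, new_rhizome = m$new_rhizome)
  Tr <- translocation(state, day, schedule, params, acc[["P"]])
  dBdt <- c(shoot = sum(dy[seq_len(L)]), flower = dy[L + 1L],
            roots = dy[L + 2L], old_rhizome = dy[L + 3L],
            new_rhizome = dy[L + 4L])
  list(dBdt = dBdt, fluxes = list(P = P, R = R, M = M, Tr = Tr))
}

# One classical RK4 update of the internal state vector. Returns the new
# vector plus the biomass added by clamping pools at zero.
rk4_update <- function(y, L, ages, temperature, radiation, flags, p, h = 1) {
  f <- function(yy) reed_derivs(yy, L, ages, temperature, radiation, flags, p)
  k1 <- f(y)
  k2 <- f(y + h / 2 * k1)
  k3 <- f(y + h / 2 * k2)
  k4 <- f(y + h * k3)
  ynew <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(ynew))) {
    bad <- which(!is.finite(ynew))[1]
    lab <- if (bad <= L) paste0("layer ", bad) else
      c("flower", "roots", "old_rhizome", "new_rhizome",
        ACC_NAMES)[bad - L]
    stop("non-finite state after RK4 update in compartment ", lab)
  }
  pools <- seq_len(L + 4L)
  clamp <- -sum(pmin(ynew[pools], 0))
  ynew[pools] <- pmax(ynew[pools], 0)
  list(y = ynew, clamp = clamp)
}

#' Advance the plant state by one day (classical RK4)
#'
#' Fourth-order Runge--Kutta update of all compartments with a step of one
#' day (or an explicit sub-step `h` for step-halving checks). Pools driven
#' below zero are clamped at zero and the clamped deficit is reported.
#'
#' @inheritParams derivatives
#' @param h step length in days (default 1).
#' @return A list with the updated `state` (a [reed_state()]; layer ages are
#'   not advanced -- the caller owns age bookkeeping), `clamp` (biomass
#'   added by clamping, g DM m-2) and `fluxes` (the RK4-integrated totals of
#'   gross photosynthesis, respiration, mortality and translocation over the
#'   step).
#' @export
rk4_step <- function(state, day, forcing, params, schedule, h = 1) {
  flags <- active_processes(day, schedule)
  layers <- state$layers
  ages <- state$ages
  headroom <- 10L
  layers <- c(layers, numeric(headroom))
  ages <- c(ages, numeric(headroom))
  L <- length(layers)
  y <- new_state_vector(layers, state$flower, state$roots,
                        state$old_rhizome, state$new_rhizome)
  res <- rk4_update(y, L, ages, forcing$temperature, forcing$radiation,
                    flags, params, h)
  ynew <- res$y
  acc <- ynew[(L + 5L):(L + 4L + N_ACC)]
  names(acc) <- ACC_NAMES
  b <- remap_elongation(ynew[seq_len(L)], acc[["allocation"]], params)
  keep <- max(c(0L, which(b > 1e-12)))
  b <- b[seq_len(keep)]
  ages_out <- c(ages, numeric(max(0L, keep - length(ages))))[seq_len(keep)]
  st <- reed_state(layers = b, ages = ages_out,
                   flower = ynew[L + 1L], roots = ynew[L + 2L],
                   old_rhizome = ynew[L + 3L], new_rhizome = ynew[L + 4L])
  list(state = st, clamp = res$clamp, fluxes = acc)
}

#' Simulate one full growth season
#'
#' Integrates the growth model over Julian days 1--365 at a one-day RK4
#' step. The initial state has zero above-ground biomass and the whole
#' initial below-ground biomass `bgb_init` in old rhizomes (the stand is
#' harvested every year, so the season starts from bare ground). On
#' `t_harvest` all remaining above-ground biomass is removed as a controlled
#' harvest, recorded separately from mortality.
#'
#' @param params a [reed_params()].
#' @param schedule a [phenology_schedule()].
#' @param forcing a data frame with columns `day` (1--365), `temperature`
#'   and `radiation`, e.g. from [synth_forcing()].
#' @param substeps number of equal RK4 sub-steps per day (default 1, the
#'   model's nominal one-day step); larger values serve as a step-halving
#'   check of the integrator while keeping the daily elongation and age
#'   bookkeeping unchanged.
#' @return A `reed_trajectory`: a data frame with one row per day holding the
#'   five pools, `agb`, `bgb`, `height` (cm), the daily flux totals
#'   (`gross_photosynthesis`, `respiration_above/below`,
#'   `mortality_above/below`, `translocation_up/down`,
#'   `senescence_transfer`), `harvested` and `clamp_adjust` (biomass added
#'   by clamping pools at zero). The initial state is attached as attribute
#'   `initial`, the inputs as attributes `params` and `schedule`.
#' @examples
#' traj <- integrate_season(reed_params(), phenology_schedule(), hwnr_forcing())
#' max(traj$agb)
#' @export
integrate_season <- function(params, schedule, forcing, substeps = 1L) {
  stopifnot(inherits(params, "reed_params"),
            inherits(schedule, "phenology_schedule"),
            substeps >= 1)
  need <- c("day", "temperature", "radiation")
  if (!all(need %in% names(forcing))) {
    stop("forcing must have columns ", paste(need, collapse = ", "))
  }
  if (!identical(as.integer(forcing$day), 1:365)) {
    stop("forcing must cover days 1..365 without gaps")
  }
  temperature <- forcing$temperature
  radiation <- forcing$radiation

  layers <- numeric(0)
  ages <- numeric(0)
  flower <- 0
  roots <- 0
  old <- params$bgb_init
  newr <- 0
  acc_prev <- numeric(N_ACC)

  out <- matrix(0, nrow = 365, ncol = 19)
  colnames(out) <- c("day", "shoot", "flower", "roots", "old_rhizome",
                     "new_rhizome", "agb", "bgb", "height",
                     "gross_photosynthesis", "respiration_above",
                     "respiration_below", "mortality_above",
                     "mortality_below", "translocation_up",
                     "translocation_down", "senescence_transfer",
                     "harvested", "clamp_adjust")

  headroom <- 10L
  for (d in 1:365) {
    flags <- active_processes(d, schedule)
    L <- length(layers) + headroom
    y <- new_state_vector(c(layers, numeric(headroom)),
                          flower, roots, old, newr)
    y[(L + 5L):(L + 4L + N_ACC)] <- acc_prev
    clamp_day <- 0
    ynew <- y
    for (ss in seq_len(substeps)) {
      res <- rk4_update(ynew, L, c(ages, numeric(headroom)),
                        temperature[d], radiation[d], flags, params,
                        h = 1 / substeps)
      ynew <- res$y
      clamp_day <- clamp_day + res$clamp
    }
    acc <- ynew[(L + 5L):(L + 4L + N_ACC)]
    day_alloc <- acc[N_ACC] - acc_prev[N_ACC]
    b <- remap_elongation(ynew[seq_len(L)], day_alloc, params)
    keep <- max(c(0L, which(b > 1e-12)))
    layers <- b[seq_len(keep)]
    ages <- c(ages, numeric(max(0L, keep - length(ages))))[seq_len(keep)] + 1
    flower <- ynew[L + 1L]
    roots <- ynew[L + 2L]
    old <- ynew[L + 3L]
    newr <- ynew[L + 4L]
    daily <- (acc - acc_prev)[1:8]
    acc_prev <- acc

    harvested <- 0
    if (d == schedule$t_harvest) {
      harvested <- sum(layers) + flower
      layers <- numeric(0)
      ages <- numeric(0)
      flower <- 0
    }
    out[d, ] <- c(d, sum(layers), flower, roots, old, newr,
                  sum(layers) + flower, roots + old + newr,
                  length(layers), daily, harvested, clamp_day)
  }
  traj <- as.data.frame(out)
  traj$day <- as.integer(traj$day)
  attr(traj, "initial") <- list(agb = 0, bgb = params$bgb_init,
                                shoot = 0, flower = 0, roots = 0,
                                old_rhizome = params$bgb_init,
                                new_rhizome = 0)
  attr(traj, "params") <- params
  attr(traj, "schedule") <- schedule
  class(traj) <- c("reed_trajectory", "data.frame")
  traj
}

#' @export
print.reed_trajectory <- function(x, ...) {
  cat("Reed growth trajectory (365 days)\n")
  cat(sprintf("  peak AGB %.1f g m-2 on day %d; max BGB %.1f g m-2 on day %d\n",
              max(x$agb), x$day[which.max(x$agb)],
              max(x$bgb), x$day[which.max(x$bgb)]))
  invisible(x)
}

#' Select the initial below-ground biomass by least mean square error
#'
#' Runs one season per candidate initial below-ground biomass and returns
#' the candidate whose simulated above-ground biomass best matches the dated
#' observations (least mean squared error); ties go to the smaller
#' candidate.
#'
#' @param candidates candidate initial BGB values (g DM m-2).
#' @param observations data frame with columns `day` and `agb`.
#' @param params,schedule,forcing as in [integrate_season()].
#' @return A list with `bgb_init` (the selected candidate) and `mse` (named
#'   vector of the mean squared errors of all candidates).
#' @export
find_initial_bgb <- function(candidates, observations, params, schedule,
                             forcing) {
  if (length(candidates) < 1) stop("need at least one candidate")
  if (nrow(observations) < 1) stop("need at least one observation")
  candidates <- sort(candidates)
  mse <- vapply(candidates, function(b0) {
    p <- params
    p$bgb_init <- b0
    traj <- integrate_season(p, schedule, forcing)
    sim <- traj$agb[match(observations$day, traj$day)]
    mean((sim - observations$agb)^2)
  }, numeric(1))
  names(mse) <- as.character(candidates)
  list(bgb_init = candidates[which.min(mse)], mse = mse)
}
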