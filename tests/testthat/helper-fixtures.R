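# Shared fixtures: the calibrated baseline and small random perturbations.

baseline_schedule <- phenology_schedule()
baseline_forcing <- hwnr_forcing()

baseline_trajectory <- local({
  traj <- NULL
  function() {
    if (is.null(traj)) {
      traj <<- integrate_season(reed_params(), baseline_schedule,
                                baseline_forcing)
    }
    traj
  }
})

# A random but physically sensible parameter draw: every rate jittered
# around the calibrated default.
draw_params <- function(rng_factor = 0.4) {
  d <- reed_params()
  jitter <- function(x) x * stats::runif(1, 1 - rng_factor, 1 + rng_factor)
  reed_params(
    p_max = jitter(d$p_max), i_half = jitter(d$i_half),
    k_ext = jitter(d$k_ext), t_opt = d$t_opt + stats::runif(1, -2, 2),
    t_width = jitter(d$t_width), a_half = jitter(d$a_half),
    k_np = jitter(d$k_np), q10 = jitter(d$q10),
    r_above = jitter(d$r_above), r_below = jitter(d$r_below),
    m_shoot = jitter(d$m_shoot), m_root = jitter(d$m_root),
    m_rhizome = jitter(d$m_rhizome),
    m_shoot_senescent = jitter(d$m_shoot_senescent),
    f_up = jitter(d$f_up), r_mobilization = jitter(d$r_mobilization),
    f_up_root = min(jitter(d$f_up_root), 1),
    f_shoot_to_rhizome = min(jitter(d$f_shoot_to_rhizome), 1),
    f_flower = min(jitter(d$f_flower), 1),
    f_senescence_transfer = min(jitter(d$f_senescence_transfer), 1),
    f_elong = min(jitter(d$f_elong), 1),
    shoot_density = jitter(d$shoot_density),
    bgb_init = jitter(d$bgb_init)
  )
}

# Daily whole-plant mass-balance residual of a trajectory, relative to the
# pool sizes: dB_t - (P_t - R_t - M_t) should vanish up to clamping and the
# recorded harvest removal.
mass_balance_residual <- function(traj) {
  init <- attr(traj, "initial")
  b <- traj$agb + traj$bgb
  db <- diff(c(init$agb + init$bgb, b)) + traj$harvested
  flux <- traj$gross_photosynthesis -
    traj$respiration_above - traj$respiration_below -
    traj$mortality_above - traj$mortality_below + traj$clamp_adjust
  max(abs(db - flux) / pmax(b, 1))
}

# Minimal hand-made trajectory for the carbon accounting tests.
make_fake_traj <- function(agb, bgb, m_above = 0, m_below = 0,
                           harvested = NULL, agb0 = agb[1], bgb0 = bgb[1]) {
  n <- length(agb)
  if (is.null(harvested)) harvested <- numeric(n)
  tr <- data.frame(day = seq_len(n), agb = agb, bgb = bgb,
                   mortality_above = rep_len(m_above, n),
                   mortality_below = rep_len(m_below, n),
                   harvested = harvested)
  attr(tr, "initial") <- list(agb = agb0, bgb = bgb0)
  class(tr) <- c("reed_trajectory", "data.frame")
  tr
}
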