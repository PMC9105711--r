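#' One-at-a-time parameter sensitivity
#'
#' Re-runs the seasonal simulation with one parameter at a time scaled by
#' `1 + fraction` (default +/-50%) and reports the percent change of a
#' scalar metric relative to the unperturbed baseline. The default metric is
#' the above-ground biomass on the day shoot senescence starts (`t_s`), the
#' quantity conventionally used to rank parameter influence in this model
#' family.
#'
#' @param base_params a [reed_params()] baseline.
#' @param param_names character vector of parameter names to perturb.
#' @param schedule a [phenology_schedule()].
#' @param forcing a 365-day forcing data frame.
#' @param fractions relative perturbations (e.g. `c(-0.5, 0.5)`).
#' @param metric function of a `reed_trajectory` returning one number;
#'   default `AGB` on day `t_s`.
#' @return A data frame with columns `parameter`, `fraction`, `metric` and
#'   `pct_change`; the first row is the baseline (fraction 0, change 0).
#' @export
sensitivity_oat <- function(base_params, param_names, schedule, forcing,
                            fractions = c(-0.5, 0.5), metric = NULL) {
  unknown <- setdiff(param_names, names(base_params))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(metric)) {
    metric <- function(traj) traj$agb[traj$day == schedule$t_s]
  }
  base_val <- metric(integrate_season(base_params, schedule, forcing))
  rows <- list(data.frame(parameter = "baseline", fraction = 0,
                          metric = base_val, pct_change = 0))
  for (nm in param_names) {
    for (fr in fractions) {
      p <- base_params
      p[[nm]] <- p[[nm]] * (1 + fr)
      validate_params(p)
      val <- metric(integrate_season(p, schedule, forcing))
      rows[[length(rows) + 1]] <- data.frame(
        parameter = nm, fraction = fr, metric = val,
        pct_change = 100 * (val - base_val) / base_val)
    }
  }
  do.call(rbind, rows)
}

#' Goodness of fit (coefficient of determination)
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about
#' the observed mean.
#'
#' @param predicted,observed numeric vectors of equal length (>= 2).
#' @return R-squared (1 for a perfect fit; can be negative for fits worse
#'   than the observed mean).
#' @export
goodness_of_fit <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2) {
    stop("predicted and observed must have equal length >= 2")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Deterministic coordinate-wise grid calibration
#'
#' Formalizes trial-and-error tuning as a reproducible procedure: for each
#' free parameter in the given order, the bounded interval is scanned on a
#' regular grid, the value minimizing the sum of squared residuals (SSR)
#' between simulated above-ground biomass on the observation days and the
#' observed values is fixed, and the scan proceeds to the next parameter;
#' the whole cycle is repeated for `sweeps` full sweeps. The SSR never
#' increases between sweeps.
#'
#' @param free_params named list of `c(lower, upper)` bounds; names are
#'   [reed_params()] fields, scanned in list order (put the most sensitive
#'   parameter first).
#' @param observations data frame with columns `day` and `agb`.
#' @param base_params a [reed_params()] with starting values for all other
#'   parameters.
#' @param schedule a [phenology_schedule()].
#' @param forcing a 365-day forcing data frame.
#' @param n_grid grid points per scan (default 21).
#' @param sweeps full coordinate sweeps (default 2).
#' @return A list with `params` (fitted [reed_params()]), `ssr` (final sum
#'   of squared residuals), `estimates` (named vector of fitted values) and
#'   `trace` (data frame of the SSR after each parameter scan).
#' @export
calibrate <- function(free_params, observations, base_params, schedule,
                      forcing, n_grid = 21, sweeps = 2) {
  if (!length(free_params)) stop("need at least one free parameter")
  if (is.null(names(free_params)) || any(!nzchar(names(free_params)))) {
    stop("free_params must be a named list of bounds")
  }
  unknown <- setdiff(names(free_params), names(base_params))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(observations) < 2) stop("need at least 2 observations")
  for (nm in names(free_params)) {
    b <- free_params[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2]) {
      stop("bounds for '", nm, "' must be finite c(lower, upper)")
    }
  }
  ssr_of <- function(p) {
    traj <- integrate_season(p, schedule, forcing)
    sim <- traj$agb[match(observations$day, traj$day)]
    sum((sim - observations$agb)^2)
  }
  p <- base_params
  trace <- list()
  ssr <- ssr_of(p)
  for (sweep in seq_len(sweeps)) {
    for (nm in names(free_params)) {
      grid <- seq(free_params[[nm]][1], free_params[[nm]][2],
                  length.out = n_grid)
      vals <- vapply(grid, function(g) {
        q <- p
        q[[nm]] <- g
        ssr_of(q)
      }, numeric(1))
      best <- grid[which.min(vals)]  # first minimum = smallest value on ties
      if (min(vals) <= ssr) {
        p[[nm]] <- best
        ssr <- min(vals)
      }
      trace[[length(trace) + 1]] <- data.frame(
        sweep = sweep, parameter = nm, value = p[[nm]], ssr = ssr)
    }
  }
  est <- vapply(names(free_params), function(nm) p[[nm]], numeric(1))
  list(params = p, ssr = ssr, estimates = est, trace = do.call(rbind, trace))
}

#' Nutrient-availability scenario experiments
#'
#' Re-runs the full season and carbon ledger with the nutrient-availability
#' constant `k_np` scaled by each multiplier, and reports annual carbon
#' sequestration (total and its living-above / living-below / mortality
#' decomposition), seasonal biomass maxima, and the percent change of the
#' annual total relative to the multiplier-1 baseline. The procedure is a
#' pure function of its inputs: repeated calls are bit-identical.
#'
#' @param base_params a [reed_params()] with the calibrated baseline `k_np`.
#' @param schedule a [phenology_schedule()].
#' @param forcing a 365-day forcing data frame.
#' @param multipliers positive scaling factors applied to `k_np`; the
#'   default brackets the baseline by -50%, -25%, +25% and +50%.
#' @param c_per_dm carbon conversion factor (see [carbon_ledger()]).
#' @return A data frame with one row per multiplier: `multiplier`, `k_np`,
#'   `annual_carbon`, `carbon_living_above`, `carbon_living_below`,
#'   `carbon_mortality`, `max_agb`, `max_bgb`, `pct_change`. The trajectories
#'   are attached as attribute `trajectories`.
#' @export
scenario_knp <- function(base_params, schedule, forcing,
                         multipliers = c(0.5, 0.75, 1, 1.25, 1.5),
                         c_per_dm = 0.44) {
  if (any(multipliers <= 0)) stop("multipliers must be > 0")
  if (!any(multipliers == 1)) multipliers <- sort(c(1, multipliers))
  runs <- lapply(multipliers, function(m) {
    p <- base_params
    p$k_np <- p$k_np * m
    traj <- integrate_season(p, schedule, forcing)
    led <- carbon_ledger(traj, c_per_dm = c_per_dm)
    list(traj = traj, led = led, m = m)
  })
  annual <- vapply(runs, function(r) r$led$annual$total, numeric(1))
  base <- annual[multipliers == 1][1]
  out <- data.frame(
    multiplier = multipliers,
    k_np = base_params$k_np * multipliers,
    annual_carbon = annual,
    carbon_living_above = vapply(runs, function(r) r$led$annual$living_above,
                                 numeric(1)),
    carbon_living_below = vapply(runs, function(r) r$led$annual$living_below,
                                 numeric(1)),
    carbon_mortality = vapply(runs, function(r) r$led$annual$mortality,
                              numeric(1)),
    max_agb = vapply(runs, function(r) max(r$traj$agb), numeric(1)),
    max_bgb = vapply(runs, function(r) max(r$traj$bgb), numeric(1)),
    pct_change = 100 * (annual - base) / base
  )
  attr(out, "trajectories") <- lapply(runs, `[[`, "traj")
  out
}
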