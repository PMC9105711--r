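#' Stoichiometric conversion factors from dry matter to CO2 and carbon
#'
#' Photosynthesis fixes carbon as carbohydrate; on a starch basis the
#' repeating monomer is C6H10O5, so per gram of dry organic matter the plant
#' has fixed `6 M(CO2) / M(C6H10O5)` grams of CO2 and
#' `6 M(C) / M(C6H10O5)` grams of carbon. Computed from standard atomic
#' weights (C 12.011, H 1.008, O 15.999), giving approximately 1.629 and
#' 0.444 -- conventionally quoted to two decimals as 1.62 and 0.44; the
#' carbon pipeline uses the conventional 0.44 by default (see
#' [carbon_ledger()]).
#'
#' @return A list with `co2_per_dm` and `c_per_dm` (g per g dry matter).
#' @examples
#' stoichiometric_factors()$c_per_dm  # ~0.444
#' @export
stoichiometric_factors <- function() {
  w_c <- 12.011
  w_h <- 1.008
  w_o <- 15.999
  monomer <- 6 * w_c + 10 * w_h + 5 * w_o     # starch monomer C6H10O5
  co2 <- w_c + 2 * w_o
  list(co2_per_dm = 6 * co2 / monomer,
       c_per_dm = 6 * w_c / monomer)
}

#' Daily net primary production from a simulated trajectory
#'
#' `NPP_t = (B_t - B_{t-1}) + M_t`, the day-to-day change in living biomass
#' plus the day's mortality, computed separately for the above- and
#' below-ground parts. Day 1 uses the initial state as `B_0`. Biomass
#' removed by the controlled harvest is added back to the harvest day's
#' `delta B` (harvest is removal, not mortality, and must not appear as a
#' negative production spike).
#'
#' @param trajectory a `reed_trajectory` from [integrate_season()].
#' @return A data frame with columns `day`, `npp_above`, `npp_below`,
#'   `npp_total`, `delta_b_above`, `delta_b_below`, `mortality_above`,
#'   `mortality_below` (all g DM m-2 d-1).
#' @export
daily_npp <- function(trajectory) {
  if (nrow(trajectory) < 2) stop("trajectory must cover at least 2 days")
  if (!identical(as.integer(trajectory$day), seq_len(nrow(trajectory)))) {
    stop("trajectory days must be 1..n without gaps")
  }
  init <- attr(trajectory, "initial")
  d_above <- diff(c(init$agb, trajectory$agb))
  # on the harvest day, compare the pre-harvest standing crop
  d_above <- d_above + trajectory$harvested
  d_below <- diff(c(init$bgb, trajectory$bgb))
  data.frame(day = trajectory$day,
             npp_above = d_above + trajectory$mortality_above,
             npp_below = d_below + trajectory$mortality_below,
             npp_total = d_above + d_below +
               trajectory$mortality_above + trajectory$mortality_below,
             delta_b_above = d_above,
             delta_b_below = d_below,
             mortality_above = trajectory$mortality_above,
             mortality_below = trajectory$mortality_below)
}

#' Convert an NPP series to carbon
#'
#' Elementwise multiplication by the carbon content of dry matter; the sign
#' is preserved, so days with negative net production yield negative carbon
#' sequestration.
#'
#' @param npp_series numeric vector of NPP (g DM m-2 d-1).
#' @param c_per_dm grams of carbon fixed per gram of dry matter; the
#'   conventional 0.44 by default, or `stoichiometric_factors()$c_per_dm`
#'   for the exact value.
#' @return Carbon series (gC m-2 d-1).
#' @export
npp_to_carbon <- function(npp_series, c_per_dm = 0.44) {
  if (c_per_dm <= 0) stop("c_per_dm must be > 0")
  npp_series * c_per_dm
}

#' Aggregate a daily series into calendar months and the year
#'
#' Sums a 365-value daily series over non-leap calendar months and over the
#' whole year.
#'
#' @param daily_series numeric vector of length 365 (Julian days 1--365).
#' @return A list with `monthly` (named numeric, Jan..Dec) and `annual`.
#' @export
aggregate_carbon <- function(daily_series) {
  if (length(daily_series) != 365) {
    stop("daily series must have 365 values, got ", length(daily_series))
  }
  mlen <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  month <- rep(seq_len(12), mlen)
  monthly <- tapply(daily_series, month, sum)
  monthly <- stats::setNames(as.numeric(monthly), month.abb)
  list(monthly = monthly, annual = sum(daily_series))
}

#' Total annual carbon stock of a site
#'
#' Scales the annual per-area carbon sequestration to the stand's
#' distribution area: `gC m-2 yr-1 x ha x 10^4 m2/ha / 10^6 g/t`.
#'
#' @param annual_per_area annual carbon sequestration (gC m-2 yr-1).
#' @param area_ha stand area in hectares.
#' @return Total annual sequestration in tonnes of carbon (tC yr-1).
#' @examples
#' total_stock(2040.73, 86.58)  # ~1766.86
#' @export
total_stock <- function(annual_per_area, area_ha) {
  if (area_ha < 0) stop("area must be >= 0")
  annual_per_area * area_ha / 100
}

#' Full carbon ledger of a simulated season
#'
#' Converts a growth trajectory into the complete carbon account: daily NPP
#' and carbon by part, monthly and annual aggregates, the living/mortality
#' decomposition, and (when an area is given) the site total stock.
#'
#' The "parts" follow the accounting of the source model family: the daily
#' above- and below-ground series are `(delta B + M) * c_per_dm` per part,
#' while the annual decomposition splits the same total into living
#' above-ground (`sum delta B_above`), living below-ground
#' (`sum delta B_below`) and mortality (`sum M`) contributions.
#'
#' @param trajectory a `reed_trajectory`.
#' @param c_per_dm carbon per gram dry matter (default the conventional
#'   0.44; use `stoichiometric_factors()$c_per_dm` for exact stoichiometry).
#' @param area_ha optional stand area (ha) for the site total.
#' @return An object of class `carbon_ledger`: list with `daily` (data
#'   frame: day, npp columns, `carbon_above`, `carbon_below`,
#'   `carbon_total`), `monthly` (data frame with above/below/total columns),
#'   `annual` (named list: `total`, `above`, `below`, `living_above`,
#'   `living_below`, `mortality`), `total_stock_tc` (or `NA`) and
#'   `c_per_dm`.
#' @export
carbon_ledger <- function(trajectory, c_per_dm = 0.44, area_ha = NA_real_) {
  npp <- daily_npp(trajectory)
  daily <- data.frame(
    day = npp$day,
    npp_above = npp$npp_above,
    npp_below = npp$npp_below,
    npp_total = npp$npp_total,
    carbon_above = npp_to_carbon(npp$npp_above, c_per_dm),
    carbon_below = npp_to_carbon(npp$npp_below, c_per_dm),
    carbon_mortality = npp_to_carbon(npp$mortality_above +
                                       npp$mortality_below, c_per_dm)
  )
  daily$carbon_total <- daily$carbon_above + daily$carbon_below
  agg_a <- aggregate_carbon(daily$carbon_above)
  agg_b <- aggregate_carbon(daily$carbon_below)
  agg_t <- aggregate_carbon(daily$carbon_total)
  monthly <- data.frame(month = month.abb,
                        carbon_above = agg_a$monthly,
                        carbon_below = agg_b$monthly,
                        carbon_total = agg_t$monthly,
                        row.names = NULL)
  annual <- list(
    total = agg_t$annual,
    above = agg_a$annual,
    below = agg_b$annual,
    living_above = sum(npp$delta_b_above) * c_per_dm,
    living_below = sum(npp$delta_b_below) * c_per_dm,
    mortality = sum(npp$mortality_above + npp$mortality_below) * c_per_dm
  )
  structure(list(daily = daily, monthly = monthly, annual = annual,
                 total_stock_tc = if (is.na(area_ha)) NA_real_ else
                   total_stock(annual$total, area_ha),
                 c_per_dm = c_per_dm, area_ha = area_ha),
            class = "carbon_ledger")
}

#' @export
print.carbon_ledger <- function(x, ...) {
  cat("Carbon ledger\n")
  cat(sprintf("  annual: %.2f gC m-2 yr-1 (above %.2f, below %.2f)\n",
              x$annual$total, x$annual$above, x$annual$below))
  peak <- which.max(x$monthly$carbon_total)
  cat(sprintf("  peak month: %s (%.1f gC m-2)\n",
              x$monthly$month[peak], x$monthly$carbon_total[peak]))
  if (!is.na(x$total_stock_tc)) {
    cat(sprintf("  site total: %.2f tC yr-1 over %.2f ha\n",
                x$total_stock_tc, x$area_ha))
  }
  invisible(x)
}
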