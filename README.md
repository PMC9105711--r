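# reedcarbon

Growth dynamics and carbon sequestration of common reed (*Phragmites
australis*) stands.

Common reed is a dominant emergent macrophyte of temperate wetlands and a
substantial carbon sink: it assimilates carbon through photosynthesis over
an annual growth cycle, stores part of it below ground in rhizomes, and in
managed urban wetlands the above-ground crop is harvested each autumn.
`reedcarbon` is for wetland ecologists and carbon-accounting practitioners
who want to (i) simulate the seasonal biomass dynamics of a reed stand,
(ii) convert simulated production into daily / monthly / annual carbon
sequestration and a site total, (iii) calibrate the simulator against
sparse biomass observations such as satellite retrievals, and (iv) run the
standard remote-sensing arithmetic around those retrievals.

## The model

The stand is five biomass pools *B* (g DM m⁻²) — shoots resolved into 1 cm
canopy layers, inflorescence, roots, old rhizomes, new rhizomes — each
obeying the daily budget

> d*B*/d*t* = *P* − *R* − *M* + *Tr*

(gross photosynthesis, respiration, mortality, inter-organ translocation),
integrated by fourth-order Runge–Kutta at a one-day step over a 365-day
year. Light attenuates through the canopy by Beer–Lambert over the biomass
above each layer; layer production saturates with light (*I*/(*I* +
*I*₅₀)), follows a Gaussian temperature response, declines with tissue age,
and scales with nutrient availability as *K*<sub>NP</sub><sup>0.25</sup>.
Six phenological switch points (reserve mobilization, growth start,
mobilization end, new-rhizome formation, panicle appearance, senescence)
plus a harvest day govern which fluxes are active. Daily net primary
production is NPP<sub>t</sub> = Δ*B*<sub>t</sub> + *M*<sub>t</sub>,
converted to carbon at 0.44 gC per g dry matter and aggregated to months,
the year and the site (area × annual per-area carbon).

The retrieval stage maps multi-band surface reflectance to above-ground
biomass with the empirical line AGB = −15.859 *x* + 4.8574, where *x* is
the maximum reflectance in the 510–560 nm window and the line is read in
10³ g m⁻²; it also provides Jeffries–Matusita / transformed-divergence
class separability and overall accuracy / Kappa / producer's / user's
accuracy of a confusion matrix. Synthetic generators (forcing year,
five-class reflectance scenes with known biomass truth, dated biomass
observations) make the whole pipeline runnable and testable without field
or satellite data.

## Worked example

One calibrated season of the Hanshiqiao Wetland Nature Reserve (HWNR)
stand, on the packaged climatological forcing year:

```r
library(reedcarbon)

traj <- integrate_season(reed_params(), phenology_schedule(), hwnr_forcing())
traj
#> Reed growth trajectory (365 days)
#>   peak AGB 2958.1 g m-2 on day 236; max BGB 2494.7 g m-2 on day 330

ledger <- carbon_ledger(traj, area_ha = hwnr_area_ha())
ledger
#> Carbon ledger
#>   annual: 2021.90 gC m-2 yr-1 (above 1560.25, below 461.65)
#>   peak month: Jul (518.8 gC m-2)
#>   site total: 1750.56 tC yr-1 over 86.58 ha
```

The stand peaks at about 2.96 kg m⁻² of above-ground biomass in late
August (day 236), rebuilds its below-ground reserves to about 2.49 kg m⁻²
by the autumn harvest, and sequesters about 2022 gC m⁻² over the year —
roughly 1750 tonnes of carbon across the 86.58 ha stand — with the monthly
maximum (519 gC m⁻²) in July.

Nutrient-availability scenarios re-run the season with the nutrient
constant scaled:

```r
scenario_knp(reed_params(), phenology_schedule(), hwnr_forcing(),
             multipliers = c(0.5, 1, 1.5))[, c("multiplier", "annual_carbon",
                                               "max_agb", "pct_change")]
#>   multiplier annual_carbon max_agb pct_change
#> 1        0.5       1602.63 2500.56     -20.74
#> 2        1.0       2021.90 2958.08       0.00
#> 3        1.5       2308.75 3270.05      14.19
```

Halving nutrient availability costs about 21% of the annual carbon
sequestration; a 50% enrichment adds about 14% — eutrophication management
and carbon storage trade off asymmetrically.

Calibration against dated biomass observations (here: synthetic
observations from a known truth) is a deterministic coordinate grid
search:

```r
obs <- synth_agb_observations(reed_params(), phenology_schedule(),
                              hwnr_forcing())
fit <- calibrate(list(p_max = c(0.15, 0.25)), obs, reed_params(),
                 phenology_schedule(), hwnr_forcing())
fit$estimates
#>  p_max
#>  0.197
```

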