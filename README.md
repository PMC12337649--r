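# icepools

Estimation of intracellular nutrient pools in bottom-ice algal communities.

## The problem

Pennate diatoms dominating the bottommost centimetres of Arctic first-year
sea ice live in brine whose salinity is set by the ice temperature
(S<sub>b</sub> = 1000·(1 − 54.11/T)<sup>−1</sup>, about 32–53 in the bloom
season). Standard "bulk" melt of an ice core dilutes that brine to
salinities below 12, osmotically shocking the cells and releasing whatever
nutrients they store internally — so a bulk nutrient measurement mixes the
ambient dissolved pool with an intracellular (IC) one. `icepools` implements
the estimation chain that separates the two, for nitrate+nitrite (N) and
silicic acid (Si):

1. **Scrape protocol** — cells scraped into cold filtered seawater (FSW),
   filtered, and their IC pool extracted with hot water. Blank-corrected
   filtrate concentration × extraction volume ÷ chl *a* mass on the filter
   gives the chl-specific pool IC-N^B, IC-Si^B (µmol (mg chl *a*)⁻¹).
2. **FSW-diluted core melt** — bottom 3 cm melted into FSW; chl *a*, cell
   abundance and biovolume, corrected for the FSW dilution. Multiplying
   IC^B by the bottom-ice chl *a* concentration gives a melt-volume-corrected
   bottom-ice IC concentration (µmol L⁻¹ of melted ice), and dividing by
   biovolume or abundance gives the IC concentration per cell volume
   (mmol L⁻¹) and content per cell (fmol cell⁻¹).
3. **Bulk melt** — nutrients measured on undiluted core melt. Regressing
   bulk concentrations on the *independently estimated* bottom-ice IC
   concentrations with standardized major axis (SMA) regression — both axes
   carry error — estimates the fraction of the IC pool released during melt
   processing: a slope near 1 means full release (N); a slope near 1/11
   means the pool largely stays in the cells (Si).

A time-series stage fits linear trends of chl *a* and the IC pools on
site-averaged series, correlates the detrended residuals against daily
maximum under-ice current speed (the spring–neap tidal cycle pulses the
nutrient flux to the ice bottom) at lags of 0 and 1 sampling cycles, and
fits the log-linear decay of the IC N:Si ratio.

Because the package is meant to be verifiable without any field download, it
ships a synthetic campaign generator (`sim_config()`, `simulate_campaign()`)
that emulates a declining spring bloom, the two-constituent semidiurnal
current with its ~14.8-day spring–neap beat, tidal coupling of the IC pools,
and all three observation protocols with configurable retention fractions
and measurement noise — with ground truth recorded for parameter-recovery
tests.

## Worked example

```r
library(icepools)
camp <- simulate_campaign(sim_config(seed = 1))  # default 2012-style campaign
an   <- analyze_campaign(camp)

print(an$retention$sma_n)
#> SMA fit (n = 36): slope = 0.9261, intercept = 1.484, r^2 = 0.868, p = 1.58e-16 [significant]
print(an$retention$sma_si)
#> SMA fit (n = 36): slope = 0.08346, intercept = 0.6692, r^2 = 0.744, p = 1.39e-11 [significant]
```

The SMA slope of bulk N on bottom-ice IC-N is 0.926 — the generator's true
release fraction is 1 (full release on melt) — and the reciprocal Si slope
is 1/0.0835 ≈ 12.0 against a true value of 11: bulk melt sees essentially
all of the stored N but only ~1/11 of the stored Si, which is why bulk-melt
N:Si ratios overstate the ratio available to the cells.

```r
print(an$temporal$trend_icb_n)
#> OLS fit (n = 12): slope = -0.1598, intercept = 15.82, r^2 = 0.926, p = 5.63e-07 [significant]
print(an$temporal$trend_icb_si)
#> OLS fit (n = 12): slope = 0.9146, intercept = 38.7, r^2 = 0.894, p = 3.49e-06 [significant]
cat(sprintf("ln(N:Si) decay rate: %.4f per day\n", an$temporal$n_si_decay$rate))
#> ln(N:Si) decay rate: -0.0286 per day
head(an$summary, 3)
#>             quantity     mean        sd  n
#> 1         chla_areal 54.24372 28.863036 36
#> 2  ic_chl_specific_n 12.78089  2.238896 36
#> 3 ic_chl_specific_si 56.07986 12.499444 36
```

The opposing trends (IC-N^B declining, IC-Si^B rising) drive the
exponential decay of the IC N:Si ratio; season means (e.g. chl-specific
IC-N of 12.8 ± 2.2 µmol mg⁻¹) sit at the scales the generator is
calibrated to. `write_report(an, "analysis")` serializes every statistic to
auditable CSVs plus a plain-text summary.

A thin command-line front end is included:

```sh
Rscript inst/scripts/icepools-cli.R simulate --seed 5 --out camp
Rscript inst/scripts/icepools-cli.R analyze  --campaign camp --out ana
Rscript inst/scripts/icepools-cli.R report   --analysis ana
```

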