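#' Configuration for a synthetic ice-algal field campaign
#'
#' Builds and validates the parameter set for the campaign generator. The
#' defaults emulate a declining Arctic spring ice-algal bloom sampled every
#' 3-4 days at three snow-depth sites over six weeks: bottom-ice chl a
#' declines linearly, the chl-specific intracellular (IC) nitrate+nitrite
#' pool declines while the IC silicic acid pool rises, a semidiurnal
#' under-ice current with spring-neap (fortnightly) modulation forces
#' oscillations in the IC pools, and three observation protocols (scrape,
#' FSW-diluted core melt, bulk melt) observe the same true state with
#' differential release of the IC pools on bulk melt: N is fully released
#' (retention 1) while only ~1/11 of the Si pool escapes the cells.
#'
#' Scale defaults follow the 2012-style season: water-column NO3+NO2 and
#' Si(OH)4 of 7.67 and 14.7 umol L^-1 at salinity 32, season-mean
#' chl-specific IC pools near 12.8 and 60 umol (mg chl a)^-1, and a
#' community mean cell volume of 1890 um^3.
#'
#' @param seed Integer RNG seed; the whole campaign is reproducible from it.
#' @param n_days Campaign length in days (default 42).
#' @param sampling_pattern Day steps between sampling events, recycled
#'   (default \code{c(3, 4)} for the 3-4 day field rhythm).
#' @param sites Site labels, one per snow class (default thin/medium/thick).
#' @param site_chla_factor Multiplicative chl a factor per site (thick snow
#'   shades the bottom-ice community; default 1.3, 1.0, 0.7).
#' @param a_m2,a_s2 Amplitudes (m s^-1) of the lunar (12.42 h) and solar
#'   (12.00 h) semidiurnal current constituents; their beat gives the
#'   ~14.8-day spring-neap envelope.
#' @param current_noise Hourly additive current noise sd, m s^-1.
#' @param chla0 Initial areal bottom-ice chl a, mg m^-2.
#' @param chla_decline_rate Linear decline, mg m^-2 day^-1.
#' @param icN0,icN_trend Initial chl-specific IC-N (umol (mg chl a)^-1) and
#'   its per-day trend (negative: the N pool declines).
#' @param icSi0,icSi_trend Initial chl-specific IC-Si and its per-day trend
#'   (positive: the Si pool builds as growth slows).
#' @param trend_mode \code{"linear"} (trends are absolute slopes per day) or
#'   \code{"exponential"} (trends are relative rates per day, giving exactly
#'   log-linear N:Si decay).
#' @param coupling_r Target correlation between detrended IC residuals and
#'   the daily maximum current (0 disables tidal coupling).
#' @param retention_N,retention_Si Fractions of the bottom-ice IC pools
#'   released into solution during bulk melt (defaults 1 and 1/11).
#' @param water_column_N,water_column_Si,water_salinity 2-m water-column
#'   reference concentrations (umol L^-1) and practical salinity.
#' @param bulk_salinity_range Range of bulk-melt salinities (uniform draw).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise applied to concentrations and fluorometry. Setting 0
#'   switches the generator to noise-free mode (counting noise off too).
#' @param mean_cell_volume Community mean cell volume, um^3 cell^-1.
#' @param biovolume_jitter_cv Site-day lognormal jitter of true biovolume
#'   about abundance x mean cell volume.
#' @param counted_cells Cells enumerated per counting sample (Poisson
#'   counting noise; >= 400 as in standard settling-chamber protocols).
#' @param cells_per_ug_chla True cell abundance per ug of chl a.
#' @param n_scrape_replicates Scrape cores per site-day (1-3).
#' @param scrape_chla_mass Typical chl a mass on a scrape filter, mg.
#' @param blank_level_N,blank_level_Si Mean daily hot-water blank
#'   concentrations, umol L^-1.
#' @param extraction_volume Hot-water extraction volume, L.
#' @param core_section_length Sampled bottom section length, m.
#' @param core_inner_diameter Corer inner diameter, m.
#' @param n_cores_pooled Cores pooled per chl a melt (1-3).
#' @param fsw_volume_range FSW volume added to the core melt, L (uniform).
#' @param start_date ISO-8601 date of campaign day 0.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_days = 42,
                       sampling_pattern = c(3, 4),
                       sites = c("thin", "medium", "thick"),
                       site_chla_factor = c(1.3, 1.0, 0.7),
                       a_m2 = 0.15, a_s2 = 0.05,
                       current_noise = 0.01,
                       chla0 = 90, chla_decline_rate = 1.9,
                       icN0 = 16, icN_trend = -0.15,
                       icSi0 = 40, icSi_trend = 0.9,
                       trend_mode = c("linear", "exponential"),
                       coupling_r = 0.5,
                       retention_N = 1, retention_Si = 1 / 11,
                       water_column_N = 7.67, water_column_Si = 14.7,
                       water_salinity = 32,
                       bulk_salinity_range = c(4, 12),
                       noise_cv = 0.1,
                       mean_cell_volume = 1890,
                       biovolume_jitter_cv = 0.1,
                       counted_cells = 400L,
                       cells_per_ug_chla = 1.72e5,
                       n_scrape_replicates = 1L,
                       scrape_chla_mass = 0.015,
                       blank_level_N = 0.2, blank_level_Si = 0.3,
                       extraction_volume = 0.040,
                       core_section_length = 0.03,
                       core_inner_diameter = 0.09,
                       n_cores_pooled = 3L,
                       fsw_volume_range = c(1, 2),
                       start_date = "2012-05-19") {
  trend_mode <- match.arg(trend_mode)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$sites) == length(cfg$site_chla_factor))
  if (cfg$retention_N < 0 || cfg$retention_N > 1 ||
      cfg$retention_Si < 0 || cfg$retention_Si > 1) {
    stop("retention fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_cv < 0 || cfg$coupling_r < 0 || cfg$coupling_r >= 1) {
    stop("`noise_cv` must be >= 0 and `coupling_r` in [0, 1)", call. = FALSE)
  }
  positive <- c("n_days", "chla0", "icN0", "icSi0", "water_column_N",
                "water_column_Si", "water_salinity", "mean_cell_volume",
                "cells_per_ug_chla", "scrape_chla_mass", "extraction_volume",
                "core_section_length", "core_inner_diameter", "counted_cells")
  for (nm in positive) {
    if (any(cfg[[nm]] <= 0)) stop(sprintf("`%s` must be positive", nm), call. = FALSE)
  }
  if (!cfg$n_cores_pooled %in% 1:3 || !cfg$n_scrape_replicates %in% 1:3) {
    stop("`n_cores_pooled` and `n_scrape_replicates` must be 1, 2 or 3",
         call. = FALSE)
  }
  # seasonal means must stay positive over the campaign
  end_chla <- cfg$chla0 - cfg$chla_decline_rate * cfg$n_days
  end_n <- trend_value(cfg$icN0, cfg$icN_trend, cfg$n_days, cfg$trend_mode)
  end_si <- trend_value(cfg$icSi0, cfg$icSi_trend, cfg$n_days, cfg$trend_mode)
  if (min(cfg$chla0, end_chla) <= 0 || min(cfg$icN0, end_n) <= 0 ||
      min(cfg$icSi0, end_si) <= 0) {
    stop("trend parameters drive a mean series non-positive within the campaign",
         call. = FALSE)
  }
  invisible(cfg)
}

trend_value <- function(x0, trend, day, mode) {
  if (mode == "exponential") x0 * exp(trend * day) else x0 + trend * day
}

#' Sampling days of a campaign
#'
#' @param cfg A [sim_config()].
#' @return Integer vector of day offsets from campaign start (day 0 first),
#'   following the configured 3-4 day rhythm up to \code{n_days}.
#' @export
sampling_days <- function(cfg) {
  steps <- rep(cfg$sampling_pattern, length.out = ceiling(cfg$n_days))
  days <- cumsum(c(0, steps))
  days[days <= cfg$n_days - 1]
}

# mean-1 multiplicative lognormal noise
rlnorm_unit <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate under-ice tidal currents
#'
#' Hourly current velocity built from the lunar (M2, 12.42 h) and solar
#' (S2, 12.00 h) semidiurnal constituents plus Gaussian noise; the daily
#' maximum speed is extracted. The two constituents beat with a period of
#' \eqn{1/(1/12.00 - 1/12.42)} hours (~14.8 days), producing the spring-neap
#' envelope in the daily maxima.
#'
#' @param cfg A [sim_config()].
#' @return A data.frame with columns \code{day} (0-based) and
#'   \code{max_speed} (m s^-1), one row per campaign day.
#' @export
simulate_currents <- function(cfg) {
  hours <- seq(0, cfg$n_days * 24 - 1)
  u <- cfg$a_m2 * sin(2 * pi * hours / 12.42) +
    cfg$a_s2 * sin(2 * pi * hours / 12.00)
  if (cfg$current_noise > 0) {
    u <- u + stats::rnorm(length(hours), sd = cfg$current_noise)
  }
  day <- hours %/% 24
  data.frame(day = 0:(cfg$n_days - 1),
             max_speed = as.numeric(tapply(abs(u), day, max)))
}

#' Simulate the true state of the bloom
#'
#' Produces the per site-day ground truth: a linearly declining areal chl a
#' with multiplicative site (snow class) factors, opposing trends in the
#' chl-specific IC-N and IC-Si pools, a tidal component added to both IC
#' series (proportional to the standardized daily-maximum current on the
#' sampling days and scaled so that the detrended residual-forcing
#' correlation targets \code{coupling_r} under the configured noise), cell
#' abundance proportional to chl a, and biovolume = abundance x mean cell
#' volume with site-day jitter.
#'
#' @param cfg A [sim_config()].
#' @param currents Output of [simulate_currents()].
#' @return A data.frame keyed by (day, site) with true chl a (areal and
#'   volumetric), IC pools, abundance, biovolume, bottom-ice IC
#'   concentrations and the day's maximum current speed.
#' @export
simulate_bloom <- function(cfg, currents) {
  days <- sampling_days(cfg)
  cmax <- currents$max_speed[match(days, currents$day)]
  z <- if (stats::sd(cmax) > 0) (cmax - mean(cmax)) / stats::sd(cmax) else cmax * 0
  # coupling amplitude: with residual noise sd sigma (site-averaged,
  # multiplicative cv at the mean level), r = k / sqrt(k^2 + sigma^2)
  n_sites <- length(cfg$sites)
  amp <- function(x0, trend) {
    level <- mean(trend_value(x0, trend, days, cfg$trend_mode))
    sigma <- cfg$noise_cv * level / sqrt(n_sites)
    if (cfg$coupling_r == 0) 0
    else cfg$coupling_r / sqrt(1 - cfg$coupling_r^2) * max(sigma, 0.02 * level)
  }
  icb_n <- trend_value(cfg$icN0, cfg$icN_trend, days, cfg$trend_mode) +
    amp(cfg$icN0, cfg$icN_trend) * z
  icb_si <- trend_value(cfg$icSi0, cfg$icSi_trend, days, cfg$trend_mode) +
    amp(cfg$icSi0, cfg$icSi_trend) * z
  if (any(icb_n <= 0) || any(icb_si <= 0)) {
    stop("configured trends plus tidal coupling drive an IC series non-positive",
         call. = FALSE)
  }
  grid <- expand.grid(site = cfg$sites, day = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$day, match(grid$site, cfg$sites)), , drop = FALSE]
  fac <- cfg$site_chla_factor[match(grid$site, cfg$sites)]
  chla_areal <- fac * (cfg$chla0 - cfg$chla_decline_rate * grid$day)
  chla_vol <- chla_areal / cfg$core_section_length  # mg m^-3 of melted ice
  abundance <- chla_vol * cfg$cells_per_ug_chla     # mg m^-3 == ug L^-1
  jitter <- rlnorm_unit(nrow(grid), cfg$biovolume_jitter_cv)
  idx <- match(grid$day, days)
  out <- data.frame(
    day = grid$day,
    site = grid$site,
    chla_areal = chla_areal,
    chla_vol = chla_vol,
    icb_n = icb_n[idx],
    icb_si = icb_si[idx],
    abundance = abundance,
    biovolume = abundance * cfg$mean_cell_volume * jitter,
    current_max = cmax[idx]
  )
  out$bottom_ic_n <- bottom_ice_ic(out$icb_n, out$chla_vol)
  out$bottom_ic_si <- bottom_ice_ic(out$icb_si, out$chla_vol)
  rownames(out) <- NULL
  out
}

#' Observe the true state through the scrape protocol
#'
#' Emulates scraping the soft skeletal bottom-ice layer into cold FSW,
#' filtering a subsample, extracting the IC pool of the filtered cells with
#' hot water, and measuring the filtrate: the filtrate concentration is the
#' daily blank plus the true chl-specific pool times the filter chl a mass
#' over the extraction volume, under multiplicative lognormal noise on the
#' released signal. The reported blank is the realized daily blank, so
#' blank correction is exact in noise-free mode.
#'
#' @param state Output of [simulate_bloom()].
#' @param cfg A [sim_config()].
#' @return A data.frame of scrape-extraction rows (one per replicate core).
#' @export
observe_scrape <- function(state, cfg) {
  reps <- cfg$n_scrape_replicates
  n <- nrow(state) * reps
  st <- state[rep(seq_len(nrow(state)), each = reps), , drop = FALSE]
  days <- sort(unique(state$day))
  blank_n_day <- cfg$blank_level_N * rlnorm_unit(length(days), cfg$noise_cv)
  blank_si_day <- cfg$blank_level_Si * rlnorm_unit(length(days), cfg$noise_cv)
  bi <- match(st$day, days)
  mass <- cfg$scrape_chla_mass * rlnorm_unit(n, cfg$noise_cv)
  data.frame(
    day = st$day,
    site = st$site,
    replicate = rep(seq_len(reps), times = nrow(state)),
    filtrate_n = blank_n_day[bi] +
      st$icb_n * mass / cfg$extraction_volume * rlnorm_unit(n, cfg$noise_cv),
    filtrate_si = blank_si_day[bi] +
      st$icb_si * mass / cfg$extraction_volume * rlnorm_unit(n, cfg$noise_cv),
    blank_n = blank_n_day[bi],
    blank_si = blank_si_day[bi],
    extraction_volume = cfg$extraction_volume,
    scrape_chla_mass = mass,
    row.names = NULL
  )
}

#' Observe the true state through the FSW-diluted core melt protocol
#'
#' Pooled bottom core sections are melted into filtered seawater; chl a,
#' cell abundance and biovolume are measured in the diluted solution.
#' Abundance observation uses Poisson counting error at the configured
#' number of enumerated cells (off in noise-free mode); chl a and biovolume
#' carry multiplicative lognormal noise.
#'
#' @param state Output of [simulate_bloom()].
#' @param cfg A [sim_config()].
#' @return A data.frame of core-melt rows with the melt geometry needed to
#'   undo the dilution.
#' @export
observe_core_melt <- function(state, cfg) {
  n <- nrow(state)
  melt_volume <- cfg$n_cores_pooled * pi * (cfg$core_inner_diameter / 2)^2 *
    cfg$core_section_length * 1000  # L of melted ice
  fsw <- stats::runif(n, cfg$fsw_volume_range[1], cfg$fsw_volume_range[2])
  df <- (fsw + melt_volume) / melt_volume
  abundance_dil <- state$abundance / df
  if (cfg$noise_cv > 0) {
    counts <- stats::rpois(n, cfg$counted_cells)
    abundance_obs <- abundance_dil * counts / cfg$counted_cells
  } else {
    abundance_obs <- abundance_dil
  }
  data.frame(
    day = state$day,
    site = state$site,
    chla_diluted = state$chla_vol / df * rlnorm_unit(n, cfg$noise_cv),
    abundance_diluted = abundance_obs,
    biovolume_diluted = state$biovolume / df * rlnorm_unit(n, cfg$noise_cv),
    fsw_volume = fsw,
    melted_ice_volume = melt_volume,
    core_section_length = cfg$core_section_length,
    row.names = NULL
  )
}

#' Observe the true state through the bulk melt protocol
#'
#' A bottom core section melted without FSW: the measured nutrient
#' concentration is the conservative brine background (water-column
#' concentration diluted to the bulk salinity) plus the retained fraction of
#' the true bottom-ice IC pool released by osmotic shock, under
#' multiplicative noise.
#'
#' @param state Output of [simulate_bloom()].
#' @param cfg A [sim_config()].
#' @return A data.frame of bulk-melt rows (salinity and both nutrients).
#' @export
observe_bulk_melt <- function(state, cfg) {
  n <- nrow(state)
  sal <- stats::runif(n, cfg$bulk_salinity_range[1], cfg$bulk_salinity_range[2])
  bg_n <- cfg$water_column_N * sal / cfg$water_salinity
  bg_si <- cfg$water_column_Si * sal / cfg$water_salinity
  data.frame(
    day = state$day,
    site = state$site,
    bulk_salinity = sal,
    no3_no2 = (bg_n + cfg$retention_N * state$bottom_ic_n) *
      rlnorm_unit(n, cfg$noise_cv),
    sioh4 = (bg_si + cfg$retention_Si * state$bottom_ic_si) *
      rlnorm_unit(n, cfg$noise_cv),
    row.names = NULL
  )
}

#' Simulate a complete field campaign
#'
#' Seeds the RNG from the configuration and runs the whole generator:
#' currents, true state, and the three observation protocols, plus 2-m
#' water-column samples on each sampling day. The result carries the ground
#' truth alongside the observations for parameter-recovery tests.
#'
#' @param cfg A [sim_config()].
#' @return A list of class \code{"ice_campaign"} with elements
#'   \code{scrape}, \code{core_melt}, \code{bulk_melt}, \code{water_column},
#'   \code{currents}, \code{truth} (data.frames) and \code{config}.
#' @export
simulate_campaign <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  currents <- simulate_currents(cfg)
  truth <- simulate_bloom(cfg, currents)
  scrape <- observe_scrape(truth, cfg)
  core_melt <- observe_core_melt(truth, cfg)
  bulk_melt <- observe_bulk_melt(truth, cfg)
  days <- sort(unique(truth$day))
  water_column <- data.frame(
    day = days,
    salinity = cfg$water_salinity,
    no3_no2 = cfg$water_column_N * rlnorm_unit(length(days), cfg$noise_cv / 2),
    sioh4 = cfg$water_column_Si * rlnorm_unit(length(days), cfg$noise_cv / 2)
  )
  out <- list(scrape = scrape, core_melt = core_melt, bulk_melt = bulk_melt,
              water_column = water_column, currents = currents, truth = truth,
              config = cfg)
  for (nm in campaign_table_names()) {
    out[[nm]] <- add_date_column(out[[nm]], cfg$start_date)
  }
  class(out) <- "ice_campaign"
  out
}

campaign_table_names <- function() {
  c("scrape", "core_melt", "bulk_melt", "water_column", "currents", "truth")
}

add_date_column <- function(df, start_date) {
  df$date <- format(as.Date(start_date) + df$day, "%Y-%m-%d")
  df[, c("date", setdiff(names(df), "date")), drop = FALSE]
}

#' Write a campaign to a directory of CSV files
#'
#' Emits \code{scrape.csv}, \code{core_melt.csv}, \code{bulk_melt.csv},
#' \code{water_column.csv}, \code{currents.csv}, \code{truth.csv} and a
#' \code{config.json} recording every generator parameter including the
#' seed. Output is byte-identical for identical campaigns.
#'
#' @param campaign An \code{"ice_campaign"} from [simulate_campaign()].
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "ice_campaign"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in campaign_table_names()) {
    path <- file.path(dir, paste0(nm, ".csv"))
    ok <- try(utils::write.csv(campaign[[nm]], path, row.names = FALSE),
              silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop(sprintf("failed to write %s: %s", path, as.character(ok)),
           call. = FALSE)
    }
  }
  cfg <- campaign$config
  writeLines(config_to_json(unclass(cfg)), file.path(dir, "config.json"))
  invisible(dir)
}

# minimal JSON writer for the flat config list (numbers, strings, vectors)
config_to_json <- function(x) {
  enc <- function(v) {
    if (is.character(v)) items <- paste0('"', v, '"')
    else items <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
    if (length(items) == 1L) items else paste0("[", paste(items, collapse = ", "), "]")
  }
  body <- vapply(names(x), function(nm) {
    sprintf('  "%s": %s', nm, enc(x[[nm]]))
  }, character(1))
  c("{", paste(body, collapse = ",\n"), "}")
}
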