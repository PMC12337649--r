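test_that("config validation rejects unphysical parameters", {
  expect_error(sim_config(retention_Si = 1.4), "retention")
  expect_error(sim_config(chla0 = 50, chla_decline_rate = 3), "non-positive")
  expect_error(sim_config(icN0 = 2, icN_trend = -0.2), "non-positive")
  expect_error(sim_config(n_cores_pooled = 5), "1, 2 or 3")
})

test_that("simulated currents carry the spring-neap beat of the two constituents", {
  cfg <- sim_config(current_noise = 0, n_days = 45)
  cur <- simulate_currents(cfg)
  expect_equal(nrow(cur), 45)
  # envelope maxima of the daily-max series spaced by the ~14.8 d beat
  m <- cur$max_speed
  peaks <- which(diff(sign(diff(m))) < 0) + 1
  expect_gte(length(peaks), 2)
  expect_true(all(abs(diff(cur$day[peaks]) - 14.8) <= 2.2))
  # solar constituent off -> no beat: daily max nearly constant
  flat <- simulate_currents(sim_config(a_s2 = 0, current_noise = 0))
  expect_lt(sd(flat$max_speed) / mean(flat$max_speed), 0.01)
  # everything off -> identically zero
  zero <- simulate_currents(sim_config(a_m2 = 0, a_s2 = 0, current_noise = 0))
  expect_true(all(zero$max_speed == 0))
})

test_that("a fixed seed reproduces the campaign and its files exactly", {
  cfg <- sim_config(seed = 99)
  a <- simulate_campaign(cfg)
  b <- simulate_campaign(cfg)
  expect_identical(a$scrape, b$scrape)
  expect_identical(a$truth, b$truth)
  d1 <- file.path(tempdir(), "camp_a"); d2 <- file.path(tempdir(), "camp_b")
  write_campaign(a, d1); write_campaign(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("campaign dimensions follow the sampling grid and all values are nonnegative", {
  cfg <- sim_config(seed = 5)
  camp <- simulate_campaign(cfg)
  n_expected <- length(sampling_days(cfg)) * length(cfg$sites)
  expect_equal(nrow(camp$truth), n_expected)
  expect_equal(nrow(camp$bulk_melt), n_expected)
  expect_equal(nrow(camp$scrape), n_expected * cfg$n_scrape_replicates)
  for (nm in c("scrape", "core_melt", "bulk_melt", "water_column", "truth")) {
    num <- camp[[nm]][vapply(camp[[nm]], is.numeric, logical(1))]
    expect_true(all(as.matrix(num) >= 0), label = nm)
  }
})

test_that("zero trends and noise give constant series", {
  cfg <- sim_config(seed = 6, chla_decline_rate = 0, icN_trend = 0,
                    icSi_trend = 0, coupling_r = 0, noise_cv = 0,
                    biovolume_jitter_cv = 0)
  truth <- simulate_campaign(cfg)$truth
  one_site <- truth[truth$site == "medium", ]
  expect_equal(length(unique(one_site$icb_n)), 1L)
  expect_equal(length(unique(one_site$chla_areal)), 1L)
})

test_that("the noise-free observation chain inverts exactly to the truth", {
  cfg <- sim_config(seed = 7, noise_cv = 0, biovolume_jitter_cv = 0)
  camp <- simulate_campaign(cfg)
  est <- derive_ic_estimates(camp)
  key <- function(df) df[order(df$day, df$site), ]
  est <- key(est); tr <- key(camp$truth)
  expect_equal(est$ic_chl_specific_n, tr$icb_n, tolerance = 1e-12)
  expect_equal(est$ic_chl_specific_si, tr$icb_si, tolerance = 1e-12)
  expect_equal(est$chla_vol, tr$chla_vol, tolerance = 1e-12)
  expect_equal(est$abundance, tr$abundance, tolerance = 1e-12)
  expect_equal(est$biovolume, tr$biovolume, tolerance = 1e-12)
})

test_that("bulk melt is brine background plus the retained intracellular pool", {
  cfg <- sim_config(seed = 8, noise_cv = 0, biovolume_jitter_cv = 0)
  camp <- simulate_campaign(cfg)
  bm <- camp$bulk_melt; tr <- camp$truth
  bg_n <- cfg$water_column_N * bm$bulk_salinity / cfg$water_salinity
  bg_si <- cfg$water_column_Si * bm$bulk_salinity / cfg$water_salinity
  # retention 1: bulk N minus background equals bottom-ice IC-N exactly
  expect_equal(bm$no3_no2 - bg_n, tr$bottom_ic_n, tolerance = 1e-12)
  expect_equal(bm$sioh4 - bg_si, tr$bottom_ic_si / 11, tolerance = 1e-12)
  # default noisy campaign: bulk N:Si stochastically exceeds the water column
  noisy <- simulate_campaign(sim_config(seed = 9))
  expect_gt(mean(noisy$bulk_melt$no3_no2 / noisy$bulk_melt$sioh4),
            cfg$water_column_N / cfg$water_column_Si)
})

test_that("scrape observation is unbiased for the chl-specific pool under noise", {
  ratios <- vapply(1:200, function(seed) {
    cfg <- sim_config(seed = seed, n_days = 8, noise_cv = 0.1)
    camp <- simulate_campaign(cfg)
    sc <- camp$scrape; tr <- camp$truth
    rec <- as.numeric(chl_specific_ic(sc$filtrate_n, sc$blank_n,
                                      sc$extraction_volume, sc$scrape_chla_mass))
    mean(rec / tr$icb_n[match(paste(sc$day, sc$site),
                              paste(tr$day, tr$site))])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.02)
})

test_that("counting error of cell abundance is Poisson at the enumerated count", {
  cvs <- vapply(1:300, function(seed) {
    set.seed(seed)
    cfg <- sim_config(counted_cells = 400L)
    st <- data.frame(day = 0, site = "medium", chla_vol = 1500,
                     abundance = 3e8, biovolume = 3e8 * 1890,
                     chla_areal = 45, icb_n = 12, icb_si = 50,
                     bottom_ic_n = 18, bottom_ic_si = 75, current_max = 0.1)
    obs <- observe_core_melt(st, cfg)
    abund <- fsw_dilution_correct(obs$abundance_diluted, obs$fsw_volume,
                                  obs$melted_ice_volume)
    abund / 3e8
  }, numeric(1))
  expect_equal(sd(cvs), 1 / sqrt(400), tolerance = 0.2)
})

test_that("detrended residual correlation recovers the configured coupling", {
  # median over seeds of the lag-0 correlation tracks coupling_r; with the
  # coupling off the signed median correlation is near zero
  lag0 <- function(seed, r) {
    camp <- simulate_campaign(sim_config(seed = seed, coupling_r = r))
    rc <- analyze_temporal(camp)$residual_correlations
    rc$r[rc$variable == "icb_n" & rc$lag == 0]
  }
  r_on <- vapply(1:60, lag0, numeric(1), r = 0.5)
  r_off <- vapply(1:60, lag0, numeric(1), r = 0)
  expect_lt(abs(median(r_on) - 0.5), 0.2)
  expect_lt(abs(median(r_off)), 0.2)
})
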