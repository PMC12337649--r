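test_that("blank correction clips at zero and flags affected samples", {
  expect_equal(as.numeric(blank_correct(5.0, 0.2)), 4.8)
  expect_equal(as.numeric(blank_correct(3.1, 0)), 3.1)
  clipped <- blank_correct(c(0.1, 2), c(0.3, 0.5))
  expect_equal(as.numeric(clipped), c(0, 1.5))
  expect_identical(attr(clipped, "clipped"), c(TRUE, FALSE))
  expect_error(blank_correct(-1, 0), ">= 0")
})

test_that("chl-specific IC pool follows the extraction arithmetic and is linear", {
  # 5 umol/L over 40 mL on a 0.0156 mg chl a filter -> 12.82 umol/mg
  expect_equal(as.numeric(chl_specific_ic(5, 0, 0.040, 0.0156)),
               5 * 0.040 / 0.0156, tolerance = 1e-12)
  expect_equal(as.numeric(chl_specific_ic(0, 0, 0.040, 0.01)), 0)
  base <- as.numeric(chl_specific_ic(5, 0.2, 0.040, 0.0156))
  expect_equal(as.numeric(chl_specific_ic(5, 0.2, 0.040, 0.0078)), 2 * base)
  expect_error(chl_specific_ic(5, 0, 0.040, 0), "positive")
})

test_that("bottom-ice IC concentration is the chl-specific pool times biomass", {
  expect_equal(bottom_ice_ic(12.8, 1000), 12.8)
  expect_equal(bottom_ice_ic(12.8, 0), 0)
  expect_equal(bottom_ice_ic(12.8, 3 * 1000), 3 * bottom_ice_ic(12.8, 1000))
})

test_that("per-cell-volume and per-cell conversions carry the right units", {
  # 20.7 umol/L over 6.80e11 um^3/L -> 30.4 mmol/L of cell volume
  expect_equal(ic_per_cell_volume(20.7, 6.80e11), 20.7 * 1e15 / 6.80e11 / 1000,
               tolerance = 1e-12)
  expect_equal(round(ic_per_cell_volume(20.7, 6.80e11), 1), 30.4)
  # 20.7 umol/L over 3.04e8 cells/L -> 68.1 fmol/cell
  expect_equal(round(ic_per_cell(20.7, 3.04e8), 1), 68.1)
  expect_equal(ic_per_cell(0, 3.04e8), 0)
  expect_error(ic_per_cell_volume(1, 0), "positive")
  expect_error(ic_per_cell(1, 0), "positive")
})

test_that("per-cell over per-cell-volume equals mean cell volume exactly", {
  set.seed(31)
  for (i in 1:25) {
    bottom_ic <- runif(1, 0.1, 50)
    abundance <- runif(1, 1e7, 1e9)
    biovolume <- abundance * runif(1, 500, 4000)
    ratio <- ic_per_cell(bottom_ic, abundance) /
      ic_per_cell_volume(bottom_ic, biovolume)
    expect_equal(ratio, biovolume / abundance * 1e-3,
                 tolerance = 1e-9)
  }
})

test_that("the estimation chain is linear in filtrate and in bottom-ice chl a", {
  p1 <- ic_profile(filtrate_n = 5, filtrate_si = 12, chla_mass = 0.015,
                   bottom_chla = 1500, abundance = 3e8, biovolume = 6e11)
  p2 <- ic_profile(filtrate_n = 10, filtrate_si = 24, chla_mass = 0.015,
                   bottom_chla = 1500, abundance = 3e8, biovolume = 6e11)
  expect_equal(p2$bottom_ice_ic_n, 2 * p1$bottom_ice_ic_n)
  expect_equal(p2$ic_content_cell_si, 2 * p1$ic_content_cell_si)
  p3 <- ic_profile(filtrate_n = 5, filtrate_si = 12, chla_mass = 0.015,
                   bottom_chla = 3000, abundance = 3e8, biovolume = 6e11)
  expect_equal(p3$bottom_ice_ic_n, 2 * p1$bottom_ice_ic_n)
  expect_equal(p3$ic_chl_specific_n, p1$ic_chl_specific_n)
})

test_that("implied mean cell volume ties content and concentration together", {
  expect_equal(implied_mean_cell_volume(36.3, 19.2), 36.3 / 19.2 * 1000,
               tolerance = 1e-12)
  expect_lt(abs(implied_mean_cell_volume(36.3, 19.2) - 1890) / 1890, 0.01)
  expect_lt(abs(implied_mean_cell_volume(110, 58.4) - 1890) / 1890, 0.01)
  expect_equal(implied_mean_cell_volume(10, 4) / implied_mean_cell_volume(10, 8), 2)
  expect_error(implied_mean_cell_volume(1, 0), "positive")
})

test_that("N:Si molar ratios match the water-column stoichiometry", {
  expect_equal(n_si_ratio(7.67, 14.7), 7.67 / 14.7)
  expect_equal(round(n_si_ratio(7.67, 14.7), 2), 0.52)
  expect_lt(abs(n_si_ratio(7.32, 14.8) - 0.50), 0.01)
  expect_equal(n_si_ratio(3.3, 3.3), 1)
  expect_error(n_si_ratio(1, 0), "undefined")
})
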