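#' Blank-correct an extraction filtrate concentration
#'
#' Subtracts the daily hot-water blank from a filtrate nutrient
#' concentration. Negative differences (blank above sample) are clipped to
#' zero and flagged rather than propagated: a negative intracellular pool is
#' not physically meaningful, but the affected samples should be visible to
#' the analyst.
#'
#' @param filtrate Filtrate concentration, umol L^-1 (>= 0).
#' @param blank Daily blank concentration, umol L^-1 (>= 0).
#' @return Numeric vector \code{pmax(filtrate - blank, 0)} with a logical
#'   attribute \code{"clipped"} marking samples where the blank exceeded the
#'   filtrate.
#' @export
blank_correct <- function(filtrate, blank) {
  if (any(filtrate < 0) || any(blank < 0)) {
    stop("filtrate and blank concentrations must be >= 0", call. = FALSE)
  }
  out <- pmax(filtrate - blank, 0)
  attr(out, "clipped") <- blank > filtrate
  out
}

#' Chl a-specific intracellular nutrient pool
#'
#' Converts a blank-corrected hot-water extraction filtrate concentration to
#' a chlorophyll-specific intracellular (IC) pool. The extraction releases
#' the IC pool of the cells concentrated on the filter into a known volume of
#' hot water; dividing the released amount (concentration x extraction
#' volume) by the mass of chl a on that filter yields the pool per unit
#' biomass:
#' \deqn{IC^B = \frac{(C_{filtrate} - C_{blank})\,V_{extract}}{m_{chl\,a}}}
#' in umol (mg chl a)^-1. This is the quantity written IC-N^B and IC-Si^B.
#'
#' @param filtrate Filtrate concentration, umol L^-1.
#' @param blank Daily blank, umol L^-1 (default 0).
#' @param extraction_volume Hot-water extraction volume, L; nominal 0.040
#'   (40 mL poured into the filter funnel).
#' @param chla_mass Mass of chl a on the extracted filter, mg (> 0).
#' @return Chl-specific IC pool, umol (mg chl a)^-1, with the
#'   \code{"clipped"} attribute from [blank_correct()].
#' @export
chl_specific_ic <- function(filtrate, blank = 0, extraction_volume = 0.040,
                            chla_mass) {
  if (any(extraction_volume <= 0)) {
    stop("`extraction_volume` must be positive", call. = FALSE)
  }
  if (any(chla_mass <= 0)) {
    stop("`chla_mass` must be positive: cannot normalize to zero biomass",
         call. = FALSE)
  }
  corrected <- blank_correct(filtrate, blank)
  out <- as.numeric(corrected) * extraction_volume / chla_mass
  attr(out, "clipped") <- attr(corrected, "clipped")
  out
}

#' Bottom-ice intracellular nutrient concentration
#'
#' Scales a chl-specific IC pool up to a melt-volume-corrected bottom-ice
#' concentration by multiplying with the bottom-ice chl a concentration from
#' FSW-diluted cores:
#' \deqn{IC_{bottom} = IC^B \times chl\,a_{bottom} / 1000}
#' (the factor 1000 converts mg m^-3 to mg L^-1). The result is in umol per
#' litre of melted bottom ice and is directly comparable to bulk-melt
#' nutrient concentrations, yet estimated independently of them.
#'
#' @param ic_chl_specific Chl-specific IC pool, umol (mg chl a)^-1.
#' @param bottom_chla Bottom-ice chl a, mg m^-3 of melted ice.
#' @return Bottom-ice IC concentration, umol L^-1 of melted ice.
#' @export
bottom_ice_ic <- function(ic_chl_specific, bottom_chla) {
  if (any(ic_chl_specific < 0) || any(bottom_chla < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  ic_chl_specific * bottom_chla / 1000
}

#' Intracellular concentration per unit cell volume
#'
#' Divides the bottom-ice IC concentration by the community biovolume to
#' express the pool as a concentration inside the cells, in mmol per litre
#' of cell volume (1 um^3 = 1e-15 L):
#' \deqn{IC_{cell vol} = \frac{IC_{bottom} \times 10^{15}}{BV \times 1000}.}
#' Values of tens of mmol L^-1 — orders of magnitude above ambient seawater
#' concentrations — are the direct evidence of intracellular storage.
#'
#' @param bottom_ic Bottom-ice IC concentration, umol L^-1 of melted ice.
#' @param biovolume Total community biovolume, um^3 L^-1 of melted ice (> 0).
#' @return IC concentration per cell volume, mmol L^-1.
#' @export
ic_per_cell_volume <- function(bottom_ic, biovolume) {
  if (any(biovolume <= 0)) stop("`biovolume` must be positive", call. = FALSE)
  bottom_ic * 1e15 / biovolume / 1000
}

#' Intracellular content per cell
#'
#' Divides the bottom-ice IC concentration by the community cell abundance
#' to give the average pool per cell, in fmol cell^-1 (1 umol = 1e9 fmol).
#'
#' @param bottom_ic Bottom-ice IC concentration, umol L^-1 of melted ice.
#' @param abundance Total cell abundance, cells L^-1 of melted ice (> 0).
#' @return IC content, fmol cell^-1.
#' @export
ic_per_cell <- function(bottom_ic, abundance) {
  if (any(abundance <= 0)) stop("`abundance` must be positive", call. = FALSE)
  bottom_ic / abundance * 1e9
}

#' Molar N:Si ratio
#'
#' Ratio of nitrate+nitrite to silicic acid amounts (mol:mol). Zero or
#' negative Si makes the ratio undefined and raises an error.
#'
#' @param n,si Amounts or concentrations in the same unit; \code{si > 0}.
#' @return \code{n / si}.
#' @export
n_si_ratio <- function(n, si) {
  if (any(si <= 0)) {
    stop("N:Si ratio undefined for non-positive Si", call. = FALSE)
  }
  n / si
}

#' Mean cell volume implied by per-cell content and per-volume concentration
#'
#' Consistency check tying the per-cell and per-cell-volume expressions of
#' the same IC pool together: content / concentration is the mean cell
#' volume,
#' \deqn{\bar V = \frac{content\ [\mathrm{fmol\,cell^{-1}}] \times 10^{-15}}
#'   {concentration\ [\mathrm{mmol\,L^{-1}}] \times 10^{-3}} \times
#'   10^{15}\ \mathrm{\mu m^3\,L^{-1}}
#'   = \frac{content}{concentration} \times 1000 .}
#' Both nutrients, estimated independently, should imply the same community
#' mean cell volume.
#'
#' @param content IC content, fmol cell^-1.
#' @param concentration IC concentration, mmol L^-1 of cell volume (> 0).
#' @return Implied mean cell volume, um^3 cell^-1.
#' @export
implied_mean_cell_volume <- function(content, concentration) {
  if (any(concentration <= 0)) {
    stop("`concentration` must be positive", call. = FALSE)
  }
  content / concentration * 1000
}

#' Full intracellular nutrient profile for one or more samples
#'
#' Runs the whole estimation chain for paired N and Si measurements of the
#' same samples: blank correction, chl normalization, melt-volume-corrected
#' bottom-ice concentration, per-cell-volume concentration, per-cell content,
#' and the molar N:Si ratio of the chl-specific pools.
#'
#' @param filtrate_n,filtrate_si Scrape-extraction filtrate concentrations,
#'   umol L^-1.
#' @param blank_n,blank_si Daily blanks, umol L^-1.
#' @param extraction_volume Extraction volume, L (default 0.040).
#' @param chla_mass Chl a mass on the extracted filter, mg.
#' @param bottom_chla Bottom-ice chl a, mg m^-3 of melted ice.
#' @param abundance Cell abundance, cells L^-1 of melted ice.
#' @param biovolume Community biovolume, um^3 L^-1 of melted ice.
#' @return A data.frame with one row per sample: \code{ic_chl_specific_n},
#'   \code{ic_chl_specific_si}, \code{bottom_ice_ic_n},
#'   \code{bottom_ice_ic_si}, \code{ic_conc_cell_vol_n},
#'   \code{ic_conc_cell_vol_si}, \code{ic_content_cell_n},
#'   \code{ic_content_cell_si}, \code{n_si_ratio}.
#' @export
ic_profile <- function(filtrate_n, filtrate_si, blank_n = 0, blank_si = 0,
                       extraction_volume = 0.040, chla_mass,
                       bottom_chla, abundance, biovolume) {
  icb_n <- chl_specific_ic(filtrate_n, blank_n, extraction_volume, chla_mass)
  icb_si <- chl_specific_ic(filtrate_si, blank_si, extraction_volume, chla_mass)
  bi_n <- bottom_ice_ic(as.numeric(icb_n), bottom_chla)
  bi_si <- bottom_ice_ic(as.numeric(icb_si), bottom_chla)
  data.frame(
    ic_chl_specific_n = as.numeric(icb_n),
    ic_chl_specific_si = as.numeric(icb_si),
    bottom_ice_ic_n = bi_n,
    bottom_ice_ic_si = bi_si,
    ic_conc_cell_vol_n = ic_per_cell_volume(bi_n, biovolume),
    ic_conc_cell_vol_si = ic_per_cell_volume(bi_si, biovolume),
    ic_content_cell_n = ic_per_cell(bi_n, abundance),
    ic_content_cell_si = ic_per_cell(bi_si, abundance),
    n_si_ratio = ifelse(as.numeric(icb_si) > 0,
                        as.numeric(icb_n) / as.numeric(icb_si), NA_real_)
  )
}
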