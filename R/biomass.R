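#' Chlorophyll a from acidification fluorometry
#'
#' Converts a paired fluorometer reading (before/after acidification with
#' dilute HCl) into a chlorophyll a concentration in the measured extract
#' solution, using the classical acid-ratio formula
#' \deqn{chl\,a = \frac{F_m}{F_m - 1}\,(F_b - F_a)\, K \,
#'   \frac{V_{extract}}{V_{filtered}}}
#' where \eqn{F_m} is the instrument's maximum acid ratio, \eqn{F_b, F_a}
#' the readings before and after acidification, and \eqn{K} the calibration
#' factor. The acid step separates chl a from phaeopigments.
#'
#' @param f_before,f_after Relative fluorescence before and after
#'   acidification; \code{f_before >= f_after >= 0}. A reading with
#'   \code{f_after > f_before} is physically inverted (more signal after
#'   destroying chl a) and raises an error.
#' @param acid_ratio_max Instrument maximum acid ratio Fm (> 1). Default 2.2,
#'   typical for bench fluorometers of this class.
#' @param calibration Calibration factor, ug L^-1 per fluorescence unit.
#' @param extract_volume Volume of the pigment extract, L.
#' @param filtered_volume Volume of sample filtered, L.
#' @return Chlorophyll a concentration, ug L^-1, in the filtered sample.
#' @examples
#' chla_concentration(10, 5, acid_ratio_max = 2.2,
#'                    extract_volume = 0.01, filtered_volume = 0.01)
#' @export
chla_concentration <- function(f_before, f_after, acid_ratio_max = 2.2,
                               calibration = 1,
                               extract_volume, filtered_volume) {
  if (any(acid_ratio_max <= 1)) {
    stop("`acid_ratio_max` must exceed 1", call. = FALSE)
  }
  if (any(extract_volume <= 0) || any(filtered_volume <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  if (any(f_after < 0)) stop("fluorescence readings must be >= 0", call. = FALSE)
  if (any(f_after > f_before)) {
    stop("f_after exceeds f_before: phaeopigment inversion in the reading",
         call. = FALSE)
  }
  acid_ratio_max / (acid_ratio_max - 1) * (f_before - f_after) *
    calibration * extract_volume / filtered_volume
}

#' Correct a measurement for filtered-seawater melt dilution
#'
#' Bottom-ice core sections are melted into 0.2-um filtered seawater (FSW) to
#' buffer the melt salinity and limit osmotic shock; every quantity measured
#' in the diluted solution must be scaled back to a per-litre-of-melted-ice
#' basis:
#' \deqn{x_{melt} = x_{measured}\,\frac{V_{FSW} + V_{melt}}{V_{melt}}.}
#'
#' @param measured Quantity per litre of the FSW-diluted solution (any unit).
#' @param fsw_volume Volume of FSW added, L (>= 0).
#' @param melted_ice_volume Volume of melted ice, L (> 0).
#' @return The quantity per litre of melted ice.
#' @export
fsw_dilution_correct <- function(measured, fsw_volume, melted_ice_volume) {
  if (any(fsw_volume < 0)) stop("`fsw_volume` must be >= 0", call. = FALSE)
  if (any(melted_ice_volume <= 0)) {
    stop("`melted_ice_volume` must be positive", call. = FALSE)
  }
  measured * (fsw_volume + melted_ice_volume) / melted_ice_volume
}

#' Areal chlorophyll a from a volumetric concentration
#'
#' Integrates a volumetric bottom-ice chl a concentration (per litre of
#' melted ice, i.e. mg m^-3) over the sampled core section length to give an
#' areal standing stock (mg m^-2). Equivalent to dividing the chl a amount in
#' the melt by the pooled core cross-section area when the melt volume equals
#' section length x area x number of cores.
#'
#' @param volumetric Chl a concentration, mg m^-3 of melted ice.
#' @param core_section_length Length of the sampled bottom-ice section, m
#'   (e.g. 0.03 for the bottom 3 cm).
#' @return Areal chl a, mg m^-2.
#' @export
areal_chla <- function(volumetric, core_section_length) {
  if (any(core_section_length <= 0)) {
    stop("`core_section_length` must be positive", call. = FALSE)
  }
  volumetric * core_section_length
}

#' Community composition summaries
#'
#' Percent contribution of pennate diatoms to cell abundance and to total
#' cell volume, and the community mean cell volume, from totals per litre of
#' melted ice.
#'
#' @param total_abundance Total cell abundance, cells L^-1 (> 0).
#' @param total_biovolume Total community biovolume, um^3 L^-1.
#' @param pennate_abundance,pennate_biovolume Pennate-diatom components; must
#'   not exceed the totals.
#' @return A data.frame with columns \code{pennate_pct_abundance},
#'   \code{pennate_pct_biovolume} (both in \[0, 100\]) and
#'   \code{mean_cell_volume} (um^3 cell^-1).
#' @export
community_fractions <- function(total_abundance, total_biovolume,
                                pennate_abundance, pennate_biovolume) {
  if (any(total_abundance <= 0)) {
    stop("`total_abundance` must be positive (zero abundance with biovolume is a data error)",
         call. = FALSE)
  }
  if (any(pennate_abundance > total_abundance) ||
      any(pennate_biovolume > total_biovolume)) {
    stop("pennate components must not exceed community totals", call. = FALSE)
  }
  if (any(c(pennate_abundance, pennate_biovolume, total_biovolume) < 0)) {
    stop("abundances and biovolumes must be >= 0", call. = FALSE)
  }
  data.frame(
    pennate_pct_abundance = 100 * pennate_abundance / total_abundance,
    pennate_pct_biovolume = 100 * pennate_biovolume / total_biovolume,
    mean_cell_volume = total_biovolume / total_abundance
  )
}
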