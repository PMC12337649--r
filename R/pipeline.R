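campaign_schemas <- function() {
  list(
    scrape = c("date", "day", "site", "filtrate_n", "filtrate_si",
               "blank_n", "blank_si", "extraction_volume", "scrape_chla_mass"),
    core_melt = c("date", "day", "site", "chla_diluted", "abundance_diluted",
                  "biovolume_diluted", "fsw_volume", "melted_ice_volume",
                  "core_section_length"),
    bulk_melt = c("date", "day", "site", "bulk_salinity", "no3_no2", "sioh4"),
    water_column = c("date", "day", "salinity", "no3_no2", "sioh4"),
    currents = c("date", "day", "max_speed")
  )
}

#' Load a campaign from a directory of CSV files
#'
#' Reads and validates the documented campaign tables. \code{scrape.csv},
#' \code{core_melt.csv}, \code{water_column.csv} and \code{currents.csv} are
#' required; \code{bulk_melt.csv} is optional (a 2010-style campaign has no
#' bulk-melt protocol) and \code{truth.csv} is read when present. Rows must
#' be unique per (date, site) within each table; numeric columns must parse;
#' errors name the offending file and columns.
#'
#' @param dir Directory containing the CSVs.
#' @return A list of class \code{"ice_campaign"}.
#' @export
load_campaign <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("campaign directory not found: %s", dir),
                             call. = FALSE)
  schemas <- campaign_schemas()
  out <- list()
  for (nm in names(schemas)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if (nm == "bulk_melt") {
        message("no bulk_melt.csv: bulk-melt stages will be skipped")
        out[[nm]] <- NULL
        next
      }
      stop(sprintf("missing required campaign file: %s", path), call. = FALSE)
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(schemas[[nm]], names(df))
    if (length(missing) > 0L) {
      stop(sprintf("%s: missing column(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    numeric_cols <- setdiff(schemas[[nm]], c("date", "site", "replicate"))
    for (col in numeric_cols) {
      if (!is.numeric(df[[col]])) {
        stop(sprintf("%s: column `%s` is not numeric", path, col), call. = FALSE)
      }
    }
    key_cols <- intersect(c("date", "site", "replicate"), names(df))
    key <- do.call(paste, df[key_cols])
    if (nm != "scrape" && anyDuplicated(key)) {
      stop(sprintf("%s: duplicate (date, site) rows", path), call. = FALSE)
    }
    out[[nm]] <- df
  }
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
  }
  class(out) <- "ice_campaign"
  out
}

#' Per-sample intracellular nutrient estimates from a campaign
#'
#' Joins the scrape and core-melt tables by (day, site) and runs the full
#' estimation chain: FSW-dilution correction of the core-melt measurements,
#' blank correction and averaging of scrape replicates (blank-corrected
#' concentrations and filter chl a masses are averaged per site-day before
#' chl normalization, which keeps blank noise from leveraging the ratio),
#' chl-specific IC pools, bottom-ice IC concentrations, per-cell-volume and
#' per-cell quantities.
#'
#' @param campaign An \code{"ice_campaign"}.
#' @return A data.frame keyed by (day, site): the [ic_profile()] columns plus
#'   \code{chla_vol} (mg m^-3), \code{chla_areal} (mg m^-2),
#'   \code{abundance} and \code{biovolume} per litre of melted ice.
#' @export
derive_ic_estimates <- function(campaign) {
  stopifnot(inherits(campaign, "ice_campaign"))
  sc <- campaign$scrape
  sc$corr_n <- as.numeric(blank_correct(sc$filtrate_n, sc$blank_n))
  sc$corr_si <- as.numeric(blank_correct(sc$filtrate_si, sc$blank_si))
  agg <- stats::aggregate(
    sc[, c("corr_n", "corr_si", "scrape_chla_mass", "extraction_volume")],
    by = list(day = sc$day, site = sc$site), FUN = mean)
  cm <- campaign$core_melt
  m <- merge(agg, cm, by = c("day", "site"))
  if (nrow(m) == 0L) stop("scrape and core_melt tables share no (day, site) keys",
                          call. = FALSE)
  chla_vol <- fsw_dilution_correct(m$chla_diluted, m$fsw_volume, m$melted_ice_volume)
  abundance <- fsw_dilution_correct(m$abundance_diluted, m$fsw_volume, m$melted_ice_volume)
  biovolume <- fsw_dilution_correct(m$biovolume_diluted, m$fsw_volume, m$melted_ice_volume)
  prof <- ic_profile(
    filtrate_n = m$corr_n, filtrate_si = m$corr_si,
    blank_n = 0, blank_si = 0,  # replicates already blank-corrected
    extraction_volume = m$extraction_volume,
    chla_mass = m$scrape_chla_mass,
    bottom_chla = chla_vol, abundance = abundance, biovolume = biovolume)
  out <- cbind(m[, c("day", "site")], prof,
               chla_vol = chla_vol,
               chla_areal = areal_chla(chla_vol, m$core_section_length),
               abundance = abundance, biovolume = biovolume)
  out[order(out$day, out$site), , drop = FALSE]
}

#' Average a site-replicated series per sampling date
#'
#' The three snow-class sites act as replicates of the same bloom; the
#' time-series analyses run on per-date site averages. SD is NA (flagged)
#' for single-site dates.
#'
#' @param df A data.frame with a \code{day} column.
#' @param value Name of the value column to average.
#' @return A data.frame with \code{day}, \code{mean}, \code{sd}, \code{n},
#'   ordered by day.
#' @export
site_average <- function(df, value) {
  stopifnot(value %in% names(df), "day" %in% names(df))
  sp <- split(df[[value]], df$day)
  out <- data.frame(
    day = as.numeric(names(sp)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                numeric(1)),
    n = vapply(sp, length, integer(1)),
    row.names = NULL
  )
  out[order(out$day), , drop = FALSE]
}

#' Dilution-line analysis of bulk-melt nutrients
#'
#' Classifies every bulk-melt sample against the conservative dilution line
#' anchored at the campaign-average 2-m water-column concentration and
#' salinity, for both nutrients; computes per-sample bulk N:Si molar ratios;
#' and compares bulk vs water-column N:Si with a Kruskal-Wallis test.
#' Samples at low bulk salinity (below \code{low_salinity_threshold}) are
#' summarized separately, since conservative behaviour is expected only
#' where little algal material melted in.
#'
#' @param campaign An \code{"ice_campaign"} with a bulk-melt table.
#' @param rel_tolerance,abs_floor Passed to [classify_vs_dilution_line()].
#' @param low_salinity_threshold Salinity below or at which the separate
#'   low-salinity summary applies (default 6.2).
#' @return A list: \code{classification} (per-sample table), \code{line_n},
#'   \code{line_si}, \code{bulk_n_si} (per-sample ratios),
#'   \code{water_n_si}, \code{kw} (Kruskal-Wallis bulk vs water N:Si),
#'   \code{low_salinity} (classification table of the low-salinity subset).
#' @export
analyze_dilution <- function(campaign, rel_tolerance = 0.15, abs_floor = 0.2,
                             low_salinity_threshold = 6.2) {
  stopifnot(inherits(campaign, "ice_campaign"))
  bm <- campaign$bulk_melt
  if (is.null(bm) || nrow(bm) == 0L) {
    stop("campaign has no bulk-melt samples", call. = FALSE)
  }
  wc <- campaign$water_column
  line_n <- dilution_line(mean(wc$no3_no2), mean(wc$salinity))
  line_si <- dilution_line(mean(wc$sioh4), mean(wc$salinity))
  cls <- data.frame(
    day = bm$day, site = bm$site, bulk_salinity = bm$bulk_salinity,
    no3_no2 = bm$no3_no2, sioh4 = bm$sioh4,
    class_n = classify_vs_dilution_line(bm$bulk_salinity, bm$no3_no2, line_n,
                                        rel_tolerance, abs_floor),
    class_si = classify_vs_dilution_line(bm$bulk_salinity, bm$sioh4, line_si,
                                         rel_tolerance, abs_floor),
    n_si = n_si_ratio(bm$no3_no2, bm$sioh4)
  )
  water_ratio <- n_si_ratio(wc$no3_no2, wc$sioh4)
  kw <- kruskal_wallis(list(bulk = cls$n_si, water = water_ratio))
  low <- cls[cls$bulk_salinity <= low_salinity_threshold, , drop = FALSE]
  list(classification = cls, line_n = line_n, line_si = line_si,
       bulk_n_si = cls$n_si, water_n_si = water_ratio, kw = kw,
       low_salinity = low)
}

#' Differential-retention analysis (bulk vs intracellular)
#'
#' Regresses bulk-melt nutrient concentrations on the independently
#' estimated bottom-ice intracellular concentrations with standardized major
#' axis (SMA) regression — both variables carry measurement error, so a
#' symmetric model-II fit is required. With the conservative brine
#' background subtracted from the bulk concentrations, the SMA slope
#' estimates the fraction of the IC pool released during bulk melt: a slope
#' near 1 for nitrate+nitrite (full release) and near 1/11 for silicic acid
#' (release resisted by the cells' silicon storage machinery).
#'
#' @param campaign An \code{"ice_campaign"} with bulk-melt samples.
#' @param subtract_background Subtract the dilution-line brine background
#'   (at each sample's bulk salinity) from the bulk concentration before
#'   regression (default TRUE).
#' @param estimates Optional precomputed [derive_ic_estimates()] table.
#' @return A list: \code{sma_n}, \code{sma_si} (\code{"reg_result"}),
#'   \code{retention_n} (slope for N), \code{retention_si}
#'   (slope for Si), \code{retention_si_reciprocal} (1/slope),
#'   \code{data} (the joined regression table), \code{n}.
#' @export
analyze_retention <- function(campaign, subtract_background = TRUE,
                              estimates = NULL) {
  stopifnot(inherits(campaign, "ice_campaign"))
  bm <- campaign$bulk_melt
  if (is.null(bm) || nrow(bm) == 0L) {
    stop("campaign has no bulk-melt samples", call. = FALSE)
  }
  if (is.null(estimates)) estimates <- derive_ic_estimates(campaign)
  m <- merge(estimates, bm, by = c("day", "site"))
  if (nrow(m) < 3L) {
    stop("fewer than 3 joint bulk/intracellular samples: stage skipped",
         call. = FALSE)
  }
  y_n <- m$no3_no2
  y_si <- m$sioh4
  if (subtract_background) {
    wc <- campaign$water_column
    line_n <- dilution_line(mean(wc$no3_no2), mean(wc$salinity))
    line_si <- dilution_line(mean(wc$sioh4), mean(wc$salinity))
    y_n <- y_n - dilution_concentration(line_n, m$bulk_salinity)
    y_si <- y_si - dilution_concentration(line_si, m$bulk_salinity)
  }
  sma_n <- sma_fit(m$bottom_ice_ic_n, y_n)
  sma_si <- sma_fit(m$bottom_ice_ic_si, y_si)
  list(sma_n = sma_n, sma_si = sma_si,
       retention_n = sma_n$slope,
       retention_si = sma_si$slope,
       retention_si_reciprocal = 1 / sma_si$slope,
       data = data.frame(day = m$day, site = m$site,
                         bottom_ice_ic_n = m$bottom_ice_ic_n,
                         bottom_ice_ic_si = m$bottom_ice_ic_si,
                         bulk_n = y_n, bulk_si = y_si),
       n = nrow(m))
}

#' Tidally forced time-series analysis
#'
#' Runs the seasonal analysis on site-averaged series: OLS trends of areal
#' chl a and of the chl-specific IC-N and IC-Si pools against elapsed time,
#' Pearson correlations of the detrended residuals against the daily
#' maximum under-ice current speed at the requested lags (in sampling
#' cycles, the biological series lagging the forcing), and the log-linear
#' decay fit of the intracellular N:Si ratio.
#'
#' @param campaign An \code{"ice_campaign"}.
#' @param lags Integer lags in sampling cycles (default \code{c(0, 1)}).
#' @param current_match \code{"same_day"} pairs each sampling day with that
#'   day's maximum current; \code{"interpolated"} linearly interpolates the
#'   daily-maximum series onto the sampling days (identical when currents
#'   exist for every sampling day).
#' @param estimates Optional precomputed [derive_ic_estimates()] table.
#' @return A list: \code{series} (site-averaged mean/sd per day for the
#'   three variables), \code{trend_chla}, \code{trend_icb_n},
#'   \code{trend_icb_si} (\code{"reg_result"}), \code{residual_correlations}
#'   (data.frame over variable x lag), \code{n_si_decay}.
#' @export
analyze_temporal <- function(campaign, lags = c(0L, 1L),
                             current_match = c("same_day", "interpolated"),
                             estimates = NULL) {
  stopifnot(inherits(campaign, "ice_campaign"))
  current_match <- match.arg(current_match)
  if (is.null(estimates)) estimates <- derive_ic_estimates(campaign)
  series <- list(
    chla = site_average(estimates, "chla_areal"),
    icb_n = site_average(estimates, "ic_chl_specific_n"),
    icb_si = site_average(estimates, "ic_chl_specific_si")
  )
  days <- series$chla$day
  cur <- campaign$currents
  forcing <- if (current_match == "same_day") {
    cur$max_speed[match(days, cur$day)]
  } else {
    stats::approx(cur$day, cur$max_speed, xout = days, rule = 2)$y
  }
  if (anyNA(forcing)) {
    stop("no current observation for one or more sampling days; use current_match = \"interpolated\"",
         call. = FALSE)
  }
  trends <- lapply(series, function(s) ols_fit(s$day, s$mean))
  resids <- lapply(series, function(s) detrend_linear(s$day, s$mean))
  rc <- do.call(rbind, lapply(names(series), function(v) {
    do.call(rbind, lapply(lags, function(L) {
      ct <- lagged_residual_correlation(resids[[v]], forcing, L)
      data.frame(variable = v, lag = L, r = ct$r, p_value = ct$p_value,
                 n = ct$n, label = significance_label(ct$p_value))
    }))
  }))
  decay <- loglinear_decay_fit(days, series$icb_n$mean / series$icb_si$mean)
  list(series = series, forcing = data.frame(day = days, max_speed = forcing),
       trend_chla = trends$chla, trend_icb_n = trends$icb_n,
       trend_icb_si = trends$icb_si,
       residuals = resids,
       residual_correlations = rc, n_si_decay = decay)
}

#' Season summary statistics
#'
#' Campaign means and SDs of the per-sample estimate table (per-sample
#' quantities first, averaged last).
#'
#' @param estimates A [derive_ic_estimates()] table.
#' @return A data.frame with \code{quantity}, \code{mean}, \code{sd},
#'   \code{n}.
#' @export
season_summary <- function(estimates) {
  cols <- c("chla_areal", "ic_chl_specific_n", "ic_chl_specific_si",
            "bottom_ice_ic_n", "bottom_ice_ic_si",
            "ic_conc_cell_vol_n", "ic_conc_cell_vol_si",
            "ic_content_cell_n", "ic_content_cell_si",
            "abundance", "biovolume", "n_si_ratio")
  cols <- intersect(cols, names(estimates))
  data.frame(
    quantity = cols,
    mean = vapply(cols, function(cl) mean(estimates[[cl]], na.rm = TRUE), numeric(1)),
    sd = vapply(cols, function(cl) stats::sd(estimates[[cl]], na.rm = TRUE), numeric(1)),
    n = vapply(cols, function(cl) sum(!is.na(estimates[[cl]])), integer(1)),
    row.names = NULL
  )
}

#' Run the complete analysis of a campaign
#'
#' Orchestrates the estimation chain and the three analysis stages. The
#' dilution and retention stages require bulk-melt samples and are skipped
#' (with a message) for campaigns without them, mirroring seasons in which
#' only the scrape and FSW-melt protocols were run.
#'
#' @param campaign An \code{"ice_campaign"} (or a directory path, which is
#'   passed to [load_campaign()]).
#' @param ... Passed on to [analyze_temporal()].
#' @return A list of class \code{"ice_analysis"}: \code{estimates},
#'   \code{summary}, \code{dilution}, \code{retention}, \code{temporal}
#'   (the bulk-dependent entries NULL when skipped).
#' @export
analyze_campaign <- function(campaign, ...) {
  if (is.character(campaign)) campaign <- load_campaign(campaign)
  stopifnot(inherits(campaign, "ice_campaign"))
  estimates <- derive_ic_estimates(campaign)
  has_bulk <- !is.null(campaign$bulk_melt) && nrow(campaign$bulk_melt) >= 3L
  dilution <- retention <- NULL
  if (has_bulk) {
    dilution <- analyze_dilution(campaign)
    retention <- analyze_retention(campaign, estimates = estimates)
  } else {
    message("bulk-melt table absent or too small: dilution and retention stages skipped")
  }
  temporal <- analyze_temporal(campaign, estimates = estimates, ...)
  structure(list(estimates = estimates, summary = season_summary(estimates),
                 dilution = dilution, retention = retention,
                 temporal = temporal),
            class = "ice_analysis")
}

#' Write an analysis report to CSV files
#'
#' Serializes the analysis into auditable CSVs: \code{ic_profiles.csv} (the
#' per-sample estimate table), \code{season_summary.csv},
#' \code{regressions.csv} (every fitted line with method, n, estimates, r^2,
#' p and significance label), \code{correlations.csv},
#' \code{dilution_classification.csv} (when available), and a plain-text
#' \code{report.txt} rendered by [format_report()].
#'
#' @param analysis An \code{"ice_analysis"}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "ice_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(analysis$estimates, file.path(dir, "ic_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$summary, file.path(dir, "season_summary.csv"),
                   row.names = FALSE)
  regs <- list(
    trend_chla = analysis$temporal$trend_chla,
    trend_icb_n = analysis$temporal$trend_icb_n,
    trend_icb_si = analysis$temporal$trend_icb_si
  )
  if (!is.null(analysis$retention)) {
    regs$sma_bulk_vs_ic_n <- analysis$retention$sma_n
    regs$sma_bulk_vs_ic_si <- analysis$retention$sma_si
  }
  reg_df <- do.call(rbind, lapply(names(regs), function(nm) {
    r <- regs[[nm]]
    data.frame(analysis = nm, method = r$method, n = r$n, slope = r$slope,
               intercept = r$intercept, r_squared = r$r_squared,
               p_value = r$p_value, label = significance_label(r$p_value))
  }))
  utils::write.csv(reg_df, file.path(dir, "regressions.csv"), row.names = FALSE)
  utils::write.csv(analysis$temporal$residual_correlations,
                   file.path(dir, "correlations.csv"), row.names = FALSE)
  if (!is.null(analysis$dilution)) {
    utils::write.csv(analysis$dilution$classification,
                     file.path(dir, "dilution_classification.csv"),
                     row.names = FALSE)
  }
  writeLines(format_report(analysis), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Render a human-readable analysis summary
#'
#' @param analysis An \code{"ice_analysis"}.
#' @return A character vector of report lines.
#' @export
format_report <- function(analysis) {
  stopifnot(inherits(analysis, "ice_analysis"))
  fmt_reg <- function(nm, r) {
    sprintf("  %-18s %s n=%-3d slope=%.4g intercept=%.4g r2=%.3f p=%.3g [%s]",
            nm, r$method, r$n, r$slope, r$intercept, r$r_squared, r$p_value,
            significance_label(r$p_value))
  }
  lines <- c("Ice-algal intracellular nutrient analysis", "")
  s <- analysis$summary
  lines <- c(lines, "Season summary (mean +/- SD):",
             sprintf("  %-22s %12.4g +/- %.4g  (n=%d)", s$quantity, s$mean,
                     s$sd, s$n), "")
  lines <- c(lines, "Temporal trends (site-averaged):",
             fmt_reg("chl a", analysis$temporal$trend_chla),
             fmt_reg("IC-N^B", analysis$temporal$trend_icb_n),
             fmt_reg("IC-Si^B", analysis$temporal$trend_icb_si), "")
  rc <- analysis$temporal$residual_correlations
  lines <- c(lines, "Detrended residual correlations vs daily max currents:",
             sprintf("  %-8s lag=%d r=%+.3f p=%.3g n=%d [%s]", rc$variable,
                     rc$lag, rc$r, rc$p_value, rc$n, rc$label), "")
  d <- analysis$temporal$n_si_decay
  lines <- c(lines, sprintf(
    "ln(IC N:Si) decay: rate=%.4g per day, r2=%.3f, p=%.3g [%s]",
    d$rate, d$r_squared, d$p_value, significance_label(d$p_value)), "")
  if (!is.null(analysis$retention)) {
    rt <- analysis$retention
    lines <- c(lines, "Differential retention (SMA, brine background subtracted):",
               fmt_reg("bulk N vs IC-N", rt$sma_n),
               fmt_reg("bulk Si vs IC-Si", rt$sma_si),
               sprintf("  estimated N release fraction: %.3f", rt$retention_n),
               sprintf("  estimated Si release fraction: 1/%.2f",
                       rt$retention_si_reciprocal), "")
  }
  if (!is.null(analysis$dilution)) {
    cl <- analysis$dilution$classification
    lines <- c(lines, "Dilution-line classification of bulk-melt samples:",
               sprintf("  N : %s", paste(names(table(cl$class_n)),
                                         table(cl$class_n), collapse = ", ")),
               sprintf("  Si: %s", paste(names(table(cl$class_si)),
                                         table(cl$class_si), collapse = ", ")),
               sprintf("  bulk vs water N:Si Kruskal-Wallis: H=%.3f p=%.3g [%s]",
                       analysis$dilution$kw$H, analysis$dilution$kw$p_value,
                       significance_label(analysis$dilution$kw$p_value)), "")
  }
  c(lines,
    "Note: p values are reported without multiple-testing correction;",
    "p < 0.01 is labelled significant and p <= 0.1 weak.")
}
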