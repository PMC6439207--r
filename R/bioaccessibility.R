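#' Bioaccessible fraction from released and total PAH mass
#'
#' The bioaccessible fraction F_bioa of a particle-bound PAH is the
#' mass released into simulated lung fluid divided by the total mass
#' bound to the particles. Internally all fractions are of 1; percent
#' appears only at I/O boundaries.
#'
#' @param released_mass PAH mass released into the fluid, ng
#'   (0 <= released <= total).
#' @param total_mass Total PAH mass in the particles, ng (> 0).
#' @return F_bioa as a fraction of 1. Vectorized.
#' @examples
#' compute_fbioa(75.41, 10000)  # 0.007541
#' @export
compute_fbioa <- function(released_mass, total_mass) {
  if (any(!is.finite(total_mass) | total_mass <= 0)) {
    stop("total_mass must be > 0", call. = FALSE)
  }
  if (any(!is.finite(released_mass) | released_mass < 0)) {
    stop("released_mass must be >= 0", call. = FALSE)
  }
  if (any(released_mass > total_mass)) {
    stop("released_mass exceeds total_mass: inconsistent measurement",
         call. = FALSE)
  }
  released_mass / total_mass
}

#' Construct a desorption time series
#'
#' One laboratory desorption experiment: cumulative PAH mass released
#' from a particle matrix into a simulated lung fluid over time. The
#' cumulative release must be non-decreasing and never exceed the total
#' loaded mass; noisy series that momentarily decrease are rejected, not
#' monotonized.
#'
#' @param analyte Analyte abbreviation or name.
#' @param fluid Simulated lung fluid label: `"gamble"`, `"alf"`,
#'   `"self"` or free text.
#' @param matrix Particle-matrix label (e.g. `"W300"`, `"PM2.5"`).
#' @param total_ng Total PAH mass loaded on the particles, ng (> 0).
#' @param time_h Sampling times, hours, non-negative and increasing.
#' @param cum_released_ng Cumulative released mass at each time, ng.
#' @return An object of class `desorption_series`.
#' @export
desorption_series <- function(analyte, fluid, matrix, total_ng,
                              time_h, cum_released_ng) {
  if (length(time_h) < 1) {
    stop("a desorption series needs at least one timepoint", call. = FALSE)
  }
  if (length(time_h) != length(cum_released_ng)) {
    stop("time_h and cum_released_ng lengths differ", call. = FALSE)
  }
  if (!isTRUE(total_ng > 0)) stop("total_ng must be > 0", call. = FALSE)
  if (any(time_h < 0)) stop("time_h must be >= 0", call. = FALSE)
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("time_h must be strictly increasing", call. = FALSE)
  }
  if (any(diff(cum_released_ng) < 0)) {
    stop(sprintf(
      "series %s/%s/%s: cumulative release decreases over time",
      analyte, fluid, matrix), call. = FALSE)
  }
  if (any(cum_released_ng < 0) || any(cum_released_ng > total_ng)) {
    stop(sprintf(
      "series %s/%s/%s: cumulative release outside [0, total_ng]",
      analyte, fluid, matrix), call. = FALSE)
  }
  structure(
    list(analyte = analyte, fluid = fluid, matrix = matrix,
         total_ng = total_ng,
         points = data.frame(time_h = time_h,
                             cum_released_ng = cum_released_ng)),
    class = "desorption_series"
  )
}

#' @export
print.desorption_series <- function(x, ...) {
  cat(sprintf(
    "Desorption series: %s in %s on %s (%g ng total, %d timepoints)\n",
    x$analyte, x$fluid, x$matrix, x$total_ng, nrow(x$points)))
  invisible(x)
}

#' Bioaccessibility measurement record
#'
#' @param analyte Analyte abbreviation or name.
#' @param fluid Simulated lung fluid label.
#' @param matrix Particle-matrix label.
#' @param f_bioa Bioaccessible fraction of 1, or `NA` for a missing
#'   measurement (never imputed downstream).
#' @return An object of class `bioaccessibility_measurement`.
#' @export
bioaccessibility_measurement <- function(analyte, fluid, matrix, f_bioa) {
  if (!is.na(f_bioa) && (f_bioa < 0 || f_bioa > 1)) {
    stop("f_bioa must lie in [0, 1] when present", call. = FALSE)
  }
  structure(
    list(analyte = analyte, fluid = fluid, matrix = matrix,
         f_bioa = f_bioa),
    class = "bioaccessibility_measurement"
  )
}

#' Reduce a desorption series to a bioaccessibility measurement
#'
#' F_bioa is defined as the total extent of desorption: the final
#' (maximal) cumulative released mass divided by the total loaded mass.
#' No kinetic asymptote is fitted.
#'
#' @param series A [desorption_series()].
#' @return A [bioaccessibility_measurement()] carrying the analyte,
#'   fluid and matrix labels of the series.
#' @export
fbioa_from_series <- function(series) {
  stopifnot(inherits(series, "desorption_series"))
  released <- max(series$points$cum_released_ng)
  bioaccessibility_measurement(
    series$analyte, series$fluid, series$matrix,
    compute_fbioa(released, series$total_ng)
  )
}

#' Loading efficiency of PAHs on a particle matrix
#'
#' Quality-control check for spiked-particle preparation: the fraction
#' of the applied PAH mass recovered on the particles. A warning is
#' raised when the efficiency falls below `threshold`, signalling
#' incomplete loading.
#'
#' @param applied_mass PAH mass applied, ng (> 0).
#' @param recovered_mass PAH mass recovered on the particles, ng (>= 0).
#' @param threshold QC threshold as a fraction of 1; default 0.9.
#' @return Loading efficiency as a fraction of 1.
#' @export
loading_efficiency <- function(applied_mass, recovered_mass,
                               threshold = 0.9) {
  if (any(!is.finite(applied_mass) | applied_mass <= 0)) {
    stop("applied_mass must be > 0", call. = FALSE)
  }
  if (any(recovered_mass < 0)) {
    stop("recovered_mass must be >= 0", call. = FALSE)
  }
  eff <- recovered_mass / applied_mass
  if (any(eff < threshold)) {
    warning(sprintf(
      "loading efficiency %s below QC threshold %.2f",
      paste(sprintf("%.3f", eff[eff < threshold]), collapse = ", "),
      threshold), call. = FALSE)
  }
  eff
}

#' Solid-water distribution coefficient
#'
#' Standard ratio definition Kd = sorbed concentration / aqueous
#' concentration. Inputs in ng/g (solid) and ng/L (aqueous) give L/g;
#' the result is returned in the conventional L/kg (x 1000).
#'
#' @param sorbed_conc Concentration on the solid, ng/g (>= 0).
#' @param aqueous_conc Concentration in solution, ng/L (> 0).
#' @return Kd in L/kg. Vectorized.
#' @examples
#' compute_kd(100, 100)  # 1000 L/kg
#' @export
compute_kd <- function(sorbed_conc, aqueous_conc) {
  if (any(!is.finite(aqueous_conc) | aqueous_conc <= 0)) {
    stop("aqueous_conc must be > 0", call. = FALSE)
  }
  if (any(sorbed_conc < 0)) {
    stop("sorbed_conc must be >= 0", call. = FALSE)
  }
  sorbed_conc / aqueous_conc * 1000
}

#' Read desorption series from CSV
#'
#' Expected columns: `analyte,fluid,matrix,total_ng,time_h,cum_released_ng`,
#' one row per timepoint; rows sharing (analyte, fluid, matrix) form one
#' series. UTF-8, comma-separated, `.` decimal, header mandatory.
#'
#' @param path CSV file path.
#' @return A list of [desorption_series()] objects.
#' @export
read_desorption_csv <- function(path) {
  df <- read_csv_checked(
    path, c("analyte", "fluid", "matrix", "total_ng", "time_h",
            "cum_released_ng"))
  key <- interaction(df$analyte, df$fluid, df$matrix, drop = TRUE,
                     lex.order = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    if (length(unique(g$total_ng)) != 1) {
      stop(sprintf("series %s/%s/%s: total_ng differs across rows",
                   g$analyte[1], g$fluid[1], g$matrix[1]), call. = FALSE)
    }
    desorption_series(g$analyte[1], g$fluid[1], g$matrix[1],
                      g$total_ng[1], g$time_h, g$cum_released_ng)
  })
}

#' Write desorption series to CSV
#'
#' @param series_list A list of [desorption_series()] objects (or one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_desorption_csv <- function(series_list, path) {
  if (inherits(series_list, "desorption_series")) {
    series_list <- list(series_list)
  }
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(analyte = s$analyte, fluid = s$fluid, matrix = s$matrix,
               total_ng = s$total_ng, time_h = s$points$time_h,
               cum_released_ng = s$points$cum_released_ng,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bioaccessibility CSV
#'
#' Expected columns: `analyte,fluid,matrix,fbioa_percent`; an empty
#' `fbioa_percent` field marks a missing measurement. Percent values
#' are converted to fractions of 1.
#'
#' @param path CSV file path.
#' @return A data.frame with columns `analyte`, `fluid`, `matrix`,
#'   `f_bioa` (fraction of 1, `NA` when missing).
#' @export
read_fbioa_csv <- function(path) {
  df <- read_csv_checked(path, c("analyte", "fluid", "matrix",
                                 "fbioa_percent"))
  f <- df$fbioa_percent / 100
  if (any(!is.na(f) & (f < 0 | f > 1))) {
    stop("fbioa_percent outside [0, 100]", call. = FALSE)
  }
  data.frame(analyte = df$analyte, fluid = df$fluid, matrix = df$matrix,
             f_bioa = f, stringsAsFactors = FALSE)
}

# Shared CSV reader: header mandatory, named schema errors.
read_csv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error in '", path, "': missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop("schema error in '", path, "': no data rows", call. = FALSE)
  }
  df
}
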