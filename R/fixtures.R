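#' Bundled reference datasets
#'
#' Three reference tables ship with the package as plain CSV under
#' `inst/extdata`, covering every input the bundled assessments need:
#'
#' * `"table1"` — bioaccessible fractions of phenanthrene and pyrene on
#'   12 biochar fine-particle matrices in Gamble's solution and
#'   artificial lysosomal fluid (ALF) at a median loading of 10 ug/g
#'   (48 measurements).
#' * `"table2"` — bioaccessible fractions in Gamble's solution for
#'   three of those biochars (W500, C500, S500) at 10, 50 and
#'   100 ug/g loadings (18 measurements; non-monotone in loading and
#'   preserved verbatim, no smoothing).
#' * `"pm25"` — an urban PM2.5 PAH profile: 15 analytes (BbF and BkF
#'   combined) with TEF, mean ambient concentration and bioaccessible
#'   fraction in simulated epithelial lung fluid; naphthalene has no
#'   bioaccessibility measurement. Stores both the canonical
#'   higher-precision F_bioa (`fbioa_percent`) and the
#'   3-significant-figure display values (`fbioa_display_percent`).
#'
#' Columns named `*_printed` or `risk_*` are expected-output values at
#' their source's printed precision; they are regression oracles for
#' the model operations, never model inputs.
#'
#' @param name One of `"table1"`, `"table2"`, `"pm25"`.
#' @return A data.frame with units normalised to package conventions;
#'   a `f_bioa` column (fraction of 1, `NA` when missing) is added
#'   alongside the percent column, and `"pm25"` gains `tc_ng_m3`
#'   (alias of `c_ng_m3`) for the TEQ model.
#' @examples
#' t1 <- load_fixture("table1")
#' subset(t1, matrix == "W300" & fluid == "gamble")
#' @export
load_fixture <- function(name = c("table1", "table2", "pm25")) {
  name <- match.arg(name)
  man <- fixture_manifest()
  path <- system.file("extdata", man$file[man$name == name],
                      package = "pahlung", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  df$f_bioa <- df$fbioa_percent / 100
  if (name == "pm25") df$tc_ng_m3 <- df$c_ng_m3
  df
}

#' Fixture manifest
#'
#' Lists the bundled datasets with their file names, units and MD5
#' checksums. [verify_fixtures()] checks the shipped files against
#' these checksums, guarding against silent edits of the reference
#' values.
#'
#' @return The manifest as a data.frame (`name`, `file`, `description`,
#'   `units`, `md5`).
#' @export
fixture_manifest <- function() {
  path <- system.file("extdata", "manifest.csv", package = "pahlung",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Verify bundled fixtures against their manifest checksums
#'
#' @return `TRUE` invisibly if every fixture matches; otherwise an
#'   error naming the mismatching file.
#' @export
verify_fixtures <- function() {
  man <- fixture_manifest()
  for (i in seq_len(nrow(man))) {
    path <- system.file("extdata", man$file[i], package = "pahlung",
                        mustWork = TRUE)
    got <- unname(tools::md5sum(path))
    if (!identical(got, man$md5[i])) {
      stop(sprintf("fixture '%s' checksum mismatch (%s != %s)",
                   man$file[i], got, man$md5[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Configuration for the synthetic desorption generator
#'
#' The generator emulates a single-compartment first-order release:
#' cumulative release = total x plateau x (1 - exp(-rate x t)), sampled
#' at `n_timepoints` evenly spaced times up to `horizon_h`, with
#' multiplicative Gaussian noise applied to the per-interval release
#' increments (negative noisy increments are truncated to zero) so the
#' series stays monotone and below the total by construction. Only the
#' plateau carries scientific meaning for the bioaccessibility models;
#' the first-order shape is a convenience, not a kinetic claim.
#'
#' @param plateau_fraction Asymptotic released fraction of total,
#'   in (0, 1].
#' @param rate_per_h First-order release rate, 1/h (> 0). Default 0.5.
#' @param n_timepoints Number of sampling times (>= 1). Default 24.
#' @param horizon_h Last sampling time, h (> 0). Default 24, giving
#'   horizon x rate = 12 with the defaults, i.e. a fully developed
#'   plateau.
#' @param noise_sigma Relative standard deviation of the increment
#'   noise (>= 0). Default 0.
#' @param seed Integer RNG seed; identical configs generate identical
#'   series.
#' @return An object of class `desorption_config`.
#' @export
desorption_config <- function(plateau_fraction, rate_per_h = 0.5,
                              n_timepoints = 24, horizon_h = 24,
                              noise_sigma = 0, seed = 1L) {
  if (!isTRUE(plateau_fraction > 0 && plateau_fraction <= 1)) {
    stop("plateau_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!isTRUE(rate_per_h > 0)) stop("rate_per_h must be > 0", call. = FALSE)
  if (!isTRUE(n_timepoints >= 1)) {
    stop("n_timepoints must be >= 1", call. = FALSE)
  }
  if (!isTRUE(horizon_h > 0)) stop("horizon_h must be > 0", call. = FALSE)
  if (!isTRUE(noise_sigma >= 0)) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  structure(
    list(plateau_fraction = plateau_fraction, rate_per_h = rate_per_h,
         n_timepoints = as.integer(n_timepoints), horizon_h = horizon_h,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "desorption_config"
  )
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic desorption series
#'
#' @param config A [desorption_config()].
#' @param total_mass Total PAH mass loaded, ng (> 0).
#' @param analyte,fluid,matrix Labels carried on the series.
#' @return A [desorption_series()] satisfying all series invariants.
#' @examples
#' cfg <- desorption_config(plateau_fraction = 0.196, noise_sigma = 0.02,
#'                          seed = 42)
#' s <- generate_desorption(cfg, total_mass = 10000)
#' fbioa_from_series(s)$f_bioa  # close to 0.196
#' @export
generate_desorption <- function(config, total_mass,
                                analyte = "synthetic", fluid = "gamble",
                                matrix = "synthetic") {
  stopifnot(inherits(config, "desorption_config"))
  if (!isTRUE(total_mass > 0)) stop("total_mass must be > 0", call. = FALSE)
  t <- seq(config$horizon_h / config$n_timepoints, config$horizon_h,
           length.out = config$n_timepoints)
  clean <- total_mass * config$plateau_fraction *
    (1 - exp(-config$rate_per_h * t))
  increments <- diff(c(0, clean))
  noisy <- if (config$noise_sigma > 0) {
    with_local_seed(config$seed, {
      pmax(0, increments *
             (1 + stats::rnorm(length(increments), 0, config$noise_sigma)))
    })
  } else {
    increments
  }
  cum <- pmin(cumsum(noisy), total_mass)
  desorption_series(analyte, fluid, matrix, total_mass, t, cum)
}
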