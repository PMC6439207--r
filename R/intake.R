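#' Acceptable daily intake (ADI) for a PAH
#'
#' ADI = CR / (IPF_BaP x TEF): the daily intake corresponding to the
#' target lifetime cancer risk CR, given the inhalation potency factor
#' of benzo[a]pyrene and the analyte's toxic equivalency factor. With
#' the defaults (CR = 1e-6, IPF = 3.9e-3 (ng/kg/day)^-1) a TEF of 0.001
#' gives the maximum ADI of about 0.26 ng/kg/day.
#'
#' @param tox A [toxicity_parameters()] object.
#' @param tef Toxic equivalency factor, > 0. Vectorized.
#' @return ADI in ng/kg/day.
#' @examples
#' compute_adi(toxicity_parameters(), 0.001)  # 0.2564...
#' compute_adi(toxicity_parameters(), 1)      # 0.000256... (BaP)
#' @export
compute_adi <- function(tox, tef) {
  if (any(!is.finite(tef) | tef <= 0)) {
    stop("tef must be > 0: ADI is undefined otherwise", call. = FALSE)
  }
  tox$cr / (tox$ipf_bap * tef)
}

#' Daily intake from a particle-matrix scenario
#'
#' DI = q_PAH x F_bioa x TR x C_particle x V_resp / BW, the inhaled
#' daily dose of a PAH carried on airborne particles characterised by
#' their PAH mass fraction. Total-concentration mode is the special case
#' `f_bioa = 1`.
#'
#' @param q_pah PAH mass fraction in the particles, ng/g (>= 0).
#' @param f_bioa Bioaccessible fraction of 1 (0 <= f_bioa <= 1).
#' @param scenario An [exposure_scenario()] with `c_particle` set
#'   (g/m3).
#' @return DI in ng/kg/day. Vectorized over `q_pah` and `f_bioa`.
#' @examples
#' # extreme biochar scenario, 10 ug/g loading, total concentration:
#' compute_di_matrix(10000, 1, extreme_biochar_scenario())  # 14
#' @export
compute_di_matrix <- function(q_pah, f_bioa, scenario) {
  if (is.na(scenario$c_particle)) {
    stop("scenario has no c_particle: the particle-matrix DI model ",
         "requires a particle concentration (g/m3)", call. = FALSE)
  }
  check_fraction(f_bioa, "f_bioa")
  if (any(q_pah < 0)) stop("q_pah must be >= 0", call. = FALSE)
  q_pah * f_bioa * scenario$tr * scenario$c_particle * scenario$v_resp /
    scenario$bw
}

#' Daily intake from an ambient-air scenario
#'
#' DI = C_PAH x F_bioa x TR x V_resp / BW, the inhaled daily dose of a
#' PAH present in ambient air at concentration C_PAH (e.g. bound to
#' PM2.5). Total-concentration mode is the special case `f_bioa = 1`.
#'
#' @param c_pah Ambient PAH concentration, ng/m3 (>= 0).
#' @param f_bioa Bioaccessible fraction of 1.
#' @param scenario An [exposure_scenario()].
#' @return DI in ng/kg/day. Vectorized over `c_pah` and `f_bioa`.
#' @examples
#' compute_di_ambient(2.30, 0.2128, exposure_scenario())  # 0.12236
#' @export
compute_di_ambient <- function(c_pah, f_bioa, scenario) {
  check_fraction(f_bioa, "f_bioa")
  if (any(c_pah < 0)) stop("c_pah must be >= 0", call. = FALSE)
  c_pah * f_bioa * scenario$tr * scenario$v_resp / scenario$bw
}

#' Classify a daily intake against its acceptable daily intake
#'
#' Risk is unacceptable ("risky") when DI exceeds ADI. The boundary
#' DI == ADI is classified acceptable by default; set
#' `boundary_risky = TRUE` for the opposite convention.
#'
#' @param di Daily intake, ng/kg/day.
#' @param adi Acceptable daily intake, ng/kg/day (> 0).
#' @param boundary_risky Treat DI == ADI as risky? Default `FALSE`.
#' @return Logical: `TRUE` when the risk is unacceptable. Vectorized.
#' @export
classify_intake <- function(di, adi, boundary_risky = FALSE) {
  if (any(!is.finite(adi) | adi <= 0)) {
    stop("adi must be > 0", call. = FALSE)
  }
  if (boundary_risky) di >= adi else di > adi
}

#' Ratio of total-based to bioaccessibility-based daily intake
#'
#' For identical inputs DI(total)/DI(bioaccessible) = 1 / F_bioa, the
#' factor by which ignoring bioaccessibility inflates the estimated
#' dose.
#'
#' @param f_bioa Bioaccessible fraction of 1 (0 < f_bioa <= 1).
#' @return Dimensionless ratio >= 1. Vectorized.
#' @examples
#' di_ratio(0.0213)  # ~47
#' @export
di_ratio <- function(f_bioa) {
  if (any(!is.finite(f_bioa) | f_bioa <= 0)) {
    stop("f_bioa must be > 0", call. = FALSE)
  }
  if (any(f_bioa > 1)) stop("f_bioa must be <= 1", call. = FALSE)
  1 / f_bioa
}

check_fraction <- function(x, what) {
  if (any(!is.na(x) & (x < 0 | x > 1))) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Assess a table of analytes with the DI/ADI model
#'
#' Runs the daily-intake model over a table of analytes in one or both
#' modes and classifies each result against its ADI. In
#' total-concentration mode F_bioa is fixed at exactly 1; in
#' bioaccessibility mode analytes with a missing F_bioa are reported as
#' "not assessed", never silently zero, and are excluded from
#' summaries.
#'
#' @param data A data.frame with column `analyte` plus, for
#'   `route = "ambient"`, `c_ng_m3` (ambient concentration) or, for
#'   `route = "matrix"`, `q_ug_g` (PAH loading, ug/g; converted x1000
#'   to the internal ng/g). Bioaccessibility comes from `fbioa_percent`
#'   (empty/`NA` = missing). Optional columns `fluid` and `matrix` are
#'   carried through.
#' @param scenario An [exposure_scenario()]; `route = "matrix"`
#'   requires `c_particle`.
#' @param tox A [toxicity_parameters()] object.
#' @param pahs Analyte registry table used to resolve TEFs (see
#'   [default_pahs()]).
#' @param mode `"both"` (default), `"total"` or `"bioaccessible"`.
#' @param route `"ambient"` (DI from air concentration) or `"matrix"`
#'   (DI from particle loading).
#' @param boundary_risky Passed to [classify_intake()].
#' @return A data.frame with one row per analyte and mode: `analyte`,
#'   `fluid`, `matrix`, `mode`, `f_bioa`, `di_ng_kg_day`,
#'   `adi_ng_kg_day`, `risky` (logical, `NA` when not assessed),
#'   `note`, `provenance` (`"matrix"` or `"ambient"` DI model).
#' @examples
#' pm <- load_fixture("pm25")
#' res <- assess_intake_table(pm, mode = "both", route = "ambient")
#' subset(res, risky & mode == "bioaccessible")$analyte
#' @export
assess_intake_table <- function(data,
                                scenario = exposure_scenario(),
                                tox = toxicity_parameters(),
                                pahs = default_pahs(),
                                mode = c("both", "total", "bioaccessible"),
                                route = c("ambient", "matrix"),
                                boundary_risky = FALSE) {
  mode <- match.arg(mode)
  route <- match.arg(route)
  modes <- if (mode == "both") c("total", "bioaccessible") else mode
  if (nrow(data) == 0) return(empty_intake_result())

  idx <- pah_lookup(pahs, data$analyte)
  tef <- pahs$tef[idx]
  adi <- compute_adi(tox, tef)
  f_bioa <- if ("fbioa_percent" %in% names(data)) {
    data$fbioa_percent / 100
  } else if ("f_bioa" %in% names(data)) {
    data$f_bioa
  } else {
    rep(NA_real_, nrow(data))
  }
  check_fraction(f_bioa, "f_bioa")
  fluid <- if ("fluid" %in% names(data)) data$fluid else NA_character_
  matrix_lab <- if ("matrix" %in% names(data)) data$matrix else
    NA_character_

  out <- lapply(modes, function(m) {
    f_used <- if (m == "total") rep(1, nrow(data)) else f_bioa
    assessed <- !is.na(f_used)
    di <- rep(NA_real_, nrow(data))
    if (route == "ambient") {
      if (!"c_ng_m3" %in% names(data)) {
        stop("schema error: ambient route requires column c_ng_m3",
             call. = FALSE)
      }
      di[assessed] <- compute_di_ambient(data$c_ng_m3[assessed],
                                         f_used[assessed], scenario)
    } else {
      if (!"q_ug_g" %in% names(data)) {
        stop("schema error: matrix route requires column q_ug_g",
             call. = FALSE)
      }
      di[assessed] <- compute_di_matrix(data$q_ug_g[assessed] * 1000,
                                        f_used[assessed], scenario)
    }
    risky <- rep(NA, nrow(data))
    risky[assessed] <- classify_intake(di[assessed], adi[assessed],
                                       boundary_risky)
    data.frame(
      analyte = pahs$abbreviation[idx], fluid = fluid,
      matrix = matrix_lab, mode = m, f_bioa = f_used,
      di_ng_kg_day = di, adi_ng_kg_day = adi, risky = risky,
      note = ifelse(assessed, "", "not assessed: missing F_bioa"),
      provenance = route, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

empty_intake_result <- function() {
  data.frame(analyte = character(), fluid = character(),
             matrix = character(), mode = character(),
             f_bioa = numeric(), di_ng_kg_day = numeric(),
             adi_ng_kg_day = numeric(), risky = logical(),
             note = character(), provenance = character(),
             stringsAsFactors = FALSE)
}
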