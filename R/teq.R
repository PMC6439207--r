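#' Acceptable BaP-equivalent concentration (ATEQ)
#'
#' ATEQ = CR / UR: the ambient BaP-equivalent concentration at which
#' lifetime exposure corresponds to the target cancer risk CR. With the
#' defaults (CR = 1e-6, UR = 8.7e-5 (ng/m3)^-1) this is about
#' 0.0115 ng/m3.
#'
#' @param tox A [toxicity_parameters()] object.
#' @return ATEQ in ng BaP-eq/m3.
#' @export
compute_ateq <- function(tox) {
  if (!isTRUE(tox$ur > 0)) stop("ur must be > 0", call. = FALSE)
  tox$cr / tox$ur
}

#' Acceptable ambient concentration for a PAH
#'
#' AC = ATEQ / TEF = (CR / UR) / TEF: the analyte-specific ambient
#' concentration whose BaP-equivalent equals ATEQ. AC values are always
#' recomputed from the constants, never tabulated.
#'
#' @param tox A [toxicity_parameters()] object.
#' @param tef Toxic equivalency factor, > 0. Vectorized.
#' @return AC in ng/m3.
#' @examples
#' compute_ac(toxicity_parameters(), 0.01)  # ~1.15 ng/m3
#' @export
compute_ac <- function(tox, tef) {
  if (any(!is.finite(tef) | tef <= 0)) {
    stop("tef must be > 0: AC is undefined otherwise", call. = FALSE)
  }
  compute_ateq(tox) / tef
}

#' Bioaccessible ambient concentration
#'
#' BC = TC x F_bioa: the part of the total ambient concentration that
#' is released in simulated lung fluid and thus available for uptake.
#'
#' @param tc Total ambient concentration, ng/m3 (>= 0).
#' @param f_bioa Bioaccessible fraction of 1.
#' @return BC in ng/m3. Vectorized.
#' @export
compute_bc <- function(tc, f_bioa) {
  if (any(tc < 0)) stop("tc must be >= 0", call. = FALSE)
  check_fraction(f_bioa, "f_bioa")
  tc * f_bioa
}

#' BaP-equivalent concentration of a PAH
#'
#' TEQ = TC x TEF: the analyte's concentration expressed in
#' benzo[a]pyrene equivalents.
#'
#' @param tc Ambient concentration, ng/m3 (>= 0).
#' @param tef Toxic equivalency factor (>= 0).
#' @return TEQ in ng BaP-eq/m3. Vectorized.
#' @export
compute_teq <- function(tc, tef) {
  if (any(tc < 0)) stop("tc must be >= 0", call. = FALSE)
  if (any(tef < 0)) stop("tef must be >= 0", call. = FALSE)
  tc * tef
}

#' Classify a concentration against its acceptable concentration
#'
#' Risk is unacceptable when the concentration exceeds AC; the boundary
#' is acceptable, matching [classify_intake()]. Algebraically
#' `conc > AC` is equivalent to `conc x TEF > ATEQ`, so classification
#' may be done per-analyte or in BaP-equivalent space interchangeably.
#'
#' @param conc Total or bioaccessible concentration, ng/m3.
#' @param ac Acceptable concentration, ng/m3 (> 0).
#' @param boundary_risky Treat conc == AC as risky? Default `FALSE`.
#' @return Logical: `TRUE` when the risk is unacceptable. Vectorized.
#' @export
classify_teq <- function(conc, ac, boundary_risky = FALSE) {
  if (any(!is.finite(ac) | ac <= 0)) stop("ac must be > 0", call. = FALSE)
  if (boundary_risky) conc >= ac else conc > ac
}

#' Assess a table of analytes with the BaP-TEQ concentration model
#'
#' For each analyte computes the acceptable concentration AC from the
#' toxicity constants and the analyte's TEF, the BaP-equivalent
#' concentration TEQ, and (where F_bioa is available) the bioaccessible
#' concentration BC, then classifies both the total and the
#' bioaccessible concentration against AC. Analytes with a missing
#' F_bioa get `risky_bioaccessible = NA` ("not assessed").
#'
#' @param data A data.frame with columns `analyte`, `tc_ng_m3` and
#'   `fbioa_percent` (empty/`NA` = missing; `f_bioa` as fraction also
#'   accepted).
#' @param tox A [toxicity_parameters()] object.
#' @param pahs Analyte registry table (see [default_pahs()]).
#' @param boundary_risky Passed to [classify_teq()].
#' @return A data.frame with columns `analyte`, `tc_ng_m3`, `f_bioa`,
#'   `bc_ng_m3`, `ac_ng_m3`, `teq_ng_m3`, `risky_total`,
#'   `risky_bioaccessible` (logical, `NA` when not assessed), `note`.
#' @examples
#' pm <- load_fixture("pm25")
#' pm$tc_ng_m3 <- pm$c_ng_m3
#' res <- assess_teq_table(pm)
#' res$analyte[res$risky_total & !res$risky_bioaccessible %in% TRUE]
#' @export
assess_teq_table <- function(data,
                             tox = toxicity_parameters(),
                             pahs = default_pahs(),
                             boundary_risky = FALSE) {
  if (nrow(data) == 0) {
    return(data.frame(analyte = character(), tc_ng_m3 = numeric(),
                      f_bioa = numeric(), bc_ng_m3 = numeric(),
                      ac_ng_m3 = numeric(), teq_ng_m3 = numeric(),
                      risky_total = logical(),
                      risky_bioaccessible = logical(),
                      note = character(), stringsAsFactors = FALSE))
  }
  if (!"tc_ng_m3" %in% names(data)) {
    stop("schema error: TEQ assessment requires column tc_ng_m3",
         call. = FALSE)
  }
  idx <- pah_lookup(pahs, data$analyte)
  tef <- pahs$tef[idx]
  f_bioa <- if ("fbioa_percent" %in% names(data)) {
    data$fbioa_percent / 100
  } else if ("f_bioa" %in% names(data)) {
    data$f_bioa
  } else {
    rep(NA_real_, nrow(data))
  }
  check_fraction(f_bioa, "f_bioa")

  ac <- compute_ac(tox, tef)
  teq <- compute_teq(data$tc_ng_m3, tef)
  bc <- rep(NA_real_, nrow(data))
  assessed <- !is.na(f_bioa)
  bc[assessed] <- compute_bc(data$tc_ng_m3[assessed], f_bioa[assessed])
  risky_bio <- rep(NA, nrow(data))
  risky_bio[assessed] <- classify_teq(bc[assessed], ac[assessed],
                                      boundary_risky)
  data.frame(
    analyte = pahs$abbreviation[idx],
    tc_ng_m3 = data$tc_ng_m3, f_bioa = f_bioa, bc_ng_m3 = bc,
    ac_ng_m3 = ac, teq_ng_m3 = teq,
    risky_total = classify_teq(data$tc_ng_m3, ac, boundary_risky),
    risky_bioaccessible = risky_bio,
    note = ifelse(assessed, "", "not assessed: missing F_bioa"),
    stringsAsFactors = FALSE
  )
}
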