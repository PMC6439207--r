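#' Default PAH analyte registry
#'
#' Returns the 15 analytes assessed in the bundled PM2.5 profile: the 16
#' US-EPA priority PAHs with benzo(b)fluoranthene and benzo(k)fluoranthene
#' treated as one combined analyte ("BbF+BkF"), each with its
#' benzo[a]pyrene toxic equivalency factor (TEF, BaP = 1) and aromatic
#' ring count.
#'
#' @return A data.frame with columns `name`, `abbreviation`, `tef`
#'   (dimensionless, > 0), `combined` (logical; `TRUE` only for the
#'   BbF+BkF pair) and `rings` (integer).
#' @examples
#' pahs <- default_pahs()
#' pahs[pahs$abbreviation == "BaP", ]
#' @export
default_pahs <- function() {
  data.frame(
    name = c("naphthalene", "acenaphthylene", "acenaphthene", "fluorene",
             "phenanthrene", "anthracene", "fluoranthene", "pyrene",
             "benzo(a)anthracene", "chrysene",
             "benzo(b)fluoranthene + benzo(k)fluoranthene",
             "benzo(a)pyrene", "indeno(1,2,3-cd)pyrene",
             "dibenz(a,h)anthracene", "benzo(g,h,i)perylene"),
    abbreviation = c("Nap", "Acl", "Ace", "Flu", "Phe", "Ant", "FA", "Pyr",
                     "BaA", "Chr", "BbF+BkF", "BaP", "Ind", "DBahA",
                     "BghiP"),
    tef = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.01, 0.001,
            0.1, 0.01, 0.2, 1, 0.1, 1, 0.01),
    combined = c(rep(FALSE, 10), TRUE, rep(FALSE, 4)),
    rings = c(2L, 3L, 3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 5L, 5L, 6L, 5L, 6L),
    stringsAsFactors = FALSE
  )
}

#' Toxicity constants for inhalation cancer-risk assessment
#'
#' Bundles the constants shared by the DI/ADI model and the BaP-TEQ
#' concentration model: the target lifetime cancer risk CR, its
#' acceptable range, the inhalation potency factor of benzo[a]pyrene
#' (IPF, converting daily intake to lifetime risk) and the WHO unit risk
#' (UR, lifetime risk per ng/m3 of BaP-equivalent exposure over 70
#' years; the lifetime assumption is metadata, no time integration is
#' performed).
#'
#' @param cr Target carcinogenic risk (dimensionless). Default `1e-6`,
#'   the conventional choice for an individual carcinogen.
#' @param cr_range Closed interval of acceptable risks containing `cr`.
#'   Default `c(1e-6, 1e-4)`.
#' @param ipf_bap Inhalation potency factor for BaP, (ng/kg/day)^-1.
#'   Default `3.9e-3`.
#' @param ur Unit risk for BaP-equivalent exposure, (ng/m3)^-1.
#'   Default `8.7e-5`.
#' @return An object of class `toxicity_parameters`.
#' @examples
#' tox <- toxicity_parameters()
#' compute_ateq(tox) # acceptable BaP-equivalent concentration, ng/m3
#' @export
toxicity_parameters <- function(cr = 1e-6, cr_range = c(1e-6, 1e-4),
                                ipf_bap = 3.9e-3, ur = 8.7e-5) {
  out <- structure(
    list(cr = cr, cr_range = cr_range, ipf_bap = ipf_bap, ur = ur),
    class = "toxicity_parameters"
  )
  stop_on_violations(validate_toxicity(out))
  out
}

#' Inhalation exposure scenario
#'
#' Exposure-factor set for the daily-intake models. Canonical internal
#' units: air volume m3, particle mass g, PAH mass ng, body mass kg,
#' time day. File loaders convert from the boundary units (ug/g
#' loadings, mg/m3 particle concentrations) before reaching this
#' constructor.
#'
#' @param tr Tracheobronchial retention, fraction of inhaled particles
#'   retained in the airways (0 < tr <= 1). Default 0.75.
#' @param v_resp Adult inhalation rate, m3/day. Default 20.
#' @param bw Adult body weight, kg. Default 60.
#' @param c_particle Optional particle concentration in air, g/m3.
#'   Required by the particle-matrix DI model.
#' @param q_pah Optional PAH mass fraction in the particle, ng/g.
#' @return An object of class `exposure_scenario`.
#' @seealso [extreme_biochar_scenario()] for the high-pollution biochar
#'   scenario used by the bundled biochar assessments.
#' @export
exposure_scenario <- function(tr = 0.75, v_resp = 20, bw = 60,
                              c_particle = NA_real_, q_pah = NA_real_) {
  out <- structure(
    list(tr = tr, v_resp = v_resp, bw = bw,
         c_particle = c_particle, q_pah = q_pah),
    class = "exposure_scenario"
  )
  stop_on_violations(validate_scenario(out))
  out
}

#' Extreme biochar pollution scenario
#'
#' The default exposure factors combined with a biochar fine-particle
#' air concentration of 5.6 mg/m3 (5.6e-3 g/m3), an extreme-pollution
#' scenario for air laden with carbonaceous fine particles. Used by the
#' bundled biochar-matrix assessments.
#'
#' @inheritParams exposure_scenario
#' @return An `exposure_scenario` with `c_particle = 5.6e-3` g/m3.
#' @export
extreme_biochar_scenario <- function(tr = 0.75, v_resp = 20, bw = 60) {
  exposure_scenario(tr = tr, v_resp = v_resp, bw = bw,
                    c_particle = 5.6e-3)
}

#' Load the default assessment registry
#'
#' Single source of truth for every symbol in the assessment models:
#' the 15 analytes with their TEFs, the toxicity constants
#' (CR, IPF_BaP, UR) and the default exposure factors (TR, V_resp, BW).
#'
#' @return A list of class `pah_registry` with elements `pahs`
#'   (see [default_pahs()]), `toxicity` and `exposure`.
#' @examples
#' reg <- load_default_registry()
#' with(reg$exposure, tr * v_resp / bw) # unit intake factor, 0.25
#' @export
load_default_registry <- function() {
  structure(
    list(pahs = default_pahs(),
         toxicity = toxicity_parameters(),
         exposure = exposure_scenario()),
    class = "pah_registry"
  )
}

validate_pahs <- function(pahs) {
  v <- character()
  if (any(!is.finite(pahs$tef) | pahs$tef <= 0)) {
    bad <- pahs$abbreviation[!is.finite(pahs$tef) | pahs$tef <= 0]
    v <- c(v, sprintf("tef: must be > 0 for analyte '%s'", bad))
  }
  if (anyDuplicated(toupper(pahs$abbreviation))) {
    dup <- unique(pahs$abbreviation[duplicated(toupper(pahs$abbreviation))])
    v <- c(v, sprintf("abbreviation: duplicated value '%s'", dup))
  }
  v
}

validate_toxicity <- function(tox) {
  v <- character()
  if (!isTRUE(tox$cr > 0)) v <- c(v, "cr: must be strictly positive")
  if (!isTRUE(tox$ipf_bap > 0)) v <- c(v, "ipf_bap: must be strictly positive")
  if (!isTRUE(tox$ur > 0)) v <- c(v, "ur: must be strictly positive")
  if (length(tox$cr_range) != 2 || !all(tox$cr_range > 0)) {
    v <- c(v, "cr_range: must be two strictly positive bounds")
  } else if (isTRUE(tox$cr > 0) &&
             (tox$cr < tox$cr_range[1] || tox$cr > tox$cr_range[2])) {
    v <- c(v, "cr: must lie within cr_range")
  }
  v
}

validate_scenario <- function(scenario) {
  v <- character()
  if (!isTRUE(scenario$tr > 0 && scenario$tr <= 1)) {
    v <- c(v, "tr: must satisfy 0 < tr <= 1")
  }
  if (!isTRUE(scenario$v_resp > 0)) v <- c(v, "v_resp: must be > 0")
  if (!isTRUE(scenario$bw > 0)) v <- c(v, "bw: must be > 0")
  if (!is.na(scenario$c_particle) && !isTRUE(scenario$c_particle >= 0)) {
    v <- c(v, "c_particle: must be >= 0 when present")
  }
  if (!is.na(scenario$q_pah) && !isTRUE(scenario$q_pah >= 0)) {
    v <- c(v, "q_pah: must be >= 0 when present")
  }
  v
}

stop_on_violations <- function(v) {
  if (length(v)) stop(paste(v, collapse = "; "), call. = FALSE)
  invisible(NULL)
}

#' Validate a registry against the model invariants
#'
#' Checks every type invariant (positive TEFs, unique abbreviations,
#' positive toxicity constants with CR inside its acceptable range,
#' exposure factors in range) and reports violations as data rather
#' than raising errors.
#'
#' @param pahs Analyte table as returned by [default_pahs()], or a
#'   `pah_registry` (in which case `tox` and `scenario` are taken from
#'   it).
#' @param tox A [toxicity_parameters()] object (or bare list).
#' @param scenario An [exposure_scenario()] object (or bare list).
#' @return Character vector of violation messages, each naming the
#'   offending field and rule; empty when all invariants hold.
#' @examples
#' validate_registry(load_default_registry()) # character(0)
#' @export
validate_registry <- function(pahs, tox = NULL, scenario = NULL) {
  if (inherits(pahs, "pah_registry")) {
    tox <- pahs$toxicity
    scenario <- pahs$exposure
    pahs <- pahs$pahs
  }
  c(if (!is.null(pahs)) validate_pahs(pahs),
    if (!is.null(tox)) validate_toxicity(tox),
    if (!is.null(scenario)) validate_scenario(scenario))
}

# Canonical key for case-insensitive analyte matching; "BbF + BkF" and
# "BbF+BkF" collapse to the same key.
analyte_key <- function(x) {
  toupper(gsub("[[:space:]]+", "", x))
}

#' Look up analytes in a registry table
#'
#' Matches abbreviations or full names case-insensitively, ignoring
#' whitespace, so `"BbF+BkF"`, `"BbF + BkF"` and `"bbf+bkf"` are
#' equivalent.
#'
#' @param pahs Analyte table (see [default_pahs()]).
#' @param analyte Character vector of abbreviations or names.
#' @return Integer row indices into `pahs`.
#' @export
pah_lookup <- function(pahs, analyte) {
  key <- analyte_key(analyte)
  idx <- match(key, analyte_key(pahs$abbreviation))
  miss <- is.na(idx)
  if (any(miss)) {
    idx[miss] <- match(key[miss], analyte_key(pahs$name))
  }
  if (anyNA(idx)) {
    stop("unknown analyte(s): ",
         paste(unique(analyte[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' @export
print.toxicity_parameters <- function(x, ...) {
  cat("Toxicity parameters\n")
  cat(sprintf("  CR      : %g (acceptable range %g - %g)\n",
              x$cr, x$cr_range[1], x$cr_range[2]))
  cat(sprintf("  IPF_BaP : %g (ng/kg/day)^-1\n", x$ipf_bap))
  cat(sprintf("  UR      : %g (ng/m3)^-1\n", x$ur))
  invisible(x)
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat("Exposure scenario\n")
  cat(sprintf("  TR        : %g (fraction retained)\n", x$tr))
  cat(sprintf("  V_resp    : %g m3/day\n", x$v_resp))
  cat(sprintf("  BW        : %g kg\n", x$bw))
  if (!is.na(x$c_particle))
    cat(sprintf("  C_particle: %g g/m3\n", x$c_particle))
  if (!is.na(x$q_pah))
    cat(sprintf("  q_PAH     : %g ng/g\n", x$q_pah))
  invisible(x)
}

#' Write a registry to a YAML configuration file
#'
#' The file has sections `pahs`, `toxicity` and `exposure`; units are
#' part of the key names so a file is self-describing. Boundary units:
#' the particle concentration is written in mg/m3 and converted back to
#' the internal g/m3 on read.
#'
#' @param registry A `pah_registry` (see [load_default_registry()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry_config <- function(registry, path) {
  pahs <- registry$pahs
  doc <- list(
    pahs = lapply(seq_len(nrow(pahs)), function(i) {
      list(abbreviation = pahs$abbreviation[i], name = pahs$name[i],
           tef = pahs$tef[i], combined = pahs$combined[i],
           rings = pahs$rings[i])
    }),
    toxicity = list(
      cr = registry$toxicity$cr,
      cr_range = as.list(registry$toxicity$cr_range),
      ipf_bap_per_ng_kg_day = registry$toxicity$ipf_bap,
      ur_per_ng_m3 = registry$toxicity$ur
    ),
    exposure = list(
      tr_fraction = registry$exposure$tr,
      v_resp_m3_day = registry$exposure$v_resp,
      bw_kg = registry$exposure$bw,
      c_particle_mg_m3 = if (is.na(registry$exposure$c_particle)) NULL else
        registry$exposure$c_particle * 1000,
      q_pah_ng_g = if (is.na(registry$exposure$q_pah)) NULL else
        registry$exposure$q_pah
    )
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a registry from a YAML configuration file
#'
#' Inverse of [write_registry_config()]: values round-trip exactly.
#' Missing sections fall back to the package defaults.
#'
#' @param path Path to a YAML file written by [write_registry_config()]
#'   or hand-edited in the same layout.
#' @return A `pah_registry`.
#' @export
read_registry_config <- function(path) {
  doc <- yaml::read_yaml(path)
  pahs <- if (is.null(doc$pahs)) default_pahs() else {
    do.call(rbind, lapply(doc$pahs, function(p) {
      data.frame(name = p$name, abbreviation = p$abbreviation,
                 tef = as.numeric(p$tef),
                 combined = isTRUE(p$combined),
                 rings = if (is.null(p$rings)) NA_integer_ else
                   as.integer(p$rings),
                 stringsAsFactors = FALSE)
    }))
  }
  tox <- if (is.null(doc$toxicity)) toxicity_parameters() else
    toxicity_parameters(
      cr = as.numeric(doc$toxicity$cr),
      cr_range = as.numeric(unlist(doc$toxicity$cr_range)),
      ipf_bap = as.numeric(doc$toxicity$ipf_bap_per_ng_kg_day),
      ur = as.numeric(doc$toxicity$ur_per_ng_m3)
    )
  expo <- if (is.null(doc$exposure)) exposure_scenario() else
    exposure_scenario(
      tr = as.numeric(doc$exposure$tr_fraction),
      v_resp = as.numeric(doc$exposure$v_resp_m3_day),
      bw = as.numeric(doc$exposure$bw_kg),
      c_particle = if (is.null(doc$exposure$c_particle_mg_m3)) NA_real_ else
        as.numeric(doc$exposure$c_particle_mg_m3) / 1000,
      q_pah = if (is.null(doc$exposure$q_pah_ng_g)) NA_real_ else
        as.numeric(doc$exposure$q_pah_ng_g)
    )
  reg <- structure(list(pahs = pahs, toxicity = tox, exposure = expo),
                   class = "pah_registry")
  stop_on_violations(validate_registry(reg))
  reg
}
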