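#' Default model configuration
#'
#' Returns the full model/study configuration used throughout the package:
#' fixed population parameters of the coupled
#' hematopoiesis / Ara-C / blast / G-CSF model, the names of the six
#' per-twin individual parameters, the pharmacodynamic form, and dosing
#' conventions. Every constant carries a provenance tag (`"repo-default"`
#' here); a configuration loaded from file may override any entry, so an
#' externally estimated parameter set can be dropped in without code
#' changes.
#'
#' Units: time in days, WBC in 10^9 cells/L, Ara-C amounts in mg and
#' concentrations in mg/L, G-CSF doses in micrograms, blasts in 10^9 cells
#' (an arbitrary consistent scale; the blast ratio kpiB is invariant to it).
#'
#' @return A nested list with elements `population_parameters`,
#'   `individual_parameter_names`, `pd_form`, `n_transit`,
#'   `infusions_per_day`, `infusion_h`, `solver`, `provenance`.
#' @export
default_config <- function() {
  list(
    population_parameters = list(
      n_transit = 3,          # maturation compartments between progenitors and blood
      e_cap     = 0.999,      # cap on the fractional proliferation inhibition
      ke_ara    = 4.5,        # effective Ara-C(-CTP) elimination, 1/day (t1/2 ~ 3.7 h)
      v_ara     = 37.3,       # Ara-C central volume, L
      ka_g      = 2.0,        # lenograstim sc absorption, 1/day
      ke_g      = 1.5,        # lenograstim linear elimination, 1/day
      kw_g      = 0.3,        # WBC-mediated G-CSF clearance, 1/day per 10^9/L
      g_scale   = 60,         # depot-to-effect scaling, ug
      beta1     = 0.25,       # G-CSF exponent on proliferation
      beta2     = 0.125,      # G-CSF exponent on transit/release
      a_l       = 0.9,        # blast self-renewal fraction
      d_l       = 0.3,        # post-mitotic blast death rate, 1/day
      k_s       = 0.102,      # shared cytokine feedback coefficient, L/10^9 cells
      blast_fb_w = 0,         # blast weight in the shared feedback signal
      blast_sens = 0.05,      # blast Ara-C sensitivity relative to slope_w
      blast_obs_frac = 0.04,  # circulating blast contribution to observed WBC,
                              # (10^9/L) per 10^9 blast cells
      bsa_default = 1.9       # body surface area default, m^2
    ),
    individual_parameter_names = c("B", "gamma", "k_tr", "slope_w", "p_l", "l0"),
    pd_form = "linear-capped",
    n_transit = 3,
    infusions_per_day = 1,    # Ara-C infusions per administration day (2 = q12h)
    infusion_h = 3,           # infusion duration, hours
    gcsf_daily_dose_ug = 263, # lenograstim daily dose
    solver = list(rtol = 1e-8, atol = 1e-10, grid_step = 0.1),
    threshold = 1.0,          # leukopenia threshold, 10^9 WBC/L
    provenance = "repo-default"
  )
}

#' Load a model configuration from a YAML file
#'
#' Entries present in the file override the defaults from
#' [default_config()]; everything else keeps its default (and its
#' `repo-default` provenance).
#'
#' @param path Path to a YAML configuration file.
#' @return A configuration list as from [default_config()].
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a study/model configuration
#'
#' Checks the configuration invariants (positive rates and volumes, positive
#' leukopenia threshold, a supported pharmacodynamic form) and reports which
#' fields are running on repo defaults.
#'
#' @param config A configuration list as from [default_config()] or
#'   [load_config()].
#' @return Invisibly, a list with `ok` (logical), `errors` (character) and
#'   `defaulted` (character vector of fields carrying repo defaults).
#' @export
validate_config <- function(config) {
  errors <- character()
  pp <- config$population_parameters
  num <- vapply(pp, function(x) is.numeric(x) && length(x) == 1, logical(1))
  if (!all(num)) {
    errors <- c(errors, paste0("non-scalar population parameter(s): ",
                               paste(names(pp)[!num], collapse = ", ")))
  } else {
    pos_req <- setdiff(names(pp), c("blast_fb_w", "blast_obs_frac", "blast_sens"))
    bad <- pos_req[vapply(pos_req, function(n) !(pp[[n]] > 0), logical(1))]
    if (length(bad))
      errors <- c(errors, paste0("non-positive population parameter(s): ",
                                 paste(bad, collapse = ", ")))
    if (pp$blast_fb_w < 0 || pp$blast_obs_frac < 0 || pp$blast_sens < 0)
      errors <- c(errors, "blast weights/sensitivity must be >= 0")
  }
  if (!is.numeric(config$threshold) || config$threshold <= 0)
    errors <- c(errors, "threshold must be > 0")
  if (!config$pd_form %in% c("linear-capped", "emax"))
    errors <- c(errors, paste0("unsupported pd_form: ", config$pd_form))
  if (!config$infusions_per_day %in% c(1, 2))
    errors <- c(errors, "infusions_per_day must be 1 or 2")
  if (length(config$individual_parameter_names) != 6)
    errors <- c(errors, "exactly six individual parameter names are required")
  defaulted <- if (identical(config$provenance, "repo-default"))
    names(pp) else character()
  res <- list(ok = length(errors) == 0, errors = errors, defaulted = defaulted)
  if (!res$ok) stop("invalid configuration: ",
                    paste(errors, collapse = "; "), call. = FALSE)
  invisible(res)
}
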