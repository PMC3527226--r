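#' Parameter names of the STAT1 pathway model
#'
#' Full set of rate constants, delays, total receptor level, immunoblot
#' scaling factors and estimable initial conditions, in canonical order.
#'
#' @format Character vector of length 25.
#' @export
pathway_parameter_names <- c(
  "k_act",     # receptor activation rate per unit IFN-gamma per minute
  "k_inact",   # active-receptor deactivation rate, 1/min
  "R_tot",     # total receptor concentration, a.u.
  "k_phos",    # STAT1 phosphorylation rate per unit active receptor, 1/(min a.u.)
  "k_inh",     # SOCS1 feedback inhibition constant, 1/a.u.
  "k_impD",    # nuclear import rate of phosphorylated STAT1, 1/min
  "k_impU",    # nuclear import rate of unphosphorylated cytoplasmic STAT1, 1/min
  "k_exp",     # nuclear export rate of unphosphorylated STAT1, 1/min
  "k_deph",    # nuclear dephosphorylation rate, 1/min
  "k_tc_socs", # SOCS1 transcription rate per unit nuclear phospho-STAT1, 1/min
  "d_m_socs",  # SOCS1 mRNA degradation rate, 1/min
  "k_tl_socs", # SOCS1 translation rate, 1/min
  "d_socs",    # SOCS1 protein degradation rate, 1/min
  "b_m_stat",  # basal STAT1 mRNA synthesis, a.u./min
  "k_tc_stat", # induced STAT1 transcription rate, 1/min
  "d_m_stat",  # STAT1 mRNA degradation rate, 1/min
  "k_tl_stat", # STAT1 translation rate, 1/min
  "d_stat",    # STAT1 protein turnover rate, 1/min
  "tau_socs",  # transcriptional delay for SOCS1, min
  "tau_stat",  # transcriptional delay for STAT1, min
  "s_pstat",   # immunoblot scaling factor, phospho-STAT1
  "s_stat",    # immunoblot scaling factor, total STAT1
  "s_socs",    # scaling factor, SOCS1 mRNA
  "stat1_uc0", # initial cytoplasmic unphosphorylated STAT1, a.u.
  "stat1_un0"  # initial nuclear unphosphorylated STAT1, a.u.
)

.scaling_factor_names <- c("s_pstat", "s_stat", "s_socs")

#' Construct a validated pathway parameter set
#'
#' @param values Named numeric vector or list covering all names in
#'   [pathway_parameter_names]. Unknown names are rejected.
#' @return Named numeric vector of class `pathway_parameters`.
#' @examples
#' p <- make_preset("PSC_like")
#' p[["k_act"]]
#' @export
pathway_parameters <- function(values) {
  values <- unlist(values)
  if (is.null(names(values))) {
    stop("parameter values must be named")
  }
  unknown <- setdiff(names(values), pathway_parameter_names)
  if (length(unknown) > 0) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(pathway_parameter_names, names(values))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  p <- as.numeric(values[pathway_parameter_names])
  names(p) <- pathway_parameter_names
  class(p) <- c("pathway_parameters", "numeric")
  validate_parameters(p)
  p
}

#' Validate a pathway parameter set
#'
#' Checks that every rate, delay, concentration and scaling factor is finite
#' and non-negative, that the total receptor concentration is strictly
#' positive, and that the scaling factors are strictly positive.
#'
#' @param p Object from [pathway_parameters()].
#' @return `p`, invisibly; errors on violation.
#' @export
validate_parameters <- function(p) {
  if (any(!is.finite(p))) {
    stop("non-finite parameter value(s): ",
         paste(names(p)[!is.finite(p)], collapse = ", "))
  }
  if (any(p < 0)) {
    stop("negative parameter value(s): ",
         paste(names(p)[p < 0], collapse = ", "))
  }
  if (p[["R_tot"]] <= 0) stop("R_tot must be > 0")
  sf <- p[.scaling_factor_names]
  if (any(sf <= 0)) stop("scaling factors must be > 0")
  invisible(p)
}

#' @export
print.pathway_parameters <- function(x, ...) {
  cat("<pathway_parameters>", length(x), "parameters\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Read / write pathway parameters as a flat YAML or JSON mapping
#'
#' Format is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#' Values round-trip exactly: JSON is written at full double precision and
#' YAML values are re-parsed as numeric.
#'
#' @param p Parameter set.
#' @param path File path.
#' @return `read_parameters` returns a `pathway_parameters` object.
#' @export
write_parameters <- function(p, path) {
  validate_parameters(p)
  vals <- as.list(stats::setNames(as.numeric(p), names(p)))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    # %.17g guarantees IEEE-double round-trip; yaml's own `precision` counts
    # decimal places and truncates small values
    handlers <- list(numeric = function(v) {
      structure(sprintf("%.17g", v), class = "verbatim")
    })
    yaml::write_yaml(vals, path, handlers = handlers)
  } else if (ext == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = I(17))
  } else {
    stop("unsupported parameter file extension: ", ext)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported parameter file extension: ", ext)
  }
  pathway_parameters(vals)
}
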