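#' Fractionation constants and end-member defaults
#'
#' Builds the set of isotopic constants used throughout the pipeline:
#' the trophic-position equation parameters, assimilation and excretion
#' fractionation factors, end-member delta-15N values, RuBisCO
#' discrimination ranges and default analytical precisions. Every value can
#' be overridden by a named argument or by a YAML configuration file with
#' per-module sections (section names are ignored; keys must match constant
#' names).
#'
#' All per-mil quantities are decimal per-mil numbers (e.g. `-29.8`), never
#' fractional ratios. Fractionation sign convention: a positive epsilon
#' depletes the product relative to the substrate.
#'
#' @param ... named overrides of individual constants.
#' @param config path to a YAML file, or an already-parsed list, whose
#'   (possibly nested) keys override defaults. Named arguments win over the
#'   file.
#'
#' @return An object of class `study_constants`: a named list with elements
#' \describe{
#'   \item{acidification_offset}{per-mil subtracted from acidified bulk
#'     delta-15N measurements (default 0.3).}
#'   \item{beta}{beta of the Glu/Phe trophic-position equation (default 3.4).}
#'   \item{delta_glu_phe}{per-trophic-level Glu-Phe enrichment (default 7.6).}
#'   \item{c13_trophic_enrichment}{per-level carbon-13 enrichment, per mil
#'     (default 1.0).}
#'   \item{n15_trophic_enrichment_range}{consumer-diet delta-15N enrichment
#'     interval (default 2.3--3.4).}
#'   \item{excretion_epsilon}{fractionation of ammonium excretion (default 2.7).}
#'   \item{ammonium_assim_epsilon_range}{fractionation of microbial ammonium
#'     assimilation (default 5--20).}
#'   \item{n2_delta}{delta-15N of dissolved dinitrogen (default 0.6).}
#'   \item{n2_fix_epsilon_max}{maximum fractionation of dinitrogen fixation
#'     (default 2.5).}
#'   \item{nitrate_assim_photo_epsilon_range}{nitrate-assimilation
#'     fractionation by photoautotrophs (default 4.0--10.0).}
#'   \item{nitrate_assim_prok_epsilon_range}{nitrate-assimilation
#'     fractionation by prokaryotes (default 0.4--5.0).}
#'   \item{rubisco1_epsilon_range, rubisco2_epsilon_range}{carbon-isotope
#'     discrimination of RuBisCO forms I and II (defaults 22--29 and
#'     17.8--23).}
#'   \item{poc_theory_offset_range}{how much heavier bulk POC of CO2-fixing
#'     organisms typically is than theoretical fixation values (default
#'     10--20).}
#'   \item{baseline_phe_diatom}{delta-15N-Phe of sedimented-diatom consumers
#'     used as the pelagic baseline (default 5.3).}
#'   \item{aa_sd_default, bulk_sd_default}{analytical precisions substituted
#'     for missing SDs: 1.0 for amino-acid, 0.2 for bulk measurements.}
#'   \item{baseline_tolerance}{per-mil tolerance of the Phe baseline
#'     comparison (default 1.0, the amino-acid precision).}
#'   \item{k_sd}{number of standard deviations around a measured mean used in
#'     source attribution (default 1).}
#' }
#'
#' @examples
#' const <- study_constants()
#' const$beta
#' study_constants(k_sd = 2)$k_sd
#' @export
study_constants <- function(..., config = NULL) {
  defaults <- list(
    acidification_offset = 0.3,
    beta = 3.4,
    delta_glu_phe = 7.6,
    c13_trophic_enrichment = 1.0,
    n15_trophic_enrichment_range = c(2.3, 3.4),
    excretion_epsilon = 2.7,
    ammonium_assim_epsilon_range = c(5, 20),
    n2_delta = 0.6,
    n2_fix_epsilon_max = 2.5,
    nitrate_assim_photo_epsilon_range = c(4.0, 10.0),
    nitrate_assim_prok_epsilon_range = c(0.4, 5.0),
    rubisco1_epsilon_range = c(22, 29),
    rubisco2_epsilon_range = c(17.8, 23),
    poc_theory_offset_range = c(10, 20),
    baseline_phe_diatom = 5.3,
    aa_sd_default = 1.0,
    bulk_sd_default = 0.2,
    baseline_tolerance = 1.0,
    k_sd = 1
  )

  overrides <- list()
  if (!is.null(config)) {
    cfg <- if (is.character(config)) yaml::read_yaml(config) else config
    overrides <- flatten_config(cfg)
  }
  dots <- list(...)
  overrides[names(dots)] <- dots

  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown constant(s): ", paste(unknown, collapse = ", "))
  }
  out <- defaults
  out[names(overrides)] <- lapply(overrides, as.numeric)

  validate_constants(out)
  structure(out, class = "study_constants")
}

# Collapse one level of per-module sections into a flat key-value list.
flatten_config <- function(cfg) {
  flat <- list()
  for (key in names(cfg)) {
    val <- cfg[[key]]
    if (is.list(val)) {
      flat[names(val)] <- lapply(val, function(v) unlist(v, use.names = FALSE))
    } else {
      flat[[key]] <- unlist(val, use.names = FALSE)
    }
  }
  flat
}

validate_constants <- function(x) {
  scalars <- c(
    "acidification_offset", "beta", "delta_glu_phe", "c13_trophic_enrichment",
    "excretion_epsilon", "n2_delta", "n2_fix_epsilon_max",
    "baseline_phe_diatom", "aa_sd_default", "bulk_sd_default",
    "baseline_tolerance", "k_sd"
  )
  ranges <- c(
    "n15_trophic_enrichment_range", "ammonium_assim_epsilon_range",
    "nitrate_assim_photo_epsilon_range", "nitrate_assim_prok_epsilon_range",
    "rubisco1_epsilon_range", "rubisco2_epsilon_range",
    "poc_theory_offset_range"
  )
  for (nm in scalars) {
    v <- x[[nm]]
    if (length(v) != 1 || !is.finite(v)) {
      stop("constant '", nm, "' must be a single finite number")
    }
  }
  for (nm in ranges) {
    v <- x[[nm]]
    if (length(v) != 2 || any(!is.finite(v))) {
      stop("constant '", nm, "' must be a finite interval of length 2")
    }
    if (v[1] > v[2]) stop("constant '", nm, "' has min > max")
  }
  if (x$k_sd < 0) stop("k_sd must be >= 0")
  invisible(x)
}

#' @export
print.study_constants <- function(x, ...) {
  cat("Study constants (per mil unless dimensionless):\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-36s %s\n", nm,
                if (length(v) == 2) sprintf("[%g, %g]", v[1], v[2])
                else format(v)))
  }
  invisible(x)
}
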