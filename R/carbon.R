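#' Equilibrium carbon-isotope fractionation between dissolved CO2 and DIC
#'
#' Dissolved CO2 is isotopically lighter than the dissolved inorganic
#' carbon pool it equilibrates with; the offset depends on temperature.
#' The classical temperature law for CO2(aq) relative to bicarbonate (the
#' dominant DIC species at seawater pH) is used:
#'
#'   epsilon(T) = 24.12 - 9866 / T_K,   T_K = temperature + 273.15
#'
#' which is negative at ocean temperatures (about -10.5 per mil at 12 degC).
#' The law is pluggable so an alternative formulation can be supplied.
#'
#' @param temperature water temperature in degrees Celsius; guarded to the
#'   liquid range 0--40.
#' @param law function of absolute temperature (K) returning the per-mil
#'   enrichment of CO2 relative to DIC.
#' @return per-mil epsilon (negative: CO2 lighter than DIC).
#' @examples
#' co2_dic_epsilon(11.9)  # about -10.49
#' @export
co2_dic_epsilon <- function(temperature,
                            law = function(t_k) 24.12 - 9866 / t_k) {
  if (any(!is.finite(temperature)) ||
      any(temperature < 0) || any(temperature > 40)) {
    stop("temperature must be within 0-40 degrees Celsius")
  }
  law(temperature + 273.15)
}

#' Delta-13C of dissolved CO2 from measured DIC
#'
#' @param dic_delta13c per-mil delta-13C of DIC (vs PDB).
#' @param temperature degrees Celsius.
#' @inheritParams co2_dic_epsilon
#' @return per-mil delta-13C of dissolved CO2 (unrounded; use
#'   [display_permil()] for reporting at one decimal).
#' @examples
#' display_permil(co2_delta_from_dic(-0.27, 11.9))  # -10.8
#' @export
co2_delta_from_dic <- function(dic_delta13c, temperature,
                               law = function(t_k) 24.12 - 9866 / t_k) {
  if (any(!is.finite(dic_delta13c))) stop("dic_delta13c must be finite")
  dic_delta13c + co2_dic_epsilon(temperature, law)
}

#' Round a per-mil value for display
#'
#' Half-away-from-zero rounding at a fixed number of decimals, the
#' convention of printed isotope values (base R's `round()` rounds half to
#' even). Internal computations stay unrounded.
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
display_permil <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Apparent RuBisCO discrimination window from tissue delta-13C
#'
#' The apparent discrimination of the symbionts' carbon fixation is the
#' offset between the CO2 they fix and the biomass they build,
#' delta13C_CO2 - delta13C_biomass (positive: biomass lighter). Because
#' bulk POC of CO2-fixing organisms in nature is typically 10--20 per mil
#' heavier than theoretical fixation values, that offset interval is added
#' on top. All interval-corner combinations of gill value, CO2 value and
#' offset are enumerated, so cross-station pairings are included.
#'
#' @param gill_delta_min,gill_delta_max per-mil interval of measured gill
#'   (biomass) delta-13C.
#' @param co2_delta_min,co2_delta_max per-mil interval of dissolved-CO2
#'   delta-13C, e.g. from [co2_delta_from_dic()] at the stations'
#'   temperatures.
#' @param poc_offset_min,poc_offset_max per-mil interval of the
#'   POC-vs-theory offset (default 10--20).
#' @return list with `epsilon_min`, `epsilon_max` (per mil), classed
#'   `discrimination_window`.
#' @examples
#' apparent_discrimination_window(-30.8, -29.0, -11.0, -10.8)  # 28-40
#' @export
apparent_discrimination_window <- function(gill_delta_min, gill_delta_max,
                                           co2_delta_min, co2_delta_max,
                                           poc_offset_min = 10,
                                           poc_offset_max = 20) {
  if (gill_delta_min > gill_delta_max) stop("inverted gill interval")
  if (co2_delta_min > co2_delta_max) stop("inverted CO2 interval")
  if (poc_offset_min > poc_offset_max) stop("inverted offset interval")

  corners <- expand.grid(gill = c(gill_delta_min, gill_delta_max),
                         co2 = c(co2_delta_min, co2_delta_max))
  apparent <- corners$co2 - corners$gill
  structure(list(epsilon_min = min(apparent) + poc_offset_min,
                 epsilon_max = max(apparent) + poc_offset_max),
            class = "discrimination_window")
}

#' @export
print.discrimination_window <- function(x, ...) {
  cat(sprintf("Apparent CO2 discrimination window: %.1f to %.1f‰\n",
              x$epsilon_min, x$epsilon_max))
  invisible(x)
}

#' Rank carboxylase forms by overlap with a discrimination window
#'
#' Compares an apparent discrimination window against the published
#' discrimination ranges of candidate CO2-fixing enzymes (by default
#' RuBisCO form I, 22--29 per mil, and form II, 17.8--23 per mil) and ranks
#' them by the length of overlap. Enzymes whose range does not intersect
#' the window at all are marked inconsistent.
#'
#' @param window a `discrimination_window` from
#'   [apparent_discrimination_window()].
#' @param enzyme_ranges named list of per-mil intervals (length-2 numeric
#'   vectors).
#' @return data.frame ordered by decreasing overlap with columns `enzyme`,
#'   `range_min`, `range_max`, `overlap` (per mil) and `consistent`;
#'   classed `enzyme_consistency`.
#' @examples
#' w <- apparent_discrimination_window(-30.8, -29.0, -11.0, -10.8)
#' enzyme_consistency(w)
#' @export
enzyme_consistency <- function(window,
                               enzyme_ranges = list(
                                 rubisco_I = c(22, 29),
                                 rubisco_II = c(17.8, 23))) {
  if (!inherits(window, "discrimination_window")) {
    stop("window must be a discrimination_window")
  }
  if (length(enzyme_ranges) == 0) stop("empty enzyme set")
  for (r in enzyme_ranges) {
    if (length(r) != 2 || r[1] > r[2]) stop("inverted enzyme range")
  }
  out <- do.call(rbind, lapply(names(enzyme_ranges), function(nm) {
    r <- enzyme_ranges[[nm]]
    hi <- min(window$epsilon_max, r[2])
    lo <- max(window$epsilon_min, r[1])
    data.frame(enzyme = nm, range_min = r[1], range_max = r[2],
               overlap = max(0, hi - lo),
               consistent = hi >= lo,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$overlap), ]
  rownames(out) <- NULL
  attr(out, "window") <- window
  class(out) <- unique(c("enzyme_consistency", class(out)))
  out
}

#' @export
print.enzyme_consistency <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Enzyme consistency with window [%.1f, %.1f]‰:\n",
              w$epsilon_min, w$epsilon_max))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s [%5.1f, %5.1f]‰  overlap %.1f‰  %s\n",
                x$enzyme[i], x$range_min[i], x$range_max[i], x$overlap[i],
                if (x$consistent[i]) "consistent" else "inconsistent"))
  }
  cat("Best-supported enzyme:", x$enzyme[1], "\n")
  invisible(x)
}
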