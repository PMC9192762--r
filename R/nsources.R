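#' Inorganic nitrogen end-member
#'
#' An end-member is a candidate inorganic nitrogen source (dinitrogen,
#' nitrate, ammonium, ...) described by its ambient delta-15N interval and
#' by the fractionation interval of the assimilation process that turns it
#' into biomass. A positive epsilon depletes the product: assimilating
#' biomass has delta = source - epsilon.
#'
#' @param name one of `"dinitrogen"`, `"nitrate_pelagic"`,
#'   `"nitrate_benthic"`, `"ammonium"`, `"custom"`.
#' @param source_delta_min,source_delta_max per-mil interval of the source
#'   pool (equal for a point value).
#' @param epsilon_min,epsilon_max per-mil interval of the assimilation
#'   fractionation.
#' @return object of class `end_member`.
#' @examples
#' end_member("dinitrogen", 0.6, 0.6, 0, 2.5)
#' @export
end_member <- function(name, source_delta_min, source_delta_max,
                       epsilon_min, epsilon_max) {
  valid <- c("dinitrogen", "nitrate_pelagic", "nitrate_benthic",
             "ammonium", "custom")
  if (!name %in% valid) {
    stop("name must be one of: ", paste(valid, collapse = ", "))
  }
  vals <- c(source_delta_min, source_delta_max, epsilon_min, epsilon_max)
  if (!all(is.finite(vals))) stop("all bounds must be finite")
  if (source_delta_min > source_delta_max) stop("inverted source interval")
  if (epsilon_min > epsilon_max) stop("inverted epsilon interval")
  structure(list(name = name,
                 source_delta_min = source_delta_min,
                 source_delta_max = source_delta_max,
                 epsilon_min = epsilon_min,
                 epsilon_max = epsilon_max),
            class = "end_member")
}

#' Default end-members for the Namibian shelf
#'
#' The four candidate nitrogen sources with their literature delta-15N
#' ranges and assimilation fractionations: dissolved dinitrogen (0.6 per
#' mil, fixation fractionation up to 2.5); pelagic nitrate upwelled from
#' South Atlantic Central Water (5.7--6.7, photoautotroph assimilation
#' 4--10); benthic nitrate in sediment-overlying water (5.9--14.3,
#' prokaryote assimilation 0.4--5); and ammonium, whose delta-15N is taken
#' equal to sediment PON (4.3--5.6 across the study stations by default)
#' with a microbial assimilation effect of 5--20.
#'
#' @param constants a [study_constants()] object supplying the epsilon
#'   ranges and the dinitrogen delta.
#' @param sediment_pon_delta per-mil interval (or point value) of sediment
#'   PON delta-15N, converted to the ammonium interval via
#'   [ammonium_delta_from_sediment_pon()].
#' @param nitrate_pelagic_delta,nitrate_benthic_delta per-mil source
#'   intervals for the two nitrate pools.
#' @return named list of [end_member()] objects.
#' @export
default_end_members <- function(constants = study_constants(),
                                sediment_pon_delta = c(4.3, 5.6),
                                nitrate_pelagic_delta = c(5.7, 6.7),
                                nitrate_benthic_delta = c(5.9, 14.3)) {
  amm <- range(ammonium_delta_from_sediment_pon(sediment_pon_delta))
  list(
    dinitrogen = end_member("dinitrogen",
                            constants$n2_delta, constants$n2_delta,
                            0, constants$n2_fix_epsilon_max),
    nitrate_pelagic = end_member("nitrate_pelagic",
                                 nitrate_pelagic_delta[1],
                                 nitrate_pelagic_delta[2],
                                 constants$nitrate_assim_photo_epsilon_range[1],
                                 constants$nitrate_assim_photo_epsilon_range[2]),
    nitrate_benthic = end_member("nitrate_benthic",
                                 nitrate_benthic_delta[1],
                                 nitrate_benthic_delta[2],
                                 constants$nitrate_assim_prok_epsilon_range[1],
                                 constants$nitrate_assim_prok_epsilon_range[2]),
    ammonium = end_member("ammonium", amm[1], amm[2],
                          constants$ammonium_assim_epsilon_range[1],
                          constants$ammonium_assim_epsilon_range[2])
  )
}

#' Expected PON delta-15N interval
#'
#' @param delta_min,delta_max per-mil bounds of the interval.
#' @param source_name label of the source the window derives from.
#' @return object of class `pon_window`. Windows are closed intervals;
#'   touching counts as overlap.
#' @export
pon_window <- function(delta_min, delta_max, source_name = "") {
  if (!is.finite(delta_min) || !is.finite(delta_max)) {
    stop("window bounds must be finite")
  }
  if (delta_min > delta_max) stop("inverted window interval")
  structure(list(delta_min = delta_min, delta_max = delta_max,
                 source_name = source_name),
            class = "pon_window")
}

#' @export
print.pon_window <- function(x, ...) {
  cat(sprintf("PON window [%g, %g]‰%s\n", x$delta_min, x$delta_max,
              if (nzchar(x$source_name)) paste0(" (", x$source_name, ")")
              else ""))
  invisible(x)
}

#' Expected bulk delta-15N window of biomass assimilating an end-member
#'
#' Biomass built from a source pool with delta-15N in
#' \[source_min, source_max\] via a process fractionating by epsilon in
#' \[eps_min, eps_max\] has delta-15N anywhere in
#' \[source_min - eps_max, source_max - eps_min\] (assimilation depletes
#' the product).
#'
#' @param source an [end_member()].
#' @return a [pon_window()].
#' @examples
#' # pelagic nitrate 5.7-6.7 with photoautotroph fractionation 4-10
#' expected_pon_window(end_member("nitrate_pelagic", 5.7, 6.7, 4, 10))
#' @export
expected_pon_window <- function(source) {
  if (!inherits(source, "end_member")) stop("source must be an end_member")
  pon_window(source$source_delta_min - source$epsilon_max,
             source$source_delta_max - source$epsilon_min,
             source$name)
}

#' Trophic-enrichment window of a consumer
#'
#' A consumer eating a diet with delta-15N in \[diet_min, diet_max\] and
#' enriched by \[enrichment_min, enrichment_max\] per trophic step has
#' delta-15N in \[diet_min + enrichment_min, diet_max + enrichment_max\].
#'
#' @param diet_min,diet_max per-mil interval of the diet.
#' @param enrichment_min,enrichment_max per-mil trophic enrichment interval
#'   (default 2.3--3.4 for bulk nitrogen).
#' @param source_name label for the resulting window.
#' @return a [pon_window()].
#' @examples
#' consumer_enrichment_window(4.6, 10.0)  # sediment PON eater: 6.9-13.4
#' @export
consumer_enrichment_window <- function(diet_min, diet_max,
                                       enrichment_min = 2.3,
                                       enrichment_max = 3.4,
                                       source_name = "") {
  if (diet_min > diet_max) stop("inverted diet interval")
  if (enrichment_min > enrichment_max) stop("inverted enrichment interval")
  pon_window(diet_min + enrichment_min, diet_max + enrichment_max,
             source_name)
}

#' Ammonium delta-15N from sediment PON
#'
#' Ammonification of PON in organic-rich marine sediments carries
#' negligible nitrogen-isotope fractionation, so pore-water ammonium is
#' assigned the delta-15N of the sediment PON it derives from.
#'
#' @param sediment_pon_delta per-mil delta-15N of sediment PON
#'   (vectorised).
#' @return the same value(s), unchanged.
#' @examples
#' ammonium_delta_from_sediment_pon(5.6)
#' @export
ammonium_delta_from_sediment_pon <- function(sediment_pon_delta) {
  if (!all(is.finite(sediment_pon_delta))) stop("input must be finite")
  sediment_pon_delta
}

#' Delta-15N of host-excreted ammonium
#'
#' Ammonium excretion depletes the excreted pool relative to the tissue it
#' comes from by the excretion fractionation factor (2.7 per mil by
#' default): excreted = tissue - epsilon.
#'
#' @param tissue_delta per-mil delta-15N of the excreting (non-symbiotic)
#'   tissue.
#' @param excretion_epsilon per-mil fractionation of excretion.
#' @return per-mil delta-15N of the excreted ammonium.
#' @examples
#' excreted_ammonium_delta(-2.5, 2.7)  # -5.2
#' @export
excreted_ammonium_delta <- function(tissue_delta, excretion_epsilon = 2.7) {
  if (!all(is.finite(tissue_delta)) || !all(is.finite(excretion_epsilon))) {
    stop("inputs must be finite")
  }
  tissue_delta - excretion_epsilon
}

#' Exclusion-based attribution of nitrogen sources
#'
#' Compares a measured tissue mean +/- k SD against the expected PON window
#' of each candidate source. A source is `consistent` if the closed
#' interval \[mean - k_sd * sd, mean + k_sd * sd\] intersects its window
#' (touching counts), otherwise `excluded`. The logic is exclusion, not
#' mixing: surviving sources are candidates, excluded sources cannot
#' explain the measurement.
#'
#' @param measured_mean,measured_sd per-mil mean and SD of the measured
#'   tissue delta-15N.
#' @param windows a list of [pon_window()] objects (or a single one), e.g.
#'   `lapply(default_end_members(), expected_pon_window)`.
#' @param k_sd number of SDs defining the measurement interval (default 1).
#' @return data.frame with one row per window: `source`, `window_min`,
#'   `window_max`, `verdict`; classed `nsource_attribution`. Attributes
#'   carry the measured mean, SD and k.
#' @examples
#' wins <- lapply(default_end_members(), expected_pon_window)
#' attribute_nitrogen_source(-4.9, 0.7, wins)
#' @export
attribute_nitrogen_source <- function(measured_mean, measured_sd, windows,
                                      k_sd = 1) {
  if (inherits(windows, "pon_window")) windows <- list(windows)
  if (length(windows) == 0) stop("empty window list")
  if (!all(vapply(windows, inherits, logical(1), "pon_window"))) {
    stop("windows must be pon_window objects")
  }
  if (k_sd < 0) stop("k_sd must be >= 0")
  if (measured_sd < 0) stop("measured_sd must be >= 0")

  lo <- measured_mean - k_sd * measured_sd
  hi <- measured_mean + k_sd * measured_sd
  out <- do.call(rbind, lapply(windows, function(w) {
    consistent <- lo <= w$delta_max && hi >= w$delta_min
    data.frame(source = w$source_name,
               window_min = w$delta_min, window_max = w$delta_max,
               verdict = if (consistent) "consistent" else "excluded",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "measured_mean") <- measured_mean
  attr(out, "measured_sd") <- measured_sd
  attr(out, "k_sd") <- k_sd
  class(out) <- unique(c("nsource_attribution", class(out)))
  out
}

#' @export
print.nsource_attribution <- function(x, ...) {
  m <- attr(x, "measured_mean")
  s <- attr(x, "measured_sd")
  k <- attr(x, "k_sd")
  cat(sprintf("Nitrogen-source attribution for measured %.1f‰ ± %.1f‰ (k = %g):\n",
              m, s, k))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-16s window [%6.1f, %6.1f]‰  %s\n", x$source[i],
                x$window_min[i], x$window_max[i], x$verdict[i]))
  }
  kept <- x$source[x$verdict == "consistent"]
  if (length(kept) > 0) {
    cat("Sources that can explain the measurement:",
        paste(kept, collapse = ", "), "\n")
  } else {
    cat("No candidate source explains the measurement.\n")
  }
  invisible(x)
}

#' @export
plot.nsource_attribution <- function(x, ...) {
  m <- attr(x, "measured_mean")
  s <- attr(x, "measured_sd")
  k <- attr(x, "k_sd")
  n <- nrow(x)
  xlim <- range(c(x$window_min, x$window_max, m - k * s, m + k * s))
  plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
       xlab = expression(delta^15 * N ~ "(‰)"), ylab = "",
       main = "Expected PON windows vs measurement", ...)
  graphics::axis(2, at = seq_len(n), labels = x$source, las = 1)
  graphics::segments(x$window_min, seq_len(n), x$window_max, seq_len(n),
                     lwd = 4,
                     col = ifelse(x$verdict == "consistent", "darkgreen",
                                  "grey60"))
  graphics::abline(v = c(m - k * s, m + k * s), lty = 2)
  graphics::abline(v = m, lty = 1)
  invisible(x)
}

#' Host-symbiont ammonium recycling consistency
#'
#' In a closed system where assimilation goes to completion no net isotope
#' fractionation is expressed, so symbionts recycling all host-excreted
#' ammonium should match its delta-15N. The check passes when the gill
#' value and the excreted-ammonium value agree within a tolerance (e.g.
#' the gill SD).
#'
#' @param gill_delta per-mil delta-15N of the symbiont-housing gill tissue.
#' @param excreted_delta per-mil delta-15N of host-excreted ammonium, e.g.
#'   from [excreted_ammonium_delta()].
#' @param tolerance per-mil tolerance (> 0).
#' @return logical.
#' @examples
#' recycling_consistency(-4.9, excreted_ammonium_delta(-2.5, 2.7), 0.7)
#' @export
recycling_consistency <- function(gill_delta, excreted_delta, tolerance) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  abs(gill_delta - excreted_delta) <= tolerance
}
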