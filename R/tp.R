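#' Trophic position from glutamic acid and phenylalanine delta-15N
#'
#' The "trophic" amino acid glutamic acid is strongly 15N-enriched with each
#' trophic transfer while the "source" amino acid phenylalanine is nearly
#' conserved, so their difference measures trophic position without a
#' separately characterised baseline:
#'
#'   TP = 1 + (d15N_Glu - d15N_Phe + beta) / Delta_Glu-Phe
#'
#' with beta = 3.4 and Delta_Glu-Phe = 7.6 per mil by default.
#'
#' @param delta15n_glu,delta15n_phe per-mil delta-15N of glutamic acid and
#'   phenylalanine (vectorised).
#' @param constants a [study_constants()] object (`beta`, `delta_glu_phe`).
#' @return numeric trophic position(s); 1 = autotroph, 2 = herbivore,
#'   3 = first-level carnivore.
#' @examples
#' compute_tp(15.16, 6.4)  # 2.6
#' compute_tp(10.6, 6.4)   # one Glu-Phe step of 4.2 above baseline -> 2
#' @seealso [classify_tp()], [propagate_tp_se()], [estimate_tp()]
#' @export
compute_tp <- function(delta15n_glu, delta15n_phe,
                       constants = study_constants()) {
  if (constants$delta_glu_phe == 0) stop("delta_glu_phe must be non-zero")
  if (!all(is.finite(delta15n_glu)) || !all(is.finite(delta15n_phe))) {
    stop("amino-acid delta-15N values must be finite")
  }
  1 + (delta15n_glu - delta15n_phe + constants$beta) / constants$delta_glu_phe
}

#' Propagated standard error of a trophic position estimate
#'
#' First-order propagation of the analytical SDs of the two amino-acid
#' determinations through the trophic-position equation; beta and
#' Delta_Glu-Phe are treated as exact because the error budget covers
#' analytical error only:
#'
#'   SE(TP) = sqrt(sd_Glu^2 + sd_Phe^2) / Delta_Glu-Phe
#'
#' @param sd_glu,sd_phe per-mil analytical SDs (vectorised, >= 0).
#' @inheritParams compute_tp
#' @return standard error in trophic-position units.
#' @examples
#' propagate_tp_se(1, 1)  # sqrt(2)/7.6 ~ 0.186, below the 0.2 bound
#' @export
propagate_tp_se <- function(sd_glu, sd_phe, constants = study_constants()) {
  if (any(sd_glu < 0) || any(sd_phe < 0)) stop("SDs must be >= 0")
  if (constants$delta_glu_phe == 0) stop("delta_glu_phe must be non-zero")
  sqrt(sd_glu^2 + sd_phe^2) / abs(constants$delta_glu_phe)
}

#' Classify a trophic position
#'
#' Maps trophic-position values to the conventional classes: exactly 1 is
#' autotrophy, (1, 2) mixotrophy, exactly 2 herbivory, (2, 3) omnivory and
#' >= 3 carnivory. Mixotrophs near the documented nutritional extremes get
#' a sublabel: `mainly_autotrophy` for TP in [1.2, 1.4] (the "approximately
#' 1.3" autotrophic phase) and `mainly_herbivory` for TP in [1.8, 2.0) (the
#' "approximately 1.9" algivorous phase). Values below 1 are reported as
#' autotrophy with a warning since they fall outside the model's range.
#'
#' @param tp numeric trophic position(s).
#' @return data.frame with columns `tp`, `trophic_class`, `sublabel`
#'   (`NA` when no sublabel applies).
#' @examples
#' classify_tp(c(1, 1.3, 1.9, 2, 2.6, 3.2))
#' @export
classify_tp <- function(tp) {
  if (!all(is.finite(tp))) stop("tp must be finite")
  # tolerance guards against floating-point dust from exact inversions
  if (any(tp < 1 - 1e-8)) {
    warning("trophic position below 1 is outside the model range; ",
            "reported as autotrophy")
  }
  cls <- ifelse(tp <= 1, "autotrophy",
         ifelse(tp < 2, "mixotrophy",
         ifelse(tp == 2, "herbivory",
         ifelse(tp < 3, "omnivory", "carnivory"))))
  sub <- rep(NA_character_, length(tp))
  sub[cls == "mixotrophy" & tp >= 1.2 & tp <= 1.4] <- "mainly_autotrophy"
  sub[cls == "mixotrophy" & tp >= 1.8 & tp < 2.0] <- "mainly_herbivory"
  data.frame(tp = tp, trophic_class = cls, sublabel = sub,
             stringsAsFactors = FALSE)
}

#' Validate a table of amino-acid delta-15N profiles
#'
#' @param x data.frame with columns `specimen_id`, `species`, `tissue`,
#'   `delta15n_glu`, `delta15n_phe` and optionally `sd_glu`, `sd_phe`
#'   (missing SDs are filled with the typical amino-acid analytical
#'   precision, 1.0 per mil, when the table is used by [estimate_tp()]).
#' @return the validated data.frame, classed `aa_profile`.
#' @export
aa_profiles <- function(x) {
  required <- c("specimen_id", "species", "tissue",
                "delta15n_glu", "delta15n_phe")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0) stop("no profiles")
  if (!"sd_glu" %in% names(x)) x$sd_glu <- NA_real_
  if (!"sd_phe" %in% names(x)) x$sd_phe <- NA_real_
  if (!all(is.finite(x$delta15n_glu)) || !all(is.finite(x$delta15n_phe))) {
    stop("amino-acid delta-15N values must be finite")
  }
  for (col in c("sd_glu", "sd_phe")) {
    given <- !is.na(x[[col]])
    if (any(x[[col]][given] < 0)) stop(col, " must be >= 0")
  }
  class(x) <- unique(c("aa_profile", class(x)))
  x
}

#' Read amino-acid profiles from CSV
#'
#' @param file path to a CSV with the header documented in [aa_profiles()].
#' @return a validated `aa_profile` data.frame.
#' @export
read_aa_profiles <- function(file) {
  aa_profiles(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' Estimate trophic positions for a table of amino-acid profiles
#'
#' Applies [compute_tp()], [propagate_tp_se()] and [classify_tp()] to each
#' specimen. `method = "individual"` (the default) estimates one TP per
#' specimen; group-level means can then be taken with `summary()`.
#' `method = "pooled"` first averages the Glu and Phe values within each
#' species x tissue group and computes one TP from the mean amino-acid
#' values (its SE uses the analytical SDs scaled by 1/sqrt(n)).
#'
#' @param profiles an `aa_profile` table (see [aa_profiles()]).
#' @param constants a [study_constants()] object.
#' @param method `"individual"` or `"pooled"`.
#' @return the input table (or the pooled group table) with columns `tp`,
#'   `se`, `trophic_class`, `sublabel` appended; classed `tp_estimate`.
#' @examples
#' prof <- aa_profiles(data.frame(
#'   specimen_id = c("v1", "v2"), species = "Nassarius vinctus",
#'   tissue = "whole", delta15n_glu = c(15.0, 15.3),
#'   delta15n_phe = c(6.3, 6.5), sd_glu = 1, sd_phe = 1))
#' est <- estimate_tp(prof)
#' summary(est)
#' @export
estimate_tp <- function(profiles, constants = study_constants(),
                        method = c("individual", "pooled")) {
  method <- match.arg(method)
  profiles <- aa_profiles(profiles)
  profiles$sd_glu[is.na(profiles$sd_glu)] <- constants$aa_sd_default
  profiles$sd_phe[is.na(profiles$sd_phe)] <- constants$aa_sd_default

  if (method == "pooled") {
    grp <- interaction(profiles$species, profiles$tissue,
                       drop = TRUE, lex.order = TRUE)
    pieces <- split(profiles, grp)
    profiles <- do.call(rbind, lapply(pieces, function(p) {
      data.frame(specimen_id = paste(p$specimen_id, collapse = "+"),
                 species = p$species[1], tissue = p$tissue[1],
                 delta15n_glu = mean(p$delta15n_glu),
                 delta15n_phe = mean(p$delta15n_phe),
                 sd_glu = sqrt(mean(p$sd_glu^2) / nrow(p)),
                 sd_phe = sqrt(mean(p$sd_phe^2) / nrow(p)),
                 n = nrow(p), stringsAsFactors = FALSE)
    }))
    rownames(profiles) <- NULL
  }

  tp <- compute_tp(profiles$delta15n_glu, profiles$delta15n_phe, constants)
  cls <- classify_tp(tp)
  profiles$tp <- tp
  profiles$se <- propagate_tp_se(profiles$sd_glu, profiles$sd_phe, constants)
  profiles$trophic_class <- cls$trophic_class
  profiles$sublabel <- cls$sublabel
  attr(profiles, "method") <- method
  class(profiles) <- unique(c("tp_estimate", class(profiles)))
  profiles
}

#' @export
print.tp_estimate <- function(x, digits = 2, ...) {
  cat("Trophic position estimates (", attr(x, "method"), " method):\n",
      sep = "")
  for (i in seq_len(nrow(x))) {
    lab <- paste(x$species[i], x$tissue[i], x$specimen_id[i], sep = " / ")
    extra <- if (!is.na(x$sublabel[i])) paste0(", ", x$sublabel[i]) else ""
    cat(sprintf("  %-50s TP %.*f ± %.*f  (%s%s)\n", lab, digits, x$tp[i],
                digits, x$se[i], x$trophic_class[i], extra))
  }
  invisible(x)
}

#' Summarise trophic position estimates per species and tissue
#'
#' Averages per-individual TP estimates within species x tissue groups and
#' classifies the group mean.
#'
#' @param object a `tp_estimate` table from [estimate_tp()].
#' @param ... unused.
#' @return data.frame with group keys, `n`, `tp_mean`, `tp_sd` (sample SD
#'   of individual TPs, 0 for singletons), `se_mean` (mean propagated SE)
#'   and the class of the mean TP.
#' @export
summary.tp_estimate <- function(object, ...) {
  grp <- interaction(object$species, object$tissue,
                     drop = TRUE, lex.order = TRUE)
  pieces <- split(seq_len(nrow(object)), grp)
  out <- do.call(rbind, lapply(pieces, function(idx) {
    tps <- object$tp[idx]
    data.frame(species = object$species[idx[1]],
               tissue = object$tissue[idx[1]],
               n = length(tps),
               tp_mean = mean(tps),
               tp_sd = if (length(tps) > 1) stats::sd(tps) else 0,
               se_mean = mean(object$se[idx]),
               stringsAsFactors = FALSE)
  }))
  cls <- classify_tp(out$tp_mean)
  out$trophic_class <- cls$trophic_class
  out$sublabel <- cls$sublabel
  rownames(out) <- NULL
  out
}

#' Compare a measured Phe baseline with a reference value
#'
#' Because phenylalanine delta-15N is nearly conserved across trophic
#' transfers, a consumer's d15N_Phe can be compared directly with the
#' baseline of a candidate food web (e.g. 5.3 per mil for
#' sedimented-diatom consumers on the Namibian shelf).
#'
#' @param measured_phe measured d15N_Phe, per mil (vectorised).
#' @param reference_phe reference baseline, per mil.
#' @param tolerance per-mil tolerance; defaults to the amino-acid analytical
#'   precision of 1.0.
#' @return data.frame with `difference` (measured - reference) and
#'   `verdict` (`consistent` when |difference| <= tolerance, else `above`
#'   or `below`).
#' @examples
#' compare_baseline_phe(c(4.7, 6.4), 5.3)
#' @export
compare_baseline_phe <- function(measured_phe, reference_phe = 5.3,
                                 tolerance = 1.0) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  diff <- measured_phe - reference_phe
  verdict <- ifelse(abs(diff) <= tolerance, "consistent",
                    ifelse(diff > 0, "above", "below"))
  data.frame(measured_phe = measured_phe, reference_phe = reference_phe,
             difference = diff, verdict = verdict, stringsAsFactors = FALSE)
}
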