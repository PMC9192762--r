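VALID_TISSUES <- c("gill", "body", "whole", "sediment")
VALID_ISOTOPES <- c("C13", "N15")

#' Validate a table of bulk isotope measurements
#'
#' A bulk record is one calibrated delta-13C or delta-15N measurement (per
#' mil vs PDB for carbon, vs atmospheric N2 for nitrogen) with specimen,
#' tissue and station context and a flag recording whether the subsample was
#' acidified before analysis.
#'
#' @param x data.frame with columns `specimen_id`, `species`, `station`,
#'   `tissue` (one of gill, body, whole, sediment), `isotope` (`"C13"` or
#'   `"N15"`), `value` (per mil), `acidified` (logical). Optional:
#'   `analytical_sd` (per mil, >= 0) and `n15_corrected` (logical provenance
#'   flag, added as `FALSE` when absent).
#' @return `x` with the optional columns filled in, classed
#'   `bulk_isotope`.
#' @examples
#' recs <- bulk_isotope_records(data.frame(
#'   specimen_id = "c1", species = "Lucinoma capensis", station = "48",
#'   tissue = "gill", isotope = "N15", value = -4.9, acidified = FALSE))
#' @export
bulk_isotope_records <- function(x) {
  required <- c("specimen_id", "species", "station", "tissue", "isotope",
                "value", "acidified")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0) stop("no records")
  if (!"analytical_sd" %in% names(x)) x$analytical_sd <- NA_real_
  if (!"n15_corrected" %in% names(x)) x$n15_corrected <- FALSE

  if (!all(x$tissue %in% VALID_TISSUES)) {
    stop("tissue must be one of: ", paste(VALID_TISSUES, collapse = ", "))
  }
  if (!all(x$isotope %in% VALID_ISOTOPES)) {
    stop("isotope must be one of: ", paste(VALID_ISOTOPES, collapse = ", "))
  }
  if (!all(is.finite(x$value))) stop("all values must be finite")
  x$acidified <- as.logical(x$acidified)
  x$n15_corrected <- as.logical(x$n15_corrected)
  if (anyNA(x$acidified)) stop("acidified must be TRUE/FALSE")
  sd_given <- !is.na(x$analytical_sd)
  if (any(x$analytical_sd[sd_given] < 0)) stop("analytical_sd must be >= 0")
  sed <- x$tissue == "sediment"
  if (any(sed & !(is.na(x$species) | x$species == ""))) {
    stop("sediment records must have an empty species field")
  }
  class(x) <- unique(c("bulk_isotope", class(x)))
  x
}

#' Read bulk isotope measurements from CSV
#'
#' @param file path to a CSV with the header documented in
#'   [bulk_isotope_records()].
#' @return a validated `bulk_isotope` data.frame.
#' @export
read_bulk_isotopes <- function(file) {
  bulk_isotope_records(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' Correct acidified bulk delta-15N values
#'
#' Acidification (HCl, to remove carbonates before carbon analysis) shifts
#' bulk delta-15N; measurements of mollusc tissue analysed both ways differ
#' by 0.3 per mil, so acidified delta-15N values are corrected by
#' subtracting that offset. Carbon values and non-acidified samples are
#' unchanged. A provenance flag marks corrected rows so the correction can
#' never be applied twice.
#'
#' @param records a `bulk_isotope` table (see [bulk_isotope_records()]).
#' @param constants a [study_constants()] object; `acidification_offset` is
#'   used.
#' @return the table with corrected delta-15N values and `n15_corrected`
#'   set on the affected rows.
#' @examples
#' recs <- bulk_isotope_records(data.frame(
#'   specimen_id = "v1", species = "Nassarius vinctus", station = "12",
#'   tissue = "whole", isotope = "N15", value = 10.7, acidified = TRUE))
#' apply_acidification_correction(recs)$value  # 10.4
#' @export
apply_acidification_correction <- function(records,
                                           constants = study_constants()) {
  records <- bulk_isotope_records(records)
  if (any(records$n15_corrected)) {
    stop("records already corrected; refusing to correct twice")
  }
  sel <- records$acidified & records$isotope == "N15"
  records$value[sel] <- records$value[sel] - constants$acidification_offset
  records$n15_corrected[sel] <- TRUE
  records
}

#' Group-wise means and standard deviations
#'
#' Summarises bulk measurements per group (by default species x tissue x
#' isotope) as n, mean and sample standard deviation, the form in which
#' such measurements are conventionally reported (mean +/- SD, n). Sample
#' SD uses the n-1 denominator; singleton groups report SD 0.
#'
#' @param records a `bulk_isotope` table.
#' @param keys character vector of grouping columns.
#' @return data.frame with the key columns plus `n`, `mean`, `sd`, classed
#'   `group_summary`.
#' @examples
#' recs <- bulk_isotope_records(data.frame(
#'   specimen_id = c("a", "b", "c"), species = "Lembulus bicuspidatus",
#'   station = "24", tissue = "whole", isotope = "C13",
#'   value = c(-16, -17, -18), acidified = FALSE))
#' summarize_groups(recs)
#' @export
summarize_groups <- function(records,
                             keys = c("species", "tissue", "isotope")) {
  records <- bulk_isotope_records(records)
  if (length(keys) == 0 || !all(keys %in% names(records))) {
    stop("grouping keys must be columns of the record table")
  }
  key_df <- records[keys]
  key_df[] <- lapply(key_df, function(col) {
    col[is.na(col)] <- ""
    as.character(col)
  })
  grp <- interaction(key_df, drop = TRUE, lex.order = TRUE)

  if (!"isotope" %in% keys) {
    mixed <- tapply(records$isotope, grp, function(v) length(unique(v)) > 1)
    if (any(mixed)) {
      stop("a group mixes C13 and N15 values; add 'isotope' to the keys")
    }
  }

  pieces <- split(seq_len(nrow(records)), grp)
  out <- do.call(rbind, lapply(pieces, function(idx) {
    vals <- records$value[idx]
    row <- key_df[idx[1], , drop = FALSE]
    row$n <- length(vals)
    row$mean <- mean(vals)
    row$sd <- if (length(vals) > 1) stats::sd(vals) else 0
    row
  }))
  rownames(out) <- NULL
  class(out) <- unique(c("group_summary", class(out)))
  out
}

#' @export
print.group_summary <- function(x, digits = 2, ...) {
  cat("Group summaries (mean ± sample SD):\n")
  keys <- setdiff(names(x), c("n", "mean", "sd"))
  for (i in seq_len(nrow(x))) {
    label <- paste(unlist(x[i, keys]), collapse = " / ")
    cat(sprintf("  %-45s %s‰ ± %s‰ (n = %d)\n", label,
                format(round(x$mean[i], digits), nsmall = 1),
                format(round(x$sd[i], digits), nsmall = 1), x$n[i]))
  }
  invisible(x)
}
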