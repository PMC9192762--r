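#' Default species isotope profiles for simulation
#'
#' The per-species, per-tissue bulk isotope means and SDs that the
#' synthetic generator draws from, together with the study sample sizes:
#' L. capensis gill (-29.8 +/- 0.9 per mil C, -4.9 +/- 0.7 N; n = 3) and
#' non-symbiotic body (-28.8 +/- 0.8 C, -2.5 +/- 0.6 N; n = 3),
#' L. bicuspidatus whole animals (-16.7 +/- 0.4 C, 5.0 +/- 0.3 N; n = 13)
#' and N. vinctus whole animals (-17.5 +/- 0.1 C, 10.4 +/- 0.4 N; n = 6).
#'
#' @return data.frame with columns `species`, `station`, `tissue`,
#'   `isotope`, `mean`, `sd`, `n`.
#' @export
default_species_profiles <- function() {
  data.frame(
    species = rep(c("Lucinoma capensis", "Lucinoma capensis",
                    "Lembulus bicuspidatus", "Nassarius vinctus"),
                  each = 2),
    station = rep(c("48", "48", "24", "12"), each = 2),
    tissue = rep(c("gill", "body", "whole", "whole"), each = 2),
    isotope = rep(c("C13", "N15"), times = 4),
    mean = c(-29.8, -4.9, -28.8, -2.5, -16.7, 5.0, -17.5, 10.4),
    sd = c(0.9, 0.7, 0.8, 0.6, 0.4, 0.3, 0.1, 0.4),
    n = rep(c(3, 3, 13, 6), each = 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate bulk isotope specimens
#'
#' Draws Gaussian bulk delta-13C / delta-15N values around each configured
#' species x tissue x isotope mean. Deterministic under a fixed seed.
#'
#' @param n_per_group number of specimens per group; `NULL` uses the `n`
#'   column of `profiles` (the study sample sizes).
#' @param profiles data.frame like [default_species_profiles()].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a validated [bulk_isotope_records()] table.
#' @examples
#' head(gen_bulk_specimens(seed = 1))
#' @export
gen_bulk_specimens <- function(n_per_group = NULL,
                               profiles = default_species_profiles(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(profiles$sd < 0)) stop("profile SDs must be >= 0")
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    n <- if (is.null(n_per_group)) p$n else n_per_group
    if (n < 1) stop("n per group must be >= 1")
    data.frame(
      specimen_id = sprintf("%s_%s_%02d",
                            abbreviate(gsub(" ", "", p$species), 6),
                            p$tissue, seq_len(n)),
      species = p$species, station = p$station, tissue = p$tissue,
      isotope = p$isotope,
      value = stats::rnorm(n, p$mean, p$sd),
      acidified = FALSE, analytical_sd = 0.2,
      stringsAsFactors = FALSE
    )
  })
  bulk_isotope_records(do.call(rbind, rows))
}

#' Simulate amino-acid delta-15N profiles at a known trophic position
#'
#' Builds Glu/Phe pairs that satisfy the trophic-position equation exactly
#' at zero noise: the true Phe value is the configured baseline and the
#' true Glu value is baseline - beta + (true_tp - 1) * Delta_Glu-Phe.
#' Independent Gaussian analytical noise is then added to each amino acid,
#' so with noise SD 1.0 per mil the spread of estimated trophic positions
#' matches the propagated analytical SE, sqrt(2)/Delta.
#'
#' @param n number of specimens (>= 1).
#' @param true_tp the true trophic position to encode.
#' @param baseline_phe per-mil Phe baseline (default the sedimented-diatom
#'   consumer value 5.3).
#' @param noise_sd per-mil analytical noise SD applied independently to
#'   Glu and Phe (default 1.0, the typical amino-acid precision).
#' @param species,tissue labels for the generated profiles.
#' @param constants a [study_constants()] object.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return an [aa_profiles()] table with `sd_glu`, `sd_phe` set to
#'   `noise_sd`.
#' @examples
#' prof <- gen_aa_profiles(3, true_tp = 2.6, baseline_phe = 6.4,
#'                         noise_sd = 0)
#' estimate_tp(prof)$tp  # exactly 2.6
#' @export
gen_aa_profiles <- function(n, true_tp, baseline_phe = 5.3, noise_sd = 1.0,
                            species = "synthetic", tissue = "whole",
                            constants = study_constants(), seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.finite(true_tp)) stop("true_tp must be finite")
  if (!is.null(seed)) set.seed(seed)

  phe_true <- baseline_phe
  glu_true <- baseline_phe - constants$beta +
    (true_tp - 1) * constants$delta_glu_phe
  aa_profiles(data.frame(
    specimen_id = sprintf("sim_%03d", seq_len(n)),
    species = species, tissue = tissue,
    delta15n_glu = glu_true + stats::rnorm(n, 0, noise_sd),
    delta15n_phe = phe_true + stats::rnorm(n, 0, noise_sd),
    sd_glu = noise_sd, sd_phe = noise_sd,
    stringsAsFactors = FALSE
  ))
}

#' Simulate a paired animal/blank incubation
#'
#' Generates a blank vial drifting linearly from a starting concentration
#' and an animal vial that adds the concentration change implied by a true
#' biomass-normalised rate: animal(t) = start + drift * t +
#' (true_rate * afdw / volume) * t, each series plus independent Gaussian
#' noise. Concentrations are floored at zero with a warning (the vial went
#' anoxic / the analyte was exhausted), mirroring real incubations.
#'
#' @param true_rate true net rate, micromol (or ml for oxygen) per hour
#'   per gram AFDW; negative = consumption.
#' @param analyte one of oxygen, nitrate, nitrite, ammonium.
#' @param afdw grams of ash-free dry weight of the simulated animal.
#' @param start_conc starting concentration; defaults per analyte to the
#'   benthic boundary layer values at the central-shelf station (nitrate
#'   21.8 umol/l, ammonium 0.86 umol/l, oxygen 0.73 ml/l, nitrite 0.2
#'   umol/l).
#' @param volume vial volume in litres (default 0.02, a 20 ml vial).
#' @param times sampling times in hours (default 0 to 52 h every 4 h).
#' @param noise_sd measurement noise SD in concentration units.
#' @param blank_drift background drift slope, concentration units per
#'   hour.
#' @param species label for the animal vial.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list with elements `animal` and `blank`, both
#'   [incubation_vial()] objects, plus `afdw` and `true_rate`.
#' @examples
#' sim <- gen_incubation_series(true_rate = -0.16, analyte = "nitrate",
#'                              afdw = 0.05, seed = 1)
#' net_rate(sim$animal, sim$blank, sim$afdw)
#' @export
gen_incubation_series <- function(true_rate, analyte = "nitrate",
                                  afdw = 0.05, start_conc = NULL,
                                  volume = 0.02, times = seq(0, 52, by = 4),
                                  noise_sd = 0, blank_drift = 0,
                                  species = "synthetic", seed = NULL) {
  if (!analyte %in% VALID_ANALYTES) {
    stop("analyte must be one of: ", paste(VALID_ANALYTES, collapse = ", "))
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (afdw <= 0 || volume <= 0) stop("afdw and volume must be > 0")
  if (is.null(start_conc)) {
    start_conc <- c(oxygen = 0.73, nitrate = 21.8, nitrite = 0.2,
                    ammonium = 0.86)[[analyte]]
  }
  if (!is.null(seed)) set.seed(seed)

  floor0 <- function(x) {
    if (any(x < 0)) {
      warning("concentrations floored at 0 (pool exhausted)")
      x[x < 0] <- 0
    }
    x
  }
  blank_conc <- start_conc + blank_drift * times +
    stats::rnorm(length(times), 0, noise_sd)
  animal_conc <- start_conc + blank_drift * times +
    (true_rate * afdw / volume) * times +
    stats::rnorm(length(times), 0, noise_sd)

  list(
    animal = incubation_vial("sim_animal", analyte, times,
                             floor0(animal_conc), volume,
                             species = species, is_blank = FALSE),
    blank = incubation_vial("sim_blank", analyte, times,
                            floor0(blank_conc), volume, is_blank = TRUE),
    afdw = afdw, true_rate = true_rate
  )
}

#' Simulate a complete synthetic study
#'
#' Generates the three input tables the pipeline consumes — bulk isotope
#' records at the study group means, amino-acid profiles per species at
#' their mean trophic positions, and paired incubation series at the
#' reported net rates — and optionally writes them (plus a YAML echo of
#' the configuration) to a directory.
#'
#' @param seed integer seed controlling all randomness.
#' @param dir if non-`NULL`, directory to write `bulk.csv`,
#'   `aa_profiles.csv`, `incubations.csv` and `sim_config.yaml` into
#'   (created if needed).
#' @param aa_noise_sd per-mil amino-acid noise (default 1.0).
#' @param constants a [study_constants()] object.
#' @return (invisibly, when writing) list with `bulk`, `aa`, `incubations`
#'   (long-format data.frame) and `config`.
#' @export
simulate_study <- function(seed, dir = NULL, aa_noise_sd = 1.0,
                           constants = study_constants()) {
  set.seed(seed)
  bulk <- gen_bulk_specimens()

  # per-species mean TPs and Phe baselines as reported for the study taxa
  aa_spec <- data.frame(
    species = c("Lucinoma capensis", "Lucinoma capensis",
                "Lembulus bicuspidatus", "Nassarius vinctus"),
    tissue = c("gill", "body", "whole", "whole"),
    true_tp = c(1.3, 1.4, 1.7, 2.6),
    baseline_phe = c(-6.0, -4.8, 4.7, 6.4),
    n = c(3, 3, 3, 3), stringsAsFactors = FALSE
  )
  aa <- do.call(rbind, lapply(seq_len(nrow(aa_spec)), function(i) {
    s <- aa_spec[i, ]
    prof <- gen_aa_profiles(s$n, s$true_tp, s$baseline_phe,
                            noise_sd = aa_noise_sd, species = s$species,
                            tissue = s$tissue, constants = constants)
    prof$specimen_id <- paste0(prof$specimen_id, "_", i)
    prof
  }))
  class(aa) <- unique(c("aa_profile", "data.frame"))

  # reported mean net rates per species and analyte
  rate_spec <- data.frame(
    species = rep(c("Lucinoma capensis", "Nassarius vinctus",
                    "Lembulus bicuspidatus"), each = 4),
    analyte = rep(c("nitrate", "ammonium", "oxygen", "nitrite"), times = 3),
    true_rate = c(-0.16, 0.14, -0.03, 0.14,
                  -0.05, 1.14, -0.11, 0.03,
                  0.0065, 0.97, -0.001, 0.1),
    stringsAsFactors = FALSE
  )
  inc_rows <- list()
  for (i in seq_len(nrow(rate_spec))) {
    r <- rate_spec[i, ]
    sim <- gen_incubation_series(r$true_rate, analyte = r$analyte,
                                 species = r$species,
                                 noise_sd = 0.01, blank_drift = -0.005)
    for (role in c("animal", "blank")) {
      v <- sim[[role]]
      inc_rows[[length(inc_rows) + 1]] <- data.frame(
        vial_id = paste0(v$vial_id, "_", i), species = v$species,
        analyte = v$analyte, time_h = v$times,
        concentration = v$concentrations, volume_l = v$volume,
        is_blank = v$is_blank, wet_weight_g = sim$afdw / 0.09,
        stringsAsFactors = FALSE)
    }
  }
  incubations <- do.call(rbind, inc_rows)

  config <- list(seed = seed, aa_noise_sd = aa_noise_sd,
                 constants = unclass(constants))
  out <- list(bulk = bulk, aa = aa, incubations = incubations,
              config = config)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(as.data.frame(bulk), file.path(dir, "bulk.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(aa), file.path(dir, "aa_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(incubations, file.path(dir, "incubations.csv"),
                     row.names = FALSE)
    yaml::write_yaml(config, file.path(dir, "sim_config.yaml"))
    return(invisible(out))
  }
  out
}
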