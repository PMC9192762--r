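# Small in-code fixtures shared across test files.

make_bulk <- function(values, species = "sp", tissue = "whole",
                      isotope = "N15", acidified = FALSE, station = "12") {
  bulk_isotope_records(data.frame(
    specimen_id = sprintf("s%02d", seq_along(values)),
    species = species, station = station, tissue = tissue,
    isotope = isotope, value = values, acidified = acidified,
    stringsAsFactors = FALSE
  ))
}

make_profile <- function(glu, phe, sd_glu = 1, sd_phe = 1,
                         species = "sp", tissue = "whole") {
  aa_profiles(data.frame(
    specimen_id = sprintf("p%02d", seq_along(glu)),
    species = species, tissue = tissue,
    delta15n_glu = glu, delta15n_phe = phe,
    sd_glu = sd_glu, sd_phe = sd_phe, stringsAsFactors = FALSE
  ))
}
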