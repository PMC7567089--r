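# tiny in-code fixtures shared across test files

make_extraction <- function(sample_id = "s1", sample_mass_mg = 1,
                            f_recovered = 1, standard_area = 1,
                            standard_ug_c = 1, delta13c_methanol = -40) {
  tibble::tibble(
    sample_id = sample_id, sample_mass_mg = sample_mass_mg,
    f_recovered = f_recovered, standard_area = standard_area,
    standard_ug_c = standard_ug_c, delta13c_methanol = delta13c_methanol
  )
}

make_peaks <- function(sample_id = "s1", fatty_acid = "C16:0", area = 1,
                       delta13c_fame = -28) {
  tibble::tibble(
    sample_id = sample_id, fatty_acid = fatty_acid, area = area,
    delta13c_fame = delta13c_fame
  )
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "spongeflux", mustWork = TRUE)
}

read_fixture_peaks <- function() {
  readr::read_csv(fixture_path("bacteria_food_plfa_peaks.csv"),
    show_col_types = FALSE)
}

read_fixture_extraction <- function() {
  readr::read_csv(fixture_path("bacteria_food_plfa_extraction.csv"),
    show_col_types = FALSE)
}
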