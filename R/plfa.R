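#' PLFA concentration from chromatogram peak areas
#'
#' Concentration of a PLFA in a sample, relative to the C19:0 internal
#' standard:
#' \deqn{C_{PLFA} = \frac{A_{PLFA} / A_{19:0} \times C_{19:0}}{g_s \times f}
#'   \times \frac{n}{n+1}}
#' where \eqn{g_s} is the amount of sample extracted (mg), \eqn{f} the
#' fraction of the DCM phase recovered, and \eqn{n} the number of carbon
#' atoms of the fatty acid. The factor \eqn{n/(n+1)} removes the methyl
#' carbon added during derivatization to the FAME.
#'
#' @param area Peak area of the PLFA (arbitrary chromatogram units).
#' @param standard_area Peak area of the C19:0 internal standard.
#' @param standard_ug_c Carbon amount of the internal standard (ug C).
#' @param sample_mass_mg Amount of sample extracted (mg).
#' @param f_recovered Fraction of DCM recovered, in (0, 1].
#' @param chain_length Carbon number n of the fatty acid.
#' @return Concentration in ug C per mg sample.
#' @examples
#' plfa_concentration(1, 1, 1, 1, 1, 19)  # 0.95
#' @export
plfa_concentration <- function(area, standard_area, standard_ug_c,
                               sample_mass_mg, f_recovered, chain_length) {
  if (any(standard_area <= 0, na.rm = TRUE)) {
    abort("`standard_area` must be > 0.", class = "spongeflux_error_domain")
  }
  if (any(f_recovered <= 0 | f_recovered > 1, na.rm = TRUE)) {
    abort("`f_recovered` must lie in (0, 1].", class = "spongeflux_error_domain")
  }
  if (any(sample_mass_mg <= 0, na.rm = TRUE)) {
    abort("`sample_mass_mg` must be > 0.", class = "spongeflux_error_domain")
  }
  (area / standard_area * standard_ug_c) / (sample_mass_mg * f_recovered) *
    chain_length / (chain_length + 1)
}

#' Correct FAME delta-13C for the derivatization methyl carbon
#'
#' The methyl ester measured by GC-c-IRMS carries one methanol-derived
#' carbon. Mass balance over the n fatty-acid carbons gives
#' \deqn{\delta^{13}C_{PLFA} = \frac{(n+1)\,\delta^{13}C_{FAME} -
#'   \delta^{13}C_{methanol}}{n}.}
#' When the FAME and the methanol share the same delta the correction is the
#' identity; its magnitude shrinks as 1/n.
#'
#' @param delta_fame Measured delta-13C of the FAME (per mil).
#' @param delta_methanol delta-13C of the derivatization methanol (per mil).
#' @param chain_length Carbon number n of the fatty acid (>= 1).
#' @return delta-13C of the underlying fatty acid (per mil).
#' @examples
#' correct_fame_delta(0, -40, 15)  # +2.667
#' @export
correct_fame_delta <- function(delta_fame, delta_methanol, chain_length) {
  if (any(chain_length < 1, na.rm = TRUE)) {
    abort("`chain_length` must be >= 1.", class = "spongeflux_error_domain")
  }
  ((chain_length + 1) * delta_fame - delta_methanol) / chain_length
}

#' Mix a fatty acid delta back into its methyl ester
#'
#' Inverse of [correct_fame_delta()]; used by the forward simulator and for
#' round-trip checks: \eqn{\delta_{FAME} = (n\,\delta_{PLFA} +
#' \delta_{methanol}) / (n+1)}.
#'
#' @param delta_plfa delta-13C of the fatty acid (per mil).
#' @inheritParams correct_fame_delta
#' @export
fame_from_plfa_delta <- function(delta_plfa, delta_methanol, chain_length) {
  (chain_length * delta_plfa + delta_methanol) / (chain_length + 1)
}

join_peaks <- function(peaks, extractions, standard_name = "C19:0") {
  required <- c("sample_id", "fatty_acid", "area", "delta13c_fame")
  stopifnot(all(required %in% names(peaks)))
  fa <- parse_fatty_acid(peaks$fatty_acid)
  x <- peaks |>
    mutate(fatty_acid = fa$fatty_acid, chain_length = fa$chain_length) |>
    inner_join(extractions, by = "sample_id")
  is_std <- x$fatty_acid == canonical_fatty_acid(standard_name)
  excluded <- x[is_std, c("sample_id", "fatty_acid")]
  if (nrow(excluded)) excluded$reason <- "internal standard peak"
  x <- x[!is_std, , drop = FALSE]
  x$conc_ug_per_mg <- plfa_concentration(
    x$area, x$standard_area, x$standard_ug_c,
    x$sample_mass_mg, x$f_recovered, x$chain_length
  )
  structure(x, excluded = excluded)
}

#' Relative PLFA profile of each sample
#'
#' Computes per-PLFA concentrations from a chromatogram peak table (see
#' [plfa_concentration()]), expresses each PLFA as a percentage of the total
#' PLFA carbon of its sample, and attaches a biomarker class (see
#' [classify_fatty_acid()]). Internal-standard peaks (`standard_name`) are
#' excluded from the profile; the exclusions are recorded in the
#' `"excluded"` attribute so no row disappears silently.
#'
#' @param peaks Tibble with columns `sample_id`, `fatty_acid`, `area`,
#'   `delta13c_fame`.
#' @param extractions Tibble with columns `sample_id`, `sample_mass_mg`,
#'   `f_recovered`, `standard_area`, `standard_ug_c`, `delta13c_methanol`.
#' @param classification Optional override table for [classify_fatty_acid()].
#' @param standard_name Name of the internal standard peak (default C19:0).
#' @return Tibble with one row per sample and fatty acid: concentration
#'   (ug C/mg), `pct` of total PLFA carbon, and `class`. Per-sample
#'   percentages sum to 100.
#' @export
plfa_profile <- function(peaks, extractions, classification = NULL,
                         standard_name = "C19:0") {
  x <- join_peaks(peaks, extractions, standard_name)
  excluded <- attr(x, "excluded")
  out <- x |>
    group_by(.data$sample_id) |>
    mutate(total = sum(.data$conc_ug_per_mg)) |>
    ungroup()
  if (any(out$total <= 0)) {
    bad <- unique(out$sample_id[out$total <= 0])
    warn(paste0("All-zero PLFA areas for sample(s): ",
      paste(bad, collapse = ", "), "; percentages set to NA."))
  }
  out <- out |>
    mutate(
      pct = ifelse(.data$total > 0, 100 * .data$conc_ug_per_mg / .data$total, NA_real_),
      class = classify_fatty_acid(.data$fatty_acid, classification)
    ) |>
    select("sample_id", "fatty_acid", "chain_length", "class",
      "conc_ug_per_mg", "pct")
  structure(out, excluded = excluded, class = class(out))
}

#' Biomarker class totals of PLFA profiles
#'
#' Sums the per-PLFA percentages of [plfa_profile()] within each biomarker
#' class. All three classes are reported for every sample (zero when
#' absent); totals sum to 100 per sample.
#'
#' @param profile Output of [plfa_profile()].
#' @return Tibble `sample_id` x `class` with `pct_total`.
#' @export
plfa_class_totals <- function(profile) {
  sums <- profile |>
    group_by(.data$sample_id, .data$class) |>
    summarise(pct_total = sum(.data$pct), .groups = "drop")
  tidyr::expand_grid(sample_id = unique(profile$sample_id),
    class = plfa_classes) |>
    left_join(sums, by = c("sample_id", "class")) |>
    mutate(pct_total = ifelse(is.na(.data$pct_total), 0, .data$pct_total)) |>
    arrange(.data$sample_id, .data$class)
}

#' Total PLFA carbon as a percentage of holobiont carbon
#'
#' Scales per-sample PLFA concentrations (ug C per mg dry mass) to the whole
#' specimen and expresses the summed PLFA carbon pool as a percentage of the
#' specimen's total organic carbon.
#'
#' @param profile Output of [plfa_profile()] (sample ids must be specimen ids).
#' @param specimens Tibble with `specimen_id`, `dry_weight_g`, `c_org_umol`.
#' @return Tibble with `specimen_id`, `plfa_umol_c`, `plfa_pct_of_c`.
#' @export
plfa_total_carbon <- function(profile, specimens) {
  profile |>
    group_by(sample_id = .data$sample_id) |>
    summarise(conc = sum(.data$conc_ug_per_mg), .groups = "drop") |>
    inner_join(specimens, by = c(sample_id = "specimen_id")) |>
    mutate(
      plfa_umol_c = .data$conc * .data$dry_weight_g * 1000 / 12.011,
      plfa_pct_of_c = 100 * .data$plfa_umol_c / .data$c_org_umol
    ) |>
    select(specimen_id = "sample_id", "plfa_umol_c", "plfa_pct_of_c")
}

#' Per-PLFA background delta-13C from unlabelled specimens
#'
#' Pools the derivatization-corrected delta-13C of unlabelled (background)
#' specimens into a species-by-fatty-acid background table, weighting
#' specimens by PLFA concentration.
#'
#' @inheritParams plfa_profile
#' @param specimens Specimen table with `specimen_id`, `species` and `role`
#'   (backgrounds have `role == "background"`).
#' @return Tibble `species`, `fatty_acid`, `delta13c_plfa`.
#' @export
plfa_background <- function(peaks, extractions, specimens,
                            standard_name = "C19:0") {
  bg_ids <- specimens$specimen_id[specimens$role == "background"]
  x <- join_peaks(peaks[peaks$sample_id %in% bg_ids, , drop = FALSE],
    extractions, standard_name)
  x |>
    inner_join(specimens[, c("specimen_id", "species")],
      by = c(sample_id = "specimen_id")) |>
    mutate(delta13c_plfa = correct_fame_delta(
      .data$delta13c_fame, .data$delta13c_methanol, .data$chain_length)) |>
    group_by(.data$species, .data$fatty_acid) |>
    summarise(
      delta13c_plfa = sum(.data$delta13c_plfa * .data$conc_ug_per_mg) /
        sum(.data$conc_ug_per_mg),
      .groups = "drop"
    )
}

#' Fatty acids labelled above background but absent from the food source
#'
#' Labelled fatty acids that do not occur in the food-source profile must
#' have been synthesised de novo by the holobiont. Membership is decided on
#' canonical names; the result is disjoint from the source profile by
#' construction.
#'
#' @param labelled Character vector of fatty acids whose excess enrichment
#'   exceeds the detection threshold.
#' @param source_profile Character vector of fatty acids present in the food
#'   source.
#' @return Character vector (canonical names) of de novo synthesised PLFAs.
#' @export
detect_de_novo <- function(labelled, source_profile) {
  if (length(labelled) == 0) return(character())
  setdiff(canonical_fatty_acid(labelled),
    if (length(source_profile)) canonical_fatty_acid(source_profile) else character())
}

#' Per-PLFA tracer incorporation rates
#'
#' Quantifies 13C-tracer incorporation into each PLFA of each labelled
#' specimen: the derivatization-corrected delta is compared with the
#' species-specific per-PLFA background (falling back to the species-wide
#' concentration-weighted background, then to `natural_delta` with a QC
#' warning), converted to atom fraction excess, and multiplied by the
#' whole-specimen PLFA carbon pool. Rates are normalised by holobiont carbon
#' biomass (mmol) and substrate exposure time (days):
#' rate_i = E_i x pool_i / biomass / duration. Per-PLFA percentages are of
#' the summed rate per specimen; fatty acids labelled above `threshold` but
#' absent from the food-source profile are flagged de novo.
#'
#' @inheritParams plfa_profile
#' @param specimens Specimen table (`specimen_id`, `species`, `role`,
#'   `dry_weight_g`, `c_org_umol`).
#' @param incubations Incubation table (`specimen_id`, `food_source`,
#'   `n_pulses`, `pulse_duration_h`).
#' @param background Optional tibble `species`, `fatty_acid`,
#'   `delta13c_plfa`; computed with [plfa_background()] when NULL.
#' @param source_profiles Optional tibble `food_source`, `fatty_acid` giving
#'   the fatty acids present in each food source (for de novo flags).
#' @param mode Atom-fraction mode, see [delta_to_fraction()].
#' @param threshold Atom-fraction-excess detection threshold for calling a
#'   PLFA "labelled" (default 1e-5).
#' @param natural_delta Fallback background delta-13C (per mil) when no
#'   unlabelled specimen covers a fatty acid (default -25).
#' @return Tibble, one row per labelled specimen and fatty acid:
#'   `excess`, `pool_umol_c`, `rate` (umol tracer C per mmol sponge C per
#'   day), `pct_of_total`, `labelled`, `de_novo`, `class`.
#' @export
plfa_incorporation <- function(peaks, extractions, specimens, incubations,
                               background = NULL, source_profiles = NULL,
                               classification = NULL,
                               mode = c("exact", "approx"),
                               threshold = 1e-5, natural_delta = -25,
                               standard_name = "C19:0") {
  mode <- match.arg(mode)
  if (is.null(background)) {
    background <- plfa_background(peaks, extractions, specimens, standard_name)
  }
  lab <- incubations[!is.na(incubations$specimen_id), , drop = FALSE]
  x <- join_peaks(peaks[peaks$sample_id %in% lab$specimen_id, , drop = FALSE],
    extractions, standard_name)
  x <- x |>
    inner_join(specimens[, c("specimen_id", "species", "dry_weight_g", "c_org_umol")],
      by = c(sample_id = "specimen_id")) |>
    inner_join(lab[, c("specimen_id", "food_source", "n_pulses", "pulse_duration_h")],
      by = c(sample_id = "specimen_id")) |>
    mutate(delta13c_plfa = correct_fame_delta(
      .data$delta13c_fame, .data$delta13c_methanol, .data$chain_length)) |>
    left_join(background, by = c("species", "fatty_acid"),
      suffix = c("", "_bg"))
  # fall back to species-wide concentration-weighted background, then default
  species_bg <- background |>
    group_by(.data$species) |>
    summarise(bg_species = mean(.data$delta13c_plfa), .groups = "drop")
  x <- left_join(x, species_bg, by = "species")
  missing_fa <- is.na(x$delta13c_plfa_bg)
  if (any(missing_fa)) {
    warn(paste0("No per-PLFA background for ",
      sum(missing_fa), " peak(s) (e.g. ",
      paste(head(unique(x$fatty_acid[missing_fa]), 3), collapse = ", "),
      "); using species-wide or natural-abundance background."))
  }
  bg_delta <- ifelse(missing_fa,
    ifelse(is.na(x$bg_species), natural_delta, x$bg_species),
    x$delta13c_plfa_bg)
  dur_d <- x$n_pulses * x$pulse_duration_h / 24
  x$excess <- excess_from_delta(x$delta13c_plfa, bg_delta, "13C", mode)
  x$pool_umol_c <- x$conc_ug_per_mg * x$dry_weight_g * 1000 / 12.011
  x$rate <- x$excess * x$pool_umol_c / (x$c_org_umol / 1000) / dur_d
  src <- if (is.null(source_profiles)) NULL else
    split(canonical_fatty_acid(source_profiles$fatty_acid), source_profiles$food_source)
  x |>
    group_by(.data$sample_id) |>
    mutate(pct_of_total = 100 * .data$rate / sum(.data$rate)) |>
    ungroup() |>
    mutate(
      labelled = .data$excess > threshold,
      de_novo = .data$labelled & purrr::map2_lgl(
        .data$fatty_acid, .data$food_source,
        function(f, s) !is.null(src) && !is.null(src[[s]]) && !(f %in% src[[s]])
      ),
      class = classify_fatty_acid(.data$fatty_acid, classification)
    ) |>
    select(specimen_id = "sample_id", "species", "food_source", "fatty_acid",
      "class", "conc_ug_per_mg", "pool_umol_c", "delta13c_plfa", "excess",
      "rate", "pct_of_total", "labelled", "de_novo")
}
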