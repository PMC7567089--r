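#' Biomass-normalised bulk tracer assimilation rate
#'
#' Multiplies the excess fractional abundance of the tissue by the element
#' pool it refers to, then normalises by the specimen's biomass in that
#' element (mmol) and by the substrate exposure time (days):
#' rate = E x pool / (biomass/1000) / duration. For whole-tissue
#' measurements the pool *is* the biomass (total organic C or N), in which
#' case the rate reduces to 1000 x E / duration.
#'
#' @param excess Atom fraction excess of the tissue (see [atom_excess()]).
#' @param pool_umol Size of the measured element pool (umol C or N).
#' @param biomass_umol Specimen biomass in the same element (umol).
#' @param duration_d Cumulative substrate exposure time (days).
#' @return Rate in umol tracer per mmol sponge C (or N) per day. Linear in
#'   `excess`; negative excess gives a negative rate (flagged downstream,
#'   never clamped).
#' @examples
#' bulk_assimilation(1e-3, 700, 1000, 1)  # 0.7
#' @export
bulk_assimilation <- function(excess, pool_umol, biomass_umol, duration_d) {
  if (any(pool_umol <= 0, na.rm = TRUE) || any(biomass_umol <= 0, na.rm = TRUE) ||
      any(duration_d <= 0, na.rm = TRUE)) {
    abort("`pool_umol`, `biomass_umol` and `duration_d` must be > 0.",
      class = "spongeflux_error_domain")
  }
  excess * pool_umol / (biomass_umol / 1000) / duration_d
}

#' Tracer respiration rate from dissolved inorganic carbon samples
#'
#' For each feeding pulse the tracer respired into the DIC pool is the rise
#' in DIC atom fraction between the start (`t0`) and end (`t_end`) of the
#' pulse times the DIC pool of the chamber:
#' tracer = (F(t_end) - F(t0)) x DIC x V. Pulse masses accumulate and the
#' total is normalised by biomass (mmol C) and cumulative exposure time
#' (days). Duplicate water samples (`replicate` column) are averaged within
#' each pulse and time point. The `t_end` DIC concentration is used for the
#' pool size; `pool = "mean"` averages t0 and t_end instead.
#'
#' @param dic One incubation's DIC samples: tibble with columns `pulse`,
#'   `time_point` (`"t0"`/`"t_end"`), `dic_umol_per_l`, `delta13c` and
#'   optionally `replicate`.
#' @param background_delta Not used in the difference itself (t0 serves as
#'   the within-pulse background) but kept for interface symmetry; ignored.
#' @param volume_l Chamber volume (L).
#' @param biomass_c_umol Specimen organic carbon (umol C).
#' @param duration_d Cumulative exposure time (days).
#' @param mode Atom-fraction mode, see [delta_to_fraction()].
#' @param pool `"t_end"` (default) or `"mean"`.
#' @param control_tracer_umol_d Optional mean tracer production rate
#'   (umol/d) of sponge-free control chambers, subtracted before biomass
#'   normalisation.
#' @return Rate in umol tracer C per mmol sponge C per day, with attribute
#'   `"per_pulse"` carrying the per-pulse tracer masses (umol).
#' @examples
#' dic <- tibble::tibble(pulse = 1, time_point = c("t0", "t_end"),
#'   dic_umol_per_l = 2100, delta13c = c(0, 10))
#' respiration_from_dic(dic, volume_l = 2, biomass_c_umol = 1000,
#'   duration_d = 1)
#' @export
respiration_from_dic <- function(dic, volume_l, biomass_c_umol, duration_d,
                                 mode = c("exact", "approx"),
                                 pool = c("t_end", "mean"),
                                 control_tracer_umol_d = 0,
                                 background_delta = NULL) {
  mode <- match.arg(mode)
  pool <- match.arg(pool)
  if (any(volume_l <= 0) || any(biomass_c_umol <= 0) || any(duration_d <= 0)) {
    abort("`volume_l`, `biomass_c_umol` and `duration_d` must be > 0.",
      class = "spongeflux_error_domain")
  }
  w <- dic |>
    group_by(.data$pulse, .data$time_point) |>
    summarise(
      dic_umol_per_l = mean(.data$dic_umol_per_l),
      delta13c = mean(.data$delta13c), .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "time_point",
      values_from = c("dic_umol_per_l", "delta13c"))
  need <- c("delta13c_t0", "delta13c_t_end")
  miss <- setdiff(need, names(w))
  if (length(miss) > 0 || anyNA(w[intersect(need, names(w))])) {
    gaps <- if (length(miss) > 0) {
      paste("all pulses missing", paste(sub("delta13c_", "", miss), collapse = ", "))
    } else {
      bad <- w$pulse[!complete.cases(w[need])]
      paste("pulse(s)", paste(bad, collapse = ", "), "missing a time point")
    }
    abort(paste0("Incomplete DIC series: ", gaps, "."),
      class = "spongeflux_error_missing_dic")
  }
  dic_pool <- switch(pool,
    t_end = w$dic_umol_per_l_t_end,
    mean = (w$dic_umol_per_l_t0 + w$dic_umol_per_l_t_end) / 2
  )
  dF <- delta_to_fraction(w$delta13c_t_end, "13C", mode) -
    delta_to_fraction(w$delta13c_t0, "13C", mode)
  per_pulse <- dF * dic_pool * volume_l
  rate <- (sum(per_pulse) - control_tracer_umol_d * duration_d) /
    (biomass_c_umol / 1000) / duration_d
  structure(rate, per_pulse = setNames(per_pulse, w$pulse))
}

#' Assimilation-to-respiration efficiency
#'
#' Percentage of total tracer processing (assimilation + respiration) that
#' was assimilated: 100 x A / (A + R). Undefined (NA, with a warning) when
#' both inputs are zero.
#'
#' @param assimilation,respiration Rates in the same units.
#' @return Efficiency in percent.
#' @examples
#' efficiency(0.61, 0.09)  # 87.1
#' @export
efficiency <- function(assimilation, respiration) {
  both_zero <- assimilation == 0 & respiration == 0
  if (any(both_zero, na.rm = TRUE)) {
    warn("Efficiency undefined when assimilation and respiration are both 0; returning NA.")
  }
  ifelse(both_zero, NA_real_,
    100 * assimilation / (assimilation + respiration))
}

#' Molar C:N ratio of assimilation
#'
#' Ratio of the biomass-normalised carbon assimilation rate to the
#' biomass-normalised nitrogen assimilation rate of the same specimen.
#' Invariant to rescaling both rates; undefined (NA) when the nitrogen rate
#' is zero.
#'
#' @param rate_c,rate_n Assimilation rates (umol tracer per mmol sponge C or
#'   N per day).
#' @return Dimensionless mol C : mol N ratio.
#' @export
assimilation_cn_ratio <- function(rate_c, rate_n) {
  ifelse(rate_n == 0, NA_real_, rate_c / rate_n)
}

#' Bulk assimilation and respiration rates for a whole experiment
#'
#' The main bulk pipeline: joins specimens, post-incubation tissue isotope
#' measurements, incubation schedules and DIC samples, and returns one row
#' per specimen and element with assimilation, respiration (carbon only),
#' total processing and efficiency. Specimens without an incubation record
#' (e.g. unlabelled background individuals) are excluded and accounted for
#' in the `"excluded"` attribute.
#'
#' @param specimens Tibble: `specimen_id`, `species`, `status`,
#'   `dry_weight_g`, `c_org_umol`, `n_org_umol`, `bg_delta13c`,
#'   `bg_delta15n` (and optionally `role`).
#' @param bulk_isotopes Tibble: `specimen_id`, `delta13c`, `delta15n`.
#' @param incubations Tibble: `incubation_id`, `specimen_id` (NA for
#'   sponge-free controls), `food_source`, `n_pulses`, `pulse_duration_h`,
#'   `chamber_volume_l`.
#' @param dic_samples Tibble: `incubation_id`, `pulse`, `time_point`,
#'   `dic_umol_per_l`, `delta13c`, `replicate`. NULL skips respiration.
#' @param mode Atom-fraction mode, see [delta_to_fraction()].
#' @param control_correct Subtract the mean tracer production of sponge-free
#'   control chambers from each specimen's respired tracer (default FALSE).
#' @param dic_pool Passed to [respiration_from_dic()] (`"t_end"` or `"mean"`).
#' @return Tibble with columns `specimen_id`, `species`, `food_source`,
#'   `element`, `assimilation_rate`, `respiration_rate`, `total_processing`,
#'   `efficiency_pct`, `cn_assimilation` (on C rows), `qc_negative_excess`.
#' @export
bulk_rates <- function(specimens, bulk_isotopes, incubations,
                       dic_samples = NULL, mode = c("exact", "approx"),
                       control_correct = FALSE,
                       dic_pool = c("t_end", "mean")) {
  mode <- match.arg(mode)
  dic_pool <- match.arg(dic_pool)
  lab <- incubations[!is.na(incubations$specimen_id), , drop = FALSE]
  x <- specimens |>
    inner_join(bulk_isotopes, by = "specimen_id") |>
    inner_join(lab, by = "specimen_id")
  dropped <- anti_join(specimens, x, by = "specimen_id")
  excluded <- tibble(
    specimen_id = dropped$specimen_id,
    reason = ifelse(dropped$specimen_id %in% bulk_isotopes$specimen_id,
      "no incubation record (unlabelled background specimen)",
      "no bulk isotope measurement")
  )
  dur_d <- x$n_pulses * x$pulse_duration_h / 24

  e_c <- excess_from_delta(x$delta13c, x$bg_delta13c, "13C", mode)
  e_n <- excess_from_delta(x$delta15n, x$bg_delta15n, "15N", mode)
  assim_c <- bulk_assimilation(e_c, x$c_org_umol, x$c_org_umol, dur_d)
  assim_n <- bulk_assimilation(e_n, x$n_org_umol, x$n_org_umol, dur_d)

  resp_c <- rep(NA_real_, nrow(x))
  if (!is.null(dic_samples)) {
    control_rate <- 0
    if (control_correct) {
      ctrl <- incubations[is.na(incubations$specimen_id), , drop = FALSE]
      if (nrow(ctrl) > 0) {
        rates <- purrr::pmap_dbl(
          list(ctrl$incubation_id, ctrl$chamber_volume_l,
            ctrl$n_pulses * ctrl$pulse_duration_h / 24),
          function(id, vol, dd) {
            d <- dic_samples[dic_samples$incubation_id == id, , drop = FALSE]
            if (nrow(d) == 0) return(NA_real_)
            # tracer umol per day in a sponge-free chamber
            r <- respiration_from_dic(d, vol, 1000, dd, mode, dic_pool)
            sum(attr(r, "per_pulse")) / dd
          })
        control_rate <- mean(rates, na.rm = TRUE)
        if (is.nan(control_rate)) control_rate <- 0
      }
    }
    resp_c <- purrr::pmap_dbl(
      list(x$incubation_id, x$chamber_volume_l, x$c_org_umol, dur_d),
      function(id, vol, bc, dd) {
        d <- dic_samples[dic_samples$incubation_id == id, , drop = FALSE]
        if (nrow(d) == 0) return(NA_real_)
        as.numeric(respiration_from_dic(d, vol, bc, dd, mode, dic_pool,
          control_tracer_umol_d = control_rate))
      })
  }

  total_c <- assim_c + resp_c
  out <- bind_rows(
    tibble(
      specimen_id = x$specimen_id, species = x$species,
      food_source = x$food_source, element = "C",
      excess = e_c,
      assimilation_rate = assim_c, respiration_rate = resp_c,
      total_processing = total_c,
      efficiency_pct = ifelse(is.na(resp_c), NA_real_,
        suppressWarnings(efficiency(assim_c, resp_c))),
      cn_assimilation = assimilation_cn_ratio(assim_c, assim_n),
      duration_d = dur_d
    ),
    tibble(
      specimen_id = x$specimen_id, species = x$species,
      food_source = x$food_source, element = "N",
      excess = e_n,
      assimilation_rate = assim_n, respiration_rate = NA_real_,
      total_processing = assim_n,
      efficiency_pct = NA_real_, cn_assimilation = NA_real_,
      duration_d = dur_d
    )
  ) |>
    mutate(qc_negative_excess = .data$excess < 0) |>
    arrange(.data$element, .data$species, .data$specimen_id)
  structure(out, excluded = excluded)
}

#' Relative assimilation and respiration (percent of total processing)
#'
#' Splits each specimen's total carbon processing into assimilated and
#' respired percentages; the two stack to exactly 100.
#'
#' @param rates Output of [bulk_rates()].
#' @return Tibble with `specimen_id`, `species`, `food_source`,
#'   `assimilated_pct`, `respired_pct`.
#' @export
relative_processing <- function(rates) {
  rates |>
    filter(.data$element == "C", !is.na(.data$respiration_rate)) |>
    mutate(
      assimilated_pct = 100 * .data$assimilation_rate / .data$total_processing,
      respired_pct = 100 * .data$respiration_rate / .data$total_processing
    ) |>
    select("specimen_id", "species", "food_source",
      "assimilated_pct", "respired_pct")
}
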