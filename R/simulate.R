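# Forward simulator of complete tracer feeding experiments. The generator
# draws per-specimen flux truths from the preset distributions, pushes them
# through the same isotope bookkeeping the analysis pipeline inverts
# (tissue excess, DIC trajectories, per-PLFA label allocation) and applies
# measurement noise in delta space.

#' Measurement and between-individual noise settings for the simulator
#'
#' @param measurement Scale on all measurement noise: bulk/PLFA delta SD
#'   (0.2 per mil at background, plus a proportional term of 0.5 percent of
#'   the enrichment above background), DIC delta SD (0.05 per mil), and
#'   chromatogram peak-area CV (5 percent). 0 switches measurement noise off.
#' @param individual Scale on all between-individual variation (lognormal
#'   CVs of rates, biomass and composition, and the logit-scale efficiency
#'   spread). 0 pins every specimen to the preset means.
#' @return A `sim_noise` list.
#' @export
sim_noise <- function(measurement = 1, individual = 1) {
  stopifnot(measurement >= 0, individual >= 0)
  structure(list(
    delta_sd = 0.2 * measurement,
    delta_rel_sd = 0.005 * measurement,
    dic_delta_sd = 0.05 * measurement,
    area_cv = 0.05 * measurement,
    individual = individual
  ), class = "sim_noise")
}

# lognormal with a given mean and CV (mean-preserving under any cv)
rlnorm_mean <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

sim_constants <- list(
  dic_umol_per_l = 2100, dic_t0_delta = 0.5,
  plfa_bg_delta = -26, methanol_delta = -40,
  sample_mass_mg = 150, f_recovered = 0.9,
  standard_area = 5000, standard_ug_c = 20,
  mol_mass_c = 12.011
)

delta_noise <- function(delta_true, delta_ref, noise) {
  sdv <- noise$delta_sd + noise$delta_rel_sd * abs(delta_true - delta_ref)
  delta_true + rnorm(length(delta_true), 0, sdv)
}

# per-specimen flux truth draw (rejection-sampled to the label mass budget)
draw_specimen_truth <- function(pr, sp, cal, noise) {
  ind <- noise$individual
  dur_d <- pr$n_pulses * pr$pulse_duration_h / 24
  food <- food_presets()
  food <- food[food$food_id == pr$food_id, ]
  fed_c_pulse <- pr$dose_umol_c_l * pr$chamber_volume_l * food$f13c_source
  fed_n_pulse <- pr$dose_umol_c_l / food$source_cn * pr$chamber_volume_l *
    food$f15n_source
  # a configuration whose mean demand exceeds the label fed is impossible
  mean_c_org <- sp$dry_weight_g * sp$carbon_pct_dw / 100 / sim_constants$mol_mass_c * 1e6
  mean_demand <- pr$total_mean * mean_c_org / 1000 * dur_d / pr$n_pulses
  if (mean_demand > fed_c_pulse) {
    abort(paste0("Preset `", pr$preset, "`: mean tracer demand per pulse (",
      signif(mean_demand, 3), " umol) exceeds the label fed (",
      signif(fed_c_pulse, 3), " umol)."),
      class = "spongeflux_error_mass_balance")
  }
  for (try in seq_len(1000)) {
    dw <- rlnorm_mean(1, sp$dry_weight_g, sp$dry_weight_cv * ind)
    c_org <- dw * sp$carbon_pct_dw / 100 / sim_constants$mol_mass_c * 1e6
    n_org <- c_org / sp$tissue_cn
    if (ind > 0) {
      z1 <- rnorm(1)
      z2 <- cal$rho * z1 + sqrt(1 - cal$rho^2) * rnorm(1)
      s2 <- (cal$sdlog_t * ind)^2
      total <- exp(log(pr$total_mean) - s2 / 2 + cal$sdlog_t * ind * z1)
      eff <- plogis(cal$mu_logit + cal$sigma_logit * ind * z2)
    } else {
      total <- pr$total_mean
      eff <- pr$eff_mean
    }
    assim_c <- eff * total
    resp_c <- (1 - eff) * total
    assim_n <- if (!is.na(pr$cn_mean)) {
      assim_c / rlnorm_mean(1, pr$cn_mean, pr$cn_cv * ind)
    } else {
      rlnorm_mean(1, pr$assim_n_mean, pr$assim_n_cv * ind)
    }
    plfa_rate <- min(rlnorm_mean(1, pr$plfa_rate_mean, pr$plfa_rate_cv * ind),
      0.5 * assim_c)
    ok_c <- total * c_org / 1000 * dur_d / pr$n_pulses <= fed_c_pulse
    ok_n <- assim_n * n_org / 1000 * dur_d / pr$n_pulses <= fed_n_pulse
    if (ok_c && ok_n) {
      return(list(
        dry_weight_g = dw, c_org_umol = c_org, n_org_umol = n_org,
        assim_c = assim_c, resp_c = resp_c, total_c = total,
        efficiency_pct = 100 * eff, assim_n = assim_n,
        cn_assimilation = assim_c / assim_n,
        plfa_rate = plfa_rate, duration_d = dur_d,
        fed_c_pulse = fed_c_pulse, fed_n_pulse = fed_n_pulse
      ))
    }
  }
  abort(paste0("Preset `", pr$preset,
    "`: could not draw a specimen within the label mass budget."),
    class = "spongeflux_error_mass_balance")
}

make_plfa_layer <- function(id, species_row, c_org, dw, truth = NULL,
                            shares = NULL, duration_d = NULL, noise,
                            plfa_pct_draw) {
  cst <- sim_constants
  prof <- sponge_plfa_presets()
  prof <- prof[prof$species == species_row$species, ]
  fa <- parse_fatty_acid(prof$fatty_acid)
  total_plfa_umol <- plfa_pct_draw / 100 * c_org
  pool_umol <- prof$pct / 100 * total_plfa_umol
  conc <- pool_umol * cst$mol_mass_c / (dw * 1000)
  area_true <- conc * cst$sample_mass_mg * cst$f_recovered /
    cst$standard_ug_c * cst$standard_area * (fa$chain_length + 1) / fa$chain_length
  area <- area_true * rlnorm_mean(length(area_true), 1, noise$area_cv)

  delta_plfa_bg <- rep(cst$plfa_bg_delta, nrow(prof))
  if (is.null(truth)) {
    delta_plfa <- delta_plfa_bg
  } else {
    share <- shares$share[match(prof$fatty_acid, shares$fatty_acid)]
    share[is.na(share)] <- 0
    tracer_umol <- share * truth$plfa_rate * (c_org / 1000) * duration_d
    e_fa <- tracer_umol / pool_umol
    f_fa <- delta_to_fraction(delta_plfa_bg, "13C") + e_fa
    if (any(f_fa >= 0.98)) {
      abort("Impossible PLFA label allocation: atom fraction >= 0.98.",
        class = "spongeflux_error_mass_balance")
    }
    delta_plfa <- fraction_to_delta(f_fa, "13C")
  }
  fame_true <- fame_from_plfa_delta(delta_plfa, cst$methanol_delta, fa$chain_length)
  fame_bg <- fame_from_plfa_delta(delta_plfa_bg, cst$methanol_delta, fa$chain_length)
  peaks <- tibble(
    sample_id = id,
    fatty_acid = prof$fatty_acid,
    area = area,
    delta13c_fame = delta_noise(fame_true, fame_bg, noise)
  )
  # internal standard peak row (excluded from profiles downstream)
  peaks <- bind_rows(peaks, tibble(
    sample_id = id, fatty_acid = "C19:0",
    area = cst$standard_area, delta13c_fame = -30
  ))
  extraction <- tibble(
    sample_id = id,
    sample_mass_mg = cst$sample_mass_mg,
    f_recovered = cst$f_recovered,
    standard_area = cst$standard_area,
    standard_ug_c = cst$standard_ug_c,
    delta13c_methanol = cst$methanol_delta
  )
  list(peaks = peaks, extraction = extraction)
}

#' Simulate a complete tracer feeding experiment
#'
#' Generates the full input-table bundle of a multi-pulse chamber feeding
#' experiment with known ground truth: specimens (labelled plus unlabelled
#' background individuals), incubation schedules (plus sponge-free control
#' chambers), post-incubation bulk tissue isotope measurements, per-pulse
#' t0/t_end DIC samples in duplicate, PLFA chromatogram peak tables with
#' extraction records, and a truth table carrying every generated
#' parameter. The forward model inverts exactly under zero noise:
#' tissue excess = rate x duration / 1000, DIC atom-fraction rise =
#' respired tracer / (DIC x V) per pulse, and per-PLFA deltas follow from
#' the allocated label share over the PLFA carbon pool.
#'
#' @param presets Character vector of preset names (see [flux_presets()]) or
#'   a tibble of preset rows with the same columns.
#' @param n Optional override of specimens per preset (single integer or
#'   vector along `presets`).
#' @param seed Optional integer seed; the bundle is byte-identical under
#'   the same seed.
#' @param noise A [sim_noise()] object.
#' @param controls Generate sponge-free control chambers (default TRUE).
#' @param plfa Generate the PLFA layer (default TRUE).
#' @return A `sponge_experiment` list of tibbles: `specimens`,
#'   `incubations`, `bulk_isotopes`, `dic_samples`, `plfa_peaks`,
#'   `extractions`, `source_profiles`, `truth`.
#' @examples
#' sim <- simulate_experiment("geodia_dom", seed = 1)
#' sim$truth
#' @export
simulate_experiment <- function(presets = "geodia_dom", n = NULL, seed = NULL,
                                noise = sim_noise(), controls = TRUE,
                                plfa = TRUE) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      simulate_experiment(presets, n, NULL, noise, controls, plfa)))
  }
  if (is.character(presets)) {
    all_pr <- flux_presets()
    missing <- setdiff(presets, all_pr$preset)
    if (length(missing)) abort(paste0("Unknown preset(s): ",
      paste(missing, collapse = ", ")), class = "spongeflux_error_domain")
    presets <- all_pr[match(presets, all_pr$preset), ]
  }
  if (!is.null(n)) presets$n <- rep(n, length.out = nrow(presets))
  cst <- sim_constants
  spp <- species_presets()

  specimens <- list(); incubations <- list(); bulk <- list(); dic <- list()
  peaks <- list(); extractions <- list(); truth <- list()

  for (i in seq_len(nrow(presets))) {
    pr <- presets[i, ]
    sp <- spp[spp$species == pr$species, ]
    cal <- calibrate_flux_preset(pr)
    if (noise$individual != 1 && noise$individual > 0) {
      # re-centre the efficiency distribution under the scaled spread
      q <- gh_nodes(48)
      sxs <- cal$sigma_logit * noise$individual
      cal$mu_logit <- uniroot(function(m)
        sum(q$w * plogis(m + sxs * q$x)) - pr$eff_mean, c(-30, 30),
        tol = 1e-12)$root
    }
    shares <- incorporation_share_presets()
    shares <- shares[shares$preset == pr$preset, ]
    for (j in seq_len(pr$n)) {
      id <- paste0(pr$preset, "_", j)
      tr <- draw_specimen_truth(pr, sp, cal, noise)
      specimens[[id]] <- tibble(
        specimen_id = id, species = pr$species, status = sp$microbial_status,
        role = "labelled",
        dry_weight_g = tr$dry_weight_g, c_org_umol = tr$c_org_umol,
        n_org_umol = tr$n_org_umol,
        bg_delta13c = sp$bg_delta13c, bg_delta15n = sp$bg_delta15n
      )
      incubations[[id]] <- tibble(
        incubation_id = id, specimen_id = id, food_source = pr$food_source,
        n_pulses = pr$n_pulses, pulse_duration_h = pr$pulse_duration_h,
        chamber_volume_l = pr$chamber_volume_l,
        dose_umol_c_l = pr$dose_umol_c_l
      )
      # bulk tissue deltas from the true excess
      f_c <- delta_to_fraction(sp$bg_delta13c, "13C") +
        tr$assim_c * tr$duration_d / 1000
      f_n <- delta_to_fraction(sp$bg_delta15n, "15N") +
        tr$assim_n * tr$duration_d / 1000
      d_c <- fraction_to_delta(f_c, "13C")
      d_n <- fraction_to_delta(f_n, "15N")
      bulk[[id]] <- tibble(
        specimen_id = id,
        delta13c = delta_noise(d_c, sp$bg_delta13c, noise),
        delta15n = delta_noise(d_n, sp$bg_delta15n, noise)
      )
      # DIC trajectory: equal tracer split across pulses, duplicate samples
      tracer_pulse <- tr$resp_c * (tr$c_org_umol / 1000) * tr$duration_d /
        pr$n_pulses
      f_t0 <- delta_to_fraction(cst$dic_t0_delta, "13C")
      f_tend <- f_t0 + tracer_pulse / (cst$dic_umol_per_l * pr$chamber_volume_l)
      d_tend <- fraction_to_delta(f_tend, "13C")
      grid <- tidyr::expand_grid(pulse = seq_len(pr$n_pulses),
        time_point = c("t0", "t_end"), replicate = 1:2)
      d_true <- ifelse(grid$time_point == "t0", cst$dic_t0_delta, d_tend)
      sdv <- noise$dic_delta_sd + noise$delta_rel_sd *
        abs(d_true - cst$dic_t0_delta)
      dic[[id]] <- tibble(
        incubation_id = id, pulse = grid$pulse, time_point = grid$time_point,
        replicate = grid$replicate,
        dic_umol_per_l = cst$dic_umol_per_l,
        delta13c = d_true + rnorm(nrow(grid), 0, sdv)
      )
      if (plfa) {
        plfa_pct <- rlnorm_mean(1, sp$plfa_pct_of_c,
          sp$plfa_pct_cv * noise$individual)
        layer <- make_plfa_layer(id, sp, tr$c_org_umol, tr$dry_weight_g,
          truth = tr, shares = shares, duration_d = tr$duration_d,
          noise = noise, plfa_pct_draw = plfa_pct)
        peaks[[id]] <- layer$peaks
        extractions[[id]] <- layer$extraction
      }
      truth[[id]] <- tibble(
        specimen_id = id, preset = pr$preset, species = pr$species,
        food_source = pr$food_source,
        dry_weight_g = tr$dry_weight_g, c_org_umol = tr$c_org_umol,
        n_org_umol = tr$n_org_umol,
        assim_c = tr$assim_c, resp_c = tr$resp_c, total_c = tr$total_c,
        efficiency_pct = tr$efficiency_pct,
        assim_n = tr$assim_n, cn_assimilation = tr$cn_assimilation,
        plfa_rate = tr$plfa_rate, duration_d = tr$duration_d,
        fed_c_pulse_umol = tr$fed_c_pulse, fed_n_pulse_umol = tr$fed_n_pulse
      )
    }
  }

  # unlabelled background individuals for every species involved
  for (s in unique(presets$species)) {
    sp <- spp[spp$species == s, ]
    for (j in seq_len(sp$n_background)) {
      id <- paste0(s, "_bg_", j)
      dw <- rlnorm_mean(1, sp$dry_weight_g, sp$dry_weight_cv * noise$individual)
      c_org <- dw * sp$carbon_pct_dw / 100 / cst$mol_mass_c * 1e6
      specimens[[id]] <- tibble(
        specimen_id = id, species = s, status = sp$microbial_status,
        role = "background",
        dry_weight_g = dw, c_org_umol = c_org,
        n_org_umol = c_org / sp$tissue_cn,
        bg_delta13c = sp$bg_delta13c, bg_delta15n = sp$bg_delta15n
      )
      bulk[[id]] <- tibble(
        specimen_id = id,
        delta13c = delta_noise(sp$bg_delta13c, sp$bg_delta13c, noise),
        delta15n = delta_noise(sp$bg_delta15n, sp$bg_delta15n, noise)
      )
      if (plfa) {
        plfa_pct <- rlnorm_mean(1, sp$plfa_pct_of_c,
          sp$plfa_pct_cv * noise$individual)
        layer <- make_plfa_layer(id, sp, c_org, dw, truth = NULL,
          noise = noise, plfa_pct_draw = plfa_pct)
        peaks[[id]] <- layer$peaks
        extractions[[id]] <- layer$extraction
      }
    }
  }

  # sponge-free control chambers per food source
  if (controls) {
    for (fs in unique(presets$food_source)) {
      pr <- presets[presets$food_source == fs, ][1, ]
      for (j in 1:3) {
        id <- paste0("ctrl_", fs, "_", j)
        incubations[[id]] <- tibble(
          incubation_id = id, specimen_id = NA_character_, food_source = fs,
          n_pulses = pr$n_pulses, pulse_duration_h = pr$pulse_duration_h,
          chamber_volume_l = pr$chamber_volume_l,
          dose_umol_c_l = pr$dose_umol_c_l
        )
        grid <- tidyr::expand_grid(pulse = seq_len(pr$n_pulses),
          time_point = c("t0", "t_end"), replicate = 1:2)
        dic[[id]] <- tibble(
          incubation_id = id, pulse = grid$pulse,
          time_point = grid$time_point, replicate = grid$replicate,
          dic_umol_per_l = cst$dic_umol_per_l,
          delta13c = cst$dic_t0_delta +
            rnorm(nrow(grid), 0, noise$dic_delta_sd)
        )
      }
    }
  }

  src <- food_plfa_presets() |>
    inner_join(food_presets()[, c("food_id", "food_source")], by = "food_id") |>
    filter(.data$food_id %in% presets$food_id) |>
    select("food_source", "food_id", "fatty_acid", "pct")

  structure(list(
    specimens = bind_rows(specimens),
    incubations = bind_rows(incubations),
    bulk_isotopes = bind_rows(bulk),
    dic_samples = bind_rows(dic),
    plfa_peaks = if (plfa) bind_rows(peaks) else tibble(),
    extractions = if (plfa) bind_rows(extractions) else tibble(),
    source_profiles = src,
    truth = bind_rows(truth)
  ), class = "sponge_experiment")
}

#' @export
print.sponge_experiment <- function(x, ...) {
  cat("Simulated feeding experiment:",
    nrow(x$truth), "labelled specimens,",
    sum(x$specimens$role == "background"), "background specimens,",
    length(unique(x$incubations$incubation_id[is.na(x$incubations$specimen_id)])),
    "control chambers\n")
  cat("Presets:", paste(unique(x$truth$preset), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a null experiment with no species or food-source effects
#'
#' Copies the flux truth distribution of the first preset onto every
#' requested preset so that all group-level truths are equal; species and
#' food-source labels are retained. Used for type-I-error calibration of
#' the permutational statistics.
#'
#' @inheritParams simulate_experiment
#' @export
simulate_null_experiment <- function(presets, n = NULL, seed = NULL,
                                     noise = sim_noise(), controls = FALSE,
                                     plfa = FALSE) {
  all_pr <- flux_presets()
  rows <- all_pr[match(presets, all_pr$preset), ]
  truth_cols <- c("total_mean", "total_cv", "eff_mean", "resp_mean",
    "sigma_logit", "cn_mean", "cn_cv", "assim_n_mean", "assim_n_cv",
    "plfa_rate_mean", "plfa_rate_cv")
  rows[truth_cols] <- rows[rep(1, nrow(rows)), truth_cols]
  simulate_experiment(rows, n = n, seed = seed, noise = noise,
    controls = controls, plfa = plfa)
}

#' Simulate unlabelled PLFA chromatogram tables for one species
#'
#' Generates `n` background-style specimens of a species and their PLFA
#' peak and extraction tables with default peak-area noise; used for
#' profile summaries independent of any feeding.
#'
#' @param species `"geodia"`, `"hymedesmia"` or `"vazella"`.
#' @param n Number of specimens.
#' @inheritParams simulate_experiment
#' @return List with `specimens`, `plfa_peaks`, `extractions`.
#' @export
simulate_plfa_profiles <- function(species, n, seed = NULL,
                                   noise = sim_noise()) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      simulate_plfa_profiles(species, n, NULL, noise)))
  }
  sp <- species_presets()
  sp <- sp[sp$species == species, ]
  if (nrow(sp) != 1) abort("Unknown species.", class = "spongeflux_error_domain")
  cst <- sim_constants
  specimens <- list(); peaks <- list(); extractions <- list()
  for (j in seq_len(n)) {
    id <- paste0(species, "_profile_", j)
    dw <- rlnorm_mean(1, sp$dry_weight_g, sp$dry_weight_cv * noise$individual)
    c_org <- dw * sp$carbon_pct_dw / 100 / cst$mol_mass_c * 1e6
    specimens[[id]] <- tibble(
      specimen_id = id, species = species, status = sp$microbial_status,
      role = "background", dry_weight_g = dw, c_org_umol = c_org,
      n_org_umol = c_org / sp$tissue_cn,
      bg_delta13c = sp$bg_delta13c, bg_delta15n = sp$bg_delta15n
    )
    plfa_pct <- rlnorm_mean(1, sp$plfa_pct_of_c,
      sp$plfa_pct_cv * noise$individual)
    layer <- make_plfa_layer(id, sp, c_org, dw, truth = NULL, noise = noise,
      plfa_pct_draw = plfa_pct)
    peaks[[id]] <- layer$peaks
    extractions[[id]] <- layer$extraction
  }
  list(specimens = bind_rows(specimens), plfa_peaks = bind_rows(peaks),
    extractions = bind_rows(extractions))
}

#' Per-pulse label mass balance of a simulated experiment
#'
#' Audits the forward model: per specimen and pulse, the tracer fed must be
#' at least the tracer assimilated plus respired (attributed equally across
#' pulses, since tissue is measured once at the end).
#'
#' @param x A `sponge_experiment`.
#' @return Tibble per specimen: fed and demanded tracer per pulse (umol)
#'   for C and N, with logical `ok_c`, `ok_n`.
#' @export
mass_balance <- function(x) {
  x$truth |>
    inner_join(x$incubations[, c("specimen_id", "n_pulses")],
      by = "specimen_id") |>
    mutate(
      demand_c_pulse = .data$total_c * .data$c_org_umol / 1000 *
        .data$duration_d / .data$n_pulses,
      demand_n_pulse = .data$assim_n * .data$n_org_umol / 1000 *
        .data$duration_d / .data$n_pulses,
      ok_c = .data$demand_c_pulse <= .data$fed_c_pulse_umol,
      ok_n = .data$demand_n_pulse <= .data$fed_n_pulse_umol
    ) |>
    select("specimen_id", "preset", "fed_c_pulse_umol", "demand_c_pulse",
      "ok_c", "fed_n_pulse_umol", "demand_n_pulse", "ok_n")
}

#' Write a simulated experiment to CSV files
#'
#' @param x A `sponge_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(x)) {
    readr::write_csv(x[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read a simulated experiment back from CSV files
#'
#' @param dir Directory written by [write_experiment()].
#' @return A `sponge_experiment`.
#' @export
read_experiment <- function(dir) {
  nms <- c("specimens", "incubations", "bulk_isotopes", "dic_samples",
    "plfa_peaks", "extractions", "source_profiles", "truth")
  out <- lapply(nms, function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(path)) readr::read_csv(path, show_col_types = FALSE)
    else tibble()
  })
  structure(setNames(out, nms), class = "sponge_experiment")
}
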