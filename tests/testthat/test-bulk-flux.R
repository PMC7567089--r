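test_that("bulk assimilation is the biomass-normalised excess flux", {
  expect_equal(bulk_assimilation(0, 700, 1000, 1), 0)
  expect_equal(bulk_assimilation(1e-3, 700, 1000, 1), 0.7)
  expect_equal(bulk_assimilation(2e-3, 700, 1000, 1), 1.4) # linear in E
  # whole-tissue case: pool == biomass, rate = 1000 E / duration
  expect_equal(bulk_assimilation(5e-4, 12345, 12345, 2), 0.25)
  expect_error(bulk_assimilation(1e-3, 700, 1000, 0),
    class = "spongeflux_error_domain")
  expect_error(bulk_assimilation(1e-3, 700, -1, 1),
    class = "spongeflux_error_domain")
})

test_that("DIC respiration accumulates per-pulse tracer and normalises", {
  # hand-computed: dF = 5e-6, DIC 2100, V 2 L, 1 mmol biomass, 1 day
  f0 <- delta_to_fraction(0, "13C")
  d_end <- fraction_to_delta(f0 + 5e-6, "13C")
  dic <- tibble::tibble(pulse = 1, time_point = c("t0", "t_end"),
    dic_umol_per_l = 2100, delta13c = c(0, d_end))
  r <- respiration_from_dic(dic, volume_l = 2, biomass_c_umol = 1000,
    duration_d = 1)
  expect_equal(as.numeric(r), 0.021, tolerance = 1e-9)

  # flat series respires nothing
  flat <- tibble::tibble(pulse = rep(1:2, each = 2),
    time_point = rep(c("t0", "t_end"), 2),
    dic_umol_per_l = 2100, delta13c = 5)
  expect_equal(as.numeric(respiration_from_dic(flat, 2, 1000, 1)), 0)

  # two identical pulses double the tracer mass before time-normalisation
  dic2 <- dplyr::bind_rows(dic, dplyr::mutate(dic, pulse = 2))
  r2 <- respiration_from_dic(dic2, 2, 1000, 1)
  expect_equal(sum(attr(r2, "per_pulse")), 2 * sum(attr(r, "per_pulse")))

  # duplicates are averaged
  dup <- dplyr::bind_rows(dplyr::mutate(dic, replicate = 1),
    dplyr::mutate(dic, replicate = 2))
  expect_equal(as.numeric(respiration_from_dic(dup, 2, 1000, 1)),
    0.021, tolerance = 1e-9)
})

test_that("incomplete DIC series raise a structured error naming the gap", {
  dic <- tibble::tibble(pulse = c(1, 1, 2), time_point = c("t0", "t_end", "t0"),
    dic_umol_per_l = 2100, delta13c = 0)
  err <- expect_error(respiration_from_dic(dic, 2, 1000, 1),
    class = "spongeflux_error_missing_dic")
  expect_match(conditionMessage(err), "2")
})

test_that("efficiency behaves at its boundary cases", {
  expect_equal(efficiency(1, 0), 100)
  expect_equal(efficiency(1, 1), 50)
  expect_equal(efficiency(0.61, 0.09), 87.142857, tolerance = 1e-6)
  expect_warning(e0 <- efficiency(0, 0), "undefined")
  expect_true(is.na(e0))
})

test_that("assimilation C:N is a scale-invariant ratio", {
  expect_equal(assimilation_cn_ratio(1, 1), 1)
  expect_equal(assimilation_cn_ratio(0.48, 1.2), 0.4)
  expect_equal(assimilation_cn_ratio(3 * 0.48, 3 * 1.2), 0.4)
  expect_true(is.na(assimilation_cn_ratio(1, 0)))
})

test_that("bulk_rates recovers simulated truth exactly without noise", {
  sim <- simulate_experiment(c("geodia_dom", "vazella_bacteria"), seed = 1,
    noise = sim_noise(0, 0))
  r <- bulk_rates(sim$specimens, sim$bulk_isotopes, sim$incubations,
    sim$dic_samples)
  rc <- dplyr::inner_join(dplyr::filter(r, element == "C"), sim$truth,
    by = "specimen_id")
  expect_equal(rc$assimilation_rate, rc$assim_c, tolerance = 1e-9)
  expect_equal(rc$respiration_rate, rc$resp_c, tolerance = 1e-9)
  expect_equal(rc$total_processing, rc$total_c, tolerance = 1e-9)
  expect_equal(rc$efficiency_pct.x, rc$efficiency_pct.y, tolerance = 1e-9)
  expect_equal(rc$cn_assimilation.x, rc$cn_assimilation.y, tolerance = 1e-9)
  rn <- dplyr::inner_join(dplyr::filter(r, element == "N"), sim$truth,
    by = "specimen_id")
  expect_equal(rn$assimilation_rate, rn$assim_n, tolerance = 1e-9)
})

test_that("relative assimilated and respired fractions stack to exactly 100", {
  sim <- simulate_experiment("hymedesmia_dom", seed = 4)
  r <- bulk_rates(sim$specimens, sim$bulk_isotopes, sim$incubations,
    sim$dic_samples)
  rel <- relative_processing(r)
  expect_equal(rel$assimilated_pct + rel$respired_pct,
    rep(100, nrow(rel)))
})

test_that("background specimens are excluded with a reason, never dropped silently", {
  sim <- simulate_experiment("geodia_dom", seed = 2)
  r <- bulk_rates(sim$specimens, sim$bulk_isotopes, sim$incubations,
    sim$dic_samples)
  excl <- attr(r, "excluded")
  expect_equal(nrow(excl), sum(sim$specimens$role == "background"))
  expect_true(all(grepl("no incubation", excl$reason)))
  expect_equal(length(unique(r$specimen_id)) + nrow(excl),
    nrow(sim$specimens))
})

test_that("control-chamber correction subtracts sponge-free DIC drift", {
  sim <- simulate_experiment("geodia_dom", seed = 8, noise = sim_noise(0, 0))
  r0 <- bulk_rates(sim$specimens, sim$bulk_isotopes, sim$incubations,
    sim$dic_samples, control_correct = FALSE)
  r1 <- bulk_rates(sim$specimens, sim$bulk_isotopes, sim$incubations,
    sim$dic_samples, control_correct = TRUE)
  # noise-free controls have zero drift, so the correction is a no-op
  expect_equal(r1$respiration_rate, r0$respiration_rate, tolerance = 1e-12)
})
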