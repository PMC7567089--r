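test_that("preset calibration hits the target moments by quadrature", {
  q <- spongeflux:::gh_nodes(60)
  for (nm in c("geodia_dom", "geodia_bacteria", "hymedesmia_bacteria")) {
    pr <- dplyr::filter(flux_presets(), preset == nm)
    cal <- calibrate_flux_preset(nm)
    # E[e] = preset efficiency
    e_mean <- sum(q$w * stats::plogis(cal$mu_logit + cal$sigma_logit * q$x))
    expect_equal(e_mean, pr$eff_mean, tolerance = 1e-6)
    # E[T(1-e)] = preset respiration (re-evaluated independently)
    tv <- exp(cal$meanlog_t + cal$sdlog_t * q$x)
    inner <- vapply(q$x, function(a) {
      sum(q$w * (1 - stats::plogis(cal$mu_logit +
        cal$sigma_logit * (cal$rho * a + sqrt(1 - cal$rho^2) * q$x))))
    }, 1)
    expect_equal(sum(q$w * tv * inner), pr$resp_mean, tolerance = 1e-6)
    # E[T] = preset total (lognormal closed form)
    expect_equal(exp(cal$meanlog_t + cal$sdlog_t^2 / 2), pr$total_mean,
      tolerance = 1e-10)
  }
  # presets whose printed respiration is not jointly attainable run at rho 0
  expect_equal(calibrate_flux_preset("vazella_bacteria")$rho, 0)
  expect_equal(calibrate_flux_preset("vazella_dom")$rho, 0)
})

test_that("the bundle is deterministic under a seed", {
  a <- simulate_experiment(c("geodia_dom", "vazella_bacteria"), seed = 77)
  b <- simulate_experiment(c("geodia_dom", "vazella_bacteria"), seed = 77)
  for (nm in names(a)) expect_identical(a[[nm]], b[[nm]])
  c <- simulate_experiment(c("geodia_dom", "vazella_bacteria"), seed = 78)
  expect_false(identical(a$bulk_isotopes, c$bulk_isotopes))
})

test_that("writing and re-reading a bundle round-trips and is byte-stable", {
  sim <- simulate_experiment("hymedesmia_bacteria", seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(sim, d1)
  write_experiment(sim, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- read_experiment(d1)
  expect_equal(nrow(back$truth), nrow(sim$truth))
  expect_equal(back$truth$assim_c, sim$truth$assim_c, tolerance = 1e-12)
})

test_that("per-pulse label mass balance holds across the preset matrix", {
  for (seed in 1:3) {
    sim <- simulate_experiment(flux_presets()$preset, seed = seed, plfa = FALSE)
    mb <- mass_balance(sim)
    expect_true(all(mb$ok_c))
    expect_true(all(mb$ok_n))
  }
})

test_that("an impossible configuration raises a generation error", {
  pr <- dplyr::filter(flux_presets(), preset == "geodia_dom")
  pr$total_mean <- 500 # demands far more label than is fed
  pr$resp_mean <- NA
  expect_error(simulate_experiment(pr, seed = 1),
    class = "spongeflux_error_mass_balance")
})

test_that("unlabelled background specimens centre on zero excess", {
  sim <- simulate_experiment("geodia_dom", seed = 31)
  bg <- dplyr::inner_join(
    dplyr::filter(sim$specimens, role == "background"),
    sim$bulk_isotopes, by = "specimen_id")
  e <- excess_from_delta(bg$delta13c, bg$bg_delta13c, "13C")
  expect_lt(max(abs(e)), 1e-5) # 0.2 per-mil noise is ~2e-6 in atom fraction
  expect_false(all(e == 0)) # but noise is present
})

test_that("null experiments copy one truth distribution onto every group", {
  sim <- simulate_null_experiment(c("geodia_dom", "hymedesmia_dom"),
    seed = 13, plfa = FALSE)
  tr <- sim$truth
  expect_equal(length(unique(tr$species)), 2)
  # same truth distribution: compare preset-level parameters via many draws
  m <- tapply(tr$total_c, tr$species, mean)
  expect_true(all(is.finite(m)))
})

test_that("Welch p-values are uniform under the generated null", {
  p <- vapply(1:300, function(i) {
    sim <- simulate_null_experiment(c("geodia_dom", "hymedesmia_dom"),
      seed = 1000 + i, noise = sim_noise(1, 1), plfa = FALSE,
      controls = FALSE)
    r <- bulk_rates(sim$specimens, sim$bulk_isotopes, sim$incubations,
      sim$dic_samples)
    rc <- dplyr::filter(r, element == "C")
    g <- split(rc$total_processing, rc$species)
    welch_t(g[[1]], g[[2]])$p_value
  }, 1)
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})
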