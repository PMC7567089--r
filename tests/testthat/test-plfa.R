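test_that("concentration formula matches hand-computed values and scalings", {
  # unit inputs leave only the methyl-carbon factor n/(n+1)
  expect_equal(plfa_concentration(1, 1, 1, 1, 1, 19), 19 / 20)
  expect_equal(plfa_concentration(0, 1, 1, 1, 1, 16), 0)
  base <- plfa_concentration(2, 5, 3, 2, 0.8, 16)
  expect_equal(plfa_concentration(2, 5, 3, 2, 0.4, 16), 2 * base)
  # degree 1 in area, degree -1 in sample mass and recovery
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- runif(1, 0.1, 10); gs <- runif(1, 1, 100); f <- runif(1, 0.2, 1)
      k <- runif(1, 0.5, 3); n <- sample(10:30, 1)
      expect_equal(plfa_concentration(k * a, 1, 1, gs, f, n),
        k * plfa_concentration(a, 1, 1, gs, f, n))
      expect_equal(plfa_concentration(a, 1, 1, k * gs, f, n),
        plfa_concentration(a, 1, 1, gs, f, n) / k)
      expect_equal(plfa_concentration(a, 1, 1, gs, pmin(k * f, 1), n),
        plfa_concentration(a, 1, 1, gs, f, n) / pmin(k, 1 / f))
    }
  })
  expect_error(plfa_concentration(1, 0, 1, 1, 1, 16),
    class = "spongeflux_error_domain")
  expect_error(plfa_concentration(1, 1, 1, 1, 0, 16),
    class = "spongeflux_error_domain")
})

test_that("FAME methyl correction matches mass balance and inverts exactly", {
  expect_equal(correct_fame_delta(-40, -40, 15), -40) # fixed point
  expect_equal(correct_fame_delta(0, -40, 15), 40 / 15)
  # magnitude shrinks monotonically with chain length
  mag <- abs(correct_fame_delta(0, -40, 10:30) - 0)
  expect_true(all(diff(mag) < 0))
  # re-adding the methanol carbon reproduces the FAME delta to 1e-10
  withr::with_seed(11, {
    d_fame <- runif(50, -50, 5000)
    n <- sample(10:30, 50, replace = TRUE)
    d_plfa <- correct_fame_delta(d_fame, -40, n)
    expect_equal(fame_from_plfa_delta(d_plfa, -40, n), d_fame,
      tolerance = 1e-10)
  })
})

test_that("profile summary yields percentages of total PLFA carbon", {
  ext <- make_extraction()
  one <- plfa_profile(make_peaks(fatty_acid = "C16:0", area = 3), ext)
  expect_equal(one$pct, 100)

  # packaged bacterial food fixture reproduces its three-component composition
  prof <- plfa_profile(read_fixture_peaks(), read_fixture_extraction())
  expect_equal(nrow(prof), 3) # C19:0 standard row excluded
  got <- setNames(prof$pct, prof$fatty_acid)
  expect_equal(got[["C16:0"]], 22.4, tolerance = 1e-6)
  expect_equal(got[["C18:1"]], 59.9, tolerance = 1e-6)
  expect_equal(got[["C18:0"]], 17.7, tolerance = 1e-6)
  expect_equal(attr(prof, "excluded")$fatty_acid, "C19:0")

  # permutation invariance
  pk <- read_fixture_peaks()
  prof2 <- plfa_profile(pk[c(3, 1, 4, 2), ], read_fixture_extraction())
  expect_equal(
    dplyr::arrange(prof2, fatty_acid)$pct,
    dplyr::arrange(prof, fatty_acid)$pct
  )

  # all-zero areas are flagged, not silently zeroed
  expect_warning(
    z <- plfa_profile(make_peaks(fatty_acid = c("C16:0", "C18:0"),
      area = c(0, 0)), ext),
    "All-zero"
  )
  expect_true(all(is.na(z$pct)))
})

test_that("class totals cover all three classes and sum to 100", {
  sim <- simulate_plfa_profiles("hymedesmia", 4, seed = 5)
  prof <- plfa_profile(sim$plfa_peaks, sim$extractions)
  tot <- plfa_class_totals(prof)
  sums <- tot |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(pct_total))
  expect_equal(sums$s, rep(100, 4), tolerance = 1e-9)
  expect_equal(sort(unique(tot$class)),
    c("bacteria_specific", "sponge_specific", "unspecific"))
})

test_that("total PLFA carbon is reported as a share of holobiont carbon", {
  sim <- simulate_plfa_profiles("geodia", 3, seed = 9, noise = sim_noise(0, 0))
  prof <- plfa_profile(sim$plfa_peaks, sim$extractions)
  tc <- plfa_total_carbon(prof, sim$specimens)
  expect_equal(tc$plfa_pct_of_c, rep(0.9, 3), tolerance = 1e-9)
})

test_that("de novo detection returns labelled fatty acids absent from the source", {
  out <- detect_de_novo(c("C18:1", "Cy-C17:0"), c("C16:0", "C18:0", "C18:1"))
  expect_equal(out, "Cy-C17:0")
  expect_equal(detect_de_novo(c("C16:0"), c("C16:0", "C18:0")), character())
  expect_equal(detect_de_novo(character(), c("C16:0")), character())
  # disjointness holds for arbitrary inputs
  src <- c("C16:0", "C18:1", "C20:5ω3")
  lab <- c("C16:0", "i-C15:0", "Me-C18:0", "C20:5w3")
  expect_length(intersect(detect_de_novo(lab, src),
    canonical_fatty_acid(src)), 0)
})

test_that("tracer incorporation recovers the simulated truth without noise", {
  sim <- simulate_experiment("geodia_dom", seed = 3, noise = sim_noise(0, 0))
  inc <- plfa_incorporation(sim$plfa_peaks, sim$extractions, sim$specimens,
    sim$incubations, source_profiles = sim$source_profiles)
  tot <- inc |>
    dplyr::group_by(specimen_id) |>
    dplyr::summarise(rate = sum(rate)) |>
    dplyr::inner_join(sim$truth, by = "specimen_id")
  expect_equal(tot$rate, tot$plfa_rate, tolerance = 1e-9)
  # percentages sum to 100 per specimen
  psum <- inc |>
    dplyr::group_by(specimen_id) |>
    dplyr::summarise(s = sum(pct_of_total))
  expect_equal(psum$s, rep(100, nrow(psum)), tolerance = 1e-9)
  # de novo flags match the source profile membership
  flagged <- inc |>
    dplyr::filter(labelled) |>
    dplyr::mutate(in_source = fatty_acid %in%
      canonical_fatty_acid(sim$source_profiles$fatty_acid[
        sim$source_profiles$food_source == "dom"]))
  expect_true(all(flagged$de_novo == !flagged$in_source))
})

test_that("a single labelled PLFA carries 100% of the incorporation", {
  specimens <- tibble::tibble(specimen_id = c("a", "bg"), species = "sp",
    status = "LMA", role = c("labelled", "background"),
    dry_weight_g = 1, c_org_umol = 1000, n_org_umol = 200,
    bg_delta13c = -20, bg_delta15n = 7)
  incubations <- tibble::tibble(incubation_id = "a", specimen_id = "a",
    food_source = "dom", n_pulses = 1, pulse_duration_h = 24,
    chamber_volume_l = 2)
  ext <- make_extraction(c("a", "bg"))
  peaks <- dplyr::bind_rows(
    make_peaks("a", c("C16:0", "C18:0"), area = c(1, 1),
      delta13c_fame = c(100, -28)),
    make_peaks("bg", c("C16:0", "C18:0"), area = c(1, 1),
      delta13c_fame = c(-28, -28))
  )
  inc <- plfa_incorporation(peaks, ext, specimens, incubations)
  expect_equal(inc$pct_of_total[inc$fatty_acid == "C16:0"], 100)
  expect_equal(inc$rate[inc$fatty_acid == "C18:0"], 0)
  expect_true(inc$labelled[inc$fatty_acid == "C16:0"])
})

test_that("missing backgrounds fall back with a QC warning", {
  specimens <- tibble::tibble(specimen_id = c("a", "bg"), species = "sp",
    status = "LMA", role = c("labelled", "background"),
    dry_weight_g = 1, c_org_umol = 1000, n_org_umol = 200,
    bg_delta13c = -20, bg_delta15n = 7)
  incubations <- tibble::tibble(incubation_id = "a", specimen_id = "a",
    food_source = "dom", n_pulses = 1, pulse_duration_h = 24,
    chamber_volume_l = 2)
  ext <- make_extraction(c("a", "bg"))
  peaks <- dplyr::bind_rows(
    make_peaks("a", c("C16:0", "i-C15:0"), area = c(1, 1),
      delta13c_fame = c(50, 60)),
    make_peaks("bg", "C16:0", area = 1, delta13c_fame = -28)
  )
  expect_warning(
    inc <- plfa_incorporation(peaks, ext, specimens, incubations),
    "background"
  )
  expect_equal(nrow(inc), 2)
  expect_true(all(is.finite(inc$rate)))
})
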