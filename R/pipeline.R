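# End-to-end orchestration: validate input tables, run the bulk and PLFA
# pipelines and the permutational statistics, write tidy CSV outputs and a
# reproducibility manifest.

table_schemas <- list(
  specimens = c("specimen_id", "species", "dry_weight_g", "c_org_umol",
    "n_org_umol", "bg_delta13c", "bg_delta15n"),
  incubations = c("incubation_id", "specimen_id", "food_source", "n_pulses",
    "pulse_duration_h", "chamber_volume_l"),
  bulk_isotopes = c("specimen_id", "delta13c", "delta15n"),
  dic_samples = c("incubation_id", "pulse", "time_point", "dic_umol_per_l",
    "delta13c"),
  plfa_peaks = c("sample_id", "fatty_acid", "area", "delta13c_fame"),
  extractions = c("sample_id", "sample_mass_mg", "f_recovered",
    "standard_area", "standard_ug_c", "delta13c_methanol")
)

#' Validate an input table against its expected schema
#'
#' Checks the required columns and basic row-level sanity (positive
#' biomass, positive pool sizes, delta values above -1000 per mil) and
#' returns a line-addressed report.
#'
#' @param df The table.
#' @param name One of `names(spongeflux:::table_schemas)`.
#' @return A character vector of problems (empty when valid).
#' @export
validate_table <- function(df, name) {
  req <- table_schemas[[name]]
  if (is.null(req)) abort(paste0("Unknown table `", name, "`."),
    class = "spongeflux_error_domain")
  problems <- character()
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    problems <- c(problems,
      paste0(name, ": missing column(s) ", paste(miss, collapse = ", ")))
    return(problems)
  }
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) paste0(name, " row(s) ",
      paste(head(idx, 5), collapse = ","),
      if (length(idx) > 5) "..." else "", ": ", what)
  }
  problems <- c(problems,
    if (name == "specimens") c(
      bad_row(df$dry_weight_g <= 0, "dry_weight_g must be > 0"),
      bad_row(df$c_org_umol <= 0, "c_org_umol must be > 0"),
      bad_row(df$n_org_umol <= 0, "n_org_umol must be > 0"),
      bad_row(df$c_org_umol / df$n_org_umol <= 1 |
          df$c_org_umol / df$n_org_umol >= 100,
        "tissue C:N outside (1, 100)")),
    if (name == "bulk_isotopes") c(
      bad_row(df$delta13c <= -1000, "delta13c must be > -1000"),
      bad_row(df$delta15n <= -1000, "delta15n must be > -1000")),
    if (name == "dic_samples") c(
      bad_row(df$dic_umol_per_l <= 0, "dic_umol_per_l must be > 0"),
      bad_row(!df$time_point %in% c("t0", "t_end"),
        "time_point must be t0 or t_end")),
    if (name == "incubations") c(
      bad_row(df$n_pulses < 1, "n_pulses must be >= 1"),
      bad_row(df$chamber_volume_l <= 0, "chamber_volume_l must be > 0"))
  )
  problems
}

#' Run the full analysis pipeline
#'
#' Validates the input bundle, computes bulk assimilation/respiration rates
#' and efficiencies, PLFA profiles, class totals and per-PLFA tracer
#' incorporation, runs the permutational statistics (two-factor PERMANOVA
#' on total processing rates per element, pairwise species comparisons,
#' Welch's t on assimilation C:N between food sources where both are
#' present), and writes all result tables plus a run manifest to
#' `out_dir`. Reruns with the same inputs and seed are byte-identical.
#'
#' @param input A `sponge_experiment` (see [simulate_experiment()]) or a
#'   directory of CSVs as written by [write_experiment()].
#' @param out_dir Output directory; created if needed. NULL skips writing.
#' @param mode Atom-fraction mode, see [delta_to_fraction()].
#' @param control_correct Subtract control-chamber DIC drift, see
#'   [bulk_rates()].
#' @param classification Optional biomarker override table.
#' @param threshold Detection threshold for labelled PLFAs.
#' @param permutations,seed Passed to the permutational tests.
#' @return Invisibly, a list with `rates`, `relative`, `profiles`,
#'   `class_totals`, `incorporation`, `stats` (list of tidy tables) and
#'   `manifest`.
#' @export
run_all <- function(input, out_dir = NULL, mode = c("exact", "approx"),
                    control_correct = FALSE, classification = NULL,
                    threshold = 1e-5, permutations = 9999, seed = NULL) {
  mode <- match.arg(mode)
  x <- if (is.character(input)) read_experiment(input) else input
  stopifnot(inherits(x, "sponge_experiment") || is.list(x))

  problems <- unlist(lapply(
    intersect(names(table_schemas), names(x)[vapply(x, nrow, 1L) > 0]),
    function(nm) validate_table(x[[nm]], nm)))
  if (length(problems)) {
    abort(paste0("Input validation failed:\n",
      paste("-", problems, collapse = "\n")),
      class = "spongeflux_error_schema")
  }
  if (!"role" %in% names(x$specimens)) x$specimens$role <- "labelled"

  rates <- bulk_rates(x$specimens, x$bulk_isotopes, x$incubations,
    x$dic_samples, mode = mode, control_correct = control_correct)
  rel <- relative_processing(rates)

  has_plfa <- !is.null(x$plfa_peaks) && nrow(x$plfa_peaks) > 0
  profiles <- class_totals <- incorporation <- NULL
  if (has_plfa) {
    profiles <- plfa_profile(x$plfa_peaks, x$extractions, classification)
    class_totals <- plfa_class_totals(profiles)
    incorporation <- plfa_incorporation(
      x$plfa_peaks, x$extractions, x$specimens, x$incubations,
      source_profiles = x$source_profiles, classification = classification,
      mode = mode, threshold = threshold)
  }

  stats_out <- list()
  cdat <- rates[rates$element == "C" & !is.na(rates$total_processing), ]
  two_species <- length(unique(cdat$species)) >= 2
  two_sources <- length(unique(cdat$food_source)) >= 2
  if (two_species || two_sources) {
    crossed <- two_species && two_sources &&
      all(table(cdat$species, cdat$food_source) > 0)
    fml <- if (crossed) ~ species * food_source
      else if (two_species) ~species else ~food_source
    for (el in c("C", "N")) {
      d <- rates[rates$element == el & !is.na(rates$total_processing), ]
      stats_out[[paste0("permanova_total_", el)]] <-
        tidy(permanova(d, "total_processing", fml,
          permutations = permutations, seed = seed))
      if (two_species) {
        stats_out[[paste0("pairwise_total_", el)]] <-
          pairwise_permanova(d, "total_processing", "species",
            permutations = permutations, seed = seed)
      }
    }
    eff <- cdat[!is.na(cdat$efficiency_pct), ]
    if (nrow(eff) && two_species) {
      stats_out$pairwise_efficiency <-
        pairwise_permanova(eff, "efficiency_pct", "species",
          permutations = permutations, seed = seed)
    }
  }
  if (two_sources) {
    cn <- cdat[!is.na(cdat$cn_assimilation), ]
    src <- split(cn$cn_assimilation, cn$food_source)
    if (length(src) == 2 && all(lengths(src) >= 2)) {
      stats_out$welch_cn <- welch_t(src[[1]], src[[2]]) |>
        mutate(group_x = names(src)[1], group_y = names(src)[2])
    }
  }

  excluded <- attr(rates, "excluded")
  manifest <- list(
    package = "spongeflux",
    version = as.character(utils::packageVersion("spongeflux")),
    mode = mode, control_correct = control_correct,
    threshold = threshold, permutations = permutations,
    seed = seed,
    config_hash = rlang::hash(list(mode, control_correct, threshold,
      permutations, seed)),
    n_specimens_in = nrow(x$specimens),
    n_specimens_analyzed = length(unique(rates$specimen_id)),
    excluded = excluded,
    qc = list(
      n_negative_excess = sum(rates$qc_negative_excess, na.rm = TRUE)
    )
  )
  stopifnot(manifest$n_specimens_in ==
    manifest$n_specimens_analyzed + nrow(excluded))

  out <- list(rates = rates, relative = rel, profiles = profiles,
    class_totals = class_totals, incorporation = incorporation,
    stats = stats_out, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(rates, file.path(out_dir, "rates.csv"))
    readr::write_csv(rel, file.path(out_dir, "relative_processing.csv"))
    if (has_plfa) {
      readr::write_csv(profiles, file.path(out_dir, "plfa_profiles.csv"))
      readr::write_csv(class_totals, file.path(out_dir, "plfa_class_totals.csv"))
      readr::write_csv(incorporation, file.path(out_dir, "plfa_incorporation.csv"))
    }
    for (nm in names(stats_out)) {
      readr::write_csv(stats_out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}
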