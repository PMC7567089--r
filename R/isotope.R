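#' International reference standards for isotope ratio conversion
#'
#' Registry of the two reference standards used throughout the package:
#' Vienna Pee Dee Belemnite for carbon (R_ref = 0.01118) and atmospheric
#' nitrogen for nitrogen (R_ref = 0.00368). All delta values handled by the
#' package are per mil relative to these scales.
#'
#' @return A tibble with columns `element` (`"13C"`, `"15N"`), `standard`
#'   (`"VPDB"`, `"AIR"`) and `r_ref` (dimensionless heavy/light isotope ratio
#'   of the reference).
#' @examples
#' iso_standards()
#' @export
iso_standards <- function() {
  tibble(
    element = c("13C", "15N"),
    standard = c("VPDB", "AIR"),
    r_ref = c(0.01118, 0.00368)
  )
}

iso_elements <- c("13C", "15N")

check_element <- function(element) {
  if (!all(element %in% iso_elements)) {
    abort(
      paste0(
        "`element` must be one of ",
        paste0('"', iso_elements, '"', collapse = ", "),
        "; got: ", paste(unique(setdiff(element, iso_elements)), collapse = ", ")
      ),
      class = "spongeflux_error_element"
    )
  }
  invisible(element)
}

r_ref_for <- function(element, standards = iso_standards()) {
  check_element(element)
  standards$r_ref[match(element, standards$element)]
}

#' Convert delta notation to an isotope ratio
#'
#' Inverts the delta definition \eqn{\delta = (R_{sample}/R_{ref} - 1) \times
#' 1000} to recover the heavy/light isotope ratio of a sample.
#'
#' @param delta Numeric vector of delta values in per mil. Must be greater
#'   than -1000 (the ratio must stay positive).
#' @param element `"13C"` or `"15N"` (recycled against `delta`).
#' @param standards Reference standard registry, see [iso_standards()].
#' @return Numeric vector of isotope ratios (dimensionless, > 0).
#' @examples
#' delta_to_ratio(0, "13C")     # returns R_ref of VPDB
#' delta_to_ratio(1000, "13C")  # 0.02236
#' @seealso [ratio_to_delta()], [delta_to_fraction()]
#' @export
delta_to_ratio <- function(delta, element, standards = iso_standards()) {
  if (any(delta <= -1000, na.rm = TRUE)) {
    abort("`delta` must be > -1000 per mil (isotope ratio must stay positive).",
      class = "spongeflux_error_domain")
  }
  (delta / 1000 + 1) * r_ref_for(element, standards)
}

#' Convert an isotope ratio back to delta notation
#'
#' @param ratio Numeric vector of heavy/light isotope ratios (> 0).
#' @inheritParams delta_to_ratio
#' @return Delta values in per mil.
#' @export
ratio_to_delta <- function(ratio, element, standards = iso_standards()) {
  if (any(ratio <= 0, na.rm = TRUE)) {
    abort("`ratio` must be strictly positive.", class = "spongeflux_error_domain")
  }
  (ratio / r_ref_for(element, standards) - 1) * 1000
}

#' Convert an isotope ratio to fractional abundance
#'
#' The fractional (atom) abundance of the heavy isotope is
#' \eqn{F = R / (1 + R)}: heavy atoms over all atoms of the element.
#'
#' @param ratio Numeric vector of isotope ratios (> 0).
#' @return Atom fractions in (0, 1).
#' @examples
#' ratio_to_fraction(1)        # 0.5, equal abundance
#' ratio_to_fraction(0.01118)  # ~0.011056, 13C at VPDB
#' @export
ratio_to_fraction <- function(ratio) {
  if (any(ratio <= 0, na.rm = TRUE)) {
    abort("`ratio` must be strictly positive.", class = "spongeflux_error_domain")
  }
  ratio / (1 + ratio)
}

#' Convert fractional abundance to an isotope ratio
#'
#' Inverse of [ratio_to_fraction()]: \eqn{R = F / (1 - F)}.
#'
#' @param fraction Atom fractions in (0, 1).
#' @return Isotope ratios.
#' @export
fraction_to_ratio <- function(fraction) {
  if (any(fraction <= 0 | fraction >= 1, na.rm = TRUE)) {
    abort("`fraction` must lie strictly between 0 and 1.",
      class = "spongeflux_error_domain")
  }
  fraction / (1 - fraction)
}

#' Convert delta notation to fractional abundance
#'
#' Two modes are provided. `mode = "exact"` composes [delta_to_ratio()] with
#' [ratio_to_fraction()], giving the standard atom-fraction definition
#' \eqn{F = R/(1+R)}. `mode = "approx"` returns \eqn{(\delta/1000 + 1) \times
#' R_{ref}} directly, i.e. it uses the isotope ratio itself as the atom
#' fraction -- a small-R approximation common in spreadsheet workflows. The
#' two agree to within 1.2 percent relative for carbon at natural abundance;
#' `approx` always exceeds `exact` by the factor \eqn{(1 + R_{sample})}.
#'
#' @inheritParams delta_to_ratio
#' @param mode `"exact"` (default) or `"approx"`.
#' @return Atom fractions.
#' @examples
#' delta_to_fraction(0, "13C")                   # 0.01105639
#' delta_to_fraction(0, "13C", mode = "approx")  # 0.01118
#' @export
delta_to_fraction <- function(delta, element, mode = c("exact", "approx"),
                              standards = iso_standards()) {
  mode <- match.arg(mode)
  r <- delta_to_ratio(delta, element, standards)
  switch(mode, exact = ratio_to_fraction(r), approx = r)
}

#' Convert fractional abundance back to delta notation
#'
#' Inverse of [delta_to_fraction()] under the same `mode`.
#'
#' @inheritParams delta_to_fraction
#' @param fraction Atom fractions.
#' @export
fraction_to_delta <- function(fraction, element, mode = c("exact", "approx"),
                              standards = iso_standards()) {
  mode <- match.arg(mode)
  r <- switch(mode, exact = fraction_to_ratio(fraction), approx = fraction)
  ratio_to_delta(r, element, standards)
}

#' Excess (above-background) fractional abundance
#'
#' Tracer enrichment of a sample is its atom fraction minus the natural
#' (pre-feeding) background: \eqn{E = F_{sample} - F_{background}}. Negative
#' values can occur for noisy near-background samples and are preserved, not
#' clamped; downstream summaries flag them in QC output.
#'
#' @param f_sample,f_background Atom fractions (vectors recycle).
#' @return Atom fraction excess (may be negative).
#' @export
atom_excess <- function(f_sample, f_background) {
  f_sample - f_background
}

#' Excess enrichment straight from delta values
#'
#' Convenience wrapper converting sample and background deltas to atom
#' fractions (see [delta_to_fraction()]) and subtracting.
#'
#' @param delta_sample,delta_background Delta values in per mil.
#' @inheritParams delta_to_fraction
#' @return Atom fraction excess.
#' @examples
#' excess_from_delta(50, -20, "13C")
#' @export
excess_from_delta <- function(delta_sample, delta_background, element,
                              mode = c("exact", "approx"),
                              standards = iso_standards()) {
  mode <- match.arg(mode)
  atom_excess(
    delta_to_fraction(delta_sample, element, mode, standards),
    delta_to_fraction(delta_background, element, mode, standards)
  )
}
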