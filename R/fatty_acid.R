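#' Parse fatty acid names in CX:Y omega-Z nomenclature
#'
#' PLFAs are written `CX:Y` followed by an optional omega position, where X
#' is the carbon chain length, Y the number of double bonds and Z the
#' position of the first double bond counted from the methyl end. Optional
#' prefixes: `i` (iso) and `ai` (anteiso) for terminal methyl branching,
#' `Me` for mid-chain methyl branching, `Cy` for a cyclopropyl ring. The
#' parser tolerates case variants, a missing leading `C`, optional hyphens
#' after the prefix, and `w` in place of the omega glyph.
#'
#' @param name Character vector of fatty acid names, e.g. `"C20:5ω3"`,
#'   `"Cy-C17:0"`, `"i-C25:1ω7"`.
#' @return A tibble with one row per input: `input`, `prefix` (`"none"`,
#'   `"i"`, `"ai"`, `"Me"`, `"Cy"`), `chain_length`, `double_bonds`,
#'   `omega_position` (NA when unstated) and the canonical `fatty_acid`
#'   name. Formatting a parsed name and re-parsing it is idempotent.
#' @examples
#' parse_fatty_acid(c("C20:5w3", "cy-c17:0", "iC25:1w7"))
#' @export
parse_fatty_acid <- function(name) {
  if (length(name) == 0) {
    return(tibble(input = character(), prefix = character(),
      chain_length = integer(), double_bonds = integer(),
      omega_position = integer(), fatty_acid = character()))
  }
  rx <- "^\\s*(?:(i|ai|me|cy)[-_ ]?)?c?([0-9]+):([0-9]+)(?:[ωw]([0-9]+))?\\s*$"
  lowered <- tolower(name)
  m <- regmatches(lowered, regexec(rx, lowered))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    abort(
      paste0("Cannot parse fatty acid name(s): ",
        paste0('"', unique(name[bad]), '"', collapse = ", ")),
      class = "spongeflux_error_parse"
    )
  }
  parts <- do.call(rbind, m)
  prefix_in <- parts[, 2]
  prefix <- c(none = "none", i = "i", ai = "ai", me = "Me", cy = "Cy")[
    ifelse(prefix_in == "", "none", prefix_in)]
  chain <- as.integer(parts[, 3])
  db <- as.integer(parts[, 4])
  omega <- suppressWarnings(as.integer(parts[, 5]))
  if (any(chain < 10 | chain > 34)) {
    abort(
      paste0("Chain length outside the supported 10-34 range: ",
        paste(unique(name[chain < 10 | chain > 34]), collapse = ", ")),
      class = "spongeflux_error_domain"
    )
  }
  if (any(db > 6)) {
    abort(
      paste0("More than 6 double bonds: ",
        paste(unique(name[db > 6]), collapse = ", ")),
      class = "spongeflux_error_domain"
    )
  }
  tibble(
    input = as.character(name),
    prefix = unname(prefix),
    chain_length = chain,
    double_bonds = db,
    omega_position = omega,
    fatty_acid = format_fatty_acid(unname(prefix), chain, db, omega)
  )
}

#' Format fatty acid components as a canonical name
#'
#' @param prefix One of `"none"`, `"i"`, `"ai"`, `"Me"`, `"Cy"`.
#' @param chain_length,double_bonds,omega_position Integer vectors
#'   (`omega_position` may be NA).
#' @return Canonical names such as `"i-C15:0"` or `"C20:5ω3"`.
#' @export
format_fatty_acid <- function(prefix, chain_length, double_bonds,
                              omega_position = NA_integer_) {
  pre <- ifelse(prefix == "none", "", paste0(prefix, "-"))
  om <- ifelse(is.na(omega_position), "", paste0("ω", omega_position))
  paste0(pre, "C", chain_length, ":", double_bonds, om)
}

#' Canonicalise fatty acid names
#'
#' @param name Character vector of fatty acid names in any tolerated spelling.
#' @return Canonical names (see [parse_fatty_acid()]).
#' @export
canonical_fatty_acid <- function(name) {
  parse_fatty_acid(name)$fatty_acid
}

#' Classify fatty acids into biomarker classes
#'
#' Assigns each fatty acid to `bacteria_specific`, `sponge_specific` or
#' `unspecific`. An explicit classification table (columns `fatty_acid`,
#' `class`) always wins for the fatty acids it lists; the remaining fatty
#' acids fall through to rules that reproduce the standard biomarker
#' assignments of the sponge PLFA literature:
#'
#' * prefix `Cy` or `Me` (cyclopropyl / mid-methyl branched): bacteria;
#' * prefix `i`/`ai` with chain length <= 19: bacteria;
#' * chain length >= 22 (very-long-chain demospongic acids and their
#'   branched variants): sponge;
#' * everything else: unspecific.
#'
#' @param name Character vector of fatty acid names.
#' @param table Optional tibble/data.frame with columns `fatty_acid` and
#'   `class` overriding the rules (names are canonicalised before matching).
#' @return Character vector of class labels.
#' @examples
#' classify_fatty_acid(c("Me-C16:0", "C28:2ω7", "C16:1"))
#' @export
classify_fatty_acid <- function(name, table = NULL) {
  fa <- parse_fatty_acid(name)
  cls <- dplyr::case_when(
    fa$prefix %in% c("Cy", "Me") ~ "bacteria_specific",
    fa$prefix %in% c("i", "ai") & fa$chain_length <= 19 ~ "bacteria_specific",
    fa$chain_length >= 22 ~ "sponge_specific",
    TRUE ~ "unspecific"
  )
  if (!is.null(table)) {
    stopifnot(all(c("fatty_acid", "class") %in% names(table)))
    bad <- setdiff(unique(table$class), plfa_classes)
    if (length(bad) > 0) {
      abort(paste0("Unknown biomarker class in table: ",
        paste(bad, collapse = ", ")), class = "spongeflux_error_domain")
    }
    key <- canonical_fatty_acid(table$fatty_acid)
    hit <- match(fa$fatty_acid, key)
    cls[!is.na(hit)] <- table$class[hit[!is.na(hit)]]
  }
  cls
}

plfa_classes <- c("bacteria_specific", "sponge_specific", "unspecific")
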