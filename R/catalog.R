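#' The 30-item PANSS catalog with its five-domain assignment
#'
#' Returns the ordered item codes (P1-P7, N1-N7, G1-G16) and the mapping of
#' each item to one of the five symptom domains recovered by network community
#' analysis of PANSS data: Positive/Impaired Salience (POS), Impaired
#' Cognition-Control (COG), Impulsive-Hostile (HOS), Distress (DST; anxiety
#' G2, guilt G3, tension G4, depression G6), and Negative/Withdrawn-Disengaged
#' (NEG).
#'
#' @return object of class `item_catalog`: list with `codes` (character, 30
#'   items in scale order) and `domain_of` (named character vector mapping
#'   item code to domain label).
#' @export
panss_catalog <- function() {
  codes <- c(paste0("P", 1:7), paste0("N", 1:7), paste0("G", 1:16))
  domain_of <- c(
    P1 = "POS", P2 = "COG", P3 = "POS", P4 = "COG", P5 = "POS",
    P6 = "POS", P7 = "HOS",
    N1 = "NEG", N2 = "NEG", N3 = "NEG", N4 = "NEG", N5 = "COG",
    N6 = "NEG", N7 = "COG",
    G1 = "POS", G2 = "DST", G3 = "DST", G4 = "DST", G5 = "COG",
    G6 = "DST", G7 = "NEG", G8 = "HOS", G9 = "POS", G10 = "COG",
    G11 = "COG", G12 = "POS", G13 = "COG", G14 = "HOS", G15 = "COG",
    G16 = "POS")
  domain_of <- domain_of[codes]
  structure(list(codes = codes, domain_of = domain_of),
            class = "item_catalog")
}

#' Item codes belonging to a domain
#'
#' @param catalog an `item_catalog`.
#' @param domain domain label (e.g. `"DST"`).
#' @return character vector of member item codes.
#' @export
domain_items <- function(catalog, domain) {
  catalog$codes[catalog$domain_of[catalog$codes] == domain]
}

validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "item_catalog"))
  if (length(catalog$codes) != 30L)
    stop("catalog must contain exactly 30 items")
  if (!all(catalog$codes %in% names(catalog$domain_of)))
    stop("every item must be mapped to a domain")
  invisible(catalog)
}

#' @export
print.item_catalog <- function(x, ...) {
  cat("PANSS item catalog: 30 items in", length(unique(x$domain_of)),
      "domains\n")
  for (d in unique(x$domain_of))
    cat(sprintf("  %s: %s\n", d, paste(x$codes[x$domain_of == d],
                                       collapse = " ")))
  invisible(x)
}
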