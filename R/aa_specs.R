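#' Amino acid specifications
#'
#' Per-amino-acid constants used across the package: number of carbons in the
#' underivatized molecule, number of carbons added by derivatization, and the
#' biosynthetic precursor family (branched-chain AAs from pyruvate, Thr/Lys/Asp
#' from oxaloacetate, Phe from phosphoenolpyruvate).
#'
#' The added-carbon counts default to N-acetyl isopropyl ester chemistry
#' (acetyl + isopropyl = 5 carbons for a monofunctional amino acid, two extra
#' for the acetylated side chains of Thr and Lys, three extra for the second
#' esterified carboxyl of Asp). Derivatization schemes differ between labs, so
#' these counts are configurable placeholders, not asserted study values:
#' override them via [aa_spec()] or a standards table if your chemistry adds a
#' different number of carbons.
#'
#' @param code Three-letter amino acid code, e.g. `"Val"`.
#' @param n_carbon Carbons in the underivatized amino acid (>= 2).
#' @param n_added_carbon Carbons added by derivatization (>= 0).
#' @param precursor_family One of `"pyruvate"`, `"oxaloacetate"`,
#'   `"phosphoenolpyruvate"`.
#' @param name Full amino acid name (optional).
#'
#' @return `aa_spec()` returns a one-row data frame; `default_aa_specs()`
#'   returns a data frame with one row per amino acid (the six essential AAs
#'   plus Asp) and columns `code`, `name`, `n_carbon`, `n_added_carbon`,
#'   `precursor_family`.
#' @examples
#' default_aa_specs()
#' aa_spec("Val", n_carbon = 5, n_added_carbon = 5, precursor_family = "pyruvate")
#' @export
aa_spec <- function(code, n_carbon, n_added_carbon,
                    precursor_family = c("pyruvate", "oxaloacetate",
                                         "phosphoenolpyruvate"),
                    name = code) {
  precursor_family <- match.arg(precursor_family)
  stopifnot(is.character(code), nchar(code) == 3L,
            n_carbon >= 2, n_carbon == round(n_carbon),
            n_added_carbon >= 0, n_added_carbon == round(n_added_carbon))
  data.frame(code = code, name = name,
             n_carbon = as.integer(n_carbon),
             n_added_carbon = as.integer(n_added_carbon),
             precursor_family = precursor_family,
             stringsAsFactors = FALSE)
}

#' @rdname aa_spec
#' @export
default_aa_specs <- function() {
  rbind(
    aa_spec("Thr", 4, 7, "oxaloacetate",        name = "threonine"),
    aa_spec("Lys", 6, 7, "oxaloacetate",        name = "lysine"),
    aa_spec("Phe", 9, 5, "phosphoenolpyruvate", name = "phenylalanine"),
    aa_spec("Val", 5, 5, "pyruvate",            name = "valine"),
    aa_spec("Ile", 6, 5, "pyruvate",            name = "isoleucine"),
    aa_spec("Leu", 6, 5, "pyruvate",            name = "leucine"),
    aa_spec("Asp", 4, 8, "oxaloacetate",        name = "aspartate")
  )
}

# fetch one spec row by code, with a helpful error
lookup_aa_spec <- function(code, specs = default_aa_specs()) {
  i <- match(code, specs$code)
  if (anyNA(i)) {
    stop("unknown amino acid code(s): ",
         paste(code[is.na(i)], collapse = ", "), call. = FALSE)
  }
  specs[i, , drop = FALSE]
}
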