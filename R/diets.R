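#' Diet composition
#'
#' Describes one experimental diet as mass fractions of its ingredients and
#' the carbon isotope values of its three carbon sources: casein (C3 protein,
#' \eqn{\delta^{13}}C about -26.5 per mil), sucrose (C4, -12.2 per mil) and
#' cornmeal (C4, -12.0 per mil). Cornmeal is partly protein
#' (`cornmeal_protein_fraction`, default 10% by weight) and contributes to
#' both the protein and the carbohydrate pools; its carbohydrate mass defaults
#' to its non-protein mass.
#'
#' @param treatment_label Label such as `"40P:40C"` (percent protein :
#'   percent carbohydrate).
#' @param mass_fraction_casein,mass_fraction_sucrose,mass_fraction_cornmeal,mass_fraction_other
#'   Ingredient mass fractions of the dry diet; must sum to 1 within 1e-6.
#'   `mass_fraction_other` absorbs oils, fibre, vitamins and minerals; it
#'   defaults to the remainder.
#' @param cornmeal_protein_fraction Protein fraction of cornmeal by weight
#'   (default 0.10).
#' @param cornmeal_carbohydrate_fraction Carbohydrate fraction of cornmeal;
#'   defaults to its non-protein mass.
#' @param delta_casein,delta_sucrose,delta_cornmeal Source
#'   \eqn{\delta^{13}}C values (per mil vs VPDB).
#'
#' @return An object of class `"diet_composition"` (a named list).
#' @examples
#' d <- diet_composition("9P:75C", mass_fraction_casein = 0.051,
#'                       mass_fraction_sucrose = 0.36,
#'                       mass_fraction_cornmeal = 0.39)
#' protein_source_fractions(d)
#' @export
diet_composition <- function(treatment_label,
                             mass_fraction_casein,
                             mass_fraction_sucrose,
                             mass_fraction_cornmeal,
                             mass_fraction_other = NULL,
                             cornmeal_protein_fraction = 0.10,
                             cornmeal_carbohydrate_fraction =
                               1 - cornmeal_protein_fraction,
                             delta_casein = -26.5,
                             delta_sucrose = -12.2,
                             delta_cornmeal = -12.0) {
  if (is.null(mass_fraction_other)) {
    mass_fraction_other <- 1 - mass_fraction_casein - mass_fraction_sucrose -
      mass_fraction_cornmeal
  }
  fr <- c(casein = mass_fraction_casein, sucrose = mass_fraction_sucrose,
          cornmeal = mass_fraction_cornmeal, other = mass_fraction_other)
  if (any(fr < -1e-9) || any(fr > 1 + 1e-9)) {
    stop("diet '", treatment_label, "': mass fractions must lie in [0, 1]",
         call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-6) {
    stop("diet '", treatment_label, "': mass fractions sum to ",
         format(sum(fr)), ", not 1", call. = FALSE)
  }
  stopifnot(cornmeal_protein_fraction >= 0, cornmeal_protein_fraction <= 1,
            cornmeal_carbohydrate_fraction >= 0,
            cornmeal_carbohydrate_fraction <= 1,
            is.finite(delta_casein), is.finite(delta_sucrose),
            is.finite(delta_cornmeal))
  structure(list(
    treatment_label = treatment_label,
    mass_fraction_casein = mass_fraction_casein,
    mass_fraction_sucrose = mass_fraction_sucrose,
    mass_fraction_cornmeal = mass_fraction_cornmeal,
    mass_fraction_other = mass_fraction_other,
    cornmeal_protein_fraction = cornmeal_protein_fraction,
    cornmeal_carbohydrate_fraction = cornmeal_carbohydrate_fraction,
    delta_casein = delta_casein,
    delta_sucrose = delta_sucrose,
    delta_cornmeal = delta_cornmeal
  ), class = "diet_composition")
}

#' Default four-diet design
#'
#' The four diets of the feeding experiment, varying inversely in C3 protein
#' versus C4 carbohydrate: 40P:40C, 21P:45C, 12P:55C and 9P:75C (percent
#' protein : percent carbohydrate). Sucrose is held at 36% of the diet in all
#' treatments; cornmeal supplies the remaining carbohydrate and, being 10%
#' protein by weight, also part of the protein (so e.g. the 9% protein diet is
#' 5.1% casein plus 3.9% cornmeal protein from 39% cornmeal).
#'
#' @return A named list of [diet_composition()] objects.
#' @export
default_diets <- function() {
  spec <- data.frame(
    label    = c("40P:40C", "21P:45C", "12P:55C", "9P:75C"),
    protein  = c(0.40, 0.21, 0.12, 0.09),
    carb     = c(0.40, 0.45, 0.55, 0.75)
  )
  sucrose <- 0.36
  diets <- lapply(seq_len(nrow(spec)), function(i) {
    cornmeal <- spec$carb[i] - sucrose
    casein <- spec$protein[i] - 0.10 * cornmeal
    diet_composition(spec$label[i],
                     mass_fraction_casein = casein,
                     mass_fraction_sucrose = sucrose,
                     mass_fraction_cornmeal = cornmeal)
  })
  names(diets) <- spec$label
  diets
}

#' @export
print.diet_composition <- function(x, ...) {
  cat("Diet", x$treatment_label, "\n")
  cat(sprintf("  casein %.3f  sucrose %.3f  cornmeal %.3f  other %.3f\n",
              x$mass_fraction_casein, x$mass_fraction_sucrose,
              x$mass_fraction_cornmeal, x$mass_fraction_other))
  cat(sprintf("  d13C: casein %.1f  sucrose %.1f  cornmeal %.1f (permil)\n",
              x$delta_casein, x$delta_sucrose, x$delta_cornmeal))
  invisible(x)
}

#' Total protein fraction of a diet
#'
#' Casein plus the protein contained in cornmeal, per gram of dry food.
#' @param diet A [diet_composition()].
#' @return Numeric scalar in \[0, 1\].
#' @export
total_protein_fraction <- function(diet) {
  stopifnot(inherits(diet, "diet_composition"))
  diet$mass_fraction_casein +
    diet$mass_fraction_cornmeal * diet$cornmeal_protein_fraction
}

#' Split of dietary protein between casein and cornmeal
#'
#' Fractions of the diet's total protein mass contributed by casein and by
#' cornmeal (which is `cornmeal_protein_fraction` protein by weight).
#'
#' @param diet A [diet_composition()].
#' @return Named numeric vector `c(casein = ..., cornmeal = ...)` summing to 1.
#' @export
protein_source_fractions <- function(diet) {
  stopifnot(inherits(diet, "diet_composition"))
  m_cas <- diet$mass_fraction_casein
  m_cornp <- diet$mass_fraction_cornmeal * diet$cornmeal_protein_fraction
  total <- m_cas + m_cornp
  if (total <= 0) {
    stop("diet '", diet$treatment_label, "' contains no protein; ",
         "protein source fractions undefined", call. = FALSE)
  }
  c(casein = m_cas / total, cornmeal = m_cornp / total)
}
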