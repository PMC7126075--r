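#' Amino acid concentration profile of a protein source
#'
#' Concentrations of amino acids in one dietary protein source, as gram AA
#' per gram protein (or per gram dry source, flagged by `unit`). Used to
#' concentration-weight the dietary mixing model: an amino acid scarce in
#' casein but abundant in cornmeal protein draws its dietary
#' \eqn{\delta^{13}}C toward the cornmeal value.
#'
#' @param source Source name, e.g. `"casein"`.
#' @param concentration Named numeric vector, names are 3-letter AA codes,
#'   values g AA per g (all >= 0).
#' @param unit `"per_g_protein"` (default) or `"per_g_source"`.
#' @return An object of class `"aa_profile"`.
#' @export
aa_profile <- function(source, concentration,
                       unit = c("per_g_protein", "per_g_source")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(concentration), length(concentration) > 0,
            !is.null(names(concentration)), all(concentration >= 0))
  structure(list(source = source, concentration = concentration, unit = unit),
            class = "aa_profile")
}

#' Default amino acid profiles for casein and cornmeal protein
#'
#' Representative literature-style compositions (g AA per g protein) for
#' bovine casein and for cornmeal (maize) protein, covering the six essential
#' amino acids plus Asp. These are configurable placeholders — the package
#' does not assert them as any particular study's measured values; supply your
#' own profile via [aa_profile()] or [read_aa_profile()] for real analyses.
#' The qualitative contrasts they encode are the well-known ones: maize
#' protein is lysine-poor and leucine-rich relative to casein.
#'
#' @return An [aa_profile()].
#' @export
default_casein_profile <- function() {
  aa_profile("casein", c(
    Thr = 0.042, Lys = 0.078, Phe = 0.050, Val = 0.066,
    Ile = 0.054, Leu = 0.095, Asp = 0.068))
}

#' @rdname default_casein_profile
#' @export
default_cornmeal_profile <- function() {
  aa_profile("cornmeal", c(
    Thr = 0.035, Lys = 0.028, Phe = 0.049, Val = 0.047,
    Ile = 0.036, Leu = 0.122, Asp = 0.065))
}

#' Microbial synthesis fractionation offsets
#'
#' Per-amino-acid isotopic fractionation (\eqn{\Delta^{13}}C, per mil)
#' imposed by microbial de novo synthesis relative to the carbohydrate
#' substrate pool. The default offsets are configurable placeholders of
#' realistic magnitude (a few per mil depletion, larger for amino acids with
#' longer biosynthetic routes); heterotrophic culture studies report
#' compound-specific fractionations of roughly this size. Supply measured
#' factors via `fractionation_table()` or [read_fractionation()] for real
#' analyses.
#'
#' @param offset Named numeric vector of per-mil offsets, names are AA codes.
#' @return An object of class `"fractionation_table"`.
#' @export
fractionation_table <- function(offset) {
  stopifnot(is.numeric(offset), !is.null(names(offset)),
            all(is.finite(offset)))
  structure(list(offset = offset), class = "fractionation_table")
}

#' @rdname fractionation_table
#' @export
default_fractionation <- function() {
  fractionation_table(c(
    Thr = -1.0, Lys = -2.0, Phe = -3.5, Val = -3.0, Ile = -2.5, Leu = -4.0))
}

#' Dietary-protein end member (concentration-weighted mixing)
#'
#' \eqn{\delta^{13}}C that a muscle amino acid would carry if 100% of it were
#' directly routed from dietary protein. Each amino acid's dietary value is
#' the mixture of casein and cornmeal-protein values weighted by the product
#' of protein mass per gram diet and the AA's concentration in that protein:
#' \deqn{\delta_{AA} = \frac{m_{cas} c_{cas} \delta_{cas} +
#'   m_{cornP} c_{corn} \delta_{corn}}{m_{cas} c_{cas} + m_{cornP} c_{corn}}}
#'
#' @param diet A [diet_composition()].
#' @param casein_profile,cornmeal_profile [aa_profile()] objects (g AA per g
#'   protein).
#' @param aa Character vector of AA codes to compute; defaults to the codes
#'   shared by both profiles.
#' @return Named numeric vector of per-mil values. Amino acids absent from
#'   both sources get `NA` with a warning naming them.
#' @examples
#' d <- default_diets()[["9P:75C"]]
#' dietary_aa_delta(d, default_casein_profile(), default_cornmeal_profile())
#' @export
dietary_aa_delta <- function(diet, casein_profile, cornmeal_profile,
                             aa = NULL) {
  stopifnot(inherits(diet, "diet_composition"),
            inherits(casein_profile, "aa_profile"),
            inherits(cornmeal_profile, "aa_profile"))
  if (casein_profile$unit != cornmeal_profile$unit) {
    stop("profile units differ: ", casein_profile$unit, " vs ",
         cornmeal_profile$unit, call. = FALSE)
  }
  if (is.null(aa)) {
    aa <- intersect(names(casein_profile$concentration),
                    names(cornmeal_profile$concentration))
  }
  miss <- setdiff(aa, union(names(casein_profile$concentration),
                            names(cornmeal_profile$concentration)))
  if (length(miss)) {
    stop("no concentration for amino acid(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m_cas <- diet$mass_fraction_casein
  m_cornp <- diet$mass_fraction_cornmeal * diet$cornmeal_protein_fraction
  c_cas <- casein_profile$concentration[aa]
  c_cas[is.na(c_cas)] <- 0
  c_corn <- cornmeal_profile$concentration[aa]
  c_corn[is.na(c_corn)] <- 0
  w_cas <- m_cas * c_cas
  w_corn <- m_cornp * c_corn
  total <- w_cas + w_corn
  out <- (w_cas * diet$delta_casein + w_corn * diet$delta_cornmeal) / total
  bad <- total == 0
  if (any(bad)) {
    out[bad] <- NA_real_
    warning("dietary end member undefined (zero concentration in both ",
            "sources) for: ", paste(aa[bad], collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.numeric(out), aa)
}

#' Carbohydrate pool delta13C of a diet
#'
#' Mass-weighted mean \eqn{\delta^{13}}C of the dietary carbohydrates
#' (sucrose plus the carbohydrate fraction of cornmeal) — the substrate pool
#' from which gut microbes synthesize amino acids de novo.
#'
#' @param diet A [diet_composition()].
#' @return Per-mil scalar.
#' @export
carbohydrate_pool_delta <- function(diet) {
  stopifnot(inherits(diet, "diet_composition"))
  m_suc <- diet$mass_fraction_sucrose
  m_cornc <- diet$mass_fraction_cornmeal * diet$cornmeal_carbohydrate_fraction
  total <- m_suc + m_cornc
  if (total <= 0) {
    stop("diet '", diet$treatment_label, "' contains no carbohydrate; ",
         "pool delta undefined", call. = FALSE)
  }
  (m_suc * diet$delta_sucrose + m_cornc * diet$delta_cornmeal) / total
}

#' Microbial-synthesis end member
#'
#' \eqn{\delta^{13}}C a muscle amino acid would carry if 100% of it were
#' synthesized de novo by gut microbes from the dietary carbohydrate pool:
#' the pool value shifted by the AA-specific fractionation offset.
#'
#' @param carb_delta Carbohydrate pool \eqn{\delta^{13}}C (per mil), from
#'   [carbohydrate_pool_delta()].
#' @param fractionation A [fractionation_table()].
#' @param aa AA codes to compute; defaults to all codes in the table.
#' @return Named numeric vector of per-mil values.
#' @export
microbial_endmember_delta <- function(carb_delta, fractionation, aa = NULL) {
  stopifnot(is.finite(carb_delta), inherits(fractionation,
                                            "fractionation_table"))
  if (is.null(aa)) aa <- names(fractionation$offset)
  miss <- setdiff(aa, names(fractionation$offset))
  if (length(miss)) {
    stop("no fractionation offset for amino acid(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  carb_delta + fractionation$offset[aa]
}

#' Build the two-source end-member set
#'
#' For every diet and amino acid, computes the dietary-routing end member
#' ([dietary_aa_delta()], optionally shifted by a routing trophic
#' discrimination, default 0) and the microbial-synthesis end member
#' ([carbohydrate_pool_delta()] plus fractionation offset). These are the two
#' sources of the mixing model in [estimate_mixing()].
#'
#' @param diets List of [diet_composition()] objects.
#' @param casein_profile,cornmeal_profile [aa_profile()] objects.
#' @param fractionation A [fractionation_table()].
#' @param aa AA codes; default [ESSENTIAL_AA].
#' @param routing_offset Per-mil trophic discrimination applied to the
#'   routed (dietary) end member; scalar or named per-AA vector, default 0.
#' @return A data frame of class `"endmember_set"` with columns `treatment`,
#'   `aa`, `delta_dietary`, `delta_microbial`.
#' @examples
#' em <- build_endmembers(default_diets())
#' head(em)
#' @export
build_endmembers <- function(diets,
                             casein_profile = default_casein_profile(),
                             cornmeal_profile = default_cornmeal_profile(),
                             fractionation = default_fractionation(),
                             aa = ESSENTIAL_AA,
                             routing_offset = 0) {
  stopifnot(length(diets) > 0)
  if (inherits(diets, "diet_composition")) diets <- list(diets)
  off <- if (length(routing_offset) == 1L && is.null(names(routing_offset))) {
    stats::setNames(rep(routing_offset, length(aa)), aa)
  } else {
    stopifnot(all(aa %in% names(routing_offset)))
    routing_offset[aa]
  }
  rows <- lapply(diets, function(d) {
    dd <- dietary_aa_delta(d, casein_profile, cornmeal_profile, aa = aa)
    mm <- microbial_endmember_delta(carbohydrate_pool_delta(d),
                                    fractionation, aa = aa)
    data.frame(treatment = d$treatment_label, aa = aa,
               delta_dietary = as.numeric(dd + off),
               delta_microbial = as.numeric(mm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("endmember_set", "data.frame")
  out
}

# fetch end members for (treatment, aa) pairs; errors name missing pairs
endmember_lookup <- function(endmembers, treatment, aa) {
  key <- paste(treatment, aa, sep = "\r")
  have <- paste(endmembers$treatment, endmembers$aa, sep = "\r")
  i <- match(key, have)
  if (anyNA(i)) {
    missing <- unique(paste0("(", treatment[is.na(i)], ", ", aa[is.na(i)], ")"))
    stop("no end members for treatment/amino-acid pair(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  endmembers[i, c("delta_dietary", "delta_microbial")]
}
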