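#' Supply parameters: digestibility and mucosal catabolism
#'
#' Per-amino-acid fractions governing how much of the gross dietary amino
#' acid content reaches the host's systemic pool: true ileal digestibility,
#' and the fraction catabolized by the intestinal mucosa (presumably in part
#' by gut microbes) before reaching circulation.
#'
#' Default mucosal catabolism follows published estimates for non-ruminant
#' mammals on casein-based diets: 30% for Ile, 40% for Leu and Val, 45% for
#' Phe, 50% for Lys and 60% for Thr. Default digestibility values are
#' representative placeholders for highly digestible casein-based diets
#' (0.89-0.95); substitute measured values via [read_named_values()] for real
#' analyses.
#'
#' @param values Named numeric vector in \[0, 1\], names are AA codes.
#' @return A named numeric vector (validated).
#' @export
default_mucosal_catabolism <- function() {
  c(Ile = 0.30, Leu = 0.40, Val = 0.40, Phe = 0.45, Lys = 0.50, Thr = 0.60,
    Asp = 0.85)
}

#' @rdname default_mucosal_catabolism
#' @export
default_digestibility <- function() {
  c(Thr = 0.89, Lys = 0.94, Phe = 0.93, Val = 0.92, Ile = 0.92, Leu = 0.95,
    Asp = 0.91)
}

#' @rdname default_mucosal_catabolism
#' @export
check_fraction_table <- function(values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop("fractions must lie in [0, 1]; offending entries: ",
         paste(names(values)[!is.finite(values) | values < 0 | values > 1],
               collapse = ", "), call. = FALSE)
  }
  values
}

#' Metabolic demand table
#'
#' Amino acid requirements of rapidly growing mice, expressed as percent of
#' dry food. The defaults are representative placeholder values on the scale
#' of published rodent requirement estimates (a few tenths of a percent of
#' diet for most essential AAs, more for leucine; a larger nominal figure for
#' Asp reflecting its role as biosynthetic precursor); they are config
#' inputs, not asserted study values.
#'
#' @return Named numeric vector, percent of dry food.
#' @export
default_demand <- function() {
  c(Thr = 0.40, Lys = 0.40, Phe = 0.76, Val = 0.50, Ile = 0.40, Leu = 0.70,
    Asp = 1.20)
}

#' Experiment ration
#'
#' Total food intake over the experiment: daily ration times duration. Used
#' to put cumulative amino acid supply on the same footing as cumulative
#' demand.
#'
#' @param daily_ration Grams of dry food per day (> 0).
#' @param experiment_days Experiment length in days (integer >= 1); the
#'   feeding experiment ran 120 days.
#' @return Total grams of dry food.
#' @examples
#' experiment_ration(3, 120)  # 360 g
#' @export
experiment_ration <- function(daily_ration, experiment_days) {
  if (!is.finite(daily_ration) || daily_ration <= 0) {
    stop("daily_ration must be positive", call. = FALSE)
  }
  if (!is.finite(experiment_days) || experiment_days < 1 ||
      experiment_days != round(experiment_days)) {
    stop("experiment_days must be a positive whole number", call. = FALSE)
  }
  daily_ration * experiment_days
}

#' Dietary amino acid supply
#'
#' Bioavailable supply of each amino acid as a percent of dry food:
#' \deqn{supply_{AA} = (m_{cas} c_{cas} + m_{cornP} c_{corn}) \times
#'   digestibility_{AA} \times (1 - catabolism_{AA}) \times 100}
#' i.e. gross dietary content (protein mass per g food times AA concentration
#' per g protein, summed over casein and cornmeal protein) discounted for
#' incomplete digestibility and for the fraction consumed by the intestinal
#' mucosa before reaching the host's systemic pool.
#'
#' @param diet A [diet_composition()].
#' @param casein_profile,cornmeal_profile [aa_profile()] objects (g AA per g
#'   protein).
#' @param digestibility,mucosal_catabolism Named fraction vectors; defaults
#'   [default_digestibility()], [default_mucosal_catabolism()].
#' @param aa AA codes; default all codes present in `digestibility`.
#' @return Data frame with columns `aa`, `gross_pct` (before discounts) and
#'   `supply_pct`, both percent of dry food.
#' @examples
#' aa_supply(default_diets()[["12P:55C"]])
#' @export
aa_supply <- function(diet,
                      casein_profile = default_casein_profile(),
                      cornmeal_profile = default_cornmeal_profile(),
                      digestibility = default_digestibility(),
                      mucosal_catabolism = default_mucosal_catabolism(),
                      aa = names(digestibility)) {
  stopifnot(inherits(diet, "diet_composition"))
  check_fraction_table(digestibility)
  check_fraction_table(mucosal_catabolism)
  miss_d <- setdiff(aa, names(digestibility))
  miss_m <- setdiff(aa, names(mucosal_catabolism))
  if (length(miss_d) || length(miss_m)) {
    stop("missing digestibility entries for: ",
         paste(miss_d, collapse = ", "),
         if (length(miss_m)) paste0("; missing mucosal catabolism entries ",
                                    "for: ", paste(miss_m, collapse = ", ")),
         call. = FALSE)
  }
  m_cas <- diet$mass_fraction_casein
  m_cornp <- diet$mass_fraction_cornmeal * diet$cornmeal_protein_fraction
  c_cas <- casein_profile$concentration[aa]
  c_cas[is.na(c_cas)] <- 0
  c_corn <- cornmeal_profile$concentration[aa]
  c_corn[is.na(c_corn)] <- 0
  gross <- (m_cas * c_cas + m_cornp * c_corn) * 100
  supply <- gross * digestibility[aa] * (1 - mucosal_catabolism[aa])
  data.frame(aa = aa, gross_pct = as.numeric(gross),
             supply_pct = as.numeric(supply), stringsAsFactors = FALSE)
}

#' Compare amino acid supply with metabolic demand
#'
#' Ratio of bioavailable dietary supply to metabolic demand, both as percent
#' of dry food, with a classification into deficit / balanced / surplus by a
#' configurable band around 1.
#'
#' @param supply Data frame from [aa_supply()] (columns `aa`, `supply_pct`),
#'   or a named numeric vector of supply percentages.
#' @param demand Named numeric vector of demand percentages; default
#'   [default_demand()].
#' @param balanced_band Length-2 numeric: ratios inside this closed interval
#'   are "balanced" (default \[0.9, 1.1\]).
#' @return Data frame with columns `aa`, `supply_pct`, `demand_pct`, `ratio`,
#'   `class`. Zero demand gives `NA` ratio and class `"undefined"` with a
#'   warning.
#' @examples
#' supply_vs_demand(aa_supply(default_diets()[["9P:75C"]]))
#' @export
supply_vs_demand <- function(supply, demand = default_demand(),
                             balanced_band = c(0.9, 1.1)) {
  if (is.numeric(supply)) {
    supply <- data.frame(aa = names(supply), supply_pct = as.numeric(supply),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("aa", "supply_pct") %in% names(supply)),
            length(balanced_band) == 2L, balanced_band[1] <= balanced_band[2])
  miss <- setdiff(supply$aa, names(demand))
  if (length(miss)) {
    stop("missing demand entries for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dem <- demand[supply$aa]
  ratio <- ifelse(dem > 0, supply$supply_pct / dem, NA_real_)
  if (any(dem == 0)) {
    warning("zero demand for: ", paste(supply$aa[dem == 0], collapse = ", "),
            "; ratio undefined", call. = FALSE)
  }
  cls <- ifelse(is.na(ratio), "undefined",
                ifelse(ratio < balanced_band[1], "deficit",
                       ifelse(ratio > balanced_band[2], "surplus",
                              "balanced")))
  data.frame(aa = supply$aa, supply_pct = supply$supply_pct,
             demand_pct = as.numeric(dem), ratio = as.numeric(ratio),
             class = cls, stringsAsFactors = FALSE)
}
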