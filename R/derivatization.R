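#' Derivatization carbon mass balance
#'
#' Amino acids are derivatized before GC-IRMS analysis, which adds exogenous
#' carbon; the measured \eqn{\delta^{13}}C of the derivative is a
#' carbon-weighted mixture of the amino acid's carbon and the added carbon.
#' `calibrate_added_carbon()` solves the mass balance for the
#' \eqn{\delta^{13}}C of the added carbon from a standard of known isotopic
#' composition:
#' \deqn{\delta_{add} = \frac{(n_{AA}+n_{add})\,\delta_{deriv} -
#'   n_{AA}\,\delta_{known}}{n_{add}}}
#' `correct_derivatization()` inverts the same balance to recover the
#' underivatized amino acid's value from a sample measurement:
#' \deqn{\delta_{AA} = \frac{(n_{AA}+n_{add})\,\delta_{meas} -
#'   n_{add}\,\delta_{add}}{n_{AA}}}
#' The two functions are exact inverses. All values are on the per-mil scale
#' relative to VPDB; the linear-in-delta approximation is negligible at
#' natural abundance.
#'
#' @param delta_known \eqn{\delta^{13}}C (per mil) of the underivatized
#'   standard.
#' @param delta_derivatized \eqn{\delta^{13}}C (per mil) measured on the
#'   derivatized standard.
#' @param delta_measured \eqn{\delta^{13}}C (per mil) measured on a
#'   derivatized sample.
#' @param delta_added \eqn{\delta^{13}}C (per mil) of derivatization carbon,
#'   as returned by `calibrate_added_carbon()`.
#' @param n_carbon,n_added_carbon Carbon counts of the underivatized amino
#'   acid and of the derivatization addition; see [aa_spec()].
#'
#' @return A numeric vector of \eqn{\delta^{13}}C values (per mil).
#' @examples
#' calibrate_added_carbon(-12, -18, n_carbon = 5, n_added_carbon = 3)  # -28
#' correct_derivatization(-20, delta_added = -30, n_carbon = 5, n_added_carbon = 3)
#' @export
calibrate_added_carbon <- function(delta_known, delta_derivatized,
                                   n_carbon, n_added_carbon) {
  stopifnot(is.finite(delta_known), is.finite(delta_derivatized),
            n_carbon >= 2)
  if (any(n_added_carbon <= 0)) {
    stop("calibration undefined when no carbon is added by derivatization ",
         "(n_added_carbon must be > 0)", call. = FALSE)
  }
  ((n_carbon + n_added_carbon) * delta_derivatized -
     n_carbon * delta_known) / n_added_carbon
}

#' @rdname calibrate_added_carbon
#' @export
correct_derivatization <- function(delta_measured, delta_added,
                                   n_carbon, n_added_carbon) {
  stopifnot(all(is.finite(delta_measured)), n_carbon >= 2,
            n_added_carbon >= 0)
  if (any(n_added_carbon > 0) && any(!is.finite(delta_added))) {
    stop("delta_added must be finite when n_added_carbon > 0", call. = FALSE)
  }
  if (all(n_added_carbon == 0)) return(delta_measured)
  ((n_carbon + n_added_carbon) * delta_measured -
     n_added_carbon * delta_added) / n_carbon
}

#' Calibrate a table of derivatization standards
#'
#' Applies [calibrate_added_carbon()] row-wise to a standards table and
#' appends a `delta_added` column.
#'
#' @param standards Data frame with columns `aa_code`, `n_carbon`,
#'   `n_added_carbon`, `delta_known`, `delta_derivatized` (the layout written
#'   by [read_derivatization_standards()]).
#' @return The input with a `delta_added` column appended.
#' @export
calibrate_standards <- function(standards) {
  need <- c("aa_code", "n_carbon", "n_added_carbon",
            "delta_known", "delta_derivatized")
  miss <- setdiff(need, names(standards))
  if (length(miss)) {
    stop("standards table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  standards$delta_added <- calibrate_added_carbon(
    standards$delta_known, standards$delta_derivatized,
    standards$n_carbon, standards$n_added_carbon)
  standards
}

#' @rdname calibrate_standards
#' @param path Path to a tab-delimited standards table.
#' @export
read_derivatization_standards <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  calibrate_standards(x)
}
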