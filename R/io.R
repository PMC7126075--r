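# Tab-delimited I/O. Every table written by the pipeline carries a single
# leading comment line with the config hash so outputs are auditable; all
# readers skip '#' comment lines.

#' Read and write pipeline tables
#'
#' `write_tsv_stamped()` writes a data frame as tab-delimited text with an
#' optional `# config_md5: <hash>` header line; `read_tsv_stamped()` reads it
#' back (comment lines skipped).
#'
#' @param x Data frame.
#' @param path File path.
#' @param hash Optional hash string to stamp.
#' @return `read_tsv_stamped()` returns a data frame.
#' @export
write_tsv_stamped <- function(x, path, hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_md5: ", hash), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_stamped
#' @export
read_tsv_stamped <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read an isotope dataset
#'
#' Long-format tab-delimited text with columns `individual_id`, `treatment`,
#' `aa`, `delta_muscle` (per mil) and optionally `sd`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_isotopes <- function(path) {
  x <- read_tsv_stamped(path)
  need <- c("individual_id", "treatment", "aa", "delta_muscle")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("isotope file ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$delta_muscle))) {
    stop("isotope file ", path, " contains non-finite delta values",
         call. = FALSE)
  }
  x
}

#' Read an amino acid profile
#'
#' Tab-delimited with columns `aa` and `concentration` (g AA per g protein
#' unless `unit` says otherwise).
#'
#' @param path File path.
#' @param source Source name; default the file name without extension.
#' @param unit Concentration unit flag.
#' @return An [aa_profile()].
#' @export
read_aa_profile <- function(path, source = NULL,
                            unit = c("per_g_protein", "per_g_source")) {
  unit <- match.arg(unit)
  x <- read_tsv_stamped(path)
  stopifnot(all(c("aa", "concentration") %in% names(x)))
  aa_profile(source %||% sub("\\.[^.]*$", "", basename(path)),
             stats::setNames(x$concentration, x$aa), unit = unit)
}

#' Read a fractionation table
#'
#' Tab-delimited with columns `aa` and `offset` (per mil).
#' @param path File path.
#' @return A [fractionation_table()].
#' @export
read_fractionation <- function(path) {
  x <- read_tsv_stamped(path)
  stopifnot(all(c("aa", "offset") %in% names(x)))
  fractionation_table(stats::setNames(x$offset, x$aa))
}

#' Read a named value table
#'
#' Two-column tab-delimited file keyed by 3-letter AA code; used for
#' digestibility, mucosal catabolism and demand tables.
#'
#' @param path File path.
#' @param value_col Name of the value column (default `"value"`).
#' @return Named numeric vector.
#' @export
read_named_values <- function(path, value_col = "value") {
  x <- read_tsv_stamped(path)
  stopifnot("aa" %in% names(x), value_col %in% names(x))
  stats::setNames(x[[value_col]], x$aa)
}

#' Read a diet table
#'
#' One row per treatment with columns `treatment_label`,
#' `mass_fraction_casein`, `mass_fraction_sucrose`, `mass_fraction_cornmeal`
#' and optionally `mass_fraction_other`, `cornmeal_protein_fraction`,
#' `delta_casein`, `delta_sucrose`, `delta_cornmeal`.
#'
#' @param path File path.
#' @return Named list of [diet_composition()] objects.
#' @export
read_diets <- function(path) {
  x <- read_tsv_stamped(path)
  need <- c("treatment_label", "mass_fraction_casein", "mass_fraction_sucrose",
            "mass_fraction_cornmeal")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("diet file ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  diets <- lapply(seq_len(nrow(x)), function(i) {
    args <- as.list(x[i, intersect(names(x), names(formals(
      diet_composition)))])
    do.call(diet_composition, args)
  })
  names(diets) <- x$treatment_label
  diets
}

#' Read an OTU table with taxonomy sidecar
#'
#' Counts as tab-delimited samples x taxa (first column = sample id), or
#' taxa-as-rows with `taxa_as_rows = TRUE`. Taxonomy sidecar has columns
#' `taxon_id`, `phylum`, `family`. Groups file has columns `sample`,
#' `treatment`.
#'
#' @param counts_path,taxonomy_path,groups_path File paths.
#' @param taxa_as_rows Set `TRUE` if the counts file has taxa in rows.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(counts_path, taxonomy_path, groups_path,
                           taxa_as_rows = FALSE) {
  cx <- read_tsv_stamped(counts_path)
  m <- as.matrix(cx[, -1, drop = FALSE])
  rownames(m) <- cx[[1]]
  if (taxa_as_rows) m <- t(m)
  storage.mode(m) <- "integer"
  tax <- read_tsv_stamped(taxonomy_path)
  gx <- read_tsv_stamped(groups_path)
  stopifnot(all(c("sample", "treatment") %in% names(gx)))
  otu_table(m, tax, stats::setNames(gx$treatment, gx$sample))
}

#' Write an OTU table
#'
#' Writes counts (samples x taxa), taxonomy and groups as three tab-delimited
#' files alongside each other.
#'
#' @param otu An [otu_table()].
#' @param counts_path,taxonomy_path,groups_path Output paths.
#' @param hash Optional config hash to stamp.
#' @export
write_otu_table <- function(otu, counts_path, taxonomy_path, groups_path,
                            hash = NULL) {
  stopifnot(inherits(otu, "aamix_otu"))
  cx <- data.frame(sample = rownames(otu$counts), otu$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_stamped(cx, counts_path, hash)
  write_tsv_stamped(otu$taxonomy, taxonomy_path, hash)
  write_tsv_stamped(data.frame(sample = names(otu$group),
                               treatment = as.character(otu$group),
                               stringsAsFactors = FALSE),
                    groups_path, hash)
  invisible(NULL)
}

#' Write an end-member set in long format
#'
#' Tidy long table with columns `treatment`, `aa`, `role` (dietary or
#' microbial) and `delta`.
#'
#' @param endmembers An `"endmember_set"`.
#' @param path Output path.
#' @param hash Optional config hash.
#' @export
write_endmembers_long <- function(endmembers, path, hash = NULL) {
  long <- rbind(
    data.frame(treatment = endmembers$treatment, aa = endmembers$aa,
               role = "dietary", delta = endmembers$delta_dietary,
               stringsAsFactors = FALSE),
    data.frame(treatment = endmembers$treatment, aa = endmembers$aa,
               role = "microbial", delta = endmembers$delta_microbial,
               stringsAsFactors = FALSE))
  write_tsv_stamped(long, path, hash)
}
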