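#' Validate pipeline inputs
#'
#' Report-only validation of a run configuration: referenced files must
#' exist, diet mass fractions must sum to 1, amino acid codes must be
#' recognized, isotope records must be well formed, and every OTU sample
#' must carry a treatment label. Nothing is thrown; the caller decides what
#' to do with violations.
#'
#' @param config A configuration list (see [run_pipeline()]) or the path to
#'   a YAML file containing one.
#' @return Data frame with columns `stage`, `item`, `message`; zero rows if
#'   everything is well formed.
#' @export
validate_inputs <- function(config) {
  config <- load_config(config)
  v <- list()
  note <- function(stage, item, message) {
    v[[length(v) + 1L]] <<- data.frame(stage = stage, item = item,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  known_aa <- default_aa_specs()$code
  paths <- config$paths %||% list()
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !identical(paths[[nm]], "default") &&
        !file.exists(paths[[nm]])) {
      note("paths", nm, paste0("file not found: ", paths[[nm]]))
    }
  }
  diets <- try_quiet(get_diets(config))
  if (inherits(diets, "try-error")) {
    note("endmembers", "diets", attr(diets, "condition")$message)
  } else {
    for (d in diets) {
      s <- d$mass_fraction_casein + d$mass_fraction_sucrose +
        d$mass_fraction_cornmeal + d$mass_fraction_other
      if (abs(s - 1) > 1e-6) {
        note("endmembers", d$treatment_label,
             sprintf("mass fractions sum to %.4f, not 1", s))
      }
    }
  }
  iso_path <- paths$isotopes
  if (!is.null(iso_path) && file.exists(iso_path)) {
    iso <- try_quiet(read_isotopes(iso_path))
    if (inherits(iso, "try-error")) {
      note("mix", "isotopes", attr(iso, "condition")$message)
    } else {
      bad <- setdiff(unique(iso$aa), known_aa)
      for (code in bad) {
        recs <- which(iso$aa == code)
        note("mix", paste0("record ", recs[1]),
             paste0("unknown amino acid code '", code, "'"))
      }
    }
  }
  if (!is.null(paths$otu_counts) && file.exists(paths$otu_counts) &&
      !is.null(paths$otu_groups) && file.exists(paths$otu_groups)) {
    cx <- try_quiet(read_tsv_stamped(paths$otu_counts))
    gx <- try_quiet(read_tsv_stamped(paths$otu_groups))
    if (!inherits(cx, "try-error") && !inherits(gx, "try-error") &&
        all(c("sample", "treatment") %in% names(gx))) {
      unl <- setdiff(cx[[1]], gx$sample)
      for (s in unl) note("community", s, "sample has no treatment label")
    }
  }
  if (length(v) == 0) {
    return(data.frame(stage = character(), item = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

try_quiet <- function(expr) try(expr, silent = TRUE)

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

get_diets <- function(config) {
  p <- config$paths$diets
  if (is.null(p) || identical(p, "default")) default_diets() else read_diets(p)
}

get_profile <- function(config, which) {
  p <- config$paths[[paste0(which, "_profile")]]
  if (is.null(p) || identical(p, "default")) {
    if (which == "casein") default_casein_profile() else
      default_cornmeal_profile()
  } else read_aa_profile(p, source = which)
}

get_fractionation <- function(config) {
  p <- config$paths$fractionation
  if (is.null(p) || identical(p, "default")) default_fractionation() else
    read_fractionation(p)
}

get_named <- function(config, key, default) {
  p <- config$paths[[key]]
  if (is.null(p) || identical(p, "default")) default else
    read_named_values(p)
}

#' Run the full analysis pipeline
#'
#' Config-driven orchestration of all stages: optional synthetic-data
#' simulation, end-member construction, mixing-model estimation,
#' supply/demand accounting, and community statistics. Stages whose inputs
#' are absent are skipped with a logged notice; each stage writes tidy
#' tab-delimited tables stamped with the MD5 hash of the configuration, so
#' identical config + seed reruns produce byte-identical tables.
#'
#' The configuration is a list (or YAML file) with entries:
#' \describe{
#'   \item{paths}{named file paths: `diets`, `casein_profile`,
#'     `cornmeal_profile`, `fractionation`, `isotopes`, `otu_counts`,
#'     `otu_taxonomy`, `otu_groups`, `digestibility`, `mucosal_catabolism`,
#'     `demand`. Any may be `"default"` (use packaged defaults) or omitted.}
#'   \item{simulate}{if present with `enabled: true`, synthetic isotope and
#'     OTU datasets are generated first (fields `n_individuals`, `n_ceca`,
#'     `noise_sd`) and used as the stage inputs.}
#'   \item{seed}{integer; drives simulation and permutation tests.}
#'   \item{n_perm}{permutations for ANOSIM/db-RDA/Spearman (default 999).}
#'   \item{policy}{`clip_order` ("before"/"after"), `dbrda_direction`
#'     ("isotope_response"/"community_response"), `axis_prop` (default 0.8),
#'     `separation_floor` (default 1).}
#' }
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$seed` when non-NULL.
#' @return Invisibly, a list with the in-memory results of each executed
#'   stage plus `log` (character vector) and `config_hash`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  config <- load_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config$seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  viol <- validate_inputs(config)
  if (nrow(viol) > 0) {
    stop("input validation failed:\n",
         paste(sprintf("  [%s] %s: %s", viol$stage, viol$item, viol$message),
               collapse = "\n"), call. = FALSE)
  }

  # canonical config file + hash stamped into every output table
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))

  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  results <- list(config_hash = hash)
  n_perm <- config$n_perm %||% 999L
  pol <- config$policy %||% list()
  say("run: seed=%d n_perm=%d config_md5=%s", config$seed, n_perm, hash)

  diets <- get_diets(config)
  casein <- get_profile(config, "casein")
  cornmeal <- get_profile(config, "cornmeal")
  frac <- get_fractionation(config)

  ## stage: simulate (optional)
  iso <- NULL
  otu <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sim_cfg <- config$simulate
    design <- experiment_design(
      treatments = diets,
      n_individuals = sim_cfg$n_individuals %||% 6L,
      seed = config$seed)
    truth <- default_ground_truth(treatment_labels(design),
                                  noise_sd = sim_cfg$noise_sd %||% 0.5)
    sim <- simulate_experiment(design, truth = truth,
                               n_ceca = sim_cfg$n_ceca %||% 5L,
                               seed = config$seed)
    iso <- sim$isotopes
    otu <- sim$otu
    write_tsv_stamped(iso, file.path(out_dir, "synthetic_isotopes.tsv"), hash)
    write_otu_table(otu,
                    file.path(out_dir, "synthetic_otu_counts.tsv"),
                    file.path(out_dir, "synthetic_otu_taxonomy.tsv"),
                    file.path(out_dir, "synthetic_otu_groups.tsv"), hash)
    write_tsv_stamped(truth$p_microbial,
                      file.path(out_dir, "synthetic_ground_truth.tsv"), hash)
    results$simulation <- sim
    say("simulate: %d treatments x %d mice (isotopes), %d ceca/treatment, noise_sd=%.3g",
        length(diets), design$n_individuals, sim_cfg$n_ceca %||% 5L,
        truth$noise_sd)
  } else {
    if (!is.null(config$paths$isotopes)) iso <- read_isotopes(
      config$paths$isotopes)
    if (!is.null(config$paths$otu_counts)) {
      otu <- read_otu_table(config$paths$otu_counts,
                            config$paths$otu_taxonomy,
                            config$paths$otu_groups,
                            taxa_as_rows = isTRUE(config$otu_taxa_as_rows))
    }
  }

  ## stage: end members
  endmembers <- build_endmembers(diets, casein, cornmeal, frac,
                                 routing_offset = pol$routing_offset %||% 0)
  write_endmembers_long(endmembers, file.path(out_dir, "endmembers.tsv"),
                        hash)
  results$endmembers <- endmembers
  say("endmembers: %d treatments x %d amino acids", length(diets),
      length(unique(endmembers$aa)))

  ## stage: mixing
  if (!is.null(iso)) {
    est <- estimate_mixing(iso, endmembers,
                           clip_order = pol$clip_order %||% "before",
                           separation_floor = pol$separation_floor %||% 1)
    write_tsv_stamped(contribution_table(est),
                      file.path(out_dir, "contributions.tsv"), hash)
    write_tsv_stamped(est$individual,
                      file.path(out_dir, "mixing_individual.tsv"), hash)
    results$mixing <- est
    say("mix: %d records -> %d contribution cells (clip_order=%s)",
        nrow(iso), nrow(est$summary), est$clip_order)
  } else {
    say("mix: skipped (no isotope dataset)")
  }

  ## stage: supply/demand
  digest <- get_named(config, "digestibility", default_digestibility())
  catab <- get_named(config, "mucosal_catabolism",
                     default_mucosal_catabolism())
  demand <- get_named(config, "demand", default_demand())
  sd_tab <- do.call(rbind, lapply(diets, function(d) {
    s <- aa_supply(d, casein, cornmeal, digest, catab)
    out <- supply_vs_demand(s, demand,
                            balanced_band = pol$balanced_band %||%
                              c(0.9, 1.1))
    cbind(treatment = d$treatment_label, out)
  }))
  rownames(sd_tab) <- NULL
  write_tsv_stamped(sd_tab, file.path(out_dir, "supply_demand.tsv"), hash)
  results$supply_demand <- sd_tab
  say("supply: %d treatments x %d amino acids", length(diets),
      length(unique(sd_tab$aa)))

  ## stage: community
  if (!is.null(otu)) {
    ra <- relative_abundance(otu, "phylum")
    write_tsv_stamped(data.frame(sample = rownames(ra), ra,
                                 check.names = FALSE),
                      file.path(out_dir, "relative_abundance_phylum.tsv"),
                      hash)
    div <- shannon_diversity(otu$counts)
    d <- bray_curtis(otu)
    write_tsv_stamped(data.frame(sample = rownames(d), d,
                                 check.names = FALSE),
                      file.path(out_dir, "bray_curtis.tsv"), hash)
    an <- anosim_test(d, otu$group, n_perm = n_perm, seed = config$seed)
    ord <- pcoa_ord(d)
    write_tsv_stamped(data.frame(sample = rownames(ord$coordinates),
                                 ord$coordinates, check.names = FALSE),
                      file.path(out_dir, "pcoa_coordinates.tsv"), hash)
    fb <- firmicutes_bacteroidetes(otu)
    # rank-correlate Firmicutes proportion with the diet's protein rank
    prot <- vapply(diets, total_protein_fraction, numeric(1))
    rc <- rank_correlation(fb$firmicutes,
                           prot[fb$treatment],
                           n_perm = n_perm, seed = config$seed)
    stats_tab <- data.frame(
      statistic = c("anosim_R", "anosim_p", "shannon_mean",
                    "spearman_rho_firmicutes_vs_protein", "spearman_p"),
      value = c(an$statistic, an$p_value, mean(div), rc$rho, rc$p_perm),
      stringsAsFactors = FALSE)
    results$community <- list(anosim = an, pcoa = ord, diversity = div,
                              fb = fb, spearman = rc)
    say("community: ANOSIM R=%.3f p=%.4g; spearman rho=%.3f", an$statistic,
        an$p_value, rc$rho)
    if (!is.null(iso)) {
      db <- community_isotope_association(
        otu, iso,
        direction = pol$dbrda_direction %||% "isotope_response",
        axis_prop = pol$axis_prop %||% 0.8,
        n_perm = n_perm, seed = config$seed)
      stats_tab <- rbind(stats_tab, data.frame(
        statistic = c("dbrda_r2", "dbrda_r2_adjusted", "dbrda_F", "dbrda_p",
                      "dbrda_aic", "dbrda_n_axes"),
        value = c(db$r2, db$r2_adjusted, db$f_stat, db$p_perm, db$aic,
                  db$n_axes_used),
        stringsAsFactors = FALSE))
      results$community$dbrda <- db
      say("community: db-RDA adjR2=%.3f F=%.3f p=%.4g", db$r2_adjusted,
          db$f_stat, db$p_perm)
    }
    write_tsv_stamped(stats_tab, file.path(out_dir, "community_stats.tsv"),
                      hash)
  } else {
    say("community: skipped (no OTU table)")
  }

  writeLines(log, file.path(out_dir, "run_log.txt"))
  results$log <- log
  invisible(results)
}
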