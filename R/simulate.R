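#' Experiment design for the synthetic generator
#'
#' The factorial layout being simulated: which diets, how many individuals
#' per diet, which amino acids, and the base seed. The feeding study design
#' is four diets with six mice per treatment for isotope measurements and
#' five ceca per treatment for 16S sequencing.
#'
#' @param treatments List of [diet_composition()] objects; default
#'   [default_diets()].
#' @param n_individuals Individuals per treatment for isotopes (default 6).
#' @param aa Amino acid codes (default [ESSENTIAL_AA]).
#' @param seed Base integer seed (default 1).
#' @return Object of class `"experiment_design"`.
#' @export
experiment_design <- function(treatments = default_diets(),
                              n_individuals = 6L,
                              aa = ESSENTIAL_AA,
                              seed = 1L) {
  stopifnot(length(treatments) >= 1,
            all(vapply(treatments, inherits, logical(1), "diet_composition")),
            n_individuals >= 1, n_individuals == round(n_individuals),
            length(aa) >= 1)
  structure(list(treatments = treatments,
                 n_individuals = as.integer(n_individuals),
                 aa = aa, seed = as.integer(seed)),
            class = "experiment_design")
}

treatment_labels <- function(design) {
  vapply(design$treatments, `[[`, character(1), "treatment_label")
}

# deterministic, file-name-safe individual ids: "40P40C_m1" ...
individual_ids <- function(label, n) {
  sprintf("%s_m%d", gsub("[^A-Za-z0-9]", "", label), seq_len(n))
}

#' Ground truth for synthetic isotope data
#'
#' The latent quantity the mixing model estimates: the true microbial
#' fraction for every (treatment, amino acid) cell, plus the Gaussian
#' measurement noise SD on the delta scale.
#'
#' `default_ground_truth()` encodes the contribution pattern reported for
#' this system: Val rising to 0.60 and Ile to 0.40 in the lowest-protein
#' diet, a below-5% floor for Phe there and for Thr/Lys in the two
#' high-protein diets, with Thr/Lys rising several-fold as protein drops,
#' and 10-40% for most other cells. The default noise SD is 0.5 per mil, a
#' typical compound-specific isotope measurement SD.
#'
#' @param p_microbial Data frame with columns `treatment`, `aa`, `p` (each p
#'   in \[0, 1\]).
#' @param noise_sd Measurement noise SD in per mil (>= 0, default 0.5).
#' @return Object of class `"ground_truth"`.
#' @export
ground_truth <- function(p_microbial, noise_sd = 0.5) {
  stopifnot(all(c("treatment", "aa", "p") %in% names(p_microbial)),
            all(p_microbial$p >= 0), all(p_microbial$p <= 1),
            is.finite(noise_sd), noise_sd >= 0)
  structure(list(p_microbial = p_microbial, noise_sd = noise_sd),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @param treatments Treatment labels, in order of decreasing protein;
#'   default the four standard diets.
#' @export
default_ground_truth <- function(treatments = c("40P:40C", "21P:45C",
                                                "12P:55C", "9P:75C"),
                                 noise_sd = 0.5) {
  stopifnot(length(treatments) == 4L)
  p <- rbind(
    Thr = c(0.03, 0.03, 0.10, 0.15),
    Lys = c(0.03, 0.03, 0.10, 0.15),
    Phe = c(0.15, 0.15, 0.10, 0.03),
    Val = c(0.35, 0.35, 0.40, 0.60),
    Ile = c(0.30, 0.30, 0.35, 0.40),
    Leu = c(0.15, 0.15, 0.20, 0.20))
  colnames(p) <- treatments
  long <- expand.grid(aa = rownames(p), treatment = treatments,
                      stringsAsFactors = FALSE)
  long$p <- p[cbind(long$aa, long$treatment)]
  ground_truth(long[c("treatment", "aa", "p")], noise_sd = noise_sd)
}

truth_lookup <- function(truth, treatment, aa) {
  key <- paste(treatment, aa, sep = "\r")
  have <- paste(truth$p_microbial$treatment, truth$p_microbial$aa, sep = "\r")
  i <- match(key, have)
  if (anyNA(i)) {
    stop("no ground-truth fraction for pair(s): ",
         paste(unique(paste0("(", treatment[is.na(i)], ", ", aa[is.na(i)],
                             ")")), collapse = ", "), call. = FALSE)
  }
  truth$p_microbial$p[i]
}

#' Simulate an isotope dataset with known ground truth
#'
#' For each individual and amino acid, draws
#' \deqn{\delta_{muscle} = (1 - p)\,\delta_{diet} + p\,\delta_{microbe} +
#'   \varepsilon, \quad \varepsilon \sim N(0, \sigma)}
#' with `p` from the ground truth and end members from `endmembers`.
#' Deterministic given `seed`. A hard internal assertion rejects draws more
#' than 10 noise SDs from the mixture value (which cannot occur in practice).
#'
#' @param design An [experiment_design()].
#' @param truth A [ground_truth()].
#' @param endmembers An `"endmember_set"` covering every (treatment, aa)
#'   pair of the design; missing pairs raise an error naming them.
#' @param seed Integer seed; defaults to the design's seed.
#' @return Data frame with columns `individual_id`, `treatment`, `aa`,
#'   `delta_muscle`.
#' @export
simulate_isotope_dataset <- function(design, truth, endmembers,
                                     seed = design$seed) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "ground_truth"))
  labels <- treatment_labels(design)
  grid <- do.call(rbind, lapply(labels, function(lab) {
    ids <- individual_ids(lab, design$n_individuals)
    expand.grid(individual_id = ids, aa = design$aa,
                stringsAsFactors = FALSE)[, c(1, 2)] |>
      transform(treatment = lab)
  }))
  grid <- grid[c("individual_id", "treatment", "aa")]
  em <- endmember_lookup(endmembers, grid$treatment, grid$aa)
  p <- truth_lookup(truth, grid$treatment, grid$aa)
  mix <- (1 - p) * em$delta_dietary + p * em$delta_microbial
  eps <- with_seed(seed, stats::rnorm(nrow(grid), 0, truth$noise_sd))
  if (truth$noise_sd > 0 && any(abs(eps) > 10 * truth$noise_sd)) {
    stop("simulated noise beyond 10 SD; aborting", call. = FALSE)
  }
  grid$delta_muscle <- mix + eps
  rownames(grid) <- NULL
  grid
}

#' Community profile for synthetic OTU tables
#'
#' Expected phylum-level composition per treatment, the Dirichlet
#' concentration controlling inter-individual variability, and the
#' sequencing depth. Taxa are generated as `taxa_per_phylum` OTUs per
#' phylum, splitting the phylum's expected abundance evenly; each sample's
#' taxon proportions are drawn Dirichlet(concentration x expected) and
#' counts multinomial at the sequencing depth.
#'
#' `default_community_profile()` mirrors the reported structure of this
#' system: ceca dominated (>= 90%) by Firmicutes and Bacteroidetes, roughly
#' even in the two high-protein diets (49.5/46.9% and 45.5/47.6%) and
#' Firmicutes-dominated in the low-protein diets (82.5% and 66.2%).
#'
#' @param phylum_mixture Named list: treatment -> named numeric vector of
#'   expected phylum relative abundances summing to 1.
#' @param dirichlet_concentration Positive scalar; larger means samples
#'   closer to the expectation (default 50).
#' @param sequencing_depth Reads per sample (integer >= 1, default 10000).
#' @param taxa_per_phylum OTUs simulated per phylum (default 8).
#' @return Object of class `"community_profile"`.
#' @export
community_profile <- function(phylum_mixture,
                              dirichlet_concentration = 50,
                              sequencing_depth = 10000L,
                              taxa_per_phylum = 8L) {
  stopifnot(is.list(phylum_mixture), length(phylum_mixture) >= 1,
            dirichlet_concentration > 0, taxa_per_phylum >= 1)
  if (!is.numeric(sequencing_depth) || sequencing_depth < 1 ||
      sequencing_depth != round(sequencing_depth)) {
    stop("sequencing_depth must be a positive integer", call. = FALSE)
  }
  for (lab in names(phylum_mixture)) {
    mx <- phylum_mixture[[lab]]
    if (abs(sum(mx) - 1) > 1e-6 || any(mx < 0)) {
      stop("phylum mixture for '", lab, "' must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  structure(list(phylum_mixture = phylum_mixture,
                 dirichlet_concentration = dirichlet_concentration,
                 sequencing_depth = as.integer(sequencing_depth),
                 taxa_per_phylum = as.integer(taxa_per_phylum)),
            class = "community_profile")
}

#' @rdname community_profile
#' @export
default_community_profile <- function() {
  community_profile(list(
    "40P:40C" = c(Firmicutes = 0.495, Bacteroidetes = 0.469,
                  Proteobacteria = 0.036),
    "21P:45C" = c(Firmicutes = 0.455, Bacteroidetes = 0.476,
                  Proteobacteria = 0.069),
    "12P:55C" = c(Firmicutes = 0.825, Bacteroidetes = 0.125,
                  Proteobacteria = 0.050),
    "9P:75C"  = c(Firmicutes = 0.662, Bacteroidetes = 0.288,
                  Proteobacteria = 0.050)))
}

# representative family names per phylum for the taxonomy sidecar
phylum_families <- function(phylum) {
  fam <- switch(phylum,
    Firmicutes = c("Lactobacillaceae", "Lachnospiraceae", "Ruminococcaceae"),
    Bacteroidetes = c("Bacteroidaceae", "Porphyromonadaceae", "Rikenellaceae",
                      "S24-7"),
    Proteobacteria = "Alcaligenaceae",
    "unclassified")
  fam
}

#' Simulate an OTU table with diet-dependent community structure
#'
#' Draws one sample per (treatment, replicate): taxon proportions from a
#' Dirichlet centred on the treatment's phylum mixture, then counts from a
#' multinomial at the sequencing depth. Row sums equal the depth exactly;
#' reproducible given `seed`.
#'
#' @param profile A [community_profile()]; must cover every requested
#'   treatment.
#' @param treatments Treatment labels; default all labels in the profile.
#' @param n_per_treatment Samples per treatment (default 5, the number of
#'   ceca sequenced per diet).
#' @param sample_ids Optional named list: treatment -> character vector of
#'   ids to use (so OTU samples can share identifiers with isotope
#'   individuals); default generated ids.
#' @param seed Integer seed.
#' @return An [otu_table()].
#' @export
simulate_otu_table <- function(profile,
                               treatments = names(profile$phylum_mixture),
                               n_per_treatment = 5L,
                               sample_ids = NULL,
                               seed = 1L) {
  stopifnot(inherits(profile, "community_profile"), n_per_treatment >= 1)
  miss <- setdiff(treatments, names(profile$phylum_mixture))
  if (length(miss)) {
    stop("no phylum mixture for treatment(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  phyla <- unique(unlist(lapply(profile$phylum_mixture[treatments], names)))
  k <- profile$taxa_per_phylum
  taxonomy <- do.call(rbind, lapply(phyla, function(ph) {
    fams <- phylum_families(ph)
    data.frame(taxon_id = sprintf("%s_OTU%d", substr(ph, 1, 4), seq_len(k)),
               phylum = ph,
               family = rep_len(fams, k),
               stringsAsFactors = FALSE)
  }))
  expected_for <- function(lab) {
    mx <- profile$phylum_mixture[[lab]]
    e <- numeric(nrow(taxonomy))
    for (ph in names(mx)) {
      sel <- taxonomy$phylum == ph
      e[sel] <- mx[[ph]] / sum(sel)
    }
    # phyla absent from this treatment's mixture get a vanishing expectation
    e[e == 0] <- 1e-8
    e / sum(e)
  }
  counts <- with_seed(seed, {
    rows <- list()
    for (lab in treatments) {
      ids <- if (!is.null(sample_ids)) sample_ids[[lab]] else
        sprintf("%s_c%d", gsub("[^A-Za-z0-9]", "", lab),
                seq_len(n_per_treatment))
      stopifnot(length(ids) == n_per_treatment)
      e <- expected_for(lab)
      for (s in ids) {
        pr <- rdirichlet1(profile$dirichlet_concentration * e)
        rows[[s]] <- as.integer(stats::rmultinom(1, profile$sequencing_depth,
                                                 pr))
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- taxonomy$taxon_id
    m
  })
  group <- rep(treatments, each = n_per_treatment)
  names(group) <- rownames(counts)
  otu_table(counts, taxonomy, group)
}

#' Simulate a complete paired experiment
#'
#' Generates everything downstream stages need, with shared sample
#' identifiers: an isotope dataset (`n_individuals` mice per treatment), an
#' OTU table for the first `n_ceca` individuals of each treatment, the end
#' members used, and the ground truth. Isotope and OTU artifacts use
#' separate seeded RNG streams derived from `seed`, so each is independently
#' reproducible.
#'
#' @param design An [experiment_design()].
#' @param truth A [ground_truth()]; default [default_ground_truth()] over the
#'   design's treatments (requires exactly four treatments).
#' @param profile A [community_profile()]; default
#'   [default_community_profile()].
#' @param endmembers End-member set; default built from the design's diets
#'   with default profiles and fractionation.
#' @param n_ceca OTU samples per treatment (default 5; must not exceed
#'   `n_individuals`).
#' @param seed Base seed; defaults to the design's.
#' @return List with elements `isotopes`, `otu`, `endmembers`, `truth`,
#'   `design`.
#' @examples
#' sim <- simulate_experiment(seed = 42)
#' nrow(sim$isotopes)  # 4 diets x 6 mice x 6 amino acids
#' @export
simulate_experiment <- function(design = experiment_design(),
                                truth = NULL,
                                profile = default_community_profile(),
                                endmembers = NULL,
                                n_ceca = 5L,
                                seed = design$seed) {
  stopifnot(inherits(design, "experiment_design"),
            n_ceca >= 1, n_ceca <= design$n_individuals)
  labels <- treatment_labels(design)
  if (is.null(truth)) truth <- default_ground_truth(labels)
  if (is.null(endmembers)) {
    endmembers <- build_endmembers(design$treatments, aa = design$aa)
  }
  bad <- setdiff(labels, names(profile$phylum_mixture))
  if (length(bad)) {
    stop("community profile missing treatment(s): ",
         paste(bad, collapse = ", "), " (treatment labels must be ",
         "consistent across sub-configs)", call. = FALSE)
  }
  iso <- simulate_isotope_dataset(design, truth, endmembers, seed = seed)
  ids <- lapply(labels, function(lab)
    individual_ids(lab, design$n_individuals)[seq_len(n_ceca)])
  names(ids) <- labels
  otu <- simulate_otu_table(profile, treatments = labels,
                            n_per_treatment = n_ceca, sample_ids = ids,
                            seed = seed + 1L)
  list(isotopes = iso, otu = otu, endmembers = endmembers, truth = truth,
       design = design)
}
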