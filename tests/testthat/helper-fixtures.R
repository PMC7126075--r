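# Shared builders for small test fixtures.

# end-member set with a single treatment/AA cell at a chosen separation
single_cell_endmembers <- function(treatment = "T1", aa = "Val",
                                   delta_diet = -26.5,
                                   delta_microbe = -12.1) {
  em <- data.frame(treatment = treatment, aa = aa,
                   delta_dietary = delta_diet,
                   delta_microbial = delta_microbe,
                   stringsAsFactors = FALSE)
  class(em) <- c("endmember_set", "data.frame")
  em
}

# one-diet design with n mice and a single amino acid
single_cell_design <- function(n = 6, aa = "Val", seed = 1) {
  d <- diet_composition("T1", mass_fraction_casein = 0.2,
                        mass_fraction_sucrose = 0.36,
                        mass_fraction_cornmeal = 0.2)
  experiment_design(treatments = list(d), n_individuals = n, aa = aa,
                    seed = seed)
}

single_cell_truth <- function(p = 0.4, noise_sd = 0.5, treatment = "T1",
                              aa = "Val") {
  ground_truth(data.frame(treatment = treatment, aa = aa, p = p,
                          stringsAsFactors = FALSE),
               noise_sd = noise_sd)
}

# small random OTU-style count matrix
random_counts <- function(n_samples, n_taxa, lambda = 20) {
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  rownames(m) <- paste0("s", seq_len(n_samples))
  colnames(m) <- paste0("t", seq_len(n_taxa))
  m
}

# ANOSIM R statistic by direct enumeration-ready computation (independent of
# the package implementation): Clarke's formula on midranks
anosim_r_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  idx <- which(lower.tri(d), arr.ind = TRUE)
  r <- rank(d[lower.tri(d)])
  between <- groups[idx[, 1]] != groups[idx[, 2]]
  (mean(r[between]) - mean(r[!between])) / (n * (n - 1) / 4)
}
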