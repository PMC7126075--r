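test_that("noise-free isotope simulation sits exactly on the end members", {
  em <- single_cell_endmembers(delta_diet = -26.5, delta_microbe = -12.1)
  design <- single_cell_design(n = 4)
  iso0 <- simulate_isotope_dataset(design, single_cell_truth(0, 0), em)
  expect_equal(iso0$delta_muscle, rep(-26.5, 4))
  iso1 <- simulate_isotope_dataset(design, single_cell_truth(1, 0), em)
  expect_equal(iso1$delta_muscle, rep(-12.1, 4))
  iso5 <- simulate_isotope_dataset(design, single_cell_truth(0.5, 0), em)
  expect_equal(iso5$delta_muscle, rep(-19.3, 4))  # closed-form mixture
})

test_that("isotope simulation is deterministic and bounded", {
  em <- single_cell_endmembers()
  design <- single_cell_design(n = 50, seed = 7)
  truth <- single_cell_truth(0.5, noise_sd = 0.5)
  a <- simulate_isotope_dataset(design, truth, em)
  b <- simulate_isotope_dataset(design, truth, em)
  expect_identical(a, b)
  # generated deltas stay within the end-member envelope plus 6 noise SDs
  lo <- min(-26.5, -12.1) - 6 * 0.5
  hi <- max(-26.5, -12.1) + 6 * 0.5
  expect_true(all(a$delta_muscle >= lo & a$delta_muscle <= hi))
})

test_that("simulated deltas converge to the mixture value (law of large numbers)", {
  em <- single_cell_endmembers()
  design <- single_cell_design(n = 10000, seed = 99)
  truth <- single_cell_truth(0.37, noise_sd = 0.5)
  iso <- simulate_isotope_dataset(design, truth, em)
  target <- (1 - 0.37) * -26.5 + 0.37 * -12.1
  se <- 0.5 / sqrt(10000)
  expect_lt(abs(mean(iso$delta_muscle) - target), 3 * se)
})

test_that("missing end members fail naming the treatment and amino acid", {
  em <- single_cell_endmembers(aa = "Val")
  design <- single_cell_design(n = 2, aa = c("Val", "Thr"))
  truth <- ground_truth(data.frame(treatment = "T1", aa = c("Val", "Thr"),
                                   p = 0.2), noise_sd = 0)
  expect_error(simulate_isotope_dataset(design, truth, em), "Thr")
})

test_that("OTU simulation respects depth, integrality and determinism", {
  prof <- default_community_profile()
  a <- simulate_otu_table(prof, n_per_treatment = 3, seed = 5)
  b <- simulate_otu_table(prof, n_per_treatment = 3, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts >= 0))
  expect_true(all(a$counts == round(a$counts)))
  expect_equal(unname(rowSums(a$counts)),
               rep(prof$sequencing_depth, nrow(a$counts)))
  expect_error(community_profile(list(A = c(F1 = 1)), sequencing_depth = 0),
               "positive integer")
  expect_error(community_profile(list(A = c(F1 = 0.5))), "sum to 1")
})

test_that("large concentration and depth converge to the expected mixture", {
  prof <- community_profile(
    list(A = c(Firmicutes = 0.7, Bacteroidetes = 0.3)),
    dirichlet_concentration = 1e7, sequencing_depth = 200000L,
    taxa_per_phylum = 4L)
  otu <- simulate_otu_table(prof, n_per_treatment = 2, seed = 11)
  ra <- relative_abundance(otu, "phylum")
  expect_equal(unname(ra[, "Firmicutes"]), c(0.7, 0.7), tolerance = 0.01)
})

test_that("disjoint dominant phyla yield near-perfect ANOSIM separation", {
  prof <- community_profile(
    list(A = c(Firmicutes = 0.97, Bacteroidetes = 0.03),
         B = c(Firmicutes = 0.03, Bacteroidetes = 0.97)),
    dirichlet_concentration = 80, sequencing_depth = 5000L)
  otu <- simulate_otu_table(prof, n_per_treatment = 5, seed = 13)
  res <- anosim_test(bray_curtis(otu), otu$group, n_perm = 199, seed = 1)
  expect_gt(res$statistic, 0.9)
  expect_lt(res$p_value, 0.05)
})

test_that("the full synthetic experiment pairs samples and reproduces itself", {
  sim <- simulate_experiment(seed = 42)
  expect_equal(nrow(sim$isotopes), 4 * 6 * 6)
  expect_equal(nrow(sim$otu$counts), 4 * 5)
  # ceca samples are a subset of isotope individuals (shared identifiers)
  expect_true(all(rownames(sim$otu$counts) %in%
                    sim$isotopes$individual_id))
  # per-treatment group labels agree between the two artifacts
  iso_map <- unique(sim$isotopes[c("individual_id", "treatment")])
  expect_equal(unname(sim$otu$group[iso_map$individual_id[
    iso_map$individual_id %in% names(sim$otu$group)]]),
    iso_map$treatment[iso_map$individual_id %in% names(sim$otu$group)])
  sim2 <- simulate_experiment(seed = 42)
  expect_identical(sim$isotopes, sim2$isotopes)
  expect_identical(sim$otu$counts, sim2$otu$counts)
  # different seed changes the draws
  sim3 <- simulate_experiment(seed = 43)
  expect_false(identical(sim$isotopes$delta_muscle,
                         sim3$isotopes$delta_muscle))
})

test_that("inconsistent treatment labels across sub-configs are rejected", {
  design <- experiment_design(treatments = list(
    diet_composition("X1", 0.2, 0.36, 0.2)))
  expect_error(
    simulate_experiment(design, truth = single_cell_truth(0.2, 0.5, "X1"),
                        profile = default_community_profile()),
    "missing treatment")
})

test_that("a single-replicate design is valid with SE reported as undefined", {
  design <- single_cell_design(n = 1)
  sim_iso <- simulate_isotope_dataset(design, single_cell_truth(0.4, 0.5),
                                      single_cell_endmembers())
  s <- contribution_table(estimate_mixing(sim_iso,
                                          single_cell_endmembers()))
  expect_equal(s$n, 1)
  expect_true(is.na(s$se))
  expect_false(is.na(s$mean))
})
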