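low_protein_diet <- function() {
  diet_composition("9P:75C", mass_fraction_casein = 0.051,
                   mass_fraction_sucrose = 0.36,
                   mass_fraction_cornmeal = 0.39)
}

test_that("protein source split follows casein and cornmeal protein masses", {
  f <- protein_source_fractions(low_protein_diet())
  expect_equal(unname(f["cornmeal"]), 0.039 / 0.090, tolerance = 1e-12)
  expect_equal(sum(f), 1)

  no_corn <- diet_composition("NC", 0.2, 0.36, 0)
  expect_equal(unname(protein_source_fractions(no_corn)["casein"]), 1)

  corn_no_protein <- diet_composition("CNP", 0.2, 0.36, 0.3,
                                      cornmeal_protein_fraction = 0)
  expect_equal(unname(protein_source_fractions(corn_no_protein)["casein"]), 1)

  zero_protein <- diet_composition("ZP", 0, 0.36, 0.3,
                                   cornmeal_protein_fraction = 0)
  expect_error(protein_source_fractions(zero_protein), "no protein")
})

test_that("diet composition validates mass fractions", {
  expect_error(diet_composition("bad", 0.5, 0.36, 0.3, 0.2), "sum to")
  expect_error(diet_composition("bad", -0.1, 0.36, 0.3), "\\[0, 1\\]")
})

test_that("dietary end member is concentration-weighted two-source mixing", {
  d <- low_protein_diet()
  eq <- aa_profile("x", c(Val = 0.05, Leu = 0.05))
  delta <- dietary_aa_delta(d, eq, eq)
  # equal concentrations collapse to protein-fraction weighting
  f <- protein_source_fractions(d)
  oracle <- f["casein"] * -26.5 + f["cornmeal"] * -12.0
  expect_equal(unname(delta["Val"]), unname(oracle), tolerance = 1e-12)
  expect_equal(unname(delta["Val"]), -20.22, tolerance = 1e-2)

  # single-source collapse when cornmeal lacks the amino acid
  corn0 <- aa_profile("corn", c(Val = 0))
  expect_equal(unname(dietary_aa_delta(d, aa_profile("cas", c(Val = 0.05)),
                                       corn0)["Val"]), -26.5)

  # scale invariance: doubling all concentrations changes nothing
  twice <- aa_profile("x", c(Val = 0.10, Leu = 0.10))
  expect_equal(dietary_aa_delta(d, twice, twice), delta)

  # zero in both sources -> NA with a warning naming the amino acid
  z <- aa_profile("z", c(Val = 0, Leu = 0.05))
  expect_warning(res <- dietary_aa_delta(d, z, z), "Val")
  expect_true(is.na(res["Val"]))
  expect_false(is.na(res["Leu"]))
})

test_that("dietary end member stays within the source delta range", {
  set.seed(7)
  for (k in 1:25) {
    corn <- runif(1, 0.01, 0.3)
    cas <- runif(1, 0.01, 0.35)
    d <- diet_composition("r", cas, 0.3, corn)
    prof_a <- aa_profile("a", c(Val = runif(1, 0.001, 0.2)))
    prof_b <- aa_profile("b", c(Val = runif(1, 0.001, 0.2)))
    delta <- dietary_aa_delta(d, prof_a, prof_b)["Val"]
    expect_gte(delta, min(d$delta_casein, d$delta_cornmeal) - 1e-12)
    expect_lte(delta, max(d$delta_casein, d$delta_cornmeal) + 1e-12)
  }
})

test_that("carbohydrate pool delta is mass-weighted over sucrose and cornmeal", {
  # explicit weights: sucrose 0.36 at -12.2, cornmeal carb 0.39 at -12.0
  d <- diet_composition("x", 0.0, 0.36, 0.39,
                        cornmeal_protein_fraction = 0,
                        cornmeal_carbohydrate_fraction = 1,
                        mass_fraction_other = 0.25)
  expect_equal(carbohydrate_pool_delta(d),
               (0.36 * -12.2 + 0.39 * -12.0) / 0.75, tolerance = 1e-12)
  expect_equal(carbohydrate_pool_delta(d), -12.096, tolerance = 1e-3)

  no_corn <- diet_composition("nc", 0.2, 0.36, 0)
  expect_equal(carbohydrate_pool_delta(no_corn), -12.2)

  same <- diet_composition("same", 0.2, 0.36, 0.2, delta_sucrose = -12,
                           delta_cornmeal = -12)
  expect_equal(carbohydrate_pool_delta(same), -12)

  no_carb <- diet_composition("nocarb", 0.5, 0, 0,
                              mass_fraction_other = 0.5)
  expect_error(carbohydrate_pool_delta(no_carb), "no carbohydrate")
})

test_that("microbial end member adds the fractionation offset", {
  ft <- fractionation_table(c(Val = -3.0, Leu = 0))
  em <- microbial_endmember_delta(-12.1, ft)
  expect_equal(unname(em["Val"]), -15.1)
  expect_equal(unname(em["Leu"]), -12.1)  # zero offset = pool value
  # translation equivariance
  shifted <- microbial_endmember_delta(-11.1, ft)
  expect_equal(shifted, em + 1)
  expect_error(microbial_endmember_delta(-12.1, ft, aa = c("Val", "Thr")),
               "Thr")
})

test_that("end-member set is total over the treatment x amino-acid grid", {
  em <- build_endmembers(default_diets())
  expect_equal(nrow(em), 4 * 6)
  expect_true(all(is.finite(em$delta_dietary)))
  expect_true(all(is.finite(em$delta_microbial)))
  expect_equal(nrow(unique(em[c("treatment", "aa")])), 24)
  # routing offset shifts only the dietary end member
  em2 <- build_endmembers(default_diets(), routing_offset = 1.5)
  expect_equal(em2$delta_dietary, em$delta_dietary + 1.5)
  expect_equal(em2$delta_microbial, em$delta_microbial)
})
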