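test_that("relative abundance aggregates and normalizes per sample", {
  counts <- rbind(s1 = c(60L, 40L, 0L), s2 = c(10L, 0L, 0L))
  colnames(counts) <- c("f1", "b1", "b2")
  tax <- data.frame(taxon_id = c("f1", "b1", "b2"),
                    phylum = c("Firmicutes", "Bacteroidetes",
                               "Bacteroidetes"),
                    family = c("Lactobacillaceae", "Bacteroidaceae", ""))
  otu <- otu_table(counts, tax, c(s1 = "A", s2 = "A"))
  ra <- relative_abundance(otu, "phylum")
  expect_equal(ra["s1", "Firmicutes"], 0.6)
  expect_equal(ra["s1", "Bacteroidetes"], 0.4)
  expect_equal(ra["s2", "Firmicutes"], 1)  # single-phylum sample
  expect_equal(unname(rowSums(ra)), c(1, 1))
  # proportions invariant to library size
  otu10 <- otu_table(counts * 10L, tax, c(s1 = "A", s2 = "A"))
  expect_equal(relative_abundance(otu10, "phylum"), ra)
  # unassigned families pool as unclassified
  raf <- relative_abundance(otu, "family")
  expect_true("unclassified" %in% colnames(raf))
  # empty samples are excluded with a warning
  counts0 <- rbind(counts, s3 = c(0L, 0L, 0L))
  otu0 <- otu_table(counts0, tax, c(s1 = "A", s2 = "A", s3 = "A"))
  expect_warning(ra0 <- relative_abundance(otu0, "phylum"), "s3")
  expect_equal(nrow(ra0), 2)
})

test_that("Shannon diversity matches closed forms and vegan", {
  expect_equal(shannon_diversity(rep(1, 4)), log(4))
  expect_equal(shannon_diversity(c(5, 0, 0)), 0)
  expect_equal(shannon_diversity(c(8, 2)),
               -0.8 * log(0.8) - 0.2 * log(0.2))
  expect_error(shannon_diversity(c(0, 0)), "all-zero")
  set.seed(5)
  m <- random_counts(6, 12)
  expect_equal(unname(shannon_diversity(m)),
               unname(vegan::diversity(m, index = "shannon")))
})

test_that("Bray-Curtis matches its formula, bounds, and vegan", {
  x <- rbind(a = c(6, 0, 2), b = c(0, 4, 2))
  expect_equal(bray_curtis(x, scale = FALSE)["a", "b"], 10 / 14)
  same <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(bray_curtis(same, scale = FALSE)["a", "b"], 0)
  disjoint <- rbind(a = c(1, 0), b = c(0, 5))
  expect_equal(bray_curtis(disjoint, scale = TRUE)["a", "b"], 1)

  set.seed(9)
  for (k in 1:10) {
    m <- random_counts(5, 8)
    d <- bray_curtis(m, scale = FALSE)
    expect_true(isSymmetric(unname(d)))
    expect_equal(unname(diag(d)), rep(0, 5))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(unname(d),
                 unname(as.matrix(vegan::vegdist(m, method = "bray"))))
  }
  # total-sum scaling matches vegan on proportions
  m <- random_counts(6, 10)
  prop <- sweep(m, 1, rowSums(m), "/")
  expect_equal(unname(bray_curtis(m, scale = TRUE)),
               unname(as.matrix(vegan::vegdist(prop, method = "bray"))))
})

test_that("ANOSIM reproduces the hand-ranked separated example", {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  # ranks: two within distances at midrank 1.5, four between at 4.5;
  # R = (4.5 - 1.5) / (4*3/4) = 1
  res <- anosim_test(d, c("g1", "g1", "g2", "g2"), n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("ANOSIM statistic agrees with vegan and is centered under the null", {
  set.seed(21)
  m <- random_counts(10, 15)
  g <- rep(c("A", "B"), each = 5)
  d <- bray_curtis(m, scale = FALSE)
  ours <- anosim_test(d, g, n_perm = 99, seed = 2)
  veg <- vegan::anosim(as.dist(d), grouping = factor(g), permutations = 99)
  expect_equal(ours$statistic, unname(veg$statistic), tolerance = 1e-10)
  expect_true(abs(ours$statistic) <= 1)
  # permuted statistics have mean near zero (null symmetry)
  big <- anosim_test(d, g, n_perm = 999, seed = 3)
  expect_lt(abs(mean(big$permuted)), 0.05)
})

test_that("ANOSIM permutation p matches exhaustive enumeration at n = 6", {
  set.seed(33)
  m <- random_counts(6, 10)
  g <- rep(c("A", "B"), each = 3)
  d <- bray_curtis(m, scale = FALSE)
  r_obs <- anosim_r_oracle(d, g)
  # enumerate all 6!/(3!3!) = 20 distinct assignments of 3 labels
  combs <- combn(6, 3)
  r_all <- apply(combs, 2, function(ix) {
    gg <- rep("B", 6); gg[ix] <- "A"
    anosim_r_oracle(d, gg)
  })
  p_exact <- mean(r_all >= r_obs - 1e-12)
  res <- anosim_test(d, g, n_perm = 999, seed = 4)
  expect_equal(res$statistic, r_obs, tolerance = 1e-12)
  mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 999) + 2 / 999
  expect_lt(abs(res$p_value - p_exact), mc_err + 1e-9)
})

test_that("PCoA reconstructs Euclidean-embeddable distances", {
  set.seed(13)
  pts <- matrix(rnorm(5 * 3), 5, 3,
                dimnames = list(paste0("s", 1:5), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa_ord(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)
  # eigenvalues agree with classical MDS
  cs <- cmdscale(d, k = 3, eig = TRUE)
  expect_equal(ord$eigenvalues[1:3], cs$eig[1:3], tolerance = 1e-8)
})

test_that("PCoA handles collinear, symmetric and duplicate configurations", {
  # 3 collinear points: d(1,2)=1, d(1,3)=1, d(2,3)=2 -> one positive axis
  d <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3,
              dimnames = list(1:3, 1:3))
  ord <- pcoa_ord(d)
  expect_equal(ncol(ord$coordinates), 1)
  expect_equal(as.matrix(dist(ord$coordinates)), unname(d) + 0 * d,
               ignore_attr = TRUE, tolerance = 1e-10)
  # equilateral triangle -> two equal eigenvalues
  de <- matrix(1, 3, 3) - diag(3)
  orde <- pcoa_ord(de)
  expect_equal(orde$eigenvalues[1], orde$eigenvalues[2], tolerance = 1e-10)
  # duplicate sample -> coincident coordinates
  dd <- as.matrix(dist(rbind(c(0, 0), c(0, 0), c(3, 4))))
  ordd <- pcoa_ord(dd)
  expect_equal(ordd$coordinates[1, ], ordd$coordinates[2, ],
               tolerance = 1e-10)
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("negative eigenvalues are reported and Lingoes correction removes them", {
  set.seed(17)
  d <- bray_curtis(random_counts(8, 12, lambda = 3))
  d <- bray_curtis(random_counts(8, 12, lambda = 3))  # second draw is non-Euclidean
  ord <- pcoa_ord(d)
  expect_true(length(ord$negative_eigenvalues) > 0)  # Bray-Curtis typical
  ordl <- pcoa_ord(d, correction = "lingoes")
  expect_length(ordl$negative_eigenvalues, 0)
})

test_that("axis selection takes the smallest set reaching the variance target", {
  set.seed(19)
  d <- as.matrix(dist(matrix(rnorm(10 * 4), 10, 4)))
  ord <- pcoa_ord(d)
  ax <- select_pcoa_axes(ord, min_prop = 0.8)
  k <- ncol(ax)
  expect_gte(sum(ord$rel_eig[1:k]), 0.8 - 1e-9)
  if (k > 1) expect_lt(sum(ord$rel_eig[1:(k - 1)]), 0.8)
  expect_lte(ncol(select_pcoa_axes(ord, min_prop = 1)), nrow(d) - 2)
})

test_that("db-RDA matches closed forms and vegan's constrained proportion", {
  set.seed(23)
  X <- matrix(rnorm(12 * 2), 12, 2)
  B <- matrix(c(1, -0.5, 0.3, 0.8, -1, 0.2), 2, 3)
  # exact linear response: R2 = 1, p at its floor
  Y <- X %*% B
  res <- dbrda_test(Y, X, n_perm = 99, seed = 1)
  expect_equal(res$r2, 1, tolerance = 1e-12)
  expect_equal(res$p_perm, 1 / 100)
  # single axis, single response: R2 equals squared Pearson correlation
  x1 <- rnorm(15); y1 <- 0.6 * x1 + rnorm(15)
  res1 <- dbrda_test(y1, x1, n_perm = 99, seed = 2)
  expect_equal(res1$r2, cor(x1, y1)^2, tolerance = 1e-12)
  # multivariate noisy case against vegan::rda
  Yn <- Y + matrix(rnorm(36), 12, 3)
  resn <- dbrda_test(Yn, X, n_perm = 99, seed = 3)
  v <- vegan::rda(Yn ~ X)
  expect_equal(resn$r2, unname(v$CCA$tot.chi / v$tot.chi),
               tolerance = 1e-10)
  expect_equal(resn$r2_adjusted,
               unname(vegan::RsquareAdj(v)$adj.r.squared), tolerance = 1e-10)
})

test_that("db-RDA guards rank deficiency and sample shortage", {
  set.seed(29)
  x <- rnorm(10)
  X <- cbind(x, 2 * x)  # rank 1
  Y <- matrix(rnorm(20), 10, 2)
  expect_warning(res <- dbrda_test(Y, X, n_perm = 19, seed = 1),
                 "rank-deficient")
  expect_equal(res$n_axes_used, 1)
  expect_error(dbrda_test(matrix(rnorm(8), 4, 2), matrix(rnorm(12), 4, 3),
                          n_perm = 19), "too few samples")
})

test_that("db-RDA detects a built-in community-isotope dependence", {
  # strong dependence: response constructed from the predictor axes
  set.seed(31)
  hits <- 0
  n_runs <- 60
  for (k in seq_len(n_runs)) {
    X <- matrix(rnorm(12 * 2), 12, 2)
    Y <- X %*% matrix(rnorm(6), 2, 3) * 1.5 + matrix(rnorm(36, sd = 0.8),
                                                     12, 3)
    if (dbrda_test(Y, X, n_perm = 99)$p_perm < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.8)
})

test_that("Spearman correlation matches rank formula, base R, and flags ties", {
  expect_equal(rank_correlation(1:5, 2 * (1:5), n_perm = 19, seed = 1)$rho, 1)
  expect_equal(rank_correlation(1:5, 5:1, n_perm = 19, seed = 1)$rho, -1)
  r <- rank_correlation(1:4, c(2, 1, 4, 3), n_perm = 199, seed = 1)
  expect_equal(r$rho, 0.6)
  set.seed(37)
  x <- rnorm(20); y <- x + rnorm(20)
  expect_equal(rank_correlation(x, y, n_perm = 19, seed = 1)$rho,
               cor(x, y, method = "spearman"))
  # midrank ties agree with base R too
  xt <- c(1, 1, 2, 3, 3); yt <- c(2, 1, 1, 3, 3)
  expect_equal(rank_correlation(xt, yt, n_perm = 19, seed = 1)$rho,
               cor(xt, yt, method = "spearman"))
  expect_error(rank_correlation(rep(1, 5), 1:5, n_perm = 19), "constant")
})

test_that("Firmicutes:Bacteroidetes summary tracks the phylum table", {
  sim <- simulate_experiment(seed = 8)
  fb <- firmicutes_bacteroidetes(sim$otu)
  ra <- relative_abundance(sim$otu, "phylum")
  expect_equal(fb$firmicutes, unname(ra[, "Firmicutes"]))
  expect_equal(fb$fb_ratio, fb$firmicutes / fb$bacteroidetes)
  expect_equal(nrow(fb), 20)
})
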