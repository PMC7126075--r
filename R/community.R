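#' OTU table container
#'
#' Samples-by-taxa count matrix with a taxonomy sidecar and per-sample
#' treatment labels.
#'
#' @param counts Integer matrix, samples in rows, taxa in columns, with
#'   dimnames; counts must be non-negative.
#' @param taxonomy Data frame with columns `taxon_id`, `phylum`, `family`
#'   covering every column of `counts`.
#' @param group Named character vector mapping every sample to its treatment
#'   label.
#' @return Object of class `"aamix_otu"`.
#' @export
otu_table <- function(counts, taxonomy, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample rownames and taxon colnames", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(all(c("taxon_id", "phylum", "family") %in% names(taxonomy)))
  miss_tax <- setdiff(colnames(counts), taxonomy$taxon_id)
  if (length(miss_tax)) {
    stop("taxa without taxonomy: ", paste(miss_tax, collapse = ", "),
         call. = FALSE)
  }
  miss_grp <- setdiff(rownames(counts), names(group))
  if (length(miss_grp)) {
    stop("samples without group label: ", paste(miss_grp, collapse = ", "),
         call. = FALSE)
  }
  structure(list(counts = counts,
                 taxonomy = taxonomy[match(colnames(counts),
                                           taxonomy$taxon_id), , drop = FALSE],
                 group = group[rownames(counts)]),
            class = "aamix_otu")
}

#' @export
print.aamix_otu <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa;",
      length(unique(x$group)), "treatment group(s)\n")
  invisible(x)
}

#' Relative abundance at a taxonomic rank
#'
#' Aggregates counts to phylum or family (taxa unassigned at that rank are
#' pooled as `"unclassified"`) and converts to per-sample proportions.
#' Samples with zero total counts are excluded with a warning.
#'
#' @param otu An [otu_table()].
#' @param rank `"phylum"`, `"family"`, or `"taxon"` (no aggregation).
#' @return Numeric matrix, samples x rank levels, rows summing to 1.
#' @export
relative_abundance <- function(otu, rank = c("phylum", "family", "taxon")) {
  rank <- match.arg(rank)
  stopifnot(inherits(otu, "aamix_otu"))
  counts <- otu$counts
  if (rank != "taxon") {
    lev <- otu$taxonomy[[rank]]
    lev[is.na(lev) | lev == ""] <- "unclassified"
    agg <- t(rowsum(t(counts), lev))
    counts <- agg
  }
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning("excluding sample(s) with zero counts: ",
            paste(rownames(counts)[tot == 0], collapse = ", "),
            call. = FALSE)
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(counts, 1, tot, "/")
}

#' Firmicutes:Bacteroidetes summary
#'
#' Per-sample relative abundances of the two dominant phyla and their ratio,
#' alongside the treatment label — the summary used to relate community
#' structure to dietary protein content.
#'
#' @param otu An [otu_table()].
#' @return Data frame with columns `sample`, `treatment`, `firmicutes`,
#'   `bacteroidetes`, `fb_ratio`.
#' @export
firmicutes_bacteroidetes <- function(otu) {
  ra <- relative_abundance(otu, "phylum")
  f <- if ("Firmicutes" %in% colnames(ra)) ra[, "Firmicutes"] else 0
  b <- if ("Bacteroidetes" %in% colnames(ra)) ra[, "Bacteroidetes"] else 0
  data.frame(sample = rownames(ra),
             treatment = as.character(otu$group[rownames(ra)]),
             firmicutes = as.numeric(f), bacteroidetes = as.numeric(b),
             fb_ratio = as.numeric(ifelse(b > 0, f / b, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Shannon diversity
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over nonzero proportions, in nats.
#'
#' @param x Count or proportion vector, or a samples-x-taxa matrix (row-wise).
#' @return Numeric scalar or per-sample vector.
#' @examples
#' shannon_diversity(c(8, 2))        # about 0.5004
#' shannon_diversity(rep(1, 4))      # log(4)
#' @export
shannon_diversity <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, shannon_diversity))
  stopifnot(is.numeric(x), all(x >= 0))
  tot <- sum(x)
  if (tot == 0) stop("all-zero sample: diversity undefined", call. = FALSE)
  p <- x[x > 0] / tot
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between all pairs
#' of sample rows. With `scale = TRUE` (default) each sample is first
#' total-sum-scaled to proportions, so the dissimilarity compares
#' compositions rather than library sizes.
#'
#' @param x Samples-x-taxa numeric matrix (counts or proportions) or an
#'   [otu_table()].
#' @param scale Total-sum-scale rows to proportions first (default `TRUE`).
#' @return Symmetric matrix with zero diagonal and entries in \[0, 1\];
#'   a pair of all-zero samples gives `NA` with a warning.
#' @examples
#' bray_curtis(rbind(a = c(6, 0, 2), b = c(0, 4, 2)), scale = FALSE)  # 10/14
#' @export
bray_curtis <- function(x, scale = TRUE) {
  if (inherits(x, "aamix_otu")) x <- x$counts
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, all(x >= 0))
  if (scale) {
    tot <- rowSums(x)
    nz <- tot > 0
    x[nz, ] <- sweep(x[nz, , drop = FALSE], 1, tot[nz], "/")
  }
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(x[i, ] + x[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) NA_real_ else
        sum(abs(x[i, ] - x[j, ])) / denom
    }
  }
  if (anyNA(d)) {
    warning("Bray-Curtis undefined for pair(s) of all-zero samples",
            call. = FALSE)
  }
  d
}

# lower-triangle pair indices of an n x n matrix
lower_pairs <- function(n) {
  j <- rep(seq_len(n - 1), times = (n - 1):1)
  i <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  cbind(i = i, j = j)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a distance matrix
#' (Clarke 1993). Distances are converted to midranks; the statistic is
#' \deqn{R = \frac{\bar r_B - \bar r_W}{n(n-1)/4}}
#' where \eqn{\bar r_B} and \eqn{\bar r_W} are mean ranks of between- and
#' within-group distances. R lies in \[-1, 1\]; values near 1 indicate that
#' all between-group distances exceed all within-group ones. Significance is
#' assessed by permuting group labels:
#' \eqn{p = (1 + \#\{R^* \ge R\}) / (1 + n_{perm})}.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param groups Group label per sample (length = number of samples); at
#'   least two groups with two or more members each.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @return List of class `"anosim_test"`: `statistic` (R), `p_value`,
#'   `n_perm`, `permuted` (vector of permuted R values).
#' @examples
#' d <- matrix(1, 4, 4) - diag(4); d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0
#' anosim_test(d, c("a", "a", "b", "b"), n_perm = 99, seed = 1)$statistic  # 1
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(isSymmetric(unname(d)), length(groups) == n, n_perm >= 1)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("ANOSIM needs at least two groups with at least two members each",
         call. = FALSE)
  }
  pr <- lower_pairs(n)
  r <- rank(d[pr])  # midranks
  divisor <- n * (n - 1) / 4
  stat_for <- function(g) {
    between <- g[pr[, 1]] != g[pr[, 2]]
    (mean(r[between]) - mean(r[!between])) / divisor
  }
  r_obs <- stat_for(groups)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) stat_for(sample(groups)), numeric(1))
  })
  p <- (1 + sum(permuted >= r_obs)) / (1 + n_perm)
  structure(list(statistic = r_obs, p_value = p, n_perm = n_perm,
                 permuted = permuted),
            class = "anosim_test")
}

#' @export
print.anosim_test <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Principal coordinates analysis (PCoA)
#'
#' Classical metric scaling of a distance matrix: Gower double-centering of
#' \eqn{-d^2/2} followed by eigen-decomposition. Axes are ordered by
#' descending eigenvalue; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues, so pairwise Euclidean distances of
#' the coordinates reproduce the input distances when the matrix is
#' Euclidean-embeddable. Negative eigenvalues (common for Bray-Curtis) are
#' reported and their axes dropped by default; `correction = "lingoes"`
#' instead adds the smallest constant to all squared off-diagonal distances
#' that makes the matrix embeddable.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param correction `"none"` (default) or `"lingoes"`.
#' @param eig_tol Relative tolerance below which eigenvalues are treated as
#'   zero.
#' @return List of class `"pcoa_ord"`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `rel_eig` (positive eigenvalues as
#'   proportions of their sum), `negative_eigenvalues`, `correction`.
#' @export
pcoa_ord <- function(d, correction = c("none", "lingoes"), eig_tol = 1e-9) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric",
                                    call. = FALSE)
  n <- nrow(d)
  d2 <- d^2
  if (correction == "lingoes") {
    ev0 <- eigen(gower_center(d2), symmetric = TRUE, only.values = TRUE)$values
    c1 <- -min(ev0)
    if (c1 > 0) d2 <- d2 + 2 * c1 * (1 - diag(n))
  }
  B <- gower_center(d2)
  ee <- eigen(B, symmetric = TRUE)
  vals <- ee$values
  tol <- eig_tol * max(abs(vals), 1)
  pos <- which(vals > tol)
  coords <- ee$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 rel_eig = vals[pos] / sum(vals[pos]),
                 negative_eigenvalues = vals[vals < -tol],
                 correction = correction),
            class = "pcoa_ord")
}

gower_center <- function(d2) {
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% d2 %*% J
}

#' Select leading PCoA axes
#'
#' The smallest set of leading axes explaining at least `min_prop` of the
#' positive-eigenvalue variance, capped at `n - 2` axes so downstream
#' regression keeps residual degrees of freedom.
#'
#' @param ord A [pcoa_ord()] result.
#' @param min_prop Target proportion of positive-eigenvalue variance
#'   (default 0.8).
#' @param max_axes Cap; default `n - 2`.
#' @return Coordinate matrix restricted to the selected axes.
#' @export
select_pcoa_axes <- function(ord, min_prop = 0.8, max_axes = NULL) {
  stopifnot(inherits(ord, "pcoa_ord"), min_prop > 0, min_prop <= 1)
  n <- nrow(ord$coordinates)
  if (is.null(max_axes)) max_axes <- max(1L, n - 2L)
  k <- which(cumsum(ord$rel_eig) >= min_prop - 1e-12)[1]
  if (is.na(k)) k <- length(ord$rel_eig)
  k <- min(k, max_axes, ncol(ord$coordinates))
  ord$coordinates[, seq_len(k), drop = FALSE]
}

#' Distance-based redundancy analysis (db-RDA)
#'
#' Multivariate least-squares fit of a response matrix `Y` (here: per-sample
#' amino acid \eqn{\delta^{13}}C values) on predictor axes `X` (here: leading
#' PCoA axes of a Bray-Curtis matrix). Columns of `Y` are centered; the
#' constrained proportion of variance is
#' \eqn{R^2 = \mathrm{tr}(\hat Y^\top \hat Y)/\mathrm{tr}(Y^\top Y)}, with
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - m - 1)} and pseudo-F
#' \eqn{(R^2/m) / ((1 - R^2)/(n - m - 1))} for `m` predictors. Significance
#' is assessed by permuting the rows of `Y`:
#' \eqn{p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})}. An AIC in the Gaussian
#' least-squares form (`N log(RSS/N) + 2 q (m + 1)` with `N = n q` response
#' cells) is reported for comparability, not used for selection.
#'
#' @param Y Numeric response matrix (samples x variables) or vector.
#' @param X Numeric predictor matrix (samples x axes) or vector.
#' @param n_perm Row permutations (default 999, the study used 1000).
#' @param seed Optional integer seed.
#' @return List of class `"dbrda_test"`: `r2`, `r2_adjusted`, `f_stat`,
#'   `p_perm`, `n_perm`, `n_axes_used`, `aic`, `permuted_f`.
#' @export
dbrda_test <- function(Y, X, n_perm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  stopifnot(nrow(X) == n, n_perm >= 1)
  qrX <- qr(cbind(1, X))
  rank_x <- qrX$rank - 1L  # predictors beyond the intercept
  if (rank_x < ncol(X)) {
    warning("rank-deficient predictors: using ", rank_x, " of ", ncol(X),
            " axes", call. = FALSE)
  }
  m <- rank_x
  if (n <= m + 1) {
    stop("too few samples (", n, ") for ", m, " predictor axes", call. = FALSE)
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  tss <- sum(Yc^2)
  if (tss == 0) stop("response matrix has zero variance", call. = FALSE)
  fitted_ss <- function(Ym) {
    H <- qr.fitted(qrX, Ym)  # includes intercept; Ym centered so = projection
    sum(H^2)
  }
  r2 <- fitted_ss(Yc) / tss
  r2 <- min(max(r2, 0), 1)
  f_from_r2 <- function(r2) (r2 / m) / ((1 - r2) / (n - m - 1))
  f_obs <- f_from_r2(r2)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      Yp <- Yc[sample.int(n), , drop = FALSE]
      f_from_r2(min(fitted_ss(Yp) / tss, 1))
    }, numeric(1))
  })
  p <- (1 + sum(permuted >= f_obs)) / (1 + n_perm)
  q <- ncol(Yc)
  rss <- (1 - r2) * tss
  N <- n * q
  aic <- N * log(rss / N) + 2 * q * (m + 1)
  structure(list(r2 = r2,
                 r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - m - 1),
                 f_stat = f_obs, p_perm = p, n_perm = n_perm,
                 n_axes_used = m, aic = aic, permuted_f = permuted),
            class = "dbrda_test")
}

#' @export
print.dbrda_test <- function(x, ...) {
  cat(sprintf(
    "db-RDA: R2 = %.3f, adj R2 = %.3f, F = %.3f, p = %.4g (%d perms, %d axes)\n",
    x$r2, x$r2_adjusted, x$f_stat, x$p_perm, x$n_perm, x$n_axes_used))
  invisible(x)
}

#' Link community composition to amino acid isotope values
#'
#' Full db-RDA pipeline: Bray-Curtis dissimilarities among OTU samples, PCoA,
#' selection of leading axes ([select_pcoa_axes()]), then [dbrda_test()] of
#' the per-sample amino acid \eqn{\delta^{13}}C matrix against those axes.
#' Only samples present in both datasets are used. With
#' `direction = "community_response"` the roles are swapped (PCoA axes as
#' response, isotope matrix as predictors); the default treats isotopes as
#' the response.
#'
#' @param otu An [otu_table()].
#' @param isotopes Isotope data frame (`individual_id`, `aa`,
#'   `delta_muscle`); individuals are matched to OTU sample names.
#' @param direction `"isotope_response"` (default) or `"community_response"`.
#' @param axis_prop Passed to [select_pcoa_axes()] (default 0.8).
#' @param n_perm,seed Passed to [dbrda_test()].
#' @return A `"dbrda_test"` result with attribute `"n_samples"`.
#' @export
community_isotope_association <- function(otu, isotopes,
                                          direction = c("isotope_response",
                                                        "community_response"),
                                          axis_prop = 0.8,
                                          n_perm = 999, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(otu, "aamix_otu"))
  Y <- isotope_matrix(isotopes)
  shared <- intersect(rownames(otu$counts), rownames(Y))
  if (length(shared) < 4) {
    stop("too few shared samples between OTU table and isotope dataset (",
         length(shared), ")", call. = FALSE)
  }
  d <- bray_curtis(otu$counts[shared, , drop = FALSE])
  ax <- select_pcoa_axes(pcoa_ord(d), min_prop = axis_prop)
  Y <- Y[shared, , drop = FALSE]
  res <- if (direction == "isotope_response") {
    dbrda_test(Y, ax, n_perm = n_perm, seed = seed)
  } else {
    dbrda_test(ax, Y, n_perm = n_perm, seed = seed)
  }
  attr(res, "n_samples") <- length(shared)
  res
}

# long isotope records -> samples x AA matrix
isotope_matrix <- function(isotopes) {
  stopifnot(all(c("individual_id", "aa", "delta_muscle") %in%
                  names(isotopes)))
  ids <- unique(isotopes$individual_id)
  aas <- unique(isotopes$aa)
  m <- matrix(NA_real_, length(ids), length(aas),
              dimnames = list(ids, aas))
  m[cbind(match(isotopes$individual_id, ids), match(isotopes$aa, aas))] <-
    isotopes$delta_muscle
  if (anyNA(m)) {
    stop("isotope dataset is not complete over individuals x amino acids",
         call. = FALSE)
  }
  m
}

#' Spearman rank correlation with permutation p-value
#'
#' Spearman's rho computed as the Pearson correlation of midranks, with a
#' two-sided permutation p-value (`|rho*| >= |rho|` under shuffles of `y`).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param n_perm Permutations (default 999).
#' @param seed Optional integer seed.
#' @return List of class `"rank_correlation"`: `rho`, `p_perm`, `n_perm`.
#' @examples
#' rank_correlation(1:4, c(2, 1, 4, 3), n_perm = 99, seed = 1)$rho  # 0.6
#' @export
rank_correlation <- function(x, y, n_perm = 999, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant vector: rank correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) stats::cor(rx, sample(ry)),
           numeric(1))
  })
  p <- (1 + sum(abs(permuted) >= abs(rho) - 1e-12)) / (1 + n_perm)
  structure(list(rho = rho, p_perm = p, n_perm = n_perm),
            class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, permutation p = %.4g (%d perms)\n",
              x$rho, x$p_perm, x$n_perm))
  invisible(x)
}
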